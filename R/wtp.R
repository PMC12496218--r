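#' Marginal WTP for a log-transformed attribute
#'
#' For attributes entering utility as `beta * log(L)`, the marginal WTP at
#' level `L` is `beta / L`; at the lowest program-relevant level (`L = 1`)
#' it equals `beta` itself, which is how headline WTP values for log
#' attributes are reported.  The companion discrete-change mode returns the
#' value of moving from level `L` to `L + 1`, `beta * (log(L+1) - log(L))`.
#'
#' @param beta WTP-space coefficient, EUR.
#' @param level attribute level code, at least 1.
#' @param mode `"marginal"` (default) or `"discrete"`.
#' @return EUR value.
#' @examples
#' marginal_wtp_log(27.62, 1)            # 27.62
#' marginal_wtp_log(10, 2)               # 5
#' marginal_wtp_log(10, 2, "discrete")   # 10 * (log 3 - log 2)
#' @export
marginal_wtp_log <- function(beta, level, mode = c("marginal", "discrete")) {
  mode <- match.arg(mode)
  if (any(level < 1)) stop("level must be at least 1")
  switch(mode,
         marginal = beta / level,
         discrete = beta * (log(level + 1) - log(level)))
}

#' WTP implied by a linear species-count attribute
#'
#' Species-presence attributes enter utility linearly in the count, so the
#' WTP of a configuration is the per-level WTP times its level code: with a
#' per-species value of EUR 48.41 for large herbivores, both species
#' (code 3, counting bison as two improvement steps) are worth EUR 145.23.
#'
#' @param per_level_wtp per-level WTP, EUR.
#' @param level_code nonnegative level code.
#' @return EUR value.
#' @examples
#' linear_attribute_wtp(48.41, 3)  # 145.23
#' linear_attribute_wtp(80.30, 2)  # 160.60
#' @export
linear_attribute_wtp <- function(per_level_wtp, level_code) {
  if (any(level_code < 0)) stop("level_code must be nonnegative")
  per_level_wtp * level_code
}

#' Per-party WTP table with baseline shifts
#'
#' For each coefficient slot and each party, reports the mean WTP: the
#' baseline party carries the estimated mean `mu`, every other party carries
#' `mu + lambda_party` with a delta-method standard error.  The shift column
#' is identically zero (with no standard error) for the baseline party, and
#' the shift standard error equals the corresponding `lambda` coefficient's
#' standard error.  Stars mark two-sided significance at the 10/5/1% levels
#' (of `mu` for the baseline row, of the shift otherwise).
#'
#' @param result a fitted `mxl_fit` whose model includes the `voting`
#'   covariate.
#' @param parties optional [party_meta()] table restricting/ordering the
#'   parties; defaults to the baseline plus every party present in the
#'   fitted coefficients.
#' @param vcov_type `"sandwich"` (default) or `"hessian"`.
#' @return A `data.frame` of class `wtp_table` with columns `party`,
#'   `attribute`, `wtp`, `se`, `ci_lo`, `ci_hi`, `shift`, `shift_se`,
#'   `signif`, and the baseline party as an attribute.
#' @export
party_wtp_table <- function(result, parties = NULL,
                            vcov_type = c("sandwich", "hessian")) {
  if (!"voting" %in% names(result$baseline))
    stop("the fitted model has no voting covariate")
  V <- vcov.mxl_fit(result, match.arg(vcov_type))
  baseline <- unname(result$baseline["voting"])
  lam_names <- grep("^lambda\\[.*:voting", names(result$par), value = TRUE)
  fitted_parties <- unique(sub("^lambda\\[.*:voting(.*)\\]$", "\\1", lam_names))
  if (!is.null(parties)) {
    miss <- setdiff(setdiff(parties$party, baseline), fitted_parties)
    if (length(miss))
      stop("party(ies) absent from the fitted model: ",
           paste(miss, collapse = ", "))
    plist <- parties$party
  } else plist <- c(baseline, fitted_parties)
  slots <- result$layout$slot_names
  rows <- list()
  z95 <- qnorm(0.975)
  for (s in slots) {
    mu_nm <- paste0("mu[", s, "]")
    mu_hat <- result$par[[mu_nm]]
    mu_var <- V[mu_nm, mu_nm]
    for (p in plist) {
      if (p == baseline) {
        se <- sqrt(mu_var)
        rows[[length(rows) + 1]] <- data.frame(
          party = p, attribute = s, wtp = mu_hat, se = se,
          ci_lo = mu_hat - z95 * se, ci_hi = mu_hat + z95 * se,
          shift = 0, shift_se = NA_real_,
          signif = significance_marker(2 * pnorm(-abs(mu_hat / se))))
      } else {
        la_nm <- paste0("lambda[", s, ":voting", p, "]")
        la <- result$par[[la_nm]]
        la_se <- sqrt(V[la_nm, la_nm])
        wtp <- mu_hat + la
        se <- sqrt(mu_var + V[la_nm, la_nm] + 2 * V[mu_nm, la_nm])
        rows[[length(rows) + 1]] <- data.frame(
          party = p, attribute = s, wtp = wtp, se = se,
          ci_lo = wtp - z95 * se, ci_hi = wtp + z95 * se,
          shift = la, shift_se = la_se,
          signif = significance_marker(2 * pnorm(-abs(la / la_se))))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  # log-attribute rows report the coefficient itself, i.e. the marginal WTP
  # at the lowest level; see marginal_wtp_log() for the discrete-change view
  attr(out, "log_attribute_convention") <- "marginal_at_lowest_level"
  class(out) <- c("wtp_table", "data.frame")
  out
}

#' Empirical status-quo choice share
#'
#' The fraction of choice tasks in which the status-quo alternative was
#' chosen: the share of choices unwilling to support the program at the
#' presented cost levels.  A pure count, invariant to row order.
#'
#' @param data a `choice_data` object.
#' @param covariates covariate `data.frame` (needed when grouping).
#' @param by covariate column to group by (default `"voting"`); `NULL` for
#'   the overall share only.
#' @param groups optional vector of group levels to report; levels with no
#'   respondents are reported as `NA`, not zero.
#' @return A `data.frame` with columns `group`, `n_tasks`, `sq_share`, plus
#'   the overall share as attribute `"overall"`.
#' @export
sq_share <- function(data, covariates = NULL, by = "voting", groups = NULL) {
  design <- attr(data, "design")
  if (!design$has_status_quo) stop("the design has no status-quo alternative")
  df <- as.data.frame(data)
  if (anyNA(df$chosen)) stop("chosen flags are required")
  sq_chosen <- df$is_sq == 1 & df$chosen == 1
  n_tasks_total <- nrow(df[!duplicated(df[c("respondent_id", "task")]), ])
  overall <- sum(sq_chosen) / n_tasks_total
  if (is.null(covariates)) by <- NULL
  if (is.null(by)) {
    out <- data.frame(group = "all", n_tasks = n_tasks_total,
                      sq_share = overall)
  } else {
    if (is.null(covariates)) stop("covariates are required to group by '", by, "'")
    g <- covariates[[by]][match(df$respondent_id, covariates$respondent_id)]
    if (anyNA(g)) stop("covariate '", by, "' does not cover every respondent")
    tasks <- !duplicated(df[c("respondent_id", "task")])
    nt <- tapply(tasks, g, sum)
    ns <- tapply(sq_chosen, g, sum)
    lev <- if (is.null(groups)) names(nt) else as.character(groups)
    out <- data.frame(group = lev,
                      n_tasks = as.integer(nt[lev]),
                      sq_share = as.numeric(ns[lev] / nt[lev]))
  }
  attr(out, "overall") <- overall
  out
}

#' Model-predicted status-quo probability
#'
#' Simulated average, over draws and tasks, of the status-quo choice
#' probability implied by a fitted model, grouped by a respondent covariate.
#' On data simulated from the same model this agrees with the empirical
#' [sq_share()] up to sampling error.
#'
#' @param result a converged `mxl_fit`.
#' @param data,covariates the dataset the probabilities are evaluated on.
#' @param draws optional [make_draws()] set; defaults to a fresh set with
#'   the fit's seed, draw count and dimension.
#' @param by grouping covariate (default `"voting"`); `NULL` for overall.
#' @return As [sq_share()], with column `sq_prob`.
#' @export
predicted_sq_probability <- function(result, data, covariates, draws = NULL,
                                     by = "voting") {
  spec <- spec_from_result(result)
  prep <- prepare_estimation(data, covariates, spec)
  lay <- prep$layout
  if (lay$D > 0) {
    if (is.null(draws))
      draws <- make_draws(length(prep$ids), result$n_draws, lay$D,
                          seed = result$seed)
    dm <- draws$draws; R <- draws$n_draws
  } else {
    dm <- matrix(0, 0, 0); R <- 1L
  }
  pr <- cpp_mean_probs(full_par(result$par, lay), prep$A, prep$cost,
                       prep$task_start, prep$resp_task_start, prep$X,
                       dm, lay$rand_idx, R)
  df <- as.data.frame(data)
  sq <- df$is_sq == 1
  n_tasks_total <- sum(!duplicated(df[c("respondent_id", "task")]))
  overall <- sum(pr[sq]) / n_tasks_total
  if (is.null(by)) {
    out <- data.frame(group = "all", n_tasks = n_tasks_total,
                      sq_prob = overall)
  } else {
    g <- covariates[[by]][match(df$respondent_id, covariates$respondent_id)]
    tasks <- !duplicated(df[c("respondent_id", "task")])
    nt <- tapply(tasks, g, sum)
    ps <- tapply(ifelse(sq, pr, 0), g, sum)
    out <- data.frame(group = names(nt), n_tasks = as.integer(nt),
                      sq_prob = as.numeric(ps / nt))
  }
  attr(out, "overall") <- overall
  out
}

# rebuild a model_spec consistent with a fitted result (for re-preparing data)
spec_from_result <- function(result) {
  lay <- result$layout
  model_spec(random_coefs = setdiff(lay$rand_names, "money"),
             money_random = "money" %in% lay$rand_names,
             covariates = names(result$covariate_groups) %||% character(0),
             baseline = result$baseline,
             n_draws = max(result$n_draws, 1L))
}

#' Party summary along the three rewilding dimensions
#'
#' Collapses a per-party WTP table into the party-map metrics: mean WTP
#' across the landscape interventions (forests, rivers, agriculture), WTP
#' for ecological connectivity, and mean WTP across the large-animal
#' interventions (carnivores, herbivores), joined with the parties'
#' political coordinates when supplied.
#'
#' @param table a [party_wtp_table()] covering all six non-cost attributes.
#' @param parties optional [party_meta()] with coordinates to attach.
#' @return A `data.frame` with one row per party: `landscape_wtp`,
#'   `connectivity_wtp`, `animal_wtp` and any party coordinates.
#' @export
dimension_means <- function(table, parties = NULL) {
  need <- c("forest", "river", "agriculture", "connectivity",
            "carnivores", "herbivores")
  miss <- setdiff(need, unique(table$attribute))
  if (length(miss))
    stop("WTP table lacks attribute row(s): ", paste(miss, collapse = ", "))
  get <- function(p, a) table$wtp[table$party == p & table$attribute == a]
  ps <- unique(table$party)
  out <- data.frame(
    party = ps,
    landscape_wtp = vapply(ps, function(p)
      mean(c(get(p, "forest"), get(p, "river"), get(p, "agriculture"))), 0),
    connectivity_wtp = vapply(ps, function(p) get(p, "connectivity"), 0),
    animal_wtp = vapply(ps, function(p)
      mean(c(get(p, "carnivores"), get(p, "herbivores"))), 0),
    row.names = NULL)
  if (!is.null(parties))
    out <- merge(out, as.data.frame(parties), by = "party", all.x = TRUE,
                 sort = FALSE)
  out
}

#' Plot the political party map
#'
#' Positions parties on the economic left-right x EU-integration plane and
#' scales point size with a chosen WTP metric.  Writes a PNG when `file` is
#' given.
#'
#' @param summary output of [dimension_means()] including coordinates.
#' @param metric column to scale by (default `"landscape_wtp"`).
#' @param file optional PNG path.
#' @return The input, invisibly.
#' @export
plot_party_map <- function(summary, metric = "landscape_wtp", file = NULL) {
  if (!all(c("econ_lr", "eu_position") %in% names(summary)))
    stop("summary lacks party coordinates")
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  v <- summary[[metric]]
  cex <- 1 + 2.5 * (v - min(v)) / max(diff(range(v)), 1e-9)
  plot(summary$econ_lr, summary$eu_position, cex = cex, pch = 19,
       col = "steelblue", xlab = "economic left-right",
       ylab = "EU integration", main = paste("Party map:", metric))
  graphics::text(summary$econ_lr, summary$eu_position, summary$party, pos = 3)
  invisible(summary)
}
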