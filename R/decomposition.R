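# Variance decomposition of WTP heterogeneity into covariate-explained and
# residual parts.  For coefficient j with fitted loadings lambda_j and
# residual variance Omega_jj, the explained share is
#   100 * var(lambda_j' X) / (var(lambda_j' X) + Omega_jj)
# with the variance taken across respondents (n - 1 denominator).  Relative
# contributions of covariate groups are normalized to sum to 100 within each
# coefficient; for a single standardized covariate the group's raw
# contribution reduces to lambda_jk^2 * var(X_k).

decomp_context <- function(result, covariates) {
  use <- names(result$covariate_groups)
  if (length(use) == 0)
    stop("the fitted model has no covariates to decompose over")
  cd <- covariate_design(covariates, use = use, baseline = result$baseline)
  idx <- match(result$layout$x_names, colnames(cd$X))
  if (anyNA(idx))
    stop("covariate table is inconsistent with the fitted model (missing ",
         paste(result$layout$x_names[is.na(idx)], collapse = ", "), ")")
  X <- cd$X[, idx, drop = FALSE]
  # group index map in the fitted column order
  groups <- lapply(cd$groups, function(g)
    match(colnames(cd$X)[g], colnames(X)))
  list(X = X, groups = groups)
}

# per-coefficient loading vector on the covariate columns: lambda row for a
# WTP slot, gamma for the log money term ("cost")
coef_loadings <- function(result, attribute, need_resid = TRUE) {
  lay <- result$layout
  if (attribute %in% c("cost", "money")) {
    if (need_resid && !"money" %in% lay$rand_names)
      stop("the money term carries no random component in this model")
    resid <- if ("money" %in% lay$rand_names)
      result$params$omega["money", "money"] else NA_real_
    list(load = result$params$gamma, resid = resid,
         par_names = paste0("gamma[", lay$x_names, "]"))
  } else {
    if (!attribute %in% lay$slot_names)
      stop("unknown coefficient slot '", attribute, "'")
    if (need_resid && !attribute %in% lay$rand_names)
      stop("coefficient '", attribute, "' has no random component; its ",
           "variance cannot be decomposed")
    resid <- if (attribute %in% lay$rand_names)
      result$params$omega[attribute, attribute] else NA_real_
    list(load = result$params$lambda[attribute, ],
         resid = resid,
         par_names = paste0("lambda[", attribute, ":", lay$x_names, "]"))
  }
}

#' Share of WTP variance explained by covariates
#'
#' Percentage of the total variance of a random coefficient accounted for
#' by the fitted covariate index: `100 * var(lambda' X) / (var(lambda' X) +
#' Omega_jj)`.  Zero loadings give 0%; a zero residual variance with
#' nonzero loadings gives 100%; a coefficient with no variance at all is
#' reported as `NA` (missing), not zero.
#'
#' @param result a fitted `mxl_fit`.
#' @param covariates covariate `data.frame`.
#' @param attribute coefficient slot (`"sq"`, an attribute name, or
#'   `"cost"` for the log money term).
#' @return Percentage in `[0, 100]`, or `NA` when total variance is zero.
#' @export
explained_share <- function(result, covariates, attribute) {
  ctx <- decomp_context(result, covariates)
  cl <- coef_loadings(result, attribute)
  v_obs <- var(drop(ctx$X %*% cl$load))
  tot <- v_obs + cl$resid
  if (tot <= 0) {
    warning("total variance of '", attribute, "' is zero; share undefined")
    return(NA_real_)
  }
  100 * v_obs / tot
}

#' Relative contribution of a covariate group
#'
#' Raw contribution of a covariate group to a coefficient's observed
#' heterogeneity: the variance across respondents of the group's fitted
#' linear combination (which for a single covariate reduces to
#' `lambda_jk^2 var(X_k)`, and for grouped categorical covariates captures
#' the within-group covariance).  The relative contribution normalizes raw
#' contributions to sum to 100 over all groups; the unnormalized share of
#' total variance is returned alongside.
#'
#' @param result a fitted `mxl_fit`.
#' @param covariates covariate `data.frame`.
#' @param attribute coefficient slot (or `"cost"`).
#' @param group covariate name(s) (entries of the model's covariate set)
#'   forming the group.
#' @return `list(relative, raw, share_of_total)`: `relative` in percent of
#'   explained heterogeneity, `share_of_total` in percent of total
#'   (explained + residual) variance.
#' @export
covariate_contribution <- function(result, covariates, attribute, group) {
  ctx <- decomp_context(result, covariates)
  if (length(group) == 0) stop("group must be nonempty")
  bad <- setdiff(group, names(ctx$groups))
  if (length(bad))
    stop("unknown covariate group member(s): ", paste(bad, collapse = ", "))
  cl <- coef_loadings(result, attribute)
  raw_all <- vapply(ctx$groups, function(g)
    var(drop(ctx$X[, g, drop = FALSE] %*% cl$load[g])), 0)
  cols <- unlist(ctx$groups[group])
  if (anyDuplicated(cols)) stop("overlapping covariate groups")
  raw <- var(drop(ctx$X[, cols, drop = FALSE] %*% cl$load[cols]))
  denom <- sum(raw_all)
  v_obs <- var(drop(ctx$X %*% cl$load))
  list(relative = if (denom > 0) 100 * raw / denom else NA_real_,
       raw = raw,
       share_of_total = 100 * raw / (v_obs + cl$resid))
}

#' Joint Wald significance of a covariate group's loadings
#'
#' Tests the joint zero restriction on the loadings of a covariate group
#' for one coefficient, via [wald_test()] on the corresponding `lambda`
#' (or `gamma`) block, and returns a significance marker at the 10/5/1%
#' levels (`ns`, `*`, `**`, `***`).
#'
#' @inheritParams covariate_contribution
#' @param vcov_type `"sandwich"` (default) or `"hessian"`.
#' @return `list(marker, statistic, df, p)`.
#' @export
group_wald_significance <- function(result, attribute, group,
                                    vcov_type = c("sandwich", "hessian")) {
  lay <- result$layout
  cl <- coef_loadings(result, attribute, need_resid = FALSE)
  gidx <- unlist(lapply(group, function(g) result$covariate_groups[[g]]))
  if (is.null(gidx) || length(gidx) == 0)
    stop("unknown covariate group: ", paste(group, collapse = ", "))
  par_nm <- cl$par_names[gidx]
  wt <- wald_test(result, par_nm, vcov_type = match.arg(vcov_type))
  c(list(marker = significance_marker(wt$p)), wt)
}

#' Full heterogeneity decomposition table
#'
#' Builds the per-coefficient grid of relative covariate-group
#' contributions (rows normalized to sum to 100), joint Wald significance
#' markers per cell, the explained share of total variance per coefficient,
#' and a mean row over the non-monetary attributes (excluding the
#' status-quo constant and the cost term).
#'
#' @param result a fitted `mxl_fit`.
#' @param covariates covariate `data.frame`.
#' @param groups named list mapping group labels to covariate names; must
#'   partition the model's covariate set.  Defaults to one group per
#'   covariate (categorical covariates are naturally grouped).
#' @param include_cost decompose the log money term as a final row.
#' @param vcov_type `"sandwich"` (default) or `"hessian"`.
#' @return A `decomposition_table`: `data.frame` with one row per
#'   coefficient plus the mean row; group columns in percent, a `sum`
#'   column, and `explained_share`; significance markers in
#'   `attr(, "significance")`.
#' @export
build_decomposition_table <- function(result, covariates, groups = NULL,
                                      include_cost = TRUE,
                                      vcov_type = c("sandwich", "hessian")) {
  vcov_type <- match.arg(vcov_type)
  ctx <- decomp_context(result, covariates)
  if (is.null(groups))
    groups <- setNames(as.list(names(ctx$groups)), names(ctx$groups))
  all_members <- unlist(groups)
  if (anyDuplicated(all_members) ||
      !setequal(all_members, names(ctx$groups)))
    stop("groups must partition the model's covariate set")
  lay <- result$layout
  rows <- intersect(lay$slot_names, lay$rand_names)
  if (include_cost && "money" %in% lay$rand_names) rows <- c(rows, "cost")
  gl <- names(groups)
  tab <- matrix(NA_real_, length(rows), length(gl),
                dimnames = list(rows, gl))
  stars <- matrix("", length(rows), length(gl), dimnames = list(rows, gl))
  expl <- numeric(length(rows))
  for (i in seq_along(rows)) {
    at <- rows[i]
    for (j in seq_along(gl)) {
      cc <- covariate_contribution(result, covariates, at, groups[[gl[j]]])
      tab[i, j] <- cc$relative
      if (!is.null(result$vcov_sandwich) || !is.null(result$vcov_hessian))
        stars[i, j] <- group_wald_significance(result, at, groups[[gl[j]]],
                                               vcov_type)$marker
    }
    expl[i] <- explained_share(result, covariates, at)
  }
  mean_rows <- setdiff(rows, c("sq", "cost"))
  out <- as.data.frame(tab)
  out$sum <- rowSums(tab)
  out$explained_share <- expl
  out <- cbind(attribute = rows, out)
  if (length(mean_rows) > 0) {
    m <- colMeans(out[out$attribute %in% mean_rows, -1, drop = FALSE])
    out <- rbind(out, data.frame(attribute = "mean", as.list(m)))
  }
  rownames(out) <- NULL
  attr(out, "significance") <- as.data.frame(stars)
  class(out) <- c("decomposition_table", "data.frame")
  out
}

#' @export
print.decomposition_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  st <- attr(x, "significance")
  for (nm in names(st)) {
    shown <- formatC(df[[nm]], digits = digits, format = "f")
    shown[seq_len(nrow(st))] <- paste0(shown[seq_len(nrow(st))], st[[nm]])
    df[[nm]] <- shown
  }
  print(df, ...)
  invisible(x)
}
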