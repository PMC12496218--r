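#' True parameter set for simulation
#'
#' The data-generating parameters of the WTP-space mixed logit: coefficient
#' means `mu` (EUR) over the status-quo constant plus the non-cost
#' attributes, covariate loadings `lambda` on those means, the location
#' `pi` of the log marginal utility of money, covariate loadings `gamma`
#' on the log money term, and the lower-triangular Cholesky factor
#' `omega_chol` of the joint covariance of the stochastic components
#' (the WTP residuals and the money residual share one joint normal, so
#' `omega_chol` is `(K+1) x (K+1)` with the money term last).
#'
#' @param mu named numeric vector: first element `sq` (status-quo constant),
#'   then one entry per non-cost attribute, in design order.
#' @param pi scalar location of `log(alpha)`.
#' @param lambda `K x C` matrix of covariate loadings (default none);
#'   column names must match the covariate design-matrix columns.
#' @param gamma length-`C` loadings on `log(alpha)`.
#' @param omega_chol `(K+1) x (K+1)` lower-triangular Cholesky factor with
#'   nonnegative diagonal; default zero (no unobserved heterogeneity).
#' @param covariates character vector of covariate columns `lambda`/`gamma`
#'   refer to (in the covariate table, before one-hot expansion).
#' @param baseline named character vector of baseline levels for categorical
#'   covariates, e.g. `c(voting = "PiS")`.
#' @return An object of class `true_parameters`.
#' @export
true_parameters <- function(mu, pi, lambda = NULL, gamma = NULL,
                            omega_chol = NULL, covariates = character(0),
                            baseline = NULL) {
  K <- length(mu)
  if (is.null(names(mu)) || names(mu)[1] != "sq")
    stop("mu must be named, with the status-quo constant 'sq' first")
  if (is.null(omega_chol)) omega_chol <- matrix(0, K + 1, K + 1)
  omega_chol <- as.matrix(omega_chol)
  if (!all(dim(omega_chol) == K + 1))
    stop("omega_chol must be ", K + 1, " x ", K + 1,
         " (WTP coefficients plus the money term)")
  if (any(omega_chol[upper.tri(omega_chol)] != 0))
    stop("omega_chol must be lower triangular")
  if (any(diag(omega_chol) < 0))
    stop("omega_chol must have a nonnegative diagonal")
  if (is.null(lambda)) lambda <- matrix(0, K, 0)
  lambda <- as.matrix(lambda)
  if (nrow(lambda) != K) stop("lambda must have one row per mu entry")
  if (is.null(gamma)) gamma <- numeric(ncol(lambda))
  if (length(gamma) != ncol(lambda))
    stop("gamma length must match the number of lambda columns")
  structure(list(mu = mu, lambda = lambda, pi = pi, gamma = gamma,
                 omega_chol = omega_chol, covariates = covariates,
                 baseline = baseline),
            class = "true_parameters")
}

#' Implied covariance of the random components
#' @param params a [true_parameters()] object (or fitted parameter set).
#' @return The `(K+1) x (K+1)` covariance matrix `omega_chol %*% t(omega_chol)`.
#' @export
omega_matrix <- function(params) params$omega_chol %*% t(params$omega_chol)

#' Simulation configuration
#'
#' Bundles everything needed to generate a synthetic stated-preference
#' dataset with the statistical structure the estimator assumes: the design,
#' sample size, party shares, covariate distributions, true parameters and a
#' seed.  All randomness flows from that single seed.
#'
#' @param n_respondents sample size.
#' @param design a [design_spec()].
#' @param true_params a [true_parameters()] object.
#' @param party_shares a [party_meta()] table (ignored when the true
#'   parameters use no `voting` covariate and `covariate_spec` omits it).
#' @param covariate_spec named list describing respondent covariate
#'   distributions; each entry is `list(type = "normal"|"bernoulli"|
#'   "ordinal"|"categorical", ...)` with `mean`/`sd`, `prob`, or
#'   `levels`/`prob` fields.  Continuous covariates default to standardized
#'   scales.
#' @param seed integer master seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_respondents, design, true_params,
                              party_shares = NULL, covariate_spec = NULL,
                              seed = 1L) {
  stopifnot(n_respondents >= 1, inherits(design, "design_spec"),
            inherits(true_params, "true_parameters"))
  K <- length(attribute_names(design)) + 1L
  if (length(true_params$mu) != K)
    stop("true mu has length ", length(true_params$mu),
         " but the design implies ", K, " (sq + attributes)")
  if (is.null(covariate_spec)) covariate_spec <- list()
  for (nm in true_params$covariates) {
    if (nm == "voting") {
      if (is.null(party_shares))
        stop("true parameters use 'voting' but no party_shares were given")
      next
    }
    if (!nm %in% names(covariate_spec))
      stop("no covariate_spec entry for covariate '", nm, "'")
  }
  for (nm in names(covariate_spec)) {
    cs <- covariate_spec[[nm]]
    if (!is.null(cs$prob)) {
      if (any(cs$prob < 0) || abs(sum(cs$prob) - 1) > 1e-9 && cs$type != "bernoulli")
        stop("covariate '", nm, "': probabilities must be in [0,1] and sum to 1")
    }
  }
  structure(list(n_respondents = as.integer(n_respondents), design = design,
                 true_params = true_params, party_shares = party_shares,
                 covariate_spec = covariate_spec, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Sample respondent covariates
#'
#' Draws the respondent covariate table from the distributions declared in
#' the configuration; party affiliation is drawn from the declared sample
#' shares.  Deterministic under a fixed configuration seed.
#'
#' @param config a [simulation_config()].
#' @return A covariate `data.frame` keyed by `respondent_id`.
#' @export
sample_covariates <- function(config) {
  set.seed(config$seed)
  n <- config$n_respondents
  out <- data.frame(respondent_id = seq_len(n))
  for (nm in names(config$covariate_spec)) {
    cs <- config$covariate_spec[[nm]]
    out[[nm]] <- switch(cs$type,
      normal = rnorm(n, mean = cs$mean %||% 0, sd = cs$sd %||% 1),
      bernoulli = as.numeric(runif(n) < (cs$prob %||% 0.5)),
      ordinal = sample(cs$levels %||% seq_along(cs$prob), n, TRUE, cs$prob),
      categorical = sample(cs$levels, n, TRUE, cs$prob),
      stop("covariate '", nm, "': unknown type '", cs$type, "'"))
    if (cs$type == "normal" && !is.null(cs$sd) && cs$sd <= 0)
      stop("covariate '", nm, "': sd must be positive")
  }
  if (!is.null(config$party_shares))
    out$voting <- sample(config$party_shares$party, n, TRUE,
                         config$party_shares$share)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# align lambda columns to a covariate design matrix, by name; declared
# loadings for categories that no respondent carries are dropped (they
# cannot contribute), but every design-matrix column must have a loading
align_lambda <- function(lambda, x_names) {
  if (is.null(colnames(lambda))) {
    if (ncol(lambda) != length(x_names))
      stop("lambda has ", ncol(lambda), " columns but the covariate design ",
           "matrix has ", length(x_names))
    return(lambda)
  }
  idx <- match(x_names, colnames(lambda))
  if (anyNA(idx))
    stop("lambda columns do not match the covariate design matrix: missing ",
         paste(x_names[is.na(idx)], collapse = ", "))
  lambda[, idx, drop = FALSE]
}

#' Draw individual-level coefficients
#'
#' Realizes the hierarchical structure of the model: per respondent,
#' `beta_n = mu + lambda X_n + zeta_n` with `(zeta_n, eta_n)` jointly
#' multivariate normal with covariance `omega_chol %*% t(omega_chol)`, and
#' `alpha_n = exp(pi + gamma X_n + eta_n)` (always positive).
#'
#' @param covariates covariate `data.frame`.
#' @param params a [true_parameters()] object.
#' @param seed integer seed for the normal draws.
#' @return A `data.frame` with `respondent_id`, one `beta_*` column per
#'   coefficient (status-quo constant first) and the money scalar `alpha`.
#' @export
draw_individual_coefficients <- function(covariates, params, seed = 1L) {
  n <- nrow(covariates)
  K <- length(params$mu)
  if (ncol(params$lambda) > 0) {
    cd <- covariate_design(covariates, use = params$covariates,
                           baseline = params$baseline)
    X <- cd$X
    lambda <- align_lambda(params$lambda, colnames(X))
    gamma <- params$gamma
    if (!is.null(colnames(params$lambda)))
      gamma <- gamma[match(colnames(X), colnames(params$lambda))]
    mean_beta <- matrix(params$mu, n, K, byrow = TRUE) + X %*% t(lambda)
    mean_logalpha <- params$pi + drop(X %*% gamma)
  } else {
    mean_beta <- matrix(params$mu, n, K, byrow = TRUE)
    mean_logalpha <- rep(params$pi, n)
  }
  set.seed(seed)
  u <- matrix(rnorm(n * (K + 1)), n, K + 1)
  ze <- u %*% t(params$omega_chol)
  beta <- mean_beta + ze[, seq_len(K), drop = FALSE]
  alpha <- exp(mean_logalpha + ze[, K + 1])
  out <- data.frame(respondent_id = covariates$respondent_id)
  cn <- paste0("beta_", names(params$mu))
  for (k in seq_len(K)) out[[cn[k]]] <- beta[, k]
  out$alpha <- alpha
  out
}

#' Random design template
#'
#' Builds an (unanswered) choice dataset: for each respondent and task, the
#' status-quo alternative at its fixed baseline plus program alternatives
#' with attribute levels drawn uniformly at random and cost drawn from the
#' design's cost levels.  Uniformly random level balance stands in for an
#' optimized experimental design; it identifies the model at fixture scale.
#'
#' @param design a [design_spec()].
#' @param n_respondents sample size.
#' @param seed integer seed.
#' @return A `choice_data` object without chosen flags.
#' @export
make_design_template <- function(design, n_respondents, seed = 1L) {
  set.seed(seed)
  Tn <- design$n_tasks_per_respondent
  P <- design$n_program_alternatives
  A <- P + design$has_status_quo
  n_rows <- n_respondents * Tn * A
  alt0 <- if (design$has_status_quo) 0L else 1L
  df <- data.frame(
    respondent_id = rep(seq_len(n_respondents), each = Tn * A),
    task = rep(rep(seq_len(Tn) - 1L, each = A), n_respondents),
    alt = rep(seq(alt0, length.out = A), n_respondents * Tn))
  df$is_sq <- as.integer(design$has_status_quo & df$alt == 0L)
  prog <- df$is_sq == 0L
  for (nm in attribute_names(design)) {
    a <- design$attributes[[nm]]
    codes <- unique(a$level_codes)
    v <- numeric(n_rows)
    v[prog] <- sample(codes, sum(prog), TRUE)
    if (a$kind == "log_level") {
      v[!prog] <- 1
      v <- log(v)
    }
    df[[nm]] <- v
  }
  cn <- cost_attribute(design)
  v <- numeric(n_rows)
  v[prog] <- sample(design$cost_levels, sum(prog), TRUE)
  df[[cn]] <- v
  df$chosen <- NA_integer_
  as_choice_data(df, design, check_chosen = FALSE)
}

#' Simulate choices from individual coefficients
#'
#' For each task, computes the systematic utilities
#' `V = alpha_n * (beta_n' a - cost)` and draws the chosen alternative from
#' the implied multinomial logit probabilities.
#'
#' @param template a `choice_data` template (no chosen flags required).
#' @param coefficients output of [draw_individual_coefficients()].
#' @param seed integer seed.
#' @return The template with `chosen` filled in (exactly one per task).
#' @export
simulate_choices <- function(template, coefficients, seed = 1L) {
  design <- attr(template, "design")
  slots <- c("sq", attribute_names(design))
  bcols <- paste0("beta_", slots)
  miss <- setdiff(bcols, names(coefficients))
  if (length(miss))
    stop("coefficient table lacks column(s): ", paste(miss, collapse = ", "))
  idx <- match(template$respondent_id, coefficients$respondent_id)
  if (anyNA(idx)) stop("coefficients do not cover every respondent")
  B <- as.matrix(coefficients[idx, bcols, drop = FALSE])
  A <- cbind(sq = template$is_sq,
             as.matrix(as.data.frame(template)[attribute_names(design)]))
  alpha <- coefficients$alpha[idx]
  V <- alpha * (rowSums(A * B) - template[[cost_attribute(design)]])
  if (any(!is.finite(V)))
    stop("non-finite systematic utility (extreme alpha or coefficients); ",
         "first offending row ", which(!is.finite(V))[1])
  set.seed(seed)
  df <- as.data.frame(template)
  df$chosen <- 0L
  key <- cumsum(!duplicated(data.frame(df$respondent_id, df$task)))
  split_rows <- split(seq_len(nrow(df)), key)
  u <- runif(length(split_rows))
  for (i in seq_along(split_rows)) {
    rows <- split_rows[[i]]
    v <- V[rows]
    p <- exp(v - max(v))
    p <- p / sum(p)
    pick <- min(findInterval(u[i], cumsum(p), left.open = TRUE) + 1L,
                length(rows))
    df$chosen[rows[pick]] <- 1L
  }
  as_choice_data(df, design)
}

#' Generate a complete synthetic fixture
#'
#' End-to-end bundle: covariates, individual coefficients, a random design
#' template and simulated choices, optionally written to disk (choice CSV,
#' covariate CSV, and a YAML manifest recording the seed and true
#' parameters).
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory.
#' @return `list(data, covariates, coefficients, true_params, config)`.
#' @export
make_fixture <- function(config, dir = NULL) {
  set.seed(config$seed)
  sub <- sample.int(2^31 - 1, 3)
  covariates <- sample_covariates(config)
  coefficients <- draw_individual_coefficients(covariates, config$true_params,
                                               seed = sub[1])
  template <- make_design_template(config$design, config$n_respondents,
                                   seed = sub[2])
  data <- simulate_choices(template, coefficients, seed = sub[3])
  out <- list(data = data, covariates = covariates,
              coefficients = coefficients,
              true_params = config$true_params, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_choice_table(data, file.path(dir, "choices.csv"))
    write_covariate_table(covariates, file.path(dir, "covariates.csv"))
    manifest <- list(
      seed = config$seed,
      n_respondents = config$n_respondents,
      package_version = as.character(utils::packageVersion("wtpmxl")),
      true_params = true_params_to_list(config$true_params))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  out
}

#' Default study-scale simulation configuration
#'
#' A configuration emulating the structure of the Oder Delta survey: the
#' six-attribute design with 12 cards and two program alternatives plus the
#' status quo, a six-party landscape with realistic vote shares, the
#' standard covariate set (standardized continuous covariates), and
#' generating parameters whose magnitudes echo the WTP scale reported for
#' such programs (tens of EUR for landscape attributes, about EUR 50-90 for
#' large animals) and whose implied status-quo share lands near 10-18%.
#'
#' @param n_respondents sample size (the study samples were about 1000 per
#'   country).
#' @param seed master seed.
#' @return A [simulation_config()].
#' @export
default_simulation_config <- function(n_respondents = 1000, seed = 1L) {
  design <- rewilding_design()
  parties <- party_meta(
    party = c("PiS", "KO", "P2050", "NL", "KONF", "PSL"),
    share = c(0.34, 0.27, 0.12, 0.10, 0.09, 0.08),
    econ_lr = c(3.5, 5.5, 5.0, 2.5, 8.5, 5.0),
    eu_position = c(3.5, 6.5, 6.0, 6.0, 1.5, 5.0),
    country = "PL")
  K <- 7L
  mu <- c(sq = 30, forest = 15, river = 28, agriculture = 12,
          connectivity = 50, carnivores = 80, herbivores = 48)
  # shifts: left/pro-EU parties value landscape rewilding more
  covs <- c("log_distance", "age", "income", "voting")
  lam_cols <- c("log_distance", "age", "income",
                paste0("voting", c("KO", "P2050", "NL", "KONF", "PSL")))
  lambda <- matrix(0, K, length(lam_cols),
                   dimnames = list(names(mu), lam_cols))
  lambda["forest", "votingKO"] <- 20
  lambda["river", "votingKO"] <- 12
  lambda["connectivity", "votingNL"] <- 15
  lambda["carnivores", "votingNL"] <- 9
  lambda["herbivores", "votingKO"] <- 5
  lambda["river", "votingKONF"] <- -12
  lambda["sq", "votingKONF"] <- 60
  lambda["sq", "votingKO"] <- -40
  lambda[c("forest", "river", "connectivity"), "log_distance"] <- -6
  lambda["carnivores", "age"] <- -5
  lambda[c("river", "agriculture"), "income"] <- 5
  gamma <- c(0, 0, 0.15, rep(0, 5))
  sds <- c(sq = 150, forest = 35, river = 35, agriculture = 30,
           connectivity = 40, carnivores = 60, herbivores = 40, money = 0.6)
  omega_chol <- diag(sds)
  tp <- true_parameters(mu = mu, pi = log(0.05), lambda = lambda,
                        gamma = gamma, omega_chol = omega_chol,
                        covariates = covs, baseline = c(voting = "PiS"))
  covariate_spec <- list(
    log_distance = list(type = "normal", mean = 0, sd = 1),
    age = list(type = "normal", mean = 0, sd = 1),
    income = list(type = "normal", mean = 0, sd = 1),
    male = list(type = "bernoulli", prob = 0.49),
    city_size = list(type = "ordinal", levels = 1:5,
                     prob = c(0.25, 0.25, 0.2, 0.15, 0.15)),
    education = list(type = "ordinal", levels = 1:3,
                     prob = c(0.3, 0.45, 0.25)))
  simulation_config(n_respondents, design, tp, party_shares = parties,
                    covariate_spec = covariate_spec, seed = seed)
}
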