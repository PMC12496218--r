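#' Model specification for WTP-space estimation
#'
#' Declares which coefficients are random, which respondent covariates enter
#' the coefficient means, the categorical baselines, and the simulation and
#' optimizer settings.  The cost coefficient is never part of the random WTP
#' block: it is the numeraire, and its (log) marginal utility is carried by
#' the separate money term.
#'
#' @param random_coefs character vector of coefficient slots with random
#'   components, out of `"sq"` and the non-cost attribute names; `NULL`
#'   (default) makes all of them random.
#' @param money_random whether the log money term carries a random component.
#' @param covariates character vector of covariate columns entering the
#'   means; `NULL` uses every column of the covariate table.  `character(0)`
#'   estimates a model without observed heterogeneity.
#' @param baseline named character vector of baseline levels for categorical
#'   covariates (e.g. `c(voting = "PiS")`); defaults to the largest category.
#' @param n_draws simulated-likelihood draws per respondent (default 2000;
#'   reduced-draw fits are routine for tests and bootstraps).
#' @param independent_money force the money random term to be independent of
#'   the WTP residuals (zero off-diagonal Cholesky row); by default the
#'   joint covariance is fully estimated.
#' @param maxit,reltol optimizer control (BFGS).
#' @param chol_init diagonal value(s) used to initialize the Cholesky factor
#'   when no explicit start is given: WTP rows get `chol_init[1]` EUR, the
#'   money row `chol_init[2]`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(random_coefs = NULL, money_random = TRUE,
                       covariates = NULL, baseline = NULL, n_draws = 2000,
                       independent_money = FALSE, maxit = 1000,
                       reltol = 1e-8, chol_init = c(5, 0.2)) {
  stopifnot(n_draws >= 1)
  structure(list(random_coefs = random_coefs, money_random = money_random,
                 covariates = covariates, baseline = baseline,
                 n_draws = as.integer(n_draws),
                 independent_money = independent_money,
                 maxit = as.integer(maxit), reltol = reltol,
                 chol_init = chol_init),
            class = "model_spec")
}

# ---- parameter layout ------------------------------------------------------

# layout: slot_names (sq + attributes), x_names, rand_slots (names),
# rand_idx (0-based, money slot = K), D, K, C, par_names (full vector),
# free (logical mask over the full vector)
make_layout <- function(design, x_names, spec) {
  slots <- c(if (design$has_status_quo) "sq", attribute_names(design))
  K <- length(slots)
  rand <- spec$random_coefs
  if (is.null(rand)) rand <- slots
  bad <- setdiff(rand, slots)
  if (length(bad))
    stop("unknown random coefficient slot(s): ", paste(bad, collapse = ", "))
  rand <- slots[slots %in% rand]  # design order
  rand_idx <- match(rand, slots) - 1L
  rand_names <- rand
  if (spec$money_random) {
    rand_idx <- c(rand_idx, K)
    rand_names <- c(rand_names, "money")
  }
  D <- length(rand_idx)
  C <- length(x_names)
  par_names <- c(paste0("mu[", slots, "]"),
                 if (C > 0) paste0("lambda[", rep(slots, C), ":",
                                   rep(x_names, each = K), "]"),
                 "pi",
                 if (C > 0) paste0("gamma[", x_names, "]"))
  chol_names <- character(0)
  free_chol <- logical(0)
  if (D > 0) {
    for (i in seq_len(D)) for (j in seq_len(i)) {
      chol_names <- c(chol_names,
                      paste0("chol[", rand_names[i], ",", rand_names[j], "]"))
      fixed <- spec$independent_money && rand_names[i] == "money" && j < i
      free_chol <- c(free_chol, !fixed)
    }
  }
  par_names <- c(par_names, chol_names)
  free <- c(rep(TRUE, K + K * C + 1 + C), free_chol)
  list(slot_names = slots, x_names = x_names, rand_names = rand_names,
       rand_idx = as.integer(rand_idx), K = K, C = C, D = D,
       par_names = par_names, free = free)
}

full_par <- function(free_par, layout) {
  p <- numeric(length(layout$par_names))
  p[layout$free] <- free_par
  p
}

par_to_params <- function(free_par, layout) {
  p <- full_par(free_par, layout)
  K <- layout$K; C <- layout$C; D <- layout$D
  mu <- setNames(p[seq_len(K)], layout$slot_names)
  lambda <- matrix(p[K + seq_len(K * C)], K, C,
                   dimnames = list(layout$slot_names, layout$x_names))
  pi_ <- p[K + K * C + 1]
  gamma <- setNames(p[K + K * C + 1 + seq_len(C)], layout$x_names)
  chol <- matrix(0, D, D, dimnames = list(layout$rand_names, layout$rand_names))
  if (D > 0) {
    q <- K + K * C + 1 + C
    for (i in seq_len(D)) for (j in seq_len(i)) {
      q <- q + 1
      chol[i, j] <- p[q]
    }
  }
  list(mu = mu, lambda = lambda, pi = pi_, gamma = gamma, chol = chol,
       omega = chol %*% t(chol))
}

params_to_full_par <- function(params, layout) {
  K <- layout$K; C <- layout$C; D <- layout$D
  lambda <- params$lambda
  gamma <- params$gamma
  if (C > 0) {
    lambda <- align_lambda(as.matrix(lambda), layout$x_names)
    if (!is.null(colnames(params$lambda)))
      gamma <- gamma[match(layout$x_names, colnames(params$lambda))]
  }
  if (!is.null(names(params$mu))) {
    if (!setequal(names(params$mu), layout$slot_names))
      stop("mu names do not match the model's coefficient slots")
    mu <- params$mu[layout$slot_names]
    if (C > 0 && !is.null(rownames(lambda)))
      lambda <- lambda[layout$slot_names, , drop = FALSE]
  } else mu <- params$mu
  p <- c(as.numeric(mu),
         if (C > 0) as.numeric(lambda),
         params$pi,
         if (C > 0) as.numeric(gamma))
  if (D > 0) {
    ch <- params$chol
    if (is.null(ch)) {
      # derive the Cholesky of the random-subset covariance from a full
      # (K+1)-dimensional factor, as used by the simulator
      oc <- params$omega_chol
      Om <- oc %*% t(oc)
      sub <- Om[layout$rand_idx + 1L, layout$rand_idx + 1L, drop = FALSE]
      ch <- psd_chol(sub)
    }
    for (i in seq_len(D)) p <- c(p, ch[i, seq_len(i)])
  }
  p
}

# ---- elementary pieces -----------------------------------------------------

#' Systematic utility in WTP space
#'
#' Computes `V = alpha * (beta' x - cost)`: the money-metric value of an
#' alternative scaled by the marginal utility of money.  `V` is linear in
#' each WTP coefficient and homogeneous of degree one in `alpha`.
#'
#' @param x encoded attribute vector (status-quo dummy first) or a matrix
#'   with one row per alternative.
#' @param cost cost in EUR (scalar or one per row).
#' @param beta WTP coefficient vector, EUR.
#' @param alpha positive money-utility scalar.
#' @return Utility value(s).
#' @examples
#' systematic_utility(rep(0, 7), 50, rep(0, 7), 1)  # -50: cost only
#' @export
systematic_utility <- function(x, cost, beta, alpha) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x)) || !all(is.finite(beta)) || !all(is.finite(alpha)) ||
      !all(is.finite(cost)))
    stop("non-finite inputs to systematic_utility")
  drop(alpha * (x %*% beta - cost))
}

#' Multinomial logit choice probabilities
#'
#' Overflow-safe softmax of a utility vector (maximum subtracted before
#' exponentiation).
#'
#' @param utilities finite numeric vector, one entry per alternative
#'   (at least two).
#' @return Probability vector summing to one.
#' @examples
#' choice_probability(c(log(2), 0))  # 2/3, 1/3
#' @export
choice_probability <- function(utilities) {
  if (length(utilities) < 2) stop("need at least two alternatives")
  if (!all(is.finite(utilities))) stop("utilities must be finite")
  e <- exp(utilities - max(utilities))
  e / sum(e)
}

# ---- estimation plumbing ---------------------------------------------------

prepare_estimation <- function(data, covariates, spec) {
  design <- attr(data, "design")
  if (is.null(design)) stop("data must be a choice_data object")
  df <- as.data.frame(data)
  A <- as.matrix(df[attribute_names(design)])
  if (design$has_status_quo) A <- cbind(sq = df$is_sq, A)
  for (j in seq_len(ncol(A)))
    if (sd(A[, j]) == 0)
      stop("attribute column '", colnames(A)[j],
           "' is constant across all alternatives; coefficient not identified")
  cost <- df[[cost_attribute(design)]]
  chosen <- as.integer(df$chosen)
  task_key <- cumsum(!duplicated(df[c("respondent_id", "task")]))
  task_start <- c(0L, which(diff(task_key) != 0), nrow(df))
  resp_key_by_task <- df$respondent_id[!duplicated(df[c("respondent_id", "task")])]
  resp_task_start <- c(0L, which(diff(as.integer(factor(
    resp_key_by_task, levels = unique(resp_key_by_task)))) != 0),
    length(resp_key_by_task))
  ids <- unique(df$respondent_id)
  use <- spec$covariates
  if (is.null(use)) use <- setdiff(names(covariates), "respondent_id")
  if (length(use) > 0) {
    cov <- covariates[match(ids, covariates$respondent_id), , drop = FALSE]
    if (anyNA(cov$respondent_id))
      stop("covariate table does not cover every respondent in the data")
    cd <- covariate_design(cov, use = use, baseline = spec$baseline)
    X <- cd$X
  } else {
    cd <- list(X = matrix(0, length(ids), 0), baseline = character(0),
               groups = list())
    X <- cd$X
  }
  layout <- make_layout(design, colnames(X) %||% character(0), spec)
  list(A = A, cost = cost, chosen = chosen,
       task_start = as.integer(task_start),
       resp_task_start = as.integer(resp_task_start),
       X = X, layout = layout, cd = cd, ids = ids, design = design)
}

eval_loglik <- function(free_par, prep, draws, n_draws, want_grad = TRUE,
                        want_scores = FALSE) {
  lay <- prep$layout
  res <- cpp_panel_loglik(full_par(free_par, lay), prep$A, prep$cost,
                          prep$chosen, prep$task_start, prep$resp_task_start,
                          prep$X, draws, lay$rand_idx, n_draws,
                          want_grad, want_scores)
  if (want_grad) res$grad <- res$grad[lay$free]
  if (want_scores) res$scores <- res$scores[, lay$free, drop = FALSE]
  res
}

#' Simulated panel log-likelihood and gradient
#'
#' Evaluates the maximum-simulated-likelihood objective at a given parameter
#' set: per respondent, the product over tasks of logit choice probabilities
#' is averaged over the normal draws (transformed through the Cholesky
#' factor), and the log of that average is summed over respondents.  All
#' per-draw computation is done in log space with log-sum-exp, so deep
#' underflow is reported rather than silently returned as `-Inf`.
#'
#' With a zero Cholesky factor the value collapses exactly to the analytic
#' multinomial logit log-likelihood, for any draw set.
#'
#' @param params parameter list with `mu`, `lambda`, `pi`, `gamma` and
#'   either `chol` (over the random subset) or a full `omega_chol` as in
#'   [true_parameters()].
#' @param data a `choice_data` object.
#' @param covariates covariate `data.frame`.
#' @param draws a [make_draws()] draw set (dimension matching the random
#'   coefficient count), or `NULL` for a purely fixed-coefficient model.
#' @param spec a [model_spec()].
#' @return `list(loglik, gradient)`; the gradient is over the free
#'   parameters and matches finite differences to first order.
#' @export
simulated_loglik <- function(params, data, covariates, draws = NULL,
                             spec = model_spec()) {
  prep <- prepare_estimation(data, covariates, spec)
  lay <- prep$layout
  if (lay$D > 0) {
    if (is.null(draws)) stop("a draw set is required when coefficients are random")
    if (draws$dim != lay$D)
      stop("draw set has dimension ", draws$dim, ", model needs ", lay$D)
    dm <- draws$draws
    R <- draws$n_draws
  } else {
    dm <- matrix(0, 0, 0)
    R <- 1L
  }
  pfull <- params_to_full_par(params, lay)
  free <- pfull[lay$free]
  res <- eval_loglik(free, prep, dm, R, want_grad = TRUE)
  list(loglik = res$loglik,
       gradient = setNames(res$grad, lay$par_names[lay$free]))
}

run_bfgs <- function(start, prep, draws, n_draws, spec) {
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  ev <- function(p) {
    if (is.null(cache$par) || !identical(p, cache$par)) {
      cache$val <- eval_loglik(p, prep, draws, n_draws)
      cache$par <- p
    }
    cache$val
  }
  # a non-finite objective (overflowing alpha during line search) is
  # rejected by returning a huge value rather than aborting the fit
  opt <- optim(start,
               fn = function(p) tryCatch(-ev(p)$loglik,
                                         error = function(e) 1e10),
               gr = function(p) tryCatch(-ev(p)$grad,
                                         error = function(e) numeric(length(p))),
               method = "BFGS",
               control = list(maxit = spec$maxit, reltol = spec$reltol))
  opt
}

finish_fit <- function(opt, prep, draws, n_draws, spec, model_type, seed,
                       se = TRUE) {
  lay <- prep$layout
  nm <- lay$par_names[lay$free]
  par <- setNames(opt$par, nm)
  final <- eval_loglik(opt$par, prep, draws, n_draws, want_grad = TRUE,
                       want_scores = se)
  res <- list(model_type = model_type,
              par = par,
              params = par_to_params(opt$par, lay),
              loglik = final$loglik,
              grad_norm = sqrt(sum(final$grad^2)),
              convergence = opt$convergence == 0,
              iterations = unname(opt$counts["function"]),
              n_draws = if (lay$D > 0) n_draws else 0L,
              seed = seed,
              n_respondents = length(prep$ids),
              layout = lay,
              baseline = prep$cd$baseline,
              covariate_groups = prep$cd$groups,
              vcov_hessian = NULL, vcov_sandwich = NULL)
  if (se) {
    cache <- new.env(parent = emptyenv())
    gr <- function(p) -eval_loglik(p, prep, draws, n_draws)$grad
    H <- optimHess(opt$par, fn = function(p)
      -eval_loglik(p, prep, draws, n_draws, want_grad = FALSE)$loglik, gr = gr)
    Hi <- tryCatch(solve(H), error = function(e) {
      warning("Hessian is singular; using pseudo-inverse")
      pseudo_inverse(H)
    })
    Hi <- (Hi + t(Hi)) / 2
    meat <- crossprod(final$scores)
    Vs <- Hi %*% meat %*% Hi
    Vs <- (Vs + t(Vs)) / 2
    dimnames(Hi) <- dimnames(Vs) <- list(nm, nm)
    res$vcov_hessian <- Hi
    res$vcov_sandwich <- Vs
  }
  class(res) <- "mxl_fit"
  res
}

# lower-triangular Cholesky-type factor of a positive *semi*definite matrix
# (zero pivots allowed), used when mapping simulator covariances onto the
# estimation parameterization
psd_chol <- function(M, tol = 1e-10) {
  n <- nrow(M)
  L <- matrix(0, n, n)
  scale <- max(diag(M), 1)
  for (j in seq_len(n)) {
    prev <- seq_len(j - 1)
    d <- M[j, j] - sum(L[j, prev]^2)
    if (d < -tol * scale) stop("matrix is not positive semidefinite")
    L[j, j] <- sqrt(max(d, 0))
    if (j < n) {
      below <- (j + 1):n
      r <- M[below, j] -
        L[below, prev, drop = FALSE] %*% L[j, prev]
      if (L[j, j] > 0) L[below, j] <- r / L[j, j]
      else if (any(abs(r) > tol * scale))
        stop("matrix is not positive semidefinite")
    }
  }
  L
}

pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Preference-space multinomial logit (V = b'a + b_c * cost): globally
# concave, so any quasi-Newton run finds the optimum.  Its solution,
# converted to WTP space (alpha = -b_c, beta = b / alpha), seeds the
# WTP-space fits, which are not concave and can stall on the alpha -> 0
# plateau when started naively.
pref_space_start <- function(prep) {
  Z <- cbind(prep$A, cost = prep$cost)
  ts <- prep$task_start
  nt <- length(ts) - 1L
  row_task <- rep(seq_len(nt), diff(ts))
  chosen <- prep$chosen == 1L
  negll <- function(b) {
    v <- drop(Z %*% b)
    mx <- tapply(v, row_task, max)[row_task]
    e <- exp(v - mx)
    se <- tapply(e, row_task, sum)[row_task]
    -sum(log(e[chosen] / se[chosen]))
  }
  grad <- function(b) {
    v <- drop(Z %*% b)
    mx <- tapply(v, row_task, max)[row_task]
    e <- exp(v - mx)
    se <- tapply(e, row_task, sum)[row_task]
    p <- e / se
    -drop(crossprod(Z, (chosen - p)))
  }
  opt <- optim(numeric(ncol(Z)), negll, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  b <- opt$par
  bc <- b[length(b)]
  alpha <- if (bc < -1e-8) -bc else 0.05
  list(beta = b[-length(b)] / alpha, pi = log(alpha))
}

#' Fit the fixed-coefficient (multinomial logit) model
#'
#' Maximizes the WTP-space likelihood with all random components switched
#' off: `beta_n = mu + lambda x_n`, `alpha_n = exp(pi + gamma x_n)`.  Used
#' on its own and as the starting point for [fit_mxl()].
#'
#' @param data a `choice_data` object.
#' @param covariates covariate `data.frame` (can be a bare `respondent_id`
#'   table when `spec` declares `covariates = character(0)`).
#' @param spec a [model_spec()].
#' @param start optional named start vector over the free parameters.
#' @param se compute variance matrices (inverse Hessian and
#'   respondent-clustered sandwich).
#' @return An object of class `mxl_fit`.
#' @export
fit_mnl <- function(data, covariates, spec = model_spec(), start = NULL,
                    se = TRUE) {
  spec0 <- spec
  spec0$random_coefs <- character(0)
  spec0$money_random <- FALSE
  prep <- prepare_estimation(data, covariates, spec0)
  lay <- prep$layout
  if (is.null(start)) {
    ps <- pref_space_start(prep)
    start <- numeric(sum(lay$free))
    start[seq_len(lay$K)] <- ps$beta
    start[lay$K + lay$K * lay$C + 1] <- ps$pi
  }
  dm <- matrix(0, 0, 0)
  opt <- run_bfgs(start, prep, dm, 1L, spec0)
  finish_fit(opt, prep, dm, 1L, spec0, "mnl", seed = NA_integer_, se = se)
}

#' Fit the WTP-space mixed logit by maximum simulated likelihood
#'
#' Estimates `mu`, `lambda`, `pi`, `gamma` and the Cholesky factor of the
#' joint covariance of the random components by BFGS on the simulated
#' log-likelihood, using a fixed scrambled-Sobol draw set.  Starting values
#' come from [fit_mnl()] with the Cholesky initialized to a small positive
#' diagonal.  Non-convergence is flagged on the result, never silent.
#'
#' @inheritParams fit_mnl
#' @param seed integer seed for the scrambled Sobol draws.
#' @param draws optional pre-built [make_draws()] draw set (its dimension
#'   must match the model's random-coefficient count).
#' @return An object of class `mxl_fit`: estimated parameter set, maximized
#'   simulated log-likelihood, gradient norm, inverse-Hessian and sandwich
#'   variance matrices, convergence flag, draw count and seed.
#' @export
fit_mxl <- function(data, covariates, spec = model_spec(), seed = 1L,
                    start = NULL, se = TRUE, draws = NULL) {
  prep <- prepare_estimation(data, covariates, spec)
  lay <- prep$layout
  if (lay$D == 0) return(fit_mnl(data, covariates, spec, se = se))
  if (is.null(draws))
    draws <- make_draws(length(prep$ids), spec$n_draws, lay$D, seed = seed)
  if (draws$dim != lay$D)
    stop("draw set dimension ", draws$dim, " != model dimension ", lay$D)
  if (draws$n_respondents != length(prep$ids))
    stop("draw set respondents != dataset respondents")
  if (is.null(start)) {
    mnl <- fit_mnl(data, covariates, spec, se = FALSE)
    start <- numeric(sum(lay$free))
    nm <- lay$par_names[lay$free]
    start[match(names(mnl$par), nm)] <- mnl$par
    diag_names <- paste0("chol[", lay$rand_names, ",", lay$rand_names, "]")
    init <- ifelse(lay$rand_names == "money", spec$chol_init[2],
                   spec$chol_init[1])
    start[match(diag_names, nm)] <- init
  }
  opt <- run_bfgs(start, prep, draws$draws, draws$n_draws, spec)
  res <- finish_fit(opt, prep, draws$draws, draws$n_draws, spec, "mxl",
                    seed = seed, se = se)
  if (!res$convergence)
    warning("optimizer did not converge within ", spec$maxit, " iterations")
  res
}

#' @export
print.mxl_fit <- function(x, ...) {
  cat("WTP-space ", toupper(x$model_type), " fit: ",
      x$n_respondents, " respondents, logLik ", sprintf("%.2f", x$loglik),
      if (x$model_type == "mxl") paste0(", ", x$n_draws, " draws"),
      ", ", if (x$convergence) "converged" else "NOT converged", "\n",
      sep = "")
  cat("mu (EUR):\n")
  print(round(x$params$mu, 3))
  cat("exp(pi) =", signif(exp(x$params$pi), 4), "\n")
  if (x$layout$D > 0) {
    cat("sd of random components:\n")
    print(round(sqrt(diag(x$params$omega)), 3))
  }
  invisible(x)
}

#' @export
logLik.mxl_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par), class = "logLik")
}

#' @export
coef.mxl_fit <- function(object, ...) object$par

#' @export
vcov.mxl_fit <- function(object, type = c("sandwich", "hessian"), ...) {
  type <- match.arg(type)
  v <- if (type == "sandwich") object$vcov_sandwich else object$vcov_hessian
  if (is.null(v)) stop("fit was computed without standard errors (se = FALSE)")
  v
}

#' Wald test of a joint zero restriction
#'
#' Quadratic-form test `theta' V^-1 theta` for a subset of the estimated
#' parameter vector against a chi-square with as many degrees of freedom as
#' restricted coefficients.  The respondent-clustered sandwich variance is
#' used by default; a singular sub-matrix falls back to a pseudo-inverse
#' with a warning (degrees of freedom unchanged).
#'
#' @param result an `mxl_fit`.
#' @param subset parameter names or indices into `coef(result)`.
#' @param vcov_type `"sandwich"` (default) or `"hessian"`.
#' @return `list(statistic, df, p)`.
#' @export
wald_test <- function(result, subset, vcov_type = c("sandwich", "hessian")) {
  V <- vcov.mxl_fit(result, match.arg(vcov_type))
  if (is.character(subset)) {
    idx <- match(subset, names(result$par))
    if (anyNA(idx))
      stop("unknown parameter(s): ",
           paste(subset[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(subset)
  if (any(idx < 1 | idx > length(result$par)))
    stop("subset indices out of range")
  th <- result$par[idx]
  Vs <- V[idx, idx, drop = FALSE]
  Vi <- tryCatch(solve(Vs), error = function(e) {
    warning("singular sub-variance-matrix in wald_test; using pseudo-inverse")
    pseudo_inverse(Vs)
  })
  stat <- drop(t(th) %*% Vi %*% th)
  df <- length(idx)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

significance_marker <- function(p) {
  cut(p, breaks = c(-Inf, 0.01, 0.05, 0.10, Inf),
      labels = c("***", "**", "*", "ns")) |> as.character()
}
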