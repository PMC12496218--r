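true_params_to_list <- function(tp) {
  list(mu = as.list(tp$mu), pi = tp$pi,
       lambda = if (ncol(tp$lambda) > 0)
         setNames(lapply(seq_len(ncol(tp$lambda)),
                         function(j) as.numeric(tp$lambda[, j])),
                  colnames(tp$lambda)) else NULL,
       lambda_rows = names(tp$mu),
       gamma = as.numeric(tp$gamma),
       omega_chol = lapply(seq_len(nrow(tp$omega_chol)),
                           function(i) as.numeric(tp$omega_chol[i, ])),
       covariates = as.list(tp$covariates),
       baseline = if (length(tp$baseline)) as.list(tp$baseline) else NULL)
}

true_params_from_list <- function(x) {
  mu <- unlist(x$mu)
  K <- length(mu)
  lam_names <- names(x$lambda)
  lambda <- if (length(lam_names))
    matrix(unlist(x$lambda), nrow = K,
           dimnames = list(unlist(x$lambda_rows), lam_names))
  else matrix(0, K, 0)
  true_parameters(
    mu = mu, pi = x$pi, lambda = lambda,
    gamma = unlist(x$gamma) %||% numeric(ncol(lambda)),
    omega_chol = do.call(rbind, lapply(x$omega_chol, as.numeric)),
    covariates = unlist(x$covariates) %||% character(0),
    baseline = if (length(x$baseline)) unlist(x$baseline) else NULL)
}

#' Read a fixture manifest
#'
#' Reloads the YAML manifest written by [make_fixture()], reconstructing
#' the true parameter set exactly.
#'
#' @param path path to `manifest.yaml`.
#' @return A list with `seed`, `n_respondents`, `package_version`, and
#'   `true_params` (a [true_parameters()] object).
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  m$true_params <- true_params_from_list(m$true_params)
  m
}

#' Serialize / deserialize an estimation result
#'
#' Writes a fitted model to a portable JSON file holding the full parameter
#' vector, both variance matrices, the log-likelihood and all
#' reproducibility metadata; `read_estimation_result` restores it.
#'
#' @param result an object of class `mxl_fit`.
#' @param path output JSON path.
#' @return `write_estimation_result` returns `path` invisibly;
#'   `read_estimation_result` returns the restored `mxl_fit`.
#' @export
write_estimation_result <- function(result, path) {
  ser <- list(
    package_version = as.character(utils::packageVersion("wtpmxl")),
    model = result$model_type,
    loglik = result$loglik,
    convergence = result$convergence,
    grad_norm = result$grad_norm,
    n_draws = result$n_draws,
    seed = result$seed,
    n_respondents = result$n_respondents,
    par = as.list(setNames(as.numeric(result$par), names(result$par))),
    free_names = names(result$par),
    vcov_hessian = result$vcov_hessian,
    vcov_sandwich = result$vcov_sandwich,
    layout = result$layout,
    baseline = as.list(result$baseline),
    covariate_groups = result$covariate_groups,
    iterations = result$iterations)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_estimation_result
#' @export
read_estimation_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- setNames(as.numeric(x$par), x$free_names)
  layout <- x$layout
  layout$rand_idx <- as.integer(layout$rand_idx)
  for (nm in c("K", "C", "D")) layout[[nm]] <- as.integer(layout[[nm]])
  layout$free <- as.logical(layout$free)
  for (nm in c("slot_names", "x_names", "rand_names", "par_names"))
    layout[[nm]] <- as.character(unlist(layout[[nm]]))
  res <- list(model_type = x$model, par = par, loglik = x$loglik,
              convergence = x$convergence, grad_norm = x$grad_norm,
              n_draws = x$n_draws, seed = x$seed,
              n_respondents = x$n_respondents,
              vcov_hessian = nm_matrix(x$vcov_hessian, names(par)),
              vcov_sandwich = nm_matrix(x$vcov_sandwich, names(par)),
              layout = layout,
              baseline = unlist(x$baseline),
              covariate_groups = lapply(x$covariate_groups, as.integer),
              iterations = x$iterations,
              params = NULL)
  res$params <- par_to_params(par, layout)
  class(res) <- "mxl_fit"
  res
}

nm_matrix <- function(m, nm) {
  if (is.null(m)) return(NULL)
  m <- as.matrix(m)
  dimnames(m) <- list(nm, nm)
  m
}
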