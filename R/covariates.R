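#' Build the respondent covariate design matrix
#'
#' Expands the covariate table into the numeric matrix \eqn{X_n} entering
#' the coefficient means: continuous and ordinal covariates pass through,
#' categorical `voting` and `region` are one-hot encoded against a declared
#' baseline level (shift parameterization), which is omitted.  The default
#' baseline is the largest category, mirroring the use of the
#' largest-support party as the reference in applied work.
#'
#' @param covariates covariate `data.frame` keyed by `respondent_id`.
#' @param use character vector of covariate columns to include (default:
#'   every column except `respondent_id`).
#' @param baseline named list/character vector giving the baseline level for
#'   categorical columns, e.g. `c(voting = "PiS")`.  Missing entries default
#'   to the most frequent level.
#' @return A list with `X` (numeric matrix, one row per respondent, informative
#'   column names such as `votingKO`), `baseline` (named character vector),
#'   `groups` (named list mapping each original covariate to its column
#'   indices in `X`), and `respondent_id`.
#' @export
covariate_design <- function(covariates, use = NULL, baseline = NULL) {
  stopifnot("respondent_id" %in% names(covariates))
  if (is.null(use)) use <- setdiff(names(covariates), "respondent_id")
  miss <- setdiff(use, names(covariates))
  if (length(miss))
    stop("covariate column(s) not found: ", paste(miss, collapse = ", "))
  cols <- list(); groups <- list(); bl <- character(0)
  for (nm in use) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      v <- as.character(v)
      tab <- sort(table(v), decreasing = TRUE)
      ref <- if (!is.null(baseline) && nm %in% names(baseline))
        as.character(baseline[[nm]]) else names(tab)[1]
      if (!ref %in% v)
        stop("baseline level '", ref, "' absent from covariate '", nm, "'")
      lev <- c(ref, setdiff(names(tab), ref))
      f <- factor(v, levels = lev)
      m <- model.matrix(~ f)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, lev[-1])
      cols[[nm]] <- m
      bl[nm] <- ref
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  at <- 0L
  for (nm in use) {
    k <- ncol(cols[[nm]])
    groups[[nm]] <- seq_len(k) + at
    at <- at + k
  }
  list(X = X, baseline = bl, groups = groups,
       respondent_id = covariates$respondent_id)
}

#' @importFrom stats model.matrix
NULL
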