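# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# compact two-attribute fixture with known parameters (two parties)
small_fixture <- function() {
  cached("small_fixture", function() make_fixture(recovery_config(150, seed = 42)))
}

# mixed logit fit of the small fixture, with standard errors
small_fit <- function() {
  cached("small_fit", function() {
    fx <- small_fixture()
    spec <- model_spec(covariates = "voting", baseline = c(voting = "gray"),
                      n_draws = 100)
    fit_mxl(fx$data, fx$covariates, spec, seed = 7)
  })
}

# MNL fit of the same fixture (for nesting checks)
small_mnl <- function() {
  cached("small_mnl", function() {
    fx <- small_fixture()
    spec <- model_spec(covariates = "voting", baseline = c(voting = "gray"))
    fit_mnl(fx$data, fx$covariates, spec)
  })
}

# fixture with deterministic, exactly orthogonal numeric covariates
decomp_fixture <- function() {
  cached("decomp_fixture", function() {
    fx <- make_fixture(recovery_config(100, seed = 33))
    fx$covariates$x1 <- rep(c(1, -1), 50)
    fx$covariates$x2 <- rep(c(1, 1, -1, -1), 25)
    fx
  })
}

decomp_spec <- model_spec(covariates = c("x1", "x2"))

# a raw (labelled) one-respondent table under the default rewilding design
raw_choice_rows <- function() {
  data.frame(
    respondent_id = 1, task = rep(0:11, each = 3), alt = rep(0:2, 12),
    is_sq = rep(c(1, 0, 0), 12),
    forest = rep(c("status quo", "low", "high"), 12),
    river = rep(c("status quo", "medium", "low"), 12),
    agriculture = rep(c("status quo", "high", "medium"), 12),
    connectivity = rep(c("status quo", "low", "low"), 12),
    carnivores = rep(c("none", "just wolf", "both"), 12),
    herbivores = rep(c("none", "elk", "both"), 12),
    cost_eur = rep(c(0, 50, 100), 12),
    chosen = rep(c(0, 1, 0), 12))
}

# hand-built estimation result (no fitting) for analysis-function tests:
# takes a parameter list and the data/covariate context it refers to
manual_result <- function(params, data, covariates, spec) {
  prep <- wtpmxl:::prepare_estimation(data, covariates, spec)
  lay <- prep$layout
  par_full <- wtpmxl:::params_to_full_par(params, lay)
  par <- setNames(par_full[lay$free], lay$par_names[lay$free])
  structure(list(model_type = "manual", par = par,
                 params = wtpmxl:::par_to_params(par_full[lay$free], lay),
                 loglik = NA_real_, grad_norm = NA_real_, convergence = TRUE,
                 iterations = 0L, n_draws = 0L, seed = NA_integer_,
                 n_respondents = length(prep$ids), layout = lay,
                 baseline = prep$cd$baseline,
                 covariate_groups = prep$cd$groups,
                 vcov_hessian = NULL, vcov_sandwich = NULL),
            class = "mxl_fit")
}
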