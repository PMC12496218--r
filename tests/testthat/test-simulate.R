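test_that("covariate sampling respects shares, seeds and point masses", {
  base <- recovery_config(40, seed = 5)
  one <- base
  one$party_shares <- party_meta("A", 1)
  cov1 <- sample_covariates(one)
  expect_true(all(cov1$voting == "A"))
  # binomial bound at n = 10^4 for a 0.3 share
  big <- recovery_config(10000, seed = 6)
  big$party_shares <- party_meta(c("A", "B"), c(0.3, 0.7))
  covb <- sample_covariates(big)
  ph <- mean(covb$voting == "A")
  expect_lt(abs(ph - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  # same seed twice -> identical
  expect_identical(sample_covariates(base), sample_covariates(base))
})

test_that("individual coefficients follow the hierarchical structure", {
  cfg <- recovery_config(8, seed = 2)
  cov <- sample_covariates(cfg)
  tp <- cfg$true_params
  # degenerate draw: zero covariance, no covariates
  tp0 <- true_parameters(mu = tp$mu, pi = tp$pi)
  co <- draw_individual_coefficients(cov, tp0, seed = 1)
  expect_equal(unname(as.matrix(co[paste0("beta_", names(tp$mu))])),
               matrix(tp$mu, 8, 3, byrow = TRUE))
  expect_equal(co$alpha, rep(exp(tp$pi), 8))
  # moment checks at 10^5 draws
  cfgN <- recovery_config(1e5, seed = 3)
  covN <- sample_covariates(cfgN)
  coN <- draw_individual_coefficients(covN, cfgN$true_params, seed = 4)
  cd <- covariate_design(covN, use = "voting", baseline = c(voting = "gray"))
  mean_beta <- matrix(cfgN$true_params$mu, 1e5, 3, byrow = TRUE) +
    cd$X %*% t(cfgN$true_params$lambda)
  B <- as.matrix(coN[paste0("beta_", names(cfgN$true_params$mu))])
  Om <- omega_matrix(cfgN$true_params)
  for (k in 1:3) {
    se <- sqrt(Om[k, k] / 1e5)
    expect_lt(abs(mean(B[, k]) - mean(mean_beta[, k])), 4 * se)
  }
  resid <- B - mean_beta
  Shat <- var(resid)
  # sampling sd of a covariance entry is about |entry| * sqrt(2/n)
  expect_lt(max(abs(Shat - Om[1:3, 1:3])),
            6 * max(diag(Om)) * sqrt(2 / 1e5))
  expect_true(all(coN$alpha > 0))
  # log-alpha residual variance matches the money diagonal
  eta <- log(coN$alpha) - (cfgN$true_params$pi +
                             drop(cd$X %*% cfgN$true_params$gamma))
  expect_lt(abs(var(eta) - Om[4, 4]), 0.01)
})

test_that("simulated choices follow the analytic logit shares", {
  # fixed coefficients, many replicate tasks: empirical shares match softmax
  d <- design_spec(
    attributes = list(
      attribute_spec("river", "log_level",
                     c("status quo", "low", "medium", "high"), 1:4),
      attribute_spec("cost_eur", "cost")),
    n_tasks_per_respondent = 1, n_program_alternatives = 2,
    cost_levels = c(10, 50))
  n <- 20000
  df <- data.frame(
    respondent_id = rep(seq_len(n), each = 3),
    task = 0L, alt = rep(0:2, n), is_sq = rep(c(1L, 0L, 0L), n),
    river = rep(c(0, log(2), log(4)), n),
    cost_eur = rep(c(0, 10, 50), n), chosen = NA_integer_)
  template <- as_choice_data(df, d, check_chosen = FALSE)
  beta_sq <- 20; beta_river <- 30; alpha <- 0.05
  co <- data.frame(respondent_id = seq_len(n), beta_sq = beta_sq,
                   beta_river = beta_river, alpha = alpha)
  sim <- simulate_choices(template, co, seed = 31)
  v <- alpha * c(beta_sq, beta_river * log(2) - 10, beta_river * log(4) - 50)
  p_oracle <- exp(v - max(v)) / sum(exp(v - max(v)))  # hand softmax
  shares <- tapply(sim$chosen, sim$alt, sum) / n
  mc <- 3.5 * sqrt(p_oracle * (1 - p_oracle) / n)
  expect_true(all(abs(as.numeric(shares) - p_oracle) < mc))
  # zero coefficients: uniform thirds
  co0 <- data.frame(respondent_id = seq_len(n), beta_sq = 0,
                    beta_river = 0, alpha = 1e-8)
  sim0 <- simulate_choices(template, co0, seed = 8)
  sh0 <- tapply(sim0$chosen, sim0$alt, sum) / n
  expect_true(all(abs(as.numeric(sh0) - 1 / 3) < 3.5 * sqrt(2 / 9 / n)))
  # dominated status quo never gets chosen
  codom <- data.frame(respondent_id = seq_len(n), beta_sq = -1e4,
                      beta_river = 0, alpha = 0.05)
  simdom <- simulate_choices(template, codom, seed = 9)
  expect_equal(sum(simdom$chosen[simdom$is_sq == 1]), 0)
  # non-finite utility is rejected with a diagnostic
  cobad <- data.frame(respondent_id = seq_len(n), beta_sq = Inf,
                      beta_river = 0, alpha = 1)
  expect_error(simulate_choices(template, cobad, seed = 1), "non-finite")
})

test_that("fixtures are reproducible bundles with faithful manifests", {
  cfg <- recovery_config(50, seed = 17)
  dir <- tempfile()
  fx <- make_fixture(cfg, dir = dir)
  expect_equal(length(unique(fx$data$respondent_id)), 50)
  expect_equal(nrow(unique(as.data.frame(fx$data)[c("respondent_id", "task")])),
               50 * 12)
  m <- read_manifest(file.path(dir, "manifest.yaml"))
  expect_equal(m$seed, 17)
  expect_equal(m$true_params$mu, cfg$true_params$mu)
  expect_equal(m$true_params$lambda, cfg$true_params$lambda)
  expect_equal(m$true_params$omega_chol, cfg$true_params$omega_chol)
  expect_equal(m$true_params$baseline, cfg$true_params$baseline)
  # same config -> identical dataset; different seed -> different choices
  fx2 <- make_fixture(cfg)
  expect_identical(as.data.frame(fx2$data), as.data.frame(fx$data))
  cfg3 <- recovery_config(50, seed = 18)
  fx3 <- make_fixture(cfg3)
  expect_false(identical(fx3$data$chosen, fx$data$chosen))
})

test_that("the study-scale default emulates the survey structure", {
  cfg <- default_simulation_config(n_respondents = 80, seed = 3)
  expect_equal(cfg$design$n_tasks_per_respondent, 12L)
  expect_equal(cfg$design$n_program_alternatives, 2L)
  expect_true(cfg$design$has_status_quo)
  expect_equal(sum(cfg$party_shares$share), 1)
  fx <- make_fixture(cfg)
  expect_equal(nrow(fx$data), 80 * 12 * 3)
  s <- sq_share(fx$data, fx$covariates)
  expect_true(attr(s, "overall") > 0 && attr(s, "overall") < 1)
})
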