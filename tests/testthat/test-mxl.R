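test_that("systematic utility is the money-metric form", {
  expect_equal(systematic_utility(rep(0, 7), 50, rep(0, 7), 1), -50)
  # status-quo alternative: only the ASC enters, scaled by alpha
  x <- c(1, rep(0, 6)); b <- c(3, rep(0, 6))
  expect_equal(systematic_utility(x, 0, b, 2), 6)
  # homogeneity of degree one in alpha
  set.seed(1)
  for (i in 1:10) {
    x <- runif(4); b <- rnorm(4); cost <- runif(1, 0, 100); a <- runif(1, 0, 2)
    expect_equal(systematic_utility(x, cost, b, 2 * a),
                 2 * systematic_utility(x, cost, b, a))
  }
  expect_error(systematic_utility(c(1, NA), 0, c(1, 1), 1), "non-finite")
})

test_that("choice probabilities are an overflow-safe softmax", {
  expect_equal(choice_probability(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(choice_probability(c(log(2), 0)), c(2 / 3, 1 / 3))
  p <- choice_probability(c(1000, 0))
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1)
  expect_equal(p[1], 1, tolerance = 1e-12)
  expect_error(choice_probability(5), "two alternatives")
  expect_error(choice_probability(c(Inf, 0)), "finite")
})

test_that("simulated likelihood collapses to analytic MNL at zero covariance", {
  fx <- small_fixture()
  tp <- fx$true_params
  p0 <- list(mu = tp$mu, lambda = tp$lambda, pi = tp$pi, gamma = tp$gamma,
             omega_chol = matrix(0, 4, 4))
  spec <- model_spec(covariates = "voting", baseline = c(voting = "gray"),
                     n_draws = 64)
  dr <- make_draws(150, 64, 4, seed = 3)
  sim <- simulated_loglik(p0, fx$data, fx$covariates, dr, spec)
  spec_mnl <- model_spec(random_coefs = character(0), money_random = FALSE,
                         covariates = "voting", baseline = c(voting = "gray"))
  ana <- simulated_loglik(p0, fx$data, fx$covariates, NULL, spec_mnl)
  expect_equal(sim$loglik, ana$loglik, tolerance = 1e-12)
  # and it does not depend on the draw set
  dr2 <- make_draws(150, 32, 4, seed = 99)
  sim2 <- simulated_loglik(p0, fx$data, fx$covariates, dr2, spec)
  expect_equal(sim2$loglik, sim$loglik, tolerance = 1e-12)
})

test_that("analytic gradient matches finite differences", {
  fx <- cached("grad_fixture", function() make_fixture(recovery_config(40, seed = 13)))
  spec <- model_spec(covariates = "voting", baseline = c(voting = "gray"),
                     n_draws = 32)
  prep <- wtpmxl:::prepare_estimation(fx$data, fx$covariates, spec)
  lay <- prep$layout
  dr <- make_draws(40, 32, 4, seed = 5)
  tp <- fx$true_params
  p0 <- wtpmxl:::params_to_full_par(
    list(mu = tp$mu, lambda = tp$lambda, pi = tp$pi, gamma = tp$gamma,
         omega_chol = tp$omega_chol), lay)[lay$free]
  f <- function(p) wtpmxl:::eval_loglik(p, prep, dr$draws, dr$n_draws,
                                        want_grad = FALSE)$loglik
  g <- wtpmxl:::eval_loglik(p0, prep, dr$draws, dr$n_draws)$grad
  g_fd <- vapply(seq_along(p0), function(i) {
    h <- 1e-5 * max(1, abs(p0[i]))
    e <- numeric(length(p0)); e[i] <- h
    (f(p0 + e) - f(p0 - e)) / (2 * h)
  }, 0)
  expect_lt(max(abs(g - g_fd) / pmax(1, abs(g_fd))), 1e-4)
})

test_that("currency rescaling is a reparameterization, not a model change", {
  fx <- small_fixture()
  tp <- fx$true_params
  spec <- model_spec(covariates = "voting", baseline = c(voting = "gray"),
                     n_draws = 32)
  dr <- make_draws(150, 32, 4, seed = 21)
  base <- simulated_loglik(
    list(mu = tp$mu, lambda = tp$lambda, pi = tp$pi, gamma = tp$gamma,
         omega_chol = tp$omega_chol),
    fx$data, fx$covariates, dr, spec)
  # double every cost; double mu/lambda and the WTP rows of the Cholesky,
  # shift pi by -log(2): identical likelihood
  d <- attr(fx$data, "design")
  df2 <- as.data.frame(fx$data)
  df2$cost_eur <- 2 * df2$cost_eur
  d2 <- d; d2$cost_levels <- 2 * d$cost_levels
  data2 <- as_choice_data(df2, d2)
  oc2 <- tp$omega_chol
  oc2[1:3, ] <- 2 * oc2[1:3, ]
  resc <- simulated_loglik(
    list(mu = 2 * tp$mu, lambda = 2 * tp$lambda, pi = tp$pi - log(2),
         gamma = tp$gamma, omega_chol = oc2),
    data2, fx$covariates, dr, spec)
  expect_equal(resc$loglik, base$loglik, tolerance = 1e-10)
})

test_that("MNL estimation recovers zero-covariance truth", {
  cfg <- recovery_config(1500, seed = 23)
  cfg$true_params$omega_chol <- matrix(0, 4, 4)
  fx <- make_fixture(cfg)
  spec <- model_spec(covariates = "voting", baseline = c(voting = "gray"))
  fit <- fit_mnl(fx$data, fx$covariates, spec)
  expect_true(fit$convergence)
  se <- sqrt(diag(fit$vcov_sandwich))
  truth <- wtpmxl:::params_to_full_par(
    list(mu = cfg$true_params$mu, lambda = cfg$true_params$lambda,
         pi = cfg$true_params$pi, gamma = cfg$true_params$gamma,
         omega_chol = cfg$true_params$omega_chol),
    fit$layout)[fit$layout$free]
  expect_true(all(abs(fit$par - truth) < 3.5 * se))
  # optimality: fitted likelihood at least as high as at the truth
  at_truth <- simulated_loglik(
    list(mu = cfg$true_params$mu, lambda = cfg$true_params$lambda,
         pi = cfg$true_params$pi, gamma = cfg$true_params$gamma,
         omega_chol = matrix(0, 4, 4)),
    fx$data, fx$covariates, NULL,
    model_spec(random_coefs = character(0), money_random = FALSE,
               covariates = "voting", baseline = c(voting = "gray")))
  expect_gte(fit$loglik, at_truth$loglik)
})

test_that("near-uniform data yields the uniform benchmark likelihood", {
  cfg <- recovery_config(200, seed = 29)
  cfg$true_params <- true_parameters(
    mu = c(sq = 0, river = 0, herbivores = 0), pi = -12)
  fx <- make_fixture(cfg)
  spec <- model_spec(covariates = character(0))
  # alpha sits near its boundary here, so skip the (singular) Hessian
  fit <- fit_mnl(fx$data, fx$covariates, spec, se = FALSE)
  n_tasks <- 200 * 12
  expect_lt(abs(fit$loglik - n_tasks * log(1 / 3)), 6)
  # constant attribute columns are reported as unidentified
  d <- attr(fx$data, "design")
  df <- as.data.frame(fx$data)
  df$river <- 0
  expect_error(fit_mnl(as_choice_data(df, d), fx$covariates, spec),
               "river")
})

test_that("the mixed logit nests the MNL", {
  mnl <- small_mnl()
  mxl <- small_fit()
  expect_true(mxl$convergence)
  expect_gte(mxl$loglik, mnl$loglik)
  # spec with no random coefficients reduces to the MNL exactly
  spec0 <- model_spec(random_coefs = character(0), money_random = FALSE,
                      covariates = "voting", baseline = c(voting = "gray"))
  fx <- small_fixture()
  red <- fit_mxl(fx$data, fx$covariates, spec0, seed = 1)
  expect_equal(red$par, mnl$par, tolerance = 1e-6)
  expect_equal(red$loglik, mnl$loglik, tolerance = 1e-8)
})

test_that("draw-count doubling moves the converged objective only slightly", {
  fx <- small_fixture()
  tp <- fx$true_params
  spec <- model_spec(covariates = "voting", baseline = c(voting = "gray"))
  p <- list(mu = tp$mu, lambda = tp$lambda, pi = tp$pi, gamma = tp$gamma,
            omega_chol = tp$omega_chol)
  ll <- vapply(c(250, 500, 1000), function(R) {
    dr <- make_draws(150, R, 4, seed = 77)
    simulated_loglik(p, fx$data, fx$covariates, dr, spec)$loglik
  }, 0)
  expect_lt(abs(ll[3] - ll[2]), abs(ll[2] - ll[1]) + 0.5)
  expect_lt(abs(ll[3] - ll[2]) / abs(ll[3]), 5e-3)
})

test_that("Wald machinery has the textbook identities", {
  fit <- small_fit()
  # one coefficient: statistic is the squared z-score, exactly
  nm <- "lambda[river:votinggreen]"
  wt <- wald_test(fit, nm)
  z2 <- (fit$par[[nm]] / sqrt(fit$vcov_sandwich[nm, nm]))^2
  expect_equal(wt$statistic, unname(z2), tolerance = 1e-12)
  expect_equal(wt$df, 1)
  # permutation invariance of the subset
  sub <- c("mu[sq]", "mu[river]", "pi")
  expect_equal(wald_test(fit, sub)$statistic,
               wald_test(fit, rev(sub))$statistic, tolerance = 1e-10)
  expect_error(wald_test(fit, "nope"), "unknown parameter")
})
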