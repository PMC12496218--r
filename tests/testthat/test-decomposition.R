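test_that("explained share covers the boundary and constructed cases", {
  fx <- decomp_fixture()
  v1 <- var(fx$covariates$x1)
  mk <- function(lambda, omega_diag) {
    oc <- diag(sqrt(omega_diag))
    manual_result(list(mu = c(sq = 10, river = 20, herbivores = 5),
                       lambda = lambda, pi = -3, gamma = c(0, 0),
                       omega_chol = oc),
                  fx$data, fx$covariates, decomp_spec)
  }
  lam0 <- matrix(0, 3, 2, dimnames = list(NULL, c("x1", "x2")))
  # no loadings: nothing explained
  r <- mk(lam0, c(1, 4, 1, 0.01))
  expect_equal(explained_share(r, fx$covariates, "river"), 0)
  # no residual variance: fully explained
  lam <- lam0; lam[2, 1] <- 7
  r <- mk(lam, c(1, 0, 1, 0.01))
  expect_equal(explained_share(r, fx$covariates, "river"), 100)
  # residual variance set equal to the observed part: exactly half
  r <- mk(lam, c(1, 49 * v1, 1, 0.01))
  expect_equal(explained_share(r, fx$covariates, "river"), 50)
  # degenerate: no variance at all is missing, not zero
  r <- mk(lam0, c(1, 0, 1, 0.01))
  expect_warning(es <- explained_share(r, fx$covariates, "river"), "zero")
  expect_true(is.na(es))
  expect_error(explained_share(r, fx$covariates, "nope"), "unknown")
})

test_that("covariate contributions normalize and respect symmetry", {
  fx <- decomp_fixture()
  lam <- matrix(c(0, 3, 0, 0, -3, 0), 3, 2,
                dimnames = list(NULL, c("x1", "x2")))
  r <- manual_result(list(mu = c(sq = 10, river = 20, herbivores = 5),
                          lambda = lam, pi = -3, gamma = c(0, 0),
                          omega_chol = diag(c(1, 2, 1, 0.1))),
                     fx$data, fx$covariates, decomp_spec)
  # equal |loading| on orthogonal covariates of equal variance: 50/50
  c1 <- covariate_contribution(r, fx$covariates, "river", "x1")
  c2 <- covariate_contribution(r, fx$covariates, "river", "x2")
  expect_equal(c1$relative, 50)
  expect_equal(c2$relative, 50)
  # zero loading contributes nothing
  lam2 <- lam; lam2[2, 2] <- 0
  r2 <- manual_result(list(mu = c(sq = 10, river = 20, herbivores = 5),
                           lambda = lam2, pi = -3, gamma = c(0, 0),
                           omega_chol = diag(c(1, 2, 1, 0.1))),
                      fx$data, fx$covariates, decomp_spec)
  expect_equal(covariate_contribution(r2, fx$covariates, "river", "x2")$relative, 0)
  # single nonzero loading captures all explained heterogeneity
  expect_equal(covariate_contribution(r2, fx$covariates, "river", "x1")$relative, 100)
  expect_error(covariate_contribution(r, fx$covariates, "river", character(0)),
               "nonempty")
  expect_error(covariate_contribution(r, fx$covariates, "river", "zzz"),
               "unknown")
})

test_that("group Wald markers agree with single-coefficient z-tests", {
  fit <- small_fit()
  gw <- group_wald_significance(fit, "river", "voting")
  nm <- "lambda[river:votinggreen]"
  z <- fit$par[[nm]] / sqrt(fit$vcov_sandwich[nm, nm])
  p_z <- 2 * pnorm(-abs(z))
  expect_equal(gw$p, unname(p_z), tolerance = 1e-10)
  expect_equal(gw$df, 1)
})

test_that("decomposition tables are normalized Table-style grids", {
  fx <- decomp_fixture()
  set.seed(41)
  lam <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("x1", "x2")))
  oc <- diag(c(2, 3, 1.5, 0.2)); oc[2, 1] <- 1
  r <- manual_result(list(mu = c(sq = 10, river = 20, herbivores = 5),
                          lambda = lam, pi = -3, gamma = c(0.1, -0.2),
                          omega_chol = oc),
                     fx$data, fx$covariates, decomp_spec)
  tab <- build_decomposition_table(r, fx$covariates)
  # every row (including cost and the mean row) sums to 100
  expect_true(all(abs(tab$sum - 100) < 1e-6))
  expect_setequal(tab$attribute, c("sq", "river", "herbivores", "cost", "mean"))
  # the mean row averages the non-monetary attributes only
  body <- tab[tab$attribute %in% c("river", "herbivores"), ]
  mrow <- tab[tab$attribute == "mean", ]
  expect_equal(mrow$x1, mean(body$x1))
  expect_equal(mrow$x2, mean(body$x2))
  expect_equal(mrow$explained_share, mean(body$explained_share))
  # invariant to the ordering of the respondent rows
  tab2 <- build_decomposition_table(r, fx$covariates[rev(seq_len(100)), ])
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
  # group maps must partition the covariate set
  expect_error(build_decomposition_table(r, fx$covariates,
                                         groups = list(a = "x1")),
               "partition")
  expect_error(build_decomposition_table(r, fx$covariates,
                                         groups = list(a = c("x1", "x2"),
                                                       b = "x2")),
               "partition")
})

test_that("a fitted model's decomposition is internally consistent", {
  fit <- small_fit()
  fx <- small_fixture()
  tab <- build_decomposition_table(fit, fx$covariates)
  expect_true(all(abs(tab$sum - 100) < 1e-6))
  expect_true(all(tab$explained_share >= 0 & tab$explained_share <= 100))
  st <- attr(tab, "significance")
  expect_true(all(unlist(st) %in% c("ns", "*", "**", "***")))
})
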