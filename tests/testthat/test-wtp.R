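test_that("log-attribute WTP transformations follow the closed forms", {
  # at the lowest level the marginal WTP is the coefficient itself
  for (b in c(-5, 0, 13.7, 27.62))
    expect_equal(marginal_wtp_log(b, 1), b)
  expect_equal(marginal_wtp_log(10, 2), 5)
  expect_equal(marginal_wtp_log(10, 2, "discrete"), 10 * (log(3) - log(2)))
  expect_equal(marginal_wtp_log(0, 7), 0)
  expect_error(marginal_wtp_log(1, 0.5), "at least 1")
})

test_that("linear species attributes scale WTP by the level code", {
  set.seed(2)
  b <- rnorm(20, 50, 20)
  for (code in 0:3)
    expect_equal(linear_attribute_wtp(b, code), b * code)
  expect_error(linear_attribute_wtp(10, -1), "nonnegative")
})

test_that("per-party WTP tables carry baseline means and party shifts", {
  fit <- small_fit()
  tab <- party_wtp_table(fit)
  expect_s3_class(tab, "wtp_table")
  expect_equal(attr(tab, "baseline"), "gray")
  base_rows <- tab[tab$party == "gray", ]
  # baseline shift identically zero, with no standard error
  expect_true(all(base_rows$shift == 0))
  expect_true(all(is.na(base_rows$shift_se)))
  expect_equal(base_rows$wtp[base_rows$attribute == "river"],
               unname(fit$par["mu[river]"]))
  # shift and its SE equal the lambda coefficient and its SE
  g <- tab[tab$party == "green" & tab$attribute == "river", ]
  expect_equal(g$shift, unname(fit$par["lambda[river:votinggreen]"]))
  expect_equal(g$shift_se,
               sqrt(fit$vcov_sandwich["lambda[river:votinggreen]",
                                      "lambda[river:votinggreen]"]))
  expect_equal(g$wtp, unname(fit$par["mu[river]"] +
                               fit$par["lambda[river:votinggreen]"]))
  # confidence intervals contain the point estimate
  expect_true(all(tab$ci_lo <= tab$wtp & tab$wtp <= tab$ci_hi))
  # known simulated shifts are recovered within 3 SE
  truth <- small_fixture()$true_params$lambda[, "votinggreen"]
  for (at in names(truth)) {
    row <- tab[tab$party == "green" & tab$attribute == at, ]
    expect_lt(abs(row$shift - truth[[at]]), 3 * row$shift_se)
  }
  expect_error(party_wtp_table(fit, party_meta(c("gray", "pink"), c(0.5, 0.5))),
               "pink")
})

test_that("status-quo shares are pure counts", {
  fx <- small_fixture()
  s <- sq_share(fx$data, fx$covariates, by = "voting")
  df <- as.data.frame(fx$data)
  # independent tally
  oracle_all <- sum(df$is_sq == 1 & df$chosen == 1) / (150 * 12)
  expect_equal(attr(s, "overall"), oracle_all)
  for (g in s$group) {
    ids <- fx$covariates$respondent_id[fx$covariates$voting == g]
    sub <- df[df$respondent_id %in% ids, ]
    expect_equal(s$sq_share[s$group == g],
                 sum(sub$is_sq == 1 & sub$chosen == 1) / (length(ids) * 12))
  }
  # row order invariance
  perm <- as_choice_data(df[sample.int(nrow(df)), ], attr(fx$data, "design"))
  s2 <- sq_share(perm, fx$covariates, by = "voting")
  expect_equal(s2, s)
  # saturation: everyone picks the status quo
  df_sat <- df
  df_sat$chosen <- as.integer(df_sat$is_sq == 1)
  sat <- sq_share(as_choice_data(df_sat, attr(fx$data, "design")))
  expect_equal(attr(sat, "overall"), 1)
  # a party with no respondents is missing, not zero
  s3 <- sq_share(fx$data, fx$covariates, by = "voting",
                 groups = c("gray", "green", "purple"))
  expect_true(is.na(s3$sq_share[s3$group == "purple"]))
})

test_that("model-predicted SQ probabilities are coherent", {
  fx <- small_fixture()
  # degenerate model: all coefficients zero -> every alternative at 1/3
  spec0 <- model_spec(random_coefs = character(0), money_random = FALSE,
                      covariates = character(0))
  zero <- manual_result(list(mu = c(sq = 0, river = 0, herbivores = 0),
                             lambda = NULL, pi = -30, gamma = NULL,
                             omega_chol = matrix(0, 4, 4)),
                        fx$data, fx$covariates, spec0)
  p0 <- predicted_sq_probability(zero, fx$data, fx$covariates, by = NULL)
  expect_equal(attr(p0, "overall"), 1 / 3, tolerance = 1e-9)
  # a hugely negative SQ constant drives the probability to zero
  neg <- manual_result(list(mu = c(sq = -1e5, river = 0, herbivores = 0),
                            lambda = NULL, pi = 0, gamma = NULL,
                            omega_chol = matrix(0, 4, 4)),
                       fx$data, fx$covariates, spec0)
  pn <- predicted_sq_probability(neg, fx$data, fx$covariates, by = NULL)
  expect_lt(attr(pn, "overall"), 1e-12)
  # self-consistency: fitted model reproduces the empirical share
  fit <- small_fit()
  pr <- predicted_sq_probability(fit, fx$data, fx$covariates, by = "voting")
  emp <- sq_share(fx$data, fx$covariates, by = "voting")
  expect_lt(abs(attr(pr, "overall") - attr(emp, "overall")), 0.05)
  expect_true(all(abs(pr$sq_prob - emp$sq_share) < 0.08))
})

test_that("party summaries average the right attribute groups", {
  parties <- c("A", "B")
  tab <- expand.grid(party = parties,
                     attribute = c("sq", "forest", "river", "agriculture",
                                   "connectivity", "carnivores", "herbivores"),
                     stringsAsFactors = FALSE)
  wtp_map <- c(sq = 0, forest = 10, river = 20, agriculture = 30,
               connectivity = 44, carnivores = 50, herbivores = 70)
  tab$wtp <- wtp_map[tab$attribute] + ifelse(tab$party == "B", 5, 0)
  s <- dimension_means(tab)
  expect_equal(s$landscape_wtp[s$party == "A"], 20)   # mean(10, 20, 30)
  expect_equal(s$connectivity_wtp[s$party == "A"], 44)
  expect_equal(s$animal_wtp[s$party == "A"], 60)      # mean(50, 70)
  expect_equal(s$landscape_wtp[s$party == "B"], 25)
  pm <- party_meta(parties, c(0.6, 0.4), econ_lr = c(3, 7),
                   eu_position = c(6, 2))
  s2 <- dimension_means(tab, pm)
  expect_equal(s2$econ_lr, c(3, 7))
  expect_error(dimension_means(tab[tab$attribute != "river", ]), "river")
})
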