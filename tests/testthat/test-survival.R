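test_that("survival calls honour the 400/300 px boundaries exactly", {
  pre <- data.frame(track_id = 1, time = 0:5, area_px = 100 * exp(0.3 * (0:5)))
  mk_post <- function(delta) data.frame(track_id = 1, time = 0:16,
                                        area_px = 50 + delta * (0:16) / 16)
  expect_equal(call_survival(pre, mk_post(400))$call, "survivor")
  expect_equal(call_survival(pre, mk_post(299))$call, "non_survivor")
  expect_equal(call_survival(pre, mk_post(350))$call, "ignored")
  expect_equal(call_survival(pre, mk_post(0))$call, "non_survivor")

  short <- data.frame(track_id = 1, time = 0:10, area_px = rep(50, 11))
  expect_error(call_survival(pre, short), "window")

  # calls partition records; the ignored band is exactly [300, 400)
  deltas <- seq(250, 450, by = 10)
  calls <- vapply(deltas, function(d) call_survival(pre, mk_post(d))$call,
                  character(1))
  expect_true(all(calls[deltas < 300] == "non_survivor"))
  expect_true(all(calls[deltas >= 300 & deltas < 400] == "ignored"))
  expect_true(all(calls[deltas >= 400] == "survivor"))
})

test_that("binned survival frequencies match hypergeometric enumeration", {
  rec <- data.frame(call = c(rep("survivor", 10), rep("non_survivor", 10)),
                    pre_mu = c(rep(0.1, 10), rep(0.4, 10)))
  out <- survival_by_bin(rec, "pre_mu", c(0, 0.25, 0.5))
  expect_equal(out$pct_survival, c(100, 0))
  expect_equal(out$p[1], 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(out$p[1], enum_fisher_p(10, 0, 0, 10), tolerance = 1e-12)

  # identical survival in all bins: p near 1
  rec2 <- data.frame(call = rep(c("survivor", "non_survivor"), 10),
                     pre_mu = rep(c(0.1, 0.1, 0.4, 0.4), 5))
  out2 <- survival_by_bin(rec2, "pre_mu", c(0, 0.25, 0.5))
  expect_true(all(out2$p >= 0.99))

  # ignored records are dropped before binning
  rec3 <- rbind(rec, data.frame(call = "ignored", pre_mu = 0.1))
  expect_equal(sum(survival_by_bin(rec3, "pre_mu", c(0, 0.25, 0.5))$n), 20)

  # one bin holding every record is degenerate
  out4 <- suppressWarnings(survival_by_bin(rec, "pre_mu", c(0, 0.5, 1)))
  expect_true(out4$degenerate[1])
  expect_true(is.na(out4$p[1]))

  # random small tables agree with the enumeration oracle
  set.seed(4)
  for (i in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    s1 <- rbinom(1, n1, 0.5); s2 <- rbinom(1, n2, 0.5)
    rec5 <- data.frame(
      call = c(rep("survivor", s1), rep("non_survivor", n1 - s1),
               rep("survivor", s2), rep("non_survivor", n2 - s2)),
      pre_mu = c(rep(0.1, n1), rep(0.4, n2)))
    out5 <- survival_by_bin(rec5, "pre_mu", c(0, 0.25, 0.5))
    expect_equal(out5$p[1], enum_fisher_p(s1, n1 - s1, s2, n2 - s2),
                 tolerance = 1e-9)
  }
})

test_that("logistic regression recovers planted effects and prefers parsimony", {
  coh <- simulate_survival_cohort(5000, beta0 = 2.5, beta_mu = -8,
                                  beta_genotype = 0.7, seed = 42)
  fit <- logistic_survival_model(coh)
  cf <- fit$coefficients
  b_mu <- cf[cf$term == "mu", ]
  b_g <- cf[cf$term == "genotypeg1", ]
  expect_lt(abs(b_mu$estimate - (-8)), 2 * b_mu$se)
  expect_lt(abs(b_g$estimate - 0.7), 2 * b_g$se)
  expect_lt(b_mu$estimate, 0)   # survival decreases with growth rate

  # no planted interaction: the main-effects model wins in >= 90% of
  # seeded replicates
  sel <- vapply(1:50, function(s) {
    coh_s <- simulate_survival_cohort(1500, beta0 = 2.5, beta_mu = -8,
                                      beta_genotype = 0.7, seed = 1000 + s)
    logistic_survival_model(coh_s)$selected
  }, character(1))
  expect_gte(mean(sel == "main_effects"), 0.9)

  all_live <- data.frame(mu = runif(20), genotype = rep(c("g0", "g1"), 10),
                         survived = TRUE)
  expect_error(logistic_survival_model(all_live), "separation")
  sep_mu <- data.frame(mu = c(runif(10, 0, 0.2), runif(10, 0.5, 0.7)),
                       genotype = rep(c("g0", "g1"), 10),
                       survived = rep(c(TRUE, FALSE), each = 10))
  expect_error(logistic_survival_model(sep_mu), "mu")
})

test_that("plating survival test uses the arcsine square-root transform", {
  same <- plating_survival_test(rep(c(0.1, 0.12, 0.11), 2),
                                rep(c("a", "b"), each = 3))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  ab <- plating_survival_test(c(0.10, 0.12, 0.11, 0.30, 0.33, 0.29),
                              rep(c("a", "b"), each = 3))
  expect_lt(ab$p, 0.01)
  # closed-form oracle on the transformed values
  za <- asin(sqrt(c(0.10, 0.12, 0.11))); zb <- asin(sqrt(c(0.30, 0.33, 0.29)))
  sp <- sqrt((2 * var(za) + 2 * var(zb)) / 4)
  t_manual <- (mean(za) - mean(zb)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(ab$t, t_manual, tolerance = 1e-12)
  expect_equal(ab$p, 2 * pt(-abs(t_manual), df = 4), tolerance = 1e-12)

  # p = 0 transforms to 0 without error
  expect_silent(plating_survival_test(c(0, 0.01, 0, 0.2, 0.3),
                                      c("a", "a", "a", "b", "b")))
  expect_error(plating_survival_test(c(1.2, 0.5, 0.5, 0.6),
                                     c("a", "a", "b", "b")), "0, 1")
})

test_that("survival probability decreasing in growth rate gives negative slope", {
  coh <- simulate_survival_cohort(800, beta0 = 2, beta_mu = -6,
                                  beta_genotype = 0, seed = 7)
  fit <- logistic_survival_model(coh)
  cf <- fit$coefficients
  expect_lt(cf$estimate[cf$term == "mu"], 0)
})
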