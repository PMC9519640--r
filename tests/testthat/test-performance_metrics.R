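test_that("auc equals brute-force pair enumeration and handles degenerate orderings", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.2, 0.1),
                                c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(auc_mann_whitney(rep(0.3, 50),
                                rep(c(TRUE, FALSE), 25))$auc, 0.5)
  expect_error(auc_mann_whitney(runif(5), rep(TRUE, 5)), "both outcome")
  set.seed(41)
  for (r in 1:10) {
    n <- sample(20:200, 1)
    p <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # ties guaranteed
    y <- runif(n) < 0.3
    if (all(y) || all(!y)) next
    pe <- p[y]; pn <- p[!y]
    brute <- (sum(outer(pe, pn, ">")) + 0.5 * sum(outer(pe, pn, "=="))) /
      (length(pe) * length(pn))
    expect_equal(auc_mann_whitney(p, y)$auc, brute, tolerance = 1e-12)
  }
})

test_that("auc is invariant under strictly increasing transforms", {
  d <- toy_logit_data(n = 400, seed = 43)
  a0 <- auc_mann_whitney(d$p, d$y)$auc
  for (tr in list(function(x) 3 * x - 1, qlogis, function(x) x^3)) {
    expect_equal(auc_mann_whitney(tr(d$p), d$y)$auc, a0,
                 tolerance = 1e-12)
  }
})

test_that("the reference cross-tab NIRIS model has AUC 0.70 with a DeLong CI", {
  recs <- expand_crosstab(ref_xtab())
  fit <- customize_ct_model(recs, "niris")
  a <- auc_mann_whitney(fit$fitted_probabilities, recs$dead_6mo)
  expect_equal(round(a$auc, 2), 0.70)
  expect_lt(a$ci_low, a$auc)
  expect_gt(a$ci_high, a$auc)
  expect_true(a$ci_low >= 0 && a$ci_high <= 1)
})

test_that("auc agrees with pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  d <- toy_logit_data(n = 300, seed = 47)
  mine <- auc_mann_whitney(d$p, d$y)
  ref <- pROC::roc(d$y, d$p, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(mine$ci_low, mine$ci_high), ci[c(1, 3)],
               tolerance = 1e-7)
})

test_that("delong comparison is symmetric, self-consistent, and matches pROC", {
  d <- toy_logit_data(n = 300, seed = 53)
  set.seed(54)
  p2 <- plogis(qlogis(d$p) + rnorm(300, sd = 1))
  self <- delong_compare(d$p, d$p, d$y)
  expect_equal(self$auc_a - self$auc_b, 0)
  expect_equal(self$p_value, 1)
  ab <- delong_compare(d$p, p2, d$y)
  ba <- delong_compare(p2, d$p, d$y)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  # structural-component mean reproduces the Mann-Whitney AUC exactly
  expect_equal(ab$auc_a, auc_mann_whitney(d$p, d$y)$auc,
               tolerance = 1e-12)
  expect_error(delong_compare(d$p[-1], p2, d$y), "length")
  skip_if_not_installed("pROC")
  r1 <- pROC::roc(d$y, d$p, quiet = TRUE, direction = "<")
  r2 <- pROC::roc(d$y, p2, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(ab$p_value, ref$p.value, tolerance = 1e-7)
})

test_that("nagelkerke r-squared follows its closed form and the reference value", {
  mk <- function(ll1, ll0, n) list(log_likelihood = ll1,
                                   null_log_likelihood = ll0, n = n)
  expect_equal(nagelkerke_r2(mk(-100, -100, 50)), 0)
  expect_equal(nagelkerke_r2(mk(0, -60, 100)), 1)
  expect_error(nagelkerke_r2(mk(-120, -100, 50)), "not nested")
  recs <- expand_crosstab(ref_xtab())
  fit <- customize_ct_model(recs, "niris")
  expect_equal(round(nagelkerke_r2(fit), 3), 0.147)
  # duplication of every observation enters only through n
  ll0 <- fit$null_log_likelihood; ll1 <- fit$log_likelihood; n <- fit$n
  for (k in c(2, 5)) {
    closed <- (1 - exp(2 * k * (ll0 - ll1) / (k * n))) /
      (1 - exp(2 * k * ll0 / (k * n)))
    expect_equal(nagelkerke_r2(mk(k * ll1, k * ll0, k * n)), closed,
                 tolerance = 1e-12)
    expect_equal(closed, nagelkerke_r2(fit), tolerance = 1e-12)
  }
})

test_that("hosmer-lemeshow is exact on perfectly calibrated bins and rejects coarse risks", {
  # 10 risk levels, observed rate equal to predicted within each level
  p <- rep(seq(0.05, 0.5, 0.05), each = 40)
  y <- unlist(lapply(seq(0.05, 0.5, 0.05),
                     function(r) rep(c(TRUE, FALSE), c(r * 40, 40 - r * 40))))
  hl <- hosmer_lemeshow(p, y, groups = 10)
  expect_equal(hl$chi2, 0, tolerance = 1e-12)
  expect_equal(hl$p_value, 1)
  expect_equal(hl$df, 8)
  coarse <- rep(seq(0.1, 0.9, 0.1), each = 20)  # 9 distinct levels
  yc <- rep(c(TRUE, FALSE), 90)
  expect_error(hosmer_lemeshow(coarse, yc, groups = 10),
               "not applicable")
})

test_that("idi reproduces direct arithmetic, its second representation, and antisymmetry", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  p_old <- c(0.6, 0.4, 0.3, 0.1)
  p_new <- c(0.7, 0.5, 0.2, 0.2)
  res <- idi(p_new, p_old, y)
  expect_equal(res$idi, 0.1, tolerance = 1e-12)
  expect_equal(res$idi,
               (res$mean_p_new_events - res$mean_p_old_events) -
                 (res$mean_p_new_nonevents - res$mean_p_old_nonevents))
  expect_equal(idi(p_old, p_old, y)$idi, 0)
  expect_equal(idi(p_old, p_new, y)$idi, -res$idi, tolerance = 1e-12)
  expect_true(res$idi >= -2 && res$idi <= 2)
  # integral representation on a larger, tied-value set
  d <- toy_logit_data(n = 500, seed = 67)
  set.seed(68)
  pn <- round(plogis(qlogis(d$p) + rnorm(500, sd = 0.5)), 2)
  po <- round(d$p, 2)
  r <- idi(pn, po, d$y)
  expect_equal(r$idi, (r$is_new - r$is_old) - (r$ip_new - r$ip_old),
               tolerance = 1e-8)
  expect_error(idi(pn[-1], po, d$y), "length")
})

test_that("bootstrap idi interval is seeded, covers the estimate, and stays near the analytic one", {
  d <- toy_logit_data(n = 400, seed = 71)
  set.seed(72)
  pn <- plogis(qlogis(d$p) + rnorm(400, sd = 0.4))
  set.seed(1)
  b1 <- idi(pn, d$p, d$y, ci_method = "bootstrap", boot_reps = 500)
  set.seed(1)
  b2 <- idi(pn, d$p, d$y, ci_method = "bootstrap", boot_reps = 500)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_lt(b1$ci_low, b1$idi)
  expect_gt(b1$ci_high, b1$idi)
  a <- idi(pn, d$p, d$y)
  expect_equal(b1$ci_high - b1$ci_low, a$ci_high - a$ci_low,
               tolerance = 0.35)
})

test_that("chi-square independence matches hand computation and flags degenerate tables", {
  even <- crosstab(0:2, events = c(10, 20, 30),
                   nonevents = c(20, 40, 60))
  expect_equal(chi_square_independence(even)$chi2, 0, tolerance = 1e-12)
  hand <- chi_square_independence(matrix(c(10, 20, 10, 0), 2))
  expect_equal(round(hand$chi2, 2), 13.33)
  expect_equal(hand$df, 1)
  ref <- chi_square_independence(ref_xtab())
  expect_lt(ref$p_value, 0.01)
  expect_equal(ref$df, 4)
  expect_error(chi_square_independence(
    crosstab(0:1, events = c(0, 0), nonevents = c(5, 5))),
    "marginal")
  expect_error(chi_square_independence(matrix(1:3, 1)), "2 x 2")
})
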