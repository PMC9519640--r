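# Discrimination and calibration battery: Mann-Whitney AUC with DeLong
# confidence interval, DeLong comparison of correlated AUCs,
# Nagelkerke's R-squared, Hosmer-Lemeshow test, integrated
# discrimination improvement (IDI), and Pearson chi-square on
# cross-tabulations.

.check_two_class <- function(outcomes) {
  y <- as.logical(outcomes)
  if (anyNA(y)) stop("outcomes contain missing values", call. = FALSE)
  if (all(y) || all(!y)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  y
}

# DeLong placement values ("structural components"): for each event,
# the fraction of non-events it outranks (ties half-weighted), and
# vice versa. Midranks give an O(n log n) computation.
.delong_placements <- function(p, y) {
  p_ev <- p[y]
  p_ne <- p[!y]
  m <- length(p_ev)
  n <- length(p_ne)
  r_all <- rank(c(p_ev, p_ne), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(p_ev, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(p_ne, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, m = m, n = n,
       auc = mean(v10))
}

#' Mann-Whitney AUC with DeLong confidence interval
#'
#' Area under the ROC curve estimated as the ties-corrected pairwise
#' concordance: (concordant pairs + half the tied pairs) divided by
#' (events x non-events). The 95% confidence interval is a Wald
#' interval on the AUC scale using the DeLong variance, truncated to
#' `[0, 1]`.
#'
#' @param probabilities Numeric risk scores or predicted probabilities.
#' @param outcomes Logical vector, `TRUE` = event.
#' @param conf_level Confidence level, default 0.95.
#' @return A list with `auc`, `ci_low`, `ci_high`, `se`, `n_events`,
#'   `n_nonevents`.
#' @examples
#' auc_mann_whitney(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
#' @export
auc_mann_whitney <- function(probabilities, outcomes,
                             conf_level = 0.95) {
  y <- .check_two_class(outcomes)
  p <- as.numeric(probabilities)
  if (length(p) != length(y)) {
    stop("probabilities and outcomes differ in length", call. = FALSE)
  }
  if (anyNA(p)) stop("probabilities contain missing values", call. = FALSE)
  pl <- .delong_placements(p, y)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = pl$auc,
       ci_low = max(0, pl$auc - z * se),
       ci_high = min(1, pl$auc + z * se),
       se = se, n_events = pl$m, n_nonevents = pl$n)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two risk models evaluated on the same patients
#' using the DeLong structural-component (placement-value) estimator of
#' the joint covariance, with a two-sided normal p-value for the AUC
#' difference. Comparing a model with itself gives difference 0 and
#' p = 1.
#'
#' @param p_model_a,p_model_b Predicted probabilities from the two
#'   models, same patients in the same order.
#' @param outcomes Logical vector, `TRUE` = event.
#' @return A list with `auc_a`, `auc_b`, `covariance` (2x2 matrix for
#'   (AUC_a, AUC_b)), `z`, `p_value`.
#' @export
delong_compare <- function(p_model_a, p_model_b, outcomes) {
  y <- .check_two_class(outcomes)
  pa <- as.numeric(p_model_a)
  pb <- as.numeric(p_model_b)
  if (length(pa) != length(y) || length(pb) != length(y)) {
    stop("model probability vectors must match outcomes in length",
         call. = FALSE)
  }
  pla <- .delong_placements(pa, y)
  plb <- .delong_placements(pb, y)
  s10 <- stats::cov(cbind(pla$v10, plb$v10))
  s01 <- stats::cov(cbind(pla$v01, plb$v01))
  S <- s10 / pla$m + s01 / pla$n
  dimnames(S) <- list(c("a", "b"), c("a", "b"))
  diff <- pla$auc - plb$auc
  v_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (v_diff <= .Machine$double.eps) {
    z <- 0
    p <- 1
  } else {
    z <- diff / sqrt(v_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pla$auc, auc_b = plb$auc, covariance = S,
       z = z, p_value = p)
}

#' Nagelkerke's R-squared
#'
#' Rescaled Cox-Snell pseudo-R-squared of a logistic fit:
#' `R2_CS = 1 - exp(2 (LL0 - LL1) / n)` divided by its maximum
#' attainable value `1 - exp(2 LL0 / n)`, giving a number in `[0, 1]`
#' where 1 indicates a model that fully explains the outcome.
#'
#' @param fit A [fit_logistic()] object (or any list with
#'   `log_likelihood`, `null_log_likelihood` and `n`).
#' @return Numeric scalar in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  ll1 <- fit$log_likelihood
  ll0 <- fit$null_log_likelihood
  n <- fit$n
  if (is.null(ll1) || is.null(ll0) || is.null(n)) {
    stop("fit must carry log_likelihood, null_log_likelihood and n",
         call. = FALSE)
  }
  if (ll1 < ll0 - 1e-8) {
    stop("model log-likelihood is below the null log-likelihood; ",
         "the models are not nested on the same data", call. = FALSE)
  }
  r2_cs <- 1 - exp(2 * (ll0 - ll1) / n)
  r2_cs / (1 - exp(2 * ll0 / n))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Splits patients into risk-ordered groups by quantiles of the
#' predicted probability (ties assigned to the lower bin) and computes
#' `chi2 = sum (O - E)^2 / (E (1 - E / n_g))` over groups, with
#' `groups - 2` degrees of freedom. Models with fewer distinct risk
#' levels than groups (e.g. a 5- or 6-level categorical score) are not
#' testable this way and raise an error.
#'
#' @param probabilities Predicted probabilities.
#' @param outcomes Logical vector, `TRUE` = event.
#' @param groups Number of risk groups, default 10 (deciles of risk).
#' @return A list with `chi2`, `df`, `p_value`, `groups` and a
#'   per-group `table` (n, observed, expected).
#' @export
hosmer_lemeshow <- function(probabilities, outcomes, groups = 10) {
  y <- .check_two_class(outcomes)
  p <- as.numeric(probabilities)
  if (length(p) != length(y)) {
    stop("probabilities and outcomes differ in length", call. = FALSE)
  }
  if (length(p) < groups) {
    stop("need at least as many observations as groups", call. = FALSE)
  }
  if (length(unique(p)) < groups) {
    stop("Hosmer-Lemeshow test not applicable: only ",
         length(unique(p)), " distinct risk levels for ", groups,
         " groups; the test requires at least as many distinct ",
         "predicted probabilities as groups", call. = FALSE)
  }
  breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1),
                                   names = FALSE, type = 2))
  bin <- cut(p, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  obs <- tapply(as.numeric(y), bin, sum)
  expd <- tapply(p, bin, sum)
  ng <- tapply(p, bin, length)
  chi2 <- sum((obs - expd)^2 / (expd * (1 - expd / ng)))
  df <- groups - 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       groups = groups,
       table = data.frame(n = as.integer(ng),
                          observed = as.integer(obs),
                          expected = as.numeric(expd)))
}

# Exact integral over [0,1] of the empirical step function
# c -> mean(p > c): equals mean(p), computed here by explicit
# piecewise-constant summation so the identity can be asserted against
# the group-mean route rather than assumed.
.step_integral <- function(p) {
  grid <- sort(unique(c(0, p, 1)))
  widths <- diff(grid)
  mids <- grid[-length(grid)] + widths / 2
  heights <- vapply(mids, function(c) mean(p > c), numeric(1))
  sum(heights * widths)
}

#' Integrated discrimination improvement (IDI)
#'
#' Difference in discrimination slopes between a new and an old risk
#' model:
#' `IDI = (mean p_new|events - mean p_old|events) -
#'        (mean p_new|nonevents - mean p_old|nonevents)`.
#' The equivalent representation
#' `IDI = (IS_new - IS_old) - (IP_new - IP_old)`, with
#' `IS = integral of sensitivity` and `IP = integral of 1 -
#' specificity` over the calculated-risk axis, is also computed (exact
#' sums over the empirical step functions, no smoothing) and returned.
#' The IDI ranges theoretically from -2 to 2.
#'
#' The default 95% interval is analytic: the standard error combines
#' the within-events and within-nonevents variances of the paired
#' differences `p_new - p_old`, normal-approximated.
#' `ci_method = "bootstrap"` resamples patients (2000 replicates by
#' default) and takes percentile bounds.
#'
#' @param p_new,p_old Predicted probabilities from the new and old
#'   models, same patients in the same order.
#' @param outcomes Logical vector, `TRUE` = event.
#' @param ci_method `"analytic"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates when `ci_method =
#'   "bootstrap"`.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `idi_result`: a list with `idi`, the four
#'   group means (`mean_p_new_events`, `mean_p_old_events`,
#'   `mean_p_new_nonevents`, `mean_p_old_nonevents`), the integral
#'   representation (`is_new`, `is_old`, `ip_new`, `ip_old`), `se`
#'   (analytic), `ci_low`, `ci_high`, `ci_method`.
#' @export
idi <- function(p_new, p_old, outcomes,
                ci_method = c("analytic", "bootstrap"),
                boot_reps = 2000, conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  y <- .check_two_class(outcomes)
  pn <- as.numeric(p_new)
  po <- as.numeric(p_old)
  if (length(pn) != length(y) || length(po) != length(y)) {
    stop("p_new, p_old and outcomes must have the same length",
         call. = FALSE)
  }
  m_new_ev <- mean(pn[y]);  m_old_ev <- mean(po[y])
  m_new_ne <- mean(pn[!y]); m_old_ne <- mean(po[!y])
  est <- (m_new_ev - m_old_ev) - (m_new_ne - m_old_ne)

  is_new <- .step_integral(pn[y]);  is_old <- .step_integral(po[y])
  ip_new <- .step_integral(pn[!y]); ip_old <- .step_integral(po[!y])

  d_ev <- pn[y] - po[y]
  d_ne <- pn[!y] - po[!y]
  se <- sqrt(stats::var(d_ev) / length(d_ev) +
             stats::var(d_ne) / length(d_ne))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "analytic") {
    ci <- c(est - z * se, est + z * se)
  } else {
    n <- length(y)
    stat <- vapply(seq_len(boot_reps), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]
      if (all(yb) || all(!yb)) return(NA_real_)
      (mean(pn[idx][yb]) - mean(po[idx][yb])) -
        (mean(pn[idx][!yb]) - mean(po[idx][!yb]))
    }, numeric(1))
    ci <- unname(stats::quantile(stat,
                                 c((1 - conf_level) / 2,
                                   1 - (1 - conf_level) / 2),
                                 na.rm = TRUE))
  }
  structure(list(idi = est,
                 mean_p_new_events = m_new_ev,
                 mean_p_old_events = m_old_ev,
                 mean_p_new_nonevents = m_new_ne,
                 mean_p_old_nonevents = m_old_ne,
                 is_new = is_new, is_old = is_old,
                 ip_new = ip_new, ip_old = ip_old,
                 se = se, ci_low = ci[1], ci_high = ci[2],
                 ci_method = ci_method),
            class = "idi_result")
}

#' @export
print.idi_result <- function(x, ...) {
  cat(sprintf("IDI = %.4f (95%% CI %.4f to %.4f, %s)\n",
              x$idi, x$ci_low, x$ci_high, x$ci_method))
  invisible(x)
}

#' Construct a category-by-outcome cross-tabulation
#'
#' A minimal container for an ordered-category contingency table of
#' events and non-events, as printed in cohort reports (e.g. NIRIS
#' category against 6-month vital status).
#'
#' @param labels Ordered category labels.
#' @param events,nonevents Non-negative integer counts per category.
#' @return An object of class `ct_crosstab` (a data frame with columns
#'   `label`, `events`, `nonevents`).
#' @export
crosstab <- function(labels, events, nonevents) {
  if (length(events) != length(labels) ||
      length(nonevents) != length(labels)) {
    stop("labels, events and nonevents must have equal length",
         call. = FALSE)
  }
  if (any(events < 0) || any(nonevents < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(data.frame(label = as.character(labels),
                       events = as.integer(events),
                       nonevents = as.integer(nonevents),
                       stringsAsFactors = FALSE),
            class = c("ct_crosstab", "data.frame"))
}

#' Pearson chi-square test of independence on a cross-tabulation
#'
#' Tests whether the outcome distribution depends on the category, with
#' `df = (rows - 1)(cols - 1)` and an upper-tail p-value. No continuity
#' correction is applied.
#'
#' @param xtab A [crosstab()] object, or a numeric matrix of counts
#'   with at least two rows and two columns.
#' @return A list with `chi2`, `df`, `p_value`.
#' @export
chi_square_independence <- function(xtab) {
  m <- if (inherits(xtab, "ct_crosstab")) {
    as.matrix(xtab[, c("events", "nonevents")])
  } else {
    as.matrix(xtab)
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least a 2 x 2 table", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal total; expected counts undefined", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}
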