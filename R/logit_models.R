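# Logistic model fitting: first-level customization of each CT score,
# the clinical base model, and combined clinical + CT models.

#' Fit a logistic regression and return a `logistic_fit`
#'
#' Maximum-likelihood logistic regression via iteratively reweighted
#' least squares (relative log-likelihood convergence 1e-10, at most
#' 100 iterations). The returned object carries both the model and the
#' intercept-only log-likelihood on the same data, so pseudo-R-squared
#' measures can be computed without refitting.
#'
#' Degenerate inputs are rejected rather than silently fitted: a
#' single-class outcome, more parameters than observations, and
#' complete or quasi-complete separation (any coefficient diverging
#' beyond 30 in absolute value) are errors.
#'
#' @param outcome Logical (or 0/1) vector; `TRUE` = event.
#' @param design Numeric matrix of covariates, one column per term,
#'   without an intercept column (the intercept is always added). `NULL`
#'   or a zero-column matrix fits the intercept-only model.
#' @param predictor_spec Optional character description of the
#'   covariates and their coding, stored on the fit.
#' @return An object of class `logistic_fit`: a list with
#'   `coefficients`, `log_likelihood`, `null_log_likelihood`, `n`,
#'   `fitted_probabilities`, `predictor_spec`, `converged`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' y <- runif(200) < plogis(-1 + x)
#' fit <- fit_logistic(y, cbind(x = x))
#' coef(fit)
#' @export
fit_logistic <- function(outcome, design = NULL, predictor_spec = NULL) {
  y <- as.logical(outcome)
  if (anyNA(y)) stop("outcome contains missing values", call. = FALSE)
  n <- length(y)
  if (n == 0) stop("empty outcome vector", call. = FALSE)
  if (all(y) || all(!y)) {
    stop("outcome has a single class; a logit cannot be fitted",
         call. = FALSE)
  }
  if (is.null(design)) {
    design <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  design <- as.matrix(design)
  if (!is.numeric(design)) stop("design must be numeric", call. = FALSE)
  if (nrow(design) != n) {
    stop("design has ", nrow(design), " rows but outcome has ", n,
         call. = FALSE)
  }
  if (anyNA(design)) stop("design contains missing values", call. = FALSE)
  p <- ncol(design) + 1L
  if (n < p) {
    stop("under-determined fit: ", n, " observations for ", p,
         " parameters", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, design)
  # separation is diagnosed explicitly below; silence glm.fit's
  # "fitted probabilities numerically 0 or 1" chatter
  fit <- suppressWarnings(
    stats::glm.fit(X, as.numeric(y),
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)))
  beta <- fit$coefficients
  if (anyNA(beta)) {
    bad <- colnames(X)[is.na(beta)]
    stop("collinear covariate(s) dropped by the fit: ",
         paste(bad, collapse = ", "),
         "; remove or recode them before fitting", call. = FALSE)
  }
  if (any(abs(beta[-1]) > 30)) {
    stop("separation detected: coefficient(s) ",
         paste(names(beta[-1])[abs(beta[-1]) > 30], collapse = ", "),
         " diverged beyond |beta| = 30", call. = FALSE)
  }
  prob <- fit$fitted.values
  ll <- sum(stats::dbinom(as.numeric(y), 1, prob, log = TRUE))
  if (p > 1 && ll > -1e-6) {
    stop("separation detected: the model fits the outcome perfectly ",
         "(deviance ~ 0); maximum-likelihood estimates do not exist",
         call. = FALSE)
  }
  rate <- mean(y)
  ll0 <- sum(y) * log(rate) + sum(!y) * log(1 - rate)
  structure(list(
    coefficients = beta,
    log_likelihood = ll,
    null_log_likelihood = ll0,
    n = n,
    fitted_probabilities = as.numeric(prob),
    outcome = y,
    predictor_spec = predictor_spec %||%
      paste(colnames(X), collapse = " + "),
    converged = fit$converged
  ), class = "logistic_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
logLik.logistic_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit:", x$predictor_spec, "\n")
  cat("  n =", x$n, " events =", sum(x$outcome), "\n")
  cat("  logLik =", format(x$log_likelihood),
      " (null ", format(x$null_log_likelihood), ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

# Dummy-code a categorical score against a reference level, dropping
# levels absent from the data with a warning.
.dummy_code <- function(values, levels_all, reference, label) {
  values <- as.character(values)
  observed <- levels_all[levels_all %in% unique(values)]
  absent <- setdiff(levels_all, observed)
  if (length(absent) > 0) {
    warning(label, " level(s) absent from data, dummies dropped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  non_ref <- setdiff(observed, reference)
  if (length(non_ref) == 0) {
    stop(label, " is constant; it cannot be fitted against the outcome",
         call. = FALSE)
  }
  X <- vapply(non_ref, function(lv) as.numeric(values == lv),
              numeric(length(values)))
  X <- matrix(X, ncol = length(non_ref),
              dimnames = list(NULL, paste0(label, non_ref)))
  X
}

# Extract outcome + scores from a cohort table, computing the scores
# from findings columns when not already present.
.scores_for <- function(records, system) {
  stopifnot(is.data.frame(records))
  if (!"dead_6mo" %in% names(records)) {
    stop("records must carry a 'dead_6mo' outcome column", call. = FALSE)
  }
  if (system %in% names(records)) {
    return(records[[system]])
  }
  score_all(records)[[system]]
}

#' First-level customization of one CT score
#'
#' Refits the logistic link of a CT scoring system to the cohort at
#' hand without changing the score itself: the Marshall classification
#' and NIRIS enter as dummy-coded categorical variables (reference
#' class I, category 0 respectively), the Helsinki score as a single
#' linear term. Scores are computed from the findings columns unless a
#' precomputed column of the same name is present.
#'
#' @param records Cohort table with a logical `dead_6mo` outcome and
#'   either findings columns or a precomputed score column.
#' @param system `"marshall"`, `"helsinki"` or `"niris"`.
#' @return A [fit_logistic()] object.
#' @export
customize_ct_model <- function(records,
                               system = c("marshall", "helsinki",
                                          "niris")) {
  system <- match.arg(system)
  score <- .scores_for(records, system)
  y <- records$dead_6mo
  design <- switch(system,
    marshall = .dummy_code(score, c("I", "II", "III", "IV", "V", "VI"),
                           reference = "I", label = "marshall"),
    niris = .dummy_code(score, as.character(0:4),
                        reference = "0", label = "niris"),
    helsinki = {
      v <- as.numeric(score)
      if (length(unique(v)) < 2) {
        stop("helsinki score is constant; ",
             "collinear with the intercept", call. = FALSE)
      }
      matrix(v, ncol = 1, dimnames = list(NULL, "helsinki"))
    })
  fit_logistic(y, design,
               predictor_spec = paste0(system, " (",
                 if (system == "helsinki") "linear" else "dummy-coded",
                 ")"))
}

.base_covariates <- c("age_years", "gcs", "saps2_modified",
                      "chronic_comorbidity")

# Build the base-model design matrix; drops constant covariates with a
# warning (e.g. a cohort with no comorbid patients).
.base_design <- function(records) {
  missing_cols <- setdiff(.base_covariates, names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing base-model covariate column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- cbind(age_years = as.numeric(records$age_years),
             gcs = as.numeric(records$gcs),
             saps2_modified = as.numeric(records$saps2_modified),
             chronic_comorbidity = as.numeric(records$chronic_comorbidity))
  constant <- apply(X, 2, function(c) length(unique(c)) < 2)
  if (any(constant)) {
    warning("constant base covariate(s) dropped: ",
            paste(colnames(X)[constant], collapse = ", "), call. = FALSE)
    X <- X[, !constant, drop = FALSE]
  }
  X
}

#' Clinical base model for 6-month mortality
#'
#' Fits the clinical reference logit: linear age, linear GCS, linear
#' modified SAPS II (the SAPS II score stripped of its age, GCS and
#' chronic-comorbidity components, supplied as data) and a binary
#' chronic-comorbidity flag.
#'
#' @param records Cohort table with `dead_6mo` and the four clinical
#'   covariates.
#' @return A [fit_logistic()] object.
#' @export
build_base_model <- function(records) {
  if (!"dead_6mo" %in% names(records)) {
    stop("records must carry a 'dead_6mo' outcome column", call. = FALSE)
  }
  X <- .base_design(records)
  fit_logistic(records$dead_6mo, X,
               predictor_spec = paste("base:",
                                      paste(colnames(X),
                                            collapse = " + ")))
}

#' Combined clinical + CT model
#'
#' Adds one CT system (coded as in [customize_ct_model()]) to the
#' clinical base covariates in a single logit fit. The predictor
#' specification lists the base covariates first, then the CT terms.
#'
#' @inheritParams customize_ct_model
#' @return A [fit_logistic()] object.
#' @export
build_combined_model <- function(records,
                                 system = c("marshall", "helsinki",
                                            "niris")) {
  system <- match.arg(system)
  Xbase <- .base_design(records)
  score <- .scores_for(records, system)
  Xct <- switch(system,
    marshall = .dummy_code(score, c("I", "II", "III", "IV", "V", "VI"),
                           reference = "I", label = "marshall"),
    niris = .dummy_code(score, as.character(0:4),
                        reference = "0", label = "niris"),
    helsinki = matrix(as.numeric(score), ncol = 1,
                      dimnames = list(NULL, "helsinki")))
  fit_logistic(records$dead_6mo, cbind(Xbase, Xct),
               predictor_spec = paste0("base: ",
                 paste(colnames(Xbase), collapse = " + "),
                 "; ct: ", system))
}
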