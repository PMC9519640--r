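# Seeded generator of FICC-like TBI cohorts. Category marginals,
# category-conditional mortality, age medians and GCS-band mixtures
# default to the published Finnish ICU TBI cohort tables; the joint
# structure (a single latent severity shared by modified SAPS II and
# mortality) is the generator's own minimal assumption.

#' Default parameters for the synthetic cohort generator
#'
#' Returns the parameter list used by [generate_cohort()]. Defaults
#' reproduce the published cohort's printed marginals: NIRIS category
#' prevalences, category-conditional 6-month mortality, median ages and
#' GCS-band mixtures per category, and the chronic-comorbidity
#' prevalence (8.3%).
#'
#' @param n Cohort size, default 3031.
#' @param niris_probs Probability of NIRIS categories 0-4.
#' @param mortality_by_category 6-month death probability per category.
#' @param age_location_by_category Median age (years) per category.
#' @param gcs_band_probs_by_category 5 x 3 matrix, P(GCS 3-8 / 9-12 /
#'   13-15) within each category.
#' @param comorbidity_prob Probability of a significant chronic
#'   comorbidity.
#' @param saps2_effect Points of modified SAPS II per unit of latent
#'   severity; larger values make SAPS II a cleaner severity readout
#'   and raise base-model discrimination.
#' @param severity_weight Log-odds of death per unit of latent
#'   severity, within category.
#' @param seed Integer seed; the cohort is a deterministic function of
#'   the full parameter set.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n = 3031,
                          niris_probs = c(0.106, 0.074, 0.428, 0.174,
                                          0.219),
                          mortality_by_category = c(0.084, 0.053,
                                                    0.170, 0.270,
                                                    0.466),
                          age_location_by_category = c(38, 43, 54, 59,
                                                       60),
                          gcs_band_probs_by_category = NULL,
                          comorbidity_prob = 0.083,
                          saps2_effect = 15,
                          severity_weight = 2.7,
                          seed = 1L) {
  if (is.null(gcs_band_probs_by_category)) {
    gcs_band_probs_by_category <- rbind(
      c(104, 52, 164) / 320,
      c(77, 37, 111) / 225,
      c(512, 268, 517) / 1297,
      c(240, 138, 148) / 526,
      c(477, 90, 96) / 663)
  }
  # printed category percentages sum to 1.001 by rounding; accept that
  # and renormalise, but reject anything further from a distribution
  if (length(niris_probs) != 5 || any(niris_probs < 0) ||
      abs(sum(niris_probs) - 1) > 2e-3) {
    stop("niris_probs must be 5 non-negative probabilities summing ",
         "to 1", call. = FALSE)
  }
  params <- list(n = n,
                 niris_probs = niris_probs / sum(niris_probs),
                 mortality_by_category = mortality_by_category,
                 age_location_by_category = age_location_by_category,
                 gcs_band_probs_by_category = gcs_band_probs_by_category,
                 comorbidity_prob = comorbidity_prob,
                 saps2_effect = saps2_effect,
                 severity_weight = severity_weight,
                 seed = as.integer(seed))
  validate_cohort_params(params)
  structure(params, class = "cohort_params")
}

#' Validate cohort-generator parameters
#'
#' @param params A list as built by [cohort_params()].
#' @return Invisibly, `params`; errors on violated constraints.
#' @export
validate_cohort_params <- function(params) {
  with(params, {
    if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
      stop("n must be a single non-negative integer", call. = FALSE)
    }
    if (length(niris_probs) != 5 || any(niris_probs < 0) ||
        any(niris_probs > 1) ||
        abs(sum(niris_probs) - 1) > 1e-9) {
      stop("niris_probs must be 5 probabilities summing to 1",
           call. = FALSE)
    }
    if (length(mortality_by_category) != 5 ||
        any(mortality_by_category <= 0) ||
        any(mortality_by_category >= 1)) {
      stop("mortality_by_category must be 5 probabilities in (0,1)",
           call. = FALSE)
    }
    if (length(age_location_by_category) != 5 ||
        any(age_location_by_category <= 18)) {
      stop("age_location_by_category must be 5 medians above 18",
           call. = FALSE)
    }
    g <- gcs_band_probs_by_category
    if (!is.matrix(g) || any(dim(g) != c(5, 3)) || any(g < 0) ||
        any(abs(rowSums(g) - 1) > 1e-9)) {
      stop("gcs_band_probs_by_category must be a 5 x 3 row-stochastic ",
           "matrix", call. = FALSE)
    }
    if (comorbidity_prob < 0 || comorbidity_prob > 1) {
      stop("comorbidity_prob must be in [0,1]", call. = FALSE)
    }
  })
  invisible(params)
}

# Force at least one of several candidate features to be active per
# row: rows where none fired get `force` set TRUE.
.ensure_any <- function(flags, force_col) {
  none <- !Reduce(`|`, flags)
  flags[[force_col]] <- flags[[force_col]] | none
  flags
}

runif_in <- function(n, lo, hi) stats::runif(n, lo, hi)

#' Sample CT findings consistent with a NIRIS category
#'
#' Draws structured findings satisfying the target category's criteria
#' and no higher category's, so `niris_category()` round-trips to
#' `category` for every draw. Within that guarantee, feature mixtures
#' are chosen so that the induced Marshall-class and Helsinki-score
#' distributions follow the published concordance pattern (higher
#' categories dominated by mass lesions over 25 cm^3, cistern
#' compression and IVH increasingly frequent with category). Uses the
#' current R random-number stream.
#'
#' @param category Integer in `0:4`.
#' @param n Number of findings rows to draw.
#' @return A findings `data.frame` with `n` rows, each re-scoring to
#'   `category`.
#' @export
findings_for_category <- function(category, n = 1) {
  stopifnot(length(category) == 1, category %in% 0:4, n >= 0)
  f <- ct_findings()[rep(1, n), , drop = FALSE]
  rownames(f) <- NULL
  if (n == 0 || category == 0) {
    if (n > 0) stopifnot(all(niris_category(f) == 0))
    return(f)
  }
  u <- function(p) stats::runif(n) < p
  if (category == 1) {
    flags <- .ensure_any(list(fracture = u(0.5), pneumo = u(0.12),
                              sah = u(0.55), tiny = u(0.35)),
                         "sah")
    f$skull_fracture <- flags$fracture
    f$pneumocephalus <- flags$pneumo
    f$sah_present <- flags$sah
    tiny_type <- sample(c("sdh", "ich", "edh"), n, replace = TRUE,
                        prob = c(0.45, 0.4, 0.15))
    tv <- runif_in(n, 0.05, 0.45)
    f$sdh_volume_cm3 <- ifelse(flags$tiny & tiny_type == "sdh", tv, 0)
    f$ich_contusion_volume_cm3 <-
      ifelse(flags$tiny & tiny_type == "ich", tv, 0)
    f$edh_volume_cm3 <- ifelse(flags$tiny & tiny_type == "edh", tv, 0)
  } else if (category == 2) {
    flags <- .ensure_any(list(lesion = u(0.85), dai = u(0.12),
                              ivh = u(0.12), hydro = u(0.04),
                              shift = u(0.30)),
                         "lesion")
    type <- sample(c("sdh", "ich", "edh"), n, replace = TRUE,
                   prob = c(0.45, 0.35, 0.20))
    # volumes capped below the category-3 thresholds (15 / 50 cm^3)
    vol <- ifelse(type == "sdh", runif_in(n, 0.5, 45),
                  runif_in(n, 0.5, 14.5))
    f$sdh_volume_cm3 <- ifelse(flags$lesion & type == "sdh", vol, 0)
    f$ich_contusion_volume_cm3 <-
      ifelse(flags$lesion & type == "ich", vol, 0)
    f$edh_volume_cm3 <- ifelse(flags$lesion & type == "edh", vol, 0)
    second <- u(0.25) & flags$lesion
    vol2 <- runif_in(n, 0.5, 10)
    f$ich_contusion_volume_cm3 <- ifelse(
      second & type != "ich" & f$ich_contusion_volume_cm3 == 0,
      vol2, f$ich_contusion_volume_cm3)
    f$sdh_volume_cm3 <- ifelse(
      second & type == "ich" & f$sdh_volume_cm3 == 0,
      vol2, f$sdh_volume_cm3)
    f$dai_present <- flags$dai
    f$ivh_present <- flags$ivh
    f$hydrocephalus <- ifelse(flags$hydro, "mild_moderate", "none")
    f$midline_shift_mm <- ifelse(flags$shift, runif_in(n, 0.5, 5), 0)
    f$sah_present <- u(0.30)
    f$skull_fracture <- u(0.35)
    f$pneumocephalus <- u(0.05)
    f$suprasellar_cisterns <- ifelse(u(0.15), "compressed", "normal")
    f$basal_cisterns <- ifelse(u(0.18), "compressed", "present")
  } else if (category == 3) {
    flags <- .ensure_any(list(bigsdh = u(0.65), midich = u(0.15),
                              shift = u(0.55), herni = u(0.12)),
                         "bigsdh")
    f$sdh_volume_cm3 <- ifelse(flags$bigsdh, runif_in(n, 50.5, 180),
                               ifelse(u(0.4), runif_in(n, 0.5, 45), 0))
    f$ich_contusion_volume_cm3 <-
      ifelse(flags$midich, runif_in(n, 15.5, 20),
             ifelse(u(0.35), runif_in(n, 0.5, 14.5), 0))
    f$midline_shift_mm <- ifelse(flags$shift, runif_in(n, 5.5, 10), 0)
    f$herniation <- ifelse(flags$herni, "focal", "none")
    f$sah_present <- u(0.45)
    f$ivh_present <- u(0.18)
    f$skull_fracture <- u(0.4)
    cist <- stats::runif(n)
    f$suprasellar_cisterns <- ifelse(cist < 0.40, "compressed",
                              ifelse(cist < 0.50, "obliterated",
                                     "normal"))
    bas <- stats::runif(n)
    f$basal_cisterns <- ifelse(bas < 0.35, "compressed",
                        ifelse(bas < 0.45, "absent", "present"))
    big <- pmax(f$sdh_volume_cm3, f$ich_contusion_volume_cm3) > 25
    f$mass_lesion_evacuated <- big & u(0.65)
  } else {
    flags <- .ensure_any(list(bigich = u(0.55), hugesdh = u(0.45),
                              shift = u(0.55), diffuse = u(0.18),
                              duret = u(0.08), hydro = u(0.04)),
                         "bigich")
    f$ich_contusion_volume_cm3 <-
      ifelse(flags$bigich, runif_in(n, 20.5, 120),
             ifelse(u(0.3), runif_in(n, 0.5, 20), 0))
    f$sdh_volume_cm3 <- ifelse(flags$hugesdh, runif_in(n, 30, 150),
                               ifelse(u(0.3), runif_in(n, 0.5, 20), 0))
    # an SDH alone only reaches category 4 above 200 cm^3; pair the
    # 30-150 cm^3 subdurals with another defining feature instead
    f$midline_shift_mm <- ifelse(flags$shift, runif_in(n, 10.5, 25),
                                 ifelse(u(0.4), runif_in(n, 5.5, 10),
                                        0))
    f$herniation <- ifelse(flags$diffuse, "diffuse",
                           ifelse(u(0.25), "focal", "none"))
    f$duret_hemorrhage <- flags$duret
    f$hydrocephalus <- ifelse(flags$hydro, "severe", "none")
    f$sah_present <- u(0.55)
    f$ivh_present <- u(0.35)
    f$skull_fracture <- u(0.45)
    cist <- stats::runif(n)
    f$suprasellar_cisterns <- ifelse(cist < 0.30, "compressed",
                              ifelse(cist < 0.75, "obliterated",
                                     "normal"))
    bas <- stats::runif(n)
    f$basal_cisterns <- ifelse(bas < 0.30, "compressed",
                        ifelse(bas < 0.65, "absent", "present"))
    big <- pmax(f$sdh_volume_cm3, f$ich_contusion_volume_cm3,
                f$edh_volume_cm3) > 25
    f$mass_lesion_evacuated <- big & u(0.6)
  }
  got <- niris_category(f)
  # rejection step: resample any row that slipped out of category
  # (defensive; the construction above keeps within bounds)
  bad <- which(got != category)
  guard <- 0
  while (length(bad) > 0 && guard < 25) {
    f[bad, ] <- findings_for_category(category, length(bad))
    bad <- which(niris_category(f) != category)
    guard <- guard + 1
  }
  if (length(bad) > 0) {
    stop("internal error: could not sample findings for category ",
         category, call. = FALSE)
  }
  f
}

# Category intercepts: solve E_z[plogis(a + w z)] = target for
# z ~ N(0,1), by Gauss-Legendre-free adaptive quadrature.
.solve_category_intercepts <- function(targets, weight) {
  vapply(targets, function(m) {
    marginal <- function(a) {
      stats::integrate(function(z) {
        stats::plogis(a + weight * z) * stats::dnorm(z)
      }, -8, 8, rel.tol = 1e-10)$value - m
    }
    stats::uniroot(marginal, c(-15, 15), tol = 1e-10)$root
  }, numeric(1))
}

#' Generate a synthetic TBI cohort
#'
#' Draws a patient-level cohort with the study-table structure: NIRIS
#' category from `niris_probs`; findings via [findings_for_category()]
#' (guaranteed round-trip); a standard-normal latent severity per
#' patient; GCS band from the category-conditional mixture, then a
#' uniform integer within the band; age from a category-shifted
#' log-normal matching the printed medians (spread from the overall
#' printed IQR); chronic comorbidity as an independent Bernoulli;
#' modified SAPS II increasing in latent severity
#' (`saps2_effect` points per unit); and 6-month death from a logistic
#' model in category and latent severity whose category intercepts are
#' solved numerically so that the expected category-conditional death
#' rates equal `mortality_by_category`.
#'
#' @param params A [cohort_params()] object.
#' @return A `data.frame` of class `synthetic_cohort`: one row per
#'   patient with `patient_id`, clinical covariates, all findings
#'   columns, `dead_6mo`, plus the generating `niris_true` category and
#'   `latent_severity` (kept for recovery tests; not inputs to any
#'   fitted model).
#' @export
generate_cohort <- function(params = cohort_params()) {
  validate_cohort_params(params)
  n <- params$n
  if (n == 0) {
    out <- cbind(data.frame(patient_id = character(0),
                            age_years = numeric(0), gcs = integer(0),
                            saps2_modified = numeric(0),
                            chronic_comorbidity = logical(0)),
                 ct_findings()[0, ],
                 data.frame(dead_6mo = logical(0),
                            niris_true = integer(0),
                            latent_severity = numeric(0)))
    return(structure(out, class = c("synthetic_cohort", "data.frame")))
  }
  set.seed(params$seed, kind = "Mersenne-Twister")
  category <- sample(0:4, n, replace = TRUE, prob = params$niris_probs)
  findings <- ct_findings()[rep(1, n), , drop = FALSE]
  rownames(findings) <- NULL
  for (k in 0:4) {
    idx <- which(category == k)
    if (length(idx) > 0) {
      findings[idx, ] <- findings_for_category(k, length(idx))
    }
  }
  z <- stats::rnorm(n)
  # suprasellar cistern grade responds to mass effect: category level
  # plus latent severity. Not a NIRIS criterion, so the category
  # round-trip is unaffected; it is the main within-category channel
  # through which the Helsinki score tracks prognosis.
  mass_effect <- c(-3.6, -2.8, -1.4, 0.3, 1.1)[category + 1] +
    0.9 * z + stats::rnorm(n, sd = 0.6)
  findings$suprasellar_cisterns <-
    ifelse(mass_effect > 1.1, "obliterated",
           ifelse(mass_effect > 0.1, "compressed", "normal"))
  alpha <- .solve_category_intercepts(params$mortality_by_category,
                                      params$severity_weight)
  p_death <- stats::plogis(alpha[category + 1] +
                             params$severity_weight * z)
  dead <- stats::runif(n) < p_death

  band <- vapply(seq_len(n), function(i) {
    sample.int(3, 1,
               prob = params$gcs_band_probs_by_category[category[i] + 1, ])
  }, integer(1))
  gcs_lo <- c(3L, 9L, 13L)[band]
  gcs_hi <- c(8L, 12L, 15L)[band]
  gcs <- gcs_lo + as.integer(floor(stats::runif(n) *
                                     (gcs_hi - gcs_lo + 1L)))

  med <- params$age_location_by_category[category + 1]
  age <- 18 + stats::rlnorm(n, meanlog = log(med - 18), sdlog = 0.55)
  age <- pmin(round(age, 1), 100)

  saps2 <- round(pmax(0, 16 + params$saps2_effect * z +
                        stats::rnorm(n, sd = 5)))
  comorb <- stats::runif(n) < params$comorbidity_prob

  out <- cbind(data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                          age_years = age, gcs = gcs,
                          saps2_modified = saps2,
                          chronic_comorbidity = comorb,
                          stringsAsFactors = FALSE),
               findings,
               data.frame(dead_6mo = dead, niris_true = category,
                          latent_severity = z))
  structure(out, class = c("synthetic_cohort", "data.frame"))
}

#' Expand a category-by-outcome cross-tabulation to patient level
#'
#' Deterministically rebuilds a patient-level record table from a
#' printed contingency table: one row per count, carrying the category
#' label, the outcome, and a fixed representative findings value per
#' category (so the category re-scores correctly). Clinical covariates
#' are absent; downstream model fitting treats such fixtures as
#' CT-category-only data.
#'
#' @param xtab A [crosstab()] whose labels are NIRIS categories 0-4 (or
#'   a subset).
#' @return A `data.frame` with findings columns, `niris` and `dead_6mo`,
#'   tagged with attribute `crosstab_expansion = TRUE`.
#' @export
expand_crosstab <- function(xtab) {
  stopifnot(inherits(xtab, "ct_crosstab"))
  if (any(xtab$events < 0) || any(xtab$nonevents < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  reps <- list(
    "0" = ct_findings(),
    "1" = ct_findings(sah_present = TRUE),
    "2" = ct_findings(sdh_volume_cm3 = 10),
    "3" = ct_findings(sdh_volume_cm3 = 60,
                      suprasellar_cisterns = "compressed"),
    "4" = ct_findings(ich_contusion_volume_cm3 = 30,
                      midline_shift_mm = 12,
                      suprasellar_cisterns = "obliterated"))
  rows <- lapply(seq_len(nrow(xtab)), function(i) {
    lab <- xtab$label[i]
    total <- xtab$events[i] + xtab$nonevents[i]
    if (total == 0) return(NULL)
    rep_f <- reps[[lab]]
    if (is.null(rep_f)) {
      stop("no representative findings for category label '", lab, "'",
           call. = FALSE)
    }
    f <- rep_f[rep(1, total), , drop = FALSE]
    f$niris <- as.integer(lab)
    f$dead_6mo <- rep(c(TRUE, FALSE),
                      c(xtab$events[i], xtab$nonevents[i]))
    f
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows) == 0) {
    cbind(ct_findings()[0, ],
          data.frame(niris = integer(0), dead_6mo = logical(0)))
  } else {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  attr(out, "crosstab_expansion") <- TRUE
  out
}
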