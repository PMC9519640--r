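# End-to-end orchestration: cohort table I/O, the full validation
# pipeline (scoring -> recalibration -> base/combined fits -> metric
# battery), and report rendering.

.model_rows <- c("NIRIS", "Marshall CT", "Helsinki CT", "Base",
                 "Base + NIRIS", "Base + Marshall CT",
                 "Base + Helsinki CT")

#' Read and validate a cohort table
#'
#' Reads a delimited text file (comma-separated; tab accepted) with one
#' row per patient and the documented column names: the findings
#' columns of [ct_findings_columns()], a logical `dead_6mo`, and
#' optionally `patient_id`, `age_years`, `gcs`, `saps2_modified`,
#' `chronic_comorbidity`. Rows failing validation (invalid findings,
#' GCS outside 3-15, age under 18, negative SAPS II, missing outcome)
#' are dropped; the dropped counts per reason are messaged and attached
#' as attribute `excluded`.
#'
#' @param path File path.
#' @return A validated records `data.frame`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  mandatory <- c(ct_findings_columns(), "dead_6mo")
  miss <- setdiff(mandatory, names(df))
  if (length(miss) > 0) {
    stop("cohort file is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (v in c("sah_present", "ivh_present", "dai_present",
              "skull_fracture", "pneumocephalus", "duret_hemorrhage",
              "mass_lesion_evacuated", "dead_6mo",
              "chronic_comorbidity")) {
    if (v %in% names(df)) df[[v]] <- as.logical(df[[v]])
  }
  if (nrow(df) == 0) {
    warning("cohort file has a header but no rows", call. = FALSE)
    return(df)
  }
  reasons <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    reasons[is.na(reasons) & bad] <<- why
  }
  flag(is.na(df$dead_6mo), "missing dead_6mo outcome")
  if ("gcs" %in% names(df)) {
    flag(!is.na(df$gcs) & (df$gcs < 3 | df$gcs > 15),
         "gcs out of range")
  }
  if ("age_years" %in% names(df)) {
    flag(!is.na(df$age_years) & df$age_years < 18, "age under 18")
  }
  if ("saps2_modified" %in% names(df)) {
    flag(!is.na(df$saps2_modified) & df$saps2_modified < 0,
         "negative saps2_modified")
  }
  findings_ok <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch({
      validate_ct_findings(df[i, ct_findings_columns(), drop = FALSE])
      TRUE
    }, error = function(e) FALSE)
  }, logical(1))
  flag(!findings_ok, "invalid CT findings")
  keep <- is.na(reasons)
  excluded <- as.data.frame(table(reason = reasons[!keep]),
                            stringsAsFactors = FALSE)
  if (nrow(excluded) > 0) {
    names(excluded) <- c("reason", "count")
    for (i in seq_len(nrow(excluded))) {
      message("dropped ", excluded$count[i], " row(s): ",
              excluded$reason[i])
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Write a cohort table
#'
#' Writes records as comma-separated UTF-8 text with a header row,
#' booleans as `TRUE`/`FALSE`, suitable for [read_cohort()]
#' round-tripping.
#'
#' @param records Cohort `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.safe_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full external-validation pipeline
#'
#' Scores every patient with the three CT systems, refits each score's
#' logit (first-level customization), fits the clinical base model and
#' the three combined clinical + CT models, and evaluates each model's
#' discrimination and calibration: Mann-Whitney AUC with DeLong 95% CI,
#' Nagelkerke's R-squared, Hosmer-Lemeshow p (reported `NA` for models
#' with fewer distinct risk levels than groups, i.e. the categorical
#' NIRIS and Marshall recalibrations), DeLong p against the reference
#' model (NIRIS for CT-only models; Base for combined models), and IDI
#' against the base model for the combined models.
#'
#' On fixtures built by [expand_crosstab()] (no patient-level
#' covariates, representative findings only) only the NIRIS row is
#' computed; all other rows are `NA`.
#'
#' @param records Cohort table with outcomes; typically from
#'   [generate_cohort()], [read_cohort()] or [expand_crosstab()].
#' @param config Optional list: `hl_groups` (default 10), `ci_method`
#'   for the IDI (default `"analytic"`), `seed` recorded in the
#'   metadata (and used for bootstrap CIs when requested).
#' @return An object of class `validation_report`: list with `models`
#'   (7-row data frame: `model`, `auc`, `auc_lo`, `auc_hi`, `delong_p`,
#'   `hl_p`, `nagelkerke_r2`, `idi`, `idi_lo`, `idi_hi`), `summary`,
#'   `crosstabs`, `meta`.
#' @export
run_validation <- function(records, config = list()) {
  hl_groups <- config$hl_groups %||% 10
  ci_method <- config$ci_method %||% "analytic"
  if (!"dead_6mo" %in% names(records)) {
    stop("stage 'input': records must carry a 'dead_6mo' outcome",
         call. = FALSE)
  }
  fixture_only <- isTRUE(attr(records, "crosstab_expansion"))
  has_base <- all(.base_covariates %in% names(records)) &&
    !anyNA(records[, .base_covariates])

  if (!is.null(config$seed)) {
    set.seed(config$seed, kind = "Mersenne-Twister")
  }

  if (!fixture_only) {
    scores <- .safe_stage("scoring", score_all(records))
    records$marshall <- as.character(scores$marshall)
    records$helsinki <- scores$helsinki
    records$niris <- scores$niris
  }

  fits <- stats::setNames(vector("list", 7), .model_rows)
  fits[["NIRIS"]] <- .safe_stage("customize niris",
                                 customize_ct_model(records, "niris"))
  if (!fixture_only) {
    fits[["Marshall CT"]] <-
      .safe_stage("customize marshall",
                  customize_ct_model(records, "marshall"))
    fits[["Helsinki CT"]] <-
      .safe_stage("customize helsinki",
                  customize_ct_model(records, "helsinki"))
    if (has_base) {
      fits[["Base"]] <- .safe_stage("base model",
                                    build_base_model(records))
      for (sys in c("niris", "marshall", "helsinki")) {
        row <- paste("Base +",
                     c(niris = "NIRIS", marshall = "Marshall CT",
                       helsinki = "Helsinki CT")[sys])
        fits[[row]] <- .safe_stage(paste("combined", sys),
                                   build_combined_model(records, sys))
      }
    }
  }

  y <- as.logical(records$dead_6mo)
  na_row <- function(model) {
    data.frame(model = model, auc = NA_real_, auc_lo = NA_real_,
               auc_hi = NA_real_, delong_p = NA_real_,
               hl_p = NA_real_, nagelkerke_r2 = NA_real_,
               idi = NA_real_, idi_lo = NA_real_, idi_hi = NA_real_)
  }
  metric_row <- function(model, fit, ref_fit, idi_ref_fit) {
    if (is.null(fit)) return(na_row(model))
    p <- fit$fitted_probabilities
    a <- auc_mann_whitney(p, y)
    hl <- tryCatch(hosmer_lemeshow(p, y, groups = hl_groups)$p_value,
                   error = function(e) NA_real_)
    dl <- if (is.null(ref_fit)) NA_real_ else {
      delong_compare(p, ref_fit$fitted_probabilities, y)$p_value
    }
    iv <- if (is.null(idi_ref_fit)) {
      list(idi = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    } else {
      idi(p, idi_ref_fit$fitted_probabilities, y,
          ci_method = ci_method)
    }
    data.frame(model = model, auc = a$auc, auc_lo = a$ci_low,
               auc_hi = a$ci_high, delong_p = dl, hl_p = hl,
               nagelkerke_r2 = nagelkerke_r2(fit), idi = iv$idi,
               idi_lo = iv$ci_low, idi_hi = iv$ci_high)
  }
  ref_for <- function(model) {
    if (model %in% c("Marshall CT", "Helsinki CT")) {
      fits[["NIRIS"]]
    } else if (startsWith(model, "Base +")) {
      fits[["Base"]]
    } else {
      NULL   # reference rows compare to themselves: reported NA
    }
  }
  models <- do.call(rbind, lapply(.model_rows, function(mr) {
    .safe_stage(paste("metrics", mr),
                metric_row(mr, fits[[mr]], ref_for(mr),
                           if (startsWith(mr, "Base +"))
                             fits[["Base"]] else NULL))
  }))
  rownames(models) <- NULL

  qn <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
  summary_tab <- list(
    n = nrow(records),
    deaths_6mo = sum(y),
    death_rate_6mo = mean(y),
    age_median_iqr = if ("age_years" %in% names(records) &&
                         !anyNA(records$age_years))
      qn(records$age_years) else NULL,
    gcs_median_iqr = if ("gcs" %in% names(records) &&
                         !anyNA(records$gcs))
      qn(records$gcs) else NULL)

  niris_tab <- table(factor(records$niris, levels = 0:4), y)
  xt_outcome <- crosstab(0:4, events = niris_tab[, "TRUE"],
                         nonevents = niris_tab[, "FALSE"])
  xt_marshall <- if (!fixture_only) {
    table(marshall = records$marshall,
          niris = factor(records$niris, levels = 0:4))
  } else NULL

  structure(list(models = models,
                 summary = summary_tab,
                 crosstabs = list(niris_outcome = xt_outcome,
                                  niris_marshall = xt_marshall),
                 meta = list(seed = config$seed %||% NA,
                             n = nrow(records),
                             excluded = attr(records, "excluded"),
                             fixture_only = fixture_only,
                             hl_groups = hl_groups,
                             ci_method = ci_method)),
            class = "validation_report")
}

# Render one numeric cell at display precision; NA cells print "NA".
.fmt <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(round(x, digits), format = "f",
                                 digits = digits))
}

#' Render a validation report as a text table
#'
#' Display precision follows reporting convention: AUC to 2 decimals,
#' Nagelkerke's R-squared and IDI to 3, p-values to 3.
#'
#' @param report A `validation_report`.
#' @return Character vector of table lines.
#' @export
format_report <- function(report) {
  m <- report$models
  tab <- data.frame(
    Model = m$model,
    `AUC (95% CI)` = ifelse(is.na(m$auc), "NA",
      paste0(.fmt(m$auc, 2), " (", .fmt(m$auc_lo, 2), "-",
             .fmt(m$auc_hi, 2), ")")),
    `DeLong p` = .fmt(m$delong_p, 3),
    `H-L p` = .fmt(m$hl_p, 2),
    `Nagelkerke R2` = .fmt(m$nagelkerke_r2, 3),
    `IDI (95% CI)` = ifelse(is.na(m$idi), "NA",
      paste0(.fmt(m$idi, 3), " (", .fmt(m$idi_lo, 3), "-",
             .fmt(m$idi_hi, 3), ")")),
    check.names = FALSE)
  c(sprintf("6-month mortality validation report (n = %d, %d deaths)",
            report$summary$n, report$summary$deaths_6mo),
    utils::capture.output(print(tab, row.names = FALSE)))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Write a validation report to disk
#'
#' `format = "csv"` writes the machine-readable model table (full
#' precision, `NA` cells as `NA`), which re-parses to equal values.
#' `format = "text"` writes the rendered table of [format_report()].
#'
#' @param report A `validation_report`.
#' @param path Output path.
#' @param format `"csv"` or `"text"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("csv", "text")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(report$models, path, row.names = FALSE,
                     quote = TRUE, na = "NA")
  } else {
    writeLines(format_report(report), path)
  }
  invisible(path)
}
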