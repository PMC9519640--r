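# Structured admission-CT findings: construction and validation.

#' Column names of a CT-findings table
#'
#' A cohort table carries one column per structured CT finding, in this
#' order. Volumes are decimal cm^3 of the largest single lesion of each
#' type (0 = absent), midline shift is decimal mm, enums are lowercase
#' strings, flags are logical.
#'
#' @return Character vector of the 15 findings column names.
#' @export
ct_findings_columns <- function() {
  c("edh_volume_cm3", "sdh_volume_cm3", "ich_contusion_volume_cm3",
    "sah_present", "ivh_present", "dai_present", "skull_fracture",
    "pneumocephalus", "suprasellar_cisterns", "basal_cisterns",
    "midline_shift_mm", "hydrocephalus", "herniation",
    "duret_hemorrhage", "mass_lesion_evacuated")
}

.suprasellar_levels <- c("normal", "compressed", "obliterated")
.basal_levels <- c("present", "compressed", "absent")
.hydrocephalus_levels <- c("none", "mild_moderate", "severe")
.herniation_levels <- c("none", "focal", "diffuse")

#' Construct a table of structured CT findings
#'
#' Builds a validated data frame of admission-CT findings, one row per
#' patient. All arguments are recycled to a common length; the default
#' value of every argument is the "all-normal" finding, so
#' `ct_findings()` is a radiologically normal scan.
#'
#' @param edh_volume_cm3 Volume (cm^3) of the largest epidural haematoma;
#'   0 means absent.
#' @param sdh_volume_cm3 Volume (cm^3) of the largest subdural haematoma.
#' @param ich_contusion_volume_cm3 Volume (cm^3) of the largest
#'   intracerebral haematoma or parenchymal contusion.
#' @param sah_present Subarachnoid hemorrhage present?
#' @param ivh_present Intraventricular hemorrhage present?
#' @param dai_present Diffuse axonal injury present?
#' @param skull_fracture Skull fracture present?
#' @param pneumocephalus Pneumocephalus present?
#' @param suprasellar_cisterns One of `"normal"`, `"compressed"`,
#'   `"obliterated"`.
#' @param basal_cisterns One of `"present"`, `"compressed"`, `"absent"`.
#' @param midline_shift_mm Midline shift in mm (non-negative).
#' @param hydrocephalus One of `"none"`, `"mild_moderate"`, `"severe"`.
#' @param herniation One of `"none"`, `"focal"`, `"diffuse"`.
#' @param duret_hemorrhage Duret (secondary brainstem) hemorrhage present?
#' @param mass_lesion_evacuated Was a mass lesion surgically evacuated?
#'   Distinguishes Marshall class V from VI.
#'
#' @return A `data.frame` with the columns of [ct_findings_columns()].
#' @examples
#' ct_findings()                       # all-normal scan
#' ct_findings(sdh_volume_cm3 = 30, suprasellar_cisterns = "compressed")
#' @export
ct_findings <- function(edh_volume_cm3 = 0,
                        sdh_volume_cm3 = 0,
                        ich_contusion_volume_cm3 = 0,
                        sah_present = FALSE,
                        ivh_present = FALSE,
                        dai_present = FALSE,
                        skull_fracture = FALSE,
                        pneumocephalus = FALSE,
                        suprasellar_cisterns = "normal",
                        basal_cisterns = "present",
                        midline_shift_mm = 0,
                        hydrocephalus = "none",
                        herniation = "none",
                        duret_hemorrhage = FALSE,
                        mass_lesion_evacuated = FALSE) {
  x <- data.frame(
    edh_volume_cm3 = as.numeric(edh_volume_cm3),
    sdh_volume_cm3 = as.numeric(sdh_volume_cm3),
    ich_contusion_volume_cm3 = as.numeric(ich_contusion_volume_cm3),
    sah_present = as.logical(sah_present),
    ivh_present = as.logical(ivh_present),
    dai_present = as.logical(dai_present),
    skull_fracture = as.logical(skull_fracture),
    pneumocephalus = as.logical(pneumocephalus),
    suprasellar_cisterns = as.character(suprasellar_cisterns),
    basal_cisterns = as.character(basal_cisterns),
    midline_shift_mm = as.numeric(midline_shift_mm),
    hydrocephalus = as.character(hydrocephalus),
    herniation = as.character(herniation),
    duret_hemorrhage = as.logical(duret_hemorrhage),
    mass_lesion_evacuated = as.logical(mass_lesion_evacuated),
    stringsAsFactors = FALSE
  )
  validate_ct_findings(x)
  x
}

#' Validate a CT-findings table
#'
#' Checks the invariants of structured CT findings: all columns present,
#' volumes and shift finite and non-negative, enums restricted to their
#' documented levels, flags logical and non-missing. Missing or unknown
#' values are rejected, not imputed.
#'
#' @param findings A data frame with the columns of
#'   [ct_findings_columns()].
#' @return Invisibly, `findings`. Throws an error describing every
#'   violated constraint otherwise.
#' @export
validate_ct_findings <- function(findings) {
  stopifnot(is.data.frame(findings))
  missing_cols <- setdiff(ct_findings_columns(), names(findings))
  if (length(missing_cols) > 0) {
    stop("findings table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  vol_cols <- c("edh_volume_cm3", "sdh_volume_cm3",
                "ich_contusion_volume_cm3", "midline_shift_mm")
  for (v in vol_cols) {
    x <- findings[[v]]
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
      problems <- c(problems,
                    paste0(v, " must be finite, non-missing and >= 0"))
    }
  }
  flag_cols <- c("sah_present", "ivh_present", "dai_present",
                 "skull_fracture", "pneumocephalus", "duret_hemorrhage",
                 "mass_lesion_evacuated")
  for (v in flag_cols) {
    x <- findings[[v]]
    if (!is.logical(x) || anyNA(x)) {
      problems <- c(problems, paste0(v, " must be logical, non-missing"))
    }
  }
  enum_spec <- list(suprasellar_cisterns = .suprasellar_levels,
                    basal_cisterns = .basal_levels,
                    hydrocephalus = .hydrocephalus_levels,
                    herniation = .herniation_levels)
  for (v in names(enum_spec)) {
    x <- as.character(findings[[v]])
    bad <- !x %in% enum_spec[[v]]
    if (anyNA(x) || any(bad)) {
      problems <- c(problems,
                    paste0(v, " must be one of ",
                           paste(enum_spec[[v]], collapse = "/")))
    }
  }
  if (length(problems) > 0) {
    stop("invalid CT findings: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  invisible(findings)
}
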