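# Deterministic mapping from structured CT findings to the three
# admission-CT severity systems: Helsinki CT score, Marshall CT
# classification, and NIRIS category. All scorers are vectorised over
# the rows of a findings table.

#' Helsinki CT score
#'
#' Additive CT score built from mass-lesion type, lesion size, IVH and
#' suprasellar cistern status. Components: subdural haematoma +2,
#' intracerebral haematoma/contusion +2, epidural haematoma -3, any
#' lesion volume strictly over 25 cm^3 +2, intraventricular hemorrhage
#' +3, suprasellar cisterns normal 0 / compressed +1 / obliterated +5.
#' Lesion-type points are additive across coexisting lesion types; the
#' size point is assessed on the maximum of the three per-type volumes.
#' The attainable range is -3 to 14.
#'
#' @param findings A findings table as built by [ct_findings()].
#' @return Integer vector of scores, one per row, each in `[-3, 14]`.
#' @examples
#' helsinki_score(ct_findings())                        # 0
#' helsinki_score(ct_findings(edh_volume_cm3 = 10))     # -3
#' @export
helsinki_score <- function(findings) {
  validate_ct_findings(findings)
  vmax <- pmax(findings$edh_volume_cm3, findings$sdh_volume_cm3,
               findings$ich_contusion_volume_cm3)
  cistern_pts <- c(normal = 0L, compressed = 1L, obliterated = 5L)
  score <- 2L * (findings$sdh_volume_cm3 > 0) +
    2L * (findings$ich_contusion_volume_cm3 > 0) +
    -3L * (findings$edh_volume_cm3 > 0) +
    2L * (vmax > 25) +
    3L * findings$ivh_present +
    cistern_pts[as.character(findings$suprasellar_cisterns)]
  as.integer(unname(score))
}

#' Marshall CT classification
#'
#' Six-class scheme: diffuse injury I-IV plus evacuated (V) and
#' non-evacuated (VI) mass lesion. Any high- or mixed-density lesion
#' strictly over 25 cm^3 classifies as V (evacuated) or VI
#' (non-evacuated) regardless of the diffuse criteria; otherwise
#' midline shift over 5 mm gives IV, compressed or absent basal
#' cisterns give III, any visible intracranial pathology gives II, and
#' a normal scan gives I. "Visible pathology" for class II is any
#' nonzero lesion volume or any of SAH, IVH, DAI, skull fracture or
#' pneumocephalus.
#'
#' @param findings A findings table as built by [ct_findings()].
#' @return Ordered factor with levels `I < II < III < IV < V < VI`.
#' @examples
#' marshall_class(ct_findings())                              # I
#' marshall_class(ct_findings(midline_shift_mm = 7))          # IV
#' @export
marshall_class <- function(findings) {
  validate_ct_findings(findings)
  vmax <- pmax(findings$edh_volume_cm3, findings$sdh_volume_cm3,
               findings$ich_contusion_volume_cm3)
  visible <- vmax > 0 | findings$sah_present | findings$ivh_present |
    findings$dai_present | findings$skull_fracture |
    findings$pneumocephalus
  cls <- ifelse(vmax > 25,
                ifelse(findings$mass_lesion_evacuated, "V", "VI"),
         ifelse(findings$midline_shift_mm > 5, "IV",
         ifelse(findings$basal_cisterns %in% c("compressed", "absent"),
                "III",
         ifelse(visible, "II", "I"))))
  factor(cls, levels = c("I", "II", "III", "IV", "V", "VI"),
         ordered = TRUE)
}

#' NIRIS category
#'
#' NeuroImaging Radiological Interpretation System (updated
#' definitions): ordinal severity categories 0-4. The highest category
#' whose criterion list is met is returned:
#' \describe{
#'   \item{4}{EDH/ICH/contusion > 20 cm^3, SDH > 200 cm^3, severe
#'     hydrocephalus, midline shift > 10 mm, diffuse herniation, or
#'     Duret hemorrhage.}
#'   \item{3}{EDH/ICH/contusion > 15 cm^3, SDH > 50 cm^3, midline shift
#'     > 5 mm, or focal herniation.}
#'   \item{2}{any haematoma/contusion >= 0.5 cm^3, diffuse axonal
#'     injury, IVH, mild/moderate hydrocephalus, or midline shift in
#'     (0, 5] mm.}
#'   \item{1}{skull fracture, pneumocephalus, any lesion under
#'     0.5 cm^3, or subarachnoid hemorrhage.}
#'   \item{0}{no abnormal finding.}
#' }
#' A lesion of exactly 0.5 cm^3 counts as category 2, so the volume
#' axis is partitioned; shift bands are half-open: (0,5] -> 2,
#' (5,10] -> 3, above 10 -> 4.
#'
#' @param findings A findings table as built by [ct_findings()].
#' @return Integer vector of categories in `0:4`.
#' @examples
#' niris_category(ct_findings(sah_present = TRUE))        # 1
#' niris_category(ct_findings(midline_shift_mm = 12))     # 4
#' @export
niris_category <- function(findings) {
  validate_ct_findings(findings)
  edh <- findings$edh_volume_cm3
  sdh <- findings$sdh_volume_cm3
  ich <- findings$ich_contusion_volume_cm3
  shift <- findings$midline_shift_mm
  nonsdh_max <- pmax(edh, ich)
  anyvol <- pmax(edh, sdh, ich)

  cat4 <- nonsdh_max > 20 | sdh > 200 |
    findings$hydrocephalus == "severe" | shift > 10 |
    findings$herniation == "diffuse" | findings$duret_hemorrhage
  cat3 <- nonsdh_max > 15 | sdh > 50 | shift > 5 |
    findings$herniation == "focal"
  cat2 <- anyvol >= 0.5 | findings$dai_present | findings$ivh_present |
    findings$hydrocephalus == "mild_moderate" | (shift > 0 & shift <= 5)
  cat1 <- findings$skull_fracture | findings$pneumocephalus |
    (anyvol > 0 & anyvol < 0.5) | findings$sah_present

  as.integer(ifelse(cat4, 4L, ifelse(cat3, 3L, ifelse(cat2, 2L,
             ifelse(cat1, 1L, 0L)))))
}

#' Score a cohort with all three CT systems
#'
#' Applies the Marshall classification, Helsinki score and NIRIS
#' category row-wise to the findings columns of a cohort table, order
#' preserved. Rows whose findings fail validation are reported together
#' with their identifiers.
#'
#' @param records A data frame containing the findings columns of
#'   [ct_findings_columns()], optionally a `patient_id` column used in
#'   error messages.
#' @return A `data.frame` with columns `marshall` (ordered factor),
#'   `helsinki` (integer) and `niris` (integer), one row per record.
#' @export
score_all <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    return(data.frame(marshall = factor(character(0),
                                        levels = c("I", "II", "III",
                                                   "IV", "V", "VI"),
                                        ordered = TRUE),
                      helsinki = integer(0), niris = integer(0)))
  }
  findings <- records[, intersect(ct_findings_columns(), names(records)),
                      drop = FALSE]
  ids <- if ("patient_id" %in% names(records)) {
    as.character(records$patient_id)
  } else {
    as.character(seq_len(nrow(records)))
  }
  all_ok <- tryCatch({
    validate_ct_findings(findings)
    TRUE
  }, error = function(e) FALSE)
  ok <- if (all_ok) rep(TRUE, nrow(findings)) else {
    vapply(seq_len(nrow(findings)), function(i) {
      tryCatch({
        validate_ct_findings(findings[i, , drop = FALSE])
        TRUE
      }, error = function(e) FALSE)
    }, logical(1))
  }
  if (any(!ok)) {
    msgs <- vapply(which(!ok), function(i) {
      err <- tryCatch({
        validate_ct_findings(findings[i, , drop = FALSE])
        ""
      }, error = function(e) conditionMessage(e))
      paste0("record ", ids[i], ": ", err)
    }, character(1))
    stop("invalid findings in ", sum(!ok), " record(s):\n",
         paste(msgs, collapse = "\n"), call. = FALSE)
  }
  data.frame(marshall = marshall_class(findings),
             helsinki = helsinki_score(findings),
             niris = niris_category(findings))
}
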