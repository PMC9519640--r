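test_that("findings construction and validation enforce the invariants", {
  f <- ct_findings()
  expect_identical(nrow(f), 1L)
  expect_setequal(names(f), ct_findings_columns())
  expect_error(ct_findings(edh_volume_cm3 = -1), "edh_volume")
  expect_error(ct_findings(midline_shift_mm = Inf), "midline_shift")
  expect_error(ct_findings(suprasellar_cisterns = "open"),
               "suprasellar_cisterns")
  expect_error(ct_findings(hydrocephalus = "massive"), "hydrocephalus")
  expect_error(validate_ct_findings(ct_findings()[, -1]),
               "missing columns")
})

test_that("helsinki score sums its printed components", {
  expect_identical(helsinki_score(ct_findings()), 0L)
  expect_identical(helsinki_score(ct_findings(edh_volume_cm3 = 10)), -3L)
  maximal <- ct_findings(sdh_volume_cm3 = 30,
                         ich_contusion_volume_cm3 = 5,
                         ivh_present = TRUE,
                         suprasellar_cisterns = "obliterated")
  expect_identical(helsinki_score(maximal), 14L)
  expect_identical(
    helsinki_score(ct_findings(sdh_volume_cm3 = 30,
                               suprasellar_cisterns = "compressed")),
    5L)
  # size point requires strictly more than 25 cm^3
  expect_identical(helsinki_score(ct_findings(sdh_volume_cm3 = 25)), 2L)
  expect_identical(helsinki_score(ct_findings(sdh_volume_cm3 = 25.1)), 4L)
})

test_that("helsinki score stays in [-3, 14] over the findings lattice and attains both endpoints", {
  scores <- helsinki_score(helsinki_lattice())
  expect_true(all(scores >= -3 & scores <= 14))
  expect_identical(min(scores), -3L)
  expect_identical(max(scores), 14L)
})

test_that("marshall classification follows the class rules with mass-lesion precedence", {
  expect_equal(as.character(marshall_class(ct_findings())), "I")
  expect_equal(as.character(marshall_class(
    ct_findings(sdh_volume_cm3 = 10, midline_shift_mm = 3))), "II")
  expect_equal(as.character(marshall_class(
    ct_findings(basal_cisterns = "compressed"))), "III")
  expect_equal(as.character(marshall_class(
    ct_findings(midline_shift_mm = 7, sdh_volume_cm3 = 10))), "IV")
  big <- ct_findings(ich_contusion_volume_cm3 = 30,
                     mass_lesion_evacuated = TRUE)
  expect_equal(as.character(marshall_class(big)), "V")
  big$mass_lesion_evacuated <- FALSE
  expect_equal(as.character(marshall_class(big)), "VI")
  # lesion > 25 overrides every diffuse class, whatever else is present
  override <- ct_findings(sdh_volume_cm3 = 40, midline_shift_mm = 12,
                          basal_cisterns = "absent")
  expect_equal(as.character(marshall_class(override)), "VI")
})

test_that("every findings value maps to exactly one marshall class", {
  grid <- expand.grid(vol = c(0, 10, 30), shift = c(0, 3, 6, 12),
                      basal = c("present", "compressed", "absent"),
                      sah = c(FALSE, TRUE), evac = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  f <- ct_findings(sdh_volume_cm3 = grid$vol,
                   midline_shift_mm = grid$shift,
                   basal_cisterns = grid$basal,
                   sah_present = grid$sah,
                   mass_lesion_evacuated = grid$evac)
  cls <- marshall_class(f)
  expect_false(anyNA(cls))
  expect_true(all(cls %in% c("I", "II", "III", "IV", "V", "VI")))
  expect_true(all(cls[grid$vol > 25] %in% c("V", "VI")))
})

test_that("niris returns the highest category whose criteria are met", {
  expect_identical(niris_category(ct_findings()), 0L)
  expect_identical(niris_category(ct_findings(sah_present = TRUE)), 1L)
  expect_identical(niris_category(ct_findings(edh_volume_cm3 = 0.3)), 1L)
  expect_identical(niris_category(
    ct_findings(sdh_volume_cm3 = 60, midline_shift_mm = 4)), 3L)
  expect_identical(niris_category(ct_findings(midline_shift_mm = 12)), 4L)
  # boundary 0.5 cm^3 belongs to category 2; shift bands half-open
  expect_identical(niris_category(ct_findings(sdh_volume_cm3 = 0.5)), 2L)
  expect_identical(niris_category(ct_findings(midline_shift_mm = 5)), 2L)
  expect_identical(niris_category(ct_findings(midline_shift_mm = 5.1)), 3L)
  expect_identical(niris_category(ct_findings(midline_shift_mm = 10)), 3L)
  expect_identical(niris_category(ct_findings(duret_hemorrhage = TRUE)), 4L)
  # SDH thresholds differ from the other lesion types
  expect_identical(niris_category(ct_findings(sdh_volume_cm3 = 60)), 3L)
  expect_identical(niris_category(ct_findings(ich_contusion_volume_cm3 = 18)), 3L)
  expect_identical(niris_category(ct_findings(ich_contusion_volume_cm3 = 21)), 4L)
  expect_identical(niris_category(ct_findings(sdh_volume_cm3 = 201)), 4L)
})

test_that("increasing any severity-relevant quantity never decreases the niris category", {
  set.seed(31)
  vols <- c(0, 0.3, 1, 16, 21, 26, 60, 201)
  shifts <- c(0, 3, 6, 12)
  hyd <- c("none", "mild_moderate", "severe")
  hern <- c("none", "focal", "diffuse")
  for (r in 1:200) {
    f <- ct_findings(edh_volume_cm3 = sample(vols, 1),
                     sdh_volume_cm3 = sample(vols, 1),
                     ich_contusion_volume_cm3 = sample(vols, 1),
                     midline_shift_mm = sample(shifts, 1),
                     hydrocephalus = sample(hyd, 1),
                     herniation = sample(hern, 1),
                     ivh_present = sample(c(TRUE, FALSE), 1),
                     dai_present = sample(c(TRUE, FALSE), 1))
    base_cat <- niris_category(f)
    for (col in c("edh_volume_cm3", "sdh_volume_cm3",
                  "ich_contusion_volume_cm3", "midline_shift_mm")) {
      g <- f
      g[[col]] <- g[[col]] + sample(c(0.4, 5, 50, 200), 1)
      expect_gte(niris_category(g), base_cat)
    }
    g <- f
    g$hydrocephalus <- hyd[min(3, match(f$hydrocephalus, hyd) + 1)]
    expect_gte(niris_category(g), base_cat)
    g <- f
    g$herniation <- hern[min(3, match(f$herniation, hern) + 1)]
    expect_gte(niris_category(g), base_cat)
  }
})

test_that("score_all applies the three scorers element-wise with joint consistency", {
  expect_identical(nrow(score_all(ct_findings()[0, ])), 0L)
  normal <- score_all(ct_findings())
  expect_equal(as.character(normal$marshall), "I")
  expect_identical(normal$helsinki, 0L)
  expect_identical(normal$niris, 0L)
  set.seed(5)
  one_each <- do.call(rbind, lapply(0:4, findings_for_category))
  expect_identical(score_all(one_each)$niris, 0:4)
  bad <- ct_findings()[rep(1, 3), ]
  bad$patient_id <- c("a", "b", "c")
  bad$midline_shift_mm[2] <- -4
  expect_error(score_all(bad), "record b")
})
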