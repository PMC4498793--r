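test_that("regional descriptors partition their whole-brain totals", {
  ph <- small_folded(0.2)
  m <- measure_subject(ph$map, ph$regions, subject_id = "P1", timepoint = 41,
                       descriptors = c("V_CoGM", "A_inner", "GI"))
  rec <- m$records
  lobes <- names(REGION_CODES)
  v_lobe <- sum(rec$value[rec$descriptor == "V_CoGM" & rec$region %in% lobes])
  v_whole <- rec$value[rec$descriptor == "V_CoGM" & rec$region == "whole"]
  expect_equal(v_lobe, v_whole, tolerance = 1e-12)  # exact mask partition

  a_lobe <- sum(rec$value[rec$descriptor == "A_inner" & rec$region %in% lobes])
  a_whole <- rec$value[rec$descriptor == "A_inner" & rec$region == "whole"]
  expect_lt(abs(a_lobe / a_whole - 1), 0.01)  # faces assigned uniquely

  # hemispheres partition the whole for volumes
  v_hemi <- sum(rec$value[rec$descriptor == "V_CoGM" & rec$region %in% c("R", "L")])
  expect_equal(v_hemi, v_whole, tolerance = 1e-12)
})

test_that("all lobar GIs are 1 for a convex sphere phantom", {
  sp <- phantom_spec(R0 = 15, fold_amp = 0, t_cortex = 2, t_csf = 2,
                     spacing = 0.8)
  ph <- generate_phantom(sp, truth = "none")
  m <- measure_subject(ph$map, ph$regions, descriptors = "GI")
  gis <- m$records$value[m$records$region %in% names(REGION_CODES)]
  expect_true(all(abs(gis - 1) <= 0.07))
})

test_that("increase factors are per-subject ratios with missing handling", {
  ph <- small_folded(0.1)
  m30 <- measure_subject(ph$map, ph$regions, subject_id = "S1",
                         timepoint = 30, descriptors = c("V_UWM", "GI"))
  m40 <- m30
  m40$timepoint <- 41
  m40$records$timepoint <- 41
  fx <- increase_factors(m30, m40)
  expect_true(all(abs(fx$factor - 1) < 1e-12, na.rm = TRUE))

  m40b <- m40
  m40b$records$value <- m40b$records$value * 2
  fx2 <- increase_factors(m30, m40b)
  expect_true(all(abs(fx2$factor - 2) < 1e-12, na.rm = TRUE))

  # missing propagates, zero denominators give NA
  m30z <- m30
  m30z$records$value[1] <- 0
  m30z$records$value[2] <- NA
  fxz <- increase_factors(m30z, m40)
  key <- paste(m30$records$region[1:2], m30$records$descriptor[1:2])
  got <- fxz$factor[match(key, paste(fxz$region, fxz$descriptor))]
  expect_true(all(is.na(got)))

  m40$subject_id <- "S2"
  expect_error(increase_factors(m30, m40), "mismatch")
})

test_that("factors are equivariant under region relabelling", {
  ph <- small_folded(0.1)
  m30 <- measure_subject(ph$map, ph$regions, subject_id = "S1",
                         timepoint = 30, descriptors = "V_CoGM")
  m40 <- measure_subject(ph$map, ph$regions, subject_id = "S1",
                         timepoint = 41, descriptors = "V_CoGM")
  m40$records$value <- m40$records$value * 1.5
  fx <- increase_factors(m30, m40)
  # permute region labels consistently in both measurements
  perm <- function(m) {
    swap <- c(FR = "OL", OL = "FR")
    idx <- m$records$region %in% names(swap)
    m$records$region[idx] <- swap[m$records$region[idx]]
    m
  }
  fx2 <- increase_factors(perm(m30), perm(m40))
  ref <- fx$factor[match(c("FR", "OL"), fx$region)]
  got <- fx2$factor[match(c("OL", "FR"), fx2$region)]
  expect_equal(got, ref, tolerance = 1e-12)
})
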