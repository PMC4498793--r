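test_that("sphere phantom matches closed forms", {
  sp <- phantom_spec(R0 = 30, fold_amp = 0, t_cortex = 3, t_csf = 3,
                     spacing = 1.0)
  ph <- generate_phantom(sp, truth = "parametric")
  expect_lt(abs(tissue_volume(ph$map, "UWM") * 1000 / (4 / 3 * pi * 30^3) - 1),
            0.01)
  tr <- ph$truth
  expect_lt(abs(tr$V_UWM / (4 / 3 * pi * 30^3) - 1), 1e-3)
  expect_lt(abs(tr$A_inner / (4 * pi * 30^2) - 1), 1e-3)
  expect_equal(tr$GI_true, 1, tolerance = 1e-3)
  expect_equal(tr$C_true, 1, tolerance = 1e-3)
})

test_that("labels partition the grid", {
  ph <- small_folded(0.2)
  counts <- tabulate(ph$map$values + 1L, nbins = 5)
  expect_equal(sum(counts), prod(dim(ph$map$values)))
  expect_true(all(counts[2:4] > 0))
  # region map covers exactly the non-background voxels
  expect_true(all((ph$regions$values > 0) == (ph$map$values > 0)))
})

test_that("fold shaping in R and C++ agree and reduce to the sinusoid", {
  u <- seq(-1, 1, length.out = 41)
  for (prm in list(c(0.3, -0.2), c(0.15, 0.4), c(Inf, 0))) {
    rv <- cortmorph:::fold_shape_r(u, prm[1], prm[2])
    cv <- vapply(u, function(ui)
      cortmorph:::cpp_fold_shape(ui, prm[1], prm[2]), 1.0)
    expect_equal(rv, cv, tolerance = 1e-12)
  }
  expect_equal(cortmorph:::fold_shape_r(u, Inf, 0), u)
  # derivative consistency (finite differences)
  h <- 1e-6
  d1 <- (cortmorph:::fold_shape_r(u + h, 0.3, -0.2) -
           cortmorph:::fold_shape_r(u - h, 0.3, -0.2)) / (2 * h)
  expect_equal(cortmorph:::fold_shape_d1(u, 0.3, -0.2), d1, tolerance = 1e-6)
})

test_that("surface quadrature is refinement-consistent for folded phantoms", {
  sp <- phantom_spec(R0 = 30, fold_amp = 0.15, fold_freq = c(8, 8),
                     t_cortex = 2, t_csf = 2, spacing = 1.0)
  q1 <- cortmorph:::parametric_truth(sp, 256L, light = TRUE)
  q2 <- cortmorph:::parametric_truth(sp, 1024L, light = TRUE)
  expect_lt(abs(q1$A_inner / q2$A_inner - 1), 1e-3)
  expect_lt(abs(q1$V_UWM / q2$V_UWM - 1), 1e-3)
})

test_that("oracle descriptors grow monotonically with fold amplitude", {
  vals <- lapply(c(0.1, 0.2, 0.3), function(a) {
    sp <- phantom_spec(R0 = 25, fold_amp = a, fold_freq = c(8, 8),
                       t_cortex = 2, t_csf = 2, spacing = 1.0)
    oracle_descriptors(sp, n_theta = 256, components = "parametric")
  })
  A <- vapply(vals, `[[`, 1.0, "A_inner")
  GI <- vapply(vals, `[[`, 1.0, "GI_true")
  C <- vapply(vals, `[[`, 1.0, "C_true")
  expect_true(all(diff(A) > 0))
  expect_true(all(diff(GI) > 0))
  expect_true(all(diff(C) > 0))
  expect_true(all(GI >= 1))
})

test_that("grid size refusal names the required extent", {
  expect_error(phantom_spec(R0 = 30, fold_amp = 0.2, t_cortex = 2,
                            t_csf = 2, spacing = 1, dims = c(40L, 40L, 40L)),
               "extent")
})

test_that("cohort generation is deterministic and respects the class design", {
  des <- cohort_design(n_subjects = 85, seed = 11, spacing = 1.0)
  ch1 <- generate_cohort(des)
  ch2 <- generate_cohort(des)
  expect_identical(ch1$covariates, ch2$covariates)
  expect_identical(ch1$specs[[3]]$t40$R0, ch2$specs[[3]]$t40$R0)
  expect_equal(as.vector(table(ch1$covariates$class_cogm)), c(27, 35, 23))
  expect_true(all(ch1$covariates$interval > 0))
  # fissure width increases with class on average
  mw <- tapply(ch1$covariates$fissure_width, ch1$covariates$class_cogm, mean)
  expect_true(mw[["moderate_severe"]] > mw[["normal"]])
  # subsetting stability: subject k's geometry draws depend only on the
  # root seed (class assignment necessarily depends on the design size, so
  # compare under a zero-effect design)
  null_eff <- list(t30 = NULL, t40 = NULL)
  chN <- generate_cohort(cohort_design(n_subjects = 85, seed = 11,
                                       spacing = 1.0, effects = null_eff))
  ch5 <- generate_cohort(cohort_design(n_subjects = 5, seed = 11,
                                       spacing = 1.0, effects = null_eff))
  expect_equal(ch5$specs[[4]]$t40$t_cortex, chN$specs[[4]]$t40$t_cortex)
  expect_equal(ch5$specs[[2]]$t30$R0, chN$specs[[2]]$t30$R0)
})

test_that("class effects move geometry in the expected directions", {
  effects <- CLASS_EFFECTS_DEFAULT
  des0 <- cohort_design(n_subjects = 6, class_counts = c(2, 2, 2), seed = 5,
                        size_sd_shared = 0, size_sd_tp = 0, amp_sd = 0,
                        thick_sd = 0, spacing = 1.0)
  ch <- generate_cohort(des0)
  cls <- ch$covariates$class_cogm
  t40 <- vapply(ch$specs, function(s) s$t40$t_cortex, 1.0)
  a40 <- vapply(ch$specs, function(s) s$t40$fold_amp, 1.0)
  expect_gt(mean(t40[cls == "moderate_severe"]), mean(t40[cls == "normal"]))
  expect_lt(mean(a40[cls == "moderate_severe"]), mean(a40[cls == "normal"]))
  # zero-effect design: no systematic class differences
  des_null <- cohort_design(n_subjects = 6, class_counts = c(2, 2, 2),
                            seed = 5, size_sd_shared = 0, size_sd_tp = 0,
                            amp_sd = 0, thick_sd = 0, spacing = 1.0,
                            effects = list(t30 = NULL, t40 = NULL))
  chn <- generate_cohort(des_null)
  tn <- vapply(chn$specs, function(s) s$t40$t_cortex, 1.0)
  expect_equal(max(tn) - min(tn), 0, tolerance = 1e-12)
})

test_that("voxelized descriptors converge to ground truth under refinement", {
  sp1 <- phantom_spec(R0 = 16, fold_amp = 0.15, fold_freq = c(6, 6),
                      t_cortex = 2, t_csf = 2, spacing = 2.0)
  tr <- oracle_descriptors(sp1, n_theta = 256, components = "parametric")
  errs <- vapply(c(2.0, 1.0, 0.5), function(h) {
    sph <- phantom_spec(R0 = 16, fold_amp = 0.15, fold_freq = c(6, 6),
                        t_cortex = 2, t_csf = 2, spacing = h)
    m <- generate_phantom(sph, truth = "none")$map
    abs(tissue_volume(m, "UWM") * 1000 / tr$V_UWM - 1)
  }, 1.0)
  expect_lt(errs[3], 0.005)
  expect_true(errs[3] < errs[1])
})
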