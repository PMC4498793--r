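test_that("slab potential is linear and thickness exact", {
  map <- fixture("slab", slab_map(d = 3, spacing = 0.25))
  pf <- solve_laplace(map)
  expect_true(pf$converged)
  psi <- array(pf$psi, dim(map$values))
  z <- (seq_len(dim(map$values)[3]) - 0.5) * 0.25
  # closed form: psi = (z - z_inner_face) / d in the CoGM slab
  mid <- dim(map$values)[1] %/% 2
  in_slab <- which(map$values[mid, mid, ] == 2L)
  expect_lt(max(abs(psi[mid, mid, in_slab] - (z[in_slab] - 2) / 3)), 0.02)

  tf <- thickness_field(pf, map)
  vals <- tf$thickness[map$values == 2L]
  expect_lt(abs(median(vals, na.rm = TRUE) - 3), 0.05)
  expect_lt(abs(mean(vals, na.rm = TRUE) - 3), 0.06)  # 2% slab exactness
})

test_that("spherical shell matches the radial harmonic closed form", {
  map <- small_shell()  # r1 = 10, r2 = 13, 0.5 mm
  pf <- solve_laplace(map)
  psi <- array(pf$psi, dim(map$values))
  expect_gte(min(psi), 0)   # discrete maximum principle
  expect_lte(max(psi), 1)
  d <- dim(map$values)
  x <- (seq_len(d[1]) - 0.5) * 0.5 - d[1] * 0.25
  r <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  sel <- abs(r - 11.5) < 0.2 & map$values == 2L
  target <- (1 / 10 - 1 / 11.5) / (1 / 10 - 1 / 13)
  expect_lt(abs(mean(psi[sel]) - target), 0.02)

  tf <- thickness_field(pf, map)
  expect_lt(abs(median_thickness(tf) - 3), 0.15)
})

test_that("streamline step refinement changes the median by < 1%", {
  map <- small_shell()
  pf <- fixture("shell_pf", solve_laplace(map))
  t1 <- median_thickness(thickness_field(pf, map))          # default h/4
  t2 <- median_thickness(thickness_field(pf, map, step = 0.0625))
  expect_lt(abs(t2 / t1 - 1), 0.01)
})

test_that("thickness is invariant under 90-degree rotation", {
  ph <- small_folded(0.2)
  map <- ph$map
  pf <- solve_laplace(map)
  m1 <- median_thickness(thickness_field(pf, map))
  rot <- tissue_label_map(aperm(map$values, c(3, 1, 2)),
                          map$spacing[c(3, 1, 2)])
  m2 <- median_thickness(thickness_field(solve_laplace(rot), rot))
  expect_equal(m1, m2, tolerance = 1e-6)
})

test_that("median is a robust order statistic over valid voxels", {
  tf <- structure(list(thickness = c(1, 1, 1, 10),
                       reason = c(0L, 0L, 0L, 0L),
                       qc = c(n_cogm = 4, valid = 4, stationary = 0,
                              runaway = 0, wrong_exit = 0, pinned = 0)),
                  class = "thickness_field")
  expect_equal(median_thickness(tf), 1)
  tf$thickness <- rep(1.4, 4)
  expect_equal(median_thickness(tf), 1.4)
  tf$thickness <- rep(NA_real_, 4)
  res <- median_thickness(tf)
  expect_true(is.na(res))
  expect_match(attr(res, "reason"), "no valid")
})

test_that("isolated or boundary-free problems are handled as specified", {
  lab <- array(0L, c(8, 8, 8))
  lab[3:6, 3:6, 3:6] <- 2L  # CoGM with no UWM anywhere
  lab[1, 1, 1] <- 1L        # UWM present but not adjacent: no inner boundary
  map <- tissue_label_map(lab, rep(1, 3))
  expect_error(solve_laplace(map), "inner")

  # one-voxel cortex: pinned voxels get face-to-face distance
  slab1 <- slab_map(d = 1, spacing = 1, nxy = 10L, pad = 2)
  pf <- solve_laplace(slab1)
  tf <- thickness_field(pf, slab1)
  pinned <- tf$reason[slab1$values == 2L] == 4L
  expect_true(all(pinned))
  expect_equal(unique(tf$thickness[slab1$values == 2L]), 1)
})
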