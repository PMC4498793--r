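#' Specify a folded two-shell brain phantom
#'
#' The phantom's white-matter (UWM) compartment is the region under the
#' radial graph
#' \deqn{\rho(\theta,\varphi) = R_0 (1 + a\, S_{w,b}(\sin l\theta \sin m\varphi))}
#' where \eqn{S_{w,b}} is a monotone fold-shaping map (identity for
#' `wall_width = Inf`, giving the plain sinusoidal fold; finite values
#' sharpen the fold walls with a tanh profile and `wall_bias` makes gyral
#' plateaus and sulcal slots unequally wide, which is what real cortices
#' look like). The cortex (CoGM) is the constant-thickness sheet
#' `0 < dist(UWM) <= t_cortex` (Euclidean distance in mm) and the
#' extracerebral CSF the rind `t_cortex < dist <= t_cortex + t_csf`. Because
#' the cortex is a true distance offset, its outer surface self-merges
#' wherever a sulcal slot is narrower than `2 t_cortex` — deliberately
#' emulating the partial invisibility of sulcal CSF in clinical neonatal
#' images (outer area below inner area, median thickness above the
#' volume-to-area mean).
#'
#' @param R0 base inner radius, mm.
#' @param fold_amp dimensionless fold amplitude `a`, `0 <= a < 1`.
#' @param fold_freq integer angular frequencies `c(l, m)`.
#' @param t_cortex cortical sheet thickness, mm (`0 < t_cortex < R0`).
#' @param t_csf CSF rind thickness, mm.
#' @param spacing voxel spacing, mm (scalar isotropic or length 3).
#' @param wall_width fold wall sharpness `w` (dimensionless; `Inf` =
#'   sinusoid; useful sharp values are around 0.1-0.3).
#' @param wall_bias plateau bias `b` in (-1, 1); positive values narrow the
#'   gyral plateaus, negative values narrow the sulcal slots.
#' @param margin background margin around the outer CSF surface, mm.
#' @param dims optional explicit grid size; refused (with the required
#'   extent) if it cannot contain the outer CSF surface.
#' @param seed integer; recorded for provenance of derived cohorts.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(R0, fold_amp = 0, fold_freq = c(8L, 8L),
                         t_cortex = 2, t_csf = 3, spacing = 0.7,
                         wall_width = Inf, wall_bias = 0, margin = 2,
                         dims = NULL, seed = NULL) {
  if (length(fold_freq) == 1L) fold_freq <- rep(fold_freq, 2L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(R0 > 0, t_cortex > 0, t_csf >= 0, R0 > t_cortex,
            fold_amp >= 0, fold_amp < 1, all(spacing > 0),
            all(fold_freq == round(fold_freq)), all(fold_freq > 0),
            abs(wall_bias) < 1)
  r_env <- R0 * (1 + fold_amp) + t_cortex + t_csf
  extent <- 2 * (r_env + margin)
  need_dims <- as.integer(ceiling(extent / spacing))
  if (is.null(dims)) {
    dims <- need_dims
  } else {
    dims <- as.integer(dims)
    if (any(dims * spacing < 2 * r_env))
      stop(sprintf(
        "grid too small to contain the outer CSF surface: need extent >= %.1f mm per axis (%s voxels at this spacing)",
        2 * r_env, paste(need_dims, collapse = " x ")))
  }
  structure(list(R0 = R0, fold_amp = fold_amp, fold_freq = as.integer(fold_freq),
                 t_cortex = t_cortex, t_csf = t_csf, spacing = spacing,
                 wall_width = wall_width, wall_bias = wall_bias,
                 margin = margin, dims = dims, seed = seed),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: R0=%.2f mm, a=%.3f, (l,m)=(%d,%d), w=%.3g, b=%.3g, t_cx=%.2f, t_csf=%.2f, %s voxels @ %.3g mm\n",
    x$R0, x$fold_amp, x$fold_freq[1], x$fold_freq[2], x$wall_width,
    x$wall_bias, x$t_cortex, x$t_csf, paste(x$dims, collapse = "x"),
    x$spacing[1]))
  invisible(x)
}

# Fold shaping map and derivative (kept in lock-step with the C++
# voxelizer; equality is asserted in the test suite).
fold_shape_r <- function(u, w, b) {
  if (!is.finite(w) || w <= 0 || w > 50) return(u)
  np <- tanh((1 - b) / w); nm <- tanh((1 + b) / w)
  2 * (tanh((u - b) / w) + nm) / (np + nm) - 1
}
fold_shape_d1 <- function(u, w, b) {
  if (!is.finite(w) || w <= 0 || w > 50) return(rep(1, length(u)))
  np <- tanh((1 - b) / w); nm <- tanh((1 + b) / w)
  2 / (w * (np + nm)) / cosh((u - b) / w)^2
}
fold_shape_d2 <- function(u, w, b) {
  if (!is.finite(w) || w <= 0 || w > 50) return(rep(0, length(u)))
  -(2 / w) * tanh((u - b) / w) * fold_shape_d1(u, w, b)
}

#' Generate a phantom label map
#'
#' Voxelizes a [phantom_spec()] into a [tissue_label_map()], an octant
#' region map standing in for a lobar parcellation, and (optionally) the
#' quadrature ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param truth `"parametric"` (fast analytic quadrature: V_UWM, A_inner,
#'   GI, C), `"full"` (adds fine-grid V_CoGM/V_CSF/A_outer/T oracles) or
#'   `"none"`.
#' @param ... passed to [oracle_descriptors()].
#' @return list with elements `map`, `regions`, `truth`.
#' @export
generate_phantom <- function(spec, truth = c("parametric", "none", "full"), ...) {
  truth <- match.arg(truth)
  stopifnot(inherits(spec, "phantom_spec"))
  centre <- spec$dims * spec$spacing / 2
  labs <- cpp_phantom_labels(spec$dims, spec$spacing, centre, spec$R0,
                             spec$fold_amp, spec$fold_freq[1],
                             spec$fold_freq[2], spec$wall_width,
                             spec$wall_bias, spec$t_cortex, spec$t_csf,
                             0.2)
  map <- tissue_label_map(labs, spacing = spec$spacing)
  regions <- octant_regions(map)
  tr <- switch(truth,
               none = NULL,
               parametric = oracle_descriptors(spec, components = "parametric", ...),
               full = oracle_descriptors(spec, ...))
  list(map = map, regions = regions, truth = tr)
}

#' Octant parcellation of a label map
#'
#' Assigns every non-background voxel to one of 8 lobar codes by the octant
#' of its physical position about the volume centre: right hemisphere
#' `x > 0` (odd codes), frontal `y > 0, z > 0`, temporal `y > 0, z <= 0`,
#' parietal `y <= 0, z > 0`, occipital `y <= 0, z <= 0`. A geometric
#' stand-in for an atlas-registered parcellation.
#'
#' @param map a [tissue_label_map()].
#' @return A `region_map`: same-grid integer array with labels 0 (none) and
#'   1..8 = FR, FL, TR, TL, PR, PL, OR, OL.
#' @export
octant_regions <- function(map) {
  d <- dim(map$values)
  ctr <- d * map$spacing / 2
  xs <- (seq_len(d[1]) - 0.5) * map$spacing[1] - ctr[1]
  ys <- (seq_len(d[2]) - 0.5) * map$spacing[2] - ctr[2]
  zs <- (seq_len(d[3]) - 0.5) * map$spacing[3] - ctr[3]
  right <- array(rep(xs > 0, times = d[2] * d[3]), d)
  yp <- array(rep(rep(ys > 0, each = d[1]), times = d[3]), d)
  zp <- array(rep(zs > 0, each = d[1] * d[2]), d)
  lobe <- ifelse(yp & zp, 0L, ifelse(yp & !zp, 2L, ifelse(!yp & zp, 4L, 6L)))
  reg <- 1L + lobe + ifelse(right, 0L, 1L)
  reg[map$values == 0L] <- 0L
  structure(list(values = reg, spacing = map$spacing, origin = map$origin),
            class = "region_map")
}

REGION_CODES <- c(FR = 1L, FL = 2L, TR = 3L, TL = 4L, PR = 5L, PL = 6L,
                  OR = 7L, OL = 8L)

#' Quadrature ground truth for a phantom
#'
#' Computes reference descriptor values independent of the voxel pipeline:
#' UWM volume and inner surface area by midpoint quadrature of the
#' parametric surface integrals (refined until the relative change is below
#' `conv_tol`, otherwise refused); the gyrification index as inner area over
#' the facet area of the convex hull of a dense surface sample; the global
#' curvature measure from the analytic fundamental forms of the inner
#' surface and its outward distance offset (offset elements annihilated by
#' curvature caustics are dropped). With `components = "full"`, CoGM/CSF
#' volumes, outer area and the two-surface nearest-distance thickness oracle
#' are added from a fine-grid voxelization at `fine` mm (a volume
#' quadrature; the distance oracle samples the Euclidean distance from the
#' inner to the outer boundary).
#'
#' @param spec a [phantom_spec()].
#' @param n_theta base number of polar quadrature nodes (azimuthal is 2x).
#' @param fine fine-grid spacing for the volumetric oracles, mm.
#' @param conv_tol refinement convergence tolerance for the quadrature.
#' @param components `"parametric"` or `"full"`.
#' @return list of ground-truth values (mm-based units: mm^3, mm^2, mm).
#' @export
oracle_descriptors <- function(spec, n_theta = 512, fine = NULL,
                               conv_tol = 1e-3,
                               components = c("full", "parametric")) {
  components <- match.arg(components)
  q1 <- parametric_truth(spec, n_theta, light = TRUE)
  q2 <- parametric_truth(spec, 2L * n_theta, light = TRUE)
  for (nm in c("V_UWM", "A_inner")) {
    rel <- abs(q2[[nm]] - q1[[nm]]) / max(abs(q2[[nm]]), 1e-12)
    if (rel > conv_tol)
      stop(sprintf("quadrature not converged for %s (rel change %.2g at n_theta = %d); increase n_theta",
                   nm, rel, 2L * n_theta))
  }
  out <- parametric_truth(spec, n_theta, light = FALSE)
  out$V_UWM <- q2$V_UWM
  out$A_inner <- q2$A_inner
  out$GI_true <- q2$A_inner / out$A_hull
  if (components == "full") {
    if (is.null(fine)) fine <- min(spec$spacing) / 2
    out <- c(out, volumetric_truth(spec, fine))
  }
  out
}

# Midpoint-rule quadrature of the parametric inner surface plus hull and
# curvature functionals. light = TRUE computes only V and A (used for the
# refinement convergence check without the memory cost of the second
# fundamental form at doubled node counts).
parametric_truth <- function(spec, n_theta, light = FALSE) {
  l <- spec$fold_freq[1]; m <- spec$fold_freq[2]
  R0 <- spec$R0; a <- spec$fold_amp
  w <- spec$wall_width; b <- spec$wall_bias
  nth <- n_theta; nph <- 2L * n_theta
  th <- (seq_len(nth) - 0.5) * pi / nth
  ph <- (seq_len(nph) - 0.5) * 2 * pi / nph
  dth <- pi / nth; dph <- 2 * pi / nph
  TH <- matrix(th, nth, nph)
  PH <- matrix(ph, nth, nph, byrow = TRUE)
  slt <- sin(l * TH); clt <- cos(l * TH)
  smp <- sin(m * PH); cmp <- cos(m * PH)
  u <- slt * smp
  S <- fold_shape_r(u, w, b); S1 <- fold_shape_d1(u, w, b)
  S2 <- fold_shape_d2(u, w, b)
  rho <- R0 * (1 + a * S)
  u_t <- l * clt * smp
  u_p <- m * slt * cmp
  u_tt <- -l^2 * u
  u_pp <- -m^2 * u
  u_tp <- l * m * clt * cmp
  rho_t <- R0 * a * S1 * u_t
  rho_p <- R0 * a * S1 * u_p
  rho_tt <- R0 * a * (S2 * u_t^2 + S1 * u_tt)
  rho_pp <- R0 * a * (S2 * u_p^2 + S1 * u_pp)
  rho_tp <- R0 * a * (S2 * u_t * u_p + S1 * u_tp)
  st <- sin(TH); ct <- cos(TH)
  sp <- sin(PH); cp <- cos(PH)

  V <- sum(rho^3 / 3 * st) * dth * dph
  dA <- rho * st * sqrt(rho^2 + rho_t^2 + (rho_p / st)^2)
  A <- sum(dA) * dth * dph
  if (light) return(list(V_UWM = V, A_inner = A))

  # position and derivatives for fundamental forms
  rx <- st * cp; ry <- st * sp; rz <- ct
  rtx <- ct * cp; rty <- ct * sp; rtz <- -st
  rpx <- -st * sp; rpy <- st * cp; rpz <- 0
  Xt <- list(rho_t * rx + rho * rtx, rho_t * ry + rho * rty, rho_t * rz + rho * rtz)
  Xp <- list(rho_p * rx + rho * rpx, rho_p * ry + rho * rpy, rho_p * rz)
  rttx <- -rx; rtty <- -ry; rttz <- -rz
  rtpx <- -ct * sp; rtpy <- ct * cp
  rppx <- -st * cp; rppy <- -st * sp
  Xtt <- list(rho_tt * rx + 2 * rho_t * rtx + rho * rttx,
              rho_tt * ry + 2 * rho_t * rty + rho * rtty,
              rho_tt * rz + 2 * rho_t * rtz + rho * rttz)
  Xtp <- list(rho_tp * rx + rho_t * rpx + rho_p * rtx + rho * rtpx,
              rho_tp * ry + rho_t * rpy + rho_p * rty + rho * rtpy,
              rho_tp * rz + rho_p * rtz)
  Xpp <- list(rho_pp * rx + 2 * rho_p * rpx + rho * rppx,
              rho_pp * ry + 2 * rho_p * rpy + rho * rppy,
              rho_pp * rz)
  E <- Xt[[1]]^2 + Xt[[2]]^2 + Xt[[3]]^2
  Fq <- Xt[[1]] * Xp[[1]] + Xt[[2]] * Xp[[2]] + Xt[[3]] * Xp[[3]]
  G <- Xp[[1]]^2 + Xp[[2]]^2 + Xp[[3]]^2
  nxv <- Xt[[2]] * Xp[[3]] - Xt[[3]] * Xp[[2]]
  nyv <- Xt[[3]] * Xp[[1]] - Xt[[1]] * Xp[[3]]
  nzv <- Xt[[1]] * Xp[[2]] - Xt[[2]] * Xp[[1]]
  nn <- sqrt(nxv^2 + nyv^2 + nzv^2)
  nxv <- nxv / nn; nyv <- nyv / nn; nzv <- nzv / nn
  L <- Xtt[[1]] * nxv + Xtt[[2]] * nyv + Xtt[[3]] * nzv
  M <- Xtp[[1]] * nxv + Xtp[[2]] * nyv + Xtp[[3]] * nzv
  N <- Xpp[[1]] * nxv + Xpp[[2]] * nyv + Xpp[[3]] * nzv
  # sign: outward-convex positive (sphere -> +1/R)
  H <- -(E * N - 2 * Fq * M + G * L) / (2 * (E * G - Fq^2))
  K <- (L * N - M^2) / (E * G - Fq^2)
  disc <- pmax(H^2 - K, 0)
  k1 <- H + sqrt(disc); k2 <- H - sqrt(disc)
  dAq <- nn  # |Xt x Xp|, element dA/(dth dph); equals the dA above
  I_in <- sum(H^2 * dAq) * dth * dph

  t <- spec$t_cortex
  f1 <- 1 + t * k1; f2 <- 1 + t * k2
  ok <- f1 > 0 & f2 > 0
  k1o <- k1 / f1; k2o <- k2 / f2
  Ho <- (k1o + k2o) / 2
  I_out <- sum((Ho^2 * f1 * f2 * dAq)[ok]) * dth * dph
  A_outer_par <- sum((f1 * f2 * dAq)[ok]) * dth * dph
  C_true <- sqrt((I_in + I_out) / (8 * pi))

  # convex hull of a dense surface sample (prefiltered to the outer band)
  P <- cbind(as.vector(rho * rx), as.vector(rho * ry), as.vector(rho * rz))
  keep <- as.vector(rho) >= max(rho) - max(2.5, 0.25 * a * R0 + 1)
  P <- P[keep, , drop = FALSE]
  if (nrow(P) > 60000) P <- P[seq(1, nrow(P), length.out = 60000), ]
  hull <- cpp_convex_hull(P)
  GI_true <- A / hull$area

  list(V_UWM = V, A_inner = A, A_hull = hull$area, V_hull = hull$volume,
       GI_true = GI_true, C_true = C_true, I_inner = I_in, I_outer = I_out,
       A_outer_offset = A_outer_par, intact_fraction = mean(ok))
}

# Fine-grid volumetric oracles: label volumes by voxel counting, outer area
# by the weighted-surfel estimator on the refined grid, thickness by the
# nearest-distance between the inner and outer boundary surfaces.
volumetric_truth <- function(spec, fine) {
  fspec <- spec
  fspec$spacing <- rep(fine, 3L)
  fspec$dims <- as.integer(ceiling(spec$dims * spec$spacing / fine))
  ph <- generate_phantom(fspec, truth = "none")
  map <- ph$map
  vv <- prod(map$spacing)
  counts <- tabulate(map$values + 1L, nbins = 5L)
  d <- dim(map$values)
  # outer area at fine grid
  faces <- cpp_boundary_faces(map$values, d, c(1L, 2L), c(0L, 3L, 4L), TRUE)
  G <- cpp_gauss_smooth(as.numeric(map$values %in% c(1L, 2L)), d, rep(1.5, 3))
  w <- cpp_face_weights(G, d, faces)
  A_outer <- sum(w) * fine^2
  # two-surface nearest distance: EDT from the outer boundary, sampled at
  # inner-boundary CoGM voxels
  inner_faces <- cpp_boundary_faces(map$values, d, 2L, 1L, FALSE)
  outer_mask <- array(0L, d)
  outer_mask[unique(faces[faces[, 1] %in% which(map$values == 2L) - 1L, 1]) + 1L] <- 1L
  if (sum(outer_mask) == 0) {
    T_true <- NA_real_
  } else {
    dto <- cpp_edt(outer_mask, d, map$spacing, FALSE)$dist
    inner_vox <- unique(inner_faces[, 1]) + 1L
    # distance measured between boundary voxel centres; one fine voxel
    # separates each centre pair from the geometric faces
    T_true <- stats::median(dto[inner_vox]) + fine
  }
  list(V_CoGM = counts[3] * vv, V_CSF = counts[4] * vv,
       V_UWM_vox = counts[2] * vv, A_outer = A_outer, T_true = T_true,
       fine_spacing = fine)
}
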