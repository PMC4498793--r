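REGION_OF_HEMI <- list(R = c(1L, 3L, 5L, 7L), L = c(2L, 4L, 6L, 8L))

region_codes_for <- function(region) {
  switch(region,
         whole = 0L:8L,
         R = REGION_OF_HEMI$R, L = REGION_OF_HEMI$L,
         REGION_CODES[[region]])
}

resample_regions <- function(regions, target_spacing, target_dims) {
  vals <- cpp_resample_nn(regions$values, dim(regions$values),
                          regions$spacing, target_dims, target_spacing)
  structure(list(values = array(vals, target_dims), spacing = target_spacing,
                 origin = regions$origin), class = "region_map")
}

#' Measure all cortical descriptors for one subject
#'
#' Computes the descriptor set over the 11 reporting regions (whole brain,
#' both hemispheres, 8 lobes): tissue volumes by mask intersection on the
#' native grid; inner/outer surface areas by restricting the weighted
#' boundary elements to the region of their carrying voxel; median
#' streamline thickness over each region's valid CoGM voxels; regional GI
#' as region-restricted inner area over region-restricted hull-boundary
#' area (hull faces assigned to the region of the nearest UWM voxel);
#' regional C from region-restricted vertex sums with unchanged
#' normalization. Surface-based descriptors are computed on an isotropic
#' resampling (min in-plane spacing) when the native grid is anisotropic;
#' volumes and thickness stay native.
#'
#' @param map a [tissue_label_map()].
#' @param regions a `region_map` on the same grid (defaults to the octant
#'   parcellation).
#' @param subject_id,timepoint identifiers attached to the records.
#' @param descriptors subset of descriptors to compute (all by default;
#'   dropping `C_global` and/or `T_median` skips the expensive stages).
#' @param regions_report which reporting regions to emit.
#' @return A `subject_measurement`: `records` (descriptor data.frame) and
#'   `qc` (invalid-thickness fraction, mesh component counts, solver info).
#' @export
measure_subject <- function(map, regions = NULL, subject_id = "subject",
                            timepoint = NA_real_,
                            descriptors = DESCRIPTORS_ALL,
                            regions_report = REGIONS_ALL) {
  stopifnot(inherits(map, "tissue_label_map"),
            all(descriptors %in% DESCRIPTORS_ALL))
  if (is.null(regions)) regions <- octant_regions(map)
  if (!all(dim(regions$values) == dim(map$values)))
    stop("region map grid does not match the label map")
  qc <- list()
  recs <- list()
  rr <- regions_report

  reg_native <- regions$values
  need_iso <- any(c("A_inner", "A_outer", "GI", "C_global") %in% descriptors)

  # volumes (native grid)
  vol_roles <- c(V_UWM = "UWM", V_CoGM = "CoGM", V_CSF = "CSF")
  for (dsc in intersect(names(vol_roles), descriptors)) {
    for (rg in rr) {
      mask <- array(reg_native %in% region_codes_for(rg), dim(reg_native))
      recs[[length(recs) + 1L]] <-
        descriptor_record(subject_id, timepoint, rg, dsc,
                          tissue_volume(map, vol_roles[[dsc]], mask))
    }
  }

  if (need_iso) {
    iso <- ensure_isotropic(map)
    d_iso <- dim(iso$values)
    reg_iso <- if (identical(d_iso, dim(map$values))) regions
               else resample_regions(regions, iso$spacing, d_iso)
    h2 <- iso$spacing[1]^2
    surf <- list()
    for (side in intersect(c("inner", "outer"),
                           c(if ("A_inner" %in% descriptors || "GI" %in% descriptors) "inner",
                             if ("A_outer" %in% descriptors) "outer"))) {
      bs <- extract_interface(iso, side)
      wts <- face_weights(bs)
      face_region <- reg_iso$values[bs$faces[, 1] + 1L]
      surf[[side]] <- list(wts = wts, region = face_region)
    }
    if (!is.null(surf$inner) && "A_inner" %in% descriptors)
      for (rg in rr)
        recs[[length(recs) + 1L]] <- descriptor_record(
          subject_id, timepoint, rg, "A_inner",
          sum(surf$inner$wts[surf$inner$region %in% region_codes_for(rg)]) * h2 / 100)
    if (!is.null(surf$outer))
      for (rg in rr)
        recs[[length(recs) + 1L]] <- descriptor_record(
          subject_id, timepoint, rg, "A_outer",
          sum(surf$outer$wts[surf$outer$region %in% region_codes_for(rg)]) * h2 / 100)

    if ("GI" %in% descriptors) {
      hull <- convex_hull_mask(iso, "UWM")
      hull_lab <- array(as.integer(hull), d_iso)
      hf <- cpp_boundary_faces(hull_lab, d_iso, 1L, 0L, TRUE)
      G <- cpp_gauss_smooth(as.numeric(hull_lab), d_iso, rep(1.2, 3))
      hw <- cpp_face_weights(G, d_iso, hf)
      # hull faces inherit the region of the nearest UWM voxel
      uwm <- array(as.integer(iso$values == 1L), d_iso)
      ft <- cpp_edt(uwm, d_iso, iso$spacing, TRUE)
      hull_region <- reg_iso$values[ft$nearest[hf[, 1] + 1L]]
      for (rg in rr) {
        codes <- region_codes_for(rg)
        num <- sum(surf$inner$wts[surf$inner$region %in% codes])
        den <- sum(hw[hull_region %in% codes])
        recs[[length(recs) + 1L]] <- descriptor_record(
          subject_id, timepoint, rg, "GI",
          if (den > 0) num / den else NA_real_,
          note = if (den > 0) NA_character_ else "empty hull restriction")
      }
      qc$hull_area <- attr(hull, "area")
    }

    if ("C_global" %in% descriptors) {
      vsums <- list()
      for (side in c("inner", "outer")) {
        msh <- vertex_mean_curvature(extract_mesh(iso, side))
        H <- cpp_smooth_vertex_field(msh$triangles, nrow(msh$vertices),
                                     msh$H, 60L)
        vidx <- pmin(pmax(floor(sweep(msh$vertices, 2, iso$spacing, "/")) + 1L, 1L),
                     matrix(rep(d_iso, each = nrow(msh$vertices)), ncol = 3))
        lin <- vidx[, 1] + d_iso[1] * (vidx[, 2] - 1L) +
          d_iso[1] * d_iso[2] * (vidx[, 3] - 1L)
        vreg <- reg_iso$values[lin]
        if (any(vreg == 0L)) {
          brain <- array(as.integer(reg_iso$values > 0L), d_iso)
          ftb <- cpp_edt(brain, d_iso, iso$spacing, TRUE)
          vreg[vreg == 0L] <- reg_iso$values[ftb$nearest[lin[vreg == 0L]]]
        }
        ok <- !is.na(H) & !is.na(msh$vertex_area)
        vsums[[side]] <- list(e = H[ok]^2 * msh$vertex_area[ok],
                              region = vreg[ok])
        qc[[paste0("mesh_components_", side)]] <- msh$n_components
      }
      for (rg in rr) {
        codes <- region_codes_for(rg)
        e <- sum(vsums$inner$e[vsums$inner$region %in% codes]) +
          sum(vsums$outer$e[vsums$outer$region %in% codes])
        recs[[length(recs) + 1L]] <- descriptor_record(
          subject_id, timepoint, rg, "C_global", sqrt(e / (8 * pi)))
      }
    }
  }

  if ("T_median" %in% descriptors) {
    pf <- solve_laplace(map)
    tf <- thickness_field(pf, map)
    qc$laplace_iterations <- pf$iterations
    qc$thickness_qc <- tf$qc
    qc$invalid_thickness_fraction <-
      unname((tf$qc[["stationary"]] + tf$qc[["runaway"]] +
                tf$qc[["wrong_exit"]]) / tf$qc[["n_cogm"]])
    for (rg in rr) {
      mask <- array(reg_native %in% region_codes_for(rg), dim(reg_native))
      med <- median_thickness(tf, mask)
      recs[[length(recs) + 1L]] <- descriptor_record(
        subject_id, timepoint, rg, "T_median", as.numeric(med),
        note = if (is.na(med)) attr(med, "reason") else NA_character_)
    }
  }

  structure(list(records = do.call(rbind, recs), qc = qc,
                 subject_id = subject_id, timepoint = timepoint),
            class = "subject_measurement")
}

#' Longitudinal increase factors
#'
#' Per-subject ratio of each descriptor at the later timepoint to the
#' earlier one, per region (the ratio is computed within subject; cohort
#' summaries then average the per-subject factors, never the ratio of
#' cohort means). Missing if either value is missing or the early value is
#' zero.
#'
#' @param m30,m40 `subject_measurement`s of the same subject, timepoints
#'   ordered.
#' @return data.frame of factor records (`units = ""`).
#' @export
increase_factors <- function(m30, m40) {
  stopifnot(inherits(m30, "subject_measurement"),
            inherits(m40, "subject_measurement"))
  if (!identical(m30$subject_id, m40$subject_id))
    stop("subject id mismatch: ", m30$subject_id, " vs ", m40$subject_id)
  if (!is.na(m30$timepoint) && !is.na(m40$timepoint) &&
      m40$timepoint <= m30$timepoint)
    stop("timepoints must be ordered (second argument is the later scan)")
  a <- m30$records[, c("region", "descriptor", "value")]
  b <- m40$records[, c("region", "descriptor", "value")]
  mrg <- merge(a, b, by = c("region", "descriptor"),
               suffixes = c("_30", "_40"))
  fac <- ifelse(!is.na(mrg$value_30) & !is.na(mrg$value_40) &
                  mrg$value_30 != 0,
                mrg$value_40 / mrg$value_30, NA_real_)
  data.frame(subject_id = m30$subject_id, region = mrg$region,
             descriptor = mrg$descriptor, factor = fac,
             stringsAsFactors = FALSE)
}
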