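#' Canonical tissue label scheme
#'
#' Internal label codes used throughout the package: background 0,
#' unmyelinated white matter (UWM) 1, cortical grey matter (CoGM) 2,
#' extracerebral CSF 3, and an OTHER class 4 for tissue that takes no part in
#' the cortical descriptors. Files using different integer codes can be
#' ingested by passing a modified scheme to [load_label_volume()] (see
#' [read_label_scheme()]).
#'
#' @format Named integer vector mapping role names to file codes.
#' @export
default_label_scheme <- c(BG = 0L, UWM = 1L, CoGM = 2L, CSF = 3L, OTHER = 4L)

LABEL_ROLES <- names(default_label_scheme)

#' Construct a tissue label map
#'
#' The central image container of the package: a 3D integer lattice of
#' tissue labels plus the physical voxel spacing in mm. All geometry
#' downstream is computed in physical coordinates (voxel centre of index
#' `(i, j, k)`, 1-based, sits at `origin + (index - 0.5) * spacing`), never
#' in index units, because clinical neonatal acquisitions are strongly
#' anisotropic.
#'
#' @param values 3D integer array with values in the canonical scheme
#'   (0 = BG, 1 = UWM, 2 = CoGM, 3 = CSF, 4 = OTHER).
#' @param spacing numeric length-3, mm per axis, strictly positive.
#' @param origin physical position of the volume corner, mm.
#' @return An object of class `tissue_label_map`.
#' @export
tissue_label_map <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("label volume must be a 3D array, got ", length(dim(values)),
         " dimensions")
  if (is.double(values)) {
    if (any(values != round(values), na.rm = TRUE))
      stop("label volume contains non-integer values")
    storage.mode(values) <- "integer"
  }
  if (anyNA(values)) stop("label volume contains missing values")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  bad <- setdiff(unique(as.vector(values)), unname(default_label_scheme))
  if (length(bad))
    stop("unknown label value(s): ", paste(sort(bad), collapse = ", "),
         " (expected codes ", paste(default_label_scheme, collapse = ", "), ")")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "tissue_label_map")
}

#' @export
print.tissue_label_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("tissue_label_map: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  tab <- tabulate(x$values + 1L, nbins = 5L)
  names(tab) <- LABEL_ROLES
  vv <- prod(x$spacing) / 1000
  for (r in LABEL_ROLES)
    cat(sprintf("  %-5s %10d voxels  %8.1f cm^3\n", r, tab[[r]], tab[[r]] * vv))
  invisible(x)
}

#' Read a label scheme from a YAML config
#'
#' A small text config mapping role names (`BG`, `UWM`, `CoGM`, `CSF`,
#' `OTHER`) to the integer codes a third-party segmentation uses, e.g.
#' `UWM: 3`.
#'
#' @param path YAML file.
#' @return Named integer vector usable as the `scheme` argument of
#'   [load_label_volume()].
#' @export
read_label_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  scheme <- default_label_scheme
  extra <- setdiff(names(raw), LABEL_ROLES)
  if (length(extra))
    stop("unknown label role(s) in scheme config: ", paste(extra, collapse = ", "))
  for (nm in names(raw)) scheme[[nm]] <- as.integer(raw[[nm]])
  if (anyDuplicated(scheme)) stop("label scheme assigns one code to two roles")
  scheme
}

#' Load a tissue label volume from NIfTI
#'
#' Reads a single 3D volume, validates that every voxel carries a label from
#' the scheme, and recodes it to the canonical internal codes. Spacing is
#' taken from the NIfTI header.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param scheme named integer vector mapping the five role names to the
#'   codes used in the file; defaults to [default_label_scheme].
#' @return A [tissue_label_map()].
#' @export
load_label_volume <- function(path, scheme = default_label_scheme) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D single-volume NIfTI, got dimensions ",
         paste(dim(arr), collapse = " x "))
  if (any(arr != round(arr)))
    stop("NIfTI data are not integer labels: ", path)
  arr <- array(as.integer(arr), dim(arr))
  stopifnot(setequal(names(scheme), LABEL_ROLES))
  bad <- setdiff(unique(as.vector(arr)), unname(scheme))
  if (length(bad))
    stop("unknown label value(s) in ", basename(path), ": ",
         paste(sort(bad), collapse = ", "))
  # recode file codes -> canonical codes
  recoded <- arr
  for (r in LABEL_ROLES) {
    code <- scheme[[r]]
    canon <- default_label_scheme[[r]]
    if (code != canon) recoded[arr == code] <- canon
  }
  spacing <- RNifti::pixdim(img)[1:3]
  tissue_label_map(recoded, spacing = spacing)
}

#' Write a tissue label map to NIfTI
#'
#' @param map a [tissue_label_map()] (or a region map).
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Nearest-neighbour resampling of a label map
#'
#' Resamples in physical space; the label set can only shrink, never grow.
#' Refuses targets coarser than 4x the original spacing on any axis, where
#' nearest-neighbour subsampling would silently destroy thin structures.
#'
#' @param map a [tissue_label_map()].
#' @param target numeric: mm per axis (length 1 or 3).
#' @return A resampled [tissue_label_map()].
#' @export
resample_nearest <- function(map, target) {
  if (length(target) == 1L) target <- rep(target, 3L)
  if (length(target) != 3L || any(target <= 0))
    stop("target spacing must be 1 or 3 positive values")
  if (any(target > 4 * map$spacing))
    stop("refusing to resample coarser than 4x the original spacing (",
         paste(signif(map$spacing, 3), collapse = ", "), " -> ",
         paste(signif(target, 3), collapse = ", "), " mm): information loss")
  if (isTRUE(all.equal(target, map$spacing))) return(map)
  dims <- dim(map$values)
  extent <- dims * map$spacing
  new_dims <- pmax(1L, as.integer(round(extent / target)))
  vals <- cpp_resample_nn(map$values, dims, map$spacing,
                          new_dims, target)
  tissue_label_map(vals, spacing = target, origin = map$origin)
}

#' Is the voxel grid isotropic?
#' @param map a [tissue_label_map()].
#' @param tol relative tolerance.
#' @return logical.
#' @export
is_isotropic <- function(map, tol = 1e-6) {
  diff(range(map$spacing)) <= tol * mean(map$spacing)
}

# Resample to isotropic spacing = min(in-plane spacing) when needed; the
# default preprocessing for the surface-area, gyrification and curvature
# estimators, which assume isotropy. Volumes and thickness stay on the
# native grid.
ensure_isotropic <- function(map) {
  if (is_isotropic(map)) return(map)
  resample_nearest(map, min(map$spacing))
}

#' Tissue volume in cm^3
#'
#' Volume of a label class: voxel count times physical voxel volume.
#'
#' @param map a [tissue_label_map()].
#' @param role one of `"UWM"`, `"CoGM"`, `"CSF"`, `"OTHER"`, `"BG"`.
#' @param mask optional logical array restricting the count (e.g. a region).
#' @return volume in cm^3.
#' @export
tissue_volume <- function(map, role = "CoGM", mask = NULL) {
  code <- default_label_scheme[[match.arg(role, LABEL_ROLES)]]
  sel <- map$values == code
  if (!is.null(mask)) sel <- sel & mask
  sum(sel) * prod(map$spacing) / 1000
}

REGIONS_ALL <- c("whole", "R", "L", "FR", "FL", "TR", "TL", "PR", "PL", "OR", "OL")
DESCRIPTORS_ALL <- c("V_UWM", "V_CoGM", "V_CSF", "A_inner", "A_outer",
                     "T_median", "GI", "C_global")
DESCRIPTOR_UNITS <- c(V_UWM = "cm^3", V_CoGM = "cm^3", V_CSF = "cm^3",
                      A_inner = "cm^2", A_outer = "cm^2", T_median = "mm",
                      GI = "", C_global = "")

#' Assemble descriptor records
#'
#' One row per (subject, timepoint, region, descriptor, value); the unit of
#' all downstream statistics. Volumes are in cm^3, areas in cm^2, thickness
#' in mm, gyrification index and global mean curvature dimensionless.
#'
#' @param subject_id subject identifier.
#' @param timepoint postmenstrual age at scan, weeks.
#' @param region one of `"whole"`, hemispheres `"R"`/`"L"` or lobe codes
#'   (`"FR"`, `"FL"`, `"TR"`, `"TL"`, `"PR"`, `"PL"`, `"OR"`, `"OL"`).
#' @param descriptor descriptor name (see `DESCRIPTORS_ALL`).
#' @param value numeric value (NA allowed, with `note`).
#' @param note optional free-text QC note per row.
#' @return data.frame of descriptor records.
#' @export
descriptor_record <- function(subject_id, timepoint, region, descriptor,
                              value, note = NA_character_) {
  stopifnot(all(region %in% REGIONS_ALL), all(descriptor %in% DESCRIPTORS_ALL))
  bad <- !is.na(value) & value < 0 &
    descriptor %in% c("V_UWM", "V_CoGM", "V_CSF", "A_inner", "A_outer",
                      "T_median", "GI")
  if (any(bad)) stop("negative value for nonnegative descriptor")
  data.frame(subject_id = as.character(subject_id), timepoint = timepoint,
             region = region, descriptor = descriptor, value = value,
             units = unname(DESCRIPTOR_UNITS[descriptor]), note = note,
             stringsAsFactors = FALSE)
}

#' Read / write descriptor tables
#'
#' Long-format CSV, UTF-8 with a header row; one descriptor record per row.
#'
#' @param x descriptor data.frame (for writing).
#' @param path CSV path.
#' @return The data.frame (reading), or `path` invisibly (writing).
#' @export
write_descriptor_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_csv
#' @export
read_descriptor_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timepoint", "region", "descriptor", "value")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("descriptor CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  x
}

#' Read a cohort covariate table
#'
#' One row per subject: PMA at both scans, abnormality classes (total brain
#' and CoGM score, three levels with moderate and severe merged) and
#' interhemispheric fissure width.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_covariate_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "pma_30", "pma_40", "class_total", "class_cogm")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("covariate CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  validate_covariates(x)
}

validate_covariates <- function(x) {
  lv <- c("normal", "mild", "moderate_severe")
  for (cl in c("class_total", "class_cogm")) {
    bad <- setdiff(unique(x[[cl]]), lv)
    if (length(bad)) stop("unknown abnormality class in ", cl, ": ",
                          paste(bad, collapse = ", "))
    x[[cl]] <- factor(x[[cl]], levels = lv)
  }
  if (is.null(x$interval)) x$interval <- x$pma_40 - x$pma_30
  if (any(x$interval <= 0)) stop("scan interval must be positive for every subject")
  x
}
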