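#' Regional SUVR quantification
#'
#' Standardized uptake value ratios on a template-space PET: for each
#' requested ROI role, the mean activity over all voxels whose label maps to
#' that role, divided by the mean activity over the cerebellar gray matter
#' voxels. Composite ROIs pool voxels across their member labels
#' (voxel-weighted), never averages of sub-ROI means. No partial-volume
#' correction is applied.
#'
#' @param pet template-space [volume3d] (or array) congruent with the atlas.
#' @param atlas an [roi_atlas()].
#' @param roi_roles character vector of roles to quantify.
#' @param subject_id,scan_id,pipeline provenance columns for the output
#'   table.
#' @return data.frame (one row per ROI) with columns `subject_id`,
#'   `scan_id`, `pipeline`, `roi_role`, `suvr`, `n_voxels`. Empty ROIs get
#'   `NA` with a warning; a non-positive cerebellar-gray mean is an error.
#' @examples
#' tp <- make_template(c(32, 32, 32), seed = 7)
#' pet <- volume3d(array(1, dim(tp$template$data)))
#' compute_suvr(pet, tp$atlas)$suvr    # uniform activity -> all SUVR 1
#' @export
compute_suvr <- function(pet, atlas,
                         roi_roles = c("braak12", "braak34", "braak56",
                                       "metatemporal", "ec", "itg"),
                         subject_id = NA_character_,
                         scan_id = NA_character_,
                         pipeline = c("mrfree", "classic", "native_truth")) {
  pipeline <- match.arg(pipeline)
  arr <- .as_vol_array(pet)
  if (!all(dim(arr) == dim(atlas$labels)))
    stop("PET and atlas grids are not congruent")
  ref_vox <- .role_voxels(atlas, "cerebellar_gray")
  ref <- mean(arr[ref_vox])
  if (!is.finite(ref) || ref <= 0)
    stop("cerebellar gray reference mean is zero or negative")
  suvr <- nvox <- numeric(length(roi_roles))
  for (i in seq_along(roi_roles)) {
    vox <- .role_voxels(atlas, roi_roles[i])
    nvox[i] <- length(vox)
    if (length(vox) == 0L) {
      warning("ROI role '", roi_roles[i], "' has no voxels; SUVR set to NA")
      suvr[i] <- NA_real_
    } else {
      suvr[i] <- mean(arr[vox]) / ref
    }
  }
  data.frame(subject_id = subject_id, scan_id = scan_id, pipeline = pipeline,
             roi_role = roi_roles, suvr = suvr, n_voxels = nvox,
             stringsAsFactors = FALSE)
}

#' Atlas file IO
#'
#' `write_atlas()` writes the label map as NIfTI and the role table as CSV;
#' `load_atlas()` reads them back (or any user-supplied label map / role
#' table pair, e.g. a real MNI-space parcellation) and validates the atlas
#' invariants: known role names, no duplicate (label, role) rows, full role
#' coverage of non-background labels, and a nonempty cerebellar gray
#' reference.
#'
#' @param atlas an [roi_atlas()].
#' @param label_path NIfTI label-map path.
#' @param role_path delimited text file with columns `label`, `role`.
#' @return `load_atlas()`: an [roi_atlas()]; `write_atlas()`: invisibly the
#'   label path.
#' @export
load_atlas <- function(label_path, role_path) {
  vol <- read_volume(label_path)
  labels <- vol$data
  if (max(abs(labels - round(labels))) > 1e-6)
    stop("label map is not integer-valued")
  labels <- array(as.integer(round(labels)), dim(labels))
  roles <- utils::read.csv(role_path, stringsAsFactors = FALSE)
  roi_atlas(labels, roles)
}

#' @rdname load_atlas
#' @export
write_atlas <- function(atlas, label_path, role_path) {
  write_volume(volume3d(array(as.numeric(atlas$labels), dim(atlas$labels))),
               label_path)
  utils::write.csv(atlas$roles, role_path, row.names = FALSE)
  invisible(label_path)
}

#' SUVR table IO
#'
#' @param suvr_table data.frame as returned by [compute_suvr()] (rows may be
#'   concatenated across subjects/pipelines).
#' @param path CSV path.
#' @return `read_suvr()`: the data.frame; `write_suvr()`: `path` invisibly.
#' @export
write_suvr <- function(suvr_table, path) {
  utils::write.csv(suvr_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_suvr
#' @export
read_suvr <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
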