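#' Voxel image container
#'
#' A minimal container for a 3-D scalar brain image in a common template
#' space: a numeric array plus the voxel-to-world affine and the voxel size.
#' No resampling is ever performed by this package; images, label maps and
#' masks must already share a grid, and shape mismatches are hard errors.
#'
#' @param values Numeric 3-D array (raw uptake or SUVR, unitless).
#' @param affine 4x4 voxel-to-world transform in mm. Defaults to a diagonal
#'   transform built from `grid_spacing`.
#' @param grid_spacing Numeric length-3 voxel size in mm (default 2-mm
#'   isotropic, the grid the 3x3x3 node cubes are specified on).
#' @param suvr Logical flag: `TRUE` once the image has been intensity
#'   normalized to a reference region.
#' @return An object of class `voxel_image` with fields `values`, `affine`,
#'   `grid_spacing`, `suvr`.
#' @export
voxel_image <- function(values, affine = NULL, grid_spacing = c(2, 2, 2),
                        suvr = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array, got ",
         paste(dim(values), collapse = "x"))
  }
  grid_spacing <- as.numeric(grid_spacing)
  if (length(grid_spacing) != 3L || any(!is.finite(grid_spacing)) ||
      any(grid_spacing <= 0)) {
    stop("`grid_spacing` must be three strictly positive voxel sizes (mm)")
  }
  if (is.null(affine)) {
    affine <- diag(c(grid_spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be a 4x4 matrix")
  structure(
    list(values = values, affine = affine, grid_spacing = grid_spacing,
         suvr = isTRUE(suvr)),
    class = "voxel_image"
  )
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("<voxel_image> %s voxels, %s mm%s\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$grid_spacing), collapse = "x"),
              if (x$suvr) ", SUVR" else ""))
  invisible(x)
}

#' @export
dim.voxel_image <- function(x) dim(x$values)

#' Atlas label image
#'
#' Integer parcellation on the same grid as its companion [voxel_image()]:
#' 0 is background, positive integers are region ids.
#'
#' @param labels Integer 3-D array of region labels.
#' @param names Optional character vector mapping region ids to names; either
#'   named by id or parallel to `sort(unique positive labels)`.
#' @param affine,grid_spacing As in [voxel_image()].
#' @return An object of class `label_image` with fields `labels`,
#'   `region_ids`, `names`, `affine`, `grid_spacing`.
#' @export
label_image <- function(labels, names = NULL, affine = NULL,
                        grid_spacing = c(2, 2, 2)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3-D array")
  }
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be nonnegative integers (0 = background)")
  }
  storage.mode(labels) <- "integer"
  region_ids <- sort(unique(labels[labels > 0L]))
  if (!is.null(names)) {
    if (!is.null(base::names(names))) {
      names <- names[as.character(region_ids)]
    } else if (length(names) != length(region_ids)) {
      stop("`names` must be named by region id or match the number of regions")
    }
    names <- stats::setNames(as.character(names), region_ids)
  }
  grid_spacing <- as.numeric(grid_spacing)
  if (is.null(affine)) affine <- diag(c(grid_spacing, 1))
  structure(
    list(labels = labels, region_ids = as.integer(region_ids), names = names,
         affine = as.matrix(affine), grid_spacing = grid_spacing),
    class = "label_image"
  )
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %s voxels, %d regions\n",
              paste(dim(x$labels), collapse = "x"), length(x$region_ids)))
  invisible(x)
}

#' @export
dim.label_image <- function(x) dim(x$labels)

# shared shape guard: the package never resamples, so any mismatch is fatal
check_same_grid <- function(a, b, what = "images") {
  da <- if (inherits(a, "voxel_image")) dim(a$values) else dim(a$labels)
  db <- if (inherits(b, "voxel_image")) dim(b$values) else
    if (inherits(b, "label_image")) dim(b$labels) else dim(b)
  if (!identical(da, db)) {
    stop(sprintf("shape mismatch between %s: %s vs %s (no implicit resampling)",
                 what, paste(da, collapse = "x"), paste(db, collapse = "x")))
  }
  invisible(TRUE)
}

#' Read a 3-D NIfTI-1 image
#'
#' Reads a `.nii`/`.nii.gz` volume as a [voxel_image()]. The image is taken
#' as-is: no resampling, no reorientation.
#'
#' @param path Path to a readable NIfTI-1 file.
#' @return A [voxel_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3-D volume in ", path, " but found ",
         length(d), " dimensions")
  }
  values <- array(as.numeric(img), dim = d)
  voxel_image(values,
              affine = unclass(RNifti::xform(img)),
              grid_spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' Read a NIfTI parcellation as a label image
#'
#' @param path Path to a NIfTI file of integer region labels.
#' @param names Optional region-id to name mapping (see [label_image()]).
#' @return A [label_image()].
#' @export
load_labels <- function(path, names = NULL) {
  img <- load_image(path)
  label_image(round(img$values), names = names, affine = img$affine,
              grid_spacing = img$grid_spacing)
}

#' Write a voxel or label image to NIfTI-1
#'
#' Values are stored as float64 so that a write/read round trip is
#' bit-exact.
#'
#' @param image A [voxel_image()] or [label_image()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  values <- if (inherits(image, "label_image")) image$labels else image$values
  spacing <- image$grid_spacing
  nif <- RNifti::asNifti(values)
  RNifti::pixdim(nif) <- spacing
  RNifti::writeNifti(nif, path, datatype = "double")
  invisible(path)
}

#' Intensity-normalize an image to a reference region (SUVR)
#'
#' Divides every voxel by the mean uptake within a reference-region mask
#' (classically the cerebellar crus for tau PET), yielding a standardized
#' uptake value ratio image.
#'
#' @param image A [voxel_image()] of raw uptake.
#' @param reference_mask A [label_image()] (any nonzero label is reference),
#'   a logical/numeric array mask, or a [voxel_image()] holding a mask.
#' @return A [voxel_image()] flagged as SUVR.
#' @export
compute_suvr <- function(image, reference_mask) {
  stopifnot(inherits(image, "voxel_image"))
  mask <- as_mask_array(reference_mask)
  check_same_grid(image, mask, "image and reference mask")
  if (!any(mask)) stop("reference mask is empty")
  ref_mean <- mean(image$values[mask])
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    stop("mean reference uptake must be finite and positive, got ", ref_mean)
  }
  voxel_image(image$values / ref_mean, affine = image$affine,
              grid_spacing = image$grid_spacing, suvr = TRUE)
}

as_mask_array <- function(mask) {
  if (inherits(mask, "label_image")) return(mask$labels > 0L)
  if (inherits(mask, "voxel_image")) return(mask$values != 0)
  if (is.array(mask)) return(mask != 0)
  stop("unsupported mask type: ", paste(class(mask), collapse = "/"))
}

#' Pooled regional statistic
#'
#' Pools the voxels of all listed regions and returns one statistic over the
#' pooled set. Pooling (rather than averaging per-region statistics) matters
#' for the tau composite, which is the median over the voxels of six
#' temporal-lobe regions taken together.
#'
#' @param image A [voxel_image()].
#' @param labels A [label_image()] on the same grid.
#' @param region_ids Integer region ids to pool.
#' @param statistic `"mean"` or `"median"`.
#' @return A scalar.
#' @export
region_statistic <- function(image, labels, region_ids,
                             statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(image, "voxel_image"), inherits(labels, "label_image"))
  check_same_grid(image, labels, "image and labels")
  region_ids <- as.integer(region_ids)
  sel <- labels$labels %in% region_ids
  if (!any(sel)) {
    missing <- setdiff(region_ids, labels$region_ids)
    stop("no voxels found for regions {", paste(region_ids, collapse = ", "),
         "}; ids absent from atlas: {", paste(missing, collapse = ", "), "}")
  }
  vox <- image$values[sel]
  if (statistic == "mean") mean(vox) else stats::median(vox)
}

#' Configuration for regional tau/amyloid comparator measures
#'
#' @param entorhinal_ids Atlas ids of the (bilateral) entorhinal cortex.
#' @param composite_ids Atlas ids of the six tau-composite regions
#'   (entorhinal, amygdala, parahippocampal, fusiform, inferior temporal,
#'   middle temporal; bilateral).
#' @param tau_threshold Tau positivity cutpoint on the composite SUVR
#'   (strictly greater than; default 1.23).
#' @param amyloid_threshold Amyloid positivity cutpoint on the mean cortical
#'   SUVR (strictly greater than; default 1.17).
#' @param reference_ids Optional atlas ids of the reference region used for
#'   SUVR normalization (cerebellar crus).
#' @return A list of class `regional_config`.
#' @export
regional_config <- function(entorhinal_ids, composite_ids,
                            tau_threshold = 1.23, amyloid_threshold = 1.17,
                            reference_ids = NULL) {
  stopifnot(length(entorhinal_ids) >= 1, length(composite_ids) >= 1,
            is.finite(tau_threshold), is.finite(amyloid_threshold))
  structure(
    list(entorhinal_ids = as.integer(entorhinal_ids),
         composite_ids = as.integer(composite_ids),
         tau_threshold = tau_threshold,
         amyloid_threshold = amyloid_threshold,
         reference_ids = if (!is.null(reference_ids)) as.integer(reference_ids)),
    class = "regional_config"
  )
}

#' Regional comparator measures: entorhinal SUVR, tau composite, positivity
#'
#' Computes the conventional region-of-interest measures the network method
#' is compared against: the mean entorhinal SUVR, the tau composite SUVR
#' (median over the pooled voxels of six temporal-lobe regions), and
#' positivity flags using strict `>` thresholds.
#'
#' @param suvr A [voxel_image()] already normalized to the reference region.
#' @param labels A [label_image()] on the same grid.
#' @param config A [regional_config()].
#' @param amyloid_suvr Optional scalar mean cortical amyloid SUVR from a
#'   matching amyloid scan; when given, an amyloid positivity flag is added.
#' @return A list of class `regional_measures` with fields `entorhinal_suvr`,
#'   `composite_suvr`, `tau_positive`, and optionally `amyloid_suvr`,
#'   `amyloid_positive`.
#' @export
regional_measures <- function(suvr, labels, config, amyloid_suvr = NULL) {
  stopifnot(inherits(config, "regional_config"))
  missing <- setdiff(unique(c(config$entorhinal_ids, config$composite_ids)),
                     labels$region_ids)
  if (length(missing)) {
    stop("regions required for comparator measures are missing from the ",
         "atlas: {", paste(missing, collapse = ", "), "}")
  }
  ent <- region_statistic(suvr, labels, config$entorhinal_ids, "mean")
  comp <- region_statistic(suvr, labels, config$composite_ids, "median")
  out <- list(
    entorhinal_suvr = ent,
    composite_suvr = comp,
    tau_positive = comp > config$tau_threshold
  )
  if (!is.null(amyloid_suvr)) {
    stopifnot(is.finite(amyloid_suvr))
    out$amyloid_suvr <- amyloid_suvr
    out$amyloid_positive <- amyloid_suvr > config$amyloid_threshold
  }
  structure(out, class = "regional_measures")
}
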