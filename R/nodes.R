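#' Binarize a probabilistic gray-matter map
#'
#' Voxels with probability at or above the threshold become part of the
#' gray-matter mask used to validate node cubes. The inclusive rule
#' (`>= threshold`) is configurable only through `threshold`.
#'
#' @param prob_map A [voxel_image()] with values in \[0, 1\].
#' @param threshold Probability cutoff, default 0.3.
#' @return A logical 3-D array mask.
#' @export
binarize_gm <- function(prob_map, threshold = 0.3) {
  stopifnot(inherits(prob_map, "voxel_image"))
  v <- prob_map$values
  tol <- 1e-6
  if (any(v < -tol | v > 1 + tol, na.rm = TRUE)) {
    stop("gray-matter probability map has values outside [0, 1]")
  }
  v >= threshold
}

#' Center voxel of an atlas region
#'
#' Returns the 0-based voxel coordinate nearest (Euclidean, in voxel units)
#' to the region's center of mass. Ties are broken deterministically by
#' lexicographic (x, y, z) order, so the result does not depend on storage
#' order. All voxel coordinates in this package are 0-based; world (mm)
#' coordinates come only from the affine.
#'
#' @param labels A [label_image()].
#' @param region_id A positive integer region id.
#' @return Integer length-3 voxel coordinate (0-based).
#' @export
region_center <- function(labels, region_id) {
  stopifnot(inherits(labels, "label_image"))
  idx <- which(labels$labels == as.integer(region_id), arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("region ", region_id, " is empty or absent")
  com <- colMeans(idx) - 1  # 0-based center of mass
  # candidate integer coordinates: floor/ceiling of the COM on each axis
  cand <- as.matrix(expand.grid(floor(com[1]):ceiling(com[1]),
                                floor(com[2]):ceiling(com[2]),
                                floor(com[3]):ceiling(com[3])))
  d2 <- colSums((t(cand) - com)^2)
  ord <- order(d2, cand[, 1], cand[, 2], cand[, 3])
  as.integer(cand[ord[1L], ])
}

#' Voxel coordinates of a node cube
#'
#' The cube of `edge^3` voxels centered at a coordinate: by default a 3x3x3
#' block, which on a 2-mm grid is the 6-mm node cube. Coordinates are
#' 0-based and may fall outside the image; callers detect that via `shape`.
#'
#' @param center Integer length-3 voxel coordinate (0-based).
#' @param edge Odd cube edge in voxels (default 3).
#' @param shape Optional image dimensions; when given, the attribute
#'   `out_of_bounds` marks coordinates outside `[0, shape)`.
#' @return An `edge^3` x 3 integer matrix of voxel coordinates, with
#'   attribute `out_of_bounds` (logical vector) when `shape` is supplied.
#' @export
cube_voxels <- function(center, edge = 3L, shape = NULL) {
  edge <- as.integer(edge)
  if (edge < 1L || edge %% 2L == 0L) {
    stop("cube edge must be an odd positive integer, got ", edge)
  }
  center <- as.integer(center)
  stopifnot(length(center) == 3L)
  h <- (edge - 1L) %/% 2L
  off <- (-h):h
  grid <- as.matrix(expand.grid(x = center[1] + off, y = center[2] + off,
                                z = center[3] + off))
  grid <- grid[order(grid[, 1], grid[, 2], grid[, 3]), , drop = FALSE]
  dimnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  if (!is.null(shape)) {
    oob <- grid[, 1] < 0L | grid[, 1] >= shape[1] |
      grid[, 2] < 0L | grid[, 2] >= shape[2] |
      grid[, 3] < 0L | grid[, 3] >= shape[3]
    attr(grid, "out_of_bounds") <- oob
  }
  grid
}

# linear (1-based) indices into an array for a 0-based coordinate matrix
cube_linear_index <- function(coords, shape) {
  1L + coords[, 1] + shape[1] * (coords[, 2] + shape[2] * coords[, 3])
}

#' Node-selection configuration
#'
#' @param cube_edge Cube edge in voxels (odd; default 3, i.e. 6 mm on the
#'   expected 2-mm grid).
#' @param gm_threshold Gray-matter binarization threshold used when a
#'   probabilistic map is passed to [select_nodes()] directly.
#' @param limbic_ids Region ids of the limbic node set (bilateral amygdala
#'   and parahippocampal gyrus in the reference atlas) used for limbic
#'   strength.
#' @param include_list Optional explicit region-id include list that
#'   overrides rule-based selection (e.g. a published final node list).
#' @return A list of class `node_config`.
#' @export
node_config <- function(cube_edge = 3L, gm_threshold = 0.3,
                        limbic_ids = NULL, include_list = NULL) {
  structure(
    list(cube_edge = as.integer(cube_edge), gm_threshold = gm_threshold,
         limbic_ids = if (!is.null(limbic_ids)) as.integer(limbic_ids),
         include_list = if (!is.null(include_list)) as.integer(include_list)),
    class = "node_config"
  )
}

#' Select network nodes from an atlas and a gray-matter mask
#'
#' Places one cube per atlas region at the region center and applies the two
#' inclusion rules: (a) every cube voxel lies inside the binarized
#' gray-matter mask (and inside the image), and (b) the cube overlaps no
#' other region's cube. Rule (a) is checked first, so a node failing both is
#' recorded as `gm_coverage`. Overlap excludes *both* regions involved,
#' making the selection independent of region enumeration order.
#'
#' @param labels A [label_image()].
#' @param gm_mask A logical array from [binarize_gm()], or a [voxel_image()]
#'   probability map (binarized at `config$gm_threshold`).
#' @param config A [node_config()].
#' @return An object of class `node_set`: list with `nodes` (data underlying
#'   one [as.data.frame.node_set()] row per region), `cubes` (named list of
#'   voxel-coordinate matrices), `limbic_ids`, `cube_edge`, `grid_spacing`.
#' @export
select_nodes <- function(labels, gm_mask, config = node_config()) {
  stopifnot(inherits(labels, "label_image"), inherits(config, "node_config"))
  if (inherits(gm_mask, "voxel_image")) {
    gm_mask <- binarize_gm(gm_mask, config$gm_threshold)
  }
  check_same_grid(labels, gm_mask, "labels and gray-matter mask")
  ids <- labels$region_ids
  if (length(ids) == 0L) stop("atlas contains no regions")
  shape <- dim(labels$labels)
  if (!isTRUE(all.equal(labels$grid_spacing, c(2, 2, 2), tolerance = 1e-6))) {
    side <- config$cube_edge * labels$grid_spacing
    warning(sprintf(
      "grid spacing is %s mm, not the expected 2 mm; node cubes are %s mm",
      paste(format(labels$grid_spacing), collapse = "x"),
      paste(format(side), collapse = "x")))
  }

  n <- length(ids)
  centers <- matrix(NA_integer_, n, 3)
  cubes <- vector("list", n)
  gm_ok <- logical(n)
  for (i in seq_len(n)) {
    centers[i, ] <- region_center(labels, ids[i])
    cube <- cube_voxels(centers[i, ], config$cube_edge, shape)
    cubes[[i]] <- cube
    oob <- attr(cube, "out_of_bounds")
    gm_ok[i] <- !any(oob) && all(gm_mask[cube_linear_index(cube, shape)])
  }

  # symmetric overlap: any shared voxel between two cubes excludes both
  lin <- lapply(cubes, cube_linear_index, shape = shape)
  all_lin <- unlist(lin, use.names = FALSE)
  dup_vox <- unique(all_lin[duplicated(all_lin)])
  overlaps <- vapply(lin, function(v) any(v %in% dup_vox), logical(1))

  reason <- rep("none", n)
  reason[!gm_ok] <- "gm_coverage"
  reason[gm_ok & overlaps] <- "overlap"
  included <- gm_ok & !overlaps

  if (!is.null(config$include_list)) {
    # explicit include list overrides the rules; reasons are still reported
    included <- ids %in% config$include_list
  }

  nm <- if (!is.null(labels$names)) unname(labels$names[as.character(ids)])
        else paste0("region_", ids)
  nodes <- data.frame(
    region_id = ids, name = nm,
    center_x = centers[, 1], center_y = centers[, 2], center_z = centers[, 3],
    included = included, exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
  limbic <- config$limbic_ids
  structure(
    list(nodes = nodes, cubes = stats::setNames(cubes, ids),
         limbic_ids = limbic, cube_edge = config$cube_edge,
         grid_spacing = labels$grid_spacing, shape = shape),
    class = "node_set"
  )
}

#' @export
print.node_set <- function(x, ...) {
  cat(sprintf("<node_set> %d regions, %d included (%s-voxel cubes)\n",
              nrow(x$nodes), sum(x$nodes$included), x$cube_edge))
  excl <- table(x$nodes$exclusion_reason[!x$nodes$included])
  if (length(excl)) {
    cat("excluded:", paste(names(excl), excl, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.node_set <- function(x, ...) x$nodes

#' Region ids of the included nodes, in atlas order
#' @param node_set A `node_set`.
#' @return Integer vector.
#' @export
included_ids <- function(node_set) {
  stopifnot(inherits(node_set, "node_set"))
  node_set$nodes$region_id[node_set$nodes$included]
}

#' Write / read a node table as TSV
#'
#' @param node_set A `node_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(node_set, path) {
  utils::write.table(as.data.frame(node_set), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a regional profile of node-mean SUVRs
#'
#' The node value is the arithmetic mean of the SUVR over the cube's voxels
#' (27 for the default 3x3x3 cube); these means are the inputs to the
#' network weighting.
#'
#' @param suvr A [voxel_image()] on the node grid.
#' @param node_set A `node_set` from [select_nodes()].
#' @param subject_id Subject identifier carried through the pipeline.
#' @return An object of class `regional_profile`: list with `subject_id`,
#'   `node_ids` and `values` (one mean per included node, in node order).
#' @export
extract_profile <- function(suvr, node_set, subject_id = "subject") {
  stopifnot(inherits(suvr, "voxel_image"), inherits(node_set, "node_set"))
  if (!identical(dim(suvr$values), as.integer(node_set$shape))) {
    stop("SUVR image shape does not match the node-set geometry")
  }
  ids <- included_ids(node_set)
  shape <- node_set$shape
  vals <- vapply(as.character(ids), function(id) {
    vox <- suvr$values[cube_linear_index(node_set$cubes[[id]], shape)]
    if (any(!is.finite(vox))) {
      stop("non-finite voxel inside the cube of node ", id)
    }
    mean(vox)
  }, numeric(1))
  regional_profile(unname(vals), node_ids = ids, subject_id = subject_id)
}

#' Construct a regional profile directly from node means
#'
#' @param values Numeric vector of node-mean SUVRs.
#' @param node_ids Integer node/region ids, parallel to `values`.
#' @param subject_id Subject identifier.
#' @return An object of class `regional_profile`.
#' @export
regional_profile <- function(values, node_ids = seq_along(values),
                             subject_id = "subject") {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("profile values must be finite")
  if (length(node_ids) != length(values)) {
    stop("`node_ids` and `values` lengths differ")
  }
  structure(
    list(subject_id = as.character(subject_id),
         node_ids = as.integer(node_ids), values = values),
    class = "regional_profile"
  )
}

#' @export
print.regional_profile <- function(x, ...) {
  cat(sprintf("<regional_profile> %s: %d nodes, mean %.3f\n",
              x$subject_id, length(x$values), mean(x$values)))
  invisible(x)
}
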