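#' Build a synthetic atlas phantom
#'
#' Packs `k` disjoint cuboid regions (each large enough to host the default
#' 3x3x3 node cube, with at least one voxel of margin between regions and
#' the image border) onto a regular lattice of candidate slots, picks `k`
#' slots at random, and assigns each region a tau tier: the first four are
#' limbic (standing in for bilateral amygdala/parahippocampus), the rest
#' split between temporal and isocortical, with optional off-target regions
#' that never accumulate tau. The gray-matter probability is 1 inside the
#' regions and `gm_background` elsewhere.
#'
#' @param grid Image dimensions in voxels (default 40^3 at 2 mm).
#' @param k Number of regions.
#' @param region_edge Cuboid edge in voxels (>= 3; default 7).
#' @param seed Integer seed; the atlas is deterministic given the seed.
#' @param gm_background Gray-matter probability outside the regions.
#' @param n_off_target Number of trailing regions assigned the off-target
#'   tier (amplitude 0 under the default simulation).
#' @return An object of class `phantom_atlas`: list with `labels`
#'   ([label_image()]), `gm_prob` ([voxel_image()]), `tiers` (named
#'   character vector, region id -> tier), `limbic_ids`, `seed`.
#' @export
make_phantom_atlas <- function(grid = c(40, 40, 40), k = 8, region_edge = 7,
                               seed = 1, gm_background = 0,
                               n_off_target = 0) {
  grid <- as.integer(grid)
  k <- as.integer(k)
  region_edge <- as.integer(region_edge)
  stopifnot(length(grid) == 3L, k >= 2L, region_edge >= 3L,
            n_off_target >= 0L, n_off_target <= k - 4L || n_off_target == 0L)
  stride <- region_edge + 1L            # 1-voxel gap between adjacent slots
  starts <- lapply(grid, function(g) {
    if (g - 1L - region_edge < 1L) return(integer(0))
    seq.int(1L, g - 1L - region_edge, by = stride)
  })
  n_slots <- prod(lengths(starts))
  if (n_slots < k) {
    stop(sprintf("grid %s cannot host %d disjoint regions of edge %d",
                 paste(grid, collapse = "x"), k, region_edge))
  }
  slots <- as.matrix(expand.grid(starts[[1]], starts[[2]], starts[[3]]))
  pick <- with_local_seed(seed, sort(sample.int(n_slots, k)))

  labels <- array(0L, dim = grid)
  for (i in seq_len(k)) {
    s <- slots[pick[i], ]
    labels[(s[1] + 1):(s[1] + region_edge),
           (s[2] + 1):(s[2] + region_edge),
           (s[3] + 1):(s[3] + region_edge)] <- i   # 0-based starts -> R index
  }

  n_limbic <- min(4L, k)
  n_rest <- k - n_limbic - n_off_target
  tiers <- c(rep("limbic", n_limbic),
             rep("temporal", ceiling(n_rest / 2)),
             rep("isocortical", floor(n_rest / 2)),
             rep("off_target", n_off_target))
  names(tiers) <- seq_len(k)
  region_names <- paste0(tiers, "_", stats::ave(seq_len(k), tiers,
                                                FUN = seq_along))
  gm <- array(gm_background, dim = grid)
  gm[labels > 0L] <- 1

  structure(
    list(labels = label_image(labels, names = region_names),
         gm_prob = voxel_image(gm),
         tiers = tiers,
         limbic_ids = as.integer(names(tiers)[tiers == "limbic"]),
         region_edge = region_edge, seed = as.integer(seed)),
    class = "phantom_atlas"
  )
}

#' @export
print.phantom_atlas <- function(x, ...) {
  cat(sprintf("<phantom_atlas> %s voxels, %d regions (%s)\n",
              paste(dim(x$labels$labels), collapse = "x"),
              length(x$tiers),
              paste(names(table(x$tiers)), table(x$tiers), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Simulation settings for synthetic tau cohorts
#'
#' Regional tau follows an additive hinge model of a latent severity
#' `s in [0, 1]`: a region in tier `t` has mean SUVR
#' `baseline + amplitude_t * max(0, s - onset_t)` plus regional measurement
#' noise, with onsets ordered limbic < temporal < isocortical so that tau
#' appears first in limbic regions and spreads outward as severity grows.
#' Defaults keep SUVR in a realistic 1-3.5 range.
#'
#' @param n_subjects Cohort size (default 50).
#' @param severity_range Range of the uniform severity distribution.
#' @param onsets Named severity onsets per tier (strictly increasing over
#'   limbic, temporal, isocortical; off_target never activates).
#' @param amplitudes Named SUVR amplitudes per tier at `s = 1 + onset`.
#' @param baseline_mean,baseline_sd Subject-level baseline SUVR and its
#'   between-subject spread.
#' @param noise_sd Regional measurement noise (SUVR).
#' @param seed Integer seed recorded in the output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 50, severity_range = c(0, 1),
                       onsets = c(limbic = 0, temporal = 0.35,
                                  isocortical = 0.7),
                       amplitudes = c(limbic = 2.5, temporal = 2,
                                      isocortical = 1.5, off_target = 0),
                       baseline_mean = 1, baseline_sd = 0.05,
                       noise_sd = 0.05, seed = 1) {
  stopifnot(n_subjects >= 1, baseline_sd >= 0, noise_sd >= 0,
            all(c("limbic", "temporal", "isocortical") %in% names(onsets)))
  ord <- onsets[c("limbic", "temporal", "isocortical")]
  if (any(diff(ord) <= 0)) stop("tier onsets must satisfy limbic < temporal < isocortical")
  structure(
    list(n_subjects = as.integer(n_subjects),
         severity_range = severity_range, onsets = onsets,
         amplitudes = amplitudes, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a cohort of regional tau profiles
#'
#' Draws per-subject severities (uniform over `config$severity_range`
#' unless given explicitly) and evaluates the hinge accumulation model of
#' [sim_config()] for every atlas region.
#'
#' @param atlas A [make_phantom_atlas()] phantom.
#' @param config A [sim_config()].
#' @param severities Optional explicit severities (overrides the random
#'   draw; length becomes the cohort size).
#' @return A list of class `sim_cohort`: `means` (subjects x regions matrix
#'   of planted regional SUVR means), `severities`, `config`, `atlas_seed`.
#' @export
simulate_profiles <- function(atlas, config = sim_config(),
                              severities = NULL) {
  stopifnot(inherits(atlas, "phantom_atlas"), inherits(config, "sim_config"))
  ids <- atlas$labels$region_ids
  tiers <- atlas$tiers[as.character(ids)]
  onset <- config$onsets[tiers]
  onset[is.na(onset)] <- Inf             # off-target never activates
  amp <- config$amplitudes[tiers]
  amp[is.na(amp)] <- 0

  with_local_seed(config$seed, {
    if (is.null(severities)) {
      severities <- stats::runif(config$n_subjects,
                                 config$severity_range[1],
                                 config$severity_range[2])
    }
    n <- length(severities)
    means <- matrix(NA_real_, n, length(ids),
                    dimnames = list(sprintf("sub_%03d", seq_len(n)), ids))
    for (i in seq_len(n)) {
      base_i <- config$baseline_mean + stats::rnorm(1, 0, config$baseline_sd)
      hinge <- pmax(0, severities[i] - onset)
      means[i, ] <- base_i + amp * hinge +
        stats::rnorm(length(ids), 0, config$noise_sd)
    }
    structure(
      list(means = means, severities = severities, config = config,
           atlas_seed = atlas$seed),
      class = "sim_cohort"
    )
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d subjects x %d regions, severity %.2f-%.2f\n",
              nrow(x$means), ncol(x$means), min(x$severities),
              max(x$severities)))
  invisible(x)
}

#' Regional profiles of a simulated cohort
#'
#' @param cohort A `sim_cohort`.
#' @return List of [regional_profile()] objects (planted regional means,
#'   i.e. the noise-free node values a perfect extraction would recover).
#' @export
cohort_profiles <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  ids <- as.integer(colnames(cohort$means))
  lapply(seq_len(nrow(cohort$means)), function(i) {
    regional_profile(cohort$means[i, ], node_ids = ids,
                     subject_id = rownames(cohort$means)[i])
  })
}

#' Render a regional profile into a phantom image
#'
#' Fills each atlas region with its planted mean plus independent voxel
#' noise; everything outside the regions sits at a non-specific background
#' level.
#'
#' @param profile A [regional_profile()] whose node ids match the atlas
#'   region ids.
#' @param atlas A [make_phantom_atlas()] phantom.
#' @param voxel_noise_sd Voxelwise Gaussian noise (SUVR), default 0.
#' @param seed Integer seed; rendering is deterministic given the seed.
#' @param background Non-specific background value (default 1).
#' @return A [voxel_image()] flagged as SUVR.
#' @export
render_image <- function(profile, atlas, voxel_noise_sd = 0, seed = 1,
                         background = 1) {
  stopifnot(inherits(profile, "regional_profile"),
            inherits(atlas, "phantom_atlas"))
  ids <- atlas$labels$region_ids
  if (!setequal(profile$node_ids, ids)) {
    stop("profile node ids do not match the atlas regions")
  }
  labels <- atlas$labels$labels
  img <- array(background, dim = dim(labels))
  with_local_seed(seed, {
    for (j in seq_along(profile$node_ids)) {
      sel <- which(labels == profile$node_ids[j])
      img[sel] <- profile$values[j] +
        stats::rnorm(length(sel), 0, voxel_noise_sd)
    }
  })
  voxel_image(img, grid_spacing = atlas$gm_prob$grid_spacing, suvr = TRUE)
}

#' Write a simulated cohort to disk
#'
#' Writes the planted regional means and severities as CSV plus a JSON
#' sidecar echoing the simulation settings.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof_path <- file.path(dir, "profiles.csv")
  df <- data.frame(subject_id = rownames(cohort$means),
                   severity = cohort$severities,
                   cohort$means, check.names = FALSE)
  utils::write.csv(df, prof_path, row.names = FALSE)
  cfg_path <- file.path(dir, "sim_config.json")
  jsonlite::write_json(unclass(cohort$config), cfg_path, digits = NA,
                       auto_unbox = TRUE)
  invisible(c(profiles = prof_path, config = cfg_path))
}
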