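#' Published staging thresholds
#'
#' The fixed decision thresholds of the four-stage scheme: limbic strength
#' splits the cohort at 14.463 (stages 1-2 vs 3-4) and at 9.867 (stage 1 vs
#' 2); global efficiency splits the high-limbic branch at 0.901 (stage 3 vs
#' 4). Values at a threshold go to the lower branch (`<=` convention).
#'
#' @param limbic_high Limbic-strength split between stages 1-2 and 3-4.
#' @param limbic_low Limbic-strength split between stage 1 and 2.
#' @param efficiency Global-efficiency split between stage 3 and 4.
#' @return A list of class `stage_thresholds`.
#' @export
stage_thresholds <- function(limbic_high = 14.463, limbic_low = 9.867,
                             efficiency = 0.901) {
  stopifnot(is.finite(limbic_high), is.finite(limbic_low),
            is.finite(efficiency), limbic_low <= limbic_high)
  structure(list(limbic_high = limbic_high, limbic_low = limbic_low,
                 efficiency = efficiency),
            class = "stage_thresholds")
}

#' Assign ordinal tau stages by fixed thresholds
#'
#' Maps limbic strength and global efficiency to stages 1-4:
#' limbic <= `limbic_low` is stage 1, limbic in (`limbic_low`,
#' `limbic_high`] is stage 2; above `limbic_high`, efficiency <=
#' `efficiency` is stage 3, otherwise stage 4. Total on finite inputs:
#' every (limbic, efficiency) pair maps to exactly one stage.
#'
#' @param measures A [network_measures()] object, a data frame with columns
#'   `limbic_strength` and `global_efficiency`, or a numeric vector of
#'   limbic strengths.
#' @param efficiency Numeric vector of global efficiencies (only when
#'   `measures` is a bare numeric vector).
#' @param thresholds A [stage_thresholds()].
#' @return Integer vector of stages in 1..4.
#' @export
stage_by_thresholds <- function(measures, efficiency = NULL,
                                thresholds = stage_thresholds()) {
  stopifnot(inherits(thresholds, "stage_thresholds"))
  if (inherits(measures, "network_measures")) {
    limbic <- measures$limbic_strength
    efficiency <- measures$global_efficiency
  } else if (is.data.frame(measures)) {
    need <- c("limbic_strength", "global_efficiency")
    miss <- setdiff(need, names(measures))
    if (length(miss)) stop("missing measure column(s): ",
                           paste(miss, collapse = ", "))
    limbic <- measures$limbic_strength
    efficiency <- measures$global_efficiency
  } else {
    limbic <- as.numeric(measures)
    if (is.null(efficiency)) stop("`efficiency` is required with numeric input")
  }
  if (length(limbic) != length(efficiency)) {
    stop("limbic strength and efficiency lengths differ")
  }
  if (any(!is.finite(limbic)) || any(!is.finite(efficiency))) {
    stop("staging needs finite limbic strength and global efficiency")
  }
  th <- thresholds
  ifelse(limbic <= th$limbic_high,
         ifelse(limbic <= th$limbic_low, 1L, 2L),
         ifelse(efficiency <= th$efficiency, 3L, 4L))
}

# ---------------------------------------------------------------------------
# Conditional-inference tree (simplified)
# ---------------------------------------------------------------------------

# run `expr` under a private RNG stream; the global .Random.seed is restored
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Fit a threshold tree by permutation-based recursive partitioning
#'
#' A simplified conditional-inference tree for numeric features and a
#' numeric (or ordinal) response. At each node every feature's association
#' with the response is scored by the absolute Spearman rank correlation;
#' its p-value comes from a joint permutation null (the same `n_perm`
#' response permutations are reused across features) and is
#' Bonferroni-corrected over the non-degenerate features. If the smallest
#' corrected p-value exceeds `alpha`, or the node is smaller than
#' `2 * min_node`, the node becomes a leaf. Otherwise the winning feature is
#' split at the cutpoint maximizing the standardized two-sample rank-sum
#' statistic, subject to both children holding at least `min_node` rows.
#' Leaves are numbered into stages 1..K by ascending mean of the *first*
#' feature, so with limbic strength first the stages follow tau severity.
#'
#' This learner follows the conditional-inference recipe (association test,
#' multiplicity-corrected stopping, best-cut search) but is not bit-identical
#' to the partykit implementation, which uses asymptotic influence-function
#' statistics.
#'
#' @param features Data frame of numeric candidate split variables (at
#'   least one column; column order fixes the stage-numbering feature).
#' @param response Numeric or ordered vector, one value per row.
#' @param alpha Significance level for the (corrected) association test.
#' @param min_node Minimum rows per child node (default 20).
#' @param n_perm Number of response permutations (default 9999).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return An object of class `stage_tree`: list with the recursive `tree`
#'   (split nodes: `var`, `threshold`, `p_adjusted`; leaves: `stage`, `n`),
#'   `n_stages`, `features`, and the call parameters.
#' @export
fit_stage_tree <- function(features, response, alpha = 0.05, min_node = 20L,
                           n_perm = 9999L, seed = 1L) {
  features <- as.data.frame(features)
  if (ncol(features) < 1L) stop("at least one feature is required")
  if (!all(vapply(features, is.numeric, logical(1)))) {
    stop("all features must be numeric")
  }
  if (is.ordered(response) || is.factor(response)) {
    response <- as.numeric(response)
  }
  response <- as.numeric(response)
  n <- nrow(features)
  if (length(response) != n) stop("response length must match feature rows")
  if (any(!is.finite(response)) ||
      any(!vapply(features, function(x) all(is.finite(x)), logical(1)))) {
    stop("features and response must be finite")
  }
  min_node <- as.integer(min_node)

  grow <- function(idx) {
    n_i <- length(idx)
    y <- response[idx]
    if (n_i < 2L * min_node || length(unique(y)) < 2L) {
      return(list(type = "leaf", n = n_i,
                  mean_first = mean(features[[1L]][idx])))
    }
    ry <- rank(y)
    ry_std <- (ry - mean(ry)) / stats::sd(ry)
    usable <- vapply(features, function(x) length(unique(x[idx])) > 1L,
                     logical(1))
    if (!any(usable)) {
      return(list(type = "leaf", n = n_i,
                  mean_first = mean(features[[1L]][idx])))
    }
    if (any(!usable)) {
      message("skipping constant feature(s) at a node: ",
              paste(names(features)[!usable], collapse = ", "))
    }
    use <- which(usable)
    rx <- vapply(use, function(j) {
      r <- rank(features[[j]][idx])
      (r - mean(r)) / stats::sd(r)
    }, numeric(n_i))                          # n_i x m, standardized ranks
    obs <- abs(crossprod(rx, ry_std)) / (n_i - 1)   # |Spearman rho| per feature
    perm <- vapply(seq_len(n_perm), function(b) sample.int(n_i),
                   integer(n_i))
    null <- abs(crossprod(rx, matrix(ry_std[perm], n_i, n_perm))) / (n_i - 1)
    p_raw <- (1 + rowSums(null >= as.vector(obs))) / (n_perm + 1)
    p_adj <- pmin(1, p_raw * length(use))
    if (min(p_adj) > alpha) {
      return(list(type = "leaf", n = n_i,
                  mean_first = mean(features[[1L]][idx])))
    }
    best <- which(p_adj == min(p_adj))
    if (length(best) > 1L) best <- best[which.max(obs[best])]
    j_star <- use[best]
    cut <- best_cutpoint(features[[j_star]][idx], ry, min_node)
    if (is.null(cut)) {
      return(list(type = "leaf", n = n_i,
                  mean_first = mean(features[[1L]][idx])))
    }
    go_left <- features[[j_star]][idx] <= cut
    list(type = "split", var = names(features)[j_star], threshold = cut,
         p_adjusted = p_adj[[best]], n = n_i,
         left = grow(idx[go_left]), right = grow(idx[!go_left]))
  }

  tree <- with_local_seed(seed, grow(seq_len(n)))
  tree <- number_leaves(tree)
  structure(
    list(tree = tree$node, n_stages = tree$n_leaves,
         features = names(features), alpha = alpha, min_node = min_node,
         n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "stage_tree"
  )
}

# best cut of x against response ranks ry: maximize the standardized
# two-sample rank-sum statistic over admissible cutpoints (>= min_node per
# child, never between tied x values); ties in the statistic go to the
# smallest threshold. Returns NULL when no admissible cut exists.
best_cutpoint <- function(x, ry, min_node) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  rys <- ry[ord]
  csum <- cumsum(rys)
  k <- seq_len(n - 1L)
  admissible <- k >= min_node & k <= n - min_node & xs[k] < xs[k + 1L]
  if (!any(admissible)) return(NULL)
  mu_y <- mean(ry)
  var_y <- mean((ry - mu_y)^2)
  nl <- k[admissible]
  s <- csum[admissible]
  stat <- abs(s - nl * mu_y) / sqrt(nl * (n - nl) / (n - 1) * var_y)
  pick <- which.max(stat)            # first maximum = smallest threshold
  kk <- nl[pick]
  (xs[kk] + xs[kk + 1L]) / 2
}

# assign stages 1..K to leaves by ascending mean of the first feature
number_leaves <- function(node) {
  means <- numeric(0)
  collect <- function(nd) {
    if (nd$type == "leaf") means[length(means) + 1L] <<- nd$mean_first
    else { collect(nd$left); collect(nd$right) }
  }
  collect(node)
  stages <- rank(means, ties.method = "first")
  i <- 0L
  relabel <- function(nd) {
    if (nd$type == "leaf") {
      i <<- i + 1L
      nd$stage <- as.integer(stages[i])
    } else {
      nd$left <- relabel(nd$left)
      nd$right <- relabel(nd$right)
    }
    nd
  }
  list(node = relabel(node), n_leaves = length(means))
}

#' @export
print.stage_tree <- function(x, ...) {
  cat(sprintf("<stage_tree> %d stages, alpha %.3g, %d permutations\n",
              x$n_stages, x$alpha, x$n_perm))
  show <- function(nd, indent) {
    pad <- strrep("  ", indent)
    if (nd$type == "leaf") {
      cat(sprintf("%sstage %d (n=%d)\n", pad, nd$stage, nd$n))
    } else {
      cat(sprintf("%s%s <= %.4g (p=%.3g)\n", pad, nd$var, nd$threshold,
                  nd$p_adjusted))
      show(nd$left, indent + 1L)
      cat(sprintf("%s%s > %.4g\n", pad, nd$var, nd$threshold))
      show(nd$right, indent + 1L)
    }
  }
  show(x$tree, 1L)
  invisible(x)
}

#' Predict stages from a fitted threshold tree
#'
#' @param object A `stage_tree`.
#' @param newdata Data frame containing the tree's feature columns.
#' @param ... Unused.
#' @return Integer vector of stages.
#' @export
predict.stage_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) stop("newdata lacks feature column(s): ",
                         paste(miss, collapse = ", "))
  one <- function(nd, row) {
    if (nd$type == "leaf") return(nd$stage)
    if (row[[nd$var]] <= nd$threshold) one(nd$left, row) else one(nd$right, row)
  }
  vapply(seq_len(nrow(newdata)),
         function(i) one(object$tree, newdata[i, , drop = FALSE]),
         integer(1))
}

#' Collect the split thresholds of a fitted tree
#'
#' @param object A `stage_tree`.
#' @return Data frame with columns `var`, `threshold`, `n`, `p_adjusted` in
#'   depth-first order.
#' @export
tree_splits <- function(object) {
  stopifnot(inherits(object, "stage_tree"))
  out <- list()
  walk <- function(nd) {
    if (nd$type == "split") {
      out[[length(out) + 1L]] <<- data.frame(
        var = nd$var, threshold = nd$threshold, n = nd$n,
        p_adjusted = nd$p_adjusted, stringsAsFactors = FALSE)
      walk(nd$left); walk(nd$right)
    }
  }
  walk(object$tree)
  if (length(out)) do.call(rbind, out) else
    data.frame(var = character(0), threshold = numeric(0), n = integer(0),
               p_adjusted = numeric(0))
}

#' Serialize a fitted stage tree to JSON
#'
#' @param object A `stage_tree`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_stage_tree_json <- function(object, path) {
  stopifnot(inherits(object, "stage_tree"))
  jsonlite::write_json(unclass(object), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Per-stage mean profiles and mean nodal strengths
#'
#' Averages the regional profiles and the nodal-strength vectors of the
#' subjects assigned to each stage — the tabular counterpart of stage-mean
#' tau images. Empty stages are reported as all-`NA` rows rather than
#' dropped.
#'
#' @param profiles List of [regional_profile()] objects over the same nodes.
#' @param assignments Integer stage per profile, or a data frame with
#'   columns `subject_id` and `stage`.
#' @param n_stages Number of stages to report (default: the largest
#'   assigned stage).
#' @return A list of class `stage_summary`: `profile_means` and
#'   `strength_means` (stage x node matrices) and `n` (subjects per stage).
#' @export
stage_summary <- function(profiles, assignments,
                          n_stages = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  if (is.data.frame(assignments)) {
    ids <- vapply(profiles, `[[`, character(1), "subject_id")
    m <- match(ids, assignments$subject_id)
    if (any(is.na(m))) stop("unassigned subject(s): ",
                            paste(ids[is.na(m)], collapse = ", "))
    stage <- as.integer(assignments$stage[m])
  } else {
    stage <- as.integer(assignments)
    if (length(stage) != length(profiles)) {
      stop("one stage assignment per profile is required")
    }
  }
  if (any(is.na(stage))) stop("every subject must be assigned a stage")
  if (is.null(n_stages)) n_stages <- max(stage)
  node_ids <- profiles[[1L]]$node_ids
  prof_mat <- t(vapply(profiles, function(p) {
    if (!identical(p$node_ids, node_ids)) stop("profiles have mismatched nodes")
    p$values
  }, numeric(length(node_ids))))
  str_mat <- t(vapply(profiles,
                      function(p) unname(nodal_strength(build_network(p))),
                      numeric(length(node_ids))))
  agg <- function(mat) {
    out <- matrix(NA_real_, n_stages, ncol(mat),
                  dimnames = list(paste0("stage_", seq_len(n_stages)),
                                  node_ids))
    for (s in seq_len(n_stages)) {
      rows <- which(stage == s)
      if (length(rows)) out[s, ] <- colMeans(mat[rows, , drop = FALSE])
    }
    out
  }
  structure(
    list(profile_means = agg(prof_mat), strength_means = agg(str_mat),
         n = tabulate(stage, nbins = n_stages)),
    class = "stage_summary"
  )
}

#' @export
print.stage_summary <- function(x, ...) {
  cat(sprintf("<stage_summary> %d stages, n = %s\n",
              length(x$n), paste(x$n, collapse = "/")))
  invisible(x)
}
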