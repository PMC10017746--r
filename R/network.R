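#' Build the individualized tau network
#'
#' Edge weights are absolute differences of node-mean SUVRs,
#' `w_ij = |x_i - x_j|`: a large weight marks a pair of regions with very
#' different tau burden. The network is weighted, undirected and fully
#' connected by construction (up to zero-weight edges between nodes with
#' identical means).
#'
#' @param profile A [regional_profile()] with at least two nodes.
#' @return An object of class `tau_network`: list with `node_ids` and the
#'   symmetric nonnegative `weights` matrix (zero diagonal).
#' @export
build_network <- function(profile) {
  stopifnot(inherits(profile, "regional_profile"))
  x <- profile$values
  if (length(x) < 2L) stop("a network needs at least 2 nodes")
  w <- abs(outer(x, x, "-"))
  diag(w) <- 0
  dimnames(w) <- list(profile$node_ids, profile$node_ids)
  structure(list(node_ids = profile$node_ids, weights = w),
            class = "tau_network")
}

#' @export
print.tau_network <- function(x, ...) {
  cat(sprintf("<tau_network> %d nodes, mean weight %.4f\n",
              length(x$node_ids), mean(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

#' Direct network distances from edge weights
#'
#' The network distance between two nodes is the inverse of the edge
#' weight, so a larger tau difference means a shorter distance. Zero-weight
#' edges (identical node means) get an infinite direct distance; the
#' diagonal stays zero.
#'
#' @param net A `tau_network`.
#' @return A square matrix of direct distances (may contain `Inf`).
#' @export
weights_to_distances <- function(net) {
  stopifnot(inherits(net, "tau_network"))
  w <- net$weights
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  d
}

#' All-pairs shortest path lengths
#'
#' Shortest path length `d_ij` is the minimum network distance between two
#' nodes over direct and indirect routes: whenever
#' `d_ij > d_ik + d_kj`, the indirect route replaces the direct one.
#' Computed by Dijkstra from every source by default; the Floyd-Warshall
#' route is provided as an algorithmically independent alternative and the
#' two must agree.
#'
#' @param direct Square matrix of nonnegative direct distances with zero
#'   diagonal (`Inf` allowed), e.g. from [weights_to_distances()].
#' @param method `"dijkstra"` (default) or `"floyd"`.
#' @return Matrix of shortest path lengths; unreachable pairs stay `Inf`.
#' @export
shortest_paths <- function(direct, method = c("dijkstra", "floyd")) {
  method <- match.arg(method)
  d <- as.matrix(direct)
  if (nrow(d) != ncol(d)) stop("direct distance matrix must be square")
  if (any(is.na(d)) || any(d < 0)) {
    stop("direct distances must be nonnegative (Inf allowed)")
  }
  if (any(diag(d) != 0)) stop("direct distance matrix must have zero diagonal")
  out <- if (method == "dijkstra") dijkstra_all(d) else floyd_warshall(d)
  dimnames(out) <- dimnames(d)
  out
}

# dense-graph Dijkstra from every source; O(n^3) total, n <= ~100 here
dijkstra_all <- function(d) {
  n <- nrow(d)
  out <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    todo <- rep(TRUE, n)
    for (k in seq_len(n)) {
      u <- which.min(replace(dist, !todo, Inf))
      if (!is.finite(dist[u]) || !todo[u]) break
      todo[u] <- FALSE
      alt <- dist[u] + d[u, ]
      upd <- todo & alt < dist
      dist[upd] <- alt[upd]
    }
    out[s, ] <- dist
  }
  diag(out) <- 0
  out
}

floyd_warshall <- function(d) {
  n <- nrow(d)
  for (k in seq_len(n)) {
    via <- outer(d[, k], d[k, ], "+")  # Inf-safe
    d <- pmin(d, via)
  }
  diag(d) <- 0
  d
}

#' Nodal strength
#'
#' The strength of a node is the sum of all edge weights incident to it,
#' `s_i = sum_j w_ij`.
#'
#' @param net A `tau_network`.
#' @return Named numeric vector of nodal strengths.
#' @export
nodal_strength <- function(net) {
  stopifnot(inherits(net, "tau_network"))
  stats::setNames(rowSums(net$weights), net$node_ids)
}

#' Weighted global efficiency
#'
#' The average inverse shortest path length over all ordered node pairs,
#' `E = (1/n) * sum_i sum_{j != i} (1/d_ij) / (n - 1)`, with network
#' distance the inverse edge weight. Pairs that remain unreachable (zero
#' weight and no finite indirect route) contribute 0, the usual
#' weighted-efficiency convention.
#'
#' @param net A `tau_network`.
#' @param paths Optional precomputed shortest-path matrix (to avoid
#'   recomputation); must come from this network.
#' @return Scalar efficiency on the SUVR-difference scale.
#' @export
global_efficiency <- function(net, paths = NULL) {
  stopifnot(inherits(net, "tau_network"))
  n <- length(net$node_ids)
  if (n < 2L) stop("efficiency needs at least 2 nodes")
  if (is.null(paths)) paths <- shortest_paths(weights_to_distances(net))
  inv <- 1 / paths
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Strength and efficiency summary of one subject's network
#'
#' Bundles the three headline measures: global efficiency, global strength
#' (mean nodal strength over all nodes) and limbic strength (mean nodal
#' strength over the limbic node set, classically the bilateral amygdala and
#' parahippocampal gyrus).
#'
#' @param profile A [regional_profile()].
#' @param node_set Optional `node_set` carrying `limbic_ids`.
#' @param limbic_ids Limbic region ids; overrides `node_set$limbic_ids`.
#'   When neither is available, limbic strength is `NA`.
#' @return An object of class `network_measures`: list with
#'   `global_efficiency`, `global_strength`, `limbic_strength`,
#'   `nodal_strengths`, `subject_id`.
#' @export
network_measures <- function(profile, node_set = NULL, limbic_ids = NULL) {
  stopifnot(inherits(profile, "regional_profile"))
  if (is.null(limbic_ids) && !is.null(node_set)) {
    limbic_ids <- node_set$limbic_ids
  }
  net <- build_network(profile)
  s <- nodal_strength(net)
  eff <- global_efficiency(net)
  limbic <- NA_real_
  if (!is.null(limbic_ids)) {
    missing <- setdiff(limbic_ids, profile$node_ids)
    if (length(missing)) {
      stop("limbic node(s) not present in the profile: {",
           paste(missing, collapse = ", "), "}")
    }
    limbic <- mean(s[as.character(limbic_ids)])
  }
  structure(
    list(global_efficiency = eff, global_strength = mean(s),
         limbic_strength = limbic, nodal_strengths = s,
         subject_id = profile$subject_id),
    class = "network_measures"
  )
}

#' @export
print.network_measures <- function(x, ...) {
  cat(sprintf(
    "<network_measures> %s: efficiency %.4f, strength %.4f, limbic %.4f\n",
    x$subject_id, x$global_efficiency, x$global_strength, x$limbic_strength))
  invisible(x)
}

#' @export
as.data.frame.network_measures <- function(x, ...) {
  data.frame(subject_id = x$subject_id,
             global_efficiency = x$global_efficiency,
             global_strength = x$global_strength,
             limbic_strength = x$limbic_strength,
             stringsAsFactors = FALSE)
}

#' Serialize a network to JSON
#'
#' Writes node ids and the upper-triangle weights (row-major pairs).
#'
#' @param net A `tau_network`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "tau_network"))
  ut <- which(upper.tri(net$weights), arr.ind = TRUE)
  obj <- list(
    node_ids = net$node_ids,
    edges = data.frame(i = net$node_ids[ut[, 1]], j = net$node_ids[ut[, 2]],
                       weight = net$weights[ut])
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
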