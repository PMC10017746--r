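# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: shortest paths by exhaustive simple-path
# enumeration, AUC by explicit pair counting.

# exhaustive shortest paths over all simple paths (feasible for n <= 7)
enum_shortest_paths <- function(direct) {
  n <- nrow(direct)
  out <- matrix(Inf, n, n)
  diag(out) <- 0
  best_len <- function(cur, target, visited, len) {
    if (cur == target) return(len)
    b <- Inf
    for (nxt in which(!visited)) {
      step <- direct[cur, nxt]
      if (is.finite(step)) {
        v <- visited
        v[nxt] <- TRUE
        b <- min(b, best_len(nxt, target, v, len + step))
      }
    }
    b
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        visited <- rep(FALSE, n)
        visited[i] <- TRUE
        out[i, j] <- best_len(i, j, visited, 0)
      }
    }
  }
  out
}

# efficiency recomputed from first principles on a profile
enum_efficiency <- function(values) {
  w <- abs(outer(values, values, "-"))
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  sp <- enum_shortest_paths(d)
  inv <- 1 / sp
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- length(values)
  sum(inv) / (n * (n - 1))
}

# AUC by explicit concordant/tied pair counting
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# a tiny two-region label image with fully controllable geometry
make_two_region_labels <- function(shape = c(20, 20, 20),
                                   centers = list(c(5, 5, 5), c(14, 14, 14)),
                                   half = 2L, ids = c(1L, 2L)) {
  arr <- array(0L, dim = shape)
  for (i in seq_along(centers)) {
    ctr <- centers[[i]]
    arr[(ctr[1] - half + 1):(ctr[1] + half + 1),
        (ctr[2] - half + 1):(ctr[2] + half + 1),
        (ctr[3] - half + 1):(ctr[3] + half + 1)] <- ids[i]
  }
  label_image(arr)
}

full_gm <- function(shape = c(20, 20, 20)) {
  array(TRUE, dim = shape)
}
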