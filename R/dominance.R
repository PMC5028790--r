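# Percolation & Conductance core: directed pathway enumeration, triad
# transitivity, transitivity-weighted win imputation, Beta dyadic dominance
# probabilities, and per-animal dominance certainty.

#' Enumerate directed simple dominance pathways
#'
#' Counts, for every ordered pair of animals and every path length up to
#' `max_len`, the number of distinct directed simple paths (no repeated
#' node) in the win digraph.  An edge i -> j exists when animal i has beaten
#' animal j at least once.  Length-1 "paths" are the raw direct win counts
#' (direct evidence scales with the number of observations); lengths >= 2
#' count distinct routes through intermediaries.
#'
#' For `max_len <= 3` the counts are computed in closed form from powers of
#' the adjacency matrix with non-simple walks subtracted; longer paths fall
#' back to an exhaustive depth-first enumeration.
#'
#' @param W win/loss count matrix (square, zero diagonal).
#' @param max_len maximum path length (default 3).
#' @return a `pathway_counts` object: list with `ids`, `max_len`, and
#'   `counts`, an N x N x max_len array.
#' @export
enumerate_directed_paths <- function(W, max_len = 3) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (max_len < 1) stop("max_len must be >= 1")
  max_len <- as.integer(max_len)
  n <- nrow(W)
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  A <- (W > 0) * 1
  diag(A) <- 0
  counts <- array(0, dim = c(n, n, max_len),
                  dimnames = list(ids, ids, NULL))
  counts[, , 1] <- W
  if (max_len >= 2 && n >= 3) {
    if (max_len <= 3) {
      A2 <- A %*% A
      P2 <- A2
      diag(P2) <- 0
      counts[, , 2] <- P2
      if (max_len == 3) {
        d2 <- diag(A2)
        A3 <- A2 %*% A
        # subtract walks revisiting the source or the target; add back the
        # doubly-degenerate i->j->i->j walks
        P3 <- A3 - A * matrix(d2, n, n, byrow = TRUE) -
          matrix(d2, n, n) * A + A * t(A) * A
        diag(P3) <- 0
        counts[, , 3] <- P3
      }
    } else {
      counts[, , 2:max_len] <-
        count_simple_paths_dfs(A, max_len)[, , 2:max_len]
    }
  } else if (max_len >= 2 && n < 3) {
    # with two nodes only length-1 paths exist; nothing to add
  }
  structure(list(ids = ids, max_len = max_len, counts = counts),
            class = "pathway_counts")
}

# Exhaustive DFS enumeration of simple paths up to max_len.  Exact but
# exponential; intended for small networks or max_len > 3.
count_simple_paths_dfs <- function(A, max_len) {
  n <- nrow(A)
  out <- array(0, dim = c(n, n, max_len))
  adj <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  rec <- function(origin, path, last, len) {
    for (k in adj[[last]]) {
      if (k %in% path) next
      out[origin, k, len] <<- out[origin, k, len] + 1
      if (len < max_len) rec(origin, c(path, k), k, len + 1L)
    }
  }
  for (i in seq_len(n)) rec(i, i, i, 1L)
  out
}

#' Triad transitivity of a win/loss network
#'
#' Orients each dyad by its majority win direction (ties leave the dyad
#' unoriented).  Every triad whose three dyads are all oriented is classed
#' as transitive (consistent with a linear order) or cyclic, and
#' `t = transitive / (transitive + cyclic)`.  With no closed triads the
#' proportion is undefined (`NA`).
#'
#' @param W win/loss count matrix.
#' @return a `transitivity_report`: list with `n_transitive`, `n_cyclic`, `t`.
#' @export
compute_transitivity <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (nrow(W) < 3) stop("transitivity needs at least 3 animals")
  D <- (W > t(W)) * 1          # majority-win orientation
  M <- D + t(D)                # 1 where the dyad is oriented
  closed <- sum(diag(M %*% M %*% M)) / 6
  cyclic <- sum(diag(D %*% D %*% D)) / 3
  transitive <- closed - cyclic
  t_val <- if (closed == 0) NA_real_ else transitive / closed
  structure(list(n_transitive = as.integer(round(transitive)),
                 n_cyclic = as.integer(round(cyclic)),
                 t = t_val),
            class = "transitivity_report")
}

#' Weight of an imputed win from an indirect pathway
#'
#' `g(t, l) = beta * max(2t - 1, 0)^(l - 1)` for path length `l >= 2`: the
#' weight grows with network transitivity `t`, decays with path length,
#' vanishes for uninformative transitivity (t <= 0.5), and is always below
#' 1 so a single direct win outweighs any single imputed win.
#'
#' @param t triad transitivity in `[0, 1]` (NA treated as 0.5).
#' @param len path length (>= 2).
#' @param beta ceiling of the imputation weight, in (0, 1); default 0.5.
#' @return numeric weight in `[0, beta]`.
#' @export
indirect_weight <- function(t, len, beta = 0.5) {
  if (beta <= 0 || beta >= 1) stop("beta must be in (0, 1)")
  if (is.na(t)) t <- 0.5
  if (t < 0 || t > 1) stop("t must be in [0, 1]")
  beta * max(2 * t - 1, 0)^(len - 1)
}

#' Impute indirect wins from pathway counts
#'
#' Combines direct win counts with transitivity-weighted indirect pathway
#' counts: `weighted_ij = w_ij + sum_{l=2..L} g(t, l) * paths_ij(l)`.
#'
#' @param paths a `pathway_counts` object.
#' @param t triad transitivity (from [compute_transitivity()]); NA is
#'   treated as the uninformative value 0.5, which zeroes the imputation.
#' @param beta imputation weight ceiling, see [indirect_weight()].
#' @return matrix of weighted win counts.
#' @export
impute_wins <- function(paths, t, beta = 0.5) {
  stopifnot(inherits(paths, "pathway_counts"))
  weighted <- paths$counts[, , 1]
  if (paths$max_len >= 2) {
    for (len in 2:paths$max_len)
      weighted <- weighted + indirect_weight(t, len, beta) *
        paths$counts[, , len]
  }
  weighted
}

#' Dyadic dominance probabilities from weighted wins
#'
#' For each pair, `DP_ij = P(X > 0.5)` with `X ~ Beta(a_ij, a_ji)` and
#' `a_ij = weighted_wins_ij + prior`.  The add-one prior (uniform Beta)
#' makes a pair with no direct or indirect evidence perfectly ambiguous
#' (`DP = 0.5`).  `DP_ij + DP_ji = 1` holds exactly; the diagonal is `NA`.
#'
#' @param weighted_wins matrix of (possibly imputed) win counts.
#' @param prior pseudo-count added to each direction (default 1).
#' @return a matrix of dominance probabilities in `[0, 1]`.
#' @export
dominance_probability <- function(weighted_wins, prior = 1) {
  stopifnot(is.matrix(weighted_wins))
  if (any(weighted_wins < 0, na.rm = TRUE))
    stop("weighted wins must be nonnegative")
  if (prior <= 0) stop("prior must be positive")
  a <- weighted_wins + prior
  DP <- 1 - pbeta(0.5, a, t(a))
  dimnames(DP) <- dimnames(weighted_wins)
  diag(DP) <- NA_real_
  DP
}

#' Dyadic certainty: fold dominance probability about 0.5
#'
#' `c_ij = max(DP_ij, 1 - DP_ij)` discards rank direction and keeps only
#' how decided the relationship is, on `[0.5, 1]`.
#'
#' @param DP dominance probability matrix.
#' @return symmetric certainty matrix (diagonal `NA`).
#' @export
dyadic_certainty <- function(DP) {
  stopifnot(is.matrix(DP))
  pmax(DP, 1 - DP)
}

#' Average dominance certainty per animal
#'
#' `DC_i` is the mean dyadic certainty of animal i over all partners, a
#' measure of how unambiguously it fits the group hierarchy, in `[0.5, 1]`.
#'
#' @param certainty dyadic certainty matrix (diagonal `NA`).
#' @return named numeric vector of DC values.
#' @export
average_dominance_certainty <- function(certainty) {
  stopifnot(is.matrix(certainty))
  if (nrow(certainty) < 2)
    stop("dominance certainty needs at least 2 animals")
  rowMeans(certainty, na.rm = TRUE)
}

#' Full dominance inference for one group
#'
#' Convenience wrapper running pathway enumeration, transitivity,
#' win imputation, dominance probabilities, dyadic certainty and average
#' dominance certainty in one call.
#'
#' @param W win/loss count matrix.
#' @param max_len maximum pathway length (default 3).
#' @param beta imputation weight ceiling (default 0.5).
#' @param prior Beta pseudo-count (default 1).
#' @return a `dominance_fit`: list with `paths`, `transitivity`,
#'   `weighted_wins`, `DP`, `certainty`, `DC`.
#' @export
dominance_fit <- function(W, max_len = 3, beta = 0.5, prior = 1) {
  paths <- enumerate_directed_paths(W, max_len)
  trans <- if (nrow(W) >= 3) compute_transitivity(W) else
    structure(list(n_transitive = 0L, n_cyclic = 0L, t = NA_real_),
              class = "transitivity_report")
  weighted <- impute_wins(paths, trans$t, beta)
  DP <- dominance_probability(weighted, prior)
  cert <- dyadic_certainty(DP)
  DC <- average_dominance_certainty(cert)
  structure(list(paths = paths, transitivity = trans,
                 weighted_wins = weighted, DP = DP,
                 certainty = cert, DC = DC),
            class = "dominance_fit")
}
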