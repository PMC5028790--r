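# Independent oracles used across the suite: brute-force enumeration and
# quadrature routines kept deliberately naive and separate from the package
# implementation paths they check.

# exhaustive DFS enumeration of directed simple paths up to max_len
oracle_path_counts <- function(A, max_len) {
  n <- nrow(A)
  out <- array(0, dim = c(n, n, max_len))
  rec <- function(path, last, len) {
    for (k in seq_len(n)) {
      if (A[last, k] > 0 && !(k %in% path)) {
        out[path[1], k, len] <<- out[path[1], k, len] + 1
        if (len < max_len) rec(c(path, k), k, len + 1L)
      }
    }
  }
  for (i in seq_len(n)) rec(i, i, 1L)
  out
}

# triad-by-triad classification of transitive vs cyclic triads
oracle_triads <- function(W) {
  n <- nrow(W)
  D <- (W > t(W)) * 1
  n_trans <- 0L; n_cyc <- 0L
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    trio <- c(i, j, k)
    edges <- 0L
    for (a in trio) for (b in trio) if (a != b && D[a, b] == 1)
      edges <- edges + 1L
    if (edges != 3L) next  # not all three dyads oriented
    outdeg <- sapply(trio, function(a) sum(D[a, setdiff(trio, a)]))
    if (any(outdeg == 2)) n_trans <- n_trans + 1L else n_cyc <- n_cyc + 1L
  }
  list(n_transitive = n_trans, n_cyclic = n_cyc)
}

# P(X > 0.5) for X ~ Beta(a, b) by direct numerical quadrature
oracle_beta_tail <- function(a, b) {
  dens <- function(x) x^(a - 1) * (1 - x)^(b - 1) / beta(a, b)
  integrate(dens, 0.5, 1, rel.tol = 1e-10)$value
}

# exhaustive minimum-cost order over all permutations
oracle_best_order <- function(DP) {
  n <- nrow(DP)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    cost <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- DP[p[i], p[j]]
      if (!is.na(v)) cost <- cost + 1 - v
    }
    if (cost < best) best <- cost
  }
  best
}

# run counting over the observed-day subsequence of a stool record
oracle_bouts <- function(observed, stool) {
  x <- stool[observed]
  count <- 0L
  in_run <- FALSE
  for (v in x) {
    if (v && !in_run) { count <- count + 1L; in_run <- TRUE }
    if (!v) in_run <- FALSE
  }
  count
}

# small random win/loss matrix
random_winloss <- function(n, n_events = 4 * n, ids = LETTERS[seq_len(n)]) {
  W <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (e in seq_len(n_events)) {
    ij <- sample.int(n, 2)
    W[ij[1], ij[2]] <- W[ij[1], ij[2]] + 1L
  }
  W
}

# events data.frame helper
make_events <- function(actor, recipient,
                        aggression = "threat", submission = "move away") {
  n <- length(actor)
  data.frame(date = rep("2013-03-01", n), actor = actor,
             recipient = recipient,
             aggression = rep(aggression, length.out = n),
             submission = rep(submission, length.out = n),
             stringsAsFactors = FALSE)
}

write_events_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
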