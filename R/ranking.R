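# Linear rank order from the dominance probability matrix, proportion
# outranked, certainty categorization by segmented regression, and
# node-removal sensitivity checks.

#' Cost of a linear order under a dominance probability matrix
#'
#' `cost(order) = sum over pairs placed i-above-j of (1 - DP_ij)`: a fully
#' consistent matrix is cost-minimal at the true order, and placements
#' contradicted by strong probabilities are penalized.
#'
#' @param DP dominance probability matrix.
#' @param order character vector of ids, or integer indices, best to worst.
#' @return numeric cost.
#' @export
order_cost <- function(DP, order) {
  idx <- if (is.character(order)) match(order, rownames(DP)) else order
  if (any(is.na(idx))) stop("order contains unknown ids")
  sub <- DP[idx, idx]
  vals <- sub[upper.tri(sub)]
  sum(1 - vals, na.rm = TRUE)
}

#' Lowest-cost linear rank order by simulated annealing
#'
#' Minimizes [order_cost()] over permutations with adjacent-transposition
#' proposals, geometric cooling over `200 * N^2` proposals, and a final
#' deterministic descent.  Zero-cost-change swaps are never accepted, so a
#' fully ambiguous matrix returns the ids in their original order
#' (deterministic tie-break).
#'
#' @param DP dominance probability matrix.
#' @param seed RNG seed for the annealing run (default 0).
#' @param n_iter number of proposals (default `200 * N^2`).
#' @param t0,t1 initial and final temperatures of the geometric schedule.
#' @return a `rank_order`: list with `ids` (best to worst), `ordinal`
#'   (named, 1 = top), and `cost`.
#' @export
find_lowest_cost_order <- function(DP, seed = 0, n_iter = NULL,
                                   t0 = 0.5, t1 = 1e-4) {
  stopifnot(is.matrix(DP), nrow(DP) == ncol(DP))
  n <- nrow(DP)
  ids <- rownames(DP)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1)
    return(structure(list(ids = ids, ordinal = setNames(1L, ids), cost = 0),
                     class = "rank_order"))
  if (is.null(n_iter)) n_iter <- 200L * n^2
  res <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    anneal_order_cpp(DP, seq_len(n) - 1L, as.integer(n_iter), t0, t1)
  })
  ord <- res$order
  ordinal <- integer(n)
  ordinal[ord] <- seq_len(n)
  structure(list(ids = ids[ord],
                 ordinal = setNames(ordinal, ids),
                 cost = res$cost),
            class = "rank_order")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Proportion of groupmates outranked
#'
#' Transforms ordinal ranks into `(N - ordinal) / (N - 1)`, so the top
#' animal scores 1 and the bottom animal 0, comparable across groups of
#' different size.
#'
#' @param order a `rank_order` or a named ordinal vector (1 = top).
#' @return named numeric vector in `[0, 1]`.
#' @export
proportion_outranked <- function(order) {
  ordinal <- if (inherits(order, "rank_order")) order$ordinal else order
  n <- length(ordinal)
  if (n < 2) stop("proportion outranked needs at least 2 animals")
  (n - ordinal) / (n - 1)
}

#' Categorize dominance certainty by segmented regression
#'
#' Fits a continuous two-breakpoint piecewise-linear regression of the
#' sorted DC values against their empirical quantile (Muggeo-style
#' iterative linearization, with an exhaustive grid search as fallback),
#' and labels animals low / moderate / high by the fitted DC values at the
#' breakpoints.  Each group is categorized separately because DC
#' distributions differ between groups.
#'
#' @param dc named numeric vector of average dominance certainty values for
#'   one group.
#' @param min_n minimum group size (default 10).
#' @return a `certainty_categories`: list with `breakpoints_q` (quantile
#'   scale), `breakpoints_dc` (DC scale), and `category` (named factor,
#'   levels low/moderate/high).
#' @export
categorize_certainty <- function(dc, min_n = 10) {
  if (length(dc) < min_n)
    stop("need at least ", min_n, " animals to categorize certainty")
  if (is.null(names(dc))) names(dc) <- as.character(seq_along(dc))
  if (sd(dc) < 1e-10) {
    warning("constant DC values: single 'moderate' category")
    cat_f <- factor(rep("moderate", length(dc)),
                    levels = c("low", "moderate", "high"))
    names(cat_f) <- names(dc)
    return(structure(list(breakpoints_q = NULL, breakpoints_dc = NULL,
                          category = cat_f),
                     class = "certainty_categories"))
  }
  o <- order(dc)
  y <- dc[o]
  n <- length(y)
  x <- (seq_len(n) - 1) / (n - 1)
  fit <- fit_two_breakpoints(x, y)
  bq <- fit$psi
  bdc <- piecewise_predict(fit, bq)
  cat_chr <- ifelse(dc <= bdc[1], "low",
                    ifelse(dc <= bdc[2], "moderate", "high"))
  cat_f <- factor(cat_chr, levels = c("low", "moderate", "high"))
  names(cat_f) <- names(dc)
  structure(list(breakpoints_q = bq, breakpoints_dc = bdc,
                 category = cat_f),
            class = "certainty_categories")
}

# Continuous piecewise-linear fit with two breakpoints.  Muggeo's iterative
# linearization: refit lm with hinge terms U = (x - psi)_+ and working
# terms V = -1(x > psi); update psi by gamma/beta until the correction is
# negligible.  Falls back to an RSS grid search when the iteration leaves
# the data range or fails to converge; either solution is polished by a
# derivative-free local minimization of the RSS over the knot pair.
fit_two_breakpoints <- function(x, y, max_iter = 50, tol = 1e-7) {
  rng <- range(x)
  psi <- quantile(x, c(1 / 3, 2 / 3), names = FALSE)
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    U1 <- pmax(x - psi[1], 0); U2 <- pmax(x - psi[2], 0)
    V1 <- -(x > psi[1]); V2 <- -(x > psi[2])
    fit <- lm(y ~ x + U1 + U2 + V1 + V2)
    b <- coef(fit)
    if (any(is.na(b[c("U1", "U2")])) || abs(b["U1"]) < 1e-10 ||
        abs(b["U2"]) < 1e-10) break
    g <- c(ifelse(is.na(b["V1"]), 0, b["V1"]),
           ifelse(is.na(b["V2"]), 0, b["V2"]))
    step <- g / b[c("U1", "U2")]
    psi_new <- sort(psi + step)
    if (psi_new[1] <= rng[1] || psi_new[2] >= rng[2] ||
        diff(psi_new) < 1e-6) break
    moved <- max(abs(psi_new - psi))
    psi <- psi_new
    if (moved < tol) { ok <- TRUE; break }
  }
  fit <- if (ok) piecewise_refit(x, y, psi) else NULL
  if (is.null(fit)) fit <- grid_two_breakpoints(x, y)
  polish_breakpoints(x, y, fit)
}

polish_breakpoints <- function(x, y, fit) {
  rng <- range(x)
  rss_of <- function(psi) {
    if (psi[1] <= rng[1] || psi[2] >= rng[2] ||
        psi[2] - psi[1] < 1e-4) return(Inf)
    f <- piecewise_refit(x, y, psi)
    if (is.null(f)) Inf else f$rss
  }
  opt <- stats::optim(fit$psi, rss_of, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 400))
  if (is.finite(opt$value) && opt$value < fit$rss)
    fit <- piecewise_refit(x, y, sort(opt$par))
  fit
}

piecewise_refit <- function(x, y, psi) {
  U1 <- pmax(x - psi[1], 0); U2 <- pmax(x - psi[2], 0)
  fit <- lm(y ~ x + U1 + U2)
  if (any(is.na(coef(fit)))) return(NULL)
  list(psi = psi, coef = coef(fit), rss = sum(resid(fit)^2))
}

grid_two_breakpoints <- function(x, y) {
  cand <- unique(quantile(x, seq(0.05, 0.95, by = 0.025), names = FALSE))
  best <- NULL
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (cand[j] - cand[i] < 0.05) next
    f <- piecewise_refit(x, y, c(cand[i], cand[j]))
    if (!is.null(f) && (is.null(best) || f$rss < best$rss)) best <- f
  }
  if (is.null(best)) stop("breakpoint fit failed")
  best
}

piecewise_predict <- function(fit, xnew) {
  b <- fit$coef
  as.numeric(b[1] + b[2] * xnew + b[3] * pmax(xnew - fit$psi[1], 0) +
               b[4] * pmax(xnew - fit$psi[2], 0))
}

#' Node-removal sensitivity of dominance certainty
#'
#' Removes each named animal from the win/loss network one at a time,
#' recomputes average dominance certainty for the remaining animals, and
#' reports Pearson and Spearman correlations with the original DC values.
#' High correlations indicate that the network measure is robust to the
#' non-independence of network data.
#'
#' @param W win/loss count matrix.
#' @param nodes ids of animals to remove (one at a time).
#' @param ... passed to [dominance_fit()].
#' @return data.frame with `node`, `pearson`, `spearman`.
#' @export
node_removal_sensitivity <- function(W, nodes, ...) {
  stopifnot(is.matrix(W))
  ids <- rownames(W)
  unknown <- setdiff(nodes, ids)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  if (nrow(W) - 1 < 3)
    stop("removal would leave fewer than 3 animals")
  dc0 <- dominance_fit(W, ...)$DC
  res <- lapply(nodes, function(nd) {
    keep <- setdiff(ids, nd)
    dc1 <- dominance_fit(W[keep, keep, drop = FALSE], ...)$DC
    data.frame(node = nd,
               pearson = cor(dc0[keep], dc1),
               spearman = cor(dc0[keep], dc1, method = "spearman"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
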