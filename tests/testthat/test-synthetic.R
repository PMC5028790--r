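test_that("the winner model honours steepness limits and determinism", {
  # near-infinite steepness, no ambiguity: higher-scored animal always wins
  set.seed(2)
  h <- simulate_hierarchy(10, steepness = 1e6, ambiguity_level = 0)
  ev <- simulate_events(h, 300)
  ordinal <- setNames(seq_along(h$ids), h$ids)
  expect_true(all(ordinal[ev$actor] < ordinal[ev$recipient]))

  # zero steepness: every win probability is exactly 0.5
  h0 <- simulate_hierarchy(10, steepness = 0, ambiguity_level = 0)
  off <- !diag(10)
  expect_true(all(h0$win_prob[off] == 0.5))

  # same seed, same study; different seeds differ
  s1 <- make_paper_regime_study(seed = 3)
  s2 <- make_paper_regime_study(seed = 3)
  s3 <- make_paper_regime_study(seed = 4)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$subjects, s2$subjects)
  expect_false(identical(s1$events, s3$events))
})

test_that("event sparsity matches the occupancy regime", {
  set.seed(12)
  n <- 100
  h <- simulate_hierarchy(n)
  ev <- simulate_events(h, round(0.8 * choose(n, 2)))
  W <- build_winloss(ev, h$ids)
  inter <- (W + t(W))[upper.tri(W)]
  occ <- mean(inter > 0)
  mean_per <- mean(inter[inter > 0])
  # binomial-occupancy oracle under the same dyad weights
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  wts <- exp(-(pairs[, 2] - pairs[, 1]) / 20)
  p_dyad <- wts / sum(wts)
  occ_expect <- mean(1 - (1 - p_dyad)^nrow(ev))
  expect_equal(occ, occ_expect, tolerance = 0.05)
  expect_equal(mean_per, (nrow(ev) / choose(n, 2)) / occ_expect,
               tolerance = 0.05)
})

test_that("outcome generation reproduces its own coefficient structure", {
  set.seed(22)
  n <- 10000
  subjects <- data.frame(
    animal_id = paste0("a", 1:n),
    sex = "F", age = 8, age_cat = "6-12", group = "G1",
    sampling_order = 5,
    rank = runif(n), dc = runif(n, 0.5, 1))

  # null model: stratum means all equal exp(intercept)
  cfg <- default_outcome_config()
  cfg$group_sd <- 0
  cfg$il6 <- list(family = "nbinom2", size = 5, intercept = 2)
  out <- simulate_outcomes(subjects, cfg)
  lowr <- out$subjects$rank < 0.5
  expect_equal(mean(out$subjects$il6[lowr]), exp(2), tolerance = 0.05)
  expect_equal(mean(out$subjects$il6[!lowr]), exp(2), tolerance = 0.05)

  # negative rank x certainty interaction flips the rank slope between
  # low- and high-certainty strata
  cfg$il6 <- list(family = "nbinom2", size = 5, intercept = 1,
                  rank = 6, dc = 3, rank_dc = -8)
  out2 <- simulate_outcomes(subjects, cfg)
  s <- out2$subjects
  lo <- s$dc < 0.6; hi <- s$dc > 0.9
  slope <- function(m) coef(lm(log1p(il6) ~ rank, data = m))["rank"]
  expect_gt(slope(s[lo, ]), 0)   # rank raises outcome when dc is low
  expect_lt(slope(s[hi, ]), 0)   # and lowers it when dc is high

  # NB dispersion ordering: smaller size, larger variance/mean ratio
  cfg$il6 <- list(family = "nbinom2", size = 1, intercept = 2)
  v1 <- with(simulate_outcomes(subjects, cfg)$subjects, var(il6) / mean(il6))
  cfg$il6$size <- 10
  v10 <- with(simulate_outcomes(subjects, cfg)$subjects,
              var(il6) / mean(il6))
  expect_gt(v1, v10)
})

test_that("simulated outcome inputs are validated", {
  subjects <- data.frame(animal_id = "a", sex = "F", age_cat = "6-12",
                         group = "G1", sampling_order = 1, rank = 1.2,
                         dc = 0.8)
  expect_error(simulate_outcomes(subjects), "rank")
  subjects$rank <- 0.5; subjects$dc <- 0.4
  expect_error(simulate_outcomes(subjects), "dc")
  subjects$dc <- 0.8
  cfg <- default_outcome_config()
  cfg$il6$size <- -1
  expect_error(simulate_outcomes(subjects, cfg), "family parameter")
})

test_that("the reference study sits in the stated sparse high-transitivity regime", {
  study <- make_paper_regime_study(seed = 0)
  expect_identical(study, make_paper_regime_study(seed = 0))
  g <- "G1"
  sub <- study$subjects[study$subjects$group == g, ]
  W <- build_winloss(study$events[study$events$group == g, ], sub)
  tr <- compute_transitivity(W)
  expect_gt(tr$t, 0.95)
  inter <- (W + t(W))[upper.tri(W)]
  expect_gt(mean(inter > 0), 0.3)
  expect_lt(mean(inter[inter > 0]), 2)

  # health observations follow the roster and the bout invariant
  expect_true(all(study$health$animal_id %in% study$subjects$animal_id))
  expect_false(any(study$health$liquid_stool & !study$health$observed))
})

test_that("simulated events round-trip through the ingest schema", {
  study <- make_paper_regime_study(seed = 5)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(study$events[study$events$group == "G2",
                                c("date", "actor", "recipient",
                                  "aggression", "submission")],
                   p, row.names = FALSE)
  ev <- read_events(p)
  sub <- study$subjects[study$subjects$group == "G2", ]
  W <- build_winloss(ev, sub)
  expect_equal(sum(W), nrow(ev))
})

test_that("the pipeline recovers the latent order and interaction sign", {
  # end-to-end over 20 seeded studies: infer rank and certainty from the
  # events, then let AICc model selection pick the best-supported IL-6
  # model; the generating rank x certainty interaction should surface with
  # its (negative) sign in at least 80% of seeds
  spearman <- c()
  sign_hits <- 0L
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    study <- make_paper_regime_study(seed = seed)
    animals <- list()
    for (g in unique(study$subjects$group)) {
      sub <- study$subjects[study$subjects$group == g, ]
      W <- build_winloss(study$events[study$events$group == g, ], sub)
      fit <- dominance_fit(W)
      ord <- find_lowest_cost_order(fit$DP)
      r <- proportion_outranked(ord)
      spearman <- c(spearman,
                    cor(study$truth$rank[sub$animal_id],
                        r[sub$animal_id], method = "spearman"))
      sub$rank <- r[sub$animal_id]
      sub$dc <- fit$DC[sub$animal_id]
      animals[[g]] <- sub
    }
    df <- do.call(rbind, animals)
    fits <- suppressWarnings(fit_hypothesis_set(df, "il6"))
    best <- suppressWarnings(selection_table(fits))$hypothesis[1]
    b <- fits[[best]]$coefficients
    if ("rank:dc" %in% b$term &&
        b$estimate[b$term == "rank:dc"] < 0)
      sign_hits <- sign_hits + 1L
  }
  expect_gte(mean(spearman), 0.9)
  expect_gte(sign_hits / n_seeds, 0.8)
})
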