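# Synthetic colony generator: a latent linear hierarchy with controllable
# steepness and localized ambiguity, sparse dyadic agonistic events, and
# health outcomes generated from log-linear models with rank, certainty and
# rank x certainty effects plus a group random intercept.  The generating
# truth is retained so every downstream estimate can be scored.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Latent dominance hierarchy for one group
#'
#' Latent scores are equally spaced on `[0, 1]` (1 = top animal).  The
#' probability that the higher-scored animal of a dyad wins an interaction
#' is `plogis(steepness * score_difference)` (a Bradley-Terry / logistic
#' winner model).  Ambiguity flattens the win probability of selected dyads
#' toward 0.5; it is concentrated among rank-adjacent dyads in the middle
#' of the hierarchy, which produces the characteristic U-shaped
#' certainty-rank relationship.
#'
#' @param n number of animals.
#' @param steepness logistic scale of score differences (log-odds across
#'   the full score range); larger is steeper.
#' @param ambiguity_level maximal flattening in `[0, 1]` (1 collapses a
#'   dyad to a coin flip).
#' @param ambiguity_decay ordinal rank distance over which the flattening
#'   decays (ambiguity is strongest between rank-adjacent animals).
#' @param ambiguity_width width (on the 0-1 rank-midpoint scale) of the
#'   Gaussian mid-hierarchy concentration of ambiguity.
#' @param ids animal ids (default `"A001"...`).
#' @return a `true_hierarchy`: list with `ids`, `scores`, `steepness`, and
#'   `win_prob`, the matrix of per-dyad win probabilities.
#' @export
simulate_hierarchy <- function(n, steepness = 130, ambiguity_level = 0.95,
                               ambiguity_decay = 20, ambiguity_width = 0.15,
                               ids = sprintf("A%03d", seq_len(n))) {
  stopifnot(n >= 2, steepness >= 0, ambiguity_level >= 0,
            ambiguity_level <= 1)
  scores <- (n - seq_len(n)) / (n - 1)
  ord <- seq_len(n)
  d <- abs(outer(ord, ord, "-"))
  mid <- (outer(ord, ord, "+") / 2) / (n + 1)
  amb <- ambiguity_level * exp(-(d - 1) / ambiguity_decay) *
    exp(-((mid - 0.5) / ambiguity_width)^2)
  p <- plogis(steepness * outer(scores, scores, "-"))
  p <- 0.5 + (p - 0.5) * (1 - amb)
  diag(p) <- NA_real_
  dimnames(p) <- list(ids, ids)
  structure(list(ids = ids, scores = setNames(scores, ids),
                 steepness = steepness, win_prob = p),
            class = "true_hierarchy")
}

#' Simulate sparse dyadic agonistic events
#'
#' Dyads are sampled with probability decaying exponentially in ordinal
#' rank distance (animals interact mostly with near-ranked partners); the
#' winner of each event is drawn from the hierarchy's per-dyad win
#' probability.  Events are spread over a 6-week, 4-days-per-week
#' observation calendar and given aggression/submission categories drawn
#' from the closed vocabularies, so the output ingests through
#' [read_events()] unchanged.
#'
#' @param hierarchy a `true_hierarchy`.
#' @param n_events number of events to draw.
#' @param dyad_decay exponential decay scale (in ordinal rank distance) of
#'   the dyad sampling weights.
#' @param start_date first observation day.
#' @return data.frame of events (`date`, `actor`, `recipient`,
#'   `aggression`, `submission`).
#' @export
simulate_events <- function(hierarchy, n_events, dyad_decay = 20,
                            start_date = as.Date("2013-03-04")) {
  stopifnot(inherits(hierarchy, "true_hierarchy"), n_events >= 0)
  n <- length(hierarchy$ids)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dist <- pairs[, 2] - pairs[, 1]
  wts <- exp(-dist / dyad_decay)
  if (n_events == 0)
    return(data.frame(date = character(0), actor = character(0),
                      recipient = character(0), aggression = character(0),
                      submission = character(0),
                      stringsAsFactors = FALSE))
  k <- sample.int(nrow(pairs), n_events, replace = TRUE, prob = wts)
  i <- pairs[k, 1]; j <- pairs[k, 2]
  p_i_wins <- hierarchy$win_prob[cbind(i, j)]
  i_wins <- runif(n_events) < p_i_wins
  actor <- ifelse(i_wins, hierarchy$ids[i], hierarchy$ids[j])
  recipient <- ifelse(i_wins, hierarchy$ids[j], hierarchy$ids[i])
  # 4 observation days per week for 6 weeks
  days <- start_date + as.vector(outer(c(0, 1, 2, 3), 7 * 0:5, "+"))
  data.frame(
    date = as.character(sort(sample(days, n_events, replace = TRUE))),
    actor = actor, recipient = recipient,
    aggression = sample(aggression_categories, n_events, replace = TRUE,
                        prob = c(0.35, 0.40, 0.18, 0.07)),
    submission = sample(submission_categories, n_events, replace = TRUE,
                        prob = c(0.20, 0.35, 0.20, 0.10, 0.05, 0.10)),
    stringsAsFactors = FALSE)
}

#' Simulate a subject roster for one group
#'
#' Sex ratio and age distribution emulate a captive breeding colony
#' (about 72% female; ages 3-29 y with mean near 7.7).  Blood samples are
#' processed in batches of ~15 animals; `sampling_order` is the batch
#' index.
#'
#' @param n number of animals.
#' @param group group id.
#' @param ids animal ids.
#' @param p_female proportion of females.
#' @param batch_size blood-processing batch size.
#' @return data.frame with `animal_id`, `sex`, `age`, `age_cat`, `group`,
#'   `sampling_order`.
#' @export
simulate_subjects <- function(n, group = "G1",
                              ids = sprintf("A%03d", seq_len(n)),
                              p_female = 0.72, batch_size = 15) {
  sex <- ifelse(runif(n) < p_female, "F", "M")
  age <- pmin(3 + rgamma(n, shape = 2, rate = 0.42), 29)
  batch <- ceiling(sample.int(n) / batch_size)
  data.frame(animal_id = ids, sex = sex, age = age,
             age_cat = age_category(age), group = group,
             sampling_order = batch, stringsAsFactors = FALSE)
}

#' Default outcome-generating coefficients
#'
#' Log-linear coefficient sets for the four outcomes, following the H5/H8
#' effect structure (rank, certainty, rank x certainty, sex and age
#' effects, with sampling order for blood outcomes and a per-observation-
#' day rate for diarrhea), plus the group random-intercept SD and family
#' parameters (NB dispersion `size`, gamma `shape`).
#'
#' @return named list of per-outcome coefficient lists.
#' @export
default_outcome_config <- function() {
  list(
    il6 = list(family = "nbinom2", size = 1.5,
               intercept = -3.71, rank = 12.6, dc = 7.35, rank_dc = -15.0,
               sexF = 0.034, age3 = -0.66, age45 = -0.88, age13 = 0.24,
               sampling_order = 0.053),
    tnfa = list(family = "nbinom2", size = 1.5,
                intercept = -6.34, rank = 22.0, dc = 13.9, rank_dc = -26.2,
                sexF = -0.4, age3 = -0.47, age45 = -0.83, age13 = 0.33,
                sampling_order = 0.061),
    crp = list(family = "gamma", shape = 2,
               intercept = 2.48, rank = -0.08, dc = -1.79, sexF = -5.70,
               rank_dc = 0.11, rank_sexF = 13.2, dc_sexF = 6.75,
               rank_dc_sexF = -14.9, il6 = 0.004, sampling_order = 0.026,
               age3 = -0.004, age45 = -0.046, age13 = 0.27),
    diarrhea = list(family = "bernoulli_days",
                    intercept = 4.0, rank = -0.96, dc = -7.00,
                    sexF = -0.31, age3 = -1.09, age45 = 0.067,
                    age13 = 0.65, frailty_sd = 1.2),
    group_sd = 0.4
  )
}

#' Outcome coefficients for the reference synthetic study
#'
#' The reference study keeps the colony-study coefficient structure but
#' rescales the cytokine rank and rank x certainty terms so that the
#' rank-slope reversal (the crossing pattern between low- and high-
#' certainty animals) happens at the centre of the generator's own realized
#' dominance-certainty range, with a log-slope span of about +/-3 across
#' that range, and uses a tighter NB dispersion (size 16).  Without this
#' rescaling the crossing point implied by the colony coefficients lies
#' outside the generator's DC range (which is narrower than a real
#' colony's), and the generating interaction would be undetectable by
#' construction rather than by inference.
#'
#' @param base coefficient set to rescale.
#' @return named list of per-outcome coefficient lists.
#' @export
fixture_outcome_config <- function(base = default_outcome_config()) {
  # crossing at DC = 0.925 (mid of the realized true-DC range), span ~ +/-3
  base$il6$rank <- 42.55
  base$il6$rank_dc <- -46
  base$il6$size <- 16
  base$tnfa$rank <- 46.25
  base$tnfa$rank_dc <- -50
  base$tnfa$size <- 16
  base
}

outcome_linear_predictor <- function(cfg, df, group_effect) {
  sexF <- as.numeric(df$sex == "F")
  eta <- cfg$intercept +
    (cfg$rank %||% 0) * df$rank +
    (cfg$dc %||% 0) * df$dc +
    (cfg$rank_dc %||% 0) * df$rank * df$dc +
    (cfg$sexF %||% 0) * sexF +
    (cfg$rank_sexF %||% 0) * df$rank * sexF +
    (cfg$dc_sexF %||% 0) * df$dc * sexF +
    (cfg$rank_dc_sexF %||% 0) * df$rank * df$dc * sexF +
    (cfg$age3 %||% 0) * as.numeric(df$age_cat == "3") +
    (cfg$age45 %||% 0) * as.numeric(df$age_cat == "4-5") +
    (cfg$age13 %||% 0) * as.numeric(df$age_cat == "13+")
  if (!is.null(cfg$sampling_order))
    eta <- eta + cfg$sampling_order * df$sampling_order
  if (!is.null(cfg$il6))
    eta <- eta + cfg$il6 * df$il6
  eta + group_effect
}

#' Simulate biomarkers and health observations
#'
#' Log-mean linear predictors (see [default_outcome_config()]) drive
#' negative-binomial draws for IL-6 and TNF-alpha, gamma draws for CRP
#' (with IL-6 entering its predictor as a covariate), and a per-
#' observation-day liquid-stool hazard (`p = 1 - exp(-exp(eta))`) for
#' diarrhea, scored on a twice-weekly, 6-week observation calendar.  The
#' diarrhea hazard carries an animal-level lognormal frailty
#' (`frailty_sd`), so aggregated bout counts are overdispersed rather
#' than binomial.
#'
#' @param subjects roster with `rank` and `dc` columns in `[0,1]` /
#'   `[0.5,1]`.
#' @param config outcome coefficient configuration.
#' @param n_obs_days number of health observation days (twice weekly over
#'   6 weeks by default).
#' @param p_observed probability an animal is present on an observation
#'   day.
#' @param start_date first health observation day.
#' @return list with `subjects` (biomarker columns added) and `health`
#'   (per animal-day observation records).
#' @export
simulate_outcomes <- function(subjects, config = default_outcome_config(),
                              n_obs_days = 12, p_observed = 0.97,
                              start_date = as.Date("2013-03-05")) {
  stopifnot(all(c("rank", "dc") %in% names(subjects)))
  if (any(subjects$rank < 0 | subjects$rank > 1))
    stop("rank must be in [0, 1]")
  if (any(subjects$dc < 0.5 | subjects$dc > 1))
    stop("dc must be in [0.5, 1]")
  for (oc in c("il6", "tnfa", "crp"))
    if (!is.null(config[[oc]]$size %||% config[[oc]]$shape) &&
        (config[[oc]]$size %||% config[[oc]]$shape) <= 0)
      stop("family parameter for ", oc, " must be positive")
  groups <- unique(subjects$group)
  u <- setNames(rnorm(length(groups), 0, config$group_sd %||% 0), groups)
  ug <- u[subjects$group]

  eta_il6 <- outcome_linear_predictor(config$il6, subjects, ug)
  subjects$il6 <- rnbinom(nrow(subjects), mu = exp(eta_il6),
                          size = config$il6$size)
  eta_tnfa <- outcome_linear_predictor(config$tnfa, subjects, ug)
  subjects$tnfa <- rnbinom(nrow(subjects), mu = exp(eta_tnfa),
                           size = config$tnfa$size)
  eta_crp <- outcome_linear_predictor(config$crp, subjects, ug)
  shape <- config$crp$shape
  subjects$crp <- rgamma(nrow(subjects), shape = shape,
                         rate = shape / exp(eta_crp))

  # animal-level lognormal frailty: susceptibility to enteric upsets varies
  # between individuals, which also makes the aggregated bout counts
  # overdispersed (negative-binomial-like) rather than binomial
  eta_d <- outcome_linear_predictor(config$diarrhea, subjects, ug) +
    rnorm(nrow(subjects), 0, config$diarrhea$frailty_sd %||% 0)
  p_day <- 1 - exp(-exp(eta_d))
  # twice-weekly calendar
  days <- start_date +
    as.vector(outer(c(0, 3), 7 * seq_len(ceiling(n_obs_days / 2)) - 7,
                    "+"))[seq_len(n_obs_days)]
  nd <- length(days)
  na <- nrow(subjects)
  observed <- runif(na * nd) < p_observed
  stool <- observed & (runif(na * nd) < rep(p_day, each = nd))
  health <- data.frame(
    animal_id = rep(subjects$animal_id, each = nd),
    date = as.character(rep(days, times = na)),
    observed = observed, liquid_stool = stool,
    stringsAsFactors = FALSE)
  list(subjects = subjects, health = health)
}

#' Configuration of the reference synthetic study
#'
#' Three groups of about 120 animals; events per group chosen so that the
#' expected interactions-per-dyad ratio is 0.80, which with the rank-
#' distance-biased dyad sampling yields roughly 42% of dyads interacting
#' and just under two interactions per interacting dyad; a steep hierarchy
#' with mid-hierarchy rank ambiguity (high triad transitivity); and
#' H5-style health-outcome effects.
#'
#' @param group_sizes animals per group.
#' @param events_per_dyad expected events per (possible) dyad.
#' @param steepness,ambiguity_level,ambiguity_decay,ambiguity_width see
#'   [simulate_hierarchy()].
#' @param dyad_decay see [simulate_events()].
#' @param outcomes see [fixture_outcome_config()].
#' @return configuration list for [simulate_study()].
#' @export
paper_regime_config <- function(group_sizes = c(126, 120, 114),
                                events_per_dyad = 0.80,
                                steepness = 130,
                                ambiguity_level = 0.95,
                                ambiguity_decay = 20,
                                ambiguity_width = 0.15,
                                dyad_decay = 20,
                                outcomes = fixture_outcome_config()) {
  list(group_sizes = group_sizes, events_per_dyad = events_per_dyad,
       steepness = steepness, ambiguity_level = ambiguity_level,
       ambiguity_decay = ambiguity_decay, ambiguity_width = ambiguity_width,
       dyad_decay = dyad_decay, outcomes = outcomes)
}

#' Simulate a complete multi-group study with retained truth
#'
#' Generates, per group, a latent hierarchy, sparse agonistic events, a
#' subject roster, biomarkers and health observations.  The generating
#' truth (latent order, per-dyad win probabilities, true proportion
#' outranked, true dominance certainty, outcome coefficients) is kept in
#' `$truth` so downstream recovery can be scored.
#'
#' @param config from [paper_regime_config()].
#' @param seed RNG seed; the same seed reproduces the study exactly.
#' @return a `synthetic_study`: list with `events`, `subjects`, `health`,
#'   `truth`, `config`.
#' @export
simulate_study <- function(config = paper_regime_config(), seed = 0) {
  set.seed(seed)
  events <- list(); subjects <- list(); health <- list()
  truth <- list(order = list(), win_prob = list(), rank = c(), dc = c())
  for (g in seq_along(config$group_sizes)) {
    n <- config$group_sizes[g]
    gid <- paste0("G", g)
    ids <- sprintf("%s-%03d", gid, seq_len(n))
    hier <- simulate_hierarchy(
      n, steepness = config$steepness,
      ambiguity_level = config$ambiguity_level,
      ambiguity_decay = config$ambiguity_decay,
      ambiguity_width = config$ambiguity_width, ids = ids)
    ev <- simulate_events(hier, round(config$events_per_dyad * choose(n, 2)),
                          dyad_decay = config$dyad_decay)
    ev$group <- gid
    sub <- simulate_subjects(n, group = gid, ids = ids)
    # generating status covariates: true proportion outranked and true DC
    sub$rank <- (n - seq_len(n)) / (n - 1)
    cert <- pmax(hier$win_prob, 1 - hier$win_prob)
    sub$dc <- rowMeans(cert, na.rm = TRUE)
    events[[g]] <- ev
    subjects[[g]] <- sub
    truth$order[[gid]] <- ids
    truth$win_prob[[gid]] <- hier$win_prob
  }
  subjects <- do.call(rbind, subjects)
  out <- simulate_outcomes(subjects, config$outcomes)
  truth$rank <- setNames(subjects$rank, subjects$animal_id)
  truth$dc <- setNames(subjects$dc, subjects$animal_id)
  truth$coefficients <- config$outcomes
  structure(list(events = do.call(rbind, events),
                 subjects = out$subjects, health = out$health,
                 truth = truth, config = config, seed = seed),
            class = "synthetic_study")
}

#' One-call reference fixture
#'
#' The three-group, ~120-animal sparse high-transitivity study used
#' throughout the test suite.
#'
#' @param seed RNG seed (default 0).
#' @return a `synthetic_study`.
#' @export
make_paper_regime_study <- function(seed = 0) {
  simulate_study(paper_regime_config(), seed = seed)
}
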