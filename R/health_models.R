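# Status-health hypothesis set: negative-binomial / gamma mixed models with
# a group random intercept, AICc multimodel selection, candidate sets, and
# coefficient-to-fold-change effect sizes.

#' The fixed hypothesis set relating status to health
#'
#' Named list of status/demography term sets, H0 (controls only) through H8
#' (full sex x rank x certainty interaction).  Outcome-specific control
#' variables (sampling order and IL-6 for blood outcomes, the
#' log-observation-days offset for diarrhea) are added by [model_spec()].
#'
#' @return named list of character vectors of model terms.
#' @export
hypothesis_set <- function() {
  list(
    H0  = character(0),
    H1  = c("sex", "age_cat"),
    H2  = c("sex", "age_cat", "rank"),
    H3  = c("sex", "age_cat", "dc"),
    H4  = c("sex", "age_cat", "rank", "dc"),
    H5  = c("sex", "age_cat", "rank", "dc", "rank:dc"),
    H6  = c("sex", "age_cat", "rank", "dc", "rank:age_cat"),
    H7a = c("sex", "age_cat", "rank", "dc", "rank:sex"),
    H7b = c("sex", "age_cat", "rank", "dc", "dc:sex"),
    H8  = c("sex", "age_cat", "rank", "dc", "rank:dc", "rank:sex",
            "dc:sex", "rank:dc:sex")
  )
}

outcome_settings <- function(outcome) {
  switch(outcome,
    crp = list(column = "crp", family = "gamma",
               controls = c("sampling_order", "il6"), offset = NULL),
    il6 = list(column = "il6", family = "nbinom2",
               controls = "sampling_order", offset = NULL),
    tnfa = list(column = "tnfa", family = "nbinom2",
                controls = "sampling_order", offset = NULL),
    diarrhea = list(column = "diarrhea_bouts", family = "nbinom2",
                    controls = character(0),
                    offset = "log(observation_days)"),
    stop("unknown outcome '", outcome,
         "'; expected one of crp, il6, tnfa, diarrhea")
  )
}

#' Build a model specification for one hypothesis and outcome
#'
#' Assembles the model formula (controls + hypothesis terms + random group
#' intercept, plus the observation-days offset for diarrhea) and the
#' response family: gamma with log link for CRP, negative binomial (NB2,
#' log link) for IL-6, TNF-alpha and diarrhea bouts.
#'
#' @param hypothesis one of `names(hypothesis_set())`.
#' @param outcome one of `"crp"`, `"il6"`, `"tnfa"`, `"diarrhea"`.
#' @return a `model_spec`: list with `hypothesis`, `outcome`, `formula`,
#'   `family`.
#' @export
model_spec <- function(hypothesis, outcome) {
  hs <- hypothesis_set()
  if (!hypothesis %in% names(hs))
    stop("unknown hypothesis '", hypothesis, "'")
  os <- outcome_settings(outcome)
  rhs <- c(os$controls, hs[[hypothesis]])
  if (!is.null(os$offset)) rhs <- c(rhs, sprintf("offset(%s)", os$offset))
  rhs <- c(if (length(rhs)) rhs else "1", "(1 | group)")
  fml <- as.formula(paste(os$column, "~", paste(rhs, collapse = " + ")))
  structure(list(hypothesis = hypothesis, outcome = outcome,
                 formula = fml, family = os$family),
            class = "model_spec")
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters (fixed effects + dispersion +
#'   random-intercept variance).
#' @param n sample size.
#' @return numeric AICc.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n - k - 1 <= 0")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one status-health model
#'
#' Fits the specified generalized linear mixed model with a log link and a
#' random group intercept by Laplace approximation (via glmmTMB).  The
#' parameter count `k` is the number of fixed-effect coefficients plus one
#' dispersion parameter (NB size or gamma shape) plus one random-intercept
#' variance.
#'
#' @param data analysis table with outcome, covariates, and `group`.
#' @param spec a [model_spec()].
#' @return an `outcome_fit`: list with `hypothesis`, `outcome`,
#'   `coefficients` (term/estimate/se data.frame), `loglik`, `k`, `n`,
#'   `aicc`, `converged`, and the underlying `model`.
#' @export
fit_outcome_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  os <- outcome_settings(spec$outcome)
  if (!os$column %in% names(data))
    stop("outcome column '", os$column, "' not found")
  data <- prepare_model_frame(data)
  if (nlevels(data$group) < 2)
    stop("random group intercept needs at least 2 groups")
  fam <- switch(spec$family,
                gamma = stats::Gamma(link = "log"),
                nbinom2 = glmmTMB::nbinom2(link = "log"))
  fit <- suppressWarnings(
    glmmTMB::glmmTMB(spec$formula, data = data, family = fam))
  conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  sm <- summary(fit)$coefficients$cond
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], row.names = NULL,
                      stringsAsFactors = FALSE)
  ll <- as.numeric(logLik(fit))
  k <- nrow(coefs) + 1L + 1L
  n <- stats::nobs(fit)
  structure(list(hypothesis = spec$hypothesis, outcome = spec$outcome,
                 coefficients = coefs, loglik = ll, k = k, n = n,
                 aicc = aicc(ll, k, n), converged = conv, model = fit),
            class = "outcome_fit")
}

# Referent coding: males and adults (6-12 y) are the reference categories.
prepare_model_frame <- function(data) {
  data <- as.data.frame(data)
  data$sex <- factor(data$sex, levels = c("M", "F"))
  if (!"age_cat" %in% names(data) && "age" %in% names(data))
    data$age_cat <- age_category(data$age)
  data$age_cat <- factor(data$age_cat, levels = age_levels)
  data$group <- factor(data$group)
  data
}

#' Fit the full hypothesis set for one outcome
#'
#' @param data analysis table.
#' @param outcome one of `"crp"`, `"il6"`, `"tnfa"`, `"diarrhea"`.
#' @param hypotheses hypothesis ids to fit (default: all).
#' @return named list of `outcome_fit` objects (class `outcome_fits`).
#' @export
fit_hypothesis_set <- function(data, outcome,
                               hypotheses = names(hypothesis_set())) {
  fits <- lapply(hypotheses, function(h)
    fit_outcome_model(data, model_spec(h, outcome)))
  names(fits) <- hypotheses
  structure(fits, class = "outcome_fits")
}

#' AICc selection table from AICc scores
#'
#' Computes `dAICc`, model likelihoods `L = exp(-dAICc / 2)`, Akaike
#' weights `w = L / sum(L)`, and evidence ratios (weight of the best model
#' over each model's weight, equal to `exp(dAICc / 2)`), sorted by AICc.
#'
#' @param aicc_scores named numeric vector of AICc values (or of dAICc
#'   values; only differences matter).
#' @return a `selection_table` data.frame with columns `hypothesis`,
#'   `aicc`, `delta_aicc`, `likelihood`, `weight`, `evidence_ratio`.
#' @export
aicc_selection <- function(aicc_scores) {
  if (length(aicc_scores) < 2) stop("need at least 2 models")
  if (is.null(names(aicc_scores)))
    names(aicc_scores) <- paste0("M", seq_along(aicc_scores))
  ord <- order(aicc_scores)
  a <- aicc_scores[ord]
  delta <- a - a[1]
  L <- exp(-delta / 2)
  w <- L / sum(L)
  out <- data.frame(hypothesis = names(a), aicc = as.numeric(a),
                    delta_aicc = as.numeric(delta),
                    likelihood = as.numeric(L), weight = as.numeric(w),
                    evidence_ratio = as.numeric(w[1] / w),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("selection_table", "data.frame")
  out
}

#' Selection table from a set of fitted models
#'
#' Non-converged fits are dropped with a warning before ranking.
#'
#' @param fits an `outcome_fits` list from [fit_hypothesis_set()].
#' @return a `selection_table` (see [aicc_selection()]).
#' @export
selection_table <- function(fits) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv))
    warning("dropping non-converged model(s): ",
            paste(names(fits)[!conv], collapse = ", "))
  fits <- fits[conv]
  if (length(fits) < 2) stop("need at least 2 converged fits")
  aicc_selection(vapply(fits, `[[`, numeric(1), "aicc"))
}

#' Candidate model set from a selection table
#'
#' A single best model is retained when its Akaike weight is at least
#' `weight_threshold` (0.90); otherwise all models with `dAICc <=
#' delta_max` (5) form the candidate set, excluding the null model, which
#' offers no interpretable status effect.
#'
#' @param table a `selection_table`.
#' @param weight_threshold single-model weight rule (default 0.90).
#' @param delta_max dAICc cutoff for the candidate set (default 5).
#' @param exclude_null drop the null model from multi-model sets?
#' @param null_id id of the null model (default `"H0"`).
#' @return character vector of hypothesis ids, in increasing dAICc order.
#' @export
candidate_set <- function(table, weight_threshold = 0.90, delta_max = 5,
                          exclude_null = TRUE, null_id = "H0") {
  stopifnot(inherits(table, "selection_table"))
  if (table$weight[1] >= weight_threshold)
    return(table$hypothesis[1])
  ids <- table$hypothesis[table$delta_aicc <= delta_max]
  if (exclude_null) ids <- setdiff(ids, null_id)
  ids
}

#' Multiplicative effect size from a log-link coefficient
#'
#' For a log-link model, changing a predictor by `delta` multiplies the
#' expected outcome by `exp(coefficient * delta)`.  The result is reported
#' as an "x times increase" when above 1 and as the reciprocal ("x times
#' decrease") when below 1.
#'
#' @param coefficient effective slope on the log scale.
#' @param delta change in the predictor.
#' @return an `effect_size`: list with `fold` (raw multiplier),
#'   `multiplier` (>= 1), `direction` (`"increase"` / `"decrease"` /
#'   `"none"`).
#' @export
fold_change <- function(coefficient, delta) {
  fold <- exp(coefficient * delta)
  direction <- if (fold > 1) "increase" else if (fold < 1) "decrease"
  else "none"
  structure(list(fold = fold, multiplier = max(fold, 1 / fold),
                 direction = direction),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("%.2f times %s\n", x$multiplier, x$direction))
  invisible(x)
}

#' Effective slope of a predictor in the presence of interactions
#'
#' The effective slope is the predictor's main-effect coefficient plus each
#' interaction coefficient involving it, multiplied by the supplied
#' moderator values (e.g. `c(dc = 0.85, sexF = 1)`).  An interaction whose
#' moderator value is not supplied is an error.
#'
#' @param coefs an `outcome_fit`, a coefficient data.frame (`term`,
#'   `estimate`), or a named numeric vector.
#' @param predictor name of the predictor term.
#' @param moderators named numeric vector of moderator values.
#' @return numeric effective slope.
#' @export
effect_slope <- function(coefs, predictor, moderators = c()) {
  if (inherits(coefs, "outcome_fit")) coefs <- coefs$coefficients
  if (is.data.frame(coefs))
    coefs <- setNames(coefs$estimate, coefs$term)
  parts <- strsplit(names(coefs), ":", fixed = TRUE)
  slope <- 0
  found <- FALSE
  for (i in seq_along(coefs)) {
    comp <- parts[[i]]
    if (!(predictor %in% comp)) next
    found <- TRUE
    others <- setdiff(comp, predictor)
    if (length(others) == 0) {
      slope <- slope + coefs[[i]]
    } else {
      missing <- setdiff(others, names(moderators))
      if (length(missing))
        stop("moderator value(s) required for: ",
             paste(missing, collapse = ", "))
      slope <- slope + coefs[[i]] * prod(moderators[others])
    }
  }
  if (!found) stop("predictor '", predictor, "' not found in coefficients")
  slope
}

#' Fold change for a predictor shift, honouring interactions
#'
#' @inheritParams effect_slope
#' @param delta change in the predictor.
#' @return an `effect_size` (see [fold_change()]).
#' @export
fold_change_effect <- function(coefs, predictor, delta, moderators = c()) {
  fold_change(effect_slope(coefs, predictor, moderators), delta)
}
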