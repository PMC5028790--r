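# Ingestion and validation of raw study records: agonistic events, health
# observations, subject rosters; win/loss matrices; diarrhea bouts;
# biomarker preprocessing.

#' Closed vocabularies for agonistic event categories
#'
#' Aggression is recorded by severity; submission by the recipient's
#' response.  `"none"` marks events where no submission was recorded.
#'
#' @export
aggression_categories <- c("threat", "mild", "moderate", "intense")

#' @rdname aggression_categories
#' @export
submission_categories <- c("freeze/turn away", "move away", "run away <6m",
                           "run away >6m", "crouch", "none")

#' Read dyadic agonistic events from CSV
#'
#' Expects a UTF-8 CSV with columns `date` (ISO-8601), `actor`, `recipient`,
#' `aggression` and `submission`.  Every row is validated: self-directed
#' events and categories outside the closed vocabularies are fatal errors
#' that name the offending line.
#'
#' @param path path to the events CSV.
#' @return a data.frame of events (class `agonistic_events`).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("date", "actor", "recipient", "aggression", "submission")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("events file is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0) {
    df <- df[required]
    class(df) <- c("agonistic_events", "data.frame")
    return(df)
  }
  df <- df[required]
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_date <- is.na(as.Date(df$date, format = "%Y-%m-%d"))
  if (any(bad_date))
    stop("unparseable ISO-8601 date on line(s) ",
         paste(line[bad_date], collapse = ", "))
  self <- df$actor == df$recipient
  if (any(self))
    stop("self-directed event (actor == recipient) on line(s) ",
         paste(line[self], collapse = ", "))
  bad_aggr <- !(df$aggression %in% aggression_categories)
  if (any(bad_aggr))
    stop("unknown aggression category ",
         paste(sprintf("'%s' (line %d)", df$aggression[bad_aggr],
                       line[bad_aggr]), collapse = ", "))
  bad_sub <- !(df$submission %in% submission_categories)
  if (any(bad_sub))
    stop("unknown submission category ",
         paste(sprintf("'%s' (line %d)", df$submission[bad_sub],
                       line[bad_sub]), collapse = ", "))
  class(df) <- c("agonistic_events", "data.frame")
  df
}

#' Read twice-weekly health observations from CSV
#'
#' Columns: `animal_id`, `date`, `observed` (logical; FALSE when the animal
#' was absent), `liquid_stool` (logical; only meaningful when observed).
#'
#' @param path path to the health observation CSV.
#' @return a data.frame of health observations.
#' @export
read_health <- function(path) {
  if (!file.exists(path)) stop("health file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("animal_id", "date", "observed", "liquid_stool")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("health file is missing required column(s): ",
         paste(missing, collapse = ", "))
  df$observed <- as.logical(df$observed)
  df$liquid_stool <- as.logical(df$liquid_stool)
  if (any(df$liquid_stool & !df$observed, na.rm = TRUE))
    stop("liquid_stool recorded on unobserved day(s)")
  df
}

#' Read the subject roster from CSV
#'
#' Columns: `animal_id`, `sex` (M/F), `age` (years), `group`, and optionally
#' `sampling_order`, `il6`, `tnfa`, `crp`.
#'
#' @param path path to the subjects CSV.
#' @return a data.frame of subjects.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("subjects file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("animal_id", "sex", "age", "group")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("subjects file is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (any(duplicated(df$animal_id)))
    stop("duplicated animal_id in subjects file")
  bad_sex <- !(df$sex %in% c("M", "F"))
  if (any(bad_sex))
    stop("sex must be 'M' or 'F'; offending id(s): ",
         paste(df$animal_id[bad_sex], collapse = ", "))
  df
}

#' Build a win/loss matrix from agonistic events
#'
#' Every retained aggressive event counts as one win for the actor over the
#' recipient, regardless of whether a submission was recorded.  The matrix
#' is square over all subjects (ids ordered as in `subjects`), with a zero
#' diagonal; `counts[i, j]` is the number of events with actor `i` and
#' recipient `j`.
#'
#' @param events data.frame with `actor` and `recipient` columns (and
#'   `aggression` if filtering by category).
#' @param subjects data.frame with `animal_id`, or a character vector of ids.
#' @param include_categories aggression categories to retain (default: all).
#' @return an integer matrix with dimnames set to the animal ids.
#' @export
build_winloss <- function(events, subjects,
                          include_categories = aggression_categories) {
  ids <- if (is.data.frame(subjects)) subjects$animal_id else subjects
  if (anyDuplicated(ids)) stop("duplicated animal ids")
  if (nrow(events) > 0) {
    unknown <- setdiff(unique(c(events$actor, events$recipient)), ids)
    if (length(unknown))
      stop("event id(s) not in subjects: ", paste(unknown, collapse = ", "))
    keep <- events$aggression %in% include_categories
    events <- events[keep, , drop = FALSE]
  }
  counts <- table(factor(events$actor, levels = ids),
                  factor(events$recipient, levels = ids))
  W <- matrix(as.integer(counts), nrow = length(ids),
              dimnames = list(ids, ids))
  diag(W) <- 0L
  W
}

#' Count diarrhea bouts for one animal
#'
#' A bout is a maximal run of consecutive *observation* days with liquid
#' stool; it ends only at an observed day with no liquid stool.  Unobserved
#' days neither extend nor break a run.
#'
#' @param observations data.frame with `date`, `observed`, `liquid_stool`
#'   for a single animal.
#' @return list with `bouts` and `observed_days`.
#' @export
count_diarrhea_bouts <- function(observations) {
  if (is.null(observations) || nrow(observations) == 0)
    return(list(bouts = 0L, observed_days = 0L))
  observations <- observations[order(observations$date), , drop = FALSE]
  obs <- as.logical(observations$observed)
  stool <- as.logical(observations$liquid_stool)
  if (any(stool & !obs, na.rm = TRUE))
    stop("liquid_stool recorded on an unobserved day")
  x <- stool[obs]
  x[is.na(x)] <- FALSE
  bouts <- if (length(x)) with(rle(x), sum(values)) else 0L
  list(bouts = as.integer(bouts), observed_days = as.integer(sum(obs)))
}

#' Age category with adults (6-12 y) as the referent band
#'
#' Bands: juveniles "3", subadults "4-5", adults "6-12", geriatric "13+".
#' Subjects younger than 3 are outside the study population and rejected.
#'
#' @param age_years numeric vector of ages in years.
#' @return character vector of categories.
#' @export
age_category <- function(age_years) {
  if (any(is.na(age_years)) || any(age_years < 3))
    stop("age must be >= 3 years (study population is 3-29 y)")
  cut_pts <- c(3, 4, 6, 13, Inf)
  labels <- c("3", "4-5", "6-12", "13+")
  as.character(cut(age_years, breaks = cut_pts, labels = labels,
                   right = FALSE))
}

#' Factor levels for age category, adults first (referent)
#' @keywords internal
age_levels <- c("6-12", "3", "4-5", "13+")

#' Preprocess biomarker concentrations
#'
#' Cytokine values (IL-6, TNF-alpha) below the assay detection threshold of
#' 1.6 pg/mL are assigned the value 1 (strict comparison: exactly 1.6 is
#' kept).  CRP above 10 is flagged (`crp_over_10`) as a sign of possible
#' infection but the animal is retained.  Adds `age_cat` when absent.
#'
#' @param subjects subject table with `il6`, `tnfa`, `crp` columns (any
#'   subset is allowed; missing columns pass through).
#' @param detection_limit cytokine detection threshold (pg/mL).
#' @param assigned_value value assigned below the threshold.
#' @param crp_flag_threshold CRP level above which the flag is set.
#' @return the subject table with preprocessed biomarkers.
#' @export
preprocess_biomarkers <- function(subjects, detection_limit = 1.6,
                                  assigned_value = 1,
                                  crp_flag_threshold = 10) {
  for (v in intersect(c("il6", "tnfa", "crp"), names(subjects))) {
    x <- subjects[[v]]
    if (any(x < 0, na.rm = TRUE))
      stop("negative ", v, " concentration")
  }
  for (v in intersect(c("il6", "tnfa"), names(subjects))) {
    x <- subjects[[v]]
    x[!is.na(x) & x < detection_limit] <- assigned_value
    subjects[[v]] <- x
  }
  if ("crp" %in% names(subjects))
    subjects$crp_over_10 <- !is.na(subjects$crp) &
      subjects$crp > crp_flag_threshold
  if (!("age_cat" %in% names(subjects)) && "age" %in% names(subjects))
    subjects$age_cat <- age_category(subjects$age)
  subjects
}
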