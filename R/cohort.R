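# Cohort container: one-row-per-subject baseline/survival table plus a
# long-format table of repeated PSA measurements, tied together by subject id.

DOSE_LEVELS    <- c("le50", "51-69", "ge70")
STAGE_LEVELS   <- c("1-2", "3-4")
GLEASON_LEVELS <- c("2-5", "6", "7", "8-10")

LONG_COLS <- c("subject_id", "time_years", "psa_ng_ml")
SURV_COLS <- c("subject_id", "event_time_years", "event", "hormone_therapy",
               "dose_group", "stage_group", "gleason_group", "age_years")

#' Assemble a validated PSA cohort
#'
#' @param subjects Data frame with columns
#'   \code{subject_id, event_time_years, event, hormone_therapy, dose_group,
#'   stage_group, gleason_group, age_years}.  \code{dose_group} takes levels
#'   \code{le50, 51-69, ge70}; \code{stage_group} \code{1-2, 3-4};
#'   \code{gleason_group} \code{2-5, 6, 7, 8-10}; \code{hormone_therapy} and
#'   \code{event} are 0/1.
#' @param observations Data frame with columns
#'   \code{subject_id, time_years, psa_ng_ml} (time in years since end of
#'   radiotherapy).
#' @param transform A [transform_spec()]; applied to every PSA value to
#'   produce the \code{psa_star} column used by the models.
#' @return An object of class \code{psa_cohort}: a list with elements
#'   \code{subjects}, \code{observations} (with \code{psa_star} added) and
#'   \code{transform}.
#' @export
psa_cohort <- function(subjects, observations, transform = transform_spec()) {
  subjects <- as.data.frame(subjects)
  observations <- as.data.frame(observations)
  subjects$subject_id <- as.character(subjects$subject_id)
  observations$subject_id <- as.character(observations$subject_id)
  for (col in c("dose_group", "stage_group", "gleason_group"))
    subjects[[col]] <- as.character(subjects[[col]])
  observations$psa_star <- transform_psa(observations$psa_ng_ml, transform)
  out <- structure(list(subjects = subjects, observations = observations,
                        transform = transform),
                   class = "psa_cohort")
  validate_cohort(out)
  out
}

#' Validate a PSA cohort
#'
#' Checks schema, category levels, positivity, the plausibility range of raw
#' PSA, and the no-observation-after-event invariant.  Each violated rule
#' raises a distinct error listing the offending subject ids or values.
#'
#' @param cohort A [psa_cohort()].
#' @return The cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "psa_cohort"))
  s <- cohort$subjects; o <- cohort$observations
  miss_s <- setdiff(SURV_COLS, names(s))
  if (length(miss_s))
    stop("cohort: survival table is missing column(s): ",
         paste(miss_s, collapse = ", "))
  miss_o <- setdiff(LONG_COLS, names(o))
  if (length(miss_o))
    stop("cohort: longitudinal table is missing column(s): ",
         paste(miss_o, collapse = ", "))
  if (anyDuplicated(s$subject_id))
    stop("cohort: duplicated subject_id(s): ",
         paste(unique(s$subject_id[duplicated(s$subject_id)]), collapse = ", "))
  chk_level <- function(col, levels) {
    bad <- !(s[[col]] %in% levels)
    if (any(bad))
      stop("cohort: unknown ", col, " level(s) '",
           paste(unique(s[[col]][bad]), collapse = "', '"),
           "' for subject(s): ", paste(s$subject_id[bad], collapse = ", "))
  }
  chk_level("dose_group", DOSE_LEVELS)
  chk_level("stage_group", STAGE_LEVELS)
  chk_level("gleason_group", GLEASON_LEVELS)
  if (!all(s$event %in% c(0, 1)) || !all(s$hormone_therapy %in% c(0, 1)))
    stop("cohort: event and hormone_therapy must be 0/1")
  if (any(s$event_time_years <= 0))
    stop("cohort: non-positive event_time_years for subject(s): ",
         paste(s$subject_id[s$event_time_years <= 0], collapse = ", "))
  orphan <- setdiff(o$subject_id, s$subject_id)
  if (length(orphan))
    stop("cohort: observations reference unknown subject(s): ",
         paste(unique(orphan), collapse = ", "))
  noobs <- setdiff(s$subject_id, o$subject_id)
  if (length(noobs))
    stop("cohort: subject(s) with no observations: ",
         paste(noobs, collapse = ", "))
  if (any(o$time_years < 0))
    stop("cohort: negative observation time(s) for subject(s): ",
         paste(unique(o$subject_id[o$time_years < 0]), collapse = ", "))
  rng <- cohort$transform$psa_range
  badpsa <- o$psa_ng_ml <= rng[1] | o$psa_ng_ml > rng[2]
  if (any(badpsa))
    stop("cohort: psa_ng_ml outside plausibility range (", rng[1], ", ",
         rng[2], "] for subject(s): ",
         paste(unique(o$subject_id[badpsa]), collapse = ", "))
  et <- s$event_time_years[match(o$subject_id, s$subject_id)]
  late <- o$time_years > et + 1e-12
  if (any(late))
    stop("cohort: observation(s) after event/censoring time for subject(s): ",
         paste(unique(o$subject_id[late]), collapse = ", "))
  invisible(cohort)
}

#' @export
print.psa_cohort <- function(x, ...) {
  cat("PSA cohort:", nrow(x$subjects), "subjects,",
      nrow(x$observations), "PSA measurements\n")
  cat("  events:", sum(x$subjects$event), sprintf("(%.1f%%)",
      100 * mean(x$subjects$event)), "\n")
  cat("  transform:", x$transform$name,
      if (x$transform$name == "log_shift") sprintf("(shift %g)", x$transform$shift),
      "\n")
  invisible(x)
}

#' Read a cohort from a pair of CSV files
#'
#' Expects a long-format longitudinal file with header
#' \code{subject_id,time_years,psa_ng_ml} and a one-row-per-subject survival
#' file with header \code{subject_id,event_time_years,event,hormone_therapy,
#' dose_group,stage_group,gleason_group,age_years}.  Comma-separated, UTF-8,
#' '.' decimal; missing values in required columns are rejected.
#'
#' @param longitudinal_path,survival_path Paths to the two CSVs.
#' @param transform A [transform_spec()] applied to every PSA value.
#' @return A validated [psa_cohort()].
#' @export
read_cohort <- function(longitudinal_path, survival_path,
                        transform = transform_spec()) {
  for (p in c(longitudinal_path, survival_path))
    if (!file.exists(p)) stop("read_cohort: file not found: ", p)
  lon <- utils::read.csv(longitudinal_path, stringsAsFactors = FALSE)
  sur <- utils::read.csv(survival_path, stringsAsFactors = FALSE)
  if (!identical(names(lon), LONG_COLS))
    stop("read_cohort: longitudinal header must be exactly: ",
         paste(LONG_COLS, collapse = ","))
  if (!identical(names(sur), SURV_COLS))
    stop("read_cohort: survival header must be exactly: ",
         paste(SURV_COLS, collapse = ","))
  if (anyNA(lon) || anyNA(sur))
    stop("read_cohort: missing values are not permitted in required columns")
  psa_cohort(sur, lon, transform)
}

#' Write a cohort to a directory as two CSV files
#'
#' Writes \code{longitudinal.csv} and \code{survival.csv} such that
#' [read_cohort()] restores the cohort exactly (categories/ids) and to
#' within 1e-12 relative error (floats).
#'
#' @param cohort A valid [psa_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  validate_cohort(cohort)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lp <- file.path(dir, "longitudinal.csv")
  sp <- file.path(dir, "survival.csv")
  lon <- cohort$observations[, LONG_COLS]
  sur <- cohort$subjects[, SURV_COLS]
  utils::write.csv(format(lon, digits = 17, trim = TRUE, scientific = FALSE),
                   lp, row.names = FALSE, quote = FALSE)
  utils::write.csv(format(sur, digits = 17, trim = TRUE, scientific = FALSE),
                   sp, row.names = FALSE, quote = FALSE)
  invisible(c(longitudinal = lp, survival = sp))
}
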