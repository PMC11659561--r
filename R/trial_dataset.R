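# Canonical column registry for the participant-eye table: one row per
# eye, demographics repeated on each of a participant's rows. `required`
# columns must be present and non-missing; the rest may be absent or NA.
trial_column_types <- function() {
  list(
    participant_id        = list(type = "character", required = TRUE),
    laterality            = list(type = "character", required = TRUE,
                                 values = c("left", "right")),
    age                   = list(type = "numeric"),
    sex                   = list(type = "character",
                                 values = c("male", "female")),
    race                  = list(type = "character", values = race_categories()),
    ethnicity             = list(type = "character",
                                 values = ethnicity_categories()),
    hba1c                 = list(type = "numeric"),
    etdrs_base            = list(type = "integer", required = TRUE),
    etdrs_modifier        = list(type = "character",
                                 values = c("", LETTERS[1:6])),
    dme_level1            = list(type = "logical", required = TRUE),
    cidme                 = list(type = "logical"),
    csdme                 = list(type = "logical"),
    centerfield_thickness = list(type = "numeric"),
    level2_grade          = list(type = "character",
                                 values = c("detected", "not_detected",
                                            "ungradable")),
    ai_output             = list(type = "character",
                                 values = c("detected", "not_detected",
                                            "insufficient_quality")),
    dilated               = list(type = "logical"),
    n_attempts            = list(type = "integer")
  )
}

#' Demographic category vocabularies
#'
#' Categorical vocabularies for the participant-eye table, matching the
#' enrollment case-report conventions of US screening trials (race as a
#' single self-reported category, ethnicity as Hispanic/non-Hispanic).
#'
#' @return Character vector of allowed category labels.
#' @export
race_categories <- function() {
  c("White", "American Indian or Alaska Native", "Asian",
    "Black or African American", "Latino",
    "Native Hawaiian or Other Pacific Islander", "Refuse to provide",
    "Unknown", "Other", "Mixed Race")
}

#' @rdname race_categories
#' @export
ethnicity_categories <- function() {
  c("Hispanic or Latino", "Not Hispanic or Latino",
    "Unknown or Not Reported")
}

#' Construct and validate a participant-eye trial dataset
#'
#' The central data container: a data frame with one row per eye and
#' demographics repeated across a participant's rows, validated against
#' the column registry. Invariants enforced: at most one row per
#' (participant, laterality) and at most two eyes per participant;
#' demographics identical within participant; `dme_level1` equals
#' `cidme | csdme` wherever both component flags are recorded;
#' `n_attempts` between 1 and 6 (three undilated plus three dilated
#' imaging attempts).
#'
#' @param eyes Data frame of eye rows; see [trial_column_types()] names.
#'   Optional columns are filled with `NA` when absent.
#' @param metadata Named list of provenance information (source, seed,
#'   generator settings); stored as an attribute.
#' @return An object of class `trial_dataset` (also a data frame).
#' @export
trial_dataset <- function(eyes, metadata = list()) {
  eyes <- as.data.frame(eyes, stringsAsFactors = FALSE)
  reg <- trial_column_types()
  req <- names(reg)[vapply(reg, function(x) isTRUE(x$required), logical(1))]
  missing_cols <- setdiff(req, names(eyes))
  if (length(missing_cols)) {
    stop_df("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(eyes), names(reg))
  if (length(unknown)) {
    stop_df("unknown column(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in setdiff(names(reg), names(eyes))) {
    eyes[[nm]] <- rep(switch(reg[[nm]]$type,
                             character = NA_character_,
                             numeric   = NA_real_,
                             integer   = NA_integer_,
                             logical   = NA), nrow(eyes))
  }
  eyes <- eyes[, names(reg)]
  if (nrow(eyes) == 0) {
    return(structure(eyes, class = c("trial_dataset", "data.frame"),
                     metadata = metadata))
  }

  for (nm in names(reg)) {
    spec <- reg[[nm]]
    col <- eyes[[nm]]
    coerced <- switch(spec$type,
                      character = as.character(col),
                      numeric   = as.numeric(col),
                      integer   = as.integer(col),
                      logical   = as.logical(col))
    if (isTRUE(spec$required) && anyNA(coerced)) {
      stop_df("column '", nm, "': missing value at row(s) ",
              paste(utils::head(which(is.na(coerced)), 5), collapse = ", "))
    }
    if (!is.null(spec$values)) {
      bad <- which(!is.na(coerced) & !(coerced %in% spec$values))
      if (length(bad)) {
        stop_df("row ", bad[1], ": column '", nm, "' has unknown value '",
                coerced[bad[1]], "'")
      }
    }
    eyes[[nm]] <- coerced
  }
  check_etdrs_base(eyes$etdrs_base)
  eyes$etdrs_modifier[is.na(eyes$etdrs_modifier)] <- ""

  key <- paste(eyes$participant_id, eyes$laterality)
  if (anyDuplicated(key)) {
    stop_df("duplicate (participant_id, laterality) at row(s) ",
            paste(which(duplicated(key)), collapse = ", "))
  }
  n_eyes <- table(eyes$participant_id)
  if (any(n_eyes > 2)) {
    stop_df("participant(s) with more than two eyes: ",
            paste(names(n_eyes)[n_eyes > 2], collapse = ", "))
  }
  for (nm in c("age", "sex", "race", "ethnicity", "hba1c")) {
    per <- tapply(eyes[[nm]], eyes$participant_id,
                  function(x) length(unique(x)))
    if (any(per > 1)) {
      stop_df("column '", nm, "' differs between eyes of participant(s): ",
              paste(names(per)[per > 1], collapse = ", "))
    }
  }
  both <- !is.na(eyes$cidme) & !is.na(eyes$csdme)
  if (any(both & eyes$dme_level1 != (eyes$cidme | eyes$csdme))) {
    stop_df("dme_level1 inconsistent with cidme/csdme at row(s) ",
            paste(which(both & eyes$dme_level1 != (eyes$cidme | eyes$csdme)),
                  collapse = ", "))
  }
  na_ok <- is.na(eyes$n_attempts)
  if (any(!na_ok & (eyes$n_attempts < 1 | eyes$n_attempts > 6))) {
    stop_df("n_attempts must be between 1 and 6")
  }
  th <- eyes$centerfield_thickness
  if (any(!is.na(th) & th <= 0)) {
    stop_df("centerfield_thickness must be positive")
  }
  structure(eyes, class = c("trial_dataset", "data.frame"),
            metadata = metadata)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %d participants, %d eyes\n",
              n_participants(x), nrow(x)))
  md <- attr(x, "metadata")
  if (length(md)) {
    cat("  metadata:", paste(names(md), vapply(md, function(v)
      paste(format(v), collapse = ","), character(1)),
      sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Dataset dimensions
#' @param ds A [trial_dataset()].
#' @return Integer count.
#' @export
n_participants <- function(ds) length(unique(ds$participant_id))

#' @rdname n_participants
#' @export
n_eyes <- function(ds) nrow(ds)

#' Participant-level demographic table
#'
#' One row per participant, in order of first appearance, with the
#' demographic fields and the number of eyes contributed.
#'
#' @param ds A [trial_dataset()].
#' @return Data frame with one row per participant.
#' @export
participants <- function(ds) {
  first <- !duplicated(ds$participant_id)
  out <- as.data.frame(ds)[first, c("participant_id", "age", "sex", "race",
                                    "ethnicity", "hba1c")]
  out$n_eyes <- as.integer(table(ds$participant_id)[out$participant_id])
  rownames(out) <- NULL
  out
}

participant_ids <- function(ds) unique(ds$participant_id)

# Subset a dataset to the given participants, preserving metadata.
subset_participants <- function(ds, ids) {
  out <- as.data.frame(ds)[ds$participant_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  trial_dataset(out, metadata = attr(ds, "metadata"))
}

#' Participant-level reference positivity (worst-eye rule)
#'
#' A participant is reference-positive when any eye meets the DRD case
#' definition under the chosen reference standard ("worst eye" rule).
#'
#' @param ds A [trial_dataset()].
#' @param reference `"level1"` (prognostic standard: ETDRS + DME flags) or
#'   `"level2"` (reading-center grading of the same images the AI reads).
#' @return Named logical vector, one element per participant (order of
#'   first appearance). Under `"level2"`, participants whose eyes are all
#'   ungradable or ungraded are `NA`.
#' @export
participant_reference_positive <- function(ds, reference = c("level1", "level2")) {
  reference <- match.arg(reference)
  ids <- participant_ids(ds)
  if (reference == "level1") {
    pos <- is_drd_positive(ds$etdrs_base, ds$dme_level1)
    out <- tapply(pos, factor(ds$participant_id, levels = ids), any)
  } else {
    g <- ds$level2_grade
    if (all(is.na(g))) stop_df("no level2_grade labels present")
    val <- ifelse(is.na(g) | g == "ungradable", NA, g == "detected")
    out <- tapply(val, factor(ds$participant_id, levels = ids),
                  function(v) if (all(is.na(v))) NA else any(v, na.rm = TRUE))
  }
  setNames(as.logical(out), ids)
}

#' Participant-level AI output
#'
#' Aggregates per-eye AI outputs to the participant: `detected` if any
#' diagnosable eye is detected; `not_detected` if at least one eye is
#' diagnosable and none detected; `insufficient_quality` only when every
#' eye is insufficient. One diagnosable eye therefore suffices for a
#' participant-level result, consistent with participant diagnosability
#' exceeding eye-level diagnosability.
#'
#' @param ds A [trial_dataset()] whose every eye carries `ai_output`.
#' @return Named character vector, one element per participant.
#' @export
participant_ai_output <- function(ds) {
  if (anyNA(ds$ai_output)) {
    stop_df("ai_output missing for participant(s): ",
            paste(unique(ds$participant_id[is.na(ds$ai_output)])[1:3],
                  collapse = ", "))
  }
  ids <- participant_ids(ds)
  out <- tapply(ds$ai_output, factor(ds$participant_id, levels = ids),
                function(a) {
                  if (any(a == "detected")) "detected"
                  else if (any(a == "not_detected")) "not_detected"
                  else "insufficient_quality"
                })
  setNames(as.character(out), ids)
}

#' Read / write the participant-eye CSV table
#'
#' The on-disk dialect is comma-separated UTF-8 with a header row, one
#' row per eye, missing values as empty fields, and the canonical column
#' names of [trial_column_types()]. `write_trial_table()` followed by
#' `read_trial_table()` is the identity on valid datasets. Malformed
#' rows are reported with their position.
#'
#' @param path File path.
#' @param ds A [trial_dataset()].
#' @return `read_trial_table()` returns a [trial_dataset()];
#'   `write_trial_table()` returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  raw <- read.csv(path, colClasses = "character", na.strings = "",
                  check.names = FALSE, fileEncoding = "UTF-8")
  reg <- trial_column_types()
  unknown <- setdiff(names(raw), names(reg))
  if (length(unknown)) {
    stop_df(path, ": unknown column(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in intersect(names(raw), names(reg))) {
    spec <- reg[[nm]]
    if (spec$type %in% c("numeric", "integer")) {
      v <- raw[[nm]]
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        stop_df(path, ": line ", bad[1] + 1, ": column '", nm,
                "' has non-numeric value '", v[bad[1]], "'")
      }
      raw[[nm]] <- if (spec$type == "integer") as.integer(num) else num
    } else if (spec$type == "logical") {
      v <- toupper(raw[[nm]])
      ok <- is.na(v) | v %in% c("TRUE", "FALSE")
      if (!all(ok)) {
        stop_df(path, ": line ", which(!ok)[1] + 1, ": column '", nm,
                "' has non-logical value '", raw[[nm]][which(!ok)[1]], "'")
      }
      raw[[nm]] <- as.logical(v)
    }
  }
  # modifier of "" round-trips as NA through the empty-field convention
  if ("etdrs_modifier" %in% names(raw)) {
    raw$etdrs_modifier[is.na(raw$etdrs_modifier)] <- ""
  }
  trial_dataset(raw, metadata = list(source = path))
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(ds, path) {
  stopifnot(inherits(ds, "trial_dataset"))
  write.csv(as.data.frame(ds), path, row.names = FALSE, na = "",
            fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' Disposition (waterfall) summary of nested analysis populations
#'
#' Counts participants and eyes at each stage of the trial disposition
#' (enrolled, completed, analyzable) together with stage-to-stage
#' exclusions, as reported in a STARD flow diagram. Later stages must be
#' subsets (by participant id) of earlier stages.
#'
#' @param enrolled,completed,analyzable Nested [trial_dataset()]s.
#' @return Data frame of class `waterfall_summary` with columns `stage`,
#'   `participants`, `eyes`, `excluded_participants`, `excluded_eyes`.
#' @export
waterfall_summary <- function(enrolled, completed, analyzable) {
  stages <- list(enrolled = enrolled, completed = completed,
                 analyzable = analyzable)
  ids <- lapply(stages, participant_ids)
  for (i in 2:3) {
    if (!all(ids[[i]] %in% ids[[i - 1]])) {
      stop_df("'", names(stages)[i], "' is not a subset of '",
              names(stages)[i - 1], "'")
    }
  }
  np <- vapply(stages, n_participants, integer(1))
  ne <- vapply(stages, n_eyes, integer(1))
  out <- data.frame(stage = names(stages), participants = np, eyes = ne,
                    excluded_participants = c(NA, -diff(np)),
                    excluded_eyes = c(NA, -diff(ne)),
                    row.names = NULL)
  class(out) <- c("waterfall_summary", "data.frame")
  out
}

#' @export
print.waterfall_summary <- function(x, ...) {
  cat("Disposition (STARD waterfall):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-10s %4d participants (%4d eyes)", x$stage[i],
                x$participants[i], x$eyes[i]))
    if (!is.na(x$excluded_participants[i])) {
      cat(sprintf("  [excluded: %d participants, %d eyes]",
                  x$excluded_participants[i], x$excluded_eyes[i]))
    }
    cat("\n")
  }
  invisible(x)
}
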