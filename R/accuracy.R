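#' Confusion counts with insufficient-quality cells
#'
#' A six-cell table: TP/FP/FN/TN among diagnosable units plus the counts
#' of insufficient-quality units split by true status. Insufficient
#' units never enter the four accuracy cells unless worst-case imputation
#' is applied explicitly.
#'
#' @param tp,fp,fn,tn Non-negative counts among diagnosable units.
#' @param insufficient_pos,insufficient_neg Insufficient-quality counts
#'   by true status.
#' @param unit,reference Optional provenance labels.
#' @return An object of class `confusion_table`.
#' @seealso [build_table()] to tabulate a dataset, [worst_case_impute()].
#' @export
confusion_counts <- function(tp, fp, fn, tn, insufficient_pos = 0,
                             insufficient_neg = 0, unit = NA_character_,
                             reference = NA_character_) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn,
              insufficient_pos = insufficient_pos,
              insufficient_neg = insufficient_neg)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_df("confusion counts must be non-negative integers")
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 insufficient_pos = insufficient_pos,
                 insufficient_neg = insufficient_neg,
                 unit = unit, reference = reference,
                 n_excluded_ungradable = 0L),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> unit=%s reference=%s\n", x$unit, x$reference))
  cat(sprintf("  tp=%d fp=%d fn=%d tn=%d  insufficient: +%d / -%d  (total %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$insufficient_pos, x$insufficient_neg,
              total_units(x)))
  if (x$n_excluded_ungradable > 0) {
    cat(sprintf("  excluded (Level II ungradable): %d\n",
                x$n_excluded_ungradable))
  }
  invisible(x)
}

total_units <- function(t) {
  t$tp + t$fp + t$fn + t$tn + t$insufficient_pos + t$insufficient_neg
}

# Internal eye-level truth under a reference standard. Level II
# ungradable (or ungraded) eyes are NA and are excluded from tables.
eye_truth <- function(ds, reference) {
  if (reference == "level1") {
    is_drd_positive(ds$etdrs_base, ds$dme_level1)
  } else {
    g <- ds$level2_grade
    if (all(is.na(g))) stop_df("no level2_grade labels in dataset")
    ifelse(is.na(g) | g == "ungradable", NA, g == "detected")
  }
}

#' Build a confusion table from a trial dataset
#'
#' Classifies every unit (eye or participant) into exactly one of the six
#' cells of a [confusion_counts()] table against the chosen reference
#' standard. At the participant level the worst-eye rule defines truth
#' and [participant_ai_output()] defines the index result. Under the
#' Level II reference, units whose reference grade is ungradable are
#' excluded and counted in `n_excluded_ungradable`.
#'
#' @param ds A [trial_dataset()] with `ai_output` on every eye.
#' @param unit `"eye"` or `"participant"`.
#' @param reference `"level1"` or `"level2"`.
#' @return A `confusion_table`.
#' @export
build_table <- function(ds, unit = c("eye", "participant"),
                        reference = c("level1", "level2")) {
  unit <- match.arg(unit)
  reference <- match.arg(reference)
  if (anyNA(ds$ai_output)) {
    stop_df("ai_output missing for eye(s) of participant(s): ",
            paste(utils::head(unique(ds$participant_id[is.na(ds$ai_output)]), 3),
                  collapse = ", "))
  }
  if (unit == "eye") {
    truth <- eye_truth(ds, reference)
    res <- ds$ai_output
  } else {
    truth <- participant_reference_positive(ds, reference)
    res <- participant_ai_output(ds)
  }
  keep <- !is.na(truth)
  n_ungr <- sum(!keep)
  truth <- truth[keep]
  res <- res[keep]
  ins <- res == "insufficient_quality"
  det <- res == "detected"
  out <- confusion_counts(
    tp = sum(truth & det & !ins), fp = sum(!truth & det & !ins),
    fn = sum(truth & !det & !ins), tn = sum(!truth & !det & !ins),
    insufficient_pos = sum(truth & ins), insufficient_neg = sum(!truth & ins),
    unit = unit, reference = reference)
  out$n_excluded_ungradable <- n_ungr
  out
}

metric_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined: empty margin", call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Accuracy metrics of a confusion table
#'
#' Sensitivity `tp/(tp+fn)` and specificity `tn/(tn+fp)` among
#' diagnosable units; predictive values `tp/(tp+fp)`, `tn/(tn+fn)`; and
#' likelihood ratios `PLR = sens/(1-spec)`, `NLR = (1-sens)/spec`.
#' Insufficient-quality counts are excluded throughout. Empty margins
#' yield `NA` with a warning, never silent zero.
#'
#' @param t A `confusion_table`.
#' @return A ratio (or named pair for the paired accessors).
#' @export
sensitivity <- function(t) metric_ratio(t$tp, t$tp + t$fn, "sensitivity")

#' @rdname sensitivity
#' @export
specificity <- function(t) metric_ratio(t$tn, t$tn + t$fp, "specificity")

#' @rdname sensitivity
#' @export
predictive_values <- function(t) {
  c(ppv = metric_ratio(t$tp, t$tp + t$fp, "ppv"),
    npv = metric_ratio(t$tn, t$tn + t$fn, "npv"))
}

#' @rdname sensitivity
#' @export
likelihood_ratios <- function(t) {
  se <- sensitivity(t)
  sp <- specificity(t)
  plr <- if (is.na(se) || is.na(sp)) NA_real_
         else metric_ratio(se, 1 - sp, "plr")
  nlr <- if (is.na(se) || is.na(sp)) NA_real_
         else metric_ratio(1 - se, sp, "nlr")
  c(plr = plr, nlr = nlr)
}

#' Diagnosability
#'
#' Fraction of units whose AI output is a disease-level result rather
#' than insufficient quality. At the participant level a single
#' diagnosable eye suffices (see [participant_ai_output()]).
#'
#' @param ds A [trial_dataset()].
#' @param unit `"eye"` or `"participant"`.
#' @return Ratio in \[0, 1\].
#' @export
diagnosability <- function(ds, unit = c("eye", "participant")) {
  unit <- match.arg(unit)
  out <- if (unit == "eye") ds$ai_output else participant_ai_output(ds)
  if (anyNA(out)) stop_df("ai_output missing")
  mean(out != "insufficient_quality")
}

#' Worst-case imputation of insufficient-quality units
#'
#' Reassigns every insufficient-quality diseased unit as a false
#' negative and every insufficient-quality non-diseased unit as a false
#' positive, zeroing the insufficient cells. The total is preserved and
#' neither sensitivity nor specificity can increase.
#'
#' @param t A `confusion_table`.
#' @return A `confusion_table` with the insufficient counts folded in.
#' @export
worst_case_impute <- function(t) {
  out <- t
  out$fn <- t$fn + t$insufficient_pos
  out$fp <- t$fp + t$insufficient_neg
  out$insufficient_pos <- 0L
  out$insufficient_neg <- 0L
  out
}

#' Full accuracy summary for a dataset
#'
#' Convenience wrapper computing the confusion table and all derived
#' metrics at the chosen unit/reference, optionally after worst-case
#' imputation.
#'
#' @inheritParams build_table
#' @param worst_case Apply [worst_case_impute()] before computing
#'   metrics.
#' @return An object of class `accuracy_summary`.
#' @export
accuracy_summary <- function(ds, unit = c("eye", "participant"),
                             reference = c("level1", "level2"),
                             worst_case = FALSE) {
  unit <- match.arg(unit)
  reference <- match.arg(reference)
  tab <- build_table(ds, unit, reference)
  if (worst_case) tab <- worst_case_impute(tab)
  pv <- suppressWarnings(predictive_values(tab))
  lr <- suppressWarnings(likelihood_ratios(tab))
  structure(list(
    sensitivity = suppressWarnings(sensitivity(tab)),
    specificity = suppressWarnings(specificity(tab)),
    ppv = pv[["ppv"]], npv = pv[["npv"]],
    plr = lr[["plr"]], nlr = lr[["nlr"]],
    diagnosability = diagnosability(ds, unit),
    n_units = total_units(tab), unit = unit, reference = reference,
    worst_case = worst_case, table = tab
  ), class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf("Accuracy (%s level, %s reference%s; n = %d)\n", x$unit,
              x$reference, if (x$worst_case) ", worst-case imputed" else "",
              x$n_units))
  cat(sprintf("  sensitivity   %s\n", fmt_pct(x$sensitivity)))
  cat(sprintf("  specificity   %s\n", fmt_pct(x$specificity)))
  cat(sprintf("  PPV / NPV     %s / %s\n", fmt_pct(x$ppv), fmt_pct(x$npv)))
  cat(sprintf("  PLR / NLR     %.2f / %.2f\n", x$plr, x$nlr))
  cat(sprintf("  diagnosability %s\n", fmt_pct(x$diagnosability)))
  invisible(x)
}
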