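#' Non-inferiority hypothesis specification
#'
#' One-sided non-inferiority margins for the two co-primary endpoints:
#' `H0: p < p0` against `HA: p >= p0`, with `p0 = 0.75` for sensitivity
#' and `p0 = 0.775` for specificity, tested at one-sided alpha 0.025.
#' Study success requires both nulls to be rejected. `point_thresholds`
#' carries the 80%/80% regulatory clearance reference points.
#'
#' @param p0_sensitivity,p0_specificity Null (inferiority) margins.
#' @param alpha_one_sided One-sided type-I error.
#' @param point_thresholds Named clearance reference points.
#' @return A list of class `ni_hypothesis`.
#' @export
ni_hypothesis <- function(p0_sensitivity = 0.75, p0_specificity = 0.775,
                          alpha_one_sided = 0.025,
                          point_thresholds = c(sensitivity = 0.80,
                                               specificity = 0.80)) {
  stopifnot(p0_sensitivity > 0, p0_specificity > 0,
            p0_sensitivity < point_thresholds[["sensitivity"]],
            p0_specificity < point_thresholds[["specificity"]],
            alpha_one_sided > 0, alpha_one_sided < 0.5)
  structure(list(p0_sensitivity = p0_sensitivity,
                 p0_specificity = p0_specificity,
                 alpha_one_sided = alpha_one_sided,
                 point_thresholds = point_thresholds),
            class = "ni_hypothesis")
}

#' Bootstrap settings
#'
#' Settings for the participant-clustered bootstrap: number of
#' replicates, seed, whether each replicate is spectrum-expanded (extra
#' participants carrying vision-threatening disease appended until the
#' vtDRD share of DRD-positive eyes reaches `spectrum_target`), and the
#' one-sided confidence level of the reported lower bound.
#'
#' @param n_replicates Bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param spectrum_target Target fraction of Level-I DRD-positive eyes
#'   that are vtDRD, in (0, 1).
#' @param expand_spectrum Apply spectrum expansion within each replicate.
#' @param bound_level One-sided confidence level of the lower bound.
#' @return A list of class `bootstrap_settings`.
#' @export
bootstrap_settings <- function(n_replicates = 10000L, seed = 1L,
                               spectrum_target = 0.20,
                               expand_spectrum = TRUE,
                               bound_level = 0.975) {
  stopifnot(n_replicates >= 100, spectrum_target > 0, spectrum_target < 1,
            bound_level > 0.5, bound_level < 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 spectrum_target = spectrum_target,
                 expand_spectrum = isTRUE(expand_spectrum),
                 bound_level = bound_level),
            class = "bootstrap_settings")
}

#' Resample whole participants with replacement
#'
#' The elementary step of the clustered bootstrap: participants (each a
#' cluster of one or two eyes) are drawn with replacement to the original
#' participant count; a drawn participant always carries all its eyes, so
#' inter-eye correlation is preserved. Duplicated draws receive
#' disambiguated participant ids. Uses the current RNG state.
#'
#' @param ds A non-empty [trial_dataset()].
#' @return A [trial_dataset()] with the same participant count.
#' @export
cluster_resample <- function(ds) {
  ids <- participant_ids(ds)
  if (length(ids) == 0) stop_df("cannot resample an empty dataset")
  rows_by <- split(seq_len(nrow(ds)), factor(ds$participant_id, levels = ids))
  draw <- sample.int(length(ids), length(ids), replace = TRUE)
  rows <- unlist(rows_by[draw], use.names = FALSE)
  out <- as.data.frame(ds)[rows, , drop = FALSE]
  out$participant_id <- paste0(out$participant_id, ".",
                               rep(seq_along(draw), lengths(rows_by)[draw]))
  rownames(out) <- NULL
  trial_dataset(out, metadata = attr(ds, "metadata"))
}

vt_pos_counts <- function(ds) {
  pos <- is_drd_positive(ds$etdrs_base, ds$dme_level1)
  vt <- is_vtdrd(ds$etdrs_base, ds$dme_level1)
  list(pos = pos, vt = vt)
}

#' Expand the disease spectrum of a dataset
#'
#' Counteracts disease-spectrum bias by appending whole participants who
#' carry at least one vision-threatening (vtDRD) eye, drawn with
#' replacement from the dataset's carriers, until the fraction of
#' Level-I DRD-positive eyes that are vtDRD first reaches or exceeds
#' `target`. A dataset already at or above target is returned unchanged.
#' Uses the current RNG state.
#'
#' @param ds A [trial_dataset()].
#' @param target Target vtDRD share of DRD-positive eyes.
#' @return A [trial_dataset()], possibly with appended participants
#'   carrying disambiguated ids.
#' @export
spectrum_expand <- function(ds, target = 0.20) {
  stopifnot(target > 0, target < 1)
  cn <- vt_pos_counts(ds)
  n_pos <- sum(cn$pos)
  n_vt <- sum(cn$vt)
  if (n_pos > 0 && n_vt / n_pos >= target) return(ds)
  carrier_ids <- unique(ds$participant_id[cn$vt])
  if (length(carrier_ids) == 0) {
    stop_df("spectrum expansion impossible: no vtDRD carrier participants")
  }
  df <- as.data.frame(ds)
  extra <- list()
  k <- 0
  while (n_pos == 0 || n_vt / n_pos < target) {
    k <- k + 1
    id <- carrier_ids[sample.int(length(carrier_ids), 1)]
    add <- df[df$participant_id == id, , drop = FALSE]
    add$participant_id <- paste0(id, ".x", k)
    extra[[k]] <- add
    n_pos <- n_pos + sum(is_drd_positive(add$etdrs_base, add$dme_level1))
    n_vt <- n_vt + sum(is_vtdrd(add$etdrs_base, add$dme_level1))
  }
  out <- rbind(df, do.call(rbind, extra))
  rownames(out) <- NULL
  trial_dataset(out, metadata = attr(ds, "metadata"))
}

# Per-participant sufficient statistics for the fast bootstrap path:
# a matrix with one row per participant and columns tp, fn, fp, tn
# (diagnosable units at the chosen unit/reference), pos_eyes and
# vt_eyes (Level-I counts driving spectrum expansion).
participant_stats <- function(ds, unit, reference) {
  ids <- participant_ids(ds)
  fac <- factor(ds$participant_id, levels = ids)
  cn <- vt_pos_counts(ds)
  pos_eyes <- tapply(cn$pos, fac, sum)
  vt_eyes <- tapply(cn$vt, fac, sum)
  if (unit == "eye") {
    truth <- eye_truth(ds, reference)
    ins <- ds$ai_output == "insufficient_quality"
    det <- ds$ai_output == "detected"
    cell <- function(v) as.vector(tapply(v, fac, sum))
    keep <- !is.na(truth)
    z <- function(x) ifelse(keep, x, FALSE)
    m <- cbind(tp = cell(z(truth & det & !ins)),
               fn = cell(z(truth & !det & !ins)),
               fp = cell(z(!truth & det & !ins)),
               tn = cell(z(!truth & !det & !ins)))
  } else {
    truth <- participant_reference_positive(ds, reference)
    res <- participant_ai_output(ds)
    ins <- res == "insufficient_quality"
    det <- res == "detected"
    keep <- !is.na(truth)
    z <- function(x) as.numeric(keep & !is.na(x) & x)
    m <- cbind(tp = z(truth & det & !ins), fn = z(truth & !det & !ins),
               fp = z(!truth & det & !ins), tn = z(!truth & !det & !ins))
  }
  cbind(m, pos_eyes = as.vector(pos_eyes), vt_eyes = as.vector(vt_eyes))
}

# One clustered-bootstrap replicate on the sufficient-statistics matrix:
# resample participant multiplicities, optionally append vt carriers
# drawn from the replicate itself until the spectrum target is crossed,
# and return the six summed statistics. NULL marks a degenerate
# replicate (expansion required but no carriers drawn).
boot_replicate_sums <- function(stats, carriers, expand, target) {
  n <- nrow(stats)
  idx <- sample.int(n, n, replace = TRUE)
  cnt <- tabulate(idx, n)
  sums <- colSums(stats * cnt)
  if (expand && sums[["pos_eyes"]] > 0 &&
      sums[["vt_eyes"]] / sums[["pos_eyes"]] < target) {
    rep_carriers <- intersect(unique(idx), carriers)
    if (length(rep_carriers) == 0) return(NULL)
    while (sums[["vt_eyes"]] / sums[["pos_eyes"]] < target) {
      j <- rep_carriers[sample.int(length(rep_carriers), 1)]
      sums <- sums + stats[j, ]
    }
  }
  sums
}

#' Clustered-bootstrap non-inferiority analysis of an accuracy metric
#'
#' The primary analysis: `n_replicates` participant-clustered bootstrap
#' replicates of the dataset, each optionally spectrum-expanded, with the
#' metric recomputed per replicate. Reports the empirical one-sided
#' lower confidence bound (the `1 - bound_level` percentile of the
#' replicate distribution) and an add-one-smoothed bootstrap
#' non-inferiority p-value `(1 + #{replicates <= p0}) / (B + 1)`.
#' Replicates with an undefined metric (empty margin) are excluded and
#' counted; more than 10% degenerate replicates is an error. Fully
#' reproducible under `settings$seed`.
#'
#' @param ds A [trial_dataset()].
#' @param metric `"sensitivity"` or `"specificity"`.
#' @param unit,reference As in [build_table()].
#' @param settings A [bootstrap_settings()].
#' @param hypothesis A [ni_hypothesis()]; supplies `p0` for the metric.
#' @return An object of class `bootstrap_result` with the point
#'   estimate, replicate values, lower bound and p-value.
#' @export
bootstrap_metric <- function(ds, metric = c("sensitivity", "specificity"),
                             unit = c("eye", "participant"),
                             reference = c("level1", "level2"),
                             settings = bootstrap_settings(),
                             hypothesis = ni_hypothesis()) {
  metric <- match.arg(metric)
  unit <- match.arg(unit)
  reference <- match.arg(reference)
  stopifnot(inherits(settings, "bootstrap_settings"),
            inherits(hypothesis, "ni_hypothesis"))
  tab <- build_table(ds, unit, reference)
  point <- if (metric == "sensitivity") sensitivity(tab) else specificity(tab)
  if (is.na(point)) stop_df("metric undefined on the full dataset")
  p0 <- if (metric == "sensitivity") hypothesis$p0_sensitivity
        else hypothesis$p0_specificity

  stats <- participant_stats(ds, unit, reference)
  carriers <- which(stats[, "vt_eyes"] > 0)
  num_col <- if (metric == "sensitivity") "tp" else "tn"
  den_cols <- if (metric == "sensitivity") c("tp", "fn") else c("tn", "fp")

  B <- settings$n_replicates
  set.seed(settings$seed)
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    sums <- boot_replicate_sums(stats, carriers, settings$expand_spectrum,
                                settings$spectrum_target)
    if (is.null(sums)) next
    den <- sum(sums[den_cols])
    if (den > 0) reps[b] <- sums[[num_col]] / den
  }
  excluded <- sum(is.na(reps))
  if (excluded > 0.1 * B) {
    stop_df("bootstrap degenerate: ", excluded, " of ", B,
            " replicates had an undefined ", metric,
            " (empty margin); the dataset is too sparse for this analysis")
  }
  reps <- reps[!is.na(reps)]
  lower <- unname(quantile(reps, 1 - settings$bound_level, type = 1))
  ni_p <- (1 + sum(reps <= p0)) / (length(reps) + 1)
  structure(list(metric = metric, unit = unit, reference = reference,
                 point_estimate = point, replicate_values = reps,
                 lower_bound = lower, ni_p_value = ni_p, p0 = p0,
                 n_excluded_replicates = excluded, settings = settings),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%s (%s level, %s reference): %s (one-sided %s lower bound: %s)\n",
              x$metric, x$unit, x$reference, fmt_pct(x$point_estimate),
              fmt_pct(x$settings$bound_level), fmt_pct(x$lower_bound)))
  cat(sprintf("  non-inferiority vs p0 = %s: p = %.4g  (%d replicates%s)\n",
              fmt_pct(x$p0), x$ni_p_value, length(x$replicate_values),
              if (x$n_excluded_replicates > 0)
                sprintf(", %d degenerate excluded", x$n_excluded_replicates)
              else ""))
  invisible(x)
}

#' Study-level success
#'
#' The trial succeeds only when both co-primary null hypotheses
#' (sensitivity and specificity inferiority) are rejected at the
#' one-sided alpha.
#'
#' @param sensitivity_result,specificity_result [bootstrap_metric()]
#'   results computed at matching settings.
#' @param hypothesis A [ni_hypothesis()].
#' @return Logical scalar.
#' @export
study_success <- function(sensitivity_result, specificity_result,
                          hypothesis = ni_hypothesis()) {
  stopifnot(inherits(sensitivity_result, "bootstrap_result"),
            inherits(specificity_result, "bootstrap_result"))
  if (sensitivity_result$metric != "sensitivity" ||
      specificity_result$metric != "specificity") {
    stop_df("results must be a sensitivity and a specificity bootstrap")
  }
  s1 <- sensitivity_result$settings
  s2 <- specificity_result$settings
  same <- identical(s1$n_replicates, s2$n_replicates) &&
    identical(s1$spectrum_target, s2$spectrum_target) &&
    identical(s1$expand_spectrum, s2$expand_spectrum) &&
    identical(s1$bound_level, s2$bound_level)
  if (!same) stop_df("mismatched bootstrap settings between endpoints")
  sensitivity_result$ni_p_value < hypothesis$alpha_one_sided &&
    specificity_result$ni_p_value < hypothesis$alpha_one_sided
}

# Fixed-margin design dataset used by the power simulation: n_pos
# DRD-positive eyes of which n_vt are vtDRD (ETDRS 60), n_neg negative
# eyes (ETDRS 20), shuffled into two-eye participants.
design_dataset <- function(n_pos_eyes, n_vt_min, n_neg_eyes,
                           true_sensitivity, true_specificity) {
  base <- c(rep(60L, n_vt_min), rep(35L, n_pos_eyes - n_vt_min),
            rep(20L, n_neg_eyes))
  modifier <- ifelse(base == 35L, "F", "")
  ord <- sample.int(length(base))
  base <- base[ord]
  modifier <- modifier[ord]
  m <- length(base)
  pid <- sprintf("D%04d", rep(seq_len(ceiling(m / 2)), each = 2)[seq_len(m)])
  lat <- rep(c("right", "left"), length.out = m)
  truth <- base >= 35
  det <- runif(m) < ifelse(truth, true_sensitivity, 1 - true_specificity)
  trial_dataset(data.frame(
    participant_id = pid, laterality = lat, etdrs_base = base,
    etdrs_modifier = modifier, dme_level1 = FALSE,
    ai_output = ifelse(det, "detected", "not_detected"),
    stringsAsFactors = FALSE), metadata = list(source = "design simulation"))
}

#' Design power simulation
#'
#' Simulates repeated trials at the design sample sizes (positive eyes
#' including a minimum vision-threatening stratum, plus negative eyes) at
#' a hypothesised true operating point, runs the full clustered-bootstrap
#' non-inferiority analysis on each, and reports the fraction of trials
#' rejecting each null and achieving study success, with Monte Carlo
#' standard errors.
#'
#' @param n_trials Number of simulated trials (>= 1; hundreds
#'   recommended).
#' @param true_sensitivity,true_specificity Assumed true operating point.
#' @param n_pos_eyes,n_vt_min,n_neg_eyes Design counts: DRD-positive
#'   eyes, minimum vtDRD eyes among them, and negative eyes.
#' @param hypothesis A [ni_hypothesis()].
#' @param settings A [bootstrap_settings()]; its seed and per-trial
#'   derived seeds drive all randomness.
#' @return List of class `power_result` with per-endpoint and
#'   study-level power estimates.
#' @export
power_simulation <- function(n_trials, true_sensitivity = 0.85,
                             true_specificity = 0.90,
                             n_pos_eyes = 200L, n_vt_min = 20L,
                             n_neg_eyes = 140L,
                             hypothesis = ni_hypothesis(),
                             settings = bootstrap_settings(n_replicates = 500L)) {
  if (!is.numeric(n_trials) || n_trials < 1) {
    stop_df("n_trials must be a positive integer")
  }
  n_trials <- as.integer(n_trials)
  rej <- matrix(FALSE, n_trials, 2,
                dimnames = list(NULL, c("sensitivity", "specificity")))
  for (t in seq_len(n_trials)) {
    set.seed(derive_seed(settings$seed, t))
    ds <- design_dataset(n_pos_eyes, n_vt_min, n_neg_eyes,
                         true_sensitivity, true_specificity)
    st <- bootstrap_settings(n_replicates = settings$n_replicates,
                             seed = derive_seed(settings$seed, t + 1000000),
                             spectrum_target = settings$spectrum_target,
                             expand_spectrum = settings$expand_spectrum,
                             bound_level = settings$bound_level)
    bs <- bootstrap_metric(ds, "sensitivity", "eye", "level1", st, hypothesis)
    bp <- bootstrap_metric(ds, "specificity", "eye", "level1", st, hypothesis)
    rej[t, ] <- c(bs$ni_p_value, bp$ni_p_value) < hypothesis$alpha_one_sided
  }
  pw <- colMeans(rej)
  both <- mean(rej[, 1] & rej[, 2])
  mc_se <- sqrt(both * (1 - both) / n_trials)
  structure(list(power_sensitivity = pw[["sensitivity"]],
                 power_specificity = pw[["specificity"]],
                 power_study = both, mc_se = mc_se, n_trials = n_trials),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Power over %d simulated trials: sensitivity %.3f, specificity %.3f, study %.3f (MC se %.3f)\n",
    x$n_trials, x$power_sensitivity, x$power_specificity, x$power_study,
    x$mc_se))
  invisible(x)
}
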