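#' Two-level subgroup contrast specification
#'
#' Defines the partition used by the bias audit. Built-in contrasts
#' mirror the trial's prespecified subgroup analyses: sex (male vs
#' female), race (Black vs non-Black) and ethnicity (Hispanic vs
#' non-Hispanic, with unknown/not-reported excluded). A custom contrast
#' supplies a function mapping the [participants()] table to the two
#' labels (or `NA` to exclude).
#'
#' @param attribute `"sex"`, `"race"`, `"ethnicity"` or `"custom"`.
#' @param min_n Minimum participants per group below which results are
#'   suppressed entirely (the reporting rule; default 10).
#' @param partition For `"custom"`: `function(participants_df)` returning
#'   a character vector over `labels` (or `NA`).
#' @param labels For `"custom"`: the two group labels.
#' @return An object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(attribute = c("sex", "race", "ethnicity", "custom"),
                          min_n = 10L, partition = NULL, labels = NULL) {
  attribute <- match.arg(attribute)
  stopifnot(min_n >= 1)
  if (attribute == "sex") {
    labels <- c("male", "female")
    partition <- function(p) ifelse(is.na(p$sex), NA, p$sex)
  } else if (attribute == "race") {
    labels <- c("Black", "non-Black")
    partition <- function(p) ifelse(is.na(p$race), NA,
                                    ifelse(p$race == "Black or African American",
                                           "Black", "non-Black"))
  } else if (attribute == "ethnicity") {
    labels <- c("Hispanic", "non-Hispanic")
    partition <- function(p) ifelse(is.na(p$ethnicity) |
                                      p$ethnicity == "Unknown or Not Reported",
                                    NA,
                                    ifelse(p$ethnicity == "Hispanic or Latino",
                                           "Hispanic", "non-Hispanic"))
  } else {
    if (!is.function(partition) || length(labels) != 2) {
      stop_df("custom contrast needs a partition function and two labels")
    }
  }
  structure(list(attribute = attribute, labels = labels,
                 partition = partition, min_n = as.integer(min_n)),
            class = "subgroup_spec")
}

assign_groups <- function(ds, spec) {
  p <- participants(ds)
  g <- spec$partition(p)
  bad <- !is.na(g) & !(g %in% spec$labels)
  if (any(bad)) stop_df("partition returned values outside the group labels")
  setNames(g, p$participant_id)
}

#' Per-subgroup accuracy
#'
#' Computes the accuracy metric within each cell of a two-level
#' participant partition. Groups below `min_n` participants are
#' suppressed (no estimates retained), per the minimum-subgroup
#' reporting rule.
#'
#' @param ds A [trial_dataset()].
#' @param spec A [subgroup_spec()].
#' @param metric `"sensitivity"` or `"specificity"` (used for display;
#'   the full [accuracy_summary()] is computed per group).
#' @param unit,reference As in [build_table()].
#' @return List with per-group summaries, participant counts and
#'   `reported` flags.
#' @export
subgroup_accuracy <- function(ds, spec, metric = c("sensitivity", "specificity"),
                              unit = "eye", reference = "level1") {
  metric <- match.arg(metric)
  g <- assign_groups(ds, spec)
  n_by <- vapply(spec$labels, function(l) sum(g == l, na.rm = TRUE), integer(1))
  reported <- n_by >= spec$min_n
  groups <- lapply(spec$labels, function(l) {
    if (!reported[[l]] || n_by[[l]] == 0) return(NULL)
    accuracy_summary(subset_participants(ds, names(g)[!is.na(g) & g == l]),
                     unit, reference)
  })
  names(groups) <- spec$labels
  list(metric = metric, groups = groups, n = n_by, reported = reported,
       spec = spec)
}

#' Clustered-bootstrap subgroup bias test
#'
#' Two-sided test of a metric difference between the two cells of a
#' participant partition. Participants are resampled with replacement
#' (clusters intact, groups pooled so group sizes vary as they would in
#' repeated sampling); the p-value is twice the add-one-smoothed
#' fraction of replicate differences on the opposite side of zero from
#' the observed difference, capped at 1, unadjusted for multiple
#' comparisons. Groups below `min_n` yield a fully suppressed report.
#' Spectrum expansion is not applied: the contrast compares subgroups of
#' the realised sample.
#'
#' @inheritParams subgroup_accuracy
#' @param settings A [bootstrap_settings()] (seed and replicate count;
#'   `expand_spectrum` is ignored here).
#' @return An object of class `bias_report`.
#' @export
bias_test <- function(ds, spec, metric = c("sensitivity", "specificity"),
                      unit = "eye", reference = "level1",
                      settings = bootstrap_settings()) {
  metric <- match.arg(metric)
  g <- assign_groups(ds, spec)
  n_by <- vapply(spec$labels, function(l) sum(g == l, na.rm = TRUE), integer(1))
  blank <- structure(list(metric = metric, spec = spec, n = n_by,
                          group_estimates = NULL, difference = NA_real_,
                          p_value = NA_real_, reported = FALSE,
                          settings = settings),
                     class = "bias_report")
  if (any(n_by < spec$min_n)) return(blank)

  stats <- participant_stats(ds, unit, reference)
  gvec <- g[participant_ids(ds)]
  num_col <- if (metric == "sensitivity") "tp" else "tn"
  den_cols <- if (metric == "sensitivity") c("tp", "fn") else c("tn", "fp")
  mask <- cbind(!is.na(gvec) & gvec == spec$labels[1],
                !is.na(gvec) & gvec == spec$labels[2])
  grp_metric <- function(cnt, k) {
    s <- colSums(stats * (cnt * mask[, k]))
    den <- sum(s[den_cols])
    if (den == 0) NA_real_ else s[[num_col]] / den
  }
  n <- nrow(stats)
  ones <- rep(1, n)
  est <- c(grp_metric(ones, 1), grp_metric(ones, 2))
  if (anyNA(est)) {
    stop_df("metric undefined in a subgroup on the full dataset")
  }
  d_obs <- est[1] - est[2]

  B <- settings$n_replicates
  set.seed(settings$seed)
  d_rep <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    cnt <- tabulate(sample.int(n, n, replace = TRUE), n)
    d_rep[b] <- grp_metric(cnt, 1) - grp_metric(cnt, 2)
  }
  excluded <- sum(is.na(d_rep))
  if (excluded > 0.1 * B) {
    stop_df("bias bootstrap degenerate: ", excluded, " of ", B,
            " replicates had an undefined subgroup metric")
  }
  d_rep <- d_rep[!is.na(d_rep)]
  p <- if (d_obs == 0) 1 else {
    min(1, 2 * (1 + sum(d_rep * sign(d_obs) <= 0)) / (length(d_rep) + 1))
  }
  structure(list(metric = metric, spec = spec, n = n_by,
                 group_estimates = setNames(est, spec$labels),
                 difference = d_obs, p_value = p, reported = TRUE,
                 n_excluded_replicates = excluded, settings = settings),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  header <- sprintf("%s: %s vs %s", x$metric, x$spec$labels[1],
                    x$spec$labels[2])
  if (!x$reported) {
    cat(header, "- not reported (n<", x$spec$min_n, ")\n")
    return(invisible(x))
  }
  cat(sprintf("%s: %s (n=%d) vs %s (n=%d); difference %+.3f, p = %.3f\n",
              header, fmt_pct(x$group_estimates[1]), x$n[1],
              fmt_pct(x$group_estimates[2]), x$n[2], x$difference,
              x$p_value))
  invisible(x)
}

intersect_spec <- function(spec_a, la, spec_b, lb, min_n) {
  pa <- spec_a$partition
  pb <- spec_b$partition
  subgroup_spec(
    "custom", min_n = min_n,
    labels = c(paste0(spec_a$attribute, "=", la, "&", spec_b$attribute, "=", lb),
               "complement"),
    partition = function(p) {
      ga <- pa(p)
      gb <- pb(p)
      ifelse(is.na(ga) | is.na(gb), NA,
             ifelse(ga == la & gb == lb,
                    paste0(spec_a$attribute, "=", la, "&",
                           spec_b$attribute, "=", lb),
                    "complement"))
    })
}

#' Intersectional bias audit
#'
#' Runs [bias_test()] for each supplied attribute contrast and, for every
#' pair of contrasts, for each of the four intersection cells against its
#' complement. Cells below the minimum-subgroup rule are returned as
#' suppressed reports.
#'
#' @param ds A [trial_dataset()].
#' @param specs List of at least two [subgroup_spec()]s.
#' @param metrics Metrics to audit.
#' @param unit,reference As in [build_table()].
#' @param settings A [bootstrap_settings()]; each report gets a derived
#'   seed so the audit is reproducible as a whole.
#' @return Named list of `bias_report`s.
#' @export
intersectional_audit <- function(ds, specs,
                                 metrics = c("sensitivity", "specificity"),
                                 unit = "eye", reference = "level1",
                                 settings = bootstrap_settings()) {
  if (!is.list(specs) || length(specs) < 2) {
    stop_df("an intersectional audit needs at least two subgroup specs")
  }
  reports <- list()
  k <- 0
  add <- function(name, spec, metric) {
    k <<- k + 1
    st <- bootstrap_settings(n_replicates = settings$n_replicates,
                             seed = derive_seed(settings$seed, k),
                             spectrum_target = settings$spectrum_target,
                             expand_spectrum = settings$expand_spectrum,
                             bound_level = settings$bound_level)
    reports[[paste(metric, name, sep = ":")]] <<-
      bias_test(ds, spec, metric, unit, reference, st)
  }
  for (metric in metrics) {
    for (sp in specs) add(sp$attribute, sp, metric)
    for (i in seq_len(length(specs) - 1)) {
      for (j in seq((i + 1), length(specs))) {
        for (la in specs[[i]]$labels) {
          for (lb in specs[[j]]$labels) {
            spx <- intersect_spec(specs[[i]], la, specs[[j]], lb,
                                  min(specs[[i]]$min_n, specs[[j]]$min_n))
            add(spx$labels[1], spx, metric)
          }
        }
      }
    }
  }
  reports
}
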