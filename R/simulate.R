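#' Default demographic mix for the synthetic generator
#'
#' Marginal demographic distribution of the analyzable trial population:
#' 50.8% male, 45.7% Hispanic, 17.3% Black, age mean 54.1 (sd 12.0)
#' years, HbA1c mean 10.0% (sd 1.99).
#'
#' @return Named list of demographic parameters.
#' @export
default_demographics <- function() {
  list(
    p_male = 0.508,
    race_probs = c("White" = 0.679, "Black or African American" = 0.173,
                   "Asian" = 0.062, "American Indian or Alaska Native" = 0.023,
                   "Latino" = 0.038,
                   "Native Hawaiian or Other Pacific Islander" = 0.011,
                   "Mixed Race" = 0.009, "Other" = 0.004, "Unknown" = 0.001),
    ethnicity_probs = c("Hispanic or Latino" = 0.457,
                        "Not Hispanic or Latino" = 0.536,
                        "Unknown or Not Reported" = 0.007),
    age_mean = 54.1, age_sd = 12.0,
    hba1c_mean = 10.0, hba1c_sd = 1.99
  )
}

#' Default ETDRS severity weights
#'
#' Empirical level frequencies of the 1073-eye analyzable set, used as
#' the generator's severity distribution.
#'
#' @return Data frame with columns `base`, `modifier`, `weight`.
#' @export
paper_etdrs_weights <- function() {
  t2 <- table2_counts()
  data.frame(base = t2$base, modifier = t2$modifier,
             weight = t2$n / sum(t2$n), stringsAsFactors = FALSE)
}

#' Synthetic trial configuration
#'
#' All knobs of the seeded trial generator, with defaults calibrated to
#' the published trial marginals: eye-level DRD prevalence 0.290 and
#' participant-level 0.389 (via the inter-eye severity correlation), DME
#' at 43/1073 eyes allocated across severity strata, AI operating point
#' (sensitivity 0.796, specificity 0.884), eye-level insufficient-quality
#' rate 0.094 clustered within participant so that participant
#' diagnosability is 0.958, reading-center (Level II) operating point
#' (sensitivity 0.672, specificity 0.998), and OCT centerfield thickness
#' moments by disease status.
#'
#' `inter_eye_severity_correlation` is a mixing weight in \[0, 1\]: with
#' that probability both eyes share one severity draw, otherwise the two
#' eyes draw independently. `q_fail_within_participant_correlation` plays
#' the same role for insufficient-quality failures.
#'
#' @param n_participants Number of participants (two eyes each).
#' @param etdrs_weights Severity distribution; see [paper_etdrs_weights()].
#' @param p_dme_given_stratum Named probabilities of DME given severity
#'   stratum: `low` (< 35), `moderate` (35-47), `high` (>= 53).
#' @param inter_eye_severity_correlation Shared-draw mixing weight for
#'   eye severity; default calibrated so participant prevalence is 0.389.
#' @param ai_sensitivity,ai_specificity AI operating point among
#'   diagnosable eyes.
#' @param q_fail_eye Marginal per-eye insufficient-quality probability.
#' @param q_fail_within_participant_correlation Shared-draw mixing weight
#'   for quality failures; default calibrated so that at least one eye is
#'   diagnosable in 95.8% of participants.
#' @param level2_sensitivity,level2_specificity Level II reading-center
#'   operating point against the Level I standard.
#' @param demographics See [default_demographics()].
#' @param thickness_model Named list of `c(mean, sd)` (micrometres) for
#'   `dme`, `positive` (DRD+ without DME) and `negative` eyes.
#' @param dilation_rate Fraction of eyes needing pharmacologic dilation.
#' @param seed Integer seed; identical configs generate identical data.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 567L,
                       etdrs_weights = paper_etdrs_weights(),
                       p_dme_given_stratum = c(low = 36 / 798, moderate = 0,
                                               high = 7 / 24),
                       inter_eye_severity_correlation = 0.6138,
                       ai_sensitivity = 0.796,
                       ai_specificity = 0.884,
                       q_fail_eye = 0.094,
                       q_fail_within_participant_correlation = 0.3894,
                       level2_sensitivity = 0.672,
                       level2_specificity = 0.998,
                       demographics = default_demographics(),
                       thickness_model = list(dme = c(307, 25),
                                              positive = c(245, 35),
                                              negative = c(242, 22)),
                       dilation_rate = 0.155,
                       seed = 20230329L) {
  probs <- c(inter_eye_severity_correlation, ai_sensitivity, ai_specificity,
             q_fail_eye, q_fail_within_participant_correlation,
             level2_sensitivity, level2_specificity, dilation_rate,
             p_dme_given_stratum)
  if (any(probs < 0 | probs > 1)) {
    stop_df("all probabilities must lie in [0, 1]")
  }
  if (abs(sum(etdrs_weights$weight) - 1) > 1e-9) {
    stop_df("etdrs_weights must sum to 1")
  }
  if (n_participants < 0) stop_df("n_participants must be >= 0")
  structure(list(
    n_participants = as.integer(n_participants),
    etdrs_weights = etdrs_weights,
    p_dme_given_stratum = p_dme_given_stratum,
    inter_eye_severity_correlation = inter_eye_severity_correlation,
    ai_sensitivity = ai_sensitivity, ai_specificity = ai_specificity,
    q_fail_eye = q_fail_eye,
    q_fail_within_participant_correlation = q_fail_within_participant_correlation,
    level2_sensitivity = level2_sensitivity,
    level2_specificity = level2_specificity,
    demographics = demographics,
    thickness_model = thickness_model,
    dilation_rate = dilation_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

dme_stratum <- function(base) {
  ifelse(base < 35, "low", ifelse(base < 53, "moderate", "high"))
}

#' Draw ETDRS severity levels
#'
#' Samples levels (base plus modifier) from the configured severity
#' distribution. Uses the current RNG state; call `set.seed()` first for
#' reproducibility.
#'
#' @param n Number of draws.
#' @param config A [sim_config()].
#' @return Data frame with columns `base` and `modifier`.
#' @export
sample_etdrs <- function(n, config = sim_config()) {
  w <- config$etdrs_weights
  i <- sample.int(nrow(w), n, replace = TRUE, prob = w$weight)
  data.frame(base = w$base[i], modifier = w$modifier[i],
             stringsAsFactors = FALSE)
}

#' Simulate AI outputs given true disease status
#'
#' Marginal (unclustered) AI output model: an eye is insufficient quality
#' with probability `q_fail_eye`; otherwise detected with probability
#' `ai_sensitivity` if truly positive, `1 - ai_specificity` if negative.
#' Uses the current RNG state.
#'
#' @param truth_positive Logical vector of true eye-level DRD status.
#' @param config A [sim_config()].
#' @return Character vector of AI outputs.
#' @export
simulate_ai_output <- function(truth_positive, config = sim_config()) {
  check_flag(truth_positive, "truth_positive")
  n <- length(truth_positive)
  fail <- runif(n) < config$q_fail_eye
  p_det <- ifelse(truth_positive, config$ai_sensitivity,
                  1 - config$ai_specificity)
  det <- runif(n) < p_det
  out <- ifelse(fail, "insufficient_quality",
                ifelse(det, "detected", "not_detected"))
  out
}

#' Generate a synthetic trial dataset
#'
#' Seeded, fully reproducible generator of a participant-eye dataset with
#' the dependence structure the clustered analysis assumes: correlated
#' within-participant eye severity (shared-draw mixture), DME assigned
#' per severity stratum, OCT thickness drawn conditional on disease
#' status (DME eyes from a shifted component so that center-involvement
#' classification is exercised), AI output drawn conditional on truth
#' with within-participant clustering of insufficient-quality failures,
#' Level II grades drawn conditional on truth, and demographics from the
#' configured mixes. Every participant contributes two eyes.
#'
#' @param config A [sim_config()].
#' @return A [trial_dataset()]; `metadata` records the seed and knobs.
#' @export
generate_trial <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  md <- list(source = "synthetic", seed = config$seed,
             generator = "drdscreen::generate_trial")
  if (n == 0) {
    empty <- data.frame(participant_id = character(), laterality = character(),
                        etdrs_base = integer(), dme_level1 = logical())
    return(trial_dataset(empty, metadata = md))
  }
  set.seed(config$seed)
  pid <- sprintf("S%05d", seq_len(n))

  # severity: shared-draw mixture between eyes
  shared <- runif(n) < config$inter_eye_severity_correlation
  e1 <- sample_etdrs(n, config)
  e2 <- sample_etdrs(n, config)
  e2[shared, ] <- e1[shared, ]

  eye <- data.frame(
    participant_id = rep(pid, each = 2),
    laterality = rep(c("right", "left"), n),
    etdrs_base = as.integer(as.vector(rbind(e1$base, e2$base))),
    etdrs_modifier = as.vector(rbind(e1$modifier, e2$modifier)),
    stringsAsFactors = FALSE
  )
  m <- nrow(eye)

  # DME per eye given stratum
  p_dme <- config$p_dme_given_stratum[dme_stratum(eye$etdrs_base)]
  eye$dme_level1 <- runif(m) < p_dme
  drd <- is_drd_positive(eye$etdrs_base, eye$dme_level1)

  # OCT central subfield thickness (micrometres)
  tm <- config$thickness_model
  grp <- ifelse(eye$dme_level1, "dme", ifelse(drd, "positive", "negative"))
  mu <- vapply(tm, `[`, numeric(1), 1)[grp]
  sg <- vapply(tm, `[`, numeric(1), 2)[grp]
  eye$centerfield_thickness <- round(pmax(rnorm(m, mu, sg), 50), 1)
  eye$cidme <- eye$dme_level1 & eye$centerfield_thickness > 300
  eye$csdme <- eye$dme_level1 & !eye$cidme

  # insufficient-quality failures: shared-draw mixture within participant
  share_q <- rep(runif(n) < config$q_fail_within_participant_correlation,
                 each = 2)
  f_shared <- rep(runif(n) < config$q_fail_eye, each = 2)
  f_own <- runif(m) < config$q_fail_eye
  fail <- ifelse(share_q, f_shared, f_own)

  p_det <- ifelse(drd, config$ai_sensitivity, 1 - config$ai_specificity)
  det <- runif(m) < p_det
  eye$ai_output <- ifelse(fail, "insufficient_quality",
                          ifelse(det, "detected", "not_detected"))

  p_l2 <- ifelse(drd, config$level2_sensitivity,
                 1 - config$level2_specificity)
  eye$level2_grade <- ifelse(runif(m) < p_l2, "detected", "not_detected")

  eye$dilated <- runif(m) < config$dilation_rate
  eye$n_attempts <- ifelse(fail, 6L, 1L + rbinom(m, 2L, 0.1))

  d <- config$demographics
  eye$sex <- rep(ifelse(runif(n) < d$p_male, "male", "female"), each = 2)
  eye$race <- rep(sample(names(d$race_probs), n, replace = TRUE,
                         prob = d$race_probs), each = 2)
  eye$ethnicity <- rep(sample(names(d$ethnicity_probs), n, replace = TRUE,
                              prob = d$ethnicity_probs), each = 2)
  eye$age <- rep(round(pmin(pmax(rnorm(n, d$age_mean, d$age_sd), 22), 90), 1),
                 each = 2)
  eye$hba1c <- rep(round(pmin(pmax(rnorm(n, d$hba1c_mean, d$hba1c_sd), 4), 16),
                         1), each = 2)
  trial_dataset(eye, metadata = md)
}
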