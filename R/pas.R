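#' Inputs to the Population Achieved Sensitivity statistic
#'
#' The five quantities entering PAS for one screening system:
#' sensitivity `s_c` and diagnosability `d_c` in the subpopulation with
#' access, access fraction `c`, measured prevalence `p_c` with access,
#' and estimated prevalence `p_nc_hat` without access. The conservative
#' default assumes equal prevalence 0.2 in both subpopulations.
#'
#' @param s_c,d_c,c,p_c,p_nc_hat Probabilities in \[0, 1\].
#' @return A list of class `pas_inputs`.
#' @export
pas_inputs <- function(s_c, d_c = 1, c = 1, p_c = 0.2, p_nc_hat = p_c) {
  v <- c(s_c = s_c, d_c = d_c, c = c, p_c = p_c, p_nc_hat = p_nc_hat)
  if (any(is.na(v)) || any(v < 0 | v > 1)) {
    stop_df("all PAS inputs must lie in [0, 1]")
  }
  structure(as.list(v), class = "pas_inputs")
}

#' Population Achieved Sensitivity (PAS)
#'
#' PAS measures the number of true cases a screening system identifies
#' at population scale, combining sensitivity, access, prevalence and
#' diagnosability:
#' \deqn{PAS = \frac{s_c \, c \, p_c \, d_c}{c\,p_c + (1-c)\,\hat p_{nc}}}
#' which collapses exactly to the simplified product
#' \eqn{s_c \, c \, d_c} whenever the two subpopulation prevalences are
#' equal.
#'
#' @param inputs A [pas_inputs()].
#' @return PAS value in \[0, 1\].
#' @seealso [pas_simplified()], [pas_break_even_ratio()].
#' @export
pas <- function(inputs) {
  stopifnot(inherits(inputs, "pas_inputs"))
  den <- inputs$c * inputs$p_c + (1 - inputs$c) * inputs$p_nc_hat
  if (den == 0) stop_df("PAS undefined: zero prevalence denominator")
  inputs$s_c * inputs$c * inputs$p_c * inputs$d_c / den
}

#' Simplified PAS under equal prevalence
#'
#' The product `s_c * c * d_c`, exactly equal to [pas()] when the
#' prevalence with and without access coincide.
#'
#' @param s_c,c,d_c Probabilities in \[0, 1\].
#' @return Product in \[0, 1\].
#' @export
pas_simplified <- function(s_c, c, d_c) {
  v <- c(s_c, c, d_c)
  if (any(is.na(v)) || any(v < 0 | v > 1)) stop_df("inputs must lie in [0, 1]")
  s_c * c * d_c
}

#' PAS break-even adoption ratio between two screening systems
#'
#' The adoption multiple at which a new (typically cheaper, more
#' adoptable) system identifies as many true cases as the reference
#' system: `PAS(reference) / PAS(new)` with the shared access fraction
#' cancelled. If the new system's adoption exceeds the reference's by
#' more than this ratio, it identifies more true cases in the population
#' despite any sensitivity deficit.
#'
#' @param reference_system,new_system [pas_inputs()] with equal access
#'   fractions (access cancels in the ratio).
#' @return Ratio > 0.
#' @export
pas_break_even_ratio <- function(reference_system, new_system) {
  stopifnot(inherits(reference_system, "pas_inputs"),
            inherits(new_system, "pas_inputs"))
  if (reference_system$c != new_system$c) {
    stop_df("access fraction must be equal across systems (it cancels)")
  }
  p_new <- pas(new_system)
  if (p_new == 0) stop_df("new-system PAS is zero; ratio undefined")
  pas(reference_system) / p_new
}

#' Monte-Carlo interval for the PAS break-even ratio
#'
#' Propagates sensitivity uncertainty into the break-even ratio: each
#' system's sensitivity is drawn from a normal distribution on the
#' probability scale with standard error inferred from its 95% CI
#' half-width (`(upper - lower) / (2 * 1.96)`; a one-sided CI with `NA`
#' upper uses `(point - lower) / 1.96`), truncated to (0, 1); the 2.5th
#' and 97.5th percentiles of the simulated ratios are reported. This is
#' an interpretation of CI propagation, not a reproduction of any
#' specific published method.
#'
#' @param reference_sens,new_sens Point sensitivities.
#' @param reference_ci,new_ci Length-2 `c(lower, upper)` 95% CIs; the
#'   upper limit may be `NA` when only a lower bound was reported.
#' @param reference_d,new_d Diagnosabilities (default equal).
#' @param n_draws Monte-Carlo draws.
#' @param seed Integer seed.
#' @return Named numeric `c(lower, upper)`.
#' @export
pas_ratio_interval <- function(reference_sens, reference_ci, new_sens, new_ci,
                               reference_d = 1, new_d = 1,
                               n_draws = 100000L, seed = 1L) {
  se_from_ci <- function(point, ci) {
    if (length(ci) != 2 || is.na(ci[1])) stop_df("degenerate CI")
    if (is.na(ci[2])) (point - ci[1]) / 1.96 else (ci[2] - ci[1]) / (2 * 1.96)
  }
  se_ref <- se_from_ci(reference_sens, reference_ci)
  se_new <- se_from_ci(new_sens, new_ci)
  if (se_ref < 0 || se_new < 0) stop_df("degenerate CI")
  set.seed(seed)
  eps <- 1e-9
  draw <- function(point, se) {
    pmin(pmax(rnorm(n_draws, point, se), eps), 1 - eps)
  }
  ratio <- (draw(reference_sens, se_ref) * reference_d) /
    (draw(new_sens, se_new) * new_d)
  out <- quantile(ratio, c(0.025, 0.975), names = FALSE)
  c(lower = out[1], upper = out[2])
}

#' Clinical-outcome risk annotation of an AI output
#'
#' Fixed lookup tying the binary screening output to untreated clinical
#' outcome risk from the trial literature: a "disease present" output
#' carries about an 18.5% risk of proliferative or worse retinopathy
#' within 3 years and about 11%/35% risk of moderate or worse vision
#' loss at 1/3 years, and maps to ICD-10 category E11.339x; a "disease
#' not present" output carries risks of at most 1.8% for these outcomes.
#' The percentages are encoded as published, not re-derived.
#'
#' @param ai_label `"detected"` or `"not_detected"`.
#' @return A list of class `risk_profile` with fields `label`,
#'   `risk_pdr_3y`, `risk_modvl_1y`, `risk_modvl_3y`, `icd10_category`.
#' @export
risk_annotation <- function(ai_label = c("detected", "not_detected")) {
  ai_label <- match.arg(ai_label)
  if (ai_label == "detected") {
    out <- list(label = "detected", risk_pdr_3y = 0.185,
                risk_modvl_1y = 0.11, risk_modvl_3y = 0.35,
                icd10_category = "E11.339x")
  } else {
    out <- list(label = "not_detected", risk_pdr_3y = 0.018,
                risk_modvl_1y = 0.014, risk_modvl_3y = 0.014,
                icd10_category = NA_character_)
  }
  structure(out, class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf("Output '%s': PDR risk (3y) %s; moderate+ vision loss %s (1y), %s (3y)%s\n",
              x$label, fmt_pct(x$risk_pdr_3y), fmt_pct(x$risk_modvl_1y),
              fmt_pct(x$risk_modvl_3y),
              if (!is.na(x$icd10_category))
                paste0("; ICD-10 ", x$icd10_category) else ""))
  invisible(x)
}
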