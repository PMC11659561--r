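#' Valid ETDRS severity base codes
#'
#' The ETDRS diabetic retinopathy severity scale uses a fixed set of
#' ordinal base codes from 10 (no retinopathy) to 90. Within-level
#' modifier letters (A-F) refine the grade for display and stratification
#' but never enter ordinal comparisons: every clinical threshold in this
#' package compares the integer base only.
#'
#' @return Integer vector of the recognised base codes, ascending.
#' @export
etdrs_bases <- function() {
  c(10L, 12L, 14L, 15L, 20L, 35L, 43L, 47L, 53L, 55L, 60L, 61L, 65L,
    71L, 75L, 81L, 85L, 90L)
}

etdrs_modifiers <- function() c("", LETTERS[1:6])

check_etdrs_base <- function(base, what = "etdrs_base") {
  if (any(is.na(base)) || !all(base %in% etdrs_bases())) {
    bad <- unique(base[is.na(base) | !(base %in% etdrs_bases())])
    stop_df(what, ": unknown ETDRS base code(s): ",
            paste(bad, collapse = ", "))
  }
  invisible(base)
}

check_flag <- function(x, what) {
  if (!is.logical(x) || any(is.na(x))) {
    stop_df(what, " must be TRUE/FALSE with no missing values")
  }
  invisible(x)
}

#' Case definition: diabetic retinal disease (DRD)
#'
#' An eye is DRD-positive when its ETDRS severity base is at least 35, or
#' diabetic macular edema (DME) is present. This is the referable-disease
#' cut-off used for the primary accuracy endpoints.
#'
#' @param etdrs_base Integer ETDRS base code(s); see [etdrs_bases()].
#' @param dme Logical; DME present in the eye.
#' @return Logical vector, `TRUE` where the eye meets the case definition.
#' @seealso [is_vtdrd()] for the vision-threatening threshold.
#' @examples
#' is_drd_positive(35, FALSE)  # TRUE
#' is_drd_positive(10, TRUE)   # TRUE via the DME disjunct
#' @export
is_drd_positive <- function(etdrs_base, dme) {
  check_etdrs_base(etdrs_base)
  check_flag(dme, "dme")
  etdrs_base >= 35 | dme
}

#' Case definition: vision-threatening DRD (vtDRD)
#'
#' An eye is vtDRD-positive when its ETDRS base is at least 53, or DME is
#' present.
#'
#' @inheritParams is_drd_positive
#' @return Logical vector.
#' @export
is_vtdrd <- function(etdrs_base, dme) {
  check_etdrs_base(etdrs_base)
  check_flag(dme, "dme")
  etdrs_base >= 53 | dme
}

#' Classify center-involved DME from OCT central subfield thickness
#'
#' Center-involved diabetic macular edema (CIDME) is defined as an OCT
#' central subfield (1.0 mm circle on the fovea) thickness strictly
#' greater than 300 micrometres. A missing thickness yields `NA`
#' (indeterminate), never silently `FALSE`.
#'
#' @param centerfield_thickness Numeric, micrometres; must be positive
#'   where non-missing.
#' @return Logical vector with `NA` where thickness is missing.
#' @examples
#' classify_cidme(c(307, 300, 243, NA))
#' @export
classify_cidme <- function(centerfield_thickness) {
  known <- !is.na(centerfield_thickness)
  if (any(centerfield_thickness[known] <= 0)) {
    stop_df("centerfield_thickness must be positive (micrometres)")
  }
  out <- rep(NA, length(centerfield_thickness))
  out[known] <- centerfield_thickness[known] > 300
  out
}
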