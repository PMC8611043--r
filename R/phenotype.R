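#' Histology score feature groups
#'
#' The eight biopsy features of the esophageal histology scoring system,
#' grouped into those reflecting eosinophilic inflammation (eosinophil
#' inflammation EI scored from the peak eosinophil count, eosinophil
#' abscess EA, surface layering SL, surface epithelial alteration SEA)
#' and those reflecting architecture (basal zone hyperplasia BZH, dilated
#' intercellular spaces DIS, dyskeratotic epithelial cells DEC, lamina
#' propria fibrosis LPF).
#'
#' @param group `"eosinophilic"` or `"structural"`.
#' @return Character vector of feature codes.
#' @export
hss_features <- function(group = c("eosinophilic", "structural")) {
  switch(match.arg(group),
         eosinophilic = c("EI", "EA", "SL", "SEA"),
         structural = c("BZH", "DIS", "DEC", "LPF"))
}

#' Total score of one histology feature
#'
#' Each feature is scored 0-3 for grade (severity) and 0-3 for stage
#' (extent); the feature total is their sum, ranging 0-6.
#'
#' @param grade,stage Integer scores in 0..3 (vectorized).
#' @return Integer total(s) in 0..6.
#' @export
hss_feature_total <- function(grade, stage) {
  if (any(is.na(grade)) || any(is.na(stage)) ||
      any(grade < 0 | grade > 3) || any(stage < 0 | stage > 3) ||
      any(grade != round(grade)) || any(stage != round(stage)))
    stop("grade and stage must be integers in 0..3", call. = FALSE)
  as.integer(grade + stage)
}

#' Histology group ratio for one biopsy
#'
#' The ratio of the sum of assigned feature totals to the maximum
#' possible score for that biopsy: sum of the group's evaluated feature
#' totals divided by 6 times the number of evaluated features.
#' Unevaluated features (`NA`, e.g. LPF when no lamina propria is
#' present) are removed from both numerator and denominator.
#'
#' @param totals Named numeric vector of feature totals (0-6, `NA` =
#'   unevaluated), named by feature code.
#' @param group `"eosinophilic"` or `"structural"`.
#' @param drop_unevaluated If `FALSE`, unevaluated features instead count
#'   a zero total against the full denominator.
#'
#' @return Ratio in \[0, 1\].
#' @export
hss_group_ratio <- function(totals, group = c("eosinophilic", "structural"),
                            drop_unevaluated = TRUE) {
  group <- match.arg(group)
  feats <- hss_features(group)
  miss <- setdiff(feats, names(totals))
  if (length(miss) > 0L)
    stop("missing feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- totals[feats]
  if (any(!is.na(x) & (x < 0 | x > 6)))
    stop("feature totals must lie in 0..6", call. = FALSE)
  if (!drop_unevaluated) x[is.na(x)] <- 0
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no evaluated features in group", call. = FALSE)
  sum(x) / (6 * length(x))
}

#' Disease-activity classification from peak eosinophil counts
#'
#' Active disease: at least 15 eosinophils per high-power field. Inactive
#' disease: below 15 with a prior disease history. Control: at most 2
#' without history. Counts of 3-14 without history fall in none of the
#' stated classes and are labelled indeterminate rather than silently
#' assigned.
#'
#' @param peak_eos Peak eosinophils per high-power field (non-negative,
#'   vectorized).
#' @param has_history Logical: prior histologically confirmed disease.
#'
#' @return Character vector over `{"active", "inactive", "control",
#'   "indeterminate"}`.
#' @export
classify_activity <- function(peak_eos, has_history) {
  if (any(is.na(peak_eos)) || any(peak_eos < 0))
    stop("peak_eos must be non-negative", call. = FALSE)
  n <- max(length(peak_eos), length(has_history))
  peak_eos <- rep_len(peak_eos, n)
  has_history <- rep_len(has_history, n)
  ifelse(peak_eos >= 15, "active",
         ifelse(has_history, "inactive",
                ifelse(peak_eos <= 2, "control", "indeterminate")))
}

#' Delta-CT expression with housekeeping-gene quality gate
#'
#' The housekeeping-gene (GAPDH) cycle threshold must be strictly below
#' 30 for a sample to be acceptable; the delta-CT is then the
#' gene-of-interest CT minus the GAPDH CT (lower delta-CT means higher
#' expression). Rejected samples yield `NA`.
#'
#' @param ct_goi Gene-of-interest CT value(s) (positive, finite).
#' @param ct_gapdh GAPDH CT value(s).
#' @param gapdh_max Exclusive GAPDH acceptability threshold (cycles).
#'
#' @return Numeric delta-CT, `NA` where the GAPDH gate rejects the
#'   sample; the return carries a `"rejected"` attribute with the reason
#'   (`"gapdh_qc"` or `NA`) per element.
#' @export
delta_ct <- function(ct_goi, ct_gapdh, gapdh_max = 30) {
  if (any(!is.finite(ct_goi)) || any(!is.finite(ct_gapdh)))
    stop("CT values must be finite", call. = FALSE)
  if (any(ct_goi <= 0) || any(ct_gapdh <= 0))
    stop("CT values must be positive", call. = FALSE)
  ok <- ct_gapdh < gapdh_max
  out <- ifelse(ok, ct_goi - ct_gapdh, NA_real_)
  attr(out, "rejected") <- ifelse(ok, NA_character_, "gapdh_qc")
  out
}

#' Fold change between two delta-CT groups
#'
#' Geometric fold change of group A relative to group B:
#' 2^(mean delta-CT of B - mean delta-CT of A). A group with one cycle
#' lower mean delta-CT is expressed two-fold higher.
#'
#' @param delta_ct_a,delta_ct_b Numeric vectors of delta-CT values (`NA`s
#'   dropped).
#'
#' @return Positive fold change; `fold_change(a, b) * fold_change(b, a)`
#'   is 1.
#' @export
fold_change <- function(delta_ct_a, delta_ct_b) {
  a <- delta_ct_a[!is.na(delta_ct_a)]
  b <- delta_ct_b[!is.na(delta_ct_b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("empty group after removing rejected samples", call. = FALSE)
  2^(mean(b) - mean(a))
}
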