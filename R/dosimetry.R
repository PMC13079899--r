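#' Dose thresholds, guardbands and element weights
#'
#' Per-region dosimetric prescription: the tumour carries a minimum fluence
#' threshold `d_min` (under-dosing allows recurrence), organs at risk carry
#' a maximum threshold `d_max` (over-dosing causes morbidity). Grey and
#' white matter are guardbanded by default: planning assumes a death
#' threshold of 0.1x the real one, so reported OAR damage is conservative.
#' Skull and CSF carry no dose constraint.
#'
#' Fluence units are J/mm^2 on the scale set by the dose-matrix treatment
#' duration (default 1 s at 1 W = 1 J emitted). The default thresholds are
#' calibrated to that scale; see the package vignette.
#'
#' @param d_min Tumour minimum threshold fluence, J/mm^2.
#' @param d_max Named vector of nominal OAR death thresholds, J/mm^2
#'   (default grey and white matter).
#' @param guardband Named vector of OAR guardband factors in (0, 1].
#' @param weights Named per-region cost weights (w_i); unlisted OAR regions
#'   default to `oar_weight`.
#' @param oar_weight Default OAR:tumour weight ratio.
#' @return A tibble of class `dose_thresholds`: columns `region`, `role`
#'   (`tumour` / `oar`), `nominal`, `guardband`, `threshold` (effective,
#'   filled by [apply_guardband()]; equals `nominal` until then), `weight`.
#' @export
dose_thresholds <- function(d_min = 1.5e-4,
                            d_max = c(grey = 3e-3, white = 3e-3),
                            guardband = c(grey = 0.1, white = 0.1),
                            weights = NULL, oar_weight = 0.25) {
  stopifnot(d_min > 0, all(d_max > 0))
  oar <- names(d_max)
  gb <- setNames(rep(1, length(oar)), oar)
  gb[names(guardband)] <- guardband
  if (any(gb <= 0 | gb > 1)) abort("guardband factors must lie in (0, 1]")
  wt <- setNames(rep(oar_weight, length(oar)), oar)
  wt["tumour"] <- 1
  if (!is.null(weights)) wt[names(weights)] <- weights
  if (any(wt <= 0)) abort("weights must be positive")
  out <- tibble::tibble(
    region = c("tumour", oar),
    role = c("tumour", rep("oar", length(oar))),
    nominal = c(d_min, unname(d_max)),
    guardband = c(1, unname(gb)),
    threshold = c(d_min, unname(d_max)),
    weight = unname(wt[c("tumour", oar)])
  )
  structure(out, class = c("dose_thresholds", class(tibble::tibble())))
}

#' Apply OAR safety guardbands
#'
#' Sets each OAR's effective threshold to `guardband x nominal` (default
#' 0.1x the real death threshold for grey and white matter). The tumour
#' minimum threshold is never guardbanded.
#'
#' @param thresholds A [dose_thresholds()] tibble.
#' @return The tibble with the `threshold` column updated and the
#'   `guardbanded` attribute set.
#' @export
apply_guardband <- function(thresholds) {
  stopifnot(inherits(thresholds, "dose_thresholds"))
  if (any(thresholds$guardband <= 0 | thresholds$guardband > 1)) {
    abort("guardband factors must lie in (0, 1]")
  }
  thresholds$threshold <- ifelse(
    thresholds$role == "oar",
    thresholds$nominal * thresholds$guardband,
    thresholds$nominal
  )
  attr(thresholds, "guardbanded") <- TRUE
  thresholds
}

# per-element threshold/weight table aligned with model$elements; regions
# without a prescription get role "none"
element_dosimetry <- function(model, thresholds) {
  el <- model$elements
  th <- tibble::as_tibble(thresholds)[, c("region", "role", "threshold", "weight")]
  out <- dplyr::left_join(el, th, by = "region")
  out$role[is.na(out$role)] <- "none"
  out$weight[is.na(out$weight)] <- 0
  out
}

#' Dose-volume outcome metric v100
#'
#' The volume of each constrained tissue receiving at least 100% of its
#' threshold dose. For the tumour this is reported as a percentage of the
#' tumour volume (coverage); for each OAR it is the absolute over-dosed
#' volume in mm^3 (against the guardbanded threshold). An element exactly
#' at threshold counts as receiving it.
#'
#' @param field Per-element fluence vector, J/mm^2 (e.g. from
#'   [superpose()]).
#' @param model A `tissue_model`.
#' @param thresholds A [dose_thresholds()] tibble (apply
#'   [apply_guardband()] first for guardbanded reporting).
#' @return An `outcome_summary` tibble: `tissue`, `role`, `v100`, `unit`.
#' @examples
#' # three tumour elements, volumes 1, 2, 3 mm^3, doses 2.0, 0.5, 1.5,
#' # threshold 1.0 -> (1 + 3) / 6 = 66.7% coverage
#' @export
v100 <- function(field, model, thresholds) {
  ed <- element_dosimetry(model, thresholds)
  if (length(field) != nrow(ed)) abort("field and model are not aligned")
  if (!any(ed$role == "tumour")) abort("model has no tumour elements")
  ed$phi <- field
  tum <- dplyr::filter(ed, .data$role == "tumour")
  tum_v100 <- 100 * sum(tum$volume[tum$phi >= tum$threshold]) / sum(tum$volume)
  oar <- dplyr::filter(ed, .data$role == "oar")
  oar_sum <- dplyr::summarise(
    dplyr::group_by(oar, tissue = .data$region),
    v100 = sum(.data$volume[.data$phi >= .data$threshold]),
    .groups = "drop"
  )
  out <- dplyr::bind_rows(
    tibble::tibble(tissue = "tumour", role = "tumour", v100 = tum_v100, unit = "%"),
    dplyr::mutate(oar_sum, role = "oar", unit = "mm^3")
  )
  structure(out, class = c("outcome_summary", class(tibble::tibble())))
}

#' Spread of outcomes between power extremes
#'
#' Given outcome summaries at the maximum, minimum and nominal source
#' powers, computes per-tissue \eqn{\Delta v_{100} = v_{100}^{max} -
#' v_{100}^{min}} and the relative change \eqn{\Delta v_{100}^{\%} =
#' 100 \Delta v_{100} / v_{100}}. A tissue with zero nominal v100 has an
#' undefined relative change, reported as `NA`.
#'
#' @param v_max,v_min,v_nom `outcome_summary` tibbles over the same
#'   tissues.
#' @return Tibble: `tissue`, `v100`, `v100_max`, `v100_min`, `dv100`,
#'   `dv100_pct`.
#' @export
spread_metrics <- function(v_max, v_min, v_nom) {
  stopifnot(
    identical(v_max$tissue, v_min$tissue),
    identical(v_max$tissue, v_nom$tissue)
  )
  tibble::tibble(
    tissue = v_nom$tissue,
    v100 = v_nom$v100,
    v100_max = v_max$v100,
    v100_min = v_min$v100,
    dv100 = v_max$v100 - v_min$v100,
    dv100_pct = ifelse(v_nom$v100 > 0,
      100 * (v_max$v100 - v_min$v100) / v_nom$v100, NA_real_
    )
  )
}

#' Geometric mean
#'
#' `exp(mean(log(x)))` of strictly positive values; used to average v100
#' outcomes across tumour models, where it tracks the underlying trend
#' while damping outliers.
#'
#' @param values Positive numeric vector.
#' @param na.rm Drop `NA`s first?
#' @return Scalar geometric mean.
#' @export
geometric_mean <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  if (any(values <= 0)) abort("geometric_mean requires strictly positive values")
  exp(mean(log(values)))
}

#' Paired t-test across tumour models
#'
#' Two-sided paired t-test on per-model metric vectors (e.g. tumour v100
#' under two planning strategies across nine models). Differences of zero
#' variance are degenerate for the t statistic: if all differences are
#' exactly zero the p-value is reported as 1; otherwise the test errors.
#' No multiple-comparisons correction is applied.
#'
#' @param a,b Equal-length numeric vectors (length >= 2), paired by model.
#' @return Tibble: `estimate` (mean difference a - b), `statistic`, `df`,
#'   `p_value`, `significant` (at the 0.05 level).
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (isTRUE(all.equal(stats::var(d), 0)) || stats::var(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(
        estimate = 0, statistic = 0, df = length(d) - 1,
        p_value = 1, significant = FALSE
      ))
    }
    abort("paired differences have zero variance but are not all zero; t-test degenerate")
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble::tibble(
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    significant = tt$p.value < 0.05
  )
}
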