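#' Mean absolute moment of a bundle state
#'
#' The buckling indicator used for classification: `B_r` times the mean,
#' over the selected filaments and over the interior joints `j = 2..n`, of
#' `|tan^2(theta_ij - theta_i(j-1))|` — the same discrete curvature measure
#' as the bending energy, but deliberately without the `1/(2l)` weighting;
#' the 1e-5 undeformed threshold of [classify_state()] is tied to this
#' convention. The `B_r` factor compensates for the outer filaments
#' deforming less under a given load.
#'
#' @param params A [bundle_params()] object.
#' @param theta `m x n` angle matrix.
#' @param subset `"all"` filaments, `"outer"` (rows 1 and m) or `"inner"`
#'   (rows 2..m-1; requires `m >= 3`).
#' @return A non-negative scalar.
#' @export
mean_absolute_moment <- function(params, theta,
                                 subset = c("all", "outer", "inner")) {
  subset <- match.arg(subset)
  check_state(params, theta)
  m <- params$m
  rows <- switch(subset,
                 all = seq_len(m),
                 outer = c(1L, m),
                 inner = {
                   if (m < 3) stop("subset = \"inner\" requires m >= 3")
                   seq(2L, m - 1L)
                 })
  dtheta <- theta[rows, -1L, drop = FALSE] -
    theta[rows, -params$n, drop = FALSE]
  params$B_r * mean(abs(tan(dtheta)^2))
}

#' Pinching parameter of a bundle state
#'
#' A mirror-antisymmetry score in `[0, 1]`. Filaments are paired across the
#' bundle's mid-line (`i` with `m+1-i`) and, for every pair and segment,
#' the normalized angle difference `|th_i - th_pair| / (|th_i| + |th_pair|)`
#' is averaged over all `n` segments and all `m_h` pairs (`m_h = m/2` for
#' even `m`, `(m-1)/2` for odd `m`). Mirror-antisymmetric deformation
#' (upper and lower halves bending in opposite directions) scores 1,
#' mirror-symmetric deformation scores 0. A pair of exactly straight
#' segments is neither evidence of symmetry nor antisymmetry: zero
#' denominators contribute 0.
#'
#' @inheritParams mean_absolute_moment
#' @return A scalar in `[0, 1]`.
#' @export
pinching_parameter <- function(params, theta) {
  check_state(params, theta)
  m <- params$m
  mh <- if (m %% 2 == 0) m %/% 2L else (m - 1L) %/% 2L
  lo <- theta[seq_len(mh), , drop = FALSE]
  hi <- theta[m + 1L - seq_len(mh), , drop = FALSE]
  den <- abs(lo) + abs(hi)
  term <- abs(lo - hi) / den
  term[den == 0] <- 0
  sum(term) / (params$n * mh)
}

#' Classify a bundle state into one of four deformation modes
#'
#' Applies the decision rule, in order:
#' 1. mean absolute moment over all filaments `<= moment_threshold`
#'    (default 1e-5) — `undeformed`;
#' 2. otherwise, inner/outer moment ratio `> ratio_threshold` (default 5)
#'    — `internal` (perfectly straight outer filaments give an infinite
#'    ratio, which counts as internal);
#' 3. otherwise, pinching parameter `> pinch_threshold` (default 0.75)
#'    — `pinched`;
#' 4. otherwise — `global`.
#'
#' For `m = 2` there are no inner filaments and rule 2 is skipped.
#'
#' @inheritParams mean_absolute_moment
#' @param moment_threshold Undeformed/buckled threshold on the mean
#'   absolute moment.
#' @param ratio_threshold Inner/outer moment ratio above which buckling is
#'   classed as internal.
#' @param pinch_threshold Pinching-parameter threshold for the
#'   asymmetrically pinched class.
#' @return A one-row tibble: `moment_all`, `moment_outer`, `moment_inner`,
#'   `pinch`, `label` (factor with levels undeformed, global, pinched,
#'   internal).
#' @export
classify_state <- function(params, theta, moment_threshold = 1e-5,
                           ratio_threshold = 5, pinch_threshold = 0.75) {
  moment_all <- mean_absolute_moment(params, theta, "all")
  moment_outer <- mean_absolute_moment(params, theta, "outer")
  moment_inner <- if (params$m >= 3) {
    mean_absolute_moment(params, theta, "inner")
  } else {
    NA_real_
  }
  pinch <- pinching_parameter(params, theta)
  label <- if (moment_all <= moment_threshold) {
    "undeformed"
  } else if (params$m >= 3 && moment_inner > moment_threshold &&
             isTRUE(moment_inner / moment_outer > ratio_threshold)) {
    "internal"
  } else if (pinch > pinch_threshold) {
    "pinched"
  } else {
    "global"
  }
  tibble::tibble(
    moment_all = moment_all, moment_outer = moment_outer,
    moment_inner = moment_inner, pinch = pinch,
    label = factor(label, levels = c("undeformed", "global", "pinched",
                                     "internal"))
  )
}
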