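#' Cardiovascular risk thresholds
#'
#' Cutpoints banding the total-cholesterol-to-HDL ratio (sex-specific) and the
#' HDL percentage into four ordinal risk levels: 1 below-average, 2 average,
#' 3 above-average (moderate), 4 above-average (high). Defaults are the
#' standard screening cutpoints: male ratio 4.2 / 7.4 / 11.5, female ratio
#' 3.9 / 5.8 / 9.0, HDL\% 25 / 15 / 9. Risk increases with the ratio and
#' decreases with HDL\%.
#'
#' The printed bands leave small gaps (e.g. male ratio between 7.3 and 7.4)
#' and share the value 15 between two HDL\% rows; this package resolves both
#' by continuous half-open intervals at the cutpoints, so every positive
#' input classifies to exactly one level. The conventions are centralized
#' here and documented in \code{\link{classify_ratio}} and
#' \code{\link{classify_hdl_percent}}.
#'
#' @param male,female strictly increasing ratio cutpoints (length 3).
#' @param hdl_pct strictly decreasing HDL-percentage cutpoints (length 3).
#' @return An object of class \code{risk_thresholds}.
#' @export
risk_thresholds <- function(male = c(4.2, 7.4, 11.5),
                            female = c(3.9, 5.8, 9.0),
                            hdl_pct = c(25, 15, 9)) {
  stopifnot(length(male) == 3L, length(female) == 3L, length(hdl_pct) == 3L)
  if (any(diff(male) <= 0) || any(diff(female) <= 0)) {
    stop("ratio cutpoints must be strictly increasing", call. = FALSE)
  }
  if (any(diff(hdl_pct) >= 0)) {
    stop("HDL% cutpoints must be strictly decreasing", call. = FALSE)
  }
  structure(list(male = male, female = female, hdl_pct = hdl_pct),
            class = "risk_thresholds")
}

#' Risk level labels
#' @return Character vector of the four ordinal level labels.
#' @export
risk_levels <- function() {
  c("below-average", "average", "above-average (moderate)",
    "above-average (high)")
}

.ratio_cuts <- function(sex, thresholds) {
  sex <- match.arg(sex, c("M", "F"))
  if (sex == "M") thresholds$male else thresholds$female
}

#' Classify a CHOL/HDL ratio into a risk level
#'
#' Half-open intervals at the sex-specific cutpoints \eqn{t_1 < t_2 < t_3}:
#' \eqn{[0, t_1) \to 1}, \eqn{[t_1, t_2) \to 2}, \eqn{[t_2, t_3] \to 3},
#' \eqn{(t_3, \infty) \to 4}. A ratio exactly at \eqn{t_1} or \eqn{t_2}
#' belongs to the higher-risk interval; exactly \eqn{t_3} remains moderate.
#'
#' @param sex \code{"M"} or \code{"F"} (recycled against \code{ratio}).
#' @param ratio positive finite CHOL/HDL ratio(s).
#' @param thresholds a \code{\link{risk_thresholds}}.
#' @return Integer risk level(s) in 1..4.
#' @examples
#' classify_ratio("M", 5.0)   # average risk
#' classify_ratio("F", 9.5)   # above-average (high)
#' @export
classify_ratio <- function(sex, ratio, thresholds = risk_thresholds()) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("ratio must be positive and finite", call. = FALSE)
  }
  n <- max(length(sex), length(ratio))
  sex <- rep_len(as.character(sex), n)
  ratio <- rep_len(ratio, n)
  out <- integer(n)
  for (s in unique(sex)) {
    t <- .ratio_cuts(s, thresholds)
    r <- ratio[sex == s]
    out[sex == s] <- ifelse(r < t[1L], 1L,
                     ifelse(r < t[2L], 2L,
                     ifelse(r <= t[3L], 3L, 4L)))
  }
  out
}

#' Classify an HDL percentage into a risk level
#'
#' With cutpoints 25 / 15 / 9: \eqn{(25, 100] \to 1}, \eqn{[15, 25] \to 2},
#' \eqn{[9, 15) \to 3}, \eqn{(0, 9) \to 4}. The shared cutpoint 15 resolves
#' in favor of the lower-risk band.
#'
#' @param hdl_pct HDL percentage(s) in (0, 100].
#' @param thresholds a \code{\link{risk_thresholds}}.
#' @return Integer risk level(s) in 1..4.
#' @export
classify_hdl_percent <- function(hdl_pct, thresholds = risk_thresholds()) {
  if (any(!is.finite(hdl_pct)) || any(hdl_pct <= 0) || any(hdl_pct > 100)) {
    stop("hdl_pct must be in (0, 100]", call. = FALSE)
  }
  t <- thresholds$hdl_pct
  ifelse(hdl_pct > t[1L], 1L,
  ifelse(hdl_pct >= t[2L], 2L,
  ifelse(hdl_pct >= t[3L], 3L, 4L)))
}

# Category midpoints used as kernel centers: interior categories use the
# interval midpoint; the open outer categories use cutpoint -/+ bandwidth.
.soft_centers <- function(cuts, bandwidth) {
  c(cuts[1L] - bandwidth,
    (cuts[1L] + cuts[2L]) / 2,
    (cuts[2L] + cuts[3L]) / 2,
    cuts[3L] + bandwidth)
}

#' Soft risk-category assignment
#'
#' Represents a CHOL/HDL ratio as a membership vector over the four risk
#' levels instead of a single label, so that values close to a cutoff carry
#' weight on both adjacent categories. Each category carries a piecewise
#' linear tent kernel: weight 1 at the category's midpoint, 0.5 at each of
#' its cutpoints, declining linearly to 0 at the neighboring category's
#' midpoint (the open outer categories stay at 1 beyond their midpoint,
#' taken as cutpoint \eqn{\pm} bandwidth). Kernels are normalized to sum
#' to one. Consequences: at an interval midpoint all weight sits on that
#' category; exactly at a shared cutpoint the two adjacent categories split
#' the weight equally; away from every cutpoint the hard category's weight
#' dominates, so the argmax of the soft assignment agrees with
#' \code{\link{classify_ratio}} everywhere off the cutpoint set.
#'
#' @param sex \code{"M"} or \code{"F"}.
#' @param ratio positive finite CHOL/HDL ratio(s).
#' @param thresholds a \code{\link{risk_thresholds}}.
#' @param bandwidth positive kernel bandwidth; default half the narrowest
#'   interior interval width for the given sex.
#' @return A numeric matrix (length(ratio) x 4) of membership weights, rows
#'   summing to one.
#' @export
soft_assign <- function(sex, ratio, thresholds = risk_thresholds(),
                        bandwidth = NULL) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("ratio must be positive and finite", call. = FALSE)
  }
  sex <- match.arg(sex, c("M", "F"))
  cuts <- .ratio_cuts(sex, thresholds)
  if (is.null(bandwidth)) {
    widths <- c(cuts[1L], diff(cuts))  # level-1 band spans (0, t1)
    bandwidth <- min(widths[-1L]) / 2  # narrowest interior interval
  }
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be positive", call. = FALSE)
  }
  ctr <- .soft_centers(cuts, bandwidth)
  bounds <- cuts  # shared cutpoints between consecutive categories
  W <- matrix(0, length(ratio), 4L)
  for (j in 1:4) {
    # knots of the tent for category j: (prev center, 0) (lower cut, .5)
    # (center, 1) (upper cut, .5) (next center, 0); outer sides are flat at 1
    xk <- c(if (j > 1L) ctr[j - 1L] else -Inf,
            if (j > 1L) bounds[j - 1L] else -Inf,
            ctr[j],
            if (j < 4L) bounds[j] else Inf,
            if (j < 4L) ctr[j + 1L] else Inf)
    yk <- c(0, 0.5, 1, 0.5, 0)
    if (j == 1L) yk[1:2] <- 1
    if (j == 4L) yk[4:5] <- 1
    W[, j] <- .tent_eval(ratio, xk, yk, flat_left = (j == 1L),
                         flat_right = (j == 4L))
  }
  W <- W / rowSums(W)
  stopifnot(all(abs(rowSums(W) - 1) < 1e-12))
  colnames(W) <- paste0("level", 1:4)
  W
}

# piecewise-linear tent evaluated at x; flat (value 1) beyond the center on
# the open side of the outer categories
.tent_eval <- function(x, xk, yk, flat_left = FALSE, flat_right = FALSE) {
  fin <- is.finite(xk)
  xs <- xk[fin]
  ys <- yk[fin]
  lo <- if (flat_left) 1 else 0
  hi <- if (flat_right) 1 else 0
  stats::approx(xs, ys, xout = x, yleft = lo, yright = hi,
                ties = "ordered")$y
}
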