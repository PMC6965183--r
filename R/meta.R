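#' Inverse-variance fixed-effects meta-analysis of one variant
#'
#' Combines per-group effect estimates with weights \eqn{w_i = 1/SE_i^2}:
#' combined beta \eqn{= \sum w_i b_i / \sum w_i}, combined SE
#' \eqn{= (\sum w_i)^{-1/2}}, two-sided p from the normal reference. With a
#' single estimate the input is returned unchanged.
#'
#' @param beta numeric vector of per-group estimates.
#' @param se numeric vector of their standard errors, all > 0.
#' @return list with `beta`, `se`, `p`, `k`, and (for k >= 2) `Q`, `q_p`,
#'   `i2` from [cochran_q()].
#' @export
ivw_meta <- function(beta, se) {
  if (length(beta) != length(se)) stop("beta and se lengths differ")
  k <- length(beta)
  if (k == 0L) stop("no estimates to combine")
  if (any(!is.finite(se)) || any(se <= 0)) stop("all standard errors must be > 0")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  out <- list(beta = b, se = s,
              p = 2 * stats::pnorm(-abs(b / s)), k = k)
  if (k >= 2L) {
    het <- cochran_q(beta, se)
    out$Q <- het$Q
    out$q_p <- het$p
    out$i2 <- het$i2
  } else {
    out$Q <- NA_real_; out$q_p <- NA_real_; out$i2 <- NA_real_
  }
  out
}

#' Cochran's Q heterogeneity test and I-squared
#'
#' \eqn{Q = \sum w_i (b_i - b_{fixed})^2} with \eqn{w_i = 1/SE_i^2} and
#' \eqn{b_{fixed}} the inverse-variance-weighted mean; df = k - 1; p from
#' the chi-square reference. \eqn{I^2 = \max(0, (Q - df)/Q) \times 100} is
#' the percentage of variation across estimates attributable to
#' heterogeneity, truncated at 0. For k = 2 estimates Q reduces to
#' \eqn{(b_1 - b_2)^2 / (SE_1^2 + SE_2^2)}.
#'
#' @param beta,se estimate and standard-error vectors, k >= 2, se > 0.
#' @return list with `Q`, `df`, `p`, `i2` (continuous percent; round for
#'   reporting).
#' @export
cochran_q <- function(beta, se) {
  k <- length(beta)
  if (k < 2L) stop("heterogeneity needs at least 2 estimates")
  if (length(se) != k) stop("beta and se lengths differ")
  if (any(!is.finite(se)) || any(se <= 0)) stop("all standard errors must be > 0")
  w <- 1 / se^2
  bf <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bf)^2)
  df <- k - 1L
  list(Q = Q, df = df,
       p = stats::pchisq(Q, df = df, lower.tail = FALSE),
       i2 = max(0, (Q - df) / Q) * 100)
}

#' Meta-analyze association scans across ancestry groups
#'
#' Runs [ivw_meta()] per variant over the groups in which it was scanned
#' (i.e. passed the per-group MAF filter). Variants present in fewer than
#' `min_groups` groups are not combined: they are returned separately as
#' the `"group_only"` attribute, mirroring the carry-forward of variants
#' shared between two or more groups.
#'
#' @param results an `assoc_result` data.frame stacking several groups, or
#'   a list of them. Flagged rows are excluded from combination.
#' @param min_groups minimum number of groups per combined variant
#'   (default 2).
#' @return data.frame of class `meta_result`: `variant`, `chrom`, `pos`,
#'   `k`, `n`, `beta`, `se`, `p`, `Q`, `q_p`, `i2`.
#' @export
meta_scan <- function(results, min_groups = 2L) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  ok <- is.na(results$flag) | results$flag == ""
  res <- results[ok & !is.na(results$se) & results$se > 0, , drop = FALSE]
  pieces <- split(res, res$variant)
  rows <- lapply(pieces, function(d) {
    m <- ivw_meta(d$beta, d$se)
    data.frame(variant = d$variant[1], chrom = d$chrom[1], pos = d$pos[1],
               k = m$k, n = sum(d$n), beta = m$beta, se = m$se, p = m$p,
               Q = m$Q, q_p = m$q_p, i2 = m$i2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  single <- out[out$k < min_groups, , drop = FALSE]
  out <- out[out$k >= min_groups, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("meta_result", "data.frame")
  attr(out, "group_only") <- single
  out
}
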