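#' Gene-drug interaction scan: baseline versus on-treatment heterogeneity
#'
#' The arbiter analysis. For each variant shared between an association
#' scan of the baseline LDL-C level (ln X residuals) and a scan of the
#' on-treatment level (ln Y residuals), a two-estimate Cochran's Q compares
#' the two betas:
#' \deqn{Q = (b_{on} - b_{base})^2 / (SE_{base}^2 + SE_{on}^2),\quad
#'       p = P(\chi^2_1 > Q).}
#' A variant whose allele shifts baseline and on-treatment levels equally
#' (pure baseline effect) gives Q near 0 however strong the effect; a true
#' effect on statin response shifts only the on-treatment beta and inflates
#' Q.
#'
#' The default mirrors the independence-assumed Q. Because the two scans
#' are computed on the same individuals, their estimates are positively
#' correlated (shared biological variance), which makes the default
#' conservative. `rho` supplies the correlation between the two residual
#' vectors to use the corrected variance
#' \eqn{SE_{base}^2 + SE_{on}^2 - 2\rho\, SE_{base} SE_{on}}; this
#' correlation-corrected test is calibrated (uniform null p-values) and is
#' the variant to use when nominal error rates matter.
#'
#' @param baseline_results,ontreat_results `assoc_result`/`meta_result`
#'   data.frames from the baseline-level and on-treatment-level scans of
#'   the same individuals (meta-combined across groups first, when groups
#'   exist).
#' @param rho correlation between the baseline and on-treatment residual
#'   vectors; 0 (default) reproduces the independence-assumed test. Compute
#'   it as `cor(base_phen$value, on_phen$value)`.
#' @return data.frame of class `interaction_result`: `variant`, `chrom`,
#'   `pos`, `b_base`, `se_base`, `b_on`, `se_on`, `Q`, `p`, `i2`. The count
#'   of variants missing from either scan is attached as attribute
#'   `"n_dropped"`.
#' @export
interaction_scan <- function(baseline_results, ontreat_results, rho = 0) {
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  ok <- function(d) {
    f <- if ("flag" %in% names(d)) (is.na(d$flag) | d$flag == "") else TRUE
    d[f & !is.na(d$se) & d$se > 0, , drop = FALSE]
  }
  b <- ok(baseline_results)
  o <- ok(ontreat_results)
  shared <- intersect(b$variant, o$variant)
  n_dropped <- length(union(b$variant, o$variant)) - length(shared)
  if (n_dropped > 0)
    message(n_dropped, " variant(s) missing from one of the two scans; omitted")
  if (!length(shared)) stop("no variants shared between the two scans")
  bi <- b[match(shared, b$variant), ]
  oi <- o[match(shared, o$variant), ]
  v <- bi$se^2 + oi$se^2 - 2 * rho * bi$se * oi$se
  Q <- (oi$beta - bi$beta)^2 / v
  out <- data.frame(variant = shared, chrom = bi$chrom, pos = bi$pos,
                    b_base = bi$beta, se_base = bi$se,
                    b_on = oi$beta, se_on = oi$se,
                    Q = Q, p = stats::pchisq(Q, df = 1, lower.tail = FALSE),
                    i2 = pmax(0, (Q - 1) / Q) * 100,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_result", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}
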