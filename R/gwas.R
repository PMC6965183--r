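#' Minor-allele-frequency filter
#'
#' Retains variants whose within-group minor allele frequency is strictly
#' above the group's threshold. Common variants are defined by MAF > 1% in
#' the smaller ancestry groups; the designated large group uses the more
#' liberal MAF > 0.05% threshold, which still guarantees a minimum minor
#' allele count at its sample size.
#'
#' @param panel a `genotype_panel`.
#' @param threshold MAF threshold; if `NULL`, chosen by group via
#'   `large_group`.
#' @param large_group label of the group using the liberal threshold.
#' @param liberal,default the two thresholds (0.0005 and 0.01).
#' @return the filtered `genotype_panel`; empirical MAF is stored in the
#'   metadata column `maf_observed`.
#' @export
maf_filter <- function(panel, threshold = NULL, large_group = "european",
                       liberal = 0.0005, default = 0.01) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (ncol(panel$dosages) == 0L) stop("empty panel")
  if (is.null(threshold))
    threshold <- if (identical(panel$group, large_group)) liberal else default
  af <- colMeans(panel$dosages) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf > threshold
  panel$variants <- panel$variants[keep, , drop = FALSE]
  panel$variants$maf_observed <- maf[keep]
  panel$dosages <- panel$dosages[, keep, drop = FALSE]
  panel
}

#' Single-variant association scan
#'
#' Regresses phenotype residuals on allelic dosage under an additive model
#' of inheritance, one simple linear regression per variant. P-values use
#' the t reference with n - 2 degrees of freedom. Monomorphic
#' (zero-dosage-variance) variants are reported with `flag = "monomorphic"`
#' and NA estimates rather than dropped silently; perfect fits (zero
#' residual variance) are flagged `"degenerate"` with the exact beta and NA
#' p.
#'
#' @param phen a `phenotype_vector` (or data.frame with `id`, `value`).
#' @param panel a `genotype_panel` whose dosage rownames cover `phen$id`.
#' @return data.frame of class `assoc_result`: `variant`, `chrom`, `pos`,
#'   `group`, `n`, `beta`, `se`, `p`, `flag`.
#' @export
assoc_scan <- function(phen, panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- match(phen$id, rownames(panel$dosages))
  if (anyNA(idx))
    stop("phenotype ids absent from the genotype panel: ",
         paste(utils::head(phen$id[is.na(idx)], 3), collapse = ", "),
         if (sum(is.na(idx)) > 3) ", ...")
  G <- panel$dosages[idx, , drop = FALSE]
  y <- as.numeric(phen$value)
  n <- length(y)
  if (n < 3L) stop("need at least 3 individuals for the t test (df = n - 2)")
  yc <- y - mean(y)
  gm <- colMeans(G)
  Sgg <- colSums(G^2) - n * gm^2
  Sgy <- drop(crossprod(G, yc))
  Syy <- sum(yc^2)
  beta <- ifelse(Sgg > 0, Sgy / Sgg, NA_real_)
  sse <- pmax(Syy - beta^2 * Sgg, 0)
  sigma2 <- sse / (n - 2)
  se <- sqrt(sigma2 / Sgg)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  flag <- rep("", ncol(G))
  mono <- Sgg <= 0
  degen <- !mono & sigma2 <= .Machine$double.eps * Syy
  flag[mono] <- "monomorphic"
  flag[degen] <- "degenerate"
  se[mono] <- NA_real_
  se[degen] <- 0
  p[mono | degen] <- NA_real_
  out <- data.frame(variant = panel$variants$variant,
                    chrom = panel$variants$chrom, pos = panel$variants$pos,
                    group = panel$group, n = n, beta = beta, se = se, p = p,
                    flag = flag, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Genomic inflation factor
#'
#' \eqn{\lambda} = median of the 1-df chi-square quantiles implied by the
#' p-values, divided by the null 1-df chi-square median (0.4549364231).
#' \eqn{\lambda \approx 1} indicates no systematic inflation of the test
#' statistics.
#'
#' @param results an `assoc_result` data.frame, or a bare numeric vector of
#'   p-values. Flagged (NA) p-values are ignored.
#' @return the scalar inflation factor.
#' @export
genomic_inflation <- function(results) {
  p <- if (is.data.frame(results)) results$p else as.numeric(results)
  p <- p[!is.na(p)]
  if (!length(p)) stop("no valid p-values")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Write association summary statistics as TSV
#'
#' The interchange format consumed by the meta-analysis, interaction and
#' locus-calling stages: columns `variant`, `chrom`, `pos`, `group`, `n`,
#' `beta`, `se`, `p`, `flag`.
#'
#' @param results an `assoc_result` (or meta/interaction) data.frame.
#' @param path output path.
#' @export
write_assoc_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_assoc_tsv
#' @export
read_assoc_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}
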