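#' Call independent loci from summary statistics
#'
#' Greedy distance-based clumping: repeatedly take the smallest-p
#' unassigned variant with p below the suggestive threshold as a lead, and
#' assign every unassigned variant within the window of it on the same
#' chromosome to its locus. Loci are tiered genome-wide (lead
#' p < 5e-8) or suggestive (lead p < 1e-5); significant/suggestive variants
#' more than the window apart are independent loci. Ties in p are broken by
#' position; the procedure is deterministic given its input.
#'
#' @param results data.frame with columns `variant`, `chrom`, `pos`, `p`
#'   (any scan, meta or interaction table).
#' @param sig genome-wide significance threshold (strict `<`), default
#'   5e-8.
#' @param sug suggestive threshold (strict `<`), default 1e-5.
#' @param window locus half-width in base pairs, default 500000 (0.5 Mb).
#' @return data.frame of class `locus_table`: one row per locus with
#'   `lead_variant`, `chrom`, `pos`, `p`, `tier`, `n_members`, `span_bp`,
#'   `members` (comma-separated variant ids).
#' @export
call_loci <- function(results, sig = 5e-8, sug = 1e-5, window = 5e5) {
  need <- c("variant", "chrom", "pos", "p")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- results[!is.na(results$p), need, drop = FALSE]
  d <- d[order(d$p, d$chrom, d$pos), , drop = FALSE]
  assigned <- rep(FALSE, nrow(d))
  loci <- list()
  repeat {
    i <- which(!assigned & d$p < sug)[1]
    if (is.na(i)) break
    mem <- which(!assigned & d$chrom == d$chrom[i] &
                   abs(d$pos - d$pos[i]) <= window)
    assigned[mem] <- TRUE
    loci[[length(loci) + 1L]] <- data.frame(
      lead_variant = d$variant[i], chrom = d$chrom[i], pos = d$pos[i],
      p = d$p[i],
      tier = if (d$p[i] < sig) "genome-wide" else "suggestive",
      n_members = length(mem),
      span_bp = max(d$pos[mem]) - min(d$pos[mem]),
      members = paste(d$variant[mem][order(d$pos[mem])], collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- if (length(loci)) do.call(rbind, loci) else
    data.frame(lead_variant = character(0), chrom = character(0),
               pos = numeric(0), p = numeric(0), tier = character(0),
               n_members = integer(0), span_bp = numeric(0),
               members = character(0), stringsAsFactors = FALSE)
  class(out) <- c("locus_table", "data.frame")
  out
}
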