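#' Phenotype specification
#'
#' Names one of the seven phenotype definitions analysed by the pipeline.
#' Five are drug-response phenotypes built from the baseline (X) and
#' on-treatment (Y) LDL-C pair:
#' \describe{
#'   \item{logdiff_adj}{ln(Y) - ln(X), adjusted for ln(X) (the
#'     Postmus-style definition).}
#'   \item{pct_unadj}{(Y - X)/X, unadjusted.}
#'   \item{logdiff_unadj}{ln(Y) - ln(X), unadjusted.}
#'   \item{pct_adj}{(Y - X)/X, adjusted for X.}
#'   \item{ontreat_adj_baseline}{on-treatment level ln(Y) adjusted for
#'     ln(X) used alone as the response.}
#' }
#' and two are level phenotypes feeding the gene-drug interaction test:
#' \describe{
#'   \item{baseline_level}{ln(X); statin type and dose are dropped from its
#'     covariate set (treatment covariates cannot affect a pretreatment
#'     level).}
#'   \item{ontreat_level}{ln(Y), full covariate set.}
#' }
#' "Adjusted" means the baseline value (ln(X), or raw X for `pct_adj`) is
#' appended to the covariates before residualization. Percent-change
#' residuals are rank-normalized by default since they are not already on a
#' transformed scale.
#'
#' @param definition one of the seven definition names above.
#' @param covariates character vector of covariate column names to
#'   residualize on (in addition to any baseline adjustment implied by the
#'   definition).
#' @param rank_normalize logical; `NULL` (default) means TRUE for the two
#'   pct definitions, FALSE otherwise.
#' @return object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(definition = c("logdiff_adj", "pct_unadj",
                                          "logdiff_unadj", "pct_adj",
                                          "ontreat_adj_baseline",
                                          "baseline_level", "ontreat_level"),
                           covariates = character(0),
                           rank_normalize = NULL) {
  definition <- match.arg(definition)
  if (is.null(rank_normalize))
    rank_normalize <- definition %in% c("pct_unadj", "pct_adj")
  structure(list(definition = definition, covariates = covariates,
                 rank_normalize = rank_normalize),
            class = "phenotype_spec")
}

#' Ordinary-least-squares residualization
#'
#' Residualizes a response on a covariate table by OLS with an intercept
#' always included, returning residuals that are exactly mean-zero. Factor
#' and character covariates are expanded to dummies via the usual model
#' matrix. A rank-deficient covariate matrix is an error naming the
#' collinear columns, because silently dropped covariates would change the
#' phenotype definition.
#'
#' @param values numeric response vector.
#' @param covariates data.frame of covariates, same number of rows; may
#'   have zero columns (pure centering).
#' @return numeric residual vector.
#' @export
residualize <- function(values, covariates = NULL) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing values in response")
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L)
    return(values - mean(values))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(values))
    stop("covariates and values lengths differ")
  if (anyNA(covariates))
    stop("missing covariate values; exclude individuals upstream")
  X <- stats::model.matrix(~ ., data = covariates)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  unname(qr.resid(q, values))
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal scores through their ranks:
#' \eqn{\Phi^{-1}((rank_i - c) / (n - 2c + 1))} with the Blom offset
#' c = 0.375. Ties receive average ranks before transformation. The map is
#' strictly order-preserving on distinct inputs and invariant to any
#' strictly monotone transform of its input.
#'
#' @param values numeric vector, length >= 2, not all identical.
#' @param c offset constant; default Blom (0.375).
#' @return transformed numeric vector.
#' @export
rank_inverse_normal <- function(values, c = 0.375) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  if (anyNA(values)) stop("missing values")
  if (max(values) == min(values))
    stop("all values identical: no ordering information to transform")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - c) / (n - 2 * c + 1))
}

#' Build a phenotype vector from measurement pairs
#'
#' Computes the raw phenotype per the definition, appends the baseline
#' value to the covariates for the "adjusted" definitions, residualizes by
#' OLS within the group, and rank-normalizes when the spec says so. For
#' `baseline_level`, statin type/dose covariates are dropped automatically.
#'
#' @param pairs measurement-pair data.frame from [select_pairs()] (columns
#'   `id`, `baseline`, `ontreat`), or any data.frame with those columns.
#' @param covariates covariate data.frame with an `id` column; rows are
#'   matched to `pairs$id`. Columns not named in `spec$covariates` are
#'   ignored.
#' @param spec a [phenotype_spec()].
#' @param group group label recorded in the output.
#' @return data.frame of class `phenotype_vector`: `id`, `value`,
#'   `definition`, `group`.
#' @export
build_response <- function(pairs, covariates = NULL, spec, group = "all") {
  stopifnot(inherits(spec, "phenotype_spec"))
  X <- pairs$baseline
  Y <- pairs$ontreat
  if (any(X <= 0) || any(Y <= 0))
    stop("nonpositive LDL-C measurement: log-scale phenotypes undefined")
  def <- spec$definition
  raw <- switch(def,
    logdiff_adj = ,
    logdiff_unadj = log(Y) - log(X),
    pct_unadj = ,
    pct_adj = (Y - X) / X,
    ontreat_adj_baseline = ,
    ontreat_level = log(Y),
    baseline_level = log(X))

  covar_names <- spec$covariates
  if (def == "baseline_level")
    covar_names <- setdiff(covar_names, c("statin_type", "statin_dose"))
  cv <- NULL
  if (length(covar_names)) {
    if (is.null(covariates)) stop("covariates required by the spec but absent")
    miss <- setdiff(covar_names, names(covariates))
    if (length(miss)) stop("covariate column(s) missing: ",
                           paste(miss, collapse = ", "))
    idx <- match(pairs$id, covariates$id)
    if (anyNA(idx)) stop("covariates missing for some individuals")
    cv <- covariates[idx, covar_names, drop = FALSE]
  } else {
    cv <- as.data.frame(matrix(nrow = nrow(pairs), ncol = 0))
  }
  if (def %in% c("logdiff_adj", "ontreat_adj_baseline")) cv$.lnX <- log(X)
  if (def == "pct_adj") cv$.X <- X
  res <- residualize(raw, cv)
  if (spec$rank_normalize) res <- rank_inverse_normal(res)
  out <- data.frame(id = pairs$id, value = res, definition = def,
                    group = group, stringsAsFactors = FALSE)
  class(out) <- c("phenotype_vector", "data.frame")
  out
}

#' Write a phenotype vector as TSV
#'
#' Columns `id`, `value`, `definition`, `group`.
#'
#' @param phen a `phenotype_vector`.
#' @param path output path.
#' @export
write_phenotype_tsv <- function(phen, path) {
  utils::write.table(phen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
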