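#' Parameters of the measurement-error bias model
#'
#' The single-variant version of the generative model used for closed-form
#' work: dosage g with variance \eqn{v = 2\,maf(1-maf)} under
#' Hardy-Weinberg,
#' \deqn{\ln X = \mu + \beta_b g + e + u,\qquad
#'       \ln Y = \mu + \beta_b g + e + \ln(1-r) + \beta_r g + w,}
#' \eqn{e \sim N(0,\sigma_{bio}^2)}, \eqn{u, w \sim N(0,\sigma_m^2)} all
#' independent. Covariates are omitted: they are independent of genotype in
#' the simulator and residualized out exactly in the large-sample limit.
#'
#' @param beta_baseline per-allele effect on true log baseline.
#' @param beta_response per-allele effect on log response.
#' @param maf minor allele frequency in (0, 1).
#' @param sigma_biology,sigma_measure log-scale SDs, as in [sim_params()].
#' @param response_fraction median fractional reduction r (does not enter
#'   any slope; kept for completeness).
#' @return object of class `model_params`.
#' @export
model_params <- function(beta_baseline = 0, beta_response = 0, maf = 0.3,
                         sigma_biology = 0.25, sigma_measure = 0.18,
                         response_fraction = 0.35) {
  if (maf <= 0 || maf >= 1) stop("maf must lie strictly in (0, 1)")
  if (sigma_measure < 0 || sigma_biology < 0) stop("SDs must be >= 0")
  if (response_fraction <= 0 || response_fraction >= 1)
    stop("response_fraction must lie strictly in (0, 1)")
  structure(list(beta_baseline = beta_baseline,
                 beta_response = beta_response, maf = maf,
                 sigma_biology = sigma_biology,
                 sigma_measure = sigma_measure,
                 response_fraction = response_fraction),
            class = "model_params")
}

# Internal: the moments of (g, lnX, lnY) needed everywhere.
theory_moments <- function(params) {
  bb <- params$beta_baseline; br <- params$beta_response
  v <- 2 * params$maf * (1 - params$maf)
  s2b <- params$sigma_biology^2; s2m <- params$sigma_measure^2
  list(v = v,
       var_x = bb^2 * v + s2b + s2m,                  # Var(lnX)
       var_y = (bb + br)^2 * v + s2b + s2m,           # Var(lnY)
       var_d = br^2 * v + 2 * s2m,                    # Var(lnY - lnX)
       cov_dx = br * bb * v - s2m,                    # Cov(D, lnX)
       cov_yx = bb * (bb + br) * v + s2b,             # Cov(lnY, lnX)
       s2m = s2m, s2b = s2b, bb = bb, br = br)
}

#' Large-sample expected genotype slope per phenotype definition
#'
#' The closed-form limit of the per-allele regression coefficient produced
#' by the two-stage procedure (residualize the phenotype on its covariates,
#' then regress the residuals on dosage) under the Gaussian
#' measurement-error model. Writing D = lnY - lnX and
#' \eqn{S_X^2 = Var(\ln X)}:
#' \describe{
#'   \item{logdiff_unadj}{slope \eqn{= \beta_r} exactly — the change score
#'     is unbiased whatever the baseline genetics or measurement error.}
#'   \item{logdiff_adj}{slope \eqn{= \beta_r - \gamma\beta_b} with
#'     \eqn{\gamma = (\beta_r\beta_b v - \sigma_m^2)/S_X^2}. For a pure
#'     baseline variant (\eqn{\beta_r = 0}) this is
#'     \eqn{+\beta_b\,\sigma_m^2 / S_X^2}: a spurious apparent "response"
#'     whose sign tracks the baseline effect — regression toward the mean
#'     imported into the genotype coefficient by the baseline covariate.
#'     It vanishes when \eqn{\sigma_m = 0} (measurement error must be
#'     present) or \eqn{\beta_b = 0} (no baseline pathway). With
#'     \eqn{\sigma_m = 0} and \eqn{\beta_b \neq 0} the two-stage procedure
#'     still attenuates a true response effect multiplicatively (by
#'     \eqn{\sigma_{bio}^2 / S_X^2}) — benign in the sense that it cannot
#'     manufacture an effect where \eqn{\beta_r = 0}.}
#'   \item{ontreat_adj_baseline}{slope
#'     \eqn{= (\beta_b+\beta_r) - \gamma_Y \beta_b},
#'     \eqn{\gamma_Y = Cov(\ln Y, \ln X)/S_X^2}; carries the same
#'     \eqn{\beta_b \sigma_m^2 / S_X^2} bias term.}
#'   \item{baseline_level}{\eqn{\beta_b}.}
#'   \item{ontreat_level}{\eqn{\beta_b + \beta_r}.}
#' }
#' No closed form is claimed for the two rank-normalized percent-change
#' definitions; they are validated by simulation equivalence with their
#' log-scale counterparts.
#'
#' @param params a [model_params()].
#' @param definition a phenotype definition name or [phenotype_spec()].
#' @return the expected per-allele slope (log-LDL-C units per allele).
#' @export
expected_slope <- function(params, definition) {
  stopifnot(inherits(params, "model_params"))
  if (inherits(definition, "phenotype_spec")) definition <- definition$definition
  m <- theory_moments(params)
  if (m$v == 0) stop("degenerate dosage variance")
  switch(definition,
    logdiff_unadj = m$br,
    logdiff_adj = {
      gamma <- m$cov_dx / m$var_x
      m$br - gamma * m$bb
    },
    ontreat_adj_baseline = {
      gamma <- m$cov_yx / m$var_x
      (m$bb + m$br) - gamma * m$bb
    },
    baseline_level = m$bb,
    ontreat_level = m$bb + m$br,
    pct_unadj = ,
    pct_adj = stop("no closed form for rank-normalized percent-change ",
                   "definitions; validate by simulation"),
    stop("unknown definition: ", definition))
}

# Internal: residual variance of the dosage regression for a definition,
# i.e. Var(phenotype residual) - slope^2 * v.
theory_residual_var <- function(params, definition) {
  m <- theory_moments(params)
  slope <- expected_slope(params, definition)
  var_p <- switch(definition,
    logdiff_unadj = m$var_d,
    logdiff_adj = m$var_d - m$cov_dx^2 / m$var_x,
    ontreat_adj_baseline = m$var_y - m$cov_yx^2 / m$var_x,
    baseline_level = m$var_x,
    ontreat_level = m$var_y,
    stop("unknown definition: ", definition))
  var_p - slope^2 * m$v
}

#' Expected rejection rate of the single-variant scan
#'
#' Power (or type-I error rate) of the two-sided t test of the dosage
#' slope at sample size n, from the noncentral t implied by the model:
#' noncentrality \eqn{= slope \sqrt{n v} / \sigma_{resid}} with the
#' residual SD of the definition's regression, df = n - 2. When the
#' expected slope is 0 the rate equals alpha exactly.
#'
#' @param params a [model_params()].
#' @param definition phenotype definition name.
#' @param n sample size (>= 10).
#' @param alpha two-sided significance level in (0, 1).
#' @return rejection probability.
#' @export
expected_rejection_rate <- function(params, definition, n, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  if (n < 10) stop("n must be >= 10")
  m <- theory_moments(params)
  slope <- expected_slope(params, definition)
  rv <- theory_residual_var(params, definition)
  if (rv <= 0)
    stop("phenotype has zero residual variance under these parameters; ",
         "the scan is degenerate")
  ncp <- slope * sqrt(n * m$v) / sqrt(rv)
  df <- n - 2
  crit <- stats::qt(1 - alpha / 2, df = df)
  stats::pt(-crit, df = df, ncp = ncp) +
    stats::pt(crit, df = df, ncp = ncp, lower.tail = FALSE)
}

#' Bias table over a parameter grid
#'
#' Tabulates the expected adjusted and unadjusted change-score slopes (and
#' the bias, their difference from \eqn{\beta_r}) over a grid of baseline
#' effects and measurement-error SDs. A compact view of how the spurious
#' coefficient scales with its two drivers.
#'
#' @param beta_baseline,sigma_measure numeric vectors defining the grid.
#' @param beta_response,maf,sigma_biology scalars held fixed.
#' @return data.frame with one row per grid point.
#' @export
bias_table <- function(beta_baseline = c(-0.1, -0.05, 0, 0.05, 0.1),
                       sigma_measure = c(0, 0.09, 0.18),
                       beta_response = 0, maf = 0.3, sigma_biology = 0.25) {
  grid <- expand.grid(beta_baseline = beta_baseline,
                      sigma_measure = sigma_measure)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- model_params(beta_baseline = grid$beta_baseline[i],
                      beta_response = beta_response, maf = maf,
                      sigma_biology = sigma_biology,
                      sigma_measure = grid$sigma_measure[i])
    adj <- expected_slope(p, "logdiff_adj")
    unadj <- expected_slope(p, "logdiff_unadj")
    data.frame(beta_baseline = grid$beta_baseline[i],
               sigma_measure = grid$sigma_measure[i],
               slope_unadj = unadj, slope_adj = adj,
               bias_adj = adj - beta_response)
  })
  do.call(rbind, rows)
}
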