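#' Simulation parameters for a synthetic statin cohort
#'
#' Bundles every generative parameter of the synthetic-data module: group
#' sample sizes, the variant panel with per-allele genetic effects, the
#' log-scale variance components of the LDL-C model, the multiplicative
#' statin response, covariate distributions, and EHR record-generation
#' controls. The generative model for individual i with dosage vector g_i is
#'
#' \deqn{\ln B_i = \mu + \sum_j \beta_{b,j} g_{ij} + c'z_i + e_i,\quad
#'       e_i \sim N(0, \sigma_{bio}^2)}
#' \deqn{\ln X_i = \ln B_i + u_i,\qquad
#'       \ln Y_i = \ln B_i + \ln(1-r) + \sum_j \beta_{r,j} g_{ij} + w_i}
#'
#' with u, w independent N(0, sigma_measure^2) measurement errors. X is the
#' observed baseline LDL-C and Y the observed on-treatment LDL-C, both in
#' mg/dL.
#'
#' @param n_individuals named integer vector: individuals per ancestry group.
#' @param variants data.frame with columns `variant`, `chrom`, `pos`, `maf`,
#'   `beta_baseline`, `beta_response` (and optionally `class`, a label used
#'   only in reports). Defaults to [demo_variants()].
#' @param mu_baseline mean log baseline LDL-C (log mg/dL). The default
#'   corresponds to a median baseline of ~130 mg/dL.
#' @param sigma_biology SD of the biological (true) log baseline around its
#'   genetic + covariate prediction.
#' @param sigma_measure SD of the log-scale measurement error, applied
#'   independently to the baseline and the on-treatment measurement. The
#'   default 0.18, against sigma_biology 0.25, puts ~34% of the non-genetic
#'   log-baseline variance in measurement error.
#' @param response_fraction median fractional LDL-C reduction r on statin,
#'   in (0,1); on-treatment level is multiplied by (1-r).
#' @param covariate_effects named numeric vector of log-scale effects of the
#'   simulated covariates on true baseline (names among `age`, `sex`, `bmi`,
#'   `smoking`, `diabetes`, `hypertension`); covariates are independent of
#'   genotype.
#' @param dosage_jitter half-width of uniform jitter added to integer dosages
#'   (clipped to \[0,2\]) to emulate imputation uncertainty; 0 disables.
#' @param ehr list of record-generation controls, see [simulate_ehr_records()]:
#'   `p_single_fill`, `p_no_pre_lipid`, `p_post_outside_window`,
#'   `p_cotherapy`, `mean_dispensings`, `days_supply`, `extra_lipids`.
#' @param seed integer seed; mandatory, all stages derive their streams
#'   from it deterministically.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_individuals = c(european = 12000, african = 8000),
                       variants = demo_variants(),
                       mu_baseline = log(130),
                       sigma_biology = 0.25,
                       sigma_measure = 0.18,
                       response_fraction = 0.35,
                       covariate_effects = c(age = 0.002, sex = -0.02, bmi = 0.004),
                       dosage_jitter = 0,
                       ehr = list(),
                       seed) {
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` is mandatory and must be a single integer")
  stopifnot(is.numeric(n_individuals), all(n_individuals >= 1),
            !is.null(names(n_individuals)))
  variants <- as.data.frame(variants)
  req <- c("variant", "chrom", "pos", "maf", "beta_baseline", "beta_response")
  if (!all(req %in% names(variants)))
    stop("`variants` must have columns: ", paste(req, collapse = ", "))
  if (any(variants$maf <= 0 | variants$maf >= 1))
    stop("minor allele frequencies must lie strictly in (0, 1)")
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  if (any(unlist(tapply(variants$pos, variants$chrom, function(p) diff(p) <= 0))))
    stop("variant positions must be strictly increasing within a chromosome")
  if (sigma_measure < 0) stop("sigma_measure must be >= 0")
  if (sigma_biology < 0) stop("sigma_biology must be >= 0")
  if (response_fraction <= 0 || response_fraction >= 1)
    stop("response_fraction must lie strictly in (0, 1)")
  if (dosage_jitter < 0 || dosage_jitter > 1) stop("dosage_jitter must be in [0, 1]")
  ehr_defaults <- list(p_single_fill = 0, p_no_pre_lipid = 0,
                       p_post_outside_window = 0, p_cotherapy = 0,
                       mean_dispensings = 4, days_supply = 30,
                       extra_lipids = 1)
  bad <- setdiff(names(ehr), names(ehr_defaults))
  if (length(bad)) stop("unknown ehr control(s): ", paste(bad, collapse = ", "))
  ehr <- utils::modifyList(ehr_defaults, ehr)
  structure(list(n_individuals = n_individuals, variants = variants,
                 mu_baseline = mu_baseline, sigma_biology = sigma_biology,
                 sigma_measure = sigma_measure,
                 response_fraction = response_fraction,
                 covariate_effects = covariate_effects,
                 dosage_jitter = dosage_jitter, ehr = ehr,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Demonstration variant panel
#'
#' Eight independent planted variants in four classes of two: `null` (no
#' genetic effect), `baseline_only` (effect on true baseline LDL-C only),
#' `response_only` (effect on statin response only), and `both` (effects on
#' baseline and response with agreeing direction, as observed at APOE).
#' Effect sizes are on the log-LDL-C scale per minor allele and are large
#' enough that a cohort of 20,000 detects every non-null pathway at
#' genome-wide significance.
#'
#' @return data.frame usable as the `variants` field of [sim_params()].
#' @export
demo_variants <- function() {
  data.frame(
    variant = sprintf("rs%05d", 1:8),
    chrom = c("1", "2", "5", "6", "9", "12", "17", "19"),
    pos = c(10e6, 20e6, 30e6, 40e6, 50e6, 60e6, 70e6, 80e6),
    maf = c(0.30, 0.25, 0.30, 0.20, 0.35, 0.25, 0.30, 0.40),
    beta_baseline = c(0, 0, 0.10, -0.10, 0, 0, -0.10, 0.10),
    beta_response = c(0, 0, 0, 0, -0.05, 0.05, -0.05, 0.05),
    class = c("null", "null", "baseline_only", "baseline_only",
              "response_only", "response_only", "both", "both"),
    stringsAsFactors = FALSE
  )
}

# Deterministic per-stage, per-group seed stream derived from params$seed.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, salt) {
  s <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.numeric(seed) * 7919 + s) %% 2147483647)
}

#' Simulate a genotype panel for one ancestry group
#'
#' Draws integer allelic dosages per variant under Hardy-Weinberg
#' proportions, dosage ~ Binomial(2, maf), independently across variants
#' (no linkage disequilibrium). With `dosage_jitter > 0` a uniform jitter
#' clipped to \[0,2\] emulates imputation uncertainty.
#'
#' @param params a [sim_params()] object.
#' @param group group label, one of `names(params$n_individuals)`.
#' @return object of class `genotype_panel`: list with `group`, `variants`
#'   (metadata data.frame) and `dosages` (individuals x variants matrix,
#'   rownames are individual ids).
#' @export
simulate_genotypes <- function(params, group) {
  stopifnot(inherits(params, "sim_params"))
  if (!group %in% names(params$n_individuals))
    stop("unknown group: ", group)
  n <- params$n_individuals[[group]]
  v <- params$variants
  set.seed(derive_seed(params$seed, paste0("geno/", group)))
  dos <- vapply(v$maf, function(m) stats::rbinom(n, 2L, m), numeric(n))
  dos <- matrix(dos, nrow = n)
  if (params$dosage_jitter > 0) {
    jit <- matrix(stats::runif(length(dos), -params$dosage_jitter,
                               params$dosage_jitter), nrow = n)
    dos <- pmin(pmax(dos + jit, 0), 2)
  }
  rownames(dos) <- sprintf("%s_%06d", group, seq_len(n))
  colnames(dos) <- v$variant
  structure(list(group = group, variants = v, dosages = dos),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype panel:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "variants, group", x$group, "\n")
  invisible(x)
}

#' Simulate the observed baseline / on-treatment LDL-C pair
#'
#' Applies the generative model documented in [sim_params()]: a true log
#' baseline with genetic and covariate effects, an independent log-scale
#' measurement error on each of the two measurements, and a multiplicative
#' statin response (1 - r) with per-allele response effects. Covariates are
#' drawn independent of genotype.
#'
#' @param panel a `genotype_panel`.
#' @param params the [sim_params()] the panel was generated from.
#' @return list with `pairs` (data.frame id, X, Y in mg/dL), `covariates`
#'   (data.frame id, age, sex, bmi, smoking, diabetes, hypertension,
#'   statin_type, statin_dose), and `true_state` (data.frame id, lnB, u, w
#'   latent draws; for oracle checks only, never consumed by analysis
#'   stages).
#' @export
simulate_ldl_pair <- function(panel, params) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(params, "sim_params"))
  r <- params$response_fraction
  if (r <= 0 || r >= 1) stop("response_fraction must lie strictly in (0, 1)")
  n <- nrow(panel$dosages)
  ids <- rownames(panel$dosages)
  set.seed(derive_seed(params$seed, paste0("pheno/", panel$group)))
  covar <- data.frame(
    id = ids,
    age = round(stats::rnorm(n, 58, 10)),
    sex = stats::rbinom(n, 1L, 0.5),
    bmi = round(stats::rnorm(n, 28, 4.5), 1),
    smoking = stats::rbinom(n, 1L, 0.25),
    diabetes = stats::rbinom(n, 1L, 0.20),
    hypertension = stats::rbinom(n, 1L, 0.45),
    statin_type = sample(c("atorvastatin", "simvastatin", "lovastatin",
                           "pravastatin", "rosuvastatin"), n, replace = TRUE,
                         prob = c(0.35, 0.35, 0.15, 0.10, 0.05)),
    statin_dose = sample(c(10, 20, 40, 80), n, replace = TRUE,
                         prob = c(0.25, 0.40, 0.25, 0.10)),
    stringsAsFactors = FALSE
  )
  ce <- params$covariate_effects
  cz <- rep(0, n)
  for (nm in names(ce)) {
    if (!nm %in% names(covar)) stop("covariate_effects names unknown: ", nm)
    # age/bmi enter centered so mu_baseline stays the population log-median
    x <- covar[[nm]]
    if (nm %in% c("age", "bmi")) x <- x - mean(x)
    cz <- cz + ce[[nm]] * x
  }
  G <- panel$dosages
  lnB <- params$mu_baseline + drop(G %*% panel$variants$beta_baseline) + cz +
    stats::rnorm(n, 0, params$sigma_biology)
  u <- stats::rnorm(n, 0, params$sigma_measure)
  w <- stats::rnorm(n, 0, params$sigma_measure)
  lnX <- lnB + u
  lnY <- lnB + log1p(-r) + drop(G %*% panel$variants$beta_response) + w
  list(pairs = data.frame(id = ids, X = exp(lnX), Y = exp(lnY),
                          stringsAsFactors = FALSE),
       covariates = covar,
       true_state = data.frame(id = ids, lnB = lnB, u = u, w = w,
                               stringsAsFactors = FALSE))
}

#' Simulate EHR-like longitudinal records around simulated LDL-C pairs
#'
#' Wraps each individual's (X, Y) pair in dated electronic-health-record
#' events: statin dispensings (with days' supply), lipid measurements placed
#' inside and outside the legal on-treatment window, and co-therapy
#' dispensings of non-statin LDL-C drugs. Violations of the downstream
#' eligibility filters are injected at the configured rates so that every
#' cohort filter branch is exercised, and each injected violation is written
#' to a ledger for oracle comparisons.
#'
#' Injection controls (in `params$ehr`): `p_single_fill` (only one statin
#' dispensing, fails the new-user rule), `p_no_pre_lipid` (no pretreatment
#' lipid), `p_post_outside_window` (the only post lipid falls after the
#' window closes), `p_cotherapy` (an ezetimibe fill whose coverage interval
#' contains the on-treatment measurement date, making it ineligible).
#'
#' @param params a [sim_params()] object.
#' @param sim output of [simulate_ldl_pair()].
#' @param group group label used for seeding and ids.
#' @return object of class `cohort_records`: list of data.frames
#'   `dispensings` (id, date, statin_type, dose, days_supply),
#'   `cotherapy` (id, date, drug_class, days_supply),
#'   `lipids` (id, date, ldl), `covariates`, and `ledger`
#'   (id, violation in none/single_fill/no_pre_lipid/post_outside_window/
#'   cotherapy_overlap).
#' @export
simulate_ehr_records <- function(params, sim, group = "cohort") {
  stopifnot(inherits(params, "sim_params"))
  e <- params$ehr
  pr <- sim$pairs
  n <- nrow(pr)
  set.seed(derive_seed(params$seed, paste0("ehr/", group)))
  # one violation class at most per individual, mutually exclusive draw
  p <- c(single_fill = e$p_single_fill, no_pre_lipid = e$p_no_pre_lipid,
         post_outside_window = e$p_post_outside_window,
         cotherapy_overlap = e$p_cotherapy)
  if (any(p < 0) || sum(p) > 1)
    stop("violation probabilities must be nonnegative and sum to at most 1")
  viol <- apply(stats::rmultinom(n, 1L, c(p, none = 1 - sum(p))), 2L,
                function(col) c(names(p), "none")[which(col == 1L)])
  origin <- as.Date("2005-01-01")
  init <- origin + sample.int(3000L, n, replace = TRUE)
  ds <- e$days_supply
  n_disp <- pmax(2L, stats::rpois(n, e$mean_dispensings))
  n_disp[viol == "single_fill"] <- 1L

  # dispensings: refills every days_supply days from initiation
  disp_id <- rep(pr$id, n_disp)
  disp_k <- sequence(n_disp) - 1L
  disp <- data.frame(
    id = disp_id,
    date = rep(init, n_disp) + disp_k * ds,
    statin_type = rep(sim$covariates$statin_type, n_disp),
    dose = rep(sim$covariates$statin_dose, n_disp),
    days_supply = ds,
    stringsAsFactors = FALSE
  )

  # lipid measurements: a distant early pre lipid (noise), the baseline
  # lipid shortly before initiation, and the on-treatment lipid inside
  # [init + 21, init + days_supply + 21] (or past it, when injected)
  base_lag <- sample(7:90, n, replace = TRUE)
  on_lag <- 21L + sample.int(ds, n, replace = TRUE) - 1L
  on_lag[viol == "post_outside_window"] <- ds + 21L + sample(7:60,
    sum(viol == "post_outside_window"), replace = TRUE)
  lip <- data.frame(id = pr$id, date = init - base_lag, ldl = pr$X,
                    stringsAsFactors = FALSE)
  lip <- rbind(lip, data.frame(id = pr$id, date = init + on_lag, ldl = pr$Y,
                               stringsAsFactors = FALSE))
  if (e$extra_lipids > 0) {
    # historical noise measurements well before baseline
    keep <- stats::rbinom(n, 1L, min(1, e$extra_lipids)) == 1L &
      viol != "no_pre_lipid"
    if (any(keep)) {
      old <- data.frame(
        id = pr$id[keep],
        date = init[keep] - sample(200:800, sum(keep), replace = TRUE),
        ldl = round(pr$X[keep] * exp(stats::rnorm(sum(keep), 0, 0.1)), 1),
        stringsAsFactors = FALSE)
      lip <- rbind(lip, old)
    }
  }
  # no_pre_lipid violation: strip every pre-initiation lipid of flagged ids
  drop_pre <- viol == "no_pre_lipid"
  pre_rows <- lip$date < init[match(lip$id, pr$id)]
  lip <- lip[!(drop_pre[match(lip$id, pr$id)] & pre_rows), ]

  # co-therapy overlapping the on-treatment measurement date
  co_ids <- pr$id[viol == "cotherapy_overlap"]
  cot <- data.frame(id = character(0), date = origin[0],
                    drug_class = character(0), days_supply = numeric(0),
                    stringsAsFactors = FALSE)
  if (length(co_ids)) {
    idx <- match(co_ids, pr$id)
    cot <- data.frame(
      id = co_ids,
      date = init[idx] + on_lag[idx] - sample(0:10, length(co_ids), replace = TRUE),
      drug_class = sample(c("ezetimibe", "bile acid sequestrant", "fibrate",
                            "niacin", "omega-3"), length(co_ids), replace = TRUE),
      days_supply = 30,
      stringsAsFactors = FALSE)
  }
  structure(list(dispensings = disp[order(disp$id, disp$date), ],
                 cotherapy = cot,
                 lipids = lip[order(lip$id, lip$date), ],
                 covariates = sim$covariates,
                 ledger = data.frame(id = pr$id, violation = viol,
                                     stringsAsFactors = FALSE)),
            class = "cohort_records")
}

#' Simulate a complete multi-group cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_ldl_pair()] and [simulate_ehr_records()] for every group in
#' `params$n_individuals`.
#'
#' @param params a [sim_params()] object.
#' @return named list per group, each with `panel`, `sim`
#'   (pairs/covariates/true_state), and `records`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  out <- lapply(names(params$n_individuals), function(g) {
    panel <- simulate_genotypes(params, g)
    sim <- simulate_ldl_pair(panel, params)
    rec <- simulate_ehr_records(params, sim, group = g)
    list(panel = panel, sim = sim, records = rec)
  })
  names(out) <- names(params$n_individuals)
  out
}

#' Export variant metadata as a minimal VCF-like table
#'
#' Writes a five-column plain-text table (CHROM, POS, ID, REF, ALT) for
#' interoperability with variant-centric tools. Alleles are placeholders
#' (A/G) since the simulator models dosages, not sequences.
#'
#' @param variants variant metadata data.frame (`variant`, `chrom`, `pos`).
#' @param path output path.
#' @export
write_variants_table <- function(variants, path) {
  out <- data.frame(CHROM = variants$chrom, POS = variants$pos,
                    ID = variants$variant, REF = "A", ALT = "G")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
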