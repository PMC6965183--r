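# Shared fixtures built in code.

# Bare-bones single-variant simulation used by theory/power tests: returns
# g, lnX, lnY for the Gaussian measurement-error model without the EHR layer.
sim_single <- function(n, bb = 0, br = 0, maf = 0.3, sb = 0.25, sm = 0.18,
                       r = 0.35) {
  g <- stats::rbinom(n, 2, maf)
  e <- stats::rnorm(n, 0, sb)
  u <- stats::rnorm(n, 0, sm)
  w <- stats::rnorm(n, 0, sm)
  lnX <- log(130) + bb * g + e + u
  lnY <- log(130) + bb * g + e + log(1 - r) + br * g + w
  list(g = g, lnX = lnX, lnY = lnY)
}

# Minimal genotype panel wrapper around a dosage matrix.
panel_from_matrix <- function(G, group = "toy", chrom = NULL, pos = NULL) {
  m <- ncol(G)
  rownames(G) <- sprintf("%s_%06d", group, seq_len(nrow(G)))
  v <- data.frame(variant = sprintf("v%03d", seq_len(m)),
                  chrom = if (is.null(chrom)) rep("1", m) else chrom,
                  pos = if (is.null(pos)) seq_len(m) * 1e6 else pos,
                  maf = colMeans(G) / 2,
                  beta_baseline = 0, beta_response = 0,
                  stringsAsFactors = FALSE)
  colnames(G) <- v$variant
  structure(list(group = group, variants = v, dosages = G),
            class = "genotype_panel")
}

phen_from_values <- function(values, panel, definition = "logdiff_unadj") {
  out <- data.frame(id = rownames(panel$dosages), value = values,
                    definition = definition, group = panel$group,
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_vector", "data.frame")
  out
}

# Hand-written five-individual EHR toy panel exercising each cohort rule:
#   p1: single statin fill                      -> excluded (new-user rule)
#   p2: no pretreatment lipid                   -> excluded
#   p3: post lipid outside the legal window     -> excluded
#   p4: fully valid                             -> retained
#   p5: fully valid (several candidate lipids)  -> retained
toy_records <- function() {
  d0 <- as.Date("2010-01-01")  # initiation date for everyone
  disp <- data.frame(
    id = c("p1", rep(c("p2", "p3", "p4", "p5"), each = 2)),
    date = d0 + c(0, 0, 30, 0, 30, 0, 30, 0, 30),
    statin_type = "simvastatin", dose = 20, days_supply = 30,
    stringsAsFactors = FALSE)
  lip <- data.frame(
    id = c("p1", "p1",          # valid pair but only one fill
           "p2",                # post only
           "p3", "p3",          # pre ok, post at day 60 > day 51 close
           "p4", "p4", "p4", "p4",  # -400, -10, +5 (early), +25 (valid)
           "p5", "p5"),
    date = d0 + c(-15, 30,
                  25,
                  -20, 60,
                  -400, -10, 5, 25,
                  -5, 40),
    ldl = c(150, 100,
            110,
            140, 95,
            160, 150, 140, 100,
            155, 105),
    stringsAsFactors = FALSE)
  covar <- data.frame(id = paste0("p", 1:5), age = 60, sex = 1, bmi = 27,
                      smoking = 0, diabetes = 0, hypertension = 0,
                      statin_type = "simvastatin", statin_dose = 20,
                      stringsAsFactors = FALSE)
  structure(list(dispensings = disp,
                 cotherapy = data.frame(id = character(0),
                                        date = as.Date(character(0)),
                                        drug_class = character(0),
                                        days_supply = numeric(0),
                                        stringsAsFactors = FALSE),
                 lipids = lip, covariates = covar, ledger = NULL),
            class = "cohort_records")
}
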