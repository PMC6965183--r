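test_that("genotype simulation is reproducible and respects Hardy-Weinberg", {
  sp <- sim_params(n_individuals = c(a = 4), variants = data.frame(
    variant = "v1", chrom = "1", pos = 100, maf = 0.5,
    beta_baseline = 0, beta_response = 0), seed = 5)
  p1 <- simulate_genotypes(sp, "a")
  p2 <- simulate_genotypes(sp, "a")
  expect_identical(p1$dosages, p2$dosages)
  expect_true(all(p1$dosages %in% 0:2))
  expect_equal(dim(p1$dosages), c(4L, 1L))

  # near-zero MAF: all dosages 0
  sp0 <- sim_params(n_individuals = c(a = 100), variants = data.frame(
    variant = "v1", chrom = "1", pos = 100, maf = 1e-9,
    beta_baseline = 0, beta_response = 0), seed = 5)
  expect_true(all(simulate_genotypes(sp0, "a")$dosages == 0))

  # empirical allele frequency converges: within 3 binomial SEs at n = 50,000
  n <- 50000
  spc <- sim_params(n_individuals = c(a = n), variants = data.frame(
    variant = "v1", chrom = "1", pos = 100, maf = 0.2,
    beta_baseline = 0, beta_response = 0), seed = 9)
  af <- mean(simulate_genotypes(spc, "a")$dosages) / 2
  expect_lt(abs(af - 0.2), 3 * sqrt(0.2 * 0.8 / (2 * n)))

  expect_error(sim_params(n_individuals = c(a = 10), variants = data.frame(
    variant = "v1", chrom = "1", pos = 100, maf = 1.2,
    beta_baseline = 0, beta_response = 0), seed = 1), "allele frequencies")
})

test_that("LDL pair generation matches the generative model exactly in the noise-free limit", {
  v <- data.frame(variant = c("v1", "v2"), chrom = "1", pos = c(1e6, 2e6),
                  maf = c(0.3, 0.4), beta_baseline = 0, beta_response = 0)
  sp <- sim_params(n_individuals = c(a = 200), variants = v,
                   sigma_measure = 0, response_fraction = 0.35,
                   covariate_effects = c(age = 0), seed = 3)
  panel <- simulate_genotypes(sp, "a")
  sim <- simulate_ldl_pair(panel, sp)
  expect_true(all(sim$pairs$X > 0 & sim$pairs$Y > 0))
  # sigma_m = 0, all beta = 0: Y/X = 1 - r exactly for every individual
  expect_equal(sim$pairs$Y / sim$pairs$X, rep(0.65, 200), tolerance = 1e-12)

  # with sigma_m = 0 and sigma_biology = 0, lnY - lnX = ln(1-r) + sum(br*g)
  v2 <- v; v2$beta_response <- c(-0.05, 0.08)
  sp2 <- sim_params(n_individuals = c(a = 300), variants = v2,
                    sigma_measure = 0, sigma_biology = 0,
                    covariate_effects = c(age = 0), seed = 4)
  panel2 <- simulate_genotypes(sp2, "a")
  sim2 <- simulate_ldl_pair(panel2, sp2)
  expected <- unname(log(0.65) + drop(panel2$dosages %*% v2$beta_response))
  expect_equal(log(sim2$pairs$Y) - log(sim2$pairs$X), expected,
               tolerance = 1e-12)
})

test_that("latent structure has the derived second moments", {
  # no genetics: corr(lnX, lnY) = sb^2 / (sb^2 + sm^2); Var(lnX) additive
  n <- 100000
  sb <- 0.25; sm <- 0.18
  v <- data.frame(variant = "v1", chrom = "1", pos = 1e6, maf = 0.3,
                  beta_baseline = 0, beta_response = 0)
  sp <- sim_params(n_individuals = c(a = n), variants = v,
                   sigma_biology = sb, sigma_measure = sm,
                   covariate_effects = c(age = 0), seed = 17)
  sim <- simulate_ldl_pair(simulate_genotypes(sp, "a"), sp)
  r_obs <- cor(log(sim$pairs$X), log(sim$pairs$Y))
  r_exp <- sb^2 / (sb^2 + sm^2)
  expect_lt(abs(r_obs - r_exp), 4 / sqrt(n))

  # null baseline genetics: corr(g, lnX) within 3 SEs of 0 at n = 20,000
  sp_null <- sim_params(n_individuals = c(a = 20000), variants = v,
                        covariate_effects = c(age = 0), seed = 21)
  panel <- simulate_genotypes(sp_null, "a")
  simn <- simulate_ldl_pair(panel, sp_null)
  expect_lt(abs(cor(panel$dosages[, 1], log(simn$pairs$X))),
            3 / sqrt(20000))

  # with baseline genetics: Var(lnX) = sb^2 + sm^2 + sum(bb^2 * 2maf(1-maf))
  vb <- v; vb$beta_baseline <- 0.1
  spb <- sim_params(n_individuals = c(a = n), variants = vb,
                    covariate_effects = c(age = 0), seed = 23)
  simb <- simulate_ldl_pair(simulate_genotypes(spb, "a"), spb)
  expect_equal(var(log(simb$pairs$X)),
               sb^2 + sm^2 + 0.1^2 * 2 * 0.3 * 0.7, tolerance = 0.02)
})

test_that("EHR record generation injects violations per its own ledger", {
  # all violation rates 0: every individual passes every filter
  sp <- sim_params(n_individuals = c(a = 400), seed = 31)
  co <- simulate_cohort(sp)
  kept <- attr(new_user_filter(co$a$records), "retained")
  expect_length(kept, 400)

  # single-fill probability 1: new-user filter retains nobody
  sp1 <- sim_params(n_individuals = c(a = 50), seed = 32,
                    ehr = list(p_single_fill = 1))
  co1 <- simulate_cohort(sp1)
  expect_length(attr(new_user_filter(co1$a$records), "retained"), 0)

  # 10% co-therapy overlap: excluded-on-treatment count equals the ledger
  sp2 <- sim_params(n_individuals = c(a = 1000), seed = 33,
                    ehr = list(p_cotherapy = 0.1))
  co2 <- simulate_cohort(sp2)
  rec <- co2$a$records
  pr <- select_pairs(rec)
  n_led <- sum(rec$ledger$violation == "cotherapy_overlap")
  expect_gt(n_led, 0)
  expect_identical(sum(attr(pr, "exclusions")), n_led)
  expect_setequal(setdiff(rec$ledger$id, pr$id),
                  rec$ledger$id[rec$ledger$violation == "cotherapy_overlap"])

  # determinism of the whole record layer
  co2b <- simulate_cohort(sp2)
  expect_identical(co2$a$records, co2b$a$records)
})
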