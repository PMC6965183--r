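#' Read a run configuration file
#'
#' Plain-text YAML key-value configuration for [run_experiment()]. The
#' `seed` key is mandatory; every other key falls back to the
#' [sim_params()] / [run_experiment()] defaults. Recognized keys:
#' `seed`, `n_individuals` (map group -> count), `variants` (path to a TSV
#' with the [sim_params()] variant columns, or inline list of maps),
#' `mu_baseline`, `sigma_biology`, `sigma_measure`, `response_fraction`,
#' `dosage_jitter`, `ehr` (map of record-generation controls),
#' `definitions` (list of phenotype definition names), `covariates`,
#' `sig`, `sug`, `window`, `outdir`.
#'
#' @param path path to the YAML file.
#' @return list of class `run_config` with elements `params` (a
#'   [sim_params()]) and the remaining orchestration settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set `seed`")
  variants <- if (is.null(cfg$variants)) demo_variants()
    else if (is.character(cfg$variants)) utils::read.delim(cfg$variants,
                                                           stringsAsFactors = FALSE)
    else do.call(rbind, lapply(cfg$variants, as.data.frame))
  sp_args <- list(seed = cfg$seed, variants = variants)
  if (!is.null(cfg$n_individuals)) sp_args$n_individuals <- unlist(cfg$n_individuals)
  for (k in c("mu_baseline", "sigma_biology", "sigma_measure",
              "response_fraction", "dosage_jitter"))
    if (!is.null(cfg[[k]])) sp_args[[k]] <- cfg[[k]]
  if (!is.null(cfg$ehr)) sp_args$ehr <- cfg$ehr
  structure(list(
    params = do.call(sim_params, sp_args),
    definitions = cfg$definitions %||% NULL,
    covariates = cfg$covariates %||% NULL,
    sig = cfg$sig %||% 5e-8, sug = cfg$sug %||% 1e-5,
    window = cfg$window %||% 5e5,
    outdir = cfg$outdir %||% NULL), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full baseline-adjustment bias experiment
#'
#' Orchestrates every stage on a synthetic multi-group cohort: simulation,
#' new-user filtering and pair selection, construction of all phenotype
#' definitions, per-group association scans, fixed-effects meta-analysis,
#' the baseline-vs-on-treatment interaction scan, locus calling at the
#' genome-wide and suggestive thresholds, and the genomic inflation factor
#' per scan. The report compares, per phenotype definition, which planted
#' variant classes were flagged at genome-wide significance — the
#' in-silico analogue of counting significant loci with and without
#' baseline adjustment.
#'
#' @param config a `run_config` from [read_run_config()], a [sim_params()]
#'   object (orchestration defaults are used), or a bare seed.
#' @param definitions phenotype definitions to run; default all seven.
#' @param covariates covariate column names residualized out of every
#'   phenotype (statin type/dose are dropped automatically for the
#'   baseline level).
#' @param sig,sug,window locus-calling thresholds, see [call_loci()].
#' @param outdir if non-NULL, stage outputs (TSVs and a Markdown report)
#'   are written there; the pipeline is resumable from these tables.
#' @return list of class `bias_report`; see Details. Key elements:
#'   `flagged` (named list: definition -> character vector of flagged
#'   planted classes), `loci`, `meta`, `interaction`, `lambda`, `counts`.
#' @export
run_experiment <- function(config,
                           definitions = c("logdiff_adj", "pct_unadj",
                                           "logdiff_unadj", "pct_adj",
                                           "ontreat_adj_baseline",
                                           "baseline_level", "ontreat_level"),
                           covariates = c("age", "sex", "bmi", "smoking",
                                          "diabetes", "hypertension",
                                          "statin_type", "statin_dose"),
                           sig = 5e-8, sug = 1e-5, window = 5e5,
                           outdir = NULL) {
  if (inherits(config, "run_config")) {
    params <- config$params
    definitions <- config$definitions %||% definitions
    covariates <- config$covariates %||% covariates
    sig <- config$sig; sug <- config$sug; window <- config$window
    outdir <- config$outdir %||% outdir
  } else if (inherits(config, "sim_params")) {
    params <- config
  } else if (is.numeric(config) && length(config) == 1L) {
    params <- sim_params(seed = config)
  } else stop("config must be a run_config, sim_params, or a seed")
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  groups <- names(params$n_individuals)
  cohort <- simulate_cohort(params)

  counts <- list()
  scans <- stats::setNames(vector("list", length(definitions)), definitions)
  for (d in definitions) scans[[d]] <- list()

  for (g in groups) {
    rec <- new_user_filter(cohort[[g]]$records)
    pairs <- select_pairs(rec)
    panel <- maf_filter(cohort[[g]]$panel, large_group = groups[1])
    counts[[g]] <- c(simulated = params$n_individuals[[g]],
                     retained = nrow(pairs),
                     variants_kept = ncol(panel$dosages))
    covar <- cohort[[g]]$records$covariates
    for (d in definitions) {
      spec <- phenotype_spec(d, covariates = covariates)
      phen <- build_response(pairs, covar, spec, group = g)
      scans[[d]][[g]] <- assoc_scan(phen, panel)
    }
    if (!is.null(outdir)) {
      write_records_tsv(cohort[[g]]$records,
                        file.path(outdir, paste0("records_", g, ".tsv")))
      utils::write.table(pairs, file.path(outdir, paste0("pairs_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  meta <- lapply(definitions, function(d) {
    if (length(groups) >= 2L) meta_scan(scans[[d]])
    else {
      m <- scans[[d]][[groups[1]]]
      m$k <- 1L
      m
    }
  })
  names(meta) <- definitions

  lambda <- vapply(meta, function(m) genomic_inflation(m$p), numeric(1))

  interaction <- NULL
  if (all(c("baseline_level", "ontreat_level") %in% definitions)) {
    interaction <- interaction_scan(meta[["baseline_level"]],
                                    meta[["ontreat_level"]])
  }

  tables <- meta
  if (!is.null(interaction)) tables$interaction <- interaction
  loci <- lapply(tables, call_loci, sig = sig, sug = sug, window = window)

  cls <- params$variants$class
  if (is.null(cls)) cls <- rep("planted", nrow(params$variants))
  names(cls) <- params$variants$variant
  flagged <- lapply(loci, function(lt) {
    leads <- lt$lead_variant[lt$tier == "genome-wide"]
    sort(unique(unname(cls[leads])))
  })

  report <- structure(list(
    seed = params$seed, groups = groups, counts = counts,
    definitions = definitions, scans = scans, meta = meta,
    interaction = interaction, loci = loci, lambda = lambda,
    flagged = flagged, thresholds = c(sig = sig, sug = sug, window = window)),
    class = "bias_report")

  if (!is.null(outdir)) {
    for (d in definitions)
      write_assoc_tsv(meta[[d]], file.path(outdir, paste0("meta_", d, ".tsv")))
    if (!is.null(interaction))
      write_assoc_tsv(interaction, file.path(outdir, "interaction.tsv"))
    for (nm in names(loci))
      utils::write.table(loci[[nm]], file.path(outdir, paste0("loci_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(format_report_md(report), file.path(outdir, "report.md"))
  }
  report
}

format_report_md <- function(x) {
  out <- c("# Baseline-adjustment bias experiment", "",
           paste0("Seed: ", x$seed), "", "## Cohort counts", "")
  for (g in names(x$counts)) {
    ct <- x$counts[[g]]
    out <- c(out, paste0("- ", g, ": simulated ", ct[["simulated"]],
                         ", retained ", ct[["retained"]],
                         ", variants kept ", ct[["variants_kept"]]))
  }
  out <- c(out, "", "## Genome-wide flagged planted classes per model", "")
  for (nm in names(x$flagged)) {
    fl <- x$flagged[[nm]]
    # lambda is a null-calibration diagnostic: meaningless on a small
    # all-planted panel, so only printed for scans of many variants
    lam <- if (nm %in% names(x$lambda) && nrow(x$meta[[nm]]) >= 1000)
      sprintf(" (lambda %.3f)", x$lambda[[nm]]) else ""
    out <- c(out, paste0("- ", nm, lam, ": ",
                         if (length(fl)) paste(fl, collapse = ", ") else "none"))
  }
  nl <- vapply(x$loci, function(l) sum(l$tier == "genome-wide"), numeric(1))
  out <- c(out, "", "## Genome-wide locus counts", "",
           paste0("- ", names(nl), ": ", nl))
  out
}

#' @export
print.bias_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}
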