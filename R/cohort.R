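#' Select the baseline / on-treatment LDL-C measurement pair per individual
#'
#' Implements the study's measurement-pair rule. Statin initiation is the
#' date of the first statin dispensing. The baseline is the most recent
#' lipid measurement strictly before initiation; the on-treatment value is
#' the earliest lipid measurement inside the window
#' \[initiation + 21 days, initiation + first-fill days' supply + 21 days\]
#' (endpoints inclusive). Any lipid measurement dated inside a co-therapy
#' coverage interval \[fill date, fill date + days' supply\] of a non-statin
#' LDL-C drug (bile acid sequestrant, ezetimibe, fibrate, prescription
#' niacin, prescription omega-3) is ineligible for either role. Individuals
#' without a valid pair are excluded (exclusion is a value, not an error).
#'
#' @param records a `cohort_records` object (see [simulate_ehr_records()]).
#' @param lag_days the "3 weeks" convention in days; default 21 calendar
#'   days, endpoints inclusive.
#' @return data.frame with one row per individual having a valid pair:
#'   `id`, `baseline`, `baseline_date`, `ontreat`, `ontreat_date`,
#'   `init_date`, `first_days_supply`. An attribute `"exclusions"` tabulates
#'   why the remaining individuals were excluded.
#' @export
select_pairs <- function(records, lag_days = 21) {
  stopifnot(inherits(records, "cohort_records"))
  disp <- records$dispensings
  lip <- records$lipids
  cot <- records$cotherapy
  all_ids <- unique(c(records$covariates$id, disp$id, lip$id))

  if (nrow(disp) == 0L) {
    out <- empty_pairs()
    attr(out, "exclusions") <- c(no_dispensing = length(all_ids))
    return(out)
  }
  o <- order(disp$id, disp$date)
  disp <- disp[o, , drop = FALSE]
  first <- disp[!duplicated(disp$id), , drop = FALSE]
  init <- first$date
  names(init) <- first$id
  ds1 <- first$days_supply
  names(ds1) <- first$id

  # co-therapy coverage: flag lipids dated inside any interval of the same id
  covered <- rep(FALSE, nrow(lip))
  if (!is.null(cot) && nrow(cot) > 0L) {
    lip$.row <- seq_len(nrow(lip))
    m <- merge(lip[c("id", "date", ".row")], cot[c("id", "date", "days_supply")],
               by = "id", suffixes = c("", ".co"))
    hit <- m$date >= m$date.co & m$date <= m$date.co + m$days_supply
    covered[unique(m$.row[hit])] <- TRUE
    lip$.row <- NULL
  }
  lip_init <- init[lip$id]
  lip_ds1 <- ds1[lip$id]
  eligible <- !covered & !is.na(lip_init)

  pick <- function(cand, decreasing) {
    # one lipid per id: extreme date, record order breaking exact date ties
    o <- order(cand$id, if (decreasing) -as.numeric(cand$date) else
      as.numeric(cand$date), cand$.ord)
    cand <- cand[o, , drop = FALSE]
    sel <- cand[!duplicated(cand$id), , drop = FALSE]
    ties <- sum(paste(cand$id, cand$date) %in% paste(sel$id, sel$date)) -
      nrow(sel)
    if (ties > 0)
      warning(ties, " lipid date tie(s) broken by record order")
    sel
  }
  lip$.ord <- seq_len(nrow(lip))

  pre <- lip[eligible & lip$date < lip_init, , drop = FALSE]
  base_sel <- pick(pre, decreasing = TRUE)

  in_win <- eligible & lip$date >= lip_init + lag_days &
    lip$date <= lip_init + lip_ds1 + lag_days
  post <- lip[in_win & !is.na(in_win), , drop = FALSE]
  on_sel <- pick(post, decreasing = FALSE)

  ok <- intersect(base_sel$id, on_sel$id)
  bi <- base_sel[match(ok, base_sel$id), ]
  oi <- on_sel[match(ok, on_sel$id), ]
  out <- data.frame(id = ok,
                    baseline = bi$ldl, baseline_date = bi$date,
                    ontreat = oi$ldl, ontreat_date = oi$date,
                    init_date = init[ok],
                    first_days_supply = ds1[ok],
                    stringsAsFactors = FALSE, row.names = NULL)
  excl_ids <- setdiff(all_ids, ok)
  reason <- ifelse(!excl_ids %in% names(init), "no_dispensing",
                   ifelse(!excl_ids %in% base_sel$id, "no_valid_baseline",
                          "no_valid_ontreatment"))
  attr(out, "exclusions") <- table(factor(reason, levels = c(
    "no_dispensing", "no_valid_baseline", "no_valid_ontreatment")))
  out
}

empty_pairs <- function() {
  data.frame(id = character(0), baseline = numeric(0),
             baseline_date = as.Date(character(0)), ontreat = numeric(0),
             ontreat_date = as.Date(character(0)),
             init_date = as.Date(character(0)),
             first_days_supply = numeric(0), stringsAsFactors = FALSE)
}

#' Measurement pair for a single individual
#'
#' Single-record convenience wrapper around [select_pairs()].
#'
#' @param record a `cohort_records` object restricted to one individual (or
#'   containing several, in which case `id` selects one).
#' @param id individual id; defaults to the only id present.
#' @param lag_days see [select_pairs()].
#' @return a one-row pair data.frame, or `NULL` when no valid pair exists
#'   (the exclusion marker).
#' @export
select_pair <- function(record, id = NULL, lag_days = 21) {
  pr <- select_pairs(record, lag_days = lag_days)
  if (is.null(id)) {
    if (nrow(pr) > 1L) stop("several individuals present; give `id`")
    if (nrow(pr) == 0L) return(NULL)
    return(pr)
  }
  if (!id %in% pr$id) return(NULL)
  pr[pr$id == id, , drop = FALSE]
}

#' New-user eligibility filter
#'
#' Retains the individuals who qualify as new statin users for the response
#' analysis: at least two statin dispensing records (excluding potentially
#' nonadherent one-fill users), at least one lipid measurement strictly
#' before statin initiation, and at least one valid on-treatment measurement
#' (per the [select_pairs()] window and co-therapy rules).
#'
#' @param records a `cohort_records` object.
#' @param lag_days see [select_pairs()].
#' @return the eligible subset, as a `cohort_records` object restricted to
#'   retained individuals; attribute `"retained"` holds their ids.
#' @export
new_user_filter <- function(records, lag_days = 21) {
  stopifnot(inherits(records, "cohort_records"))
  n_disp <- table(records$dispensings$id)
  multi <- names(n_disp)[n_disp >= 2L]
  pairs <- select_pairs(records, lag_days = lag_days)
  keep <- intersect(multi, pairs$id)
  out <- records
  for (tab in c("dispensings", "cotherapy", "lipids", "covariates", "ledger")) {
    if (!is.null(out[[tab]]) && nrow(out[[tab]]))
      out[[tab]] <- out[[tab]][out[[tab]]$id %in% keep, , drop = FALSE]
  }
  attr(out, "retained") <- keep
  out
}

#' Write / read cohort records as event-long TSV
#'
#' One row per event, typed by an `event_kind` column
#' (`dispensing`, `cotherapy`, `lipid`); dates in ISO-8601. Covariates are
#' written to a companion wide TSV.
#'
#' @param records a `cohort_records` object.
#' @param events_path path for the events TSV.
#' @param covariates_path path for the covariates TSV.
#' @return (invisibly) the events path.
#' @export
write_records_tsv <- function(records, events_path,
                              covariates_path = sub("\\.tsv$", ".covariates.tsv",
                                                    events_path)) {
  stopifnot(inherits(records, "cohort_records"))
  d <- records$dispensings
  ev <- data.frame(id = d$id, event_kind = "dispensing",
                   date = format(d$date), drug = d$statin_type,
                   dose = d$dose, days_supply = d$days_supply, ldl = NA)
  if (nrow(records$cotherapy)) {
    co <- records$cotherapy
    ev <- rbind(ev, data.frame(id = co$id, event_kind = "cotherapy",
                               date = format(co$date), drug = co$drug_class,
                               dose = NA, days_supply = co$days_supply,
                               ldl = NA))
  }
  li <- records$lipids
  ev <- rbind(ev, data.frame(id = li$id, event_kind = "lipid",
                             date = format(li$date), drug = NA, dose = NA,
                             days_supply = NA, ldl = li$ldl))
  ev <- ev[order(ev$id, ev$date), ]
  utils::write.table(ev, events_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(records$covariates, covariates_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(events_path)
}

#' @rdname write_records_tsv
#' @export
read_records_tsv <- function(events_path,
                             covariates_path = sub("\\.tsv$", ".covariates.tsv",
                                                   events_path)) {
  ev <- utils::read.delim(events_path, stringsAsFactors = FALSE)
  ev$date <- as.Date(ev$date)
  covar <- utils::read.delim(covariates_path, stringsAsFactors = FALSE)
  d <- ev[ev$event_kind == "dispensing", ]
  co <- ev[ev$event_kind == "cotherapy", ]
  li <- ev[ev$event_kind == "lipid", ]
  structure(list(
    dispensings = data.frame(id = d$id, date = d$date, statin_type = d$drug,
                             dose = d$dose, days_supply = d$days_supply,
                             stringsAsFactors = FALSE),
    cotherapy = data.frame(id = co$id, date = co$date,
                           drug_class = co$drug, days_supply = co$days_supply,
                           stringsAsFactors = FALSE),
    lipids = data.frame(id = li$id, date = li$date, ldl = li$ldl,
                        stringsAsFactors = FALSE),
    covariates = covar, ledger = NULL), class = "cohort_records")
}
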