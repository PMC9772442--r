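#' @name pk_dataset
#' @title NONMEM-dialect event datasets
#'
#' @description
#' Datasets are CSV event streams with one row per dose or observation and
#' the header
#' `ID,TIME,EVID,AMT,DVID,DV,MDV,SS,II,ADDL,BLQ` followed by the covariate
#' columns `MORBID,SEX,AGE,WT,FORM,SMOK,DRINK,VPA,QTP,CLZ,OLZ,RIS,AMI,ALT,
#' AST,BUN,CR`.  `EVID` 1 marks a dose (AMT in mg, DV empty), `EVID` 0 an
#' observation (`DVID` 1 = VEN, 2 = ODV, DV in ng/ml).  `MDV` 1 marks a
#' non-informative DV.  Times are hours from the subject's first record;
#' a dose and an observation may share a time (the dose sorts first).
#' Assay quantitation limits are carried alongside the records, keyed by
#' health status and analyte, because the two source study designs used
#' different assays.
NULL

.dialect_cols <- c("ID", "TIME", "EVID", "AMT", "DVID", "DV", "MDV", "SS",
                   "II", "ADDL", "BLQ")
.covariate_cols <- c("MORBID", "SEX", "AGE", "WT", "FORM", "SMOK", "DRINK",
                     "VPA", "QTP", "CLZ", "OLZ", "RIS", "AMI",
                     "ALT", "AST", "BUN", "CR")

#' Default assay quantitation limits
#'
#' Healthy-subject (intensive study) VEN assay: 0.2-200 ng/ml.  Patient
#' (TDM study) assays: 4-400 ng/ml for VEN and 20-2000 ng/ml for ODV.
#' ODV was not assayed in the intensive study, so no healthy ODV limit is
#' defined.
#'
#' @return Data frame with columns `morbid`, `analyte`, `lloq`, `uloq`.
#' @export
default_assay_limits <- function() {
  data.frame(morbid = c(0, 1, 1),
             analyte = c("VEN", "VEN", "ODV"),
             lloq = c(0.2, 4, 20),
             uloq = c(200, 400, 2000))
}

.new_dataset <- function(records, limits) {
  structure(list(records = records, limits = limits), class = "pk_dataset")
}

#' Construct a dataset from an event-record data frame
#'
#' Validates the record stream and attaches assay limits.
#'
#' @param records data frame in the dialect described at [pk_dataset].
#' @param limits assay quantitation limits, as [default_assay_limits()].
#' @return A `pk_dataset`.
#' @export
.int_cols <- c("ID", "EVID", "DVID", "MDV", "SS", "ADDL", "BLQ", "MORBID",
               "SEX", "FORM", "SMOK", "DRINK", "VPA", "QTP", "CLZ", "OLZ",
               "RIS", "AMI")
.dbl_cols <- c("TIME", "AMT", "DV", "II", "AGE", "WT", "ALT", "AST", "BUN",
               "CR")

as_pk_dataset <- function(records, limits = default_assay_limits()) {
  for (nm in intersect(.int_cols, names(records)))
    records[[nm]] <- as.integer(records[[nm]])
  for (nm in intersect(.dbl_cols, names(records)))
    records[[nm]] <- as.double(records[[nm]])
  .validate_records(records)
  ord <- order(records$ID, records$TIME, -records$EVID)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  .new_dataset(records, limits)
}

.validate_records <- function(rec) {
  missing_cols <- setdiff(c(.dialect_cols, .covariate_cols), names(rec))
  if (length(missing_cols) > 0)
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(rec$TIME) | rec$TIME < 0)
  if (length(bad) > 0)
    stop("validation error: negative or non-finite TIME at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  obs <- rec$EVID == 0
  bad <- which(obs & !is.na(rec$AMT) & rec$AMT != 0)
  if (length(bad) > 0)
    stop("validation error: observation row carries a dose amount at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!obs & !is.na(rec$DV) & rec$DV != 0)
  if (length(bad) > 0)
    stop("validation error: dose row carries a DV at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(obs & !(rec$DVID %in% c(1, 2)))
  if (length(bad) > 0)
    stop("validation error: observation row without a valid DVID at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!obs & (!is.finite(rec$AMT) | rec$AMT <= 0))
  if (length(bad) > 0)
    stop("validation error: dose row without a positive AMT at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  for (id in unique(rec$ID)) {
    sub <- rec[rec$ID == id, ]
    if (any(sub$EVID == 0 & sub$MDV == 0) && !any(sub$EVID == 1))
      stop("validation error: subject ", id,
           " has observations but no dose record", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a dataset from CSV
#'
#' @param path CSV file in the dialect described at [pk_dataset].
#' @param limits assay limits to attach, as [default_assay_limits()].
#' @return A `pk_dataset`.
#' @export
read_pk_dataset <- function(path, limits = default_assay_limits()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- read.csv(path, stringsAsFactors = FALSE)
  as_pk_dataset(rec, limits)
}

#' Write a dataset to CSV
#'
#' Numeric fields are rendered at full (round-trip) precision.
#'
#' @param dataset a `pk_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "pk_dataset"))
  rec <- dataset$records
  out <- rec
  for (nm in names(out))
    if (is.numeric(out[[nm]]))
      out[[nm]] <- vapply(out[[nm]], function(x)
        if (is.na(x)) "" else format(x, digits = 17), character(1))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pk_dataset <- function(x, ...) {
  rec <- x$records
  obs <- rec[rec$EVID == 0 & rec$MDV == 0, ]
  cat(sprintf("pk_dataset: %d subjects, %d records (%d observations: %d VEN, %d ODV)\n",
              length(unique(rec$ID)), nrow(rec), nrow(obs),
              sum(obs$DVID == 1), sum(obs$DVID == 2)))
  invisible(x)
}

.limit_for <- function(limits, morbid, analyte) {
  row <- limits[limits$morbid == morbid & limits$analyte == analyte, ]
  if (nrow(row) != 1)
    stop("configuration error: no quantitation limits defined for ",
         ifelse(morbid == 0, "healthy", "patient"), " ", analyte,
         " observations", call. = FALSE)
  row
}

#' Apply quantitation-limit rules
#'
#' Implements the source designs' handling of unquantifiable observations.
#' For healthy subjects (intensive study, `MORBID = 0`): observations below
#' the LLOQ in the absorption phase are retained with DV set to 0 and the
#' BLQ flag raised; below-LLOQ observations in the elimination phase, and
#' observations above the upper limit, are excluded.  The absorption phase
#' of a dosing interval ends at the time of the maximum observed
#' concentration of that analyte in the interval (ties count as absorption
#' phase).  For patients (TDM study, `MORBID = 1`): observations outside
#' the quantitation range are excluded.  The operation is idempotent.
#'
#' @param dataset a `pk_dataset`.
#' @return A list with elements `dataset` (filtered) and `report`, a data
#'   frame counting retained-as-zero and excluded observations by health
#'   status and analyte.
#' @export
apply_blq_rules <- function(dataset) {
  stopifnot(inherits(dataset, "pk_dataset"))
  rec <- dataset$records
  limits <- dataset$limits
  obs_idx <- which(rec$EVID == 0 & rec$MDV == 0)
  drop <- logical(nrow(rec))
  anl <- c("VEN", "ODV")

  rep_key <- list()
  bump <- function(morbid, analyte, field) {
    key <- paste(morbid, analyte)
    if (is.null(rep_key[[key]]))
      rep_key[[key]] <<- list(morbid = morbid, analyte = analyte,
                              n_obs = 0, n_zeroed = 0, n_excluded = 0)
    rep_key[[key]][[field]] <<- rep_key[[key]][[field]] + 1
  }

  for (id in unique(rec$ID[obs_idx])) {
    sub <- which(rec$ID == id)
    sobs <- intersect(sub, obs_idx)
    if (length(sobs) == 0) next
    morbid <- rec$MORBID[sobs[1]]
    dose_times <- sort(rec$TIME[sub][rec$EVID[sub] == 1])
    for (a in 1:2) {
      aobs <- sobs[rec$DVID[sobs] == a]
      if (length(aobs) == 0) next
      lim <- .limit_for(limits, morbid, anl[a])
      for (j in aobs) bump(morbid, anl[a], "n_obs")
      if (morbid == 1) {
        out <- aobs[rec$DV[aobs] < lim$lloq | rec$DV[aobs] > lim$uloq]
        drop[out] <- TRUE
        for (j in out) bump(morbid, anl[a], "n_excluded")
      } else {
        # interval index: last dose time <= observation time
        int_of <- findInterval(rec$TIME[aobs], dose_times)
        for (iv in unique(int_of)) {
          grp <- aobs[int_of == iv]
          tmax <- rec$TIME[grp][which.max(rec$DV[grp])]
          for (j in grp) {
            dv <- rec$DV[j]
            if (dv > lim$uloq) {
              drop[j] <- TRUE
              bump(morbid, anl[a], "n_excluded")
            } else if (dv < lim$lloq) {
              if (rec$TIME[j] <= tmax) {
                rec$DV[j] <- 0
                rec$BLQ[j] <- 1L
                bump(morbid, anl[a], "n_zeroed")
              } else {
                drop[j] <- TRUE
                bump(morbid, anl[a], "n_excluded")
              }
            }
          }
        }
      }
    }
  }
  report <- do.call(rbind, lapply(rep_key, as.data.frame))
  if (is.null(report))
    report <- data.frame(morbid = numeric(0), analyte = character(0),
                         n_obs = numeric(0), n_zeroed = numeric(0),
                         n_excluded = numeric(0))
  rownames(report) <- NULL
  out <- rec[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(dataset = .new_dataset(out, limits), report = report)
}

#' Write an exclusion report as tab-separated text
#'
#' @param report the `report` element of [apply_blq_rules()].
#' @param path output path.
#' @export
write_exclusion_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Extract one subject's regimen, observations and covariates
#'
#' @param dataset a `pk_dataset`.
#' @param subject_id subject identifier.
#' @return A list with `regimen` (a [pk_regimen()]), `observations` (data
#'   frame: `time`, `dv`, `analyte`, `blq`), and `covariates` (one-row data
#'   frame of the covariate columns).  Observation times are hours from the
#'   subject's first dose.
#' @export
build_subject <- function(dataset, subject_id) {
  stopifnot(inherits(dataset, "pk_dataset"))
  rec <- dataset$records
  sub <- rec[rec$ID == subject_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown subject: ", subject_id, call. = FALSE)
  doses <- sub[sub$EVID == 1, , drop = FALSE]
  obs <- sub[sub$EVID == 0 & sub$MDV == 0, , drop = FALSE]
  if (nrow(doses) == 0) stop("subject ", subject_id, " has no dose records",
                             call. = FALSE)
  t0 <- min(doses$TIME)
  if (nrow(obs) > 0 && any(obs$TIME < t0))
    stop("validation error: observation before any dose for subject ",
         subject_id, call. = FALSE)
  reg <- do.call(pk_regimen, lapply(seq_len(nrow(doses)), function(i)
    dose_event(doses$TIME[i] - t0, doses$AMT[i],
               interdose_interval = doses$II[i],
               n_additional_doses = doses$ADDL[i],
               steady_state = doses$SS[i] > 0)))
  observations <- data.frame(
    time = obs$TIME - t0,
    dv = obs$DV,
    analyte = c("VEN", "ODV")[obs$DVID],
    blq = obs$BLQ)
  covariates <- sub[1, .covariate_cols, drop = FALSE]
  rownames(covariates) <- NULL
  list(regimen = reg, observations = observations, covariates = covariates)
}
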