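dataset_columns <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "DVID",
                     "MDV", "WT")

#' Read an analysis dataset
#'
#' Reads a pharmacometric-style comma-delimited longitudinal dataset with
#' header columns `ID` (subject), `TIME` (min), `EVID` (1 dose, 0
#' observation), `AMT` (dose mg, dose rows), `RATE` (mg/min; 0 = bolus),
#' `DV` (observation value), `DVID` (1 plasma concentration mg/L, 2
#' activated clotting time s, 3 reaction time min), `MDV` (1 on dose rows)
#' and `WT` (kg). Validation errors report the offending file row.
#'
#' @param path path to a delimited text file.
#' @return validated data.frame of records.
#' @export
read_pkpd_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  missing <- setdiff(dataset_columns, names(dat))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  dat <- dat[dataset_columns]
  # header is row 1 in the file
  frow <- function(i) i + 1L
  for (cl in dataset_columns) {
    bad <- which(!is.na(dat[[cl]]) & !is.numeric(dat[[cl]]))
    if (!is.numeric(dat[[cl]])) {
      suppressWarnings(num <- as.numeric(dat[[cl]]))
      bad <- which(!is.na(dat[[cl]]) & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric value in column %s at file row %d",
                     cl, frow(bad[1])), call. = FALSE)
      dat[[cl]] <- num
    }
  }
  if (any(bad <- dat$TIME < 0))
    stop(sprintf("negative TIME at file row %d", frow(which(bad)[1])),
         call. = FALSE)
  obs <- dat$EVID == 0
  if (any(bad <- obs & (is.na(dat$DVID) | !(dat$DVID %in% 1:3))))
    stop(sprintf("observation row without valid DVID at file row %d",
                 frow(which(bad)[1])), call. = FALSE)
  if (any(bad <- obs & is.na(dat$DV)))
    stop(sprintf("observation row without DV at file row %d",
                 frow(which(bad)[1])), call. = FALSE)
  for (id in unique(dat$ID)) {
    ri <- which(dat$ID == id)
    di <- ri[dat$EVID[ri] == 1]
    oi <- ri[dat$EVID[ri] == 0]
    if (!length(di))
      stop(sprintf("subject %s has no dose row (first record at file row %d)",
                   format(id), frow(ri[1])), call. = FALSE)
    if (length(oi) && min(oi) < min(di))
      stop(sprintf("observation before any dose row for subject %s at file row %d",
                   format(id), frow(min(oi))), call. = FALSE)
  }
  dat
}

#' Write an analysis dataset
#'
#' @param data dataset data.frame (see [read_pkpd_data()] for layout).
#' @param path output path; comma-delimited text with header.
#' @return `path`, invisibly.
#' @export
write_pkpd_data <- function(data, path) {
  stopifnot(all(dataset_columns %in% names(data)))
  utils::write.csv(data[dataset_columns], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

# Split a validated dataset into per-subject lists used by the fitters.
split_subjects <- function(data) {
  lapply(split(data, data$ID), function(d) {
    d <- d[order(d$TIME, -d$EVID), ]
    dose_row <- d[d$EVID == 1, ][1, ]
    dur <- if (!is.na(dose_row$RATE) && dose_row$RATE > 0)
      dose_row$AMT / dose_row$RATE else 0
    obs <- d[d$EVID == 0, c("TIME", "DV", "DVID")]
    list(id = d$ID[1], weight = d$WT[1], dose = dose_row$AMT,
         infusion_duration = dur,
         times = obs$TIME, y = obs$DV, dvid = obs$DVID)
  })
}
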