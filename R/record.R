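#' Construct an ECG record
#'
#' A single multi-lead ECG: named lead signals in millivolts, a sampling
#' rate, per-lead acquisition offsets (the report slot starts 0/2.5/5/7.5 s
#' for report-style records), a binary acute-myocardial-infarction label and
#' optional free-text interpretation.
#'
#' @param signals Named list of numeric sample vectors (mV); names must be
#'   canonical lead names and all vectors must have equal length.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param lead_offsets Named numeric vector of acquisition offsets in
#'   seconds.  Defaults to the report slot offsets for the supplied leads.
#' @param label Binary label, 0 (no AMI) or 1 (AMI), or `NA` if unknown.
#' @param interpretation_text Optional free-text automatic interpretation.
#' @param subject_id,record_id Opaque identifiers.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signals, sampling_rate,
                       lead_offsets = NULL,
                       label = NA_integer_,
                       interpretation_text = NULL,
                       subject_id = NA_character_,
                       record_id = NA_character_) {
  if (!is.list(signals) || is.null(names(signals)) || !length(signals)) {
    stop("`signals` must be a non-empty named list of numeric vectors")
  }
  bad <- setdiff(names(signals), lead_order())
  if (length(bad)) stop("unknown lead name(s): ", paste(bad, collapse = ", "))
  lens <- lengths(signals)
  if (length(unique(lens)) != 1L) {
    stop("all lead signals must have equal length; got lengths ",
         paste(unique(lens), collapse = ", "))
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number")
  }
  layout <- slot_layout()
  if (is.null(lead_offsets)) {
    lead_offsets <- layout$offsets[layout$slot_of[names(signals)]]
    names(lead_offsets) <- names(signals)
  }
  if (!all(lead_offsets %in% layout$offsets)) {
    stop("lead offsets must be one of ",
         paste(layout$offsets, collapse = ", "), " seconds")
  }
  if (!is.na(label) && !label %in% c(0, 1)) stop("`label` must be 0, 1 or NA")
  structure(
    list(
      signals = lapply(signals, as.numeric),
      sampling_rate = sampling_rate,
      lead_offsets = lead_offsets,
      label = as.integer(label),
      interpretation_text = interpretation_text,
      subject_id = as.character(subject_id),
      record_id = as.character(record_id)
    ),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  n <- length(x$signals[[1]])
  cat("<ecg_record> ", x$record_id, ": ", length(x$signals), " leads x ", n,
      " samples @ ", x$sampling_rate, " Hz (", n / x$sampling_rate,
      " s/lead), label = ", x$label, "\n", sep = "")
  invisible(x)
}

#' Write / read an ECG record as CSV + JSON sidecar
#'
#' The sample arrays go to `<stem>.csv` (one column per lead, canonical
#' order) and the metadata (lead names, offsets, sampling rate, label,
#' interpretation text, identifiers) to `<stem>.json`.
#'
#' @param record An [ecg_record()].
#' @param stem File path without extension.
#' @return `write_ecg_record()` returns `stem` invisibly;
#'   `read_ecg_record()` returns the reconstructed [ecg_record()].
#' @export
write_ecg_record <- function(record, stem) {
  stopifnot(inherits(record, "ecg_record"))
  sig <- as.data.frame(record$signals, check.names = FALSE)
  utils::write.csv(sig, paste0(stem, ".csv"), row.names = FALSE)
  meta <- list(
    leads = names(record$signals),
    sampling_rate = record$sampling_rate,
    lead_offsets = as.list(record$lead_offsets),
    label = record$label,
    interpretation_text = record$interpretation_text,
    subject_id = record$subject_id,
    record_id = record$record_id
  )
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_ecg_record
#' @export
read_ecg_record <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  sig <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
  ecg_record(
    signals = as.list(sig)[meta$leads],
    sampling_rate = meta$sampling_rate,
    lead_offsets = unlist(meta$lead_offsets)[meta$leads],
    label = if (is.null(meta$label)) NA_integer_ else meta$label,
    interpretation_text = meta$interpretation_text,
    subject_id = meta$subject_id,
    record_id = meta$record_id
  )
}

#' Write / read a dataset of ECG records with a manifest
#'
#' Each record is stored via [write_ecg_record()] under its `record_id`;
#' `manifest.csv` lists record_id, subject_id, label and (when present) the
#' generator territory attribute.
#'
#' @param records List of [ecg_record()] objects.
#' @param dir Output directory (created if needed).
#' @export
write_ecg_dataset <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    record_id = vapply(records, function(r) r$record_id, character(1)),
    subject_id = vapply(records, function(r) r$subject_id, character(1)),
    label = vapply(records, function(r) r$label, integer(1)),
    territory = vapply(records, function(r) {
      t <- attr(r, "territory"); if (is.null(t)) NA_character_ else t
    }, character(1)),
    stringsAsFactors = FALSE
  )
  for (r in records) write_ecg_record(r, file.path(dir, r$record_id))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_ecg_dataset
#' @export
read_ecg_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              colClasses = c(record_id = "character",
                                             subject_id = "character"))
  lapply(manifest$record_id, function(id) read_ecg_record(file.path(dir, id)))
}

# Channel-name aliases seen in WFDB-style exports.
wfdb_channel_map <- function(nm) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", nm))
  canon <- lead_order()
  lookup <- stats::setNames(canon, toupper(canon))
  extra <- c(LEADI = "I", LEADII = "II", LEADIII = "III",
             AVR = "aVR", AVL = "aVL", AVF = "aVF")
  out <- lookup[key]
  miss <- is.na(out)
  out[miss] <- extra[key[miss]]
  unname(out)
}

#' Import a WFDB-style signal export as an ECG record
#'
#' Adapter for multi-channel signal tables such as the CSV produced by the
#' WFDB `rdsamp -c -v` application: a data frame or matrix with one column
#' per channel, channel names mapped onto the canonical 12 lead names
#' (case-insensitive; `AVR`/`LEAD I` style aliases accepted).  Columns that
#' do not map to a lead (e.g. an elapsed-time column) are dropped.
#'
#' @param x Data frame or numeric matrix with named channel columns.
#' @param sampling_rate Sampling rate in Hz.
#' @param ... Passed on to [ecg_record()] (label, identifiers, ...).
#' @return An [ecg_record()].
#' @export
as_ecg_record <- function(x, sampling_rate, ...) {
  x <- as.data.frame(x, check.names = FALSE)
  mapped <- wfdb_channel_map(names(x))
  keep <- !is.na(mapped)
  if (!any(keep)) stop("no column maps onto a canonical ECG lead name")
  sig <- as.list(x[, keep, drop = FALSE])
  names(sig) <- mapped[keep]
  ecg_record(sig[order(match(names(sig), lead_order()))],
             sampling_rate = sampling_rate, ...)
}
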