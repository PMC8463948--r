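# Cohort labeling: emergency-room visits, ICD-10 based AMI labels, and the
# exclusion rules applied to the coded visits.

normalize_icd10 <- function(code) {
  toupper(gsub("[^A-Za-z0-9]", "", as.character(code)))
}

is_ami_code <- function(code) {
  nc <- normalize_icd10(code)
  startsWith(nc, "I21") | startsWith(nc, "I22")
}

# Hours between two time points; accepts numeric (hours) or POSIXct.
hours_between <- function(a, b) {
  if (inherits(a, "POSIXt") || inherits(b, "POSIXt")) {
    abs(as.numeric(difftime(a, b, units = "hours")))
  } else {
    abs(as.numeric(a) - as.numeric(b))
  }
}

#' Label and filter emergency-room ECGs
#'
#' Applies the cohort rules to tidy visit tables: keep ECGs recorded within
#' 24 hours (closed interval) of the visit from patients aged at least 20;
#' label an ECG positive when its visit carries an ICD-10 code beginning
#' I21 or I22 (dots ignored, subcodes included); exclude the ECGs of a
#' coded visit when no AMI code has a registration time, or none was
#' registered within 24 hours of that ECG.  Exclusions never apply to
#' visits without an AMI code.  Every input ECG appears either in the
#' labeled output or in the exclusion log.
#'
#' @param visits Data frame with columns `visit_id`, `subject_id`,
#'   `visit_time`, `age`.
#' @param diagnoses Data frame with columns `visit_id`, `code`,
#'   `registration_time` (`NA` = null registration).
#' @param ecgs Data frame with columns `ecg_id`, `visit_id`, `ecg_time`.
#' @return List with `labeled` (data frame `ecg_id`, `visit_id`,
#'   `subject_id`, `label`) and `exclusions` (data frame `ecg_id`,
#'   `visit_id`, `reason`); malformed rows are logged per record with
#'   reason `malformed`, never aborting the run.
#' @export
label_and_filter <- function(visits, diagnoses, ecgs) {
  stopifnot(all(c("visit_id", "subject_id", "visit_time", "age") %in%
                  names(visits)),
            all(c("visit_id", "code", "registration_time") %in%
                  names(diagnoses)),
            all(c("ecg_id", "visit_id", "ecg_time") %in% names(ecgs)))
  vrow <- match(ecgs$visit_id, visits$visit_id)
  labeled <- list()
  excluded <- list()
  ami_by_visit <- split(diagnoses[is_ami_code(diagnoses$code), ],
                        f = diagnoses$visit_id[is_ami_code(diagnoses$code)])
  for (i in seq_len(nrow(ecgs))) {
    e <- ecgs[i, ]
    keep <- function(label) {
      labeled[[length(labeled) + 1L]] <<- data.frame(
        ecg_id = e$ecg_id, visit_id = e$visit_id,
        subject_id = visits$subject_id[vrow[i]], label = label)
    }
    drop <- function(reason) {
      excluded[[length(excluded) + 1L]] <<- data.frame(
        ecg_id = e$ecg_id, visit_id = e$visit_id, reason = reason)
    }
    if (is.na(vrow[i])) { drop("unknown_visit"); next }
    v <- visits[vrow[i], ]
    dt <- tryCatch(hours_between(e$ecg_time, v$visit_time),
                   error = function(err) NA_real_)
    if (is.na(dt)) { drop("malformed"); next }
    if (is.na(v$age) || v$age < 20) { drop("age_under_20"); next }
    if (dt > 24) { drop("ecg_outside_24h"); next }
    ami <- ami_by_visit[[as.character(e$visit_id)]]
    if (is.null(ami) || !nrow(ami)) { keep(0L); next }
    reg <- ami$registration_time
    has_time <- !is.na(reg)
    if (!any(has_time)) { drop("ami_registration_null"); next }
    within <- vapply(which(has_time), function(j) {
      d <- tryCatch(hours_between(reg[j], e$ecg_time),
                    error = function(err) NA_real_)
      !is.na(d) && d <= 24
    }, logical(1))
    if (any(within)) keep(1L) else drop("ami_registration_out_of_window")
  }
  bind <- function(lst, empty) {
    if (length(lst)) do.call(rbind, lst) else empty
  }
  list(
    labeled = bind(labeled, data.frame(ecg_id = character(0),
                                       visit_id = character(0),
                                       subject_id = character(0),
                                       label = integer(0))),
    exclusions = bind(excluded, data.frame(ecg_id = character(0),
                                           visit_id = character(0),
                                           reason = character(0)))
  )
}

#' Class prevalence of labeled ECGs
#'
#' @param x Integer/logical label vector, or the `labeled` data frame
#'   produced by [label_and_filter()].
#' @param percent Return a percentage instead of a fraction.
#' @return Fraction (or percentage) of positive labels.
#' @examples
#' prevalence(c(rep(1, 2465), rep(0, 138549 - 2465)), percent = TRUE) # 1.78
#' @export
prevalence <- function(x, percent = FALSE) {
  labels <- if (is.data.frame(x)) x$label else x
  if (!length(labels)) stop("no labeled ECGs")
  p <- mean(labels == 1)
  if (percent) 100 * p else p
}
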