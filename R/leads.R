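#' Canonical 12-lead order
#'
#' The fixed lead ordering used everywhere in the package: mask indices,
#' encoder channel order, and the flattening order of the classifier input.
#'
#' @return Character vector of the 12 standard lead names.
#' @export
lead_order <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
}

LIMB_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF")
PRECORDIAL_LEADS <- paste0("V", 1:6)

#' Report slot layout of a standard 12-lead ECG
#'
#' A standard 12-lead report prints 2.5 s per lead from a 10 s acquisition,
#' in four columns of three simultaneously recorded leads each.  Leads in
#' different columns are asynchronous; the column start offsets are
#' 0, 2.5, 5 and 7.5 s.
#'
#' @return A list with `slots` (list of 4 character vectors), `offsets`
#'   (numeric, seconds, one per slot), `slot_of` (named integer vector
#'   mapping lead name to slot index) and `total_duration` (seconds).
#' @export
slot_layout <- function() {
  slots <- list(
    c("I", "II", "III"),
    c("aVR", "aVL", "aVF"),
    c("V1", "V2", "V3"),
    c("V4", "V5", "V6")
  )
  slot_of <- rep(seq_along(slots), each = 3L)
  names(slot_of) <- unlist(slots)
  list(
    slots = slots,
    offsets = c(0, 2.5, 5, 7.5),
    slot_of = slot_of,
    total_duration = 10
  )
}

# Coefficients of every limb lead in the (I, II) basis.  Einthoven's law
# (II = I + III) and the Goldberger definitions of the augmented leads make
# the six limb leads a rank-2 linear family, so any two of them determine
# the rest.
limb_basis <- function() {
  rbind(
    I   = c(1, 0),
    II  = c(0, 1),
    III = c(-1, 1),
    aVR = c(-0.5, -0.5),
    aVL = c(1, -0.5),
    aVF = c(-0.5, 1)
  )
}

#' Reconstruct all six limb leads from any two
#'
#' The six limb leads span a two-dimensional linear space: Einthoven's law
#' gives `II = I + III` and the Goldberger relations give
#' `aVR = -(I + II)/2`, `aVL = I - II/2`, `aVF = II - I/2`.  Given any two
#' distinct limb leads the remaining four are recovered exactly by solving
#' this linear system sample-wise.
#'
#' @param known Named list of exactly two numeric vectors; names must be two
#'   distinct limb leads (`I`, `II`, `III`, `aVR`, `aVL`, `aVF`) and the
#'   vectors must have equal length.
#' @return Named list of all six limb-lead sample vectors in canonical
#'   order; the supplied leads are returned unchanged.
#' @examples
#' out <- reconstruct_limb_leads(list(I = c(1.0), III = c(0.5)))
#' out$II   # 1.5
#' out$aVR  # -1.25
#' @export
reconstruct_limb_leads <- function(known) {
  if (!is.list(known) || is.null(names(known))) {
    stop("`known` must be a named list of two limb-lead sample vectors")
  }
  nms <- names(known)
  if (length(known) != 2L || anyDuplicated(nms)) {
    stop("exactly two distinct limb leads must be supplied, got: ",
         paste(nms, collapse = ", "))
  }
  bad <- setdiff(nms, LIMB_LEADS)
  if (length(bad)) {
    stop("not a limb lead: ", paste(bad, collapse = ", "),
         " (precordial leads cannot be reconstructed)")
  }
  if (!all(vapply(known, is.numeric, logical(1)))) {
    stop("lead samples must be numeric vectors")
  }
  if (length(known[[1]]) != length(known[[2]])) {
    stop("supplied lead arrays must have equal length (",
         length(known[[1]]), " vs ", length(known[[2]]), ")")
  }
  B <- limb_basis()
  A <- B[nms, , drop = FALSE]          # 2x2, invertible for any distinct pair
  xy <- solve(A, rbind(known[[1]], known[[2]]))  # rows: coords in (I, II)
  full <- B %*% xy                      # 6 x n
  out <- lapply(seq_len(nrow(full)), function(i) as.numeric(full[i, ]))
  names(out) <- rownames(B)
  # return measured leads bit-identically
  out[nms] <- known
  out
}

#' Construct a lead set
#'
#' An ordered subset of the 12 leads together with asynchrony metadata.
#' In multi-lead sets lead II is derived from the slot-2 augmented leads
#' (aVR, aVL, aVF) rather than taken from slot 1, so that every member of a
#' 2-, 3- or 4-lead set originates from a distinct 2.5 s report slot.
#'
#' @param leads Character vector of lead names in canonical order.
#' @param derived_ii Logical; if `TRUE`, lead II is the slot-2 derived
#'   version (offset 2.5 s) computed from aVR/aVL/aVF.
#' @return An object of class `lead_set`.
#' @export
lead_set <- function(leads, derived_ii = length(leads) > 1L) {
  leads <- as.character(leads)
  stopifnot(length(leads) >= 1L)
  if (anyDuplicated(leads)) stop("duplicate leads in lead set")
  bad <- setdiff(leads, lead_order())
  if (length(bad)) stop("unknown lead(s): ", paste(bad, collapse = ", "))
  leads <- lead_order()[lead_order() %in% leads]  # canonical order
  if (length(leads) > 1L && length(leads) < 12L && !("I" %in% leads)) {
    stop("multi-lead sets must contain lead I")
  }
  layout <- slot_layout()
  slot <- layout$slot_of[leads]
  if (derived_ii && "II" %in% leads) slot[leads == "II"] <- 2L
  if (length(leads) %in% 2:4) {
    if (anyDuplicated(slot)) {
      stop("leads ", paste(leads, collapse = ", "),
           " are not completely asynchronous (shared report slot)")
    }
  }
  note <- if (derived_ii && "II" %in% leads) {
    "lead II derived from slot-2 augmented leads (aVR, aVL, aVF)"
  } else {
    "all member leads taken as printed"
  }
  structure(
    list(leads = leads, n_leads = length(leads), slots = unname(slot),
         derived_ii = derived_ii && "II" %in% leads, derivation_note = note),
    class = "lead_set"
  )
}

#' @export
print.lead_set <- function(x, ...) {
  cat("<lead_set> {", paste(x$leads, collapse = ", "), "} (",
      x$n_leads, " leads; ", x$derivation_note, ")\n", sep = "")
  invisible(x)
}

#' @export
format.lead_set <- function(x, ...) paste(x$leads, collapse = ",")

#' Enumerate the tested asynchronous lead sets
#'
#' Enumerates, in a deterministic canonical order, the lead sets evaluated
#' for each lead count: lead I is part of every multi-lead set (it is the
#' lead a smartwatch measures without being moved); 3- and 4-lead sets also
#' contain the slot-2 derived lead II; the remaining members are precordial
#' leads chosen so all members come from distinct report slots.
#'
#' * `n_leads = 4`: \{I, II\} plus one of V1--V3 and one of V4--V6 (9 sets)
#' * `n_leads = 3`: \{I, II\} plus one precordial lead (6 sets)
#' * `n_leads = 2`: \{I\} plus one of \{II, V1--V6\} (7 sets)
#' * `n_leads = 1`: \{I\} or \{II\} (2 sets)
#' * `n_leads = 12`: the full 12-lead set (1 set)
#'
#' @param n_leads Integer, one of 1, 2, 3, 4, 12.
#' @return List of [lead_set()] objects.
#' @export
enumerate_lead_sets <- function(n_leads) {
  if (length(n_leads) != 1L || !n_leads %in% c(1, 2, 3, 4, 12)) {
    stop("`n_leads` must be one of 1, 2, 3, 4, 12")
  }
  n_leads <- as.integer(n_leads)
  if (n_leads == 12L) {
    return(list(lead_set(lead_order(), derived_ii = FALSE)))
  }
  if (n_leads == 1L) {
    return(list(lead_set("I", derived_ii = FALSE),
                lead_set("II", derived_ii = FALSE)))
  }
  if (n_leads == 2L) {
    partners <- c("II", PRECORDIAL_LEADS)
    return(lapply(partners, function(p) lead_set(c("I", p))))
  }
  if (n_leads == 3L) {
    return(lapply(PRECORDIAL_LEADS, function(p) lead_set(c("I", "II", p))))
  }
  # n_leads == 4: one precordial from slot 3, one from slot 4
  sets <- list()
  for (a in c("V1", "V2", "V3")) {
    for (b in c("V4", "V5", "V6")) {
      sets[[length(sets) + 1L]] <- lead_set(c("I", "II", a, b))
    }
  }
  sets
}

#' Convert a lead set to a lead mask
#'
#' @param x A [lead_set()] or character vector of lead names.
#' @return A [lead_mask()] with the member leads available.
#' @export
as_lead_mask <- function(x) {
  leads <- if (inherits(x, "lead_set")) x$leads else as.character(x)
  lead_mask(lead_order() %in% leads)
}

#' Slice the asynchronous 2.5 s segments of a lead set from a record
#'
#' Extracts one 2.5 s segment per member lead, each tagged with its
#' acquisition offset.  Records may hold either the full 10 s simultaneous
#' signals (each lead's report slot window is then cut out) or report-style
#' signals already 2.5 s long.  When the set's lead II is the slot-2
#' derived version it is computed from the augmented leads via
#' [reconstruct_limb_leads()]; a missing limb lead is likewise reconstructed
#' from any two available limb leads before slicing.
#'
#' @param record An [ecg_record()].
#' @param set A [lead_set()].
#' @return Named list with `segments` (named list of numeric vectors of
#'   length `2.5 * sampling_rate`), `offsets` (named numeric, seconds) and
#'   `sampling_rate`.
#' @export
slice_asynchronous <- function(record, set) {
  stopifnot(inherits(record, "ecg_record"), inherits(set, "lead_set"))
  fs <- record$sampling_rate
  seg_len <- as.integer(round(2.5 * fs))
  layout <- slot_layout()

  get_lead <- function(lead, slot) {
    sig <- record$signals[[lead]]
    if (is.null(sig)) {
      # attempt limb-lead reconstruction from two leads of the same slot
      if (lead %in% LIMB_LEADS) {
        donors <- intersect(layout$slots[[slot]], names(record$signals))
        donors <- setdiff(donors, lead)
        if (length(donors) >= 2L) {
          rec <- reconstruct_limb_leads(record$signals[donors[1:2]])
          sig <- rec[[lead]]
          # donors live in `slot`, so the reconstructed trace does too
          attr(sig, "offset_override") <- layout$offsets[slot]
        }
      }
      if (is.null(sig)) stop("record is missing lead ", lead,
                             " and it cannot be reconstructed")
    }
    sig
  }

  slice_one <- function(sig, slot, recorded_offset) {
    n <- length(sig)
    if (n == seg_len) {
      list(seg = sig, offset = recorded_offset)
    } else if (n >= as.integer(round(fs * layout$total_duration))) {
      start <- as.integer(round(layout$offsets[slot] * fs))
      list(seg = sig[(start + 1L):(start + seg_len)],
           offset = layout$offsets[slot])
    } else {
      stop("lead signal of length ", n, " is neither a 2.5 s segment nor a ",
           layout$total_duration, " s record at ", fs, " Hz")
    }
  }

  segments <- list()
  offsets <- numeric(0)
  for (lead in set$leads) {
    if (lead == "II" && set$derived_ii) {
      # slot-2 derived lead II from the augmented leads
      have <- intersect(c("aVR", "aVL", "aVF"), names(record$signals))
      if (length(have) < 2L) {
        stop("record is missing the augmented leads needed to derive lead II")
      }
      rec <- reconstruct_limb_leads(record$signals[have[1:2]])
      sl <- slice_one(rec$II, 2L, 2.5)
      segments[[lead]] <- sl$seg
      offsets[lead] <- sl$offset
    } else {
      slot <- unname(layout$slot_of[lead])
      sig <- get_lead(lead, slot)
      rec_off <- record$lead_offsets[[lead]]
      ov <- attr(sig, "offset_override")
      if (!is.null(ov)) rec_off <- ov
      if (is.null(rec_off)) rec_off <- layout$offsets[slot]
      sl <- slice_one(as.numeric(sig), slot, rec_off)
      segments[[lead]] <- sl$seg
      offsets[lead] <- sl$offset
    }
  }
  list(segments = segments, offsets = offsets, sampling_rate = fs)
}
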