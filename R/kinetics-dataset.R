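#' @import data.table
#' @importFrom methods is
NULL

# canonical event-table columns, one row per aligned polymerase event
KIN_COLS <- c("molecule_id", "subread_index", "strand", "mapqv", "accuracy",
              "ref_pos", "op", "read_base", "ref_base", "ipd")

#' Aligned SMRT kinetics dataset
#'
#' Container for aligned single-molecule kinetic observations. Events are kept
#' as one flat table with one row per aligned event (match, mismatch,
#' insertion or deletion); rows belonging to one subread (one pass of the
#' polymerase over one strand of one molecule, keyed by
#' `(molecule_id, subread_index)`) are stored in the polymerase's temporal
#' order, so reference positions increase along forward-strand subreads and
#' decrease along reverse-strand subreads. `read_base` and `ref_base` are
#' recorded in the read's own orientation (complemented for reverse-strand
#' subreads). Inter-pulse durations (`ipd`) are present exactly for the event
#' types that emit a base (match, mismatch, insertion); `ref_pos` is present
#' exactly for event types that consume reference (match, mismatch, deletion)
#' and is 0-based.
#'
#' @param events data.frame/data.table with columns `molecule_id`,
#'   `subread_index`, `strand` (0 = forward, 1 = reverse), `mapqv`,
#'   `accuracy`, `ref_pos`, `op` (one of `"M","X","I","D"`), `read_base`,
#'   `ref_base`, `ipd`.
#' @param reference_id name of the reference sequence the events are aligned
#'   to.
#' @param reference_length length of that reference in bases.
#' @param sample_type `"native"` for native DNA or `"WGA"` for
#'   whole-genome-amplified (methylation-free) control DNA.
#' @param ipd_unit unit the raw IPDs are recorded in (e.g. `"seconds"` or
#'   `"frames"`). Carried as metadata and never converted; scoring is
#'   unit-free after log-mean subtraction but native and control inputs must
#'   agree.
#' @param provenance free-form metadata list.
#' @param validate if `FALSE`, skip invariant checks (used internally on
#'   freshly generated data).
#' @return An object of class `kinetics_dataset`.
#' @export
kinetics_dataset <- function(events, reference_id, reference_length,
                             sample_type = c("native", "WGA"),
                             ipd_unit = "seconds", provenance = list(),
                             validate = TRUE) {
  sample_type <- match.arg(sample_type)
  events <- as.data.table(events)
  missing_cols <- setdiff(KIN_COLS, names(events))
  if (length(missing_cols))
    stop("events table is missing columns: ", paste(missing_cols, collapse = ", "))
  events <- events[, KIN_COLS, with = FALSE]
  if (validate && nrow(events)) {
    if (!all(events$op %in% c("M", "X", "I", "D")))
      stop("unknown alignment op; expected M, X, I or D")
    if (!all(events$strand %in% c(0L, 1L)))
      stop("strand must be 0 (forward) or 1 (reverse)")
    emits <- events$op %in% c("M", "X", "I")
    if (any(is.na(events$ipd[emits])))
      stop("ipd missing on a base-emitting event (M/X/I)")
    if (any(!is.na(events$ipd[!emits])))
      stop("deletion events must not carry an ipd")
    consumes <- events$op %in% c("M", "X", "D")
    if (any(is.na(events$ref_pos[consumes])))
      stop("ref_pos missing on a reference-consuming event (M/X/D)")
    if (any(!is.na(events$ref_pos[!consumes])))
      stop("insertion events must not carry a ref_pos")
    if (any(events$ref_pos >= reference_length, na.rm = TRUE) ||
        any(events$ref_pos < 0, na.rm = TRUE))
      stop("ref_pos out of range for reference_length = ", reference_length)
    if (any(events$ipd < 0, na.rm = TRUE))
      stop("negative ipd values")
  }
  structure(
    list(events = events,
         reference_id = as.character(reference_id),
         reference_length = as.integer(reference_length),
         sample_type = sample_type,
         ipd_unit = ipd_unit,
         provenance = provenance),
    class = "kinetics_dataset")
}

#' @export
print.kinetics_dataset <- function(x, ...) {
  ev <- x$events
  nmol <- if (nrow(ev)) uniqueN(ev$molecule_id) else 0L
  nsub <- if (nrow(ev)) nrow(unique(ev[, .(molecule_id, subread_index)])) else 0L
  cat(sprintf("<kinetics_dataset> %s sample on '%s' (%d bp)\n",
              x$sample_type, x$reference_id, x$reference_length))
  cat(sprintf("  %d molecules, %d subreads, %d aligned events (ipd unit: %s)\n",
              nmol, nsub, nrow(ev), x$ipd_unit))
  invisible(x)
}

#' @export
summary.kinetics_dataset <- function(object, ...) {
  ev <- object$events
  sub <- ev[, .(n_events = .N, aligned_len = sum(op != "I"),
                mapqv = mapqv[1L], accuracy = accuracy[1L]),
            by = .(molecule_id, subread_index, strand)]
  out <- list(dataset = object, subreads = sub)
  class(out) <- "summary.kinetics_dataset"
  out
}

#' @export
print.summary.kinetics_dataset <- function(x, ...) {
  print(x$dataset)
  s <- x$subreads
  if (nrow(s)) {
    cat(sprintf("  aligned length per subread: median %d [%d-%d]\n",
                as.integer(stats::median(s$aligned_len)),
                min(s$aligned_len), max(s$aligned_len)))
    cat(sprintf("  passes per molecule: median %g\n",
                stats::median(s[, .N, by = molecule_id]$N)))
  }
  invisible(x)
}

#' Number of distinct molecules in a dataset
#' @param ds a `kinetics_dataset`.
#' @return integer count.
#' @export
n_molecules <- function(ds) {
  stopifnot(inherits(ds, "kinetics_dataset"))
  if (!nrow(ds$events)) return(0L)
  uniqueN(ds$events$molecule_id)
}

# replace the event table, keeping metadata
replace_events <- function(ds, events) {
  ds$events <- as.data.table(events)
  ds
}

# subset a dataset to a set of molecule ids
subset_molecules <- function(ds, ids) {
  replace_events(ds, ds$events[molecule_id %in% ids])
}
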