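# Methylation-motif specification and site finding on a reference sequence.
# Degenerate IUPAC codes and bipartite motifs (N-run spacers, e.g. TCANNNNNNTRG)
# are supported; a bipartite motif pair such as TCAN6TRG / CYAN6TGA is one
# spec scanned on both strands (the second written form is the
# reverse-complement reading of the first).

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Methylation motif specification
#'
#' @param iupac motif string over the IUPAC alphabet; runs of `N` encode
#'   bipartite spacers.
#' @param modified_index 0-based offset of the methylated base within the
#'   motif. If `NULL`, defaults to the first `A` (the usual 6mA workflow)
#'   with a warning, since bipartite type III motifs do not determine the
#'   modified adenine by themselves.
#' @param name motif name used in site tables; defaults to the IUPAC string.
#' @return An object of class `motif_spec`.
#' @export
motif_spec <- function(iupac, modified_index = NULL, name = iupac) {
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "")[[1L]]
  bad <- setdiff(chars, IUPAC_LETTERS)
  if (length(bad))
    stop("invalid IUPAC character(s) in motif: ", paste(bad, collapse = ", "))
  if (is.null(modified_index)) {
    modified_index <- which(chars == "A")[1L] - 1L
    if (is.na(modified_index))
      stop("motif ", iupac, " has no A; supply modified_index explicitly")
    warning("modified_index not given for ", iupac,
            "; defaulting to first A (offset ", modified_index, ")")
  }
  modified_index <- as.integer(modified_index)
  if (modified_index < 0L || modified_index >= length(chars))
    stop("modified_index out of range for motif of length ", length(chars))
  if (chars[modified_index + 1L] == "N")
    stop("modified base may not be an N spacer position")
  structure(list(iupac = iupac, modified_index = modified_index,
                 name = as.character(name)),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  marked <- strsplit(x$iupac, "")[[1L]]
  marked[x$modified_index + 1L] <-
    paste0("[", marked[x$modified_index + 1L], "]")
  cat(sprintf("<motif_spec> %s: 5'-%s (modified offset %d)\n",
              x$name, paste(marked, collapse = ""), x$modified_index))
  invisible(x)
}

#' Parse `IUPAC:index[:name]` motif shorthand
#' @param text e.g. `"RGATCY:1"` or `"GATC:1:dam"`.
#' @return A [motif_spec()].
#' @export
parse_motif <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1L]]
  motif_spec(parts[1L],
             modified_index = if (length(parts) >= 2L) as.integer(parts[2L]),
             name = if (length(parts) >= 3L) parts[3L] else parts[1L])
}

#' Locate motif sites on a reference
#'
#' Scans the reference (step 1, all overlapping matches reported) with IUPAC
#' matching for forward-strand sites and scans with the reverse-complement
#' motif for reverse-strand sites, mapping each site to the forward-strand
#' coordinate of its modified base.
#'
#' @param reference a character string or `DNAString` over A/C/G/T (other
#'   letters never match).
#' @param motif a [motif_spec()].
#' @param both_strands if `FALSE`, only forward-strand sites are returned.
#' @return data.table with columns `ref_pos` (0-based forward coordinate of
#'   the modified base), `strand` (0/1) and `motif_name`, sorted by
#'   `(ref_pos, strand)`.
#' @export
find_motif_sites <- function(reference, motif, both_strands = TRUE) {
  stopifnot(inherits(motif, "motif_spec"))
  subject <- if (is(reference, "DNAString")) reference
             else Biostrings::DNAString(reference)
  len <- nchar(motif$iupac)
  empty <- data.table(ref_pos = integer(), strand = integer(),
                      motif_name = character())
  if (length(subject) < len) return(empty)
  pat <- Biostrings::DNAString(motif$iupac)
  fwd <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
  out <- list(data.table(
    ref_pos = Biostrings::start(fwd) - 1L + motif$modified_index,
    strand = 0L))
  if (both_strands) {
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                    subject, fixed = FALSE)
    out[[2L]] <- data.table(
      ref_pos = Biostrings::start(rev) - 1L + (len - 1L - motif$modified_index),
      strand = 1L)
  }
  sites <- rbindlist(out)
  if (!nrow(sites)) return(empty)
  sites[, motif_name := motif$name]
  setorder(sites, ref_pos, strand)
  unique(sites)
}

#' Expand a degenerate motif into its explicit specifications
#'
#' Cartesian expansion of the IUPAC degeneracy codes, e.g. `RGATCY` expands
#' to AGATCC, AGATCT, GGATCC, GGATCT. Spacer `N`s are not expandable and
#' raise an error.
#'
#' @param motif a [motif_spec()] containing no `N`.
#' @return A list of explicit [motif_spec()]s sharing the parent's
#'   `modified_index`, named `<parent>/<explicit>`.
#' @export
expand_degenerate <- function(motif) {
  stopifnot(inherits(motif, "motif_spec"))
  chars <- strsplit(motif$iupac, "")[[1L]]
  if (any(chars == "N"))
    stop("cannot expand a motif containing N spacers: ", motif$iupac)
  codes <- Biostrings::IUPAC_CODE_MAP
  choices <- lapply(chars, function(ch) strsplit(codes[[ch]], "")[[1L]])
  grid <- do.call(expand.grid,
                  c(rev(choices), list(stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_along(choices)), drop = FALSE]
  explicit <- apply(grid, 1L, paste, collapse = "")
  explicit <- sort(unique(explicit))
  lapply(explicit, function(m)
    motif_spec(m, motif$modified_index, name = paste0(motif$name, "/", m)))
}
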