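# Readers and writers for the aligned-kinetics TSV dialect, PacBio-style
# aligned BAM/SAM with per-base IPD tags, and score tables.

#' Read an aligned-kinetics TSV file
#'
#' The on-disk dialect is a UTF-8, tab-separated table with header
#' `molecule_id subread_index strand mapqv accuracy ref_pos op read_base
#' ref_base ipd`; `op` is one of `M` (match), `X` (mismatch), `I`
#' (insertion), `D` (deletion); `.` encodes null fields; coordinates are
#' 0-based; strand is 0 (forward) / 1 (reverse). Rows sharing
#' `(molecule_id, subread_index)` form one subread and their file order is
#' the polymerase's temporal order.
#'
#' @param path path to the TSV file.
#' @param reference_id,reference_length,sample_type,ipd_unit dataset metadata
#'   (the dialect carries events only). `reference_length` defaults to
#'   `max(ref_pos) + 1`.
#' @return A [kinetics_dataset()].
#' @export
read_kinetics_tsv <- function(path, reference_id = "ref",
                              reference_length = NULL,
                              sample_type = c("native", "WGA"),
                              ipd_unit = "seconds") {
  sample_type <- match.arg(sample_type)
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               na.strings = NULL, quote = "")
  if (!identical(names(raw), KIN_COLS))
    stop("malformed header in ", path, "; expected columns: ",
         paste(KIN_COLS, collapse = ", "))
  n <- nrow(raw)
  if (n == 0L) {
    ev <- data.table(molecule_id = character(), subread_index = integer(),
                     strand = integer(), mapqv = integer(),
                     accuracy = numeric(), ref_pos = integer(),
                     op = character(), read_base = character(),
                     ref_base = character(), ipd = numeric())
    return(kinetics_dataset(ev, reference_id, reference_length %||% 0L,
                            sample_type, ipd_unit))
  }
  # line numbers in error messages count the header as line 1
  line_of <- function(i) i + 1L
  parse_num <- function(x, what) {
    out <- suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
    bad <- which(!is.na(x) & x != "." & is.na(out))
    if (length(bad))
      stop("non-numeric ", what, " at line ", line_of(bad[1L]), " of ", path)
    out
  }
  op <- raw$op
  bad_op <- which(!op %in% c("M", "X", "I", "D"))
  if (length(bad_op))
    stop("unknown op '", op[bad_op[1L]], "' at line ", line_of(bad_op[1L]),
         " of ", path)
  strand_chr <- raw$strand
  bad_strand <- which(!strand_chr %in% c("0", "1"))
  if (length(bad_strand))
    stop("unknown strand token '", strand_chr[bad_strand[1L]], "' at line ",
         line_of(bad_strand[1L]), " of ", path)
  ev <- data.table(
    molecule_id = raw$molecule_id,
    subread_index = as.integer(parse_num(raw$subread_index, "subread_index")),
    strand = as.integer(strand_chr),
    mapqv = as.integer(parse_num(raw$mapqv, "mapqv")),
    accuracy = parse_num(raw$accuracy, "accuracy"),
    ref_pos = as.integer(parse_num(raw$ref_pos, "ref_pos")),
    op = op,
    read_base = ifelse(raw$read_base == ".", NA_character_, raw$read_base),
    ref_base = ifelse(raw$ref_base == ".", NA_character_, raw$ref_base),
    ipd = parse_num(raw$ipd, "ipd"))
  if (is.null(reference_length))
    reference_length <- max(ev$ref_pos, na.rm = TRUE) + 1L
  kinetics_dataset(ev, reference_id, reference_length, sample_type, ipd_unit,
                   provenance = list(source = path))
}

#' Write a dataset in the aligned-kinetics TSV dialect
#'
#' Floats are written at 9 significant digits; reading the file back
#' reproduces the dataset to that precision, and re-writing a file produced
#' by this writer is byte-identical.
#'
#' @param ds a [kinetics_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kinetics_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "kinetics_dataset"))
  ev <- ds$events
  out <- data.table(
    molecule_id = ev$molecule_id,
    subread_index = fmt_int(ev$subread_index),
    strand = fmt_int(ev$strand),
    mapqv = fmt_int(ev$mapqv),
    accuracy = fmt_num(ev$accuracy),
    ref_pos = fmt_int(ev$ref_pos),
    op = ev$op,
    read_base = fmt_chr(ev$read_base),
    ref_base = fmt_chr(ev$ref_base),
    ipd = fmt_num(ev$ipd))
  setnames(out, KIN_COLS)
  fwrite(out, path, sep = "\t", quote = FALSE, col.names = TRUE)
  invisible(path)
}

# ---- PacBio-style aligned BAM/SAM with per-base IPD tag ---------------------

#' Read aligned PacBio-style kinetics from BAM (or SAM)
#'
#' Pairs the per-base IPD array tag (`ip`) with alignment operations via the
#' CIGAR string, producing the same subread semantics as
#' [read_kinetics_tsv()]: events in polymerase order (reverse-strand subreads
#' reversed back from reference order, bases complemented), soft/hard clips
#' dropped, MapQV taken from the mapping-quality field and accuracy
#' recomputed as matches / aligned read bases. Query names of the form
#' `movie/zmw/qstart_qend` (PacBio subreads) are grouped by `movie/zmw` with
#' subread indices assigned in order of appearance; names of the form
#' `molecule/<integer>` keep the explicit index.
#'
#' @param bam_path aligned BAM (a `.sam` path is converted on the fly).
#' @param ref_fasta FASTA file holding the mapped reference.
#' @param sample_type,ipd_unit dataset metadata; PacBio `ip` tags are frame
#'   counts, synthetic fixtures record seconds.
#' @return A [kinetics_dataset()].
#' @export
read_pacbio_bam <- function(bam_path, ref_fasta,
                            sample_type = c("native", "WGA"),
                            ipd_unit = "frames") {
  sample_type <- match.arg(sample_type)
  if (grepl("\\.sam$", bam_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam_path <- Rsamtools::asBam(bam_path, destination = dest,
                                 overwrite = TRUE, indexDestination = FALSE)
  }
  ref_set <- Biostrings::readDNAStringSet(ref_fasta)
  names(ref_set) <- sub("\\s.*$", "", names(ref_set))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = "ip")
  b <- Rsamtools::scanBam(bam_path, param = param)[[1L]]
  nreads <- length(b$qname)
  if (nreads == 0L)
    stop("no reads in ", bam_path)
  ref_names <- unique(as.character(b$rname[!is.na(b$rname)]))
  if (length(ref_names) && !all(ref_names %in% names(ref_set)))
    stop("reference name mismatch: BAM maps to ",
         paste(setdiff(ref_names, names(ref_set)), collapse = ", "),
         " but FASTA holds ", paste(names(ref_set), collapse = ", "))
  ip_list <- b$tag$ip
  if (is.null(ip_list)) ip_list <- vector("list", nreads)
  seqs <- as.character(b$seq)
  per_read <- vector("list", nreads)
  keep_meta <- vector("list", nreads)
  for (i in seq_len(nreads)) {
    flag <- b$flag[i]
    if (bitwAnd(flag, 4L) > 0L) {
      warning("skipping unmapped read ", b$qname[i])
      next
    }
    ip <- ip_list[[i]]
    if (is.null(ip))
      stop("read ", b$qname[i], " carries no per-base IPD ('ip') tag")
    cig <- b$cigar[i]
    ops <- cigar_ops(cig)
    refseq <- ref_set[[as.character(b$rname[i])]]
    qbases <- strsplit(seqs[i], "")[[1L]]
    if (length(ip) != length(qbases))
      stop("ip tag length differs from sequence length for read ", b$qname[i])
    rpos <- b$pos[i] - 1L      # 0-based
    qpos <- 1L
    ev_op <- character(0); ev_ref <- integer(0)
    ev_rb <- character(0); ev_fb <- character(0); ev_ipd <- numeric(0)
    for (k in seq_along(ops$len)) {
      len <- ops$len[k]
      o <- ops$op[k]
      if (o %in% c("M", "=", "X")) {
        idx <- seq_len(len)
        rb <- qbases[qpos + idx - 1L]
        fb <- strsplit(as.character(Biostrings::subseq(refseq, rpos + 1L,
                                                       rpos + len)), "")[[1L]]
        ev_op <- c(ev_op, ifelse(rb == fb, "M", "X"))
        ev_ref <- c(ev_ref, rpos + idx - 1L)
        ev_rb <- c(ev_rb, rb)
        ev_fb <- c(ev_fb, fb)
        ev_ipd <- c(ev_ipd, ip[qpos + idx - 1L])
        rpos <- rpos + len; qpos <- qpos + len
      } else if (o == "I") {
        idx <- seq_len(len)
        ev_op <- c(ev_op, rep("I", len))
        ev_ref <- c(ev_ref, rep(NA_integer_, len))
        ev_rb <- c(ev_rb, qbases[qpos + idx - 1L])
        ev_fb <- c(ev_fb, rep(NA_character_, len))
        ev_ipd <- c(ev_ipd, ip[qpos + idx - 1L])
        qpos <- qpos + len
      } else if (o == "D" || o == "N") {
        idx <- seq_len(len)
        fb <- strsplit(as.character(Biostrings::subseq(refseq, rpos + 1L,
                                                       rpos + len)), "")[[1L]]
        ev_op <- c(ev_op, rep("D", len))
        ev_ref <- c(ev_ref, rpos + idx - 1L)
        ev_rb <- c(ev_rb, rep(NA_character_, len))
        ev_fb <- c(ev_fb, fb)
        ev_ipd <- c(ev_ipd, rep(NA_real_, len))
        rpos <- rpos + len
      } else if (o == "S") {
        qpos <- qpos + len
      } # H, P consume nothing stored
    }
    reverse <- bitwAnd(flag, 16L) > 0L
    if (reverse) {
      ord <- rev(seq_along(ev_op))
      ev_op <- ev_op[ord]; ev_ref <- ev_ref[ord]; ev_ipd <- ev_ipd[ord]
      ev_rb <- complement_bases(ev_rb[ord])
      ev_fb <- complement_bases(ev_fb[ord])
    }
    acc <- sum(ev_op == "M") / sum(ev_op %in% c("M", "X", "I"))
    per_read[[i]] <- data.table(op = ev_op, ref_pos = ev_ref,
                                read_base = ev_rb, ref_base = ev_fb,
                                ipd = ev_ipd)
    keep_meta[[i]] <- list(qname = b$qname[i],
                           strand = as.integer(reverse),
                           mapqv = as.integer(b$mapq[i]),
                           accuracy = acc)
  }
  kept <- which(!vapply(per_read, is.null, logical(1)))
  if (!length(kept))
    stop("no mapped reads in ", bam_path)
  meta <- rbindlist(lapply(keep_meta[kept], as.data.table))
  parsed <- parse_subread_names(meta$qname)
  tabs <- vector("list", length(kept))
  for (j in seq_along(kept)) {
    t <- per_read[[kept[j]]]
    t[, `:=`(molecule_id = parsed$molecule_id[j],
             subread_index = parsed$subread_index[j],
             strand = meta$strand[j], mapqv = meta$mapqv[j],
             accuracy = meta$accuracy[j])]
    tabs[[j]] <- t
  }
  ev <- rbindlist(tabs)[, KIN_COLS, with = FALSE]
  setorder(ev, molecule_id, subread_index)  # stable: keeps event order inside subreads
  rid <- if (length(ref_names)) ref_names[1L] else names(ref_set)[1L]
  kinetics_dataset(ev, rid, length(ref_set[[rid]]), sample_type, ipd_unit,
                   provenance = list(source = bam_path))
}

cigar_ops <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1L]]
  parts <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1L]]
  if (!length(parts) || sum(nchar(parts)) != nchar(cigar))
    stop("unparseable CIGAR: ", cigar)
  list(len = as.integer(sub("[A-Z=]$", "", parts)),
       op = sub("^\\d+", "", parts))
}

# "movie/zmw/qs_qe" -> molecule movie/zmw, index by appearance order;
# "anything/<int>" -> explicit index; otherwise whole name + appearance order.
parse_subread_names <- function(qnames) {
  mol <- qnames
  idx <- rep(NA_integer_, length(qnames))
  pacbio <- grepl("^.+/\\d+/\\d+_\\d+$", qnames)
  mol[pacbio] <- sub("/\\d+_\\d+$", "", qnames[pacbio])
  explicit <- !pacbio & grepl("^.+/\\d+$", qnames)
  mol[explicit] <- sub("/\\d+$", "", qnames[explicit])
  idx[explicit] <- as.integer(sub("^.*/", "", qnames[explicit]))
  need <- which(is.na(idx))
  if (length(need)) {
    dt <- data.table(i = need, mol = mol[need])
    dt[, k := seq_len(.N) - 1L, by = mol]
    idx[need] <- dt$k
  }
  list(molecule_id = mol, subread_index = idx)
}

#' Write a dataset as an aligned SAM file with per-base IPD tags
#'
#' Emits one SAM record per subread with the per-base IPDs in an `ip:B:f`
#' float-array tag (in SEQ order), suitable for round-tripping through
#' [read_pacbio_bam()]. Reverse-strand subreads are written in reference
#' orientation with reverse-complemented SEQ, as an aligner would.
#'
#' @param ds a [kinetics_dataset()].
#' @param path output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_kinetics_sam <- function(ds, path) {
  stopifnot(inherits(ds, "kinetics_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", ds$reference_id,
                       ds$reference_length)), con)
  ev <- copy(ds$events)
  if (!nrow(ev)) return(invisible(path))
  ev[, .row := .I]
  subs <- split(ev, by = c("molecule_id", "subread_index"), sorted = FALSE)
  lines <- vapply(subs, function(s) {
    strand <- s$strand[1L]
    if (strand == 1L) {
      # back to reference orientation
      s <- s[rev(seq_len(.N))]
      rb <- complement_bases(s$read_base)
    } else rb <- s$read_base
    cons <- s$op %in% c("M", "X", "D")
    pos1 <- min(s$ref_pos[cons]) + 1L
    has_base <- s$op %in% c("M", "X", "I")
    seq_chr <- paste(rb[has_base], collapse = "")
    ip <- s$ipd[has_base]
    runs <- rle(ifelse(s$op %in% c("M", "X"), "M", s$op))
    cig <- paste0(runs$lengths, runs$values, collapse = "")
    sprintf("%s/%d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tip:B:f,%s",
            s$molecule_id[1L], s$subread_index[1L],
            if (strand == 1L) 16L else 0L, ds$reference_id, pos1,
            s$mapqv[1L], cig, seq_chr,
            paste(sprintf("%.9g", ip), collapse = ","))
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

# ---- score tables -----------------------------------------------------------

SCORE_COLS <- list(
  smsn = c("molecule_id", "strand", "ref_pos", "cov_sm", "score"),
  agg  = c("strand", "ref_pos", "native_n", "wga_n", "score"),
  smp  = c("molecule_id", "strand", "n_sites", "score"))

score_kind <- function(scores) {
  k <- attr(scores, "score_kind")
  if (!is.null(k)) return(k)
  for (k in names(SCORE_COLS))
    if (all(SCORE_COLS[[k]] %in% names(scores))) return(k)
  stop("cannot determine score kind from columns: ",
       paste(names(scores), collapse = ", "))
}

#' Write a score table as TSV
#'
#' One row per score; columns fixed per score kind (`smsn`: molecule_id,
#' strand, ref_pos, cov_sm, score; `agg`: strand, ref_pos, native_n, wga_n,
#' score; `smp`: molecule_id, strand, n_sites, score). Floats at 9
#' significant digits.
#'
#' @param scores a score table from [smsn_scores()], [agg_scores()] or
#'   [smp_scores()], or a list of such tables of one kind.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  if (is.list(scores) && !is.data.frame(scores)) {
    kinds <- unique(vapply(scores, score_kind, character(1)))
    if (length(kinds) > 1L)
      stop("mixed score kinds: ", paste(kinds, collapse = ", "))
    scores <- rbindlist(scores)
    setattr(scores, "score_kind", kinds)
  }
  kind <- score_kind(scores)
  cols <- SCORE_COLS[[kind]]
  dt <- as.data.table(scores)[, cols, with = FALSE]
  out <- dt[, lapply(.SD, function(col)
    if (is.double(col)) fmt_num(col) else fmt_chr(col))]
  fwrite(out, path, sep = "\t", quote = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#' @param path TSV path.
#' @return data.table with a `score_kind` attribute.
#' @export
read_scores <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  kind <- score_kind(dt)
  for (col in intersect(c("strand", "ref_pos", "cov_sm", "native_n", "wga_n",
                          "n_sites"), names(dt)))
    set(dt, j = col, value = as.integer(dt[[col]]))
  set(dt, j = "score", value = as.numeric(dt$score))
  setattr(dt, "score_kind", kind)
  dt[]
}
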