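# Seeded generator of paired native/WGA aligned-kinetics datasets with known
# per-molecule and per-site methylation truth. The generative model mirrors
# the single-molecule sequencing picture: a circularised insert is traversed
# repeatedly by the polymerase, alternating strands, each pass emitting one
# subread; per-pass raw IPDs are log-normal around a fixed per-(strand,
# position) sequence-context offset plus a per-molecule rate offset, with a
# methylation shift delta added at modified motif positions; alignment
# errors (mismatch/insertion/deletion, equal shares) perturb events but not
# the truth.

#' Methylation regimes for the synthetic generator
#'
#' `regime_constitutive()`: every molecule methylated at every site (an
#' always-active MTase). `regime_phase_variable(f_active)`: a fraction of
#' molecules fully methylated, the rest fully non-methylated (phasevarion
#' ON/OFF switching). `regime_stochastic(p_site)`: each (molecule, site)
#' methylated independently with probability `p_site` (stochastic target
#' skipping). `strands` restricts methylation to one strand to emulate
#' hemi-methylation (e.g. behind the replication fork).
#'
#' @param f_active fraction of molecules with the MTase active.
#' @param p_site per-site methylation probability.
#' @param strands strand(s) on which sites can be methylated.
#' @return A regime description list.
#' @export
regime_constitutive <- function(strands = c(0L, 1L))
  list(type = "constitutive", strands = as.integer(strands))

#' @rdname regime_constitutive
#' @export
regime_phase_variable <- function(f_active, strands = c(0L, 1L)) {
  stopifnot(f_active >= 0, f_active <= 1)
  list(type = "phase_variable", f_active = f_active,
       strands = as.integer(strands))
}

#' @rdname regime_constitutive
#' @export
regime_stochastic <- function(p_site, strands = c(0L, 1L)) {
  stopifnot(p_site >= 0, p_site <= 1)
  list(type = "stochastic", p_site = p_site, strands = as.integer(strands))
}

#' Synthetic kinetics configuration
#'
#' Defaults describe a short-insert (~250 bp) SMRT library, where a long
#' polymerase read yields many passes per molecule and therefore high
#' single-molecule coverage; `library = "long"` switches to ~5 kb inserts
#' giving 1-2 passes, the long-read phasing regime. The methylation shift
#' `delta` defaults to 2 natural-log units, the location of the methylated
#' 6mA score component; per-pass log-IPD noise defaults to 1.2 so that
#' single-molecule mean scores at around 10 passes have a spread near the
#' 0.5 used for simulated score mixtures.
#'
#' @param seed RNG seed for molecule-level randomness.
#' @param reference_length length of the simulated reference (ignored when a
#'   reference is supplied to [simulate_dataset()]).
#' @param motif a [motif_spec()] defining methylation target sites.
#' @param n_molecules number of molecules.
#' @param library `"short"` or `"long"` insert-size preset.
#' @param insert_mean,insert_sd insert length distribution (bases);
#'   defaults 250/30 (short) or 5000/500 (long).
#' @param read_length total polymerase read length; the pass count is
#'   `floor(read_length / (insert + adapter_len))`, at least 1.
#' @param adapter_len hairpin adapter length per pass.
#' @param context_sd sd of the fixed per-(strand, position) baseline log-IPD
#'   context offsets (shared between native/WGA twins via `context_seed`).
#' @param noise_sd per-pass log-IPD noise sd.
#' @param molecule_sd sd of the per-molecule rate offset (removed by
#'   per-molecule normalization downstream).
#' @param delta methylation log-IPD shift at modified positions.
#' @param regime a [regime_constitutive()], [regime_phase_variable()] or
#'   [regime_stochastic()].
#' @param error_rate alignment error probability per event, split equally
#'   across mismatch/insertion/deletion.
#' @param sample_type `"native"` or `"WGA"`; WGA forces `delta = 0` and all
#'   truth flags false.
#' @param ipd_unit recorded IPD unit.
#' @param context_seed seed for the context offsets and default reference;
#'   native/WGA twins must share it so the WGA subtraction removes context
#'   bias. Defaults to `seed`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, reference_length = 20000L,
                       motif = motif_spec("GATC", 1L),
                       n_molecules = 100L,
                       library = c("short", "long"),
                       insert_mean = NULL, insert_sd = NULL,
                       read_length = 8000L, adapter_len = 50L,
                       context_sd = 0.4, noise_sd = 1.2, molecule_sd = 0.3,
                       delta = 2.0, regime = regime_constitutive(),
                       error_rate = 0.08,
                       sample_type = c("native", "WGA"),
                       ipd_unit = "seconds", context_seed = NULL) {
  library <- match.arg(library)
  sample_type <- match.arg(sample_type)
  insert_mean <- insert_mean %||% switch(library, short = 250, long = 5000)
  insert_sd <- insert_sd %||% switch(library, short = 30, long = 500)
  stopifnot(inherits(motif, "motif_spec"), reference_length > 0,
            n_molecules >= 1, insert_mean > 0, insert_sd >= 0,
            read_length > 0, adapter_len >= 0, context_sd >= 0,
            noise_sd >= 0, molecule_sd >= 0, error_rate >= 0,
            error_rate <= 1)
  structure(list(seed = as.integer(seed),
                 reference_length = as.integer(reference_length),
                 motif = motif, n_molecules = as.integer(n_molecules),
                 library = library, insert_mean = insert_mean,
                 insert_sd = insert_sd, read_length = as.integer(read_length),
                 adapter_len = as.integer(adapter_len),
                 context_sd = context_sd, noise_sd = noise_sd,
                 molecule_sd = molecule_sd, delta = delta, regime = regime,
                 error_rate = error_rate, sample_type = sample_type,
                 ipd_unit = ipd_unit,
                 context_seed = as.integer(context_seed %||% seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s sample, %d molecules on %d bp reference\n",
              x$sample_type, x$n_molecules, x$reference_length))
  cat(sprintf("  %s library: insert %g+-%g bp, read length %d => ~%d passes\n",
              x$library, x$insert_mean, x$insert_sd, x$read_length,
              max(1L, x$read_length %/% (round(x$insert_mean) + x$adapter_len))))
  cat(sprintf("  motif %s, delta %g, regime %s, error rate %g\n",
              x$motif$name, x$delta, x$regime$type, x$error_rate))
  cat(sprintf("  seeds: %d (molecules), %d (context)\n", x$seed,
              x$context_seed))
  invisible(x)
}

#' WGA twin of a native simulation config
#'
#' Same reference and context seed (so context offsets are shared and the
#' WGA subtraction genuinely removes context bias), different molecule seed,
#' `sample_type = "WGA"`.
#'
#' @param cfg a native [sim_config()].
#' @param seed molecule seed for the twin; default offsets the native seed.
#' @param n_molecules optionally different control depth.
#' @return A [sim_config()].
#' @export
wga_twin <- function(cfg, seed = cfg$seed + 104729L,
                     n_molecules = cfg$n_molecules) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$seed <- as.integer(seed)
  cfg$n_molecules <- as.integer(n_molecules)
  cfg$sample_type <- "WGA"
  cfg
}

#' Simulate a uniform random reference sequence
#' @param length sequence length in bases.
#' @param seed RNG seed.
#' @return A character string over A/C/G/T.
#' @export
simulate_reference <- function(length, seed = 1L) {
  if (length == 0) return("")
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""))
}

context_offsets <- function(len, sd, seed) {
  with_seed(seed, list(fwd = stats::rnorm(len, 0, sd),
                       rev = stats::rnorm(len, 0, sd)))
}

#' Simulate an aligned-kinetics dataset with known methylation truth
#'
#' @param cfg a [sim_config()].
#' @param reference optional reference sequence (character); by default a
#'   random reference of `cfg$reference_length` bases generated under
#'   `cfg$context_seed`, so native/WGA twins share it.
#' @return A list with elements `dataset` (a [kinetics_dataset()]), `truth`
#'   (list of `molecules` and `sites` truth tables) and `sites` (all motif
#'   sites on the reference).
#' @export
simulate_dataset <- function(cfg, reference = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  reference <- reference %||% simulate_reference(cfg$reference_length,
                                                 cfg$context_seed)
  L <- nchar(reference)
  if (round(cfg$insert_mean) > L)
    stop("mean insert length (", round(cfg$insert_mean),
         ") exceeds reference length (", L, ")")
  sites <- find_motif_sites(reference, cfg$motif)
  is_wga <- cfg$sample_type == "WGA"
  if (!is_wga && cfg$delta != 0 && nrow(sites) == 0L)
    stop("reference contains no ", cfg$motif$name,
         " site; methylation regime is unsatisfiable")
  ctx <- context_offsets(L, cfg$context_sd, cfg$context_seed)
  refv <- strsplit(reference, "")[[1L]]
  out <- with_seed(cfg$seed,
                   simulate_molecules(cfg, L, sites, ctx, refv, is_wga))
  ds <- kinetics_dataset(out$events, reference_id = "synthetic_ref",
                         reference_length = L, sample_type = cfg$sample_type,
                         ipd_unit = cfg$ipd_unit,
                         provenance = list(generator = "smalr::simulate_dataset",
                                           seed = cfg$seed,
                                           context_seed = cfg$context_seed),
                         validate = FALSE)
  list(dataset = ds, truth = out$truth, sites = sites)
}

simulate_molecules <- function(cfg, L, sites, ctx, refv, is_wga) {
  n <- cfg$n_molecules
  mol <- data.table(molecule_id = sprintf("mol%06d", seq_len(n)))
  ins_len <- pmax(30L, pmin(L, as.integer(round(
    stats::rnorm(n, cfg$insert_mean, cfg$insert_sd)))))
  mol[, `:=`(insert_len = ins_len,
             start = as.integer(floor(stats::runif(n, 0, L - ins_len + 1))),
             npass = pmax(1L, cfg$read_length %/% (ins_len + cfg$adapter_len)),
             first_strand = sample(0:1, n, replace = TRUE),
             mol_offset = stats::rnorm(n, 0, cfg$molecule_sd))]
  # molecule-level methylation truth
  regime <- cfg$regime
  mol[, methylated := if (is_wga) FALSE else switch(
    regime$type,
    constitutive = TRUE,
    phase_variable = stats::runif(n) < regime$f_active,
    stochastic = TRUE)]
  mol[, regime_label := if (is_wga) "WGA" else regime$type]
  # per-(molecule, site) truth for sites inside the insert
  if (nrow(sites)) {
    cov_sites <- sites[, .(strand, ref_pos)][
      mol[, .(molecule_id, start, end = start + insert_len,
              methylated)],
      on = .(ref_pos >= start, ref_pos < end), nomatch = NULL,
      .(molecule_id, strand = x.strand, ref_pos = x.ref_pos, methylated)]
    cov_sites[, site_meth := methylated &
                (strand %in% regime$strands) & !is_wga]
    if (!is_wga && regime$type == "stochastic")
      cov_sites[site_meth == TRUE,
                site_meth := stats::runif(.N) < regime$p_site]
    cov_sites[, methylated := NULL]
    setnames(cov_sites, "site_meth", "methylated")
  } else {
    cov_sites <- data.table(molecule_id = character(), strand = integer(),
                            ref_pos = integer(), methylated = logical())
  }
  # subreads: passes alternate strands
  sub <- mol[rep(seq_len(n), npass)]
  sub[, subread_index := seq_len(.N) - 1L, by = molecule_id]
  sub[, strand := (first_strand + subread_index) %% 2L]
  # events: one template position per event, in polymerase (read) order
  ev <- sub[rep(seq_len(nrow(sub)), sub$insert_len),
            .(molecule_id, subread_index, strand, start, insert_len,
              mol_offset)]
  ev[, j := seq_len(.N) - 1L, by = .(molecule_id, subread_index)]
  ev[, ref_pos := fifelse(strand == 0L, start + j,
                          start + insert_len - 1L - j)]
  ev[, c("start", "insert_len", "j") := NULL]
  # methylation flag per event (signal appears on the site's strand)
  ev[, meth := FALSE]
  meth_sites <- cov_sites[methylated == TRUE]
  if (nrow(meth_sites))
    ev[meth_sites, meth := TRUE, on = c("molecule_id", "strand", "ref_pos")]
  # log-normal IPD around context + molecule offset (+ delta if methylated)
  delta <- if (is_wga) 0 else cfg$delta
  ctxv <- fifelse(ev$strand == 0L, ctx$fwd[ev$ref_pos + 1L],
                  ctx$rev[ev$ref_pos + 1L])
  ev[, ipd := exp(ctxv + mol_offset + delta * meth +
                    stats::rnorm(.N, 0, cfg$noise_sd))]
  ev[, meth := NULL]
  # reference bases, in read orientation
  fb <- refv[ev$ref_pos + 1L]
  ev[, ref_base := fifelse(strand == 0L, fb, complement_bases(fb))]
  ev[, read_base := ref_base]
  ev[, op := "M"]
  # alignment errors: equal shares of mismatch / insertion / deletion
  if (cfg$error_rate > 0) {
    err <- stats::runif(nrow(ev)) < cfg$error_rate
    etype <- integer(nrow(ev))
    etype[err] <- sample(3L, sum(err), replace = TRUE)
    bases <- c("A", "C", "G", "T")
    # mismatches: random base different from the reference base
    xi <- which(etype == 1L)
    if (length(xi)) {
      shift <- sample(3L, length(xi), replace = TRUE)
      cur <- match(ev$ref_base[xi], bases)
      set(ev, xi, "read_base", bases[((cur - 1L + shift) %% 4L) + 1L])
      set(ev, xi, "op", "X")
    }
    # deletions: no read base, no IPD
    di <- which(etype == 2L)
    if (length(di)) {
      set(ev, di, "op", "D")
      set(ev, di, "read_base", NA_character_)
      set(ev, di, "ipd", NA_real_)
    }
    # insertions: an extra non-reference base after the (unchanged) event
    ii <- which(etype == 3L)
    if (length(ii)) {
      ins <- ev[ii, .(molecule_id, subread_index, strand, mol_offset)]
      ins[, `:=`(ref_pos = NA_integer_, op = "I",
                 read_base = sample(bases, .N, replace = TRUE),
                 ref_base = NA_character_,
                 ipd = exp(mol_offset + stats::rnorm(.N, 0, cfg$noise_sd)))]
      ev[, ord := seq_len(.N)]
      ins[, ord := ev$ord[ii] + 0.5]
      ev <- rbind(ev, ins, use.names = TRUE)
      setorder(ev, ord)
      ev[, ord := NULL]
    }
  }
  ev[, mol_offset := NULL]
  # per-subread accuracy (matches / aligned read bases) and MapQV
  ev[, accuracy := {
    emit <- op %in% c("M", "X", "I")
    sum(op == "M") / max(1L, sum(emit))
  }, by = .(molecule_id, subread_index)]
  ev[, mapqv := 254L]
  setcolorder(ev, KIN_COLS)
  truth <- list(
    molecules = mol[, .(molecule_id, regime = regime_label, methylated)],
    sites = cov_sites)
  list(events = ev, truth = truth)
}

#' Write a paired native/WGA synthetic fixture to disk
#'
#' Emits `native.tsv`, `wga.tsv`, `reference.fasta`, truth tables
#' (`truth_molecules.tsv`, `truth_sites.tsv`) and a `manifest.yaml`
#' recording seeds, the full configuration and a config hash; optionally
#' also twin SAM files with per-base IPD tags. Same config + seed produces
#' byte-identical files.
#'
#' @param cfg a native [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param sam also write `native.sam` / `wga.sam`.
#' @param wga_n_molecules control depth; defaults to the native count.
#' @return Named list of written paths, invisibly.
#' @export
write_fixture_pair <- function(cfg, out_dir, sam = FALSE,
                               wga_n_molecules = cfg$n_molecules) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reference <- simulate_reference(cfg$reference_length, cfg$context_seed)
  native <- simulate_dataset(cfg, reference)
  wcfg <- wga_twin(cfg, n_molecules = wga_n_molecules)
  wga <- simulate_dataset(wcfg, reference)
  paths <- list(
    native = file.path(out_dir, "native.tsv"),
    wga = file.path(out_dir, "wga.tsv"),
    reference = file.path(out_dir, "reference.fasta"),
    truth_molecules = file.path(out_dir, "truth_molecules.tsv"),
    truth_sites = file.path(out_dir, "truth_sites.tsv"),
    manifest = file.path(out_dir, "manifest.yaml"))
  write_kinetics_tsv(native$dataset, paths$native)
  write_kinetics_tsv(wga$dataset, paths$wga)
  refset <- Biostrings::DNAStringSet(reference)
  names(refset) <- "synthetic_ref"
  Biostrings::writeXStringSet(refset, paths$reference)
  fwrite(native$truth$molecules, paths$truth_molecules, sep = "\t")
  fwrite(native$truth$sites, paths$truth_sites, sep = "\t")
  if (sam) {
    paths$native_sam <- file.path(out_dir, "native.sam")
    paths$wga_sam <- file.path(out_dir, "wga.sam")
    write_kinetics_sam(native$dataset, paths$native_sam)
    write_kinetics_sam(wga$dataset, paths$wga_sam)
  }
  cfg_plain <- unclass(cfg)
  cfg_plain$motif <- unclass(cfg_plain$motif)
  manifest <- list(generator = "smalr::write_fixture_pair",
                   seed = cfg$seed, wga_seed = wcfg$seed,
                   context_seed = cfg$context_seed,
                   config = cfg_plain, config_hash = config_hash(cfg))
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}
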