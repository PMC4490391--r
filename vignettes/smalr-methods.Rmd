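---
title: "Methods: single-molecule methylation scoring from SMRT kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule methylation scoring from SMRT kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement model

SMRT sequencing reads a circularised double-stranded insert repeatedly:
each traversal of one strand is a subread, and a molecule typically yields
many subreads whose number grows as the insert shrinks. The instrument
records an inter-pulse duration (IPD) for every incorporated base. A
methylated template base (6mA, 4mC) slows the polymerase, so IPDs at that
position are stochastically longer than on unmethylated template.

Raw IPDs are noisy and biased by three nuisance factors the package
removes in order:

1. **Alignment errors.** Subreads with MapQV < 240, accuracy < 80% or
   aligned length < 100 bases are dropped; surviving IPDs within
   `error_mask_radius` (default 1) read positions of any mismatch,
   insertion or deletion are masked. The error event's own IPD is always
   masked — an IPD attached to a miscalled or spurious base does not
   measure the template position it is nominally aligned to. "Error"
   deliberately covers mismatches, insertions and deletions alike.
2. **Polymerase rate drift.** A polymerase slows over the minutes-long
   movie, so later subreads of the same molecule run slower wholesale.
   Taking natural logs and subtracting the per-molecule mean of all
   surviving log IPDs removes this molecule-level rate factor exactly (the
   per-molecule mean of the output is 0 to machine precision, and all
   scores are invariant under molecule-wise rescaling of raw IPDs — hence
   also under the choice of seconds versus frames, provided native and
   control agree; mixed units are rejected rather than converted).
3. **Sequence context.** IPDs depend strongly on the local sequence around
   the incorporation site. No context model is fitted; instead every score
   subtracts a whole-genome-amplified (WGA) control measured at the same
   strand and position, which carries the same context bias but no
   methylation.

Adapter transitions bias kinetics near subread ends, so the first 10 and
last 15 events of each subread are trimmed. One ordering decision is ours:
the centring mean is computed over the IPDs that survive masking *and*
trimming, because that makes the zero-mean invariant exact and testable;
computing the mean before trimming is available via
`preprocess_config(mean_before_trim = TRUE)` and differs only through the
few trimmed observations per subread.

## Scores

With clean observations `x(i, s, p, k)` (molecule *i*, strand *s*,
reference position *p*, observation *k*) and the control mean
`c(s, p)` (pooled over all WGA molecules):

- `SM_SN(i, s, p) = mean_k x(i, s, p, k) − c(s, p)`, computed at motif
  sites with at least `min_cov` observations (default 10). The score of an
  unmethylated site is centred at 0; a methylated 6mA site centres near 2
  natural-log units. Its spread shrinks as `1/sqrt(cov_SM)`, which is why
  short-insert libraries (many passes) suit single-nucleotide resolution.
- `Agg_SN(s, p)` pools all native molecules first — the population-level
  statistic that conventional pipelines report. It equals the
  cov_SM-weighted mean of the SM_SN scores at the site, a relationship the
  test suite checks against brute-force recomputation.
- `SM_P(i, s)` pools the molecule's observations across *all* covered
  motif sites on a strand and subtracts the unweighted mean of the per-site
  control means over the same sites. Averaging control means per site
  (rather than pooling raw WGA observations) makes the statistic
  independent of uneven WGA depth across sites; the wording of the
  construction admits both readings and this one is fixed here. Sites
  without a control entry are excluded from both sides, never imputed —
  imputation would reinject the context bias the control exists to remove.
  Palindromic motifs yield one SM_P score per strand; the two strand
  readings are never merged, so hemi-methylated molecules remain visible.
- `approx_smsn_scores()` drops the control subtraction entirely for
  organisms without WGA data; the score is then biased by context but
  still resolves bimodality (the two components just ride on a context
  offset).

`cov_SM` counts surviving IPD observations after masking and trimming, not
nominal passes, because that is the quantity that powers the score.

## Methylated fraction by EM

The methylated fraction of a motif is read from the score distribution
with a self-contained two-component Gaussian EM
(`fit_two_gaussian_em()`): deterministic initialisation (median split and
a k-means split, best log-likelihood kept; a seeded random restart can be
added), convergence when the log-likelihood gain drops below `tol`
(default 1e-6), and a standard-deviation floor of 1e-3 against component
collapse. A self-contained EM — rather than an external mixture package —
pins the behaviour bit-for-bit; `mclust` appears only as an independent
cross-check in the tests.

Two numerical decisions matter at the boundaries:

- **One population or two.** A one-component Gaussian is fitted alongside
  and compared by BIC. BIC alone is conservative for moderately separated
  components at a few hundred scores (it discards clearly bimodal fits in
  roughly a sixth of simulated draws at n ≈ 165), so a fitted pair
  separated by at least 2 pooled standard deviations whose minor component
  carries at least 10 expected observations is kept as two components
  regardless. Both constants were fixed on simulated sanity cases (pure
  Gaussians versus labelled mixtures) before the evaluation suite was
  frozen.
- **Single-population readout.** When one component is selected, the
  sample is one population and the fraction is 1 or 0 according to which
  side of `midpoint` (default 1, half the canonical 6mA shift) its mean
  falls. A sign rule would be a coin flip exactly in the most common case,
  a fully unmethylated motif whose mean straddles 0.

`methylated_fraction()` is the high-component weight; no posterior
thresholding enters the fraction estimate. Thresholds appear only in
molecule calling. At a few hundred scores with overlapping components the
1-versus-2 decision itself carries uncertainty; fractions from fewer than
~400 scores should be read with that caveat.

## Molecule calls and empirical FDR

Calling individual molecules methylated (or non-methylated) uses
`empirical_fdr()`: at each candidate threshold (the sorted native scores),
the FDR estimate is the control tail fraction over the native tail
fraction, capped at 1. The negative control is WGA-derived SM_P scores for
methylated calls and IPD-shuffled native scores
(`shuffle_control_smp()`, which permutes site observations across
molecules while preserving each molecule's covered-site structure) for
non-methylated calls — the shuffle disperses the rare unmodified IPDs so
the control reflects molecules at the population-average methylation
level.

The curve is made non-increasing in threshold extremity by a running
minimum from the *least* extreme threshold. The alternative suffix
minimum (over more extreme thresholds) lets a chance zero in the sparse
far tail — one native score beyond the last control score — collapse the
entire curve to zero under the null, which contradicts what a null
construction must report (FDR ≈ 1 everywhere). The estimator remains
optimistic in the extreme tail where counts are single digits; calls
should be read from `fdr_call_fraction()` at a cap (default 1%), not from
individual tail thresholds.

## The synthetic generator

`simulate_dataset()` draws, per molecule: an insert position and length
(short preset 250 ± 30 bp; long preset 5000 ± 500 bp), a pass count
`floor(read_length / (insert + adapter))` with alternating strands
(defaults give ~26 passes for short inserts, 1–2 for long — the two
library regimes the method exploits), a molecule rate offset
(log-sd 0.3), and a methylation state per regime. Each emitted base gets

    IPD = exp(context(s, p) + molecule_offset + delta * methylated(i, s, p)
              + Normal(0, noise_sd))

with errors injected at `error_rate` (default 0.08, equal shares
mismatch/insertion/deletion; insertions add a spurious base, deletions
drop one). The per-(strand, position) context offsets (sd 0.4) are drawn
once from `context_seed` and shared between a native dataset and its
`wga_twin()` — this shared context is precisely the mechanism that makes
the WGA subtraction work, so the twins must be generated with the same
`context_seed`. `delta` defaults to 2.0 natural-log units, the observed
location of the methylated 6mA score component; `noise_sd` defaults to
1.2 so that single-molecule mean scores at around 10 passes spread with
sd near the 0.5 used for the simulated score mixtures. Three regimes
encode the biological scenarios: `constitutive` (always-on MTase),
`phase_variable(f_active)` (ON/OFF switching across molecules),
`stochastic(p_site)` (independent per-site skipping); a `strands` modifier
restricts methylation to one strand to emulate hemi-methylation.

What the generator does *not* emulate: pulse-width signal, polymerase
pausing, chemistry-version kinetics differences, context-dependent error
rates, mappability structure of real genomes, or extended multi-position
kinetic footprints of a modification (scores read the modified base's
position only). Tests passing on this generator therefore demonstrate the
statistical machinery — not that real-instrument noise is fully captured.
The single-pass log-normal IPD model is itself a modelling choice,
motivated by the approximate normality of mean log IPD scores; no
explicit noise model is published for single passes.

## Motifs

IUPAC motifs are scanned on both strands with step 1 (all overlapping
matches), reverse-strand sites mapped back to forward coordinates of the
modified base. A bipartite pair such as TCAN6TRG / CYAN6TGA is one spec
scanned both ways — the second written form is the reverse-complement
reading. The modified-base offset inside a bipartite type III motif is not
derivable from the motif itself, so `modified_index` is user input; when
omitted it defaults to the first adenine with a warning.
`expand_degenerate()` provides the explicit expansions (RGATCY → AGATCC,
AGATCT, GGATCC, GGATCT) used when testing specificity sub-motif by
sub-motif.

## Evaluation problem sizes

The acceptance checks run entirely on the generator, at sizes chosen to
keep each experiment's sampling error several times smaller than the
tolerance it is compared against: score-mixture EM recovery at n = 10,000
per mixing fraction; null centring on ~1,600 SM_SN scores from 1,100
short-insert molecules on a 20 kb reference; regime discrimination on 500
long-insert molecules (~480 SM_P scores per regime); and coverage
stability on a 500 kb reference with a dense 3-base motif (GAC) and
14-pass 100 bp inserts, which keeps sites-per-insert comparable to GATC on
250 bp inserts while allowing ~360 molecules at ×1 coverage. For the
coverage experiment the ×1 estimate is the median over 12 independent
downsampling replicates: the claim under test is stability of the
estimator across coverage, and a single ×1 subsample at desk scale would
mostly measure its own sampling scatter (a few percentage points) rather
than the estimator.

## Known limitations

- 5mC is out of scope: its kinetic signature is too weak at the modified
  base for this scoring scheme.
- Scores read one position; MTases with extended kinetic footprints would
  benefit from multi-position models, which are not implemented.
- The EM fraction inherits a slight downward bias when a minority of
  sites is stably non-methylated in the "methylated" population — the
  mixture then sits between the pure components; no correction is
  applied, the behaviour is documented.
- The FDR estimator is empirical and two-sample; it does not correct
  across motifs (each motif is analysed independently).
- `read_pacbio_bam()` recomputes accuracy from the alignment and trusts
  the `ip` tag's unit only as declared by the caller; legacy cmp.h5 input
  is not supported.
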