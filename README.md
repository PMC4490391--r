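# smalr

Single-molecule detection and phasing of bacterial DNA methylation from
SMRT sequencing kinetics.

## The problem

During single-molecule real-time (SMRT) sequencing, a base modification on
the template — in bacteria chiefly N6-methyladenine (6mA) and
N4-methylcytosine (4mC) — slows the polymerase, lengthening the
inter-pulse duration (IPD) at the modified position. Conventional analyses
aggregate IPDs across all sequenced molecules before calling methylation,
which erases exactly the biology that makes bacterial methylomes
interesting: partially methylated motifs, stochastic site skipping by a
methyltransferase (MTase), and phase-variable MTases that split a clonal
population into epigenetically distinct subpopulations (phasevarions).

`smalr` scores methylation **per molecule**, using whole-genome-amplified
(WGA) DNA — amplification erases all methylation — as a kinetic control
that cancels local sequence-context IPD bias. It is aimed at
microbiologists and epigenomics researchers analysing aligned SMRT
kinetics for motif-level heterogeneity and single-molecule epigenetic
phasing.

## The statistics

After subread filtering (MapQV ≥ 240, accuracy ≥ 80%, aligned length ≥ 100
bases), masking of IPDs within one position of alignment errors, trimming
of 10/15 bases at subread ends, and per-molecule mean-centring of natural
log IPDs:

- **SM_SN** (single-molecule, single-nucleotide), for molecule *i*, strand
  *s*, motif position *p*:

      SM_SN(i,s,p) = mean(log IPD_native(i,s,p)) − mean(log IPD_WGA(s,p))

  where the WGA mean pools all control molecules at (s, p). With
  single-molecule coverage cov_SM ≥ 15 passes, 6mA is detected with
  sensitivity and specificity above 98% on synthetic data.

- **Agg_SN** — the population-level analogue: all native molecules pooled
  at (s, p) minus the WGA mean (what aggregate pipelines compute).

- **SM_P** (single-molecule, pooled), for phasing long reads: the
  molecule's surviving log IPDs at *all* motif sites on a strand, pooled
  irrespective of position, minus the unweighted mean of the per-site WGA
  means over the same sites. A long read with ≥ 10 motif sites gets a
  reliable per-molecule methylation call even at 1–2 passes.

- The **methylated fraction** of a motif is the weight of the higher-mean
  component of a two-Gaussian mixture fitted to the score distribution by
  EM (methylated 6mA sites centre near SM_SN ≈ 2, non-methylated near 0).

- Molecule-level calls use an **empirical FDR**: the tail ratio of a
  matched negative control (WGA scores for methylated calls; IPD-shuffled
  scores for non-methylated calls) to the native score distribution.

A seeded synthetic generator (`simulate_dataset()`) emulates
molecule/subread structure, fixed per-position context bias shared between
native and WGA twins, alignment errors, and constitutive / phase-variable /
stochastic methylation regimes with a known truth table, so every claim
above is testable without sequencing data.

## Worked example

Estimate the methylated fraction of GATC sites for an MTase that
methylates each site with probability 0.6:

```r
library(smalr)

cfg <- sim_config(seed = 7, reference_length = 20000, n_molecules = 300,
                  motif = motif_spec("GATC", 1), regime = regime_stochastic(0.6))
native <- simulate_dataset(cfg)
wga    <- simulate_dataset(wga_twin(cfg, n_molecules = 300))
native$dataset
#> <kinetics_dataset> native sample on 'synthetic_ref' (20000 bp)
#>   300 molecules, 7860 subreads, 2011651 aligned events (ipd unit: seconds)

obs  <- preprocess(native$dataset)
ctrl <- build_control(preprocess(wga$dataset))

sm  <- smsn_scores(obs, ctrl, native$sites, min_cov = 10)
fit <- fit_two_gaussian_em(sm)
fit
#> <smalr_mixfit> two-component Gaussian mixture, n = 345
#>   low : weight 0.3747, mean  -0.0719, sd 0.4444
#>   high: weight 0.6253, mean   1.9978, sd 0.4404
#>   loglik -426.66 after 20 iterations (converged); BIC prefers 2 component(s)

methylated_fraction(fit)
#> [1] 0.6253445
mean(native$truth$sites$methylated)   # generator truth for comparison
#> [1] 0.5891341
```

The two mixture components sit at scores ≈ 0 (non-methylated) and ≈ 2
(methylated); the high-component weight, 62.5%, estimates the methylated
fraction and agrees with the realised per-site truth of 58.9% to within
sampling error of the 345 scores.

A command-line front end wrapping the same functions ships in
`inst/scripts/smalr`:

```sh
smalr simulate --config sim.yaml --out fixtures/
smalr smsn --native fixtures/native.tsv --wga fixtures/wga.tsv \
      --ref fixtures/reference.fasta --motif GATC:1 --out smsn.tsv
smalr mixture --scores smsn.tsv --out mixturefit.json
```

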