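---
title: "Dosage-based qPCR sex genotyping: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-based qPCR sex genotyping: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zdose)
```

## The dosage model

In a ZZ/Z0 sex-determination system, males carry two copies of every
Z-linked locus and females one, while autosomal loci sit at two copies in
both sexes. Real-time PCR amplifies template exponentially: with
amplification efficiency $E$ (fold increase per cycle minus one), a
reaction crossing the detection threshold at quantification cycle
$C_q^{\mathrm{ref}}$ for one template copy crosses at

$$C_q(c) = C_q^{\mathrm{ref}} - \frac{\ln c}{\ln(1+E)}$$

for $c$ copies. At $E = 1$ (perfect doubling) a 2-fold dosage difference is
exactly one cycle. The within-sample difference

$$\Delta C_q = C_q(\text{autosome}) - C_q(\text{sex target})$$

cancels the (unknown and widely varying) amount of input DNA, because both
assays amplify the same extract. Subtracting a male reference — the median
of the male cluster, or a male standard run in the same batch — yields
$\Delta\Delta C_q$, with expected values $0$ for ZZ and
$-\ln 2 / \ln(1+E_{\text{sex}})$ for Z0; at $E_{\text{sex}} = 1$ that is
exactly $-1$. Classification uses the midpoint threshold $-0.5$.

Assumptions worth keeping in mind: both assays must amplify within the
accepted efficiency window (90–110%, checked by dilution series with
`estimate_efficiency()`); the sex assay must be truly Z-specific (verified
at design time by in-silico PCR and at the bench by melt curves, which this
package represents computationally by the specificity verdict of
`insilico_pcr()`); and the batch must either contain both sexes (so
two-cluster normalization is anchored) or include a male standard.

## The calling procedure and its tunables

1. **Replicate screening** (`summarize_replicates()`): technical replicates
   (default quadruplicates) are screened once against the mean of all
   non-missing raw values; wells deviating by strictly more than
   `outlier_threshold` (default 1 cycle) are discarded, and mean/SEM are
   recomputed on the survivors. The screen is deliberately single-pass and
   deterministic; an iterative screen could cascade on bimodal groups.
   "Undetermined" wells are absent replicates, never the terminal cycle.
   If the screen leaves fewer than two wells, the sample keeps its value
   but is force-flagged `repeat`.
2. **Dosage** (`compute_delta_cq()`): $\Delta C_q$ with a combined SEM
   defined as the arithmetic sum of the two per-assay SEMs — intentionally
   conservative relative to quadrature, and the definition used when the
   assay was validated.
3. **Normalization** (`split_two_clusters()`, `normalize_ddcq()`): the
   exact 1-D two-cluster partition is found by exhaustive search over the
   sorted split points (the optimum of 1-D 2-means is always contiguous,
   so the search is exact, not heuristic); the higher-median cluster is
   male. Ties in within-cluster sum of squares break toward the larger
   inter-cluster gap. When the gap falls below `min_cluster_gap` (default
   0.3 cycles) the batch is flagged unimodal — likely single-sex — and the
   male-standard pathway is recommended instead; this matters because
   cluster-median normalization of an all-female batch would silently
   relabel females as males.
4. **Calling** (`call_sex()`): `male` above the threshold (default
   $-0.5$), `female` below, `repeat` when $|\Delta\Delta C_q + 0.5|$ is
   smaller than the sample's combined SEM or the value sits exactly at the
   threshold (the threshold is *between* the classes, so a value on it
   belongs to neither). Threshold calling happens after cluster-based
   normalization; when the two disagree about a sample the disagreement is
   reported in the run diagnostics rather than silently resolved.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws each replicate as
`expected_cq + sample_offset + N(0, noise_sd)`:

- `noise_sd` (default 0.12 cycles): Gaussian replicate noise on the cycle
  scale, the standard model for Cq residuals. The default was chosen so
  that a realistic cohort lands in the separation regime observed in real
  swab data (male–female median distance near one cycle with a clearly
  open gap between the nearest opposite-sex points); across 20 seeds the
  default 81-animal configuration shows median distances of about
  0.95–1.05 and nearest-point gaps of about 0.56–0.77 cycles.
- `sample_offset_sd` (default 0.5 cycles): a per-sample offset shared by
  both assays, modelling the widely varying DNA yields of non-invasive
  swabs. It cancels exactly in $\Delta C_q$, and the property suite checks
  that.
- `outlier_prob`/`outlier_shift` (default off): occasional gross well
  failures, injected as ±`outlier_shift` cycles, to exercise the outlier
  screen.
- One global seed drives a single stated-order stream, so a plate is fully
  reproducible and the caller's RNG state is untouched.

The simulator does *not* model fluorescence curves, efficiency drift,
PCR inhibitors, plate-position effects, or cross-contamination. Passing
tests on simulated plates therefore demonstrate that the *analysis* is
correct under the dosage model with realistic noise — they do not prove
any particular wet-lab assay works; that evidence must come from dilution
series and blinded validation of the assay itself.

## Primer screening

`design_candidates()` enumerates every primer window within the size
bounds on both strands, filters on hard constraints (GC window, maximum
homopolymer run, 3'-terminal G/C clamp, Tm window), pairs windows whose
product length falls in the product range, and returns the single
lowest-penalty pair per target, where the penalty is the weighted absolute
deviation from the size/Tm/GC optima (defaults 1.0 per °C, 0.5 per %GC,
1.0 per nt). Tie-breaks are deterministic: penalty, then leftmost forward
site, then shortest product. Two presets mirror the parameter sets the
published cephalopod assays were designed with; the `ceph_pipeline` preset
returns one pair per FASTA entry, so 12 autosomal plus 12 Z-linked targets
yield a panel of 24 primer sets.

Melting temperatures use unified nearest-neighbor thermodynamics with the
entropy-based monovalent-salt correction at 50 nM total strand and 50 mM
monovalent cation. Absolute NN Tm depends strongly on the salt model:
under these conditions typical validated primers compute to ~51–54 °C,
roughly 7 °C below the scale on which the presets' 59/60 °C optima were
originally specified (that scale includes a divalent-cation correction).
The preset Tm windows are therefore set at optimum −10/+5 °C on the
package's own scale, and the penalty still pulls designs toward the stated
optimum; ranking between candidate primers is insensitive to the shared
offset. Primer-dimer Tm (`dimer_tm()`) is the nearest-neighbor Tm of the
most stable ungapped complementary segment over all antiparallel
registers, with $-\infty$ as the sentinel when no register pairs at all;
the exact dimer metric of commercial design tools is unpublished, so the
30 °C acceptance bound is applied to this documented metric.

In-silico PCR (`insilico_pcr()`) accepts binding sites with up to 2 total
mismatches but requires the 5 3'-terminal bases (the extension seed) to
match exactly, and pairs opposite-strand sites up to 5,000 nt apart; a
pair is specific when exactly one amplicon is predicted and its length is
inside the constraint product range. These defaults are stated choices
(the corresponding settings of dedicated specificity checkers vary) and
are all adjustable through `pcr_policy()`.

`refine_to_consensus()` ports a primer designed on a reference genome to a
related species by substituting consensus variants under the footprint,
erroring on gaps, keeping the reference base under compatible IUPAC
ambiguity, and warning when a substitution touches the 3' seed.

## Numerical choices

- The exact binomial upper tail is summed term-by-term in log space, which
  is exact to full double precision at every scale this assay produces
  (an 81/81 result gives $p = 0.5^{81} \approx 4 \times 10^{-25}$, far
  above double underflow); no normal approximation is ever used.
- Student's t tests pool variances (the classical test; Welch is available
  via `var_equal = FALSE`). Degenerate zero-variance input returns the
  documented limits ($p = 1$ for equal means, $p = 0$ otherwise) instead
  of an error, so scripted pipelines never crash on constant data.
- Quartiles use linear interpolation between order statistics
  (`type = 7`), whiskers extend to the most extreme points within
  1.5 × IQR.
- Two-cluster ties and designer ties have stated deterministic breaks (see
  above); all randomness in the package lives in the simulator.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on simulated or toy
data chosen at desk scale: cohorts of 8–81 animals with quadruplicate
replicates, dilution series of five points, design targets of 120–420 nt,
and 24-target design panels. These sizes exercise every code path in
seconds while matching the scale at which the assay is actually run.

## Known limitations

- Single-run normalization only: no multi-plate batch-effect correction
  beyond the per-run male reference.
- The designer does not compute hairpin free energies or perform
  genome-scale BLAST screening; specificity is checked by exhaustive
  in-silico PCR over the supplied sequences, which is appropriate for
  contig- or chromosome-scale inputs, not whole mammalian genomes.
- The threshold/cluster interaction is resolved by calling on the
  normalized threshold and reporting disagreements; with pathological
  batches (e.g. exactly one sex plus one outlier) a male standard remains
  the only safe anchor.
- Real replicate noise magnitude and outlier frequency are assay- and
  instrument-specific; the simulator defaults are stated assumptions, and
  conclusions about a new assay should re-estimate them from its own
  replicates.
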