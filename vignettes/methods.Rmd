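---
title: "Calling DNA break-dependent phosphosites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling DNA break-dependent phosphosites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbphos)
```

## The problem

During meiosis, Spo11 introduces programmed DNA double-strand breaks that
activate the sensor kinases Mec1/Tel1 (the ATR/ATM orthologs) and, through
them, the effector kinase Mek1. Comparing phosphoproteomes of a
break-proficient strain (*SPO11*) against a catalytically dead mutant
(*spo11-YF*) isolates the phosphorylation events that depend on break
formation. The statistical difficulty is that label-free phosphoproteomics
data are missing not at random (MNAR): low-abundance signals preferentially
fall below the detection limit. A site that is phosphorylated *only* when
breaks form is therefore not "significantly enriched" — it is simply never
observed in the mutant, and a fold-change test cannot score it at all.

`dsbphos` implements the resulting dual design:

* a **quantitative arm** — parts-per-million (ppm) normalisation, log2
  transform, and an empirical-Bayes moderated two-group test with
  Benjamini–Hochberg (BH) control — for sites observed often enough in
  both conditions; and
* a **qualitative arm** — presence/absence classification — for sites with
  an all-or-nothing detection pattern.

Both arms run separately per acquisition method (DDA and DIA, which
measure the same samples with different physics), and the per-method calls
are merged into one site-level result.

## Data model and preprocessing

A study is a `phospho_set`: an intensities matrix (rows are phosphosites,
phosphopeptides or proteins; columns are samples) with `NA` for missing,
plus row annotations and a design (condition, replicate, method). Report
files use 0 for "not detected"; zeros become `NA` at read time, because
the qualitative arm depends on missingness being preserved and a
log-transform of 0 is meaningless. No imputation happens anywhere, for the
same reason.

Identification-quality filters mirror standard practice: contaminant and
reversed-decoy rows are dropped, and site-level rows must have phosphate
localization probability ≥ 0.9. The threshold is inclusive, matching the
convention of the upstream search tools. Peptide-level (DIA) reports carry
no localization column and pass through unfiltered.

Quantitative preprocessing is deliberately minimal, following the original
analysis: each sample column is scaled so its observed values sum to one
million (`normalize_ppm()`), then log2-transformed. The missingness filter
(`filter_min_detection()`) keeps rows observed in at least 3 of a method's
6 measurements.

DIA quantification arrives at the phosphopeptide level.
`collapse_peptides_to_sites()` locates each peptide in the proteome and
maps within-peptide phospho offsets to protein coordinates; peptides whose
sequence is not unique in their protein cannot be placed and are dropped
with a warning. Several peptides covering one site are summed per sample
over observed values, so a site counts as observed wherever any of its
peptides is. We collapse *before* classification, and record that choice
in the output provenance.

## The quantitative arm

Per row, with group means on the log2 scale, the effect is
$\Delta = \bar{x}_{SPO11} - \bar{x}_{spo11\text{-}YF}$ (positive =
induced by breaks) and $s^2$ the pooled residual variance on
$df = n_1 + n_2 - 2$ degrees of freedom. Variances are shrunk toward a
prior $\sigma^2 \sim s_0^2\, d_0 / \chi^2_{d_0}$, estimated across rows by
method of moments on $\log s^2$ (digamma/trigamma matching, the standard
empirical-Bayes fit; the prior df is capped at $10^6$ when the observed
spread of $\log s^2$ is no larger than its pure sampling component). The
moderated statistic is

$$
s_{post}^2 = \frac{d_0 s_0^2 + df\, s^2}{d_0 + df}, \qquad
t = \frac{\Delta}{s_{post}\sqrt{1/n_1 + 1/n_2}},
$$

with two-sided p-values on $df + d_0$ degrees of freedom. At $d_0 = 0$
this is exactly the ordinary pooled t-test — a limit the test suite pins
down — and the implementation is cross-checked against an independent
moderated-statistics package on complete matrices.

Eligibility: a row needs at least two observed values in each condition.
The study description ("detected in both conditions in at least three of
the six samples") does not fix what happens to, say, a 3 + 0 pattern; we
resolve it as *≥ 3 observed total and ≥ 2 per condition*, so that a
variance exists in both groups, and rows failing this are handed to the
qualitative arm rather than silently dropped. BH families are one per
(method, level): DDA phospho, DIA phospho, protein — the three analyses
are separate experiments. Significance uses adjusted p < 0.1, two-sided
(sidedness is not otherwise specified anywhere; two-sided is the
conservative default), with the fold-change sign deciding
`break_dependent_quant` versus `lost_quant`.

## The qualitative arm

"Present" means a non-zero, non-missing raw intensity; classification runs
on pre-normalisation detection status. A site present in **all** *SPO11*
replicates and absent in **all** *spo11-YF* replicates is
`break_dependent_qual`; the mirror pattern is `lost_qual`; every other
pattern is left unlabelled by this arm. Of the $2^6 = 64$ patterns in a
3 + 3 design, exactly one yields each label — the suite verifies the full
truth table against an independently coded oracle. The arm runs on all
identification-filtered rows, regardless of the ≥3-of-6 filter (a 3 + 0
row fails quantitative eligibility precisely *because* it is the pattern
this arm exists for).

When both arms could speak for a site, the quantitative label wins — it
carries an effect size and a p-value — and the qualitative evidence is
kept in the `qual_label` column. Qualitative labels never carry p-values.

## Merging acquisition methods

`merge_methods()` takes the union keyed by (protein, position, residue).
Provenance is the union of contributing methods. A site called
break-dependent by one method and lost by the other is flagged `conflict`
and excluded from both directional sets; we never silently prefer a
method. When no conflicts occur, the merged break-dependent count obeys
$|A \cup B| = |A| + |B| - |A \cap B|$; with the per-method counts reported
for the original study (158 and 241, 67 shared) this identity yields 332,
which the acceptance suite recomputes by actually merging call sets of
those sizes.

## Sequence features

* **Windows** are stored at flank 7 and sliced to flank 3 for analysis, so
  wider motifs remain reachable without re-extraction; termini are padded
  with `_`, and pads never enter any count.
* **Consensus classes**: S/TQ (centre S/T with Q at +1; Mec1/Tel1),
  RxxS/T (R at −3; Mek1), and the hybrid RxxTQE (centre T, R at −3, Q at
  +1, E at +2), which by construction implies both parents.
* **motif-x** style extraction: per centre residue, greedily fix the
  (position, residue) pair with the smallest binomial upper-tail p-value
  of the foreground count at the background frequency, restrict both sets
  to matches, recurse until nothing clears the per-step cutoff (default
  0.05, the setting used in the original analysis) and the minimum support
  (`max(5, 5%)` of the foreground); emit, remove matches, repeat.
  Tie-breaks are fully deterministic (smaller p, larger count, smaller
  position, residue order). One numerical guard: a residue absent from a
  (possibly already restricted) background would make every foreground
  count "infinitely" significant, so its frequency is floored at
  $1/(n_{bg}+1)$. With small backgrounds and the 0.05 per-step cutoff the
  greedy scheme *will* fix occasional spurious positions — that is
  inherent to motif-x, whose classic default cutoff is $10^{-6}$; use
  ample backgrounds, or a stricter cutoff, for sparse data.
* **Tryptic detectability**: cleavage after K/R, suppressed before P, zero
  missed cleavages; peptides shorter than 6 residues are flagged
  `too_small`, longer than 40 `large`. This reproduces the two canonical
  blind spots of the break-response phosphoproteome: on the mature
  (initiator-Met-removed) histone H3 tail, T11 sits on the 5-mer `STGGK`;
  and a Hop1-T318-like site sits on a 49-residue peptide. Numbering always
  follows the supplied sequence — for histone-style mature numbering the
  caller supplies the mature sequence; the tool never adjusts coordinates
  itself. The shipped Hop1 sequence is a labelled synthetic stand-in
  (`synthetic_hop1_standin()`) that reproduces the tryptic architecture
  around position 318; it is not the database sequence.
* **Proximity**: a site counts if another break-dependent site lies within
  5 residues (inclusive) on the same protein. **Disorder overlap** counts
  sites inside supplied disorder intervals *strictly longer than* 30
  residues (1-based closed coordinates — a deliberate divergence from
  genomic BED, documented in `read_disorder()`).

## The protein-level bootstrap set-shift test

For a query set of proteins, the observed statistic is the median log2
fold change (mean available by option). `B = 1000` draws sample an
equal-sized set *without replacement* from all quantified proteins; the
set is called shifted when the observed median falls outside the central
95% of the draws. Calibration is checked empirically: over 400 null query
sets the false-positive rate stays within two standard errors of 5%, and
a planted 0.5-log2 shift in a 50-protein set is detected.

## The synthetic-study generator

`truth_config()` defines the study the tests and the acceptance script
run. The defaults are frozen as the package's reference conditions:

| parameter | default | meaning |
|---|---|---|
| sites | 2,000 | 100 fully dependent, 100 induced, 25 lost (structural), 25 lost (quantitative), 1,750 constitutive |
| `delta` | 1.5 | condition effect, log2 units |
| `mu0`, `sigma_b` | 20, 1.2 | per-site base abundance (log2 raw) and spread |
| `sigma_e` | 0.4 | replicate noise (log2) |
| dropout | midpoint 17.5 (DDA) / 17.0 (DIA), slope 0.8 | logistic detection curve on latent log2 intensity |
| planting | 0.155 (Q at +1), 0.247 (R at −3, 80% with T centre) | consensus-context planting on break-dependent sites |

The abundance and noise scales are typical of label-free log2 intensity
data (roughly 2-fold replicate scatter, ~2.5 orders of magnitude dynamic
range across sites); a 1.5-log2 condition effect is a clearly real but not
extreme response; and the dropout midpoints sit ~2–2.5 SD below the mean
abundance so that missingness is common at the low end (and the DIA
channel is modestly more complete than DDA), which is what makes the
qualitative arm non-trivial. The planting rates are set so that, after
adding chance occurrences at background residue frequencies, about 19% of
break-dependent sites carry an S/TQ context and about 28% an RxxS/T
context — the proportions characteristic of the meiotic break response.

Two modelling choices matter:

* **Structural zeros versus dropout.** Fully break-dependent sites carry
  *no* signal in *spo11-YF* — the biology forbids the phosphorylation,
  rather than the instrument missing it. This is what makes the
  presence/absence arm identifiable; quantitative-only dependence arises
  from the logistic dropout instead.
* **MNAR as a smooth curve.** Dropout is a logistic function of latent
  intensity, not a hard threshold (the threshold is the slope → 0 limit),
  so "qualitative-only" and "quantitative" dependent sites both arise
  naturally at intermediate abundances.

Site placement enforces a minimum same-protein spacing of 8 residues so
planted contexts can never rewrite a neighbouring site's acceptor or
window. DIA rows are the 0-missed tryptic peptides covering each site,
exercising the collapse path end to end. Raw intensities are emitted at 6
significant digits (ordinary export precision), which also makes the
write-then-read round-trip exact. Generators are deterministic given a
seed, with one stream per emitted table.

What the generator does *not* emulate — and hence what green tests do not
prove about real data: co-eluting isobaric peptides and localization
ambiguity (localization probabilities are drawn, not modelled), shared
peptides between proteins, missed cleavages and semi-tryptic forms,
intensity-dependent variance trends, batch structure, and the compositional
background of a real proteome (e.g. the ~17% background RxxS/T frequency
of real phosphoproteomes has no counterpart in i.i.d.-residue proteins).

## Numerical notes and degenerate inputs

* All-missing sample columns survive ppm normalisation as all-missing,
  with a warning; a zero intensity reaching the log step is an error
  (it means the read-time missingness decision was skipped).
* If fewer than two rows have positive variance, the prior cannot be
  estimated; the moderated test then falls back to the ordinary t
  ($d_0 = 0$). With zero residual *and* prior variance the verdict is
  exact: $t = 0$ for a zero difference, $\pm\infty$ otherwise.
* At `sigma_e = 0` the total-sum scaling itself becomes the only source
  of between-condition difference: induced sites inflate the *SPO11*
  column totals, so after ppm every constitutive site shows the same
  small negative offset with zero variance — "infinitely significant".
  The exact-recovery property of the noiseless limit therefore holds for
  the quantitative arm on the latent log2 intensities, and the test suite
  states it that way; with realistic noise the offset is far inside one
  residual SD and the null-calibration checks cover the normalised path.
* Percentages intended for comparison with "approximately" figures are
  conventionally rounded half away from zero to whole percent.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run: five default studies
(2,000 sites each) for recovery; 2,000-row null tables for calibration;
1,000 random p-vectors for the BH oracle; 50 small seeded instances for
the motif-x greedy-versus-exhaustive oracle; 400 × 1,000-draw bootstraps
for set-shift calibration; and the 64-pattern truth table. These sizes
give stable estimates (binomial SEs of a few percent or less) at a few
minutes of total compute.

## Known limitations

Localization re-scoring, match-between-runs emulation, imputation,
multi-factor designs, moderated F-tests, intensity-dependent variance
trends and protein inference are out of scope. Motif extraction reports
fixed-position motifs only (no degenerate residue classes such as
\[DE\]). Disorder intervals are consumed, never predicted. The merge
assumes site coordinates are comparable across methods, i.e. both reports
were searched against the same protein database.
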