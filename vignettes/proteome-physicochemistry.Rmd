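---
title: "Physicochemical proteome profiling and virtual 2D maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physicochemical proteome profiling and virtual 2D maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteomap)
library(dplyr)
```

proteomap computes, for every protein in a multi-FASTA proteome, the three
bulk physicochemical quantities that proteome-scale comparative studies rest
on — amino-acid composition, average molecular weight (MW), and isoelectric
point (pI) — and reduces them to group-level summaries, correlation and
principal-component structure, and virtual two-dimensional (pI × MW)
proteome maps with a formal modality call. This vignette explains the models
behind each stage, the parameters that matter, and the design decisions that
were genuinely open.

## The charge model and the isoelectric point

The pI is the pH at which a protein's net charge vanishes. We model the
charge with Henderson–Hasselbalch protonation of the ionizable groups: the
N-terminus and the side chains of His, Lys, Arg are basic; the C-terminus
and the side chains of Asp, Glu, Cys, Tyr are acidic. At pH $x$, with
$n_g$ copies of group $g$ and acid-dissociation constant $\mathrm{p}K_g$,

$$
Q(x) \;=\; \sum_{g \in \text{basic}} \frac{n_g}{1 + 10^{\,x - \mathrm{p}K_g}}
\;-\; \sum_{g \in \text{acidic}} \frac{n_g}{1 + 10^{\,\mathrm{p}K_g - x}} .
$$

$Q$ is continuous and strictly decreasing, positive at pH 0 and negative at
pH 14 (the C-terminus is always present), so a unique root exists in
$[0, 14]$. `isoelectric_point()` brackets it by bisection to a tolerance of
`tol` pH units (default $10^{-3}$; ~14 iterations), which is far below the
reproducibility of any experimental pI. The test suite checks the bisection
root against an exhaustive $10^{-4}$-step grid search of $Q$ on hundreds of
random peptides for every registered pKa set.

Different laboratories have published different pKa constants, and the pI
of the same sequence can differ by more than half a pH unit between sets.
The registry ships four named sets — `ipc_protein` (default), `ipc_peptide`
(both from Kozlowski's IPC calculator work), `emboss`, and `sillero` — and
every user-facing function accepts a `pka_set` argument. `ipc_protein` is
the default because it was optimized for full-length proteins, which is
what proteome-scale FASTA inputs contain. Cysteine is treated as free and
ionizable (no disulfide modelling), the convention of bulk-proteome
calculators.

Molecular weight is the sum of *average* (not monoisotopic) residue masses
from the Expasy reference table plus one water — again the bulk-proteome
convention; isotope-resolved masses are meaningless at proteome scale.

## Ambiguity codes

Predicted proteomes contain ambiguity codes. The reader accepts
X, B, Z, U, O, J and exposes two policies: `"flag"` (default) keeps the
record and counts the codes, `"strict"` rejects it. The default keeps
records because group summaries should be totals over all predicted
sequences, not over the subset that happens to be cleanly annotated; the
strict path exists because the filtering choice is a genuine judgment call
and both must be reproducible. Under `"flag"`:

* composition fractions are taken over canonical residues only (the 20
  fractions always sum to 1);
* MW assigns each code a documented mass: B = mean(N, D), Z = mean(Q, E),
  J = mean(I, L), U the mass of C, O the mass of K, X the mean of all 20;
* the charge model ignores them (no ionizable groups), which biases pI by
  at most the handful of codes a real record carries.

A terminal `*` is stripped (a stop-codon translation artifact); an internal
`*` is rejected as a broken gene model. Digits, gaps, and other
non-alphabet characters are always errors.

## Aggregation choices

Host-group summaries are unweighted arithmetic means **over proteins**, not
over proteomes, and the pooled kingdom summary likewise weights every
protein equally — so a host contributing ten times as many proteins
contributes ten times the weight. This matches how a collective
"amino acids per protein" average is normally quoted, and the alternative
(mean of host means) is recoverable from the per-host table.

The acidic/neutral/basic partition calls a protein *neutral* when
$|\mathrm{pI} - 7| \le$ `neutral_tol`, default 0.005 — i.e. the pI prints
as 7.00. Bulk proteomes have almost no exactly-neutral proteins
(neutral fractions are typically well below 1%), so the window must be
narrow to be informative; it is a parameter because no standard width
exists. Extreme records (longest, shortest, highest/lowest pI) resolve ties
by input order, keeping reports deterministic.

## Correlation and PCA of composition

The host × residue matrix of mean composition percentages feeds two
Pearson analyses: host-by-host correlation of the 20-element composition
rows, and residue-by-residue correlation of the across-host abundance
vectors. `tidy()` attaches Fisher-z confidence intervals (the interval
method is our choice; n is small, so the intervals are wide and should be
read as rough guides).

PCA is implemented as NIPALS — sequential power-iteration extraction with
deflation, `max_iter` 100 and a convergence tolerance of $10^{-8}$ on the
relative score change — because that is the algorithm comparative
proteome-composition studies typically run. NIPALS on a complete matrix is
mathematically ordinary PCA, so the tests hold it to an exact
eigendecomposition oracle (explained variance within $10^{-6}$, loadings
equal up to sign); the sign is fixed by making each component's
largest-magnitude loading positive. The matrix is column-centered and
deliberately **unscaled**: the columns are already commensurate
(percentages of the same whole), and unit-variance scaling would inflate
the influence of rare residues such as Trp and Cys.

## The virtual 2D map and modality

`build_map()` bins proteins on pI ∈ [2, 14] × log10 MW ∈ [2.5, 6.5]
(roughly 0.3 kDa to 3000 kDa; values outside are clamped into edge bins
with a message). MW is analysed on the log10 scale throughout: protein
masses span more than three orders of magnitude, so a linear-scale density
is dominated by a single spike.

The unimodal/bimodal/trimodal character of a proteome is classically read
off such maps by eye. `classify_modality()` makes the call reproducible:

1. Gaussian KDE of the pI marginal on a 512-point grid over pH 2–14, with
   bandwidth = `bandwidth_factor` × Silverman's rule of thumb (default
   factor 1.0);
2. the same for the log10-MW marginal (grid spanning the data ± 3
   bandwidths);
3. count local maxima whose **topographic prominence** — height above the
   highest saddle connecting the peak to taller terrain — is at least
   `prominence_frac` of the density maximum (default 0.05, i.e. ripples
   below 5% of the main peak are ignored).

The headline label follows the pI mode count; the MW count is reported
alongside, never merged, because the two marginals can legitimately
disagree. Both parameters are exposed (and echoed into every result)
because the visual judgment they replace has no canonical values; the
defaults were chosen so that clearly separated mixture components are
counted and sub-5% ripples are not, and the peak-counting logic is tested
against a brute-force prominence oracle on random mixture densities.
Inputs with fewer than `min_n = 50` profiles are refused with an explicit
`insufficient` signal rather than classified noisily; a degenerate input
(all values identical) counts as one mode. No statistical test of
multimodality (dip test, mixture BIC) is attempted — the classifier
formalises the density-reading, nothing more.

## The synthetic generator

Real proteome-scale inputs are too large to ship, so `sample_proteome()`
generates ground-truth proteomes: each record picks a mixture component by
weight, draws a length from a discretised log-normal (truncated at 5
residues), and samples residues i.i.d. from the component's frequency
vector. Residues are i.i.d. because every downstream statistic here depends
only on composition, length, MW and pI — sequence order is irrelevant, so
positional structure would add cost without adding test power. Lengths are
log-normal because protein-length distributions are strongly right-skewed.
The generic default (`length_log_mean` 5.551, `length_log_sd` 0.9) gives a
mean length of about 386 residues, a realistic proteome-scale average.

Seeding is per record: record $i$'s stream derives from the master seed by
a counter, so the same spec is byte-identical across runs and growing a
proteome never changes earlier records.

Three residue-frequency presets provide charge modes. `acidic_profile()`
raises Asp/Glu and lowers Lys/Arg/His so sampled proteins land near pI 4.6
(sd ≈ 0.5 at archetype lengths); `basic_profile()` mirrors this toward pI
≈ 10.6 (sd ≈ 0.6). `neutral_profile()` balances acidic and basic residues
*and* enriches cysteine to 15%: the thiol's pKa (7.6 in the default set)
buffers the charge curve near neutrality, which steepens the root and
keeps the mid mode tight (pI ≈ 7.0, sd ≈ 0.42) — without that buffering
the neutral zone is flat and the mode smears. The Cys level is admittedly
unrealistic for natural proteins; the preset is engineered for a
well-separated mid mode, not biological verisimilitude.

`host_archetype()` assembles 1, 2 or 3 of these presets with near-equal
weights and a tighter length distribution (log-sd 0.40 around a median of
~350 residues), giving component pI means separated by at least 4 empirical
standard deviations. The end-to-end recovery property — the classifier
returns k modes for the k-component archetype in at least 95% of seeded
runs at n = 2000 — is asserted in the test suite over 20 seeds per k.

What the generator does **not** emulate: real host-specific composition
signatures, length–composition dependence, phylogenetic correlation
between proteins, ambiguity codes, and the heavy tail of giant
polyproteins. Passing tests therefore demonstrate that the pipeline's
machinery is correct and its detection thresholds behave as documented on
data with known structure — not that any particular biological host group
is uni-, bi- or trimodal.

## Numerical and degenerate-input choices

* Bisection bracket fixed at [0, 14]; reported pI rounds to 3 decimals in
  outputs.
* KDE of identical values raises a degenerate-distribution condition,
  treated downstream as one mode.
* Exact plateaus in a density (possible with symmetric grids) are collapsed
  by run-length before peak finding; the middle index represents the run.
* Correlation of a constant vector is refused, not returned as NA.
* NIPALS on a numerically rank-deficient residual stops early with a
  warning; requesting more than `min(rows − 1, cols)` components is an
  error.
* All TSV/JSON outputs are written deterministically; every report
  directory contains the effective configuration and an md5 manifest, and
  the full synth → profile → report pipeline is byte-identical for a fixed
  seed.

## Problem sizes

The shipped tests profile synthetic proteomes of 80–2000 proteins (mean
length ≈ 350 residues), check the pI oracle on 200 random peptides of
length 1–500 per pKa set, and run the modality-recovery sweep at 20 seeds ×
3 archetypes × 2000 proteins; the whole suite completes in about a minute
on one core. These sizes were chosen because every asserted property is
already stable at them: recovery rates and oracle deviations do not change
at 10× the data, only the runtime does.

## A worked miniature

```{r example, message = FALSE}
dir <- tempfile()
run_synth("bimodal", n_proteins = 300, seed = 1, out_dir = dir)
profiles <- run_profile(file.path(dir, "bimodal_manifest.tsv"))
summarize_kingdom(profiles)
classify_modality(profiles)
```

## Known limitations

The charge model ignores folding, post-translational modification and
local electrostatic environment, so computed pI is the usual denatured
estimate. MW ignores modification mass. The modality call depends on
bandwidth and prominence parameters that have no canonical values; results
should be quoted with the parameters, which every `ModalityResult` and
report JSON therefore carries. Host-level biology (which real host groups
show which modality) is outside what synthetic validation can establish.
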