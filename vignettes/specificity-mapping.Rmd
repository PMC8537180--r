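---
title: "Methods: correlated mutations, fingerprint motifs and kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlated mutations, fingerprint motifs and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevomotif)
```

# The problem and the model

Enzyme families like glycoside hydrolase family 65 (GH65) pool many
substrate specificities — maltose, trehalose, kojibiose and nigerose
phosphorylases, trehalases, and several rarer activities — inside one fold,
and whole-sequence similarity does not separate them. The working model of
this package is that specificity is encoded at a small number of alignment
positions that behave like switches: within a subfamily of one specificity
they are (nearly) invariant, and across subfamily boundaries they change
*together*. Such positions show up as strongly correlated column pairs in a
correlated-mutations analysis (CMA) of the family alignment, and the
residue combination a subfamily carries at them — its *fingerprint motif* —
acts as a compact specificity label (e.g. `KV[MF]NES` for maltose
phosphorylases versus `EEAPxx` for kojibiose phosphorylases).

The pipeline stages and their contracts:

curation → column-pair correlation → network and position selection →
per-subgroup motifs → classification and mechanism call → tree annotation,
with Michaelis–Menten fitting as the downstream biochemical confirmation
step.

# The correlation statistic

The service originally used for family-scale CMA does not publish its
statistic, so the package defines one with the same operational properties
(symmetric, bounded in [0, 1], comparable across pairs):

$$\mathrm{NMI}(i,j) = \frac{MI(i,j)}{\min(H(i), H(j))}$$

where entropies and mutual information are computed in bits from
*weighted* residue counts. Weights are Henikoff position-based weights, so
clusters of near-identical sequences do not dominate the counts. Rows
carrying a gap or `X` at either column are dropped for that pair
(pairwise-complete).

Numerical guards, all exposed as arguments:

* `min_pairs = 20` — a pair is masked (`NA`) when fewer than 20 rows remain
  after gap removal; plug-in mutual information is strongly biased upward
  at low counts.
* `h_min = 0.1` bits — a pair is masked when either column is nearly
  invariant; the normalisation divides by the smaller entropy, so
  near-zero-entropy columns would otherwise produce unstable scores.
* Scores are clamped to [0, 1] against floating-point drift.

No average-product correction is applied: the documented thresholds (0.8
for an edge, 0.9 for a "strong" score) refer to the raw normalised score,
and an APC-corrected variant would silently change their meaning. The
statistic is invariant under row permutation and under bijective residue
relabeling of any single column (both are asserted over random instances in
the test-suite).

**Selection rule.** A position becomes a specificity-determining candidate
iff its best score over all pairs exceeds 0.9 *and* it has at least two
partners scoring at or above 0.8. Output is ordered by ascending reference
number, which also breaks ties deterministically.

**Numbering.** All user-facing positions use the residue numbering of a
designated reference sequence (for GH65, the kojibiose phosphorylase of
*Caldicellulosiruptor saccharolyticus* is the conventional anchor); the
k-th non-gap residue of the reference row numbers its column k.

# Curation rules

* **Redundancy** — greedy longest-first clustering; a sequence joins the
  first representative with identity above the threshold (default 0.90).
  Identity is matches in a global alignment divided by the shorter
  sequence's length, with fixed match = 1 / mismatch = 0 / linear gap −1
  scoring, so results are bit-stable. There is no k-mer prefilter: the
  comparison is exact and quadratic, intended for curated desk-scale sets
  (≤ a few thousand sequences); `run_pipeline()` therefore keeps this stage
  behind an opt-in flag. A keep-list re-adds annotated representatives that
  clustering would discard.
* **Catalytic acid** — rows whose residue at a user-supplied catalytic
  column is outside `{D, E}` are removed. The default treats gaps, `X` and
  any non-acidic residue as "lacking" the catalytic acid; passing a wider
  `allowed_residues` set recovers the laxer gap-only reading. The column is
  user-supplied because the catalytic position is family-specific.
* **Gap columns** — a column is dropped iff its gap fraction is ≥ the
  threshold (default 0.95); `X` counts as a residue, not a gap
  (conservative reading of "gap content"). The operation is idempotent.
  Correlation analysis always runs on the trimmed alignment: trimming only
  removes columns that could not have produced unmasked scores, and
  numbering is re-derived afterwards, so this choice is safe and makes runs
  reproducible from one canonical alignment.

The pipeline applies the stages in the fixed order redundancy → catalytic
filter → trim.

# Fingerprints and classification

Per subgroup and selected position the package reports weighted residue
frequencies (gaps/`X` excluded from the normalisation), information content
`log2(20) − H` (Schneider–Stephens, no small-sample correction, hence in
[0, log2 20] ≈ [0, 4.32] bits), and a consensus token:

* single residue when the top frequency ≥ 0.5 and leads the runner-up by
  ≥ 0.2;
* `[AB]` when the top two frequencies are each ≥ 0.2 and jointly ≥ 0.7;
* `x` otherwise.

These thresholds are not published anywhere; they are this package's
defaults, chosen once so that fixture subgroups built from the printed
family motifs reproduce those motifs, and they are arguments, not
constants. Frequency ties inside a bracket are broken by the conventional
substitution-matrix residue order (`ARNDCQEGHILKMFPSTWYV`), which is what
puts `M` before `F` in `KV[MF]NES` when both occur at exactly 50 %.

Classification scores a query's residues against each reference motif as
matched positions / informative positions, where `x` matches everything
but is excluded from the denominator — `EEAPxx` is a four-position
constraint. Ties and sub-threshold best scores (default 0.8) return
`unknown`; all-wildcard motifs are masked. The packaged reference table
contains only motifs that are established in the literature text (MP, KP,
TP, oligoNP, T6PP, plus the single-sequence motif of uncharacterised
subgroup 7); no motifs were invented for the other subgroups.

The mechanism call (phosphorylase / hydrolase / undetermined) inspects
residues at phosphate-binding columns. The package ships **no default
sites** — they are structure-derived, family-specific assumptions — and
instead installs an editable example configuration
(`extdata/phosphate_sites_example.yaml`). A gap at any configured site
yields `undetermined` rather than a guess.

Two related numbering caveats are deliberately left to the user: reconciling
the selected position 416 with the neighbouring threonine of the WET motif
reported under a different numbering, and converting positions quoted in
other species' numbering — both are representable but no automatic
conversion is attempted. Dotted subgroup labels (`10.1`) are passed through
verbatim; the package does not define sub-subgroup criteria.

# Tree annotation

`assign_subgroups()` is a reconstruction aid for what is, in expert hands,
a manual task. It walks the tree from the root down and accepts the largest
clades in which at least `homogeneity` (default 0.9) of the leaves share an
identical residue string over the selected positions, with at least
`min_clade_size` (default 5) leaves. Top-down traversal is the only order
consistent with the intended behaviour: on a clean two-subfamily tree it
returns exactly two subgroups, whereas a smallest-clades-first order would
shatter every homogeneous clade into minimum-size fragments. Note that
raising `homogeneity` does *not* monotonically increase the subgroup count:
stricter floors admit smaller clades, and clades below `min_clade_size`
are dropped entirely (leaves fall into the unassigned subgroup `"0"`).
User-supplied partition tables always take precedence.

Ring export writes one iTOL COLORSTRIP file per selected position
(ascending reference number = inner to outer ring), colored by the packaged
RasMol amino-acid table; gaps are white, `X` grey. Files are byte-stable
for identical inputs and round-trip through `read_itol_ring()`.

# Kinetics

`fit_michaelis_menten()` performs unweighted non-linear least squares of
`v = Vmax·S/(KM+S)` (the convention of the usual desktop fitting tools),
started from a Hanes–Woolf linearisation `S/v = S/Vmax + KM/Vmax` and
solved with Levenberg–Marquardt under positivity bounds. Unweighted is the
default because the simulated noise model (and typical initial-rate data)
is close to homoscedastic on the measured scale; weighting is a matter of
changing the residual definition and is intentionally not hidden behind the
interface. A KM estimate that collapses onto its lower bound (saturating-
only designs) raises an error instead of returning a meaningless number.

Units are fixed and documented: rates as specific activity in U/mg with
1 U = 1 µmol/min, concentrations in mM, so
`kcat [s⁻¹] = Vmax [U/mg] · MW [kDa] / 60` and efficiency `kcat/KM` in
mM⁻¹ s⁻¹. The efficiency is reported both raw and rounded to two
significant figures, since the rounded value (13 mM⁻¹ s⁻¹ for
kcat = 9.9 s⁻¹, KM = 0.77 mM, where the raw ratio is 12.86) is the
conventional quoting style. pH/temperature profile modelling is out of
scope; the simulator only produces initial-rate data.

# The synthetic family generator

`generate_family()` realises the statistical structure the selection rule
assumes. Each planted group of columns shares a partition of the
subgroups into residue classes; a sequence shows its subgroup's class
residue with probability `coupling`, otherwise a uniform random residue,
and every planted residue is then flipped to a random other residue with
probability `epsilon`. Unplanted columns are i.i.d. draws from a shared
background profile (a database-average amino-acid composition by default),
independent of subgroup. The accompanying tree is a star of ladders, one
clade per subgroup, and the ground truth travels with every serialised
dataset as a JSON sidecar.

The shipped GH65-analog specification (`gh65_analog_spec()`,
`extdata/gh65_analog.yaml`) uses 22 subgroups × 50 sequences × 600 columns
at `epsilon = 0.02` with 24 planted positions:

* the strong six (64, 392, 394, 402, 416, 585 in the gap-free reference's
  numbering) share an 11-class "pairs" partition at coupling 1.0 — their
  pairwise scores land near 0.94;
* fifteen catalytic-domain positions share the same partition at coupling
  0.93 — their scores against the strong six land mid-band between 0.8 and
  0.9, giving the hub its 20 partners while keeping them below the strong
  threshold;
* the loop trio 56/62/63 shares a shifted pairing of its own at coupling
  0.97 — mutually in-band, cross-partition scores well below 0.8.

The couplings were calibrated once, from the closed-form behaviour of the
statistic under the noise model, so that the score bands straddle the
conventional 0.8/0.9 thresholds under exactly the stated family
dimensions; they are part of the shipped study conditions, not tuning
knobs. The acceptance script recomputes the resulting network counts from
scratch at any seed.

What the generator does **not** emulate: phylogenetic autocorrelation in
background columns (subgroup-independent i.i.d. draws mean background
pairs carry no confounded tree signal, which flatters any correlation
statistic), indel structure beyond uniform random gaps, substitution-model
evolution along branches, and between-subgroup sequence divergence outside
the planted columns. Consequently, passing the analog recovery tests shows
that the statistic, thresholds and bookkeeping behave as specified under
the planted model — not that the thresholds transfer to a real family
alignment, where phylogenetic confounding typically inflates
between-clade correlations. A tree-aware background mode is the natural
extension point. A further deliberate artefact: because the planted
partition groups the 22 subgroups into 11 residue classes, paired
subgroups share identical fingerprint motifs in the analog, unlike the
distinct per-subgroup logos of a real family.

Problem sizes in the test-suite were chosen to keep the default run fast
while leaving the statistics well-conditioned: the full analog (1100 × 600)
is exercised once end-to-end; property suites run on 8–30-row toys with
100 random instances per invariance; kinetics recovery uses 200 simulated
triplicate experiments at 3 % noise. The complete suite runs in about half
a minute on one CPU.

# Known limitations

* The correlation statistic is one defensible choice among several; scores
  are comparable within a run, but absolute thresholds are
  statistic-specific. The matrix interface would accept a drop-in
  replacement statistic.
* Whole-family counts from any particular real alignment (sequence counts
  after curation, numbers of correlated positions) depend on the database
  snapshot and alignment pipeline, which are outside this package's scope;
  the package consumes prebuilt alignments and trees and never builds them.
* `assign_subgroups()` reconstructs clade-level homogeneity, not expert
  judgment; it will merge adjacent subfamilies whose fingerprints coincide
  and fragment clades whose signatures are noisy.
* Mutual information needs tens of effective sequences per subgroup;
  single-sequence branches (like the analog of subgroup 7) can only be
  described by their literal residue string, never by a logo.
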