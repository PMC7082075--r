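---
title: "Methods: topology-restricted SBM discovery, enrichment, and isotherm fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topology-restricted SBM discovery, enrichment, and isotherm fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmhunt)
```

This vignette records the models and procedures `sbmhunt` implements, the
parameters that matter and why their defaults are what they are, the design
choices made where the design was genuinely open, and the limits of what the
synthetic benchmarks demonstrate.

## The motif grammar

The SNX-BAR-binding motif is bipartite: an N-terminal hydrophobic element and
a C-terminal ΦXΦ anchor separated by a flexible linker. Two patterns are
scanned over each search region:

* Type I: `[ILMV] X [FY] X [RK]`, a linker of 2–13 residues, then `Φ X Φ`;
* Type II: `[FYW] X [FY]`, a linker of 3–15 residues, then `Φ X Φ`.

The residue classes are configurable (`residue_classes()`). The hydrophobic
class Φ defaults to {F, I, L, M, V, W, Y}: this covers every anchor validated
experimentally for this motif family (W·M in CI-MPR, L·I in SEMA4C, V·L in
TRAILR1, and the Y·L look-alike in DMT1-II) while excluding the weakly
hydrophobic A/G/C and H, which keeps the chance-match rate manageable on
proteome-scale input. `X` in a sequence (unknown residue) matches *nothing*,
including the pattern's "any" positions: an unobserved residue cannot be
asserted hydrophobic, basic, or anything else.

Key residues are reported under the field's fixed position names — the first
N-element residue is position 1, the anchor occupies positions 21–23 —
regardless of the actual linker length. These are names, not coordinates;
absolute residue numbers are always reported alongside.

### Enumeration and canonicalization

`enumerate_matches()` returns **every** `(start, linker length)` combination
satisfying the grammar, overlapping ones included. Raw matches sharing an
identical anchor interval describe one binding site, so `canonical_sbms()`
collapses each anchor group to a single representative, preferring Type I
over Type II, then the linker length closest to 5 residues (the loop length
with the highest measured affinity in the deletion series that probed it;
ties break toward the shorter linker), then the smallest N-element start. The
preference affects only which representative is *reported* — never the
match/no-match decision or a protein's SBM count, which is the number of
distinct anchors. Proteins may legitimately carry more than one SBM, and the
pipeline reports all of them.

Whether one protein may contribute overlapping Type I and Type II instances
at the same anchor was an open point; canonicalization resolves it explicitly
as one instance.

## Search-space restriction

Only transmembrane proteins annotated to the plasma membrane, endosome,
Golgi, or lysosome are scanned (`sbm_locations()`, case-insensitive,
configurable). Topology is taken at face value from the annotations:
membrane sides alternate across successive TM segments starting from the
annotated side of the N-terminus, and the search region is the unique
cytoplasmic segment of a single-pass protein or the greatest-start
cytoplasmic segment of a multipass protein. "Last cytoplasmic region" is read
as the segment with the greatest start coordinate — including a C-terminal
tail when topology places it inside — because the motif's validated carriers
are searched in their C-terminal cytoplasmic tails. Single-pass proteins
whose only cytoplasmic segment is N-terminal (type II membrane topology) are
searched in that segment: the annotations decide, not a special case.
Proteins with no cytoplasmic segment are skipped. Re-entrant loops, signal
peptides, GPI anchors, and tail-anchored special cases are not modeled.

For un-annotated input a fallback caller (`hydropathy_tm()`) provides TM
segments from sliding-window Kyte–Doolittle hydropathy: window 19 residues,
centre threshold 1.6, minimum segment length 15 — standard hydropathy-plot
practice for helical TM detection. When orientation is also missing,
`guess_n_term_side()` uses the mean hydropathy sign of the 10 N-terminal
residues and flags the result as a guess.

## Filter rules

Three secondary-structure rules plus a domain rule gate every canonical
instance. Each structure rule is *existential over prediction sources*: it
passes if at least one source satisfies it, and the verdict records which
sources did. The wording of the underlying procedure ties "at least one
prediction tool" explicitly only to the strand rule; applying existential
semantics uniformly is this package's recorded choice, and different rules
may be satisfied by different sources.

1. **β-strand** — the first three N-element residues all labeled `E` by a
   single source. Strict 3-of-3 is used; whether 2-of-3 was ever tolerated is
   unknowable from the published procedure, and strictness is the
   conservative reading.
2. **Upstream coil** — at least one `C` among the up-to-8 residues
   immediately before the N-element. The window stops at the search-region
   start inside the pipeline (the procedure searches cytoplasmic regions
   only; residues upstream of the region are membrane or lumenal and their
   predicted states are not evidence about the tail). An *empty* window — a
   motif at the region boundary — fails: absence of evidence for a coil is
   treated as failure, and the verdict makes this visible so users can relax
   it deliberately.
3. **Linker coil** — at least one `C` strictly between the N-element and the
   anchor.
4. **Domain exclusion** — the span from N-element start to anchor end must
   not overlap any annotated folded-domain interval by even one residue
   (adjacency is not overlap).

Rules filter *motifs*, not representatives: when an anchor's canonical
representative fails the structure rules but another raw match of the same
anchor passes all of them (and the domain rule), that raw match is reported
and the anchor passes.

Two monotonicity properties follow from this design and are enforced by
tests: adding a prediction source can only turn verdicts false→true, and
removing domain annotations never shrinks the pass set.

## The structure predictor

The built-in predictor is a GOR-family, information-theoretic *singlet*
model: for each state `S ∈ {H, E, C}`, residue `R`, and window offset
`m ∈ [-8, 8]` it stores

```
info(S, R, m) = log((c(S,R,m) + a) / (c(¬S,R,m) + a))
              + log((c(¬S) + a) / (c(S) + a))
```

with additive smoothing `a > 0` (default 1; a zero pseudocount is rejected —
unseen combinations must not produce infinities). A singlet model rather than
pair statistics is deliberate: the published parameter tables of the original
pair-statistics predictors are not reproducible here, and the filter rules
need only a plausible, controllable {H,E,C} source. Externally computed
predictions are first-class substitutes via `read_ss_predictions()`.

Prediction scores each position as the state's **prior log-odds plus** the
summed `info` values over in-range offsets. The prior term is added once and
deliberately: inside `info` the state-count term cancels across the
likelihood ratio, so the windowed sum alone is a pure likelihood ratio
against the state's complement; without the prior, prediction on
residue-independent labels would be uniform over the three states instead of
collapsing to the majority state. Adding the prior once is the Bayes decision
for this model, leaves strong-signal behavior untouched (a deterministic
residue→state rule is still recovered at ≥ 99% Q3), and gives the correct
null calibration (Q3 → majority-state frequency on signal-free labels).
Score ties resolve to `C` — coil is the unopinionated state: it fails the
strand rule and satisfies the coil rules, making ties conservative for
rule 1. Non-canonical residues contribute zero to every state's score.
Window half-width 8 (default) spans the 17-residue context classical for
this model family.

Training is deterministic: identical data and parameters give bit-identical
tables, which serialize to a versioned TSV (`write_info_table()`).

## Enrichment statistics

For a hit set against an annotated universe, only proteins carrying at least
one GO term enter the counts: `N` (annotated universe), `n` (universe
proteins with the term), `M` (annotated hits), `m` (hits with the term). The
enrichment ratio is `(m/M)/(n/N)`; it is reported as not-computable when
`M = 0` or `n = 0`. The p-value is the exact upper-tail hypergeometric sum

```
p = Σ_{m' = m}^{n} C(M, m') C(N−M, n−m') / C(N, n)
```

with undefined binomial coefficients contributing zero, evaluated in log
space with compensated (Kahan) summation so that small-universe results are
reproducible to ≤ 1e-12 against exact integer enumeration. p-values are
computed only for enriched terms (E-ratio ≥ 1), matching the procedure being
reimplemented; depleted terms appear without a p. No multiple-testing
correction is applied by default — the original analysis reports raw
hypergeometric p — but Benjamini–Hochberg adjustment is available behind
`adjust = TRUE`. GO ancestry propagation (the true-path rule) is *not*
applied: direct annotations are counted as provided. Hits are counted inside
the universe, not excluded from it.

## The binding isotherm

Affinities are quantified with the single-site ("one set of sites") model.
With total titrant `Xt` and macromolecule `Mt` in the cell, fractional
saturation is the smaller root of

```
Θ² − Θ (1 + Xt/(n·Mt) + 1/(n·Ka·Mt)) + Xt/(n·Mt) = 0
```

and cumulative heat is `Q = n·Θ·Mt·ΔH·V0`. Concentrations after the i-th
injection follow the perfusion-displacement convention
(`Mt = Mt0 (1−ΔV/2V0)/(1+ΔV/2V0)`, `Xt = Xs (ΔV/V0)/(1+ΔV/2V0)`), and
per-injection heats carry the standard correction for heat displaced out of
the cell: `ΔQᵢ = Qᵢ − Qᵢ₋₁ + (dVᵢ/V0)(Qᵢ + Qᵢ₋₁)/2`.

Units are fixed internally — volumes in liters, concentrations molar,
enthalpy cal/mol, heats µcal — with conversions only at I/O; ΔH is reported
in kcal/mol. The default design is the instrument schedule used throughout
the underlying study: one 0.2 µl purge injection then 19 × 2 µl into a
200 µl cell of 300 µM macromolecule, titrating 3 mM ligand at 25 °C. The
purge injection exists to clear the syringe tip and is excluded from the fit
objective by default (configurable).

Fitting is weighted least squares over `(log Ka, log n, ΔH[, baseline])` —
log parameterization for conditioning and positivity — via
Levenberg–Marquardt from a fixed log-spaced `Ka` grid (10² to 10⁹ M⁻¹, half-
decade steps; the three best grid points seed the optimizer). There is no
random initialization: fits are bit-reproducible. The fit reports the Wiseman
`c` value (`n·Ka·Mt0`) and flags `c < 1` as low-information — the regime
where the isotherm is too shallow to pin down Kd, which is how
non-binding-grade affinities (Kd beyond a few hundred µM under this design)
manifest.

**Precision limit.** Noiseless simulate-then-fit round trips recover all
three parameters to < 1e-6 relative error across Kd from 1 to 200 µM. With
Gaussian noise of 2% of the largest per-injection heat, the median relative
Kd error at Kd = 18 µM over 50 seeds is ≈ 7% (the acceptance script computes
this as `itc_noisy_median_kd_err_pct`). That is not an estimator defect: the
Cramér–Rao bound for this 19-point design at that noise level puts the floor
for the median |relative Kd error| near 6% with `(n, Ka, ΔH)` all free, and
restarting the optimizer from the true parameters reproduces the same
least-squares optimum. Users who need tighter Kd under comparable noise must
change the design (more injections, higher `c`, or replicates), not the
fitter.

## What the synthetic data does and does not show

`gen_proteome()` emits three populations, all single-pass membrane proteins
with an N-terminus-outside topology (the canonical geometry of the motif's
validated carriers; multipass topology handling is exercised by unit tests
instead):

* **planted positives** whose tails are built over a *filter-inert* filler
  alphabet (no hydrophobic-class, F/Y, or R/K letters) around a
  grammar-conforming motif with structure labels that satisfy all three
  rules — by construction the planted motif is the only possible match in
  the protein;
* **decoys** that differ from a planted positive in exactly one respect:
  position 3 mutated to H (the natural non-binder variant of the grammar),
  location swapped to mitochondrion, strand labels removed, linker labels
  hardened to strand, upstream coil removed, or a folded-domain interval
  overlaid on the motif;
* **background** proteins drawn residue-i.i.d. with hydrophobics
  down-weighted, rejection-sampled until they contain no rule-passing chance
  match, with run-structured random {H,E,C} labels.

Every emitted planted/decoy protein is verified against the pipeline's own
predicates at generation time; a dataset whose truth table disagrees with the
pipeline fails loudly rather than shipping a wrong oracle. This makes the
planted-recovery benchmark exact (precision = recall = 1 is the *designed*
outcome, and any deviation is a pipeline bug), but it also bounds what
passing proves: the generator does not emulate real proteome length or
composition distributions, real secondary-structure label error, a real GO
DAG, or annotation noise. Perfect recovery on this benchmark demonstrates
that the pipeline implements its stated rules exactly — not that the rules
themselves have any particular sensitivity or specificity on a real
proteome, which depends on external predictors and annotation quality the
package deliberately takes as input.

Problem sizes used by the shipped benchmarks — a 135-protein synthetic
proteome (100 background, 10 planted, 25 decoys), a 440-protein GO universe,
1,000 random sequences for scanner cross-validation, 50-seed Monte-Carlo ITC
recovery, 10,000-position predictor corpora — were chosen as the smallest
sizes at which each property is sharply testable.

## Known limitations

* The published 71-protein candidate list is not reproducible from this
  package alone: it depends on a versioned external proteome and GO release,
  two external structure predictors, and a manual curation step. The package
  reproduces the *method*; annotation files stand in for the external
  predictors.
* Topology is trusted as annotated; the hydropathy fallback is a coarse
  stand-in for a real topology predictor and marks its orientation guess.
* The grammar is Boolean by design — no position-weight scoring or affinity
  prediction from sequence.
* Kd precision under noise is design-limited (see the isotherm section).
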