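---
title: "Probe panel design and in silico reverse line blot typing: models and methods"
author: "rlbh package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe panel design and in silico reverse line blot typing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

Reverse line blot hybridization (RLBH) types environmental samples below
the species level: a marker region (typically the 16S--23S internal
transcribed spacer, which evolves fast enough to separate groups that are
indistinguishable on 16S rRNA) is PCR-amplified from community DNA with
labelled primers and hybridized against a membrane carrying a line of
group-specific oligonucleotide probes.  A probe line lights up when the
sample contains sequence variants perfectly matching that probe.  Applied
across many habitats, the resulting presence/absence matrix supports
niche-preference statistics: detection frequencies, sympatry--allopatry
(Venn) analysis, and constrained ordination against environmental
gradients.

`rlbh` implements the computational side of this workflow end to end:

1. design of group-specific, optionally degenerate probe panels against a
   labelled strain collection (`designPanel`);
2. in silico PCR, including the nested scheme used for low-template
   samples, and a hybridization signal model producing ordinal detection
   matrices (`amplify`, `nestedAmplify`, `hybridizePools`);
3. the ecology statistics on binarized detections (`ordinate`,
   `forwardSelect`, `cooccurrence`);
4. a synthetic-data generator with known ground truth so every stage is
   testable without any sequence download (`generateStudy`).

# Sequence model and degenerate matching

Sequences are handled over the IUPAC alphabet.  Internally every
character maps to a 4-bit mask (A=1, C=2, G=4, T=8; ambiguity codes are
bitwise unions), so "does this probe position accept this target base"
is a single AND.  A probe position mismatches a target base exactly when
the mask intersection is empty, which makes mismatch counting degenerate
aware on the probe side; target sequences must be concrete A/C/G/T
(ambiguity codes in references would require a matching policy that
sequenced-strain data does not need).  Window scans
(`minMismatches`) report the minimum mismatch count over all windows and
optionally both strands; ties resolve to the smallest start, with the
given strand preferred, so results are byte-reproducible.  Coordinates
are 0-based and half-open throughout, which keeps amplicon arithmetic
(`end - start = length`, slice = `substr(start+1, end)`) free of
off-by-one cases.

Pairwise identity (`pairwiseIdentity`) is a Needleman--Wunsch global
alignment (match +1, mismatch -1, gap open -2, gap extend -1 by default,
computed by `Biostrings::pairwiseAlignment`) with identity defined as
matches over alignment length.  Published similarity figures for marker
collections rarely state their metric, so the scores are configurable and
reported alongside results rather than treated as reproduction targets.

# Melting-temperature models

Three Tm models are provided (`tmModel`): the Wallace 2(A+T)+4(G+C) rule,
the GC/salt formula 81.5 + 16.6 log10[Na+] + 0.41 %GC - 600/N, and
nearest-neighbor thermodynamics using the unified DNA/DNA dimer
parameter set (vendored as a plain-text table so results are bit
reproducible), with Tm = dH / (dS + R ln(c/4)) - 273.15 and the entropy
salt correction 0.368 (N-1) ln[Na+].  Defaults are Na+ = 0.05 M and an
oligo concentration of 0.25 uM.  Degenerate oligos aggregate over their
concrete expansions (mean by default; min/max available), with a
degeneracy cap (64) guarding combinatorial blow-up.

Published probe tables often list Tm values whose generating formula is
not stated; no simple model reproduces such values exactly.  The package
therefore carries published Tm values as reference metadata only (see
`referenceOligos()`) and never uses them as test oracles.

# Probe panel design

The design procedure for one group:

1. **Profile.**  Every member is placed on the coordinates of the first
   member at its best-scoring gapless offset (full-sequence granularity),
   and each column stores the union of member bases.  For indel-free
   collections — the generator's output and the intended input domain —
   this is identical to matching each window against each member at its
   best offset, and it is deterministic and cheap.  An externally
   supplied alignment can replace this step by pre-aligning sequences.
2. **Windows.**  Every window of every allowed length (default 18--31 nt)
   is enumerated on the profile.  Columns where members disagree become
   IUPAC codes; windows with more than `maxDegeneratePositions` (default
   2) such columns are dropped.
3. **Constraints.**  Candidates must perfect-match at least
   `minGroupCoverage` (default all) of the group and keep at least
   `minNontargetMismatches` (default 2, hard floor 1) mismatches to every
   non-target strain on both strands.  The specificity scan runs in two
   phases: a homologous-window upper bound prunes hopeless candidates,
   then per-diagonal mismatch prefix sums give the exact minimum (and the
   nearest non-target strain) for every survivor.
4. **Ranking.**  Survivors sort by coverage, then a specificity key, then
   degeneracy, Tm distance to the requested window, and position.  With
   `centralWeighting` on (default), the specificity key counts
   mismatches in the central third of the probe twice: a mismatch at a
   probe's end barely destabilizes the duplex and discriminates poorly in
   hybridization, so a candidate with fewer but central mismatches is
   preferred over one with more terminal ones.
5. **Panel assembly.**  `designPanel` takes each group's top candidate,
   anchoring the panel on the median Tm of the per-group leaders and
   substituting next-ranked candidates (greedily, in group order) so the
   panel spread stays within `2 * tmTolerance`.  Groups with no feasible
   candidate are reported, never dropped silently.  The default tolerance
   is deliberately wide (10 degrees): discriminative windows sit where
   the marker forces them, and their base composition — hence Tm — can
   vary widely, so a tight default would trade specificity for Tm
   cosmetics.  Real assays absorb residual Tm differences by adjusting
   per-probe concentrations (the `gains` of the hybridization model);
   users designing for a tightly matched single-wash panel should set
   `tmTolerance` to 1--2.5 and accept reduced coverage.

**Nested groups.**  When one group's members are a subset of another's
(e.g. a finer subgroup within a broader lineage), each group's non-target
set excludes the other's members, so probes for both levels can coexist
in a panel.  Strains carry all their group labels, so validation
(`validatePanel`) counts a parent probe detecting a child strain as a
true positive.

# Assay simulation

The simulator is site logic, not reaction kinetics: thermal-cycling
parameters are metadata.  A primer binds where its (degenerate-aware)
mismatch count is within budget (default 1) and its 3'-terminal clamp
(default 3 bases) is mismatch-free, since 3' mismatches abort extension.
Every pairing of a plus-strand forward site with a downstream minus-
strand reverse site within the product length bounds yields an amplicon
equal to the template slice; the nested scheme re-amplifies outer
products with the inner pair.

Hybridization signal for a probe is `gain * sum(abundance)` over pool
members whose amplicon contains a probe site within the mismatch
tolerance (default 0: perfect match, matching the perfect-match design
philosophy), classified into `none / weak / average / very_strong` by a
detection floor (1e-3) and two cut points (1e-2, 1e-1 on the relative
abundance scale at gain 1).  The linear signal model and its cut points
are the package's own definition — membrane assays report only ordinal
classes — and are configurable.  Binarization counts any signal as
present by default (`exclude_weak` is available for sensitivity
analysis), and is idempotent on binary input.  Real cross-hybridization
at one or two mismatches is chemistry dependent; the tolerance knob
stands in for it, with no attempt to fit any particular assay's weak
signals.

# Ecology statistics

**Ordination.**  `ordinate` implements the CA family from the chi-square
standardized residuals of the row/column-mass model: CA is the SVD of
that matrix; CCA projects it onto the column space of the weighted,
standardized environmental matrix (weighted least squares via QR) before
the SVD.  PCA/RDA are the linear analogues on the centred response.
Species-focused scaling (species scores scaled by the square roots of the
eigenvalues) is the default; axis signs are fixed by making the
largest-magnitude species score on each axis positive, so outputs are
byte-reproducible.  All-zero rows or columns are a named error — the
explicit `dropEmpty` step decides what leaves the analysis.  Rank
deficiency in the environment matrix is an error listing collinear
columns.  Both regression directions are supported (environment
explaining groups, or groups as explanatory variables with environmental
characteristics as the explained table), recorded in the result metadata.
The choice between unimodal (CCA) and linear (RDA) ordination is left to
the user as a method switch; the conventional rule bases it on the
gradient length of a detrended correspondence analysis, which this
package does not implement.

**Permutation test.**  The added constrained variance of a candidate
variable given the selected set is tested by unrestricted permutation of
the candidate's habitat rows (raw-data scheme; permutation schemes
permuting residuals exist but the raw scheme is the one classic
ordination software applies by default).  The statistic is a pseudo-F
(added variance over residual variance per residual degree of freedom),
and the p-value uses the add-one convention (1+b)/(1+m), which never
returns 0 and has floor 1/(m+1) — 1/1000 at 999 permutations.
Permutations are vectorized as one matrix product per test.

**Forward selection.**  At each step all remaining candidates are
tested; their p-values are Holm-adjusted across the step's tests and the
largest-added-variance candidate with adjusted p below alpha enters.
Without adjustment, testing the best of several noise candidates at raw
alpha inflates the family-wise entry error to roughly
1-(1-alpha)^(number of candidates) per step.  In addition, the selected
model's adjusted constrained fraction is compared against that of the
model containing all candidates (closed-form Ezekiel adjustment for RDA,
permutation-based adjustment for CCA): selection stops once the
cumulative adjusted R2 reaches the global one, and after the first
variable no candidate may push it beyond — the classic double stopping
criterion against stepwise overselection.  Both guards can be disabled
(`adjust = "none"`, `globalStop = FALSE`) to reproduce the plain
procedure.  Collinear candidates (e.g. a duplicated variable) are
skipped, so exactly one copy of a duplicated informative variable can
enter.  Every stochastic step derives from one explicit seed; there is no
hidden global generator state.

**Missing environmental values** must be resolved explicitly
(`resolveMissing`: drop the habitat, or mean-impute); ordination refuses
NA input rather than guessing.

**Co-occurrence.**  `cooccurrence` counts all 2^k presence/absence
combinations (Venn cells) for a subset of up to 8 groups, pairwise
co-occurrence counts, and a "never co-occurs" flag per pair — complete
allopatry across many habitats being the signature of niche separation.
Richness is reported as mean and sample SD of per-habitat group counts.

# The synthetic study generator

`generateCollection` emulates the statistical structure of an
intra-subspecies marker collection:

* one ancestor core (default 500 nt) mutates into per-group backbones at
  rate 0.02 per site, and each strain adds within-group substitutions at
  rate 0.002, never touching its own diagnostic site.  These defaults
  put within-group identities at or above ~98.4% and across-collection
  identities around ~94%, the band reported for ITS collections of this
  kind;
* each group receives a diagnostic site: a 20-nt window carrying 6
  evenly spaced substitutions of the group backbone at fixed, evenly
  spaced offsets across groups (non-overlap is checked).  Substituted
  sites — rather than fully random 20-mers — keep the across-collection
  identity in the intended band while guaranteeing a multi-mismatch
  margin to every non-target backbone;
* nested pairs plant an additional child site into a fraction of a
  parent group's strains, which then carry both labels;
* every marker is flanked by conserved regions carrying the reference
  assay's outer and inner primer sites (`referencePrimers()`), so the
  generated FASTA is amplifiable by the bundled nested scheme with zero
  manual edits.

`generateHabitats` draws pH uniformly over 3.9--8.5 (121 habitats by
default) with conductivity increasing in pH plus Gaussian noise, an
absorbance-at-250-nm DOC proxy decreasing in pH, and independent oxygen,
temperature and altitude structure — the canonical situation in which
acidic, low-conductivity, humic habitats sit at higher altitudes.
`generatePools` assembles communities by ecotype sorting: group presence
is Bernoulli with Gaussian niche probability
`pmax * exp(-(x - mu)^2 / (2 sigma^2))` in the driving variable (a
unimodal response, consistent with the assumptions of CCA), and present
groups contribute one uniformly drawn member strain with log-normal
abundance (meanlog -1, sdlog 0.5; only relative values matter
downstream).  Niche optima and breadths have no empirical source and are
illustrative defaults.

What the generator does **not** emulate: indels (no alignment machinery
in the core path; an aligned input can be supplied instead), rate
heterogeneity and recombination, chimeric amplicons, PCR efficiency
bias, and the membrane chemistry behind weak signals.  Tests passing on
synthetic data therefore demonstrate the correctness of the algorithms
under the stated model, not the wet-lab performance of any particular
probe panel.

# Numerical and reproducibility choices

* Eigenvalues below 1e-12 are treated as null axes; oracle comparisons
  in the test suite run at 1e-8 (constrained ordination against an
  independently coded dense solve) and 1e-10 (CA inertia against the
  closed-form chi-square identity).
* All tie-breaks (window scans, candidate ranking, panel assembly,
  nearest non-target attribution) are fixed and documented, so repeated
  runs are byte-identical; the command-line pipeline writes manifests
  recording every spec and seed.
* The test suite exercises probe-design recovery on 20 generator seeds
  (10 groups x 10 strains, 500-nt cores), permutation calibration on 500
  replicates at 199 permutations, forward-selection recovery on 40 seeds
  at 999 permutations, and 20-seed end-to-end niche-separation and
  nesting simulations at 120 and 60 habitats — sizes chosen to give the
  property checks stable pass/fail behaviour on a single CPU.

# Known limitations

* Degenerate bases are supported in probes/primers only; reference
  strains must be concrete sequences.
* The gapless profile alignment degrades for collections with frequent
  indels; supply pre-aligned sequences in that case.
* The hybridization model is deliberately minimal; its ordinal classes
  should not be interpreted as calibrated signal intensities.
* Adjusted R2 for CCA uses a permutation estimate and is therefore
  itself stochastic (seeded).
* Tm values depend on the parameter set and salt model; cross-package
  comparisons should fix both.
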