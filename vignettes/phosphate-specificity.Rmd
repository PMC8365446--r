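---
title: "Predicting NrdJ phosphate specificity from the apical loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting NrdJ phosphate specificity from the apical loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnrspec)
```

## The scientific problem

Ribonucleotide reductases (RNRs) reduce ribonucleotides to
deoxyribonucleotides and are specific for either ribonucleoside
*diphosphate* (NDP) or *triphosphate* (NTP) substrates. In the
adenosylcobalamin-dependent class II enzymes (NrdJ) both specificities
occur, and the structural determinant is a short loop of the
phosphate-binding site positioned apically with respect to the substrate's
phosphate groups. Diphosphate reducers carry the motif P-N-S-P in this loop
(the serine hydrogen-bonds the β-phosphate and sterically excludes a
γ-phosphate); triphosphate reducers carry P-[A/S/G]-G-R, where the glycine
opens space for the γ-phosphate and the arginine reorients the loop.
Swapping two of these residues is enough to switch the substrate preference
of a model enzyme, which is what licenses using the motif as a *predictor*
of specificity across the class.

`rnrspec` implements the full inference chain built on that observation:

1. locate the apical loop in a query sequence and extract its motif
   (`extract_motif_pairwise()`, `extract_motif_msa()`);
2. classify the motif against a curated lexicon into NDP / NTP / UNKNOWN
   (`classify_motif()`, `census()`);
3. summarise per-column conservation of motif classes as sequence-logo
   matrices (`build_logo()`);
4. map specificity states onto a phylogeny and quantify how often the
   character changed (`fitch_count()`, `is_monophyletic()`);
5. aggregate per-genome labels into co-occurrence categories
   (`summarize_cooccurrence()`);
6. estimate the kinetic parameters used to validate a motif graft
   (`fit_model()`, `apparent_fit()`).

Every step can be exercised on synthetic data with known ground truth
(`generate_family()`, `generate_genomes()`, `generate_tree_states()`,
`simulate_assay()`).

## Anchoring and motif extraction

Extraction maps query residues into the coordinate system of an annotated
reference (`reference_anchor()`): a global Needleman–Wunsch alignment
(BLOSUM62, gap open 11, extend 1 per residue — standard protein defaults;
`X` is tolerated and scored 0) aligns the query to the reference, and the
query residues occupying the reference apical-loop span are read off. The
default reference is a synthetic 150-residue NrdJ-like backbone whose
apical loop sits at residues 66–69, mirroring the numbering of the Thermus
virus P74-23 enzyme in which the loop positions 67–69 were mutated.

One numerical subtlety deserves a design note. The motif families differ in
length: the five-residue P-Q-G-S-P loop must map onto a four-residue
reference span through an insertion. Optimal affine-gap alignments are free
to slide such an insertion gap to the span boundary whenever the flanking
substitution scores favour it (aligning R with S scores −1, R with P −2 in
BLOSUM62), so a rule that only accepts insertions *strictly inside* the
span silently truncates the motif. The extraction therefore delimits the
loop by the two anchor columns immediately flanking the span: every query
residue strictly between them is loop. If a flanking anchor is itself
deleted in the query, the extraction falls back to the span-column rule.
Queries whose alignment score falls below 25% of the reference
self-alignment score are reported `UNMAPPED` — the coordinate transfer is
then meaningless; sequences gapped at a span column are `PARTIAL`. Both are
excluded from classification (they count as UNKNOWN).

When a curated multiple alignment with known loop columns is available,
`extract_motif_msa()` bypasses alignment entirely and reads the designated
columns, gaps removed. Because nothing in this package hard-codes which MSA
columns form the loop in any particular alignment, the columns are an
explicit argument.

## The motif lexicon

Classification is data-driven: the lexicon ships as a CSV
(`motif_lexicon()`) so it can be versioned and extended as further motifs
are characterised. The default rows are the experimentally calibrated
NrdJ patterns:

| pattern | label | rationale |
|---|---|---|
| `[P/F]-N-S-P` | NDP | positions 2–4 fully conserved; Phe tolerated at 1 |
| `P-[A/S/G]-G-R` | NTP | position 2 varies among Ala/Ser/Gly |
| `P-S-M-R` | NTP | Met variant, always with Ser at position 2 |
| `P-[Q/A]-G-S-P` | NTP | five-residue variant; Ala substitutes Gln |

Matching is case-insensitive and first-match-wins in table order (the
patterns are mutually exclusive, so order only matters defensively).
Everything else is UNKNOWN — deliberately including P-A-G-S, which was
engineered into a model enzyme but yielded an inactive protein and
therefore carries no specificity evidence. NTP patterns stay P-anchored at
position 1: the Phe tolerance is documented only for the NDP motif, and the
lexicon does not extrapolate it.

## Sequence logos

Logo matrices use observed column frequencies with an optional uniform
pseudocount (default 0), information content
$IC = \log_2 20 - H(p)$ in bits, and the WebLogo gap convention: gaps
reduce a column's *occupancy* rather than acting as a 21st symbol, and
letter heights are $p_r \cdot IC \cdot \text{occupancy}$. No HMM-style
posterior weighting is applied — logos summarise the given subset of
sequences as-is, which is a documented divergence from web services that
weight by profile match. A small-sample correction is available
(`small_sample = TRUE`) but off by default; the motif-class subsets this
package targets are large enough (dozens of sequences) that the correction
is negligible.

## Parsimony mapping on the phylogeny

The evolutionary claim behind the motif's distribution is that diphosphate
specificity arose *once*: on the class II phylogeny the NDP-motif tips form
a single clade, i.e. the binary specificity character needs exactly one
change. `fitch_count()` computes the small-parsimony minimum number of
changes. Internally it runs a unit-cost dynamic programme over the observed
state alphabet (Sankoff-style) rather than the classical two-set Fitch
recursion, for one reason: real trees contain polytomies, and the popular
union/intersection extension of Fitch to multifurcations undercounts there
(a polytomy whose children carry states A, A, B, B costs two changes, not
one). The DP is exact on arbitrary multifurcating trees, equals Fitch on
binary trees, and is verified in the test suite against exhaustive
enumeration of all internal labelings on small trees and against an
independent phylogenetics library on binary trees.

Monophyly is assessed in the unrooted sense — some edge bipartition
separates exactly the focal tips — because the root of the published NrdJ
phylogeny is not part of the claim. Tips with UNKNOWN state are pruned
before either computation: an unclassifiable motif is missing data, not a
third character state. For a binary character with both states present,
`fitch_count() == 1` and monophyly of either state are equivalent, and the
test suite checks that equivalence over hundreds of random trees.

## Genome co-occurrence

`categorize_genome()` reduces a genome's NrdJ copies to one category.
UNKNOWN labels are dropped *before* the two-copy threshold, so a genome
with one classified and one unclassifiable copy is SINGLE, not multi-copy:
the source analysis does not state how it handled unclassifiable copies,
and this is the conservative choice (it never manufactures a multi-copy
observation out of ignorance). Identical duplicate sequences count as
separate copies, since the unit of observation is the gene occurrence. The
headline statistic is the percentage of multi-copy genomes whose copies
differ in predicted specificity; it is reported at full precision and
rounded to the nearest integer only for display.

## Kinetics

The assay arithmetic and model fitting mirror standard enzymology practice.
`activity_from_product()` converts an end-point product concentration into
a turnover (min⁻¹). `fit_model()` fits either the original
Michaelis–Menten law
$v = k_{cat} S / (K_M + S)$
or the uncompetitive substrate-surplus-inhibition form
$v = k_{cat} S / \left(K_M + S(1 + S/K_i)\right)$
by unweighted least squares with the Levenberg–Marquardt algorithm
(`minpack.lm`), standard errors from the Jacobian at the optimum. The
surplus-inhibition equation is the standard textbook form; it nests
Michaelis–Menten as $K_i \to \infty$ and peaks at $S = \sqrt{K_M K_i}$.

Starting values are scale-free: $k_{cat,0}$ is the maximum observed rate
and $K_{M,0}$ is the half-saturation read off the *rising limb* of the
curve — the smallest substrate level whose mean rate reaches half-maximum.
(Choosing the substrate whose rate is merely *nearest* half-maximum can
land on the falling limb of an inhibited curve and start the optimiser in a
degenerate spot.) Convergence is a reported flag, never a silent failure:
on strongly inhibited data over a wide substrate range, a plain
Michaelis–Menten fit legitimately fails or returns a $K_M$ standard error
exceeding the estimate, and the package surfaces exactly that.
`apparent_fit()` implements the truncated-range workaround — fit plain
Michaelis–Menten only below a substrate cut-off where inhibition is not yet
apparent — and flags the result, because the apparent $K_M$ obtained this
way is only a lower bound on the true value.

## What the synthetic generators emulate — and what they do not

The generators define the study conditions under which the pipeline is
tested.

* **Families** (`generate_family()`): each sequence is a fixed 150-residue
  NrdJ-like scaffold with its assigned motif planted at position 66, then
  mutated at a per-site substitution rate (default 0.1 — the divergence of
  the real sequence set is not documented, and 10% background divergence is
  a realistic within-family figure) and a per-site indel rate (default
  0.01, single-residue events). Mutations and indels never touch the loop
  blocks ± a margin, so ground truth stays well defined. Motif counts are
  apportioned deterministically (largest remainder), so a zero-noise census
  recovers the planted fractions exactly. The default motif mix plants the
  minor motifs at their observed shares (P-S-M-R 2.1%, P-Q-G-S-P 1.7%,
  P-N-S-P 44%) with the remainder (52.2%) to P-A-G-R; the source's printed
  percentages total 100.8% and therefore cannot be realised jointly.
* **Genomes** (`generate_genomes()`): copy numbers and multi-copy
  specificity categories, apportioned deterministically (for exact count
  tables) or sampled. Category determines the copies' motifs (MIXED = one
  P-N-S-P plus P-A-G-R copies).
* **Trees** (`generate_tree_states()`): random topologies with the derived
  NDP state laid out as one clade (SINGLE_ORIGIN), k separated clades
  (K_ORIGINS — parsimony count exactly k by construction), or independent
  per-tip draws (RANDOM). The default derived-tip fraction 0.44 mirrors the
  observed NDP share.
* **Assays** (`simulate_assay()`): rates from the chosen rate law with
  multiplicative Gaussian noise $v(1+\varepsilon)$,
  $\varepsilon \sim N(0, cv^2)$, truncated at zero — the error model of the
  source experiments is not stated, and a constant coefficient of variation
  is the usual behaviour of HPLC-quantified initial rates. The default
  design (grid 0.05–3 mM bracketing $K_M = 0.30$, 3 replicates, 5% CV)
  matches a wild-type characterisation.

None of the generators attempt realistic NrdJ domain architecture,
B12-binding or allosteric sites, codon-level evolution, or phylogenetic
correlation between sequence and tree — the family generator and the tree
generator are independent. Passing tests therefore demonstrate that the
*computational chain* is correct under controlled truth, not that the
biological claims hold on real data; for real data the package consumes
standard FASTA/Newick/CSV inputs.

## Numerical choices and degenerate inputs

* Alignment tie-breaking is delegated to the DP engine and is
  deterministic; scores are validated against a brute-force enumeration
  oracle for short sequences.
* `fitch_count()` requires ≥ 2 tips with non-ignored states and errors when
  all tips are ignored; a one-state tree costs 0 changes.
* Monophyly of a single tip or of all tips is trivially true.
* All-gap logo columns error under a zero pseudocount (there is no
  distribution to report) and return the uniform distribution under a
  positive one; IC is clipped at 0 when a small-sample correction
  overshoots.
* Fits require ≥ 4 distinct substrate levels (≥ 5 with inhibition);
  optimiser tolerances are 1e-10 (relative) with 500 iterations maximum.
* Generators restore the caller's RNG state; identical seeds give
  byte-identical outputs.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise the methods well past their small-sample regime
while staying comfortable on a laptop: families of up to 1655 sequences
(the size of the real representative alignment), 1200 genomes (1108
multi-copy), 64-tip trees, and 100 simulated assay datasets of 30 points
each. Exhaustive oracles (all alignments, all internal labelings) run at
sequence lengths ≤ 5 and tree sizes ≤ 8, where enumeration is exact and
fast.

## Known limitations

* Pairwise anchoring assumes the query is homologous to the reference over
  most of its length; the score floor rejects non-homologs but fragments
  covering only the loop region will be UNMAPPED, not rescued.
* The lexicon is NrdJ-calibrated. Class I (NrdA) enzymes show the NDP motif
  with more variability and class III (NrdD) enzymes are not covered;
  applying the classifier outside class II is extrapolation.
* Branch support is ignored: monophyly is a yes/no topological statement on
  the given tree.
* The kinetics module starts from quantified (substrate, rate) or
  (time, product) data; chromatogram processing and calibration are out of
  scope.
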