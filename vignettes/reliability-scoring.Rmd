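---
title: "Integrating and scoring physical protein–protein interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating and scoring physical protein–protein interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiscore)
```

## The problem

Interaction databases disagree about what a protein–protein interaction is.
The same experiment reaches a consolidated resource through several source
databases, each with its own identifiers, its own reading of the PSI-MI
controlled vocabulary, and its own handling of co-purified complexes. A
consumer who wants *physical* interactions with an honest statement of how
much to trust each one has to (i) integrate the sources into one
deduplicated set of binary interactions and (ii) attach a reliability score
to every interaction. `ppiscore` implements both steps, plus the machinery
to evaluate the scores against gold standards built from experiment scale
and subcellular localization.

## Integration

Raw records are read from PSI-MITAB 2.5/2.7 and from a compact PSI-MI XML
2.5 dialect, and pass through a fixed sequence of stages:

1. **Term normalization.** Interaction-type and detection-method terms are
   resolved against a static snapshot of the PSI-MI vocabulary, by MI
   accession first and by name otherwise. Unrecognized terms become the
   sentinel `"unknown"`; they stay in the data and score at the minimal
   weight rather than being dropped, because an obsolete label is not
   evidence against the interaction. Each downgrade is counted as a remap
   event in the integration report.
2. **Spoke expansion.** Complexes become binary pairs by connecting every
   prey to the bait; with several baits, the baits are additionally assumed
   to bind each other, giving `k·p + k(k−1)/2` pairs for `k` baits and `p`
   preys. No prey–prey pairs are ever emitted — co-purification says that
   the preys bind the bait, not one another. A complex with no declared
   bait cannot be oriented and is rejected whole.
3. **Physicality filter.** Evidence passes when its types intersect
   {`association`, `physical association`, `direct interaction`} (or are
   entirely `"unknown"`), no type is a recognized indirect one
   (colocalization, genetic, predicted), and no detection method is
   genetic interference. Failing evidence items are pruned from otherwise
   valid interactions; an interaction left with no admissible evidence is
   rejected. Filtering at evidence granularity keeps an interaction seen
   both by two-hybrid and by a genetic screen, while discarding only the
   genetic support.
4. **Protein / same-species filter.** Both participants must be proteins of
   the same taxon.
5. **Canonicalization.** Source identifiers are replaced through the
   identifier-mapping sidecar table; unmapped identifiers are rejected into
   an auditable list rather than guessed. (Sequence-alignment remapping is
   out of scope; the mapping arrives as data.)
6. **Deduplication.** Pairs are compared under an order-invariant key —
   `pair_key(A,B) == pair_key(B,A)`, self-pairs allowed — and evidence is
   merged per publication: one evidence item per distinct Pubmed ID, with
   type, method and source-database sets unioned across databases and the
   experiment scale taken as the maximum reported. The maximum is the
   conservative choice for the later small-scale/high-throughput labeling:
   when databases disagree about how large an experiment was, we prefer to
   label it high-throughput rather than promote it into the positive gold
   standard.
7. **Species threshold.** Species with fewer than 10 interactions in the
   combined unique set are dropped (configurable), with a per-species
   census in the output.

The stage order affects only which reason a doomed pair is rejected under,
never the surviving set; the pipeline is order-insensitive in its input and
idempotent on its own output, and both properties are tested.

## The method-based score

Experimental support is summarized by three components, each in [0, 1],
whose arithmetic mean is the method-based score:

* **Publication component** `min(n, s)/s` for `n` distinct supporting
  publications, saturating at `s = 7`: one more paper always helps, but
  seven independent reports are treated as conclusive.
* **Detection-method component.** Each distinct (publication, category)
  occurrence counts once, where the category is one of *biophysical*,
  *protein complementation assay*, *biochemical*, *post-transcriptional
  interference*, *imaging technique* or *unknown*, and every sub-method
  inherits its parent category's weight. The component is the
  frequency-weighted mean of the category weights times the same
  `min(n, s)/s` saturation applied to the occurrence count.
* **Interaction-type component.** The same aggregation over
  (publication, type) occurrences with weights for *direct interaction*,
  *physical association*, *association* and *unknown*.

Counting occurrences per **merged** publication list is the anti-inflation
rule: the same experiment imported from five databases contributes one
occurrence, not five, and the scorer refuses unmerged evidence outright.
Duplicating every evidence item under another database name provably leaves
the score unchanged (property-tested).

Two consequences of the frequency-weighted form are worth stating plainly.
First, below the saturation point the component reduces to
`Σ n_c·w_c / s`, so a single biophysical publication scores `1/7` — weak
evidence is weak even when high-quality. Second, the component is *not*
monotone under adding arbitrary evidence: appending a low-weight
(e.g. unknown-method) publication to an already saturated set of
biophysical ones lowers the weighted mean. This is deliberate: the
component measures the *quality profile* of the evidence, while sheer
volume is credited by the publication component. Monotonicity does hold,
and is tested, for the publication component always and for all components
when the added evidence carries top-weight categories.

The default category and type weights shipped with the package
(biophysical 1.0, biochemical 1.0, complementation 0.66, imaging 0.33,
post-transcriptional interference 0.33, unknown 0.05; direct interaction
1.0, physical association 0.75, association 0.33, unknown 0.05) are
configuration, not ground truth: they stand in for the community MIScore
defaults and can be replaced wholesale through the JSON config
(`read_score_config()`).

## The annotation-based score

Three boolean features of the interacting proteins are read from sidecar
tables:

* the proteins carry Pfam domains observed to bind in 3D structures of
  complexes (an unordered domain-pair lookup);
* the proteins share at least one Gene Ontology term (exact term-ID
  equality, no ancestor closure — the cheapest reading, with an optional
  restriction to chosen GO aspects);
* an interaction between homologs of the two proteins exists in the same
  or another species (an interolog, supplied as a table; computing
  homology is out of scope).

Each feature contributes a likelihood ratio and the ratios multiply under a
naive-Bayes conditional-independence assumption (an explicit 8-row table
mode is also available for calibrations where independence is too wrong).
The shipped defaults use present-LRs 14 / 3 / 4 for domains / GO /
homology — ordering the features by their discriminative power, interacting
domain pairs strongest — and a common absent-LR of `0.163^(1/3)`, so that
an interaction with no feature support has a likelihood ratio of exactly
0.163. Configuration validation enforces positivity, a no-feature ratio
below 1, and monotonicity of the ratio along the feature partial order.

A ratio maps to a score by `lr / (1 + lr)`: strictly increasing, with
`score(1) = 0.5`, so a score above 0.5 is *equivalent* to a likelihood
ratio above 1 — the high-confidence reading of the annotation score. An
explicit LR→score table can override the mapping; the equivalence is
property-tested across random valid configurations.

A protein absent from every sidecar table contributes empty sets, so an
unannotated protein yields all-false features and the baseline score
`0.163/1.163 ≈ 0.140` — low confidence from ignorance, which is exactly
what the method-based score exists to compensate.

## Combined score and classification

The combined score is the geometric mean `sqrt(annotation · method)`. The
geometric mean punishes disagreement: a pair with one excellent and one
zero score combines to zero, which an arithmetic mean would hide. An
interaction is called high-confidence when the combined score strictly
exceeds 0.281; the per-score flags (annotation ≥ 0.5, method ≥ 0.485,
both non-strict, following the source wording of each cutoff) are reported
for transparency but do not by themselves grant high confidence. A config
switch (`either_flag_high`) enables the alternative reading in which
either flag suffices; it is off by default because the combined rule is
the stricter and better-defined one. Classification happens in double
precision before any serialization rounding (output TSVs carry 6
decimals).

## Evaluation

Gold standards follow the scale-and-localization recipe: positives are
interactions supported by at least one small-scale experiment (≤ 100
associations); negatives are interactions supported *only* by
high-throughput experiments whose proteins have known, disjoint cellular
compartments. A protein with no compartment annotation cannot enter the
negative set — absence of annotation is not evidence of different
localization. The positive pool is down-sampled uniformly to the negative
count (seeded, without replacement); repeated draws are available to
attach a spread to each AUC, with a single draw as the default since the
negative set never varies.

The ROC sweeps all distinct score values, grouping ties into single steps,
and the AUC is the trapezoidal area — equal to the Mann–Whitney pairwise
statistic `P(score⁺ > score⁻) + ½P(equal)`, an identity the tests verify
against a brute-force pairwise oracle and against an independent ROC
implementation.

## The synthetic-data generator

Real source-database releases cannot ship with a package, so every
end-to-end property is exercised on seeded synthetic corpora
(`generate_corpus()`), which emit exactly the formats the readers consume:
MITAB files per synthetic database with planted cross-database duplicates
and invalid vocabulary terms, a compact PSI-MI XML file of complexes
(including bait-less ones), all sidecar tables, and a ground-truth table.
A companion oracle, `expected_integration()`, recomputes the
post-integration state from the ground truth by direct brute-force
application of the rules — complexes expanded by enumerating member pairs
with at least one bait, filters applied per instance, survivors grouped by
pair key — sharing no code with the pipeline, and the two must agree
exactly (tested over 50 seeded corpora).

The generator's defaults describe a corpus of 800 interactions among 300
proteins in 3 species, half genuine and half spurious, with evidence and
annotations enriched in the genuine ones: publications per interaction
`1 + Poisson(0.35)` vs `1 + Poisson(0.05)`; per-publication small-scale
probability 0.6 vs 0.05; detection methods skewed toward biophysical and
biochemical categories for genuine pairs and toward complementation,
imaging and unknown for spurious ones; feature planting
P(domain pair) = 0.5 vs 0.08, P(shared GO) = 0.6 vs 0.15,
P(interolog) = 0.4 vs 0.05; and a shared compartment forced for 75% of
genuine pairs. The Poisson mixture puts roughly 83% of interactions on a
single publication and leaves a clear majority of evidence
high-throughput, mimicking the shape of real integrated interactomes where
reliability scoring matters most. Planted error records (cross-species,
non-protein, colocalization-typed, genetic-interference, bait-less,
unmappable) arrive in known counts so the reject report can be checked
exactly.

What the generator does **not** emulate: real identifier pathologies
(merged/demerged accessions), correlated annotation sparsity (hub proteins
are better annotated in reality), GO-term semantics (terms are atoms, so
ancestor-closure questions cannot arise), and inter-database curation
disagreements beyond term invalidity. Passing the synthetic evaluation
therefore shows that the machinery is correct and that the scores behave
as designed under feature enrichment — not that the default weights are
optimal for any particular organism's interactome.

On these corpora the package's own evaluation (20 seeds, balanced gold
standards of ~250 pairs per class) shows the combined score's AUC meeting
or exceeding both individual scores in at least 15 of 20 seeds with all
three AUCs above 0.5 — the qualitative ordering one expects when two
complementary, individually informative signals are fused. The absolute
AUC values depend on the planted enrichment and are not comparable to any
published corpus.

## Numerical choices and edge cases

* Scores are computed in double precision; TSV output rounds to 6
  decimals, and classification precedes rounding.
* `0.163^(1/3)` cubed reproduces `0.163` to within one ulp, so the
  baseline check holds at tolerance 1e-9 without special-casing.
* Empty evidence gives a defined score floor (all method components 0),
  not an error; scoring *unmerged* evidence is an error, not a warning,
  because silent double-counting was the failure mode the merge exists to
  prevent.
* Degenerate ROC inputs (a single class) are errors; constant scores give
  AUC 0.5 by the tie convention.
* Self-interactions are retained throughout (`pair_key(A,A)` is valid).
* Records lacking a taxon are rejected at parse time, not defaulted: the
  cross-species filter cannot act on a guess.
* The balanced gold standard requires at least as many positives as
  negatives; very small corpora can violate this, and the error message
  says so rather than silently shrinking the negative set.

## Problem sizes

The shipped tests run the integration oracle on 50 corpora of 60–300
interactions and the AUC-ordering property on 20 corpora of 800
interactions; a full generate–integrate–score–evaluate cycle at the
default size takes a few seconds. These sizes were chosen as the smallest
at which the statistical properties are stable across seeds.
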