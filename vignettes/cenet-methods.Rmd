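---
title: "ceNET construction from EV and tissue expression: methods and design"
author: "cenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ceNET construction from EV and tissue expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenet)
```

## The model

A competing endogenous RNA network (ceNET) encodes the ceRNA hypothesis:
any transcript that physically binds a miRNA — mRNA, lncRNA or circRNA —
competes with the miRNA's other targets for it. An up-regulated miRNA
means its sponging mechanisms are off, so its bound targets are expected
down-regulated; a down-regulated miRNA means sponging is on and its
targets are released. `cenet` applies this logic to the special case where
the miRNA signal originates in extracellular-vesicle (EV) cargo and is
read out in a receiving tissue:

1. **Concordance (seed selection).** A miRNA enters the seed set for stage
   $s$ and direction $d \in \{\text{up}, \text{down}\}$ when both the EV
   table and the tissue table at $s$ call it $d$. Records called `ns`
   never qualify. Up-seeds define the **DOWN** ceNET and down-seeds the
   **UP** ceNET — the polarity names the expected target direction, not
   the miRNA direction.
2. **Whole-genome expansion.** Every CLIP-supported interaction whose
   miRNA is a seed becomes an edge of the unfiltered bipartite network.
   Seeds with no interaction at all are kept in `missingSeeds`; this is a
   real phenomenon in CLIP-backed interaction databases, not an error.
3. **Polarity filter.** An edge survives iff its target appears in the
   tissue ceRNA DE records with direction equal to the network polarity.
   Seed miRNAs whose edges are all removed move to `droppedSeeds`, so
   `missingSeeds`, `droppedSeeds` and the connected miRNAs always
   partition the seed set.
4. **Enrichment.** The filtered network's gene set is tested for
   over-representation against a local annotation file (GMT) with the
   hypergeometric upper tail, BH-FDR per annotation category, a
   log10(observed/expected) strength filter and a minimum-hit filter,
   then grouped by Jaccard similarity of hit sets.

### Assumptions

* **Stable EV release.** One stage-independent EV table is intersected
  with each tissue stage. This mirrors the assumption that stressed
  neurons release a stable set of dysregulated miRNAs while the tissue
  response evolves; if your EV data are stage-resolved, run the pipeline
  per stage with different EV tables.
* **Directions, not magnitudes.** Concordance and filtering use only the
  trichotomous call (`up`/`down`/`ns`). Fold-change magnitudes enter only
  through `inferDirection()` when a table carries `log2fc`/`padj` instead
  of an explicit call.
* **Atomic identifiers.** miRNA ids are compared as exact strings after
  whitespace trimming; no arm or isoform collapsing (a -5p and a -3p arm
  are different molecules with different targets). circRNAs are
  identified by host-gene-symbol strings; there is no back-splice
  coordinate model.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lfcThreshold` | 0 | minimum \|log2 fold change\| for `inferDirection`; 0 admits any significant change, matching consumption of pre-filtered published DE calls |
| `padjThreshold` | 0.05 | adjusted-p cutoff; ≥ 1 disables the p filter entirely |
| `clipSupportMin` | 0 | minimum CLIP experiments per edge; 0 keeps the interaction table as published |
| `fdrMax` | 0.05 | BH-FDR gate for enrichment |
| `strengthMin` | 0.01 | minimum log10(observed/expected); 0.01 excludes terms barely above proportional representation |
| `minHits` | 2 | minimum query genes in a term; singleton overlaps are uninformative |
| `similarityMin` | 0.2 | Jaccard threshold for single-linkage term grouping |

Upstream DE thresholds used by the source studies are not restated by the
data this package consumes; the `lfc`/`padj` defaults are configuration,
not a fact about those studies, and explicit `direction` columns always
take precedence.

## Design choices

* **Direction conflicts.** If a table carries both `direction` and
  `log2fc` and they disagree in sign, reading fails: silent precedence in
  either direction would hide a corrupted table. A miRNA appearing twice
  in one compartment with conflicting calls is excluded from seed
  selection and reported, because there is no principled way to pick a
  side.
* **(id, class) target matching.** A target is matched in the ceRNA DE
  records by the pair (identifier, RNA class), since class identity is
  structural in these networks. If the identifier exists only under a
  different class, the interaction table's class wins and the mismatch is
  reported; if the identifier exists under its own class but with the
  wrong direction, the edge is simply dropped.
* **BH families per category.** Annotation categories (e.g. GO-CC,
  phenotype ontologies, tissue) answer different questions and are
  displayed separately, so each category is its own multiple-testing
  family. Terms with at least one query hit form the tested family;
  zero-hit terms have p = 1 by definition and would only dilute the
  correction.
* **Strength, not composite signal.** The 0.01 effect-size gate applies
  to strength = log10((k/n)/(K/N)). Composite scores blending FDR and
  strength are not reproducible from a threshold description alone, so
  the package uses the simple, documented quantity.
* **Jaccard + single linkage for grouping.** Term-grouping similarity is
  the Jaccard index of query-hit sets with single-linkage components,
  chosen for definability and determinism; group representatives are the
  lowest-FDR terms and group ids are numbered in representative order.
  Grouping runs over the full result of one `enrich()` call.
* **Connected nodes only.** Degree-0 miRNAs after filtering are excluded
  from exported node sets (network figures show connected components) but
  preserved in `droppedSeeds` and the JSON report.

## Numerical and determinism choices

* All member lists, node tables and edge tables are sorted with radix
  (C-locale) ordering, so outputs are byte-identical across platforms and
  reruns; the pipeline is a pure function of (config, input files).
* The hypergeometric tail is delegated to `stats::phyper(lower.tail =
  FALSE)`, which evaluates the upper tail directly; the test suite checks
  it against exact combinatorial enumeration for every parameter
  combination with universe size up to 60 at 1e-12 relative tolerance.
* Hypergeometric p-values are discrete and super-uniform: the attainable
  p just below a nominal level is strictly smaller than that level, and
  the gap closes only as term and query sizes grow. The null-calibration
  test therefore uses large terms (thousands of genes) where the
  attainable p-values are dense; with small terms the raw rejection rate
  at 0.05 is structurally below 0.05 — conservative, never inflated.
* Degenerate inputs are defined, not errors: empty seed sets produce
  empty networks with a warning; an empty interaction table puts every
  seed in `missingSeeds`; exporting an empty network yields a valid file
  with zero edges; `K = N` gives p = 1.
* GraphML cannot carry missing string attributes, so an unfiltered
  target's absent direction is written as the empty string and restored
  to `NA` on import.

## The synthetic-data generator

`genDETables()` plants known up- and down-concordant miRNA fractions,
assigns the remaining miRNAs deliberately non-concordant label pairs, and
draws tissue ceRNA directions so that the edges planted by
`genInteractionTable()` are polarity-consistent. Background interactions
are sampled per (miRNA, ceRNA) pair, excluding pairs that would pass the
polarity filter by accident — so in a noiseless run the filtered networks
equal the planted truth exactly, which is what makes end-to-end parameter
recovery a sharp test. Tissue labels can be flipped with probability
`noiseFlipProb` to study robustness. `genAnnotation()` plants one term
covering a configurable fraction of the planted network's genes.

Defaults (60 miRNAs, 10% concordant in each direction, 120 ceRNAs per
class, edge density 0.02, 3 planted edges per seed, 20 terms, 25-gene
planted term at 80% coverage) give desk-scale instances of a few hundred
interactions that exercise every code path in well under a second each;
the published analysis this emulates had 23 concordant miRNAs across two
stages against a genome-wide interaction space.

Expression means are drawn log-normally around class baselines only so
that mean ordering always matches the direction call; they carry no other
semantics. Three derived RNG streams (`rngSeed`, `+1`, `+2`) make each
generator reproducible standalone.

**What passing synthetic tests does not show:** the generator plants
clean, independent direction labels and class-balanced targets. Real DE
tables have correlated calls, library-size artifacts, identifier drift
between annotation releases, and CLIP tables have hub miRNAs with
thousands of targets. Recovery of planted structure validates the
machinery, not the biology of any particular dataset.

## The packaged worked example

`inst/extdata/table1` encodes the per-stage cortex miRNA direction calls
of the motivating amyloid-pathology mouse study, with published
normalized means (median-of-ratios scale) for the concordant miRNAs. The
EV-side table is *reconstructed*: only the concordant result is
published, so EV directions are the ones implied by the concordance rule,
plus non-concordant decoys; its expression means are synthetic. The
ceRNA, interaction and annotation files are synthetic stand-ins (named
`*_synthetic.*`) shaped to exercise the fixture end to end, including a
seed with no interactions at each stage. Seed-set contents and sizes —
5/2/10/6 across (stage × direction), with one miRNA shared by both
up-regulated sets — are recomputed by the test suite and by
`scripts/acceptance.R`; nothing downstream of seed selection in the
fixture reproduces in-paper network or term content.

## Known limitations

* Live interaction or annotation databases are out of scope; the package
  reads flat files only, and published figure-level term lists depend on
  database snapshots that flat fixtures cannot reproduce.
* The polarity filter is binary; partial or dose-dependent sponging is
  not modeled.
* Overlap significance of seed sets across stages is not tested
  (intersections are reported raw).
* One EV table serves all stages by design; stage-resolved EV data
  require separate runs.
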