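---
title: "Metaproteomic subgroup inference and strict-dominance biomarker screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaproteomic subgroup inference and strict-dominance biomarker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapro)
```

## The analysis problem

Shotgun metaproteomics of a stool specimen yields tens of thousands of
peptide-spectrum matches against a catalogue of millions of microbial
(plus human and contaminant) protein sequences. Because gut communities
are dense in homologous proteins, a peptide rarely identifies a single
database entry. The unit of analysis is therefore not the protein but
the **protein subgroup** ("metaprotein"): the set of catalogue entries
identified by exactly the same set of observed peptides, which the data
cannot distinguish. `metapro` implements the post-identification part
of such a study: subgroup inference under parsimony, quantification by
specific spectral counts, consensus taxonomic and functional
annotation, replicate-concordance QC, and a deliberately stringent
biomarker screen across clinical groups (healthy controls and three
inflammatory bowel disease phenotypes: ulcerative colitis and colonic
or ileo-colonic Crohn's disease).

The package consumes three plain tab-separated inputs: a peptide
evidence table (peptide, matched accessions, spectral counts per
sample), a per-accession annotation table (source, seven-rank lineage,
KEGG Orthology entries), and a sample sheet (sample, subject, clinical
group, fresh/frozen preparation). Spectrum-to-peptide matching, FDR
control and sequence alignment happen upstream and are out of scope.

## Subgroup inference

`infer_subgroups()` proceeds in well-separated steps:

1. **Validation.** An accession is retained when at least
   `min_peptides` (default 2) distinct observed peptides match it,
   pooled over all samples — one peptide in one sample and another in
   a different sample both count.
2. **Indistinguishability collapse.** Accessions with identical
   observed-peptide sets merge into one subgroup.
3. **Parsimony subsumption.** A subgroup whose peptide set is a strict
   subset of another's adds no explanatory power and is removed.
   Because equal sets have already merged, strict-subset removal is
   order independent and a single pass reaches the fixpoint (subset
   relations are transitive); the test suite asserts this under input
   permutation and against a brute-force oracle.
4. **Specific peptides.** A peptide observed in exactly one surviving
   subgroup is *specific* to it; specific peptides attest presence and
   drive quantification.
5. **No-specific-peptide drop.** Subgroups left without any specific
   peptide cannot be quantified or attested and are removed entirely,
   after which specificity is recomputed once over the survivors. The
   number of removal passes is configurable (`drop_passes`); the
   default is a single pass, which keeps the procedure bounded and
   deterministic. We chose dropping over keeping such subgroups
   unquantified because every downstream consumer requires specific
   counts.

Group identifiers are connected components of the surviving
subgroup–peptide graph; ids (`g0001.s01`) are assigned by sorting on
descending peptide count with a lexicographic accession tie-break, so
reruns on identical input give identical ids.

One subtlety uncovered during testing: the intuitive property "raising
`min_peptides` never increases the number of subgroups" is a theorem
for steps 1–3 (a removed small set can never make a retained set
non-maximal), but it can fail across step 5, because discarding a
peptide-sharing competitor at a higher threshold can *restore*
specificity to a subgroup that the lower threshold dropped. The
property test therefore targets the parsimony core.

## Quantification and aggregation

Subgroup abundance in a sample is the sum of the spectral counts of
its specific peptides; shared peptides never contribute (removing a
shared peptide provably leaves the matrix unchanged). Group-level
descriptive matrices divide pooled group sums by the number of samples
in the group, with fresh and frozen samples pooled. Taxon aggregation
sums subgroups within each taxon at a requested rank, binning
subgroups whose consensus is shallower as `unclassified`, so column
totals are conserved at every rank (and normalization and aggregation
commute — asserted by test, since the order is not dictated by the
procedure). KO aggregation deliberately multi-counts: a subgroup
annotated with *k* KOs contributes its full abundance to all *k* rows,
so KO totals are not conserved and are documented as such.

## Consensus annotation

Per-protein annotations (best-bit-score taxonomy, KO assignments) are
an input. A subgroup's consensus rank is the deepest rank at which all
members agree, comparing trimmed strings case-sensitively — dialect
normalization belongs to the annotation producer, not this package.
Functional (KO) annotation applies only to subgroups whose members
share the full species-level assignment; below that gate the KO set is
empty. Unannotated accessions are completed with an empty microbial
lineage rather than dropped: they can then never reach a consensus,
which is the conservative behaviour.

## Concordance and group statistics

Each subject contributes a fresh and a frozen sample of the same
specimen; strong Pearson correlation between the two full abundance
profiles justifies deferred (frozen) diagnostics. Correlations are
computed on raw counts by default (a `log1p` option exists) because
the dominant high-abundance subgroups are exactly what a diagnostic
assay would see; the working concordance threshold is r > 0.9.
Clustering of the correlation matrix uses average linkage on
d = 1 − r with columns pre-sorted by sample id, making the merge tree
independent of input order; the tree is exported as Newick text.
Group comparisons of diversity metrics use two-sided Wilcoxon
rank-sum tests — exact when both arms have at most 25 tie-free
observations, otherwise the tie-corrected normal approximation without
continuity correction — with Benjamini–Hochberg adjustment within each
metric's family of pairwise comparisons at a 0.05 threshold.

## The strict-dominance screen

With few subjects per group, distributional tests on 2,000+ subgroups
have little power and fragile assumptions. The screen instead demands
**strict dominance**: subgroup *s* is a hit for contrast (A, B) when
every sample of A strictly exceeds every sample of B (over), or
strictly falls below it (under). Ties never qualify — in particular a
subgroup absent from both sides is never a hit — and fresh and frozen
samples enter as ordinary members of their side, so a single
discordant replicate vetoes a candidate. The screen runs on raw
per-sample counts: dominance is invariant under any monotone
transform, so normalization could not change the result.

The staged strategy mirrors clinical triage: first all IBD versus
controls, then ileo-colonic Crohn's versus the pooled other IBD
phenotypes (annotating which of those hits also dominate when controls
join the comparison side), then colonic Crohn's versus ulcerative
colitis. Stages are independent screens over the full matrix, not
residual filters, so one subgroup may legitimately appear in several
lists. Hit matrices are exported for heatmaps as natural-log counts
(pseudocount 1, the conventional choice for spectral counts) centred
per row, and each hit carries its specific peptides ranked by total
spectral count — the proteotypic payload a targeted assay would start
from.

## The synthetic-data generator

Raw spectra cannot be reprocessed at desk scale, so the generator
produces complete, ground-truthed inputs with the statistical
structure the analysis assumes:

* **Design.** 8 CTRL, 3 CDC, 2 CDIC and 7 UC subjects, two
  preparations each — 40 samples, the study design being emulated.
* **Catalogue.** 31 gut species across five phyla (Firmicutes,
  Bacteroidetes, Proteobacteria, Actinobacteria, Verrucomicrobia) with
  full seven-rank lineages, 60 random tryptic-friendly proteins per
  species (~210 residues, cleavage-site frequency ≈ 10%), 150 human
  proteins and 15 contaminants. In-silico digestion allows one missed
  cleavage and keeps peptides of ≥ 6 residues, and the catalogue is
  collision-checked so that, absent planted homology, no peptide maps
  to two proteins. A configurable fraction (default 15%) of microbial
  proteins is duplicated under a new accession with a species drawn
  from the same genus: the duplicate shares the entire peptide set,
  creating the indistinguishable pairs (and genus-level consensus
  cases) the inference must handle.
* **Counts.** Per-family log-normal baselines (median 12 counts,
  sdlog 1.2) × group effects × a subject-level latent factor
  (sdlog 0.3) shared by the subject's two preparations × small
  preparation noise (sdlog 0.05) × per-sample depth (sdlog 0.15),
  split across peptides by Dirichlet-like detectability weights, with
  negative-binomial counting noise (size 15; `Inf` switches noise off
  entirely, giving counts equal to rounded expectations). These
  choices were fixed once so that paired fresh/frozen profiles
  correlate strongly (r ≈ 0.98) while distinct subjects do not —
  the regime the analysis assumes.
* **Planted structure.** Group-level shifts emulate the reported
  biology (Proteobacteria ×2.5 in ileo-colonic Crohn's, human
  proteins ×2 in patients, Firmicutes ×0.6 in patients). Separately,
  seven biomarker families are planted with strictly separating
  profiles (fold 5, or structural absence for the under-represented
  control-only pattern). Rejection sampling makes the ground truth
  exact in the realized counts: each planted family is redrawn until
  it separates with the configured margin in its own stage and in no
  other, and every *other* family is redrawn — subject effects
  included, so the redraw changes its expectation, not just its noise
  — until it strictly separates nowhere. Without that mirrored
  negative control, the CDIC bloom alone produced dozens of accidental
  strict separators (2 CDIC subjects give the dominance criterion very
  little to veto with), and "the planted set" would not be a
  well-defined truth for precision/recall.

What the generator does **not** emulate: peptide modifications and
misassignment, correlated protein co-expression within a taxon,
compositionality of spectral counting, batch effects, and catalogue
incompleteness. Passing tests on synthetic data therefore demonstrate
algorithmic correctness against a known truth, not clinical validity
of any marker.

## Problem sizes and determinism

The default configuration generates ~2,300 catalogue proteins,
~60,000 observed peptides and ~2,000 quantified subgroups across 40
samples; a full simulate-infer-annotate-quantify-screen run takes well
under a minute on one core, and the oracle-equivalence test batteries
use 200 random bipartite instances (≤ 10 proteins × ≤ 15 peptides) and
100 random count matrices. All randomness flows from a single integer
seed; the pipeline itself is deterministic given its inputs, reruns
are byte-identical, and the run manifest records input/output
checksums and per-stage row counts.

## A worked example

```{r example, eval = FALSE}
library(metapro)

cfg <- default_sim_config(seed = 17)
sim <- simulate_dataset(cfg, out_dir = "sim")

inference <- infer_subgroups(sim$evidence)
ann <- annotate_subgroups(
  inference, resolve_annotations(sim$evidence,
                                 sim$catalogue$annotations))
ab <- subgroup_abundance(sim$evidence, inference)

pairs <- flag_discordant_pairs(pearson_matrix(ab), sim$sheet)
hits <- iterative_screen(ab, sim$sheet)
report <- proteotypic_report(hits, inference, sim$evidence, ann,
                             sim$sheet)
```

## Known limitations

* Probabilistic protein inference, razor-peptide and intensity-based
  quantification are out of scope by design.
* The no-specific-peptide drop runs a single pass by default; a
  pathological chain of mutually shared peptides could leave a
  specificity-less subgroup after the final recomputation (raise
  `drop_passes` if that matters for a dataset).
* The strict screen has no error model: with very small groups its
  false-discovery behaviour is controlled only by the all-samples
  requirement itself, which is why it is paired with a decision-tree
  style report rather than p-values.
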