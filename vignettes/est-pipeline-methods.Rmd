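---
title: "Methods: comparative EST analysis with planted ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative EST analysis with planted ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Expressed sequence tag (EST) surveys of non-model organisms — here,
charophyte green algae, the lineage from which land plants arose — ask a
comparative question: which genes does the organism share with a land
plant, which with the sister chlorophyte lineage, and which look like
nothing sequenced before? `estpipe` re-implements that analysis as a
tested pipeline: hybrid Sanger/454 reads are cleaned and clustered into
unigenes, coding regions are predicted with a hexamer model, unigenes
are screened against labelled reference proteins for taxonomic binning,
ortholog sets are built from reciprocal best hits (RBH) across four
taxa, putative novel genes are flagged, a curated gene panel is
screened, and GO annotations are transferred and compared at ontology
level 3 with Fisher's exact test.

Because the historical raw data and period databases are not
reproducible at desk scale, the package centres on a synthetic-data
module that generates the whole study design with machine-readable
ground truth, so every stage is tested against planted answers rather
than against irreproducible archival numbers.

# The synthetic study design

`generator_params()` encodes the study conditions:

* **Four taxa on a fixed topology**
  `((ref_plant,(charoA,charoB)),ref_chlorophyte)`, with per-branch
  substitution rates (subs/site) of 0.05 (streptophyte stem), 0.15
  (plant terminal), 0.05 (charophyte stem), 0.08 per charophyte
  terminal and 0.35 (chlorophyte terminal). These place the charophytes
  much closer to the plant (about 0.28 subs/site) than to the
  chlorophyte (about 0.53), so "shares more orthologs with the plant"
  is a planted, checkable property rather than an empirical claim.
  At these rates the realised protein identities are roughly 60–75%
  charophyte–plant and 45–50% charophyte–chlorophyte, comfortably
  inside the sensitivity of the seeded aligner.
* **Codon-level evolution.** Each family starts from an ancestral CDS
  sampled from a biased codon-usage distribution (one preferred codon
  per amino acid, weight 8:1, GC-tilted to the taxon target by an
  exponential-tilt parameter solved so the expected GC equals the
  target). Substitutions are single-nucleotide codon neighbours
  weighted 3:1 synonymous:nonsynonymous; among synonymous alternatives
  the preferred codon is favoured, making the usage bias — and hence
  the hexamer coding signal — stationary under divergence. Stops are
  never created; the terminal stop codon is a family property.
* **Per-taxon GC targets** default to 0.49 and 0.41 for the two focal
  charophyte-like taxa (the observed contrast between a Coleochaete-
  and a Spirogyra-like library), 0.44 and 0.52 for the references.
  With the exponential tilt the realised GC of ≥ 1 Mb of generated
  sequence sits within ±0.02 of the target.
* **Transcripts** are 5′ UTR + CDS + stop + 3′ UTR (mean UTRs 80/150
  nt; mean CDS 250 codons). A configurable fraction (default 20%,
  within the 16–25% range such surveys report) of transcripts is
  non-coding: iid bases at the taxon GC target, so they carry no
  hexamer signal relative to the background model by construction.
* **Reads.** Sanger reads are long (mean 915 nt, the observed raw
  Sanger average), low-error and 5′-anchored on the sense strand; 454
  reads are shorter (mean 378 nt, the GS FLX Titanium average), start
  uniformly, come off either strand, carry a library adapter, and make
  ±1 errors in homopolymer runs of length ≥ 3 at a per-run rate
  (default 0.01). Quality strings are emitted per base but are not
  indel-realistic — a stated non-goal.
* **Contaminants** (default 10% of reads, the upper bound such surveys
  estimate) come from a labelled pool of coding-like source genes in
  five categories (Bacteria, Fungi, Viruses, Archaea, other
  Eukaryotes), each with a full lineage path so taxonomy binning can
  recover the planted category. The injected count is
  `Binomial(n_reads, fraction)`, i.e. the fraction is interpreted
  relative to the genuine read count.
* **Expression heterogeneity** is modelled as a per-transcript
  lognormal depth weight only; a multi-condition design is out of
  scope.
* **Determinism.** One global seed fans out to per-stage child seeds by
  hashing stable stage tags (`child_seed()`), so identical parameters
  and seed give byte-identical outputs, including the truth tables.

What passing tests on these data do *not* show: robustness to
chimeras, vector contamination, flowgram-specific 454 error structure,
paralog-rich gene families beyond the simple duplication model
(default rate 0.05), or the database-coverage biases of a real
taxonomy screen.

# Stage models and numerical choices

**Read cleaning.** Adapters are removed by ends-anchored approximate
matching (Hamming distance, default ≤ 2) — adapters are ligated at read
ends, so a full alignment search is unnecessary. Quality trimming is a
single sliding-window rule (window 20, mean-phred floor 15) applied
from both ends, followed by a 60 nt length filter; the historical
pipeline chained several tools without published parameters, so these
defaults are declared, not reconstructed. Low-complexity masking is a
DUST-style triplet score (sum of `c(c-1)/2` over triplet counts divided
by the triplet positions in the window; window 64, threshold 2.0,
half-overlapping windows); masked bases are lowercased, excluded from
clustering seeds, but retained in the sequence.

**Clustering.** The classic acceptance rule — at least 100 aligned
columns at ≥ 95% identity, identity computed over the overlap region
only (the rule is ambiguous between overlap-region and whole-read
identity; the overlap-region reading is adopted and flagged here) —
drives a greedy longest-first, first-accept incremental clusterer.
Candidate overlaps come from shared 12-mers; the best diagonal band
(half-width 20) is aligned with free end gaps (match +1, mismatch −2,
gap open 3, extend 1). The consensus is a per-column majority over
aligned members with ties keeping the incumbent base (order-stable
determinism); read insertions relative to the consensus are dropped,
end overhangs extend it. This is deliberately simpler than a full
overlap-layout-consensus assembler: deterministic and adequate at desk
scale, with both assembly steps (454-only, then combined with Sanger)
using the same clusterer and thresholds. Provenance follows the
two-step design: final clusters with ≥ 2 step-2 members are contigs;
lone items are 454-only contigs, 454 single reads, or Sanger-only
singletons — the three singleton classes such surveys tabulate.

**Coding prediction.** A phase-aware hexamer log-odds table (4096 × 3,
pseudocount 1) is trained from a supplied CDS set against a phase-free
background — the package trains on the plant reference's CDS, standing
in for a fixed published score matrix. Prediction is a dynamic program
over three frame states per strand: each position contributes the
log-odds of its hexamer at the phase implied by the state; frame
switches pay a penalty (default 20) — a deliberate collapse of explicit
insert/delete HMM states into one parameter, enough to tolerate the
single-base 454 homopolymer errors; in-frame stop codons pay 100
(consensus errors can create stops, so they are penalised, not
forbidden). The best local segment wins per strand, the better strand
wins overall; verdicts fall to "none" below score 40 or segment length
150 nt. These two thresholds have no published counterpart and were
fixed at design time against the generator's score distributions
(planted CDS score in the hundreds, non-coding maxima around 40 with
segments under 150 nt). The reported frame is the dominant (modal)
frame of the path, since an optimal path occasionally prepends a short
spurious UTR segment in another frame. Translation emits `X` at frame
switches. Non-nucleotide symbols contribute zero.

**Homology search.** Exact amino-acid 4-mer words seed diagonals; a
diagonal with two seeds within 40 positions is extended by banded
(half-width 32) affine-gap local alignment under BLOSUM62 (gap open 11,
extend 1). Raw scores convert to bit scores and E-values with fixed
Karlin–Altschul constants λ = 0.267, K = 0.041 and `E = K·m·n·e^(−λS)`
with m the query length and n the summed subject length. Three
simplifications are documented biases: fixed constants rather than
per-search estimation, no effective-length correction, and exact (not
neighbourhood) seed words — all acceptable because every use-site
threshold in the analysis is coarse (10⁻⁴ to 10⁻²⁰). A full
Smith–Waterman (`smith_waterman()`, guard 2000 residues) serves as the
in-package oracle; the suite checks the banded score equals the exact
optimum whenever a two-hit seed exists. Translated searches run all six
frames and report the best, with coordinates mapped back to the
nucleotide query. Self-hits are retained in search output and excluded
at the orthology stage — one exclusion point.

**Orthology.** Per species pair, an RBH edge requires mutual top hits
below 10⁻⁶, with a fixed top-hit tie-break cascade (min E, max bit
score, max identity, lexicographically smallest subject) so best hits
are unique. Multi-species ortholog sets are pairwise-complete cliques.
How genes that fit several candidate sets were historically resolved is
unstated; the package assigns each gene its maximum-size valid set,
breaking ties by summed bit score and then lexicographic species-subset
order — deterministic and verified against exhaustive enumeration. The
Venn partition counts genes (not sets) per species-subset region,
because the additivity statement — per-species region counts sum to the
species total — only holds under the partition-by-gene reading; the
pipeline enforces that additivity as a hard gate. Unassigned paralogs
fall to the species-only region.

**Taxonomy, novelty, panels.** Lineage binning uses the translated
nucleotide unigenes (not predicted peptides, for fidelity to how such
screens are run) against a labelled protein set at E < 10⁻⁴; the top
hit's lineage string is matched against category tokens
most-specific-first (Viruses → Archaea → Bacteria → Fungi → Chlorophyta
→ Streptophyta → other Eukaryotes) because lineage paths contain
multiple category tokens; where the "other Eukaryotes" boundary lands
(e.g. metazoan hits) is our codification by that precedence rule. A
unigene is *novel* iff it has a predicted coding region and no
significant hit at the taxonomy cutoff — the novelty threshold is
deliberately tied to the taxonomy screen's 10⁻⁴, since that is the
screen "no hits" refers to. NoHit without coding is classed
noncoding-or-contaminant. Panel screening is a translated search at
E < 10⁻²⁰ reporting per-panel-gene hit counts and E-value ranges.

**GO enrichment.** Annotations transfer from the single top reference
hit at E < 10⁻⁶ (full term set inherited; multi-hit mapped-group
transfer is a stated simplification away from the historical tool).
The ontology loads from OBO 1.2 with `is_a` edges only (`part_of`
excluded as the conservative approximation of the default graph), the
root counting as level 1 so "level 3" means grandchildren of the root —
the alternative root-is-0 convention was rejected to match the tool
convention the analysis followed. Terms at level ≥ 3 contribute to all
their level-3 ancestors, once per gene. Significance is a two-sided
Fisher's exact test summing hypergeometric tables no more probable
than the observed one (implemented on `dhyper` with the standard
(1+10⁻⁷) tie tolerance; verified against literal binomial-coefficient
enumeration for all margins ≤ 30); stars are `*` p < 0.01 and `**`
p < 0.001 on raw p-values — no multiple-testing correction is applied
to the stars, matching the reporting style, though a Bonferroni column
is emitted alongside.

# Problem sizes

The suite and the acceptance script run everything from scratch on one
CPU. Sizes were chosen as the smallest that make the properties
non-vacuous: the shared fixture uses 60 gene families (~190 proteins,
~870 kb of transcript); the end-to-end pipeline test uses 15 families
at read depths 1.5×/3.5× (Sanger/454); the directional-orthology check
runs 20 replicates of 40 families; the GC-concentration check generates
≥ 1 Mb; Fisher enumeration is exhaustive for margins ≤ 30. A full
pipeline run at these sizes takes under a minute; the whole suite a few
minutes.

# Known limitations

* The clusterer is first-accept greedy, not globally optimal; highly
  repetitive reads can merge through a masked region's flanks.
* E-values are approximate (fixed λ/K, no length adjustment); they are
  used only against coarse thresholds.
* The coding DP has no explicit insertion/deletion states, so a
  frameshift's exact position within a homopolymer run is arbitrary.
* Single-top-hit GO transfer understates annotations relative to
  mapped-group transfer.
* The generator's contaminants are free of homology to the references
  by construction; a real nr screen faces conserved-domain hits that
  the precedence rule can only approximate.
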