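---
title: "Methods: how planthgt detects and assesses microbe-to-plant HGT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how planthgt detects and assesses microbe-to-plant HGT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`planthgt` packages the inference chain behind genome-mining surveys of
horizontally transferred abiotic-stress-resistance genes in plants:
taxonomy-aware screening of homology evidence, phylogenetic verification,
codon-adaptation scoring, and structural fold comparison, with a planted-HGT
simulator that makes the whole chain falsifiable. This vignette records the
models, the tunable parameters, and the design decisions that were genuinely
open, so a maintainer can see *why* the code is the way it is.

## The screening rule

The screen consumes BLAST outfmt-6 hit tables annotated with subject
lineages. A hit is *outside* the recipient lineage when the two lineages do
not share a name at the **boundary rank**. Published descriptions of such
screens say "distant phylum, class, etc." without committing to one rank, so
the boundary is a configuration knob, defaulting to **phylum** — the most
inclusive rank at which "microbe vs plant" is still meaningful and the rank
at which donor taxa are conventionally reported.

With `T` the best-hits set of the filtered table, a gene is a candidate iff
*(best hit of `T` is outside OR the outside fraction of `T` strictly exceeds
0.90)* AND *no within-lineage hit anywhere in the filtered table scores at
least the best outside bitscore*. Decisions that needed fixing:

* **The denominator of ">90% of the best hits"** is ambiguous: we provide
  two top-set modes, `top_n` (default 50, mirroring top-hit-list semantics
  of BLAST reports) and `bitscore_fraction` (all hits within 95% of the
  maximum bitscore), with `top_n` the default.
* **Strictness**: the majority condition is a strict `>` at 0.90, so a
  table whose top set is exactly 90% outside does not pass on majority
  alone.
* **Dominance is global**: "lower-scoring hits or no hits within the
  lineage" is read as a statement about the *whole* filtered table, not the
  top set; an inside hit tied with the best outside hit vetoes the call.
* **Tie-breaking**: equal bitscores sort by ascending E-value, then
  lexicographic subject id. Every verdict is therefore independent of input
  row order, which the tests check by permutation.
* **Self-exclusion**: hits sharing the recipient's name at species rank
  (configurable up to genus) are dropped before screening, removing the
  gene's own genome from its evidence.
* **Unannotated subjects** (no name at the boundary rank) count as *inside*
  by default: an unannotated taxon should not be able to create an HGT
  call. The policy is invertible per configuration.

One structural consequence worth knowing: because the top set is a prefix of
the bitscore-sorted table, dominance can never hold while the best hit of
the top set is inside — two corners of the `(best, majority, dominance)`
truth table are unrealizable, and the tests assert both the behaviour of the
six feasible corners and the impossibility of the other two.

Lineage strings such as `"Bacteria; Proteobacteria; Gammaproteobacteria"`
are parsed positionally onto a domain–phylum–class–…–species ladder. The
kingdom rank is deliberately absent from the default parse ladder: donor
taxon notation in this literature runs domain;phylum;class and never carries
a kingdom field. Nonstandard grouping fields ("FCB group", "Terrabacteria
group") are accepted at their position and flagged, not rejected, because
real donor strings are heterogeneous. Empty fields keep their position, so
partially annotated lineages stay aligned.

The **alien index** `AI = ln(e_in + 1e-200) − ln(e_out + 1e-200)` is a
corroborating diagnostic only; the epsilon keeps zero E-values finite, and a
side with no hits contributes `e = 1` so that "no inside evidence" yields a
large positive score.

## The nesting test

Qualitative statements like "nested within bacterial sequences" become a
measurement: from the smallest clade containing the focal leaves, ascend
until the clade holds at least `m` non-focal leaves, then measure the
foreign fraction of those neighbours and the minimum support along the path.
Defaults: `m = 5` (smaller neighbour sets are noise-prone), `theta = 0.8`
(a clear foreign majority without demanding perfect exclusivity),
`s_min = 70` (a conventional bootstrap credibility floor — the literature
this serves reports "well-supported" trees without naming a cutoff, so the
floor is a knob). Raising `theta` or `s_min` can only lose nested verdicts,
which the tests check as a monotonicity property.

Support scales are auto-detected (any value above 1 implies percentages; a
fractional-scale tree with `s_min = 70` has the threshold divided by 100).
Unrooted trees with branch lengths are midpoint-rooted — published trees
are displayed rooted but the rooting method is rarely stated, and midpoint
rooting is reproducible without an outgroup annotation. Reaching the root
with fewer than `m` non-focal leaves yields `indeterminate`, never an
error.

## Codon adaptation

The reference-weight table follows the classic recipe: pool codon counts
over the highly expressed reference set (the EF-Tu convention), then
`w_ij = x_ij / max_j x_ij` within each synonymous family. Codons unobserved
in the reference receive a pseudo-count of **0.5 before division** — the
standard repair that keeps every weight positive and every log finite. ATG,
TGG and the three stops are excluded (the usual convention; they carry no
synonymous choice), leaving the 59 informative codons of the standard
nuclear code; other genetic codes are selectable by table id. CAI is the
geometric mean of weights over a gene's scorable codons, computed in log
space; ambiguous triplets are skipped and tallied, a trailing partial codon
warns, and a gene with no scorable codon is an explicit error rather than a
silent zero.

## Structure comparison

Superposition is the SVD form of the Kabsch solution with the determinant
sign correction, so reflections are never returned and collinear traces
stay well-defined. The TM-score uses
`d0 = max(1.24 (L − 15)^(1/3) − 1.8, 0.5)` Å (the 0.5 Å floor is the
small-protein convention) and the iterative-trim schedule: superpose on all
pairs, repeatedly keep pairs closer than `max(d0, 4.5)` Å, re-superpose and
re-score *all* pairs, stop when the kept set converges (at most 20
iterations), and report the maximum score seen. The full dynamic-programming
alignment search of TM-align is deliberately **not** re-implemented: in the
workflow this package serves, alignments come from upstream tools, and the
score on a given correspondence is the testable core. Because which chain
normalizes a published TM-score is often unstated, both normalizations are
available (`L_norm_mode` in the pairwise table; the default is the second,
donor-side trace).

## What the simulator emulates — and what it does not

`simulate_world()` builds the study conditions end to end: a Yule species
tree with three marked top-level clades (recipient plants, microbial
donors, an outgroup), one codon-bias profile per clade (one preferred codon
per synonymous family, used with probability `b + (1−b)/n_i`, default
`b = 0.8` — strong but not deterministic bias), homolog families whose
proteins accumulate Poisson substitutions along the tree
(`divergence_scale = 0.3` substitutions/site per unit branch length, which
places within-clade identities around 70–85% and cross-clade identities
near 40–45%, i.e. clearly separated hit strata), and planted HGT events
that replace a recipient gene with the donor's gene. Hit evidence is
synthesized from observed amino-acid identity through fixed
Karlin–Altschul-style constants (`lambda = 0.267`, `K = 0.041`) rather than
by running an aligner: deterministic, dependency-free, and monotone in
identity, which is all the screen consumes. Gene trees are emitted as truth
with fixed supports (default 95, jitterable to probe `s_min`), with the
planted leaf grafted as sister to its donor.

**Amelioration is synonymous-only.** The parameter `a` re-samples a
fraction of the transferred gene's codon positions under the recipient's
profile, using one uniform draw per position so the recoded sets are nested
across an `a` grid (exact monotone coupling — the Spearman checks measure
the model, not sampling noise). Because amelioration does not touch the
protein sequence, the protein-level screen's sensitivity is constant in
`a`; it is the CAI signal that decays. That is the faithful reading of
codon amelioration, and it means the benchmark's "sensitivity is
non-increasing in `a`" property holds trivially at the protein level while
the interesting decay shows up in the expressivity stage.

What passing these tests does **not** show about real data: the simulator
has no indels or gapped alignments (identity and scores are closed-form on
equal-length genes), no codon-substitution model (GY94-style processes are
out of scope), no rate heterogeneity across sites, no gene loss or
duplication, no contamination, and its lineages are clean three-clade
worlds rather than the tangled taxonomies of real databases. The benchmark
quantifies the *logic* of the pipeline under its stated model, not BLAST or
PhyML behaviour.

Default problem sizes — 6 recipient, 8 donor and 8 other taxa, 100
families of 200-residue proteins, 10 planted events, seed 42; 200-family
worlds for the nesting calibration — were chosen as the smallest worlds in
which all three clades have non-trivial internal structure and rates are
estimated on a few hundred decisions, and they keep a full benchmark run in
tens of seconds on one core.

## Degenerate inputs and determinism

Empty hit tables, tables left empty by filtering, genes with no outside
hits, and trees whose root is reached early all produce well-defined
non-candidate / indeterminate results, never exceptions. Every stage output
is materialized as TSV with a header recording the package version, a hash
of the scientific configuration (deliberately excluding the output
directory) and the seed; two runs with identical inputs and seed are
byte-identical, which the tests enforce. The manual-curation step that a
human would perform on product descriptions is mechanized as an editable
keyword lexicon with a fixed category precedence (metal before
osmotic/drought before heat/cold before oxidative before acid/pH before DNA
damage/UV before organic pollutant) and an `uncategorized` bucket —
reproducibility over curator judgment; the precedence order resolves real
ambiguities such as "Acid phosphatase" (a metal-immobilizing secreted
enzyme, not an acid-stress gene) and "Heat shock protein. Metallo
peptidase" (heat/cold, despite the metallo- prefix).

## Known limitations

* The screen sees only what the hit table contains; database composition
  biases (over-represented clades inflating the top set) are the caller's
  responsibility.
* The nesting test assumes the focal leaves' placement is the only
  question; it does not model incomplete lineage sorting or long-branch
  attraction, and it consumes one tree per family rather than a posterior
  sample.
* CAI against a single reference set cannot separate expression level from
  mutational bias; the package reports the index, not an expression claim.
* TM-scores on a fixed correspondence underestimate similarity when the
  true alignment differs from the given one.
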