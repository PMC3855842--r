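---
title: "Consensus annotation integration: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus annotation integration: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prokannot)
```

# The problem

A draft microbial genome arrives with evidence from many tools that do not
agree: three ab initio predictors call overlapping but different CDS sets,
RNA finders report rRNA/tRNA genes, homology searches against several
protein databases return ranked hit tables, and a domain scanner adds
signatures, InterPro accessions and GO terms. This package integrates that
evidence into one annotation and provides the bookkeeping around it:
taxonomy sanity checks per contig, hierarchical summaries, enrichment
statistics for gene lists, and a benchmarking metric for comparing two
annotations of the same sequence.

Everything operates on a single internal representation — one row per gene
call with 1-based inclusive coordinates — and the format readers/writers own
all coordinate-convention handling (GFF3 is already 1-based inclusive; NCBI
TBL writes minus-strand features with reversed coordinates). Keeping one
convention internally removes the dominant off-by-one bug class.

# Consensus gene calling

## Model

Prokaryotic gene callers disagree mostly about start codons, rarely about
stops: alternate upstream/downstream ATG/GTG choices move the 5' end while
the reading frame pins the stop. We therefore cluster calls by the key
*(contig, strand, stop coordinate)* — `end` on the plus strand, `start` on
minus — and emit one consensus gene per cluster:

1. each predictor contributes one candidate start per cluster;
2. the start with the most predictor votes wins;
3. a vote tie resolves toward the longest ORF (the conservative choice:
   a longer ORF contains the shorter candidates);
4. any remaining tie would fall to a configured predictor priority order.
   With distinct numeric candidates the longest-ORF rule is already unique,
   so this branch is documented but effectively unreachable for CDS
   clustering; it exists so the procedure is total by construction.

The result is deterministic and invariant under permutation of predictors
and of call order, which the test suite asserts directly.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `min_cds_len` | 90 nt | minimum consensus CDS (30 aa), a common small-ORF floor below which ab initio calls are mostly noise |
| `orphan_policy` | `keep` | whether single-predictor clusters survive |
| `max_rna_overlap` | 0 nt | tolerated CDS overlap with an RNA gene |
| `predictor_priority` | input order | final tie-break order |

RNA genes have absolute precedence: the rRNA/tRNA calls are unioned into a
per-contig mask (merged with interval arithmetic from IRanges), and any CDS
whose overlap with a mask interval exceeds `max_rna_overlap` is removed —
RNA genes are never removed. Because only predictor *outputs* are inputs
here, RNA precedence is implemented as a post hoc filter on predictions
rather than by masking the sequence before prediction; for downstream
results the two formulations are equivalent.

# Product assignment

For each CDS the databases are scanned in precedence order (default
`uniprot > nr > kegg > cdd`, mirroring the usual search narrative). Within a
database, hits are ranked by (bit score desc, e-value asc, subject id asc) —
a total order, so ties cannot make results depend on input order — and the
best hit passing all of e-value ≤ 1e-5, identity ≥ 30 % and query coverage
≥ 0.5 (when coverage is computable) with a *non-hypothetical* cleaned name
wins. Names are cleaned first (strip `MULTISPECIES:` and `RecName: Full=`
prefixes, trailing `[organism]` brackets, UniProt `; EC=...` tails, collapse
whitespace) so database formatting never leaks into products. If every
eligible hit is hypothetical, the best InterPro-integrated domain supplies a
`<signature>-family protein` name; then the best passing hit's name even if
hypothetical; the floor is `hypothetical protein` with source `none`.

The hypothetical vocabulary (`hypothetical`, `uncharacterized/-ised`,
`unknown function`, `predicted protein`, `DUF`) is configuration, shipped as
a default so results are reproducible. Functional + orphan always equals the
number of assignments, and loosening the e-value threshold can only grow the
functional count (a monotonicity property in the tests).

An open accounting question is whether RNA genes count as "functional" in
genome-level totals; the default tallies CDS only, with
`count_rna_functional = TRUE` folding RNA genes in when a total over all
gene calls is wanted.

# Contig taxonomy voting

Each gene votes once: the species of its top-ranked homology hit (explicit
species column when present, otherwise the last `[...]` bracket of the
subject description; optional truncation to the binomial, with a three-token
rule for *Candidatus* names). Per scope — contig or genome — species are
ranked by votes, and a vote tie is broken by the **total alignment length
summed over all of that species' hits among the scope's genes**, not just
the top hits. That reading is what makes an alignment-length tie-break
meaningful at all: the below-top hits only enter through it. A residual tie
falls back to lexicographic order so the ranking is total and deterministic.
One designated homology table is used (default label `nr`); pooling across
databases would double-count evidence of correlated searches.

# Summaries and enrichment

*Hierarchies.* Any per-gene assignment of root-first lineage paths (COG
categories, GO slims, taxonomy) builds a tree whose node counts are
**distinct genes** in the subtree — a gene reached by two paths through a
node counts once there. The flattened form (one `count TAB path...` row per
leaf, lexicographically sorted) is Krona's text import format.

*Completeness.* The observed fraction of a supplied archaeal/bacterial core
COG list, as a percentage rounded to 2 decimals half away from zero. The
package ships no canonical core list; completeness is only meaningful
relative to the list the user supplies.

*Pathways.* Naive KO-membership counting: a gene counts once per pathway
reachable through any of its KOs. No parsimony-based pathway inference is
attempted, deliberately — the counts are labelled as membership tallies. The
canonical KEGG highlight URL (`show_pathway?mapNNNNN+K...`) is built from
the sorted, deduplicated KO set so equal sets give equal URLs.

*Enrichment.* Upper-tail hypergeometric probability `P[X >= k]` computed via
`stats::phyper`, adjusted by Bonferroni or Benjamini–Hochberg via
`stats::p.adjust`. The tests pin the tail against an exhaustive enumeration
of all `C(N, n)` draws for every configuration with `N <= 12`, and the
worked example (`N=20, K=5, n=5, k=3` → `1126/15504`) against an exact
combinatorial sum, to 1e-12.

# Benchmarking two annotations

Reference genes are partitioned into *identical* (both coordinates exact),
*similar* (start **or** stop within the offset, default 50 bp) and *not
detected*. Three decisions make the footnote-style rule operational:

- **"Same region"** means same contig, same strand, same feature type, and
  at least 1 nt of overlap. Without the overlap requirement a gene 10 kb
  away with a coincidentally equal start offset would count as similar.
- **"Start or stop"** is a logical OR: a shared stop with a start shifted
  beyond the offset is still similar. A corollary worth knowing: at
  `offset = 0` a shared-stop pair with a shifted start is still similar,
  because one of its deltas is 0.
- **Matching is one-to-one**, so false negatives (unmatched reference) and
  false positives (unmatched test) are well defined. Identical pairs are
  matched first; the remaining similar-eligible pairs are resolved by
  maximum-cardinality bipartite matching (igraph), with weights arranged so
  that cardinality dominates, total coordinate shift is minimized second,
  and the leftmost reference gene is preferred third — fully deterministic.
  The tests verify the matched count equals a brute-force enumeration of
  injective assignments on hundreds of small random instances.

Percentages are reported on the reference total, rounded to 2 decimals half
away from zero, and the three categories always partition the reference set.
`comparison_report()` also accepts bare category counts, so published count
tables can be turned into percentage reports without re-deriving a matching.

# Synthetic data: what it emulates and what it does not

The generator places non-overlapping genes sequentially along contigs with
intergenic gaps of 100–300 nt, CDS of 300–1500 nt (multiples of 3, ATG/TAA
written into an otherwise uniform-random sequence), and a handful of RNA
genes (16S/23S/5S, then tRNAs). Default study conditions: 50 genes on 2
contigs, of which 5 RNA; perturbation of 5 frame-preserving start shifts
(multiples of 3 up to 50 nt, inward so the shifted gene stays inside the
original and the "same region" clause is guaranteed), 3 deletions, 4
insertions placed strictly inside intergenic gaps so they can never match
anything; homology tables of 1–5 ranked hits per CDS with a 70/30 species
mixture on the top hit and a 0.3 hypothetical-name fraction drawn per gene
(per gene, not per hit, so an all-hypothetical gene stays hypothetical
through every fallback). Because shifts are frame-preserving multiples of 3,
the generator requires `max_shift >= 3` whenever shifts are requested.

By construction the benchmark on a perturbed fixture must read
`(n-k-m, k, m, j)`; the acceptance tests check that identity across 20
seeds, and the planted 0.7 species majority is recovered genome-wide on 100
genes across 20 seeds (a 0.7 binomial majority fails with probability
~1e-5 per seed, so recovery is expected every time).

What the generator does **not** emulate: codon usage and GC structure (no
stage here reads codon statistics), overlapping genes on opposite strands,
partial genes at contig edges, realistic phylogenetic hit correlation, or
database-version noise. Passing tests therefore demonstrate the integration
arithmetic — clustering, voting, matching, counting — not predictor or
database accuracy on real genomes: the published benchmark counts for real
*E. coli*-scale genomes require live predictors and versioned databases and
are out of reach of a self-contained test, which is why the tests pin the
report *arithmetic* to published percentage triples and the matching
*semantics* to constructed boundary cases instead.

# Numerical and degenerate-input choices

- Percentage rounding is everywhere 2 decimals, half away from zero
  (`round_half_up`), not banker's rounding.
- All orderings used for output (homology ranks, taxonomy ranking, pathway
  ties, hierarchy children, Krona rows) end in a lexicographic key, so every
  output is a total order and byte-stable.
- Empty inputs return empty-but-typed results (empty call tables, an empty
  mask, a zero report with `NA` percentages) rather than errors, except
  where the contract is a precondition (empty predictor map, empty core
  list, list genes missing from the enrichment background).
- The pipeline degrades explicitly: with no homology tables it still writes
  all annotation outputs, products floor at `hypothetical protein`, and the
  taxonomy stage is skipped with a warning.
- Problem sizes in the test suite (50–100 genes, ≤ 8 genes per side for the
  exhaustive matching oracle, `N <= 12` for draw enumeration) are chosen so
  each oracle is genuinely exhaustive yet the whole suite stays fast.

# Known limitations

- Start-vote granularity is per predictor; a predictor emitting two calls
  with the same stop contributes only its first.
- TBL coverage is the gene/CDS/rRNA/tRNA subset with `locus_tag`/`product`
  qualifiers — not full INSDC qualifier coverage. A bare `gene` record with
  no typed feature line is read back as a CDS.
- The warehouse XML model is a minimal explicit schema (organism, contig,
  gene, protein, GO/pathway/domain identifier references), not a full
  warehouse genomic model.
- Taxonomy voting is evidence, not a verdict: no taxonomy database lookups,
  no LCA computation.
```{r example}
spec <- fixture_spec(seed = 7)
sim <- simulate_annotated_genome(spec)
pert <- perturb_annotation(sim$truth, spec)
comparison_report(match_gene_calls(pert$test, sim$truth, offset = 50))
```
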