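---
title: "Methods: cataloging and prioritizing trait-associated variants in the miRNA regulome"
author: "mirtas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cataloging and prioritizing trait-associated variants in the miRNA regulome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `mirtas`, in the spirit of a methods supplement: what
each stage assumes, which knobs matter, what the synthetic test world
does and does not establish, and where genuinely open design questions
were decided one way rather than another.

## The problem

A GWAS reports an *index SNP* per association, but linkage
disequilibrium means the causal variant can be any SNP in strong LD with
it. Most associations land outside coding sequence, and one
under-examined class of regulatory mechanisms is the miRNA regulome:
variants in miRNA precursors (altering biogenesis), in miRNA promoters
(altering expression), and in 3′-UTR seed-match sites (creating or
destroying miRNA target sites). `mirtas` enumerates the trait-associated
SNPs (TASs) in each of these element classes and ranks them by whether
any *competing* functional explanation exists in the same LD block.

## LD blocks from phased haplotypes

r² between two bi-allelic loci is computed directly from phased
haplotype frequencies,

$$r^2 = \frac{(p_{AB} - p_A p_B)^2}{p_A(1-p_A)\,p_B(1-p_B)},$$

not from genotype EM — the intended input is a phased reference panel,
so haplotype phase is known. Conventions that matter:

* **Missing alleles** are excluded pairwise (a haplotype missing either
  allele does not contribute to that pair).
* **Monomorphic loci** make the denominator zero; r² is defined as 0.
  The index SNP of a block is nonetheless always a member, carried with
  r² = 1 by definition.
* **Strict inequality.** Block membership requires r² *strictly*
  greater than the threshold (default 0.6), so a worked 8-haplotype
  panel engineered to r² = 0.6 exactly is excluded — this boundary is a
  frozen test case.
* **Search window.** Pairwise r² is only computed within ±1 Mb of the
  index SNP (configurable). The procedure this reimplements is silent
  on its window; genome-wide pairwise r² would be wasteful and useful
  LD rarely extends past 1 Mb, so the window is a deliberate,
  documented default rather than an inferred one.
* **MAF tie at 0.5** reports the alternate allele as minor. Frequencies
  of exactly 50% occur in real output tables, so the tie-break must be
  deterministic.
* **Index SNPs absent from the panel** produce an empty block flagged
  `unresolved` plus a warning — associations are skipped, never
  silently dropped, and the funnel counts them.
* Multi-allelic and non-SNV panel records are dropped at load with a
  warning; the model is each bi-allelic polymorphic locus.
* r² is computed with the two per-locus variance terms grouped before
  multiplication so that `compute_r2(a, b)` and `compute_r2(b, a)` are
  bit-identical.

Super-population assignment maps free-text cohort ancestry onto
EUR/AFR/AMR/ASN by case-insensitive keyword substring matching, rows
checked in that fixed order with the first matching row winning and EUR
as the fallback. Keyword order resolves genuinely ambiguous strings
reproducibly; the function is total (every string maps somewhere).
Keywords carrying flanking spaces (e.g. `" UK "`) are matched against
space-padded text so they only hit as standalone tokens.

## Catalog filtering

Associations are kept at p strictly below 1 × 10⁻⁵; rows whose SNP
field contains more than one rsID token encode multi-SNP haplotypes and
are dropped, as are rows with no rsID. Malformed p-values are tolerated
(they parse to NA and fail the strict threshold) because public catalog
exports contain them. All drop counts are logged.

## Seed-site prediction

The site engine is exact string matching of the three canonical seed
site types on the mRNA sense strand: with miRNA positions numbered from
the 5′ end, `7mer-m8` = revcomp(positions 2–8), `8mer-1a` =
revcomp(2–8) + A, `7mer-1a` = revcomp(2–7) + A (the A opposite position
1 is an anchor, not a complement). Conventions:

* U and T are equivalent: all sequences are normalized to the RNA
  alphabet before matching, and predictions on DNA- and RNA-alphabet
  inputs are identical (a tested invariant).
* `N` never matches. Characters outside `{A,C,G,T,U,N}` are data
  errors, not silent skips.
* Overlapping matches for one miRNA at one seed location collapse to
  the strongest type (8mer-1a > 7mer-m8 > 7mer-1a): an 8mer at offset
  *i* implies and suppresses the 7mer-m8 at *i* and the 7mer-1a at
  *i*+1. A 7mer-m8 and a 7mer-1a can only co-occur at adjacent offsets
  via an 8mer, so no other collapse rule is needed (proved in a test).
* Offsets are 0-based on the UTR sense strand in all outputs.
* All (including overlapping) occurrences are found via
  `Biostrings::matchPattern`; the test suite checks the engine against
  an independent sliding-window Watson–Crick oracle.

**Conservation** (1–5) counts human plus the species among mouse, rat,
dog, chicken whose orthologous UTR contains a same-type site for the
same miRNA *anywhere* in the sequence. This alignment-free reading is a
deliberate decision: the alternative — positional conservation through
a multiple alignment — requires an MSA pipeline that the inputs do not
carry, and "exactly conserved" is satisfiable by presence of the exact
site sequence. The choice is recorded here and in output metadata; a
missing ortholog UTR counts as absent.

## Allelic complements and site diffs

SNPs on a UTR are grouped into clusters by transitive chaining at
pairwise distance ≤ 7 nt (the widest 7mer span; two SNPs 7 nt apart can
co-occupy one site). Each cluster of size *k* yields all 2ᵏ − 1
non-reference allele combinations — including combinations never
observed as haplotypes, deliberately, for comprehensiveness — while all
other positions stay at reference. Cluster size is capped at 10 SNPs
(1,023 combinations) with a hard error; nothing in the source procedure
bounds this, and the cap converts a combinatorial explosion into a
diagnosable failure.

Alleles arriving in genomic (VCF) coordinates are flipped onto the
transcript strand for minus-strand genes — position reflected,
alleles complemented — before substitution; strand bugs are the
dominant failure mode of this analysis class, so the fixture plants its
"created site" event on a minus-strand gene to keep the path tested.
A SNP whose stated reference allele disagrees with the UTR base is a
data error naming the SNP.

Site identity for diffing is (miRNA, offset, type) with offsets in
reference coordinates (only bi-allelic SNVs are modeled, so alternates
never change length). A type change is one abolished plus one created
record. `diff_sites(x, x)` is empty by construction.

In the pipeline, diffs are computed for the *TAS* SNPs within each
TAS-bearing UTR: the funnel counts TASs that create or abolish sites.
The same machinery (`utr_site_diffs`) accepts any SNP set if a full
panel-wide complement scan is wanted.

## Prioritization policy

The disqualifying-annotation sets differ by element kind, mirroring the
asymmetry in the source procedure: precursor and promoter TASs are
demoted by *any exonic* variant in the block; target-site TASs by a
*nonsynonymous or transcriptional-regulatory* SNP. This asymmetry is
the default policy object, not hard-coded. eQTL hits annotate but never
disqualify (they have no stated filtering role). Demoted records are
rescued to `supported` by a validated miRNA:gene pair matching a
predicted site in the block, or by very strong LD (r² > 0.9, strict)
with the index SNP, or by being the index SNP. Tiering is monotone:
adding annotations can only demote (a tested property).

## The Monte Carlo hub test

The targeting score of a miRNA over a gene set is a weighted count of
its conserved predicted sites: weight 1.5 for an 8mer-1a, and 1.5 for
any site with another same-miRNA site in the same UTR starting within
60 nt (start-to-start, both sites weighted); otherwise 1. Three
decisions here were genuinely open:

* **"Within 60 nt"** is read as pairwise proximity between two sites in
  the same UTR, consistent with the site-cooperativity literature the
  weighting evokes, not distance to a UTR boundary.
* **Site-level vs gene-level weighting**: the default scores every site
  (a weighted sum); a `score_mode = "gene"` switch scores each target
  gene by its maximum site weight, for sensitivity analysis.
* **"Conserved"** defaults to conservation = 5 (all five species),
  configurable down to 1.

The null is `reps` (default 100,000) uniform draws of
|candidates| genes without replacement from the universe of genes with
admitted UTRs. Each replicate score *T* is normalized for average UTR
length in ratio form, *T* × L̄_test / L̄_random. The exact algebraic
form of this normalization was an open question; the ratio form is the
only expression that combines the three quantities it is defined in
terms of — a score and the two average UTR lengths — and it is recorded
in the result object's metadata. The empirical p-value uses add-one smoothing,
p = (1 + #{null ≥ observed}) / (reps + 1), so p ∈ (0, 1] and a score
topping every replicate at reps = 999 reports exactly 0.001.

Because the weighting rule only inspects sites within one UTR, the
score is additive over genes; the implementation precomputes a per-gene
score vector once and the Monte Carlo loop reduces to sampled sums,
which is what makes 10⁵ replicates per (miRNA, trait) pair cheap.
Replicate streams are seeded deterministically per pair from the run
seed, so scans are reproducible and insensitive to pair order.
Significance is flagged at empirical p ≤ 0.01; no multiple-testing
correction is applied across miRNAs, matching the procedure this
follows (raw empirical p against a fixed threshold).

## The synthetic world

`fixture_spec()` describes a deliberately small but complete world, and
its defaults are the stated conditions of the analysis wherever the
procedure states one (p < 1e-5 planted/decoy rows, r² > 0.6 blocks, an
exact r² = 0.6 boundary pair, weight 1.5 / 60 nt / conservation-5 hub
scoring). Where no value is stated, defaults were chosen once, a
priori, at what a practitioner would call realistic desk scale:

* 200 haplotypes (100 diploid samples — the order of a 1000G-style
  super-population panel), 60 background SNPs, one chromosome.
* 6 miRNAs, 60 genes with UTRs of 180–320 nt, four ortholog species per
  gene.
* Hub enrichment: one trait list of 15 genes, 40% of which carry a
  conserved 8mer for the hub miRNA, against a 5% background carrier
  rate. These fractions are the stated enrichment conditions; the list
  and universe sizes were fixed by an a-priori power calculation (6
  planted carriers vs a hypergeometric null mean of ~2.3 of 9 carriers
  puts the observed score >3 SD above the null), *before* any test was
  run, so the planted hub clears p ≤ 0.01 at 2,000 replicates with
  margin rather than by tuning.

Ground truth is engineered, then *verified at generation time*: the
abolishing/creating SNPs are found by deterministic search over
(position, allele) until the substitution produces exactly the planted
site difference against the full miRNA set, and ortholog UTRs are
scrubbed or seeded until the planted conservation number is exact. If
no clean plant exists the generator raises an error rather than
emitting a fixture that silently disagrees with its manifest.
Generation is byte-identical under a fixed seed (all randomness flows
from `rng_seed`; sub-generators use fixed offsets so standalone and
composed generation agree), and fixtures are written as real files in
the same formats the pipeline parses — there is no privileged in-memory
path, so the I/O code is exercised.

What a green fixture suite establishes: the machinery — filters, LD
algebra, strand handling, enumeration, tiering, Monte Carlo calibration
— is correct on inputs with known answers. What it does not establish:
anything about real genomes. The world has no realistic LD decay
(engineered duplicate columns and independent background columns, not
coalescent structure), no GC/length realism beyond the configured
range, uniform random UTR sequence, and one chromosome. Headline counts
from the original full-scale analysis (hundreds of thousands of TASs)
depend on specific public database snapshots and are out of reach at
desk scale by design.

## Numerical and degenerate-input conventions

* Strict inequalities at both LD thresholds (0.6, 0.9) and the strict
  catalog p cutoff; boundary cases are frozen tests.
* r² clamped to [0, 1] against floating-point drift; symmetric
  grouping of the denominator (see above).
* Empty inputs degrade, not fail: an empty catalog yields empty stage
  tables and a warning; a gene absent from the site index scores 0; a
  miRNA with no sites anywhere gets p = 1.
* Errors are classed (`mirtas_config_error`, `mirtas_data_error`) and
  the CLI maps them to exit codes 2 and 3.
* UTR admission reasons are checked in a fixed order (multi-mapped,
  spliced, too-short, unmapped) so each rejection carries one
  deterministic reason, and admitted ∪ rejected always partitions the
  input.

## Known limitations

* Seed matching only: no context scores, thermodynamics, non-seed
  ("centered", 3′-compensatory) or ORF sites.
* Conservation is presence-based, not alignment-positional (flagged in
  output metadata).
* No imputation, phasing, or genotype-likelihood handling; bi-allelic
  SNVs only (no indels in UTR complements).
* The null gene sampler is uniform — no GC, expression or
  length-matched sampling beyond the mean-UTR-length ratio correction.
* Promoters are consumed as given (BED); no promoter discovery from
  chromatin data, and no enhancer/long-range elements.
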