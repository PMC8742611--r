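---
title: "Methods: deconvolution, contact building and enrichment analysis in redchip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deconvolution, contact building and enrichment analysis in redchip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redchip)
options(redchip.verbose = FALSE)
```

# The chemistry model

A protein-centric RNA–DNA proximity ligation library is built by
cross-linking RNA–protein–DNA complexes, ligating a biotinylated bridge
adapter between RNA 3′ ends and nearby DNA ends, immunoprecipitating
against a protein of interest, cutting the DNA side with an MmeI-type
enzyme that leaves a short tag, and reverse-transcribing the RNA side from
the bridge with template switching at the RNA 5′ end. `redchip` models the
resulting read 1 as

```
[DNA tag][bridge][template-switch G's][RNA cDNA ...]
```

and treats read 2 as redundant (single-side deconvolution). The package
makes no assumption about the bridge oligo identity: it is a required
configuration value (`bridge_config()`); `example_bridge()` is the fixed
20-mer used by the simulator and the examples.

## Deconvolution rules and parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `max_mismatches` | 1 | substitutions | Hamming tolerance for the bridge match; `N` counts as a mismatch; no indels |
| `dna_tag_min`, `dna_tag_max` | 18, 22 | bp | accepted DNA tag lengths, the MmeI-type cut-length window |
| `rna_min_len` | 14 | bp | minimum RNA part length after trimming; shorter parts cannot map uniquely |
| `gggg_trim` | TRUE | — | trim the leading run of up to 4 G's of the cDNA (template-switch artifact) |

Statuses are assigned by the first failing rule in fixed order
`NO_BRIDGE` → `MULTI_BRIDGE` → `DNA_SHORT`/`DNA_LONG` → `RNA_SHORT` → `OK`,
so the six statuses partition any library. Design choices worth stating:

* **Substitution-only bridge matching.** The bridge is short; an
  indel-tolerant search would add complexity for negligible yield. This is
  a documented limitation: a read with an indel inside the bridge is
  counted `NO_BRIDGE`.
* **Ambiguous chimeras are discarded.** A pair with two or more acceptable
  bridge hits (`MULTI_BRIDGE`) is dropped rather than resolved to the
  leftmost hit; an ambiguous split would risk a spurious contact.
* **Transcript-sense RNA parts.** The cDNA after the bridge is
  reverse-complemented before reporting, which turns the downstream gene
  assignment into a plain strand equality.
* **Capped G-trimming and ground truth.** Trimming removes
  `min(run length, 4)` leading G's of the cDNA. When the first templated
  base of the cDNA is itself a G, trimming is ambiguous by construction, so
  the simulator defines its per-read ground truth *after* applying the same
  capped trim to its own read. Reconstruction of noise-free libraries is
  then exactly bit-identical, which is what the round-trip tests assert.
* **The NlaIII-side residue is retained.** Whether the DNA tag keeps the
  restriction half-site is irrelevant to mapping; the tag is used verbatim.

Bridge matching is delegated to `Biostrings` pattern matching, restricted
to fully contained offsets, and is property-tested against a brute-force
Hamming scan.

# Mapping and contact building

The bundled `align_exact()` is a fixture aligner for synthetic data: each
part is searched on both strands for exact occurrences and is usable only
when it occurs exactly once genome-wide. Real libraries enter through
`ingest_alignments()` (SAM text or a 6-column TSV), a deliberately thin
coordinates-only path: no CIGAR interpretation, mapping quality 0 or
secondary/supplementary flags mean non-unique. Multi-mapping parts are
excluded outright — for enrichment testing, contact specificity beats
sensitivity.

Gene assignment is strand-aware over the annotated gene body (exon
structure is ignored; intronic hits count). Among same-strand overlapping
genes the largest overlap wins, ties go to the smaller gene, then to the
lexicographically smaller id — a deterministic, biotype-blind rule. An
antisense transcript is only counted if it is itself annotated.

PCR duplicates are collapsed on the 5′-coordinate key
`(rna_chrom, rna_start, dna_chrom, dna_start, fraction, replicate)`, the
standard proximity-ligation duplicate definition; sequence content is not
part of the key. Every stage reports counts in and out, and two
conservation identities hold for any input: statuses sum to the number of
read pairs, and OK reads equal contacts plus rejected reads
(unmapped/multi-mapped plus duplicates).

# Enrichment model

For gene $g$ with $c_g$ contacts of the relevant class in a library of $N$
total contacts, the fold change between replicate-matched IP and input
libraries is the proportion ratio

$$\mathrm{FC}_g = \frac{c_g^{IP}/N^{IP}}{c_g^{input}/N^{input}}.$$

Total-count normalization is the minimal depth correction and is invariant
under rescaling either library, a property the tests assert. Contact
classes:

* **cis** — DNA part overlapping the window spanning the gene body ± 1 Mb
  (gene included), clamped to the chromosome;
* **trans** — DNA part on any nonparental chromosome. Parental-chromosome
  contacts beyond the window belong to neither class.

$\mathrm{FC}_g$ is reported as `NA` when either count is below `min_count`
(default 10 per fraction); without an abundance filter the ratio of two
small Poisson counts blows up and dominates any ranking. A gene is called
enriched when the fold change is defined and **strictly** greater than the
threshold (default 1.3) in **every** replicate. Replicates are never merged
for calling; the pooled-count `fc_merged` column is descriptive only.
Whether per-replicate inputs should be matched or pooled is genuinely open;
`redchip` matches replicate $k$ IP against replicate $k$ input, the more
conservative choice because replicate-specific depth artifacts cancel.

Chromatin-state operations classify a contact by its DNA-part **midpoint**
(tags are ~20 bp, so the midpoint is orientation-free); contacts outside
every segment are excluded from denominators and reported. The peak
metaprofile bins the signed distance from the DNA-part midpoint to the
nearest peak center (ties toward the upstream peak) into an odd number of
equal bins across ±`flank_bp`, normalized to contacts per million.

## Statistical tests

Group differences in fold change between RNA biotypes use a two-sided
rank-sum (Mann–Whitney U) comparison: for groups of at most 8 the null is
enumerated completely (midranks handle ties exactly); larger groups use the
tie-corrected normal approximation of `stats::wilcox.test`. List overlaps
use the one-sided hypergeometric upper tail via `stats::phyper`. Both are
verified against brute-force oracles (full enumeration; direct
`choose()` summation). When many pairs are tested, `biotype_fc_tests()`
reports Benjamini–Hochberg adjusted p values alongside the raw ones.

# The simulator: what it emulates and what it does not

`simulate_reference()` / `simulate_contacts()` / `contacts_to_reads()`
generate a complete synthetic experiment. Defaults define the package's
reference study: 2 chromosomes × 2 Mb, 200 non-overlapping genes
(biotype mix 70% protein-coding, 14% lincRNA, 8% antisense, 4% snRNA, 4%
snoRNA), a 5-state segmentation in 250-kb blocks with "Polycomb" as the
designated protein-bound state, 40 peaks inside that state, two replicates
of 50,000 contacts per fraction, 5% of genes enriched at factor
$e = 2$. These sizes keep a full 20-replicate recovery study comfortably
within desk-scale compute while leaving per-gene counts (median ~190 cis
contacts per library) in the regime where the `min_count` filter and the
1.3 threshold behave as they would on deep real libraries.

The generative model mirrors the analysis assumptions:

* expression weights are log-normal(0, 1) — arbitrary but configurable,
  giving the heavy-tailed per-gene counts real libraries show;
* a contact is cis with probability `p_cis` (default 0.75, matching the
  strongly cis-skewed character of RNA–DNA ligation data), placed at a
  signed distance from the RNA position drawn from a symmetric exponential
  (Laplace) with scale 25 kb — real contact decay is not modeled in the
  analysis, but some decay is needed for the ±1 Mb window to be meaningful;
* trans contacts are uniform on a random nonparental chromosome;
* the IP fraction is an importance-reweighted copy of the input
  distribution: draws whose gene is enriched *and* whose DNA position falls
  in the designated state get weight $e$, then rejection sampling
  renormalizes. This creates exactly the proportion-ratio signal the
  estimator targets, making parameter recovery well-posed.

Enriched genes are not drawn at random: they are the genes whose Laplace
placement mass is best covered by the designated state, emulating the
biology in which Polycomb-associated RNAs contact Polycomb chromatin. This
matters quantitatively: the recoverable cis fold change of an enriched gene
is $e \cdot m_g / Z$, where $m_g$ is its designated-state placement mass
and $Z \approx 1 + (e-1)\sum_{g'\,\mathrm{enriched}} w_{g'} \bar m_{g'}$ the
renormalization; choosing well-covered genes makes $m_g \approx 1$, so the
estimator should recover $\approx e$ up to the few-percent depression from
$Z$. The acceptance suite measures exactly this (mean recovered FC ~1.9 for
$e = 2$ across 20 simulations, sensitivity > 0.95, false-positive rate
well below 5%, and a null call rate below 1% when $e = 1$).

Reads are rendered with a uniformly drawn tag orientation, 0–3 non-templated
template-switch G's, optional bridge deletion (`noise`) and uniform
per-base substitutions (`sub_rate`). Not emulated: base-quality error
models, GC bias, splicing, repeat structure, realistic chromatin-state
maps, UMI chemistry. Passing tests therefore demonstrate correctness of
the algorithms under the stated generative model, not performance on the
artifacts of real sequencing — for real libraries the deconvolution
statistics and the `ingest_alignments()` path are the entry points.

# Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; conversions happen only
  at format boundaries (GTF in, bedGraph out), and both conversions are
  round-trip tested.
* `simulate_reference()` rejection-samples the genome until fewer than 1%
  of 20-mers are duplicated, so exact-match alignment loses under 1% of
  reads; `sequences = FALSE` skips sequence generation entirely for
  analysis-scale studies that never touch reads.
* Flatness of the uniform-placement metaprofile is asserted with a
  simultaneous (Bonferroni-corrected across bins) band at the nominal
  3-sigma level plus a chi-square goodness-of-fit test: a per-bin 3-sigma
  band applied independently to 41 bins would false-alarm on roughly one
  in ten seeds by multiplicity alone.
* Degenerate inputs have defined behavior: empty libraries yield empty
  outputs with zero counts; an empty peak set, a non-odd bin count, a zero
  library total, identical groups in the rank-sum test, and a universe
  smaller than a set union all raise (or return) the documented result.
* All randomness flows from a single integer seed per stage; repeated runs
  are byte-identical, which the determinism tests assert.

# Known limitations

* Single-side deconvolution: read 2 is not used to extend or confirm the
  RNA part; mate reconciliation is unspecified territory and left out.
* No indel tolerance in bridge matching.
* Gene-body (not exon-aware) RNA assignment; no splice-aware alignment and
  no repeat rescue of multi-mapping parts.
* The exact column schema of published contact tables varies by study; the
  TSV dialect here is this package's own, chosen for diff-stability, and
  is not claimed byte-compatible with any deposition.
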