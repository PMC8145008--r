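---
title: "Methods: virome decontamination, standardisation and discovery with viromedeck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virome decontamination, standardisation and discovery with viromedeck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromedeck)
```

## The problem

Shotgun virome sequencing of field samples — here, pooled insect larvae
and leaves of their host plant, barcoded into one run alongside process
negative controls — yields taxon-by-sample read-count tables that are
contaminated twice over: taxonomic binning produces low-count artefacts,
and barcode leakage moves reads between libraries. Downstream of the
count table, candidate viral contigs need confirmation against a
comprehensive database, reconstruction against their closest reference,
and classification against family-specific identity thresholds before a
discovery claim can be made.

viromedeck implements this post-assembly workflow as composable,
separately testable stages, together with a synthetic-community
generator that plants every kind of error the pipeline is supposed to
catch, so each stage can be validated against known ground truth.

## Count-table standardisation

The standardisation model treats a sample's **relative abundance** of a
taxon as its count divided by the library's total cleaned reads (not by
the viral column sum — classified fractions vary several-fold across
libraries, and dividing by the viral total would entangle the two).

Three operations, applied in this order:

1. **Abundance threshold** (`apply_abundance_threshold`). A cell
   survives only if its relative abundance strictly exceeds the
   threshold, default 1/10,000 reads/taxon/sample. The boundary is
   strict: one read in a 10,000-read library is removed.
2. **Negative-control subtraction**
   (`subtract_control_contamination`). For every taxon detected in any
   control, the taxon is zeroed in each specimen where its abundance is
   equal or inferior — inclusive — to its **maximum** abundance across
   controls. The maximum (not the mean) is the conservative comparator
   when controls disagree; the comparison basis is relative abundance
   by default because library depths differ across barcodes, with raw
   counts available as a switch.
3. **Per-kb normalisation** (`normalize_per_kb`). Counts divided by the
   taxon's total contig length in kb, making abundances comparable
   across genomes of different length. When a taxon has several
   contigs, their summed length is used.

Removal means setting the cell to zero; a taxon row is dropped only
when it becomes all-zero. Both filters log every removed cell. Because
the total cleaned reads travel with the table, re-applying the
standardisation to its own output removes nothing new (idempotence),
and neither filter can ever increase a cell.

Display helpers mirror the usual presentation: `log10_matrix` uses
log10(count + 1) so absence maps to 0 in heatmaps, `classified_fraction`
summarises the virally-classified share of each library, and
`host_class_split` partitions reads into arthropod-infecting,
plant/fungus-infecting and phage classes.

## Accumulation curves

`accumulation_exact` computes the analytic sample-based rarefaction
estimator: with N samples and taxon i present in n_i of them, the
expected richness of a random k-sample subset is

E[S(k)] = Σ_i [ 1 − C(N − n_i, k) / C(N, k) ],

with C(a, b) = 0 when a < b, evaluated via log-binomials for stability.
`accumulation_random` estimates the same curve by averaging over seeded
random sample orderings and adds a plain (no finite-population
correction) standard deviation band. The exact estimator is the
reference; the permutation mode exists for sd bands and to mirror the
common ecology-package default. `plateau_check` calls a curve saturated
when the final increment E[S(N)] − E[S(N−1)] is at or below a
tolerance (inclusive). Presence is evaluated on the standardised table,
where count > 0 means "survived both filters".

## Contig confirmation and binning

`filter_hits_by_evalue` and `reciprocal_confirmation` implement the
two-search design: a forward search against a viral database (e-value
< 1e-5, strict) proposes candidates; a reciprocal search against a
comprehensive database (e-value < 1e-3, strict) confirms them. The best
reciprocal hit — lowest e-value, ties broken by higher bit score, then
lexicographic subject id — must itself be viral; a cellular best hit
rejects the contig as a false positive. A contig with **no** reciprocal
hit is retained but flagged: a genuinely cellular sequence would find
its cellular homolog in a comprehensive database, so silence does not
contradict the forward call. `bin_to_families` then aggregates confirmed
contig counts to family level, conserving totals; when a contig's
forward hits span families, the best forward hit's family is the
caller's responsibility — the binning interface takes one family per
contig.

## Consensus calling

`call_consensus` reconstructs a known isolate against its closest
reference from a per-position pileup: where depth ≥ 5 (inclusive) and
the majority base differs from the reference, the majority base is
emitted and a variant recorded; everywhere else — low depth, no
coverage, concordant majority — the reference base is kept. The rule is
evaluated on the majority base, matching single-pass consensus
semantics. Ties keep the reference when it participates, otherwise take
the alphabetically smallest tied base, flagged ambiguous. The model is
substitution-only: consensus length always equals reference length, and
indels are a documented limitation. With min_depth = ∞ the consensus
degenerates to the reference, and raising min_depth can only shrink the
variant list.

## Pairwise alignment and identity

`global_align` is an affine-gap (Gotoh) global aligner: a gap of length
L costs open + L·extend. Defaults are +2/−3 with open 5 / extend 2 for
nucleotides and BLOSUM62 with open 11 / extend 1 for proteins —
conventional values, since demarcation practice does not fix alignment
parameters. The traceback is deterministic; because its tie preference
is not symmetric in the argument order, the aligner canonicalises the
order internally and mirrors the result, so identity is exactly
symmetric. The test suite checks the scores against two independent
oracles: exhaustive enumeration of all alignments for short pairs, and
the Biostrings reference aligner for longer ones.

`pairwise_identity` is matches / counted columns × 100. The default
policy excludes terminal-gap columns and counts internal gaps as
mismatches — the convention of pairwise-identity demarcation tools;
`include_all` and `exclude_all_gaps` are available because published
tools differ and the choice moves identities by a few points on gappy
pairs. `identity_matrix` fills the symmetric matrix with 100 on the
diagonal.

## ORF scanning, CDS completeness, in-silico PCR

`find_orfs` scans six frames for ATG-initiated, stop-terminated frames
whose length (stop codon included) strictly exceeds the cutoff
(default 300 nt — an exactly-300-nt ORF is excluded); of nested starts
sharing a stop, only the longest is reported. ORFs that run off the
sequence end without a stop are not reported. `cds_completeness` flags
a reconstruction near-full only strictly above 90% of the reference
CDS.

`in_silico_pcr` locates the forward primer on the plus strand and the
reverse primer as its reverse complement, with IUPAC degeneracy and an
optional per-site mismatch budget (Biostrings pattern matching does the
scanning). Primers are conventionally named by the template coordinate
of their 5′ end, so the function reports both the 5′-to-5′ difference
(`region_length = rev_start − fwd_start`) and the inclusive
`product_length` (one more), avoiding an off-by-one ambiguity between
naming conventions.

## Species demarcation

Classification is a pure function of an evidence record (identities to
the closest relative) and a rule table. The shipped rules are the two
family criteria the discovery workflow needs: Alphaflexiviridae —
distinct species below 80% aa identity in capsid or polymerase — and
Iflaviridae — below 90% aa identity in the capsid. The ladder:

1. nt genome identity ≥ 98% → **known_isolate**. The floor sits just
   below the 98.2% minimum observed for known isolates in the study
   this workflow models, and is configurable.
2. A family rule exists: marker identity strictly below threshold →
   **novel_species**, else **known_strain**. For capsid-or-polymerase
   rules with both markers supplied, the conservative reading requires
   both below threshold ("either" is a switch).
3. No rule: best supplied aa identity below 60% →
   **putative_novel_no_criterion**. The floor sits just above the
   57.2% maximum observed for novel genomes; identities between the
   floors return **indeterminate** rather than forcing a call.

`summarize_discovery` tallies known-isolate contigs, the distinct known
species they represent (deduplicated on closest relative, so two
segments of one virus count once), and putative novel species split by
host class.

## The synthetic-data generator

`simulate_community` emulates the study design the analysis assumes: 14
insect-pool and 2 plant-pool specimen libraries plus 3 negative
controls; 9 arthropod-infecting, 11 plant/fungus-infecting and 3 phage
taxa. Eligible taxa (plant pools carry no arthropod viruses) are
resident in a library with occupancy probability 0.7 — without
sub-complete occupancy every accumulation curve would saturate at one
sample — and residents draw lognormal(0, 1.5) abundances, normalised to
proportions and allocated multinomially to 10,000 reads per specimen
library. These sizes keep relative-abundance granularity (1/10,000)
exactly at the default threshold while keeping the test suite fast; the
generator is not a read-level simulator (no FASTQ, qualities or
assembly), so it validates count-table logic, not upstream
bioinformatics.

Contamination follows a barcode-leakage model: donors are drawn among
taxa whose maximum donor relative abundance is at least 1% — leakage
from rare taxa is invisible at realistic control depth — and each donor
leaks into every non-resident specimen column at
`contamination_intensity` (default 0.3) × its donor relative abundance,
and into every control at `control_intensity` (default 1.0) × the same.
The two intensities are separate parameters because the guarantee the
control-subtraction rule offers — every planted contaminant removed —
holds exactly when controls see the leak at least as strongly as
specimens; the defaults put the generator in that regime with a margin
well above multinomial noise. Controls are sampled at a tenth of a
specimen library's depth (Poisson per taxon), reflecting how little
material blanks carry.

`simulate_contig_and_pileup` plants substitutions into a random
reference and builds a pileup whose reads support the mutated isolate
(Poisson depth, default mean 30; per-base error 0.01 spread uniformly
over the three other bases; a chosen fraction of mutated positions
forced below depth 5). `simulate_hit_tables` plants false-positive
contigs whose reciprocal best hit is cellular. Every generator is
seed-deterministic and returns a truth object naming each planting.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere on sequences.
* The binomial ratios in the exact rarefaction estimator are computed
  as `exp(lchoose(...) − lchoose(...))`.
* Readers validate and reject rather than coerce; writers emit stable
  column order so outputs diff cleanly. The pileup format is a plain
  7-column TSV (pos, ref, A, C, G, T, N) to keep fixtures text-only; a
  converter from standard text pileups is a natural extension point.
* The package's interface is its functions plus `run_pipeline`, which
  composes the stages in the canonical order (confirm → bin →
  standardise → rarefy → consensus → demarcate), writes canonical TSV
  outputs and a manifest of versions, seeds and filter in/out counts
  sufficient to re-run bit-identically.
* Test problem sizes: brute-force alignment oracles run on pairs up to
  8 nt (exhaustive enumeration), exhaustive rarefaction oracles on 6×8
  incidence matrices (≤ 2⁶ subsets per size), permutation agreement at
  10,000 permutations, consensus recovery on 1–2 kb contigs.

## Limitations

* Substitution-only consensus; no indels, no quality weighting, no
  iterative remapping.
* Pairwise alignment only; multiple alignment and tree inference are
  out of scope, so `capsid_or_polymerase` evidence must be computed by
  the caller per marker.
* The decontamination rule is the subtraction heuristic it implements —
  not a statistical mixture model of contamination; taxa genuinely
  shared between a sample and a control at similar abundance are
  removed by design.
* The generator draws abundances independently per sample; it does not
  model co-occurrence structure, nor compositional correlation between
  taxa, so tests validate filter logic rather than ecological realism.
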