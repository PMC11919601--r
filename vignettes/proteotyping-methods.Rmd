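---
title: "Bacterial proteotyping by FDR-free PSM counting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bacterial proteotyping by FDR-free PSM counting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteotyper)
library(dplyr)
```

## The identification model

`proteotyper` identifies a pure bacterial isolate from bottom-up proteomics
data by a deliberately simple statistic: count, for every taxon in a
reference database, how many peptide-spectrum matches (PSMs) map onto that
taxon's in-silico tryptic peptidome, and report the taxon with the most
mapped PSMs. Three design choices make this work:

1. **No FDR control.** The search engine's best match per MS2 spectrum is
   kept regardless of score. The method never claims any individual
   peptide is present; it only needs mapped PSMs to *accumulate* on the
   correct taxon. False matches — typically low-quality spectra — hit
   peptides essentially at random across the reference, so every other
   taxon acts as a decoy and collects only a thin, near-uniform share of
   noise. Skipping the FDR step also means true matches are not
   sacrificed to control an error rate that is irrelevant to the question
   being asked.
2. **Shared peptides count once per taxon.** A peptide carried by many
   taxa increments each of them by one per PSM; a peptide carried by many
   paralogs within one taxon still increments that taxon only once per
   PSM. Counts therefore reflect spectra, not database redundancy.
3. **Isoleucine/leucine collapse.** I and L are isobaric and cannot be
   distinguished by mass spectrometry, so every sequence is rewritten
   with `I -> L` on both the database and the PSM side
   (`normalize_il()`). The collapsed strings remain valid sequences.

Identification runs in up to two iterations. The first maps PSMs against
a *species-level* database holding one representative proteome per
species. The second, optional iteration re-maps the same PSMs against a
*strain-level* database holding **every** complete-genome strain of the
genus identified first. Because a species is represented by a single
strain in iteration one, a sample strain that resembles a sibling
species' representative more than its own species' representative is
misidentified there — and corrected in iteration two, where the database
contains all strains. `scenario_strain_correction()` constructs exactly
this situation and the test suite asserts both the failure and the
correction.

A quality-control rule guards the whole procedure: a sample mapping fewer
than 500 PSMs (`qc_threshold`, configurable) fails QC. That signature
usually means a degraded sample or an organism from a kingdom absent from
the database; `identify_with_fallback()` then re-maps against an
alternate-kingdom index (e.g. fungal proteomes) and returns whichever
result maps more PSMs.

## Reference database construction

Species representatives are selected from NCBI-style assembly metadata by
three criteria: ANI status `"OK"`, a known binomial species name, and a
declared reference or representative genome. "Known name" is
operationalised as: the organism name has at least two tokens and the
second is not a placeholder (`sp.`, `bacterium`, `uncultured`,
`unidentified`); NCBI gives no formal rule, and this matches its naming
practice. Among several qualifying assemblies of one species the order of
preference is reference genome, then representative genome, then type
strain, then lexicographically smallest accession — an invented but
deterministic tie-break (historically such ties were resolved by hand).
Type-strain status is read from an explicit boolean column; populating it
is left to the user because assembly metadata encodes it inconsistently.

Strain databases for the second iteration keep *all* assemblies of the
genus (plus configured alias genera — Escherichia/Shigella and
Rhizobium/Agrobacterium by default, since each pair is effectively one
genus) that have ANI status `"OK"` and assembly level `"Complete
Genome"`, with no per-species deduplication.

## Digestion parameters

`digest_params()` defaults to trypsin/P (cleavage C-terminal of K/R,
including before proline — the convention of modern search engines), up
to 2 missed cleavages, peptide length 7–50, and I/L collapse. Minimum
length 7 matches standard search settings; the missed-cleavage and upper
length bounds are search-engine defaults, since only "fully tryptic" is
fixed by the method itself, and all are configurable. Fragments
containing a non-canonical residue (X, B, Z, U, O, J, `*`) are excluded
and tallied: such peptides cannot be matched by a mass-based search and
would only inflate index size. N-terminal methionine is not optionally
removed. Peptide novelty checks against known-evidence proteins
(`flag_novel_peptides()`) use their own convention — up to 2 missed
cleavages, length 7–30 — mirroring how protein-level-evidence databases
are customarily digested for peptide lookup.

## Chunked searches

Very large peptide spaces exceed search-engine memory, so the reference
FASTA is split into chunks (`split_fasta_for_search()`, round-robin over
accession-sorted records — deterministic, each record in exactly one
chunk) and each chunk is searched independently.
`combine_chunked_searches()` merges chunk results by keeping, per
spectrum, the PSM with the highest hyperscore. Score ties are broken by
lexicographically smallest peptide and then lowest chunk id; the outcome
of a merge is therefore identical no matter how the chunks are grouped or
ordered (the merge is associative), which the tests verify on random
splits. The spectrum key deliberately excludes charge so a
spectrum searched at several charge states still yields one PSM.

## Abundance normalisation

Two iBAQ transforms are provided. `relative_ibaq()` divides each
protein's iBAQ by the sample total, log10-transforms and shifts by +10;
the pre-log relative values sum to one per sample. `zscore_ibaq()`
standardises log10 iBAQ per sample to mean 0, standard deviation 1, and
shifts by +5. Sigma is the *population* standard deviation (divisor n),
so a two-protein sample standardises symmetrically to exactly 4 and 6.
In both transforms an iBAQ of zero is treated as missing — not detected
is not the same as absent — and propagates as `NA` rather than `-Inf`.
All-zero samples and zero-variance samples are errors, named per sample.

## Orthogroup conservation classes

Orthogroups (OGs; groups of two or more homologous proteins across
proteomes, e.g. from OrthoFinder) are summarised as a binary OG-by-taxon
presence matrix: a 1 means at least one member protein occurs in that
taxon's proteome; OGs with fewer than two member proteins are rejected.
For each taxonomic rank from domain down to genus, each clade yields a
taxon-specific conservation array (TSCA): the indicator vector of clade
membership over the matrix's taxon order (the domain array is all ones).
Every OG is assigned the conservation class — D, P, C, O, F or G — of the
TSCA at minimum hamming distance from its presence row. Hamming ties are
resolved toward the most general rank, then the lowest clade taxid, so
conservation is never overstated as lineage-specific; resolved-by-rule
ties are flagged in the output. Six classes (including order/O) are
implemented.

The expression-versus-conservation summary
(`expression_conservation_summary()`) keeps, within each class, the OGs
at or below the class's 75% hamming quantile (the quantile is computed
over all OGs of the class, including hamming-0 ones), collapses paralogs
to their per-taxon median z-scored iBAQ, and reports the maximum of those
medians as the OG's expression level.

## The synthetic cohort generator

`generate_proteomes()` evolves a set of ancestral random proteins down a
regular taxonomy (domain > phylum > genus > species > strain) by per-rank
substitution, with rates that decrease toward the leaves. The defaults —
4 phyla x 3 genera x 5 species x 2 strains, 30 proteins of mean length
240, substitution probabilities 0.5/0.25/0.08/0.02 for
phylum/genus/species/strain — were chosen once to give peptide-sharing
structure resembling real bacteria: strains of one species share most of
their tryptic peptidome, congeners share a few percent, and unrelated
genera share almost nothing, so similarity ranks strictly by taxonomic
depth. Substitutions only (no indels) keep digestion oracles simple;
identification depends only on peptide-set overlap structure, which
substitutions fully exercise. When a K/R site is mutated the replacement
stays K/R with probability 0.5, so some cleavage sites drift while the
overall tryptic fragment length distribution is preserved.

PSM tables are simulated at the match level (`simulate_psm_table()`):
a fraction `1 - noise_fraction` of PSMs draw peptides uniformly from the
true strain's peptidome (hyperscores ~ Normal(25, 1)), the rest draw
uniformly from the entire reference peptide space (~ Normal(12, 1)),
emulating an unfiltered search where low-quality spectra match randomly.
The default benchmark (`benchmark_identification()`) uses 2000 PSMs per
sample at 30% noise across 200 samples — sizes at which the whole
benchmark completes in well under a minute per hundred samples on one
core. Random streams are separated: the proteome stream derives from the
cohort seed, each sample's PSM stream from its own seed, so changing the
number of PSMs never perturbs the proteomes.

What the generator does *not* emulate — and what passing benchmarks
therefore cannot show — includes: spectrum-level effects (peak quality,
chimeric spectra), peptide detectability bias (hydrophobicity, charge,
length preferences of LC-MS), contaminant proteins, horizontal gene
transfer and mobile elements, genome incompleteness, and mixed cultures.
Results on the synthetic cohort demonstrate the counting statistic's
behaviour under its own noise model, not field performance.

## Numerical and degenerate-input choices

- Ranking ties: PSM count, then distinct contributing peptides, then
  taxid. A rank-1 tie that the peptide criterion cannot break is flagged
  (`tie_at_rank1`) rather than hidden, since such pairs (e.g. taxa
  sharing most of their peptidome) are genuinely ambiguous.
- Jaccard of two empty peptide sets is an error, not 1: the ratio is
  undefined and silently returning a value would mask upstream problems.
- The "peptide identity" of a sample strain against a reference is the
  asymmetric overlap fraction |A∩B|/|A| (`metric = "overlap_fraction"`),
  exposed separately from Jaccard.
- Index serialisation is a gzipped, versioned, sorted postings-list TSV
  with a JSON manifest — diffable, streamable, and byte-stable for fixed
  inputs; a version mismatch is a hard error.
- Empty PSM tables map to all-zero counts with a warning; an empty
  reference index is an error.
- Assembly tables are read through a configurable column map so both real
  NCBI `assembly_summary.txt` files and fixture tables load identically.

## Known limitations

Mixed cultures are out of scope: the counting statistic assumes one
dominant organism per sample. Search-engine behaviour (scoring,
modification handling) is consumed, not modelled; contaminant spectra are
mapped like any other PSM and are expected to spread like noise. The
species database carries one strain per species by construction, which is
exactly the failure mode the second iteration exists to repair.
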