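---
title: "Surface biotinylation topology evidence: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface biotinylation topology evidence: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surftopo)
```

## The experiment this package models

Transmembrane proteins (TMPs) cross the plasma membrane one or more times;
knowing which residues face the extracellular space (the protein's
*topology*) constrains structure prediction and drug design. One way to
obtain residue-level topology evidence is to chemically label the cell
surface: a membrane-impermeable, amine-reactive reagent
(Sulfo-NHS-SS-biotin) covalently tags accessible primary amines — lysine
side chains and free N-termini — but only on the extracellular side of an
intact membrane. After membrane isolation, tryptic digestion, affinity
enrichment of biotinylated peptides, reductive elution and alkylation, each
label survives as one of two mass shifts on the peptide:

| remnant            | composition | monoisotopic shift |
|--------------------|-------------|--------------------|
| thioacyl           | C3H4OS      | +87.9983 Da        |
| CAMthiopropanoyl   | C5H7NO2S    | +145.0198 Da       |

The alkylated form is the thioacyl form plus a carbamidomethyl group
(C2H3NO), which the package verifies by mass additivity.

The decisive refinement modelled here is *pre-digestion*: mild proteolysis
of intact cells (trypsin or chymotrypsin) before labelling. Partial surface
proteolysis creates new peptide N-termini and uncovers occluded lysines,
both of which become labellable — so pre-digested samples reveal
extracellular positions invisible to plain surface labelling. Comparing
non-pre-digested controls (NPT/NPC) against treated samples separates
pre-existing from digestion-gained sites.

The pipeline consumes three inputs: a proteome FASTA, per-residue topology
annotations (TSV over the alphabet I/M/O/U: intracellular, membrane,
extracellular, unknown), and search-engine-style modified-peptide tables.
It emits called labelled sites, per-condition comparisons, validation
against the reference topology, and an extracellular ("O") constraint list
for consensus topology predictors.

## Pipeline model

1. **Filtering.** Rows are kept when the identification score is at least
   `min_logprob` (default 2, the score the original search pairs with a
   peptide FDR at or below 1%; FDR is not recomputed — no decoy information
   is available downstream of the search engine) *and* at least one reported
   modification matches a label mass within `mass_tolerance` (absolute,
   default 0.01 Da — wide enough to absorb both printed precisions of the
   label masses, e.g. 145.0198 vs +145.020). The boundary is inclusive.
   Rows whose only shift is deamidation (+0.984 Da, the N→D conversion that
   PNGaseF treatment also produces) are removed: that shift is never label
   evidence.

2. **Mapping.** Peptides are located by exact substring search over the
   whole proteome. Short-peptide BLAST with permissive settings is, in
   effect, an exhaustive lookup; exact matching is deterministic and
   testable against a brute-force all-offsets scan. Multi-locus peptides
   contribute evidence to *every* matched protein, flagged `ambiguous`, and
   sites supported only by ambiguous evidence are reported separately.

3. **Localization.** A label at peptide position 0 sits on the peptide
   N-terminal amine: it is a `protein_nterm` site when the match starts at
   residue 1 — or residue 2 of a Met-initiated protein when `mature_nterm`
   is set (initiator-methionine removal), the default — otherwise a
   `peptide_nterm` site created by pre-digestion. An internal label is valid
   only on lysine (`lysine_sidechain`); a label mass on an internal
   non-lysine is recorded as invalid evidence with a reason, never silently
   dropped. Coordinates are 1-based (UniProt convention).

4. **Site calling.** Evidence is grouped by (accession, position); a site
   may carry different contexts in different peptides and keeps all of them.
   Support is counted per condition (enzyme × treatment time), by default as
   observation rows (PSM-level; `support_unit = "distinct_peptides"` is the
   alternative, since "identified at least three times" admits both
   readings). A site is called in a condition when support reaches
   `min_support` (default 3). Sites reaching `control_min_support` in
   unlabelled control preparations are subtracted; with the sparse controls
   typical of this assay the subtraction is an identity.

5. **Comparison and validation.** Per enzyme series, the merged digest set
   (union of treated conditions) is partitioned against the series control
   into control-only ("lost to pre-digestion"), shared, and digest-only
   sites. Reference classes are Extracellular (O), Intracellular (I or M —
   "not extracellular"; membrane-residue calls are also shown in a separate
   diagnostic column so membrane-adjacent calls stay visible) and Unknown
   (U or unannotated). Accuracy is Extracellular / (Extracellular +
   Intracellular) over the merged unique site set, deduplicated by
   (accession, position); it is reported as `NA` when no known-class site
   exists. Constraint export writes one `accession TAB position TAB O` line
   per called site; this evidence type never supports I or M constraints.

## The forward simulator

The simulator generates the whole experiment so every downstream stage has
ground truth to recover. Per condition it:

1. cuts the protein at protease sites whose residue is extracellular,
   each independently with probability `p_cleave` (a Bernoulli per-site
   model — the simplest model of mild digestion, with `p_cleave` standing
   in monotonically for digestion time); intact membranes shield I and M
   residues completely, so no surface cut ever occurs there;
2. enumerates accessible primary amines — the protein N-terminus when
   extracellular, each surface-fragment N-terminus (regardless of residue
   identity, which is how a serine can carry a peptide-N-terminal label),
   and extracellular lysines — and labels each with probability
   `label_efficiency`, drawing the alkylated form with probability
   `alkylation_rate`;
3. digests the surface fragments with trypsin to completion, never cleaving
   after a labelled lysine (the blocked-cleavage mechanism that produces
   the assay's characteristic missed cleavages). The membrane-prep digest
   acts on the surface fragments rather than the intact chain: surface
   proteolysis has already severed the backbone, which is what lets a
   chymotryptic surface cut site survive as a tryptic peptide N-terminus;
4. emits one observation row per support draw per site, plus unlabelled
   cysteine-containing "piggyback" peptides (co-purified via disulphide
   bonds), deamidation-only confounder rows, and — at `contamination_rate`
   — wrongly labelled intracellular amines with low-confidence scores.

### Occluded lysines

Treating every extracellular lysine as accessible would never produce
digestion-*uncovered* lysines, which are central to the assay. The simulator therefore draws, once per proteome, a per-protein set
of *buried* extracellular lysines (`buried_fraction`, default 0.3):
folded-surface positions occluded in the native state. A buried lysine
becomes labellable only in a pre-digested condition in which at least one
surface cut occurred in that protein. Because the mask is drawn with the
proteome (not per condition), accessibility is consistent across
conditions.

### Observability and peptide identifiability

Search engines do not identify very short peptides, and 2–4-residue
peptides match a proteome promiscuously. The simulator emits a site only
when it can sit on a peptide of at least 7 residues, extending the
0-missed-cleavage fragment by up to two missed cleavages (never across a
surface cut, which has severed the chain; never N-terminally past a
position-0 label, which pins the peptide start). Sites failing this are
recorded as unobservable and excluded from ground truth — they are real
labels the instrument could not see.

One asymmetry needs care: labelling an *uncovered* lysine blocks a tryptic
cut, which can lengthen a neighbouring peptide past the identifiability
threshold only in digest conditions. Such a detectability change is a
peptide-form artefact, not a genuine accessibility gain, so pre-existing
amine sites are additionally required to be detectable in the undigested
context (tryptic fragments with all exposed lysines label-blocked). With
full labelling efficiency this makes "digest-only" exactly equivalent to
"caused by new N-termini or uncovered lysines"; at lower efficiency the
equivalence is approximate because labelling itself is stochastic.

The proteome generator also regenerates proteins until every 7-mer is
unique proteome-wide, so identifiable peptides map to a single locus and
mapping ambiguity is an opt-in property of user data rather than a random
feature of fixtures. Real proteomes do contain repeated peptides; the
mapper handles and flags them, but clean ground-truth recovery is only
claimed for unique-sequence proteomes.

### Support and score models

Support per (site, condition) is `shift + Poisson(mean − shift)` with
`shift = max(1, min(3, floor(mean)))`: true sites are modelled as
reproducibly sampled — at the default mean of 5 every true site receives at
least the three observations that make it reportable under the study's own
filter, while means below 3 collapse toward single observations so sparse
designs under-support sites (raising the support threshold then costs
recall while precision stays perfect, and the package's tests assert that
direction). Scores are Normal, truncated at zero: confident observations at
`score_mu_true = 4` (sd 1) and spurious ones at `score_mu_false = 1.2`, so
the LogProb ≥ 2 filter is exercised meaningfully from both sides. The truth
table records, per site, both the emitted support and the confidently
scored support (score ≥ 2), because an observation below the score
threshold is not an identification by the assay's definition.

### Default study conditions

Defaults are fixed once, from the study the simulator emulates, and are not
tuning knobs: 75 proteins with a single-pass (type I/II) fraction of 56/75
and large ectodomains (80–300 residues); an alkylation rate of 0.93 (the
assay reports ~93% of labels in the +145.020 Da form); a small
contamination rate (0.02) so that nearly all observations are biotinylated
or cysteine-containing (the assay reports ~97%); a quarter of proteins
with reference topology withheld (emitted all-U), mirroring the share of
positions with no prior characterization; and surface cut probabilities of
0 / 0.3 / 0.5 for control / shorter / longer treatment. Label efficiency
(0.8), the buried fraction (0.3) and the per-site cut probabilities are
free parameters the study does not quantify; they are documented here as
such and chosen to give realistic site yields. The two treatment times per
enzyme are opaque strings (NPC, 10min, 20min; NPT, 15min, 25min) and are
never interpreted arithmetically.

## Numerical choices and degenerate inputs

- Monoisotopic atomic masses (C, H, N, O, S) are embedded to ≥ 6 decimals so
  mass tests are self-contained; the deamidation shift is computed as
  O − N − H = +0.9840 Da.
- Mass matching uses an absolute 0.01 Da tolerance; the nearest label mass
  wins a tie.
- The Keil rule (no cleavage before proline) defaults on for both enzymes
  and both digestion stages and is configurable; chymotrypsin uses the
  five-residue high-specificity rule (F, Y, W, M, L) only.
- Empty observation tables, control-only tables and proteomes without
  topology are warnings with well-formed empty or all-Unknown outputs, not
  errors; parse and configuration errors (duplicate accessions, topology
  length mismatches, unknown parameter keys, probabilities outside [0, 1])
  fail loudly and name the offender.
- All simulation randomness flows from one integer seed; per-condition
  seeds are derived by small offsets, and identical configuration + seed
  reproduces byte-identical emitted datasets.

## What the tests do and do not show

The test suite recovers simulated ground truth exactly on clean data (no
contamination, full labelling efficiency, mean support 5, confident
scores) at 200 proteins, validates 0 intracellular calls there, and checks
the digestion model against a brute-force oracle on 1000 random sequences
plus a 10^4-trial binomial check of the partial-digestion cut frequency.
Module tests run at 6–60 proteins; the shared fixture uses 40. These sizes
were chosen to make every stochastic assertion stable across seeds.

Passing these tests shows the pipeline's bookkeeping — digestion rules,
coordinate arithmetic, context classification, support counting, set
algebra, validation — is correct, and that the statistical behaviour
(alkylated share, monotonicity, contamination surfacing as intracellular
calls) moves as designed. It does not show that real spectra are searched
correctly (the search engine is upstream and out of scope), nor that real
abundance, retention-time or co-isolation effects are captured: the
simulator has no intensity model, its support distribution is an
assumption, and real topology references contain errors the Unknown class
only partly absorbs.

## Known limitations

- Exact matching does not tolerate sequence variants or isoforms absent
  from the FASTA; one-mismatch mapping is deliberately out of scope.
- Site-localization probabilities (PTM scores) are not modelled; a label is
  taken at the position the search row states.
- Accuracy is undefined (reported N/A) when every called site is Unknown.
- The unlabelled-control subtraction assumes control samples share the
  proteome and conditions of labelled ones.
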