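---
title: "Screening genomes for null alleles in recessive retinal-degeneration genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genomes for null alleles in recessive retinal-degeneration genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdscreen)
```

# The problem

Recessive hereditary retinal degeneration (HRD) is caused by biallelic
mutations in any of more than a hundred genes. Each gene contributes few
cases, but a healthy individual can carry a deleterious allele in *any* of
them, so the aggregate carrier frequency can be high even though the
disease itself is rare. `hrdscreen` estimates that aggregate frequency from
a cohort of whole-genome variant call sets by counting individuals who
carry at least one *null* allele in a gene panel, and then propagates that
count through a small set of population-genetic calculations.

"Null" is defined narrowly and operationally, because these are the only
variant classes whose loss of function can be asserted from sequence alone:

* **nonsense** — an SNV whose mutated codon translates to a stop;
* **frameshift** — a coding indel whose length change is not a multiple of 3;
* **canonical splice change** — any variant touching intronic offset +1,
  +2, −1 or −2 of any intron (including introns between purely UTR exons,
  since exon loss upstream of the start codon can still destroy the
  transcript).

Start-codon loss is classified (`start_lost`) but deliberately **not**
counted as null: it is not part of the definition above, and its functional
consequence (downstream re-initiation) is less certain. Stop gains are null
regardless of their position in the transcript; no last-exon
nonsense-mediated-decay escape rule is applied. Missense pathogenicity
prediction is out of scope: missense alleles enter only through the
extrapolation ratio described below.

# The pipeline

## Transcript models and coordinates

Each gene is represented by one transcript: stranded, multi-exon, with
genomic CDS bounds and a mandatory reference sequence (models without
retrievable sequence are rejected rather than skipped, so a screen can
never silently lose a panel gene). When the transcript table offers several
transcripts per gene, the one with the longest CDS is kept, ties broken by
the lexicographically smallest transcript id. This canonical-transcript
rule is a package decision: annotation sources frequently enrol several
transcripts per gene and a deterministic, reproducible choice matters more
than which particular transcript wins.

Genomic input coordinates are 1-based inclusive (the VCF/GTF convention);
all internal interval arithmetic is 0-based half-open, converted only at
the I/O boundary. c. coordinates follow the usual clinical conventions:
c.1 is the A of the start codon, 5′UTR positions are negative, 3′UTR
positions are `*N`, and intronic positions are anchored to the nearest
exon boundary with a signed offset (`+k` past a donor, `-k` before an
acceptor; an exact midpoint anchors to the donor). `genomic_to_cds()` and
`cds_to_genomic()` are exact inverses on every exonic and intronic
position, a property the test suite checks exhaustively.

## Variant normalization

Variants are normalized to the VCF convention: shared prefix/suffix
trimmed to the single anchor base of an indel, and indels left-aligned by
repeated shifting while the flanking reference sequence permits an
equivalent spelling. The HGVS 3′-shift rule is **not** applied afterwards:
annotation strings are rendered from the left-aligned representation. The
two conventions disagree in repetitive contexts; rendering from the
left-aligned form keeps one canonical spelling per variant and matches the
house style of the legacy annotations the fixture reproduces
(`c.868delC`, `c.493_494insA`, ...). The synthetic data avoids planting
indels in ambiguous homopolymer runs so this choice never changes a
planted spelling.

## Consequence classification

Rules apply in a fixed order; the first match wins:

1. canonical splice (checked first, so an exonic indel that reaches into a
   ±1/±2 intronic base is splice — splice-site destruction is a standalone
   null class, not a coding event);
2. coding rules (frameshift / in-frame indel by length arithmetic;
   stop-gained / start-lost / missense / synonymous for SNVs by local codon
   translation; a length-preserving multi-nucleotide substitution is
   in-frame unless it writes a stop into the replaced codons);
3. exonic UTR, then intronic beyond ±2, then a `noncoding_other` fallback
   for boundary-spanning deletions.

The classifier is validated against an independent oracle that rebuilds
the entire mutant transcript, re-splices, translates, and compares whole
proteins — the two routes must agree on every random variant (the suite
runs over a thousand coding variants plus mixed-region variants, both
strands).

Frameshift protein names (`p.Q290fs`) label the first codon whose
**nucleotide triplet** differs between the reference and the shifted
mutant CDS, with the reference amino acid at that codon. Naming the first
*amino-acid* difference instead is not well defined for insertions at
codon boundaries whose inserted bases re-encode the reference amino acid
(the inserted codon can be synonymous with the codon it displaces), and
the triplet rule reproduces the legacy annotation style the fixture
encodes, including the wobble case where a partially deleted codon is
rebuilt unchanged and the name moves to the next codon. A frameshifting
indel whose immediate codon happens to become a stop is still reported
`fs`: the category (and the name) describe the frame disruption.

## Screening and carrier statistics

An individual is a carrier if it holds ≥1 null allele in any panel gene;
zygosity does not change carrier status, but a homozygous null counts two
alleles in the per-individual tally and raises a warning (an unaffected
cohort should not contain one). Absence of a VCF record is treated as
homozygous reference — no-call regions are not modelled. The FILTER column
is ignored by default (`pass_only = TRUE` restricts to PASS), since
upstream quality filtering belongs to the variant caller.

The default confidence interval is the Wald construction with
`z = 1.959964`, clipped to [0, 1]. Wilson and Clopper–Pearson intervals
are available (`binom_ci(method=)`) and intentionally disagree with Wald
at the fixture's `k = 10, n = 46` — the package treats the interval method
as part of the reported result, not an implementation detail. Wald is
anti-conservative at this sample size: exact binomial enumeration (run in
the test suite) puts its true coverage a few points below the nominal 95%
at `n = 46`, degrading further for small `p`. The tests therefore assert
empirical coverage against the enumeration value, within Monte-Carlo
error, rather than against 0.95 exactly.

The "one in X individuals" extrapolation is the **reciprocal of the
expected number of mutations per genome** after inflation:
`X = 1/(m·(1+r))`, optionally divided by the known-gene case fraction
`f`. Parameters and defaults: `r = 0.87` missense alleles per null allele
(a literature constant taken as input, not recomputed) and `f = 0.70`.
An alternative reading — treat the inflated rate as a Poisson mean and
report `1/(1 − e^{−rate})`, the probability of carrying at least one
allele — is exposed via `convention = "poisson_carrier"`; it gives
systematically larger X and is not the default, because the reciprocal is
the convention under which the package's reported figures (2.5 and 1.7 on
the fixture) are defined.

Consanguinity risk uses standard inbreeding-load arithmetic,
`P(affected) = Σᵢ[(1−F)qᵢ² + F qᵢ]`, treating genes as independent and
alleles as rare (no compound-heterozygote terms across genes). The risk
ratio versus panmixia is unbounded as `qᵢ → 0` at fixed `F` — rare-allele
amplification — which the tests assert numerically.

# The synthetic-data module

`simulate_cohort()` is a statistical stand-in for a real cohort, not a
genome simulator. Defaults encode the study conditions the package is
built around: 46 individuals, a 106-gene panel, and a per-gene null-allele
frequency of `0.217/(2·106)` so the expected number of null alleles per
genome is ≈ 0.217 in aggregate. Background rates (4 synonymous, 4
missense, 6 deep-intronic, 2 non-canonical splice-region variants expected
per individual) are round numbers chosen to exercise every benign
classification path at a realistic order of magnitude for a small gene
panel. Genotypes at each gene's engineered null site are drawn under
Hardy–Weinberg (`q²` homozygous, `2q(1−q)` heterozygous); homozygotes are
reported via a message.

Every planted variant is benign or null **by construction**, not by
post-hoc classification: nonsense plants use a reserved CGA codon (C→T
gives TGA), frameshift plants sit inside reserved codons whose flanking
bases forbid left-alignment shifts, benign synonymous/missense plants use
reserved CTT/GCT wobble sites, and intronic plants use offsets beyond ±8
(deep) or ±3..8 (splice-region, still benign). The truth manifest is
therefore an exact reference for recovery testing: the screen must find
precisely the planted nulls, no more and no fewer, across seeds.

`build_fixture_cohort()` is the deterministic counterpart: no randomness
at all, seven engineered genes whose codon layout pins down ten specific
null annotations (e.g. codon 1465 of the CEP290 stand-in is CGA so
c.4393C>T reads p.R1465X; intron 11 of the CC2D2A stand-in begins
immediately after c.1017; the AHI1 stand-in has a 5′UTR intron after
c.−55), 99 filler genes completing a 106-gene panel, and 46 diploid
individuals — ten carrying one heterozygous null each, all with six benign
background variants. Gene sequences are synthetic filler codons; no real
transcript sequence is embedded. Written twice, the bundle is
byte-identical.

What the generator does **not** emulate: real human genomic background,
linkage disequilibrium, population structure, sequencing error, no-call
regions, overlapping genes, and multi-transcript loci. Passing tests
demonstrate that the pipeline's logic is correct on well-formed input —
they say nothing about robustness to caller artefacts or reference-build
mismatches in real data.

# Numerical and degenerate-input choices

* Ties in intronic anchoring go to the donor side; ties in canonical
  transcript choice to the smallest transcript id; report rows are sorted
  (individual, gene, position) so output is stable under input shuffling.
* `k = 0` screens are valid (frequency 0, CI clipped at 0);
  `extrapolate_one_in_x()` refuses `m = 0` explicitly rather than
  returning infinity.
* An empty VCF body yields an empty cohort; missing genotypes are skipped
  and counted, multi-allelic records are split into biallelic variants
  before normalization.
* A panel gene without a transcript model aborts the screen with the
  offending gene names — a configuration error, not a datum.

# Problem sizes in the test suite

The suite validates coordinates exhaustively on transcripts up to ~2 kb,
runs the classifier/oracle comparison on >1,000 random coding variants,
recovery on 20 simulated cohorts (46 individuals, 8 genes each), carrier
convergence on 500 small simulated cohorts, and CI coverage on 2,000
binomial replicates — sizes chosen to make every property statistically
meaningful while keeping the default run in tens of seconds.

# Known limitations

* One transcript per gene: consequences on alternative isoforms are not
  reported.
* The ±2 splice rule is a conservative proxy; extended splice-region or
  deep-intronic splice-creating variants are never called null.
* Wald's anti-conservative coverage at n = 46 is inherited by design; use
  `method = "wilson"` or `"exact"` when the interval itself matters more
  than matching the package's default reporting convention.
* The extrapolation constants (0.87, 0.70) are inputs with no uncertainty
  propagation; the one-in-X figures are point extrapolations, not
  estimates with intervals.
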