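---
title: "Mining Tc1-like elements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining Tc1-like elements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tlemine)
```

# The problem

Tc1-like elements (TLEs) are Class II DNA transposons of the Tc1/mariner
superfamily. A complete element carries terminal inverted repeats (TIRs) —
in the family studied here 33 bp long and beginning with 5'-CAGT (ending,
by complementarity, with ACTG-3') — and is flanked on both sides by a
duplicated "TA", the target-site duplication (TSD) created on insertion
into a genomic TA. Internally it encodes a transposase whose catalytic
center is an acidic triad; the count of residues between the second and
third residues defines the subgroup (DD34E for Tc1-like, DD34D/DD37D/DD39D
and others for mariner-like elements). `tlemine` implements the full
annotation workflow for such families: homology-seeded discovery,
TIR/TSD-bounded element definition, family retrieval, consensus-divergence
dating, related-empty-site analysis, expression mapping, and a bootstrap
neighbor-joining transposase phylogeny — together with a seeded synthetic
genome generator that provides ground truth for every stage.

# The synthetic data model

`simulate_tle_genome()` plants a designed family into an i.i.d. background
genome:

* **Background** — independent bases at a chosen GC content. Real genomes
  carry repeats, compositional domains and genes; none of these are
  simulated, so passing recovery tests demonstrates correctness of the
  algorithms under the stated signal model, not robustness to every real
  genomic nuisance.
* **Consensus element** — `TIR + buffer + 5'UTR + CDS + 3'UTR + buffer +
  revcomp(TIR)`, by default 1,584 bp with 33-bp TIRs and a 338-aa
  transposase, the architecture of the archetypal moss family. A fixed
  4-bp non-pairing buffer ("GGGG" opposite "GGGG", which cannot base-pair)
  sits just inside each terminus so that the designed TIR length is the
  unique score-maximal inverted repeat; without it, a detector allowing a
  10% mismatch fraction would almost always extend a perfect TIR a few
  bases into random sequence (3 random extra positions at L = 36 are
  always within the `floor(0.1 * 36) = 3` mismatch budget).
* **Transposase design** — random residues except a fixed N-terminus and
  fixed 6+4-residue blocks around each catalytic position, mimicking the
  conserved motifs that real Tc1/mariner transposases carry around the
  triad. The triad spacing is encoded by the class label (`DD34E` puts
  34 residues between the second D and the E; the first-to-second spacing
  is fixed at 76). The conserved blocks are what make reference-anchored
  triad mapping meaningful on generated proteins.
* **Divergence** — each copy is mutated independently: per-site
  substitutions at `p_sub` (uniform over the three alternatives, no
  transition/transversion bias, since the dating clock is stated in raw
  percent divergence) and per-site indel events at `p_indel` with lengths
  1–3 (uniform) and insertion/deletion equiprobable. No published indel
  model exists for these families; this is the simplest neutral choice.
* **ORF disruption** — a stated fraction of copies receives one internal
  stop codon, placed in the first 85% of the CDS so that no >= 95%-length
  fragment survives. Random substitutions also create premature stops
  (about half of all copies at `p_sub = 0.015` carry one), so the truth
  table's `has_intact_orf` is computed *operationally* on the mutated copy
  — longest ORF at least 95% of the designed protein length — with the
  same rule the annotator later applies.
* **Insertion** — each copy lands at a distinct genomic "TA" (kept >= 400
  bp apart so flanks stay unique), which is duplicated; the copy is
  reverse-complemented with probability 0.5 so both orientations are
  exercised. Genome length grows by exactly `copy length + 2` per
  insertion.
* **Companions** — related-empty-site loci (pre-insertion paralogs,
  excision footprints with 1–10 extra junction bases, AT-rich
  simple-repeat contexts), transcripts (optionally spliced; every
  intact-ORF copy gets one full-CDS transcript), and small-RNA reads with
  or without CDS matches.

Everything is driven by one integer seed; a fixed seed gives byte-identical
FASTA/BED/TSV outputs.

# The mining model

`mine_elements()` is a two-stage miner.

**Stage 1 — de novo.** `search_transposase()` translates all six frames
(stops kept as markers), seeds exact 4-aa words shared with the query, and
extends each seed cluster by local BLOSUM62 alignment. A hit must reach
50% of the query's self-score over the aligned region *and* an absolute
floor (default 60), which in practice silences background genomes
completely while retaining fragments of roughly 25 aa and up. Hits are
clustered per element (gap <= 350 bp: a disrupted or frameshifted
transposase fragments into several nearby hits, while neighboring planted
elements are farther apart), and each cluster is extended to the
best-scoring TA-flanked inverted-repeat pair (`extend_to_element()`).
Pairing uses edit distance rather than ungapped mismatches — an indel
inside a TIR merely shifts the arms — and rejects pairs whose pairing
continues essentially unbroken past the candidate length: those are
inverted *duplications*, most importantly the genome-scale inverted repeat
formed by two neighboring copies inserted on opposite strands, not
terminal repeats. Extension is also bounded by the neighboring hit
clusters, since one element carries one transposase.

**Stage 2 — consensus-anchored.** A provisional consensus built from the
stage-1 candidates defines two terminus anchors (first and last 100 bp;
the anchor must reach well beyond the TIR, because the TIR itself is
shared by both termini and both orientations). `anchor_scan_members()`
then scans every TA-preceded and TA-followed position in the genome for
windows within 25% edit distance of an anchor, in both orientations, and
pairs starts with ends of consistent orientation within 0.3–1.5 times the
consensus length, preferring the pair with the smallest summed edit
distance. This recovers exact boundaries even for copies whose own TIRs
have decayed past de-novo detection, and for copies whose transposase is
too degraded to produce a homology hit. Clusters that the scan leaves
uncovered fall back to per-cluster boundary refinement; exact-terminal
retrieval (`retrieve_members()`, zero end mismatches, the historical
family-retrieval rule) is run last as a safety net. The final member set
is re-aligned, the consensus rebuilt, and members flagged full-length
(intact terminal 4-mers + >= 90% consensus coverage) and intact-ORF
(longest ORF >= 95% of the consensus ORF length).

# Family dynamics and dating

The family alignment is a center-star multiple alignment around the member
closest to the consensus length ("once a gap, always a gap" merging of
pairwise global alignments). The consensus takes the per-column majority
base, omits majority-gap columns, and breaks base ties toward the
exemplar. Each copy's divergence is the complement of its pairwise
similarity to the consensus, where similarity is identities over alignment
columns after trimming terminal-gap columns; internal gap columns count as
mismatches, so indels contribute to divergence but truncation artifacts do
not. Divergences are binned at 0.5%; the modal bin center divided by the
clock rate (default 1% per million years, the rate conventional for moss
TE dating, overridable via `clock_model()`) gives the age of the dominant
amplification burst.

Two numerical notes. First, the rebuilt consensus absorbs shared noise, so
recovered mean divergence is biased slightly *below* the applied
substitution rate; the validation band [0.8, 1.05] x rate is asymmetric
for this reason, and the test pools three 75-copy families per rate
because a single 75-copy mean has a sampling error of about 3% of its
value. Second, the stated rates (1%, 2%, 4%) fall exactly on 0.5%-bin
boundaries, so "the modal bin contains the rate" is checked on the closed
bin (|modal center − rate| <= 0.25): with the true mean on a boundary,
either adjacent bin is a correct mode and open-interval membership would
be a coin flip by construction.

The `"±"` in a family summary is reported both ways (sd and se = sd/√n);
for a 75-copy family with the observed spread, se is the reading
compatible with published values of the form 2.18 ± 0.08%. Mean identity
figures are computed copy-to-consensus (matching the divergence
definition), not as all-pairs averages; both interpretations exist in the
literature.

# Triad classification

`locate_triad()` aligns a protein locally (BLOSUM62) to the best-scoring
annotated reference and maps the reference's three catalytic positions
through the alignment; the call is complete when all three map to D/D/[DE]
in order. Classification is reference-anchored rather than a de-novo
acidic-residue scan because acidic-rich proteins over-call badly under
pattern scanning. The packaged reference set is *synthetic*: one designed
exemplar per spacing class (DD34E, DD34D, DD35E, DD37D, DD37E, DD39D)
produced by the package's own transposase designer, sharing its conserved
triad-flanking blocks. Users analyzing real proteins should supply their
own annotated references in the same FASTA + TSV format.
`triad_completeness()` answers the survey-table question: Y iff all three
residues map, are acidic, and the second-to-third spacing is within the
known 31–39 range.

# Related empty sites

For each insertion, 100-bp flanks (excluding the TSD) are matched against
the genome at >= 80% identity; co-linear left/right matches separated by
at most 50 bp define a candidate RES. A junction of exactly "TA" is the
pre-insertion state; "TA" plus 1–10 extra bases is an excision footprint;
flanks that are AT-rich (>= 80% A/T) with low dinucleotide entropy are
called AT-rich simple-repeat context regardless of junction, since such
matches reflect repeat homology rather than a specific paralog. The
entropy threshold is 3.0 bits: random DNA sits near 3.9 bits while
short-unit repeats, even carrying a few percent of point mutations, stay
below about 2.7. Junctions that are a tandem duplication of a 1–4 bp unit
additionally raise a microsatellite-duplication flag. RES records never
overlap annotated family members (self-exclusion). The flank length,
identity, and junction tolerance are unpublished operational choices,
exposed as arguments.

# Expression and phylogeny

Transcripts are aligned transcript-global/member-local so spliced-out
introns appear as long transcript-row gaps; runs of >= 20 aligned columns
form matched blocks and >= 20-column transcript gaps count as introns.
Because members may be supplied as genomic plus-strand slices and
transcripts arrive in mRNA sense, both are brought to a common orientation
(shared 12-mer vote) before alignment. A transcript encodes a full
transposase when its longest ORF reaches 95% of the family ORF length;
counting deduplicates by id + sequence and cross-references each counted
transcript to its source copy. Small RNAs are matched to the CDS on both
strands with at most two mismatches (tolerance exposed; the published
analyses do not state one).

The transposase phylogeny uses identity distances (1 − fractional identity
from global BLOSUM62 alignments — an uncorrected distance, documented as a
simplification relative to model-based corrections), neighbor joining via
\pkg{ape}, and bootstrap support from resampling the columns of a
center-star protein alignment; 1,000 replicates is the conventional
setting. Trees are emitted unrooted with supports as internal node labels.

# Problem sizes used in validation

The validation suite exercises the complete pipeline on a 200-kb genome
with one 75-copy family at `p_sub = 0.015`, `p_indel = 0.001` and 10%
targeted ORF disruption — sizes chosen to match the scale of the moss
family this architecture models (85 genomic copies, 75 full-length) while
keeping a full run in the low minutes on one core. Divergence-rate
recovery uses three independent 75-copy families at each of 1%, 2% and 4%;
the related-empty-site suite plants 15 cases (5 per class) around 15
copies in 60 kb; the expression fixture keeps 9 intact-ORF and 3 disrupted
copies, mirroring a family with nine actively transcribed members.
`scripts/acceptance.R` re-runs the same conditions from a single
command-line seed.

# Known limitations

* The background model is i.i.d.; tandem repeats, segmental duplications
  and gene content can create TA-flanked inverted structures the miner
  would have to arbitrate in real data.
* Identity-based phylogeny distances saturate for deep divergences; the
  tree is meant for family-level relationships.
* The e-value statistics of database search are not reproduced; the
  score-threshold calibration is validated on synthetic data only.
* Copy counts and divergence figures for real genome assemblies depend on
  assembly quality and search thresholds, and should be read as
  assembly-level, not genome-level, quantities.
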