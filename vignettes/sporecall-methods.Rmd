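---
title: "Two-stage GHMM gene prediction from assembled RNA-seq transcripts"
author: "SporeCall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage GHMM gene prediction from assembled RNA-seq transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SporeCall)
```

## The problem

Fungal genomes are gene-dense, with short introns (tens to a couple of
hundred nucleotides) and little alternative splicing.  Two consequences
matter for annotation.  First, transcript assembly from RNA-seq works
unusually well: a large fraction of assembled transcripts are full length, so
coding sequences can be predicted *directly from transcript sequence* rather
than only from the genome.  Second, the density creates a characteristic
failure mode: untranslated regions (UTRs) of neighbouring genes overlap on
the genomic DNA, so assemblers merge the reads of adjacent loci into single
"transcripts" spanning two or more genes — on the same strand, or (with
unstranded RNA-seq chemistry) on opposite strands (sense–antisense, S-AS,
overlap).

SporeCall predicts protein-coding genes from an assembled genome plus
genome-aligned assembled transcripts (GTF/GFF3, e.g. from a short-read
assembler).  It uses RNA-seq evidence twice: to train its models without any
curated training set (self-training), and *at prediction time*, by first
decoding the transcript sequences themselves and then decoding selected
genomic regions under transcript-derived splice constraints.

## Stage 1: prediction from virtually spliced transcripts

Each transcript's exon blocks are concatenated ("virtually spliced"), so
stage 1 never has to find introns: any intron boundary in a stage-1 gene is,
by construction, exactly an evidenced intron of the alignment.  The
transcript-space generalised hidden Markov model (GHMM) has states

* `five_prime_utr`, `three_prime_utr` — variable length, k-order Markov
  chain emissions (default order 5, shared table);
* `kozak_start` — fixed 11 nt, a second-order weighted array matrix (WAM)
  ending at, and including, the ATG;
* `cds` — the coding body between the ATG and the stop codon, emitted by a
  three-periodic Markov chain (default order 5) with durations restricted to
  multiples of 3;
* `stop_codon` — fixed 3 nt, a literal motif over TAA/TAG/TGA;
* `middle_utr` — the inter-gene region inside a merged transcript; it makes
  parses with several genes per transcript possible (`stop_codon ->
  middle_utr -> kozak_start`), which is how same-strand merged transcripts
  are handled correctly;
* `noncoding_transcript` — a whole-transcript alternative for transcripts
  without convincing coding content.

Self-training starts from the longest methionine-initiated ORF of each
transcript, with three published restrictions re-applied at every round:
coding examples shorter than 600 nt are excluded from emission training (the
small-false-positive guard), ORFs of 300 nt or more are excised from UTR
examples, and of genomically overlapping candidate genes only the longest is
kept.  The GHMM is then run and retrained twice — exactly twice, regardless
of convergence — and run a final time.

Unknown-strand transcripts (unstranded libraries) are spliced in both
orientations; the orientation with the higher parse log-probability wins,
ties going to the forward strand.

## Stage 2: prediction from genome sequence

Stage-1 genes that are error-prone are discarded: every single-exon gene
(these harbour the antisense false positives that arise when a UTR of a
merged transcript contains coding sequence of the opposite strand), and
every gene whose reading frame is still open at the transcript's 5'
boundary, i.e. whose ORF could extend beyond the supporting transcript
("suspected incomplete", the signature of a 5'-truncated assembly).  The
genome outside the retained genes — discarded loci, flanks, transcript-free
gaps, padded by 200 nt and split into windows of at most 10 kb — is then
decoded by a second GHMM on both strands, which also recovers genes that
were not expressed at all.

The stage-2 model reuses the stage-1 coding, start and stop models, folds
the UTRs into a larger `intergenic` state, and adds an explicit intron
sub-model: donor, branch-point and acceptor states with first-order WAM
emissions, joined by variable-length spacer chains.  Donor and acceptor
windows extend 2 nt into the adjacent exon and their lengths are fitted
per-genome: moving outward from the invariant GT (inward from the AG), a
position belongs to the boundary while its base composition differs from the
pooled intron-interior composition by a chi-square test at p = 0.01 (df = 3,
critical value 11.345), up to a total of 22 nt.  The maximum intron length
is 1.1 times the longest evidenced intron, capped at 5000 nt (the cap is
removable for long-intron species).

Reading frame is carried across introns by expanding the exon state by
(entry phase, exit phase) — nine states whose durations satisfy
`d = (exit - entry) mod 3` — and tagging the intron chain with the exit
phase; the 2 + 2 exonic nucleotides inside the donor and acceptor windows
advance the frame by one codon between exons.  In-frame stop codons are
excluded from exon states by a frame-aware position mask, so every stage-2
gene translates cleanly (a final validation drops the rare candidate whose
stop straddles a splice junction, which the per-position mask cannot see).

RNA-seq restricts stage-2 introns in two ways: donor/acceptor boundaries
must sit on GT/AG dinucleotides, and they are forbidden wherever a
same-strand transcript covers the position — except within 50 nt of that
transcript's ends, where assemblies fray.  Unstranded data forbids
boundaries on both strands.  Additionally, wherever deleting an evidenced
intron would let an ORF read through it without hitting a stop codon, the
window is flagged for alternative-splice prediction and structurally novel
stage-2 candidates there are kept as variants.

## Merging, filtering, reporting

Stage-1 and stage-2 predictions are merged with stage-1 winning same-strand
coding overlaps (RNA-seq-supported predictions are higher confidence);
alternative-splice candidates that differ structurally survive into variant
arbitration.  Three filters follow, in order: genes translating to fewer
than 30 amino acids are removed; of overlapping splice variants only those
with at least one unique intron or at least 10 unique amino acids are
retained (the highest-scoring variant of a locus always survives); and a
gene overlapping a larger opposite-strand gene is removed when less than
20% of its coding sequence lies outside the larger gene's span.

Two reports complete a run.  Transcripts whose extent overlaps the coding
sequences of two or more final genes are listed as suspected merged
(fused) assemblies with the strand pattern of their constituents.  And in
every transcript left without any overlapping prediction, a gene is forced
by re-running the stage-1 model with the transition into the non-coding
state set to zero; these "dubious" genes are written to a separate file and
never join the main annotation.

## Scoring and numerical choices

* All decoding is explicit-duration Viterbi in log space, exact and
  deterministic.  Ties are broken toward the parse whose segment-boundary
  sequence is lexicographically smallest, then by state order; the same rule
  is implemented in `enumerateParses()`, an exhaustive oracle used by the
  test suite to verify the decoder on hundreds of random models.
* Emission tables carry a pseudocount (0.01 per cell).  The first k
  positions of every decoded segment are scored with shortened
  (segment-local) contexts from backoff tables estimated at training time.
  Markov chain orders fall back automatically when fewer than
  `50 * 4^k` training events are available.
* WAMs additionally use hierarchical backoff smoothing (order-m conditionals
  shrunk towards order-(m-1) with prior strength 8): with a few hundred
  training windows, unsmoothed order-2 tables assign catastrophic penalties
  to unseen (context, base) pairs and can score a genuine translation start
  below a random window.
* Per-gene scores are log-odds against the background state (UTR chain in
  stage 1, intergenic chain in stage 2) over the same span.  Raw parse
  log-probabilities scale with length and would rank short spurious genes
  above long real ones wherever two candidates compete (opposite-strand
  reconciliation, variant arbitration).
* Duration models are smoothed length histograms (triangular kernel,
  half-width `max(2, width/50)` by default) with a small uniform floor and a
  geometric tail fitted to the mean excess above the observed maximum.
  Coding durations live on a step-3 grid.  For decoding speed the intergenic
  duration grid is capped (default 500 nt + tail) with a self-transition
  covering longer gaps, and window sizes are bounded at 10 kb with 2.5 kb
  overlap; these are resolution/cost choices, not statements about gene
  structure.
* The ATG at the end of the start window and the GT/AG intron dinucleotides
  are hard constraints (forbidden otherwise), not just soft preferences —
  the gene-model invariants hold structurally.
* Constraint masks and frame-aware stop exclusion enter the decoder as
  additive penalty tracks; forbidden positions are tracked as prefix counts
  per reading-frame class rather than folded into cumulative sums, where
  their magnitude would destroy floating-point precision.

Choices the method leaves open, decided here: the branch-point WAM is 7 nt
wide, trained by two rounds of argmax alignment within 6–50 nt upstream of
the acceptor, initialised from the canonical fungal branch consensus
(TACTAAC) as a soft prior; intron spacers are order-2 chains; transition
probabilities are estimated by counting state adjacencies in the training
parses with pseudocount 1, with the prior of the non-coding transcript state
re-estimated each self-training round from the fraction of transcripts
parsed as non-coding; the stage-2 coding tables are copied from stage 1
(retraining them is configurable); two-strand decoding is implemented as
independent forward and reverse decodings per window with higher-log-odds
reconciliation of overlaps, rather than a doubled state space.

## The synthetic test-bed

The package ships a seeded generator (`generateSynthetic()`) rather than
bundled genomes, so the whole pipeline is testable offline.  Its default
world is a compact fungal-like genome: lognormal intergenic gaps (~400 nt),
1–6 exons per gene, gamma-distributed CDS lengths (mean ~1200 nt,
multiples of 3, stop-free by construction), introns of 40–200 nt shaped as
GT + donor consensus (AAGT), a TACTAAC branch point ending 10–40 nt before
the acceptor, a pyrimidine-skewed acceptor (TTTC) + AG, and an A-rich Kozak
context before each ATG.  Coding sequence is drawn from a three-periodic
order-2 chain with Dirichlet-drawn conditionals, GC-skewed relative to the
AT-rich intergenic background — the same asymmetry that, in real genomes,
makes the reverse complement of coding sequence resemble coding sequence and
thereby produces the antisense false positives stage 2 exists to remove.
Every transcript-assembly pathology is individually switchable: unexpressed
genes, 5'-truncated transcripts, same-strand and sense–antisense merges,
false-positive introns.

What passing on this test-bed does and does not show: the generator draws
from exactly the model family the predictor fits (Markov chains, consensus
WAMs, clean GT..AG introns), so accuracy on it is an upper bound for real
data, where codon usage is not Markovian, splice signals are weaker and
dirtier, and assemblies contain artifacts beyond the five modelled ones.
The test-bed validates the *mechanisms* — training-set construction,
constraint handling, merged-transcript resolution, filtering — not a
real-genome accuracy claim.

Problem sizes used by the test suite and the acceptance script: 200 random
decoder-vs-oracle models (≤ 12 nt, ≤ 4 states); a 300-gene genome for
parameter recovery; a 200-gene clean genome for end-to-end accuracy; 30–40
gene genomes for each mechanism-isolation fixture.

## Known limitations

* Only ATG starts and GT..AG introns are modelled; non-canonical splice
  sites (GC-AG, AT-AC), selenocysteine readthrough and non-ATG initiation
  are out of scope.
* Genes whose ATG sits within 8 nt of the transcript 5' end cannot be
  represented in stage 1 (the fixed 11-nt start window does not fit); such
  genes are recovered, if at all, by stage 2.
* The intron-length cap is enforced through the spacer duration bounds;
  because the branch-to-acceptor spacer has its own window, the effective
  maximum is met exactly only when that spacer is minimal (conservative by
  at most the branch-window width).
* Transcripts are assumed to lie on single contigs; trans-splicing and
  multi-contig alignments are rejected at parse time.
* A stop codon assembled across a splice junction is caught by post-hoc
  validation, not by the decoder's in-frame stop mask.
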