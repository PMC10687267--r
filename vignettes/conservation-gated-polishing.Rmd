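---
title: "Conservation-gated correction of modification-mediated nanopore errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation-gated correction of modification-mediated nanopore errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The error model

Nanopore basecalling converts an electrical current trace into bases. DNA
modifications perturb the current; when the modification type is
represented in the basecaller's training data the model compensates, but a
*novel* modification system that edits a genome at tens of thousands of
motif sites produces errors with three linked properties:

* **systematic recurrence** — the same draft locus is miscalled across
  reads, so the pileup majority is wrong and read-consensus polishing
  cannot fix it;
* **discordancy** — the miscall is not deterministic, so a visible
  minority of reads still carry the true base;
* **depressed quality** — the basecaller is uncertain, so Phred scores at
  the locus are much lower than background.

Because regulatory modifications are conserved within a lineage, the true
allele is recoverable from closely related genomes: at a genuinely
modified locus the homologs are essentially unanimous, whereas at a true
strain variant they agree with each other but *disagreement is genuine* —
and critically, the read pileup there is clean and high-quality. The
correction rule therefore uses read evidence to nominate loci and homolog
conservation only as a gate, never as the sole trigger.

## Pipeline and parameters

### Homolog selection

Candidates are ranked by MinHash sketch identity (`build_sketch()`,
`mash_similarity()`): each genome is reduced to the `sketch_size`
(default 1000) smallest 53-bit hashes of its distinct canonical k-mers
(k = 21; a k-mer and its reverse complement hash identically, so sketches
are strand-symmetric). The Jaccard similarity `j` estimated from the
merged bottom-s of two sketches maps to an identity through the Mash
distance `d = -ln(2j/(1+j))/k`. The top `t = 20` genomes with identity
strictly above 0.95 proceed.

Sketch identity has limited resolution between very close genomes, so
survivors are re-estimated by fragment alignment (`fragment_ani()`): the
candidate is chopped into non-overlapping 3000 bp fragments (a terminal
remainder shorter than 1500 bp is dropped, a longer one is kept; fragments
never span FASTA records) and each fragment is mapped to the draft with
minimap2. A fragment is *aligned* when the exactly matching bases of its
best hit cover at least 80% of the fragment. ANI is the mean identity
(matches over alignment columns) of aligned fragments; ASI is the
percentage of fragments that aligned at all, which falls when the two
genomes differ by insertions, deletions or transferred genes rather than
point mutations. Retention requires ANI > 99 and ASI > 90 (strict);
when fewer than 3 genomes pass, the strict filters are abandoned and the
whole Mash screen is retained (`fallback_used` is flagged) — conservation
estimated from almost no genomes is worse than conservation from slightly
more distant ones.

Two conventions here were genuinely open and are fixed as follows: the
*homolog* is the fragmented query and the draft the reference (ASI then
measures how much of the homolog maps onto the draft), and multi-record
FASTA files are sketched per file. Both are documented function contracts.

### Pileup statistics

`pileup_from_read_alignments()` reduces a reads-to-draft SAM/BAM to dense
per-position A/C/G/T counts plus the summed Phred quality; secondary,
supplementary and unmapped records are excluded, and only aligned
(`M`/`=`/`X`) bases count — insertions, deletions, clipped bases and `N`s
contribute nothing. Quality is averaged arithmetically in Phred space
(the default; probability-space averaging is available via
`mean_quality(space = "probability")`). Reads are not quality-trimmed.
MAPQ is not filtered by default (`min_mapq = 0`). Homolog alignments
(`pileup_add_homologs()`) contribute counts only — a homolog base has no
basecall quality — and each homolog query contributes at most one count
per draft position regardless of overlapping alignments.

### Candidate calling and correction

A locus is a candidate iff

* allele discordancy `(depth − major)/depth` **>** 0.05, and
* mean quality **<** 15,

both strict, as are all retention cutoffs above. The ratio is computed as
`(depth − major)/depth` rather than `1 − major/depth` because with integer
counts the former is exact: a pileup of 1 minority base in 20 is *exactly*
0.05 and must not pass a strict 5% threshold through floating-point
round-off. Depth floors (reads ≥ 5, homologs ≥ 3) guard against deciding
conservation from one or two genomes; both are exposed parameters.

For each candidate the homolog consensus is the maximal-count allele
(a tie leaves it undefined and the locus untouched); its conservation is
`max/sum` over homologs *aligned at that locus* — uncovered homologs
abstain. The correction applies only when all gates pass:

1. conservation reaches the requirement — exactly 1.0 in default mode
   (integer counts make the comparison exact), or ≥ 0.8 inside an
   occurrence of a user-supplied motif on either strand (IUPAC W/S are
   expanded; other ambiguity codes are rejected);
2. the consensus differs from the draft allele (a candidate whose
   consensus *equals* the draft is left untouched and logged, not
   re-examined);
3. the consensus allele is observed among the read alleles at the locus —
   the corrected-to base must exist in the pileup. `allow_unseen_allele`
   relaxes this for expert use.

Corrections are single-base substitutions, so coordinates never shift and
re-polishing the output with the same alignments is a no-op: at a
corrected locus the consensus now equals the draft allele and gate 2
closes. This idempotence is asserted in the test suite.

### Motif extraction

The extraction procedure is deliberately simple and auditable rather than
a wrapper around a motif-discovery suite: fixed-width windows (default 11,
odd) centered on corrected loci, strand-canonicalized (each window is
replaced by the lexicographic minimum of itself and its reverse
complement, making the report invariant to reverse-complementing the
genome), summarized as a position frequency matrix, a per-column consensus
(single base at ≥ 0.75 frequency, two-base IUPAC code when the top two
reach 0.9, else N) and a ranked count of all k-mers (default k = 5)
overlapping the window center. Centering on the corrected base and
scanning every overlapping k-mer means the modified base may sit at any
offset inside the motif and the motif is still recovered whole. Windows
are taken from the *polished* sequence, where the corrected locus carries
the true base and the motif context is intact. The report is built from
corrected loci; candidate loci can be passed instead when exploring.

### Evaluation

`assembly_quality()` aligns assembly to reference (minimap2, `--eqx`,
chained primary + supplementary segments) and reports
`Q = -10·log10(errors/aligned bases)` capped at 60, the conventional
reporting ceiling for a perfect desk-scale genome; indels are counted per
base by default and per event with `indel_per_event = TRUE`.

## What the synthetic generator emulates — and what it does not

`simulate_truth_set()` constructs the full scenario with a known answer.
Its defaults *are* the study conditions used throughout the tests and the
acceptance script: a 50 kb truth genome, 40 modified loci planted at the
central base of GCAGC occurrences (extra occurrences are planted when the
random background has too few), draft errors drawn from a fixed
transversion table, 20 strain-variant decoys (homologs unanimously carry a
transition allele that the draft does not, while reads confirm the draft
at high quality), 10 homologs at 0.5% SNP divergence (~99.5% ANI, SNPs
never placed on planted loci), and 30x reads of 3 kb. At modified loci a
read shows the error base with probability 0.7 and the truth base with
probability 0.3 at Phred 6–12 (expected discordancy 0.3, expected mean
quality 9 — comfortably inside the 5%/Q15 candidate region); background
bases err at 1% with Phred 20–30. Reads are emitted pre-aligned with
exact CIGARs so the suite never requires an external aligner, and all
randomness flows from one seed: identical seeds give byte-identical files.

The generator is honest about what it is not: it has no homopolymer indel
model, no signal-level error structure, no quality-by-position decay, no
chimeras, and a clean separation between "modified" and "background" loci
that real genomes blur. Passing tests therefore demonstrate that the
*decision logic* is correct under the stated error model — discordant
low-quality loci corrected, conserved strain variants spared — not that
the thresholds are optimal for any particular real dataset. The 5%/Q15
defaults are exposed parameters precisely because they are empirical.

Decoys deserve a note: they are constructed so that conservation alone
*would* correct them (homologs are unanimous and disagree with the draft).
They stay untouched only because their read pileups are clean and
high-quality, i.e. they never become candidates. This pins down the design
point that read evidence nominates and homologs merely confirm.

A known sensitivity limit, also exercised in the tests: a modification
that biases basecalls *consistently* (no minority of correct reads, or
quality not depressed) produces no discordancy signal and is invisible to
the method; with `minor_fraction = 0` the generator reproduces this and
the draft error survives polishing.

## Numerical and implementation choices

* **Hashing.** Sketch hashes are splitmix64 over 2-bit-packed canonical
  k-mers (2 ≤ k ≤ 31), seeded, and truncated to 53 bits so they are exact
  in R doubles; the seed is stored in sketches and the database header,
  and sketches from different seeds refuse to compare.
* **Alignment.** All pairwise alignment (fragment ANI, optional read
  mapping, evaluation) delegates to minimap2, the aligner this field uses
  for exactly these steps; a missing binary raises an error that tells
  the user to supply pre-aligned SAM instead. SAM/BAM parsing is
  Rsamtools/GenomicAlignments; malformed-CIGAR records are skipped with
  a counted warning rather than failing the run.
* **Degenerate inputs.** Zero-depth loci have undefined discordancy,
  quality and conservation and are never candidates; an empty pileup
  yields an empty candidate table; polishing refuses to run with no
  homolog alignments at all, since conservation is then undefined
  everywhere; an empty sketch database ranks nothing and warns.
* **Tie-breaks.** Candidate ranking sorts by identity then genome id;
  k-mer ranking by count then k-mer; a homolog consensus tie disables
  the correction.
* **Problem sizes.** The test suite runs the full default conditions
  (50 kb, 30x, 10 homologs) across 20 seeds in its acceptance block and
  uses 8 kb / 25x fixtures elsewhere; these sizes give stable statistics
  (~1.5 M pileup bases per run) while keeping a full run in minutes on a
  single core.

## Limitations

* Substitutions only: homopolymer and other indel errors are the domain
  of upstream read- and reference-based polishers and are out of scope.
* Sensitivity depends on the homolog collection: for rare lineages with
  few close relatives the fallback widens the screen, but truly isolated
  genomes cannot be polished this way — the specificity-first gates then
  simply make no corrections.
* The motif extractor reports context enrichment; it does not model
  spaced or bipartite motifs and is not a general motif-discovery tool.
* Evaluation identity is computed over minimap2's chained alignment; for
  assemblies with large structural disagreements the aligned fraction,
  not only Q, must be inspected.
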