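---
title: "Models and methods behind snapvar"
author: "snapvar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snapvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

snapvar is a desk-scale, fully in-memory secondary-analysis pipeline for
paired-end short-read sequencing data. One call to `runGermline()` takes a
reference and raw read pairs through alignment, duplicate marking, base
quality score recalibration (BQSR), exhaustive indel realignment, pileup
snapshot construction and joint SNP+indel genotyping, and emits VCF. The
per-base evidence is persisted in a block-compressed, indexed *snapshot*
store, so calling can be repeated — and tumor–normal somatic analysis run —
without ever touching the reads again.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the bundled simulator does and does not emulate.

# The aligner

Alignment is seed-and-extend: a hash table over all reference k-mers
(default `k = 16`, k-mers occurring more than `maxOcc = 64` times flagged
repetitive and skipped) yields candidate diagonals for a read and its
reverse complement; diagonals within 25 bp cluster into candidate loci and
each locus is extended by affine-gap dynamic programming over a padded
window (match +1, mismatch −4, gap open 6, gap extend 1, so a length-L gap
costs 6 + L). Soft clipping falls out of the local-alignment semantics:
read ends are clipped exactly when clipping improves the score. A gapless
fast path (maximum-scoring subarray along the seeded diagonal) handles the
large majority of reads and falls back to the DP whenever a single clean
1 bp gap could still beat it.

Pairing maximizes `score1 + score2 + bonus` (bonus 20 for FR-oriented
mates whose insert lies within mean ± 4 sd); a seedless mate is rescued by
DP inside the window implied by its placed partner, accepted at ≥ 0.55 of
the maximal score. Mapping quality is 60 when the best candidate beats the
second best by ≥ 10 score points, otherwise six times the gap, and 0 for
ties; ties among placements resolve to the lowest (contig, position,
strand with + first) for determinism.

# Duplicate marking without sorting

Pairs are keyed by the unclipped 5′ coordinates and strands of both mates
(soft clips restored, mate keys ordered canonically), accumulated in one
hash pass — no coordinate sort of the read set is ever performed. Within a
key the pair with the highest summed base quality survives; exact ties
keep the first pair in input order, which makes the kept-*set* size
permutation-invariant even though the identity of a tie's survivor depends
on input order.

# Base quality recalibration

Covariates are the classical trio: reported quality, machine cycle in
sequencing orientation, and the preceding+current dinucleotide (17 bins,
one for a missing/N context). Every aligned, non-clipped base with
reported Q ≥ 2 contributes an observation; mismatches are counted against
the reference. The empirical quality of a cell is
`phred((mismatches + 1) / (observations + 2))`, capped at 60 — the +1/+2
smoothing keeps empty and error-free cells finite. Unseen cells fall back
to the reported-quality marginal.

There is no external known-sites file: a first-pass pileup masks every
position whose non-reference fraction is ≥ 0.2, so genuine variation is
not tabulated as machine error. This keeps the tool download-free; the
cost is that a small number of true-variant bases near the 0.2 boundary
can leak into the table, which at these sample sizes moves cells by far
less than one phred.

# Exhaustive indel realignment

Every insertion/deletion edit op across the reads becomes a hypothesis;
hypotheses are left-normalized through repeat context, merged, and kept at
support ≥ 2. Soft-clip clusters (≥ 4 reads sharing a boundary) seed an
insertion hypothesis resolved by the consensus of the clipped bases —
except within 30 bp of a gap-derived hypothesis, where the clips are
already explained by that event and a separate insertion seed would plant
artifact evidence.

Hypotheses group into windows (anchor ± 100 bp; 100 bp reads overlapping
the anchor therefore always lie inside). The haplotype set is the
reference window, one single-event edit per hypothesis, and — beyond the
one-event-per-haplotype design — a single *combined* haplotype applying
all mutually compatible gap-derived hypotheses. The combined haplotype
exists because two co-occurring indels on one haplotype are unreachable by
single-event edits and leave mismatch artifacts behind; restricting it to
one greedy-by-support compatible set keeps the work bounded at
`|haplotypes| ≤ |hypotheses| + 2`.

Every window read is scored against every haplotype with the aligner's DP
(exhaustive read × haplotype evaluation); the haplotype with the largest
summed read score wins, reference winning ties. A read is rewritten into
reference coordinates through the chosen events only when its score on the
winning haplotype strictly beats its original score; the rewritten
alignment legitimately pays the gap penalty in reference space, so the
monotonicity guarantee is on scores against the selected haplotype.
Two safeguards keep rewriting honest: alignments may not begin or end with
an insertion (boundary insertion runs become soft clips), and a composed
alignment containing adjacent I/D ops — a self-cancelling gap pair that is
never optimal under affine scoring, and arises exactly when a read does
not carry one of the haplotype's events — is rejected, leaving the read's
original placement. Realignment is idempotent: a second pass rewrites
nothing.

# The snapshot store

A snapshot holds one column per reference position (or per target-region
position in exome mode): stranded counts and quality/mapping-quality sums
for each base, an N/other count, a deletion-span count, total depth, and
indel event tables (inserted sequence or deletion length → stranded
support and, for insertions, summed base quality). Insertions anchor on
the reference base to their left, matching VCF anchoring; a deletion
registers its length at the anchor and increments span counts across the
deleted positions. The invariant `depth = base counts + N + deletion
spans` holds at every column.

On disk the container is little-endian binary: magic `SNP1`, version,
reference checksum, contig table, declared regions, block size (default
65,536 positions), a block index (byte offset, compressed sizes and a
payload checksum per block), then per-block deflate-compressed column and
event payloads. Deflate is the codec because it is what base R provides;
the format keeps the codec behind the block boundary so the choice does
not affect semantics. Region queries decompress only overlapping blocks;
a single-position query costs one block. Queries outside the declared
regions raise an explicit out-of-coverage error rather than returning an
empty result, and block corruption is caught by the checksum.

The store intentionally keeps per-base aggregates, not reads: read
identity is not recoverable, and mapping quality is kept as a per-base sum
(the caller uses the mean) rather than a histogram. Those are the two
documented fidelity gaps versus a BAM-backed pileup.

# The 16-genotype model

At each column the caller enumerates exactly sixteen diploid genotypes:
the ten unordered base pairs, four base/indel heterozygotes, the
homozygous indel `I/I`, and the compound indel heterozygote `I1/I2`, where
`I1` and `I2` are the two best-supported indel events at the site (ties
broken by type then payload). Genotypes referencing an absent event carry
posterior zero.

Observations at a column are the base counts (each class with its mean
quality) plus the event counts. A read is one observation: reads carrying
an indel event also deposited an aligned base at the anchor during pileup
(that keeps the depth invariant), so the caller subtracts total event
support from the reference-base count before forming observations. At a
strong indel column (event support ≥ 3 and ≥ 20% of depth) the residual
reference-looking bases are mostly reads that end too close to the event
to exhibit it; their evidence is alignment-limited rather than
base-quality-limited, so their quality is capped at 10. Deletion events
carry no per-event quality in the column and are scored at a fixed
evidence quality of 30 (`delQual`).

Each observation class with count n and quality q contributes
`n · log(½ P(obs|a1,q) + ½ P(obs|a2,q))` with `P(obs|a,q) = 1 − ε` on an
allele match and `ε/3` otherwise, `ε = 10^(−q/10)` (floored so a match
never has probability below 0.25). Priors derive from
`θ_snp = 10⁻³`, `θ_indel = 10⁻⁴` and a transition:transversion ratio of 2
(so transitions take 2/3 of the SNP het prior mass, consistent with a
genome-wide Ti/Tv near 2): ref/alt het `θ_snp·w`, hom alt `θ_snp·w/2`,
ref/I `θ_indel`, `I/I` `θ_indel/2`, compound and doubly non-reference
genotypes at product-order mass, hom-ref absorbing the remainder; the
sixteen priors sum to one, as do the posteriors at every site (asserted).

A site is emitted when the posterior-maximal genotype is not homozygous
reference; `QUAL = −10·log₁₀ P(hom-ref | data)`, capped at 10,000. Indel
alleles expand to left-normalized, anchored REF/ALT strings, and a
genotype mixing allele classes yields one record with two ALTs.

# Random-forest filtration

The classifier is a 200-tree seeded random forest over ten per-call
features (QUAL, depth, alt fraction, phred-scaled Fisher strand bias, mean
mapping quality, mean alt base quality, homopolymer run length, distance
to the nearest other candidate, indel flag, indel length), trained on
simulator-labeled calls: planted variants are positives, unfiltered calls
absent from the truth are negatives. Filter semantics follow the
probability/QUAL rule: PASS iff probability ≥ 0.95 and QUAL ≥ 30, LowQual
iff probability ≥ 0.95 but QUAL < 30, else RF_FAIL; with no model,
everything passes through flagged UNFILTERED.

# Somatic calling and CNV segmentation

The somatic caller works on a snapshot pair with matching reference
checksums. Per candidate site it evaluates the joint posterior over the
16 × 16 normal/tumor genotype pairs,
`prior(G_n) · P(D_n|G_n) · T(G_t|G_n) · P(D_t|G_t)`, where the somatic
transition keeps `G_t = G_n` with probability `1 − μ` (default
`μ = 10⁻⁶`) and spreads `μ` uniformly over the 15 alternatives. Indel
alleles are bound from the combined tumor+normal event support so `I`
names the same event in both samples. The somatic score is
`−10·log₁₀(1 − M)` with M the posterior mass of pairs where the normal is
homozygous reference and the tumor carries a novel allele; calls need
score ≥ 30 plus conventional artifact guards (normal and tumor depth ≥ 8,
normal alt fraction < 0.03, alt reads on both strands for SNVs — all
tunable).

One identifiability limit is worth knowing: the score is bounded above by
the germline-het-with-allele-dropout alternative at
`−10·log₁₀(θ_snp · w · 0.5^{D_n} / (μ/15))`, which crosses 30 only once
the normal depth reaches 24 at the defaults. Below that, no tumor signal
— however clean — can clear the threshold, so sensitivity statements in
the test suite condition on normal depth ≥ 24. Tumor purity is not
modeled; alt fractions are reported so users can post-filter.

CNV segmentation computes, per fixed 1 kb window, the median-normalized
depth ratio `r = log₂((tumor/tumor median)/(normal/normal median))`,
GC-corrected by subtracting the median ratio of the window's 2.5%-wide GC
bin, after masking windows with mean normal depth < 10. Recursive binary
splitting maximizes the two-sided t statistic; a split is accepted when
the mean shift is ≥ 0.2 and the Bonferroni-adjusted p value (within the
current segment's candidate splits) is below 10⁻⁴. Segments are GAIN at
mean r ≥ +0.3, LOSS at ≤ −0.3, else NEUTRAL, and they tile the analyzed
windows exactly. Binary segmentation was chosen over CBS or an HMM for
simplicity and determinism; at the simulated sharp breakpoints it recovers
boundaries within ±2 windows.

# The simulator

The simulator is first-class, tested code and the oracle for everything
else. `makeReference()` draws an i.i.d. sequence at the target GC (default
0.41). `plantVariants()` places SNPs and indels by per-base Bernoulli
draws (SNP rate 10⁻³ and indel rate 10⁻⁴ by default, matching genome-wide
human densities; the benchmark experiment raises the indel rate to 10⁻³
for counting power), het fraction 2/3, transitions drawn at 2:1,
geometric indel lengths (p = 0.4, max 20). `simulateReads()` draws
fragments uniformly per haplotype with a Gaussian insert (500 ± 25),
FR orientation, 100 bp reads at the requested depth; substitution errors
rise linearly from 0.1% at cycle 1 to 0.5% at cycle 100, reported
qualities are the phred of the cycle error rate jittered by ±3, and read
indel errors occur at 10⁻⁵ per base. The origin table records every
read's true placement and error cycles, enabling exact aligner accuracy
and coverage measurement. `makeTumorPair()` adds heterozygous somatic
events and scales fragment density by cn/2 inside CNV regions;
`makeTrio()` gives the child one haplotype from each parent (no
recombination at these scales), so the truth is Mendelian-consistent by
construction unless de novo variants are injected.

Two deliberate design points:

* **Unique truth representations.** A deletion/insertion pair planted
  within a few bases on one haplotype can edit the genome into a string
  exactly reproducible by a short run of substitutions — the planted
  representation then is not uniquely recoverable even by a perfect
  caller, and the package's exact allele matching would count a correct
  haplotype as an error. The planter therefore enforces a 10 bp guard
  band around indels (the degeneracy arises only when the substitution
  representation is no more expensive than the two-gap one, i.e. within
  about 6 bp); SNP–SNP spacing stays at 1 bp.
* **Parametric error model.** Real base callers have empirical, machine-
  specific error profiles; the linear cycle model preserves the
  properties the pipeline is sensitive to (quality-informative errors and
  a cycle trend) without external profile files. Consequently, passing
  tests demonstrate correctness under quality-faithful, mostly
  independent errors — not robustness to systematic, context-correlated
  error modes of real instruments, nor to mapping ambiguity of genuine
  genomic repeats beyond what random sequence contains.

# Evaluation

Calls are compared to truth by exact matching after left-normalization on
both sides: SNPs on (contig, position, alt allele); indels on the
normalized (anchor, type, payload) with no positional tolerance.
Multi-ALT records are decomposed into per-allele records first. With an
origin table, truth is restricted to variants covered by at least one
simulated read and per-variant simulated depth is recorded for
stratification; genotype concordance (het/hom) is reported separately
from site sensitivity. FDR is FP/(TP+FP).

# Problem sizes and determinism

All stages are deterministic given seeds: generators are pure functions
of (parameters, seed), alignment tie-breaks are lexicographic, and
rewriting rules require strict improvement. The test suite exercises a
60 kb/40× study for the unit and property tests, a 150 kb/30× trio, a
200 kb/40× tumor pair, and one 1 Mb/40× benchmark with roughly a thousand
planted SNPs and a thousand indels — the configuration
`scripts/acceptance.R` reruns from scratch. These sizes were chosen so the
whole suite completes in minutes on one core while every statistical
assertion retains real power (hundreds to a thousand events per check).

# Known limitations

* Columns aggregate reads, so per-read haplotype phasing and read-pair
  evidence are unavailable to the caller; sites are modeled independently.
* The realigner considers one combined haplotype, not the full
  combinatorial set; more than two interacting events in one window may
  stay partially unresolved.
* The somatic caller does not model tumor purity or subclonality, and its
  score saturates at shallow normal depth as described above.
* Multi-sample joint calling, gVCF output and structural variants beyond
  short indels are out of scope.
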