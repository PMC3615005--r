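---
title: "seqscrub: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqscrub: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes and why
the defaults are what they are. It covers the read-QC model, the
k-mer screening and filtering machinery with its threshold calibration,
the simulator and what it does and does not emulate, the numerical
choices, and known limitations.

## The quality-control chain

Raw sequencing libraries carry two distinct kinds of artifact. The
first is technical: base quality decays toward the 3' end of a read,
PCR amplification introduces exact duplicates, and library construction
leaves adapter and barcode ("tag") sequences inside reads. The second
is biological: reads from species other than the sequencing target,
introduced during sample handling or present in the sample itself, and
usually unknown in advance. `seqscrub` treats the two in sequence —
first technical read QC, then contamination identification and removal
— because technical filtering changes read content and should precede
any taxonomic decision.

### Read QC: stage order and accounting

`processReadSet()` applies, per read (or per mate of a pair), a fixed
stage order:

1. trim to `targetLength` (keep the 5' prefix);
2. trim the maximal all-below-`endTrimQuality` prefix and suffix
   (interior bases are never touched);
3. drop reads now shorter than `minLengthAfterTrim`;
4. drop reads with a tag match;
5. drop reads whose fraction of bases at or above `filterQuality` is
   below `minQualityFraction`;
6. remove exact duplicates, keeping the first occurrence.

The ordering is a design choice where several orders are defensible:
trimming runs first because it can salvage a read that would otherwise
fail the quality-fraction filter, and duplicate removal runs last so a
duplicate of a read already removed for cause cannot mask that cause in
the report. Each removed read is attributed to its *first* failing
stage, which makes the report a partition: on every run,
`input_reads == output_reads + sum(removed_by_cause)`. This identity is
enforced by a class validity check, not just tested.

The "fraction of bases above a threshold" filter is directional by
construction: a read *passes* when
`#{i : q_i >= filterQuality} / length >= minQualityFraction`. A
zero-length read (possible after end trimming) can never pass, but such
reads are already removed as `length` failures since
`minLengthAfterTrim >= 1`.

**Pairs.** With `keepPairs = "both-pass"` (default) a pair is emitted
only when both mates survive stages 1–5; the innocent mate of a dropped
pair is counted under the cause `pair_partner`. With `"either-pass"` a
pair is emitted whole when at least one mate survives. Duplicate
removal always operates on pair keys (`seq1 | seq2`), so mate order
matters and pairs never desynchronize.

**Parallel contract.** Stages 1–5 are a pure map over fixed-size read
blocks (`chunkSize`, default 10,000); blocks may run on several forked
workers (`threads`). Duplicate removal happens on the order-preserving
merge. Output is therefore bit-identical for any thread count — a
stronger guarantee than parallel QC tools usually give, and one the
test suite checks at threads 1, 2 and 8.

**Tag matching.** Tags are matched as full-length placements at inward
shifts `0..maxShift` from either end, with at most `maxMismatches`
Hamming mismatches (defaults 5 and 2; both ends scanned). Matching
reads are *dropped*, not clipped: with tags at arbitrary shifts the
remaining fragment is of doubtful provenance, and dropping keeps the
semantics of every stage "remove or keep", never "rewrite". A bundled
FASTA of standard Illumina/454 adapter sequences is used when
`TagSet(NULL)` is constructed. Partial tag overlap hanging off a read
end is not considered a match; 3'-adapter read-through shorter than the
full tag is out of scope.

**Duplicates** are exact, case-normalised, full-sequence identities.
No reverse-complement collapsing and no 5'-prefix ("optical/PCR stack")
heuristics: exactness makes the operation reproducible and its truth
trivially checkable against the simulator. The alternatives are
documented here precisely because they are *not* implemented.

### Contamination screening

Both screens replace database alignment with a canonical k-mer best-hit
classifier over user-supplied reference sequences. The decision
structure (best-hit species assignment, proportion-of-sample
quantification) mirrors alignment-based screening while staying
self-contained and deterministic.

- **rDNA screen** (qualitative): reads whose fraction of canonical
  k-mers present in the rRNA reference index (k = 12) reaches
  `minHitFraction = 0.5` are extracted and assigned to the
  best-scoring rRNA label. Ribosomal sequences are the classic
  taxonomic marker: 16S for prokaryotes, 18S for eukaryotes; which
  screen runs is decided purely by which reference file the user
  supplies.
- **Subsample screen** (quantitative): a Bernoulli subsample
  (`sampleProportion`, seeded) of all reads is classified against the
  candidate genome index (k = 16). Bernoulli ("each read independently
  with probability p") is the primitive matching "a user-defined
  proportion of all reads"; an exact-size mode exists behind a flag.
  Proportions are computed over classified reads, with the unassigned
  count reported separately.

A non-target label is **flagged** when it reaches
`dominanceThreshold = 0.02` of assigned rDNA reads *and* occurs in the
quantitative profile. The 2% default reflects the practical floor below
which rDNA hits are dominated by inter-species rRNA conservation noise
rather than genuine contamination; it is configurable. The two screens
thereby verify each other: one qualitative vote, one quantitative vote,
flag only on agreement. With no declared target, everything is
reported and nothing flagged — flagging is only meaningful relative to
an intended sequencing target.

**KL divergence.** `klDivergence(p, q)` returns
`sum(p_i * ln(p_i / q_i))` after aligning the label sets, substituting
`1e-10` for zero cells and renormalising. Direction is fixed as
KL(observed ‖ reference) and the base is `e` (nats). Any such
convention is defensible; this one is stated so results are
comparable across runs.

### Contaminant removal and the 0.4 threshold

`filterContaminants()` maps each read against the contaminant index and
removes it when the best shared-k-mer fraction reaches
`minMapFraction`. The default 0.4 is an analytic calibration, not a
fit. For a read of length L with e well-separated substitution errors,
each error destroys up to k of the L−k+1 k-mer windows, so the intact
fraction is approximately

    f(e) = (L - k + 1 - e*k) / (L - k + 1).

At L = 100, k = 16: f(1) = 0.81, f(2) = 0.62, f(3) = 0.44. Under a 1%
uniform error rate the error count per 100 bp read is Binomial(100,
0.01): P(e <= 1) = 0.74, P(e <= 2) = 0.92, P(e <= 3) = 0.98. A
threshold of 0.8 would therefore reject every read carrying two or more
spread errors and pass barely 74% of true contaminant reads; 0.4
accepts up to three spread errors and passes about 98%. Specificity is
not the binding constraint: a read from an unrelated genome shares
k-mers only by chance (p ≈ m/4^16 per k-mer for an index of m k-mers),
so even 0.4 is far above the noise floor for genome-scale references —
though users filtering against *closely related* genomes should raise
it. The same arithmetic sets the taxonomic assignment default
`minScore = 0.4` (at k = 16), while rDNA extraction keeps
`minHitFraction = 0.5` because at k = 12 three spread errors still
leave f(3) = 0.60 of the windows intact.

Reads mapping above threshold to both the target (when a target index
is supplied) and a contaminant are removed — the conservative choice —
and counted as ambiguous. Ties in best-hit assignment break to the
lexicographically smallest label, deterministically, with the tie count
logged.

## The simulator

`simulateReads()` is a minimal paired-end model: uniform fragment
starts, fixed insert size (default 500 bp; a Gaussian `insertSd` is
available but defaults to 0 since a fixed insert is the simplest model
consistent with the mixtures the package validates against), mate 1
forward from the fragment 5' end, mate 2 reverse-complement from the
3' end, and i.i.d. substitution errors at `errorRate` (default 1%) to a
uniformly chosen different base. Pairs per component are
`round(coverage * G / (2 * readLength))`, so coverage counts the bases
of *both* mates — the convention that makes "70x of a 12.8 Mb genome at
100 bp" yield ~9 million reads. Qualities are a constant Q35 unless
artifacts are injected.

What it deliberately does **not** emulate: indels, position-dependent
or motif-dependent error profiles, quality-error correlation, GC
coverage bias, chimeric fragments, real rRNA conservation across
species. Consequences for interpreting green tests: recovery rates
measured here are upper bounds for real libraries; in particular, real
16S/18S regions are *conserved* across taxa, so a real rDNA screen has
cross-species hits that the synthetic, independent rRNA regions cannot
produce, and real aligner-based filtering faces indels that k-mer
containment does not model.

**Embedded rRNA regions.** Each synthetic genome carries a designated
subsequence (default 1,500 bp, placed at one-third of the genome) that
is also written out as that component's rRNA reference. The rDNA screen
therefore has exact ground truth: a read is an rDNA read when it lies
entirely within the region (`isRdnaRead()`); reads merely overlapping
the boundary are excluded from sensitivity/specificity accounting.

**Artifact injection** selects disjoint read subsets for duplication
(copies re-emitted immediately after their originals), tag carry-over
(full tag prepended or appended, alternating) and 3' quality decay
(linear ramp from the read's own first-base quality to
`decayMinQuality = 2`). Disjointness keeps cause attribution exact, so
injected counts can be compared one-to-one with the QC report.

### Study designs and problem sizes

`communityDesign("genomic")` reproduces a three-species design — a
yeast-like eukaryotic target at 70x with two bacterial contaminants at
20x, mixed 82.5/6.7/10.8% by reads, 100 bp pairs — at 1/100 linear
genome scale (genome lengths 127,965 / 36,316 / 58,653 bp, derived as
reads x readLength / coverage at full scale, scaled). This yields
~108,500 reads and keeps a full simulate–screen–filter cycle around
half a minute on one core, which is the problem size the acceptance
checks and the acceptance script use. `communityDesign("metagenomic")`
analogously mixes ten small bacterial genomes (30x) with human-like
(0.3x, 50.5% of reads) and alga-like (2x) contamination at 70 bp, at
1/500 scale by default.

For the quantitative screen at 1/100 scale, the package uses
`sampleProportion = 0.1` in its own validation runs: a 0.1% subsample —
the natural choice at full scale, where it yields roughly ten thousand
classified reads — would leave only ~100 reads here. Holding the
*classified-read count* (~10,000) rather than the proportion fixed
keeps the binomial error of the estimated composition comparable to a
full-scale screen. Expected recovery is then governed by
sigma_i = sqrt(p_i (1 - p_i) / n): at n ≈ 10,800 and p = 0.067,
3 sigma ≈ 0.7 percentage points.

Duplicate-recovery fixtures use 0.5x coverage of a 100 kb genome (~250
reads). At this density the expected number of fragment-start
collisions is n²/2G ≈ 0.3, so the fixture contains no *natural* exact
duplicates (asserted before injection) and the injected count is the
exact expected removal count.

## Numerical and implementation choices

- **K-mer encoding.** K-mers are 2-bit encoded (A=0, C=1, G=2, T=3)
  into doubles; codes are below 4^k and k is capped at 26 so every code
  is an exact integer in double precision. Numeric order equals
  lexicographic order, so the canonical k-mer (lexicographic min of a
  k-mer and its reverse complement) is `pmin(code, rcCode)`. Window
  codes are evaluated by a Horner scheme over a per-read code matrix —
  fully vectorized, no per-k-mer strings, deterministic.
- **N handling.** Windows containing N are invalid: excluded from the
  index and from both numerator and denominator of every score. Reads
  shorter than k (or all-N) have no valid windows; they extract as
  non-rDNA, assign as unassigned and map as clean, each with a logged
  counter.
- **Quality encoding.** Qualities are stored internally as Phred+33
  strings; scores are bounded to [0, 93]. Auto-detection over the
  first 10,000 records: any character below ASCII 59 forces +33; all
  characters at or above 64 with at least one above 74 indicates +64;
  otherwise the +33 default applies (era-appropriate data can be +64,
  and the ambiguous band is resolved conservatively).
- **Degenerate inputs.** Empty FASTQ files parse to empty sets; empty
  read sets flow through every operation; an empty contaminant set
  passes input through unchanged; an empty subsample returns an empty
  profile with a warning; `falsePositiveRate` refuses
  `nPredicted = 0`.
- **Rounding.** Composition tables round percentages and Mb to one
  decimal (the convention of sequencing summary tables). Because each
  row rounds independently, the percent column can sum to 100 ± 0.1.
  `falsePositiveRate()` returns the unrounded percentage and leaves
  presentation rounding to the caller.
- **Seeding.** Every stochastic operation takes an explicit integer
  seed and restores the caller's RNG state afterwards. Compound
  operations (`simulateCommunity`) derive component sub-seeds from the
  master seed via one seeded draw, so a single integer reproduces the
  entire dataset.

## Known limitations

- K-mer containment is not alignment: no indels, no gapped or
  quality-aware matching, and sensitivity/specificity trade-offs under
  divergence differ from aligner-based removal. Against closely
  related target/contaminant pairs the 0.4 default is too permissive
  and should be raised.
- The rDNA screen depends entirely on the supplied rRNA references; it
  does not bundle 16S/18S databases and cannot discover taxa absent
  from them. Synthetic validation cannot exercise real rRNA
  cross-species conservation.
- Duplicate detection is exact-sequence only; amplification duplicates
  carrying a sequencing error are not collapsed.
- Tag handling drops whole reads; pipelines needing 3'-adapter
  *clipping* (partial overlap) should pre-process with a dedicated
  trimmer.
- The simulator's error model is substitution-only and uniform;
  platform-specific profiles, PCR chimeras and quality-model training
  are out of scope.
- Downstream evaluations (assembly, ORF prediction, functional
  annotation) are not executed; `falsePositiveRate()` and
  `compositionTable()` consume their numeric outputs as inputs.
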