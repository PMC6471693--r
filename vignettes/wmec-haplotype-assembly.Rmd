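---
title: "Haplotype assembly by GA-driven weighted minimum error correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype assembly by GA-driven weighted minimum error correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

A diploid individual carries two copies of each chromosome. Read-based
phasing reconstructs the two haplotypes — the allele sequences of the two
copies at heterozygous SNP sites — from aligned sequencing reads that
each span a handful of adjacent SNPs. Each read is reduced to a ternary
fragment over $\{0, 1, -\}$: reference allele, alternative allele, site
not covered. Stacking $m$ fragments over $n$ SNP columns gives the
fragment matrix $\mathbf{M}$, with a parallel weight matrix $\mathbf{W}$
of phred-scaled confidences.

Under the **weighted Minimum Error Correction (wMEC)** model the reads
are bipartitioned into two sets $\mathbf{M}_1, \mathbf{M}_2$ (one per
chromosome copy). Each part's haplotype is inferred by confidence-weighted
column majority, with ties — including columns a part does not cover —
resolving to allele 1 by the $\geq$ convention, deterministically. The
objective is the number of allele corrections needed to make every read
agree with its part's haplotype:
$$
\mathcal{E}(\mathbf{M}_1,\mathbf{M}_2,\mathbf{h}_1,\mathbf{h}_2)
  = \sum_{k=1}^{2}\,\sum_{\mathbf{f}\in\mathbf{M}_k} D(\mathbf{f},\mathbf{h}_k),
$$
where $D$ is the extended Hamming distance: positions where both
characters are defined and differ. A matrix is conflict-free iff some
bipartition reaches cost 0. Masked positions (`X`) behave exactly like
$-$ in $D$, so abstaining can never create phantom errors.

## The genetic algorithm

wMEC is NP-hard; the search runs over read bipartitions encoded as binary
individuals (bit $i = 0$: read $i$ in part 1). The GA is generational
with elitism:

* **tournament selection** — $\kappa$ distinct individuals, best wins,
  ties to the first sampled;
* **single-point crossover** with probability $c_r$, cut uniform over the
  internal boundaries (our reading of a "mixing ratio of 0.5": each
  parent contributes half in expectation; the phrase is nonstandard);
* **per-bit mutation** with probability $m_r$; while the best fitness has
  stalled for 2 iterations, an additional **burst mutation** flips bits
  inside one uniformly drawn *circular* run (the individual is treated as
  a circular array only here — crossover keeps a linear cut, since
  circularity is motivated by mutating consecutive elements);
* termination at cost 0, after $T$ iterations, or after
  $\theta = \lceil 0.25\,T \rceil$ non-improving iterations.

Defaults ($|P| = 100$, $c_r = 0.9$, $m_r = 0.05$,
$\kappa = \lceil 0.1|P| \rceil$ floored at 2, $T = 100$) follow the
grid-search setting selected for this problem class. The generational
loop runs in compiled code drawing all randomness from R's RNG, so a run
is a pure function of (instance, seed); the exported operator functions
are the reference definitions the compiled loop mirrors, and the test
suite holds them to independent oracles (exhaustive enumeration at small
$m$, Monte-Carlo marginals for the operators).

Replacement policy (unspecified in the source method): generational with
elitism — the best individual survives unchanged, offspring fill the
rest. Tournament sampling is without replacement. Burst run length is
uniform on $\{1,\dots,m\}$ (the least-informative choice).

## Divide et impera

Whole chromosomes are far too large for one GA, so the assembler:

1. **detects haplotype blocks** — connected components of the read/column
   co-coverage graph (columns in different blocks share no read, hence no
   phase information); implemented as a union-find over columns;
2. per block sets $\gamma$ = mean coverage (rounded half-up, floored
   at 2) and splits the position-sorted reads into
   $\Pi = \lfloor m/\gamma \rfloor$ consecutive chunks; a remainder
   smaller than $\gamma/2$ joins the last chunk, a larger one becomes its
   own smaller chunk (the source's $\Pi$ formula and its "smaller last
   sub-matrix" remark are mildly inconsistent; this rule honors both);
3. **solves each chunk with an independent GA instance**; chunks are
   dispatched to a worker pool, each with an RNG stream derived by
   hashing (master seed, block, chunk), so output is identical for any
   worker count and merge order is fixed by chunk index;
4. **orients and merges** consecutive sub-haplotype pairs (a pair is only
   defined up to a label swap): the pairing minimizing disagreement on
   already-merged columns wins; overlapping columns keep the allele from
   the sub-partition with more covering reads;
5. **repairs switch errors** (`polish_switches`, see below);
6. **resolves no-contrast columns** — a column whose defined values are
   all identical carries no phase information, and over heterozygous SNP
   sites it is a coverage artifact (every covering read sampled one
   copy); by the majority rule its value goes to the haplotype whose
   part covers it with more reads, the other haplotype abstains, and a
   coverage tie abstains on both — then **masks ambiguous positions** —
   columns covered by reads of only one part — with `X`. Abstentions
   rather than copied alleles here are what make exact zero-noise
   recovery possible: a fabricated homozygous call at a one-sidedly
   sampled heterozygous site would otherwise be a guaranteed error that
   no amount of optimization could remove.

### Numerical choices in the merge

Two refinements to the naive merge were forced by experiments with
short-read (600 bp) profiles, where consecutive chunks overlap in only
3–10 columns and those columns sit at chunk edges, estimated from 1–3
reads:

* sub-haplotype positions with **zero part coverage are masked before
  merging** — otherwise the deterministic tie allele (1) votes during
  orientation;
* the orientation vote is **coverage-weighted**: each overlap column
  contributes min(read support) of the two estimates being compared.
  With plain unweighted votes, roughly one junction per five simulated
  Roche-like instances mis-oriented on a 2–2 tie, each such event costing
  25–50% haplotype error on the block.

### Switch-error repair

A GA chunk occasionally converges to a solution that is internally
phase-switched (the classic wMEC failure mode at thin junctions), and no
orientation rule applied *between* chunks can repair a switch *inside*
one. `polish_switches` therefore runs a block-level greedy coordinate
descent on the same wMEC objective: (i) relabel each read to its
better-fitting part and re-infer haplotypes to a fixed point; (ii) for
each junction column $j$, consider flipping the labels of all reads
starting at or after $j$, score the move exactly (haplotypes re-inferred,
corrections recounted), and apply the best strictly improving move.
Candidates are shortlisted by an $O(\text{entries})$ screen (fixed
haplotypes, per-read optimal labels via prefix sums). Every accepted move
strictly lowers the correction count, so the procedure terminates and can
only improve the objective the GA optimizes. On simulated Roche-like
data this pass reduces mean haplotype error from roughly 2% to under
0.1% — it converts junction-localized failures into exact recoveries
whenever the data support the true phase.

## The synthetic-data generator

The generator emulates the study design the assembler targets: a genome
of length $f_{\mathrm{SNPs}} \cdot \#\mathrm{SNPs}$ with SNP positions
drawn uniformly without replacement (mean spacing $f_{\mathrm{SNPs}}$),
every site heterozygous ($h_2 = 1 - h_1$, $h_1$ fair-coin). Reads start
uniformly, have fixed length (600 bp Roche/454-like, 5000 bp
PacBio-RS-II-like), copy one haplotype chosen fairly, and flip each
covered allele independently with the per-base error rate. The read
count follows $\#\mathrm{reads} = \mathrm{cov} \cdot
\mathrm{len(genome)}/\mathrm{len(read)}$. Phred weights are
$-10\log_{10}$ of the entry's error rate jittered ±20% (floored at
$10^{-6}$, so error-free data gets weight 60).

Default error rates — 0.01 (Roche/454-like) and 0.13 (PacBio-like) — are
platform stand-ins: the source only states that PacBio errors are much
higher; the values follow the platforms' published characteristics and
are exposed in the configuration and recorded in the provenance JSON.

What the generator does **not** emulate: read-length distributions
(lengths are constant; real 454 and PacBio lengths vary, and occasional
long reads bridge thin junctions), empirical error models (GC bias,
homopolymer indels — the fragment-matrix abstraction has no indel
channel), paired ends, and quality-score heterogeneity along reads. A
green test therefore establishes correctness of the solver on the stated
world, not sequencing realism. One measurable consequence: with 600 bp
reads and one SNP per 200 bp, blocks fragment heavily and a few junctions
are crossed by so few reads that the wMEC optimum genuinely disagrees
with the planted truth (our solutions reach costs *below* the planted
partition's); the residual haplotype error in that condition is a
property of the stated world, not of the optimizer.

## Evaluation

The **haplotype error rate (HE)** is the percentage of SNP alleles
assigned differently from the ground truth, counted over both haplotypes,
minimized over the label swap *per block* (blocks are phased
independently, so a single global swap would charge correct blocks).
Masked positions are abstentions: excluded from numerator and
denominator, reported separately so abstention cannot hide errors.
**Block agreement** compares two solutions the same way. The **ABF
curve** averages the best fitness per iteration across runs, right-padded
with final values; elitism makes every input curve non-increasing, hence
the mean too.

## Known limitations

* Cross-block phasing is out of scope: blocks are reported independently.
* The switch repair is greedy over single-junction moves; a short
  switched segment bounded by two junctions that are individually
  non-improving would survive (not observed in the benchmark conditions).
* Ploidy is fixed at 2; no genotype constraints are imposed.
* BAM/VCF ingestion is out of scope: inputs are WIF fragment files
  (convert with the WhatsHap toolchain).
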