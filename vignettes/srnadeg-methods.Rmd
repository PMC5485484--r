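---
title: "Methods: small RNA and degradome analysis in srnadeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA and degradome analysis in srnadeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`srnadeg` implements a two-condition plant small-RNA-seq analysis with
degradome (PARE) support: read cleaning, tag collapsing, hierarchical
annotation, conserved and novel miRNA identification, exact-test
differential expression, cleavage-site calling with t-plot categories,
and qPCR 2^-ddCt quantification. A synthetic-data generator produces
every input with planted ground truth, so the full pipeline is testable
offline. This vignette records the models, the tunable parameters and
the design decisions behind each stage.

# Read cleaning

`clean_reads()` applies, in order: a mean-Phred quality floor (default
20 — survivors are the "high-quality" reads), 3' adapter trimming,
removal of reads containing ambiguous N bases, a poly(A) filter, and an
insert-length window of 18–30 nt. Adapter matching is deterministic:
the leftmost position where the adapter (or a >= 6 nt prefix of it, when
the read ends first) matches with at most one substitution is the trim
point; reads with no adapter are kept only when already no longer than
the length ceiling. The poly(A) rule discards inserts with a run of
eight or more consecutive A or at least 80% A content. These thresholds
are documented defaults for filters that sRNA-seq pipelines apply with
vendor-specific settings; all are arguments.

Counts are conserved by construction: raw reads equal clean reads plus
the per-reason removal tallies, and the clean-read length histogram is
reported over the 18–30 nt bins.

# Annotation hierarchy

Unique tags are assigned exactly one category with precedence
miRNA > rRNA > tRNA > snRNA > snoRNA > unannotated. A tag is a
conserved miRNA when an ungapped alignment, flush at the 5' end with up
to 2 nt of 3' length difference, against a known mature database has at
most two substitutions; ties go to the fewest mismatches, then to the
lexicographically smallest reference id. Noncoding matching is
exact-substring — mismatch tolerance is reserved for the miRNA class,
where the two-mismatch convention is standard. scRNA entries, when
present in a reference, are folded into the snRNA bucket because the
category table layout has no scRNA row. Category tables report
unique-tag and total-read counts per library with percentages rounded
half-up to two decimals, the convention used by printed summary tables
(`round_half_up()` exists because base R rounds half to even).

# RNA folding model

`fold_rna()` computes minimum-free-energy secondary structures with a
Zuker-style dynamic program over a reduced nearest-neighbour model:
Watson–Crick and G:U pairs; a 6x6 stacking-energy table symmetrised so
that a stacked duplex scores identically from either strand;
size-dependent hairpin, bulge and internal-loop penalties with
logarithmic extrapolation beyond the tabulated anchor sizes; a capped
internal-loop asymmetry term (0.5 kcal/mol per nt, max 3); and an
affine multiloop cost (3.4 closing + 0.4 per branch, unpaired bases
free). There are no dangles, no coaxial stacking, no pseudoknots;
interior loops are bounded at 30 unpaired bases; the minimum hairpin
loop is 3 nt. All arithmetic is in integer tenths of a kcal/mol, which
makes results exactly reproducible and lets the test suite compare the
DP against exhaustive enumeration of all nested structures (sequences
up to 18 nt) with strict equality.

Because the parameter set is reduced, absolute MFE values are
model-specific: they are meaningful against thresholds calibrated for
this model (the novel-miRNA cutoff below), not against values computed
by other folding programs.

# Novel miRNA prediction

Unannotated tags are mapped to the transcript set (exact matches only —
novel loci need unambiguous placement), and two candidate windows are
excised per mapping: `[tag_start - 150, tag_end]` and
`[tag_start, tag_end + 150]`. The 150 nt flank matches the ~150 nt
precursors typical of plant miRNAs. Each window is folded; the
top-level structural component covering the mature (at most 4 mature
bases may stick out) is excised and refolded, and the candidate must
satisfy:

1. the mature's stem runs into exactly one terminal loop — no multiloop
   between the mature and the loop;
2. the mature lies wholly on one arm, at least 2 nt from the loop;
3. at most 4 mature bases are unpaired against the star region, and the
   duplex asymmetry (difference of the two strand spans between their
   outermost paired bases) is at most 2 nt;
4. precursor MFE at most −18 kcal/mol under this model;
5. mature read count at least 5 summed over both libraries.

These five thresholds are the standard plant miRNA annotation
conventions; all are arguments. When both windows of a tag qualify, the
more stable (lower-MFE) precursor wins — a truncated window can
occasionally support a weak spurious hairpin, and the stability
tie-break resolves it. Candidates that are reverse-complement partners
of an already-accepted call (or of a conserved miRNA, via
`known_matures`) are reported as star sequences rather than as
additional miRNAs. Star support is flagged when a distinct tag sits at
the star position — an exact substring of the duplex span ±2 nt read
from the window sequence, so the canonical 2-nt 3' overhang is
tolerated. For conserved calls, where no precursor is excised,
`flag_star_support()` uses a reverse-complement alignment (±4 nt shift,
at most 2 mismatches, at least 2 supporting reads); the read-count floor
keeps chance matches from singleton background tags out.

The arm is assigned by the side of the terminal loop holding the mature
midpoint.

# Differential expression

Counts are normalised to reads per million
(`RPM = count / clean_reads * 1e6`), and the fold change is
`log2(RPM_treated / RPM_control)` with a 0.01 RPM pseudo-value applied
to zeros only inside the fold change — reported expression values are
never pseudo-counted. The exact test evaluates the tag-count
conditional law

P(y | x) = (N2/N1)^y (x+y)! / (x! y!) (1 + N2/N1)^-(x+y+1)

in log space via `lgamma` (real library depths overflow factorials).
The lower tail C sums P(k | x) for k ≤ y; the upper tail D is the
complement of the partial sum, recomputed by direct blockwise summation
whenever it falls below 1e-2, where the complement's ~1e-14 absolute
error would dominate. The two-sided p-value doubles the smaller tail
and caps at 1 (`two_sided = FALSE` gives the one-sided variant). N1 is
bound to the treated library's total and N2 to the control's; swapping
the roles is a matter of argument order and the test's tails swap
accordingly.

DE flags use raw p-values with thresholds p ≤ 0.05 (p ≤ 0.01 for
"significant") and |log2 fold change| ≥ 1; a Benjamini–Hochberg column
is emitted for reference but never gates the flags, mirroring
threshold-based sRNA practice. With a single library per condition the
exact test is calibrated for sampling (Poisson-like) variation;
biological replication is out of scope (no NB GLMs), and the
fold-change gate is what keeps the false-positive rate near the nominal
level under mild overdispersion.

A useful identity for testing: the conditional law equals a negative
binomial with size x+1 and success probability N1/(N1+N2), so
`pnbinom` provides an independent cross-check; the acceptance oracle is
stricter — an exact big-integer rational evaluation of the closed form.
At x = y with equal depths the lower tail is exactly 1/2 (a binomial
median identity), so the two-sided p-value is exactly 1.

# Degradome analysis

Degradome tags are truncated to their first 20 nt for mapping
determinism, collapsed, and annotated with precedence rRNA > tRNA >
snRNA > snoRNA > poly(N) (≥ 10% N or a run of ≥ 5 N) > cDNA_sense
(exact forward-strand match) > cDNA_antisense > other. miRNAs are
aligned antisense to transcripts by exhaustive ungapped sliding-window
scoring: mismatch 1, G:U wobble 0.5, doubled at miRNA positions 2–13,
cutoff 4.5. The gap penalty is accepted as a parameter for interface
completeness, but gapped duplexes are not searched: plant
miRNA–target pairs are overwhelmingly ungapped and the scoring scheme's
reference implementation is a sliding window.

The expected cleavage position of a candidate duplex is the transcript
coordinate opposite miRNA positions 10–11; its abundance is the summed
count of sense-mapped tags whose 5' end sits exactly there. Sites with
zero reads are dropped; the rest take the conventional t-plot category:
0 when the site is the unique per-transcript maximum, 1 at a tied
maximum, 2 above the median of occupied positions, 3 at or below that
median with more than one read, 4 with exactly one read. The median is
taken over positions with at least one read — including empty positions
would force category 2 on nearly every zero-inflated transcript.

# qPCR quantification

`ddct()` pairs replicates by index (same RNA preparation), computes
dCt = Ct_gene − Ct_reference per condition, ddCt against the mean
control dCt, and folds 2^-ddCt; both groups are rescaled by the mean
control fold so the control mean is exactly 1, matching the convention
of setting control expression to unity in qPCR figures. The group
comparison is a two-sided Welch t-test (`pooled = TRUE` switches to
Student's); Welch is the safer default when only "independent t-test"
is specified. The procedure is invariant to any constant Ct shift, and
degenerate zero-variance groups return p = 1 (equal means) or p ≈ 0.

# The synthetic experiment

`simulation_config()` defines a compact two-library drought-style
study. Defaults: 45 transcripts of 400–800 nt; 12 conserved + 8 novel
miRNAs with mature lengths weighted toward 21 and 24 nt (the two
canonical plant sRNA length modes); 4 noncoding sequences per family;
50,000 reads per library of which ~35% are miRNA reads, ~10%
noncoding-derived, ~10% decoys (too-short, too-long, poly(A),
low-quality) and the rest random background; negative-binomial counts
with dispersion 0.02 (a technical-plus-mild-biological value; 0 recovers
Poisson exactly); 30% of miRNAs differentially expressed with true
log2 fold changes drawn from {−2, −2, −1.5, 1.5, 2}, down-biased the
way severe-stress contrasts usually are; 35% of miRNAs with planted
star reads (5–15 copies). Library sizes are scaled far below a real
sequencing run so a full pipeline execution stays in the tens of
seconds; every rate the tests check is scale-free.

Hairpins are built constructively — a 5' arm containing the mature (or
its reverse complement for 3p-arm miRNAs), an unstructured A/C loop of
12–18 nt (A and C cannot pair with each other, so the loop never
closes), and the reverse complement of the arm with up to two injected
substitutions kept off the mature copy — so every planted precursor
satisfies the hairpin criteria by construction rather than by rejection
sampling. Hosts and target transcripts are disjoint, and each target
carries the reverse complement of its miRNA at a recorded position, so
every planted cleavage site is the lone dominant signal on its
transcript. Degradome libraries plant 20–21 nt tags at the true sites
(30–60 copies) over uniform singleton background plus poly(N),
noncoding and random decoys.

What the generator does not emulate: sequencing error profiles,
position-specific quality decay, isomiR heterogeneity around mature
ends, multi-locus miRNA families, genome-scale references, or
transcript abundance structure in the degradome background. Passing
tests therefore demonstrate the correctness of the algorithms under the
stated statistical model, not performance on any particular real
library.

# Numerical choices

Folding energies are integer tenths of kcal/mol end to end; ties in the
DP traceback resolve in a fixed order (hairpin, then interior by
ascending positions, then multiloop) for determinism. Table
percentages round half-up to two decimals. The exact test's tails are
evaluated as described above; `sum(ac_pmf(x, 0:K, ...))` reaches 1
within 1e-9 with K well below 5001 for the tested grids. All
simulation entry points take explicit seeds; identical seeds give
byte-identical FASTQ/FASTA output.

# Known limitations

* Single library per condition: no replicate-aware dispersion
  estimation; the exact test inherits the assumptions above.
* The reduced energy model ranks structures well but its absolute MFE
  scale is its own; the −18 kcal/mol cutoff is calibrated for it.
* Novel-miRNA discovery is transcript-anchored; intergenic loci are
  invisible without a genome.
* Degradome categories carry no per-site significance statistic; they
  rank signal shape only.
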