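---
title: "Methods: annotating, dating and dissecting a TE landscape"
author: "TElandscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating, dating and dissecting a TE landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TElandscape)
```

`TElandscape` chains the analyses of a library-based transposable element
(TE) survey — annotation, consensus curation, subfamily discovery,
divergence dating, decay and nesting analysis, an intact-ORF census and a
horizontal-transfer screen — and validates every stage on simulated
genomes whose ground truth is known exactly. This vignette records the
models, the tunable parameters with their defaults and rationale, the
numerical choices, and what the simulation-based validation does and does
not establish about real data.

## The annotation model

`find_hits()` is a deliberately simple RepeatMasker-style annotator.
Exact k-mer seeds (`k = 12`) from each library consensus, on both
strands, nominate candidate windows; each window is aligned locally
against the consensus (affine-gap Smith–Waterman, match +1, mismatch −1,
gap open −4, gap extend −1, with a gap of length L costing
`open + L·extend`); the aligned span is hard-masked and the window
re-searched so tandem and nested copies in one window are all found. A
hit is kept when the whole alignment scores at least `min_score`
(default 150), then split at gap runs longer than `split_gap = 40` bases
— an insertion interrupted by a nested element becomes one hit per
contiguous segment, which is exactly the representation the decay and
nesting modules need. Remaining overlaps are resolved best-score-first
(ties: longer hit, then family name); a lower-scoring hit that overlaps
a kept one by at most 40 bases is clipped back rather than discarded,
because alignment ends wobble by a few bases across exact junctions and
discarding would delete genuinely present elements (nested copies in
particular).

`min_score = 150` under +1 match scoring implies a ~150 bp minimum
detectable element at full identity; analyses whose object of study is
*fragments* (the decay module) use `min_score = 60` in their configs,
with a ~1 kb element, since deletion remnants of 100–300 bp are exactly
what must be counted. The k-mer seed length trades sensitivity against
window count: at `k = 12`, a random 12-mer match occurs once per ~17 Mb
per library position, negligible at desk scale, while copies up to ~35%
divergence still contain seeds with high probability.

The whole pipeline, simulator included, works on genomes of a few
hundred kilobases with library elements of 0.25–1.5 kb and copy numbers
in the tens to hundreds. That is deliberate: at this scale an exact
Smith–Waterman per window is affordable and every stage can be validated
in minutes; nothing in the algorithms depends on that scale, but the
defaults (and the tests) assume it.

## Consensus building and the single-copy boundary

`extend_to_single_copy()` implements iterative consensus curation: up to
`max_copies = 50` top-scoring copies spanning at least `min_span = 100`
bases of the probe are extracted with up to `flank = 1000` bases of
flanking sequence, aligned, collapsed to a 50% majority-rule consensus,
and the process repeats with the new consensus as probe until the
element's flanks are single-copy DNA on both sides.

Majority rule: per column, the most frequent non-gap character is
emitted if it reaches 50% of the non-gap characters and is the unique
maximum; ties — including a tie exactly at the threshold — give N, and
columns that are mostly gaps are dropped. This is conservative and
deterministic.

"Single copy" is nowhere a quantitative notion, so the package defines
one: a flank window of 50 alignment columns is single-copy when the mean
pairwise identity among the rows present in it falls below 0.60. Random
DNA gives ~0.25 expected identity, repeat-derived flanks give roughly
1 − divergence (≥ 0.7 for any family young enough to annotate), so 0.60
separates the two at all plausible ages. The boundary itself is then
refined to column resolution by walking outward from the repeat core
while per-column majority agreement stays at or above the same
threshold, tolerating noisy runs of up to 3 columns; columns in which
fewer than half the rows carry a base cannot count as repeat-like,
because progressive alignment of unalignable random flanks produces
sparse columns whose few residents agree by chance. Finally, edge
regions of the consensus that are mostly N (more than 3 N in a 10-column
window) are trimmed: they are residue of flank columns, not element
sequence. With these three mechanisms, simulated 267-bp families at 5%
divergence are recovered to edit distance 0–3 from the true master.

The multiple alignment is center-star: the center sequence maximises the
summed pairwise global alignment scores against the rest, and the others
are merged against it under "once a gap, always a gap". Above 30 input
sequences a deterministic 6-mer-profile similarity picks the center
instead — the exact rule is quadratic in copy number, the center choice
barely affects a majority-rule consensus, and the proxy keeps the MSA
linear in copy number. A full progressive aligner would add nothing
here: the downstream consumer is a per-column majority vote.

## Subfamily discovery from co-segregating sites

Intact insertions — genomic length within ±10% of the consensus length
and consensus-span coverage of at least 90% (240–294 bases for a 267-bp
consensus) — are each globally aligned to the consensus, giving a
members × consensus-positions character matrix. Subfamilies are found by
recursive splitting. At each node, candidate columns are those whose
minor allele is carried by at least `min_size = 50` members. For every
candidate pair (and triple, when at most 12 candidates remain), and for
every *allele orientation* — any allele carried by between `min_size`
and `n − min_size` members can mark the derived state, which matters
near 50/50 splits where the sampled "minor" allele at two linked columns
can belong to opposite branches — the number of members jointly carrying
the chosen alleles is compared with the independence expectation by a
one-sided binomial test, Bonferroni-corrected over every
combination-orientation tested at that node. The best significant
combination (`alpha = 0.001` after correction) splits the node into
carriers versus rest, and recursion continues until no split is
significant, a side would fall below `min_size`, or `max_depth = 8`.

The statistic is this package's own operationalisation of "significant
co-segregating sites": a planted two-subfamily scenario (n = 200, two
diagnostic sites on 40% of copies, background divergence 0.05) is
recovered with both sites exact and ~97% membership accuracy, and a
planted 8-leaf hierarchy of nested diagnostic pairs is resolved into
exactly 8 subfamilies. Candidate columns are capped at 20 per node (by
descending minor-allele count) to bound the enumeration.

Refinement (`refine_subfamily_consensus()`) rebuilds each subfamily's
majority consensus and re-assigns every insertion to its nearest
consensus by K2P distance for up to two rounds, ties going to the first
label in sort order; subfamilies that shrink below `min_size` merge into
their nearest sibling, logged. A post-hoc flag
(`flag_composite_subfamilies()`) marks subfamilies whose members are
embedded in another family's hits on both flanks in > 80% of cases:
such "subfamilies" were distributed by their host element and should be
excluded from retrotransposition dynamics.

## Divergence dating

`k2p_distance()` implements the Kimura 2-parameter estimator
`K = −1/2·ln[(1 − 2P − Q)√(1 − 2Q)]` over columns where both characters
are unambiguous bases; gap and N columns are excluded, CpG sites are
*not* treated specially. Saturated pairs (non-positive log argument)
raise a classed condition and are excluded and counted by the summary
layer — imputing them would bias family means. The implementation is
checked to 1e−12 against an independent per-column counting oracle and
against `ape`'s K80 distance.

`family_divergence()` extracts every hit, re-extends hit ends that stop
within `extend_max = 25` bases of the consensus ends (local alignment
trims mismatch-dense termini, which otherwise biases old families' mean
distances downward by ~0.003 at true divergence 0.2; ends further away
are genuine truncation and left alone), fit-aligns each copy inside the
full consensus, and computes per-hit distances over a selectable
comparison segment: the whole consensus, the ORF, or the 3′-most 500
bases of the ORF — the segment choices used when dating non-autonomous
elements, DNA transposons and non-LTR elements respectively. Summaries
report n, mean, SD (population SD by default; a switch gives sample SD —
the convention is not fixed by the downstream arithmetic), the
mean ± SD range, and the activity window obtained by dividing the range
bounds by a neutral rate (default 0.01909 substitutions/site/My, a
butterfly estimate), rounding half-up to one decimal and clamping
negative lower bounds to zero. The mean ± SD reading of the range is
verified arithmetically against all six rows of the published subfamily
divergence table this convention mirrors, and the rounding convention
reproduces all twelve printed window bounds.

On simulation, the estimator is exact: the per-family mean over
recovered copies equals the mean realised distance of the planted copies
to machine precision at 600-bp masters, so recovery accuracy is limited
only by the simulator's binomial sampling of substitutions
(SD ≈ √(d/L) per copy).

## Decay and nesting

Each hit's consensus span is classified by which element ends survive:
the 5′ end counts as present when the span starts within
`epsilon = 5%·L` of position 1, the 3′ end when it ends within the same
tolerance of L. Both ends plus a span of at least 90%·L is FULL_LENGTH;
3′-only is FIVE_PRIME_TRUNCATED — the expected footprint of incomplete
target-primed reverse transcription, which always retains the 3′ end;
5′-only is THREE_PRIME_ABSENT and neither is INTERNAL_ONLY, the two
classes that cannot arise from truncated retrotransposition and hence
evidence genomic deletion. The 5% tolerance absorbs alignment
end-trimming while keeping the classes meaningful; it is configurable.
Before classification, fragments of one insertion split by a *nested*
element are re-joined (same family and strand, consensus spans
continuing within `join_tol = 30` bases, genomic gap mostly covered by
another family's hit) so nesting is not mistaken for deletion. The
summary reports per-family class counts and the
retrotransposition-consistency ratio
`(FULL + FIVE_PRIME) / max(1, THREE_PRIME_ABSENT + INTERNAL)`.

A caveat the simulation makes explicit: an *internal* deletion produces
two masker fragments, only one of which falls in a deletion class, so
the hit-level deletion-class fraction underestimates the copy-level
deletion load (a 30% planted load with half internal deletions reads out
at ~26%). The recovery tests budget for this dilution rather than hide
it.

Nesting detection mirrors the re-join rule: two same-family, same-strand
hits adjacent on the genome whose consensus spans continue within
`join_tol = 30` bases bracket their interruption; every hit strictly
between them (with up to 10 bases of boundary jitter, since alignments
overrun exact junctions by a few chance-matching bases) is a nested
insertion, tallied into an inner-by-outer family count matrix. Planted
young-into-old simulations are recovered exactly, and the matrix
asymmetry (young elements inside old ones, never the reverse) is the
qualitative signal a relative-activity analysis builds on. The
probabilistic activity-period model that consumes such matrices is out
of scope; only detection and counts are computed. `join_tol` and the
jitter tolerance are declared values, not inferred ones.

## The intact-ORF census

`find_orfs()` scans all six frames for Met-to-stop ORFs spanning at
least 1,000 nt (the span includes the terminal stop, so a 1,089-nt ORF
encodes 362 aa). For the census, the top 50 hits by score whose
consensus span covers at least 80% of the ORF are extracted with
1,000 bp of buffer, aligned to the consensus, trimmed to the ORF
boundaries through the alignment, and translated in frame 1. A copy is
intact iff the translation before the first stop reaches 90% of the
expected amino-acid length, the first codon is ATG (alternative starts
are rejected), and there is exactly one stop codon, at the terminus of
the trimmed span. Frameshifts are deliberately not corrected: an indel
that shifts the frame produces premature stops and fails the criteria,
which is the intended literal reading of intactness. The 80% coverage
floor keeps 10–15%-truncated copies in the examined set — they fail the
Met/length criteria, which is informative — while excluding fragments
that could not contain the ORF at all.

## Horizontal-transfer screen

For every (library element, subject sequence) pair the best local
alignment is computed on both strands; a pair passes when identity is
strictly greater than 0.95 and query coverage is at least 0.80.
Identity is measured over the single best local alignment, not over
summed HSPs, and coverage is that alignment's query span over the query
length; E-values are not computed (they require database-size statistics
that add nothing to a fixed identity/coverage rule). After a locus is
recorded the subject is hard-masked and re-searched, so multiple
transfer loci in one subject are each reported. The boundary semantics
are exact: a planted copy with identity exactly 0.95 fails, and 0.80
coverage passes.

## The simulator and what validation shows

`simulate_genome()` draws i.i.d. background at a configurable GC content
(default 0.35, an insect-like value) and plants copies whose generation
follows the processes the analyses assume, in order: subfamily
diagnostic sites → K2P substitution at a target divergence (per-site
transition/transversion probabilities are the exact K2P process
probabilities at divergence d and rate ratio kappa, so the estimator
applied to a mutated copy is unbiased at its target; the *realised*
closed-form distance is recorded in the truth table) → optional 5′
truncation (uniform truncation point; only the 5′ end, matching LINE
biology) → optional one post-insertion deletion (3′-terminal or
internal, span adapted on short copies so every selected copy keeps a
detectable ≥ 100-bp remnant) → placement on a random strand at uniform
non-overlapping insertion points, except where a nesting directive
inserts a copy *into* an earlier family's copy, splitting the host's
truth interval into two sub-records sharing a parent id. ORF-census
scenarios plant exact copies with counted nonsense, 1-bp frameshift and
ORF-truncating disruptions. CpG hypermutability is not modelled — the
dating convention includes CpG sites without special treatment, so the
simulator is consistent with the estimator. The same seed reproduces
genome and truth byte for byte.

What passing the simulation-recovery suite shows: the pipeline's
algorithms are correct against known truth under the stated mutational
model — substitution-only divergence, clean insertion boundaries, one
deletion per copy, single-level nesting. What it does not show:
performance on real genomes with indel evolution inside copies,
tandem-repeat confusion, segmental duplications, assembly gaps and
collapsed repeats, diverged subfamily mixtures, or libraries whose
consensi are themselves imperfect. The package's claims are therefore
about the methods, with the masker's sensitivity on real data expected
to sit below a production annotator's.

## Numerical choices and degenerate inputs

* Alignment delegates to Biostrings' affine-gap engine; optimal scores
  are verified against exhaustive enumeration on short pairs, and
  tie-breaking among co-optimal tracebacks is the engine's
  (deterministic) choice.
* N matches nothing (scores as mismatch, even against N) and is excluded
  from identity numerators and denominators; draft-genome N runs
  therefore cannot inflate identity.
* Empty local alignments (no positive-scoring segment) return score 0
  with an empty span rather than a forced one-base alignment.
* Zero-length FASTA records, inverted hit coordinates and unknown table
  dialects raise errors naming the offending record or row.
* Mya values are rounded half away from zero (`round_half_up()`), not
  banker's rounding, matching the printed-table convention; negative
  window bounds clamp to 0.
* All randomness flows from explicit seeds; the simulator requires one.

## Known limitations

Indel evolution within planted copies is limited to the structured
events (truncation, deletion, nesting, frameshift), so alignment-gap
handling in dating sees less exercise than substitutions. The masker's
same-locus competition keeps a single winner per locus, so true
overlapping annotations (e.g. a young element inserted precisely at an
old element's edge) lose their weaker member beyond the 40-bp clip
margin. Subfamily discovery requires pairs of diagnostic sites; a
subfamily defined by a single site is by construction invisible, which
matches the co-segregation definition but not every biological reality.
Self-nesting (a family into itself) is detectable in the count matrix
but not by the adjacent-pair scan, since the interrupted copy and the
inserted copy are indistinguishable by family.
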