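---
title: "Verifying transgene freedom of genome-edited lines by k-mer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying transgene freedom of genome-edited lines by k-mer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transfree)
```

## The problem

Genome editing of vegetatively propagated crops by transient nuclease
expression leaves no route to segregate away the transformation vector:
there are no null segregants. Certifying such a line for regulatory
purposes therefore requires *sequence-level* evidence that no fragment of
the binary vector — neither the T-DNA nor the backbone, whose integration
is rare but documented — persists in the genome. transfree implements the
computational side of that certification: an exhaustive per-position k-mer
screen of whole-genome sequencing reads against the vector, a per-position
G-test against a wild-type control, replicate intersection as the
false-positive control, and three orthogonal checks (tiled in-silico PCR,
restriction-digest/probe fragment prediction, and target-site allele
classification).

## The k-mer screen and its statistic

Every position $i$ of the circular vector (length $L$) is represented by
the canonical form of the k-mer starting there — the lexicographic minimum
of the k-mer and its reverse complement, so read strand never matters —
with wrap-around windows across the origin. For a read set of $n$ reads,
the profile counts $a_i$, the number of *reads* containing position $i$'s
k-mer. Counting read-level presence rather than occurrences bounds
$a_i \le n$ and makes $n$ a meaningful sequencing-effort margin.

At each position the edited line (hits $a$, library size $n_1$) is
compared with the wild-type control (hits $c$, library size $n_2$) in the
2×2 table $\{(a, n_1-a), (c, n_2-c)\}$, which normalizes for unequal
sequencing depth through the margins. The statistic is the log-likelihood
ratio
$$G = 2\sum_{\text{cells}} O \ln(O/E), \qquad 0\ln 0 \equiv 0,$$
chi-square with 1 df under the null of equal hit proportions. The 1%
threshold is `qchisq(0.99, 1)` = 6.6349; ties at the threshold are
non-significant (the rule is *strictly greater*). No Williams or Yates
correction is applied — the printed threshold corresponds to the
uncorrected chi-square limit — and no per-position multiplicity
correction either: the false-positive control is *replicate
intersection*. Only peaks that recur, at overlapping vector positions, in
an independently re-sequenced run count as evidence of integration; under
the null the per-position replication probability falls toward
$\alpha^2$. Positions where the control is enriched can be significant
too, but verdicts consider only sample-excess peaks: the question is
presence of vector sequence in the edited line.

Significant positions are merged into segments when separated by at most
`max_gap = k - 1` positions, and each segment's end is extended by $k-1$
(a hit at a starting position implies vector sequence through
$i + k - 1$). On the circular vector, runs touching both sides of the
origin are merged; such calls are reported on the unrolled axis with
`vector_end > L`. This matters in practice: at an integration junction,
the flanking host base can coincidentally extend the integrated vector
prefix, lighting up a wrap-around position adjacent to the true
breakpoint.

Both k = 20 and k = 25 are analyzed by default. Longer k-mers are more
specific but strictly less error-tolerant (a single substitution destroys
all $k$ overlapping windows), so with sequencing errors the 25-mer track
is never more sensitive than the 20-mer track — a property the test suite
checks.

## What the generator emulates — and what it does not

The synthetic module generates i.i.d.-base host genomes at plant-like GC
(default 0.36), a circular vector partitioned into a 2 kb T-DNA and a
3 kb backbone with a 500 bp probe feature centered in the T-DNA, optional
integration of a (possibly truncated, possibly origin-wrapping) vector
segment at an exact host locus, optional host–vector homology tracts
copied verbatim into the host, and single-end reads with uniform starts,
equiprobable strands and i.i.d. substitution errors. Read length and
depth default to 100 bp at 30-fold coverage — reasonable short-read
resequencing figures chosen as package defaults, since the analysis only
uses k-mer content. Quality strings are constant placeholders.

Deliberately *not* modeled: indel sequencing errors, GC-biased or
otherwise non-uniform coverage, adapter contamination, paired ends, and
repeat structure of real plant genomes. Passing tests on this generator
demonstrate that the statistics and bookkeeping behave as designed under
clean assumptions; they do not certify performance on real libraries,
where coverage heterogeneity and genome repeats widen the null beyond
binomial sampling.

## Calibration design

Type-I calibration of the per-position G-test needs hits at every
position in both arms; reads sharing no sequence with the vector give
all-zero hit columns, $G = 0$ everywhere, and say nothing about the
statistic. `calibration_track()` therefore embeds a full-length
homologous copy of the vector in a host flank, draws two independent read
sets from that genome — equivalent to randomly splitting one sequencing
run — and tests them against each other. Two further choices make the
binomial reference for the significant fraction exact rather than
approximate:

* reads are $k$ bp long, so each read carries exactly one k-mer and
  per-position significance indicators are independent (overlapping
  longer reads would correlate neighboring positions over a window of
  roughly the read length, inflating the variance of the observed
  fraction well beyond binomial);
* per-arm coverage (default 1000×, i.e. ~50 hits per arm at k = 20) keeps
  expected cell counts deep in chi-square territory, where the realized
  rejection rate of the G-test at $\alpha = 0.01$ is within a few
  ten-thousandths of nominal.

The replicate-intersection Monte Carlo, by contrast, emulates the
realistic study condition: an integration-free line re-sequenced twice
(sample and control drawn independently from the same genome at 30×,
100 bp), peaks called per run at k = 20, and the intersection taken over
100 seed pairs.

## Orthogonal checks

**In-silico PCR.** A primer pair amplifies wherever one primer matches
one strand and the other matches the opposite strand downstream, with at
most 2 mismatches per primer, an exact 3'-terminal 3 bases, and a product
of at most 5 kb — conventional in-silico PCR defaults, exposed as
arguments, since cycling conditions do not translate into matching rules.
Circular templates amplify across the origin. The panel verdict
("vector-free by PCR") requires every vector-targeting cell on genomic
templates to be empty while the genomic control set amplifies.

**Digest and probe.** Recognition motifs are cut as exact occurrences
(both strands when non-palindromic) at a configurable offset; BamHI,
HindIII and EcoRI ship built-in. Fragments overlapping an integrated copy
of the probe sequence by at least 50 bp are reported as detectable.
Incomplete digestion is out of scope.

**Allele classification.** Each cloned amplicon is globally aligned to
the reference (match +2, mismatch −3, gap open 5, gap extend 2, affine);
indel and substitution events overlapping the nuclease target interval
are recorded in reference coordinates. A clone is intact when no event
overlaps the target; the net indel over the target determines the frame
call (non-zero multiple of 3 → in-frame, otherwise frameshift; a
substitution-only or net-zero allele keeps frame "intact" while losing
the intact flag). Clones under 70% alignment identity are excluded with a
warning. A line is a complete disruptant when no intact allele is
observed among ≥1 mutated clones; clone sampling cannot distinguish
identical mutations on homologous chromosomes, so only distinct observed
alleles are counted.

## Numerical and degenerate-input choices

* Margin products in $G$ are computed in double precision (they overflow
  32-bit integers at NGS library sizes); tiny negative round-off at
  $O \approx E$ is clamped to 0.
* A table with a zero row sum is untestable: $G = $ `NA`, treated as
  non-significant.
* Empty read sets warn and return an all-zero profile with library size
  0; reads shorter than $k$ contribute no hits but count toward the
  library size.
* k-mer windows containing non-ACGT characters are dropped from the
  index and skipped in reads.
* Alignment gap placement follows the aligner's deterministic tie-break,
  so event coordinates are reproducible run to run.
* Generators are pure functions of their arguments including the seed,
  and restore the caller's RNG state.

## Worked example

A complete run at the study's simulated conditions — 50 kb host, 5 kb
vector, a 2 kb T-DNA integration, two replicate sequencing runs at 30×:

```{r example, eval = FALSE}
host <- make_host_genome(50000, gc = 0.36, seed = 2)
vec <- make_vector(2000, 3000, seed = 20)
edited <- integrate_vector(host, vec, c(1, 2000), host_locus = 25000)

verdict <- run_verification(list(
  vector = vec,
  reads_sample  = simulate_reads(edited$genome, 30, 100, seed = 3),
  reads_control = simulate_reads(host, 30, 100, seed = 4),
  reads_sample2 = simulate_reads(edited$genome, 30, 100, seed = 5),
  reads_control2 = simulate_reads(host, 30, 100, seed = 6)
))
verdict$transgene_free          # FALSE
verdict$per_k[["20"]]$replicated  # one call covering vector positions 1-2000
```

## Problem sizes used by the test and acceptance runs

All simulations run at desk scale as the package's own choice of study
conditions: hosts of 10–50 kb, the 5 kb default vector, 30× coverage for
detection scenarios, 1000× per arm with k-length reads for calibration,
and 100 seed pairs for the replicate Monte Carlo. The full suite and the
acceptance script each complete in a few minutes on one CPU.

## Known limitations

* Breakpoints are resolved only to within $k$ positions by construction;
  split-read or assembly-based refinement is out of scope.
* The screen is presence/absence at k-mer resolution: vector segments
  shorter than $k$, or diverged beyond exact k-mer identity, are
  invisible.
* Host–vector homology tracts (plant-derived vector elements) produce
  genuine shared k-mers; they appear as non-replicating background peaks
  and are the reason replicate intersection, not any single run, carries
  the verdict.
* The in-silico PCR model is purely sequence-based (no melting
  temperature or efficiency model), and the digest model assumes complete
  digestion.
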