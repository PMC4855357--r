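---
title: "Methods: sorting, replicate filtering and benchmarking of double-tagged amplicon libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sorting, replicate filtering and benchmarking of double-tagged amplicon libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The data model

A *design* couples three small text files:

* a tag file mapping tag identifiers to tag sequences (all the same length
  within a file, plain ACGT);
* a primer file of one or more primer sets, each a name plus forward and
  reverse primer written in IUPAC code;
* a PCR file listing, per reaction, the sample, the forward tag, the reverse
  tag and the sequencing pool. Replicate indices are assigned per sample in
  file order, and every sample must have the same number of replicates.

A library molecule is modelled as

```
fwd_tag + fwd_primer + insert + revcomp(rev_primer) + revcomp(rev_tag)
```

and may be sequenced in either orientation. Reads are assumed merged and
adapter-trimmed before they reach the sorter.

## Sorting

For each read the sorter tries both orientations. In one orientation, a hit
requires, from the 5′ end: an exact, anchored match to one of the design's
forward tags; a forward primer matched IUPAC-aware with at most
`max_primer_mismatch` substitutions (default 2, no indels); and symmetrically
at the 3′ end the reverse-complemented reverse primer followed by the
reverse-complemented reverse tag. Tags are matched exactly because they are
the sample identity — a fuzzy tag match converts sequencing error directly
into cross-sample contamination. Primers tolerate substitutions because
primer template mismatches are expected and carry no identity information.

A read is **discarded as ambiguous** when its interpretation is not unique:
both orientations yield a clean hit, more than one primer set matches, or a
single orientation admits more than one distinct (forward tag, reverse tag,
insert) triple. Unambiguous hits are trimmed to the insert; an **empty insert
is kept** (length filtering is the filter stage's job, and a zero-length
insert is still evidence of the tag pair). The accounting identity

```
n_input = n_sorted + n_discarded            (+ n_chimera_removed later)
```

holds exactly at all times.

Sorting dereplicates first: identical reads are collapsed before any
matching, and all per-read work is vectorised over unique sequences. Each
surviving record carries the tag combination, the insert, its copy number,
and a flag saying whether that combination appears in the design (`used`).
Reads in *unused* combinations are the direct signal of tag jumping and feed
the diagnostics (`combo_summary()`, `tag_matrix()`, `diagnose_swaps()`).

`diagnose_swaps()` looks for designed combinations with at most
`silent_threshold` reads and pairs each with unused combinations above
`loud_threshold` reads that share exactly one tag with it. Sharing exactly
one tag is the fingerprint of a single mislabelled or mis-pipetted tag;
a loud combination sharing both tags is the designed reaction itself, and one
sharing neither is uninformative.

## The y / t / l filter

Given per-sample tables of (sequence, replicate, count), a sequence survives
for a sample when

1. it is present (count ≥ 1) in at least `y` of the sample's replicates;
2. it reaches at least `t` copies in at least `y` replicates;
3. its length is at least `l`.

`t` is read **per replicate** by default: the quantity that separates real
template from polymerase noise is independent evidence, and copies within one
replicate are not independent — a single early-cycle error is amplified into
many copies of the same replicate. Requiring `t` copies in each of `y`
replicates demands the evidence be both repeated and independently repeated.
The alternative reading, `t` summed over replicates, is available as
`t_mode = "total"` for comparison. With `t = 1` the two presence conditions
coincide, and the step ledger recorded by `apply_filters()` is always
monotone: `n_input ≥ n_after_y ≥ n_after_t ≥ n_after_l`.

## Renkonen dissimilarity

Replicate profiles are compared on relative frequencies. For replicates `a`
and `b` of one sample,

```
RSI(a, b) = 1 − Σ_s min(p_a(s), p_b(s))
```

summed over the union of sequences. It is 0 for identical profiles and 1 for
disjoint ones, invariant under rescaling of counts, and symmetric. A
replicate with no reads is reported (dissimilarity 1 against everything, with
a warning) rather than dropped, because a failed PCR is a finding.
`sample_rsi()` averages a sample's pairwise values and flags samples whose
mean exceeds `threshold` (default 0.6) as `dissimilar`.

## Benchmarking against a truth set

`seq_identity()` aligns two sequences with free end gaps (overlap alignment),
match +1, mismatch −1, gap −1 per base, and defines identity as the number of
matched columns divided by the shorter length. Among equal-scoring alignments
the one with **more matched columns** wins — identity is the quantity of
interest, so ties must not be resolved against it. The dynamic programme is
vectorised by packing `score × 10^6 + matches` into one number, which is safe
for sequences below ~500 kb, far beyond amplicon lengths.

`classify_truth()` calls a unique (sample, sequence) pair a true positive
when its best identity against any reference reaches `min_identity` (default
0.97, i.e. up to 4 substitutions on a 157 bp insert). `benchmark_rates()`
fixes the denominators at the *unfiltered* class sizes, so TPR/FNR and
FPR/TNR each sum to 1 and an empty class yields `NA`, never 0.

## The generator

`simulate_library()` emits reads molecule by molecule: a reference insert is
drawn per read (uniform or lognormal abundances), point errors are applied as
binomial draws per base, optional indels likewise, chimeras are single
breakpoint recombinants of two distinct references, IUPAC positions in the
primers are realised uniformly, about half the reads are reverse
complemented, and a tag jump replaces one tag of the pair with another tag
from the same pool. Every read gets a truth row (reference, error count,
chimera parents and breakpoint, intended versus emitted combination, jump and
orientation flags), so every pipeline number can be checked against ground
truth. A `swap_plant` argument relabels one designed combination to another
at emission, planting the silent/loud signature that `diagnose_swaps()` is
meant to find.

The defaults — 4 samples × 4 replicates in one pool, matched 7 bp tags, 10
references of 157 bp, 1250 reads per replicate (20 000 reads), point-error
rate 0.002, tag-jump rate 0.05, chimera rate 0.01 — describe a small but
realistic mini-barcode study and were fixed once as the package's study
conditions. All randomness derives from the mandatory `seed`; a given
configuration is byte-reproducible.

## Numerical and size choices

* Sorting work is linear in unique sequences; the default study (≈6000
  uniques) sorts in seconds.
* Alignment is reserved for benchmarking (uniques × references); sorting and
  filtering never align.
* Copy numbers are integers end to end; frequencies are computed in double
  precision only inside the RSI.
* Chimera interchange writes one FASTA per combination with `;size=N`
  abundance annotations and accepts either a plain list of flagged ids or
  UCHIME's tabbed format (only rows flagged `Y` are taken). Removed reads
  move from `n_sorted` to `n_chimera_removed`, preserving the accounting
  identity.

## Limitations

* Tags must match exactly; designs needing error-tolerant tags (e.g. long
  Golay codes) are out of scope.
* Primer matching allows substitutions only, no indels.
* Reads must be pre-merged; paired-end merging and quality trimming are
  upstream concerns.
* The generator's error model is uniform per base and ignores quality
  scores, motif-dependent error and polymerase bias.
* `benchmark_rates()` scores unique sequences, not reads; abundance-weighted
  rates are not provided.
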