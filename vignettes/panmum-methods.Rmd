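---
title: "Anchor-based multiple alignment with prefix-free parsing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based multiple alignment with prefix-free parsing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`panmum` aligns m highly similar DNA sequences — think one chromosome from
each of many individuals of the same species — into a single colinear MSA.
This vignette explains the model behind the pipeline, the parameters that
matter, the numerical and design choices that were genuinely open, and
what the test suite does and does not demonstrate.

## Assumptions

The method is a special-purpose aligner. It assumes the inputs are
near-identical *colinear* sequences: divergence dominated by SNPs and
short indels, possibly with missing segments (incomplete assemblies),
and with large structural rearrangements rare. Inversions and
transpositions are not modelled; a planted inversion simply never
anchors, coverage drops, and its bases end up in gap blocks or unaligned
layouts (the fixture generator can plant inversions precisely to
demonstrate this failure mode).

## Phase 1: prefix-free parsing

A Karp–Rabin rolling hash scans each sequence with a window of
`window` = 10 bases. A window is a *trigger* when its hash is divisible
by `modulus`. Each phrase ends at a trigger (the final phrase runs to the
sequence end regardless), so expected phrase length grows with the
modulus: `modulus = 100` (backbone default) gives coarse phrases and a
short parse; `modulus = 20` (used inside large gaps, and available for
the backbone) gives finer phrases, more anchors and higher pre-extension
coverage at more compute. The window size hardly affects the parse as
long as it is not tiny, which is why it is fixed at 10.

Numerical choices: the hash uses a 61-bit Mersenne modulus and a fixed
odd multiplier, implemented in C++ with 128-bit intermediates, so parses
are reproducible across platforms. The hash modulus `p` need not be
prime. The first `window − 1` positions of a sequence cannot close a
phrase (the window must fit); a phrase shorter than the window is
admitted as-is. The prefix-free property that gives the technique its
name is never relied upon.

One dictionary is built jointly over all m sequences and sorted in byte
order. This is the only reading under which parse-level matching across
sequences is sound: two parse symbols must be equal exactly when their
phrases are base-identical. Per-sequence dictionaries would make equal
ranks meaningless across sequences.

## Phase 2: backbone

**Enhanced GSA.** The generalized suffix array over the m parses is
built with per-document sentinels #1 < … < #m, all smaller than every
symbol, so equal suffixes from different documents order by document
index and the tie-break contract is explicit. Construction is
prefix-doubling driven by R's radix `order()` — O(n log² n), robust to
the highly repetitive inputs this tool exists for, and verified
exhaustively against a definition-level oracle (every string of length
≤ 12 over three symbols, plus random multi-document instances). LCP uses
Kasai's algorithm; lcp-intervals are enumerated with the classic stack
algorithm; both are compiled code.

**multiMUMs.** The detection test — lcp-interval of width m, document
entries pairwise distinct, BWT entries not all equal — is the interval
formulation of "occurs exactly once in every sequence and cannot be
extended on either side in all sequences simultaneously". The extracted
statement of the interval conditions in our source material rendered the
distinctness/inequality signs ambiguously; the implemented reading is
the one consistent with the worked example (documents 1,2,3 pairwise
distinct; BWT symbols A, #2, A not all equal), which reproduces the
published multiMUM (2, 2, 1, 2) exactly, and every reported multiMUM is
re-checked against the raw definition in the tests.

**Chaining.** Fragments are weighted by expanded base length and chained
under the precedence relation f ≪ f′ (f ends strictly before f′ begins in
every compared sequence). Up to `dp_threshold` = 2000 fragments the exact
O(mk²) dynamic program runs; above it, the sorted-by-score heuristic
(process fragments by position in sequence 1, scan processed fragments in
decreasing score, take the first valid predecessor). Ties between
equal-score predecessors break to the smaller end position in the
ordering sequence, then to the smaller fragment index, making both
chainers deterministic. The heuristic is exact on mutually colinear
inputs and empirically near-exact on the near-colinear inputs this
pipeline produces; the tests quantify the discrepancy rate on randomized
instances.

**Extension.** Anchors are lifted to base level (each symbol replaced by
its phrase; the lift is an exact match because equal symbols expand
identically) and extended left, then right, simultaneously in all
sequences. A mismatch is crossed only when at least
`extension_min_match` = 10 bases match exactly beyond it before the next
mismatch or a bound; the crossing consumes exactly one base in every
sequence. This pure-substitution model is deliberate: a length-changing
event inside an extension would silently misalign everything downstream,
whereas an isolated substitution is overwhelmingly the signature of a
SNP. Anchors are processed left to right; each extension is bounded by
the previous anchor's extended end and the next anchor's current start
(first come, first served), which keeps anchors non-overlapping without
a second pass.

## Phase 3: gaps

Gaps (regions between consecutive anchors) are closed independently and
recursively:

* gaps whose largest per-sequence interval is ≤ `small_gap_threshold`
  (default 10,000 bases — sized for desk-scale inputs, configurable
  upward) go straight to the center-star aligner;
* larger gaps are re-anchored with *partial* multiMUMs (width between
  ⌊m/2⌋+1 and m in the interval test; absences marked `NA`), found on
  the parse level (modulus `gap_modulus` = 20) when the gap exceeds
  `parse_gap_factor` × `small_gap_threshold`, else on the base level,
  falling back to the base level when the parse level finds nothing;
* the k-subset heuristic chains only fragments occurring in all of the k
  best-covered sequences (k from ⌊m/2⌋+1 to m), each weighted by
  length × occurrence count, and keeps the chain covering the most
  bases. Requiring occurrence in more than half the sequences is what
  makes any two compatible partial fragments comparable, so the chain is
  totally ordered. Occurrences outside the selected subset are re-added
  per sequence with a heaviest-increasing-subsequence pass constrained
  by the already-placed fragments;
* the built-in mapper (exact 21-base seeds, banded unit-cost scoring of
  the implied window) tries to place each chained fragment into the
  sequences it misses; placements with MAPQ-like quality ≥ `mapq_min`
  = 30 are accepted and chained with the same HIS pass. The quality is
  calibrated so a unique near-exact placement scores far above 30 and
  two near-equal placements score near 0. An external mapper can be
  plugged in as a function, e.g. built from a PAF-emitting command;
* fragments present in all non-empty sequences split the gap; the rest
  ride along as residual constraints (overriding weight in the
  lower-level chain). A sequence with no anchor at all, while the others
  share anchors of ≥ `removal_min_len` = 500 bases, is removed from the
  gap and laid out unaligned after it — its residues are preserved, and
  unaligned blocks are flagged and excluded from coverage;
* recursion stops at `depth_cap` = 10 (each split strictly shrinks every
  non-empty interval, so the cap is a backstop, not the usual exit).

**Small gaps.** The center-star aligner picks the slice minimizing the
total pairwise distance (all pairs for ≤ 8 non-empty slices, a
deterministic subsample above), aligns every other slice against it with
an exact banded unit-cost DP (band-doubling; a result ≤ band is provably
optimal), and merges columns under "once a gap, always a gap". The
classical guarantee — at most twice the optimal sum-of-pairs cost — is
asserted in the tests against an exhaustive three-sequence DP. When no
alignment is certified within `band_max` = 4096, the slices are laid out
unaligned rather than force-aligned: this caps worst-case cost on
content that has no sensible colinear alignment and keeps the projection
property unconditional.

## The projection property

Every code path — anchor blocks, center-star blocks, unaligned layouts,
removed sequences — preserves the invariant that ungapping row j yields
input j exactly, and `run_pipeline()` verifies it before returning. This
is the load-bearing correctness property of the whole pipeline and the
reason degenerate paths prefer "unaligned but lossless" over clever
repairs.

## The synthetic pangenome generator

`generate_pangenome()` draws a uniform ACGT ancestor and derives each
sequence independently: substitutions at `snp_rate` (alternative base
always differs from the reference), indels at `indel_rate` with
geometric lengths, larger missing segments (leading, trailing and
internal) totalling `missing_fraction`, and optional inversions. Every
variant is recorded so the truth record replays to the exact sequence.
Defaults model intra-species resequencing: SNP rate 1e-3, indel rate
about 2e-4 when enabled, missing fractions up to 0.2 mirroring real
fragmented assembly sets. All randomness flows from one seed and the
session RNG state is restored.

What it emulates: density and spectrum of small variants, fragmentation,
the existence (not the biology) of inversions. What it does not:
recombination, mutation-rate heterogeneity, tandem-repeat expansion,
sequencing error, and realistic repeat structure — the hard case for
suffix-based anchoring. Passing tests therefore demonstrate algorithmic
correctness and robustness on clean divergence models, not performance
on centromeric or otherwise repeat-dense real data.

Test and acceptance runs use desk-scale problem sizes — up to 10
sequences and 100 kb ancestors end-to-end, with the exhaustive oracle
sweeps on inputs of length ≤ 12 — chosen as the package's own testing
envelope; the algorithms themselves have no such limits.

## Known limitations

* Structural variants: inversions/transpositions are not detected, only
  survived (coverage loss).
* The heuristic chainer can be suboptimal on adversarial fragment sets;
  the exact DP is the default below 2000 fragments.
* The built-in mapper is substitution-oriented; placements that require
  large indels inside the fragment are found only via the banded
  aligner's tolerance, or by plugging in a real long-read mapper.
* Unit edit costs everywhere; no affine gap model.
* The SP-value's "exact" mode recomputes true Levenshtein distances and
  is quadratic per pair; it is intended for small inputs, with the
  induced mode as the cheap default.
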