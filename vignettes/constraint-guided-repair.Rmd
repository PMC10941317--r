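---
title: "Constraint-guided repair of DNA storage reads: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-guided repair of DNA storage reads: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligorepair)
```

## The model

DNA storage codes emit codewords under design constraints, so in a
sequencing experiment every true oligo satisfies the declared rule set and
any violation observed in a read is evidence of an error. `oligorepair`
treats the rule set as a checkable model of the data:

* **Constraint checking** locates all violations with exact 0-based
  half-open spans (`find_violations()`).
* **The per-base error metric** (`error_profile()`) redistributes each
  violation onto the bases whose change could relieve it.
* **Greedy repair** (`repair_sequence()`) edits the highest-error base at
  each step, accepting an edit only if it strictly lowers the total error,
  until the read is compliant or an edit budget is exhausted.
* **Cluster-level selection** (`repair_cluster()`) prefers observation
  over inference: keep a compliant centroid; else promote the nearest
  compliant member; only then repair, keeping the success with the fewest
  edits.

The assumptions are: errors are sparse relative to the edit budget; the
constraint set is tight enough that typical errors actually trip a rule;
and within a cluster the members are all noisy copies of one codeword.
When an error violates no rule (a substitution that leaves every window
within its GC bounds, for example) the model is blind to it — repair
restores compliance, not necessarily the original codeword. This is the
fundamental limit of code-independent repair and the reason the
cluster-level cascade prefers observed compliant sequences over repaired
ones.

## Rules and their parameters

All parameters of `constraint_set()`, with defaults chosen to mirror a
typical storage-code design:

| rule | parameters (default) | violation magnitude |
|---|---|---|
| `gc_global` | `gc_min`, `gc_max` (0.40, 0.60; fractions) | deviation from nearest bound |
| `gc_window` | `window_size` (15 nt), window bounds (inherit global) | deviation from nearest bound |
| `homopolymer` | `max_homopolymer` (3 nt) | run length − bound |
| `blacklist` | motif strings (none) | 1 per occurrence, overlaps included |
| `kmer` | `kmer_k` (off), `kmer_max_occurrences` (1) | excess occurrence count |
| `length` | `target_length` (off; exact or `c(min, max)` nt) | \|actual − target\| |
| `ambiguous` | — | 1 per `N` |

GC windows **tile** the sequence at offsets `0, w, 2w, …` rather than
sliding; adjacent fixed windows match the mental model of a codeword laid
out in blocks, keep the violation count proportional to sequence length,
and make the window a stable coordinate for reporting. A trailing
remainder shorter than `w` is evaluated as its own window. This has a
sharp consequence: a 1 nt remainder window can never satisfy fractional
GC bounds, so fixed-length designs should keep `target_length` compatible
with the window grid (a multiple of `window_size`, or a remainder long
enough to be satisfiable). The repair loop tolerates transient remainder
windows while shrinking an overlong read — the worked 32 nt example
passes through a length-31 state whose 1-base remainder window briefly
dominates the error metric — but final lengths must be satisfiable.

The `kmer` rule bounds how often any single k-mer may occur *within one
sequence* (default: no repeats), the usual repeat-avoidance constraint in
storage codes; inter-sequence uniqueness is out of scope. `N` bases are
always violations: they carry no information and are repaired with
highest priority.

## The error metric

The spec of the metric is that it must point repair at bases whose change
can reduce the violation, so each rule charges only "aggravating"
positions, scaled by the rule's weight (`rule_weights`, default 1 each):

* homopolymer run of length `r > h`: every run position scores
  `(r − h)/r` — the whole run is suspect, more so the longer it is, but a
  single run never dominates a profile the way `r` itself would;
* GC violations: the deviation is charged to G/C positions when too rich,
  A/T positions when too poor — substituting any other base cannot help;
* blacklist: every covered position scores 1 (overlapping occurrences
  stack);
* k-mer: occurrences beyond the allowed count (in left-to-right order)
  charge their positions 1;
* length: contributes a signed `length_delta` only; which base to delete
  is decided by the other rules' scores.

## Numerical and tie-breaking choices

Repair must be deterministic to be testable, so every tie is broken by a
fixed rule: the leftmost of equally-scored positions is edited first;
candidate bases are tried in the fixed order `A < C < G < T`; when an
overlong read has an all-zero profile the last base is deleted;
insertions (for too-short reads) are appended at the end with the base
minimizing the resulting total error. Substitutions require a *strict*
decrease of total error (tolerance `1e-9`); if no single substitution at
any scored position achieves one, the repair is stuck and reports failure
rather than looping. Together with the budget (`max_changes`, default 8
edits — generous against the 1–2 errors typical of a short read at
percent-level error rates) this guarantees termination. Length repair
uses explicit deletions and insertions: compliance alone cannot be
restored by substitution when the length rule is violated, and deleting
at the error-metric maximum lets one deletion fix a long run and a length
excess at once.

A note on iteration order inside a flagged homopolymer: all run positions
score equally, so the leftmost is tried first. Repair outcomes do not
depend on this for validity — the chosen base must still minimize the
resulting error — but the reported edit positions do, which is why the
rule is fixed rather than arbitrary.

## Clustering and filtering dialect

Dereplication collapses identical strings, sums abundances, and keeps the
id and qualities of the highest-mean-quality member. Clustering is the
classic greedy centroid scheme: sort the dereplicated pool by abundance
(or mean quality), pop the head as centroid, absorb every pooled sequence
with similarity *strictly above* the threshold (default 0.97). Similarity
is `1 − d/max(len)` with `d` the Levenshtein distance — alignment-free
and monotone in edit distance, a deliberate dialect difference from
alignment-identity definitions; boundary cases with terminal gaps may
cluster differently than under such tools. The default ordering is
abundance: with per-base error rates at the percent level, the error-free
read is almost always the most abundant dereplicated record, and
abundance ties are resolved reproducibly by id.

The mean-quality filter uses the arithmetic mean of integer PHRED scores
(the convention of classic read filters), keeps reads exactly at the
threshold, and defaults to Q10. The sort mode orders by
`violation_penalty − λ · meanQ/93` (ascending, `λ = 1` by default): the
combination of rule compliance and quality the declared constraints make
available, as a linear key — decoders for unordered codes then consume
compliant, high-quality sequences first. The linear form is this
package's construction; any monotone combination would serve, and `λ`
exposes the trade-off explicitly.

## The synthetic channel

`simulate_dataset()` emulates what the pipeline needs to be tested
against: constraint-satisfying references (built base-by-base with
backtracking and GC-feasibility pruning), log-normal abundance skew
(dispersion 0.5, a moderate PCR amplification bias; dispersion 0 gives
exact coverage), and per-base substitution (1%), insertion and deletion
(0.5% each) with two-level qualities (correct bases around Q38, erroneous
around Q12, truncated to \[2, 41\]). Every read carries a ground-truth
edit list that replays to the read exactly, so tests can assert against
truth rather than against the implementation.

What the channel deliberately does not model: motif- or
position-dependent error rates, synthesis dropout, nanopore-style
homopolymer length miscalls, chimeras, and quality values correlated with
true error probability beyond the two-level scheme. Passing tests
therefore show that the pipeline recovers data under sparse, uniform
errors with realistic abundance skew — not that it is robust to
instrument-specific error structure.

## What the test suite computes

Unit tests pin every operation to hand-computed or brute-force values:
violation detection is compared against naive scanners (all substrings,
all windows, all runs) on random sequences up to 200 nt; edit distance
against an independent dynamic program; repair successes against
exhaustive enumeration of all sequences within the claimed edit distance
(for short sequences and budgets, where enumeration is exact). The
enumeration check is one-sided by design: greedy repair may fail where
brute force succeeds — it is a heuristic — so only its successes are
certified. End-to-end, simulated datasets (50 references × 60 nt at
coverage 20, the package's standing test scale) are pushed through the
full pipeline and recovery is measured by exact string containment of the
references among the representatives; the same harness compares the
minimum coverage for full recovery with repair enabled against constraint
filtering alone. Recovery by exact containment requires at least one
error-free read per reference to exist and survive: references whose
every read is erroneous bound the achievable recovery rate at any
coverage, which is visible in the suite as occasional single-reference
losses at moderate coverage.

## Known limitations

* Repair is greedy and one-step-lookahead; it can fail on inputs where a
  globally optimal two-edit fix exists but no single edit strictly
  improves the profile.
* Rule-silent errors are invisible; repaired sequences are compliant, not
  certified correct. Downstream error-correcting codes remain necessary.
* The k-mer rule's quadratic-ish scan and the Levenshtein clustering are
  sized for dereplicated pools of thousands, not millions, of unique
  reads; no heuristic prefilter is included.
* Paired-end merging, host-genome separation and assembly are out of
  scope; the package consumes single-end or already-merged reads.
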