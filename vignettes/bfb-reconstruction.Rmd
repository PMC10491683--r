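---
title: "Reconstructing breakage-fusion-bridge local genomic maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing breakage-fusion-bridge local genomic maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfbmap)
```

## The generative model

A breakage-fusion-bridge (BFB) event starts from a *reference path*
`s1 s2 ... sn`, the ordered segments of the affected region. One cycle fuses
the path with its reverse complement and breaks the bridge, which is
equivalent to appending the reverse complement of some suffix of the current
path. Everything in this package is phrased against that grammar: a path is
BFB-consistent exactly when a sequence of append-reverse-complement-suffix
moves generates it, each move realizing one fold-back inversion (FBI) at the
then-current path end (`+i` ends give tail-to-tail folds, `-i` ends
head-to-head). Consequences used throughout:

* every BFB path retains the reference as a prefix and, after the first
  cycle, ends in a *palindromic suffix* (a suffix equal to its own reverse
  complement);
* undoing moves ("peeling") decides consistency and recovers a cycle
  history; a breadth-first peel gives a minimal history (`derive_history()`),
  with a depth-first approximation beyond 64 oriented segments;
* exhaustive forward closure of the grammar (`enumerate_bfb_paths()`) is a
  practical brute-force oracle for small instances and is the independent
  check used against the solver in the test suite.

## Fitting copy numbers

Observables are per-segment copy numbers (CNs) and typed junctions
(fold-backs, deletions, duplications, translocations, virus integrations).
The building blocks of a BFB path are *mono-chains* `m(a,b)` (a run of
consecutive segments, possibly reverse-complemented) and *loops* `l(a,b)`
(a run concatenated with its own reverse complement); there are `n(n+1)/2`
of each. The integer program assigns every block a copy number minimizing
the total disparity `sum(eps) + sum(xi)`:

* **Segment rows.** The estimated CN of `s_i` is the sum of mono-chain CNs
  containing it plus twice the loop CNs containing it; `eps_i` bounds its
  deviation from the observed CN.
* **Fold rows.** The estimated CN of the fold junction at segment `i` uses
  an exact ownership argument: every fold adjacency of a composed path is
  owned by the run that starts at it. A loop copy therefore owns one fold at
  each endpoint (two at `i` when `a = b = i`, since both its runs start at
  folds there), and a mono-chain copy owns at most one fold, at the endpoint
  where its run starts (head side when placed forward, tail side when
  reversed) — integer side-variables per mono-chain count these, with their
  total at most (total mono copies − 1), because one mono run is the path
  start. `xi_i` bounds the deviation from the observed junction CN;
  undetected sites have target zero, so spurious folds are charged.

  This replaces a pairwise-average rule (each used mono-chain pair sharing
  an endpoint contributing the mean of their CNs): summed over *all* used
  pairs that rule grows quadratically with stacked same-endpoint chains and
  lets unrealizable configurations fake arbitrarily large fold CNs, while
  for the ordinary case of two chains pairing at a fold both formulations
  agree. With the ownership accounting, every noise-free simulated path fits
  at objective exactly zero, which the test suite asserts. The accounting is
  necessary, not sufficient — a fitted configuration may still assign fold
  ownerships no geometry realizes — and composition (below) closes that gap.
* **Structure.** The whole-region chain `m(1,n)` is used at least once
  (path start); every used block except it must have a used *parent* (a
  strictly longer block sharing an endpoint; a loop is additionally the
  child of its same-span mono-chain so single-segment events stay
  connected); every detected fold-back must carry estimated CN at least one.
* **Evidence extensions.** Read linkage (linked/long reads, optical maps)
  arrives as oriented segment adjacencies; each fold-shaped adjacency forces
  a realizer (a loop with that endpoint or a fold-owning mono side) into the
  solution. Multi-subclone profiles solve jointly with an L1 coupling
  penalty (`joint_solve_subclones()`, default weight 1 on all clone pairs)
  so subclones share entities where the data allow.

Bounds matter for solver speed: each block's CN is capped by the minimum
observed CN over its span (halved for loops) plus a slack of 3, and these
caps double as indicator big-Ms. The backend is HiGHS through
`scipy.optimize.milp`, one persistent worker process per session speaking
JSON lines, with absolute MIP gap 0, a 10 s default time limit per solve
(incumbents are flagged), and a deterministic lexicographic tie-break:
disparity first, then total block copies, then a preference for longer
blocks — fewer, longer entities read as fewer cycles, the more parsimonious
history. A HiGHS presolve defect (status 4 "solve error" on some valid
models) is worked around by re-solving with presolve off.

## Composing the path

Blocks with positive CN form the BFB DAG (edges parent to child).
`compose_path()` walks a topological order — canonically length descending,
start ascending, mono-chains before loops — and inserts each copy at the
rightmost position that keeps every adjacency a reference or fold adjacency,
keeps a palindromic suffix, and keeps the whole path inside the grammar
(appends that are literally reverse-complement-suffix moves are accepted
without search; interior insertions are validated by peeling). The insertion
search backtracks with a bounded budget.

Entity insertion cannot reach every valid path (loop copies of different
spans may interleave in ways no insertion order reproduces), so the pipeline
falls back to `search_bfb_path()`: a direct depth-first search over
fusion-breakage moves targeting the fitted segment aggregates, with
per-site, per-direction fold budgets taken from the observed junction CNs,
iterative deepening on the move count (path length at most doubles per
move), and a biggest-suffix-first heuristic. Any accepted core path must
realize every detected fold-back at its canonical site and direction;
otherwise alternate topological orders and then alternate optimal
configurations (no-good cuts on the previous assignment) are tried, up to
six orders and six configurations by default.

## Complex events around the core

* **Imperfect fold-backs** `(s_i, s_j-bar)` are solved as perfect folds at
  the endpoint of the longer retained arm (higher index for tail-to-tail,
  lower for head-to-head), with the observed CNs of the skipped segments
  compensated upward so the perfect-path program sees a consistent profile;
  after composition the realized perfect adjacency is rewritten back and the
  skipped run dropped.
* **Deletions and duplications** inside the region are stage-2 edits: their
  CN effect is removed before solving and the edit is applied to the
  leftmost intact forward copy afterwards (which copy a real event edited is
  unknowable from bulk data; leftmost is a deterministic convention,
  overridable).
* **Insertions** are recognized as a donor contig without fold-backs
  attached to the host by exactly two junctions; the bracketing host
  adjacency is fed to the solver as linkage evidence and the donor run is
  spliced in afterwards.
* **Translocations** follow two temporal orders. BFB-to-TRX (default)
  composes per-chromosome paths and concatenates whole blocks at terminal
  junction endpoints, reverse-complementing blocks as the junction ends
  dictate. TRX-to-BFB fuses the layouts into a single virtual contig first
  and solves on the fusion; it is forced for virus integration, where viral
  segments join a host chromosome before the cycles run. The fused reference
  must read centromere-to-unstable-end, so fusion is attempted from each
  human-side chain endpoint and the first resolving orientation kept.
* **Virtual fold-backs.** When detected junctions cannot explain the CN
  stair, candidate folds at CN-step boundaries (largest step first) are
  offered to the solver with a flat penalty of 2 disparity units each,
  greedily keeping those that improve the objective, up to 3 per event.
  Fold-backs realized by the final path but absent from the input are
  reported in `flags$virtual_folds` — undetected junctions inferred to
  complete the event, the behavior low-depth or low-purity data needs.

## The simulator and what it does (not) cover

`simulate_history()` replays the grammar with uniformly drawn cuts (the
truncation distribution is unspecified in the field; uniform over cuts
keeping a nonempty appended block is this package's choice).
`apply_complex_template()` builds the six benchmark archetypes — perfect,
imperfect folds, insertion, translocation, duplication+insertion, and virus
integration — parametrically; the perfect default (six segments, fusions at
H6, H2, H4, H3, final cut 1) is the instance the acceptance script scores.
`derive_observables()` emits exact segment multiplicities with optional
rounded Gaussian jitter, the realized junction list with independent
dropout (junction CN = number of realized fold adjacencies, read-support
semantics), and oriented-adjacency linkage. `simulate_batch()`
rejection-samples paths into the benchmark ranges (6–15 segments, 2–7
cycles, total CN 13–105, largest CN 3–11) with a seeded manifest.

Simulated CN noise and junction dropout emulate depth and purity effects at
the observable level only: no reads are simulated, so caller-specific
artifacts (mismapping near breakpoints, fragmented calls, jittered
positions beyond the 50 bp snapping tolerance) are not represented. Passing
round trips demonstrate the solver and composer are exact inverses of the
generative model, not that any particular caller's output will be as clean.

## Numerical and degenerate-input choices

Problem sizes follow the benchmark scales: property tests run hundreds of
round trips at up to 8 segments and 6 cycles, and the solver-versus-oracle
agreement check is exhaustive over all 9,968 (CN vector, fold-site set)
instances with at most 4 segments and total CN 12. Defaults: breakpoint
snapping and junction matching tolerance 50 bp, SV grouping gap 1 Mb
(the clustering radius is not stated numerically in the field literature;
1 Mb sits above caller jitter and below typical inter-event spacing),
candidate span limit 10 Mb, purity 1 and ploidies 2/2 for depth conversion.
Degenerate inputs: identical breakpoint pairs are valid perfect fold-backs
at table level but rejected by the classifier as self-junctions; empty
junction sets solve (reference-only or doubled-reference fits); fold-free
multi-copy profiles are not charged for the undetectable junctions between
copies (the run-start total is an inequality, not an equality).

## Known limitations

* The composition search and peeling are exponential in the worst case;
  budgets and the 64-segment history cutoff keep them desk-scale, and
  histories beyond the cutoff are flagged approximate.
* Fold ownership in the ILP is a relaxation; unrealizable optima are
  filtered by composition, at the cost of extra solves on adversarial
  inputs.
* One derivative path per candidate is reconstructed; allele-specific or
  multi-molecule scenarios (e.g. a co-existing unrearranged homologue) must
  be handled by pre-subtracting the baseline CN.
* Cycle counts are minimal generating histories; a real event may have used
  more cycles than the most parsimonious derivation.
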