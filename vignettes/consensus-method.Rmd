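---
title: "Consensus domain assignment: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus domain assignment: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domcons)
```

## The model

`domcons` treats a domain assignment as a partition of a chain's residues
(1-based sequential indices) into domains, each made of one or more
non-overlapping contiguous fragments; residues may be left unassigned
between domains (linkers). Given one such partition per method, the
package answers two questions: *which methods agree*, and *what partition
does the (possibly weighted) majority support*.

### Pairwise agreement

Agreement between two methods requires (i) the same number of domains,
(ii) the same number of fragments per matched domain, and (iii) for every
matched domain — and, by default, every matched fragment within it — a
residue intersection covering at least `overlap_threshold` (default 0.80)
of **each** partner's residues. Three points here were genuinely open and
are the package's own choices:

* **Bidirectionality.** "80% of the residues should be the same" could be
  read one-sidedly. We require the intersection to cover 80% of *both*
  domains: the one-sided form is asymmetric, which would contradict the
  symmetric role agreement plays in grouping, and the bidirectional form
  is the strictest consistent reading. Symmetry of the resulting relation
  is property-tested on random pairs.
* **Domain pairing** is positional after canonical ordering (domains
  sorted by the start of their N-terminal fragment): counts already have
  to match, domains are disjoint, and positional pairing is deterministic.
  An overlap-maximizing pairing (exhaustive over permutations, practical
  because chains rarely exceed a handful of domains) is available via
  `consensus_params(pairing = "optimal")` for robustness studies.
* **Fragment-level checks** apply the same bidirectional 80% rule to
  positionally matched fragments; `compare_fragments = FALSE` relaxes the
  criterion to whole-domain residue sets only. The strict form is the
  default because fragment structure is part of the assignment the
  methods disagree about.

The agreement relation is reflexive and symmetric but **not transitive**:
boundary shifts can accumulate, so A can agree with B and B with C while
A and C differ by too much. The test suite carries an explicit witness
(two-domain partitions split at 100/90/75 on a 200-residue chain).

### Grouping and reliability

Methods are processed in a fixed order (`method_order`, defaulting to the
seven supported methods). The first method founds group 1 and is its
representative; each later method joins the *first* group (in creation
order) whose representative it agrees with, else founds its own group.
Because the relation is not transitive, the grouping of borderline cases
depends on this order; the fixed order makes results deterministic, and a
regression fixture documents an instance where reordering changes the
partition. Whenever the relation *is* transitive the greedy procedure
provably returns the connected components of the agreement graph, which
the tests verify against a brute-force component search.

Reliability of a group is the share of the vote it carries:
`100·|members|/n` in simple mode, `100·Σw(members)/Σw(all)` in weighted
mode. The weighted combination formula is the package's choice — the
minimal generalization of "percentage of contributing methods" — and
reduces exactly to the simple score when all weights are equal and the
rule adjustment is zero (tested). Weights are renormalized over the
methods actually present, so a method that produced no output simply
drops out of both numerator and denominator.

### Threshold and near ties

A consensus is declared when the top group's reliability reaches
`consensus_threshold` (40%). If the runner-up is strictly less than
`near_tie_window` (10) points behind a qualifying top group, both are
reported with status `tied_consensus`; at most two groups are ever
reported. Ties in reliability are broken by group-creation order. A tied
runner-up *below* 40% is co-reported (the qualifying condition applies to
the top group only) and flagged in the report
(`runner_up_below_threshold`); with seven equally weighted methods this
cannot actually occur, since reliabilities are multiples of 100/7 and a
gap under 10 points forces equality.

### Weight rules

The nine context rules adjust the base weights in fixed order; "reduced
by 10%" is implemented multiplicatively (×0.9, increase ×1.1 via
`rule_adjustment`), not as a 10-point subtraction — weights are
heterogeneous percentages and repeated absolute subtraction could drive
the lowest-weighted method negative. Each rule fires at most once; rules
naming methods absent from the set are skipped; every application is
recorded in a provenance list. Two readings were fixed here: the
abbreviation "DP" in the first rule denotes DomainParser2 (PDP is spelled
out where it is meant), and the alpha-beta rule's "disagree with PDP and
NCBI" is operationalized as "not in PDP's agreement group", since that
rule only fires when PDP and NCBI already agree on the domain count.

### Structure class

The class used by the weight rules is computed from DSSP codes: helix
elements are maximal runs of H/G/I, strand elements maximal runs of E
(isolated bridges, B, are not sheet runs). Among residues inside any
element, a chain is all-alpha when the strand share is at most
`ss_class_minor_fraction` (0.05), all-beta symmetrically, irregular when
there are no elements, alpha-beta otherwise. The 5% tolerance is a
package choice: a verbatim "all" would let a single stray strand residue
flip the class.

### Boundaries and secondary-structure cuts

A boundary is a residue at which a fragment starts or ends, excluding the
chain termini; the residue-level definition (rather than an inter-residue
gap) matches the way the cut rules are phrased in residues. A helix is
cut by a boundary that avoids the `helix_end_exclusion` = 2 residues at
each end; a strand by one avoiding `strand_end_exclusion` = 1. Hence a
helix of length ≤ 4 and a strand of length ≤ 2 can never be cut (tested
by exhaustive enumeration over element lengths 1–12). Statistics count
each boundary at most once per element kind; per-method fractions divide
by that method's boundary count, and a zero-boundary method reports 0
with a flag rather than NaN. Boundaries that two adjacent fragments share
at the same residue are deduplicated per method by default
(`dedupe_boundaries = FALSE` keeps them, since some methods report
abutting fragments deliberately). For the rendered context track the
*untrimmed* element spans are drawn; trimming applies only to the
statistics.

## File formats

* **Native table** (TSV or JSON): `pdb_id, chain_id, method, domain_id,
  start, end`, one fragment per row, `#` comments, header required.
  Write–read round-trips are bit-exact at the row level.
* **CATH Domall** (read-only): fixed-field records, one per chain, with
  per-domain segment counts and per-segment boundaries. A Domall record
  carries only segment endpoints, not the chain's residue list, so a true
  sequential renumbering of insertion-coded residues is not derivable
  from the file alone: author residue numbers are used as indices, chains
  starting below residue 1 are shifted to start at 1 (the offset is kept
  as an attribute for traceability), and insertion-coded endpoints keep
  their numeric part with a warning. Trailing fragment records
  (unassigned bits) are skipped.
* **DSSP** (read-only, plus a minimal writer for fixtures): the summary
  structure column of classic DSSP text; residues renumbered sequentially
  per chain; chain-break records terminate elements.

Chains shorter than 40 residues are accepted with a warning — no hard
minimum-length filter is enforced, since meaningful cutoffs vary by use.

## The synthetic generator

Testing needs multi-method assignment sets with controlled agreement
structure, so the package plants a truth and perturbs it per method:

* `generate_true_partition(length, n_domains, seed)` tiles the chain with
  contiguous domains of at least 20 residues each — a floor chosen as the
  smallest span structural biologists would plausibly call a domain-sized
  unit, and one that keeps the 80% criterion meaningful at the chain
  lengths used in testing.
* `perturbation_spec` controls boundary jitter (uniform shifts up to
  ±`boundary_jitter` residues), under-cutting (`merge_prob`),
  over-cutting (`split_prob`) and fragmentation (`fragment_prob`; the
  carved-out middle segment is handed to a neighbouring domain, or left
  unassigned on a single-domain chain). Domain pieces never shrink below
  5 residues; invalid draws are retried up to 100 times before falling
  back to the truth with a warning.
* Every method draws from its own stream seeded by hashing (seed, method
  name), so generated sets are independent of method iteration order and
  byte-reproducible.

The generator emulates the *kinds* of disagreement real methods show —
boundary placement noise, over- and under-cutting, fragmentation — but
not any specific method's quantitative error profile, nor structurally
correlated errors (real methods err on the *same* hard chains, not
independently). Passing tests therefore demonstrate the correctness of
the consensus machinery under controlled disagreement, not the field
accuracy of any method.

## Problem sizes and determinism

The test suite runs synthetic chains of 100–600 residues with 1–8
domains: large enough that the 80% criterion has resolution, small enough
that thousands of property-test cases run in well under a minute. The
randomized acceptance study uses 500 seven-method sets of 300 residues
and 1–4 true domains. All stochastic tests fix their seeds; the
acceptance script derives every stream from its single `--seed` argument.

## Known limitations

* Single chains only: no quaternary or multi-chain domain assignment, no
  alternate conformations.
* The package consumes method outputs; it does not run PDP, PUU, etc.
* SCOP's cla format is not parsed; expert assignments enter via Domall or
  the native table.
* Insertion-code handling in Domall is approximate (see above).
* Reliability is per-chain, not per-boundary; partial consensus on a
  subset of boundaries is out of scope.
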