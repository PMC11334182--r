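---
title: "Discrete modeling with BioRECIPE spreadsheets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete modeling with BioRECIPE spreadsheets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biorecipe)
```

## The two layouts and what they assume

BioRECIPE represents the same biological knowledge at two granularities.
The *Interaction List* is event-based: each row is one signed, directed
influence between two entities, with four attribute blocks — node (name,
type, identifier, database, compartment for each participant), edge (sign,
connection type, mechanism, site), context (cell line, cell type, tissue,
organism) and provenance (score, source, evidence statements, paper
identifiers). The *Executable Model* is element-based: each row is one
discrete variable carrying everything a simulator needs. The element row
aggregates all interactions in which the element is the target, so the two
layouts are two views of one signed directed graph; `assemble_model()` and
`disassemble_model()` move between them and conserve that graph exactly
(this is property-tested on randomized lists).

The canonical column sets used here are 26 headers for interactions and 17
for elements (`biorecipe_columns()`). Header matching is deliberately
forgiving — case, spaces, underscores and hyphens are ignored — because
these files are edited by hand; unrecognized columns are preserved verbatim
on round trip and reported as warnings, never dropped silently. Controlled
vocabularies (entity types, signs, connection types, spontaneous behaviors,
relation synonyms) live in an editable YAML file under `inst/extdata/`, since
the format is intentionally not tied to any single ontology.

Entity identity during assembly and merging is `(database, identifier)` when
both are curated, otherwise case-folded name plus entity type. Names alone
are ambiguous (the gene and the protein of one symbol are different nodes),
so two same-named rows with different types stay distinct; a consequence is
that sloppy, partially-typed curation can split an entity — identifiers are
the reliable key, and the validator enforces that an identifier always comes
with its database.

## Update semantics

An element with `L` levels holds a value in `0 … L-1`. Rules are written in
a small expression grammar: a comma list is `max` (any active regulator
suffices), a bare parenthesized list is `min` (all required), `sum(...)` is a
weighted sum with integer weights (`3*B`), `!X` is the multi-level
complement, and `X^` is an indicator of X's highest level. Boolean models
are simply the `L = 2` special case. Complement and weights attach to
variable leaves only; complementing a whole group is a parse error rather
than a silent reinterpretation.

The combination law for one update is a *net-regulation comparison*: with
positive-rule value `P` and negative-rule value `N`, the element steps up by
its increment when `P > N`, down when `P < N`, and holds on a tie. With only
one rule present the comparison is against zero, and the `Spontaneous`
attribute supplies the behavior when regulation is inactive: a
negative-only element with `spontaneous = increase` rises whenever its
inhibitor is off — which is exactly Boolean NOT at `L = 2`, verified by
truth-table enumeration in the test suite (and OR for positive `max` rules).
Ties holding the current value is a deliberate, conservative choice: it
makes update outcomes reproducible and keeps opposing evidence from
oscillating an element on its own. The step size is the per-element
`Increment`, clamped into `[0, L-1]`; the alternative of jumping directly to
the rule's value would make multi-level responses discontinuous in their
inputs.

Weighted-sum rules are compared against the same thresholds as everything
else (the opposing rule, or zero); no per-element firing threshold is
introduced. Anyone needing `sum(...) >= k` semantics can express the
cutoff with the opposing rule.

## Simulation schemes

*Synchronous (deterministic):* at step `t`, every non-constant element whose
`Update Rate` divides `t` recomputes from the step `t-1` state; all updates
apply simultaneously. Update rates therefore act as modular gates — a rate-2
element moves at steps 2, 4, 6, … — which makes slow/fast timescale
separation expressible without randomness.

*Random-asynchronous (stochastic):* one element is updated per step, chosen
with probability proportional to `1 / update_rate`. Constant elements are
excluded from selection: choosing them would be a no-op and would only
dilute the effective step count of everything else. A seed is mandatory;
run `r` of a multi-run simulation uses `seed + r - 1`, the seed is recorded
in each trajectory, and identical inputs and seeds give byte-identical
outputs. The RNG state of the calling session is saved and restored around
every seeded operation.

The update-rate reading differs between the schemes by necessity — the
format only states that rates exist. The modular-gate (synchronous) and
inverse-weight (asynchronous) interpretations agree in the limit of rate 1
and both make a rate-`k` element move `k`-fold slower on average. `Update
Group` is parsed, validated and preserved on round trip but ignored by the
simulation kernel; ranked group schedules are out of scope.

## Attractor enumeration

`find_attractors()` builds the exhaustive synchronous state-transition map
(mixed-radix encoding of the state space, capped at `2^20` states by
default) and finds all cycles of the resulting functional graph, assigning
every state to the attractor its forward orbit reaches, so basin sizes
always partition the state space. Update rates are ignored here — they make
the synchronous map time-dependent, under which "attractor of the map" is
not well defined — and a warning says so when a model has rates ≠ 1. Cycles
are rotated so their lexicographically smallest state comes first and are
then sorted by that state, making output order deterministic.

## Spreadsheet dialects and numerical conventions

CSV is UTF-8 with RFC-4180 quoting; TSV is unquoted, with tabs or newlines
inside cells rejected at write time; XLSX uses a single worksheet (reading
via readxl, writing through a minimal single-sheet OOXML writer with
inline-string cells). An empty cell always means "attribute absent", never
an empty-string value. Multi-valued cells (`Paper IDs`, `Initial Values`)
are comma-separated; values containing literal commas are not representable
and should be avoided. Booleans are read as TRUE/FALSE, 1/0 or yes/no
(case-insensitive) and written as TRUE/FALSE. Rules are re-serialized in
canonical minimal-parenthesization form on write, so a file round trip
normalizes `max(A,B)` to `A, B` while preserving the parsed rule exactly
(`parse_rule(serialize_rule(ast))` is the identity, property-tested on
randomized ASTs). CSV and TSV writing is byte-deterministic; XLSX is not
guaranteed byte-stable (the container embeds timestamps) but is
content-stable.

Validation never throws on record content: every failure is an `Issue`
(severity, row, column, message), errors always carry at least a row or a
column, and readers return all rows — flagged ones included — so a curator
can fix a sheet in one pass. Writers refuse input with error-level issues.

## Fixtures: what they emulate and what they do not

The motifs are the standard small discrete-dynamics benchmarks: `toggle`
(mutual repression; two fixed points plus the synchronous 2-cycle),
`repressilator` (negative 3-ring; a 6-cycle and the (0,0,0)/(1,1,1)
2-cycle), `cascade3` (a 3-level chain with the source clamped at 2 —
the terminal element first reaches level 2 at synchronous step 3, one step
per stage), and coherent/incoherent feed-forward loops. Repressive motifs
encode NOT as negative-only rules with `spontaneous = increase`, the
idiomatic encoding under the net-regulation semantics. Downstream cascade
elements use `spontaneous = decrease` so the signal decays when the source
is removed.

`random_interaction_list()` and `random_model()` are seeded generators whose
outputs always satisfy the schema invariants (generator-validator
consistency is property-tested); the interaction generator also returns its
ground-truth signed edge set for oracle comparisons, and can fill in
plausible context and provenance strings. They emulate the *structure* of
curated data — vocabulary-conformant, no self-loops, no duplicate edges —
not its biology: entity names are synthetic tokens, context fillers are
drawn from a tiny fixed palette, and rule structure is sampled uniformly
from the grammar rather than from the motif distribution of real pathways.
Passing round-trip and conservation tests on these fixtures demonstrates
the machinery is lossless and deterministic, not that any particular
biological model is correct.

Problem sizes used by the shipped checks — 200 random lists and 200 random
models for round-trip fidelity, 1,000 random rule/state pairs against a
naive recursive evaluator, 1,000 asynchronous toggle runs (their
fixed-point split is expected in 0.45–0.55, the 3-sigma binomial band at
p = 0.5), 100 fixtures for conversion conservation — were chosen to give
the property tests real coverage while the whole suite stays fast on a
single CPU.

## Interoperability and its limits

SIF export writes `regulator <tab> relation <tab> regulated` with
`activates`/`inhibits`; import additionally accepts `activate`, `inhibit`,
`positive`, `negative`, `+`, `-`. Triplet tables use predicates
`increases`/`decreases` and carry evidence text and paper identifiers both
ways. Both formats are lossy relative to BioRECIPE, so every export returns
the list of non-empty columns it had to drop; every import skips rows whose
relation or predicate it cannot map to a causal sign — correlative and
associative statements are rejected with warnings rather than guessed at.
Graph export emits plain node/edge tables usable by any network tool. Rich
model-exchange standards (SBML and SBML-qual, CellML, BioPAX, KGML, SBOL)
are out of scope.

## Known limitations

* Scenario indices are 1-based in both the R API and the CLI.
* Cells cannot contain a literal comma inside one value of a multi-valued
  field.
* Attractor enumeration is exhaustive only; no sampling fallback is
  provided for state spaces beyond the bound, and update rates are ignored
  there.
* The asynchronous scheme estimates nothing beyond empirical trajectory
  statistics; steady-state probabilities are left to the caller.
* XLSX support is single-sheet, value-only (no styles, formulas or merged
  cells).
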