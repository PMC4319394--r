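---
title: "cellsim: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellsim: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellsim)
```

cellsim turns CellML documents — the XML exchange format for cell-level
ODE/DAE models in computational physiology — into validated, annotated,
executable simulations. This vignette is the package's own account of
the procedures it implements, the parameters that matter, the numerical
choices, and what its tests do and do not demonstrate.

## The document model and the MathML subset

A parsed model holds components (variables plus equations), connections,
units definitions, imports (CellML 1.1 only), and two verbatim blocks:
the embedded RDF/XML annotation element and any foreign-namespace
children. The two CellML versions are distinguished strictly by their
published namespace URIs; feature usage is never sniffed, so version
detection is deterministic.

Only the content-MathML subset that ODE/DAE cell models need is
interpreted: arithmetic, powers and roots, `exp`/`ln`/`log`,
`abs`/`floor`/`ceiling`, trigonometry with inverses, boolean
connectives, relations, `piecewise`, and first-order derivatives with a
single bound variable. Anything outside the subset is a hard, located
error naming the element — failing loudly is preferred to silently
mis-simulating a model whose mathematics were partially dropped. Every
number (`cn`) must carry a units attribute; this is the strict reading
of the rule that all quantities have units.

Reaction, group/encapsulation and scripting elements of the wider
CellML specification are preserved opaquely for round-tripping but not
interpreted; encapsulation therefore does not affect connection
semantics here. The round-trip guarantee is structural (equality up to
source locations), not byte-level, except for the RDF and foreign
blocks, which reappear verbatim.

Source locations are recovered by indexing tag occurrences in the raw
text and assigning the *k*-th parsed element of a tag the *k*-th
occurrence (document order equals preorder traversal). The guarantee —
the recorded line's text contains the element's tag — is exactly what
jump-to-line diagnostics need, and it keeps the parser on plain xml2.

## Validation: severities and dimensional rules

Structural faults (duplicate names, dangling references, interface
direction mismatches, a variable both initialised and computed, a
variable never defined, `ci` references to undeclared names) are
**errors**. Dimensional inconsistencies are **warnings**: units
discipline in published repositories is uneven, and a model with an
imperfect unit declaration is still usually worth simulating. Scale
mismatches with equal dimensions (litre vs metre³-style) get a distinct,
lower-priority code (`scale-mismatch`) from genuine dimension mismatches
(`mismatched-addition`), because they call for different fixes.

Units reduce to a vector of exponents over the seven SI base dimensions
plus a multiplier and an optional offset (celsius-style units keep their
offset; it does not participate in comparisons). Booleans are a
pseudo-dimension incompatible with every physical dimension, so a
relation used as a number is flagged. The rules are: addition-class
operators (and both sides of an equality, and piecewise branches)
require equal exponent vectors; products and quotients add and subtract
them and combine multipliers; a power needs a constant-valued
dimensionless exponent (a power with a non-constant exponent is rejected
unless the base is dimensionless, because its dimension is not
statically determinable); transcendental functions need dimensionless
arguments; a derivative divides the dependent dimension by the bound
one. When an operator fails a rule, the walker reports once and
propagates "unknown" upward, so one defect yields one diagnostic rather
than a cascade. Circular units definitions are errors, reported once per
cycle. A user-declared base unit introduces a dimension not expressible
over SI; it is treated as dimensionless with unit scale, which keeps
checking permissive for such models.

Issues are sorted by (line, column) and are bitwise deterministic.
Values are never rescaled across connections or literals: dimensionally
equal but scale-mismatched pairs warn and pass through unchanged. A
strict mode (the CLI's `--strict-units`) upgrades units warnings to
errors.

## Flattening (1.1 → 1.0)

Import resolution works against a locator abstraction (an in-memory map
in tests, the filesystem in the CLI, resolving relative to the importing
file) so the whole path runs without downloads; remote hrefs are refused
by default for reproducibility. Each imported units definition or
component is instantiated under its local name; transitive needs — units
used by an imported component, components connected to it in its source
document, and their connections — are pulled in, with instantiation
memoized per (document, element) so diamond imports do not duplicate.
Name collisions are renamed with numeric suffixes (`_1`, `_2`, …)
applied to the later arrival, and a rename log is attached to the
result. CellML 1.1 initial values that reference another variable are
rewritten to that variable's literal. Annotations whose subjects are
imported elements travel with them. The output is version 1.0 with no
imports, and flattening an already-flat document is byte-idempotent.

## Classification, ordering, and the runtime

Connected variables are merged with union–find; the canonical member of
a group is the declaration carrying the initial value, else the
`out`-interface site, else the first in document order. Conflicting
initial values within a group are an error. Each merged variable gets
exactly one of six categories:

| category | rule |
|---|---|
| variable of integration | the unique bound variable of all derivatives (two distinct ones is an error; a model with no derivative is rejected — this runtime requires at least one ODE) |
| state | its derivative is an equation target (must carry an initial value) |
| rate | that derivative, tracked as a first-class parameter |
| constant | has an initial value, never computed by an equation |
| computed constant | equation target whose transitive dependencies exclude the VOI, states, rates, and algebraic variables (computed once per run) |
| algebraic | every remaining computed variable, including the unknowns of implicit blocks |

The dependency rule for computed constants is applied as a fixpoint; an
independent brute-force classifier (direct dependency-closure
enumeration) cross-checks it in the tests.

Equations are rewritten to assignment form when one side is a bare
variable or derivative; defining the same target twice is an error. A
dependency graph over the steps is condensed: strongly connected
components of size > 1, and equations with no assignment form (such as
`x + y = 3`), become NLA blocks, grouped by shared unknowns; a block
whose equation and unknown counts differ is reported as structurally
singular. The topological order of the condensation is the plan, each
step tagged with its phase (computed constants, rates, algebraic).

The plan is generated into R source and compiled into closures — the
runtime. Computed constants live at the tail of the constants vector.
`compute_rates` executes the algebraic-phase steps too (in plan order),
so every quantity a rate needs is available; `compute_algebraic`
re-executes them against the stored rates. Inside the evaluators an NLA
block loads its unknowns from the solver vector, evaluates residuals
`lhs − rhs`, and calls the registered Newton solver with a warm start:
the previous solution per block, zeros on the first call. The warm-start
store lives in a per-session environment, so concurrent sessions share
nothing; given identical inputs (including that environment's state) the
evaluators are pure.

## Solvers

The fixed-step methods are the textbook formulas. "RK2" is the
**midpoint** method, deliberately distinct from Heun's method —
otherwise the solver list would contain the same method twice; the two
coincide on linear problems, which the tests exploit as a consistency
check. The adaptive integrator delegates to deSolve's lsoda
(Adams/BDF switching), with relative/absolute tolerance, maximum step
and maximum step-count properties, and is queried at grid points through
interpolated output rather than forcing integrator steps onto the grid —
the standard variable-step practice. Jacobians are always
finite-difference; there is no symbolic differentiation.

The Newton NLA solver uses a forward-difference Jacobian with
perturbation `sqrt(eps)·max(|x_i|, 1)` and a halving line search capped
at 10 halvings (with one full-step fallback for the last-ulp stall near
a root); success is a residual max-norm below the tolerance (default
`1e-12`). Singular Jacobians and iteration exhaustion are distinct,
reported errors.

Semi-explicit index-1 DAE systems are handled by backward Euler over the
Newton solver (`F(t+h, y₊, (y₊−y)/h) = 0`), or by any explicit path with
per-step NLA block solving. A full BDF-style DAE integrator is **not**
re-implemented; that is a documented limitation, and the structural
check (every implicit block's unknowns are algebraic) defines the class
of models accepted.

Observed convergence orders on the decay problem (error at `t = 1`
against the closed form, `p̂ = log2(E(h)/E(h/2))` at `h = 0.01`) are the
package's standing health check: ≈1 for Euler and backward Euler, ≈2
for Heun and midpoint, ≈4 for classic RK4.

## Simulation semantics

The recording grid is `start + i·interval`, computed by index
multiplication — never by accumulation — so `voi[last]` is within a few
ulps of `end` whenever `(end−start)/interval` is integral within `1e-9`
relative tolerance; otherwise the grid ends at the last point below
`end`. Fixed-step solvers take `ceil(interval/step)` equal substeps per
interval when a finer internal `step` property is set, else one step per
interval.

Every model parameter is always tracked — constants, computed constants,
states, rates, algebraic — so any series can be extracted (and plotted
against any other) after the run without re-simulating. The price is
memory, so a capacity estimate (`(parameters+1) × points × 8` bytes,
default cap 1 GiB) raises an error *before* a run starts rather than
mid-flight.

Pause points snap to the nearest grid point at or after the requested
value. Modifications (constants and states only; modifying a computed
parameter is a category error naming its category) apply **before** the
paused point is recorded, so stored data are always self-consistent; the
interval leading into the pause is integrated with the pre-modification
values on both the fixed-step and adaptive paths. Changing a constant
re-derives the computed constants at the pause, keeping their stored
series consistent with their definition. Sessions own all mutable state
(solver position, warm starts, store), so interleaved sessions reproduce
sequential runs bitwise.

The CSV exporter writes a header row labelled
`component/name (units)` — VOI first, then parameters in
category-then-name order (constants, computed constants, states, rates,
algebraic) — one row per grid point, numbers as `%.16e` (17 significant
digits, which round-trips IEEE doubles exactly), `\n` endings, no
quoting (identifier rules forbid commas). Exporters are a registry;
`csv` ships and duplicates are rejected.

## Source export

The four shipped targets (C, FORTRAN 77, MATLAB, Python) are data files
in `inst/formats/`, in exactly the flat `key = value` syntax users
supply — there is no privileged built-in path, which keeps the extension
mechanism honest. A format names a rendering (`infix`, `call` or
`prefix` plus a token) for every operator it will meet; an operator used
by the model but absent from the format is an error naming the operator.
The FORTRAN emitter wraps at 72 columns with column-6 continuation;
the Python output is executable, and the tests run it and compare
against the native runtime at random evaluation points to `1e-12`.
NLA blocks are emitted as a clearly marked stub in exported source (the
executable contract is the native runtime); models whose rates depend on
implicit blocks therefore export for reading, not for running — a known
limitation.

## Annotation

Triples live in a constrained RDF/XML form inside the document:
`rdf:Description` per subject (`#cmeta:id` fragment against the
document's own locator), one property element per triple with an
`rdf:resource` object. Predicates are the full published biomodels.net
vocabularies (13 biology, 5 model qualifiers); unknown terms are
rejected with the valid list. Objects are stored exclusively as
identifiers.org URIs; MIRIAM URNs in pre-existing documents are
converted on read (percent-decoding the id) and flagged as deprecated
source forms, never written back. Annotating an element without a
`cmeta:id` goes through deterministic minting (`id_00001`, skipping
collisions, in document order). A malformed RDF block is a contained
error: annotations are reported unreadable, the model still simulates.
Ontology term *lookup* (turning "calcium" into a CHEBI id) is an
external service and is out of core paths; terms pass through
unvalidated against any ontology.

## Fixtures: what they emulate and what they do not

All test inputs are generated in code. `make_decay()` is the minimal
consistent-units ODE with a closed form; `make_fhn()` is a
FitzHugh–Nagumo model chosen to populate all six categories (a computed
constant `eb = eps·b` and an algebraic `u = v − w` are included
deliberately), with the conventional coefficients `eps = 0.08`,
`a = 0.7`, `b = 0.8`, `I = 0.5`; `make_nla()` couples a linear implicit
pair to an ODE; `make_import_pair()` exercises imports, transitive units
and cross-document connections; the invalid suite has one known defect
per file for all eight defect codes. FitzHugh–Nagumo stands in for a
full Hodgkin–Huxley transcription as the "rich" fixture: it is
nonlinear and moderately stiff at small `eps` but hand-checkable.

What passing these tests shows: the pipeline's contracts hold
end-to-end on models that exercise every category, the import mechanism,
implicit blocks, and every defect code. What it does not show: behaviour
on repository-scale models (hundreds of variables, heavy piecewise
gating, reactions or encapsulation semantics), true stiffness of the
Hodgkin–Huxley class, or units pathologies beyond the codes constructed
here. Test problem sizes are deliberately small — grids of 21–101
points, convergence studies with 100–200 steps, one cross-solver FHN
comparison at internal step `1e-4` over `[0, 2]` — chosen so the whole
suite documents the contracts in seconds.

## Known limitations

* No unit auto-conversion: scale-mismatched connections warn and pass
  values through unscaled; literals are taken as written.
* User-declared base units are dimensionally invisible (treated as
  dimensionless) rather than carried as fresh dimensions.
* No event detection/root finding, no multistep families beyond the
  shipped list, no BDF/IDA-class DAE integration (semi-explicit index-1
  only).
* Exported source stubs out NLA blocks.
* Purely algebraic models (no derivative at all) are rejected; the
  runtime is built around at least one ODE.
* `cn` with `e-notation` type attributes and higher-order `bvar`
  degrees are outside the supported MathML subset.
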