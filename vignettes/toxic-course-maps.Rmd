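---
title: "Toxic course maps: model, assumptions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Toxic course maps: model, assumptions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxcourse)
```

`toxcourse` represents drug-induced toxic courses the way ontology-based
toxicology knowledge systems such as the ToXic Process Ontology (TXPO) do:
as typed knowledge graphs of processes linked by causal relations, queried
by route search and evaluated by a qualitative homeostasis imbalance
model. This vignette is the package's own account of that model: what it
assumes, which parameters matter, what the fixtures emulate, and where the
design was genuinely open.

## The typed knowledge base

Every entity is a **continuant** (persists through time: objects, roles,
qualities, molecules, biological structures) or an **occurrent** (unfolds
in time: processes). The category is either declared on the entity or
inferred from an `is_a` path to a declared category root; an entity whose
category cannot be resolved is tolerated but unconstrained. The relation
vocabulary is fixed — `is_a`, `has_part`/`part_of`, `has_result`,
`occurs_in`, `has_role`, `has_participant` — and domain/range constraints
are enforced at insertion time rather than by a description-logic
reasoner: `has_result` links occurrents only, `occurs_in` goes occurrent →
continuant, `has_role` goes continuant → role-kind continuant, and `is_a`
insertions that would close a cycle are rejected. This replaces the
reasoner-based consistency checking of OWL workflows with explicit
structural checks; existential restrictions and disjointness inference are
deliberately out of scope.

Three modelling choices deserve a note:

- **Layers are annotations, not axioms.** The three-layer organization
  (top = domain-independent, intermediate = biomedical, lower =
  toxicology-specific) is narrative in the source material, so each entity
  carries a layer tag assigned at construction time; an untagged but
  connected entity falls back to `intermediate`, and disconnected entities
  are `unassigned` with a recorded warning.
- **Roles are ternary.** A molecule's role depends on the process context
  (amiodarone is a cationic amphiphilic drug and a competitive inhibitor
  of phospholipase in the negative regulation of phospholipid degradation,
  but a mitochondrial respiratory-chain inhibitor in the negative
  regulation of the respiratory electron transport chain). OWL `has_role`
  is binary, so the context is an explicit third component of the triple,
  serialized as a reified statement.
- **`part_of` is a view.** Whole–part facts are stored canonically as
  `has_part`; the inverse is derived on demand, so the two views cannot
  disagree.

## RDF serialization

No RDF triple-store binding is available to this package's R dependency
set, so the Turtle side is a constrained codec written here: documents are
emitted one triple per line with prefixed names and plain literals, in a
fully sorted order (serialization is byte-deterministic), and the reader
accepts exactly that subset plus `<full-IRI>` terms and comments. RDF/XML
goes through `xml2` using the striped `rdf:Description` syntax. English
relation names map to `rdfs:subClassOf` (`is_a`), `BFO_0000051`
(`has_part`), `BFO_0000066` (`occurs_in`), `RO_0000087` (`has_role`) and
`RO_0000057` (`has_participant`); `has_result` has no Relations Ontology
counterpart and lives, together with the engine's annotation properties
(layer, category, kind, role context, substitution records), in a fallback
vocabulary namespace under the OBO PURL base. Unrecognized predicates are
kept verbatim in a side channel and re-emitted, so a richer document can
pass through without data loss; typed-constraint violations are collected
into an import report while the import continues.

## Courses: inheritance and specialization

A toxic course is a process sequence whose members are attached with
`has_part` and ordered by `has_result` causal edges, `(cause, effect)`
matching the arrow direction of course diagrams. Child courses inherit the
parent's processes. Inheritance is computed at materialization time
(`build_course_graph()`), not by copying triples into the knowledge base:
this keeps the base normalized, mirrors how is-a subsumption works, and
makes materialization pure — repeated calls on an unchanged base are
identical.

Specialization (`specialize_course()`) is an explicit, id-level
substitution map — a curator action, not free-text label surgery. Each
target either names an existing entity or is created as a new lower-layer
process that `is_a` its source (sphingomyelin accumulation in lysosome
specializes phospholipid accumulation in lysosome), which keeps the
specialized terms connected for layer classification and cause
generalization. A target label that collides with an unrelated existing
process is an error. Causal cycles are rejected in course validation by
default — toxic courses are progressions — with an `allow_cycles` escape
hatch for feedback loops.

A materialized course only keeps `has_result` edges whose *both* endpoints
are course members. An asserted edge touching exactly one member (a
reference into another course sharing a process) is recorded as a
validation warning and excluded, which keeps each course graph
self-contained while shared process entities still align across courses in
merged maps.

## Route search and functional decomposition

Route search is plain directed reachability with shortest-hop depths:
downstream follows the causal arrows (prospective: what will progress),
upstream reverses them (retrospective: what could have caused a finding).
Routes stay within one course by default; cross-course questions go
through the merged general map instead. `max_depth` is unlimited unless
set. Cross-course comparison matches nodes by id, or optionally by
case-folded labels with the `[course]` bracket suffix stripped, because
courses curated separately may use distinct ids for one phenomenon.
Pathological findings attach to processes as annotations and are carried
along in route results; findings that the source diagrams print *inside*
causal chains (ballooning, myelin figure in lysosome) are additionally
ordinary occurrent nodes, so they participate in reachability.

Functional decomposition reads `has_part` among processes as
"sub-function of the sub-system": a cell decreases phospholipid through
the catabolic process and transport in lysosomes, enzyme transport in the
late endosome and phospholipase gene expression in the nucleus, each child
annotated with its `occurs_in` structure. Dysfunction propagates bottom-up
to exactly the ancestors of the failed node — the whole-functions whose
achievement depends on the failed part — leaving sibling branches
untouched.

## The general course map and cause generalization

Merging course graphs is a keyed union (by id or normalized label) that
records per-node course membership; a node is *common* when its membership
reaches the threshold (default 2 courses). The merge is order-invariant
and the "large node" display of common processes is pure rendering
metadata: the JSON export carries a `size` field equal to the membership
count.

Cause generalization partitions the upstream neighbours of a target node
by their nearest shared `is_a` ancestor, merging greedily while the
common ancestor is *informative*. The source material does not define the
grouping algorithm, and its natural reading ("any ancestor below the
occurrent root") degenerates — in any realistic hierarchy all processes
share a generic *process* ancestor below the root, which would collapse
every cause into one group. The package's default ceiling is therefore the
**top layer**: an ancestor labels a group only if it is not a
domain-independent top-layer term. With that ceiling, phospholipid
accumulation in lysosome and bile acid accumulation group under
accumulation of intracellular substances, while smooth endoplasmic
reticulum proliferation stays a singleton labelled by its own most
specific informative ancestor, increase in number of organelles. The
ceiling is configurable per call.

## The imbalance model

Performance levels form the five-point ordinal scale `very_low < low <
medium < high < very_high`; all shifts clamp to this range. A scenario
binds four course processes — functional demand (toxic activity),
defence supply, the outcome emitted on imbalance, and optionally a
hyperfunction-damage process — plus modifiers. Defaults encode
homeostasis: baseline demand `medium`, supply cap `very_high`.

Resolution is deterministic and ordered: raises/lowers apply first, caps
second (multiple caps combine by minimum), then supply adapts:
`S = min(D, C)`, optionally lifted by a forced floor. Classification:

- `imbalanced_demand` iff `D > S` — the outcome process manifests;
- `balanced_latent` when balance holds but a capping modifier leaves zero
  adaptation reserve (`C − D ≤ 0`) — this formalizes the latent stage:
  no outcome, but the system cannot adapt to further demand;
- `imbalanced_supply` when a forced supply sits at `very_high` and
  exceeds demand by at least the over-supply threshold (default 2 steps;
  only the fibrosis-style example constrains it, so it is a configurable
  parameter rather than a fixed constant);
- `balanced` otherwise. Equality of supply and demand counts as balanced:
  the source states only that demand *exceeding* performance causes
  imbalance.

Cap modifiers carry the cap **level** directly rather than a step count
(a cap "at medium" is what the scenarios state; steps-from-default would
be opaque), while raise/lower modifiers use integer step magnitudes.
Whether adaptation should instead unfold over multiple evaluation rounds
(a trajectory) is left unimplemented rather than guessed; the
instantaneous model reproduces all four published scenario outcomes, and a
trajectory mode would be an extension, not a reinterpretation.

These invariants are property-tested: raising demand never turns an
imbalance back into balance, lowering the cap never increases reserve,
and a modifier-free scenario is always the balanced homeostasis fixed
point.

## Fixtures: what they emulate, and what they do not

`build_published_kb()` deterministically reconstructs the printed fragments:
the functioning-process hierarchy, the decomposition of decreasing
phospholipid, the phospholipidosis chain (compound accumulation in
lysosome → negative regulation of phospholipid degradation → hypofunction
of phospholipid degradation → phospholipid metabolism imbalance →
phospholipid accumulation in lysosome), the sphingomyelin specialization
with the ceramide chain, the four imbalance course variants under their
published PURL ids (`TXPO:0001964`, `TXPO:0003369`, `TXPO:0000949`,
`TXPO:0001468`), NASH/cholestasis/ground-glass fragments, and the role
and participant assignments (amiodarone, PLA2G15,
desipramine/imipramine, ASAH1). Two harmonizations were needed:
"negative regulation of phospholipase-mediated phospholipid degradation"
(route-search prose) and "negative regulation of phospholipid
degradation" (course diagram) are one entity under the diagram's label,
and "increasing hepatocellular volume" / "increasing hepatocyte volume"
are one shared process, so cross-course comparison and the merged map
agree.

The fixtures encode *only* what is explicitly printed — course maps in
the source are shown truncated, so tests assert containment, never exact
node counts, for those maps. Passing tests therefore show that the engine
reproduces the published worked examples and satisfies the model's
invariants; they do not show coverage of the full released ontology
(9,395 entities), which would require a download and is out of scope
here. All other entities use the reserved `TXPOX` prefix precisely so no
unprinted real identifier is asserted.

`build_random_kb()` generates property-test instances: processes
partitioned into courses, causal edges drawn forward along a global
topological order (every course acyclic by construction) with a given
density, and a random course is-a hierarchy; it restores the caller's RNG
state and reports its own construction tallies as ground truth. Random
instances exercise structure, not biology: node labels and topology carry
no domain meaning.

## Numerical and procedural choices

- Set-valued results are returned in lexicographic id order; internal
  semantics are set-based. Ties in cause-group labelling (equal-depth
  ancestors) break lexicographically.
- Serialization output is byte-deterministic; reified role and
  substitution statements are numbered in sorted triple order.
- Degenerate inputs: an empty knowledge base serializes to a valid
  prefix-only document; a course with no processes is an empty graph; a
  single-node route contains only its origin at depth 0.
- Problem sizes in the shipped tests — 200 random DAGs of up to 50 nodes
  for route search, 60-process bases for closure checks, 120–200-process
  bases for round-trips — were chosen as the smallest sizes that exercise
  branching, diamond reachability and multi-course structure; all oracles
  are naive reference implementations (fixpoint joins, recursive DFS,
  exhaustive ancestor-set intersection) independent of the engine's code
  paths.

## Known limitations

Embedded engine, not a service: SPARQL hosting and interactive
visualization are replaced by in-process queries and
visualization-ready JSON exports. No quantitative kinetics, dose–response
or probabilistic causal inference on edges. Layer assignment of imported
entities depends on annotations; a foreign OWL file without them will
classify everything connected as intermediate. The Turtle reader accepts
the package's own subset, not full Turtle (no blank nodes, collections or
multi-line literals); richer documents should enter via RDF/XML.
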