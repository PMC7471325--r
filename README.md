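# toxcourse

Toxic course knowledge graphs and qualitative imbalance evaluation for
drug-induced liver injury.

## The problem

Hepatotoxicity mechanisms span granularities from molecules to organelles,
cells and tissue, and unfold as *courses*: chains of processes that run
from a latent stage to a manifest toxicity. Pathway databases centred on
molecule–molecule interactions do not capture this, and adverse-outcome
pathways capture only measurable key events. The ontology-engineering
answer — exemplified by the ToXic Process Ontology (TXPO) — is a typed
knowledge graph in which every entity is a *continuant* (objects, roles,
qualities) or an *occurrent* (processes), arranged in a three-layer is-a
hierarchy (domain-independent top layer, biomedical intermediate layer,
toxicology-specific lower layer), with a small relation vocabulary:

| relation | meaning |
|---|---|
| `is_a` | generalization (transitive, acyclic) |
| `has_part` / `part_of` | whole–part, incl. course membership and functional decomposition |
| `has_result` | causal arrow between processes: `(cause, effect)` |
| `occurs_in` | localization of a process in a biological structure |
| `has_role` | context-dependent role of a molecule in a process |
| `has_participant` | molecule participating in a process |

`toxcourse` is an embedded R engine for this model. It covers:

- a typed in-memory knowledge base with insertion-time domain/range
  checks, is-a transitive closure and layer classification;
- Turtle and RDF/XML import/export with OBO-style CURIE ⇄ PURL mapping
  (`TXPO:0001964` ⇄ `http://purl.obolibrary.org/obo/TXPO_0001964`);
- toxic courses materialized as causal graphs, with parent→child process
  *inheritance* and term-substitution *specialization* (e.g.
  phospholipid → sphingomyelin turns phospholipidosis into sphingomyelin
  disorder);
- upstream/downstream route search, cross-course route comparison,
  functional decomposition trees, and bottom-up dysfunction propagation;
- merged *general course maps* that flag processes common to several
  courses and group a node's causes by their nearest informative is-a
  ancestor;
- a qualitative demand–supply imbalance evaluator.

## The imbalance model

Homeostasis is a balance between a toxic activity (*demand*, D) and a
biological defence functioning process (*supply*, S), both measured on the
ordinal scale

```
very_low < low < medium < high < very_high        (0 .. 4)
```

Cells normally hold both at `medium`. Supply adapts upward to meet demand
but cannot exceed its cap C (default `very_high`); modifiers raise or
lower demand, or cap supply:

```
S_eff = min(D_eff, C_eff),   reserve = C_eff − D_eff
```

The assessment is `imbalanced_demand` when `D_eff > S_eff` (the outcome
process manifests, e.g. phospholipid accumulation in lysosome);
`balanced_latent` when balance holds but a capping modifier has driven the
reserve to zero — the latent stage, where any further demand tips the
system; `imbalanced_supply` when a forced defence at `very_high` exceeds
demand by ≥ 2 steps (hyperfunction damage, e.g. fibrosis); otherwise
`balanced`.

## Worked example

```r
library(toxcourse)

built <- build_published_kb()        # deterministic published-course fixtures
kb <- built$kb
kb_stats(kb)
#> entities: 105  toxic courses: 9  processes: 74

g <- build_course_graph(kb, "TXPOX:phospholipidosis")
#> <tox_course_graph> TXPOX:phospholipidosis: 10 processes, 7 causal edges

up <- route(g, "TXPOX:phospholipid_accumulation_in_lysosome", "upstream")
causes <- setdiff(up$nodes, up$origin)
paste(g$labels[causes[order(-up$depth[causes])]], collapse = " -> ")
#> "compound accumulation in lysosome -> negative regulation of phospholipid
#>  degradation -> hypofunction of phospholipid degradation ->
#>  phospholipid metabolism imbalance"

evaluate_imbalance(published_scenario(kb, "latent"))
#> <tox_assessment> balanced_latent (demand medium, supply medium, reserve +0)
evaluate_imbalance(published_scenario(kb, "moderate"))
#> <tox_assessment> imbalanced_demand (demand high, supply medium, reserve -1)
#>   outcomes: TXPOX:phospholipid_accumulation_in_lysosome
```

The retrospective route recovers the full printed causal chain of
phospholipidosis in order. The two assessments separate the latent stage
(a cationic amphiphilic drug caps degradation at `medium`; balance holds
with zero adaptation reserve and no outcome) from manifest toxicity (an
additional demand raise through positive regulation of phospholipid
biosynthesis makes demand exceed supply, and the accumulation outcome
fires).

There is also a shell entry point (`exec/toxcourse`) wrapping the same
engine:

```sh
toxcourse build-fixtures --out /tmp/fx
toxcourse route --input /tmp/fx/fixtures.ttl --course TXPOX:phospholipidosis \
          --node TXPOX:lipid_vacuolation --direction upstream
toxcourse imbalance --builtin niemann_pick
```

## Scope notes

Fixtures encode only processes explicitly printed in the source figures
and text (the `TXPOX` CURIE prefix is reserved for them so they can never
collide with released TXPO identifiers); they are fragments, not a
re-curation of the full ontology. Description-logic reasoning beyond is-a
transitive closure, SPARQL endpoint hosting and graph layout are out of
scope — see the methods vignette (`vignettes/toxic-course-maps.Rmd`) for
the model, its assumptions and design decisions.
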