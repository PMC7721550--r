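# kgql

A graph-oriented biomedical query language and a federated execution
engine for R.

Biomedical knowledge is scattered across independent services — clinical
cohort statistics here, curated gene–disease–chemical linkages there —
each exposing its own graph API. A translational question such as *"which
diseases are differentially diagnosed in males versus females, and which
genes and chemical substances are associated with those diseases?"* spans
several of them at once. `kgql` is for researchers and informaticians who
want to pose such questions as a single declarative query and get back one
coherent, provenance-annotated knowledge graph.

## What it does

A query describes a **linear concept path** in a small hierarchical
vocabulary (a Biolink-style upper ontology of entity concepts and
predicates):

```
set cohort = "FIX:cohort_sex"
select population_of_individual_organisms:cohort->disease->gene->chemical_substance
  from "/schema"
  where cohort = $cohort
  and icees.table = "patient"
  and icees.feature = "Sex"
  and icees.maximum_p_value = 0.5
```

The engine then runs a four-stage pipeline:

1. **Compile** — a hand-written lexer/parser turns the program into an
   AST; the `select` path becomes a query graph `q₁ → q₂ → … → qₙ` of
   concept-typed template nodes. `where` constraints are classified into
   node pins (`cohort = $cohort`), service-scoped options
   (`icees.maximum_p_value = 0.5`), and deferred result filters.
2. **Plan** — every registered knowledge source advertises a *transition
   map*: the set of (source concept, target concept, predicate) steps it
   can answer. Their union is the federated schema. Each query edge
   `(cᵢ, pᵢ, cᵢ₊₁)` is matched against it (concept compatibility is
   bidirectional subtype match; an unlabeled hop matches any predicate),
   and consecutive edges served by one source coalesce into a plan
   segment.
3. **Execute** — segments are invoked in order through one normalized
   source contract; the node identifiers bound at segment *i*'s final
   alias pin segment *i+1*'s first query node (forward answer
   propagation). Whole-query results are cached under the SHA-256 of the
   raw query text.
4. **Merge** — per-segment responses are unioned into one knowledge
   graph. Nodes merge by CURIE with their source sets unioned; edges
   deduplicate on (subject, predicate, object, source) so the same
   assertion from two services remains two provenance-stamped edges.
   Per-segment answer rows are stitched by a relational join on the
   shared alias, giving one row per complete path binding.

Post-query views mirror an interactive explorer's controls: an
edge-weight range filter (absent weights pass as 1.0), a node-connectivity
range filter computed on the pre-filter graph, a knowledge-source
allow-list, a deterministic tabular answer view, JSONPath variable
extraction, and a named-graph store.

The package ships two fixture federations (a clinical cohort service and
a curated linkage service, with distractor content), a seeded
random-federation generator, and a brute-force path-enumeration oracle
used to test the engine's answer semantics.

## Worked example

```r
library(kgql)

fed <- build_use_case(1)              # cohort + linkage fixture federation
res <- run_program(fed$query_text, fed$registry)
glance(res$message)
#> # A tibble: 1 × 4
#>   n_nodes n_edges n_answers n_sources
#>     <int>   <int>     <int>     <int>
#> 1      18      17        13         2

to_table(res$message)[, c("disease", "gene", "chemical_substance")]
#> # A tibble: 13 × 3
#>    disease                             gene          chemical_substance
#>  1 ovarian cancer (FIX:ovarian_cancer) PTH (FIX:PTH) adenine (FIX:uc1_chem_06)
#>  2 ovarian cancer (FIX:ovarian_cancer) PTH (FIX:PTH) calciol (FIX:uc1_chem_10)
#>  3 ovarian cancer (FIX:ovarian_cancer) PTH (FIX:PTH) calcitriol (FIX:uc1_chem_01)
#>  ...                                   ...           ...
#> 13 ovarian cancer (FIX:ovarian_cancer) PTH (FIX:PTH) vitamin D (FIX:uc1_chem_03)
```

The 13 answer rows are the complete cohort → ovarian cancer → *PTH* →
chemical pathway set: the cohort service asserts that ovarian cancer is
differentially diagnosed by sex, the linkage service connects it to the
parathyroid-hormone gene, and *PTH* to 13 chemical substances (calcitriol,
calcium atom, vitamin D, …, cinacalcet). `n_sources = 2` records that the
merged graph preserves both services' provenance; the shared disease node
carries both source names. The same machinery is available from the shell
via `inst/cli/kgql run <query.tql> --registry <registry.yaml> --out …`.

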