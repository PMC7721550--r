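---
title: "Federated knowledge-graph querying: the model behind kgql"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated knowledge-graph querying: the model behind kgql}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgql)
```

## The problem and the model

Biomedical knowledge services expose subject–predicate–object assertions
over typed entities, but no single service covers a whole translational
question. `kgql` treats a question as a *linear concept path*
$c_1 \xrightarrow{p_1} c_2 \xrightarrow{p_2} \cdots \xrightarrow{p_{n-1}} c_n$
over a hierarchical vocabulary, decomposes the path across services
according to what each advertises it can answer, and merges the partial
answers back into one graph. The linearity restriction is deliberate:
it keeps planning a left-to-right scan, answer propagation a single
frontier of node identifiers, and answer stitching an ordinary relational
join. Branching or cyclic query graphs are out of scope.

Three data structures carry the whole pipeline:

* a **concept model**: two single-inheritance trees, one for entity
  concepts rooted at `named_thing`, one for predicates rooted at
  `related_to`. Subtype tests (`is_subtype()`) are reflexive and
  transitive chain walks.
* a **message**: `query_graph` + `knowledge_graph` + `knowledge_map`, the
  envelope exchanged with every source. The knowledge map is the answer
  binding — one row per complete instantiation of the query template.
* a **federated schema**: the union of per-source transition maps, i.e.
  tuples (source concept, target concept, predicate, service).

## Semantics of matching

One compatibility rule is used everywhere — by the planner, by the
fixture sources, and by the test oracle — so that the three agree by
construction on *what counts as a match*, while their *implementations*
stay independent:

* **concepts**: bidirectional subtype compatibility. A query node typed
  `disease` accepts a node or transition typed `genetic_condition` (more
  specific) and one typed `named_thing` (more general). Endpoints
  advertise at different granularities; a one-directional rule would
  silently drop coarser services.
* **predicates**: the same rule on the predicate tree; an unlabeled hop
  is a wildcard.
* **direction**: edges are stored directed (subject → object) but are
  traversable in either direction during matching, and node degree is
  undirected (a self-loop counts twice). The fixture services assert
  gene → disease edges while queries ask disease → gene; requiring
  orientation agreement would make path phrasing depend on curation
  conventions.

## Planning

Each query edge is matched against the schema; the services able to
serve it are its candidates. Segmentation is greedy with two documented
tie-breaks: a service that can extend the current segment is preferred
(maximal coalescing, which minimizes service invocations), and among new
candidates the lexicographically smallest service name wins. Ties must
break deterministically because the cache and the test suite both rely
on identical inputs producing identical plans. One service is chosen per
edge even when several qualify; fanning a step out to all capable
services and unioning the results is a coherent alternative semantics,
but it interacts badly with per-segment answer propagation and is left
as an extension.

Planning only happens for the reserved service reference `"/schema"`. A
concrete reference (`from "/robokop"`) bypasses planning and sends the
whole path to that service — the abbreviated-name escape hatch.

## Execution and provenance

Segments run in order behind a single source contract: a name, a
transition map, and `invoke(fragment, options)`. Responses are validated
before merging — referential closure, every fragment alias bound, node
concepts compatible with the fragment, pins respected, and every edge
stamped with the invoking service's name. A violating response is
quarantined as a federation error rather than silently merged; with
federated sources the response is the untrusted input.

The node identifiers bound at segment *i*'s last alias become pins on
segment *i+1*'s first query node. An empty upstream answer set
short-circuits the run: an empty cohort is a legitimate answer, not an
error, and downstream services are not invoked.

Merging unions nodes by CURIE (source sets unioned, the most specific
compatible concept kept, attributes last-writer-wins with displaced
values retained under an `attribute_provenance` audit entry) and
deduplicates edges on (subject, predicate, object, source) — identical
assertions from two services deliberately remain two edges, because
per-source provenance is the point. Answer stitching is a natural join:
partners must agree on *every* alias both segments bind, which reduces
to the single join alias for ordinary plans and makes merging a message
with itself idempotent.

## The query cache

Results are cached under the SHA-256 of the raw query text, with no
normalization: any textual change, including whitespace, circumvents the
cache. The cache stores the merged but *unfiltered* message; filters are
cheap per-view operations and callers may re-filter one cached result
many ways. Disabling the cache stops serving and storing but keeps
entries; clearing empties them.

## Filters and views

The three structural filters mirror an interactive explorer's controls
and are applied in a fixed order — weight, connectivity, source:

* **edge weight** in $[0,1]$; an absent weight passes as $1.0$. Most
  curated assertions carry no weight, and they must survive default
  settings. The $[0,1]$ scale itself is an assumption; sources supply no
  weight semantics, and a bounded range is what a range control needs.
* **connectivity**: node degree computed on the *pre-filter* graph, so
  the weight and connectivity filters commute in their read phase and
  the result does not depend on evaluation order.
* **source allow-list**: empty means all. Nodes that merely become
  isolated are kept; only the connectivity filter removes nodes.

Answer rows that reference any removed node or edge are dropped rather
than re-bound, so every surviving row remains verifiable against the
filtered graph, and the filtered message always passes full validation.
Tightening any range can only remove elements (monotonicity), which the
test suite asserts on generated messages.

## The query language

The grammar is a deliberate reconstruction, small enough to state in
full:

```
program     := statement+
statement   := SET ident '=' value
             | SELECT concept[':' alias]
                 (('->' | '-[' predicate ']->') concept[':' alias])*
               FROM string
               (WHERE constraint (AND constraint)*)?
               (SET (string AS)? ident)?
             | CREATE GRAPH ident AT string FROM ident
constraint  := ident ('.' ident)* ('=' | '<' | '>' | '<=' | '>=' | '!=') value
value       := string | number | $ident
```

Keywords are case-insensitive, `#` starts a line comment, `$name`
references must be assigned earlier, and `AND` is the only connective —
constraint lists are conjunctive. Constraints are classified at compile
time: an alias with `=` pins node identifiers, a dotted name whose
prefix is a declared service becomes a service-scoped option forwarded
with that service's invocation, and anything else is a deferred result
filter. The embedded `select … set` form binds either a JSONPath
extraction over the canonical message serialization or, with no path,
the whole knowledge graph. The JSONPath evaluator implements the subset
the language exercises — root, child, quoted child, wildcard, and
(zero-based) index steps — and returns an empty match list rather than
erroring on absent members. Every lexical, syntax, and compile error
carries a 1-based line/column position.

The pretty-printer emits a normal form (one statement per line,
lower-case keywords) chosen so that `parse(print(ast))` reproduces the
AST exactly; this round trip is property-tested on 500 generated
programs.

## Serialization

Messages serialize to a canonical JSON dialect: alphabetically ordered
keys, nodes sorted by id, edges by (subject, predicate, object, source),
answer rows deduplicated and sorted by their bound identifiers, full
numeric precision. Canonical bytes are what make the cache-transparency
and round-trip guarantees testable as byte equality. The dialect is this
package's own, modeled on the message = query graph + knowledge graph +
bindings pattern of federated biomedical APIs; cross-version
compatibility with any external API standard is a non-goal, as is
identifier harmonization — a CURIE is an opaque verbatim key.

## What the fixtures emulate — and what they do not

`build_use_case(1)` and `build_use_case(2)` encode two published
federated pathways: a clinical cohort service asserting differentially
diagnosed diseases (by sex, and by rural/urban residence) and a curated
service linking one of those diseases to a gene and that gene to a
printed list of chemicals (13 and 17 respectively). Identifiers are
synthetic (`FIX:` prefix) because the sources print names, not CURIEs;
labels carry the published names verbatim so tests compare label sets.
Both shards contain distractors — diseases with no downstream gene
links, gene–phenotype and disease–chemical edges off the canonical
path — so the worked-example tests cannot pass by returning everything.
The fixtures do not attempt the cohort statistics (p-values, feature
tables) behind the clinical service's assertions; the `icees.*` options
in the canonical queries are representative parameters, transmitted and
recorded but not interpreted by any fixture.

`random_federation(seed, …)` generates structurally valid federations:
concepts drawn from a mutually incomparable pool, a guaranteed-connected
transition chain plus random extras, each unordered concept pair
assigned to exactly one source, at least one realized edge per
transition, and edge weights uniform on $[0,1]$. The single-source-pair
restriction is what makes the planner's choice provably unique, so the
oracle-equivalence suite tests stitching and propagation, not tie-break
luck. None of this models the statistics of real knowledge graphs
(degree distributions, predicate frequencies, identifier overlap
patterns); a green equivalence suite shows the engine's relational
semantics are correct, not that real endpoints will return biologically
sensible answers.

The brute-force oracle enumerates all matching node sequences by
recursive search over the union graph — an intentionally naive,
separate implementation of the same matching semantics, exponential in
path length and used only at test sizes.

## Problem sizes and numerical choices

The test suite runs the oracle equivalence on 200 seeded federations of
up to 3 sources, 8 concepts, and 5 nodes per concept with 2–4-hop
queries; the parser round trip on 500 programs; and the scale smoke on a
2-source federation of 8,000 nodes per concept and edge density
$3\times10^{-4}$, which yields a merged answer graph above 20,000 nodes.
These sizes were chosen as the smallest that exercise every code path
meaningfully. There are no floating-point tolerances anywhere: every
comparison in the engine is on identifiers, names, or exact counts, and
weights are only ever compared against user-supplied bounds.

Degenerate inputs are defined rather than rejected where a meaning
exists: the empty message envelope has an empty query graph; a
single-node query is answered by concept matching alone; an unknown
JSONPath member yields an empty list; storing a named graph under an
existing name overwrites with a warning.

## Known limitations

Linear paths only; one service per edge; no identifier harmonization
across sources (the same entity under two CURIEs merges as two nodes);
no cost-based planning, retries, or authentication in the bundled HTTP
adapter (which exists for live use but is excluded from the test suite);
and the packaged vocabulary is a ~15-concept stand-in for a full
upper-level ontology, sufficient for the bundled federations and tests.
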