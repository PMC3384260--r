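---
title: "Composing biological events: model, rules, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composing biological events: model, rules, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioscope)
```

## The model

`bioscope` extracts biological events from text in two phases. The first
phase builds a *general* semantic interpretation; the second constrains it
to a shared-task annotation scheme. Nothing in the first phase knows about
event definitions or role inventories — that separation is the point of the
design: the linguistics is reusable, the task adaptation is a handful of
small rule tables.

**Predications.** The unit of meaning is the *predication*: a predicate
(a trigger word bound in a dictionary) with a scalar modality value
`mv ∈ [0, 1]`, a polarity (`positive`/`negative`/`neutral`) and ordered
logical arguments (one Object, one Subject, any number of Adjuncts). An
*atomic* predication takes only ontologically simple arguments — entity
mentions or semantically free tokens, which we treat as entities of unknown
type. An *embedding* predication takes at least one other predication as an
argument; causation, speculation, temporal linkage and saliency all live at
this layer. The `mv` value expresses how strongly the predication holds on
a context-dependent modal scale: 1 is the strongest association, 0 is
negative association, and intermediate values encode hedging ("may",
"presumably").

**The embedding graph.** Per-sentence syntactic dependency parses (in the
collapsed representation with conjunct propagation) are transformed into a
document-level directed acyclic graph whose nodes are *surface elements*
(tokens or collapsed multi-token units) and whose uppercase-labelled arcs
point in the direction of *semantic* dependency. Five transformation
classes produce it, applied in a fixed order:

1. **corrective** — repairs systematically misparsed modifier coordination
   (`Tat and Sp1 proteins`) into an explicit conjunction node;
2. **collapse** — merges multi-token entity and trigger mentions into one
   semantically bound node, merging their parallel dependencies;
3. **split** — rewrites coordination dependencies into `CC` arcs from a
   conjunction node to each conjunct, and redirects external arcs pointing
   at a conjunct to the conjunction node;
4. **inversion** — switches the direction of modifier-like dependencies
   (`amod`, `advmod`, `aux`, `neg`, `det`, ...) whose dependent
   semantically embeds its governor. When several inverted modifiers share
   a governor they are *chained in surface order* (`Thus > may > not >
   involve`), which is the only reading that reproduces the worked modal
   chains; this chaining is our decision, stated here because the source
   analyses print only the resulting relations;
5. **identity** — any remaining dependency passes through with its label
   uppercased, since many dependencies are already isomorphic to embedding
   relations.

The engine is data-driven: the inversion label set and the coordination
label prefix are options of `graph_options()`, so further hand-crafted
rules can be added as configuration rather than code. Adjacent sentences
are linked by `PREV` arcs between their topmost nodes, and coreference adds
`COREF` arcs; both enable inter-sentential event participants.

**Composition.** The graph is traversed children-first. At each
trigger-bound node, argument identification rules — typed 4-tuples
⟨relation, POS, inclusions, exclusions⟩ → {Object, Subject, Adjunct} —
assign the node's children to logical argument slots. The constraint
semantics is `(inclusions empty or satisfied) and not(exclusions
satisfied)`, testing the predicate's lemma or semantic type; the published
form of this constraint would make a non-empty inclusion list vacuous, so
we implement the reading its rule table evidently intends. *Argument
propagation* lets a bound descendant serve as an argument when every node
on the path below the licensed child is semantically free; valence-shifter
tokens count as transparent on such paths (otherwise a modal could never
reach the predication below its negator). When a slot resolves to a
conjunction node or a plural anaphor, the predication is *distributed*:
one copy per conjunct, all other slots shared.

Every predication initializes with `mv = strength × 1.0` (atomic triggers
default to strength 1, hence `mv = 1`) and with polarity composed from the
trigger's dictionary polarity and the embedded predication's polarity:
neutral passes the embedded value through, negative is absorbing, positive
flips to negative only over a negative embedded value. This single
initialization rule reproduces every modality value printed in the worked
analyses (assumptive 0.7, demonstrative 1.0, correlative 0.5, ...).

**Modality operators.** `MODAL` and valence-shifter nodes *percolate* onto
the nearest predication(s) below them in the graph, innermost operator
first:

* a NEGATOR inverts `mv ← 1 − mv`, forces negative polarity and marks the
  predication negated;
* a MODAL with category strength *s* applies `mv ← s·mv` when `mv ≥ 0.5`
  and `mv ← mv + (1 − s)(1 − mv)` otherwise — hedging a positive claim
  lowers it, hedging a negated claim raises it off the floor
  (`may not involve`: 1 → 0 → 0.3 at strength 0.7);
* a DIMINISHER applies the same two-branch formula; an INTENSIFIER applies
  the mirror image, pushing values away from the scale midpoint. The exact
  numeric effect of diminishers/intensifiers is a design decision of this
  package — the source analyses exhibit the phenomenon but not a formula —
  and the symmetric treatment keeps all operators within one algebra.

"Nearest predication(s) below" is likewise our resolution of an
underdetermined point: when modals stack non-adjacently, each operator
updates only the closest predication-bearing node(s) in its subtree, and
operators apply innermost-first. *Negative raising* predicates (`think`,
`believe`) transfer a negator attacking them onto their complement
predication, leaving their own `mv` untouched.

All operators clamp to `[0, 1]` as a safety net; tests sweep random
operator chains to confirm the bound is never active except at the
boundaries.

## Coreference

Four deterministic anaphora classes add `COREF` arcs:

* **RELAT** — `REL(X, RP)` with `RCMOD(ANT, X)` links a relative pronoun
  to the NP head its clause modifies;
* **APPOS** — appositions, abbreviations and `including`/`such as`
  constructions corefer symmetrically; the later element is normalized to
  be the anaphor;
* **PRON** — third-person personal/possessive pronouns only, with number
  agreement;
* **DNP** (sortal anaphora) — definite/demonstrative NPs not bound to an
  entity, with number agreement plus at least one of: head-word identity,
  singular hypernymy (`this protein` ← any protein entity), plural
  hypernymy over a conjunction of entities (`these factors` ← `CD1, CD2,
  and CD3`), meronymy (`the dimer` ← a conjunction or a slash-compound),
  or the event constraint (anaphor and antecedent lexicalize the same
  event type; implemented as same dictionary type plus a shared lemma
  stem, deliberately narrow).

Candidates are prior nodes in the paragraph that are semantically bound,
hypernym heads, or conjunction nodes; the *closest* compatible, unblocked
candidate in the undirected graph (intra-sentential + `PREV` arcs) wins,
with token distance and then earlier offset as tie-breaks — the distance
metric is our choice, since "closest in the graph" admits several
readings. Structural blockers: direct embedding between the pair;
subject-antecedent with object-anaphor of the same predicate unless the
anaphor is reflexive; subject-antecedent with adjunct-anaphor. Plural
anaphora over a conjunction fan out into one arc per conjunct, which is
what makes distributed events (`their expression` → one event per protein)
fall out of ordinary argument resolution. The shipped hypernym defaults are
the four heads named in the source description (`gene`, `protein`,
`factor`, `cytokine`); corpora induce larger lists, so the lexicons are a
parameter (`compat_lexicons()`), and fixtures that need `receptor`-like
heads pass an extended list explicitly.

## Mapping to task annotations

Embedding predications convert to event or modification types through a
constraint table over track, type, polarity and modality value (e.g.
CAUSAL+neutral → Regulation; SUCCESS+negative → Negation; SPECULATIVE with
`mv > 0` → Speculation). The published core of that table is knowingly
partial; the shipped file extends it (rows marked `extension`) with the
mappings the worked analyses imply — CAUSAL±polarity to
Positive/Negative_regulation, assumptive/epistemic speculation, and a
Negation modification for events whose predication was negated. Logical
arguments map to semantic roles (Object → Theme, Subject → Cause, with the
Binding, Process and Scope exceptions), and pruning then drops
non-conforming participants, semantically free participants, unmappable
predications (DEONTIC, TEMPORAL, attributives after their arguments
transfer to the embedded predication), and events missing a mandatory
participant — except Process, which may take no participants at all —
cascading until a fixed point. Speculation/Negation modifications attach to
the nearest *mapped* event(s) within the modal's scope; when several are in
scope each receives one, a fan-out the source leaves unstated.

One known representational tension: distributing a predication over n
conjuncts yields n single-Theme events, while one worked binding analysis
prints a single two-participant event over a coreferent conjunction. The
distribution semantics is consistent with the other worked analyses and is
applied uniformly here.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `strength` (per lexicon entry) | 1.0 | category strength in [0, 1]; scales `mv` on initialization and percolation |
| `propagation_depth` | `Inf` | free nodes an argument may propagate through; 1 trades recall for precision |
| `coref_classes` | all four | which anaphora classes run; mirrors the ablation design |
| `compat_lexicons()` | 4 hypernyms, 5 meronyms | sortal-anaphora compatibility vocabulary |
| `graph_options()$invert_labels` | 10 labels | dependency labels treated as semantic-direction inversions |

## What the fixtures emulate — and what they do not

The built-in cases (`builtin_cases()`) encode the worked examples as
standoff text + entities + dependency parses, with parses transcribed
where printed and minimally authored otherwise (all marked `authored`).
The random-graph generator (`random_graph()`) produces tree-shaped
embedding graphs of up to 12 nodes with random bindings, operators and
rule-licensing arcs, and the composer is checked against an independent
recursive evaluator (`compose_oracle()`) over 1000 seeds, plus a sweep at
propagation depth 1. Problem sizes — 19 fixture documents of 1–2 sentences
and 3–12-node random trees — were chosen because the semantics under test
is per-sentence and per-chain; nothing in the algebra grows with corpus
size.

Passing these tests shows the *rule algebra* is implemented faithfully. It
does not show corpus-level extraction quality: real parses are noisy in
ways the fixtures are not, the shipped seed lexicon is far smaller than a
corpus-derived dictionary, paragraph segmentation of full-text articles is
not exercised, and non-core participants (Site, ToLoc) are out of scope
entirely. The generator also omits coordination and coreference (those are
covered by the worked-example fixtures, not the random sweep) and
negative-raising triggers (covered by a dedicated fixture).

## Numerical and procedural choices

* Character offsets are 0-based, half-open, matching the standoff formats.
* Traversal order is a deterministic reverse-topological order with ties
  broken by character offset, so predication identifiers and all outputs
  are reproducible run to run; output files are byte-identical across
  runs.
* A coreference antecedent can sit higher in the graph than its anaphor;
  such antecedents are composed on demand with a re-entrancy guard that
  degrades pathological mutual references to free arguments instead of
  looping.
* Cycles introduced by transformation artifacts are broken by dropping the
  arc whose dependent has the latest character offset, with a warning; the
  composed predication graph is asserted acyclic afterwards.
* Greedy longest-first, left-to-right matching for multi-word triggers is
  our policy (the source allows multi-word triggers "to some extent"
  without stating one); the matcher is verified against an exhaustive
  segmentation oracle on short inputs.
* Ambiguous trigger counts resolve to the maximum-likelihood event type
  with a lexicographic tie-break (`assign_types_mle()`), and all-zero
  triggers are excluded.
* Events that become indistinguishable after distribution (same type,
  trigger and roles) are deduplicated before serialization.

## Known limitations

Determiner-based negation (`no NF-κB bound ...`) inverts the graph
direction correctly but the negator then scopes over an entity rather than
a predication, so the negation is not propagated to the event — the same
failure mode the source reports for the minus-sign idiom (`CD14- surface
Ag expression`). Copular constructions are not given embedding status.
Quantifiers over anaphors (`any of these receptors`) are ignored, faithfully
reproducing a known class of false positives. Event coreference beyond the
narrow event constraint, cataphora, and statistical antecedent ranking are
non-goals.
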