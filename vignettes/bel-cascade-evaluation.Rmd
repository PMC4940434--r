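---
title: "Cascade evaluation of BEL statement extraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascade evaluation of BEL statement extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belscore)
```

## The problem

The Biological Expression Language (BEL) encodes causal and correlative
biological findings as triples: a subject term, a relationship type and
an object, e.g. `p(HGNC:TIMP1) =| act(p(HGNC:MMP9))` — the TIMP1
protein directly decreases the molecular activity of MMP9. Text-mining
systems that generate BEL statements from literature evidence produce
output that is structured, partially correct, and hard to score with a
plain right/wrong comparison: a system may identify both entities but
miss the direction of the effect, or recover the causal triple while
omitting an activity function. `belscore` implements an evaluation
scheme built for this situation: statements are normalized by a set of
deliberate simplifications, decomposed into fragments at several
structural levels, and scored with micro-averaged precision, recall and
F-measure at each level, so partial correctness earns partial credit.

## The restricted grammar

The sublanguage accepted here is the restricted evaluation subset of BEL, not the
full language. Statements have the shape

```
fterm  REL  fterm | ( statement )
```

where a *fterm* is either a plain term `fn(NS:value[,pmod(...)])` or a
wrapper function over terms, and `REL` is one of `increases` (`->`),
`decreases` (`-|`), `directlyIncreases` (`=>`), `directlyDecreases`
(`=|`) or `association` (`--`). Seven namespaces are admitted, each
with fixed abundance/process functions: `p/g/r/m` for HGNC and MGI,
`p/g/r` for EGID, `bp` for GOBP, `path` for MESHD, `a` for CHEBI, and
the placeholder namespace `PH` (compatible with every function).
Wrapper functions are the activity family (`act`, `kin`, `tscript`,
`cat`), `deg`, `tloc` (whose location arguments are stored verbatim but
never validated — they are discarded at evaluation time anyway),
`complex` (one or more member terms), and the modification `pmod`,
legal only inside protein terms. A nested statement may appear in
object position, at most one level deep; deeper nesting is rejected,
matching the shape of the evaluation corpora.

Parsing decisions worth stating explicitly:

* Namespace prefixes are case-insensitive (canonically upper case);
  entity values, function and relation keywords are case-sensitive.
  Gene-symbol casing is meaningful — `MGI:Mmp9` is a different entity
  key than `HGNC:MMP9` unless an equivalence table says otherwise.
* Both single and double quotes are accepted around values; the
  canonical renderer emits single quotes, only where the value contains
  characters outside `[A-Za-z0-9_.]`. Unicode typographic quotes and
  dash variants are normalized to ASCII before tokenization, because
  real submissions (and typeset examples) contain them.
* `complex()` with a single member is accepted: the partial-credit rule
  for complexes ("one correct member suffices") implies partial
  complexes are legitimate predictions.
* The validator never throws; it returns every violation found in one
  pass, with character offsets, so a submission file can be repaired in
  one round.
* One open point in the function/namespace table was resolved
  literally: EGID admits `p/g/r` only, so `m(EGID:...)` is rejected.

## Evaluation simplifications

All comparisons are made on simplified statements
(`bel_simplify()`); the four rules make the evaluation liberal where
gold annotations carry more detail than evidence text can support:

1. **Entity mapping.** Entities are replaced by canonical keys from an
   equivalence table (`bel_read_equivalences()`), so that cross-species
   or cross-vocabulary identifiers (MGI, EGID vs HGNC) score as equal.
   The mapping applies to the `(namespace, value)` pair, not the whole
   term, so `p()`/`g()`/`r()` distinctions survive — the term level
   scores the abundance function too. Without a table the mapping is
   the identity; an optional off-by-default heuristic upper-cases MGI
   symbols into HGNC. The official equivalence resources are external
   downloads, and the package must run self-contained.
2. **Activity collapsing.** `kin`, `tscript`, `cat` become `act`:
   recognizing *some* molecular activity is credited, the subtype is
   not required.
3. **Argument stripping.** `pmod(P,S,15)` becomes `pmod(P)` (residue
   and position dropped); `tloc` loses its location arguments.
4. **Direction merging.** `directlyIncreases`/`directlyDecreases` are
   treated as `increases`/`decreases`.

Two canonicalization choices go beyond the stated rules and are this
package's own: `complex()` members are compared as **sets** (members
sorted lexicographically at simplification), and the symmetric
`association` relation has its two arguments put in lexicographic
order. Whether the original evaluation service ordered complex members
is not documented; set semantics is the defensible reading of a complex
as an unordered collection, and the JSON report header flags it.
Simplification is idempotent, and never changes the number of terms or
any placeholder flag.

## The cascade levels and matching

Each simplified statement is decomposed (`bel_fragments()`) into:

| level | fragment |
|---|---|
| term | every contained term, modifications stripped |
| function (primary) | wrapper with arguments, e.g. `act(p(MGI:Hras))`; `pmod` keyed to its host term as `pmod(P)@p(HGNC:RB1)` |
| function (secondary) | the bare function name |
| relation (primary) | the triple with all functions except `complex` discarded |
| relation (secondary) | the same triple, scored two-of-three |
| full | the whole canonical statement |

`pmod` primary fragments carry their host term because a function is
only evaluable together with its argument, and for a modification the
host term *is* the argument.

Matching (`bel_match_level()`) proceeds per evidence text over fragment
multisets, in deterministic phases:

1. **Exact phase** — canonical-key equality, per-key count minima.
2. **Partial phase**, strongest predicate first, among non-placeholder
   predictions: at the function level a `complex()` matches on at least
   one shared member; at the primary relation level all three triple
   components must match, a `complex()` side matching on member
   intersection; at the secondary relation level all-three matches are
   consumed first, then two-of-three, then the association special case
   (below). Ties break by input order: gold fragments in order, first
   unmatched prediction. One prediction earns at most one true
   positive.
3. **Placeholder phase** — remaining placeholder-bearing predictions
   are wildcard-paired to leftover gold fragments *for the report
   only*: they contribute neither a true nor a false positive, and the
   paired gold fragment still counts as a false negative.
4. Remaining non-placeholder predictions are false positives, remaining
   gold fragments false negatives.

The strongest-first ordering within phase 2 is a deliberate refinement
of a single relaxed greedy pass: a loose two-of-three match may
otherwise consume a prediction that an all-three match needs, which
would let a primary-level true positive lack its secondary counterpart
and break the cascade's monotonicity (every primary TP implies a
secondary TP; a full-statement TP implies a relation TP). With the
ordering, monotonicity holds by construction, and the property suite
verifies it on a thousand generated corpora.

**Placeholder semantics.** `PH:placeholder` entities and the
`association` relation let a system submit a syntactically complete
statement while admitting ignorance. They influence recall only: a
placeholder-bearing prediction is never a false positive, and never a
true positive either — with one exception. An `association` prediction
whose subject and object are both correct scores a true positive at the
secondary relation level (the relation type was the only unknown, and
two components are correct); with only one correct argument it falls
back to placeholder treatment (false negative, no false positive). A
triple whose *entity* is a placeholder never scores even when the other
two components match: crediting it would let placeholders raise
precision, which contradicts their purpose. This is the one point where
the two-of-three wording and the placeholder rule collide, and the
placeholder rule is given precedence here.

Counts are summed over evidence texts and micro-averaged:
P = TP/(TP+FP), R = TP/(TP+FN), F = 2PR/(P+R), with the 0-denominator
conventions P = R = F = 0. Reported percentages round **half-up** to
one decimal (`bel_percent()`), the convention of the published tables
(316/806 prints as 39.2%); R's own banker's rounding would differ on
ties. Statements that fail validation are recorded as rejected and
excluded: their gold counterparts simply remain false negatives, never
false positives.

A second, independent matcher (`bel_oracle_match()`) evaluates the
matching predicates into explicit gold-by-prediction boolean matrices
and consumes them in the same documented order. It shares no matching
code with the phase-based implementation and serves as the reference
for both the test suite and the expected counts attached to synthetic
corpora.

## Ranked retrieval evaluation

For evidence retrieval, each BEL statement is a query with up to 10
judged evidence texts (longer candidate lists are truncated; evidences
longer than two sentences are discarded at load, as they were never
judged — the sentence count is an explicit input column, not computed
by sentence splitting). Relevance labels are nested: `full` (the
statement is entirely expressed) implies `relaxed` (extractable with
context) implies `context` (entities and some relation present).

Average precision of one ranked list is the mean, over the ranks
holding relevant items, of precision at that rank; a list with no
relevant item scores 0. MAP is the unweighted mean of AP over
statements. Statements with zero relevant evidences are **included**
with AP = 0 by default: excluding them would reward a system for
retrieving nothing on hard queries. An `exclude` mode is provided since
the original convention is not documented. Micro precision (total
relevant over total judged) is permutation-invariant; MAP is not, so
three reference rankings bound it: worst (relevant items last — the
provable minimum), best (relevant items first — the maximum) and random
(MAP averaged over 2000 uniform reorderings per list by default). Each
list gets its own RNG substream derived from the one user seed, so
results are bit-reproducible and independent of list order.

## The synthetic generator

Real gold corpora for this task are not redistributable, so the package
generates its own (`bel_sample_corpus()`). The generator draws from the
restricted grammar with the class proportions of the task's training
corpus as defaults: 87% of terms are proteins, 69% of function wrappers
are activities, 73% of relations express an increase. The residual
mass is spread over the remaining classes in fixed ratios chosen to
touch every grammar production (processes, pathologies, chemicals,
genes/RNA; complexes, degradation, translocation, modifications), with
roughly 45%/25% of subjects/objects carrying a wrapper and a fifth of
directed relations written in their `directly*` form — values in the
range a curated causal-statement corpus exhibits, fixed once here.
Entity identifiers come from small built-in pools that include the
symbols of the published grammar examples, so generated corpora stay
human-readable.

Predictions are derived by perturbation operators (`bel_perturb()`):
entity swaps, relation flips, function drops/changes, placeholder
insertion, statement omission and spurious additions. Each gold
statement receives at most one operator, so operators act on disjoint
subsets; expected per-level confusion counts for the resulting pair are
computed with the reference matcher, not the production scorer, giving
end-to-end tests an independent ground truth.

What the generator does *not* emulate: natural-language evidence (there
are no sentences, only statement/evidence identifiers), realistic
vocabulary sizes (pools are small, so repeated entities within an
evidence are common — which usefully exercises multiset matching), and
annotator disagreement. Passing the property suite therefore
demonstrates the scorer's correctness on well-formed input at corpus
scale, not extraction quality on real text.

## Numerical and testing choices

* Determinism everywhere: corpus generation, perturbation and the
  random MAP bound take explicit seeds; repeated runs are identical.
* The property suite runs 1000 single-evidence corpora for the scoring
  invariants (TP+FN equals the gold fragment count at every level,
  cascade monotonicity, placeholder neutrality), 120 corpora of up to
  five statements per evidence for the matcher/reference-matcher
  equivalence, and 500 judgment sets for the MAP bound ordering, with
  the Monte-Carlo random bound checked against exact permutation
  enumeration on lists of up to six items. These sizes keep the suite
  in the low minutes while exercising every matching pass; they are
  stated here so a reader can scale them up.
* `scripts/acceptance.R` re-derives the headline numbers from scratch
  at every run — nothing in the package stores a result.

## Known limitations

* Only the restricted sublanguage is parsed: no annotations, evidence
  blocks, `SET` statements, or the full namespace catalogue of standard
  BEL.
* Whether the original service flattened nested-statement objects
  further, capped predictions per evidence, or wildcarded whole missing
  branches at the full-statement level is undocumented; this package's
  choices (canonical nested string as the object component, no cap,
  wildcarding only `PH` entities and `association`) are fixed and
  visible in the report output.
* The equivalence machinery ships with an identity fallback, not the
  official cross-namespace resources; scores involving cross-species
  entity mentions will differ from an evaluation run with the full
  equivalence tables unless one is supplied.
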