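# belscore

Scoring machinery for causal-relation extraction from biomedical text,
expressed in the **Biological Expression Language (BEL)**. BEL encodes
biological findings as subject–predicate–object statements such as

```
p(MGI:Cav1,pmod(P)) -> a(CHEBI:'nitric oxide')
```

("phosphorylated Cav1 protein increases the abundance of nitric oxide").
Systems that extract such statements from literature are rarely entirely
right or entirely wrong: they may name the right proteins but the wrong
relation, or recover the relation but miss a molecular-activity
function. `belscore` implements a **cascade evaluation** that gives
partial credit at successive structural levels, plus the companion
evaluation for ranked evidence retrieval. It is aimed at developers of
biomedical relation-extraction systems and at anyone re-running or
auditing such evaluations offline.

## What it does

* **Grammar** — tokenizer, recursive-descent parser, validator and
  canonical renderer for the restricted BEL sublanguage over the
  namespaces HGNC, MGI, EGID, GOBP, MESHD and CHEBI (plus the
  `PH:placeholder` dummy namespace), the abundance/process functions
  `p, g, r, m, a, bp, path`, the wrapper functions
  `act/kin/tscript/cat, deg, tloc, complex, pmod`, and the relations
  `-> , -| , => , =| , --`. Long forms (`proteinAbundance`,
  `increases`, ...) are interchangeable with short forms.
* **Simplification** — the evaluation normal form: entity equivalence
  mapping (e.g. mouse/EGID identifiers onto HGNC), `kin/tscript/cat`
  collapsed to `act`, `pmod` reduced to its modification type, `tloc`
  locations dropped, `directly*` relations merged with their plain
  forms.
* **Cascade scorer** — per evidence text, gold and predicted statements
  are cut into fragments and matched at six levels: terms, functions
  (primary: with arguments; secondary: bare names), relationship triples
  (primary: all three components; secondary: two of three) and full
  statements. Counts are micro-averaged into precision P = TP/(TP+FP),
  recall R = TP/(TP+FN) and F = 2PR/(P+R). Placeholder predictions
  (`PH:placeholder` entities, the `association` relation) count as
  false negatives but never as false positives, so they affect recall
  only.
* **Ranked retrieval scorer** — average precision
  AP = mean over relevant ranks r of (#relevant in top r)/r, mean
  average precision over statements under nested relevance criteria
  (full ⊂ relaxed ⊂ context), and worst / random / best reranking
  bounds (the random bound averages MAP over 2000 seeded reorderings by
  default).
* **Synthetic generator** — grammar-driven corpora with the training
  distribution of the task (87% protein terms, 69% activity functions,
  73% increase relations) and controlled prediction perturbations whose
  expected confusion counts are computed by an independent reference
  matcher.

## Worked example

```r
library(belscore)

gold <- data.frame(evidence_id = "ev1", text = "act(p(MGI:Hras)) -> p(MGI:Mmp9)")
pred <- data.frame(evidence_id = "ev1", text = "p(MGI:Hras) -> p(MGI:Mmp9)")
bel_report_table(bel_score_corpus(gold, pred))
#>                level tp fp fn precision recall   f
#> 1               term  2  0  0       100    100 100
#> 2           function  0  0  1         0      0   0
#> 3 function_secondary  0  0  1         0      0   0
#> 4           relation  1  0  0       100    100 100
#> 5 relation_secondary  1  0  0       100    100 100
#> 6               full  0  1  1         0      0   0
```

The prediction names both terms correctly (term level 100%), and since
functions are discarded at the relationship level the triple
`p(MGI:Hras) increases p(MGI:Mmp9)` also scores; but the missing
`act()` wrapper costs the function level (one false negative) and the
full-statement level (the rendered statement differs: one false
positive, one false negative).

Simplification in action:

```r
bel_render(bel_simplify(bel_parse("cat(p(HGNC:FAS)) => p(HGNC:RB1,pmod(P,S,15))")))
#> [1] "act(p(HGNC:FAS)) -> p(HGNC:RB1,pmod(P))"
```

Ranked retrieval with bounds:

```r
j <- bel_sample_judgments(n_statements = 96, seed = 3)
bel_map_with_bounds(j, "full", n_shuffles = 2000, seed = 4)
#> <bel_ranking_scores> criterion=full TP=247 FP=510 P=32.6% MAP=44.1% (worst 24.2%, random 44.8%, best 85.4%)
```

A submitted ranking always sits between the worst bound (all relevant
items ranked last) and the best bound (all relevant items first); the
random bound says what an uninformative ranking of the same items would
score.

## Command line

The installed `exec/belscore` script exposes the same functionality:

```sh
belscore validate predictions.tsv
belscore task1 --gold gold.tsv --pred predictions.tsv --report report.json
belscore task2-map --judgments judgments.tsv --shuffles 2000 --seed 1
belscore synth --out-prefix toy --seed 1
```

Submissions are two-column TSV (`evidence_id <TAB> statement`);
judgments are five-column TSV (`statement_id`, `rank`, `evidence_id`,
`label`, `sentence_count`). Exit codes: 0 success, 1 validation
failures, 2 usage/I-O errors.

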