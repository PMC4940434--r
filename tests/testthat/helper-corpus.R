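# Shared fixtures and independent oracles used across the suite.

# every example statement printed in the grammar's reference tables
# (relationship table, function table, evaluation-level table) and the
# statement-visualization caption
table_statements <- c(
  "a(CHEBI:'brefeldin A') -| p(HGNC:SCOC)",
  "p(HGNC:TIMP1) =| act(p(HGNC:MMP9))",
  "p(MGI:Bmp4) -> p(MGI:Acta2)",
  "p(HGNC:VEGFA) => act(p(HGNC:KDR))",
  "complex(p(MGI:Itga8),p(MGI:Itgb1)) -> bp(GOBP:'cell adhesion')",
  "p(MGI:Cav1,pmod(P)) -> a(CHEBI:'nitric oxide')",
  "p(MGI:Lyve1) -> deg(a(CHEBI:'hyaluronic acid'))",
  "a(CHEBI:'brefeldin A') -> tloc(p(MGI:Stk16))",
  "complex(p(MGI:Cckbr),p(MGI:Gast)) -> act(p(MGI:Prkd1))",
  "p(HGNC:BCL2A1) -| bp(GOBP:'apoptotic process')",
  "act(p(MGI:Hras)) -> p(MGI:Mmp9)",
  "cat(p(HGNC:FAS)) -> p(HGNC:RB1,pmod(P))"
)

# standalone terms from the namespace table
table_terms <- c(
  "p(HGNC:MAPK14)", "p(MGI:Mapk14)", "p(EGID:1432)",
  "bp(GOBP:'cell proliferation')", "path(MESHD:Hyperoxia)",
  "a(CHEBI:lipopolysaccharide)"
)

# long-form / short-form statement pairs that must parse identically
long_short_pairs <- list(
  c("proteinAbundance(HGNC:MAPK14) increases biologicalProcess(GOBP:'cell proliferation')",
    "p(HGNC:MAPK14) -> bp(GOBP:'cell proliferation')"),
  c("p(MGI:Bmp4) increases p(MGI:Acta2)", "p(MGI:Bmp4) -> p(MGI:Acta2)"),
  c("p(HGNC:VEGFA) directlyIncreases molecularActivity(p(HGNC:KDR))",
    "p(HGNC:VEGFA) => act(p(HGNC:KDR))"),
  c("p(HGNC:TIMP1) directlyDecreases act(p(HGNC:MMP9))",
    "p(HGNC:TIMP1) =| act(p(HGNC:MMP9))"),
  c("geneAbundance(HGNC:TP53) decreases pathology(MESHD:Hyperoxia)",
    "g(HGNC:TP53) -| path(MESHD:Hyperoxia)"),
  c("complexAbundance(p(MGI:Itga8),p(MGI:Itgb1)) increases biologicalProcess(GOBP:'cell adhesion')",
    "complex(p(MGI:Itga8),p(MGI:Itgb1)) -> bp(GOBP:'cell adhesion')"),
  c("proteinAbundance(MGI:Cav1,proteinModification(P)) increases abundance(CHEBI:'nitric oxide')",
    "p(MGI:Cav1,pmod(P)) -> a(CHEBI:'nitric oxide')"),
  c("p(MGI:Lyve1) increases degradation(a(CHEBI:'hyaluronic acid'))",
    "p(MGI:Lyve1) -> deg(a(CHEBI:'hyaluronic acid'))"),
  c("a(CHEBI:'brefeldin A') increases translocation(p(MGI:Stk16))",
    "a(CHEBI:'brefeldin A') -> tloc(p(MGI:Stk16))"),
  c("rnaAbundance(EGID:4318) association microRNAAbundance(HGNC:MAPK14)",
    "r(EGID:4318) -- m(HGNC:MAPK14)")
)

# exact mean AP over all uniform reorderings of a relevance multiset:
# every placement of the k relevant items among n ranks is equally likely
exact_random_ap <- function(flags) {
  n <- length(flags)
  k <- sum(flags)
  if (k == 0L || k == n) return(belscore::bel_average_precision(flags))
  placements <- utils::combn(n, k)
  mean(apply(placements, 2, function(pos) {
    f <- rep(FALSE, n)
    f[pos] <- TRUE
    belscore::bel_average_precision(f)
  }))
}

# total gold fragments at a level of an evidence result must equal tp + fn
gold_fragment_count <- function(texts, level) {
  frs <- lapply(texts, function(tx)
    belscore::bel_fragments(belscore::bel_simplify(belscore::bel_parse(tx))))
  sum(vapply(frs, function(fr) length(fr[[level]]), integer(1)))
}
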