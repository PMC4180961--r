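# frozen values below come from the diamond fixture: corpus {A1},{A2},{B1},{D}
# gives IC(A1)=IC(B)=ln2, IC(A2)=IC(B1)=IC(D)=ln4, IC(A)=ln(4/3), IC(root)=0

diamond_corpus <- function() {
  dag <- toy_dag()
  sets <- list(e1 = "A1", e2 = "A2", e3 = "B1", e4 = "D")
  prop <- propagate(dag, annotation_table("patient", sets))
  list(dag = dag, ic = information_content(dag, prop), prop = prop)
}

test_that("common ancestors match the brute-force intersection", {
  w <- diamond_corpus()
  annot <- w$prop$annotations$e4           # propagated {D,A1,B,A,root}
  expect_true("D" %in% common_ancestors(w$dag, "D", annot))
  expect_setequal(common_ancestors(w$dag, "B1", w$prop$annotations$e2), "root")
  expect_setequal(
    common_ancestors(w$dag, "B1", annot),
    intersect(oracle_ancestors(c("A","B","A1","A2","B1","D","D"),
                               c("root","root","A","A","B","A1","B"), "B1"),
              annot))
})

test_that("phenomatch score reproduces frozen hand computations", {
  w <- diamond_corpus()
  annot <- w$prop$annotations$e4
  expect_equal(phenomatch_score("root", annot, w$ic, w$dag), 0)
  # exact term match scores IC(t)
  expect_equal(phenomatch_score("A1", annot, w$ic, w$dag), log(2))
  # {A1,B1} vs annot: A1 matches itself (ln2), B1's best CA is B (ln2)
  expect_equal(phenomatch_score(c("A1", "B1"), annot, w$ic, w$dag),
               2 * log(2))
  expect_equal(phenomatch_score(character(0), annot, w$ic, w$dag), 0)
})

test_that("phenogram score is the max over genes, 0 when empty", {
  w <- diamond_corpus()
  annot <- w$prop$annotations$e4
  sets <- list(g1 = c("A1", "B1"), g2 = "A2", g3 = "root")
  per_gene <- vapply(sets, phenomatch_score, numeric(1), annot = annot,
                     ic = w$ic, dag = w$dag)
  expect_equal(phenogram_score(sets, annot, w$ic, w$dag), max(per_gene))
  expect_equal(phenogram_score(list(), annot, w$ic, w$dag), 0)
  expect_equal(phenogram_score(sets["g1"], annot, w$ic, w$dag),
               per_gene[["g1"]])
})

test_that("phenomatch equals the oracle exactly on random ontologies", {
  for (seed in 11:20) {
    n <- sample(10:50, 1)
    e <- rand_dag_edges(n, seed)
    dag <- ontology_dag(e$child, e$parent)
    set.seed(seed + 100)
    corpus <- lapply(1:8, function(i) sample(dag$terms, sample(1:4, 1)))
    names(corpus) <- paste0("d", 1:8)
    ic <- information_content(dag, propagate(dag, annotation_table("disease", corpus)))
    oic <- oracle_ic(e$child, e$parent, corpus)
    annot_direct <- sample(dag$terms, sample(1:5, 1))
    annot <- unique(unlist(dag$anc[annot_direct]))
    gene_terms <- sample(dag$terms, sample(1:5, 1))
    expect_equal(phenomatch_score(gene_terms, annot, ic, dag),
                 oracle_phenomatch(e$child, e$parent, gene_terms,
                                   annot_direct, oic),
                 tolerance = 1e-12)
  }
})

test_that("phenomatch monotonicity and self-match bound", {
  w <- diamond_corpus()
  for (seed in 1:10) {
    set.seed(seed)
    gene_terms <- sample(w$dag$terms, sample(1:4, 1))
    base_direct <- sample(w$dag$terms, 2)
    annot <- unique(unlist(w$dag$anc[base_direct]))
    s1 <- phenomatch_score(gene_terms, annot, w$ic, w$dag)
    # adding a term never decreases the score
    extra <- sample(w$dag$terms, 1)
    annot2 <- unique(c(annot, unlist(w$dag$anc[extra])))
    expect_gte(phenomatch_score(gene_terms, annot2, w$ic, w$dag), s1)
    # self-match bound
    expect_lte(s1, sum(ic_upper <- vapply(gene_terms, function(t) {
      v <- w$ic$ic[[t]]
      if (is.null(v) || is.na(v)) 0 else v
    }, numeric(1))) + 1e-12)
  }
})

test_that("gene-term propagation switch is honoured", {
  w <- diamond_corpus()
  annot <- w$prop$annotations$e1           # {A1, A, root}
  direct <- phenomatch_score("A1", annot, w$ic, w$dag)
  prop <- phenomatch_score("A1", annot, w$ic, w$dag, use_propagated = TRUE)
  # propagated closure adds A and root as extra summands
  expect_equal(prop, direct + w$ic$ic[["A"]])
})

test_that("target assignment handles the three statuses", {
  dag <- ontology_dag(c("a", "b", "A", "B"), c("A", "B", "root", "root"))
  targets <- target_term_set(c("A", "B"), c("ta", "tb"), dag)
  prop <- propagate(dag, annotation_table(
    "patient", list(p1 = "a", p2 = "b", tie = c("a", "b"), none = "root")))
  ic <- information_content(dag, prop)
  res <- assign_target_terms(prop, targets, ic, dag)
  expect_equal(res$status,
               c("assigned", "assigned", "ambiguous", "unassigned"))
  expect_equal(res$target[[1]], "A")
  expect_equal(res$target[[2]], "B")
  expect_error(assign_target_terms(annotation_table("patient", list(p = "a")),
                                   targets, ic, dag), "propagated")
})

test_that("target assignment ignores target order", {
  dag <- ontology_dag(c("a", "b", "A", "B"), c("A", "B", "root", "root"))
  prop <- propagate(dag, annotation_table("patient", list(p = c("a"))))
  ic <- information_content(dag, propagate(dag, annotation_table(
    "patient", list(q1 = "a", q2 = "b"))))
  t1 <- target_term_set(c("A", "B"), c("ta", "tb"), dag)
  t2 <- target_term_set(c("B", "A"), c("tb", "ta"), dag)
  a1 <- assign_target_term(prop$annotations$p, t1, ic, dag)
  a2 <- assign_target_term(prop$annotations$p, t2, ic, dag)
  expect_equal(a1$target, a2$target)
})

test_that("random placement comparison separates planted from random", {
  w <- toy_world()
  # three patients whose deletions cover the T1 gene gB
  cohort <- data.frame(patient_id = c("P1", "P2", "P3"), chrom = "c1",
                       start = c(1.6e6, 1.5e6, 1.65e6),
                       end = c(1.8e6, 1.9e6, 1.75e6),
                       stringsAsFactors = FALSE)
  pat <- propagate(w$dag, annotation_table(
    "patient", list(P1 = "t1a", P2 = "t1a", P3 = "t1a")))
  res <- score_vs_random_placement(cohort, pat, w$arch, w$gene_ann,
                                   w$ic_genes, w$dag, n_placements = 200,
                                   seed = 5)
  expect_gt(res$real_mean, res$random_mean)
  expect_lt(res$p_value, 0.05)
  # degenerate: nobody scores anywhere
  pat0 <- propagate(w$dag, annotation_table(
    "patient", list(P1 = "root", P2 = "root", P3 = "root")))
  res0 <- score_vs_random_placement(cohort, pat0, w$arch, w$gene_ann,
                                    w$ic_genes, w$dag, n_placements = 10,
                                    seed = 5)
  expect_equal(res0$p_value, 1)
})
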