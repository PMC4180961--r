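test_that("synthetic ontology has the closed-form term count and layout", {
  cfg <- small_config(subtree_depth = 3, branching = 3)
  onto <- generate_ontology(cfg)
  per_subtree <- (3^4 - 1) / (3 - 1)            # full 3-ary tree, depth 3
  expect_equal(length(onto$dag$terms), 1 + 10 * per_subtree)
  # all targets are children of the root
  expect_true(all(vapply(onto$targets$term, function(t)
    identical(onto$dag$parents[[t]], onto$dag$root), logical(1))))
  # depth 0 -> star graph of the 10 targets
  star <- generate_ontology(small_config(subtree_depth = 0))
  expect_equal(length(star$dag$terms), 11)
  # target subtrees are disjoint
  d1 <- descendants(onto$dag, onto$targets$term[[1]])
  d2 <- descendants(onto$dag, onto$targets$term[[2]])
  expect_length(intersect(d1, d2), 0)
})

test_that("gene annotations honour the unannotated fraction and one subtree", {
  cfg <- small_config(seed = 9)
  onto <- generate_ontology(cfg)
  ga <- generate_gene_annotations(onto$dag, onto$targets, cfg)
  n_ann <- length(ga$annotations)
  expect_equal(cfg$n_genes - n_ann,
               round(cfg$fraction_unannotated * cfg$n_genes))
  gene_target <- attr(ga, "gene_target")
  desc_sets <- lapply(onto$targets$term, descendants, dag = onto$dag)
  names(desc_sets) <- onto$targets$term
  ok <- vapply(names(ga$annotations), function(g)
    all(ga$annotations[[g]] %in% desc_sets[[gene_target[[g]]]]), logical(1))
  expect_true(all(ok))
  expect_true(all(lengths(ga$annotations) >= 1 & lengths(ga$annotations) <= 5))
  # seed determinism
  ga2 <- generate_gene_annotations(onto$dag, onto$targets, cfg)
  expect_identical(ga$annotations, ga2$annotations)
})

test_that("architecture round-trips its gap structure through derive_boundaries", {
  cfg <- small_config(seed = 5)
  onto <- generate_ontology(cfg)
  arch <- generate_architecture(cfg, onto$targets)
  # recompute expected boundaries from raw domain coordinates only
  expected <- do.call(rbind, lapply(split(arch$domains, arch$domains$chrom),
                                    function(d) {
    d <- d[order(d$start), ]
    gs <- d$end[-nrow(d)]; ge <- d$start[-1]
    keep <- ge - gs > 0 & ge - gs <= 400000
    data.frame(chrom = d$chrom[[1]], start = gs[keep], end = ge[keep])
  }))
  rownames(expected) <- NULL
  expect_equal(arch$boundaries, expected)
  # no gene straddles a boundary, all enhancer tissues are known
  for (i in seq_len(nrow(arch$boundaries))) {
    b <- arch$boundaries[i, ]
    expect_false(any(partial_overlap(list(chrom = b$chrom, start = b$start,
                                          end = b$end), arch$genes)))
  }
  expect_true(all(arch$enhancers$tissue %in% onto$targets$tissue))
})

test_that("cohort planting is exact and recoverable at zero noise", {
  cfg <- small_config(seed = 6)
  onto <- generate_ontology(cfg)
  ga <- generate_gene_annotations(onto$dag, onto$targets, cfg)
  arch <- generate_architecture(cfg, onto$targets)
  coh <- generate_cohort(arch, onto$dag, onto$targets, ga, cfg)
  # deterministic mixture allocation
  expect_equal(as.integer(table(coh$truth$mechanism)[c("tdbd", "mixed",
                                                       "gde", "benign")]),
               as.integer(cnvmech:::mixture_counts(cfg$mixture,
                                                   cfg$n_patients)[
                 c("tdbd", "mixed", "gde", "benign")]))
  pat_prop <- propagate(onto$dag, coh$annotations)
  ic_p <- information_content(onto$dag, pat_prop, "patients")
  ic_g <- information_content(onto$dag, propagate(onto$dag, ga), "genes")
  calls <- classify_cohort(coh$cohort, pat_prop, arch, onto$dag, ga,
                           ic_p, ic_g, onto$targets)
  map <- c(tdbd = "TDBD_only", mixed = "TDBD_GDE", gde = "GDE",
           benign = "unexplained")
  expect_equal(calls$category, unname(map[coh$truth$mechanism]))
  # seed determinism of the whole cohort
  coh2 <- generate_cohort(arch, onto$dag, onto$targets, ga, cfg)
  expect_identical(coh$cohort, coh2$cohort)
  expect_identical(coh$annotations$annotations, coh2$annotations$annotations)
})

test_that("generator errors when the architecture cannot host the mixture", {
  cfg <- simulation_config(seed = 1, n_patients = 50, domains_per_chrom = 3,
                           n_chrom = 1)
  onto <- generate_ontology(cfg)
  ga <- generate_gene_annotations(onto$dag, onto$targets, cfg)
  arch <- generate_architecture(cfg, onto$targets)
  expect_error(generate_cohort(arch, onto$dag, onto$targets, ga, cfg),
               "architecture too small")
})

test_that("count matrix plants tissue-specific signal deterministically", {
  cfg <- small_config(seed = 2,
                      dnase = list(n_windows = 2000, planted_per_tissue = 50))
  dn <- generate_count_matrix(cfg)
  expect_equal(dim(dn$counts$counts), c(2000, 16))
  expect_equal(sort(unname(lengths(dn$truth))), rep(50L, 4))
  # planted windows are disjoint across tissues
  expect_equal(anyDuplicated(unlist(dn$truth)), 0)
  dn2 <- generate_count_matrix(cfg)
  expect_identical(dn$counts$counts, dn2$counts$counts)
  # zero effect -> t-statistics centred at zero
  cfg0 <- small_config(seed = 2, dnase = list(n_windows = 2000, effect = 0))
  dn0 <- generate_count_matrix(cfg0)
  st <- tissue_t_statistics(log_transform_normalize(dn0$counts), dn0$design)
  expect_lt(abs(mean(st$t)), 0.05)
  # negative-binomial option produces overdispersed counts
  cfgnb <- small_config(seed = 2, dnase = list(n_windows = 2000, effect = 0,
                                               size = 2))
  dnnb <- generate_count_matrix(cfgnb)
  expect_gt(var(as.numeric(dnnb$counts$counts)),
            var(as.numeric(dn0$counts$counts)))
})
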