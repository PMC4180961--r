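# fixture layout (toy_world): domains [0,1M) [1.2M,2.2M) [2.4M,3.4M) on c1;
# boundaries [1M,1.2M) and [2.2M,2.4M); brain enhancer at 0.1M, heart at
# 2.5M; genes gA (0.5M, no annotation), gB (1.7M, t1a), gD (2.0M, t1b),
# gC (2.9M, t2a); targets T1<->brain, T2<->heart

patient <- function(w, id, start, end, terms) {
  list(patient_id = id, chrom = "c1", start = start, end = end,
       annot = unique(unlist(w$dag$anc[terms])))
}

test_that("tdbd evidence requires boundary + opposite-side enhancer/gene", {
  w <- toy_world()
  del <- list(chrom = "c1", start = 0.9e6, end = 1.3e6)
  ev <- tdbd_evidence(del, "T1", w$arch, w$gene_prop, w$targets)
  expect_true(ev$flag)
  expect_equal(ev$enhancer_side, "left")
  expect_equal(ev$gene, "gB")
  expect_equal(nrow(ev$boundaries), 1)
  # same-side enhancer and gene: heart enhancer and gC both right of the
  # deletion over the second boundary
  del2 <- list(chrom = "c1", start = 2.15e6, end = 2.45e6)
  expect_false(tdbd_evidence(del2, "T2", w$arch, w$gene_prop, w$targets)$flag)
  # no boundary contained -> false regardless of flanks
  del3 <- list(chrom = "c1", start = 1.5e6, end = 1.8e6)
  expect_false(tdbd_evidence(del3, "T1", w$arch, w$gene_prop, w$targets)$flag)
  expect_error(tdbd_evidence(del, NA_character_, w$arch, w$gene_prop,
                             w$targets), "not assessed")
})

test_that("gde evidence is the within-deletion phenogram threshold", {
  w <- toy_world()
  annot <- unique(unlist(w$dag$anc["t1a"]))
  # gene-free deletion
  expect_false(gde_evidence(list(chrom = "c1", start = 0.9e6, end = 1.3e6),
                            annot, w$arch, w$gene_ann, w$ic_genes, w$dag))
  # deletion containing the exactly-matching gene
  expect_true(gde_evidence(list(chrom = "c1", start = 1.6e6, end = 1.8e6),
                           annot, w$arch, w$gene_ann, w$ic_genes, w$dag))
  # genes annotated only to the root never score
  dag2 <- w$dag
  ga2 <- annotation_table("gene", list(gB = "root"))
  expect_false(gde_evidence(list(chrom = "c1", start = 1.6e6, end = 1.8e6),
                            annot, w$arch, ga2, w$ic_genes, dag2))
})

test_that("classification lattice produces all four categories", {
  w <- toy_world()
  pat <- propagate(w$dag, annotation_table("patient", list(
    TD = "t1a",            # deletion over boundary 1, gene-free
    MX = "t1a",            # same boundary but swallowing gB
    GD = "t1a",            # inside domain 2 over gB
    UN = "t2a")))          # gene- and boundary-free deletion
  cohort <- data.frame(
    patient_id = c("TD", "MX", "GD", "UN"), chrom = "c1",
    start = c(0.9e6, 0.95e6, 1.5e6, 2.55e6),
    end = c(1.3e6, 1.9e6, 1.8e6, 2.7e6), stringsAsFactors = FALSE)
  ic_p <- information_content(w$dag, pat, "patients")
  calls <- classify_cohort(cohort, pat, w$arch, w$dag, w$gene_ann,
                           ic_p, w$ic_genes, w$targets)
  expect_equal(calls$category, c("TDBD_only", "TDBD_GDE", "GDE", "unexplained"))
  expect_true(calls$s_adjacent[[1]] > calls$s_within[[1]])
  expect_true(calls$s_within[[2]] >= calls$s_adjacent[[2]])
  expect_true(calls$gde_evidence[[2]] && calls$gde_evidence[[3]])
  # categories are exclusive and exhaustive over assessed patients
  expect_true(all(calls$category %in%
                    c("TDBD_only", "TDBD_GDE", "GDE", "unexplained")))
})

test_that("unassignable patients are not assessed", {
  w <- toy_world()
  pat <- propagate(w$dag, annotation_table("patient", list(
    NA1 = "root", AMB = c("t1a", "t2a"))))
  cohort <- data.frame(patient_id = c("NA1", "AMB"), chrom = "c1",
                       start = c(0.9e6, 0.9e6), end = c(1.3e6, 1.3e6),
                       stringsAsFactors = FALSE)
  ic_p <- information_content(w$dag, pat, "patients")
  calls <- classify_cohort(cohort, pat, w$arch, w$dag, w$gene_ann,
                           ic_p, w$ic_genes, w$targets)
  expect_equal(calls$category, rep("not_assessed", 2))
  expect_equal(calls$assignment, c("unassigned", "ambiguous"))
})

test_that("gde evidence is monotone under deletion growth", {
  w <- toy_world()
  annot <- unique(unlist(w$dag$anc["t1a"]))
  starts <- c(1.65e6, 1.6e6, 1.3e6, 0.5e6)
  ends <- c(1.75e6, 1.9e6, 2.3e6, 3.0e6)
  flags <- vapply(seq_along(starts), function(i)
    gde_evidence(list(chrom = "c1", start = starts[[i]], end = ends[[i]]),
                 annot, w$arch, w$gene_ann, w$ic_genes, w$dag), logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0) || all(flags))
})

test_that("no-boundary enhancer adoption control", {
  w <- toy_world()
  # heart enhancer 100 kb left, gC 200 kb right of this deletion
  del <- list(chrom = "c1", start = 2.6e6, end = 2.8e6)
  expect_true(no_boundary_enhancer_adoption(del, "T2", w$arch, w$gene_prop,
                                            w$targets))
  # wrong tissue: no brain enhancer within the flanks
  expect_false(no_boundary_enhancer_adoption(del, "T1", w$arch, w$gene_prop,
                                             w$targets))
  # signature outside a narrow window
  expect_false(no_boundary_enhancer_adoption(del, "T2", w$arch, w$gene_prop,
                                             w$targets, width = 5e4))
  # boundary-overlapping deletion is an error
  expect_error(no_boundary_enhancer_adoption(
    list(chrom = "c1", start = 0.9e6, end = 1.3e6), "T1", w$arch,
    w$gene_prop, w$targets), "not applicable")
})

test_that("cohort summary fractions sum to one over assessed patients", {
  calls <- data.frame(
    patient_id = paste0("P", 1:6),
    category = c("TDBD_only", "GDE", "GDE", "unexplained", "not_assessed",
                 "TDBD_GDE"), stringsAsFactors = FALSE)
  s <- cohort_summary(calls)
  expect_equal(s$n_assessed, 5)
  expect_equal(sum(s$fractions), 1)
  expect_equal(unname(s$fractions[["GDE"]]), 2 / 5)
  all_un <- cohort_summary(data.frame(patient_id = "P1",
                                      category = "unexplained"))
  expect_equal(unname(all_un$fractions[["unexplained"]]), 1)
})
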