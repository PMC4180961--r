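# Permutation null models: phenotype shuffling across target groups, gene
# annotation permutation, empirical P values, and the replicate drivers.
# A precomputed "cohort model" makes per-replicate reclassification a table
# lookup; its equality with the reference per-patient path is asserted in the
# test suite.

#' Shuffle patient phenotypes across target groups
#'
#' Every patient receives the full phenotype annotation set (and hence the
#' target term) of a uniformly chosen donor patient from a *different*
#' target group, sampling with replacement. Deletion coordinates stay fixed.
#'
#' @param tab Patient `annotation_table` (direct or propagated; the donor's
#'   set is copied verbatim).
#' @param groups Named character vector mapping patient id -> target group.
#'   Patients absent from `groups` keep their own annotations.
#' @param seed Integer seed.
#' @return An `annotation_table` with reassigned sets; the donor of each
#'   patient is recorded in `attr(, "donors")`.
#' @export
shuffle_patient_phenotypes <- function(tab, groups, seed = 1) {
  stopifnot(inherits(tab, "annotation_table"))
  groups <- groups[!is.na(groups)]
  if (length(unique(groups)) < 2L) {
    stop("need at least two non-empty target groups to shuffle")
  }
  set.seed(seed)
  ids <- names(groups)
  donors <- stats::setNames(ids, ids)
  for (p in ids) {
    pool <- ids[groups != groups[[p]]]
    donors[[p]] <- pool[[sample.int(length(pool), 1L)]]
  }
  ann <- tab$annotations
  ann[ids] <- tab$annotations[donors]
  out <- annotation_table(tab$entity_kind, ann, propagated = tab$propagated)
  attr(out, "donors") <- donors
  out
}

#' Permute gene annotations
#'
#' A uniform random permutation of the gene identifiers relabels the
#' annotation table: gene `g` receives the term set of `perm(g)`. The
#' multiset of term sets -- the number of annotated genes and the depth of
#' annotation -- is invariant.
#'
#' @param tab Gene `annotation_table`.
#' @param seed Integer seed.
#' @return Permuted `annotation_table` with `attr(, "perm")`.
#' @export
permute_gene_annotations <- function(tab, seed = 1) {
  stopifnot(inherits(tab, "annotation_table"))
  n <- length(tab$annotations)
  if (n < 2L) stop("need at least 2 genes to permute")
  set.seed(seed)
  perm <- sample.int(n)
  ann <- tab$annotations[perm]
  names(ann) <- names(tab$annotations)
  out <- annotation_table(tab$entity_kind, ann, propagated = tab$propagated)
  attr(out, "perm") <- perm
  out
}

#' Empirical P value from permutation replicates
#'
#' `p = #{null >= observed} / n_reps`, with no continuity correction; a zero
#' count is reported as `"< 1/n_reps"`.
#'
#' @param observed Observed rate.
#' @param nulls Numeric vector of null replicate rates (non-empty).
#' @return List with numeric `p` and the display string `p_report`.
#' @export
empirical_p <- function(observed, nulls) {
  if (!length(nulls)) stop("empty null replicate vector")
  p <- mean(nulls >= observed)
  list(p = p,
       p_report = if (p == 0) paste0("< ", format(1 / length(nulls))) else
         format(p))
}

# ---------------------------------------------------------------------------
# Fast cohort model: precomputes everything classification needs so that a
# (deletion, annotation-set) pair classifies in O(1).

max0 <- function(v) if (length(v)) max(v) else 0

build_cohort_model <- function(cohort, patient_annotations, arch, dag,
                               gene_annotations, ic_patients, ic_genes,
                               targets, score_scope = c("regions", "all")) {
  score_scope <- match.arg(score_scope)
  if (!patient_annotations$propagated) stop("patient annotations must be propagated")
  gene_prop <- propagate(dag, gene_annotations)
  attr(targets, "desc_cache") <- target_descendants(dag, targets)
  pids <- cohort$patient_id
  annots <- patient_annotations$annotations[pids]
  assign <- lapply(annots, assign_target_term, targets = targets,
                   ic_patients = ic_patients, dag = dag)
  target <- vapply(assign, `[[`, character(1), "target")
  status <- vapply(assign, `[[`, character(1), "status")
  tau <- match(target, targets$term)          # NA when not assessed

  gene_ids <- arch$genes$gene_id
  gene_targets <- vapply(targets$term, function(tt)
    vapply(gene_ids, function(g)
      tt %in% gene_prop$annotations[[g]], logical(1)),
    logical(length(gene_ids)))
  if (is.null(dim(gene_targets))) {
    gene_targets <- matrix(gene_targets, nrow = length(gene_ids))
  }

  n_del <- nrow(cohort)
  n_tgt <- nrow(targets)
  has_boundary <- logical(n_del)
  genes_in <- genes_left <- genes_right <- vector("list", n_del)
  enh_left <- enh_right <- matrix(FALSE, n_del, n_tgt)
  for (i in seq_len(n_del)) {
    deletion <- list(chrom = cohort$chrom[[i]], start = cohort$start[[i]],
                     end = cohort$end[[i]])
    has_boundary[[i]] <- any(complete_overlap(deletion, arch$boundaries))
    adj <- adjacent_regions(deletion, arch)
    gi <- function(region) match(genes_in_region(arch$genes, region$chrom,
                                                 region$start, region$end),
                                 gene_ids)
    genes_in[[i]] <- gi(deletion)
    genes_left[[i]] <- gi(adj$left)
    genes_right[[i]] <- gi(adj$right)
    etiss <- function(region) {
      if (region$start >= region$end) return(character(0))
      unique(arch$enhancers$tissue[partial_overlap(region, arch$enhancers)])
    }
    enh_left[i, ] <- targets$tissue %in% etiss(adj$left)
    enh_right[i, ] <- targets$tissue %in% etiss(adj$right)
  }

  # gene permutation can move any annotated gene into a region, so the
  # "all" scope scores every gene; the cheaper "regions" scope suffices for
  # phenotype shuffling, where region gene content is fixed
  needed <- if (score_scope == "all") {
    which(gene_ids %in% names(gene_annotations$annotations))
  } else {
    sort(unique(c(unlist(genes_in), unlist(genes_left),
                  unlist(genes_right))))
  }
  term_sets <- lapply(gene_ids[needed], function(g)
    gene_annotations$annotations[[g]])
  names(term_sets) <- gene_ids[needed]
  S_needed <- phenomatch_matrix(term_sets, annots, ic_genes, dag)
  S <- matrix(0, length(gene_ids), length(annots),
              dimnames = list(gene_ids, pids))
  S[needed, ] <- S_needed

  # per-deletion, per-target TDBD signature (enhancer one side, target gene
  # on the other, boundary contained)
  gene_side_target <- function(gl) {
    m <- matrix(FALSE, n_del, n_tgt)
    for (i in seq_len(n_del)) {
      g <- gl[[i]]
      if (length(g)) m[i, ] <- apply(gene_targets[g, , drop = FALSE], 2L, any)
    }
    m
  }
  gtl <- gene_side_target(genes_left)
  gtr <- gene_side_target(genes_right)
  tdbd_target <- has_boundary & ((enh_left & gtr) | (enh_right & gtl))

  list(cohort = cohort, pids = pids, annots = annots, status = status,
       target = target, tau = tau, targets = targets,
       gene_ids = gene_ids, gene_targets = gene_targets,
       has_boundary = has_boundary, genes_in = genes_in,
       genes_left = genes_left, genes_right = genes_right,
       enh_left = enh_left, enh_right = enh_right,
       tdbd_target = tdbd_target, S = S, score_scope = score_scope)
}

# n_del x n_annot matrix of mechanism categories (character)
model_category_matrix <- function(model) {
  n_del <- nrow(model$cohort)
  n_ann <- length(model$annots)
  S_within <- vapply(seq_len(n_del), function(i)
    if (length(model$genes_in[[i]]))
      apply(model$S[model$genes_in[[i]], , drop = FALSE], 2L, max)
    else rep(0, n_ann), numeric(n_ann))
  S_adj <- vapply(seq_len(n_del), function(i) {
    g <- unique(c(model$genes_left[[i]], model$genes_right[[i]]))
    if (length(g)) apply(model$S[g, , drop = FALSE], 2L, max)
    else rep(0, n_ann)
  }, numeric(n_ann))
  S_within <- t(matrix(S_within, nrow = n_ann))   # n_del x n_annot
  S_adj <- t(matrix(S_adj, nrow = n_ann))
  cat_m <- matrix("not_assessed", n_del, n_ann)
  for (k in seq_len(n_ann)) {
    if (model$status[[k]] != "assigned") next
    tk <- model$tau[[k]]
    tdbd <- model$tdbd_target[, tk]
    sw <- S_within[, k]
    sa <- S_adj[, k]
    gde <- sw > 0
    cat_m[, k] <- ifelse(tdbd,
                         ifelse(sa > sw, "TDBD_only",
                                ifelse(gde, "TDBD_GDE", "TDBD_only")),
                         ifelse(gde, "GDE", "unexplained"))
  }
  cat_m
}

rate_from_categories <- function(categories, rate = c("TDBD_only",
                                                      "TDBD_or_mixed")) {
  rate <- match.arg(rate)
  keep <- categories != "not_assessed"
  if (!any(keep)) return(NA_real_)
  hit <- if (rate == "TDBD_only") categories == "TDBD_only" else
    categories %in% c("TDBD_only", "TDBD_GDE")
  mean(hit[keep])
}

#' Phenotype-shuffle permutation test of the TDBD rate
#'
#' Recomputes target assignment and mechanism classification after assigning
#' each assessed patient the phenotype profile of a random patient from a
#' different target group, `n_reps` times, and reports the empirical P value
#' of the observed TDBD rate against the null rates.
#'
#' @param cohort Data.frame `patient_id,chrom,start,end`.
#' @param patient_annotations Propagated patient `annotation_table`.
#' @param arch,dag,gene_annotations,ic_patients,ic_genes,targets Pipeline
#'   inputs as in [classify_cohort()].
#' @param n_reps Number of permutation replicates (default 10000).
#' @param seed Integer seed; all replicate randomness derives from it.
#' @param rate `"TDBD_only"` counts only pure boundary-disruption calls;
#'   `"TDBD_or_mixed"` also counts mixed TDBD/GDE calls.
#' @param model Optional precomputed internal cohort model (reused across
#'   repeated tests on the same cohort).
#' @return A `permutation_result` list: `observed_rate`, `null_rates`,
#'   `n_reps`, `empirical_p`, `p_report`, `seed`.
#' @export
run_phenotype_shuffle_test <- function(cohort, patient_annotations, arch, dag,
                                       gene_annotations, ic_patients,
                                       ic_genes, targets, n_reps = 10000,
                                       seed = 1, rate = "TDBD_only",
                                       model = NULL) {
  stopifnot(n_reps >= 1)
  if (is.null(model)) {
    model <- build_cohort_model(cohort, patient_annotations, arch, dag,
                                gene_annotations, ic_patients, ic_genes,
                                targets)
  }
  cat_m <- attr(model, "cat_m")
  if (is.null(cat_m)) cat_m <- model_category_matrix(model)
  assigned <- which(model$status == "assigned")
  if (length(unique(model$tau[assigned])) < 2L) {
    stop("need at least two non-empty target groups to shuffle")
  }
  observed <- rate_from_categories(cat_m[cbind(assigned, assigned)], rate)
  set.seed(seed)
  taus <- model$tau[assigned]
  pools <- lapply(seq_along(assigned), function(j)
    assigned[taus != taus[[j]]])
  null_rates <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    donors <- vapply(pools, function(pool)
      pool[[sample.int(length(pool), 1L)]], integer(1))
    cats <- cat_m[cbind(assigned, donors)]
    null_rates[[r]] <- rate_from_categories(cats, rate)
  }
  ep <- empirical_p(observed, null_rates)
  structure(list(observed_rate = observed, null_rates = null_rates,
                 n_reps = n_reps, empirical_p = ep$p, p_report = ep$p_report,
                 seed = seed, rate = rate),
            class = "permutation_result")
}

#' Gene-annotation permutation test of the TDBD rate
#'
#' Null model that relabels gene identifiers in the phenotype annotation
#' table by a uniform random permutation per replicate, holding the number
#' of disease genes and the depth of annotation constant, then reclassifies
#' the cohort (patients keep their own phenotypes).
#'
#' @inheritParams run_phenotype_shuffle_test
#' @param n_reps Number of permutation replicates (default 1000).
#' @return A `permutation_result`.
#' @export
run_gene_permutation_test <- function(cohort, patient_annotations, arch, dag,
                                      gene_annotations, ic_patients,
                                      ic_genes, targets, n_reps = 1000,
                                      seed = 1, rate = "TDBD_only",
                                      model = NULL) {
  stopifnot(n_reps >= 1)
  if (is.null(model)) {
    model <- build_cohort_model(cohort, patient_annotations, arch, dag,
                                gene_annotations, ic_patients, ic_genes,
                                targets, score_scope = "all")
  }
  if (model$score_scope != "all") {
    stop("gene permutation needs a cohort model built with score_scope = 'all'")
  }
  assigned <- which(model$status == "assigned")
  n_genes <- length(model$gene_ids)

  classify_one <- function(i, row_of) {
    # row_of maps an architecture gene index to the S/gene_targets row whose
    # annotation it carries under the current permutation
    tk <- model$tau[[i]]
    rows_in <- row_of(model$genes_in[[i]])
    rows_l <- row_of(model$genes_left[[i]])
    rows_r <- row_of(model$genes_right[[i]])
    sw <- max0(model$S[rows_in, model$pids[[i]]])
    sa <- max0(model$S[c(rows_l, rows_r), model$pids[[i]]])
    gene_l <- any(model$gene_targets[rows_l, tk])
    gene_r <- any(model$gene_targets[rows_r, tk])
    tdbd <- model$has_boundary[[i]] &&
      ((model$enh_left[i, tk] && gene_r) || (model$enh_right[i, tk] && gene_l))
    mechanism_category(TRUE, tdbd, sw > 0, sw, sa)
  }
  observed <- rate_from_categories(
    vapply(assigned, classify_one, character(1), row_of = identity), rate)

  set.seed(seed)
  null_rates <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    # permute annotated gene identities: architecture gene g carries the
    # annotation of perm(g)
    perm <- sample.int(n_genes)
    perm_rows <- function(g) perm[g]
    cats <- vapply(assigned, classify_one, character(1), row_of = perm_rows)
    null_rates[[r]] <- rate_from_categories(cats, rate)
  }
  ep <- empirical_p(observed, null_rates)
  structure(list(observed_rate = observed, null_rates = null_rates,
                 n_reps = n_reps, empirical_p = ep$p, p_report = ep$p_report,
                 seed = seed, rate = rate),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation test (", x$rate, "): observed rate ",
      signif(x$observed_rate, 4), ", null mean ",
      signif(mean(x$null_rates), 4), ", empirical P ", x$p_report,
      " (", x$n_reps, " reps)\n", sep = "")
  invisible(x)
}
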