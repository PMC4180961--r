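# Phenotypic similarity between patients and genes: target-term assignment,
# Resnik-style phenomatch scores, phenogram scores and the random-placement
# score comparison.

#' Define the set of target terms and their tissues
#'
#' The ten target terms are top-level phenotype categories, each paired with
#' the tissue whose enhancers are relevant for that organ system (e.g.
#' abnormality of the forebrain <-> fetal brain).
#'
#' @param terms Character vector of distinct target term identifiers.
#' @param tissues Character vector of tissue labels, parallel to `terms`.
#' @param dag Optional `ontology`; if given, all targets are checked to exist.
#' @return A `target_set` data.frame with columns `term` and `tissue`.
#' @export
target_term_set <- function(terms, tissues, dag = NULL) {
  stopifnot(is.character(terms), is.character(tissues),
            length(terms) == length(tissues))
  if (anyDuplicated(terms)) stop("target terms must be distinct")
  if (anyDuplicated(tissues)) stop("tissue labels must be distinct")
  if (!is.null(dag)) check_terms(dag, terms, "target term")
  structure(data.frame(term = terms, tissue = tissues,
                       stringsAsFactors = FALSE),
            class = c("target_set", "data.frame"))
}

#' Assign a patient to a target term
#'
#' For each target term `T_i`, the patient's propagated annotation set is
#' intersected with `desc(T_i)`; the patient is assigned to the target whose
#' intersection carries the strictly largest total information content
#' (patient-corpus IC). Patients sharing no term with any target branch are
#' `unassigned`; a non-unique maximum yields `ambiguous`.
#'
#' @param annot Character vector: the patient's *propagated* term set.
#' @param targets A `target_set`.
#' @param ic_patients Patient-corpus `ic_table`.
#' @param dag An `ontology` object.
#' @param tol Relative tolerance used to detect tied maxima.
#' @return List with `status` (`"assigned"`, `"unassigned"` or
#'   `"ambiguous"`), `target` (term id or `NA`), and the per-target score
#'   vector `scores`.
#' @export
assign_target_term <- function(annot, targets, ic_patients, dag, tol = 1e-9) {
  stopifnot(inherits(targets, "target_set"), inherits(dag, "ontology"))
  check_terms(dag, annot, "annotation term")
  desc_sets <- target_descendants(dag, targets)
  hits <- lapply(desc_sets, intersect, y = annot)
  scores <- vapply(hits, function(s) sum(ic_values(ic_patients, s)), numeric(1))
  names(scores) <- targets$term
  nonempty <- lengths(hits) > 0L
  if (!any(nonempty)) {
    return(list(status = "unassigned", target = NA_character_, scores = scores))
  }
  cand <- scores[nonempty]
  top <- max(cand)
  winners <- names(cand)[cand >= top - tol * max(1, abs(top))]
  if (length(winners) > 1L) {
    return(list(status = "ambiguous", target = NA_character_, scores = scores))
  }
  list(status = "assigned", target = winners, scores = scores)
}

# Memoised descendant sets for the targets (cached on the target_set by the
# cohort driver; recomputed here when absent).
target_descendants <- function(dag, targets) {
  cache <- attr(targets, "desc_cache")
  if (!is.null(cache)) return(cache)
  out <- lapply(targets$term, descendants, dag = dag)
  names(out) <- targets$term
  out
}

#' Assign target terms for a whole cohort
#'
#' @param tab Propagated patient `annotation_table` (errors if unpropagated).
#' @inheritParams assign_target_term
#' @return A data.frame with one row per patient: `patient_id`, `status`,
#'   `target`.
#' @export
assign_target_terms <- function(tab, targets, ic_patients, dag, tol = 1e-9) {
  stopifnot(inherits(tab, "annotation_table"))
  if (!tab$propagated) stop("patient annotations must be propagated before target assignment")
  attr(targets, "desc_cache") <- target_descendants(dag, targets)
  res <- lapply(tab$annotations, assign_target_term, targets = targets,
                ic_patients = ic_patients, dag = dag, tol = tol)
  data.frame(patient_id = names(tab$annotations),
             status = vapply(res, `[[`, character(1), "status"),
             target = vapply(res, `[[`, character(1), "target"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Common ancestors of a gene term and a patient term set
#'
#' `CA(t_g, annot_j) = anc(annot_j) intersect anc(t_g)`; since `annot_j` is
#' propagated it equals its own ancestor closure. The result always contains
#' the root when `annot_j` is non-empty.
#'
#' @param dag An `ontology`.
#' @param t_g A single gene term.
#' @param annot Propagated patient term set.
#' @return Character vector of common ancestor terms.
#' @export
common_ancestors <- function(dag, t_g, annot) {
  check_terms(dag, annot, "annotation term")
  intersect(ancestors(dag, t_g), annot)
}

#' Phenomatch score of one gene against a patient
#'
#' `S_g = sum over t_g in T_g of max{ IC(t) : t in CA(t_g, annot_j) }`, using
#' the phenomatch corpus IC (disease/gene annotations). The sum runs over the
#' gene's *direct* term set; a gene with no terms scores 0.
#'
#' @param gene_terms Character vector: the gene's direct phenotype terms.
#' @param annot Propagated patient term set.
#' @param ic Phenomatch-corpus `ic_table`.
#' @param dag An `ontology`.
#' @param use_propagated If `TRUE`, sum over the gene's propagated closure
#'   instead of its direct terms (alternative reading; not the default).
#' @return Non-negative numeric score.
#' @export
phenomatch_score <- function(gene_terms, annot, ic, dag, use_propagated = FALSE) {
  if (!length(gene_terms)) return(0)
  check_terms(dag, gene_terms, "gene term")
  if (use_propagated) {
    gene_terms <- unique(unlist(dag$anc[gene_terms], use.names = FALSE))
  }
  sum(vapply(gene_terms, function(t)
    max_ic(ic, intersect(dag$anc[[t]], annot)), numeric(1)))
}

#' Phenogram score of a gene set against a patient
#'
#' The maximum phenomatch score over the genes of a region (within the
#' deletion, or adjacent to it). An empty region scores 0, so the
#' "phenogram score above zero" gene-dosage criterion is automatically false
#' for gene-free regions.
#'
#' @param gene_term_sets List of character vectors (one per gene).
#' @inheritParams phenomatch_score
#' @return Non-negative numeric score.
#' @export
phenogram_score <- function(gene_term_sets, annot, ic, dag) {
  if (!length(gene_term_sets)) return(0)
  max(vapply(gene_term_sets, phenomatch_score, numeric(1),
             annot = annot, ic = ic, dag = dag))
}

# Vectorised phenomatch scores for many genes against many patients.
# Returns a genes x patients matrix. Used by the permutation machinery where
# per-pair calls would be too slow; equality with phenomatch_score() is
# asserted in the test suite.
phenomatch_matrix <- function(gene_term_sets, annot_sets, ic, dag) {
  n_g <- length(gene_term_sets)
  n_a <- length(annot_sets)
  S <- matrix(0, n_g, n_a,
              dimnames = list(names(gene_term_sets), names(annot_sets)))
  if (!n_g || !n_a) return(S)
  terms <- unique(unlist(gene_term_sets, use.names = FALSE))
  if (!length(terms)) return(S)
  check_terms(dag, terms, "gene term")
  # flat (term, ancestor, ic(ancestor)) table, grouped by term
  anc_list <- dag$anc[terms]
  anc_flat <- unlist(anc_list, use.names = FALSE)
  term_idx <- rep.int(seq_along(terms), lengths(anc_list))
  ic_flat <- ic_values(ic, anc_flat)
  grp <- split(seq_along(anc_flat), term_idx)
  gene_term_idx <- lapply(gene_term_sets, match, table = terms)
  for (a in seq_len(n_a)) {
    member <- anc_flat %in% annot_sets[[a]]
    best <- vapply(grp, function(idx) {
      v <- ic_flat[idx][member[idx]]
      if (!length(v)) 0 else max(v)
    }, numeric(1))
    S[, a] <- vapply(gene_term_idx, function(ti)
      if (!length(ti)) 0 else sum(best[ti]), numeric(1))
  }
  S
}

#' Compare observed phenogram scores with random length-preserving placements
#'
#' For every deletion the within-deletion phenogram score is computed; each
#' deletion is then placed uniformly at random on the genome `n_placements`
#' times (length preserved; chromosomes weighted by the number of valid start
#' positions) and scored the same way. The two score samples are compared
#' with a two-sided Wilcoxon/Mann-Whitney rank-sum test.
#'
#' @param cohort Data.frame with columns `patient_id`, `chrom`, `start`, `end`.
#' @param patient_annotations Propagated patient `annotation_table`.
#' @param arch A `genome_architecture` (supplies genes and chromosome sizes).
#' @param gene_annotations Direct gene `annotation_table` (term sets used in
#'   the phenomatch sum).
#' @param ic Phenomatch-corpus `ic_table`.
#' @param dag An `ontology`.
#' @param n_placements Placements per deletion (>= 1).
#' @param seed Integer seed controlling the placements.
#' @return List with `real_scores`, `random_scores`, their means/sds, the
#'   rank-sum `statistic` and two-sided `p_value`.
#' @export
score_vs_random_placement <- function(cohort, patient_annotations, arch,
                                      gene_annotations, ic, dag,
                                      n_placements = 100, seed = 1) {
  stopifnot(n_placements >= 1)
  if (!patient_annotations$propagated) stop("patient annotations must be propagated")
  term_sets <- gene_annotations$annotations
  score_region <- function(chrom, start, end, annot) {
    g <- genes_in_region(arch$genes, chrom, start, end)
    phenogram_score(term_sets[intersect(g, names(term_sets))], annot, ic, dag)
  }
  real <- mapply(function(pid, chrom, start, end)
    score_region(chrom, start, end, patient_annotations$annotations[[pid]]),
    cohort$patient_id, cohort$chrom, cohort$start, cohort$end)
  lens <- cohort$end - cohort$start
  plc <- random_placement(lens, arch$chrom_lengths, n_reps = n_placements,
                          seed = seed)
  rand <- mapply(function(i, chrom, start, end) {
    pid <- cohort$patient_id[[i]]
    score_region(chrom, start, end, patient_annotations$annotations[[pid]])
  }, plc$deletion, plc$chrom, plc$start, plc$end)
  degenerate <- stats::var(c(real, rand)) == 0  # all scores identical
  wt <- suppressWarnings(stats::wilcox.test(real, rand, exact = FALSE,
                                            correct = TRUE))
  list(real_scores = unname(real), random_scores = unname(rand),
       real_mean = mean(real), real_sd = stats::sd(real),
       random_mean = mean(rand), random_sd = stats::sd(rand),
       statistic = unname(wt$statistic),
       p_value = if (degenerate) 1 else wt$p.value)
}
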