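# Per-deletion mechanism classification: boundary-disruption (TDBD) evidence,
# gene-dosage (GDE) evidence, the classification lattice, the no-boundary
# enhancer-adoption control and cohort summaries.

MECHANISM_LEVELS <- c("TDBD_only", "TDBD_GDE", "GDE", "unexplained",
                      "not_assessed")

#' Evidence for topological-domain-boundary disruption
#'
#' A deletion shows TDBD evidence iff (a) it completely overlaps at least one
#' domain boundary, (b) an enhancer of the patient's target tissue overlaps
#' one adjacent region, and (c) a gene annotated (after propagation) to the
#' target term or one of its descendants overlaps the *other* adjacent
#' region. Both orientations are checked.
#'
#' @param deletion List with `chrom,start,end`.
#' @param target Target term the patient is assigned to.
#' @param arch A `genome_architecture`.
#' @param gene_annotations_prop Propagated gene `annotation_table`.
#' @param targets A `target_set` (maps target term -> tissue).
#' @param adjacency Optional precomputed [adjacent_regions()] result.
#' @return List with `flag` plus supporting detail: contained `boundaries`,
#'   `enhancer_side`, and the supporting `gene`.
#' @export
tdbd_evidence <- function(deletion, target, arch, gene_annotations_prop,
                          targets, adjacency = NULL) {
  stopifnot(inherits(arch, "genome_architecture"))
  if (is.na(target)) stop("patient has no assigned target term (not assessed)")
  tissue <- targets$tissue[match(target, targets$term)]
  if (is.na(tissue)) stop("target term not in target set: ", target)
  bhit <- complete_overlap(deletion, arch$boundaries)
  boundaries <- arch$boundaries[bhit, , drop = FALSE]
  if (!nrow(boundaries)) {
    return(list(flag = FALSE, boundaries = boundaries,
                enhancer_side = NA_character_, gene = NA_character_))
  }
  if (is.null(adjacency)) adjacency <- adjacent_regions(deletion, arch)
  enh <- arch$enhancers[arch$enhancers$tissue == tissue, , drop = FALSE]
  has_enh <- function(region) region$start < region$end &&
    any(partial_overlap(region, enh))
  target_gene <- function(region) {
    ids <- genes_in_region(arch$genes, region$chrom, region$start, region$end)
    ids[vapply(ids, function(g)
      target %in% gene_annotations_prop$annotations[[g]], logical(1))]
  }
  genes_l <- target_gene(adjacency$left)
  genes_r <- target_gene(adjacency$right)
  if (has_enh(adjacency$left) && length(genes_r)) {
    return(list(flag = TRUE, boundaries = boundaries, enhancer_side = "left",
                gene = genes_r[[1L]]))
  }
  if (has_enh(adjacency$right) && length(genes_l)) {
    return(list(flag = TRUE, boundaries = boundaries, enhancer_side = "right",
                gene = genes_l[[1L]]))
  }
  list(flag = FALSE, boundaries = boundaries,
       enhancer_side = NA_character_, gene = NA_character_)
}

#' Evidence for a gene-dosage effect
#'
#' TRUE iff the phenogram score over genes within the deletion is above zero,
#' i.e. some deleted gene has positive phenotypic similarity to the patient.
#'
#' @param deletion List with `chrom,start,end`.
#' @param annot Propagated patient term set.
#' @param arch A `genome_architecture`.
#' @param gene_annotations Direct gene `annotation_table`.
#' @param ic Phenomatch-corpus `ic_table`.
#' @param dag An `ontology`.
#' @return Logical flag.
#' @export
gde_evidence <- function(deletion, annot, arch, gene_annotations, ic, dag) {
  ids <- genes_in_region(arch$genes, deletion$chrom, deletion$start,
                         deletion$end)
  sets <- gene_annotations$annotations[intersect(ids, names(gene_annotations$annotations))]
  phenogram_score(sets, annot, ic, dag) > 0
}

# classification lattice shared by the reference and fast paths
mechanism_category <- function(assessed, tdbd, gde, s_within, s_adjacent) {
  if (!assessed) return("not_assessed")
  if (tdbd) {
    if (s_adjacent > s_within) return("TDBD_only")
    if (gde) return("TDBD_GDE")
    return("TDBD_only")
  }
  if (gde) return("GDE")
  "unexplained"
}

#' Classify a single patient's deletion
#'
#' Runs target assignment, adjacency construction, TDBD/GDE evidence and the
#' within/adjacent phenogram score comparison, and applies the lattice:
#' TDBD evidence with adjacent score strictly above the within score is
#' `TDBD_only`; TDBD evidence otherwise (with GDE evidence) is `TDBD_GDE`;
#' GDE evidence without TDBD evidence is `GDE`; anything else `unexplained`.
#' Unassigned or ambiguous patients are `not_assessed`.
#'
#' @param patient List with `patient_id`, deletion coordinates
#'   (`chrom,start,end`) and propagated term set `annot`.
#' @param arch A `genome_architecture`.
#' @param dag An `ontology`.
#' @param gene_annotations Direct gene `annotation_table`.
#' @param gene_annotations_prop Propagated gene table (derived if `NULL`).
#' @param ic_patients,ic_genes Patient-corpus and phenomatch-corpus IC tables.
#' @param targets A `target_set`.
#' @return One-row data.frame mechanism call.
#' @export
classify_deletion <- function(patient, arch, dag, gene_annotations,
                              gene_annotations_prop = NULL,
                              ic_patients, ic_genes, targets) {
  if (is.null(gene_annotations_prop)) {
    gene_annotations_prop <- propagate(dag, gene_annotations)
  }
  assign <- assign_target_term(patient$annot, targets, ic_patients, dag)
  deletion <- list(chrom = patient$chrom, start = patient$start,
                   end = patient$end)
  adjacency <- adjacent_regions(deletion, arch)
  score_region <- function(region) {
    if (region$start >= region$end) return(0)
    ids <- genes_in_region(arch$genes, region$chrom, region$start, region$end)
    sets <- gene_annotations$annotations[intersect(ids, names(gene_annotations$annotations))]
    phenogram_score(sets, patient$annot, ic_genes, dag)
  }
  s_within <- score_region(deletion)
  s_adjacent <- max(score_region(adjacency$left), score_region(adjacency$right))
  gde <- gde_evidence(deletion, patient$annot, arch, gene_annotations,
                      ic_genes, dag)
  if (assign$status != "assigned") {
    return(data.frame(
      patient_id = patient$patient_id, category = "not_assessed",
      target = NA_character_, assignment = assign$status,
      tdbd_evidence = NA, gde_evidence = gde,
      s_within = s_within, s_adjacent = s_adjacent,
      boundary = NA_character_, enhancer_side = NA_character_,
      gene = NA_character_, stringsAsFactors = FALSE))
  }
  ev <- tdbd_evidence(deletion, assign$target, arch,
                      gene_annotations_prop, targets, adjacency)
  category <- mechanism_category(TRUE, ev$flag, gde, s_within, s_adjacent)
  data.frame(
    patient_id = patient$patient_id, category = category,
    target = assign$target, assignment = assign$status,
    tdbd_evidence = ev$flag, gde_evidence = gde,
    s_within = s_within, s_adjacent = s_adjacent,
    boundary = if (nrow(ev$boundaries))
      paste0(ev$boundaries$chrom, ":", ev$boundaries$start, "-",
             ev$boundaries$end, collapse = ";") else NA_character_,
    enhancer_side = ev$enhancer_side, gene = ev$gene,
    stringsAsFactors = FALSE)
}

#' Classify a whole cohort
#'
#' @param cohort Data.frame `patient_id,chrom,start,end`.
#' @param patient_annotations Propagated patient `annotation_table`.
#' @inheritParams classify_deletion
#' @return Data.frame of mechanism calls, one row per patient.
#' @export
classify_cohort <- function(cohort, patient_annotations, arch, dag,
                            gene_annotations, ic_patients, ic_genes, targets) {
  if (!patient_annotations$propagated) {
    stop("patient annotations must be propagated")
  }
  gene_prop <- propagate(dag, gene_annotations)
  attr(targets, "desc_cache") <- target_descendants(dag, targets)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[[i]]
    patient <- list(patient_id = pid, chrom = cohort$chrom[[i]],
                    start = cohort$start[[i]], end = cohort$end[[i]],
                    annot = patient_annotations$annotations[[pid]])
    classify_deletion(patient, arch, dag, gene_annotations, gene_prop,
                      ic_patients, ic_genes, targets)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' No-boundary enhancer-adoption control
#'
#' For deletions that do not completely overlap any boundary, checks whether
#' the TDBD enhancer/gene opposite-side signature holds within fixed 400-kb
#' flanking windows. Applying it to a boundary-overlapping deletion is an
#' error.
#'
#' @inheritParams tdbd_evidence
#' @param width Flank width in bp (default 400 kb).
#' @return Logical flag.
#' @export
no_boundary_enhancer_adoption <- function(deletion, target, arch,
                                          gene_annotations_prop, targets,
                                          width = DEFAULT_FLANK) {
  if (any(complete_overlap(deletion, arch$boundaries))) {
    stop("deletion completely overlaps a boundary; control not applicable")
  }
  if (is.na(target)) return(FALSE)
  tissue <- targets$tissue[match(target, targets$term)]
  fl <- flanking_windows(deletion, arch$chrom_lengths, width = width)
  enh <- arch$enhancers[arch$enhancers$tissue == tissue, , drop = FALSE]
  has_enh <- function(region) region$start < region$end &&
    any(partial_overlap(region, enh))
  has_gene <- function(region) {
    ids <- genes_in_region(arch$genes, region$chrom, region$start, region$end)
    any(vapply(ids, function(g)
      target %in% gene_annotations_prop$annotations[[g]], logical(1)))
  }
  (has_enh(fl$left) && has_gene(fl$right)) ||
    (has_enh(fl$right) && has_gene(fl$left))
}

#' Summarise cohort mechanism calls
#'
#' @param calls Data.frame from [classify_cohort()].
#' @return List with per-category `counts` and `fractions` over assessed
#'   patients (fractions sum to 1), plus `n_assessed` and `n_total`.
#' @export
cohort_summary <- function(calls) {
  counts <- table(factor(calls$category, levels = MECHANISM_LEVELS))
  assessed <- calls$category != "not_assessed"
  frac <- if (any(assessed)) {
    tab <- table(factor(calls$category[assessed],
                        levels = setdiff(MECHANISM_LEVELS, "not_assessed")))
    as.numeric(tab) / sum(tab)
  } else {
    rep(NA_real_, 4L)
  }
  names(frac) <- setdiff(MECHANISM_LEVELS, "not_assessed")
  list(counts = counts, fractions = frac,
       n_assessed = sum(assessed), n_total = nrow(calls))
}
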