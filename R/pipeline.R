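# Pipeline driver: reads every input, keeps each patient's largest deletion,
# runs target assignment, scoring and classification, and writes results.
# Output is a pure function of (inputs, config): repeated runs are
# byte-identical.

#' Pipeline configuration
#'
#' @param ontology,targets,gene_annotations,domains,genes,enhancers,chrom_sizes,cohort
#'   Input file paths (formats as produced by [simulate_bundle()]).
#' @param out_dir Output directory.
#' @param max_gap Maximum boundary length (default 400 kb).
#' @param flank Fixed flank width for the no-boundary control (default 400 kb).
#' @param rate Rate definition for permutation tests.
#' @param n_perm Phenotype-shuffle replicates to run after classification
#'   (0 = skip).
#' @param seed Seed for any permutation randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ontology, targets, gene_annotations, domains,
                            genes, enhancers, chrom_sizes, cohort, out_dir,
                            max_gap = MAX_BOUNDARY_GAP,
                            flank = DEFAULT_FLANK,
                            rate = "TDBD_only", n_perm = 0, seed = 1) {
  structure(list(ontology = ontology, targets = targets,
                 gene_annotations = gene_annotations, domains = domains,
                 genes = genes, enhancers = enhancers,
                 chrom_sizes = chrom_sizes, cohort = cohort,
                 out_dir = out_dir, max_gap = max_gap, flank = flank,
                 rate = rate, n_perm = n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Keep only the largest deletion per patient
#'
#' @param cohort Data.frame `patient_id,chrom,start,end`.
#' @return Filtered data.frame, one row per patient, original order of first
#'   appearance.
#' @export
largest_deletion_per_patient <- function(cohort) {
  if (!nrow(cohort)) return(cohort)
  len <- cohort$end - cohort$start
  keep <- unlist(lapply(split(seq_len(nrow(cohort)), cohort$patient_id),
                        function(idx) idx[[which.max(len[idx])]]))
  out <- cohort[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full classification pipeline
#'
#' Reads all inputs, restricts to each patient's single largest deletion,
#' propagates annotations, derives both IC corpora (patient corpus for
#' target assignment, gene corpus for phenomatch), classifies every
#' deletion, writes `results.tsv` and `summary.json` to the output
#' directory, and optionally runs the phenotype-shuffle permutation test.
#' Filtering-step counts (assigned / ambiguous / unassigned and per-category
#' totals) go to the message stream.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `calls`, `summary`, `counts` and (when
#'   `n_perm > 0`) `permutation`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- c("ontology", "targets", "gene_annotations", "domains", "genes",
              "enhancers", "chrom_sizes", "cohort")
  missing <- inputs[!vapply(inputs, function(f)
    file.exists(config[[f]]), logical(1))]
  if (length(missing)) {
    stop("missing input file(s): ",
         paste(unlist(config[missing]), collapse = ", "))
  }
  note <- function(...) if (!quiet) message(...)

  dag <- read_ontology(config$ontology)
  targets <- read_targets(config$targets, dag)
  gene_ann <- read_annotations(config$gene_annotations, "gene")
  chrom_lengths <- read_chrom_sizes(config$chrom_sizes)
  arch <- genome_architecture(chrom_lengths,
                              read_bed(config$domains),
                              read_bed(config$genes, "gene_id"),
                              read_bed(config$enhancers, "tissue"),
                              max_gap = config$max_gap)
  coh <- read_cohort(config$cohort)
  n_records <- nrow(coh$cohort)
  cohort <- largest_deletion_per_patient(coh$cohort)
  note("cohort: ", n_records, " records, ", nrow(cohort),
       " patients (largest deletion each)")

  pat_prop <- propagate(dag, coh$annotations)
  ic_patients <- information_content(dag, pat_prop, corpus_id = "patients")
  gene_prop <- propagate(dag, gene_ann)
  ic_genes <- information_content(dag, gene_prop, corpus_id = "genes")

  if (nrow(cohort)) {
    calls <- classify_cohort(cohort, pat_prop, arch, dag, gene_ann,
                             ic_patients, ic_genes, targets)
  } else {
    calls <- data.frame(patient_id = character(0), category = character(0),
                        stringsAsFactors = FALSE)
  }
  summary <- cohort_summary(calls)
  counts <- c(total = nrow(cohort),
              assigned = sum(calls$assignment == "assigned"),
              ambiguous = sum(calls$assignment == "ambiguous"),
              unassigned = sum(calls$assignment == "unassigned"))
  note("target assignment: ", counts[["assigned"]], " assigned, ",
       counts[["ambiguous"]], " ambiguous, ",
       counts[["unassigned"]], " unassigned")
  note("categories: ",
       paste(names(summary$counts), as.integer(summary$counts),
             sep = "=", collapse = ", "))

  result <- list(calls = calls, summary = summary, counts = counts)
  if (config$n_perm > 0 && nrow(cohort)) {
    result$permutation <- run_phenotype_shuffle_test(
      cohort, pat_prop, arch, dag, gene_ann, ic_patients, ic_genes,
      targets, n_reps = config$n_perm, seed = config$seed,
      rate = config$rate)
  }

  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  write_results(calls, file.path(config$out_dir, "results.tsv"))
  summary_json <- list(
    counts = as.list(stats::setNames(as.integer(summary$counts),
                                     names(summary$counts))),
    fractions = as.list(summary$fractions),
    n_assessed = summary$n_assessed, n_total = summary$n_total,
    filtering = as.list(counts))
  if (!is.null(result$permutation)) {
    pr <- result$permutation
    summary_json$permutation <- list(
      observed_rate = pr$observed_rate, null_mean = mean(pr$null_rates),
      empirical_p = pr$empirical_p, p_report = pr$p_report,
      n_reps = pr$n_reps, seed = pr$seed, rate = pr$rate)
  }
  jsonlite::write_json(summary_json,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}
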