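# File readers and writers. All interval files use the BED convention
# (0-based half-open, tab-separated); parsers are strict and report the
# offending line number.

split_lines <- function(path) {
  lines <- readLines(path)
  lines[nzchar(trimws(lines))]
}

parse_error <- function(path, lineno, msg) {
  stop(basename(path), " line ", lineno, ": ", msg, call. = FALSE)
}

#' Read a BED interval file
#'
#' BED3 (`chrom start end`) or BED4 with a name column (gene id, tissue
#' label or patient id). Empty files yield an empty collection.
#'
#' @param path File path.
#' @param name_col Optional name for the fourth column.
#' @return Data.frame of intervals.
#' @export
read_bed <- function(path, name_col = NULL) {
  lines <- split_lines(path)
  ncol_want <- 3L + !is.null(name_col)
  out <- empty_bed(if (is.null(name_col)) character(0) else name_col)
  if (!length(lines)) return(out)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < ncol_want) {
      parse_error(path, i, paste0("expected >= ", ncol_want, " columns"))
    }
    s <- suppressWarnings(as.numeric(p[[2]]))
    e <- suppressWarnings(as.numeric(p[[3]]))
    if (is.na(s) || is.na(e)) parse_error(path, i, "non-numeric coordinates")
    if (!(s >= 0 && s < e)) {
      parse_error(path, i, paste0("malformed interval [", p[[2]], ", ",
                                  p[[3]], ") (need 0 <= start < end)"))
    }
  }
  df <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    start = as.numeric(vapply(parts, `[[`, character(1), 2L)),
    end = as.numeric(vapply(parts, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE)
  if (!is.null(name_col)) {
    df[[name_col]] <- vapply(parts, `[[`, character(1), 4L)
  }
  df
}

#' Write a BED interval file
#'
#' Round-trips [read_bed()] bit-exactly (coordinates are written as
#' integers).
#'
#' @param df Data.frame with `chrom,start,end` and optional extra column.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end", setdiff(names(df), c("chrom", "start", "end")))
  out <- df[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromosome sizes
#'
#' Two-column TSV: chromosome name, length.
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  lines <- split_lines(path)
  if (!length(lines)) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lens <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  bad <- which(is.na(lens) | lens <= 0)
  if (length(bad)) parse_error(path, bad[[1]], "invalid chromosome length")
  stats::setNames(lens, vapply(parts, `[[`, character(1), 1L))
}

#' Read an ontology from OBO-subset or parent-edge TSV
#'
#' OBO files are recognised by a `[Term]` stanza; only `id:` and `is_a:`
#' lines are interpreted. Otherwise the file is a two-column TSV of
#' `child_id<TAB>parent_id` edges.
#'
#' @param path File path.
#' @return An `ontology` object.
#' @export
read_ontology <- function(path) {
  lines <- readLines(path)
  if (any(trimws(lines) == "[Term]")) {
    child <- parent <- character(0)
    cur <- NA_character_
    for (ln in lines) {
      ln <- trimws(ln)
      if (ln == "[Term]") { cur <- NA_character_; next }
      if (startsWith(ln, "id:")) cur <- trimws(sub("^id:", "", ln))
      if (startsWith(ln, "is_a:")) {
        tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        if (is.na(cur)) stop("is_a before id in ", basename(path))
        child <- c(child, cur)
        parent <- c(parent, tgt)
      }
    }
    return(ontology_dag(child, parent))
  }
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 2L)
  if (length(short)) parse_error(path, short[[1]], "expected 2 columns")
  ontology_dag(vapply(parts, `[[`, character(1), 1L),
               vapply(parts, `[[`, character(1), 2L))
}

#' Write an ontology as a parent-edge TSV
#' @param dag An `ontology`.
#' @param path Output path.
#' @export
write_ontology <- function(dag, path) {
  edges <- data.frame(
    child = rep(names(dag$parents), lengths(dag$parents)),
    parent = unlist(dag$parents, use.names = FALSE))
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an entity -> term annotation TSV
#'
#' Two columns (`entity_id`, `term_id`), one pair per line, optional header.
#'
#' @param path File path.
#' @param entity_kind Entity kind for the resulting table.
#' @return A direct `annotation_table`.
#' @export
read_annotations <- function(path, entity_kind = "gene") {
  lines <- split_lines(path)
  if (length(lines) && grepl("^(entity|entity_id|id)\t", lines[[1]])) {
    lines <- lines[-1L]
  }
  if (!length(lines)) {
    return(annotation_table(entity_kind, stats::setNames(list(), character(0))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 2L)
  if (length(short)) parse_error(path, short[[1]], "expected 2 columns")
  ent <- vapply(parts, `[[`, character(1), 1L)
  term <- vapply(parts, `[[`, character(1), 2L)
  annotation_table(entity_kind, lapply(split(term, ent), unique))
}

#' Write annotations as a two-column TSV
#' @param tab An `annotation_table`.
#' @param path Output path.
#' @export
write_annotations <- function(tab, path) {
  df <- data.frame(
    entity = rep(names(tab$annotations), lengths(tab$annotations)),
    term = unlist(tab$annotations, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an IC table as TSV (term, frequency, ic)
#' @param ic An `ic_table`.
#' @param path Output path.
#' @export
write_ic_table <- function(ic, path) {
  df <- data.frame(term = names(ic$ic), frequency = unname(ic$frequency),
                   ic = unname(ic$ic))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a cohort TSV
#'
#' Columns: `patient_id, chrom, start, end, terms` where `terms` is a
#' pipe-separated list of phenotype term ids (possibly empty).
#'
#' @param path File path.
#' @return List with `cohort` data.frame and direct patient `annotations`.
#' @export
read_cohort <- function(path) {
  lines <- split_lines(path)
  if (length(lines) && startsWith(lines[[1]], "patient_id\t")) {
    lines <- lines[-1L]
  }
  if (!length(lines)) {
    return(list(cohort = data.frame(patient_id = character(0),
                                    chrom = character(0), start = numeric(0),
                                    end = numeric(0), stringsAsFactors = FALSE),
                annotations = annotation_table("patient",
                                               stats::setNames(list(), character(0)))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 4L) parse_error(path, i, "expected >= 4 columns")
    s <- suppressWarnings(as.numeric(p[[3]]))
    e <- suppressWarnings(as.numeric(p[[4]]))
    if (is.na(s) || is.na(e) || !(s >= 0 && s < e)) {
      parse_error(path, i, "malformed deletion interval")
    }
  }
  cohort <- data.frame(
    patient_id = vapply(parts, `[[`, character(1), 1L),
    chrom = vapply(parts, `[[`, character(1), 2L),
    start = as.numeric(vapply(parts, `[[`, character(1), 3L)),
    end = as.numeric(vapply(parts, `[[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  terms <- lapply(parts, function(p) {
    if (length(p) < 5L || !nzchar(p[[5]])) character(0) else
      strsplit(p[[5]], "|", fixed = TRUE)[[1]]
  })
  # multiple records per patient are allowed (largest is picked downstream);
  # annotations are pooled per patient id
  ann <- lapply(split(terms, cohort$patient_id), function(x)
    unique(unlist(x, use.names = FALSE)))
  list(cohort = cohort,
       annotations = annotation_table("patient", ann))
}

#' Write a cohort TSV
#' @param cohort Data.frame `patient_id,chrom,start,end`.
#' @param annotations Direct patient `annotation_table`.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, annotations, path) {
  terms <- vapply(cohort$patient_id, function(p)
    paste(annotations$annotations[[p]], collapse = "|"), character(1))
  df <- data.frame(patient_id = cohort$patient_id, chrom = cohort$chrom,
                   start = format(cohort$start, scientific = FALSE, trim = TRUE),
                   end = format(cohort$end, scientific = FALSE, trim = TRUE),
                   terms = terms, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a windowed count matrix TSV
#'
#' Header line `chrom start end <sample...>`; one row per window.
#'
#' @param path File path.
#' @return A `window_counts` object.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("count matrix needs chrom,start,end + samples")
  windows <- df[, 1:3]
  names(windows) <- c("chrom", "start", "end")
  counts <- as.matrix(df[, -(1:3), drop = FALSE])
  window_count_matrix(windows, counts)
}

#' Write a windowed count matrix TSV
#' @param wc A `window_counts` object.
#' @param path Output path.
#' @export
write_count_matrix <- function(wc, path) {
  df <- cbind(wc$windows, as.data.frame(wc$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a sample -> tissue design TSV
#' @param path File path (two columns: sample_id, tissue_label).
#' @return A `tissue_design`.
#' @export
read_design <- function(path) {
  lines <- split_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 2L)
  if (length(short)) parse_error(path, short[[1]], "expected 2 columns")
  tissue_design(vapply(parts, `[[`, character(1), 1L),
                vapply(parts, `[[`, character(1), 2L))
}

#' Read a target-term map TSV (tissue_label, term_id)
#' @param path File path.
#' @param dag Optional `ontology` for validation.
#' @return A `target_set`.
#' @export
read_targets <- function(path, dag = NULL) {
  lines <- split_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 2L)
  if (length(short)) parse_error(path, short[[1]], "expected 2 columns")
  target_term_set(vapply(parts, `[[`, character(1), 2L),
                  vapply(parts, `[[`, character(1), 1L), dag)
}

#' Write mechanism calls as TSV
#' @param calls Data.frame from [classify_cohort()].
#' @param path Output path.
#' @export
write_results <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Write the full synthetic input bundle to a directory
#'
#' Emits ontology edges, target map, gene annotations, domain/gene/enhancer
#' BED files, chromosome sizes, the cohort with phenotypes, ground-truth
#' labels, the DNase count matrix with its design, and a config echo
#' (JSON) -- everything [run_pipeline()] consumes.
#'
#' @param config A `simulation_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
simulate_bundle <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- generate_all(config)
  p <- function(f) file.path(dir, f)
  write_ontology(sim$dag, p("ontology.tsv"))
  utils::write.table(
    data.frame(tissue = sim$targets$tissue, term = sim$targets$term),
    p("targets.tsv"), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_annotations(sim$gene_annotations, p("gene_annotations.tsv"))
  write_bed(sim$arch$domains, p("domains.bed"))
  write_bed(sim$arch$genes, p("genes.bed"))
  write_bed(sim$arch$enhancers, p("enhancers.bed"))
  utils::write.table(
    data.frame(chrom = names(sim$arch$chrom_lengths),
               length = format(sim$arch$chrom_lengths, scientific = FALSE,
                               trim = TRUE)),
    p("chrom.sizes"), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_cohort(sim$cohort, sim$patient_annotations, p("cohort.tsv"))
  utils::write.table(sim$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  write_count_matrix(sim$dnase$counts, p("dnase_counts.tsv"))
  utils::write.table(
    data.frame(sample = sim$dnase$design$samples,
               tissue = sim$dnase$design$tissues),
    p("dnase_design.tsv"), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  jsonlite::write_json(config[setdiff(names(config), "dnase")],
                       p("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(list.files(dir, full.names = TRUE))
}
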