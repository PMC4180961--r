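# Synthetic-data generator: a stated world with planted ground truth for
# every pipeline input -- ontology, annotations, genome architecture,
# deletion cohort and DNase window counts.

DEFAULT_TISSUES <- c("fetal_brain", "fetal_heart", "fetal_kidney",
                     "fetal_lung", "fetal_muscle", "fetal_intestine",
                     "fetal_stomach", "fetal_adrenal", "fetal_thymus",
                     "white_blood_cells")

#' Simulation configuration
#'
#' Captures the stated world of the generator: ontology shape, genome
#' architecture, cohort mixture, annotation noise and the DNase count model.
#' Defaults emulate a deletion cohort over a domain-partitioned genome with
#' ten tissue branches.
#'
#' @param seed Top-level integer seed; every generator derives its own
#'   substream from it.
#' @param n_targets Number of target phenotype branches (10).
#' @param subtree_depth,branching Shape of each target's full k-ary subtree.
#' @param n_patients Cohort size.
#' @param mixture Named fractions `tdbd, mixed, gde, benign`; must sum to 1.
#' @param noise Annotation noise: probability that a planted phenotype term
#'   is replaced by a uniformly random ontology term.
#' @param n_chrom,domains_per_chrom Genome layout.
#' @param domain_range,gap_range Domain and boundary-gap length ranges (bp);
#'   gaps never exceed 400 kb.
#' @param frac_large_gaps Fraction of inter-domain gaps drawn from
#'   `large_gap_range` instead (unorganized chromatin, > 400 kb, so they do
#'   not become boundaries).
#' @param large_gap_range Length range of unorganized gaps.
#' @param genes_per_domain,gene_width Genes placed per domain and their size.
#' @param fraction_unannotated Exact fraction of genes left without
#'   phenotype annotation.
#' @param terms_per_gene_range Annotated genes draw this many terms from one
#'   target subtree.
#' @param enhancer_width Enhancer interval size; every domain carries one
#'   enhancer of each tissue (roughly the genome-wide density of the top
#'   20,000 sites per tissue spread over ~3,000 domains).
#' @param null_phenotypes If `TRUE`, patient phenotypes are redrawn
#'   independently of the deletion geometry after planting (a cohort
#'   generated under the null, used for calibration of permutation tests).
#' @param dnase List for the count-matrix generator: `n_windows`,
#'   `n_tissues`, `n_replicates`, `background_mean`, `planted_per_tissue`,
#'   `effect` (log-scale), `depth_range`, optional negative-binomial `size`
#'   (NULL = Poisson).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              n_targets = 10,
                              subtree_depth = 3,
                              branching = 3,
                              n_patients = 200,
                              mixture = c(tdbd = 0.1, mixed = 0.2,
                                          gde = 0.6, benign = 0.1),
                              noise = 0,
                              n_chrom = 2,
                              domains_per_chrom = 200,
                              domain_range = c(6e5, 1.4e6),
                              gap_range = c(1e5, 4e5),
                              frac_large_gaps = 0.05,
                              large_gap_range = c(5e5, 8e5),
                              genes_per_domain = 3,
                              gene_width = 1e4,
                              fraction_unannotated = 0.2,
                              terms_per_gene_range = c(1, 5),
                              enhancer_width = 1e3,
                              null_phenotypes = FALSE,
                              dnase = list()) {
  stopifnot(all(c("tdbd", "mixed", "gde", "benign") %in% names(mixture)))
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture fractions must sum to 1")
  stopifnot(n_patients > 0, n_targets > 0, domains_per_chrom > 0,
            noise >= 0, noise <= 1, gap_range[[2]] <= MAX_BOUNDARY_GAP)
  dn <- utils::modifyList(
    list(n_windows = 10000, n_tissues = 4, n_replicates = 4,
         background_mean = 20, planted_per_tissue = 200, effect = 2,
         depth_range = c(0.5, 2), size = NULL),
    dnase)
  structure(list(
    seed = as.integer(seed), n_targets = n_targets,
    subtree_depth = subtree_depth, branching = branching,
    n_patients = n_patients, mixture = mixture, noise = noise,
    n_chrom = n_chrom, domains_per_chrom = domains_per_chrom,
    domain_range = domain_range, gap_range = gap_range,
    frac_large_gaps = frac_large_gaps, large_gap_range = large_gap_range,
    genes_per_domain = genes_per_domain, gene_width = gene_width,
    fraction_unannotated = fraction_unannotated,
    terms_per_gene_range = terms_per_gene_range,
    enhancer_width = enhancer_width,
    null_phenotypes = isTRUE(null_phenotypes),
    n_genes = genes_per_domain * domains_per_chrom * n_chrom,
    dnase = dn), class = "simulation_config")
}

sub_seed <- function(config, offset) (config$seed + offset) %% .Machine$integer.max

#' Generate the synthetic ontology and target set
#'
#' A single root with `n_targets` disjoint target branches, each a full
#' k-ary subtree of the configured depth. Structure is deterministic given
#' the shape (no randomness needed).
#'
#' @param config A `simulation_config`.
#' @return List with `dag` (an `ontology`) and `targets` (a `target_set`).
#' @export
generate_ontology <- function(config) {
  root <- "T:ROOT"
  child <- character(0)
  parent <- character(0)
  add_subtree <- function(node, depth) {
    if (depth == 0) return(invisible(NULL))
    for (b in seq_len(config$branching)) {
      ch <- paste0(node, ".", b)
      child <<- c(child, ch)
      parent <<- c(parent, node)
      add_subtree(ch, depth - 1)
    }
  }
  for (i in seq_len(config$n_targets)) {
    tgt <- sprintf("T:%02d", i)
    child <- c(child, tgt)
    parent <- c(parent, root)
    add_subtree(tgt, config$subtree_depth)
  }
  dag <- ontology_dag(child, parent)
  tissues <- if (config$n_targets <= length(DEFAULT_TISSUES)) {
    DEFAULT_TISSUES[seq_len(config$n_targets)]
  } else {
    paste0("tissue_", seq_len(config$n_targets))
  }
  targets <- target_term_set(sprintf("T:%02d", seq_len(config$n_targets)),
                             tissues, dag)
  list(dag = dag, targets = targets)
}

#' Generate gene phenotype annotations
#'
#' Each phenotypically active gene is annotated to 1-5 terms drawn from a
#' single target subtree; an exact fraction of genes stays unannotated
#' (genes without a known disease association).
#'
#' @param dag The synthetic `ontology`.
#' @param targets Its `target_set`.
#' @param config A `simulation_config`.
#' @return A direct gene `annotation_table`; `attr(, "gene_target")` records
#'   each annotated gene's target branch.
#' @export
generate_gene_annotations <- function(dag, targets, config) {
  set.seed(sub_seed(config, 1))
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  n_un <- round(config$fraction_unannotated * config$n_genes)
  unannotated <- sample(gene_ids, n_un)
  desc_sets <- lapply(targets$term, descendants, dag = dag)
  names(desc_sets) <- targets$term
  ann <- list()
  gene_target <- character(0)
  for (g in gene_ids) {
    if (g %in% unannotated) next
    tgt <- sample(targets$term, 1L)
    k <- sample(seq(config$terms_per_gene_range[[1]],
                    config$terms_per_gene_range[[2]]), 1L)
    pool <- desc_sets[[tgt]]
    ann[[g]] <- sample(pool, min(k, length(pool)))
    gene_target[[g]] <- tgt
  }
  out <- annotation_table("gene", ann, propagated = FALSE)
  attr(out, "gene_target") <- gene_target
  attr(out, "all_gene_ids") <- gene_ids
  out
}

#' Generate the synthetic genome architecture
#'
#' Chromosomes alternate domains and gaps; gaps at most 400 kb become
#' boundaries (an exact round-trip of [derive_boundaries()]), a small
#' fraction are longer "unorganized" gaps. Genes sit at fixed interior
#' fractions of each domain and every domain carries one enhancer of each
#' tissue near its start.
#'
#' @param config A `simulation_config`.
#' @param targets The `target_set` (supplies tissue labels).
#' @return A `genome_architecture`.
#' @export
generate_architecture <- function(config, targets) {
  set.seed(sub_seed(config, 2))
  tissues <- targets$tissue
  domains <- genes <- enhancers <- list()
  chrom_lengths <- numeric(0)
  gene_counter <- 0L
  for (c_i in seq_len(config$n_chrom)) {
    chrom <- paste0("chr", c_i)
    pos <- 0
    for (d_i in seq_len(config$domains_per_chrom)) {
      dlen <- round(stats::runif(1, config$domain_range[[1]],
                                 config$domain_range[[2]]))
      dstart <- pos
      dend <- pos + dlen
      domains[[length(domains) + 1L]] <-
        data.frame(chrom = chrom, start = dstart, end = dend,
                   stringsAsFactors = FALSE)
      # genes at interior fractions 1/(n+1), ..., n/(n+1)
      for (k in seq_len(config$genes_per_domain)) {
        gene_counter <- gene_counter + 1L
        gs <- round(dstart + dlen * k / (config$genes_per_domain + 1))
        genes[[length(genes) + 1L]] <-
          data.frame(chrom = chrom, start = gs,
                     end = gs + config$gene_width,
                     gene_id = sprintf("g%04d", gene_counter),
                     stringsAsFactors = FALSE)
      }
      # one enhancer per tissue clustered near the domain start
      es <- round(dstart + dlen * 0.02) +
        (seq_along(tissues) - 1L) * 2L * config$enhancer_width
      enhancers[[length(enhancers) + 1L]] <-
        data.frame(chrom = chrom, start = es,
                   end = es + config$enhancer_width, tissue = tissues,
                   stringsAsFactors = FALSE)
      pos <- dend
      if (d_i < config$domains_per_chrom) {
        large <- stats::runif(1) < config$frac_large_gaps
        gap <- if (large) {
          round(stats::runif(1, config$large_gap_range[[1]],
                             config$large_gap_range[[2]]))
        } else {
          round(stats::runif(1, config$gap_range[[1]],
                             config$gap_range[[2]]))
        }
        pos <- pos + gap
      }
    }
    chrom_lengths[[chrom]] <- pos + 5e5
  }
  genome_architecture(chrom_lengths,
                      do.call(rbind, domains),
                      do.call(rbind, genes),
                      do.call(rbind, enhancers))
}

# deterministic allocation of category counts (largest-remainder on rounding)
mixture_counts <- function(mixture, n) {
  counts <- floor(mixture * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- mixture * n - counts
    bump <- order(-frac)[seq_len(rem)]
    counts[bump] <- counts[bump] + 1
  }
  stats::setNames(as.integer(counts), names(mixture))
}

#' Generate a deletion cohort with planted mechanisms
#'
#' Mechanism labels are allocated deterministically from the mixture
#' fractions. Boundary-disruption (tdbd) patients get a deletion that covers
#' one boundary, contains no gene, and has a tissue-matched enhancer in one
#' domain-bounded adjacent region and a gene of the matching target branch
#' in the other; mixed patients additionally contain an annotated gene whose
#' similarity at least matches the adjacent genes'; gde patients delete an
#' annotated gene without touching a boundary; benign patients get deletions
#' in gene- and boundary-free territory with random phenotypes. Planted
#' phenotype terms are the relevant gene's own terms; annotation noise is
#' applied last.
#'
#' @param arch A `genome_architecture` from [generate_architecture()].
#' @param dag,targets The synthetic ontology and target set.
#' @param gene_annotations Direct gene `annotation_table`.
#' @param config A `simulation_config`.
#' @return List: `cohort` (data.frame `patient_id,chrom,start,end`),
#'   `annotations` (direct patient `annotation_table`), `truth` (data.frame
#'   `patient_id,mechanism`).
#' @export
generate_cohort <- function(arch, dag, targets, gene_annotations, config) {
  set.seed(sub_seed(config, 3))
  counts <- mixture_counts(config$mixture, config$n_patients)
  gene_target <- attr(gene_annotations, "gene_target")
  gene_prop <- propagate(dag, gene_annotations)
  ic_genes <- information_content(dag, gene_prop, corpus_id = "genes")
  term_sets <- gene_annotations$annotations

  genes <- arch$genes
  doms <- arch$domains
  dom_key <- paste0(doms$chrom, ":", doms$start)
  gene_dom <- match(paste0(genes$chrom, ":",
                           vapply(seq_len(nrow(genes)), function(i) {
                             d <- doms[doms$chrom == genes$chrom[[i]] &
                                         doms$start <= genes$start[[i]] &
                                         genes$start[[i]] < doms$end, , drop = FALSE]
                             d$start[[1]]
                           }, numeric(1))), dom_key)
  genes_of_domain <- split(seq_len(nrow(genes)), gene_dom)

  annotated_in_domain <- function(d) {
    g <- genes_of_domain[[as.character(d)]]
    g[genes$gene_id[g] %in% names(term_sets)]
  }
  # consecutive same-chromosome domain pairs separated by a true boundary
  bnd <- arch$boundaries
  pair_left <- match(paste0(bnd$chrom, ":",
                            vapply(seq_len(nrow(bnd)), function(i) {
                              d <- doms[doms$chrom == bnd$chrom[[i]] &
                                          doms$end == bnd$start[[i]], , drop = FALSE]
                              d$start[[1]]
                            }, numeric(1))), dom_key)
  pair_right <- match(paste0(bnd$chrom, ":", bnd$end), dom_key)

  region_score <- function(region, annot) {
    ids <- genes_in_region(genes, region$chrom, region$start, region$end)
    phenogram_score(term_sets[intersect(ids, names(term_sets))], annot,
                    ic_genes, dag)
  }
  adjacency_scores <- function(deletion, annot) {
    adj <- adjacent_regions(deletion, arch)
    c(within = region_score(deletion, annot),
      adjacent = max(region_score(adj$left, annot),
                     region_score(adj$right, annot)))
  }

  patients <- list()
  truth <- character(0)
  annots <- list()
  pid_counter <- 0L
  add_patient <- function(deletion, terms, mechanism) {
    pid_counter <<- pid_counter + 1L
    pid <- sprintf("P%04d", pid_counter)
    patients[[pid]] <<- data.frame(patient_id = pid, chrom = deletion$chrom,
                                   start = deletion$start,
                                   end = deletion$end,
                                   stringsAsFactors = FALSE)
    annots[[pid]] <<- terms
    truth[[pid]] <<- mechanism
  }

  # --- tdbd: deletion over one boundary, gene-free, signature across it
  bnd_order <- sample(nrow(bnd))
  b_cursor <- 1L
  n_bnd <- nrow(bnd)
  next_boundary <- function() {
    if (b_cursor > n_bnd) return(NA_integer_)
    i <- bnd_order[[b_cursor]]
    b_cursor <<- b_cursor + 1L
    i
  }
  plant_tdbd <- function() {
    repeat {
      b <- next_boundary()
      if (is.na(b)) return(FALSE)
      dl <- pair_left[[b]]; dr <- pair_right[[b]]
      if (is.na(dl) || is.na(dr)) next
      cand <- annotated_in_domain(dr)
      if (!length(cand)) next
      g_adj <- genes$gene_id[[cand[[sample.int(length(cand), 1L)]]]]
      tau <- gene_target[[g_adj]]
      Ldom <- doms[dl, ]; Rdom <- doms[dr, ]
      deletion <- list(chrom = Ldom$chrom,
                       start = round(Ldom$start + 0.9 * (Ldom$end - Ldom$start)),
                       end = round(Rdom$start + 0.1 * (Rdom$end - Rdom$start)))
      terms <- term_sets[[g_adj]]
      sc <- adjacency_scores(deletion,
                             unique(unlist(dag$anc[terms], use.names = FALSE)))
      if (sc[["within"]] == 0 && sc[["adjacent"]] > 0) {
        add_patient(deletion, terms, "tdbd")
        return(TRUE)
      }
    }
  }

  # --- mixed: deletion over boundary(ies) containing a same-target gene
  plant_mixed <- function() {
    repeat {
      b <- next_boundary()
      if (is.na(b)) return(FALSE)
      dl <- pair_left[[b]]; dr <- pair_right[[b]]
      if (is.na(dl) || is.na(dr)) next
      # deletion spans from inside domain dl across >= 1 full domain up to
      # inside a later domain on the same chromosome
      chrom <- doms$chrom[[dl]]
      later <- which(doms$chrom == chrom & doms$start > doms$start[[dr]])
      ends <- c(dr + 1L, dr + 2L)
      ends <- ends[ends %in% later]
      done <- FALSE
      for (de in ends) {
        contained <- setdiff(seq(dr, de - 1L), NA)
        cand_in <- unlist(lapply(contained, annotated_in_domain))
        cand_adj <- annotated_in_domain(de)
        if (!length(cand_in) || !length(cand_adj)) next
        for (ga in cand_adj[sample.int(length(cand_adj))]) {
          g_adj <- genes$gene_id[[ga]]
          tau <- gene_target[[g_adj]]
          same <- cand_in[vapply(cand_in, function(gi)
            identical(gene_target[[genes$gene_id[[gi]]]], tau), logical(1))]
          if (!length(same)) next
          for (gi in same[sample.int(length(same))]) {
            g_in <- genes$gene_id[[gi]]
            Ldom <- doms[dl, ]; Edom <- doms[de, ]
            deletion <- list(
              chrom = chrom,
              start = round(Ldom$start + 0.9 * (Ldom$end - Ldom$start)),
              end = round(Edom$start + 0.1 * (Edom$end - Edom$start)))
            terms <- term_sets[[g_in]]
            annot <- unique(unlist(dag$anc[terms], use.names = FALSE))
            sc <- adjacency_scores(deletion, annot)
            if (sc[["within"]] > 0 && sc[["within"]] >= sc[["adjacent"]]) {
              add_patient(deletion, terms, "mixed")
              done <- TRUE
              break
            }
          }
          if (done) break
        }
        if (done) break
      }
      if (done) return(TRUE)
    }
  }

  # --- gde and benign use single domains
  dom_order <- sample(nrow(doms))
  d_cursor <- 1L
  next_domain <- function() {
    if (d_cursor > nrow(doms)) return(NA_integer_)
    i <- dom_order[[d_cursor]]
    d_cursor <<- d_cursor + 1L
    i
  }
  plant_gde <- function() {
    repeat {
      d <- next_domain()
      if (is.na(d)) return(FALSE)
      cand <- annotated_in_domain(d)
      if (!length(cand)) next
      g <- genes$gene_id[[cand[[sample.int(length(cand), 1L)]]]]
      D <- doms[d, ]
      dlen <- D$end - D$start
      deletion <- list(chrom = D$chrom,
                       start = round(D$start + 0.15 * dlen),
                       end = round(D$start + 0.8 * dlen))
      terms <- term_sets[[g]]
      annot <- unique(unlist(dag$anc[terms], use.names = FALSE))
      sc <- adjacency_scores(deletion, annot)
      if (sc[["within"]] > 0) {
        add_patient(deletion, terms, "gde")
        return(TRUE)
      }
    }
  }
  plant_benign <- function() {
    d <- next_domain()
    if (is.na(d)) return(FALSE)
    D <- doms[d, ]
    dlen <- D$end - D$start
    # between the genes at fractions 0.5 and 0.75 (gene width << domain)
    deletion <- list(chrom = D$chrom,
                     start = round(D$start + 0.55 * dlen),
                     end = round(D$start + 0.7 * dlen))
    tgt <- sample(targets$term, 1L)
    pool <- descendants(dag, tgt)
    terms <- sample(pool, min(sample(1:3, 1L), length(pool)))
    add_patient(deletion, terms, "benign")
    TRUE
  }

  planters <- list(tdbd = plant_tdbd, mixed = plant_mixed,
                   gde = plant_gde, benign = plant_benign)
  for (mech in names(counts)) {
    for (i in seq_len(counts[[mech]])) {
      if (!planters[[mech]]()) {
        stop("architecture too small to place the requested mixture (",
             mech, " patient ", i, " of ", counts[[mech]], ")")
      }
    }
  }

  # null mode: sever the mechanism-phenotype linkage by redrawing every
  # patient's phenotype independently of the deletion geometry
  if (config$null_phenotypes) {
    annots <- lapply(annots, function(ts) {
      tgt <- sample(targets$term, 1L)
      pool <- descendants(dag, tgt)
      sample(pool, min(sample(1:3, 1L), length(pool)))
    })
  }

  # annotation noise: each planted term replaced by a uniform random term
  if (config$noise > 0) {
    all_terms <- dag$terms
    annots <- lapply(annots, function(ts) {
      hit <- stats::runif(length(ts)) < config$noise
      ts[hit] <- sample(all_terms, sum(hit), replace = TRUE)
      unique(ts)
    })
  }

  cohort <- do.call(rbind, patients)
  rownames(cohort) <- NULL
  list(cohort = cohort,
       annotations = annotation_table("patient", annots, propagated = FALSE),
       truth = data.frame(patient_id = cohort$patient_id,
                          mechanism = unname(truth[cohort$patient_id]),
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic DNase window count matrix
#'
#' Background counts are Poisson with the configured mean (or negative
#' binomial when `size` is set); for each tissue, its planted windows have
#' the mean multiplied by `exp(effect)` in that tissue's samples only.
#' Per-sample depth factors scale the means so normalisation is exercised.
#'
#' @param config A `simulation_config` (`config$dnase` holds the model).
#' @return List: `counts` (a `window_counts`), `design` (a `tissue_design`),
#'   `truth` (list tissue -> planted window indices), `depth_factors`.
#' @export
generate_count_matrix <- function(config) {
  dn <- config$dnase
  set.seed(sub_seed(config, 4))
  tissues <- paste0("tissue", seq_len(dn$n_tissues))
  samples <- as.vector(vapply(tissues, function(ti)
    paste0(ti, "_rep", seq_len(dn$n_replicates)),
    character(dn$n_replicates)))
  design <- tissue_design(samples, rep(tissues, each = dn$n_replicates))
  n_w <- dn$n_windows
  if (dn$planted_per_tissue * dn$n_tissues > n_w) {
    stop("more planted windows than windows available")
  }
  planted_all <- sample.int(n_w, dn$planted_per_tissue * dn$n_tissues)
  truth <- split(planted_all,
                 rep(tissues, each = dn$planted_per_tissue))
  depth <- stats::runif(length(samples), dn$depth_range[[1]],
                        dn$depth_range[[2]])
  names(depth) <- samples
  counts <- matrix(0L, n_w, length(samples),
                   dimnames = list(NULL, samples))
  for (s in seq_along(samples)) {
    mu <- rep(dn$background_mean, n_w)
    ti <- design$tissues[[s]]
    mu[truth[[ti]]] <- mu[truth[[ti]]] * exp(dn$effect)
    mu <- mu * depth[[s]]
    counts[, s] <- if (is.null(dn$size)) {
      stats::rpois(n_w, mu)
    } else {
      stats::rnbinom(n_w, mu = mu, size = dn$size)
    }
  }
  windows <- data.frame(chrom = "chrW", start = (seq_len(n_w) - 1L) * 200L,
                        end = seq_len(n_w) * 200L, stringsAsFactors = FALSE)
  list(counts = window_count_matrix(windows, counts), design = design,
       truth = truth, depth_factors = depth)
}

#' Generate the full synthetic input bundle
#'
#' Convenience wrapper running every generator off one config.
#'
#' @param config A `simulation_config`.
#' @return List with `dag`, `targets`, `gene_annotations`, `arch`,
#'   `cohort`, `patient_annotations`, `truth`, `dnase`.
#' @export
generate_all <- function(config = simulation_config()) {
  onto <- generate_ontology(config)
  gene_ann <- generate_gene_annotations(onto$dag, onto$targets, config)
  arch <- generate_architecture(config, onto$targets)
  coh <- generate_cohort(arch, onto$dag, onto$targets, gene_ann, config)
  dn <- generate_count_matrix(config)
  list(dag = onto$dag, targets = onto$targets, gene_annotations = gene_ann,
       arch = arch, cohort = coh$cohort,
       patient_annotations = coh$annotations, truth = coh$truth,
       dnase = dn)
}
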