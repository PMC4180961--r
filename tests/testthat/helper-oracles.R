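# Independent brute-force oracles and tiny fixtures. The oracles only use
# the raw edge lists / matrices, never the package's precomputed structures.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ancestor closure by repeated expansion over the edge list (includes t)
oracle_ancestors <- function(child, parent, t) {
  out <- t
  repeat {
    nxt <- unique(c(out, parent[child %in% out]))
    if (length(nxt) == length(out)) return(sort(out))
    out <- nxt
  }
}

oracle_descendants <- function(child, parent, t) {
  terms <- unique(c(child, parent))
  sort(terms[vapply(terms, function(x)
    t %in% oracle_ancestors(child, parent, x), logical(1))])
}

oracle_propagate <- function(child, parent, sets) {
  lapply(sets, function(ts)
    sort(unique(unlist(lapply(ts, oracle_ancestors, child = child,
                              parent = parent)))))
}

# corpus IC from direct annotation sets
oracle_ic <- function(child, parent, sets) {
  prop <- oracle_propagate(child, parent, sets)
  counts <- table(unlist(prop))
  -log(as.numeric(counts) / length(sets)) -> ic
  names(ic) <- names(counts)
  ic
}

# phenomatch by exhaustive enumeration of (gene term, common ancestor) pairs
oracle_phenomatch <- function(child, parent, gene_terms, annot_direct, ic) {
  if (!length(gene_terms)) return(0)
  annot_closure <- unique(unlist(lapply(annot_direct, oracle_ancestors,
                                        child = child, parent = parent)))
  sum(vapply(gene_terms, function(tg) {
    ca <- intersect(oracle_ancestors(child, parent, tg), annot_closure)
    vals <- ic[ca]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) 0 else max(vals)
  }, numeric(1)))
}

# random DAG: term 1 is the root; term i >= 2 draws 1-2 parents among 1..i-1
rand_dag_edges <- function(n, seed) {
  set.seed(seed)
  child <- parent <- character(0)
  ids <- paste0("t", seq_len(n))
  for (i in 2:n) {
    k <- sample(1:2, 1)
    ps <- sample(i - 1, min(k, i - 1))
    child <- c(child, rep(ids[[i]], length(ps)))
    parent <- c(parent, ids[ps])
  }
  list(child = child, parent = parent, ids = ids)
}

# naive per-window pooled sd and t-statistics, straight from the formulas
naive_pooled_sd <- function(X, tissues) {
  vapply(seq_len(nrow(X)), function(w) {
    ss <- 0; df <- 0
    for (ti in unique(tissues)) {
      idx <- which(tissues == ti)
      if (length(idx) < 2) next
      xb <- mean(X[w, idx])
      ss <- ss + sum((X[w, idx] - xb)^2)
      df <- df + length(idx) - 1
    }
    sqrt(ss / df)
  }, numeric(1))
}

naive_tstats <- function(X, tissues) {
  uts <- unique(tissues)
  m <- length(uts)
  s <- naive_pooled_sd(X, tissues)
  s0 <- mean(s)
  out <- matrix(0, nrow(X), m, dimnames = list(NULL, uts))
  for (w in seq_len(nrow(X))) {
    tm <- vapply(uts, function(ti) mean(X[w, tissues == ti]), numeric(1))
    xbar <- mean(tm)
    for (j in seq_len(m)) {
      nj <- sum(tissues == uts[[j]])
      out[w, j] <- (tm[[j]] - xbar) / (sqrt(1 / m + 1 / nj) * (s[[w]] + s0))
    }
  }
  out
}

# quadratic all-pairs complete-overlap counts
quad_complete_counts <- function(deletions, features) {
  vapply(seq_len(nrow(deletions)), function(i) {
    sum(vapply(seq_len(nrow(features)), function(j) {
      features$chrom[[j]] == deletions$chrom[[i]] &&
        deletions$start[[i]] <= features$start[[j]] &&
        features$end[[j]] <= deletions$end[[i]]
    }, logical(1)))
  }, integer(1))
}

# ---------------------------------------------------------------------------
# shared fixtures

# diamond: root <- A <- {A1, A2}; root <- B <- B1; D has parents A1 and B
toy_dag <- function() {
  ontology_dag(child = c("A", "B", "A1", "A2", "B1", "D", "D"),
               parent = c("root", "root", "A", "A", "B", "A1", "B"))
}

# two-branch target ontology + small genome used by classification tests
toy_world <- function() {
  dag <- ontology_dag(
    child = c("T1", "T2", "t1a", "t1b", "t2a"),
    parent = c("root", "root", "T1", "T1", "T2"))
  targets <- target_term_set(c("T1", "T2"), c("brain", "heart"), dag)
  genes <- data.frame(
    chrom = "c1",
    start = c(0.5e6, 1.7e6, 2.0e6, 2.9e6),
    end = c(0.51e6, 1.71e6, 2.01e6, 2.91e6),
    gene_id = c("gA", "gB", "gD", "gC"), stringsAsFactors = FALSE)
  enhancers <- data.frame(
    chrom = "c1", start = c(0.1e6, 2.5e6), end = c(0.101e6, 2.501e6),
    tissue = c("brain", "heart"), stringsAsFactors = FALSE)
  domains <- data.frame(chrom = "c1",
                        start = c(0, 1.2e6, 2.4e6),
                        end = c(1e6, 2.2e6, 3.4e6), stringsAsFactors = FALSE)
  arch <- genome_architecture(c(c1 = 10e6), domains, genes, enhancers)
  gene_ann <- annotation_table("gene", list(gB = "t1a", gD = "t1b",
                                            gC = "t2a"))
  gene_prop <- propagate(dag, gene_ann)
  ic_genes <- information_content(dag, gene_prop, "genes")
  list(dag = dag, targets = targets, arch = arch, gene_ann = gene_ann,
       gene_prop = gene_prop, ic_genes = ic_genes)
}

# small simulation config for fast unit tests
small_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_patients = 40, domains_per_chrom = 60,
                    ...)
}
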