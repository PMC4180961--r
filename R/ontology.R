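# Rooted-DAG phenotype ontology: construction, traversal, annotation
# propagation and corpus-specific information content.

#' Construct a rooted phenotype ontology DAG
#'
#' Builds an ontology from child -> parent edges, validates that the graph is
#' acyclic with a single root, and precomputes the ancestor closure of every
#' term (each term is an ancestor of itself).
#'
#' @param child,parent Character vectors of equal length; each pair is one
#'   `is_a` edge from the more specific `child` term to its `parent`.
#' @return An object of class `ontology` with elements `terms`, `parents`,
#'   `children`, `root` and the precomputed ancestor list `anc`.
#' @examples
#' dag <- ontology_dag(child = c("a", "b"), parent = c("b", "root"))
#' ancestors(dag, "a")
#' @export
ontology_dag <- function(child, parent) {
  stopifnot(is.character(child), is.character(parent),
            length(child) == length(parent))
  if (any(child == parent)) {
    stop("self-loop edge(s): ", paste(unique(child[child == parent]), collapse = ", "))
  }
  terms <- sort(unique(c(child, parent)))
  parents <- split(parent, factor(child, levels = terms))
  parents <- lapply(parents, unique)
  children <- split(child, factor(parent, levels = terms))
  children <- lapply(children, unique)

  roots <- terms[lengths(parents) == 0L]
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root; found ",
         length(roots), ": ", paste(utils::head(roots, 5L), collapse = ", "))
  }
  root <- roots

  # Kahn topological sort from the root downwards; leftovers indicate cycles.
  indeg <- lengths(parents)
  queue <- root
  topo <- character(0)
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) != length(terms)) {
    bad <- setdiff(terms, topo)
    stop("ontology contains a cycle or terms unreachable from the root: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }

  # Ancestor closure in topological order (parents are processed first).
  anc <- vector("list", length(terms))
  names(anc) <- terms
  for (t in topo) {
    ps <- parents[[t]]
    anc[[t]] <- if (length(ps)) {
      unique(c(t, unlist(anc[ps], use.names = FALSE)))
    } else {
      t
    }
  }

  structure(
    list(terms = terms, parents = parents, children = children,
         root = root, anc = anc),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology DAG:", length(x$terms), "terms, root =", x$root, "\n")
  invisible(x)
}

check_terms <- function(dag, t, what = "term") {
  missing <- setdiff(t, dag$terms)
  if (length(missing)) {
    stop("unknown ", what, "(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Ancestors of a term (including the term itself)
#'
#' @param dag An `ontology` object.
#' @param t A single term identifier.
#' @return Character vector of all terms reachable from `t` via parent edges,
#'   including `t`.
#' @export
ancestors <- function(dag, t) {
  stopifnot(inherits(dag, "ontology"), length(t) == 1L)
  check_terms(dag, t)
  dag$anc[[t]]
}

#' Descendants of a term (including the term itself)
#'
#' `descendants(dag, t)` is the set of terms whose ancestor set contains `t`;
#' for the root it is every term.
#'
#' @inheritParams ancestors
#' @return Character vector of descendant terms, including `t`.
#' @export
descendants <- function(dag, t) {
  stopifnot(inherits(dag, "ontology"), length(t) == 1L)
  check_terms(dag, t)
  out <- t
  frontier <- t
  while (length(frontier)) {
    nxt <- unique(unlist(dag$children[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Create an annotation table
#'
#' Maps entities (patients, genes or diseases) to sets of ontology terms.
#' Direct tables carry the curated terms; [propagate()] replaces each set by
#' its ancestor closure.
#'
#' @param entity_kind One of `"patient"`, `"gene"`, `"disease"`.
#' @param annotations Named list; each element is a character vector of term
#'   identifiers for one entity.
#' @param propagated Logical flag: has the ancestor closure been applied?
#' @return An object of class `annotation_table`.
#' @export
annotation_table <- function(entity_kind = c("patient", "gene", "disease"),
                             annotations, propagated = FALSE) {
  entity_kind <- match.arg(entity_kind)
  stopifnot(is.list(annotations))
  if (is.null(names(annotations)) && length(annotations)) {
    stop("annotations must be a named list (entity id -> term set)")
  }
  annotations <- lapply(annotations, function(x) unique(as.character(x)))
  structure(list(entity_kind = entity_kind, annotations = annotations,
                 propagated = isTRUE(propagated)),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("annotation_table (", x$entity_kind, "): ", length(x$annotations),
      " entities, ", if (x$propagated) "propagated" else "direct", "\n", sep = "")
  invisible(x)
}

#' Propagate annotations up the ontology
#'
#' Applies the annotation propagation rule: an entity annotated to a term is
#' implicitly annotated to every ancestor of that term. The result is
#' ancestor-closed and a fixed point of the operation.
#'
#' @param dag An `ontology` object.
#' @param tab An `annotation_table`.
#' @return The propagated `annotation_table`.
#' @export
propagate <- function(dag, tab) {
  stopifnot(inherits(dag, "ontology"), inherits(tab, "annotation_table"))
  for (ent in names(tab$annotations)) {
    missing <- setdiff(tab$annotations[[ent]], dag$terms)
    if (length(missing)) {
      stop("entity '", ent, "' annotated to unknown term(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  prop <- lapply(tab$annotations, function(ts) {
    if (!length(ts)) return(character(0))
    unique(unlist(dag$anc[ts], use.names = FALSE))
  })
  annotation_table(tab$entity_kind, prop, propagated = TRUE)
}

#' Corpus-specific information content
#'
#' For every term `t`, the annotation frequency `p_t` is the fraction of
#' annotated entities whose propagated term set contains `t`, and the
#' information content is `IC(t) = -ln(p_t)` (natural log). Terms to which no
#' entity is annotated have undefined frequency and are absent from the table;
#' downstream scoring treats them as contributing nothing.
#'
#' @param dag An `ontology` object.
#' @param tab A propagated `annotation_table` with at least one entity.
#' @param corpus_id Label for the corpus (e.g. `"patients"`, `"genes"`).
#' @return An object of class `ic_table` with named numeric vectors
#'   `frequency` and `ic`.
#' @export
information_content <- function(dag, tab, corpus_id = tab$entity_kind) {
  stopifnot(inherits(dag, "ontology"), inherits(tab, "annotation_table"))
  if (!tab$propagated) stop("annotations must be propagated before computing IC")
  n <- length(tab$annotations)
  if (n == 0L) stop("empty annotation corpus: no entities")
  counts <- table(unlist(tab$annotations, use.names = FALSE))
  check_terms(dag, names(counts), what = "annotated term")
  freq <- as.numeric(counts) / n
  names(freq) <- names(counts)
  structure(list(corpus_id = corpus_id, frequency = freq, ic = -log(freq)),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat("ic_table (corpus: ", x$corpus_id, "): ", length(x$ic),
      " terms with defined IC\n", sep = "")
  invisible(x)
}

# IC of terms, 0 for terms without a defined value. Internal lookup helper.
ic_values <- function(ic, terms) {
  v <- ic$ic[terms]
  v[is.na(v)] <- 0
  unname(v)
}

# Max IC over a term set; terms with undefined IC are absent from the max,
# and an all-undefined set scores 0 (the root always has IC 0 anyway).
max_ic <- function(ic, terms) {
  if (!length(terms)) return(0)
  v <- ic$ic[terms]
  v <- v[!is.na(v)]
  if (!length(v)) 0 else max(v)
}
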