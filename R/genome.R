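# Interval model of the genome: topological domains, derived boundaries,
# genes, tissue-specific enhancers, deletions. All coordinates are 0-based
# half-open [start, end), the BED convention.

MAX_BOUNDARY_GAP <- 400000L   # gaps larger than this are unorganized chromatin
DEFAULT_FLANK <- 400000L      # fixed flank for the no-boundary control

check_intervals <- function(df, chrom_lengths = NULL, what = "interval") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop("malformed ", what, " (need 0 <= start < end) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(df$chrom), names(chrom_lengths))
    if (length(unknown)) stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    over <- which(df$end > chrom_lengths[df$chrom])
    if (length(over)) {
      stop(what, " exceeds chromosome length at row(s): ",
           paste(utils::head(over, 5L), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Assemble a genome architecture
#'
#' Bundles chromosome sizes, topological domains, genes and tissue-specific
#' enhancers; domain boundaries are derived on construction as the inter-domain
#' gaps of positive length up to `max_gap` (400 kb by default). Larger gaps
#' count as unorganized chromatin, not boundaries.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param domains Data.frame `chrom,start,end`: sorted non-overlapping domains.
#' @param genes Data.frame `chrom,start,end,gene_id`.
#' @param enhancers Data.frame `chrom,start,end,tissue`.
#' @param max_gap Maximum boundary length in bp.
#' @return An object of class `genome_architecture` with a derived
#'   `boundaries` element.
#' @export
genome_architecture <- function(chrom_lengths, domains,
                                genes = empty_bed("gene_id"),
                                enhancers = empty_bed("tissue"),
                                max_gap = MAX_BOUNDARY_GAP) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  check_intervals(domains, chrom_lengths, "domain")
  if (nrow(genes)) check_intervals(genes, chrom_lengths, "gene")
  if (nrow(enhancers)) check_intervals(enhancers, chrom_lengths, "enhancer")
  boundaries <- derive_boundaries(domains, chrom_lengths, max_gap = max_gap)
  structure(list(chrom_lengths = chrom_lengths, domains = domains,
                 boundaries = boundaries, genes = genes,
                 enhancers = enhancers, max_gap = max_gap),
            class = "genome_architecture")
}

#' @export
print.genome_architecture <- function(x, ...) {
  cat("genome_architecture:", length(x$chrom_lengths), "chromosomes,",
      nrow(x$domains), "domains,", nrow(x$boundaries), "boundaries,",
      nrow(x$genes), "genes,", nrow(x$enhancers), "enhancers\n")
  invisible(x)
}

empty_bed <- function(extra = character(0)) {
  df <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                   stringsAsFactors = FALSE)
  for (col in extra) df[[col]] <- character(0)
  df
}

#' Derive topological domain boundaries from domain intervals
#'
#' Every maximal gap between consecutive domains on a chromosome whose length
#' is positive and at most `max_gap` becomes a boundary. Zero-length gaps
#' (abutting domains) and gaps beyond `max_gap` (unorganized chromatin) are
#' not boundaries; chromosome ends never are.
#'
#' @param domains Data.frame `chrom,start,end`, non-overlapping per chromosome.
#' @param chrom_lengths Named numeric vector (used for validation only).
#' @param max_gap Maximum boundary length in bp (default 400 kb).
#' @return Data.frame `chrom,start,end` of boundaries.
#' @export
derive_boundaries <- function(domains, chrom_lengths = NULL,
                              max_gap = MAX_BOUNDARY_GAP) {
  check_intervals(domains, chrom_lengths, "domain")
  out <- lapply(split(domains, domains$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
      stop("overlapping domains on chromosome ", d$chrom[[1L]])
    }
    if (nrow(d) < 2L) return(NULL)
    gs <- d$end[-nrow(d)]
    ge <- d$start[-1L]
    keep <- ge - gs > 0 & ge - gs <= max_gap
    if (!any(keep)) return(NULL)
    data.frame(chrom = d$chrom[[1L]], start = gs[keep], end = ge[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- empty_bed()
  rownames(out) <- NULL
  out
}

#' Complete overlap of features by a deletion
#'
#' A feature is completely overlapped when the deletion contains it entirely:
#' `deletion$start <= feature$start` and `feature$end <= deletion$end`
#' (non-strict, so shared endpoints count), on the same chromosome.
#'
#' @param deletion List or one-row data.frame with `chrom,start,end`.
#' @param features Data.frame of intervals.
#' @return Logical vector, one flag per feature.
#' @export
complete_overlap <- function(deletion, features) {
  if (!nrow(features)) return(logical(0))
  features$chrom == deletion$chrom &
    deletion$start <= features$start &
    features$end <= deletion$end
}

# >=1 bp overlap of half-open intervals on the same chromosome
partial_overlap <- function(region, features) {
  if (!nrow(features)) return(logical(0))
  features$chrom == region$chrom &
    features$start < region$end &
    region$start < features$end
}

# gene_ids overlapping [start, end) by >= 1 bp
genes_in_region <- function(genes, chrom, start, end) {
  if (start >= end || !nrow(genes)) return(character(0))
  genes$gene_id[partial_overlap(list(chrom = chrom, start = start, end = end),
                                genes)]
}

region_df <- function(chrom, start, end, provenance) {
  list(chrom = chrom, start = start, end = end, provenance = provenance)
}

#' Adjacent regions of a deletion
#'
#' The left (right) adjacent region spans from the start (end) of the domain
#' containing the deletion's start (end) breakpoint up to that breakpoint.
#' A breakpoint lying in no domain (boundary gap, unorganized chromatin or
#' beyond all domains) falls back to a fixed flank of `fallback` bp clipped
#' to the chromosome; the provenance of each side records which rule applied.
#'
#' @param deletion List with `chrom,start,end`.
#' @param arch A `genome_architecture`.
#' @param fallback Flank width in bp used when no domain contains a breakpoint.
#' @return List with `left` and `right` regions (each `chrom,start,end`,
#'   possibly empty with `start == end`) and their `provenance`
#'   (`"domain-bounded"` or `"400kb-fallback"`).
#' @export
adjacent_regions <- function(deletion, arch, fallback = DEFAULT_FLANK) {
  stopifnot(inherits(arch, "genome_architecture"))
  chrom <- deletion$chrom
  glen <- arch$chrom_lengths[[chrom]]
  d <- arch$domains[arch$domains$chrom == chrom, , drop = FALSE]
  containing <- function(pos) {
    hit <- which(d$start <= pos & pos < d$end)
    if (length(hit)) d[hit[[1L]], ] else NULL
  }
  dl <- containing(deletion$start)
  left <- if (!is.null(dl)) {
    region_df(chrom, dl$start, deletion$start, "domain-bounded")
  } else {
    region_df(chrom, max(0, deletion$start - fallback), deletion$start,
              "400kb-fallback")
  }
  # the right breakpoint is deletion$end - 1 (end is exclusive)
  dr <- containing(deletion$end - 1L)
  right <- if (!is.null(dr)) {
    region_df(chrom, deletion$end, dr$end, "domain-bounded")
  } else {
    region_df(chrom, deletion$end, min(glen, deletion$end + fallback),
              "400kb-fallback")
  }
  # degenerate clipping: a breakpoint exactly at a domain edge yields an
  # empty region (start == end)
  if (left$end < left$start) left$start <- left$end
  if (right$end < right$start) right$end <- right$start
  list(left = left, right = right,
       provenance = c(left = left$provenance, right = right$provenance))
}

#' Fixed-width flanking windows of a deletion
#'
#' Used for the no-boundary enhancer-adoption control: fixed flanks of
#' `width` bp on both sides, clipped to the chromosome.
#'
#' @param deletion List with `chrom,start,end`.
#' @param chrom_lengths Named numeric vector.
#' @param width Flank width in bp (> 0).
#' @return List with `left` and `right` regions.
#' @export
flanking_windows <- function(deletion, chrom_lengths, width = DEFAULT_FLANK) {
  if (width <= 0) stop("flank width must be > 0")
  glen <- chrom_lengths[[deletion$chrom]]
  list(
    left = region_df(deletion$chrom, max(0, deletion$start - width),
                     deletion$start, "fixed-flank"),
    right = region_df(deletion$chrom, deletion$end,
                      min(glen, deletion$end + width), "fixed-flank")
  )
}

#' Count completely-overlapped features per deletion
#'
#' Uses an interval index (GenomicRanges) to count, for every deletion, the
#' features it contains entirely, and the fraction of deletions containing
#' at least one.
#'
#' @param deletions,features Data.frames of intervals (`chrom,start,end`).
#' @return List with per-deletion `counts` and the `fraction` with >= 1.
#' @export
count_complete_overlaps <- function(deletions, features) {
  n <- nrow(deletions)
  if (!n) return(list(counts = integer(0), fraction = NA_real_))
  if (!nrow(features)) return(list(counts = integer(n), fraction = 0))
  del_gr <- as_granges(deletions)
  feat_gr <- as_granges(features)
  counts <- integer(n)
  # complete overlap = feature falls entirely within the deletion
  ov <- GenomicRanges::findOverlaps(feat_gr, del_gr, type = "within")
  tab <- table(S4Vectors_subjectHits(ov))
  counts[as.integer(names(tab))] <- as.integer(tab)
  list(counts = counts, fraction = mean(counts >= 1L))
}

# 0-based half-open -> 1-based closed GRanges
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

S4Vectors_subjectHits <- function(ov) S4Vectors::subjectHits(ov)

#' Random length-preserving placement of deletions
#'
#' Each deletion length is placed uniformly at random over all valid start
#' positions across chromosomes (chromosome picked with probability
#' proportional to `chrom_length - deletion_length + 1`), `n_reps` times.
#' Deterministic given `seed`.
#'
#' @param deletion_lengths Numeric vector of lengths in bp.
#' @param chrom_lengths Named numeric vector.
#' @param n_reps Replicates.
#' @param seed Integer seed.
#' @return Data.frame `rep, deletion, chrom, start, end` with one row per
#'   placed deletion per replicate.
#' @export
random_placement <- function(deletion_lengths, chrom_lengths, n_reps, seed) {
  stopifnot(n_reps >= 1, length(deletion_lengths) >= 1)
  if (any(deletion_lengths > max(chrom_lengths))) {
    stop("deletion longer than every chromosome: ",
         max(deletion_lengths), " bp")
  }
  if (any(deletion_lengths <= 0)) stop("deletion lengths must be positive")
  set.seed(seed)
  n_del <- length(deletion_lengths)
  out <- vector("list", n_reps)
  chroms <- names(chrom_lengths)
  for (r in seq_len(n_reps)) {
    chrom <- character(n_del)
    start <- numeric(n_del)
    for (i in seq_len(n_del)) {
      L <- deletion_lengths[[i]]
      valid <- pmax(chrom_lengths - L + 1, 0)
      ch <- sample(seq_along(chroms), 1L, prob = valid)
      chrom[[i]] <- chroms[[ch]]
      # uniform over {0, ..., G - L}
      start[[i]] <- floor(stats::runif(1, 0, valid[[ch]]))
    }
    out[[r]] <- data.frame(rep = r, deletion = seq_len(n_del), chrom = chrom,
                           start = start, end = start + deletion_lengths,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
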