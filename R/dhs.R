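# Tissue-specific DNase I hypersensitivity ranking from windowed read-count
# matrices: normalisation, pooled within-tissue sd, regularised t-statistics,
# CTS-DHS / ubiquitous rankings, split-half reproducibility and sample
# clustering distance.

#' Create a window count matrix
#'
#' @param windows Data.frame `chrom,start,end` of fixed-width (200 bp),
#'   sorted, non-overlapping windows.
#' @param counts Integer matrix, windows x samples, non-negative; column
#'   names are sample ids.
#' @return Object of class `window_counts`.
#' @export
window_count_matrix <- function(windows, counts) {
  stopifnot(is.data.frame(windows), is.matrix(counts),
            nrow(windows) == nrow(counts))
  if (is.null(colnames(counts))) stop("counts must have sample column names")
  if (any(counts < 0)) stop("counts must be non-negative")
  w <- windows$end - windows$start
  if (length(unique(w)) > 1L) stop("windows must have a fixed width")
  structure(list(windows = windows, counts = counts), class = "window_counts")
}

#' Create a tissue design
#'
#' @param samples Character vector of sample ids.
#' @param tissues Character vector of tissue labels, parallel to `samples`;
#'   each sample belongs to exactly one tissue.
#' @return Object of class `tissue_design` with the per-tissue sample sets.
#' @export
tissue_design <- function(samples, tissues) {
  stopifnot(length(samples) == length(tissues))
  if (anyDuplicated(samples)) stop("duplicated sample ids")
  groups <- split(samples, tissues)
  structure(list(samples = samples, tissues = tissues, groups = groups),
            class = "tissue_design")
}

#' Log-transform and depth-normalise a count matrix
#'
#' `X = ln(count + 1)`, then each sample's column is multiplied by the
#' sequencing-depth factor (average raw read count over all samples) /
#' (that sample's average raw read count). The alternative order -- scale the
#' raw counts first, then log -- is available via `mode = "scale-then-log"`.
#'
#' @param raw A `window_counts` object or a bare counts matrix.
#' @param mode Normalisation order; the default is the log-then-scale
#'   reading.
#' @return Numeric matrix of normalised log counts (windows x samples).
#' @export
log_transform_normalize <- function(raw, mode = c("log-then-scale",
                                                  "scale-then-log")) {
  mode <- match.arg(mode)
  counts <- if (inherits(raw, "window_counts")) raw$counts else raw
  stopifnot(nrow(counts) >= 1L, ncol(counts) >= 1L)
  sample_means <- colMeans(counts)
  if (any(sample_means == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[sample_means == 0], collapse = ", "))
  }
  factor <- mean(sample_means) / sample_means
  if (mode == "log-then-scale") {
    sweep(log1p(counts), 2L, factor, `*`)
  } else {
    log1p(sweep(counts, 2L, factor, `*`))
  }
}

design_groups <- function(X, design) {
  g <- lapply(design$groups, function(s) {
    idx <- match(s, colnames(X))
    if (anyNA(idx)) stop("design sample(s) absent from matrix: ",
                         paste(s[is.na(idx)], collapse = ", "))
    idx
  })
  g
}

#' Pooled within-tissue standard deviation per window
#'
#' `s = sqrt( sum_j sum_{i in C_j} (X_i - Xbar_j)^2 / sum_j (n_j - 1) )`,
#' assuming equal variance across tissues.
#'
#' @param X Normalised log-count matrix (windows x samples).
#' @param design A `tissue_design`.
#' @param allow_singletons If `TRUE`, tissues with a single sample contribute
#'   zero sum-of-squares and zero degrees of freedom instead of erroring
#'   (used internally by the split-half analysis on odd group sizes).
#' @return Numeric vector of per-window pooled sds.
#' @export
pooled_within_tissue_sd <- function(X, design, allow_singletons = FALSE) {
  groups <- design_groups(X, design)
  nj <- lengths(groups)
  if (!allow_singletons && any(nj < 2L)) {
    stop("tissue(s) with fewer than 2 samples: ",
         paste(names(groups)[nj < 2L], collapse = ", "))
  }
  df <- sum(pmax(nj - 1L, 0L))
  if (df == 0L) {
    # every tissue a singleton: no variance information; the split-half
    # path still needs rankings, so s degenerates to zero
    if (allow_singletons) return(rep(0, nrow(X)))
    stop("no within-tissue degrees of freedom")
  }
  ss <- 0
  for (idx in groups) {
    if (length(idx) < 2L) next
    sub <- X[, idx, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  sqrt(ss / df)
}

#' Tissue-specificity t-statistics per window
#'
#' For tissue `j`,
#' `t_j = (Xbar_j - Xbar) / ( sqrt(1/m + 1/n_j) * (s + s0) )`,
#' where `Xbar_j` is the tissue mean, `Xbar` the unweighted mean of the `m`
#' tissue means (the ubiquitous profile), `s` the per-window pooled
#' within-tissue sd and `s0` its mean over all windows, a regulariser against
#' small variance estimates.
#'
#' @inheritParams pooled_within_tissue_sd
#' @return Object of class `specificity_table`: window table, matrices of
#'   tissue means and t-statistics, `grand_mean`, `s`, `s0`, and per-tissue
#'   rankings (window indices by decreasing t, genomic-order tie-break).
#' @export
tissue_t_statistics <- function(X, design, allow_singletons = FALSE,
                                windows = NULL) {
  groups <- design_groups(X, design)
  m <- length(groups)
  nj <- lengths(groups)
  tissue_means <- vapply(groups, function(idx)
    rowMeans(X[, idx, drop = FALSE]), numeric(nrow(X)))
  if (is.null(dim(tissue_means))) {
    tissue_means <- matrix(tissue_means, nrow = nrow(X),
                           dimnames = list(NULL, names(groups)))
  }
  grand <- rowMeans(tissue_means)
  s <- pooled_within_tissue_sd(X, design, allow_singletons = allow_singletons)
  s0 <- mean(s)
  denom_s <- s + s0
  if (any(denom_s == 0)) {
    if (allow_singletons && all(s == 0)) {
      # degenerate singleton halves: rank by scaled mean differences
      denom_s <- rep(1, length(denom_s))
    } else {
      stop("all-constant matrix: s + s0 is zero at some window")
    }
  }
  tstat <- vapply(seq_len(m), function(j)
    (tissue_means[, j] - grand) / (sqrt(1 / m + 1 / nj[[j]]) * denom_s),
    numeric(nrow(X)))
  tstat <- matrix(tstat, nrow = nrow(X), dimnames = list(NULL, names(groups)))
  rankings <- lapply(seq_len(m), function(j)
    order(-tstat[, j], seq_len(nrow(X))))
  names(rankings) <- names(groups)
  structure(list(windows = windows, tissue_means = tissue_means,
                 grand_mean = grand, s = s, s0 = s0, t = tstat,
                 rankings = rankings),
            class = "specificity_table")
}

#' @export
print.specificity_table <- function(x, ...) {
  cat("specificity_table:", nrow(x$t), "windows x", ncol(x$t),
      "tissues (s0 =", signif(x$s0, 4), ")\n")
  invisible(x)
}

#' Call cell-type-specific DHS windows for a tissue
#'
#' The `top_n` windows by decreasing tissue t-statistic, as BED-style
#' intervals labelled with the tissue.
#'
#' @param table A `specificity_table` carrying its `windows`.
#' @param tissue Tissue label.
#' @param top_n Number of windows to call (default 20000, the genome-wide
#'   choice; must not exceed the window count).
#' @return Data.frame `chrom,start,end,tissue`.
#' @export
call_cts_dhs <- function(table, tissue, top_n = 20000) {
  stopifnot(inherits(table, "specificity_table"))
  if (!tissue %in% colnames(table$t)) stop("unknown tissue: ", tissue)
  if (top_n > nrow(table$t)) stop("top_n exceeds number of windows")
  idx <- table$rankings[[tissue]][seq_len(top_n)]
  out <- table$windows[idx, , drop = FALSE]
  out$tissue <- tissue
  rownames(out) <- NULL
  out
}

#' Ubiquitous DHS ranking
#'
#' Windows ranked by the grand mean of the tissue means (the profile of all
#' tissues combined); the top set serves as the non-specific control.
#'
#' @param X Normalised log-count matrix.
#' @param design A `tissue_design`.
#' @param top_n Number of windows to return.
#' @param windows Optional window table to subset.
#' @return If `windows` given, a BED-style data.frame; otherwise the window
#'   indices.
#' @export
ubiquitous_ranking <- function(X, design, top_n, windows = NULL) {
  groups <- design_groups(X, design)
  tissue_means <- vapply(groups, function(idx)
    rowMeans(X[, idx, drop = FALSE]), numeric(nrow(X)))
  if (is.null(dim(tissue_means))) {
    tissue_means <- matrix(tissue_means, nrow = nrow(X))
  }
  grand <- rowMeans(tissue_means)
  if (top_n > nrow(X)) stop("top_n exceeds number of windows")
  idx <- order(-grand, seq_len(nrow(X)))[seq_len(top_n)]
  if (is.null(windows)) return(idx)
  out <- windows[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split-half reproducibility of CTS-DHS rankings
#'
#' Samples are split into two stratified halves (per tissue); the full
#' normalisation + t-statistic pipeline runs on each half, and for each `n`
#' in `grid` the reproducible ratio `|top_n(half1) /\ top_n(half2)| / n` is
#' computed per tissue. The estimated maximum of each curve comes from
#' piecewise-linear interpolation over the grid (the argmax grid point).
#'
#' @param raw A `window_counts` object or counts matrix.
#' @param design A `tissue_design`; every tissue needs >= 2 samples.
#' @param grid Increasing integer vector of top-n values.
#' @param seed Integer seed for the stratified split.
#' @return List with `curves` (data.frame `tissue,n,ratio`), per-tissue
#'   `maxima` (n at the curve maximum), and the two halves' sample ids.
#' @export
split_half_reproducibility <- function(raw, design, grid, seed = 1) {
  counts <- if (inherits(raw, "window_counts")) raw$counts else raw
  nj <- lengths(design$groups)
  if (any(nj < 2L)) {
    stop("tissue(s) with a single sample cannot be split: ",
         paste(names(design$groups)[nj < 2L], collapse = ", "))
  }
  grid <- sort(unique(as.integer(grid)))
  if (max(grid) > nrow(counts)) stop("grid exceeds number of windows")
  set.seed(seed)
  half1 <- unlist(lapply(design$groups, function(s) {
    s <- sample(s)
    s[seq_len(ceiling(length(s) / 2))]
  }), use.names = FALSE)
  half2 <- setdiff(design$samples, half1)
  rank_half <- function(ids) {
    sub <- counts[, ids, drop = FALSE]
    d <- tissue_design(ids, design$tissues[match(ids, design$samples)])
    X <- log_transform_normalize(sub)
    tissue_t_statistics(X, d, allow_singletons = TRUE)$rankings
  }
  r1 <- rank_half(half1)
  r2 <- rank_half(half2)
  curves <- do.call(rbind, lapply(names(design$groups), function(ti) {
    ratio <- vapply(grid, function(n)
      length(intersect(r1[[ti]][seq_len(n)], r2[[ti]][seq_len(n)])) / n,
      numeric(1))
    data.frame(tissue = ti, n = grid, ratio = ratio, stringsAsFactors = FALSE)
  }))
  maxima <- vapply(split(curves, curves$tissue), function(cv) {
    cv$n[[which.max(cv$ratio)]]
  }, numeric(1))
  list(curves = curves, maxima = maxima, half1 = half1, half2 = half2)
}

#' Sample distance matrix from DNase profiles
#'
#' Pairwise `1 - cor(x, y)` (Pearson) of the per-sample log-count profiles;
#' suitable for hierarchical clustering of samples by cell type.
#'
#' @param X Normalised log-count matrix (windows x samples), >= 2 samples.
#' @return Symmetric matrix with zero diagonal.
#' @export
sample_distance_matrix <- function(X) {
  if (ncol(X) < 2L) stop("need at least 2 samples")
  d <- 1 - stats::cor(X)
  diag(d) <- 0
  d
}
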