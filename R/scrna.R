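## Patch-seq expression pipeline: cDNA-level and expression-level QC,
## counts-per-10k log normalization, PCA + k-means clustering, one-vs-rest
## rank-sum marker detection under the padj < 0.05 & FC > 1.5 rule, and
## panel-vote cluster annotation.

#' Quality-control filter for patch-seq cells
#'
#' Applies the cDNA gates (yield strictly greater than `min_yield_ng`; size
#' peak inside `peak_range_bp`, inclusive) plus configurable expression-level
#' gates (minimum detected genes, maximum ERCC fraction). The report lists
#' per-rule casualties; a cell may fail several rules.
#'
#' @param cm a `"count_matrix"` whose `meta` has `cdna_yield_ng` and
#'   `cdna_peak_bp`.
#' @param min_yield_ng strict lower bound on cDNA yield (default 1).
#' @param peak_range_bp inclusive window for the cDNA size peak
#'   (default c(1000, 5000)).
#' @param min_genes minimum number of detected (non-ERCC, count > 0) genes
#'   (default 200; set 0 to disable).
#' @param max_ercc_frac maximum fraction of counts from spike-ins
#'   (default 0.5; set 1 to disable).
#' @return list with `kept` (filtered `"count_matrix"`) and `report` (totals,
#'   percentage failing, and per-rule counts).
#' @export
qc_filter <- function(cm, min_yield_ng = 1, peak_range_bp = c(1000, 5000),
                      min_genes = 200, max_ercc_frac = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- cm$meta
  if (!all(c("cdna_yield_ng", "cdna_peak_bp") %in% names(m)))
    stop("meta must contain cdna_yield_ng and cdna_peak_bp")
  fail_yield <- !(m$cdna_yield_ng > min_yield_ng)
  fail_peak <- m$cdna_peak_bp < peak_range_bp[1] | m$cdna_peak_bp > peak_range_bp[2]
  n_det <- colSums(cm$counts[!cm$is_ercc, , drop = FALSE] > 0)
  fail_genes <- n_det < min_genes
  tot <- colSums(cm$counts)
  ercc_frac <- ifelse(tot > 0,
                      colSums(cm$counts[cm$is_ercc, , drop = FALSE]) / tot, 1)
  fail_ercc <- ercc_frac > max_ercc_frac
  fail <- fail_yield | fail_peak | fail_genes | fail_ercc
  report <- list(
    n_total = ncol(cm$counts),
    n_failed = sum(fail),
    n_kept = sum(!fail),
    percent_failed = 100 * sum(fail) / ncol(cm$counts),
    per_rule = c(yield = sum(fail_yield), size_peak = sum(fail_peak),
                 min_genes = sum(fail_genes), ercc_fraction = sum(fail_ercc)),
    failed_cells = colnames(cm$counts)[fail]
  )
  if (all(fail)) {
    stop(sprintf(
      "QC removed all %d cells (yield: %d, size peak: %d, detected genes: %d, ERCC fraction: %d)",
      report$n_total, report$per_rule[["yield"]], report$per_rule[["size_peak"]],
      report$per_rule[["min_genes"]], report$per_rule[["ercc_fraction"]]))
  }
  kept <- count_matrix(cm$counts[, !fail, drop = FALSE],
                       cm$meta[!fail, , drop = FALSE])
  list(kept = kept, report = report)
}

#' Counts-per-10k log normalization
#'
#' Scales every cell to 10,000 counts computed over biological genes only
#' (spike-in rows are excluded from the scaling denominator, though they are
#' scaled by the same factor), then applies `log1p`. Not idempotent: the
#' output is on the log scale, re-running it is meaningless.
#'
#' @param cm a `"count_matrix"`.
#' @param scale_to target library size (default 1e4).
#' @return numeric matrix (genes x cells) of log1p-normalized expression with
#'   attribute `is_ercc`.
#' @export
normalize_log <- function(cm, scale_to = 1e4) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- colSums(cm$counts[!cm$is_ercc, , drop = FALSE])
  f <- ifelse(lib > 0, scale_to / lib, 0)
  norm <- log1p(sweep(cm$counts, 2, f, `*`))
  attr(norm, "is_ercc") <- cm$is_ercc
  norm
}

#' Cluster cells on normalized expression
#'
#' Default path: restrict to the `n_hvg` highest-variance biological genes,
#' z-score each gene, project onto the top `n_pcs` principal components, and
#' run k-means with many restarts. Deterministic under a fixed seed and
#' invariant (up to label permutation) to cell order.
#'
#' @param norm normalized matrix from [normalize_log()].
#' @param k number of clusters (default 4).
#' @param seed RNG seed for k-means restarts.
#' @param n_hvg number of high-variance genes (default 500).
#' @param n_pcs number of principal components (default 20).
#' @return integer vector of cluster labels (1..k) named by cell. Labels are
#'   renumbered by decreasing cluster size so they are stable across cell
#'   orderings.
#' @export
cluster_cells <- function(norm, k = 4, seed = 1L, n_hvg = 500, n_pcs = 20) {
  is_ercc <- attr(norm, "is_ercc") %||% rep(FALSE, nrow(norm))
  x <- norm[!is_ercc, , drop = FALSE]
  if (k > ncol(x)) stop("k exceeds the number of cells")
  v <- apply(x, 1, var)
  x <- x[order(v, decreasing = TRUE)[seq_len(min(n_hvg, sum(v > 0)))], ,
         drop = FALSE]
  x <- t(scale(t(x)))
  x[!is.finite(x)] <- 0
  n_pcs <- min(n_pcs, ncol(x) - 1L, nrow(x))
  pc <- prcomp(t(x), center = FALSE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                       drop = FALSE]
  km <- with_seed(seed, kmeans(pc, centers = k, nstart = 25, iter.max = 100))
  lab <- km$cluster
  # renumber by decreasing size, ties broken by first occurrence in sorted
  # cell-id order so the labelling is independent of input cell order
  ord <- order(-tabulate(lab, k), vapply(seq_len(k), function(cl) {
    min(colnames(norm)[lab == cl])
  }, character(1)))
  setNames(match(lab, ord), colnames(norm))
}

# Vectorized one-vs-rest tie-corrected rank-sum z per gene (rows of `mat`).
# Returns two-sided normal-approximation p-values; constant genes get p = 1.
ranksum_p_rows <- function(mat, in_group) {
  n <- ncol(mat); nx <- sum(in_group); ny <- n - nx
  ranks <- t(apply(mat, 1, rank))
  u <- rowSums(ranks[, in_group, drop = FALSE]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  tie_term <- apply(mat, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  }) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  z <- ifelse(sigma2 > 0, (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2), 0)
  p <- ifelse(sigma2 > 0, pmin(1, 2 * pnorm(-abs(z))), 1)
  list(u = u, z = z, p = p)
}

#' One-vs-rest marker detection under the padj/fold-change rule
#'
#' For every cluster and every biological gene: a tie-corrected Wilcoxon
#' rank-sum test (normal approximation with continuity correction; cohorts of
#' at most 12 tie-free cells use the exact enumeration branch of
#' [mann_whitney()]) of
#' cells-in-cluster versus all other cells; fold-change as the ratio of mean
#' `expm1(normalized)` expression with a small pseudocount; Benjamini-Hochberg
#' adjustment across genes within each cluster; and the marker flag
#' `padj < padj_threshold & fold_change > fc_threshold`.
#'
#' @param norm normalized matrix from [normalize_log()].
#' @param labels cluster label per cell.
#' @param padj_threshold,fc_threshold the marker rule (defaults 0.05 and 1.5).
#' @param pseudocount added to both group means before forming the ratio
#'   (default 1e-9).
#' @param min_cells minimum cells per cluster (default 3).
#' @return data frame: `gene`, `cluster`, `log2_fc`, `fold_change`, `p`,
#'   `p_adj`, `is_marker`.
#' @export
find_markers <- function(norm, labels, padj_threshold = 0.05,
                         fc_threshold = 1.5, pseudocount = 1e-9,
                         min_cells = 3) {
  stopifnot(ncol(norm) == length(labels))
  is_ercc <- attr(norm, "is_ercc") %||% rep(FALSE, nrow(norm))
  x <- norm[!is_ercc, , drop = FALSE]
  labels <- as.character(labels)
  out <- list()
  for (cl in sort(unique(labels))) {
    in_g <- labels == cl
    if (sum(in_g) < min_cells)
      stop(sprintf("cluster '%s' has fewer than %d cells", cl, min_cells))
    if (ncol(x) <= 12) {
      # tiny cohorts: per-gene exact Mann-Whitney (enumeration branch)
      pu <- t(vapply(seq_len(nrow(x)), function(i) {
        mw <- mann_whitney(x[i, in_g], x[i, !in_g])
        c(mw$statistic[["U"]], mw$p.value)
      }, numeric(2)))
      rs <- list(u = pu[, 1], p = pu[, 2])
    } else {
      rs <- ranksum_p_rows(x, in_g)
    }
    # normalized input is non-negative; clamp guards artificial inputs
    mean_in <- pmax(rowMeans(expm1(x[, in_g, drop = FALSE])), 0)
    mean_out <- pmax(rowMeans(expm1(x[, !in_g, drop = FALSE])), 0)
    fc <- (mean_in + pseudocount) / (mean_out + pseudocount)
    padj <- p.adjust(rs$p, method = "BH")
    out[[cl]] <- data.frame(
      gene = rownames(x), cluster = cl,
      log2_fc = log2(fc), fold_change = fc,
      p = rs$p, p_adj = padj,
      is_marker = padj < padj_threshold & fc > fc_threshold,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Annotate clusters as interneuron or pyramidal by marker panels
#'
#' Each cluster votes with its marker genes: the count of interneuron-panel
#' genes versus pyramidal-panel genes among `is_marker` rows. The majority
#' wins; ties (including zero overlap with both panels) give `"ambiguous"`.
#' Panel order is irrelevant.
#'
#' @param markers marker table from [find_markers()].
#' @param panels named list of two character vectors, `INT` and `PY`
#'   (defaults [interneuron_panel()] and [pyramidal_panel()]).
#' @return named character vector, one of `"INT"`, `"PY"`, `"ambiguous"` per
#'   cluster.
#' @export
annotate_clusters <- function(markers,
                              panels = list(INT = interneuron_panel(),
                                            PY = pyramidal_panel())) {
  stopifnot(all(c("gene", "cluster", "is_marker") %in% names(markers)),
            all(c("INT", "PY") %in% names(panels)))
  cls <- sort(unique(markers$cluster))
  out <- vapply(cls, function(cl) {
    mg <- markers$gene[markers$cluster == cl & markers$is_marker]
    v_int <- length(intersect(mg, panels$INT))
    v_py <- length(intersect(mg, panels$PY))
    if (v_int > v_py) "INT" else if (v_py > v_int) "PY" else "ambiguous"
  }, character(1))
  setNames(out, cls)
}
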