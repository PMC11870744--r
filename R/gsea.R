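## Preranked gene-set enrichment: weighted Kolmogorov-Smirnov running sum
## with a gene-label permutation null.

# Weighted KS enrichment score for a sorted ranking. `stat` must be sorted
# decreasing; `hit` is logical membership per position.
running_es <- function(stat, hit, weight = 1) {
  w <- abs(stat)^weight
  sw <- sum(w[hit])
  n <- length(stat); nh <- sum(hit)
  inc <- numeric(n)
  if (sw > 0) inc[hit] <- w[hit] / sw else inc[hit] <- 1 / nh
  inc[!hit] <- -1 / (n - nh)
  rs <- cumsum(inc)
  i <- which.max(abs(rs))
  rs[i]
}

#' Permutation gene-set enrichment score
#'
#' Ranks genes by a signed statistic (decreasing), computes the weighted
#' Kolmogorov-Smirnov running-sum enrichment score (increments proportional to
#' `|statistic|^weight` at set members, constant decrements elsewhere; the ES
#' is the extremum of the running sum), and calibrates it against a null built
#' by permuting gene labels of the set. The normalized score (NES) divides the
#' ES by the mean absolute null ES of the same sign; the permutation p-value
#' counts same-sign null scores at least as extreme, with the +1 correction.
#'
#' @param stats named numeric vector: the ranking statistic per gene (e.g. the
#'   signed rank-sum z from [find_markers()]).
#' @param gene_set character vector of gene ids; must intersect `names(stats)`.
#' @param n_perm number of label permutations (default 1000, minimum 100).
#' @param seed RNG seed.
#' @param weight exponent on `|statistic|` (default 1).
#' @return list with `es`, `nes`, `p.value`, `n_perm`, `set_size` (genes in
#'   both set and ranking) and `leading_edge` (genes contributing to the ES
#'   extremum).
#' @export
enrichment_score <- function(stats, gene_set, n_perm = 1000, seed = 1L,
                             weight = 1) {
  stopifnot(!is.null(names(stats)), n_perm >= 100)
  gene_set <- unique(gene_set)
  stats <- sort(stats, decreasing = TRUE)
  hit <- names(stats) %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene set has no overlap with the ranking")
  if (nh == length(stats)) stop("gene set covers the entire ranking")
  w <- abs(stats)^weight
  es_obs <- running_es(stats, hit, weight)
  # leading edge: genes up to (or from) the running-sum extremum
  sw <- sum(w[hit]); n <- length(stats)
  inc <- numeric(n)
  if (sw > 0) inc[hit] <- w[hit] / sw else inc[hit] <- 1 / nh
  inc[!hit] <- -1 / (n - nh)
  rs <- cumsum(inc)
  i_ext <- which.max(abs(rs))
  le <- if (es_obs >= 0) names(stats)[seq_len(i_ext)][hit[seq_len(i_ext)]]
        else names(stats)[i_ext:n][hit[i_ext:n]]
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    running_es(stats, sample(hit), weight)
  }, numeric(1)))
  same <- null_es[sign(null_es) == sign(es_obs)]
  nes <- if (length(same) > 0) es_obs / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es_obs))) / (1 + length(same))
  list(es = es_obs, nes = nes, p.value = p, n_perm = n_perm,
       set_size = nh, leading_edge = le)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path file path.
#' @param sets named list of character vectors (for writing).
#' @param descriptions optional character vector of per-set descriptions.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
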