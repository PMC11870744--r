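## Patch-seq expression simulator: a minimal hierarchical count model with the
## structure the rank-sum marker test assumes. Library sizes are log-normal,
## counts are Poisson draws of scaled relative expression with Bernoulli
## dropout, clusters differ only through planted fold-changes on named marker
## genes, donors contribute a per-gene log-normal random effect, and ERCC
## spike-in rows are independent of cluster.

#' Reference marker panels
#'
#' Small gene panels used for cluster annotation and as enrichment fixtures:
#' cortical interneuron markers, cortical pyramidal markers, a cellular
#' senescence panel (with LMNB1 as the expected-down gene, excluded from the
#' positive panel unless requested) and a SASP (senescence-associated
#' secretory phenotype) panel of interleukins, chemokines, proteases and shed
#' receptors.
#'
#' @param include_negative for `senescence_panel`, include the expected-down
#'   gene LMNB1 (default FALSE).
#' @return character vector of gene symbols.
#' @export
interneuron_panel <- function() c("GAD1", "GAD2", "ERBB4", "DLX1", "LHX6")

#' @rdname interneuron_panel
#' @export
pyramidal_panel <- function() c("SATB2", "CUX2", "SLC17A6", "SLC17A7")

#' @rdname interneuron_panel
#' @export
senescence_panel <- function(include_negative = FALSE) {
  pos <- c("CDKN1A", "TP53", "NFKBIA", "GLB1", "PTGS2", "H2AX")
  if (include_negative) c(pos, "LMNB1") else pos
}

#' @rdname interneuron_panel
#' @export
sasp_panel <- function() c("IL1A", "IL1B", "CCL4", "CCL2", "CXCL8", "CXCL12",
                           "MMP2", "CTSB", "ICAM1", "TNFRSF1B", "TNFRSF12A")

# Each cluster carries its named panel genes plus a block of anonymous
# cluster-specific genes, mirroring the dozens-of-DEGs-per-cluster structure
# real transcriptomic clusters show (a lone marker gene would make a cluster
# undetectable to any clustering method).
default_markers <- function(n_extra = 25, extra_log2fc = 2) {
  py2_up <- unique(c(senescence_panel(), sasp_panel(), "SLC17A7", "NEFM", "NEFH"))
  blocks <- lapply(c(INT = "INT", PY1 = "PY1", PY2 = "PY2", PY3 = "PY3"),
                   function(cl) setNames(rep(extra_log2fc, n_extra),
                                         sprintf("%sM%03d", cl, seq_len(n_extra))))
  list(
    INT = c(setNames(rep(3, 5), interneuron_panel()), blocks$INT),
    PY1 = c(setNames(rep(2, 2), c("SATB2", "CUX2")), blocks$PY1),
    PY2 = c(setNames(rep(2, length(py2_up)), py2_up), blocks$PY2),
    PY3 = c(setNames(rep(2, 1), "SLC17A6"), blocks$PY3)
  )
}

#' Specification for the patch-seq expression simulator
#'
#' Defaults emulate the study conditions of the patch-seq cohort: 197 QC-passing
#' neurons in four clusters (interneurons plus three pyramidal clusters, the
#' smallest pyramidal cluster PY2 being the 13.7% senescence-marker-high
#' minority: 53 INT / 81 PY1 / 27 PY2 / 36 PY3), ERCC spike-in rows, and
#' per-cluster marker genes planted at 4-fold (log2 fold-change 2; interneuron
#' panel at 8-fold) over a log-normal baseline.
#'
#' @param n_cells named integer vector of cells per cluster.
#' @param n_genes total number of biological genes (marker genes are assigned
#'   into this universe; must be at least the number of distinct markers).
#' @param n_ercc number of ERCC spike-in rows (default 92).
#' @param markers named list (one element per cluster) of named numeric
#'   vectors: log2 fold-change per marker gene. Fold-changes must be > 0 on
#'   the natural scale (log2fc may be any finite value).
#' @param dropout_rate probability that a biological count is zeroed
#'   (default 0.15).
#' @param n_donors number of donors, assigned round-robin within cluster.
#' @param donor_sd standard deviation of the per-donor per-gene log-normal
#'   effect (default 0.1).
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters
#'   (defaults log(2e4), 0.3).
#' @param n_fail_qc number of additional cells generated to fail the cDNA QC
#'   gates (yield <= 1 ng or size peak outside 1000-5000 bp); 0 by default.
#' @param seed integer RNG seed.
#' @return list of class `"expr_sim_spec"`.
#' @export
expr_sim_spec <- function(n_cells = c(INT = 53, PY1 = 81, PY2 = 27, PY3 = 36),
                          n_genes = 2000, n_ercc = 92,
                          markers = default_markers(),
                          dropout_rate = 0.15,
                          n_donors = 36, donor_sd = 0.1,
                          libsize_meanlog = log(2e4), libsize_sdlog = 0.3,
                          n_fail_qc = 0, seed = 1L) {
  stopifnot(length(n_cells) >= 1, all(n_cells >= 0), !is.null(names(n_cells)))
  if (!all(names(markers) %in% names(n_cells)))
    stop("marker list names must match cluster names")
  all_markers <- unique(unlist(lapply(markers, names)))
  if (n_genes < length(all_markers))
    stop("n_genes must be at least the number of distinct marker genes")
  if (dropout_rate < 0 || dropout_rate > 1) stop("dropout_rate must be in [0,1]")
  for (m in markers)
    if (any(!is.finite(m))) stop("fold-changes must be finite")
  structure(list(n_cells = n_cells, n_genes = n_genes, n_ercc = n_ercc,
                 markers = markers, dropout_rate = dropout_rate,
                 n_donors = n_donors, donor_sd = donor_sd,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog,
                 n_fail_qc = as.integer(n_fail_qc), seed = as.integer(seed)),
            class = "expr_sim_spec")
}

#' Simulate a patch-seq count matrix with known cluster labels
#'
#' @param spec an [expr_sim_spec()].
#' @return a `"count_matrix"` (see [count_matrix()]) whose `meta` carries the
#'   usual covariates (donor, sex, age, region, layer, pathology, cDNA yield
#'   and size peak) plus `cluster_true`; the `truth` attribute records the
#'   spec, the marker gene placement and the per-cluster expected expression.
#' @export
gen_expression <- function(spec) {
  stopifnot(inherits(spec, "expr_sim_spec"))
  with_seed(spec$seed, {
    clusters <- rep(names(spec$n_cells), spec$n_cells)
    n_bio_cells <- length(clusters)
    n_fail <- spec$n_fail_qc
    n_tot <- n_bio_cells + n_fail

    all_markers <- unique(unlist(lapply(spec$markers, names)))
    gene_ids <- c(all_markers,
                  sprintf("GENE%04d", seq_len(spec$n_genes - length(all_markers))))
    ercc_ids <- sprintf("ERCC-%05d", seq_len(spec$n_ercc))

    base_mean <- rlnorm(spec$n_genes, meanlog = 1, sdlog = 1)
    names(base_mean) <- gene_ids
    # cluster expected relative expression
    rel <- sapply(names(spec$n_cells), function(cl) {
      r <- base_mean
      m <- spec$markers[[cl]]
      if (!is.null(m)) r[names(m)] <- r[names(m)] * 2^m
      r
    })
    donors <- paste0("donor", sprintf("%02d", seq_len(spec$n_donors)))
    donor_eff <- matrix(exp(rnorm(spec$n_genes * spec$n_donors, 0, spec$donor_sd)),
                        spec$n_genes, spec$n_donors,
                        dimnames = list(gene_ids, donors))

    cell_cluster <- c(clusters, rep(NA_character_, n_fail))
    donor_of <- donors[(seq_len(n_tot) - 1L) %% spec$n_donors + 1L]
    libsize <- rlnorm(n_tot, spec$libsize_meanlog, spec$libsize_sdlog)
    ercc_mean <- rlnorm(spec$n_ercc, meanlog = 2, sdlog = 1.2)

    counts <- matrix(0L, spec$n_genes + spec$n_ercc, n_tot,
                     dimnames = list(c(gene_ids, ercc_ids),
                                     sprintf("cell%04d", seq_len(n_tot))))
    for (j in seq_len(n_tot)) {
      cl <- cell_cluster[j]
      r <- if (is.na(cl)) base_mean else rel[, cl]
      r <- r * donor_eff[, donor_of[j]]
      lam <- libsize[j] * r / sum(r)
      x <- rpois(spec$n_genes, lam)
      if (spec$dropout_rate > 0)
        x <- x * rbinom(spec$n_genes, 1L, 1 - spec$dropout_rate)
      counts[seq_len(spec$n_genes), j] <- x
      counts[spec$n_genes + seq_len(spec$n_ercc), j] <- rpois(spec$n_ercc, ercc_mean)
    }

    yield <- exp(rnorm(n_tot, log(3), 0.4)) + 1      # passing cells: > 1 ng
    peak <- round(rnorm(n_tot, 2500, 500))
    peak <- pmin(pmax(peak, 1100), 4900)
    if (n_fail > 0) {
      fail_idx <- n_bio_cells + seq_len(n_fail)
      # alternate failure mode: low yield vs bad size distribution
      low_yield <- fail_idx[seq_along(fail_idx) %% 2L == 1L]
      bad_peak <- setdiff(fail_idx, low_yield)
      yield[low_yield] <- runif(length(low_yield), 0.05, 1.0)  # <= 1 ng
      peak[bad_peak] <- sample(c(runif(length(bad_peak), 200, 900),
                                 runif(length(bad_peak), 5500, 9000)),
                               length(bad_peak))
    }
    meta <- data.frame(
      cell = colnames(counts),
      donor = donor_of,
      sex = sample(c("M", "F"), n_tot, replace = TRUE),
      age = sample(18:60, n_tot, replace = TRUE),
      region = sample(c("FL", "TL", "PL", "IL"), n_tot, replace = TRUE),
      layer = sample(c("L2/3", "L4", "L5"), n_tot, replace = TRUE),
      pathology = sample(c("FCD", "TLE", "PT"), n_tot, replace = TRUE),
      cdna_yield_ng = yield,
      cdna_peak_bp = peak,
      cluster_true = cell_cluster,
      stringsAsFactors = FALSE
    )
    cm <- count_matrix(counts, meta)
    attr(cm, "truth") <- list(spec = spec, markers = spec$markers,
                              rel_expression = rel,
                              qc_fail_cells = if (n_fail > 0)
                                colnames(counts)[n_bio_cells + seq_len(n_fail)]
                              else character(0))
    cm
  })
}

#' Construct a gene-by-cell count matrix with covariates
#'
#' @param counts integer matrix, genes x cells, with rownames (gene ids) and
#'   colnames (cell ids).
#' @param meta data frame of per-cell covariates; must have a `cell` column
#'   aligned with `colnames(counts)`.
#' @param ercc_pattern regular expression identifying spike-in rows.
#' @return list of class `"count_matrix"` with elements `counts`, `meta`,
#'   `is_ercc`.
#' @export
count_matrix <- function(counts, meta, ercc_pattern = "^ERCC-") {
  counts <- as.matrix(counts)
  stop_if_not_count(counts, "counts")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and cell colnames")
  stopifnot(is.data.frame(meta), "cell" %in% names(meta))
  if (!identical(as.character(meta$cell), colnames(counts)))
    stop("meta$cell must align with colnames(counts)")
  structure(list(counts = counts, meta = meta,
                 is_ercc = grepl(ercc_pattern, rownames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes (%d ERCC) x %d cells\n",
              nrow(x$counts), sum(x$is_ercc), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write / read a count matrix in MTX + TSV layout
#'
#' Writes `matrix.mtx` (MatrixMarket sparse), `genes.tsv` (gene, is_ercc) and
#' `metadata.tsv` (per-cell covariates, first column `cell`) into `dir`.
#'
#' @param x a `"count_matrix"`.
#' @param dir directory (created if needed).
#' @return `write_count_matrix` returns `dir` invisibly; `read_count_matrix`
#'   the reconstructed object.
#' @export
write_count_matrix <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  write.table(data.frame(gene = rownames(x$counts), is_ercc = x$is_ercc),
              file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(x$meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- read.delim(file.path(dir, "genes.tsv"))
  meta <- read.delim(file.path(dir, "metadata.tsv"))
  storage.mode(m) <- "integer"
  rownames(m) <- genes$gene
  colnames(m) <- meta$cell
  count_matrix(m, meta)
}
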