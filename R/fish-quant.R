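## Expansion-FISH quantification: Laplacian-of-Gaussian spot detection,
## DAPI-based soma segmentation, cube-law expansion correction, spot-to-soma
## assignment, two-class molecular classification and the through-origin
## density slope.

## --- small 3D image utilities -------------------------------------------

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(x, n_bins = 256) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(n_bins, floor((x - r[1]) / diff(r) * n_bins) + 1), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + k / n_bins * diff(r)
}

# shift a 3D array by one voxel along an axis, replicating the border
shift3 <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- pmin(pmax(idx[[axis]] - by, 1L), d[axis])
  idx[[axis]] <- src
  do.call(`[`, c(list(a), idx))
}

# separable Gaussian smoothing (sigma in voxels per axis)
gauss_smooth3 <- function(a, sigma_vox) {
  d <- dim(a)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-(-half:half)^2 / (2 * s^2)); k <- k / sum(k)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[axis])
    pad_top <- m[rep(1L, half), , drop = FALSE]
    pad_bot <- m[rep(nrow(m), half), , drop = FALSE]
    padded <- rbind(pad_top, m, pad_bot)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * padded[i:(i + nrow(m) - 1), , drop = FALSE]
    a <- aperm(array(out, dim = d[perm]), match(seq_len(3), perm))
  }
  a
}

# 6-neighbour Laplacian with per-axis spacing
laplacian3 <- function(a, spacing) {
  out <- array(0, dim(a))
  for (axis in 1:3) {
    out <- out + (shift3(a, axis, 1L) + shift3(a, axis, -1L) - 2 * a) /
      spacing[axis]^2
  }
  out
}

# connected components of a logical 3D mask (6-connectivity) via igraph
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  fg <- which(mask)
  if (length(fg) == 0) return(lab)
  vid <- array(0L, d); vid[fg] <- seq_along(fg)
  edges <- list()
  for (axis in 1:3) {
    nb <- shift3(vid, axis, 1L)
    sel <- vid > 0L & nb > 0L & nb != vid
    if (any(sel)) edges[[length(edges) + 1L]] <- cbind(vid[sel], nb[sel])
  }
  if (length(edges) == 0) {
    comp <- seq_along(fg)
  } else {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  # renumber components in first-voxel order for determinism
  first <- tapply(seq_along(fg), comp, min)
  remap <- integer(max(comp)); remap[as.integer(names(first))[order(first)]] <-
    seq_along(first)
  lab[fg] <- remap[comp]
  lab
}

# exact per-axis squared Euclidean distance transform (distance of foreground
# voxels to the nearest background voxel), Felzenszwalb-Huttenlocher envelopes
sq_edt <- function(mask, spacing) {
  d <- dim(mask)
  # large finite sentinel instead of Inf so the envelope intersections stay
  # well-defined; it exceeds any attainable squared distance
  big <- 1e12
  f <- array(ifelse(mask, big, 0), d)
  dt1 <- function(fv, s) {
    n <- length(fv)
    v <- integer(n); z <- numeric(n + 1)
    k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
    for (q in 2:n) {
      repeat {
        p <- v[k]
        sint <- ((fv[q] + (s * q)^2) - (fv[p] + (s * p)^2)) /
          (2 * s^2 * (q - p))
        if (sint <= z[k]) { k <- k - 1L } else break
      }
      k <- k + 1L; v[k] <- q; z[k] <- sint; z[k + 1] <- Inf
    }
    out <- numeric(n); k <- 1L
    for (q in 1:n) {
      while (z[k + 1] < q) k <- k + 1L
      out[q] <- (s * (q - v[k]))^2 + fv[v[k]]
    }
    out
  }
  for (axis in 1:3) {
    s <- spacing[axis]
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(f, perm)
    m <- matrix(ap, nrow = d[axis])
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      if (any(is.finite(col)) && any(col > 0)) m[, j] <- dt1(col, s)
    }
    f <- aperm(array(m, dim = d[perm]), match(seq_len(3), perm))
  }
  f
}

## --- operations ----------------------------------------------------------

#' Detect spots in a 3D channel volume
#'
#' Laplacian-of-Gaussian blob detection: the volume is smoothed with a
#' separable Gaussian (sigma given in um, converted to voxels per axis), the
#' negated 6-neighbour Laplacian is the blob response, and responses that are
#' strict local maxima over their 26-neighbourhood and exceed `threshold` are
#' reported. Sub-voxel positions come from the response centre-of-mass in the
#' 3x3x3 neighbourhood.
#'
#' @param vol 3D numeric array.
#' @param voxel_size_um voxel size (x, y, z) in um; required (the z
#'   anisotropy enters both the smoothing and the Laplacian).
#' @param sigma_um Gaussian scale in um (default one xy voxel).
#' @param threshold minimum LoG response (default: Otsu on the positive
#'   responses).
#' @return data frame `x`, `y`, `z` (um, post-expansion), `quality` (response).
#' @export
detect_spots <- function(vol, voxel_size_um, sigma_um = NULL, threshold = NULL) {
  if (missing(voxel_size_um) || is.null(voxel_size_um) ||
      length(voxel_size_um) != 3 || any(voxel_size_um <= 0))
    stop("voxel_size_um (x, y, z) must be provided and positive")
  stopifnot(length(dim(vol)) == 3)
  if (is.null(sigma_um)) sigma_um <- voxel_size_um[1]
  sig_vox <- pmax(sigma_um / voxel_size_um, 0.5)
  sm <- gauss_smooth3(vol, sig_vox)
  resp <- -laplacian3(sm, voxel_size_um) * mean(voxel_size_um)^2
  if (is.null(threshold)) {
    pos <- resp[resp > 0]
    if (length(pos) == 0) return(data.frame(x = numeric(0), y = numeric(0),
                                            z = numeric(0), quality = numeric(0)))
    threshold <- otsu_threshold(pos)
  }
  if (!is.finite(threshold))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      quality = numeric(0)))
  is_max <- resp > threshold
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    is_max <- is_max & resp >= shift3(resp, axis, by)
  }
  # full 26-neighbourhood check on the survivors
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      quality = numeric(0)))
  d <- dim(resp)
  keep <- logical(nrow(cand))
  pos_out <- matrix(NA_real_, nrow(cand), 3)
  for (i in seq_len(nrow(cand))) {
    ijk <- cand[i, ]
    rng <- lapply(1:3, function(a) max(1, ijk[a] - 1):min(d[a], ijk[a] + 1))
    nb <- resp[rng[[1]], rng[[2]], rng[[3]]]
    v0 <- resp[ijk[1], ijk[2], ijk[3]]
    if (v0 < max(nb) - 1e-12) next
    keep[i] <- TRUE
    # centre of mass of the (positive) response in the neighbourhood
    w <- pmax(nb, 0)
    if (sum(w) > 0) {
      com <- vapply(1:3, function(a) {
        coords <- slice.index(nb, a)
        sum(w * rng[[a]][coords]) / sum(w)
      }, numeric(1))
    } else com <- ijk
    pos_out[i, ] <- (com - 0.5) * voxel_size_um
  }
  out <- data.frame(x = pos_out[keep, 1], y = pos_out[keep, 2],
                    z = pos_out[keep, 3],
                    quality = resp[cand[keep, , drop = FALSE]])
  out[order(out$x, out$y, out$z), , drop = FALSE]
}

#' Segment somas from a DAPI volume
#'
#' Otsu threshold, 6-connected component labelling, and a distance-transform
#' watershed-style split: components containing several well-separated
#' distance maxima are divided by nearest-seed assignment. Objects smaller
#' than `min_volume_um3` are dropped. With `bypass = TRUE` the input is
#' assumed to be a labelled mask already and is returned unchanged.
#'
#' @param dapi 3D numeric array (or integer label array with `bypass`).
#' @param voxel_size_um voxel size (x, y, z) in um.
#' @param min_volume_um3 minimum object volume (default 100).
#' @param min_seed_sep_um minimum distance between watershed seeds
#'   (default 5 um).
#' @param bypass return `dapi` unchanged (externally provided masks).
#' @return integer label array (0 = background) with attribute
#'   `volumes_um3` (named per-label post-expansion volume).
#' @export
segment_somas <- function(dapi, voxel_size_um, min_volume_um3 = 100,
                          min_seed_sep_um = 5, bypass = FALSE) {
  if (bypass) {
    lab <- dapi
    storage.mode(lab) <- "integer"
    ids <- sort(setdiff(unique(as.integer(lab)), 0L))
    vx <- prod(voxel_size_um)
    attr(lab, "volumes_um3") <- setNames(
      vapply(ids, function(i) sum(lab == i) * vx, numeric(1)),
      as.character(ids))
    return(lab)
  }
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be > 0")
  stopifnot(length(dim(dapi)) == 3)
  thr <- otsu_threshold(as.numeric(dapi))
  mask <- dapi > thr
  lab <- label_components(mask)
  n_comp <- max(lab)
  if (n_comp > 0) {
    dt <- sqrt(sq_edt(mask, voxel_size_um))
    out <- array(0L, dim(lab)); next_id <- 0L
    for (cid in seq_len(n_comp)) {
      vox <- which(lab == cid)
      if (length(vox) == 0) next
      ijk <- arrayInd(vox, dim(lab))
      dvals <- dt[vox]
      # greedy maxima-picking: seeds in decreasing depth, suppressed within
      # min_seed_sep_um of an accepted seed
      ord <- order(-dvals)
      seeds <- matrix(numeric(0), 0, 3)
      seed_depth <- numeric(0)
      um <- sweep(ijk, 2, voxel_size_um, `*`)
      for (i in ord) {
        if (dvals[i] < max(dvals) * 0.3) break
        if (nrow(seeds) > 0) {
          dd <- sqrt(rowSums((seeds - matrix(um[i, ], nrow(seeds), 3,
                                             byrow = TRUE))^2))
          if (min(dd) < min_seed_sep_um) next
        }
        seeds <- rbind(seeds, um[i, ]); seed_depth <- c(seed_depth, dvals[i])
      }
      if (nrow(seeds) <= 1) {
        next_id <- next_id + 1L
        out[vox] <- next_id
      } else {
        assign_to <- max.col(-vapply(seq_len(nrow(seeds)), function(s) {
          rowSums(sweep(um, 2, seeds[s, ])^2)
        }, numeric(nrow(um))))
        for (s in seq_len(nrow(seeds))) {
          next_id <- next_id + 1L
          out[vox[assign_to == s]] <- next_id
        }
      }
    }
    lab <- out
  }
  # minimum-volume filter, then renumber densely
  vx <- prod(voxel_size_um)
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  vols <- vapply(ids, function(i) sum(lab == i) * vx, numeric(1))
  keep <- ids[vols >= min_volume_um3]
  out <- array(0L, dim(lab))
  for (j in seq_along(keep)) out[lab == keep[j]] <- j
  attr(out, "volumes_um3") <- setNames(vols[match(keep, ids)],
                                       as.character(seq_along(keep)))
  out
}

#' Correct an observed volume for physical expansion
#'
#' Expansion scales lengths by the expansion factor, so volumes scale by its
#' cube: `volume_pre = volume_observed / expansion_factor^3`.
#'
#' @param volume_um3 observed (post-expansion) volume(s).
#' @param expansion_factor linear expansion factor, >= 1.
#' @return pre-expansion volume(s).
#' @examples
#' correct_expansion(800, 2)  # 100
#' @export
correct_expansion <- function(volume_um3, expansion_factor) {
  if (expansion_factor < 1) stop("expansion_factor must be >= 1")
  volume_um3 / expansion_factor^3
}

#' Assign detected spots to segmented somas
#'
#' A spot belongs to the soma whose voxel (for labelled arrays) or ellipsoid
#' (for geometry tables) contains its coordinate; spots outside every soma are
#' unassigned. Voxel containment uses 0-based half-open voxel bounds, i.e.
#' coordinate `c` falls in voxel `floor(c / voxel_size)`; a spot exactly on a
#' boundary belongs to the voxel on its non-negative side.
#'
#' @param spots data frame with `gene`, `x`, `y`, `z` (post-expansion um).
#' @param somas either an integer label array (with `voxel_size_um`) or a
#'   cell-geometry data frame with columns `cell`, `cx`, `cy`, `cz`, `ax`,
#'   `ay`, `az` (ellipsoid centres and semi-axes, post-expansion um).
#' @param voxel_size_um required when `somas` is a label array.
#' @return list with `counts` (cells x genes integer matrix), `unassigned`
#'   (per-gene count) and `assignment` (per-spot label, 0 = background).
#'   Assigned + unassigned always equals the number of spots.
#' @export
assign_spots <- function(spots, somas, voxel_size_um = NULL) {
  stopifnot(all(c("gene", "x", "y", "z") %in% names(spots)))
  genes <- sort(unique(as.character(spots$gene)))
  if (is.data.frame(somas)) {
    stopifnot(all(c("cell", "cx", "cy", "cz", "ax", "ay", "az") %in% names(somas)))
    n <- nrow(somas)
    lab_of <- integer(nrow(spots))
    if (nrow(spots) > 0) {
      for (i in seq_len(n)) {
        d2 <- ((spots$x - somas$cx[i]) / somas$ax[i])^2 +
              ((spots$y - somas$cy[i]) / somas$ay[i])^2 +
              ((spots$z - somas$cz[i]) / somas$az[i])^2
        hit <- d2 <= 1 & lab_of == 0L
        lab_of[hit] <- i
      }
    }
    cell_ids <- as.character(somas$cell)
  } else {
    if (is.null(voxel_size_um)) stop("voxel_size_um required for label arrays")
    d <- dim(somas)
    ijk <- cbind(floor(spots$x / voxel_size_um[1]) + 1,
                 floor(spots$y / voxel_size_um[2]) + 1,
                 floor(spots$z / voxel_size_um[3]) + 1)
    inside <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
              ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
              ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    lab_of <- integer(nrow(spots))
    lab_of[inside] <- somas[ijk[inside, , drop = FALSE]]
    n <- max(somas)
    cell_ids <- as.character(seq_len(n))
  }
  counts <- matrix(0L, n, length(genes), dimnames = list(cell_ids, genes))
  unassigned <- setNames(integer(length(genes)), genes)
  for (g in genes) {
    sel <- spots$gene == g
    tab <- tabulate(lab_of[sel], nbins = n)
    counts[, g] <- tab
    unassigned[g] <- sum(sel) - sum(tab)
  }
  list(counts = counts, unassigned = unassigned, assignment = lab_of)
}

#' Classify neurons into molecular classes from per-cell densities
#'
#' Two-class k-means on per-gene z-scored log1p transcript densities
#' (count / soma volume). The cluster with the higher mean CDKN1A + NFKBIA
#' density is named PY2 — the classification is purely molecular, soma size
#' plays no role. If the two-cluster split is weak (mean silhouette on the
#' density profile below `silhouette_floor`) a `"no-split"` warning is
#' emitted. Degenerate all-equal input yields all-`"unassigned"`.
#'
#' @param counts cells x genes matrix of spot counts.
#' @param volumes_um3 per-cell soma volume (same length/order as rows).
#' @param seed RNG seed for k-means restarts.
#' @param anchor_genes genes whose density names the high class
#'   (default CDKN1A, NFKBIA).
#' @param silhouette_floor minimum mean silhouette for a credible split
#'   (default 0.3; see the methods vignette for the Monte-Carlo calibration).
#' @param max_sil_cells silhouette is estimated on at most this many cells.
#' @return factor of labels `PY1`/`PY2` (or `unassigned`), with attributes
#'   `silhouette` and `densities` (the cells x genes density matrix).
#' @export
classify_cells <- function(counts, volumes_um3, seed = 1L,
                           anchor_genes = c("CDKN1A", "NFKBIA"),
                           silhouette_floor = 0.3, max_sil_cells = 1000L) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(volumes_um3), all(volumes_um3 > 0))
  if (nrow(counts) < 10) stop("need >= 10 cells to classify")
  dens <- counts / volumes_um3
  x <- scale(log1p(dens))
  if (all(!is.finite(x)) || all(apply(dens, 2, function(v) length(unique(v))) == 1)) {
    lab <- factor(rep("unassigned", nrow(counts)),
                  levels = c("PY1", "PY2", "unassigned"))
    attr(lab, "silhouette") <- NA_real_
    attr(lab, "densities") <- dens
    return(lab)
  }
  x[!is.finite(x)] <- 0
  km <- with_seed(seed, kmeans(x, centers = 2, nstart = 25, iter.max = 100))
  anchors <- intersect(anchor_genes, colnames(counts))
  if (length(anchors) == 0) stop("anchor genes absent from count matrix")
  m1 <- mean(dens[km$cluster == 1, anchors, drop = FALSE])
  m2 <- mean(dens[km$cluster == 2, anchors, drop = FALSE])
  py2_cl <- if (m2 > m1) 2L else 1L
  lab <- factor(ifelse(km$cluster == py2_cl, "PY2", "PY1"),
                levels = c("PY1", "PY2", "unassigned"))
  sil <- mean_silhouette(x, km$cluster, max_sil_cells, seed)
  if (is.finite(sil) && sil < silhouette_floor)
    warning(sprintf("no-split: mean silhouette %.3f below floor %.3f; ",
                    sil, silhouette_floor),
            "the two-class structure is not supported", call. = FALSE)
  attr(lab, "silhouette") <- sil
  attr(lab, "densities") <- dens
  lab
}

# mean silhouette width for a 2-cluster partition, on a subsample
mean_silhouette <- function(x, cl, max_n, seed) {
  n <- nrow(x)
  idx <- if (n > max_n) with_seed(seed, sample(n, max_n)) else seq_len(n)
  xs <- x[idx, , drop = FALSE]; cs <- cl[idx]
  if (length(unique(cs)) < 2) return(NA_real_)
  dd <- as.matrix(stats::dist(xs))
  s <- vapply(seq_along(cs), function(i) {
    own <- cs == cs[i]; own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(dd[i, own])
    b <- mean(dd[i, cs != cs[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Through-origin density slope
#'
#' The class-level transcript density of a gene is the slope of the
#' least-squares line through the origin of per-cell count versus soma
#' volume: `slope = sum(count * volume) / sum(volume^2)` (zero volume implies
#' zero expected count). An ordinary two-parameter fit is available behind
#' `intercept = TRUE` for comparison.
#'
#' @param counts per-cell spot counts of one gene.
#' @param volumes_um3 per-cell soma volumes.
#' @param subset optional logical/integer subset of cells (e.g. one class).
#' @param intercept fit an ordinary line instead (returns its slope).
#' @return slope in counts per um^3.
#' @export
density_slope <- function(counts, volumes_um3, subset = NULL,
                          intercept = FALSE) {
  stopifnot(length(counts) == length(volumes_um3))
  if (!is.null(subset)) {
    counts <- counts[subset]; volumes_um3 <- volumes_um3[subset]
  }
  if (length(counts) < 3) stop("need >= 3 cells for the density slope")
  if (intercept) {
    unname(coef(lm(counts ~ volumes_um3))[2])
  } else {
    sum(counts * volumes_um3) / sum(volumes_um3^2)
  }
}

#' Paired per-sample comparison with a normality gate
#'
#' Compares matched per-sample summary values (e.g. the PY1 and PY2 density
#' slopes of one gene across samples). Differences are tested for normality
#' (Shapiro-Wilk at `alpha_normal`); if consistent with normal, a two-tailed
#' paired t test is used, otherwise the exact two-tailed Wilcoxon signed-rank
#' test. Identical pairs short-circuit to p = 1.
#'
#' @param x,y paired per-sample values (same length >= 4).
#' @param alpha_normal significance level of the normality gate (default 0.05).
#' @return list with `test` (`"paired t"`, `"signed-rank"`, `"degenerate"`),
#'   `statistic`, `p.value`, `shapiro_p`, `n`.
#' @export
per_sample_paired_compare <- function(x, y, alpha_normal = 0.05) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 paired samples")
  d <- y - x
  if (all(d == 0))
    return(list(test = "degenerate", statistic = NA_real_, p.value = 1,
                shapiro_p = NA_real_, n = n))
  sw <- tryCatch(shapiro.test(d)$p.value, error = function(e) 0)
  if (sw >= alpha_normal) {
    tt <- t.test(y, x, paired = TRUE)
    list(test = "paired t", statistic = unname(tt$statistic),
         p.value = tt$p.value, shapiro_p = sw, n = n)
  } else {
    wt <- wilcoxon_signed_rank(d)
    list(test = "signed-rank", statistic = unname(wt$statistic),
         p.value = wt$p.value, shapiro_p = sw, n = n)
  }
}
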