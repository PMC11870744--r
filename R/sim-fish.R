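## Expansion-FISH sample simulator. Somas are axis-aligned ellipsoids (so the
## ground-truth volume is analytic), spot counts are Poisson in
## density x pre-expansion volume, and spots are uniform within the soma.
## Two output modes: a spot/cell table (with soma geometry for analytic
## containment) or rendered 3D stacks (DAPI + one channel per gene) at the
## post-expansion voxel size.

fish_genes <- function() c("NFKBIA", "CDKN1A", "CCL2", "CUX2", "NEFM", "NEFH")

default_fish_densities <- function() {
  # spots per um^3 of pre-expansion soma volume; PY2 elevated for the
  # senescence / neurofilament genes, CUX2 similar between classes
  m <- rbind(NFKBIA = c(0.05, 0.12), CDKN1A = c(0.03, 0.10),
             CCL2 = c(0.02, 0.05), CUX2 = c(0.08, 0.10),
             NEFM = c(0.04, 0.09), NEFH = c(0.03, 0.07))
  colnames(m) <- c("PY1", "PY2")
  m
}

#' Specification for the expansion-FISH simulator
#'
#' Defaults emulate one imaged brain slice: ~31% of pyramidal neurons in the
#' high (PY2) molecular class (2369 of 7688 across the full data set), PY2
#' somas stochastically larger than PY1, six probed genes with PY2-elevated
#' densities for the senescence and neurofilament markers, 2x physical
#' expansion, and the post-expansion voxel size (0.23, 0.23, 0.4) um.
#'
#' @param n_cells number of neurons.
#' @param fraction_py2 expected fraction in the PY2 class (strictly in (0,1)).
#' @param radius_meanlog named numeric (PY1, PY2): log mean of the
#'   sphere-equivalent pre-expansion soma radius (um).
#' @param radius_sdlog log-sd of the radius distribution.
#' @param densities 6 x 2 matrix (genes x PY1/PY2) of spots per um^3 of
#'   pre-expansion volume; all entries >= 0.
#' @param expansion_factor physical expansion (>= 1, default 2).
#' @param voxel_size_um post-expansion voxel size, (x, y, z).
#' @param axis_jitter_sdlog log-sd of the ellipsoid axis anisotropy (volume
#'   preserved; 0 gives spheres).
#' @param n_biocytin number of cells flagged as biocytin-filled per class.
#' @param seed integer RNG seed.
#' @return list of class `"fish_sim_spec"`.
#' @export
fish_sim_spec <- function(n_cells = 339, fraction_py2 = 2369 / 7688,
                          radius_meanlog = c(PY1 = log(6), PY2 = log(7.2)),
                          radius_sdlog = 0.12,
                          densities = default_fish_densities(),
                          expansion_factor = 2,
                          voxel_size_um = c(0.23, 0.23, 0.4),
                          axis_jitter_sdlog = 0.08,
                          n_biocytin = 2, seed = 1L) {
  if (fraction_py2 <= 0 || fraction_py2 >= 1)
    stop("fraction_py2 must be strictly between 0 and 1")
  if (any(densities < 0)) stop("densities must be >= 0")
  if (expansion_factor < 1) stop("expansion_factor must be >= 1")
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be > 0")
  stopifnot(nrow(densities) == length(fish_genes()),
            all(c("PY1", "PY2") %in% colnames(densities)))
  rownames(densities) <- fish_genes()
  structure(list(n_cells = as.integer(n_cells), fraction_py2 = fraction_py2,
                 radius_meanlog = radius_meanlog, radius_sdlog = radius_sdlog,
                 densities = densities, expansion_factor = expansion_factor,
                 voxel_size_um = voxel_size_um,
                 axis_jitter_sdlog = axis_jitter_sdlog,
                 n_biocytin = n_biocytin, seed = as.integer(seed)),
            class = "fish_sim_spec")
}

#' Simulate an expansion-FISH sample
#'
#' In `"spot_table"` mode the sample carries a cell table (class, analytic
#' pre-/post-expansion soma volume, ellipsoid geometry, biocytin flag), a spot
#' table (gene, x/y/z in post-expansion um) and the true per-cell per-gene
#' counts. In `"volume"` mode the same geometry is additionally rendered into
#' 3D stacks at the post-expansion voxel size: a DAPI channel with filled
#' ellipsoids and one channel per gene with Gaussian spots (sigma = 1 voxel in
#' xy, 1 z-plane).
#'
#' @param spec a [fish_sim_spec()].
#' @param mode `"spot_table"` or `"volume"`.
#' @param noise_sd additive Gaussian noise on rendered channels (volume mode).
#' @param make_spots generate individual spot coordinates (default TRUE); with
#'   FALSE only the per-cell counts are drawn, which is much lighter for
#'   large cohorts where only count-level quantities are needed.
#' @return list of class `"fish_sample"`: `cells`, `spots`, `voxel_size_um`,
#'   `expansion_factor`, `truth` (spec + true counts matrix), and in volume
#'   mode `dapi` plus `channels` (named list of 3D arrays).
#' @export
gen_fish <- function(spec, mode = c("spot_table", "volume"), noise_sd = 0,
                     make_spots = TRUE) {
  stopifnot(inherits(spec, "fish_sim_spec"))
  mode <- match.arg(mode)
  if (mode == "volume" && !make_spots)
    stop("volume mode requires make_spots = TRUE")
  genes <- fish_genes()
  with_seed(spec$seed, {
    n <- spec$n_cells
    cls <- ifelse(runif(n) < spec$fraction_py2, "PY2", "PY1")
    r <- rlnorm(n, spec$radius_meanlog[cls], spec$radius_sdlog)
    # anisotropy jitter normalized to preserve r^3 (analytic volume)
    ax <- matrix(rlnorm(3 * n, 0, spec$axis_jitter_sdlog), n, 3)
    ax <- ax / exp(rowMeans(log(ax)))       # geometric mean 1
    semi_pre <- ax * r                      # pre-expansion semi-axes, um
    vol_pre <- 4 / 3 * pi * r^3
    ef <- spec$expansion_factor
    semi_post <- semi_pre * ef
    vol_post <- vol_pre * ef^3

    # lay cells out on a jittered 3D grid in post-expansion coordinates
    max_sa <- max(semi_post)
    pitch <- 2 * max_sa + 4
    n_side <- ceiling(n^(1 / 3))
    grid <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                                  z = seq_len(n_side)))[seq_len(n), , drop = FALSE]
    centers <- grid * pitch - pitch / 2 +
      matrix(runif(3 * n, -1, 1), n, 3)

    dens <- t(spec$densities[, cls, drop = FALSE])   # cells x genes
    counts <- matrix(rpois(n * length(genes), dens * vol_pre),
                     n, length(genes), dimnames = list(NULL, genes))

    spots <- vector("list", length(genes))
    if (make_spots) for (g in seq_along(genes)) {
      per_cell <- counts[, g]
      tot <- sum(per_cell)
      if (tot == 0) {
        spots[[g]] <- data.frame(gene = character(0), x = numeric(0),
                                 y = numeric(0), z = numeric(0),
                                 quality = numeric(0))
        next
      }
      cell_of <- rep(seq_len(n), per_cell)
      # uniform points in the unit ball, scaled by the cell's ellipsoid
      u <- matrix(rnorm(3 * tot), tot, 3)
      u <- u / sqrt(rowSums(u^2)) * runif(tot)^(1 / 3)
      xyz <- u * semi_post[cell_of, , drop = FALSE] +
        centers[cell_of, , drop = FALSE]
      spots[[g]] <- data.frame(gene = genes[g], x = xyz[, 1], y = xyz[, 2],
                               z = xyz[, 3], quality = 1)
    }
    spots <- if (make_spots) do.call(rbind, spots) else
      data.frame(gene = character(0), x = numeric(0), y = numeric(0),
                 z = numeric(0), quality = numeric(0))

    bio <- logical(n)
    for (cc in c("PY1", "PY2")) {
      idx <- which(cls == cc)
      bio[sample(idx, min(spec$n_biocytin, length(idx)))] <- TRUE
    }
    cells <- data.frame(
      cell = sprintf("cell%04d", seq_len(n)),
      class_true = cls,
      volume_pre_um3 = vol_pre, volume_post_um3 = vol_post,
      cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
      ax = semi_post[, 1], ay = semi_post[, 2], az = semi_post[, 3],
      biocytin = bio, stringsAsFactors = FALSE
    )
    out <- list(cells = cells, spots = spots,
                voxel_size_um = spec$voxel_size_um,
                expansion_factor = ef,
                truth = list(spec = spec, counts = counts,
                             class = cls, volume_pre_um3 = vol_pre))
    if (mode == "volume") {
      dims <- ceiling((n_side * pitch) / spec$voxel_size_um)
      vx <- spec$voxel_size_um
      dapi <- array(0, dims)
      # voxel-center coordinate grids
      gx <- (seq_len(dims[1]) - 0.5) * vx[1]
      gy <- (seq_len(dims[2]) - 0.5) * vx[2]
      gz <- (seq_len(dims[3]) - 0.5) * vx[3]
      for (i in seq_len(n)) {
        rngx <- which(abs(gx - centers[i, 1]) <= semi_post[i, 1])
        rngy <- which(abs(gy - centers[i, 2]) <= semi_post[i, 2])
        rngz <- which(abs(gz - centers[i, 3]) <= semi_post[i, 3])
        if (!length(rngx) || !length(rngy) || !length(rngz)) next
        dx2 <- ((gx[rngx] - centers[i, 1]) / semi_post[i, 1])^2
        dy2 <- ((gy[rngy] - centers[i, 2]) / semi_post[i, 2])^2
        dz2 <- ((gz[rngz] - centers[i, 3]) / semi_post[i, 3])^2
        inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
        dapi[rngx, rngy, rngz][inside] <- 1
      }
      channels <- lapply(genes, function(gname) {
        ch <- array(0, dims)
        sp <- spots[spots$gene == gname, , drop = FALSE]
        if (nrow(sp) > 0) {
          for (s in seq_len(nrow(sp))) {
            ijk <- pmin(pmax(floor(c(sp$x[s] / vx[1], sp$y[s] / vx[2],
                                     sp$z[s] / vx[3])) + 1, 1), dims)
            ch <- add_gaussian_spot(ch, ijk, sigma_vox = c(1, 1, 1))
          }
        }
        ch
      })
      names(channels) <- genes
      if (noise_sd > 0) {
        dapi <- dapi + array(rnorm(prod(dims), 0, noise_sd), dims)
        channels <- lapply(channels, function(ch)
          ch + array(rnorm(prod(dims), 0, noise_sd), dims))
      }
      out$dapi <- dapi
      out$channels <- channels
    }
    structure(out, class = "fish_sample")
  })
}

# add a unit-amplitude separable Gaussian at voxel ijk (3 voxels support)
add_gaussian_spot <- function(a, ijk, sigma_vox) {
  d <- dim(a)
  off <- -3:3
  kx <- exp(-off^2 / (2 * sigma_vox[1]^2))
  ky <- exp(-off^2 / (2 * sigma_vox[2]^2))
  kz <- exp(-off^2 / (2 * sigma_vox[3]^2))
  ix <- ijk[1] + off; iy <- ijk[2] + off; iz <- ijk[3] + off
  okx <- ix >= 1 & ix <= d[1]; oky <- iy >= 1 & iy <= d[2]
  okz <- iz >= 1 & iz <= d[3]
  blob <- outer(outer(kx[okx], ky[oky]), kz[okz])
  a[ix[okx], iy[oky], iz[okz]] <- a[ix[okx], iy[oky], iz[okz]] + blob
  a
}

#' @export
print.fish_sample <- function(x, ...) {
  cat(sprintf("fish_sample: %d cells (%d PY2-true), %d spots, EF = %g\n",
              nrow(x$cells), sum(x$cells$class_true == "PY2"),
              nrow(x$spots), x$expansion_factor))
  if (!is.null(x$dapi))
    cat(sprintf("  rendered stacks: %s voxels\n",
                paste(dim(x$dapi), collapse = " x ")))
  invisible(x)
}

#' Write FISH tables as TSV
#'
#' Writes `<prefix>_cells.tsv` and `<prefix>_spots.tsv`.
#' @param x a `"fish_sample"`.
#' @param prefix path prefix.
#' @export
write_fish_tables <- function(x, prefix) {
  stopifnot(inherits(x, "fish_sample"))
  write.table(x$cells, paste0(prefix, "_cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(x$spots, paste0(prefix, "_spots.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
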