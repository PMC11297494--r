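# Memoized coefficient caches shared across test files; building the
# low-order tables is cheap but there is no reason to repeat it.
.cache_store <- new.env(parent = emptyenv())
get_test_cache <- function(order) {
  key <- as.character(order)
  if (is.null(.cache_store[[key]])) .cache_store[[key]] <- build_cache(order)
  .cache_store[[key]]
}

# full compute pipeline for a cloud: grid, frame, moments at given order
cloud_moments <- function(cloud, cache, order, radius_mode = "gyration_multiple") {
  g <- rasterize(cloud)
  f <- unit_ball_frame(g, radius_mode = radius_mode)
  list(grid = g, frame = f,
       zm = zernike_moments(geometric_moments(g, f, order), cache, order))
}

# Gram matrix of the chi-implied basis by brute-force quadrature on a
# D^3 midpoint grid over the unit ball, evaluated in z-slabs.
quadrature_gram <- function(cache, D) {
  x <- seq(-1 + 1 / D, 1 - 1 / D, length.out = D)
  h <- x[2] - x[1]
  mono <- cache$mono_index
  nslot <- nrow(cache$zm_index)
  chi_t_re <- Matrix::t(cache$chi_re)
  chi_t_im <- Matrix::t(cache$chi_im)
  G <- matrix(0 + 0i, nslot, nslot)
  xy <- expand.grid(x = x, y = x)
  for (kz in seq_len(D)) {
    keep <- xy$x^2 + xy$y^2 + x[kz]^2 <= 1
    if (!any(keep)) next
    px <- xy$x[keep]; py <- xy$y[keep]; pz <- x[kz]
    P <- matrix(0, length(px), nrow(mono))
    for (j in seq_len(nrow(mono))) {
      P[, j] <- px^mono$r[j] * py^mono$s[j] * pz^mono$t[j]
    }
    B <- as.matrix(P %*% chi_t_re) + 1i * as.matrix(P %*% chi_t_im)
    G <- G + Conj(t(B)) %*% B
  }
  G * h^3
}

# an exactly axis-aligned anisotropic density: centered product Gaussian
# with distinct per-axis widths on an odd, symmetric grid, so the second-
# order tensor is diagonal to machine precision with descending entries
aligned_lobe_grid <- function(D = 33L, widths = c(0.30, 0.20, 0.13)) {
  stopifnot(D %% 2L == 1L)
  half <- (D - 1L) / 2L
  ax <- (-half):half
  R <- half  # physical half-width in voxels
  gx <- exp(-ax^2 / (2 * (widths[1] * D)^2))
  gy <- exp(-ax^2 / (2 * (widths[2] * D)^2))
  gz <- exp(-ax^2 / (2 * (widths[3] * D)^2))
  vals <- outer(outer(gx, gy), gz)
  voxel_grid(vals, 1.0, origin = c(-half, -half, -half))
}
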