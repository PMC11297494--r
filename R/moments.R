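#' Geometric moments of a grid in unit-ball coordinates
#'
#' Computes the raw monomial moments
#' `M[r,s,t] = sum_voxels value * u1^r * u2^s * u3^t * (voxel_edge*scale)^3`
#' over unit-ball coordinates `u = scale * (x - center)`, for all
#' `r + s + t <= max_order`.  The sum is evaluated with separable per-axis
#' power tables combined by nested tensor contractions, which is
#' mathematically identical to the naive per-voxel triple loop but reduces
#' the work to three dense matrix products.  Voxels falling outside the unit
#' ball (possible under the `gyration_multiple` frame) are excluded and the
#' excluded mass fraction is recorded.
#'
#' @param grid a `voxel_grid`.
#' @param frame a `unit_ball_frame` for the grid.
#' @param max_order maximum total degree `N` (up to 40).
#' @return object of class `geometric_moments`: list with `order`, `values`
#'   (vector aligned with [monomial_index()]), `index`, and attribute
#'   `clipped_fraction`.
#' @export
geometric_moments <- function(grid, frame, max_order) {
  max_order <- check_order(max_order, lower = 0L)
  if (!inherits(grid, "voxel_grid")) {
    abort_validation("geometric_moments expects a voxel_grid")
  }
  if (!inherits(frame, "unit_ball_frame")) {
    abort_validation("geometric_moments expects a unit_ball_frame")
  }
  d <- dim(grid$values)
  u <- lapply(1:3, function(a) {
    (grid$origin[a] + (seq_len(d[a]) - 1) * grid$voxel_edge - frame$center[a]) *
      frame$scale
  })
  vals <- grid$values
  total <- sum(vals)
  # clip density outside the unit ball
  clipped <- 0
  if (max(abs(u[[1]]))^2 + max(abs(u[[2]]))^2 + max(abs(u[[3]]))^2 > 1) {
    r2 <- outer(outer(u[[1]]^2, u[[2]]^2, `+`), u[[3]]^2, `+`)
    out <- r2 > 1
    if (any(out & vals > 0)) {
      clipped <- sum(vals[out]) / max(total, .Machine$double.xmin)
      vals <- vals * !out
    }
  }
  N1 <- max_order + 1L
  pow <- lapply(1:3, function(a) outer(u[[a]], 0:max_order, `^`))  # D_a x N1
  # contract axis 1: B[r, (j,k)]
  B <- crossprod(pow[[1]], matrix(vals, d[1], d[2] * d[3]))
  # contract axis 2: C[s, (r,k)]
  Bp <- matrix(aperm(array(B, c(N1, d[2], d[3])), c(2L, 1L, 3L)), d[2], N1 * d[3])
  C <- crossprod(pow[[2]], Bp)
  # contract axis 3: M[t, (r,s)]
  Cp <- matrix(aperm(array(C, c(N1, N1, d[3])), c(3L, 2L, 1L)), d[3], N1 * N1)
  M <- crossprod(pow[[3]], Cp)                      # N1 x (s, r) blocks
  Marr <- aperm(array(M, c(N1, N1, N1)), c(2L, 3L, 1L))  # [t,r,s] -> [r,s,t]
  Marr <- Marr * (grid$voxel_edge * frame$scale)^3
  idx <- monomial_index(max_order)
  structure(list(order = max_order,
                 values = Marr[cbind(idx$r + 1L, idx$s + 1L, idx$t + 1L)],
                 index = idx),
            class = "geometric_moments", clipped_fraction = clipped)
}

#' @export
print.geometric_moments <- function(x, ...) {
  cat(sprintf("geometric_moments: order %d, M[0,0,0] = %.6g\n",
              x$order, x$values[1]))
  invisible(x)
}

# internal constructor for a zernike_moments object
new_zernike_moments <- function(order, index, values) {
  structure(list(order = order, index = index, values = values),
            class = "zernike_moments")
}

#' Contract geometric moments into complex 3D Zernike moments
#'
#' `Omega[n,l,m] = sum_{r+s+t<=n} conj(chi[n,l,m,r,s,t]) * M[r,s,t]`,
#' performed as a single sparse-dense product against the cache's
#' coefficient matrix.  The output order is `min(gm$order, cache$max_order)`
#' (or lower if `max_order` is given); the geometric moments must cover at
#' least that order.
#'
#' @param gm a `geometric_moments` object.
#' @param cache a `zernike_cache`.
#' @param max_order optional lower output order.
#' @return object of class `zernike_moments`: `order`, `index` (the
#'   [zm_index()] table) and complex `values`.
#' @export
zernike_moments <- function(gm, cache, max_order = NULL) {
  if (!inherits(gm, "geometric_moments")) {
    abort_validation("zernike_moments expects a geometric_moments object")
  }
  if (!inherits(cache, "zernike_cache")) {
    abort_validation("zernike_moments expects a zernike_cache")
  }
  if (is.null(max_order)) {
    order_out <- min(gm$order, cache$max_order)
  } else {
    order_out <- check_order(max_order)
    if (order_out > cache$max_order) {
      abort_validation("requested order exceeds cache order")
    }
    if (order_out > gm$order) {
      abort_validation("geometric moments order below requested output order")
    }
  }
  eff <- truncate_cache(cache, order_out)
  M <- gm_as_columns(list(gm), eff)
  vals <- contract_moments(M, eff)
  new_zernike_moments(order_out, eff$zm_index, vals[, 1L])
}

# order gm values into the cache's monomial column layout; returns a matrix
# with one column per grid
gm_as_columns <- function(gms, cache) {
  key_cache <- with(cache$mono_index, paste(r, s, t))
  vapply(gms, function(gm) {
    if (gm$order == cache$max_order) return(gm$values)
    pos <- match(key_cache, with(gm$index, paste(r, s, t)))
    gm$values[pos]
  }, numeric(nrow(cache$mono_index)))
}

contract_moments <- function(M, cache) {
  re <- as.matrix(cache$chi_re %*% M)
  im <- -as.matrix(cache$chi_im %*% M)   # conj(chi)
  matrix(complex(real = re, imaginary = im), nrow = nrow(re))
}

#' @export
print.zernike_moments <- function(x, ...) {
  cat(sprintf("zernike_moments: order %d, %d slots, |Omega[0,0,0]| = %.6g\n",
              x$order, length(x$values), Mod(x$values[1])))
  invisible(x)
}

#' Batched Zernike moments over many grids
#'
#' Computes moments for a batch of `(grid, frame)` pairs.  The geometric
#' moments of each grid are gathered into the columns of one dense matrix
#' and the Zernike contraction is performed as a single stacked
#' sparse-dense product, so results are identical (up to floating-point
#' associativity) to mapping [zernike_moments()] over the batch while the
#' heavy contraction remains one array operation that alternative array
#' backends could substitute.
#'
#' @param grids non-empty list; each element a list of a `voxel_grid` and a
#'   `unit_ball_frame` (named `grid`/`frame` or positional).
#' @param max_order shared output order.
#' @param cache a `zernike_cache` of order at least `max_order`.
#' @return list of `zernike_moments`, one per input grid.
#' @export
batch_moments <- function(grids, max_order, cache) {
  if (!is.list(grids) || length(grids) == 0L) {
    abort_validation("batch_moments requires a non-empty list of grids")
  }
  max_order <- check_order(max_order)
  if (max_order > cache$max_order) {
    abort_validation("requested order exceeds cache order")
  }
  eff <- truncate_cache(cache, max_order)
  gms <- lapply(grids, function(el) {
    g <- if (!is.null(el$grid)) el$grid else el[[1L]]
    f <- if (!is.null(el$frame)) el$frame else el[[2L]]
    geometric_moments(g, f, max_order)
  })
  M <- gm_as_columns(gms, eff)
  vals <- contract_moments(M, eff)
  lapply(seq_along(gms), function(j) {
    new_zernike_moments(max_order, eff$zm_index, vals[, j])
  })
}

#' Export moments as a data.frame / CSV
#'
#' @param zm a `zernike_moments` object.
#' @param path optional CSV path; when given, rows `(n, l, m, real, imag)`
#'   are written.
#' @return data.frame with columns `n`, `l`, `m`, `real`, `imag`.
#' @export
moments_table <- function(zm, path = NULL) {
  df <- data.frame(zm$index, real = Re(zm$values), imag = Im(zm$values))
  if (!is.null(path)) {
    ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE); TRUE },
                   error = function(e) FALSE)
    if (!ok) abort_io(sprintf("cannot write moments to '%s'", path))
  }
  df
}

#' Reconstruct the full m-range moment vector of one (n, l) block
#'
#' Negative-m components follow from conjugate symmetry of moments of a
#' real density: `Omega[n,l,-m] = (-1)^m * conj(Omega[n,l,m])`.
#'
#' @param zm a `zernike_moments` object.
#' @param n,l block indices.
#' @return complex vector of length `2l + 1`, ordered `m = -l..l`.
#' @export
moment_block <- function(zm, n, l) {
  rows <- which(zm$index$n == n & zm$index$l == l)
  if (length(rows) != l + 1L) abort_validation("no such (n, l) block")
  pos <- zm$values[rows]                 # m = 0..l
  if (l == 0L) return(pos)
  m <- 1:l
  neg <- (-1)^m * Conj(pos[m + 1L])
  c(rev(neg), pos)
}
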