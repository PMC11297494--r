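# Independent oracles for the moment pipeline.
#
# The basis functions are evaluated per voxel from stable recurrences
# (normalized associated Legendre recursion for the spherical harmonics,
# the Jacobi three-term recurrence for the radial polynomials), sharing no
# code or closed-form coefficients with the package's chi-contraction path.

# normalized associated Legendre Pbar_l^m(x) (Condon-Shortley phase,
# orthonormal over the sphere with the e^{im phi} factor), for all
# 0 <= m <= l <= lmax; x may be a vector.  Returns list [[l+1]][[m+1]].
oracle_legendre <- function(x, lmax) {
  out <- lapply(0:lmax, function(l) vector("list", l + 1L))
  sx <- sqrt(pmax(0, 1 - x^2))
  pmm <- rep(sqrt(1 / (4 * pi)), length(x))
  for (m in 0:lmax) {
    if (m > 0) pmm <- -sqrt((2 * m + 1) / (2 * m)) * sx * pmm
    out[[m + 1L]][[m + 1L]] <- pmm
    if (m < lmax) {
      p_prev <- pmm
      p_cur <- x * sqrt(2 * m + 3) * pmm
      out[[m + 2L]][[m + 1L]] <- p_cur
      if (m + 2L <= lmax) {
        for (l in (m + 2L):lmax) {
          a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
          b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
          p_new <- a * (x * p_cur - b * p_prev)
          out[[l + 1L]][[m + 1L]] <- p_new
          p_prev <- p_cur; p_cur <- p_new
        }
      }
    }
  }
  out
}

# Jacobi polynomial P_k^(0, beta)(u) by the three-term recurrence; u vector.
oracle_jacobi <- function(k, beta, u) {
  if (k == 0) return(rep(1, length(u)))
  p_prev <- rep(1, length(u))
  p_cur <- 1 + (beta + 2) * (u - 1) / 2
  if (k == 1) return(p_cur)
  for (n in 2:k) {
    ab <- beta                      # alpha = 0
    c1 <- 2 * n * (n + ab) * (2 * n + ab - 2)
    c2 <- (2 * n + ab - 1) * (-beta^2)
    c3 <- (2 * n + ab - 1) * (2 * n + ab) * (2 * n + ab - 2)
    c4 <- 2 * (n - 1) * (n + beta - 1) * (2 * n + ab)
    p_new <- ((c3 * u + c2) * p_cur - c4 * p_prev) / c1
    p_prev <- p_cur; p_cur <- p_new
  }
  p_cur
}

# orthonormal radial polynomial R_nl(r) via the Jacobi recurrence
oracle_radial <- function(n, l, r) {
  k <- (n - l) %/% 2L
  sqrt(2 * n + 3) * r^l * oracle_jacobi(k, l + 0.5, 2 * r^2 - 1)
}

# per-voxel direct summation of Omega[n,l,m] = sum value * conj(Z_nlm(u)) du^3
oracle_zernike_moments <- function(grid, frame, max_order) {
  d <- dim(grid$values)
  ax <- lapply(1:3, function(a) {
    (grid$origin[a] + (seq_len(d[a]) - 1) * grid$voxel_edge -
       frame$center[a]) * frame$scale
  })
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  vals <- as.vector(grid$values)
  r <- sqrt(rowSums(pts^2))
  keep <- r <= 1 & vals != 0
  pts <- pts[keep, , drop = FALSE]; vals <- vals[keep]
  r <- r[keep]
  ct <- ifelse(r > 0, pts[, 3] / r, 1)
  phi <- atan2(pts[, 2], pts[, 1])
  leg <- oracle_legendre(ct, max_order)
  du3 <- (grid$voxel_edge * frame$scale)^3
  idx <- zm_index(max_order)
  out <- complex(length.out = nrow(idx))
  for (i in seq_len(nrow(idx))) {
    n <- idx$n[i]; l <- idx$l[i]; m <- idx$m[i]
    Z <- oracle_radial(n, l, r) * leg[[l + 1L]][[m + 1L]] * exp(1i * m * phi)
    out[i] <- sum(vals * Conj(Z)) * du3
  }
  new_zm <- structure(list(order = max_order, index = idx, values = out),
                      class = "zernike_moments")
  new_zm
}

# naive triple-loop geometric moments (direct per-voxel summation)
oracle_geometric_moments <- function(grid, frame, max_order) {
  d <- dim(grid$values)
  ax <- lapply(1:3, function(a) {
    (grid$origin[a] + (seq_len(d[a]) - 1) * grid$voxel_edge -
       frame$center[a]) * frame$scale
  })
  idx <- monomial_index(max_order)
  du3 <- (grid$voxel_edge * frame$scale)^3
  vals <- numeric(nrow(idx))
  for (q in seq_len(nrow(idx))) {
    acc <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      acc <- acc + sum(grid$values[i, j, ] *
                         ax[[1]][i]^idx$r[q] * ax[[2]][j]^idx$s[q] *
                         ax[[3]]^idx$t[q])
    }
    vals[q] <- acc * du3
  }
  structure(list(order = max_order, values = vals, index = idx),
            class = "geometric_moments")
}

# seeded random grid fixture (values in [0, 1), cubic, frame centered)
random_grid <- function(dim = 16L, seed = 1, voxel_edge = 1) {
  vals <- zernike3d:::with_seed(seed,
    array(stats::runif(dim^3), dim = rep(dim, 3L)))
  voxel_grid(vals, voxel_edge, origin = rep(-(dim - 1) / 2 * voxel_edge, 3L))
}

# angular difference between two rotations, degrees
rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
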