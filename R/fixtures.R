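# Run code under a private, seeded RNG stream, restoring the caller's
# .Random.seed afterwards: fixture generators are deterministic in their
# seed argument and never disturb the global stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Construct a rigid motion
#'
#' @param rotation 3 x 3 proper rotation matrix (orthonormal, det +1).
#' @param translation 3-vector in Angstrom.
#' @param seed integer recorded as provenance (use [random_motion()] for a
#'   seeded random motion).
#' @return object of class `rigid_motion`.
#' @export
rigid_motion <- function(rotation, translation = c(0, 0, 0), seed = NA_integer_) {
  stopifnot_finite_matrix(rotation, "rotation")
  check_rotation(rotation)
  if (length(translation) != 3L || any(!is.finite(translation))) {
    abort_validation("translation must be a finite 3-vector")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 seed = seed),
            class = "rigid_motion")
}

check_rotation <- function(R, tol = 1e-8) {
  if (any(dim(R) != c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0) {
    abort_validation("rotation must be a proper orthonormal 3 x 3 matrix")
  }
  invisible(R)
}

#' Uniform random rotation (quaternion method)
#'
#' @param seed integer seed.
#' @return 3 x 3 proper rotation matrix.
#' @export
random_rotation <- function(seed) {
  q <- with_seed(seed, stats::rnorm(4))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3L, 3L, byrow = TRUE)
}

#' Seeded random rigid motion
#'
#' @param seed integer seed.
#' @param max_shift translation components drawn uniformly from
#'   `[-max_shift, max_shift]` Angstrom.
#' @return a [rigid_motion()].
#' @export
random_motion <- function(seed, max_shift = 10) {
  tr <- with_seed(seed + 1L, stats::runif(3, -max_shift, max_shift))
  rigid_motion(random_rotation(seed), tr, seed = seed)
}

#' Seeded anisotropic random point cloud
#'
#' Draws a Gaussian cloud with unequal axis spreads and resamples (within
#' the same seeded stream, hence deterministically) until the eigenvalues
#' of the centered second-moment tensor are separated by at least 20% of
#' the largest — the anisotropy the Canterakis principal-frame steps need.
#'
#' @param n_points number of points, at least 4.
#' @param spread overall scale in Angstrom (default 5).
#' @param seed integer seed.
#' @return a [point_cloud()] with unit weights.
#' @export
make_asymmetric_cloud <- function(n_points, spread = 5, seed = 1) {
  if (n_points < 4L) abort_validation("n_points must be at least 4")
  axes <- c(1, 0.65, 0.4)
  coords <- with_seed(seed, {
    for (try in 1:200) {
      cc <- matrix(stats::rnorm(3L * n_points), n_points, 3L) %*%
        diag(spread * axes)
      cen <- scale(cc, scale = FALSE)
      ev <- eigen(crossprod(cen) / n_points, symmetric = TRUE,
                  only.values = TRUE)$values
      if (min(ev[1] - ev[2], ev[2] - ev[3]) >= 0.2 * ev[1]) break
      cc <- NULL
    }
    if (is.null(cc)) abort_validation("could not draw an anisotropic cloud")
    cc
  })
  point_cloud(coords, source_label = sprintf("asymmetric(seed=%d)", seed))
}

#' Ideal helical C-alpha trace
#'
#' A smooth, connectivity-free protein-like fixture: points on an ideal
#' alpha-helix (default rise 1.5 Angstrom and twist 100 degrees per
#' residue, radius 2.3 Angstrom), axis along z.
#'
#' @param n_residues number of residues, at least 5.
#' @param rise rise per residue in Angstrom.
#' @param twist twist per residue in degrees.
#' @param radius helix radius in Angstrom.
#' @return a [point_cloud()] with unit weights.
#' @export
make_helix_cloud <- function(n_residues, rise = 1.5, twist = 100, radius = 2.3) {
  if (n_residues < 5L) abort_validation("n_residues must be at least 5")
  i <- seq_len(n_residues) - 1
  th <- i * twist * pi / 180
  coords <- cbind(radius * cos(th), radius * sin(th), i * rise)
  coords <- sweep(coords, 2L, colMeans(coords))
  # a finite discrete helix's principal axis is slightly tilted off its
  # geometric axis; rotate so the leading second-moment eigenvector is
  # exactly z, which downstream orientation checks rely on
  v1 <- eigen(crossprod(coords) / n_residues, symmetric = TRUE)$vectors[, 1]
  if (v1[3] < 0) v1 <- -v1
  axis <- c(v1[2], -v1[1], 0)                  # v1 x ez direction
  s <- sqrt(sum(axis^2))
  if (s > 1e-12) {
    axis <- axis / s
    ang <- acos(min(1, max(-1, v1[3])))
    K <- matrix(c(0, axis[3], -axis[2],
                  -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    coords <- coords %*% t(R)
  }
  point_cloud(coords, source_label = sprintf("helix(n=%d)", n_residues))
}

#' Apply a rigid motion to a point cloud
#'
#' `coords' = R %*% coords + t`; weights are unchanged.
#'
#' @param cloud a `point_cloud`.
#' @param motion a `rigid_motion`.
#' @return the transformed `point_cloud`.
#' @export
apply_motion <- function(cloud, motion) {
  if (!inherits(motion, "rigid_motion")) {
    abort_validation("apply_motion expects a rigid_motion")
  }
  point_cloud(t(motion$rotation %*% t(cloud$coords) + motion$translation),
              cloud$weights,
              source_label = paste0(cloud$source_label, "+motion"))
}

#' The 24 proper octahedral rotations
#'
#' All 3 x 3 signed axis-permutation matrices with determinant +1, for
#' exact-rotation invariance checks via [rotate_grid_octahedral()].
#'
#' @return list of 24 rotation matrices.
#' @export
octahedral_rotations <- function() {
  out <- list()
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
    R <- matrix(0, 3, 3)
    R[cbind(1:3, p)] <- c(sx, sy, sz)
    if (abs(det(R) - 1) < 1e-12) out[[length(out) + 1L]] <- R
  }
  out
}
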