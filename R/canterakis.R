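# --- Wigner rotation machinery -------------------------------------------

# ZYZ Euler angles (alpha, beta, gamma) with R = Rz(alpha) Ry(beta) Rz(gamma).
euler_zyz <- function(R) {
  cb <- max(-1, min(1, R[3, 3]))
  beta <- acos(cb)
  if (abs(R[3, 3]) < 1 - 1e-12) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else if (R[3, 3] > 0) {      # beta ~ 0: only alpha + gamma fixed
    beta <- 0
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  } else {                        # beta ~ pi: only alpha - gamma fixed
    beta <- pi
    alpha <- atan2(R[2, 1], -R[1, 1])
    gamma <- 0
  }
  c(alpha, beta, gamma)
}

# memoized ragged index plan for the degree-l Wigner small-d sum
wigner_plan_env <- new.env(parent = emptyenv())
wigner_plan <- function(l) {
  key <- as.character(l)
  plan <- wigner_plan_env[[key]]
  if (!is.null(plan)) return(plan)
  mp <- integer(0); m <- integer(0); s <- integer(0); pair <- integer(0)
  pid <- 0L
  for (mi in -l:l) for (mpi in -l:l) {
    pid <- pid + 1L
    smin <- max(0L, mi - mpi); smax <- min(l + mi, l - mpi)
    if (smax < smin) next
    ss <- smin:smax
    mp <- c(mp, rep.int(mpi, length(ss)))
    m <- c(m, rep.int(mi, length(ss)))
    s <- c(s, ss)
    pair <- c(pair, rep.int(pid, length(ss)))
  }
  plan <- list(mp = mp, m = m, s = s, pair = pair, npair = (2L * l + 1L)^2L)
  wigner_plan_env[[key]] <- plan
  plan
}

# power with the 0^0 = 1 convention, safe in log-assembled products
pow0 <- function(base, p) {
  if (base == 0) return(as.numeric(p == 0L))
  base^p
}

# Wigner small-d matrix d^l_{m',m}(beta), indexed [mp + l + 1, m + l + 1].
# logpref is the cached log sqrt-factorial prefactor table for degree l;
# lf the log-factorial vector.  Terms are assembled in log space.
wigner_d <- function(l, beta, logpref, lf) {
  if (l == 0L) return(matrix(1, 1L, 1L))
  pl <- wigner_plan(l)
  c2 <- cos(beta / 2); s2 <- sin(beta / 2)
  pc <- 2L * l + pl$m - pl$mp - 2L * pl$s
  ps <- pl$mp - pl$m + 2L * pl$s
  logmag <- logpref[cbind(pl$mp + l + 1L, pl$m + l + 1L)] -
    lf[l + pl$m - pl$s + 1L] - lf[pl$s + 1L] -
    lf[pl$mp - pl$m + pl$s + 1L] - lf[l - pl$mp - pl$s + 1L]
  cpow <- vapply(pc, pow0, numeric(1), base = abs(c2))
  spow <- vapply(ps, pow0, numeric(1), base = abs(s2))
  sgn <- (-1)^((pl$mp - pl$m + pl$s) %% 2L) *
    sign(c2)^(pc %% 2L) * sign(s2)^(ps %% 2L)
  terms <- sgn * exp(logmag) * cpow * spow
  d <- rowsum(terms, pl$pair, reorder = TRUE)
  out <- matrix(0, 2L * l + 1L, 2L * l + 1L)
  # pair ids were assigned with mp varying fastest inside m
  out[cbind(((as.integer(rownames(d)) - 1L) %% (2L * l + 1L)) + 1L,
            ((as.integer(rownames(d)) - 1L) %/% (2L * l + 1L)) + 1L)] <- d[, 1L]
  out
}

# full Wigner D^l_{m',m}(alpha, beta, gamma) = e^{-i m' a} d^l(b) e^{-i m g}
wigner_D <- function(l, euler, logpref, lf) {
  d <- wigner_d(l, euler[2], logpref, lf)
  mm <- -l:l
  exp(-1i * mm * euler[1]) * d %*% diag(exp(-1i * mm * euler[3]),
                                        2L * l + 1L)
}

#' Rotate a moment set in the moment domain
#'
#' Applies the degree-l unitary rotation action (Wigner rotation of the
#' spherical components) to each `(n, l)` block, giving the moments of the
#' rotated object `g(x) = f(R^-1 x)` without touching any voxel grid.
#' Because the action is unitary within blocks, invariant descriptors are
#' unchanged.
#'
#' @param zm a `zernike_moments` object of a real density.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param cache a `zernike_cache` of order at least `zm$order`.
#' @return the rotated `zernike_moments`.
#' @export
rotate_moments <- function(zm, rotation, cache) {
  if (!inherits(zm, "zernike_moments")) {
    abort_validation("rotate_moments expects a zernike_moments object")
  }
  stopifnot_finite_matrix(rotation, "rotation")
  check_rotation(rotation)
  if (cache$max_order < zm$order) {
    abort_validation("cache order below moment order")
  }
  if (all(rotation == diag(3))) return(zm)   # exact identity: bit-for-bit
  eu <- euler_zyz(rotation)
  lf <- cache$log_factorials
  vals <- zm$values
  out <- vals
  for (l in unique(zm$index$l)) {
    if (l == 0L) next
    D <- wigner_D(l, eu, cache$rotation_tables[[l + 1L]], lf)
    for (n in unique(zm$index$n[zm$index$l == l])) {
      rows <- which(zm$index$n == n & zm$index$l == l)   # m = 0..l
      full <- moment_block(zm, n, l)
      out[rows] <- (D %*% full)[(l + 1L):(2L * l + 1L)]
    }
  }
  new_zernike_moments(zm$order, zm$index, out)
}

# --- Canterakis normalization --------------------------------------------

# Second-order density tensor in unit-ball coordinates, recovered from the
# degree-0 and degree-2 moment slots by inverting the chi relation (the
# quadratic monomial moments are a linear image of Omega[0,0,0],
# Omega[2,0,0] and the Omega[2,2,m] block).
second_order_tensor <- function(zm, cache) {
  slots <- list(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(2, 2, 1), c(2, 2, 2))
  mono <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
                c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  A <- matrix(0, 7L, 7L); y <- numeric(7L)
  row <- 0L
  for (sl in slots) {
    srow <- which(cache$zm_index$n == sl[1] & cache$zm_index$l == sl[2] &
                    cache$zm_index$m == sl[3])
    zrow <- which(zm$index$n == sl[1] & zm$index$l == sl[2] &
                    zm$index$m == sl[3])
    cols <- cache$mono_lut[mono + 1L]
    cre <- cache$chi_re[srow, cols]
    cim <- cache$chi_im[srow, cols]
    row <- row + 1L
    A[row, ] <- cre; y[row] <- Re(zm$values[zrow])
    if (sl[3] > 0) {             # m > 0 slots contribute an imaginary row
      row <- row + 1L
      A[row, ] <- -cim; y[row] <- Im(zm$values[zrow])
    }
  }
  Mq <- solve(A, y)
  if (Mq[1] <= 0) abort_validation("non-positive total mass in moments")
  matrix(c(Mq[2], Mq[5], Mq[6],
           Mq[5], Mq[3], Mq[7],
           Mq[6], Mq[7], Mq[4]), 3L, 3L) / Mq[1]
}

proper_flips <- list(diag(c(1, 1, 1)), diag(c(1, -1, -1)),
                     diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))

#' Canterakis normalization: alternative moments with their rotations
#'
#' Computes the principal-frame rotation that diagonalizes the second-order
#' density tensor implied by the degree-2 moment block (eigenvalues in
#' descending order, each eigenvector's largest-magnitude component made
#' positive, frame forced proper), then emits the four alternative
#' orientations obtained by composing it with the proper sign-flip
#' symmetries `diag(1,1,1)`, `diag(1,-1,-1)`, `diag(-1,1,-1)`,
#' `diag(-1,-1,1)`.  Each candidate carries the fully rotated moment set.
#'
#' Shapes whose second-order tensor is (near-)degenerate — e.g. spherically
#' or axially symmetric densities — have no stable principal frame at this
#' order; a degenerate-normalization error is raised.  Higher-order
#' tie-breaking can be plugged in via `degenerate_handler`, which receives
#' the tensor and must return a proper base rotation.
#'
#' @param zm a `zernike_moments` object of order at least 2.
#' @param cache a `zernike_cache` of order at least `zm$order`.
#' @param gap_tol minimum relative eigenvalue gap (fraction of the largest
#'   eigenvalue) below which the frame is declared degenerate.
#' @param degenerate_handler optional function(tensor) -> 3 x 3 proper
#'   rotation used instead of raising the degenerate error.
#' @return list of 4 `candidate_rotation` objects, each with fields
#'   `rotation` and `moments`.
#' @export
normalize_moments <- function(zm, cache, gap_tol = 0.01,
                              degenerate_handler = NULL) {
  if (!inherits(zm, "zernike_moments") || zm$order < 2L) {
    abort_validation("normalization needs moments of order >= 2")
  }
  Tm <- second_order_tensor(zm, cache)
  eg <- eigen(Tm, symmetric = TRUE)
  ev <- eg$values
  gap <- min(ev[1] - ev[2], ev[2] - ev[3]) / max(ev[1], .Machine$double.eps)
  if (gap < gap_tol) {
    if (is.null(degenerate_handler)) {
      abort_degenerate(paste0(
        "second-order moment tensor is near-degenerate (relative eigenvalue ",
        sprintf("gap %.3g < %.3g); ", gap, gap_tol),
        "the principal frame is ambiguous at this order - supply a ",
        "degenerate_handler implementing higher-order tie-breaking, or ",
        "accept the ambiguity with a larger candidate set"))
    }
    R0 <- check_rotation(degenerate_handler(Tm))
  } else {
    V <- eg$vectors
    for (j in 1:3) {
      if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
    }
    if (det(V) < 0) V[, 3] <- -V[, 3]
    R0 <- t(V)
  }
  lapply(proper_flips, function(F) {
    Rc <- F %*% R0
    structure(list(rotation = Rc,
                   moments = rotate_moments(zm, Rc, cache)),
              class = "candidate_rotation")
  })
}

#' @export
print.candidate_rotation <- function(x, ...) {
  cat("candidate_rotation:\n")
  print(round(x$rotation, 6))
  invisible(x)
}

# flattened full m-range moment vector over blocks with n >= min_n
candidate_vector <- function(zm, min_n) {
  blocks <- unique(zm$index[zm$index$n >= min_n, c("n", "l")])
  unlist(lapply(seq_len(nrow(blocks)), function(i) {
    moment_block(zm, blocks$n[i], blocks$l[i])
  }))
}

# 4x4 homogeneous helpers
hom_translate <- function(v) { M <- diag(4); M[1:3, 4] <- v; M }
hom_scale <- function(s) diag(c(s, s, s, 1))
hom_rotate <- function(R) { M <- diag(4); M[1:3, 1:3] <- R; M }

#' Superpose two structures from their alternative moment sets
#'
#' For every pair of candidate orientations (moving x fixed) the real part
#' of the complex inner product of the flattened alternative-moment vectors
#' is computed; the maximizing pair determines the rotation
#' `R = t(R_fixed) %*% R_moving`, and the returned 4 x 4 homogeneous
#' transform maps moving-structure Angstrom coordinates onto the fixed
#' structure by composing: translate to the moving unit-ball center, scale
#' into the moving unit ball, rotate, scale out of the fixed unit ball, and
#' translate to the fixed center.
#'
#' By default blocks with `n >= 2` enter the dot product (degree 0 carries
#' no orientation signal) and the vectors are not norm-scaled; both choices
#' are exposed as arguments since the canonical choice is not established.
#'
#' @param moving_cands,fixed_cands candidate lists from
#'   [normalize_moments()].
#' @param moving_frame,fixed_frame the structures' `unit_ball_frame`s.
#' @param min_n lowest moment order entering the dot product.
#' @param scale_vectors if `TRUE`, candidate vectors are unit-normalized
#'   before the dot product.
#' @param moving,fixed optional provenance labels stored in the result.
#' @return object of class `superposition_result` with fields `transform`
#'   (4 x 4), `score`, `best_pair`, `moving`, `fixed`.
#' @export
superpose <- function(moving_cands, moving_frame, fixed_cands, fixed_frame,
                      min_n = 2L, scale_vectors = FALSE,
                      moving = "moving", fixed = "fixed") {
  if (length(moving_cands) == 0L || length(fixed_cands) == 0L) {
    abort_validation("candidate lists must be non-empty")
  }
  om <- moving_cands[[1]]$moments$order
  of <- fixed_cands[[1]]$moments$order
  if (om != of) {
    abort_validation(sprintf("moment order mismatch: %d vs %d", om, of))
  }
  vm <- lapply(moving_cands, function(cand) {
    v <- candidate_vector(cand$moments, min_n)
    if (scale_vectors) v / sqrt(max(sum(Mod(v)^2), .Machine$double.xmin)) else v
  })
  vf <- lapply(fixed_cands, function(cand) {
    v <- candidate_vector(cand$moments, min_n)
    if (scale_vectors) v / sqrt(max(sum(Mod(v)^2), .Machine$double.xmin)) else v
  })
  scores <- matrix(0, length(vm), length(vf))
  for (i in seq_along(vm)) for (j in seq_along(vf)) {
    scores[i, j] <- Re(sum(vm[[i]] * Conj(vf[[j]])))
  }
  best <- arrayInd(which.max(scores), dim(scores))
  i <- best[1L]; j <- best[2L]
  R <- t(fixed_cands[[j]]$rotation) %*% moving_cands[[i]]$rotation
  transform <- hom_translate(fixed_frame$center) %*%
    hom_scale(1 / fixed_frame$scale) %*% hom_rotate(R) %*%
    hom_scale(moving_frame$scale) %*% hom_translate(-moving_frame$center)
  structure(list(transform = transform, score = scores[i, j],
                 best_pair = c(moving = i, fixed = j),
                 moving = moving, fixed = fixed),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition_result: score %.6g, pair (%d, %d)\n",
              x$score, x$best_pair[1], x$best_pair[2]))
  print(round(x$transform, 6))
  invisible(x)
}

#' Apply a homogeneous transform to point coordinates
#'
#' @param coords `N x 3` matrix of Angstrom coordinates.
#' @param transform 4 x 4 homogeneous matrix.
#' @return transformed `N x 3` matrix.
#' @export
apply_transform <- function(coords, transform) {
  stopifnot_finite_matrix(transform, "transform")
  h <- transform %*% rbind(t(coords), 1)
  t(h[1:3, , drop = FALSE])
}

#' End-to-end superposition of two point clouds
#'
#' Convenience wrapper: rasterizes both clouds, computes their moments,
#' normalizes, and superposes.
#'
#' @param moving_cloud,fixed_cloud `point_cloud` objects.
#' @param cache a `zernike_cache`.
#' @param max_order moment order used (default `min(20, cache order)`).
#' @param voxel_edge,sigma rasterization settings.
#' @param radius_mode,radius_param unit-ball frame settings.
#' @param ... further arguments passed to [superpose()].
#' @return a `superposition_result`.
#' @export
superpose_clouds <- function(moving_cloud, fixed_cloud, cache,
                             max_order = min(20L, cache$max_order),
                             voxel_edge = 1.0, sigma = 1.5,
                             radius_mode = "gyration_multiple",
                             radius_param = 3.2, ...) {
  pipe <- function(cloud, label) {
    g <- rasterize(cloud, voxel_edge = voxel_edge, sigma = sigma)
    f <- unit_ball_frame(g, radius_mode = radius_mode,
                         radius_param = radius_param)
    zm <- zernike_moments(geometric_moments(g, f, max_order), cache, max_order)
    list(cands = normalize_moments(zm, cache), frame = f, label = label)
  }
  mv <- pipe(moving_cloud, moving_cloud$source_label)
  fx <- pipe(fixed_cloud, fixed_cloud$source_label)
  superpose(mv$cands, mv$frame, fx$cands, fx$frame,
            moving = mv$label, fixed = fx$label, ...)
}
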