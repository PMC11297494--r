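CACHE_SCHEMA_VERSION <- 1L

#' Index table of Zernike moment slots
#'
#' Enumerates the valid `(n, l, m)` triples for moments up to a maximum
#' order: `n <= max_order`, `0 <= l <= n` with `n - l` even, `0 <= m <= l`.
#' Negative `m` components are implied by conjugate symmetry and never
#' stored.
#'
#' @param max_order maximum expansion order `N`.
#' @return data.frame with integer columns `n`, `l`, `m`, one row per slot,
#'   ordered by `n`, then `l`, then `m`.
#' @export
zm_index <- function(max_order) {
  check_order(max_order, lower = 0L)
  rows <- vector("list", max_order + 1L)
  for (n in 0:max_order) {
    l <- seq.int(n %% 2L, n, by = 2L)
    li <- rep.int(l, l + 1L)
    mi <- unlist(lapply(l, function(x) 0:x), use.names = FALSE)
    rows[[n + 1L]] <- data.frame(n = n, l = li, m = mi)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Index table of geometric-moment monomials
#'
#' All exponent triples `(r, s, t)` with `r + s + t <= max_order`, in the
#' canonical column order shared by [geometric_moments()] and the cache's
#' contraction matrices.
#'
#' @param max_order maximum total degree.
#' @return data.frame with integer columns `r`, `s`, `t`.
#' @export
monomial_index <- function(max_order) {
  check_order(max_order, lower = 0L)
  g <- expand.grid(r = 0:max_order, s = 0:max_order, t = 0:max_order,
                   KEEP.OUT.ATTRS = FALSE)
  out <- g[g$r + g$s + g$t <= max_order, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Lookup array: mono_lut[r+1, s+1, t+1] -> column id (NA outside the simplex)
monomial_lut <- function(mono, max_order) {
  lut <- array(NA_integer_, dim = rep(max_order + 1L, 3L))
  lut[cbind(mono$r + 1L, mono$s + 1L, mono$t + 1L)] <- seq_len(nrow(mono))
  lut
}

check_order <- function(max_order, lower = 1L, upper = 40L) {
  if (length(max_order) != 1L || !is.finite(max_order) ||
      max_order != as.integer(max_order) ||
      max_order < lower || max_order > upper) {
    abort_validation(sprintf(
      "max_order must be a single integer in [%d, %d], got %s",
      lower, upper, paste(format(max_order), collapse = ", ")))
  }
  as.integer(max_order)
}

# Monomial terms of the complex solid harmonic S_l^m = r^l * Y_l^m /
# sqrt((2l+1)/(4pi)) for m >= 0 (Condon-Shortley phase).  All factorial
# magnitudes are assembled in log space; only the combined term is
# exponentiated.  Returns a data.frame (a, b, c, re, im) with a+b+c = l.
solid_harmonic_terms <- function(l, m, lf) {
  kmax <- (l - m) %/% 2L
  A <- integer(0); B <- integer(0); RE <- double(0); IM <- double(0)
  Cc <- integer(0)
  base <- 0.5 * (lf[l + m + 1L] + lf[l - m + 1L])
  for (kp in 0:kmax) {
    i <- rep(0:(kp + m), each = kp + 1L)
    j <- rep.int(0:kp, kp + m + 1L)
    logmag <- base - (2 * kp + m) * log(2) -
      lf[kp + m + 1L] - lf[kp + 1L] - lf[l - m - 2L * kp + 1L] +
      (lf[kp + m + 1L] - lf[i + 1L] - lf[kp + m - i + 1L]) +
      (lf[kp + 1L] - lf[j + 1L] - lf[kp - j + 1L])
    # complex unit: i^(kp+m-i) * (-i)^(kp-j), sign (-1)^m * (-1)^kp
    upow <- ((kp + m - i) + (kp - j)) %% 4L
    unit <- (1i)^upow * (-1)^((kp - j) %% 2L)
    coef <- (-1)^((m + kp) %% 2L) * unit * exp(logmag)
    A <- c(A, i + j)
    B <- c(B, (kp + m - i) + (kp - j))
    Cc <- c(Cc, rep.int(l - m - 2L * kp, length(i)))
    RE <- c(RE, Re(coef)); IM <- c(IM, Im(coef))
  }
  key <- paste(A, B, Cc)
  re <- rowsum(RE, key, reorder = FALSE)
  im <- rowsum(IM, key, reorder = FALSE)
  first <- !duplicated(key)
  keep <- abs(re[, 1L]) + abs(im[, 1L]) > 0
  data.frame(a = A[first], b = B[first], c = Cc[first],
             re = re[, 1L], im = im[, 1L])[keep, , drop = FALSE]
}

# Coefficient of r^(l + 2*nu) in the orthonormal radial polynomial
# R_nl(r) = sqrt(2n+3) * r^l * P_k^(0, l+1/2)(2 r^2 - 1),  k = (n-l)/2,
# normalized so that  integral_0^1 R_nl^2 r^2 dr = 1.
# Each coefficient is a single signed product of Gamma factors (no
# alternating inner sum), evaluated in log space.
radial_coefficient <- function(k, l, nu, lf) {
  beta <- l + 0.5
  logmag <- lgamma(k + beta + 1 + nu) - lf[k - nu + 1L] -
    lgamma(beta + 1 + nu) - lf[nu + 1L]
  (-1)^((k + nu) %% 2L) * exp(logmag)
}

# Multinomial expansion of (x^2 + y^2 + z^2)^nu:
# data.frame (da, db, dc, coef) with da+db+dc = 2*nu (even exponents).
ball_power_terms <- function(nu, lf) {
  g <- expand.grid(al = 0:nu, be = 0:nu, KEEP.OUT.ATTRS = FALSE)
  g <- g[g$al + g$be <= nu, , drop = FALSE]
  ga <- nu - g$al - g$be
  coef <- exp(lf[nu + 1L] - lf[g$al + 1L] - lf[g$be + 1L] - lf[ga + 1L])
  data.frame(da = 2L * g$al, db = 2L * g$be, dc = 2L * ga, coef = coef)
}

#' Build a coefficient cache
#'
#' Precomputes every order-dependent table the moment pipeline needs:
#' log-space factorials, the sparse polynomial coefficients `chi` that
#' contract geometric moments into complex 3D Zernike moments, and the
#' per-degree log prefactors of the Wigner rotation action used by
#' Canterakis normalization.  All factorial-derived quantities are assembled
#' in log space and exponentiated only in final combined form, so the tables
#' remain finite up to the supported maximum order of 40.
#'
#' The implied Zernike basis is orthonormal over the unit ball:
#' `integral_{|u|<=1} Z_nlm conj(Z_n'l'm') du = delta`, i.e. the
#' conventional `3/(4 pi)` volume factor is absorbed into the basis.  This
#' single convention is shared by moments, descriptors and normalization.
#'
#' @param max_order maximum order `N`, between 1 and 40.
#' @return an object of class `zernike_cache`.
#' @examples
#' cache <- build_cache(4)
#' cache$max_order
#' @export
build_cache <- function(max_order) {
  max_order <- check_order(max_order)
  N <- max_order
  lf <- lgamma(seq_len(2L * N + 2L))        # lf[x+1] = log(x!) for x = 0..2N+1
  zmi <- zm_index(N)
  mono <- monomial_index(N)
  lut <- monomial_lut(mono, N)

  ball <- lapply(0:(N %/% 2L), ball_power_terms, lf = lf)

  trip_i <- vector("list", nrow(zmi))
  trip_j <- vector("list", nrow(zmi))
  trip_re <- vector("list", nrow(zmi))
  trip_im <- vector("list", nrow(zmi))

  # slot row ids grouped by (l, m) so each solid harmonic is expanded once
  slot_of <- function(n, l, m) which(zmi$n == n & zmi$l == l & zmi$m == m)
  for (l in 0:N) {
    kmax_l <- (N - l) %/% 2L
    for (m in 0:l) {
      harm <- solid_harmonic_terms(l, m, lf)
      # cross the harmonic monomials with each (x^2+y^2+z^2)^nu expansion
      cross <- vector("list", kmax_l + 1L)
      for (nu in 0:kmax_l) {
        bp <- ball[[nu + 1L]]
        nh <- nrow(harm); nb <- nrow(bp)
        hi <- rep(seq_len(nh), times = nb)
        bi <- rep(seq_len(nb), each = nh)
        cross[[nu + 1L]] <- list(
          r = harm$a[hi] + bp$da[bi],
          s = harm$b[hi] + bp$db[bi],
          t = harm$c[hi] + bp$dc[bi],
          re = harm$re[hi] * bp$coef[bi],
          im = harm$im[hi] * bp$coef[bi])
      }
      ang_norm <- sqrt((2 * l + 1) / (4 * pi))
      for (k in 0:kmax_l) {
        n <- l + 2L * k
        slot <- slot_of(n, l, m)
        q <- vapply(0:k, radial_coefficient, numeric(1), k = k, l = l, lf = lf)
        norm_nl <- sqrt(2 * n + 3) * ang_norm
        r <- integer(0); s <- integer(0); tt <- integer(0)
        re <- double(0); im <- double(0)
        for (nu in 0:k) {
          cr <- cross[[nu + 1L]]
          w <- norm_nl * q[nu + 1L]
          r <- c(r, cr$r); s <- c(s, cr$s); tt <- c(tt, cr$t)
          re <- c(re, w * cr$re); im <- c(im, w * cr$im)
        }
        col <- lut[cbind(r + 1L, s + 1L, tt + 1L)]
        agg_re <- rowsum(re, col, reorder = FALSE)
        agg_im <- rowsum(im, col, reorder = FALSE)
        ucol <- as.integer(rownames(agg_re))
        keep <- (abs(agg_re[, 1L]) + abs(agg_im[, 1L])) > 1e-300
        trip_i[[slot]] <- rep.int(slot, sum(keep))
        trip_j[[slot]] <- ucol[keep]
        trip_re[[slot]] <- agg_re[keep, 1L]
        trip_im[[slot]] <- agg_im[keep, 1L]
      }
    }
  }

  ii <- unlist(trip_i, use.names = FALSE)
  jj <- unlist(trip_j, use.names = FALSE)
  vre <- unlist(trip_re, use.names = FALSE)
  vim <- unlist(trip_im, use.names = FALSE)
  if (any(!is.finite(vre)) || any(!is.finite(vim))) {
    abort_validation("non-finite chi coefficient encountered during cache build")
  }
  dims <- c(nrow(zmi), nrow(mono))
  chi_re <- Matrix::sparseMatrix(i = ii, j = jj, x = vre, dims = dims)
  chi_im <- Matrix::sparseMatrix(i = ii, j = jj, x = vim, dims = dims)

  # Wigner small-d log prefactors per degree:
  # P[mp+l+1, m+l+1] = log sqrt((l+m)! (l-m)! (l+mp)! (l-mp)!)
  rotation_tables <- lapply(0:N, function(l) {
    mm <- -l:l
    half <- 0.5 * (lf[l + mm + 1L] + lf[l - mm + 1L])
    outer(half, half, `+`)
  })

  structure(list(
    schema_version = CACHE_SCHEMA_VERSION,
    max_order = N,
    log_factorials = lf,
    zm_index = zmi,
    mono_index = mono,
    mono_lut = lut,
    chi_re = chi_re,
    chi_im = chi_im,
    rotation_tables = rotation_tables
  ), class = "zernike_cache")
}

#' @export
print.zernike_cache <- function(x, ...) {
  cat(sprintf(
    "zernike_cache: max_order %d, %d moment slots, %d monomials, %d chi entries\n",
    x$max_order, nrow(x$zm_index), nrow(x$mono_index),
    length(x$chi_re@x)))
  invisible(x)
}

#' Look up the chi coefficients of one moment slot
#'
#' @param cache a `zernike_cache`.
#' @param n,l,m slot indices.
#' @return data.frame with columns `r`, `s`, `t`, `coef` (complex): the
#'   polynomial coefficients of the basis function `Z_nlm` in the monomials
#'   `u1^r u2^s u3^t`.
#' @export
cache_chi_entries <- function(cache, n, l, m) {
  slot <- which(cache$zm_index$n == n & cache$zm_index$l == l &
                  cache$zm_index$m == m)
  if (length(slot) != 1L) abort_validation("no such (n, l, m) slot in cache")
  re <- cache$chi_re[slot, ]
  im <- cache$chi_im[slot, ]
  keep <- which(re != 0 | im != 0)
  data.frame(r = cache$mono_index$r[keep], s = cache$mono_index$s[keep],
             t = cache$mono_index$t[keep],
             coef = complex(real = re[keep], imaginary = im[keep]))
}

#' Truncate a cache to a lower order
#'
#' A cache built at order `N` serves any request of order `<= N`; this
#' subsets every table so downstream results match a natively built cache
#' of the lower order.
#'
#' @param cache a `zernike_cache`.
#' @param max_order target order, at most `cache$max_order`.
#' @return a `zernike_cache` of the requested order.
#' @export
truncate_cache <- function(cache, max_order) {
  max_order <- check_order(max_order)
  if (max_order > cache$max_order) {
    abort_validation(sprintf(
      "requested order %d exceeds cache order %d", max_order, cache$max_order))
  }
  if (max_order == cache$max_order) return(cache)
  N <- max_order
  keep_row <- which(cache$zm_index$n <= N)
  keep_col <- which(cache$mono_index$r + cache$mono_index$s +
                      cache$mono_index$t <= N)
  zmi <- cache$zm_index[keep_row, , drop = FALSE]
  mono <- cache$mono_index[keep_col, , drop = FALSE]
  rownames(zmi) <- NULL; rownames(mono) <- NULL
  structure(list(
    schema_version = cache$schema_version,
    max_order = N,
    log_factorials = cache$log_factorials[seq_len(2L * N + 2L)],
    zm_index = zmi,
    mono_index = mono,
    mono_lut = monomial_lut(mono, N),
    chi_re = cache$chi_re[keep_row, keep_col, drop = FALSE],
    chi_im = cache$chi_im[keep_row, keep_col, drop = FALSE],
    rotation_tables = cache$rotation_tables[seq_len(N + 1L)]
  ), class = "zernike_cache")
}

#' Persist a coefficient cache
#'
#' The cache is written as a single serialized container carrying a schema
#' version and its maximum order; [load_cache()] reproduces every table
#' bit-exactly.
#'
#' @param cache a `zernike_cache`.
#' @param path destination file path.
#' @export
save_cache <- function(cache, path) {
  if (!inherits(cache, "zernike_cache")) {
    abort_validation("save_cache expects a zernike_cache object")
  }
  ok <- tryCatch({ saveRDS(cache, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write cache to '%s'", path))
  invisible(NULL)
}

#' @rdname save_cache
#' @return `load_cache` returns the restored `zernike_cache`.
#' @export
load_cache <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cache file '%s' does not exist", path))
  obj <- tryCatch(readRDS(path), error = function(e) NULL, warning = function(w) NULL)
  if (is.null(obj) || !is.list(obj) || is.null(obj$schema_version) ||
      !inherits(obj, "zernike_cache")) {
    abort_cache_format(sprintf(
      "file '%s' is not a valid coefficient cache; rebuild with build_cache()",
      path))
  }
  if (obj$schema_version != CACHE_SCHEMA_VERSION) {
    abort_cache_format(sprintf(
      "cache schema version %s does not match supported version %d; rebuild",
      format(obj$schema_version), CACHE_SCHEMA_VERSION))
  }
  obj
}
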