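#' Rotation-invariant descriptor of a moment set
#'
#' For each valid `(n, l)` pair, the Euclidean norm of the full `m`-range
#' moment vector with negative components reconstructed by conjugate
#' symmetry:
#' `F[n,l] = sqrt(|Omega[n,l,0]|^2 + 2 * sum_{m=1..l} |Omega[n,l,m]|^2)`.
#' Rotations act unitarily within each `(n, l)` block, so `F` is unchanged
#' by any rotation of the underlying shape.
#'
#' @param zm a `zernike_moments` object.
#' @return object of class `invariant_descriptor`: `order`, `index`
#'   (data.frame of `n`, `l`) and non-negative `values`.
#' @export
invariants <- function(zm) {
  if (!inherits(zm, "zernike_moments")) {
    abort_validation("invariants expects a zernike_moments object")
  }
  w <- ifelse(zm$index$m == 0L, 1, 2)
  key <- zm$index$n * 1000L + zm$index$l
  sq <- rowsum(w * Mod(zm$values)^2, key, reorder = FALSE)
  first <- !duplicated(key)
  structure(list(order = zm$order,
                 index = data.frame(n = zm$index$n[first],
                                    l = zm$index$l[first]),
                 values = unname(sqrt(pmax(sq[, 1L], 0)))),
            class = "invariant_descriptor")
}

#' @export
print.invariant_descriptor <- function(x, ...) {
  cat(sprintf("invariant_descriptor: order %d, %d (n, l) pairs, norm %.6g\n",
              x$order, length(x$values), sqrt(sum(x$values^2))))
  invisible(x)
}

#' Truncate a descriptor to a lower order
#'
#' @param desc an `invariant_descriptor`.
#' @param max_order target order.
#' @return the truncated descriptor.
#' @export
truncate_descriptor <- function(desc, max_order) {
  max_order <- check_order(max_order, lower = 0L)
  if (max_order >= desc$order) return(desc)
  keep <- desc$index$n <= max_order
  structure(list(order = max_order,
                 index = desc$index[keep, , drop = FALSE],
                 values = desc$values[keep]),
            class = "invariant_descriptor")
}

#' Volumetric similarity score between two descriptors
#'
#' Both scores are generic, symmetric, and bounded in `[0, 1]`; neither is
#' the trained composite score of prior shape-retrieval work (whose learned
#' weights are not public):
#'
#' * `cosine` (default): inner product of the descriptor vectors divided by
#'   their norms; 0 if either norm is zero.
#' * `normalized_l1`: `1 - sum|a_i - b_i| / sum(|a_i| + |b_i|)`.
#'
#' Descriptors of unequal order are truncated to the common order before
#' scoring (optionally to `max_order` first, so order-20 and order-40
#' pipelines can be compared).
#'
#' @param a,b `invariant_descriptor` objects.
#' @param mode `"cosine"` or `"normalized_l1"`.
#' @param max_order optional truncation order applied to both sides.
#' @return similarity score in `[0, 1]`.
#' @export
similarity <- function(a, b, mode = c("cosine", "normalized_l1"),
                       max_order = NULL) {
  mode <- match.arg(mode)
  if (!inherits(a, "invariant_descriptor") ||
      !inherits(b, "invariant_descriptor")) {
    abort_validation("similarity expects two invariant_descriptor objects")
  }
  common <- min(a$order, b$order)
  if (!is.null(max_order)) common <- min(common, check_order(max_order))
  a <- truncate_descriptor(a, common)
  b <- truncate_descriptor(b, common)
  na2 <- sum(a$values^2); nb2 <- sum(b$values^2)
  if (na2 == 0 && nb2 == 0) {
    warning("both descriptors are all-zero; similarity defined as 0")
    return(0)
  }
  if (mode == "cosine") {
    if (na2 == 0 || nb2 == 0) return(0)
    return(min(1, max(0, sum(a$values * b$values) / sqrt(na2 * nb2))))
  }
  denom <- sum(abs(a$values) + abs(b$values))
  min(1, max(0, 1 - sum(abs(a$values - b$values)) / denom))
}

#' Export a descriptor as a data.frame / CSV
#'
#' @param desc an `invariant_descriptor`.
#' @param path optional CSV path; rows `(n, l, value)`.
#' @return data.frame with columns `n`, `l`, `value`.
#' @export
descriptor_table <- function(desc, path = NULL) {
  df <- data.frame(desc$index, value = desc$values)
  if (!is.null(path)) {
    ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE); TRUE },
                   error = function(e) FALSE)
    if (!ok) abort_io(sprintf("cannot write descriptor to '%s'", path))
  }
  df
}
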