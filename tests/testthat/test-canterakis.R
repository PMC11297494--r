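test_that("moment rotation is exact for the identity and unitary per block", {
  cache <- get_test_cache(10)
  st <- cloud_moments(make_asymmetric_cloud(30, seed = 2), cache, 10)
  zi <- rotate_moments(st$zm, diag(3), cache)
  expect_identical(zi$values, st$zm$values)
  R <- random_rotation(17)
  zr <- rotate_moments(st$zm, R, cache)
  d0 <- invariants(st$zm); dr <- invariants(zr)
  expect_lt(max(abs(dr$values - d0$values)), 1e-10 * max(d0$values))
  expect_error(rotate_moments(st$zm, diag(3) * 1.5, cache),
               class = "zernike3d_validation_error")
})

test_that("moment rotations compose like the rotations themselves", {
  cache <- get_test_cache(10)
  st <- cloud_moments(make_asymmetric_cloud(30, seed = 3), cache, 10)
  for (s in c(21, 22, 23)) {
    R1 <- random_rotation(s); R2 <- random_rotation(s + 50)
    a <- rotate_moments(rotate_moments(st$zm, R2, cache), R1, cache)
    b <- rotate_moments(st$zm, R1 %*% R2, cache)
    expect_lt(max(Mod(a$values - b$values)), 1e-10 * max(Mod(st$zm$values)))
  }
})

test_that("moment-domain rotation agrees with voxel-domain rotation", {
  cache <- get_test_cache(10)
  cl <- make_asymmetric_cloud(30, seed = 4)
  st <- cloud_moments(cl, cache, 10)
  R <- random_rotation(33)
  zr <- rotate_moments(st$zm, R, cache)
  st2 <- cloud_moments(apply_motion(cl, rigid_motion(R)), cache, 10)
  expect_lt(max(Mod(zr$values - st2$zm$values)),
            1e-2 * max(Mod(st2$zm$values)))
})

test_that("normalization of an axis-aligned density yields a near-identity candidate", {
  cache <- get_test_cache(8)
  g <- aligned_lobe_grid(33)
  f <- unit_ball_frame(g)
  zm <- zernike_moments(geometric_moments(g, f, 8), cache)
  cands <- normalize_moments(zm, cache)
  expect_length(cands, 4L)
  devs <- vapply(cands, function(cd) max(abs(cd$rotation - diag(3))),
                 numeric(1))
  expect_lt(min(devs), 1e-6)
  # every candidate is a proper rotation carrying the same invariants
  d0 <- invariants(zm)
  for (cd in cands) {
    expect_lt(max(abs(crossprod(cd$rotation) - diag(3))), 1e-10)
    expect_gt(det(cd$rotation), 0)
    expect_lt(max(abs(invariants(cd$moments)$values - d0$values)),
              1e-8 * max(d0$values))
  }
})

test_that("spherically symmetric input triggers the degenerate-normalization error", {
  cache <- get_test_cache(8)
  g <- rasterize(point_cloud(matrix(0, 1, 3)), truncation = 8)
  f <- unit_ball_frame(g)
  zm <- zernike_moments(geometric_moments(g, f, 8), cache)
  err <- tryCatch(normalize_moments(zm, cache), error = identity)
  expect_s3_class(err, "zernike3d_degenerate_error")
  expect_match(conditionMessage(err), "higher-order")
  # a caller-supplied tie-break hook replaces the error
  cands <- normalize_moments(zm, cache,
                             degenerate_handler = function(Tm) diag(3))
  expect_length(cands, 4L)
})

test_that("self-superposition returns the identity transform", {
  cache <- get_test_cache(12)
  st <- cloud_moments(make_asymmetric_cloud(40, seed = 6), cache, 12)
  cands <- normalize_moments(st$zm, cache)
  res <- superpose(cands, st$frame, cands, st$frame)
  expect_lt(max(abs(res$transform - diag(4))), 1e-6)
  expect_equal(res$transform[4, ], c(0, 0, 0, 1))
})

test_that("known rigid motions are recovered below the voxel scale", {
  cache <- get_test_cache(12)
  cl <- make_asymmetric_cloud(48, seed = 8)
  fx <- cloud_moments(cl, cache, 12)
  fx_cands <- normalize_moments(fx$zm, cache)
  for (s in c(101, 202, 303, 404, 505)) {
    mo <- random_motion(s)
    mv <- cloud_moments(apply_motion(cl, mo), cache, 12)
    res <- superpose(normalize_moments(mv$zm, cache), mv$frame,
                     fx_cands, fx$frame)
    R <- res$transform[1:3, 1:3]
    expect_lt(rotation_angle_deg(R %*% mo$rotation), 1)
    moved <- apply_transform(apply_motion(cl, mo)$coords, res$transform)
    rmsd <- sqrt(mean(rowSums((moved - cl$coords)^2)))
    expect_lt(rmsd, 1)                       # < 1 voxel edge
  }
})

test_that("forward and reverse superposition are mutually inverse", {
  cache <- get_test_cache(12)
  a <- cloud_moments(make_asymmetric_cloud(40, seed = 9), cache, 12)
  b <- cloud_moments(
    apply_motion(make_asymmetric_cloud(40, seed = 9), random_motion(77)),
    cache, 12)
  ca <- normalize_moments(a$zm, cache); cb <- normalize_moments(b$zm, cache)
  ab <- superpose(ca, a$frame, cb, b$frame)
  ba <- superpose(cb, b$frame, ca, a$frame)
  expect_lt(max(abs(ab$transform[1:3, 1:3] %*% ba$transform[1:3, 1:3] -
                      diag(3))), 1e-3)
})

test_that("unrelated shapes score below their self-scores yet superpose properly", {
  cache <- get_test_cache(10)
  a <- cloud_moments(make_asymmetric_cloud(40, seed = 21), cache, 10)
  b <- cloud_moments(make_asymmetric_cloud(40, seed = 22, spread = 6),
                     cache, 10)
  ca <- normalize_moments(a$zm, cache); cb <- normalize_moments(b$zm, cache)
  ab <- superpose(ca, a$frame, cb, b$frame, scale_vectors = TRUE)
  self_a <- superpose(ca, a$frame, ca, a$frame, scale_vectors = TRUE)$score
  self_b <- superpose(cb, b$frame, cb, b$frame, scale_vectors = TRUE)$score
  expect_lt(ab$score, self_a)
  expect_lt(ab$score, self_b)
  R <- ab$transform[1:3, 1:3]
  scale_free <- R / det(R)^(1 / 3)
  expect_lt(max(abs(crossprod(scale_free) - diag(3))), 1e-6)
})

test_that("superposition validates its inputs", {
  cache <- get_test_cache(8)
  st <- cloud_moments(make_asymmetric_cloud(30, seed = 10), cache, 8)
  cands8 <- normalize_moments(st$zm, cache)
  zm6 <- zernike_moments(geometric_moments(st$grid, st$frame, 6),
                         get_test_cache(6))
  cands6 <- normalize_moments(zm6, get_test_cache(6))
  expect_error(superpose(cands8, st$frame, cands6, st$frame),
               class = "zernike3d_validation_error")
  expect_error(superpose(list(), st$frame, cands8, st$frame),
               class = "zernike3d_validation_error")
  expect_error(normalize_moments(zernike_moments(
    geometric_moments(st$grid, st$frame, 1), get_test_cache(1)), cache),
    class = "zernike3d_validation_error")
})
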