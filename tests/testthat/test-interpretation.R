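test_that("latent time courses are the spatial projection of the data", {
  set.seed(1)
  data <- array(rnorm(3 * 4 * 5), c(3, 4, 5))        # trials x ch x time
  ep <- epoch_set(data, 100, c(0, 0.05))

  S <- latent_timecourses(diag(4), ep)               # W = identity
  for (i in 1:3) expect_equal(S[, , i], data[i, , ])

  e2 <- matrix(c(0, 1, 0, 0), 4, 1)                  # unit basis vector
  S2 <- latent_timecourses(e2, ep)
  for (i in 1:3) expect_equal(S2[1, , i], data[i, 2, ])

  W <- matrix(rnorm(8), 4, 2)
  S3 <- latent_timecourses(W, ep)
  for (i in 1:3) expect_equal(S3[, , i], t(W) %*% data[i, , ],
                              ignore_attr = TRUE)

  expect_error(latent_timecourses(matrix(0, 3, 2), ep), "shape mismatch")
})

test_that("activation patterns match the brute-force covariance route", {
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(2:5, 1)
    k <- sample(1:min(3, n), 1)
    ntr <- sample(2:4, 1)
    nt <- sample(6:12, 1)
    data <- array(rnorm(ntr * n * nt), c(ntr, n, nt))
    W <- matrix(rnorm(n * k), n, k)
    ps <- compute_patterns(W, data)
    expect_equal(ps$A, brute_patterns(W, data), tolerance = 1e-8)
  }
})

test_that("patterns reduce to hand algebra on a two-channel example", {
  # exact empirical covariance [[2,1],[1,1]] via a scaled orthogonal design
  U <- cbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  L <- t(chol(matrix(c(2, 1, 1, 1), 2)))
  X <- L %*% U                                       # 2 x 4, Sigma_X exact
  data <- array(0, c(1, 2, 4))
  data[1, , ] <- X
  W <- matrix(c(1, 0), 2, 1)
  ps <- compute_patterns(W, data)
  expect_equal(ps$sigma_X, matrix(c(2, 1, 1, 1), 2), tolerance = 1e-12)
  expect_equal(ps$sigma_S, matrix(2), tolerance = 1e-12)
  expect_equal(ps$A, matrix(c(1, 0.5), 2, 1), tolerance = 1e-12)
})

test_that("whitened data with orthonormal filters returns the filters", {
  U <- cbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))  # Sigma_X = identity
  data <- array(0, c(1, 2, 4))
  data[1, , ] <- U
  W <- diag(2)
  expect_equal(compute_patterns(W, data)$A, W, tolerance = 1e-12)
})

test_that("duplicate latent sources trigger the degeneracy warning", {
  set.seed(5)
  data <- array(rnorm(2 * 4 * 20), c(2, 4, 20))
  W <- cbind(c(1, 0, 0, 0), c(1, 0, 0, 0))
  expect_warning(ps <- compute_patterns(W, data), "degenerate-latents")
  expect_true(ps$degenerate)
  expect_true(all(is.finite(ps$A)))
})

test_that("latent-source class weights normalise the output L1 norms", {
  w <- array(1, c(21, 16, 2))
  expect_equal(ls_class_weights(w, 0), rep(1 / 16, 16))
  expect_equal(ls_class_weights(w, 1), rep(0.0625, 16))

  w2 <- array(0, c(4, 5, 2))
  w2[2, 3, 2] <- -2.5
  expect_equal(ls_class_weights(w2, 1), c(0, 0, 1, 0, 0))
  expect_error(ls_class_weights(w2, 0), "undefined-weights")

  set.seed(9)
  w3 <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  for (ci in 0:1) {
    brute <- numeric(3)
    for (s in 1:3) for (j in 1:2) brute[s] <- brute[s] + abs(w3[j, s, ci + 1])
    expect_equal(ls_class_weights(w3, ci), brute / sum(brute),
                 tolerance = 1e-12)
    expect_equal(sum(ls_class_weights(w3, ci)), 1, tolerance = 1e-12)
  }
})

test_that("pattern averaging weights the columns", {
  A <- cbind(c(1, 0), c(0, 1))
  expect_equal(average_pattern(A), c(0.5, 0.5))
  expect_equal(average_pattern(A, c(1, 0)), c(1, 0))
  set.seed(3)
  A2 <- matrix(rnorm(12), 4, 3)
  # uniform class weights coincide with the mean pattern
  expect_equal(average_pattern(A2, rep(1 / 3, 3)), average_pattern(A2))
  expect_error(average_pattern(A2, c(1, 0)), "length")
})

test_that("FVE is a squared correlation with the reconstruction", {
  set.seed(21)
  data <- array(rnorm(5 * 3 * 40), c(5, 3, 40))
  W <- matrix(rnorm(9), 3, 3)                  # invertible: perfect basis
  ps <- compute_patterns(W, data)
  fm <- fve_map(data, ps$A, ps$S_hat)
  expect_equal(fm$fve, rep(1, 3), tolerance = 1e-8)
  expect_equal(fm$full_fve, 1, tolerance = 1e-8)

  # affine transforms of a perfect reconstruction still explain everything
  fm2 <- fve_map(data, 2 * ps$A, ps$S_hat)
  expect_equal(fm2$fve, rep(1, 3), tolerance = 1e-8)

  # an independent-noise reconstruction explains nothing
  k <- 2
  S_noise <- array(rnorm(k * 40 * 5), c(k, 40, 5))
  A_noise <- matrix(rnorm(3 * k), 3, k)
  fm3 <- fve_map(data, A_noise, S_noise)
  expect_true(all(fm3$fve < 0.05))

  # full FVE is invariant to channel reordering
  perm <- c(3, 1, 2)
  fm4 <- fve_map(data[, perm, , drop = FALSE],
                 ps$A[perm, , drop = FALSE], ps$S_hat)
  expect_equal(fm4$full_fve, fm$full_fve, tolerance = 1e-10)
})

test_that("constant channels are flagged and excluded from full FVE", {
  set.seed(2)
  data <- array(rnorm(2 * 3 * 30), c(2, 3, 30))
  data[, 2, ] <- 4                              # constant channel
  A <- matrix(rnorm(6), 3, 2)
  S <- array(rnorm(2 * 30 * 2), c(2, 30, 2))
  fm <- fve_map(data, A, S)
  expect_equal(fm$flagged, 2L)
  expect_true(is.na(fm$fve[2]))
  expect_equal(fm$full_fve, mean(fm$fve[-2]))
})

test_that("frontal diagnostic correlates pattern and output L1 norms", {
  set.seed(7)
  A <- matrix(rnorm(8 * 4), 8, 4)
  w <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  mask <- c(TRUE, TRUE, rep(FALSE, 6))
  d <- frontal_diagnostic(A, w, mask, class_index = 1)
  f_brute <- colSums(abs(A[1:2, ]))
  o_brute <- apply(abs(w[, , 2]), 2, sum)
  expect_equal(d$frontal_l1, f_brute)
  expect_equal(d$output_l1, o_brute)
  expect_equal(d$pearson_r, cor(f_brute, o_brute))
  expect_false(d$undefined)

  # constant frontal loadings leave the correlation undefined
  A0 <- A; A0[1:2, ] <- 1
  d0 <- frontal_diagnostic(A0, w, mask)
  expect_true(d0$undefined)
  expect_true(is.na(d0$pearson_r))

  expect_error(frontal_diagnostic(A, w, rep(FALSE, 8)), "frontal mask")
  expect_error(frontal_diagnostic(A[, 1:2], w[, 1:2, , drop = FALSE], mask),
               "3 latent sources")
})
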