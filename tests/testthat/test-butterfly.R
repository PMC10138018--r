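test_that("bit reversal permutation matches iterated even/odd splitting", {
  expect_identical(bit_reversal_permutation(2), c(1L, 2L))
  expect_identical(bit_reversal_permutation(4), c(1L, 3L, 2L, 4L))
  # oracle: recursive even/odd index splitting
  split_oracle <- function(idx) {
    if (length(idx) == 1) return(idx)
    c(split_oracle(idx[seq(1, length(idx), 2)]),
      split_oracle(idx[seq(2, length(idx), 2)]))
  }
  expect_identical(bit_reversal_permutation(8), split_oracle(1:8))
  expect_identical(bit_reversal_permutation(8) - 1L,
                   c(0L, 4L, 2L, 6L, 1L, 5L, 3L, 7L))
  for (n in c(2L, 16L, 64L)) {
    p <- bit_reversal_permutation(n)
    expect_identical(p[p], seq_len(n))  # self-inverse
  }
  expect_error(bit_reversal_permutation(6), "power of two")
})

test_that("elementary layer operators behave per their 2x2 definitions", {
  pr <- layer_pairing(2, 1)
  out <- theta_apply(pi / 4, pr, c(1, 0))
  expect_equal(out, complex(real = c(1, 1) / sqrt(2)), tolerance = 1e-12)
  # theta = 0 maps (a, b) to (a, -b)
  expect_equal(theta_apply(0, pr, c(3, 2)), as.complex(c(3, -2)))
  # pairwise norm preservation for random angles
  set.seed(1)
  for (i in 1:20) {
    th <- runif(4, -pi, pi)
    v <- rand_cplx(8)
    out <- theta_apply(th, layer_pairing(8, 2), v)
    expect_equal(sum(abs(out)^2), sum(abs(v)^2), tolerance = 1e-12)
  }
  expect_error(theta_apply(c(0, 0), pr, c(1, 0)), "one angle per pair")

  v <- rand_cplx(6)
  expect_equal(phi_apply(numeric(6), v), v)
  expect_equal(phi_apply(rep(pi, 1), 1), as.complex(-1), tolerance = 1e-12)
  ph <- runif(6, -10, 10)
  expect_equal(abs(phi_apply(ph, v)), abs(v), tolerance = 1e-12)

  expect_equal(gamma_apply(numeric(6), v), v)
  expect_equal(gamma_apply(log(2), 3), as.complex(6))
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(gamma_apply(a, gamma_apply(b, v)), gamma_apply(a + b, v),
               tolerance = 1e-12)
})

test_that("FFT-initialized flat butterfly equals the unitary DFT oracle", {
  p2 <- fft_initialization(bf_grid(2, 1))
  B2 <- sapply(1:2, function(j) butterfly_forward(p2, diag(2)[, j]))
  expect_equal(Re(B2), matrix(c(1, 1, 1, -1), 2) / sqrt(2), tolerance = 1e-12)
  expect_equal(max(abs(Im(B2))), 0, tolerance = 1e-12)

  # delta at index 0 on N=4 maps to the constant 1/2 vector
  p4 <- fft_initialization(bf_grid(4, 1))
  expect_equal(butterfly_forward(p4, c(1, 0, 0, 0)),
               as.complex(rep(0.5, 4)), tolerance = 1e-12)

  for (n in c(4, 8, 16, 64)) {
    p <- fft_initialization(bf_grid(n, 1))
    B <- butterfly_forward(p, diag(1 + 0i, n))
    expect_lt(max(abs(B - unitary_dft(n))), 1e-10)
    # adjoint equals the inverse unitary DFT
    Badj <- butterfly_adjoint(p, diag(1 + 0i, n))
    expect_lt(max(abs(Badj - Conj(t(unitary_dft(n))))), 1e-10)
    # all theta = pi/4, all gamma = 0
    expect_true(all(abs(unlist(p$theta) - pi / 4) < 1e-15))
    expect_true(all(unlist(p$gamma) == 0))
  }
})

test_that("FFT-initialized 2D butterfly equals the separable 2D DFT", {
  for (d in list(c(4, 4), c(8, 4), c(4, 8), c(16, 16))) {
    p <- fft_initialization(bf_grid(d[1], d[2]), "two_d")
    B <- butterfly_forward(p, diag(1 + 0i, d[1] * d[2]))
    expect_lt(max(abs(B - unitary_dft2(d[1], d[2]))), 1e-10)
  }
})

test_that("adjoint identity and gamma=0 unitarity hold for random draws", {
  set.seed(7)
  for (n in c(4, 8, 16, 64)) {
    g <- bf_grid(n, 1)
    for (i in 1:25) {
      p <- random_params(g)
      x <- rand_cplx(n); y <- rand_cplx(n)
      lhs <- sum(Conj(butterfly_forward(p, x)) * y)
      rhs <- sum(Conj(x) * butterfly_adjoint(p, y))
      expect_lt(abs(lhs - rhs), 1e-10 * sqrt(sum(abs(x)^2) * sum(abs(y)^2)))
      # unitary when gamma = 0: B^dagger B = identity, norms preserved
      p0 <- p
      p0$gamma <- lapply(p0$gamma, function(v) numeric(length(v)))
      bv <- butterfly_forward(p0, x)
      expect_equal(sqrt(sum(abs(bv)^2)) / sqrt(sum(abs(x)^2)), 1,
                   tolerance = 1e-10)
      expect_equal(butterfly_adjoint(p0, bv), x, tolerance = 1e-10)
    }
  }
})

test_that("butterfly transforms are linear and validate their inputs", {
  set.seed(8)
  g <- bf_grid(4, 4)
  p <- random_params(g, "two_d")
  x <- rand_cplx(16); y <- rand_cplx(16)
  expect_equal(butterfly_forward(p, 2 * x + 3i * y),
               2 * butterfly_forward(p, x) + 3i * butterfly_forward(p, y),
               tolerance = 1e-12)
  expect_error(butterfly_forward(p, rand_cplx(8)), "does not match")
  p$gamma[[1]][1] <- NA_real_
  expect_error(butterfly_forward(p, x), "finite")
})

test_that("parameter shapes per layer match the design counting rules", {
  for (m in c(2L, 4L, 8L, 16L, 32L)) for (l in c(2L, 4L, 8L, 16L, 32L)) {
    g <- bf_grid(m, l); n <- m * l
    pf <- fft_initialization(g, "flat")
    expect_equal(length(pf$phi), log2(n))
    expect_equal(sum(lengths(unlist(pf$theta, recursive = FALSE))),
                 n / 2 * log2(n))
    expect_equal(sum(lengths(pf$phi)), n * log2(n))
    expect_equal(sum(lengths(pf$gamma)), n * log2(n))
    p2 <- fft_initialization(g, "two_d")
    expect_equal(length(p2$phi), max(log2(m), log2(l)))
    expect_equal(sum(lengths(unlist(p2$theta, recursive = FALSE))),
                 m / 2 * log2(m) + l / 2 * log2(l))
    expect_equal(sum(lengths(p2$phi)), n * max(log2(m), log2(l)))
  }
})
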