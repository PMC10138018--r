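test_that("spectrum diagonal multiplies by exp(lambda)", {
  expect_equal(lambda_apply(rep(0 + 0i, 3), c(1, 2, 3)), as.complex(1:3))
  expect_equal(lambda_apply(1i * pi, 2), as.complex(-2), tolerance = 1e-12)
  expect_equal(lambda_apply(1 + 0i, 1), as.complex(exp(1)), tolerance = 1e-12)
  expect_error(lambda_apply(rep(0 + 0i, 2), 1:3), "equal length")
})

test_that("delta-initialized BCOs act as the identity", {
  set.seed(11)
  for (design in c("flat", "two_d")) for (mir in c(TRUE, FALSE)) {
    op <- bco_delta_init(bf_grid(4, 4), design, mir)
    v <- rnorm(16)
    expect_lt(max(abs(bco_apply(op, v) - v)), 1e-10)
  }
  # serial chain of 3 delta BCOs is the identity, parallel sum is n*v
  net <- network_init(network_config(bf_grid(4, 4), 3))
  v <- rnorm(16)
  expect_lt(max(abs(network_apply(net, v) - v)), 1e-10)
  expect_lt(max(abs(network_apply(net, v, "parallel") - 3 * v)), 1e-10)
  # single-BCO network equals bco_apply; zero maps to zero
  expect_equal(network_apply(net[1], v), Re(bco_apply(net[[1]], v)))
  expect_equal(bco_apply(net[[1]], numeric(16)), rep(0 + 0i, 16))
})

test_that("FFT-configured mirrored BCO reproduces circular convolution", {
  set.seed(12)
  for (n in c(16, 64)) {
    k <- rnorm(n)
    lam <- log(sqrt(n) * drop(unitary_dft(n) %*% k))
    op <- bf_bco(fft_initialization(bf_grid(n, 1)), lambda = lam)
    v <- rnorm(n)
    expect_lt(max(abs(Re(bco_apply(op, v)) - circ_conv(k, v))), 1e-8)
    # materialized operator equals the circulant matrix of k
    if (n <= 16)
      expect_lt(max(abs(materialize_matrix(list(op)) -
                        circulant_matrix(k))), 1e-8)
  }
})

test_that("materialized matrix agrees with network application", {
  set.seed(13)
  g <- bf_grid(4, 4)
  net <- list(bf_bco(random_params(g), rand_cplx(16) * 0.3,
                     random_params(g)),
              bf_bco(random_params(g, "two_d"), rand_cplx(16) * 0.3))
  for (comp in c("serial", "parallel")) {
    M <- materialize_matrix(net, comp)
    for (i in 1:20) {
      v <- rnorm(16)
      expect_lt(max(abs(M %*% v - network_apply(net, v, comp))), 1e-10)
    }
  }
  expect_error(materialize_matrix(net, cap = 8), "cap")
  expect_error(network_apply(list(), rnorm(4)), "empty")
})

test_that("mirrored BCO with gamma = 0 and imaginary spectrum is unitary", {
  set.seed(14)
  g <- bf_grid(8, 1)
  p <- random_params(g)
  p$gamma <- lapply(p$gamma, function(v) numeric(length(v)))
  op <- bf_bco(p, 1i * runif(8, -pi, pi))
  for (i in 1:10) {
    v <- rand_cplx(8)
    expect_equal(sqrt(sum(abs(bco_apply(op, v))^2)),
                 sqrt(sum(abs(v)^2)), tolerance = 1e-10)
  }
})

test_that("parameter counts reproduce the closed forms and printed tables", {
  # closed forms per transform for all grid combinations
  for (m in c(2L, 4L, 8L, 16L, 32L)) for (l in c(2L, 4L, 8L, 16L, 32L)) {
    g <- bf_grid(m, l); n <- m * l
    flat <- network_config(g, 1, mirrored = TRUE, design = "flat")
    expect_equal(count_parameters(flat),
                 (n / 2) * log2(n) + 2 * n * log2(n) + 2 * n)
    twod <- network_config(g, 1, mirrored = TRUE, design = "two_d")
    expect_equal(count_parameters(twod),
                 m / 2 * log2(m) + l / 2 * log2(l) +
                   2 * n * max(log2(m), log2(l)) + 2 * n)
  }
  # printed 16x16 architecture table
  g16 <- bf_grid(16)
  printed <- c(net1 = 5632, net2 = 11264, net3 = 16896, net4 = 32256,
               net5 = 7872, net6 = 14208, net7 = 32256)
  dens <- c(net1 = 8.59, net2 = 17.19, net3 = 25.78, net4 = 49.22,
            net5 = 12.01, net6 = 21.68, net7 = 49.22)
  for (nm in names(printed)) {
    cfg <- network_preset(nm, g16)
    expect_equal(count_parameters(cfg), as.numeric(printed[[nm]]),
                     label = nm)
    expect_equal(round(network_density(cfg), 2), dens[[nm]], label = nm)
    # counting an instantiated network agrees with the config formula
    expect_equal(count_parameters(network_init(cfg)), printed[[nm]])
  }
  # resolution scaling row
  cfg32 <- network_preset("net4", bf_grid(32))
  expect_equal(count_parameters(cfg32), 159744)
  expect_equal(round(network_density(cfg32), 2), 15.23)
  # composition does not change the count
  expect_equal(count_parameters(network_preset("net7", g16)),
                   count_parameters(network_preset("net4", g16)))
})
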