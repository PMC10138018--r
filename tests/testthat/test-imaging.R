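test_that("Poisson Hamiltonian matches the term-by-term formula", {
  # d = 0 everywhere reduces to the total rate
  mu <- runif(8, 0.5, 3)
  expect_equal(poisson_hamiltonian(rep(0, 8), mu), sum(mu))
  # gradient in mu vanishes at mu = d (single pixel, finite differences)
  h <- 1e-6
  expect_lt(abs(poisson_hamiltonian(4, 4 + h) -
                poisson_hamiltonian(4, 4 - h)) / (2 * h), 1e-4)
  # oracle including the dropped log(d!) data term: the difference of the
  # two Hamiltonians at fixed d must be identical with and without it
  set.seed(61)
  d <- rpois(8, 3); mu1 <- runif(8, 0.5, 4); mu2 <- runif(8, 0.5, 4)
  full <- function(mu) sum(mu - d * log(mu) + lgamma(d + 1))
  expect_equal(poisson_hamiltonian(d, mu1) - poisson_hamiltonian(d, mu2),
               full(mu1) - full(mu2), tolerance = 1e-10)
  expect_error(poisson_hamiltonian(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(poisson_hamiltonian(c(1, 2), c(0, 1)), "positive")
})

test_that("inverse-gamma transform standardizes the point-source prior", {
  cfg <- prior_config(alpha = 1, q = 1)
  # median of the latent maps to the prior median 1/log(2)
  expect_equal(inverse_gamma_transform(0, cfg), 1 / log(2),
               tolerance = 1e-10)
  # oracle: numeric inversion of the inverse-gamma CDF at the normal CDF
  pinvgamma <- function(x, a, q) 1 - pgamma(1 / x, a, rate = q)
  for (xi in c(-2, -0.5, 0.7, 2.5)) {
    target <- pnorm(xi)
    x <- uniroot(function(t) pinvgamma(t, 1, 1) - target,
                 c(1e-8, 1e8), tol = 1e-12)$root
    expect_equal(inverse_gamma_transform(xi, cfg), x, tolerance = 1e-6)
  }
  # monotone and positive
  xs <- inverse_gamma_transform(seq(-6, 6, length.out = 200), cfg)
  expect_true(all(diff(xs) > 0) && all(xs > 0))
  # distributional check: transformed normals follow the inverse-gamma CDF
  set.seed(62)
  cfg2 <- prior_config(alpha = 2, q = 1.5)
  smp <- inverse_gamma_transform(rnorm(1e5), cfg2)
  ks <- suppressWarnings(ks.test(smp, function(x) pinvgamma(x, 2, 1.5)))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("zero counts drive the MAP estimate into the faint prior bulk", {
  g <- bf_grid(4, 4)
  net <- list(bco_delta_init(g))  # flat (identity) response
  counts <- matrix(0L, 4, 4)
  rec <- reconstruct_map(counts, net, max_steps = 50)
  expect_true(all(rec$signal < 1 / log(2)))  # below the prior median
  expect_true(all(rec$rates >= 1e-8))
  expect_true(!is.unsorted(rev(rec$trace)))
})

test_that("a known circulant response is inverted on noise-free counts", {
  # high-count scene through an exactly representable (circulant) blur;
  # counts taken at the rates themselves (no Poisson draw)
  g <- bf_grid(8)
  mod <- svpsf_model(g, beta = 0, eta = 2e-3)
  k <- psf_kernel(mod, c(0, 0))
  lam <- log(sqrt(64) * drop(unitary_dft2(8, 8) %*% as.vector(k)))
  op <- bf_bco(fft_initialization(g, "two_d"), lambda = lam)
  truth <- matrix(0, 8, 8)
  pos <- rbind(c(2, 2), c(5, 6), c(6, 1))
  truth[pos + 1] <- c(950, 920, 980)
  rates <- apply_synthetic_response(mod, truth)
  counts <- matrix(as.integer(round(rates)), 8, 8)
  rec <- reconstruct_map(counts, list(op), max_steps = 150)
  # reconstructed argmax pixels coincide with the true sources
  top3 <- order(rec$signal, decreasing = TRUE)[1:3]
  expect_setequal(top3, pos[, 1] + 1 + 8 * pos[, 2])
  # recovered brightness within 5%
  expect_lt(max(abs(sort(rec$signal[top3]) - sort(truth[truth > 0])) /
                sort(truth[truth > 0])), 0.05)
  # predicted rates honour the clip floor
  expect_true(all(rec$rates >= 1e-8))
})

test_that("central sources of a full imaging run are recovered exactly", {
  g <- bf_grid(16)
  mod <- svpsf_model(g)
  fit <- fit16_net4()
  sc <- simulate_scene(g, 15, c(900, 1000), seed = 1)
  counts <- poisson_observe(apply_synthetic_response(mod, scene_image(sc)),
                            seed = 101)
  rec <- reconstruct_map(counts, fit, max_steps = 150)
  expect_true(!is.unsorted(rev(rec$trace)))
  lm <- local_maxima(rec$signal)
  keys <- paste(lm[, 1], lm[, 2])
  hit <- paste(sc$positions[, 1], sc$positions[, 2]) %in% keys
  rhat <- sqrt((sc$positions[, 1] - mod$centre[1])^2 +
               (sc$positions[, 2] - mod$centre[2])^2) / mod$rmax
  # the qualitative claim: sources in the central half of the field sit as
  # local maxima exactly at their true pixels
  expect_true(all(hit[rhat <= 0.5]))
  # every source (including blurred border ones) is detected within 1.5 px
  for (i in seq_len(15)) {
    dr <- pmin(abs(lm[, 1] - sc$positions[i, 1]),
               16 - abs(lm[, 1] - sc$positions[i, 1]))
    dc <- pmin(abs(lm[, 2] - sc$positions[i, 2]),
               16 - abs(lm[, 2] - sc$positions[i, 2]))
    expect_lt(min(sqrt(dr^2 + dc^2)), 1.5)
  }
})

test_that("Poisson residuals are calibrated in the well-constrained centre", {
  # repeated observations of one fixed scene through a wide invariant
  # blur: per pixel, the residuals d - mu_hat average near zero (relative
  # to the rate; the MAP point estimate carries a small deterministic
  # shrinkage bias) with variance near mu_hat
  g <- bf_grid(8)
  mod <- svpsf_model(g, beta = 0, eta = 0.02)
  k <- psf_kernel(mod, c(0, 0))
  lam <- log(sqrt(64) * drop(unitary_dft2(8, 8) %*% as.vector(k)))
  op <- bf_bco(fft_initialization(g, "two_d"), lambda = lam)
  truth <- matrix(0, 8, 8); truth[4, 4] <- 950; truth[3, 6] <- 920
  rates <- apply_synthetic_response(mod, truth)
  centre <- which(rates > 5)
  reps <- 12
  resid <- matrix(NA_real_, length(centre), reps)
  muhat <- matrix(NA_real_, length(centre), reps)
  for (r in seq_len(reps)) {
    counts <- poisson_observe(rates, seed = 200 + r)
    rec <- reconstruct_map(counts, list(op), max_steps = 120)
    resid[, r] <- (as.vector(counts) - as.vector(rec$rates))[centre]
    muhat[, r] <- as.vector(rec$rates)[centre]
  }
  pmu <- rowMeans(muhat)
  expect_lt(abs(mean(resid)), 0.1 * mean(pmu))
  ratio <- mean(apply(resid, 1, var) / pmu)
  expect_gt(ratio, 0.5); expect_lt(ratio, 1.5)
})
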