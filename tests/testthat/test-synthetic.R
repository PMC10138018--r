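test_that("variance profile matches its closed form at the printed settings", {
  mod <- svpsf_model(bf_grid(16))
  expect_equal(variance_profile(mod, mod$centre), 1e-5)
  # corner pixel sits at rhat = 1
  expect_equal(variance_profile(mod, c(0, 0)), 0.01001)
  # monotone non-decreasing in rhat along a ray
  vars <- sapply(0:7, function(r) variance_profile(mod, c(7.5 - r, 7.5)))
  expect_true(all(diff(vars) >= 0))
  expect_error(variance_profile(mod, c(-1, 0)), "on the grid")
  expect_error(svpsf_model(bf_grid(4), eta = 0), "eta > 0")
})

test_that("PSF kernels are normalized Gaussians on the pixel torus", {
  g <- bf_grid(32)
  mod <- svpsf_model(g)
  # peak value at rho = 0 is the continuous prefactor in pixel units
  z <- c(4, 4)
  s2p <- variance_profile(mod, z) * 32^2
  k <- psf_kernel(mod, z)
  expect_equal(k[1, 1], 1 / (2 * pi * s2p), tolerance = 1e-12)
  expect_true(all(k <= k[1, 1]))
  # symmetric under reflection of each axis (periodic indices)
  expect_equal(k, k[c(1, 32:2), ], tolerance = 1e-15)
  expect_equal(k, k[, c(1, 32:2)], tolerance = 1e-15)
  # discrete sum ~ 1 once sigma^2 is at least 4 pixel widths^2
  # (pixel width 1/32 in image-normalized units)
  for (s2 in c(4 / 32^2, 8 / 32^2, 0.01)) {
    modw <- svpsf_model(g, beta = 0, eta = s2)
    expect_equal(sum(psf_kernel(modw, c(0, 0))), 1, tolerance = 0.02)
  }
  # kernel width grows with centre distance (second moment comparison)
  second_moment <- function(z) {
    k <- psf_kernel(mod, z)
    d2 <- outer(pmin(0:31, 32 - 0:31)^2, pmin(0:31, 32 - 0:31)^2, "+")
    sum(k * d2) / sum(k)
  }
  expect_lt(second_moment(c(15.5, 15.5)), second_moment(c(8, 8)))
  expect_lt(second_moment(c(8, 8)), second_moment(c(0, 0)))
})

test_that("synthetic response matches a brute-force double loop", {
  g <- bf_grid(4)
  mod <- svpsf_model(g, beta = 0.05, eta = 1e-3)
  # oracle: direct evaluation of the response sum per output pixel
  brute <- function(s) {
    out <- matrix(0, 4, 4)
    for (yr in 0:3) for (yc in 0:3) {
      acc <- 0
      for (xr in 0:3) for (xc in 0:3) {
        s2p <- variance_profile(mod, c(xr, xc)) * 16
        dr <- min(abs(yr - xr), 4 - abs(yr - xr))
        dc <- min(abs(yc - xc), 4 - abs(yc - xc))
        acc <- acc + s[xr + 1, xc + 1] *
          exp(-(dr^2 + dc^2) / (2 * s2p)) / (2 * pi * s2p)
      }
      out[yr + 1, yc + 1] <- acc
    }
    out
  }
  set.seed(31)
  for (i in 1:5) {
    s <- matrix(rexp(16), 4, 4)
    expect_equal(apply_synthetic_response(mod, s), brute(s),
                 tolerance = 1e-12)
  }
  # linearity and zero signal
  s1 <- matrix(rexp(16), 4); s2 <- matrix(rexp(16), 4)
  expect_equal(apply_synthetic_response(mod, 2 * s1 + 3 * s2),
               2 * apply_synthetic_response(mod, s1) +
                 3 * apply_synthetic_response(mod, s2), tolerance = 1e-12)
  expect_equal(apply_synthetic_response(mod, matrix(0, 4, 4)),
               matrix(0, 4, 4))
})

test_that("a point source maps to its translated kernel", {
  mod <- svpsf_model(bf_grid(8))
  z <- c(5, 2)
  s <- matrix(0, 8, 8); s[z[1] + 1, z[2] + 1] <- 40
  resp <- apply_synthetic_response(mod, s)
  k <- psf_kernel(mod, z)
  shifted <- k[((0:7 - z[1]) %% 8) + 1, ((0:7 - z[2]) %% 8) + 1]
  expect_equal(resp, 40 * shifted, tolerance = 1e-12)
  # the response peaks at the source position
  expect_equal(which.max(resp), z[1] + 1 + 8 * z[2])
})

test_that("response stacks hold one response per source pixel", {
  mod16 <- svpsf_model(bf_grid(16))
  stack <- build_response_stack(mod16)
  expect_identical(dim(stack), c(256L, 256L))
  mod <- svpsf_model(bf_grid(4), beta = 0.05, eta = 1e-3)
  stack4 <- build_response_stack(mod)
  for (z in c(1, 7, 16)) {
    delta <- numeric(16); delta[z] <- 1
    expect_equal(stack4[, z], apply_synthetic_response(mod, delta),
                 tolerance = 1e-14)
  }
  # beta = 0: spatially invariant, the stack is a circulant-structured
  # matrix whose columns are periodic shifts of column 1
  mod0 <- svpsf_model(bf_grid(4), beta = 0, eta = 2e-3)
  st0 <- build_response_stack(mod0)
  k0 <- matrix(st0[, 1], 4, 4)
  for (z in 0:15) {
    zr <- z %% 4; zc <- z %/% 4
    expect_equal(matrix(st0[, z + 1], 4, 4),
                 k0[((0:3 - zr) %% 4) + 1, ((0:3 - zc) %% 4) + 1],
                 tolerance = 1e-14)
  }
})

test_that("scene simulation is seeded and respects its contracts", {
  g <- bf_grid(16)
  s1 <- simulate_scene(g, seed = 5)
  s2 <- simulate_scene(g, seed = 5)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$brightness, s2$brightness)
  expect_identical(nrow(s1$positions), 15L)  # default source count
  expect_true(all(s1$brightness >= 900 & s1$brightness <= 1000))
  expect_false(any(duplicated(s1$positions)))
  img <- scene_image(s1)
  expect_equal(sum(img > 0), 15)
  expect_equal(sum(img), sum(s1$brightness))
  expect_error(simulate_scene(bf_grid(2), n_sources = 5), "cannot place")
})

test_that("Poisson observations have the right moments and seeding", {
  expect_identical(poisson_observe(matrix(0, 3, 3), seed = 1),
                   matrix(0L, 3, 3))
  draws <- poisson_observe(rep(5, 1e5), seed = 2)
  expect_lt(abs(mean(draws) - 5), 0.05)
  expect_lt(abs(var(draws) - 5), 0.15)
  expect_identical(poisson_observe(rep(2, 10), seed = 3),
                   poisson_observe(rep(2, 10), seed = 3))
  expect_warning(poisson_observe(c(-0.1, 2), seed = 1), "clipped")
  expect_error(poisson_observe(c(Inf, 1), seed = 1), "finite")
})
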