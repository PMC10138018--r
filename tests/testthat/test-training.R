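test_that("likelihood and prior Hamiltonians evaluate their closed forms", {
  expect_equal(gaussian_likelihood_hamiltonian(1:5, 1:5, 1e-6), 0)
  # single pixel: residual 1e-3 at variance 1e-6 contributes 1/2
  expect_equal(gaussian_likelihood_hamiltonian(1e-3, 0, 1e-6), 0.5)
  expect_error(gaussian_likelihood_hamiltonian(1, 1, 0), "positive")
  # oracle: dense quadratic form with diagonal noise covariance
  set.seed(51)
  d <- rnorm(8); r <- rnorm(8); nv <- 0.37
  Ninv <- diag(1 / nv, 8)
  expect_equal(gaussian_likelihood_hamiltonian(d, r, nv),
               0.5 * drop(t(d - r) %*% Ninv %*% (d - r)), tolerance = 1e-12)

  expect_equal(prior_hamiltonian(rep(1, 4), rep(1, 4)), 0)
  expect_equal(prior_hamiltonian(1, 0, 1), 0.5)
  # additivity over parameter blocks
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(prior_hamiltonian(a, b),
               prior_hamiltonian(a[1:2], b[1:2]) +
                 prior_hamiltonian(a[3:6], b[3:6]))
})

test_that("training on an identity stack stays at the exact initialization", {
  g <- bf_grid(4, 4)
  data <- list(signals = diag(40, 16), targets = diag(40, 16))
  res <- train_map(network_config(g, 1), data, max_steps = 5)
  sim <- structure(diag(16), grid = g, class = c("response_stack", "matrix"))
  expect_lt(total_error(sim, network_response_stack(res$network)), 1e-6)
})

test_that("a circulant response is learned to below 1% by one mirrored BCO", {
  g <- bf_grid(8)
  mod <- svpsf_model(g, beta = 0, eta = 1e-3)
  fit <- bf_fit(mod, network_config(g, 1, mirrored = TRUE, design = "flat"),
                max_steps = 100, cg_max_iter = 30)
  expect_lt(fit$zeta, 0.01)
  # loss trace is non-increasing across accepted Newton steps
  expect_true(all(diff(fit$trace) <= 1e-8 * abs(fit$trace[-length(fit$trace)])))
})

test_that("the fitted model object supports the standard methods", {
  g <- bf_grid(8)
  mod <- svpsf_model(g, beta = 0, eta = 1e-3)
  fit <- cached_fit("fit8_circulant", function()
    bf_fit(mod, network_config(g, 1), max_steps = 40, cg_max_iter = 30))
  expect_s3_class(fit, "butterfly_fit")
  expect_output(print(fit), "zeta")
  sm <- summary(fit)
  expect_equal(sm$n_parameters, count_parameters(fit$config))
  expect_output(print(sm), "density")
  cf <- coef(fit)
  expect_equal(length(cf), count_parameters(fit$config))
  expect_true(all(is.finite(cf)))
  # predict on an image returns the (approximate) blurred image
  img <- matrix(0, 8, 8); img[4, 5] <- 1
  pred <- predict(fit, img)
  truth <- apply_synthetic_response(mod, img)
  expect_equal(dim(pred), c(8, 8))
  expect_lt(max(abs(pred - truth)), 0.05 * max(truth))
  # residuals are the stack difference; fitted returns the learned stack
  expect_equal(residuals(fit),
               unclass(fit$sim_stack) - unclass(fitted(fit)))
})

coef_vec <- function(res)
  unlist(lapply(res$network, function(op) c(unlist(op$b1[c("theta", "phi",
    "gamma")]), Re(op$lambda), Im(op$lambda))))

test_that("training is deterministic", {
  g <- bf_grid(4)
  mod <- svpsf_model(g, eta = 1e-3)
  data <- training_pairs(mod)
  r1 <- train_map(network_config(g, 1), data, max_steps = 10)
  r2 <- train_map(network_config(g, 1), data, max_steps = 10)
  expect_identical(r1$trace, r2$trace)
  expect_identical(coef_vec(r1), coef_vec(r2))
})

test_that("the quasi-Newton fallback optimizer also reduces the loss", {
  g <- bf_grid(4)
  data <- training_pairs(svpsf_model(g, eta = 1e-3))
  res <- train_map(network_config(g, 1), data, max_steps = 50,
                   optimizer = "lbfgs")
  obj0 <- map_objective(network_init(network_config(g, 1)),
                        data$signals, data$targets, 1e-6)
  expect_lt(res$value, obj0$value(obj0$x0))
})
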