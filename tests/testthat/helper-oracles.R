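# Independent oracles and shared fixtures. The oracles are direct O(N^2)
# constructions, kept free of the package's butterfly code paths.

# unitary DFT matrix, computed entry by entry from the definition
unitary_dft <- function(n)
  outer(0:(n - 1), 0:(n - 1),
        function(k, x) exp(-2i * pi * k * x / n)) / sqrt(n)

# separable unitary 2D DFT on the column-major flattening of an m x l image
unitary_dft2 <- function(m, l) unitary_dft(l) %x% unitary_dft(m)

# 1D circular convolution (k * v)[y] = sum_x k[(y - x) mod n] v[x]
circ_conv <- function(k, v) {
  n <- length(k)
  vapply(0:(n - 1), function(y)
    sum(k[((y - 0:(n - 1)) %% n) + 1] * v), numeric(1))
}

# dense circulant matrix of kernel k (column z = k shifted by z)
circulant_matrix <- function(k) {
  n <- length(k)
  sapply(0:(n - 1), function(z) k[((0:(n - 1) - z) %% n) + 1])
}

# random butterfly parameters with moderate gamma so products stay tame
random_params <- function(grid, design = "flat", gamma_sd = 0.2) {
  tpl <- fft_initialization(grid, design)
  tpl$theta <- lapply(tpl$theta, function(st) lapply(st, function(v)
    stats::runif(length(v), -pi, pi)))
  tpl$phi <- lapply(tpl$phi, function(v) stats::runif(length(v), -pi, pi))
  tpl$gamma <- lapply(tpl$gamma, function(v) stats::rnorm(length(v),
                                                         sd = gamma_sd))
  tpl
}

rand_cplx <- function(n) complex(real = stats::rnorm(n),
                                 imaginary = stats::rnorm(n))

# session-level cache so expensive trained networks are fitted once and
# shared between test files
.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(key, fun) {
  if (is.null(.fit_cache[[key]])) .fit_cache[[key]] <- fun()
  .fit_cache[[key]]
}

# the reference experiment at full printed scale: 16x16 synthetic response,
# Net4 architecture, brightness-40 point sources, noise variance 1e-6,
# 300 Newton steps
fit16_net4 <- function() cached_fit("fit16_net4", function() {
  bf_fit(svpsf_model(bf_grid(16)), network_preset("net4", bf_grid(16)),
         max_steps = 300, cg_max_iter = 30)
})

# scaled-down architecture comparison on 8x8, 100 Newton steps
fit8 <- function(preset) cached_fit(paste0("fit8_", preset), function() {
  bf_fit(svpsf_model(bf_grid(8)), network_preset(preset, bf_grid(8)),
         max_steps = 100, cg_max_iter = 30)
})
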