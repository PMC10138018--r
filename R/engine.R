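# Internal operator engine.
#
# A butterfly network is compiled into ordered "op programs". Each op is one
# of:
#   perm  - fixed index permutation (bit reversal wiring)
#   mix   - pairwise Theta rotations at one stride, angles from a named
#           parameter slot
#   diag  - entrywise multiplication by exp(gamma + sgn*1i*phi)
#   lam   - entrywise multiplication by exp(lambda), lambda = re + 1i*im
#
# Programs act column-wise on complex N x P matrices, so a full batch of
# signals is pushed through in one pass. Hand-written reverse-mode (VJP) and
# forward-mode (JVP) rules for every op give exact gradients and
# Gauss-Newton Hessian-vector products for MAP training; the VJP of a
# program is exactly the adjoint operator acting on the cotangent, plus
# parameter-gradient accumulation.

op_perm <- function(p) {
  ip <- integer(length(p)); ip[p] <- seq_along(p)
  list(op = "perm", p = p, ip = ip)
}
op_mix <- function(mix, ref) c(list(op = "mix", ref = ref), mix)
op_diag <- function(phi_ref, gamma_ref, sgn)
  list(op = "diag", phi_ref = phi_ref, gamma_ref = gamma_ref, sgn = sgn)
op_lam <- function(re_ref, im_ref)
  list(op = "lam", re_ref = re_ref, im_ref = im_ref)

# Parameter slot names for one butterfly transform with name prefix `pre`.
ref_theta <- function(pre, s, t) paste0(pre, ".th.", s, ".", t)
ref_phi   <- function(pre, s) paste0(pre, ".ph.", s)
ref_gamma <- function(pre, s) paste0(pre, ".ga.", s)

# Forward program of B: input bit reversal, then per stage Theta (one mix
# per pairing block), then the combined Gamma*Phi diagonal.
prog_butterfly <- function(plan, pre) {
  ops <- list(op_perm(plan$perm))
  for (s in seq_len(plan$n_stages)) {
    for (t in seq_along(plan$stages[[s]]$mixes))
      ops[[length(ops) + 1L]] <- op_mix(plan$stages[[s]]$mixes[[t]],
                                        ref_theta(pre, s, t))
    ops[[length(ops) + 1L]] <- op_diag(ref_phi(pre, s), ref_gamma(pre, s), 1)
  }
  ops
}

# Adjoint program of B: conjugate-transposed layers in reverse order, then
# the (self-inverse) bit reversal. Theta is real symmetric orthogonal per
# pair, so its adjoint reuses the same mix rule.
prog_butterfly_adjoint <- function(plan, pre) {
  ops <- list()
  for (s in rev(seq_len(plan$n_stages))) {
    ops[[length(ops) + 1L]] <- op_diag(ref_phi(pre, s), ref_gamma(pre, s), -1)
    for (t in rev(seq_along(plan$stages[[s]]$mixes)))
      ops[[length(ops) + 1L]] <- op_mix(plan$stages[[s]]$mixes[[t]],
                                        ref_theta(pre, s, t))
  }
  ops[[length(ops) + 1L]] <- op_perm(plan$perm)
  ops
}

as_cplx_mat <- function(v, n) {
  if (is.null(dim(v))) v <- matrix(v, nrow = length(v))
  if (nrow(v) != n) stop("input length ", nrow(v), " does not match grid size ", n)
  if (!is.complex(v)) storage.mode(v) <- "complex"
  v
}

# Execute a program. With tape = TRUE also records the input of every op
# (the output of op i is the input of op i+1), which run_vjp/run_jvp reuse.
run_fwd <- function(ops, pars, V, tape = FALSE) {
  inputs <- if (tape) vector("list", length(ops))
  for (i in seq_along(ops)) {
    o <- ops[[i]]
    if (tape) inputs[[i]] <- V
    V <- switch(o$op,
      perm = V[o$p, , drop = FALSE],
      mix = {
        th <- pars[[o$ref]][o$map]
        (o$sgn * cos(th)) * V + sin(th) * V[o$partner, , drop = FALSE]
      },
      diag = exp(pars[[o$gamma_ref]] + (o$sgn * 1i) * pars[[o$phi_ref]]) * V,
      lam = exp(pars[[o$re_ref]] + 1i * pars[[o$im_ref]]) * V)
  }
  if (tape) list(out = V, inputs = inputs) else V
}

op_output <- function(ops, tp, i)
  if (i == length(ops)) tp$out else tp$inputs[[i + 1L]]

# Reverse-mode pass: cotangent W flows backwards through the program;
# parameter gradients are accumulated into the environment `acc` (named
# numeric vectors, same slots as `pars`).
run_vjp <- function(ops, pars, tp, W, acc) {
  for (i in rev(seq_along(ops))) {
    o <- ops[[i]]
    W <- switch(o$op,
      perm = W[o$ip, , drop = FALSE],
      mix = {
        Vin <- tp$inputs[[i]]
        th <- pars[[o$ref]][o$map]
        cs <- cos(th); sn <- sin(th)
        g <- .rowSums(Re(Conj((-o$sgn * sn) * Vin +
                              cs * Vin[o$partner, , drop = FALSE]) * W),
                      nrow(W), ncol(W))
        acc[[o$ref]] <- acc[[o$ref]] + as.vector(rowsum(g, o$map))
        (o$sgn * cs) * W + sn * W[o$partner, , drop = FALSE]
      },
      diag = {
        out <- op_output(ops, tp, i)
        cw <- Conj(out) * W
        acc[[o$gamma_ref]] <- acc[[o$gamma_ref]] +
          .rowSums(Re(cw), nrow(W), ncol(W))
        acc[[o$phi_ref]] <- acc[[o$phi_ref]] +
          o$sgn * .rowSums(Im(cw), nrow(W), ncol(W))
        Conj(exp(pars[[o$gamma_ref]] + (o$sgn * 1i) * pars[[o$phi_ref]])) * W
      },
      lam = {
        out <- op_output(ops, tp, i)
        cw <- Conj(out) * W
        acc[[o$re_ref]] <- acc[[o$re_ref]] +
          .rowSums(Re(cw), nrow(W), ncol(W))
        acc[[o$im_ref]] <- acc[[o$im_ref]] +
          .rowSums(Im(cw), nrow(W), ncol(W))
        Conj(exp(pars[[o$re_ref]] + 1i * pars[[o$im_ref]])) * W
      })
  }
  W
}

# Forward-mode pass: propagates the tangent dV of the input together with
# parameter tangents dpars (named like `pars`; missing slots mean zero).
run_jvp <- function(ops, pars, tp, dpars, dV) {
  for (i in seq_along(ops)) {
    o <- ops[[i]]
    dV <- switch(o$op,
      perm = dV[o$p, , drop = FALSE],
      mix = {
        th <- pars[[o$ref]][o$map]
        cs <- cos(th); sn <- sin(th)
        out <- (o$sgn * cs) * dV + sn * dV[o$partner, , drop = FALSE]
        dth_raw <- dpars[[o$ref]]
        if (!is.null(dth_raw)) {
          Vin <- tp$inputs[[i]]
          out <- out + ((-o$sgn * sn) * Vin +
                        cs * Vin[o$partner, , drop = FALSE]) * dth_raw[o$map]
        }
        out
      },
      diag = {
        out <- op_output(ops, tp, i)
        mult <- exp(pars[[o$gamma_ref]] + (o$sgn * 1i) * pars[[o$phi_ref]])
        d <- mult * dV
        dga <- dpars[[o$gamma_ref]]; dph <- dpars[[o$phi_ref]]
        if (!is.null(dga)) d <- d + out * dga
        if (!is.null(dph)) d <- d + out * ((o$sgn * 1i) * dph)
        d
      },
      lam = {
        out <- op_output(ops, tp, i)
        d <- exp(pars[[o$re_ref]] + 1i * pars[[o$im_ref]]) * dV
        dre <- dpars[[o$re_ref]]; dim <- dpars[[o$im_ref]]
        if (!is.null(dre)) d <- d + out * dre
        if (!is.null(dim)) d <- d + out * (1i * dim)
        d
      })
  }
  dV
}

# Adjoint application of a program (conjugate transpose of the realized
# linear operator) without parameter-gradient accumulation or tape: the
# imaging step only needs the fixed trained operator and its adjoint.
run_adjoint <- function(ops, pars, W) {
  for (i in rev(seq_along(ops))) {
    o <- ops[[i]]
    W <- switch(o$op,
      perm = W[o$ip, , drop = FALSE],
      mix = {
        th <- pars[[o$ref]][o$map]
        (o$sgn * cos(th)) * W + sin(th) * W[o$partner, , drop = FALSE]
      },
      diag = Conj(exp(pars[[o$gamma_ref]] +
                        (o$sgn * 1i) * pars[[o$phi_ref]])) * W,
      lam = Conj(exp(pars[[o$re_ref]] + 1i * pars[[o$im_ref]])) * W)
  }
  W
}

# Lower an op program for the compiled engine: parameter references become
# 0-based slot indices into the fixed parameter-list order, index vectors
# become 0-based.
lower_ops <- function(ops, par_names) {
  ref_idx <- function(nm) {
    i <- match(nm, par_names)
    if (is.na(i)) stop("unknown parameter slot: ", nm)
    i - 1L
  }
  lapply(ops, function(o) switch(o$op,
    perm = list(type = 0L, p = o$p - 1L, ip = o$ip - 1L),
    mix = list(type = 1L, partner = o$partner - 1L, map = o$map - 1L,
               sgn = o$sgn, ref = ref_idx(o$ref), K = o$K),
    diag = list(type = 2L, phi_ref = ref_idx(o$phi_ref),
                gamma_ref = ref_idx(o$gamma_ref), dsgn = o$sgn),
    lam = list(type = 3L, re_ref = ref_idx(o$re_ref),
               im_ref = ref_idx(o$im_ref))))
}

compile_engine <- function(eng) {
  par_names <- names(eng$pars)
  progs <- lapply(eng$branches, function(br)
    eng_compile(lower_ops(br, par_names), length(par_names)))
  list(progs = progs, par_names = par_names)
}

new_grad_env <- function(pars) {
  acc <- new.env(parent = emptyenv())
  for (nm in names(pars)) assign(nm, numeric(length(pars[[nm]])), envir = acc)
  acc
}

grad_env_to_list <- function(acc, pars) {
  out <- pars
  for (nm in names(pars)) out[[nm]] <- get(nm, envir = acc)
  out
}
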