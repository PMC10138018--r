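// Compiled core of the operator engine: forward, reverse-mode (VJP),
// forward-mode (JVP) and plain adjoint passes over a lowered op program.
// Mirrors R/engine.R op for op; the R implementation remains the reference
// the compiled path is tested against.
//
// The tape is a reusable buffer object: slot i holds the input of op i
// (slot n_ops the final output), and a forward-with-tape pass writes each
// op's output directly into the next slot, so after the first call no
// allocations happen on the training hot path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cx_mat;
using arma::cx_vec;
using arma::uvec;
using arma::vec;
typedef std::complex<double> cplx;

enum OpType { OP_PERM = 0, OP_MIX = 1, OP_DIAG = 2, OP_LAM = 3 };

struct Op {
  int type;
  uvec p, ip;            // perm (0-based)
  uvec partner, map;     // mix (0-based)
  vec sgn;               // mix: +1 first pair member, -1 second
  int ref = -1;          // mix: angle slot
  int K = 0;             // mix: raw angle count
  int phi_ref = -1, gamma_ref = -1;  // diag
  double dsgn = 1.0;                 // diag: sign of i*phi
  int re_ref = -1, im_ref = -1;      // lam
};

struct Program {
  std::vector<Op> ops;
  int n_par = 0;
};

struct Tape {
  std::vector<cx_mat> slots;  // slots[i] = input of op i; back() = output
};

// [[Rcpp::export]]
SEXP eng_compile(List ops, int n_par) {
  Program* prog = new Program();
  prog->n_par = n_par;
  for (R_xlen_t i = 0; i < ops.size(); ++i) {
    List o = ops[i];
    Op op;
    op.type = as<int>(o["type"]);
    switch (op.type) {
    case OP_PERM:
      op.p = as<uvec>(o["p"]);
      op.ip = as<uvec>(o["ip"]);
      break;
    case OP_MIX:
      op.partner = as<uvec>(o["partner"]);
      op.map = as<uvec>(o["map"]);
      op.sgn = as<vec>(o["sgn"]);
      op.ref = as<int>(o["ref"]);
      op.K = as<int>(o["K"]);
      break;
    case OP_DIAG:
      op.phi_ref = as<int>(o["phi_ref"]);
      op.gamma_ref = as<int>(o["gamma_ref"]);
      op.dsgn = as<double>(o["dsgn"]);
      break;
    case OP_LAM:
      op.re_ref = as<int>(o["re_ref"]);
      op.im_ref = as<int>(o["im_ref"]);
      break;
    default:
      stop("unknown op type");
    }
    prog->ops.push_back(op);
  }
  return XPtr<Program>(prog, true);
}

// [[Rcpp::export]]
SEXP eng_new_tape() {
  return XPtr<Tape>(new Tape(), true);
}

static inline const double* par_ptr(const List& pars, int ref, int* len = 0) {
  SEXP s = pars[ref];
  if (len) *len = (int)Rf_xlength(s);
  return REAL(s);
}

// multiplier of a diag op: exp(gamma + dsgn*1i*phi)
static void diag_mult(const List& pars, const Op& o, std::vector<cplx>& m) {
  int n = 0;
  const double* ga = par_ptr(pars, o.gamma_ref, &n);
  const double* ph = par_ptr(pars, o.phi_ref);
  m.resize(n);
  for (int i = 0; i < n; ++i)
    m[i] = std::exp(ga[i]) * cplx(std::cos(o.dsgn * ph[i]),
                                  std::sin(o.dsgn * ph[i]));
}

static void lam_mult(const List& pars, const Op& o, std::vector<cplx>& m) {
  int n = 0;
  const double* re = par_ptr(pars, o.re_ref, &n);
  const double* im = par_ptr(pars, o.im_ref);
  m.resize(n);
  for (int i = 0; i < n; ++i)
    m[i] = std::exp(re[i]) * cplx(std::cos(im[i]), std::sin(im[i]));
}

static void mix_trig(const List& pars, const Op& o, std::vector<double>& cs,
                     std::vector<double>& sn) {
  const double* raw = par_ptr(pars, o.ref);
  const arma::uword n = o.map.n_elem;
  cs.resize(n); sn.resize(n);
  for (arma::uword i = 0; i < n; ++i) {
    double t = raw[o.map[i]];
    cs[i] = std::cos(t); sn[i] = std::sin(t);
  }
}

struct Work {  // per-pass scratch, reused across ops
  std::vector<cplx> m;
  std::vector<double> cs, sn, dth;
};

// out = op(in); out must not alias in for perm/mix
static void op_fwd(const Op& o, const List& pars, Work& wk,
                   const cx_mat& in, cx_mat& out) {
  const arma::uword n = in.n_rows, p = in.n_cols;
  out.set_size(n, p);
  switch (o.type) {
  case OP_PERM:
    for (arma::uword j = 0; j < p; ++j) {
      const cplx* v = in.colptr(j); cplx* y = out.colptr(j);
      for (arma::uword i = 0; i < n; ++i) y[i] = v[o.p[i]];
    }
    break;
  case OP_MIX:
    mix_trig(pars, o, wk.cs, wk.sn);
    for (arma::uword j = 0; j < p; ++j) {
      const cplx* v = in.colptr(j); cplx* y = out.colptr(j);
      for (arma::uword i = 0; i < n; ++i)
        y[i] = (o.sgn[i] * wk.cs[i]) * v[i] + wk.sn[i] * v[o.partner[i]];
    }
    break;
  case OP_DIAG:
  case OP_LAM:
    if (o.type == OP_DIAG) diag_mult(pars, o, wk.m);
    else lam_mult(pars, o, wk.m);
    for (arma::uword j = 0; j < p; ++j) {
      const cplx* v = in.colptr(j); cplx* y = out.colptr(j);
      for (arma::uword i = 0; i < n; ++i) y[i] = wk.m[i] * v[i];
    }
    break;
  }
}

// [[Rcpp::export]]
arma::cx_mat eng_fwd(SEXP progp, List pars, arma::cx_mat V) {
  XPtr<Program> prog(progp);
  Work wk;
  cx_mat buf;
  for (const Op& o : prog->ops) {
    op_fwd(o, pars, wk, V, buf);
    V.swap(buf);
  }
  return V;
}

// Forward pass recording every op input into the (reused) tape; returns
// the output. The tape stays valid until the next eng_fwd_tape call on it.
// [[Rcpp::export]]
arma::cx_mat eng_fwd_tape(SEXP progp, List pars, arma::cx_mat V,
                          SEXP tapep) {
  XPtr<Program> prog(progp);
  XPtr<Tape> tape(tapep);
  const size_t n_ops = prog->ops.size();
  tape->slots.resize(n_ops + 1);
  Work wk;
  tape->slots[0] = std::move(V);
  for (size_t i = 0; i < n_ops; ++i)
    op_fwd(prog->ops[i], pars, wk, tape->slots[i], tape->slots[i + 1]);
  return tape->slots[n_ops];
}

// Reverse pass: returns list(grads, W): parameter gradients (slot order)
// and the back-propagated cotangent.
// [[Rcpp::export]]
List eng_vjp(SEXP progp, List pars, SEXP tapep, arma::cx_mat W) {
  XPtr<Program> prog(progp);
  XPtr<Tape> tape(tapep);
  if (tape->slots.size() != prog->ops.size() + 1)
    stop("tape does not match program (run eng_fwd_tape first)");
  std::vector<vec> grads(prog->n_par);
  for (int k = 0; k < prog->n_par; ++k) {
    int len = 0; par_ptr(pars, k, &len);
    grads[k] = vec(len, arma::fill::zeros);
  }
  Work wk;
  cx_mat buf;
  for (int idx = (int)prog->ops.size() - 1; idx >= 0; --idx) {
    const Op& o = prog->ops[idx];
    const cx_mat& Vin = tape->slots[idx];
    const cx_mat& Vout = tape->slots[idx + 1];
    const arma::uword n = W.n_rows, p = W.n_cols;
    switch (o.type) {
    case OP_PERM:
      buf.set_size(n, p);
      for (arma::uword j = 0; j < p; ++j) {
        const cplx* w = W.colptr(j); cplx* y = buf.colptr(j);
        for (arma::uword i = 0; i < n; ++i) y[i] = w[o.ip[i]];
      }
      W.swap(buf);
      break;
    case OP_MIX: {
      mix_trig(pars, o, wk.cs, wk.sn);
      double* g = grads[o.ref].memptr();
      buf.set_size(n, p);
      for (arma::uword j = 0; j < p; ++j) {
        const cplx* v = Vin.colptr(j);
        const cplx* w = W.colptr(j);
        cplx* y = buf.colptr(j);
        for (arma::uword i = 0; i < n; ++i) {
          // d out_i / d theta = -sgn*sin*v_i + cos*v_partner
          cplx dv = (-o.sgn[i] * wk.sn[i]) * v[i] +
            wk.cs[i] * v[o.partner[i]];
          g[o.map[i]] += dv.real() * w[i].real() + dv.imag() * w[i].imag();
          y[i] = (o.sgn[i] * wk.cs[i]) * w[i] + wk.sn[i] * w[o.partner[i]];
        }
      }
      W.swap(buf);
      break;
    }
    case OP_DIAG: {
      diag_mult(pars, o, wk.m);
      double* gga = grads[o.gamma_ref].memptr();
      double* gph = grads[o.phi_ref].memptr();
      for (arma::uword j = 0; j < p; ++j) {
        const cplx* out = Vout.colptr(j);
        cplx* w = W.colptr(j);
        for (arma::uword i = 0; i < n; ++i) {
          cplx cw = std::conj(out[i]) * w[i];
          gga[i] += cw.real();
          gph[i] += o.dsgn * cw.imag();
          w[i] *= std::conj(wk.m[i]);
        }
      }
      break;
    }
    case OP_LAM: {
      lam_mult(pars, o, wk.m);
      double* gre = grads[o.re_ref].memptr();
      double* gim = grads[o.im_ref].memptr();
      for (arma::uword j = 0; j < p; ++j) {
        const cplx* out = Vout.colptr(j);
        cplx* w = W.colptr(j);
        for (arma::uword i = 0; i < n; ++i) {
          cplx cw = std::conj(out[i]) * w[i];
          gre[i] += cw.real();
          gim[i] += cw.imag();
          w[i] *= std::conj(wk.m[i]);
        }
      }
      break;
    }
    }
  }
  List gl(prog->n_par);
  for (int k = 0; k < prog->n_par; ++k) gl[k] = wrap(grads[k]);
  return List::create(Named("grads") = gl, Named("W") = W);
}

// Forward-mode pass with full parameter tangents `dpars` (same slot order
// as `pars`), starting from input tangent dV.
// [[Rcpp::export]]
arma::cx_mat eng_jvp(SEXP progp, List pars, SEXP tapep, List dpars,
                     arma::cx_mat dV) {
  XPtr<Program> prog(progp);
  XPtr<Tape> tape(tapep);
  if (tape->slots.size() != prog->ops.size() + 1)
    stop("tape does not match program (run eng_fwd_tape first)");
  Work wk;
  cx_mat buf;
  for (size_t idx = 0; idx < prog->ops.size(); ++idx) {
    const Op& o = prog->ops[idx];
    const cx_mat& Vin = tape->slots[idx];
    const cx_mat& Vout = tape->slots[idx + 1];
    const arma::uword n = dV.n_rows, p = dV.n_cols;
    switch (o.type) {
    case OP_PERM:
      buf.set_size(n, p);
      for (arma::uword j = 0; j < p; ++j) {
        const cplx* v = dV.colptr(j); cplx* y = buf.colptr(j);
        for (arma::uword i = 0; i < n; ++i) y[i] = v[o.p[i]];
      }
      dV.swap(buf);
      break;
    case OP_MIX: {
      mix_trig(pars, o, wk.cs, wk.sn);
      const double* draw = par_ptr(dpars, o.ref);
      buf.set_size(n, p);
      for (arma::uword j = 0; j < p; ++j) {
        const cplx* v = Vin.colptr(j);
        const cplx* d = dV.colptr(j);
        cplx* y = buf.colptr(j);
        for (arma::uword i = 0; i < n; ++i) {
          double dth = draw[o.map[i]];
          y[i] = (o.sgn[i] * wk.cs[i]) * d[i] + wk.sn[i] * d[o.partner[i]] +
            ((-o.sgn[i] * wk.sn[i]) * v[i] + wk.cs[i] * v[o.partner[i]]) * dth;
        }
      }
      dV.swap(buf);
      break;
    }
    case OP_DIAG: {
      diag_mult(pars, o, wk.m);
      const double* dga = par_ptr(dpars, o.gamma_ref);
      const double* dph = par_ptr(dpars, o.phi_ref);
      for (arma::uword j = 0; j < p; ++j) {
        const cplx* out = Vout.colptr(j);
        cplx* d = dV.colptr(j);
        for (arma::uword i = 0; i < n; ++i)
          d[i] = wk.m[i] * d[i] + out[i] * cplx(dga[i], o.dsgn * dph[i]);
      }
      break;
    }
    case OP_LAM: {
      lam_mult(pars, o, wk.m);
      const double* dre = par_ptr(dpars, o.re_ref);
      const double* dim = par_ptr(dpars, o.im_ref);
      for (arma::uword j = 0; j < p; ++j) {
        const cplx* out = Vout.colptr(j);
        cplx* d = dV.colptr(j);
        for (arma::uword i = 0; i < n; ++i)
          d[i] = wk.m[i] * d[i] + out[i] * cplx(dre[i], dim[i]);
      }
      break;
    }
    }
  }
  return dV;
}

// Adjoint (conjugate transpose) application of the realized operator.
// [[Rcpp::export]]
arma::cx_mat eng_adjoint(SEXP progp, List pars, arma::cx_mat W) {
  XPtr<Program> prog(progp);
  Work wk;
  cx_mat buf;
  for (int idx = (int)prog->ops.size() - 1; idx >= 0; --idx) {
    const Op& o = prog->ops[idx];
    const arma::uword n = W.n_rows, p = W.n_cols;
    switch (o.type) {
    case OP_PERM:
      buf.set_size(n, p);
      for (arma::uword j = 0; j < p; ++j) {
        const cplx* w = W.colptr(j); cplx* y = buf.colptr(j);
        for (arma::uword i = 0; i < n; ++i) y[i] = w[o.ip[i]];
      }
      W.swap(buf);
      break;
    case OP_MIX: {
      mix_trig(pars, o, wk.cs, wk.sn);
      buf.set_size(n, p);
      for (arma::uword j = 0; j < p; ++j) {
        const cplx* w = W.colptr(j); cplx* y = buf.colptr(j);
        for (arma::uword i = 0; i < n; ++i)
          y[i] = (o.sgn[i] * wk.cs[i]) * w[i] + wk.sn[i] * w[o.partner[i]];
      }
      W.swap(buf);
      break;
    }
    case OP_DIAG:
    case OP_LAM: {
      if (o.type == OP_DIAG) diag_mult(pars, o, wk.m);
      else lam_mult(pars, o, wk.m);
      for (arma::uword j = 0; j < p; ++j) {
        cplx* w = W.colptr(j);
        for (arma::uword i = 0; i < n; ++i) w[i] *= std::conj(wk.m[i]);
      }
      break;
    }
    }
  }
  return W;
}
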