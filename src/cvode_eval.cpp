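#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

typedef std::complex<double> cplx;

// opcodes for the postfix expression programs (two ints per op: code, arg)
//   1 var(arg = 0-based gene index)   2 sin   3 cos
//   4 add   5 sub   6 mul   7 protected div
static const int OP_VAR = 1, OP_SIN = 2, OP_COS = 3,
                 OP_ADD = 4, OP_SUB = 5, OP_MUL = 6, OP_DIV = 7;

static inline cplx pdiv(const cplx& a, const cplx& b, double eps) {
  double m = std::abs(b);
  if (m >= eps) return a / b;
  if (m == 0.0) return a / eps;
  return a / (eps * (b / m));
}

static inline cplx from_r(const Rcomplex& z) { return cplx(z.r, z.i); }
static inline Rcomplex to_r(const cplx& z) {
  Rcomplex out; out.r = z.real(); out.i = z.imag(); return out;
}

static cplx eval_prog(const int* code, int len, const cplx* state, double eps,
                      std::vector<cplx>& stack) {
  stack.clear();
  for (int k = 0; k < len; k += 2) {
    const int op = code[k], arg = code[k + 1];
    switch (op) {
    case OP_VAR: stack.push_back(state[arg]); break;
    case OP_SIN: stack.back() = std::sin(stack.back()); break;
    case OP_COS: stack.back() = std::cos(stack.back()); break;
    case OP_ADD: { cplx b = stack.back(); stack.pop_back(); stack.back() += b; } break;
    case OP_SUB: { cplx b = stack.back(); stack.pop_back(); stack.back() -= b; } break;
    case OP_MUL: { cplx b = stack.back(); stack.pop_back(); stack.back() *= b; } break;
    case OP_DIV: { cplx b = stack.back(); stack.pop_back();
                   stack.back() = pdiv(stack.back(), b, eps); } break;
    default: stop("invalid opcode %d", op);
    }
    (void)arg;
  }
  if (stack.size() != 1) stop("malformed expression program");
  return stack.back();
}

// Evaluate every term program of one model at a single complex state.
// [[Rcpp::export]]
ComplexVector cpp_eval_terms(IntegerVector code, IntegerVector starts,
                             IntegerVector lens, ComplexVector state,
                             double eps) {
  const int nt = starts.size();
  std::vector<cplx> s(state.size());
  for (int i = 0; i < state.size(); ++i) s[i] = from_r(state[i]);
  std::vector<cplx> stack; stack.reserve(32);
  ComplexVector out(nt);
  for (int t = 0; t < nt; ++t)
    out[t] = to_r(eval_prog(&code[starts[t]], lens[t], s.data(), eps, stack));
  return out;
}

struct Model {
  std::vector<int> code;
  std::vector<int> starts, lens;
  std::vector<cplx> coefs;  // sign-folded coefficients
};

static inline cplx model_rhs(const Model& mod, const cplx* state, double eps,
                             std::vector<cplx>& stack) {
  cplx acc(0.0, 0.0);
  for (size_t t = 0; t < mod.starts.size(); ++t)
    acc += mod.coefs[t] *
           eval_prog(&mod.code[mod.starts[t]], mod.lens[t], state, eps, stack);
  return acc;
}

static Model make_model(IntegerVector code, IntegerVector starts,
                        IntegerVector lens, ComplexVector coefs) {
  Model mod;
  mod.code.assign(code.begin(), code.end());
  mod.starts.assign(starts.begin(), starts.end());
  mod.lens.assign(lens.begin(), lens.end());
  mod.coefs.resize(coefs.size());
  for (int i = 0; i < coefs.size(); ++i) mod.coefs[i] = from_r(coefs[i]);
  return mod;
}

// Decoupled RK4 integration of a single gene's model.  Non-target genes are
// read from `sgrid`, the data interpolated on the half-step stage grid:
// column k*2*substeps + 2*sub + {0,1,2} holds the state at stage times
// t_k + sub*h, +h/2, +h of substep `sub` in sample interval k.
// [[Rcpp::export]]
List cpp_rk4_decoupled(IntegerVector code, IntegerVector starts,
                       IntegerVector lens, ComplexVector coefs, int target,
                       ComplexMatrix sgrid, NumericVector hsub, int substeps,
                       Rcomplex z0, double eps, double div_limit) {
  const int m = sgrid.nrow();
  const int n_int = hsub.size();
  if (target < 0 || target >= m) stop("target index out of range");
  Model mod = make_model(code, starts, lens, coefs);
  std::vector<cplx> grid(static_cast<size_t>(m) * sgrid.ncol());
  for (int j = 0; j < sgrid.ncol(); ++j)
    for (int i = 0; i < m; ++i) grid[static_cast<size_t>(j) * m + i] = from_r(sgrid(i, j));
  std::vector<cplx> s(m), stack; stack.reserve(32);
  ComplexVector traj(n_int + 1);
  cplx z = from_r(z0);
  traj[0] = z0;
  bool diverged = false;
  for (int k = 0; k < n_int && !diverged; ++k) {
    const double h = hsub[k];
    for (int sub = 0; sub < substeps; ++sub) {
      const size_t c0 = (static_cast<size_t>(k) * substeps + sub) * 2;
      const cplx* s0 = &grid[c0 * m];
      const cplx* sh = &grid[(c0 + 1) * m];
      const cplx* s1 = &grid[(c0 + 2) * m];
      std::copy(s0, s0 + m, s.begin()); s[target] = z;
      cplx k1 = model_rhs(mod, s.data(), eps, stack);
      std::copy(sh, sh + m, s.begin()); s[target] = z + 0.5 * h * k1;
      cplx k2 = model_rhs(mod, s.data(), eps, stack);
      s[target] = z + 0.5 * h * k2;
      cplx k3 = model_rhs(mod, s.data(), eps, stack);
      std::copy(s1, s1 + m, s.begin()); s[target] = z + h * k3;
      cplx k4 = model_rhs(mod, s.data(), eps, stack);
      z += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      if (!std::isfinite(z.real()) || !std::isfinite(z.imag()) ||
          std::abs(z) > div_limit) { diverged = true; break; }
    }
    traj[k + 1] = diverged ? to_r(cplx(NA_REAL, NA_REAL)) : to_r(z);
    if (diverged)
      for (int kk = k + 1; kk <= n_int; ++kk)
        traj[kk] = to_r(cplx(NA_REAL, NA_REAL));
  }
  return List::create(_["traj"] = traj, _["diverged"] = diverged);
}

// Coupled RK4 integration of a full m-gene system on a uniform time grid.
// [[Rcpp::export]]
List cpp_rk4_coupled(List codes, List starts, List lens, List coefs,
                     ComplexVector z0, int n_points, double dt, int substeps,
                     double eps, double div_limit) {
  const int m = z0.size();
  std::vector<Model> mods(m);
  for (int i = 0; i < m; ++i)
    mods[i] = make_model(codes[i], starts[i], lens[i], coefs[i]);
  std::vector<cplx> z(m), k1(m), k2(m), k3(m), k4(m), tmp(m), stack;
  stack.reserve(32);
  for (int i = 0; i < m; ++i) z[i] = from_r(z0[i]);
  ComplexMatrix traj(m, n_points);
  for (int i = 0; i < m; ++i) traj(i, 0) = z0[i];
  const double h = dt / substeps;
  bool diverged = false;
  for (int p = 1; p < n_points && !diverged; ++p) {
    for (int sub = 0; sub < substeps; ++sub) {
      for (int i = 0; i < m; ++i) k1[i] = model_rhs(mods[i], z.data(), eps, stack);
      for (int i = 0; i < m; ++i) tmp[i] = z[i] + 0.5 * h * k1[i];
      for (int i = 0; i < m; ++i) k2[i] = model_rhs(mods[i], tmp.data(), eps, stack);
      for (int i = 0; i < m; ++i) tmp[i] = z[i] + 0.5 * h * k2[i];
      for (int i = 0; i < m; ++i) k3[i] = model_rhs(mods[i], tmp.data(), eps, stack);
      for (int i = 0; i < m; ++i) tmp[i] = z[i] + h * k3[i];
      for (int i = 0; i < m; ++i) k4[i] = model_rhs(mods[i], tmp.data(), eps, stack);
      for (int i = 0; i < m; ++i) {
        z[i] += (h / 6.0) * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
        if (!std::isfinite(z[i].real()) || !std::isfinite(z[i].imag()) ||
            std::abs(z[i]) > div_limit) diverged = true;
      }
      if (diverged) break;
    }
    for (int i = 0; i < m; ++i)
      traj(i, p) = diverged ? to_r(cplx(NA_REAL, NA_REAL)) : to_r(z[i]);
    if (diverged)
      for (int pp = p; pp < n_points; ++pp)
        for (int i = 0; i < m; ++i) traj(i, pp) = to_r(cplx(NA_REAL, NA_REAL));
  }
  return List::create(_["traj"] = traj, _["diverged"] = diverged);
}
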