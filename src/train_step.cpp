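// Fast single-precision training step: both GCN stacks, max readout,
// projection, the three MLP heads, the batch contrastive term and the full
// hand-derived backward pass, fused in one call per minibatch.
//
// This mirrors the reference R implementation (R/model.R, R/nn.R,
// R/contrastive.R) exactly, in float32 for speed; the test suite checks
// the two paths agree on losses and gradients. Single-threaded and
// deterministic given the per-step seed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;
using Rcpp::List;
using Rcpp::as;

namespace {

struct Csc {  // column-compressed sparse matrix (from a dgCMatrix)
  Rcpp::IntegerVector p, i;
  fvec x;
  int n = 0;
  bool empty = true;
};

Csc csc_from(const Rcpp::S4& m) {
  Csc A;
  A.p = m.slot("p");
  A.i = m.slot("i");
  A.x = conv_to<fvec>::from(as<vec>(m.slot("x")));
  A.n = as<Rcpp::IntegerVector>(m.slot("Dim"))[0];
  A.empty = false;
  return A;
}

// Y = A %*% X with A symmetric sparse, X dense.
fmat spmm(const Csc& A, const fmat& X) {
  fmat Y(A.n, X.n_cols, fill::zeros);
  const int ncol = (int)X.n_cols;
  for (int c = 0; c < ncol; ++c) {
    const float* xc = X.colptr(c);
    float* yc = Y.colptr(c);
    for (int j = 0; j < A.n; ++j) {
      const float xj = xc[j];
      for (int k = A.p[j]; k < A.p[j + 1]; ++k) yc[A.i[k]] += A.x[k] * xj;
    }
  }
  return Y;
}

std::vector<fmat> fmat_list(const List& xs) {
  std::vector<fmat> out;
  for (R_xlen_t k = 0; k < xs.size(); ++k) {
    out.push_back(conv_to<fmat>::from(as<mat>(xs[k])));
  }
  return out;
}

struct GcnCache {
  std::vector<fmat> M, G;  // per-layer input product and combined gradmask
  fmat H;
};

// gradmask = relu'(P) * inverted-dropout mask; H = P % gradmask.
void apply_mask(fmat& P, fmat& G, float dropout, bool training,
                std::mt19937_64& rng) {
  G.set_size(P.n_rows, P.n_cols);
  const uword n = P.n_elem;
  float* p = P.memptr();
  float* g = G.memptr();
  if (training && dropout > 0) {
    const float scale = 1.0f / (1.0f - dropout);
    std::uniform_real_distribution<float> U(0.0f, 1.0f);
    for (uword k = 0; k < n; ++k) {
      g[k] = (p[k] > 0 ? 1.0f : 0.0f) * (U(rng) >= dropout ? scale : 0.0f);
      p[k] *= g[k];
    }
  } else {
    for (uword k = 0; k < n; ++k) {
      g[k] = p[k] > 0 ? 1.0f : 0.0f;
      p[k] *= g[k];
    }
  }
}

GcnCache gcn_forward(const std::vector<fmat>& W, const Csc& A, const fmat& M1,
                     float dropout, bool training, std::mt19937_64& rng) {
  GcnCache c;
  const size_t L = W.size();
  fmat H;
  for (size_t l = 0; l < L; ++l) {
    fmat M = (l == 0) ? M1 : spmm(A, H);
    fmat P = M * W[l];
    fmat G;
    apply_mask(P, G, dropout, training, rng);
    H = P;  // P was modified in place to relu+dropout output
    c.M.push_back(std::move(M));
    c.G.push_back(std::move(G));
  }
  c.H = H;
  return c;
}

std::vector<fmat> gcn_backward(const std::vector<fmat>& W, const Csc& A,
                               const GcnCache& c, fmat dH) {
  const size_t L = W.size();
  std::vector<fmat> dW(L);
  for (size_t l = L; l-- > 0;) {
    fmat dP = dH % c.G[l];
    dW[l] = c.M[l].t() * dP;
    if (l > 0) dH = spmm(A, fmat(dP * W[l].t()));
  }
  return dW;
}

struct Mlp {
  fmat W1, W2;
  frowvec b1, b2;
};

Mlp mlp_from(const List& par) {
  Mlp m;
  m.W1 = conv_to<fmat>::from(as<mat>(par["W1"]));
  m.W2 = conv_to<fmat>::from(as<mat>(par["W2"]));
  m.b1 = conv_to<frowvec>::from(as<rowvec>(par["b1"]));
  m.b2 = conv_to<frowvec>::from(as<rowvec>(par["b2"]));
  return m;
}

struct MlpCache {
  fmat X, H1, G;
  fvec p;
};

MlpCache mlp_forward(const Mlp& m, const fmat& X, float dropout,
                     bool training, std::mt19937_64& rng) {
  MlpCache c;
  c.X = X;
  fmat P1 = X * m.W1;
  P1.each_row() += m.b1;
  apply_mask(P1, c.G, dropout, training, rng);
  c.H1 = P1;
  fmat logit = c.H1 * m.W2;
  logit.each_row() += m.b2;
  c.p = 1.0f / (1.0f + exp(-logit.col(0)));
  return c;
}

// dlogit: B-vector; fills grads, returns dX.
fmat mlp_backward(const Mlp& m, const MlpCache& c, const fvec& dlogit,
                  List& g) {
  fmat dl(dlogit);
  fmat dW2 = c.H1.t() * dl;
  frowvec db2 = sum(dl, 0);
  fmat dH1 = (dl * m.W2.t()) % c.G;
  fmat dW1 = c.X.t() * dH1;
  frowvec db1 = sum(dH1, 0);
  g["W1"] = Rcpp::wrap(conv_to<mat>::from(dW1));
  g["b1"] = Rcpp::wrap(conv_to<vec>::from(db1.t()));
  g["W2"] = Rcpp::wrap(conv_to<mat>::from(dW2));
  g["b2"] = Rcpp::wrap(conv_to<vec>::from(db2.t()));
  return dH1 * m.W1.t();
}

double bce(const fvec& p, const fvec& y) {
  fvec pc = clamp(p, 1e-7f, 1.0f - 1e-7f);
  return as_scalar(mean(-(y % log(pc) + (1.0f - y) % log(1.0f - pc))));
}

}  // namespace

// [[Rcpp::export(name = ".cpp_train_step")]]
List cpp_train_step(List batch, List params, List cfg, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  const bool use_sub = as<bool>(cfg["use_subgraph"]);
  const bool use_mol = as<bool>(cfg["use_molecular"]);
  const bool use_contr = as<bool>(cfg["use_contrastive"]);
  const bool training = as<bool>(cfg["training"]);
  const float dropout = training ? (float)as<double>(cfg["dropout"]) : 0.0f;
  const float tau = (float)as<double>(cfg["temperature"]);
  const bool as_printed =
      as<std::string>(cfg["contrastive_mode"]) == "as_printed";
  const float alpha = (float)as<double>(cfg["alpha"]);
  const float beta = (float)as<double>(cfg["beta"]);
  const float lambda = (float)as<double>(cfg["lambda"]);
  const float eta = (float)as<double>(cfg["eta"]);
  const bool both = use_sub && use_mol;

  const fvec y = conv_to<fvec>::from(as<vec>(batch["y"]));
  const int B = (int)y.n_elem;

  // ---- forward: subgraph stack -> Z_T, p_sub ----
  std::vector<fmat> subW, molW;
  Csc Asub, Amol;
  GcnCache csub, cmol;
  fmat Z_T;
  Mlp head_sub, head_const, head_joint;
  MlpCache hs, hc, hj;
  uvec virt_rows;
  if (use_sub) {
    List sb = batch["sub"];
    subW = fmat_list(as<List>(as<List>(params["sub"])["W"]));
    Asub = csc_from(as<Rcpp::S4>(sb["Ahat"]));
    fmat M1 = conv_to<fmat>::from(as<mat>(sb["M1"]));
    csub = gcn_forward(subW, Asub, M1, dropout, training, rng);
    virt_rows = as<uvec>(sb["virt_rows"]) - 1;
    Z_T = csub.H.rows(virt_rows);
    head_sub = mlp_from(as<List>(params["head_sub"]));
    hs = mlp_forward(head_sub, Z_T, dropout, training, rng);
  }

  // ---- forward: molecular stack -> Z_C, p_const ----
  fmat Z_C, R;
  umat amax;
  uvec offs, pi, pj;
  int U = 0;
  if (use_mol) {
    List mb = batch["mol"];
    molW = fmat_list(as<List>(as<List>(params["mol"])["W"]));
    Amol = csc_from(as<Rcpp::S4>(mb["Ahat"]));
    fmat M1 = conv_to<fmat>::from(as<mat>(mb["M1"]));
    cmol = gcn_forward(molW, Amol, M1, dropout, training, rng);
    offs = as<uvec>(mb["offs"]);  // length U+1, 0-based row offsets
    U = (int)offs.n_elem - 1;
    const int e = (int)cmol.H.n_cols;
    R.set_size(U, e);
    amax.set_size(U, e);
    for (int u = 0; u < U; ++u) {
      const fmat block = cmol.H.rows(offs[u], offs[u + 1] - 1);
      for (int c = 0; c < e; ++c) {
        uword w = block.col(c).index_max();
        R(u, c) = block(w, c);
        amax(u, c) = offs[u] + w;
      }
    }
    pi = as<uvec>(mb["pi"]) - 1;
    pj = as<uvec>(mb["pj"]) - 1;
    Z_C = join_rows(R.rows(pj), R.rows(pi));
    head_const = mlp_from(as<List>(params["head_const"]));
    hc = mlp_forward(head_const, Z_C, dropout, training, rng);
  }

  // ---- fusion + contrastive ----
  fmat projW;
  frowvec projb;
  fmat Zc_p, F;
  fmat Ut, Vt;  // row-normalized views
  fvec nt, nv;
  fmat S, E;
  fvec denom;
  double l_contr = 0;
  if (both) {
    List pr = params["proj"];
    projW = conv_to<fmat>::from(as<mat>(pr["W"]));
    projb = conv_to<frowvec>::from(as<rowvec>(pr["b"]));
    Zc_p = Z_C * projW;
    Zc_p.each_row() += projb;
    F = join_rows(join_rows(Zc_p + Z_T, Zc_p % Z_T), join_rows(Zc_p, Z_T));
    head_joint = mlp_from(as<List>(params["head_joint"]));
    hj = mlp_forward(head_joint, F, dropout, training, rng);
    if (use_contr && alpha > 0) {
      nt = sqrt(sum(square(Z_T), 1));
      nv = sqrt(sum(square(Zc_p), 1));
      nt = clamp(nt, 1e-12f, datum::inf);
      nv = clamp(nv, 1e-12f, datum::inf);
      Ut = Z_T.each_col() / nt;
      Vt = Zc_p.each_col() / nv;
      S = Ut * Vt.t();
      fvec mx = max(S, 1) / tau;
      E = exp(S / tau - repmat(mx, 1, B));
      fvec dE = E.diag();
      denom = sum(E, 1) + (as_printed ? (float)B * dE : fvec(B, fill::zeros));
      fvec li = -(S.diag() / tau - mx) + log(denom);
      l_contr = as_scalar(mean(conv_to<vec>::from(li)));
    }
  }

  const double l_sub = use_sub ? bce(hs.p, y) : 0.0;
  const double l_const = use_mol ? bce(hc.p, y) : 0.0;
  const double l_joint = both ? bce(hj.p, y) : 0.0;
  const double l_total =
      alpha * l_contr + beta * l_const + lambda * l_sub + eta * l_joint;

  // ---- backward ----
  List grads = List::create();
  fmat dZ_T, dZ_C;
  if (use_sub) dZ_T.zeros(B, Z_T.n_cols);
  if (use_mol) dZ_C.zeros(B, Z_C.n_cols);

  if (use_sub && lambda > 0) {
    List g = List::create();
    fvec dlog = lambda * (clamp(hs.p, 1e-7f, 1.0f - 1e-7f) - y) / (float)B;
    dZ_T += mlp_backward(head_sub, hs, dlog, g);
    grads["head_sub"] = g;
  }
  if (use_mol && beta > 0) {
    List g = List::create();
    fvec dlog = beta * (clamp(hc.p, 1e-7f, 1.0f - 1e-7f) - y) / (float)B;
    dZ_C += mlp_backward(head_const, hc, dlog, g);
    grads["head_const"] = g;
  }
  if (both) {
    fmat dZc_p(B, Zc_p.n_cols, fill::zeros);
    if (eta > 0) {
      List g = List::create();
      fvec dlog = eta * (clamp(hj.p, 1e-7f, 1.0f - 1e-7f) - y) / (float)B;
      fmat dF = mlp_backward(head_joint, hj, dlog, g);
      grads["head_joint"] = g;
      const uword e = Zc_p.n_cols;
      fmat d1 = dF.cols(0, e - 1);
      fmat d2 = dF.cols(e, 2 * e - 1);
      fmat d3 = dF.cols(2 * e, 3 * e - 1);
      fmat d4 = dF.cols(3 * e, 4 * e - 1);
      dZc_p += d1 + d2 % Z_T + d3;
      dZ_T += d1 + d2 % Zc_p + d4;
    }
    if (use_contr && alpha > 0) {
      fmat dS = E.each_col() / denom / tau;
      fvec extra = as_printed ? fvec((float)B * E.diag() / denom / tau)
                              : fvec(B, fill::zeros);
      dS.diag() += extra - 1.0f / tau;
      dS /= (float)B;
      fmat dU = dS * Vt;
      fmat dV = dS.t() * Ut;
      fmat gT = Ut;
      gT.each_col() %= fvec(sum(dU % Ut, 1));
      gT = dU - gT;
      gT.each_col() /= nt;
      fmat gC = Vt;
      gC.each_col() %= fvec(sum(dV % Vt, 1));
      gC = dV - gC;
      gC.each_col() /= nv;
      dZ_T += alpha * gT;
      dZc_p += alpha * gC;
    }
    grads["proj"] = List::create(
        Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(fmat(Z_C.t() * dZc_p))),
        Rcpp::Named("b") =
            Rcpp::wrap(conv_to<vec>::from(fvec(sum(dZc_p, 0).t()))));
    dZ_C += dZc_p * projW.t();
  }

  if (use_sub) {
    fmat dH(csub.H.n_rows, csub.H.n_cols, fill::zeros);
    dH.rows(virt_rows) = dZ_T;
    std::vector<fmat> dW = gcn_backward(subW, Asub, csub, std::move(dH));
    List wl(dW.size());
    for (size_t l = 0; l < dW.size(); ++l) {
      wl[l] = Rcpp::wrap(conv_to<mat>::from(dW[l]));
    }
    grads["sub"] = List::create(Rcpp::Named("W") = wl);
  }
  if (use_mol) {
    const uword e = R.n_cols;
    fmat dR(U, e, fill::zeros);
    for (int b = 0; b < B; ++b) {
      dR.row(pj[b]) += dZ_C.submat(b, 0, b, e - 1);
      dR.row(pi[b]) += dZ_C.submat(b, e, b, 2 * e - 1);
    }
    fmat dHm(cmol.H.n_rows, e, fill::zeros);
    for (int u = 0; u < U; ++u) {
      for (uword c = 0; c < e; ++c) dHm(amax(u, c), c) += dR(u, c);
    }
    std::vector<fmat> dW = gcn_backward(molW, Amol, cmol, std::move(dHm));
    List wl(dW.size());
    for (size_t l = 0; l < dW.size(); ++l) {
      wl[l] = Rcpp::wrap(conv_to<mat>::from(dW[l]));
    }
    grads["mol"] = List::create(Rcpp::Named("W") = wl);
  }

  return List::create(
      Rcpp::Named("losses") = List::create(
          Rcpp::Named("l_contr") = l_contr, Rcpp::Named("l_const") = l_const,
          Rcpp::Named("l_sub") = l_sub, Rcpp::Named("l_joint") = l_joint,
          Rcpp::Named("l_total") = l_total),
      Rcpp::Named("grads") = grads,
      Rcpp::Named("p") = List::create(
          Rcpp::Named("p_sub") =
              use_sub ? Rcpp::wrap(conv_to<vec>::from(hs.p)) : R_NilValue,
          Rcpp::Named("p_const") =
              use_mol ? Rcpp::wrap(conv_to<vec>::from(hc.p)) : R_NilValue,
          Rcpp::Named("p_ct") =
              both ? Rcpp::wrap(conv_to<vec>::from(hj.p)) : R_NilValue));
}
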