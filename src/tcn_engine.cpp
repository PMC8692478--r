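// Fast path for the temporal-convolution residual block.
//
// Batch layout matches the R engine: a (channels x T*B) matrix, columns
// grouped sample-major with time running fastest inside each sample, so a
// causal shift never crosses a sample boundary. The R implementations in
// R/nn.R are the reference; these kernels must agree with them exactly
// (dropout aside, whose masks are drawn from R's RNG stream in both paths
// but in a different order).

#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static std::vector<mat> as_taps(const List& W) {
  std::vector<mat> taps;
  taps.reserve(W.size());
  for (R_xlen_t i = 0; i < W.size(); ++i) taps.push_back(as<mat>(W[i]));
  return taps;
}

// Copy of X shifted s steps into the past within each sample block (left
// zero padding); lets every tap run as a single large GEMM.
static mat shift_copy(const mat& X, int s, int T, int B) {
  mat out(X.n_rows, X.n_cols, fill::zeros);
  if (s >= T) return out;
  for (int bb = 0; bb < B; ++bb) {
    const int c0 = bb * T;
    out.cols(c0 + s, c0 + T - 1) = X.cols(c0, c0 + T - 1 - s);
  }
  return out;
}

static mat conv_fwd(const mat& X, const std::vector<mat>& W, const vec& b,
                    int d, int T, int B) {
  mat out = W[0] * X;
  const int k = (int)W.size();
  for (int i = 1; i < k; ++i) {
    const int s = d * i;
    if (s >= T) continue;
    out += W[i] * shift_copy(X, s, T, B);
  }
  out.each_col() += b;
  return out;
}

static void conv_bwd(const mat& dOut, const mat& X, const std::vector<mat>& W,
                     int d, int T, int B, List& gW, vec& gb, mat& dX) {
  const int k = (int)W.size();
  gW = List(k);
  gW[0] = dOut * X.t();
  gb = sum(dOut, 1);
  dX = W[0].t() * dOut;
  for (int i = 1; i < k; ++i) {
    const int s = d * i;
    if (s >= T) { gW[i] = mat(W[i].n_rows, W[i].n_cols, fill::zeros); continue; }
    gW[i] = dOut * shift_copy(X, s, T, B).t();
    const mat P = W[i].t() * dOut; // scatter back: adjoint of the shift
    for (int bb = 0; bb < B; ++bb) {
      const int c0 = bb * T;
      dX.cols(c0, c0 + T - 1 - s) += P.cols(c0 + s, c0 + T - 1);
    }
  }
}

// Spatial dropout keep-mask: whole feature maps per sample, drawn from R's
// RNG so results are reproducible under set.seed().
static mat dropout_mask(int C, int B, double rate) {
  mat keep(C, B);
  const double inv = 1.0 / (1.0 - rate);
  for (int j = 0; j < B; ++j)
    for (int i = 0; i < C; ++i)
      keep(i, j) = (unif_rand() < 1.0 - rate) ? inv : 0.0;
  return keep;
}

static mat expand_mask(const mat& keep, int T) {
  mat full(keep.n_rows, keep.n_cols * T);
  for (uword j = 0; j < keep.n_cols; ++j)
    full.cols(j * T, (j + 1) * T - 1) = repmat(keep.col(j), 1, T);
  return full;
}

// [[Rcpp::export]]
List cpp_block_fwd(const arma::mat& X, const List& P, int d, int k_size,
                   double dropout, int T, int B, bool training,
                   bool keep_cache) {
  List c1 = P["c1"], c2 = P["c2"];
  std::vector<mat> W1 = as_taps(c1["W"]), W2 = as_taps(c2["W"]);
  vec b1 = as<vec>(c1["b"]), b2 = as<vec>(c2["b"]);

  mat Z1 = conv_fwd(X, W1, b1, d, T, B);
  mat M1 = conv_to<mat>::from(Z1 > 0.0);
  mat A1 = Z1 % M1;
  mat D1;
  const bool use_drop = training && dropout > 0.0;
  if (use_drop) {
    D1 = expand_mask(dropout_mask(A1.n_rows, B, dropout), T);
    A1 %= D1;
  }
  mat Z2 = conv_fwd(A1, W2, b2, d, T, B);
  mat M2 = conv_to<mat>::from(Z2 > 0.0);
  mat A2 = Z2 % M2;
  mat D2;
  if (use_drop) {
    D2 = expand_mask(dropout_mask(A2.n_rows, B, dropout), T);
    A2 %= D2;
  }
  mat out;
  if (P.containsElementNamed("proj")) {
    List pr = P["proj"];
    std::vector<mat> Wp = as_taps(pr["W"]);
    vec bp = as<vec>(pr["b"]);
    out = A2 + conv_fwd(X, Wp, bp, 1, T, B);
  } else {
    out = A2 + X;
  }
  List res = List::create(Named("out") = out);
  if (keep_cache) {
    List cache = List::create(Named("X") = X, Named("M1") = M1,
                              Named("A1") = A1, Named("M2") = M2);
    if (use_drop) { cache["D1"] = D1; cache["D2"] = D2; }
    res["cache"] = cache;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_block_bwd(const arma::mat& dOut, const List& P, const List& cache,
                   int d, int T, int B) {
  List c1 = P["c1"], c2 = P["c2"];
  std::vector<mat> W1 = as_taps(c1["W"]), W2 = as_taps(c2["W"]);
  const mat X = as<mat>(cache["X"]);
  const mat M1 = as<mat>(cache["M1"]);
  const mat A1 = as<mat>(cache["A1"]);
  const mat M2 = as<mat>(cache["M2"]);

  mat dA2 = dOut;
  if (cache.containsElementNamed("D2")) dA2 %= as<mat>(cache["D2"]);
  mat dZ2 = dA2 % M2;
  List gW2; vec gb2; mat dA1;
  conv_bwd(dZ2, A1, W2, d, T, B, gW2, gb2, dA1);
  if (cache.containsElementNamed("D1")) dA1 %= as<mat>(cache["D1"]);
  mat dZ1 = dA1 % M1;
  List gW1; vec gb1; mat dX;
  conv_bwd(dZ1, X, W1, d, T, B, gW1, gb1, dX);

  List grad;
  if (P.containsElementNamed("proj")) {
    List pr = P["proj"];
    std::vector<mat> Wp = as_taps(pr["W"]);
    List gWp; vec gbp; mat dXp;
    conv_bwd(dOut, X, Wp, 1, T, B, gWp, gbp, dXp);
    dX += dXp;
    grad = List::create(
      Named("c1") = List::create(Named("W") = gW1, Named("b") = gb1),
      Named("c2") = List::create(Named("W") = gW2, Named("b") = gb2),
      Named("proj") = List::create(Named("W") = gWp, Named("b") = gbp));
  } else {
    dX += dOut;
    grad = List::create(
      Named("c1") = List::create(Named("W") = gW1, Named("b") = gb1),
      Named("c2") = List::create(Named("W") = gW2, Named("b") = gb2));
  }
  return List::create(Named("grad") = grad, Named("dX") = dX);
}

// [[Rcpp::export]]
arma::mat cpp_conv1d_fwd(const arma::mat& X, const List& W,
                         const arma::vec& b, int d, int T, int B) {
  return conv_fwd(X, as_taps(W), b, d, T, B);
}

// ---------------------------------------------------------------------------
// Stack-level training path. One call runs a whole residual stack; the
// per-block activations live in a C++ cache handed back to R as an external
// pointer, so nothing is converted to R objects between forward and backward.

static mat gather_cols(const mat& X, const arma::ivec& map, int nIn, int nOut,
                       int B);

struct ConvP {
  std::vector<mat> W;
  vec b;
};

struct BlockP {
  ConvP c1, c2, proj;
  bool has_proj;
};

static ConvP parse_conv(const List& L) {
  ConvP c;
  c.W = as_taps(L["W"]);
  c.b = as<vec>(L["b"]);
  return c;
}

static BlockP parse_block(const List& P) {
  BlockP b;
  b.c1 = parse_conv(P["c1"]);
  b.c2 = parse_conv(P["c2"]);
  b.has_proj = P.containsElementNamed("proj");
  if (b.has_proj) b.proj = parse_conv(P["proj"]);
  return b;
}

struct BlockCache {
  mat X, M1, A1, M2, D1, D2;
  bool drop = false;
};

typedef std::vector<BlockCache> StackCache;

static void conv_bwd2(const mat& dOut, const mat& X, const ConvP& cp, int d,
                      int T, int B, List& gW, vec& gb, mat& dX, bool want_dX) {
  const int k = (int)cp.W.size();
  gW = List(k);
  gW[0] = dOut * X.t();
  gb = sum(dOut, 1);
  if (want_dX) dX = cp.W[0].t() * dOut;
  for (int i = 1; i < k; ++i) {
    const int s = d * i;
    if (s >= T) {
      gW[i] = mat(cp.W[i].n_rows, cp.W[i].n_cols, fill::zeros);
      continue;
    }
    gW[i] = dOut * shift_copy(X, s, T, B).t();
    if (want_dX) {
      const mat P = cp.W[i].t() * dOut;
      for (int bb = 0; bb < B; ++bb) {
        const int c0 = bb * T;
        dX.cols(c0, c0 + T - 1 - s) += P.cols(c0 + s, c0 + T - 1);
      }
    }
  }
}

static mat block_fwd2(const mat& X, const BlockP& P, int d, double dropout,
                      int T, int B, bool training, BlockCache* cache) {
  mat Z1 = conv_fwd(X, P.c1.W, P.c1.b, d, T, B);
  mat M1 = conv_to<mat>::from(Z1 > 0.0);
  mat A1 = Z1 % M1;
  const bool use_drop = training && dropout > 0.0;
  mat D1, D2;
  if (use_drop) {
    D1 = expand_mask(dropout_mask(A1.n_rows, B, dropout), T);
    A1 %= D1;
  }
  mat Z2 = conv_fwd(A1, P.c2.W, P.c2.b, d, T, B);
  mat M2 = conv_to<mat>::from(Z2 > 0.0);
  mat A2 = Z2 % M2;
  if (use_drop) {
    D2 = expand_mask(dropout_mask(A2.n_rows, B, dropout), T);
    A2 %= D2;
  }
  mat out = P.has_proj ? mat(A2 + conv_fwd(X, P.proj.W, P.proj.b, 1, T, B))
                       : mat(A2 + X);
  if (cache) {
    cache->X = X; cache->M1 = M1; cache->A1 = A1; cache->M2 = M2;
    cache->drop = use_drop;
    if (use_drop) { cache->D1 = D1; cache->D2 = D2; }
  }
  return out;
}

static List block_bwd2(mat& dOut, const BlockP& P, const BlockCache& c, int d,
                       int T, int B, bool want_dX) {
  mat dA2 = c.drop ? mat(dOut % c.D2) : dOut;
  mat dZ2 = dA2 % c.M2;
  List gW2; vec gb2; mat dA1;
  conv_bwd2(dZ2, c.A1, P.c2, d, T, B, gW2, gb2, dA1, true);
  if (c.drop) dA1 %= c.D1;
  mat dZ1 = dA1 % c.M1;
  List gW1; vec gb1; mat dX;
  conv_bwd2(dZ1, c.X, P.c1, d, T, B, gW1, gb1, dX, want_dX);
  List grad;
  if (P.has_proj) {
    List gWp; vec gbp; mat dXp;
    conv_bwd2(dOut, c.X, P.proj, 1, T, B, gWp, gbp, dXp, want_dX);
    if (want_dX) dX += dXp;
    grad = List::create(
      Named("c1") = List::create(Named("W") = gW1, Named("b") = gb1),
      Named("c2") = List::create(Named("W") = gW2, Named("b") = gb2),
      Named("proj") = List::create(Named("W") = gWp, Named("b") = gbp));
  } else {
    if (want_dX) dX += dOut;
    grad = List::create(
      Named("c1") = List::create(Named("W") = gW1, Named("b") = gb1),
      Named("c2") = List::create(Named("W") = gW2, Named("b") = gb2));
  }
  if (want_dX) dOut = dX;
  return grad;
}

// Dense stack (decoder). Returns out and, when caching, an XPtr cache.
// [[Rcpp::export]]
List cpp_dstack_fwd(const arma::mat& X, const List& blocks,
                    const IntegerVector& dils, double dropout, int T, int B,
                    bool training, bool keep_cache) {
  StackCache* sc = keep_cache ? new StackCache(blocks.size()) : nullptr;
  mat cur = X;
  for (R_xlen_t i = 0; i < blocks.size(); ++i) {
    BlockP P = parse_block(blocks[i]);
    cur = block_fwd2(cur, P, dils[i], dropout, T, B, training,
                     sc ? &(*sc)[i] : nullptr);
  }
  List res = List::create(Named("out") = cur);
  if (keep_cache) res["cache"] = XPtr<StackCache>(sc, true);
  return res;
}

// [[Rcpp::export]]
List cpp_dstack_bwd(const arma::mat& dOut, const List& blocks, SEXP cache,
                    const IntegerVector& dils, int T, int B, bool want_dX) {
  XPtr<StackCache> sc(cache);
  List grads(blocks.size());
  mat cur = dOut;
  for (R_xlen_t i = blocks.size() - 1; i >= 0; --i) {
    BlockP P = parse_block(blocks[i]);
    grads[i] = block_bwd2(cur, P, (*sc)[i], dils[i], T, B,
                          want_dX || i > 0);
  }
  List res = List::create(Named("grads") = grads);
  if (want_dX) res["dX"] = cur;
  return res;
}

// Pruned encoder stack: gathered-column blocks, one call per direction.

struct GBlockMaps {
  std::vector<arma::ivec> m1, m2;
  arma::ivec skip;
  int nL, nM, nN;
};

static GBlockMaps parse_maps(const List& m) {
  GBlockMaps g;
  List m1 = m["m1"], m2 = m["m2"];
  for (R_xlen_t i = 0; i < m1.size(); ++i) g.m1.push_back(as<arma::ivec>(m1[i]));
  for (R_xlen_t i = 0; i < m2.size(); ++i) g.m2.push_back(as<arma::ivec>(m2[i]));
  g.skip = as<arma::ivec>(m["skip"]);
  g.nL = as<int>(m["nL"]); g.nM = as<int>(m["nM"]); g.nN = as<int>(m["nN"]);
  return g;
}

static mat gconv_fwd2(const mat& X, const ConvP& cp,
                      const std::vector<arma::ivec>& maps, int nIn, int nOut,
                      int B) {
  mat out(cp.W[0].n_rows, (uword)(nOut * B), fill::zeros);
  for (size_t i = 0; i < cp.W.size(); ++i) {
    out += cp.W[i] * gather_cols(X, maps[i], nIn, nOut, B);
  }
  out.each_col() += cp.b;
  return out;
}

static void gconv_bwd2(const mat& dOut, const mat& X, const ConvP& cp,
                       const std::vector<arma::ivec>& maps, int nIn, int nOut,
                       int B, List& gW, vec& gb, mat& dX, bool want_dX) {
  const int k = (int)cp.W.size();
  gW = List(k);
  gb = sum(dOut, 1);
  if (want_dX) dX.zeros(X.n_rows, X.n_cols);
  for (int i = 0; i < k; ++i) {
    gW[i] = dOut * gather_cols(X, maps[i], nIn, nOut, B).t();
    if (want_dX) {
      const mat P = cp.W[i].t() * dOut;
      for (int bb = 0; bb < B; ++bb) {
        const int oi = bb * nIn, oo = bb * nOut;
        for (int j = 0; j < nOut; ++j)
          if (maps[i][j] > 0) dX.col(oi + maps[i][j] - 1) += P.col(oo + j);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_penc_fwd(const arma::mat& Xg, const List& blocks, const List& maps,
                  double dropout, int B, bool training, bool keep_cache) {
  StackCache* sc = keep_cache ? new StackCache(blocks.size()) : nullptr;
  mat cur = Xg;
  for (R_xlen_t i = 0; i < blocks.size(); ++i) {
    BlockP P = parse_block(blocks[i]);
    GBlockMaps g = parse_maps(maps[i]);
    BlockCache* c = sc ? &(*sc)[i] : nullptr;

    mat Z1 = gconv_fwd2(cur, P.c1, g.m1, g.nL, g.nM, B);
    mat M1 = conv_to<mat>::from(Z1 > 0.0);
    mat A1 = Z1 % M1;
    const bool use_drop = training && dropout > 0.0;
    mat D1, D2;
    if (use_drop) {
      D1 = expand_mask(dropout_mask(A1.n_rows, B, dropout), g.nM);
      A1 %= D1;
    }
    mat Z2 = gconv_fwd2(A1, P.c2, g.m2, g.nM, g.nN, B);
    mat M2 = conv_to<mat>::from(Z2 > 0.0);
    mat A2 = Z2 % M2;
    if (use_drop) {
      D2 = expand_mask(dropout_mask(A2.n_rows, B, dropout), g.nN);
      A2 %= D2;
    }
    mat out;
    if (P.has_proj) {
      std::vector<arma::ivec> smap(1, g.skip);
      out = A2 + gconv_fwd2(cur, P.proj, smap, g.nL, g.nN, B);
    } else {
      out = A2 + gather_cols(cur, g.skip, g.nL, g.nN, B);
    }
    if (c) {
      c->X = cur; c->M1 = M1; c->A1 = A1; c->M2 = M2; c->drop = use_drop;
      if (use_drop) { c->D1 = D1; c->D2 = D2; }
    }
    cur = out;
  }
  List res = List::create(Named("latent") = cur);
  if (keep_cache) res["cache"] = XPtr<StackCache>(sc, true);
  return res;
}

// [[Rcpp::export]]
List cpp_penc_bwd(const arma::mat& dLatent, const List& blocks, SEXP cache,
                  const List& maps, int B) {
  XPtr<StackCache> sc(cache);
  List grads(blocks.size());
  mat cur = dLatent;
  for (R_xlen_t i = blocks.size() - 1; i >= 0; --i) {
    BlockP P = parse_block(blocks[i]);
    GBlockMaps g = parse_maps(maps[i]);
    const BlockCache& c = (*sc)[i];
    const bool want_dX = i > 0;

    mat dA2 = c.drop ? mat(cur % c.D2) : cur;
    mat dZ2 = dA2 % c.M2;
    List gW2; vec gb2; mat dA1;
    gconv_bwd2(dZ2, c.A1, P.c2, g.m2, g.nM, g.nN, B, gW2, gb2, dA1, true);
    if (c.drop) dA1 %= c.D1;
    mat dZ1 = dA1 % c.M1;
    List gW1; vec gb1; mat dX;
    gconv_bwd2(dZ1, c.X, P.c1, g.m1, g.nL, g.nM, B, gW1, gb1, dX, want_dX);
    if (P.has_proj) {
      std::vector<arma::ivec> smap(1, g.skip);
      List gWp; vec gbp; mat dXp;
      gconv_bwd2(cur, c.X, P.proj, smap, g.nL, g.nN, B, gWp, gbp, dXp, want_dX);
      if (want_dX) dX += dXp;
      grads[i] = List::create(
        Named("c1") = List::create(Named("W") = gW1, Named("b") = gb1),
        Named("c2") = List::create(Named("W") = gW2, Named("b") = gb2),
        Named("proj") = List::create(Named("W") = gWp, Named("b") = gbp));
    } else {
      if (want_dX) {
        for (int bb = 0; bb < B; ++bb) {
          const int oi = bb * g.nL, oo = bb * g.nN;
          for (int j = 0; j < g.nN; ++j)
            if (g.skip[j] > 0) dX.col(oi + g.skip[j] - 1) += cur.col(oo + j);
        }
      }
      grads[i] = List::create(
        Named("c1") = List::create(Named("W") = gW1, Named("b") = gb1),
        Named("c2") = List::create(Named("W") = gW2, Named("b") = gb2));
    }
    if (want_dX) cur = dX;
  }
  return List::create(Named("grads") = grads);
}

// Fused in-place Adam update over the flat parameter vector. The caller owns
// the only references to theta/m/v (copies are taken before any aliasing).
// [[Rcpp::export]]
void cpp_adam_step(NumericVector theta, const NumericVector grad,
                   NumericVector m, NumericVector v, double lr, double beta1,
                   double beta2, double eps, int t) {
  const R_xlen_t n = theta.size();
  const double c1 = 1.0 - std::pow(beta1, t), c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = beta1 * m[i] + (1.0 - beta1) * grad[i];
    v[i] = beta2 * v[i] + (1.0 - beta2) * grad[i] * grad[i];
    theta[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

// ---------------------------------------------------------------------------
// Receptive-field-pruned encoder path.
//
// Only the encoder's final time step feeds the latent state, so each residual
// block needs outputs at a handful of columns. Blocks operate on gathered
// column sets; `map` vectors give, for each output column and filter tap, the
// 1-based position of the source column in the input set (0 = zero padding).
// Results are exactly those of the dense path restricted to the kept columns.

static mat gather_cols(const mat& X, const arma::ivec& map, int nIn, int nOut,
                       int B) {
  mat out(X.n_rows, (uword)(nOut * B), fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    const int oi = bb * nIn, oo = bb * nOut;
    for (int j = 0; j < nOut; ++j)
      if (map[j] > 0) out.col(oo + j) = X.col(oi + map[j] - 1);
  }
  return out;
}

static mat gconv_fwd(const mat& X, const std::vector<mat>& W, const vec& b,
                     const List& maps, int nIn, int nOut, int B) {
  mat out(W[0].n_rows, (uword)(nOut * B), fill::zeros);
  for (size_t i = 0; i < W.size(); ++i) {
    arma::ivec mp = as<arma::ivec>(maps[i]);
    out += W[i] * gather_cols(X, mp, nIn, nOut, B);
  }
  out.each_col() += b;
  return out;
}

static void gconv_bwd(const mat& dOut, const mat& X, const std::vector<mat>& W,
                      const List& maps, int nIn, int nOut, int B, List& gW,
                      vec& gb, mat& dX, bool want_dX) {
  const int k = (int)W.size();
  gW = List(k);
  gb = sum(dOut, 1);
  if (want_dX) dX.zeros(X.n_rows, X.n_cols);
  for (int i = 0; i < k; ++i) {
    arma::ivec mp = as<arma::ivec>(maps[i]);
    gW[i] = dOut * gather_cols(X, mp, nIn, nOut, B).t();
    if (want_dX) {
      const mat P = W[i].t() * dOut;
      for (int bb = 0; bb < B; ++bb) {
        const int oi = bb * nIn, oo = bb * nOut;
        for (int j = 0; j < nOut; ++j)
          if (mp[j] > 0) dX.col(oi + mp[j] - 1) += P.col(oo + j);
      }
    }
  }
}

// maps: list(m1 = list of k ivec (nL -> nM), m2 = list of k ivec (nM -> nN),
//            skip = ivec (positions of N inside L), nL, nM, nN)
// [[Rcpp::export]]
List cpp_pblock_fwd(const arma::mat& Xg, const List& P, const List& maps,
                    double dropout, int B, bool training, bool keep_cache) {
  const int nL = as<int>(maps["nL"]), nM = as<int>(maps["nM"]),
            nN = as<int>(maps["nN"]);
  List c1 = P["c1"], c2 = P["c2"];
  std::vector<mat> W1 = as_taps(c1["W"]), W2 = as_taps(c2["W"]);
  vec b1 = as<vec>(c1["b"]), b2 = as<vec>(c2["b"]);

  mat Z1 = gconv_fwd(Xg, W1, b1, maps["m1"], nL, nM, B);
  mat M1 = conv_to<mat>::from(Z1 > 0.0);
  mat A1 = Z1 % M1;
  mat D1;
  const bool use_drop = training && dropout > 0.0;
  if (use_drop) {
    D1 = expand_mask(dropout_mask(A1.n_rows, B, dropout), nM);
    A1 %= D1;
  }
  mat Z2 = gconv_fwd(A1, W2, b2, maps["m2"], nM, nN, B);
  mat M2 = conv_to<mat>::from(Z2 > 0.0);
  mat A2 = Z2 % M2;
  mat D2;
  if (use_drop) {
    D2 = expand_mask(dropout_mask(A2.n_rows, B, dropout), nN);
    A2 %= D2;
  }
  arma::ivec skip = as<arma::ivec>(maps["skip"]);
  mat out;
  if (P.containsElementNamed("proj")) {
    List pr = P["proj"];
    std::vector<mat> Wp = as_taps(pr["W"]);
    vec bp = as<vec>(pr["b"]);
    List smap = List::create(wrap(skip));
    out = A2 + gconv_fwd(Xg, Wp, bp, smap, nL, nN, B);
  } else {
    out = A2 + gather_cols(Xg, skip, nL, nN, B);
  }
  List res = List::create(Named("out") = out);
  if (keep_cache) {
    List cache = List::create(Named("X") = Xg, Named("M1") = M1,
                              Named("A1") = A1, Named("M2") = M2);
    if (use_drop) { cache["D1"] = D1; cache["D2"] = D2; }
    res["cache"] = cache;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_pblock_bwd(const arma::mat& dOut, const List& P, const List& cache,
                    const List& maps, int B, bool want_dX) {
  const int nL = as<int>(maps["nL"]), nM = as<int>(maps["nM"]),
            nN = as<int>(maps["nN"]);
  List c1 = P["c1"], c2 = P["c2"];
  std::vector<mat> W1 = as_taps(c1["W"]), W2 = as_taps(c2["W"]);
  const mat X = as<mat>(cache["X"]);
  const mat M1 = as<mat>(cache["M1"]);
  const mat A1 = as<mat>(cache["A1"]);
  const mat M2 = as<mat>(cache["M2"]);

  mat dA2 = dOut;
  if (cache.containsElementNamed("D2")) dA2 %= as<mat>(cache["D2"]);
  mat dZ2 = dA2 % M2;
  List gW2; vec gb2; mat dA1;
  gconv_bwd(dZ2, A1, W2, maps["m2"], nM, nN, B, gW2, gb2, dA1, true);
  if (cache.containsElementNamed("D1")) dA1 %= as<mat>(cache["D1"]);
  mat dZ1 = dA1 % M1;
  List gW1; vec gb1; mat dX;
  gconv_bwd(dZ1, X, W1, maps["m1"], nL, nM, B, gW1, gb1, dX, want_dX);

  arma::ivec skip = as<arma::ivec>(maps["skip"]);
  List grad;
  if (P.containsElementNamed("proj")) {
    List pr = P["proj"];
    std::vector<mat> Wp = as_taps(pr["W"]);
    List smap = List::create(wrap(skip));
    List gWp; vec gbp; mat dXp;
    gconv_bwd(dOut, X, Wp, smap, nL, nN, B, gWp, gbp, dXp, want_dX);
    if (want_dX) dX += dXp;
    grad = List::create(
      Named("c1") = List::create(Named("W") = gW1, Named("b") = gb1),
      Named("c2") = List::create(Named("W") = gW2, Named("b") = gb2),
      Named("proj") = List::create(Named("W") = gWp, Named("b") = gbp));
  } else {
    if (want_dX) {
      for (int bb = 0; bb < B; ++bb) {
        const int oi = bb * nL, oo = bb * nN;
        for (int j = 0; j < nN; ++j)
          if (skip[j] > 0) dX.col(oi + skip[j] - 1) += dOut.col(oo + j);
      }
    }
    grad = List::create(
      Named("c1") = List::create(Named("W") = gW1, Named("b") = gb1),
      Named("c2") = List::create(Named("W") = gW2, Named("b") = gb2));
  }
  List res = List::create(Named("grad") = grad);
  if (want_dX) res["dX"] = dX;
  return res;
}
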