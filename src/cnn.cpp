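// Compact CNN engine for the AlexNet-style CTC classifier: five "same"
// convolution layers (max-pooling after layers 1, 2 and 5) followed by
// three fully connected layers with a softmax output. Convolutions are
// im2col + gemm; the backward pass mirrors the forward exactly. All
// stochastic quantities (weights, batch order) are supplied from R, so the
// engine itself is deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

const int POOL_AFTER[5] = {1, 1, 0, 0, 1}; // pool after conv layers 1,2,5

struct Config {
  int S, C, k, act, reg, n_classes;
  arma::ivec filters;   // 5
  arma::ivec fc_sizes;  // 2 hidden FC widths
  double lambda;
};

Config read_config(const List& cfg) {
  Config c;
  c.S = as<int>(cfg["input_size"]);
  c.C = as<int>(cfg["n_channels"]);
  c.k = as<int>(cfg["filter_size"]);
  c.act = as<int>(cfg["act_code"]);
  c.reg = as<int>(cfg["reg_code"]);
  c.n_classes = as<int>(cfg["n_classes"]);
  c.lambda = as<double>(cfg["reg_factor"]);
  c.filters = as<arma::ivec>(cfg["filters"]);
  c.fc_sizes = as<arma::ivec>(cfg["fc_sizes"]);
  return c;
}

// col(ci*k*k + dy*k + dx, r*W + c) = A(ci, (r+dy-pad)*W + (c+dx-pad))
mat im2col(const mat& A, int H, int W, int k) {
  const int pad = (k - 1) / 2;
  const int Cin = A.n_rows;
  mat col(Cin * k * k, H * W, arma::fill::zeros);
  for (int dy = 0; dy < k; ++dy) {
    for (int dx = 0; dx < k; ++dx) {
      const int rowoff = dy * k + dx;
      for (int r = 0; r < H; ++r) {
        const int r2 = r + dy - pad;
        if (r2 < 0 || r2 >= H) continue;
        const int cmin = std::max(0, pad - dx);
        const int cmax = std::min(W - 1, W - 1 + pad - dx);
        if (cmin > cmax) continue;
        // contiguous run of columns
        for (int ci = 0; ci < Cin; ++ci) {
          const double* src = A.colptr(r2 * W + (cmin + dx - pad)) + ci;
          double* dst = col.colptr(r * W + cmin) + ci * k * k + rowoff;
          const int n = cmax - cmin + 1;
          const int srcstride = Cin, dststride = Cin * k * k;
          for (int t = 0; t < n; ++t)
            dst[t * dststride] = src[t * srcstride];
        }
      }
    }
  }
  return col;
}

// scatter-add transpose of im2col
void col2im_add(const mat& dcol, mat& dA, int H, int W, int k) {
  const int pad = (k - 1) / 2;
  const int Cin = dA.n_rows;
  for (int dy = 0; dy < k; ++dy) {
    for (int dx = 0; dx < k; ++dx) {
      const int rowoff = dy * k + dx;
      for (int r = 0; r < H; ++r) {
        const int r2 = r + dy - pad;
        if (r2 < 0 || r2 >= H) continue;
        const int cmin = std::max(0, pad - dx);
        const int cmax = std::min(W - 1, W - 1 + pad - dx);
        if (cmin > cmax) continue;
        for (int ci = 0; ci < Cin; ++ci) {
          const double* src = dcol.colptr(r * W + cmin) + ci * k * k + rowoff;
          double* dst = dA.colptr(r2 * W + (cmin + dx - pad)) + ci;
          const int n = cmax - cmin + 1;
          const int srcstride = Cin * k * k, dststride = Cin;
          for (int t = 0; t < n; ++t)
            dst[t * dststride] += src[t * srcstride];
        }
      }
    }
  }
}

void activate(mat& A, int act) {
  if (act == 0) {                         // ReLU
    A.for_each([](double& v) { if (v < 0) v = 0; });
  } else if (act == 1) {                  // tanh (in place: A may alias)
    A.for_each([](double& v) { v = std::tanh(v); });
  } else {                                // softmax across channels/units
    for (uword j = 0; j < A.n_cols; ++j) {
      vec z = A.col(j);
      z -= z.max();
      vec e = arma::exp(z);
      A.col(j) = e / arma::accu(e);
    }
  }
}

// dZ from dA given post-activation values A
mat activate_back(const mat& dA, const mat& A, int act) {
  if (act == 0) return dA % arma::conv_to<mat>::from(A > 0);
  if (act == 1) return dA % (1.0 - arma::square(A));
  mat dZ(arma::size(dA));
  for (uword j = 0; j < A.n_cols; ++j) {
    vec s = A.col(j), g = dA.col(j);
    dZ.col(j) = s % (g - arma::dot(g, s));
  }
  return dZ;
}

// 2x2 max pool, row-major positions; records argmax source positions.
mat pool2(const mat& A, int H, int W, arma::umat& arg) {
  const int H2 = H / 2, W2 = W / 2, F = A.n_rows;
  mat out(F, H2 * W2);
  arg.set_size(F, H2 * W2);
  for (int r = 0; r < H2; ++r) {
    for (int c = 0; c < W2; ++c) {
      const int q = r * W2 + c;
      const int p00 = (2 * r) * W + 2 * c;
      const int cand[4] = {p00, p00 + 1, p00 + W, p00 + W + 1};
      for (int f = 0; f < F; ++f) {
        double best = A(f, cand[0]);
        int bi = cand[0];
        for (int t = 1; t < 4; ++t)
          if (A(f, cand[t]) > best) { best = A(f, cand[t]); bi = cand[t]; }
        out(f, q) = best;
        arg(f, q) = bi;
      }
    }
  }
  return out;
}

mat pool2_back(const mat& dOut, const arma::umat& arg, int F, int HW) {
  mat dA(F, HW, arma::fill::zeros);
  for (uword q = 0; q < dOut.n_cols; ++q)
    for (int f = 0; f < F; ++f)
      dA(f, arg(f, q)) += dOut(f, q);
  return dA;
}

mat sample_to_mat(const NumericVector& x, int i, int S, int C) {
  mat A(C, S * S);
  const double* px = x.begin() + (R_xlen_t)i * S * S * C;
  // x dims: (row, col, channel); position p = r*S + c
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < S; ++c)
      for (int r = 0; r < S; ++r)
        A(ch, r * S + c) = px[r + S * (c + S * ch)];
  return A;
}

struct ForwardState {
  bool keep_cols = false;      // cache im2col results for the backward pass
  std::vector<mat> conv_in;    // post-pool input to each conv layer (5)
  std::vector<mat> conv_cols;  // im2col of conv_in (when keep_cols)
  std::vector<mat> conv_act;   // post-activation pre-pool maps (5)
  std::vector<arma::umat> poolarg; // for pooled layers (indexed by layer)
  std::vector<int> Hs;         // spatial size entering each conv layer
  vec flat;
  std::vector<vec> fc_act;     // post-activation fc outputs (2 hidden)
  vec probs;
};

void forward_one(const mat& A0, const std::vector<mat>& cw,
                 const std::vector<vec>& cb, const std::vector<mat>& fw,
                 const std::vector<vec>& fb, const Config& cfg,
                 ForwardState& st) {
  mat A = A0;
  int H = cfg.S;
  st.conv_in.resize(5); st.conv_act.resize(5); st.conv_cols.resize(5);
  st.poolarg.resize(5); st.Hs.resize(5);
  for (int l = 0; l < 5; ++l) {
    st.conv_in[l] = A;
    st.Hs[l] = H;
    mat col = im2col(A, H, H, cfg.k);
    mat Z = cw[l] * col;
    if (st.keep_cols) st.conv_cols[l] = std::move(col);
    Z.each_col() += cb[l];
    activate(Z, cfg.act);
    st.conv_act[l] = Z;
    if (POOL_AFTER[l]) {
      A = pool2(Z, H, H, st.poolarg[l]);
      H /= 2;
    } else A = Z;
  }
  st.flat = arma::vectorise(A);
  vec a = st.flat;
  st.fc_act.resize(2);
  for (int l = 0; l < 2; ++l) {
    vec z = fw[l] * a + fb[l];
    mat zm(z.memptr(), z.n_elem, 1, false);
    activate(zm, cfg.act);
    st.fc_act[l] = z;
    a = z;
  }
  vec z = fw[2] * a + fb[2];
  z -= z.max();
  vec e = arma::exp(z);
  st.probs = e / arma::accu(e);
}

void unpack_weights(const List& weights, std::vector<mat>& cw,
                    std::vector<vec>& cb, std::vector<mat>& fw,
                    std::vector<vec>& fb) {
  cw.resize(5); cb.resize(5); fw.resize(3); fb.resize(3);
  for (int l = 0; l < 5; ++l) {
    cw[l] = as<mat>(weights[2 * l]);
    cb[l] = as<vec>(weights[2 * l + 1]);
  }
  for (int l = 0; l < 3; ++l) {
    fw[l] = as<mat>(weights[10 + 2 * l]);
    fb[l] = as<vec>(weights[10 + 2 * l + 1]);
  }
}

} // namespace

// [[Rcpp::export(name = ".cnn_forward")]]
NumericMatrix cnn_forward(const List& weights, const NumericVector& x,
                          const List& cfg_list) {
  Config cfg = read_config(cfg_list);
  IntegerVector dims = x.attr("dim");
  const int N = dims[3];
  std::vector<mat> cw, fw; std::vector<vec> cb, fb;
  unpack_weights(weights, cw, cb, fw, fb);
  NumericMatrix out(N, cfg.n_classes);
  ForwardState st;
  for (int i = 0; i < N; ++i) {
    mat A0 = sample_to_mat(x, i, cfg.S, cfg.C);
    forward_one(A0, cw, cb, fw, fb, cfg, st);
    for (int j = 0; j < cfg.n_classes; ++j) out(i, j) = st.probs(j);
  }
  return out;
}

// Mean cross-entropy loss + kernel regularization on the FC layers, with
// gradients for every weight. y is 0-based class index.
// [[Rcpp::export(name = ".cnn_batch_grad")]]
List cnn_batch_grad(const List& weights, const NumericVector& x,
                    const IntegerVector& y, const List& cfg_list) {
  Config cfg = read_config(cfg_list);
  IntegerVector dims = x.attr("dim");
  const int N = dims[3];
  std::vector<mat> cw, fw; std::vector<vec> cb, fb;
  unpack_weights(weights, cw, cb, fw, fb);
  std::vector<mat> dcw(5), dfw(3);
  std::vector<vec> dcb(5), dfb(3);
  for (int l = 0; l < 5; ++l) {
    dcw[l].zeros(arma::size(cw[l]));
    dcb[l].zeros(cb[l].n_elem);
  }
  for (int l = 0; l < 3; ++l) {
    dfw[l].zeros(arma::size(fw[l]));
    dfb[l].zeros(fb[l].n_elem);
  }
  double loss = 0;
  NumericMatrix probs(N, cfg.n_classes);
  ForwardState st;
  st.keep_cols = true;
  for (int i = 0; i < N; ++i) {
    mat A0 = sample_to_mat(x, i, cfg.S, cfg.C);
    forward_one(A0, cw, cb, fw, fb, cfg, st);
    for (int j = 0; j < cfg.n_classes; ++j) probs(i, j) = st.probs(j);
    loss += -std::log(std::max(st.probs(y[i]), 1e-12));
    // output layer: dz = p - onehot(y)
    vec dz = st.probs;
    dz(y[i]) -= 1.0;
    vec a_prev = st.fc_act[1];
    dfw[2] += dz * a_prev.t();
    dfb[2] += dz;
    vec da = fw[2].t() * dz;
    for (int l = 1; l >= 0; --l) {
      const vec& a = st.fc_act[l];
      mat dam(da.memptr(), da.n_elem, 1, false);
      mat am(const_cast<double*>(a.memptr()), a.n_elem, 1, false);
      vec dzl = activate_back(dam, am, cfg.act);
      const vec& in = (l == 0) ? st.flat : st.fc_act[0];
      dfw[l] += dzl * in.t();
      dfb[l] += dzl;
      da = fw[l].t() * dzl;
    }
    // reshape flat gradient back to (f5, P)
    const int F5 = cfg.filters(4);
    mat dA(da.memptr(), F5, da.n_elem / F5);
    mat dAl = dA;
    for (int l = 4; l >= 0; --l) {
      int H = st.Hs[l];
      mat dZ;
      if (POOL_AFTER[l]) {
        mat dPre = pool2_back(dAl, st.poolarg[l], st.conv_act[l].n_rows,
                              H * H);
        dZ = activate_back(dPre, st.conv_act[l], cfg.act);
      } else {
        dZ = activate_back(dAl, st.conv_act[l], cfg.act);
      }
      dcw[l] += dZ * st.conv_cols[l].t();
      dcb[l] += arma::sum(dZ, 1);
      if (l > 0) {
        mat dcol = cw[l].t() * dZ;
        mat dPrev(st.conv_in[l].n_rows, H * H, arma::fill::zeros);
        col2im_add(dcol, dPrev, H, H, cfg.k);
        dAl = dPrev;
      }
    }
  }
  loss /= N;
  for (int l = 0; l < 5; ++l) { dcw[l] /= N; dcb[l] /= N; }
  for (int l = 0; l < 3; ++l) { dfw[l] /= N; dfb[l] /= N; }
  // kernel regularizer on the fully connected layers; the penalty is per
  // weight (mean, not sum), so one factor is comparable across layers of
  // very different sizes
  for (int l = 0; l < 3; ++l) {
    const double nel = (double)fw[l].n_elem;
    if (cfg.reg == 0) {           // l1
      loss += cfg.lambda * arma::accu(arma::abs(fw[l])) / nel;
      dfw[l] += cfg.lambda * arma::sign(fw[l]) / nel;
    } else {                      // l2
      loss += cfg.lambda * arma::accu(arma::square(fw[l])) / nel;
      dfw[l] += 2.0 * cfg.lambda * fw[l] / nel;
    }
  }
  List grads(16);
  for (int l = 0; l < 5; ++l) {
    grads[2 * l] = dcw[l];
    grads[2 * l + 1] = dcb[l];
  }
  for (int l = 0; l < 3; ++l) {
    grads[10 + 2 * l] = dfw[l];
    grads[10 + 2 * l + 1] = dfb[l];
  }
  return List::create(_["loss"] = loss, _["grads"] = grads,
                      _["probs"] = probs);
}
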