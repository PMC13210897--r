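// 1D U-Net engine: float GEMM (im2col) convolutions, batch norm, max
// pooling, transposed-conv upsampling, softmax head, class-weighted
// cross-entropy and Adam. Activations are (channels x batch*length)
// matrices with samples laid out contiguously along columns; all
// lengths within a layer are uniform across the batch.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static fmat im2col(const fmat& X, int B, int L, int K, int padL) {
  const int C = X.n_rows;
  fmat col(C * K, (size_t)B * L, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < K; ++k) {
      int shift = k - padL;                 // input index = t + shift
      int t0 = std::max(0, -shift), t1 = std::min(L, L - shift);
      if (t1 <= t0) continue;
      col.submat(k * C, (size_t)b * L + t0, k * C + C - 1,
                 (size_t)b * L + t1 - 1) =
        X.submat(0, (size_t)b * L + t0 + shift, C - 1,
                 (size_t)b * L + t1 - 1 + shift);
    }
  }
  return col;
}

static fmat col2im(const fmat& dcol, int B, int L, int K, int padL, int C) {
  fmat dX(C, (size_t)B * L, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < K; ++k) {
      int shift = k - padL;
      int t0 = std::max(0, -shift), t1 = std::min(L, L - shift);
      if (t1 <= t0) continue;
      dX.submat(0, (size_t)b * L + t0 + shift, C - 1,
                (size_t)b * L + t1 - 1 + shift) +=
        dcol.submat(k * C, (size_t)b * L + t0, k * C + C - 1,
                    (size_t)b * L + t1 - 1);
    }
  }
  return dX;
}

struct Adam {
  fmat mW, vW; fvec mb, vb;
  void init(const fmat& W, const fvec& b) {
    mW.zeros(W.n_rows, W.n_cols); vW.zeros(W.n_rows, W.n_cols);
    mb.zeros(b.n_elem); vb.zeros(b.n_elem);
  }
};

static void adamStep(fmat& W, fmat& m, fmat& v, const fmat& g,
                     float lr, float bc1, float bc2) {
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * square(g);
  W -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8f);
}
static void adamStep(fvec& W, fvec& m, fvec& v, const fvec& g,
                     float lr, float bc1, float bc2) {
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * square(g);
  W -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8f);
}

struct Conv {
  int Cin, Cout, K, padL;
  fmat W; fvec b;       // W: (Cout, Cin*K)
  fmat dW; fvec db;
  Adam opt;
  fmat in;              // cached input (training)

  void init(int cin, int cout, int k, std::mt19937& rng) {
    Cin = cin; Cout = cout; K = k; padL = (k - 1) / 2;
    std::normal_distribution<float> nd(0.f, std::sqrt(2.f / (cin * k)));
    W.set_size(cout, (size_t)cin * k);
    for (auto& w : W) w = nd(rng);
    b.zeros(cout);
    opt.init(W, b);
  }
  fmat forward(const fmat& X, int B, int L, bool train) {
    if (train) in = X;
    fmat col = im2col(X, B, L, K, padL);
    fmat Y = W * col;
    Y.each_col() += b;
    return Y;
  }
  fmat backward(const fmat& dY, int B, int L) {
    fmat col = im2col(in, B, L, K, padL);
    dW = dY * col.t();
    db = sum(dY, 1);
    fmat dcol = W.t() * dY;
    return col2im(dcol, B, L, K, padL, Cin);
  }
  void step(float lr, float bc1, float bc2) {
    adamStep(W, opt.mW, opt.vW, dW, lr, bc1, bc2);
    adamStep(b, opt.mb, opt.vb, db, lr, bc1, bc2);
  }
};

struct BatchNorm {
  int C;
  fvec gamma, beta, rmean, rvar;
  fvec dgamma, dbeta;
  Adam opt;
  fmat xhat; fvec invstd;
  static constexpr float eps = 1e-5f, mom = 0.1f;

  void init(int c) {
    C = c;
    gamma.ones(c); beta.zeros(c); rmean.zeros(c); rvar.ones(c);
    opt.init(fmat(gamma), beta);   // reuse Adam for (gamma, beta)
  }
  fmat forward(const fmat& X, bool train) {
    if (train) {
      fvec mu = mean(X, 1);
      fmat Xc = X.each_col() - mu;
      fvec var = mean(square(Xc), 1);
      invstd = 1.f / sqrt(var + eps);
      xhat = Xc.each_col() % invstd;
      rmean = (1 - mom) * rmean + mom * mu;
      rvar = (1 - mom) * rvar + mom * var;
      fmat Y = xhat.each_col() % gamma;
      Y.each_col() += beta;
      return Y;
    }
    fvec is = 1.f / sqrt(rvar + eps);
    fmat Y = (X.each_col() - rmean);
    Y.each_col() %= (gamma % is);
    Y.each_col() += beta;
    return Y;
  }
  fmat backward(const fmat& dY) {
    const float N = (float)dY.n_cols;
    dgamma = sum(dY % xhat, 1);
    dbeta = sum(dY, 1);
    fmat dX = dY.each_col() % gamma;
    fvec m1 = sum(dX, 1) / N;
    fvec m2 = sum(dX % xhat, 1) / N;
    dX.each_col() -= m1;
    dX -= xhat.each_col() % m2;
    dX.each_col() %= invstd;
    return dX;
  }
  void step(float lr, float bc1, float bc2) {
    fmat g(gamma), dg(dgamma);
    adamStep(g, opt.mW, opt.vW, dg, lr, bc1, bc2);
    gamma = g.col(0);
    adamStep(beta, opt.mb, opt.vb, dbeta, lr, bc1, bc2);
  }
};

struct ConvBlock {       // conv -> BN -> ReLU
  Conv conv; BatchNorm bn;
  fmat act;              // post-ReLU activation (for ReLU backward)
  void init(int cin, int cout, int k, std::mt19937& rng) {
    conv.init(cin, cout, k, rng); bn.init(cout);
  }
  fmat forward(const fmat& X, int B, int L, bool train) {
    fmat Y = bn.forward(conv.forward(X, B, L, train), train);
    Y.transform([](float v) { return v > 0.f ? v : 0.f; });
    if (train) act = Y;
    return Y;
  }
  fmat backward(fmat dY, int B, int L) {
    dY.elem(find(act <= 0.f)).zeros();
    return conv.backward(bn.backward(dY), B, L);
  }
  void step(float lr, float b1, float b2) {
    conv.step(lr, b1, b2); bn.step(lr, b1, b2);
  }
};

struct UpConv {          // transposed conv, kernel 2, stride 2
  int Cin, Cout;
  fmat W0, W1; fvec b;   // phase weights (Cout, Cin)
  fmat dW0, dW1; fvec db;
  Adam opt0, opt1;
  fmat in;
  void init(int cin, int cout, std::mt19937& rng) {
    Cin = cin; Cout = cout;
    std::normal_distribution<float> nd(0.f, std::sqrt(2.f / (cin * 2)));
    W0.set_size(cout, cin); W1.set_size(cout, cin);
    for (auto& w : W0) w = nd(rng);
    for (auto& w : W1) w = nd(rng);
    b.zeros(cout);
    opt0.init(W0, b); opt1.init(W1, b);
  }
  fmat forward(const fmat& X, int B, int L, bool train) {
    if (train) in = X;
    fmat Y0 = W0 * X, Y1 = W1 * X;
    fmat Y(Cout, (size_t)B * L * 2);
    for (size_t t = 0; t < (size_t)B * L; ++t) {
      Y.col(2 * t) = Y0.col(t);
      Y.col(2 * t + 1) = Y1.col(t);
    }
    Y.each_col() += b;
    return Y;
  }
  fmat backward(const fmat& dY, int B, int L) {
    fmat d0(Cout, (size_t)B * L), d1(Cout, (size_t)B * L);
    for (size_t t = 0; t < (size_t)B * L; ++t) {
      d0.col(t) = dY.col(2 * t);
      d1.col(t) = dY.col(2 * t + 1);
    }
    dW0 = d0 * in.t(); dW1 = d1 * in.t();
    db = sum(dY, 1);
    return W0.t() * d0 + W1.t() * d1;
  }
  void step(float lr, float bc1, float bc2) {
    adamStep(W0, opt0.mW, opt0.vW, dW0, lr, bc1, bc2);
    adamStep(W1, opt1.mW, opt1.vW, dW1, lr, bc1, bc2);
    adamStep(b, opt0.mb, opt0.vb, db, lr, bc1, bc2);
  }
};

struct MaxPool {         // width 2, stride 2
  uvec arg;              // chosen input column per output column
  fmat forward(const fmat& X, int B, int L, bool train) {
    const int C = X.n_rows;
    fmat Y(C, (size_t)B * L / 2);
    if (train) arg.set_size((size_t)C * B * L / 2);
    for (size_t t = 0; t < (size_t)B * L / 2; ++t) {
      for (int c = 0; c < C; ++c) {
        float a = X(c, 2 * t), bv = X(c, 2 * t + 1);
        if (a >= bv) { Y(c, t) = a; if (train) arg((size_t)t * C + c) = 2 * t; }
        else { Y(c, t) = bv; if (train) arg((size_t)t * C + c) = 2 * t + 1; }
      }
    }
    return Y;
  }
  fmat backward(const fmat& dY, int B, int L) {
    const int C = dY.n_rows;
    fmat dX(C, (size_t)B * L, fill::zeros);
    for (size_t t = 0; t < dY.n_cols; ++t)
      for (int c = 0; c < C; ++c)
        dX(c, arg((size_t)t * C + c)) += dY(c, t);
    return dX;
  }
};

struct UNet {
  int depth, F0, K, Cin, classes;
  std::vector<ConvBlock> enc1, enc2, dec1, dec2;
  std::vector<UpConv> up;
  std::vector<MaxPool> pool;
  ConvBlock bridge1, bridge2;
  Conv head;             // kernel-1 per-sample linear map
  int adam_t = 0;

  // caches for backward
  std::vector<fmat> skips;
  fmat probs; ivec labels_cache;

  void init(int depth_, int F0_, int K_, int Cin_, int classes_,
            unsigned seed) {
    depth = depth_; F0 = F0_; K = K_; Cin = Cin_; classes = classes_;
    std::mt19937 rng(seed);
    enc1.resize(depth); enc2.resize(depth);
    dec1.resize(depth); dec2.resize(depth);
    up.resize(depth); pool.resize(depth);
    int cin = Cin;
    for (int s = 0; s < depth; ++s) {
      int f = F0 << s;
      enc1[s].init(cin, f, K, rng);
      enc2[s].init(f, f, K, rng);
      cin = f;
    }
    int fb = F0 << depth;
    bridge1.init(cin, fb, K, rng);
    bridge2.init(fb, fb, K, rng);
    for (int s = depth - 1; s >= 0; --s) {
      int f = F0 << s;
      up[s].init(f * 2, f, rng);
      dec1[s].init(f * 2, f, K, rng);
      dec2[s].init(f, f, K, rng);
    }
    head.init(F0, classes, 1, rng);
  }

  // forward to per-sample class probabilities (classes x B*L)
  fmat forward(const fmat& X, int B, int L, bool train) {
    skips.assign(depth, fmat());
    fmat h = X;
    int len = L;
    for (int s = 0; s < depth; ++s) {
      h = enc1[s].forward(h, B, len, train);
      h = enc2[s].forward(h, B, len, train);
      skips[s] = h;
      h = pool[s].forward(h, B, len, train);
      len /= 2;
    }
    h = bridge1.forward(h, B, len, train);
    h = bridge2.forward(h, B, len, train);
    for (int s = depth - 1; s >= 0; --s) {
      h = up[s].forward(h, B, len, train);
      len *= 2;
      h = join_cols(skips[s], h);
      h = dec1[s].forward(h, B, len, train);
      h = dec2[s].forward(h, B, len, train);
    }
    fmat logits = head.forward(h, B, len, train);
    logits.each_row() -= max(logits, 0);
    fmat e = exp(logits);
    fmat p = e.each_row() / sum(e, 0);
    return p;
  }

  // weighted cross-entropy on cached probabilities
  double loss(const fmat& p, const ivec& y, const fvec& w) {
    double num = 0, den = 0;
    for (size_t i = 0; i < y.n_elem; ++i) {
      float wi = w(y(i));
      num -= wi * std::log(std::max(p(y(i), i), 1e-12f));
      den += wi;
    }
    return num / den;
  }

  double trainBatch(const fmat& X, const ivec& y, const fvec& w,
                    int B, int L, float lr) {
    fmat p = forward(X, B, L, true);
    double lo = loss(p, y, w);
    // gradient of weighted CE wrt logits
    double den = 0;
    for (size_t i = 0; i < y.n_elem; ++i) den += w(y(i));
    fmat dlog = p;
    for (size_t i = 0; i < y.n_elem; ++i) {
      dlog(y(i), i) -= 1.f;
      dlog.col(i) *= (float)(w(y(i)) / den);
    }
    backward(dlog, B, L);
    ++adam_t;
    float bc1 = 1.f - std::pow(0.9f, (float)adam_t);
    float bc2 = 1.f - std::pow(0.999f, (float)adam_t);
    step(lr, bc1, bc2);
    return lo;
  }

  void backward(const fmat& dlogits, int B, int L) {
    int len = L;
    fmat d = head.backward(dlogits, B, len);
    std::vector<fmat> dskips(depth);
    for (int s = 0; s < depth; ++s) {
      d = dec2[s].backward(d, B, len);
      d = dec1[s].backward(d, B, len);
      int f = F0 << s;
      dskips[s] = d.rows(0, f - 1);
      d = up[s].backward(d.rows(f, 2 * f - 1), B, len / 2);
      len /= 2;
    }
    d = bridge2.backward(d, B, len);
    d = bridge1.backward(d, B, len);
    for (int s = depth - 1; s >= 0; --s) {
      len *= 2;                       // un-pooled length at this stage
      d = pool[s].backward(d, B, len);
      d += dskips[s];
      d = enc2[s].backward(d, B, len);
      d = enc1[s].backward(d, B, len);
    }
  }

  void step(float lr, float b1, float b2) {
    for (int s = 0; s < depth; ++s) {
      enc1[s].step(lr, b1, b2); enc2[s].step(lr, b1, b2);
      dec1[s].step(lr, b1, b2); dec2[s].step(lr, b1, b2);
      up[s].step(lr, b1, b2);
    }
    bridge1.step(lr, b1, b2); bridge2.step(lr, b1, b2);
    head.step(lr, b1, b2);
  }

  void collect(std::vector<fmat*>& Ws, std::vector<fvec*>& vs) {
    for (int s = 0; s < depth; ++s) {
      Ws.push_back(&enc1[s].conv.W); vs.push_back(&enc1[s].conv.b);
      vs.push_back(&enc1[s].bn.gamma); vs.push_back(&enc1[s].bn.beta);
      vs.push_back(&enc1[s].bn.rmean); vs.push_back(&enc1[s].bn.rvar);
      Ws.push_back(&enc2[s].conv.W); vs.push_back(&enc2[s].conv.b);
      vs.push_back(&enc2[s].bn.gamma); vs.push_back(&enc2[s].bn.beta);
      vs.push_back(&enc2[s].bn.rmean); vs.push_back(&enc2[s].bn.rvar);
    }
    Ws.push_back(&bridge1.conv.W); vs.push_back(&bridge1.conv.b);
    vs.push_back(&bridge1.bn.gamma); vs.push_back(&bridge1.bn.beta);
    vs.push_back(&bridge1.bn.rmean); vs.push_back(&bridge1.bn.rvar);
    Ws.push_back(&bridge2.conv.W); vs.push_back(&bridge2.conv.b);
    vs.push_back(&bridge2.bn.gamma); vs.push_back(&bridge2.bn.beta);
    vs.push_back(&bridge2.bn.rmean); vs.push_back(&bridge2.bn.rvar);
    for (int s = depth - 1; s >= 0; --s) {
      Ws.push_back(&up[s].W0); Ws.push_back(&up[s].W1);
      vs.push_back(&up[s].b);
      Ws.push_back(&dec1[s].conv.W); vs.push_back(&dec1[s].conv.b);
      vs.push_back(&dec1[s].bn.gamma); vs.push_back(&dec1[s].bn.beta);
      vs.push_back(&dec1[s].bn.rmean); vs.push_back(&dec1[s].bn.rvar);
      Ws.push_back(&dec2[s].conv.W); vs.push_back(&dec2[s].conv.b);
      vs.push_back(&dec2[s].bn.gamma); vs.push_back(&dec2[s].bn.beta);
      vs.push_back(&dec2[s].bn.rmean); vs.push_back(&dec2[s].bn.rvar);
    }
    Ws.push_back(&head.W); vs.push_back(&head.b);
  }
};

// [[Rcpp::export]]
SEXP unet_create(int depth, int init_filters, int kernel, int in_channels,
                 int classes, int seed) {
  UNet* net = new UNet();
  net->init(depth, init_filters, kernel, in_channels, classes,
            (unsigned)seed);
  Rcpp::XPtr<UNet> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
bool unet_ptr_valid(SEXP ptr_) {
  return TYPEOF(ptr_) == EXTPTRSXP && R_ExternalPtrAddr(ptr_) != NULL;
}

// [[Rcpp::export]]
double unet_param_count(SEXP ptr_) {
  Rcpp::XPtr<UNet> ptr(ptr_);
  std::vector<fmat*> Ws; std::vector<fvec*> vs;
  ptr->collect(Ws, vs);
  double n = 0;
  // running BN stats are state, not parameters: subtract them
  for (auto W : Ws) n += W->n_elem;
  for (auto v : vs) n += v->n_elem;
  Rcpp::XPtr<UNet> p2(ptr_);
  UNet* net = p2;
  double bn_stats = 0;
  for (int s = 0; s < net->depth; ++s)
    bn_stats += net->enc1[s].bn.rmean.n_elem + net->enc1[s].bn.rvar.n_elem +
                net->enc2[s].bn.rmean.n_elem + net->enc2[s].bn.rvar.n_elem +
                net->dec1[s].bn.rmean.n_elem + net->dec1[s].bn.rvar.n_elem +
                net->dec2[s].bn.rmean.n_elem + net->dec2[s].bn.rvar.n_elem;
  bn_stats += net->bridge1.bn.rmean.n_elem + net->bridge1.bn.rvar.n_elem +
              net->bridge2.bn.rmean.n_elem + net->bridge2.bn.rvar.n_elem;
  return n - bn_stats;
}

// [[Rcpp::export]]
Rcpp::NumericVector unet_get_state(SEXP ptr_) {
  Rcpp::XPtr<UNet> ptr(ptr_);
  std::vector<fmat*> Ws; std::vector<fvec*> vs;
  ptr->collect(Ws, vs);
  size_t n = 0;
  for (auto W : Ws) n += W->n_elem;
  for (auto v : vs) n += v->n_elem;
  Rcpp::NumericVector out(n);
  size_t off = 0;
  for (auto W : Ws) for (auto x : *W) out[off++] = x;
  for (auto v : vs) for (auto x : *v) out[off++] = x;
  return out;
}

// [[Rcpp::export]]
void unet_set_state(SEXP ptr_, Rcpp::NumericVector state) {
  Rcpp::XPtr<UNet> ptr(ptr_);
  std::vector<fmat*> Ws; std::vector<fvec*> vs;
  ptr->collect(Ws, vs);
  size_t n = 0;
  for (auto W : Ws) n += W->n_elem;
  for (auto v : vs) n += v->n_elem;
  if ((size_t)state.size() != n)
    Rcpp::stop("state vector has wrong length");
  size_t off = 0;
  for (auto W : Ws) for (auto& x : *W) x = (float)state[off++];
  for (auto v : vs) for (auto& x : *v) x = (float)state[off++];
}

// [[Rcpp::export]]
Rcpp::NumericMatrix unet_forward(SEXP ptr_, Rcpp::NumericMatrix X,
                                 int B, bool training = false) {
  Rcpp::XPtr<UNet> ptr(ptr_);
  if (X.nrow() != ptr->Cin) Rcpp::stop("input channel mismatch");
  int L = X.ncol() / B;
  if ((size_t)B * L != (size_t)X.ncol() || L % (1 << ptr->depth))
    Rcpp::stop("sample length must be divisible by 2^depth");
  fmat Xf(ptr->Cin, X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i) Xf(i, j) = (float)X(i, j);
  fmat p = ptr->forward(Xf, B, L, training);
  Rcpp::NumericMatrix out(p.n_rows, p.n_cols);
  for (size_t j = 0; j < p.n_cols; ++j)
    for (size_t i = 0; i < p.n_rows; ++i) out(i, j) = p(i, j);
  return out;
}

// [[Rcpp::export]]
double unet_train_batch(SEXP ptr_, Rcpp::NumericMatrix X,
                        Rcpp::IntegerVector y, Rcpp::NumericVector w,
                        int B, double lr) {
  Rcpp::XPtr<UNet> ptr(ptr_);
  int L = X.ncol() / B;
  if ((size_t)B * L != (size_t)X.ncol() || L % (1 << ptr->depth))
    Rcpp::stop("sample length must be divisible by 2^depth");
  if (y.size() != X.ncol()) Rcpp::stop("label length mismatch");
  fmat Xf(ptr->Cin, X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i) Xf(i, j) = (float)X(i, j);
  ivec yv(y.size());
  for (int i = 0; i < y.size(); ++i) yv(i) = y[i];
  fvec wv(w.size());
  for (int i = 0; i < w.size(); ++i) wv(i) = (float)w[i];
  return ptr->trainBatch(Xf, yv, wv, B, L, (float)lr);
}

// [[Rcpp::export]]
double unet_eval_loss(SEXP ptr_, Rcpp::NumericMatrix X,
                      Rcpp::IntegerVector y, Rcpp::NumericVector w, int B) {
  Rcpp::XPtr<UNet> ptr(ptr_);
  int L = X.ncol() / B;
  fmat Xf(ptr->Cin, X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i) Xf(i, j) = (float)X(i, j);
  ivec yv(y.size());
  for (int i = 0; i < y.size(); ++i) yv(i) = y[i];
  fvec wv(w.size());
  for (int i = 0; i < w.size(); ++i) wv(i) = (float)w[i];
  fmat p = ptr->forward(Xf, B, L, false);
  return ptr->loss(p, yv, wv);
}
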