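// Convolutional dual-output autoencoder: encoder -> dense bottleneck ->
// mirrored decoder, trained with a soft-Dice objective.  Layout conventions:
//   - images are H x W matrices in [0,1]; feature maps are arma::cube H x W x C
//   - conv weights are (9 * C_in) x C_out matrices applied via im2col
//   - dense weights are (in x out); y = W^T x + b
// The architecture: n_blocks conv blocks (3x3, ReLU), 2x2 max-pool after the
// first n_blocks-1 blocks, channels double per block but freeze after block
// n_blocks-1 (so the full-scale preset bottoms out at 32x32x256 = 262,144),
// then flatten -> hidden -> latent -> hidden -> flatten, and a mirrored
// decoder with nearest-neighbour upsampling; final 1-channel conv + sigmoid.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct Shapes {
  int n_blocks, input_size, hidden, latent;
  std::vector<int> ch; // ch[0] = 1 input channel
  int sb, F;           // bottom spatial size, flatten length
};

static Shapes make_shapes(const List& meta) {
  Shapes s;
  s.n_blocks   = as<int>(meta["n_blocks"]);
  s.input_size = as<int>(meta["input_size"]);
  int base     = as<int>(meta["base_filters"]);
  int maxc     = as<int>(meta["max_channels"]);
  s.hidden     = as<int>(meta["hidden"]);
  s.latent     = as<int>(meta["latent_dim"]);
  s.ch.assign(s.n_blocks + 1, 1);
  for (int i = 1; i < s.n_blocks; ++i)
    s.ch[i] = std::min(base << (i - 1), maxc);
  s.ch[s.n_blocks] = s.ch[s.n_blocks - 1];
  s.sb = s.input_size >> (s.n_blocks - 1);
  s.F  = s.sb * s.sb * s.ch[s.n_blocks];
  return s;
}

// 3x3 same-padding im2col: one column per (channel, offset) pair.
static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * W, 9 * C);
  mat shifted(H, W);
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    int k = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr, ++k) {
        shifted.zeros();
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        if (r1 > r0 && c1 > c0)
          shifted.submat(r0, c0, r1 - 1, c1 - 1) =
            s.submat(r0 + dr, c0 + dc, r1 - 1 + dr, c1 - 1 + dc);
        out.col(c * 9 + k) = vectorise(shifted);
      }
    }
  }
  return out;
}

static cube col2im3(const mat& dcols, int H, int W, int C) {
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    int k = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr, ++k) {
        mat d = reshape(dcols.col(c * 9 + k), H, W);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        if (r1 > r0 && c1 > c0)
          dx.slice(c).submat(r0 + dr, c0 + dc, r1 - 1 + dr, c1 - 1 + dc) +=
            d.submat(r0, c0, r1 - 1, c1 - 1);
      }
    }
  }
  return dx;
}

static cube conv_apply(const mat& cols, const mat& Wm, const vec& b,
                       int H, int W) {
  mat y = cols * Wm;
  y.each_row() += b.t();
  cube out(H, W, Wm.n_cols);
  for (uword c = 0; c < Wm.n_cols; ++c)
    out.slice(c) = reshape(y.col(c), H, W);
  return out;
}

static mat cube_to_mat(const cube& x) { // (H*W) x C
  mat m(x.n_rows * x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c) m.col(c) = vectorise(x.slice(c));
  return m;
}

static cube mat_to_cube(const mat& m, int H, int W) {
  cube x(H, W, m.n_cols);
  for (uword c = 0; c < m.n_cols; ++c) x.slice(c) = reshape(m.col(c), H, W);
  return x;
}

static cube maxpool2(const cube& x, cube& argmask) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(H / 2, W / 2, C);
  argmask.zeros(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W / 2; ++j)
      for (int i = 0; i < H / 2; ++i) {
        double best = x(2 * i, 2 * j, c);
        int br = 2 * i, bc = 2 * j;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di)
            if (x(2 * i + di, 2 * j + dj, c) > best) {
              best = x(2 * i + di, 2 * j + dj, c);
              br = 2 * i + di; bc = 2 * j + dj;
            }
        y(i, j, c) = best;
        argmask(br, bc, c) = 1.0;
      }
  return y;
}

static cube maxpool2_back(const cube& dy, const cube& argmask) {
  const int H = argmask.n_rows, W = argmask.n_cols, C = argmask.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = argmask(i, j, c) * dy(i / 2, j / 2, c);
  return dx;
}

static cube up2(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        y(i, j, c) = x(i / 2, j / 2, c);
  return y;
}

static cube up2_back(const cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        dx(i / 2, j / 2, c) += dy(i, j, c);
  return dx;
}

struct Params {
  std::vector<mat> encW, decW; // decW[i] maps ch[i] -> ch[i-1], i = 2..n
  std::vector<vec> encB, decB;
  std::vector<vec> encG, encBe, decG, decBe; // instance-norm scale/shift
  mat fc1W, fc2W, fc3W, fc4W, outW;
  vec fc1b, fc2b, fc3b, fc4b, outb;
};

static Params get_params(const List& pl, const Shapes& s) {
  Params p;
  p.encW.resize(s.n_blocks + 1); p.encB.resize(s.n_blocks + 1);
  p.decW.resize(s.n_blocks + 1); p.decB.resize(s.n_blocks + 1);
  p.encG.resize(s.n_blocks + 1); p.encBe.resize(s.n_blocks + 1);
  p.decG.resize(s.n_blocks + 1); p.decBe.resize(s.n_blocks + 1);
  char nm[32];
  for (int i = 1; i <= s.n_blocks; ++i) {
    snprintf(nm, 32, "enc_W%d", i); p.encW[i] = as<mat>(pl[nm]);
    snprintf(nm, 32, "enc_b%d", i); p.encB[i] = as<vec>(pl[nm]);
    snprintf(nm, 32, "enc_g%d", i); p.encG[i] = as<vec>(pl[nm]);
    snprintf(nm, 32, "enc_h%d", i); p.encBe[i] = as<vec>(pl[nm]);
  }
  for (int i = 2; i <= s.n_blocks; ++i) {
    snprintf(nm, 32, "dec_W%d", i); p.decW[i] = as<mat>(pl[nm]);
    snprintf(nm, 32, "dec_b%d", i); p.decB[i] = as<vec>(pl[nm]);
    snprintf(nm, 32, "dec_g%d", i); p.decG[i] = as<vec>(pl[nm]);
    snprintf(nm, 32, "dec_h%d", i); p.decBe[i] = as<vec>(pl[nm]);
  }
  p.fc1W = as<mat>(pl["fc1_W"]); p.fc1b = as<vec>(pl["fc1_b"]);
  p.fc2W = as<mat>(pl["fc2_W"]); p.fc2b = as<vec>(pl["fc2_b"]);
  p.fc3W = as<mat>(pl["fc3_W"]); p.fc3b = as<vec>(pl["fc3_b"]);
  p.fc4W = as<mat>(pl["fc4_W"]); p.fc4b = as<vec>(pl["fc4_b"]);
  p.outW = as<mat>(pl["out_W"]); p.outb = as<vec>(pl["out_b"]);
  return p;
}

struct Cache {
  std::vector<mat> enc_cols;   // im2col of each enc conv input
  std::vector<cube> enc_pre;   // post-norm, pre-ReLU activations
  std::vector<cube> enc_xhat;  // instance-norm normalised conv outputs
  std::vector<vec> enc_istd;
  std::vector<cube> enc_arg;   // pool argmasks (blocks 1..n-1)
  vec f, h1pre, h1, z, h2pre, h2, f2pre, f2;
  std::vector<mat> dec_cols;
  std::vector<cube> dec_pre, dec_xhat;
  std::vector<vec> dec_istd;
  mat out_cols;
  mat prob;
};

// Per-sample, per-channel normalisation over the spatial dims with
// learnable scale/shift; batch-size independent.
static cube inorm_fw(const cube& x, const vec& g, const vec& be,
                     cube& xhat, vec& istd) {
  const int C = x.n_slices;
  xhat.set_size(size(x));
  istd.set_size(C);
  cube y(size(x));
  for (int c = 0; c < C; ++c) {
    const double mu = accu(x.slice(c)) / x.slice(c).n_elem;
    mat ctr = x.slice(c) - mu;
    const double v = accu(ctr % ctr) / ctr.n_elem;
    istd(c) = 1.0 / std::sqrt(v + 1e-5);
    xhat.slice(c) = ctr * istd(c);
    y.slice(c) = g(c) * xhat.slice(c) + be(c);
  }
  return y;
}

static cube inorm_bw(const cube& dy, const cube& xhat, const vec& istd,
                     const vec& g, vec& dg, vec& dbe) {
  const int C = dy.n_slices;
  cube dx(size(dy));
  for (int c = 0; c < C; ++c) {
    dg(c) += accu(dy.slice(c) % xhat.slice(c));
    dbe(c) += accu(dy.slice(c));
    mat dxh = dy.slice(c) * g(c);
    const double m1 = accu(dxh) / dxh.n_elem;
    const double m2 = accu(dxh % xhat.slice(c)) / dxh.n_elem;
    dx.slice(c) = istd(c) * (dxh - m1 - xhat.slice(c) * m2);
  }
  return dx;
}

static void forward_pass(const Params& p, const Shapes& s, const mat& img,
                         Cache& K) {
  const int n = s.n_blocks;
  K.enc_cols.resize(n + 1); K.enc_pre.resize(n + 1); K.enc_arg.resize(n + 1);
  K.enc_xhat.resize(n + 1); K.enc_istd.resize(n + 1);
  K.dec_cols.resize(n + 1); K.dec_pre.resize(n + 1);
  K.dec_xhat.resize(n + 1); K.dec_istd.resize(n + 1);
  cube x(img.n_rows, img.n_cols, 1);
  x.slice(0) = img;
  for (int i = 1; i <= n; ++i) {
    K.enc_cols[i] = im2col3(x);
    cube pre = conv_apply(K.enc_cols[i], p.encW[i], p.encB[i],
                          x.n_rows, x.n_cols);
    pre = inorm_fw(pre, p.encG[i], p.encBe[i], K.enc_xhat[i], K.enc_istd[i]);
    K.enc_pre[i] = pre;
    cube post = clamp(pre, 0.0, datum::inf); // ReLU
    if (i <= n - 1) x = maxpool2(post, K.enc_arg[i]);
    else            x = post;
  }
  K.f = vectorise(x);
  K.h1pre = p.fc1W.t() * K.f + p.fc1b;
  K.h1 = clamp(K.h1pre, 0.0, datum::inf);
  K.z = p.fc2W.t() * K.h1 + p.fc2b;              // linear latent
  K.h2pre = p.fc3W.t() * K.z + p.fc3b;
  K.h2 = clamp(K.h2pre, 0.0, datum::inf);
  K.f2pre = p.fc4W.t() * K.h2 + p.fc4b;
  K.f2 = clamp(K.f2pre, 0.0, datum::inf);
  cube d(s.sb, s.sb, s.ch[n]);
  std::memcpy(d.memptr(), K.f2.memptr(), sizeof(double) * s.F);
  for (int i = n; i >= 2; --i) { // upsample first: convs act at full scale
    d = up2(d);
    K.dec_cols[i] = im2col3(d);
    cube pre = conv_apply(K.dec_cols[i], p.decW[i], p.decB[i],
                          d.n_rows, d.n_cols);
    pre = inorm_fw(pre, p.decG[i], p.decBe[i], K.dec_xhat[i], K.dec_istd[i]);
    K.dec_pre[i] = pre;
    d = clamp(pre, 0.0, datum::inf);
  }
  cube dc = d;
  K.out_cols = im2col3(dc);
  cube logit = conv_apply(K.out_cols, p.outW, p.outb, dc.n_rows, dc.n_cols);
  K.prob = 1.0 / (1.0 + exp(-logit.slice(0)));
}

// [[Rcpp::export]]
List ae_forward_cpp(List params, List meta, arma::mat img) {
  Shapes s = make_shapes(meta);
  Params p = get_params(params, s);
  Cache K;
  forward_pass(p, s, img, K);
  return List::create(_["prob"] = K.prob, _["latent"] = K.z);
}

// Accumulates gradients over a batch; returns summed grads, mean loss/dice.
// [[Rcpp::export]]
List ae_grad_batch_cpp(List params, List meta, List imgs, List masks,
                       double eps) {
  Shapes s = make_shapes(meta);
  Params p = get_params(params, s);
  const int n = s.n_blocks, B = imgs.size();
  Params g; // gradient accumulator, zero-initialised to param shapes
  g.encW.resize(n + 1); g.encB.resize(n + 1);
  g.decW.resize(n + 1); g.decB.resize(n + 1);
  g.encG.resize(n + 1); g.encBe.resize(n + 1);
  g.decG.resize(n + 1); g.decBe.resize(n + 1);
  for (int i = 1; i <= n; ++i) {
    g.encW[i] = zeros<mat>(size(p.encW[i]));
    g.encB[i] = zeros<vec>(size(p.encB[i]));
    g.encG[i] = zeros<vec>(size(p.encG[i]));
    g.encBe[i] = zeros<vec>(size(p.encBe[i]));
  }
  for (int i = 2; i <= n; ++i) {
    g.decW[i] = zeros<mat>(size(p.decW[i]));
    g.decB[i] = zeros<vec>(size(p.decB[i]));
    g.decG[i] = zeros<vec>(size(p.decG[i]));
    g.decBe[i] = zeros<vec>(size(p.decBe[i]));
  }
  g.fc1W = zeros<mat>(size(p.fc1W)); g.fc1b = zeros<vec>(size(p.fc1b));
  g.fc2W = zeros<mat>(size(p.fc2W)); g.fc2b = zeros<vec>(size(p.fc2b));
  g.fc3W = zeros<mat>(size(p.fc3W)); g.fc3b = zeros<vec>(size(p.fc3b));
  g.fc4W = zeros<mat>(size(p.fc4W)); g.fc4b = zeros<vec>(size(p.fc4b));
  g.outW = zeros<mat>(size(p.outW)); g.outb = zeros<vec>(size(p.outb));

  double loss_sum = 0.0, dice_sum = 0.0;
  for (int b = 0; b < B; ++b) {
    mat img = as<mat>(imgs[b]);
    mat msk = as<mat>(masks[b]);
    Cache K;
    forward_pass(p, s, img, K);
    const mat& pr = K.prob;
    const double s1 = accu(pr % msk), s2 = accu(pr % pr), s3 = accu(msk % msk);
    const double den = s2 + s3 + eps;
    const double dice = (2.0 * s1 + eps) / den;
    loss_sum += 1.0 - dice;
    dice_sum += dice;
    // dL/dp for L = 1 - (2 s1 + eps) / den
    mat dLdp = -(2.0 * msk * den - (2.0 * s1 + eps) * 2.0 * pr) / (den * den);
    dLdp /= static_cast<double>(B);
    mat dlogit = dLdp % pr % (1.0 - pr);

    // output conv
    mat dY = vectorise(dlogit);
    g.outW += K.out_cols.t() * dY;
    g.outb += sum(dY, 0).t();
    mat dcols = dY * p.outW.t();
    cube d = col2im3(dcols, dlogit.n_rows, dlogit.n_cols, s.ch[1]);

    // decoder blocks i = 2..n (reverse of forward n..2)
    for (int i = 2; i <= n; ++i) {
      cube relu_m = conv_to<cube>::from(K.dec_pre[i] > 0.0);
      d %= relu_m;
      d = inorm_bw(d, K.dec_xhat[i], K.dec_istd[i], p.decG[i],
                   g.decG[i], g.decBe[i]);
      mat dYm = cube_to_mat(d);
      g.decW[i] += K.dec_cols[i].t() * dYm;
      g.decB[i] += sum(dYm, 0).t();
      d = col2im3(dYm * p.decW[i].t(), d.n_rows, d.n_cols, s.ch[i]);
      d = up2_back(d);
    }
    vec df2 = vectorise(d);
    vec df2pre = df2 % conv_to<vec>::from(K.f2pre > 0.0);
    g.fc4W += K.h2 * df2pre.t(); g.fc4b += df2pre;
    vec dh2 = p.fc4W * df2pre;
    vec dh2pre = dh2 % conv_to<vec>::from(K.h2pre > 0.0);
    g.fc3W += K.z * dh2pre.t(); g.fc3b += dh2pre;
    vec dz = p.fc3W * dh2pre;
    g.fc2W += K.h1 * dz.t(); g.fc2b += dz;
    vec dh1 = p.fc2W * dz;
    vec dh1pre = dh1 % conv_to<vec>::from(K.h1pre > 0.0);
    g.fc1W += K.f * dh1pre.t(); g.fc1b += dh1pre;
    vec df = p.fc1W * dh1pre;

    cube de(s.sb, s.sb, s.ch[n]);
    std::memcpy(de.memptr(), df.memptr(), sizeof(double) * s.F);
    for (int i = n; i >= 1; --i) {
      if (i <= n - 1) de = maxpool2_back(de, K.enc_arg[i]);
      cube relu_m = conv_to<cube>::from(K.enc_pre[i] > 0.0);
      de %= relu_m;
      de = inorm_bw(de, K.enc_xhat[i], K.enc_istd[i], p.encG[i],
                    g.encG[i], g.encBe[i]);
      mat dYm = cube_to_mat(de);
      g.encW[i] += K.enc_cols[i].t() * dYm;
      g.encB[i] += sum(dYm, 0).t();
      if (i > 1)
        de = col2im3(dYm * p.encW[i].t(), de.n_rows, de.n_cols, s.ch[i - 1]);
    }
  }

  List gl;
  char nm[32];
  for (int i = 1; i <= n; ++i) {
    snprintf(nm, 32, "enc_W%d", i); gl[nm] = g.encW[i];
    snprintf(nm, 32, "enc_b%d", i); gl[nm] = g.encB[i];
    snprintf(nm, 32, "enc_g%d", i); gl[nm] = g.encG[i];
    snprintf(nm, 32, "enc_h%d", i); gl[nm] = g.encBe[i];
  }
  gl["fc1_W"] = g.fc1W; gl["fc1_b"] = g.fc1b;
  gl["fc2_W"] = g.fc2W; gl["fc2_b"] = g.fc2b;
  gl["fc3_W"] = g.fc3W; gl["fc3_b"] = g.fc3b;
  gl["fc4_W"] = g.fc4W; gl["fc4_b"] = g.fc4b;
  for (int i = 2; i <= n; ++i) {
    snprintf(nm, 32, "dec_W%d", i); gl[nm] = g.decW[i];
    snprintf(nm, 32, "dec_b%d", i); gl[nm] = g.decB[i];
    snprintf(nm, 32, "dec_g%d", i); gl[nm] = g.decG[i];
    snprintf(nm, 32, "dec_h%d", i); gl[nm] = g.decBe[i];
  }
  gl["out_W"] = g.outW; gl["out_b"] = g.outb;
  return List::create(_["grads"] = gl,
                      _["loss"] = loss_sum / B,
                      _["dice"] = dice_sum / B);
}
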