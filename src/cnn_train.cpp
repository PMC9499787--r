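// Single-precision training loop for the pulse CNN. The layer stack is
// fixed (conv x2, maxpool 3, conv x2, global average pool, dropout,
// softmax head); minibatch order and dropout draws are supplied by the
// caller so a run is exactly reproducible from one seed. All heavy steps
// are sgemm calls on im2col buffers reused across batches.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <cstring>
#include <cmath>

#ifdef FC_LEN_T
extern "C" void sgemm_(const char*, const char*, const int*, const int*,
                       const int*, const float*, const float*, const int*,
                       const float*, const int*, const float*, float*,
                       const int*, FC_LEN_T, FC_LEN_T);
#define SGEMM_CALL(ta, tb, m, n, k, al, A, lda, B, ldb, be, C, ldc) \
  sgemm_(ta, tb, m, n, k, al, A, lda, B, ldb, be, C, ldc, (FC_LEN_T)1, (FC_LEN_T)1)
#else
extern "C" void sgemm_(const char*, const char*, const int*, const int*,
                       const int*, const float*, const float*, const int*,
                       const float*, const int*, const float*, float*,
                       const int*);
#define SGEMM_CALL(ta, tb, m, n, k, al, A, lda, B, ldb, be, C, ldc) \
  sgemm_(ta, tb, m, n, k, al, A, lda, B, ldb, be, C, ldc)
#endif

namespace {

void sgemm(char ta, char tb, int m, int n, int k, float alpha, const float* A,
           int lda, const float* B, int ldb, float beta, float* C, int ldc) {
  char tastr[2] = {ta, 0}, tbstr[2] = {tb, 0};
  SGEMM_CALL(tastr, tbstr, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

typedef std::vector<float> fvec;

// (B*L x C) activations -> (B*Lout x K*C) im2col buffer, column-major.
void im2col(const float* A, float* cols, int B, int L, int C, int K) {
  const int Lout = L - K + 1;
  const int ldA = B * L, ldc = B * Lout;
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c)
      for (int b = 0; b < B; ++b)
        std::memcpy(cols + (k * C + c) * ldc + b * Lout,
                    A + c * ldA + b * L + k, Lout * sizeof(float));
}

void col2im_add(const float* cols, float* dA, int B, int L, int C, int K) {
  const int Lout = L - K + 1;
  const int ldA = B * L, ldc = B * Lout;
  std::memset(dA, 0, (size_t)ldA * C * sizeof(float));
  for (int k = 0; k < K; ++k)
    for (int c = 0; c < C; ++c)
      for (int b = 0; b < B; ++b) {
        const float* src = cols + (k * C + c) * ldc + b * Lout;
        float* dst = dA + c * ldA + b * L + k;
        for (int i = 0; i < Lout; ++i) dst[i] += src[i];
      }
}

struct Param {
  fvec w, m, v;
  Param() {}
  explicit Param(size_t n) : w(n, 0.f), m(n, 0.f), v(n, 0.f) {}
};

void adam(Param& p, const float* g, float lr, int t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  const float c1 = 1.f - std::pow(b1, (float)t);
  const float c2 = 1.f - std::pow(b2, (float)t);
  for (size_t i = 0; i < p.w.size(); ++i) {
    p.m[i] = b1 * p.m[i] + (1.f - b1) * g[i];
    p.v[i] = b2 * p.v[i] + (1.f - b2) * g[i] * g[i];
    p.w[i] -= lr * (p.m[i] / c1) / (std::sqrt(p.v[i] / c2) + eps);
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_train_cnn(const Rcpp::NumericMatrix& X,
                         const Rcpp::IntegerVector& y, int K, int F1, int F2,
                         int F3, int F4, int pool, int ncls, int epochs,
                         int batch, double lr_in, double dropout_rate,
                         const Rcpp::List& init,
                         const Rcpp::IntegerMatrix& orders,
                         const Rcpp::NumericVector& dropu) {
  const int n = X.nrow(), L0 = X.ncol();
  const int L1 = L0 - K + 1, L2 = L1 - K + 1, Lp = L2 / pool;
  const int L3 = Lp - K + 1, L4 = L3 - K + 1;
  const float lr = (float)lr_in, drop = (float)dropout_rate;
  const float keep_scale = drop > 0 ? 1.f / (1.f - drop) : 1.f;

  // parameters (converted from the R initialization)
  const char* nm[10] = {"W1", "b1", "W2", "b2", "W3", "b3",
                        "W4", "b4", "W5", "b5"};
  std::vector<Param> P(10);
  for (int i = 0; i < 10; ++i) {
    Rcpp::NumericVector v(init[nm[i]]);
    P[i] = Param(v.size());
    for (int j = 0; j < v.size(); ++j) P[i].w[j] = (float)v[j];
  }

  const int Bm = batch;
  fvec A0(Bm * L0), A1((size_t)Bm * L1 * F1), A2((size_t)Bm * L2 * F2);
  fvec Pm((size_t)Bm * Lp * F2), A3((size_t)Bm * L3 * F3), A4((size_t)Bm * L4 * F4);
  std::vector<int> argmax((size_t)Bm * Lp * F2);
  fvec G(Bm * F4), H(Bm * F4), mask(Bm * F4), logits(Bm * ncls);
  fvec cols1((size_t)Bm * L1 * K), cols2((size_t)Bm * L2 * K * F1);
  fvec cols3((size_t)Bm * L3 * K * F2), cols4((size_t)Bm * L4 * K * F3);
  size_t colmax = std::max(cols2.size(), std::max(cols3.size(), cols4.size()));
  fvec dcols(colmax);
  fvec dA1((size_t)Bm * L1 * F1), dA2((size_t)Bm * L2 * F2), dPm((size_t)Bm * Lp * F2);
  fvec dA3((size_t)Bm * L3 * F3), dA4((size_t)Bm * L4 * F4);
  fvec dG(Bm * F4), dlog(Bm * ncls);
  fvec gW1(P[0].w.size()), gb1(F1), gW2(P[2].w.size()), gb2(F2);
  fvec gW3(P[4].w.size()), gb3(F3), gW4(P[6].w.size()), gb4(F4);
  fvec gW5(P[8].w.size()), gb5(ncls);

  Rcpp::NumericVector ep_loss(epochs), ep_acc(epochs);
  size_t du = 0;
  int t_step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    int hits = 0;
    for (int s = 0; s < n; s += batch) {
      const int B = std::min(batch, n - s);
      const int r1 = B * L1, r2 = B * L2, rp = B * Lp, r3 = B * L3, r4 = B * L4;

      // ---- forward ----
      for (int b = 0; b < B; ++b) {
        int row = orders(s + b, ep) - 1;
        for (int j = 0; j < L0; ++j) A0[b * L0 + j] = (float)X(row, j);
      }
      float zero = 0.f, onef = 1.f;

      im2col(A0.data(), cols1.data(), B, L0, 1, K);
      for (int f = 0; f < F1; ++f)
        for (int r = 0; r < r1; ++r) A1[(size_t)f * r1 + r] = P[1].w[f];
      sgemm('N', 'N', r1, F1, K, onef, cols1.data(), r1, P[0].w.data(), K,
            onef, A1.data(), r1);
      for (size_t i = 0; i < (size_t)r1 * F1; ++i) A1[i] = A1[i] > 0 ? A1[i] : 0;

      im2col(A1.data(), cols2.data(), B, L1, F1, K);
      for (int f = 0; f < F2; ++f)
        for (int r = 0; r < r2; ++r) A2[(size_t)f * r2 + r] = P[3].w[f];
      sgemm('N', 'N', r2, F2, K * F1, onef, cols2.data(), r2, P[2].w.data(),
            K * F1, onef, A2.data(), r2);
      for (size_t i = 0; i < (size_t)r2 * F2; ++i) A2[i] = A2[i] > 0 ? A2[i] : 0;

      for (int f = 0; f < F2; ++f)
        for (int b = 0; b < B; ++b)
          for (int i = 0; i < Lp; ++i) {
            size_t base = (size_t)f * r2 + b * L2 + i * pool;
            int am = 0;
            float best = A2[base];
            for (int u = 1; u < pool; ++u)
              if (A2[base + u] > best) { best = A2[base + u]; am = u; }
            size_t o = (size_t)f * rp + b * Lp + i;
            Pm[o] = best;
            argmax[o] = (int)(base + am);
          }

      im2col(Pm.data(), cols3.data(), B, Lp, F2, K);
      for (int f = 0; f < F3; ++f)
        for (int r = 0; r < r3; ++r) A3[(size_t)f * r3 + r] = P[5].w[f];
      sgemm('N', 'N', r3, F3, K * F2, onef, cols3.data(), r3, P[4].w.data(),
            K * F2, onef, A3.data(), r3);
      for (size_t i = 0; i < (size_t)r3 * F3; ++i) A3[i] = A3[i] > 0 ? A3[i] : 0;

      im2col(A3.data(), cols4.data(), B, L3, F3, K);
      for (int f = 0; f < F4; ++f)
        for (int r = 0; r < r4; ++r) A4[(size_t)f * r4 + r] = P[7].w[f];
      sgemm('N', 'N', r4, F4, K * F3, onef, cols4.data(), r4, P[6].w.data(),
            K * F3, onef, A4.data(), r4);
      for (size_t i = 0; i < (size_t)r4 * F4; ++i) A4[i] = A4[i] > 0 ? A4[i] : 0;

      for (int f = 0; f < F4; ++f)
        for (int b = 0; b < B; ++b) {
          float acc = 0.f;
          for (int i = 0; i < L4; ++i) acc += A4[(size_t)f * r4 + b * L4 + i];
          G[f * B + b] = acc / L4;
        }

      for (int b = 0; b < B; ++b)
        for (int f = 0; f < F4; ++f) {
          // draws consumed sample-major so the stream is batch-independent
          float u = (float)dropu[du + (size_t)(s + b) * F4 + f];
          float m = (drop > 0 && u < drop) ? 0.f : keep_scale;
          mask[f * B + b] = m;
          H[f * B + b] = G[f * B + b] * m;
        }

      for (int c = 0; c < ncls; ++c)
        for (int b = 0; b < B; ++b) logits[c * B + b] = P[9].w[c];
      sgemm('N', 'N', B, ncls, F4, onef, H.data(), B, P[8].w.data(), F4, onef,
            logits.data(), B);

      for (int b = 0; b < B; ++b) {
        float mx = logits[b];
        int arg = 0;
        for (int c = 1; c < ncls; ++c)
          if (logits[c * B + b] > mx) { mx = logits[c * B + b]; arg = c; }
        float Zs = 0.f;
        for (int c = 0; c < ncls; ++c) {
          float e = std::exp(logits[c * B + b] - mx);
          logits[c * B + b] = e;
          Zs += e;
        }
        int yt = y[orders(s + b, ep) - 1] - 1;
        float p_true = 0.f;
        for (int c = 0; c < ncls; ++c) {
          logits[c * B + b] /= Zs;
          if (c == yt) p_true = logits[c * B + b];
        }
        loss_sum -= std::log(std::max(p_true, 1e-12f));
        if (arg == yt) ++hits;
        for (int c = 0; c < ncls; ++c)
          dlog[c * B + b] = (logits[c * B + b] - (c == yt ? 1.f : 0.f)) / B;
      }

      // ---- backward ----
      sgemm('T', 'N', F4, ncls, B, onef, H.data(), B, dlog.data(), B, zero,
            gW5.data(), F4);
      for (int c = 0; c < ncls; ++c) {
        float acc = 0.f;
        for (int b = 0; b < B; ++b) acc += dlog[c * B + b];
        gb5[c] = acc;
      }
      sgemm('N', 'T', B, F4, ncls, onef, dlog.data(), B, P[8].w.data(), F4,
            zero, dG.data(), B);
      for (size_t i = 0; i < (size_t)B * F4; ++i) dG[i] *= mask[i];

      for (int f = 0; f < F4; ++f)
        for (int b = 0; b < B; ++b) {
          float gv = dG[f * B + b] / L4;
          for (int i = 0; i < L4; ++i) {
            size_t o = (size_t)f * r4 + b * L4 + i;
            dA4[o] = A4[o] > 0 ? gv : 0.f;
          }
        }

      sgemm('T', 'N', K * F3, F4, r4, onef, cols4.data(), r4, dA4.data(), r4,
            zero, gW4.data(), K * F3);
      for (int f = 0; f < F4; ++f) {
        float acc = 0.f;
        for (int r = 0; r < r4; ++r) acc += dA4[(size_t)f * r4 + r];
        gb4[f] = acc;
      }
      sgemm('N', 'T', r4, K * F3, F4, onef, dA4.data(), r4, P[6].w.data(),
            K * F3, zero, dcols.data(), r4);
      col2im_add(dcols.data(), dA3.data(), B, L3, F3, K);
      for (size_t i = 0; i < (size_t)r3 * F3; ++i)
        if (A3[i] <= 0) dA3[i] = 0;

      sgemm('T', 'N', K * F2, F3, r3, onef, cols3.data(), r3, dA3.data(), r3,
            zero, gW3.data(), K * F2);
      for (int f = 0; f < F3; ++f) {
        float acc = 0.f;
        for (int r = 0; r < r3; ++r) acc += dA3[(size_t)f * r3 + r];
        gb3[f] = acc;
      }
      sgemm('N', 'T', r3, K * F2, F3, onef, dA3.data(), r3, P[4].w.data(),
            K * F2, zero, dcols.data(), r3);
      col2im_add(dcols.data(), dPm.data(), B, Lp, F2, K);

      std::memset(dA2.data(), 0, (size_t)r2 * F2 * sizeof(float));
      for (size_t o = 0; o < (size_t)rp * F2; ++o) {
        int f = (int)(o / rp);
        dA2[(size_t)f * r2 + (argmax[o] - (size_t)f * r2)] += dPm[o];
      }
      for (size_t i = 0; i < (size_t)r2 * F2; ++i)
        if (A2[i] <= 0) dA2[i] = 0;

      sgemm('T', 'N', K * F1, F2, r2, onef, cols2.data(), r2, dA2.data(), r2,
            zero, gW2.data(), K * F1);
      for (int f = 0; f < F2; ++f) {
        float acc = 0.f;
        for (int r = 0; r < r2; ++r) acc += dA2[(size_t)f * r2 + r];
        gb2[f] = acc;
      }
      sgemm('N', 'T', r2, K * F1, F2, onef, dA2.data(), r2, P[2].w.data(),
            K * F1, zero, dcols.data(), r2);
      col2im_add(dcols.data(), dA1.data(), B, L1, F1, K);
      for (size_t i = 0; i < (size_t)r1 * F1; ++i)
        if (A1[i] <= 0) dA1[i] = 0;

      sgemm('T', 'N', K, F1, r1, onef, cols1.data(), r1, dA1.data(), r1, zero,
            gW1.data(), K);
      for (int f = 0; f < F1; ++f) {
        float acc = 0.f;
        for (int r = 0; r < r1; ++r) acc += dA1[(size_t)f * r1 + r];
        gb1[f] = acc;
      }

      ++t_step;
      adam(P[0], gW1.data(), lr, t_step);
      adam(P[1], gb1.data(), lr, t_step);
      adam(P[2], gW2.data(), lr, t_step);
      adam(P[3], gb2.data(), lr, t_step);
      adam(P[4], gW3.data(), lr, t_step);
      adam(P[5], gb3.data(), lr, t_step);
      adam(P[6], gW4.data(), lr, t_step);
      adam(P[7], gb4.data(), lr, t_step);
      adam(P[8], gW5.data(), lr, t_step);
      adam(P[9], gb5.data(), lr, t_step);
    }
    du += (size_t)n * F4;
    ep_loss[ep] = loss_sum / n;
    ep_acc[ep] = (double)hits / n;
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List out_params;
  int dims[10][2] = {{K, F1},      {F1, 1}, {K * F1, F2}, {F2, 1},
                     {K * F2, F3}, {F3, 1}, {K * F3, F4}, {F4, 1},
                     {F4, ncls},   {ncls, 1}};
  for (int i = 0; i < 10; ++i) {
    if (dims[i][1] == 1) {
      Rcpp::NumericVector v(P[i].w.size());
      for (size_t j = 0; j < P[i].w.size(); ++j) v[j] = P[i].w[j];
      out_params[nm[i]] = v;
    } else {
      Rcpp::NumericMatrix m(dims[i][0], dims[i][1]);
      for (size_t j = 0; j < P[i].w.size(); ++j) m[j] = P[i].w[j];
      out_params[nm[i]] = m;
    }
  }
  return Rcpp::List::create(Rcpp::Named("params") = out_params,
                            Rcpp::Named("loss") = ep_loss,
                            Rcpp::Named("accuracy") = ep_acc);
}
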