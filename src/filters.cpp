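#include <Rcpp.h>
using namespace Rcpp;

// 2-D linear filtering (cross-correlation) keeping the image size.
// pad = 0: out-of-image pixels are zero; pad = 1: nearest-edge replication.
// Kernel center is at (nrow/2, ncol/2), 0-based (odd-sized kernels).
// The interior (where the kernel fits entirely inside the image) runs
// without boundary tests; borders are handled per-pixel.
// [[Rcpp::export]]
NumericMatrix conv2d_same(NumericMatrix x, NumericMatrix k, int pad) {
  const int nr = x.nrow(), nc = x.ncol();
  const int kr = k.nrow(), kc = k.ncol();
  const int cr = kr / 2, cc = kc / 2;
  NumericMatrix out(nr, nc);
  const double *xp = x.begin();
  const double *kp = k.begin();
  double *op = out.begin();

  // constant image: under edge replication the response is constant too
  if (pad == 1) {
    const size_t n = (size_t)nr * nc;
    size_t s = 1;
    while (s < n && xp[s] == xp[0]) ++s;
    if (s == n) {
      double ks = 0.0;
      for (int v = 0; v < kr * kc; ++v) ks += kp[v];
      std::fill(op, op + n, xp[0] * ks);
      return out;
    }
  }

  const int i0 = cr, i1 = nr - (kr - 1 - cr);       // interior rows [i0, i1)
  const int j0 = cc, j1 = nc - (kc - 1 - cc);       // interior cols [j0, j1)

  if (i1 > i0 && j1 > j0) {
    for (int j = j0; j < j1; ++j) {
      for (int v = 0; v < kc; ++v) {
        const double *xcol = xp + (size_t)(j + v - cc) * nr;
        const double *kcol = kp + (size_t)v * kr;
        double *ocol = op + (size_t)j * nr;
        for (int u = 0; u < kr; ++u) {
          const double kv = kcol[u];
          if (kv == 0.0) continue;
          const double *xs = xcol + u - cr;
          for (int i = i0; i < i1; ++i) ocol[i] += kv * xs[i];
        }
      }
    }
  }

  // border pixels (any i/j outside the interior box)
  for (int j = 0; j < nc; ++j) {
    const bool j_in = (j >= j0 && j < j1);
    for (int i = 0; i < nr; ++i) {
      if (j_in && i >= i0 && i < i1) continue;
      double acc = 0.0;
      for (int v = 0; v < kc; ++v) {
        int xj = j + v - cc;
        if (pad == 1) {
          xj = xj < 0 ? 0 : (xj >= nc ? nc - 1 : xj);
        } else if (xj < 0 || xj >= nc) {
          continue;
        }
        const double *xcol = xp + (size_t)xj * nr;
        const double *kcol = kp + (size_t)v * kr;
        for (int u = 0; u < kr; ++u) {
          int xi = i + u - cr;
          if (pad == 1) {
            xi = xi < 0 ? 0 : (xi >= nr ? nr - 1 : xi);
          } else if (xi < 0 || xi >= nr) {
            continue;
          }
          acc += xcol[xi] * kcol[u];
        }
      }
      op[(size_t)j * nr + i] = acc;
    }
  }
  return out;
}
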