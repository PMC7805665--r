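// BLAS-backed 3D tensor kernels for the segmentation networks.
//
// Array convention: volumes are R arrays with dim c(d1, d2, d3, C),
// column-major, voxel (i,j,k) of channel c at linear index
// i + d1*(j + d2*(k + d3*c)) (0-based).  All kernels are written for
// that layout; convolutions are lowered to im2col + GEMM so the heavy
// lifting runs in the BLAS.

#include <RcppArmadillo.h>
#ifndef FCONE
# define USE_FC_LEN_T
#endif
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

extern "C" void F77_NAME(sgemm)(const char* transa, const char* transb,
                                const int* m, const int* n, const int* k,
                                const float* alpha, const float* a, const int* lda,
                                const float* b, const int* ldb, const float* beta,
                                float* c, const int* ldc FCLEN FCLEN);



static NumericVector alloc_arr(std::initializer_list<int> dims) {
  R_xlen_t n = 1;
  IntegerVector dm((int)dims.size());
  int i = 0;
  for (int d : dims) { dm[i++] = d; n *= d; }
  NumericVector v(n);
  v.attr("dim") = dm;
  return v;
}

static IntegerVector alloc_int_arr(std::initializer_list<int> dims) {
  R_xlen_t n = 1;
  IntegerVector dm((int)dims.size());
  int i = 0;
  for (int d : dims) { dm[i++] = d; n *= d; }
  IntegerVector v(n);
  v.attr("dim") = dm;
  return v;
}

static inline void get_dims4(const NumericVector& x, int& d1, int& d2, int& d3, int& C) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (x, y, z, channel)");
  d1 = dm[0]; d2 = dm[1]; d3 = dm[2]; C = dm[3];
}

// ---------------------------------------------------------------------------
// 3x3x3 convolution, stride 1, zero padding 1 ("same")
// weight array dim c(3,3,3,Cin,Cout) viewed as matrix (27*Cin) x Cout
// ---------------------------------------------------------------------------

// Zero-padded shifted-GEMM convolution.  The volume is copied once into a
// zero-padded buffer (d1+2, d2+2, d3+2); each of the 27 kernel taps is then
// one constant-pointer-shift GEMM accumulated into a padded output.  The
// interposed zero rows/slices make every shifted read correct (no
// wrap-around), so no im2col buffer is needed and the working set stays
// small.  The inner GEMMs run in single precision (the surrounding
// pipeline is double); the ~1e-7 relative rounding this introduces is far
// below the noise scale of optimization.

static void pad_channels_f(const double* x, int d1, int d2, int d3, int C,
                           arma::fmat& P) {
  const int D1 = d1 + 2, D2 = d2 + 2, D3 = d3 + 2;
  const size_t Np = (size_t)D1 * D2 * D3;
  const size_t N = (size_t)d1 * d2 * d3;
  P.zeros(Np, C);
  for (int c = 0; c < C; ++c) {
    float* pc = P.colptr(c);
    const double* xc = x + N * c;
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j) {
        float* dst = pc + 1 + (size_t)D1 * ((j + 1) + (size_t)D2 * (k + 1));
        const double* srcp = xc + (size_t)d1 * (j + (size_t)d2 * k);
        for (int i = 0; i < d1; ++i) dst[i] = (float)srcp[i];
      }
  }
}

static void unpad_channels_f(const arma::fmat& P, int d1, int d2, int d3, int C,
                             double* y, const double* bias) {
  const int D1 = d1 + 2, D2 = d2 + 2;
  const size_t N = (size_t)d1 * d2 * d3;
  for (int c = 0; c < C; ++c) {
    const float* pc = P.colptr(c);
    double* yc = y + N * c;
    double bc = bias ? bias[c] : 0.0;
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j) {
        const float* srcp = pc + 1 + (size_t)D1 * ((j + 1) + (size_t)D2 * (k + 1));
        double* dst = yc + (size_t)d1 * (j + (size_t)d2 * k);
        for (int i = 0; i < d1; ++i) dst[i] = (double)srcp[i] + bc;
      }
  }
}

// accumulate Ypad += sum_s shift_s(Ppad) * W_s ; W given as R array
// (3,3,3,Ca,Cb); transposed = use W_{-s}^T (for the data gradient).
static void conv_padded_f(const arma::fmat& P, arma::fmat& Y, const double* wp,
                          int Ca, int Cb, int D1, int D2, int D3, bool transposed) {
  const long Np = (long)D1 * D2 * D3;
  arma::fmat Ws(Ca, Cb);
  for (int c2 = 0; c2 < 3; ++c2)
    for (int b2 = 0; b2 < 3; ++b2)
      for (int a2 = 0; a2 < 3; ++a2) {
        for (int cb = 0; cb < Cb; ++cb)
          for (int ca = 0; ca < Ca; ++ca) {
            size_t widx;
            if (!transposed)
              widx = a2 + 3*(b2 + 3*(c2 + 3*((size_t)ca + (size_t)Ca * cb)));
            else  // flipped tap, swapped channel roles: W[2-a,2-b,2-c, cb, ca]
              widx = (2-a2) + 3*((2-b2) + 3*((2-c2) + 3*((size_t)cb + (size_t)Cb * ca)));
            Ws(ca, cb) = (float)wp[widx];
          }
        long s = (a2 - 1) + (long)D1 * (b2 - 1) + (long)D1 * D2 * (c2 - 1);
        long r0 = std::max(0L, -s), r1 = Np - 1 - std::max(0L, s);
        if (r1 < r0) continue;
        int M = (int)(r1 - r0 + 1), K = Ca, Ncol = Cb, lda = (int)Np, ldc = (int)Np;
        float one = 1.0f;
        F77_CALL(sgemm)("N", "N", &M, &Ncol, &K, &one,
                        P.memptr() + (r0 + s), &lda, Ws.memptr(), &K, &one,
                        Y.memptr() + r0, &ldc FCONE FCONE);
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int d1, d2, d3, Cin;
  get_dims4(x, d1, d2, d3, Cin);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5 || wd[0] != 3 || wd[1] != 3 || wd[2] != 3 || wd[3] != Cin)
    stop("weight must have dim c(3,3,3,Cin,Cout) matching input channels");
  int Cout = wd[4];
  const int D1 = d1 + 2, D2 = d2 + 2, D3 = d3 + 2;
  arma::fmat P;
  pad_channels_f(REAL(x), d1, d2, d3, Cin, P);
  arma::fmat Y((size_t)D1 * D2 * D3, Cout, arma::fill::zeros);
  conv_padded_f(P, Y, REAL(w), Cin, Cout, D1, D2, D3, false);
  NumericVector out = alloc_arr({d1, d2, d3, Cout});
  unpad_channels_f(Y, d1, d2, d3, Cout, REAL(out), REAL(b));
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, NumericVector w, NumericVector gy, bool need_gx) {
  int d1, d2, d3, Cin;
  get_dims4(x, d1, d2, d3, Cin);
  IntegerVector wd = w.attr("dim");
  int Cout = wd[4];
  const int D1 = d1 + 2, D2 = d2 + 2, D3 = d3 + 2;
  const long Np = (long)D1 * D2 * D3;
  arma::fmat P, G;
  pad_channels_f(REAL(x), d1, d2, d3, Cin, P);
  pad_channels_f(REAL(gy), d1, d2, d3, Cout, G);
  NumericVector gw = alloc_arr({3, 3, 3, Cin, Cout});
  double* gwp = REAL(gw);
  NumericVector gb(Cout);
  {
    const double* gyp = REAL(gy);
    const size_t N = (size_t)d1 * d2 * d3;
    for (int c = 0; c < Cout; ++c) {
      double acc = 0.0;
      const double* gc = gyp + N * c;
      for (size_t t = 0; t < N; ++t) acc += gc[t];
      gb[c] = acc;
    }
  }
  arma::fmat GWs(Cin, Cout);
  for (int c2 = 0; c2 < 3; ++c2)
    for (int b2 = 0; b2 < 3; ++b2)
      for (int a2 = 0; a2 < 3; ++a2) {
        long s = (a2 - 1) + (long)D1 * (b2 - 1) + (long)D1 * D2 * (c2 - 1);
        long r0 = std::max(0L, -s), r1 = Np - 1 - std::max(0L, s);
        int M = Cin, Ncol = Cout, K = (int)(r1 - r0 + 1), ld = (int)Np;
        float one = 1.0f, zero = 0.0f;
        F77_CALL(sgemm)("T", "N", &M, &Ncol, &K, &one,
                        P.memptr() + (r0 + s), &ld, G.memptr() + r0, &ld, &zero,
                        GWs.memptr(), &M FCONE FCONE);
        for (int cb = 0; cb < Cout; ++cb)
          for (int ca = 0; ca < Cin; ++ca)
            gwp[a2 + 3*(b2 + 3*(c2 + 3*((size_t)ca + (size_t)Cin * cb)))] = (double)GWs(ca, cb);
      }
  if (!need_gx)
    return List::create(_["gx"] = R_NilValue, _["gw"] = gw, _["gb"] = gb);
  arma::fmat GX(Np, Cin, arma::fill::zeros);
  conv_padded_f(G, GX, REAL(w), Cout, Cin, D1, D2, D3, true);
  NumericVector gx = alloc_arr({d1, d2, d3, Cin});
  unpad_channels_f(GX, d1, d2, d3, Cin, REAL(gx), nullptr);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Non-overlapping strided convolution (kernel == stride == f per axis);
// used for V-Net downsampling.  weight dim c(f1,f2,f3,Cin,Cout).
// ---------------------------------------------------------------------------

static void gather_blocks(const double* x, int d1, int d2, int d3, int Cin,
                          int f1, int f2, int f3, arma::mat& cols) {
  const int o1 = d1 / f1, o2 = d2 / f2, o3 = d3 / f3;
  const int No = o1 * o2 * o3, pf = f1 * f2 * f3;
  const size_t N = (size_t)d1 * d2 * d3;
  cols.set_size(No, pf * Cin);
  for (int cin = 0; cin < Cin; ++cin) {
    const double* xc = x + (size_t)cin * N;
    for (int cc = 0; cc < f3; ++cc)
      for (int bb = 0; bb < f2; ++bb)
        for (int aa = 0; aa < f1; ++aa) {
          int r = aa + f1 * bb + f1 * f2 * cc + pf * cin;
          double* col = cols.colptr(r);
          for (int k = 0; k < o3; ++k)
            for (int j = 0; j < o2; ++j) {
              const double* src = xc + (size_t)aa + (size_t)d1 * ((size_t)(f2 * j + bb) + (size_t)d2 * (f3 * k + cc));
              double* dst = col + (size_t)0 + (size_t)o1 * (j + (size_t)o2 * k);
              if (f1 == 1) std::memcpy(dst, src, sizeof(double) * o1);
              else for (int i = 0; i < o1; ++i) dst[i] = src[(size_t)i * f1];
            }
        }
  }
}

static void scatter_blocks(const arma::mat& cols, int d1, int d2, int d3, int Cin,
                           int f1, int f2, int f3, double* gx) {
  const int o1 = d1 / f1, o2 = d2 / f2, o3 = d3 / f3;
  const int pf = f1 * f2 * f3;
  const size_t N = (size_t)d1 * d2 * d3;
  for (int cin = 0; cin < Cin; ++cin) {
    double* gxc = gx + (size_t)cin * N;
    for (int cc = 0; cc < f3; ++cc)
      for (int bb = 0; bb < f2; ++bb)
        for (int aa = 0; aa < f1; ++aa) {
          int r = aa + f1 * bb + f1 * f2 * cc + pf * cin;
          const double* col = cols.colptr(r);
          for (int k = 0; k < o3; ++k)
            for (int j = 0; j < o2; ++j) {
              double* dst = gxc + (size_t)aa + (size_t)d1 * ((size_t)(f2 * j + bb) + (size_t)d2 * (f3 * k + cc));
              const double* src = col + (size_t)o1 * (j + (size_t)o2 * k);
              if (f1 == 1) std::memcpy(dst, src, sizeof(double) * o1);
              else for (int i = 0; i < o1; ++i) dst[(size_t)i * f1] = src[i];
            }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_blockdown_fwd(NumericVector x, NumericVector w, NumericVector b, IntegerVector f) {
  int d1, d2, d3, Cin;
  get_dims4(x, d1, d2, d3, Cin);
  int f1 = f[0], f2 = f[1], f3 = f[2];
  if (d1 % f1 || d2 % f2 || d3 % f3) stop("input not divisible by stride");
  IntegerVector wd = w.attr("dim");
  int Cout = wd[4];
  int o1 = d1 / f1, o2 = d2 / f2, o3 = d3 / f3;
  int No = o1 * o2 * o3;
  arma::mat cols;
  gather_blocks(REAL(x), d1, d2, d3, Cin, f1, f2, f3, cols);
  arma::mat W(const_cast<double*>(REAL(w)), f1 * f2 * f3 * Cin, Cout, false, true);
  NumericVector out = alloc_arr({o1, o2, o3, Cout});
  arma::mat O(REAL(out), No, Cout, false, true);
  O = cols * W;
  for (int c = 0; c < Cout; ++c) O.col(c) += b[c];
  return out;
}

// [[Rcpp::export]]
List cpp_blockdown_bwd(NumericVector x, NumericVector w, NumericVector gy, IntegerVector f) {
  int d1, d2, d3, Cin;
  get_dims4(x, d1, d2, d3, Cin);
  int f1 = f[0], f2 = f[1], f3 = f[2];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[4];
  int No = (d1 / f1) * (d2 / f2) * (d3 / f3);
  arma::mat cols;
  gather_blocks(REAL(x), d1, d2, d3, Cin, f1, f2, f3, cols);
  arma::mat W(const_cast<double*>(REAL(w)), f1 * f2 * f3 * Cin, Cout, false, true);
  arma::mat GY(const_cast<double*>(REAL(gy)), No, Cout, false, true);
  NumericVector gw = alloc_arr({f1, f2, f3, Cin, Cout});
  arma::mat GW(REAL(gw), f1 * f2 * f3 * Cin, Cout, false, true);
  GW = cols.t() * GY;
  NumericVector gb(Cout);
  for (int c = 0; c < Cout; ++c) gb[c] = arma::accu(GY.col(c));
  arma::mat gcols = GY * W.t();
  NumericVector gx = alloc_arr({d1, d2, d3, Cin});
  scatter_blocks(gcols, d1, d2, d3, Cin, f1, f2, f3, REAL(gx));
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Non-overlapping transposed convolution (kernel == stride == f per axis);
// used for V-Net upsampling.  weight dim c(f1,f2,f3,Cout,Cin).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_blockup_fwd(NumericVector x, NumericVector w, NumericVector b, IntegerVector f) {
  int d1, d2, d3, Cin;
  get_dims4(x, d1, d2, d3, Cin);
  int f1 = f[0], f2 = f[1], f3 = f[2];
  IntegerVector wd = w.attr("dim");
  if (wd[4] != Cin) stop("weight/input channel mismatch");
  int Cout = wd[3];
  int u1 = d1 * f1, u2 = d2 * f2, u3 = d3 * f3;
  int Nin = d1 * d2 * d3;
  arma::mat X(const_cast<double*>(REAL(x)), Nin, Cin, false, true);
  arma::mat W(const_cast<double*>(REAL(w)), f1 * f2 * f3 * Cout, Cin, false, true);
  arma::mat blocks = W * X.t();  // (pf*Cout) x Nin
  NumericVector out = alloc_arr({u1, u2, u3, Cout});
  double* y = REAL(out);
  const int pf = f1 * f2 * f3;
  const size_t Nu = (size_t)u1 * u2 * u3;
  for (int cout = 0; cout < Cout; ++cout) {
    double* yc = y + (size_t)cout * Nu;
    for (int cc = 0; cc < f3; ++cc)
      for (int bb = 0; bb < f2; ++bb)
        for (int aa = 0; aa < f1; ++aa) {
          int r = aa + f1 * bb + f1 * f2 * cc + pf * cout;
          for (int k = 0; k < d3; ++k)
            for (int j = 0; j < d2; ++j) {
              double* dst = yc + (size_t)aa + (size_t)u1 * ((size_t)(f2 * j + bb) + (size_t)u2 * (f3 * k + cc));
              const double* src = blocks.colptr(0) ;
              for (int i = 0; i < d1; ++i) {
                size_t n = (size_t)i + (size_t)d1 * (j + (size_t)d2 * k);
                dst[(size_t)i * f1] = blocks(r, n) + b[cout];
              }
              (void)src;
            }
        }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_blockup_bwd(NumericVector x, NumericVector w, NumericVector gy, IntegerVector f) {
  int d1, d2, d3, Cin;
  get_dims4(x, d1, d2, d3, Cin);
  int f1 = f[0], f2 = f[1], f3 = f[2];
  IntegerVector wd = w.attr("dim");
  int Cout = wd[3];
  int u1 = d1 * f1, u2 = d2 * f2, u3 = d3 * f3;
  int Nin = d1 * d2 * d3;
  const int pf = f1 * f2 * f3;
  const size_t Nu = (size_t)u1 * u2 * u3;
  // gather gy into block layout: (pf*Cout) x Nin
  arma::mat gblocks(pf * Cout, Nin);
  const double* gyp = REAL(gy);
  NumericVector gb(Cout);
  for (int cout = 0; cout < Cout; ++cout) {
    const double* gc = gyp + (size_t)cout * Nu;
    double acc = 0.0;
    for (size_t t = 0; t < Nu; ++t) acc += gc[t];
    gb[cout] = acc;
    for (int cc = 0; cc < f3; ++cc)
      for (int bb = 0; bb < f2; ++bb)
        for (int aa = 0; aa < f1; ++aa) {
          int r = aa + f1 * bb + f1 * f2 * cc + pf * cout;
          for (int k = 0; k < d3; ++k)
            for (int j = 0; j < d2; ++j) {
              const double* src = gc + (size_t)aa + (size_t)u1 * ((size_t)(f2 * j + bb) + (size_t)u2 * (f3 * k + cc));
              for (int i = 0; i < d1; ++i) {
                size_t n = (size_t)i + (size_t)d1 * (j + (size_t)d2 * k);
                gblocks(r, n) = src[(size_t)i * f1];
              }
            }
        }
  }
  arma::mat X(const_cast<double*>(REAL(x)), Nin, Cin, false, true);
  arma::mat W(const_cast<double*>(REAL(w)), pf * Cout, Cin, false, true);
  NumericVector gw = alloc_arr({f1, f2, f3, Cout, Cin});
  arma::mat GW(REAL(gw), pf * Cout, Cin, false, true);
  GW = gblocks * X;
  NumericVector gx = alloc_arr({d1, d2, d3, Cin});
  arma::mat GX(REAL(gx), Nin, Cin, false, true);
  GX = gblocks.t() * W;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Non-overlapping max pooling with per-axis factor (U-Net downsampling)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector f) {
  int d1, d2, d3, C;
  get_dims4(x, d1, d2, d3, C);
  int f1 = f[0], f2 = f[1], f3 = f[2];
  if (d1 % f1 || d2 % f2 || d3 % f3) stop("input not divisible by pool factor");
  int o1 = d1 / f1, o2 = d2 / f2, o3 = d3 / f3;
  NumericVector out = alloc_arr({o1, o2, o3, C});
  IntegerVector arg = alloc_int_arr({o1, o2, o3, C});
  const double* xp = REAL(x);
  double* yp = REAL(out);
  int* ap = INTEGER(arg);
  const size_t N = (size_t)d1 * d2 * d3;
  size_t n = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * N;
    for (int k = 0; k < o3; ++k)
      for (int j = 0; j < o2; ++j)
        for (int i = 0; i < o1; ++i, ++n) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int cc = 0; cc < f3; ++cc)
            for (int bb = 0; bb < f2; ++bb)
              for (int aa = 0; aa < f1; ++aa) {
                size_t idx = (size_t)(f1 * i + aa) + (size_t)d1 * ((size_t)(f2 * j + bb) + (size_t)d2 * (f3 * k + cc));
                if (xc[idx] > best) { best = xc[idx]; bidx = idx; }
              }
          yp[n] = best;
          ap[n] = (int)((size_t)c * N + bidx);
        }
  }
  return List::create(_["y"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector argmax, NumericVector gy, IntegerVector in_dims) {
  NumericVector gx = alloc_arr({in_dims[0], in_dims[1], in_dims[2], in_dims[3]});
  double* gxp = REAL(gx);
  const double* gyp = REAL(gy);
  const int* ap = INTEGER(argmax);
  R_xlen_t n = gy.size();
  for (R_xlen_t t = 0; t < n; ++t) gxp[ap[t]] += gyp[t];
  return gx;
}

// ---------------------------------------------------------------------------
// Trilinear resize to arbitrary output grid (half-voxel centre alignment)
// ---------------------------------------------------------------------------

static void axis_map(int din, int dout, std::vector<int>& i0, std::vector<int>& i1, std::vector<double>& wf) {
  i0.resize(dout); i1.resize(dout); wf.resize(dout);
  for (int o = 0; o < dout; ++o) {
    double src = (o + 0.5) * (double)din / dout - 0.5;
    if (src < 0) src = 0;
    if (src > din - 1) src = din - 1;
    int a = (int)std::floor(src);
    if (a > din - 2) a = std::max(0, din - 2);
    i0[o] = a;
    i1[o] = std::min(a + 1, din - 1);
    wf[o] = src - a;
  }
}

// [[Rcpp::export]]
NumericVector cpp_resize_fwd(NumericVector x, IntegerVector out_dims) {
  int d1, d2, d3, C;
  get_dims4(x, d1, d2, d3, C);
  int o1 = out_dims[0], o2 = out_dims[1], o3 = out_dims[2];
  std::vector<int> a0, a1, b0, b1, c0, c1;
  std::vector<double> wa, wb, wc;
  axis_map(d1, o1, a0, a1, wa);
  axis_map(d2, o2, b0, b1, wb);
  axis_map(d3, o3, c0, c1, wc);
  NumericVector out = alloc_arr({o1, o2, o3, C});
  const double* xp = REAL(x);
  double* yp = REAL(out);
  const size_t N = (size_t)d1 * d2 * d3;
  size_t n = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * N;
    for (int k = 0; k < o3; ++k)
      for (int j = 0; j < o2; ++j)
        for (int i = 0; i < o1; ++i, ++n) {
          double v = 0;
          for (int zc = 0; zc < 2; ++zc) {
            int kk = zc ? c1[k] : c0[k];
            double wz = zc ? wc[k] : 1 - wc[k];
            if (wz == 0) continue;
            for (int yc2 = 0; yc2 < 2; ++yc2) {
              int jj = yc2 ? b1[j] : b0[j];
              double wy = yc2 ? wb[j] : 1 - wb[j];
              if (wy == 0) continue;
              for (int xc2 = 0; xc2 < 2; ++xc2) {
                int ii = xc2 ? a1[i] : a0[i];
                double wx = xc2 ? wa[i] : 1 - wa[i];
                if (wx == 0) continue;
                v += wz * wy * wx * xc[(size_t)ii + (size_t)d1 * (jj + (size_t)d2 * kk)];
              }
            }
          }
          yp[n] = v;
        }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bwd(NumericVector gy, IntegerVector in_dims) {
  IntegerVector od = gy.attr("dim");
  int o1 = od[0], o2 = od[1], o3 = od[2], C = od[3];
  int d1 = in_dims[0], d2 = in_dims[1], d3 = in_dims[2];
  std::vector<int> a0, a1, b0, b1, c0, c1;
  std::vector<double> wa, wb, wc;
  axis_map(d1, o1, a0, a1, wa);
  axis_map(d2, o2, b0, b1, wb);
  axis_map(d3, o3, c0, c1, wc);
  NumericVector gx = alloc_arr({d1, d2, d3, C});
  double* gxp = REAL(gx);
  const double* gyp = REAL(gy);
  const size_t N = (size_t)d1 * d2 * d3;
  size_t n = 0;
  for (int c = 0; c < C; ++c) {
    double* gxc = gxp + (size_t)c * N;
    for (int k = 0; k < o3; ++k)
      for (int j = 0; j < o2; ++j)
        for (int i = 0; i < o1; ++i, ++n) {
          double g = gyp[n];
          if (g == 0) continue;
          for (int zc = 0; zc < 2; ++zc) {
            int kk = zc ? c1[k] : c0[k];
            double wz = zc ? wc[k] : 1 - wc[k];
            if (wz == 0) continue;
            for (int yc2 = 0; yc2 < 2; ++yc2) {
              int jj = yc2 ? b1[j] : b0[j];
              double wy = yc2 ? wb[j] : 1 - wb[j];
              if (wy == 0) continue;
              for (int xc2 = 0; xc2 < 2; ++xc2) {
                int ii = xc2 ? a1[i] : a0[i];
                double wx = xc2 ? wa[i] : 1 - wa[i];
                if (wx == 0) continue;
                gxc[(size_t)ii + (size_t)d1 * (jj + (size_t)d2 * kk)] += g * wz * wy * wx;
              }
            }
          }
        }
  }
  return gx;
}

// ---------------------------------------------------------------------------
// Sampling a 3-d scalar grid at arbitrary continuous coordinates
// (spatial augmentation warps).  coords: Nout x 3, 0-based voxel units.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector x, NumericMatrix coords, IntegerVector out_dims,
                       int method, double fill) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("warp expects a 3-d array");
  int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  R_xlen_t N = coords.nrow();
  NumericVector out = alloc_arr({out_dims[0], out_dims[1], out_dims[2]});
  if ((R_xlen_t)out_dims[0] * out_dims[1] * out_dims[2] != N) stop("coords/out_dims mismatch");
  const double* xp = REAL(x);
  double* yp = REAL(out);
  for (R_xlen_t n = 0; n < N; ++n) {
    double px = coords(n, 0), py = coords(n, 1), pz = coords(n, 2);
    if (method == 0) {  // nearest
      long i = (long)std::lround(px), j = (long)std::lround(py), k = (long)std::lround(pz);
      if (i < 0 || i >= d1 || j < 0 || j >= d2 || k < 0 || k >= d3) { yp[n] = fill; continue; }
      yp[n] = xp[(size_t)i + (size_t)d1 * (j + (size_t)d2 * k)];
    } else {           // trilinear, out-of-bounds corners read the fill value
      double v = 0;
      long i0 = (long)std::floor(px), j0 = (long)std::floor(py), k0 = (long)std::floor(pz);
      double fx = px - i0, fy = py - j0, fz = pz - k0;
      for (int zc = 0; zc < 2; ++zc) {
        long kk = k0 + zc;
        double wz = zc ? fz : 1 - fz;
        if (wz == 0) continue;
        for (int yc = 0; yc < 2; ++yc) {
          long jj = j0 + yc;
          double wy = yc ? fy : 1 - fy;
          if (wy == 0) continue;
          for (int xc = 0; xc < 2; ++xc) {
            long ii = i0 + xc;
            double wx = xc ? fx : 1 - fx;
            if (wx == 0) continue;
            double s = (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
                         ? fill : xp[(size_t)ii + (size_t)d1 * (jj + (size_t)d2 * kk)];
            v += wz * wy * wx * s;
          }
        }
      }
      yp[n] = v;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing of a 3-d grid (edge-clamped)
// ---------------------------------------------------------------------------

static void smooth_axis(std::vector<double>& buf, double* x, int d1, int d2, int d3,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * radius + 1);
  double s = 0;
  for (int t = -radius; t <= radius; ++t) {
    kern[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += kern[t + radius];
  }
  for (auto& v : kern) v /= s;
  int dims[3] = {d1, d2, d3};
  int n = dims[axis];
  buf.resize(n);
  size_t stride = 1;
  for (int a = 0; a < axis; ++a) stride *= dims[a];
  int nlines = d1 * d2 * d3 / n;
  // iterate over all lines along `axis`
  for (int line = 0; line < nlines; ++line) {
    // compute base index of this line
    size_t base = 0;
    int rem = line;
    size_t mult = 1;
    for (int a = 0; a < 3; ++a) {
      if (a == axis) { mult *= dims[a]; continue; }
      int da = dims[a];
      base += (size_t)(rem % da) * mult;
      rem /= da;
      mult *= da;
    }
    for (int t = 0; t < n; ++t) buf[t] = x[base + (size_t)t * stride];
    for (int t = 0; t < n; ++t) {
      double acc = 0;
      for (int u = -radius; u <= radius; ++u) {
        int p = t + u;
        if (p < 0) p = 0;
        if (p >= n) p = n - 1;
        acc += kern[u + radius] * buf[p];
      }
      x[base + (size_t)t * stride] = acc;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector x, NumericVector sigma) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("expected a 3-d array");
  NumericVector y = clone(x);
  std::vector<double> buf;
  for (int axis = 0; axis < 3; ++axis)
    smooth_axis(buf, REAL(y), dm[0], dm[1], dm[2], axis, sigma[axis]);
  return y;
}

// ---------------------------------------------------------------------------
// Instance normalization (per channel over the spatial grid, affine)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_instnorm_fwd(NumericVector x, NumericVector gamma, NumericVector beta, double eps) {
  int d1, d2, d3, C;
  get_dims4(x, d1, d2, d3, C);
  const size_t N = (size_t)d1 * d2 * d3;
  NumericVector y = alloc_arr({d1, d2, d3, C});
  NumericVector mu(C), istd(C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + N * c;
    double* yc = yp + N * c;
    double s = 0, s2 = 0;
    for (size_t t = 0; t < N; ++t) { s += xc[t]; s2 += xc[t] * xc[t]; }
    double m = s / N;
    double var = s2 / N - m * m;
    if (var < 0) var = 0;
    double is = 1.0 / std::sqrt(var + eps);
    double g = gamma[c] * is, b = beta[c] - m * g;
    for (size_t t = 0; t < N; ++t) yc[t] = xc[t] * g + b;
    mu[c] = m; istd[c] = is;
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_instnorm_bwd(NumericVector x, NumericVector gamma, NumericVector gy,
                      NumericVector mu, NumericVector istd) {
  int d1, d2, d3, C;
  get_dims4(x, d1, d2, d3, C);
  const size_t N = (size_t)d1 * d2 * d3;
  NumericVector gx = alloc_arr({d1, d2, d3, C});
  NumericVector dgamma(C), dbeta(C);
  const double* xp = REAL(x);
  const double* gp = REAL(gy);
  double* gxp = REAL(gx);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + N * c;
    const double* gc = gp + N * c;
    double* gxc = gxp + N * c;
    double m = mu[c], is = istd[c], gam = gamma[c];
    double sg = 0, sgx = 0;
    for (size_t t = 0; t < N; ++t) {
      double xh = (xc[t] - m) * is;
      sg += gc[t];
      sgx += gc[t] * xh;
    }
    dbeta[c] = sg;
    dgamma[c] = sgx;
    double m1 = gam * sg / N, m2 = gam * sgx / N;
    for (size_t t = 0; t < N; ++t) {
      double xh = (xc[t] - m) * is;
      gxc[t] = is * (gam * gc[t] - m1 - xh * m2);
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}


// ---------------------------------------------------------------------------
// Fused elementwise helpers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  double* yp = REAL(y);
  R_xlen_t n = x.size();
  for (R_xlen_t t = 0; t < n; ++t) yp[t] = xp[t] > 0 ? xp[t] : slope * xp[t];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bwd(NumericVector x, NumericVector gy, double slope) {
  NumericVector g(x.size());
  g.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  const double* gp = REAL(gy);
  double* out = REAL(g);
  R_xlen_t n = x.size();
  for (R_xlen_t t = 0; t < n; ++t) out[t] = xp[t] > 0 ? gp[t] : slope * gp[t];
  return g;
}

// Inverted dropout.  The per-element mask comes from a xorshift64* stream
// whose seed is drawn from R's RNG, so results are reproducible under
// set.seed while avoiding a slow per-element unif_rand call.
// [[Rcpp::export]]
List cpp_dropout_fwd(NumericVector x, double p) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  y.attr("dim") = x.attr("dim");
  RawVector keep(n);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  Rbyte* kp = RAW(keep);
  double scale = 1.0 / (1.0 - p);
  GetRNGstate();
  uint64_t s = (uint64_t)(unif_rand() * 4294967296.0) << 32 ^
               (uint64_t)(unif_rand() * 4294967296.0);
  PutRNGstate();
  if (s == 0) s = 0x9E3779B97F4A7C15ULL;
  uint64_t thresh = (uint64_t)(p * 18446744073709551615.0);
  for (R_xlen_t t = 0; t < n; ++t) {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    uint64_t r = s * 0x2545F4914F6CDD1DULL;
    int k = r >= thresh;
    kp[t] = (Rbyte)k;
    yp[t] = k ? xp[t] * scale : 0.0;
  }
  return List::create(_["y"] = y, _["keep"] = keep, _["scale"] = scale);
}

// [[Rcpp::export]]
NumericVector cpp_dropout_bwd(RawVector keep, NumericVector gy, double scale) {
  R_xlen_t n = gy.size();
  NumericVector g(n);
  g.attr("dim") = gy.attr("dim");
  const Rbyte* kp = RAW(keep);
  const double* gp = REAL(gy);
  double* out = REAL(g);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = kp[t] ? gp[t] * scale : 0.0;
  return g;
}


// ---------------------------------------------------------------------------
// 1x1x1 convolution (channel mixing) without reshaping copies
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv1_fwd(NumericVector x, NumericMatrix w, NumericVector b) {
  int d1, d2, d3, Cin;
  get_dims4(x, d1, d2, d3, Cin);
  if (w.nrow() != Cin) stop("1x1x1 conv: channel mismatch");
  int Cout = w.ncol();
  int N = d1 * d2 * d3;
  NumericVector y = alloc_arr({d1, d2, d3, Cout});
  double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &N, &Cout, &Cin, &one, REAL(x), &N,
                  REAL(w), &Cin, &zero, REAL(y), &N FCONE FCONE);
  double* yp = REAL(y);
  for (int c = 0; c < Cout; ++c) {
    double bc = b[c];
    if (bc != 0.0) for (int t = 0; t < N; ++t) yp[(size_t)N * c + t] += bc;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv1_bwd(NumericVector x, NumericMatrix w, NumericVector gy) {
  int d1, d2, d3, Cin;
  get_dims4(x, d1, d2, d3, Cin);
  int Cout = w.ncol();
  int N = d1 * d2 * d3;
  NumericVector gx = alloc_arr({d1, d2, d3, Cin});
  NumericMatrix gw(Cin, Cout);
  NumericVector gb(Cout);
  double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "T", &N, &Cin, &Cout, &one, REAL(gy), &N,
                  REAL(w), &Cin, &zero, REAL(gx), &N FCONE FCONE);
  F77_CALL(dgemm)("T", "N", &Cin, &Cout, &N, &one, REAL(x), &N,
                  REAL(gy), &N, &zero, REAL(gw), &Cin FCONE FCONE);
  const double* gp = REAL(gy);
  for (int c = 0; c < Cout; ++c) {
    double acc = 0.0;
    for (int t = 0; t < N; ++t) acc += gp[(size_t)N * c + t];
    gb[c] = acc;
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Fused softmax + (dice + cross-entropy) loss and gradient w.r.t. logits
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_loss_grad(NumericVector logits, IntegerVector labels, int num_classes,
                   double eps, double clamp) {
  IntegerVector dm = logits.attr("dim");
  int C = dm[3];
  if (C != num_classes) stop("logit channels != num_classes");
  R_xlen_t N = (R_xlen_t)dm[0] * dm[1] * dm[2];
  if (labels.size() != N) stop("labels/logits shape mismatch");
  const double* zp = REAL(logits);
  const int* lp = INTEGER(labels);
  NumericVector u(logits.size());
  u.attr("dim") = logits.attr("dim");
  double* up = REAL(u);
  std::vector<double> num(C, 0.0), denU(C, 0.0), cnt(C, 0.0);
  double ce = 0.0;
  std::vector<double> uv(C);
  for (R_xlen_t t = 0; t < N; ++t) {
    double mx = zp[t];
    for (int c = 1; c < C; ++c) mx = std::max(mx, zp[t + N * c]);
    double sum = 0.0;
    for (int c = 0; c < C; ++c) { uv[c] = std::exp(zp[t + N * c] - mx); sum += uv[c]; }
    int lab = lp[t];
    for (int c = 0; c < C; ++c) {
      double uc = uv[c] / sum;
      up[t + N * c] = uc;
      denU[c] += uc;
      if (c == lab) num[c] += uc;
    }
    cnt[lab] += 1.0;
    ce -= std::log(std::max(up[t + N * lab], clamp));
  }
  ce /= N;
  double l_dice = 0.0;
  std::vector<double> den(C), t1(C), t2(C);
  for (int c = 0; c < C; ++c) {
    den[c] = denU[c] + cnt[c] + eps;
    l_dice += num[c] / den[c];
    t1[c] = -2.0 / C / den[c];                 // coefficient of v_ic
    t2[c] = 2.0 / C * num[c] / (den[c] * den[c]);  // constant per class
  }
  l_dice *= -2.0 / C;
  // grad wrt u, then through the softmax: gz = u * (gu - sum_c gu*u)
  NumericVector gz(logits.size());
  gz.attr("dim") = logits.attr("dim");
  double* gzp = REAL(gz);
  for (R_xlen_t t = 0; t < N; ++t) {
    int lab = lp[t];
    double dot = 0.0;
    for (int c = 0; c < C; ++c) {
      double uc = up[t + N * c];
      double gu = t2[c];
      if (c == lab) {
        gu += t1[c];
        gu += -1.0 / (N * std::max(uc, clamp));  // cross-entropy term
      }
      uv[c] = gu;
      dot += gu * uc;
    }
    for (int c = 0; c < C; ++c)
      gzp[t + N * c] = up[t + N * c] * (uv[c] - dot);
  }
  return List::create(_["total"] = l_dice + ce, _["dice"] = l_dice,
                      _["cross_entropy"] = ce, _["grad_logits"] = gz,
                      _["u"] = u);
}


// broadcast-multiply a C-channel activation by a single-channel map
// [[Rcpp::export]]
NumericVector cpp_mul_alpha_fwd(NumericVector x, NumericVector alpha) {
  int d1, d2, d3, C;
  get_dims4(x, d1, d2, d3, C);
  R_xlen_t N = (R_xlen_t)d1 * d2 * d3;
  if (alpha.size() != N) stop("alpha grid does not match feature grid");
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  const double* ap = REAL(alpha);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + N * c;
    double* yc = yp + N * c;
    for (R_xlen_t t = 0; t < N; ++t) yc[t] = xc[t] * ap[t];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_mul_alpha_bwd(NumericVector x, NumericVector alpha, NumericVector gy) {
  int d1, d2, d3, C;
  get_dims4(x, d1, d2, d3, C);
  R_xlen_t N = (R_xlen_t)d1 * d2 * d3;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector ga(N);
  ga.attr("dim") = alpha.attr("dim");
  const double* xp = REAL(x);
  const double* ap = REAL(alpha);
  const double* gp = REAL(gy);
  double* gxp = REAL(gx);
  double* gap = REAL(ga);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + N * c;
    const double* gc = gp + N * c;
    double* gxc = gxp + N * c;
    for (R_xlen_t t = 0; t < N; ++t) {
      gxc[t] = gc[t] * ap[t];
      gap[t] += gc[t] * xc[t];
    }
  }
  return List::create(_["gx"] = gx, _["ga"] = ga);
}

// ---------------------------------------------------------------------------
// Fused instance norm + leaky ReLU (the tail of every conv block)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_in_lrelu_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                      double eps, double slope) {
  int d1, d2, d3, C;
  get_dims4(x, d1, d2, d3, C);
  const size_t N = (size_t)d1 * d2 * d3;
  NumericVector y = alloc_arr({d1, d2, d3, C});
  NumericVector mu(C), istd(C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + N * c;
    double* yc = yp + N * c;
    double s = 0, s2 = 0;
    for (size_t t = 0; t < N; ++t) { s += xc[t]; s2 += xc[t] * xc[t]; }
    double m = s / N;
    double var = s2 / N - m * m;
    if (var < 0) var = 0;
    double is = 1.0 / std::sqrt(var + eps);
    double g = gamma[c] * is, b = beta[c] - m * g;
    for (size_t t = 0; t < N; ++t) {
      double v = xc[t] * g + b;
      yc[t] = v > 0 ? v : slope * v;
    }
    mu[c] = m; istd[c] = is;
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_in_lrelu_bwd(NumericVector x, NumericVector gamma, NumericVector beta,
                      NumericVector gy, NumericVector mu, NumericVector istd,
                      double slope) {
  int d1, d2, d3, C;
  get_dims4(x, d1, d2, d3, C);
  const size_t N = (size_t)d1 * d2 * d3;
  NumericVector gx = alloc_arr({d1, d2, d3, C});
  NumericVector dgamma(C), dbeta(C);
  const double* xp = REAL(x);
  const double* gp = REAL(gy);
  double* gxp = REAL(gx);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + N * c;
    const double* gc = gp + N * c;
    double* gxc = gxp + N * c;
    double m = mu[c], is = istd[c], gam = gamma[c], bet = beta[c];
    double sg = 0, sgx = 0;
    for (size_t t = 0; t < N; ++t) {
      double xh = (xc[t] - m) * is;
      double pre = xh * gam + bet;
      double g2 = pre > 0 ? gc[t] : slope * gc[t];  // through the leaky ReLU
      gxc[t] = g2;                                  // stash g2
      sg += g2;
      sgx += g2 * xh;
    }
    dbeta[c] = sg;
    dgamma[c] = sgx;
    double m1 = gam * sg / N, m2 = gam * sgx / N;
    for (size_t t = 0; t < N; ++t) {
      double xh = (xc[t] - m) * is;
      gxc[t] = is * (gam * gxc[t] - m1 - xh * m2);
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
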