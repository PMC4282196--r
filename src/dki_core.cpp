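// Voxel-loop kernels for the DKI pipeline: batched weighted linear
// least-squares fitting of the 22-parameter kurtosis signal model,
// eigenframe kurtosis metrics, separable Gaussian smoothing, and 3D
// connected-component labelling. Kept in C++ because they run once per
// voxel (or per Monte-Carlo iteration) over whole volumes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Flag bits shared with R/fit.R (keep in sync with .dki_flags there).
static const int FLAG_NONPOS_SIGNAL = 1;  // some volumes excluded (S <= 0)
static const int FLAG_FIT_FAIL      = 2;  // unusable voxel / singular design
static const int FLAG_NONPD_D       = 4;  // diffusion tensor not positive definite
static const int FLAG_CLIPPED       = 8;  // a kurtosis metric hit the clip range

// Unique kurtosis-tensor element index quadruples (0-based) and their
// multinomial multiplicities in the quartic form sum_{ijkl} n_i n_j n_k n_l W_ijkl.
static const int W_IDX[15][4] = {
  {0,0,0,0},{1,1,1,1},{2,2,2,2},
  {0,0,0,1},{0,0,0,2},{0,1,1,1},{1,1,1,2},{0,2,2,2},{1,2,2,2},
  {0,0,1,1},{0,0,2,2},{1,1,2,2},
  {0,0,1,2},{0,1,1,2},{0,1,2,2}};
static const double W_MULT[15] = {1,1,1,4,4,4,4,4,4,6,6,6,12,12,12};

static inline double quartic_form(const double *w15, const double n[3]) {
  double s = 0.0;
  for (int k = 0; k < 15; ++k) {
    const int *q = W_IDX[k];
    s += W_MULT[k] * n[q[0]] * n[q[1]] * n[q[2]] * n[q[3]] * w15[k];
  }
  return s;
}

// Fit ln S = X beta per voxel by WLLS: unweighted initial solve, then one
// reweighting pass with weights equal to the squared predicted signal.
// Y: nvol x nvox signal matrix; X: nvol x p design matrix.
// Voxels whose signals are all positive share one precomputed unweighted
// solve; the reweighting pass uses Cholesky-factorised normal equations.
// [[Rcpp::export]]
List cpp_wlls_fit(const arma::mat& Y, const arma::mat& X) {
  const arma::uword nvol = Y.n_rows, nvox = Y.n_cols, p = X.n_cols;
  arma::mat beta(p, nvox, arma::fill::value(arma::datum::nan));
  IntegerVector flags(nvox);
  arma::mat P;  // p x nvol pseudo-inverse for the all-volumes case
  bool haveP = arma::pinv(P, X);

  arma::vec b0(p), b1(p), w(nvol), ly(nvol);
  arma::mat Xw(nvol, p), A(p, p);
  for (arma::uword v = 0; v < nvox; ++v) {
    arma::uvec use = arma::find(Y.col(v) > 0.0);
    int fl = 0;
    if (use.n_elem < nvol) fl |= FLAG_NONPOS_SIGNAL;
    if (use.n_elem < p) { flags[v] = fl | FLAG_FIT_FAIL; continue; }
    const bool full = (use.n_elem == nvol);
    bool ok;
    if (full && haveP) {
      ly = arma::log(Y.col(v));
      b0 = P * ly;
      ok = b0.is_finite();
    } else {
      arma::mat Xu = X.rows(use);
      arma::vec lyu = arma::log(arma::vec(Y.col(v)).elem(use));
      ok = arma::solve(b0, Xu, lyu, arma::solve_opts::no_approx) && b0.is_finite();
      if (ok) {
        arma::vec wu = arma::exp(2.0 * (Xu * b0));
        arma::mat Xwu = Xu.each_col() % arma::sqrt(wu);
        ok = arma::solve(b1, Xwu, lyu % arma::sqrt(wu),
                         arma::solve_opts::no_approx) && b1.is_finite();
        if (ok) { beta.col(v) = b1; flags[v] = fl; }
        else flags[v] = fl | FLAG_FIT_FAIL;
        continue;
      }
    }
    if (!ok) { flags[v] = fl | FLAG_FIT_FAIL; continue; }
    // one reweighting pass: w_i = S_hat_i^2 = exp(2 * x_i' b0)
    w = arma::exp(2.0 * (X * b0));
    Xw = X.each_col() % w;
    A = X.t() * Xw;                 // X' diag(w) X
    ok = arma::solve(b1, A, Xw.t() * ly,
                     arma::solve_opts::likely_sympd + arma::solve_opts::no_approx) &&
         b1.is_finite();
    if (!ok) {
      // normal equations can lose precision when the weights span many
      // orders of magnitude; fall back to a weighted QR least-squares solve
      arma::vec sw = arma::sqrt(w);
      Xw = X.each_col() % sw;
      ok = arma::solve(b1, Xw, ly % sw, arma::solve_opts::no_approx) &&
           b1.is_finite();
    }
    if (!ok) { flags[v] = fl | FLAG_FIT_FAIL; continue; }
    beta.col(v) = b1;
    flags[v] = fl;
  }
  return List::create(_["beta"] = beta, _["flags"] = flags);
}

// Eigenframe kurtosis metrics per voxel from fitted parameters.
// params: 22 x nvox (log S0, 6 D elements xx yy zz xy xz yz, 15 V = MD^2*W
// elements in the ordering above). dirs: ndir x 3 unit vectors used for the
// MK directional average. Returns mk, k_axial, k_radial, updated flags.
// [[Rcpp::export]]
List cpp_kurtosis_maps(const arma::mat& params, const arma::mat& dirs,
                       IntegerVector flags_in, double clip_lo, double clip_hi) {
  const arma::uword nvox = params.n_cols, ndir = dirs.n_rows;
  NumericVector mk(nvox, NA_REAL), ka(nvox, NA_REAL), kr(nvox, NA_REAL);
  IntegerVector flags = clone(flags_in);

  for (arma::uword v = 0; v < nvox; ++v) {
    if (flags[v] & FLAG_FIT_FAIL) continue;
    arma::mat D(3, 3);
    D(0,0) = params(1,v); D(1,1) = params(2,v); D(2,2) = params(3,v);
    D(0,1) = D(1,0) = params(4,v);
    D(0,2) = D(2,0) = params(5,v);
    D(1,2) = D(2,1) = params(6,v);
    double md = arma::trace(D) / 3.0;
    arma::vec eval; arma::mat evec;
    if (!arma::eig_sym(eval, evec, D) || eval(0) <= 0.0 || md <= 0.0) {
      flags[v] |= FLAG_NONPD_D; continue;   // eig_sym is ascending: eval(0) = lambda3
    }
    double w15[15];
    for (int k = 0; k < 15; ++k) w15[k] = params(7 + k, v) / (md * md);

    // MK: average apparent kurtosis over the direction set
    double acc = 0.0; bool bad = false;
    for (arma::uword d = 0; d < ndir; ++d) {
      double n[3] = {dirs(d,0), dirs(d,1), dirs(d,2)};
      double dapp = n[0]*n[0]*D(0,0) + n[1]*n[1]*D(1,1) + n[2]*n[2]*D(2,2) +
        2.0*(n[0]*n[1]*D(0,1) + n[0]*n[2]*D(0,2) + n[1]*n[2]*D(1,2));
      if (dapp <= 0.0) { bad = true; break; }
      acc += (md * md) / (dapp * dapp) * quartic_form(w15, n);
    }
    if (bad) { flags[v] |= FLAG_NONPD_D; continue; }
    double mkv = acc / (double)ndir;

    // axial/radial: kurtosis along eigenvectors, lambda sorted descending
    double kev[3];
    for (int i = 0; i < 3; ++i) {
      int col = 2 - i;                       // descending order
      double lam = eval(col);
      double n[3] = {evec(0,col), evec(1,col), evec(2,col)};
      kev[i] = (md * md) / (lam * lam) * quartic_form(w15, n);
    }
    double kav = kev[0], krv = 0.5 * (kev[1] + kev[2]);

    bool clipped = false;
    double* vals[3] = {&mkv, &kav, &krv};
    for (int i = 0; i < 3; ++i) {
      if (*vals[i] < clip_lo) { *vals[i] = clip_lo; clipped = true; }
      if (*vals[i] > clip_hi) { *vals[i] = clip_hi; clipped = true; }
    }
    if (clipped) flags[v] |= FLAG_CLIPPED;
    mk[v] = mkv; ka[v] = kav; kr[v] = krv;
  }
  return List::create(_["mk"] = mk, _["k_axial"] = ka, _["k_radial"] = kr,
                      _["flags"] = flags);
}

// Separable Gaussian smoothing of a 3D array with zero padding outside the
// grid. sigma is in voxels, per axis; kernels are discretely normalised so a
// constant volume embedded in an infinite domain is preserved.
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector vol, IntegerVector dim,
                           NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  const int strides[3] = {1, nx, nx * ny};
  const int sizes[3] = {nx, ny, nz};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0.0) continue;
    int r = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * r + 1);
    double sum = 0.0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); sum += k[i + r]; }
    for (double& kv : k) kv /= sum;

    const int n = sizes[ax], st = strides[ax];
    const int o1 = (ax == 0) ? ny : nx, o2 = (ax == 2) ? ny : nz;
    const int st1 = (ax == 0) ? nx : 1, st2 = (ax == 2) ? nx : nx * ny;
    for (int j2 = 0; j2 < o2; ++j2)
      for (int j1 = 0; j1 < o1; ++j1) {
        const int base = j1 * st1 + j2 * st2;
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          const int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
          for (int j = lo; j <= hi; ++j) acc += a[base + j * st] * k[j - i + r];
          b[base + i * st] = acc;
        }
      }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// 3D connected components under 6/18/26 connectivity. Returns integer labels
// (0 = background), in scan order of first encounter.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        nb.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<int> stack;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx]) continue;
    lab[idx] = ++next;
    stack.assign(1, idx);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (auto& d : nb) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        int j = xx + nx * (yy + ny * zz);
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
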