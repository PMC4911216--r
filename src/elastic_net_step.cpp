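// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// One elastic-net update of the cortical sheet.
//
// Y: N x d cortical reference vectors, N = H*W nodes stored column-major
//    (node j <-> grid row j % H, grid column j / H, 0-based).
// X: M x d feature points; alpha: M per-feature coverage weights.
//
// Responsibilities p_ij = softmax_j(-|x_i - y_j|^2 / 2K^2), normalised
// over cortical nodes per feature and evaluated with a per-feature
// max-shift (log-sum-exp guard: K shrinks ~5.6-fold over a run and
// plain exp underflows). With the responsibilities held fixed, the
// elastic-net energy is quadratic in Y and the update jumps to its
// minimiser, the solution of the SPD system
//
//   (diag(w) + beta K Lp) Ynew = P' diag(alpha) X,
//   w_j = sum_i alpha_i p_ij,
//
// where Lp = -L is the (positive semidefinite) graph Laplacian of the
// non-periodic 4-neighbour lattice with free boundary. This implicit
// fixed-point step is unconditionally stable (the explicit Euler form
// y += delta diverges here: beta*K*lambda_max(L) >> 2 early in the
// anneal) and monotonically decreases the energy, by the standard
// EM/majorise-minimise argument. Solved by Jacobi-preconditioned
// conjugate gradients on the 5-point stencil, warm-started at Y.
// step_size in (0, 1] interpolates between Y and the minimiser.
//
// [[Rcpp::export]]
arma::mat en_step_cpp(const arma::mat& Y, const arma::mat& X,
                      const arma::vec& alpha, double K, double beta,
                      int H, int W, double step_size = 1.0) {
  const uword N = Y.n_rows, M = X.n_rows, d = Y.n_cols;
  const double inv2K2 = 1.0 / (2.0 * K * K);

  vec yn = sum(square(Y), 1);
  vec xn = sum(square(X), 1);

  mat cover(N, d, fill::zeros);  // sum_i alpha_i p_ij x_i
  vec wsum(N, fill::zeros);      // sum_i alpha_i p_ij

  const uword block = 512;       // feature block: caps the N x B buffer
  mat P;
  vec ab;
  for (uword b0 = 0; b0 < M; b0 += block) {
    const uword b1 = std::min(b0 + block, M) - 1;
    const mat Xb = X.rows(b0, b1);
    const uword B = Xb.n_rows;
    mat G = Y * Xb.t();          // N x B inner products
    P.set_size(N, B);
    ab.set_size(B);
    const double* ynp = yn.memptr();
    for (uword i = 0; i < B; ++i) {
      double* pc = P.colptr(i);
      const double* gc = G.colptr(i);
      const double xni = xn(b0 + i);
      double tmax = -datum::inf;
      for (uword j = 0; j < N; ++j) {
        const double t = (2.0 * gc[j] - ynp[j] - xni) * inv2K2;
        pc[j] = t;
        if (t > tmax) tmax = t;
      }
      const double cut = tmax - 45.0;
      double s = 0.0;
      for (uword j = 0; j < N; ++j) {
        const double t = pc[j];
        const double e = (t < cut) ? 0.0 : std::exp(t - tmax);
        pc[j] = e;
        s += e;
      }
      ab(i) = alpha(b0 + i) / s;  // s >= 1 (the max term)
    }
    // fold the per-feature alpha_i / s_i into the GEMMs
    cover += P * (Xb.each_col() % ab);
    wsum += P * ab;
  }

  const double bk = beta * K;

  if (bk == 0.0) {  // no continuity term: the system is diagonal
    mat Ynew = Y;
    for (uword j = 0; j < N; ++j)
      if (wsum(j) > 1e-300)
        Ynew.row(j) = cover.row(j) / wsum(j);
    return Y + step_size * (Ynew - Y);
  }

  // node degrees on the free-boundary lattice
  vec deg(N);
  for (uword c = 0; c < (uword)W; ++c)
    for (uword r = 0; r < (uword)H; ++r)
      deg(c * H + r) = (r > 0) + (r + 1 < (uword)H) +
                       (c > 0) + (c + 1 < (uword)W);

  // A v = w.*v + bk*(deg.*v - sum of neighbours)
  auto matvec = [&](const vec& v) {
    vec out = wsum % v + bk * (deg % v);
    for (uword c = 0; c < (uword)W; ++c) {
      for (uword r = 0; r < (uword)H; ++r) {
        const uword j = c * H + r;
        double nb = 0.0;
        if (r > 0)            nb += v(j - 1);
        if (r + 1 < (uword)H) nb += v(j + 1);
        if (c > 0)            nb += v(j - H);
        if (c + 1 < (uword)W) nb += v(j + H);
        out(j) -= bk * nb;
      }
    }
    return out;
  };

  mat Ynew(N, d);
  const vec Mi = 1.0 / (wsum + bk * deg + 1e-300);  // Jacobi preconditioner
  for (uword col = 0; col < d; ++col) {
    const vec b = cover.col(col);
    vec x = Y.col(col);                    // warm start
    vec r = b - matvec(x);
    vec z = Mi % r;
    vec p = z;
    double rz = dot(r, z);
    const double btol = std::max(1e-24 * dot(b, b), 1e-300);
    for (int it = 0; it < 1000; ++it) {
      if (dot(r, r) <= btol) break;
      vec Ap = matvec(p);
      const double a = rz / dot(p, Ap);
      x += a * p;
      r -= a * Ap;
      z = Mi % r;
      const double rz_new = dot(r, z);
      p = z + (rz_new / rz) * p;
      rz = rz_new;
    }
    Ynew.col(col) = x;
  }

  return Y + step_size * (Ynew - Y);
}

// Responsibility matrix for small instances (tests / diagnostics only;
// materialises the full N x M matrix).
// [[Rcpp::export]]
arma::mat en_responsibilities_cpp(const arma::mat& Y, const arma::mat& X,
                                  double K) {
  const uword N = Y.n_rows, M = X.n_rows;
  const double inv2K2 = 1.0 / (2.0 * K * K);
  vec yn = sum(square(Y), 1);
  vec xn = sum(square(X), 1);
  mat G = Y * X.t();
  mat P(N, M);
  for (uword i = 0; i < M; ++i) {
    vec t = -(yn + xn(i) - 2.0 * G.col(i)) * inv2K2;
    t -= t.max();
    vec e = exp(t);
    P.col(i) = e / accu(e);
  }
  return P;
}

// Factored elastic-net update for product-structured feature sets.
//
// The feature set is the Cartesian product of ns spatial positions S
// (ns x 2) and nf ocularity/orientation combinations Fm (nf x 3), with
// coverage weights Aw (ns x nf). Because the Gaussian kernel separates
// over the two coordinate blocks, responsibilities factorise as
// p_{(s,f),j} ~ A_js * B_jf, and all sums needed for the update reduce
// to GEMMs of size N x ns x nf, with only N*(ns+nf) exponentials
// instead of N*ns*nf. Per-column max shifts on the exponent matrices
// cancel exactly in the normalised sums (log-sum-exp guard). The
// result is identical to en_step_cpp on the flattened feature set.
//
// [[Rcpp::export]]
arma::mat en_step_factored_cpp(const arma::mat& Y, const arma::mat& S,
                               const arma::mat& Fm, const arma::mat& Aw,
                               double K, double beta, int H, int W,
                               double step_size = 1.0) {
  const uword N = Y.n_rows, ns = S.n_rows, nf = Fm.n_rows;
  const double inv2K2 = 1.0 / (2.0 * K * K);

  const mat Ys = Y.cols(0, 1);
  const mat Yf = Y.cols(2, 4);

  // spatial exponent matrix: A_js = exp(-(|S_s - Ys_j|^2) / 2K^2)
  mat A = 2.0 * inv2K2 * (Ys * S.t());
  {
    const vec yn = inv2K2 * sum(square(Ys), 1);
    const vec sn = inv2K2 * sum(square(S), 1);
    A.each_col() -= yn;
    A.each_row() -= sn.t();
  }
  A.each_row() -= max(A, 0);
  A.transform([](double t) { return (t < -700.0) ? 0.0 : std::exp(t); });

  mat B = 2.0 * inv2K2 * (Yf * Fm.t());
  {
    const vec yn = inv2K2 * sum(square(Yf), 1);
    const vec fn = inv2K2 * sum(square(Fm), 1);
    B.each_col() -= yn;
    B.each_row() -= fn.t();
  }
  B.each_row() -= max(B, 0);
  B.transform([](double t) { return (t < -700.0) ? 0.0 : std::exp(t); });

  // per-feature normalisers Z_sf = sum_j A_js B_jf  (shifts cancel)
  mat C = Aw / (A.t() * B);  // ns x nf: alpha_sf / Z_sf

  // coverage sums
  mat U = B * C.t();         // N x ns
  mat Wm = A % U;            // W_js = sum_f p alpha, spatial marginal
  vec wsum = sum(Wm, 1);
  mat cover(N, 5);
  cover.cols(0, 1) = Wm * S;
  mat V = A * C;             // N x nf
  cover.cols(2, 4) = (B % V) * Fm;

  const double bk = beta * K;

  if (bk == 0.0) {
    mat Ynew = Y;
    for (uword j = 0; j < N; ++j)
      if (wsum(j) > 1e-300)
        Ynew.row(j) = cover.row(j) / wsum(j);
    return Y + step_size * (Ynew - Y);
  }

  vec deg(N);
  for (uword c = 0; c < (uword)W; ++c)
    for (uword r = 0; r < (uword)H; ++r)
      deg(c * H + r) = (r > 0) + (r + 1 < (uword)H) +
                       (c > 0) + (c + 1 < (uword)W);

  auto matvec = [&](const vec& v) {
    vec out = wsum % v + bk * (deg % v);
    for (uword c = 0; c < (uword)W; ++c) {
      for (uword r = 0; r < (uword)H; ++r) {
        const uword j = c * H + r;
        double nb = 0.0;
        if (r > 0)            nb += v(j - 1);
        if (r + 1 < (uword)H) nb += v(j + 1);
        if (c > 0)            nb += v(j - H);
        if (c + 1 < (uword)W) nb += v(j + H);
        out(j) -= bk * nb;
      }
    }
    return out;
  };

  mat Ynew(N, 5);
  const vec Mi = 1.0 / (wsum + bk * deg + 1e-300);
  for (uword col = 0; col < 5; ++col) {
    const vec b = cover.col(col);
    vec x = Y.col(col);
    vec r = b - matvec(x);
    vec z = Mi % r;
    vec p = z;
    double rz = dot(r, z);
    const double btol = std::max(1e-24 * dot(b, b), 1e-300);
    for (int it = 0; it < 1000; ++it) {
      if (dot(r, r) <= btol) break;
      vec Ap = matvec(p);
      const double a = rz / dot(p, Ap);
      x += a * p;
      r -= a * Ap;
      z = Mi % r;
      const double rz_new = dot(r, z);
      p = z + (rz_new / rz) * p;
      rz = rz_new;
    }
    Ynew.col(col) = x;
  }

  return Y + step_size * (Ynew - Y);
}
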