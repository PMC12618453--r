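// Projected minibatch Adam for the 48-weight dispersed constitutive network.
//
// The R side precomputes design arrays (n x 8 each) such that the predicted
// stress of data row r is
//   pred_r = sum_k C(r,k) * dpsi_k(U(r,k); w_k)
// with C = C0 + kf*Cf + ks*Cs + kn*Cn and U = U0 + kf*Uf + ks*Us + kn*Un.
// Per invariant row k the six weights are
//   w(k,0) lin, w(k,1) exp1_in, w(k,2) exp1_out,
//   w(k,3) quad, w(k,4) exp2_in, w(k,5) exp2_out
// and
//   dpsi = lin + a1*b1*exp(a1*u) + 2*quad*u + 2*a2*b2*u*exp(a2*u^2).
//
// Loss: per deformation state the squared L2 norm of the full stress
// residual tensor, averaged over states, + alpha * L1 on the
// stiffness-carrying weights. A shear state contributes both symmetric
// components sigma_ij = sigma_ji, so its single data row carries weight 2;
// biaxial states contribute their two rows (sigma_ff, sigma_nn) with weight
// 1 each. rowW holds these weights and nstates the number of states.
// Weights are projected onto w >= 0 after every Adam step. Optionally the
// three dispersion parameters are trained directly as additional Adam
// parameters, projected onto [0, 1/3] after every step (a latent logistic
// parameterization was tried and rejected: its gradient vanishes at the
// boundaries, trapping kappas that transiently hit 0 or 1/3).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Design {
  mat C0, Cf, Cs, Cn, U0, Uf, Us, Un;
  vec y, rowW;
  double nstates;
};

void build_CU(const Design& d, const vec& kap, mat& C, mat& U) {
  C = d.C0 + kap(0) * d.Cf + kap(1) * d.Cs + kap(2) * d.Cn;
  U = d.U0 + kap(0) * d.Uf + kap(1) * d.Us + kap(2) * d.Un;
}

// dpsi and (optionally) its derivative with respect to u
void dpsi_mat(const mat& U, const mat& W, mat& D, mat* DdU) {
  const uword n = U.n_rows;
  D.set_size(n, 8);
  if (DdU) DdU->set_size(n, 8);
  for (uword k = 0; k < 8; ++k) {
    const double lin = W(k, 0), a1 = W(k, 1), b1 = W(k, 2);
    const double quad = W(k, 3), a2 = W(k, 4), b2 = W(k, 5);
    const vec u = U.col(k);
    const vec e1 = exp(a1 * u);
    const vec e2 = exp(a2 * square(u));
    D.col(k) = lin + a1 * b1 * e1 + 2.0 * quad * u + 2.0 * a2 * b2 * (u % e2);
    if (DdU)
      DdU->col(k) = a1 * a1 * b1 * e1 + 2.0 * quad +
                    2.0 * a2 * b2 * (e2 % (1.0 + 2.0 * a2 * square(u)));
  }
}

double full_mse(const Design& d, const mat& C, const mat& U, const mat& W) {
  mat D;
  dpsi_mat(U, W, D, nullptr);
  const vec pred = sum(C % D, 1);
  const vec r = pred - d.y;
  return dot(d.rowW, square(r)) / d.nstates;
}

double penalty_l1(const mat& W, const double alpha) {
  return alpha * (accu(W.col(0)) + accu(W.col(2)) + accu(W.col(3)) +
                  accu(W.col(5)));
}

}  // namespace

// [[Rcpp::export(name = ".adam_fit_cpp")]]
Rcpp::List adam_fit_cpp(const arma::mat& C0, const arma::mat& Cf,
                        const arma::mat& Cs, const arma::mat& Cn,
                        const arma::mat& U0, const arma::mat& Uf,
                        const arma::mat& Us, const arma::mat& Un,
                        const arma::vec& y, const arma::vec& rowW,
                        const double nstates, const arma::mat& w0,
                        const arma::vec& kappa0, const bool train_kappa,
                        const double alpha, const double lr,
                        const int max_epochs, const int batch_size,
                        const int patience, const double improve_tol,
                        const bool monitor_loss, const unsigned int seed) {
  Design d{C0, Cf, Cs, Cn, U0, Uf, Us, Un, y, rowW, nstates};
  const uword n = y.n_elem;

  mat W = w0;                       // 8 x 6, non-negative
  vec kap = kappa0;                 // dispersion parameters in [0, 1/3]

  // Adam state
  mat mW(8, 6, fill::zeros), vW(8, 6, fill::zeros);
  vec mz(3, fill::zeros), vz(3, fill::zeros);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double b1t = 1.0, b2t = 1.0;

  std::mt19937 rng(seed);
  uvec idx = regspace<uvec>(0, n - 1);

  mat C, U;
  build_CU(d, kap, C, U);
  // By default early stopping monitors the unregularized fit (mean squared
  // stress error): the L1 term keeps shrinking weights long after the fit
  // has converged, so monitoring the full objective would let the penalty
  // trade the fit away before stopping. The best monitored state is
  // restored. monitor_loss = true monitors the full regularized objective
  // instead, which runs the optimization to its L1 equilibrium (used to
  // study the regularization path).
  double best_loss = full_mse(d, C, U, W) +
                     (monitor_loss ? penalty_l1(W, alpha) : 0.0);
  mat bestW = W;
  vec best_kap = kap;
  int stall = 0, epochs_run = 0;
  bool diverged = false;
  std::vector<double> history;
  history.reserve(max_epochs);

  mat D, DdU;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    epochs_run = epoch + 1;
    // Fisher-Yates shuffle with our own deterministic RNG
    for (uword i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<uword> pick(0, i);
      std::swap(idx(i), idx(pick(rng)));
    }
    for (uword start = 0; start < n; start += batch_size) {
      const uword stop = std::min<uword>(start + batch_size, n) - 1;
      const uvec rows = idx.subvec(start, stop);

      if (train_kappa) build_CU(d, kap, C, U);
      const mat Cb = C.rows(rows);
      const mat Ub = U.rows(rows);
      dpsi_mat(Ub, W, D, train_kappa ? &DdU : nullptr);
      const vec r = sum(Cb % D, 1) - d.y(rows);
      const vec wr = d.rowW(rows);

      // gradients of the state-weighted mean squared residual:
      // (2/sum(w)) * sum_r w_r r_r dpred_r/dtheta
      const vec rw = r % wr;
      const mat A = Cb.each_col() % rw;  // nb x 8
      mat G(8, 6, fill::zeros);
      for (uword k = 0; k < 8; ++k) {
        const double a1 = W(k, 1), ob1 = W(k, 2);
        const double a2 = W(k, 4), ob2 = W(k, 5);
        const vec u = Ub.col(k);
        const vec a = A.col(k);
        const vec e1 = exp(a1 * u);
        const vec e2 = exp(a2 * square(u));
        G(k, 0) = accu(a);                                    // lin
        G(k, 1) = accu(a % (ob1 * e1 % (1.0 + a1 * u)));      // exp1_in
        G(k, 2) = accu(a % (a1 * e1));                        // exp1_out
        G(k, 3) = accu(a % (2.0 * u));                        // quad
        G(k, 4) = accu(a % (2.0 * ob2 * (u % e2) %
                            (1.0 + a2 * square(u))));         // exp2_in
        G(k, 5) = accu(a % (2.0 * a2 * (u % e2)));            // exp2_out
      }
      // unbiased minibatch estimate of the state-mean MSE gradient:
      // (1/nstates) * (n_rows/nb) * sum_batch w_r r_r dpred_r
      const double bscale =
          2.0 * static_cast<double>(n) /
          (d.nstates * static_cast<double>(rows.n_elem));
      G *= bscale;
      // L1 subgradient on the non-negative orthant. The penalty acts on the
      // stiffness-carrying weights: the collapsed identity-node weights and
      // the outer weights of the exponential nodes. The inner exponents are
      // shape parameters, not magnitudes, and stay unpenalized.
      G.col(0) += alpha;  // lin
      G.col(2) += alpha;  // exp1_out
      G.col(3) += alpha;  // quad
      G.col(5) += alpha;  // exp2_out

      vec Gz(3, fill::zeros);
      if (train_kappa) {
        const mat dCf = d.Cf.rows(rows), dCs = d.Cs.rows(rows),
                  dCn = d.Cn.rows(rows);
        const mat dUf = d.Uf.rows(rows), dUs = d.Us.rows(rows),
                  dUn = d.Un.rows(rows);
        const vec gf = sum(dCf % D, 1) + sum((Cb % DdU) % dUf, 1);
        const vec gs = sum(dCs % D, 1) + sum((Cb % DdU) % dUs, 1);
        const vec gn = sum(dCn % D, 1) + sum((Cb % DdU) % dUn, 1);
        const double bscale =
            2.0 * static_cast<double>(n) /
            (d.nstates * static_cast<double>(rows.n_elem));
        Gz(0) = bscale * dot(rw, gf);
        Gz(1) = bscale * dot(rw, gs);
        Gz(2) = bscale * dot(rw, gn);
      }

      if (!G.is_finite() || (train_kappa && !Gz.is_finite())) {
        diverged = true;
        break;
      }

      b1t *= b1;
      b2t *= b2;
      mW = b1 * mW + (1.0 - b1) * G;
      vW = b2 * vW + (1.0 - b2) * square(G);
      W -= lr * (mW / (1.0 - b1t)) / (sqrt(vW / (1.0 - b2t)) + eps);
      W.transform([](double x) { return x < 0.0 ? 0.0 : x; });
      if (train_kappa) {
        mz = b1 * mz + (1.0 - b1) * Gz;
        vz = b2 * vz + (1.0 - b2) * square(Gz);
        kap -= lr * (mz / (1.0 - b1t)) / (sqrt(vz / (1.0 - b2t)) + eps);
        kap = clamp(kap, 0.0, 1.0 / 3.0);
      }
    }
    if (diverged) break;

    build_CU(d, kap, C, U);
    const double L = full_mse(d, C, U, W) +
                     (monitor_loss ? penalty_l1(W, alpha) : 0.0);
    history.push_back(L);
    if (!std::isfinite(L)) {
      diverged = true;
      break;
    }
    if (L < best_loss - improve_tol) {
      stall = 0;
    } else {
      ++stall;
    }
    if (L < best_loss) {
      best_loss = L;
      bestW = W;
      best_kap = kap;
    }
    if (stall >= patience) break;
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = bestW, Rcpp::Named("kappas") = best_kap,
      Rcpp::Named("loss") = best_loss, Rcpp::Named("epochs") = epochs_run,
      Rcpp::Named("diverged") = diverged,
      Rcpp::Named("history") = history);
}
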