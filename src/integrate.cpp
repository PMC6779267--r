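// Euler-Maruyama integrator for the adaptive frequency-modulated
// Stuart-Landau whole-brain model:
//
//   dz_j = [ (a_j + i w_j - |z_j|^2) z_j + G sum_i C_ij (z_i - z_j) ] dt
//          + beta dW_j                       (complex Wiener increment)
//   dw_j = [ w0_j - lambda w_j + m psi_j ] dt,   psi_j = sum_i C_ij theta_i
//
// theta_i is the TWO-quadrant arctangent atan(Im z / Re z) in [-pi/2, pi/2]
// (the model-internal phase convention; signal-level observables use the
// four-quadrant convention instead). Noise uses the R RNG so a set.seed()
// call in the R wrapper makes trajectories bitwise reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double two_quadrant_phase(double re, double im) {
  if (re == 0.0) {
    if (im == 0.0) return 0.0;
    return (im > 0.0 ? 1.0 : -1.0) * M_PI_2;
  }
  return std::atan(im / re);
}

// [[Rcpp::export(name = ".sl_integrate")]]
List sl_integrate(const arma::mat& C, const arma::vec& a,
                  const arma::vec& omega0, double G, double lam, double m,
                  double beta, const arma::vec& z0re, const arma::vec& z0im,
                  const arma::vec& w0, double dt, int burn_steps, int n_out,
                  int steps_per_sample, bool record_omega, bool record_psi) {
  const arma::uword N = C.n_rows;
  if (a.n_elem != N || omega0.n_elem != N || z0re.n_elem != N ||
      z0im.n_elem != N || w0.n_elem != N)
    stop("parameter/state dimension does not match the connectome");
  if (n_out < 1) stop("need at least one output sample");

  RNGScope scope;

  arma::vec zre = z0re, zim = z0im, om = w0;
  arma::vec s = arma::sum(C, 1);  // row sums for the diffusive coupling term
  arma::vec theta(N), psi(N), czre(N), czim(N), r2(N), dre(N), dim_(N);

  arma::mat out_re(n_out, N), out_im(n_out, N);
  arma::mat out_om(record_omega ? n_out : 0, record_omega ? N : 0);
  arma::mat out_psi(record_psi ? n_out : 0, record_psi ? N : 0);

  const double sqrtdt = std::sqrt(dt);
  const bool noisy = beta > 0.0;
  const long total_steps = (long)burn_steps + (long)(n_out - 1) * steps_per_sample;

  long step = 0;
  int rec = 0;
  // record the state at t = burn_in + k * tr for k = 0..n_out-1
  auto maybe_record = [&]() {
    if (step >= burn_steps && (step - burn_steps) % steps_per_sample == 0) {
      for (arma::uword j = 0; j < N; ++j) {
        if (!std::isfinite(zre[j]) || !std::isfinite(zim[j]) ||
            !std::isfinite(om[j]))
          stop("trajectory blew up (non-finite state) at step %ld", step);
        out_re(rec, j) = zre[j];
        out_im(rec, j) = zim[j];
        if (record_omega) out_om(rec, j) = om[j];
        if (record_psi) {
          out_psi(rec, j) = arma::dot(C.row(j).t(),
                                      theta);  // psi from the last step
        }
      }
      ++rec;
    }
  };

  // psi of the initial state (for record_psi at step 0)
  for (arma::uword j = 0; j < N; ++j) theta[j] = two_quadrant_phase(zre[j], zim[j]);
  maybe_record();

  for (step = 1; step <= total_steps; ++step) {
    // drift at the pre-step state
    for (arma::uword j = 0; j < N; ++j)
      theta[j] = two_quadrant_phase(zre[j], zim[j]);
    psi = C * theta;
    czre = C * zre;
    czim = C * zim;
    r2 = zre % zre + zim % zim;
    dre = (a - r2) % zre - om % zim + G * (czre - s % zre);
    dim_ = (a - r2) % zim + om % zre + G * (czim - s % zim);

    zre += dt * dre;
    zim += dt * dim_;
    if (noisy) {
      for (arma::uword j = 0; j < N; ++j) {
        zre[j] += beta * sqrtdt * norm_rand();
        zim[j] += beta * sqrtdt * norm_rand();
      }
    }
    om += dt * (omega0 - lam * om + m * psi);

    double mx = std::max(arma::abs(zre).max(), arma::abs(zim).max());
    if (!std::isfinite(mx) || mx > 1e6)
      stop("trajectory blew up at step %ld (|z| > 1e6 or non-finite)", step);

    // theta of the updated state, so recorded psi matches the stored state
    for (arma::uword j = 0; j < N; ++j)
      theta[j] = two_quadrant_phase(zre[j], zim[j]);
    maybe_record();
  }

  List res = List::create(_["z_re"] = out_re, _["z_im"] = out_im);
  if (record_omega) res["omega"] = out_om;
  if (record_psi) res["psi"] = out_psi;
  return res;
}
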