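#include <Rcpp.h>
using namespace Rcpp;

// Numerical guards shared with the R reference implementation:
// z-scores clipped at +/-38 before Phi/phi, total log-likelihood floored
// at -1e10 so MCMC chains remain movable from invalid regions.
static const double Z_CLIP = 38.0;
static const double LL_FLOOR = -1e10;
static const double DENS_FLOOR = 1e-300;

static inline double clipz(double z) {
  if (z > Z_CLIP) return Z_CLIP;
  if (z < -Z_CLIP) return -Z_CLIP;
  return z;
}

// inline standard-normal CDF/PDF (erfc-based; agrees with R's pnorm to
// ~1e-15 relative and avoids the per-call overhead of the R API)
static const double INV_SQRT2 = 0.7071067811865475244;
static const double INV_SQRT2PI = 0.3989422804014326779;
static inline double Phi(double z) { return 0.5 * std::erfc(-z * INV_SQRT2); }
static inline double phi(double z) {
  return INV_SQRT2PI * std::exp(-0.5 * z * z);
}

// First-passage density of one linear ballistic accumulator with start
// point ~ U[0, A], boundary b, drift ~ N(v, s) across trials.
static inline double fpt_pdf(double t, double A, double b, double v, double s) {
  if (t <= 0.0) return 0.0;
  double ts = t * s;
  double z1 = clipz((b - t * v) / ts);
  double z2 = clipz((b - A - t * v) / ts);
  double f = (-v * Phi(z2) + s * phi(z2) + v * Phi(z1) - s * phi(z1)) / A;
  return f > 0.0 ? f : 0.0;
}

// Companion CDF (probability the accumulator has crossed by decision time t).
static inline double fpt_cdf(double t, double A, double b, double v, double s) {
  if (t <= 0.0) return 0.0;
  double ts = t * s;
  double z1 = clipz((b - t * v) / ts);
  double z2 = clipz((b - A - t * v) / ts);
  double F = 1.0 + ((b - A - t * v) / A) * Phi(z2)
                 - ((b - t * v) / A) * Phi(z1)
                 + (ts / A) * phi(z2)
                 - (ts / A) * phi(z1);
  if (F < 0.0) return 0.0;
  if (F > 1.0) return 1.0;
  return F;
}

// Summed trial log-likelihood for a block of parameter vectors (one row per
// MCMC chain). theta columns: A, B, v_true, v_false, sv, t0; b = A + B.
// choice: 1 = "true" accumulator won, 0 = "false". When renormalize is true
// the defective density is divided by 1 - P(both trial drifts <= 0).
// [[Rcpp::export]]
NumericVector lba_loglik_chains(NumericMatrix theta, NumericVector rt,
                                IntegerVector choice, bool renormalize) {
  int nch = theta.nrow();
  int ntr = rt.size();
  NumericVector out(nch);
  for (int k = 0; k < nch; ++k) {
    double A = theta(k, 0), B = theta(k, 1);
    double vt = theta(k, 2), vf = theta(k, 3);
    double s = theta(k, 4), t0 = theta(k, 5);
    double b = A + B;
    if (!(A > 0.0) || !(B > 0.0) || !(s > 0.0) || !(t0 > 0.0) ||
        !R_finite(A) || !R_finite(B) || !R_finite(vt) || !R_finite(vf) ||
        !R_finite(s) || !R_finite(t0)) {
      out[k] = LL_FLOOR;
      continue;
    }
    double lognorm = 0.0;
    if (renormalize) {
      double p_none = R::pnorm(-vt / s, 0.0, 1.0, 1, 0) *
                      R::pnorm(-vf / s, 0.0, 1.0, 1, 0);
      lognorm = std::log(1.0 - p_none);
    }
    double ll = 0.0;
    bool bad = false;
    for (int i = 0; i < ntr; ++i) {
      double t = rt[i] - t0;
      if (t <= 0.0) { bad = true; break; }
      double d;
      if (choice[i] == 1) {
        d = fpt_pdf(t, A, b, vt, s) * (1.0 - fpt_cdf(t, A, b, vf, s));
      } else {
        d = fpt_pdf(t, A, b, vf, s) * (1.0 - fpt_cdf(t, A, b, vt, s));
      }
      if (d < DENS_FLOOR) d = DENS_FLOOR;
      ll += std::log(d) - lognorm;
    }
    if (bad || !R_finite(ll) || ll < LL_FLOOR) ll = LL_FLOOR;
    out[k] = ll;
  }
  return out;
}

// One DE-MCMC crossover update of a participant's parameter block, all
// chains at once: symmetric proposal x_k + gamma (x_m - x_n) + U(-e, e)
// on the transformed scale (log for positive-domain parameters), MH
// acceptance against loglik + truncated-normal link + Jacobian. Uses R's
// RNG so runs are reproducible from the R-level seed.
// free_idx: 0-based column of each free parameter in the full parameter
// vector; fixed_template: full-length vector pre-filled with fixed values.
// [[Rcpp::export]]
List lba_block_update(NumericMatrix x, NumericMatrix nat,
                      NumericMatrix mu, NumericMatrix sigma,
                      LogicalVector logged, IntegerVector free_idx,
                      NumericVector fixed_template,
                      NumericVector rt, IntegerVector choice, bool renormalize,
                      NumericVector ll, NumericVector linklp, NumericVector jac,
                      double gamma, double jitter) {
  int nch = x.nrow(), d = x.ncol(), npar = fixed_template.size();
  NumericMatrix xn = clone(x), natn = clone(nat);
  NumericVector lln = clone(ll), linkn = clone(linklp), jacn = clone(jac);
  NumericMatrix xp(nch, d);
  NumericMatrix thetap(nch, npar);
  int nacc = 0;

  for (int k = 0; k < nch; ++k) {
    int m = (int)(unif_rand() * (nch - 1));
    int n = (int)(unif_rand() * (nch - 2));
    m = (k + 1 + m) % nch;
    // pick n distinct from both k and m
    int cnt = -1, nn = -1;
    for (int c = 0; c < nch; ++c) {
      if (c == k || c == m) continue;
      if (++cnt == n) { nn = c; break; }
    }
    for (int j = 0; j < d; ++j) {
      xp(k, j) = x(k, j) + gamma * (x(m, j) - x(nn, j)) +
        (unif_rand() * 2.0 - 1.0) * jitter;
    }
  }

  for (int k = 0; k < nch; ++k) {
    for (int j = 0; j < npar; ++j) thetap(k, j) = fixed_template[j];
    for (int j = 0; j < d; ++j) {
      double v = logged[j] ? std::exp(xp(k, j)) : xp(k, j);
      thetap(k, free_idx[j]) = v;
    }
  }
  NumericVector llp = lba_loglik_chains(thetap, rt, choice, renormalize);

  for (int k = 0; k < nch; ++k) {
    double linkp = 0.0, jacp = 0.0;
    bool ok = true;
    for (int j = 0; j < d; ++j) {
      double v = thetap(k, free_idx[j]);
      if (!(v > 0.0) || !R_finite(v)) { ok = false; break; }
      double sd = sigma(k, j);
      double mn = mu(k, j);
      linkp += R::dnorm(v, mn, sd, 1) - R::pnorm(mn / sd, 0.0, 1.0, 1, 1);
      if (logged[j]) jacp += xp(k, j);
    }
    if (!ok) continue;
    double logr = (llp[k] + linkp + jacp) - (lln[k] + linkn[k] + jacn[k]);
    if (!R_finite(logr)) continue;
    if (std::log(unif_rand()) < logr) {
      for (int j = 0; j < d; ++j) xn(k, j) = xp(k, j);
      for (int j = 0; j < npar; ++j) natn(k, j) = thetap(k, j);
      lln[k] = llp[k]; linkn[k] = linkp; jacn[k] = jacp;
      ++nacc;
    }
  }
  return List::create(_["x"] = xn, _["nat"] = natn, _["ll"] = lln,
                      _["linklp"] = linkn, _["jac"] = jacn,
                      _["nacc"] = nacc);
}
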