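// Joint negative log-likelihood of the zero-inflated hierarchical
// occupancy-abundance model for spatially replicated detection-nondetection
// data, with the discrete cell-level presence state z marginalised
// analytically and all Gaussian random effects integrated out by the Laplace
// approximation (TMB's `random` mechanism).
//
// Observation model per plot:  y ~ Bernoulli(1 - exp(-z * d * a)), with a the
// plot area as an offset on the log scale (log_a, in km^2 so that d is a
// density per km^2).  Density:  log d = mu + beta' x + e1_i + e2_j + e3_ij.
// Occupancy: logit psi = eta + gamma' x + u1_i + u2_j.  (e2_j, u2_j) are
// bivariate normal with correlation rho; other effects are independent
// normals.  Cell-level occurrence may be known (m = 1, z fixed) through
// detections or auxiliary occurrence sources; otherwise z is summed out.
//
// model_type: 0 = baseline (no occupancy layer, plain cloglog GLMM with
// offset), 1 = integrated (zero-inflated, auxiliary information used).
// active: flags for (sigma1, sigma2, sigma3, tau1, tau2); inactive components
// have their effect vectors mapped to zero on the R side and contribute no
// prior term, so zero-variance degenerate fits stay finite.
#include <TMB.hpp>

template <class Type>
Type objective_function<Type>::operator()()
{
  // pair-level tables: one entry per modelled (species, cell) pair that has
  // plots and/or known occurrence state
  DATA_IVECTOR(pair_sp);    // 0-based species index
  DATA_IVECTOR(pair_cell);  // 0-based cell index
  DATA_IVECTOR(pair_m);     // 1 = z known
  DATA_IVECTOR(pair_z);     // known z value (ignored when m = 0)
  DATA_IVECTOR(pair_e3);    // index into e3, or -1 when the pair has no plots

  // plot-level tables
  DATA_IVECTOR(plot_pair);  // 0-based pair index
  DATA_VECTOR(plot_y);      // detection 0/1
  DATA_VECTOR(plot_loga);   // log plot area (km^2), the cloglog offset

  // cell-level design: column for each fixed-effect term after the intercept
  DATA_MATRIX(Xd);          // density covariates (n_cell x p_d)
  DATA_MATRIX(Xo);          // occupancy covariates (n_cell x p_o)

  DATA_INTEGER(model_type);
  DATA_IVECTOR(active);     // length 5: sigma1, sigma2, sigma3, tau1, tau2

  PARAMETER(mu);
  PARAMETER_VECTOR(beta);
  PARAMETER(eta);
  PARAMETER_VECTOR(gamma);
  PARAMETER_VECTOR(log_sigma);  // length 3
  PARAMETER_VECTOR(log_tau);    // length 2
  PARAMETER(rho_t);             // atanh(rho)

  PARAMETER_VECTOR(e1);  // species, density
  PARAMETER_VECTOR(u1);  // species, occupancy
  PARAMETER_VECTOR(e2);  // cell, density
  PARAMETER_VECTOR(u2);  // cell, occupancy
  PARAMETER_VECTOR(e3);  // species x cell, density (pairs with plots only)

  Type s1 = exp(log_sigma(0)), s2 = exp(log_sigma(1)), s3 = exp(log_sigma(2));
  Type t1 = exp(log_tau(0)), t2 = exp(log_tau(1));
  Type rho = tanh(rho_t);

  Type nll = 0;

  // Gaussian priors on random effects (skipped for inactive components)
  if (active(0)) nll -= dnorm(e1, Type(0), s1, true).sum();
  if (active(2)) nll -= dnorm(e3, Type(0), s3, true).sum();
  if (model_type == 1 && active(3)) nll -= dnorm(u1, Type(0), t1, true).sum();
  if (model_type == 1 && active(1) && active(4)) {
    // (e2, u2) bivariate normal via marginal x conditional factorisation
    Type cs = t2 * sqrt(Type(1) - rho * rho);
    for (int j = 0; j < e2.size(); j++) {
      nll -= dnorm(e2(j), Type(0), s2, true);
      nll -= dnorm(u2(j), rho * t2 / s2 * e2(j), cs, true);
    }
  } else {
    if (active(1)) nll -= dnorm(e2, Type(0), s2, true).sum();
    if (model_type == 1 && active(4)) nll -= dnorm(u2, Type(0), t2, true).sum();
  }

  int P = pair_sp.size();
  vector<Type> logdet(P);   // detection log-lik given z = 1, per pair
  for (int p = 0; p < P; p++) logdet(p) = 0;

  // accumulate per-plot Bernoulli terms given presence
  for (int q = 0; q < plot_pair.size(); q++) {
    int p = plot_pair(q);
    int i = pair_sp(p), j = pair_cell(p);
    Type lpd = mu + e1(i) + e2(j);
    for (int c = 0; c < Xd.cols(); c++) lpd += beta(c) * Xd(j, c);
    if (pair_e3(p) >= 0) lpd += e3(pair_e3(p));
    Type dm = exp(lpd + plot_loga(q));  // expected count d * a
    if (plot_y(q) > Type(0.5)) {
      // log(1 - exp(-dm)), computed stably
      logdet(p) += logspace_sub(Type(0), -dm);
    } else {
      logdet(p) += -dm;
    }
  }

  if (model_type == 0) {
    // baseline GLMM: p = 1 - exp(-d a) unconditionally
    for (int p = 0; p < P; p++) nll -= logdet(p);
  } else {
    for (int p = 0; p < P; p++) {
      int i = pair_sp(p), j = pair_cell(p);
      Type lpo = eta + u1(i) + u2(j);
      for (int c = 0; c < Xo.cols(); c++) lpo += gamma(c) * Xo(j, c);
      Type log_psi = -logspace_add(Type(0), -lpo);   // log plogis(lpo)
      Type log_1mpsi = -logspace_add(Type(0), lpo);
      if (pair_m(p) == 1) {
        if (pair_z(p) == 1)
          nll -= logdet(p) + log_psi;
        else
          nll -= log_1mpsi;  // all y are 0 by data validation; z=0 branch
      } else {
        // z unknown: exact marginalisation over the two branches.
        // All y are 0 here (a detection forces m = 1), so the z = 0 branch
        // has detection likelihood 1.
        nll -= logspace_add(log_psi + logdet(p), log_1mpsi);
      }
    }
  }

  ADREPORT(rho);
  return nll;
}
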