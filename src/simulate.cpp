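// Fast path for the origin-fixation simulation: mass-action equilibrium of
// the five-species dimerization system and the propose/fix loop.  The R-level
// equilibrium functions (R/equilibrium.R) implement the same model through
// base R's polyroot(); tests cross-check the two routes and both are checked
// against an ODE steady-state oracle.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double KAB_DEGENERATE = 1e-12;

// exp(-dG/RT) with an overflow clamp; dG below ~ -400 kcal/mol is far
// outside anything mutation accumulation can produce.
static double assoc_k(double dG, double RT, bool hetero) {
  double x = -dG / RT;
  if (x > 700.0) x = 700.0;
  double k = std::exp(x);
  return hetero ? 2.0 * k : k;
}

// Pre-duplication closed form: c_A from the positive root of the quadratic
// mass balance, c_AA = k c_A^2.  s is the synthesis rate of *folded* subunits.
static void eq_pre(double s, double dA, double dAA, double kAA,
                   double &cA, double &cAA) {
  if (s <= 0.0) { cA = 0.0; cAA = 0.0; return; }
  // stable form of the quadratic root (no cancellation for weak binding)
  cA = 2.0 * s / (dA + std::sqrt(dA * dA + 8.0 * dAA * kAA * s));
  cAA = kAA * cA * cA;
}

// Stable positive root of 2 a c^2 + q c - s = 0 (per-subunit flux balance
// at fixed concentration of the partner monomer).
static double flux_balance_root(double s, double q, double a) {
  if (s <= 0.0) return 0.0;
  if (a < 1e-300) return s / q;
  return 2.0 * s / (q + std::sqrt(q * q + 8.0 * a * s));
}

// Damped Newton iteration on the two subunit flux balances
//   F1 = dA cA + 2 a cA^2 + h cA cB - sA = 0
//   F2 = dB cB + 2 b cB^2 + h cA cB - sB = 0
// (a = dAA kAA, b = dBB kBB, h = dAB kAB).  The Jacobian is an M-matrix, so
// Newton from the decoupled (no-heterodimer) solution converges globally;
// used to polish the quartic root and as a fallback when root extraction
// loses precision at extreme parameter scales (e.g. nearly fully misfolded
// paralogs).
static bool eq_post_iterate(double sA, double sB, double dA, double dB,
                            double dAA, double dAB, double dBB,
                            double kAA, double kAB, double kBB,
                            double cA0, double cB0,
                            arma::vec::fixed<5> &out) {
  double a = dAA * kAA, b = dBB * kBB, h = dAB * kAB;
  if (sA <= 0.0 || sB <= 0.0) {  // one subunit absent: no heterodimer
    double cA = flux_balance_root(sA, dA, a);
    double cB = flux_balance_root(sB, dB, b);
    out = {cA, cB, kAA * cA * cA, 0.0, kBB * cB * cB};
    return true;
  }
  double cA = std::max(cA0, 1e-300), cB = std::max(cB0, 1e-300);
  bool ok = false;
  for (int it = 0; it < 200; ++it) {
    double F1 = dA * cA + 2.0 * a * cA * cA + h * cA * cB - sA;
    double F2 = dB * cB + 2.0 * b * cB * cB + h * cA * cB - sB;
    double J11 = dA + 4.0 * a * cA + h * cB, J12 = h * cA;
    double J21 = h * cB, J22 = dB + 4.0 * b * cB + h * cA;
    double det = J11 * J22 - J12 * J21;  // > 0: strictly diagonally dominant
    double dcA = (F1 * J22 - F2 * J12) / det;
    double dcB = (J11 * F2 - J21 * F1) / det;
    // damp so that concentrations stay positive (at most halve per step)
    double damp = 1.0;
    if (dcA > 0.5 * cA) damp = std::min(damp, 0.5 * cA / dcA);
    if (dcB > 0.5 * cB) damp = std::min(damp, 0.5 * cB / dcB);
    cA -= damp * dcA;
    cB -= damp * dcB;
    if (damp == 1.0 && std::abs(dcA) <= 1e-13 * cA &&
        std::abs(dcB) <= 1e-13 * cB) { ok = true; break; }
  }
  if (!ok) {
    // step-size test can chatter in the last bits; accept on residuals
    double F1 = dA * cA + 2.0 * a * cA * cA + h * cA * cB - sA;
    double F2 = dB * cB + 2.0 * b * cB * cB + h * cA * cB - sB;
    if (std::abs(F1) > 1e-10 * sA || std::abs(F2) > 1e-10 * sB) return false;
  }
  out = {cA, cB, kAA * cA * cA, kAB * cA * cB, kBB * cB * cB};
  return true;
}

// Post-duplication equilibrium: quartic in c_A, back-substitution for the
// other species, unique all-positive root, iteratively polished.  Throws if
// no physical root.
static arma::vec::fixed<5> eq_post(double sA, double sB,
                                   double dA, double dB, double dAA,
                                   double dAB, double dBB,
                                   double kAA, double kAB, double kBB) {
  arma::vec::fixed<5> out;
  if (kAB < KAB_DEGENERATE) {
    // continuous limit: no heterodimer, two independent single-gene systems
    double cA, cAA, cB, cBB;
    eq_pre(sA, dA, dAA, kAA, cA, cAA);
    eq_pre(sB, dB, dBB, kBB, cB, cBB);
    out = {cA, cB, cAA, 0.0, cBB};
    return out;
  }
  double a = dAA * kAA, b = dBB * kBB, h = dAB * kAB;
  arma::vec coef = {
    2.0 * a * (4.0 * a * b / h - h),
    dA * (8.0 * a * b / h - h) - 2.0 * dB * a,
    2.0 * b * dA * dA / h + sA * (h - 8.0 * a * b / h) - dA * dB - h * sB,
    sA * (dB - 4.0 * dA * b / h),
    2.0 * sA * sA * b / h};
  // strip a vanishing leading coefficient (possible when both homodimer
  // association constants underflow)
  arma::uword first = 0;
  double cmax = arma::abs(coef).max();
  while (first < 3 && std::abs(coef(first)) <= 1e-14 * cmax) ++first;
  arma::cx_vec roots = arma::roots(coef.subvec(first, 4));

  int n_ok = 0;
  arma::vec::fixed<5> best;
  for (arma::uword i = 0; i < roots.n_elem; ++i) {
    double re = roots(i).real(), im = roots(i).imag();
    if (std::abs(im) > 1e-9 * std::max(1.0, std::abs(re))) continue;
    if (re <= 0.0) continue;
    double cA = re;
    double cB = (sA / cA - 2.0 * a * cA - dA) / h;
    double tol = -1e-9 * std::max(cA, std::abs(cB));
    if (cB < tol) continue;
    // back-substitution through the A-side balance cancels catastrophically
    // when binding is strong, so re-derive c_B from the B-side balance and
    // polish; every admissible root must converge to the unique equilibrium
    double cB0 = flux_balance_root(sB, dB + h * cA, b);
    arma::vec::fixed<5> cand;
    if (!eq_post_iterate(sA, sB, dA, dB, dAA, dAB, dBB, kAA, kAB, kBB,
                         cA, cB0, cand))
      continue;
    if (n_ok > 0) {
      double rel = arma::abs(cand - best).max() /
                   std::max(1e-300, arma::abs(best).max());
      if (rel > 1e-6)
        stop("post-duplication equilibrium: multiple all-positive roots");
      continue;
    }
    best = cand;
    n_ok = 1;
  }
  if (n_ok == 0) {
    // root extraction can lose the physical root when parameter scales are
    // extreme; recover it from the flux-balance iteration started at the
    // decoupled (no-heterodimer) solution
    double cA0, cAA0, cB0, cBB0;
    eq_pre(sA, dA, dAA, kAA, cA0, cAA0);
    eq_pre(sB, dB, dBB, kBB, cB0, cBB0);
    arma::vec::fixed<5> it;
    if (eq_post_iterate(sA, sB, dA, dB, dAA, dAB, dBB, kAA, kAB, kBB,
                        cA0, cB0, it))
      return it;
    stop("post-duplication equilibrium: no all-positive root (sA=%g, sB=%g)",
         sA, sB);
  }
  return best;
}

// [[Rcpp::export(name = ".eq_post_cpp")]]
NumericVector eq_post_cpp(double sA, double sB, NumericVector decay,
                          double kAA, double kAB, double kBB) {
  arma::vec::fixed<5> c = eq_post(sA, sB, decay[0], decay[1], decay[2],
                                  decay[3], decay[4], kAA, kAB, kBB);
  return NumericVector::create(c(0), c(1), c(2), c(3), c(4));
}

static double folded_fraction(double gf) { return 1.0 / (1.0 + std::exp(gf)); }

static double lognormal_fitness(double act, double alpha, double beta) {
  if (act <= 0.0) return 0.0;
  double l = std::log2(act / alpha);
  return std::pow(beta, l * l);
}

// Kimura diffusion approximation with relative selection coefficient
static double p_fix_kimura(double f_old, double f_new, double N) {
  if (f_old <= 0.0) return f_new > 0.0 ? 1.0 : 1.0 / N;
  double s = f_new / f_old - 1.0;
  if (std::abs(s) < 1e-12) return 1.0 / N;
  double num = -std::expm1(-2.0 * s);
  double den = -std::expm1(-2.0 * N * s);
  if (den == 0.0) return 1.0 / N;
  double p = num / den;
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

static double p_fix(double f_old, double f_new, double N, int model,
                    bool neutral) {
  if (neutral)  // selection switched off: every proposal is neutral
    return model == 1 ? 1.0 : 1.0 / N;
  if (model == 1) {  // Metropolis-style alternative
    if (f_old <= 0.0) return f_new > 0.0 ? 1.0 : 0.0;
    double r = f_new / f_old;
    return r >= 1.0 ? 1.0 : r;
  }
  return p_fix_kimura(f_old, f_new, N);
}

struct SysState {
  double sA, sB;         // raw gene-level synthesis rates
  double gfA, gfB;       // folding free energies
  double gAA, gAB, gBB;  // binding free energies
};

// Full origin-fixation replicate.  The duplication is proposed first and
// retried until fixed (fixation #1); afterwards coding / expression events
// are proposed until n_fix mutations have been fixed in total.
//
// source_type: 0 = parametric trivariate normal (mu + square-root factor),
//              1 = empirical table (rows of ddG_fold, ddG_bind_HM, ddG_bind_HET)
// fix_model:   0 = Kimura diffusion, 1 = Metropolis ratio
// [[Rcpp::export(name = ".sim_replicate_cpp")]]
List sim_replicate_cpp(double s_init, double gf_init, double gbind_init,
                       NumericVector decay, NumericVector activities,
                       double RT, double alpha, double beta,
                       double pop_size, int fix_model, bool neutral,
                       double p_exp, int n_fix, int source_type,
                       NumericVector mu, NumericMatrix factor_u,
                       NumericMatrix eff_table,
                       double sn_xi, double sn_omega, double sn_delta,
                       double max_proposals) {
  double dA = decay[0], dB = decay[1], dAA = decay[2], dAB = decay[3],
         dBB = decay[4];
  double a_mono = activities[0], a_AA = activities[1], a_AB = activities[2],
         a_BB = activities[3];
  double sn_tau = std::sqrt(std::max(0.0, 1.0 - sn_delta * sn_delta));

  IntegerVector kind(n_fix), target(n_fix), table_row(n_fix, NA_INTEGER),
      n_prop(n_fix);
  NumericMatrix eff(n_fix, 3), state_m(n_fix, 7), conc_m(n_fix, 5);
  NumericVector act_v(n_fix), fit_v(n_fix);

  // pre-duplication reference
  double cA0, cAA0;
  eq_pre(s_init * folded_fraction(gf_init), dA, dAA,
         assoc_k(gbind_init, RT, false), cA0, cAA0);
  double f_pre = lognormal_fitness(a_mono * cA0 + a_AA * cAA0, alpha, beta);

  SysState st{ s_init, s_init, gf_init, gf_init,
               gbind_init, gbind_init, gbind_init };
  arma::vec::fixed<5> conc;
  double cur_act = 0.0, cur_fit = 0.0;
  double total_prop = 0.0;

  // fixation #1: the duplication (identical copy of the ancestral gene)
  {
    conc = eq_post(st.sA * folded_fraction(st.gfA),
                   st.sB * folded_fraction(st.gfB), dA, dB, dAA, dAB, dBB,
                   assoc_k(st.gAA, RT, false), assoc_k(st.gAB, RT, true),
                   assoc_k(st.gBB, RT, false));
    cur_act = a_mono * (conc(0) + conc(1)) + a_AA * conc(2) +
              a_AB * conc(3) + a_BB * conc(4);
    cur_fit = lognormal_fitness(cur_act, alpha, beta);
    double p = p_fix(f_pre, cur_fit, pop_size, fix_model, neutral);
    int tries = 0;
    while (true) {
      ++tries;
      if (++total_prop > max_proposals)
        stop("proposal budget exceeded while fixing the duplication");
      if (R::unif_rand() < p) break;
    }
    kind[0] = 0; target[0] = NA_INTEGER; n_prop[0] = tries;
    state_m(0, 0) = st.sA; state_m(0, 1) = st.sB;
    state_m(0, 2) = st.gfA; state_m(0, 3) = st.gfB;
    state_m(0, 4) = st.gAA; state_m(0, 5) = st.gAB; state_m(0, 6) = st.gBB;
    for (int j = 0; j < 5; ++j) conc_m(0, j) = conc(j);
    act_v[0] = cur_act; fit_v[0] = cur_fit;
  }

  int n_table = eff_table.nrow();
  int done = 1, tries = 0;
  while (done < n_fix) {
    if (++total_prop > max_proposals)
      stop("proposal budget exceeded (%d of %d fixations reached)", done,
           n_fix);
    ++tries;
    SysState cand = st;
    int tgt = (R::unif_rand() < 0.5) ? 0 : 1;  // 0 = A, 1 = B
    int knd;
    int row = NA_INTEGER;
    double e1 = 0.0, e2 = 0.0, e3 = 0.0;
    if (R::unif_rand() < p_exp) {
      knd = 2;  // expression: multiplicative synthesis-rate change
      double z0 = R::norm_rand(), z1 = R::norm_rand();
      double eps = sn_xi + sn_omega * (sn_delta * std::abs(z0) + sn_tau * z1);
      e1 = eps;
      if (tgt == 0) cand.sA *= (1.0 + eps); else cand.sB *= (1.0 + eps);
      if (cand.sA < 0.0) cand.sA = 0.0;
      if (cand.sB < 0.0) cand.sB = 0.0;
    } else {
      knd = 1;  // coding: correlated ddG triple
      if (source_type == 0) {
        double z0 = R::norm_rand(), z1 = R::norm_rand(), z2 = R::norm_rand();
        e1 = mu[0] + z0 * factor_u(0, 0) + z1 * factor_u(1, 0) +
             z2 * factor_u(2, 0);
        e2 = mu[1] + z0 * factor_u(0, 1) + z1 * factor_u(1, 1) +
             z2 * factor_u(2, 1);
        e3 = mu[2] + z0 * factor_u(0, 2) + z1 * factor_u(1, 2) +
             z2 * factor_u(2, 2);
      } else {
        row = (int)std::floor(R::unif_rand() * n_table);
        if (row >= n_table) row = n_table - 1;
        e1 = eff_table(row, 0); e2 = eff_table(row, 1); e3 = eff_table(row, 2);
        ++row;  // report 1-based
      }
      if (tgt == 0) { cand.gfA += e1; cand.gAA += e2; }
      else          { cand.gfB += e1; cand.gBB += e2; }
      cand.gAB += e3;
    }
    arma::vec::fixed<5> cc =
        eq_post(cand.sA * folded_fraction(cand.gfA),
                cand.sB * folded_fraction(cand.gfB), dA, dB, dAA, dAB, dBB,
                assoc_k(cand.gAA, RT, false), assoc_k(cand.gAB, RT, true),
                assoc_k(cand.gBB, RT, false));
    double cand_act = a_mono * (cc(0) + cc(1)) + a_AA * cc(2) +
                      a_AB * cc(3) + a_BB * cc(4);
    double cand_fit = lognormal_fitness(cand_act, alpha, beta);
    if (R::unif_rand() < p_fix(cur_fit, cand_fit, pop_size, fix_model, neutral)) {
      st = cand; conc = cc; cur_act = cand_act; cur_fit = cand_fit;
      kind[done] = knd; target[done] = tgt + 1; table_row[done] = row;
      eff(done, 0) = e1; eff(done, 1) = e2; eff(done, 2) = e3;
      state_m(done, 0) = st.sA; state_m(done, 1) = st.sB;
      state_m(done, 2) = st.gfA; state_m(done, 3) = st.gfB;
      state_m(done, 4) = st.gAA; state_m(done, 5) = st.gAB;
      state_m(done, 6) = st.gBB;
      for (int j = 0; j < 5; ++j) conc_m(done, j) = conc(j);
      act_v[done] = cur_act; fit_v[done] = cur_fit;
      n_prop[done] = tries;
      tries = 0;
      ++done;
    }
  }
  return List::create(
      _["kind"] = kind, _["target"] = target, _["table_row"] = table_row,
      _["eff"] = eff, _["state"] = state_m, _["conc"] = conc_m,
      _["activity"] = act_v, _["fitness"] = fit_v, _["n_proposed"] = n_prop,
      _["total_proposed"] = total_prop);
}
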