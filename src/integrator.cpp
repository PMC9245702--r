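// Core stochastic integrator for the metacommunity dynamics.
//
// Time is measured in generations. Each generation is advanced by Euler
// substeps of length dt for the deterministic drift (growth, competition,
// dispersal), after which every (patch, species) abundance is redrawn from a
// Poisson distribution with the drifted value as mean. The once-per-
// generation redraw injects demographic variance equal to the abundance per
// generation (noise amplitude omega = 1) and keeps the recorded states
// integer-valued; the substep length dt only controls the accuracy of the
// deterministic drift. A zero mean yields a zero draw, so the all-extinct
// configuration is absorbing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// dispersal increment for one species column (periodic 1D ring or global)
inline void dispersal_col(const arma::vec& n, double lam, int topology,
                          arma::vec& out) {
  const arma::uword P = n.n_elem;
  if (topology == 0) { // nearest-neighbour 1D ring
    if (P == 1) { out.zeros(); return; }
    for (arma::uword x = 0; x < P; ++x) {
      const arma::uword xp = (x + 1 == P) ? 0 : x + 1;
      const arma::uword xm = (x == 0) ? P - 1 : x - 1;
      out[x] = 0.5 * lam * (n[xp] + n[xm] - 2.0 * n[x]);
    }
  } else {             // global (all-to-all, rate lambda/P per pair)
    const double nbar = arma::mean(n);
    for (arma::uword x = 0; x < P; ++x) out[x] = lam * (nbar - n[x]);
  }
}

struct Model {
  double r, K, alpha, lambda, dt;
  int topology;
  bool use_g; double g;
  bool heterogeneous;
  arma::vec rvec, lvec;
  arma::mat At; // transposed interaction matrix, diagonal zeroed

  // competition load sum_{j != i} alpha_ij N_xj
  void comp_load(const arma::mat& N, arma::mat& comp) const {
    if (heterogeneous) {
      comp = N * At;
    } else {
      const arma::vec psum = arma::sum(N, 1);
      for (arma::uword i = 0; i < N.n_cols; ++i)
        comp.col(i) = alpha * (psum - N.col(i));
    }
  }

  void growth_factor(const arma::mat& N, const arma::mat& comp,
                     arma::mat& geff) const {
    if (use_g) { geff.fill(g); return; }
    if (heterogeneous) {
      for (arma::uword i = 0; i < N.n_cols; ++i)
        geff.col(i) = 1.0 - (r / rvec[i]) * comp.col(i) / K;
    } else {
      geff = 1.0 - comp / K;
    }
  }

  // one Euler substep of the deterministic drift, in place
  void drift_step(arma::mat& N, arma::mat& comp, arma::mat& rate,
                  arma::vec& dcol, int step) const {
    comp_load(N, comp);
    if (heterogeneous) {
      for (arma::uword i = 0; i < N.n_cols; ++i)
        rate.col(i) = rvec[i] * N.col(i) % (1.0 - N.col(i) / K) -
                      (r / K) * (N.col(i) % comp.col(i));
    } else if (use_g) {
      rate = r * N % (g - N / K);
    } else {
      rate = r * N % ((1.0 - comp / K) - N / K);
    }
    for (arma::uword i = 0; i < N.n_cols; ++i) {
      dispersal_col(N.col(i), lvec[i], topology, dcol);
      rate.col(i) += dcol;
    }
    N += dt * rate;
    for (arma::uword k = 0; k < N.n_elem; ++k) {
      if (!std::isfinite(N[k]))
        stop("non-finite abundance at patch %d, species %d (generation %d)",
             (int)(k % N.n_rows) + 1, (int)(k / N.n_rows) + 1, step + 1);
      if (N[k] < 0.0) N[k] = 0.0;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericMatrix init,
              double r, double K, double alpha, double lambda, double dt,
              int topology,            // 0 = nearest_neighbor_1d, 1 = global
              bool use_g, double g,    // fixed growth factor (single-species reference dynamics)
              bool heterogeneous,
              NumericVector r_i, NumericVector lam_i, NumericMatrix alpha_ij,
              int n_gen, int record_every, bool noise,
              bool record_species, IntegerVector occ_species) {
  const int P = init.nrow(), S = init.ncol();
  arma::mat N(init.begin(), P, S); // copy; double-valued but integer contents

  Model mod;
  mod.r = r; mod.K = K; mod.alpha = alpha; mod.lambda = lambda; mod.dt = dt;
  mod.topology = topology; mod.use_g = use_g; mod.g = g;
  mod.heterogeneous = heterogeneous;
  if (heterogeneous) {
    mod.At = arma::trans(as<arma::mat>(alpha_ij));
    mod.At.diag().zeros();
    mod.rvec = as<arma::vec>(r_i);
    mod.lvec = as<arma::vec>(lam_i);
  } else {
    mod.rvec = arma::vec(S, arma::fill::value(r));
    mod.lvec = arma::vec(S, arma::fill::value(lambda));
  }

  const int n_sub = (int)std::lround(1.0 / dt); // substeps per generation
  if (std::abs(n_sub * dt - 1.0) > 1e-8)
    stop("`dt` must divide one generation evenly");

  const int n_rec = n_gen / record_every + 1;
  NumericVector rec_time(n_rec), rec_meanN(n_rec), rec_geff(n_rec),
      rec_extant(n_rec), rec_localdiv(n_rec);
  NumericMatrix sp_mean, sp_geff;
  if (record_species) {
    sp_mean = NumericMatrix(n_rec, S);
    sp_geff = NumericMatrix(n_rec, S);
  }
  const int n_occ = occ_species.size();
  std::vector<LogicalMatrix> occ;
  for (int k = 0; k < n_occ; ++k) occ.push_back(LogicalMatrix(n_rec, P));

  arma::mat comp(P, S), geff(P, S), rate(P, S);
  arma::vec dcol(P);
  int irec = 0;
  bool dead = false; // absorbing state reached: dynamics can be skipped

  for (int gen = 0; gen <= n_gen; ++gen) {
    if (gen % record_every == 0) {
      mod.comp_load(N, comp);
      mod.growth_factor(N, comp, geff);
      rec_time[irec] = gen;
      rec_meanN[irec] = arma::accu(N) / (double)(P * S);
      rec_geff[irec] = arma::accu(geff) / (double)(P * S);
      int extant = 0;
      for (int i = 0; i < S; ++i) if (arma::accu(N.col(i)) > 0) ++extant;
      rec_extant[irec] = extant;
      double div = 0.0;
      for (int x = 0; x < P; ++x)
        for (int i = 0; i < S; ++i) div += (N(x, i) > 0);
      rec_localdiv[irec] = div / (double)P;
      if (record_species) {
        for (int i = 0; i < S; ++i) {
          sp_mean(irec, i) = arma::mean(N.col(i));
          sp_geff(irec, i) = arma::mean(geff.col(i));
        }
      }
      for (int k = 0; k < n_occ; ++k) {
        const int i = occ_species[k] - 1;
        for (int x = 0; x < P; ++x) occ[k](irec, x) = N(x, i) > 0;
      }
      ++irec;
    }
    if (gen == n_gen) break;

    if (!dead) {
      for (int s = 0; s < n_sub; ++s)
        mod.drift_step(N, comp, rate, dcol, gen);
      if (noise) {
        for (arma::uword k = 0; k < N.n_elem; ++k) N[k] = R::rpois(N[k]);
        if (arma::accu(N) == 0.0) dead = true;
      }
    }
    if ((gen + 1) % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  List occ_out(n_occ);
  for (int k = 0; k < n_occ; ++k) occ_out[k] = occ[k];
  return List::create(
      _["time"] = rec_time, _["mean_abundance"] = rec_meanN,
      _["mean_geff"] = rec_geff, _["n_extant_species"] = rec_extant,
      _["mean_local_diversity"] = rec_localdiv,
      _["species_mean"] = sp_mean, _["species_geff"] = sp_geff,
      _["occupancy"] = occ_out,
      _["final_field"] = wrap(N));
}
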