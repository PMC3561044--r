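#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Continuous-time (Gillespie) simulation of ribosome traffic on one mRNA.
//
// Lattice: codons 1..L. A ribosome is labelled by its A-site codon and
// occupies `ell` codons; exclusion is a minimum A-site gap of `ell`.
// Two-state dynamics: an AWAITING ribosome at codon a captures its cognate
// tRNA at rate k[a]; a TRNA_BOUND ribosome translocates to a+1 at rate
// gamma when the gap ahead allows it (and keeps the tRNA while blocked);
// at the last codon a TRNA_BOUND ribosome terminates at rate beta.
// Initiation places an AWAITING ribosome at codon 1 at rate alpha when the
// 5'-most ribosome has cleared the first `ell` codons.
//
// one_state = true collapses capture + translocation into a single
// exponential step of mean 1/k[a] + 1/gamma (1/beta at the last codon):
// the plain codon-dependent TASEP comparator in which a blocked ribosome
// effectively "loses" its tRNA.
//
// Uses R's RNG (seed via set.seed() on the R side).

// [[Rcpp::export]]
List gillespie_sim_cpp(NumericVector k, double alpha, double gamma,
                       double beta, int ell, double burn_in,
                       double measure_time, double sample_interval,
                       int n_batches, bool one_state) {
  const int L = k.size();
  if (L < 1) stop("rate profile must have length >= 1");
  if (alpha < 0) stop("alpha must be >= 0");

  std::vector<int> pos;    // A-site codons, strictly increasing
  std::vector<int> bound;  // 0 = AWAITING_TRNA, 1 = TRNA_BOUND
  pos.reserve(L / ell + 2);
  bound.reserve(L / ell + 2);

  // collapsed one-state step rates
  std::vector<double> q(L);
  for (int i = 0; i < L; ++i) {
    double exit_rate = (i == L - 1) ? beta : gamma;
    q[i] = 1.0 / (1.0 / k[i] + 1.0 / exit_rate);
  }

  const double t_end = burn_in + measure_time;
  const double batch_len = measure_time / n_batches;
  double t = 0.0;
  double next_sample = burn_in;

  std::vector<double> batch_term(n_batches, 0.0);
  std::vector<double> batch_init(n_batches, 0.0);
  std::vector<double> batch_rho_sum(n_batches, 0.0);
  std::vector<long> batch_rho_n(n_batches, 0);
  long n_term = 0, n_init = 0, n_samples = 0;

  std::vector<double> rates;
  rates.reserve(L / ell + 3);

  RNGScope scope;
  while (t < t_end) {
    const int N = (int)pos.size();
    rates.clear();
    double entry = (N == 0 || pos[0] > ell) ? alpha : 0.0;
    rates.push_back(entry);
    double total = entry;
    for (int i = 0; i < N; ++i) {
      const int a = pos[i];
      const bool free_ahead = (i == N - 1) || (pos[i + 1] - a > ell);
      double r;
      if (one_state) {
        if (a == L) r = q[L - 1];
        else r = free_ahead ? q[a - 1] : 0.0;
      } else {
        if (!bound[i]) r = k[a - 1];
        else if (a == L) r = beta;
        else r = free_ahead ? gamma : 0.0;
      }
      rates.push_back(r);
      total += r;
    }

    double t_new;
    if (total <= 0.0) t_new = t_end;          // absorbing (e.g. alpha = 0, empty)
    else t_new = t + R::exp_rand() / total;

    // density samples fall strictly inside [burn_in, t_end); the state is
    // constant between events, so emit all samples preceding the event
    while (next_sample <= t_new && next_sample < t_end) {
      int b = (int)((next_sample - burn_in) / batch_len);
      if (b >= n_batches) b = n_batches - 1;
      batch_rho_sum[b] += (double)N / L;
      batch_rho_n[b] += 1;
      ++n_samples;
      next_sample += sample_interval;
    }

    t = t_new;
    if (t >= t_end || total <= 0.0) break;

    double u = R::unif_rand() * total;
    int ev = 0;
    double cum = rates[0];
    while (cum < u && ev < N) {
      ++ev;
      cum += rates[ev];
    }

    if (ev == 0) {  // initiation
      pos.insert(pos.begin(), 1);
      bound.insert(bound.begin(), 0);
      if (t > burn_in) {
        ++n_init;
        int b = (int)((t - burn_in) / batch_len);
        if (b >= n_batches) b = n_batches - 1;
        batch_init[b] += 1.0;
      }
    } else {
      const int i = ev - 1;
      bool terminate = false;
      if (one_state) {
        if (pos[i] == L) terminate = true;
        else pos[i] += 1;
      } else {
        if (!bound[i]) bound[i] = 1;
        else if (pos[i] == L) terminate = true;
        else {
          pos[i] += 1;
          bound[i] = 0;
        }
      }
      if (terminate) {
        pos.erase(pos.begin() + i);
        bound.erase(bound.begin() + i);
        if (t > burn_in) {
          ++n_term;
          int b = (int)((t - burn_in) / batch_len);
          if (b >= n_batches) b = n_batches - 1;
          batch_term[b] += 1.0;
        }
      }
    }
  }

  // batched Monte-Carlo standard errors
  double J = (double)n_term / measure_time;
  double init_rate = (double)n_init / measure_time;
  double mean_J = 0.0, var_J = 0.0;
  for (int b = 0; b < n_batches; ++b) mean_J += batch_term[b] / batch_len;
  mean_J /= n_batches;
  for (int b = 0; b < n_batches; ++b) {
    double d = batch_term[b] / batch_len - mean_J;
    var_J += d * d;
  }
  var_J /= (n_batches - 1);
  double J_stderr = std::sqrt(var_J / n_batches);

  double rho = 0.0, rho_stderr = 0.0;
  std::vector<double> bm;
  for (int b = 0; b < n_batches; ++b)
    if (batch_rho_n[b] > 0) bm.push_back(batch_rho_sum[b] / batch_rho_n[b]);
  if (!bm.empty()) {
    double m = 0.0;
    for (double v : bm) m += v;
    m /= bm.size();
    rho = m;
    if (bm.size() > 1) {
      double v2 = 0.0;
      for (double v : bm) v2 += (v - m) * (v - m);
      v2 /= (bm.size() - 1);
      rho_stderr = std::sqrt(v2 / bm.size());
    }
  }

  return List::create(
      _["J"] = J, _["rho"] = rho, _["J_stderr"] = J_stderr,
      _["rho_stderr"] = rho_stderr, _["n_terminations"] = (double)n_term,
      _["init_rate"] = init_rate, _["simulated_time"] = measure_time,
      _["n_samples"] = (double)n_samples);
}
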