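// Wright-Fisher forward simulation core for the two-locus, two-allele
// compensatory model.  Haplotypes are encoded as 2-bit integers in the
// fixed order AB=0, aB=1, Ab=2, ab=3: bit 0 set means the first locus
// carries the derived allele a, bit 1 set means the second locus carries
// b.  A single-locus mutation is an XOR with 1 or 2, so aB<->Ab (XOR 3)
// is never reachable in one step.  All randomness comes from R's RNG so
// set.seed() at the R level makes every routine reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static const int HAP_AB = 0;
static const int HAP_ab = 3;

// Poisson(lambda) conditioned on being >= 1, by inversion.  Used when a
// geometric skip has already told us this generation carries mutations.
static int rpois_positive(double lambda, int cap) {
  double u = unif_rand() * (-expm1(-lambda));
  double term = std::exp(-lambda) * lambda; // P(K = 1)
  double cum = term;
  int k = 1;
  while (u > cum && k < cap) {
    ++k;
    term *= lambda / k;
    cum += term;
  }
  return k;
}

// Pick a class index proportional to counts[0..3], total known.
static inline int pick_class(const int *c, int total) {
  double u = unif_rand() * total;
  double acc = c[0];
  int h = 0;
  while (u >= acc && h < 3) acc += c[++h];
  return h;
}

// m mutations hit m distinct copies chosen uniformly from the 2N copies;
// each mutated copy flips one locus with a fair coin.  Mutated copies are
// moved out of the selectable pool so no copy mutates twice.
static void mutate_inplace(int *c, int twoN, double mean4Nmu,
                           bool at_least_one, int forced_m) {
  int m;
  if (forced_m >= 0) {
    m = forced_m;
  } else {
    if (mean4Nmu <= 0.0) return;
    m = at_least_one ? rpois_positive(mean4Nmu, twoN)
                     : (int)R::rpois(mean4Nmu);
  }
  if (m <= 0) return;
  if (m > twoN) m = twoN;
  int pool[4] = {c[0], c[1], c[2], c[3]};
  int added[4] = {0, 0, 0, 0};
  int remaining = twoN;
  for (int e = 0; e < m; ++e) {
    int h = pick_class(pool, remaining);
    --pool[h];
    --remaining;
    int locus = (unif_rand() < 0.5) ? 1 : 2;
    ++added[h ^ locus];
  }
  for (int i = 0; i < 4; ++i) c[i] = pool[i] + added[i];
}

// Each recombination event draws two distinct copies uniformly (equivalent
// to frequency-proportional haplotype choice without replacement), crosses
// them over between the loci, and returns both recombinants.  Events are
// applied sequentially within a generation.
static void recombine_inplace(int *c, int twoN, double mean2Nrho,
                              int forced_k) {
  int k;
  if (forced_k >= 0) {
    k = forced_k;
  } else {
    if (mean2Nrho <= 0.0) return;
    k = (int)R::rpois(mean2Nrho);
  }
  if (k <= 0 || twoN < 2) return;
  for (int e = 0; e < k; ++e) {
    int h1 = pick_class(c, twoN);
    --c[h1];
    int h2 = pick_class(c, twoN - 1);
    --c[h2];
    int r1 = (h1 & 1) | (h2 & 2);
    int r2 = (h2 & 1) | (h1 & 2);
    ++c[r1];
    ++c[r2];
  }
}

// Fitness-weighted multinomial resampling: the next generation is 2N draws
// with replacement with probabilities proportional to count * fitness,
// fitness (1, 1-s, 1-s, 1) in haplotype order.  Implemented as sequential
// conditional binomials over the classes actually present.
static void resample_inplace(int *c, int twoN, double s) {
  double w[4] = {1.0, 1.0 - s, 1.0 - s, 1.0};
  double p[4];
  double tot = 0.0;
  int nonzero = 0, last = 0;
  for (int i = 0; i < 4; ++i) {
    p[i] = c[i] * w[i];
    tot += p[i];
    if (c[i] > 0) { ++nonzero; last = i; }
  }
  if (nonzero <= 1) return; // monomorphic: resampling is the identity
  int left = twoN;
  double ptot = tot;
  int out[4] = {0, 0, 0, 0};
  for (int i = 0; i < 4; ++i) {
    if (p[i] <= 0.0) continue;
    if (i == last || p[i] >= ptot) { out[i] = left; left = 0; break; }
    int ni = (left > 0) ? (int)R::rbinom(left, p[i] / ptot) : 0;
    out[i] = ni;
    left -= ni;
    ptot -= p[i];
  }
  for (int i = 0; i < 4; ++i) c[i] = out[i];
}

static inline int fixed_class(const int *c, int twoN) {
  for (int i = 0; i < 4; ++i)
    if (c[i] == twoN) return i;
  return -1;
}

// [[Rcpp::export]]
IntegerVector wf_mutate_cpp(IntegerVector counts, int twoN, double mean4Nmu,
                            int forced_m) {
  int c[4] = {counts[0], counts[1], counts[2], counts[3]};
  mutate_inplace(c, twoN, mean4Nmu, false, forced_m);
  return IntegerVector::create(c[0], c[1], c[2], c[3]);
}

// [[Rcpp::export]]
IntegerVector wf_recombine_cpp(IntegerVector counts, int twoN,
                               double mean2Nrho, int forced_k) {
  int c[4] = {counts[0], counts[1], counts[2], counts[3]};
  recombine_inplace(c, twoN, mean2Nrho, forced_k);
  return IntegerVector::create(c[0], c[1], c[2], c[3]);
}

// [[Rcpp::export]]
IntegerVector wf_resample_cpp(IntegerVector counts, int twoN, double s) {
  int c[4] = {counts[0], counts[1], counts[2], counts[3]};
  resample_inplace(c, twoN, s);
  return IntegerVector::create(c[0], c[1], c[2], c[3]);
}

// One full replicate: start fixed for AB, loop
// {mutate -> recombine -> resample -> fixation check} until ab fixes or
// max_generations is reached.  While the population is monomorphic only a
// mutation can change it, so the loop jumps ahead by a geometric waiting
// time to the next generation carrying at least one mutation; this is
// distributionally identical to stepping generation by generation.
// Returns the novel-fixation event list (the implicit generation-0 AB
// fixation included), the censoring flag, and the stopping generation.
// [[Rcpp::export]]
List wf_run_replicate_cpp(int twoN, double mu, double s, double rho,
                          double max_generations) {
  double mean_mut = 2.0 * twoN * mu; // 4 N mu, N diploid
  double mean_rec = (double)twoN * rho; // 2 N rho
  double p_any_mut = -expm1(-mean_mut);
  int c[4] = {twoN, 0, 0, 0};
  double gen = 0.0;
  int last_fixed = HAP_AB;
  std::vector<double> ev_gen;
  std::vector<int> ev_hap;
  ev_gen.push_back(0.0);
  ev_hap.push_back(HAP_AB);
  bool censored = true;
  R_xlen_t iter = 0;

  // generation index of the next generation containing >= 1 mutation
  double next_mut = gen + 1.0 + R::rgeom(p_any_mut);

  while (gen < max_generations) {
    if ((++iter & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    bool mono = (fixed_class(c, twoN) >= 0);
    if (mono) {
      if (next_mut > max_generations) { gen = max_generations; break; }
      gen = next_mut; // nothing can happen before the next mutation
    } else {
      gen += 1.0;
      if (gen > max_generations) { gen = max_generations; break; }
    }
    if (gen == next_mut) {
      mutate_inplace(c, twoN, mean_mut, true, -1);
      next_mut = gen + 1.0 + R::rgeom(p_any_mut);
    }
    if (mean_rec > 0.0) recombine_inplace(c, twoN, mean_rec, -1);
    resample_inplace(c, twoN, s);
    int f = fixed_class(c, twoN);
    if (f >= 0 && f != last_fixed) {
      ev_gen.push_back(gen);
      ev_hap.push_back(f);
      last_fixed = f;
      if (f == HAP_ab) { censored = false; break; }
    }
  }

  return List::create(_["event_generation"] = wrap(ev_gen),
                      _["event_haplotype"] = wrap(ev_hap),
                      _["censored"] = censored,
                      _["end_generation"] = gen);
}

// Conditional fixation times of a single selectively neutral copy in a
// haploid Wright-Fisher population of 2N: run binomial drift from count 1
// until absorption, keep the trajectories that fix.
// [[Rcpp::export]]
NumericVector neutral_fixation_times_cpp(int twoN, int n_fix) {
  std::vector<double> times;
  times.reserve(n_fix);
  while ((int)times.size() < n_fix) {
    Rcpp::checkUserInterrupt();
    int i = 1;
    double gen = 0.0;
    while (i > 0 && i < twoN) {
      i = (int)R::rbinom(twoN, (double)i / twoN);
      gen += 1.0;
    }
    if (i == twoN) times.push_back(gen);
  }
  return wrap(times);
}
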