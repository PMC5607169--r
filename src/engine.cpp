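// Fixed-time-step stochastic engine for the microtubule / polarity-factor
// model. The update rules mirror the R reference implementations in
// R/mt_engine.R and R/pf_membrane.R; equivalence is enforced by the
// mean-field oracle tests. The particle simulation uses an embedded
// xoshiro256+ stream seeded from the run seed; the auxiliary entry points
// draw from R's RNG.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

enum MtStatus { MT_EMPTY = 0, MT_GROWING = 1, MT_SHRINKING = 2, MT_PAUSED = 3 };

// ---- fast counter-free PRNG for the particle loops ---------------------
// xoshiro256+ seeded via splitmix64 from the run seed. The particle
// simulation draws ~10^4-10^5 uniforms per step; a local generator keeps
// runs reproducible from the integer seed alone and independent of R's
// RNG call ordering.

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  inline double runif() {
    return (next() >> 11) * 0x1.0p-53;
  }
};

// ---- Walker alias table for the cyclic segment-offset distribution ----

struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;
  int K;

  explicit AliasTable(const NumericVector& q) {
    K = q.size();
    prob.assign(K, 0.0);
    alias.assign(K, 0);
    std::vector<double> scaled(K);
    std::vector<int> small, large;
    for (int i = 0; i < K; ++i) {
      scaled[i] = q[i] * K;
      (scaled[i] < 1.0 ? small : large).push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = (scaled[l] + scaled[s]) - 1.0;
      (scaled[l] < 1.0 ? small : large).push_back(l);
    }
    for (int i : small) prob[i] = 1.0;
    for (int i : large) prob[i] = 1.0;
  }

  // draw from a supplied uniform variate (allows reuse of a thinned one)
  inline int draw_from(double v) const {
    double u = v * K;
    int k = (int)u;
    if (k >= K) k = K - 1;
    return (u - k) < prob[k] ? k : alias[k];
  }
};

// ---- full particle simulation -----------------------------------------

// [[Rcpp::export]]
List run_sim_cpp(int M, double R, double v_plus, double v_minus,
                 double r_cat, double r_res, double r_nuc,
                 double r_u0, double r_uinf, double p_hill, double c_star,
                 double v_m, double k_u, double l_half, int C_total,
                 double dt, int n_steps, int record_every, int equil_steps,
                 bool homogenize, NumericVector offset_probs,
                 bool record_frames, bool refresh_binding, bool feedback_cut,
                 int seed) {
  Xoshiro rng(0x9E3779B9ULL * (uint64_t)(uint32_t)seed + 1ULL);
  const double dtheta = 2.0 * M_PI / M;
  const double p_fire = 1.0 - std::exp(-r_nuc * dt);
  const double p_cat  = 1.0 - std::exp(-r_cat * dt);
  const double p_res  = 1.0 - std::exp(-r_res * dt);
  const double p_unb  = k_u * dt;
  const double dr_u   = r_u0 - r_uinf;
  AliasTable offs(offset_probs);

  std::vector<int> status(M, MT_EMPTY);
  std::vector<double> len(M, 0.0);
  std::vector<long> memb(M, 0), memb_new(M, 0);
  std::vector<int> b_site;
  std::vector<double> b_pos;
  b_site.reserve(C_total + 16);
  b_pos.reserve(C_total + 16);
  long C_free = C_total;

  std::vector<double> gam(M, 0.0), cum(M, 0.0);
  std::vector<double> cth(M), sth(M);
  for (int i = 0; i < M; ++i) {
    cth[i] = std::cos(dtheta * i);
    sth[i] = std::sin(dtheta * i);
  }

  const int n_rec = n_steps / record_every;
  NumericVector rec_time(n_rec), rec_s1(n_rec), rec_ltot(n_rec);
  IntegerVector rec_cfree(n_rec), rec_cm(n_rec), rec_cmemb(n_rec),
                rec_paused(n_rec), rec_cmeq(n_rec);
  // post-equilibration event totals (for the delivery-flux oracle)
  double n_delivered = 0, n_falloff = 0, n_unbound = 0;
  long c_m_eq = 0;   // equilibrium bound count of the current step
  IntegerMatrix frames(record_frames ? n_rec : 0, record_frames ? M : 0);
  std::vector<double> hist_sum(M, 0.0);
  int hist_n = 0, irec = 0;

  for (int s = 1; s <= n_steps; ++s) {
    if (s % 2048 == 0) Rcpp::checkUserInterrupt();

    // local smoothed reduced densities (3-segment average, cyclic);
    // the feedback-cut control instead shows every site the spatially
    // uniform mean density, severing the polarization feedback while
    // leaving all noise sources intact
    if (feedback_cut) {
      long tot0 = 0;
      for (int i = 0; i < M; ++i) tot0 += memb[i];
      double g0 = tot0 / (2.0 * M_PI * c_star);
      for (int i = 0; i < M; ++i) gam[i] = g0;
    } else {
      for (int i = 0; i < M; ++i) {
        int il = (i == 0) ? M - 1 : i - 1;
        int ir = (i == M - 1) ? 0 : i + 1;
        gam[i] = (memb[il] + memb[i] + memb[ir]) / (3.0 * dtheta * c_star);
      }
    }

    // microtubule update: transition first, then length move
    double l_tot = 0.0;
    for (int i = 0; i < M; ++i) {
      int st = status[i];
      switch (st) {
      case MT_EMPTY:
        if (rng.runif() < p_fire) st = MT_GROWING;
        break;
      case MT_GROWING:
        if (rng.runif() < p_cat) st = MT_SHRINKING;
        break;
      case MT_SHRINKING:
        if (rng.runif() < p_res) st = MT_GROWING;
        break;
      case MT_PAUSED: {
        double ru = dr_u / (1.0 + std::pow(gam[i], p_hill)) + r_uinf;
        if (rng.runif() < 1.0 - std::exp(-ru * dt)) st = MT_SHRINKING;
        break; }
      }
      if (st == MT_GROWING) {
        len[i] += v_plus * dt;
        if (len[i] >= R) { len[i] = R; st = MT_PAUSED; }
      } else if (st == MT_SHRINKING) {
        len[i] -= v_minus * dt;
        if (len[i] <= 0.0) { len[i] = 0.0; st = MT_EMPTY; }
      }
      status[i] = st;
      l_tot += len[i];
    }

    // bound particles stranded above a shrunken tip fall off
    for (size_t j = 0; j < b_site.size();) {
      if (b_pos[j] > len[b_site[j]]) {
        ++C_free;
        b_site[j] = b_site.back(); b_site.pop_back();
        b_pos[j] = b_pos.back();   b_pos.pop_back();
      } else ++j;
    }

    // fast binding equilibrium with the instantaneous MT configuration
    if (refresh_binding && !b_site.empty()) {
      // fast-exchange limit: all bound positions decorrelate within a step
      C_free += (long)b_site.size();
      b_site.clear();
      b_pos.clear();
    }
    long C_m = (long)b_site.size();
    long C_int = C_free + C_m;
    long target = 0;
    if (l_tot > 0.0)
      target = (long)std::floor(C_int * l_tot / (l_half + l_tot) + 0.5);
    if (target > C_int) target = C_int;
    c_m_eq = target;
    if (target < C_m) {
      long k = C_m - target;
      for (long t = 0; t < k; ++t) {
        size_t idx = (size_t)(rng.runif() * b_site.size());
        if (idx >= b_site.size()) idx = b_site.size() - 1;
        b_site[idx] = b_site.back(); b_site.pop_back();
        b_pos[idx] = b_pos.back();   b_pos.pop_back();
        ++C_free;
      }
    } else if (target > C_m) {
      double acc = 0.0;
      for (int i = 0; i < M; ++i) { acc += len[i]; cum[i] = acc; }
      long k = target - C_m;
      for (long t = 0; t < k; ++t) {
        double x = rng.runif() * l_tot;
        int lo = 0, hi = M - 1;
        while (lo < hi) {           // first site with cum >= x
          int mid = (lo + hi) / 2;
          if (cum[mid] < x) lo = mid + 1; else hi = mid;
        }
        double before = (lo == 0) ? 0.0 : cum[lo - 1];
        double pos = x - before;
        if (pos > len[lo]) pos = len[lo];
        b_site.push_back(lo);
        b_pos.push_back(pos);
        --C_free;
      }
    }

    // plus-end transport and boundary delivery
    for (size_t j = 0; j < b_site.size();) {
      b_pos[j] += v_m * dt;
      int site = b_site[j];
      if (b_pos[j] > len[site]) {
        if (status[site] == MT_PAUSED) {
          ++memb[site];
          if (s > equil_steps) ++n_delivered;
        } else {
          ++C_free;
          if (s > equil_steps) ++n_falloff;
        }
        b_site[j] = b_site.back(); b_site.pop_back();
        b_pos[j] = b_pos.back();   b_pos.pop_back();
      } else ++j;
    }

    // membrane unbinding / lattice diffusion
    std::fill(memb_new.begin(), memb_new.end(), 0L);
    for (int m = 0; m < M; ++m) {
      long n = memb[m];
      for (long c = 0; c < n; ++c) {
        double u = rng.runif();
        if (u < p_unb) {
          ++C_free;
          if (s > equil_steps) ++n_unbound;
        } else {
          // the surviving uniform (u - p_unb)/(1 - p_unb) feeds the
          // offset draw
          int k = offs.draw_from((u - p_unb) / (1.0 - p_unb));
          int dest = m + k;
          if (dest >= M) dest -= M;
          ++memb_new[dest];
        }
      }
    }
    memb.swap(memb_new);

    long tot_m = 0;
    for (int m = 0; m < M; ++m) tot_m += memb[m];

    // homogenized control: uniform multinomial redistribution
    if (homogenize && tot_m > 0) {
      std::fill(memb.begin(), memb.end(), 0L);
      for (long t = 0; t < tot_m; ++t) {
        int m = (int)(rng.runif() * M);
        if (m >= M) m = M - 1;
        ++memb[m];
      }
    }

    // exact integer conservation, every step
    if (C_free + (long)b_site.size() + tot_m != (long)C_total)
      stop("polarity-factor conservation violated at step %d "
           "(free %ld + bound %ld + membrane %ld != %d)",
           s, C_free, (long)b_site.size(), tot_m, C_total);

    if (record_every > 0 && s % record_every == 0 && irec < n_rec) {
      double sx = 0.0, sy = 0.0;
      int n_paused = 0;
      for (int i = 0; i < M; ++i) {
        sx += memb[i] * cth[i];
        sy += memb[i] * sth[i];
        if (status[i] == MT_PAUSED) ++n_paused;
      }
      rec_time[irec] = s * dt;
      rec_s1[irec] = tot_m > 0 ? std::sqrt(sx * sx + sy * sy) / tot_m
                               : NA_REAL;
      rec_cfree[irec] = (int)C_free;
      rec_cm[irec] = (int)b_site.size();
      rec_cmeq[irec] = (int)c_m_eq;
      rec_cmemb[irec] = (int)tot_m;
      rec_ltot[irec] = l_tot;
      rec_paused[irec] = n_paused;
      if (s > equil_steps) {
        for (int i = 0; i < M; ++i) hist_sum[i] += memb[i];
        ++hist_n;
      }
      if (record_frames)
        for (int i = 0; i < M; ++i) frames(irec, i) = (int)memb[i];
      ++irec;
    }
  }

  NumericVector hist_mean(M);
  for (int i = 0; i < M; ++i)
    hist_mean[i] = hist_n > 0 ? hist_sum[i] / hist_n : NA_REAL;
  IntegerVector fin_status(M), fin_memb(M);
  NumericVector fin_len(M);
  for (int i = 0; i < M; ++i) {
    fin_status[i] = status[i];
    fin_len[i] = len[i];
    fin_memb[i] = (int)memb[i];
  }
  return List::create(
    _["time"] = rec_time, _["s1"] = rec_s1, _["C_free"] = rec_cfree,
    _["C_m"] = rec_cm, _["C_m_eq"] = rec_cmeq, _["C_membrane"] = rec_cmemb,
    _["l_tot"] = rec_ltot, _["M_paused"] = rec_paused,
    _["events"] = NumericVector::create(
      _["delivered"] = n_delivered, _["falloff"] = n_falloff,
      _["unbound"] = n_unbound,
      _["measured_time"] = (double)(n_steps - equil_steps) * dt),
    _["hist_mean"] = hist_mean,
    _["frames"] = record_frames ? (SEXP)frames : R_NilValue,
    _["final"] = List::create(_["status"] = fin_status, _["length"] = fin_len,
                              _["memb"] = fin_memb,
                              _["C_free"] = (int)C_free));
}

// ---- microtubule population only, clamped membrane density -------------

// [[Rcpp::export]]
List run_mts_cpp(int M, double R, double v_plus, double v_minus,
                 double r_cat, double r_res, double r_nuc, double r_u,
                 double dt, int n_steps, int equil_steps, int n_batches,
                 int max_residence) {
  const double p_fire = 1.0 - std::exp(-r_nuc * dt);
  const double p_cat  = 1.0 - std::exp(-r_cat * dt);
  const double p_res  = 1.0 - std::exp(-r_res * dt);
  const double p_rel  = 1.0 - std::exp(-r_u * dt);

  std::vector<int> status(M, MT_EMPTY);
  std::vector<double> len(M, 0.0);
  std::vector<int> pause_start(M, -1);

  const int post = n_steps - equil_steps;
  if (post < n_batches) stop("too few post-equilibration steps");
  const int per_batch = post / n_batches;
  NumericMatrix occ(n_batches, 4);
  NumericVector ltot_b(n_batches);
  std::vector<double> res_dur;
  res_dur.reserve(std::min(max_residence, 1 << 20));
  long arrivals = 0, nucleations = 0;

  for (int s = 1; s <= n_steps; ++s) {
    if (s % 8192 == 0) Rcpp::checkUserInterrupt();
    double l_tot = 0.0;
    int cnt[4] = {0, 0, 0, 0};
    for (int i = 0; i < M; ++i) {
      int st = status[i];
      switch (st) {
      case MT_EMPTY:
        if (unif_rand() < p_fire) {
          st = MT_GROWING;
          if (s > equil_steps) ++nucleations;
        }
        break;
      case MT_GROWING:
        if (unif_rand() < p_cat) st = MT_SHRINKING;
        break;
      case MT_SHRINKING:
        if (unif_rand() < p_res) st = MT_GROWING;
        break;
      case MT_PAUSED:
        if (unif_rand() < p_rel) {
          st = MT_SHRINKING;
          if (pause_start[i] > equil_steps &&
              (int)res_dur.size() < max_residence)
            res_dur.push_back((s - pause_start[i]) * dt);
          pause_start[i] = -1;
        }
        break;
      }
      if (st == MT_GROWING) {
        len[i] += v_plus * dt;
        if (len[i] >= R) {
          len[i] = R; st = MT_PAUSED; pause_start[i] = s;
          if (s > equil_steps) ++arrivals;
        }
      } else if (st == MT_SHRINKING) {
        len[i] -= v_minus * dt;
        if (len[i] <= 0.0) { len[i] = 0.0; st = MT_EMPTY; }
      }
      status[i] = st;
      l_tot += len[i];
      ++cnt[st];
    }
    if (s > equil_steps) {
      int b = (s - equil_steps - 1) / per_batch;
      if (b >= n_batches) b = n_batches - 1;
      for (int k = 0; k < 4; ++k) occ(b, k) += (double)cnt[k] / M;
      ltot_b[b] += l_tot;
    }
  }
  for (int b = 0; b < n_batches; ++b) {
    // batches are equal except the last, which absorbs the remainder
    int nb = per_batch + (b == n_batches - 1 ? post - per_batch * n_batches : 0);
    for (int k = 0; k < 4; ++k) occ(b, k) /= nb;
    ltot_b[b] /= nb;
  }
  return List::create(
    _["occ"] = occ, _["l_tot"] = ltot_b,
    _["arrivals"] = (double)arrivals, _["nucleations"] = (double)nucleations,
    _["measured_time"] = post * dt,
    _["residence"] = NumericVector(res_dur.begin(), res_dur.end()));
}

// ---- inverse-CDF sampler for diffusion on the unit circle --------------

static inline double circle_cdf(double th, double inv2pi,
                                const std::vector<double>& w) {
  // P(th) = th/(2 pi) + (1/pi) sum_n w_n sin(n th), w_n = exp(-n^2 Ddt)/n
  double s = 0.0;
  double c1 = std::cos(th), s1 = std::sin(th);
  double sn = s1, snm1 = 0.0;
  for (size_t n = 0; n < w.size(); ++n) {
    s += w[n] * sn;
    double snp1 = 2.0 * c1 * sn - snm1;
    snm1 = sn; sn = snp1;
  }
  return th * inv2pi + s / M_PI;
}

// [[Rcpp::export]]
NumericVector sample_wrapped_cpp(NumericVector u, double Ddt, double tol) {
  if (Ddt <= 0) stop("Ddt must be positive");
  int nmax = std::max(1, (int)std::ceil(std::sqrt(36.85 / Ddt)));
  std::vector<double> w(nmax);
  for (int n = 1; n <= nmax; ++n)
    w[n - 1] = std::exp(-(double)n * n * Ddt) / n;
  const double inv2pi = 1.0 / (2.0 * M_PI);
  const int N = u.size();
  NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    double lo = 0.0, hi = 2.0 * M_PI;
    int guard = 0;
    while (hi - lo > tol) {
      double mid = 0.5 * (lo + hi);
      if (circle_cdf(mid, inv2pi, w) < u[i]) lo = mid; else hi = mid;
      if (++guard > 200)
        stop("bisection failed to converge in circle-diffusion sampler");
    }
    out[i] = 0.5 * (lo + hi);
  }
  return out;
}
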