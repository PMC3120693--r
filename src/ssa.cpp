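#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Delayed stochastic simulation algorithm.
//
// The engine keeps a waiting list L of delayed product releases ordered by
// release time (FIFO among equal times).  Each iteration draws a candidate
// SSA event (R1, t1); if t + t1 falls strictly before the earliest release
// it fires, otherwise the head of L is released and the candidate is
// discarded.  Ties (t + t1 == t_min) release the waitlist head first.
// All randomness comes from R's RNG so set.seed() controls the run.

struct PendingRelease {
  double time;
  unsigned long seq;   // insertion order, breaks time ties FIFO
  int species;
  int count;
};

struct ReleaseLater {
  bool operator()(const PendingRelease &a, const PendingRelease &b) const {
    if (a.time != b.time) return a.time > b.time;
    return a.seq > b.seq;
  }
};

struct DelayedProduct {
  int species;
  int stoich;
  int kind;       // 0 zero, 1 constant, 2 gamma
  double mean;
  double shape;   // gamma only
  double scale;   // gamma only
};

struct CReaction {
  double rate;
  std::vector<int> r_sp, r_st;        // reactants
  std::vector<DelayedProduct> prods;  // all products (kind 0 = instant)
};

static double draw_delay(const DelayedProduct &p) {
  switch (p.kind) {
  case 0: return 0.0;
  case 1: return p.mean;
  default: return R::rgamma(p.shape, p.scale);
  }
}

// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(int n_species, List reactions, IntegerVector init,
                 double t_stop, NumericVector sample_times) {
  const int n_rxn = reactions.size();
  std::vector<CReaction> rx(n_rxn);
  for (int i = 0; i < n_rxn; ++i) {
    List r = reactions[i];
    CReaction c;
    c.rate = as<double>(r["rate"]);
    IntegerMatrix rm = r["reactants"];   // cols: species(0-based), stoich
    for (int j = 0; j < rm.nrow(); ++j) {
      c.r_sp.push_back(rm(j, 0));
      c.r_st.push_back(rm(j, 1));
    }
    DataFrame pm = r["products"];        // species, stoich, kind, mean, sd
    IntegerVector psp = pm["species"], pst = pm["stoich"], pk = pm["kind"];
    NumericVector pmean = pm["mean"], psd = pm["sd"];
    for (int j = 0; j < psp.size(); ++j) {
      DelayedProduct p;
      p.species = psp[j];
      p.stoich = pst[j];
      p.kind = pk[j];
      p.mean = pmean[j];
      if (p.kind == 2) {
        p.shape = (pmean[j] / psd[j]) * (pmean[j] / psd[j]);
        p.scale = psd[j] * psd[j] / pmean[j];
      } else {
        p.shape = p.scale = 0.0;
      }
      c.prods.push_back(p);
    }
    rx[i] = c;
  }

  std::vector<long> x(init.begin(), init.end());
  std::priority_queue<PendingRelease, std::vector<PendingRelease>, ReleaseLater> L;
  unsigned long seq = 0;
  double t = 0.0;
  long n_events = 0;

  const int ns = sample_times.size();
  int si = 0;
  NumericMatrix series(ns, n_species);

  RNGScope rng;

  std::vector<double> a(n_rxn);
  while (t < t_stop) {
    double a0 = 0.0;
    for (int i = 0; i < n_rxn; ++i) {
      double ai = rx[i].rate;
      for (size_t j = 0; j < rx[i].r_sp.size(); ++j) {
        long cnt = x[rx[i].r_sp[j]];
        if (rx[i].r_st[j] == 1) ai *= cnt;
        else ai *= cnt * (cnt - 1) / 2.0;  // second order, same species
      }
      a[i] = ai;
      a0 += ai;
    }
    double t_min = L.empty() ? R_PosInf : L.top().time;

    double t_next;
    bool fire = false;
    int which = -1;
    if (a0 <= 0.0) {
      if (L.empty()) { t_next = t_stop; }
      else { t_next = t_min; }                 // pure release mode
    } else {
      double t1 = R::exp_rand() / a0;
      if (t + t1 < t_min) {                    // tie releases head first
        t_next = t + t1;
        fire = true;
        double u = unif_rand() * a0, cum = 0.0;
        for (int i = 0; i < n_rxn; ++i) {
          cum += a[i];
          if (u <= cum) { which = i; break; }
        }
        if (which < 0) which = n_rxn - 1;
      } else {
        t_next = t_min;
      }
    }

    if (t_next >= t_stop) {                    // nothing more before t_stop
      while (si < ns && sample_times[si] <= t_stop) {
        for (int s = 0; s < n_species; ++s) series(si, s) = x[s];
        ++si;
      }
      t = t_stop;
      break;
    }

    // counts on [t, t_next) are current; record samples strictly before event
    while (si < ns && sample_times[si] < t_next) {
      for (int s = 0; s < n_species; ++s) series(si, s) = x[s];
      ++si;
    }
    t = t_next;

    if (fire) {
      CReaction &c = rx[which];
      for (size_t j = 0; j < c.r_sp.size(); ++j) {
        x[c.r_sp[j]] -= c.r_st[j];
        if (x[c.r_sp[j]] < 0) stop("negative molecule count: invariant violated");
      }
      for (size_t j = 0; j < c.prods.size(); ++j) {
        DelayedProduct &p = c.prods[j];
        if (p.kind == 0) {
          x[p.species] += p.stoich;
        } else {
          for (int m = 0; m < p.stoich; ++m) {  // each unit draws its own delay
            PendingRelease pr;
            pr.time = t + draw_delay(p);
            pr.seq = seq++;
            pr.species = p.species;
            pr.count = 1;
            L.push(pr);
          }
        }
      }
    } else {
      PendingRelease pr = L.top();
      L.pop();
      x[pr.species] += pr.count;
    }
    ++n_events;
  }

  while (si < ns && sample_times[si] <= t_stop) {
    for (int s = 0; s < n_species; ++s) series(si, s) = x[s];
    ++si;
  }

  IntegerVector fin(n_species), pending(n_species);
  for (int s = 0; s < n_species; ++s) fin[s] = (int)x[s];
  while (!L.empty()) { pending[L.top().species] += L.top().count; L.pop(); }

  return List::create(_["final_counts"] = fin, _["pending_counts"] = pending,
                      _["series"] = series, _["n_events"] = n_events,
                      _["t"] = t);
}
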