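// Toy nearest-neighbour-free RNA folding engine.
//
// Energy model: additive per-pair energies GC/CG = -3, AU/UA = -2,
// GU/UG = -1 (arbitrary units), minimum hairpin loop of 3 unpaired
// bases, no stacking or loop terms, Boltzmann factor exp(-E/kT) with
// kT = 1.  Small enough to enumerate exactly, rich enough to expose
// genuine ensemble behaviour (competing helices, diffuse ensembles for
// shuffled sequences).
//
// All interval recursions condition on the leftmost position being
// unpaired or paired, which is an unambiguous decomposition, so the
// partition function counts every structure exactly once and
// stochastic backtracking samples with the correct probabilities.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <string>
#include <vector>

using namespace Rcpp;

static const int MIN_LOOP = 3; // unpaired bases enclosed by a pair

static inline double pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0; // sentinel: not a canonical pair
}

static inline bool can_pair(const std::string& s, int i, int k) {
  return (k - i) > MIN_LOOP && pair_energy(s[i], s[k]) < 0;
}

// column-major upper-triangular tables indexed [i + L*j], i <= j
struct FoldTables {
  int L;
  std::vector<double> E; // MFE of interval [i, j]
  std::vector<double> Z; // partition function of [i, j]
};

static inline double getE(const FoldTables& t, int i, int j) {
  return (i > j) ? 0.0 : t.E[i + t.L * j];
}
static inline double getZ(const FoldTables& t, int i, int j) {
  return (i > j) ? 1.0 : t.Z[i + t.L * j];
}

static void fill_tables(const std::string& s, FoldTables& t, bool want_E,
                        bool want_Z) {
  const int L = (int)s.size();
  t.L = L;
  if (want_E) t.E.assign((size_t)L * L, 0.0);
  if (want_Z) t.Z.assign((size_t)L * L, 1.0);
  for (int span = 1; span < L; ++span) {
    for (int i = 0; i + span < L; ++i) {
      const int j = i + span;
      double e = want_E ? getE(t, i + 1, j) : 0.0;
      double z = want_Z ? getZ(t, i + 1, j) : 0.0;
      for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
        if (!can_pair(s, i, k)) continue;
        const double pe = pair_energy(s[i], s[k]);
        if (want_E) {
          const double cand = pe + getE(t, i + 1, k - 1) + getE(t, k + 1, j);
          if (cand < e) e = cand;
        }
        if (want_Z) {
          z += std::exp(-pe) * getZ(t, i + 1, k - 1) * getZ(t, k + 1, j);
        }
      }
      if (want_E) t.E[i + L * j] = e;
      if (want_Z) t.Z[i + L * j] = z;
    }
  }
}

// Deterministic traceback of one optimal structure: prefer pairing the
// leftmost position, then the smallest partner index.
static void traceback_mfe(const std::string& s, const FoldTables& t,
                          std::vector<int>& partner) {
  const int L = t.L;
  partner.assign(L, -1);
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, L - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    const double opt = getE(t, i, j);
    bool paired = false;
    for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
      if (!can_pair(s, i, k)) continue;
      const double cand =
          pair_energy(s[i], s[k]) + getE(t, i + 1, k - 1) + getE(t, k + 1, j);
      if (cand == opt) {
        partner[i] = k;
        partner[k] = i;
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
}

static std::string partner_to_db(const std::vector<int>& partner) {
  std::string db(partner.size(), '.');
  for (size_t i = 0; i < partner.size(); ++i) {
    if (partner[i] > (int)i) {
      db[i] = '(';
      db[partner[i]] = ')';
    }
  }
  return db;
}

static void check_seq(const std::string& s) {
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
      stop("toy engine: invalid base '%s' at position %d",
           std::string(1, c).c_str(), (int)i + 1);
  }
  if (s.empty()) stop("toy engine: empty sequence");
  if (s.size() > 300)
    stop("toy engine: sequences longer than 300 nt overflow the unscaled partition function");
}

static std::mt19937_64 make_rng(int seed, int stream) {
  std::seed_seq ss{(std::uint32_t)seed, (std::uint32_t)stream, 0x5e9u};
  return std::mt19937_64(ss);
}

// Precomputed backtracking tables: for every interval [i, j] a
// cumulative weight vector over the decomposition options (i unpaired,
// then i paired with each admissible k in increasing order), so one
// backtracking decision is a single uniform draw plus a binary search.
struct Sampler {
  int L;
  std::vector<std::vector<int> > partners; // admissible k per i
  std::vector<std::size_t> offset;         // interval -> slice start
  std::vector<int> nopt;                   // interval -> option count
  std::vector<double> cum;                 // concatenated cumulative sums
};

static void build_sampler(const std::string& s, const FoldTables& t,
                          Sampler& sp) {
  const int L = t.L;
  sp.L = L;
  sp.partners.assign(L, std::vector<int>());
  for (int i = 0; i < L; ++i)
    for (int k = i + MIN_LOOP + 1; k < L; ++k)
      if (can_pair(s, i, k)) sp.partners[i].push_back(k);
  sp.offset.assign((size_t)L * L, 0);
  sp.nopt.assign((size_t)L * L, 0);
  std::size_t total = 0;
  for (int i = 0; i < L; ++i) {
    for (int j = i + 1; j < L; ++j) {
      sp.offset[i + (size_t)L * j] = total;
      int nopt = 1; // unpaired option
      for (size_t m = 0; m < sp.partners[i].size() &&
                         sp.partners[i][m] <= j; ++m)
        ++nopt;
      sp.nopt[i + (size_t)L * j] = nopt;
      total += (std::size_t)nopt;
    }
  }
  sp.cum.assign(total, 0.0);
  for (int i = 0; i < L; ++i) {
    for (int j = i + 1; j < L; ++j) {
      std::size_t off = sp.offset[i + (size_t)L * j];
      double acc = getZ(t, i + 1, j);
      sp.cum[off] = acc;
      std::size_t m = 0;
      for (; m < sp.partners[i].size() && sp.partners[i][m] <= j; ++m) {
        const int k = sp.partners[i][m];
        acc += std::exp(-pair_energy(s[i], s[k])) * getZ(t, i + 1, k - 1) *
               getZ(t, k + 1, j);
        sp.cum[off + 1 + m] = acc;
      }
    }
  }
}

// sample one structure from [0, L-1]; fills partner with -1 for unpaired
static void sample_one(const Sampler& sp, std::mt19937_64& rng,
                       std::vector<int>& partner) {
  const int L = sp.L;
  partner.assign(L, -1);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, L - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    const std::size_t off = sp.offset[i + (size_t)L * j];
    const std::size_t nopt = (std::size_t)sp.nopt[i + (size_t)L * j];
    const double total = sp.cum[off + nopt - 1];
    const double r = unif(rng) * total;
    const double* lo = &sp.cum[off];
    const double* hi = lo + nopt;
    const double* it = std::upper_bound(lo, hi, r);
    std::size_t choice = (it == hi) ? nopt - 1 : (std::size_t)(it - lo);
    if (choice == 0) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    const int k = sp.partners[i][choice - 1];
    partner[i] = k;
    partner[k] = i;
    stack.push_back(std::make_pair(i + 1, k - 1));
    stack.push_back(std::make_pair(k + 1, j));
  }
}

// [[Rcpp::export(name = ".toy_mfe")]]
List toy_mfe(std::string seq) {
  check_seq(seq);
  FoldTables t;
  fill_tables(seq, t, true, false);
  std::vector<int> partner;
  traceback_mfe(seq, t, partner);
  return List::create(_["structure"] = partner_to_db(partner),
                      _["energy"] = getE(t, 0, (int)seq.size() - 1));
}

// [[Rcpp::export(name = ".toy_sample")]]
CharacterVector toy_sample(std::string seq, int n, int seed, int stream) {
  check_seq(seq);
  if (n < 1) stop("n must be >= 1");
  FoldTables t;
  fill_tables(seq, t, false, true);
  Sampler sp;
  build_sampler(seq, t, sp);
  std::mt19937_64 rng = make_rng(seed, stream);
  CharacterVector out(n);
  std::vector<int> partner;
  for (int m = 0; m < n; ++m) {
    sample_one(sp, rng, partner);
    out[m] = partner_to_db(partner);
  }
  return out;
}

// Exact base-pair probabilities by inside-outside recursion.
// W[i][j] = partition function over the exterior of interval [i, j],
// conditioning on the innermost pair (p, q) enclosing [i, j] (or none).
// [[Rcpp::export(name = ".toy_bpp")]]
NumericMatrix toy_bpp(std::string seq) {
  check_seq(seq);
  const int L = (int)seq.size();
  FoldTables t;
  fill_tables(seq, t, false, true);
  const double Ztot = getZ(t, 0, L - 1);
  std::vector<double> W((size_t)L * L, 0.0);
  NumericMatrix P(L, L);
  for (int span = L - 1; span >= MIN_LOOP + 1; --span) {
    for (int i = 0; i + span < L; ++i) {
      const int j = i + span;
      if (!can_pair(seq, i, j)) continue;
      double w = getZ(t, 0, i - 1) * getZ(t, j + 1, L - 1);
      for (int p = 0; p < i; ++p) {
        for (int q = j + 1; q < L; ++q) {
          if (!can_pair(seq, p, q)) continue;
          w += std::exp(-pair_energy(seq[p], seq[q])) * W[p + (size_t)L * q] *
               getZ(t, p + 1, i - 1) * getZ(t, j + 1, q - 1);
        }
      }
      W[i + (size_t)L * j] = w;
      const double prob = std::exp(-pair_energy(seq[i], seq[j])) *
                          getZ(t, i + 1, j - 1) * w / Ztot;
      P(i, j) = prob;
      P(j, i) = prob;
    }
  }
  return P;
}

// [[Rcpp::export(name = ".toy_energy")]]
double toy_energy(std::string seq, IntegerVector pi, IntegerVector pj) {
  check_seq(seq);
  double e = 0.0;
  for (int m = 0; m < pi.size(); ++m) {
    const int i = pi[m] - 1, j = pj[m] - 1;
    if (i < 0 || j >= (int)seq.size() || i >= j)
      stop("invalid pair (%d, %d)", pi[m], pj[m]);
    const double pe = pair_energy(seq[i], seq[j]);
    if (pe < 0) e += pe;
  }
  return e;
}

static const char BASES[4] = {'A', 'C', 'G', 'U'};

// enumerate 1-mutant neighbours position-major, base order A<C<G<U
static std::string mutant_at(const std::string& s, int rank) {
  const int pos = rank / 3, alt = rank % 3;
  std::string m = s;
  int seen = 0;
  for (int b = 0; b < 4; ++b) {
    if (BASES[b] == s[pos]) continue;
    if (seen == alt) {
      m[pos] = BASES[b];
      break;
    }
    ++seen;
  }
  return m;
}

// Per-mutant SEN distance d(T, T'_Nsamp): for each of the 3L 1-mutant
// neighbours, sample n structures from its Boltzmann ensemble and
// average the fraction of reference pairs retained.  Each mutant uses
// an independent RNG substream indexed by its rank, so results do not
// depend on evaluation order.
// [[Rcpp::export(name = ".toy_sen_profile")]]
NumericVector toy_sen_profile(std::string seq, IntegerVector pi,
                              IntegerVector pj, int n, int seed) {
  check_seq(seq);
  const int L = (int)seq.size();
  const int npairs = pi.size();
  if (npairs < 1) stop("reference structure has no base pairs");
  std::vector<int> ref(L, -1);
  for (int m = 0; m < npairs; ++m) {
    ref[pi[m] - 1] = pj[m] - 1;
    ref[pj[m] - 1] = pi[m] - 1;
  }
  NumericVector out(3 * L);
  std::vector<int> partner;
  FoldTables t;
  Sampler sp;
  for (int r = 0; r < 3 * L; ++r) {
    const std::string mut = mutant_at(seq, r);
    fill_tables(mut, t, false, true);
    build_sampler(mut, t, sp);
    std::mt19937_64 rng = make_rng(seed, r);
    double acc = 0.0;
    for (int m = 0; m < n; ++m) {
      sample_one(sp, rng, partner);
      int kept = 0;
      for (int i = 0; i < L; ++i)
        if (ref[i] > i && partner[i] == ref[i]) ++kept;
      acc += (double)kept / (double)npairs;
    }
    out[r] = acc / n;
  }
  return out;
}

// Per-mutant centroid paired-vector: row r holds V(cent(T'_Nsamp)) of
// the r-th 1-mutant neighbour (pairs sampled in strictly more than
// half of n draws).
// [[Rcpp::export(name = ".toy_centroid_profile")]]
IntegerMatrix toy_centroid_profile(std::string seq, int n, int seed) {
  check_seq(seq);
  const int L = (int)seq.size();
  IntegerMatrix out(3 * L, L);
  std::vector<int> partner;
  std::vector<int> counts((size_t)L * L);
  FoldTables t;
  Sampler sp;
  for (int r = 0; r < 3 * L; ++r) {
    const std::string mut = mutant_at(seq, r);
    fill_tables(mut, t, false, true);
    build_sampler(mut, t, sp);
    std::mt19937_64 rng = make_rng(seed, r);
    std::fill(counts.begin(), counts.end(), 0);
    for (int m = 0; m < n; ++m) {
      sample_one(sp, rng, partner);
      for (int i = 0; i < L; ++i)
        if (partner[i] > i) ++counts[i + (size_t)L * partner[i]];
    }
    for (int i = 0; i < L; ++i)
      for (int j = i + 1; j < L; ++j)
        if (2 * counts[i + (size_t)L * j] > n) {
          out(r, i) = 1;
          out(r, j) = 1;
        }
  }
  return out;
}

// Per-mutant base-pair distance d(T, MFE(mutant)) = |T xor MFE| (symmetric
// difference of pair sets).
// [[Rcpp::export(name = ".toy_bpdist_profile")]]
NumericVector toy_bpdist_profile(std::string seq, IntegerVector pi,
                                 IntegerVector pj) {
  check_seq(seq);
  const int L = (int)seq.size();
  std::vector<int> ref(L, -1);
  for (int m = 0; m < pi.size(); ++m) {
    ref[pi[m] - 1] = pj[m] - 1;
    ref[pj[m] - 1] = pi[m] - 1;
  }
  NumericVector out(3 * L);
  std::vector<int> partner;
  for (int r = 0; r < 3 * L; ++r) {
    const std::string mut = mutant_at(seq, r);
    FoldTables t;
    fill_tables(mut, t, true, false);
    traceback_mfe(mut, t, partner);
    int d = 0;
    for (int i = 0; i < L; ++i) {
      if (ref[i] > i && partner[i] != ref[i]) ++d;      // broken
      if (partner[i] > i && ref[i] != partner[i]) ++d;  // gained
    }
    out[r] = (double)d;
  }
  return out;
}

// Base-pair distance between MFE(seq) and a target pair set, without
// the R-level structure round trip (hot path of inverse folding).
// [[Rcpp::export(name = ".toy_mfe_bpdist")]]
int toy_mfe_bpdist(std::string seq, IntegerVector pi, IntegerVector pj) {
  check_seq(seq);
  const int L = (int)seq.size();
  std::vector<int> ref(L, -1);
  for (int m = 0; m < pi.size(); ++m) {
    ref[pi[m] - 1] = pj[m] - 1;
    ref[pj[m] - 1] = pi[m] - 1;
  }
  FoldTables t;
  fill_tables(seq, t, true, false);
  std::vector<int> partner;
  traceback_mfe(seq, t, partner);
  int d = 0;
  for (int i = 0; i < L; ++i) {
    if (ref[i] > i && partner[i] != ref[i]) ++d;
    if (partner[i] > i && ref[i] != partner[i]) ++d;
  }
  return d;
}

// Inverse folding for the toy model: restarts of an adaptive walk
// minimising the base-pair distance of the candidate's MFE structure
// to the target.  Proposals preferentially mutate positions involved
// in a defect (mispaired relative to the target), the usual local
// search strategy of inverse folders; paired target positions receive
// a compensatory partner.  Base choices follow `comp` (A,C,G,U
// frequencies) so composition-constrained backgrounds remain
// reachable.  Returns the best sequence and its achieved distance.
// [[Rcpp::export(name = ".toy_inverse_fold")]]
List toy_inverse_fold(int L, IntegerVector pi, IntegerVector pj, int seed,
                      int restarts, int steps, NumericVector comp) {
  if (L < 1) stop("empty target");
  std::vector<int> ref(L, -1);
  for (int m = 0; m < pi.size(); ++m) {
    ref[pi[m] - 1] = pj[m] - 1;
    ref[pj[m] - 1] = pi[m] - 1;
  }
  const char bases[4] = {'A', 'C', 'G', 'U'};
  double cw[4];
  double ctot = 0;
  for (int b = 0; b < 4; ++b) {
    cw[b] = comp[b] > 0 ? comp[b] : 0;
    ctot += cw[b];
  }
  if (ctot == 0) {
    for (int b = 0; b < 4; ++b) cw[b] = 0.25;
    ctot = 1;
  }
  std::mt19937_64 rng = make_rng(seed, 0x1f);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  // helpers -----------------------------------------------------------
  auto drawBase = [&](const double* w, int n) {
    double tot = 0;
    for (int b = 0; b < n; ++b) tot += w[b];
    double r = unif(rng) * tot;
    for (int b = 0; b < n; ++b) {
      r -= w[b];
      if (r < 0) return b;
    }
    return n - 1;
  };
  const std::string pairTypes[6] = {"GC", "CG", "AU", "UA", "GU", "UG"};
  auto baseIdx = [&](char c) {
    return c == 'A' ? 0 : c == 'C' ? 1 : c == 'G' ? 2 : 3;
  };
  auto randomStart = [&]() {
    std::string s(L, 'A');
    double used[4] = {0, 0, 0, 0};
    double pw[6];
    for (int t = 0; t < 6; ++t)
      pw[t] = cw[baseIdx(pairTypes[t][0])] * cw[baseIdx(pairTypes[t][1])];
    double ptot = pw[0] + pw[1] + pw[2] + pw[3] + pw[4] + pw[5];
    for (int i = 0; i < L; ++i) {
      if (ref[i] > i) {
        int t;
        if (ptot > 0) {
          t = drawBase(pw, 6);
        } else {
          t = (int)(unif(rng) * 6);
        }
        s[i] = pairTypes[t][0];
        s[ref[i]] = pairTypes[t][1];
        ++used[baseIdx(s[i])];
        ++used[baseIdx(s[ref[i]])];
      }
    }
    double resid[4];
    double rtot = 0;
    for (int b = 0; b < 4; ++b) {
      resid[b] = std::max(cw[b] / ctot * L - used[b], 0.0);
      rtot += resid[b];
    }
    if (rtot == 0) for (int b = 0; b < 4; ++b) resid[b] = cw[b];
    for (int i = 0; i < L; ++i)
      if (ref[i] < 0) s[i] = bases[drawBase(resid, 4)];
    return s;
  };
  FoldTables t;
  std::vector<int> partner, defects;
  auto evalDist = [&](const std::string& s) {
    fill_tables(s, t, true, false);
    traceback_mfe(s, t, partner);
    int d = 0;
    defects.clear();
    for (int i = 0; i < L; ++i) {
      if (partner[i] != ref[i]) defects.push_back(i);
      if (ref[i] > i && partner[i] != ref[i]) ++d;
      if (partner[i] > i && ref[i] != partner[i]) ++d;
    }
    return d;
  };
  auto mutate = [&](std::string s) {
    int pos;
    if (!defects.empty() && unif(rng) < 0.8) {
      pos = defects[(int)(unif(rng) * defects.size())];
    } else {
      pos = (int)(unif(rng) * L);
    }
    double w[4];
    for (int b = 0; b < 4; ++b)
      w[b] = (bases[b] == s[pos]) ? 0 : (cw[b] > 0 ? cw[b] : 1e-3);
    char nb = bases[drawBase(w, 4)];
    s[pos] = nb;
    if (ref[pos] >= 0) {
      // compensatory partner among canonical options, comp-weighted
      const char* opts;
      int nopt;
      static const char oG[] = {'C', 'U'}, oU[] = {'A', 'G'},
                        oA[] = {'U'}, oC[] = {'G'};
      switch (nb) {
        case 'G': opts = oG; nopt = 2; break;
        case 'U': opts = oU; nopt = 2; break;
        case 'A': opts = oA; nopt = 1; break;
        default:  opts = oC; nopt = 1; break;
      }
      double pw[2];
      for (int b = 0; b < nopt; ++b) {
        pw[b] = cw[baseIdx(opts[b])];
        if (pw[b] == 0) pw[b] = 1e-3;
      }
      s[ref[pos]] = opts[nopt == 1 ? 0 : drawBase(pw, nopt)];
    }
    return s;
  };
  // search ------------------------------------------------------------
  std::string best;
  int bestD = -1;
  for (int r = 0; r < restarts && bestD != 0; ++r) {
    std::string cur = randomStart();
    int curD = evalDist(cur);
    std::vector<int> curDefects = defects;
    for (int step = 0; step < steps && curD > 0; ++step) {
      defects = curDefects;
      std::string cand = mutate(cur);
      int candD = evalDist(cand);
      if (candD <= curD) {
        cur = cand;
        curD = candD;
        curDefects = defects;
      }
    }
    if (bestD < 0 || curD < bestD) {
      best = cur;
      bestD = curD;
    }
  }
  return List::create(_["sequence"] = best, _["distance"] = bestD);
}

// RNAalifold-like consensus folding over alignment columns: a column
// pair is admissible when at least min_frac of the rows could form a
// canonical pair there; its weight is the mean pair energy across all
// rows (non-pairing rows contribute 0).  Standard interval DP on the
// column weights; gaps ('-') never pair.
// [[Rcpp::export(name = ".toy_alifold")]]
List toy_alifold(CharacterVector rows, double min_frac) {
  const int n = rows.size();
  if (n < 1) stop("empty alignment");
  std::vector<std::string> al(n);
  for (int r = 0; r < n; ++r) al[r] = as<std::string>(rows[r]);
  const int L = (int)al[0].size();
  for (int r = 1; r < n; ++r)
    if ((int)al[r].size() != L) stop("ragged alignment rows");
  // column-pair weights
  std::vector<double> wmat((size_t)L * L, 1.0); // 1.0 => disallowed
  for (int i = 0; i < L; ++i) {
    for (int j = i + MIN_LOOP + 1; j < L; ++j) {
      int okrows = 0;
      double esum = 0.0;
      for (int r = 0; r < n; ++r) {
        const char a = al[r][i], b = al[r][j];
        if (a == '-' || b == '-') continue;
        const double pe = pair_energy(a, b);
        if (pe < 0) {
          ++okrows;
          esum += pe;
        }
      }
      if (okrows >= min_frac * n && okrows > 0)
        wmat[i + (size_t)L * j] = esum / n;
    }
  }
  // MFE-style DP on weights
  std::vector<double> E((size_t)L * L, 0.0);
  for (int span = 1; span < L; ++span) {
    for (int i = 0; i + span < L; ++i) {
      const int j = i + span;
      double e = E[(i + 1) + (size_t)L * j];
      for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
        const double w = wmat[i + (size_t)L * k];
        if (w >= 0) continue;
        const double inner = (i + 1 > k - 1) ? 0.0 : E[(i + 1) + (size_t)L * (k - 1)];
        const double outer = (k + 1 > j) ? 0.0 : E[(k + 1) + (size_t)L * j];
        const double cand = w + inner + outer;
        if (cand < e) e = cand;
      }
      E[i + (size_t)L * j] = e;
    }
  }
  // traceback (prefer pairing, smallest partner)
  std::vector<int> partner(L, -1);
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, L - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    const double opt = E[i + (size_t)L * j];
    bool paired = false;
    for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
      const double w = wmat[i + (size_t)L * k];
      if (w >= 0) continue;
      const double inner = (i + 1 > k - 1) ? 0.0 : E[(i + 1) + (size_t)L * (k - 1)];
      const double outer = (k + 1 > j) ? 0.0 : E[(k + 1) + (size_t)L * j];
      if (w + inner + outer == opt) {
        partner[i] = k;
        partner[k] = i;
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  return List::create(_["structure"] = partner_to_db(partner),
                      _["energy"] = E[0 + (size_t)L * (L - 1)]);
}
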