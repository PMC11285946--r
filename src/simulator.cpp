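// Forward-time Wright-Fisher simulator with partial selfing, linked loci,
// three mutation classes and multivariate Gaussian stabilising selection.
//
// Haplotypes are sparse lists of mutation ids, kept sorted by genomic
// position.  At most one extant variant may occupy a site: a new mutation
// landing on an occupied site is discarded (first-appearing kept).  Sites
// are released when their variant is lost; sites of fixed variants stay
// occupied and the variant moves to a substitutions ledger whose trait
// contribution (2 x effect) is carried by every individual.
//
// All randomness is drawn from R's RNG so that set.seed() in R gives
// bit-identical runs.  Draw order per offspring: parent 1 (1 uniform),
// selfing decision (1 uniform), parent 2 if outcrossed (1 uniform), then
// gamete 1 and gamete 2.  Per gamete: crossover count (Poisson), crossover
// positions (uniforms), starting haplotype (1 uniform), new-mutation count
// (Poisson), then per mutation: site (uniform), class (1 uniform, gene
// regions only) and, for trait mutations, n_traits normals.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Config {
  int N;              // diploid population size
  long L;             // genome length in bp
  int bufferLen;      // neutral buffer length (bp)
  int geneLen;        // gene length (bp)
  double mu;          // per-bp per-gamete mutation rate
  double rec;         // per-bp recombination rate
  double fracNeutral, fracDel, fracTrait; // gene-mutation class split
  double selfing;     // selfing fraction sigma
  int nTraits;        // pleiotropy degree n
  double effectSd;    // total trait-effect s.d. (per-trait var effectSd^2/n)
  double Vs;          // stabilising selection variance
  double sDel;        // magnitude of deleterious selection coefficient
  double hDel;        // dominance coefficient
  int optMode;        // 0 none, 1 instant, 2 gradual
  int shiftGen;       // optimum shift generation (shift applies for g > shiftGen)
};

const int CLS_NEUTRAL = 0, CLS_TRAIT = 1, CLS_DEL = 2;

Config parse_config(const List& cfg) {
  Config c;
  c.N = as<int>(cfg["N"]);
  c.L = (long)as<double>(cfg["L"]);
  c.bufferLen = as<int>(cfg["bufferLen"]);
  c.geneLen = as<int>(cfg["geneLen"]);
  c.mu = as<double>(cfg["mu"]);
  c.rec = as<double>(cfg["rec"]);
  c.fracNeutral = as<double>(cfg["fracNeutral"]);
  c.fracDel = as<double>(cfg["fracDeleterious"]);
  c.fracTrait = as<double>(cfg["fracTrait"]);
  c.selfing = as<double>(cfg["selfing"]);
  c.nTraits = as<int>(cfg["nTraits"]);
  c.effectSd = as<double>(cfg["effectSd"]);
  c.Vs = as<double>(cfg["Vs"]);
  c.sDel = as<double>(cfg["sDel"]);
  c.hDel = as<double>(cfg["hDel"]);
  c.optMode = as<int>(cfg["optMode"]);
  c.shiftGen = as<int>(cfg["shiftGen"]);
  return c;
}

// Optimum per trait at a given generation.  The shift magnitude is
// 1/sqrt(n) on every trait so the initial fitness drop is the same for
// any pleiotropy degree; the gradual mode ramps in 100 equal increments.
double optimum_scalar(int gen, const Config& c) {
  if (c.optMode == 0 || gen <= c.shiftGen) return 0.0;
  double target = 1.0 / std::sqrt((double)c.nTraits);
  if (c.optMode == 1) return target;
  int since = gen - c.shiftGen;
  if (since >= 100) return target;
  return target * (double)since / 100.0;
}

struct SimState {
  // global mutation table (never shrinks within a run)
  std::vector<int> mpos;
  std::vector<int> mcls;
  std::vector<int> morig;
  std::vector<double> meff;   // nmut x nTraits, row-major
  std::vector<int> mstate;    // 0 active, 1 fixed, 2 lost
  std::vector<int> active;    // active mutation ids
  std::vector<unsigned char> occupied; // per-site flag
  std::vector<std::vector<int>> haps;  // 2N haplotypes, ids sorted by pos
  std::vector<double> zsub;   // 2 x summed effects of fixed trait variants
  int nsubdel = 0;            // fixed deleterious count
  std::vector<int> subids, subgen; // substitutions ledger
  int gen = 0;

  int n_mut() const { return (int)mpos.size(); }

  int add_mutation(int pos, int cls, int origin, const double* eff, int nt) {
    mpos.push_back(pos);
    mcls.push_back(cls);
    morig.push_back(origin);
    for (int t = 0; t < nt; ++t) meff.push_back(eff ? eff[t] : 0.0);
    mstate.push_back(0);
    int id = n_mut() - 1;
    active.push_back(id);
    return id;
  }
};

// ---- fitness -------------------------------------------------------------

// Fitness of the individual formed by haplotype lists ha, hb.
// Optionally accumulates per-mutation het/hom counts (for statistics).
double individual_w(const std::vector<int>& ha, const std::vector<int>& hb,
                    const SimState& S, const Config& c, double z0,
                    double* z /* length nTraits, output incl. zsub */,
                    std::vector<int>* hetcnt, std::vector<int>* homcnt) {
  const int nt = c.nTraits;
  for (int t = 0; t < nt; ++t) z[t] = S.zsub[t];
  int nhet = 0, nhom = 0;
  size_t i = 0, j = 0;
  while (i < ha.size() || j < hb.size()) {
    int ida = (i < ha.size()) ? ha[i] : -1;
    int idb = (j < hb.size()) ? hb[j] : -1;
    int take; // 0 = a only, 1 = b only, 2 = both (homozygous)
    if (ida < 0) take = 1;
    else if (idb < 0) take = 0;
    else if (ida == idb) take = 2;
    else take = (S.mpos[ida] < S.mpos[idb]) ? 0 : 1;
    int id = (take == 1) ? idb : ida;
    int dose = (take == 2) ? 2 : 1;
    if (S.mcls[id] == CLS_TRAIT) {
      const double* e = &S.meff[(size_t)id * nt];
      for (int t = 0; t < nt; ++t) z[t] += dose * e[t];
    } else if (S.mcls[id] == CLS_DEL) {
      if (dose == 2) ++nhom; else ++nhet;
    }
    if (hetcnt) {
      if (dose == 2) ++(*homcnt)[id]; else ++(*hetcnt)[id];
    }
    if (take == 0) ++i;
    else if (take == 1) ++j;
    else { ++i; ++j; }
  }
  double ss = 0.0;
  for (int t = 0; t < nt; ++t) { double d = z[t] - z0; ss += d * d; }
  double wq = std::exp(-0.5 * ss / c.Vs);
  double wd = 1.0;
  if (c.sDel > 0.0) {
    wd = std::pow(1.0 - c.hDel * c.sDel, (double)nhet) *
         std::pow(1.0 - c.sDel, (double)nhom) *
         std::pow(1.0 - c.sDel, (double)S.nsubdel);
  }
  return wq * wd;
}

void fitness_all(const SimState& S, const Config& c, double z0,
                 std::vector<double>& w, std::vector<double>& zmat,
                 std::vector<int>* hetcnt, std::vector<int>* homcnt) {
  const int N = c.N, nt = c.nTraits;
  w.resize(N);
  zmat.resize((size_t)N * nt);
  for (int i = 0; i < N; ++i)
    w[i] = individual_w(S.haps[2 * i], S.haps[2 * i + 1], S, c, z0,
                        &zmat[(size_t)i * nt], hetcnt, homcnt);
}

// cumulative fitness for parent sampling; errors if total is zero
void cumulate(const std::vector<double>& w, std::vector<double>& cw) {
  cw.resize(w.size());
  double s = 0.0;
  for (size_t i = 0; i < w.size(); ++i) { s += w[i]; cw[i] = s; }
  if (s <= 0.0) stop("degenerate population: all fitnesses are zero");
}

int sample_parent(const std::vector<double>& cw) {
  double u = unif_rand() * cw.back();
  return (int)(std::upper_bound(cw.begin(), cw.end(), u) - cw.begin());
}

// ---- gametes -------------------------------------------------------------

// Meiotic product of one parent: crossovers + new mutations.
// If `mutate` is false no new mutations are added (inbreeding-depression
// cohorts).  New mutation ids are appended to S's table.
std::vector<int> make_gamete(SimState& S, const Config& c, int parent,
                             bool mutate) {
  const std::vector<int>& ha = S.haps[2 * parent];
  const std::vector<int>& hb = S.haps[2 * parent + 1];
  int nbp = (c.rec > 0.0) ? (int)R::rpois(c.rec * (double)(c.L - 1)) : 0;
  std::vector<double> bps(nbp);
  for (int k = 0; k < nbp; ++k) bps[k] = unif_rand() * (double)(c.L - 1);
  std::sort(bps.begin(), bps.end());
  int start = (unif_rand() < 0.5) ? 0 : 1; // 0: begin on ha, 1: on hb
  std::vector<int> ga, gb;
  ga.reserve(ha.size()); gb.reserve(hb.size());
  { // positions < bps[k] lie in segment k; parity selects the source
    size_t k = 0;
    for (int id : ha) {
      while (k < bps.size() && (double)S.mpos[id] >= bps[k]) ++k;
      if (((int)k + start) % 2 == 0) ga.push_back(id);
    }
    k = 0;
    for (int id : hb) {
      while (k < bps.size() && (double)S.mpos[id] >= bps[k]) ++k;
      if (((int)k + start) % 2 == 1) gb.push_back(id);
    }
  }
  std::vector<int> g;
  g.reserve(ga.size() + gb.size());
  std::merge(ga.begin(), ga.end(), gb.begin(), gb.end(),
             std::back_inserter(g),
             [&S](int a, int b) { return S.mpos[a] < S.mpos[b]; });
  if (mutate && c.mu > 0.0) {
    int nm = (int)R::rpois(c.mu * (double)c.L);
    int period = c.bufferLen + c.geneLen;
    std::vector<double> eff(c.nTraits, 0.0);
    for (int m = 0; m < nm; ++m) {
      long site = (long)(unif_rand() * (double)c.L);
      if (site >= c.L) site = c.L - 1;
      if (S.occupied[site]) continue; // first-appearing mutation kept
      int cls;
      if (period <= 0 || (site % period) < c.bufferLen) {
        cls = CLS_NEUTRAL;
      } else {
        double u = unif_rand();
        if (u < c.fracNeutral) cls = CLS_NEUTRAL;
        else if (u < c.fracNeutral + c.fracDel) cls = CLS_DEL;
        else cls = CLS_TRAIT;
      }
      const double* ep = nullptr;
      if (cls == CLS_TRAIT) {
        double sd = c.effectSd / std::sqrt((double)c.nTraits);
        for (int t = 0; t < c.nTraits; ++t) eff[t] = norm_rand() * sd;
        ep = eff.data();
      }
      S.occupied[site] = 1;
      int id = S.add_mutation((int)site, cls, S.gen + 1, ep, c.nTraits);
      auto it = std::lower_bound(g.begin(), g.end(), (int)site,
                                 [&S](int a, int p) { return S.mpos[a] < p; });
      g.insert(it, id);
    }
  }
  return g;
}

// one full generation: viability-weighted parent sampling, selfing with
// probability sigma, then fixation/loss bookkeeping
void reproduce(SimState& S, const Config& c, const std::vector<double>& w) {
  std::vector<double> cw;
  cumulate(w, cw);
  std::vector<std::vector<int>> nh(2 * c.N);
  for (int i = 0; i < c.N; ++i) {
    int p1 = sample_parent(cw);
    int p2 = (unif_rand() < c.selfing) ? p1 : sample_parent(cw);
    nh[2 * i] = make_gamete(S, c, p1, true);
    nh[2 * i + 1] = make_gamete(S, c, p2, true);
  }
  S.haps.swap(nh);
  S.gen += 1;

  // count copies of every active mutation; sweep losses and fixations
  std::vector<int> cnt(S.n_mut(), 0);
  for (const auto& h : S.haps)
    for (int id : h) ++cnt[id];
  const int twoN = 2 * c.N;
  bool anyFixed = false;
  std::vector<int> keep;
  keep.reserve(S.active.size());
  for (int id : S.active) {
    if (cnt[id] == 0) {
      S.mstate[id] = 2;
      S.occupied[S.mpos[id]] = 0; // site free again
    } else if (cnt[id] == twoN) {
      S.mstate[id] = 1;
      anyFixed = true;
      S.subids.push_back(id);
      S.subgen.push_back(S.gen);
      if (S.mcls[id] == CLS_TRAIT) {
        const double* e = &S.meff[(size_t)id * c.nTraits];
        for (int t = 0; t < c.nTraits; ++t) S.zsub[t] += 2.0 * e[t];
      } else if (S.mcls[id] == CLS_DEL) {
        ++S.nsubdel;
      }
      // site stays occupied: a fixed variant's position cannot re-mutate
    } else {
      keep.push_back(id);
    }
  }
  S.active.swap(keep);
  if (anyFixed) {
    for (auto& h : S.haps) {
      size_t out = 0;
      for (size_t k = 0; k < h.size(); ++k)
        if (S.mstate[h[k]] == 0) h[out++] = h[k];
      h.resize(out);
    }
  }
}

// ---- inbreeding-depression cohorts --------------------------------------

// mean fitness of `n` offspring produced by obligate selfing or obligate
// outcrossing from fitness-sampled parents, with mutation disabled
double cohort_mean_w(SimState& S, const Config& c, double z0,
                     const std::vector<double>& cw, int n, bool selfed) {
  std::vector<double> z(c.nTraits);
  double sum = 0.0;
  for (int i = 0; i < n; ++i) {
    int p1 = sample_parent(cw);
    int p2 = selfed ? p1 : sample_parent(cw);
    std::vector<int> g1 = make_gamete(S, c, p1, false);
    std::vector<int> g2 = make_gamete(S, c, p2, false);
    sum += individual_w(g1, g2, S, c, z0, z.data(), nullptr, nullptr);
  }
  return sum / (double)n;
}

// ---- import / export ------------------------------------------------------

List export_pop(const SimState& S, const Config& c) {
  const int nt = c.nTraits;
  // compact: active mutations only, in position order
  std::vector<int> act = S.active;
  std::sort(act.begin(), act.end(),
            [&S](int a, int b) { return S.mpos[a] < S.mpos[b]; });
  int m = (int)act.size();
  std::vector<int> row(S.n_mut(), 0); // id -> 1-based row
  IntegerVector id(m), pos(m), cls(m), orig(m);
  NumericMatrix eff(m, nt);
  for (int k = 0; k < m; ++k) {
    int a = act[k];
    row[a] = k + 1;
    id[k] = a + 1;
    pos[k] = S.mpos[a];
    cls[k] = S.mcls[a];
    orig[k] = S.morig[a];
    for (int t = 0; t < nt; ++t) eff(k, t) = S.meff[(size_t)a * nt + t];
  }
  List haps(2 * c.N);
  for (int h = 0; h < 2 * c.N; ++h) {
    IntegerVector v(S.haps[h].size());
    for (size_t k = 0; k < S.haps[h].size(); ++k) v[k] = row[S.haps[h][k]];
    haps[h] = v;
  }
  int ns = (int)S.subids.size();
  IntegerVector sid(ns), spos(ns), scls(ns), sorig(ns), sfix(ns);
  NumericMatrix seff(ns, nt);
  for (int k = 0; k < ns; ++k) {
    int a = S.subids[k];
    sid[k] = a + 1;
    spos[k] = S.mpos[a];
    scls[k] = S.mcls[a];
    sorig[k] = S.morig[a];
    sfix[k] = S.subgen[k];
    for (int t = 0; t < nt; ++t) seff(k, t) = S.meff[(size_t)a * nt + t];
  }
  NumericVector zs(nt), opt(nt);
  double z0 = optimum_scalar(S.gen, c);
  for (int t = 0; t < nt; ++t) { zs[t] = S.zsub[t]; opt[t] = z0; }
  return List::create(
      _["haplotypes"] = haps,
      _["mutations"] = List::create(_["id"] = id, _["position"] = pos,
                                    _["class"] = cls, _["origin"] = orig),
      _["effects"] = eff,
      _["substitutions"] = List::create(_["id"] = sid, _["position"] = spos,
                                        _["class"] = scls, _["origin"] = sorig,
                                        _["fixed"] = sfix),
      _["subEffects"] = seff,
      _["generation"] = S.gen,
      _["optimum"] = opt,
      _["zSub"] = zs,
      _["nSubDel"] = S.nsubdel);
}

SimState import_pop(const List& pop, const Config& c) {
  SimState S;
  const int nt = c.nTraits;
  List mut = pop["mutations"];
  IntegerVector pos = mut["position"], cls = mut["class"];
  IntegerVector orig = mut["origin"];
  NumericMatrix eff = pop["effects"];
  int m = pos.size();
  S.occupied.assign(c.L, 0);
  std::vector<double> e(nt);
  for (int k = 0; k < m; ++k) {
    for (int t = 0; t < nt; ++t) e[t] = eff(k, t);
    S.add_mutation(pos[k], cls[k], orig[k], e.data(), nt);
    if (pos[k] >= 0 && pos[k] < c.L) S.occupied[pos[k]] = 1;
  }
  List sub = pop["substitutions"];
  IntegerVector spos = sub["position"], scls = sub["class"];
  IntegerVector sorig = sub["origin"], sfix = sub["fixed"];
  NumericMatrix seff = pop["subEffects"];
  S.zsub.assign(nt, 0.0);
  for (int k = 0; k < spos.size(); ++k) {
    for (int t = 0; t < nt; ++t) e[t] = seff(k, t);
    int id = S.add_mutation(spos[k], scls[k], sorig[k], e.data(), nt);
    S.active.pop_back();          // ledger entries are not segregating
    S.mstate[id] = 1;
    if (spos[k] >= 0 && spos[k] < c.L) S.occupied[spos[k]] = 1;
    S.subids.push_back(id);
    S.subgen.push_back(sfix[k]);
    if (scls[k] == CLS_TRAIT)
      for (int t = 0; t < nt; ++t) S.zsub[t] += 2.0 * e[t];
    else if (scls[k] == CLS_DEL) ++S.nsubdel;
  }
  List haps = pop["haplotypes"];
  if (haps.size() != 2 * c.N)
    stop("population has %d haplotypes but config N implies %d",
         (int)haps.size(), 2 * c.N);
  S.haps.resize(2 * c.N);
  for (int h = 0; h < 2 * c.N; ++h) {
    IntegerVector v = haps[h];
    std::vector<int> ids(v.size());
    for (int k = 0; k < v.size(); ++k) {
      int r = v[k] - 1;
      if (r < 0 || r >= m) stop("haplotype refers to unknown mutation row");
      ids[k] = r;
    }
    std::sort(ids.begin(), ids.end(),
              [&S](int a, int b) { return S.mpos[a] < S.mpos[b]; });
    S.haps[h] = ids;
  }
  S.gen = as<int>(pop["generation"]);
  return S;
}

} // namespace

// ---- exported entry points ------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_optimum_at(IntegerVector generation, List config) {
  Config c = parse_config(config);
  NumericVector out(generation.size());
  for (int i = 0; i < generation.size(); ++i)
    out[i] = optimum_scalar(generation[i], c);
  return out;
}

// Run `nGens` generations from a fresh (mutation-free) population or from
// `init`.  Statistics rows are emitted at the absolute generations listed in
// `statsGens`, full snapshots at `snapshotGens`.
// [[Rcpp::export]]
List cpp_simulate(List config, Nullable<List> init, int nGens,
                  IntegerVector statsGens, IntegerVector snapshotGens,
                  bool idStream, int idSize) {
  Config c = parse_config(config);
  SimState S;
  if (init.isNotNull()) {
    S = import_pop(List(init), c);
  } else {
    S.occupied.assign(c.L, 0);
    S.haps.resize(2 * c.N);
    S.zsub.assign(c.nTraits, 0.0);
  }
  std::vector<bool> isStats, isSnap;
  int gEnd = S.gen + nGens;
  isStats.assign(gEnd + 1, false);
  isSnap.assign(gEnd + 1, false);
  for (int k = 0; k < statsGens.size(); ++k)
    if (statsGens[k] >= S.gen && statsGens[k] <= gEnd) isStats[statsGens[k]] = true;
  for (int k = 0; k < snapshotGens.size(); ++k)
    if (snapshotGens[k] >= S.gen && snapshotGens[k] <= gEnd) isSnap[snapshotGens[k]] = true;

  const int nt = c.nTraits;
  int nStats = 0;
  for (int g = S.gen; g <= gEnd; ++g) if (isStats[g]) ++nStats;
  // columns: gen, meanFitness, varFitness, inbDep, segTrait, segNeutral,
  //          segDel, fHat, then per-trait meanZ, VG, Vg, VI, CLD
  int ncol = 8 + 5 * nt;
  NumericMatrix stats(nStats, ncol);
  List snaps;
  std::vector<double> w, zmat, cw;
  std::vector<int> hetcnt, homcnt;
  int srow = 0;

  for (;;) {
    int g = S.gen;
    double z0 = optimum_scalar(g, c);
    if (isStats[g]) {
      hetcnt.assign(S.n_mut(), 0);
      homcnt.assign(S.n_mut(), 0);
      fitness_all(S, c, z0, w, zmat, &hetcnt, &homcnt);
      double mw = 0.0, m2 = 0.0;
      for (double x : w) mw += x;
      mw /= c.N;
      for (double x : w) m2 += (x - mw) * (x - mw);
      m2 /= c.N;
      int segT = 0, segN = 0, segD = 0;
      double hobs = 0.0, hexp = 0.0;
      for (int id : S.active) {
        if (S.mcls[id] == CLS_TRAIT) ++segT;
        else if (S.mcls[id] == CLS_NEUTRAL) ++segN;
        else ++segD;
        double f1 = (double)hetcnt[id] / c.N;
        double p = (hetcnt[id] + 2.0 * homcnt[id]) / (2.0 * c.N);
        hobs += f1;
        hexp += 2.0 * p * (1.0 - p);
      }
      double fhat = (hexp > 0.0) ? 1.0 - hobs / hexp : NA_REAL;
      double inbdep = NA_REAL;
      if (idStream) {
        cumulate(w, cw);
        double ws = cohort_mean_w(S, c, z0, cw, idSize, true);
        double wo = cohort_mean_w(S, c, z0, cw, idSize, false);
        inbdep = (wo > 0.0) ? 1.0 - ws / wo : NA_REAL;
      }
      stats(srow, 0) = g;
      stats(srow, 1) = mw;
      stats(srow, 2) = m2;
      stats(srow, 3) = inbdep;
      stats(srow, 4) = segT;
      stats(srow, 5) = segN;
      stats(srow, 6) = segD;
      stats(srow, 7) = fhat;
      for (int t = 0; t < nt; ++t) {
        double mz = 0.0;
        for (int i = 0; i < c.N; ++i) mz += zmat[(size_t)i * nt + t];
        mz /= c.N;
        double vG = 0.0;
        for (int i = 0; i < c.N; ++i) {
          double d = zmat[(size_t)i * nt + t] - mz;
          vG += d * d;
        }
        vG /= c.N;
        double vg = 0.0, vI = 0.0;
        for (int id : S.active) {
          if (S.mcls[id] != CLS_TRAIT) continue;
          double a = S.meff[(size_t)id * nt + t];
          double f1 = (double)hetcnt[id] / c.N;
          double f2 = (double)homcnt[id] / c.N;
          double f0 = 1.0 - f1 - f2;
          double p = f1 / 2.0 + f2;
          vg += 2.0 * p * (1.0 - p) * a * a;
          vI += (2.0 * f2 * f0 - 0.5 * f1 * f1) * a * a;
        }
        stats(srow, 8 + t) = mz;
        stats(srow, 8 + nt + t) = vG;
        stats(srow, 8 + 2 * nt + t) = vg;
        stats(srow, 8 + 3 * nt + t) = vI;
        stats(srow, 8 + 4 * nt + t) = vG - vg - vI;
      }
      ++srow;
    }
    if (isSnap[g]) {
      snaps.push_back(export_pop(S, c));
    }
    if (g >= gEnd) break;
    if (!isStats[g]) fitness_all(S, c, z0, w, zmat, nullptr, nullptr);
    reproduce(S, c, w);
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["stats"] = stats,
                      _["snapshots"] = snaps,
                      _["final"] = export_pop(S, c));
}

// Per-individual fitness components for an exported population.
// [[Rcpp::export]]
List cpp_individual_fitness(List pop, List config) {
  Config c = parse_config(config);
  SimState S = import_pop(pop, c);
  double z0 = optimum_scalar(S.gen, c);
  NumericVector w(c.N);
  NumericMatrix z(c.N, c.nTraits);
  std::vector<double> zi(c.nTraits);
  for (int i = 0; i < c.N; ++i) {
    w[i] = individual_w(S.haps[2 * i], S.haps[2 * i + 1], S, c, z0,
                        zi.data(), nullptr, nullptr);
    for (int t = 0; t < c.nTraits; ++t) z(i, t) = zi[t];
  }
  return List::create(_["w"] = w, _["z"] = z, _["optimum"] = z0);
}

// Mean fitness of an obligately selfed / outcrossed cohort (mutation off).
// [[Rcpp::export]]
NumericVector cpp_cohort_fitness(List pop, List config, int n, bool selfed) {
  Config c = parse_config(config);
  SimState S = import_pop(pop, c);
  double z0 = optimum_scalar(S.gen, c);
  std::vector<double> w, zmat, cw;
  fitness_all(S, c, z0, w, zmat, nullptr, nullptr);
  cumulate(w, cw);
  std::vector<double> z(c.nTraits);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int p1 = sample_parent(cw);
    int p2 = selfed ? p1 : sample_parent(cw);
    std::vector<int> g1 = make_gamete(S, c, p1, false);
    std::vector<int> g2 = make_gamete(S, c, p2, false);
    out[i] = individual_w(g1, g2, S, c, z0, z.data(), nullptr, nullptr);
  }
  return out;
}

// One meiotic product of a given parent (1-based), for unit tests.
// Returns inherited mutation rows and any new mutations separately.
// [[Rcpp::export]]
List cpp_make_gamete(List pop, List config, int parent, bool mutate) {
  Config c = parse_config(config);
  SimState S = import_pop(pop, c);
  if (parent < 1 || parent > c.N) stop("parent index out of range");
  int m0 = S.n_mut();
  std::vector<int> g = make_gamete(S, c, parent - 1, mutate);
  std::vector<int> inherited, fresh;
  for (int id : g) (id < m0 ? inherited : fresh).push_back(id);
  IntegerVector inh(inherited.size());
  for (size_t k = 0; k < inherited.size(); ++k) inh[k] = inherited[k] + 1;
  int nf = (int)fresh.size();
  IntegerVector fpos(nf), fcls(nf);
  NumericMatrix feff(nf, c.nTraits);
  for (int k = 0; k < nf; ++k) {
    fpos[k] = S.mpos[fresh[k]];
    fcls[k] = S.mcls[fresh[k]];
    for (int t = 0; t < c.nTraits; ++t)
      feff(k, t) = S.meff[(size_t)fresh[k] * c.nTraits + t];
  }
  return List::create(_["inherited"] = inh, _["newPositions"] = fpos,
                      _["newClasses"] = fcls, _["newEffects"] = feff);
}
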