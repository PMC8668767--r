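// Compiled core of the yearly process schedule.
//
// The island population lives in a persistent C++ state (held by an external
// pointer) so that the year loop does not round-trip every plant through R.
// All kernels consume R's RNG stream in exactly the same order as the
// package's exported step functions (survival_step, growth_step,
// competition_step, reproduction_step, disturbance_step, dispersal_step), so
// a year simulated through world_year_a_cpp() + world_year_b_cpp() is
// bit-identical to the step-by-step R pipeline under the same seed. The test
// suite asserts this equivalence.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double arrh_factor(double temp_c, double E, double k) {
  return std::exp(-E / (k * (temp_c + 273.15)));
}

// ---------------------------------------------------------------------------
// persistent population state: individual-major storage
struct PopState {
  int G;   // genes per haplotype
  int nt;  // number of traits
  std::vector<int> species, patch;
  std::vector<double> mass, at, ap;
  std::vector<char> introduced;
  std::vector<double> h1, h2, phen;  // [i * G + g], [i * nt + t]
  // seed buffer: produced by reproduction, consumed by dispersal
  std::vector<int> s_species, s_patch;
  std::vector<double> s_mass, s_h1, s_h2, s_phen;

  int size() const { return (int)species.size(); }
  int n_seeds() const { return (int)s_species.size(); }
};

static void append_from_list(PopState &st, List pop) {
  IntegerVector species = pop["species"], patch = pop["patch"];
  NumericVector mass = pop["mass"], at = pop["at"], ap = pop["ap"];
  LogicalVector intro = pop["introduced"];
  NumericMatrix h1 = pop["h1"], h2 = pop["h2"], phen = pop["phen"];
  int n = species.size();
  for (int i = 0; i < n; ++i) {
    st.species.push_back(species[i]);
    st.patch.push_back(patch[i]);
    st.mass.push_back(mass[i]);
    st.at.push_back(at[i]);
    st.ap.push_back(ap[i]);
    st.introduced.push_back(intro[i]);
    for (int g = 0; g < st.G; ++g) {
      st.h1.push_back(h1(i, g));
      st.h2.push_back(h2(i, g));
    }
    for (int t = 0; t < st.nt; ++t) st.phen.push_back(phen(i, t));
  }
}

// [[Rcpp::export]]
SEXP world_create_cpp(List pop, int n_genes, int n_traits) {
  XPtr<PopState> xp(new PopState(), true);
  xp->G = n_genes;
  xp->nt = n_traits;
  append_from_list(*xp, pop);
  return xp;
}

// [[Rcpp::export]]
int world_size_cpp(SEXP xp_) {
  XPtr<PopState> xp(xp_);
  return xp->size();
}

// [[Rcpp::export]]
List world_extract_cpp(SEXP xp_) {
  XPtr<PopState> xp(xp_);
  PopState &st = *xp;
  int n = st.size(), G = st.G, nt = st.nt;
  IntegerVector species(n), patch(n);
  NumericVector mass(n), at(n), ap(n);
  LogicalVector intro(n);
  NumericMatrix h1(n, G), h2(n, G), phen(n, nt);
  for (int i = 0; i < n; ++i) {
    species[i] = st.species[i];
    patch[i] = st.patch[i];
    mass[i] = st.mass[i];
    at[i] = st.at[i];
    ap[i] = st.ap[i];
    intro[i] = st.introduced[i];
    for (int g = 0; g < G; ++g) {
      h1(i, g) = st.h1[(size_t)i * G + g];
      h2(i, g) = st.h2[(size_t)i * G + g];
    }
    for (int t = 0; t < nt; ++t) phen(i, t) = st.phen[(size_t)i * nt + t];
  }
  return List::create(
    _["species"] = species, _["patch"] = patch, _["mass"] = mass,
    _["introduced"] = intro, _["h1"] = h1, _["h2"] = h2, _["phen"] = phen,
    _["at"] = at, _["ap"] = ap);
}

// ---------------------------------------------------------------------------
// tournament competition; shared by compete_patch() and the year kernel
static void compete_members(std::vector<int> &mem,
                            const std::vector<double> &mass,
                            const double *ap, double capacity,
                            double total, std::vector<char> &dead,
                            int &n_removed) {
  int m = (int)mem.size();
  while (total > capacity && m >= 2) {
    int i = (int)(unif_rand() * m);
    if (i >= m) i = m - 1;
    int j = (int)(unif_rand() * (m - 1));
    if (j >= m - 1) j = m - 2;
    if (j >= i) ++j;
    int a = mem[i], b = mem[j];
    int loser;
    if (ap[a] < ap[b]) loser = i;
    else if (ap[b] < ap[a]) loser = j;
    else loser = (unif_rand() < 0.5) ? i : j;
    total -= mass[mem[loser]];
    dead[mem[loser]] = 1;
    ++n_removed;
    mem[loser] = mem[m - 1];
    --m;
  }
  mem.resize(m);
}

// Density-dependent mortality within one patch, as a standalone kernel for
// the R-level competition_step(). Returns 1-based indices of the removed.
// [[Rcpp::export]]
IntegerVector compete_patch(NumericVector mass, NumericVector ap,
                            double capacity) {
  int n = mass.size();
  std::vector<double> msv(mass.begin(), mass.end());
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += msv[i];
  std::vector<int> mem(n);
  for (int i = 0; i < n; ++i) mem[i] = i;
  std::vector<char> dead(n, 0);
  int n_removed = 0;
  compete_members(mem, msv, REAL(ap), capacity, total, dead, n_removed);
  IntegerVector out(n_removed);
  int o = 0;
  for (int i = 0; i < n; ++i) if (dead[i]) out[o++] = i + 1;
  return out;
}

// ---------------------------------------------------------------------------
// Survival, growth, competition, reproduction (meiosis into the seed buffer)
// and disturbance; compacts the population in place.
// [[Rcpp::export]]
List world_year_a_cpp(SEXP xp_, NumericVector patch_temp,
                      NumericVector patch_cap,
                      double E, double k, double m0, double g0, double f0,
                      double disturbance, bool active,
                      IntegerVector gene_trait, IntegerVector gene_chrom,
                      NumericVector trait_lower, NumericVector trait_upper) {
  XPtr<PopState> xp(xp_);
  PopState &st = *xp;
  const int n = st.size();
  const int np = patch_temp.size();
  const int G = st.G;
  const int nt = st.nt;
  const int col_seed = 4, col_adult = 5;  // TRAIT_NAMES column layout

  std::vector<double> ar(np);
  for (int p = 0; p < np; ++p) ar[p] = arrh_factor(patch_temp[p], E, k);

  std::vector<char> dead(n, 0);

  // 1. survival: metabolic hazard over temperature adaptation
  int n_surv = 0;
  for (int i = 0; i < n; ++i) {
    double p = m0 * std::pow(st.mass[i], -0.25) * ar[st.patch[i] - 1] /
      std::max(st.at[i], 1e-6);
    if (p > 1.0) p = 1.0;
    if (unif_rand() < p) { dead[i] = 1; ++n_surv; }
  }

  // 2. growth of surviving juveniles
  for (int i = 0; i < n; ++i) {
    if (dead[i]) continue;
    double am = st.phen[(size_t)i * nt + col_adult];
    if (st.mass[i] < am) {
      double inc = g0 * std::pow(st.mass[i], 0.75) * ar[st.patch[i] - 1];
      st.mass[i] = std::min(am, st.mass[i] + inc);
    }
  }

  // 3. competition wherever biomass exceeds capacity
  std::vector<double> biomass(np, 0.0);
  std::vector<std::vector<int> > members(np);
  for (int i = 0; i < n; ++i) {
    if (dead[i]) continue;
    int p0 = st.patch[i] - 1;
    biomass[p0] += st.mass[i];
    members[p0].push_back(i);
  }
  int n_comp = 0;
  for (int p0 = 0; p0 < np; ++p0) {
    if (biomass[p0] > patch_cap[p0]) {
      compete_members(members[p0], st.mass, st.ap.data(), patch_cap[p0],
                      biomass[p0], dead, n_comp);
      biomass[p0] = 0.0;
      for (size_t u = 0; u < members[p0].size(); ++u) {
        int i = members[p0][u];
        if (!dead[i]) biomass[p0] += st.mass[i];
      }
    }
  }
  double max_biomass = 0.0;
  for (int p0 = 0; p0 < np; ++p0)
    max_biomass = std::max(max_biomass, biomass[p0]);

  // 4. reproduction: adults grouped by (patch, species), partner drawn
  //    uniformly among the other conspecific adults of the patch
  std::vector<int> adults;
  for (int i = 0; i < n; ++i)
    if (!dead[i] && st.mass[i] >= st.phen[(size_t)i * nt + col_adult])
      adults.push_back(i);
  std::vector<double> key(adults.size());
  for (size_t a = 0; a < adults.size(); ++a)
    key[a] = (double)st.patch[adults[a]] +
      (double)np * (double)st.species[adults[a]];
  std::vector<int> ord(adults.size());
  for (size_t a = 0; a < ord.size(); ++a) ord[a] = (int)a;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int x, int y) { return key[x] < key[y]; });

  std::vector<int> mothers, fathers;
  size_t s0 = 0;
  while (s0 < ord.size()) {
    size_t e = s0;
    while (e < ord.size() && key[ord[e]] == key[ord[s0]]) ++e;
    int m = (int)(e - s0);
    if (m >= 2) {
      for (int pos = 0; pos < m; ++pos) {
        int shift = 1 + (int)(unif_rand() * (m - 1));
        if (shift > m - 1) shift = m - 1;
        mothers.push_back(adults[ord[s0 + pos]]);
        fathers.push_back(adults[ord[s0 + (pos + shift) % m]]);
      }
    }
    s0 = e;
  }

  // seed counts: fecundity allocation divided by the mother's seed mass
  std::vector<int> midx, fidx;
  for (size_t a = 0; a < mothers.size(); ++a) {
    int mi = mothers[a];
    double alloc = f0 * std::pow(st.mass[mi], 0.75) * ar[st.patch[mi] - 1];
    double cnt = std::nearbyint(alloc / st.phen[(size_t)mi * nt + col_seed]);
    for (int c = 0; c < (int)cnt; ++c) {
      midx.push_back(mi);
      fidx.push_back(fathers[a]);
    }
  }
  const int ns = (int)midx.size();

  // meiosis: one homolog picked per chromosome per gamete (draws taken
  // chromosome-major across the whole cohort, mothers first)
  int nc = 0;
  for (int g = 0; g < G; ++g) nc = std::max(nc, gene_chrom[g]);
  std::vector<char> pickm((size_t)ns * nc), pickf((size_t)ns * nc);
  for (int jc = 0; jc < nc; ++jc)
    for (int s = 0; s < ns; ++s)
      pickm[(size_t)s + (size_t)jc * ns] = unif_rand() < 0.5;
  for (int jc = 0; jc < nc; ++jc)
    for (int s = 0; s < ns; ++s)
      pickf[(size_t)s + (size_t)jc * ns] = unif_rand() < 0.5;

  std::vector<std::vector<int> > genes_of(nt);
  for (int g = 0; g < G; ++g) genes_of[gene_trait[g] - 1].push_back(g);

  st.s_species.assign(ns, 0);
  st.s_patch.assign(ns, 0);
  st.s_mass.assign(ns, 0.0);
  st.s_h1.assign((size_t)ns * G, 0.0);
  st.s_h2.assign((size_t)ns * G, 0.0);
  st.s_phen.assign((size_t)ns * nt, 0.0);
  for (int s = 0; s < ns; ++s) {
    int mi = midx[s], fi = fidx[s];
    double *sh1 = &st.s_h1[(size_t)s * G];
    double *sh2 = &st.s_h2[(size_t)s * G];
    for (int g = 0; g < G; ++g) {
      int jc = gene_chrom[g] - 1;
      sh1[g] = pickm[(size_t)s + (size_t)jc * ns]
        ? st.h1[(size_t)mi * G + g] : st.h2[(size_t)mi * G + g];
      sh2[g] = pickf[(size_t)s + (size_t)jc * ns]
        ? st.h1[(size_t)fi * G + g] : st.h2[(size_t)fi * G + g];
    }
    double *sp = &st.s_phen[(size_t)s * nt];
    for (int t = 0; t < nt; ++t) {
      double sum = 0.0;
      for (size_t u = 0; u < genes_of[t].size(); ++u) {
        int g = genes_of[t][u];
        sum += sh1[g] + sh2[g];
      }
      double v = sum / (2.0 * genes_of[t].size());
      if (v < trait_lower[t]) v = trait_lower[t];
      if (v > trait_upper[t]) v = trait_upper[t];
      sp[t] = v;
    }
    if (sp[col_seed] > 0.5 * sp[col_adult]) sp[col_seed] = 0.5 * sp[col_adult];
    st.s_species[s] = st.species[mi];
    st.s_patch[s] = st.patch[mi];
    st.s_mass[s] = sp[col_seed];
  }

  // 5. disturbance on the remaining residents
  int n_dist = 0;
  if (active && disturbance > 0) {
    for (int i = 0; i < n; ++i) {
      if (dead[i]) continue;
      if (unif_rand() < disturbance) { dead[i] = 1; ++n_dist; }
    }
  }

  // stable in-place compaction
  int o = 0;
  for (int i = 0; i < n; ++i) {
    if (dead[i]) continue;
    if (o != i) {
      st.species[o] = st.species[i];
      st.patch[o] = st.patch[i];
      st.mass[o] = st.mass[i];
      st.at[o] = st.at[i];
      st.ap[o] = st.ap[i];
      st.introduced[o] = st.introduced[i];
      std::copy(&st.h1[(size_t)i * G], &st.h1[(size_t)i * G + G],
                &st.h1[(size_t)o * G]);
      std::copy(&st.h2[(size_t)i * G], &st.h2[(size_t)i * G + G],
                &st.h2[(size_t)o * G]);
      std::copy(&st.phen[(size_t)i * nt], &st.phen[(size_t)i * nt + nt],
                &st.phen[(size_t)o * nt]);
    }
    ++o;
  }
  st.species.resize(o);
  st.patch.resize(o);
  st.mass.resize(o);
  st.at.resize(o);
  st.ap.resize(o);
  st.introduced.resize(o);
  st.h1.resize((size_t)o * G);
  st.h2.resize((size_t)o * G);
  st.phen.resize((size_t)o * nt);

  return List::create(_["n_surv"] = n_surv, _["n_comp"] = n_comp,
                      _["n_dist"] = n_dist, _["n_seeds"] = ns,
                      _["max_patch_biomass"] = max_biomass);
}

// shared per-seed dispersal math -------------------------------------------
struct DispersalDraws {
  std::vector<double> dist, ang;
};

static void draw_dispersal(int ns, const double *scale, const double *shape,
                           int stride, DispersalDraws &d) {
  d.dist.resize(ns);
  d.ang.resize(ns);
  for (int s = 0; s < ns; ++s) {
    double u = unif_rand();
    d.dist[s] = scale[(size_t)s * stride] *
      std::pow(u / (1.0 - u), 1.0 / shape[(size_t)s * stride]);
  }
  for (int s = 0; s < ns; ++s) d.ang[s] = 2.0 * M_PI * unif_rand();
}

static inline int land_patch(double origin_row, double origin_col,
                             double dist, double ang, int side) {
  double x = origin_row + dist * std::cos(ang);
  double y = origin_col + dist * std::sin(ang);
  double rf = std::floor(x + 0.5), cf = std::floor(y + 0.5);
  if (rf < 0 || rf >= side || cf < 0 || cf >= side) return -1;
  return (int)rf * side + (int)cf;
}

static inline double gauss_cpp(double b, double c, double x) {
  double d = x - b;
  return std::exp(-d * d / (2.0 * c * c));
}

// Appends this year's transport arrivals, then disperses the seed buffer:
// kernel-sampled distance in a uniform random direction from the natal patch
// center, border mortality, and the adaptation establishment filter in the
// landing patch.
// [[Rcpp::export]]
List world_year_b_cpp(SEXP xp_, List arrivals,
                      NumericVector patch_row, NumericVector patch_col,
                      NumericVector patch_temp, NumericVector patch_precip,
                      int side, double threshold, bool bernoulli) {
  XPtr<PopState> xp(xp_);
  PopState &st = *xp;
  const int G = st.G, nt = st.nt;
  append_from_list(st, arrivals);

  const int ns = st.n_seeds();
  int n_off = 0, n_est = 0;
  if (ns > 0) {
    DispersalDraws d;
    draw_dispersal(ns, &st.s_phen[6], &st.s_phen[7], nt, d);
    std::vector<int> land(ns);
    std::vector<double> vat(ns, 0.0), vap(ns, 0.0);
    for (int s = 0; s < ns; ++s) {
      int p0 = st.s_patch[s] - 1;
      land[s] = land_patch(patch_row[p0], patch_col[p0], d.dist[s], d.ang[s],
                           side);
      if (land[s] < 0) { ++n_off; continue; }
      const double *sp = &st.s_phen[(size_t)s * nt];
      vat[s] = gauss_cpp(sp[0], sp[1], patch_temp[land[s]]);
      vap[s] = gauss_cpp(sp[2], sp[3], patch_precip[land[s]]);
    }
    std::vector<char> ok(ns, 0);
    if (bernoulli) {
      for (int s = 0; s < ns; ++s) {
        double draw = unif_rand();
        ok[s] = land[s] >= 0 && draw < vat[s] * vap[s];
      }
    } else {
      for (int s = 0; s < ns; ++s)
        ok[s] = land[s] >= 0 && vat[s] * vap[s] >= threshold;
    }
    for (int s = 0; s < ns; ++s) {
      if (!ok[s]) continue;
      ++n_est;
      st.species.push_back(st.s_species[s]);
      st.patch.push_back(land[s] + 1);
      st.mass.push_back(st.s_mass[s]);
      st.at.push_back(vat[s]);
      st.ap.push_back(vap[s]);
      st.introduced.push_back(0);
      st.h1.insert(st.h1.end(), &st.s_h1[(size_t)s * G],
                   &st.s_h1[(size_t)s * G + G]);
      st.h2.insert(st.h2.end(), &st.s_h2[(size_t)s * G],
                   &st.s_h2[(size_t)s * G + G]);
      st.phen.insert(st.phen.end(), &st.s_phen[(size_t)s * nt],
                     &st.s_phen[(size_t)s * nt + nt]);
    }
  }
  st.s_species.clear();
  st.s_patch.clear();
  st.s_mass.clear();
  st.s_h1.clear();
  st.s_h2.clear();
  st.s_phen.clear();
  return List::create(_["n_dispersed"] = ns, _["n_off_island"] = n_off,
                      _["n_established"] = n_est);
}

// Standalone dispersal kernel backing the R-level dispersal_step().
// [[Rcpp::export]]
List disperse_cpp(IntegerVector species, IntegerVector patch,
                  NumericVector mass, LogicalVector introduced,
                  NumericMatrix h1, NumericMatrix h2, NumericMatrix phen,
                  NumericVector patch_row, NumericVector patch_col,
                  NumericVector patch_temp, NumericVector patch_precip,
                  int side, double threshold, bool bernoulli) {
  const int ns = species.size();
  const int G = h1.ncol();
  const int nt = phen.ncol();
  std::vector<double> scale(ns), shape(ns);
  for (int s = 0; s < ns; ++s) { scale[s] = phen(s, 6); shape[s] = phen(s, 7); }
  DispersalDraws d;
  draw_dispersal(ns, scale.data(), shape.data(), 1, d);
  std::vector<int> land(ns);
  std::vector<double> vat(ns, 0.0), vap(ns, 0.0);
  int n_off = 0;
  for (int s = 0; s < ns; ++s) {
    int p0 = patch[s] - 1;
    land[s] = land_patch(patch_row[p0], patch_col[p0], d.dist[s], d.ang[s],
                         side);
    if (land[s] < 0) { ++n_off; continue; }
    vat[s] = gauss_cpp(phen(s, 0), phen(s, 1), patch_temp[land[s]]);
    vap[s] = gauss_cpp(phen(s, 2), phen(s, 3), patch_precip[land[s]]);
  }
  std::vector<char> ok(ns, 0);
  if (bernoulli) {
    for (int s = 0; s < ns; ++s) {
      double draw = unif_rand();
      ok[s] = land[s] >= 0 && draw < vat[s] * vap[s];
    }
  } else {
    for (int s = 0; s < ns; ++s)
      ok[s] = land[s] >= 0 && vat[s] * vap[s] >= threshold;
  }
  int ne = 0;
  for (int s = 0; s < ns; ++s) if (ok[s]) ++ne;
  IntegerVector esp(ne), epa(ne);
  NumericVector ema(ne), eat(ne), eap(ne);
  LogicalVector ein(ne);
  NumericMatrix eh1(ne, G), eh2(ne, G), eph(ne, nt);
  int o = 0;
  for (int s = 0; s < ns; ++s) {
    if (!ok[s]) continue;
    esp[o] = species[s];
    epa[o] = land[s] + 1;
    ema[o] = mass[s];
    ein[o] = introduced[s];
    eat[o] = vat[s];
    eap[o] = vap[s];
    for (int g = 0; g < G; ++g) { eh1(o, g) = h1(s, g); eh2(o, g) = h2(s, g); }
    for (int t = 0; t < nt; ++t) eph(o, t) = phen(s, t);
    ++o;
  }
  return List::create(
    _["pop"] = List::create(
      _["species"] = esp, _["patch"] = epa, _["mass"] = ema,
      _["introduced"] = ein, _["h1"] = eh1, _["h2"] = eh2, _["phen"] = eph,
      _["at"] = eat, _["ap"] = eap),
    _["n_dispersed"] = ns, _["n_off_island"] = n_off,
    _["n_established"] = ne);
}
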