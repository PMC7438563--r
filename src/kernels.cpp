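#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Haplotypes in the base-genome simulator are sparse sorted vectors of
// derived-mutation positions on a single global genetic coordinate axis
// (Morgans, chromosomes laid end to end). Physical positions are a linear
// rescaling handled on the R side.
//
// Dense haplotype matrices throughout the package are loci x gametes
// (column j = gamete j), so per-gamete scans are contiguous in memory.

typedef std::vector<double> Hap;

static void chr_ranges(const NumericVector& pos, const NumericVector& cstart,
                       const NumericVector& clen,
                       std::vector<int>& pfirst, std::vector<int>& plast);

static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Sample crossover breakpoints for one meiosis. Crossovers are Poisson with
// mean = chromosome genetic length, positions uniform, no interference.
// Chromosomes assort independently (random starting haplotype each).
static void sample_breakpoints(const NumericVector& chr_start,
                               const NumericVector& chr_len,
                               std::vector<double>& bp,
                               std::vector<int>& start_hap) {
  int nc = chr_len.size();
  bp.clear();
  start_hap.resize(nc);
  for (int c = 0; c < nc; ++c) {
    start_hap[c] = unif_rand() < 0.5 ? 0 : 1;
    int k = (int)R::rpois(chr_len[c]);
    for (int j = 0; j < k; ++j) bp.push_back(chr_start[c] + unif_rand() * chr_len[c]);
  }
  std::sort(bp.begin(), bp.end());
}

// Recombine two sparse haplotypes given breakpoints; fills `out`.
static void recombine_sparse(const Hap& h0, const Hap& h1,
                             const NumericVector& chr_start,
                             const NumericVector& chr_len,
                             const std::vector<double>& bp,
                             const std::vector<int>& start_hap,
                             Hap& out) {
  out.clear();
  int nc = chr_len.size();
  size_t ib = 0;
  for (int c = 0; c < nc; ++c) {
    double a = chr_start[c];
    double end = a + chr_len[c];
    int cur = start_hap[c];
    while (a < end) {
      double b = end;
      if (ib < bp.size() && bp[ib] < end) b = bp[ib];
      const Hap& h = cur == 0 ? h0 : h1;
      Hap::const_iterator lo = std::lower_bound(h.begin(), h.end(), a);
      Hap::const_iterator hi = std::lower_bound(h.begin(), h.end(), b);
      out.insert(out.end(), lo, hi);
      if (b < end) { ++ib; cur = 1 - cur; }
      a = b;
    }
  }
}

// Forward Wright-Fisher simulation with infinite-sites mutation and
// recombination. Optionally initialised at the stationary neutral site
// frequency spectrum (E[#sites at derived count i] = theta/i) so that the
// forward phase only has to build linkage structure, not diversity.
// n_ind monoecious individuals; u_gamete = genome-wide mutation rate per
// gamete per generation. Returns the 2*n_out founder haplotypes over all
// sites segregating among them, as a (sites x gametes) raw matrix.
// [[Rcpp::export]]
List cpp_wf_sim(int n_ind, int n_gen, double u_gamete, NumericVector chr_len,
                int n_out, bool equilibrium_init) {
  int nc = chr_len.size();
  NumericVector chr_start(nc);
  double tot = 0.0;
  for (int c = 0; c < nc; ++c) { chr_start[c] = tot; tot += chr_len[c]; }

  int nh = 2 * n_ind;
  std::vector<Hap> pop(nh), nxt(nh);

  if (equilibrium_init && u_gamete > 0) {
    double theta = 4.0 * n_ind * u_gamete;
    std::vector<int> idx(nh);
    for (int i = 1; i < nh; ++i) {
      int ns = (int)R::rpois(theta / i);
      for (int s = 0; s < ns; ++s) {
        double p = unif_rand() * tot;
        for (int j = 0; j < nh; ++j) idx[j] = j;
        for (int j = 0; j < i; ++j) {  // partial Fisher-Yates: i distinct carriers
          int r = j + rand_int(nh - j);
          std::swap(idx[j], idx[r]);
          pop[idx[j]].push_back(p);
        }
      }
    }
    for (int j = 0; j < nh; ++j) std::sort(pop[j].begin(), pop[j].end());
  }

  std::vector<double> bp;
  std::vector<int> sh;
  Hap gam;
  for (int g = 0; g < n_gen; ++g) {
    for (int i = 0; i < n_ind; ++i) {
      for (int m = 0; m < 2; ++m) {
        int par = rand_int(n_ind);
        sample_breakpoints(chr_start, chr_len, bp, sh);
        recombine_sparse(pop[2 * par], pop[2 * par + 1], chr_start, chr_len, bp, sh, gam);
        int nm = (int)R::rpois(u_gamete);
        if (nm > 0) {  // merge the few new mutations, do not re-sort the gamete
          size_t base = gam.size();
          for (int s = 0; s < nm; ++s) gam.push_back(unif_rand() * tot);
          std::sort(gam.begin() + base, gam.end());
          std::inplace_merge(gam.begin(), gam.begin() + base, gam.end());
        }
        nxt[2 * i + m].swap(gam);
      }
    }
    pop.swap(nxt);
  }

  // expand to the founder cohort by one more round of random mating
  int nhout = 2 * n_out;
  std::vector<Hap> founders(nhout);
  for (int i = 0; i < n_out; ++i) {
    for (int m = 0; m < 2; ++m) {
      int par = rand_int(n_ind);
      sample_breakpoints(chr_start, chr_len, bp, sh);
      recombine_sparse(pop[2 * par], pop[2 * par + 1], chr_start, chr_len, bp, sh, gam);
      founders[2 * i + m].swap(gam);
    }
  }

  // collect segregating sites among founders
  std::vector<double> all;
  for (int j = 0; j < nhout; ++j) all.insert(all.end(), founders[j].begin(), founders[j].end());
  std::sort(all.begin(), all.end());
  std::vector<double> upos;
  std::vector<int> cnt;
  size_t i = 0;
  while (i < all.size()) {
    size_t j = i;
    while (j < all.size() && all[j] == all[i]) ++j;
    if ((int)(j - i) < nhout) { upos.push_back(all[i]); cnt.push_back((int)(j - i)); }
    i = j;
  }
  int S = upos.size();
  RawMatrix H(S, nhout);
  for (int j = 0; j < nhout; ++j) {
    const Hap& h = founders[j];
    Rbyte* col = &H(0, j);
    for (size_t k = 0; k < h.size(); ++k) {
      std::vector<double>::iterator it =
        std::lower_bound(upos.begin(), upos.end(), h[k]);
      if (it != upos.end() && *it == h[k]) col[it - upos.begin()] = 1;
    }
  }
  return List::create(_["pos"] = NumericVector(upos.begin(), upos.end()),
                      _["count"] = IntegerVector(cnt.begin(), cnt.end()),
                      _["hap"] = H);
}

// Copy one chromosome's mosaic from two parental arrays into the child
// array: loci at positions <= the next breakpoint come from the current
// source, then the source flips. Segment copies use memcpy; breakpoints
// falling between the same pair of loci (or beyond the last locus) just
// flip the state.
template <typename T>
static void copy_mosaic(const double* pos, int first, int last,
                        const T* s0, const T* s1, T* out,
                        const std::vector<double>& bp, size_t ib, size_t ibend,
                        int state) {
  int k = first;
  while (k < last) {
    int kend;
    if (ib < ibend) {
      kend = (int)(std::upper_bound(pos + k, pos + last, bp[ib]) - pos);
    } else {
      kend = last;
    }
    if (kend > k) {
      const T* src = state == 0 ? s0 : s1;
      std::memcpy(out + k, src + k, (size_t)(kend - k) * sizeof(T));
      k = kend;
    }
    if (ib < ibend) { state = 1 - state; ++ib; } else break;
  }
}

// Batch meiosis over tracked loci with founder-origin propagation.
// hap: L x (2*n_par) raw 0/1, columns 2i-2, 2i-1 are individual i's
// gametes (1-based i). origin: Lg x (2*n_par) integer founder-gamete ids
// at grid loci (may have 0 rows). pos/gpos: global genetic coords of panel
// and grid loci (ascending). cstart/clen: chromosome starts/lengths.
// sire/dam: 1-based parent individual indices per offspring.
// [[Rcpp::export]]
List cpp_meiosis_batch(RawMatrix hap, IntegerMatrix origin,
                       NumericVector pos, NumericVector gpos,
                       NumericVector cstart, NumericVector clen,
                       IntegerVector sire, IntegerVector dam) {
  int n_off = sire.size();
  int L = pos.size(), Lg = gpos.size(), nc = clen.size();
  bool track = origin.nrow() > 0;
  RawMatrix hout(L, 2 * n_off);
  IntegerMatrix oout(track ? Lg : 0, track ? 2 * n_off : 0);

  std::vector<int> pfirst, plast, gfirst, glast;
  chr_ranges(pos, cstart, clen, pfirst, plast);
  chr_ranges(gpos, cstart, clen, gfirst, glast);

  std::vector<double> bp;
  std::vector<int> sh;
  for (int o = 0; o < n_off; ++o) {
    for (int side = 0; side < 2; ++side) {
      int par = (side == 0 ? sire[o] : dam[o]) - 1;
      const Rbyte* p0 = &hap(0, 2 * par);
      const Rbyte* p1 = &hap(0, 2 * par + 1);
      Rbyte* child = &hout(0, 2 * o + side);
      sample_breakpoints(cstart, clen, bp, sh);
      for (int c = 0; c < nc; ++c) {
        double e = cstart[c] + clen[c];
        size_t ib0 = std::lower_bound(bp.begin(), bp.end(), cstart[c]) - bp.begin();
        size_t ibend = std::lower_bound(bp.begin(), bp.end(), e) - bp.begin();
        copy_mosaic(REAL(pos), pfirst[c], plast[c], p0, p1, child,
                    bp, ib0, ibend, sh[c]);
        if (track) {
          copy_mosaic(REAL(gpos), gfirst[c], glast[c],
                      &origin(0, 2 * par), &origin(0, 2 * par + 1),
                      &oout(0, 2 * o + side), bp, ib0, ibend, sh[c]);
        }
      }
    }
  }
  return List::create(_["hap"] = hout, _["origin"] = oout);
}

// Reference-allele genotype codings straight from the raw haplotype matrix
// (loci x gametes), one pass, no intermediate dosage copy. Output is
// loci x individuals so both the haplotype reads and the output writes
// are contiguous column walks.
// mode 0: dosage 0/1/2; 1: centred (m - 2 p0); 2: standardized
// (m - 2 p0)/sqrt(2 p0 (1-p0)); 3: angular-intensity
// 2*(asin(sqrt(m/2)) - asin(sqrt(p0))).
// ind, cols 1-based; ref_derived flags whether the derived allele is the
// panel's reference allele at each locus.
// [[Rcpp::export]]
NumericMatrix cpp_dosage_coded(RawMatrix hap, IntegerVector ind, IntegerVector cols,
                               LogicalVector ref_derived, NumericVector p0,
                               int mode) {
  int n = ind.size(), m = cols.size();
  NumericMatrix D(m, n);
  // per-locus lookup tables over raw dosage 0/1/2 of the derived allele
  std::vector<double> lut(3 * m);
  for (int j = 0; j < m; ++j) {
    for (int d = 0; d < 3; ++d) {
      double dos = ref_derived[j] ? d : 2 - d;
      double v;
      switch (mode) {
      case 1: v = dos - 2.0 * p0[j]; break;
      case 2: v = (dos - 2.0 * p0[j]) / std::sqrt(2.0 * p0[j] * (1.0 - p0[j])); break;
      case 3: v = 2.0 * (std::asin(std::sqrt(dos / 2.0)) - std::asin(std::sqrt(p0[j]))); break;
      default: v = dos;
      }
      lut[3 * j + d] = v;
    }
  }
  for (int i = 0; i < n; ++i) {
    const Rbyte* h0 = &hap(0, 2 * (ind[i] - 1));
    const Rbyte* h1 = &hap(0, 2 * (ind[i] - 1) + 1);
    double* dcol = &D(0, i);
    for (int j = 0; j < m; ++j) {
      int cj = cols[j] - 1;
      dcol[j] = lut[3 * j + h0[cj] + h1[cj]];
    }
  }
  return D;
}

// Mean derived-allele frequency per locus over the gametes of the given
// individuals (1-based indices).
// [[Rcpp::export]]
NumericVector cpp_col_freq(RawMatrix hap, IntegerVector ind, IntegerVector cols) {
  int n = ind.size(), m = cols.size();
  std::vector<long> acc(m, 0);
  for (int i = 0; i < n; ++i) {
    const Rbyte* h0 = &hap(0, 2 * (ind[i] - 1));
    const Rbyte* h1 = &hap(0, 2 * (ind[i] - 1) + 1);
    for (int j = 0; j < m; ++j) {
      int cj = cols[j] - 1;
      acc[j] += h0[cj] + h1[cj];
    }
  }
  NumericVector f(m);
  for (int j = 0; j < m; ++j) f[j] = (double)acc[j] / (2.0 * n);
  return f;
}

// Linkage-analysis / true-descent IBD relationship matrix from founder
// origins on the evaluation grid (Lg x gametes): entry (i,j) = 2 * f_ij
// with f_ij = mean over grid loci of (1/4) * #{(a,b) in gametes(i) x
// gametes(j): same founder origin}. Diagonal = 1 + F_IBD.
// [[Rcpp::export]]
NumericMatrix cpp_origin_gmat(IntegerMatrix origin, IntegerVector ind) {
  int n = ind.size(), L = origin.nrow();
  NumericMatrix G(n, n);
  for (int i = 0; i < n; ++i) {
    const int* a0 = &origin(0, 2 * (ind[i] - 1));
    const int* a1 = &origin(0, 2 * (ind[i] - 1) + 1);
    for (int j = i; j < n; ++j) {
      const int* b0 = &origin(0, 2 * (ind[j] - 1));
      const int* b1 = &origin(0, 2 * (ind[j] - 1) + 1);
      long m = 0;
      if (i == j) {
        for (int k = 0; k < L; ++k) m += (a0[k] == a1[k]);
        G(i, i) = 1.0 + (double)m / L;
      } else {
        for (int k = 0; k < L; ++k) {
          m += (a0[k] == b0[k]) + (a0[k] == b1[k]) + (a1[k] == b0[k]) + (a1[k] == b1[k]);
        }
        double g = 0.5 * (double)m / L;
        G(i, j) = g;
        G(j, i) = g;
      }
    }
  }
  return G;
}

// Shared-segment coverage (fraction of genome) between two haplotype
// columns. Runs of agreement are delimited at midpoints between the last
// agreeing and first disagreeing locus, extended to chromosome ends when
// terminal; only segments >= min_len (Morgans) count.
static double pair_coverage(const Rbyte* a, const Rbyte* b,
                            const NumericVector& pos,
                            const std::vector<int>& pfirst, const std::vector<int>& plast,
                            const NumericVector& cstart, const NumericVector& clen,
                            double min_len, double tot) {
  double cov = 0.0;
  int nc = clen.size();
  for (int c = 0; c < nc; ++c) {
    int i = pfirst[c];
    while (i < plast[c]) {
      if (a[i] != b[i]) { ++i; continue; }
      int j = i;
      while (j + 1 < plast[c] && a[j + 1] == b[j + 1]) ++j;
      double left = (i == pfirst[c]) ? cstart[c] : 0.5 * (pos[i - 1] + pos[i]);
      double right = (j == plast[c] - 1) ? cstart[c] + clen[c] : 0.5 * (pos[j] + pos[j + 1]);
      if (right - left >= min_len) cov += right - left;
      i = j + 1;
    }
  }
  return cov / tot;
}

static void chr_ranges(const NumericVector& pos, const NumericVector& cstart,
                       const NumericVector& clen,
                       std::vector<int>& pfirst, std::vector<int>& plast) {
  int nc = clen.size(), L = pos.size(), i = 0;
  pfirst.resize(nc); plast.resize(nc);
  for (int c = 0; c < nc; ++c) {
    double e = cstart[c] + clen[c];
    pfirst[c] = i;
    while (i < L && pos[i] < e) ++i;
    plast[c] = i;
  }
}

// Segment list for one haplotype pair (columns ca, cb; 1-based), as
// (chromosome, start, end) with positions within chromosome in Morgans.
// [[Rcpp::export]]
NumericMatrix cpp_pair_segments(RawMatrix hap, int ca, int cb,
                                NumericVector pos, NumericVector cstart,
                                NumericVector clen, double min_len) {
  int nc = clen.size();
  std::vector<int> pfirst, plast;
  chr_ranges(pos, cstart, clen, pfirst, plast);
  const Rbyte* a = &hap(0, ca - 1);
  const Rbyte* b = &hap(0, cb - 1);
  std::vector<double> seg;
  for (int c = 0; c < nc; ++c) {
    int k = pfirst[c];
    while (k < plast[c]) {
      if (a[k] != b[k]) { ++k; continue; }
      int j = k;
      while (j + 1 < plast[c] && a[j + 1] == b[j + 1]) ++j;
      double left = (k == pfirst[c]) ? cstart[c] : 0.5 * (pos[k - 1] + pos[k]);
      double right = (j == plast[c] - 1) ? cstart[c] + clen[c] : 0.5 * (pos[j] + pos[j + 1]);
      if (right - left >= min_len) {
        seg.push_back(c + 1); seg.push_back(left - cstart[c]); seg.push_back(right - cstart[c]);
      }
      k = j + 1;
    }
  }
  int ns = seg.size() / 3;
  NumericMatrix out(ns, 3);
  for (int s = 0; s < ns; ++s) {
    out(s, 0) = seg[3 * s]; out(s, 1) = seg[3 * s + 1]; out(s, 2) = seg[3 * s + 2];
  }
  return out;
}

// ROH-based relationship matrix: off-diagonal (i,j) = 1/4 * sum over the 4
// haplotype pairings of shared-segment genome fraction; diagonal =
// 1 + F_ROH (own two haplotypes).
// [[Rcpp::export]]
NumericMatrix cpp_roh_gmat(RawMatrix hap, IntegerVector ind, NumericVector pos,
                           NumericVector cstart, NumericVector clen, double min_len) {
  int n = ind.size(), nc = clen.size();
  double tot = 0.0;
  for (int c = 0; c < nc; ++c) tot += clen[c];
  std::vector<int> pfirst, plast;
  chr_ranges(pos, cstart, clen, pfirst, plast);
  NumericMatrix G(n, n);
  for (int a = 0; a < n; ++a) {
    const Rbyte* a0 = &hap(0, 2 * (ind[a] - 1));
    const Rbyte* a1 = &hap(0, 2 * (ind[a] - 1) + 1);
    G(a, a) = 1.0 + pair_coverage(a0, a1, pos, pfirst, plast, cstart, clen, min_len, tot);
    for (int b = a + 1; b < n; ++b) {
      const Rbyte* b0 = &hap(0, 2 * (ind[b] - 1));
      const Rbyte* b1 = &hap(0, 2 * (ind[b] - 1) + 1);
      double g = 0.25 * (pair_coverage(a0, b0, pos, pfirst, plast, cstart, clen, min_len, tot) +
                         pair_coverage(a0, b1, pos, pfirst, plast, cstart, clen, min_len, tot) +
                         pair_coverage(a1, b0, pos, pfirst, plast, cstart, clen, min_len, tot) +
                         pair_coverage(a1, b1, pos, pfirst, plast, cstart, clen, min_len, tot));
      G(a, b) = g;
      G(b, a) = g;
    }
  }
  return G;
}
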