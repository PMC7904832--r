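// Gene-dropping through a pedigree with Haldane (no-interference) crossovers.
//
// Founder chromosomes carry unique integer labels; each meiosis draws a
// Poisson number of crossovers at the chromosome's genetic length (Morgans)
// with uniform positions and a random starting phase.  The focal (last)
// individual's realized inbreeding coefficient is the fraction of the total
// genome where its two homologs carry the same founder-copy label.
//
// Uses R's RNG exclusively so set.seed() in R makes runs reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

// A haplotype along one chromosome: segment end positions (Morgans,
// strictly increasing, last == chromosome length) and founder-copy labels.
struct Hap {
  std::vector<double> ends;
  std::vector<int> lab;
};

int hap_label_at(const Hap &h, double x) {
  // first segment whose end exceeds x
  std::size_t i = std::upper_bound(h.ends.begin(), h.ends.end(), x) - h.ends.begin();
  if (i >= h.lab.size()) i = h.lab.size() - 1;
  return h.lab[i];
}

Hap meiosis(const Hap &h1, const Hap &h2, double L) {
  int k = static_cast<int>(R::rpois(L));
  int phase = (unif_rand() < 0.5) ? 0 : 1;
  if (k == 0) return phase == 0 ? h1 : h2;

  std::vector<double> xo(k);
  for (int i = 0; i < k; ++i) xo[i] = unif_rand() * L;
  std::sort(xo.begin(), xo.end());

  // candidate breakpoints: crossovers plus both parents' segment ends
  std::vector<double> br;
  br.reserve(h1.ends.size() + h2.ends.size() + k);
  br.insert(br.end(), h1.ends.begin(), h1.ends.end());
  br.insert(br.end(), h2.ends.begin(), h2.ends.end());
  br.insert(br.end(), xo.begin(), xo.end());
  std::sort(br.begin(), br.end());
  br.erase(std::unique(br.begin(), br.end()), br.end());

  Hap out;
  out.ends.reserve(br.size());
  out.lab.reserve(br.size());
  double prev = 0.0;
  std::size_t nxo = 0;
  for (std::size_t i = 0; i < br.size(); ++i) {
    double mid = 0.5 * (prev + br[i]);
    while (nxo < xo.size() && xo[nxo] < mid) ++nxo;
    int active = (phase + static_cast<int>(nxo)) % 2;
    int lb = active == 0 ? hap_label_at(h1, mid) : hap_label_at(h2, mid);
    if (!out.lab.empty() && out.lab.back() == lb) {
      out.ends.back() = br[i];  // extend the previous segment
    } else {
      out.ends.push_back(br[i]);
      out.lab.push_back(lb);
    }
    prev = br[i];
  }
  return out;
}

double ibd_length(const Hap &a, const Hap &b) {
  double tot = 0.0, prev = 0.0;
  std::size_t ia = 0, ib = 0;
  while (ia < a.ends.size() && ib < b.ends.size()) {
    double end = std::min(a.ends[ia], b.ends[ib]);
    if (a.lab[ia] == b.lab[ib]) tot += end - prev;
    prev = end;
    if (a.ends[ia] <= end) ++ia;
    if (ib < b.ends.size() && b.ends[ib] <= end) ++ib;
  }
  return tot;
}

}  // namespace

//' @name gene_drop_f_cpp
//' @title Realized inbreeding coefficients by gene dropping (C++ core)
//' @param father 1-based father index per individual (NA/0 for founders)
//' @param mother 1-based mother index per individual (NA/0 for founders)
//' @param chrom_len_morgans per-chromosome genetic lengths in Morgans
//' @param n_replicates number of independent gene-drop replicates
//' @return numeric vector of realized F for the last individual
//' @noRd
// [[Rcpp::export]]
NumericVector gene_drop_f_cpp(IntegerVector father, IntegerVector mother,
                              NumericVector chrom_len_morgans,
                              int n_replicates) {
  const int n_ind = father.size();
  const int n_chr = chrom_len_morgans.size();
  double genome = 0.0;
  for (int c = 0; c < n_chr; ++c) genome += chrom_len_morgans[c];

  RNGScope scope;
  NumericVector out(n_replicates);

  for (int rep = 0; rep < n_replicates; ++rep) {
    double ibd = 0.0;
    for (int c = 0; c < n_chr; ++c) {
      double L = chrom_len_morgans[c];
      std::vector<Hap> h1(n_ind), h2(n_ind);
      int next_label = 1;
      for (int i = 0; i < n_ind; ++i) {
        int fa = father[i], mo = mother[i];
        if (fa == NA_INTEGER || fa <= 0) {
          h1[i].ends.assign(1, L);
          h1[i].lab.assign(1, next_label++);
          h2[i].ends.assign(1, L);
          h2[i].lab.assign(1, next_label++);
        } else {
          h1[i] = meiosis(h1[fa - 1], h2[fa - 1], L);
          h2[i] = meiosis(h1[mo - 1], h2[mo - 1], L);
        }
      }
      ibd += ibd_length(h1[n_ind - 1], h2[n_ind - 1]);
    }
    out[rep] = ibd / genome;
  }
  return out;
}
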