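#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

#include "hz_rng.h"

using namespace Rcpp;

// Individual-based secondary-contact hybrid zone simulation.
// Diploid hermaphrodites; haplotypes are 0/1 ancestry vectors over a set of
// tracked positions (marker grid plus underdominant selected loci) on
// n_chrom chromosomes of chrom_length Morgans.  Generation cycle:
// migration -> random mating within deme (distinct parents, no selfing) ->
// offspring viability w = (1-s)^n_het over selected loci -> fill deme to
// capacity.  Gametes form with Poisson(chrom_length) crossovers at uniform
// positions (no interference).

namespace {

struct Tracked {
  // per chromosome: sorted positions and their column index in the haplotype
  std::vector<std::vector<double>> pos;
  std::vector<std::vector<int>> idx;
  int total;
};

// gamete from parent haplotypes (h0, h1 of length T) into child[]
inline void make_gamete(const uint8_t* h0, const uint8_t* h1, uint8_t* child,
                        const Tracked& tr, double chrom_len, HZRng& rng,
                        std::vector<double>& xbuf) {
  int n_chrom = tr.pos.size();
  for (int ch = 0; ch < n_chrom; ++ch) {
    const std::vector<double>& pos = tr.pos[ch];
    const std::vector<int>& idx = tr.idx[ch];
    int nco = rng.pois(chrom_len);
    int h = rng.unif() < 0.5 ? 0 : 1;
    if (nco == 0) {
      const uint8_t* src = h == 0 ? h0 : h1;
      for (size_t k = 0; k < pos.size(); ++k) child[idx[k]] = src[idx[k]];
      continue;
    }
    xbuf.resize(nco);
    for (int c = 0; c < nco; ++c) xbuf[c] = rng.unif() * chrom_len;
    std::sort(xbuf.begin(), xbuf.end());
    size_t c = 0;
    for (size_t k = 0; k < pos.size(); ++k) {
      while (c < xbuf.size() && xbuf[c] <= pos[k]) {
        h = 1 - h;
        ++c;
      }
      const uint8_t* src = h == 0 ? h0 : h1;
      child[idx[k]] = src[idx[k]];
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List hz_sim_zone(int n_demes, int capacity, double mig_parental,
                 double mig_neighbor, int generations, int n_chrom,
                 double chrom_length, NumericVector marker_pos,
                 IntegerVector sel_chrom, NumericVector sel_pos, double s,
                 double seed) {
  if (capacity <= 0 || generations <= 0)
    stop("capacity and generations must be positive");
  HZRng rng(static_cast<uint64_t>(seed));

  int m_per = marker_pos.size();        // markers per chromosome (same grid)
  int n_mark = n_chrom * m_per;         // total marker columns
  int n_sel = sel_pos.size();           // selected-locus columns
  int T = n_mark + n_sel;

  // tracked positions per chromosome, sorted
  Tracked tr;
  tr.pos.resize(n_chrom);
  tr.idx.resize(n_chrom);
  tr.total = T;
  for (int ch = 0; ch < n_chrom; ++ch) {
    std::vector<std::pair<double, int>> items;
    for (int k = 0; k < m_per; ++k)
      items.push_back({marker_pos[k], ch * m_per + k});
    for (int j = 0; j < n_sel; ++j)
      if (sel_chrom[j] == ch) items.push_back({sel_pos[j], n_mark + j});
    std::sort(items.begin(), items.end());
    for (auto& it : items) {
      tr.pos[ch].push_back(it.first);
      tr.idx[ch].push_back(it.second);
    }
  }

  int n_total = n_demes * capacity;
  // two haplotypes per individual, laid out [ind][hap][T]
  std::vector<uint8_t> pop(static_cast<size_t>(n_total) * 2 * T);
  std::vector<uint8_t> newpop(pop.size());
  // pure parental templates hold both haplotypes (2 * T)
  std::vector<uint8_t> pure0(2 * T, 0), pure1(2 * T, 1);

  // secondary contact: left demes pure source 0, right pure source 1; an odd
  // middle deme (or a single deme) starts half and half
  for (int d = 0; d < n_demes; ++d) {
    for (int k = 0; k < capacity; ++k) {
      int ind = d * capacity + k;
      uint8_t val;
      if (n_demes == 1 || 2 * d + 1 == n_demes)
        val = (k < capacity / 2) ? 0 : 1;
      else
        val = (2 * d + 1 < n_demes) ? 0 : 1;
      std::fill(pop.begin() + static_cast<size_t>(ind) * 2 * T,
                pop.begin() + static_cast<size_t>(ind + 1) * 2 * T, val);
    }
  }

  std::vector<double> xbuf;
  std::vector<uint8_t> snap;  // pre-migration snapshot for neighbor draws
  double one_minus_s = 1.0 - s;
  size_t indlen = static_cast<size_t>(2) * T;

  // migration occurs each generation; pure parental populations sit beyond
  // the edge demes (or feed a single admixed deme from both sides), so
  // recent immigrants are part of the census
  auto migrate = [&](std::vector<uint8_t>& cur) {
    snap = cur;
    for (int d = 0; d < n_demes; ++d) {
      for (int k = 0; k < capacity; ++k) {
        uint8_t* slot = &cur[static_cast<size_t>(d * capacity + k) * indlen];
        double u = rng.unif();
        const uint8_t* src = nullptr;
        if (n_demes == 1) {
          // rate applies per parental population
          if (u < mig_parental)
            src = pure0.data();
          else if (u < 2.0 * mig_parental)
            src = pure1.data();
        } else {
          if (u < mig_neighbor) {
            src = (d == 0)
                      ? pure0.data()
                      : &snap[static_cast<size_t>((d - 1) * capacity +
                                                  rng.pick(capacity)) *
                              indlen];
          } else if (u < 2.0 * mig_neighbor) {
            src = (d == n_demes - 1)
                      ? pure1.data()
                      : &snap[static_cast<size_t>((d + 1) * capacity +
                                                  rng.pick(capacity)) *
                              indlen];
          }
        }
        if (src) std::copy(src, src + indlen, slot);
      }
    }
  };

  migrate(pop);
  for (int g = 0; g < generations; ++g) {
    for (int d = 0; d < n_demes; ++d) {
      for (int k = 0; k < capacity; ++k) {
        uint8_t* child = &newpop[static_cast<size_t>(d * capacity + k) * indlen];
        for (int attempt = 0;; ++attempt) {
          // random mating within deme, two distinct parents
          int i1 = rng.pick(capacity);
          int i2 = rng.pick(capacity);
          if (capacity > 1 && i1 == i2) continue;
          const uint8_t* par1 = &pop[static_cast<size_t>(d * capacity + i1) * indlen];
          const uint8_t* par2 = &pop[static_cast<size_t>(d * capacity + i2) * indlen];
          make_gamete(par1, par1 + T, child, tr, chrom_length, rng, xbuf);
          make_gamete(par2, par2 + T, child + T, tr, chrom_length, rng, xbuf);
          if (s <= 0.0 || n_sel == 0) break;
          int nhet = 0;
          for (int j = 0; j < n_sel; ++j)
            if (child[n_mark + j] != child[T + n_mark + j]) ++nhet;
          double w = std::pow(one_minus_s, nhet);
          if (rng.unif() < w || attempt > 10000) break;
        }
      }
    }
    pop.swap(newpop);
    migrate(pop);
    if (g % 16 == 0) Rcpp::checkUserInterrupt();
  }

  // diploid ancestry counts at marker loci
  IntegerMatrix Z(n_total, n_mark);
  IntegerVector deme(n_total);
  for (int ind = 0; ind < n_total; ++ind) {
    const uint8_t* h0 = &pop[static_cast<size_t>(ind) * 2 * T];
    const uint8_t* h1 = h0 + T;
    for (int k = 0; k < n_mark; ++k) Z(ind, k) = h0[k] + h1[k];
    deme[ind] = ind / capacity + 1;
  }
  return List::create(Named("Z") = Z, Named("deme") = deme);
}
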