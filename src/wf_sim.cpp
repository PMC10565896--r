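// Forward Wright-Fisher simulation of one haploid gene under purifying
// selection: multiplicative fitness across sites, infinite-sites mutation
// within the gene (a segregating site carries a single mutation origin;
// sites of lost mutations are recycled, sites of fixed mutations are not),
// full linkage within the gene.  Genotypes are stored as bitsets over the
// currently active mutation slots so a generation is O(N) word copies.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int randint(int n) { return (int)(unif() * n); }
  inline int rpois(double lambda) {
    // inversion; lambda is small (config rejects heavy mutation pressure)
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do {
      ++k;
      p *= unif();
    } while (p > L);
    return k - 1;
  }
};

struct Slot {
  int site;    // 0-based position within the gene
  int alt;     // 0..3 base code of the derived allele
  bool isdel;  // deleterious (nonsynonymous) mutation
  bool live;
};

}  // namespace

// [[Rcpp::export(name = ".wf_sim_gene")]]
List wf_sim_gene(int N, int n_sample, int L, double u, double s_eff,
                 IntegerMatrix alt_code, LogicalMatrix nonsyn,
                 int burn_in, NumericVector rng_seed) {
  if (alt_code.nrow() != L || nonsyn.nrow() != L)
    stop("consequence tables must have one row per site");
  if (n_sample > N) stop("sample size exceeds population size");

  Xoshiro256pp rng;
  // seed from 8 uint32 draws supplied by R's RNG (keeps determinism tied
  // to set.seed while the hot loop uses a fast generator)
  for (int i = 0; i < 4; ++i) {
    uint64_t hi = (uint64_t)(rng_seed[2 * i]);
    uint64_t lo = (uint64_t)(rng_seed[2 * i + 1]);
    rng.s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
  }
  for (int i = 0; i < 16; ++i) rng.next();  // decorrelate

  int W = 1;  // words per individual
  std::vector<uint64_t> genoA((size_t)N * W, 0), genoB((size_t)N * W, 0);
  std::vector<uint8_t> cntA(N, 0), cntB(N, 0);
  std::vector<Slot> slots(64 * W);
  std::vector<int> freeslots;
  for (int i = 64 * W - 1; i >= 0; --i) {
    slots[i].live = false;
    freeslots.push_back(i);
  }
  std::vector<uint8_t> site_used(L, 0);
  std::vector<int> fixed_site, fixed_alt;
  std::vector<int> fixed_isdel;

  // fitness lookup
  std::vector<double> powtab(256);
  for (int k = 0; k < 256; ++k) powtab[k] = std::pow(1.0 - s_eff, k);
  const bool neutral = (s_eff <= 0.0);
  const double lambda = (double)N * u * (double)L;

  std::vector<uint64_t>* cur = &genoA;
  std::vector<uint64_t>* nxt = &genoB;
  std::vector<uint8_t>* ccur = &cntA;
  std::vector<uint8_t>* cnxt = &cntB;

  std::vector<int> counts;  // per-slot carrier counts, reused

  auto compact = [&](void) {
    const int nslots = 64 * W;
    counts.assign(nslots, 0);
    for (int i = 0; i < N; ++i) {
      const uint64_t* g = &(*cur)[(size_t)i * W];
      for (int w = 0; w < W; ++w) {
        uint64_t bits = g[w];
        while (bits) {
          int b = __builtin_ctzll(bits);
          counts[64 * w + b]++;
          bits &= bits - 1;
        }
      }
    }
    for (int sIdx = 0; sIdx < nslots; ++sIdx) {
      if (!slots[sIdx].live) continue;
      const int c = counts[sIdx];
      if (c == 0) {
        // lost: recycle slot and site
        site_used[slots[sIdx].site] = 0;
        slots[sIdx].live = false;
        freeslots.push_back(sIdx);
      } else if (c == N) {
        // fixed: record substitution (1-based), clear the bit everywhere
        fixed_site.push_back(slots[sIdx].site + 1);
        fixed_alt.push_back(slots[sIdx].alt);
        fixed_isdel.push_back(slots[sIdx].isdel ? 1 : 0);
        const int w = sIdx / 64, b = sIdx % 64;
        const uint64_t mask = ~(1ULL << b);
        for (int i = 0; i < N; ++i) (*cur)[(size_t)i * W + w] &= mask;
        if (slots[sIdx].isdel)
          for (int i = 0; i < N; ++i) (*ccur)[i]--;
        slots[sIdx].live = false;  // site stays used (no back mutation)
        freeslots.push_back(sIdx);
      }
    }
  };

  auto grow = [&](void) {
    const int W2 = W + 1;
    std::vector<uint64_t> a((size_t)N * W2, 0), b((size_t)N * W2, 0);
    for (int i = 0; i < N; ++i)
      std::memcpy(&a[(size_t)i * W2], &(*cur)[(size_t)i * W],
                  W * sizeof(uint64_t));
    genoA.swap(a);
    genoB.swap(b);
    cur = &genoA;
    nxt = &genoB;
    slots.resize(64 * W2);
    for (int i = 64 * W2 - 1; i >= 64 * W; --i) {
      slots[i].live = false;
      freeslots.push_back(i);
    }
    W = W2;
  };

  int free_sites_guard = 0;
  for (int gen = 0; gen < burn_in; ++gen) {
    // reproduction with selection (rejection sampling against w_max = 1)
    {
      const uint64_t* C = cur->data();
      uint64_t* X = nxt->data();
      const uint8_t* cc = ccur->data();
      uint8_t* cx = cnxt->data();
      const double* pw = powtab.data();
      if (neutral) {
        if (W == 1) {
          for (int i = 0; i < N; ++i) X[i] = C[rng.randint(N)];
        } else {
          for (int i = 0; i < N; ++i) {
            const int p = rng.randint(N);
            std::memcpy(X + (size_t)i * W, C + (size_t)p * W,
                        W * sizeof(uint64_t));
          }
        }
      } else if (W == 1) {
        for (int i = 0; i < N; ++i) {
          int p;
          for (;;) {
            p = rng.randint(N);
            const uint8_t k = cc[p];
            if (k == 0 || rng.unif() < pw[k]) break;
          }
          X[i] = C[p];
          cx[i] = cc[p];
        }
      } else {
        for (int i = 0; i < N; ++i) {
          int p;
          for (;;) {
            p = rng.randint(N);
            const uint8_t k = cc[p];
            if (k == 0 || rng.unif() < pw[k]) break;
          }
          std::memcpy(X + (size_t)i * W, C + (size_t)p * W,
                      W * sizeof(uint64_t));
          cx[i] = cc[p];
        }
      }
    }
    std::swap(cur, nxt);
    std::swap(ccur, cnxt);

    // mutation
    const int M = rng.rpois(lambda);
    for (int m = 0; m < M; ++m) {
      int p = -1;
      for (int tries = 0; tries < 20 * L; ++tries) {
        const int cand = rng.randint(L);
        if (!site_used[cand]) {
          p = cand;
          break;
        }
      }
      if (p < 0) {
        if (++free_sites_guard > 5) {
          stop("mutation supply exhausted the gene: u*L*N too large for "
               "the infinite-sites approximation");
        }
        continue;  // skip this event; compaction may free sites
      }
      if (freeslots.empty()) {
        compact();
        if (freeslots.empty()) grow();
      }
      const int sIdx = freeslots.back();
      freeslots.pop_back();
      const int j = rng.randint(3);
      slots[sIdx].site = p;
      slots[sIdx].alt = alt_code(p, j);
      slots[sIdx].isdel = !neutral && nonsyn(p, j);
      slots[sIdx].live = true;
      site_used[p] = 1;
      const int ind = rng.randint(N);
      (*cur)[(size_t)ind * W + sIdx / 64] |= (1ULL << (sIdx % 64));
      if (slots[sIdx].isdel) (*ccur)[ind]++;
    }

    if ((gen & 31) == 31) compact();
  }
  compact();

  // sample n haplotypes without replacement (partial Fisher-Yates)
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < n_sample; ++i) {
    const int j = i + rng.randint(N - i);
    std::swap(idx[i], idx[j]);
  }

  // collect active slots
  std::vector<int> act;
  for (int sIdx = 0; sIdx < 64 * W; ++sIdx)
    if (slots[sIdx].live) act.push_back(sIdx);
  const int k = (int)act.size();

  IntegerMatrix gmat(n_sample, k);
  IntegerVector sites(k), alts(k);
  LogicalVector isdel(k);
  IntegerVector popcount(k);
  for (int c = 0; c < k; ++c) {
    const int sIdx = act[c];
    sites[c] = slots[sIdx].site + 1;  // 1-based within gene
    alts[c] = slots[sIdx].alt;
    isdel[c] = slots[sIdx].isdel;
    popcount[c] = counts.empty() ? NA_INTEGER : counts[sIdx];
    const int w = sIdx / 64, b = sIdx % 64;
    for (int i = 0; i < n_sample; ++i)
      gmat(i, c) = (int)(((*cur)[(size_t)idx[i] * W + w] >> b) & 1ULL);
  }

  return List::create(
      _["sites"] = sites, _["alt"] = alts, _["is_del"] = isdel,
      _["genotypes"] = gmat, _["pop_count"] = popcount,
      _["fixed_sites"] = IntegerVector(fixed_site.begin(), fixed_site.end()),
      _["fixed_alt"] = IntegerVector(fixed_alt.begin(), fixed_alt.end()),
      _["fixed_is_del"] =
          IntegerVector(fixed_isdel.begin(), fixed_isdel.end()));
}
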