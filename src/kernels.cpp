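#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstring>
using namespace Rcpp;

// Shared low-level sequence kernels. All coordinates returned to R are
// 1-based inclusive unless stated otherwise. 'N' never matches anything,
// including another 'N'.

static inline bool base_match(char a, char b) {
  return a == b && a != 'N';
}

// ---------------------------------------------------------------------------
// Local alignment (Smith-Waterman, affine gaps).
//
// Gap semantics follow the convention where the first base of a gap costs
// `gap_open` and each subsequent base costs `gap_ext` (both given as
// positive penalties here). A gap of length L therefore costs
// gap_open + (L - 1) * gap_ext.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b,
                     double match = 1.0, double mismatch = -1.0,
                     double gap_open = 1.0, double gap_ext = 0.9) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) stop("empty sequence in local alignment");

  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, R_NegInf), Ecur(m + 1, R_NegInf);
  std::vector<double> Fcur(m + 1, R_NegInf), Fprev(m + 1, R_NegInf);

  // traceback: low 2 bits = H source (0 stop, 1 diag, 2 from E, 3 from F)
  //            bit 2: E extends (vs opens), bit 3: F extends (vs opens)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = R_NegInf; Fcur[0] = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      size_t t = (size_t) i * (m + 1) + j;
      unsigned char code = 0;
      // E: gap in a (move along b)
      double e_open = Hcur[j - 1] - gap_open;
      double e_ext  = Ecur[j - 1] - gap_ext;
      double e = e_open;
      if (e_ext > e_open) { e = e_ext; code |= 4; }
      Ecur[j] = e;
      // F: gap in b (move along a)
      double f_open = Hprev[j] - gap_open;
      double f_ext  = Fprev[j] - gap_ext;
      double f = f_open;
      if (f_ext > f_open) { f = f_ext; code |= 8; }
      Fcur[j] = f;
      // H
      double sub = base_match(a[i - 1], b[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + sub;
      double h = 0.0; unsigned char src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      Hcur[j] = h;
      tb[t] = (unsigned char)(code | src);
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }

  // traceback
  int i = bi, j = bj;
  long matches = 0, columns = 0;
  int a_end = bi, b_end = bj;
  int state = 0; // 0 = in H
  while (i > 0 && j > 0) {
    size_t t = (size_t) i * (m + 1) + j;
    unsigned char code = tb[t];
    if (state == 0) {
      int src = code & 3;
      if (src == 0) break;
      if (src == 1) {
        ++columns;
        if (base_match(a[i - 1], b[j - 1])) ++matches;
        --i; --j;
      } else if (src == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) { // in E: consumed b[j-1]
      ++columns;
      bool ext = (code & 4) != 0;
      --j;
      if (!ext) state = 0;
    } else { // in F: consumed a[i-1]
      ++columns;
      bool ext = (code & 8) != 0;
      --i;
      if (!ext) state = 0;
    }
  }
  int a_start = i + 1, b_start = j + 1;
  if (best <= 0.0) { a_start = a_end = b_start = b_end = 0; columns = 0; matches = 0; }

  return List::create(_["score"] = best,
                      _["matches"] = (double) matches,
                      _["columns"] = (double) columns,
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}

// ---------------------------------------------------------------------------
// Global alignment (Needleman-Wunsch, affine gaps, same gap semantics as the
// local aligner) of two short segments; returns match/column counts for
// identity accounting. Used to resolve the small divergent gaps between
// exact anchor blocks.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b,
                      double match = 1.0, double mismatch = -1.0,
                      double gap_open = 1.0, double gap_ext = 0.9) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) {
    return List::create(_["matches"] = 0.0, _["columns"] = (double) (n + m));
  }
  const double NEG = -1e18;
  std::vector<double> Hprev(m + 1), Hcur(m + 1);
  std::vector<double> Eprev(m + 1), Ecur(m + 1);
  std::vector<double> Fprev(m + 1), Fcur(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  Hprev[0] = 0; Eprev[0] = NEG; Fprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Eprev[j] = -gap_open - gap_ext * (j - 1);
    Hprev[j] = Eprev[j];
    Fprev[j] = NEG;
    tb[j] = 2 | 4;
  }
  for (int i = 1; i <= n; ++i) {
    Fcur[0] = -gap_open - gap_ext * (i - 1);
    Hcur[0] = Fcur[0];
    Ecur[0] = NEG;
    tb[(size_t) i * (m + 1)] = 3 | 8;
    for (int j = 1; j <= m; ++j) {
      size_t t = (size_t) i * (m + 1) + j;
      unsigned char code = 0;
      double e_open = Hcur[j - 1] - gap_open;
      double e_ext = Ecur[j - 1] - gap_ext;
      double e = e_open;
      if (e_ext > e_open) { e = e_ext; code |= 4; }
      Ecur[j] = e;
      double f_open = Hprev[j] - gap_open;
      double f_ext = Fprev[j] - gap_ext;
      double f = f_open;
      if (f_ext > f_open) { f = f_ext; code |= 8; }
      Fcur[j] = f;
      double sub = base_match(a[i - 1], b[j - 1]) ? match : mismatch;
      double h = Hprev[j - 1] + sub; unsigned char src = 1;
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      Hcur[j] = h;
      tb[t] = (unsigned char)(code | src);
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }
  long matches = 0, columns = 0;
  int i = n, j = m, state = 0;
  while (i > 0 || j > 0) {
    size_t t = (size_t) i * (m + 1) + j;
    unsigned char code = tb[t];
    if (state == 0) {
      int src = code & 3;
      if (src == 1) {
        ++columns;
        if (base_match(a[i - 1], b[j - 1])) ++matches;
        --i; --j;
      } else if (src == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ++columns;
      bool ext = (code & 4) != 0;
      --j;
      if (!ext) state = 0;
    } else {
      ++columns;
      bool ext = (code & 8) != 0;
      --i;
      if (!ext) state = 0;
    }
  }
  return List::create(_["matches"] = (double) matches,
                      _["columns"] = (double) columns);
}

// ---------------------------------------------------------------------------
// Maximal exact matches (MEMs) between a query and a target, via k-mer
// seeding and greedy extension with per-diagonal deduplication. Seeds whose
// k-mer occurs more than `max_bucket` times in the query are skipped
// (repetitive, e.g. telomeric, context); extension still recovers MEMs that
// contain at least one low-frequency seed.
// ---------------------------------------------------------------------------

static inline int code_base(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

// [[Rcpp::export]]
DataFrame cpp_mems(std::string q, std::string t, int k = 21, int min_len = 50,
                   int max_bucket = 32, int stride = 1) {
  if (stride < 1) stride = 1;
  if (stride > min_len - k + 1) stride = std::max(1, min_len - k + 1);
  const long nq = (long) q.size(), nt = (long) t.size();
  std::vector<long> qs, ts, ln;
  if (nq >= k && nt >= k) {
    // hash query k-mers (2-bit encoding, skip k-mers with N)
    std::unordered_map<uint64_t, std::vector<long>> idx;
    uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    uint64_t h = 0; int run = 0;
    for (long i = 0; i < nq; ++i) {
      int c = code_base(q[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t) c) & mask;
      if (++run >= k) idx[h].push_back(i - k + 1);
    }
    // per-diagonal farthest extension reached so far (diag = tpos - qpos)
    std::unordered_map<long, long> seen;
    h = 0; run = 0;
    for (long i = 0; i < nt; ++i) {
      int c = code_base(t[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t) c) & mask;
      if (run + 1 < k) { ++run; continue; }
      ++run;
      if ((i % stride) != 0) continue;
      auto it = idx.find(h);
      if (it == idx.end()) continue;
      const std::vector<long>& hits = it->second;
      if ((long) hits.size() > max_bucket) continue;
      long tpos = i - k + 1;
      for (long qpos : hits) {
        long diag = tpos - qpos;
        auto sit = seen.find(diag);
        if (sit != seen.end() && sit->second >= tpos + k) continue; // inside known MEM
        // extend left
        long ql = qpos, tl = tpos;
        while (ql > 0 && tl > 0 && base_match(q[ql - 1], t[tl - 1])) { --ql; --tl; }
        // extend right
        long qr = qpos + k, tr = tpos + k;
        while (qr < nq && tr < nt && base_match(q[qr], t[tr])) { ++qr; ++tr; }
        seen[diag] = tr;
        if (qr - ql >= min_len) {
          qs.push_back(ql + 1); ts.push_back(tl + 1); ln.push_back(qr - ql);
        }
      }
    }
  }
  return DataFrame::create(_["qstart"] = wrap(qs), _["tstart"] = wrap(ts),
                           _["length"] = wrap(ln));
}

// ---------------------------------------------------------------------------
// Brute-force perfect tandem array scanner (reference implementation used to
// validate the vectorized scanner). An array is reported at start a (0-based
// here, 1-based on return) for unit length L iff:
//   * s[a .. a + c*L) is an exact c-fold repeat of the unit, c >= min_copies,
//   * it is left-anchored: a == 0 or s[a-1] != s[a-1+L] (so exactly one
//     report per maximal periodic region),
//   * not extendable by a further full unit on the right,
//   * the unit is primitive (no proper period dividing L).
// ---------------------------------------------------------------------------

static bool unit_primitive(const char* u, int L) {
  for (int d = 1; d <= L / 2; ++d) {
    if (L % d != 0) continue;
    bool per = true;
    for (int i = d; i < L; ++i) if (u[i] != u[i - d]) { per = false; break; }
    if (per) return false;
  }
  return true;
}

// [[Rcpp::export]]
DataFrame cpp_tandem_brute(std::string s, int min_unit = 30, int min_copies = 2) {
  const long n = (long) s.size();
  const char* p = s.data();
  std::vector<long> st, ul, cp;
  std::vector<long> ncum(n + 1, 0);
  for (long i = 0; i < n; ++i) ncum[i + 1] = ncum[i] + (s[i] == 'N');
  for (long L = min_unit; L <= n / 2; ++L) {
    for (long a = 0; a + 2 * L <= n; ++a) {
      if (a > 0 && p[a - 1] == p[a - 1 + L] && p[a - 1] != 'N') continue; // not left-anchored
      if (ncum[a + L] - ncum[a] > 0) continue; // unit contains N
      // count full copies
      long c = 1;
      while (a + (c + 1) * L <= n) {
        bool ok = true;
        const char* u = p + a;
        const char* v = p + a + c * L;
        for (long i = 0; i < L; ++i) {
          if (u[i] != v[i] || u[i] == 'N') { ok = false; break; }
        }
        if (!ok) break;
        ++c;
      }
      if (c < min_copies) continue;
      if (!unit_primitive(s.c_str() + a, (int) L)) continue;
      st.push_back(a + 1); ul.push_back(L); cp.push_back(c);
    }
  }
  return DataFrame::create(_["start"] = wrap(st), _["unit_len"] = wrap(ul),
                           _["copies"] = wrap(cp));
}

// ---------------------------------------------------------------------------
// Vectorizable helper for the production tandem scanner: for a given unit
// length L return run-length information of the self-match vector
// m[i] = (s[i] == s[i+L]), as the start (0-based) and length of each maximal
// TRUE run of length >= L.
// ---------------------------------------------------------------------------

// Production scanner core: for every unit length L, run-length encode the
// self-match vector m[i] = (s[i] == s[i+L]); maximal TRUE runs of length
// >= L are periodic regions. Each region is reported once, anchored at its
// start, with copies = floor((run + L) / L), keeping primitive units only.
// [[Rcpp::export]]
DataFrame cpp_tandem_scan(std::string s, int min_unit = 30,
                          int min_copies = 2) {
  const long n = (long) s.size();
  const char* p = s.data();
  std::vector<long> st, ul, cp;
  for (long L = min_unit; L <= n / 2; ++L) {
    long run = 0;
    const long lim = n - L;
    for (long i = 0; i <= lim; ++i) {
      bool m = (i < lim) && p[i] == p[i + L] && p[i] != 'N';
      if (m) { ++run; continue; }
      if (run >= L) {
        long a = i - run;
        long copies = (run + L) / L;
        bool has_n = false;
        for (long p = a; p < a + L; ++p) if (s[p] == 'N') { has_n = true; break; }
        if (copies >= min_copies && !has_n &&
            unit_primitive(s.c_str() + a, (int) L)) {
          st.push_back(a + 1); ul.push_back(L); cp.push_back(copies);
        }
      }
      run = 0;
    }
  }
  return DataFrame::create(_["start"] = wrap(st), _["unit_len"] = wrap(ul),
                           _["copies"] = wrap(cp));
}

// [[Rcpp::export]]
DataFrame cpp_period_runs(std::string s, int L) {
  const long n = (long) s.size();
  std::vector<long> st, ln;
  long run = 0;
  for (long i = 0; i + L < n; ++i) {
    if (base_match(s[i], s[i + L])) {
      ++run;
    } else {
      if (run >= L) { st.push_back(i - run); ln.push_back(run); }
      run = 0;
    }
  }
  if (run >= L) { st.push_back(n - L - run); ln.push_back(run); }
  return DataFrame::create(_["start"] = wrap(st), _["run_len"] = wrap(ln));
}

// ---------------------------------------------------------------------------
// Circle scan: greedy non-overlapping matching of a circular unit against a
// telomere sequence using a sliding window of the unit length. Exact
// rotation hits are found by hash lookup; near-exact candidates (sharing a
// seed k-mer with the unit) are resolved by local alignment of the doubled
// unit against the window, with normalized score = score / unit length.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_circle_scan(std::string unit, std::string tel,
                          double min_norm = 0.98,
                          double match = 1.0, double mismatch = -1.0,
                          double gap_open = 1.0, double gap_ext = 0.9,
                          int seed_k = 28) {
  const long u = (long) unit.size();
  const long n = (long) tel.size();
  if (seed_k > (int) u / 2) seed_k = std::max(8L, u / 2);
  std::vector<long> starts, phases;
  std::vector<double> scores;
  if (u == 0) stop("empty circle unit");
  if (n < u) {
    return DataFrame::create(_["start"] = wrap(starts), _["phase"] = wrap(phases),
                             _["score"] = wrap(scores));
  }
  std::string doubled = unit + unit;
  // rotation lookup
  std::unordered_map<std::string, long> rot;
  for (long r = 0; r < u; ++r) {
    std::string s = doubled.substr(r, u);
    if (rot.find(s) == rot.end()) rot[s] = r;
  }
  // seed k-mers of the doubled unit
  std::unordered_set<uint64_t> seeds;
  uint64_t mask = (1ULL << (2 * seed_k)) - 1;
  {
    uint64_t h = 0; int run = 0;
    for (long i = 0; i < (long) doubled.size(); ++i) {
      int c = code_base(doubled[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t) c) & mask;
      if (++run >= seed_k) seeds.insert(h);
    }
  }
  // per-position: does tel[p .. p+seed_k) hit a unit seed?
  std::vector<char> seeded(n, 0);
  {
    uint64_t h = 0; int run = 0;
    for (long i = 0; i < n; ++i) {
      int c = code_base(tel[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t) c) & mask;
      if (++run >= seed_k && seeds.count(h)) seeded[i - seed_k + 1] = 1;
    }
  }
  std::vector<long> seed_cum(n + 1, 0);
  for (long i = 0; i < n; ++i) seed_cum[i + 1] = seed_cum[i] + seeded[i];

  long p = 0;
  long dp_cooldown_until = -1; // after a failed alignment, skip nearby ones
  while (p + u <= n) {
    std::string w = tel.substr(p, u);
    auto it = rot.find(w);
    if (it != rot.end()) {
      starts.push_back(p + 1); phases.push_back(it->second);
      scores.push_back(1.0);
      p += u;
      continue;
    }
    // near-exact matches share most unit k-mers; telomeric background
    // shares only scattered ones, so require dense seed coverage before
    // paying for an alignment, and cool down after a failed alignment
    // (windows straddling an array edge fail for a whole unit length)
    long hi = std::min(n - seed_k + 1, p + u - seed_k + 1);
    long need = (long) (0.5 * (double) (u - seed_k + 1));
    bool dense = p >= dp_cooldown_until && hi > p &&
      (seed_cum[hi] - seed_cum[p]) >= std::max(1L, need);
    if (dense) {
      List al = cpp_local_align(doubled, w, match, mismatch, gap_open, gap_ext);
      double norm = as<double>(al["score"]) / (double) u;
      if (norm > min_norm) {
        long a_start = as<int>(al["a_start"]);   // on doubled unit, 1-based
        long b_start = as<int>(al["b_start"]);   // on window, 1-based
        long phase = ((a_start - 1) - (b_start - 1)) % u;
        if (phase < 0) phase += u;
        starts.push_back(p + 1); phases.push_back(phase);
        scores.push_back(norm);
        p += u;
        continue;
      }
      dp_cooldown_until = p + std::max(8L, u / 8);
    }
    ++p;
  }
  return DataFrame::create(_["start"] = wrap(starts), _["phase"] = wrap(phases),
                           _["score"] = wrap(scores));
}

// ---------------------------------------------------------------------------
// Longest common prefix of two strings ('N' breaks the match).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int cpp_common_prefix(std::string a, std::string b) {
  long n = std::min(a.size(), b.size());
  long i = 0;
  while (i < n && base_match(a[i], b[i])) ++i;
  return (int) i;
}
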