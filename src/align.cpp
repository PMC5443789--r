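// Semi-global (glocal) affine-gap alignment of a read against an amplicon:
// global in the read, free end-gaps on the amplicon.  Gap of length L costs
// gap_open + L * gap_extend (both negative).  Deterministic tie-breaking:
// within a cell, diagonal > deletion > insertion; at the final cell, the
// smallest ref_end wins, diagonal state before insertion state.
//
// A fast ungapped path handles reads matching the amplicon with <= 1
// mismatch; such placements are provably optimal under any scheme with
// match > mismatch >= 2*match + gap_open + gap_extend, and share the DP's
// leftmost tie-break, so the shortcut is exact, not a heuristic.
//
// An independent reference scorer (top-down memoized recursion over
// suffixes) is compiled alongside for validation; it shares no code with
// the production DP.

#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const double NEG = -1e18;

struct Scheme {
  double match, mismatch, go, ge;
};

static inline char complement_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = complement_base(r[i]);
  return r;
}

// bases match only if equal and not N (N never matches anything)
static inline bool base_match(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

struct AlnRes {
  bool found = false;
  double score = NEG;
  int ref_start = 0, ref_end = 0;
  bool rc = false;
  // run-length encoded ops: kind in {'M','X','D','I'}
  std::vector<char> kind;
  std::vector<int> len;
  std::vector<std::string> ins;
};

// ---- fast ungapped path -------------------------------------------------

// best ungapped placement with <= 1 mismatch; returns true if found
static bool ungapped_scan(const std::string& x, const std::string& y,
                          int& best_off, int& best_mm) {
  int m = (int)x.size(), n = (int)y.size();
  best_mm = 2; best_off = -1;
  if (m > n || m == 0) return false;
  for (int s = 0; s + m <= n; ++s) {
    int mm = 0;
    for (int k = 0; k < m; ++k) {
      if (!base_match(x[k], y[s + k])) { if (++mm >= 2) break; }
    }
    if (mm < best_mm) {
      best_mm = mm; best_off = s;
      if (mm == 0) break;  // cannot be beaten; leftmost already
    }
  }
  return best_mm <= 1;
}

static AlnRes ungapped_result(const std::string& x, const std::string& y,
                              int off, const Scheme& sc, bool rc) {
  AlnRes r;
  r.found = true; r.rc = rc;
  r.ref_start = off; r.ref_end = off + (int)x.size();
  r.score = 0;
  char cur = 0; int run = 0;
  for (size_t k = 0; k < x.size(); ++k) {
    bool mt = base_match(x[k], y[off + k]);
    r.score += mt ? sc.match : sc.mismatch;
    char kd = mt ? 'M' : 'X';
    if (kd == cur) { ++run; }
    else {
      if (run > 0) { r.kind.push_back(cur); r.len.push_back(run); r.ins.push_back(""); }
      cur = kd; run = 1;
    }
  }
  if (run > 0) { r.kind.push_back(cur); r.len.push_back(run); r.ins.push_back(""); }
  return r;
}

// ---- full Gotoh DP with traceback --------------------------------------

// states: 0 = M (diagonal), 1 = D (ref base deleted), 2 = I (read base inserted)
static AlnRes gotoh_align(const std::string& x, const std::string& y,
                          const Scheme& sc, bool rc) {
  int m = (int)x.size(), n = (int)y.size();
  size_t ncell = (size_t)(m + 1) * (n + 1);
  static thread_local std::vector<double> Mbuf, Dbuf, Ibuf;
  static thread_local std::vector<unsigned char> tbMbuf, tbDbuf, tbIbuf;
  if (Mbuf.size() < ncell) {
    Mbuf.resize(ncell); Dbuf.resize(ncell); Ibuf.resize(ncell);
    tbMbuf.resize(ncell); tbDbuf.resize(ncell); tbIbuf.resize(ncell);
  }
  // raw pointers: element access through the thread-local vectors would
  // pay a TLS lookup per cell
  double *M = Mbuf.data(), *D = Dbuf.data(), *I = Ibuf.data();
  unsigned char *tbM = tbMbuf.data(), *tbD = tbDbuf.data(),
                *tbI = tbIbuf.data();
  const int W = n + 1;
#define AT(i, j) ((size_t)(i) * W + (j))

  for (int j = 0; j <= n; ++j) { M[AT(0, j)] = 0.0; D[AT(0, j)] = NEG; I[AT(0, j)] = NEG; }
  for (int i = 1; i <= m; ++i) {
    M[AT(i, 0)] = NEG; D[AT(i, 0)] = NEG;
    I[AT(i, 0)] = sc.go + i * sc.ge;
    tbI[AT(i, 0)] = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    const char xi = x[i - 1];
    for (int j = 1; j <= n; ++j) {
      size_t d = AT(i - 1, j - 1), u = AT(i - 1, j), l = AT(i, j - 1), c = AT(i, j);
      // M: tie preference M > D > I
      double bm = M[d]; unsigned char tm = 0;
      if (D[d] > bm) { bm = D[d]; tm = 1; }
      if (I[d] > bm) { bm = I[d]; tm = 2; }
      M[c] = (base_match(xi, y[j - 1]) ? sc.match : sc.mismatch) + bm;
      tbM[c] = tm;
      // D: consumes y[j-1]
      double v0 = M[l] + sc.go + sc.ge, v1 = D[l] + sc.ge, v2 = I[l] + sc.go + sc.ge;
      double bd = v0; unsigned char td = 0;
      if (v1 > bd) { bd = v1; td = 1; }
      if (v2 > bd) { bd = v2; td = 2; }
      D[c] = bd; tbD[c] = td;
      // I: consumes x[i-1]
      double w0 = M[u] + sc.go + sc.ge, w1 = D[u] + sc.go + sc.ge, w2 = I[u] + sc.ge;
      double bi = w0; unsigned char ti = 0;
      if (w1 > bi) { bi = w1; ti = 1; }
      if (w2 > bi) { bi = w2; ti = 2; }
      I[c] = bi; tbI[c] = ti;
    }
  }

  // final: best over j of M[m][j], I[m][j]; smallest j wins ties, M before I
  double best = NEG; int bj = 0; unsigned char bs = 0;
  for (int j = 0; j <= n; ++j) {
    if (M[AT(m, j)] > best) { best = M[AT(m, j)]; bj = j; bs = 0; }
    if (I[AT(m, j)] > best) { best = I[AT(m, j)]; bj = j; bs = 2; }
  }

  AlnRes r;
  r.found = true; r.rc = rc; r.score = best; r.ref_end = bj;

  // traceback
  std::vector<char> rk; std::vector<std::string> rins;
  int i = m, j = bj; unsigned char s = bs;
  while (i > 0) {
    if (s == 0) {
      rk.push_back(base_match(x[i - 1], y[j - 1]) ? 'M' : 'X');
      rins.push_back("");
      s = tbM[AT(i, j)]; --i; --j;
    } else if (s == 1) {
      rk.push_back('D'); rins.push_back("");
      s = tbD[AT(i, j)]; --j;
    } else {
      rk.push_back('I'); rins.push_back(std::string(1, x[i - 1]));
      s = tbI[AT(i, j)]; --i;
    }
  }
  r.ref_start = j;
  // reverse + run-length encode
  std::reverse(rk.begin(), rk.end());
  std::reverse(rins.begin(), rins.end());
  char cur = 0; int run = 0; std::string insacc;
  for (size_t k = 0; k < rk.size(); ++k) {
    if (rk[k] == cur) { ++run; insacc += rins[k]; }
    else {
      if (run > 0) { r.kind.push_back(cur); r.len.push_back(run); r.ins.push_back(insacc); }
      cur = rk[k]; run = 1; insacc = rins[k];
    }
  }
  if (run > 0) { r.kind.push_back(cur); r.len.push_back(run); r.ins.push_back(insacc); }
#undef AT
  return r;
}

// ---- k-mer strand / amplicon vote ---------------------------------------

static const int KMER = 12;

static inline bool kmer_code(const std::string& s, int pos, uint32_t& code) {
  code = 0;
  for (int k = 0; k < KMER; ++k) {
    uint32_t b;
    switch (s[pos + k]) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: return false;
    }
    code = (code << 2) | b;
  }
  return true;
}

static std::vector<uint32_t> kmer_index(const std::string& s) {
  std::vector<uint32_t> v;
  if ((int)s.size() >= KMER) {
    v.reserve(s.size() - KMER + 1);
    uint32_t c;
    for (int p = 0; p + KMER <= (int)s.size(); ++p)
      if (kmer_code(s, p, c)) v.push_back(c);
    std::sort(v.begin(), v.end());
  }
  return v;
}

static int kmer_hits(const std::string& read, const std::vector<uint32_t>& idx) {
  if (idx.empty() || (int)read.size() < KMER) return 0;
  int hits = 0; uint32_t c;
  for (int p = 0; p + KMER <= (int)read.size(); ++p)
    if (kmer_code(read, p, c) &&
        std::binary_search(idx.begin(), idx.end(), c)) ++hits;
  return hits;
}

// ---- driver -------------------------------------------------------------

// align one read; both_strands tries the reverse complement too (better
// score wins, forward on ties).  vote=true replaces the both-strand DP by a
// k-mer strand vote when the ungapped fast path fails and the vote is
// decisive (one strand shares k-mers, the other none); indecisive votes fall
// back to the exact both-strand DP.
static AlnRes align_read(const std::string& x, const std::string& y,
                         const Scheme& sc, bool both_strands, bool vote,
                         const std::vector<uint32_t>* yidx) {
  std::string xrc = both_strands ? revcomp(x) : std::string();

  int off_f, mm_f = 2, off_r, mm_r = 2;
  bool fast_f = ungapped_scan(x, y, off_f, mm_f);
  bool fast_r = both_strands && ungapped_scan(xrc, y, off_r, mm_r);
  if (fast_f || fast_r) {
    if (fast_f && (!fast_r || mm_f <= mm_r))
      return ungapped_result(x, y, off_f, sc, false);
    return ungapped_result(xrc, y, off_r, sc, true);
  }

  bool do_f = true, do_r = both_strands;
  if (both_strands && vote && yidx != nullptr) {
    int hf = kmer_hits(x, *yidx), hr = kmer_hits(xrc, *yidx);
    if (hf > 0 && hr == 0) do_r = false;
    else if (hr > 0 && hf == 0) do_f = false;
  }
  AlnRes best;
  if (do_f) best = gotoh_align(x, y, sc, false);
  if (do_r) {
    AlnRes rr = gotoh_align(xrc, y, sc, true);
    if (!best.found || rr.score > best.score) best = rr;
  }
  return best;
}

static List res_to_list(const AlnRes& r) {
  int k = (int)r.kind.size();
  CharacterVector kind(k); IntegerVector len(k); CharacterVector ins(k);
  for (int i = 0; i < k; ++i) {
    kind[i] = std::string(1, r.kind[i]);
    len[i] = r.len[i];
    ins[i] = r.ins[i];
  }
  return List::create(
    _["score"] = r.score,
    _["ref_start"] = r.ref_start,
    _["ref_end"] = r.ref_end,
    _["strand"] = r.rc ? "-" : "+",
    _["op_kind"] = kind,
    _["op_len"] = len,
    _["op_ins"] = ins);
}

// [[Rcpp::export]]
List cpp_align_one(std::string read, std::string ref,
                   double match, double mismatch,
                   double gap_open, double gap_extend,
                   bool both_strands, bool vote) {
  Scheme sc{match, mismatch, gap_open, gap_extend};
  std::vector<uint32_t> idx;
  if (vote) idx = kmer_index(ref);
  AlnRes r = align_read(read, ref, sc, both_strands,
                        vote, vote ? &idx : nullptr);
  return res_to_list(r);
}

// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, std::string ref,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     bool both_strands, bool vote) {
  Scheme sc{match, mismatch, gap_open, gap_extend};
  std::vector<uint32_t> idx = kmer_index(ref);
  int n = reads.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::string x = as<std::string>(reads[i]);
    out[i] = res_to_list(align_read(x, ref, sc, both_strands, vote, &idx));
  }
  return out;
}

// assign each read to the best amplicon: k-mer vote first (forward + rc
// hits per amplicon); the top amplicon is aligned, and when the vote does
// not single one out, every tied top amplicon is aligned and the best score
// wins -- equal best scores across amplicons drop the read (ref_index 0).
// [[Rcpp::export]]
List cpp_align_batch_multi(CharacterVector reads, CharacterVector refs,
                           double match, double mismatch,
                           double gap_open, double gap_extend,
                           bool both_strands, bool vote) {
  Scheme sc{match, mismatch, gap_open, gap_extend};
  int nr = refs.size();
  std::vector<std::string> refstr(nr);
  std::vector<std::vector<uint32_t>> idx(nr);
  for (int a = 0; a < nr; ++a) {
    refstr[a] = as<std::string>(refs[a]);
    idx[a] = kmer_index(refstr[a]);
  }
  int n = reads.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::string x = as<std::string>(reads[i]);
    std::string xrc = both_strands ? revcomp(x) : std::string();
    std::vector<int> hits(nr);
    int top = -1;
    for (int a = 0; a < nr; ++a) {
      hits[a] = kmer_hits(x, idx[a]);
      if (both_strands) hits[a] += kmer_hits(xrc, idx[a]);
      if (top < 0 || hits[a] > hits[top]) top = a;
    }
    std::vector<int> cand;
    for (int a = 0; a < nr; ++a)
      if (hits[a] == hits[top]) cand.push_back(a);
    if (vote && cand.size() > 1 && hits[top] > 0) {
      // decisive only if a single amplicon holds the maximum
    }
    AlnRes best; int best_a = -1; bool tie = false;
    if (vote && cand.size() == 1) {
      best = align_read(x, refstr[cand[0]], sc, both_strands, vote, &idx[cand[0]]);
      best_a = cand[0];
    } else {
      std::vector<int>& cs = cand;
      if (!vote) { cs.clear(); for (int a = 0; a < nr; ++a) cs.push_back(a); }
      for (size_t c = 0; c < cs.size(); ++c) {
        AlnRes r = align_read(x, refstr[cs[c]], sc, both_strands, vote, &idx[cs[c]]);
        if (best_a < 0 || r.score > best.score) { best = r; best_a = cs[c]; tie = false; }
        else if (r.score == best.score) tie = true;
      }
    }
    List rl = res_to_list(best);
    rl["ref_index"] = tie ? 0 : (best_a + 1);  // 1-based; 0 = dropped tie
    out[i] = rl;
  }
  return out;
}

// ---- independent reference scorer ---------------------------------------

// top-down memoized recursion over suffixes; prev: 0=M/start, 1=D, 2=I.
// free amplicon suffix: value 0 once the whole read is consumed; free
// amplicon prefix: maximize over all start offsets.
struct OracleCtx {
  const std::string* x; const std::string* y;
  Scheme sc;
  std::vector<double> memo;   // (m+1)*(n+1)*3
  std::vector<unsigned char> seen;
  int W;
};

static double oracle_f(OracleCtx& c, int i, int j, int prev) {
  int m = (int)c.x->size(), n = (int)c.y->size();
  if (i == m) return 0.0;  // remaining amplicon suffix is free
  size_t key = ((size_t)i * c.W + j) * 3 + prev;
  if (c.seen[key]) return c.memo[key];
  double best = NEG;
  if (j < n) {
    double diag = (base_match((*c.x)[i], (*c.y)[j]) ? c.sc.match : c.sc.mismatch)
      + oracle_f(c, i + 1, j + 1, 0);
    if (diag > best) best = diag;
    double del = (prev == 1 ? c.sc.ge : c.sc.go + c.sc.ge) + oracle_f(c, i, j + 1, 1);
    if (del > best) best = del;
  }
  double ins = (prev == 2 ? c.sc.ge : c.sc.go + c.sc.ge) + oracle_f(c, i + 1, j, 2);
  if (ins > best) best = ins;
  c.seen[key] = 1; c.memo[key] = best;
  return best;
}

// [[Rcpp::export]]
double cpp_reference_score(std::string read, std::string ref,
                           double match, double mismatch,
                           double gap_open, double gap_extend) {
  OracleCtx c;
  c.x = &read; c.y = &ref;
  c.sc = Scheme{match, mismatch, gap_open, gap_extend};
  int m = (int)read.size(), n = (int)ref.size();
  c.W = n + 1;
  c.memo.assign((size_t)(m + 1) * (n + 1) * 3, 0.0);
  c.seen.assign((size_t)(m + 1) * (n + 1) * 3, 0);
  double best = NEG;
  for (int j0 = 0; j0 <= n; ++j0) {
    double v = oracle_f(c, 0, j0, 0);
    if (v > best) best = v;
  }
  return best;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }
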