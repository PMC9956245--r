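// Affine-gap dynamic-programming alignment core.
//
// Conventions shared with the R layer:
//  - a gap of length L costs open + extend * L (BLAST-style "open 11 / extend 1"
//    means a length-1 gap costs 12), applied identically in local and global modes;
//  - coordinates returned to R are 1-based inclusive;
//  - identity/similarity fractions are computed over gap-free aligned columns only.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double NEG_INF = -1e18;

// Encode a sequence over an alphabet; returns -1 for unknown letters.
static std::vector<int> encode(const std::string& s,
                               const std::unordered_map<char, int>& code) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    auto it = code.find(s[i]);
    v[i] = (it == code.end()) ? -1 : it->second;
  }
  return v;
}

static std::unordered_map<char, int> make_code(const std::string& alphabet) {
  std::unordered_map<char, int> code;
  for (size_t i = 0; i < alphabet.size(); ++i) code[alphabet[i]] = (int)i;
  return code;
}

struct Hsp {
  double score;
  int qstart, qend, sstart, send;  // 1-based inclusive
  int aligned_cols;                // gap-free columns
  int identities;
  int positives;
  int mismatches;
  int gap_opens;
  int gap_residues;
  int length;                      // columns including gaps
};

// One round of local affine Smith-Waterman with traceback; masked positions
// (per-sequence) score NEG_INF against everything so successive rounds yield
// non-overlapping suboptimal HSPs.
static bool sw_round(const std::vector<int>& a, const std::vector<int>& b,
                     const IntegerMatrix& S,
                     const std::vector<char>& mask_a, const std::vector<char>& mask_b,
                     double gap_open, double gap_extend, Hsp& out) {
  const int n = (int)a.size(), m = (int)b.size();
  const double gof = gap_open + gap_extend;  // cost of opening (first gapped residue)

  // M: match/mismatch ending; X: gap in b (consumes a); Y: gap in a (consumes b)
  std::vector<double> M((n + 1) * (m + 1), 0.0), X((n + 1) * (m + 1), NEG_INF),
      Y((n + 1) * (m + 1), NEG_INF);
  // traceback: which matrix each cell came from (0 none,1 M,2 X,3 Y)
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0), tbX((n + 1) * (m + 1), 0),
      tbY((n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ai = a[i - 1], bj_ = b[j - 1];
      double sub = (mask_a[i - 1] || mask_b[j - 1]) ? NEG_INF
                                                    : (double)S(ai, bj_);
      // X: gap in b
      double xo = M[idx(i - 1, j)] - gof, xe = X[idx(i - 1, j)] - gap_extend;
      if (xo >= xe) { X[idx(i, j)] = xo; tbX[idx(i, j)] = 1; }
      else          { X[idx(i, j)] = xe; tbX[idx(i, j)] = 2; }
      // Y: gap in a
      double yo = M[idx(i, j - 1)] - gof, ye = Y[idx(i, j - 1)] - gap_extend;
      if (yo >= ye) { Y[idx(i, j)] = yo; tbY[idx(i, j)] = 1; }
      else          { Y[idx(i, j)] = ye; tbY[idx(i, j)] = 3; }
      // M
      double mm = M[idx(i - 1, j - 1)], xx = X[idx(i - 1, j - 1)],
             yy = Y[idx(i - 1, j - 1)];
      double prev = mm; unsigned char from = 1;
      if (xx > prev) { prev = xx; from = 2; }
      if (yy > prev) { prev = yy; from = 3; }
      if (from == 1 && mm <= 0.0) from = 0;  // fresh local start
      double mv = prev + sub;
      if (mv > 0.0) { M[idx(i, j)] = mv; tbM[idx(i, j)] = from; }
      else          { M[idx(i, j)] = 0.0; tbM[idx(i, j)] = 0; }
      if (M[idx(i, j)] > best) { best = M[idx(i, j)]; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) return false;

  // traceback from (bi,bj) in M until score 0
  Hsp h; h.score = best; h.qend = bi; h.send = bj;
  h.aligned_cols = 0; h.identities = 0; h.positives = 0; h.mismatches = 0;
  h.gap_opens = 0; h.gap_residues = 0; h.length = 0;
  int i = bi, j = bj, state = 1;
  int last_gap_state = 0;
  while (i > 0 && j > 0) {
    if (state == 1) {
      unsigned char from = tbM[idx(i, j)];
      // consume the aligned pair (i,j)
      h.aligned_cols++; h.length++;
      if (a[i - 1] == b[j - 1]) h.identities++; else h.mismatches++;
      if (S(a[i - 1], b[j - 1]) > 0) h.positives++;
      i--; j--;
      last_gap_state = 0;
      if (from == 0) break;            // local start
      state = from;
    } else if (state == 2) {           // gap in b, consume a[i]
      unsigned char from = tbX[idx(i, j)];
      h.length++; h.gap_residues++;
      if (last_gap_state != 2) h.gap_opens++;
      last_gap_state = 2;
      i--;
      state = (from == 1) ? 1 : 2;
    } else {                           // gap in a, consume b[j]
      unsigned char from = tbY[idx(i, j)];
      h.length++; h.gap_residues++;
      if (last_gap_state != 3) h.gap_opens++;
      last_gap_state = 3;
      j--;
      state = (from == 1) ? 1 : 3;
    }
  }
  h.qstart = i + 1; h.sstart = j + 1;
  out = h;
  return true;
}

// Collect HSPs for one pair: optimal plus greedily masked suboptimals, keeping
// those with E-value <= evalue_max; stops when the best remaining alignment is
// no longer significant.
static std::vector<Hsp> pair_hsps(const std::vector<int>& a, const std::vector<int>& b,
                                  const IntegerMatrix& S,
                                  double gap_open, double gap_extend,
                                  double lambda, double K, double evalue_max,
                                  int max_hsps) {
  std::vector<Hsp> hits;
  std::vector<char> mask_a(a.size(), 0), mask_b(b.size(), 0);
  const double mn = (double)a.size() * (double)b.size();
  for (int r = 0; r < max_hsps; ++r) {
    Hsp h;
    if (!sw_round(a, b, S, mask_a, mask_b, gap_open, gap_extend, h)) break;
    double ev = K * mn * std::exp(-lambda * h.score);
    if (ev > evalue_max) break;
    hits.push_back(h);
    for (int i = h.qstart - 1; i < h.qend; ++i) mask_a[i] = 1;
    for (int j = h.sstart - 1; j < h.send; ++j) mask_b[j] = 1;
  }
  return hits;
}

static DataFrame hsps_to_df(const std::vector<Hsp>& hits,
                            const std::vector<int>& qi, const std::vector<int>& si,
                            const std::vector<double>& ev) {
  const int n = (int)hits.size();
  IntegerVector qidx(n), sidx(n), qs(n), qe(n), ss(n), se(n), ac(n), len(n),
      mis(n), go(n), gr(n);
  NumericVector score(n), evalue(n), idf(n), simf(n);
  for (int k = 0; k < n; ++k) {
    const Hsp& h = hits[k];
    qidx[k] = qi[k]; sidx[k] = si[k];
    score[k] = h.score; evalue[k] = ev[k];
    qs[k] = h.qstart; qe[k] = h.qend; ss[k] = h.sstart; se[k] = h.send;
    ac[k] = h.aligned_cols; len[k] = h.length; mis[k] = h.mismatches;
    go[k] = h.gap_opens; gr[k] = h.gap_residues;
    idf[k] = h.aligned_cols > 0 ? (double)h.identities / h.aligned_cols : 0.0;
    simf[k] = h.aligned_cols > 0 ? (double)h.positives / h.aligned_cols : 0.0;
  }
  return DataFrame::create(
      _["query_idx"] = qidx, _["subject_idx"] = sidx, _["score"] = score,
      _["evalue"] = evalue, _["q_start"] = qs, _["q_end"] = qe,
      _["s_start"] = ss, _["s_end"] = se, _["aligned_cols"] = ac,
      _["align_length"] = len, _["mismatches"] = mis, _["gap_opens"] = go,
      _["gap_residues"] = gr, _["identity_fraction"] = idf,
      _["similarity_fraction"] = simf);
}

// [[Rcpp::export]]
DataFrame cpp_local_align(std::string a, std::string b, IntegerMatrix scores,
                          std::string alphabet, double gap_open, double gap_extend,
                          double lambda, double K, double evalue_max, int max_hsps) {
  auto code = make_code(alphabet);
  std::vector<int> ea = encode(a, code), eb = encode(b, code);
  std::vector<Hsp> hits =
      pair_hsps(ea, eb, scores, gap_open, gap_extend, lambda, K, evalue_max, max_hsps);
  std::vector<int> qi(hits.size(), 1), si(hits.size(), 2);
  std::vector<double> ev(hits.size());
  const double mn = (double)ea.size() * (double)eb.size();
  for (size_t k = 0; k < hits.size(); ++k)
    ev[k] = K * mn * std::exp(-lambda * hits[k].score);
  return hsps_to_df(hits, qi, si, ev);
}

// Sorted unique k-mer codes of an encoded sequence (letters with code >= base
// are skipped). Used by the all-vs-all shared-word prefilter.
static std::vector<long long> kmer_codes(const std::vector<int>& s, int k, int base) {
  std::vector<long long> out;
  if ((int)s.size() < k) return out;
  for (size_t i = 0; i + k <= s.size(); ++i) {
    long long c = 0; bool ok = true;
    for (int j = 0; j < k; ++j) {
      if (s[i + j] < 0 || s[i + j] >= base) { ok = false; break; }
      c = c * base + s[i + j];
    }
    if (ok) out.push_back(c);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

static bool share_kmer(const std::vector<long long>& x, const std::vector<long long>& y) {
  size_t i = 0, j = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] == y[j]) return true;
    if (x[i] < y[j]) ++i; else ++j;
  }
  return false;
}

// All-vs-all HSP search over a panel. Pairs (i <= j) are examined once;
// self-pairs included when include_self. With prefilter, pairs sharing no
// k-mer word are skipped before dynamic programming.
// [[Rcpp::export]]
DataFrame cpp_all_vs_all(CharacterVector seqs, IntegerMatrix scores,
                         std::string alphabet, double gap_open, double gap_extend,
                         double lambda, double K, double evalue_max, int max_hsps,
                         bool include_self, bool prefilter, int kmer_len) {
  const int n = seqs.size();
  const int base = 20;  // prefilter words over the standard residues only
  std::vector<std::vector<int>> enc(n);
  std::vector<std::vector<long long>> words(n);
  auto code = make_code(alphabet);
  for (int i = 0; i < n; ++i) {
    enc[i] = encode(std::string(seqs[i]), code);
    if (prefilter) words[i] = kmer_codes(enc[i], kmer_len, base);
  }
  std::vector<Hsp> hits;
  std::vector<int> qi, si;
  std::vector<double> ev;
  for (int i = 0; i < n; ++i) {
    Rcpp::checkUserInterrupt();
    for (int j = i; j < n; ++j) {
      if (i == j && !include_self) continue;
      if (prefilter && i != j && !share_kmer(words[i], words[j])) continue;
      std::vector<Hsp> h = pair_hsps(enc[i], enc[j], scores, gap_open, gap_extend,
                                     lambda, K, evalue_max, max_hsps);
      const double mn = (double)enc[i].size() * (double)enc[j].size();
      for (const Hsp& x : h) {
        hits.push_back(x); qi.push_back(i + 1); si.push_back(j + 1);
        ev.push_back(K * mn * std::exp(-lambda * x.score));
      }
    }
  }
  return hsps_to_df(hits, qi, si, ev);
}

// Global affine Needleman-Wunsch; returns identities, gap-free aligned columns
// and total alignment length (columns including gaps).
// [[Rcpp::export]]
NumericVector cpp_global_identity(std::string a, std::string b, IntegerMatrix scores,
                                  std::string alphabet, double gap_open,
                                  double gap_extend) {
  auto code = make_code(alphabet);
  std::vector<int> ea = encode(a, code), eb = encode(b, code);
  const int n = (int)ea.size(), m = (int)eb.size();
  const double gof = gap_open + gap_extend;
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  std::vector<double> M((n + 1) * (m + 1), NEG_INF), X((n + 1) * (m + 1), NEG_INF),
      Y((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0), tbX((n + 1) * (m + 1), 0),
      tbY((n + 1) * (m + 1), 0);
  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = -(gap_open + gap_extend * i);
    tbX[idx(i, 0)] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = -(gap_open + gap_extend * j);
    tbY[idx(0, j)] = (j == 1) ? 1 : 3;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double xo = M[idx(i - 1, j)] - gof, xe = X[idx(i - 1, j)] - gap_extend;
      if (xo >= xe) { X[idx(i, j)] = xo; tbX[idx(i, j)] = 1; }
      else          { X[idx(i, j)] = xe; tbX[idx(i, j)] = 2; }
      double yo = M[idx(i, j - 1)] - gof, ye = Y[idx(i, j - 1)] - gap_extend;
      if (yo >= ye) { Y[idx(i, j)] = yo; tbY[idx(i, j)] = 1; }
      else          { Y[idx(i, j)] = ye; tbY[idx(i, j)] = 3; }
      double sub = (double)scores(ea[i - 1], eb[j - 1]);
      double mm = M[idx(i - 1, j - 1)], xx = X[idx(i - 1, j - 1)],
             yy = Y[idx(i - 1, j - 1)];
      double prev = mm; unsigned char from = 1;
      if (xx > prev) { prev = xx; from = 2; }
      if (yy > prev) { prev = yy; from = 3; }
      M[idx(i, j)] = prev + sub; tbM[idx(i, j)] = from;
    }
  }
  // pick best end state
  double endM = M[idx(n, m)], endX = X[idx(n, m)], endY = Y[idx(n, m)];
  int state = 1; double best = endM;
  if (endX > best) { best = endX; state = 2; }
  if (endY > best) { best = endY; state = 3; }
  // traceback
  int i = n, j = m;
  long identities = 0, cols = 0, len = 0;
  while (i > 0 || j > 0) {
    if (state == 1) {
      unsigned char from = tbM[idx(i, j)];
      cols++; len++;
      if (ea[i - 1] == eb[j - 1]) identities++;
      i--; j--; state = from;
    } else if (state == 2) {
      unsigned char from = tbX[idx(i, j)];
      len++; i--; state = (from == 1) ? 1 : 2;
    } else {
      unsigned char from = tbY[idx(i, j)];
      len++; j--; state = (from == 1) ? 1 : 3;
    }
    if (i == 0 && j > 0 && state == 1) state = 3;
    if (j == 0 && i > 0 && state == 1) state = 2;
  }
  return NumericVector::create(_["identities"] = (double)identities,
                               _["aligned_cols"] = (double)cols,
                               _["align_length"] = (double)len,
                               _["score"] = best);
}

// Map each fragment onto a target genome: exact k-mer seeding selects candidate
// diagonals, full affine local DP is run fragment-vs-window around each, and the
// best-scoring hit's identity and fragment coverage are returned (zeros when no
// seed or no positive-score alignment exists).
// [[Rcpp::export]]
NumericMatrix cpp_map_fragments(CharacterVector fragments, std::string target,
                                int k, double match, double mismatch,
                                double gap_open, double gap_extend,
                                int max_diagonals, int margin) {
  const std::string alph = "ACGT";
  auto code = make_code(alph);
  std::vector<int> tgt = encode(target, code);
  // hash target k-mers -> positions
  std::unordered_map<long long, std::vector<int>> index;
  if ((int)tgt.size() >= k) {
    for (size_t i = 0; i + k <= tgt.size(); ++i) {
      long long c = 0; bool ok = true;
      for (int j = 0; j < k; ++j) {
        if (tgt[i + j] < 0) { ok = false; break; }
        c = c * 4 + tgt[i + j];
      }
      if (ok) {
        auto& v = index[c];
        if ((int)v.size() < 64) v.push_back((int)i);
      }
    }
  }
  IntegerMatrix S(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) S(i, j) = (i == j) ? (int)match : (int)mismatch;

  const int nf = fragments.size();
  NumericMatrix out(nf, 3);
  colnames(out) = CharacterVector::create("identity_pct", "coverage", "score");
  for (int f = 0; f < nf; ++f) {
    Rcpp::checkUserInterrupt();
    std::vector<int> frag = encode(std::string(fragments[f]), code);
    const int fl = (int)frag.size();
    // diagonal votes
    std::unordered_map<int, int> diag;
    for (int i = 0; i + k <= fl; ++i) {
      long long c = 0; bool ok = true;
      for (int j = 0; j < k; ++j) {
        if (frag[i + j] < 0) { ok = false; break; }
        c = c * 4 + frag[i + j];
      }
      if (!ok) continue;
      auto it = index.find(c);
      if (it == index.end()) continue;
      for (int tpos : it->second) diag[tpos - i]++;
    }
    if (diag.empty()) continue;
    std::vector<std::pair<int, int>> dv(diag.begin(), diag.end());
    std::sort(dv.begin(), dv.end(),
              [](const std::pair<int, int>& x, const std::pair<int, int>& y) {
                return x.second > y.second || (x.second == y.second && x.first < y.first);
              });
    double best_score = 0.0, best_id = 0.0, best_cov = 0.0;
    std::vector<std::pair<int,int>> tried;  // windows already aligned
    int used = 0;
    for (auto& d : dv) {
      if (used >= max_diagonals) break;
      int ws = std::max(0, d.first - margin);
      int we = std::min((int)tgt.size(), d.first + fl + margin);
      if (we - ws < k) continue;
      bool dup = false;
      for (auto& t : tried)
        if (std::abs(t.first - ws) < margin && std::abs(t.second - we) < margin) { dup = true; break; }
      if (dup) continue;
      tried.push_back({ws, we});
      used++;
      std::vector<int> win(tgt.begin() + ws, tgt.begin() + we);
      std::vector<char> ma(frag.size(), 0), mb(win.size(), 0);
      Hsp h;
      if (!sw_round(frag, win, S, ma, mb, gap_open, gap_extend, h)) continue;
      if (h.score > best_score) {
        best_score = h.score;
        best_id = h.aligned_cols > 0 ? 100.0 * (double)h.identities / h.aligned_cols : 0.0;
        best_cov = (double)(h.qend - h.qstart + 1) / fl;
      }
    }
    out(f, 0) = best_id; out(f, 1) = best_cov; out(f, 2) = best_score;
  }
  return out;
}
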