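#include <Rcpp.h>
#include <unordered_set>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman. A gap of length L costs gap_open + gap_ext*(L-1).
// 'N' never scores as a match (always penalised as a mismatch, never counted
// as an identity), so masked bases cannot contribute matched bases.

static inline int subscore(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string q, std::string s,
                  int match, int mismatch, int gap_open, int gap_ext) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0);
  // state matrices: H (ends in substitution), E (gap in subject, consumes q),
  // F (gap in query, consumes s); pointers for traceback
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), INT_MIN / 2),
      F((n + 1) * (m + 1), INT_MIN / 2);
  std::vector<unsigned char> ptrH((n + 1) * (m + 1), 0),
      ptrE((n + 1) * (m + 1), 0), ptrF((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: gap in subject ending at (i, j): q[i] aligned to '-'
      int eo = H[idx(i - 1, j)] - gap_open;
      int ee = E[idx(i - 1, j)] - gap_ext;
      if (eo >= ee) { E[idx(i, j)] = eo; ptrE[idx(i, j)] = 1; }
      else          { E[idx(i, j)] = ee; ptrE[idx(i, j)] = 2; }
      // F: gap in query: s[j] aligned to '-'
      int fo = H[idx(i, j - 1)] - gap_open;
      int fe = F[idx(i, j - 1)] - gap_ext;
      if (fo >= fe) { F[idx(i, j)] = fo; ptrF[idx(i, j)] = 1; }
      else          { F[idx(i, j)] = fe; ptrF[idx(i, j)] = 2; }
      // H: q[i] vs s[j]
      int sc = subscore(q[i - 1], s[j - 1], match, mismatch);
      int hd = H[idx(i - 1, j - 1)] + sc;
      int he = E[idx(i - 1, j - 1)] + sc;
      int hf = F[idx(i - 1, j - 1)] + sc;
      int h = hd; unsigned char p = 1;
      if (he > h) { h = he; p = 2; }
      if (hf > h) { h = hf; p = 3; }
      if (h < 0) { h = 0; p = 0; }
      H[idx(i, j)] = h; ptrH[idx(i, j)] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0);
  // traceback from (bi, bj) in state H
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  int identities = 0, aln_len = 0;
  int qi_end = bi, sj_end = bj, qi_start = bi, sj_start = bj;
  while (true) {
    if (state == 0) {
      unsigned char p = ptrH[idx(i, j)];
      if (p == 0) break;
      ++aln_len;
      if (q[i - 1] == s[j - 1] && q[i - 1] != 'N') ++identities;
      qi_start = i; sj_start = j;
      state = (p == 1) ? 0 : (p == 2 ? 1 : 2);
      --i; --j;
      if (state == 0 && H[idx(i, j)] == 0 && ptrH[idx(i, j)] == 0) break;
    } else if (state == 1) { // E: q[i] vs gap
      ++aln_len;
      qi_start = i;
      unsigned char p = ptrE[idx(i, j)];
      state = (p == 1) ? 0 : 1;
      --i;
    } else { // F: gap vs s[j]
      ++aln_len;
      sj_start = j;
      unsigned char p = ptrF[idx(i, j)];
      state = (p == 1) ? 0 : 2;
      --j;
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = qi_start, _["q_end"] = qi_end,
                      _["s_start"] = sj_start, _["s_end"] = sj_end,
                      _["identities"] = identities,
                      _["aln_len"] = aln_len);
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r) {
      switch (c) {
        case 'A': c = 'T'; break; case 'T': c = 'A'; break;
        case 'C': c = 'G'; break; case 'G': c = 'C'; break;
        case 'a': c = 't'; break; case 't': c = 'a'; break;
        case 'c': c = 'g'; break; case 'g': c = 'c'; break;
        default: break; // N and anything else unchanged
      }
    }
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export]]
bool has_shared_word_cpp(std::string q, std::string s, int w) {
  const int n = q.size(), m = s.size();
  if (n < w || m < w) return false;
  std::unordered_set<std::string> words;
  for (int i = 0; i + w <= n; ++i) {
    std::string k = q.substr(i, w);
    if (k.find('N') == std::string::npos) words.insert(k);
  }
  for (int j = 0; j + w <= m; ++j) {
    std::string k = s.substr(j, w);
    if (k.find('N') == std::string::npos && words.count(k)) return true;
  }
  return false;
}
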