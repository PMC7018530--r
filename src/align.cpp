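#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Affine-gap convention (NCBI style): a gap of length g costs
// -(open + extend * g), i.e. the first gapped residue scores
// gap_open + gap_extend and every further one gap_extend, with
// gap_open = -11, gap_extend = -1 under the default scheme.

namespace {

const double NEG_INF = -1e30;

// Map residue characters onto substitution-matrix row indices.
std::vector<int> encode(const std::string& s, const std::vector<int>& lut) {
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int code = lut[static_cast<unsigned char>(s[i])];
    if (code < 0)
      stop("illegal residue '%s' for the scoring alphabet", std::string(1, s[i]).c_str());
    out[i] = code;
  }
  return out;
}

std::vector<int> build_lut(const CharacterVector& alphabet) {
  std::vector<int> lut(256, -1);
  for (int k = 0; k < alphabet.size(); ++k) {
    std::string a = as<std::string>(alphabet[k]);
    if (a.size() != 1) stop("alphabet symbols must be single characters");
    lut[static_cast<unsigned char>(a[0])] = k;
  }
  return lut;
}

}  // namespace

// Full-matrix Smith-Waterman for both score and traceback. Sequences here are
// a few hundred residues, so O(nm) memory is fine.

struct SWResult {
  int score;
  int a_start, a_end, b_start, b_end;  // 0-based half-open
  int matches, columns;
  std::string aligned_a, aligned_b;
};

static SWResult sw_full(const std::vector<int>& a, const std::vector<int>& b,
                        const IntegerMatrix& sub, int go, int ge,
                        bool traceback) {
  const int n = a.size(), m = b.size();
  // state matrices: 0 = M (diagonal), 1 = Ix (gap in b, consume a), 2 = Iy
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double ix = std::max(M[at(i - 1, j)] + go + ge, Ix[at(i - 1, j)] + ge);
      double iy = std::max(M[at(i, j - 1)] + go + ge, Iy[at(i, j - 1)] + ge);
      double dprev = std::max(M[at(i - 1, j - 1)],
                              std::max(Ix[at(i - 1, j - 1)], Iy[at(i - 1, j - 1)]));
      double mm = dprev + sub(a[i - 1], b[j - 1]);
      if (mm < 0.0) mm = 0.0;
      M[at(i, j)] = mm;
      Ix[at(i, j)] = ix;
      Iy[at(i, j)] = iy;
      // first strictly-greater cell wins: deterministic best-cell choice
      if (mm > best) { best = mm; bi = i; bj = j; }
    }
  }

  SWResult res;
  res.score = static_cast<int>(best + 0.5);
  res.a_start = res.a_end = res.b_start = res.b_end = 0;
  res.matches = 0;
  res.columns = 0;
  if (res.score <= 0 || !traceback) {
    if (res.score > 0 && !traceback) { res.a_end = bi; res.b_end = bj; }
    return res;
  }

  // traceback from (bi, bj) in state M; tie-break diagonal > up > left
  std::string al_a, al_b;
  int i = bi, j = bj, state = 0;
  res.a_end = bi; res.b_end = bj;
  while (true) {
    if (state == 0) {
      double here = M[at(i, j)];
      if (here <= 0.0) break;
      al_a.push_back('\0' + a[i - 1]);  // store codes, decode later
      al_b.push_back('\0' + b[j - 1]);
      if (a[i - 1] == b[j - 1]) ++res.matches;
      ++res.columns;
      double dprev = here - sub(a[i - 1], b[j - 1]);
      --i; --j;
      if (dprev <= 1e-9) break;  // local alignment start
      if (std::abs(M[at(i, j)] - dprev) < 1e-9) state = 0;
      else if (std::abs(Ix[at(i, j)] - dprev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      // gap in b, consume a ("up"); prefer closing the gap (back to M)
      al_a.push_back('\0' + a[i - 1]);
      al_b.push_back(static_cast<char>(127));  // gap marker
      ++res.columns;
      double here = Ix[at(i, j)];
      if (std::abs(M[at(i - 1, j)] + go + ge - here) < 1e-9) {
        state = 0;
      } else {
        state = 1;
      }
      --i;
    } else {
      al_a.push_back(static_cast<char>(127));
      al_b.push_back('\0' + b[j - 1]);
      ++res.columns;
      double here = Iy[at(i, j)];
      if (std::abs(M[at(i, j - 1)] + go + ge - here) < 1e-9) {
        state = 0;
      } else {
        state = 2;
      }
      --j;
    }
  }
  res.a_start = i;
  res.b_start = j;
  std::reverse(al_a.begin(), al_a.end());
  std::reverse(al_b.begin(), al_b.end());
  res.aligned_a = al_a;
  res.aligned_b = al_b;
  return res;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b, IntegerMatrix sub,
                  CharacterVector alphabet, int gap_open, int gap_extend,
                  bool traceback) {
  std::vector<int> lut = build_lut(alphabet);
  std::vector<int> ea = encode(a, lut), eb = encode(b, lut);
  SWResult r = sw_full(ea, eb, sub, gap_open, gap_extend, traceback);
  std::string out_a, out_b;
  if (traceback) {
    out_a.reserve(r.aligned_a.size());
    out_b.reserve(r.aligned_b.size());
    for (char c : r.aligned_a)
      out_a.push_back(c == static_cast<char>(127) ? '-'
                      : as<std::string>(alphabet[static_cast<int>(c)])[0]);
    for (char c : r.aligned_b)
      out_b.push_back(c == static_cast<char>(127) ? '-'
                      : as<std::string>(alphabet[static_cast<int>(c)])[0]);
  }
  return List::create(
      _["raw_score"] = r.score,
      _["a_start"] = r.a_start, _["a_end"] = r.a_end,
      _["b_start"] = r.b_start, _["b_end"] = r.b_end,
      _["matches"] = r.matches, _["columns"] = r.columns,
      _["aligned_a"] = out_a, _["aligned_b"] = out_b);
}

// Batch score computation for index pairs into a sequence vector (1-based).
// [[Rcpp::export(name = ".sw_score_pairs_cpp")]]
IntegerVector sw_score_pairs_cpp(CharacterVector seqs, IntegerVector ia,
                                 IntegerVector ib, IntegerMatrix sub,
                                 CharacterVector alphabet, int gap_open,
                                 int gap_extend) {
  std::vector<int> lut = build_lut(alphabet);
  std::vector<std::vector<int> > enc(seqs.size());
  for (int k = 0; k < seqs.size(); ++k)
    enc[k] = encode(as<std::string>(seqs[k]), lut);
  IntegerVector out(ia.size());
  for (int p = 0; p < ia.size(); ++p) {
    const std::vector<int>& a = enc[ia[p] - 1];
    const std::vector<int>& b = enc[ib[p] - 1];
    SWResult r = sw_full(a, b, sub, gap_open, gap_extend, false);
    out[p] = r.score;
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Global (Needleman-Wunsch) alignment of a sequence against a profile given a
// precomputed column-vs-residue score matrix S (n_cols x alphabet size).
// Returns the operation string over {'M','D','I'}: M = column+residue,
// D = column aligned to a gap in the sequence, I = residue inserted
// between profile columns. Tie-break: M > D > I.
// [[Rcpp::export(name = ".profile_align_cpp")]]
std::string profile_align_cpp(NumericMatrix S, std::string seq,
                              CharacterVector alphabet, double gap_open,
                              double gap_extend) {
  std::vector<int> lut = build_lut(alphabet);
  std::vector<int> s = encode(seq, lut);
  const int n = S.nrow();       // profile columns
  const int m = s.size();       // sequence residues
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> D((n + 1) * (m + 1), NEG_INF);  // gap in sequence
  std::vector<double> I((n + 1) * (m + 1), NEG_INF);  // insertion of residue
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i)
    D[at(i, 0)] = gap_open + gap_extend * i;
  for (int j = 1; j <= m; ++j)
    I[at(0, j)] = gap_open + gap_extend * j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dprev = std::max(M[at(i - 1, j - 1)],
                              std::max(D[at(i - 1, j - 1)], I[at(i - 1, j - 1)]));
      M[at(i, j)] = dprev + S(i - 1, s[j - 1]);
      D[at(i, j)] = std::max(M[at(i - 1, j)] + gap_open + gap_extend,
                             std::max(D[at(i - 1, j)] + gap_extend,
                                      I[at(i - 1, j)] + gap_open + gap_extend));
      I[at(i, j)] = std::max(M[at(i, j - 1)] + gap_open + gap_extend,
                             std::max(I[at(i, j - 1)] + gap_extend,
                                      D[at(i, j - 1)] + gap_open + gap_extend));
    }
  }
  // traceback from best end state, preferring M > D > I
  int i = n, j = m;
  int state;
  double mm = M[at(n, m)], dd = D[at(n, m)], ii = I[at(n, m)];
  if (mm >= dd && mm >= ii) state = 0;
  else if (dd >= ii) state = 1;
  else state = 2;
  std::string ops;
  while (i > 0 || j > 0) {
    if (i == 0) { ops.push_back('I'); --j; continue; }
    if (j == 0) { ops.push_back('D'); --i; continue; }
    if (state == 0) {
      double here = M[at(i, j)];
      double want = here - S(i - 1, s[j - 1]);
      ops.push_back('M');
      --i; --j;
      if (std::abs(M[at(i, j)] - want) < 1e-9) state = 0;
      else if (std::abs(D[at(i, j)] - want) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      double here = D[at(i, j)];
      ops.push_back('D');
      if (std::abs(M[at(i - 1, j)] + gap_open + gap_extend - here) < 1e-9) state = 0;
      else if (std::abs(D[at(i - 1, j)] + gap_extend - here) < 1e-9) state = 1;
      else state = 2;
      --i;
    } else {
      double here = I[at(i, j)];
      ops.push_back('I');
      if (std::abs(M[at(i, j - 1)] + gap_open + gap_extend - here) < 1e-9) state = 0;
      else if (std::abs(I[at(i, j - 1)] + gap_extend - here) < 1e-9) state = 2;
      else state = 1;
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return ops;
}
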