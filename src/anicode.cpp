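#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

// 64-bit FNV-1a over a byte string; stable content digest for genome
// records and configuration objects.
// [[Rcpp::export]]
std::string cpp_fnv1a(const std::string& x) {
  uint64_t h = 14695981039346656037ULL;
  for (unsigned char c : x) {
    h ^= (uint64_t)c;
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}

static inline bool base_match(char a, char b) {
  // N is a masked position: it never counts as a match, even against N.
  return a == b && a != 'N';
}

// Exact local alignment (Smith-Waterman, linear gap penalty) of a query
// fragment against one subject sequence. Returns the single best-scoring
// local alignment; score ties are broken towards the smaller subject end
// coordinate, then the smaller query end coordinate, so results are
// deterministic.
//
// Returns c(score, qstart, qend, sstart, send, matches, columns), with
// 1-based inclusive coordinates, or all zeros when no positive-scoring
// alignment exists.
// [[Rcpp::export]]
IntegerVector cpp_sw_align(const std::string& query, const std::string& subject,
                           int match, int mismatch, int gap) {
  const int m = (int)query.size(), n = (int)subject.size();
  IntegerVector out(7);
  if (m == 0 || n == 0) return out;

  // H[j] holds the current row; traceback stores the move per cell:
  // 0 = stop, 1 = diagonal, 2 = up (gap in subject), 3 = left (gap in query).
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = 0;
    const char qc = query[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int sub = base_match(qc, subject[j - 1]) ? match : mismatch;
      int sdiag = prev[j - 1] + sub;
      int sup = prev[j] - gap;
      int sleft = cur[j - 1] - gap;
      int s = 0; uint8_t mv = 0;
      // preference on equal scores: diagonal, then up, then left
      if (sdiag >= s) { s = sdiag; mv = 1; }
      if (sup > s)    { s = sup;   mv = 2; }
      if (sleft > s)  { s = sleft; mv = 3; }
      if (s <= 0) { s = 0; mv = 0; }
      cur[j] = s;
      tb[(size_t)i * (n + 1) + j] = mv;
      if (s > best || (s == best && best > 0 && (j < bj || (j == bj && i < bi)))) {
        best = s; bi = i; bj = j;
      }
    }
    std::swap(prev, cur);
  }
  if (best <= 0) return out;

  // traceback from (bi, bj)
  int i = bi, j = bj, matches = 0, columns = 0;
  int qend = bi, send = bj, qstart = bi, sstart = bj;
  while (i > 0 && j > 0) {
    uint8_t mv = tb[(size_t)i * (n + 1) + j];
    if (mv == 0) break;
    ++columns;
    if (mv == 1) {
      if (base_match(query[i - 1], subject[j - 1])) ++matches;
      qstart = i; sstart = j; --i; --j;
    } else if (mv == 2) {
      qstart = i; --i;
    } else {
      sstart = j; --j;
    }
  }
  out[0] = best; out[1] = qstart; out[2] = qend;
  out[3] = sstart; out[4] = send; out[5] = matches; out[6] = columns;
  return out;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static void revcomp_inplace(std::string& s) {
  std::reverse(s.begin(), s.end());
  for (auto& c : s) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
}

// Seed-and-extend ungapped aligner: for each query fragment, exact k-mer
// seeds against the subject propose diagonals, each candidate diagonal is
// scored ungapped over the full fragment/subject overlap, and the best
// diagonal (either strand) is reported. Suited to substitution-divergent
// genomes where homologous fragments align without indels; fragments whose
// true alignment requires gaps, or whose identity is too low to retain an
// exact k-mer, fall back to no hit.
//
// Returns a matrix with one row per fragment:
// score, matches, columns, overlap (query bases in the alignment), strand
// (1 forward, -1 reverse, 0 none).
// [[Rcpp::export]]
IntegerMatrix cpp_seed_align(CharacterVector fragments, const std::string& subject,
                             int k, int match, int mismatch) {
  const int n = (int)subject.size();
  IntegerMatrix out(fragments.size(), 5);
  colnames(out) = CharacterVector::create("score", "matches", "columns",
                                          "overlap", "strand");
  if (n < k) return out;

  // subject k-mer index (2-bit codes; k-mers containing N are skipped)
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve((size_t)n);
  {
    uint64_t code = 0; int run = 0;
    for (int j = 0; j < n; ++j) {
      int b = base_code(subject[j]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k) index[code].push_back(j - k + 1);
    }
  }

  std::vector<int> diags;
  for (int f = 0; f < fragments.size(); ++f) {
    std::string frag = as<std::string>(fragments[f]);
    int bscore = 0, bmatches = 0, bcols = 0, bover = 0, bstrand = 0, bdiag = 0;
    for (int strand = 1; strand >= -1; strand -= 2) {
      std::string q = frag;
      if (strand < 0) revcomp_inplace(q);
      const int m = (int)q.size();
      if (m < k) continue;
      // collect candidate diagonals d = subject_pos - query_pos
      diags.clear();
      uint64_t code = 0; int run = 0;
      for (int p = 0; p < m; ++p) {
        int b = base_code(q[p]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (run + 1 < k) { ++run; continue; }
        ++run;
        auto it = index.find(code);
        if (it == index.end()) continue;
        for (int s : it->second) diags.push_back(s - (p - k + 1));
      }
      if (diags.empty()) continue;
      std::sort(diags.begin(), diags.end());
      diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
      for (int d : diags) {
        int i0 = std::max(0, -d), i1 = std::min(m, n - d); // [i0, i1)
        if (i1 - i0 < k) continue;
        int matches = 0;
        for (int i = i0; i < i1; ++i)
          if (base_match(q[i], subject[i + d])) ++matches;
        int cols = i1 - i0;
        int score = match * matches + mismatch * (cols - matches);
        bool better = score > bscore;
        if (score == bscore && bscore > 0) {
          // deterministic tie-break: forward strand first, then leftmost
          if (strand > bstrand) better = true;
          else if (strand == bstrand && d < bdiag) better = true;
        }
        if (better) {
          bscore = score; bmatches = matches; bcols = cols;
          bover = cols; bstrand = strand; bdiag = d;
        }
      }
    }
    out(f, 0) = bscore; out(f, 1) = bmatches; out(f, 2) = bcols;
    out(f, 3) = bover; out(f, 4) = bstrand;
  }
  return out;
}

// Positionwise identity between two equal-length sequences over an
// interval (1-based, inclusive); used by the simulator's ledger oracle.
// [[Rcpp::export]]
IntegerVector cpp_interval_matches(const std::string& a, const std::string& b,
                                   int start, int end) {
  int matches = 0, cols = 0;
  for (int i = start - 1; i < end; ++i) {
    ++cols;
    if (base_match(a[i], b[i])) ++matches;
  }
  return IntegerVector::create(matches, cols);
}
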