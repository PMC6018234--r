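#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Unit-cost global (end-to-end) edit alignment machinery shared by the
// read-classification pipeline. Alphabet is treated literally; any byte
// mismatch costs 1, as do single-base gaps on either strand.

static inline bool comp_base(char a, char b) {
  switch (a) {
  case 'A': return b == 'T';
  case 'C': return b == 'G';
  case 'G': return b == 'C';
  case 'T': return b == 'A';
  case 'U': return b == 'A';
  default: return false;
  }
}

// cost-only Needleman-Wunsch with unit costs (Levenshtein), two rows
static int nw_cost(const std::string& read, const std::string& ref) {
  const int n = read.size(), m = ref.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const char ri = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (ri == ref[j - 1] ? 0 : 1);
      int u = prev[j] + 1;     // consume read base: insertion w.r.t. reference
      int l = cur[j - 1] + 1;  // consume ref base: deletion from the read
      int best = d < u ? d : u;
      cur[j] = best < l ? best : l;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Full DP with traceback. Tie preference during traceback (from the end):
// diagonal, then deletion, then insertion. Consuming matches from the end
// first places gap runs at the smallest reference positions compatible with
// minimum cost (leftmost gaps), so a truncated 5' prefix reports as a
// deletion at reference start even when its placement is ambiguous.
// Returns run-length merged ops: op in {match=0, sub=1, del=2, ins=3},
// ref_pos = 1-based reference position where the run starts (for ins, the
// position before which bases are inserted; 1 if at reference start).
// [[Rcpp::export]]
List nw_align_cpp(std::string read, std::string ref) {
  const int n = read.size(), m = ref.size();
  NumericMatrix dummy;
  std::vector<std::vector<int> > D(n + 1, std::vector<int>(m + 1));
  for (int j = 0; j <= m; ++j) D[0][j] = j;
  for (int i = 1; i <= n; ++i) {
    D[i][0] = i;
    const char ri = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = D[i - 1][j - 1] + (ri == ref[j - 1] ? 0 : 1);
      int u = D[i - 1][j] + 1;
      int l = D[i][j - 1] + 1;
      int best = d < u ? d : u;
      D[i][j] = best < l ? best : l;
    }
  }
  // traceback
  std::vector<int> ops;      // per-base op codes, reversed
  std::vector<int> refpos;   // 1-based ref position (or insertion anchor)
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        D[i][j] == D[i - 1][j - 1] + (read[i - 1] == ref[j - 1] ? 0 : 1)) {
      ops.push_back(read[i - 1] == ref[j - 1] ? 0 : 1);
      refpos.push_back(j); --i; --j;
    } else if (j > 0 && D[i][j] == D[i][j - 1] + 1) {
      ops.push_back(2); refpos.push_back(j); --j;          // del (ref base skipped)
    } else {                                               // ins (extra read base)
      ops.push_back(3); refpos.push_back(j + 1); --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(refpos.begin(), refpos.end());
  // merge runs of identical op (insertions merge only at the same anchor)
  std::vector<int> mop, mpos, mlen;
  for (size_t k = 0; k < ops.size(); ++k) {
    if (!mop.empty() && mop.back() == ops[k] &&
        ((ops[k] == 3 && mpos.back() == refpos[k]) ||
         (ops[k] != 3 && refpos[k] == mpos.back() + mlen.back()))) {
      mlen.back() += 1;
    } else {
      mop.push_back(ops[k]); mpos.push_back(refpos[k]); mlen.push_back(1);
    }
  }
  return List::create(_["cost"] = D[n][m],
                      _["op"] = wrap(mop),
                      _["ref_pos"] = wrap(mpos),
                      _["length"] = wrap(mlen));
}

// Align each read against every reference; best = minimum cost, ties go to
// the lowest reference index (ambiguous flagged). Reads with best cost >
// max_cost are reported unaligned (ref = 0).
// [[Rcpp::export]]
List align_batch_cpp(CharacterVector reads, CharacterVector refs, int max_cost) {
  const int nr = reads.size(), nf = refs.size();
  std::vector<std::string> R(nf);
  for (int j = 0; j < nf; ++j) R[j] = as<std::string>(refs[j]);
  IntegerVector best_ref(nr), best_cost(nr);
  LogicalVector ambiguous(nr);
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int bc = INT_MAX, bj = -1; bool amb = false;
    for (int j = 0; j < nf; ++j) {
      int c = nw_cost(rd, R[j]);
      if (c < bc) { bc = c; bj = j; amb = false; }
      else if (c == bc) amb = true;
    }
    if (bc > max_cost) { best_ref[i] = 0; best_cost[i] = bc; ambiguous[i] = false; }
    else { best_ref[i] = bj + 1; best_cost[i] = bc; ambiguous[i] = amb; }
  }
  return List::create(_["ref"] = best_ref, _["cost"] = best_cost,
                      _["ambiguous"] = ambiguous);
}

// Longest intramolecular stem (consecutive antiparallel Watson-Crick run)
// that overlaps [span_start, span_end] (1-based, inclusive), with hairpin
// loop of at least min_loop unpaired bases. Exhaustive over all outermost
// pairs via the anti-diagonal run recurrence.
// [[Rcpp::export]]
int longest_stem_cpp(std::string seq, int span_start, int span_end, int min_loop) {
  const int n = seq.size();
  if (n < 2) return 0;
  std::vector<std::vector<int> > run(n + 2, std::vector<int>(n + 2, 0));
  int best = 0;
  // run[i][j]: stem length going inward with outermost pair (i, j), 1-based
  for (int i = n; i >= 1; --i) {
    for (int j = i + 1; j <= n; ++j) {
      // recurrence needs run[i+1][j-1]; iterate i descending, j ascending
      run[i][j] = comp_base(seq[i - 1], seq[j - 1]) ?
        ((i + 1 <= j - 1) ? run[i + 1][j - 1] + 1 : 1) : 0;
      if (run[i][j] == 0) continue;
      // geometry: innermost pair (i+L-1, j-L+1) must leave >= min_loop bases
      int lgeom = (j - i + 1 - min_loop) / 2;
      int L = std::min(run[i][j], lgeom);
      if (L <= best) continue;
      // overlap of either arm with the span
      int a1 = i, a2 = i + L - 1, b1 = j - L + 1, b2 = j;
      bool overl = (a1 <= span_end && a2 >= span_start) ||
                   (b1 <= span_end && b2 >= span_start);
      if (overl) best = L;
    }
  }
  return best;
}

// Longest contiguous antiparallel complementary segment between two
// molecules: max L with a[i..i+L-1] complementary (reversed) to b[j..j+L-1],
// i.e. longest common substring of a and reverse-complement(b).
// [[Rcpp::export]]
int longest_duplex_cpp(std::string a, std::string b) {
  std::string rb(b.rbegin(), b.rend());
  for (size_t k = 0; k < rb.size(); ++k) {
    switch (rb[k]) {
    case 'A': rb[k] = 'T'; break;
    case 'T': rb[k] = 'A'; break;
    case 'U': rb[k] = 'A'; break;
    case 'C': rb[k] = 'G'; break;
    case 'G': rb[k] = 'C'; break;
    default: rb[k] = 'N';
    }
  }
  const int n = a.size(), m = rb.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      cur[j] = (a[i - 1] == rb[j - 1] && a[i - 1] != 'N') ? prev[j - 1] + 1 : 0;
      if (cur[j] > best) best = cur[j];
    }
    std::swap(prev, cur);
  }
  return best;
}
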