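#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// 2-bit packed sequence comparison. A window of <= 32 nt packs into one
// 64-bit word; mismatch counts come from XOR + popcount, which is what makes
// the desk-scale Monte Carlo survey (1e4 addresses x 1e4 strands x all
// 20 nt windows) tractable.

static inline int code_of(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline int mismatches(uint64_t x, uint64_t y) {
  uint64_t z = x ^ y;
  uint64_t m = (z | (z >> 1)) & 0x5555555555555555ULL;
  return __builtin_popcountll(m);
}

static uint64_t pack_seq(const std::string& s) {
  uint64_t v = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int c = code_of(s[i]);
    if (c < 0) stop("invalid character in sequence");
    v = (v << 2) | (uint64_t)c;
  }
  return v;
}

static uint64_t pack_revcomp(const std::string& s) {
  uint64_t v = 0;
  for (size_t i = s.size(); i-- > 0;) {
    int c = code_of(s[i]);
    if (c < 0) stop("invalid character in sequence");
    v = (v << 2) | (uint64_t)(3 - c);
  }
  return v;
}

// all packed windows of width w along s (forward strand only; callers cover
// the reverse complement by also scanning the reverse-complemented query)
static void pack_windows(const std::string& s, int w,
                         std::vector<uint64_t>& out) {
  int n = (int)s.size();
  if (n < w) return;
  uint64_t mask = (2 * w >= 64) ? ~0ULL : ((1ULL << (2 * w)) - 1ULL);
  uint64_t v = 0;
  for (int i = 0; i < n; ++i) {
    int c = code_of(s[i]);
    if (c < 0) stop("invalid character in sequence");
    v = ((v << 2) | (uint64_t)c) & mask;
    if (i >= w - 1) out.push_back(v);
  }
}

// [[Rcpp::export]]
int hamming_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("unequal lengths");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) ++d;
  return d;
}

// Greedy accept-in-order orthogonality filter: candidate i survives iff its
// Hamming distance to every previously accepted sequence (and, when
// check_revcomp, to each accepted sequence's reverse complement) is
// >= threshold.
// [[Rcpp::export]]
LogicalVector greedy_orthogonal_cpp(CharacterVector seqs, int threshold,
                                    bool check_revcomp = true) {
  int n = seqs.size();
  LogicalVector keep(n);
  std::vector<uint64_t> acc_f, acc_r;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (s.size() > 32) stop("sequences longer than 32 nt not supported");
    uint64_t f = pack_seq(s);
    bool ok = true;
    for (size_t j = 0; j < acc_f.size(); ++j) {
      if (mismatches(f, acc_f[j]) < threshold ||
          (check_revcomp && mismatches(f, acc_r[j]) < threshold)) {
        ok = false;
        break;
      }
    }
    keep[i] = ok;
    if (ok) {
      acc_f.push_back(f);
      if (check_revcomp) acc_r.push_back(pack_revcomp(s));
      else acc_r.push_back(f);
    }
  }
  return keep;
}

// Minimum Hamming distance between an address (either orientation) and any
// width-length window over any strand (either orientation). Scanning both
// address orientations against forward windows covers reverse-complemented
// strand windows exactly: HD(a, rc(w)) == HD(rc(a), w).
// [[Rcpp::export]]
int min_payload_distance_cpp(std::string address, CharacterVector strands) {
  int w = (int)address.size();
  if (w > 32) stop("addresses longer than 32 nt not supported");
  uint64_t f = pack_seq(address), r = pack_revcomp(address);
  int best = w + 1;
  std::vector<uint64_t> wins;
  for (int i = 0; i < strands.size(); ++i) {
    wins.clear();
    pack_windows(as<std::string>(strands[i]), w, wins);
    for (size_t k = 0; k < wins.size(); ++k) {
      int d1 = mismatches(f, wins[k]);
      if (d1 < best) best = d1;
      int d2 = mismatches(r, wins[k]);
      if (d2 < best) best = d2;
      if (best == 0) return 0;
    }
  }
  return best;
}

// For each address: does any window of any strand (either orientation) lie
// within Hamming distance < threshold? Early exit per address. The window set
// is packed once and shared by all addresses.
// [[Rcpp::export]]
LogicalVector payload_conflict_batch_cpp(CharacterVector addresses,
                                         CharacterVector strands,
                                         int threshold) {
  if (addresses.size() == 0) return LogicalVector(0);
  int w = (int)std::string(as<std::string>(addresses[0])).size();
  if (w > 32) stop("addresses longer than 32 nt not supported");
  std::vector<uint64_t> wins;
  for (int i = 0; i < strands.size(); ++i)
    pack_windows(as<std::string>(strands[i]), w, wins);
  // codeword-structured payloads repeat windows heavily; deduplicating the
  // window set does not change any minimum distance but shrinks the scan
  std::sort(wins.begin(), wins.end());
  wins.erase(std::unique(wins.begin(), wins.end()), wins.end());
  int n = addresses.size();
  LogicalVector conflict(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(addresses[i]);
    if ((int)a.size() != w) stop("addresses must share one length");
    uint64_t f = pack_seq(a), r = pack_revcomp(a);
    bool hit = false;
    for (size_t k = 0; k < wins.size(); ++k) {
      if (mismatches(f, wins[k]) < threshold ||
          mismatches(r, wins[k]) < threshold) {
        hit = true;
        break;
      }
    }
    conflict[i] = hit;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return conflict;
}

// Global edit-distance (unit costs) alignment of each read against one
// reference, tallying substitution / insertion / deletion events per
// reference position. Tie-break during traceback: diagonal over deletion
// over insertion, giving deterministic (reference-leftmost) indel placement.
// Insertions are charged to the reference position following the inserted
// bases (clamped to the last position).
// [[Rcpp::export]]
List error_events_cpp(CharacterVector reads, std::string ref) {
  int m = (int)ref.size();
  IntegerVector sub(m), ins(m), del(m), dist(reads.size());
  std::vector<int> D; // DP table, (n+1) x (m+1), row-major
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    int n = (int)rd.size();
    D.assign((size_t)(n + 1) * (m + 1), 0);
    for (int j = 0; j <= m; ++j) D[j] = j;
    for (int i = 1; i <= n; ++i) {
      D[(size_t)i * (m + 1)] = i;
      for (int j = 1; j <= m; ++j) {
        int diag = D[(size_t)(i - 1) * (m + 1) + j - 1] +
                   (rd[i - 1] == ref[j - 1] ? 0 : 1);
        int up = D[(size_t)(i - 1) * (m + 1) + j] + 1;   // insertion in read
        int left = D[(size_t)i * (m + 1) + j - 1] + 1;   // deletion from read
        int best = diag < up ? diag : up;
        if (left < best) best = left;
        D[(size_t)i * (m + 1) + j] = best;
      }
    }
    dist[ri] = D[(size_t)n * (m + 1) + m];
    // traceback
    int i = n, j = m;
    while (i > 0 || j > 0) {
      int cur = D[(size_t)i * (m + 1) + j];
      if (i > 0 && j > 0 &&
          cur == D[(size_t)(i - 1) * (m + 1) + j - 1] +
                     (rd[i - 1] == ref[j - 1] ? 0 : 1)) {
        if (rd[i - 1] != ref[j - 1]) sub[j - 1]++;
        --i; --j;
      } else if (j > 0 && cur == D[(size_t)i * (m + 1) + j - 1] + 1) {
        del[j - 1]++; // reference base j deleted from the read
        --j;
      } else {
        ins[j < m ? j : m - 1]++; // insertion before ref position j+1
        --i;
      }
    }
    if (ri % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["sub"] = sub, _["ins"] = ins, _["del"] = del,
                      _["distance"] = dist);
}
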