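#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// Ungapped best-hit aligner with a pigeonhole seed index.
//
// A read with at most k mismatches over its whole length must contain at
// least one of k+1 non-overlapping exact seeds, so candidate placements are
// enumerated from exact seed hits and verified by direct mismatch counting.
// Ties are resolved by (fewest mismatches, record order, leftmost position,
// forward strand first), which makes the result fully deterministic.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N and anything else: never matches
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

struct SeedIndex {
  int w;                         // seed width
  std::vector<uint32_t> bucket_start;  // 4^w + 1 offsets
  std::vector<uint32_t> pos;           // global positions sorted by key
};

// counting-sort index of every w-mer position in the concatenated reference
static void build_index(const std::vector<int8_t>& ref, int w, SeedIndex& idx) {
  idx.w = w;
  size_t nkeys = ((size_t)1) << (2 * w);
  idx.bucket_start.assign(nkeys + 1, 0);
  size_t n = ref.size();
  if (n < (size_t)w) { idx.pos.clear(); return; }
  size_t npos = n - w + 1;

  // rolling key; invalid (contains N) seeds are skipped
  std::vector<uint32_t> keys(npos, UINT32_MAX);
  uint32_t key = 0, mask = (uint32_t)(nkeys - 1);
  int run = 0;  // length of current valid run
  for (size_t i = 0; i < n; ++i) {
    int c = ref[i];
    if (c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)c) & mask;
    if (++run >= w) keys[i - w + 1] = key;
  }
  for (size_t i = 0; i < npos; ++i)
    if (keys[i] != UINT32_MAX) idx.bucket_start[keys[i] + 1]++;
  for (size_t kk = 0; kk < nkeys; ++kk)
    idx.bucket_start[kk + 1] += idx.bucket_start[kk];
  idx.pos.assign(idx.bucket_start[nkeys], 0);
  std::vector<uint32_t> fill(nkeys, 0);
  for (size_t i = 0; i < npos; ++i) {
    if (keys[i] == UINT32_MAX) continue;
    uint32_t kk = keys[i];
    idx.pos[idx.bucket_start[kk] + fill[kk]++] = (uint32_t)i;
  }
}

// [[Rcpp::export]]
List cpp_builtin_align(CharacterVector ref_seqs, CharacterVector read_seqs,
                       int max_mismatches) {
  int k = max_mismatches;
  if (k < 0) stop("max_mismatches must be >= 0");
  int nref = ref_seqs.size();
  int nreads = read_seqs.size();

  // concatenated encoded reference + record boundaries
  std::vector<int8_t> ref;
  std::vector<size_t> rec_start(nref + 1, 0);
  {
    size_t total = 0;
    for (int r = 0; r < nref; ++r) total += LENGTH(STRING_ELT(ref_seqs, r));
    ref.reserve(total);
    for (int r = 0; r < nref; ++r) {
      const char* s = CHAR(STRING_ELT(ref_seqs, r));
      size_t L = LENGTH(STRING_ELT(ref_seqs, r));
      for (size_t i = 0; i < L; ++i) ref.push_back((int8_t)base_code(s[i]));
      rec_start[r + 1] = ref.size();
    }
  }

  int min_len = INT_MAX;
  for (int i = 0; i < nreads; ++i) {
    int L = LENGTH(STRING_ELT(read_seqs, i));
    if (L < min_len) min_len = L;
  }
  if (nreads == 0) min_len = 0;
  // (k+1) disjoint seeds of width w must fit in the shortest read so that
  // the pigeonhole guarantee holds for every read
  int w = min_len / (k + 1);
  if (w > 12) w = 12;
  if (w < 1) w = 1;

  SeedIndex idx;
  build_index(ref, w, idx);
  uint32_t mask = (uint32_t)((((size_t)1) << (2 * w)) - 1);

  IntegerVector out_ref(nreads, NA_INTEGER);
  IntegerVector out_start(nreads, NA_INTEGER);
  IntegerVector out_mm(nreads, NA_INTEGER);
  CharacterVector out_strand(nreads, NA_STRING);
  LogicalVector out_mapped(nreads, false);

  std::vector<int8_t> enc, enc_rc;
  for (int i = 0; i < nreads; ++i) {
    const char* s = CHAR(STRING_ELT(read_seqs, i));
    int L = LENGTH(STRING_ELT(read_seqs, i));
    if (L < w || (size_t)L > ref.size()) continue;

    enc.resize(L); enc_rc.resize(L);
    for (int j = 0; j < L; ++j) enc[j] = (int8_t)base_code(s[j]);
    for (int j = 0; j < L; ++j)
      enc_rc[j] = (int8_t)base_code(comp(s[L - 1 - j]));

    int best_mm = k + 1, best_rec = -1, best_strand = 0;
    long best_pos = -1;

    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<int8_t>& q = (strand == 0) ? enc : enc_rc;
      int nseeds = std::min(k + 1, L / w);
      for (int sdi = 0; sdi < nseeds; ++sdi) {
        int off = sdi * w;
        uint32_t key = 0;
        bool valid = true;
        for (int j = 0; j < w; ++j) {
          if (q[off + j] > 3) { valid = false; break; }
          key = ((key << 2) | (uint32_t)q[off + j]) & mask;
        }
        if (!valid) continue;
        uint32_t b0 = idx.bucket_start[key], b1 = idx.bucket_start[key + 1];
        for (uint32_t b = b0; b < b1; ++b) {
          long g = (long)idx.pos[b] - off;  // candidate global start
          if (g < 0 || (size_t)(g + L) > ref.size()) continue;
          // locate record; read must lie within one record
          int lo = 0, hi = nref;  // find r with rec_start[r] <= g < rec_start[r+1]
          while (hi - lo > 1) {
            int mid = (lo + hi) / 2;
            if ((size_t)g >= rec_start[mid]) lo = mid; else hi = mid;
          }
          int r = lo;
          if ((size_t)(g + L) > rec_start[r + 1]) continue;
          // verify (cap at current best to allow early exit)
          int mm = 0;
          for (int j = 0; j < L; ++j) {
            if (ref[g + j] != q[j] || q[j] > 3) {
              if (++mm > k) break;
            }
          }
          if (mm > k) continue;
          long p = g - (long)rec_start[r];
          bool better = false;
          if (mm < best_mm) better = true;
          else if (mm == best_mm) {
            if (r < best_rec) better = true;
            else if (r == best_rec) {
              if (p < best_pos) better = true;
              else if (p == best_pos && strand < best_strand) better = true;
            }
          }
          if (better) {
            best_mm = mm; best_rec = r; best_pos = p; best_strand = strand;
          }
        }
      }
    }
    if (best_rec >= 0) {
      out_mapped[i] = true;
      out_ref[i] = best_rec + 1;       // 1-based record index
      out_start[i] = (int)best_pos;    // 0-based start
      out_mm[i] = best_mm;
      out_strand[i] = (best_strand == 0) ? "+" : "-";
    }
  }

  return List::create(
    _["mapped"] = out_mapped, _["ref_index"] = out_ref,
    _["start"] = out_start, _["strand"] = out_strand,
    _["mismatches"] = out_mm
  );
}
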