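#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// phred+33 quality cap: 93 is the largest printable score ('~')
static const int QCAP = 93;

static inline int base2code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// Merge 3'-overlapping read pairs. read2 must already be reverse-complemented
// (and its quality string reversed) so that a true overlap aligns the suffix
// of read1 with the prefix of read2rc. Candidate overlaps of length
// >= min_overlap are scored as matches - mismatches; candidates whose
// mismatch rate exceeds max_mm_rate are infeasible; ties break toward the
// longer overlap. Consensus: agreeing sites get min(q1+q2, 93); disagreeing
// sites keep the higher-quality base with quality |q1-q2|.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2rc, CharacterVector qual2rc,
                     int min_overlap, double max_mm_rate) {
  int n = seq1.size();
  LogicalVector merged(n);
  CharacterVector mseq(n), mqual(n);
  for (int i = 0; i < n; ++i) {
    const char *s1 = CHAR(STRING_ELT(seq1, i));
    const char *q1 = CHAR(STRING_ELT(qual1, i));
    const char *s2 = CHAR(STRING_ELT(seq2rc, i));
    const char *q2 = CHAR(STRING_ELT(qual2rc, i));
    int n1 = LENGTH(STRING_ELT(seq1, i));
    int n2 = LENGTH(STRING_ELT(seq2rc, i));
    int maxov = n1 < n2 ? n1 : n2;
    int best_ov = -1, best_score = INT_MIN;
    for (int ov = min_overlap; ov <= maxov; ++ov) {
      int mm = 0;
      const char *a = s1 + (n1 - ov);
      for (int j = 0; j < ov; ++j) if (a[j] != s2[j]) ++mm;
      if ((double)mm > max_mm_rate * ov) continue;
      int score = ov - 2 * mm;
      if (score > best_score || (score == best_score && ov > best_ov)) {
        best_score = score;
        best_ov = ov;
      }
    }
    if (best_ov < 0) { merged[i] = false; continue; }
    merged[i] = true;
    int ov = best_ov, mlen = n1 + n2 - ov;
    std::string seq(mlen, 'N'), qual(mlen, '!');
    for (int j = 0; j < n1 - ov; ++j) { seq[j] = s1[j]; qual[j] = q1[j]; }
    for (int j = 0; j < ov; ++j) {
      char b1 = s1[n1 - ov + j], b2 = s2[j];
      int p1 = q1[n1 - ov + j] - 33, p2 = q2[j] - 33;
      int pos = n1 - ov + j;
      if (b1 == b2) {
        int q = p1 + p2; if (q > QCAP) q = QCAP;
        seq[pos] = b1; qual[pos] = (char)(q + 33);
      } else {
        int q = p1 >= p2 ? p1 - p2 : p2 - p1;
        seq[pos] = (p1 >= p2) ? b1 : b2;
        qual[pos] = (char)(q + 33);
      }
    }
    for (int j = ov; j < n2; ++j) {
      seq[n1 + j - ov] = s2[j]; qual[n1 + j - ov] = q2[j];
    }
    mseq[i] = seq; mqual[i] = qual;
  }
  return List::create(_["merged"] = merged, _["sequence"] = mseq,
                      _["quality"] = mqual);
}

// Seed-and-extend mapping of reads to transcripts: exact k-mer seeds index
// candidate (transcript, offset) diagonals; extension is gapless over the
// full read (terminal clipping disallowed) and identity is matches divided
// by read length. Returns, per read, the best identity and all tied best
// placements; tie-breaking is left to the caller.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector refs, int k,
                   double min_identity) {
  int nref = refs.size();
  std::unordered_map<uint64_t, std::vector<uint64_t> > index;
  index.reserve(1 << 20);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<const char*> refptr(nref);
  std::vector<int> reflen(nref);
  for (int r = 0; r < nref; ++r) {
    refptr[r] = CHAR(STRING_ELT(refs, r));
    reflen[r] = LENGTH(STRING_ELT(refs, r));
    const char *s = refptr[r];
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < reflen[r]; ++p) {
      int c = base2code(s[p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k)
        index[key].push_back(((uint64_t)r << 32) | (uint64_t)(p - k + 1));
    }
  }
  int nreads = reads.size();
  NumericVector best_identity(nreads, NA_REAL);
  std::vector<int> tie_read, tie_ref, tie_start;
  std::unordered_set<uint64_t> seen;
  for (int i = 0; i < nreads; ++i) {
    const char *rd = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    if (len < k) continue;
    seen.clear();
    double best = -1.0;
    std::vector<std::pair<int,int> > best_hits;
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < len; ++p) {
      int c = base2code(rd[p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      auto it = index.find(key);
      if (it == index.end()) continue;
      int roff = p - k + 1;
      for (uint64_t packed : it->second) {
        int r = (int)(packed >> 32);
        int tpos = (int)(packed & 0xffffffffULL);
        int start = tpos - roff;
        if (start < 0 || start + len > reflen[r]) continue;
        uint64_t ck = ((uint64_t)r << 32) | (uint64_t)start;
        if (!seen.insert(ck).second) continue;
        const char *t = refptr[r] + start;
        int matches = 0;
        for (int j = 0; j < len; ++j) if (rd[j] == t[j]) ++matches;
        double ident = (double)matches / (double)len;
        if (ident < min_identity) continue;
        if (ident > best + 1e-12) {
          best = ident;
          best_hits.clear();
          best_hits.push_back(std::make_pair(r, start));
        } else if (ident > best - 1e-12) {
          best_hits.push_back(std::make_pair(r, start));
        }
      }
    }
    if (best >= 0) {
      best_identity[i] = best;
      for (auto &h : best_hits) {
        tie_read.push_back(i + 1);
        tie_ref.push_back(h.first + 1);
        tie_start.push_back(h.second);
      }
    }
  }
  return List::create(_["best_identity"] = best_identity,
                      _["tie_read"] = wrap(tie_read),
                      _["tie_ref"] = wrap(tie_ref),
                      _["tie_start"] = wrap(tie_start));
}

// Tally aligned read bases into per-transcript 4 x L count matrices
// (rows A, C, G, T; N bases are skipped). Hits are gapless placements.
// [[Rcpp::export]]
List cpp_pileup(IntegerVector hit_read, IntegerVector hit_ref,
                IntegerVector hit_start, CharacterVector reads,
                IntegerVector ref_lengths) {
  int nref = ref_lengths.size();
  List out(nref);
  std::vector<IntegerMatrix> mats;
  mats.reserve(nref);
  for (int r = 0; r < nref; ++r)
    mats.push_back(IntegerMatrix(4, ref_lengths[r]));
  int nh = hit_read.size();
  for (int h = 0; h < nh; ++h) {
    int i = hit_read[h] - 1, r = hit_ref[h] - 1, start = hit_start[h];
    const char *rd = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    if (start < 0 || start + len > ref_lengths[r])
      stop("pileup: hit extends beyond transcript bounds");
    IntegerMatrix &m = mats[r];
    for (int j = 0; j < len; ++j) {
      int c = base2code(rd[j]);
      if (c >= 0) m(c, start + j) += 1;
    }
  }
  for (int r = 0; r < nref; ++r) out[r] = mats[r];
  return out;
}
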