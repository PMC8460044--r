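// Seed-and-extend ungapped local aligner.
//
// Stands in for an external BLASTN screen: exact k-mer seeds (every
// reference position indexed; query k-mers sampled at a stride small enough
// that any exact match of >= 28 nt is guaranteed to contain a sampled seed),
// ungapped X-drop extension with +1/-2 scoring, both strands. Circular
// references are indexed over their first copy but stored doubled, so
// alignments crossing the origin are found in one piece and reported with
// wrapped (canonical) coordinates.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct Aln {
  int ref;        // 0-based reference index
  int strand;     // +1 / -1
  int rlo, rhi;   // 0-based half-open span on the original read
  long long refAtLo, refAtHi;  // 1-based ref coords at read bases rlo, rhi-1
  int score, matches, mismatches;
};

struct Extent { int ref; int strand; long long diag; int rlo, rhi; };

// extend left/right of an exact seed; returns gain and stats at the optimum
static inline void extendDir(const std::vector<int8_t>& ref,
                             const std::vector<int8_t>& q,
                             long long j0, int i0, int dir,
                             long long jMin, long long jMax, int iMin,
                             int iMax, int match, int mismatch, int xdrop,
                             int& gain, int& len, int& mm) {
  int cur = 0, curMm = 0;
  gain = 0; len = 0; mm = 0;
  long long j = j0; int i = i0, step = 0;
  while (i >= iMin && i <= iMax && j >= jMin && j <= jMax) {
    bool hit = (q[i] >= 0 && q[i] == ref[j]);
    cur += hit ? match : mismatch;
    if (!hit) ++curMm;
    ++step;
    if (cur > gain) { gain = cur; len = step; mm = curMm; }
    if (cur < gain - xdrop) break;
    i += dir; j += dir;
  }
}

// [[Rcpp::export(name = ".align_cpp")]]
DataFrame align_cpp(CharacterVector reads, CharacterVector refs,
                    LogicalVector circular, int k, int stride, int match,
                    int mismatch, int xdrop, int maxHits, int minScore) {
  const int nRef = refs.size();
  if (nRef == 0) stop("invalid argument: empty reference set");
  // ---- encode references (circular ones doubled) ----
  std::vector<std::vector<int8_t>> refSeq(nRef);
  std::vector<long long> trueLen(nRef);
  for (int r = 0; r < nRef; ++r) {
    const char* s = CHAR(STRING_ELT(refs, r));
    long long L = LENGTH(STRING_ELT(refs, r));
    trueLen[r] = L;
    bool circ = circular[r % circular.size()];
    long long stored = circ ? 2 * L : L;
    refSeq[r].resize(stored);
    for (long long i = 0; i < stored; ++i)
      refSeq[r][i] = (int8_t)baseCode(s[i % L]);
  }
  // ---- k-mer index: sorted (kmer << 40 | refIdx << 28 | pos) ----
  // pos < 2^28, ref < 2^12, kmer 2k bits (k <= 20 -> fits in 24 high bits
  // only for k <= 12, so use two-vector sort instead)
  struct Entry { uint64_t kmer; int ref; int pos; };
  std::vector<Entry> idx;
  {
    uint64_t total = 0;
    for (int r = 0; r < nRef; ++r) total += (uint64_t)trueLen[r];
    idx.reserve(total);
  }
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int r = 0; r < nRef; ++r) {
    bool circ = circular[r % circular.size()];
    long long L = trueLen[r];
    long long nStart = circ ? L : (L - k + 1);
    if (nStart <= 0) continue;
    const std::vector<int8_t>& s = refSeq[r];
    uint64_t km = 0;
    int valid = 0;
    // rolling over stored sequence; record starts < nStart
    long long stored = (long long)s.size();
    for (long long i = 0; i < stored; ++i) {
      int c = s[i];
      if (c < 0) { valid = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        long long start = i - k + 1;
        if (start < nStart) idx.push_back({km, r, (int)start});
      }
    }
  }
  std::sort(idx.begin(), idx.end(),
            [](const Entry& a, const Entry& b) { return a.kmer < b.kmer; });

  auto lookup = [&](uint64_t km, std::vector<std::pair<int, int>>& out) {
    Entry probe{km, 0, 0};
    auto it = std::lower_bound(idx.begin(), idx.end(), probe,
                               [](const Entry& a, const Entry& b) {
                                 return a.kmer < b.kmer;
                               });
    for (; it != idx.end() && it->kmer == km; ++it)
      out.push_back({it->ref, it->pos});
  };

  // ---- align each read ----
  std::vector<int> o_read, o_ref, o_strand, o_rlo, o_rhi, o_score, o_match,
      o_mism;
  std::vector<double> o_reflo, o_refhi;

  const int nRead = reads.size();
  for (int ri = 0; ri < nRead; ++ri) {
    const char* rs = CHAR(STRING_ELT(reads, ri));
    int rlen = LENGTH(STRING_ELT(reads, ri));
    if (rlen < k)
      stop("invalid argument: read %d shorter than the seed size (%d < %d)",
           ri + 1, rlen, k);
    std::vector<int8_t> fwd(rlen), rev(rlen);
    for (int i = 0; i < rlen; ++i) fwd[i] = (int8_t)baseCode(rs[i]);
    for (int i = 0; i < rlen; ++i)
      rev[i] = fwd[rlen - 1 - i] < 0 ? -1 : (int8_t)(3 - fwd[rlen - 1 - i]);

    std::vector<Aln> alns;
    std::vector<Extent> extents;
    std::vector<std::pair<int, int>> hits;
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<int8_t>& q = strand == 0 ? fwd : rev;
      // sampled seed starts (stride, plus the final window)
      std::vector<int> starts;
      for (int p = 0; p + k <= rlen; p += stride) starts.push_back(p);
      if (starts.empty() || starts.back() != rlen - k)
        starts.push_back(rlen - k);
      for (int p : starts) {
        uint64_t km = 0;
        bool ok = true;
        for (int t = 0; t < k; ++t) {
          if (q[p + t] < 0) { ok = false; break; }
          km = (km << 2) | (uint64_t)q[p + t];
        }
        if (!ok) continue;
        hits.clear();
        lookup(km, hits);
        for (auto& h : hits) {
          int r = h.first;
          long long qpos = h.second;
          long long diag = qpos - p;
          bool seen = false;
          for (auto& e : extents)
            if (e.ref == r && e.strand == strand && e.diag == diag &&
                p >= e.rlo && p + k <= e.rhi) {
              seen = true;
              break;
            }
          if (seen) continue;
          const std::vector<int8_t>& R = refSeq[r];
          long long stored = (long long)R.size();
          int gL, lL, mL, gR, lR, mR;
          extendDir(R, q, qpos - 1, p - 1, -1, 0, stored - 1, 0, rlen - 1,
                    match, mismatch, xdrop, gL, lL, mL);
          extendDir(R, q, qpos + k, p + k, +1, 0, stored - 1, 0, rlen - 1,
                    match, mismatch, xdrop, gR, lR, mR);
          int sc = k * match + gL + gR;
          int qlo = p - lL, qhi = p + k + lR;  // on oriented read
          long long glo = qpos - lL, ghi = qpos + k - 1 + lR;
          extents.push_back({r, strand, diag, qlo, qhi});
          if (sc < minScore) continue;
          Aln a;
          a.ref = r;
          a.strand = strand == 0 ? 1 : -1;
          a.score = sc;
          a.mismatches = mL + mR;
          a.matches = (qhi - qlo) - a.mismatches;
          long long L = trueLen[r];
          long long c_lo = (glo % L) + 1, c_hi = (ghi % L) + 1;
          if (strand == 0) {
            a.rlo = qlo; a.rhi = qhi;
            a.refAtLo = c_lo; a.refAtHi = c_hi;
          } else {
            a.rlo = rlen - qhi; a.rhi = rlen - qlo;
            a.refAtLo = c_hi; a.refAtHi = c_lo;
          }
          alns.push_back(a);
        }
      }
    }
    // dedup identical canonical alignments, rank, keep top maxHits
    std::sort(alns.begin(), alns.end(), [](const Aln& a, const Aln& b) {
      if (a.score != b.score) return a.score > b.score;
      int la = a.rhi - a.rlo, lb = b.rhi - b.rlo;
      if (la != lb) return la > lb;
      if (a.ref != b.ref) return a.ref < b.ref;
      long long pa = std::min(a.refAtLo, a.refAtHi),
                pb = std::min(b.refAtLo, b.refAtHi);
      if (pa != pb) return pa < pb;
      return a.strand > b.strand;
    });
    int kept = 0;
    for (size_t i = 0; i < alns.size() && kept < maxHits; ++i) {
      bool dup = false;
      for (size_t j = 0; j < i; ++j)
        if (alns[j].ref == alns[i].ref && alns[j].strand == alns[i].strand &&
            alns[j].rlo == alns[i].rlo && alns[j].rhi == alns[i].rhi &&
            alns[j].refAtLo == alns[i].refAtLo) {
          dup = true;
          break;
        }
      if (dup) continue;
      ++kept;
      o_read.push_back(ri + 1);
      o_ref.push_back(alns[i].ref + 1);
      o_strand.push_back(alns[i].strand);
      o_rlo.push_back(alns[i].rlo);
      o_rhi.push_back(alns[i].rhi);
      o_reflo.push_back((double)alns[i].refAtLo);
      o_refhi.push_back((double)alns[i].refAtHi);
      o_score.push_back(alns[i].score);
      o_match.push_back(alns[i].matches);
      o_mism.push_back(alns[i].mismatches);
    }
  }
  return DataFrame::create(
      _["read_idx"] = o_read, _["ref_idx"] = o_ref, _["strand"] = o_strand,
      _["read_lo"] = o_rlo, _["read_hi"] = o_rhi, _["ref_at_lo"] = o_reflo,
      _["ref_at_hi"] = o_refhi, _["matches"] = o_match,
      _["mismatches"] = o_mism, _["score"] = o_score);
}
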