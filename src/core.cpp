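#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Small sequence utilities shared by the simulator, the polyA scan and the
// aligner. All coordinates returned to R are 1-based inclusive.
// ---------------------------------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp_base(c);
  return r;
}

// Longest run of 'A' and of 'T' per sequence (polyA on either strand).
// [[Rcpp::export]]
DataFrame cpp_longest_runs(CharacterVector seqs) {
  int n = seqs.size();
  IntegerVector runA(n), runT(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int bestA = 0, bestT = 0, curA = 0, curT = 0;
    for (const char* p = s; *p; ++p) {
      curA = (*p == 'A') ? curA + 1 : 0;
      curT = (*p == 'T') ? curT + 1 : 0;
      if (curA > bestA) bestA = curA;
      if (curT > bestT) bestT = curT;
    }
    runA[i] = bestA;
    runT[i] = bestT;
  }
  return DataFrame::create(_["run_a"] = runA, _["run_t"] = runT);
}

// Longest run of a single character (e.g. the minimum-quality symbol '#').
// [[Rcpp::export]]
IntegerVector cpp_max_char_run(CharacterVector strings, char ch) {
  int n = strings.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(strings, i));
    int best = 0, cur = 0;
    for (const char* p = s; *p; ++p) {
      cur = (*p == ch) ? cur + 1 : 0;
      if (cur > best) best = cur;
    }
    out[i] = best;
  }
  return out;
}

// Maximal homopolymer runs of the given bases in one sequence.
// Returns 1-based inclusive start/end plus the base.
// [[Rcpp::export]]
DataFrame cpp_find_runs(std::string seq, int min_run, std::string bases) {
  std::vector<int> starts, ends;
  std::vector<std::string> base_out;
  int n = (int)seq.size();
  int i = 0;
  while (i < n) {
    char b = seq[i];
    int j = i + 1;
    while (j < n && seq[j] == b) ++j;
    if (j - i >= min_run && bases.find(b) != std::string::npos) {
      starts.push_back(i + 1);
      ends.push_back(j);
      base_out.push_back(std::string(1, b));
    }
    i = j;
  }
  return DataFrame::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                           _["base"] = wrap(base_out),
                           _["stringsAsFactors"] = false);
}

// Best ungapped identity between two sequences over any offset, measured on
// windows of exactly `win` aligned bases. If a stretch of >= win bases has
// identity >= t somewhere, some window of length win also reaches t, so this
// is a faithful test for "identity >= t over at least win bp".
// [[Rcpp::export]]
double cpp_best_window_identity(std::string a, std::string b, int win) {
  int la = (int)a.size(), lb = (int)b.size();
  if (la < win || lb < win) return 0.0;
  double best = 0.0;
  for (int off = -(lb - win); off <= la - win; ++off) {
    // aligned region: a[i] vs b[i - off]
    int lo = std::max(0, off);
    int hi = std::min(la, lb + off);  // exclusive
    int len = hi - lo;
    if (len < win) continue;
    int mm = 0;
    // initial window
    for (int i = lo; i < lo + win; ++i) mm += (a[i] != b[i - off]);
    int bestmm = mm;
    for (int i = lo + win; i < hi; ++i) {
      mm += (a[i] != b[i - off]);
      mm -= (a[i - win] != b[i - win - off]);
      if (mm < bestmm) bestmm = mm;
    }
    double ident = 1.0 - (double)bestmm / win;
    if (ident > best) best = ident;
  }
  return best;
}

// ---------------------------------------------------------------------------
// Seed-and-extend read aligner.
//
// Exact k-mer index over the reference; candidate placements are evaluated by
// an ungapped match/mismatch scan with the best-scoring contiguous segment
// kept (soft-clipped tails). Two dialects:
//   * strict:   a placement needs >= min_anchor matching bases that do not
//               sit inside a long (>= polya_min_run) homopolymer run of the
//               read. Long-polyA reads therefore stay unmapped.
//   * trimming: a placement needs >= min_anchor matching bases overall, and
//               additionally candidate placements are generated by anchoring
//               a read homopolymer run (>= polya_min_run) onto a reference
//               run of the same base; such placements are accepted with as
//               few as polya_min_flank matching bases outside the run.
// MAPQ = min(60, 6 * (best - second best)) and 0 on ties.
// ---------------------------------------------------------------------------

static inline int base2code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

struct SeedIndex {
  std::vector<std::pair<uint64_t, uint32_t>> entries;  // (kmer, concat pos)
  int k;
};

struct RefRun {  // homopolymer run on the concatenated reference
  uint32_t start;  // 0-based concat
  uint32_t end;    // exclusive
  char base;
};

struct Candidate {
  int64_t diag;    // concat position of oriented-read base 0
  int strand;      // 0 = forward, 1 = reverse-complement
  bool polya_anchor;
};

struct Placement {
  int score;       // matching bases in the kept segment
  int chrom;       // 0-based
  int64_t pos;     // 0-based chrom-relative start of segment
  int strand;
  int clip_left;   // oriented-read bases clipped before segment
  int clip_right;
  int aln_len;
};

// Evaluate one diagonal; returns score < 0 if rejected.
static Placement evaluate_candidate(const std::string& cat,
                                    const std::vector<int64_t>& chrom_off,
                                    const std::vector<int64_t>& chrom_len,
                                    const std::string& read,
                                    const std::vector<char>& in_long_run,
                                    int64_t run_from, int64_t run_to,
                                    const Candidate& cand, bool strict,
                                    int min_anchor, int polya_min_flank,
                                    std::vector<char>& match) {
  Placement out;
  out.score = -1;
  int L = (int)read.size();
  int64_t catlen = (int64_t)cat.size();
  // locate chromosome from the midpoint of the tentative span
  int64_t mid = cand.diag + L / 2;
  if (mid < 0) mid = 0;
  if (mid >= catlen) mid = catlen - 1;
  int chrom = (int)(std::upper_bound(chrom_off.begin(), chrom_off.end(), mid) -
                    chrom_off.begin()) - 1;
  if (chrom < 0) return out;
  int64_t clo = chrom_off[chrom];
  int64_t chi = clo + chrom_len[chrom];

  // best-scoring segment: +1 match, -3 mismatch/out-of-chrom (Kadane)
  int best = 0, best_b = 0, best_e = 0;
  int cur = 0, cur_b = 0;
  match.assign(L, 0);
  for (int i = 0; i < L; ++i) {
    int64_t rp = cand.diag + i;
    bool m = (rp >= clo && rp < chi && cat[(size_t)rp] == read[i]);
    match[i] = m ? 1 : 0;
    cur += m ? 1 : -3;
    if (cur <= 0) { cur = 0; cur_b = i + 1; }
    else if (cur > best) { best = cur; best_b = cur_b; best_e = i + 1; }
  }
  if (best_e <= best_b) return out;

  int nmatch = 0, nmatch_nonrun = 0, nmatch_inrun = 0;
  for (int i = best_b; i < best_e; ++i) {
    if (!match[i]) continue;
    ++nmatch;
    bool in_run = in_long_run[i] != 0;
    if (cand.polya_anchor) in_run = (i >= run_from && i < run_to);
    if (in_run) ++nmatch_inrun; else ++nmatch_nonrun;
  }

  bool accept;
  if (cand.polya_anchor) {
    accept = (nmatch_inrun >= 20) && (nmatch_nonrun >= polya_min_flank);
  } else if (strict) {
    accept = nmatch_nonrun >= min_anchor;
  } else {
    accept = nmatch >= min_anchor;
  }
  if (!accept) return out;

  out.score = nmatch;
  out.chrom = chrom;
  out.pos = cand.diag + best_b - clo;
  out.strand = cand.strand;
  out.clip_left = best_b;
  out.clip_right = L - best_e;
  out.aln_len = best_e - best_b;
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_align_reads(CharacterVector ref_seqs, CharacterVector reads,
                          int k, int step, int max_occ, bool strict,
                          int min_anchor, int polya_min_run,
                          int polya_min_flank) {
  int nchrom = ref_seqs.size();
  std::vector<int64_t> chrom_off(nchrom), chrom_len(nchrom);
  std::string cat;
  {
    int64_t total = 0;
    for (int c = 0; c < nchrom; ++c) {
      const char* s = CHAR(STRING_ELT(ref_seqs, c));
      chrom_off[c] = total;
      chrom_len[c] = (int64_t)strlen(s);
      total += chrom_len[c];
    }
    cat.reserve((size_t)total);
    for (int c = 0; c < nchrom; ++c) cat += CHAR(STRING_ELT(ref_seqs, c));
  }
  int64_t catlen = (int64_t)cat.size();

  // --- index ---
  SeedIndex idx;
  idx.k = k;
  idx.entries.reserve((size_t)std::max<int64_t>(0, catlen - k + 1));
  {
    uint64_t key = 0;
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int valid = 0;
    for (int64_t i = 0; i < catlen; ++i) {
      int code = base2code(cat[(size_t)i]);
      if (code < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)code) & mask;
      if (++valid >= k) {
        int64_t pos = i - k + 1;
        // k-mers must not straddle a chromosome boundary
        int c = (int)(std::upper_bound(chrom_off.begin(), chrom_off.end(), pos) -
                      chrom_off.begin()) - 1;
        if (pos + k <= chrom_off[c] + chrom_len[c])
          idx.entries.emplace_back(key, (uint32_t)pos);
      }
    }
    std::sort(idx.entries.begin(), idx.entries.end());
  }

  // --- reference homopolymer runs (for the trimming dialect anchors) ---
  std::vector<RefRun> ref_runs;
  {
    int64_t i = 0;
    while (i < catlen) {
      char b = cat[(size_t)i];
      int64_t j = i + 1;
      while (j < catlen && cat[(size_t)j] == b) ++j;
      if ((b == 'A' || b == 'T') && j - i >= polya_min_run) {
        // keep runs within one chromosome only
        int c = (int)(std::upper_bound(chrom_off.begin(), chrom_off.end(), i) -
                      chrom_off.begin()) - 1;
        if (j <= chrom_off[c] + chrom_len[c]) {
          RefRun r; r.start = (uint32_t)i; r.end = (uint32_t)j; r.base = b;
          ref_runs.push_back(r);
        }
      }
      i = j;
    }
  }

  int nreads = reads.size();
  IntegerVector o_chrom(nreads), o_pos(nreads), o_strand(nreads),
      o_mapq(nreads), o_score(nreads), o_clipl(nreads), o_clipr(nreads),
      o_alen(nreads);

  std::vector<Candidate> cands;
  std::vector<char> match_buf;
  for (int r = 0; r < nreads; ++r) {
    const char* rs = CHAR(STRING_ELT(reads, r));
    std::string fwd(rs);
    int L = (int)fwd.size();
    o_chrom[r] = NA_INTEGER; o_pos[r] = NA_INTEGER; o_strand[r] = NA_INTEGER;
    o_mapq[r] = 0; o_score[r] = 0; o_clipl[r] = 0; o_clipr[r] = 0;
    o_alen[r] = 0;
    if (L < k) continue;  // too short to seed: unmapped, not an error
    std::string rev = revcomp(fwd);

    Placement best; best.score = -1;
    int second = 0;
    bool tie = false;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rd = (strand == 0) ? fwd : rev;

      // long homopolymer-run mask of the oriented read
      std::vector<char> in_long(L, 0);
      // read runs (any base) >= polya_min_run
      std::vector<std::pair<int,int>> at_runs;  // A/T runs for anchoring
      {
        int i = 0;
        while (i < L) {
          char b = rd[i];
          int j = i + 1;
          while (j < L && rd[j] == b) ++j;
          if (j - i >= polya_min_run) {
            for (int t = i; t < j; ++t) in_long[t] = 1;
            if (b == 'A' || b == 'T') at_runs.emplace_back(i, j);
          }
          i = j;
        }
      }

      cands.clear();
      // k-mer seeds
      for (int off = 0; off + k <= L; off += step) {
        uint64_t key = 0;
        bool ok = true;
        for (int t = 0; t < k; ++t) {
          int code = base2code(rd[off + t]);
          if (code < 0) { ok = false; break; }
          key = (key << 2) | (uint64_t)code;
        }
        if (!ok) continue;
        auto lo = std::lower_bound(idx.entries.begin(), idx.entries.end(),
                                   std::make_pair(key, (uint32_t)0));
        auto hi = lo;
        while (hi != idx.entries.end() && hi->first == key) ++hi;
        if (hi - lo > max_occ) continue;
        for (auto it = lo; it != hi; ++it) {
          Candidate c;
          c.diag = (int64_t)it->second - off;
          c.strand = strand;
          c.polya_anchor = false;
          cands.push_back(c);
        }
      }
      // polyA-anchored candidates (trimming dialect only)
      std::vector<std::pair<int64_t,std::pair<int,int>>> anchor_runs;
      if (!strict) {
        for (auto& rr : at_runs) {
          for (auto& gr : ref_runs) {
            if (gr.base != rd[rr.first]) continue;
            Candidate c;
            c.strand = strand; c.polya_anchor = true;
            c.diag = (int64_t)gr.start - rr.first;  // run starts aligned
            cands.push_back(c);
            anchor_runs.push_back({c.diag, rr});
            c.diag = (int64_t)gr.end - rr.second;   // run ends aligned
            cands.push_back(c);
            anchor_runs.push_back({c.diag, rr});
          }
        }
      }

      // dedup diagonals, preferring non-anchor (stricter) evaluation first
      std::sort(cands.begin(), cands.end(),
                [](const Candidate& a, const Candidate& b) {
                  if (a.diag != b.diag) return a.diag < b.diag;
                  return a.polya_anchor < b.polya_anchor;
                });
      int64_t prev_diag = INT64_MIN;
      for (size_t ci = 0; ci < cands.size(); ++ci) {
        const Candidate& c = cands[ci];
        if (c.diag == prev_diag) continue;
        prev_diag = c.diag;
        int64_t rf = 0, rt = 0;
        if (c.polya_anchor) {
          for (auto& ar : anchor_runs)
            if (ar.first == c.diag) { rf = ar.second.first; rt = ar.second.second; break; }
        }
        Placement p = evaluate_candidate(cat, chrom_off, chrom_len, rd, in_long,
                                         rf, rt, c, strict, min_anchor,
                                         polya_min_flank, match_buf);
        if (p.score < 0) continue;
        if (best.score < 0 || p.score > best.score) {
          if (best.score > 0) second = std::max(second, best.score);
          best = p;
          tie = false;
        } else if (p.score == best.score &&
                   !(p.chrom == best.chrom && p.pos == best.pos &&
                     p.strand == best.strand)) {
          tie = true;
          second = std::max(second, p.score);
          // deterministic tie-break: smallest (chrom, pos, strand)
          if (p.chrom < best.chrom ||
              (p.chrom == best.chrom &&
               (p.pos < best.pos ||
                (p.pos == best.pos && p.strand < best.strand))))
            best = p;
        } else if (p.score > second) {
          second = p.score;
        }
      }
    }

    if (best.score < 0) continue;  // unmapped
    o_chrom[r] = best.chrom + 1;
    o_pos[r] = (int)best.pos + 1;  // 1-based
    o_strand[r] = best.strand;
    o_mapq[r] = tie ? 0 : std::min(60, 6 * (best.score - second));
    o_score[r] = best.score;
    o_clipl[r] = best.clip_left;
    o_clipr[r] = best.clip_right;
    o_alen[r] = best.aln_len;
  }

  return DataFrame::create(
      _["chrom"] = o_chrom, _["pos"] = o_pos, _["strand"] = o_strand,
      _["mapq"] = o_mapq, _["score"] = o_score, _["clip_left"] = o_clipl,
      _["clip_right"] = o_clipr, _["aln_len"] = o_alen);
}
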