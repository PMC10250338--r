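// Local alignment engine: affine-gap Smith-Waterman with exact k-mer
// seeding for long reads and iterative masking so that several
// non-overlapping hits per read (concatemer units) are reported.
#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct Scoring {
  double match, mismatch, gap_open, gap_ext;
};

struct Hit {
  int rstart, rend, qstart, qend;  // read / ref, 0-based half-open
  double score;
  int matches, columns;
};

const double NEG = -1e30;

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp_base(c);
  return r;
}

inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

inline double subst(char a, char b, const Scoring& sc) {
  // N never matches anything, including another N
  if (a == b && is_acgt(a)) return sc.match;
  return sc.mismatch;
}

// trace byte layout: bits 0-1 H source (0 stop, 1 diag, 2 E, 3 F),
// bit 2 E extended, bit 3 F extended
bool sw_window(const std::string& read, int w0, int w1, const std::string& ref,
               const Scoring& sc, Hit& out) {
  const int m = w1 - w0, n = (int)ref.size();
  if (m <= 0 || n <= 0) return false;
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0), F(n + 1, NEG);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0;
    double E = NEG;
    const char rc = read[w0 + i - 1];
    uint8_t* tbrow = &tb[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      uint8_t t = 0;
      const double e_open = Hcur[j - 1] - sc.gap_open - sc.gap_ext;
      const double e_ext = E - sc.gap_ext;
      if (e_ext > e_open) {
        E = e_ext;
        t |= 4;
      } else {
        E = e_open;
      }
      const double f_open = Hprev[j] - sc.gap_open - sc.gap_ext;
      const double f_ext = F[j] - sc.gap_ext;
      if (f_ext > f_open) {
        F[j] = f_ext;
        t |= 8;
      } else {
        F[j] = f_open;
      }
      const double diag = Hprev[j - 1] + subst(rc, ref[j - 1], sc);
      double h = 0.0;
      uint8_t src = 0;
      if (diag >= h) { h = diag; src = 1; }
      if (E > h) { h = E; src = 2; }
      if (F[j] > h) { h = F[j]; src = 3; }
      Hcur[j] = h;
      tbrow[j] = t | src;
      if (h > best) {
        best = h;
        bi = i;
        bj = j;
      }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0.0) return false;
  // traceback
  int i = bi, j = bj, matches = 0, columns = 0, state = 0;  // 0=H,1=E,2=F
  while (true) {
    const uint8_t t = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      const uint8_t src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        ++columns;
        if (read[w0 + i - 1] == ref[j - 1] && is_acgt(ref[j - 1])) ++matches;
        --i;
        --j;
      } else if (src == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // gap in read consuming ref[j-1]
      ++columns;
      state = (t & 4) ? 1 : 0;
      --j;
    } else {  // gap in ref consuming read[i-1]
      ++columns;
      state = (t & 8) ? 2 : 0;
      --i;
    }
  }
  out.rstart = w0 + i;
  out.rend = w0 + bi;
  out.qstart = j;
  out.qend = bj;
  out.score = best;
  out.matches = matches;
  out.columns = columns;
  return true;
}

inline bool encode_kmer(const char* s, int k, uint64_t& code) {
  uint64_t c = 0;
  for (int t = 0; t < k; ++t) {
    int b;
    switch (s[t]) {
      case 'A': b = 0; break;
      case 'C': b = 1; break;
      case 'G': b = 2; break;
      case 'T': b = 3; break;
      default: return false;
    }
    c = (c << 2) | (uint64_t)b;
  }
  code = c;
  return true;
}

struct Rec {
  int read_idx, ref_idx, rstart, rend, qstart, qend, matches, columns;
  char strand;
  double score;
};

}  // namespace

//' @useDynLib minicircler, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = ".sw_scan_batch")]]
DataFrame sw_scan_batch(CharacterVector reads, CharacterVector refs,
                        double match, double mismatch, double gap_open,
                        double gap_ext, double score_floor, int seed_k,
                        int min_seeds, double full_dp_max_cells,
                        int max_hits) {
  const Scoring sc{match, mismatch, gap_open, gap_ext};
  const int nref = refs.size(), nread = reads.size();
  std::vector<std::string> refseq(nref);
  for (int r = 0; r < nref; ++r) refseq[r] = as<std::string>(refs[r]);

  // k-mer index over all references: kmer -> sorted unique ref indices
  std::unordered_map<uint64_t, std::vector<int>> idx;
  for (int r = 0; r < nref; ++r) {
    const std::string& q = refseq[r];
    for (int p = 0; p + seed_k <= (int)q.size(); ++p) {
      uint64_t code;
      if (!encode_kmer(q.c_str() + p, seed_k, code)) continue;
      std::vector<int>& v = idx[code];
      if (v.empty() || v.back() != r) v.push_back(r);
    }
  }

  std::vector<Rec> out;
  std::vector<std::vector<int>> seedpos(nref);

  for (int ri = 0; ri < nread; ++ri) {
    if (ri % 64 == 0) Rcpp::checkUserInterrupt();
    const std::string fwd = as<std::string>(reads[ri]);
    const int L = (int)fwd.size();
    for (int sdir = 0; sdir < 2; ++sdir) {
      const std::string rd = sdir == 0 ? fwd : revcomp(fwd);
      for (int r = 0; r < nref; ++r) seedpos[r].clear();
      bool need_seeds = false;
      for (int r = 0; r < nref; ++r)
        if ((double)L * (double)refseq[r].size() > full_dp_max_cells)
          need_seeds = true;
      if (need_seeds) {
        for (int p = 0; p + seed_k <= L; ++p) {
          uint64_t code;
          if (!encode_kmer(rd.c_str() + p, seed_k, code)) continue;
          auto it = idx.find(code);
          if (it == idx.end()) continue;
          for (int r : it->second) {
            if (seedpos[r].empty() || seedpos[r].back() != p)
              seedpos[r].push_back(p);
          }
        }
      }
      for (int r = 0; r < nref; ++r) {
        const int n = (int)refseq[r].size();
        std::vector<std::pair<int, int>> segs;  // candidate read windows
        if ((double)L * (double)n <= full_dp_max_cells) {
          segs.emplace_back(0, L);
        } else {
          const std::vector<int>& sp = seedpos[r];
          if ((int)sp.size() < min_seeds) continue;
          const int margin = n / 4 + 50;
          int c0 = 0;
          for (size_t t = 1; t <= sp.size(); ++t) {
            if (t == sp.size() || sp[t] - sp[t - 1] > n) {
              if ((int)(t - c0) >= min_seeds) {
                int w0 = std::max(0, sp[c0] - margin);
                int w1 = std::min(L, sp[t - 1] + seed_k + margin);
                if (!segs.empty() && w0 <= segs.back().second) {
                  segs.back().second = std::max(segs.back().second, w1);
                } else {
                  segs.emplace_back(w0, w1);
                }
              }
              c0 = (int)t;
            }
          }
          if (segs.empty()) continue;
        }
        int nhits = 0;
        while (!segs.empty() && nhits < max_hits) {
          auto seg = segs.back();
          segs.pop_back();
          if (seg.second - seg.first < 20) continue;
          Hit h;
          if (!sw_window(rd, seg.first, seg.second, refseq[r], sc, h)) continue;
          if (h.score < score_floor) continue;
          ++nhits;
          Rec rec;
          rec.read_idx = ri;
          rec.ref_idx = r;
          if (sdir == 0) {
            rec.rstart = h.rstart;
            rec.rend = h.rend;
          } else {  // map back to forward-read coordinates
            rec.rstart = L - h.rend;
            rec.rend = L - h.rstart;
          }
          rec.qstart = h.qstart;
          rec.qend = h.qend;
          rec.matches = h.matches;
          rec.columns = h.columns;
          rec.score = h.score;
          rec.strand = sdir == 0 ? '+' : '-';
          out.push_back(rec);
          // mask the consumed read interval, recurse into flanks
          if (h.rstart - seg.first >= 30) segs.emplace_back(seg.first, h.rstart);
          if (seg.second - h.rend >= 30) segs.emplace_back(h.rend, seg.second);
        }
      }
    }
  }

  const int nr = (int)out.size();
  IntegerVector read_idx(nr), ref_idx(nr), rs(nr), re(nr), qs(nr), qe(nr),
      mt(nr), cl(nr);
  NumericVector score(nr), ident(nr);
  CharacterVector strand(nr);
  for (int t = 0; t < nr; ++t) {
    const Rec& v = out[t];
    read_idx[t] = v.read_idx + 1;
    ref_idx[t] = v.ref_idx + 1;
    rs[t] = v.rstart;
    re[t] = v.rend;
    qs[t] = v.qstart;
    qe[t] = v.qend;
    mt[t] = v.matches;
    cl[t] = v.columns;
    score[t] = v.score;
    ident[t] = v.columns > 0 ? (double)v.matches / v.columns : 0.0;
    strand[t] = std::string(1, v.strand);
  }
  return DataFrame::create(
      _["read_idx"] = read_idx, _["ref_idx"] = ref_idx, _["read_start"] = rs,
      _["read_end"] = re, _["ref_start"] = qs, _["ref_end"] = qe,
      _["strand"] = strand, _["identity"] = ident, _["score"] = score,
      _["matches"] = mt, _["columns"] = cl,
      _["stringsAsFactors"] = false);
}
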