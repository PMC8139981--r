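#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps, Gotoh recursion.
// A gap of length L costs gap_open + L * gap_ext.
// Returns the single best-scoring local alignment with a traceback so the
// caller can derive percent identity (matches / alignment columns) and the
// aligned span on either sequence.

struct AlnResult {
  int score = 0;
  int matches = 0;
  int aln_len = 0;        // alignment columns, gaps included
  int a_start = 0, a_end = -1;  // 0-based inclusive; empty if score == 0
  int b_start = 0, b_end = -1;
};

static AlnResult sw_core(const std::string& a, const std::string& b,
                         int match, int mismatch, int gap_open, int gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  AlnResult res;
  if (n == 0 || m == 0) return res;
  const int go = gap_open + gap_ext;  // cost of first gapped column
  const int NEG = -1000000000;

  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Fcol(m + 1, NEG);
  // traceback: tbH 0=stop,1=diag,2=from E (gap in a),3=from F (gap in b)
  std::vector<uint8_t> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbE((size_t)(n + 1) * (m + 1), 0); // 1 = extend
  std::vector<uint8_t> tbF((size_t)(n + 1) * (m + 1), 0); // 1 = extend

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int Erow = NEG;
    for (int j = 1; j <= m; ++j) {
      const size_t idx = (size_t)i * (m + 1) + j;
      // E: gap in a (consume b), horizontal
      int e_open = Hcur[j - 1] - go;
      int e_ext  = Erow - gap_ext;
      Erow = std::max(e_open, e_ext);
      tbE[idx] = (e_ext > e_open) ? 1 : 0;
      // F: gap in b (consume a), vertical
      int f_open = Hprev[j] - go;
      int f_ext  = Fcol[j] - gap_ext;
      Fcol[j] = std::max(f_open, f_ext);
      tbF[idx] = (f_ext > f_open) ? 1 : 0;
      // H
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      int diag = Hprev[j - 1] + s;
      int h = 0; uint8_t t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (Erow > h) { h = Erow; t = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; t = 3; }
      Hcur[j] = h; tbH[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  res.score = best;
  if (best == 0) return res;

  // traceback
  int i = bi, j = bj, state = 0; // 0 = in H
  res.a_end = bi - 1; res.b_end = bj - 1;
  while (i > 0 && j > 0) {
    const size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      uint8_t t = tbH[idx];
      if (t == 0) break;
      if (t == 1) {
        ++res.aln_len;
        if (a[i - 1] == b[j - 1]) ++res.matches;
        --i; --j;
      } else if (t == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // E: gap in a
      ++res.aln_len;
      uint8_t ext = tbE[idx];
      --j;
      if (!ext) state = 0;
    } else { // F: gap in b
      ++res.aln_len;
      uint8_t ext = tbF[idx];
      --i;
      if (!ext) state = 0;
    }
  }
  res.a_start = i; res.b_start = j;
  return res;
}

// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b,
                  int match = 1, int mismatch = -2,
                  int gap_open = 2, int gap_ext = 1) {
  AlnResult r = sw_core(a, b, match, mismatch, gap_open, gap_ext);
  return List::create(
    _["score"] = r.score, _["matches"] = r.matches, _["aln_len"] = r.aln_len,
    _["a_start"] = r.a_start + 1, _["a_end"] = r.a_end + 1,
    _["b_start"] = r.b_start + 1, _["b_end"] = r.b_end + 1);
}

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static void collect_kmers(const std::string& s, int k,
                          std::unordered_set<uint32_t>& out) {
  if ((int)s.size() < k) return;
  uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  uint32_t cur = 0; int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint32_t)b) & mask;
    if (++run >= k) out.insert(cur);
  }
}

// Number of positions of `a` whose k-mer occurs anywhere in `b`.
// Used as an admissible clustering prefilter: an alignment with identity
// >= c whose columns number L has at most (1-c)L non-matched columns, so
// its matched columns form runs contributing at least
// cL - ((1-c)L + 1)(k-1) seed positions in `a` that must occur in `b`.
// [[Rcpp::export]]
int cpp_seed_occurrences(std::string a, std::string b, int k = 8) {
  if (k < 1 || k > 16) stop("k must be in [1, 16]");
  std::unordered_set<uint32_t> kb;
  collect_kmers(b, k, kb);
  if ((int)a.size() < k || kb.empty()) return 0;
  uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  uint32_t cur = 0; int run = 0, n = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int bb = base2bits(a[i]);
    if (bb < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint32_t)bb) & mask;
    if (++run >= k && kb.count(cur)) ++n;
  }
  return n;
}

// ---- seeded read mapping -------------------------------------------------

struct Seed { int contig; int diag; };

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector reads_rc,
                        CharacterVector contigs,
                        int k = 13, int pad = 24,
                        int match = 1, int mismatch = -2,
                        int gap_open = 2, int gap_ext = 1) {
  if (k < 4 || k > 16) stop("k must be in [4, 16]");
  const int nc = contigs.size();
  // k-mer index over contigs: kmer -> (contig, pos) list
  std::unordered_map<uint32_t, std::vector<std::pair<int,int>>> index;
  std::vector<std::string> ctg(nc);
  uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  for (int c = 0; c < nc; ++c) {
    ctg[c] = as<std::string>(contigs[c]);
    const std::string& s = ctg[c];
    uint32_t cur = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; cur = 0; continue; }
      cur = ((cur << 2) | (uint32_t)b) & mask;
      if (++run >= k) index[cur].push_back({c, (int)i - k + 1});
    }
  }

  std::vector<int> o_read, o_contig, o_strand, o_score, o_matches, o_len,
    o_rs, o_re, o_cs, o_ce;

  const int nr = reads.size();
  for (int r = 0; r < nr; ++r) {
    // per (contig, strand): best alignment
    for (int strand = 0; strand < 2; ++strand) {
      std::string rd = as<std::string>(strand == 0 ? reads[r] : reads_rc[r]);
      const int L = (int)rd.size();
      if (L < k) continue;
      // seed diagonals per contig
      std::unordered_map<int, std::vector<int>> diags;
      uint32_t cur = 0; int run = 0;
      for (int i = 0; i < L; ++i) {
        int b = base2bits(rd[i]);
        if (b < 0) { run = 0; cur = 0; continue; }
        cur = ((cur << 2) | (uint32_t)b) & mask;
        if (run + 1 >= k) {
          auto it = index.find(cur);
          if (it != index.end())
            for (auto& pc : it->second)
              diags[pc.first].push_back(pc.second - (i - k + 1));
        }
        ++run;
      }
      for (auto& kv : diags) {
        int c = kv.first;
        std::vector<int>& ds = kv.second;
        std::sort(ds.begin(), ds.end());
        ds.erase(std::unique(ds.begin(), ds.end()), ds.end());
        // group diagonals within pad of each other into windows
        size_t i0 = 0;
        AlnResult bestr; bool have = false;
        while (i0 < ds.size()) {
          size_t i1 = i0;
          while (i1 + 1 < ds.size() && ds[i1 + 1] - ds[i1] <= pad) ++i1;
          int lo = std::max(0, ds[i0] - pad);
          int hi = std::min((int)ctg[c].size(), ds[i1] + L + pad);
          if (hi > lo) {
            std::string win = ctg[c].substr(lo, hi - lo);
            AlnResult a = sw_core(rd, win, match, mismatch, gap_open, gap_ext);
            a.b_start += lo; a.b_end += lo;
            if (!have || a.score > bestr.score) { bestr = a; have = true; }
          }
          i0 = i1 + 1;
        }
        if (have && bestr.score > 0) {
          o_read.push_back(r + 1);
          o_contig.push_back(c + 1);
          o_strand.push_back(strand == 0 ? 1 : -1);
          o_score.push_back(bestr.score);
          o_matches.push_back(bestr.matches);
          o_len.push_back(bestr.aln_len);
          o_rs.push_back(bestr.a_start + 1);
          o_re.push_back(bestr.a_end + 1);
          o_cs.push_back(bestr.b_start + 1);
          o_ce.push_back(bestr.b_end + 1);
        }
      }
    }
  }
  return DataFrame::create(
    _["read_idx"] = o_read, _["contig_idx"] = o_contig,
    _["strand"] = o_strand, _["score"] = o_score,
    _["matches"] = o_matches, _["aln_len"] = o_len,
    _["read_start"] = o_rs, _["read_end"] = o_re,
    _["contig_start"] = o_cs, _["contig_end"] = o_ce,
    _["stringsAsFactors"] = false);
}
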