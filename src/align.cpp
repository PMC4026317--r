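// Three-letter-space alignment engine: complete ungapped scan, seeded
// semi-global (end-to-end) and local affine-gap dynamic programming, and the
// four-letter asymmetric difference recount used to reject false positives.
//
// Conventions: all coordinates 0-based half-open; 'N' never matches anything
// (including another 'N') and scores as a mismatch; edit scripts are CIGAR
// strings over M/I/D/S where I consumes query, D consumes reference.

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cmath>
#include <cstdint>
#include <set>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static inline bool base_match(char a, char b) {
  return a == b && a != 'N';
}

// ---------------------------------------------------------------------------
// complete ungapped scan (Hamming distance with early exit)
// ---------------------------------------------------------------------------

static void scan_ungapped(const char* q, int L, const char* ref, int G,
                          int max_mm, std::vector<int>& pos,
                          std::vector<int>& mm) {
  if (L > G) return;
  for (int s = 0; s + L <= G; ++s) {
    int d = 0;
    const char* r = ref + s;
    int i = 0;
    for (; i < L; ++i) {
      if (!base_match(q[i], r[i])) {
        if (++d > max_mm) break;
      }
    }
    if (i == L) {
      pos.push_back(s);
      mm.push_back(d);
    }
  }
}

// exact occurrences of a seed (N in the seed matches nothing)
static void scan_exact(const char* q, int L, const char* ref, int G,
                       std::vector<int>& pos) {
  if (L > G) return;
  for (int s = 0; s + L <= G; ++s) {
    int i = 0;
    for (; i < L; ++i) {
      if (!base_match(q[i], ref[s + i])) break;
    }
    if (i == L) pos.push_back(s);
  }
}

// ---------------------------------------------------------------------------
// k-mer occurrence index over a reference sequence
//
// Seeds are looked up here instead of rescanning the genome for every query.
// Completeness is preserved: for a query split into (budget + 1) equal
// pieces, any alignment within the mismatch budget leaves at least one piece
// exact (pigeonhole), and the k-mer prefix of an exact piece is exact, so
// the candidate set is a superset of the true hit set; every candidate is
// then verified in full.
// ---------------------------------------------------------------------------

static const int KIDX = 12;

struct KmerIndex {
  std::unordered_map<uint32_t, std::vector<int> > occ;
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static void build_index(const std::string& ref, KmerIndex& idx) {
  int G = (int)ref.size();
  if (G < KIDX) return;
  uint32_t key = 0;
  int valid = 0;  // consecutive valid bases ending at i
  const uint32_t mask = (KIDX >= 16) ? 0xFFFFFFFFu : ((1u << (2 * KIDX)) - 1u);
  idx.occ.reserve((size_t)G);
  for (int i = 0; i < G; ++i) {
    int c = base_code(ref[i]);
    if (c < 0) {
      valid = 0;
      key = 0;
      continue;
    }
    key = ((key << 2) | (uint32_t)c) & mask;
    if (++valid >= KIDX) idx.occ[key].push_back(i - KIDX + 1);
  }
}

// occurrences of q[off .. off+KIDX); empty when the seed contains N
static const std::vector<int>* index_lookup(const KmerIndex& idx,
                                            const std::string& q, int off) {
  uint32_t key = 0;
  for (int i = 0; i < KIDX; ++i) {
    int c = base_code(q[off + i]);
    if (c < 0) return NULL;
    key = (key << 2) | (uint32_t)c;
  }
  std::unordered_map<uint32_t, std::vector<int> >::const_iterator it =
      idx.occ.find(key);
  return (it == idx.occ.end()) ? NULL : &it->second;
}

// Hamming verification of a candidate start; -1 when over budget/bounds
static int verify_at(const char* q, int L, const char* ref, int G, int start,
                     int budget) {
  if (start < 0 || start + L > G) return -1;
  int d = 0;
  for (int i = 0; i < L; ++i) {
    if (!base_match(q[i], ref[start + i])) {
      if (++d > budget) return -1;
    }
  }
  return d;
}

// complete ungapped search via pigeonhole seeds on the index; falls back to
// the plain scan for short queries
static void ungapped_indexed(const std::string& q, const std::string& ref,
                             const KmerIndex& idx, int budget,
                             std::vector<int>& pos, std::vector<int>& mm) {
  int L = (int)q.size();
  int G = (int)ref.size();
  int np = budget + 1;
  int plen = np > 0 ? L / np : 0;
  if (plen < KIDX || (int)ref.size() < KIDX) {
    scan_ungapped(q.c_str(), L, ref.c_str(), G, budget, pos, mm);
    return;
  }
  std::vector<int> cand;
  for (int p = 0; p < np; ++p) {
    int off = p * plen;
    const std::vector<int>* occ = index_lookup(idx, q, off);
    if (!occ) continue;
    for (size_t k = 0; k < occ->size(); ++k)
      cand.push_back((*occ)[k] - off);
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  for (size_t k = 0; k < cand.size(); ++k) {
    int d = verify_at(q.c_str(), L, ref.c_str(), G, cand[k], budget);
    if (d >= 0) {
      pos.push_back(cand[k]);
      mm.push_back(d);
    }
  }
}

// ---------------------------------------------------------------------------
// affine-gap dynamic programming over an extracted reference window
// ---------------------------------------------------------------------------

struct DpResult {
  bool found;
  int score;
  int ref_start;   // offset of first consumed reference base within window
  int mm;          // mismatching M columns
  int gaps;        // inserted + deleted bases
  int clip5, clip3;  // soft-clipped query bases (local mode)
  std::string cigar;
};

// rebuild query/reference column positions for a column vector
static void column_positions(const std::vector<char>& cols, int q0, int r0,
                             std::vector<int>& qp, std::vector<int>& rp) {
  qp.resize(cols.size());
  rp.resize(cols.size());
  int q = q0, r = r0;
  for (size_t c = 0; c < cols.size(); ++c) {
    qp[c] = q;
    rp[c] = r;
    if (cols[c] == 'M' || cols[c] == 'I') ++q;
    if (cols[c] == 'M' || cols[c] == 'D') ++r;
  }
}

// shift indel runs as far left as possible without changing the score
// (the displaced aligned column is unchanged because the swapped bases are
// equal). cols holds M/I/D columns only; q0/r0 are the query/window offsets
// of the first column.
static void left_align_indels(std::vector<char>& cols, const std::string& q,
                              const std::string& w, int q0, int r0) {
  bool changed = true;
  std::vector<int> qp, rp;
  int guard = 0;
  while (changed && ++guard < 10000) {
    changed = false;
    column_positions(cols, q0, r0, qp, rp);
    size_t a = 0;
    while (a < cols.size()) {
      if (cols[a] != 'I' && cols[a] != 'D') {
        ++a;
        continue;
      }
      char op = cols[a];
      size_t b = a;
      while (b < cols.size() && cols[b] == op) ++b;
      int k = (int)(b - a);
      if (a > 0 && cols[a - 1] == 'M') {
        bool ok;
        if (op == 'D') {
          // deleted bases w[rp[a] .. rp[a]+k); shifting needs
          // w[rp[a]-1] == w[rp[a]+k-1]
          ok = base_match(w[rp[a] - 1], w[rp[a] + k - 1]);
        } else {
          ok = base_match(q[qp[a] - 1], q[qp[a] + k - 1]);
        }
        if (ok) {
          // rotate: M,[run] -> [run],M
          for (size_t c = b - 1; c > a; --c) cols[c] = cols[c - 1];
          cols[a - 1] = op;
          cols[b - 1] = 'M';
          changed = true;
          break;  // positions stale; recompute
        }
      }
      a = b;
    }
  }
}

static std::string encode_cigar(const std::vector<char>& cols, int clip5,
                                int clip3) {
  std::string out;
  char cur = 0;
  int n = 0;
  std::vector<char> full;
  for (int i = 0; i < clip5; ++i) full.push_back('S');
  full.insert(full.end(), cols.begin(), cols.end());
  for (int i = 0; i < clip3; ++i) full.push_back('S');
  for (size_t i = 0; i < full.size(); ++i) {
    if (full[i] == cur) {
      ++n;
    } else {
      if (n > 0) out += std::to_string(n) + cur;
      cur = full[i];
      n = 1;
    }
  }
  if (n > 0) out += std::to_string(n) + cur;
  return out;
}

// semi-global: the full query is aligned end-to-end; reference prefix and
// suffix of the window are free. local=true gives Smith-Waterman with
// soft-clipped query ends.
static DpResult dp_window(const std::string& q, const std::string& w,
                          int match, int mismatch, int gap_open,
                          int gap_extend, bool local) {
  int L = (int)q.size(), W = (int)w.size();
  DpResult res;
  res.found = false;
  if (L == 0 || W == 0) return res;

  int cols = W + 1;
  std::vector<int> H((L + 1) * cols, NEG), I((L + 1) * cols, NEG),
      D((L + 1) * cols, NEG);
#define AT(m, i, j) m[(size_t)(i) * cols + (j)]

  for (int j = 0; j <= W; ++j) AT(H, 0, j) = 0;
  if (!local) {
    for (int i = 1; i <= L; ++i) {
      AT(I, i, 0) = gap_open + (i - 1) * gap_extend;
      AT(H, i, 0) = AT(I, i, 0);
    }
  } else {
    for (int i = 1; i <= L; ++i) AT(H, i, 0) = 0;
  }

  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= W; ++j) {
      int sc = base_match(q[i - 1], w[j - 1]) ? match : mismatch;
      int m = AT(H, i - 1, j - 1) + sc;
      int ii = std::max(AT(H, i - 1, j) + gap_open,
                        AT(I, i - 1, j) + gap_extend);
      int dd = std::max(AT(H, i, j - 1) + gap_open,
                        AT(D, i, j - 1) + gap_extend);
      AT(I, i, j) = ii;
      AT(D, i, j) = dd;
      int h = std::max(m, std::max(ii, dd));
      if (local && h < 0) h = 0;
      AT(H, i, j) = h;
    }
  }

  // locate the alignment end
  int ei = L, ej = 0, best = NEG;
  if (!local) {
    for (int j = 0; j <= W; ++j) {
      if (AT(H, L, j) > best) {
        best = AT(H, L, j);
        ej = j;
      }
    }
  } else {
    for (int i = 1; i <= L; ++i)
      for (int j = 1; j <= W; ++j)
        if (AT(H, i, j) > best) {
          best = AT(H, i, j);
          ei = i;
          ej = j;
        }
    if (best <= 0) return res;
  }

  // traceback
  std::vector<char> path;  // reversed
  int i = ei, j = ej;
  char state = 'H';
  while (true) {
    if (local && AT(H, i, j) == 0 && state == 'H') break;
    if (!local && i == 0) break;
    if (state == 'H') {
      int v = AT(H, i, j);
      int sc = (i > 0 && j > 0)
                   ? (base_match(q[i - 1], w[j - 1]) ? match : mismatch)
                   : NEG;
      if (i > 0 && j > 0 && v == AT(H, i - 1, j - 1) + sc) {
        path.push_back('M');
        --i;
        --j;
      } else if (j > 0 && v == AT(D, i, j)) {
        state = 'D';
      } else if (i > 0 && v == AT(I, i, j)) {
        state = 'I';
      } else if (!local && j == 0 && v == AT(I, i, j)) {
        state = 'I';
      } else {
        stop("internal error: dynamic-programming traceback failed");
      }
    } else if (state == 'D') {
      path.push_back('D');
      bool open = (AT(D, i, j) == AT(H, i, j - 1) + gap_open);
      --j;
      if (open) state = 'H';
    } else {  // 'I'
      path.push_back('I');
      bool open = (AT(I, i, j) == AT(H, i - 1, j) + gap_open);
      --i;
      if (open) state = 'H';
    }
  }
#undef AT

  int qstart = i, rstart = j;
  std::vector<char> fwd(path.rbegin(), path.rend());
  left_align_indels(fwd, q, w, qstart, rstart);

  // trailing/leading deletions carry no information in free-end alignment;
  // they can appear only through left-shifting at window edges -- trim them.
  while (!fwd.empty() && fwd.front() == 'D') {
    fwd.erase(fwd.begin());
    ++rstart;
  }
  while (!fwd.empty() && fwd.back() == 'D') fwd.pop_back();

  res.found = true;
  res.score = best;
  res.ref_start = rstart;
  res.clip5 = local ? qstart : 0;
  res.clip3 = local ? (L - ei) : 0;
  res.mm = 0;
  res.gaps = 0;
  int qq = qstart, rr = rstart;
  for (size_t c = 0; c < fwd.size(); ++c) {
    if (fwd[c] == 'M') {
      if (!base_match(q[qq], w[rr])) ++res.mm;
      ++qq;
      ++rr;
    } else if (fwd[c] == 'I') {
      ++res.gaps;
      ++qq;
    } else {
      ++res.gaps;
      ++rr;
    }
  }
  res.cigar = encode_cigar(fwd, res.clip5, res.clip3);
  return res;
}

// [[Rcpp::export]]
List cpp_dp_window(std::string query, std::string window, int match,
                   int mismatch, int gap_open, int gap_extend, bool local) {
  DpResult r = dp_window(query, window, match, mismatch, gap_open, gap_extend,
                         local);
  if (!r.found) return List::create(Named("found") = false);
  return List::create(
      Named("found") = true, Named("score") = r.score,
      Named("ref_start") = r.ref_start, Named("cigar") = r.cigar,
      Named("mm3") = r.mm, Named("gaps") = r.gaps, Named("clip5") = r.clip5,
      Named("clip3") = r.clip3);
}

// ---------------------------------------------------------------------------
// batch alignment over a converted genome
// ---------------------------------------------------------------------------

struct Hit {
  int qidx, ref, start, mm, gaps, score;
  std::string cigar;
};

static bool hit_order(const Hit& a, const Hit& b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.mm != b.mm) return a.mm < b.mm;
  if (a.ref != b.ref) return a.ref < b.ref;
  if (a.start != b.start) return a.start < b.start;
  return a.cigar < b.cigar;
}

static void seed_anchors(const std::string& q, const std::string& ref,
                         const KmerIndex& idx, int n_pieces, int min_seed,
                         std::set<int>& anchors) {
  int L = (int)q.size();
  int G = (int)ref.size();
  int np = n_pieces;
  if (L / np < min_seed) np = std::max(1, L / min_seed);
  int slen = L / np;
  bool use_index = slen >= KIDX && G >= KIDX;
  for (int p = 0; p < np; ++p) {
    int off = p * slen;
    if (use_index) {
      // the k-mer prefix of an exact piece is exact: anchor superset
      const std::vector<int>* occ = index_lookup(idx, q, off);
      if (occ)
        for (size_t k = 0; k < occ->size(); ++k)
          anchors.insert((*occ)[k] - off);
    } else {
      int len = (p == np - 1) ? (L - off) : slen;
      std::vector<int> occ;
      scan_exact(q.c_str() + off, len, ref.c_str(), G, occ);
      for (size_t k = 0; k < occ.size(); ++k) anchors.insert(occ[k] - off);
    }
  }
}

// mode: 0 = ungapped, 1 = e2e (two-step), 2 = local
// [[Rcpp::export]]
List cpp_align_batch(CharacterVector queries, CharacterVector ref_seqs,
                     int mode, int max_mm, int step1_mm, int match,
                     int mismatch, int gap_open, int gap_extend,
                     double dp_trigger_frac, int band_width, int max_hits,
                     int n_pieces, int min_seed, double max_clip_frac) {
  int nq = queries.size(), nr = ref_seqs.size();
  std::vector<std::string> refs(nr);
  for (int r = 0; r < nr; ++r) refs[r] = as<std::string>(ref_seqs[r]);

  // one shared occurrence index per reference sequence for the whole batch
  std::vector<KmerIndex> idx(nr);
  for (int r = 0; r < nr; ++r) build_index(refs[r], idx[r]);

  std::vector<Hit> out;
  std::vector<int> truncated_q;

  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(queries[qi]);
    int L = (int)q.size();
    if (L == 0) continue;
    double trigger = dp_trigger_frac * L * match;
    std::vector<Hit> hits;

    if (mode == 0 || mode == 1) {
      int budget = (mode == 0) ? max_mm : step1_mm;
      for (int r = 0; r < nr; ++r) {
        std::vector<int> pos, mm;
        ungapped_indexed(q, refs[r], idx[r], budget, pos, mm);
        for (size_t k = 0; k < pos.size(); ++k) {
          Hit h;
          h.qidx = qi + 1;
          h.ref = r + 1;
          h.start = pos[k];
          h.mm = mm[k];
          h.gaps = 0;
          h.score = (L - mm[k]) * match + mm[k] * mismatch;
          h.cigar = std::to_string(L) + "M";
          hits.push_back(h);
        }
      }
    }

    if ((mode == 1 && hits.empty()) || mode == 2) {
      bool local = (mode == 2);
      for (int r = 0; r < nr; ++r) {
        int G = (int)refs[r].size();
        std::set<int> anchors;
        seed_anchors(q, refs[r], idx[r], n_pieces, min_seed, anchors);
        std::set<std::pair<int, std::string> > seen;
        for (std::set<int>::iterator it = anchors.begin();
             it != anchors.end(); ++it) {
          int ws = std::max(0, *it - band_width);
          int we = std::min(G, *it + L + band_width);
          if (we - ws < 1) continue;
          DpResult d = dp_window(q, refs[r].substr(ws, we - ws), match,
                                 mismatch, gap_open, gap_extend, local);
          if (!d.found || d.score < trigger) continue;
          if (local &&
              (d.clip5 + d.clip3) > max_clip_frac * L)
            continue;
          int start = ws + d.ref_start;
          std::pair<int, std::string> key(start, d.cigar);
          if (seen.count(key)) continue;
          seen.insert(key);
          Hit h;
          h.qidx = qi + 1;
          h.ref = r + 1;
          h.start = start;
          h.mm = d.mm;
          h.gaps = d.gaps;
          h.score = d.score;
          h.cigar = d.cigar;
          hits.push_back(h);
        }
      }
    }

    std::sort(hits.begin(), hits.end(), hit_order);
    bool trunc = (max_hits > 0 && (int)hits.size() > max_hits);
    if (trunc) hits.resize(max_hits);
    if (trunc) truncated_q.push_back(qi + 1);
    out.insert(out.end(), hits.begin(), hits.end());
  }

  int n = (int)out.size();
  IntegerVector qidx(n), ref(n), start(n), mm3(n), gaps(n), score(n);
  CharacterVector cigar(n);
  for (int k = 0; k < n; ++k) {
    qidx[k] = out[k].qidx;
    ref[k] = out[k].ref;
    start[k] = out[k].start;
    mm3[k] = out[k].mm;
    gaps[k] = out[k].gaps;
    score[k] = out[k].score;
    cigar[k] = out[k].cigar;
  }
  return List::create(Named("qidx") = qidx, Named("ref") = ref,
                      Named("start") = start, Named("cigar") = cigar,
                      Named("mm3") = mm3, Named("gaps") = gaps,
                      Named("score") = score,
                      Named("truncated") = wrap(truncated_q));
}

// ---------------------------------------------------------------------------
// four-letter asymmetric difference recount
// ---------------------------------------------------------------------------

// reads are the queries exactly as aligned (reverse-complemented for the
// reverse-complement passes) in the ORIGINAL four-letter alphabet; refs are
// the unconverted forward reference sequences. In C2T space read T over
// genome C is a match; in G2A space read A over genome G is a match.
// [[Rcpp::export]]
IntegerVector cpp_count_diff4(CharacterVector reads, CharacterVector refs,
                              IntegerVector ref_idx, IntegerVector starts,
                              CharacterVector cigars, LogicalVector c2t) {
  int n = reads.size();
  int nr = refs.size();
  std::vector<std::string> R(nr);
  for (int r = 0; r < nr; ++r) R[r] = as<std::string>(refs[r]);
  IntegerVector out(n);

  for (int k = 0; k < n; ++k) {
    std::string rd = as<std::string>(reads[k]);
    std::string cg = as<std::string>(cigars[k]);
    int ri = ref_idx[k] - 1;
    if (ri < 0 || ri >= nr) stop("reference index out of range");
    const std::string& ref = R[ri];
    bool space_c2t = c2t[k];
    size_t qp = 0;
    long rp = starts[k];
    int diff = 0;
    size_t i = 0;
    while (i < cg.size()) {
      long num = 0;
      while (i < cg.size() && isdigit(cg[i])) num = num * 10 + (cg[i++] - '0');
      if (i >= cg.size() || num <= 0)
        stop("malformed CIGAR string '%s'", cg.c_str());
      char op = cg[i++];
      if (op == 'M') {
        if (qp + num > rd.size() || rp + num > (long)ref.size() || rp < 0)
          stop("edit script inconsistent with sequences (CIGAR '%s')",
               cg.c_str());
        for (long t = 0; t < num; ++t) {
          char a = rd[qp + t], b = ref[rp + t];
          bool ok = base_match(a, b) ||
                    (space_c2t && a == 'T' && b == 'C') ||
                    (!space_c2t && a == 'A' && b == 'G');
          if (!ok) ++diff;
        }
        qp += num;
        rp += num;
      } else if (op == 'I') {
        if (qp + num > rd.size())
          stop("edit script inconsistent with sequences (CIGAR '%s')",
               cg.c_str());
        diff += (int)num;
        qp += num;
      } else if (op == 'D') {
        if (rp + num > (long)ref.size())
          stop("edit script inconsistent with sequences (CIGAR '%s')",
               cg.c_str());
        diff += (int)num;
        rp += num;
      } else if (op == 'S') {
        if (qp + num > rd.size())
          stop("edit script inconsistent with sequences (CIGAR '%s')",
               cg.c_str());
        qp += num;
      } else {
        stop("unsupported CIGAR operation '%c'", op);
      }
    }
    if (qp != rd.size())
      stop("edit script does not consume the full query (CIGAR '%s')",
           cg.c_str());
    out[k] = diff;
  }
  return out;
}
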