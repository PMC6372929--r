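#include <Rcpp.h>
#include <cstdint>
#include <deque>
#include <string>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------- basic sequence utilities ----------

static inline int b2i(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N and anything else: never a match
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); i++) out[i] = comp(out[i]);
  return out;
}

// ---------- minimizer sketch (canonical k-mers, invertible hash) ----------

static inline uint64_t hash64(uint64_t key, uint64_t mask) {
  key = (~key + (key << 21)) & mask;
  key = key ^ (key >> 24);
  key = ((key + (key << 3)) + (key << 8)) & mask;
  key = key ^ (key >> 14);
  key = ((key + (key << 2)) + (key << 4)) & mask;
  key = key ^ (key >> 28);
  key = (key + (key << 31)) & mask;
  return key;
}

struct Mini {
  uint64_t h;
  int pos;   // 0-based start of the k-mer on the forward sequence
  int rc;    // 1 if the reverse-complement k-mer was the canonical one
};

// windowed minima of hashed canonical k-mers; k-mers containing non-ACGT
// bases or equal to their own reverse complement are skipped
static void sketch(const std::string& s, int k, int w, std::vector<Mini>& out) {
  out.clear();
  int n = (int)s.size();
  if (n < k || k < 1 || w < 1) return;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int m = n - k + 1;
  std::vector<uint64_t> hv(m, 0);
  std::vector<char> valid(m, 0), strand(m, 0);
  uint64_t f = 0, r = 0;
  int l = 0;
  for (int i = 0; i < n; i++) {
    int c = b2i(s[i]);
    if (c < 0) { l = 0; f = 0; r = 0; }
    else {
      f = ((f << 2) | (uint64_t)c) & mask;
      r = (r >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      l++;
    }
    if (i >= k - 1 && l >= k) {
      int idx = i - k + 1;
      if (f < r)      { hv[idx] = hash64(f, mask); strand[idx] = 0; valid[idx] = 1; }
      else if (r < f) { hv[idx] = hash64(r, mask); strand[idx] = 1; valid[idx] = 1; }
    }
  }
  std::deque<int> dq;  // indices of valid k-mers, hashes increasing
  std::vector<char> taken(m, 0);
  for (int i = 0; i < m; i++) {
    if (valid[i]) {
      while (!dq.empty() && hv[dq.back()] >= hv[i]) dq.pop_back();
      dq.push_back(i);
    }
    while (!dq.empty() && dq.front() <= i - w) dq.pop_front();
    if (i >= w - 1 && !dq.empty()) {
      int sel = dq.front();
      if (!taken[sel]) {
        taken[sel] = 1;
        out.push_back({hv[sel], sel, strand[sel]});
      }
    }
  }
}

// all k-mer hashes of a sequence (position, hash, canonical strand,
// validity); lets tests re-derive the windowed minima independently
// [[Rcpp::export]]
DataFrame kmer_hashes_cpp(std::string s, int k) {
  int n = (int)s.size();
  int m = std::max(0, n - k + 1);
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  NumericVector hv(m);
  IntegerVector pos(m), rc(m), valid(m);
  uint64_t f = 0, r = 0;
  int l = 0;
  for (int i = 0; i < n; i++) {
    int c = b2i(s[i]);
    if (c < 0) { l = 0; f = 0; r = 0; }
    else {
      f = ((f << 2) | (uint64_t)c) & mask;
      r = (r >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      l++;
    }
    if (i >= k - 1) {
      int idx = i - k + 1;
      pos[idx] = idx;
      if (l >= k && f != r) {
        uint64_t h = (f < r) ? hash64(f, mask) : hash64(r, mask);
        hv[idx] = (double)(h & ((1ULL << 52) - 1));
        rc[idx] = (f < r) ? 0 : 1;
        valid[idx] = 1;
      }
    }
  }
  return DataFrame::create(_["pos"] = pos, _["hash"] = hv, _["rc"] = rc,
                           _["valid"] = valid);
}

// [[Rcpp::export]]
DataFrame sketch_cpp(std::string seq, int k, int w) {
  std::vector<Mini> mm;
  sketch(seq, k, w, mm);
  int n = (int)mm.size();
  IntegerVector pos(n), rc(n);
  NumericVector h(n);
  for (int i = 0; i < n; i++) {
    pos[i] = mm[i].pos; rc[i] = mm[i].rc; h[i] = (double)(mm[i].h & ((1ULL << 52) - 1));
  }
  return DataFrame::create(_["pos"] = pos, _["hash"] = h, _["rc"] = rc);
}

// ---------- minimizer index over a reference set ----------

struct MiniIndex {
  int k, w;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // value packs (ref << 33) | (pos << 1) | rc
  std::unordered_map<uint64_t, std::vector<uint64_t>> table;
  std::vector<int> n_mini;
};

// [[Rcpp::export]]
SEXP build_index_cpp(CharacterVector seqs, CharacterVector names, int k, int w) {
  MiniIndex* idx = new MiniIndex();
  idx->k = k; idx->w = w;
  std::vector<Mini> mm;
  for (int i = 0; i < seqs.size(); i++) {
    std::string s = as<std::string>(seqs[i]);
    idx->seqs.push_back(s);
    idx->names.push_back(as<std::string>(names[i]));
    sketch(s, k, w, mm);
    idx->n_mini.push_back((int)mm.size());
    for (const Mini& m : mm)
      idx->table[m.h].push_back(((uint64_t)i << 33) | ((uint64_t)m.pos << 1) | (uint64_t)m.rc);
  }
  XPtr<MiniIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
IntegerVector index_n_minimizers_cpp(SEXP xp) {
  XPtr<MiniIndex> p(xp);
  return wrap(p->n_mini);
}

// ---------- affine-gap local alignment ----------

// Scoring convention: match > 0; mismatch, gap_open, gap_extend given as
// negative penalties; a gap of length g costs gap_open + g * gap_extend.
// Non-ACGT bases are scored as mismatches and never counted as matches.

struct Aln {
  int score = 0;
  int qs = 0, qe = 0, ts = 0, te = 0;  // 0-based half-open
  int nmatch = 0, blocklen = 0;
  bool ok = false;
};

static const uint8_t TB_STOP = 0, TB_DIAG = 1, TB_E = 2, TB_F = 3;

// banded local DP on q[qlo,qhi) x t[tlo,thi) restricted to diagonals
// (global t - global q) in [d0 - band, d0 + band]; zdrop terminates row
// sweep once the running best falls zdrop below the global best.
static Aln band_align(const std::string& q, const std::string& t,
                      int qlo, int qhi, int tlo, int thi,
                      int d0, int band,
                      int ma, int mi, int go, int ge, int zdrop) {
  Aln res;
  int Lq = qhi - qlo, Lt = thi - tlo;
  if (Lq <= 0 || Lt <= 0) return res;
  const int NEG = -(1 << 28);
  // relative diagonal rel = tj - qi (local coords); allowed window:
  int dshift = tlo - qlo;
  int dlo = (d0 - band) - dshift, dhi = (d0 + band) - dshift;
  if (dhi < -(Lq - 1) || dlo > Lt - 1) return res;
  int W = dhi - dlo + 1;
  std::vector<int> H(W, NEG), E(W, NEG), F(W, NEG), Hprev(W, NEG), Fprev(W, NEG);
  std::vector<uint8_t> tb((size_t)Lq * W, 0);  // bits 0-1: H src; bit 2: E ext; bit 3: F ext
  int best = 0, bqi = -1, bo = -1;
  for (int qi = 0; qi < Lq; qi++) {
    std::swap(H, Hprev); std::swap(F, Fprev);
    std::fill(H.begin(), H.end(), NEG);
    std::fill(E.begin(), E.end(), NEG);
    std::fill(F.begin(), F.end(), NEG);
    int jmin = std::max(0, qi + dlo), jmax = std::min(Lt - 1, qi + dhi);
    if (jmin > jmax) continue;
    int rowbest = NEG;
    char qc = q[qlo + qi];
    int qv = b2i(qc);
    for (int tj = jmin; tj <= jmax; tj++) {
      int o = tj - qi - dlo;
      size_t cell = (size_t)qi * W + o;
      uint8_t code = 0;
      // E: gap consuming target, from (qi, tj-1) = same row, offset o-1
      int e = NEG;
      if (o - 1 >= 0) {
        int eh = (H[o - 1] > NEG / 2) ? H[o - 1] + go + ge : NEG;
        int ee = (E[o - 1] > NEG / 2) ? E[o - 1] + ge : NEG;
        if (ee > eh) { e = ee; code |= 4; } else e = eh;
      }
      E[o] = e;
      // F: gap consuming query, from (qi-1, tj) = prev row, offset o+1
      int f = NEG;
      if (qi > 0 && o + 1 < W) {
        int fh = (Hprev[o + 1] > NEG / 2) ? Hprev[o + 1] + go + ge : NEG;
        int fe = (Fprev[o + 1] > NEG / 2) ? Fprev[o + 1] + ge : NEG;
        if (fe > fh) { f = fe; code |= 8; } else f = fh;
      }
      F[o] = f;
      // H
      int tv = b2i(t[tlo + tj]);
      int s = (qv >= 0 && qv == tv) ? ma : mi;
      int diag = 0;  // start a new local alignment
      if (qi > 0 && tj > 0) {
        // (qi-1, tj-1): prev row, same offset
        if (Hprev[o] > NEG / 2) diag = std::max(0, Hprev[o]);
      }
      int h = diag + s;
      uint8_t src = TB_DIAG;
      if (e > h) { h = e; src = TB_E; }
      if (f > h) { h = f; src = TB_F; }
      if (h <= 0) { h = 0; src = TB_STOP; }
      H[o] = h;
      tb[cell] = (uint8_t)(code | src);
      if (h > rowbest) rowbest = h;
      if (h > best) { best = h; bqi = qi; bo = o; }
    }
    if (zdrop > 0 && rowbest < best - zdrop && qi > bqi) break;
  }
  if (best <= 0) return res;
  // traceback
  int qi = bqi, tj = bqi + dlo + bo;
  int nmatch = 0, blocklen = 0;
  int eq = qi + 1, et = tj + 1;
  bool inE = false, inF = false;
  while (qi >= 0 && tj >= 0) {
    int o = tj - qi - dlo;
    if (o < 0 || o >= W) break;
    uint8_t code = tb[(size_t)qi * W + o];
    uint8_t src = code & 3;
    if (inE) {
      blocklen++;
      bool ext = (code & 4) != 0;
      tj--; if (!ext) inE = false;
      continue;
    }
    if (inF) {
      blocklen++;
      bool ext = (code & 8) != 0;
      qi--; if (!ext) inF = false;
      continue;
    }
    if (src == TB_STOP) break;
    if (src == TB_DIAG) {
      blocklen++;
      int qv = b2i(q[qlo + qi]), tv = b2i(t[tlo + tj]);
      if (qv >= 0 && qv == tv) nmatch++;
      qi--; tj--;
      // check whether the previous H restarted at 0
      if (qi >= 0 && tj >= 0) {
        int oo = tj - qi - dlo;
        if (oo < 0 || oo >= W) break;
        // peek: if previous cell's H is a fresh start we will hit TB_STOP there
      } else break;
    } else if (src == TB_E) { inE = true; }
    else { inF = true; }
  }
  res.ok = true;
  res.score = best;
  res.qs = qlo + qi + 1; res.qe = qlo + eq;
  res.ts = tlo + tj + 1; res.te = tlo + et;
  res.nmatch = nmatch; res.blocklen = blocklen;
  return res;
}

// hmm: the traceback above stops one step late for TB_STOP after diag; handled
// by the break on TB_STOP before consuming the cell.

// full Smith-Waterman, O(|q||t|) with traceback; reference implementation
static Aln sw_full(const std::string& q, const std::string& t,
                   int ma, int mi, int go, int ge) {
  Aln res;
  int Lq = (int)q.size(), Lt = (int)t.size();
  if (Lq == 0 || Lt == 0) return res;
  const int NEG = -(1 << 28);
  std::vector<int> H(Lt + 1, 0), E(Lt + 1, NEG), Hprev(Lt + 1, 0), F(Lt + 1, NEG);
  std::vector<uint8_t> tb((size_t)Lq * Lt, 0);
  int best = 0, bqi = -1, btj = -1;
  for (int qi = 0; qi < Lq; qi++) {
    std::swap(H, Hprev);
    H[0] = 0;
    int qv = b2i(q[qi]);
    int Erow = NEG;  // E carried along the row
    for (int tj = 0; tj < Lt; tj++) {
      uint8_t code = 0;
      int eh = H[tj] /* H[qi][tj-1] is current row, index tj */ ;
      // careful: H vector indexed 1..Lt with offset; use tj index for t position tj-1
      // we store H[tj+1] for target prefix length tj+1
      eh = (tj > 0) ? H[tj] : 0;  // H of (qi, tj-1); for tj==0 no E
      int e = NEG;
      if (tj > 0) {
        int ehh = eh + go + ge;
        int eee = (Erow > NEG / 2) ? Erow + ge : NEG;
        if (eee > ehh) { e = eee; code |= 4; } else e = ehh;
      }
      Erow = e;
      int f = NEG;
      {
        int fh = Hprev[tj + 1] + go + ge;
        int fe = (F[tj + 1] > NEG / 2) ? F[tj + 1] + ge : NEG;
        if (fe > fh) { f = fe; code |= 8; } else f = fh;
      }
      F[tj + 1] = f;
      int tv = b2i(t[tj]);
      int s = (qv >= 0 && qv == tv) ? ma : mi;
      int h = Hprev[tj] + s;  // Hprev[tj] == H(qi-1, tj-1), zero-floored already
      uint8_t src = TB_DIAG;
      if (e > h) { h = e; src = TB_E; }
      if (f > h) { h = f; src = TB_F; }
      if (h <= 0) { h = 0; src = TB_STOP; }
      H[tj + 1] = h;
      tb[(size_t)qi * Lt + tj] = (uint8_t)(code | src);
      if (h > best) { best = h; bqi = qi; btj = tj; }
    }
  }
  if (best <= 0) return res;
  int qi = bqi, tj = btj, nmatch = 0, blocklen = 0;
  int eq = qi + 1, et = tj + 1;
  bool inE = false, inF = false;
  while (qi >= 0 && tj >= 0) {
    uint8_t code = tb[(size_t)qi * Lt + tj];
    uint8_t src = code & 3;
    if (inE) { blocklen++; bool ext = (code & 4) != 0; tj--; if (!ext) inE = false; continue; }
    if (inF) { blocklen++; bool ext = (code & 8) != 0; qi--; if (!ext) inF = false; continue; }
    if (src == TB_STOP) break;
    if (src == TB_DIAG) {
      blocklen++;
      int qv = b2i(q[qi]), tv = b2i(t[tj]);
      if (qv >= 0 && qv == tv) nmatch++;
      qi--; tj--;
      if (qi < 0 || tj < 0) break;
      // a zero-floored diagonal start is encoded as TB_STOP in the previous cell
    } else if (src == TB_E) inE = true;
    else inF = true;
  }
  res.ok = true; res.score = best;
  res.qs = qi + 1; res.qe = eq; res.ts = tj + 1; res.te = et;
  res.nmatch = nmatch; res.blocklen = blocklen;
  return res;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string target,
                  int match, int mismatch, int gap_open, int gap_extend) {
  Aln a = sw_full(query, target, match, mismatch, gap_open, gap_extend);
  return List::create(
    _["as_score"] = a.ok ? a.score : 0,
    _["query_start"] = a.qs, _["query_end"] = a.qe,
    _["target_start"] = a.ts, _["target_end"] = a.te,
    _["n_match"] = a.nmatch, _["block_length"] = a.blocklen,
    _["found"] = a.ok);
}

// ---------- read mapping: seed, chain, extend ----------

struct Chain {
  int ref, strand;           // strand: 0 forward, 1 reverse
  int n;                     // anchor support (distinct read positions)
  int qmin, qmax, tmin, tmax;
  int dmed, dmin, dmax;      // anchor diagonals (t - q, oriented read coords)
};

struct Hit {
  int ref, strand;
  int read_start, read_end, ref_start, ref_end;
  int blocklen, nmatch, score;
};

static void collect_chains(const MiniIndex& idx, const std::string& read,
                           int diag_gap, int min_anchors, std::vector<Chain>& chains) {
  chains.clear();
  std::vector<Mini> mm;
  sketch(read, idx.k, idx.w, mm);
  int qlen = (int)read.size(), k = idx.k;
  // anchors grouped by (ref, strand)
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> groups;  // (q', t)
  for (const Mini& m : mm) {
    auto it = idx.table.find(m.h);
    if (it == idx.table.end()) continue;
    for (uint64_t v : it->second) {
      int ref = (int)(v >> 33);
      int tpos = (int)((v >> 1) & ((1ULL << 32) - 1));
      int trc = (int)(v & 1);
      int strand = m.rc ^ trc;
      int qp = strand ? (qlen - k - m.pos) : m.pos;
      groups[((uint64_t)ref << 1) | (uint64_t)strand].push_back({qp, tpos});
    }
  }
  for (auto& kv : groups) {
    int ref = (int)(kv.first >> 1), strand = (int)(kv.first & 1);
    auto& a = kv.second;
    std::sort(a.begin(), a.end(), [](const std::pair<int,int>& x, const std::pair<int,int>& y) {
      return (x.second - x.first) < (y.second - y.first);
    });
    size_t i = 0;
    while (i < a.size()) {
      size_t j = i + 1;
      while (j < a.size() &&
             (a[j].second - a[j].first) - (a[j-1].second - a[j-1].first) <= diag_gap) j++;
      // cluster [i, j)
      Chain c; c.ref = ref; c.strand = strand;
      c.qmin = 1 << 30; c.qmax = -1; c.tmin = 1 << 30; c.tmax = -1;
      std::vector<int> qs, ds;
      for (size_t x = i; x < j; x++) {
        c.qmin = std::min(c.qmin, a[x].first);
        c.qmax = std::max(c.qmax, a[x].first);
        c.tmin = std::min(c.tmin, a[x].second);
        c.tmax = std::max(c.tmax, a[x].second);
        qs.push_back(a[x].first);
        ds.push_back(a[x].second - a[x].first);
      }
      std::sort(qs.begin(), qs.end());
      c.n = (int)(std::unique(qs.begin(), qs.end()) - qs.begin());
      std::sort(ds.begin(), ds.end());
      c.dmed = ds[ds.size() / 2];
      c.dmin = ds.front(); c.dmax = ds.back();
      if (c.n >= min_anchors) chains.push_back(c);
      i = j;
    }
  }
}

static bool hit_before(const Hit& a, const Hit& b, const std::vector<std::string>& names) {
  if (a.score != b.score) return a.score > b.score;
  if (names[a.ref] != names[b.ref]) return names[a.ref] < names[b.ref];
  return a.ref_start < b.ref_start;
}

static void map_one(const MiniIndex& idx, const std::string& read, List par,
                    std::vector<Hit>& hits) {
  hits.clear();
  int ma = par["match"], mi = par["mismatch"], go = par["gap_open"], ge = par["gap_extend"];
  int zdrop = par["z_drop"], band = par["band"], max_sec = par["max_secondary"];
  int min_anchors = par["min_chain_anchors"], min_as = par["min_as"];
  double chain_frac = par["chain_frac"];
  int diag_gap = par["diag_gap"], flank = par["flank"], max_extend = par["max_extend"];
  int qlen = (int)read.size();
  if (qlen < idx.k) return;
  std::vector<Chain> chains;
  collect_chains(idx, read, diag_gap, min_anchors, chains);
  if (chains.empty()) return;
  std::sort(chains.begin(), chains.end(), [](const Chain& x, const Chain& y) {
    if (x.n != y.n) return x.n > y.n;
    if (x.ref != y.ref) return x.ref < y.ref;
    if (x.strand != y.strand) return x.strand < y.strand;
    return x.tmin < y.tmin;
  });
  std::string rc;
  bool have_rc = false;
  int n_ext = 0;
  // region-aware chain filtering: a chain opening a new read region is
  // always extended (chimeric halves occupy disjoint intervals); within a
  // region, only chains close to the region's best are worth extending
  std::vector<std::pair<int,int>> ext_span;  // read spans of accepted chains
  std::vector<int> ext_n;
  for (const Chain& c : chains) {
    if (n_ext >= max_extend) break;
    int span_lo = c.strand ? (qlen - (c.qmax + idx.k)) : c.qmin;
    int span_hi = c.strand ? (qlen - c.qmin) : (c.qmax + idx.k);
    int region_best = 0;
    for (size_t i = 0; i < ext_span.size(); i++) {
      int ov = std::min(span_hi, ext_span[i].second) -
               std::max(span_lo, ext_span[i].first);
      int len = span_hi - span_lo;
      if (len > 0 && ov > len / 2) region_best = std::max(region_best, ext_n[i]);
    }
    if (region_best > 0 && c.n < chain_frac * region_best) continue;
    ext_span.push_back({span_lo, span_hi});
    ext_n.push_back(c.n);
    n_ext++;
    const std::string& tgt = idx.seqs[c.ref];
    int tlen = (int)tgt.size();
    const std::string* qp;
    if (c.strand) {
      if (!have_rc) { rc = revcomp_cpp(read); have_rc = true; }
      qp = &rc;
    } else qp = &read;
    int k = idx.k;
    int qlo = std::max(0, c.qmin - flank);
    int qhi = std::min(qlen, c.qmax + k + flank);
    int tlo = std::max(0, c.tmin - (c.qmin - qlo) - band);
    int thi = std::min(tlen, c.tmax + k + (qhi - (c.qmax + k)) + band);
    int band_eff = band + (c.dmax - c.dmin + 1) / 2;
    Aln a = band_align(*qp, tgt, qlo, qhi, tlo, thi, c.dmed, band_eff,
                       ma, mi, go, ge, zdrop);
    if (!a.ok || a.score < min_as) continue;
    Hit h;
    h.ref = c.ref; h.strand = c.strand;
    h.ref_start = a.ts; h.ref_end = a.te;
    h.blocklen = a.blocklen; h.nmatch = a.nmatch; h.score = a.score;
    if (c.strand) { h.read_start = qlen - a.qe; h.read_end = qlen - a.qs; }
    else { h.read_start = a.qs; h.read_end = a.qe; }
    hits.push_back(h);
  }
  // dedupe near-identical hits on the same reference/strand
  std::sort(hits.begin(), hits.end(), [&](const Hit& a, const Hit& b) {
    return hit_before(a, b, idx.names);
  });
  std::vector<Hit> keep;
  for (const Hit& h : hits) {
    bool dup = false;
    for (const Hit& g : keep) {
      if (g.ref != h.ref || g.strand != h.strand) continue;
      int ov = std::min(g.read_end, h.read_end) - std::max(g.read_start, h.read_start);
      int len = std::min(g.read_end - g.read_start, h.read_end - h.read_start);
      if (len > 0 && ov > len / 2) { dup = true; break; }
    }
    if (!dup) keep.push_back(h);
    if ((int)keep.size() >= max_sec + 1) break;
  }
  hits = keep;
}

// [[Rcpp::export]]
DataFrame map_reads_cpp(SEXP xp, CharacterVector read_ids, CharacterVector seqs, List par) {
  XPtr<MiniIndex> p(xp);
  std::vector<std::string> o_read; std::vector<std::string> o_ref;
  std::vector<std::string> o_strand;
  std::vector<int> o_rs, o_re, o_ts, o_te, o_bl, o_nm, o_as;
  std::vector<Hit> hits;
  for (int i = 0; i < seqs.size(); i++) {
    std::string s = as<std::string>(seqs[i]);
    std::string id = as<std::string>(read_ids[i]);
    map_one(*p, s, par, hits);
    for (const Hit& h : hits) {
      o_read.push_back(id);
      o_ref.push_back(p->names[h.ref]);
      o_strand.push_back(h.strand ? "-" : "+");
      o_rs.push_back(h.read_start); o_re.push_back(h.read_end);
      o_ts.push_back(h.ref_start); o_te.push_back(h.ref_end);
      o_bl.push_back(h.blocklen); o_nm.push_back(h.nmatch); o_as.push_back(h.score);
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
    _["read_id"] = o_read, _["ref_id"] = o_ref, _["strand"] = o_strand,
    _["read_start"] = o_rs, _["read_end"] = o_re,
    _["ref_start"] = o_ts, _["ref_end"] = o_te,
    _["block_length"] = o_bl, _["n_match"] = o_nm, _["as_score"] = o_as,
    _["stringsAsFactors"] = false);
}

// ---------- error process for the read simulator ----------

// Applies independent per-base substitution / insertion / deletion events
// using R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector mutate_seq_cpp(std::string s, double sub, double ins, double del) {
  static const char* B = "ACGT";
  std::string out;
  out.reserve((size_t)(s.size() * (1.0 + ins) + 16));
  int n_sub = 0, n_ins = 0, n_del = 0;
  for (size_t i = 0; i < s.size(); i++) {
    if (del > 0 && unif_rand() < del) {
      n_del++;  // base dropped
    } else {
      char c = s[i];
      if (sub > 0 && unif_rand() < sub) {
        int v = b2i(c);
        int r = (int)(unif_rand() * 3);
        if (r > 2) r = 2;
        c = (v < 0) ? B[(int)(unif_rand() * 4) & 3] : B[(v + 1 + r) & 3];
        n_sub++;
      }
      out.push_back(c);
    }
    if (ins > 0 && unif_rand() < ins) {  // at most one insertion per base
      int r = (int)(unif_rand() * 4);
      if (r > 3) r = 3;
      out.push_back(B[r]);
      n_ins++;
    }
  }
  CharacterVector res(1);
  res[0] = out;
  res.attr("n_sub") = n_sub;
  res.attr("n_ins") = n_ins;
  res.attr("n_del") = n_del;
  res.attr("template_bases") = (int)s.size();
  return res;
}
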