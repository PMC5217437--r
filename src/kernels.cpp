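// Alignment kernels: affine-gap Gotoh global alignment with traceback,
// seeded banded Smith-Waterman, unique k-mer anchor discovery and chaining.
// Conventions: 0-based half-open coordinates; ambiguity codes never match.
#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <cctype>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

const int NEG = INT_MIN / 4;

struct Scorer {
  int lookup[256];
  std::vector<int> tab;
  int nsym;
  int wild;
  Scorer(const std::string& alphabet, const IntegerMatrix& m, int wild_)
    : nsym((int)alphabet.size()), wild(wild_) {
    for (int i = 0; i < 256; i++) lookup[i] = -1;
    for (int i = 0; i < nsym; i++) {
      unsigned char c = (unsigned char)alphabet[i];
      lookup[std::toupper(c)] = i;
      lookup[std::tolower(c)] = i;
    }
    tab.resize((size_t)nsym * nsym);
    for (int i = 0; i < nsym; i++)
      for (int j = 0; j < nsym; j++) tab[(size_t)i * nsym + j] = m(i, j);
  }
  inline int s(unsigned char x, unsigned char y) const {
    int ix = lookup[x], iy = lookup[y];
    if (ix < 0 || iy < 0) return wild;
    return tab[(size_t)ix * nsym + iy];
  }
  inline bool match(unsigned char x, unsigned char y) const {
    int ix = lookup[x], iy = lookup[y];
    return ix >= 0 && ix == iy;
  }
  inline int code(unsigned char x) const { return lookup[x]; }
};

struct Hit {
  int score, qs, qe, ts, te, matches, cols;
  bool ok;
  Hit() : score(0), qs(0), qe(0), ts(0), te(0), matches(0), cols(0), ok(false) {}
};

} // namespace

namespace {

// Exact banded SW with separate E/F traceback bits.
Hit sw_full(const std::string& q, const std::string& t, const Scorer& sc,
            int go, int ge);

Hit sw_banded_exact(const std::string& q, const std::string& t, const Scorer& sc,
                    int go, int ge, long dlo, long dhi) {
  Hit out;
  int n = (int)q.size(), m = (int)t.size();
  if (n == 0 || m == 0) return out;
  if (dlo <= -(long)(n - 1) && dhi >= (long)(m - 1)) return sw_full(q, t, sc, go, ge);
  if (dlo < -(long)(n - 1)) dlo = -(long)(n - 1);
  if (dhi > (long)(m - 1)) dhi = (long)(m - 1);
  if (dlo > dhi) return out;
  long W = dhi - dlo + 1;
  // bits: 0-1 H source (0 none, 1 fresh-diag, 2 diag, 3 gap-state)
  // bit 2: H chose E (else F) when source==3
  // bit 3: E opened from H ; bit 4: F opened from H
  std::vector<uint8_t> tb((size_t)n * W, 0);
  std::vector<int> H(W, NEG), F(W, NEG), Hp(W, NEG), Fp(W, NEG);
  int best = 0, bi = -1, bj = -1;
  for (int i = 0; i < n; i++) {
    std::swap(H, Hp);
    std::swap(F, Fp);
    std::fill(H.begin(), H.end(), NEG);
    std::fill(F.begin(), F.end(), NEG);
    long jlo = std::max(0L, (long)i + dlo), jhi = std::min((long)m - 1, (long)i + dhi);
    int Eprev = NEG, hLeft = NEG;
    for (long j = jlo; j <= jhi; j++) {
      long o = j - i - dlo;
      uint8_t code = 0;
      int f = NEG;
      if (i > 0 && o + 1 < W) {
        int f1 = (Fp[o + 1] <= NEG ? NEG : Fp[o + 1] - ge);
        int f2 = (Hp[o + 1] <= NEG ? NEG : Hp[o + 1] - go - ge);
        if (f2 >= f1) { f = f2; code |= 16; } else f = f1;
      }
      int e = NEG;
      if (j > jlo) {
        int e1 = (Eprev <= NEG ? NEG : Eprev - ge);
        int e2 = (hLeft <= NEG ? NEG : hLeft - go - ge);
        if (e2 >= e1) { e = e2; code |= 8; } else e = e1;
      }
      int hd = 0;
      bool fresh = true;
      if (i > 0 && j > 0 && j - 1 >= (long)(i - 1) + dlo && j - 1 <= (long)(i - 1) + dhi) {
        if (Hp[o] > 0) { hd = Hp[o]; fresh = false; }
      }
      int d = hd + sc.s(q[i], t[j]);
      int h;
      if (d >= e && d >= f) { h = d; code |= fresh ? 1 : 2; }
      else if (e >= f) { h = e; code |= 3 | 4; }
      else { h = f; code |= 3; }
      if (h < 0) { h = NEG; code &= ~3; }
      H[o] = h;
      F[o] = f;
      tb[(size_t)i * W + o] = code;
      if (h > best) { best = h; bi = i; bj = (int)j; }
      Eprev = e;
      hLeft = h;
    }
  }
  if (bi < 0) return out;
  int i = bi, j = bj, st = 0;
  int matches = 0, cols = 0;
  bool done = false;
  while (!done && i >= 0 && j >= 0) {
    long o = (long)j - i - dlo;
    uint8_t code = tb[(size_t)i * W + o];
    if (st == 0) {
      uint8_t src = code & 3;
      if (src == 1 || src == 2) {
        cols++;
        if (sc.match(q[i], t[j])) matches++;
        if (src == 1) done = true;
        else { i--; j--; }
      } else if (src == 3) {
        st = (code & 4) ? 1 : 2;
      } else done = true;
    } else if (st == 1) { // E consumes t[j]
      cols++;
      bool open = (code & 8) != 0;
      j--;
      st = open ? 0 : 1;
    } else { // F consumes q[i]
      cols++;
      bool open = (code & 16) != 0;
      i--;
      st = open ? 0 : 2;
    }
  }
  out.ok = true;
  out.score = best;
  out.qs = i;
  out.ts = j;
  out.qe = bi + 1;
  out.te = bj + 1;
  out.matches = matches;
  out.cols = cols;
  return out;
}


// Unbanded local SW fast path (band covers the whole matrix).
Hit sw_full(const std::string& q, const std::string& t, const Scorer& sc,
            int go, int ge) {
  Hit out;
  int n = (int)q.size(), m = (int)t.size();
  if (n == 0 || m == 0) return out;
  // traceback bits as in sw_banded_exact
  std::vector<uint8_t> tb((size_t)n * m, 0);
  std::vector<int> H(m, 0), Hp(m, 0), F(m, NEG);
  int best = 0, bi = -1, bj = -1;
  const int goe = go + ge;
  for (int i = 0; i < n; i++) {
    std::swap(H, Hp);
    int e = NEG, hLeft = 0;
    uint8_t* tbrow = &tb[(size_t)i * m];
    const char qi = q[i];
    for (int j = 0; j < m; j++) {
      uint8_t code = 0;
      int f = F[j] - ge;
      int f2 = Hp[j] - goe;
      if (f2 >= f) { f = f2; code |= 16; }
      int e2 = hLeft - goe;
      e -= ge;
      if (e2 >= e) { e = e2; code |= 8; }
      int hdp = (j > 0) ? Hp[j - 1] : 0;
      bool fresh = hdp <= 0;
      int d = (fresh ? 0 : hdp) + sc.s(qi, t[j]);
      int h;
      if (d >= e && d >= f) { h = d; code |= fresh ? 1 : 2; }
      else if (e >= f) { h = e; code |= 3 | 4; }
      else { h = f; code |= 3; }
      if (h < 0) { h = 0; code &= ~3; }
      H[j] = h;
      F[j] = f;
      tbrow[j] = code;
      if (h > best) { best = h; bi = i; bj = j; }
      hLeft = h;
    }
  }
  if (bi < 0) return out;
  int i = bi, j = bj, st = 0;
  int matches = 0, cols = 0;
  bool done = false;
  while (!done && i >= 0 && j >= 0) {
    uint8_t code = tb[(size_t)i * m + j];
    if (st == 0) {
      uint8_t src = code & 3;
      if (src == 1 || src == 2) {
        cols++;
        if (sc.match(q[i], t[j])) matches++;
        if (src == 1) done = true;
        else { i--; j--; }
      } else if (src == 3) {
        st = (code & 4) ? 1 : 2;
      } else done = true;
    } else if (st == 1) {
      cols++;
      bool open = (code & 8) != 0;
      j--;
      st = open ? 0 : 1;
    } else {
      cols++;
      bool open = (code & 16) != 0;
      i--;
      st = open ? 0 : 2;
    }
  }
  out.ok = true;
  out.score = best;
  out.qs = i;
  out.ts = j;
  out.qe = bi + 1;
  out.te = bj + 1;
  out.matches = matches;
  out.cols = cols;
  return out;
}

inline int sym_bits(int nsym) {
  int b = 1;
  while ((1 << b) < nsym) b++;
  return b;
}

inline uint64_t pack_kmer(const Scorer& sc, const char* s, int k, int bits, bool& ok) {
  uint64_t v = 0;
  ok = true;
  for (int i = 0; i < k; i++) {
    int c = sc.code((unsigned char)s[i]);
    if (c < 0) { ok = false; return 0; }
    v = (v << bits) | (uint64_t)c;
  }
  return v;
}

} // namespace

// [[Rcpp::export]]
List cpp_sw_pair(std::string q, std::string t, std::string alphabet,
                 IntegerMatrix submat, int wild, int gap_open, int gap_ext) {
  Scorer sc(alphabet, submat, wild);
  Hit h = sw_banded_exact(q, t, sc, gap_open, gap_ext,
                          -(long)q.size(), (long)t.size());
  return List::create(_["ok"] = h.ok, _["score"] = h.score,
                      _["qstart"] = h.qs, _["qend"] = h.qe,
                      _["tstart"] = h.ts, _["tend"] = h.te,
                      _["matches"] = h.matches, _["cols"] = h.cols);
}

// Best local hit of every query against one target, k-mer seeded.
// Returns a matrix with one row per query:
// score, qstart, qend, tstart, tend, matches, cols (score -1 = no hit).
// [[Rcpp::export]]
NumericMatrix cpp_map_queries(CharacterVector queries, std::string target,
                              std::string alphabet, IntegerMatrix submat,
                              int wild, int gap_open, int gap_ext,
                              int k, int band_pad, int max_candidates,
                              double full_limit) {
  Scorer sc(alphabet, submat, wild);
  int m = (int)target.size();
  int bits = sym_bits((int)alphabet.size());
  if (k * bits > 62) k = 62 / bits;
  // sorted (kmer, pos) index of the target
  std::vector<std::pair<uint64_t, int> > idx;
  if (m >= k) {
    idx.reserve(m - k + 1);
    for (int j = 0; j + k <= m; j++) {
      bool ok;
      uint64_t v = pack_kmer(sc, target.data() + j, k, bits, ok);
      if (ok) idx.push_back(std::make_pair(v, j));
    }
    std::sort(idx.begin(), idx.end());
  }
  int nq = queries.size();
  NumericMatrix out(nq, 7);
  std::vector<long> diags;
  for (int qi = 0; qi < nq; qi++) {
    std::string q = as<std::string>(queries[qi]);
    int n = (int)q.size();
    Hit best;
    if ((double)(n + 1) * (m + 1) <= full_limit) {
      best = sw_banded_exact(q, target, sc, gap_open, gap_ext, -(long)n, (long)m);
    } else if (n >= k && !idx.empty()) {
      diags.clear();
      for (int i = 0; i + k <= n; i++) {
        bool ok;
        uint64_t v = pack_kmer(sc, q.data() + i, k, bits, ok);
        if (!ok) continue;
        std::pair<uint64_t, int> key(v, INT_MIN);
        std::vector<std::pair<uint64_t, int> >::iterator it =
          std::lower_bound(idx.begin(), idx.end(), key);
        int cnt = 0;
        for (; it != idx.end() && it->first == v; ++it) {
          diags.push_back((long)it->second - i);
          if (++cnt > 256) break; // repeat-region cap
        }
      }
      if (!diags.empty()) {
        std::sort(diags.begin(), diags.end());
        // cluster diagonals closer than band_pad; score = hit count
        std::vector<std::pair<int, std::pair<long, long> > > clusters; // (-count, (dlo,dhi))
        size_t s0 = 0;
        for (size_t z = 1; z <= diags.size(); z++) {
          if (z == diags.size() || diags[z] - diags[z - 1] > band_pad) {
            clusters.push_back(std::make_pair(-(int)(z - s0),
                                              std::make_pair(diags[s0], diags[z - 1])));
            s0 = z;
          }
        }
        std::sort(clusters.begin(), clusters.end());
        int nc = std::min((int)clusters.size(), max_candidates);
        for (int c = 0; c < nc; c++) {
          long dlo = clusters[c].second.first - band_pad;
          long dhi = clusters[c].second.second + band_pad;
          if (dhi - dlo + 1 > 2048) dhi = dlo + 2047;
          Hit h = sw_banded_exact(q, target, sc, gap_open, gap_ext, dlo, dhi);
          if (h.ok && (!best.ok || h.score > best.score ||
                       (h.score == best.score && h.ts < best.ts)))
            best = h;
        }
      }
    }
    if (best.ok) {
      out(qi, 0) = best.score; out(qi, 1) = best.qs; out(qi, 2) = best.qe;
      out(qi, 3) = best.ts; out(qi, 4) = best.te;
      out(qi, 5) = best.matches; out(qi, 6) = best.cols;
    } else {
      out(qi, 0) = -1;
    }
  }
  colnames(out) = CharacterVector::create("score", "qstart", "qend", "tstart",
                                          "tend", "matches", "cols");
  return out;
}

// Global affine-gap (Gotoh) alignment with full traceback.
// Returns the aligned column path: q_idx/t_idx are 0-based consumed positions,
// -1 where the column is a gap on that side.
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, std::string alphabet,
                      IntegerMatrix submat, int wild, int gap_open, int gap_ext) {
  Scorer sc(alphabet, submat, wild);
  int n = (int)a.size(), m = (int)b.size();
  size_t nm = (size_t)(n + 1) * (m + 1);
  // bits 0-1: H source (1 diag, 2 E, 3 F); bit 2: E open; bit 3: F open
  std::vector<uint8_t> tb(nm, 0);
  std::vector<int> H(m + 1), E(m + 1), Hp(m + 1);
  int go = gap_open, ge = gap_ext;
  H[0] = 0;
  E[0] = NEG;
  for (int j = 1; j <= m; j++) {
    E[j] = std::max(E[j - 1] - ge, H[j - 1] - go - ge);
    if (H[j - 1] - go - ge >= E[j - 1] - ge) tb[j] |= 4;
    H[j] = E[j];
    tb[j] |= 2;
  }
  std::vector<int> Fcol(m + 1, NEG);
  int Fdiag_prev_row0 = NEG;
  (void)Fdiag_prev_row0;
  std::vector<int> F(m + 1, NEG);
  for (int i = 1; i <= n; i++) {
    std::swap(H, Hp);
    // column 0
    int f0 = std::max(F[0] - ge, Hp[0] - go - ge);
    if (Hp[0] - go - ge >= F[0] - ge) tb[(size_t)i * (m + 1)] |= 8;
    F[0] = f0;
    H[0] = f0;
    E[0] = NEG;
    tb[(size_t)i * (m + 1)] |= 3;
    for (int j = 1; j <= m; j++) {
      size_t cell = (size_t)i * (m + 1) + j;
      uint8_t code = 0;
      int e1 = (E[j - 1] <= NEG ? NEG : E[j - 1] - ge);
      int e2 = (H[j - 1] <= NEG ? NEG : H[j - 1] - go - ge);
      int e;
      if (e2 >= e1) { e = e2; code |= 4; } else e = e1;
      int f1 = (F[j] <= NEG ? NEG : F[j] - ge);
      int f2 = (Hp[j] <= NEG ? NEG : Hp[j] - go - ge);
      int f;
      if (f2 >= f1) { f = f2; code |= 8; } else f = f1;
      int d = (Hp[j - 1] <= NEG ? NEG : Hp[j - 1] + sc.s(a[i - 1], b[j - 1]));
      int h;
      if (d >= e && d >= f) { h = d; code |= 1; }
      else if (e >= f) { h = e; code |= 2; }
      else { h = f; code |= 3; }
      E[j] = e;
      F[j] = f;
      H[j] = h;
      tb[cell] = code;
    }
  }
  // traceback
  std::vector<int> qi, ti;
  qi.reserve(n + m);
  ti.reserve(n + m);
  int i = n, j = m, st = 0;
  while (i > 0 || j > 0) {
    uint8_t code = tb[(size_t)i * (m + 1) + j];
    if (st == 0) {
      uint8_t src = code & 3;
      if (src == 1) { qi.push_back(i - 1); ti.push_back(j - 1); i--; j--; }
      else if (src == 2) st = 1;
      else st = 2;
    } else if (st == 1) { // E: gap in a, consumes b[j-1]
      qi.push_back(-1); ti.push_back(j - 1);
      bool open = (code & 4) != 0;
      j--;
      st = open ? 0 : 1;
    } else { // F: gap in b, consumes a[i-1]
      qi.push_back(i - 1); ti.push_back(-1);
      bool open = (code & 8) != 0;
      i--;
      st = open ? 0 : 2;
    }
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(ti.begin(), ti.end());
  return List::create(_["score"] = H[m],
                      _["q_idx"] = wrap(qi), _["t_idx"] = wrap(ti));
}

// MUM-like anchors: maximal extensions of k-mers unique in both sequences.
// Returns matrix (astart, bstart, len), 0-based.
// [[Rcpp::export]]
IntegerMatrix cpp_find_anchors(std::string a, std::string b, int min_len) {
  int k = std::min(min_len, 31);
  int lut[256];
  for (int i = 0; i < 256; i++) lut[i] = -1;
  lut['A'] = lut['a'] = 0; lut['C'] = lut['c'] = 1;
  lut['G'] = lut['g'] = 2; lut['T'] = lut['t'] = 3;
  typedef std::pair<uint64_t, int> KP;
  std::vector<KP> ka, kb;
  const std::string* seqs[2] = { &a, &b };
  std::vector<KP>* vecs[2] = { &ka, &kb };
  for (int s = 0; s < 2; s++) {
    const std::string& x = *seqs[s];
    int L = (int)x.size();
    if (L < k) continue;
    vecs[s]->reserve(L - k + 1);
    uint64_t v = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;
    for (int i = 0; i < L; i++) {
      int c = lut[(unsigned char)x[i]];
      if (c < 0) { run = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (++run >= k) vecs[s]->push_back(std::make_pair(v, i - k + 1));
    }
    std::sort(vecs[s]->begin(), vecs[s]->end());
  }
  // keep k-mers unique within each sequence, then merge-join
  struct Pairing { int ia, ib; };
  std::vector<Pairing> pairs;
  size_t i0 = 0, j0 = 0;
  while (i0 < ka.size() && j0 < kb.size()) {
    // advance over duplicate runs
    size_t i1 = i0 + 1;
    while (i1 < ka.size() && ka[i1].first == ka[i0].first) i1++;
    size_t j1 = j0 + 1;
    while (j1 < kb.size() && kb[j1].first == kb[j0].first) j1++;
    if (ka[i0].first < kb[j0].first) { i0 = i1; continue; }
    if (kb[j0].first < ka[i0].first) { j0 = j1; continue; }
    if (i1 - i0 == 1 && j1 - j0 == 1) {
      Pairing p; p.ia = ka[i0].second; p.ib = kb[j0].second;
      pairs.push_back(p);
    }
    i0 = i1;
    j0 = j1;
  }
  // sort by diagonal then position, merge collinear runs
  std::sort(pairs.begin(), pairs.end(), [](const Pairing& x, const Pairing& y) {
    long dx = (long)x.ib - x.ia, dy = (long)y.ib - y.ia;
    if (dx != dy) return dx < dy;
    return x.ia < y.ia;
  });
  struct Anchor { int ia, ib, len; };
  std::vector<Anchor> anchors;
  size_t z = 0;
  int na = (int)a.size(), nb = (int)b.size();
  while (z < pairs.size()) {
    long d = (long)pairs[z].ib - pairs[z].ia;
    int s = pairs[z].ia, e = s + k;
    size_t z2 = z + 1;
    while (z2 < pairs.size() && (long)pairs[z2].ib - pairs[z2].ia == d &&
           pairs[z2].ia <= e) {
      e = std::max(e, pairs[z2].ia + k);
      z2++;
    }
    // maximal extension
    int ia = s, ib = (int)(s + d);
    int len = e - s;
    while (ia > 0 && ib > 0 && lut[(unsigned char)a[ia - 1]] >= 0 &&
           lut[(unsigned char)a[ia - 1]] == lut[(unsigned char)b[ib - 1]]) {
      ia--; ib--; len++;
    }
    while (ia + len < na && ib + len < nb &&
           lut[(unsigned char)a[ia + len]] >= 0 &&
           lut[(unsigned char)a[ia + len]] == lut[(unsigned char)b[ib + len]])
      len++;
    Anchor an; an.ia = ia; an.ib = ib; an.len = len;
    if (len >= min_len) anchors.push_back(an);
    z = z2;
  }
  std::sort(anchors.begin(), anchors.end(), [](const Anchor& x, const Anchor& y) {
    if (x.ia != y.ia) return x.ia < y.ia;
    if (x.ib != y.ib) return x.ib < y.ib;
    return x.len < y.len;
  });
  anchors.erase(std::unique(anchors.begin(), anchors.end(),
                            [](const Anchor& x, const Anchor& y) {
                              return x.ia == y.ia && x.ib == y.ib && x.len == y.len;
                            }),
                anchors.end());
  IntegerMatrix out((int)anchors.size(), 3);
  for (size_t w = 0; w < anchors.size(); w++) {
    out((int)w, 0) = anchors[w].ia;
    out((int)w, 1) = anchors[w].ib;
    out((int)w, 2) = anchors[w].len;
  }
  colnames(out) = CharacterVector::create("astart", "bstart", "len");
  return out;
}

// Collinear chaining: maximise total anchored length over chains strictly
// increasing and non-overlapping in both sequences. Returns 1-based indices
// (row order of the input matrix) of the chosen chain.
// [[Rcpp::export]]
IntegerVector cpp_chain_anchors(IntegerMatrix anchors, int window) {
  int n = anchors.nrow();
  if (n == 0) return IntegerVector(0);
  std::vector<int> ord(n);
  for (int i = 0; i < n; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (anchors(x, 0) != anchors(y, 0)) return anchors(x, 0) < anchors(y, 0);
    return anchors(x, 1) < anchors(y, 1);
  });
  std::vector<long long> best(n);
  std::vector<int> par(n, -1);
  int lookback = (n <= 4000) ? n : window;
  long long gmax = -1;
  int gidx = -1;
  for (int ii = 0; ii < n; ii++) {
    int i = ord[ii];
    best[ii] = anchors(i, 2);
    int lo = std::max(0, ii - lookback);
    const int max_ov = 64; // anchors may overlap slightly (chance extensions)
    for (int jj = ii - 1; jj >= lo; jj--) {
      int j = ord[jj];
      int ov_a = anchors(j, 0) + anchors(j, 2) - anchors(i, 0);
      int ov_b = anchors(j, 1) + anchors(j, 2) - anchors(i, 1);
      int ov = std::max(0, std::max(ov_a, ov_b));
      if (ov_a <= max_ov && ov_b <= max_ov && ov < anchors(i, 2)) {
        long long cand = best[jj] + anchors(i, 2) - ov;
        if (cand > best[ii]) { best[ii] = cand; par[ii] = jj; }
      }
    }
    if (best[ii] > gmax) { gmax = best[ii]; gidx = ii; }
  }
  std::vector<int> chain;
  for (int c = gidx; c >= 0; c = par[c]) chain.push_back(ord[c] + 1);
  std::reverse(chain.begin(), chain.end());
  return wrap(chain);
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); i++) {
    switch (out[i]) {
      case 'A': out[i] = 'T'; break; case 'a': out[i] = 't'; break;
      case 'C': out[i] = 'G'; break; case 'c': out[i] = 'g'; break;
      case 'G': out[i] = 'C'; break; case 'g': out[i] = 'c'; break;
      case 'T': out[i] = 'A'; break; case 't': out[i] = 'a'; break;
      default: break;
    }
  }
  return out;
}
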