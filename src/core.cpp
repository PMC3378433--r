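#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <map>
#include <set>
#include <queue>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// small sequence utilities
// ---------------------------------------------------------------------------

static inline int bcode(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static inline char bcomp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = bcomp(c);
  return r;
}

// substitution score; non-ACGT never matches (so N breaks runs/alignments)
static inline int subsc(char a, char b, int match, int mismatch) {
  if (a == b && bcode(a) >= 0) return match;
  return mismatch;
}

// ---------------------------------------------------------------------------
// full Smith-Waterman (Gotoh affine) oracle with traceback
// gap model: first gapped base costs gap_open, each further base gap_extend
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_extend) {
  const int m = (int)a.size(), n = (int)b.size();
  const int NEG = -1000000000;
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> E((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> F((size_t)(m + 1) * (n + 1), NEG);
  // pointers: pH 0 stop, 1 diag, 2 from E, 3 from F; pE/pF 0 open-from-H, 1 extend
  std::vector<uint8_t> pH((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> pE((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> pF((size_t)(m + 1) * (n + 1), 0);
  auto ix = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int eo = H[ix(i, j - 1)] + gap_open;
      int ee = E[ix(i, j - 1)] + gap_extend;
      if (eo >= ee) { E[ix(i, j)] = eo; pE[ix(i, j)] = 0; }
      else          { E[ix(i, j)] = ee; pE[ix(i, j)] = 1; }
      int fo = H[ix(i - 1, j)] + gap_open;
      int fe = F[ix(i - 1, j)] + gap_extend;
      if (fo >= fe) { F[ix(i, j)] = fo; pF[ix(i, j)] = 0; }
      else          { F[ix(i, j)] = fe; pF[ix(i, j)] = 1; }
      int dg = H[ix(i - 1, j - 1)] + subsc(a[i - 1], b[j - 1], match, mismatch);
      int h = 0; uint8_t p = 0;
      if (dg > h) { h = dg; p = 1; }
      if (E[ix(i, j)] > h) { h = E[ix(i, j)]; p = 2; }
      if (F[ix(i, j)] > h) { h = F[ix(i, j)]; p = 3; }
      H[ix(i, j)] = h; pH[ix(i, j)] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int qs = 0, qe = 0, ss = 0, se = 0;
  if (best > 0) {
    qe = bi; se = bj;
    int i = bi, j = bj, state = 0; // 0 H, 1 E, 2 F
    while (true) {
      if (state == 0) {
        if (H[ix(i, j)] == 0) break;
        uint8_t p = pH[ix(i, j)];
        if (p == 1) { --i; --j; }
        else if (p == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        uint8_t p = pE[ix(i, j)];
        --j;
        if (p == 0) state = 0;
      } else {
        uint8_t p = pF[ix(i, j)];
        --i;
        if (p == 0) state = 0;
      }
    }
    qs = i; ss = j;
  }
  return List::create(_["score"] = best,
                      _["qstart"] = qs, _["qend"] = qe,
                      _["sstart"] = ss, _["send"] = se);
}

// ---------------------------------------------------------------------------
// banded Gotoh local alignment restricted to diagonals [dlo, dhi]
// (diag = qpos - spos, 0-based); returns best score and spans
// ---------------------------------------------------------------------------

struct BandHit {
  int score, qs, qe, ss, se;
};

static BandHit banded_gotoh(const std::string &q, const std::string &s,
                            int dlo, int dhi, int match, int mismatch,
                            int gap_open, int gap_extend) {
  const int m = (int)q.size(), n = (int)s.size();
  const int NEG = -1000000000;
  // cell (i,j) 1-based has diag (i-1)-(j-1) = i-j; constrain i-j in [dlo,dhi]
  const int w = dhi - dlo + 1;
  std::vector<int> Hprev(w + 2, 0), Eprev(w + 2, NEG), Fprev(w + 2, NEG);
  std::vector<int> Hcur(w + 2, 0), Ecur(w + 2, NEG), Fcur(w + 2, NEG);
  std::vector<uint8_t> pHm((size_t)(m + 1) * w, 0), pEm((size_t)(m + 1) * w, 0),
      pFm((size_t)(m + 1) * w, 0);
  auto off = [dhi](int i, int j) { return j - (i - dhi); }; // column in band, 0..w-1
  auto pix = [w](int i, int o) { return (size_t)i * w + o; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    int jlo = std::max(1, i - dhi), jhi = std::min(n, i - dlo);
    for (int j = jlo; j <= jhi; ++j) {
      int o = off(i, j); // 0..w-1
      // E (gap consuming subject char): from (i, j-1) -> band column o-1
      int Hleft = (o - 1 >= 0 && j - 1 >= 1) ? Hcur[o - 1 + 1] : NEG;
      int Eleft = (o - 1 >= 0 && j - 1 >= 1) ? Ecur[o - 1 + 1] : NEG;
      // note: +1 shift below for sentinel-free storage; see indexing comment
      // we store row arrays with logical index o at position o+1
      int eo = (Hleft == NEG) ? NEG : Hleft + gap_open;
      int ee = (Eleft == NEG) ? NEG : Eleft + gap_extend;
      int Ev, Fv; uint8_t pe, pf;
      if (eo >= ee) { Ev = eo; pe = 0; } else { Ev = ee; pe = 1; }
      // F (gap consuming query char): from (i-1, j) -> prev row, band column o+1
      int Hup = (o + 1 <= w - 1 && i - 1 >= 0) ? Hprev[o + 1 + 1] : NEG;
      int Fup = (o + 1 <= w - 1 && i - 1 >= 0) ? Fprev[o + 1 + 1] : NEG;
      int fo = (Hup == NEG) ? NEG : Hup + gap_open;
      int fe = (Fup == NEG) ? NEG : Fup + gap_extend;
      if (fo >= fe) { Fv = fo; pf = 0; } else { Fv = fe; pf = 1; }
      // diag from (i-1, j-1): same band column o in prev row
      int Hdiag;
      if (i - 1 == 0 || j - 1 == 0) Hdiag = 0;
      else {
        int hd = Hprev[o + 1];
        Hdiag = (hd == NEG) ? NEG : hd;
      }
      int dg = (Hdiag == NEG) ? NEG
                              : Hdiag + subsc(q[i - 1], s[j - 1], match, mismatch);
      int h = 0; uint8_t p = 0;
      if (dg > h) { h = dg; p = 1; }
      if (Ev > h) { h = Ev; p = 2; }
      if (Fv > h) { h = Fv; p = 3; }
      Hcur[o + 1] = h; Ecur[o + 1] = Ev; Fcur[o + 1] = Fv;
      pHm[pix(i, o)] = p; pEm[pix(i, o)] = pe; pFm[pix(i, o)] = pf;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  BandHit out{best, 0, 0, 0, 0};
  if (best > 0) {
    out.qe = bi; out.se = bj;
    int i = bi, j = bj, state = 0;
    while (i > 0 && j > 0) {
      int o = off(i, j);
      if (state == 0) {
        uint8_t p = pHm[pix(i, o)];
        if (p == 0) break; // H hit zero here
        if (p == 1) {
          // check whether predecessor H was the zero floor
          --i; --j;
          if (i == 0 || j == 0) break;
          // if predecessor cell H==0 the walk ends when its pointer is stop
        } else if (p == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        uint8_t p = pEm[pix(i, o)];
        --j; if (p == 0) state = 0;
      } else {
        uint8_t p = pFm[pix(i, o)];
        --i; if (p == 0) state = 0;
      }
    }
    out.qs = i; out.ss = j;
  }
  return out;
}

// ---------------------------------------------------------------------------
// seed-and-extend search: k-mer index over subjects, banded gapped
// refinement around clustered seed diagonals, both query strands
// ---------------------------------------------------------------------------

typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > KmerIndex;

static void index_kmers(const std::vector<std::string> &seqs, int k,
                        KmerIndex &idx) {
  for (int si = 0; si < (int)seqs.size(); ++si) {
    const std::string &s = seqs[si];
    if ((int)s.size() < k) continue;
    uint64_t code = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int c = bcode(s[p]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      if (++run >= k) idx[code].push_back(std::make_pair(si, p - k + 1));
    }
  }
}

static void query_kmers(const std::string &q, int k, const KmerIndex &idx,
                        int max_bucket,
                        std::map<int, std::vector<int> > &diags) {
  if ((int)q.size() < k) return;
  uint64_t code = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int p = 0; p < (int)q.size(); ++p) {
    int c = bcode(q[p]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      KmerIndex::const_iterator it = idx.find(code);
      if (it == idx.end()) continue;
      if ((int)it->second.size() > max_bucket) continue;
      int qpos = p - k + 1;
      for (size_t z = 0; z < it->second.size(); ++z)
        diags[it->second[z].first].push_back(qpos - it->second[z].second);
    }
  }
}

// best banded hit for one query string against one subject given seed diags
static bool best_hit_for_diags(const std::string &q, const std::string &s,
                               std::vector<int> &dg, int band, int match,
                               int mismatch, int gap_open, int gap_extend,
                               BandHit &out) {
  std::sort(dg.begin(), dg.end());
  dg.erase(std::unique(dg.begin(), dg.end()), dg.end());
  bool found = false;
  size_t a = 0;
  while (a < dg.size()) {
    size_t b = a;
    while (b + 1 < dg.size() && dg[b + 1] - dg[b] <= 2 * band) ++b;
    BandHit h = banded_gotoh(q, s, dg[a] - band, dg[b] + band, match, mismatch,
                             gap_open, gap_extend);
    if (!found || h.score > out.score) { out = h; found = true; }
    a = b + 1;
  }
  return found && out.score > 0;
}

// [[Rcpp::export]]
DataFrame cpp_search(CharacterVector queries, CharacterVector subjects, int k,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int band, int max_bucket) {
  std::vector<std::string> subj(subjects.size());
  for (int i = 0; i < subjects.size(); ++i) subj[i] = as<std::string>(subjects[i]);
  KmerIndex idx;
  index_kmers(subj, k, idx);

  std::vector<int> o_q, o_s, o_score, o_qs, o_qe, o_ss, o_se;
  std::vector<std::string> o_strand;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string fwd = as<std::string>(queries[qi]);
    std::string rev = revcomp_str(fwd);
    int m = (int)fwd.size();
    // best per subject over strands; plus strand preferred on ties
    std::map<int, BandHit> besth;
    std::map<int, int> beststrand; // 1 fwd, -1 rev
    for (int st = 0; st < 2; ++st) {
      const std::string &q = (st == 0) ? fwd : rev;
      std::map<int, std::vector<int> > diags;
      query_kmers(q, k, idx, max_bucket, diags);
      for (std::map<int, std::vector<int> >::iterator it = diags.begin();
           it != diags.end(); ++it) {
        BandHit h;
        if (!best_hit_for_diags(q, subj[it->first], it->second, band, match,
                                mismatch, gap_open, gap_extend, h))
          continue;
        if (st == 1) { // convert query span back to forward coordinates
          int qs = m - h.qe, qe = m - h.qs;
          h.qs = qs; h.qe = qe;
        }
        std::map<int, BandHit>::iterator bh = besth.find(it->first);
        if (bh == besth.end() || h.score > bh->second.score) {
          besth[it->first] = h;
          beststrand[it->first] = (st == 0) ? 1 : -1;
        }
      }
    }
    for (std::map<int, BandHit>::iterator it = besth.begin(); it != besth.end();
         ++it) {
      o_q.push_back(qi + 1);
      o_s.push_back(it->first + 1);
      o_score.push_back(it->second.score);
      o_qs.push_back(it->second.qs);
      o_qe.push_back(it->second.qe);
      o_ss.push_back(it->second.ss);
      o_se.push_back(it->second.se);
      o_strand.push_back(beststrand[it->first] == 1 ? "+" : "-");
    }
  }
  return DataFrame::create(_["qidx"] = o_q, _["sidx"] = o_s,
                           _["score"] = o_score, _["qstart"] = o_qs,
                           _["qend"] = o_qe, _["sstart"] = o_ss,
                           _["send"] = o_se, _["strand"] = o_strand,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// SSR scan: maximal perfect tandem repeats, primitive motifs, periods 2-5
// ---------------------------------------------------------------------------

static bool motif_primitive(const std::string &motif) {
  int p = (int)motif.size();
  for (int d = 1; d < p; ++d) {
    if (p % d != 0) continue;
    bool periodic = true;
    for (int i = d; i < p; ++i)
      if (motif[i] != motif[i - d]) { periodic = false; break; }
    if (periodic) return false;
  }
  return true;
}

// min_reps: length-4 integer vector for periods 2,3,4,5
// [[Rcpp::export]]
DataFrame cpp_find_ssrs(std::string s, IntegerVector min_reps) {
  int L = (int)s.size();
  std::vector<std::string> motifs;
  std::vector<int> starts, ends, reps, plens;
  for (int p = 2; p <= 5; ++p) {
    int need = min_reps[p - 2];
    int i = 0;
    while (i + p <= L) {
      // run start: cannot extend a single base left
      bool start_ok = (i == 0) ||
                      !(bcode(s[i - 1]) >= 0 && s[i - 1] == s[i - 1 + p]);
      if (!start_ok) { ++i; continue; }
      // all motif bases ACGT?
      bool okb = true;
      for (int z = 0; z < p; ++z)
        if (bcode(s[i + z]) < 0) { okb = false; break; }
      if (!okb) { ++i; continue; }
      int j = i + p;
      while (j < L && bcode(s[j]) >= 0 && s[j] == s[j - p]) ++j;
      int runlen = j - i;
      int r = runlen / p;
      if (r >= need) {
        std::string motif = s.substr(i, p);
        if (motif_primitive(motif)) {
          motifs.push_back(motif);
          starts.push_back(i);
          ends.push_back(i + p * r);
          reps.push_back(r);
          plens.push_back(p);
        }
      }
      i = (runlen >= 2 * p) ? (j - p + 1) : (i + 1);
    }
  }
  return DataFrame::create(_["motif"] = motifs, _["motif_len"] = plens,
                           _["repeats"] = reps, _["start"] = starts,
                           _["end"] = ends, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// greedy overlap-consensus assembler (substitution-only layout, ungapped
// diagonal overlaps, reverse-complement aware, deterministic)
// ---------------------------------------------------------------------------

struct Member { int read; int off; int strand; }; // strand +1 / -1

struct KV { uint64_t code; int pos; };
static bool kv_less(const KV &a, const KV &b) {
  return a.code < b.code || (a.code == b.code && a.pos < b.pos);
}

static void kmer_list(const std::string &s, int k, std::vector<KV> &out) {
  out.clear();
  if ((int)s.size() < k) return;
  uint64_t code = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int p = 0; p < (int)s.size(); ++p) {
    int c = bcode(s[p]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++run >= k) { KV kv; kv.code = code; kv.pos = p - k + 1; out.push_back(kv); }
  }
  std::sort(out.begin(), out.end(), kv_less);
}

struct Unit {
  std::vector<Member> mem;
  std::string cons, rccons;
  std::vector<KV> kf, kr; // sorted k-mer lists of cons and rccons
  bool alive;
  int minread;
  std::set<int> partners;
};

struct Ovl {
  bool ok;
  int score, span, diag, strand; // diag: posA - posB (B revcomp'd if strand -1)
  Ovl() : ok(false), score(-1), span(0), diag(0), strand(1) {}
};

// shared-k-mer diagonals between two sorted k-mer lists (merge join)
static void join_diags(const std::vector<KV> &a, const std::vector<KV> &b,
                       std::vector<int> &diags) {
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i].code < b[j].code) { ++i; continue; }
    if (b[j].code < a[i].code) { ++j; continue; }
    size_t i2 = i, j2 = j;
    while (i2 < a.size() && a[i2].code == a[i].code) ++i2;
    while (j2 < b.size() && b[j2].code == b[j].code) ++j2;
    if ((i2 - i) * (j2 - j) <= 4096) {
      for (size_t x = i; x < i2; ++x)
        for (size_t y = j; y < j2; ++y)
          diags.push_back(a[x].pos - b[y].pos);
    }
    i = i2; j = j2;
  }
}

// best ungapped end overlap between two units' consensus sequences
static Ovl best_overlap(const Unit &A, const Unit &B, int min_overlap,
                        double min_identity) {
  Ovl best;
  const std::string &Acons = A.cons;
  const int la = (int)Acons.size(), lb = (int)B.cons.size();
  std::vector<int> diags;
  for (int st = 0; st < 2; ++st) {
    const std::string &Bs = (st == 0) ? B.cons : B.rccons;
    diags.clear();
    join_diags(A.kf, (st == 0) ? B.kf : B.kr, diags);
    std::sort(diags.begin(), diags.end());
    diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
    for (size_t z = 0; z < diags.size(); ++z) {
      int d = diags[z];
      int as = std::max(0, d), ae = std::min(la, lb + d);
      int span = ae - as;
      if (span < min_overlap) continue;
      int matches = 0;
      for (int i = as; i < ae; ++i)
        if (Acons[i] == Bs[i - d] && bcode(Acons[i]) >= 0) ++matches;
      if ((double)matches / span < min_identity) continue;
      bool better = false;
      if (!best.ok) better = true;
      else if (matches != best.score) better = matches > best.score;
      else if (span != best.span) better = span > best.span;
      else if ((st == 0 ? 1 : -1) != best.strand) better = (st == 0);
      else better = d < best.diag;
      if (better) {
        best.ok = true; best.score = matches; best.span = span;
        best.diag = d; best.strand = (st == 0) ? 1 : -1;
      }
    }
  }
  return best;
}

struct Event {
  int score, span, u, v, ur, vr, diag, strand;
  bool validated;
};
struct EventLess {
  bool operator()(const Event &a, const Event &b) const {
    if (a.score != b.score) return a.score < b.score;
    if (a.span != b.span) return a.span < b.span;
    if (a.ur != b.ur) return a.ur > b.ur;
    if (a.vr != b.vr) return a.vr > b.vr;
    if (a.u != b.u) return a.u > b.u;
    return a.v > b.v;
  }
};

// consensus by column majority vote, ties to the first-placed member's base
static void rebuild_unit(Unit &u, const std::vector<std::string> &reads,
                         int k) {
  int L = 0;
  for (size_t z = 0; z < u.mem.size(); ++z) {
    int e = u.mem[z].off + (int)reads[u.mem[z].read].size();
    if (e > L) L = e;
  }
  std::vector<int> counts((size_t)L * 4, 0);
  std::string first(L, 'N');
  for (size_t z = 0; z < u.mem.size(); ++z) {
    const Member &mm = u.mem[z];
    const std::string &r = reads[mm.read];
    int len = (int)r.size();
    for (int p = 0; p < len; ++p) {
      char base = (mm.strand == 1) ? r[p] : bcomp(r[len - 1 - p]);
      int bc = bcode(base);
      if (bc < 0) continue;
      int c = mm.off + p;
      counts[(size_t)c * 4 + bc]++;
      if (first[c] == 'N') first[c] = base;
    }
  }
  u.cons.assign(L, 'N');
  for (int c = 0; c < L; ++c) {
    int bestn = 0, bestc = -1, nties = 0;
    for (int bc = 0; bc < 4; ++bc) {
      int x = counts[(size_t)c * 4 + bc];
      if (x > bestn) { bestn = x; bestc = bc; nties = 1; }
      else if (x == bestn && x > 0) ++nties;
    }
    if (bestc < 0) continue;
    u.cons[c] = (nties > 1) ? first[c] : "ACGT"[bestc];
  }
  u.rccons = revcomp_str(u.cons);
  kmer_list(u.cons, k, u.kf);
  kmer_list(u.rccons, k, u.kr);
}

static inline uint64_t pair_key(int a, int b) {
  if (a > b) std::swap(a, b);
  return ((uint64_t)(uint32_t)a << 32) | (uint32_t)b;
}

// [[Rcpp::export]]
List cpp_assemble(CharacterVector seqs, int min_overlap, double min_identity,
                  int k, int k_diag, int max_bucket) {
  const int n = seqs.size();
  std::vector<std::string> reads(n);
  for (int i = 0; i < n; ++i) reads[i] = as<std::string>(seqs[i]);

  std::vector<Unit> units;
  units.reserve(2 * (size_t)n + 1);
  for (int i = 0; i < n; ++i) {
    Unit u;
    Member m0; m0.read = i; m0.off = 0; m0.strand = 1;
    u.mem.push_back(m0);
    u.cons = reads[i];
    u.rccons = revcomp_str(u.cons);
    kmer_list(u.cons, k_diag, u.kf);
    kmer_list(u.rccons, k_diag, u.kr);
    u.alive = true; u.minread = i;
    units.push_back(u);
  }

  // candidate read pairs via shared k-mers (forward + revcomp lookups)
  KmerIndex idx;
  index_kmers(reads, k, idx);
  std::unordered_set<uint64_t> cand;
  for (KmerIndex::iterator it = idx.begin(); it != idx.end(); ++it) {
    std::vector<std::pair<int, int> > &v = it->second;
    if ((int)v.size() > max_bucket) continue;
    for (size_t a = 0; a < v.size(); ++a)
      for (size_t b = a + 1; b < v.size(); ++b) {
        if (v[a].first == v[b].first) continue;
        cand.insert(pair_key(v[a].first, v[b].first));
      }
  }
  for (int i = 0; i < n; ++i) {
    std::map<int, std::vector<int> > dm;
    query_kmers(units[i].rccons, k, idx, max_bucket, dm);
    for (std::map<int, std::vector<int> >::iterator it = dm.begin();
         it != dm.end(); ++it) {
      if (it->first == i) continue;
      cand.insert(pair_key(i, it->first));
    }
  }
  std::vector<uint64_t> cand_v(cand.begin(), cand.end());
  std::sort(cand_v.begin(), cand_v.end());

  std::priority_queue<Event, std::vector<Event>, EventLess> heap;
  std::unordered_map<uint64_t, int> pairscore; // validated best scores
  for (size_t z = 0; z < cand_v.size(); ++z) {
    int u = (int)(cand_v[z] >> 32), v = (int)(uint32_t)cand_v[z];
    units[u].partners.insert(v);
    units[v].partners.insert(u);
    Ovl o = best_overlap(units[u], units[v], min_overlap, min_identity);
    if (o.ok) {
      Event e;
      e.score = o.score; e.span = o.span; e.u = u; e.v = v;
      e.ur = units[u].minread; e.vr = units[v].minread;
      e.diag = o.diag; e.strand = o.strand; e.validated = true;
      heap.push(e);
      pairscore[pair_key(u, v)] = o.score;
    }
  }

  while (!heap.empty()) {
    Event e = heap.top(); heap.pop();
    if (!units[e.u].alive || !units[e.v].alive) continue;
    if (!e.validated) {
      // recompute this pair's overlap on the current (immutable) units
      int a = e.u, b = e.v;
      if (units[a].minread > units[b].minread) std::swap(a, b);
      Ovl o = best_overlap(units[a], units[b], min_overlap, min_identity);
      if (o.ok) {
        Event ne;
        ne.score = o.score; ne.span = o.span; ne.u = a; ne.v = b;
        ne.ur = units[a].minread; ne.vr = units[b].minread;
        ne.diag = o.diag; ne.strand = o.strand; ne.validated = true;
        heap.push(ne);
        pairscore[pair_key(a, b)] = o.score;
      }
      continue;
    }
    // merge e.u (A) and e.v (B): B placed at offset e.diag in A coordinates
    {
      Unit w;
      {
        Unit &A = units[e.u];
        Unit &B = units[e.v];
        std::vector<Member> bm = B.mem;
        if (e.strand == -1) {
          int Lb = (int)B.cons.size();
          for (size_t z = 0; z < bm.size(); ++z) {
            int len = (int)reads[bm[z].read].size();
            bm[z].off = Lb - (bm[z].off + len);
            bm[z].strand = -bm[z].strand;
          }
        }
        int shift = std::min(0, e.diag);
        w.mem = A.mem;
        for (size_t z = 0; z < w.mem.size(); ++z) w.mem[z].off -= shift;
        for (size_t z = 0; z < bm.size(); ++z) {
          bm[z].off += e.diag - shift;
          w.mem.push_back(bm[z]);
        }
        w.alive = true;
        w.minread = std::min(A.minread, B.minread);
        for (std::set<int>::iterator it = A.partners.begin();
             it != A.partners.end(); ++it)
          if (*it != e.v && units[*it].alive) w.partners.insert(*it);
        for (std::set<int>::iterator it = B.partners.begin();
             it != B.partners.end(); ++it)
          if (*it != e.u && units[*it].alive) w.partners.insert(*it);
        A.alive = false; B.alive = false;
        A.cons.clear(); A.rccons.clear(); A.kf.clear(); A.kr.clear();
        B.cons.clear(); B.rccons.clear(); B.kf.clear(); B.kr.clear();
      }
      rebuild_unit(w, reads, k_diag);
      int wi = (int)units.size();
      units.push_back(w);
      Unit &W = units[wi];
      for (std::set<int>::iterator it = W.partners.begin();
           it != W.partners.end(); ++it) {
        int p = *it;
        units[p].partners.erase(e.u);
        units[p].partners.erase(e.v);
        units[p].partners.insert(wi);
        // lazy: seed an event with the best previously validated score of
        // the two merged halves against p; revalidated when popped
        int est = -1;
        std::unordered_map<uint64_t, int>::iterator f1 =
            pairscore.find(pair_key(e.u, p));
        if (f1 != pairscore.end()) est = std::max(est, f1->second);
        std::unordered_map<uint64_t, int>::iterator f2 =
            pairscore.find(pair_key(e.v, p));
        if (f2 != pairscore.end()) est = std::max(est, f2->second);
        // no prior validated overlap for either half: still seed the pair
        // at the lowest admissible priority so chains keep merging
        if (est < min_overlap) est = min_overlap;
        Event ne;
        ne.score = est; ne.span = 0;
        if (W.minread < units[p].minread) { ne.u = wi; ne.v = p; }
        else { ne.u = p; ne.v = wi; }
        ne.ur = std::min(W.minread, units[p].minread);
        ne.vr = std::max(W.minread, units[p].minread);
        ne.diag = 0; ne.strand = 1; ne.validated = false;
        heap.push(ne);
      }
    }
  }

  // compact alive units ordered by smallest member read rank
  std::vector<int> alive;
  for (int u = 0; u < (int)units.size(); ++u)
    if (units[u].alive) alive.push_back(u);
  std::sort(alive.begin(), alive.end(), [&units](int a, int b) {
    return units[a].minread < units[b].minread;
  });

  IntegerVector unit_of(n), off_of(n), strand_of(n);
  CharacterVector cons(alive.size());
  IntegerVector nmem(alive.size());
  for (int z = 0; z < (int)alive.size(); ++z) {
    Unit &u = units[alive[z]];
    cons[z] = u.cons;
    nmem[z] = (int)u.mem.size();
    for (size_t q = 0; q < u.mem.size(); ++q) {
      unit_of[u.mem[q].read] = z + 1;
      off_of[u.mem[q].read] = u.mem[q].off;
      strand_of[u.mem[q].read] = u.mem[q].strand;
    }
  }
  return List::create(_["unit"] = unit_of, _["offset"] = off_of,
                      _["strand"] = strand_of, _["consensus"] = cons,
                      _["n_members"] = nmem);
}
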