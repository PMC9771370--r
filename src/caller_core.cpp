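// Junction decomposition engine.
//
// Each read is decomposed as bait-supported prefix [1..e] + optional
// insertion + prey-supported suffix [sp..L] over candidate prey diagonals,
// maximising the support score (match +1, mismatch -1 against the allele
// sets, each read position counted once) minus affine gap penalties
// (gap open 5, extend 1; at most one reference gap per side).  Overlapping
// supports (sp <= e) are microhomology and must match BOTH references
// exactly over the tract; the overlap contributes its length once.  Ties
// break by longer MH, then smaller bait end column, then smaller prey
// read-start, then smaller prey column, making calls reproducible and equal
// to the exhaustive R oracle on gap-free reads.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return 4;
  }
}

struct RefSide {
  std::vector<int> b6, s129;      // 4 = gap or non-ACGT
  std::vector<char> b6c, s129c;
  std::vector<bool> ambig;
  int n;

  void init(const std::string &b6s, const std::string &s129s) {
    n = (int) b6s.size();
    b6.resize(n); s129.resize(n); b6c.resize(n); s129c.resize(n);
    ambig.resize(n);
    for (int i = 0; i < n; ++i) {
      b6c[i] = b6s[i]; s129c[i] = s129s[i];
      b6[i] = base_code(b6s[i]); s129[i] = base_code(s129s[i]);
      ambig[i] = (b6[i] == 4 || s129[i] == 4);
    }
  }
  // col is 1-based
  inline bool match(int base, int col) const {
    if (col < 1 || col > n || base > 3) return false;
    return base == b6[col - 1] || base == s129[col - 1];
  }
};

// 12-mer hash index over reference columns (both haplotypes).
struct KmerIndex {
  int k;
  std::unordered_map<uint32_t, std::vector<int>> map;  // key -> 1-based cols

  static bool key_of(const std::vector<int> &codes, int start, int k,
                     uint32_t &key) {
    key = 0;
    for (int j = 0; j < k; ++j) {
      int c = codes[start + j];
      if (c > 3) return false;
      key = (key << 2) | (uint32_t) c;
    }
    return true;
  }

  void build(const RefSide &ref, int k_) {
    k = k_;
    uint32_t key, key2;
    const bool same = (ref.s129 == ref.b6);
    for (int c = 0; c + k <= ref.n; ++c) {
      bool ok1 = key_of(ref.b6, c, k, key);
      if (ok1) map[key].push_back(c + 1);
      if (!same && key_of(ref.s129, c, k, key2) && (!ok1 || key2 != key)) {
        map[key2].push_back(c + 1);
      }
    }
  }
};

struct Decomp {
  bool found = false;
  long score = -1;
  int mh = -1, e = 0, sp = 0, prey_col = 0;
  int cand_dl = 0, sB = 0, jB = 0, sP = 0, jP = 0;
  long bait_matched = 0, prey_matched = 0;

  // true if (sc, m, e2, sp2, pc) beats the stored optimum
  bool better(long sc, int m, int e2, int sp2, int pc) const {
    if (!found) return true;
    if (sc != score) return sc > score;
    if (m != mh) return m > mh;
    if (e2 != e) return e2 < e;
    if (sp2 != sp) return sp2 < sp;
    return pc < prey_col;
  }
};

struct PreyCand {
  int dl;                         // later (well-seeded) diagonal
  std::vector<long> best;         // best[sp]
  std::vector<int> argS, argJ;    // chosen shift and split per sp
};

// [[Rcpp::export(name = ".call_reads_cpp")]]
List call_reads_cpp(CharacterVector reads,
                    std::string bait_b6, std::string bait_s129,
                    std::string prey_b6, std::string prey_s129,
                    std::string primer, int primer_start,
                    int window, int min_flank, int seed_k,
                    int max_mh, int max_ins, int max_del,
                    std::string aflii, bool require_primer,
                    double germline_identity) {
  RefSide bait, prey, prey_rc;
  bait.init(bait_b6, bait_s129);
  prey.init(prey_b6, prey_s129);
  {
    // reverse complement of prey (both haplotypes) for inversion flagging
    auto rc = [](const std::string &s) {
      std::string r(s.rbegin(), s.rend());
      for (char &c : r) {
        switch (c) {
          case 'A': c = 'T'; break; case 'T': c = 'A'; break;
          case 'C': c = 'G'; break; case 'G': c = 'C'; break;
        }
      }
      return r;
    };
    prey_rc.init(rc(prey_b6), rc(prey_s129));
  }
  KmerIndex idx, idx_rc;
  idx.build(prey, seed_k);
  idx_rc.build(prey_rc, seed_k);

  std::vector<int> primer_code(primer.size());
  for (size_t i = 0; i < primer.size(); ++i) primer_code[i] = base_code(primer[i]);
  std::vector<int> aflii_code(aflii.size());
  for (size_t i = 0; i < aflii.size(); ++i) aflii_code[i] = base_code(aflii[i]);
  const int plen = (int) primer.size();
  const int alen = (int) aflii.size();
  const int p0 = primer_start;
  const int n_reads = reads.size();
  const int n_shift = max_del + 1;

  IntegerVector out_status(n_reads);       // 0 ok 1 unmapped 2 germline 3 inversion
  IntegerVector out_bait_end(n_reads, NA_INTEGER);
  IntegerVector out_prey_start(n_reads, NA_INTEGER);
  IntegerVector out_mh(n_reads, NA_INTEGER);
  IntegerVector out_mh_rs(n_reads, NA_INTEGER), out_mh_re(n_reads, NA_INTEGER);
  CharacterVector out_ins(n_reads, NA_STRING);
  CharacterVector out_del(n_reads, NA_STRING);
  IntegerVector out_ndel(n_reads, NA_INTEGER);
  CharacterVector out_mut(n_reads, NA_STRING);
  IntegerVector out_nmut(n_reads, NA_INTEGER);
  CharacterVector out_bgb(n_reads, NA_STRING), out_bgp(n_reads, NA_STRING);
  LogicalVector out_cross(n_reads, NA_LOGICAL);
  IntegerVector out_score(n_reads, NA_INTEGER);
  IntegerVector out_bait_matched(n_reads, NA_INTEGER);
  IntegerVector out_prey_matched(n_reads, NA_INTEGER);

  std::vector<int> rd;
  // bait DP buffers
  std::vector<long> cum0, cums, sbBest;
  std::vector<int> sbS, sbJ, runArg;
  std::vector<long> mp, suf, cumj, gmax;
  std::vector<int> gArg;

  for (int r = 0; r < n_reads; ++r) {
    std::string rs = as<std::string>(reads[r]);
    const int L = (int) rs.size();
    rd.assign(L + 1, 4);
    for (int i = 1; i <= L; ++i) rd[i] = base_code(rs[i - 1]);

    if (L < plen + 2) { out_status[r] = 1; continue; }

    // --- primer check ---------------------------------------------------
    if (require_primer && plen > 0) {
      int mm = 0;
      for (int i = 1; i <= plen; ++i) if (rd[i] != primer_code[i - 1]) ++mm;
      if (mm > 1) { out_status[r] = 1; continue; }
    }

    // --- bait support DP (one optional reference gap) --------------------
    // read pos i maps to bait column p0 + i - 1 (+ shift after the gap)
    cum0.assign(L + 1, 0);
    for (int i = 1; i <= L; ++i)
      cum0[i] = cum0[i - 1] + (bait.match(rd[i], p0 + i - 1) ? 1 : -1);
    sbBest.assign(L + 1, 0);
    sbS.assign(L + 1, 0); sbJ.assign(L + 1, 0);
    for (int e = 1; e <= L; ++e) sbBest[e] = cum0[e];
    for (int s = 1; s <= max_del; ++s) {
      cums.assign(L + 1, 0);
      for (int i = 1; i <= L; ++i)
        cums[i] = cums[i - 1] + (bait.match(rd[i], p0 + i - 1 + s) ? 1 : -1);
      long run = -1000000; int runj = -1;
      const long pen = 5 + s;
      for (int e = 1; e <= L; ++e) {
        int j = e - 1;
        if (j >= plen) {
          long v = cum0[j] - cums[j];
          if (v > run) { run = v; runj = j; }
        }
        if (runj >= 0) {
          long val = cums[e] + run - pen;
          if (val > sbBest[e]) { sbBest[e] = val; sbS[e] = s; sbJ[e] = runj; }
        }
      }
    }

    // --- germline tests ---------------------------------------------------
    bool germ = false;
    if (((double) sbBest[L] + L) / (2.0 * L) >= germline_identity) germ = true;
    if (!germ && alen > 0) {
      for (int t = plen + 1; t + alen - 1 <= L && !germ; ++t) {
        bool hit = true;
        for (int j = 0; j < alen; ++j) {
          if (rd[t + j] != aflii_code[j] ||
              !bait.match(rd[t + j], p0 + t + j - 1)) { hit = false; break; }
        }
        if (hit) germ = true;
      }
    }
    if (germ) { out_status[r] = 2; continue; }

    // --- prey seeding -----------------------------------------------------
    std::unordered_map<int, int> diag_hits;
    int minus_hits = 0;
    if (L >= plen + seed_k) {
      uint32_t key = 0, mask = (seed_k >= 16) ? 0xFFFFFFFFu
                     : ((1u << (2 * seed_k)) - 1u);
      int valid = 0;
      for (int i = plen + 1; i <= L; ++i) {
        if (rd[i] > 3) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint32_t) rd[i]) & mask;
        if (++valid < seed_k) continue;
        int start = i - seed_k + 1;  // read pos of k-mer start
        auto it = idx.map.find(key);
        if (it != idx.map.end())
          for (int c : it->second) diag_hits[c - start]++;
        auto it2 = idx_rc.map.find(key);
        if (it2 != idx_rc.map.end()) minus_hits += (int) it2->second.size();
      }
    }
    if (diag_hits.empty()) {
      out_status[r] = (minus_hits >= 3) ? 3 : 1;
      continue;
    }
    std::vector<std::pair<int,int>> diags(diag_hits.begin(), diag_hits.end());
    std::sort(diags.begin(), diags.end(),
              [](const std::pair<int,int> &a, const std::pair<int,int> &b) {
                if (a.second != b.second) return a.second > b.second;
                return a.first < b.first;
              });
    if ((int) diags.size() > 8) diags.resize(8);

    // --- per-candidate prey support DP -----------------------------------
    std::vector<PreyCand> cands;
    for (size_t ci = 0; ci < diags.size(); ++ci) {
      PreyCand pc;
      pc.dl = diags[ci].first;
      mp.assign(L + 2, 0);
      for (int i = 1; i <= L; ++i)
        mp[i] = prey.match(rd[i], i + pc.dl) ? 1 : -1;
      suf.assign(L + 2, 0);
      for (int i = L; i >= 1; --i) suf[i] = suf[i + 1] + mp[i];
      pc.best.assign(L + 2, 0);
      pc.argS.assign(L + 2, 0); pc.argJ.assign(L + 2, 0);
      for (int sp = 1; sp <= L; ++sp) pc.best[sp] = suf[sp];
      if (ci < 2) {
        for (int s = 1; s <= max_del && s < n_shift; ++s) {
          const int dj = pc.dl - s;
          const long pen = 5 + s;
          cumj.assign(L + 1, 0);
          for (int i = 1; i <= L; ++i)
            cumj[i] = cumj[i - 1] + (prey.match(rd[i], i + dj) ? 1 : -1);
          gmax.assign(L + 2, 0); gArg.assign(L + 2, 0);
          gmax[L + 1] = -1000000; gArg[L + 1] = -1;
          for (int j = L; j >= 0; --j) {
            long g = cumj[j] + suf[j + 1];
            if (g >= gmax[j + 1]) { gmax[j] = g; gArg[j] = j; }
            else { gmax[j] = gmax[j + 1]; gArg[j] = gArg[j + 1]; }
          }
          for (int sp = 1; sp <= L; ++sp) {
            // split j >= sp keeps the junction-adjacent segment non-empty.
            // On exact ties prefer the larger shift: its junction-adjacent
            // diagonal has the smaller prey column (final tie-break).
            long val = gmax[sp] - cumj[sp - 1] - pen;
            if (val >= pc.best[sp]) {
              pc.best[sp] = val; pc.argS[sp] = s; pc.argJ[sp] = gArg[sp];
            }
          }
        }
      }
      cands.push_back(std::move(pc));
    }

    // --- decomposition grid ----------------------------------------------
    Decomp best;
    const int eLo = std::max(plen, 1);
    const int eHi = L - 1;
    for (const PreyCand &pc : cands) {
      for (int e = eLo; e <= eHi; ++e) {
        const long sb = sbBest[e];
        if (sb < min_flank) continue;
        const int spLo = std::max(1, e - max_mh + 1);
        const int spHi = std::min(L, e + max_ins + 1);
        for (int sp = spLo; sp <= spHi; ++sp) {
          const long ps = pc.best[sp];
          if (ps < min_flank) continue;
          const int m = (e >= sp) ? (e - sp + 1) : 0;
          const long sc = sb + ps - m;
          const int pcol = sp + pc.dl - pc.argS[sp];
          if (!best.better(sc, m, e, sp, pcol)) continue;
          if (m > 0) {
            // MH tract must match both references exactly
            const int sB = sbS[e], jB = sbJ[e];
            const int sP = pc.argS[sp], jP = pc.argJ[sp];
            bool ok = true;
            for (int i = sp; i <= e; ++i) {
              int colB = p0 + i - 1 + ((sB > 0 && i > jB) ? sB : 0);
              int colP = i + pc.dl - ((sP > 0 && i <= jP) ? sP : 0);
              if (!bait.match(rd[i], colB) || !prey.match(rd[i], colP)) {
                ok = false; break;
              }
            }
            if (!ok) continue;
          }
          best.found = true; best.score = sc; best.mh = m;
          best.e = e; best.sp = sp; best.prey_col = pcol;
          best.cand_dl = pc.dl; best.sB = sbS[e]; best.jB = sbJ[e];
          best.sP = pc.argS[sp]; best.jP = pc.argJ[sp];
          best.bait_matched = sb; best.prey_matched = ps;
        }
      }
    }
    if (!best.found) {
      out_status[r] = (minus_hits >= 3) ? 3 : 1;
      continue;
    }

    // --- finalize ---------------------------------------------------------
    const int e = best.e, sp = best.sp;
    const int sB = best.sB, jB = best.jB, sP = best.sP, jP = best.jP;
    out_status[r] = 0;
    out_bait_end[r] = p0 + e - 1 + sB;
    out_prey_start[r] = sp + best.cand_dl - sP;
    out_mh[r] = best.mh;
    if (best.mh > 0) { out_mh_rs[r] = sp; out_mh_re[r] = e; }
    out_ins[r] = (sp > e + 1) ? rs.substr(e, sp - e - 1) : "";
    out_score[r] = (int) best.score;
    out_bait_matched[r] = (int) best.bait_matched;
    out_prey_matched[r] = (int) best.prey_matched;

    std::string dels;
    int ndel = 0;
    if (sB > 0) {
      dels += "bait:" + std::to_string(p0 + jB) + ":" + std::to_string(sB);
      ++ndel;
    }
    if (sP > 0 && jP >= sp && jP < L) {
      if (!dels.empty()) dels += ";";
      dels += "prey:" + std::to_string(jP + 1 + best.cand_dl - sP) + ":" +
              std::to_string(sP);
      ++ndel;
    }
    out_del[r] = dels;
    out_ndel[r] = ndel;

    // window read positions and their reference columns along the chosen path
    const int wbLo = std::max(1, e - window + 1);
    const int wpHi = std::min(L, sp + window - 1);
    // background per side: fewer alterations wins, tie -> B6
    int altb_b6 = 0, altb_s129 = 0, altp_b6 = 0, altp_s129 = 0;
    for (int i = wbLo; i <= e; ++i) {
      int col = p0 + i - 1 + ((sB > 0 && i > jB) ? sB : 0);
      if (col < 1 || col > bait.n) continue;
      if (bait.b6[col - 1] != rd[i]) ++altb_b6;
      if (bait.s129[col - 1] != rd[i]) ++altb_s129;
    }
    for (int i = sp; i <= wpHi; ++i) {
      int col = i + best.cand_dl - ((sP > 0 && i <= jP) ? sP : 0);
      if (col < 1 || col > prey.n) continue;
      if (prey.b6[col - 1] != rd[i]) ++altp_b6;
      if (prey.s129[col - 1] != rd[i]) ++altp_s129;
    }
    bool bait_is_b6 = altb_b6 <= altb_s129;
    bool prey_is_b6 = altp_b6 <= altp_s129;
    out_bgb[r] = bait_is_b6 ? "B6" : "S129";
    out_bgp[r] = prey_is_b6 ? "B6" : "S129";
    out_cross[r] = (bait_is_b6 != prey_is_b6);

    // mutations: window bases outside the allele set at unambiguous columns
    std::string muts;
    int nmut = 0;
    for (int i = wbLo; i <= e; ++i) {
      int col = p0 + i - 1 + ((sB > 0 && i > jB) ? sB : 0);
      if (col < 1 || col > bait.n || bait.ambig[col - 1]) continue;
      if (!bait.match(rd[i], col)) {
        char ref = bait_is_b6 ? bait.b6c[col - 1] : bait.s129c[col - 1];
        if (!muts.empty()) muts += ";";
        muts += "bait:" + std::to_string(col) + ":" + ref + ">" + rs[i - 1];
        ++nmut;
      }
    }
    for (int i = sp; i <= wpHi; ++i) {
      int col = i + best.cand_dl - ((sP > 0 && i <= jP) ? sP : 0);
      if (col < 1 || col > prey.n || prey.ambig[col - 1]) continue;
      if (!prey.match(rd[i], col)) {
        char ref = prey_is_b6 ? prey.b6c[col - 1] : prey.s129c[col - 1];
        if (!muts.empty()) muts += ";";
        muts += "prey:" + std::to_string(col) + ":" + ref + ">" + rs[i - 1];
        ++nmut;
      }
    }
    out_mut[r] = muts;
    out_nmut[r] = nmut;
  }

  return List::create(
    _["status"] = out_status,
    _["bait_end"] = out_bait_end,
    _["prey_start"] = out_prey_start,
    _["mh_len"] = out_mh,
    _["mh_read_start"] = out_mh_rs,
    _["mh_read_end"] = out_mh_re,
    _["insertion_seq"] = out_ins,
    _["deletions"] = out_del,
    _["n_deletions"] = out_ndel,
    _["mutations"] = out_mut,
    _["n_mutations"] = out_nmut,
    _["background_bait"] = out_bgb,
    _["background_prey"] = out_bgp,
    _["cross_background"] = out_cross,
    _["score"] = out_score,
    _["bait_matched"] = out_bait_matched,
    _["prey_matched"] = out_prey_matched);
}
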