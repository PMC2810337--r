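#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Nucleotide encoding: A=0 C=1 G=2 T=3, N/other=4, hard mask=5.
// Code 4 scores as a mismatch, code 5 blocks alignment entirely so that
// masked subject stretches cannot be crossed when hunting suboptimal HSPs.

static inline int enc_char(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case 'X': case 'x': return 5;
  default: return 4;
  }
}

static std::vector<uint8_t> enc_seq(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t) enc_char(s[i]);
  return v;
}

static std::vector<uint8_t> rc_enc(const std::vector<uint8_t> &v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? (uint8_t)(3 - b) : b;
  }
  return r;
}

static inline int sub_score(uint8_t a, uint8_t b, int match, int mismatch) {
  if (a == 5 || b == 5) return -1000000;
  if (a == 4 || b == 4) return mismatch;
  return (a == b) ? match : mismatch;
}

struct Hsp {
  int score, qstart, qend, sstart, send, identities, length, mismatches, gapopens;
};

// Full-matrix affine-gap Smith-Waterman with traceback. Gap of length L
// costs gap_open + L * gap_extend. Returns the single optimal local
// alignment; the caller drives suboptimal HSP discovery by masking.
static bool sw_one(const std::vector<uint8_t> &q, const std::vector<uint8_t> &s,
                   int match, int mismatch, int gap_open, int gap_extend,
                   int floor_score, Hsp &out) {
  const int m = (int) q.size(), n = (int) s.size();
  const int NEG = -1000000000;
  std::vector<int> Hrow(n + 1, 0), Erow(n + 1, NEG);
  // traceback: tbH 0 stop, 1 diag, 2 from E (gap in query row), 3 from F
  // tbE / tbF bit: 1 = extend (came from E/F), 0 = open (came from H)
  std::vector<uint8_t> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> Fcol(n + 1, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0;  // H[i-1][j-1]
    int E = NEG;    // E[i][j] running along row
    Hrow[0] = 0;
    size_t row = (size_t) i * (n + 1);
    for (int j = 1; j <= n; ++j) {
      int Hup = Hrow[j];  // H[i-1][j]
      // E: gap consuming subject (query pauses)
      int e_open = Hrow[j - 1] - gap_open - gap_extend;
      // careful: Hrow[j-1] currently holds H[i][j-1] (already updated)
      int e_ext = E - gap_extend;
      if (e_open >= e_ext) { E = e_open; tbE[row + j] = 0; }
      else { E = e_ext; tbE[row + j] = 1; }
      // F: gap consuming query
      int f_open = Hup - gap_open - gap_extend;
      int f_ext = Fcol[j] - gap_extend;
      int F;
      if (f_open >= f_ext) { F = f_open; tbF[row + j] = 0; }
      else { F = f_ext; tbF[row + j] = 1; }
      Fcol[j] = F;
      int diag = Hdiag + sub_score(q[i - 1], s[j - 1], match, mismatch);
      int h = 0; uint8_t tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E > h) { h = E; tb = 2; }
      if (F > h) { h = F; tb = 3; }
      Hdiag = Hup;
      Hrow[j] = h;
      tbH[row + j] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best < floor_score || best <= 0) return false;
  // traceback
  int i = bi, j = bj;
  int identities = 0, length = 0, mism = 0, gapopens = 0;
  while (i > 0 && j > 0) {
    size_t idx = (size_t) i * (n + 1) + j;
    uint8_t tb = tbH[idx];
    if (tb == 0) break;
    if (tb == 1) {
      ++length;
      if (q[i - 1] < 4 && q[i - 1] == s[j - 1]) ++identities; else ++mism;
      --i; --j;
    } else if (tb == 2) {
      // gap run along subject
      ++gapopens;
      while (true) {
        ++length; uint8_t ext = tbE[(size_t) i * (n + 1) + j]; --j;
        if (!ext) break;
      }
    } else {
      ++gapopens;
      while (true) {
        ++length; uint8_t ext = tbF[(size_t) i * (n + 1) + j]; --i;
        if (!ext) break;
      }
    }
  }
  out.score = best;
  out.qstart = i; out.qend = bi;       // 0-based half-open
  out.sstart = j; out.send = bj;
  out.identities = identities; out.length = length;
  out.mismatches = mism; out.gapopens = gapopens;
  return true;
}

// [[Rcpp::export]]
DataFrame cpp_sw_pair(std::string query, std::string subject,
                      int match, int mismatch, int gap_open, int gap_extend,
                      int floor_score, int max_hsps) {
  std::vector<uint8_t> q = enc_seq(query), s = enc_seq(subject);
  std::vector<Hsp> hsps;
  for (int k = 0; k < max_hsps; ++k) {
    Hsp h;
    if (!sw_one(q, s, match, mismatch, gap_open, gap_extend, floor_score, h))
      break;
    hsps.push_back(h);
    for (int j = h.sstart; j < h.send; ++j) s[j] = 5;  // mask and re-run
  }
  int nh = (int) hsps.size();
  IntegerVector score(nh), qs(nh), qe(nh), ss(nh), se(nh), idn(nh), len(nh),
      mm(nh), go(nh);
  for (int k = 0; k < nh; ++k) {
    score[k] = hsps[k].score; qs[k] = hsps[k].qstart; qe[k] = hsps[k].qend;
    ss[k] = hsps[k].sstart; se[k] = hsps[k].send;
    idn[k] = hsps[k].identities; len[k] = hsps[k].length;
    mm[k] = hsps[k].mismatches; go[k] = hsps[k].gapopens;
  }
  return DataFrame::create(_["score"] = score, _["qstart"] = qs,
                           _["qend"] = qe, _["sstart"] = ss, _["send"] = se,
                           _["identities"] = idn, _["length"] = len,
                           _["mismatches"] = mm, _["gapopens"] = go);
}

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > WordIndex;

static void index_words(const std::vector<uint8_t> &s, int sidx, int word,
                        WordIndex &ix) {
  if ((int) s.size() < word) return;
  uint64_t w = 0, mask = (1ULL << (2 * word)) - 1;
  int run = 0;
  for (int p = 0; p < (int) s.size(); ++p) {
    if (s[p] > 3) { run = 0; w = 0; continue; }
    w = ((w << 2) | s[p]) & mask;
    if (++run >= word) {
      int pos = p - word + 1;
      ix[w].push_back(((uint64_t)(uint32_t) sidx << 32) | (uint32_t) pos);
    }
  }
}

// Seed-and-window mapper: exact word matches seed candidate subject
// windows; each window is resolved by the full affine DP above. Queries
// are searched on both strands; minus-strand hits are reported with
// subject coordinates on the forward strand and query coordinates on the
// original (as-given) query orientation.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector queries, CharacterVector subjects,
                        int word, int match, int mismatch, int gap_open,
                        int gap_extend, int floor_score) {
  int ns = subjects.size(), nq = queries.size();
  std::vector<std::vector<uint8_t> > S(ns);
  WordIndex ix;
  for (int j = 0; j < ns; ++j) {
    S[j] = enc_seq(as<std::string>(subjects[j]));
    index_words(S[j], j, word, ix);
  }
  std::vector<int> o_q, o_s, o_score, o_qs, o_qe, o_ss, o_se, o_idn, o_len,
      o_mm, o_go;
  std::vector<int> o_strand;
  uint64_t mask = (1ULL << (2 * word)) - 1;
  for (int qi = 0; qi < nq; ++qi) {
    std::vector<uint8_t> qf = enc_seq(as<std::string>(queries[qi]));
    int m = (int) qf.size();
    for (int strand = 0; strand < 2; ++strand) {
      std::vector<uint8_t> q = strand ? rc_enc(qf) : qf;
      if (m < word) continue;
      // collect implied subject start offsets per subject
      std::unordered_map<int, std::vector<int> > origins;
      uint64_t w = 0; int run = 0;
      for (int p = 0; p < m; ++p) {
        if (q[p] > 3) { run = 0; w = 0; continue; }
        w = ((w << 2) | q[p]) & mask;
        if (++run >= word) {
          WordIndex::const_iterator it = ix.find(w);
          if (it == ix.end()) continue;
          int qpos = p - word + 1;
          for (size_t h = 0; h < it->second.size(); ++h) {
            int sj = (int)(it->second[h] >> 32);
            int spos = (int)(uint32_t) it->second[h];
            origins[sj].push_back(spos - qpos);
          }
        }
      }
      for (std::unordered_map<int, std::vector<int> >::iterator it =
               origins.begin(); it != origins.end(); ++it) {
        int sj = it->first;
        std::vector<int> &og = it->second;
        std::sort(og.begin(), og.end());
        og.erase(std::unique(og.begin(), og.end()), og.end());
        int n = (int) S[sj].size();
        size_t a = 0;
        while (a < og.size()) {
          size_t b = a;
          while (b + 1 < og.size() && og[b + 1] - og[b] <= m) ++b;
          int lo = og[a] - 32, hi = og[b] + m + m + 32;
          if (lo < 0) lo = 0;
          if (hi > n) hi = n;
          std::vector<uint8_t> win(S[sj].begin() + lo, S[sj].begin() + hi);
          Hsp hsp;
          if (sw_one(q, win, match, mismatch, gap_open, gap_extend,
                     floor_score, hsp)) {
            int qs = hsp.qstart, qe = hsp.qend;
            if (strand) { qs = m - hsp.qend; qe = m - hsp.qstart; }
            o_q.push_back(qi + 1); o_s.push_back(sj + 1);
            o_strand.push_back(strand);
            o_score.push_back(hsp.score);
            o_qs.push_back(qs); o_qe.push_back(qe);
            o_ss.push_back(hsp.sstart + lo); o_se.push_back(hsp.send + lo);
            o_idn.push_back(hsp.identities); o_len.push_back(hsp.length);
            o_mm.push_back(hsp.mismatches); o_go.push_back(hsp.gapopens);
          }
          a = b + 1;
        }
      }
    }
  }
  int nh = (int) o_q.size();
  CharacterVector strand_out(nh);
  for (int k = 0; k < nh; ++k) strand_out[k] = o_strand[k] ? "-" : "+";
  return DataFrame::create(
      _["qidx"] = wrap(o_q), _["sidx"] = wrap(o_s), _["strand"] = strand_out,
      _["score"] = wrap(o_score), _["qstart"] = wrap(o_qs),
      _["qend"] = wrap(o_qe), _["sstart"] = wrap(o_ss),
      _["send"] = wrap(o_se), _["identities"] = wrap(o_idn),
      _["length"] = wrap(o_len), _["mismatches"] = wrap(o_mm),
      _["gapopens"] = wrap(o_go));
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t k = 0; k < s.size(); ++k) {
      char c = s[s.size() - 1 - k];
      switch (c) {
      case 'A': r[k] = 'T'; break; case 'T': r[k] = 'A'; break;
      case 'C': r[k] = 'G'; break; case 'G': r[k] = 'C'; break;
      case 'a': r[k] = 't'; break; case 't': r[k] = 'a'; break;
      case 'c': r[k] = 'g'; break; case 'g': r[k] = 'c'; break;
      default: r[k] = c;
      }
    }
    out[i] = r;
  }
  return out;
}
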