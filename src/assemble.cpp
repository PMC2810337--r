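#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// Greedy suffix-prefix overlap assembler with majority-vote consensus.
// Entities (reads, then growing contigs) are immutable; every merge kills
// two entities and creates a new one, so heap entries only need liveness
// checks. Overlaps are gap-free: a shared k-mer fixes the candidate
// overlap length exactly, which keeps candidate discovery cheap.

static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0; case 'C': case 'c': return 1;
  case 'G': case 'g': return 2; case 'T': case 't': return 3;
  default: return 4;
  }
}

struct Entity {
  std::vector<uint8_t> seq;          // consensus
  std::vector<int> cnt;              // 4 * len base counts
  std::vector<int> members;          // input read indices
  std::string id;                    // lexicographically smallest member id
  bool alive;
};

struct Cand {
  int olen;
  std::string id1, id2;  // tie-break key (sorted pair of entity ids)
  int left, right;       // entity indices; right may be used reverse-complemented
  int combo;             // 0: L+ R+ ; 1: L+ rc(R) ; 2: rc(R) then L
  bool operator<(const Cand &o) const {
    if (olen != o.olen) return olen < o.olen;          // max-heap on length
    if (id1 != o.id1) return id1 > o.id1;              // then smallest ids
    if (id2 != o.id2) return id2 > o.id2;
    return combo > o.combo;
  }
};

static std::vector<uint8_t> rc_seq(const std::vector<uint8_t> &s) {
  std::vector<uint8_t> r(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    uint8_t b = s[s.size() - 1 - i];
    r[i] = (b < 4) ? (uint8_t)(3 - b) : b;
  }
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > WIx;

static void add_words(const std::vector<uint8_t> &s, int eidx, int k, WIx &ix) {
  if ((int) s.size() < k) return;
  uint64_t w = 0, mask = (1ULL << (2 * k)) - 1;
  int run = 0;
  for (int p = 0; p < (int) s.size(); ++p) {
    if (s[p] > 3) { run = 0; w = 0; continue; }
    w = ((w << 2) | s[p]) & mask;
    if (++run >= k)
      ix[w].push_back(((uint64_t)(uint32_t) eidx << 32) |
                      (uint32_t)(p - k + 1));
  }
}

// matches in the gap-free overlap of suffix of A (last o) vs prefix of B
static inline bool ok_overlap(const std::vector<uint8_t> &A,
                              const std::vector<uint8_t> &B, int o,
                              double min_identity) {
  int a = (int) A.size();
  int matches = 0;
  int allowed_mm = o - (int) std::ceil(min_identity * o);
  int mm = 0;
  for (int t = 0; t < o; ++t) {
    uint8_t x = A[a - o + t], y = B[t];
    if (x < 4 && x == y) ++matches;
    else if (++mm > allowed_mm) return false;
  }
  return ((double) matches / o) >= min_identity;
}

class Assembler {
public:
  std::vector<Entity> ents;
  WIx ix;
  int k, min_overlap;
  double min_identity;
  std::priority_queue<Cand> heap;

  // enumerate candidate merges between entity e and all indexed entities
  void find_candidates(int e, bool only_before) {
    const Entity &E = ents[e];
    int la = (int) E.seq.size();
    // map: partner -> set of (combo, olen)
    std::unordered_map<int, std::vector<std::pair<int, int> > > cands;
    uint64_t mask = (1ULL << (2 * k)) - 1;
    // forward-word hits
    uint64_t w = 0; int run = 0;
    for (int p = 0; p < la; ++p) {
      if (E.seq[p] > 3) { run = 0; w = 0; continue; }
      w = ((w << 2) | E.seq[p]) & mask;
      if (++run >= k) {
        int qpos = p - k + 1;
        add_hits(w, e, qpos, la, 0, only_before, cands);
        add_hits(rc_word(w), e, qpos, la, 1, only_before, cands);
      }
    }
    // evaluate
    for (std::unordered_map<int, std::vector<std::pair<int, int> > >::iterator
             it = cands.begin(); it != cands.end(); ++it) {
      int f = it->first;
      if (!ents[f].alive || f == e) continue;
      const Entity &F = ents[f];
      std::vector<uint8_t> rcF;
      bool have_rc = false;
      // best overlap per combo
      int best[4] = {0, 0, 0, 0};  // combos: 0 e->f, 1 f->e, 2 e->rc(f), 3 rc(f)->e
      std::vector<std::pair<int, int> > &v = it->second;
      std::sort(v.begin(), v.end());
      v.erase(std::unique(v.begin(), v.end()), v.end());
      for (size_t t = 0; t < v.size(); ++t) {
        int combo = v[t].first, o = v[t].second;
        if (o < min_overlap || o > (int) std::min(E.seq.size(), F.seq.size()))
          continue;
        if (o <= best[combo]) continue;
        bool good = false;
        switch (combo) {
        case 0: good = ok_overlap(E.seq, F.seq, o, min_identity); break;
        case 1: good = ok_overlap(F.seq, E.seq, o, min_identity); break;
        case 2: case 3:
          if (!have_rc) { rcF = rc_seq(F.seq); have_rc = true; }
          good = (combo == 2) ? ok_overlap(E.seq, rcF, o, min_identity)
                              : ok_overlap(rcF, E.seq, o, min_identity);
          break;
        }
        if (good) best[combo] = o;
      }
      for (int combo = 0; combo < 4; ++combo) {
        if (!best[combo]) continue;
        Cand c;
        c.olen = best[combo];
        c.id1 = std::min(E.id, F.id); c.id2 = std::max(E.id, F.id);
        switch (combo) {
        case 0: c.left = e; c.right = f; c.combo = 0; break;
        case 1: c.left = f; c.right = e; c.combo = 0; break;
        case 2: c.left = e; c.right = f; c.combo = 1; break;  // e + rc(f)
        case 3: c.left = e; c.right = f; c.combo = 2; break;  // rc(f) + e
        }
        heap.push(c);
      }
    }
  }

  uint64_t rc_word(uint64_t w) {
    uint64_t r = 0;
    for (int t = 0; t < k; ++t) { r = (r << 2) | (3 - (w & 3)); w >>= 2; }
    return r;
  }

  // hits of word w against index; rc==1 means w was reverse-complemented,
  // so a hit at fpos in F corresponds to position len(F)-fpos-k on rc(F).
  void add_hits(uint64_t w, int e, int qpos, int la, int rc, bool only_before,
                std::unordered_map<int, std::vector<std::pair<int, int> > > &cands) {
    WIx::const_iterator it = ix.find(w);
    if (it == ix.end()) return;
    for (size_t h = 0; h < it->second.size(); ++h) {
      int f = (int)(it->second[h] >> 32);
      if (f == e || !ents[f].alive) continue;
      if (only_before && f > e) continue;
      int fpos = (int)(uint32_t) it->second[h];
      int lb = (int) ents[f].seq.size();
      if (!rc) {
        cands[f].push_back(std::make_pair(0, la - qpos + fpos));   // e->f
        cands[f].push_back(std::make_pair(1, lb - fpos + qpos));   // f->e
      } else {
        int fpos2 = lb - fpos - k;  // position on rc(F)
        cands[f].push_back(std::make_pair(2, la - qpos + fpos2));  // e->rc(f)
        cands[f].push_back(std::make_pair(3, lb - fpos2 + qpos));  // rc(f)->e
      }
    }
  }

  void merge(const Cand &c) {
    Entity &L0 = ents[c.left];
    Entity &R0 = ents[c.right];
    // build oriented count/seq views
    std::vector<int> cl, cr;
    int la, lb;
    if (c.combo == 0) {          // left fwd + right fwd
      cl = L0.cnt; la = (int) L0.seq.size();
      cr = R0.cnt; lb = (int) R0.seq.size();
    } else if (c.combo == 1) {   // left fwd + rc(right)
      cl = L0.cnt; la = (int) L0.seq.size();
      cr = rc_cnt(R0.cnt); lb = (int) R0.seq.size();
    } else {                     // rc(right) + left
      cl = rc_cnt(R0.cnt); la = (int) R0.seq.size();
      cr = L0.cnt; lb = (int) L0.seq.size();
    }
    int o = c.olen;
    int nl = la + lb - o;
    Entity N;
    N.cnt.assign((size_t) nl * 4, 0);
    for (int p = 0; p < la; ++p)
      for (int b = 0; b < 4; ++b) N.cnt[(size_t) p * 4 + b] = cl[(size_t) p * 4 + b];
    for (int p = 0; p < lb; ++p)
      for (int b = 0; b < 4; ++b)
        N.cnt[(size_t)(la - o + p) * 4 + b] += cr[(size_t) p * 4 + b];
    N.seq.resize(nl);
    for (int p = 0; p < nl; ++p) {
      int bb = 0, bc = N.cnt[(size_t) p * 4];
      for (int b = 1; b < 4; ++b)
        if (N.cnt[(size_t) p * 4 + b] > bc) { bc = N.cnt[(size_t) p * 4 + b]; bb = b; }
      N.seq[p] = (uint8_t) bb;
    }
    N.members = L0.members;
    N.members.insert(N.members.end(), R0.members.begin(), R0.members.end());
    N.id = std::min(L0.id, R0.id);
    N.alive = true;
    L0.alive = false; R0.alive = false;
    ents.push_back(N);
    int e = (int) ents.size() - 1;
    add_words(ents[e].seq, e, k, ix);
    find_candidates(e, false);
  }

  static std::vector<int> rc_cnt(const std::vector<int> &c) {
    int L = (int) c.size() / 4;
    std::vector<int> r((size_t) L * 4);
    for (int p = 0; p < L; ++p)
      for (int b = 0; b < 4; ++b)
        r[(size_t) p * 4 + b] = c[(size_t)(L - 1 - p) * 4 + (3 - b)];
    return r;
  }
};

// [[Rcpp::export]]
List cpp_greedy_assemble(CharacterVector ids, CharacterVector seqs,
                         int min_overlap, double min_identity, int kmer) {
  Assembler A;
  A.k = kmer; A.min_overlap = min_overlap; A.min_identity = min_identity;
  int n = ids.size();
  for (int i = 0; i < n; ++i) {
    Entity e;
    std::string s = as<std::string>(seqs[i]);
    e.seq.resize(s.size());
    for (size_t p = 0; p < s.size(); ++p) e.seq[p] = (uint8_t) enc(s[p]);
    e.cnt.assign(e.seq.size() * 4, 0);
    for (size_t p = 0; p < e.seq.size(); ++p)
      if (e.seq[p] < 4) e.cnt[p * 4 + e.seq[p]] = 1;
    e.members.push_back(i);
    e.id = as<std::string>(ids[i]);
    e.alive = true;
    A.ents.push_back(e);
  }
  for (int i = 0; i < n; ++i) add_words(A.ents[i].seq, i, kmer, A.ix);
  for (int i = 0; i < n; ++i) A.find_candidates(i, true);
  while (!A.heap.empty()) {
    Cand c = A.heap.top(); A.heap.pop();
    if (!A.ents[c.left].alive || !A.ents[c.right].alive) continue;
    A.merge(c);
  }
  const char *BASES = "ACGTN";
  std::vector<std::string> contig_seq;
  List contig_members;
  std::vector<int> singletons;
  for (size_t e = 0; e < A.ents.size(); ++e) {
    if (!A.ents[e].alive) continue;
    if (A.ents[e].members.size() >= 2) {
      std::string s(A.ents[e].seq.size(), 'N');
      for (size_t p = 0; p < A.ents[e].seq.size(); ++p)
        s[p] = BASES[A.ents[e].seq[p] > 4 ? 4 : A.ents[e].seq[p]];
      contig_seq.push_back(s);
      IntegerVector mem(A.ents[e].members.begin(), A.ents[e].members.end());
      contig_members.push_back(mem + 1);  // 1-based read indices
    } else {
      singletons.push_back(A.ents[e].members[0] + 1);
    }
  }
  return List::create(_["contig_seq"] = wrap(contig_seq),
                      _["contig_members"] = contig_members,
                      _["singletons"] = wrap(singletons));
}
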