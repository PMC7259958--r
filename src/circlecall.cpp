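#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <tuple>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// base encoding: A=0 C=1 G=2 T=3, anything else = 4
static inline int bcode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}
static const char BCHR[5] = {'A', 'C', 'G', 'T', 'N'};
static inline char bcomp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

// ---------------------------------------------------------------------------
// Tandem-repeat period detection by autocorrelation.
// f(P) = #{i : b[i] == b[i+P], both non-N} / #{i <= L-P : both non-N}
// Best P = argmax f(P); ties broken toward the smallest P (fundamental period).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_detect_periods(CharacterVector seqs, int min_period, int max_period) {
  const int n = seqs.size();
  IntegerVector P(n), r(n), L(n);
  NumericVector f(n);
  for (int s = 0; s < n; ++s) {
    const char *b = CHAR(STRING_ELT(seqs, s));
    int len = LENGTH(STRING_ELT(seqs, s));
    L[s] = len;
    int pmax = std::min(max_period, len / 2);
    if (len < 2 * min_period || pmax < min_period) {
      P[s] = NA_INTEGER; r[s] = NA_INTEGER; f[s] = NA_REAL;
      continue;
    }
    std::vector<signed char> code(len);
    for (int i = 0; i < len; ++i) code[i] = (signed char)bcode(b[i]);
    int bestP = -1; double bestf = -1.0;
    for (int p = min_period; p <= pmax; ++p) {
      int num = 0, den = 0;
      for (int i = 0; i + p < len; ++i) {
        if (code[i] == 4 || code[i + p] == 4) continue;
        ++den;
        if (code[i] == code[i + p]) ++num;
      }
      double fp = den > 0 ? (double)num / den : 0.0;
      if (fp > bestf + 1e-12) { bestf = fp; bestP = p; }
    }
    P[s] = bestP; f[s] = bestf; r[s] = len / bestP;
  }
  return DataFrame::create(_["length"] = L, _["period"] = P,
                           _["identity"] = f, _["repeats"] = r);
}

// ---------------------------------------------------------------------------
// Bayesian consensus over repeat columns.
// Column j collects calls b[j + k*P] with Phred(+33)-decoded error probs.
// posterior(a) \propto prod_k [1 - eps_k if call_k == a else eps_k/3]
// (uniform prior over A,C,G,T). Consensus = argmax; q = 1 - posterior(max).
// Posterior ties and all-N columns emit 'N' with q = 1.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_build_consensus(CharacterVector seqs, CharacterVector quals,
                         IntegerVector periods, double eps_floor = 1e-6) {
  const int n = seqs.size();
  CharacterVector cons(n);
  List qout(n), dout(n);
  for (int s = 0; s < n; ++s) {
    const char *b = CHAR(STRING_ELT(seqs, s));
    const char *qc = CHAR(STRING_ELT(quals, s));
    int len = LENGTH(STRING_ELT(seqs, s));
    int P = periods[s];
    if (P == NA_INTEGER || P <= 0 || P > len) {
      cons[s] = NA_STRING; qout[s] = R_NilValue; dout[s] = R_NilValue;
      continue;
    }
    std::string cseq(P, 'N');
    NumericVector q(P);
    IntegerVector d(P);
    for (int j = 0; j < P; ++j) {
      double lp[4] = {0.0, 0.0, 0.0, 0.0};
      int ncall = 0, depth = 0;
      for (int idx = j; idx < len; idx += P) {
        ++depth;
        int a = bcode(b[idx]);
        if (a == 4) continue;
        double eps = std::pow(10.0, -((double)(qc[idx] - 33)) / 10.0);
        if (eps < eps_floor) eps = eps_floor;
        if (eps > 0.75) eps = 0.75;
        double lmatch = std::log1p(-eps), lmis = std::log(eps / 3.0);
        for (int a2 = 0; a2 < 4; ++a2) lp[a2] += (a2 == a) ? lmatch : lmis;
        ++ncall;
      }
      d[j] = depth;
      if (ncall == 0) { cseq[j] = 'N'; q[j] = 1.0; continue; }
      int best = 0;
      for (int a2 = 1; a2 < 4; ++a2) if (lp[a2] > lp[best]) best = a2;
      bool tie = false;
      double rel = 0.0, tot = 0.0;
      for (int a2 = 0; a2 < 4; ++a2) {
        double e = std::exp(lp[a2] - lp[best]);
        tot += e;
        if (a2 != best) {
          rel += e;
          if (lp[best] - lp[a2] < 1e-9) tie = true;
        }
      }
      if (tie) { cseq[j] = 'N'; q[j] = 1.0; }
      else { cseq[j] = BCHR[best]; q[j] = rel / tot; }
    }
    cons[s] = cseq;
    qout[s] = q;
    dout[s] = d;
  }
  return List::create(_["consensus"] = cons, _["q"] = qout, _["depth"] = dout);
}

// ---------------------------------------------------------------------------
// Fragment mapping: a tandem duplicate of each consensus is anchored to the
// reference by exact k-mer seeding and diagonal voting; on each candidate
// diagonal the period-length window is placed where the exact-match count is
// maximal (prefix-sum scan over all rotations).  A small search over paired
// diagonals (offset 1..3) recovers single short indels.  The longest mapped
// block of the duplicate is the chosen window; its start fixes the rotation
// (junction) and the reference anchor.
// ---------------------------------------------------------------------------

struct Cand { int ref; int strand; long diag; int votes; };
struct Hit {
  int ref, strand;
  long anchor;        // 0-based ref start of fragment window
  int t;              // window start within (possibly revcomp'd) duplicate
  int score;          // exact matches within window
  int indel_type;     // 0 none, 1 deletion (ref bases absent from query), 2 insertion
  int indel_qoff;     // fragment offset after which the event occurs
  int indel_len;
};

static void window_scan(const std::string &s, const char *ref, int reflen,
                        long diag, int P, Hit &h) {
  // ungapped: score(t) = sum_{i=t}^{t+P-1} match(s[i], ref[diag+i])
  int L2 = s.size();
  int tlo = (int)std::max(0L, -diag);
  int thi = (int)std::min((long)(L2 - P), (long)reflen - diag - P);
  h.score = -1;
  if (thi < tlo) return;
  std::vector<int> pref(L2 + 1, 0);
  for (int i = 0; i < L2; ++i) {
    long rp = diag + i;
    int m = (rp >= 0 && rp < reflen && s[i] == ref[rp] && s[i] != 'N') ? 1 : 0;
    pref[i + 1] = pref[i] + m;
  }
  for (int t = tlo; t <= thi; ++t) {
    int sc = pref[t + P] - pref[t];
    if (sc > h.score) { h.score = sc; h.t = t; }
  }
  h.anchor = diag + h.t;
  h.indel_type = 0; h.indel_qoff = 0; h.indel_len = 0;
}

static void gapped_scan(const std::string &s, const char *ref, int reflen,
                        long diag, int P, int max_gap, Hit &h) {
  // deletion of g ref bases after fragment offset d: tail aligns on diag+g
  // insertion of g query bases at fragment offset d: inserted bases unaligned,
  // tail aligns on diag-g
  int L2 = s.size();
  std::vector<std::vector<int> > prefs(2 * max_gap + 1);
  for (int gi = -max_gap; gi <= max_gap; ++gi) {
    long dg = diag + gi;
    std::vector<int> &pf = prefs[gi + max_gap];
    pf.assign(L2 + 1, 0);
    for (int i = 0; i < L2; ++i) {
      long rp = dg + i;
      int m = (rp >= 0 && rp < reflen && s[i] == ref[rp] && s[i] != 'N') ? 1 : 0;
      pf[i + 1] = pf[i] + m;
    }
  }
  const std::vector<int> &p0 = prefs[max_gap];
  for (int g = 1; g <= max_gap; ++g) {
    // deletion: head on diag, tail on diag+g; window spans ref [anchor, anchor+P+g)
    const std::vector<int> &pd = prefs[max_gap + g];
    for (int t = (int)std::max(0L, -diag); t + P <= L2; ++t) {
      if (diag + t < 0 || diag + t + P + g > reflen) continue;
      for (int d = 1; d < P; ++d) {
        int sc = (p0[t + d] - p0[t]) + (pd[t + P] - pd[t + d]);
        if (sc > h.score) {
          h.score = sc; h.t = t; h.anchor = diag + t;
          h.indel_type = 1; h.indel_qoff = d; h.indel_len = g;
        }
      }
    }
    // insertion: head on diag, g query bases unaligned, tail on diag-g
    const std::vector<int> &pi = prefs[max_gap - g];
    for (int t = (int)std::max(0L, -diag); t + P <= L2; ++t) {
      if (diag + t < 0 || diag + t + P - g > reflen) continue;
      for (int d = 1; d + g < P; ++d) {
        int sc = (p0[t + d] - p0[t]) + (pi[t + P] - pi[t + d + g]);
        if (sc > h.score) {
          h.score = sc; h.t = t; h.anchor = diag + t;
          h.indel_type = 2; h.indel_qoff = d; h.indel_len = g;
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_map_fragments(CharacterVector refs, CharacterVector queries,
                       int k = 15, double min_block_identity = 0.9,
                       int max_gap = 3, int max_candidates = 16,
                       int seed_step = 5, int max_kmer_hits = 64) {
  const int nref = refs.size(), nq = queries.size();
  std::vector<std::string> R(nref);
  for (int i = 0; i < nref; ++i) R[i] = as<std::string>(refs[i]);

  // k-mer index of the forward reference strands
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > index;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int ri = 0; ri < nref; ++ri) {
    const std::string &rs = R[ri];
    uint64_t key = 0; int run = 0;
    for (size_t i = 0; i < rs.size(); ++i) {
      int c = bcode(rs[i]);
      if (c == 4) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[key].push_back(std::make_pair(ri, (int)(i + 1 - k)));
    }
  }

  std::vector<int> o_qid, o_ref, o_rot, o_score, o_nloci, o_itype, o_iqoff,
    o_ilen, o_period, o_anchor, o_strand;
  std::vector<std::string> o_frag;
  std::vector<std::vector<int> > o_qidx;
  IntegerVector status(nq);   // 0 ok, 1 no-seed, 2 below-identity (junction unresolved)

  for (int qi = 0; qi < nq; ++qi) {
    if (StringVector::is_na(queries[qi])) { status[qi] = 1; continue; }
    std::string cons = as<std::string>(queries[qi]);
    int P = cons.size();
    std::string cc = cons + cons;
    std::string rc(cc.rbegin(), cc.rend());
    for (size_t i = 0; i < rc.size(); ++i) rc[i] = bcomp(rc[i]);
    const std::string *strands[2] = {&cc, &rc};

    // seed and vote per (ref, strand, diagonal)
    std::map<std::tuple<int, int, long>, int> votes;
    for (int st = 0; st < 2; ++st) {
      const std::string &s = *strands[st];
      for (int off = 0; off + k <= (int)s.size(); off += seed_step) {
        uint64_t key = 0; bool ok = true;
        for (int j = 0; j < k; ++j) {
          int c = bcode(s[off + j]);
          if (c == 4) { ok = false; break; }
          key = ((key << 2) | (uint64_t)c) & mask;
        }
        if (!ok) continue;
        std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >::iterator it =
          index.find(key);
        if (it == index.end()) continue;
        if ((int)it->second.size() > max_kmer_hits) continue;
        for (size_t h = 0; h < it->second.size(); ++h)
          votes[std::make_tuple(it->second[h].first, st,
                                (long)it->second[h].second - off)] += 1;
      }
    }
    if (votes.empty()) { status[qi] = 1; continue; }

    std::vector<Cand> cands;
    for (std::map<std::tuple<int, int, long>, int>::iterator it = votes.begin();
         it != votes.end(); ++it) {
      Cand c; c.ref = std::get<0>(it->first); c.strand = std::get<1>(it->first);
      c.diag = std::get<2>(it->first); c.votes = it->second;
      cands.push_back(c);
    }
    std::sort(cands.begin(), cands.end(),
              [](const Cand &a, const Cand &b) { return a.votes > b.votes; });
    if ((int)cands.size() > max_candidates) cands.resize(max_candidates);

    std::vector<Hit> hits;
    int best_ungapped = -1;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      const Cand &c = cands[ci];
      Hit h; h.ref = c.ref; h.strand = c.strand;
      const std::string &s = *strands[c.strand];
      window_scan(s, R[c.ref].c_str(), R[c.ref].size(), c.diag, P, h);
      if (h.score < 0) continue;
      if (h.score > best_ungapped) best_ungapped = h.score;
      hits.push_back(h);
    }
    if (hits.empty()) { status[qi] = 1; continue; }
    // gapped rescue only when no candidate explains the fragment ungapped
    // (an indel breaks the single-diagonal window; substitutions do not)
    if (best_ungapped < P - 2 && max_gap > 0) {
      for (size_t ci = 0; ci < hits.size(); ++ci) {
        const std::string &s = *strands[hits[ci].strand];
        // recover the candidate diagonal of the ungapped window
        long diag = hits[ci].anchor - hits[ci].t;
        gapped_scan(s, R[hits[ci].ref].c_str(), R[hits[ci].ref].size(),
                    diag, P, max_gap, hits[ci]);
      }
    }

    // deduplicate hits pointing at the same locus (anchor within P/2)
    std::vector<Hit> loci;
    std::sort(hits.begin(), hits.end(),
              [](const Hit &a, const Hit &b) { return a.score > b.score; });
    for (size_t i = 0; i < hits.size(); ++i) {
      bool dup = false;
      for (size_t j = 0; j < loci.size(); ++j) {
        if (hits[i].ref == loci[j].ref && hits[i].strand == loci[j].strand &&
            std::labs(hits[i].anchor - loci[j].anchor) < P / 2) { dup = true; break; }
      }
      if (!dup) loci.push_back(hits[i]);
    }
    const Hit &best = loci[0];
    if ((double)best.score / P < min_block_identity) { status[qi] = 2; continue; }
    int nloci = 0;
    for (size_t j = 0; j < loci.size(); ++j)
      if (loci[j].score >= best.score - 1) ++nloci;

    const std::string &s = *strands[best.strand];
    std::vector<int> qidx(P);
    for (int i = 0; i < P; ++i) {
      if (best.strand == 0) qidx[i] = (best.t + i) % P;
      else qidx[i] = ((2 * P - 1 - best.t - i) % P + P) % P;
    }
    o_qid.push_back(qi + 1);
    o_ref.push_back(best.ref + 1);
    o_anchor.push_back((int)best.anchor + 1);  // 1-based ref start
    o_strand.push_back(best.strand);
    o_rot.push_back(best.t % P);
    o_score.push_back(best.score);
    o_period.push_back(P);
    o_nloci.push_back(nloci);
    o_itype.push_back(best.indel_type);
    o_iqoff.push_back(best.indel_qoff);
    o_ilen.push_back(best.indel_len);
    o_frag.push_back(s.substr(best.t, P));
    o_qidx.push_back(qidx);
    status[qi] = 0;
  }

  const int na = o_qid.size();
  CharacterVector strand_out(na), frag_out(na);
  List qidx_out(na);
  for (int i = 0; i < na; ++i) {
    strand_out[i] = o_strand[i] == 0 ? "+" : "-";
    frag_out[i] = o_frag[i];
    qidx_out[i] = wrap(o_qidx[i]);
  }
  DataFrame tab = DataFrame::create(
    _["query"] = wrap(o_qid), _["ref"] = wrap(o_ref), _["start"] = wrap(o_anchor),
    _["strand"] = strand_out, _["rotation"] = wrap(o_rot), _["period"] = wrap(o_period),
    _["score"] = wrap(o_score), _["n_loci"] = wrap(o_nloci),
    _["indel_type"] = wrap(o_itype), _["indel_qoff"] = wrap(o_iqoff),
    _["indel_len"] = wrap(o_ilen), _["fwd_frag"] = frag_out,
    _["stringsAsFactors"] = false);
  return List::create(_["table"] = tab, _["qidx"] = qidx_out, _["status"] = status);
}

// ---------------------------------------------------------------------------
// Pileup accumulation in forward-reference space, bucketed by alignment strand.
// Only assayed fragment positions (4-nt trim both ends) with a non-N call and
// posterior error probability q <= q_max contribute; excluded calls contribute
// nothing, including to coverage.  Indel events at assayed offsets are tallied
// at their reference positions.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_accumulate_pileup(IntegerVector ref_len,
                           IntegerVector frag_ref, IntegerVector anchor,
                           IntegerVector strand, CharacterVector fwd_frag,
                           List qidx, List qvals,
                           IntegerVector indel_type, IntegerVector indel_qoff,
                           IntegerVector indel_len,
                           int trim = 4, double q_max = 1e-7) {
  const int nref = ref_len.size(), nf = frag_ref.size();
  std::vector<IntegerMatrix> counts;  // 12 x L: A+,C+,G+,T+,A-,C-,G-,T-,ins+,ins-,del+,del-
  for (int i = 0; i < nref; ++i) counts.push_back(IntegerMatrix(12, ref_len[i]));

  for (int fi = 0; fi < nf; ++fi) {
    int ri = frag_ref[fi] - 1;
    long a0 = anchor[fi] - 1;
    int st = strand[fi];                  // 0 = +, 1 = -
    const char *frag = CHAR(STRING_ELT(fwd_frag, fi));
    int P = LENGTH(STRING_ELT(fwd_frag, fi));
    IntegerVector qx = qidx[fi];
    NumericVector qv = qvals[fi];
    int itype = indel_type[fi], iqoff = indel_qoff[fi], ilen = indel_len[fi];
    IntegerMatrix &M = counts[ri];
    int L = ref_len[ri];

    for (int i = 0; i < P; ++i) {
      // transcript-orientation offset of this forward position (trim is applied
      // on the reorganized consensus; symmetric, so forward offsets suffice)
      if (i < trim || i >= P - trim) continue;
      if (itype == 2 && i >= iqoff && i < iqoff + ilen) continue;  // inserted bases
      long rp;
      if (itype == 1) rp = a0 + i + (i >= iqoff ? ilen : 0);
      else if (itype == 2) rp = a0 + i - (i >= iqoff + ilen ? ilen : 0);
      else rp = a0 + i;
      if (rp < 0 || rp >= L) stop("fragment position outside replicon bounds");
      int b = bcode(frag[i]);
      if (b == 4) continue;
      if (qv[qx[i]] > q_max) continue;
      M(st * 4 + b, rp) += 1;
    }
    if (itype == 1 && iqoff >= trim && iqoff <= P - trim) {
      for (int g = 0; g < ilen; ++g) {
        long rp = a0 + iqoff + g;
        if (rp >= 0 && rp < L) M(10 + st, rp) += 1;
      }
    }
    if (itype == 2 && iqoff >= trim && iqoff + ilen <= P - trim) {
      long rp = a0 + iqoff;
      if (rp >= 0 && rp < L) M(8 + st, rp) += 1;
    }
  }
  List out(nref);
  for (int i = 0; i < nref; ++i) out[i] = counts[i];
  return out;
}
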