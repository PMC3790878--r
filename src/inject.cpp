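#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Per-read error injection.  For each output cycle c:
//   1. draw a PHRED score q from the per-cycle quality distribution,
//   2. with probability p = 10^(-q/10) inject an error,
//   3. error type ~ (p_ins, p_del, p_sub):
//        substitution: replace the current template base via the
//                      row-conditional substitution matrix (template N
//                      emits a uniform random base),
//        insertion:    emit a uniform random base, template not consumed,
//        deletion:     skip one template base, re-attempt cycle c
//                      (fresh quality draw at the same cycle).
// Output length equals the requested length; the caller over-fetches the
// template to absorb deletions and regenerates reads whose template is
// exhausted anyway.  True CIGAR/MD strings of the injected alignment are
// returned for oracle alignments.

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'T': return 1;
    case 'C': return 2; case 'G': return 3;
    default: return -1;
  }
}
static const char BASE_CHR[4] = {'A', 'T', 'C', 'G'};

struct CigarBuilder {
  std::string s;
  char last = 0;
  int run = 0;
  void push(char op) {
    if (op == last) { ++run; return; }
    flush();
    last = op; run = 1;
  }
  void flush() {
    if (run > 0) { s += std::to_string(run); s += last; }
    run = 0; last = 0;
  }
};

struct MdBuilder {
  std::string s;
  int match = 0;
  bool in_del = false;
  void match1() { ++match; in_del = false; }
  void mismatch(char ref) {
    s += std::to_string(match); match = 0;
    s += ref; in_del = false;
  }
  void del(char ref) {
    if (!in_del) { s += std::to_string(match); match = 0; s += '^'; }
    s += ref; in_del = true;
  }
  void flush() { s += std::to_string(match); }
};

// [[Rcpp::export]]
List inject_errors_batch_cpp(CharacterVector templates,
                             IntegerVector target_len,
                             NumericMatrix qual_cdf,   // n_cycles x n_scores
                             IntegerVector qual_scores,
                             NumericVector err_prob,   // per score
                             NumericVector type_cum,   // (ins, ins+del, 1)
                             NumericMatrix sub_cum) {  // 4x4 row-conditional
  const int n = templates.size();
  const int n_cyc = qual_cdf.nrow();
  const int n_sc = qual_cdf.ncol();
  CharacterVector out_seq(n);
  List out_qual(n);
  IntegerVector n_ins(n), n_del(n), n_sub(n), consumed(n);
  CharacterVector out_cigar(n), out_md(n);
  LogicalVector exhausted(n);

  for (int i = 0; i < n; ++i) {
    std::string tmpl = as<std::string>(templates[i]);
    const int L = target_len[i];
    const int T = (int)tmpl.size();
    std::string seq;
    seq.reserve(L);
    IntegerVector q(L);
    CigarBuilder cig;
    MdBuilder md;
    int t = 0, ins = 0, del = 0, sub = 0;
    bool dead = false;

    int c = 0;
    while (c < L) {
      if (t >= T) { dead = true; break; }
      const int cyc = c < n_cyc ? c : n_cyc - 1;
      const double u = unif_rand();
      int k = 0;
      while (k < n_sc - 1 && qual_cdf(cyc, k) < u) ++k;
      const int score = qual_scores[k];
      const char tb = tmpl[t];
      if (unif_rand() < err_prob[k]) {
        const double u3 = unif_rand();
        if (u3 < type_cum[0]) {                       // insertion
          char nb = BASE_CHR[(int)(unif_rand() * 4) & 3];
          seq.push_back(nb); q[c] = score;
          ++ins; cig.push('I'); ++c;
        } else if (u3 < type_cum[1]) {                // deletion
          ++del; ++t; cig.push('D'); md.del(tb);      // re-attempt cycle c
        } else {                                      // substitution
          const int bi = base_idx(tb);
          char nb;
          if (bi < 0) {
            nb = BASE_CHR[(int)(unif_rand() * 4) & 3];
          } else {
            const double u4 = unif_rand();
            int j = 0;
            while (j < 3 && sub_cum(bi, j) < u4) ++j;
            nb = BASE_CHR[j];
          }
          seq.push_back(nb); q[c] = score;
          ++sub; ++t; cig.push('M'); md.mismatch(tb); ++c;
        }
      } else {                                        // faithful base
        seq.push_back(tb); q[c] = score;
        ++t; cig.push('M'); md.match1(); ++c;
      }
    }
    cig.flush();
    md.flush();
    out_seq[i] = seq;
    out_qual[i] = q;
    n_ins[i] = ins; n_del[i] = del; n_sub[i] = sub;
    consumed[i] = t;
    out_cigar[i] = cig.s;
    out_md[i] = md.s;
    exhausted[i] = dead;
  }
  return List::create(_["seq"] = out_seq, _["qual"] = out_qual,
                      _["n_ins"] = n_ins, _["n_del"] = n_del,
                      _["n_sub"] = n_sub, _["consumed"] = consumed,
                      _["cigar"] = out_cigar, _["md"] = out_md,
                      _["exhausted"] = exhausted);
}
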