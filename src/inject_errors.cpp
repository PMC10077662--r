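#include <Rcpp.h>
using namespace Rcpp;

static inline char draw_base() {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int k = (int)(unif_rand() * 4.0);
  if (k > 3) k = 3;
  return bases[k];
}

static inline char draw_qual(double mean, double sd, int qmin, int qmax) {
  int q = (int)std::lround(R::rnorm(mean, sd));
  if (q < qmin) q = qmin;
  if (q > qmax) q = qmax;
  return (char)(q + 33);  // Sanger offset
}

// Per-base independent error injection: each input base is deleted with
// del_rate, substituted (uniformly to a different base) with sub_rate, or
// copied; after each surviving position an extra random base is inserted with
// ins_rate.  Substituted/inserted bases draw Phred scores from the error-base
// distribution, copied bases from the correct-base distribution; both are
// rounded Gaussians clamped to [q_min, q_max].  Uses R's RNG stream, so
// results are reproducible under set.seed().
// [[Rcpp::export]]
List inject_errors_cpp(CharacterVector seqs,
                       double sub_rate, double ins_rate, double del_rate,
                       double q_correct_mean, double q_correct_sd,
                       double q_error_mean, double q_error_sd,
                       int q_min, int q_max) {
  const int n = seqs.size();
  CharacterVector oseq(n), oqual(n);
  RNGScope scope;

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string rs, rq;
    rs.reserve(s.size() + 16);
    rq.reserve(s.size() + 16);
    for (size_t j = 0; j < s.size(); ++j) {
      const double u = unif_rand();
      if (u < del_rate) {
        // base dropped
      } else if (u < del_rate + sub_rate) {
        char nb;
        do { nb = draw_base(); } while (nb == s[j]);
        rs.push_back(nb);
        rq.push_back(draw_qual(q_error_mean, q_error_sd, q_min, q_max));
      } else {
        rs.push_back(s[j]);
        rq.push_back(draw_qual(q_correct_mean, q_correct_sd, q_min, q_max));
      }
      if (unif_rand() < ins_rate) {
        rs.push_back(draw_base());
        rq.push_back(draw_qual(q_error_mean, q_error_sd, q_min, q_max));
      }
    }
    oseq[i] = rs;
    oqual[i] = rq;
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual);
}
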