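#include <Rcpp.h>
using namespace Rcpp;

// Hot loops of the simulator and the methylation caller. Both iterate over
// every base of every read, which is too slow in interpreted R at realistic
// coverage. All randomness goes through R's RNG so set.seed() governs it.

static inline char random_base_other_than(char b) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  char nb = b;
  while (nb == b) nb = bases[(int)(unif_rand() * 4.0) & 3];
  return nb;
}

// Simulate bisulfite-converted read sequences over one scaffold.
//
// ref: scaffold sequence (plus strand). starts: 0-based read starts.
// watson: TRUE = read from the plus (Watson) strand, FALSE = Crick.
// level_plus / level_minus: per-position true methylation level of the
// cytosine on that strand (NA where the position is not a C on that strand).
// Reads are emitted in plus-strand orientation, as an aligner would report
// them: a Crick-strand cytosine sits at a plus-strand G and reads as G
// (methylated, unconverted) or A (unmethylated, converted).
// [[Rcpp::export]]
CharacterVector cpp_simulate_reads(std::string ref,
                                   IntegerVector starts,
                                   LogicalVector watson,
                                   NumericVector level_plus,
                                   NumericVector level_minus,
                                   int read_length,
                                   double conversion_failure,
                                   double seq_error) {
  int n = starts.size();
  int L = ref.size();
  CharacterVector out(n);
  std::string buf(read_length, 'N');
  for (int i = 0; i < n; ++i) {
    int s = starts[i];
    if (s < 0 || s + read_length > L)
      stop("read start %d out of range for scaffold of length %d", s, L);
    bool w = watson[i];
    for (int j = 0; j < read_length; ++j) {
      int p = s + j;
      char b = ref[p];
      char obs = b;
      if (w && b == 'C') {
        double m = level_plus[p];
        if (NumericVector::is_na(m)) m = 0.0;
        if (unif_rand() < m) {
          obs = 'C';                       // methylated: protected
        } else {
          obs = (unif_rand() < conversion_failure) ? 'C' : 'T';
        }
      } else if (!w && b == 'G') {         // C on the Crick strand
        double m = level_minus[p];
        if (NumericVector::is_na(m)) m = 0.0;
        if (unif_rand() < m) {
          obs = 'G';
        } else {
          obs = (unif_rand() < conversion_failure) ? 'G' : 'A';
        }
      }
      if (seq_error > 0 && unif_rand() < seq_error)
        obs = random_base_other_than(obs);
      buf[j] = obs;
    }
    out[i] = buf;
  }
  return out;
}

// Pile up C/T (Watson) and G/A (Crick) votes at cytosine positions of one
// scaffold. Returns per-position methylated / unmethylated counts for the
// plus- and minus-strand cytosines, all indexed by plus-strand coordinate.
// Bases that are neither the converted nor the unconverted state of the
// reference cytosine are mismatches and cast no vote.
// [[Rcpp::export]]
List cpp_pileup(std::string ref,
                IntegerVector starts,
                LogicalVector watson,
                CharacterVector seqs) {
  int L = ref.size();
  int n = starts.size();
  IntegerVector pm(L), pu(L), mm(L), mu(L);
  long long mismatches = 0, rejected = 0;
  for (int i = 0; i < n; ++i) {
    const char *sq = CHAR(STRING_ELT(seqs, i));
    int rl = LENGTH(STRING_ELT(seqs, i));
    int s = starts[i];
    if (s < 0 || s + rl > L) { ++rejected; continue; }
    bool w = watson[i];
    for (int j = 0; j < rl; ++j) {
      int p = s + j;
      char b = ref[p];
      char obs = sq[j];
      if (w && b == 'C') {
        if (obs == 'C') ++pm[p];
        else if (obs == 'T') ++pu[p];
        else ++mismatches;
      } else if (!w && b == 'G') {
        if (obs == 'G') ++mm[p];
        else if (obs == 'A') ++mu[p];
        else ++mismatches;
      }
    }
  }
  return List::create(_["plus_meth"] = pm, _["plus_unmeth"] = pu,
                      _["minus_meth"] = mm, _["minus_unmeth"] = mu,
                      _["mismatches"] = (double)mismatches,
                      _["rejected"] = (double)rejected);
}

// Per-base depth of a set of reads over one scaffold, summed into fixed
// windows: window_depth[w] = total read bases falling in window w.
// [[Rcpp::export]]
NumericVector cpp_window_bases(IntegerVector starts, IntegerVector widths,
                               int scaffold_length, int window_size) {
  int nw = (scaffold_length + window_size - 1) / window_size;
  NumericVector out(nw);
  int n = starts.size();
  for (int i = 0; i < n; ++i) {
    int a = std::max(0, (int)starts[i]);
    int b = std::min(scaffold_length, (int)starts[i] + (int)widths[i]);
    while (a < b) {
      int w = a / window_size;
      int wend = std::min(b, (w + 1) * window_size);
      out[w] += wend - a;
      a = wend;
    }
  }
  return out;
}
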