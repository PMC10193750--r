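// PV-DM (distributed-memory paragraph vector) trainer with negative
// sampling, in the word2vec/CBOW tradition: the paragraph vector and the
// context word vectors around each position are averaged into a hidden
// vector that predicts the central word. Single-threaded with a private
// linear-congruential RNG so that a fixed seed gives bitwise-identical
// models across runs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

const int EXP_TABLE_SIZE = 1000;
const double MAX_EXP = 6.0;
const int UNIGRAM_TABLE_SIZE = 1000000;

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    state = state * 6364136223846793005ULL + 1442695040888963407ULL;
    return state;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  uint64_t bounded(uint64_t n) { return (next() >> 16) % n; }
};

std::vector<double> make_exp_table() {
  std::vector<double> t(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double e = std::exp((i / (double)EXP_TABLE_SIZE * 2.0 - 1.0) * MAX_EXP);
    t[i] = e / (e + 1.0); // sigmoid
  }
  return t;
}

double sigmoid_lookup(const std::vector<double>& tab, double x) {
  if (x >= MAX_EXP) return 1.0;
  if (x <= -MAX_EXP) return 0.0;
  int idx = (int)((x + MAX_EXP) * (EXP_TABLE_SIZE / MAX_EXP / 2.0));
  if (idx < 0) idx = 0;
  if (idx >= EXP_TABLE_SIZE) idx = EXP_TABLE_SIZE - 1;
  return tab[idx];
}

// word2vec-style unigram table over counts^0.75 for negative sampling
std::vector<int> make_unigram_table(const NumericVector& counts) {
  int vocab = counts.size();
  std::vector<int> table(UNIGRAM_TABLE_SIZE);
  double total = 0.0;
  for (int i = 0; i < vocab; ++i) total += std::pow(counts[i], 0.75);
  int i = 0;
  double cum = std::pow(counts[0], 0.75) / total;
  for (int a = 0; a < UNIGRAM_TABLE_SIZE; ++a) {
    table[a] = i;
    if ((a + 1.0) / UNIGRAM_TABLE_SIZE > cum && i < vocab - 1) {
      ++i;
      cum += std::pow(counts[i], 0.75) / total;
    }
  }
  return table;
}

// One SGD pass over a document position: average the paragraph vector and
// the (reduced-window) context word vectors, take `negative` noise samples
// for the central word, update output vectors and distribute the error to
// every contributing input vector. `update_words` is switched off in
// inference mode so only the fresh paragraph vector learns.
void train_position(const std::vector<int>& doc, int t, double* docvec,
                    std::vector<double>& syn0, std::vector<double>& syn1neg,
                    int dim, int window, int negative,
                    const std::vector<int>& unigram,
                    const std::vector<double>& exp_table, double alpha,
                    Rng& rng, bool update_words,
                    std::vector<double>& neu1, std::vector<double>& neu1e) {
  int word = doc[t];
  int reduced = (int)rng.bounded((uint64_t)window);
  int lo = t - (window - reduced);
  int hi = t + (window - reduced);
  if (lo < 0) lo = 0;
  if (hi > (int)doc.size() - 1) hi = (int)doc.size() - 1;

  std::fill(neu1.begin(), neu1.end(), 0.0);
  std::fill(neu1e.begin(), neu1e.end(), 0.0);
  int cw = 1; // the paragraph vector always contributes
  for (int c = 0; c < dim; ++c) neu1[c] = docvec[c];
  for (int p = lo; p <= hi; ++p) {
    if (p == t) continue;
    const double* wv = &syn0[(size_t)doc[p] * dim];
    for (int c = 0; c < dim; ++c) neu1[c] += wv[c];
    ++cw;
  }
  for (int c = 0; c < dim; ++c) neu1[c] /= cw;

  for (int d = 0; d <= negative; ++d) {
    int target;
    double label;
    if (d == 0) {
      target = word;
      label = 1.0;
    } else {
      target = unigram[rng.bounded(UNIGRAM_TABLE_SIZE)];
      if (target == word) continue;
      label = 0.0;
    }
    double* out = &syn1neg[(size_t)target * dim];
    double f = 0.0;
    for (int c = 0; c < dim; ++c) f += neu1[c] * out[c];
    double g = (label - sigmoid_lookup(exp_table, f)) * alpha;
    for (int c = 0; c < dim; ++c) neu1e[c] += g * out[c];
    for (int c = 0; c < dim; ++c) out[c] += g * neu1[c];
  }

  for (int c = 0; c < dim; ++c) docvec[c] += neu1e[c];
  if (update_words) {
    for (int p = lo; p <= hi; ++p) {
      if (p == t) continue;
      double* wv = &syn0[(size_t)doc[p] * dim];
      for (int c = 0; c < dim; ++c) wv[c] += neu1e[c];
    }
  }
}

std::vector<std::vector<int> > as_docs(const List& docs) {
  std::vector<std::vector<int> > out(docs.size());
  for (R_xlen_t i = 0; i < docs.size(); ++i) {
    IntegerVector v = docs[i];
    out[i] = std::vector<int>(v.begin(), v.end());
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List pvdm_train_cpp(List docs, int vocab_size, NumericVector counts, int dim,
                    int window, int epochs, int negative, double alpha,
                    double min_alpha, int seed) {
  std::vector<std::vector<int> > dv = as_docs(docs);
  int ndoc = dv.size();
  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  std::vector<double> exp_table = make_exp_table();
  std::vector<int> unigram = make_unigram_table(counts);

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> dmat((size_t)ndoc * dim);
  std::vector<double> syn1neg((size_t)vocab_size * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;
  for (size_t i = 0; i < dmat.size(); ++i)
    dmat[i] = (rng.unif() - 0.5) / dim;

  double total_words = 0.0;
  for (int i = 0; i < ndoc; ++i) total_words += dv[i].size();
  double planned = total_words * epochs;
  if (planned <= 0) stop("All documents are empty; nothing to train.");

  std::vector<double> neu1(dim), neu1e(dim);
  double processed = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < ndoc; ++i) {
      const std::vector<int>& doc = dv[i];
      double* docvec = &dmat[(size_t)i * dim];
      for (int t = 0; t < (int)doc.size(); ++t) {
        double a = alpha * (1.0 - processed / planned);
        if (a < min_alpha) a = min_alpha;
        train_position(doc, t, docvec, syn0, syn1neg, dim, window, negative,
                       unigram, exp_table, a, rng, true, neu1, neu1e);
        processed += 1.0;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix doc_out(ndoc, dim), word_out(vocab_size, dim),
      out_out(vocab_size, dim);
  for (int i = 0; i < ndoc; ++i)
    for (int c = 0; c < dim; ++c) doc_out(i, c) = dmat[(size_t)i * dim + c];
  for (int i = 0; i < vocab_size; ++i)
    for (int c = 0; c < dim; ++c) {
      word_out(i, c) = syn0[(size_t)i * dim + c];
      out_out(i, c) = syn1neg[(size_t)i * dim + c];
    }
  return List::create(_["doc_matrix"] = doc_out, _["word_matrix"] = word_out,
                      _["output_matrix"] = out_out);
}

// [[Rcpp::export]]
NumericMatrix pvdm_infer_cpp(List docs, NumericMatrix word_matrix,
                             NumericMatrix output_matrix, NumericVector counts,
                             int window, int epochs, int negative,
                             double alpha, double min_alpha, int seed) {
  std::vector<std::vector<int> > dv = as_docs(docs);
  int ndoc = dv.size();
  int dim = word_matrix.ncol();
  int vocab = word_matrix.nrow();
  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  std::vector<double> exp_table = make_exp_table();
  std::vector<int> unigram = make_unigram_table(counts);

  std::vector<double> syn0((size_t)vocab * dim);
  std::vector<double> syn1neg((size_t)vocab * dim);
  for (int i = 0; i < vocab; ++i)
    for (int c = 0; c < dim; ++c) {
      syn0[(size_t)i * dim + c] = word_matrix(i, c);
      syn1neg[(size_t)i * dim + c] = output_matrix(i, c);
    }
  // updates to syn1neg are rolled back after each document so that
  // inference of one document cannot affect another
  std::vector<double> syn1_backup = syn1neg;

  NumericMatrix doc_out(ndoc, dim);
  std::vector<double> neu1(dim), neu1e(dim);
  for (int i = 0; i < ndoc; ++i) {
    const std::vector<int>& doc = dv[i];
    std::vector<double> docvec(dim, 0.0); // zero start: empty docs stay zero
    double planned = (double)doc.size() * epochs;
    double processed = 0.0;
    for (int ep = 0; ep < epochs; ++ep) {
      for (int t = 0; t < (int)doc.size(); ++t) {
        double a = alpha * (1.0 - processed / (planned > 0 ? planned : 1.0));
        if (a < min_alpha) a = min_alpha;
        train_position(doc, t, &docvec[0], syn0, syn1neg, dim, window,
                       negative, unigram, exp_table, a, rng, false, neu1,
                       neu1e);
        processed += 1.0;
      }
    }
    syn1neg = syn1_backup;
    for (int c = 0; c < dim; ++c) doc_out(i, c) = docvec[c];
    Rcpp::checkUserInterrupt();
  }
  return doc_out;
}
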