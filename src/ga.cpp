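#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Genetic rule miner over per-feature bitmask chromosomes (Michigan style:
// one chromosome = one rule antecedent; the consequent class is fixed for
// the whole run).
//
// mu: n_cases x total_bits membership matrix; one column per linguistic term
//     (numerical features) or domain token (categorical, 0/1), missing
//     values encoded as 0 in every column of the feature.
// seg_len: bits per feature, in schema order (sum = ncol(mu)).
// labels: per-case class index 0/1/2; class_idx: the target class.
//
// Fitness of a chromosome: decode -> antecedent over the features whose
// segment is neither all-zero nor all-one; APC per case = mean over relevant
// features of the max membership among selected terms; support = mean over
// cases of APC restricted to class-matching cases; confidence =
// sum(supp)/sum(APC); fitness = (support+confidence)/2, with invalid
// chromosomes (no relevant feature) and rules firing nowhere scored 0.
//
// Uses R's RNG (honours set.seed); draws occur in a fixed order so runs are
// reproducible bit-for-bit.

namespace {

struct Eval {
  double fitness, support, confidence;
  bool valid, conf_defined;
};

class Scorer {
public:
  Scorer(const NumericMatrix& mu, const IntegerVector& seg_len,
         const IntegerVector& labels, int class_idx)
      : n_(mu.nrow()), nfeat_(seg_len.size()), labels_(labels),
        class_idx_(class_idx) {
    offsets_.resize(nfeat_);
    klen_.resize(nfeat_);
    int off = 0;
    for (int f = 0; f < nfeat_; ++f) {
      offsets_[f] = off;
      klen_[f] = seg_len[f];
      off += seg_len[f];
    }
    if (off != mu.ncol()) stop("segment lengths do not match mu columns");
    // Precompute, per feature, the per-case max membership for every
    // non-empty mask (features here have few terms, so 2^k stays tiny).
    tables_.resize(nfeat_);
    for (int f = 0; f < nfeat_; ++f) {
      int k = klen_[f];
      if (k > 16) stop("feature with more than 16 terms is not supported");
      size_t nmask = (size_t)1 << k;
      tables_[f].assign(nmask * n_, 0.0);
      std::vector<double>& tab = tables_[f];
      for (int b = 0; b < k; ++b) {
        size_t bit = (size_t)1 << b;
        const double* col = &mu(0, offsets_[f] + b);
        for (size_t mask = 0; mask < nmask; ++mask) {
          if (!(mask & bit)) continue;
          size_t base = mask & ~bit;  // already filled (smaller mask)
          double* dst = &tab[mask * n_];
          const double* prev = &tab[base * n_];
          for (int i = 0; i < n_; ++i) {
            double v = col[i];
            dst[i] = (b == 0 && base == 0) ? v : std::max(prev[i], v);
          }
        }
      }
    }
    acc_.resize(n_);
  }

  int n_bits() const {
    int L = 0;
    for (int f = 0; f < nfeat_; ++f) L += klen_[f];
    return L;
  }

  Eval eval(const std::vector<uint8_t>& bits) {
    std::fill(acc_.begin(), acc_.end(), 0.0);
    int nrel = 0;
    for (int f = 0; f < nfeat_; ++f) {
      int k = klen_[f];
      size_t mask = 0;
      for (int b = 0; b < k; ++b)
        if (bits[offsets_[f] + b]) mask |= (size_t)1 << b;
      size_t full = ((size_t)1 << k) - 1;
      if (mask == 0 || mask == full) continue;  // feature irrelevant
      ++nrel;
      const double* row = &tables_[f][mask * n_];
      for (int i = 0; i < n_; ++i) acc_[i] += row[i];
    }
    Eval e;
    if (nrel == 0) {
      e.fitness = e.support = e.confidence = 0.0;
      e.valid = false; e.conf_defined = false;
      return e;
    }
    double sum_apc = 0.0, sum_supp = 0.0;
    for (int i = 0; i < n_; ++i) {
      double apc = acc_[i] / nrel;
      sum_apc += apc;
      if (labels_[i] == class_idx_) sum_supp += apc;
    }
    e.valid = true;
    e.support = sum_supp / n_;
    if (sum_apc > 0.0) {
      e.conf_defined = true;
      e.confidence = sum_supp / sum_apc;
      e.fitness = 0.5 * (e.support + e.confidence);
    } else {
      e.conf_defined = false;
      e.confidence = 0.0;
      e.fitness = 0.0;
    }
    return e;
  }

  bool is_valid(const std::vector<uint8_t>& bits) const {
    for (int f = 0; f < nfeat_; ++f) {
      int k = klen_[f];
      int ones = 0;
      for (int b = 0; b < k; ++b) ones += bits[offsets_[f] + b];
      if (ones > 0 && ones < k) return true;
    }
    return false;
  }

private:
  int n_, nfeat_;
  IntegerVector labels_;
  int class_idx_;
  std::vector<int> offsets_, klen_;
  std::vector<std::vector<double> > tables_;
  std::vector<double> acc_;
};

inline int runif_int(int n) {
  int i = (int)(unif_rand() * n);
  return i >= n ? n - 1 : i;
}

}  // namespace

namespace {

// bounded best-ever archive of distinct valid rules (support > 0 and
// defined confidence); pruned to `cap` by fitness when it overgrows
struct Archive {
  explicit Archive(size_t cap) : cap_(cap) {}
  void offer(const std::vector<uint8_t>& bits, const Eval& e) {
    if (!e.valid || !e.conf_defined || !(e.support > 0.0)) return;
    if (worst_kept_ >= 0.0 && e.fitness < worst_kept_) return;
    std::string key(bits.begin(), bits.end());
    auto it = entries_.find(key);
    if (it == entries_.end()) {
      entries_.emplace(key, e);
      if (cap_ > 0 && entries_.size() > 4 * cap_) prune();
    }
  }
  void prune() {
    std::vector<std::pair<std::string, Eval> > all(entries_.begin(),
                                                   entries_.end());
    std::stable_sort(all.begin(), all.end(),
                     [](const std::pair<std::string, Eval>& a,
                        const std::pair<std::string, Eval>& b) {
                       return a.second.fitness > b.second.fitness;
                     });
    if (all.size() > cap_) all.resize(cap_);
    entries_.clear();
    entries_.insert(all.begin(), all.end());
    worst_kept_ = all.back().second.fitness;
  }
  size_t cap_;
  double worst_kept_ = -1.0;
  std::map<std::string, Eval> entries_;
};

}  // namespace

// [[Rcpp::export(name = "ga_mine_cpp")]]
List ga_mine_cpp(NumericMatrix mu, IntegerVector seg_len, IntegerVector labels,
                 int class_idx, int pop_size, int generations,
                 double cx_rate, double mut_rate, int elite,
                 int archive_size, int mut_per_bit) {
  if (pop_size < 2) stop("population size must be >= 2");
  if (elite < 0 || elite >= pop_size) stop("elite count must be in [0, pop_size)");
  Scorer scorer(mu, seg_len, labels, class_idx);
  const int L = scorer.n_bits();

  typedef std::vector<uint8_t> Chrom;
  std::vector<Chrom> pop(pop_size, Chrom(L));
  std::vector<Eval> evals(pop_size);
  Archive archive((size_t)std::max(archive_size, 1));

  // Don't-care-biased random initialisation: each feature segment is made
  // irrelevant (all-ones) with probability 1/2, otherwise filled with
  // uniform random bits, so the initial population spans antecedent sizes
  // from compact to broad. All-irrelevant chromosomes are resampled.
  const int nfeat = seg_len.size();
  for (int p = 0; p < pop_size; ++p) {
    for (int attempt = 0; attempt < 100; ++attempt) {
      int b0 = 0;
      for (int f = 0; f < nfeat; ++f) {
        int k = seg_len[f];
        if (unif_rand() < 0.5) {
          for (int b = 0; b < k; ++b) pop[p][b0 + b] = 1;
        } else {
          for (int b = 0; b < k; ++b)
            pop[p][b0 + b] = unif_rand() < 0.5 ? 1 : 0;
        }
        b0 += k;
      }
      if (scorer.is_valid(pop[p])) break;
    }
    evals[p] = scorer.eval(pop[p]);
    archive.offer(pop[p], evals[p]);
  }

  NumericVector best_trace(generations);
  std::vector<int> order(pop_size);
  std::vector<Chrom> next(pop_size, Chrom(L));
  std::vector<Eval> next_evals(pop_size);

  for (int g = 0; g < generations; ++g) {
    // elites: best `elite` individuals, ties to the lower index
    for (int p = 0; p < pop_size; ++p) order[p] = p;
    std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
      return evals[a].fitness > evals[b].fitness;
    });
    int filled = 0;
    for (; filled < elite; ++filled) {
      next[filled] = pop[order[filled]];
      next_evals[filled] = evals[order[filled]];
    }
    while (filled < pop_size) {
      // binary tournament, two independent uniform draws, tie -> first drawn
      int c1 = -1, c2 = -1;
      {
        int a = runif_int(pop_size), b = runif_int(pop_size);
        c1 = (evals[b].fitness > evals[a].fitness) ? b : a;
      }
      {
        int a = runif_int(pop_size), b = runif_int(pop_size);
        c2 = (evals[b].fitness > evals[a].fitness) ? b : a;
      }
      Chrom child1 = pop[c1], child2 = pop[c2];
      if (unif_rand() < cx_rate && L > 1) {
        int cut = 1 + runif_int(L - 1);
        for (int b = cut; b < L; ++b) std::swap(child1[b], child2[b]);
      }
      if (mut_per_bit) {
        // every element mutates independently with the configured rate
        for (int b = 0; b < L; ++b) if (unif_rand() < mut_rate) child1[b] ^= 1;
        for (int b = 0; b < L; ++b) if (unif_rand() < mut_rate) child2[b] ^= 1;
      } else {
        // with the configured rate, one randomly selected element flips
        if (unif_rand() < mut_rate) child1[runif_int(L)] ^= 1;
        if (unif_rand() < mut_rate) child2[runif_int(L)] ^= 1;
      }
      next[filled] = child1;
      next_evals[filled] = scorer.eval(child1);
      archive.offer(child1, next_evals[filled]);
      ++filled;
      if (filled < pop_size) {
        next[filled] = child2;
        next_evals[filled] = scorer.eval(child2);
        archive.offer(child2, next_evals[filled]);
        ++filled;
      }
    }
    pop.swap(next);
    evals.swap(next_evals);
    double best = 0.0;
    for (int p = 0; p < pop_size; ++p) best = std::max(best, evals[p].fitness);
    best_trace[g] = best;
  }

  // best-ever rules, pruned to the archive cap
  if (archive.entries_.size() > archive.cap_) archive.prune();
  const int na = (int)archive.entries_.size();
  IntegerMatrix abits(na, L);
  NumericVector afit(na), asup(na), aconf(na);
  int row = 0;
  for (std::map<std::string, Eval>::const_iterator it = archive.entries_.begin();
       it != archive.entries_.end(); ++it, ++row) {
    for (int b = 0; b < L; ++b) abits(row, b) = (int)it->first[(size_t)b];
    afit[row] = it->second.fitness;
    asup[row] = it->second.support;
    aconf[row] = it->second.confidence;
  }

  // final population (diagnostics / determinism checks)
  IntegerMatrix bits(pop_size, L);
  NumericVector fitness(pop_size);
  for (int p = 0; p < pop_size; ++p) {
    for (int b = 0; b < L; ++b) bits(p, b) = pop[p][b];
    fitness[p] = evals[p].fitness;
  }
  return List::create(_["bits"] = abits, _["fitness"] = afit,
                      _["support"] = asup, _["confidence"] = aconf,
                      _["pop_bits"] = bits, _["pop_fitness"] = fitness,
                      _["best_trace"] = best_trace);
}
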