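#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (std::size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

static bool is_acgt(const std::string& s) {
  for (char c : s)
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  return !s.empty();
}

// smallest period p of s such that s is an exact whole-number repetition of s[0..p)
static std::string primitive_unit(const std::string& s) {
  const std::size_t n = s.size();
  for (std::size_t p = 1; p <= n / 2; ++p) {
    if (n % p != 0) continue;
    bool ok = true;
    for (std::size_t i = p; i < n && ok; ++i)
      if (s[i] != s[i - p]) ok = false;
    if (ok) return s.substr(0, p);
  }
  return s;
}

// lexicographic minimum over all rotations of u and all rotations of revcomp(u)
static std::string canon_of_primitive(const std::string& u) {
  const std::size_t k = u.size();
  std::string best;
  const std::string rc = revcomp_str(u);
  for (int strand = 0; strand < 2; ++strand) {
    const std::string& base = strand == 0 ? u : rc;
    std::string doubled = base + base;
    for (std::size_t p = 0; p < k; ++p) {
      std::string rot = doubled.substr(p, k);
      if (best.empty() || rot < best) best = rot;
    }
  }
  return best;
}

// canonical motif of a unit after primitive reduction; "" if invalid
static std::string canon_motif_one(const std::string& unit,
                                   int min_len, int max_len) {
  if (!is_acgt(unit)) return "";
  std::string u = primitive_unit(unit);
  if ((int)u.size() < min_len || (int)u.size() > max_len) return "";
  return canon_of_primitive(u);
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_motif(CharacterVector units,
                                    int min_len = 2, int max_len = 20) {
  const R_xlen_t n = units.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (units[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string c = canon_motif_one(as<std::string>(units[i]), min_len, max_len);
    out[i] = c.empty() ? NA_STRING : String(c);
  }
  return out;
}

// fraction of read bases matching a perfect tandem tiling of motif,
// maximized over both strands and all tiling phases
static double tile_purity_one(const std::string& read, const std::string& motif) {
  const std::size_t n = read.size(), k = motif.size();
  if (n == 0 || k == 0) return NA_REAL;
  double best = 0.0;
  const std::string rc = revcomp_str(motif);
  for (int strand = 0; strand < 2; ++strand) {
    const std::string& m = strand == 0 ? motif : rc;
    for (std::size_t p = 0; p < k; ++p) {
      std::size_t matches = 0, j = p;
      for (std::size_t i = 0; i < n; ++i) {
        if (read[i] == m[j]) ++matches;
        if (++j == k) j = 0;
      }
      double frac = (double)matches / (double)n;
      if (frac > best) best = frac;
      if (best == 1.0) return 1.0;
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_tile_purity(CharacterVector reads, std::string motif) {
  const R_xlen_t n = reads.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (reads[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    out[i] = tile_purity_one(as<std::string>(reads[i]), motif);
  }
  return out;
}

// Classify reads as in-repeat reads (IRRs).
//
// Candidate unit lengths are pre-screened with the self-match statistic
// s_k = #{i : read[i] == read[i+k]} / (L - k). If a motif of length k tiles
// the read with purity q then each of the (1-q)L mismatching positions can
// spoil at most two shifted comparisons, so s_k >= 1 - 2(1-q)L/(L-k). A k
// failing that bound (with an epsilon of slack) cannot reach min_purity and
// is skipped; the screen is therefore exact, not heuristic.
//
// For surviving k, the few most frequent k-mers of the read are
// canonicalized and scored by full tandem tiling.
// [[Rcpp::export]]
List cpp_detect_irr(CharacterVector reads, double min_purity = 0.9,
                    int kmin = 2, int kmax = 20, int top_candidates = 3) {
  const R_xlen_t nr = reads.size();
  LogicalVector is_irr(nr);
  CharacterVector motif(nr);
  NumericVector purity(nr);

  for (R_xlen_t r = 0; r < nr; ++r) {
    is_irr[r] = false; motif[r] = NA_STRING; purity[r] = NA_REAL;
    if (reads[r] == NA_STRING) continue;
    const std::string read = as<std::string>(reads[r]);
    const int L = (int)read.size();
    if (L < 2 * kmin) continue;

    double best_purity = -1.0;
    std::string best_motif;

    const int khi = std::min(kmax, L / 2);
    for (int k = kmin; k <= khi; ++k) {
      // self-correlation screen
      int sm = 0;
      for (int i = 0; i + k < L; ++i)
        if (read[i] == read[i + k]) ++sm;
      const double s_k = (double)sm / (double)(L - k);
      const double bound =
        1.0 - 2.0 * (1.0 - min_purity) * (double)L / (double)(L - k) - 1e-9;
      if (s_k < bound) continue;

      // top k-mers of the read as candidate units
      std::unordered_map<std::string, int> counts;
      for (int i = 0; i + k <= L; ++i)
        ++counts[read.substr(i, k)];
      std::vector<std::pair<int, std::string>> ranked;
      ranked.reserve(counts.size());
      for (auto& kv : counts) ranked.push_back({kv.second, kv.first});
      std::sort(ranked.begin(), ranked.end(),
                [](const std::pair<int, std::string>& a,
                   const std::pair<int, std::string>& b) {
                  if (a.first != b.first) return a.first > b.first;
                  return a.second < b.second;
                });
      const int ncand = std::min((int)ranked.size(), top_candidates);
      for (int c = 0; c < ncand; ++c) {
        std::string cm = canon_motif_one(ranked[c].second, kmin, kmax);
        if (cm.empty() || cm == best_motif) continue;
        double p = tile_purity_one(read, cm);
        if (p > best_purity + 1e-12 ||
            (std::abs(p - best_purity) <= 1e-12 &&
             (cm.size() < best_motif.size() ||
              (cm.size() == best_motif.size() && cm < best_motif)))) {
          best_purity = p;
          best_motif = cm;
        }
      }
    }

    if (best_purity >= min_purity && !best_motif.empty()) {
      is_irr[r] = true;
      motif[r] = best_motif;
      purity[r] = best_purity;
    }
  }
  return List::create(_["is_irr"] = is_irr, _["motif"] = motif,
                      _["purity"] = purity);
}

// Independent substitution errors at rate `error_rate` per base, drawn from
// R's RNG stream so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, double error_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const R_xlen_t n = seqs.size();
  CharacterVector out(n);
  if (error_rate <= 0.0) return clone(seqs);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(seqs[i]);
    for (std::size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < error_rate) {
        char cur = s[j];
        char nb;
        do {
          nb = bases[(int)(unif_rand() * 4.0) & 3];
        } while (nb == cur);
        s[j] = nb;
      }
    }
    out[i] = s;
  }
  return out;
}

// Reverse complement over A/C/G/T/N (inputs are uppercase throughout the
// package).
// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  const R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'N');
    for (std::size_t j = 0; j < s.size(); ++j) {
      char c = s[s.size() - 1 - j];
      switch (c) {
        case 'A': r[j] = 'T'; break;
        case 'C': r[j] = 'G'; break;
        case 'G': r[j] = 'C'; break;
        case 'T': r[j] = 'A'; break;
        case 'N': r[j] = 'N'; break;
        default: stop("non-ACGTN character in sequence");
      }
    }
    out[i] = r;
  }
  return out;
}
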