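#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <string>

using namespace Rcpp;

// Needleman-Wunsch global alignment, linear gap penalty.
// Traceback is deterministic: diagonal preferred, then up (gap in b),
// then left (gap in a).
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const size_t na = a.size(), nb = b.size();
  if (na == 0 || nb == 0)
    stop("empty sequence");
  if ((double)na * (double)nb > 2.5e7)
    stop("sequences too long for full dynamic programming");
  std::vector<double> F((na + 1) * (nb + 1));
  const size_t W = nb + 1;
  for (size_t j = 0; j <= nb; ++j) F[j] = gap * (double)j;
  for (size_t i = 1; i <= na; ++i) {
    F[i * W] = gap * (double)i;
    const char ca = a[i - 1];
    for (size_t j = 1; j <= nb; ++j) {
      double s = (ca == b[j - 1]) ? match : mismatch;
      double diag = F[(i - 1) * W + (j - 1)] + s;
      double up   = F[(i - 1) * W + j] + gap;
      double left = F[i * W + (j - 1)] + gap;
      double best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      F[i * W + j] = best;
    }
  }
  // traceback
  std::string ra, rb;
  ra.reserve(na + nb); rb.reserve(na + nb);
  size_t i = na, j = nb;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (F[i * W + j] == F[(i - 1) * W + (j - 1)] + s) {
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
        --i; --j; continue;
      }
    }
    if (i > 0 && F[i * W + j] == F[(i - 1) * W + j] + gap) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; continue;
    }
    ra.push_back('-'); rb.push_back(b[j - 1]);
    --j;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb,
                      _["score"] = F[na * W + nb]);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// All position pairs (i, j), i < j, 0-based, sharing an exact k-mer with
// separation j - i in [min_sep, max_sep]. K-mers containing non-ACGT bases
// or occurring more than max_occ times are skipped.
// [[Rcpp::export]]
IntegerMatrix seed_pairs_cpp(std::string seq, int k, int min_sep, int max_sep,
                             int max_occ) {
  const int n = (int)seq.size();
  std::unordered_map<uint64_t, std::vector<int> > table;
  if (n >= k) {
    table.reserve((size_t)n);
    uint64_t key = 0;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0; // valid bases accumulated
    for (int i = 0; i < n; ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) table[key].push_back(i - k + 1);
    }
  }
  std::vector<int> pi, pj;
  for (std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
         table.begin(); it != table.end(); ++it) {
    const std::vector<int>& pos = it->second;
    if ((int)pos.size() < 2 || (int)pos.size() > max_occ) continue;
    for (size_t u = 0; u + 1 < pos.size(); ++u)
      for (size_t v = u + 1; v < pos.size(); ++v) {
        int sep = pos[v] - pos[u];
        if (sep < min_sep) continue;
        if (sep > max_sep) break;
        pi.push_back(pos[u]); pj.push_back(pos[v]);
      }
  }
  IntegerMatrix out((int)pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    out(r, 0) = pi[r]; out(r, 1) = pj[r];
  }
  return out;
}

// Ungapped X-drop extension of a direct-repeat candidate. The repeat's left
// copy is seeded on [i_lo, i_hi] (0-based inclusive) and its right copy at
// the fixed offset sep. Extends both outer ends until the running score
// drops more than xdrop below its running maximum. Returns c(s, e): the
// extended 0-based inclusive bounds of the left copy.
// [[Rcpp::export]]
IntegerVector extend_seed_cpp(std::string seq, int i_lo, int i_hi, int sep,
                              double match, double mismatch, double xdrop,
                              int max_len) {
  const int n = (int)seq.size();
  // leftward
  int s = i_lo;
  {
    double sc = 0, best = 0; int best_pos = i_lo;
    for (int p = i_lo - 1; p >= 0; --p) {
      if (i_hi - p + 1 > max_len) break;
      sc += (seq[p] == seq[p + sep]) ? match : mismatch;
      if (sc > best) { best = sc; best_pos = p; }
      if (best - sc > xdrop) break;
    }
    s = best_pos;
  }
  // rightward (right copy must stay in bounds)
  int e = i_hi;
  {
    double sc = 0, best = 0; int best_pos = i_hi;
    for (int p = i_hi + 1; p + sep < n; ++p) {
      if (p - s + 1 > max_len) break;
      sc += (seq[p] == seq[p + sep]) ? match : mismatch;
      if (sc > best) { best = sc; best_pos = p; }
      if (best - sc > xdrop) break;
    }
    e = best_pos;
  }
  return IntegerVector::create(s, e);
}

// Refine direct-repeat bounds using insertion hallmarks: an exact
// target-site duplication (tsd_min..tsd_max bp) flanking the element and
// TG...CA termini on both repeat copies. Searches s +/- window and
// e +/- window; keeps the original bounds when no hallmark scores at least
// min_score. All coordinates 0-based inclusive; element = [s, e + sep].
// [[Rcpp::export]]
List snap_bounds_cpp(std::string seq, int s, int e, int sep,
                     int tsd_min, int tsd_max, int window, double min_score) {
  const int n = (int)seq.size();
  double best_score = -1e18;
  int bs = s, be = e, btsd = 0;
  bool btg = false, bca = false;
  for (int ds = -window; ds <= window; ++ds) {
    int s2 = s + ds;
    if (s2 < 0) continue;
    for (int de = -window; de <= window; ++de) {
      int e2 = e + de;
      if (e2 + sep >= n) continue;
      if (e2 - s2 + 1 < 10 || e2 >= s2 + sep) continue;
      int tsd = 0;
      for (int t = tsd_max; t >= tsd_min; --t) {
        if (s2 - t < 0 || e2 + sep + t >= n) continue;
        if (seq.compare(s2 - t, t, seq, e2 + sep + 1, t) == 0) { tsd = t; break; }
      }
      bool tg1 = seq[s2] == 'T' && seq[s2 + 1] == 'G';
      bool tg2 = seq[s2 + sep] == 'T' && seq[s2 + sep + 1] == 'G';
      bool ca1 = seq[e2 - 1] == 'C' && seq[e2] == 'A';
      bool ca2 = seq[e2 + sep - 1] == 'C' && seq[e2 + sep] == 'A';
      double sc = (tsd > 0 ? 3.0 * tsd : 0.0) +
        2.0 * ((tg1 ? 1 : 0) + (tg2 ? 1 : 0) + (ca1 ? 1 : 0) + (ca2 ? 1 : 0)) -
        0.15 * (std::abs(ds) + std::abs(de));
      if (sc > best_score) {
        best_score = sc; bs = s2; be = e2; btsd = tsd;
        btg = tg1; bca = ca2;
      }
    }
  }
  bool snapped = best_score >= min_score;
  if (!snapped) { bs = s; be = e; btsd = 0; btg = false; bca = false; }
  std::string tsd_seq = btsd > 0 ? seq.substr(bs - btsd, btsd) : "";
  return List::create(_["s"] = bs, _["e"] = be, _["tsd"] = tsd_seq,
                      _["has_tg"] = btg, _["has_ca"] = bca,
                      _["snapped"] = snapped);
}

// Ungapped identity of the direct-repeat candidate [s, e] vs its copy at
// offset sep (0-based inclusive); cheap pre-filter before gapped scoring.
// [[Rcpp::export]]
double ungapped_identity_cpp(std::string seq, int s, int e, int sep) {
  if (e < s) return 0.0;
  int n = 0, m = 0;
  const int len = (int)seq.size();
  for (int p = s; p <= e && p + sep < len; ++p) {
    ++n;
    if (seq[p] == seq[p + sep]) ++m;
  }
  return n > 0 ? (double)m / n : 0.0;
}
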