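#include <Rcpp.h>
using namespace Rcpp;

// Sequence encoding: A=0, C=1, G=2, T=3, anything else -1 (disqualifies sites).
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Scan one sequence with an LLR matrix (4 rows A,C,G,T x L columns) on both
// strands. A site passes if its LLR >= llr_min. Minus-strand score is the
// plus-strand score of the reverse complement. Windows containing a non-ACGT
// base are excluded entirely. Starts are 0-based.
// [[Rcpp::export(name = ".scan_cpp")]]
DataFrame scan_cpp(std::string seq, NumericMatrix llrmat, double llr_min) {
  const int L = llrmat.ncol();
  const int n = (int)seq.size();
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

  std::vector<int> starts;
  std::vector<int> strands;  // 0 = '+', 1 = '-'
  std::vector<double> llrs;
  if (n >= L) {
    for (int i = 0; i + L <= n; ++i) {
      bool ok = true;
      for (int j = 0; j < L; ++j) if (code[i + j] < 0) { ok = false; break; }
      if (!ok) continue;
      double sp = 0.0, sm = 0.0;
      for (int j = 0; j < L; ++j) {
        sp += llrmat(code[i + j], j);
        sm += llrmat(3 - code[i + L - 1 - j], j);
      }
      if (sp >= llr_min) { starts.push_back(i); strands.push_back(0); llrs.push_back(sp); }
      if (sm >= llr_min) { starts.push_back(i); strands.push_back(1); llrs.push_back(sm); }
    }
  }
  return DataFrame::create(_["start"] = starts, _["strand"] = strands,
                           _["llr"] = llrs);
}

// Partition-function DP over non-overlapping bound-site configurations.
//
// Sites (sorted by start) are given as parallel arrays; motif is 1 (primary)
// or 2 (secondary); q_j = gamma_{motif(j)} * rel_affinity(j). State: last
// bound site. A[j] = sum of W(sigma) over configurations whose last bound
// site is j; B[j] = same sum weighted by the number of bound primary sites.
// The interaction term omega multiplies W for each adjacent bound heterotypic
// pair separated by a gap of 0..dT bp (gap < 0 means overlap: excluded).
// OCC = sum(B) / (E + sum(A)), E the (rescaled) weight of the empty
// configuration. Rescaling guards against overflow at large gamma.
static double occ_dp_core(const double* start, const double* end,
                          const int* motif, const double* relaff, int n,
                          double g1, double g2, double omega, double dT) {
  if (n == 0) return 0.0;
  std::vector<double> A(n), B(n);
  double E = 1.0;
  const double BIG = 1e250;
  for (int j = 0; j < n; ++j) {
    double q = (motif[j] == 1 ? g1 : g2) * relaff[j];
    double sA = E, sB = 0.0;
    for (int i = 0; i < j; ++i) {
      double gap = start[j] - end[i];
      if (gap < 0) continue;
      double w = (motif[i] != motif[j] && gap <= dT) ? omega : 1.0;
      sA += w * A[i];
      sB += w * B[i];
    }
    A[j] = q * sA;
    B[j] = q * sB + (motif[j] == 1 ? A[j] : 0.0);
    if (A[j] > BIG || B[j] > BIG) {
      const double c = 1e-200;
      E *= c;
      for (int i = 0; i <= j; ++i) { A[i] *= c; B[i] *= c; }
    }
  }
  double sumA = 0.0, sumB = 0.0;
  for (int j = 0; j < n; ++j) { sumA += A[j]; sumB += B[j]; }
  return sumB / (E + sumA);
}

// [[Rcpp::export(name = ".occ_dp_cpp")]]
double occ_dp_cpp(NumericVector start, NumericVector end, IntegerVector motif,
                  NumericVector relaff, double g1, double g2, double omega,
                  double dT) {
  return occ_dp_core(REAL(start), REAL(end), INTEGER(motif), REAL(relaff),
                     start.size(), g1, g2, omega, dT);
}

// Batched prediction over a list of per-window site matrices with columns
// (start, end, motif, rel_affinity), each sorted by start.
// [[Rcpp::export(name = ".predict_batch_cpp")]]
NumericVector predict_batch_cpp(List sitemats, double g1, double g2,
                                double omega, double dT) {
  const int nw = sitemats.size();
  NumericVector out(nw);
  for (int w = 0; w < nw; ++w) {
    NumericMatrix m = sitemats[w];
    const int n = m.nrow();
    if (n == 0) { out[w] = 0.0; continue; }
    std::vector<double> st(n), en(n), ra(n);
    std::vector<int> mo(n);
    for (int i = 0; i < n; ++i) {
      st[i] = m(i, 0); en[i] = m(i, 1); mo[i] = (int)m(i, 2); ra[i] = m(i, 3);
    }
    out[w] = occ_dp_core(st.data(), en.data(), mo.data(), ra.data(), n,
                         g1, g2, omega, dT);
  }
  return out;
}

// Training-grid evaluation: Pearson CC between predictions and chip scores
// for each parameter row (gamma1, gamma2, omega). NA when predictions are
// constant. One call evaluates the whole grid for one window set.
// [[Rcpp::export(name = ".grid_cc_cpp")]]
NumericVector grid_cc_cpp(List sitemats, NumericVector chip,
                          NumericMatrix params, double dT) {
  const int nw = sitemats.size();
  const int G = params.nrow();
  // unpack once
  std::vector<std::vector<double>> st(nw), en(nw), ra(nw);
  std::vector<std::vector<int>> mo(nw);
  for (int w = 0; w < nw; ++w) {
    NumericMatrix m = sitemats[w];
    const int n = m.nrow();
    st[w].resize(n); en[w].resize(n); ra[w].resize(n); mo[w].resize(n);
    for (int i = 0; i < n; ++i) {
      st[w][i] = m(i, 0); en[w][i] = m(i, 1);
      mo[w][i] = (int)m(i, 2); ra[w][i] = m(i, 3);
    }
  }
  double my = 0.0;
  for (int w = 0; w < nw; ++w) my += chip[w];
  my /= nw;
  double syy = 0.0;
  for (int w = 0; w < nw; ++w) syy += (chip[w] - my) * (chip[w] - my);

  NumericVector cc(G);
  std::vector<double> pred(nw);
  for (int g = 0; g < G; ++g) {
    const double g1 = params(g, 0), g2 = params(g, 1), om = params(g, 2);
    double mx = 0.0;
    for (int w = 0; w < nw; ++w) {
      pred[w] = occ_dp_core(st[w].data(), en[w].data(), mo[w].data(),
                            ra[w].data(), (int)st[w].size(), g1, g2, om, dT);
      mx += pred[w];
    }
    mx /= nw;
    double sxx = 0.0, sxy = 0.0;
    for (int w = 0; w < nw; ++w) {
      const double dx = pred[w] - mx;
      sxx += dx * dx;
      sxy += dx * (chip[w] - my);
    }
    cc[g] = (sxx <= 0.0 || syy <= 0.0) ? NA_REAL : sxy / std::sqrt(sxx * syy);
  }
  return cc;
}

// Batch scan: one call scans every window for one motif and returns the
// per-window site matrices (start, end, motif, rel_affinity) consumed by
// the occupancy DP, sorted by start. Avoids per-window R overhead in the
// shuffle/refit loops.
// [[Rcpp::export(name = ".scan_windows_cpp")]]
List scan_windows_cpp(CharacterVector seqs, NumericMatrix llrmat,
                      double llr_min, double llr_max, int motif_index) {
  const int L = llrmat.ncol();
  const int nw = seqs.size();
  List out(nw);
  std::vector<double> row;
  for (int w = 0; w < nw; ++w) {
    std::string seq = as<std::string>(seqs[w]);
    const int n = (int)seq.size();
    std::vector<int> code(n);
    for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);
    row.clear();
    for (int i = 0; i + L <= n; ++i) {
      bool ok = true;
      for (int j = 0; j < L; ++j) if (code[i + j] < 0) { ok = false; break; }
      if (!ok) continue;
      double sp = 0.0, sm = 0.0;
      for (int j = 0; j < L; ++j) {
        sp += llrmat(code[i + j], j);
        sm += llrmat(3 - code[i + L - 1 - j], j);
      }
      if (sp >= llr_min) {
        row.push_back(i); row.push_back(i + L);
        row.push_back(motif_index); row.push_back(std::exp(sp - llr_max));
      }
      if (sm >= llr_min) {
        row.push_back(i); row.push_back(i + L);
        row.push_back(motif_index); row.push_back(std::exp(sm - llr_max));
      }
    }
    const int ns = (int)row.size() / 4;
    NumericMatrix m(ns, 4);
    for (int k = 0; k < ns; ++k)
      for (int c = 0; c < 4; ++c) m(k, c) = row[4 * k + c];
    out[w] = m;
  }
  return out;
}

// Merge two per-window site matrices (each sorted by start) into one sorted
// matrix.
// [[Rcpp::export(name = ".merge_sitemats_cpp")]]
List merge_sitemats_cpp(List a, List b) {
  const int nw = a.size();
  List out(nw);
  for (int w = 0; w < nw; ++w) {
    NumericMatrix ma = a[w], mb = b[w];
    const int na = ma.nrow(), nb = mb.nrow();
    NumericMatrix m(na + nb, 4);
    int i = 0, j = 0, k = 0;
    while (i < na || j < nb) {
      bool takeA = (j >= nb) || (i < na && ma(i, 0) <= mb(j, 0));
      if (takeA) {
        for (int c = 0; c < 4; ++c) m(k, c) = ma(i, c);
        ++i;
      } else {
        for (int c = 0; c < 4; ++c) m(k, c) = mb(j, c);
        ++j;
      }
      ++k;
    }
    out[w] = m;
  }
  return out;
}
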