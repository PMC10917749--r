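// Time-resolved pairwise Fisher LDA decoding.
//
// For every unordered condition pair and every time point, a binary linear
// discriminant (class means + pooled within-class covariance, optionally
// shrunk toward a scaled identity) is trained under cross-validation on the
// channel vectors at that single time point; the returned accuracy is the
// mean over folds of the fold-wise fraction correct.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Ledoit-Wolf shrinkage intensity toward mu*I, computed from class-centered
// training samples Xc (rows) and their biased covariance S.
static double lw_intensity(const mat& Xc, const mat& S) {
  const double n = (double)Xc.n_rows;
  const double p = (double)Xc.n_cols;
  const double mu = trace(S) / p;
  mat D = S;
  D.diag() -= mu;
  const double d2 = accu(D % D);
  if (d2 <= 0.0) return 0.0;
  const double s2 = accu(S % S);
  const mat XS = Xc * S;
  double phi = 0.0;
  for (uword i = 0; i < Xc.n_rows; ++i) {
    const double q = dot(Xc.row(i), Xc.row(i));
    // ||x x' - S||_F^2 = q^2 - 2 x' S x + ||S||_F^2
    phi += q * q - 2.0 * dot(XS.row(i), Xc.row(i)) + s2;
  }
  phi /= (n * n);
  double b2 = std::min(phi, d2);
  return b2 / d2;
}

// Train on (Xa_tr, Xb_tr), classify test rows; returns fraction correct.
// Class a is the lower label index: ties at the boundary go to a.
static double lda_fold(const mat& Xa_tr, const mat& Xb_tr,
                       const mat& Xa_te, const mat& Xb_te,
                       double gamma, bool auto_gamma) {
  const uword p = Xa_tr.n_cols;
  const rowvec ma = mean(Xa_tr, 0);
  const rowvec mb = mean(Xb_tr, 0);
  mat Xc = join_cols(Xa_tr.each_row() - ma, Xb_tr.each_row() - mb);
  const double n = (double)Xc.n_rows;
  mat S = (Xc.t() * Xc) / n;  // biased pooled covariance (LW convention)
  double g = gamma;
  if (auto_gamma) g = lw_intensity(Xc, S);
  if (g > 0.0) {
    const double mu = trace(S) / (double)p;
    S = (1.0 - g) * S;
    S.diag() += g * mu;
  }
  const vec delta = (ma - mb).t();
  mat R;
  if (!chol(R, S) ||
      R.diag().min() <= 1e-8 * (1.0 + R.diag().max())) {
    Rcpp::stop("within-class covariance is singular; set a shrinkage "
               "regularization > 0 (or \"auto\")");
  }
  const vec wvec = solve(trimatu(R), solve(trimatl(R.t()), delta));
  const double c = 0.5 * dot(wvec, (ma + mb).t());
  double correct = 0.0;
  const vec sa = Xa_te * wvec;
  const vec sb = Xb_te * wvec;
  for (uword i = 0; i < sa.n_elem; ++i)
    if (sa(i) >= c) correct += 1.0;       // tie -> lower label (class a)
  for (uword i = 0; i < sb.n_elem; ++i)
    if (sb(i) < c) correct += 1.0;
  return correct / (double)(sa.n_elem + sb.n_elem);
}

// data: trials x channels x times cube; cond: 0-based condition per trial;
// fold: fold id per trial (any integers; folds are formed within each pair
// from the ids present). gamma < 0 requests Ledoit-Wolf "auto" shrinkage.
// [[Rcpp::export]]
arma::cube pairwise_decode_cpp(const arma::cube& data,
                               const arma::ivec& cond,
                               const arma::ivec& fold,
                               int n_cond, double gamma) {
  const uword n_trials = data.n_rows;
  const uword n_times = data.n_slices;
  const bool auto_gamma = gamma < 0.0;
  if (auto_gamma) gamma = 0.0;

  std::vector<std::vector<uword>> by_cond(n_cond);
  for (uword i = 0; i < n_trials; ++i) by_cond[cond(i)].push_back(i);

  cube acc(n_cond, n_cond, n_times);
  acc.fill(datum::nan);

  for (int a = 0; a < n_cond; ++a) {
    for (int b = a + 1; b < n_cond; ++b) {
      const std::vector<uword>& ia = by_cond[a];
      const std::vector<uword>& ib = by_cond[b];
      // fold ids present among this pair's trials
      std::vector<int> fids;
      for (uword i : ia) fids.push_back(fold(i));
      for (uword i : ib) fids.push_back(fold(i));
      std::sort(fids.begin(), fids.end());
      fids.erase(std::unique(fids.begin(), fids.end()), fids.end());

      // fold index sets are time-independent: build them once per pair
      std::vector<uvec> tr_a, tr_b, te_a, te_b;
      for (int f : fids) {
        std::vector<uword> tai, tbi, eai, ebi;
        for (uword i = 0; i < ia.size(); ++i)
          (fold(ia[i]) == f ? eai : tai).push_back(i);
        for (uword i = 0; i < ib.size(); ++i)
          (fold(ib[i]) == f ? ebi : tbi).push_back(i);
        if (eai.empty() && ebi.empty()) continue;
        if (tai.size() < 2 || tbi.size() < 2)
          Rcpp::stop("a cross-validation fold leaves fewer than 2 training "
                     "trials in a class; use more trials or fewer folds");
        tr_a.push_back(conv_to<uvec>::from(tai));
        tr_b.push_back(conv_to<uvec>::from(tbi));
        te_a.push_back(conv_to<uvec>::from(eai));
        te_b.push_back(conv_to<uvec>::from(ebi));
      }
      const uword n_folds_used = tr_a.size();

      mat Xa(ia.size(), data.n_cols), Xb(ib.size(), data.n_cols);
      for (uword t = 0; t < n_times; ++t) {
        for (uword i = 0; i < ia.size(); ++i)
          Xa.row(i) = data.slice(t).row(ia[i]);
        for (uword i = 0; i < ib.size(); ++i)
          Xb.row(i) = data.slice(t).row(ib[i]);

        double sum_acc = 0.0;
        for (uword f = 0; f < n_folds_used; ++f) {
          sum_acc += lda_fold(Xa.rows(tr_a[f]), Xb.rows(tr_b[f]),
                              Xa.rows(te_a[f]), Xb.rows(te_b[f]),
                              gamma, auto_gamma);
        }
        const double v = sum_acc / (double)n_folds_used;
        acc(a, b, t) = v;
        acc(b, a, t) = v;
      }
    }
  }
  return acc;
}
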