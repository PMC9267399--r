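// Core numerics: MVAR least-squares fit, transfer-function inversion on a
// frequency grid, normalized squared DTF, and the per-surrogate band-matrix
// engine used by permutation pruning. Kept in compiled code because pruning
// refits the full model-to-band pipeline (1 + n_perm) x n_epochs times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Regression of x(t) on [x(t-1) ... x(t-p)], t = t0..T (t0 is 1-based,
// t0 >= p + 1). Solved by a QR-based least-squares solve, never by normal
// equations. Returns A_1..A_p (k x k x p), the ML residual covariance
// (divisor N) and the df-adjusted covariance (divisor N - p*k).
// [[Rcpp::export]]
List cpp_fit_mvar(const arma::mat& X, int p, int t0) {
    const int k = X.n_rows;
    const int T = X.n_cols;
    if (t0 < p + 1) stop("t0 must be at least p + 1");
    const int N = T - t0 + 1;
    if (N <= p * k + k) stop("epoch too short for requested order");

    arma::mat Z(N, p * k);   // lagged regressors
    arma::mat Y(N, k);       // responses
    for (int t = 0; t < N; ++t) {
        const int tt = t0 - 1 + t;          // 0-based time of the response
        Y.row(t) = X.col(tt).t();
        for (int l = 1; l <= p; ++l)
            Z(t, arma::span((l - 1) * k, l * k - 1)) = X.col(tt - l).t();
    }

    arma::mat Q, R;
    if (!arma::qr_econ(Q, R, Z))
        stop("QR decomposition failed in MVAR fit");
    const arma::vec rd = arma::abs(R.diag());
    if (rd.min() < 1e-10 * std::max(rd.max(), 1.0))
        stop("rank-deficient regressor matrix in MVAR fit");
    const arma::mat B = arma::solve(arma::trimatu(R), Q.t() * Y);

    arma::cube A(k, k, p);
    for (int l = 0; l < p; ++l)
        A.slice(l) = B.rows(l * k, (l + 1) * k - 1).t();

    const arma::mat E = Y - Z * B;
    const arma::mat S = E.t() * E;
    const int df = N - p * k;
    return List::create(
        Named("coef") = A,
        Named("sigma_ml") = S / double(N),
        Named("sigma_ls") = (df > 0) ? arma::mat(S / double(df))
                                     : arma::mat(S * arma::datum::nan),
        Named("N") = N);
}

static bool is_lower_cube(const arma::cube& A) {
    for (arma::uword l = 0; l < A.n_slices; ++l)
        for (arma::uword j = 1; j < A.n_cols; ++j)
            for (arma::uword i = 0; i < j; ++i)
                if (A(i, j, l) != 0.0) return false;
    return true;
}

static bool is_upper_cube(const arma::cube& A) {
    for (arma::uword l = 0; l < A.n_slices; ++l)
        for (arma::uword j = 0; j < A.n_cols; ++j)
            for (arma::uword i = j + 1; i < A.n_rows; ++i)
                if (A(i, j, l) != 0.0) return false;
    return true;
}

// H(f) = [I - sum_l A_l exp(-i 2 pi f l / fs)]^{-1} at each grid frequency.
// Triangular coefficient stacks are inverted by substitution so that
// structurally-absent couplings stay exactly zero (a general pivoted solve
// can leave O(eps) residue there).
static arma::cx_cube transfer_cube(const arma::cube& A, const arma::vec& freqs,
                                   double fs) {
    const int k = A.n_rows;
    const int p = A.n_slices;
    const int nf = freqs.n_elem;
    const bool lower = is_lower_cube(A), upper = is_upper_cube(A);
    const arma::cx_mat I = arma::cx_mat(arma::eye(k, k),
                                        arma::zeros(k, k));
    arma::cx_cube H(k, k, nf);
    for (int fi = 0; fi < nf; ++fi) {
        arma::cx_mat Ab = I;
        for (int l = 1; l <= p; ++l) {
            const double w = -2.0 * arma::datum::pi * freqs(fi) * l / fs;
            Ab -= arma::cx_double(std::cos(w), std::sin(w)) * A.slice(l - 1);
        }
        arma::cx_mat Hf;
        bool ok;
        if (lower && !upper)
            ok = arma::solve(Hf, arma::trimatl(Ab), I);
        else if (upper && !lower)
            ok = arma::solve(Hf, arma::trimatu(Ab), I);
        else
            ok = arma::solve(Hf, Ab, I, arma::solve_opts::no_approx);
        if (!ok || !Hf.is_finite())
            stop("singular coefficient matrix at f = %f Hz", freqs(fi));
        H.slice(fi) = Hf;
    }
    return H;
}

// [[Rcpp::export]]
arma::cx_cube cpp_transfer(const arma::cube& A, const arma::vec& freqs,
                           double fs) {
    return transfer_cube(A, freqs, fs);
}

// Normalized squared DTF: gamma2(i <- j, f) = |H_ij|^2 / sum_m |H_im|^2.
static arma::cube dtf_from_transfer(const arma::cx_cube& H) {
    const int k = H.n_rows;
    const int nf = H.n_slices;
    arma::cube g(k, k, nf);
    for (int fi = 0; fi < nf; ++fi) {
        arma::mat num = arma::square(arma::abs(H.slice(fi)));
        arma::vec den = arma::sum(num, 1);
        for (int i = 0; i < k; ++i) {
            if (den(i) <= 0.0)
                stop("all-zero transfer row for channel %d", i + 1);
            g.slice(fi).row(i) = num.row(i) / den(i);
        }
    }
    return g;
}

// [[Rcpp::export]]
arma::cube cpp_dtf(const arma::cube& A, const arma::vec& freqs, double fs) {
    return dtf_from_transfer(transfer_cube(A, freqs, fs));
}

// Band means of gamma2 for one coefficient stack; bins is a list of 1-based
// integer vectors of grid indices per band. Returns k x k x n_bands.
static arma::cube band_means(const arma::cube& g, const List& bins) {
    const int k = g.n_rows;
    const int nb = bins.size();
    arma::cube out(k, k, nb, arma::fill::zeros);
    for (int b = 0; b < nb; ++b) {
        IntegerVector idx = bins[b];
        for (int q = 0; q < idx.size(); ++q)
            out.slice(b) += g.slice(idx[q] - 1);
        out.slice(b) /= double(idx.size());
    }
    return out;
}

// Per-epoch band-aggregated DTF matrices for an epoch stack
// (k x T x n_epochs). Returns a k x k x n_bands x n_epochs array.
// [[Rcpp::export]]
NumericVector cpp_epoch_band(const arma::cube& epochs, int p,
                             const arma::vec& freqs, double fs,
                             const List& bins) {
    const int k = epochs.n_rows;
    const int E = epochs.n_slices;
    const int nb = bins.size();
    NumericVector out(k * k * nb * E);
    out.attr("dim") = IntegerVector::create(k, k, nb, E);
    for (int e = 0; e < E; ++e) {
        List fit = cpp_fit_mvar(epochs.slice(e), p, p + 1);
        arma::cube A = fit["coef"];
        arma::cube bm = band_means(cpp_dtf(A, freqs, fs), bins);
        std::copy(bm.begin(), bm.end(), out.begin() + e * k * k * nb);
    }
    return out;
}

// Surrogate engine for permutation pruning. perms has dim
// (n_epochs, k, n_perm), 1-based epoch indices: surrogate r assembles epoch
// e, channel c from original epoch perms(e, c, r) (independent epoch-order
// shuffling per channel destroys cross-channel coupling, preserves spectra).
// Returns the element-wise median across epochs of the per-epoch band
// matrices, as a k x k x n_bands x n_perm array.
// [[Rcpp::export]]
NumericVector cpp_surrogate_band_medians(const arma::cube& epochs, int p,
                                         const arma::vec& freqs, double fs,
                                         const List& bins,
                                         const IntegerVector& perms) {
    const int k = epochs.n_rows;
    const int T = epochs.n_cols;
    const int E = epochs.n_slices;
    const int nb = bins.size();
    IntegerVector pd = perms.attr("dim");
    if (pd.size() != 3 || pd[0] != E || pd[1] != k)
        stop("perms must have dim (n_epochs, k, n_perm)");
    const int R = pd[2];

    NumericVector out(k * k * nb * R);
    out.attr("dim") = IntegerVector::create(k, k, nb, R);
    arma::cube surr(k, T, E);
    arma::cube stats(k * k, nb, E);   // per-epoch band matrices, flattened

    for (int r = 0; r < R; ++r) {
        for (int e = 0; e < E; ++e)
            for (int c = 0; c < k; ++c) {
                const int src = perms[e + E * (c + k * r)] - 1;
                surr.slice(e).row(c) = epochs.slice(src).row(c);
            }
        for (int e = 0; e < E; ++e) {
            List fit = cpp_fit_mvar(surr.slice(e), p, p + 1);
            arma::cube A = fit["coef"];
            arma::cube bm = band_means(cpp_dtf(A, freqs, fs), bins);
            stats.slice(e) = arma::reshape(
                arma::mat(bm.memptr(), k * k, nb), k * k, nb);
        }
        arma::mat med(k * k, nb);
        arma::vec tmp(E);
        for (int b = 0; b < nb; ++b)
            for (int a = 0; a < k * k; ++a) {
                for (int e = 0; e < E; ++e) tmp(e) = stats(a, b, e);
                med(a, b) = arma::median(tmp);
            }
        std::copy(med.begin(), med.end(), out.begin() + r * k * k * nb);
        if (r % 32 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

// Companion-matrix simulation of one epoch from a coefficient stack;
// innovations supplied by the caller (k x (burn_in + n)). Returns the last
// n samples.
// [[Rcpp::export]]
arma::mat cpp_simulate_var(const arma::cube& A, const arma::mat& innov,
                           int n_keep) {
    const int k = A.n_rows;
    const int p = A.n_slices;
    const int Ttot = innov.n_cols;
    arma::mat X(k, Ttot, arma::fill::zeros);
    for (int t = 0; t < Ttot; ++t) {
        arma::vec x = innov.col(t);
        for (int l = 1; l <= p && t - l >= 0; ++l)
            x += A.slice(l - 1) * X.col(t - l);
        X.col(t) = x;
    }
    if (!X.is_finite()) stop("simulation diverged (non-finite samples)");
    return X.cols(Ttot - n_keep, Ttot - 1);
}
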