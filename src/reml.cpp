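// REML engine for the family-nested random allele-substitution scan.
//
// Model per tested marker (on entry BLUPs y):
//   y = X beta + W alpha + phi + eps,
//   alpha ~ N(0, I s2a), phi ~ N(0, K s2p), eps ~ N(0, I s2e),
// where W holds family-specific founder-allele doses and K is a
// VanRaden relationship matrix built excluding markers inside the
// linkage window around the tested marker.
//
// Everything is evaluated in the eigenbasis of the *full* cross-product
// S = Xc Xc' (U D U'), so the per-marker window exclusion is a low-rank
// downdate: with lambda = (s2a/s2e, s2p/s2e),
//   V/s2e = diag(1 + lp/c * d) + B A B',
//   B = U'[W, Zw],  A = diag(la * I_q, -(lp/c) * I_w),
// and Woodbury/determinant-lemma identities give the restricted
// profile likelihood in O(n r^2) per evaluation (r = q + w).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Profile restricted -2 log-likelihood (up to an additive constant)
// and, optionally, BLUPs of the family effects with prediction-error
// variances. Btil holds q family-dose columns then w window columns.
// [[Rcpp::export(name = ".remlEval")]]
Rcpp::List remlEval(double logla, double loglp, const arma::vec& d,
                    const arma::vec& ytil, const arma::mat& Xtil,
                    const arma::mat& Btil, int q, double cm,
                    bool blup = false) {
    const double la = std::exp(logla);
    const double lp = std::exp(loglp);
    const uword n = ytil.n_elem;
    const uword p = Xtil.n_cols;
    const uword r = Btil.n_cols;
    const uword w = r - (uword)q;

    vec dv = 1.0 + (lp / cm) * d;
    vec idv = 1.0 / dv;

    vec avec(r);
    if (q > 0) avec.head(q).fill(la);
    if (w > 0) avec.tail(w).fill(-lp / cm);

    double logdetV = accu(log(dv));
    mat Mi;                         // inv(I + A B' Dv^-1 B)
    mat Bi;                         // Dv^-1 B
    if (r > 0) {
        Bi = Btil.each_col() % idv;
        mat C = Btil.t() * Bi;      // r x r
        mat M = eye<mat>(r, r) + (C.each_col() % avec);
        double val, sign;
        log_det(val, sign, M);
        if (sign <= 0 || !std::isfinite(val))
            return Rcpp::List::create(Rcpp::Named("obj") = R_PosInf);
        logdetV += val;
        Mi = inv(M);
    }

    // V^-1 x = Dv^-1 x - Dv^-1 B Mi (avec % (B' Dv^-1 x))
    auto vsolve = [&](const mat& x) -> mat {
        mat ix = x.each_col() % idv;
        if (r == 0) return ix;
        mat t = Btil.t() * ix;          // r x k
        t.each_col() %= avec;
        return ix - Bi * (Mi * t);
    };

    mat Xv = vsolve(Xtil);              // n x p
    mat xtvx = Xtil.t() * Xv;           // p x p
    vec yv = vsolve(mat(ytil)).col(0);
    vec xtvy = Xtil.t() * yv;
    double ldx, sgx;
    log_det(ldx, sgx, xtvx);
    if (sgx <= 0 || !std::isfinite(ldx))
        return Rcpp::List::create(Rcpp::Named("obj") = R_PosInf);
    vec beta = solve(xtvx, xtvy);
    double yvy = dot(ytil, yv);
    double yPy = yvy - dot(xtvy, beta);
    if (yPy <= 0)
        return Rcpp::List::create(Rcpp::Named("obj") = R_PosInf);
    double obj = logdetV + ldx + (double)(n - p) * std::log(yPy);

    if (!blup)
        return Rcpp::List::create(Rcpp::Named("obj") = obj);

    double s2e = yPy / (double)(n - p);
    vec res = ytil - Xtil * beta;
    vec vres = vsolve(mat(res)).col(0);
    vec alpha(q, fill::zeros);
    vec pev(q, fill::zeros);
    if (q > 0) {
        mat Wt = Btil.cols(0, q - 1);
        alpha = la * (Wt.t() * vres);
        mat Wv = vsolve(Wt);            // Vlam^-1 W
        mat WX = Wt.t() * Xv;           // q x p
        mat WPW = Wt.t() * Wv - WX * solve(xtvx, WX.t());
        pev = s2e * (la - la * la * WPW.diag());
        pev = clamp(pev, 0.0, datum::inf);
    }
    return Rcpp::List::create(
        Rcpp::Named("obj") = obj, Rcpp::Named("s2e") = s2e,
        Rcpp::Named("s2a") = la * s2e, Rcpp::Named("s2p") = lp * s2e,
        Rcpp::Named("beta") = beta, Rcpp::Named("alpha") = alpha,
        Rcpp::Named("pev") = pev);
}
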