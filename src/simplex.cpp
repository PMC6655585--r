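// Bounded-variable two-phase revised simplex.
//
// Solves   min c'x   s.t.  A x = b,  0 <= x <= u   (u may be +Inf).
// Callers encode inequality rows by appending slack columns and model
// reversible fluxes as forward/backward column pairs, so lower bounds of
// zero suffice.  The basis inverse is kept explicitly and refactorised
// periodically; Bland's rule engages after a run of degenerate pivots.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PIVOT_TOL = 1e-10;
static const double DUAL_TOL = 1e-9;
static const double FEAS_TOL = 1e-8;
static const int REFACTOR_EVERY = 100;

namespace {

struct SimplexState {
  mat A;            // m x N extended matrix (structural + artificial)
  vec b;            // m, >= 0 after row flips
  vec ub;           // N upper bounds
  mat Binv;         // m x m
  uvec basis;       // m column indices
  vec xB;           // m basic values
  ivec status;      // N: 0 nonbasic at lower, 1 nonbasic at upper, 2 basic
  uword m, n, N;    // rows, structural cols, total cols
};

void refactorize(SimplexState &S) {
  mat B(S.m, S.m);
  for (uword i = 0; i < S.m; ++i) B.col(i) = S.A.col(S.basis(i));
  S.Binv = solve(B, eye(S.m, S.m), solve_opts::allow_ugly);
  vec rhs = S.b;
  for (uword j = 0; j < S.N; ++j)
    if (S.status(j) == 1) rhs -= S.A.col(j) * S.ub(j);
  S.xB = S.Binv * rhs;
}

// One simplex phase. allow_enter(j) filters entering candidates.
// Returns 0 optimal, 2 unbounded, 3 iteration limit.
int run_phase(SimplexState &S, const vec &cost, bool phase2, int max_iter) {
  int degen_run = 0;
  for (int iter = 0; iter < max_iter; ++iter) {
    if (iter > 0 && iter % REFACTOR_EVERY == 0) refactorize(S);

    vec cB(S.m);
    for (uword i = 0; i < S.m; ++i) cB(i) = cost(S.basis(i));
    vec y = S.Binv.t() * cB;
    vec d = cost - S.A.t() * y;

    bool bland = degen_run > 60;
    sword q = -1;
    double best = DUAL_TOL;
    for (uword j = 0; j < S.N; ++j) {
      if (S.status(j) == 2) continue;
      if (phase2 && j >= S.n) continue;            // artificials locked out
      double viol = 0.0;
      if (S.status(j) == 0 && d(j) < -DUAL_TOL) viol = -d(j);
      else if (S.status(j) == 1 && d(j) > DUAL_TOL) viol = d(j);
      else continue;
      if (bland) { q = j; break; }
      if (viol > best) { best = viol; q = j; }
    }
    if (q < 0) return 0;  // optimal for this phase

    double s = (S.status(q) == 0) ? 1.0 : -1.0;    // direction of x_q change
    vec alpha = S.Binv * S.A.col(q);

    // ratio test: x_B changes by -s * t * alpha
    double tmax = datum::inf;
    sword leave = -1;
    int leave_to = 0;  // bound the leaving variable reaches
    for (uword i = 0; i < S.m; ++i) {
      double a = s * alpha(i);
      if (a > PIVOT_TOL) {                          // basic decreases to 0
        double t = S.xB(i) / a;
        if (t < tmax - PIVOT_TOL || (t < tmax + PIVOT_TOL && leave >= 0 &&
                                     S.basis(i) < S.basis(leave))) {
          tmax = t; leave = i; leave_to = 0;
        }
      } else if (a < -PIVOT_TOL) {                  // basic increases to ub
        double u = S.ub(S.basis(i));
        if (std::isfinite(u)) {
          double t = (u - S.xB(i)) / (-a);
          if (t < tmax - PIVOT_TOL || (t < tmax + PIVOT_TOL && leave >= 0 &&
                                       S.basis(i) < S.basis(leave))) {
            tmax = t; leave = i; leave_to = 1;
          }
        }
      }
    }
    bool flip = false;
    if (std::isfinite(S.ub(q)) && S.ub(q) < tmax) { tmax = S.ub(q); flip = true; }
    if (!std::isfinite(tmax)) return 2;             // unbounded ray

    degen_run = (tmax < 1e-11) ? degen_run + 1 : 0;

    S.xB -= s * tmax * alpha;
    if (flip) {
      S.status(q) = (S.status(q) == 0) ? 1 : 0;
      continue;
    }
    double xq = (S.status(q) == 0) ? tmax : S.ub(q) - tmax;
    uword out = S.basis(leave);
    S.status(out) = leave_to;
    S.status(q) = 2;
    S.basis(leave) = q;
    // eta update of Binv
    double piv = alpha(leave);
    rowvec prow = S.Binv.row(leave) / piv;
    for (uword i = 0; i < S.m; ++i) {
      if ((sword)i == leave) continue;
      double a = alpha(i);
      if (std::abs(a) > 1e-14) S.Binv.row(i) -= a * prow;
    }
    S.Binv.row(leave) = prow;
    S.xB(leave) = xq;
  }
  return 3;
}

}  // namespace

// [[Rcpp::export(name = ".simplex_solve")]]
Rcpp::List simplex_solve(const arma::mat &Ain, const arma::vec &bin,
                         const arma::vec &cin, const arma::vec &ubin,
                         int max_iter) {
  SimplexState S;
  S.m = Ain.n_rows; S.n = Ain.n_cols; S.N = S.n + S.m;
  S.A = join_rows(Ain, eye(S.m, S.m));
  S.b = bin;
  for (uword i = 0; i < S.m; ++i)
    if (S.b(i) < 0) { S.b(i) = -S.b(i); S.A.row(i) = -S.A.row(i); }
  S.ub = join_cols(ubin, vec(S.m, fill::value(datum::inf)));
  S.Binv = eye(S.m, S.m);
  S.basis = regspace<uvec>(S.n, S.N - 1);
  S.xB = S.b;
  S.status.set_size(S.N);
  S.status.fill(0);
  for (uword i = 0; i < S.m; ++i) S.status(S.n + i) = 2;

  if (max_iter <= 0) max_iter = 20000 + 50 * (int)(S.m + S.n);

  // phase 1: drive artificials to zero
  vec c1(S.N, fill::zeros);
  for (uword j = S.n; j < S.N; ++j) c1(j) = 1.0;
  int rc = run_phase(S, c1, false, max_iter);
  if (rc == 3)
    return Rcpp::List::create(Rcpp::Named("status") = 3);
  refactorize(S);
  double art = 0.0;
  for (uword i = 0; i < S.m; ++i)
    if (S.basis(i) >= S.n) art += std::abs(S.xB(i));
  if (art > FEAS_TOL)
    return Rcpp::List::create(Rcpp::Named("status") = 1);
  for (uword j = S.n; j < S.N; ++j) S.ub(j) = 0.0;  // pin artificials

  // phase 2
  vec c2(S.N, fill::zeros);
  c2.head(S.n) = cin;
  rc = run_phase(S, c2, true, max_iter);
  if (rc == 3)
    return Rcpp::List::create(Rcpp::Named("status") = 3);
  if (rc == 2)
    return Rcpp::List::create(Rcpp::Named("status") = 2);
  refactorize(S);

  vec x(S.n, fill::zeros);
  for (uword j = 0; j < S.n; ++j)
    if (S.status(j) == 1) x(j) = S.ub(j);
  for (uword i = 0; i < S.m; ++i)
    if (S.basis(i) < S.n) x(S.basis(i)) = S.xB(i);
  double obj = dot(cin, x);
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("x") = x);
}
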