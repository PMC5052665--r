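#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Heun integration of an isolated node (optionally with an instantaneous
// self-coupling of weight w on psi1, scaled by eta like network coupling).
// stim_drive is the already eta-scaled constant drive over [on, off) steps.
// [[Rcpp::export]]
List heun_isolated(double eta, double gamma_, double epsilon,
                   double stim_drive, int on, int off, int n_steps,
                   double dt, double self_weight, int stride) {
  int n_rec = n_steps / stride + 1;
  NumericVector p1(n_rec), p2(n_rec);
  double x1 = 0.0, x2 = 0.0, peak = 0.0;
  int r = 1;
  p1[0] = 0.0; p2[0] = 0.0;
  for (int t = 0; t < n_steps; ++t) {
    // the stimulus is constant over each step interval [t, t+1); using the
    // same value in both stages keeps Heun second order across the edges
    double s1 = (t >= on && t < off) ? stim_drive : 0.0;
    double s2 = s1;
    double k11 = eta * (x2 - gamma_ * x1 - x1 * x1 * x1)
                 + eta * self_weight * x1 + s1;
    double k12 = -eta * epsilon * x1;
    double y1 = x1 + dt * k11, y2 = x2 + dt * k12;
    double k21 = eta * (y2 - gamma_ * y1 - y1 * y1 * y1)
                 + eta * self_weight * y1 + s2;
    double k22 = -eta * epsilon * y1;
    x1 += 0.5 * dt * (k11 + k21);
    x2 += 0.5 * dt * (k12 + k22);
    if (std::abs(x1) > peak) peak = std::abs(x1);
    if ((t + 1) % stride == 0 && r < n_rec) { p1[r] = x1; p2[r] = x2; ++r; }
  }
  return List::create(_["psi1"] = p1, _["psi2"] = p2, _["peak"] = peak);
}

// Heun integration of the full delayed network.
//
//   dpsi1_i/dt = eta*(psi2_i - gamma*psi1_i - psi1_i^3)
//                + eta*[(1-alpha)*sum_j hom(i,j)*psi1_j(t)
//                       + alpha*sum_b C(a(i),b)*<psi1>_b(t - tau(a(i),b))
//                       + stim_i(t)]
//   dpsi2_i/dt = -eta*epsilon*psi1_i
//
// hom: sparse node x node (row = target); C: area x area (row = target);
// dsteps: delays rounded to integer steps; node_area: 0-based area per node;
// stim_nodes: 0-based stimulated nodes.  History before t = 0 is zero.
// The delayed drive is evaluated from a ring of recorded area means; for the
// corrector stage the means of the predictor state stand in where the delay
// is zero steps.
// [[Rcpp::export]]
List heun_network(const arma::sp_mat& hom, const arma::mat& C,
                  const arma::imat& dsteps, const arma::uvec& node_area,
                  const arma::uvec& stim_nodes, double stim_amp,
                  int stim_on, int stim_off, double alpha, double eta,
                  double gamma_, double epsilon, int n_steps, double dt,
                  int stride) {
  const arma::uword N = hom.n_rows;
  const arma::uword A = C.n_rows;
  if (node_area.n_elem != N) stop("node_area length mismatch");

  // area sizes
  arma::vec asz(A, arma::fill::zeros);
  for (arma::uword i = 0; i < N; ++i) asz(node_area(i)) += 1.0;

  // edge list of the heterogeneous coupling
  std::vector<arma::uword> e_tgt, e_src;
  std::vector<double> e_w;
  std::vector<int> e_d;
  bool any_zero_delay = false;
  for (arma::uword a = 0; a < A; ++a)
    for (arma::uword b = 0; b < A; ++b)
      if (C(a, b) != 0.0) {
        e_tgt.push_back(a); e_src.push_back(b);
        e_w.push_back(C(a, b)); e_d.push_back(dsteps(a, b));
        if (dsteps(a, b) == 0) any_zero_delay = true;
      }
  const size_t nE = e_tgt.size();

  arma::mat buf(A, n_steps + 1, arma::fill::zeros);  // area-mean history
  arma::vec x1(N, arma::fill::zeros), x2(N, arma::fill::zeros);
  int n_rec = n_steps / stride + 1;
  arma::mat rec1(N, n_rec, arma::fill::zeros), rec2(N, n_rec, arma::fill::zeros);
  int r = 1;

  arma::vec means(A), pmeans(A), adrive(A), adrive2(A);
  arma::vec drive(N), k11(N), k12(N), y1(N), y2(N), k21(N), k22(N);

  for (int t = 0; t < n_steps; ++t) {
    // record current area means into the history ring
    means.zeros();
    for (arma::uword i = 0; i < N; ++i) means(node_area(i)) += x1(i);
    for (arma::uword a = 0; a < A; ++a)
      if (asz(a) > 0) means(a) /= asz(a);
    buf.col(t) = means;

    // stage 1 drive at time t
    adrive.zeros();
    for (size_t e = 0; e < nE; ++e) {
      int idx = t - e_d[e];
      double m = (idx >= 0) ? buf(e_src[e], idx) : 0.0;
      adrive(e_tgt[e]) += e_w[e] * m;
    }
    drive = (1.0 - alpha) * (hom * x1);
    for (arma::uword i = 0; i < N; ++i) drive(i) += alpha * adrive(node_area(i));
    // stimulus constant over the step interval (both stages; see above)
    double s1 = (t >= stim_on && t < stim_off) ? stim_amp : 0.0;
    double s2 = s1;
    if (s1 != 0.0)
      for (arma::uword k = 0; k < stim_nodes.n_elem; ++k)
        drive(stim_nodes(k)) += s1;

    k11 = eta * (x2 - gamma_ * x1 - x1 % x1 % x1) + eta * drive;
    k12 = -eta * epsilon * x1;
    y1 = x1 + dt * k11;
    y2 = x2 + dt * k12;

    // stage 2 drive at time t + 1 (delayed means from the ring; zero-delay
    // edges use the predictor means)
    if (any_zero_delay) {
      pmeans.zeros();
      for (arma::uword i = 0; i < N; ++i) pmeans(node_area(i)) += y1(i);
      for (arma::uword a = 0; a < A; ++a)
        if (asz(a) > 0) pmeans(a) /= asz(a);
    }
    adrive2.zeros();
    for (size_t e = 0; e < nE; ++e) {
      double m;
      if (e_d[e] == 0) m = pmeans(e_src[e]);
      else {
        int idx = t + 1 - e_d[e];
        m = (idx >= 0) ? buf(e_src[e], idx) : 0.0;
      }
      adrive2(e_tgt[e]) += e_w[e] * m;
    }
    drive = (1.0 - alpha) * (hom * y1);
    for (arma::uword i = 0; i < N; ++i) drive(i) += alpha * adrive2(node_area(i));
    if (s2 != 0.0)
      for (arma::uword k = 0; k < stim_nodes.n_elem; ++k)
        drive(stim_nodes(k)) += s2;

    k21 = eta * (y2 - gamma_ * y1 - y1 % y1 % y1) + eta * drive;
    k22 = -eta * epsilon * y1;
    x1 += 0.5 * dt * (k11 + k21);
    x2 += 0.5 * dt * (k12 + k22);

    if ((t + 1) % 500 == 0 && !x1.is_finite())
      stop("simulation diverged at step %d", t + 1);
    if ((t + 1) % stride == 0 && r < n_rec) {
      rec1.col(r) = x1; rec2.col(r) = x2; ++r;
    }
  }
  if (!x1.is_finite() || !x2.is_finite())
    stop("simulation diverged at step %d", n_steps);
  return List::create(_["psi1"] = rec1, _["psi2"] = rec2);
}
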