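// Shallow feedforward classifier used for hotspot prediction:
// [optional batch norm] -> dense(p -> hidden, ReLU) -> dense(hidden -> 2,
// softmax), categorical cross-entropy with optional class weights,
// full-batch Adam updates, Glorot-uniform initialization from a seeded
// generator. Deterministic per seed; supports warm starts for transfer
// learning.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Params {
  mat W1, W2;
  rowvec b1, b2;
  rowvec gamma, beta;      // batch-norm affine
  rowvec run_mean, run_var; // batch-norm inference statistics
  bool batch_norm;
};

struct Adam {
  mat mW1, vW1, mW2, vW2;
  rowvec mb1, vb1, mb2, vb2, mg, vg, mbt, vbt;
  double t = 0.0;
  explicit Adam(const Params& p) {
    mW1 = zeros(size(p.W1)); vW1 = mW1;
    mW2 = zeros(size(p.W2)); vW2 = mW2;
    mb1 = zeros<rowvec>(p.b1.n_elem); vb1 = mb1;
    mb2 = zeros<rowvec>(p.b2.n_elem); vb2 = mb2;
    mg = zeros<rowvec>(p.gamma.n_elem); vg = mg;
    mbt = zeros<rowvec>(p.beta.n_elem); vbt = mbt;
  }
};

const double B1 = 0.9, B2 = 0.999, EPS = 1e-8, BN_EPS = 1e-5,
             BN_MOM = 0.9;

template <typename T>
void adam_step(T& w, T& m, T& v, const T& g, double lr, double t) {
  m = B1 * m + (1.0 - B1) * g;
  v = B2 * v + (1.0 - B2) * (g % g);
  T mhat = m / (1.0 - std::pow(B1, t));
  T vhat = v / (1.0 - std::pow(B2, t));
  w -= lr * mhat / (sqrt(vhat) + EPS);
}

mat glorot(unsigned rows, unsigned cols, std::mt19937& rng) {
  double lim = std::sqrt(6.0 / (rows + cols));
  std::uniform_real_distribution<double> unif(-lim, lim);
  mat w(rows, cols);
  for (uword j = 0; j < w.n_cols; ++j)
    for (uword i = 0; i < w.n_rows; ++i) w(i, j) = unif(rng);
  return w;
}

mat softmax_rows(mat z) {
  z.each_col() -= max(z, 1);
  mat e = exp(z);
  e.each_col() /= sum(e, 1);
  return e;
}

Params unpack(const Rcpp::List& model) {
  Params p;
  p.W1 = Rcpp::as<mat>(model["W1"]);
  p.b1 = Rcpp::as<rowvec>(model["b1"]);
  p.W2 = Rcpp::as<mat>(model["W2"]);
  p.b2 = Rcpp::as<rowvec>(model["b2"]);
  p.gamma = Rcpp::as<rowvec>(model["gamma"]);
  p.beta = Rcpp::as<rowvec>(model["beta"]);
  p.run_mean = Rcpp::as<rowvec>(model["run_mean"]);
  p.run_var = Rcpp::as<rowvec>(model["run_var"]);
  p.batch_norm = Rcpp::as<bool>(model["batch_norm"]);
  return p;
}

Rcpp::List pack(const Params& p, const vec& loss) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = p.W1, Rcpp::Named("b1") = p.b1,
      Rcpp::Named("W2") = p.W2, Rcpp::Named("b2") = p.b2,
      Rcpp::Named("gamma") = p.gamma, Rcpp::Named("beta") = p.beta,
      Rcpp::Named("run_mean") = p.run_mean,
      Rcpp::Named("run_var") = p.run_var,
      Rcpp::Named("batch_norm") = p.batch_norm,
      Rcpp::Named("loss") = loss);
}

} // namespace

// [[Rcpp::export(name = ".mlp_train_cpp")]]
Rcpp::List mlp_train_cpp(const arma::mat& X, const arma::ivec& y,
                         int hidden, double lr, int epochs, int seed,
                         bool batch_norm, arma::vec class_weights,
                         Rcpp::Nullable<Rcpp::List> init) {
  const uword n = X.n_rows, p = X.n_cols;
  if (y.n_elem != n) Rcpp::stop("X and y disagree in length");
  if (class_weights.n_elem != 2) Rcpp::stop("class_weights must be length 2");

  Params par;
  if (init.isNotNull()) {
    par = unpack(Rcpp::List(init));
    if (par.W1.n_rows != p) Rcpp::stop("warm-start weights disagree with X");
  } else {
    std::mt19937 rng(static_cast<unsigned>(seed));
    par.W1 = glorot(p, hidden, rng);
    par.b1 = zeros<rowvec>(hidden);
    par.W2 = glorot(hidden, 2, rng);
    par.b2 = zeros<rowvec>(2);
    par.gamma = ones<rowvec>(p);
    par.beta = zeros<rowvec>(p);
    par.run_mean = zeros<rowvec>(p);
    par.run_var = ones<rowvec>(p);
    par.batch_norm = batch_norm;
  }

  mat Y(n, 2, fill::zeros);
  vec w(n);
  for (uword i = 0; i < n; ++i) {
    Y(i, y(i)) = 1.0;
    w(i) = class_weights(y(i));
  }
  w /= accu(w); // per-sample weights summing to 1

  Adam opt(par);
  vec loss(epochs, fill::zeros);

  for (int e = 0; e < epochs; ++e) {
    mat Xb = X;
    rowvec mu, var, istd;
    mat xhat;
    if (par.batch_norm) {
      mu = mean(X, 0);
      var = arma::var(X, 1, 0); // population variance over the batch
      istd = 1.0 / sqrt(var + BN_EPS);
      xhat = X.each_row() - mu;
      xhat.each_row() %= istd;
      Xb = xhat.each_row() % par.gamma;
      Xb.each_row() += par.beta;
      par.run_mean = BN_MOM * par.run_mean + (1.0 - BN_MOM) * mu;
      par.run_var = BN_MOM * par.run_var + (1.0 - BN_MOM) * var;
    }

    mat A1 = Xb * par.W1;
    A1.each_row() += par.b1;
    mat H = clamp(A1, 0.0, datum::inf);
    mat Z = H * par.W2;
    Z.each_row() += par.b2;
    mat P = softmax_rows(Z);

    vec ce = -log(clamp(sum(P % Y, 1), 1e-12, 1.0));
    loss(e) = dot(w, ce);

    mat dZ = (P - Y);
    dZ.each_col() %= w;
    mat gW2 = H.t() * dZ;
    rowvec gb2 = sum(dZ, 0);
    mat dH = dZ * par.W2.t();
    dH.elem(find(A1 <= 0)).zeros();
    mat gW1 = Xb.t() * dH;
    rowvec gb1 = sum(dH, 0);

    opt.t += 1.0;
    if (par.batch_norm) {
      mat dXb = dH * par.W1.t();
      rowvec ggamma = sum(dXb % xhat, 0);
      rowvec gbeta = sum(dXb, 0);
      adam_step(par.gamma, opt.mg, opt.vg, ggamma, lr, opt.t);
      adam_step(par.beta, opt.mbt, opt.vbt, gbeta, lr, opt.t);
    }
    adam_step(par.W1, opt.mW1, opt.vW1, gW1, lr, opt.t);
    adam_step(par.b1, opt.mb1, opt.vb1, gb1, lr, opt.t);
    adam_step(par.W2, opt.mW2, opt.vW2, gW2, lr, opt.t);
    adam_step(par.b2, opt.mb2, opt.vb2, gb2, lr, opt.t);
  }

  return pack(par, loss);
}

// [[Rcpp::export(name = ".mlp_predict_cpp")]]
arma::mat mlp_predict_cpp(const Rcpp::List& model, const arma::mat& X) {
  Params par = unpack(model);
  mat Xb = X;
  if (par.batch_norm) {
    Xb = X.each_row() - par.run_mean;
    Xb.each_row() /= sqrt(par.run_var + BN_EPS);
    Xb.each_row() %= par.gamma;
    Xb.each_row() += par.beta;
  }
  mat A1 = Xb * par.W1;
  A1.each_row() += par.b1;
  mat H = clamp(A1, 0.0, datum::inf);
  mat Z = H * par.W2;
  Z.each_row() += par.b2;
  return softmax_rows(Z);
}
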