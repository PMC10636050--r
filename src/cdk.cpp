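// Gene-modular network core: forward pass, analytic gradients and the
// RMSprop mini-batch training loop. The parameter vector layout is
//   [vec(W1) | b1 | w2 | b2 | wf | bf]
// with W1 (hidden x 11) stored column-major, so it matches the R-side
// flatten/unflatten helpers exactly. All randomness (epoch shuffles,
// dropout masks) is drawn from R's RNG so set.seed() on the R side gives
// bit-reproducible training.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Net {
  mat W1;      // hidden x 11
  vec b1;      // hidden
  vec w2;      // hidden
  double b2;
  vec wf;      // n_genes
  double bf;
};

const int N_IN = 11;  // 9 class counts + 2 gene scores

Net unpack(const vec& theta, int hidden) {
  Net net;
  const int gmod = 13 * hidden + 1;  // |G|: W1, b1, w2, b2
  const int G = static_cast<int>(theta.n_elem) - gmod - 1;  // minus bf
  if (G < 1) Rcpp::stop("parameter vector too short for hidden width");
  int k = 0;
  net.W1 = mat(theta.memptr() + k, hidden, N_IN);
  k += hidden * N_IN;
  net.b1 = theta.subvec(k, k + hidden - 1);
  k += hidden;
  net.w2 = theta.subvec(k, k + hidden - 1);
  k += hidden;
  net.b2 = theta(k++);
  net.wf = theta.subvec(k, k + G - 1);
  k += G;
  net.bf = theta(k);
  return net;
}

vec pack(const mat& dW1, const vec& db1, const vec& dw2, double db2,
         const vec& dwf, double dbf) {
  vec g(dW1.n_elem + db1.n_elem + dw2.n_elem + 1 + dwf.n_elem + 1);
  int k = 0;
  g.subvec(k, k + dW1.n_elem - 1) = vectorise(dW1);
  k += dW1.n_elem;
  g.subvec(k, k + db1.n_elem - 1) = db1;
  k += db1.n_elem;
  g.subvec(k, k + dw2.n_elem - 1) = dw2;
  k += dw2.n_elem;
  g(k++) = db2;
  g.subvec(k, k + dwf.n_elem - 1) = dwf;
  k += dwf.n_elem;
  g(k) = dbf;
  return g;
}

inline mat leaky(const mat& x) { return max(0.01 * x, x); }
inline mat dleaky(const mat& x) {
  return conv_to<mat>::from(x >= 0) + 0.01 * conv_to<mat>::from(x < 0);
}

// Concatenate a batch of (11 x G) sample slices into one 11 x (G*B) matrix.
mat stack_batch(const cube& X, const uvec& idx) {
  const uword G = X.n_cols;
  mat M(N_IN, G * idx.n_elem);
  for (uword b = 0; b < idx.n_elem; ++b)
    M.cols(b * G, (b + 1) * G - 1) = X.slice(idx(b));
  return M;
}

// Loss and gradient on a batch. When dropout_p > 0, inverted-dropout masks
// over the gene latent vector are drawn (per sample, per gene, in order)
// from R's RNG. Returns penalized loss; writes gradient into `grad`.
double batch_grad(const Net& net, const cube& X, const vec& y, const uvec& idx,
                  double l2, double dropout_p, vec& grad) {
  const uword G = X.n_cols;
  const uword B = idx.n_elem;
  mat M = stack_batch(X, idx);            // 11 x GB
  mat A1 = net.W1 * M;                    // h x GB
  A1.each_col() += net.b1;
  mat H = leaky(A1);
  vec a2 = H.t() * net.w2 + net.b2;       // GB
  vec s = max(0.01 * a2, a2);             // gene latent values
  vec mask;
  if (dropout_p > 0) {
    mask.set_size(G * B);
    const double keep = 1.0 - dropout_p;
    for (uword i = 0; i < G * B; ++i)
      mask(i) = (unif_rand() >= dropout_p) ? 1.0 / keep : 0.0;
    s %= mask;
  }
  mat S(s.memptr(), G, B, false);         // column b = sample b's latent
  vec yb(B);
  for (uword b = 0; b < B; ++b) yb(b) = y(idx(b));
  vec z = S.t() * net.wf + net.bf;
  vec p = 1.0 / (1.0 + exp(-z));
  vec pc = clamp(p, 1e-12, 1.0 - 1e-12);
  double loss = mean(-(yb % log(pc) + (1.0 - yb) % log(1.0 - pc)));

  vec dz = (p - yb) / static_cast<double>(B);
  vec dwf = S * dz;
  double dbf = accu(dz);
  mat dS = net.wf * dz.t();               // G x B
  vec ds(dS.memptr(), G * B);
  if (dropout_p > 0) ds %= mask;
  vec da2 = ds % (conv_to<vec>::from(a2 >= 0) + 0.01 * conv_to<vec>::from(a2 < 0));
  vec dw2 = H * da2;
  double db2 = accu(da2);
  mat dA1 = (net.w2 * da2.t()) % dleaky(A1);
  mat dW1 = dA1 * M.t();
  vec db1 = sum(dA1, 1);

  if (l2 > 0) {
    // decay every trainable parameter, biases included (optimizer-style
    // weight decay); excluding biases lets the output bias absorb the
    // class prior and the tiny residual discriminative direction then
    // flips sign chaotically under RMSprop at high lambda
    loss += l2 * (accu(square(net.W1)) + dot(net.b1, net.b1) +
                  dot(net.w2, net.w2) + net.b2 * net.b2 +
                  dot(net.wf, net.wf) + net.bf * net.bf);
    dW1 += 2.0 * l2 * net.W1;
    db1 += 2.0 * l2 * net.b1;
    dw2 += 2.0 * l2 * net.w2;
    db2 += 2.0 * l2 * net.b2;
    dwf += 2.0 * l2 * net.wf;
    dbf += 2.0 * l2 * net.bf;
  }
  grad = pack(dW1, db1, dw2, db2, dwf, dbf);
  return loss;
}

}  // namespace

// [[Rcpp::export]]
arma::vec cdk_forward_cpp(const arma::vec& theta, const arma::cube& X,
                          int hidden) {
  Net net = unpack(theta, hidden);
  const uword N = X.n_slices;
  uvec idx = regspace<uvec>(0, N - 1);
  mat M = stack_batch(X, idx);
  mat A1 = net.W1 * M;
  A1.each_col() += net.b1;
  vec a2 = leaky(A1).t() * net.w2 + net.b2;
  vec s = max(0.01 * a2, a2);
  mat S(s.memptr(), X.n_cols, N, false);
  return 1.0 / (1.0 + exp(-(S.t() * net.wf + net.bf)));
}

// [[Rcpp::export]]
Rcpp::List cdk_grad_cpp(const arma::vec& theta, const arma::cube& X,
                        const arma::vec& y, int hidden, double l2) {
  Net net = unpack(theta, hidden);
  vec grad;
  uvec idx = regspace<uvec>(0, X.n_slices - 1);
  double loss = batch_grad(net, X, y, idx, l2, 0.0, grad);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// [[Rcpp::export]]
Rcpp::List cdk_train_cpp(arma::vec theta, const arma::cube& X,
                         const arma::vec& y, int hidden, int epochs,
                         int batch_size, double lr, double l2,
                         double dropout_p, double alpha, double eps) {
  Rcpp::RNGScope scope;  // epoch shuffles + dropout come from R's RNG
  const uword N = X.n_slices;
  vec v(theta.n_elem, fill::zeros);  // RMSprop running mean of squared grads
  vec grad(theta.n_elem);
  vec trace(epochs);
  uvec perm = regspace<uvec>(0, N - 1);
  for (int e = 0; e < epochs; ++e) {
    // Fisher-Yates with R's RNG so the shuffle is seed-reproducible
    for (uword i = N - 1; i > 0; --i) {
      uword j = static_cast<uword>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm(i), perm(j));
    }
    double epoch_loss = 0.0;
    int n_batches = 0;
    for (uword start = 0; start < N; start += batch_size) {
      uword stop = std::min(start + batch_size, N) - 1;
      uvec idx = perm.subvec(start, stop);  // final short batch used as-is
      Net net = unpack(theta, hidden);
      epoch_loss += batch_grad(net, X, y, idx, l2, dropout_p, grad);
      ++n_batches;
      v = alpha * v + (1.0 - alpha) * square(grad);
      theta -= lr * grad / (sqrt(v) + eps);
    }
    trace(e) = epoch_loss / n_batches;
  }
  return Rcpp::List::create(Rcpp::Named("theta") = theta,
                            Rcpp::Named("trace") = trace);
}
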