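#include <Rcpp.h>
using namespace Rcpp;

// Back-propagation training loop for a single-hidden-layer network
//   H_j = sigmoid(sum_i w_ij x_i - theta_j),  O = sum_j H_j v_j - b
// minimizing E = mean_k 0.5 (O_k - y_k)^2 by gradient descent with a
// classical momentum term.  "online" updates parameters after every sample
// (in data order); "batch" accumulates the full-data gradient per epoch.
// Training stops when the epoch error reaches `goal` or after `max_epochs`.

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static double epoch_error(const NumericMatrix& X, const NumericVector& y,
                          const NumericMatrix& W1, const NumericVector& th,
                          const NumericVector& W2, double b) {
  const int N = X.nrow(), n = X.ncol(), q = W1.ncol();
  double E = 0.0;
  for (int s = 0; s < N; ++s) {
    double O = -b;
    for (int j = 0; j < q; ++j) {
      double z = -th[j];
      for (int i = 0; i < n; ++i) z += X(s, i) * W1(i, j);
      O += sigmoid(z) * W2[j];
    }
    double e = O - y[s];
    E += 0.5 * e * e;
  }
  return E / N;
}

// [[Rcpp::export(name = ".bpnn_train_cpp")]]
List bpnn_train_cpp(NumericMatrix X, NumericVector y, NumericMatrix W1_,
                    NumericVector th_, NumericVector W2_, double b,
                    double eta, double momentum, double goal, int max_epochs,
                    bool online) {
  NumericMatrix W1 = clone(W1_);
  NumericVector th = clone(th_), W2 = clone(W2_);
  const int N = X.nrow(), n = X.ncol(), q = W1.ncol();
  NumericMatrix vW1(n, q);
  NumericVector vth(q), vW2(q), H(q);
  double vb = 0.0;
  std::vector<double> trace;
  trace.reserve(max_epochs);
  bool converged = false, diverged = false;
  int epochs = 0;

  for (int ep = 0; ep < max_epochs; ++ep) {
    if (online) {
      for (int s = 0; s < N; ++s) {
        double O = -b;
        for (int j = 0; j < q; ++j) {
          double z = -th[j];
          for (int i = 0; i < n; ++i) z += X(s, i) * W1(i, j);
          H[j] = sigmoid(z);
          O += H[j] * W2[j];
        }
        double err = O - y[s];
        for (int j = 0; j < q; ++j) {
          double dH = err * W2[j] * H[j] * (1.0 - H[j]);
          for (int i = 0; i < n; ++i) {
            vW1(i, j) = momentum * vW1(i, j) - eta * dH * X(s, i);
            W1(i, j) += vW1(i, j);
          }
          vth[j] = momentum * vth[j] + eta * dH;
          th[j] += vth[j];
          vW2[j] = momentum * vW2[j] - eta * err * H[j];
          W2[j] += vW2[j];
        }
        vb = momentum * vb + eta * err;
        b += vb;
      }
    } else {
      NumericMatrix gW1(n, q);
      NumericVector gth(q), gW2(q);
      double gb = 0.0;
      for (int s = 0; s < N; ++s) {
        double O = -b;
        for (int j = 0; j < q; ++j) {
          double z = -th[j];
          for (int i = 0; i < n; ++i) z += X(s, i) * W1(i, j);
          H[j] = sigmoid(z);
          O += H[j] * W2[j];
        }
        double err = (O - y[s]) / N;
        for (int j = 0; j < q; ++j) {
          double dH = err * W2[j] * H[j] * (1.0 - H[j]);
          for (int i = 0; i < n; ++i) gW1(i, j) += dH * X(s, i);
          gth[j] -= dH;
          gW2[j] += err * H[j];
        }
        gb -= err;
      }
      for (int j = 0; j < q; ++j) {
        for (int i = 0; i < n; ++i) {
          vW1(i, j) = momentum * vW1(i, j) - eta * gW1(i, j);
          W1(i, j) += vW1(i, j);
        }
        vth[j] = momentum * vth[j] - eta * gth[j];
        th[j] += vth[j];
        vW2[j] = momentum * vW2[j] - eta * gW2[j];
        W2[j] += vW2[j];
      }
      vb = momentum * vb - eta * gb;
      b += vb;
    }
    double E = epoch_error(X, y, W1, th, W2, b);
    trace.push_back(E);
    epochs = ep + 1;
    if (!std::isfinite(E)) { diverged = true; break; }
    if (E <= goal) { converged = true; break; }
  }

  return List::create(_["W1"] = W1, _["theta"] = th, _["W2"] = W2, _["b"] = b,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["epochs_run"] = epochs, _["converged"] = converged,
                      _["diverged"] = diverged);
}
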