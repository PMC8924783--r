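// 1-D convolutional network for fixed-length sensor windows.
//
// Layout conventions:
//  * a batch is an arma::cube (len, channels, n_windows); slice i is one
//    window's (time x channel) matrix,
//  * inside a block, activations are matrices with n * out_len rows
//    (window-major: window i occupies rows [i*out_len, (i+1)*out_len)) and
//    one column per filter,
//  * each block is conv (valid, stride 1) -> batch norm -> ReLU ->
//    max-pool (size = stride = pool[b]); a global max-pool over time after
//    the last block feeds a single sigmoid output unit.
//
// The entry point runs forward (batch statistics when training, running
// statistics otherwise) and, on request, full backpropagation, returning
// gradients for every parameter; the optimizer lives on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col1d(const arma::cube& A, int k) {
  const int len = A.n_rows, ch = A.n_cols, n = A.n_slices;
  const int out_len = len - k + 1;
  arma::mat M(n * out_len, k * ch);
  for (int i = 0; i < n; ++i) {
    const arma::mat& W = A.slice(i);
    for (int c = 0; c < ch; ++c) {
      for (int j = 0; j < k; ++j) {
        M.submat(i * out_len, c * k + j, (i + 1) * out_len - 1, c * k + j) =
          W.col(c).subvec(j, j + out_len - 1);
      }
    }
  }
  return M;
}

static arma::cube col2im1d(const arma::mat& dM, int len, int ch, int n, int k) {
  const int out_len = len - k + 1;
  arma::cube dA(len, ch, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < ch; ++c) {
      for (int j = 0; j < k; ++j) {
        dA.slice(i).col(c).subvec(j, j + out_len - 1) +=
          dM.col(c * k + j).subvec(i * out_len, (i + 1) * out_len - 1);
      }
    }
  }
  return dA;
}

struct BlockCache {
  arma::mat M;        // im2col of the block input
  arma::mat xhat;     // normalized pre-scale activations
  arma::rowvec inv_std;
  arma::mat act;      // post-ReLU activations (pre-pool)
  arma::umat argmax;  // (n * pooled_len) x ch indices into act rows
  int in_len, ch_in, out_len, pooled_len;
};

// [[Rcpp::export]]
List cnn_pass(List weights, const arma::cube& X, const arma::vec& y,
              const IntegerVector& kernels, const IntegerVector& pools,
              bool training, bool compute_grad, double bn_momentum,
              double bn_eps) {
  const int n_blocks = kernels.size();
  const int n = X.n_slices;
  List blocks = weights["blocks"];

  arma::cube A = X;
  std::vector<BlockCache> cache(n_blocks);
  List bn_stats(n_blocks);

  for (int b = 0; b < n_blocks; ++b) {
    List blk = blocks[b];
    arma::mat W = blk["W"];
    arma::rowvec bias = blk["b"];
    arma::rowvec gamma = blk["gamma"];
    arma::rowvec beta = blk["beta"];
    arma::rowvec rmean = blk["rmean"];
    arma::rowvec rvar = blk["rvar"];

    const int k = kernels[b];
    const int in_len = A.n_rows, ch_in = A.n_cols;
    if (in_len < k) stop("input length too short for the kernel of block %d", b + 1);
    const int out_len = in_len - k + 1;
    const int ch_out = W.n_cols;

    arma::mat M = im2col1d(A, k);
    arma::mat Z = M * W;
    Z.each_row() += bias;

    arma::rowvec mu, inv_std;
    if (training) {
      mu = arma::mean(Z, 0);
      arma::rowvec var = arma::mean(arma::square(Z.each_row() - mu), 0);
      inv_std = 1.0 / arma::sqrt(var + bn_eps);
      // report updated running statistics; the R side owns the weights
      bn_stats[b] = List::create(
        Named("rmean") = (1 - bn_momentum) * rmean + bn_momentum * mu,
        Named("rvar") = (1 - bn_momentum) * rvar + bn_momentum * var);
    } else {
      mu = rmean;
      inv_std = 1.0 / arma::sqrt(rvar + bn_eps);
    }
    arma::mat xhat = (Z.each_row() - mu);
    xhat.each_row() %= inv_std;
    arma::mat Y = xhat;
    Y.each_row() %= gamma;
    Y.each_row() += beta;
    Y.transform([](double v) { return v > 0 ? v : 0.0; });  // ReLU

    const int p = pools[b];
    const int pooled_len = out_len / p;
    if (pooled_len < 1) stop("pooling empties block %d", b + 1);
    arma::cube P(pooled_len, ch_out, n);
    arma::umat amax;
    if (compute_grad) amax.set_size(n * pooled_len, ch_out);
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < ch_out; ++c) {
        for (int t = 0; t < pooled_len; ++t) {
          int base = i * out_len + t * p;
          double best = Y(base, c);
          int besti = base;
          for (int j = 1; j < p; ++j) {
            if (Y(base + j, c) > best) { best = Y(base + j, c); besti = base + j; }
          }
          P(t, c, i) = best;
          if (compute_grad) amax(i * pooled_len + t, c) = besti;
        }
      }
    }

    if (compute_grad) {
      BlockCache& cc = cache[b];
      cc.M = std::move(M);
      cc.xhat = std::move(xhat);
      cc.inv_std = inv_std;
      cc.act = std::move(Y);
      cc.argmax = std::move(amax);
      cc.in_len = in_len; cc.ch_in = ch_in;
      cc.out_len = out_len; cc.pooled_len = pooled_len;
    }
    A = std::move(P);
  }

  // global max pool over remaining length
  const int last_len = A.n_rows, ch_last = A.n_cols;
  arma::mat F(n, ch_last);
  arma::umat gmax(n, ch_last);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < ch_last; ++c) {
      arma::vec col = A.slice(i).col(c);
      arma::uword idx = col.index_max();
      F(i, c) = col(idx);
      gmax(i, c) = idx;
    }
  }

  arma::vec w_out = weights["w_out"];
  double b_out = as<double>(weights["b_out"]);
  arma::vec logits = F * w_out + b_out;
  arma::vec scores = 1.0 / (1.0 + arma::exp(-logits));

  double loss = NA_REAL;
  if (y.n_elem == (unsigned)n) {
    arma::vec p = arma::clamp(scores, 1e-12, 1 - 1e-12);
    loss = -arma::mean(y % arma::log(p) + (1 - y) % arma::log(1 - p));
  }

  List out = List::create(Named("scores") = scores, Named("loss") = loss);
  if (training) out["bn_stats"] = bn_stats;
  if (!compute_grad) return out;
  if (y.n_elem != (unsigned)n) stop("labels required for gradients");

  // ---- backward ----
  arma::vec dlogit = (scores - y) / n;
  arma::vec dw_out = F.t() * dlogit;
  double db_out = arma::accu(dlogit);
  arma::mat dF = dlogit * w_out.t();

  // back through global max pool
  arma::cube dA(last_len, ch_last, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < ch_last; ++c) {
      dA(gmax(i, c), c, i) += dF(i, c);
    }
  }

  List grads_blocks(n_blocks);
  for (int b = n_blocks - 1; b >= 0; --b) {
    List blk = blocks[b];
    arma::mat W = blk["W"];
    arma::rowvec gamma = blk["gamma"];
    BlockCache& cc = cache[b];
    const int ch_out = W.n_cols;
    const int p = pools[b];

    // dA is (pooled_len, ch_out, n); scatter back through max pool
    arma::mat dY(n * cc.out_len, ch_out, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < ch_out; ++c) {
        for (int t = 0; t < cc.pooled_len; ++t) {
          dY(cc.argmax(i * cc.pooled_len + t, c), c) += dA(t, c, i);
        }
      }
    }

    // ReLU
    dY %= arma::conv_to<arma::mat>::from(cc.act > 0);

    // batch norm backward (batch statistics)
    const double m = (double)dY.n_rows;
    arma::rowvec dgamma = arma::sum(dY % cc.xhat, 0);
    arma::rowvec dbeta = arma::sum(dY, 0);
    arma::mat dxhat = dY;
    dxhat.each_row() %= gamma;
    arma::rowvec s1 = arma::sum(dxhat, 0);
    arma::rowvec s2 = arma::sum(dxhat % cc.xhat, 0);
    arma::mat dZ = dxhat;
    dZ.each_row() -= s1 / m;
    dZ -= cc.xhat % arma::repmat(s2 / m, dZ.n_rows, 1);
    dZ.each_row() %= cc.inv_std;

    arma::mat dW = cc.M.t() * dZ;
    arma::rowvec db = arma::sum(dZ, 0);
    arma::mat dM = dZ * W.t();
    dA = col2im1d(dM, cc.in_len, cc.ch_in, n, kernels[b]);

    grads_blocks[b] = List::create(
      Named("W") = dW, Named("b") = db,
      Named("gamma") = dgamma, Named("beta") = dbeta);
  }

  out["grads"] = List::create(
    Named("blocks") = grads_blocks,
    Named("w_out") = dw_out,
    Named("b_out") = db_out);
  return out;
}
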