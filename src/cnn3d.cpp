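// Low-level 3D-CNN primitives: same-padded 3x3x3 convolution and 2x2x2 max
// pooling, forward and backward, via vol2col + GEMM. Activations are stored
// as (V*B) x C matrices (voxels by channels, samples stacked row-blockwise);
// voxel v = x + nx*(y + ny*z), 0-based. This layout makes the vol2col
// gather/scatter contiguous runs along x, so the cost is GEMM-dominated.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gather the 27-neighbourhood of sample b of X (VB x Cin) into colT
// (V x 27*Cin); padding voxels read 0.
static void vol2colT(const mat &X, int b, int nx, int ny, int nz, mat &colT) {
    const int V = nx * ny * nz;
    const int Cin = X.n_cols;
    colT.zeros();
    int o = 0;
    for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx, ++o) {
        const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
        const int L = x1 - x0;
        if (L <= 0) continue;
        for (int c = 0; c < Cin; ++c) {
            const double *src = X.colptr(c) + (size_t)b * V;
            double *dst = colT.colptr(o * Cin + c);
            for (int z = std::max(0, -dz); z < std::min(nz, nz - dz); ++z)
            for (int y = std::max(0, -dy); y < std::min(ny, ny - dy); ++y) {
                size_t v = x0 + (size_t)nx * (y + (size_t)ny * z);
                size_t s = (x0 + dx) +
                    (size_t)nx * ((y + dy) + (size_t)ny * (z + dz));
                std::memcpy(dst + v, src + s, L * sizeof(double));
            }
        }
    }
}

// scatter-add of dcolT (V x 27*Cin) back onto sample b of dX (VB x Cin)
static void col2volT(const mat &dcolT, int b, int nx, int ny, int nz,
                     mat &dX) {
    const int V = nx * ny * nz;
    const int Cin = dX.n_cols;
    int o = 0;
    for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx, ++o) {
        const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
        const int L = x1 - x0;
        if (L <= 0) continue;
        for (int c = 0; c < Cin; ++c) {
            double *dst = dX.colptr(c) + (size_t)b * V;
            const double *src = dcolT.colptr(o * Cin + c);
            for (int z = std::max(0, -dz); z < std::min(nz, nz - dz); ++z)
            for (int y = std::max(0, -dy); y < std::min(ny, ny - dy); ++y) {
                size_t v = x0 + (size_t)nx * (y + (size_t)ny * z);
                size_t s = (x0 + dx) +
                    (size_t)nx * ((y + dy) + (size_t)ny * (z + dz));
                for (int i = 0; i < L; ++i) dst[s + i] += src[v + i];
            }
        }
    }
}

// [[Rcpp::export(rng = false)]]
arma::mat nn_conv3d_fwd(const arma::mat &X, const arma::mat &W,
                        const arma::vec &b, int nx, int ny, int nz, int B,
                        bool relu) {
    const int V = nx * ny * nz;
    const int Cin = X.n_cols, Cout = W.n_cols;
    if ((int)X.n_rows != V * B) Rcpp::stop("input size mismatch");
    if ((int)W.n_rows != Cin * 27) Rcpp::stop("weight size mismatch");
    mat Y((size_t)V * B, Cout);
    mat colT(V, 27 * Cin);
    for (int s = 0; s < B; ++s) {
        vol2colT(X, s, nx, ny, nz, colT);
        Y.rows((size_t)s * V, (size_t)s * V + V - 1) = colT * W;
    }
    Y.each_row() += b.t();
    if (relu) Y.clamp(0.0, datum::inf);
    return Y;
}

// dY must already be masked by the ReLU derivative (see nn_relu_bwd).
// [[Rcpp::export(rng = false)]]
Rcpp::List nn_conv3d_bwd(const arma::mat &X, const arma::mat &W,
                         const arma::mat &dY, int nx, int ny, int nz, int B,
                         bool need_dx) {
    const int V = nx * ny * nz;
    const int Cin = X.n_cols, Cout = W.n_cols;
    mat dW(27 * Cin, Cout, fill::zeros);
    rowvec db = sum(dY, 0);
    mat dX;
    if (need_dx) dX.zeros((size_t)V * B, Cin);
    mat colT(V, 27 * Cin), dcolT;
    const mat Wt = W.t();
    for (int s = 0; s < B; ++s) {
        vol2colT(X, s, nx, ny, nz, colT);
        const mat dYs = dY.rows((size_t)s * V, (size_t)s * V + V - 1);
        dW += colT.t() * dYs;
        if (!need_dx) continue;
        dcolT = dYs * Wt;
        col2volT(dcolT, s, nx, ny, nz, dX);
    }
    return Rcpp::List::create(Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db.t(),
                              Rcpp::Named("dX") = dX);
}

// elementwise dY * (Y > 0), done here to avoid large R temporaries
// [[Rcpp::export(rng = false)]]
arma::mat nn_relu_bwd(const arma::mat &dY, const arma::mat &Y) {
    mat out(dY.n_rows, dY.n_cols);
    const double *y = Y.memptr(), *d = dY.memptr();
    double *o = out.memptr();
    const size_t n = dY.n_elem;
    for (size_t i = 0; i < n; ++i) o[i] = y[i] > 0.0 ? d[i] : 0.0;
    return out;
}

// 2x2x2 max pooling, stride 2, floor semantics on odd extents.
// idx stores the 1-based source row of each output element.
// [[Rcpp::export(rng = false)]]
Rcpp::List nn_maxpool3d_fwd(const arma::mat &X, int nx, int ny, int nz,
                            int B) {
    const int V = nx * ny * nz;
    const int C = X.n_cols;
    const int mx = nx / 2, my = ny / 2, mz = nz / 2;
    const int V2 = mx * my * mz;
    if (V2 < 1) Rcpp::stop("extent too small to pool");
    mat Y((size_t)V2 * B, C);
    umat idx((size_t)V2 * B, C);
    for (int c = 0; c < C; ++c) {
        const double *xc = X.colptr(c);
        double *yc = Y.colptr(c);
        uword *ic = idx.colptr(c);
        for (int s = 0; s < B; ++s)
        for (int z = 0; z < mz; ++z)
        for (int y = 0; y < my; ++y)
        for (int x = 0; x < mx; ++x) {
            size_t outr = (size_t)s * V2 + x + (size_t)mx * (y + (size_t)my * z);
            double best = -datum::inf;
            size_t besti = 0;
            for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
                size_t inr = (size_t)s * V + (2 * x + dx) +
                    (size_t)nx * ((2 * y + dy) + (size_t)ny * (2 * z + dz));
                if (xc[inr] > best) { best = xc[inr]; besti = inr; }
            }
            yc[outr] = best;
            ic[outr] = besti + 1;
        }
    }
    return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(rng = false)]]
arma::mat nn_maxpool3d_bwd(const arma::mat &dY, const arma::umat &idx,
                           int n_in_rows) {
    const int C = dY.n_cols;
    mat dX(n_in_rows, C, fill::zeros);
    for (int c = 0; c < C; ++c) {
        const double *dyc = dY.colptr(c);
        const uword *ic = idx.colptr(c);
        double *dxc = dX.colptr(c);
        for (size_t r = 0; r < dY.n_rows; ++r) dxc[ic[r] - 1] += dyc[r];
    }
    return dX;
}

// ---------------------------------------------------------------------------
// Fused whole-network training step and inference pass. The four-block
// architecture (Conv3D 3x3x3 same -> ReLU -> MaxPool 2x2x2 -> BatchNorm,
// filters per the model spec, then GAP -> Dense+ReLU -> Dropout ->
// Dense(1)+sigmoid) is executed entirely in C++ in single precision:
// activations never cross the R boundary, which keeps the step
// GEMM-dominated rather than memory-copy-dominated.

static void vol2colT_f(const fmat &X, int b, int nx, int ny, int nz,
                       fmat &colT) {
    const int V = nx * ny * nz;
    const int Cin = X.n_cols;
    colT.zeros();
    int o = 0;
    for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx, ++o) {
        const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
        const int L = x1 - x0;
        if (L <= 0) continue;
        for (int c = 0; c < Cin; ++c) {
            const float *src = X.colptr(c) + (size_t)b * V;
            float *dst = colT.colptr(o * Cin + c);
            for (int z = std::max(0, -dz); z < std::min(nz, nz - dz); ++z)
            for (int y = std::max(0, -dy); y < std::min(ny, ny - dy); ++y) {
                size_t v = x0 + (size_t)nx * (y + (size_t)ny * z);
                size_t s = (x0 + dx) +
                    (size_t)nx * ((y + dy) + (size_t)ny * (z + dz));
                std::memcpy(dst + v, src + s, L * sizeof(float));
            }
        }
    }
}

static void col2volT_f(const fmat &dcolT, int b, int nx, int ny, int nz,
                       fmat &dX) {
    const int V = nx * ny * nz;
    const int Cin = dX.n_cols;
    int o = 0;
    for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx, ++o) {
        const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
        const int L = x1 - x0;
        if (L <= 0) continue;
        for (int c = 0; c < Cin; ++c) {
            float *dst = dX.colptr(c) + (size_t)b * V;
            const float *src = dcolT.colptr(o * Cin + c);
            for (int z = std::max(0, -dz); z < std::min(nz, nz - dz); ++z)
            for (int y = std::max(0, -dy); y < std::min(ny, ny - dy); ++y) {
                size_t v = x0 + (size_t)nx * (y + (size_t)ny * z);
                size_t s = (x0 + dx) +
                    (size_t)nx * ((y + dy) + (size_t)ny * (z + dz));
                for (int i = 0; i < L; ++i) dst[s + i] += src[v + i];
            }
        }
    }
}

static fmat conv_fwd_f(const fmat &X, const fmat &W, const fvec &b,
                       int nx, int ny, int nz, int B) {
    const int V = nx * ny * nz;
    fmat Y((size_t)V * B, W.n_cols);
    fmat colT(V, 27 * X.n_cols);
    for (int s = 0; s < B; ++s) {
        vol2colT_f(X, s, nx, ny, nz, colT);
        Y.rows((size_t)s * V, (size_t)s * V + V - 1) = colT * W;
    }
    for (uword c = 0; c < Y.n_cols; ++c) {
        float *yc = Y.colptr(c);
        const float bc = b(c);
        for (uword r = 0; r < Y.n_rows; ++r) {
            float v = yc[r] + bc;
            yc[r] = v > 0.0f ? v : 0.0f;   // bias + ReLU fused
        }
    }
    return Y;
}

struct ConvGrad { fmat dW; fvec db; fmat dX; };

static ConvGrad conv_bwd_f(const fmat &X, const fmat &W, const fmat &dY,
                           int nx, int ny, int nz, int B, bool need_dx) {
    const int V = nx * ny * nz;
    ConvGrad g;
    g.dW.zeros(W.n_rows, W.n_cols);
    g.db = sum(dY, 0).t();
    if (need_dx) g.dX.zeros((size_t)V * B, X.n_cols);
    fmat colT(V, 27 * X.n_cols), dcolT;
    const fmat Wt = W.t();
    for (int s = 0; s < B; ++s) {
        vol2colT_f(X, s, nx, ny, nz, colT);
        const fmat dYs = dY.rows((size_t)s * V, (size_t)s * V + V - 1);
        g.dW += colT.t() * dYs;
        if (!need_dx) continue;
        dcolT = dYs * Wt;
        col2volT_f(dcolT, s, nx, ny, nz, g.dX);
    }
    return g;
}

static void pool_fwd_f(const fmat &X, int nx, int ny, int nz, int B,
                       fmat &Y, Mat<uword> &idx) {
    const int V = nx * ny * nz;
    const int C = X.n_cols;
    const int mx = nx / 2, my = ny / 2, mz = nz / 2;
    const int V2 = mx * my * mz;
    Y.set_size((size_t)V2 * B, C);
    idx.set_size((size_t)V2 * B, C);
    for (int c = 0; c < C; ++c) {
        const float *xc = X.colptr(c);
        float *yc = Y.colptr(c);
        uword *ic = idx.colptr(c);
        for (int s = 0; s < B; ++s)
        for (int z = 0; z < mz; ++z)
        for (int y = 0; y < my; ++y)
        for (int x = 0; x < mx; ++x) {
            size_t outr = (size_t)s * V2 + x + (size_t)mx * (y + (size_t)my * z);
            float best = -datum::inf;
            size_t besti = 0;
            for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
                size_t inr = (size_t)s * V + (2 * x + dx) +
                    (size_t)nx * ((2 * y + dy) + (size_t)ny * (2 * z + dz));
                if (xc[inr] > best) { best = xc[inr]; besti = inr; }
            }
            yc[outr] = best;
            ic[outr] = besti;
        }
    }
}

struct BnCache { fvec mean, var, invstd; fmat xhat; };

static fmat bn_fwd_f(const fmat &X, const fvec &gamma, const fvec &beta,
                     double eps, BnCache &cache) {
    const uword M = X.n_rows, C = X.n_cols;
    cache.mean.set_size(C); cache.var.set_size(C); cache.invstd.set_size(C);
    cache.xhat.set_size(M, C);
    fmat Y(M, C);
    for (uword c = 0; c < C; ++c) {
        const float *xc = X.colptr(c);
        double mu = 0;
        for (uword r = 0; r < M; ++r) mu += xc[r];
        mu /= M;
        double va = 0;
        for (uword r = 0; r < M; ++r) { double d = xc[r] - mu; va += d * d; }
        va /= M;
        const float inv = 1.0f / std::sqrt((float)(va + eps));
        cache.mean(c) = (float)mu; cache.var(c) = (float)va;
        cache.invstd(c) = inv;
        float *xh = cache.xhat.colptr(c);
        float *yc = Y.colptr(c);
        const float g = gamma(c), be = beta(c), muf = (float)mu;
        for (uword r = 0; r < M; ++r) {
            xh[r] = (xc[r] - muf) * inv;
            yc[r] = g * xh[r] + be;
        }
    }
    return Y;
}

static fmat bn_bwd_f(const fmat &dY, const BnCache &cache, const fvec &gamma,
                     fvec &dgamma, fvec &dbeta) {
    const uword M = dY.n_rows, C = dY.n_cols;
    fmat dX(M, C);
    dgamma.set_size(C); dbeta.set_size(C);
    for (uword c = 0; c < C; ++c) {
        const float *dyc = dY.colptr(c);
        const float *xh = cache.xhat.colptr(c);
        double sd = 0, sdx = 0, dg = 0, db = 0;
        for (uword r = 0; r < M; ++r) {
            sd += dyc[r];
            sdx += dyc[r] * xh[r];
        }
        dg = sdx; db = sd;
        const float g = gamma(c);
        const float k = g * cache.invstd(c) / M;
        float *dxc = dX.colptr(c);
        const float sdf = (float)sd, sdxf = (float)sdx;
        for (uword r = 0; r < M; ++r)
            dxc[r] = k * (M * dyc[r] - sdf - xh[r] * sdxf);
        dgamma(c) = (float)dg; dbeta(c) = (float)db;
    }
    return dX;
}

static fmat as_fmat(SEXP m) {
    Rcpp::NumericMatrix r(m);
    fmat out(r.nrow(), r.ncol());
    const double *p = r.begin();
    float *q = out.memptr();
    for (size_t i = 0; i < out.n_elem; ++i) q[i] = (float)p[i];
    return out;
}

static fvec as_fvec(SEXP v) {
    Rcpp::NumericVector r(v);
    fvec out(r.size());
    for (int i = 0; i < r.size(); ++i) out(i) = (float)r[i];
    return out;
}

struct NetParams {
    fmat W[4]; fvec b[4], gamma[4], beta[4];
    fmat Wd, Wo; fvec bd; float bo;
};

static NetParams load_params(const Rcpp::List &params) {
    NetParams P;
    for (int k = 0; k < 4; ++k) {
        std::string i = std::to_string(k + 1);
        P.W[k] = as_fmat(params["W" + i]);
        P.b[k] = as_fvec(params["b" + i]);
        P.gamma[k] = as_fvec(params["gamma" + i]);
        P.beta[k] = as_fvec(params["beta" + i]);
    }
    P.Wd = as_fmat(params["Wd"]);
    P.bd = as_fvec(params["bd"]);
    P.Wo = as_fmat(params["Wo"]);
    P.bo = (float)Rcpp::as<double>(params["bo"]);
    return P;
}

// One fused training step: full forward and backward over a mini-batch.
// x: input volumes flattened to (V*B) x 1 (voxel-major); dropout_u: uniform
// draws (dense_units * B) from the R RNG so reproducibility is controlled
// by R; y: 0/1 labels. Returns probs, loss, parameter gradients and the
// per-block batch statistics for the running-average update.
// [[Rcpp::export(rng = false)]]
Rcpp::List nn_cnn3d_train_step(const arma::vec &x, Rcpp::IntegerVector shape,
                               int B, Rcpp::List params, double bn_eps,
                               double dropout_rate,
                               const arma::vec &dropout_u,
                               const arma::vec &y) {
    NetParams P = load_params(params);
    int nx = shape[0], ny = shape[1], nz = shape[2];
    fmat A(x.n_elem, 1);
    for (size_t i = 0; i < x.n_elem; ++i) A(i, 0) = (float)x(i);

    fmat conv_out[4], bn_in[4], block_in[4];
    Mat<uword> pidx[4];
    BnCache bnc[4];
    int dims[5][3];
    dims[0][0] = nx; dims[0][1] = ny; dims[0][2] = nz;
    for (int k = 0; k < 4; ++k) {
        dims[k + 1][0] = dims[k][0] / 2;
        dims[k + 1][1] = dims[k][1] / 2;
        dims[k + 1][2] = dims[k][2] / 2;
    }
    for (int k = 0; k < 4; ++k) {
        block_in[k] = A;
        conv_out[k] = conv_fwd_f(A, P.W[k], P.b[k],
                                 dims[k][0], dims[k][1], dims[k][2], B);
        pool_fwd_f(conv_out[k], dims[k][0], dims[k][1], dims[k][2], B,
                   bn_in[k], pidx[k]);
        A = bn_fwd_f(bn_in[k], P.gamma[k], P.beta[k], bn_eps, bnc[k]);
    }
    const int V4 = dims[4][0] * dims[4][1] * dims[4][2];
    const int C4 = A.n_cols;
    fmat feat(C4, B);  // global average pooling
    for (int s = 0; s < B; ++s)
        feat.col(s) = mean(A.rows((size_t)s * V4, (size_t)s * V4 + V4 - 1),
                           0).t();
    fmat hpre = P.Wd * feat;
    hpre.each_col() += P.bd;
    fmat h = clamp(hpre, 0.0f, datum::inf);
    fmat mask;
    if (dropout_rate > 0) {
        const float keep = 1.0f - (float)dropout_rate;
        mask.set_size(h.n_rows, h.n_cols);
        for (size_t i = 0; i < mask.n_elem; ++i)
            mask(i) = dropout_u(i) < keep ? 1.0f / keep : 0.0f;
        h %= mask;
    }
    frowvec z = P.Wo.row(0) * h;
    z += P.bo;
    vec prob(B);
    for (int s = 0; s < B; ++s) prob(s) = 1.0 / (1.0 + std::exp(-(double)z(s)));
    double loss = 0;
    const double eps_l = 1e-7;
    for (int s = 0; s < B; ++s) {
        double q = std::min(std::max(prob(s), eps_l), 1 - eps_l);
        loss -= y(s) * std::log(q) + (1 - y(s)) * std::log(1 - q);
    }
    loss /= B;

    // backward
    fmat dz(1, B);
    for (int s = 0; s < B; ++s) dz(0, s) = (float)((prob(s) - y(s)) / B);
    fmat dWo = dz * h.t();
    double dbo = accu(dz);
    fmat dh = P.Wo.t() * dz;
    if (dropout_rate > 0) dh %= mask;
    for (size_t i = 0; i < dh.n_elem; ++i)
        if (hpre(i) <= 0.0f) dh(i) = 0.0f;
    fmat dWd = dh * feat.t();
    fvec dbd = sum(dh, 1);
    fmat dfeat = P.Wd.t() * dh;  // C4 x B
    fmat dA((size_t)V4 * B, C4);
    for (int s = 0; s < B; ++s)
        dA.rows((size_t)s * V4, (size_t)s * V4 + V4 - 1) =
            repmat(dfeat.col(s).t() / (float)V4, V4, 1);

    Rcpp::List grads;
    fvec dgamma, dbeta;
    for (int k = 3; k >= 0; --k) {
        fmat dbn = bn_bwd_f(dA, bnc[k], P.gamma[k], dgamma, dbeta);
        // unpool
        fmat dconv(conv_out[k].n_rows, conv_out[k].n_cols, fill::zeros);
        for (uword c = 0; c < dbn.n_cols; ++c) {
            const float *dyc = dbn.colptr(c);
            const uword *ic = pidx[k].colptr(c);
            float *dxc = dconv.colptr(c);
            for (uword r = 0; r < dbn.n_rows; ++r) dxc[ic[r]] += dyc[r];
        }
        // ReLU mask (conv_out is post-ReLU)
        for (size_t i = 0; i < dconv.n_elem; ++i)
            if (conv_out[k](i) <= 0.0f) dconv(i) = 0.0f;
        ConvGrad g = conv_bwd_f(block_in[k], P.W[k], dconv,
                                dims[k][0], dims[k][1], dims[k][2], B, k > 0);
        std::string i = std::to_string(k + 1);
        grads["W" + i] = Rcpp::wrap(conv_to<mat>::from(g.dW));
        grads["b" + i] = Rcpp::wrap(conv_to<vec>::from(g.db));
        grads["gamma" + i] = Rcpp::wrap(conv_to<vec>::from(dgamma));
        grads["beta" + i] = Rcpp::wrap(conv_to<vec>::from(dbeta));
        dA = g.dX;
    }
    grads["Wd"] = Rcpp::wrap(conv_to<mat>::from(dWd));
    grads["bd"] = Rcpp::wrap(conv_to<vec>::from(dbd));
    grads["Wo"] = Rcpp::wrap(conv_to<mat>::from(dWo));
    grads["bo"] = dbo;

    Rcpp::List bn_stats;
    for (int k = 0; k < 4; ++k) {
        std::string i = std::to_string(k + 1);
        bn_stats["mean" + i] = Rcpp::wrap(conv_to<vec>::from(bnc[k].mean));
        bn_stats["var" + i] = Rcpp::wrap(conv_to<vec>::from(bnc[k].var));
    }
    return Rcpp::List::create(Rcpp::Named("prob") = prob,
                              Rcpp::Named("loss") = loss,
                              Rcpp::Named("grads") = grads,
                              Rcpp::Named("bn") = bn_stats);
}

// Inference pass using the batch-norm running statistics.
// [[Rcpp::export(rng = false)]]
arma::vec nn_cnn3d_infer(const arma::vec &x, Rcpp::IntegerVector shape,
                         int B, Rcpp::List params, Rcpp::List running,
                         double bn_eps) {
    NetParams P = load_params(params);
    int dims[5][3];
    dims[0][0] = shape[0]; dims[0][1] = shape[1]; dims[0][2] = shape[2];
    for (int k = 0; k < 4; ++k) {
        dims[k + 1][0] = dims[k][0] / 2;
        dims[k + 1][1] = dims[k][1] / 2;
        dims[k + 1][2] = dims[k][2] / 2;
    }
    fmat A(x.n_elem, 1);
    for (size_t i = 0; i < x.n_elem; ++i) A(i, 0) = (float)x(i);
    for (int k = 0; k < 4; ++k) {
        std::string i = std::to_string(k + 1);
        fmat conv = conv_fwd_f(A, P.W[k], P.b[k],
                               dims[k][0], dims[k][1], dims[k][2], B);
        fmat pooled;
        Mat<uword> idx;
        pool_fwd_f(conv, dims[k][0], dims[k][1], dims[k][2], B, pooled, idx);
        fvec rm = as_fvec(running["mean" + i]);
        fvec rv = as_fvec(running["var" + i]);
        for (uword c = 0; c < pooled.n_cols; ++c) {
            const float inv = 1.0f / std::sqrt(rv(c) + (float)bn_eps);
            float *pc = pooled.colptr(c);
            const float g = P.gamma[k](c), be = P.beta[k](c), mu = rm(c);
            for (uword r = 0; r < pooled.n_rows; ++r)
                pc[r] = (pc[r] - mu) * inv * g + be;
        }
        A = pooled;
    }
    const int V4 = dims[4][0] * dims[4][1] * dims[4][2];
    fmat feat(A.n_cols, B);
    for (int s = 0; s < B; ++s)
        feat.col(s) = mean(A.rows((size_t)s * V4, (size_t)s * V4 + V4 - 1),
                           0).t();
    fmat hpre = P.Wd * feat;
    hpre.each_col() += P.bd;
    fmat h = clamp(hpre, 0.0f, datum::inf);
    frowvec z = P.Wo.row(0) * h;
    z += P.bo;
    vec prob(B);
    for (int s = 0; s < B; ++s) prob(s) = 1.0 / (1.0 + std::exp(-(double)z(s)));
    return prob;
}

// Forward-only pass in training mode (batch statistics), returning the
// per-block batch-norm statistics. Used to recalibrate the running
// statistics on the training set after the final weight update, so that
// inference-time normalization matches the converged weights.
// [[Rcpp::export(rng = false)]]
Rcpp::List nn_cnn3d_bn_pass(const arma::vec &x, Rcpp::IntegerVector shape,
                            int B, Rcpp::List params, double bn_eps) {
    NetParams P = load_params(params);
    int dims[5][3];
    dims[0][0] = shape[0]; dims[0][1] = shape[1]; dims[0][2] = shape[2];
    for (int k = 0; k < 4; ++k) {
        dims[k + 1][0] = dims[k][0] / 2;
        dims[k + 1][1] = dims[k][1] / 2;
        dims[k + 1][2] = dims[k][2] / 2;
    }
    fmat A(x.n_elem, 1);
    for (size_t i = 0; i < x.n_elem; ++i) A(i, 0) = (float)x(i);
    Rcpp::List out;
    BnCache bnc;
    for (int k = 0; k < 4; ++k) {
        fmat conv = conv_fwd_f(A, P.W[k], P.b[k],
                               dims[k][0], dims[k][1], dims[k][2], B);
        fmat pooled;
        Mat<uword> idx;
        pool_fwd_f(conv, dims[k][0], dims[k][1], dims[k][2], B, pooled, idx);
        A = bn_fwd_f(pooled, P.gamma[k], P.beta[k], bn_eps, bnc);
        std::string i = std::to_string(k + 1);
        out["mean" + i] = Rcpp::wrap(conv_to<vec>::from(bnc.mean));
        out["var" + i] = Rcpp::wrap(conv_to<vec>::from(bnc.var));
    }
    return out;
}
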