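#' Architecture specification of the 3D-CNN classifier
#'
#' Four convolutional blocks, each Conv3D (3x3x3, same padding, ReLU) ->
#' MaxPool3D (2x2x2) -> BatchNorm, with 64, 64, 128 and 256 filters, then
#' global average pooling, a 512-unit ReLU dense layer with dropout 0.3,
#' and a single sigmoid output unit for ASD-vs-TC classification.
#'
#' @param conv_filters Filter counts of the four blocks (non-decreasing).
#' @param dense_units Width of the penultimate dense layer.
#' @param dropout_rate Dropout probability on the dense layer, in [0, 1).
#' @return A `cnn3d_spec` list.
#' @export
cnn3d_spec <- function(conv_filters = c(64L, 64L, 128L, 256L),
                       dense_units = 512L, dropout_rate = 0.3) {
    conv_filters <- as.integer(conv_filters)
    if (length(conv_filters) != 4L || is.unsorted(conv_filters))
        stop_ns("conv_filters must be 4 non-decreasing counts",
                "neuroslice_parameter_error")
    if (dropout_rate < 0 || dropout_rate >= 1)
        stop_ns("dropout_rate must be in [0, 1)", "neuroslice_parameter_error")
    structure(list(conv_filters = conv_filters, kernel = c(3L, 3L, 3L),
                   pool = c(2L, 2L, 2L), dense_units = as.integer(dense_units),
                   dropout_rate = dropout_rate, output_units = 1L),
              class = "cnn3d_spec")
}

#' Training hyperparameters
#'
#' Defaults follow the reference training recipe: 50 epochs, binary
#' cross-entropy loss, Adam with learning rate 0.001.
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param learning_rate Adam step size (> 0; 0 is allowed and performs no
#'   updates, useful for diagnostics).
#' @param batch_size Mini-batch size.
#' @param augment Apply random flip/rotation augmentation to training
#'   samples (never to test samples).
#' @param seed Integer seed controlling shuffling, dropout and
#'   augmentation.
#' @return A `train_config` list; `loss` is always `"binary_crossentropy"`
#'   and `optimizer` `"adam"`.
#' @export
train_config <- function(epochs = 50L, learning_rate = 0.001,
                         batch_size = 8L, augment = FALSE, seed = 1L) {
    if (epochs < 1L) stop_ns("epochs must be >= 1",
                             "neuroslice_parameter_error")
    if (learning_rate < 0) stop_ns("learning_rate must be >= 0",
                                   "neuroslice_parameter_error")
    structure(list(epochs = as.integer(epochs), loss = "binary_crossentropy",
                   optimizer = "adam", learning_rate = learning_rate,
                   batch_size = as.integer(batch_size),
                   augment = isTRUE(augment), seed = as.integer(seed)),
              class = "train_config")
}

glorot <- function(nrow, ncol, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Build the 3D-CNN model
#'
#' Initialises all weights (Glorot-uniform, seeded) for the architecture in
#' [cnn3d_spec]. Each spatial extent of `input_shape` must be at least 16 so
#' that the four 2x pooling stages remain valid.
#'
#' @param input_shape Integer vector of 3 spatial extents (single channel).
#' @param spec A [cnn3d_spec].
#' @param seed Integer seed for weight initialisation.
#' @return A `cnn3d_model` holding parameters, batch-norm running
#'   statistics and layer dimensions.
#' @export
build_cnn3d <- function(input_shape, spec = cnn3d_spec(), seed = 1L) {
    input_shape <- as.integer(input_shape)
    stopifnot(length(input_shape) == 3L)
    if (any(input_shape < 16L))
        stop_ns("each spatial extent must be >= 16 for four 2x poolings",
                "neuroslice_shape_error")
    nf <- spec$conv_filters
    cin <- c(1L, nf[1:3])
    dims <- vector("list", 5L)
    dims[[1L]] <- input_shape
    for (b in 1:4) dims[[b + 1L]] <- dims[[b]] %/% 2L
    params <- list()
    with_seed(seed, {
        for (b in 1:4) {
            fan_in <- cin[b] * 27L
            fan_out <- nf[b] * 27L
            params[[paste0("W", b)]] <- glorot(cin[b] * 27L, nf[b],
                                               fan_in, fan_out)
            params[[paste0("b", b)]] <- numeric(nf[b])
            params[[paste0("gamma", b)]] <- rep(1, nf[b])
            params[[paste0("beta", b)]] <- numeric(nf[b])
        }
        params$Wd <- glorot(spec$dense_units, nf[4L], nf[4L],
                            spec$dense_units)
        params$bd <- numeric(spec$dense_units)
        params$Wo <- glorot(1L, spec$dense_units, spec$dense_units, 1L)
        params$bo <- 0
    })
    running <- list()
    for (b in 1:4) {
        running[[paste0("mean", b)]] <- numeric(nf[b])
        running[[paste0("var", b)]] <- rep(1, nf[b])
    }
    structure(list(params = params, running = running, spec = spec,
                   input_shape = input_shape, dims = dims,
                   bn_eps = 1e-3, trained = FALSE),
              class = "cnn3d_model")
}

#' @export
print.cnn3d_model <- function(x, ...) {
    cat(sprintf(
        "<cnn3d_model> input %s, filters %s, dense %d, %strained\n",
        paste(x$input_shape, collapse = "x"),
        paste(x$spec$conv_filters, collapse = "-"),
        x$spec$dense_units, if (x$trained) "" else "un"))
    invisible(x)
}

#' Number of trainable parameters
#'
#' @param model A `cnn3d_model` or `tl_classifier`.
#' @return Integer count of trainable scalar parameters.
#' @export
n_parameters <- function(model) {
    sum(vapply(model$params, length, integer(1)))
}

# --- forward / backward ----------------------------------------------------
# Activations are (V*B) x C matrices; samples stacked row-blockwise
# (matching the compiled primitives). Batch-norm statistics are therefore
# per column.

batchnorm_fwd <- function(X, gamma, beta, eps) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = nrow(X))
    va <- colMeans(xc * xc)
    invstd <- 1 / sqrt(va + eps)
    xhat <- xc * rep(invstd, each = nrow(X))
    list(Y = xhat * rep(gamma, each = nrow(X)) +
             rep(beta, each = nrow(X)),
         xhat = xhat, invstd = invstd, mean = mu, var = va)
}

batchnorm_bwd <- function(dY, cache, gamma) {
    M <- nrow(dY)
    dxhat <- dY * rep(gamma, each = M)
    sum_d <- colSums(dxhat)
    sum_dx <- colSums(dxhat * cache$xhat)
    dX <- rep(cache$invstd / M, each = M) *
        (M * dxhat - rep(sum_d, each = M) -
         cache$xhat * rep(sum_dx, each = M))
    list(dX = dX, dgamma = colSums(dY * cache$xhat), dbeta = colSums(dY))
}

batchnorm_infer <- function(X, gamma, beta, mean, var, eps) {
    M <- nrow(X)
    (X - rep(mean, each = M)) * rep(1 / sqrt(var + eps), each = M) *
        rep(gamma, each = M) + rep(beta, each = M)
}

# Reference forward pass through the conv stack + head in double precision,
# built from the per-layer primitives. The production training step is the
# fused single-precision kernel (nn_cnn3d_train_step); this path exists for
# verification and is cross-checked against the fused path in the tests.
# x: array (nx,ny,nz,B) or 3D array.
cnn3d_forward <- function(model, x, training = FALSE, dropout_mask = NULL) {
    p <- model$params
    d <- model$dims
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    B <- dim(x)[4L]
    stopifnot(identical(dim(x)[1:3], model$input_shape))
    A <- matrix(as.numeric(x), ncol = 1L)  # (V*B) x 1
    cache <- list(B = B)
    for (b in 1:4) {
        dd <- d[[b]]
        conv <- nn_conv3d_fwd(A, p[[paste0("W", b)]], p[[paste0("b", b)]],
                              dd[1], dd[2], dd[3], B, TRUE)
        pool <- nn_maxpool3d_fwd(conv, dd[1], dd[2], dd[3], B)
        if (training) {
            bn <- batchnorm_fwd(pool$Y, p[[paste0("gamma", b)]],
                                p[[paste0("beta", b)]], model$bn_eps)
        } else {
            bn <- list(Y = batchnorm_infer(pool$Y, p[[paste0("gamma", b)]],
                                           p[[paste0("beta", b)]],
                                           model$running[[paste0("mean", b)]],
                                           model$running[[paste0("var", b)]],
                                           model$bn_eps))
        }
        if (training)
            cache[[paste0("blk", b)]] <- list(A = A, conv = conv,
                                              pool_idx = pool$idx,
                                              pool_nrow_in = nrow(conv),
                                              bn = bn)
        A <- bn$Y
    }
    V_last <- prod(d[[5L]])
    feat <- matrix(0, ncol(A), B)  # global average pooling: C x B
    for (s in seq_len(B))
        feat[, s] <- colMeans(A[((s - 1L) * V_last + 1L):(s * V_last), ,
                                drop = FALSE])
    h_pre <- p$Wd %*% feat + p$bd
    h <- pmax(h_pre, 0)
    if (training && model$spec$dropout_rate > 0) {
        if (is.null(dropout_mask)) {
            keep <- 1 - model$spec$dropout_rate
            dropout_mask <- matrix(
                (runif(length(h)) < keep) / keep, nrow(h), ncol(h))
        }
        h <- h * dropout_mask
    }
    z <- as.numeric(p$Wo %*% h + p$bo)
    prob <- 1 / (1 + exp(-z))
    cache$feat <- feat; cache$h <- h; cache$V_last <- V_last
    cache$dropout_mask <- dropout_mask
    list(prob = prob, cache = cache)
}

cnn3d_backward <- function(model, fwd, y) {
    p <- model$params
    d <- model$dims
    cache <- fwd$cache
    B <- cache$B
    grads <- list()
    dz <- matrix((fwd$prob - y) / B, nrow = 1L)     # BCE + sigmoid
    grads$Wo <- dz %*% t(cache$h)
    grads$bo <- sum(dz)
    dh <- t(p$Wo) %*% dz
    if (!is.null(cache$dropout_mask)) dh <- dh * cache$dropout_mask
    dh[cache$h <= 0] <- 0
    grads$Wd <- dh %*% t(cache$feat)
    grads$bd <- rowSums(dh)
    dfeat <- t(p$Wd) %*% dh                          # C4 x B
    V_last <- cache$V_last
    dA <- matrix(0, V_last * B, nrow(dfeat))
    for (s in seq_len(B))
        dA[((s - 1L) * V_last + 1L):(s * V_last), ] <-
            matrix(dfeat[, s] / V_last, V_last, nrow(dfeat), byrow = TRUE)
    for (b in 4:1) {
        blk <- cache[[paste0("blk", b)]]
        bnb <- batchnorm_bwd(dA, blk$bn, p[[paste0("gamma", b)]])
        grads[[paste0("gamma", b)]] <- bnb$dgamma
        grads[[paste0("beta", b)]] <- bnb$dbeta
        dpool <- nn_maxpool3d_bwd(bnb$dX, blk$pool_idx, blk$pool_nrow_in)
        dpool <- nn_relu_bwd(dpool, blk$conv)
        dd <- d[[b]]
        cb <- nn_conv3d_bwd(blk$A, p[[paste0("W", b)]], dpool,
                            dd[1], dd[2], dd[3], B, b > 1L)
        grads[[paste0("W", b)]] <- cb$dW
        grads[[paste0("b", b)]] <- as.numeric(cb$db)
        dA <- cb$dX
    }
    grads
}

adam_init <- function(params) {
    list(m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
    state$t <- state$t + 1L
    bc1 <- 1 - beta1^state$t
    bc2 <- 1 - beta2^state$t
    for (nm in names(grads)) {
        g <- grads[[nm]]
        if (!is.matrix(params[[nm]])) g <- as.vector(g)  # keep param shape
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
        params[[nm]] <- params[[nm]] -
            lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    }
    list(params = params, state = state)
}

bce_loss <- function(prob, y, eps = 1e-7) {
    q <- pmin(pmax(prob, eps), 1 - eps)
    -mean(y * log(q) + (1 - y) * log(1 - q))
}

#' Predict class probabilities
#'
#' @param object A trained `cnn3d_model`.
#' @param x Array `(nx, ny, nz, B)` of input volumes (or a single 3D
#'   volume).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Numeric vector of ASD probabilities in (0, 1).
#' @export
predict.cnn3d_model <- function(object, x, batch_size = 8L, ...) {
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    stopifnot(identical(dim(x)[1:3], object$input_shape))
    B <- dim(x)[4L]
    out <- numeric(B)
    for (s in seq(1L, B, by = batch_size)) {
        idx <- s:min(s + batch_size - 1L, B)
        out[idx] <- nn_cnn3d_infer(
            as.numeric(x[, , , idx, drop = FALSE]), object$input_shape,
            length(idx), object$params, object$running, object$bn_eps)
    }
    out
}

#' Train a model on labelled volumes
#'
#' Mini-batch Adam on binary cross-entropy. Batch-norm uses batch
#' statistics during training; after each epoch the population statistics
#' of the training set are recomputed under the current weights (one
#' forward-only pass) and stored as the inference-time running statistics,
#' so evaluation never suffers from stale normalization constants.
#' Augmentation (when enabled in the config) is applied to training samples
#' only. The run is reproducible given `config$seed`.
#'
#' @param model A `cnn3d_model` from [build_cnn3d] (or a `tl_classifier`).
#' @param x_train,y_train Training volumes `(nx,ny,nz,B)` and 0/1 labels
#'   (ASD = 1).
#' @param x_test,y_test Optional held-out set evaluated after each epoch.
#' @param config A [train_config].
#' @return List with the trained `model` and `history`, a data frame with
#'   one row per epoch: `epoch`, `train_loss`, and (when a test set is
#'   given) `test_loss`, `test_accuracy`, `test_f1`.
#' @export
train_model <- function(model, x_train, y_train, x_test = NULL,
                        y_test = NULL, config = train_config()) {
    UseMethod("train_model")
}

#' @export
train_model.cnn3d_model <- function(model, x_train, y_train, x_test = NULL,
                                    y_test = NULL, config = train_config()) {
    stopifnot(inherits(config, "train_config"))
    if (length(dim(x_train)) == 3L) dim(x_train) <- c(dim(x_train), 1L)
    n <- dim(x_train)[4L]
    y_train <- as.numeric(y_train)
    stopifnot(length(y_train) == n, n >= 1L)
    if (length(unique(y_train)) < 2L)
        warning("training set contains a single class; proceeding")
    state <- adam_init(model$params)
    history <- vector("list", config$epochs)
    with_seed(config$seed, {
        for (epoch in seq_len(config$epochs)) {
            ord <- sample.int(n)
            losses <- numeric(0)
            for (s in seq(1L, n, by = config$batch_size)) {
                idx <- ord[s:min(s + config$batch_size - 1L, n)]
                xb <- x_train[, , , idx, drop = FALSE]
                if (config$augment) xb <- augment_batch(xb)
                nb <- length(idx)
                dropout_u <- runif(model$spec$dense_units * nb)
                step <- nn_cnn3d_train_step(
                    as.numeric(xb), model$input_shape, nb, model$params,
                    model$bn_eps, model$spec$dropout_rate, dropout_u,
                    y_train[idx])
                losses <- c(losses, step$loss)
                upd <- adam_step(model$params, step$grads, state,
                                 config$learning_rate)
                model$params <- upd$params
                state <- upd$state
            }
            # refresh the batch-norm population statistics under the
            # current weights before any inference-mode evaluation
            model <- recalibrate_bn(model, x_train, config$batch_size)
            row <- data.frame(epoch = epoch, train_loss = mean(losses))
            if (!is.null(x_test)) {
                probs <- predict(model, x_test,
                                 batch_size = config$batch_size)
                pred <- classify(probs)
                row$test_loss <- cross_entropy(probs, y_test)
                row$test_accuracy <- accuracy(pred, y_test)
                row$test_f1 <- f1_score(pred, y_test)
            }
            history[[epoch]] <- row
        }
    })
    model$trained <- TRUE
    list(model = model, history = do.call(rbind, history))
}

# Recompute the batch-norm running statistics as population statistics of
# the training set under the final weights (one forward-only pass in
# training mode). The exponentially averaged statistics collected during
# optimisation lag behind the converged weights when the total number of
# steps is small; recalibration removes that lag.
recalibrate_bn <- function(model, x_train, batch_size) {
    n <- dim(x_train)[4L]
    acc <- list()
    wt <- numeric(0)
    for (s in seq(1L, n, by = batch_size)) {
        idx <- s:min(s + batch_size - 1L, n)
        st <- nn_cnn3d_bn_pass(as.numeric(x_train[, , , idx, drop = FALSE]),
                               model$input_shape, length(idx), model$params,
                               model$bn_eps)
        acc[[length(acc) + 1L]] <- st
        wt <- c(wt, length(idx))
    }
    wt <- wt / sum(wt)
    for (b in 1:4) {
        mns <- sapply(acc, function(a) as.vector(a[[paste0("mean", b)]]))
        vrs <- sapply(acc, function(a) as.vector(a[[paste0("var", b)]]))
        mns <- matrix(mns, ncol = length(wt))
        vrs <- matrix(vrs, ncol = length(wt))
        m_tot <- drop(mns %*% wt)
        # law of total variance across batches
        v_tot <- drop((vrs + mns^2) %*% wt) - m_tot^2
        model$running[[paste0("mean", b)]] <- m_tot
        model$running[[paste0("var", b)]] <- pmax(v_tot, 0)
    }
    model
}

# random flip + rotation on each sample of a batch (training RNG stream)
augment_batch <- function(x) {
    for (s in seq_len(dim(x)[4L]))
        x[, , , s] <- augment(x[, , , s])
    x
}
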