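#' Random flip and rotation augmentation
#'
#' Draws a random horizontal flip, a random vertical flip (each with
#' probability 1/2) and a rotation angle uniform in +/- `max_angle`
#' degrees, and applies them to the sample. 2D samples (with or without a
#' trailing channel axis) are transformed in-plane; 3D single-channel
#' volumes are flipped along x/y and rotated slice-wise about the z axis.
#' When the drawn transform is the identity (no flip, angle 0) the input is
#' returned unchanged. Intended for training samples only.
#'
#' @param x Matrix (2D), 3D array that is either a multi-channel 2D image
#'   (trailing dim <= 4) or a single-channel volume, interpreted by shape.
#' @param max_angle Rotation half-range in degrees; the default 36 is a
#'   tenth of a full turn.
#' @param flip_h,flip_v,angle Optional fixed transform components,
#'   overriding the random draws (used for testing and reproducibility).
#' @return The augmented sample, same shape as the input.
#' @export
augment <- function(x, max_angle = 36, flip_h = NULL, flip_v = NULL,
                    angle = NULL) {
    if (is.null(flip_h)) flip_h <- runif(1) < 0.5
    if (is.null(flip_v)) flip_v <- runif(1) < 0.5
    if (is.null(angle)) angle <- runif(1, -max_angle, max_angle)
    d <- dim(x)
    if (is.matrix(x)) {
        if (flip_h) x <- flip_axis(x, 1L)
        if (flip_v) x <- flip_axis(x, 2L)
        if (angle != 0) x <- rotate_slice(x, angle)
        return(x)
    }
    if (length(d) != 3L)
        stop_ns("augment expects a 2D slice or 3D array",
                "neuroslice_validation_error")
    if (flip_h) x <- flip_axis(x, 1L)
    if (flip_v) x <- flip_axis(x, 2L)
    if (angle != 0) {
        for (kk in seq_len(d[3L]))
            x[, , kk] <- rotate_slice(x[, , kk, drop = TRUE], angle)
    }
    x
}

#' Wrap a feature extractor as a transfer-learning backbone
#'
#' A backbone is any callable taking one 224x224x3 image and returning a
#' fixed-length numeric feature vector (the pretrained network with its
#' classification top removed). The backbone is validated on a probe input
#' at construction.
#'
#' @param extract Function `(image) -> numeric vector` of constant length.
#' @param n_features Expected output length.
#' @param name Human-readable backbone name.
#' @param trainable Whether backbone weights may be updated; only frozen
#'   (`FALSE`) backbones are supported for training.
#' @param input_shape Expected input dimensions.
#' @return A `backbone` object.
#' @export
backbone <- function(extract, n_features, name = "backbone",
                     trainable = FALSE, input_shape = c(224L, 224L, 3L)) {
    stopifnot(is.function(extract))
    probe <- extract(array(0, dim = input_shape))
    if (!is.numeric(probe) || length(probe) != n_features)
        stop_ns(sprintf(
            "backbone output must be a length-%d numeric vector", n_features),
            "neuroslice_contract_error")
    structure(list(extract = extract, n_features = as.integer(n_features),
                   name = name, trainable = isTRUE(trainable),
                   input_shape = as.integer(input_shape)),
              class = "backbone")
}

#' Deterministic stub backbone for tests and examples
#'
#' Averages the three channels, pools the image onto a coarse `grid` x
#' `grid` raster, and projects it through a fixed random matrix. Stands in
#' for a pretrained feature extractor so that the transfer-learning harness
#' is exercisable without shipping network weights.
#'
#' @param n_features Output feature length.
#' @param grid Pooling grid side.
#' @param seed Seed fixing the projection.
#' @return A [backbone].
#' @export
stub_backbone <- function(n_features = 8L, grid = 7L, seed = 42L) {
    W <- with_seed(seed,
                   matrix(rnorm(n_features * grid * grid), n_features))
    extract <- function(image) {
        sl <- (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
        pooled <- resize_bilinear(sl, grid, grid)
        as.numeric(W %*% as.numeric(pooled))
    }
    backbone(extract, n_features, name = sprintf("stub%d", n_features))
}

#' Attach a sigmoid classification head to a backbone
#'
#' Replaces the removed top layer of a pretrained feature extractor with a
#' single dense sigmoid unit (`n_features + 1` trainable parameters). The
#' head is trained with [train_model] under the same configuration used
#' for the 3D-CNN; the backbone stays frozen.
#'
#' @param bb A [backbone] with `trainable = FALSE`.
#' @param seed Seed for head initialisation.
#' @return A `tl_classifier` with fields `backbone` and `params`
#'   (`Wo`, `bo`).
#' @export
build_tl_classifier <- function(bb, seed = 1L) {
    stopifnot(inherits(bb, "backbone"))
    if (bb$trainable)
        stop_ns("only frozen backbones are supported for training",
                "neuroslice_contract_error")
    params <- with_seed(seed, list(
        Wo = glorot(1L, bb$n_features, bb$n_features, 1L), bo = 0))
    structure(list(backbone = bb, params = params),
              class = "tl_classifier")
}

tl_features <- function(model, x) {
    # x: list of images, or array (h, w, 3, B)
    imgs <- if (is.list(x)) x else
        lapply(seq_len(dim(x)[4L]), function(s) x[, , , s, drop = TRUE])
    vapply(imgs, model$backbone$extract,
           numeric(model$backbone$n_features))
}

#' @export
predict.tl_classifier <- function(object, x, ...) {
    feat <- tl_features(object, x)
    if (is.null(dim(feat))) feat <- matrix(feat, nrow = 1L)
    z <- as.numeric(object$params$Wo %*% feat + object$params$bo)
    1 / (1 + exp(-z))
}

#' @export
train_model.tl_classifier <- function(model, x_train, y_train,
                                      x_test = NULL, y_test = NULL,
                                      config = train_config()) {
    stopifnot(inherits(config, "train_config"))
    y_train <- as.numeric(y_train)
    feat <- tl_features(model, x_train)      # F x N (frozen: precomputable)
    n <- ncol(feat)
    stopifnot(length(y_train) == n)
    feat_test <- if (!is.null(x_test)) tl_features(model, x_test)
    state <- adam_init(model$params)
    history <- vector("list", config$epochs)
    with_seed(config$seed, {
        for (epoch in seq_len(config$epochs)) {
            ord <- sample.int(n)
            losses <- numeric(0)
            for (s in seq(1L, n, by = config$batch_size)) {
                idx <- ord[s:min(s + config$batch_size - 1L, n)]
                fb <- feat[, idx, drop = FALSE]
                z <- as.numeric(model$params$Wo %*% fb + model$params$bo)
                prob <- 1 / (1 + exp(-z))
                losses <- c(losses, bce_loss(prob, y_train[idx]))
                dz <- matrix((prob - y_train[idx]) / length(idx), 1L)
                grads <- list(Wo = dz %*% t(fb), bo = sum(dz))
                upd <- adam_step(model$params, grads, state,
                                 config$learning_rate)
                model$params <- upd$params
                state <- upd$state
            }
            row <- data.frame(epoch = epoch, train_loss = mean(losses))
            if (!is.null(feat_test)) {
                z <- as.numeric(model$params$Wo %*% feat_test +
                                model$params$bo)
                probs <- 1 / (1 + exp(-z))
                pred <- classify(probs)
                row$test_loss <- cross_entropy(probs, y_test)
                row$test_accuracy <- accuracy(pred, y_test)
                row$test_f1 <- f1_score(pred, y_test)
            }
            history[[epoch]] <- row
        }
    })
    list(model = model, history = do.call(rbind, history))
}
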