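test_that("architecture matches the layer-by-layer parameter counts", {
    m <- build_cnn3d(c(16, 16, 16), seed = 1)
    # first conv block: 64 filters of 3x3x3 on 1 input channel
    expect_identical(length(m$params$W1) + length(m$params$b1), 1792L)
    # feature vector entering the dense layer: 256 (GAP over last conv)
    expect_identical(dim(m$params$Wd), c(512L, 256L))
    expect_identical(dim(m$params$Wo), c(1L, 512L))
    expect_identical(m$spec$conv_filters, c(64L, 64L, 128L, 256L))
    expect_error(build_cnn3d(c(8, 16, 16)), class = "neuroslice_shape_error")
    expect_error(cnn3d_spec(conv_filters = c(64, 32, 128, 256)),
                 class = "neuroslice_parameter_error")
})

test_that("forward pass outputs probabilities in (0, 1)", {
    m <- build_cnn3d(c(16, 16, 16), seed = 2)
    set.seed(1)
    x <- array(rnorm(16^3 * 3, 0, 10), dim = c(16, 16, 16, 3))
    p <- predict(m, x)
    expect_length(p, 3)
    expect_true(all(p > 0 & p < 1))
})

test_that("fused training kernel agrees with the double-precision reference", {
    set.seed(7)
    m <- build_cnn3d(c(16, 16, 16), spec = cnn3d_spec(dropout_rate = 0),
                     seed = 3)
    x <- array(rnorm(16^3 * 4), dim = c(16, 16, 16, 4))
    y <- c(0, 1, 1, 0)
    fwd <- neuroslice:::cnn3d_forward(m, x, training = TRUE)
    grads <- neuroslice:::cnn3d_backward(m, fwd, y)
    st <- neuroslice:::nn_cnn3d_train_step(as.numeric(x), m$input_shape, 4L,
                                           m$params, m$bn_eps, 0, numeric(0),
                                           y)
    expect_lt(max(abs(fwd$prob - st$prob)), 1e-5)
    expect_equal(st$loss, neuroslice:::bce_loss(fwd$prob, y),
                 tolerance = 1e-5)
    for (nm in names(m$params)) {
        rel <- max(abs(grads[[nm]] - st$grads[[nm]])) /
            (max(abs(grads[[nm]])) + 1e-12)
        expect_lt(rel, 1e-4)
    }
})

test_that("reference gradients match finite differences", {
    set.seed(11)
    m <- build_cnn3d(c(16, 16, 16), spec = cnn3d_spec(dropout_rate = 0),
                     seed = 5)
    x <- array(rnorm(16^3 * 2), dim = c(16, 16, 16, 2))
    y <- c(0, 1)
    lossf <- function(mm) {
        f <- neuroslice:::cnn3d_forward(mm, x, training = TRUE)
        neuroslice:::bce_loss(f$prob, y)
    }
    fwd <- neuroslice:::cnn3d_forward(m, x, training = TRUE)
    gr <- neuroslice:::cnn3d_backward(m, fwd, y)
    set.seed(99)
    h <- 1e-6
    for (nm in c("W2", "gamma3", "beta1", "Wd", "Wo")) {
        i <- sample(length(m$params[[nm]]), 1)
        m2 <- m
        m2$params[[nm]][i] <- m$params[[nm]][i] + h
        l1 <- lossf(m2)
        m2$params[[nm]][i] <- m$params[[nm]][i] - h
        l0 <- lossf(m2)
        fd <- (l1 - l0) / (2 * h)
        expect_equal(gr[[nm]][i], fd, tolerance = 1e-3)
    }
})

test_that("a zero learning rate leaves the weights untouched", {
    m <- build_cnn3d(c(16, 16, 16), seed = 4)
    x <- array(rnorm(16^3 * 4), dim = c(16, 16, 16, 4))
    fit <- train_model(m, x, c(0, 1, 0, 1),
                       config = train_config(epochs = 1, learning_rate = 0,
                                             batch_size = 2, seed = 1))
    for (nm in names(m$params))
        expect_identical(fit$model$params[[nm]], m$params[[nm]])
})

test_that("training history has one row per epoch and is seed-deterministic", {
    b <- phantom_batch(2)
    m <- build_cnn3d(c(16, 16, 16), seed = 1)
    cfg <- train_config(epochs = 3, batch_size = 2, seed = 42)
    f1 <- train_model(m, b$x, b$y, b$x, b$y, cfg)
    f2 <- train_model(m, b$x, b$y, b$x, b$y, cfg)
    expect_identical(nrow(f1$history), 3L)
    expect_identical(f1$history, f2$history)
    expect_true(all(c("train_loss", "test_loss", "test_accuracy", "test_f1")
                    %in% names(f1$history)))
    f3 <- train_model(m, b$x, b$y, b$x, b$y,
                      train_config(epochs = 3, batch_size = 2, seed = 43))
    expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("the network can drive training loss to zero on a separable set", {
    b <- phantom_batch(4, class_effect = 0.3, noise_sd = 10)
    # dropout off: the capacity property concerns the deterministic network
    m <- build_cnn3d(c(16, 16, 16), spec = cnn3d_spec(dropout_rate = 0),
                     seed = 1)
    fit <- train_model(m, b$x, b$y,
                       config = train_config(epochs = 25, batch_size = 2,
                                             learning_rate = 0.005, seed = 1))
    p <- predict(fit$model, b$x)
    expect_identical(accuracy(classify(p), b$y), 1)
    expect_lt(fit$history$train_loss[25], fit$history$train_loss[1])
})

test_that("single-class training warns but proceeds", {
    m <- build_cnn3d(c(16, 16, 16), seed = 1)
    x <- array(rnorm(16^3 * 2), dim = c(16, 16, 16, 2))
    expect_warning(train_model(m, x, c(1, 1),
                               config = train_config(epochs = 1,
                                                     batch_size = 2)),
                   regexp = "single class")
})

test_that("augmentation identity, involution and shape contracts hold", {
    m <- matrix(rnorm(144), 12, 12)
    expect_identical(augment(m, flip_h = FALSE, flip_v = FALSE, angle = 0), m)
    expect_identical(flip_axis(flip_axis(m, 1), 1), m)
    expect_identical(flip_axis(flip_axis(m, 2), 2), m)
    a <- augment(m, flip_h = TRUE, flip_v = FALSE, angle = 17)
    expect_identical(dim(a), dim(m))
    vol <- array(rnorm(12^3), dim = c(12, 12, 12))
    av <- augment(vol, flip_h = FALSE, flip_v = TRUE, angle = -20)
    expect_identical(dim(av), dim(vol))
    # rotation by 0 is exact; +-90 on a symmetric grid is near-lossless
    expect_identical(rotate_slice(m, 0), m)
    r90 <- rotate_slice(rotate_slice(m, 90), -90)
    expect_equal(r90[3:10, 3:10], m[3:10, 3:10], tolerance = 1e-8)
})

test_that("transfer-learning head trains on a frozen stub backbone", {
    bb <- stub_backbone(n_features = 8)
    clf <- build_tl_classifier(bb, seed = 1)
    # head parameter count: F weights + 1 bias
    expect_identical(n_parameters(clf), 9L)
    set.seed(2)
    imgs <- lapply(1:12, function(i) {
        base <- if (i %% 2 == 0) 0.2 else 0.8
        to_three_channels(matrix(base + rnorm(224^2, 0, 0.05), 224, 224))
    })
    y <- as.integer(seq_len(12) %% 2 == 1)
    w_before <- environment(clf$backbone$extract)$W
    fit <- train_model(clf, imgs, y,
                       config = train_config(epochs = 40, batch_size = 4,
                                             learning_rate = 0.05, seed = 1))
    w_after <- environment(fit$model$backbone$extract)$W
    expect_identical(w_before, w_after)  # frozen backbone untouched
    p <- predict(fit$model, imgs)
    expect_true(all(p > 0 & p < 1))
    expect_identical(accuracy(classify(p), y), 1)
    expect_error(build_tl_classifier(backbone(function(img) rnorm(4), 4,
                                              trainable = TRUE)),
                 class = "neuroslice_contract_error")
    expect_error(backbone(function(img) c(1, 2), 5),
                 class = "neuroslice_contract_error")
})
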