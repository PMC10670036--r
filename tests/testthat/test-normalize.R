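test_that("single-cluster FCM reduces to the arithmetic mean", {
    set.seed(1)
    x <- rnorm(500, 10, 3)
    f <- fcm_fit(x, k = 1)
    expect_equal(f$centroids, mean(x), tolerance = 1e-8)
})

test_that("FCM recovers the atoms of a balanced three-point mixture", {
    # 100 copies each of {0, 50, 100}: the atom set is an exact fixed point
    # of the update equations (points at a centroid get crisp membership),
    # so the fit must land within 0.5 of the atoms.
    x <- rep(c(0, 50, 100), each = 100)
    f <- fcm_fit(x, k = 3, m = 2)
    expect_lt(max(abs(f$centroids - c(0, 50, 100))), 0.5)
    # verify the fixed point independently: one hand-rolled update from the
    # converged centroids must return them unchanged
    cen <- f$centroids
    d2 <- outer(x, cen, `-`)^2
    u <- matrix(0, length(x), 3)
    for (j in seq_along(x)) {
        z <- d2[j, ] == 0
        u[j, ] <- if (any(z)) as.numeric(z) / sum(z) else
            (1 / d2[j, ]) / sum(1 / d2[j, ])
    }
    upd <- colSums(u^2 * x) / colSums(u^2)
    expect_equal(upd, cen, tolerance = 1e-6)
})

test_that("FCM agrees with an independent implementation", {
    skip_if_not_installed("e1071")
    set.seed(4)
    x <- c(rnorm(200, 0, 1), rnorm(200, 10, 1), rnorm(200, 30, 2))
    f <- fcm_fit(x, k = 3, m = 2)
    ref <- e1071::cmeans(matrix(x), centers = matrix(c(5, 15, 25)), m = 2,
                         iter.max = 200)
    expect_lt(max(abs(f$centroids - sort(as.numeric(ref$centers)))), 0.1)
})

test_that("memberships are a partition of unity and the objective never increases", {
    set.seed(9)
    for (k in c(2, 3, 4)) {
        x <- runif(400, 0, 100)
        f <- fcm_fit(x, k = k)
        expect_lt(max(abs(rowSums(f$membership) - 1)), 1e-9)
        expect_true(all(diff(f$objective_trace) <= 1e-9))
        expect_gte(f$objective, 0)
        expect_identical(sum(f$membership_summary), 400L)
        expect_true(all(diff(f$centroids) > 0))
    }
})

test_that("FCM input contracts are enforced", {
    expect_error(fcm_fit(c(1, 1, 1), k = 2),
                 class = "neuroslice_degeneracy_error")
    expect_error(fcm_fit(c(1, NA, 3), k = 2),
                 class = "neuroslice_validation_error")
    expect_error(fcm_fit(1:10, k = 2, m = 1),
                 class = "neuroslice_parameter_error")
})

test_that("normalization fixes the reference tissue mean at exactly 1", {
    pp <- tiny_params(shape = c(20L, 20L, 20L))
    v <- make_smri_phantom(pp, "TC")
    m <- phantom_masks(pp$shape)
    nv <- tissue_mean_normalize(v)
    expect_identical(mean(nv$data[m$wm]), 1)
    expect_true(all(nv$data[!m$brain] == 0))
    # tissue contrast is preserved as ratios to the WM mean
    expect_equal(mean(nv$data[m$gm]), 0.5, tolerance = 1e-12)
})

test_that("normalization is scale-invariant and idempotent", {
    pp <- tiny_params(shape = c(16L, 16L, 16L), noise_sd = 20, seed = 2L)
    v <- make_smri_phantom(pp, "TC")
    n1 <- tissue_mean_normalize(v)
    for (alpha in c(0.01, 7)) {
        va <- volume_image(v$data * alpha, v$affine)
        expect_equal(tissue_mean_normalize(va)$data, n1$data,
                     tolerance = 1e-6)
    }
    n2 <- tissue_mean_normalize(n1)
    expect_lt(max(abs(n2$data - n1$data)), 1e-4)
})

test_that("centroids are recovered within 2% under 5% noise", {
    pp <- phantom_params(shape = c(24L, 24L, 24L), noise_sd = 25,
                         subject_jitter = 0, seed = 11L)
    v <- make_smri_phantom(pp, "TC")
    fit <- attr(tissue_mean_normalize(v), "fcm")
    truth <- c(100, 250, 500)
    expect_true(all(abs(fit$centroids - truth) / truth < 0.02))
})

test_that("an all-zero volume cannot be normalized", {
    z <- volume_image(array(0, dim = c(8, 8, 8)))
    expect_error(tissue_mean_normalize(z),
                 class = "neuroslice_degeneracy_error")
})

test_that("normalize_cohort writes renormalized volumes with an updated manifest", {
    pp <- tiny_params(shape = c(12L, 12L, 12L), noise_sd = 10, seed = 6L)
    dir <- file.path(tempdir(), "normcoh")
    m <- make_cohort(1, 2, pp, file.path(dir, "raw"), "sMRI")
    norm <- normalize_cohort(m, file.path(dir, "norm"))
    expect_identical(norm$subject_id, m$subject_id)
    wm <- phantom_masks(pp$shape)$wm
    for (p in norm$path)
        expect_equal(mean(read_volume(p)$data[wm]), 1, tolerance = 1e-5)
})
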