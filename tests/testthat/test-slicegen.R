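test_that("subject split reproduces the reference cohort counts", {
    sp <- split_subjects(fake_cohort(79, 105), fraction = 0.8, seed = 1)
    expect_identical(sum(sp$train$label == "ASD"), 64L)
    expect_identical(sum(sp$train$label == "TC"), 84L)
    expect_identical(sum(sp$test$label == "ASD"), 15L)
    expect_identical(sum(sp$test$label == "TC"), 21L)
    sp10 <- split_subjects(fake_cohort(10, 0), fraction = 0.8, seed = 1)
    expect_identical(nrow(sp10$train), 8L)
    expect_identical(nrow(sp10$test), 2L)
})

test_that("split partitions are disjoint, exhaustive and deterministic", {
    coh <- fake_cohort(13, 17)
    s1 <- split_subjects(coh, 0.8, seed = 5)
    s2 <- split_subjects(coh, 0.8, seed = 5)
    s3 <- split_subjects(coh, 0.8, seed = 6)
    expect_identical(s1$test$subject_id, s2$test$subject_id)
    expect_false(identical(s1$test$subject_id, s3$test$subject_id))
    expect_length(intersect(s1$train$subject_id, s1$test$subject_id), 0)
    expect_setequal(c(s1$train$subject_id, s1$test$subject_id),
                    coh$subject_id)
    dup <- coh; dup$subject_id[2] <- dup$subject_id[1]
    expect_error(split_subjects(dup, 0.8, 1),
                 class = "neuroslice_validation_error")
    expect_error(split_subjects(coh, 1.2, 1),
                 class = "neuroslice_validation_error")
})

test_that("middle slice and centred windows follow the floor convention", {
    expect_identical(middle_slice_index(176), 88L)
    expect_identical(middle_slice_index(256), 128L)
    expect_identical(middle_slice_index(5), 2L)
    expect_error(middle_slice_index(0), class = "neuroslice_validation_error")

    expect_identical(centered_window(176, 30), list(start = 73L, stop = 103L))
    expect_identical(centered_window(176, 50), list(start = 63L, stop = 113L))
    expect_identical(centered_window(9, 9), list(start = 0L, stop = 9L))
    expect_error(centered_window(10, 11), class = "neuroslice_validation_error")
})

test_that("window laws hold across lengths and widths", {
    for (d in c(5L, 31L, 64L, 176L)) {
        expect_identical(centered_window(d, 1L)$start, middle_slice_index(d))
        for (n in unique(c(1L, 2L, d %/% 2L, d))) {
            w <- centered_window(d, n)
            expect_identical(w$stop - w$start, n)
            expect_gte(w$start, 0L)
            expect_lte(w$stop, d)
        }
    }
})

test_that("temporal strategies produce the documented windows", {
    expect_identical(select_temporal_window(176, "mid_n", 30)[c("start", "stop")],
                     list(start = 73L, stop = 103L))
    expect_identical(select_temporal_window(176, "all")[c("start", "stop")],
                     list(start = 0L, stop = 176L))
    expect_identical(select_temporal_window(176, "all_trim")[c("start", "stop")],
                     list(start = 10L, stop = 166L))
    expect_error(select_temporal_window(20, "all_trim"),
                 class = "neuroslice_validation_error")
    expect_error(select_temporal_window(10, "mid_n"),
                 class = "neuroslice_validation_error")
})

test_that("temporal mean equals the brute-force per-voxel loop", {
    set.seed(3)
    dat <- array(rnorm(6 * 5 * 4 * 12), dim = c(6, 5, 4, 12))
    s <- time_series_image(dat)
    w <- select_temporal_window(12, "mid_n", 5)
    got <- temporal_mean(s, w)$data
    ref <- array(0, dim = c(6, 5, 4))
    for (i in 1:6) for (j in 1:5) for (k in 1:4)
        ref[i, j, k] <- mean(dat[i, j, k, (w$start + 1):w$stop])
    expect_equal(got, ref, tolerance = 1e-12)
    # two-volume average and constant series
    w2 <- list(start = 0L, stop = 2L)
    expect_equal(temporal_mean(s, w2)$data,
                 (dat[, , , 1] + dat[, , , 2]) / 2)
    # linearity
    s3 <- time_series_image(dat * 3)
    expect_equal(temporal_mean(s3, w)$data, 3 * got, tolerance = 1e-12)
})

test_that("slice extraction takes the centred block and resizes to 224", {
    pp <- tiny_params(shape = c(64L, 64L, 64L), noise_sd = 5, seed = 4L)
    v <- make_smri_phantom(pp, "TC")
    sl <- extract_slices(v, "axial", 10)
    expect_length(sl, 10)
    expect_identical(sapply(sl, function(s) attr(s, "slice_index")), 27:36)
    expect_true(all(sapply(sl, function(s) identical(dim(s), c(224L, 224L)))))
    # n = 1 grabs exactly the middle slice (consistency of the two rules)
    one <- extract_slices(v, "coronal", 1, target = 64L)[[1]]
    mid <- middle_slice_index(64)
    attr(one, "slice_index") <- NULL
    expect_equal(unname(one), unname(v$data[, mid + 1L, ]), tolerance = 1e-12)
    # sagittal slices along x
    sx <- extract_slices(v, "sagittal", 3, target = 32L)
    expect_length(sx, 3)
})

test_that("bilinear resize preserves constants and equal-size identity", {
    cs <- matrix(3.7, 10, 8)
    expect_equal(resize_bilinear(cs, 224, 224),
                 matrix(3.7, 224, 224), tolerance = 1e-12)
    set.seed(5)
    m <- matrix(rnorm(224 * 224), 224, 224)
    expect_equal(resize_bilinear(m, 224, 224), m, tolerance = 1e-6)
    expect_error(resize_bilinear(matrix(numeric(0), 0, 0)),
                 class = "neuroslice_validation_error")
})

test_that("resampling agrees with an independent implementation", {
    skip_if_not_installed("EBImage")
    # smooth field: the two implementations differ only in sub-pixel
    # alignment conventions, which smoothness makes negligible
    g <- outer(seq(-2, 2, length.out = 40), seq(-2, 2, length.out = 40),
               function(a, b) exp(-(a^2 + b^2)))
    ours <- resize_bilinear(g, 80, 80)
    ref <- EBImage::resize(g, 80, 80)
    expect_gt(cor(as.vector(ours), as.vector(ref)), 0.999)
    expect_lt(max(abs(ours - ref)), 0.02)
})

test_that("trilinear volume resize preserves constants and linear ramps", {
    v <- array(2.5, dim = c(9, 9, 9))
    expect_equal(resize_volume(v, c(16, 16, 16)),
                 array(2.5, dim = c(16, 16, 16)), tolerance = 1e-12)
    ramp <- array(rep(seq(0, 1, length.out = 17), each = 1), dim = c(17, 5, 3))
    for (i in 1:17) ramp[i, , ] <- (i - 1) / 16
    shrunk <- resize_volume(ramp, c(9, 5, 3))
    expect_equal(shrunk[, 1, 1], seq(0, 1, length.out = 9), tolerance = 1e-12)
})

test_that("channel duplication is bitwise", {
    m <- matrix(rnorm(25), 5, 5)
    x3 <- to_three_channels(m)
    expect_identical(dim(x3), c(5L, 5L, 3L))
    expect_identical(x3[, , 1], m)
    expect_identical(x3[, , 2], m)
    expect_identical(x3[, , 3], m)
})

test_that("structural dataset generation obeys the count law and split boundary", {
    pp <- tiny_params(shape = c(16L, 16L, 16L), noise_sd = 10, seed = 9L)
    dir <- file.path(tempdir(), "smrigen")
    coh <- make_cohort(3, 2, pp, file.path(dir, "raw"), "sMRI")
    sp <- split_subjects(coh, 0.8, seed = 1)  # floor: 0 test ASD, 0 test TC
    ds <- generate_smri_dataset(sp, "axial", 4, file.path(dir, "out"),
                                target = 32L)
    s <- ds$samples
    expect_identical(nrow(s), 5L * 4L)
    for (part in c("train", "test")) for (lab in c("ASD", "TC")) {
        nsub <- sum(sp[[part]]$label == lab)
        expect_identical(sum(s$partition == part & s$label == lab), nsub * 4L)
    }
    expect_length(intersect(s$subject_id[s$partition == "train"],
                            s$subject_id[s$partition == "test"]), 0)
    expect_true(all(file.exists(s$path)))
    expect_true(file.exists(file.path(dir, "out", "provenance.csv")))
    # unreadable subject is reported by id
    bad <- sp; bad$train$path[1] <- tempfile()
    expect_error(generate_smri_dataset(bad, "axial", 2, file.path(dir, "bad")),
                 regexp = bad$train$subject_id[1])
})

test_that("functional dataset generation yields one sample per subject", {
    pp <- tiny_params(shape = c(12L, 12L, 12L), noise_sd = 5,
                      n_timepoints = 12L, activation_amplitude = 60,
                      seed = 10L)
    dir <- file.path(tempdir(), "fmrigen")
    coh <- make_cohort(2, 3, pp, file.path(dir, "raw"), "fMRI")
    sp <- split_subjects(coh, 0.8, seed = 2)
    ds <- generate_fmri_dataset(sp, "mid_n", 6, file.path(dir, "out"))
    expect_identical(nrow(ds$samples), 5L)
    expect_identical(sum(ds$samples$label == "ASD"), 2L)
    # strategy "all" equals mid_n with n = T
    ds_all <- generate_fmri_dataset(sp, "all", NULL, file.path(dir, "out_all"))
    ds_mid <- generate_fmri_dataset(sp, "mid_n", 12, file.path(dir, "out_mid"))
    for (i in seq_len(5))
        expect_equal(read_volume(ds_all$samples$path[i])$data,
                     read_volume(ds_mid$samples$path[i])$data,
                     tolerance = 1e-6)
    # loading into memory for training
    tr <- load_volume_samples(ds, "train")
    expect_identical(dim(tr$x)[4], nrow(sp$train))
    expect_identical(sort(unique(tr$y)), c(0L, 1L))
})
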