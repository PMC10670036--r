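test_that("noiseless phantom compartments carry exact tissue intensities", {
    pp <- tiny_params(shape = c(24L, 24L, 24L))
    v <- make_smri_phantom(pp, "TC")
    m <- phantom_masks(pp$shape)
    expect_true(all(v$data[m$wm] == 500))
    expect_true(all(v$data[m$gm] == 250))
    expect_true(all(v$data[m$csf] == 100))
    expect_true(all(v$data[!m$brain] == 0))
    # ASD label perturbs only GM, by the configured fraction
    pp2 <- tiny_params(shape = c(24L, 24L, 24L), class_effect = 0.2)
    a <- make_smri_phantom(pp2, "ASD")
    expect_true(all(a$data[m$gm] == 250 * 1.2))
    expect_true(all(a$data[m$wm] == 500))
})

test_that("phantom generation is deterministic in the seed", {
    pp <- phantom_params(shape = c(12L, 12L, 12L), noise_sd = 20, seed = 7L)
    expect_identical(make_smri_phantom(pp, "ASD")$data,
                     make_smri_phantom(pp, "ASD")$data)
    pp$n_timepoints <- 5L
    expect_identical(make_fmri_phantom(pp, "TC")$data,
                     make_fmri_phantom(pp, "TC")$data)
    pp2 <- pp; pp2$seed <- 8L
    expect_false(identical(make_smri_phantom(pp, "ASD")$data,
                           make_smri_phantom(pp2, "ASD")$data))
})

test_that("WM-region mean under noise matches the stated noise model", {
    # Monte-Carlo: noise_sd = 0.1 * wm mean; WM voxel mean within 3 s.e.
    pp <- tiny_params(shape = c(32L, 32L, 32L), noise_sd = 50, seed = 5L)
    v <- make_smri_phantom(pp, "TC")
    wm <- phantom_masks(pp$shape)$wm
    n <- sum(wm)
    expect_gt(n, 1000)
    se <- 50 / sqrt(n)
    expect_lt(abs(mean(v$data[wm]) - 500), 3 * se)
    # and the voxelwise spread matches sigma within 5%
    expect_lt(abs(sd(v$data[wm]) - 50) / 50, 0.05)
})

test_that("4D phantom: zero amplitude and zero noise reproduce the baseline", {
    pp <- tiny_params(shape = c(12L, 12L, 12L), activation_amplitude = 0,
                      n_timepoints = 6L)
    s <- make_fmri_phantom(pp, "ASD")
    for (t in 2:6)
        expect_identical(s$data[, , , t], s$data[, , , 1])
})

test_that("temporal signal has zero mean over the full series", {
    pp <- tiny_params(shape = c(12L, 12L, 12L), activation_amplitude = 80,
                      n_timepoints = 16L)
    s <- make_fmri_phantom(pp, "ASD")
    base <- make_fmri_phantom(tiny_params(shape = c(12L, 12L, 12L),
                                          activation_amplitude = 0,
                                          n_timepoints = 16L), "ASD")
    full <- select_temporal_window(16L, "all")
    expect_equal(temporal_mean(s, full)$data, base$data[, , , 1],
                 tolerance = 1e-6)
    # default series length is 176 timepoint volumes
    expect_identical(phantom_params()$n_timepoints, 176L)
})

test_that("cohorts are written with the requested composition and are reproducible", {
    pp <- tiny_params(shape = c(8L, 8L, 8L), noise_sd = 10, seed = 3L)
    d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
    m1 <- make_cohort(3, 4, pp, d1, "sMRI")
    expect_identical(nrow(m1), 7L)
    expect_identical(sum(m1$label == "ASD"), 3L)
    expect_identical(anyDuplicated(m1$subject_id), 0L)
    expect_true(all(file.exists(m1$path)))
    m2 <- make_cohort(3, 4, pp, d2, "sMRI")
    for (i in seq_len(7))
        expect_identical(read_volume(m1$path[i])$data,
                         read_volume(m2$path[i])$data)
    # degenerate compositions
    m0 <- make_cohort(0, 3, pp, file.path(tempdir(), "coh0"), "sMRI")
    expect_identical(sum(m0$label == "ASD"), 0L)
    expect_identical(nrow(m0), 3L)
})

test_that("class separation is many sigma at strong effect and low noise", {
    shape <- c(16L, 16L, 16L)
    gm <- phantom_masks(shape)$gm
    gm_means <- function(lab) sapply(1:8, function(i) {
        pp <- phantom_params(shape = shape, noise_sd = 5, subject_jitter = 0,
                             class_effect = 0.3, seed = 100L + i)
        mean(make_smri_phantom(pp, lab)$data[gm])
    })
    asd <- gm_means("ASD"); tc <- gm_means("TC")
    gap <- mean(asd) - mean(tc)
    noise <- sqrt(var(asd) / 8 + var(tc) / 8)
    expect_gt(gap / max(noise, 1e-12), 5)
})

test_that("invalid phantom parameters are rejected", {
    expect_error(phantom_params(tissue_intensities = c(250, 100, 500)),
                 class = "neuroslice_parameter_error")
    expect_error(phantom_params(noise_sd = -1),
                 class = "neuroslice_parameter_error")
    expect_error(phantom_params(n_timepoints = 0),
                 class = "neuroslice_parameter_error")
})
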