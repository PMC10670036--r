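# Small deterministic fixtures shared across test files.

tiny_params <- function(shape = c(16L, 16L, 16L), noise_sd = 0,
                        subject_jitter = 0, seed = 1L, ...) {
    phantom_params(shape = shape, noise_sd = noise_sd,
                   subject_jitter = subject_jitter, seed = seed, ...)
}

# cohort data frame without files on disk (for split tests)
fake_cohort <- function(n_asd, n_tc) {
    n <- n_asd + n_tc
    data.frame(subject_id = sprintf("s%04d", seq_len(n)),
               label = rep(c("ASD", "TC"), c(n_asd, n_tc)),
               path = rep("unused", n), stringsAsFactors = FALSE)
}

# labelled in-memory phantom batch as a 4D array (for model tests)
phantom_batch <- function(n_per_class, shape = c(16L, 16L, 16L),
                          class_effect = 0.3, noise_sd = 10, seed = 1L) {
    n <- 2L * n_per_class
    x <- array(0, dim = c(shape, n))
    y <- rep(c(1L, 0L), n_per_class)
    for (i in seq_len(n)) {
        pp <- phantom_params(shape = shape, noise_sd = noise_sd,
                             subject_jitter = 0, class_effect = class_effect,
                             seed = seed + 13L * i)
        lab <- if (y[i] == 1L) "ASD" else "TC"
        x[, , , i] <- make_smri_phantom(pp, lab)$data / 500
    }
    list(x = x, y = y)
}
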