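#' Parameters of the synthetic brain phantom
#'
#' The phantom emulates the statistical structure the pipeline assumes of a
#' skull-stripped brain scan: nested axis-aligned ellipsoidal tissue
#' compartments (zero background, then a CSF shell, grey matter, and white
#' matter innermost) with distinct mean intensities plus additive Gaussian
#' noise. For the 4D variant, each timepoint is the structural baseline plus
#' a regional cosine signal confined to the innermost compartment, with one
#' full period over the series (so its mean over the whole series is zero),
#' present only in ASD-labelled phantoms.
#'
#' Class differences: `class_effect` scales the grey-matter intensity of
#' ASD-labelled 3D phantoms by `1 + class_effect`; `activation_amplitude`
#' sets the temporal signal strength of ASD-labelled 4D phantoms (typical
#' controls get amplitude 0). `subject_jitter` adds per-subject
#' multiplicative variability to all tissue intensities, mimicking
#' scanner/biological variation between subjects.
#'
#' @param shape Integer vector of 3 grid extents.
#' @param tissue_intensities Named numeric vector `c(csf=, gm=, wm=)` of
#'   compartment mean intensities, strictly increasing (T1-like contrast).
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param class_effect Fractional GM intensity perturbation for ASD (>= 0).
#' @param n_timepoints Series length for 4D phantoms.
#' @param activation_amplitude Temporal signal amplitude for ASD (4D only).
#' @param subject_jitter SD of the per-subject log-normal intensity factor.
#' @param seed Integer RNG seed.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(shape = c(64L, 64L, 64L),
                           tissue_intensities = c(csf = 100, gm = 250, wm = 500),
                           noise_sd = 25,
                           class_effect = 0.1,
                           n_timepoints = 176L,
                           activation_amplitude = 50,
                           subject_jitter = 0.02,
                           seed = 1L) {
    shape <- as.integer(shape)
    ti <- tissue_intensities
    if (length(shape) != 3L || any(shape < 1L))
        stop_ns("`shape` must be 3 positive extents",
                "neuroslice_parameter_error")
    if (length(ti) != 3L || is.unsorted(ti, strictly = TRUE) || any(ti <= 0))
        stop_ns("tissue intensities must satisfy 0 < csf < gm < wm",
                "neuroslice_parameter_error")
    names(ti) <- c("csf", "gm", "wm")
    if (noise_sd < 0 || class_effect < 0 || subject_jitter < 0)
        stop_ns("noise_sd, class_effect and subject_jitter must be >= 0",
                "neuroslice_parameter_error")
    if (n_timepoints < 1L)
        stop_ns("n_timepoints must be >= 1", "neuroslice_parameter_error")
    structure(list(shape = shape, tissue_intensities = ti,
                   noise_sd = noise_sd, class_effect = class_effect,
                   n_timepoints = as.integer(n_timepoints),
                   activation_amplitude = activation_amplitude,
                   subject_jitter = subject_jitter, seed = as.integer(seed)),
              class = "phantom_params")
}

# squared normalized ellipsoid radius for every voxel; <= 1 is inside.
# `frac` scales the reference semi-axes (0.42 of each grid extent).
ellipsoid_r2 <- function(shape, frac) {
    ctr <- (shape + 1) / 2
    semi <- 0.42 * shape * frac
    gx <- ((seq_len(shape[1]) - ctr[1]) / semi[1])^2
    gy <- ((seq_len(shape[2]) - ctr[2]) / semi[2])^2
    gz <- ((seq_len(shape[3]) - ctr[3]) / semi[3])^2
    outer(outer(gx, gy, `+`), gz, `+`)
}

#' Compartment masks of the phantom geometry
#'
#' @param shape Integer vector of 3 grid extents.
#' @return A list of logical arrays `csf`, `gm`, `wm` (mutually exclusive)
#'   and `brain` (their union). The WM compartment is also the activation
#'   region of the 4D phantom.
#' @export
phantom_masks <- function(shape) {
    shape <- as.integer(shape)
    outer_r2 <- ellipsoid_r2(shape, 1)
    gm_r2 <- ellipsoid_r2(shape, 0.8)
    wm_r2 <- ellipsoid_r2(shape, 0.52)
    wm <- wm_r2 <= 1
    gm <- gm_r2 <= 1 & !wm
    csf <- outer_r2 <= 1 & !wm & !gm
    list(csf = csf, gm = gm, wm = wm, brain = outer_r2 <= 1)
}

phantom_baseline <- function(params, label, jitter_mult) {
    m <- phantom_masks(params$shape)
    ti <- params$tissue_intensities * jitter_mult
    if (label == "ASD") ti["gm"] <- ti["gm"] * (1 + params$class_effect)
    x <- array(0, dim = params$shape)
    x[m$csf] <- ti[["csf"]]
    x[m$gm] <- ti[["gm"]]
    x[m$wm] <- ti[["wm"]]
    list(x = x, masks = m)
}

#' Generate one synthetic 3D structural phantom
#'
#' @param params A [phantom_params] object.
#' @param label `"ASD"` or `"TC"`; ASD perturbs the GM intensity by
#'   `class_effect`.
#' @return A [volume_image]. Reproducible: the same `params$seed` always
#'   yields the same volume.
#' @export
make_smri_phantom <- function(params, label = c("TC", "ASD")) {
    stopifnot(inherits(params, "phantom_params"))
    label <- match.arg(label)
    with_seed(params$seed, {
        jit <- exp(rnorm(1L, 0, params$subject_jitter))
        b <- phantom_baseline(params, label, jit)
        x <- b$x
        # noise only inside the brain: background stays exactly zero,
        # as in a skull-stripped scan (and as the nonzero foreground
        # mask of the normalizer assumes)
        if (params$noise_sd > 0) {
            nb <- sum(b$masks$brain)
            x[b$masks$brain] <- x[b$masks$brain] +
                rnorm(nb, 0, params$noise_sd)
        }
        volume_image(x, spacing_affine(params$shape))
    })
}

#' Generate one synthetic 4D functional phantom
#'
#' Timepoint `t` (0-based) equals the structural baseline plus
#' `amplitude * cos(2*pi*t/T)` inside the innermost compartment plus noise,
#' where `amplitude` is `activation_amplitude` for ASD and 0 for TC. The
#' cosine completes exactly one period over the series, so the full-series
#' temporal mean equals the baseline; a centred sub-window straddling the
#' half-period retains most of the amplitude, which is what makes windowed
#' mean images class-informative.
#'
#' @inheritParams make_smri_phantom
#' @return A [time_series_image] with `params$n_timepoints` volumes.
#' @export
make_fmri_phantom <- function(params, label = c("TC", "ASD")) {
    stopifnot(inherits(params, "phantom_params"))
    label <- match.arg(label)
    nt <- params$n_timepoints
    with_seed(params$seed, {
        jit <- exp(rnorm(1L, 0, params$subject_jitter))
        b <- phantom_baseline(params, "TC", jit)  # no GM effect in 4D
        amp <- if (label == "ASD") params$activation_amplitude else 0
        x <- array(0, dim = c(params$shape, nt))
        signal <- amp * cos(2 * pi * (seq_len(nt) - 1) / nt)
        for (t in seq_len(nt)) {
            vol <- b$x
            if (amp != 0) vol[b$masks$wm] <- vol[b$masks$wm] + signal[t]
            x[, , , t] <- vol
        }
        if (params$noise_sd > 0) {
            brain <- which(array(b$masks$brain, dim = dim(x)))
            x[brain] <- x[brain] + rnorm(length(brain), 0, params$noise_sd)
        }
        time_series_image(x, spacing_affine(params$shape))
    })
}

# 1 mm isotropic affine centred on the grid
spacing_affine <- function(shape) {
    aff <- diag(4)
    aff[1:3, 4] <- -(shape + 1) / 2
    aff
}

#' Generate a labelled phantom cohort on disk
#'
#' Writes one NIfTI file per subject plus a manifest CSV compatible with
#' [read_manifest()]. Per-subject seeds are derived deterministically from
#' `params$seed`, so the cohort is a pure function of its arguments.
#'
#' @param n_asd,n_tc Number of ASD and TC subjects (>= 0).
#' @param params A [phantom_params] object.
#' @param out_dir Output directory (created if needed).
#' @param modality `"sMRI"` (3D) or `"fMRI"` (4D).
#' @param compress Write `.nii.gz` (default) or `.nii`.
#' @return The manifest data frame (`subject_id`, `label`, `path`).
#' @export
make_cohort <- function(n_asd, n_tc, params, out_dir,
                        modality = c("sMRI", "fMRI"), compress = TRUE) {
    stopifnot(inherits(params, "phantom_params"), n_asd >= 0, n_tc >= 0)
    modality <- match.arg(modality)
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
        stop_ns(sprintf("cannot create directory: %s", out_dir),
                "neuroslice_io_error")
    labels <- rep(c("ASD", "TC"), c(n_asd, n_tc))
    n <- length(labels)
    if (n == 0L)
        return(data.frame(subject_id = character(), label = character(),
                          path = character(), stringsAsFactors = FALSE))
    ids <- sprintf("sub-%04d", seq_len(n))
    ext <- if (compress) ".nii.gz" else ".nii"
    paths <- file.path(out_dir, paste0(ids, ext))
    for (i in seq_len(n)) {
        p_i <- params
        # distinct, deterministic per-subject seed stream
        p_i$seed <- (params$seed + 7919L * i) %% .Machine$integer.max
        if (modality == "sMRI")
            write_volume(make_smri_phantom(p_i, labels[i]), paths[i])
        else
            write_series(make_fmri_phantom(p_i, labels[i]), paths[i])
    }
    manifest <- data.frame(subject_id = ids, label = labels, path = paths,
                           stringsAsFactors = FALSE)
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    manifest
}
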