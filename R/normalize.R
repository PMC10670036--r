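#' Fuzzy c-means clustering of intensities
#'
#' Standard FCM on 1D intensity data: alternating updates of the fuzzy
#' memberships and cluster centroids minimising
#' \deqn{J = \sum_{i}\sum_{j} u_{ij}^m (x_j - c_i)^2,}
#' stopped when the largest centroid change falls below `tol` or after
#' `max_iter` iterations. Centroids are initialised at evenly spaced
#' intensity quantiles, which makes the fit deterministic; `seed` is used
#' only when `init = "random"`.
#'
#' @param intensities Numeric vector of finite intensities.
#' @param k Number of clusters (>= 1).
#' @param m Fuzzifier (> 1); 2 is the conventional choice for brain MRI.
#' @param tol Convergence tolerance on the centroid update.
#' @param max_iter Iteration cap.
#' @param init `"quantile"` (deterministic, default) or `"random"`.
#' @param seed RNG seed for random initialisation.
#' @return An `fcm_result`: `centroids` (sorted ascending), `membership`
#'   (n x k matrix, rows summing to 1, columns ordered like `centroids`),
#'   `hard` (1-based index of the maximal membership per point),
#'   `membership_summary` (voxel counts by hard assignment), `n_iter`,
#'   `objective` (final value) and `objective_trace` (one value per
#'   iteration, non-increasing).
#' @export
fcm_fit <- function(intensities, k = 3L, m = 2, tol = 1e-5, max_iter = 100L,
                    init = c("quantile", "random"), seed = 1L) {
    x <- as.numeric(intensities)
    init <- match.arg(init)
    if (length(x) == 0L || !all(is.finite(x)))
        stop_ns("intensities must be non-empty and finite",
                "neuroslice_validation_error")
    k <- as.integer(k)
    if (k < 1L) stop_ns("k must be >= 1", "neuroslice_parameter_error")
    if (m <= 1) stop_ns("fuzzifier m must be > 1", "neuroslice_parameter_error")
    if (length(unique(x)) < k)
        stop_ns(sprintf("need at least %d distinct intensities for k = %d", k, k),
                "neuroslice_degeneracy_error")

    centers <- if (init == "quantile") {
        unname(quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                        names = FALSE))
    } else {
        with_seed(seed, sample(unique(x), k))
    }
    if (anyDuplicated(centers))  # degenerate quantiles on skewed data
        centers <- seq(min(x), max(x), length.out = k)
    centers <- sort(centers)

    expo <- 2 / (m - 1)
    trace <- numeric(0)
    n_iter <- 0L
    u <- NULL
    for (iter in seq_len(max_iter)) {
        d2 <- outer(x, centers, `-`)^2                   # n x k
        u <- fcm_memberships(d2, expo)
        um <- u^m
        new_centers <- as.numeric(crossprod(um, x) / colSums(um))
        trace <- c(trace, sum(um * d2))
        delta <- max(abs(new_centers - centers))
        centers <- new_centers
        n_iter <- iter
        if (delta < tol) break
    }
    ord <- order(centers)
    centers <- centers[ord]
    u <- u[, ord, drop = FALSE]
    hard <- max.col(u, ties.method = "first")
    counts <- tabulate(hard, nbins = k)
    names(counts) <- paste0("cluster", seq_len(k))
    structure(list(centroids = centers, fuzzifier_m = m, n_iter = n_iter,
                   objective = trace[length(trace)], objective_trace = trace,
                   membership = u, hard = hard,
                   membership_summary = counts),
              class = "fcm_result")
}

# membership update; points coinciding with a centroid get crisp membership
fcm_memberships <- function(d2, expo) {
    n <- nrow(d2); k <- ncol(d2)
    if (k == 1L) return(matrix(1, n, 1L))
    inv <- d2^(-expo / 2)          # (1/d^2)^(1/(m-1))
    zero <- !is.finite(inv)
    u <- inv / rowSums(inv)
    bad <- rowSums(zero) > 0L
    if (any(bad)) {
        u[bad, ] <- 0
        first_zero <- apply(zero[bad, , drop = FALSE], 1L, which.max)
        u[cbind(which(bad), first_zero)] <- 1
    }
    u
}

#' @export
print.fcm_result <- function(x, ...) {
    cat(sprintf("<fcm_result> k=%d, m=%g, %d iterations, objective %.6g\n",
                length(x$centroids), x$fuzzifier_m, x$n_iter, x$objective))
    cat("centroids:", paste(signif(x$centroids, 6), collapse = ", "), "\n")
    invisible(x)
}

#' FCM tissue-mean intensity normalization
#'
#' Clusters the foreground (nonzero) voxels of a volume into `k` intensity
#' classes with [fcm_fit], computes the mean intensity of the voxels
#' hard-assigned to the reference tissue — by default the cluster with the
#' highest centroid, a white-matter proxy on T1-like contrast — and divides
#' every voxel by that tissue mean. After normalization the reference
#' tissue mean equals 1 and background zeros remain zero. The operation is
#' scale-invariant (`normalize(a*V) == normalize(V)` for `a > 0`) and
#' idempotent.
#'
#' @param vol A [volume_image] with at least one nonzero voxel.
#' @param k Number of tissue classes (default 3: CSF/GM/WM).
#' @param m,tol,max_iter FCM parameters, see [fcm_fit].
#' @param reference Index (1 = lowest centroid) of the reference tissue;
#'   defaults to `k`, the highest-centroid cluster.
#' @return A [volume_image] with normalized intensities; the `fcm_result`
#'   and the reference tissue mean are attached as attributes `fcm` and
#'   `reference_mean`.
#' @export
tissue_mean_normalize <- function(vol, k = 3L, m = 2, tol = 1e-5,
                                  max_iter = 100L, reference = k) {
    stopifnot(inherits(vol, "volume_image"))
    fg <- vol$data != 0
    if (!any(fg))
        stop_ns("volume has no nonzero foreground voxels",
                "neuroslice_degeneracy_error")
    fit <- fcm_fit(vol$data[fg], k = k, m = m, tol = tol, max_iter = max_iter)
    reference <- as.integer(reference)
    stopifnot(reference >= 1L, reference <= k)
    ref_voxels <- vol$data[fg][fit$hard == reference]
    if (length(ref_voxels) == 0L)
        stop_ns("reference tissue cluster is empty",
                "neuroslice_degeneracy_error")
    ref_mean <- mean(ref_voxels)
    out <- volume_image(vol$data / ref_mean, vol$affine)
    attr(out, "fcm") <- fit
    attr(out, "reference_mean") <- ref_mean
    out
}

#' Normalize every subject of a cohort to disk
#'
#' Applies [tissue_mean_normalize] to each manifest entry and writes the
#' normalized volumes, returning an updated manifest. Running this once and
#' pointing several slice-generation configurations at its output avoids
#' re-fitting the FCM per configuration.
#'
#' @param manifest Data frame with `subject_id`, `label`, `path` (3D files).
#' @param out_dir Output directory.
#' @param ... Passed to [tissue_mean_normalize].
#' @return The updated manifest data frame.
#' @export
normalize_cohort <- function(manifest, out_dir, ...) {
    validate_cohort(manifest)
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
        stop_ns(sprintf("cannot create directory: %s", out_dir),
                "neuroslice_io_error")
    out <- manifest
    for (i in seq_len(nrow(manifest))) {
        vol <- read_volume(manifest$path[i])
        norm <- tissue_mean_normalize(vol, ...)
        out$path[i] <- file.path(out_dir,
                                 paste0(manifest$subject_id[i], "_norm.nii.gz"))
        write_volume(norm, out$path[i])
    }
    write_manifest(out, file.path(out_dir, "manifest.csv"))
    out
}
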