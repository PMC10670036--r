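#' Anatomical plane to array axis mapping
#'
#' The axial, coronal and sagittal planes slice along the z, y and x array
#' axes respectively (fixed convention).
#'
#' @param name `"axial"`, `"coronal"` or `"sagittal"`.
#' @return A `brain_plane` list with fields `name` and `axis` (3, 2, 1).
#' @export
brain_plane <- function(name = c("axial", "coronal", "sagittal")) {
    name <- match.arg(name)
    axis <- c(axial = 3L, coronal = 2L, sagittal = 1L)[[name]]
    structure(list(name = name, axis = axis), class = "brain_plane")
}

as_brain_plane <- function(plane) {
    if (inherits(plane, "brain_plane")) plane else brain_plane(plane)
}

#' Subject-level stratified train/test split
#'
#' Subjects are partitioned before any sample generation, so no subject can
#' contribute images to both partitions (leakage prevention). The split is
#' stratified by class with per-class test count `floor((1-fraction)*n)`,
#' and is deterministic given `seed`.
#'
#' @param cohort Data frame with `subject_id`, `label`, `path`; subject ids
#'   must be unique.
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer RNG seed.
#' @return A `split_manifest`: data frames `train` and `test`, plus
#'   `fraction` and `seed`.
#' @export
split_subjects <- function(cohort, fraction = 0.8, seed = 1L) {
    validate_cohort(cohort)
    if (nrow(cohort) == 0L)
        stop_ns("cohort is empty", "neuroslice_validation_error")
    if (fraction <= 0 || fraction >= 1)
        stop_ns("fraction must be in (0, 1)", "neuroslice_validation_error")
    test_ids <- character(0)
    for (cls in sort(unique(cohort$label))) {
        ids <- sort(cohort$subject_id[cohort$label == cls])
        # tolerance guards against binary representation of the fraction
        # (e.g. (1 - 0.8) * 105 = 20.999...96 must floor to 21, not 20)
        n_test <- floor((1 - fraction) * length(ids) + 1e-9)
        if (n_test > 0L)
            test_ids <- c(test_ids,
                          with_seed(seed + match(cls, c("ASD", "TC")),
                                    sample(ids, n_test)))
    }
    is_test <- cohort$subject_id %in% test_ids
    structure(list(train = cohort[!is_test, , drop = FALSE],
                   test = cohort[is_test, , drop = FALSE],
                   fraction = fraction, seed = as.integer(seed)),
              class = "split_manifest")
}

#' @export
print.split_manifest <- function(x, ...) {
    tab <- function(df) paste(sprintf("%d %s", table(df$label)[c("ASD", "TC")],
                                      c("ASD", "TC")), collapse = " / ")
    cat(sprintf("<split_manifest> train: %s; test: %s (fraction %.2f)\n",
                tab(x$train), tab(x$test), x$fraction))
    invisible(x)
}

#' Middle slice index
#'
#' 0-based index `floor(dim_size/2)` of the central slice along an axis of
#' extent `dim_size` (the "coordinate d/2" convention).
#'
#' @param dim_size Axis extent (>= 1).
#' @return Integer 0-based slice index.
#' @export
middle_slice_index <- function(dim_size) {
    if (dim_size < 1) stop_ns("dim_size must be >= 1",
                              "neuroslice_validation_error")
    as.integer(floor(dim_size / 2))
}

#' Centred n-slice window
#'
#' The half-open 0-based index window `[c - floor(n/2), c - floor(n/2) + n)`
#' with `c = middle_slice_index(length)`. For a 176-long axis and `n = 30`
#' this is `[73, 103)`.
#'
#' @param length Axis extent.
#' @param n Window width, `1 <= n <= length`.
#' @return List with 0-based `start` and exclusive `stop`; width exactly `n`.
#' @export
centered_window <- function(length, n) {
    if (n < 1 || n > length)
        stop_ns("need 1 <= n <= length", "neuroslice_validation_error")
    start <- middle_slice_index(length) - as.integer(floor(n / 2))
    list(start = as.integer(start), stop = as.integer(start + n))
}

#' Extract centred 2D slices from a volume
#'
#' Takes the `n` slices of the [centered_window] along the plane's axis, in
#' ascending index order, each resized to `target` x `target` by bilinear
#' interpolation.
#'
#' @param vol A [volume_image].
#' @param plane A [brain_plane] or plane name.
#' @param n Number of slices (must not exceed the axis extent).
#' @param target Output resolution per side (default 224).
#' @return A list of `n` matrices; each element carries the 0-based slice
#'   index as attribute `slice_index`.
#' @export
extract_slices <- function(vol, plane, n, target = 224L) {
    stopifnot(inherits(vol, "volume_image"))
    plane <- as_brain_plane(plane)
    extent <- vol$shape[plane$axis]
    w <- centered_window(extent, n)
    idx <- seq.int(w$start, w$stop - 1L)  # 0-based
    lapply(idx, function(i) {
        sl <- switch(plane$axis,
                     vol$data[i + 1L, , ],
                     vol$data[, i + 1L, ],
                     vol$data[, , i + 1L])
        out <- resize_bilinear(sl, target, target)
        attr(out, "slice_index") <- i
        out
    })
}

#' Temporal window selection for 4D series
#'
#' Three strategies over a series of `T` timepoint volumes:
#' `mid_n` takes the centred `n`-wide window ([centered_window]); `all`
#' takes every timepoint; `all_trim` drops the first and last 10 timepoints
#' (guarding against start/end acquisition artefacts), requiring `T > 20`.
#'
#' @param n_timepoints Series length `T`.
#' @param strategy `"mid_n"`, `"all"` or `"all_trim"`.
#' @param n Window width (required for `mid_n`).
#' @return A `temporal_window` list with 0-based `start`, exclusive `stop`
#'   and the `strategy`.
#' @export
select_temporal_window <- function(n_timepoints,
                                   strategy = c("mid_n", "all", "all_trim"),
                                   n = NULL) {
    strategy <- match.arg(strategy)
    if (n_timepoints < 1)
        stop_ns("n_timepoints must be >= 1", "neuroslice_validation_error")
    w <- switch(strategy,
        mid_n = {
            if (is.null(n))
                stop_ns("strategy 'mid_n' requires n",
                        "neuroslice_validation_error")
            centered_window(n_timepoints, n)
        },
        all = list(start = 0L, stop = as.integer(n_timepoints)),
        all_trim = {
            if (n_timepoints <= 20L)
                stop_ns("'all_trim' requires more than 20 timepoints",
                        "neuroslice_validation_error")
            list(start = 10L, stop = as.integer(n_timepoints - 10L))
        })
    structure(c(w, list(strategy = strategy)), class = "temporal_window")
}

#' Temporal mean image
#'
#' Voxelwise arithmetic mean of the timepoint volumes indexed by the
#' half-open window `[start, stop)`, collapsing a 4D series to 3D.
#'
#' @param series A [time_series_image].
#' @param window A `temporal_window` (or any list with 0-based `start` and
#'   exclusive `stop`).
#' @return A [volume_image].
#' @export
temporal_mean <- function(series, window) {
    stopifnot(inherits(series, "time_series_image"))
    start <- window$start; stop_ <- window$stop
    if (is.null(start) || is.null(stop_) || start < 0 ||
        stop_ > series$n_timepoints || start >= stop_)
        stop_ns("invalid temporal window for this series",
                "neuroslice_validation_error")
    sub <- series$data[, , , (start + 1L):stop_, drop = FALSE]
    volume_image(rowMeans(sub, dims = 3L), series$affine)
}

slice_filename <- function(subject_id, plane, slice_index) {
    sprintf("%s_%s_%03d.png", subject_id, plane$name, slice_index)
}

#' Generate a 2D slice dataset from structural volumes
#'
#' For every subject of both partitions: read the volume, optionally apply
#' [tissue_mean_normalize], extract the centred `n_slices` along `plane`,
#' and export each as a 224x224 8-bit PNG under
#' `out_dir/{train,test}/{ASD,TC}/`. Sample counts obey
#' `n_subjects(partition, class) * n_slices`, and the subject sets feeding
#' the two partitions are disjoint by construction of the split.
#'
#' @param split A `split_manifest` from [split_subjects].
#' @param plane A [brain_plane] or plane name.
#' @param n_slices Slices per subject (1, 10 and 50 are the conventional
#'   choices).
#' @param out_dir Output directory.
#' @param normalize Apply FCM tissue-mean normalization before slicing
#'   (default TRUE). Set to FALSE when the manifest already points at
#'   volumes written by [normalize_cohort].
#' @param target Output resolution per side.
#' @param ... FCM parameters passed to [tissue_mean_normalize].
#' @return A `slice_dataset`: data frame `samples` with columns
#'   `subject_id`, `label`, `partition`, `plane`, `slice_index`, `path`,
#'   written also to `out_dir/provenance.csv`.
#' @export
generate_smri_dataset <- function(split, plane, n_slices, out_dir,
                                  normalize = TRUE, target = 224L, ...) {
    stopifnot(inherits(split, "split_manifest"))
    plane <- as_brain_plane(plane)
    rows <- list()
    for (partition in c("train", "test")) {
        manifest <- split[[partition]]
        for (i in seq_len(nrow(manifest))) {
            sid <- manifest$subject_id[i]
            lab <- manifest$label[i]
            vol <- tryCatch(read_volume(manifest$path[i]), error = function(e)
                stop_ns(sprintf("subject %s: %s", sid, conditionMessage(e)),
                        "neuroslice_io_error"))
            if (normalize) vol <- tissue_mean_normalize(vol, ...)
            dir <- file.path(out_dir, partition, lab)
            if (!dir.exists(dir))
                dir.create(dir, recursive = TRUE, showWarnings = FALSE)
            slices <- extract_slices(vol, plane, n_slices, target = target)
            for (sl in slices) {
                si <- attr(sl, "slice_index")
                p <- file.path(dir, slice_filename(sid, plane, si))
                write_png(sl, p)
                rows[[length(rows) + 1L]] <- data.frame(
                    subject_id = sid, label = lab, partition = partition,
                    plane = plane$name, slice_index = si, path = p,
                    stringsAsFactors = FALSE)
            }
        }
    }
    samples <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(samples))
        samples <- data.frame(subject_id = character(), label = character(),
                              partition = character(), plane = character(),
                              slice_index = integer(), path = character())
    write.csv(samples, file.path(out_dir, "provenance.csv"),
              row.names = FALSE)
    structure(list(samples = samples, plane = plane$name,
                   n_slices = n_slices, modality = "sMRI"),
              class = "slice_dataset")
}

#' Generate a 3D mean-image dataset from functional series
#'
#' For every subject of both partitions: read the 4D series, select the
#' temporal window, compute the [temporal_mean] image, apply
#' [tissue_mean_normalize], and write one 3D NIfTI sample per subject under
#' `out_dir/{train,test}/{ASD,TC}/`.
#'
#' @param split A `split_manifest` whose paths are 4D files.
#' @param strategy,n Temporal strategy and width, see
#'   [select_temporal_window].
#' @param out_dir Output directory.
#' @param normalize Apply tissue-mean normalization to the mean image.
#' @param ... FCM parameters passed to [tissue_mean_normalize].
#' @return A `slice_dataset` with one 3D sample per subject and a
#'   provenance CSV.
#' @export
generate_fmri_dataset <- function(split, strategy = "mid_n", n = NULL,
                                  out_dir, normalize = TRUE, ...) {
    stopifnot(inherits(split, "split_manifest"))
    rows <- list()
    for (partition in c("train", "test")) {
        manifest <- split[[partition]]
        for (i in seq_len(nrow(manifest))) {
            sid <- manifest$subject_id[i]
            lab <- manifest$label[i]
            series <- tryCatch(read_series(manifest$path[i]),
                               error = function(e)
                stop_ns(sprintf("subject %s: %s", sid, conditionMessage(e)),
                        "neuroslice_io_error"))
            w <- select_temporal_window(series$n_timepoints, strategy, n)
            vol <- temporal_mean(series, w)
            if (normalize) vol <- tissue_mean_normalize(vol, ...)
            dir <- file.path(out_dir, partition, lab)
            if (!dir.exists(dir))
                dir.create(dir, recursive = TRUE, showWarnings = FALSE)
            p <- file.path(dir, paste0(sid, "_mean.nii.gz"))
            write_volume(vol, p)
            rows[[length(rows) + 1L]] <- data.frame(
                subject_id = sid, label = lab, partition = partition,
                plane = "3d", slice_index = NA_integer_, path = p,
                stringsAsFactors = FALSE)
        }
    }
    samples <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(samples))
        samples <- data.frame(subject_id = character(), label = character(),
                              partition = character(), plane = character(),
                              slice_index = integer(), path = character())
    write.csv(samples, file.path(out_dir, "provenance.csv"),
              row.names = FALSE)
    structure(list(samples = samples, strategy = strategy, n = n,
                   modality = "fMRI"),
              class = "slice_dataset")
}

#' @export
print.slice_dataset <- function(x, ...) {
    cat(sprintf("<slice_dataset> %s, %d samples (%d train / %d test)\n",
                x$modality, nrow(x$samples),
                sum(x$samples$partition == "train"),
                sum(x$samples$partition == "test")))
    invisible(x)
}

#' Load the 3D samples of a dataset into memory
#'
#' Reads every sample of a (3D, fMRI-style) `slice_dataset` into a 4D array
#' for model training, optionally resampling each volume to `shape`.
#'
#' @param dataset A `slice_dataset` from [generate_fmri_dataset].
#' @param partition `"train"` or `"test"`.
#' @param shape Optional target shape for [resize_volume].
#' @return List with `x` (array nx x ny x nz x N), `y` (0/1 labels, ASD = 1),
#'   and `subject_id`.
#' @export
load_volume_samples <- function(dataset, partition = c("train", "test"),
                                shape = NULL) {
    stopifnot(inherits(dataset, "slice_dataset"))
    partition <- match.arg(partition)
    s <- dataset$samples[dataset$samples$partition == partition, ,
                         drop = FALSE]
    vols <- lapply(s$path, function(p) {
        v <- read_volume(p)$data
        if (!is.null(shape)) v <- resize_volume(v, shape) else v
    })
    if (length(vols) == 0L)
        return(list(x = NULL, y = integer(0), subject_id = character(0)))
    d <- dim(vols[[1L]])
    x <- array(unlist(vols, use.names = FALSE), dim = c(d, length(vols)))
    list(x = x, y = as.integer(s$label == "ASD"), subject_id = s$subject_id)
}
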