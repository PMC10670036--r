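#' 3D volume container
#'
#' A minimal in-memory representation of a structural MRI scan: a 3D
#' intensity array together with its 4x4 voxel-to-world affine and the voxel
#' spacing (mm) implied by the affine.
#'
#' @param data 3D numeric array of finite intensities.
#' @param affine 4x4 voxel-to-world transform. Defaults to identity.
#' @return An object of class `volume_image` with fields `data`, `shape`,
#'   `affine` and `spacing`.
#' @export
volume_image <- function(data, affine = diag(4)) {
    if (!is.array(data) || length(dim(data)) != 3L)
        stop_ns("`data` must be a 3D array", "neuroslice_validation_error")
    if (!all(is.finite(data)))
        stop_ns("intensities must be finite", "neuroslice_validation_error")
    affine <- validate_affine(affine)
    structure(list(data = data, shape = dim(data), affine = affine,
                   spacing = affine_spacing(affine)),
              class = "volume_image")
}

#' 4D time-series container
#'
#' A 4D functional MRI series: `T` timepoint volumes sharing one affine.
#'
#' @param data 4D numeric array (x, y, z, t) of finite intensities.
#' @param affine 4x4 voxel-to-world transform.
#' @return An object of class `time_series_image` with fields `data`,
#'   `shape`, `affine`, `spacing` and `n_timepoints`.
#' @export
time_series_image <- function(data, affine = diag(4)) {
    if (!is.array(data) || length(dim(data)) != 4L)
        stop_ns("`data` must be a 4D array", "neuroslice_validation_error")
    if (!all(is.finite(data)))
        stop_ns("intensities must be finite", "neuroslice_validation_error")
    affine <- validate_affine(affine)
    structure(list(data = data, shape = dim(data), affine = affine,
                   spacing = affine_spacing(affine),
                   n_timepoints = dim(data)[4L]),
              class = "time_series_image")
}

validate_affine <- function(affine) {
    affine <- unname(as.matrix(affine))
    if (!identical(dim(affine), c(4L, 4L)) || !all(is.finite(affine)))
        stop_ns("`affine` must be a finite 4x4 matrix",
                "neuroslice_validation_error")
    affine
}

affine_spacing <- function(affine) {
    sqrt(colSums(affine[1:3, 1:3, drop = FALSE]^2))
}

#' @export
print.volume_image <- function(x, ...) {
    cat(sprintf("<volume_image> %s voxels, spacing %s mm\n",
                paste(x$shape, collapse = "x"),
                paste(signif(x$spacing, 4), collapse = "x")))
    invisible(x)
}

#' @export
print.time_series_image <- function(x, ...) {
    cat(sprintf("<time_series_image> %s voxels, %d timepoints\n",
                paste(x$shape[1:3], collapse = "x"), x$n_timepoints))
    invisible(x)
}

read_nifti_array <- function(path) {
    if (!is.character(path) || length(path) != 1L || !file.exists(path))
        stop_ns(sprintf("file not found: %s", path), "neuroslice_io_error")
    img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                    error = function(e) stop_ns(
                        sprintf("failed to parse NIfTI file %s: %s",
                                path, conditionMessage(e)),
                        "neuroslice_io_error"))
    aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
    attributes(aff) <- list(dim = c(4L, 4L))
    dat <- as.array(img)
    attributes(dat) <- list(dim = dim(dat))  # drop RNifti bookkeeping
    list(data = dat, affine = aff)
}

#' Read a 3D NIfTI volume
#'
#' Loads a `.nii` / `.nii.gz` file. The array is used in voxel (array) space
#' exactly as stored; no reorientation to canonical axes is performed.
#'
#' @param path Path to a 3D NIfTI file.
#' @return A [volume_image].
#' @seealso [read_series()] for 4D files.
#' @export
read_volume <- function(path) {
    x <- read_nifti_array(path)
    d <- dim(x$data)
    if (length(d) != 3L)
        stop_ns(sprintf(
            "%s has %d dimensions; expected a 3D volume (use read_series() for 4D files)",
            path, length(d)), "neuroslice_dim_error")
    volume_image(x$data, x$affine)
}

#' Read a 4D NIfTI time series
#'
#' @param path Path to a 4D NIfTI file.
#' @return A [time_series_image]; `n_timepoints` equals the file's
#'   4th-dimension extent.
#' @export
read_series <- function(path) {
    x <- read_nifti_array(path)
    if (length(dim(x$data)) != 4L)
        stop_ns(sprintf(
            "%s has %d dimensions; expected a 4D series (use read_volume() for 3D files)",
            path, length(dim(x$data))), "neuroslice_dim_error")
    time_series_image(x$data, x$affine)
}

write_nifti_array <- function(data, affine, path) {
    img <- RNifti::asNifti(data)
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
    ok <- tryCatch({ RNifti::writeNifti(img, path, datatype = "float"); TRUE },
                   error = function(e) FALSE)
    if (!ok || !file.exists(path))
        stop_ns(sprintf("could not write NIfTI file: %s", path),
                "neuroslice_io_error")
    invisible(path)
}

#' Write a volume or series to NIfTI
#'
#' Data are stored as float32, the on-disk dtype used throughout the
#' package: round-trip fidelity at reasonable file size.
#'
#' @param vol A [volume_image].
#' @param series A [time_series_image].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
    stopifnot(inherits(vol, "volume_image"))
    write_nifti_array(vol$data, vol$affine, path)
}

#' @rdname write_volume
#' @export
write_series <- function(series, path) {
    stopifnot(inherits(series, "time_series_image"))
    write_nifti_array(series$data, series$affine, path)
    # the NIfTI writer canonicalises a trailing singleton dimension away;
    # restore dim[0] = 4 so a single-timepoint series stays 4D on disk
    if (series$n_timepoints == 1L) patch_nifti_dim4(path)
    invisible(path)
}

patch_nifti_dim4 <- function(path) {
    gz <- grepl("\\.gz$", path)
    con <- if (gz) gzfile(path, "rb") else file(path, "rb")
    raw_all <- readBin(con, "raw", file.info(path)$size * 20 + 1024)
    close(con)
    dims <- readBin(raw_all[41:56], "integer", 8, size = 2)
    dims[1] <- 4L; dims[5] <- 1L
    raw_all[41:56] <- writeBin(as.integer(dims), raw(), size = 2)
    con <- if (gz) gzfile(path, "wb") else file(path, "wb")
    writeBin(raw_all, con)
    close(con)
    invisible(path)
}

#' Export a 2D slice as an 8-bit grayscale PNG
#'
#' Intensities are mapped per slice by min-max scaling to 0..255 with
#' round-half-even rounding; a constant slice maps to all zeros. The mapping
#' is monotone: brighter voxels never store darker pixels.
#'
#' @param slice2d 2D numeric matrix with finite entries.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_png <- function(slice2d, path) {
    if (!is.matrix(slice2d) || !all(is.finite(slice2d)))
        stop_ns("`slice2d` must be a finite numeric matrix",
                "neuroslice_validation_error")
    ok <- tryCatch({ png::writePNG(png_scale(slice2d) / 255, path); TRUE },
                   error = function(e) FALSE)
    if (!ok || !file.exists(path))
        stop_ns(sprintf("could not write PNG file: %s", path),
                "neuroslice_io_error")
    invisible(path)
}

# min-max map to integers 0..255; round() is IEC 60559 round-half-even
png_scale <- function(slice2d) {
    rng <- range(slice2d)
    if (rng[1] == rng[2]) return(matrix(0, nrow(slice2d), ncol(slice2d)))
    round((slice2d - rng[1]) / (rng[2] - rng[1]) * 255)
}

#' Read and write subject manifests
#'
#' A manifest is a CSV with columns `subject_id`, `label` (`ASD` or `TC`)
#' and `path`, one row per subject.
#'
#' @param cohort Data frame with columns `subject_id`, `label`, `path`.
#' @param path CSV file path.
#' @return `read_manifest` returns the validated data frame.
#' @export
write_manifest <- function(cohort, path) {
    validate_cohort(cohort)
    write.csv(cohort[, c("subject_id", "label", "path")], path,
              row.names = FALSE)
    invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
    if (!file.exists(path))
        stop_ns(sprintf("manifest not found: %s", path), "neuroslice_io_error")
    m <- read.csv(path, stringsAsFactors = FALSE)
    validate_cohort(m)
    m
}

validate_cohort <- function(cohort) {
    need <- c("subject_id", "label", "path")
    if (!is.data.frame(cohort) || !all(need %in% names(cohort)))
        stop_ns("cohort must have columns subject_id, label, path",
                "neuroslice_validation_error")
    if (anyDuplicated(cohort$subject_id))
        stop_ns("duplicate subject_id in cohort", "neuroslice_validation_error")
    if (!all(cohort$label %in% c("ASD", "TC")))
        stop_ns("labels must be 'ASD' or 'TC'", "neuroslice_validation_error")
    invisible(cohort)
}
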