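# Linear-interpolation resampling shared by the 2D slice path (224x224
# inputs for image backbones) and the 3D volume path (CNN input resizing).
# Align-corners convention: output sample i (1..n_out) reads input coordinate
# 1 + (i-1)*(n_in-1)/(n_out-1), so equal sizes are an exact identity and
# constants are preserved exactly.

# n_out x n_in weight matrix for 1D linear interpolation
interp_matrix <- function(n_in, n_out) {
    if (n_in == 1L) return(matrix(1, n_out, 1L))
    pos <- if (n_out == 1L) (n_in + 1) / 2 else
        1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
    lo <- pmin(floor(pos), n_in - 1L)
    w <- pos - lo
    A <- matrix(0, n_out, n_in)
    A[cbind(seq_len(n_out), lo)] <- A[cbind(seq_len(n_out), lo)] + (1 - w)
    A[cbind(seq_len(n_out), lo + 1L)] <- A[cbind(seq_len(n_out), lo + 1L)] + w
    A
}

#' Resize a 2D slice by bilinear interpolation
#'
#' @param slice2d 2D numeric matrix with finite entries.
#' @param width,height Target extents (default 224, the input resolution
#'   expected by the image classification backbones).
#' @return A `width` x `height` matrix.
#' @export
resize_bilinear <- function(slice2d, width = 224L, height = 224L) {
    if (!is.matrix(slice2d) || nrow(slice2d) < 1L || ncol(slice2d) < 1L)
        stop_ns("`slice2d` must be a non-empty matrix",
                "neuroslice_validation_error")
    if (!all(is.finite(slice2d)))
        stop_ns("`slice2d` must be finite", "neuroslice_validation_error")
    A <- interp_matrix(nrow(slice2d), as.integer(width))
    B <- interp_matrix(ncol(slice2d), as.integer(height))
    A %*% slice2d %*% t(B)
}

#' Resize a 3D volume by trilinear interpolation
#'
#' Used to bring volumes to the cubic input resolution of the 3D-CNN.
#'
#' @param x 3D numeric array.
#' @param shape Integer vector of 3 target extents.
#' @return A resized 3D array.
#' @export
resize_volume <- function(x, shape) {
    if (!is.array(x) || length(dim(x)) != 3L)
        stop_ns("`x` must be a 3D array", "neuroslice_validation_error")
    shape <- as.integer(shape)
    stopifnot(length(shape) == 3L, all(shape >= 1L))
    d <- dim(x)
    if (identical(d, shape)) return(x)
    # interpolate one axis at a time; each step is a matrix product over
    # the unfolded array
    A1 <- interp_matrix(d[1], shape[1])
    x <- A1 %*% matrix(x, d[1], d[2] * d[3])
    dim(x) <- c(shape[1], d[2], d[3])
    A2 <- interp_matrix(d[2], shape[2])
    x <- aperm(x, c(2, 1, 3))
    x <- A2 %*% matrix(x, d[2], shape[1] * d[3])
    dim(x) <- c(shape[2], shape[1], d[3])
    x <- aperm(x, c(2, 1, 3))
    A3 <- interp_matrix(d[3], shape[3])
    x <- aperm(x, c(3, 1, 2))
    x <- A3 %*% matrix(x, d[3], shape[1] * shape[2])
    dim(x) <- c(shape[3], shape[1], shape[2])
    aperm(x, c(2, 3, 1))
}

#' Duplicate a grayscale slice into three identical channels
#'
#' Image backbones pretrained on natural images expect 3-channel input;
#' grayscale MRI slices are replicated channel-wise.
#'
#' @param slice2d 2D numeric matrix.
#' @return A 3D array of shape `c(dim(slice2d), 3)` whose channels are
#'   bitwise-identical copies.
#' @export
to_three_channels <- function(slice2d) {
    if (!is.matrix(slice2d) || length(slice2d) == 0L)
        stop_ns("`slice2d` must be a non-empty matrix",
                "neuroslice_validation_error")
    array(rep(slice2d, 3L), dim = c(dim(slice2d), 3L))
}

#' Rotate a 2D slice about its centre
#'
#' Bilinear resampling on the inverse mapping; samples falling outside the
#' slice read 0 (background). Output dimensions equal input dimensions.
#' An angle of 0 returns the input unchanged.
#'
#' @param slice2d 2D numeric matrix.
#' @param angle Rotation angle in degrees, counter-clockwise.
#' @return A rotated matrix of the same dimensions.
#' @export
rotate_slice <- function(slice2d, angle) {
    stopifnot(is.matrix(slice2d))
    if (angle == 0) return(slice2d)
    n1 <- nrow(slice2d); n2 <- ncol(slice2d)
    th <- angle * pi / 180
    c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
    g <- expand.grid(i = seq_len(n1), j = seq_len(n2))
    di <- g$i - c1; dj <- g$j - c2
    # inverse rotation of the output grid into the input
    si <- cos(th) * di + sin(th) * dj + c1
    sj <- -sin(th) * di + cos(th) * dj + c2
    i0 <- floor(si); j0 <- floor(sj)
    wi <- si - i0; wj <- sj - j0
    at <- function(ii, jj) {
        ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2
        v <- numeric(length(ii))
        v[ok] <- slice2d[cbind(ii[ok], jj[ok])]
        v
    }
    out <- (1 - wi) * (1 - wj) * at(i0, j0) +
        wi * (1 - wj) * at(i0 + 1, j0) +
        (1 - wi) * wj * at(i0, j0 + 1) +
        wi * wj * at(i0 + 1, j0 + 1)
    matrix(out, n1, n2)
}

#' Flip an array along one axis
#'
#' @param x Numeric array (any number of dimensions) or matrix.
#' @param axis Axis index to reverse.
#' @return The flipped array.
#' @export
flip_axis <- function(x, axis) {
    d <- dim(x)
    stopifnot(axis >= 1L, axis <= length(d))
    idx <- rep(list(quote(expr = )), length(d))
    idx[[axis]] <- rev(seq_len(d[axis]))
    do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}
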