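#' Binary voxel volume
#'
#' Container for a segmented 3D micro-CT image: a binary array (foreground =
#' bone) plus its isotropic voxel edge length in micrometres.  All
#' morphometric estimators in the package operate on this class.
#'
#' @param data 3D array, logical or coercible to logical (0/1).  Foreground
#'   (`TRUE`) is bone.
#' @param voxel_um Isotropic voxel edge length, in micrometres (> 0).
#'   Anisotropic voxels are not supported.
#' @param ground_truth Optional named list of analytic reference values
#'   (attached by the phantom generators).
#'
#' @return An object of class `voxel_volume`: the logical array with
#'   attributes `voxel_um` and (optionally) `ground_truth`.
#' @examples
#' v <- voxel_volume(array(TRUE, c(8, 8, 8)), voxel_um = 10)
#' bv_tv(v)
#' @export
voxel_volume <- function(data, voxel_um, ground_truth = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.")
  }
  if (!is.logical(data)) {
    vals <- unique(as.vector(data))
    if (!all(vals %in% c(0, 1))) {
      abort("`data` must be binary (logical or 0/1).")
    }
    storage.mode(data) <- "logical"
  }
  if (anyNA(data)) abort("`data` must not contain NA.")
  if (!is.numeric(voxel_um) || length(voxel_um) != 1L || voxel_um <= 0) {
    abort("`voxel_um` must be a single positive number.")
  }
  if (max(dim(data)) < 8L) {
    abort("at least one dimension of `data` must be >= 8 voxels.")
  }
  structure(data,
            voxel_um = as.numeric(voxel_um),
            ground_truth = ground_truth,
            class = c("voxel_volume", "array"))
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, %.3g um/voxel\n",
              d[1], d[2], d[3], voxel_um(x)))
  cat(sprintf("  foreground fraction: %.4f\n", mean(x)))
  gt <- attr(x, "ground_truth")
  if (!is.null(gt)) {
    cat("  ground truth:", paste(names(gt), signif(unlist(gt), 4),
                                 sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname voxel_volume
#' @param x A `voxel_volume`.
#' @export
voxel_um <- function(x) {
  stopifnot(inherits(x, "voxel_volume"))
  attr(x, "voxel_um")
}

#' Complement (background) of a voxel volume
#'
#' Swaps foreground and background, preserving voxel metadata.  Used by the
#' trabecular-separation estimator, which applies the local-thickness
#' operator to the marrow phase.
#'
#' @param x A [voxel_volume()].
#' @return A `voxel_volume` with foreground and background exchanged.
#' @export
complement_volume <- function(x) {
  stopifnot(inherits(x, "voxel_volume"))
  voxel_volume(!unclass(x), voxel_um = voxel_um(x))
}

# strip class/attrs -> plain logical array
vv_array <- function(x) {
  a <- unclass(x)
  attr(a, "voxel_um") <- NULL
  attr(a, "ground_truth") <- NULL
  a
}

#' Plot a slice of a voxel volume
#'
#' @param object A [voxel_volume()].
#' @param slice Index of the axial (third-axis) slice; defaults to the middle.
#' @param ... Unused.
#' @return A ggplot object showing the binary slice.
#' @export
autoplot.voxel_volume <- function(object, slice = NULL, ...) {
  d <- dim(object)
  slice <- slice %||% ((d[3] + 1L) %/% 2L)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$bone <- as.vector(object[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$bone)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey95", `TRUE` = "grey20"),
                               guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("slice %d / %d", slice, d[3]),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
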