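#' Image volume with voxel spacing
#'
#' A minimal container for a 3-D scalar magnitude grid: a numeric array
#' carrying its voxel spacing in mm and a free-text modality tag. All
#' spatial operations in the package (distance transforms, layer depths,
#' gradient slopes) are computed in mm using this spacing.
#'
#' @param data 3-D numeric array.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param modality character tag, e.g. `"na-signal"` or `"concentration"`.
#' @return An object of class `na_volume`: the array with `spacing` and
#'   `modality` attributes.
#' @examples
#' v <- na_volume(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxel_spacing(v)
#' @export
na_volume <- function(data, spacing, modality = "na-signal") {
  if (length(dim(data)) != 3L) stop_data("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_data("`spacing` must be 3 positive voxel sizes in mm")
  structure(data, spacing = spacing, modality = modality, class = "na_volume")
}

#' @rdname na_volume
#' @param x an `na_volume` (or any array with a `spacing` attribute).
#' @export
voxel_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) stop_data("object carries no voxel spacing")
  sp
}

#' @export
print.na_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<na_volume> %s  %d x %d x %d voxels @ %s mm\n",
              attr(x, "modality"), d[1], d[2], d[3],
              paste(format(voxel_spacing(x)), collapse = " x ")))
  r <- range(x, na.rm = TRUE)
  cat(sprintf("  range [%.3g, %.3g]\n", r[1], r[2]))
  invisible(x)
}

# strip class/attrs for raw arithmetic
as_array <- function(x) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(x))
  a
}

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers over \pkg{RNifti}. `write_volume()` stores the voxel
#' spacing in the NIfTI header (pixdim, mm); `read_volume()` restores it.
#' Label volumes (masks) round-trip as integer grids.
#'
#' @param x an `na_volume` or 3-D array (with `spacing` if no `spacing`
#'   argument is given).
#' @param path file path, conventionally ending in `.nii.gz`.
#' @param spacing optional mm spacing override when `x` is a bare array.
#' @return `read_volume()` returns an `na_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @export
write_volume <- function(x, path, spacing = NULL) {
  sp <- if (is.null(spacing)) voxel_spacing(x) else as.numeric(spacing)
  img <- RNifti::asNifti(as_array(x))
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param modality modality tag to attach on read.
#' @export
read_volume <- function(path, modality = "na-signal") {
  img <- RNifti::readNifti(path)
  na_volume(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[seq_len(3)], modality = modality)
}
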