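#' 3-D grayscale volume with isotropic voxel size
#'
#' A thin container: a numeric or integer 3-D array in `(z, y, x)` axis order
#' (1-based indexing throughout the package) carrying its isotropic voxel
#' size in micrometres as an attribute.  The voxel size must always be given
#' explicitly; there is no assumed default, because the metric interpretation
#' of the mucus metrics depends on it.
#'
#' @param data 3-D array, axis order `(z, y, x)`.
#' @param voxel_size_um isotropic voxel edge length in micrometres (> 0).
#' @return `data` with class `volume3d` and a `voxel_size_um` attribute.
#' @export
volume3d <- function(data, voxel_size_um) {
  vol_dims(data)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      is.na(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be a single positive number")
  attr(data, "voxel_size_um") <- as.numeric(voxel_size_um)
  class(data) <- c("volume3d", class(data))
  data
}

#' Voxel size of a volume
#' @param x a [volume3d()] object.
#' @return voxel edge length in micrometres.
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size_um")
  if (is.null(vs)) stop("object carries no voxel_size_um attribute")
  vs
}
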