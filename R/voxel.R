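#' Voxel containers
#'
#' `voxel_image()` wraps a 3D numeric array of Hounsfield-unit intensities,
#' `label_map()` a 3D integer array of bone labels (0 = background), and
#' `binary_mask()` a 3D logical array. All three carry a voxel spacing in
#' micrometres (length-3, isotropic unless read otherwise from file headers).
#'
#' @param values 3D array (numeric, integer, or logical respectively).
#' @param spacing voxel spacing in micrometres; a scalar is recycled to
#'   length 3.
#' @return An object of class `voxel_image`, `label_map`, or `binary_mask`:
#'   a list with elements `values` and `spacing`.
#' @examples
#' img <- voxel_image(array(200, c(4, 4, 4)), spacing = 17.5)
#' dim(img$values)
#' @export
voxel_image <- function(values, spacing = 17.5) {
  values <- check_grid(values, "numeric")
  new_volume(values, spacing, "voxel_image")
}

#' @rdname voxel_image
#' @export
label_map <- function(values, spacing = 17.5) {
  values <- check_grid(values, "integer")
  if (any(values < 0L)) stop("label values must be >= 0 (0 = background)")
  new_volume(values, spacing, "label_map")
}

#' @rdname voxel_image
#' @export
binary_mask <- function(values, spacing = 17.5) {
  values <- check_grid(values, "logical")
  new_volume(values, spacing, "binary_mask")
}

new_volume <- function(values, spacing, class) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be a positive scalar or length-3 vector (micrometres)")
  }
  structure(list(values = values, spacing = spacing), class = class)
}

check_grid <- function(values, mode) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a 3D array")
  }
  if (any(dim(values) < 1L) || length(values) == 0L) stop("grid is empty")
  switch(mode,
    numeric = storage.mode(values) <- "double",
    integer = storage.mode(values) <- "integer",
    logical = storage.mode(values) <- "logical"
  )
  values
}

grid_dim <- function(obj) dim(obj$values)

is_isotropic <- function(obj) {
  diff(range(obj$spacing)) < 1e-9
}

# Scalar spacing for physical-distance operations; warns once per call site
# when the grid is anisotropic (distances then use the mean spacing).
iso_spacing <- function(obj, what = "distance computation") {
  if (!is_isotropic(obj)) {
    warning(sprintf("anisotropic spacing %s; %s uses mean spacing",
                    paste(signif(obj$spacing, 6), collapse = " x "), what))
  }
  mean(obj$spacing)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values))) {
    stop(sprintf("grid shape mismatch: %s vs %s",
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")))
  }
  invisible(TRUE)
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("<voxel_image> %s voxels, spacing %s um, range [%g, %g] HU\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 6), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  labs <- sort(unique(x$values[x$values > 0L]))
  cat(sprintf("<label_map> %s voxels, spacing %s um, %d labels\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 6), collapse = "x"), length(labs)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground\n",
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

#' Voxel counts per positive label
#'
#' @param lm a [label_map()].
#' @return named integer vector, names = label ids present in the map.
#' @export
label_counts <- function(lm) {
  stopifnot(inherits(lm, "label_map"))
  v <- lm$values
  pos <- v[v > 0L]
  if (length(pos) == 0L) return(setNames(integer(0), character(0)))
  tab <- tabulate(pos)
  keep <- which(tab > 0L)
  setNames(tab[keep], as.character(keep))
}
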