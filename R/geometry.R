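#' Construct a masked voxel grid
#'
#' A `BrainGeometry` records the 3-D grid shape, a binary inclusion mask, and
#' the integer grid coordinates of every in-mask voxel. All spatial maps and
#' trial matrices in the package are defined over the in-mask voxels of one
#' geometry, in mask scan order (x fastest, then y, then z; the natural order
#' of R arrays).
#'
#' @param shape integer triple, voxels per axis; every axis must be >= 4.
#' @param mask_rule `"ellipsoid"` keeps voxels inside the inscribed ellipsoid
#'   (voxel centers at cell midpoints), `"full"` keeps everything.
#' @param seed unused for the deterministic rules; kept so all generators share
#'   a signature.
#' @return object of class `BrainGeometry` with fields `shape`, `mask`
#'   (logical array), `n_voxels`, `coords` (`n_voxels x 3` integer matrix).
#' @examples
#' g <- generate_geometry(c(4, 4, 4), "full")
#' g$n_voxels # 64
#' @export
generate_geometry <- function(shape, mask_rule = c("ellipsoid", "full"),
                              seed = NULL) {
  mask_rule <- match.arg(mask_rule)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(!is.finite(shape))) {
    stop("shape must be an integer triple")
  }
  if (any(shape < 4)) {
    stop("degenerate shape: every axis must be >= 4 (got ",
         paste(shape, collapse = "x"), ")")
  }
  if (mask_rule == "full") {
    mask <- array(TRUE, shape)
  } else {
    # Inscribed ellipsoid: semi-axes shape/2, centered; voxel centers i - 1/2.
    cx <- (seq_len(shape[1]) - 0.5 - shape[1] / 2) / (shape[1] / 2)
    cy <- (seq_len(shape[2]) - 0.5 - shape[2] / 2) / (shape[2] / 2)
    cz <- (seq_len(shape[3]) - 0.5 - shape[3] / 2) / (shape[3] / 2)
    d2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
    mask <- d2 <= 1
  }
  coords <- which(mask, arr.ind = TRUE)
  colnames(coords) <- c("x", "y", "z")
  structure(
    list(shape = shape, mask = mask, n_voxels = nrow(coords),
         coords = coords, mask_rule = mask_rule),
    class = "BrainGeometry"
  )
}

#' @export
print.BrainGeometry <- function(x, ...) {
  cat(sprintf("BrainGeometry %s, rule '%s', %d in-mask voxels\n",
              paste(x$shape, collapse = "x"), x$mask_rule, x$n_voxels))
  invisible(x)
}

#' @keywords internal
#' @noRd
check_geometry <- function(geom) {
  stopifnot(inherits(geom, "BrainGeometry"),
            geom$n_voxels == sum(geom$mask),
            nrow(geom$coords) == geom$n_voxels)
  invisible(geom)
}

# Scatter a flat in-mask vector back into a full 3-D array (NA outside mask).
#' @keywords internal
#' @noRd
unmask <- function(values, geom) {
  a <- array(NA_real_, geom$shape)
  a[geom$mask] <- values
  a
}
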