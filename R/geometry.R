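#' Tissue geometry with an abrupt fiber-orientation border
#'
#' Builds a rectangular domain split by a straight vertical border at
#' `border_x`. In the left ("transverse") region the fibers run parallel to
#' the border (along y), so propagation in x is across fibers; in the right
#' ("longitudinal") region the fibers are orthogonal to the border, so
#' propagation in x is along fibers. An optional isotropic strip centred on
#' the border can be added to pin reentrant waves. A cable (1D) geometry is
#' obtained with `height = 0`.
#'
#' Coordinates are 0-based node indices with physical position `x = i * h`;
#' the border lies on the half-node plane between two columns, and a node
#' exactly on the border belongs to the left region.
#'
#' @param width,height domain size in mm (`height = 0` gives a 1D cable).
#' @param h grid spacing in mm (0.125 for 1D production, 0.25 for 2D).
#' @param border_x border coordinate in mm; must be strictly inside.
#' @param iso_strip_width total width (mm) of an isotropic strip centred on
#'   the border; 0 for none.
#' @return a `tissue_geometry` object.
#' @examples
#' cable_geometry()                  # 64 mm, h = 0.125, border at 32 mm
#' tissue_geometry(64, 32, h = 0.25) # 2D sheet
#' @export
tissue_geometry <- function(width, height = 0, h = 0.125,
                            border_x = width / 2, iso_strip_width = 0) {
  if (width <= 0 || h <= 0) abort("`width` and `h` must be positive")
  if (border_x <= 0 || border_x >= width)
    abort("`border_x` must be strictly inside the domain")
  if (iso_strip_width < 0) abort("`iso_strip_width` must be >= 0")
  nx <- as.integer(round(width / h))
  ny <- max(1L, as.integer(round(height / h)))
  structure(
    list(width = width, height = height, h = h, border_x = border_x,
         iso_strip_width = iso_strip_width, nx = nx, ny = ny),
    class = "tissue_geometry")
}

#' @rdname tissue_geometry
#' @param length cable length in mm.
#' @export
cable_geometry <- function(length = 64, h = 0.125, border_x = length / 2,
                           iso_strip_width = 0) {
  tissue_geometry(width = length, height = 0, h = h, border_x = border_x,
                  iso_strip_width = iso_strip_width)
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat(sprintf("<tissue_geometry> %g x %g mm (%d x %d nodes, h = %g mm)\n",
              x$width, x$height, x$nx, x$ny, x$h))
  cat(sprintf("  border at x = %g mm%s\n", x$border_x,
              if (x$iso_strip_width > 0)
                sprintf(", isotropic strip %g mm", x$iso_strip_width)
              else ""))
  invisible(x)
}

# region label for a physical x (mm): midpoint convention, border-left rule
region_of <- function(geom, x) {
  half <- geom$iso_strip_width / 2
  ifelse(half > 0 & abs(x - geom$border_x) <= half, "isotropic",
         ifelse(x <= geom$border_x, "transverse", "longitudinal"))
}

#' Per-node region labels
#'
#' @param geom a [tissue_geometry()].
#' @return tibble with `ix`, `iy` (0-based indices), `x`, `y` (mm) and
#'   `region` in transverse/longitudinal/isotropic.
#' @export
region_map <- function(geom) {
  ix <- rep(0:(geom$nx - 1), times = geom$ny)
  iy <- rep(0:(geom$ny - 1), each = geom$nx)
  x <- ix * geom$h
  tibble(ix = ix, iy = iy, x = x, y = iy * geom$h,
         region = region_of(geom, x))
}

#' Build the half-node conductivity map
#'
#' Assigns coupling coefficients to every internodal link. With fibers
#' parallel to the border on the left and orthogonal on the right, the
#' x-direction coefficient is sigma_perp on the left and sigma_par on the
#' right (mirrored for y); an isotropic strip uses sigma_par in both
#' directions. sigma_perp is derived from the anisotropy ratio as
#' `sigma_par / AR^2`, so AR equals the ratio of conduction velocities
#' along and across fibers. Each link takes the region of its midpoint.
#'
#' @param geom a [tissue_geometry()].
#' @param AR anisotropy ratio (>= 1; fiber orientation is encoded by the
#'   region map, not by AR).
#' @param sigma_par along-fiber coupling coefficient (mm^2/ms).
#' @return a `conductivity_map` with matrices `sigx` ((nx-1) x ny) and
#'   `sigy` (nx x (ny-1)) and attributes `AR`, `sigma_par`, `sigma_perp`.
#' @examples
#' g <- cable_geometry()
#' cm <- build_conductivity(g, AR = 2)
#' attr(cm, "sigma_perp")   # 0.0385
#' @export
build_conductivity <- function(geom, AR, sigma_par = 0.154) {
  stopifnot(inherits(geom, "tissue_geometry"))
  if (!is.numeric(AR) || length(AR) != 1 || AR < 1)
    abort("`AR` must be >= 1 (orientation is encoded by the region map)")
  if (sigma_par <= 0) abort("`sigma_par` must be positive")
  sigma_perp <- sigma_par / AR^2
  nx <- geom$nx; ny <- geom$ny; h <- geom$h

  # x links between columns i and i+1 (0-based), midpoint (i + 1/2) h
  xmid <- ((0:(nx - 2)) + 0.5) * h
  regx <- region_of(geom, xmid)
  sx_col <- ifelse(regx == "transverse", sigma_perp,
                   ifelse(regx == "longitudinal", sigma_par, sigma_par))
  sigx <- matrix(rep(sx_col, ny), nrow = nx - 1, ncol = ny)

  # y links within a column: region of the column's node position
  if (ny > 1) {
    xnode <- (0:(nx - 1)) * h
    regy <- region_of(geom, xnode)
    sy_col <- ifelse(regy == "transverse", sigma_par,
                     ifelse(regy == "longitudinal", sigma_perp, sigma_par))
    sigy <- matrix(rep(sy_col, ny - 1), nrow = nx, ncol = ny - 1)
  } else {
    sigy <- matrix(numeric(0), nrow = nx, ncol = 0)
  }
  structure(list(sigx = sigx, sigy = sigy),
            AR = AR, sigma_par = sigma_par, sigma_perp = sigma_perp,
            class = "conductivity_map")
}

#' @export
print.conductivity_map <- function(x, ...) {
  cat(sprintf("<conductivity_map> AR = %g, sigma_par = %g, sigma_perp = %g mm^2/ms\n",
              attr(x, "AR"), attr(x, "sigma_par"), attr(x, "sigma_perp")))
  invisible(x)
}

node_index <- function(geom, x, y = 0) {
  ix <- as.integer(round(x / geom$h))
  iy <- as.integer(round(y / geom$h))
  ix <- pmin(pmax(ix, 0L), geom$nx - 1L)
  iy <- pmin(pmax(iy, 0L), geom$ny - 1L)
  iy * geom$nx + ix
}
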