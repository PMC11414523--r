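# Wire paths and sampled complex vector electric fields.
#
# A wire path is an ordered polyline whose first point is the lead tip;
# arc length l in the voltage integral is measured from there. Fields
# are complex 3-vectors sampled on a regular (rectilinear) grid and
# interpolated trilinearly, component by component, with no
# extrapolation outside the grid bounds. Coordinates are right-handed
# with z along the scanner bore axis; all lengths in metres.

#' Wire path through the field domain
#'
#' @param points Numeric matrix with >= 2 rows and columns x, y, z in m;
#'   the first row is the lead tip. Consecutive points must be distinct.
#' @return An object of class `wire_path`.
#' @seealso [straight_path()], [path_segments()], [total_length()]
#' @export
wire_path <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 2)
    stop("`points` must be an n x 3 matrix with n >= 2", call. = FALSE)
  if (!is.numeric(points) || any(!is.finite(points)))
    stop("`points` must be finite numeric coordinates", call. = FALSE)
  seg <- diff(points)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0))
    stop("consecutive path points must be distinct", call. = FALSE)
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points), class = "wire_path")
}

#' @export
print.wire_path <- function(x, ...) {
  cat(sprintf("<wire_path> %d points, arc length %.4f m\n",
              nrow(x$points), total_length(x)))
  invisible(x)
}

#' Segment decomposition of a wire path
#'
#' @param path A [wire_path()].
#' @return A list with `midpoints` (matrix), `unit` (unit segment
#'   vectors), `length` (segment lengths, m) and `mid_arclength` (arc
#'   length of each segment midpoint from the lead tip, m).
#' @export
path_segments <- function(path) {
  stopifnot(inherits(path, "wire_path"))
  p <- path$points
  seg <- diff(p)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  list(midpoints = (p[-nrow(p), , drop = FALSE] + p[-1, , drop = FALSE]) / 2,
       unit = seg / len,
       length = len,
       mid_arclength = cum[-length(cum)] + len / 2)
}

#' Total arc length of a wire path
#'
#' @param path A [wire_path()].
#' @return Length in m.
#' @export
total_length <- function(path) {
  stopifnot(inherits(path, "wire_path"))
  sum(sqrt(rowSums(diff(path$points)^2)))
}

#' Evenly sampled straight wire path
#'
#' @param start Length-3 start point (the lead tip), m.
#' @param direction Length-3 direction vector (any nonzero magnitude;
#'   normalised internally).
#' @param length Total path length in m, > 0.
#' @param step Sampling step in m, > 0; the end point is always
#'   included so the final segment may be shorter.
#' @return A [wire_path()].
#' @examples
#' straight_path(c(0, 0, 0), c(0, 0, 1), 0.5, 1e-3)
#' @export
straight_path <- function(start, direction, length, step) {
  stopifnot(length(start) == 3, length(direction) == 3)
  if (!(length > 0) || !(step > 0))
    stop("`length` and `step` must be > 0", call. = FALSE)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("`direction` must be a nonzero vector", call. = FALSE)
  u <- direction / nrm
  s <- seq(0, length, by = step)
  if (s[base::length(s)] < length) s <- c(s, length)
  wire_path(outer(s, u) + matrix(start, nrow = base::length(s), ncol = 3,
                                 byrow = TRUE))
}

#' Subdivide long path segments
#'
#' Inserts evenly spaced points into any segment longer than
#' `max_segment`, leaving the geometry unchanged.
#'
#' @param path A [wire_path()].
#' @param max_segment Maximum allowed segment length, m.
#' @return A [wire_path()].
#' @export
refine_path <- function(path, max_segment) {
  stopifnot(inherits(path, "wire_path"), max_segment > 0)
  p <- path$points
  seg <- diff(p)
  len <- sqrt(rowSums(seg^2))
  if (all(len <= max_segment)) return(path)
  pieces <- lapply(seq_len(nrow(seg)), function(i) {
    n <- ceiling(len[i] / max_segment)
    t <- seq(0, 1, length.out = n + 1)[-(n + 1)]
    outer(t, seg[i, ]) + matrix(p[i, ], nrow = n, ncol = 3, byrow = TRUE)
  })
  wire_path(rbind(do.call(rbind, pieces), p[nrow(p), ]))
}

#' Complex vector E-field on a regular grid
#'
#' @param x,y,z Strictly increasing axis coordinate vectors, m.
#' @param Ex,Ey,Ez Complex arrays of dimension
#'   `c(length(x), length(y), length(z))`, V/m.
#' @return An object of class `efield_grid`.
#' @export
efield_grid <- function(x, y, z, Ex, Ey, Ez) {
  for (ax in list(x, y, z)) {
    if (length(ax) < 2 || any(diff(ax) <= 0))
      stop("grid axes must be strictly increasing with >= 2 points",
           call. = FALSE)
  }
  dm <- c(length(x), length(y), length(z))
  for (E in list(Ex, Ey, Ez)) {
    if (!identical(dim(E), as.integer(dm)))
      stop("field array dimensions must match the axis lengths", call. = FALSE)
  }
  structure(list(x = x, y = y, z = z,
                 Ex = Ex + 0i, Ey = Ey + 0i, Ez = Ez + 0i),
            class = "efield_grid")
}

#' @export
print.efield_grid <- function(x, ...) {
  cat(sprintf("<efield_grid> %d x %d x %d nodes, peak |Ez| = %.3g V/m\n",
              length(x$x), length(x$y), length(x$z), max(Mod(x$Ez))))
  invisible(x)
}

# Fractional index of query values q on a strictly increasing axis;
# errors (naming the coordinate) when outside the axis range.
.axis_locate <- function(ax, q, name) {
  if (any(q < ax[1] - 1e-12) || any(q > ax[length(ax)] + 1e-12)) {
    bad <- q[which(q < ax[1] - 1e-12 | q > ax[length(ax)] + 1e-12)[1]]
    stop(sprintf("query point outside field domain: %s = %g m (grid spans [%g, %g])",
                 name, bad, ax[1], ax[length(ax)]), call. = FALSE)
  }
  i <- findInterval(q, ax, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(ax) - 1L)
  list(i = i, t = (q - ax[i]) / (ax[i + 1] - ax[i]))
}

# Trilinear interpolation of one complex component array at points
# (n x 3 matrix). Exact for fields affine in (x, y, z).
.trilinear <- function(field, arr, pts) {
  lx <- .axis_locate(field$x, pts[, 1], "x")
  ly <- .axis_locate(field$y, pts[, 2], "y")
  lz <- .axis_locate(field$z, pts[, 3], "z")
  ix <- lx$i; iy <- ly$i; iz <- lz$i
  tx <- lx$t; ty <- ly$t; tz <- lz$t
  idx <- function(dx, dy, dz) cbind(ix + dx, iy + dy, iz + dz)
  c000 <- arr[idx(0, 0, 0)]; c100 <- arr[idx(1, 0, 0)]
  c010 <- arr[idx(0, 1, 0)]; c110 <- arr[idx(1, 1, 0)]
  c001 <- arr[idx(0, 0, 1)]; c101 <- arr[idx(1, 0, 1)]
  c011 <- arr[idx(0, 1, 1)]; c111 <- arr[idx(1, 1, 1)]
  c00 <- c000 * (1 - tx) + c100 * tx
  c10 <- c010 * (1 - tx) + c110 * tx
  c01 <- c001 * (1 - tx) + c101 * tx
  c11 <- c011 * (1 - tx) + c111 * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  c0 * (1 - tz) + c1 * tz
}

#' Interpolate a complex E-field at arbitrary points
#'
#' Trilinear interpolation of each complex component independently; no
#' extrapolation (points outside the grid raise an error naming the
#' offending coordinate).
#'
#' @param field An [efield_grid()].
#' @param points n x 3 matrix of query points, m.
#' @return n x 3 complex matrix of field vectors, V/m.
#' @export
interpolate_field <- function(field, points) {
  stopifnot(inherits(field, "efield_grid"))
  points <- matrix(points, ncol = 3)
  cbind(.trilinear(field, field$Ex, points),
        .trilinear(field, field$Ey, points),
        .trilinear(field, field$Ez, points))
}

#' Tangential field component along a wire path
#'
#' Scalar product of the (interpolated) complex field vector with the
#' unit segment direction at each segment midpoint:
#' `Et = E . dl / |dl|`. Accepts a constant field as a complex length-3
#' vector.
#'
#' @param field An [efield_grid()] or a complex length-3 vector (V/m).
#' @param path A [wire_path()] lying inside the field domain.
#' @return Complex vector, one tangential component per path segment.
#' @export
tangential_component <- function(field, path) {
  stopifnot(inherits(path, "wire_path"))
  seg <- path_segments(path)
  if (is.numeric(field) || is.complex(field)) {
    if (length(field) != 3)
      stop("a constant field must be a length-3 (complex) vector", call. = FALSE)
    return(as.complex((seg$unit + 0i) %*% (field + 0i)))
  }
  stopifnot(inherits(field, "efield_grid"))
  ev <- interpolate_field(field, seg$midpoints)
  rowSums(ev * seg$unit)
}

#' Specification of a synthetic body-coil-like E-field
#'
#' Parametric surrogate for the electric field of a body transmit coil
#' in a torso phantom: the dominant component is `Ez`, smallest on the
#' phantom midline and growing linearly towards the lateral edges, with
#' a smooth cosine taper along the bore axis, a linear phase advance
#' along z, and small transverse components.
#'
#' @param amplitude Peak `|Ez|` in V/m (>= 0).
#' @param lateral_scale Lateral half-width of the phantom, m (> 0).
#' @param longitudinal_period Spatial period of the complex phase along
#'   z, m (> 0).
#' @param half_widths Length-3 phantom half-widths (x, y, z), m (> 0).
#' @param floor Fraction of `amplitude` remaining on the midline
#'   (default 0.15).
#' @param transverse_fraction Peak `|Ex|`, `|Ey|` relative to
#'   `amplitude` (default 0.08, <= 0.1).
#' @return An object of class `synthetic_field_spec`.
#' @export
synthetic_field_spec <- function(amplitude = 100,
                                 lateral_scale = 0.21,
                                 longitudinal_period = 0.65,
                                 half_widths = c(0.21, 0.05, 0.325),
                                 floor = 0.15,
                                 transverse_fraction = 0.08) {
  if (!(amplitude >= 0)) stop("`amplitude` must be >= 0", call. = FALSE)
  if (!(lateral_scale > 0) || !(longitudinal_period > 0) ||
      any(!(half_widths > 0)))
    stop("scales and half-widths must be > 0", call. = FALSE)
  structure(list(amplitude = amplitude, lateral_scale = lateral_scale,
                 longitudinal_period = longitudinal_period,
                 half_widths = half_widths, floor = floor,
                 transverse_fraction = transverse_fraction),
            class = "synthetic_field_spec")
}

#' Generate a synthetic body-coil-like field on a grid
#'
#' Builds an [efield_grid()] from a [synthetic_field_spec()]:
#' `Ez(x, y, z) = E0 (floor + (1 - floor) |x| / sx) cos(pi z / (2 sz))
#' e^{2 pi i z / P}` with small in-phase transverse components. By
#' construction `|Ez|` is minimal on the `x = 0` midline and maximal at
#' the lateral edge of the slab at `z = 0`.
#'
#' @param spec A [synthetic_field_spec()].
#' @param x,y,z Axis coordinate vectors, m.
#' @return An [efield_grid()].
#' @export
synthetic_body_coil_field <- function(spec, x, y, z) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  sx <- spec$half_widths[1]; sz <- spec$half_widths[3]
  dims <- c(length(x), length(y), length(z))
  X <- array(rep(x, times = dims[2] * dims[3]), dim = dims)
  Z <- array(rep(z, each = dims[1] * dims[2]), dim = dims)
  lat <- spec$floor + (1 - spec$floor) * pmin(abs(X) / sx, 1)
  taper <- cos(pi * Z / (2 * sz))
  taper[abs(Z) > sz] <- 0
  phase <- exp(2i * pi * Z / spec$longitudinal_period)
  Ez <- spec$amplitude * lat * taper * phase
  tf <- spec$transverse_fraction * spec$amplitude
  Ex <- tf * (X / sx) * taper * phase
  Ey <- 0.25 * tf * taper * phase
  efield_grid(x, y, z, Ex, Ey, Ez)
}

#' Write / read an E-field grid as delimited text
#'
#' One node per line in x-fastest order with header columns
#' `x_m y_m z_m ReEx ImEx ReEy ImEy ReEz ImEz`, chosen over a binary
#' format for inspectability.
#'
#' @param field An [efield_grid()].
#' @param path File path.
#' @return `path` (write) or an [efield_grid()] (read).
#' @export
write_efield_grid <- function(field, path) {
  stopifnot(inherits(field, "efield_grid"))
  g <- expand.grid(x = field$x, y = field$y, z = field$z,
                   KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(x_m = g$x, y_m = g$y, z_m = g$z,
                   ReEx = as.vector(Re(field$Ex)), ImEx = as.vector(Im(field$Ex)),
                   ReEy = as.vector(Re(field$Ey)), ImEy = as.vector(Im(field$Ey)),
                   ReEz = as.vector(Re(field$Ez)), ImEz = as.vector(Im(field$Ez)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_efield_grid
#' @export
read_efield_grid <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("x_m", "y_m", "z_m", "ReEx", "ImEx", "ReEy", "ImEy", "ReEz", "ImEz")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("E-field grid file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- sort(unique(df$x_m)); y <- sort(unique(df$y_m)); z <- sort(unique(df$z_m))
  dm <- c(length(x), length(y), length(z))
  if (nrow(df) != prod(dm))
    stop("E-field grid file does not cover a full regular grid", call. = FALSE)
  # restore x-fastest order regardless of row order on disk
  o <- order(df$z_m, df$y_m, df$x_m)
  df <- df[o, ]
  mk <- function(re, im) array(complex(real = re, imaginary = im), dim = dm)
  efield_grid(x, y, z, mk(df$ReEx, df$ImEx), mk(df$ReEy, df$ImEy),
              mk(df$ReEz, df$ImEz))
}

#' Write / read a wire path as CSV
#'
#' Columns `x_m, y_m, z_m`, one point per row, lead tip first.
#'
#' @param path_obj A [wire_path()].
#' @param path File path.
#' @return `path` (write) or a [wire_path()] (read).
#' @export
write_wire_path <- function(path_obj, path) {
  stopifnot(inherits(path_obj, "wire_path"))
  df <- as.data.frame(path_obj$points)
  names(df) <- c("x_m", "y_m", "z_m")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wire_path
#' @export
read_wire_path <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_m", "y_m", "z_m")
  if (!all(need %in% names(df)))
    stop("wire path CSV must have columns x_m, y_m, z_m", call. = FALSE)
  wire_path(as.matrix(df[, need]))
}
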