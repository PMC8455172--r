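#' Hexagonal lattice geometry
#'
#' Constructs the geometry of the two-dimensional hexagonal lattice on which
#' cells are simulated. Each lattice site has diameter `delta` (the average
#' cell diameter, 20 micrometres by default) and every pair of neighbouring
#' site centres is exactly `delta` apart: within a row sites are spaced
#' `delta` in x, rows are spaced `delta * sqrt(3) / 2` in y, and even rows are
#' offset by `delta / 2`. The default domain matches the imaged region of the
#' WM983C scratch-assay experiment, 1309.09 x 1745.35 micrometres.
#'
#' Site centres are addressed by 1-based (row, column) indices `(i, j)` with
#' Cartesian coordinates (in micrometres)
#' \deqn{x = (j - 1)\Delta \ (i\ \mathrm{odd}), \quad
#'       x = (j - 1/2)\Delta \ (i\ \mathrm{even}), \quad
#'       y = i\,\Delta\sqrt{3}/2.}
#'
#' @param width Domain width in micrometres (x extent).
#' @param height Domain height in micrometres (y extent).
#' @param delta Lattice site diameter in micrometres.
#' @return An object of class `hex_geometry`: a list with fields `delta`,
#'   `width`, `height`, `n_rows`, `n_cols`.
#' @examples
#' geom <- hex_geometry()
#' geom$n_rows
#' @export
hex_geometry <- function(width = 1309.09, height = 1745.35, delta = 20) {
  stopifnot(is.numeric(delta), length(delta) == 1, delta > 0,
            is.numeric(width), width > 0, is.numeric(height), height > 0)
  row_spacing <- delta * sqrt(3) / 2
  n_rows <- max(1L, as.integer(floor(height / row_spacing + 1e-9)))
  # largest column count whose even-row centres (offset delta/2) stay in-domain
  n_cols <- max(1L, as.integer(floor(width / delta + 0.5 + 1e-9)))
  structure(
    list(delta = delta, width = width, height = height,
         n_rows = n_rows, n_cols = n_cols),
    class = "hex_geometry"
  )
}

#' @export
print.hex_geometry <- function(x, ...) {
  cat(sprintf(
    "<hex_geometry> %.2f x %.2f um, delta = %g um (%d rows x %d cols, %d sites)\n",
    x$width, x$height, x$delta, x$n_rows, x$n_cols,
    x$n_rows * x$n_cols))
  invisible(x)
}

in_domain <- function(i, j, geom) {
  i >= 1L & i <= geom$n_rows & j >= 1L & j <= geom$n_cols
}

# round-half-up: ties toward +Inf so the index map is deterministic
round_half_up <- function(x) floor(x + 0.5)

#' Convert lattice indices to Cartesian coordinates
#'
#' Maps (row, column) lattice indices to the Cartesian coordinates of the site
#' centres in micrometres. Odd rows start at x = 0; even rows are offset by
#' half a site diameter.
#'
#' @param sites A data frame with integer columns `i` (row) and `j` (column).
#' @param geom A [hex_geometry()].
#' @return A tibble with columns `i`, `j`, `x`, `y` (micrometres).
#' @examples
#' site_to_xy(data.frame(i = 1, j = 1), hex_geometry())
#' @export
site_to_xy <- function(sites, geom) {
  stopifnot(inherits(geom, "hex_geometry"),
            all(c("i", "j") %in% names(sites)))
  i <- as.integer(sites$i); j <- as.integer(sites$j)
  if (!all(in_domain(i, j, geom))) {
    stop("site_to_xy(): some (i, j) indices lie outside the lattice domain",
         call. = FALSE)
  }
  d <- geom$delta
  x <- ifelse(i %% 2L == 0L, (j - 0.5) * d, (j - 1) * d)
  y <- i * d * sqrt(3) / 2
  tibble::tibble(i = i, j = j, x = x, y = y)
}

#' Convert Cartesian coordinates to lattice indices
#'
#' Snaps points in micrometres onto the lattice by inverting the site-centre
#' map: the row is the nearest row index from y, then the column is the
#' nearest column in that row (parity-aware offset). Rounding ties go toward
#' +Inf so the map is deterministic. Exact site centres round-trip exactly.
#'
#' @param points A data frame with numeric columns `x` and `y` (micrometres).
#' @param geom A [hex_geometry()].
#' @return A tibble with columns `x`, `y`, `i`, `j`.
#' @examples
#' xy_to_site(data.frame(x = 0, y = 17.32), hex_geometry())
#' @export
xy_to_site <- function(points, geom) {
  stopifnot(inherits(geom, "hex_geometry"),
            all(c("x", "y") %in% names(points)))
  x <- as.numeric(points$x); y <- as.numeric(points$y)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("xy_to_site(): coordinates must be finite", call. = FALSE)
  }
  d <- geom$delta
  i <- as.integer(round_half_up(2 * y / (sqrt(3) * d)))
  j <- as.integer(ifelse(i %% 2L == 0L,
                         round_half_up(x / d + 0.5),
                         round_half_up(x / d + 1)))
  bad <- !in_domain(i, j, geom)
  if (any(bad)) {
    stop(sprintf(
      "xy_to_site(): %d point(s) map outside the lattice domain (first at x = %g, y = %g)",
      sum(bad), x[which(bad)[1]], y[which(bad)[1]]), call. = FALSE)
  }
  tibble::tibble(x = x, y = y, i = i, j = j)
}

#' Hexagonal neighbourhood of a lattice site
#'
#' Returns the in-domain nearest neighbours of a site: up to six sites at
#' Euclidean distance exactly `delta`. Sites on the domain boundary have fewer
#' than six neighbours; attempts to move or place daughters outside the domain
#' are aborted by the simulator, which realises zero-net-flux boundaries.
#'
#' @param i,j Scalar row and column index of the site.
#' @param geom A [hex_geometry()].
#' @return A tibble with columns `i`, `j` of neighbouring sites.
#' @examples
#' nrow(hex_neighbours(5, 5, hex_geometry()))  # interior site: 6
#' @export
hex_neighbours <- function(i, j, geom) {
  stopifnot(inherits(geom, "hex_geometry"), length(i) == 1, length(j) == 1)
  i <- as.integer(i); j <- as.integer(j)
  if (!in_domain(i, j, geom)) {
    stop("hex_neighbours(): site outside the lattice domain", call. = FALSE)
  }
  off <- neighbour_offsets(i)
  ni <- i + off$di; nj <- j + off$dj
  keep <- in_domain(ni, nj, geom)
  tibble::tibble(i = ni[keep], j = nj[keep])
}

# row-parity dependent index offsets of the six hexagonal neighbours
neighbour_offsets <- function(i) {
  if (i %% 2L == 0L) {
    list(di = c(0L, 0L, -1L, -1L, 1L, 1L), dj = c(-1L, 1L, 0L, 1L, 0L, 1L))
  } else {
    list(di = c(0L, 0L, -1L, -1L, 1L, 1L), dj = c(-1L, 1L, -1L, 0L, -1L, 0L))
  }
}
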