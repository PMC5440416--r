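#' Map grid geometry
#'
#' A rectangular grid of `nx` by `ny` neurons, optionally with toroidal
#' (wrap-around) boundary conditions.  Neuron positions are 1-based `(x, y)`
#' pairs; the linear neuron index runs row-major with x fastest,
#' `index = (y - 1) * nx + x`.
#'
#' @param nx,ny neuron counts in the x and y direction (>= 1).
#' @param toroid logical; wrap both axes when `TRUE`.
#' @return an object of class `cpann_grid`.
#' @export
grid_geometry <- function(nx, ny, toroid = FALSE) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 1 || ny < 1)
    stop("nx and ny must be integers >= 1", call. = FALSE)
  structure(list(nx = nx, ny = ny, toroid = isTRUE(toroid)),
            class = "cpann_grid")
}

#' @export
print.cpann_grid <- function(x, ...) {
  cat(sprintf("%dx%d %s grid\n", x$nx, x$ny,
              if (x$toroid) "toroidal" else "planar"))
  invisible(x)
}

n_neurons <- function(g) g$nx * g$ny

# all neuron positions in linear order (x fastest)
grid_positions <- function(g) {
  cbind(x = rep(seq_len(g$nx), times = g$ny),
        y = rep(seq_len(g$ny), each = g$nx))
}

position_index <- function(g, pos) (pos[2] - 1L) * g$nx + pos[1]

index_position <- function(g, idx) {
  c(x = ((idx - 1L) %% g$nx) + 1L, y = ((idx - 1L) %/% g$nx) + 1L)
}

check_on_grid <- function(g, pos) {
  if (length(pos) != 2 || anyNA(pos) ||
      pos[1] < 1 || pos[1] > g$nx || pos[2] < 1 || pos[2] > g$ny)
    stop("position (", paste(pos, collapse = ","), ") is off the ",
         g$nx, "x", g$ny, " grid", call. = FALSE)
  invisible(pos)
}

#' Topological (ring) distance between two neurons
#'
#' The Chebyshev ring index: square rings around a neuron, so the eight
#' immediate neighbours are all at distance 1.  On a toroidal grid each axis
#' wraps, `d = min(|delta|, n - |delta|)`.  This is the distance the
#' neighbourhood correction radius is measured in.
#'
#' @param g a [grid_geometry()].
#' @param a,b positions, `c(x, y)`, 1-based.
#' @return integer ring index >= 0.
#' @export
topological_distance <- function(g, a, b) {
  check_on_grid(g, a); check_on_grid(g, b)
  dx <- abs(a[1] - b[1]); dy <- abs(a[2] - b[2])
  if (g$toroid) {
    dx <- min(dx, g$nx - dx)
    dy <- min(dy, g$ny - dy)
  }
  as.integer(max(dx, dy))
}

# ring distance from one neuron (linear index) to every neuron, vectorized
ring_distances_from <- function(g, idx) {
  pos <- grid_positions(g)
  p <- index_position(g, idx)
  dx <- abs(pos[, 1] - p[1]); dy <- abs(pos[, 2] - p[2])
  if (g$toroid) {
    dx <- pmin(dx, g$nx - dx)
    dy <- pmin(dy, g$ny - dy)
  }
  as.integer(pmax(dx, dy))
}

#' Triangular neighbourhood correction factor
#'
#' Full correction (factor 1) at the winning neuron, decreasing linearly
#' with the ring index and reaching 0 beyond the current correction radius:
#' `a(ring) = max(0, 1 - ring / (radius_now + 1))`.
#'
#' @param ring ring index (>= 0) of the neuron being corrected.
#' @param radius_now current correction radius (>= 0).
#' @param kind neighbourhood shape; only `"triangular"` is implemented.
#' @return correction factor in `[0, 1]`.
#' @export
neighborhood_factor <- function(ring, radius_now, kind = "triangular") {
  kind <- match.arg(kind, "triangular")
  if (any(ring < 0) || radius_now < 0)
    stop("ring and radius_now must be >= 0", call. = FALSE)
  f <- 1 - ring / (radius_now + 1)
  f[ring > radius_now] <- 0
  pmax(f, 0)
}
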