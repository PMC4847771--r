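#' Toroidal arena geometry
#'
#' The arena is a cube of side `L` with periodic boundaries on all three axes.
#' `wrap_position()` maps coordinates into the half-open fundamental cell
#' `[0, L)` (a coordinate of exactly `L` wraps to 0).  `torus_distance()` is
#' the minimal-image Euclidean distance used for neighbour detection and
#' signal attenuation; `raw_distance()` is the plain (non-wrapped) Euclidean
#' distance used by the distance-to-goal statistic.
#'
#' @param p,a,b Numeric length-3 vectors, or matrices with one point per row.
#' @param L Arena side length.
#'
#' @return `wrap_position()` returns coordinates of the same shape as `p`;
#'   the distance functions return a numeric vector (one value per row pair).
#' @examples
#' wrap_position(c(601, 0, -1), 600)
#' torus_distance(c(1, 0, 0), c(599, 0, 0), 600)
#' raw_distance(c(0, 0, 0), c(600, 0, 0))
#' @export
wrap_position <- function(p, L) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  if (!all(is.finite(p))) stop("non-finite coordinate in `p`")
  p %% L
}

#' @rdname wrap_position
#' @export
torus_distance <- function(a, b, L) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("non-finite coordinate")
  }
  d <- torus_displacement(a, b, L)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

#' Minimal-image displacement on the torus
#'
#' Displacement vector `to - from` reduced to the minimal image, each
#' component in `[-L/2, L/2]`.
#'
#' @param from,to Numeric length-3 vectors or matrices (one point per row).
#' @param L Arena side length.
#' @return Same shape as the broader of `from` / `to`.
#' @export
torus_displacement <- function(from, to, L) {
  d <- to - from
  d - L * round(d / L)
}

#' @rdname wrap_position
#' @export
raw_distance <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("non-finite coordinate")
  }
  d <- b - a
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

#' All pairwise minimal-image distances
#'
#' @param pos `n x 3` matrix of wrapped positions.
#' @param L Arena side length.
#' @return `n x n` symmetric matrix of toroidal distances.
#' @export
pairwise_torus_distance <- function(pos, L) {
  stopifnot(is.matrix(pos), ncol(pos) == 3L)
  d2 <- 0
  for (k in 1:3) {
    dk <- outer(pos[, k], pos[, k], "-")
    dk <- dk - L * round(dk / L)
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}
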