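SECTOR_NAMES <- c("front", "rear", "left", "right", "top", "bottom")

#' Body frame of a moving agent
#'
#' Right-handed orthonormal frame attached to the heading: `forward` is the
#' unit velocity, `up` is the world z axis orthogonalised against `forward`
#' (falling back to the world x axis when the heading is parallel to z), and
#' `right = forward x up`.  Roll is not modelled.
#'
#' @param v Velocity vector (length 3, non-zero).
#' @return A list of class `body_frame` with unit vectors `forward`, `up`,
#'   `right`.
#' @examples
#' body_frame(c(1, 0, 0))
#' @export
body_frame <- function(v) {
  if (length(v) != 3L || any(!is.finite(v))) stop("`v` must be 3 finite values")
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero velocity has no body frame")
  f <- v / n
  up <- c(0, 0, 1) - f[3] * f
  nu <- sqrt(sum(up^2))
  if (nu < 1e-8) {
    up <- c(1, 0, 0) - f[1] * f
    nu <- sqrt(sum(up^2))
  }
  up <- up / nu
  right <- c(f[2] * up[3] - f[3] * up[2],
             f[3] * up[1] - f[1] * up[3],
             f[1] * up[2] - f[2] * up[1])
  structure(list(forward = f, up = up, right = right), class = "body_frame")
}

#' Sensor sector of a direction
#'
#' Assigns a unit direction to one of the six body-mounted sensors (front,
#' rear, left, right, top, bottom) by the largest dot product with the
#' corresponding sector axis; exact ties resolve to the first sector in that
#' fixed order.
#'
#' @param direction Unit direction vector from receiver to source.
#' @param frame [body_frame()] of the receiver.
#' @return Integer sector index in 1..6, named.
#' @export
sector_of <- function(direction, frame) {
  df <- sum(direction * frame$forward)
  dr <- sum(direction * frame$right)
  du <- sum(direction * frame$up)
  dots <- c(front = df, rear = -df, left = -dr, right = dr,
            top = du, bottom = -du)
  idx <- which.max(dots)  # which.max takes the first maximum: fixed tie-break
  structure(as.integer(idx), names = SECTOR_NAMES[idx])
}

#' Directional signal sensing
#'
#' Every emitter within the sensing radius (minimal-image/toroidal distance
#' `d` in `(0, 100]` by default) contributes `intensity / max(d, sense_floor)`
#' to the sector sensor closest to its minimal-image direction; each sector is
#' finally clipped to \[0, 1\].  Emitters beyond the radius are ignored.  The
#' receiver itself must not be in the emitter list.
#'
#' @param receiver_pos,receiver_vel Position and velocity of the receiver.
#' @param emitter_pos Matrix (`m x 3`) of emitter positions (may have 0 rows).
#' @param emitter_sig Numeric vector of emitted intensities in \[0, 1\].
#' @param world [world_config()].
#' @return Named numeric vector of 6 sector readings in \[0, 1\].
#' @examples
#' w <- world_config()
#' sense(c(0, 0, 0), c(1, 0, 0), matrix(c(50, 0, 0), 1), 0.5, w)
#' @export
sense <- function(receiver_pos, receiver_vel, emitter_pos, emitter_sig,
                  world = world_config()) {
  if (is.null(emitter_pos) || NROW(emitter_pos) == 0L) {
    return(structure(numeric(6), names = SECTOR_NAMES))
  }
  emitter_pos <- matrix(emitter_pos, ncol = 3)
  stopifnot(nrow(emitter_pos) == length(emitter_sig),
            all(emitter_sig >= 0), all(emitter_sig <= 1))
  frame <- body_frame(receiver_vel)
  reading <- numeric(6)
  disp <- torus_displacement(matrix(receiver_pos, nrow(emitter_pos), 3,
                                    byrow = TRUE),
                             emitter_pos, world$arena_side)
  d <- sqrt(rowSums(disp^2))
  for (j in seq_along(d)) {
    if (d[j] > world$sensing_radius || emitter_sig[j] <= 0) next
    if (d[j] < 1e-12) {
      # coincident emitter: direction undefined, assign to front by convention
      reading[1L] <- reading[1L] + emitter_sig[j] / world$sense_floor
      next
    }
    s <- sector_of(disp[j, ] / d[j], frame)
    reading[s] <- reading[s] + emitter_sig[j] / max(d[j], world$sense_floor)
  }
  structure(pmin(reading, 1), names = SECTOR_NAMES)
}

#' Sensor readings for a whole population
#'
#' Applies [sense()] to every agent, each agent receiving from all others.
#' Used by the reference simulation step; the compiled engine implements the
#' same computation.
#'
#' @param pos `n x 3` matrix of positions.
#' @param vel `n x 3` matrix of velocities.
#' @param sig Numeric vector of emitted intensities.
#' @param world [world_config()].
#' @return `n x 6` matrix of sector readings.
#' @export
sense_all <- function(pos, vel, sig, world = world_config()) {
  n <- nrow(pos)
  out <- matrix(0, n, 6, dimnames = list(NULL, SECTOR_NAMES))
  if (n < 2L || all(sig <= 0)) return(out)
  for (i in seq_len(n)) {
    out[i, ] <- sense(pos[i, ], vel[i, ], pos[-i, , drop = FALSE], sig[-i],
                      world)
  }
  out
}
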