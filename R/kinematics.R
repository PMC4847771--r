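#' Map controller outputs to steering angles
#'
#' Affine map from the unit interval onto `[-alpha_max, alpha_max]`:
#' `theta = alpha_max * (2 o1 - 1)` (yaw), `psi = alpha_max * (2 o2 - 1)`
#' (pitch).  Output 0.5 steers straight.
#'
#' @param o1,o2 Motor outputs in \[0, 1\] (vectorised).
#' @param cfg [kinematics_config()].
#' @return A list with numeric `theta` and `psi`, radians.
#' @examples
#' outputs_to_angles(0.75, 0.5, kinematics_config(alpha_max = pi / 4))
#' @export
outputs_to_angles <- function(o1, o2, cfg = kinematics_config()) {
  stopifnot(all(o1 >= 0 & o1 <= 1), all(o2 >= 0 & o2 <= 1))
  list(theta = cfg$alpha_max * (2 * o1 - 1),
       psi = cfg$alpha_max * (2 * o2 - 1))
}

#' Steer the velocity by yaw and pitch angles
#'
#' Adds `c1 * tan(theta)` along the body-frame right axis and `c2 * tan(psi)`
#' along the body-frame up axis, then renormalises to the constant world
#' speed.  A zero command returns the velocity unchanged; in the (measure
#' zero) degenerate case where steering cancels the velocity, the previous
#' heading is kept.
#'
#' @param v Current velocity (norm = `world$speed`).
#' @param theta,psi Yaw and pitch angles, radians, inside `(-pi/2, pi/2)`.
#' @param frame [body_frame()] of the agent (from `v`).
#' @param cfg [kinematics_config()].
#' @param world [world_config()].
#' @return New velocity with `||v|| = world$speed`.
#' @export
update_velocity <- function(v, theta, psi, frame = body_frame(v),
                            cfg = kinematics_config(),
                            world = world_config()) {
  if (theta == 0 && psi == 0) return(v)
  v2 <- v + cfg$c1 * tan(theta) * frame$right + cfg$c2 * tan(psi) * frame$up
  n <- sqrt(sum(v2^2))
  if (n < 1e-12) return(v)
  v2 / n * world$speed
}

#' Advance a position by one iteration
#'
#' `p' = wrap(p + v)` on the torus.
#'
#' @param p Position (length 3 or `n x 3`).
#' @param v Velocity of matching shape.
#' @param world [world_config()].
#' @return Wrapped new position.
#' @export
update_position <- function(p, v, world = world_config()) {
  wrap_position(p + v, world$arena_side)
}
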