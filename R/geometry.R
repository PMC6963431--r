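# Agent geometry: disc bodies with two azimuthally placed bonding sites on a
# primary axis, trigger zones, and the ring-mode bond-angle displacement.

#' Construct a single tubulin agent
#'
#' A tubulin is a disc with two bonding sites, A and B, placed on its primary
#' axis: site A at azimuth 0 and site B at azimuth pi (opposite poles). The
#' orientation is the in-plane rotation of the primary axis. Mainly useful
#' for tests and small worked examples; simulations build whole worlds with
#' [init_world()].
#'
#' @param kind `"alpha"` or `"beta"`.
#' @param position numeric length-2 centre position, tray units.
#' @param orientation rotation of the primary axis, radians.
#' @param config an [mt_config()] (supplies radius and tray size).
#' @return an object of class `mt_tubulin`.
#' @examples
#' t1 <- make_tubulin("alpha", c(1, 1), pi / 2)
#' site_world_position(t1, "A")
#' @export
make_tubulin <- function(kind = c("alpha", "beta"), position = c(0, 0),
                         orientation = 0, config = mt_config()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(position), length(position) == 2)
  r <- config$tubulin_radius
  if (position[1] < 0 || position[1] > config$space_width) {
    abort(sprintf(
      "x position %g lies outside the configuration space [0, %g]",
      position[1], config$space_width))
  }
  if (position[2] < 0 || position[2] > config$space_height) {
    abort(sprintf(
      "y position %g lies outside the configuration space [0, %g]",
      position[2], config$space_height))
  }
  structure(
    list(kind = kind, position = as.numeric(position),
         velocity = c(0, 0), orientation = as.numeric(orientation),
         radius = r, site_a_angle = 0, site_b_angle = pi,
         nucleotide = NULL, site_a_occupied = FALSE,
         site_b_occupied = FALSE),
    class = "mt_tubulin")
}

#' World-frame position of a bonding site
#'
#' The site sits on the disc rim at `position + radius * u(orientation +
#' site_angle)` where `u` is the unit vector of an angle.
#'
#' @param t an `mt_tubulin` from [make_tubulin()].
#' @param site `"A"` or `"B"`.
#' @return numeric length-2 world position.
#' @export
site_world_position <- function(t, site = c("A", "B")) {
  site <- match.arg(site)
  ang <- t$orientation +
    if (site == "A") t$site_a_angle else t$site_b_angle
  t$position + t$radius * c(cos(ang), sin(ang))
}

# vectorised site positions for tubulins in a world ---------------------------
site_xy <- function(w, idx, site) {
  ang <- w$tub_orient[idx] +
    if (site == "A") w$site_a[idx] else w$site_b[idx]
  cbind(w$tub_x[idx] + w$tubulin_radius * cos(ang),
        w$tub_y[idx] + w$tubulin_radius * sin(ang))
}

#' Number of dimers needed to close a ring
#'
#' With a junction bend of `theta` degrees, a chain closes geometrically when
#' the cumulative bend reaches one full turn, i.e. after `360 / theta`
#' members; 30 degrees accommodates 12 members.
#'
#' @param theta_degrees per-junction bend angle in degrees.
#' @return integer member count.
#' @export
ring_capacity <- function(theta_degrees) {
  stopifnot(is.numeric(theta_degrees), theta_degrees > 0)
  as.integer(round(360 / theta_degrees))
}

#' Displace the free bonding sites of an activated dimer (ring mode)
#'
#' On activation in ring mode the two outward-facing free sites of the dimer
#' (the B site of the alpha member and the A site of the beta member) are
#' rotated symmetrically by +theta/2 and -theta/2 off the primary axis. When
#' two such dimers bond, the facing-site constraint then turns the chain by
#' exactly `theta` per junction, all in the same rotational sense, so a chain
#' closes after `360 / theta` members. The internal alpha-beta bond is left
#' untouched; `theta = 0` degenerates to a straight protofilament.
#'
#' @param w an `mt_world` in ring mode.
#' @param alpha_id tubulin index of the dimer's alpha member.
#' @param theta junction bend in radians, in `(0, pi/2]` (or exactly 0 for
#'   the degenerate straight case).
#' @return the modified world.
#' @export
displace_bond_angles <- function(w, alpha_id, theta) {
  if (!identical(w$mode, "ring")) {
    abort("bond-angle displacement applies only to ring-mode worlds")
  }
  if (!(theta == 0 || (theta > 0 && theta <= pi / 2))) {
    abort("`theta` must lie in (0, pi/2] radians (or be exactly 0)")
  }
  beta_id <- w$bond_a[alpha_id]
  if (w$tub_kind[alpha_id] != KIND_ALPHA || beta_id == 0L) {
    abort("`alpha_id` must be the alpha member of a formed dimer")
  }
  w$site_b[alpha_id] <- pi + theta / 2
  w$site_a[beta_id] <- -theta / 2
  w
}

# reset displaced angles on deactivation (breakage in ring mode)
reset_bond_angles <- function(w, alpha_id) {
  beta_id <- w$bond_a[alpha_id]
  w$site_b[alpha_id] <- pi
  if (beta_id > 0L) w$site_a[beta_id] <- 0
  w
}
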