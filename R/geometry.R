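# The membrane is two laterally infinite walls pierced by a finite
# cylindrical pore whose axis is +x. All surfaces are continuous: a bead
# interacts with a surface through its centre's Euclidean distance to it.

#' Membrane geometry: two walls pierced by a finite cylindrical pore
#'
#' Derives the static membrane from a parameter set: two parallel planes at
#' `pore_center[1] +/- pore_length/2` (the cis and trans faces), each an
#' annulus around the circular aperture of radius `pore_radius`, joined by
#' the inner cylinder surface. The pore axis is fixed to +x; translocation
#' proceeds from the cis side (small x) to the trans side (large x).
#'
#' @param params a [simulation_parameters()] object.
#' @return A `membrane_geometry` list with fields `pore_axis`, `pore_center`,
#'   `pore_length`, `pore_radius`, `cis_plane_x`, `trans_plane_x`.
#' @export
membrane_geometry <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  g <- structure(list(
    pore_axis = c(1, 0, 0),
    pore_center = as.numeric(params$pore_center),
    pore_length = params$pore_length,
    pore_radius = params$pore_radius,
    cis_plane_x = params$pore_center[1] - params$pore_length / 2,
    trans_plane_x = params$pore_center[1] + params$pore_length / 2
  ), class = "membrane_geometry")
  stopifnot(g$pore_radius > 0, g$pore_length > 0)
  g
}

#' @export
print.membrane_geometry <- function(x, ...) {
  cat(sprintf(
    "<membrane_geometry> pore axis +x, centre (%g, %g, %g), length %g, radius %g\n",
    x$pore_center[1], x$pore_center[2], x$pore_center[3],
    x$pore_length, x$pore_radius))
  invisible(x)
}

.as_points <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3)
    points <- matrix(points, nrow = 1)
  }
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  storage.mode(points) <- "double"
  points
}

#' Classify points as cis, pore or trans
#'
#' A point is in the pore iff its x lies within the pore span (inclusive) and
#' its radial distance from the axis is strictly below the pore radius.
#' Points left of the cis plane are cis, right of the trans plane trans. A
#' point inside the wall material (x within the span, radius >= pore radius)
#' is assigned by the sign of its x-offset from the pore centre: cis if
#' negative, trans otherwise -- it sits in a wall's interaction zone and is
#' never force-free.
#'
#' @param points a 3-vector or an n x 3 matrix of coordinates (sigma units).
#' @param geom a [membrane_geometry()] object.
#' @return Character vector in `c("cis", "pore", "trans")`.
#' @export
region_of <- function(points, geom) {
  pts <- .as_points(points)
  stopifnot(all(is.finite(pts)))
  c("cis", "pore", "trans")[cpp_region_of(pts, unclass(geom))]
}

#' Distance to the membrane walls
#'
#' Minimum Euclidean distance from each point to the union of the two
#' annular wall faces; for points whose perpendicular foot would land inside
#' the aperture, the distance is to the aperture rim circle, so the distance
#' field is continuous around the pore mouth. Points inside the pore bore do
#' not see the walls (the inner cylinder takes over) and get a sentinel value
#' far beyond any interaction cutoff.
#'
#' @inheritParams region_of
#' @return Numeric vector of distances (sigma units).
#' @export
wall_distance <- function(points, geom) {
  pts <- .as_points(points)
  stopifnot(all(is.finite(pts)))
  cpp_wall_distance(pts, unclass(geom))
}

#' Distance to the inner pore cylinder surface
#'
#' For points whose axial coordinate lies within the pore span this is
#' `|pore_radius - radial|`; otherwise the distance to the nearer rim circle.
#'
#' @inheritParams region_of
#' @return Numeric vector of distances (sigma units).
#' @export
pore_surface_distance <- function(points, geom) {
  pts <- .as_points(points)
  stopifnot(all(is.finite(pts)))
  cpp_pore_surface_distance(pts, unclass(geom))
}

#' Export the membrane surface as a Wavefront OBJ mesh (debug aid)
#'
#' Triangulates the two annular faces and the inner cylinder for quick
#' visual inspection in any mesh viewer.
#'
#' @inheritParams region_of
#' @param path output `.obj` file.
#' @param n_theta azimuthal resolution.
#' @param outer_radius lateral extent to which the (infinite) walls are drawn.
#' @return `path`, invisibly.
#' @export
write_membrane_obj <- function(geom, path, n_theta = 48, outer_radius = NULL) {
  if (is.null(outer_radius)) outer_radius <- 4 * geom$pore_radius
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  cy <- geom$pore_center[2]; cz <- geom$pore_center[3]
  ring <- function(x, r) cbind(x, cy + r * cos(th), cz + r * sin(th))
  verts <- rbind(
    ring(geom$cis_plane_x, geom$pore_radius),    # 1: cis inner
    ring(geom$cis_plane_x, outer_radius),        # 2: cis outer
    ring(geom$trans_plane_x, geom$pore_radius),  # 3: trans inner
    ring(geom$trans_plane_x, outer_radius)       # 4: trans outer
  )
  quad_faces <- function(a, b) {
    # stitch ring a to ring b (0-based ring ids) with triangles
    i <- seq_len(n_theta); j <- c(seq_len(n_theta)[-1], 1L)
    rbind(cbind(a * n_theta + i, a * n_theta + j, b * n_theta + i),
          cbind(b * n_theta + i, a * n_theta + j, b * n_theta + j))
  }
  faces <- rbind(quad_faces(0, 1), quad_faces(2, 3), quad_faces(0, 2))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", verts[, 1], verts[, 2], verts[, 3]), con)
  writeLines(sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
  invisible(path)
}
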