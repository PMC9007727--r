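# Single-sphere MEG forward model (Sarvas closed form).
#
# For a current dipole with moment Q at position r0 inside a homogeneous
# conducting sphere, the magnetic field outside the sphere is
#
#   B(r) = mu0 / (4 pi F^2) * ( F (Q x r0) - (Q x r0 . r) grad F )
#   F    = a (r a + r^2 - r0 . r),     a = r - r0,  a = |a|, r = |r|
#   grad F = (a^2/r + a.r/a + 2a + 2r) r - (a + 2r + a.r/a) r0
#
# with all positions taken relative to the sphere centre.  The field is
# linear in Q; a radial moment (Q parallel to r0) and a dipole at the centre
# both produce a null field, which serve as exact self-checks.

MU0 <- 4 * pi * 1e-7

#' Sarvas dipole-to-sensor transfer matrix
#'
#' Returns the n_channels x 3 matrix `M` such that the projected field on
#' each sensor's pickup orientation is `M %*% Q` for any dipole moment `Q`
#' (A·m).  All geometry in metres.
#'
#' @param dipole_pos 3-vector, metres (absolute coordinates).
#' @param sensors `sensor_array`.
#' @param sphere `sphere_model`.
#' @return n_channels x 3 matrix, tesla per (A·m).
#' @export
sarvas_basis <- function(dipole_pos, sensors, sphere) {
  stopifnot(inherits(sensors, "sensor_array"), inherits(sphere, "sphere_model"))
  r0 <- as.numeric(dipole_pos) - sphere$center
  if (sqrt(sum(r0^2)) >= sphere$radius)
    stop("dipole lies on or outside the head sphere")
  rs <- sweep(sensors$positions, 2, sphere$center)   # n x 3
  rr <- sqrt(rowSums(rs^2))
  if (any(rr <= sphere$radius))
    stop("all sensors must lie strictly outside the head sphere")
  a_vec <- rs - matrix(r0, nrow(rs), 3, byrow = TRUE)
  a <- sqrt(rowSums(a_vec^2))
  if (any(a < 1e-9)) stop("dipole coincident with a sensor (singular geometry)")
  r0r <- as.numeric(rs %*% r0)
  ar <- rowSums(a_vec * rs)
  F_ <- a * (rr * a + rr^2 - r0r)
  c1 <- a^2 / rr + ar / a + 2 * a + 2 * rr
  c2 <- a + 2 * rr + ar / a
  gradF <- rs * c1 - matrix(r0, nrow(rs), 3, byrow = TRUE) * c2

  o <- sensors$orientations
  # B . o = mu0/(4 pi F^2) * Q . ( F (r0 x o) - (gradF . o) (r0 x r) )
  r0xo <- cross3(matrix(r0, nrow(o), 3, byrow = TRUE), o)
  r0xr <- cross3(matrix(r0, nrow(rs), 3, byrow = TRUE), rs)
  go <- rowSums(gradF * o)
  # F > 0 always: F = a r (a + r - r0.r/r) and |r0| < radius < r
  (r0xo * F_ - r0xr * go) * (MU0 / (4 * pi * F_^2))
}

#' Sarvas field projected on the sensor array
#'
#' @param dipole_pos 3-vector, metres.
#' @param dipole_moment 3-vector, A·m.
#' @inheritParams sarvas_basis
#' @return numeric vector of per-channel field values (tesla).
#' @export
sarvas_field <- function(dipole_pos, dipole_moment, sensors, sphere) {
  as.numeric(sarvas_basis(dipole_pos, sensors, sphere) %*% as.numeric(dipole_moment))
}

#' Build the lead-field matrix for a cortical mesh
#'
#' One column block per mesh vertex.  With `moment_convention = "free"` the
#' block is the 3-column Sarvas basis (x/y/z unit moments); with `"fixed"`
#' (default) the three degrees of freedom are contracted with the vertex
#' normal, giving one column per vertex.  Mesh vertices are mm; the lead
#' field is in T/(A·m).
#'
#' @param mesh `cortical_mesh` (vertices in mm).
#' @param sensors `sensor_array` (metres).
#' @param sphere `sphere_model` (metres).
#' @param moment_convention "fixed" (normal-constrained) or "free".
#' @return object of class `leadfield`: list with `matrix`
#'   (channels x columns), `source_positions` (mm), `moment_convention`.
#' @export
build_leadfield <- function(mesh, sensors, sphere,
                            moment_convention = c("fixed", "free")) {
  moment_convention <- match.arg(moment_convention)
  stopifnot(inherits(mesh, "cortical_mesh"))
  if (mesh$n_vertices == 0) stop("empty mesh")
  n <- mesh$n_vertices
  p <- sensors$n_channels
  verts_m <- mesh$vertices / MM_PER_M
  rel <- sweep(verts_m, 2, sphere$center)
  inside <- sqrt(rowSums(rel^2)) < sphere$radius
  if (!all(inside))
    warning(sum(!inside), " mesh vertices lie outside the head sphere")

  if (moment_convention == "free") {
    L <- matrix(0, p, 3 * n)
    for (v in seq_len(n))
      L[, (3 * v - 2):(3 * v)] <- sarvas_basis(verts_m[v, ], sensors, sphere)
  } else {
    L <- matrix(0, p, n)
    for (v in seq_len(n))
      L[, v] <- sarvas_basis(verts_m[v, ], sensors, sphere) %*% mesh$normals[v, ]
  }
  structure(list(matrix = L, source_positions = mesh$vertices,
                 moment_convention = moment_convention),
            class = "leadfield")
}
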