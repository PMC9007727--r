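#' @rawNamespace import(Matrix, except = c(head, tail))
#' @importFrom stats runif rnorm sd fft cor dist aggregate
#' @importFrom utils head tail write.csv read.csv packageVersion
NULL

# Coordinate conventions: user-facing positions are mm, MNI-style axes
# (x right, y anterior, z superior).  The forward model works in metres;
# conversion happens once, at the module boundary (see build_leadfield).

MM_PER_M <- 1000

#' Sensor array
#'
#' A set of point magnetometers: positions (metres) and unit pickup
#' orientations.  The default fixture uses 275 channels, radially oriented
#' from the head-sphere centre, on a helmet-like cap.
#'
#' @param positions n x 3 matrix, metres.
#' @param orientations n x 3 matrix of unit vectors.
#' @return An object of class `sensor_array`.
#' @export
sensor_array <- function(positions, orientations) {
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  stopifnot(ncol(positions) == 3, ncol(orientations) == 3,
            nrow(positions) == nrow(orientations))
  nrm <- sqrt(rowSums(orientations^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("sensor orientations must have unit norm")
  structure(list(positions = positions, orientations = orientations,
                 n_channels = nrow(positions)),
            class = "sensor_array")
}

#' Single-sphere head model
#'
#' @param center 3-vector, metres.
#' @param radius positive scalar, metres.
#' @return An object of class `sphere_model`.
#' @export
sphere_model <- function(center = c(0, 0, 0.04), radius = 0.09) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3, length(radius) == 1, radius > 0)
  structure(list(center = center, radius = radius), class = "sphere_model")
}

#' Triangulated cortical mesh
#'
#' Vertices are mm MNI.  Vertex normals are computed from the faces
#' (area-weighted average of incident face normals) unless supplied, and
#' oriented outward with respect to the mesh centroid.  The vertex adjacency
#' graph (symmetric, empty diagonal) is derived from the faces and stored as
#' a sparse matrix; it is the `A` of the Green's-function smoother.
#'
#' @param vertices n x 3 matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param normals optional n x 3 matrix of unit vectors.
#' @return An object of class `cortical_mesh` with fields `vertices`,
#'   `faces`, `normals`, `adjacency`, `n_vertices`.
#' @export
cortical_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  n <- nrow(vertices)
  if (n < 3 || nrow(faces) < 1) stop("mesh must have >= 3 vertices and >= 1 face")
  if (any(faces < 1L) || any(faces > n)) stop("face index out of range")

  if (is.null(normals)) {
    v1 <- vertices[faces[, 1], , drop = FALSE]
    v2 <- vertices[faces[, 2], , drop = FALSE]
    v3 <- vertices[faces[, 3], , drop = FALSE]
    fn <- cross3(v2 - v1, v3 - v1)        # area-weighted face normals
    idx <- c(faces[, 1], faces[, 2], faces[, 3])
    acc <- rowsum(rbind(fn, fn, fn), idx)
    normals <- matrix(0, n, 3)
    normals[as.integer(rownames(acc)), ] <- acc
    ctr <- colMeans(vertices)
    out <- vertices - matrix(ctr, n, 3, byrow = TRUE)
    flip <- rowSums(normals * out) < 0
    normals[flip, ] <- -normals[flip, ]
    nrm <- sqrt(rowSums(normals^2))
    nrm[nrm == 0] <- 1
    normals <- normals / nrm
  } else {
    normals <- as.matrix(normals)
    nrm <- sqrt(rowSums(normals^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("supplied normals must be unit vectors")
  }

  ii <- c(faces[, 1], faces[, 2], faces[, 2], faces[, 3], faces[, 3], faces[, 1])
  jj <- c(faces[, 2], faces[, 1], faces[, 3], faces[, 2], faces[, 1], faces[, 3])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  A@x[] <- 1                    # collapse duplicate edges to 0/1
  diag(A) <- 0
  A <- Matrix::drop0(A)

  structure(list(vertices = vertices, faces = faces, normals = normals,
                 adjacency = A, n_vertices = n),
            class = "cortical_mesh")
}

# row-wise cross product of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Nearest mesh vertex to a position
#'
#' Euclidean nearest neighbour; ties broken by lowest index.
#'
#' @param position_mm 3-vector, mm.
#' @param mesh a `cortical_mesh`.
#' @return integer vertex index.
#' @export
nearest_vertex <- function(position_mm, mesh) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  d2 <- rowSums(sweep(mesh$vertices, 2, position_mm)^2)
  which.min(d2)  # which.min returns the first (lowest-index) minimum
}

#' Deterministic fixture geometry
#'
#' Generates a convex-ish cortical shell mesh (a jittered latitude/longitude
#' sphere of radius `shell_radius_mm` centred on the head-sphere centre)
#' inside a single-sphere head model, plus a helmet-shaped array of radial
#' point magnetometers.  The two vertices nearest to `anchor_mm` (default:
#' the simulation's two dipole locations) are snapped exactly onto those
#' positions so that simulated dipoles lie on the mesh.
#'
#' @param n_vertices requested vertex count (>= 12); the realized count is
#'   the nearest latitude/longitude grid (+2 poles).
#' @param seed integer; the geometry is a deterministic function of it.
#' @param n_sensors number of channels (default 275).
#' @param shell_radius_mm cortical shell radius, mm (default 66.5).
#' @param sphere head sphere (`sphere_model`); default centre (0,0,40) mm,
#'   radius 90 mm, expressed in metres.
#' @param sensor_radius_mm sensor shell radius, mm (default 120).
#' @param jitter_mm radial jitter SD applied to shell vertices (default 1.5).
#' @param tilt_deg source-orientation tilt from the radial direction
#'   (default 75).  Radially oriented dipoles are magnetically silent
#'   inside a spherical conductor, so the fixture assigns each vertex a
#'   smooth, mostly tangential orientation field (tilted towards the local
#'   polar direction) in place of the geometric surface normal; this
#'   emulates the locally coherent but non-radial orientations of folded
#'   cortex and keeps every simulated source visible to the array.
#' @param anchor_mm k x 3 matrix of positions to snap vertices onto.
#' @return list with `mesh` (`cortical_mesh`, mm), `sensors`
#'   (`sensor_array`, metres), `sphere` (`sphere_model`, metres).
#' @export
fixture_geometry <- function(n_vertices = 2000, seed = 1, n_sensors = 275,
                             shell_radius_mm = 66.5,
                             sphere = sphere_model(),
                             sensor_radius_mm = 120,
                             jitter_mm = 1.5,
                             tilt_deg = 75,
                             anchor_mm = rbind(c(-38, 43, 5), c(-54, -13, 5))) {
  if (n_vertices < 12) stop("n_vertices must be >= 12")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))

  ctr_mm <- sphere$center * MM_PER_M

  n_lat <- max(3L, round(sqrt((n_vertices - 2) / 2)))
  n_lon <- 2L * n_lat
  lat <- seq(0, pi, length.out = n_lat + 2)[2:(n_lat + 1)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[1:n_lon]
  grid <- expand.grid(lat = lat, lon = lon)
  r <- shell_radius_mm + rnorm(nrow(grid) + 2, 0, jitter_mm)
  unit <- cbind(sin(grid$lat) * cos(grid$lon),
                sin(grid$lat) * sin(grid$lon),
                cos(grid$lat))
  verts <- rbind(unit * r[seq_len(nrow(grid))],
                 c(0, 0, r[nrow(grid) + 1]),       # north pole
                 c(0, 0, -r[nrow(grid) + 2]))      # south pole
  verts <- sweep(verts, 2, ctr_mm, "+")
  np <- nrow(grid) + 1L
  sp <- nrow(grid) + 2L

  # faces on the lat/lon grid (vertex id of (i in 1..n_lat, j in 1..n_lon))
  vid <- function(i, j) (((j - 1L) %% n_lon)) * n_lat + i
  faces <- list()
  for (j in seq_len(n_lon)) {
    j2 <- j + 1L
    for (i in seq_len(n_lat - 1L)) {
      a <- vid(i, j); b <- vid(i + 1L, j); c2 <- vid(i, j2); d <- vid(i + 1L, j2)
      faces[[length(faces) + 1L]] <- c(a, b, c2)
      faces[[length(faces) + 1L]] <- c(b, d, c2)
    }
    faces[[length(faces) + 1L]] <- c(np, vid(1L, j), vid(1L, j2))
    faces[[length(faces) + 1L]] <- c(sp, vid(n_lat, j2), vid(n_lat, j))
  }
  faces <- do.call(rbind, faces)

  # snap nearest vertices onto the anchor positions (dipole sites)
  if (!is.null(anchor_mm)) {
    anchor_mm <- as.matrix(anchor_mm)
    taken <- integer(0)
    for (k in seq_len(nrow(anchor_mm))) {
      d2 <- rowSums(sweep(verts, 2, anchor_mm[k, ])^2)
      d2[taken] <- Inf
      idx <- which.min(d2)
      verts[idx, ] <- anchor_mm[k, ]
      taken <- c(taken, idx)
    }
  }

  # keep every vertex strictly inside the head sphere
  rel <- sweep(verts, 2, ctr_mm)
  rr <- sqrt(rowSums(rel^2))
  rmax <- sphere$radius * MM_PER_M * 0.98
  scale_in <- pmin(1, rmax / rr)
  verts <- sweep(rel * scale_in, 2, ctr_mm, "+")

  # orientation field: unit radial direction tilted towards the local polar
  # tangent e_theta (smooth away from the poles, where e_theta degenerates)
  u <- sweep(verts, 2, ctr_mm)
  u <- u / sqrt(rowSums(u^2))
  st <- sqrt(u[, 1]^2 + u[, 2]^2)
  e_th <- cbind(u[, 3] * u[, 1] / st, u[, 3] * u[, 2] / st, -st)
  e_th[st < 1e-8, ] <- rep(c(1, 0, 0), each = sum(st < 1e-8))
  tilt <- tilt_deg * pi / 180
  ors <- cos(tilt) * u + sin(tilt) * e_th
  ors <- ors / sqrt(rowSums(ors^2))
  mesh <- cortical_mesh(verts, faces, normals = ors)

  # sensors: Fibonacci spiral on a spherical cap (helmet), radial pickup
  k <- seq_len(n_sensors)
  golden <- pi * (3 - sqrt(5))
  zmin <- -0.45                         # cap extends below the "ears"
  z <- 1 - (k - 0.5) / n_sensors * (1 - zmin)
  th <- golden * (k - 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  sunit <- cbind(rho * cos(th), rho * sin(th), z)
  spos_mm <- sweep(sunit * sensor_radius_mm, 2, ctr_mm, "+")
  sensors <- sensor_array(spos_mm / MM_PER_M, sunit)

  list(mesh = mesh, sensors = sensors, sphere = sphere)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
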