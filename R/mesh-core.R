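#' Triangle mesh objects
#'
#' A `tri_mesh` is the unit of all geometry in conchydro: a triangle surface
#' given by an `n x 3` vertex matrix (cm) and an `m x 3` integer face matrix
#' of 1-based vertex indices. Closed, consistently outward-oriented meshes
#' enclose a solid whose volume, centroid and inertia tensor are computed
#' exactly from the surface by the divergence theorem. Coordinates are
#' right-handed with z vertical (up) and the planispiral coiling axis along y.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in cm.
#' @param faces integer matrix, m x 3, 1-based vertex indices with outward
#'   (counter-clockwise seen from outside) winding.
#' @param name optional label.
#' @param density optional material density in g/cm^3.
#' @return An object of class `tri_mesh`.
#' @examples
#' m <- mesh_cube(1)
#' signed_volume(m)
#' @export
tri_mesh <- function(vertices, faces, name = NULL, density = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 name = name, density = density),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh%s: %d vertices, %d faces%s\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$density)) "" else
                sprintf(", density %.4g g/cm^3", x$density)))
  invisible(x)
}

face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

face_areas <- function(mesh) {
  fc <- face_corners(mesh)
  0.5 * sqrt(rowSums(cross3(fc$b - fc$a, fc$c - fc$a)^2))
}

#' Drop degenerate (near-zero-area) faces
#'
#' Faces with area below `tol` (cm^2) are removed before integration; the
#' count of dropped faces is reported via `message()`.
#'
#' @param mesh a [tri_mesh()].
#' @param tol area tolerance in cm^2.
#' @return The cleaned mesh.
#' @export
drop_degenerate_faces <- function(mesh, tol = 1e-12) {
  if (nrow(mesh$faces) == 0L) return(mesh)
  keep <- face_areas(mesh) > tol
  if (!all(keep)) {
    message(sprintf("dropped %d degenerate face(s)", sum(!keep)))
    mesh$faces <- mesh$faces[keep, , drop = FALSE]
  }
  mesh
}

edge_table <- function(mesh) {
  f <- mesh$faces
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  key <- paste(lo, hi)
  list(from = from, to = to, key = key, forward = from < to)
}

#' Watertightness and orientation diagnostics
#'
#' Checks that every edge is shared by exactly two faces with opposite
#' winding — i.e. the mesh is a closed, consistently oriented manifold
#' suitable for divergence-theorem integrals.
#'
#' @param mesh a [tri_mesh()].
#' @return A list with `passes`, counts of `boundary_edges`,
#'   `non_manifold_edges`, `misoriented_edges`, `degenerate_faces`, and the
#'   offending undirected edge keys in `boundary_edge_list`.
#' @export
validate_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) {
    return(list(passes = FALSE, boundary_edges = 0L, non_manifold_edges = 0L,
                misoriented_edges = 0L, degenerate_faces = 0L,
                boundary_edge_list = character(0)))
  }
  et <- edge_table(mesh)
  cnt <- table(et$key)
  boundary <- names(cnt)[cnt == 1L]
  nonmanifold <- names(cnt)[cnt > 2L]
  # a consistently oriented closed surface has each undirected edge once in
  # each direction; paired edges traversed twice the same way are misoriented
  fwd <- tapply(et$forward, et$key, sum)
  shared2 <- names(cnt)[cnt == 2L]
  miso <- shared2[fwd[shared2] != 1L]
  ndeg <- sum(face_areas(mesh) <= 1e-12)
  list(passes = length(boundary) == 0L && length(nonmanifold) == 0L &&
         length(miso) == 0L && ndeg == 0L,
       boundary_edges = length(boundary),
       non_manifold_edges = length(nonmanifold),
       misoriented_edges = length(miso),
       degenerate_faces = ndeg,
       boundary_edge_list = boundary)
}

stop_if_open <- function(mesh) {
  d <- validate_watertight(mesh)
  if (d$boundary_edges > 0L || d$non_manifold_edges > 0L) {
    stop(sprintf(
      "mesh%s is not watertight: %d boundary edge(s), %d non-manifold edge(s); first offenders: %s",
      if (is.null(mesh$name)) "" else paste0(" '", mesh$name, "'"),
      d$boundary_edges, d$non_manifold_edges,
      paste(utils::head(d$boundary_edge_list, 5L), collapse = ", ")))
  }
  invisible(mesh)
}

#' Signed volume of a closed mesh
#'
#' Divergence-theorem integral over the surface; positive when the mesh is
#' outward-oriented.
#'
#' @param mesh a closed [tri_mesh()].
#' @param check validate watertightness first (default TRUE).
#' @return Signed volume in cm^3.
#' @export
signed_volume <- function(mesh, check = TRUE) {
  if (check) stop_if_open(mesh)
  fc <- face_corners(mesh)
  sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
}

#' Center of volume of the enclosed solid
#'
#' @inheritParams signed_volume
#' @return Length-3 numeric, cm.
#' @export
mesh_centroid <- function(mesh, check = TRUE) {
  if (check) stop_if_open(mesh)
  fc <- face_corners(mesh)
  det6 <- rowSums(fc$a * cross3(fc$b, fc$c)) # 6 * signed tet volume
  v <- sum(det6) / 6
  if (abs(v) < 1e-300) stop("mesh encloses zero volume; centroid undefined")
  colSums(det6 / 24 * (fc$a + fc$b + fc$c)) / v
}

#' Mass, center and inertia tensor of a uniform-density solid
#'
#' Exact polyhedral integrals (tetrahedral decomposition against the origin).
#' The tensor is reported about the centroid; `izz_about()` in the result
#' gives the moment about a vertical (z) axis through any pivot via the
#' parallel-axis theorem.
#'
#' @param mesh a closed [tri_mesh()].
#' @param density g/cm^3; defaults to the mesh's density tag.
#' @param pivot optional 3-vector: also report `izz_vertical`, the moment
#'   about the vertical axis through this point (g cm^2).
#' @return List with `mass` (g), `center` (cm), `tensor` (3x3, g cm^2 about
#'   the center), `volume` (cm^3), and optionally `izz_vertical`.
#' @export
inertia_tensor <- function(mesh, density = mesh$density, pivot = NULL) {
  if (is.null(density)) stop("density required (argument or mesh$density)")
  if (density <= 0) stop("density must be > 0")
  stop_if_open(mesh)
  fc <- face_corners(mesh)
  det6 <- rowSums(fc$a * cross3(fc$b, fc$c))
  vol <- sum(det6) / 6
  ctr <- colSums(det6 / 24 * (fc$a + fc$b + fc$c)) / vol
  # second moments about the origin: for tet (0,a,b,c),
  # S_pq = det/120 * (sum_i sum_j v_ip v_jq + sum_i v_ip v_iq)
  S <- matrix(0, 3, 3)
  sv <- fc$a + fc$b + fc$c
  for (p in 1:3) for (q in p:3) {
    spq <- sum(det6 / 120 *
                 (sv[, p] * sv[, q] +
                    fc$a[, p] * fc$a[, q] +
                    fc$b[, p] * fc$b[, q] +
                    fc$c[, p] * fc$c[, q]))
    S[p, q] <- spq
    S[q, p] <- spq
  }
  mass <- density * vol
  # shift second moments to the centroid, then I = tr(S) Id - S
  Sc <- density * S - mass * (ctr %o% ctr)
  I <- diag(sum(diag(Sc)), 3) - Sc
  out <- list(mass = mass, center = ctr, tensor = I, volume = vol)
  if (!is.null(pivot)) {
    d2 <- sum((ctr[1:2] - pivot[1:2])^2)
    out$izz_vertical <- I[3, 3] + mass * d2
  }
  out
}

#' Moment of inertia about a vertical axis, summed over components
#'
#' Moments of inertia are additive: the total is the sum over components of
#' unique density, each taken about the same vertical axis.
#'
#' @param components list of [tri_mesh()] (with density tags) or lists with
#'   `mass`, `center`, and optionally `izz_own` (own-axis moment, g cm^2).
#' @param pivot 3-vector; the vertical axis passes through its (x, y).
#' @return Total Izz in g cm^2.
#' @export
izz_total <- function(components, pivot = c(0, 0, 0)) {
  sum(vapply(components, function(comp) {
    if (inherits(comp, "tri_mesh")) {
      inertia_tensor(comp, pivot = pivot)$izz_vertical
    } else {
      own <- if (is.null(comp$izz_own)) 0 else comp$izz_own
      own + comp$mass * sum((comp$center[1:2] - pivot[1:2])^2)
    }
  }, numeric(1)))
}

# ---- transforms ------------------------------------------------------------

#' Rigid and scaling transforms of meshes
#'
#' @param mesh a [tri_mesh()].
#' @param offset length-3 translation (cm).
#' @return The transformed mesh.
#' @export
mesh_translate <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, offset, "+")
  mesh
}

#' @rdname mesh_translate
#' @param rotation 3x3 rotation matrix.
#' @export
mesh_rotate <- function(mesh, rotation) {
  mesh$vertices <- mesh$vertices %*% t(rotation)
  mesh
}

#' @rdname mesh_translate
#' @param factor uniform scale factor about the origin.
#' @export
mesh_scale <- function(mesh, factor) {
  mesh$vertices <- mesh$vertices * factor
  mesh
}

#' @rdname mesh_translate
#' @export
mesh_invert <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Disjoint union of meshes into a single multi-component mesh
#'
#' @param ... [tri_mesh()] objects or a single list of them.
#' @param name optional label of the result.
#' @return A `tri_mesh` whose surface is the union of the inputs' surfaces.
#' @export
mesh_merge <- function(..., name = NULL) {
  meshes <- list(...)
  if (length(meshes) == 1L && !inherits(meshes[[1]], "tri_mesh"))
    meshes <- meshes[[1]]
  meshes <- Filter(Negate(is.null), meshes)
  if (length(meshes) == 0L) stop("no meshes to merge")
  vs <- lapply(meshes, `[[`, "vertices")
  off <- cumsum(c(0L, vapply(vs, nrow, integer(1))))
  fs <- Map(function(m, o) m$faces + o, meshes, off[-length(off)])
  tri_mesh(do.call(rbind, vs), do.call(rbind, fs), name = name,
           density = meshes[[1]]$density)
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis "x", "y" or "z".
#' @param angle_deg angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  switch(axis,
    x = rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca)),
    y = rbind(c(ca, 0, sa), c(0, 1, 0), c(-sa, 0, ca)),
    z = rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1)))
}

# minimal rotation taking unit vector u onto unit vector v (Rodrigues)
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-15) {
    if (c_ > 0) return(diag(3))
    # opposite vectors: rotate pi about any axis orthogonal to u
    o <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(u[2] * o[3] - u[3] * o[2],
            u[3] * o[1] - u[1] * o[3],
            u[1] * o[2] - u[2] * o[1])
    ax <- ax / sqrt(sum(ax^2))
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    return(diag(3) + 2 * K %*% K)
  }
  ax <- ax / s
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + s * K + (1 - c_) * K %*% K
}

# ---- primitives ------------------------------------------------------------

#' Mesh primitives
#'
#' Axis-aligned boxes, cubes and icospheres used throughout the tests and as
#' analytic references.
#'
#' @param edge cube edge length (cm).
#' @param origin corner of the cube/box at this point.
#' @return A closed, outward-oriented [tri_mesh()].
#' @export
mesh_cube <- function(edge = 1, origin = c(0, 0, 0)) {
  mesh_box(lower = origin, upper = origin + edge)
}

#' @rdname mesh_cube
#' @param lower,upper opposite corners of the box.
#' @export
mesh_box <- function(lower = c(0, 0, 0), upper = c(1, 1, 1)) {
  g <- as.matrix(expand.grid(x = c(lower[1], upper[1]),
                             y = c(lower[2], upper[2]),
                             z = c(lower[3], upper[3])))
  # vertex order: (x fastest) 1:(-,-,-) 2:(+,-,-) 3:(-,+,-) 4:(+,+,-)
  #               5:(-,-,+) 6:(+,-,+) 7:(-,+,+) 8:(+,+,+)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # bottom (z-)
    c(5, 6, 7), c(6, 8, 7),   # top (z+)
    c(1, 2, 5), c(2, 6, 5),   # y-
    c(3, 7, 4), c(4, 7, 8),   # y+
    c(1, 5, 3), c(3, 5, 7),   # x-
    c(2, 4, 6), c(4, 8, 6))   # x+
  tri_mesh(g, f)
}

#' @rdname mesh_cube
#' @param radius sphere radius (cm).
#' @param subdivisions icosahedron subdivision level (faces = 20 * 4^s).
#' @param center sphere center.
#' @export
mesh_icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    ekey <- new.env(hash = TRUE, parent = emptyenv())
    vlist <- list(v)
    midpoint <- function(i, j) {
      k <- paste(min(i, j), max(i, j))
      id <- ekey[[k]]
      if (!is.null(id)) return(id)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      vlist[[length(vlist) + 1L]] <<- matrix(p, 1)
      nv <<- nv + 1L
      ekey[[k]] <- nv
      nv
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[(i - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  tri_mesh(sweep(v * radius, 2, center, "+"), f)
}
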