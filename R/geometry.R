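#' Reference parameters for the *Rudarius ercodes* model
#'
#' Physical constants and observed values used as study conditions throughout
#' the package: model dimensions, body mass, artificial-seawater properties at
#' 24 degrees C, the slow/fast fin frequencies, the measured swimming speeds,
#' and the cycle counts needed to reach them for the closed and full-open
#' caudal-fin configurations. The two published surface areas of the authors'
#' closed and full-open meshes are carried as metadata only (they depend on a
#' mesh that is not reproduced here).
#'
#' @return A named list of constants (SI units; speeds in BL/s).
#' @export
rercodes_reference <- function() {
  list(
    total_length = 0.057,        # m
    total_width  = 0.007,        # m
    total_height = 0.040,        # m
    mass         = 0.0026,       # kg
    rho          = 1023.6881,    # kg/m^3, artificial seawater, 24 C
    nu           = 9.5818e-7,    # m^2/s
    body_length_small = 0.045,   # m, smaller observed individual
    f_slow = 10, f_fast = 29, f_avg = 14,           # Hz
    u_e_slow = 0.73, u_e_fast = 2.68,               # BL/s
    cycles_to_ue = list(
      f10 = c(closed = 11.4, full_open = 14.9),
      f29 = c(closed = 11.7, full_open = 13.8)
    ),
    caudal_presets = c(closed = 5, open30 = 30, open60 = 60, full_open = 100),
    reynolds_avg = 4637,
    # metadata only, not asserted against this package's meshes:
    published_area = c(closed = 2.47e-3, full_open = 2.18e-3)  # m^2
  )
}

#' Build the parametric swimmer geometry
#'
#' Constructs a watertight triangulated surface model of a deep-bodied
#' balistiform swimmer: an ellipsoidal body, thin dorsal and anal fin strips
#' whose rays undulate, and a caudal fin made of two rounded lobes folded
#' symmetrically about the peduncle axis by half the opening angle each.
#' Closed (small `open_angle`) collapses the lobes onto the vertical midplane;
#' opening folds them laterally out of it, which leaves the overall width
#' unchanged (the lobes stay inside the body width).
#'
#' The mesh is a union of closed component shells; every edge of every shell
#' is shared by exactly two triangles, and each triangle carries a region tag
#' in `{body, dorsal_fin, anal_fin, caudal_fin}`.
#'
#' @param length,width,height Overall bounding dimensions, m. Defaults are the
#'   57 x 7 x 40 mm *R. ercodes* model.
#' @param open_angle Caudal-fin opening angle phi in degrees, in `[0, 180)`.
#'   Presets observed or modeled: 5 (closed), 30, 60, 100 (full-open).
#' @param mass Body mass, kg.
#' @param resolution Integer mesh-refinement level (>= 1); element count grows
#'   quadratically with it.
#' @return An object of class `swimmer_geometry`: list with `vertices`
#'   (n x 3, m), `triangles` (m x 3, 1-based), `region` (per-triangle factor),
#'   `vertex_region`, dimension fields, `open_angle`, `mass`, `fin_height`
#'   (`H`, base line to free edge), `fin_base_z`, `fin_span` (x-interval of
#'   the undulating fin base), `caudal` (lobe span, root chord, peduncle x).
#' @examples
#' g <- build_swimmer_geometry(open_angle = 5, resolution = 2)
#' surface_area(g)
#' @export
build_swimmer_geometry <- function(length = 0.057, width = 0.007,
                                   height = 0.040, open_angle = 5,
                                   mass = 0.0026, resolution = 4) {
  if (any(c(length, width, height, mass) <= 0))
    stop("invalid geometry spec: dimensions and mass must be positive")
  if (open_angle < 0 || open_angle >= 180)
    stop("invalid geometry spec: 'open_angle' must lie in [0, 180) degrees")
  resolution <- as.integer(resolution)
  if (resolution < 1) stop("invalid geometry spec: 'resolution' must be >= 1")

  L <- length; W <- width; Hgt <- height
  sc <- L / 0.057                       # proportional scaling of the layout
  body_len <- 0.92 * L
  body_h   <- 0.35 * Hgt                # body depth; fins supply the rest
  caudal_root_chord <- 0.14 * L
  caudal_span <- 0.0042 * sc            # lobe half-span R about the axis
  x_ped <- L - caudal_root_chord
  fin_span <- c(0.25, 0.78) * L
  fin_base_z <- 0.8 * body_h / 2
  fin_thick <- 0.0006 * sc
  n <- resolution

  shells <- list()
  # body: lat-long ellipsoid, closed at the poles
  shells$body <- .ellipsoid_mesh(center = c(body_len / 2, 0, 0),
                                 semi = c(body_len / 2, W / 2, body_h / 2),
                                 n_lon = 8 * n, n_lat = 4 * n)
  # dorsal / anal fin strips: thin vertical slabs
  zt <- Hgt / 2
  for (fin in c("dorsal_fin", "anal_fin")) {
    sgn <- if (fin == "dorsal_fin") 1 else -1
    xs <- seq(fin_span[1], fin_span[2], length.out = 8 * n + 1)
    zs <- sgn * seq(fin_base_z, zt, length.out = 2 * n + 1)
    grid <- expand.grid(x = xs, z = zs)
    P <- cbind(grid$x, 0, grid$z)
    shells[[fin]] <- .slab_mesh(P, nu = length(xs), nv = length(zs),
                                normal = c(0, 1, 0), thickness = fin_thick)
  }
  # caudal lobes: through-axis rounded plates rotated +-phi/2 about the x-axis
  phi2 <- open_angle / 2 * pi / 180
  for (k in c(1, -1)) {
    dvec <- c(0, sin(k * phi2), cos(k * phi2))   # in-plate transverse dir
    nvec <- c(0, -dvec[3], dvec[2])              # plate normal
    ss <- seq(-caudal_span, caudal_span, length.out = 4 * n + 1)
    cf <- seq(0, 1, length.out = 2 * n + 1)
    chord <- caudal_root_chord *
      sqrt(pmax(1 - (ss / caudal_span)^2, 0.15^2))
    P <- matrix(0, (4 * n + 1) * (2 * n + 1), 3)
    i <- 1
    for (zz in seq_along(cf)) {
      for (si in seq_along(ss)) {
        P[i, ] <- c(x_ped + cf[zz] * chord[si], 0, 0) + ss[si] * dvec
        i <- i + 1
      }
    }
    nm <- paste0("caudal_fin", if (k == 1) "_a" else "_b")
    shells[[nm]] <- .slab_mesh(P, nu = 4 * n + 1, nv = 2 * n + 1,
                               normal = nvec, thickness = fin_thick)
  }

  verts <- NULL; tris <- NULL; region <- character(0); vreg <- character(0)
  for (nm in names(shells)) {
    sh <- shells[[nm]]
    tag <- sub("_[ab]$", "", nm)
    off <- if (is.null(verts)) 0L else nrow(verts)
    verts <- rbind(verts, sh$vertices)
    tris <- rbind(tris, sh$triangles + off)
    region <- c(region, rep(tag, nrow(sh$triangles)))
    vreg <- c(vreg, rep(tag, nrow(sh$vertices)))
  }
  structure(
    list(vertices = verts, triangles = tris,
         region = factor(region,
                         levels = c("body", "dorsal_fin", "anal_fin",
                                    "caudal_fin")),
         vertex_region = vreg,
         total_length = L, total_width = W, total_height = Hgt,
         open_angle = open_angle, mass = mass,
         fin_height = zt - fin_base_z, fin_base_z = fin_base_z,
         fin_span = fin_span,
         caudal = list(span = caudal_span, root_chord = caudal_root_chord,
                       x_peduncle = x_ped),
         resolution = resolution),
    class = "swimmer_geometry"
  )
}

#' @export
print.swimmer_geometry <- function(x, ...) {
  cat(sprintf(
    "swimmer geometry: %.3g x %.3g x %.3g m, caudal fin %g deg open\n",
    x$total_length, x$total_width, x$total_height, x$open_angle))
  cat(sprintf("  %d vertices, %d triangles (%s)\n", nrow(x$vertices),
              nrow(x$triangles),
              paste(levels(x$region), table(x$region), collapse = ", ")))
  invisible(x)
}

# closed lat-long ellipsoid
.ellipsoid_mesh <- function(center, semi, n_lon, n_lat) {
  # interior rings plus two pole vertices
  lat <- seq(0, pi, length.out = n_lat + 1)[2:n_lat]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  ring <- function(phi) {
    cbind(center[1] + semi[1] * cos(phi),
          center[2] + semi[2] * sin(phi) * cos(lon),
          center[3] + semi[3] * sin(phi) * sin(lon))
  }
  verts <- do.call(rbind, lapply(lat, ring))
  north <- center + c(semi[1], 0, 0)
  south <- center - c(semi[1], 0, 0)
  verts <- rbind(verts, north, south)
  iN <- nrow(verts) - 1L; iS <- nrow(verts)
  idx <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  tris <- list()
  for (j in seq_len(n_lon)) {                   # pole fans
    tris[[length(tris) + 1L]] <- c(iN, idx(1, j), idx(1, j + 1))
    tris[[length(tris) + 1L]] <- c(iS, idx(n_lat - 1, j + 1), idx(n_lat - 1, j))
  }
  for (i in seq_len(n_lat - 2)) {               # band quads
    for (j in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i, j + 1); cc <- idx(i + 1, j + 1); d <- idx(i + 1, j)
      tris[[length(tris) + 1L]] <- c(a, b, cc)
      tris[[length(tris) + 1L]] <- c(a, cc, d)
    }
  }
  list(vertices = verts, triangles = do.call(rbind, tris))
}

# closed thin slab: mid-surface grid P (nu x nv, row-major in u), offset both
# ways along 'normal', side walls stitched around the boundary
.slab_mesh <- function(P, nu, nv, normal, thickness) {
  nrm <- normal / sqrt(sum(normal^2))
  off <- matrix(nrm, nrow(P), 3, byrow = TRUE) * (thickness / 2)
  verts <- rbind(P + off, P - off)
  ntop <- nrow(P)
  id <- function(u, v) (v - 1L) * nu + u        # top sheet index
  tris <- list()
  for (v in seq_len(nv - 1)) {
    for (u in seq_len(nu - 1)) {
      a <- id(u, v); b <- id(u + 1, v); cc <- id(u + 1, v + 1); d <- id(u, v + 1)
      tris[[length(tris) + 1L]] <- c(a, b, cc)       # top
      tris[[length(tris) + 1L]] <- c(a, cc, d)
      tris[[length(tris) + 1L]] <- c(a, cc, b) + ntop  # bottom, reversed
      tris[[length(tris) + 1L]] <- c(a, d, cc) + ntop
    }
  }
  # boundary ring (counter-clockwise around the grid edge)
  ring <- c(id(seq_len(nu), 1L),
            id(nu, seq(2L, nv)),
            id(seq(nu - 1L, 1L), nv),
            id(1L, seq(nv - 1L, 2L)))
  m <- length(ring)
  for (k in seq_len(m)) {
    a <- ring[k]; b <- ring[k %% m + 1L]
    tris[[length(tris) + 1L]] <- c(a, b, b + ntop)
    tris[[length(tris) + 1L]] <- c(a, b + ntop, a + ntop)
  }
  list(vertices = verts, triangles = do.call(rbind, tris))
}

#' Total surface area of a triangulated mesh
#'
#' Sum of the triangle areas computed from cross products. Degenerate
#' (zero-area) triangles are excluded with a warning.
#'
#' @param mesh A `swimmer_geometry` object, or any list with `vertices` and
#'   `triangles`.
#' @return Surface area in m^2.
#' @export
surface_area <- function(mesh) {
  a <- triangle_areas(mesh)
  degen <- a <= .Machine$double.eps * max(a, 1)
  if (any(degen)) {
    warning(sprintf("%d degenerate zero-area triangles excluded", sum(degen)))
    a <- a[!degen]
  }
  sum(a)
}

#' Per-triangle areas of a mesh
#' @inheritParams surface_area
#' @return Numeric vector of areas, m^2.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - p1
  e2 <- v[tr[, 3], , drop = FALSE] - p1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Check that every mesh edge is shared by exactly two triangles
#' @inheritParams surface_area
#' @return `TRUE` if watertight, otherwise `FALSE` (with the offending edge
#'   count as attribute `"bad_edges"`).
#' @export
is_watertight <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  ok <- all(tab == 2L)
  structure(ok, bad_edges = sum(tab != 2L))
}

#' Axis-aligned bounding box of a mesh
#' @inheritParams surface_area
#' @return 2 x 3 matrix (rows min/max; columns x, y, z).
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min),
        max = apply(mesh$vertices, 2, max))
}

#' Planar (cut-plane) analogue of the swimmer
#'
#' Intersects the swimmer mesh with the horizontal plane `z = z_cut` and
#' reports the in-plane chords that define the two-dimensional solver
#' analogue: the body chord, the x-span of the undulating fin, and the
#' projected caudal-fin chord together with the lateral offset of the folded
#' lobes. Folding the caudal fin out of the cut plane (opening it) samples
#' the rounded lobe farther from the axis, so the in-plane caudal chord is
#' non-increasing in the opening angle.
#'
#' @param mesh A `swimmer_geometry` object.
#' @param z_cut Cut height, m; must lie within the mesh z-extent.
#' @return An object of class `planar_analogue`: list with `body_chord`,
#'   `fin_edge_span` (x-interval or `NULL`), `caudal_chord`, `caudal_offset`
#'   (lateral distance of each lobe's cut from the midline), `z_cut`.
#' @export
planar_analogue <- function(mesh, z_cut) {
  stopifnot(inherits(mesh, "swimmer_geometry"))
  bb <- mesh_bbox(mesh)
  if (z_cut < bb["min", 3] || z_cut > bb["max", 3])
    stop("z_cut outside the mesh z-extent")
  xr <- function(tags) .plane_cut_xrange(mesh, z_cut, tags)
  body <- xr("body")
  fin <- xr("dorsal_fin")
  caud <- xr("caudal_fin")
  caudal_chord <- if (is.null(caud)) 0 else diff(caud$range)
  if (is.null(caud))
    warning("cut plane misses the caudal fin; caudal_chord set to 0")
  structure(
    list(body_chord = if (is.null(body)) 0 else diff(body$range),
         fin_edge_span = if (is.null(fin)) NULL else fin$range,
         caudal_chord = caudal_chord,
         caudal_offset = if (is.null(caud)) NA_real_ else caud$mean_abs_y,
         z_cut = z_cut),
    class = "planar_analogue"
  )
}

#' @export
print.planar_analogue <- function(x, ...) {
  cat(sprintf(
    "planar analogue at z = %g m: body chord %.4g m, caudal chord %.4g m (offset %.4g m)\n",
    x$z_cut, x$body_chord, x$caudal_chord,
    if (is.na(x$caudal_offset)) 0 else x$caudal_offset))
  invisible(x)
}

# x-range and mean |y| of the intersection of tagged triangles with z = z_cut
.plane_cut_xrange <- function(mesh, z_cut, tags) {
  keep <- mesh$region %in% tags
  if (!any(keep)) return(NULL)
  tr <- mesh$triangles[keep, , drop = FALSE]
  v <- mesh$vertices
  pts_x <- numeric(0); pts_y <- numeric(0)
  for (i in seq_len(nrow(tr))) {
    p <- v[tr[i, ], , drop = FALSE]
    z <- p[, 3] - z_cut
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      z1 <- z[e[1]]; z2 <- z[e[2]]
      if ((z1 <= 0 && z2 >= 0 || z1 >= 0 && z2 <= 0) && z1 != z2) {
        w <- z1 / (z1 - z2)
        pts_x <- c(pts_x, p[e[1], 1] + w * (p[e[2], 1] - p[e[1], 1]))
        pts_y <- c(pts_y, p[e[1], 2] + w * (p[e[2], 2] - p[e[1], 2]))
      }
    }
  }
  if (!length(pts_x)) return(NULL)
  list(range = range(pts_x), mean_abs_y = mean(abs(pts_y)))
}

#' Write a mesh as ASCII STL
#' @inheritParams surface_area
#' @param path Output file path.
#' @param name Solid name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "swimmer") {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(tr))) {
    p <- v[tr[i, ], , drop = FALSE]
    e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeLines(c(sprintf("  facet normal %e %e %e", nrm[1], nrm[2], nrm[3]),
                 "    outer loop",
                 sprintf("      vertex %e %e %e", p[, 1], p[, 2], p[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Write a surface mesh as legacy ASCII VTK (PolyData)
#' @inheritParams write_stl
#' @return `path`, invisibly.
#' @export
write_vtk_surface <- function(mesh, path, name = "swimmer") {
  v <- mesh$vertices; tr <- mesh$triangles - 1L
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%e %e %e", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4L * nrow(tr)), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  if (!is.null(mesh$region)) {
    writeLines(c(sprintf("CELL_DATA %d", nrow(tr)),
                 "SCALARS region int 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%d", as.integer(mesh$region)), con)
  }
  invisible(path)
}
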