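# independent oracles used across the test files

# brute-force surface area: explicit per-triangle cross product loop
brute_force_area <- function(mesh) {
  total <- 0
  for (i in seq_len(nrow(mesh$triangles))) {
    p <- mesh$vertices[mesh$triangles[i, ], , drop = FALSE]
    e1 <- p[2, ] - p[1, ]
    e2 <- p[3, ] - p[1, ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    total <- total + 0.5 * sqrt(sum(cr^2))
  }
  total
}

# closed lat-long unit sphere mesh (independent of the package builders)
sphere_mesh <- function(n_lat, n_lon, radius = 1) {
  lat <- seq(0, pi, length.out = n_lat + 1)[2:n_lat]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  verts <- do.call(rbind, lapply(lat, function(phi)
    cbind(radius * sin(phi) * cos(lon), radius * sin(phi) * sin(lon),
          radius * cos(phi))))
  verts <- rbind(verts, c(0, 0, radius), c(0, 0, -radius))
  iN <- nrow(verts) - 1L; iS <- nrow(verts)
  idx <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  tris <- list()
  for (j in seq_len(n_lon)) {
    tris[[length(tris) + 1L]] <- c(iN, idx(1, j), idx(1, j + 1))
    tris[[length(tris) + 1L]] <- c(iS, idx(n_lat - 1, j + 1), idx(n_lat - 1, j))
  }
  for (i in seq_len(n_lat - 2)) for (j in seq_len(n_lon)) {
    a <- idx(i, j); b <- idx(i, j + 1); cc <- idx(i + 1, j + 1); d <- idx(i + 1, j)
    tris[[length(tris) + 1L]] <- c(a, b, cc)
    tris[[length(tris) + 1L]] <- c(a, cc, d)
  }
  list(vertices = verts, triangles = do.call(rbind, tris))
}

# unit cube as a closed triangulated mesh (12 triangles)
cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  tr <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = side
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = side
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = side
  list(vertices = v, triangles = tr)
}

# tiny deterministic propulsion config for fast end-to-end runs
small_case <- function(preset = "closed", n_cycles = 1, nx = 96, ny = 48,
                       steps_per_cycle = 100) {
  cfg <- gen_paper_case(preset, f = 10, scale = "reduced",
                        n_cycles = n_cycles, nx = nx, ny = ny)
  cfg$timestepping$steps_per_cycle <- steps_per_cycle
  cfg
}
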