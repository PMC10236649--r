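# Shared fixtures, built once per test run. Everything is generated in
# code; meshes are small unless a test needs voxel-scale realism.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env, inherits = FALSE)
}

base_shape_fixture <- function(resolution = 2) {
  memo(paste0("base_", resolution), make_base_shape(resolution))
}

# a unit tetrahedron mesh (watertight)
tetra_mesh <- function(scale = 1) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * scale
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f)
}

# an axis-aligned cube [0, s]^3 with outward orientation
cube_mesh <- function(s = 1) {
  v <- as.matrix(expand.grid(x = c(0, s), y = c(0, s), z = c(0, s)))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = s
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = s
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6)   # x = s
  )
  triangle_mesh(v, f)
}

# icosphere by subdividing an icosahedron, radius r
icosphere_mesh <- function(r = 1, subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_key <- new.env(parent = emptyenv())
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      got <- edge_key[[key]]
      if (!is.null(got)) return(got)
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      edge_key[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- mid(a, b); bc <- mid(b, c3); ca <- mid(c3, a)
      nf[4 * t - 3, ] <- c(a, ab, ca)
      nf[4 * t - 2, ] <- c(b, bc, ab)
      nf[4 * t - 1, ] <- c(c3, ca, bc)
      nf[4 * t, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  triangle_mesh(v * r, f)
}

sphere_fixture <- function(r = 20, subdiv = 3) {
  memo(paste0("sphere_", r, "_", subdiv), icosphere_mesh(r, subdiv))
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}
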