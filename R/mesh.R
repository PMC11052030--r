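#' Build a closed triangulated membrane mesh (icosphere)
#'
#' Recursively subdivides an icosahedron and projects vertices onto a sphere
#' of the given radius, yielding a near-uniform closed 2-manifold.  The
#' per-edge equilibrium length \code{l0}, the per-face reference areas, and
#' the total reference area \code{A0} and volume \code{V0} are taken from
#' the built geometry.  Faces are consistently outward-oriented (positive
#' enclosed volume).
#'
#' @param radius sphere radius (reduced length); the model cell radius is 8.
#' @param level subdivision level (0 = icosahedron; F = 20 * 4^level).
#' @param center sphere centre.
#' @return object of class \code{membrane_mesh}: list with \code{vertices}
#'   (V x 3), \code{edges} (E x 2), \code{faces} (F x 3), \code{l0},
#'   \code{face_a0}, \code{A0}, \code{V0}, and per-edge dihedral quadruples
#'   \code{dihedrals} (E x 4: opposite vertex, edge i, edge j, opposite
#'   vertex) with built angles \code{dihedral0}.
#' @export
build_membrane_mesh <- function(radius = 8, level = 3, center = c(0, 0, 0)) {
  stopifnot(level >= 0, radius > 0)
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

  for (lv in seq_len(level)) {
    cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- vector("list", 4 * nrow(f))
    newf <- matrix(0L, 4 * nrow(f), 3)
    extra <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      extra[[length(extra) + 1L]] <<- m
      idx <- nv + length(extra)
      cache[[key]] <- idx
      idx
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * t - 3, ] <- c(a, ab, ca)
      newf[4 * t - 2, ] <- c(b, bc, ab)
      newf[4 * t - 1, ] <- c(cc, ca, bc)
      newf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, extra))
    f <- newf
  }

  v <- v * radius
  v <- sweep(v, 2, center, "+")

  # orient every face outward (positive signed volume contribution)
  ctr <- colMeans(v)
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ] - ctr; b <- v[f[t, 2], ] - ctr; cc <- v[f[t, 3], ] - ctr
    if (sum(a * .cross3(b - a, cc - a)) < 0) f[t, ] <- f[t, c(1, 3, 2)]
  }

  e <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1, sort)))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  storage.mode(e) <- "integer"
  storage.mode(f) <- "integer"

  mesh <- structure(list(vertices = v, edges = e, faces = f), class = "membrane_mesh")
  geo <- mesh_geometry(mesh, v)
  mesh$l0 <- geo$edge_len
  mesh$face_a0 <- geo$face_area
  mesh$A0 <- geo$area
  mesh$V0 <- geo$volume
  dq <- .edge_dihedrals(mesh)
  mesh$dihedrals <- dq$quad
  mesh$dihedral0 <- dq$angle0
  mesh
}

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

#' Geometry of a triangulated mesh at given vertex positions
#'
#' @param mesh a \code{membrane_mesh}.
#' @param pos V x 3 vertex positions (defaults to the built vertices).
#' @return list with \code{edge_len}, \code{face_area}, total \code{area}
#'   and signed enclosed \code{volume}.
#' @export
mesh_geometry <- function(mesh, pos = mesh$vertices) {
  d <- pos[mesh$edges[, 1], , drop = FALSE] - pos[mesh$edges[, 2], , drop = FALSE]
  elen <- sqrt(rowSums(d^2))
  a <- pos[mesh$faces[, 1], , drop = FALSE]
  b <- pos[mesh$faces[, 2], , drop = FALSE]
  cc <- pos[mesh$faces[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  nx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  ny <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  nz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  farea <- 0.5 * sqrt(nx^2 + ny^2 + nz^2)
  vol <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
             a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
             a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  list(edge_len = elen, face_area = farea, area = sum(farea), volume = vol)
}

#' Check the closed-manifold invariants of a mesh
#'
#' Every edge must be shared by exactly two faces and the Euler
#' characteristic V - E + F must equal 2 (sphere topology); the enclosed
#' volume must be positive (outward orientation).
#'
#' @param mesh a \code{membrane_mesh}.
#' @return TRUE invisibly; errors otherwise.
#' @export
check_mesh <- function(mesh) {
  V <- nrow(mesh$vertices); E <- nrow(mesh$edges); F <- nrow(mesh$faces)
  if (V - E + F != 2) stop("Euler characteristic is ", V - E + F, ", not 2")
  ekey <- paste(pmin(mesh$edges[, 1], mesh$edges[, 2]),
                pmax(mesh$edges[, 1], mesh$edges[, 2]))
  fe <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  fkey <- paste(pmin(fe[, 1], fe[, 2]), pmax(fe[, 1], fe[, 2]))
  cnt <- table(fkey)
  if (!all(cnt == 2)) stop("mesh is not a closed 2-manifold")
  if (!setequal(names(cnt), ekey)) stop("edge list does not match faces")
  if (mesh_geometry(mesh)$volume <= 0) stop("mesh volume is not positive")
  invisible(TRUE)
}

# Per-edge dihedral quadruples (k, i, j, l): k and l are the vertices
# opposite edge (i, j) in its two adjacent faces.  angle0 is the dihedral
# angle of the built mesh (the relaxed sphere's spontaneous curvature).
.edge_dihedrals <- function(mesh) {
  f <- mesh$faces
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  opp <- new.env(hash = TRUE)
  addopp <- function(i, j, k) {
    kk <- key(i, j)
    opp[[kk]] <- c(opp[[kk]], k)
  }
  for (t in seq_len(nrow(f))) {
    addopp(f[t, 1], f[t, 2], f[t, 3])
    addopp(f[t, 2], f[t, 3], f[t, 1])
    addopp(f[t, 3], f[t, 1], f[t, 2])
  }
  E <- nrow(mesh$edges)
  quad <- matrix(0L, E, 4)
  for (eidx in seq_len(E)) {
    i <- mesh$edges[eidx, 1]; j <- mesh$edges[eidx, 2]
    kl <- opp[[key(i, j)]]
    quad[eidx, ] <- c(kl[1], i, j, kl[2])
  }
  angle0 <- vapply(seq_len(E), function(eidx)
    dihedral_angle(mesh$vertices[quad[eidx, 1], ], mesh$vertices[quad[eidx, 2], ],
                   mesh$vertices[quad[eidx, 3], ], mesh$vertices[quad[eidx, 4], ]),
    numeric(1))
  list(quad = quad, angle0 = angle0)
}

#' Dihedral angle of four points
#'
#' Signed angle between the planes (p1,p2,p3) and (p2,p3,p4), by the
#' atan2 construction used in molecular simulation.
#'
#' @param p1,p2,p3,p4 length-3 positions.
#' @return angle in radians, in (-pi, pi].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c1 <- .cross3(b1, b2); c2 <- .cross3(b2, b3)
  atan2(sqrt(sum(b2^2)) * sum(b1 * c2), sum(c1 * c2))
}

#' Write a mesh to OFF format
#'
#' @param mesh a \code{membrane_mesh}.
#' @param path output file.
#' @param pos optional vertex positions overriding the built ones.
#' @export
write_off <- function(mesh, path, pos = mesh$vertices) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(pos), nrow(mesh$faces)), con)
  writeLines(apply(pos, 1, function(p) paste(format(p, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(f) paste(c(3, f), collapse = " ")), con)
  invisible(path)
}

#' Read an OFF mesh
#'
#' @param path OFF file written by \code{\link{write_off}}.
#' @return a \code{membrane_mesh} (geometry fields recomputed).
#' @export
read_off <- function(path) {
  ln <- readLines(path)
  stopifnot(ln[1] == "OFF")
  hd <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- hd[1]; nf <- hd[2]
  v <- do.call(rbind, lapply(ln[3:(2 + nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  f <- do.call(rbind, lapply(ln[(3 + nv):(2 + nv + nf)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]])[2:4] + 1L))
  e <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1, sort)))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  storage.mode(e) <- "integer"
  mesh <- structure(list(vertices = v, edges = e, faces = f),
                    class = "membrane_mesh")
  geo <- mesh_geometry(mesh)
  mesh$l0 <- geo$edge_len; mesh$face_a0 <- geo$face_area
  mesh$A0 <- geo$area; mesh$V0 <- geo$volume
  dq <- .edge_dihedrals(mesh)
  mesh$dihedrals <- dq$quad; mesh$dihedral0 <- dq$angle0
  mesh
}

#' @export
print.membrane_mesh <- function(x, ...) {
  cat("membrane_mesh: V =", nrow(x$vertices), " E =", nrow(x$edges),
      " F =", nrow(x$faces), "\n")
  cat("A0 =", signif(x$A0, 6), " V0 =", signif(x$V0, 6),
      " mean l0 =", signif(mean(x$l0), 4), "\n")
  invisible(x)
}
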