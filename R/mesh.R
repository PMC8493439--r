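# Triangulated surface meshes: construction, ASCII OFF input/output,
# edge adjacency, and iterative neighbor-mean smoothing of vertex fields.

#' Construct a surface mesh
#'
#' Builds a triangulated surface mesh object with a precomputed, symmetric,
#' edge-connected vertex adjacency list. Vertices are 1-indexed.
#'
#' @param vertices Numeric matrix, one row per vertex, 3 columns (x, y, z).
#' @param faces Integer matrix, one row per triangle, 3 columns of vertex
#'   indices.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `adjacency` (list of integer neighbor vectors) and `edges`
#'   (2-column matrix of unique undirected edges).
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must have 3 columns")
  nv <- nrow(vertices)
  if (nv < 3 || nrow(faces) < 1) stop("mesh must have >= 3 vertices and >= 1 face")
  if (any(faces < 1) || any(faces > nv))
    stop("faces index vertices outside 1..", nv)
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(nv)))
  adj <- lapply(adj, function(x) sort(unique(as.integer(x))))
  structure(list(vertices = vertices, faces = faces,
                 adjacency = adj, edges = e),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Number of vertices in a mesh
#' @param mesh A `surface_mesh`.
#' @return Integer vertex count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Read an ASCII OFF mesh file
#'
#' @param path Path to an OFF file (triangular faces only).
#' @return A `surface_mesh`.
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  body <- scan(text = paste(lines[-(1:2)], collapse = "\n"), quiet = TRUE)
  verts <- matrix(body[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  rest <- body[-seq_len(3 * nv)]
  fm <- matrix(rest[seq_len(4 * nf)], ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3)) stop("only triangular faces are supported")
  surface_mesh(verts, fm[, 2:4] + 1L)
}

#' Write an ASCII OFF mesh file
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    paste(formatC(v, format = "g", digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(f)
    paste(c(3L, f), collapse = " ")), con)
  invisible(path)
}

#' Icosphere mesh
#'
#' Generates a geodesic sphere by repeated midpoint subdivision of a regular
#' icosahedron, projecting each new vertex onto the unit sphere. Subdivision
#' levels 0, 1, 2, 3 give 12, 42, 162 and 642 vertices; the 642-vertex level
#' is a convenient stand-in for a (decimated) cortical hemisphere surface.
#'
#' @param subdivisions Number of subdivision passes (non-negative integer).
#' @param radius Sphere radius (mm).
#' @return A `surface_mesh`.
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
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
  normalize <- function(m) m / sqrt(rowSums(m^2))
  v <- normalize(v)
  for (s in seq_len(subdivisions)) {
    midpoint <- new.env(hash = TRUE)
    verts <- v
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midpoint[[key]]
      if (is.null(idx)) {
        m <- (verts[a, ] + verts[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        verts <<- rbind(verts, m)
        idx <- nrow(verts)
        midpoint[[key]] <- idx
      }
      idx
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(cc, ca, bc)
      nf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- verts; f <- nf
  }
  surface_mesh(v * radius, f)
}

# Sparse row-stochastic smoothing operator S = (I + A) row-normalized.
.mesh_smoother <- function(mesh) {
  nv <- n_vertices(mesh)
  e <- mesh$edges
  S <- Matrix::sparseMatrix(i = c(seq_len(nv), e[, 1], e[, 2]),
                            j = c(seq_len(nv), e[, 2], e[, 1]),
                            x = 1, dims = c(nv, nv))
  Matrix::Diagonal(x = 1 / Matrix::rowSums(S)) %*% S
}

#' Smooth vertex fields on a mesh
#'
#' Applies `iterations` passes of neighbor-mean smoothing (each vertex is
#' replaced by the mean of itself and its edge neighbors) to one or more
#' per-vertex fields. This is the package's model of surface smoothing.
#'
#' @param x Numeric vector (one field) or matrix with one column per vertex
#'   (rows are subjects/fields).
#' @param mesh A `surface_mesh`.
#' @param iterations Number of smoothing passes; 0 returns `x` unchanged.
#' @return Smoothed object of the same shape as `x`.
#' @export
smooth_vertex_field <- function(x, mesh, iterations = 1) {
  if (iterations == 0) return(x)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(m) != n_vertices(mesh))
    stop("field length does not match mesh vertex count")
  S <- .mesh_smoother(mesh)
  for (i in seq_len(iterations)) m <- as.matrix(Matrix::tcrossprod(m, S))
  if (vec) drop(m) else m
}

# Mean lag-1 neighbor correlation of per-subject residual fields; used to
# pick a smoothing level for the smooth-noise Monte Carlo null.
.neighbor_correlation <- function(fields, mesh) {
  e <- mesh$edges
  a <- fields[, e[, 1], drop = FALSE]
  b <- fields[, e[, 2], drop = FALSE]
  suppressWarnings(stats::cor(as.vector(a), as.vector(b)))
}
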