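#' Triangulated surface mesh
#'
#' Container for a triangulated cortical surface: vertex coordinates in
#' millimetres (rows of a numeric matrix) and triangular faces given as
#' 1-based vertex-index triples. Coordinates are taken as given, i.e. at the
#' surface the user supplies (typically mid-thickness). One connected
#' hemisphere is analyzed at a time: construction fails on meshes whose edge
#' graph has more than one connected component, so that downstream distance
#' maps are finite everywhere.
#'
#' @param vertices numeric matrix (n x 3) of coordinates in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices`, `faces`, `n_vertices`, and an internal cache environment
#'   used to memoise the geodesic graph and distance matrices.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  n <- nrow(vertices)
  if (any(is.na(vertices))) stop("vertices contain missing values")
  if (any(faces < 1L) || any(faces > n))
    stop("face indices must be in 1..", n)
  ed <- mesh_edges(list(vertices = vertices, faces = faces))
  if (any(ed[, 3] == 0))
    stop("mesh contains zero-length edges")
  g <- igraph::make_graph(t(ed[, 1:2, drop = FALSE]),
                          n = n, directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no != 1L)
    stop("mesh edge graph has ", comp$no,
         " connected components; analyze one hemisphere at a time")
  mesh <- list(vertices = vertices, faces = faces, n_vertices = n,
               .cache = new.env(parent = emptyenv()))
  class(mesh) <- "triangle_mesh"
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", x$n_vertices, "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

# unique undirected edges with Euclidean lengths: columns (i, j, length)
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  cbind(e, len)
}

#' Snap a 3D coordinate to the nearest mesh vertex
#'
#' Injection-site coordinates need not coincide with mesh vertices; this
#' returns the index of the closest vertex (Euclidean) and the snap distance.
#'
#' @param mesh a [triangle_mesh()].
#' @param xyz numeric length-3 coordinate in mm.
#' @return list with `vertex` (1-based index) and `distance_mm`.
#' @export
snap_to_vertex <- function(mesh, xyz) {
  stopifnot(length(xyz) == 3L)
  d2 <- colSums((t(mesh$vertices) - as.numeric(xyz))^2)
  v <- which.min(d2)
  list(vertex = v, distance_mm = sqrt(d2[[v]]))
}

#' Read / write a surface mesh as paired CSV files
#'
#' The plain-text dialect stores `vertices.csv` with columns `x,y,z` (mm) and
#' `faces.csv` with columns `i,j,k` holding 0-based vertex indices (converted
#' to R's 1-based indexing on read).
#'
#' @param vertices_csv,faces_csv file paths.
#' @return [read_surface_csv()] returns a [triangle_mesh()].
#' @export
read_surface_csv <- function(vertices_csv, faces_csv) {
  v <- utils::read.csv(vertices_csv)
  f <- utils::read.csv(faces_csv)
  triangle_mesh(as.matrix(v[, c("x", "y", "z")]),
                as.matrix(f[, c("i", "j", "k")]) + 1L)
}

#' @param mesh a [triangle_mesh()].
#' @rdname read_surface_csv
#' @export
write_surface_csv <- function(mesh, vertices_csv, faces_csv) {
  v <- as.data.frame(mesh$vertices)
  names(v) <- c("x", "y", "z")
  f <- as.data.frame(mesh$faces - 1L)
  names(f) <- c("i", "j", "k")
  utils::write.csv(v, vertices_csv, row.names = FALSE)
  utils::write.csv(f, faces_csv, row.names = FALSE)
  invisible(c(vertices_csv, faces_csv))
}
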