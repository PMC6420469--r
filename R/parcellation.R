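#' Surface parcellation
#'
#' Per-vertex integer area labels plus an id-to-name table, modelled on
#' atlas parcellations such as the 91-area M132 macaque atlas. Every vertex
#' must carry a label and every label must have a name; every named area that
#' appears in the labels has at least one vertex.
#'
#' @param labels integer vector, one non-negative area id per vertex.
#' @param names named character vector or data.frame with columns
#'   `label_id`, `name` mapping area ids to area names.
#' @return object of class `parcellation` with elements `labels` (integer
#'   vector) and `names` (named character vector, names = ids).
#' @export
parcellation <- function(labels, names) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be non-negative integers for every vertex")
  if (is.data.frame(names)) {
    nm <- as.character(names$name)
    base::names(nm) <- as.character(names$label_id)
    names <- nm
  }
  if (is.null(base::names(names)))
    stop("`names` must map area ids to area names")
  missing_ids <- setdiff(unique(labels), as.integer(base::names(names)))
  if (length(missing_ids))
    stop("labels reference area ids without names: ",
         paste(missing_ids, collapse = ", "))
  p <- list(labels = labels, names = names)
  class(p) <- "parcellation"
  p
}

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation:", length(x$labels), "vertices,",
      length(unique(x$labels)), "areas\n")
  invisible(x)
}

#' Area ids present in a parcellation
#' @param parc a [parcellation()].
#' @return sorted integer vector of area ids.
#' @export
area_ids <- function(parc) sort(unique(parc$labels))

#' Vertices of one area
#' @param parc a [parcellation()].
#' @param area_id integer area id.
#' @return integer vector of 1-based vertex indices.
#' @export
area_vertices <- function(parc, area_id) {
  v <- which(parc$labels == area_id)
  if (!length(v)) stop("unknown or empty area id: ", area_id)
  v
}

#' Resolve area names to ids
#' @param parc a [parcellation()].
#' @param x character area names or integer ids.
#' @return integer area ids.
#' @export
resolve_areas <- function(parc, x) {
  if (is.numeric(x)) {
    ids <- as.integer(x)
  } else {
    hit <- match(as.character(x), parc$names)
    if (anyNA(hit))
      stop("unknown area name(s): ", paste(x[is.na(hit)], collapse = ", "),
           "; known: ", paste(parc$names, collapse = ", "))
    ids <- as.integer(names(parc$names)[hit])
  }
  bad <- setdiff(ids, unique(parc$labels))
  if (length(bad)) stop("area id(s) not in parcellation: ",
                        paste(bad, collapse = ", "))
  ids
}

#' Border vertices of a set of areas
#'
#' A border vertex of an area is a vertex inside the area with at least one
#' edge-neighbour outside it.
#'
#' @param mesh a [triangle_mesh()].
#' @param parc a [parcellation()].
#' @param region_ids integer area ids.
#' @return integer vector of border vertex indices (union over the areas).
#' @export
region_border_vertices <- function(mesh, parc, region_ids) {
  ed <- mesh_edges(mesh)
  lab <- parc$labels
  out <- integer(0)
  for (id in region_ids) {
    inside <- lab == id
    if (!any(inside)) stop("unknown or empty area id: ", id)
    if (all(inside)) stop("area ", id, " covers the whole mesh: no border")
    cross <- inside[ed[, 1]] != inside[ed[, 2]]
    b <- unique(c(ed[cross, 1], ed[cross, 2]))
    out <- c(out, b[inside[b]])
  }
  sort(unique(out))
}

#' Geodesic distance from the closest border of a region set
#'
#' The spatial predictor of the gradient models: for each vertex, the minimum
#' over the given regions (typically the primary sensory-motor areas) of the
#' geodesic distance to that region's border vertices. Vertices lying inside
#' any of the regions are assigned 0, so the map is anchored at (not signed
#' across) the primary borders.
#'
#' @param mesh a [triangle_mesh()].
#' @param parc a [parcellation()].
#' @param regions integer area ids or character area names.
#' @return numeric per-vertex distance map (mm) with attribute `sources`.
#' @export
distance_from_region_borders <- function(mesh, parc, regions) {
  ids <- resolve_areas(parc, regions)
  border <- region_border_vertices(mesh, parc, ids)
  d <- geodesic_distances(mesh, border)
  d[parc$labels %in% ids] <- 0
  attr(d, "sources") <- ids
  d
}

#' Area centroid (geodesic median)
#'
#' The vertex of an area minimizing the summed geodesic distance to all
#' vertices of that area; ties are broken by the lowest vertex index. Used as
#' the spatial stand-in for labeled neurons whose exact positions within an
#' area are unknown.
#'
#' @param mesh a [triangle_mesh()].
#' @param parc a [parcellation()].
#' @param area_id one area id.
#' @return 1-based vertex index of the centroid.
#' @export
area_centroid <- function(mesh, parc, area_id) {
  v <- area_vertices(parc, area_id)
  if (length(v) == 1L) return(v)
  D <- geodesic_distance_matrix(mesh, from = v)
  tot <- rowSums(D[, v, drop = FALSE])
  v[which.min(tot)]  # which.min takes the first (lowest-index) minimum
}

#' Centroids of all areas
#' @param mesh a [triangle_mesh()].
#' @param parc a [parcellation()].
#' @return named integer vector: area id -> centroid vertex.
#' @export
area_centroids <- function(mesh, parc) {
  ids <- area_ids(parc)
  vapply(ids, function(id) area_centroid(mesh, parc, id), integer(1)) |>
    stats::setNames(ids)
}

#' Mean of a per-vertex map within each area
#' @param parc a [parcellation()].
#' @param values numeric per-vertex vector (NAs are dropped within an area).
#' @return named numeric vector: area id -> mean value.
#' @export
area_means <- function(parc, values) {
  stopifnot(length(values) == length(parc$labels))
  ids <- area_ids(parc)
  out <- vapply(ids, function(id) {
    v <- values[parc$labels == id]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  stats::setNames(out, ids)
}

#' Read / write per-vertex labels as CSV
#'
#' `labels.csv` has columns `vertex_id` (0-based) and `label_id`;
#' `names.csv` has columns `label_id` and `name`.
#'
#' @param labels_csv,names_csv file paths.
#' @return a [parcellation()].
#' @export
read_labels_csv <- function(labels_csv, names_csv) {
  lab <- utils::read.csv(labels_csv)
  nm <- utils::read.csv(names_csv)
  lab <- lab[order(lab$vertex_id), ]
  parcellation(lab$label_id, nm)
}

#' @param parc a [parcellation()].
#' @rdname read_labels_csv
#' @export
write_labels_csv <- function(parc, labels_csv, names_csv) {
  utils::write.csv(data.frame(vertex_id = seq_along(parc$labels) - 1L,
                              label_id = parc$labels),
                   labels_csv, row.names = FALSE)
  utils::write.csv(data.frame(label_id = as.integer(names(parc$names)),
                              name = unname(parc$names)),
                   names_csv, row.names = FALSE)
  invisible(c(labels_csv, names_csv))
}
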