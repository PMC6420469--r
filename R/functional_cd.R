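#' Frame censoring by framewise displacement
#'
#' Keeps the timepoints whose framewise displacement (FD, mm) is below or
#' equal to the threshold; the inclusive 0.2 mm rule is the scrubbing
#' criterion applied to the resting-state scans.
#'
#' @param fd non-negative numeric vector of per-timepoint FD in mm.
#' @param threshold_mm inclusive threshold, default 0.2.
#' @return integer vector of kept timepoint indices (1-based, in order).
#' @export
censor_frames <- function(fd, threshold_mm = 0.2) {
  if (threshold_mm <= 0) stop("threshold must be positive")
  if (any(fd < 0)) stop("FD values must be non-negative")
  keep <- which(fd <= threshold_mm)
  if (!length(keep)) stop("no frames survive FD censoring")
  keep
}

#' Vertex-by-vertex correlation matrix
#'
#' Pearson product-moment correlation between every pair of vertex time
#' series. Vertices with zero variance cannot be correlated; their rows and
#' columns are returned as `NA` with a warning, and downstream thresholding
#' skips them.
#'
#' @param ts numeric matrix, vertices x timepoints (>= 3 timepoints).
#' @return symmetric correlation matrix with unit diagonal (NA rows/columns
#'   for zero-variance vertices).
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3L) stop("need at least 3 timepoints")
  # standardized tcrossprod: algebraically identical to the product-moment
  # formula but runs through BLAS, which matters at full mesh resolution
  ctr <- ts - rowMeans(ts)
  ss <- sqrt(rowSums(ctr^2))
  bad <- ss == 0 | is.na(ss)
  if (any(bad)) {
    warning(sum(bad), " zero-variance vertex series excluded from correlation")
    ctr[bad, ] <- 0
    ss[bad] <- 1
  }
  C <- tcrossprod(ctr / ss)
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  if (any(bad)) {
    C[bad, ] <- NA_real_
    C[, bad] <- NA_real_
  }
  C
}

#' Top-q correlated targets of a vertex
#'
#' The node-wise threshold: the k = round(q * (N - 1)) vertices (at least 1)
#' most strongly correlated with vertex `v`, where N counts the valid
#' (non-NA) vertices including `v` itself; the vertex itself is excluded.
#' Ties at the cutoff are resolved towards the lower vertex index, making the
#' selection deterministic.
#'
#' @param conn correlation matrix from [correlation_matrix()].
#' @param v vertex index.
#' @param q threshold fraction in (0, 1), default 0.02.
#' @return integer vector of k target vertex indices.
#' @export
topq_targets <- function(conn, v, q = 0.02) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  row <- conn[, v]
  row[v] <- NA_real_
  valid <- which(!is.na(row))
  if (!length(valid)) stop("vertex ", v, " has no valid correlations")
  k <- max(1L, as.integer(round(q * length(valid))))
  k <- min(k, length(valid))
  ord <- valid[order(-row[valid], valid)]
  ord[seq_len(k)]
}

# number of targets per vertex used by fc_distance_map (shared k across
# vertices when the valid set is common)
topq_k <- function(n_valid, q) {
  max(1L, min(n_valid, as.integer(round(q * n_valid))))
}

#' Functional connectivity distance map
#'
#' For each vertex, the unweighted mean geodesic distance to its top-q most
#' correlated vertices (default q = 0.02, the node-wise 2% threshold). Only
#' correlation ranks matter, so any strictly increasing transform of the
#' correlations leaves the map unchanged. Zero-variance vertices propagate
#' as `NA`.
#'
#' @param mesh a [triangle_mesh()].
#' @param conn correlation matrix (vertices matching the mesh).
#' @param q threshold fraction, default 0.02.
#' @param dist optional precomputed geodesic distance matrix
#'   ([geodesic_distance_matrix()]); computed (and memoised) if missing.
#' @return numeric per-vertex map (mm) of class `numeric`, `NA` at excluded
#'   vertices, with attribute `q`.
#' @export
fc_distance_map <- function(mesh, conn, q = 0.02, dist = NULL) {
  n <- mesh$n_vertices
  if (nrow(conn) != n) stop("correlation matrix does not match mesh")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (is.null(dist)) dist <- geodesic_distance_matrix(mesh)
  bad <- is.na(diag(conn))
  n_valid <- sum(!bad)
  if (n_valid < 2L) stop("fewer than 2 valid vertices")
  k <- topq_k(n_valid - 1L, q)
  idx <- .topk_columns(conn, k)   # k x n, NA-padded when a column runs short
  vals <- dist[cbind(as.vector(idx), rep(seq_len(n), each = k))]
  out <- colMeans(matrix(vals, k, n), na.rm = TRUE)
  out[bad] <- NA_real_
  out[is.nan(out)] <- NA_real_
  attr(out, "q") <- q
  out
}

#' Aggregate subject maps into a per-area table
#'
#' Fixed aggregation order: first the vertex-wise mean across subjects, then
#' the mean across each area's vertices. A vertex missing in any subject is
#' treated as missing overall; an area whose vertices are all missing is
#' reported as `NA`, not zero.
#'
#' @param maps list of per-vertex maps (one per subject), or a matrix with
#'   one column per subject.
#' @param parc a [parcellation()].
#' @return data.frame with columns `area_id`, `name`, `mean_cd_mm`,
#'   `n_vertices` (count of non-missing vertices entering the area mean).
#' @export
aggregate_maps <- function(maps, parc) {
  if (is.list(maps)) maps <- do.call(cbind, maps)
  if (nrow(maps) != length(parc$labels))
    stop("map vertex count does not match parcellation")
  vertex_mean <- rowMeans(maps)            # NA if missing in any subject
  ids <- area_ids(parc)
  mean_cd <- area_means(parc, vertex_mean)
  n_vtx <- vapply(ids, function(id)
    sum(!is.na(vertex_mean[parc$labels == id])), integer(1))
  data.frame(area_id = ids,
             name = unname(parc$names[as.character(ids)]),
             mean_cd_mm = unname(mean_cd),
             n_vertices = n_vtx)
}

#' Per-subject functional connectivity distance
#'
#' Convenience wrapper over the per-scan pipeline: censor each scan by FD,
#' concatenate the retained frames across scans, correlate, threshold at the
#' node-wise top-q, and average geodesic distances.
#'
#' @param mesh a [triangle_mesh()].
#' @param scans list of vertices x timepoints matrices for one subject.
#' @param fd list of FD vectors matching `scans` (or NULL to keep all frames).
#' @param q threshold fraction, default 0.02.
#' @param fd_threshold_mm FD censoring threshold, default 0.2.
#' @param dist optional precomputed geodesic distance matrix.
#' @return per-vertex FC distance map (mm).
#' @export
subject_fc_distance <- function(mesh, scans, fd = NULL, q = 0.02,
                                fd_threshold_mm = 0.2, dist = NULL) {
  if (!is.list(scans)) scans <- list(scans)
  if (!is.null(fd)) {
    if (!is.list(fd)) fd <- list(fd)
    stopifnot(length(fd) == length(scans))
    scans <- Map(function(x, f) x[, censor_frames(f, fd_threshold_mm),
                                  drop = FALSE],
                 scans, fd)
  }
  ts <- do.call(cbind, scans)
  conn <- correlation_matrix(ts)
  fc_distance_map(mesh, conn, q = q, dist = dist)
}
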