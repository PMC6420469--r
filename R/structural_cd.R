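#' Retrograde tracer injection record
#'
#' One tracer injection: the injected area, the injection-site vertex, and
#' the number of labeled (projecting) neurons per source area. Counts for the
#' injected area itself (intrinsic neurons) may be present but are excluded
#' from connectivity distance.
#'
#' @param injection_area area id of the injected region.
#' @param injection_vertex 1-based mesh vertex of the injection site.
#' @param counts named numeric vector: source area id -> labeled neuron count.
#' @param id optional injection identifier (defaults to the area id).
#' @return object of class `injection_record`.
#' @export
injection_record <- function(injection_area, injection_vertex, counts,
                             id = NULL) {
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  counts <- counts[counts > 0]
  extr <- counts[names(counts) != as.character(injection_area)]
  if (!length(extr) || sum(extr) <= 0)
    stop("injection ", injection_area,
         ": needs at least one extrinsic source area with count > 0")
  rec <- list(id = if (is.null(id)) as.character(injection_area) else id,
              injection_area = as.integer(injection_area),
              injection_vertex = as.integer(injection_vertex),
              counts = counts)
  class(rec) <- "injection_record"
  rec
}

#' Structural connectivity distance of one injection
#'
#' The labeled-neuron-count-weighted mean geodesic distance from the
#' injection site to the centroids of its extrinsic source areas:
#' sum_a count_a * d(site, centroid_a) / sum_a count_a. Since all neurons of
#' a source area share the area centroid as spatial reference, this equals
#' the mean geodesic distance over individual labeled neurons. Intrinsic
#' (within-area) neurons are excluded, and scaling all counts by a positive
#' constant leaves the result unchanged.
#'
#' @param mesh a [triangle_mesh()].
#' @param parc a [parcellation()].
#' @param rec an [injection_record()].
#' @param reference `"vertex"` (default) measures from the recorded injection
#'   vertex; `"centroid"` measures from the injected area's centroid.
#' @param centroids optional precomputed [area_centroids()] table.
#' @return connectivity distance in mm.
#' @export
sc_distance <- function(mesh, parc, rec, reference = c("vertex", "centroid"),
                        centroids = NULL) {
  reference <- match.arg(reference)
  if (!rec$injection_area %in% parc$labels)
    stop("injection area ", rec$injection_area, " absent from parcellation")
  if (is.null(centroids)) centroids <- area_centroids(mesh, parc)
  cnt <- rec$counts[names(rec$counts) != as.character(rec$injection_area)]
  cnt <- cnt[cnt > 0]
  if (!length(cnt)) stop("all extrinsic counts are zero")
  src_centroid <- centroids[names(cnt)]
  if (anyNA(src_centroid))
    stop("source area(s) missing from parcellation: ",
         paste(names(cnt)[is.na(src_centroid)], collapse = ", "))
  origin <- if (reference == "vertex") rec$injection_vertex else
    centroids[[as.character(rec$injection_area)]]
  d <- geodesic_distance_matrix(mesh, from = origin)[1L, src_centroid]
  sum(cnt * d) / sum(cnt)
}

#' Per-injection table for the structural gradient model
#'
#' One row per injection with the response and all model terms: structural
#' connectivity distance (`cd_mm`), the injected region's vertex count
#' (`region_size_vertices`, a covariate correcting for the intrinsic-neuron
#' exclusion favouring large areas), the injection site's geometric
#' centrality (`centrality_mm`), and its geodesic distance from the closest
#' primary-area border (`dist_primary_mm`, the predictor of interest; 0 for
#' injections inside a primary area).
#'
#' @param mesh a [triangle_mesh()].
#' @param parc a [parcellation()].
#' @param records list of [injection_record()]s.
#' @param primary primary area ids or names.
#' @param reference passed to [sc_distance()].
#' @return data.frame with columns `injection`, `injection_area`,
#'   `injection_vertex`, `cd_mm`, `region_size_vertices`, `centrality_mm`,
#'   `dist_primary_mm`.
#' @export
build_sc_table <- function(mesh, parc, records, primary,
                           reference = c("vertex", "centroid")) {
  reference <- match.arg(reference)
  if (!length(records)) stop("need at least one injection record")
  centroids <- area_centroids(mesh, parc)
  dp <- distance_from_region_borders(mesh, parc, primary)
  rows <- lapply(records, function(rec) {
    origin <- if (reference == "vertex") rec$injection_vertex else
      centroids[[as.character(rec$injection_area)]]
    data.frame(
      injection = rec$id,
      injection_area = rec$injection_area,
      injection_vertex = rec$injection_vertex,
      cd_mm = sc_distance(mesh, parc, rec, reference, centroids),
      region_size_vertices = sum(parc$labels == rec$injection_area),
      centrality_mm = geometric_centrality(mesh, origin),
      dist_primary_mm = dp[origin])
  })
  do.call(rbind, rows)
}

#' Read tracer data from CSV
#'
#' `counts_csv` mirrors the public weighted-connectome layout with columns
#' `injection_area`, `source_area`, `neuron_count`; `sites_csv` has columns
#' `injection_area`, `vertex_id` (0-based). Area columns may hold ids or
#' names resolvable against the parcellation.
#'
#' @param counts_csv,sites_csv file paths.
#' @param parc a [parcellation()].
#' @return list of [injection_record()]s.
#' @export
read_tracer_csv <- function(counts_csv, sites_csv, parc) {
  cnt <- utils::read.csv(counts_csv)
  sites <- utils::read.csv(sites_csv)
  lapply(seq_len(nrow(sites)), function(i) {
    inj <- resolve_areas(parc, sites$injection_area[i])
    sub <- cnt[resolve_areas(parc, cnt$injection_area) == inj, ]
    counts <- stats::setNames(as.numeric(sub$neuron_count),
                              resolve_areas(parc, sub$source_area))
    injection_record(inj, sites$vertex_id[i] + 1L, counts)
  })
}

#' Write injection records to CSV
#' @param records list of [injection_record()]s.
#' @param counts_csv,sites_csv output paths.
#' @export
write_tracer_csv <- function(records, counts_csv, sites_csv) {
  cnt <- do.call(rbind, lapply(records, function(r)
    data.frame(injection_area = r$injection_area,
               source_area = as.integer(names(r$counts)),
               neuron_count = as.numeric(r$counts))))
  sites <- do.call(rbind, lapply(records, function(r)
    data.frame(injection_area = r$injection_area,
               vertex_id = r$injection_vertex - 1L)))
  utils::write.csv(cnt, counts_csv, row.names = FALSE)
  utils::write.csv(sites, sites_csv, row.names = FALSE)
  invisible(c(counts_csv, sites_csv))
}
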