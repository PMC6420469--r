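#' Functional connectivity-distance pipeline
#'
#' Composes the functional stages: per-scan FD censoring, per-subject scan
#' concatenation and correlation, node-wise top-q thresholding, geodesic
#' averaging, subject-then-parcel aggregation, and the gradient GLM against
#' distance from the primary-area borders.
#'
#' @param mesh a [triangle_mesh()].
#' @param parc a [parcellation()].
#' @param subjects list, one element per subject, each with `scans` (list of
#'   vertices x timepoints matrices) and optional `fd` (list of FD vectors),
#'   as produced by [plant_gradient_timeseries()].
#' @param primary primary area ids or names.
#' @param q node-wise threshold fraction, default 0.02.
#' @param fd_threshold_mm FD censoring threshold, default 0.2.
#' @return list with `subject_maps` (vertices x subjects matrix),
#'   `area_table` ([aggregate_maps()] output plus per-area mean
#'   `dist_primary_mm`), `dist_primary` (vertex map), and `glm`
#'   (a `gradient_glm`).
#' @export
run_functional_pipeline <- function(mesh, parc, subjects, primary,
                                    q = 0.02, fd_threshold_mm = 0.2) {
  dist_all <- geodesic_distance_matrix(mesh)
  maps <- vapply(subjects, function(s)
    subject_fc_distance(mesh, s$scans, s$fd, q = q,
                        fd_threshold_mm = fd_threshold_mm, dist = dist_all),
    numeric(mesh$n_vertices))
  tab <- aggregate_maps(maps, parc)
  dp <- distance_from_region_borders(mesh, parc, primary)
  tab$dist_primary_mm <- unname(area_means(parc, dp))
  fit <- functional_gradient_test(
    stats::setNames(tab$mean_cd_mm, tab$area_id),
    stats::setNames(tab$dist_primary_mm, tab$area_id))
  list(subject_maps = maps, area_table = tab, dist_primary = dp, glm = fit)
}

#' Structural connectivity-distance pipeline
#'
#' Composes the structural stages: per-injection connectivity distance from
#' tracer counts, the covariate table, and the gradient GLM with region-size
#' and centrality covariates.
#'
#' @param mesh a [triangle_mesh()].
#' @param parc a [parcellation()].
#' @param records list of [injection_record()]s.
#' @param primary primary area ids or names.
#' @param reference passed to [sc_distance()].
#' @return list with `sc_table` ([build_sc_table()] output) and `glm`.
#' @export
run_structural_pipeline <- function(mesh, parc, records, primary,
                                    reference = c("vertex", "centroid")) {
  tab <- build_sc_table(mesh, parc, records, primary, match.arg(reference))
  list(sc_table = tab, glm = structural_gradient_test(tab))
}
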