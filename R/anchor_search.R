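# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                            envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# X must include the intercept column; signed R2 carries the sign of the
# coefficient in column `xcol`. Returns NA for degenerate/collinear designs.
signed_r2_fit <- function(X, y, xcol = 2L) {
  beta <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                   error = function(e) NULL)
  if (is.null(beta)) return(NA_real_)
  rss <- sum((y - X %*% beta)^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  sign(beta[xcol]) * (1 - rss / tss)
}

# design matrix shared by all anchor GLMs: intercept + placeholder distance
# column + the two covariates of no interest
anchor_design <- function(sites) {
  cbind(1, 0, as.numeric(sites$region_size_vertices),
        as.numeric(sites$centrality_mm))
}

#' Signed variance explained by an anchor set
#'
#' Replaces the distance-from-primary predictor of the structural gradient
#' model by the geodesic distance from each injection site to the nearest
#' vertex of an arbitrary anchor set, keeping the region-size and centrality
#' covariates, and returns sign(distance coefficient) * R-squared of the
#' fit. A degenerate predictor (all sites equidistant from the anchor set)
#' yields `NA`.
#'
#' @param mesh a [triangle_mesh()].
#' @param sites data.frame from [build_sc_table()].
#' @param anchors vertex indices of the candidate anchor set.
#' @param site_dist optional precomputed matrix of geodesic distances,
#'   sites x all vertices ([geodesic_distance_matrix()] from the injection
#'   vertices); computed if missing.
#' @return signed R-squared in [-1, 1], or `NA` for a degenerate sample.
#' @export
anchor_glm <- function(mesh, sites, anchors, site_dist = NULL) {
  if (!length(anchors)) stop("anchor set is empty")
  if (is.null(site_dist))
    site_dist <- geodesic_distance_matrix(mesh, from = sites$injection_vertex)
  X <- anchor_design(sites)
  D <- site_dist[, anchors, drop = FALSE]
  x <- do.call(pmin, lapply(seq_len(ncol(D)), function(j) D[, j]))
  if (stats::sd(x) == 0) return(NA_real_)
  X[, 2] <- x
  signed_r2_fit(X, as.numeric(sites$cd_mm), xcol = 2L)
}

new_search_map <- function(values, counts, statistic, extra = list()) {
  m <- c(list(values = values, counts = counts, statistic = statistic), extra)
  class(m) <- "search_map"
  m
}

#' @export
print.search_map <- function(x, ...) {
  cat("search_map (", x$statistic, "): ", sum(x$counts > 0),
      " vertices visited; peak at vertex ", search_peak(x), "\n", sep = "")
  invisible(x)
}

#' Peak vertex of a search map
#' @param map a `search_map`.
#' @return index of the vertex with the highest statistic (for hill-climb
#'   maps, the highest positive-relationship inclusion count).
#' @export
search_peak <- function(map) {
  v <- map$values
  v[is.na(v)] <- -Inf
  which.max(v)
}

#' Random anchor search
#'
#' Hypothesis-free localization of anchor regions by random sampling: draws
#' anchor sets of size uniform in `set_size`, fits the anchor GLM for each,
#' and maps every vertex's mean signed R-squared over the samples that
#' included it. Degenerate samples are skipped and counted.
#'
#' @param mesh a [triangle_mesh()].
#' @param sites data.frame from [build_sc_table()].
#' @param n_samples number of random anchor sets (the full-scale analysis
#'   uses 100,000; scaled-down runs are fine because the map statistic is a
#'   per-vertex mean).
#' @param set_size integer range (min, max) of anchor-set sizes, default
#'   c(3, 5).
#' @param seed RNG seed for reproducibility.
#' @return a `search_map` with `values` = per-vertex mean signed R-squared
#'   (NA where never sampled), `counts` = per-vertex sample counts, and
#'   fields `n_samples`, `skipped`, `seed`.
#' @export
random_anchor_search <- function(mesh, sites, n_samples = 2000,
                                 set_size = c(3, 5), seed = NULL) {
  stopifnot(n_samples >= 1)
  n <- mesh$n_vertices
  site_dist <- geodesic_distance_matrix(mesh, from = sites$injection_vertex)
  X <- anchor_design(sites)
  y <- as.numeric(sites$cd_mm)
  sums <- numeric(n); counts <- integer(n); skipped <- 0L
  with_local_seed(seed, {
    sizes <- sample(seq.int(set_size[1], set_size[2]), n_samples,
                    replace = TRUE)
    for (s in seq_len(n_samples)) {
      anchors <- sample.int(n, sizes[s])
      D <- site_dist[, anchors, drop = FALSE]
      x <- do.call(pmin, lapply(seq_len(ncol(D)), function(j) D[, j]))
      if (stats::sd(x) == 0) { skipped <- skipped + 1L; next }
      X[, 2] <- x
      r2 <- signed_r2_fit(X, y, xcol = 2L)
      if (is.na(r2)) { skipped <- skipped + 1L; next }
      sums[anchors] <- sums[anchors] + r2
      counts[anchors] <- counts[anchors] + 1L
    }
  })
  values <- ifelse(counts > 0, sums / counts, NA_real_)
  new_search_map(values, counts, "mean_signed_r2",
                 list(n_samples = n_samples, skipped = skipped, seed = seed,
                      set_size = set_size))
}

# candidate moves for a vertex: all vertices within step_mm geodesic;
# if mesh resolution is coarser than the step, fall back to the 1-ring of
# mesh neighbours (the minimal moves the mesh admits)
move_candidates <- function(v, step_mm, dist_all, ring) {
  cand <- which(dist_all[v, ] <= step_mm)
  cand <- cand[cand != v]
  if (!length(cand)) cand <- ring[[v]]
  cand
}

#' Hill-climbing anchor search
#'
#' Local optimization with restarts: starting from a random anchor set (size
#' uniform in `set_size`), anchors are moved in steps of at most `step_mm`
#' along the surface towards higher variance explained. Each iteration
#' evaluates moving every anchor to each of its candidate vertices and
#' accepts the single best strictly-improving move of |signed R-squared|;
#' the restart stops when no move improves (a stable set). The map counts,
#' for every vertex, how often it belonged to a final stable set, split by
#' the sign of the final signed R-squared (positive: connectivity distance
#' grows with distance from the anchors).
#'
#' @param mesh a [triangle_mesh()].
#' @param sites data.frame from [build_sc_table()].
#' @param n_restarts number of random restarts (the full-scale analysis uses
#'   1,000).
#' @param step_mm maximal per-move geodesic offset, default 1.
#' @param set_size integer range of anchor-set sizes, default c(3, 5).
#' @param seed RNG seed.
#' @param max_iter per-restart iteration cap; restarts hitting it are
#'   recorded as failed.
#' @return a `search_map` with `values` = counts_pos - counts_neg, `counts` =
#'   total final-set inclusion counts, plus `counts_pos`, `counts_neg`,
#'   per-restart objective `trajectories`, `failed`, `skipped`, `seed`.
#' @export
hill_climb_search <- function(mesh, sites, n_restarts = 100, step_mm = 1.0,
                              set_size = c(3, 5), seed = NULL,
                              max_iter = 10000) {
  stopifnot(n_restarts >= 1)
  n <- mesh$n_vertices
  site_dist <- geodesic_distance_matrix(mesh, from = sites$injection_vertex)
  dist_all <- geodesic_distance_matrix(mesh)
  g <- geodesic_graph(mesh, augment = FALSE)
  ring <- igraph::as_adj_list(g)
  ring <- lapply(ring, as.integer)
  X <- anchor_design(sites)
  y <- as.numeric(sites$cd_mm)
  obj_of <- function(anchors) {
    D <- site_dist[, anchors, drop = FALSE]
    x <- do.call(pmin, lapply(seq_len(ncol(D)), function(j) D[, j]))
    if (stats::sd(x) == 0) return(NA_real_)
    X[, 2] <- x
    signed_r2_fit(X, y, xcol = 2L)
  }
  counts_pos <- integer(n); counts_neg <- integer(n)
  skipped <- 0L; failed <- 0L
  trajectories <- vector("list", n_restarts)
  with_local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      size <- sample(seq.int(set_size[1], set_size[2]), 1L)
      anchors <- sample.int(n, size)
      cur <- obj_of(anchors)
      if (is.na(cur)) { skipped <- skipped + 1L; next }
      traj <- abs(cur)
      it <- 0L
      repeat {
        it <- it + 1L
        if (it > max_iter) { failed <- failed + 1L; anchors <- NULL; break }
        best_obj <- abs(cur); best_signed <- cur
        best_i <- 0L; best_v <- 0L
        for (i in seq_along(anchors)) {
          for (v in move_candidates(anchors[i], step_mm, dist_all, ring)) {
            if (v %in% anchors) next
            trial <- anchors; trial[i] <- v
            o <- obj_of(trial)
            if (!is.na(o) && abs(o) > best_obj) {
              best_obj <- abs(o); best_signed <- o
              best_i <- i; best_v <- v
            }
          }
        }
        if (best_i == 0L) break  # stable set: no strictly improving move
        anchors[best_i] <- best_v
        cur <- best_signed
        traj <- c(traj, abs(cur))
      }
      trajectories[[r]] <- traj
      if (is.null(anchors)) next
      if (cur >= 0) counts_pos[anchors] <- counts_pos[anchors] + 1L
      else counts_neg[anchors] <- counts_neg[anchors] + 1L
    }
  })
  new_search_map(counts_pos - counts_neg, counts_pos + counts_neg,
                 "inclusion_count",
                 list(counts_pos = counts_pos, counts_neg = counts_neg,
                      n_restarts = n_restarts, step_mm = step_mm,
                      set_size = set_size, skipped = skipped,
                      failed = failed, trajectories = trajectories,
                      seed = seed))
}
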