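#' Geodesic icosphere mesh
#'
#' Recursive subdivision of a regular icosahedron with vertices projected to
#' the sphere; the synthetic stand-in for a cortical hemisphere surface.
#' Vertex count is 10 * 4^subdivisions + 2 (12, 42, 162, 642, 2562, ...).
#'
#' @param subdivisions number of subdivision rounds (>= 0), default 4.
#' @param radius sphere radius in mm, default 30 (hemisphere scale of a
#'   macaque brain).
#' @return a [triangle_mesh()].
#' @export
make_icosphere <- function(subdivisions = 4, radius = 30) {
  stopifnot(subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  s <- 0L
  while (s < subdivisions) {
    nv <- nrow(v)
    key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    e1 <- key(f[, 1], f[, 2]); e2 <- key(f[, 2], f[, 3])
    e3 <- key(f[, 3], f[, 1])
    ek <- unique(c(e1, e2, e3))
    mid_idx <- stats::setNames(seq_along(ek) + nv, ek)
    ab <- do.call(rbind, strsplit(ek, "_", fixed = TRUE))
    a <- as.integer(ab[, 1]); b <- as.integer(ab[, 2])
    mid <- (v[a, ] + v[b, ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    v <- rbind(v, mid)
    m1 <- mid_idx[e1]; m2 <- mid_idx[e2]; m3 <- mid_idx[e3]
    f <- rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
               cbind(f[, 3], m3, m2), cbind(m1, m2, m3))
    s <- s + 1L
  }
  triangle_mesh(v * radius, unname(f))
}

#' Geodesic-Voronoi parcellation
#'
#' Partitions the mesh into `n_areas` areas by nearest geodesic seed vertex
#' (seeds drawn uniformly without replacement); ties go to the lower seed
#' index. A repair pass reattaches any stray disconnected fragments to an
#' adjacent area so every area is edge-connected. Emulates an atlas
#' parcellation (e.g. 91 areas per hemisphere).
#'
#' @param mesh a [triangle_mesh()].
#' @param n_areas number of areas (<= vertex count), default 91.
#' @param seed RNG seed.
#' @return a [parcellation()] with area ids 1..n_areas named "area_<id>";
#'   attribute `seeds` holds the seed vertices.
#' @export
make_parcellation <- function(mesh, n_areas = 91, seed = NULL) {
  n <- mesh$n_vertices
  stopifnot(n_areas >= 1, n_areas <= n)
  seeds <- with_local_seed(seed, sample.int(n, n_areas))
  D <- geodesic_distance_matrix(mesh, from = seeds)
  lab <- max.col(-t(D), ties.method = "first")
  # repair: keep the component containing the seed, reassign the rest
  ed <- mesh_edges(mesh)
  g_edge <- igraph::make_graph(t(ed[, 1:2, drop = FALSE]), n = n,
                               directed = FALSE)
  for (pass in 1:10) {
    changed <- FALSE
    for (id in seq_len(n_areas)) {
      vs <- which(lab == id)
      if (!length(vs)) stop("area ", id, " lost all vertices; resample seeds")
      sub <- igraph::induced_subgraph(g_edge, vs)
      comp <- igraph::components(sub)
      if (comp$no == 1L) next
      keep_comp <- comp$membership[match(seeds[id], vs)]
      stray <- vs[comp$membership != keep_comp]
      nb <- igraph::adjacent_vertices(g_edge, stray)
      for (i in seq_along(stray)) {
        out_lab <- lab[as.integer(nb[[i]])]
        out_lab <- out_lab[out_lab != id]
        if (length(out_lab)) {
          lab[stray[i]] <- sort(out_lab)[1L]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  nm <- stats::setNames(paste0("area_", seq_len(n_areas)),
                        seq_len(n_areas))
  p <- parcellation(lab, nm)
  attr(p, "seeds") <- seeds
  p
}

#' Designate spread-out primary areas
#'
#' Picks `n_anchors` areas by farthest-point sampling on area centroids (the
#' first at random, each next maximizing the minimal geodesic distance to
#' those already chosen), mimicking the wide spacing of the primary visual,
#' auditory, somatosensory and motor fields.
#'
#' @param mesh a [triangle_mesh()].
#' @param parc a [parcellation()].
#' @param n_anchors number of primary areas, default 4.
#' @param seed RNG seed.
#' @return integer vector of area ids.
#' @export
choose_primary_areas <- function(mesh, parc, n_anchors = 4, seed = NULL) {
  ids <- area_ids(parc)
  cent <- area_centroids(mesh, parc)
  D <- geodesic_distance_matrix(mesh, from = cent)[, cent, drop = FALSE]
  first <- with_local_seed(seed, sample.int(length(ids), 1L))
  chosen <- first
  while (length(chosen) < n_anchors) {
    dmin <- apply(D[chosen, , drop = FALSE], 2L, min)
    dmin[chosen] <- -Inf
    chosen <- c(chosen, which.max(dmin))
  }
  ids[chosen]
}

#' Simulation configuration
#'
#' Bundles the generator parameters. Defaults emulate the study conditions:
#' an order-4 icosphere (2,562 vertices) of radius 30 mm standing in for one
#' hemisphere, 91 areas, 10 subjects with 2 scans of 250 timepoints each, 29
#' tracer injections, and 4 primary (anchor) areas. `beta_true` (mm per mm)
#' sets the planted gradient of connection length anchored at the primary
#' borders, acting through two mechanisms: in the time-series model the
#' geodesic offset of each vertex's long-range correlation partner grows as
#' rho0 + beta_true * dist_primary ([plant_gradient_timeseries()]); in the
#' tracer model the exponential decay length of labeled-neuron counts grows
#' as lambda0 + beta_true * dist_primary ([plant_tracer_counts()]).
#' `lambda0 = 5` mm matches the scale of the exponential distance rule for
#' macaque cortical connectivity; `epsilon` is white measurement noise added
#' on top of the correlated signal; `n0` is the expected labeled-neuron
#' count at zero distance.
#'
#' @param subdivisions,radius_mm icosphere parameters.
#' @param n_areas,n_subjects,n_timepoints,n_scans,n_injections,n_anchors
#'   study-design counts.
#' @param lambda0_mm,beta_true,epsilon gradient and noise parameters.
#' @param rho0_mm,w_partner functional-kernel parameters: baseline geodesic
#'   offset of each vertex's long-range partner patch, and the weight of the
#'   partner term relative to local spatial coherence.
#' @param n0 tracer count scale.
#' @param fd_shape,fd_mean_mm gamma parameters of simulated framewise
#'   displacement (per-frame mean 0.06 mm; occasional frames exceed the
#'   0.2 mm censoring threshold).
#' @param seed top-level RNG seed from which all stage seeds derive.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(subdivisions = 4, radius_mm = 30,
                              n_areas = 91, n_subjects = 10,
                              n_timepoints = 250, n_scans = 2,
                              n_injections = 29, n_anchors = 4,
                              lambda0_mm = 5, beta_true = 0.3,
                              rho0_mm = 5, w_partner = 0.8,
                              epsilon = 0.2, n0 = 1000,
                              fd_shape = 4, fd_mean_mm = 0.06,
                              seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$lambda0_mm > 0, cfg$rho0_mm > 0, cfg$epsilon > 0,
            cfg$w_partner >= 0, cfg$n_areas >= 1,
            cfg$n_subjects >= 1, cfg$n_timepoints >= 2, cfg$n_scans >= 1,
            cfg$n_injections >= 1, cfg$n_anchors >= 1)
  class(cfg) <- "simulation_config"
  cfg
}

# per-vertex decay length of the planted tracer gradient; errors if
# non-positive
gradient_lambda <- function(dist_primary, cfg) {
  lam <- cfg$lambda0_mm + cfg$beta_true * dist_primary
  if (any(lam <= 0)) stop("lambda(v) <= 0: check lambda0_mm / beta_true")
  lam
}

#' Long-range partner vertices of the planted functional gradient
#'
#' For each vertex v, the partner p(v) lies at geodesic offset
#' rho(v) = rho0 + beta_true * dist_primary(v) from v, in a tangent
#' direction drawn independently per vertex from the given seed, and is
#' snapped to the nearest mesh vertex. Random directions keep the field
#' statistically isotropic: a fixed displacement axis would imprint a
#' systematic large-scale pattern on the null (beta_true = 0) connectivity
#' maps, which must be flat up to noise.
#'
#' @param mesh a [triangle_mesh()] (sphere-like; radius taken from the mean
#'   vertex norm).
#' @param dist_primary per-vertex border-distance map.
#' @param cfg a [simulation_config()].
#' @param seed RNG seed for the directions (defaults to `cfg$seed + 3`).
#' @return integer vector: partner vertex index per vertex.
#' @export
partner_vertices <- function(mesh, dist_primary, cfg, seed = cfg$seed + 3) {
  V <- mesh$vertices
  r <- mean(sqrt(rowSums(V^2)))
  vu <- V / sqrt(rowSums(V^2))
  # orthonormal tangent basis at each vertex; +x fallback at the z poles
  e1 <- cbind(-vu[, 2], vu[, 1], 0)
  n1 <- sqrt(rowSums(e1^2))
  degen <- n1 < 1e-9
  e1[degen, ] <- matrix(c(1, 0, 0), sum(degen), 3, byrow = TRUE)
  n1[degen] <- 1
  e1 <- e1 / n1
  e2 <- cbind(vu[, 2] * e1[, 3] - vu[, 3] * e1[, 2],
              vu[, 3] * e1[, 1] - vu[, 1] * e1[, 3],
              vu[, 1] * e1[, 2] - vu[, 2] * e1[, 1])
  phi <- with_local_seed(seed, stats::runif(nrow(V), 0, 2 * pi))
  that <- cos(phi) * e1 + sin(phi) * e2
  theta <- (cfg$rho0_mm + cfg$beta_true * dist_primary) / r
  P <- (vu * cos(theta) + that * sin(theta)) * r
  # nearest vertex by maximal inner product (equivalent on a sphere)
  max.col(P %*% t(vu), ties.method = "first")
}

#' Correlated time series with a planted connectivity-distance gradient
#'
#' Draws zero-mean Gaussian series from a signal model that plants a
#' gradient of connection length: each vertex mixes a locally coherent
#' field with the same field read out at a distant partner location,
#'
#'   x_v(t) = f_v(t) + w_partner * f_p(v)(t) + sqrt(epsilon) * eta_v(t),
#'
#' where f is a zero-mean Gaussian field with covariance
#' S = exp(-d(v,u)/lambda0), p(v) is the partner at geodesic offset
#' rho0 + beta_true * dist_primary(v) ([partner_vertices()]), and eta is
#' white noise. The implied covariance K = (I + wP) S (I + wP)' + epsilon I
#' (P the partner permutation-like selector) is positive semidefinite by
#' construction: every vertex carries short-range spatial coherence plus a
#' long-range correlation patch centred on its partner, and the further a
#' vertex lies from primary cortex, the more distant its strongest
#' correlates — exactly the gradient the functional pipeline should
#' recover. Per-frame framewise displacement is simulated alongside each
#' scan.
#'
#' @param mesh a [triangle_mesh()].
#' @param dist_primary per-vertex border-distance map
#'   ([distance_from_region_borders()]).
#' @param cfg a [simulation_config()].
#' @param seed RNG seed (defaults to `cfg$seed + 1`).
#' @param return_cov also return the implied vertex-by-vertex covariance K
#'   as attribute `K` (quadratic in mesh size; default FALSE).
#' @return list with one element per subject, each a list with `scans`
#'   (list of vertices x n_timepoints matrices) and `fd` (list of FD
#'   vectors); attribute `partners` holds the partner vertex of each vertex
#'   (and `K` the target covariance when `return_cov = TRUE`).
#' @export
plant_gradient_timeseries <- function(mesh, dist_primary, cfg,
                                      seed = cfg$seed + 1,
                                      return_cov = FALSE) {
  D <- geodesic_distance_matrix(mesh)
  partners <- partner_vertices(mesh, dist_primary, cfg, seed = seed)
  # the local-field factor depends only on (mesh, lambda0): memoise it
  ckey <- paste0("cholS_", format(cfg$lambda0_mm))
  L <- mesh$.cache[[ckey]]
  if (is.null(L)) {
    S <- exp(-D / cfg$lambda0_mm)
    diag(S) <- diag(S) + 1e-6  # guards chol against metric-approximation error
    L <- chol(S)
    mesh$.cache[[ckey]] <- L
    mesh$.cache[[paste0("S_", format(cfg$lambda0_mm))]] <- S
  }
  S <- mesh$.cache[[paste0("S_", format(cfg$lambda0_mm))]]
  n <- mesh$n_vertices
  w <- cfg$w_partner
  ntp <- cfg$n_timepoints
  subjects <- with_local_seed(seed, {
    lapply(seq_len(cfg$n_subjects), function(s) {
      # one factor multiply covers all scans of the subject
      Z <- matrix(stats::rnorm(n * ntp * cfg$n_scans), n)
      f <- crossprod(L, Z)
      x <- f + w * f[partners, , drop = FALSE] +
        sqrt(cfg$epsilon) * matrix(stats::rnorm(length(f)), n)
      scans <- lapply(seq_len(cfg$n_scans), function(sc)
        x[, (sc - 1L) * ntp + seq_len(ntp), drop = FALSE])
      fd <- lapply(seq_len(cfg$n_scans), function(sc)
        stats::rgamma(ntp, shape = cfg$fd_shape,
                      scale = cfg$fd_mean_mm / cfg$fd_shape))
      list(scans = scans, fd = fd)
    })
  })
  if (return_cov) {
    K <- S + w * S[, partners, drop = FALSE] +
      w * S[partners, , drop = FALSE] +
      w * w * S[partners, partners, drop = FALSE]
    diag(K) <- diag(K) + cfg$epsilon
    attr(subjects, "K") <- K
  }
  attr(subjects, "partners") <- partners
  subjects
}

#' Tracer counts with a planted connectivity-distance gradient
#'
#' Chooses `n_injections` distinct areas, places each injection at a random
#' vertex of its area, and draws labeled-neuron counts for every extrinsic
#' area from Poisson(n0 * exp(-d(site, centroid_a) / lambda_i)) with
#' lambda_i = lambda0 + beta_true * dist_primary(site) — the exponential
#' decay of connectivity strength with distance, with a decay length that
#' grows away from primary cortex. An injection drawing all-zero counts is
#' redrawn with a doubled count scale (with a message).
#'
#' @param mesh a [triangle_mesh()].
#' @param parc a [parcellation()].
#' @param dist_primary per-vertex border-distance map.
#' @param cfg a [simulation_config()].
#' @param seed RNG seed (defaults to `cfg$seed + 2`).
#' @return list of [injection_record()]s.
#' @export
plant_tracer_counts <- function(mesh, parc, dist_primary, cfg,
                                seed = cfg$seed + 2) {
  ids <- area_ids(parc)
  stopifnot(cfg$n_injections <= length(ids))
  centroids <- area_centroids(mesh, parc)
  with_local_seed(seed, {
    inj_areas <- sample(ids, cfg$n_injections)
    lapply(inj_areas, function(a) {
      vs <- area_vertices(parc, a)
      vtx <- if (length(vs) == 1L) vs else sample(vs, 1L)
      lam <- gradient_lambda(dist_primary[vtx], cfg)
      src <- setdiff(ids, a)
      d <- geodesic_distance_matrix(mesh, from = vtx)[1L, centroids[
        as.character(src)]]
      scale <- cfg$n0
      repeat {
        counts <- stats::rpois(length(src), scale * exp(-d / lam))
        if (sum(counts) > 0) break
        message("injection ", a, ": all-zero counts, redrawing with n0 = ",
                scale * 2)
        scale <- scale * 2
      }
      keep <- counts > 0
      injection_record(a, vtx,
                       stats::setNames(as.numeric(counts[keep]), src[keep]))
    })
  })
}

#' Generate a complete synthetic dataset
#'
#' Mesh, parcellation, primary areas, border-distance map, per-subject time
#' series with FD, and tracer injections — everything the functional and
#' structural pipelines consume, with the ground truth recorded.
#'
#' @param cfg a [simulation_config()].
#' @param with_timeseries,with_tracer switch off stages you do not need
#'   (time series dominate the cost).
#' @return list with `mesh`, `parc`, `primary` (area ids), `dist_primary`,
#'   `timeseries`, `records`, `config`, `ground_truth`.
#' @export
simulate_dataset <- function(cfg = simulation_config(),
                             with_timeseries = TRUE, with_tracer = TRUE) {
  mesh <- make_icosphere(cfg$subdivisions, cfg$radius_mm)
  parc <- make_parcellation(mesh, cfg$n_areas, seed = cfg$seed)
  primary <- choose_primary_areas(mesh, parc, cfg$n_anchors,
                                  seed = cfg$seed + 10)
  dist_primary <- distance_from_region_borders(mesh, parc, primary)
  ts <- if (with_timeseries)
    plant_gradient_timeseries(mesh, dist_primary, cfg) else NULL
  recs <- if (with_tracer)
    plant_tracer_counts(mesh, parc, dist_primary, cfg) else NULL
  list(mesh = mesh, parc = parc, primary = primary,
       dist_primary = dist_primary, timeseries = ts, records = recs,
       config = cfg,
       ground_truth = list(
         primary_areas = primary,
         primary_vertices = which(parc$labels %in% primary),
         lambda0_mm = cfg$lambda0_mm, beta_true = cfg$beta_true,
         seed = cfg$seed))
}
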