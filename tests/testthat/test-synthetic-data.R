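test_that("icosphere vertex counts and radius follow the subdivision rule", {
  expect_identical(make_icosphere(0, 1)$n_vertices, 12L)
  expect_identical(make_icosphere(2, 30)$n_vertices, 162L)
  expect_identical(ico4()$n_vertices, 2562L)  # 10 * 4^4 + 2
  m <- make_icosphere(2, 30)
  expect_equal(sqrt(rowSums(m$vertices^2)), rep(30, 162), tolerance = 1e-9)
})

test_that("geodesic-Voronoi parcellation labels by nearest seed, connected", {
  mesh <- ico4()
  parc <- make_parcellation(mesh, 91, seed = 1)
  expect_identical(length(unique(parc$labels)), 91L)
  expect_true(all(table(parc$labels) >= 1))
  expect_length(parc$labels, mesh$n_vertices)
  seeds <- attr(parc, "seeds")
  D <- geodesic_distance_matrix(mesh, from = seeds)
  nearest <- max.col(-t(D), ties.method = "first")
  # the connectivity repair may reassign a stray vertex or two, no more
  expect_lt(mean(parc$labels != nearest), 0.005)
  # every area is edge-connected
  ed <- geograd:::mesh_edges(mesh)
  g <- igraph::make_graph(t(ed[, 1:2]), n = mesh$n_vertices, directed = FALSE)
  for (id in area_ids(parc)) {
    comp <- igraph::components(igraph::induced_subgraph(g, area_vertices(parc, id)))
    expect_equal(comp$no, 1)
  }
  # degenerate single-area case
  p1 <- make_parcellation(jittered_sphere(), 1, seed = 2)
  expect_identical(unique(p1$labels), 1L)
})

test_that("primary-area choice spreads anchors apart", {
  mesh <- jittered_sphere()
  parc <- make_parcellation(mesh, 20, seed = 3)
  prim <- choose_primary_areas(mesh, parc, 4, seed = 3)
  expect_length(unique(prim), 4L)
  cents <- area_centroids(mesh, parc)[as.character(prim)]
  D <- geodesic_distance_matrix(mesh, from = cents)[, cents]
  expect_gt(min(D[upper.tri(D)]), 15)  # far apart on a 30 mm sphere
})

test_that("partner offsets track the planted gradient", {
  mesh <- ico4()
  parc <- make_parcellation(mesh, 91, seed = 1)
  primary <- choose_primary_areas(mesh, parc, 4, seed = 11)
  dp <- distance_from_region_borders(mesh, parc, primary)
  cfg <- simulation_config()
  partners <- partner_vertices(mesh, dp, cfg)
  D <- geodesic_distance_matrix(mesh)
  off <- D[cbind(seq_along(partners), partners)]
  target <- cfg$rho0_mm + cfg$beta_true * dp
  # snapping and metric approximation allow a few mm of slack
  expect_lt(median(abs(off - target)), 2)
  expect_gt(cor(off, dp), 0.9)
})

test_that("time-series generator is seed-deterministic with valid FD", {
  mesh <- jittered_sphere()
  cfg <- simulation_config(subdivisions = 2, n_subjects = 2, n_timepoints = 40,
                           n_scans = 2, seed = 8)
  dp <- distance_from_region_borders(mesh, make_parcellation(mesh, 10, seed = 8),
                                     c(1, 2))
  t1 <- plant_gradient_timeseries(mesh, dp, cfg, seed = 9)
  t2 <- plant_gradient_timeseries(mesh, dp, cfg, seed = 9)
  expect_identical(t1[[1]]$scans, t2[[1]]$scans)
  expect_identical(t1[[2]]$fd, t2[[2]]$fd)
  expect_length(t1, 2L)
  expect_identical(dim(t1[[1]]$scans[[1]]), c(162L, 40L))
  expect_true(all(unlist(t1[[1]]$fd) >= 0))
})

test_that("sample covariance of long series converges to the target K", {
  mesh <- make_icosphere(1, 30)  # 42 vertices keeps the Monte-Carlo cheap
  parc <- make_parcellation(mesh, 6, seed = 10)
  dp <- distance_from_region_borders(mesh, parc, 1)
  cfg <- simulation_config(subdivisions = 1, n_areas = 6, n_subjects = 1,
                           n_scans = 1, n_timepoints = 10000, seed = 10)
  ts <- plant_gradient_timeseries(mesh, dp, cfg, seed = 11, return_cov = TRUE)
  K <- attr(ts, "K")
  S <- cov(t(ts[[1]]$scans[[1]]))
  expect_lt(max(abs(S - K)), 0.05 * max(abs(K)))
})

test_that("tracer counts follow the exponential distance decay", {
  mesh <- ico4()
  parc <- make_parcellation(mesh, 91, seed = 1)
  dp0 <- rep(0, mesh$n_vertices)  # constant lambda = lambda0
  cfg <- simulation_config(beta_true = 0, n0 = 1e6, n_injections = 3,
                           seed = 12)
  recs <- plant_tracer_counts(mesh, parc, dp0, cfg, seed = 13)
  cents <- area_centroids(mesh, parc)
  for (rec in recs) {
    cnt <- rec$counts
    d <- geodesic_distance_matrix(mesh, from = rec$injection_vertex)[
      1, cents[names(cnt)]]
    keep <- cnt > 50  # Poisson noise negligible only at high expectation
    fitl <- lm(log(cnt[keep]) ~ d[keep])
    expect_equal(unname(coef(fitl)[2]), -1 / cfg$lambda0_mm,
                 tolerance = 0.05)
  }
})

test_that("tracer generator yields the configured number of records", {
  fx <- small_structural_fixture()
  expect_length(fx$records, 29L)
  areas <- vapply(fx$records, function(r) r$injection_area, integer(1))
  expect_identical(anyDuplicated(areas), 0L)
  for (rec in fx$records) {
    expect_true(rec$injection_vertex %in% area_vertices(fx$parc,
                                                        rec$injection_area))
    expect_gt(sum(rec$counts), 0)
  }
  # determinism
  r2 <- plant_tracer_counts(fx$mesh, fx$parc, fx$dist_primary, fx$cfg,
                            seed = fx$cfg$seed + 20)
  expect_identical(vapply(r2, function(r) r$injection_vertex, integer(1)),
                   vapply(fx$records, function(r) r$injection_vertex,
                          integer(1)))
})

test_that("an all-zero draw is redrawn at a larger count scale", {
  mesh <- jittered_sphere()
  parc <- make_parcellation(mesh, 10, seed = 14)
  dp <- rep(0, mesh$n_vertices)
  cfg <- simulation_config(n0 = 1e-6, n_injections = 2, beta_true = 0,
                           seed = 15)
  expect_message(recs <- plant_tracer_counts(mesh, parc, dp, cfg, seed = 16),
                 "redrawing")
  expect_true(all(vapply(recs, function(r) sum(r$counts) > 0, logical(1))))
})

test_that("simulate_dataset assembles a coherent bundle", {
  cfg <- simulation_config(subdivisions = 2, n_areas = 12, n_subjects = 2,
                           n_timepoints = 30, n_scans = 1, n_injections = 6,
                           n_anchors = 2, seed = 17)
  sim <- simulate_dataset(cfg)
  expect_identical(sim$mesh$n_vertices, 162L)
  expect_length(sim$timeseries, 2L)
  expect_length(sim$records, 6L)
  expect_identical(sort(unique(sim$parc$labels[sim$ground_truth$primary_vertices])),
                   sort(sim$primary))
  expect_true(all(sim$dist_primary[sim$ground_truth$primary_vertices] == 0))
})
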