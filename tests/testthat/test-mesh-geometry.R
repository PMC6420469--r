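test_that("mesh constructor validates faces, edges and connectivity", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_s3_class(triangle_mesh(v, rbind(c(1, 2, 3))), "triangle_mesh")
  expect_error(triangle_mesh(v, rbind(c(1, 2, 4))), "face indices")
  expect_error(triangle_mesh(rbind(v, c(0, 0, 0)), rbind(c(1, 2, 3), c(1, 2, 4))),
               "zero-length")
  # two disjoint triangles: refused at load time
  v2 <- rbind(v, v + 10)
  expect_error(triangle_mesh(v2, rbind(c(1, 2, 3), c(4, 5, 6))),
               "connected components")
})

test_that("geodesic distance is zero at sources and exact on a single edge", {
  m <- two_triangle_mesh(edge = 1.2)
  d <- geodesic_distances(m, 1)
  expect_identical(d[1], 0)
  expect_equal(d[2], 1.2, tolerance = 1e-12)
  expect_error(geodesic_distances(m, integer(0)), "empty")
  expect_error(geodesic_distances(m, 99), "out of range")
})

test_that("antipodal icosphere distance approximates the great-circle arc", {
  mesh <- make_icosphere(4, 100)
  # vertex 1 of the icosahedron and its antipode survive subdivision
  v1 <- mesh$vertices[1, ]
  anti <- which.min(colSums((t(mesh$vertices) + v1)^2))
  d <- geodesic_distances(mesh, 1)[anti]
  expect_lt(abs(d - pi * 100) / (pi * 100), 0.03)
})

test_that("sphere accuracy: median relative error below 3%", {
  mesh <- ico4()
  set.seed(1234)
  src <- sample(mesh$n_vertices, 50)
  dst <- sample(mesh$n_vertices, 50)
  D <- geodesic_distance_matrix(mesh, from = src)
  dgeo <- D[cbind(seq_along(src), dst)]
  r <- 30
  cosang <- rowSums(mesh$vertices[src, ] * mesh$vertices[dst, ]) / r^2
  dtrue <- r * acos(pmin(pmax(cosang, -1), 1))
  rel <- abs(dgeo - dtrue) / dtrue
  expect_lt(median(rel), 0.03)
})

test_that("computed distance never exceeds the edge-graph path length", {
  mesh <- jittered_sphere()
  ed <- geograd:::mesh_edges(mesh)
  for (src in c(1, 57)) {
    oracle <- oracle_dijkstra(mesh$n_vertices, ed, src)
    d <- geodesic_distances(mesh, src)
    expect_true(all(d <= oracle + 1e-9))
    # and the unfolding shortcut actually helps somewhere
    expect_true(any(d < oracle - 1e-9))
  }
})

test_that("single-source distances are symmetric in source and target", {
  mesh <- jittered_sphere()
  set.seed(5)
  for (i in 1:5) {
    uv <- sample(mesh$n_vertices, 2)
    d1 <- geodesic_distances(mesh, uv[1])[uv[2]]
    d2 <- geodesic_distances(mesh, uv[2])[uv[1]]
    expect_equal(d1, d2, tolerance = 1e-6)
  }
})

test_that("multi-source map equals the elementwise minimum of per-source maps", {
  mesh <- jittered_sphere()
  srcs <- c(3, 80, 140)
  d <- geodesic_distances(mesh, srcs)
  per <- sapply(srcs, function(s) geodesic_distances(mesh, s))
  expect_equal(as.numeric(d), apply(per, 1, min), tolerance = 1e-12)
  expect_true(all(d >= 0))
  expect_true(all(d[srcs] == 0))
})

test_that("border distance is 0 inside regions and edge-exact one step out", {
  m <- two_triangle_mesh(edge = 1.2)
  parc <- parcellation(c(1, 2, 2, 2), data.frame(label_id = 1:2,
                                                 name = c("a", "b")))
  d <- distance_from_region_borders(m, parc, 1)
  expect_identical(d[1], 0)
  expect_equal(d[2], 1.2, tolerance = 1e-12)  # one edge outside the border
  # a region covering the whole mesh has no border
  parc_all <- parcellation(rep(1, 4), data.frame(label_id = 1, name = "a"))
  expect_error(distance_from_region_borders(m, parc_all, 1), "border")
})

test_that("multi-region border distance is the min of per-region maps", {
  mesh <- jittered_sphere()
  parc <- make_parcellation(mesh, 12, seed = 2)
  ids <- c(2, 7, 11)
  d <- distance_from_region_borders(mesh, parc, ids)
  per <- sapply(ids, function(i) distance_from_region_borders(mesh, parc, i))
  expect_equal(as.numeric(d), apply(per, 1, min), tolerance = 1e-12)
})

test_that("area centroid is the geodesic median with brute-force agreement", {
  mesh <- jittered_sphere()
  parc <- make_parcellation(mesh, 6, seed = 4)
  for (id in area_ids(parc)) {
    vs <- area_vertices(parc, id)
    D <- geodesic_distance_matrix(mesh, from = vs)
    tot <- rowSums(D[, vs, drop = FALSE])
    expect_identical(area_centroid(mesh, parc, id), vs[which.min(tot)])
  }
  # single-vertex area maps to that vertex
  lab <- parc$labels
  lab[7] <- 99L
  nm <- rbind(data.frame(label_id = as.integer(names(parc$names)),
                         name = unname(parc$names)),
              data.frame(label_id = 99L, name = "solo"))
  parc2 <- parcellation(lab, nm)
  expect_identical(area_centroid(mesh, parc2, 99), 7L)
})

test_that("geometric centrality equals the mean of the distance map", {
  mesh <- jittered_sphere()
  for (v in c(1, 44)) {
    expect_equal(geometric_centrality(mesh, v),
                 mean(geodesic_distances(mesh, v)), tolerance = 1e-12)
  }
  # near-uniform on a symmetric sphere
  ico <- make_icosphere(2, 30)
  cen <- geometric_centrality(ico, seq_len(ico$n_vertices))
  expect_lt((max(cen) - min(cen)) / mean(cen), 0.02)
})

test_that("coordinates snap to the nearest vertex with the snap distance", {
  mesh <- two_triangle_mesh()
  s <- snap_to_vertex(mesh, c(0.05, 0.02, 0))
  expect_identical(s$vertex, 1L)
  expect_equal(s$distance_mm, sqrt(0.05^2 + 0.02^2), tolerance = 1e-12)
})
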