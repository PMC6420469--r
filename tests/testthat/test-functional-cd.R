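test_that("frame censoring applies the inclusive FD rule", {
  expect_identical(censor_frames(c(0.1, 0.1, 0.1)), 1:3)
  expect_identical(censor_frames(c(0.3, 0.05, 0.25, 0.2)), c(2L, 4L))
  expect_true(4L %in% censor_frames(c(0.3, 0.05, 0.25, 0.2)))  # 0.2 kept
  expect_error(censor_frames(c(0.5, 0.9)), "no frames")
  expect_error(censor_frames(c(0.1), threshold_mm = 0), "positive")
  expect_error(censor_frames(c(-0.1, 0.1)), "non-negative")
})

test_that("correlation matrix matches the product-moment formula", {
  ts <- rbind(c(1, 2, 4, 3), c(2, 1, 5, 6))
  C <- correlation_matrix(ts)
  x <- ts[1, ]; y <- ts[2, ]
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(C[1, 2], manual, tolerance = 1e-12)
  expect_equal(C, t(C))
  expect_identical(diag(C), c(1, 1))
  # anti-correlated series
  ts2 <- rbind(c(1, 2, 3, 5), -c(1, 2, 3, 5))
  expect_equal(correlation_matrix(ts2)[1, 2], -1, tolerance = 1e-12)
  # agreement with stats::cor on random data
  set.seed(8)
  ts3 <- matrix(rnorm(20 * 30), 20)
  expect_equal(correlation_matrix(ts3), stats::cor(t(ts3)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(correlation_matrix(ts[, 1:2]), "3 timepoints")
})

test_that("zero-variance vertices are excluded with a warning and propagate", {
  set.seed(9)
  ts <- matrix(rnorm(5 * 20), 5)
  ts[3, ] <- 7
  expect_warning(C <- correlation_matrix(ts), "zero-variance")
  expect_true(all(is.na(C[3, ])))
  expect_true(all(is.na(C[, 3])))
  mesh <- jittered_sphere()
  set.seed(10)
  big <- matrix(rnorm(mesh$n_vertices * 50), mesh$n_vertices)
  big[10, ] <- 0
  suppressWarnings(Cb <- correlation_matrix(big))
  map <- fc_distance_map(mesh, Cb, q = 0.05)
  expect_true(is.na(map[10]))
  expect_false(anyNA(map[-10]))
})

test_that("top-q target selection sizes, excludes self, breaks ties low", {
  set.seed(11)
  n <- 101
  C <- correlation_matrix(matrix(rnorm(n * 200), n))
  tq <- topq_targets(C, 5, q = 0.02)
  expect_length(tq, 2)  # round(0.02 * 100)
  for (v in c(1, 50)) expect_false(v %in% topq_targets(C, v, q = 0.1))
  # engineered tie at the cutoff: both candidates share the k-th value
  Ct <- diag(4)
  Ct[1, 2:4] <- Ct[2:4, 1] <- c(0.9, 0.5, 0.5)
  Ct[2, 3] <- Ct[3, 2] <- 0.1; Ct[2, 4] <- Ct[4, 2] <- 0.1
  Ct[3, 4] <- Ct[4, 3] <- 0.2
  expect_identical(topq_targets(Ct, 1, q = 0.5), c(2L, 3L))  # 3 beats tied 4
  expect_error(topq_targets(Ct, 1, q = 1.2), "in \\(0, 1\\)")
})

test_that("FC distance map: k = 1 reduces to nearest-in-correlation distance", {
  mesh <- two_triangle_mesh()
  C <- diag(4)
  C[1, 2:4] <- C[2:4, 1] <- c(0.2, 0.9, 0.1)
  C[2, 3] <- C[3, 2] <- 0.8; C[2, 4] <- C[4, 2] <- 0.3
  C[3, 4] <- C[4, 3] <- 0.4
  D <- geodesic_distance_matrix(mesh)
  map <- fc_distance_map(mesh, C, q = 0.25)  # k = round(0.25 * 3) = 1
  expect_equal(map[1], D[1, 3], tolerance = 1e-12)
  expect_equal(map[2], D[2, 3], tolerance = 1e-12)
})

test_that("FC distance map depends on correlation ranks only", {
  mesh <- jittered_sphere()
  set.seed(12)
  C <- correlation_matrix(matrix(rnorm(mesh$n_vertices * 60), mesh$n_vertices))
  m1 <- fc_distance_map(mesh, C, q = 0.02)
  m2 <- fc_distance_map(mesh, tanh(3 * C), q = 0.02)  # strictly increasing
  expect_identical(as.numeric(m1), as.numeric(m2))
})

test_that("FC distance map matches the brute-force oracle and its bounds", {
  mesh <- jittered_sphere()
  set.seed(13)
  C <- correlation_matrix(matrix(rnorm(mesh$n_vertices * 80), mesh$n_vertices))
  D <- geodesic_distance_matrix(mesh)
  for (q in c(0.02, 0.1)) {
    map <- fc_distance_map(mesh, C, q = q)
    oracle <- oracle_fc_map(C, D, q)
    expect_equal(as.numeric(map), oracle, tolerance = 1e-10)
  }
  map <- fc_distance_map(mesh, C, q = 0.02)
  offdiag_min <- apply(D + diag(Inf, nrow(D)), 1, min)
  expect_true(all(map >= offdiag_min - 1e-9))
  expect_true(all(map <= apply(D, 1, max) + 1e-9))
})

test_that("aggregation averages subjects first, then parcels", {
  parc <- parcellation(c(1, 1, 2, 2, 3, 3),
                       data.frame(label_id = 1:3, name = c("a", "b", "c")))
  m1 <- c(1, 3, 5, 7, 2, 2)
  tab <- aggregate_maps(list(m1, m1), parc)
  expect_equal(tab$mean_cd_mm, c(2, 6, 2))
  tab2 <- aggregate_maps(list(rep(1, 6), rep(4, 6)), parc)
  expect_equal(tab2$mean_cd_mm, rep(2.5, 3))
  # hand-computed 3 areas x 2 subjects
  m2 <- c(2, 4, 6, 10, 0, 8)
  tab3 <- aggregate_maps(list(m1, m2), parc)
  expect_equal(tab3$mean_cd_mm, c(mean(c(1.5, 3.5)), mean(c(5.5, 8.5)),
                                  mean(c(1, 5))))
  # with missing vertices the aggregation order matters; subjects come first:
  # vertex 3 is missing for subject 1, so it drops out entirely, and area 2
  # reduces to vertex 4's cross-subject mean (7+1)/2 = 4
  m3 <- c(1, 3, NA, 7, 2, 2)
  m4 <- c(5, 1, 8, 1, 2, 2)
  tab4 <- aggregate_maps(list(m3, m4), parc)
  expect_equal(tab4$mean_cd_mm[2], 4)
  parcel_first <- mean(c(mean(7), mean(c(8, 1))))  # 5.75: the wrong order
  expect_false(isTRUE(all.equal(tab4$mean_cd_mm[2], parcel_first)))
  expect_identical(tab4$n_vertices, c(2L, 1L, 2L))
  # an area losing every vertex is missing, not zero
  m5 <- c(NA, NA, 1, 1, 1, 1)
  tab5 <- aggregate_maps(list(m5), parc)
  expect_true(is.na(tab5$mean_cd_mm[1]))
})

test_that("per-subject pipeline censors frames before correlating", {
  mesh <- two_triangle_mesh()
  set.seed(14)
  base <- matrix(rnorm(4 * 40), 4)
  spike <- base
  spike[, 40] <- c(100, -100, 100, -100)  # frame that would flip correlations
  fd <- c(rep(0.05, 39), 5)
  censored <- subject_fc_distance(mesh, spike, fd, q = 0.3)
  clean <- subject_fc_distance(mesh, base[, 1:39], q = 0.3)
  expect_equal(as.numeric(censored), as.numeric(clean), tolerance = 1e-12)
})
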