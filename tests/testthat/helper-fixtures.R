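# Shared fixtures and independent oracles. Everything is built in code; the
# big icosphere and its distance matrix are memoised so the acceptance tests
# do not rebuild them per block.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

ico4 <- function() fixture("ico4", function() make_icosphere(4, 30))

# a small irregular mesh (162 vertices): icosphere with radially jittered
# vertices, so edge lengths are unequal and ties are rare
jittered_sphere <- function(seed = 99, subdivisions = 2, radius = 30) {
  base <- make_icosphere(subdivisions, radius)
  set.seed(seed)
  scale <- 1 + stats::runif(base$n_vertices, -0.08, 0.08)
  triangle_mesh(base$vertices * scale, base$faces)
}

# flat strip of two triangles: vertices 1-2 joined by an edge of length
# `edge`, no shorter on-surface route between them
two_triangle_mesh <- function(edge = 1.2) {
  v <- rbind(c(0, 0, 0), c(edge, 0, 0), c(edge / 2, 2, 0), c(edge / 2, -2, 0))
  triangle_mesh(v, rbind(c(1, 2, 3), c(1, 4, 2)))
}

# plain-R Dijkstra on an explicit edge list; independent of igraph
oracle_dijkstra <- function(n, edges, source) {
  dist <- rep(Inf, n)
  dist[source] <- 0
  visited <- rep(FALSE, n)
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]; w <- edges[i, 3]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  repeat {
    u <- which(!visited & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    visited[u] <- TRUE
    for (j in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][j, 1]; w <- adj[[u]][j, 2]
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist
}

# brute-force FC distance map: sort each correlation row, average distances
oracle_fc_map <- function(conn, dist, q) {
  n <- nrow(conn)
  out <- rep(NA_real_, n)
  bad <- is.na(diag(conn))
  k <- max(1L, as.integer(round(q * (sum(!bad) - 1L))))
  for (v in which(!bad)) {
    row <- conn[, v]
    row[v] <- NA
    cand <- which(!is.na(row))
    ord <- cand[order(-row[cand], cand)]
    out[v] <- mean(dist[v, ord[seq_len(k)]])
  }
  out
}

# brute-force structural connectivity distance
oracle_sc_distance <- function(mesh, parc, rec) {
  cents <- sapply(sort(unique(parc$labels)), function(id) {
    vs <- which(parc$labels == id)
    D <- geodesic_distance_matrix(mesh, from = vs)
    vs[which.min(rowSums(D[, vs, drop = FALSE]))]
  })
  names(cents) <- sort(unique(parc$labels))
  cnt <- rec$counts[names(rec$counts) != as.character(rec$injection_area)]
  cnt <- cnt[cnt > 0]
  d <- geodesic_distance_matrix(mesh, from = rec$injection_vertex)[1, ]
  num <- 0; den <- 0
  for (a in names(cnt)) {
    num <- num + cnt[[a]] * d[cents[[a]]]
    den <- den + cnt[[a]]
  }
  num / den
}

# closed-form OLS via the normal equations
oracle_ols <- function(y, X) {
  X1 <- cbind(1, X)
  solve(t(X1) %*% X1, t(X1) %*% y)[, 1]
}

# externally studentized residuals by explicit leave-one-out refits
oracle_rstudent <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  n <- length(y)
  p <- ncol(X1)
  vapply(seq_len(n), function(i) {
    b <- solve(t(X1[-i, ]) %*% X1[-i, ], t(X1[-i, ]) %*% y[-i])
    resid_i <- y[i] - X1[i, , drop = FALSE] %*% b
    s2 <- sum((y[-i] - X1[-i, ] %*% b)^2) / (n - 1 - p)
    h <- X1[i, , drop = FALSE] %*% solve(t(X1[-i, ]) %*% X1[-i, ]) %*%
      t(X1[i, , drop = FALSE])
    as.numeric(resid_i / sqrt(s2 * (1 + h)))
  }, numeric(1))
}

# a fully assembled small structural dataset with planted gradient
small_structural_fixture <- function(seed = 3) {
  fixture(paste0("struct", seed), function() {
    mesh <- ico4()
    cfg <- simulation_config(seed = seed)
    parc <- make_parcellation(mesh, 91, seed = seed)
    primary <- choose_primary_areas(mesh, parc, 4, seed = seed + 10)
    dp <- distance_from_region_borders(mesh, parc, primary)
    recs <- plant_tracer_counts(mesh, parc, dp, cfg, seed = seed + 20)
    tab <- build_sc_table(mesh, parc, recs, primary)
    list(mesh = mesh, cfg = cfg, parc = parc, primary = primary,
         dist_primary = dp, records = recs, sc_table = tab,
         anchor_vertices = which(parc$labels %in% primary))
  })
}
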