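test_that("build_network applies strict cutoffs and matches a brute-force oracle", {
  two <- data.frame(chain = "A", resno = 1:2, x = c(0, 5), y = 0, z = 0)
  expect_equal(sum(build_network(two)$adjacency) / 2, 1)

  consec <- data.frame(chain = "A", resno = 1:2, x = c(0, 3.8), y = 0, z = 0)
  expect_equal(sum(build_network(consec)$adjacency), 0)

  expect_error(build_network(two, lower_cut = 8, upper_cut = 4), "lower_cut")

  set.seed(42)
  pts <- data.frame(chain = "A", resno = 1:50,
                    x = runif(50, 0, 25), y = runif(50, 0, 25), z = runif(50, 0, 25))
  net <- build_network(pts)
  oracle <- matrix(0L, 50, 50)
  for (i in 1:49) for (j in (i + 1):50) {
    d <- sqrt(sum((pts[i, 3:5] - pts[j, 3:5])^2))
    if (d > 4 && d < 8) oracle[i, j] <- oracle[j, i] <- 1L
  }
  expect_equal(unname(net$adjacency), oracle)
  expect_equal(unname(net$degree), rowSums(oracle))
})

test_that("Laplacian structure: zero row sums, PSD, all-ones kernel", {
  a <- er_adjacency(20, 0.3, 11)
  net <- network_from_adjacency(a)
  L <- laplacian_matrix(net)
  expect_equal(max(abs(rowSums(L))), 0)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  expect_equal(as.numeric(L %*% rep(1, 20)), rep(0, 20))
})

test_that("fiedler_vector matches the analytic P3 spectrum and detects disconnection", {
  p3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  fv <- fiedler_vector(network_from_adjacency(p3))
  expect_equal(fv$values, c(0, 1, 3), tolerance = 1e-10)
  expect_equal(fv$fiedler, c(1, 0, -1) / sqrt(2), tolerance = 1e-10)
  expect_equal(sum(fv$fiedler), 0, tolerance = 1e-8)  # orthogonal to ones

  tri <- matrix(1, 3, 3) - diag(3)
  two_tri <- rbind(cbind(tri, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), tri))
  expect_error(fiedler_vector(network_from_adjacency(two_tri)), "disconnected")
})

test_that("Fiedler signs split two cliques joined by a bridge (min-cut bipartition)", {
  k5 <- matrix(1, 5, 5) - diag(5)
  a <- rbind(cbind(k5, matrix(0, 5, 5)), cbind(matrix(0, 5, 5), k5))
  a[5, 6] <- a[6, 5] <- 1L
  part <- spectral_clusters(network_from_adjacency(a), k = 2)
  expect_equal(part$labels, rep(c(1L, 2L), each = 5))
})

test_that("spectral clustering recovers planted 3-block graphs (k = 3 and merged k = 2)", {
  pb <- planted_blocks(c(30, 30, 30), 0.5, 0.02, seed = 7)
  net <- network_from_adjacency(pb$adjacency)
  p3 <- spectral_clusters(net, k = 3, seed = 1)
  expect_equal(ari(p3$labels, pb$labels), 1)

  p2 <- spectral_clusters(net, k = 2, seed = 1)
  merges <- list(c(1, 1, 2), c(1, 2, 1), c(1, 2, 2))
  best <- max(vapply(merges, function(m) ari(p2$labels, m[pb$labels]), numeric(1)))
  expect_gte(best, 0.9)
})

test_that("symmetric barbell splits into equal halves at k = 2", {
  k4 <- matrix(1, 4, 4) - diag(4)
  a <- rbind(cbind(k4, matrix(0, 4, 4)), cbind(matrix(0, 4, 4), k4))
  a[4, 5] <- a[5, 4] <- 1L
  part <- spectral_clusters(network_from_adjacency(a), k = 2)
  expect_equal(tabulate(part$labels), c(4L, 4L))
})

test_that("betweenness matches hand counts and the brute-force oracle", {
  p3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  bc <- betweenness_centrality(network_from_adjacency(p3))
  expect_equal(bc$bc, c(0, 1, 0))

  star <- matrix(0L, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1L
  expect_equal(betweenness_centrality(network_from_adjacency(star))$bc[1], 6)

  a <- er_adjacency(25, 0.2, 3)
  net <- network_from_adjacency(a)
  expect_equal(betweenness_centrality(net)$bc, bc_oracle(a), tolerance = 1e-9)
})

test_that("betweenness tiers follow the raw-count thresholds", {
  a <- er_adjacency(15, 0.3, 2)
  bc <- betweenness_centrality(network_from_adjacency(a), high = 10, medium = 5)
  expect_identical(bc$tier, ifelse(bc$bc > 10, "high",
                                   ifelse(bc$bc > 5, "medium", "low")))
})

test_that("interchain_pairing counts, dominant pair and edge cases", {
  g <- cached_trimer(30, 20, 5, 5, 7)
  net <- build_network(g$model)
  pr <- interchain_pairing(net)
  expect_equal(unname(pr$counts), unname(g$truth$interchain_achieved))
  expect_identical(pr$dominant_pair, c("A", "B"))

  gs <- cached_trimer(20, 8, 8, 8, 5)   # exact C3 symmetry
  prs <- interchain_pairing(build_network(gs$model))
  expect_equal(length(unique(prs$counts)), 1L)
  expect_equal(prs$asymmetry, 1)

  # dimer with no inter-chain edges: flagged dominant pair
  far <- data.frame(chain = rep(c("A", "B"), each = 2), resno = rep(1:2, 2),
                    x = c(0, 5, 500, 505), y = 0, z = 0)
  pr0 <- interchain_pairing(build_network(far))
  expect_true(all(pr0$counts == 0))
  expect_true(is.na(pr0$dominant_pair[1]))
  one_chain <- build_network(data.frame(chain = "A", resno = 1:2,
                                        x = c(0, 5), y = 0, z = 0))
  expect_error(interchain_pairing(one_chain), "2 chains")
})

test_that("cluster_color_map emits per-residue labels in sequence order", {
  g <- cached_trimer(20, 8, 8, 8, 5)
  net <- build_network(g$model)
  part <- spectral_clusters(net, k = 3, seed = 1)
  cm <- cluster_color_map(part)
  expect_identical(names(cm), c("chain", "residue_number", "cluster"))
  expect_equal(nrow(cm), 60L)
  # each chain dominated (> 80%) by one label on the planted fixture
  modal_frac <- vapply(split(cm$cluster, cm$chain),
                       function(x) max(table(x)) / length(x), numeric(1))
  expect_true(all(modal_frac > 0.8))

  empty <- part; empty$labels <- integer(0)
  expect_error(cluster_color_map(empty), "empty")
})

test_that("build_network is invariant under rigid motion", {
  g <- cached_trimer(20, 12, 5, 8, 5)
  ca <- calpha_coordinates(g$model)
  net1 <- build_network(ca)
  R <- oligotopo:::rotation_from_euler(c(1.0, -0.2, 0.4))
  xyz <- as.matrix(ca[, c("x", "y", "z")]) %*% t(R)
  ca2 <- ca; ca2$x <- xyz[, 1] + 3; ca2$y <- xyz[, 2] - 9; ca2$z <- xyz[, 3]
  expect_equal(build_network(ca2)$adjacency, net1$adjacency)
})
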