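# Connectome construction and degree metrics: endpoint assignment, tract
# volumes as voxel unions, ICV normalization, the low-count noise filter,
# and degree/sparsity against brute-force oracles.

make_atlas <- function(n_regions = 10) {
  generate_atlas(synth_config(n_participants = 1, n_regions = n_regions))
}

test_that("streamlines are assigned by endpoint labels only", {
  atlas <- make_atlas(10)
  v5 <- atlas$block_origin[5, ]
  v9 <- atlas$block_origin[9, ]
  poly <- rbind(v5, (v5 + v9) / 2, v9)
  expect_equal(assign_streamline(poly, atlas), c(5L, 9L))
  # both endpoints in the same region: unassigned (no self-loops)
  expect_null(assign_streamline(rbind(v5, v5 + c(1, 0, 0)), atlas))
  # endpoint in background: unassigned
  bg <- v5 - c(1, 0, 0)  # gap voxel next to the block
  expect_null(assign_streamline(rbind(bg, v9), atlas))
  # voxel outside the grid errors
  expect_error(assign_streamline(rbind(c(0, 1, 1), v9), atlas), "outside")
})

test_that("tract volume is the union of visited voxels times voxel volume", {
  # streamlines visiting {a,b,c} and {b,c,d}: 4 distinct voxels x 8 mm^3
  a <- rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1))
  b <- rbind(c(2, 1, 1), c(3, 1, 1), c(4, 1, 1))
  expect_equal(edge_tract_volume(list(a, b), 8, c(10, 10, 10)), 32)
  # one streamline of 10 distinct voxels on a 2 mm grid: 80 mm^3
  s <- cbind(1:10, 1, 1)
  expect_equal(edge_tract_volume(list(s), 8, c(10, 10, 10)), 80)
  # duplicate identical streamlines leave the volume unchanged
  expect_equal(edge_tract_volume(list(s, s, s), 8, c(10, 10, 10)), 80)
})

test_that("ICV normalization divides elementwise and is scale invariant", {
  m <- matrix(c(0, 32, 32, 0), 2, 2)
  expect_equal(normalize_icv(m, 1.5e6)[1, 2], 32 / 1.5e6)
  c_ <- 3.7
  expect_equal(normalize_icv(m * c_, 1.5e6 * c_), normalize_icv(m, 1.5e6))
  expect_equal(normalize_icv(matrix(0, 3, 3), 2e6), matrix(0, 3, 3))
  expect_error(normalize_icv(m, 0), "positive")
  expect_error(normalize_icv(m, -1), "positive")
})

test_that("noise filter removes 1-2 streamline edges, keeps 3+, idempotent", {
  count <- matrix(0L, 4, 4)
  count[1, 2] <- count[2, 1] <- 1L
  count[1, 3] <- count[3, 1] <- 2L
  count[2, 3] <- count[3, 2] <- 3L
  count[3, 4] <- count[4, 3] <- 7L
  w <- (count > 0) * 1e-5
  cn <- connectome(w, count, icv_mm3 = 1.5e6)
  f <- noise_filter(cn)
  expect_equal(f$streamline_count[1, 2], 0)
  expect_equal(f$streamline_count[1, 3], 0)
  expect_equal(f$streamline_count[2, 3], 3)
  expect_equal(f$weight[3, 4], 1e-5)
  expect_identical(noise_filter(f)$weight, f$weight)  # idempotent
  # filtering never adds edges and never increases degree
  d0 <- degree_profile(cn)$degree
  d1 <- degree_profile(f)$degree
  expect_true(all(d1 <= d0))
})

test_that("degree profile: closed forms, oracle equivalence, sparsity identity", {
  # star graph on 5 nodes
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  p <- degree_profile(star)
  expect_equal(unname(p$degree), c(4, 1, 1, 1, 1))
  expect_equal(p$whole_brain, 8 / 5)
  # complete graph has sparsity 0; empty graph sparsity 1
  comp <- 1 - diag(6)
  expect_equal(degree_profile(comp)$sparsity, 0)
  expect_equal(sparsity(matrix(0, 6, 6)), 1)
  # random 12-node graphs: degrees equal brute force and igraph; sparsity + density = 1
  set.seed(31)
  for (rep in 1:5) {
    adj <- random_adj(12, runif(1, 0.1, 0.7))
    p <- degree_profile(adj)
    expect_equal(unname(p$degree), brute_force_degrees(adj))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(unname(p$degree), unname(igraph::degree(g)))
    dens <- igraph::edge_density(g)
    expect_equal(p$sparsity + dens, 1)
  }
})

test_that("regional degrees average member nodes; empty groups error", {
  adj <- random_adj(8, 0.5)
  rt <- data.frame(region_id = 1:8,
                   group = rep(c("frontal", "basal_ganglia"), each = 4))
  p <- degree_profile(adj, rt)
  expect_equal(unname(p$regional["frontal"]),
               mean(brute_force_degrees(adj)[1:4]))
  expect_equal(unname(p$regional["basal_ganglia"]),
               mean(brute_force_degrees(adj)[5:8]))
  rt_bad <- data.frame(region_id = integer(0), group = character(0))
  expect_length(degree_profile(adj, rt_bad)$regional, 0)
})

test_that("masking restricts degrees and preserves symmetry invariants", {
  set.seed(7)
  adj <- random_adj(10, 0.5)
  mask <- random_adj(10, 0.4)
  p_masked <- degree_profile(adj, edge_mask = mask)
  p_raw <- degree_profile(adj)
  expect_true(all(p_masked$degree <= p_raw$degree))
  expect_true(all(p_masked$degree <= brute_force_degrees(mask)))
})

test_that("connectome invariants: symmetry, zero diagonal, count-weight coupling", {
  co <- generate_cohort(synth_config(n_participants = 3, n_regions = 10,
                                     make_events = FALSE, seed = 8))
  for (cn in co$connectomes) {
    f <- noise_filter(cn)
    expect_equal(f$weight, t(f$weight))
    expect_equal(unname(diag(f$weight)), rep(0, 10))
    # weight > 0 iff streamline count >= 3 after filtering
    expect_equal(f$weight > 0, f$streamline_count >= 3)
  }
})

test_that("end-to-end: target edges with >= 3 streamlines are recovered exactly", {
  cfg <- synth_config(n_participants = 1, n_regions = 12, seed = 21)
  atlas <- generate_atlas(cfg)
  set.seed(77)
  pairs <- which(upper.tri(matrix(0, 12, 12)), arr.ind = TRUE)
  sel <- sample(nrow(pairs), 20)
  te <- data.frame(i = pairs[sel, 1], j = pairs[sel, 2],
                   count = sample(1:6, 20, replace = TRUE))
  sl <- generate_streamlines(atlas, te)
  cn <- noise_filter(build_connectome(sl, atlas, icv_mm3 = 1.4e6))
  expected <- te[te$count >= 3, ]
  got <- which(cn$weight > 0 & upper.tri(cn$weight), arr.ind = TRUE)
  expect_setequal(paste(expected$i, expected$j),
                  paste(got[, 1], got[, 2]))
})

test_that("passthrough assignment credits all visited region pairs", {
  atlas <- make_atlas(10)
  # straight line from region 1 through region 2's row neighbours
  v1 <- atlas$block_origin[1, ]
  v3 <- atlas$block_origin[3, ]
  poly <- rbind(v1, v1 + c(1, 0, 0), v1 + c(3, 0, 0), v3)
  cn_end <- build_connectome(list(poly), atlas, 1.5e6)
  cn_pass <- build_connectome(list(poly), atlas, 1.5e6,
                              assignment = "passthrough")
  expect_gte(sum(cn_pass$streamline_count) / 2,
             sum(cn_end$streamline_count) / 2)
})
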