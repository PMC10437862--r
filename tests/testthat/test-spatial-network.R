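test_that("torus grid has the right node count, pitch and neighbour structure", {
  g40 <- build_torus_grid(40, 40, 0.5)
  expect_equal(nrow(g40$coords), 1600)
  expect_equal(g40$width, 20)
  expect_equal(g40$height, 40 * 0.5 * sqrt(3) / 2)

  # every node of a 6x6 grid has exactly 6 neighbours at the lattice spacing
  g6 <- build_torus_grid(6, 6, 0.5)
  D <- toroidal_distance_matrix(g6)
  n_at_spacing <- rowSums(abs(D - 0.5) < 1e-9)
  expect_true(all(n_at_spacing == 6))

  # nearest-neighbour distance equals the spacing for every node
  diag(D) <- Inf
  expect_equal(unname(apply(D, 1, min)), rep(0.5, 36))

  # smallest even grid: all pairwise distances equal by symmetry
  g2 <- build_torus_grid(2, 2, 1.0)
  D2 <- toroidal_distance_matrix(g2)
  offd <- D2[row(D2) != col(D2)]
  expect_true(all(abs(offd - offd[1]) < 1e-12))

  expect_error(build_torus_grid(5, 6, 0.5), "even")
  expect_error(build_torus_grid(6, 7, 0.5), "even")
})

test_that("toroidal distance matches brute force over periodic images", {
  g <- build_torus_grid(10, 8, 0.7)
  set.seed(42)
  n <- nrow(g$coords)
  u <- sample.int(n, 300, replace = TRUE)
  v <- sample.int(n, 300, replace = TRUE)
  got <- toroidal_distance(g, u, v)
  want <- mapply(function(a, b) brute_torus_distance(g, a, b), u, v)
  expect_equal(got, want, tolerance = 1e-12)
  # symmetry and identity
  expect_equal(got, toroidal_distance(g, v, u))
  expect_equal(toroidal_distance(g, u, u), rep(0, length(u)))
  expect_error(toroidal_distance(g, 0, 1), "range")
})

test_that("edge sampling is exact in count, loop-free and reproducible", {
  g <- build_torus_grid(10, 10, 0.5)
  for (eta in c(0, 2, 5)) {
    net <- sample_network(g, eta, 500, seed = 7)
    expect_equal(nrow(net$edges), 500)
    expect_true(all(net$edges$source != net$edges$target))
    expect_equal(nrow(dplyr::distinct(net$edges, source, target)), 500)
    net2 <- sample_network(g, eta, 500, seed = 7)
    expect_identical(net$edges, net2$edges)
  }
  expect_error(sample_network(g, 1, 100 * 99 + 1, seed = 1), "exceeds")
})

test_that("eta = 0 sampling reproduces the all-pairs distance distribution", {
  g <- build_torus_grid(8, 8, 0.5)
  D <- toroidal_distance_matrix(g)
  all_d <- D[row(D) != col(D)]
  breaks <- unique(stats::quantile(all_d, seq(0, 1, 0.2)))
  breaks[1] <- 0
  breaks[length(breaks)] <- max(all_d) + 1
  expected_p <- as.vector(table(cut(all_d, breaks))) / length(all_d)
  # pool edges from several seeds for a stable chi-square test
  obs <- unlist(lapply(1:8, function(s) {
    sample_network(g, 0, 800, seed = s)$edges$distance_mm
  }))
  counts <- as.vector(table(cut(obs, breaks)))
  pval <- suppressWarnings(stats::chisq.test(counts, p = expected_p)$p.value)
  expect_gt(pval, 0.01)
})

test_that("mean edge distance decreases with eta and large eta pins edges to neighbours", {
  g <- build_torus_grid(10, 10, 0.5)
  means <- sapply(1:5, function(eta) {
    mean(sapply(1:8, function(s) {
      mean(sample_network(g, eta, 400, seed = s)$edges$distance_mm)
    }))
  })
  expect_true(all(diff(means) < 0))
  net <- sample_network(g, 50, 60, seed = 3)
  expect_true(all(abs(net$edges$distance_mm - 0.5) < 1e-9))
})

test_that("delay quantisation follows the documented rounding rule", {
  net <- make_connectome(4, rbind(c(1, 2), c(2, 3), c(3, 4)),
                         distance = c(0.5, 1.0, 0.05))
  out <- assign_delays(net, velocity = 4, dt = 1e-4)
  # 0.5 mm -> 0.125 ms -> 1.25 steps -> 1; 1.0 mm -> 2.5 steps -> 2 (half to
  # even); 0.05 mm -> 0.125 steps -> floor at 1
  expect_equal(out$edges$delay_steps, c(1L, 2L, 1L))
  off <- assign_delays(net, 4, 1e-4, enabled = FALSE)
  expect_equal(off$edges$delay_steps, c(0L, 0L, 0L))
})

test_that("graph metrics match closed forms and a brute-force reference", {
  k5 <- make_connectome(5, complete_edges(5))
  m <- graph_metrics(k5)
  expect_equal(m$clustering, 1)
  expect_equal(m$path_length, 1)
  expect_equal(m$efficiency, 1)

  ring <- make_connectome(6, cbind(1:6, c(2:6, 1)))
  mr <- graph_metrics(ring)
  expect_equal(mr$path_length, 3) # mean of 1..5
  expect_equal(mr$efficiency, mean(1 / (1:5)))

  # random directed graphs vs Floyd-Warshall + explicit triple counting
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    all_e <- complete_edges(n)
    m_e <- sample(nrow(all_e), round(0.2 * nrow(all_e)))
    edges <- all_e[m_e, , drop = FALSE]
    net <- make_connectome(n, edges)
    got <- graph_metrics(net)
    sp <- brute_shortest_paths(n, edges)
    off <- row(sp) != col(sp)
    fin <- off & is.finite(sp)
    expect_equal(got$path_length, mean(sp[fin]), tolerance = 1e-12)
    expect_equal(got$efficiency, sum(1 / sp[fin]) / sum(off), tolerance = 1e-12)
    expect_equal(got$clustering, brute_directed_clustering(n, edges),
                 tolerance = 1e-12)
  }
})

test_that("position shuffling preserves the adjacency and degree sequence", {
  g <- build_torus_grid(8, 8, 0.5)
  net <- assign_delays(sample_network(g, 4, 300, seed = 5), 4, 1e-4)
  sh <- shuffle_positions(net, g, seed = 17)
  expect_identical(sh$net$edges$source, net$edges$source)
  expect_identical(sh$net$edges$target, net$edges$target)
  expect_identical(sh$net$edges$delay_steps, net$edges$delay_steps)
  expect_false(isTRUE(all.equal(sh$net$edges$distance_mm,
                                net$edges$distance_mm)))
  # shuffled distances are consistent with the permuted embedding
  expect_equal(sh$net$edges$distance_mm,
               toroidal_distance(g, sh$perm[net$edges$source],
                                 sh$perm[net$edges$target]))
  # recomputing delays from shuffled distances changes them
  sh2 <- shuffle_positions(net, g, seed = 17, recompute_delays = TRUE,
                           velocity = 4, dt = 1e-4)
  expect_false(identical(sh2$net$edges$delay_steps, net$edges$delay_steps))
})

test_that("edge lists round-trip through CSV", {
  g <- build_torus_grid(6, 6, 0.5)
  net <- assign_delays(sample_network(g, 2, 100, seed = 9), 4, 1e-4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_edgelist_csv(net, path)
  back <- read_edgelist_csv(path, n_nodes = 36)
  expect_equal(back$edges, net$edges)
})
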