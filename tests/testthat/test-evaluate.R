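test_that("graph correlation is the Pearson correlation of dyad vectors", {
  a <- rand_net(8, 0.4, 1)
  expect_equal(graph_correlation(a, a), 1.0)
  comp <- daily_network(1 - a$adjacency - diag(8), a$roster)
  expect_equal(graph_correlation(a, comp), -1.0)
  # hand-computed 4-node example over the 6 dyads
  x <- net_from_edges(4, list(c(1, 2), c(1, 3), c(3, 4)))
  y <- net_from_edges(4, list(c(1, 2), c(2, 3)))
  vx <- c(1, 1, 0, 0, 0, 1)  # dyads (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  vy <- c(1, 0, 0, 1, 0, 0)
  hand <- sum((vx - mean(vx)) * (vy - mean(vy))) /
    sqrt(sum((vx - mean(vx))^2) * sum((vy - mean(vy))^2))
  expect_equal(graph_correlation(x, y), hand)
  # symmetry and joint-relabelling invariance
  expect_equal(graph_correlation(x, y), graph_correlation(y, x))
  p <- c(3, 1, 4, 2)
  xp <- daily_network(x$adjacency[p, p], x$roster)
  yp <- daily_network(y$adjacency[p, p], y$roster)
  expect_equal(graph_correlation(xp, yp), graph_correlation(x, y))
  # zero-variance networks are undefined
  empty <- daily_network(matrix(0L, 4, 4), x$roster)
  expect_warning(r <- graph_correlation(x, empty), "zero-variance")
  expect_true(is.na(r))
})

test_that("centrality rank correlations follow hand-ranked Spearman", {
  star <- net_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  path <- net_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(centrality_rho(star, star, "degree"), 1.0)
  # star degrees (3,1,1,1) vs path degrees (1,2,2,1), average ranks:
  # (4,2,2,2) vs (1.5,3.5,3.5,1.5) -> r = -2/sqrt(12)
  expect_equal(centrality_rho(star, path, "degree"), -1 / sqrt(3))
  expect_equal(centrality_rho(star, star, "betweenness"), 1.0)
  expect_equal(centrality_rho(star, star, "eigenvector"), 1.0)
  # constant centrality is undefined
  ring <- net_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  expect_warning(r <- centrality_rho(ring, path, "degree"), "constant")
  expect_true(is.na(r))
})

test_that("label permutation has zero expected degree correlation", {
  # exact expectation: for any fixed degree vector the permuted ranks are a
  # mean-centred draw, so E[rho] = 0 (verified by full enumeration over all
  # 5! permutations at n = 5)
  n <- 30
  net <- rand_net(n, 0.3, 44)
  set.seed(45)
  n_perm <- 20000L
  rhos <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    perm <- daily_network(net$adjacency[p, p], net$roster)
    centrality_rho(net, perm, "degree")
  }, numeric(1))
  se <- sd(rhos) / sqrt(n_perm)
  expect_lt(abs(mean(rhos)), 3 * se)
})

test_that("correlograms tabulate all day pairs by lag", {
  h <- generate_herd(25, 4, seed = 61)
  cov <- build_dyad_covariates(h$pedigree, h$herd, h$herd$cow_id)
  ser <- generate_network_series(h, cov, n_days = 14, seed = 62)
  cg <- pairwise_correlogram(ser)
  expect_equal(nrow(cg$pairs), choose(14, 2))  # 91 ordered day pairs
  expect_equal(sum(cg$by_lag$n_pairs), 91)
  # a persistent series decays: lag-1 mean above lag-10 mean
  expect_gt(cg$by_lag$mean_correlation[cg$by_lag$lag == 1],
            cg$by_lag$mean_correlation[cg$by_lag$lag == 10])
  # i.i.d. networks have near-zero correlation at every lag
  iid <- lapply(1:10, function(d) rand_net(25, 0.2, 700 + d))
  cg0 <- pairwise_correlogram(iid)
  expect_true(all(abs(cg0$by_lag$mean_correlation) < 0.1))
})

test_that("window enumeration matches the sliding-window design", {
  w <- enumerate_windows(14, 5)
  expect_equal(nrow(w), 9)
  expect_equal(w$target_day, w$window_end + 1L)
  expect_equal(w$window_end - w$window_start, rep(4L, 9))
  expect_equal(nrow(enumerate_windows(6, 5)), 1)
  expect_warning(w0 <- enumerate_windows(5, 5), "more than")
  expect_equal(nrow(w0), 0)
})

test_that("scenario prediction scores simulations against the target day", {
  h <- generate_herd(25, 4, seed = 81)
  cov <- build_dyad_covariates(h$pedigree, h$herd, h$herd$cow_id)
  ser <- generate_network_series(h, cov, n_days = 6, seed = 82)
  sc <- enumerate_windows(6, 5)[1, ]
  res <- predict_scenario(ser, cov, model_spec("M1"), sc, n_sim = 50,
                          seed = 83)
  expect_s3_class(res, "accuracy_summary")
  expect_equal(res$n_networks, 50)
  expect_true(res$converged)
  expect_true(abs(res$graph_corr["mean"]) <= 1)
  res2 <- predict_scenario(ser, cov, model_spec("M1"), sc, n_sim = 50,
                           seed = 83)
  expect_equal(res, res2)
  # a window with no network change cannot be fitted: scenario is skipped
  frozen <- c(rep(list(ser[[1]]), 5), ser[2])
  skip_res <- predict_scenario(frozen, cov, model_spec("M1"),
                               enumerate_windows(6, 5)[1, ], n_sim = 10,
                               seed = 84)
  expect_true(skip_res$skipped)
  expect_equal(skip_res$n_networks, 0)
})

test_that("the naive baseline centres on the permutation expectations", {
  h <- generate_herd(40, 6, seed = 85)
  cov <- build_dyad_covariates(h$pedigree, h$herd, h$herd$cow_id)
  ser <- generate_network_series(h, cov, n_days = 2, seed = 86)
  base <- naive_baseline(ser[[1]], ser[[2]], n_perm = 400, seed = 87)
  expect_equal(base$n_networks, 400)
  n <- 40
  se_rho <- 1 / sqrt(n - 1) / sqrt(400)
  expect_lt(abs(base$degree_rho["mean"]), 3 * se_rho)
  expect_lt(abs(base$graph_corr["mean"]), 0.02)
  # permuting the previous-day network is available behind the switch
  alt <- naive_baseline(ser[[1]], ser[[2]], n_perm = 50, seed = 88,
                        permute = "previous")
  expect_equal(alt$n_networks, 50)
  expect_lt(abs(alt$graph_corr["mean"]), 0.1)
})

test_that("accuracy SDs shrink as the standard error of the mean with 4x draws", {
  h <- generate_herd(40, 6, seed = 95)
  cov <- build_dyad_covariates(h$pedigree, h$herd, h$herd$cow_id)
  ser <- generate_network_series(h, cov, n_days = 6, seed = 96)
  sc <- enumerate_windows(6, 5)[1, ]
  r1 <- predict_scenario(ser, cov, model_spec("M1"), sc, n_sim = 100, seed = 97)
  r4 <- predict_scenario(ser, cov, model_spec("M1"), sc, n_sim = 400, seed = 98)
  expect_gte(r1$graph_corr["sd"], 0)
  expect_gte(r4$graph_corr["sd"], 0)
  se1 <- r1$graph_corr["sd"] / sqrt(100)
  se4 <- r4$graph_corr["sd"] / sqrt(400)
  expect_lt(se4, se1)
})

test_that("the pipeline produces a full scenario table and reproduces", {
  cfg <- list(synthetic = list(n_cows = 20L, n_founder_pairs = 4L,
                               n_days = 7L, initial_density = 0.12,
                               coefs = NULL),
              groups = "g1", areas = c("resting", "feeding"),
              models = "M1", n_sim = 20L, n_perm = 20L, seed = 5L)
  rep1 <- run_pipeline(cfg)
  expect_s3_class(rep1, "herdnet_report")
  # 1 group x 2 areas x (7-5) windows x 1 model
  expect_equal(nrow(rep1$scenarios), 4)
  expect_named(rep1$correlograms, c("g1.resting", "g1.feeding"))
  rep2 <- run_pipeline(cfg)
  expect_equal(rep1$scenarios, rep2$scenarios)
  d <- withr::local_tempdir()
  write_report(rep1, d)
  expect_true(file.exists(file.path(d, "scenarios.csv")))
  expect_true(file.exists(file.path(d, "correlogram.csv")))
  expect_true(file.exists(file.path(d, "manifest.yaml")))
  expect_equal(nrow(read.csv(file.path(d, "scenarios.csv"))), 4)
})
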