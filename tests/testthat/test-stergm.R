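test_that("transition decomposition satisfies the separability identities", {
  a <- rand_net(10, 0.3, 1)
  b <- rand_net(10, 0.3, 2)
  tr <- decompose_transition(a, b)
  expect_equal(tr$y_plus$adjacency, pmax(a$adjacency, b$adjacency))
  expect_equal(tr$y_minus$adjacency, pmin(a$adjacency, b$adjacency))
  # y_plus >= y_prev >= y_minus, elementwise over all dyads
  expect_true(all(tr$y_plus$adjacency >= a$adjacency))
  expect_true(all(a$adjacency >= tr$y_minus$adjacency))
  # reconstruction: y_next = y_minus | (y_plus \ y_prev), dyad by dyad
  recon <- pmax(tr$y_minus$adjacency,
                tr$y_plus$adjacency * (1L - a$adjacency))
  expect_equal(recon, b$adjacency)
  # degenerate cases
  same <- decompose_transition(a, a)
  expect_equal(same$y_plus$adjacency, a$adjacency)
  expect_equal(same$y_minus$adjacency, a$adjacency)
  e1 <- net_from_edges(4, list(c(1, 2)))
  e2 <- net_from_edges(4, list(c(3, 4)))
  dis <- decompose_transition(e1, e2)
  expect_equal(sum(dis$y_minus$adjacency), 0)
  expect_equal(sum(dis$y_plus$adjacency) / 2, 2)
  expect_error(decompose_transition(a, rand_net(9, 0.3, 3)), "roster")
})

test_that("change statistics match toggle differences of whole-network stats", {
  cov <- tiny_cov(8, parity = c(1, 1, 2, 2, 3, 4, 5, 1),
                  birth_offsets = c(0, 2, 50, 53, 100, 200, 300, 400))
  spec <- model_spec("M2")
  net <- rand_net(8, 0.4, 7)
  for (i in 1:7) for (j in (i + 1):8) {
    on <- net$adjacency; on[i, j] <- on[j, i] <- 1L
    off <- net$adjacency; off[i, j] <- off[j, i] <- 0L
    brute <- oracle_stats(on, cov) - oracle_stats(off, cov)
    expect_equal(unname(change_statistics(net, c(i, j), spec, cov)),
                 unname(brute[spec$terms]))
  }
  # canonical examples: edges always 1; a path i-k-j gives one triangle
  path <- net_from_edges(3, list(c(1, 3), c(2, 3)))
  cs <- change_statistics(path, c(1, 2), spec, tiny_cov(3))
  expect_equal(cs[["edges"]], 1)
  expect_equal(cs[["triangles"]], 1)
})

test_that("edges-only MPLE equals the closed-form intercept", {
  y1 <- net_from_edges(5, list(c(1, 2), c(1, 3), c(4, 5)))
  y2 <- net_from_edges(5, list(c(1, 2), c(2, 3), c(4, 5), c(3, 5)))
  fit <- fit_mple(as_transitions(list(y1, y2)), model_spec("M1", "edges"),
                  tiny_cov(5))
  # 7 empty dyads, 2 formed; 3 present dyads, 2 persisted
  expect_equal(unname(coef(fit, "formation")), qlogis(2 / 7), tolerance = 1e-6)
  expect_equal(unname(coef(fit, "persistence")), qlogis(2 / 3), tolerance = 1e-6)
})

test_that("MPLE equals direct transition-likelihood maximisation (M1)", {
  # independent oracle: code the transition log-likelihood from the model
  # definition (Bernoulli per free dyad with logistic probabilities) and
  # maximise it numerically
  cov <- related_cov()
  spec <- model_spec("M1", terms = c("edges", "kinship", "kindergarten"))
  series <- lapply(1:6, function(k) rand_net(5, 0.5, 300 + k, cov$roster))
  trs <- as_transitions(series)
  fit <- fit_mple(trs, spec, cov)
  expect_true(fit$converged)
  dyads <- which(upper.tri(diag(5)), arr.ind = TRUE)
  xmat <- cbind(1, cov$kinship[dyads], as.numeric(cov$kindergarten[dyads]))
  negll <- function(theta, phase) {
    ll <- 0
    for (tr in trs) {
      prev <- tr$y_prev$adjacency[dyads]
      nxt <- tr$y_next$adjacency[dyads]
      sel <- if (phase == "formation") prev == 0 else prev == 1
      eta <- drop(xmat[sel, , drop = FALSE] %*% theta)
      ll <- ll + sum(nxt[sel] * eta - log1p(exp(eta)))
    }
    -ll
  }
  for (phase in c("formation", "persistence")) {
    ora <- optim(rep(0, 3), negll, phase = phase, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_equal(unname(coef(fit, phase)), ora$par, tolerance = 1e-6)
  }
})

test_that("degenerate transitions flag separation instead of erroring", {
  # identical networks: no formation events, no dissolution events
  net <- rand_net(8, 0.3, 5)
  fit <- fit_mple(as_transitions(list(net, net)), model_spec("M1", "edges"),
                  tiny_cov(8))
  expect_false(fit$converged)
  expect_false(fit$diagnostics$formation$converged)
  # complete previous network: formation phase has no free dyads
  full <- daily_network(1 - diag(8), as.character(1:8))
  expect_error(fit_mple(list(decompose_transition(full, net)),
                        model_spec("M1", "edges"), tiny_cov(8)),
               "zero free dyads")
})

test_that("dyad-independent simulation matches closed-form tie probabilities", {
  cov <- tiny_cov(6, parity = c(1, 2, 3, 3, 2, 1),
                  birth_offsets = c(0, 1, 2, 200, 201, 400))
  spec <- model_spec("M1")
  coefs <- list(
    formation = c(edges = -1.2, parity2 = 0.3, parity3plus = -0.2,
                  parity_match = 0.5, kinship = 0, kindergarten = 0.7),
    persistence = c(edges = 0.8, parity2 = -0.3, parity3plus = 0.2,
                    parity_match = 0.2, kinship = 0, kindergarten = 0.3))
  y_prev <- rand_net(6, 0.4, 77)
  n_sim <- 2000L
  sims <- simulate_transition(y_prev, coefs, spec = spec, cov = cov,
                              n_samples = n_sim, seed = 99)
  dyads <- which(upper.tri(diag(6)), arr.ind = TRUE)
  freq <- rowMeans(vapply(sims, function(net) net$adjacency[dyads],
                          numeric(nrow(dyads))))
  for (r in seq_len(nrow(dyads))) {
    ij <- dyads[r, , drop = FALSE]
    phase <- if (y_prev$adjacency[ij] == 1) "persistence" else "formation"
    eta <- sum(coefs[[phase]] *
                 change_statistics(y_prev, ij[1, ], spec, cov))
    p <- plogis(eta)
    se <- sqrt(p * (1 - p) / n_sim)
    expect_lt(abs(freq[r] - p), 3 * se + 1e-9)
  }
})

test_that("extreme coefficients drive the chain to its limiting regimes", {
  cov <- tiny_cov(10)
  spec <- model_spec("M1")
  freeze <- list(
    formation = c(edges = -10, parity2 = 0, parity3plus = 0,
                  parity_match = 0, kinship = 0, kindergarten = 0),
    persistence = c(edges = 10, parity2 = 0, parity3plus = 0,
                    parity_match = 0, kinship = 0, kindergarten = 0))
  y1 <- rand_net(10, 0.5, 13)
  nxt <- simulate_transition(y1, freeze, spec = spec, cov = cov,
                             n_samples = 1, seed = 4)[[1]]
  expect_gt(graph_correlation(y1, nxt), 0.95)
  # both phases strongly negative: the network empties
  die <- list(formation = freeze$formation,
              persistence = replace(freeze$persistence, 1, -10))
  nxt <- simulate_transition(y1, die, spec = spec, cov = cov,
                             n_samples = 1, seed = 4)[[1]]
  expect_lt(sum(nxt$adjacency), 4)
  # empty previous network + suppressed formation: all samples empty
  empty <- daily_network(matrix(0L, 10, 10), as.character(1:10))
  sims <- simulate_transition(empty, die, spec = spec, cov = cov,
                              n_samples = 5, seed = 4)
  expect_true(all(vapply(sims, function(s) sum(s$adjacency) == 0, logical(1))))
})

test_that("the MH sampler reproduces exact M2 phase distributions on 4 nodes", {
  cov <- tiny_cov(4, parity = c(1, 2, 3, 1), birth_offsets = c(0, 3, 40, 80))
  spec <- model_spec("M2")
  coefs <- list(
    formation = c(edges = -0.5, parity2 = 0.2, parity3plus = 0.1,
                  parity_match = 0.3, kinship = 0, kindergarten = 0.4,
                  triangles = 0.8),
    persistence = c(edges = 0.5, parity2 = 0, parity3plus = 0,
                    parity_match = 0, kinship = 0, kindergarten = 0,
                    triangles = 0.5))
  y_prev <- net_from_edges(4, list(c(1, 2)))
  sims <- simulate_transition(y_prev, coefs, spec = spec, cov = cov,
                              n_samples = 2000, burn_in = 20, seed = 17)
  prev <- y_prev$adjacency
  free <- which(upper.tri(prev) & prev == 0L, arr.ind = TRUE)
  exact <- enumerate_phase(prev, free, coefs$formation, cov)
  obs <- vapply(sims, function(net) paste(net$adjacency[free], collapse = ""),
                character(1))
  p_hat <- as.numeric(table(factor(obs, levels = exact$key)) / length(obs))
  expect_lt(sum(abs(p_hat - exact$prob)) / 2, 0.08)
})

test_that("MPLE is unbiased for M1 at Monte-Carlo precision", {
  truth <- default_coefs("M1")
  h <- generate_herd(40, 6, seed = 70)
  cov <- build_dyad_covariates(h$pedigree, h$herd, h$herd$cow_id)
  spec <- model_spec("M1")
  reps <- 200L
  est_f <- matrix(NA_real_, reps, 6)
  est_p <- matrix(NA_real_, reps, 6)
  for (s in seq_len(reps)) {
    ser <- generate_network_series(h, cov, coefs = truth, n_days = 5,
                                   seed = 7000 + s)
    fit <- fit_mple(as_transitions(ser), spec, cov)
    est_f[s, ] <- coef(fit, "formation")
    est_p[s, ] <- coef(fit, "persistence")
  }
  # family-corrected bound for 12 simultaneous comparisons
  z_f <- (colMeans(est_f) - truth$formation) / (apply(est_f, 2, sd) / sqrt(reps))
  z_p <- (colMeans(est_p) - truth$persistence) / (apply(est_p, 2, sd) / sqrt(reps))
  expect_true(all(abs(c(z_f, z_p)) < 3))
})

test_that("degeneracy assessment flags pathological fits and passes sound ones", {
  h <- generate_herd(30, 5, seed = 55)
  cov <- build_dyad_covariates(h$pedigree, h$herd, h$herd$cow_id)
  ser <- generate_network_series(h, cov, n_days = 6, seed = 56)
  fit <- fit_mple(as_transitions(ser), model_spec("M1"), cov)
  rep_ok <- assess_degeneracy(fit, cov = cov, seed = 1)
  expect_false(rep_ok$degenerate)
  # a large positive triangle coefficient melts the graph toward completeness
  bad <- fit
  bad$spec <- model_spec("M2")
  bad$formation$coef <- c(fit$formation$coef, triangles = 5)
  bad$persistence$coef <- c(fit$persistence$coef, triangles = 5)
  bad$observed_stats <- lapply(bad$observed_stats, function(g)
    c(g, triangles = 0))
  rep_bad <- assess_degeneracy(bad, cov = cov, seed = 2, burn_in = 40)
  expect_true(rep_bad$degenerate)
  # non-finite standard errors flag without simulating
  nf <- fit
  nf$formation$se[1] <- NaN
  expect_true(assess_degeneracy(nf, cov = cov, seed = 3)$degenerate)
})

test_that("fit objects expose the standard modelling interface", {
  h <- generate_herd(20, 4, seed = 91)
  cov <- build_dyad_covariates(h$pedigree, h$herd, h$herd$cow_id)
  ser <- generate_network_series(h, cov, n_days = 4, seed = 92)
  fit <- fit_mple(as_transitions(ser), model_spec("M1"), cov)
  expect_s3_class(fit, "stergm_fit")
  expect_named(coef(fit), c("formation", "persistence"))
  expect_equal(dim(vcov(fit, "formation")), c(6, 6))
  expect_output(print(fit), "STERGM fit")
  expect_output(print(summary(fit)), "Persistence phase")
  pr <- predict(fit, ser[[4]], cov = cov)
  expect_true(all(pr[upper.tri(pr)] >= 0 & pr[upper.tri(pr)] <= 1))
  sims <- simulate(fit, nsim = 3, seed = 1, cov = cov)
  expect_length(sims, 3)
  sims2 <- simulate(fit, nsim = 3, seed = 1, cov = cov)
  expect_identical(lapply(sims, `[[`, "adjacency"),
                   lapply(sims2, `[[`, "adjacency"))
})
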