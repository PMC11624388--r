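#' Graph correlation between two networks
#'
#' Pearson product-moment correlation between the strict-upper-triangle
#' dyad vectors of the two adjacency matrices -- the covariance of the
#' adjacency matrices divided by their standard deviations. Requires
#' identical rosters. If either network has zero variance (empty or
#' complete), the correlation is undefined and `NA` is returned with a
#' warning.
#'
#' @param a,b [daily_network()] objects on the same roster.
#' @return correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
graph_correlation <- function(a, b) {
  stopifnot(inherits(a, "daily_network"), inherits(b, "daily_network"))
  if (!identical(a$roster, b$roster)) stop("rosters differ")
  va <- upper_tri_vec(a$adjacency); vb <- upper_tri_vec(b$adjacency)
  if (sd(va) == 0 || sd(vb) == 0) {
    warning("zero-variance network; graph correlation undefined")
    return(NA_real_)
  }
  cor(va, vb)
}

centrality_vector <- function(net, measure) {
  switch(measure,
         degree = igraph::degree(as_igraph(net)),
         betweenness = igraph::betweenness(as_igraph(net)),
         eigenvector = {
           # dense symmetric eigendecomposition: deterministic, and nodes in
           # exactly symmetric positions get exactly tied scores
           ev <- eigen(net$adjacency, symmetric = TRUE)
           if (max(abs(ev$values)) < 1e-12) return(rep(0, nrow(net$adjacency)))
           v <- abs(ev$vectors[, which.max(ev$values)])
           round(v / max(v), 12)
         },
         stop("unknown centrality measure: ", measure))
}

#' Spearman correlation of node centralities across two networks
#'
#' Computes the chosen centrality per node in each network and returns the
#' Spearman rank correlation between the two vectors (average ranks for
#' ties). Degree centrality tracks how well the total number of social
#' contacts per cow is recovered; betweenness and eigenvector centrality
#' probe brokerage and core positions.
#'
#' @param a,b [daily_network()] objects on the same roster.
#' @param measure `"degree"`, `"betweenness"` or `"eigenvector"`.
#' @return Spearman rho, or `NA` (with warning) if a centrality vector is
#'   constant.
#' @export
centrality_rho <- function(a, b, measure = c("degree", "betweenness",
                                             "eigenvector")) {
  measure <- match.arg(measure)
  stopifnot(inherits(a, "daily_network"), inherits(b, "daily_network"))
  if (!identical(a$roster, b$roster)) stop("rosters differ")
  ca <- centrality_vector(a, measure); cb <- centrality_vector(b, measure)
  if (sd(ca) == 0 || sd(cb) == 0) {
    warning("constant ", measure, " vector; rank correlation undefined")
    return(NA_real_)
  }
  cor(ca, cb, method = "spearman")
}

#' Pairwise graph-correlation correlogram of a daily series
#'
#' Graph correlation for every day pair (1-2, 1-3, ..., 13-14), tabulated
#' by lag, plus the mean correlation per lag. The decay of the mean with
#' lag indicates how many past days carry information about today's
#' network -- the basis for choosing the sliding-window length.
#'
#' @param series list of [daily_network()] in day order (>= 2).
#' @return object of class `correlogram`: list with `pairs` (data.frame
#'   `day_i`, `day_j`, `lag`, `correlation`) and `by_lag` (data.frame `lag`,
#'   `mean_correlation`, `n_pairs`).
#' @export
pairwise_correlogram <- function(series) {
  stopifnot(length(series) >= 2L)
  nd <- length(series)
  pairs <- do.call(rbind, lapply(seq_len(nd - 1L), function(i)
    data.frame(day_i = i, day_j = (i + 1L):nd)))
  pairs$lag <- pairs$day_j - pairs$day_i
  pairs$correlation <- mapply(function(i, j)
    graph_correlation(series[[i]], series[[j]]), pairs$day_i, pairs$day_j)
  by_lag <- aggregate(correlation ~ lag, pairs,
                      function(v) mean(v, na.rm = TRUE))
  names(by_lag)[2] <- "mean_correlation"
  by_lag$n_pairs <- as.vector(table(pairs$lag))
  structure(list(pairs = pairs, by_lag = by_lag), class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat("Graph-correlation correlogram over", nrow(x$pairs), "day pairs\n")
  print(round(x$by_lag, 3), row.names = FALSE)
  invisible(x)
}

#' @export
plot.correlogram <- function(x, ...) {
  graphics::plot(x$pairs$lag, x$pairs$correlation, xlab = "lag (days)",
                 ylab = "graph correlation", ...)
  graphics::lines(x$by_lag$lag, x$by_lag$mean_correlation, col = 2, lwd = 2)
  invisible(x)
}

#' Enumerate sliding-window prediction scenarios
#'
#' A scenario fits the model on `window_len` consecutive days and predicts
#' the following day, so `n_days` days give `n_days - window_len` scenarios
#' (14 days with 5-day windows: 9 per group and functional area).
#'
#' @param n_days days available.
#' @param window_len window length in days (default 5).
#' @return data.frame with columns `window_start`, `window_end`,
#'   `target_day`; zero rows (with a warning) when `n_days <= window_len`.
#' @export
enumerate_windows <- function(n_days, window_len = 5L) {
  if (n_days <= window_len) {
    warning("need more than ", window_len, " days; returning no scenarios")
    return(data.frame(window_start = integer(0), window_end = integer(0),
                      target_day = integer(0)))
  }
  start <- seq_len(n_days - window_len)
  data.frame(window_start = start, window_end = start + window_len - 1L,
             target_day = start + window_len)
}

summarise_scores <- function(scores, n_networks, extra = list()) {
  agg <- function(v) {
    drop_n <- sum(is.na(v))
    if (drop_n)
      warning(drop_n, " undefined correlation(s) dropped from the summary")
    c(mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE))
  }
  out <- c(list(
    graph_corr = agg(scores$graph_corr),
    degree_rho = agg(scores$degree_rho),
    betweenness_rho = agg(scores$betweenness_rho),
    eigenvector_rho = agg(scores$eigenvector_rho),
    n_networks = n_networks), extra)
  class(out) <- "accuracy_summary"
  out
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf("Accuracy over %d networks%s\n", x$n_networks,
              if (!is.null(x$skipped) && x$skipped) " [SKIPPED]" else ""))
  for (m in c("graph_corr", "degree_rho", "betweenness_rho",
              "eigenvector_rho"))
    cat(sprintf("  %-16s mean %6.3f  sd %.3f\n", m, x[[m]]["mean"],
                x[[m]]["sd"]))
  invisible(x)
}

score_networks <- function(sims, observed) {
  one <- function(net, measure) suppressWarnings(
    centrality_rho(net, observed, measure))
  data.frame(
    graph_corr = vapply(sims, function(s)
      suppressWarnings(graph_correlation(s, observed)), numeric(1)),
    degree_rho = vapply(sims, one, numeric(1), measure = "degree"),
    betweenness_rho = vapply(sims, one, numeric(1), measure = "betweenness"),
    eigenvector_rho = vapply(sims, one, numeric(1), measure = "eigenvector"))
}

#' Fit, predict and score one sliding-window scenario
#'
#' Fits the STERGM on the window's transitions, simulates `n_sim` candidate
#' next-day networks from the window's final observed network, and scores
#' each against the observed target-day network by graph correlation and
#' Spearman centrality correlations. Non-converged fits are not simulated:
#' the scenario is returned with `skipped = TRUE`, mirroring the practice of
#' comparing only converged models.
#'
#' @param series list of [daily_network()] in day order.
#' @param cov covariates on the series roster.
#' @param spec a [model_spec()].
#' @param scenario one row of [enumerate_windows()] (or a list with
#'   `window_start`, `window_end`, `target_day`).
#' @param n_sim simulated networks per scenario (default 100).
#' @param burn_in MH burn-in sweeps for triangle models.
#' @param seed optional integer seed.
#' @return an `accuracy_summary` with means and SDs over the simulated
#'   networks, the fitted model in `$fit`, and `skipped`/`converged` flags.
#' @export
predict_scenario <- function(series, cov, spec, scenario, n_sim = 100L,
                             burn_in = 20L, seed = NULL) {
  days <- scenario$window_start:scenario$window_end
  stopifnot(scenario$target_day == scenario$window_end + 1L,
            scenario$target_day <= length(series))
  fit <- fit_mple(as_transitions(series[days]), spec, cov)
  if (!fit$converged) {
    out <- summarise_scores(
      data.frame(graph_corr = NA_real_, degree_rho = NA_real_,
                 betweenness_rho = NA_real_, eigenvector_rho = NA_real_)[0, ],
      n_networks = 0L,
      extra = list(fit = fit, converged = FALSE, skipped = TRUE,
                   scenario = scenario))
    return(out)
  }
  y_prev <- series[[scenario$window_end]]
  sims <- simulate_transition(y_prev, fit, cov = cov, n_samples = n_sim,
                              burn_in = burn_in, seed = seed)
  scores <- score_networks(sims, series[[scenario$target_day]])
  summarise_scores(scores, n_networks = n_sim,
                   extra = list(fit = fit, converged = TRUE, skipped = FALSE,
                                scenario = scenario))
}

#' Naive permutation baseline
#'
#' The baseline destroys individual identity while preserving network
#' structure: the animal identifications of the consecutive networks are
#' randomly permuted `n_perm` times and each permuted network is scored
#' against the observed target-day network. With `permute = "target"`
#' (default) the target-day network's own labels are permuted and scored
#' against its unpermuted self; `permute = "previous"` permutes the
#' previous-day network instead. Under either reading the expected graph
#' correlation and the expected Spearman degree correlation are exactly
#' zero (for any fixed network, the permuted dyad and rank vectors are
#' mean-centred draws), so reported baseline means round to 0.00 up to
#' sampling noise.
#'
#' @param y_prev previous-day [daily_network()].
#' @param y_obs observed target-day [daily_network()].
#' @param n_perm number of label permutations (default 100).
#' @param seed optional integer seed.
#' @param permute which network's labels to permute.
#' @return an `accuracy_summary` over the `n_perm` permuted networks.
#' @export
naive_baseline <- function(y_prev, y_obs, n_perm = 100L, seed = NULL,
                           permute = c("target", "previous")) {
  permute <- match.arg(permute)
  stopifnot(identical(y_prev$roster, y_obs$roster))
  base <- if (permute == "target") y_obs else y_prev
  n <- length(y_obs$roster)
  with_seed(seed, {
    sims <- lapply(seq_len(n_perm), function(k) {
      pi <- sample.int(n)
      adj <- base$adjacency[pi, pi]
      dimnames(adj) <- list(y_obs$roster, y_obs$roster)
      daily_network(adj, y_obs$roster, day = y_obs$day, area = y_obs$area)
    })
    scores <- score_networks(sims, y_obs)
    summarise_scores(scores, n_networks = n_perm,
                     extra = list(converged = TRUE, skipped = FALSE))
  })
}
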