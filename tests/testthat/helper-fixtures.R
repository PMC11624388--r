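# fixture builders shared across test files; everything is generated in code

# a small founder-only covariate set with hand-chosen parity / birth data
tiny_cov <- function(n, parity = rep(1L, n), birth_offsets = seq_len(n) * 30,
                     farms = rep("f", n)) {
  roster <- as.character(seq_len(n))
  herd <- data.frame(cow_id = roster, parity = parity,
                     birth_date = as.Date("2020-01-01") + birth_offsets,
                     birth_farm = farms, stringsAsFactors = FALSE)
  ped <- data.frame(animal_id = roster, sire_id = NA_character_,
                    dam_id = NA_character_, stringsAsFactors = FALSE)
  build_dyad_covariates(ped, herd, roster)
}

# five related cows (full sibs, an inbred daughter, two unrelated founders)
# with a kindergarten trio: every M1 covariate takes several values
related_cov <- function() {
  ped <- data.frame(
    animal_id = c("S", "D", "A", "B", "C", "X", "Y"),
    sire_id = c(NA, NA, "S", "S", "S", NA, NA),
    dam_id = c(NA, NA, "D", "D", "A", NA, NA), stringsAsFactors = FALSE)
  herd <- data.frame(
    cow_id = c("A", "B", "C", "X", "Y"),
    birth_date = as.Date("2020-01-01") + c(0, 3, 200, 1, 400),
    birth_farm = c("f1", "f1", "f1", "f1", "f2"),
    parity = c(1, 2, 3, 1, 2))
  build_dyad_covariates(ped, herd, herd$cow_id)
}

rand_net <- function(n, density, seed, roster = as.character(seq_len(n)),
                     area = NA) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- rbinom(choose(n, 2), 1L, density)
  adj <- adj + t(adj)
  daily_network(adj, roster, area = area)
}

net_from_edges <- function(n, edges, roster = as.character(seq_len(n)),
                           area = NA) {
  adj <- matrix(0L, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- 1L
    adj[e[2], e[1]] <- 1L
  }
  daily_network(adj, roster, area = area)
}

# constant-position series for contact tests
const_series <- function(id, x, y, T) position_series(id, rep(x, T), rep(y, T))

# independent whole-network sufficient statistics via igraph (used as the
# enumeration oracle for the MH sampler and change-statistic tests)
oracle_stats <- function(adj, cov) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  e <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  pc <- as.character(cov$parity)
  c(edges = nrow(e),
    parity2 = sum(pc[e[, 1]] == "2") + sum(pc[e[, 2]] == "2"),
    parity3plus = sum(pc[e[, 1]] == "3+") + sum(pc[e[, 2]] == "3+"),
    parity_match = sum(pc[e[, 1]] == pc[e[, 2]]),
    kinship = sum(cov$kinship[e]),
    kindergarten = sum(cov$kindergarten[e]),
    triangles = sum(igraph::count_triangles(g)) / 3)
}

# exact ERGM distribution over the free dyads of one phase, by enumeration
enumerate_phase <- function(prev, free, theta, cov) {
  m <- nrow(free)
  states <- as.matrix(expand.grid(rep(list(0:1), m)))
  lw <- apply(states, 1, function(s) {
    adj <- prev
    adj[free] <- s
    adj[free[, 2:1, drop = FALSE]] <- s
    sum(theta * oracle_stats(adj, cov)[names(theta)])
  })
  p <- exp(lw - max(lw))
  list(states = states, prob = p / sum(p),
       key = apply(states, 1, paste, collapse = ""))
}
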