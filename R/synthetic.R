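#' Generate a synthetic herd with a three-generation pedigree
#'
#' Builds a herd of lactating cows plus their founder ancestors, structured
#' so that every covariate of the exogenous model is exercised: full-sib and
#' paternal half-sib pairs (additive relationship >= 0.25), parent-offspring
#' pairs within the roster, all three parity classes (1, 2, 3+), and
#' calf-group ("kindergarten") mates born within 7 days on the same farm.
#' Founders are listed first, so the pedigree is in parents-first order.
#'
#' Roughly the first third of the roster are daughters of founder pairs
#' (parity 3+); the rest are daughters of those cows by founder sires
#' (parities 1 and 2), creating maternal lines and half-sib clusters.
#' Birth dates are drawn in seasonal batches on two rearing farms so that
#' some, but not all, same-cohort pairs share a kindergarten.
#'
#' @param n_cows roster size (>= 4).
#' @param n_founder_pairs founder sire/dam pairs (>= 2).
#' @param seed integer seed; the generator is deterministic given it.
#' @return list with `herd` (data.frame of roster cows: `cow_id`,
#'   `parity_class`, `parity`, `birth_date`, `birth_farm`, `sire_id`,
#'   `dam_id`) and `pedigree` (data.frame over founders + roster with
#'   `animal_id`, `sire_id`, `dam_id`).
#' @export
generate_herd <- function(n_cows, n_founder_pairs, seed = 1L) {
  if (n_cows < 4L) stop("n_cows must be >= 4")
  if (n_founder_pairs < 2L) stop("n_founder_pairs must be >= 2")
  with_seed(seed, {
    sires <- sprintf("S%02d", seq_len(n_founder_pairs))
    dams <- sprintf("D%02d", seq_len(n_founder_pairs))
    cows <- sprintf("C%03d", seq_len(n_cows))
    n_g2 <- max(2L, ceiling(n_cows / 3))
    sire_id <- character(n_cows); dam_id <- character(n_cows)
    # generation 2: daughters of founder pairs; consecutive cows often share
    # a pair, yielding full sibs
    pair_of <- ((seq_len(n_g2) - 1L) %/% 2L) %% n_founder_pairs + 1L
    sire_id[seq_len(n_g2)] <- sires[pair_of]
    dam_id[seq_len(n_g2)] <- dams[pair_of]
    # generation 3: dam drawn from generation 2, sire a founder; reusing
    # sires creates paternal half-sib clusters
    g3 <- setdiff(seq_len(n_cows), seq_len(n_g2))
    sire_id[g3] <- sires[sample.int(n_founder_pairs, length(g3), replace = TRUE)]
    dam_id[g3] <- cows[sample.int(n_g2, length(g3), replace = TRUE)]
    # parity: older generation 3+, younger split between 1 and 2
    parity <- integer(n_cows)
    parity[seq_len(n_g2)] <- sample(3:6, n_g2, replace = TRUE)
    parity[g3] <- sample(1:2, length(g3), replace = TRUE)
    # birth dates in ~3-week seasonal batches on two rearing farms: cows in
    # the same batch and farm are kindergarten mates
    base <- as.Date("2014-01-01")
    batch <- sample.int(max(2L, n_cows %/% 6L), n_cows, replace = TRUE)
    birth_date <- base + (6 - parity) * 365L + batch * 21L +
      sample.int(5L, n_cows, replace = TRUE)
    birth_farm <- sample(c("farm_A", "farm_B"), n_cows, replace = TRUE,
                         prob = c(0.7, 0.3))
    herd <- data.frame(
      cow_id = cows,
      parity_class = cut(parity, c(0, 1, 2, Inf), labels = c("1", "2", "3+")),
      parity = parity, birth_date = birth_date, birth_farm = birth_farm,
      sire_id = sire_id, dam_id = dam_id, stringsAsFactors = FALSE)
    pedigree <- data.frame(
      animal_id = c(sires, dams, cows),
      sire_id = c(rep(NA_character_, 2L * n_founder_pairs), sire_id),
      dam_id = c(rep(NA_character_, 2L * n_founder_pairs), dam_id),
      stringsAsFactors = FALSE)
    list(herd = herd, pedigree = pedigree)
  })
}

#' Default ground-truth STERGM coefficients for synthetic herds
#'
#' The regime emulated: sparse daily networks (density around 0.10) whose
#' consecutive-day graph correlations stay below 0.20, with positive kin,
#' kindergarten and parity-homophily effects. The lag-1 correlation of a
#' dyad-independent day-to-day process is approximately the persistence
#' probability minus the formation probability, so these intercepts put it
#' near 0.19.
#'
#' @param variant `"M1"` or `"M2"`; M2 adds a small positive triangle
#'   coefficient in both phases.
#' @return list with `formation` and `persistence` named coefficient vectors.
#' @export
default_coefs <- function(variant = c("M1", "M2")) {
  variant <- match.arg(variant)
  f <- c(edges = -2.7, parity2 = 0.10, parity3plus = 0.15,
         parity_match = 0.25, kinship = 1.0, kindergarten = 0.7)
  p <- c(edges = -1.3, parity2 = 0.10, parity3plus = 0.10,
         parity_match = 0.30, kinship = 1.0, kindergarten = 0.8)
  if (variant == "M2") {
    f <- c(f, triangles = 0.15)
    p <- c(p, triangles = 0.15)
  }
  list(formation = f, persistence = p)
}

#' Simulate a daily-network series from known STERGM coefficients
#'
#' Draws day 1 as an Erdos-Renyi graph at `initial_density`, then samples
#' each day-to-day transition from the STERGM with the supplied formation
#' and persistence coefficients, using the same transition sampler the
#' fitted models use for prediction. This is the ground-truth generator for
#' parameter-recovery and pipeline-calibration experiments.
#'
#' @param herd output of [generate_herd()] (or any object whose `herd`
#'   element has `cow_id`); the roster is `herd$herd$cow_id`.
#' @param cov a [build_dyad_covariates()] set on that roster.
#' @param coefs list with `formation`/`persistence` named vectors (see
#'   [default_coefs()]).
#' @param n_days number of daily networks (>= 2).
#' @param spec a [model_spec()]; defaults to M1/M2 according to whether the
#'   coefficients carry a `triangles` entry.
#' @param initial_density density of the day-1 Erdos-Renyi draw.
#' @param burn_in MH burn-in sweeps for triangle models.
#' @param seed integer seed.
#' @param area area tag stored on the networks.
#' @return list of `n_days` [daily_network()] objects.
#' @export
generate_network_series <- function(herd, cov, coefs = default_coefs(),
                                    n_days = 14L, spec = NULL,
                                    initial_density = 0.10, burn_in = 20L,
                                    seed = 1L, area = NA) {
  stopifnot(n_days >= 2L, initial_density > 0, initial_density < 1)
  roster <- as.character(herd$herd$cow_id %||% herd$cow_id)
  if (is.null(spec)) {
    variant <- if ("triangles" %in% names(coefs$formation)) "M2" else "M1"
    spec <- model_spec(variant)
  }
  miss <- setdiff(spec$terms, names(coefs$formation))
  if (length(miss))
    stop("coefficients missing for term(s): ", paste(miss, collapse = ", "))
  n <- length(roster)
  with_seed(seed, {
    adj <- matrix(0L, n, n, dimnames = list(roster, roster))
    adj[upper.tri(adj)] <- rbinom(n_dyads(n), 1L, initial_density)
    adj <- adj + t(adj)
    out <- vector("list", n_days)
    out[[1]] <- daily_network(adj, roster, day = 1L, area = area)
    for (d in 2L:n_days) {
      nxt <- simulate_transition(out[[d - 1L]], coefs, spec = spec, cov = cov,
                                 n_samples = 1L, burn_in = burn_in)[[1]]
      nxt$day <- d
      out[[d]] <- nxt
    }
    out
  })
}

# greedy round scheduling: partition the union of per-area edge sets into
# rounds such that within a round each cow has at most one meeting and each
# area uses at most `caps[area]` meeting cells
schedule_meetings <- function(edges_by_area, caps) {
  todo <- do.call(rbind, lapply(names(edges_by_area), function(a) {
    e <- edges_by_area[[a]]
    if (is.null(e) || nrow(e) == 0L) return(NULL)
    data.frame(i = e[, 1], j = e[, 2], area = a, stringsAsFactors = FALSE)
  }))
  rounds <- list()
  while (!is.null(todo) && nrow(todo) > 0L) {
    used <- integer(0)
    count <- c(resting = 0L, feeding = 0L)
    take <- logical(nrow(todo))
    for (r in seq_len(nrow(todo))) {
      a <- todo$area[r]
      if (count[[a]] >= caps[[a]]) next
      if (todo$i[r] %in% used || todo$j[r] %in% used) next
      take[r] <- TRUE
      used <- c(used, todo$i[r], todo$j[r])
      count[[a]] <- count[[a]] + 1L
    }
    if (!any(take)) stop("meeting scheduler stalled")   # cannot happen: caps >= 1
    rounds[[length(rounds) + 1L]] <- todo[take, ]
    todo <- todo[!take, ]
  }
  rounds
}

# meeting-cell centres inside an area's polygons, on a `spacing`-metre grid
# kept `margin` metres off the polygon boundary
area_cells <- function(barn, area, spacing = 4, margin = 0.7) {
  gx <- seq(margin, barn$bounds[1] - margin, by = spacing)
  gy <- seq(margin, barn$bounds[2] - margin, by = spacing)
  pts <- expand.grid(x = gx, y = gy)
  ok <- assign_functional_area(pts$x, pts$y, barn) == area &
    assign_functional_area(pts$x - margin, pts$y - margin, barn) == area &
    assign_functional_area(pts$x + margin, pts$y + margin, barn) == area
  pts[ok, , drop = FALSE]
}

# delete seconds from a series in runs whose length distribution has mode 1
# (>= 80% single seconds), totalling ~rate of the day; runs are separated by
# at least one observed second so run lengths are preserved
inject_missing <- function(T, rate) {
  target <- round(rate * T)
  if (target == 0L) return(integer(0))
  lens <- sample(c(1L, 2L, 3L, 4L), size = ceiling(1.3 * target),
                 replace = TRUE, prob = c(0.85, 0.11, 0.03, 0.01))
  lens <- lens[cumsum(lens) <= target]
  if (sum(lens) < target) lens <- c(lens, rep(1L, target - sum(lens)))
  # lay the runs out over the day with >= 1 s gaps, random extra slack
  k <- length(lens)
  slack <- T - sum(lens) - (k - 1L)
  if (slack < 0) stop("missing_rate too high to keep runs separated")
  extra <- tabulate(sample.int(k + 1L, slack, replace = TRUE), k + 1L)
  starts <- cumsum(c(1L + extra[1], lens[-k] + 1L + extra[-c(1, k + 1L)]))
  unlist(lapply(seq_len(k), function(r) seq.int(starts[r],
                                                length.out = lens[r])))
}

#' Generate one day of per-second trajectories consistent with target networks
#'
#' Produces bout-based synthetic tracks: the day is cut into rounds, and in
#' each round every cow dwells (with ±0.2 m jitter) at an assigned grid
#' cell. A dyad with an edge in a target network shares a cell (mates offset
#' ±0.4 m) inside that network's functional area for at least one full
#' round -- guaranteeing >= `min round length` seconds within 2.5 m -- while
#' all other cell centres are 4 m apart, so non-edge dyads never come within
#' 2.5 m. Missingness is then injected per cow as deleted runs of seconds
#' with modal length 1 s.
#'
#' @param herd output of [generate_herd()] (roster source).
#' @param barn a [barn_geometry()].
#' @param target_networks a single [daily_network()] with an `area` tag, or
#'   a list of one per area (e.g. `list(resting = ..., feeding = ...)`).
#' @param missing_rate fraction of seconds to delete per cow, in `[0, 1)`.
#' @param seed integer seed.
#' @param day_seconds day grid length (default 86400).
#' @param min_round_seconds minimum dwell per round; must exceed the 600 s
#'   contact filter (default 900).
#' @return named list of [position_series()], one per roster cow.
#' @export
generate_position_day <- function(herd, barn, target_networks,
                                  missing_rate = 0, seed = 1L,
                                  day_seconds = 86400L,
                                  min_round_seconds = 900L) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (inherits(target_networks, "daily_network"))
    target_networks <- setNames(list(target_networks),
                                target_networks$area %||% "resting")
  roster <- as.character(herd$herd$cow_id %||% herd$cow_id)
  n <- length(roster)
  for (net in target_networks)
    if (!all(net$roster %in% roster))
      stop("target network roster must be a subset of the herd")
  cells <- list(resting = area_cells(barn, "resting"),
                feeding = area_cells(barn, "feeding"))
  caps <- vapply(cells, nrow, integer(1))
  if (any(caps < 1L)) stop("barn has no usable meeting cells in some area")
  edges_by_area <- lapply(target_networks, function(net) {
    e <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
    cbind(match(net$roster[e[, 1]], roster), match(net$roster[e[, 2]], roster))
  })
  names(edges_by_area) <- vapply(target_networks, function(net)
    as.character(net$area %||% "resting"), character(1))
  with_seed(seed, {
    rounds <- schedule_meetings(edges_by_area, caps)
    n_rounds <- max(1L, length(rounds))
    round_len <- day_seconds %/% n_rounds
    if (round_len < min_round_seconds)
      stop("too many meetings for the day: rounds of ", round_len,
           " s are shorter than min_round_seconds")
    X <- matrix(NA_real_, day_seconds, n)
    Y <- matrix(NA_real_, day_seconds, n)
    all_cells <- rbind(cells$resting, cells$feeding)
    for (r in seq_len(n_rounds)) {
      t0 <- (r - 1L) * round_len + 1L
      t1 <- if (r == n_rounds) day_seconds else r * round_len
      meet <- if (length(rounds) >= r) rounds[[r]] else NULL
      # meeting cells per area, disjoint cows
      cell_x <- numeric(n); cell_y <- numeric(n); taken <- NULL
      busy <- integer(0)
      if (!is.null(meet) && nrow(meet)) {
        for (a in unique(meet$area)) {
          sel <- meet[meet$area == a, , drop = FALSE]
          pick <- cells[[a]][sample.int(nrow(cells[[a]]), nrow(sel)), ,
                             drop = FALSE]
          cell_x[sel$i] <- pick$x - 0.4; cell_y[sel$i] <- pick$y
          cell_x[sel$j] <- pick$x + 0.4; cell_y[sel$j] <- pick$y
          taken <- rbind(taken, pick)
          busy <- c(busy, sel$i, sel$j)
        }
      }
      solo <- setdiff(seq_len(n), busy)
      avail <- all_cells
      if (!is.null(taken))
        avail <- avail[!(paste(avail$x, avail$y) %in%
                           paste(taken$x, taken$y)), , drop = FALSE]
      if (nrow(avail) < length(solo))
        stop("not enough grid cells for ", n, " cows in this barn")
      pick <- avail[sample.int(nrow(avail), length(solo)), , drop = FALSE]
      cell_x[solo] <- pick$x; cell_y[solo] <- pick$y
      len <- t1 - t0 + 1L
      jit <- function() runif(len * n, -0.2, 0.2)
      X[t0:t1, ] <- rep(cell_x, each = len) + jit()
      Y[t0:t1, ] <- rep(cell_y, each = len) + jit()
    }
    series <- lapply(seq_len(n), function(k) {
      xs <- X[, k]; ys <- Y[, k]
      if (missing_rate > 0) {
        drop_idx <- inject_missing(day_seconds, missing_rate)
        xs[drop_idx] <- NA_real_; ys[drop_idx] <- NA_real_
      }
      position_series(roster[k], xs, ys, day = 1L,
                      day_seconds = day_seconds)
    })
    names(series) <- roster
    series
  })
}
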