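#' Daily contact network
#'
#' An undirected binary network over a fixed roster of cows for one day and
#' one functional area.
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param roster ordered cow ids (defaults to the matrix dimnames).
#' @param day day label.
#' @param area `"resting"` or `"feeding"` (or `NA` for generic networks).
#' @return object of class `daily_network`.
#' @export
daily_network <- function(adjacency, roster = rownames(adjacency),
                          day = NA, area = NA) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (is.null(roster)) roster <- as.character(seq_len(n))
  roster <- unname(as.character(roster))
  stopifnot(ncol(adjacency) == n, length(roster) == n,
            all(adjacency %in% c(0, 1)))
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  diag(adjacency) <- 0
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(roster, roster)
  structure(list(adjacency = adjacency, roster = as.character(roster),
                 day = day, area = area),
            class = "daily_network")
}

#' @export
print.daily_network <- function(x, ...) {
  n <- length(x$roster)
  e <- sum(x$adjacency) / 2
  cat(sprintf("Daily network: %d cows, %d edges (density %.3f)%s%s\n",
              n, e, e / choose(n, 2),
              if (!is.na(x$day)) paste0(", day ", x$day) else "",
              if (!is.na(x$area)) paste0(", ", x$area, " area") else ""))
  invisible(x)
}

#' Plot a daily network as a sociogram
#'
#' Minimal igraph rendering: nodes are cows, edges are proximity contacts.
#'
#' @param x a [daily_network()].
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.daily_network <- function(x, ...) {
  g <- as_igraph(x)
  igraph::plot.igraph(g, vertex.size = 5, vertex.label.cex = 0.5, ...)
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

# number of dyads (unordered pairs) on a roster of size n
n_dyads <- function(n) n * (n - 1L) / 2L

upper_tri_vec <- function(adj) adj[upper.tri(adj)]

#' Tally per-dyad contact seconds by functional area
#'
#' For every second of the day and every dyad, a contact second is counted
#' when the two cows are within `radius` metres of each other *and* both are
#' assigned to the same functional area; the second is credited to that
#' area. Seconds where either cow is in the excluded area never count, so a
#' dyad's resting + feeding tallies sum to at most the day length.
#'
#' @param series named list of gap-free [position_series()], one per cow.
#' @param barn a [barn_geometry()].
#' @param radius contact radius in metres. The default 2.5 m is the maximum
#'   separation of two cows lying in adjacent 1.25 m cubicles.
#' @return list with elements `resting` and `feeding`, each an object of
#'   class `contact_tally`: a symmetric integer matrix of contact seconds
#'   over the roster, plus `day`/`area` attributes.
#' @export
tally_contact_seconds <- function(series, barn, radius = 2.5) {
  stopifnot(length(series) >= 2L, inherits(barn, "barn_geometry"))
  roster <- unname(vapply(series, `[[`, "", "cow_id"))
  if (anyDuplicated(roster)) stop("duplicate cow ids in series roster")
  lens <- vapply(series, function(s) length(s$x), integer(1))
  if (length(unique(lens)) != 1L)
    stop("all series must cover the same day grid")
  if (any(vapply(series, function(s) anyNA(s$x), logical(1))))
    stop("series must be gap-free; run interpolate_gaps() first")
  T <- lens[1]; n <- length(series)
  X <- matrix(unlist(lapply(series, `[[`, "x")), nrow = T)
  Y <- matrix(unlist(lapply(series, `[[`, "y")), nrow = T)
  A <- matrix(0L, nrow = T, ncol = n)
  for (j in seq_len(n)) A[, j] <- area_codes(X[, j], Y[, j], barn)
  res <- tally_contacts_cpp(X, Y, A, radius)
  day <- series[[1]]$day
  mk <- function(m, area) {
    dimnames(m) <- list(roster, roster)
    structure(list(seconds = m, roster = roster, day = day, area = area),
              class = "contact_tally")
  }
  list(resting = mk(res[[1]], "resting"), feeding = mk(res[[2]], "feeding"))
}

#' @export
print.contact_tally <- function(x, ...) {
  cat(sprintf("Contact tally (%s area): %d cows, %d dyads with > 0 s\n",
              x$area, length(x$roster), sum(x$seconds[upper.tri(x$seconds)] > 0)))
  invisible(x)
}

#' Threshold a contact tally into a daily binary network
#'
#' Dyads with at least `min_seconds` of same-area contact get an edge; daily
#' contacts of less than `min_seconds` are filtered out as stochastic
#' encounters. The boundary is retained: exactly `min_seconds` is an edge.
#'
#' @param tally a `contact_tally` from [tally_contact_seconds()].
#' @param min_seconds duration threshold in seconds (default 600 = 10 min).
#' @return a [daily_network()].
#' @export
build_daily_network <- function(tally, min_seconds = 600L) {
  stopifnot(inherits(tally, "contact_tally"))
  adj <- (tally$seconds >= min_seconds) * 1L
  diag(adj) <- 0L
  daily_network(adj, tally$roster, day = tally$day, area = tally$area)
}

#' Build daily networks for a sequence of position files
#'
#' Runs the full per-day pipeline -- read, interpolate, area assignment,
#' contact tally, duration filter -- over consecutive daily position files
#' and returns one network per day per functional area on the identical
#' roster. Cows excluded for a day (too few fixes) become isolated nodes for
#' that day, with a warning.
#'
#' @param paths character vector of daily position files, in day order.
#' @param barn a [barn_geometry()].
#' @param roster ordered cow ids fixed in advance (cows present all days).
#' @param radius,min_seconds contact thresholds (defaults 2.5 m, 600 s).
#' @param day_seconds per-day grid length.
#' @return list with elements `resting` and `feeding`, each a list of
#'   [daily_network()] in day order.
#' @export
network_series <- function(paths, barn, roster, radius = 2.5,
                           min_seconds = 600L, day_seconds = 86400L) {
  out <- list(resting = vector("list", length(paths)),
              feeding = vector("list", length(paths)))
  for (d in seq_along(paths)) {
    series <- read_positions(paths[d], day = d, day_seconds = day_seconds)
    series <- series[names(series) %in% roster]
    if (length(series) == 0L) stop("day ", d, ": no usable cows")
    series <- interpolate_gaps(series)
    missing_ids <- setdiff(roster, names(series))
    if (length(missing_ids))
      warning("day ", d, ": cow(s) ", paste(missing_ids, collapse = ", "),
              " have no usable track; kept as isolated nodes")
    tallies <- tally_contact_seconds(series, barn, radius = radius)
    for (area in c("resting", "feeding")) {
      full <- matrix(0L, length(roster), length(roster),
                     dimnames = list(roster, roster))
      sec <- tallies[[area]]$seconds
      ids <- rownames(sec)
      full[ids, ids] <- sec
      tal <- structure(list(seconds = full, roster = roster, day = d,
                            area = area), class = "contact_tally")
      out[[area]][[d]] <- build_daily_network(tal, min_seconds = min_seconds)
    }
  }
  out
}

#' Write a daily network as an edge list
#'
#' Writes `cow_a,cow_b,weight_seconds` rows (weight 1 if no tally given),
#' one per edge, plus an ordered roster file alongside.
#'
#' @param net a [daily_network()].
#' @param path output CSV path; the roster goes to `<path>.roster`.
#' @param tally optional matching `contact_tally` supplying edge weights.
#' @export
write_network <- function(net, path, tally = NULL) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  w <- if (is.null(tally)) rep(1L, nrow(idx)) else tally$seconds[idx]
  df <- data.frame(cow_a = net$roster[idx[, 1]], cow_b = net$roster[idx[, 2]],
                   weight_seconds = w)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  writeLines(net$roster, paste0(path, ".roster"))
}
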