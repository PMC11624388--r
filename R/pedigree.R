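#' Read a pedigree/herd file
#'
#' Delimited text with columns
#' `animal_id,sire_id,dam_id,birth_date,birth_farm,parity`; empty `sire_id`
#' or `dam_id` fields mean unknown parents. Only `animal_id`, `sire_id` and
#' `dam_id` are required; the remaining columns are needed when the file
#' also serves as the herd profile for covariate construction.
#'
#' @param path path to the CSV file.
#' @return data.frame with character ids (`NA` for unknown parents), `Date`
#'   birth dates and integer parity where present.
#' @export
read_pedigree <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(animal_id = "character"))
  stopifnot(all(c("animal_id", "sire_id", "dam_id") %in% names(df)))
  for (col in c("animal_id", "sire_id", "dam_id")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][df[[col]] %in% c("", "NA")] <- NA_character_
  }
  if ("birth_date" %in% names(df)) df$birth_date <- as.Date(df$birth_date)
  if ("parity" %in% names(df)) df$parity <- as.integer(df$parity)
  df
}

#' Write a herd/pedigree data.frame to CSV
#'
#' @param herd data.frame as produced by [generate_herd()].
#' @param path output path.
#' @export
write_pedigree <- function(herd, path) {
  write.csv(herd, path, row.names = FALSE, quote = FALSE, na = "")
}

# Kahn topological order over the pedigree DAG; errors on cycles.
pedigree_order <- function(id, sire, dam) {
  n <- length(id)
  idx <- function(p) match(p, id)          # NA for unknown/unlisted parents
  si <- idx(sire); di <- idx(dam)
  indeg <- integer(n)
  children <- vector("list", n)
  for (k in seq_len(n)) {
    for (p in c(si[k], di[k])) if (!is.na(p)) {
      indeg[k] <- indeg[k] + 1L
      children[[p]] <- c(children[[p]], k)
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (c in children[[v]]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(order) < n) {
    left <- setdiff(seq_len(n), order)
    stop("pedigree contains a cycle involving: ",
         paste(id[left], collapse = ", "))
  }
  order
}

#' Additive relationship matrix by the tabular method
#'
#' Computes the pedigree-based expected additive genetic relationship matrix
#' A by the tabular recursion over animals in topological (parents-first)
#' order: for animal i with parents s and d,
#' `A[i,i] = 1 + 0.5 * A[s,d]` and `A[i,j] = 0.5 * (A[j,s] + A[j,d])` for
#' earlier animals j, with unknown parents contributing 0. Diagonals exceed
#' 1 by the animal's inbreeding coefficient; parent-offspring and full-sib
#' pairs of non-inbred animals get 0.5.
#'
#' @param ped data.frame with columns `animal_id`, `sire_id`, `dam_id`
#'   (character; `NA` = unknown). Parents referenced but not listed are
#'   treated as unknown founders, with a warning.
#' @return symmetric numeric matrix with animal ids as dimnames.
#' @export
additive_relationship_matrix <- function(ped) {
  id <- as.character(ped$animal_id)
  if (anyDuplicated(id)) stop("duplicate animal ids in pedigree")
  sire <- as.character(ped$sire_id); dam <- as.character(ped$dam_id)
  unl <- setdiff(c(sire, dam), c(id, NA))
  if (length(unl)) {
    warning("parent(s) not listed in pedigree treated as founders: ",
            paste(unl, collapse = ", "))
    sire[sire %in% unl] <- NA; dam[dam %in% unl] <- NA
  }
  ord <- pedigree_order(id, sire, dam)
  n <- length(id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  si <- match(sire, id); di <- match(dam, id)
  pos <- integer(n)   # processing rank of each animal
  pos[ord] <- seq_len(n)
  for (k in ord) {
    s <- si[k]; d <- di[k]
    A[k, k] <- 1 + 0.5 * (if (!is.na(s) && !is.na(d)) A[s, d] else 0)
    earlier <- ord[seq_len(pos[k] - 1L)]
    if (length(earlier)) {
      rel <- 0.5 * ((if (!is.na(s)) A[earlier, s] else 0) +
                      (if (!is.na(d)) A[earlier, d] else 0))
      A[earlier, k] <- rel
      A[k, earlier] <- rel
    }
  }
  A
}

#' Kindergarten (shared early-rearing) indicator matrix
#'
#' Two cows share a "kindergarten" when they were born at most `window_days`
#' apart on the same farm -- a proxy for being reared together as calves,
#' which predicts adult affiliative contact. The day window is inclusive:
#' exactly `window_days` apart still counts.
#'
#' @param herd data.frame with columns `cow_id` (or `animal_id`),
#'   `birth_date` (`Date`) and `birth_farm`.
#' @param window_days inclusive birth-date window in days (default 7).
#' @return symmetric 0/1 integer matrix with zero diagonal.
#' @export
kindergarten_matrix <- function(herd, window_days = 7) {
  ids <- as.character(herd$cow_id %||% herd$animal_id)
  bd <- herd$birth_date; bf <- herd$birth_farm
  bad <- ids[is.na(bd) | is.na(bf)]
  if (length(bad))
    stop("missing birth date/farm for cow(s): ", paste(bad, collapse = ", "))
  dd <- abs(outer(as.numeric(bd), as.numeric(bd), `-`)) <= window_days
  ff <- outer(as.character(bf), as.character(bf), `==`)
  K <- (dd & ff) * 1L
  diag(K) <- 0L
  dimnames(K) <- list(ids, ids)
  K
}

#' Assemble the dyadic covariates of the exogenous model
#'
#' Restricts the additive relationship matrix to the roster, builds the
#' kindergarten matrix, and maps parity to the three classes `1`, `2`, `3+`.
#'
#' @param ped pedigree data.frame (may include non-roster ancestors).
#' @param herd herd data.frame with `cow_id` (or `animal_id`), `birth_date`,
#'   `birth_farm`, `parity` for at least the roster cows.
#' @param roster ordered cow ids to index all matrices by.
#' @param window_days kindergarten window (default 7 d, inclusive).
#' @return object of class `dyad_covariates`: list with `roster`, `kinship`,
#'   `kindergarten`, `parity` (factor with levels `1`, `2`, `3+`).
#' @export
build_dyad_covariates <- function(ped, herd, roster, window_days = 7) {
  roster <- as.character(roster)
  if (length(roster) == 0L) stop("empty roster")
  herd_ids <- as.character(herd$cow_id %||% herd$animal_id)
  missing_ped <- setdiff(roster, as.character(ped$animal_id))
  if (length(missing_ped))
    stop("roster cow(s) absent from pedigree: ",
         paste(missing_ped, collapse = ", "))
  missing_herd <- setdiff(roster, herd_ids)
  if (length(missing_herd))
    stop("roster cow(s) absent from herd records: ",
         paste(missing_herd, collapse = ", "))
  A <- additive_relationship_matrix(ped)[roster, roster]
  hh <- herd[match(roster, herd_ids), ]
  K <- kindergarten_matrix(hh, window_days = window_days)
  dimnames(K) <- list(roster, roster)
  parity <- cut(as.integer(hh$parity), breaks = c(0, 1, 2, Inf),
                labels = c("1", "2", "3+"))
  names(parity) <- roster
  structure(list(roster = roster, kinship = A, kindergarten = K,
                 parity = parity),
            class = "dyad_covariates")
}

#' @export
print.dyad_covariates <- function(x, ...) {
  cat(sprintf("Dyad covariates: %d cows\n", length(x$roster)))
  cat(sprintf("  kinship range [%.3f, %.3f]; kindergarten dyads: %d\n",
              min(x$kinship[upper.tri(x$kinship)]),
              max(x$kinship[upper.tri(x$kinship)]),
              sum(x$kindergarten[upper.tri(x$kindergarten)])))
  cat("  parity classes: ", paste(sprintf("%s=%d", levels(x$parity),
                                          table(x$parity)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
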