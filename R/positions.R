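#' Per-second position series
#'
#' A `position_series` holds one cow-day of indoor-positioning fixes on the
#' regular 1-s grid: coordinate vectors `x` and `y` of length `day_seconds`
#' (default 86400), with `NA` marking seconds without a fix. Second `t` of
#' the day (0-based) is stored at index `t + 1`.
#'
#' @param cow_id cow identifier.
#' @param x,y numeric vectors of length `day_seconds`; `NA` = missing fix.
#' @param day day label (anything coercible to character).
#' @param day_seconds number of seconds in the day grid.
#' @return object of class `position_series`.
#' @export
position_series <- function(cow_id, x, y, day = NA, day_seconds = length(x)) {
  stopifnot(length(x) == day_seconds, length(y) == day_seconds)
  bad <- which(is.na(x) != is.na(y))
  if (length(bad)) { x[bad] <- NA_real_; y[bad] <- NA_real_ }
  structure(list(cow_id = as.character(cow_id), day = day,
                 x = as.numeric(x), y = as.numeric(y)),
            class = "position_series")
}

#' @export
print.position_series <- function(x, ...) {
  n <- length(x$x); miss <- sum(is.na(x$x))
  cat(sprintf("Position series: cow %s, day %s, %d s (%d missing, %.1f%%)\n",
              x$cow_id, as.character(x$day), n, miss, 100 * miss / n))
  invisible(x)
}

n_gaps <- function(series) sum(is.na(series$x))

#' Read per-second positions from a delimited file
#'
#' Expects columns `cow_id, timestamp, x, y` (header required). Timestamps
#' are either epoch/day-offset integer seconds or ISO-8601 date-times
#' (auto-detected); they are mapped to 0-based seconds within `day`.
#' Seconds with no record carry `NA`; duplicate (cow, second) records keep
#' the last occurrence, with a message.
#'
#' @param path path to a CSV file.
#' @param day day label; for ISO-8601 timestamps, the civil date (UTC) whose
#'   rows are kept.
#' @param day_seconds length of the per-day second grid.
#' @return named list of [position_series()], one per cow; empty (with a
#'   warning) if the file has no rows.
#' @export
read_positions <- function(path, day = NA, day_seconds = 86400L) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) {
    warning("no position rows in ", path)
    return(structure(list(), names = character()))
  }
  need <- c("cow_id", "timestamp", "x", "y")
  if (!all(need %in% names(df)))
    stop("position file must have columns ", paste(need, collapse = ", "))
  ts <- df$timestamp
  if (is.character(ts)) {
    tt <- as.POSIXct(ts, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
    bad <- which(is.na(tt))
    if (length(bad))
      stop("malformed timestamp at line ", bad[1] + 1L, " of ", path)
    if (!is.na(day)) {
      keep <- as.Date(tt) == as.Date(day)
      df <- df[keep, ]; tt <- tt[keep]
    }
    sec <- as.integer(tt - trunc(tt[1], "days"))
    day <- if (is.na(day)) as.character(as.Date(tt[1])) else day
  } else {
    sec <- as.integer(ts)
    if (max(sec, na.rm = TRUE) >= day_seconds) sec <- sec - min(sec, na.rm = TRUE)
  }
  bad <- which(!is.finite(sec) | sec < 0L | sec >= day_seconds |
                 !is.finite(df$x) | !is.finite(df$y))
  if (length(bad))
    stop("malformed position row at line ", bad[1] + 1L, " of ", path)
  out <- list()
  for (id in unique(as.character(df$cow_id))) {
    rows <- which(df$cow_id == id)
    s <- sec[rows]
    if (anyDuplicated(s)) {
      message(sum(duplicated(s)), " duplicate second(s) for cow ", id,
              "; keeping the last record")
    }
    xs <- rep(NA_real_, day_seconds); ys <- rep(NA_real_, day_seconds)
    xs[s + 1L] <- df$x[rows]    # later rows overwrite earlier duplicates
    ys[s + 1L] <- df$y[rows]
    out[[id]] <- position_series(id, xs, ys, day = day,
                                 day_seconds = day_seconds)
  }
  out
}

#' Write a collection of position series to CSV
#'
#' Inverse of [read_positions()]: one row per observed fix, columns
#' `cow_id, timestamp, x, y` with timestamp as 0-based integer seconds.
#' Missing seconds are simply absent from the file.
#'
#' @param series named list of [position_series()].
#' @param path output path.
#' @export
write_positions <- function(series, path) {
  rows <- lapply(series, function(s) {
    obs <- which(!is.na(s$x))
    data.frame(cow_id = s$cow_id, timestamp = obs - 1L,
               x = s$x[obs], y = s$y[obs])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
}

#' Fill positioning gaps by modified Akima interpolation
#'
#' Interior gaps are filled by applying [makima()] independently to x(t) and
#' y(t) over the observed seconds; observed fixes are never altered. Leading
#' and trailing gaps take the nearest observed value (constant extension)
#' rather than a cubic extrapolation, which could leave the barn. After
#' filling, the series has no missing seconds.
#'
#' @param series a [position_series()] (or a list of them, filled
#'   element-wise; series with fewer than `min_obs` fixes are dropped with a
#'   warning, mirroring the exclusion of cow-days that cannot be
#'   interpolated).
#' @param min_obs minimum observed fixes required (default 2).
#' @return the gap-free series (or list).
#' @export
interpolate_gaps <- function(series, min_obs = 2L) {
  if (!inherits(series, "position_series")) {
    ok <- vapply(series, function(s) sum(!is.na(s$x)) >= min_obs, logical(1))
    if (any(!ok))
      warning("excluding ", sum(!ok), " cow-day(s) with < ", min_obs,
              " observed fixes: ",
              paste(vapply(series[!ok], `[[`, "", "cow_id"), collapse = ", "))
    return(lapply(series[ok], interpolate_gaps, min_obs = min_obs))
  }
  obs <- which(!is.na(series$x))
  if (length(obs) < min_obs)
    stop("cannot interpolate: only ", length(obs), " observed fix(es) for cow ",
         series$cow_id)
  gap <- which(is.na(series$x))
  if (length(gap) == 0L) return(series)
  series$x[gap] <- makima(obs, series$x[obs], gap)
  series$y[gap] <- makima(obs, series$y[obs], gap)
  series
}
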