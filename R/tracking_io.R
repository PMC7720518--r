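#' Default Movebank-dialect column mapping
#'
#' Maps the standard Movebank export column names onto the internal fix
#' fields. Pass a modified copy to [read_relocations()] for other dialects.
#'
#' @return Named character vector with elements `individual_id`,
#'   `timestamp`, `lon`, `lat` giving the source column names.
#' @export
movebank_columns <- function() {
  c(individual_id = "individual-local-identifier",
    timestamp     = "timestamp",
    lon           = "location-long",
    lat           = "location-lat")
}

.parse_timestamps <- function(ts, tz) {
  formats <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
               "%Y-%m-%d %H:%M", "%Y-%m-%d")
  cand <- lapply(formats, function(f) as.POSIXct(strptime(ts, f, tz = tz)))
  n_ok <- vapply(cand, function(z) sum(!is.na(z)), 0L)
  out <- cand[[which.max(n_ok)]]
  if (any(is.na(out))) {
    bad <- which(is.na(out))[1]
    stop(sprintf("unparseable timestamp at row %d: '%s'", bad, ts[bad]))
  }
  out
}

#' Read GPS relocations
#'
#' Reads a relocation table (Movebank-dialect CSV by default, or an
#' equivalent data.frame), parses timestamps, drops rows with missing
#' coordinates (with a warning giving the count), collapses exact
#' duplicates of (individual, timestamp), and returns fixes sorted by
#' individual and time.
#'
#' @param x Path to a CSV file, or a data.frame already in memory.
#' @param col_map Named character vector mapping internal fields to source
#'   columns; see [movebank_columns()].
#' @param tz Time zone of the input timestamps (stored as UTC-compatible
#'   POSIXct).
#' @return A data.frame with columns `individual_id`, `timestamp`, `lon`,
#'   `lat`, sorted by (individual, timestamp). The number of rows dropped
#'   for missing coordinates is stored in attribute `n_dropped`.
#' @export
read_relocations <- function(x, col_map = movebank_columns(), tz = "UTC") {
  raw <- if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x)
    utils::read.csv(x, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x, check.names = FALSE)
  }
  missing_cols <- setdiff(unname(col_map), names(raw))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  fixes <- data.frame(
    individual_id = as.character(raw[[col_map[["individual_id"]]]]),
    timestamp = .parse_timestamps(as.character(raw[[col_map[["timestamp"]]]]), tz),
    lon = suppressWarnings(as.numeric(raw[[col_map[["lon"]]]])),
    lat = suppressWarnings(as.numeric(raw[[col_map[["lat"]]]])),
    stringsAsFactors = FALSE
  )
  bad_coord <- !is.finite(fixes$lon) | !is.finite(fixes$lat)
  n_dropped <- sum(bad_coord)
  if (n_dropped > 0) {
    warning(sprintf("dropped %d row(s) with missing coordinates", n_dropped))
    fixes <- fixes[!bad_coord, , drop = FALSE]
  }
  if (any(fixes$lon < -180 | fixes$lon > 180 | fixes$lat < -90 | fixes$lat > 90))
    stop("coordinates outside valid lon/lat ranges")
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), , drop = FALSE]
  dup <- duplicated(fixes[, c("individual_id", "timestamp")])
  fixes <- fixes[!dup, , drop = FALSE]
  rownames(fixes) <- NULL
  attr(fixes, "n_dropped") <- n_dropped
  fixes
}

#' Read season windows
#'
#' Reads a season-window table (`individual_id,season_label,start,end`,
#' ISO-8601 timestamps) defining, per individual, the date range of each
#' nonbreeding season ("bird-year").
#'
#' @param x CSV path or data.frame.
#' @param tz Time zone of the window timestamps.
#' @return Data.frame with `individual_id`, `season_label`, `start`, `end`.
#' @export
read_season_windows <- function(x, tz = "UTC") {
  raw <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else as.data.frame(x)
  need <- c("individual_id", "season_label", "start", "end")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing season-window columns: ", paste(miss, collapse = ", "))
  out <- data.frame(
    individual_id = as.character(raw$individual_id),
    season_label = as.character(raw$season_label),
    start = .parse_timestamps(as.character(raw$start), tz),
    end = .parse_timestamps(as.character(raw$end), tz),
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) stop("season window with start >= end")
  # windows of one individual must not overlap
  for (id in unique(out$individual_id)) {
    w <- out[out$individual_id == id, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    if (nrow(w) > 1 && any(w$start[-1] <= w$end[-nrow(w)]))
      stop("overlapping season windows for individual ", id)
  }
  out
}

#' Subset fixes to nonbreeding-season windows and split into tracks
#'
#' Keeps only fixes falling inside a season window (closed interval
#' `[start, end]`) and splits them into one track per
#' (individual, season) -- the "bird-year". Windows that contain no fixes
#' are omitted with a message.
#'
#' @param fixes Fix table from [read_relocations()].
#' @param windows Window table from [read_season_windows()].
#' @return Named list of track data.frames, each with a `track_id` column
#'   (`individual_id` and `season_label` joined by `_`).
#' @export
subset_seasons <- function(fixes, windows) {
  known <- unique(fixes$individual_id)
  unknown <- setdiff(unique(windows$individual_id), known)
  if (length(unknown))
    warning("season windows reference unknown individuals: ",
            paste(unknown, collapse = ", "))
  tracks <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    sel <- fixes$individual_id == w$individual_id &
      fixes$timestamp >= w$start & fixes$timestamp <= w$end
    if (!any(sel)) {
      message(sprintf("window %s/%s contains no fixes; omitted",
                      w$individual_id, w$season_label))
      next
    }
    tr <- fixes[sel, , drop = FALSE]
    tr$track_id <- paste(w$individual_id, w$season_label, sep = "_")
    rownames(tr) <- NULL
    tracks[[tr$track_id[1]]] <- tr
  }
  tracks
}

#' Normalize the fix rate of a track
#'
#' Greedy anchor-walk resampling to a target fix interval: the first fix is
#' kept; from the last kept fix at time t, the earliest subsequent fix with
#' timestamp >= t + interval - tolerance is kept next; closer fixes are
#' skipped. A gap larger than interval + tolerance starts a new burst
#' (recorded in `burst_id`) so later step extraction does not bridge it.
#' The operation is idempotent.
#'
#' @param track A time-sorted track data.frame.
#' @param interval Target fix interval in seconds (default 2 h).
#' @param tolerance Tolerance in seconds (default 20 min).
#' @return The resampled track with a `burst_id` column.
#' @export
normalize_fix_rate <- function(track, interval = 7200, tolerance = 1200) {
  if (nrow(track) == 0) {
    track$burst_id <- integer(0)
    return(track)
  }
  t <- as.numeric(track$timestamp)
  if (is.unsorted(t)) stop("track timestamps must be sorted")
  keep <- integer(nrow(track))
  burst <- integer(nrow(track))
  k <- 1L
  keep[1] <- 1L
  burst[1] <- 1L
  cur <- 1L
  cur_burst <- 1L
  repeat {
    nxt <- which(t > t[cur] & t >= t[cur] + interval - tolerance)
    nxt <- nxt[nxt > cur]
    if (!length(nxt)) break
    nxt <- nxt[1]
    k <- k + 1L
    if (t[nxt] - t[cur] > interval + tolerance) cur_burst <- cur_burst + 1L
    keep[k] <- nxt
    burst[k] <- cur_burst
    cur <- nxt
  }
  out <- track[keep[seq_len(k)], , drop = FALSE]
  out$burst_id <- burst[seq_len(k)]
  rownames(out) <- NULL
  out
}

#' Filter apparent-speed outliers
#'
#' Iteratively removes the later fix of any consecutive pair whose
#' straight-line speed exceeds `vmax`, recomputing pairs after each
#' removal, until no violation remains. Requires projected coordinates
#' (`x`, `y` in meters).
#'
#' @param track Track data.frame with `x`, `y` columns.
#' @param vmax Maximum plausible speed in m/s (default 12 m/s = 43 km/h).
#' @return The filtered track.
#' @export
filter_speed <- function(track, vmax = 12) {
  if (is.null(track$x) || is.null(track$y))
    stop("filter_speed() requires projected coordinates; run project_fixes() first")
  if (nrow(track) < 2) return(track)
  repeat {
    t <- as.numeric(track$timestamp)
    dt <- diff(t)
    dd <- sqrt(diff(track$x)^2 + diff(track$y)^2)
    v <- dd / dt
    bad <- which(v > vmax)
    if (!length(bad)) break
    track <- track[-(bad[1] + 1L), , drop = FALSE]
    if (nrow(track) < 2) break
  }
  rownames(track) <- NULL
  track
}

#' Preprocess raw fixes into clean bird-year tracks
#'
#' Convenience wrapper: project coordinates, subset to season windows,
#' split into bird-year tracks, normalize the fix rate and filter apparent
#' speed outliers (in either order).
#'
#' @param fixes Fix table from [read_relocations()].
#' @param windows Season windows from [read_season_windows()].
#' @param proj Analysis projection ([eqc_projection()]).
#' @param interval,tolerance Fix interval and tolerance in seconds.
#' @param vmax Speed threshold in m/s.
#' @param normalize_first If `TRUE` (default) resample the fix rate before
#'   speed filtering; set `FALSE` to filter first.
#' @return Named list of cleaned track data.frames with `x`, `y`,
#'   `burst_id` columns.
#' @export
preprocess_tracks <- function(fixes, windows, proj = eqc_projection(),
                              interval = 7200, tolerance = 1200, vmax = 12,
                              normalize_first = TRUE) {
  fixes <- project_fixes(fixes, proj)
  tracks <- subset_seasons(fixes, windows)
  out <- lapply(tracks, function(tr) {
    if (normalize_first) {
      tr <- normalize_fix_rate(tr, interval, tolerance)
      tr <- filter_speed(tr, vmax)
    } else {
      tr$burst_id <- 1L   # bursts are defined by normalization
      tr <- filter_speed(tr, vmax)
      tr$burst_id <- NULL
      tr <- normalize_fix_rate(tr, interval, tolerance)
    }
    tr
  })
  out[vapply(out, nrow, 0L) > 0]
}
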