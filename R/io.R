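# File dialects.
#
# Activity CSV (one session, one column-group per occupied tube):
#   #photobeam-activity v1
#   #t0=<ISO8601, whole seconds, UTC>
#   #zt0=<float hours>
#   #geometry=<n_tubes>x<n_beams>
#   #flies=<comma-separated fly ids>        (optional; default tubeNN labels)
#   sec,tube01_count,tube01_pos,...         (no column-name row, no quoting)
#
# Stimulus log CSV:
#   #photobeam-stim v1
#   time_ms,tubes,color,intensity
#   rows; `tubes` is a range string and may itself contain commas, so rows
#   are parsed positionally (first field + last two fields).

.pb_t0_fmt <- "%Y-%m-%dT%H:%M:%SZ"

format_num <- function(x) {
  sprintf("%.17g", x)
}

#' Write an activity CSV
#'
#' Serialises one or more [activity_trace()]s sharing a session (same `t0`,
#' `zt0`, duration and geometry) into the package's activity CSV dialect.
#' The file round-trips bit-identically through [read_activity_csv()].
#'
#' @param traces A single `activity_trace` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(traces, path) {
  if (inherits(traces, "activity_trace")) traces <- list(traces)
  if (!length(traces) || !all(vapply(traces, inherits, TRUE, "activity_trace"))) {
    stop("traces must be activity_trace objects")
  }
  durs <- vapply(traces, `[[`, 1L, "duration")
  t0s <- vapply(traces, function(tr) as.numeric(tr$t0), 1)
  zt0s <- vapply(traces, `[[`, 1, "zt0")
  if (length(unique(durs)) != 1L) stop("usage error: traces have mixed durations")
  if (length(unique(t0s)) != 1L || length(unique(zt0s)) != 1L) {
    stop("usage error: traces have mixed t0/zt0")
  }
  geom <- traces[[1L]]$geometry
  t0 <- as.POSIXct(t0s[1L], origin = "1970-01-01", tz = "UTC")
  header <- c(
    "#photobeam-activity v1",
    paste0("#t0=", format(t0, .pb_t0_fmt, tz = "UTC")),
    paste0("#zt0=", format_num(zt0s[1L])),
    sprintf("#geometry=%dx%d", geom$n_tubes, geom$n_beams),
    paste0("#flies=", paste(vapply(traces, `[[`, "", "fly_id"), collapse = ","))
  )
  body <- data.table::data.table(sec = 0:(durs[1L] - 1L))
  for (i in seq_along(traces)) {
    body[[sprintf("tube%02d_count", i)]] <- traces[[i]]$counts
    body[[sprintf("tube%02d_pos", i)]] <- traces[[i]]$position
  }
  writeLines(header, path)
  data.table::fwrite(body, path, append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read an activity CSV
#'
#' Parses the activity CSV dialect back into a list of [activity_trace()]s,
#' one per tube column-group. Malformed headers raise a format error naming
#' the offending line; a non-monotonic second column raises an integrity
#' error; rows violating the displacement invariant are tolerated with a
#' warning (real hardware can glitch).
#'
#' @param path Input file path.
#' @return A list of `activity_trace` objects.
#' @export
read_activity_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  n_head <- length(header)
  fmt_err <- function(i, why) {
    stop(sprintf("format error in %s, header line %d: %s", path, i, why),
         call. = FALSE)
  }
  if (n_head < 4L) fmt_err(n_head + 1L, "expected at least 4 '#' header lines")
  if (header[1L] != "#photobeam-activity v1") fmt_err(1L, "bad magic/version")
  if (!grepl("^#t0=", header[2L])) fmt_err(2L, "expected #t0=<ISO8601>")
  t0 <- as.POSIXct(sub("^#t0=", "", header[2L]), format = .pb_t0_fmt, tz = "UTC")
  if (is.na(t0)) fmt_err(2L, "unparseable t0 timestamp")
  if (!grepl("^#zt0=", header[3L])) fmt_err(3L, "expected #zt0=<hours>")
  zt0 <- suppressWarnings(as.numeric(sub("^#zt0=", "", header[3L])))
  if (is.na(zt0)) fmt_err(3L, "unparseable zt0")
  gm <- regmatches(header[4L], regexec("^#geometry=([0-9]+)x([0-9]+)$", header[4L]))[[1L]]
  if (length(gm) != 3L) fmt_err(4L, "expected #geometry=<n_tubes>x<n_beams>")
  geom <- beam_geometry(n_tubes = as.integer(gm[2L]), n_beams = as.integer(gm[3L]))
  fly_ids <- NULL
  if (n_head >= 5L) {
    if (!grepl("^#flies=", header[5L])) fmt_err(5L, "expected #flies=<ids>")
    fly_ids <- strsplit(sub("^#flies=", "", header[5L]), ",", fixed = TRUE)[[1L]]
  }

  body <- data.table::fread(path, skip = n_head, header = FALSE, sep = ",",
                            integer64 = "numeric", data.table = TRUE)
  if (!nrow(body)) stop("format error: no data rows in ", path)
  if ((ncol(body) - 1L) %% 2L != 0L) {
    stop("format error: expected sec + (count,pos) column pairs in ", path)
  }
  n_flies <- (ncol(body) - 1L) %/% 2L
  sec <- body[[1L]]
  if (any(sec != seq_len(nrow(body)) - 1L)) {
    stop("integrity error: non-monotonic or gapped timestamps in ", path)
  }
  if (is.null(fly_ids)) fly_ids <- sprintf("tube%02d", seq_len(n_flies))
  if (length(fly_ids) != n_flies) {
    stop("format error: #flies header names ", length(fly_ids),
         " flies but file has ", n_flies, " tube column-groups")
  }
  traces <- vector("list", n_flies)
  for (i in seq_len(n_flies)) {
    tr <- withCallingHandlers(
      activity_trace(fly_ids[i], counts = body[[2L * i]],
                     position = body[[2L * i + 1L]],
                     t0 = t0, zt0 = zt0, geometry = geom,
                     check_displacement = FALSE),
      warning = function(w) w
    )
    bad <- displacement_violations(tr)
    if (length(bad)) {
      warning(sprintf("%s: tube %d violates the displacement invariant at row(s) %s",
                      basename(path), i,
                      paste(head(bad + n_head + 1L, 5L), collapse = ", ")),
              call. = FALSE)
    }
    traces[[i]] <- tr
  }
  traces
}

#' Write / read a stimulus log file
#'
#' Lossless round trip of a [stimulus_log()] through the stimulus-log CSV
#' dialect. Writing an empty log yields a header-only file; reading an
#' unsorted file raises an integrity error.
#'
#' @param log A `stimulus_log`.
#' @param path File path.
#' @return `write_stimulus_log`: `path` invisibly; `read_stimulus_log`: a
#'   `stimulus_log`.
#' @export
write_stimulus_log <- function(log, path) {
  if (!inherits(log, "stimulus_log")) stop("log must be a stimulus_log")
  lines <- c("#photobeam-stim v1", "time_ms,tubes,color,intensity")
  if (nrow(log)) {
    tubes <- vapply(log$tubes, format_tube_set, "")
    lines <- c(lines, sprintf("%d,%s,%s,%s", log$time_ms, tubes, log$color,
                              format_num(log$intensity)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stimulus_log
#' @export
read_stimulus_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L || lines[1L] != "#photobeam-stim v1" ||
      lines[2L] != "time_ms,tubes,color,intensity") {
    stop("format error in ", path, ": bad stimulus-log header")
  }
  rows <- lines[-(1:2)]
  rows <- rows[nzchar(rows)]
  if (!length(rows)) return(stimulus_log())
  fields <- strsplit(rows, ",", fixed = TRUE)
  parsed <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 4L) {
      stop(sprintf("format error in %s, line %d: expected 4 fields", path, i + 2L))
    }
    # `tubes` may contain commas; rejoin the middle fields.
    list(time_ms = as.integer(f[1L]),
         tubes = paste(f[2:(length(f) - 2L)], collapse = ","),
         color = f[length(f) - 1L],
         intensity = as.numeric(f[length(f)]))
  })
  time_ms <- vapply(parsed, `[[`, 1L, "time_ms")
  if (anyNA(time_ms)) stop("format error in ", path, ": unparseable time_ms")
  if (is.unsorted(time_ms)) {
    stop("integrity error: events in ", path, " are not sorted by time_ms")
  }
  stimulus_log(time_ms = time_ms,
               tubes = vapply(parsed, `[[`, "", "tubes"),
               color = vapply(parsed, `[[`, "", "color"),
               intensity = vapply(parsed, `[[`, 1, "intensity"))
}

#' Write / read a zone-assignment CSV
#'
#' Zone assignments from closed-loop runs are serialised as one row per
#' second with `L`/`R` labels per fly, preceded by headers recording the
#' feedback rule so occupancy analyses can be re-run from the file.
#'
#' @param zones A `zone_assignment` (see [run_closed_loop()]).
#' @param path File path.
#' @return `write_zone_csv`: `path` invisibly; `read_zone_csv`: a
#'   `zone_assignment`.
#' @export
write_zone_csv <- function(zones, path) {
  if (!inherits(zones, "zone_assignment")) stop("zones must be a zone_assignment")
  rule <- attr(zones, "rule")
  header <- c(
    "#photobeam-zones v1",
    sprintf("#boundary_beam=%d", rule$boundary_beam),
    sprintf("#left_color=%s", rule$left_color),
    sprintf("#right_color=%s", rule$right_color),
    sprintf("#swap_at_s=%d", if (is.null(rule$swap_at_s)) -1L else as.integer(rule$swap_at_s)),
    sprintf("#feedback_start_s=%d", attr(zones, "feedback_start_s")),
    paste0("#flies=", paste(colnames(zones), collapse = ","))
  )
  lab <- matrix(c("L", "R")[zones], nrow = nrow(zones))
  body <- data.table::data.table(sec = 0:(nrow(zones) - 1L))
  for (j in seq_len(ncol(zones))) body[[paste0("fly", j)]] <- lab[, j]
  writeLines(header, path)
  data.table::fwrite(body, path, append = TRUE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_zone_csv
#' @export
read_zone_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 7L)
  if (length(lines) < 7L || lines[1L] != "#photobeam-zones v1") {
    stop("format error in ", path, ": bad zone-file header")
  }
  take <- function(i, key) {
    if (!grepl(paste0("^#", key, "="), lines[i])) {
      stop("format error in ", path, ": expected #", key, " on line ", i)
    }
    sub(paste0("^#", key, "="), "", lines[i])
  }
  boundary <- as.integer(take(2L, "boundary_beam"))
  left <- take(3L, "left_color")
  right <- take(4L, "right_color")
  swap <- as.integer(take(5L, "swap_at_s"))
  fb_start <- as.integer(take(6L, "feedback_start_s"))
  flies <- strsplit(take(7L, "flies"), ",", fixed = TRUE)[[1L]]
  body <- data.table::fread(path, skip = 7L, header = FALSE, data.table = FALSE)
  m <- as.matrix(body[, -1L, drop = FALSE])
  zones <- matrix(match(m, c("L", "R")), nrow = nrow(body))
  colnames(zones) <- flies
  rule <- feedback_rule(boundary_beam = boundary, left_color = left,
                        right_color = right,
                        swap_at_s = if (swap < 0L) NULL else swap)
  zone_assignment(zones, rule = rule, feedback_start_s = fb_start)
}
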