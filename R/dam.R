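#' Simulate DAM2 activity-monitor streams
#'
#' Emulates TriKinetics DAM2 recordings for a set of flies with known death
#' times. While a fly is alive its channel emits Poisson counts at
#' `activity_rate` per bin (scaled for the bin width); the bin containing
#' the death gets a partial-exposure rate, and every later bin is exactly
#' zero. A `damaged_fraction` of channels emit nothing from the start,
#' emulating flies injured during loading, which the low-activity filter is
#' designed to remove. Recordings run for `days` days (default 6) and are
#' split across 32-channel monitors.
#'
#' @param death_hours Numeric vector, one death time (hours since assay
#'   start) per fly; `Inf` for a fly that outlives the recording.
#' @param sampling_min Bin width in minutes (>= 1).
#' @param activity_rate Mean counts per minute while alive.
#' @param damaged_fraction Probability a channel is damaged (near-zero
#'   counts throughout).
#' @param days Recording length in days.
#' @param start Assay start time (POSIXct, UTC).
#' @param seed Optional integer seed.
#' @return A list with `monitors` (list of `dam_record` tibbles, one per
#'   32-channel monitor) and `channel_map` (tibble `monitor`, `channel`,
#'   `fly`, `damaged`).
#' @examples
#' str(simulate_dam_streams(c(35.5, 80), activity_rate = 5, seed = 1), max.level = 1)
#' @export
simulate_dam_streams <- function(death_hours, sampling_min = 1,
                                 activity_rate = 2, damaged_fraction = 0,
                                 days = 6,
                                 start = as.POSIXct("2015-01-05 09:00:00", tz = "UTC"),
                                 seed = NULL) {
  if (any(death_hours < 0)) abort("`death_hours` must be non-negative.")
  if (sampling_min < 1) abort("`sampling_min` must be at least 1 minute.")
  stopifnot_scalar_prob(damaged_fraction, "damaged_fraction")

  with_seed_(seed, {
    n_fly <- length(death_hours)
    n_monitor <- ceiling(n_fly / 32)
    n_bins <- as.integer(days * 24 * 60 / sampling_min)
    bin_h <- sampling_min / 60
    bin_end_h <- seq_len(n_bins) * bin_h
    stamps <- start + bin_end_h * 3600

    damaged <- rbinom(n_fly, 1L, damaged_fraction) == 1L
    channel_map <- tibble(
      monitor = rep(seq_len(n_monitor), each = 32)[seq_len(n_fly)],
      channel = ((seq_len(n_fly) - 1L) %% 32L) + 1L,
      fly = seq_len(n_fly),
      damaged = damaged
    )

    monitors <- lapply(seq_len(n_monitor), function(m) {
      counts <- matrix(0L, n_bins, 32)
      flies <- which(channel_map$monitor == m)
      for (f in flies) {
        ch <- channel_map$channel[channel_map$fly == f]
        if (damaged[f]) next
        d <- death_hours[f]
        # exposure fraction of each bin spent alive
        alive_frac <- pmin(pmax((d - (bin_end_h - bin_h)) / bin_h, 0), 1)
        rate <- activity_rate * sampling_min * alive_frac
        nz <- which(rate > 0)
        counts[nz, ch] <- rpois(length(nz), rate[nz])
      }
      structure(
        tibble(index = seq_len(n_bins), datetime = stamps, status = 1L) |>
          dplyr::bind_cols(as_tibble(counts, .name_repair = ~ sprintf("ch%02d", 1:32))),
        class = c("dam_record", "tbl_df", "tbl", "data.frame"),
        monitor = m, sampling_min = sampling_min, assay_start = start
      )
    })
    list(monitors = monitors, channel_map = channel_map)
  })
}

# DAM2 timestamps are written/parsed with explicit English month
# abbreviations so files round-trip independently of the system locale.
format_dam_time_ <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  list(
    date = sprintf("%02d %s %02d", lt$mday, month.abb[lt$mon + 1L],
      lt$year %% 100L),
    time = sprintf("%02d:%02d:%02d", lt$hour, lt$min, floor(lt$sec))
  )
}

parse_dam_time_ <- function(date, time) {
  parts <- strsplit(date, " ", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) abort(sprintf("Malformed DAM date at row %d.", bad[1]))
  d <- vapply(parts, `[`, "", 1L)
  mo <- match(vapply(parts, `[`, "", 2L), month.abb)
  yr <- as.integer(vapply(parts, `[`, "", 3L))
  if (anyNA(mo)) abort(sprintf("Unrecognized month at row %d.", which(is.na(mo))[1]))
  as.POSIXct(sprintf("%04d-%02d-%s %s", 2000L + yr, mo, d, time), tz = "UTC")
}

#' Write a DAM record to a monitor text file
#'
#' Writes the tab-separated DAM2 dialect: record index, date, time, machine
#' status, then 32 channel count columns.
#'
#' @param record A `dam_record` tibble (see [simulate_dam_streams()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dam <- function(record, path) {
  ts <- format_dam_time_(record$datetime)
  counts <- as.matrix(record[grep("^ch[0-9]+$", names(record))])
  lines <- paste(record$index, ts$date, ts$time, record$status,
    apply(counts, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a DAM2 monitor file
#'
#' Parses the tab-separated DAM2 dialect (record index, date, time, status,
#' then 32 channel counts; extra metadata columns between the status and the
#' counts are tolerated and skipped: the final 32 columns are always taken
#' as the counts). Rows with the wrong column count, unparseable fields, or
#' non-monotone timestamps raise an error naming the offending row.
#'
#' @param path Path to a DAM2 monitor text file.
#' @param sampling_min Bin width in minutes (used only to locate the assay
#'   start one bin before the first record).
#' @return A `dam_record` tibble: `index`, `datetime`, `status`, `ch01` ..
#'   `ch32`.
#' @export
read_dam <- function(path, sampling_min = 1) {
  raw <- readLines(path)
  if (length(raw) == 0) abort("DAM file is empty.")
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 36L)
  if (length(bad)) {
    abort(sprintf("DAM row %d has %d columns; expected at least 36 (4 header + 32 counts).",
      bad[1], nf[bad[1]]))
  }
  idx <- as.integer(vapply(fields, `[`, "", 1L))
  dates <- vapply(fields, `[`, "", 2L)
  times <- vapply(fields, `[`, "", 3L)
  status <- as.integer(vapply(fields, `[`, "", 4L))
  counts <- t(vapply(seq_along(fields), function(i) {
    v <- suppressWarnings(as.integer(tail(fields[[i]], 32L)))
    if (anyNA(v)) abort(sprintf("Non-numeric count in DAM row %d.", i))
    v
  }, integer(32)))
  if (any(counts < 0)) {
    abort(sprintf("Negative count in DAM row %d.", which(rowSums(counts < 0) > 0)[1]))
  }
  datetime <- parse_dam_time_(dates, times)
  if (any(diff(as.numeric(datetime)) <= 0)) {
    abort(sprintf("Non-monotone timestamp at DAM row %d.",
      which(diff(as.numeric(datetime)) <= 0)[1] + 1L))
  }
  colnames(counts) <- sprintf("ch%02d", 1:32)
  structure(
    dplyr::bind_cols(tibble(index = idx, datetime = datetime, status = status),
      as_tibble(counts)),
    class = c("dam_record", "tbl_df", "tbl", "data.frame"),
    sampling_min = sampling_min,
    assay_start = datetime[1] - sampling_min * 60
  )
}

#' Extract per-fly death times from a DAM record
#'
#' Death is operationalized as permanent cessation of activity: the death
#' time of a channel is the end of its last non-zero bin. Channels whose
#' total counts during the first `filter_window` hours fall below
#' `filter_min_counts` are flagged as filtered (damaged/low-activity from
#' the start) and carry no death time. Channels still active in the final
#' bin are censored at the recording end. An optional refractory rule
#' (`blip_gap_hours`, default off) discards trailing single-count blips
#' separated from the preceding activity by at least that many quiet hours.
#'
#' @param record A `dam_record` tibble.
#' @param assay_start Assay start time; defaults to one bin before the first
#'   record (attribute set by [read_dam()]/[simulate_dam_streams()]).
#' @param filter_window Low-activity filter window in hours.
#' @param filter_min_counts Minimum total counts required in the window.
#' @param blip_gap_hours Optional refractory gap (hours); `NULL` disables.
#' @return Tibble of lifespan calls: `channel`, `death_hours`, `censored`,
#'   `filtered`, `reason`.
#' @export
extract_lifespans <- function(record, assay_start = NULL,
                              filter_window = 2, filter_min_counts = 5,
                              blip_gap_hours = NULL) {
  assay_start <- assay_start %||% attr(record, "assay_start") %||%
    (record$datetime[1] - (attr(record, "sampling_min") %||% 1) * 60)
  hours <- as.numeric(difftime(record$datetime, assay_start, units = "hours"))
  span <- max(hours)
  if (filter_window > span) {
    abort("`filter_window` is longer than the recording span.")
  }
  counts <- as.matrix(record[grep("^ch[0-9]+$", names(record))])
  in_window <- hours <= filter_window

  purrr::map_dfr(seq_len(ncol(counts)), function(ch) {
    x <- counts[, ch]
    if (sum(x[in_window]) < filter_min_counts) {
      return(tibble(channel = ch, death_hours = NA_real_, censored = FALSE,
        filtered = TRUE, reason = "low activity from start"))
    }
    nz <- which(x > 0)
    if (!is.null(blip_gap_hours)) {
      while (length(nz) > 1 && x[nz[length(nz)]] == 1 &&
        hours[nz[length(nz)]] - hours[nz[length(nz) - 1]] >= blip_gap_hours) {
        nz <- nz[-length(nz)]
      }
    }
    last <- nz[length(nz)]
    if (last == length(x)) {
      tibble(channel = ch, death_hours = span, censored = TRUE,
        filtered = FALSE, reason = "active at recording end")
    } else {
      tibble(channel = ch, death_hours = hours[last], censored = FALSE,
        filtered = FALSE, reason = NA_character_)
    }
  })
}

#' Summarize lifespan calls into line means
#'
#' @param calls Lifespan-call tibble from [extract_lifespans()] (optionally
#'   with a `monitor` column when several monitors are pooled).
#' @param channel_map Tibble mapping channels to genotypes: columns
#'   `channel` and `line` (plus `monitor` when present in `calls`).
#' @param drop_censored Censored flies are excluded from means by default
#'   and reported per line in `n_censored`.
#' @return Tibble `line`, `mean`, `sd`, `n`, `n_censored`. Lines whose every
#'   channel was filtered are absent, and listed in the `"exclusions"`
#'   attribute together with per-channel reasons.
#' @export
summarize_lines <- function(calls, channel_map, drop_censored = TRUE) {
  keys <- intersect(c("monitor", "channel"), names(calls))
  merged <- dplyr::left_join(calls, channel_map, by = keys)
  unmapped <- merged[!merged$filtered & is.na(merged$line), ]
  if (nrow(unmapped) > 0) {
    abort(sprintf("Channel %d has no genotype assignment.", unmapped$channel[1]))
  }
  usable <- merged[!merged$filtered & (!merged$censored | !drop_censored), ]
  out <- usable |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(
      mean = mean(.data$death_hours),
      sd = sd(.data$death_hours),
      n = dplyr::n(), .groups = "drop"
    )
  cens <- merged |>
    dplyr::filter(!.data$filtered, .data$censored) |>
    dplyr::count(.data$line, name = "n_censored")
  out <- dplyr::left_join(out, cens, by = "line") |>
    dplyr::mutate(n_censored = dplyr::coalesce(.data$n_censored, 0L))
  excluded <- setdiff(unique(merged$line[!is.na(merged$line)]), out$line)
  attr(out, "exclusions") <- merged |>
    dplyr::filter(.data$line %in% excluded) |>
    dplyr::select(dplyr::any_of(c("monitor", "channel")), "line", "reason")
  out
}
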