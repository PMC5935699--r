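# Delimited-text readers for the four data dialects, plus result
# serialization. All readers go through data.table::fread (delimiter
# auto-detection) and use a column `mapping` so files with drifting
# header names can be adapted without editing code. Dropped or split
# records are reported via messages, never silently.

#' Read a univariate time series from delimited text
#'
#' @param path file path.
#' @param mapping named list mapping roles to column names, e.g.
#'   `list(time = "year", value = "count")`. `time` may be `NULL` for
#'   an implicitly ordered series.
#' @return Numeric vector of values (empty cells become `NA`), with
#'   attribute `times` when a time column is mapped. Rows are ordered
#'   by the time column.
#' @export
read_series <- function(path, mapping = list(time = "year", value = "count")) {
  dt <- data.table::fread(path, data.table = FALSE)
  if (!mapping$value %in% names(dt)) {
    stop_arg("mapping", sprintf("value column '%s' not found", mapping$value))
  }
  if (!is.null(mapping$time)) {
    if (!mapping$time %in% names(dt)) {
      stop_arg("mapping", sprintf("time column '%s' not found", mapping$time))
    }
    dt <- dt[order(dt[[mapping$time]]), , drop = FALSE]
  }
  v <- dt[[mapping$value]]
  if (!is.numeric(v)) {
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(vn))
    if (length(bad)) {
      stop(sprintf("unparseable value in row %d of %s", bad[1], path))
    }
    v <- vn
  }
  if (!is.null(mapping$time)) attr(v, "times") <- dt[[mapping$time]]
  v
}

#' Read an annual-count series and check for gaps
#'
#' @param path two-column delimited file.
#' @param mapping column mapping (`time`, `value`).
#' @param years required year coverage; missing years are an error.
#' @return Integer vector of counts ordered by year, attribute `times`.
#' @export
read_count_series <- function(path, mapping = list(time = "year",
                                                   value = "count"),
                              years = NULL) {
  v <- read_series(path, mapping)
  yrs <- attr(v, "times")
  if (!is.null(years)) {
    gap <- setdiff(years, yrs)
    if (length(gap)) {
      stop(sprintf("missing years in %s: %s", path,
                   paste(gap, collapse = ", ")))
    }
    v <- v[match(years, yrs)]
    attr(v, "times") <- years
  }
  if (any(!is.na(v) & (v < 0 | v != round(v)))) {
    stop_arg("path", "counts must be non-negative integers")
  }
  v
}

#' Read 2-D trajectories from delimited text
#'
#' Splits rows into per-cell tracks ordered by frame; a gap in the frame
#' sequence splits the track into separate tracks (reported via a
#' message), and duplicated (cell, frame) rows are an error.
#'
#' @param path file path.
#' @param mapping named list with roles `cell`, `frame`, `x`, `y`.
#' @param frame_min frame interval in minutes, attached to each track.
#' @return List of tracks; each is a list with `cell_id`, `frames` and
#'   `xy` (position matrix, micrometers).
#' @export
read_trajectories <- function(path,
                              mapping = list(cell = "cell_id",
                                             frame = "frame",
                                             x = "x_um", y = "y_um"),
                              frame_min = 5) {
  dt <- data.table::fread(path, data.table = FALSE)
  need <- unlist(mapping)
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop_arg("mapping", paste("columns not found:", paste(miss, collapse = ", ")))
  }
  out <- list()
  for (id in unique(dt[[mapping$cell]])) {
    sub <- dt[dt[[mapping$cell]] == id, , drop = FALSE]
    sub <- sub[order(sub[[mapping$frame]]), , drop = FALSE]
    fr <- sub[[mapping$frame]]
    if (anyDuplicated(fr)) {
      stop(sprintf("duplicate (cell, frame) rows for cell %s", id))
    }
    brk <- c(0L, which(diff(fr) != 1L), length(fr))
    if (length(brk) > 2L) {
      message(sprintf("cell %s: frame gaps split track into %d segments",
                      id, length(brk) - 1L))
    }
    for (seg in seq_len(length(brk) - 1L)) {
      idx <- (brk[seg] + 1L):brk[seg + 1L]
      out[[length(out) + 1L]] <- list(
        cell_id = id, frames = fr[idx],
        xy = cbind(sub[[mapping$x]][idx], sub[[mapping$y]][idx]),
        frame_min = frame_min
      )
    }
  }
  out
}

#' Read a temperature-anomaly series with known uncertainty
#'
#' Accepts delimited text with year, anomaly and a two-standard-error
#' column; the per-year known noise is half the two-standard-error
#' interval. With `readxl` installed, `.xlsx` workbooks are read
#' directly (`sheet` selects the sheet); otherwise export the sheet to
#' CSV first.
#'
#' @param path file path (`.csv`/`.tsv` or `.xlsx`).
#' @param mapping named list with roles `time`, `value`, `two_se`.
#' @param sheet sheet name or index for workbooks.
#' @param years optional year window to keep.
#' @return List with `years`, `anomaly` and `sigma` (= two SE / 2).
#' @export
read_temperature_series <- function(path,
                                    mapping = list(time = "year",
                                                   value = "anomaly_C",
                                                   two_se = "two_se_C"),
                                    sheet = 1, years = NULL) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading workbooks requires the 'readxl' package; ",
           "export the sheet to CSV instead")
    }
    dt <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    dt <- data.table::fread(path, data.table = FALSE)
  }
  need <- unlist(mapping)
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop_arg("mapping", paste("columns not found:", paste(miss, collapse = ", ")))
  }
  dt <- dt[order(dt[[mapping$time]]), , drop = FALSE]
  if (!is.null(years)) dt <- dt[dt[[mapping$time]] %in% years, , drop = FALSE]
  sigma <- dt[[mapping$two_se]] / 2
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop_arg("path", "two-standard-error column must be positive everywhere")
  }
  list(years = dt[[mapping$time]], anomaly = dt[[mapping$value]],
       sigma = sigma)
}

#' Write a univariate series (plus optional truth sidecar) to CSV
#'
#' @param values numeric vector.
#' @param path output CSV path.
#' @param times optional time labels.
#' @param truth optional list written as a JSON sidecar `<path>.truth.json`.
#' @param value_name,time_name column names.
#' @export
write_series <- function(values, path, times = NULL, truth = NULL,
                         value_name = "value", time_name = "time") {
  df <- if (is.null(times)) {
    stats::setNames(data.frame(seq_along(values), values),
                    c(time_name, value_name))
  } else {
    stats::setNames(data.frame(times, values), c(time_name, value_name))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Export per-step posteriors to a long-format table
#'
#' One row per (step, dimension, center) with the marginal posterior
#' weight; reads back losslessly with [read_posterior_table()].
#'
#' @param fit a [gb_fit()] result with smoothed states.
#' @param path output CSV path.
#' @param type `"smoothed"` or `"filtered"`.
#' @export
write_posterior_table <- function(fit, path, type = "smoothed") {
  m <- fit[[type]]
  if (is.null(m)) stop("fit does not store ", type, " posteriors")
  g <- fit$grid
  rows <- list()
  for (d in seq_along(g$dim_names)) {
    marg <- t(apply(m, 1L, function(w) {
      grid_marginal(grid_dist(g, w), g$dim_names[d])$w
    }))
    rows[[d]] <- data.frame(
      step = rep(seq_len(nrow(m)), each = g$n[d]),
      dimension = g$dim_names[d],
      center = rep(g$centers[[d]], times = nrow(m)),
      weight = as.numeric(t(marg))
    )
  }
  df <- do.call(rbind, rows)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read back a posterior table written by [write_posterior_table()]
#' @param path CSV path.
#' @return Data frame with columns step, dimension, center, weight.
#' @export
read_posterior_table <- function(path) {
  data.table::fread(path, data.table = FALSE)
}
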