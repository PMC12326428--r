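# Readers and writers for every stream/record format the pipeline uses.
# All files are comma-separated, dot-decimal, UTF-8, LF, with mandatory
# headers; times are written in seconds with 3 decimal places.

fmt_num <- function(x, digits) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[is.na(x)] <- "NA"
  out
}

# Strict numeric parser: errors with file, line and column on failure.
parse_num_col <- function(x, col, path, header_lines = 1L) {
  bad <- !grepl("^\\s*(NA|[-+]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][-+]?[0-9]+)?)\\s*$",
                x)
  if (any(bad))
    stop("unparsable number in ", path, " line ",
         which(bad)[1] + header_lines, " column `", col, "`: '",
         x[which(bad)[1]], "'")
  suppressWarnings(as.numeric(x))
}

read_stream_csv <- function(path, columns, logical_cols = character(0)) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (!identical(names(df), columns))
    stop(path, ": expected header `", paste(columns, collapse = ","),
         "`, found `", paste(names(df), collapse = ","), "`")
  for (col in columns) {
    df[[col]] <- if (col %in% logical_cols) {
      as.logical(df[[col]])
    } else {
      parse_num_col(df[[col]], col, path)
    }
  }
  df
}

#' Read and write the pipeline's stream CSV formats
#'
#' Acceleration (`t,ax,ay,az`), GPS (`t,lat,lon,speed,fix3d`), mask-ratio
#' (`t,mpr`) and schedule (`start,end,label`) files. Headers are mandatory;
#' `t` is written with 3 decimal places; numeric round-trips are lossless at
#' the declared precision and a malformed number is reported with its file,
#' line and column.
#'
#' @param x The stream data frame to write.
#' @param path File path.
#' @return Readers return the parsed data frame; writers return `path`
#'   invisibly.
#' @name stream_io
NULL

#' @rdname stream_io
#' @export
write_accel_csv <- function(x, path) {
  writeLines(c("t,ax,ay,az",
               paste(fmt_num(x$t, 3), fmt_num(x$ax, 6), fmt_num(x$ay, 6),
                     fmt_num(x$az, 6), sep = ",")), path)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_accel_csv <- function(path) {
  read_stream_csv(path, c("t", "ax", "ay", "az"))
}

#' @rdname stream_io
#' @export
write_gps_csv <- function(x, path) {
  writeLines(c("t,lat,lon,speed,fix3d",
               paste(fmt_num(x$t, 3), fmt_num(x$lat, 8), fmt_num(x$lon, 8),
                     fmt_num(x$speed, 4), x$fix3d, sep = ",")), path)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_gps_csv <- function(path) {
  read_stream_csv(path, c("t", "lat", "lon", "speed", "fix3d"),
                  logical_cols = "fix3d")
}

#' @rdname stream_io
#' @export
write_mask_csv <- function(x, path) {
  writeLines(c("t,mpr",
               paste(fmt_num(x$t, 3), fmt_num(x$mpr, 6), sep = ",")), path)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_mask_csv <- function(path) {
  read_stream_csv(path, c("t", "mpr"))
}

#' @rdname stream_io
#' @export
write_schedule_csv <- function(x, path) {
  writeLines(c("start,end,label",
               paste(fmt_num(x$start, 3), fmt_num(x$end, 3), x$label,
                     sep = ",")), path)
  invisible(path)
}

#' @rdname stream_io
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (!identical(names(df), c("start", "end", "label")))
    stop(path, ": expected header `start,end,label`")
  out <- data.frame(start = parse_num_col(df$start, "start", path),
                    end = parse_num_col(df$end, "end", path),
                    label = df$label, stringsAsFactors = FALSE)
  attr(out, "total_duration") <- if (nrow(out)) max(out$end) else 0
  class(out) <- c("behaviour_schedule", "data.frame")
  out
}

#' Read and write indicator series CSVs
#'
#' Format `t_rel,channel,value`, one file per session (channels may be
#' stacked).
#'
#' @param series A named list of `indicator_series` (or one series with a
#'   `channel` attribute).
#' @param path File path.
#' @return Reader: data frame `t_rel, channel, value`; writer: `path`.
#' @export
write_indicators_csv <- function(series, path) {
  if (inherits(series, "indicator_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    if (is.null(s)) return(NULL)
    ch <- attr(s, "channel") %||% "UNKNOWN"
    paste(fmt_num(s$t_rel, 3), ch, fmt_num(s$value, 6), sep = ",")
  })
  writeLines(c("t_rel,channel,value", unlist(rows)), path)
  invisible(path)
}

#' @rdname write_indicators_csv
#' @export
read_indicators_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (!identical(names(df), c("t_rel", "channel", "value")))
    stop(path, ": expected header `t_rel,channel,value`")
  data.frame(t_rel = parse_num_col(df$t_rel, "t_rel", path),
             channel = df$channel,
             value = parse_num_col(df$value, "value", path))
}

#' Read and write controller event logs as JSON-lines
#'
#' One JSON object per line: `{"t": ..., "kind": ..., "payload": ...}`.
#'
#' @param events Event data frame from [run_controller()].
#' @param path File path.
#' @return Reader: the event data frame; writer: `path` invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(list(t = events$t[i], kind = events$kind[i],
                          payload = events$payload[i]),
                     auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events_jsonl
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed JSON at ", path,
                                             " line ", i))
    data.frame(t = obj$t, kind = obj$kind,
               payload = obj$payload %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read and write session records
#'
#' @param sessions Session data frame from [run_controller()].
#' @param path File path.
#' @return Reader: the session data frame; writer: `path` invisibly.
#' @export
write_sessions_csv <- function(sessions, path) {
  utils::write.csv(sessions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sessions_csv
#' @export
read_sessions_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Structured run configuration, on disk as YAML
#'
#' A run configuration nests the per-module parameter blocks (controller,
#' classifier, indicators, MCMC, simulation) plus the master seed; every
#' field has a documented default matching the published constants where
#' those exist. `--config`-style files round-trip through these functions.
#'
#' @param controller A [controller_config()] (stored as a plain list).
#' @param classifier List of [train_tree()] parameters.
#' @param indicators List of indicator parameters.
#' @param mcmc An [mcmc_config()].
#' @param simulation List of [synth_bundle()] parameters.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(controller = controller_config(),
                       classifier = list(max_depth = 3, min_leaf = 5),
                       indicators = list(static_window_s = 2,
                                         smooth_window_s = 2,
                                         pre_window_s = 5,
                                         post_window_s = 5),
                       mcmc = mcmc_config(),
                       simulation = list(total_duration = 1800),
                       seed = 1L) {
  structure(list(controller = unclass(controller),
                 classifier = classifier, indicators = indicators,
                 mcmc = unclass(mcmc), simulation = simulation,
                 seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` to write.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[nm]])) cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    else cfg[[nm]] <- raw[[nm]]
  }
  # YAML renders vectors (colony, audio_set) as lists; flatten them back
  cfg$controller <- lapply(cfg$controller,
                           function(x) if (is.list(x)) unlist(x) else x)
  cfg$controller <- do.call(controller_config, cfg$controller)
  cfg$mcmc <- do.call(mcmc_config, cfg$mcmc)
  cfg
}

#' Write a run manifest
#'
#' Records the configuration snapshot, master seed, content digests (MD5)
#' of the input files and a timestamp, so a run can be re-executed and
#' checked for bit-identical outputs.
#'
#' @param path Manifest output path (JSON).
#' @param config A [run_config()].
#' @param inputs Character vector of input file paths to digest.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config, inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(config = unclass(config), seed = config$seed,
                   inputs = digests,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
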