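#' Read a deployment summary table
#'
#' Reads a CSV of per-deployment field-experiment outcomes (one row per
#' logger deployment): video and playback counts by stimulus type,
#' cancellations, logging hours and a failure flag (loggers whose hardware
#' failed record their logging time but no videos). The packaged fixture
#' `deployments_table1.csv` carries the published ten-deployment summary.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A `deployment_table` data frame with columns `test_id`,
#'   `n_videos`, `n_playback`, `n_predator`, `n_noise`, `n_cancelled`,
#'   `logging_h`, `failed`.
#' @export
#' @examples
#' dep <- read_deployments()
#' deployment_totals(dep)
read_deployments <- function(path = system.file("extdata",
                                                "deployments_table1.csv",
                                                package = "playbacklogger")) {
  cols <- c("test_id", "n_videos", "n_playback", "n_predator", "n_noise",
            "n_cancelled", "logging_h", "failed")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), cols))
    stop("deployment table must have columns: ", paste(cols, collapse = ", "))
  validate_deployments(df)
  class(df) <- c("deployment_table", "data.frame")
  df
}

#' Write a deployment summary table
#'
#' @param records A `deployment_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_deployments <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_deployments <- function(records) {
  counts <- records[c("n_videos", "n_playback", "n_predator", "n_noise",
                      "n_cancelled")]
  bad <- which(apply(counts < 0, 1, any) |
                 records$n_playback != records$n_predator + records$n_noise |
                 records$n_videos < records$n_playback)
  if (length(bad))
    stop("deployment row invariant violated for: ",
         paste(records$test_id[bad], collapse = ", "))
  invisible(records)
}

#' Column totals over all deployments
#'
#' Integer sums of the count columns over every row, failed deployments
#' included (their counts are zero).
#'
#' @param records A [read_deployments()] table.
#' @return Named list: integer `n_videos, n_playback, n_predator, n_noise,
#'   n_cancelled` plus numeric `logging_h` (all rows) and `logging_h_ok`
#'   (non-failed rows only).
#' @export
deployment_totals <- function(records) {
  if (nrow(records) < 1L) stop("need at least one deployment row")
  validate_deployments(records)
  counts <- vapply(records[c("n_videos", "n_playback", "n_predator",
                             "n_noise", "n_cancelled")],
                   function(x) as.integer(sum(x)), integer(1))
  c(as.list(counts),
    logging_h = sum(records$logging_h),
    logging_h_ok = sum(records$logging_h[!records$failed]))
}

# Rows satisfying the deployment success rule (>= `min_playback` playbacks).
successful_rows <- function(records, min_playback = 2) {
  records$n_playback >= min_playback
}

#' Count successful deployments
#'
#' A deployment is successful when the logger performed at least
#' `min_playback` playback experiments (default 2).
#'
#' @param records A [read_deployments()] table.
#' @param min_playback Success threshold.
#' @return Integer count.
#' @export
count_successful <- function(records, min_playback = 2) {
  sum(successful_rows(records, min_playback))
}

#' Medians and ranges over successful deployments
#'
#' Median (midpoint of the two central order statistics for even n) and
#' (min, max) range of the per-deployment video count, playback count and
#' logging hours, computed over successful deployments only.
#'
#' @param records A [read_deployments()] table.
#' @param min_playback Success threshold (default 2 playbacks).
#' @return List of `median` and `range` per measure, or an empty flagged
#'   list when no deployment qualifies.
#' @export
medians_ranges <- function(records, min_playback = 2) {
  ok <- records[successful_rows(records, min_playback), ]
  if (nrow(ok) == 0L) {
    warning("no successful deployments under the rule")
    return(structure(list(), empty = TRUE))
  }
  mr <- function(x) list(median = stats::median(x),
                         range = c(min(x), max(x)))
  list(videos = mr(ok$n_videos), playbacks = mr(ok$n_playback),
       logging_h = mr(ok$logging_h))
}
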