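## Session, metrics and grand-average I/O ------------------------------------
##
## Session format: a tab-separated channel matrix with "#"-prefixed metadata
## header lines (sampling rate and channel order) plus a sibling JSON
## manifest (<stem>.json).  There is no universal force-plate text standard;
## this keeps everything inspectable with standard tools.  Time is implicit
## (row index / sampling rate): platform sampling is uniform.

manifest_path <- function(path) sub("\\.[^.]*$", ".json", path)

#' Write a session record
#'
#' Writes the channel matrix as TSV (6-decimal fixed precision, deterministic
#' column order) with `#` metadata header lines, and the manifest as a
#' sibling `.json` file.
#'
#' @param record a [session_record()].
#' @param path output path for the channel matrix (e.g. `"s01_eo_01.tsv"`).
#' @return `path`, invisibly.
#' @export
write_session <- function(record, path) {
  ch <- record$channels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# liftpost session v1",
               sprintf("# sampling_rate: %g", record$sampling_rate),
               sprintf("# channels: %s", paste(names(ch), collapse = "\t"))),
             con)
  mat <- vapply(ch, function(v) sprintf("%.6f", v), character(length(ch[[1]])))
  write.table(mat, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(record$manifest, manifest_path(path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a session record
#'
#' Counterpart of [write_session()]; validates the result (required
#' channels, uniform lengths, manifest vocabularies) and preserves unknown
#' channels.
#'
#' @param path path to the `.tsv` channel matrix; the manifest is read from
#'   the sibling `.json` file.
#' @return a [session_record()].
#' @export
read_session <- function(path) {
  if (!file.exists(path)) lp_stop("missing_file", "no such file: %s", path)
  header <- character(0)
  con <- file(path, "r")
  repeat {
    line <- readLines(con, 1)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  close(con)
  rate_line <- grep("sampling_rate:", header, value = TRUE)
  chan_line <- grep("channels:", header, value = TRUE)
  if (!length(rate_line) || !length(chan_line))
    lp_stop("bad_header", "header must declare sampling_rate and channels")
  rate <- as.numeric(sub(".*sampling_rate:\\s*", "", rate_line[1]))
  chan_names <- strsplit(sub(".*channels:\\s*", "", chan_line[1]),
                         "\\s+")[[1]]
  mat <- read.table(path, sep = "\t", comment.char = "#",
                    col.names = chan_names)
  mp <- manifest_path(path)
  manifest <- if (file.exists(mp)) {
    tryCatch(jsonlite::read_json(mp, simplifyVector = TRUE),
             error = function(e) lp_stop("bad_manifest",
                                         "unparseable manifest: %s", mp))
  } else lp_stop("bad_manifest", "missing manifest: %s", mp)
  session_record(as.list(mat), manifest, sampling_rate = rate)
}

#' Write a metrics table
#'
#' Comma-separated with header, floats at fixed 6-decimal precision,
#' deterministic column order (as given); an empty table yields a
#' header-only file.
#'
#' @param table a data.frame of per-trial or per-subject metrics.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(table, path) {
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.6f", v))
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write a grand average
#'
#' Tab-separated: `time_ms`, then `mean`, `lo`, `hi` per axis, fixed
#' 6-decimal precision.
#'
#' @param ga a [grand_average()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grand_average <- function(ga, path) {
  cols <- list(time_ms = sprintf("%.2f", ga$time_ms))
  for (ax in names(ga$axes)) {
    a <- ga$axes[[ax]]
    cols[[paste0(ax, "_mean")]] <- sprintf("%.6f", a$mean)
    cols[[paste0(ax, "_lo")]] <- sprintf("%.6f", a$lo)
    cols[[paste0(ax, "_hi")]] <- sprintf("%.6f", a$hi)
  }
  write.table(as.data.frame(cols), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write the ground-truth sidecar of a synthetic session
#'
#' JSON sidecar (`<stem>_truth.json`) listing injected onsets and metric
#' values; never read by the analysis stages.
#'
#' @param truth the `truth` component returned by [generate_session()].
#' @param path path of the session `.tsv` the truth belongs to.
#' @return the sidecar path, invisibly.
#' @export
write_truth <- function(truth, path) {
  tp <- sub("\\.[^.]*$", "_truth.json", path)
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(tp)
}
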