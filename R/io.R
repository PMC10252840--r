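# Reading and validating STEW-dialect recordings; rating/label mapping.

#' Construct an EEG recording object
#'
#' The in-memory unit of the pipeline: one subject/condition multichannel
#' segment with its sampling rate, electrode names, and (optionally) the
#' self-reported workload rating on the 1-9 scale.
#'
#' @param data Numeric matrix, channels x samples, all values finite.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per data row.
#' @param subject_id Integer subject identifier or `NA`.
#' @param condition `"lo"` (rest) or `"hi"` (task), or `NA`.
#' @param rating Workload rating 1-9, or `NA`.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs = 128, channel_names = STEW_CHANNELS,
                          subject_id = NA_integer_, condition = NA_character_,
                          rating = NA_integer_) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric matrix (channels x samples)", call. = FALSE)
  if (any(!is.finite(data)))
    stop("data contains non-finite values", call. = FALSE)
  if (nrow(data) != length(channel_names))
    stop("channel_names length (", length(channel_names),
         ") must match data rows (", nrow(data), ")", call. = FALSE)
  if (!is.na(condition) && !condition %in% c("lo", "hi"))
    stop("condition must be 'lo', 'hi' or NA", call. = FALSE)
  if (!is.na(rating) && (rating < 1 || rating > 9))
    stop("rating must lie in 1..9", call. = FALSE)
  structure(
    list(subject_id = as.integer(subject_id), condition = condition,
         rating = as.integer(rating), fs = fs,
         channel_names = channel_names, data = data),
    class = "eeg_recording")
}

.io_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "stresswave_io_error")))
}

# filename grammar: sub{NN}_{lo|hi}.txt
.parse_stew_filename <- function(path) {
  base <- basename(path)
  m <- regmatches(base, regexec("^sub0*([0-9]+)_(lo|hi)\\.txt$", base))[[1]]
  if (length(m) == 3L) {
    list(subject = as.integer(m[2]), condition = m[3])
  } else {
    list(subject = NA_integer_, condition = NA_character_)
  }
}

#' Read a STEW-dialect recording
#'
#' Parses a whitespace-delimited numeric table (one row per time sample,
#' one column per electrode). Blank lines and trailing whitespace are
#' tolerated; scientific notation is accepted. Subject and condition are
#' taken from the filename when it matches `sub{NN}_{lo|hi}.txt`, else left
#' `NA`. Failures raise distinct condition classes:
#' `stresswave_empty_file`, `stresswave_bad_channel_count`,
#' `stresswave_non_numeric`.
#'
#' @param path Path to the text file.
#' @param fs Sampling rate to record (Hz).
#' @param expected_channels Required column count.
#' @return An `eeg_recording` (data stored channels x samples).
#' @export
read_recording <- function(path, fs = 128, expected_channels = 14L) {
  if (!file.exists(path)) .io_error("stresswave_missing_file",
                                    paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    .io_error("stresswave_empty_file", paste0("empty recording file: ", path))

  toks <- strsplit(lines, "[[:space:]]+")
  counts <- lengths(toks)
  if (any(counts != expected_channels))
    .io_error("stresswave_bad_channel_count",
              sprintf("%s: expected %d columns, found %d (first offending row %d)",
                      path, expected_channels,
                      counts[which(counts != expected_channels)[1]],
                      which(counts != expected_channels)[1]))
  vals <- suppressWarnings(as.numeric(unlist(toks, use.names = FALSE)))
  if (any(is.na(vals)))
    .io_error("stresswave_non_numeric",
              paste0(path, ": non-numeric token in numeric table"))

  data <- t(matrix(vals, nrow = expected_channels))  # rows = samples
  meta <- .parse_stew_filename(path)
  new_recording(t(data), fs = fs,
                channel_names = rep_len(STEW_CHANNELS, expected_channels),
                subject_id = meta$subject, condition = meta$condition)
}

#' Read a ratings file
#'
#' Lines of the form `subject,condition,rating`.
#'
#' @param path Path to `ratings.txt`.
#' @return Data frame with columns `subject`, `condition`, `rating`.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) .io_error("stresswave_missing_file",
                                    paste0("no such file: ", path))
  df <- utils::read.csv(path, header = FALSE,
                        col.names = c("subject", "condition", "rating"),
                        stringsAsFactors = FALSE)
  df$subject <- as.integer(df$subject)
  df$rating <- as.integer(df$rating)
  df
}

#' Read a directory of STEW-dialect recordings
#'
#' Loads every `sub*_lo.txt` / `sub*_hi.txt` file and, when a
#' `ratings.txt` is present, attaches each recording's rating.
#'
#' @param dir Directory path.
#' @inheritParams read_recording
#' @return List of `eeg_recording` objects.
#' @export
read_stew_dir <- function(dir, fs = 128, expected_channels = 14L) {
  files <- sort(list.files(dir, pattern = "^sub[0-9]+_(lo|hi)\\.txt$",
                           full.names = TRUE))
  if (length(files) == 0L)
    .io_error("stresswave_missing_file",
              paste0("no recording files found in ", dir))
  recs <- lapply(files, read_recording, fs = fs,
                 expected_channels = expected_channels)
  ratings_path <- file.path(dir, "ratings.txt")
  if (file.exists(ratings_path)) {
    ratings <- read_ratings(ratings_path)
    for (i in seq_along(recs)) {
      r <- recs[[i]]
      hit <- which(ratings$subject == r$subject_id &
                     ratings$condition == r$condition)
      if (length(hit) == 1L) recs[[i]]$rating <- ratings$rating[hit]
    }
  }
  recs
}

#' Map a workload rating to its burden category
#'
#' Ratings 1-3 are low burden, 4-6 moderate, 7-9 high.
#'
#' @param rating Integer rating(s) in 1..9.
#' @return Character vector: `"low"`, `"moderate"` or `"high"`.
#' @export
rating_to_burden <- function(rating) {
  if (any(is.na(rating)) || any(rating < 1) || any(rating > 9) ||
      any(rating != round(rating)))
    stop("rating must be an integer in 1..9", call. = FALSE)
  c("low", "moderate", "high")[findInterval(rating, c(1, 4, 7))]
}

#' Binary stress label for a recording
#'
#' Default policy `"by_condition"` maps the rest segment ("lo") to 0 and
#' the task segment ("hi") to 1 -- the reading of "stress vs. relax" used
#' throughout the pipeline. Policy `"by_rating"` instead thresholds the
#' self-reported rating (default: rating >= 7, the high-burden band, is
#' stress).
#'
#' @param recording An `eeg_recording`.
#' @param policy `"by_condition"` or `"by_rating"`.
#' @param threshold Rating threshold for `"by_rating"`.
#' @return Integer 0 (relax) or 1 (stress).
#' @export
to_binary_label <- function(recording, policy = c("by_condition", "by_rating"),
                            threshold = 7L) {
  stopifnot(inherits(recording, "eeg_recording"))
  policy <- match.arg(policy)
  if (policy == "by_condition") {
    if (is.na(recording$condition))
      stop("policy 'by_condition' requires a condition", call. = FALSE)
    return(if (recording$condition == "hi") 1L else 0L)
  }
  if (is.na(recording$rating))
    stop("policy 'by_rating' requires a rating", call. = FALSE)
  if (recording$rating >= threshold) 1L else 0L
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> subject ", x$subject_id, ", condition ", x$condition,
      ", rating ", x$rating, "\n  ", nrow(x$data), " channels x ",
      ncol(x$data), " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}
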