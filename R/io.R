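# On-disk dialect (versioned, v1):
#   <dir>/<channel>.csv   row 1 = start time in seconds since session start,
#                         row 2 = sampling rate in Hz, remaining rows = values
#   <dir>/annotation.csv  header start_s,end_s,phase
#   <dir>/truth.json      optional simulator ground-truth sidecar
# UTF-8, comma-separated, dot decimal. Modeled on the wristband CSV export
# (timestamp row, rate row, value rows).

#' Read a phase-annotation file
#'
#' @param path Path to an annotation CSV with header `start_s,end_s,phase`.
#' @return A [phase_annotation()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("missing_annotation: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "phase")
  if (!all(need %in% names(df))) {
    stop("malformed_annotation: expected columns start_s,end_s,phase",
         call. = FALSE)
  }
  phase_annotation(df$start_s, df$end_s, df$phase)
}

#' Write a phase-annotation file
#'
#' @param annotation A [phase_annotation()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotation, path) {
  stopifnot(inherits(annotation, "phase_annotation"))
  df <- data.frame(start_s = annotation$start, end_s = annotation$end,
                   phase = annotation$phase)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_channel_file <- function(path, name) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) < 3) stop("malformed_channel_file: ", path,
                            " needs start row, rate row and >= 1 value",
                            call. = FALSE)
  num <- suppressWarnings(as.numeric(raw))
  if (any(is.na(num))) {
    stop("nonnumeric_value: row ", which(is.na(num))[1], " of ", path,
         call. = FALSE)
  }
  if (num[2] <= 0) stop("invalid_sampling_rate: rate row of ", path,
                        " must be > 0", call. = FALSE)
  channel_series(name, num[-(1:2)], sampling_rate = num[2], start_time = num[1])
}

#' Read a subject recording from a directory
#'
#' Expects one CSV per channel in the dialect documented above plus an
#' `annotation.csv`, and attaches `truth.json` as ground truth when present.
#'
#' @param directory_path Directory holding the session files.
#' @param subject_id Subject identifier to attach.
#' @param channels Channel names to require; defaults to the six raw channels.
#' @return A [recording()].
#' @export
read_recording <- function(directory_path, subject_id,
                           channels = channel_names()) {
  if (!dir.exists(directory_path)) {
    stop("missing_directory: ", directory_path, call. = FALSE)
  }
  files <- file.path(directory_path, paste0(channels, ".csv"))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop("missing_channel: ", paste(channels[missing], collapse = ", "),
         call. = FALSE)
  }
  chans <- Map(read_channel_file, files, channels)
  ann <- read_annotations(file.path(directory_path, "annotation.csv"))
  truth_path <- file.path(directory_path, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  }
  recording(subject_id, unname(chans), ann, ground_truth = truth)
}

#' Write a recording to a directory
#'
#' One CSV per channel plus `annotation.csv`; simulator ground truth, when
#' present, goes to `truth.json`. Values are written with full precision so
#' [read_recording()] inverts this exactly.
#'
#' @param recording A [recording()].
#' @param directory_path Output directory (created if needed).
#' @return `directory_path`, invisibly.
#' @export
write_recording <- function(recording, directory_path) {
  stopifnot(inherits(recording, "recording"))
  if (!length(recording$channels)) {
    stop("empty_channels: nothing to write", call. = FALSE)
  }
  ok <- dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory_path)) {
    stop("unwritable_path: ", directory_path, call. = FALSE)
  }
  for (ch in recording$channels) {
    lines <- c(format(ch$start_time, digits = 17),
               format(ch$sampling_rate, digits = 17),
               format(ch$values, digits = 17, trim = TRUE, scientific = FALSE))
    writeLines(lines, file.path(directory_path, paste0(ch$name, ".csv")))
  }
  write_annotations(recording$annotation,
                    file.path(directory_path, "annotation.csv"))
  if (!is.null(recording$ground_truth)) {
    jsonlite::write_json(recording$ground_truth,
                         file.path(directory_path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(directory_path)
}

#' Write a cohort of recordings, one subdirectory per subject
#'
#' @param cohort List of [recording()] objects.
#' @param directory_path Output root directory.
#' @return `directory_path`, invisibly.
#' @export
write_cohort <- function(cohort, directory_path) {
  for (rec in cohort) {
    write_recording(rec, file.path(directory_path, rec$subject_id))
  }
  invisible(directory_path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory_path Root directory with one subdirectory per subject.
#' @param channels Channel names to require per subject.
#' @return List of [recording()] objects, ordered by subject directory name.
#' @export
read_cohort <- function(directory_path, channels = channel_names()) {
  subs <- list.dirs(directory_path, recursive = FALSE)
  lapply(subs, function(d) read_recording(d, basename(d), channels))
}
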