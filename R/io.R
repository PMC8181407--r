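# Plain-text recording / annotation IO.
#
# Recording CSV layout (one self-contained file):
#   '#' header lines carry metadata:
#     # s1s2seg-recording v1
#     # sampling_rate_hz: 1000
#     # channel: name=<name> kind=<unipolar|bipolar> catheter=<label>
#                pos1=x,y,z [pos2=x,y,z]   (omitted when geometry-free;
#                pos?=timevarying moves the coordinates to data columns
#                named <name>.pos<k>.<x|y|z>)
#   then a regular comma-separated table with one column per channel (mV).
# Values use '.' as decimal separator.

.fmt_pos <- function(m) paste(format(m[1L, ], trim = TRUE, digits = 17),
                              collapse = ",")

#' Write a recording to a plain-text CSV bundle
#'
#' The format round-trips voltages exactly (full double precision) and
#' metadata losslessly; see [readRecording()].
#'
#' @param rec an [EgmRecording-class].
#' @param path output file path.
#' @param format only `"csv"` is supported in this build; `"hdf5"` signals
#'   an error (no HDF5 binding is available to this package).
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 output is not supported in this build; use format = 'csv'")
  .stop_if_not(nChannels(rec) > 0, "recording has no channels")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# s1s2seg-recording v1", con)
  writeLines(sprintf("# sampling_rate_hz: %.17g", samplingRate(rec)), con)
  extra <- list()
  for (i in seq_len(nChannels(rec))) {
    nm <- channelNames(rec)[i]
    parts <- sprintf("name=%s kind=%s catheter=%s", nm, rec@channelKind[i],
                     rec@catheter[i])
    p <- rec@positions[[i]]
    for (k in seq_along(p)) {
      if (nrow(p[[k]]) == 1L) {
        parts <- paste0(parts, sprintf(" pos%d=%s", k, .fmt_pos(p[[k]])))
      } else {
        parts <- paste0(parts, sprintf(" pos%d=timevarying", k))
        cols <- as.data.frame(p[[k]])
        names(cols) <- sprintf("%s.pos%d.%s", nm, k, c("x", "y", "z"))
        extra <- c(extra, cols)
      }
    }
    writeLines(paste("# channel:", parts), con)
  }
  tab <- as.data.frame(signalMatrix(rec))
  if (length(extra)) tab <- cbind(tab, as.data.frame(extra))
  write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.parse_kv <- function(line) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}

#' Read a recording written by [writeRecording()]
#'
#' @param path file path.
#' @param format only `"csv"` is supported; `"hdf5"` signals an error.
#' @return an [EgmRecording-class]; recordings without position metadata are
#'   geometry-free (distance operations will refuse them).
#' @export
readRecording <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 input is not supported in this build; use format = 'csv'")
  .stop_if_not(file.exists(path), paste("no such file:", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- lines[hdr]
  fs_line <- grep("^# sampling_rate_hz:", meta, value = TRUE)
  if (length(fs_line) != 1L)
    stop("recording format error: missing sampling rate")
  fs <- as.numeric(sub("^# sampling_rate_hz:", "", fs_line))
  ch_lines <- sub("^# channel:", "", grep("^# channel:", meta, value = TRUE))
  if (length(ch_lines) == 0L)
    stop("recording format error: no channel declarations")
  info <- lapply(ch_lines, .parse_kv)
  tab <- read.csv(textConnection(lines[-hdr]), check.names = FALSE)
  nms <- vapply(info, `[[`, "", "name")
  missing <- setdiff(nms, names(tab))
  if (length(missing))
    stop("recording format error: missing signal column(s): ",
         paste(missing, collapse = ", "))
  if (anyNA(tab[nms]))
    stop("recording format error: unequal trace lengths or missing values")
  sig <- as.matrix(tab[nms])
  colnames(sig) <- nms
  positions <- lapply(seq_along(info), function(i) {
    kv <- info[[i]]
    out <- list()
    for (k in 1:2) {
      key <- paste0("pos", k)
      if (!key %in% names(kv)) next
      if (identical(kv[[key]], "timevarying")) {
        cols <- sprintf("%s.pos%d.%s", kv[["name"]], k, c("x", "y", "z"))
        .stop_if_not(all(cols %in% names(tab)),
                     "recording format error: missing position columns")
        out[[k]] <- as.matrix(tab[cols])
        dimnames(out[[k]]) <- NULL
      } else {
        out[[k]] <- matrix(as.numeric(strsplit(kv[[key]], ",")[[1]]),
                           nrow = 1)
      }
    }
    out
  })
  EgmRecording(sig, samplingRate = fs,
               kind = vapply(info, `[[`, "", "kind"),
               catheter = vapply(info, `[[`, "", "catheter"),
               positions = positions)
}

.ANNOT_COLS <- c("channel", "start", "peak", "end", "label", "train_index",
                 "trusted")

#' Create an activity-annotation table
#'
#' One row per detected event (stimulus or atrial activity). `start`, `peak`
#' and `end` are 0-based sample indices with half-open `[start, end)`
#' windows and `start <= peak < end`. Labels: `S1`, `S2`, `atrial`, `extra`,
#' `discarded`.
#'
#' @param channel integer channel indices (1-based).
#' @param start,peak,end 0-based sample indices.
#' @param label event label.
#' @param train_index pacing-train index or `NA`.
#' @param trusted logical trust flag.
#' @return a data frame with the annotation columns.
#' @export
activityAnnotation <- function(channel = integer(0), start = integer(0),
                               peak = integer(0), end = integer(0),
                               label = character(0),
                               train_index = NA_integer_, trusted = TRUE) {
  n <- length(start)
  if (n == 0L) {
    return(data.frame(channel = integer(0), start = integer(0),
                      peak = integer(0), end = integer(0),
                      label = character(0), train_index = integer(0),
                      trusted = logical(0)))
  }
  df <- data.frame(channel = rep_len(as.integer(channel), n),
                   start = as.integer(start),
                   peak = as.integer(peak), end = as.integer(end),
                   label = rep_len(as.character(label), n),
                   train_index = rep_len(as.integer(train_index), n),
                   trusted = rep_len(as.logical(trusted), n))
  .stop_if_not(all(df$start <= df$peak & df$peak < df$end),
               "annotation windows must satisfy start <= peak < end")
  df
}

#' Write annotations to CSV
#' @param annots annotation data frame (see [activityAnnotation()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(annots, path) {
  out <- if (nrow(annots) == 0L)
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(.ANNOT_COLS))),
                    .ANNOT_COLS)
  else annots[.ANNOT_COLS]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotation CSV
#' @param path file path.
#' @return annotation data frame.
#' @export
readAnnotations <- function(path) {
  df <- read.csv(path)
  .stop_if_not(all(.ANNOT_COLS %in% names(df)),
               "annotation file is missing required columns")
  df$trusted <- as.logical(df$trusted)
  df[.ANNOT_COLS]
}

#' Read a QRS fiducial table
#'
#' Expects columns `qrs_start`, `qrs_peak`, `qrs_end` (0-based sample
#' indices); rows must be time-ordered and non-overlapping.
#'
#' @param path CSV file path.
#' @return data frame of QRS windows.
#' @export
readQrsTable <- function(path) {
  df <- read.csv(path)
  .stop_if_not(all(c("qrs_start", "qrs_peak", "qrs_end") %in% names(df)),
               "QRS table must have columns qrs_start, qrs_peak, qrs_end")
  .stop_if_not(all(df$qrs_start <= df$qrs_peak & df$qrs_peak <= df$qrs_end),
               "QRS rows must satisfy start <= peak <= end")
  if (nrow(df) > 1L)
    .stop_if_not(all(diff(df$qrs_start) > 0) &&
                 all(df$qrs_end[-nrow(df)] <= df$qrs_start[-1L]),
                 "QRS rows must be time-ordered and non-overlapping")
  df
}
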