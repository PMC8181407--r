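#' @importFrom stats fft sd median quantile runif convolve prcomp nls coef
#'   dist rle
#' @importFrom utils head tail read.csv write.csv
NULL

# Samples <-> time helpers. Public tables use 0-based sample indices with
# half-open [start, end) windows; 1 sample == 1 ms at the default 1 kHz.
.ms2smp <- function(ms, fs) as.integer(round(ms * fs / 1000))
.smp2ms <- function(smp, fs) smp * 1000 / fs

# Evaluate expr with a local RNG seed, restoring global RNG state afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Centered moving average; width in samples (made odd), edges zero-padded.
.moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  k <- rep(1 / width, width)
  as.numeric(stats::filter(c(rep(0, width), x, rep(0, width)), k,
                           sides = 2))[(width + 1L):(width + length(x))]
}

# Moving maximum of |x| as a crude envelope; width in samples.
.envelope <- function(x, width) {
  n <- length(x)
  width <- max(1L, as.integer(width))
  half <- width %/% 2L
  ax <- abs(x)
  if (width <= 1L || n == 0L) return(ax)
  out <- ax
  for (s in seq_len(half)) {
    out <- pmax(out,
                c(ax[-seq_len(s)], rep(0, s)),      # shift left by s
                c(rep(0, s), ax[seq_len(n - s)]))   # shift right by s
  }
  out
}

# Maximal runs of det > thr as half-open [start, end) windows (0-based),
# peak = index attaining the run maximum.
.runs_above <- function(det, thr) {
  above <- det > thr
  if (!any(above)) {
    return(data.frame(start = integer(0), peak = integer(0),
                      end = integer(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(i) {
    s <- starts[i]; e <- ends[i]
    p <- s - 1L + which.max(det[s:e])
    c(s, p, e + 1L)  # half-open end
  })
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L] - 1L, peak = m[, 2L] - 1L, end = m[, 3L] - 1L)
}

# Zero-phase Butterworth filtering (forward-backward).
.butter_zerophase <- function(x, fs, cutoff_hz, type = c("high", "low"),
                              order = 4L) {
  type <- match.arg(type)
  w <- cutoff_hz / (fs / 2)
  stopifnot(w > 0, w < 1)
  bf <- signal::butter(order, w, type = type)
  as.numeric(signal::filtfilt(bf, x))
}

.stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
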