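# shared peak-picking machinery (dF/F events and spike-rate events)

# indices of local maxima (first sample of plateaus counts)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(vapply(2:(n - 1), function(i)
    x[i] > x[i - 1] && x[i] >= x[i + 1], logical(1))) + 1L
}

# topographic prominence of the peak at index i: height above the higher of
# the two minima separating it from the nearest higher terrain (or the edge)
peak_prominence <- function(x, i) {
  h <- x[i]
  left <- if (i == 1L) h else {
    j <- i - 1L; m <- x[j]
    while (j > 1L && x[j] <= h) { j <- j - 1L; m <- min(m, x[j]) }
    m
  }
  right <- if (i == length(x)) h else {
    j <- i + 1L; m <- x[j]
    while (j < length(x) && x[j] <= h) { j <- j + 1L; m <- min(m, x[j]) }
    m
  }
  h - max(min(left, h), min(right, h))
}

# contiguous index runs where cond is TRUE
threshold_segments <- function(cond) {
  if (!any(cond)) return(list())
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  keep <- which(r$values)
  lapply(keep, function(k) starts[k]:ends[k])
}

# one event per threshold-crossing segment: the first local maximum meeting
# the prominence and separation rules; prominence measured on the full trace
segment_peaks <- function(x, t, segments, min_prominence, min_separation,
                          accepted_times = numeric(0)) {
  maxima <- local_maxima(x)
  picked <- integer(0)
  acc <- accepted_times
  for (seg in segments) {
    cand <- maxima[maxima %in% seg]
    if (length(cand) == 0L) cand <- seg[which.max(x[seg])]
    for (i in cand) {
      if (length(acc) > 0 && min(abs(t[i] - acc)) < min_separation) next
      if (peak_prominence(x, i) < min_prominence) next
      picked <- c(picked, i)
      acc <- c(acc, t[i])
      break
    }
  }
  picked
}

# free-running peak detection (no threshold segments): all local maxima in
# time order, greedily accepted under the prominence and separation rules
free_peaks <- function(x, t, min_prominence, min_separation) {
  maxima <- local_maxima(x)
  picked <- integer(0); acc <- numeric(0)
  for (i in maxima) {
    if (peak_prominence(x, i) < min_prominence) next
    if (length(acc) > 0 && min(abs(t[i] - acc)) < min_separation) next
    picked <- c(picked, i)
    acc <- c(acc, t[i])
  }
  picked
}
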