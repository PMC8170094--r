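# Independent brute-force segmentation of a distance trace into binding
# events, written as a restartable forward scan (distinct from the
# single-pass state machine in the package). Returns a data frame of
# 1-based (start, end, resolved).
brute_force_events <- function(d, enter = 9, ret = 13, exit = 20) {
  n <- length(d)
  out <- data.frame(start = integer(0), end = integer(0),
                    resolved = logical(0))
  i <- 1L
  while (i <= n) {
    if (d[i] < enter) {
      start <- i
      last_in <- i
      j <- i + 1L
      closed <- FALSE
      while (j <= n) {
        if (d[j] <= ret) last_in <- j
        if (d[j] >= exit) { closed <- TRUE; break }
        j <- j + 1L
      }
      end <- if (closed) last_in else n
      out <- rbind(out, data.frame(start = start, end = end,
                                   resolved = closed))
      i <- if (closed) j + 1L else n + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Random piecewise-constant-with-jumps trace exercising all threshold bands
random_trace <- function(n = 200) {
  d <- cumsum(stats::rnorm(n, 0, 4))
  d <- abs(d %% 60)  # fold into [0, 60) so all bands are visited
  tibble::tibble(time_ps = (seq_len(n) - 1) * 10, distance_A = d)
}
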