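# Independent oracles used across tests.

# Connected components of a 3-D logical array under face (6-)connectivity,
# via an adjacency graph and igraph's component finder — independent of the
# package's frontier-BFS labeling.
floodFillOracle <- function(arr) {
  d <- dim(arr)
  cells <- which(arr)
  if (!length(cells)) return(list(sizes = integer(0), membership = integer(0)))
  pos <- arrayInd(cells, d)
  key <- function(p) paste(p[, 1], p[, 2], p[, 3])
  idx <- stats::setNames(seq_along(cells), key(pos))
  edges <- integer(0)
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (o in seq_len(3)) {
    nb <- sweep(pos, 2, offs[o, ], "+")
    ok <- nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    nbKey <- key(nb[ok, , drop = FALSE])
    hit <- !is.na(idx[nbKey])
    from <- which(ok)[hit]
    to <- idx[nbKey[hit]]
    edges <- c(edges, rbind(from, to))
  }
  g <- igraph::make_graph(edges, n = length(cells), directed = FALSE)
  comp <- igraph::components(g)
  list(sizes = as.integer(comp$csize), membership = comp$membership)
}

# FFT-periodogram oracle: dominant period (hours) of an hourly series.
fftPeakPeriod <- function(x, dtHours = 1) {
  n <- length(x)
  s <- Mod(stats::fft(x - mean(x)))^2
  k <- 2:floor(n / 2)
  kPeak <- k[which.max(s[k])]
  n * dtHours / (kPeak - 1)
}

# Circular mean resultant length.
resultantLength <- function(phi) {
  sqrt(mean(cos(phi))^2 + mean(sin(phi))^2)
}

# Small deterministic stream builder: explicit sessions of touch times (ms).
streamFromSessions <- function(sessions, id = "manual") {
  ev <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(timestampMs = c(s[1] - 50, s, s[length(s)] + 1000),
               type = c("screen_on", rep("touch", length(s)), "screen_off"))
  }))
  ev <- ev[order(ev$timestampMs), ]
  new("TouchEventStream", subjectId = id, events = ev,
      age = NULL, gender = NULL)
}
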