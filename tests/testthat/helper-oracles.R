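# independent oracles (kept free of the implementation paths they check)

# best ungapped segment over ALL diagonals by direct scanning (no seeding)
oracle_best_ungapped <- function(q, s, match = 1, mismatch = -2) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  best <- -Inf
  for (diag in (-(length(qc) - 1)):(length(sc) - 1)) {
    qi <- max(1, 1 - diag)
    si <- qi + diag
    len <- min(length(qc) - qi + 1, length(sc) - si + 1)
    if (len < 1) next
    sc_here <- ifelse(qc[qi:(qi + len - 1)] == sc[si:(si + len - 1)] &
                        qc[qi:(qi + len - 1)] %in% c("A", "C", "G", "T"),
                      match, mismatch)
    cur <- 0
    for (v in sc_here) {
      cur <- max(0, cur) + v
      if (cur > best) best <- cur
    }
  }
  best
}

# exact hypergeometric upper tail by enumerating every draw of size n
oracle_hyper_enum <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  carriers <- seq_len(K)  # which population members carry the term
  hits <- apply(draws, 2, function(d) sum(d %in% carriers))
  mean(hits >= k)
}

# closed-form simple OLS on log10 scale
oracle_loglog_ols <- function(x, y) {
  lx <- log10(x); ly <- log10(y)
  sxx <- sum((lx - mean(lx))^2)
  sxy <- sum((lx - mean(lx)) * (ly - mean(ly)))
  slope <- sxy / sxx
  intercept <- mean(ly) - slope * mean(lx)
  r2 <- sxy^2 / (sxx * sum((ly - mean(ly))^2))
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# pure-R exhaustive read mapping for tiny instances (independent of both
# C++ routes)
oracle_map_read <- function(read, consensus, max_mm = 2) {
  bits <- function(ch) {
    m <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L, W = 9L,
           K = 12L, M = 3L, B = 14L, D = 13L, H = 11L, V = 7L)
    b <- m[ch]
    b[is.na(b)] <- 0L
    b
  }
  rb <- bits(strsplit(read, "", fixed = TRUE)[[1]])
  out <- list()
  for (g in names(consensus)) {
    sb <- bits(strsplit(consensus[[g]], "", fixed = TRUE)[[1]])
    L <- length(rb)
    if (length(sb) < L) next
    for (p in 0:(length(sb) - L)) {
      mm <- sum(bitwAnd(rb, sb[(p + 1):(p + L)]) == 0L)
      if (mm <= max_mm)
        out[[length(out) + 1]] <- data.frame(gene = g, offset = p, mm = mm)
    }
  }
  if (length(out) == 0) return(NULL)
  d <- do.call(rbind, out)
  d[d$mm == min(d$mm), , drop = FALSE]
}
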