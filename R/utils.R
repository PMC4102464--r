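# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round-half-up to `digits` decimals (base round() is round-half-even, which
# would turn e.g. 93.45 into 93.4)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stop_arg <- function(...) stop(..., call. = FALSE)

# IUPAC code for a set of observed bases, and back
.iupac_codes <- c(
  "1" = "A", "2" = "C", "3" = "M", "4" = "G", "5" = "R", "6" = "S", "7" = "V",
  "8" = "T", "9" = "W", "10" = "Y", "11" = "H", "12" = "K", "13" = "D",
  "14" = "B", "15" = "N")
.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)

iupac_from_bits <- function(bits) {
  out <- rep("n", length(bits))
  nz <- bits > 0L
  out[nz] <- .iupac_codes[as.character(bits[nz])]
  out
}

is_ambiguity_bits <- function(bits) {
  bits > 0L & !(bits %in% c(1L, 2L, 4L, 8L))
}

# per-character base bitmask for an ACGT string; other characters -> 0
seq_bits <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  b <- .base_bits[ch]
  b[is.na(b)] <- 0L
  as.integer(b)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute a fraction of positions with a different random base; returns
# list(seq, n_sub)
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(list(seq = s, n_sub = 0L))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  list(seq = paste(ch, collapse = ""), n_sub = length(hit))
}

# proportion of identical characters between equal-length strings
seq_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}
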