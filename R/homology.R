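#' Karlin-Altschul parameters for an ungapped match/mismatch scheme
#'
#' `lambda` is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s(i,j)) = 1`, found by bracketed root-finding
#' to `|f| < 1e-10`. `K` follows the standard ungapped lattice approximation
#' (Karlin-Altschul 1990, as implemented in BLAST's ungapped statistics):
#' `K = delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-delta * lambda)))`
#' where `delta` is the score lattice span, `H` the relative entropy, and
#' `sigma` a Spitzer-type series over n-step score sums.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param composition base composition (length 4, sums to 1).
#' @param max_iter number of terms of the Spitzer series.
#' @return list with `lambda`, `K`, `H`.
#' @examples
#' karlin_altschul_params(1, -2)$lambda  # ~1.33
#' @export
karlin_altschul_params <- function(match = 1, mismatch = -2,
                                   composition = rep(0.25, 4),
                                   max_iter = 200) {
  if (abs(sum(composition) - 1) > 1e-8)
    stop_arg("composition must sum to 1")
  if (match <= 0 || mismatch >= 0)
    stop_arg("need match > 0 and mismatch < 0")
  pm <- sum(composition^2)
  es <- pm * match + (1 - pm) * mismatch
  if (es >= 0)
    stop_arg("expected score per aligned pair must be negative")
  f <- function(l) pm * exp(l * match) + (1 - pm) * exp(l * mismatch) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- uniroot(f, c(1e-12, hi), tol = 1e-14)$root
  stopifnot(abs(f(lambda)) < 1e-10)
  H <- lambda * (pm * match * exp(lambda * match) +
                 (1 - pm) * mismatch * exp(lambda * mismatch))

  # gcd of the two step sizes defines the score lattice
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  delta <- gcd2(abs(match), abs(mismatch))

  # sigma = sum_j (1/j) [ E(e^{lambda S_j}; S_j < 0) + P(S_j >= 0) ]
  lo <- mismatch * max_iter
  scores <- lo:(match * max_iter)
  p <- numeric(length(scores))           # distribution of S_j over `scores`
  p[scores == 0] <- 1
  sigma <- 0
  step_lo <- which(scores == mismatch) - which(scores == 0)
  step_hi <- which(scores == match) - which(scores == 0)
  for (j in seq_len(max_iter)) {
    pn <- numeric(length(p))
    idx <- seq_along(p)
    src <- idx - step_hi
    ok <- src >= 1 & src <= length(p)
    pn[idx[ok]] <- pn[idx[ok]] + pm * p[src[ok]]
    src <- idx - step_lo
    ok <- src >= 1 & src <= length(p)
    pn[idx[ok]] <- pn[idx[ok]] + (1 - pm) * p[src[ok]]
    p <- pn
    neg <- scores < 0
    term <- (sum(p[neg] * exp(lambda * scores[neg])) + sum(p[!neg])) / j
    sigma <- sigma + term
    if (term < 1e-12) break
  }
  K <- delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-delta * lambda)))
  list(lambda = lambda, K = K, H = H)
}

#' Scoring scheme for the seeded nucleotide search
#'
#' Bundles the match/mismatch rewards, the Karlin-Altschul parameters they
#' imply, and the total length of the searched database (the standard BLAST
#' convention for the `n` of `E = K m n exp(-lambda S)`).
#'
#' @inheritParams karlin_altschul_params
#' @param db_len total database length in bp.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, db_len,
                           composition = rep(0.25, 4)) {
  ka <- karlin_altschul_params(match, mismatch, composition)
  structure(list(match = match, mismatch = mismatch, db_len = db_len,
                 lambda = ka$lambda, K = ka$K, H = ka$H),
            class = "scoring_scheme")
}

#' Ungapped E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of ungapped
#' segments scoring at least `S` between a random query of length `m` and a
#' database of total length `n`.
#'
#' @param score alignment score (>= 0).
#' @param m query length.
#' @param n database total length.
#' @param lambda,K Karlin-Altschul parameters.
#' @return numeric E-value.
#' @examples
#' evalue(60, 700, 1e7, lambda = 1.33, K = 0.62)
#' @export
evalue <- function(score, m, n, lambda, K) {
  if (any(score < 0)) stop_arg("score must be >= 0")
  K * m * n * exp(-lambda * score)
}

#' Seeded ungapped search of queries against subjects
#'
#' Finds, for every query/subject pair sharing at least one exact word of
#' `word_size`, the maximal-scoring ungapped segment over all shared-word
#' diagonals (Kadane's algorithm per diagonal). N counts as a mismatch.
#' Output follows a blast outfmt-6-like column order; coordinates are
#' 0-based half-open.
#'
#' @param queries,subjects named character vectors of sequences.
#' @param scheme a [scoring_scheme()]; its `db_len` feeds the E-value.
#' @param word_size seed word length (>= 8).
#' @return data.frame: `query`, `subject`, `score`, `identity`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`.
#' @export
search_hits <- function(queries, subjects, scheme, word_size = 11) {
  if (word_size < 8) stop_arg("word_size must be >= 8")
  if (any(nchar(queries) == 0) || any(nchar(subjects) == 0))
    stop_arg("empty sequence")
  if (is.null(names(queries))) names(queries) <- sprintf("q%d", seq_along(queries))
  if (is.null(names(subjects))) names(subjects) <- sprintf("s%d", seq_along(subjects))
  raw <- cpp_search_hits(unname(queries), unname(subjects), as.integer(word_size),
                         as.integer(scheme$match), as.integer(scheme$mismatch))
  data.frame(
    query = names(queries)[raw$query],
    subject = names(subjects)[raw$subject],
    score = raw$score,
    identity = ifelse(raw$length > 0, raw$matches / raw$length, 0),
    q_start = raw$q_start, q_end = raw$q_end,
    s_start = raw$s_start, s_end = raw$s_end,
    evalue = evalue(raw$score, nchar(queries)[raw$query], scheme$db_len,
                    scheme$lambda, scheme$K),
    stringsAsFactors = FALSE)
}

#' Best ungapped hit between one query and one subject
#'
#' @inheritParams search_hits
#' @param query,subject single sequences.
#' @return one-row hit data.frame, or `NULL` when no word is shared.
#' @export
seed_and_extend <- function(query, subject, scheme, word_size = 11) {
  if (nchar(query) == 0 || nchar(subject) == 0) stop_arg("empty sequence")
  h <- search_hits(c(q = unname(query)), c(s = unname(subject)), scheme,
                   word_size)
  if (nrow(h) == 0) return(NULL)
  h[1, , drop = FALSE]
}

# best hit per query: highest score, then lowest evalue, then lexicographic
# subject id (deterministic tie-break)
best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$query, -hits$score, hits$evalue, hits$subject)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query), , drop = FALSE]
}

#' Reciprocal best-hit ortholog assignment
#'
#' A contig is retained for gene `R` iff (i) `R` is the contig's best hit
#' with `E < threshold`, (ii) the reverse search assigns `R`'s best hit to
#' that same contig, also with `E < threshold`. Everything else is dropped.
#' Ties in best-hit score break deterministically by (lower E-value, then
#' lexicographic subject id).
#'
#' @param forward_hits hit table from [search_hits()] with contigs as
#'   queries and reference genes as subjects.
#' @param reverse_hits hit table with genes as queries, contigs as subjects.
#' @param threshold E-value cutoff applied in both directions.
#' @return data.frame: `contig_id`, `gene_id`, `evalue_fwd`, `evalue_rev`.
#' @export
reciprocal_best_hits <- function(forward_hits, reverse_hits,
                                 threshold = 1e-10) {
  fb <- best_hits(forward_hits)
  rb <- best_hits(reverse_hits)
  fb <- fb[fb$evalue < threshold, , drop = FALSE]
  rb <- rb[rb$evalue < threshold, , drop = FALSE]
  if (nrow(fb) == 0 || nrow(rb) == 0)
    return(data.frame(contig_id = character(), gene_id = character(),
                      evalue_fwd = numeric(), evalue_rev = numeric(),
                      stringsAsFactors = FALSE))
  m <- match(fb$subject, rb$query)
  keep <- !is.na(m) & rb$subject[m] == fb$query
  out <- data.frame(contig_id = fb$query[keep], gene_id = fb$subject[keep],
                    evalue_fwd = fb$evalue[keep],
                    evalue_rev = rb$evalue[m[keep]],
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$contig_id), , drop = FALSE]
}
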