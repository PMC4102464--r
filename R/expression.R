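#' Reads per kilobase per million uniquely mapped reads
#'
#' `RPKM = count / ((length/1000) * (total_unique/1e6))`. Gene length is the
#' non-n consensus length, since n-padded positions cannot recruit reads.
#'
#' @param count unique read count (vectorized).
#' @param gene_length_bp non-n gene length in bp (> 0).
#' @param total_unique_mapped total uniquely mapped reads in the sample
#'   (> 0).
#' @return numeric RPKM.
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, gene_length_bp, total_unique_mapped) {
  if (any(gene_length_bp <= 0)) stop_arg("gene_length_bp must be > 0")
  if (any(total_unique_mapped <= 0)) stop_arg("total_unique_mapped must be > 0")
  count / ((gene_length_bp / 1000) * (total_unique_mapped / 1e6))
}

#' Expression matrix from per-sample unique counts
#'
#' @param counts genes x samples matrix of unique read counts.
#' @param gene_lengths named or positionally matched non-n gene lengths.
#' @return object of class `expression_matrix`: list with `counts`, `rpkm`,
#'   `gene_lengths`, `total_unique` per sample.
#' @export
expression_matrix <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts)))
    gene_lengths <- gene_lengths[rownames(counts)]
  total <- colSums(counts)
  rk <- sweep(counts / (gene_lengths / 1000), 2, total / 1e6, "/")
  structure(list(counts = counts, rpkm = rk,
                 gene_lengths = gene_lengths, total_unique = total),
            class = "expression_matrix")
}

#' Remove genes with very low counts in any sample
#'
#' A gene is retained only when every sample has at least `min_reads` unique
#' reads mapped; low counts make fold-change estimates spurious.
#'
#' @param counts genes x samples count matrix.
#' @param min_reads minimum unique reads required in each sample.
#' @return character vector (or integer indices when unnamed) of retained
#'   genes.
#' @export
low_count_filter <- function(counts, min_reads = 10) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts >= min_reads) == ncol(counts)
  if (!is.null(rownames(counts))) rownames(counts)[keep] else which(keep)
}

#' Relative difference between purple and white expression
#'
#' `RD = (P - W) / max(P, W)`, a signed statistic bounded in \[-1, 1\];
#' positive when purple exceeds white, and antisymmetric under swapping the
#' morphs.
#'
#' @param p,w RPKM of the purple and white sample (vectorized).
#' @return numeric RD.
#' @examples
#' relative_difference(200, 100)  # 0.5
#' @export
relative_difference <- function(p, w) {
  mx <- pmax(p, w)
  if (any(mx <= 0)) stop_arg("relative difference undefined when both zero")
  (p - w) / mx
}

#' Between-population consistency of the relative difference
#'
#' Signed difference of the two populations' RD values; zero means the two
#' populations agree exactly in direction and magnitude.
#'
#' @param rd_pop1,rd_pop2 RD in the two populations.
#' @return numeric consistency in \[-2, 2\].
#' @export
consistency <- function(rd_pop1, rd_pop2) rd_pop1 - rd_pop2

#' Thresholds of the differential-expression call
#'
#' @param rd_cutoff absolute mean-RD threshold for differential expression.
#' @param consistency_cutoff absolute consistency threshold; with RD values
#'   uniform on \[-1, 1\] the default keeps the most consistent quartile.
#' @param min_reads low-count filter threshold.
#' @return named list of thresholds.
#' @export
de_thresholds <- function(rd_cutoff = 0.5, consistency_cutoff = 0.25,
                          min_reads = 10) {
  stopifnot(rd_cutoff > 0, consistency_cutoff > 0, min_reads > 0)
  list(rd_cutoff = rd_cutoff, consistency_cutoff = consistency_cutoff,
       min_reads = min_reads)
}

#' Classify consistently differentially expressed genes
#'
#' The ranking statistic is the mean RD over the two population pairs.
#' `P>W` requires mean RD above `rd_cutoff` with |consistency| inside
#' `consistency_cutoff`; `W>P` is the mirror image; genes past the RD cutoff
#' but outside the consistency band are `inconsistent`; the rest are
#' `not_DE`.
#'
#' @param rpkm_matrix genes x samples RPKM matrix with the four sample
#'   columns of [pipeline_samples()] (purple/white in each population).
#' @param thresholds a [de_thresholds()] list.
#' @return data.frame (one row per gene): `gene_id`, `rd_pop1`, `rd_pop2`,
#'   `mean_rd`, `consistency`, `fold_pop1`, `fold_pop2`, `class`.
#' @export
classify_differential <- function(rpkm_matrix,
                                  thresholds = de_thresholds()) {
  s <- pipeline_samples()
  stopifnot(all(s %in% colnames(rpkm_matrix)))
  rd1 <- relative_difference(rpkm_matrix[, "SR_P"], rpkm_matrix[, "SR_W"])
  rd2 <- relative_difference(rpkm_matrix[, "MS_P"], rpkm_matrix[, "MS_W"])
  mrd <- (rd1 + rd2) / 2
  cons <- consistency(rd1, rd2)
  cl <- rep("not_DE", nrow(rpkm_matrix))
  de <- abs(mrd) > thresholds$rd_cutoff
  consistent <- abs(cons) < thresholds$consistency_cutoff
  cl[de & !consistent] <- "inconsistent"
  cl[de & consistent & mrd > 0] <- "P>W"
  cl[de & consistent & mrd < 0] <- "W>P"
  data.frame(
    gene_id = rownames(rpkm_matrix),
    rd_pop1 = rd1, rd_pop2 = rd2, mean_rd = mrd, consistency = cons,
    fold_pop1 = rpkm_matrix[, "SR_P"] / rpkm_matrix[, "SR_W"],
    fold_pop2 = rpkm_matrix[, "MS_P"] / rpkm_matrix[, "MS_W"],
    class = cl, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-position purple/white fold-change profile
#'
#' Windowed depth ratios along a gene, with a pseudocount guarding against
#' zero white depth; the gene-average fold change is the ratio of total
#' depths (equivalently of mean depths).
#'
#' @param depth_p,depth_w equal-length per-position unique-read depth
#'   vectors for the purple and white sample.
#' @param window window width in bp for the ratio series.
#' @param pseudocount added to both windowed depths.
#' @return list with `profile` (data.frame: `position` (window center),
#'   `depth_p`, `depth_w`, `ratio`) and `gene_average`.
#' @export
fold_change_profile <- function(depth_p, depth_w, window = 25,
                                pseudocount = 1) {
  if (length(depth_p) != length(depth_w))
    stop_arg("depth vectors must have equal length")
  n <- length(depth_p)
  starts <- seq(1, n, by = window)
  dp <- vapply(starts, function(s) sum(depth_p[s:min(s + window - 1, n)]),
               numeric(1))
  dw <- vapply(starts, function(s) sum(depth_w[s:min(s + window - 1, n)]),
               numeric(1))
  list(profile = data.frame(
         position = pmin(starts + floor(window / 2), n),
         depth_p = dp, depth_w = dw,
         ratio = (dp + pseudocount) / (dw + pseudocount)),
       gene_average = (sum(depth_p) + pseudocount) /
                      (sum(depth_w) + pseudocount))
}
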