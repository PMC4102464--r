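#' Anchor a gene's contigs onto the reference coordinate frame
#'
#' Each contig is placed by the diagonal of its best ungapped hit to the
#' reference gene (contigs and reference are collinear transcript sequences,
#' so a single offset suffices). Contig termini extending past the reference
#' (UTR overhangs) extend the column frame; the reference row itself is not
#' part of the consensus.
#'
#' @param gene_id gene identifier.
#' @param contigs data.frame with columns `contig_id`, `sample`, `sequence`,
#'   already assigned to this gene by the homology module.
#' @param reference the reference gene row (`sequence`, `cds_start`,
#'   `cds_end`).
#' @param scheme a [scoring_scheme()].
#' @param word_size seed word length.
#' @param kmer kmer label carried through to the consensus record.
#' @return object of class `anchored_alignment`: list with `gene_id`,
#'   `kmer`, `frame_start` (offset of column 1 in reference coordinates, may
#'   be negative), `frame_len`, `ref_len`, `cds_start`, `cds_end`, and
#'   `rows` (data.frame `contig_id`, `sample`, `offset`, `sequence`).
#' @export
anchor_contigs <- function(gene_id, contigs, reference, scheme,
                           word_size = 11, kmer = NA_integer_) {
  if (nrow(contigs) < 1) stop_arg("no contigs supplied for ", gene_id)
  offs <- integer(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    hit <- seed_and_extend(contigs$sequence[i], reference$sequence, scheme,
                           word_size)
    if (is.null(hit))
      stop_arg("contig ", contigs$contig_id[i], " has no hit to ", gene_id,
               " (pipeline ordering violation)")
    offs[i] <- hit$s_start - hit$q_start
  }
  build_frame(gene_id, contigs, offs, reference, kmer)
}

# assemble the anchored_alignment object from per-contig reference offsets
build_frame <- function(gene_id, contigs, offs, reference, kmer) {
  ref_len <- nchar(reference$sequence)
  frame_start <- min(0L, offs)
  frame_end <- max(ref_len, max(offs + nchar(contigs$sequence)))
  structure(list(
    gene_id = gene_id, kmer = kmer,
    frame_start = as.integer(frame_start),
    frame_len = as.integer(frame_end - frame_start),
    ref_len = as.integer(ref_len),
    cds_start = reference$cds_start, cds_end = reference$cds_end,
    rows = data.frame(contig_id = contigs$contig_id,
                      sample = contigs$sample,
                      offset = as.integer(offs),
                      sequence = contigs$sequence,
                      stringsAsFactors = FALSE)),
    class = "anchored_alignment")
}

#' Build an IUPAC-ambiguity consensus from an anchored alignment
#'
#' Per column: a single observed base is reported as-is; two or more
#' distinct bases become the IUPAC code for exactly the observed base set;
#' columns covered by no contig become `n`. The ambiguity fraction is the
#' share of non-n characters that are ambiguity codes (n's excluded from the
#' denominator). Coverage of a column by a gap in one contig but a base in
#' another uses the bases present (missing data, not a fifth state).
#'
#' @param aln an [anchor_contigs()] result.
#' @return object of class `consensus_record`: list with `gene_id`, `kmer`,
#'   `sequence`, `ambiguity_fraction`, `assembled_length` (non-n count),
#'   `frame_start`, `ref_len`, `cds_start`, `cds_end`,
#'   `cds_coverage_fraction`, `utr5_extra_bp`, `utr3_extra_bp`.
#' @export
build_consensus <- function(aln) {
  stopifnot(inherits(aln, "anchored_alignment"))
  pres <- integer(aln$frame_len)
  for (i in seq_len(nrow(aln$rows))) {
    b <- seq_bits(aln$rows$sequence[i])
    cols <- aln$rows$offset[i] - aln$frame_start + seq_along(b)
    keep <- b > 0L
    pres[cols[keep]] <- bitwOr(pres[cols[keep]], b[keep])
  }
  chars <- iupac_from_bits(pres)
  nonn <- sum(pres > 0L)
  amb <- sum(is_ambiguity_bits(pres))
  cds_cols <- (aln$cds_start - aln$frame_start + 1L):(aln$cds_end - aln$frame_start)
  cds_cov <- sum(pres[cds_cols] > 0L) / (aln$cds_end - aln$cds_start)
  before <- seq_len(aln$cds_start - aln$frame_start)
  after_start <- aln$cds_end - aln$frame_start + 1L
  after <- if (after_start <= aln$frame_len) after_start:aln$frame_len else integer(0)
  structure(list(
    gene_id = aln$gene_id, kmer = aln$kmer,
    sequence = paste(chars, collapse = ""),
    ambiguity_fraction = if (nonn > 0) amb / nonn else 0,
    assembled_length = as.integer(nonn),
    frame_start = aln$frame_start, ref_len = aln$ref_len,
    cds_start = aln$cds_start, cds_end = aln$cds_end,
    cds_coverage_fraction = cds_cov,
    utr5_extra_bp = as.integer(sum(pres[before] > 0L)),
    utr3_extra_bp = as.integer(sum(pres[after] > 0L))),
    class = "consensus_record")
}

#' Choose the per-gene kmer assembly
#'
#' Among the per-kmer consensus records whose ambiguity fraction is below
#' the threshold, the longest assembled (non-n) record wins; length ties go
#' to the smaller kmer (deterministic, and consistent with small kmers
#' dominating real multi-kmer transcriptomes). When no record passes, the
#' gene is emitted for QC triage (`NULL` returned).
#'
#' @param records list of [build_consensus()] records for one gene.
#' @param ambiguity_threshold maximum tolerated ambiguity fraction
#'   (default 0.019, the expected ceiling of intraspecific variation).
#' @return the chosen `consensus_record`, or `NULL` when all fail.
#' @export
select_kmer <- function(records, ambiguity_threshold = 0.019) {
  if (length(records) == 0) stop_arg("no consensus records supplied")
  amb <- vapply(records, `[[`, numeric(1), "ambiguity_fraction")
  ok <- which(amb < ambiguity_threshold)
  if (length(ok) == 0) return(NULL)
  len <- vapply(records[ok], `[[`, integer(1), "assembled_length")
  km <- vapply(records[ok], `[[`, integer(1), "kmer")
  pick <- ok[order(-len, km)][1]
  records[[pick]]
}

# identity between two anchored rows over a set of frame columns they share;
# returns NA when overlap < min_overlap
row_identity <- function(aln, i, j, cols, min_overlap = 20L) {
  a <- seq_bits(aln$rows$sequence[i])
  b <- seq_bits(aln$rows$sequence[j])
  ca <- aln$rows$offset[i] - aln$frame_start + seq_along(a)
  cb <- aln$rows$offset[j] - aln$frame_start + seq_along(b)
  shared <- intersect(intersect(ca, cb), cols)
  if (length(shared) < min_overlap) return(NA_real_)
  mean(a[match(shared, ca)] == b[match(shared, cb)])
}

# identity of one contig row to the reference over frame columns `cols`
row_ref_identity <- function(aln, i, reference_seq, cols, min_overlap = 20L) {
  a <- seq_bits(aln$rows$sequence[i])
  ca <- aln$rows$offset[i] - aln$frame_start + seq_along(a)
  rcols <- (1L - aln$frame_start):(aln$ref_len - aln$frame_start)
  rb <- seq_bits(reference_seq)
  shared <- intersect(intersect(ca, rcols), cols)
  if (length(shared) < min_overlap) return(NA_real_)
  mean(a[match(shared, ca)] == rb[shared + aln$frame_start])
}

#' Triage an alignment whose consensus exceeds the ambiguity threshold
#'
#' Repairs are attempted in order of their frequency in practice:
#' (a) misalignment: each contig is re-anchored by a fresh seeded alignment
#' to the reference and the consensus rebuilt; (b) UTR-divergent paralogs:
#' if contigs agree >= 98% in CDS columns but < 90% in UTR columns they are
#' assumed to be co-expressed paralogs, kept, and the record labeled;
#' (c) divergent contigs: any contig whose CDS identity to the reference
#' falls more than 5 points below the best contig's is removed and the
#' consensus rebuilt. A record that still fails the threshold after repair
#' is dropped.
#'
#' @param aln the [anchor_contigs()] alignment.
#' @param record its [build_consensus()] record
#'   (`ambiguity_fraction >= threshold`).
#' @param reference the reference gene row.
#' @param scheme a [scoring_scheme()].
#' @param ambiguity_threshold QC threshold on the ambiguity fraction.
#' @param word_size seed word length for re-anchoring.
#' @return list with `outcome` (data.frame: `gene_id`, `category`,
#'   `contigs_removed`), `record` (repaired `consensus_record`, or `NULL`
#'   when the gene is dropped), and `alignment` (possibly repaired).
#' @export
triage_high_ambiguity <- function(aln, record, reference, scheme,
                                  ambiguity_threshold = 0.019,
                                  word_size = 11) {
  stopifnot(record$ambiguity_fraction >= ambiguity_threshold)
  out <- function(category, removed, rec, a)
    list(outcome = data.frame(gene_id = aln$gene_id, category = category,
                              contigs_removed = paste(removed, collapse = ","),
                              stringsAsFactors = FALSE),
         record = rec, alignment = a)

  # (a) re-anchor every contig
  re <- try(anchor_contigs(aln$gene_id, data.frame(
    contig_id = aln$rows$contig_id, sample = aln$rows$sample,
    sequence = aln$rows$sequence, stringsAsFactors = FALSE),
    reference, scheme, word_size, kmer = aln$kmer), silent = TRUE)
  if (!inherits(re, "try-error") && !identical(re$rows$offset, aln$rows$offset)) {
    rec2 <- build_consensus(re)
    if (rec2$ambiguity_fraction < ambiguity_threshold)
      return(out("misalignment", character(0), rec2, re))
    aln <- re
    record <- rec2
  }

  cds_cols <- (aln$cds_start - aln$frame_start + 1L):(aln$cds_end - aln$frame_start)
  utr_cols <- setdiff(seq_len(aln$frame_len), cds_cols)
  nr <- nrow(aln$rows)

  # (b) paralog signature: conserved CDS, divergent UTR between contigs
  if (nr >= 2) {
    pairs <- utils::combn(nr, 2)
    cdsid <- apply(pairs, 2, function(p) row_identity(aln, p[1], p[2], cds_cols))
    utrid <- apply(pairs, 2, function(p) row_identity(aln, p[1], p[2], utr_cols))
    have <- !is.na(cdsid)
    if (any(have) && all(cdsid[have] >= 0.98) &&
        any(!is.na(utrid) & utrid < 0.90))
      return(out("utr_divergent_paralog", character(0), record, aln))
  }

  # (c) remove contigs with CDS identity > 5 points below the best
  refid <- vapply(seq_len(nr), function(i)
    row_ref_identity(aln, i, reference$sequence, cds_cols), numeric(1))
  if (any(!is.na(refid))) {
    best <- max(refid, na.rm = TRUE)
    drop <- which(!is.na(refid) & refid < best - 0.05)
    if (length(drop) > 0 && length(drop) < nr) {
      keep <- setdiff(seq_len(nr), drop)
      a2 <- build_frame(aln$gene_id,
                        data.frame(contig_id = aln$rows$contig_id[keep],
                                   sample = aln$rows$sample[keep],
                                   sequence = aln$rows$sequence[keep],
                                   stringsAsFactors = FALSE),
                        aln$rows$offset[keep], reference, aln$kmer)
      rec2 <- build_consensus(a2)
      if (rec2$ambiguity_fraction < ambiguity_threshold)
        return(out("divergent_contig_removed", aln$rows$contig_id[drop],
                   rec2, a2))
    }
  }
  out("misalignment", character(0), NULL, aln)  # unresolvable: gene dropped
}

#' Coverage statistics of a consensus record in the reference frame
#'
#' Percent CDS coverage is `100 * (non-n columns within the CDS) / (CDS
#' length)` rounded half-up to one decimal for reporting; the UTR extras are
#' non-n columns outside the CDS bounds.
#'
#' @param record a [build_consensus()] record.
#' @return data.frame: `gene_id`, `cds_length`, `assembled_length`,
#'   `percent_cds_coverage`, `utr5_extra_bp`, `utr3_extra_bp`.
#' @export
coverage_stats <- function(record) {
  data.frame(
    gene_id = record$gene_id,
    cds_length = record$cds_end - record$cds_start,
    assembled_length = record$assembled_length,
    percent_cds_coverage = round_half_up(100 * record$cds_coverage_fraction, 1),
    utr5_extra_bp = record$utr5_extra_bp,
    utr3_extra_bp = record$utr3_extra_bp,
    stringsAsFactors = FALSE)
}

#' Append an externally characterized sequence to a transcriptome
#'
#' Used when a gene missed by the E-value filter has a previously sequenced
#' version that should still be carried through expression analysis.
#'
#' @param transcriptome named character vector of consensus sequences.
#' @param id,sequence the record to append.
#' @return the extended named character vector.
#' @export
append_external_sequence <- function(transcriptome, id, sequence) {
  if (id %in% names(transcriptome))
    stop_arg("duplicate id: ", id)
  c(transcriptome, setNames(sequence, id))
}

#' Consensus directly from a haplotype pair
#'
#' Collapses the two haplotypes of a gene into one IUPAC consensus (the
#' idealized full-coverage assembly), bypassing the contig stage. Useful for
#' expression-recovery experiments where assembly is not under study.
#'
#' @param hap1,hap2 equal-length haplotype sequences.
#' @return character consensus with IUPAC codes at heterozygous sites.
#' @export
consensus_from_haplotypes <- function(hap1, hap2) {
  b1 <- seq_bits(hap1)
  b2 <- seq_bits(hap2)
  stopifnot(length(b1) == length(b2))
  paste(iupac_from_bits(bitwOr(b1, b2)), collapse = "")
}
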