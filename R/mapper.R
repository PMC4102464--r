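#' Build the hash index over an IUPAC-aware consensus transcriptome
#'
#' Every reference position starting an h-mer free of `n` is indexed;
#' ambiguity codes are expanded so any compatible read word retrieves the
#' position. A secondary index at the pigeonhole rescue width (read length
#' divided by allowed mismatches + 1) makes the seeded search provably
#' equivalent to an exhaustive scan at every mismatch level.
#'
#' @param consensus named character vector of reference sequences (IUPAC
#'   codes and `n` permitted).
#' @param h seed hash length (>= 8).
#' @param rescue_w rescue chunk width; default 13 suits 40 bp reads with 2
#'   allowed mismatches.
#' @param max_ambig windows with more ambiguity codes than this are not
#'   expanded (guards against pathological references; irrelevant below the
#'   1.9% ambiguity QC gate).
#' @return object of class `hash_index`.
#' @export
build_hash_index <- function(consensus, h = 14, rescue_w = 13,
                             max_ambig = 12) {
  if (h < 8) stop_arg("hash length must be >= 8")
  if (is.null(names(consensus))) stop_arg("consensus sequences must be named")
  ptr <- cpp_build_index(names(consensus), unname(consensus), as.integer(h),
                         as.integer(rescue_w), as.integer(max_ambig))
  structure(list(ptr = ptr, h = as.integer(h),
                 rescue_w = as.integer(rescue_w),
                 gene_names = names(consensus),
                 gene_lengths = nchar(consensus)),
            class = "hash_index")
}

#' @export
print.hash_index <- function(x, ...) {
  st <- cpp_index_stats(x$ptr)
  cat(sprintf("hash_index: %d genes, h = %d, %d indexed positions\n",
              st$n_genes, st$h, st$n_positions))
  invisible(x)
}

#' Number of indexed h-mer start positions
#' @param index a [build_hash_index()] object.
#' @return integer count of indexed reference positions.
#' @export
index_positions <- function(index) cpp_index_stats(index$ptr)$n_positions

#' Look up an exact h-mer in the index
#' @param index a [build_hash_index()] object.
#' @param word ACGT word of length `h`.
#' @return data.frame of compatible placements (`gene_id`, `offset`).
#' @export
index_lookup <- function(index, word) {
  r <- cpp_index_lookup(index$ptr, word)
  data.frame(gene_id = index$gene_names[r$gene], offset = r$offset,
             stringsAsFactors = FALSE)
}

#' Map reads and classify their fates
#'
#' Reads are seeded with every overlapping h-mer, candidate placements are
#' verified over the full read with IUPAC-compatible mismatch counting (a
#' read base contained in the reference code's base set is a match; `n`
#' never matches), and only the minimal-mismatch placement set is kept.
#' Exactly one placement makes the read unique; two or more anywhere (even
#' the same gene) make it multi-mapped and excluded; reads exceeding the
#' mismatch cap everywhere are mismatch-filtered; reads with no candidate
#' placement (or shorter than h) are unseeded.
#'
#' @param reads character vector of reads (FASTQ sequences).
#' @param index a [build_hash_index()] object.
#' @param max_mismatch mismatch cap per placement.
#' @param depth also accumulate per-gene per-position unique-read depth.
#' @return object of class `mapping_summary`: list with `totals` (named
#'   vector: generated, aligned, unique, multi, filtered, unseeded),
#'   `gene_counts` (unique reads per gene), `placements` (data.frame:
#'   `status`, `gene_id`, `offset`, `mismatches`), and `depth` (list of
#'   per-gene integer vectors, when requested).
#' @export
map_reads <- function(reads, index, max_mismatch = 2, depth = FALSE) {
  stopifnot(inherits(index, "hash_index"))
  r <- cpp_map_reads(index$ptr, unname(reads), as.integer(max_mismatch),
                     isTRUE(depth))
  status <- factor(c("unique", "multi", "filtered", "unseeded")[r$status + 1],
                   levels = c("unique", "multi", "filtered", "unseeded"))
  totals <- c(generated = length(reads),
              aligned = sum(status %in% c("unique", "multi")),
              unique = sum(status == "unique"),
              multi = sum(status == "multi"),
              filtered = sum(status == "filtered"),
              unseeded = sum(status == "unseeded"))
  structure(list(
    totals = totals,
    gene_counts = r$gene_counts,
    placements = data.frame(
      read_id = if (is.null(names(reads))) seq_along(reads) else names(reads),
      status = status,
      gene_id = ifelse(is.na(r$gene), NA_character_,
                       index$gene_names[r$gene]),
      offset = r$offset, mismatches = r$mismatches,
      stringsAsFactors = FALSE),
    depth = if (isTRUE(depth)) r$depth else NULL),
    class = "mapping_summary")
}

#' @export
print.mapping_summary <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0("mapping_summary: %d reads; %d aligned (%.1f%%), ",
                     "%d unique (%.1f%%), %d multi, %d filtered, %d unseeded\n"),
              t["generated"], t["aligned"], 100 * t["aligned"] / t["generated"],
              t["unique"], 100 * t["unique"] / t["generated"],
              t["multi"], t["filtered"], t["unseeded"]))
  invisible(x)
}

#' Exhaustive-scan mapping oracle
#'
#' Independent brute-force route: every position of every reference gene is
#' tried for every read. Intended for validating [map_reads()] on small
#' instances; identical classification semantics.
#'
#' @inheritParams map_reads
#' @param consensus named character vector of reference sequences.
#' @return data.frame: `status`, `gene_id`, `offset`, `mismatches`.
#' @export
map_reads_bruteforce <- function(reads, consensus, max_mismatch = 2) {
  r <- cpp_map_reads_bruteforce(names(consensus), unname(consensus),
                                unname(reads), as.integer(max_mismatch))
  data.frame(
    read_id = if (is.null(names(reads))) seq_along(reads) else names(reads),
    status = c("unique", "multi", "none")[r$status + 1],
    gene_id = ifelse(is.na(r$gene), NA_character_, names(consensus)[r$gene]),
    offset = r$offset, mismatches = r$mismatches,
    stringsAsFactors = FALSE)
}

#' Read-fate percentages
#'
#' Each category as a percentage of reads generated, rounded half-up to one
#' decimal, as reported in mapping summary tables.
#'
#' @param summary a `mapping_summary`, or a named vector/list with entries
#'   `generated`, `aligned`, `multi`, `unique` (and optionally `filtered`).
#' @return named numeric vector of percentages.
#' @examples
#' read_fate_percentages(c(generated = 86.35e6, aligned = 37.27e6,
#'                         multi = 4.11e6, unique = 33.16e6))
#' @export
read_fate_percentages <- function(summary) {
  t <- if (inherits(summary, "mapping_summary")) summary$totals
       else unlist(summary)
  if (is.na(t["generated"]) || t["generated"] <= 0)
    stop_arg("generated read count must be positive")
  cats <- intersect(c("aligned", "filtered", "multi", "unique"), names(t))
  setNames(round_half_up(100 * t[cats] / t[["generated"]], 1), cats)
}

#' Write unique placements as a minimal SAM file
#'
#' Emits the eleven mandatory SAM columns (header included) for
#' interoperability with samtools-based tooling: uniquely mapped reads get
#' an ungapped `<len>M` CIGAR against their consensus gene; everything else
#' is recorded as unmapped.
#'
#' @param summary a [map_reads()] `mapping_summary`.
#' @param reads the named read vector that was mapped.
#' @param index the [build_hash_index()] used (for reference lengths).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(summary, reads, index, path) {
  stopifnot(inherits(summary, "mapping_summary"))
  pl <- summary$placements
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", index$gene_names,
                   index$gene_lengths))
  unique_hit <- pl$status == "unique"
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                 pl$read_id,
                 ifelse(unique_hit, 0L, 4L),
                 ifelse(unique_hit, pl$gene_id, "*"),
                 ifelse(unique_hit, pl$offset + 1L, 0L),
                 ifelse(unique_hit, 255L, 0L),
                 ifelse(unique_hit, paste0(nchar(reads), "M"), "*"),
                 unname(reads))
  writeLines(c(hdr, rec), path)
  invisible(path)
}
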