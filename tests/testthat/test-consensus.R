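ref_row <- function(seq, cds_start, cds_end, id = "G1") {
  data.frame(gene_id = id, sequence = seq, cds_start = cds_start,
             cds_end = cds_end, strand = "+", stringsAsFactors = FALSE)
}
ctg_df <- function(seqs, ids = sprintf("c%d", seq_along(seqs)),
                   sample = "P") {
  data.frame(contig_id = ids, sample = sample, sequence = seqs,
             stringsAsFactors = FALSE)
}

test_that("anchor_contigs recovers offsets and extends the frame", {
  sch <- scoring_scheme(1, -2, db_len = 1000)
  g <- rand_dna(300, seed = 61)
  ref <- ref_row(g, 0L, 300L)

  # contig identical to the CDS: one row, offset 0, frame = reference
  aln <- anchor_contigs("G1", ctg_df(g), ref, sch)
  expect_equal(nrow(aln$rows), 1)
  expect_equal(aln$rows$offset, 0L)
  expect_equal(aln$frame_len, 300L)

  # contig with a 54 bp 5' overhang extends the frame by 54 columns
  over <- paste0(rand_dna(54, seed = 62), g)
  aln2 <- anchor_contigs("G1", ctg_df(over), ref, sch)
  expect_equal(aln2$frame_start, -54L)
  expect_equal(aln2$frame_len, 354L)
  rec2 <- build_consensus(aln2)
  expect_equal(rec2$utr5_extra_bp, 54L)

  # two contigs overlapping by 100 bp occupy shared columns (offset oracle)
  c1 <- substr(g, 1, 180)
  c2 <- substr(g, 81, 300)
  aln3 <- anchor_contigs("G1", ctg_df(c(c1, c2)), ref, sch)
  expect_equal(sort(aln3$rows$offset), c(0L, 80L))
  rec3 <- build_consensus(aln3)
  expect_equal(rec3$assembled_length, 300L)

  expect_error(
    anchor_contigs("G1", ctg_df(paste(rep("AC", 50), collapse = "")), ref,
                   sch), "no hit")
})

test_that("build_consensus applies the ambiguity and n-padding rules", {
  sch <- scoring_scheme(1, -2, db_len = 1000)
  g <- rand_dna(200, seed = 63)
  ref <- ref_row(g, 0L, 200L)
  aln <- anchor_contigs("G1", ctg_df(c(g, g)), ref, sch)
  rec <- build_consensus(aln)
  expect_identical(rec$sequence, g)
  expect_equal(rec$ambiguity_fraction, 0)

  # one A-vs-G disagreement out of 200 -> R, fraction 1/200
  ch <- strsplit(g, "")[[1]]
  pos <- which(ch == "A")[1]
  ch[pos] <- "G"
  g2 <- paste(ch, collapse = "")
  aln2 <- anchor_contigs("G1", ctg_df(c(g, g2)), ref, sch)
  rec2 <- build_consensus(aln2)
  expect_equal(substr(rec2$sequence, pos, pos), "R")
  expect_equal(rec2$ambiguity_fraction, 1 / 200)

  # an internal 37-column gap becomes n's, excluded from the denominator
  left <- substr(g, 1, 80)
  right <- substr(g, 118, 200)
  aln3 <- anchor_contigs("G1", ctg_df(c(left, right)), ref, sch)
  rec3 <- build_consensus(aln3)
  expect_equal(vapply(strsplit(rec3$sequence, ""), function(x)
    sum(x == "n"), integer(1)), 37L, ignore_attr = TRUE)
  expect_equal(rec3$assembled_length, 163L)
  expect_equal(rec3$ambiguity_fraction, 0)

  # consensus is invariant under contig reordering
  alnA <- anchor_contigs("G1", ctg_df(c(g, g2, left)), ref, sch)
  alnB <- anchor_contigs("G1", ctg_df(c(left, g2, g)), ref, sch)
  expect_identical(build_consensus(alnA)$sequence,
                   build_consensus(alnB)$sequence)
})

test_that("select_kmer picks the longest clean record, ties to smaller kmer", {
  mk <- function(kmer, len, amb) structure(
    list(gene_id = "G1", kmer = as.integer(kmer), sequence = "",
         ambiguity_fraction = amb, assembled_length = as.integer(len)),
    class = "consensus_record")
  expect_equal(select_kmer(list(mk(19, 800, 0.005), mk(25, 900, 0.025)))$kmer, 19L)
  expect_equal(select_kmer(list(mk(19, 700, 0.001), mk(21, 800, 0.001),
                                mk(23, 750, 0.001)))$assembled_length, 800L)
  expect_equal(select_kmer(list(mk(25, 800, 0.001), mk(19, 800, 0.001)))$kmer, 19L)
  expect_null(select_kmer(list(mk(19, 800, 0.02), mk(21, 900, 0.05))))
  expect_error(select_kmer(list()), "no consensus")

  # the selected record never breaches the threshold (property)
  set.seed(64)
  for (i in 1:50) {
    recs <- lapply(1:4, function(j)
      mk(17 + 2 * j, sample(200:900, 1), runif(1, 0, 0.04)))
    pick <- select_kmer(recs)
    if (!is.null(pick)) expect_lt(pick$ambiguity_fraction, 0.019)
  }
})

test_that("two-haplotype ambiguity matches the planted divergence", {
  set.seed(65)
  sch <- scoring_scheme(1, -2, db_len = 5000)
  for (d in c(0.005, 0.01, 0.015)) {
    g <- rand_dna(1500)
    ch <- strsplit(g, "")[[1]]
    i <- sample(1500, round(d * 1500))
    for (j in i) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    h2 <- paste(ch, collapse = "")
    ref <- ref_row(g, 0L, 1500L)
    rec <- build_consensus(anchor_contigs("G1", ctg_df(c(g, h2)), ref, sch))
    expect_lt(abs(rec$ambiguity_fraction - d), 3 * sqrt(d / 1500) + 1e-9)
    # direct haplotype collapse agrees
    expect_identical(rec$sequence, consensus_from_haplotypes(g, h2))
  }
})

test_that("triage repairs misalignments, keeps paralogs, drops divergent contigs", {
  sch <- scoring_scheme(1, -2, db_len = 2000)
  g <- rand_dna(600, seed = 66)
  ref <- ref_row(g, 100L, 500L)

  # (a) a contig shifted by 5 columns: re-anchoring restores a clean record
  aln <- anchor_contigs("G1", ctg_df(c(g, substr(g, 51, 400))), ref, sch)
  broken <- aln
  broken$rows$offset[2] <- broken$rows$offset[2] + 5L
  bad <- build_consensus(broken)
  expect_gte(bad$ambiguity_fraction, 0.019)
  tri <- triage_high_ambiguity(broken, bad, ref, sch)
  expect_equal(tri$outcome$category, "misalignment")
  expect_lt(tri$record$ambiguity_fraction, 0.019)

  # (b) same CDS, 30%-diverged UTRs -> paralog label, contigs retained
  mut_utr <- function(s, lo, hi) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(lo:hi, round(0.3 * (hi - lo + 1)))
    for (j in i) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    paste(ch, collapse = "")
  }
  set.seed(67)
  par <- mut_utr(mut_utr(g, 1, 100), 501, 600)
  alnP <- anchor_contigs("G1", ctg_df(c(g, par)), ref, sch)
  recP <- build_consensus(alnP)
  expect_gte(recP$ambiguity_fraction, 0.019)
  triP <- triage_high_ambiguity(alnP, recP, ref, sch)
  expect_equal(triP$outcome$category, "utr_divergent_paralog")
  expect_equal(nrow(triP$alignment$rows), 2)

  # (c) one contig at 22% CDS divergence among 11% contigs is removed
  mut_all <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), round(rate * length(ch)))
    for (j in i) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    paste(ch, collapse = "")
  }
  set.seed(68)
  near1 <- mut_all(g, 0.11)        # the focal species' own sequence
  near2 <- mut_all(near1, 0.005)   # its second haplotype
  far <- mut_all(g, 0.22)          # a highly diverged rogue contig
  alnD <- anchor_contigs("G1", ctg_df(c(near1, near2, far),
                                      ids = c("n1", "n2", "far")), ref, sch)
  recD <- build_consensus(alnD)
  expect_gte(recD$ambiguity_fraction, 0.019)
  triD <- triage_high_ambiguity(alnD, recD, ref, sch)
  expect_equal(triD$outcome$category, "divergent_contig_removed")
  expect_equal(triD$outcome$contigs_removed, "far")
})

test_that("coverage_stats reports rounded percentages and UTR extras", {
  sch <- scoring_scheme(1, -2, db_len = 1000)
  g <- rand_dna(400, seed = 69)
  ref <- ref_row(g, 50L, 350L)
  # cover 280 of the 300 CDS bases -> 93.3%
  rec <- build_consensus(anchor_contigs("G1", ctg_df(substr(g, 51, 330)),
                                        ref, sch))
  expect_equal(coverage_stats(rec)$percent_cds_coverage, 93.3)
  expect_equal(coverage_stats(rec)$utr5_extra_bp, 0L)

  # contig entirely in the 3' UTR: zero CDS coverage
  rec0 <- build_consensus(anchor_contigs("G1", ctg_df(substr(g, 355, 400)),
                                         ref, sch))
  st0 <- coverage_stats(rec0)
  expect_equal(st0$percent_cds_coverage, 0)
  expect_equal(st0$utr5_extra_bp, 0L)
  expect_equal(st0$utr3_extra_bp, 46L)
})

test_that("append_external_sequence extends the mapping reference", {
  tx <- c(gene1 = rand_dna(200, seed = 70))
  tx2 <- append_external_sequence(tx, "CHI_sanger", rand_dna(150, seed = 71))
  expect_length(tx2, 2)
  expect_error(append_external_sequence(tx2, "gene1", "ACGT"), "duplicate")
  # the appended gene recruits reads downstream like any other
  idx <- build_hash_index(tx2)
  read <- substr(tx2[["CHI_sanger"]], 11, 50)
  ms <- map_reads(read, idx)
  expect_equal(ms$placements$gene_id, "CHI_sanger")
  expect_equal(unname(ms$gene_counts["CHI_sanger"]), 1)
})
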