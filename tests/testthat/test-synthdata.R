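test_that("generate_reference honours bounds, determinism and length profile", {
  one <- generate_reference(1, median_length = 300, sdlog = 0, seed = 7)
  expect_equal(nrow(one), 1L)
  expect_equal(nchar(one$sequence), 300L)
  expect_true(one$cds_start >= 0 && one$cds_start < one$cds_end &&
                one$cds_end <= 300)
  expect_match(one$sequence, "^[ACGT]+$")

  expect_identical(generate_reference(5, seed = 3), generate_reference(5, seed = 3))
  expect_error(generate_reference(0), "positive")

  big <- generate_reference(500, median_length = 676, seed = 1)
  expect_equal(length(unique(big$gene_id)), 500L)
  # median retained-gene length of the emulated study
  expect_lt(abs(median(nchar(big$sequence)) - 676), 60)
})

test_that("mutate_transcriptome realizes the configured divergences", {
  ref <- data.frame(gene_id = sprintf("RS%05d", 1:40),
                    sequence = vapply(rep(1000, 40), rand_dna, character(1)),
                    cds_start = 100L, cds_end = 900L, strand = "+",
                    stringsAsFactors = FALSE)
  p0 <- sim_params(n_genes = 40, coding_divergence = 0, paralog_fraction = 0,
                   intraspecific_variation = 0, n_pw = 1, n_wp = 1)
  mt0 <- mutate_transcriptome(ref, p0, seed = 5)
  expect_identical(mt0$transcriptome$hap1, ref$sequence)
  expect_identical(mt0$transcriptome$hap2, ref$sequence)

  p <- sim_params(n_genes = 40, coding_divergence = 0.11, n_pw = 1, n_wp = 1,
                  paralog_fraction = 0.2)
  mt <- mutate_transcriptome(ref, p, seed = 6)
  tx <- mt$transcriptome
  ids <- mapply(seq_identity, ref$sequence, tx$hap1[1:40])
  expect_lt(abs(mean(ids) - 0.89), 0.02)

  # paralogs: conserved CDS, ~70% UTR identity
  par <- tx[tx$is_paralog, ]
  expect_gt(nrow(par), 0)
  for (i in seq_len(nrow(par))) {
    parent <- tx[tx$gene_id == par$source_gene[i], ]
    cds_id <- seq_identity(substr(par$hap1[i], 101, 900),
                           substr(parent$hap1, 101, 900))
    utr_id <- seq_identity(paste0(substr(par$hap1[i], 1, 100),
                                  substr(par$hap1[i], 901, 1000)),
                           paste0(substr(parent$hap1, 1, 100),
                                  substr(parent$hap1, 901, 1000)))
    expect_gte(cds_id, 0.98)
    expect_lt(abs(utr_id - 0.70), 0.10)
  }

  # haplotypes differ at no more than the intraspecific cap (plus
  # binomial slack)
  hapdiv <- mapply(function(a, b) 1 - seq_identity(a, b), tx$hap1, tx$hap2)
  expect_true(all(hapdiv <= 0.019 + 3 * sqrt(0.019 / 1000)))

  # DE labels consistent with planted fold changes
  gt <- mt$ground_truth
  expect_true(all(gt$fold_change[gt$labels == "P>W", ] > 1))
  expect_true(all(gt$fold_change[gt$labels == "W>P", ] < 1))
  expect_true(all(gt$fold_change > 0))
})

test_that("simulate_reads matches counts, proportions and 3' bias", {
  tx1 <- data.frame(gene_id = "g1", hap1 = rand_dna(540, seed = 1),
                    hap2 = rand_dna(540, seed = 1), cds_start = 0L,
                    cds_end = 540L, source_gene = "g1", is_paralog = FALSE,
                    stringsAsFactors = FALSE)
  gt1 <- list(levels = matrix(10, 1, 4,
                              dimnames = list("g1", pipeline_samples())))
  p <- sim_params(n_genes = 1, reads_per_sample = 1000, bias3p_strength = 0,
                  error_rate = 0, n_pw = 0, n_wp = 0)
  rd <- simulate_reads(tx1, gt1, "SR_P", p, seed = 2)
  expect_length(rd$reads, 1000L)
  expect_true(all(nchar(rd$reads) == 40L))
  # uniform start positions over deciles (500 possible starts)
  dec <- table(cut(rd$truth$start, breaks = seq(0, 500, by = 50),
                   include.lowest = TRUE))
  expect_gt(stats::chisq.test(dec)$p.value, 0.01)

  # 2:1 expression ratio recovered within binomial error
  tx2 <- rbind(tx1, within(tx1, gene_id <- "g2"))
  tx2$hap1[2] <- tx2$hap2[2] <- rand_dna(540, seed = 9)
  tx2$source_gene[2] <- "g2"
  gt2 <- list(levels = matrix(c(2, 1), 2, 4,
                              dimnames = list(c("g1", "g2"),
                                              pipeline_samples())))
  p2 <- sim_params(n_genes = 2, reads_per_sample = 6000, n_pw = 0, n_wp = 0)
  rd2 <- simulate_reads(tx2, gt2, "SR_P", p2, seed = 3)
  n1 <- sum(rd2$truth$gene_id == "g1")
  expect_lt(abs(n1 / 6000 - 2 / 3), 3 * sqrt(2 / 9 / 6000))

  # 3' bias pushes mean start toward the 3' end
  pb <- sim_params(n_genes = 1, reads_per_sample = 10000,
                   bias3p_strength = 2, n_pw = 0, n_wp = 0)
  pu <- sim_params(n_genes = 1, reads_per_sample = 10000,
                   bias3p_strength = 0, n_pw = 0, n_wp = 0)
  mb <- mean(simulate_reads(tx1, gt1, "SR_P", pb, seed = 4)$truth$start)
  mu <- mean(simulate_reads(tx1, gt1, "SR_P", pu, seed = 4)$truth$start)
  expect_gt(mb, mu)

  expect_error(simulate_reads(tx1[0, ], gt1, "SR_P", p), "empty")
})

test_that("simulate_contigs yields substrings, target contig counts and chimeras", {
  w <- make_world(n_genes = 4, seed = 11, paralog_fraction = 0)
  tx <- w$transcriptome
  ctg <- simulate_contigs(tx[1, ], kmer_list = 19L, w$params,
                          sample_ids = "P", seed = 1)
  expect_true(all(vapply(ctg$sequence, function(s)
    grepl(s, tx$hap1[1], fixed = TRUE) || grepl(s, tx$hap2[1], fixed = TRUE),
    logical(1))))

  w2 <- make_world(n_genes = 60, seed = 12, paralog_fraction = 0)
  ctg2 <- simulate_contigs(w2$transcriptome, kmer_list = c(19L, 25L),
                           w2$params, sample_ids = c("P", "W"), seed = 2)
  per <- nrow(ctg2) / (60 * 2 * 2)
  expect_lt(abs(per - 1.475) / 1.475, 0.10)

  # smaller kmers recover more of the gene
  cov19 <- sum(nchar(ctg2$sequence[ctg2$kmer == 19]))
  cov25 <- sum(nchar(ctg2$sequence[ctg2$kmer == 25]))
  expect_gt(cov19, cov25)

  w3 <- make_world(n_genes = 200, seed = 13, chimera_rate = 0.05,
                   paralog_fraction = 0)
  ctg3 <- simulate_contigs(w3$transcriptome, kmer_list = 19L, w3$params,
                           sample_ids = "P", seed = 3)
  expect_lt(abs(mean(ctg3$is_chimera) - 0.05), 0.02)
  expect_error(simulate_contigs(w3$transcriptome, integer(0), w3$params),
               "non-empty")
})

test_that("generate_go_annotations plants (only) the configured signal", {
  genes <- sprintf("g%04d", 1:1000)
  de <- sample(genes, 25)
  ann0 <- generate_go_annotations(genes, n_terms = 10,
                                  background_freq = 0.3, seed = 4)
  expect_identical(ann0, generate_go_annotations(genes, n_terms = 10,
                                                 background_freq = 0.3,
                                                 seed = 4))
  # term frequency independent of DE label when nothing is planted
  carrier <- genes %in% ann0$gene_id[ann0$term_id == "GO:0000001"]
  tab <- table(carrier, genes %in% de)
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)

  spec <- list(term = "GO:0000002", background = 0.05, de_freq = 0.40,
               de_genes = de)
  ann <- generate_go_annotations(genes, n_terms = 10,
                                 enriched_term_spec = spec, seed = 5)
  k <- sum(de %in% ann$gene_id[ann$term_id == "GO:0000002"])
  expect_lt(abs(k - 10), 3.5 * sqrt(25 * 0.4 * 0.6) + 1)
})

test_that("generators are byte-stable under a fixed seed", {
  w1 <- make_world(n_genes = 6, seed = 77)
  w2 <- make_world(n_genes = 6, seed = 77)
  expect_identical(w1$transcriptome, w2$transcriptome)
  expect_identical(w1$ground_truth$levels, w2$ground_truth$levels)
  r1 <- simulate_reads(w1$transcriptome, w1$ground_truth, "MS_W", w1$params,
                       seed = 8)
  r2 <- simulate_reads(w2$transcriptome, w2$ground_truth, "MS_W", w2$params,
                       seed = 8)
  expect_identical(r1, r2)
})

test_that("ground-truth fold changes are recoverable from RPKM downstream", {
  # at the default stated world (300 genes, 3e5 >= 1e5 reads/sample), RPKM
  # ratios track the realized level ratios (the levels matrix IS the
  # truth; the planted fold parameter is pre-noise)
  p <- sim_params()
  ref <- generate_reference(p$n_genes, seed = 140)
  mt <- mutate_transcriptome(ref, p, seed = 141)
  tx <- mt$transcriptome
  gt <- mt$ground_truth
  consensus <- setNames(mapply(consensus_from_haplotypes, tx$hap1, tx$hap2),
                        tx$gene_id)
  idx <- build_hash_index(consensus)
  counts <- vapply(c("SR_P", "SR_W"), function(s) {
    rd <- simulate_reads(tx, gt, s, p, seed = 142 + (s == "SR_W"))
    map_reads(rd$reads, idx)$gene_counts
  }, numeric(length(consensus)))
  em <- expression_matrix(cbind(counts, counts), nchar(consensus))
  lev <- gt$levels[rownames(em$rpkm), ]
  true_rpkm <- sweep(lev * 1e9, 2,
                     colSums(lev * nchar(consensus)[rownames(lev)]), "/")
  ok <- true_rpkm[, "SR_P"] >= 10 & true_rpkm[, "SR_W"] >= 10
  est <- em$rpkm[ok, "SR_P"] / em$rpkm[ok, "SR_W"]
  tru <- lev[ok, "SR_P"] / lev[ok, "SR_W"]
  relerr <- abs(est / tru - 1)
  # Poisson noise at the RPKM-10 floor leaves a small tail beyond 25%
  expect_gte(mean(relerr <= 0.25), 0.9)
  expect_lte(median(relerr), 0.10)
})
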