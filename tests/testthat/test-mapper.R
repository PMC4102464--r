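test_that("hash index covers positions and expands ambiguity codes", {
  ref <- c(g1 = rand_dna(20, seed = 81))
  idx <- build_hash_index(ref)
  expect_equal(index_positions(idx), 7)  # 20 - 14 + 1

  # an R position matches both A- and G-bearing words
  s <- rand_dna(30, seed = 82)
  sR <- s
  substr(sR, 10, 10) <- "R"
  idxR <- build_hash_index(c(g1 = sR))
  wA <- substr(s, 5, 18); substr(wA, 6, 6) <- "A"
  wG <- substr(s, 5, 18); substr(wG, 6, 6) <- "G"
  expect_equal(index_lookup(idxR, wA)$offset, 4)
  expect_equal(index_lookup(idxR, wG)$offset, 4)

  # n interrupts indexing
  sn <- s
  substr(sn, 15, 15) <- "n"
  expect_equal(index_positions(build_hash_index(c(g1 = sn))),
               index_positions(build_hash_index(c(g1 = s))) - 14)

  # lookups equal a direct scan for 100 random words
  world <- c(a = rand_dna(300, seed = 83), b = rand_dna(300, seed = 84))
  idx2 <- build_hash_index(world)
  set.seed(85)
  for (i in 1:100) {
    g <- sample(names(world), 1)
    p <- sample(300 - 14 + 1, 1)
    w <- substr(world[[g]], p, p + 13)
    got <- index_lookup(idx2, w)
    # direct scan over both references
    exp_rows <- do.call(rbind, lapply(names(world), function(nm) {
      hits <- which(vapply(1:(300 - 13), function(q)
        substr(world[[nm]], q, q + 13) == w, logical(1)))
      if (length(hits)) data.frame(gene_id = nm, offset = hits - 1) else NULL
    }))
    expect_equal(got[order(got$gene_id, got$offset), ],
                 exp_rows[order(exp_rows$gene_id, exp_rows$offset), ],
                 ignore_attr = TRUE)
  }
  expect_error(build_hash_index(unname(world)), "named")
})

test_that("map_reads placement semantics follow the unique/multi/filtered rules", {
  g <- rand_dna(200, seed = 86)
  idx <- build_hash_index(c(g1 = g))

  r0 <- substr(g, 21, 60)
  ms <- map_reads(r0, idx)
  expect_equal(as.character(ms$placements$status), "unique")
  expect_equal(ms$placements$offset, 20)
  expect_equal(ms$placements$mismatches, 0)

  # three substitutions exceed the cap
  r3 <- r0
  for (p in c(5, 20, 35))
    substr(r3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(r3, p, p))[1]
  ms3 <- map_reads(r3, idx)
  expect_equal(as.character(ms3$placements$status), "filtered")
  expect_equal(ms3$totals[["unique"]], 0)

  # equal-mismatch placements on two genes -> multi, no gene counts
  idx2 <- build_hash_index(c(g1 = g, g2 = g))
  msM <- map_reads(r0, idx2)
  expect_equal(as.character(msM$placements$status), "multi")
  expect_equal(sum(msM$gene_counts), 0)

  # two placements within ONE gene (repeated 40-mer) -> multi as well
  rep_gene <- paste0(g, rand_dna(30, seed = 87), substr(g, 21, 60))
  idx3 <- build_hash_index(c(g1 = rep_gene))
  msR <- map_reads(r0, idx3)
  expect_equal(as.character(msR$placements$status), "multi")

  # reads shorter than h are unseeded
  expect_equal(as.character(map_reads("ACGTACGTACGT", idx)$placements$status),
               "unseeded")

  # reference ambiguity codes count as matches
  gR <- g
  substr(gR, 30, 30) <- "R"
  idxA <- build_hash_index(c(g1 = gR))
  rA <- r0
  substr(rA, 10, 10) <- "A"   # position 30 of the gene
  rG <- r0
  substr(rG, 10, 10) <- "G"
  expect_equal(map_reads(rA, idxA)$placements$mismatches, 0)
  expect_equal(map_reads(rG, idxA)$placements$mismatches, 0)
})

test_that("seeded mapper equals exhaustive scans (two independent oracles)", {
  w <- make_world(n_genes = 8, reads_per_sample = 1000, seed = 88)
  consensus <- world_consensus(w)
  idx <- build_hash_index(consensus)
  rd <- simulate_reads(w$transcriptome, w$ground_truth, "SR_W", w$params,
                       seed = 89)
  ms <- map_reads(rd$reads, idx)
  bf <- map_reads_bruteforce(rd$reads, consensus)
  expect_identical(ms$placements$status == "unique", bf$status == "unique")
  u <- ms$placements$status == "unique"
  expect_identical(ms$placements$gene_id[u], bf$gene_id[u])
  expect_identical(ms$placements$offset[u], bf$offset[u])
  expect_identical(ms$placements$mismatches[u], bf$mismatches[u])

  # pure-R oracle on a small subsample (independent of both C++ routes)
  set.seed(90)
  for (i in sample(length(rd$reads), 25)) {
    o <- oracle_map_read(rd$reads[[i]], consensus)
    pl <- ms$placements[i, ]
    if (is.null(o)) {
      expect_true(pl$status %in% c("filtered", "unseeded"))
    } else if (nrow(o) > 1) {
      expect_equal(as.character(pl$status), "multi")
    } else {
      expect_equal(as.character(pl$status), "unique")
      expect_equal(pl$gene_id, o$gene)
      expect_equal(pl$offset, o$offset)
    }
  }

  # count bookkeeping invariants
  t <- ms$totals
  expect_equal(t[["generated"]],
               t[["unique"]] + t[["multi"]] + t[["filtered"]] + t[["unseeded"]])
  expect_equal(sum(ms$gene_counts), t[["unique"]])
})

test_that("well-separated genes never cross-assign simulated reads", {
  set.seed(91)
  genes <- setNames(vapply(rep(400, 6), rand_dna, character(1)),
                    sprintf("g%d", 1:6))
  idx <- build_hash_index(genes)
  for (g in names(genes)) {
    starts <- sample(400 - 39, 50)
    reads <- substring(genes[[g]], starts, starts + 39)
    # up to 2 errors per read
    reads <- vapply(reads, function(r) {
      for (p in sample(40, sample(0:2, 1))) {
        substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(r, p, p)), 1)
      }
      r
    }, character(1), USE.NAMES = FALSE)
    ms <- map_reads(reads, idx)
    u <- ms$placements$status == "unique"
    expect_true(all(ms$placements$gene_id[u] == g))
  }
})

test_that("read-fate percentages divide by generated reads", {
  expect_error(read_fate_percentages(c(generated = 0, unique = 0)), "positive")
  p <- read_fate_percentages(c(generated = 200, aligned = 100, multi = 10,
                               unique = 90, filtered = 80))
  expect_equal(unname(p["aligned"]), 50)
  expect_equal(unname(p["unique"]), 45)
})

test_that("write_sam emits valid minimal records", {
  g <- rand_dna(120, seed = 92)
  idx <- build_hash_index(c(gene1 = g))
  reads <- c(r1 = substr(g, 11, 50), r2 = strrep("A", 40))
  ms <- map_reads(reads, idx)
  fp <- tempfile(fileext = ".sam")
  write_sam(ms, reads, idx, fp)
  lines <- readLines(fp)
  expect_true(any(grepl("^@SQ\tSN:gene1\tLN:120$", lines)))
  rec <- strsplit(grep("^r1\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(rec[2:6], c("0", "gene1", "11", "255", "40M"))
  expect_equal(length(rec), 11L)
})
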