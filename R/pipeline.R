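#' Pipeline configuration
#'
#' One flat object holding every threshold of the pipeline plus the
#' synthetic-world parameters, so a run is fully reproducible from
#' `(config, seed)`.
#'
#' @param outdir output directory.
#' @param sim a [sim_params()] object describing the synthetic inputs.
#' @param evalue_threshold reciprocal-best-hit E-value cutoff.
#' @param ambiguity_threshold consensus ambiguity QC gate.
#' @param hash_length mapper seed length.
#' @param max_mismatch mapper mismatch cap.
#' @param word_size homology seed word length.
#' @param min_reads low-count filter threshold.
#' @param rd_cutoff,consistency_cutoff differential-expression thresholds.
#' @param top_fraction study-set fraction for GO enrichment.
#' @param fdr_strict,fdr_loose enrichment reporting tiers.
#' @param outlier_genes gene ids excluded from the fold-change regression
#'   (defaults to the flagship CHS-like gene at run time when `NULL`).
#' @param seed master seed; all stage seeds derive from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("petalseq_run_"),
                            sim = sim_params(),
                            evalue_threshold = 1e-10,
                            ambiguity_threshold = 0.019,
                            hash_length = 14,
                            max_mismatch = 2,
                            word_size = 11,
                            min_reads = 10,
                            rd_cutoff = 0.5,
                            consistency_cutoff = 0.25,
                            top_fraction = 0.02,
                            fdr_strict = 0.01,
                            fdr_loose = 0.05,
                            outlier_genes = NULL,
                            seed = 1L) {
  structure(list(outdir = outdir, sim = sim,
                 evalue_threshold = evalue_threshold,
                 ambiguity_threshold = ambiguity_threshold,
                 hash_length = as.integer(hash_length),
                 max_mismatch = as.integer(max_mismatch),
                 word_size = as.integer(word_size),
                 min_reads = min_reads, rd_cutoff = rd_cutoff,
                 consistency_cutoff = consistency_cutoff,
                 top_fraction = top_fraction, fdr_strict = fdr_strict,
                 fdr_loose = fdr_loose, outlier_genes = outlier_genes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Every violated invariant is reported (errors are return values, not
#' conditions). In particular the assembler constraint that the maximum
#' kmer not exceed read length minus 10 is enforced here.
#'
#' @param config a [pipeline_config()].
#' @return list with `ok` (logical) and `errors` (character vector).
#' @export
validate_config <- function(config) {
  e <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) e[[length(e) + 1L]] <<- msg
  s <- config$sim
  chk(inherits(s, "sim_params"), "sim must be a sim_params object")
  if (inherits(s, "sim_params")) {
    chk(all(s$kmer_list <= s$read_length - 10L),
        "maximum kmer is read length - 10")
    chk(s$read_length >= config$hash_length + config$max_mismatch,
        "read length must cover hash length plus allowed mismatches")
  }
  chk(config$evalue_threshold > 0, "evalue_threshold must be positive")
  chk(config$ambiguity_threshold > 0 && config$ambiguity_threshold < 1,
      "ambiguity_threshold must be in (0, 1)")
  chk(config$hash_length >= 8, "hash_length must be >= 8")
  chk(config$max_mismatch >= 0, "max_mismatch must be >= 0")
  chk(config$min_reads > 0, "min_reads must be positive")
  chk(config$rd_cutoff > 0 && config$rd_cutoff <= 1,
      "rd_cutoff must be in (0, 1]")
  chk(config$consistency_cutoff > 0 && config$consistency_cutoff <= 2,
      "consistency_cutoff must be in (0, 2]")
  chk(config$top_fraction > 0 && config$top_fraction < 1,
      "top_fraction must be in (0, 1)")
  chk(config$fdr_strict > 0 && config$fdr_strict <= config$fdr_loose &&
        config$fdr_loose < 1, "FDR tiers must satisfy 0 < strict <= loose < 1")
  chk(is.numeric(config$seed) && length(config$seed) == 1L,
      "seed must be a single integer")
  list(ok = length(e) == 0, errors = e)
}

.pipeline_stages <- c("simulate", "assign", "consensus", "map", "express",
                      "classify", "enrich", "validate")

#' Run the full pipeline
#'
#' Executes simulate, assign (reciprocal best hits per sample and kmer),
#' consensus (per-gene kmer choice plus ambiguity triage), map, express,
#' classify, enrich and validate in order, writing every stage's artifacts
#' under `config$outdir`. Reruns with the same config and seed are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param stop_after optional stage name to stop at.
#' @return invisible list of stage results plus `manifest` (data.frame of
#'   per-stage record counts and timings).
#' @export
run_pipeline <- function(config, stop_after = "validate") {
  v <- validate_config(config)
  if (!v$ok)
    stop_arg("invalid configuration:\n  ", paste(v$errors, collapse = "\n  "))
  stop_after <- match.arg(stop_after, .pipeline_stages)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$sim
  seed <- config$seed
  samples <- pipeline_samples()
  manifest <- data.frame(stage = character(), records = integer(),
                         seconds = numeric(), stringsAsFactors = FALSE)
  res <- list()
  tick <- function(stage, n, t0) {
    manifest[nrow(manifest) + 1L, ] <<- list(stage, as.integer(n),
                                             round(proc.time()[3] - t0, 2))
    message(sprintf("[%s] %d records", stage, n))
  }
  done <- function() {
    write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))
    res$manifest <- manifest
    invisible(res)
  }

  ## simulate ---------------------------------------------------------------
  t0 <- proc.time()[3]
  ref <- generate_reference(sim$n_genes, seed = seed)
  mt <- mutate_transcriptome(ref, sim, seed = seed + 1L)
  tx <- mt$transcriptome
  gt <- mt$ground_truth
  contigs <- simulate_contigs(tx, sim$kmer_list, sim,
                              sample_ids = c("P", "W"), seed = seed + 2L)
  wp_genes <- tx$gene_id[gt$labels == "W>P"]
  annotations <- generate_go_annotations(
    tx$gene_id, n_terms = 50,
    enriched_term_spec = list(term = "GO:0000001", background = 0.05,
                              de_freq = 0.40, de_genes = wp_genes),
    seed = seed + 3L)
  reads <- lapply(seq_along(samples), function(i)
    simulate_reads(tx, gt, samples[i], sim, seed = seed + 10L + i))
  names(reads) <- samples
  write_fasta(setNames(ref$sequence, ref$gene_id),
              file.path(config$outdir, "reference.fasta"))
  write_fasta(setNames(contigs$sequence, contigs$contig_id),
              file.path(config$outdir, "contigs.fasta"))
  for (s in samples)
    write_fastq(reads[[s]]$reads, file.path(config$outdir,
                                            paste0("reads_", s, ".fastq")))
  write_tsv(annotations, file.path(config$outdir, "annotations.tsv"))
  write_tsv(data.frame(gene_id = tx$gene_id, label = gt$labels,
                       fold_SR = gt$fold_change[, "SR"],
                       fold_MS = gt$fold_change[, "MS"]),
            file.path(config$outdir, "ground_truth.tsv"))
  res$reference <- ref; res$transcriptome <- tx; res$ground_truth <- gt
  res$contigs <- contigs; res$reads <- reads; res$annotations <- annotations
  tick("simulate", nrow(contigs) + length(samples) * sim$reads_per_sample, t0)
  if (stop_after == "simulate") return(done())

  ## assign -----------------------------------------------------------------
  t0 <- proc.time()[3]
  refseq <- setNames(ref$sequence, ref$gene_id)
  scheme_f <- scoring_scheme(db_len = sum(nchar(refseq)))
  assign_rows <- list()
  for (s in c("P", "W")) for (k in sim$kmer_list) {
    sub <- contigs[contigs$sample == s & contigs$kmer == k, , drop = FALSE]
    if (nrow(sub) == 0) next
    ctg <- setNames(sub$sequence, sub$contig_id)
    fwd <- search_hits(ctg, refseq, scheme_f, config$word_size)
    scheme_r <- scoring_scheme(db_len = sum(nchar(ctg)))
    rev <- search_hits(refseq, ctg, scheme_r, config$word_size)
    rbh <- reciprocal_best_hits(fwd, rev, config$evalue_threshold)
    if (nrow(rbh) == 0) next
    rbh$sample <- s; rbh$kmer <- k
    rbh$sequence <- sub$sequence[match(rbh$contig_id, sub$contig_id)]
    assign_rows[[length(assign_rows) + 1L]] <- rbh
    hit_path <- file.path(config$outdir,
                          sprintf("hits_%s_k%02d.tsv", s, k))
    write_tsv(fwd[, c("query", "subject", "score", "identity", "q_start",
                      "q_end", "s_start", "s_end", "evalue")], hit_path)
  }
  assignments <- do.call(rbind, assign_rows)
  res$assignments <- assignments
  tick("assign", if (is.null(assignments)) 0L else nrow(assignments), t0)
  if (stop_after == "assign") return(done())

  ## consensus --------------------------------------------------------------
  t0 <- proc.time()[3]
  chosen <- list()
  qc_log <- list()
  for (g in unique(assignments$gene_id)) {
    gref <- ref[ref$gene_id == g, ]
    per_kmer <- list()
    for (k in sim$kmer_list) {
      sub <- assignments[assignments$gene_id == g & assignments$kmer == k, ,
                         drop = FALSE]
      if (nrow(sub) == 0) next
      aln <- anchor_contigs(g, data.frame(contig_id = sub$contig_id,
                                          sample = sub$sample,
                                          sequence = sub$sequence,
                                          stringsAsFactors = FALSE),
                            gref, scheme_f, config$word_size, kmer = k)
      per_kmer[[length(per_kmer) + 1L]] <- list(aln = aln,
                                                rec = build_consensus(aln))
    }
    if (length(per_kmer) == 0) next
    recs <- lapply(per_kmer, `[[`, "rec")
    pick <- select_kmer(recs, config$ambiguity_threshold)
    if (is.null(pick)) {
      # triage the longest record's alignment
      len <- vapply(recs, `[[`, integer(1), "assembled_length")
      best <- which.max(len)
      tri <- triage_high_ambiguity(per_kmer[[best]]$aln, recs[[best]], gref,
                                   scheme_f, config$ambiguity_threshold,
                                   config$word_size)
      qc_log[[length(qc_log) + 1L]] <- tri$outcome
      if (is.null(tri$record)) next
      pick <- tri$record
    }
    chosen[[g]] <- pick
  }
  consensus_seqs <- vapply(chosen, `[[`, character(1), "sequence")
  stats_tab <- do.call(rbind, lapply(chosen, coverage_stats))
  write_fasta(consensus_seqs, file.path(config$outdir, "consensus.fasta"))
  write_tsv(stats_tab, file.path(config$outdir, "consensus_stats.tsv"))
  qc_tab <- if (length(qc_log)) do.call(rbind, qc_log) else
    data.frame(gene_id = character(), category = character(),
               contigs_removed = character(), stringsAsFactors = FALSE)
  write_tsv(qc_tab, file.path(config$outdir, "qc_log.tsv"))
  res$consensus <- chosen; res$consensus_stats <- stats_tab; res$qc <- qc_tab
  tick("consensus", length(chosen), t0)
  if (stop_after == "consensus") return(done())

  ## map --------------------------------------------------------------------
  t0 <- proc.time()[3]
  rescue_w <- max(8L, sim$read_length %/% (config$max_mismatch + 1L))
  rescue_w <- min(rescue_w, config$hash_length)
  index <- build_hash_index(consensus_seqs, h = config$hash_length,
                            rescue_w = rescue_w)
  maps <- lapply(samples, function(s)
    map_reads(reads[[s]]$reads, index, config$max_mismatch))
  names(maps) <- samples
  fate <- do.call(rbind, lapply(samples, function(s) {
    t <- maps[[s]]$totals
    data.frame(sample = s, t(t), t(read_fate_percentages(maps[[s]])),
               stringsAsFactors = FALSE)
  }))
  write_tsv(fate, file.path(config$outdir, "mapping_summary.tsv"))
  counts <- vapply(samples, function(s) maps[[s]]$gene_counts,
                   numeric(length(consensus_seqs)))
  rownames(counts) <- names(consensus_seqs)
  res$maps <- maps; res$counts <- counts; res$mapping_summary <- fate
  tick("map", sum(fate$unique), t0)
  if (stop_after == "map") return(done())

  ## express ----------------------------------------------------------------
  t0 <- proc.time()[3]
  gene_len <- vapply(chosen, `[[`, integer(1), "assembled_length")
  em <- expression_matrix(counts, gene_len)
  expr_tab <- data.frame(
    gene_id = rep(rownames(counts), ncol(counts)),
    sample = rep(colnames(counts), each = nrow(counts)),
    count = as.vector(counts), rpkm = signif(as.vector(em$rpkm), 3),
    stringsAsFactors = FALSE)
  write_tsv(expr_tab, file.path(config$outdir, "expression.tsv"))
  res$expression <- em
  tick("express", nrow(counts), t0)
  if (stop_after == "express") return(done())

  ## classify ---------------------------------------------------------------
  t0 <- proc.time()[3]
  retained <- low_count_filter(em$counts, config$min_reads)
  diff_tab <- classify_differential(
    em$rpkm[retained, , drop = FALSE],
    de_thresholds(config$rd_cutoff, config$consistency_cutoff,
                  config$min_reads))
  out_tab <- diff_tab
  for (col in c("rd_pop1", "rd_pop2", "mean_rd", "consistency"))
    out_tab[[col]] <- round(out_tab[[col]], 3)
  write_tsv(out_tab, file.path(config$outdir, "differential.tsv"))
  res$retained <- retained; res$differential <- diff_tab
  tick("classify", nrow(diff_tab), t0)
  if (stop_after == "classify") return(done())

  ## enrich -----------------------------------------------------------------
  t0 <- proc.time()[3]
  enr <- list()
  for (dir in c("P>W", "W>P")) {
    study <- select_top_fraction(diff_tab, config$top_fraction, dir,
                                 config$consistency_cutoff)
    nullset <- build_null_set(retained, list(study))
    e <- go_enrichment(study, nullset, annotations,
                       alpha_strict = config$fdr_strict,
                       alpha_loose = config$fdr_loose)
    if (nrow(e) > 0) e$direction <- dir
    enr[[dir]] <- list(study = study, result = e)
  }
  enr_tab <- do.call(rbind, lapply(enr, function(x)
    if (nrow(x$result)) x$result else NULL))
  if (!is.null(enr_tab))
    write_tsv(enr_tab, file.path(config$outdir, "enrichment.tsv"))
  res$enrichment <- enr
  tick("enrich", if (is.null(enr_tab)) 0L else nrow(enr_tab), t0)
  if (stop_after == "enrich") return(done())

  ## validate ---------------------------------------------------------------
  t0 <- proc.time()[3]
  assay <- unique(c(gt$chs_gene, tx$gene_id[gt$labels != "null"]))
  assay <- intersect(assay, retained)
  if (length(assay) >= 3) {
    qpcr <- simulate_qpcr_table(gt, assay, seed = seed + 20L)
    std <- ddct_standardize(qpcr, calibrator = "SR_P")
    key <- cbind(match(std$gene, rownames(em$rpkm)),
                 match(std$sample, colnames(em$rpkm)))
    x <- linearize_qpcr(std$delta_ct, std$efficiency)
    y <- em$rpkm[key]
    ok <- y > 0
    reg <- regress_loglog(x[ok], y[ok])
    outliers <- config$outlier_genes
    if (is.null(outliers)) outliers <- gt$chs_gene
    dsub <- diff_tab[diff_tab$gene_id %in% assay, ]
    qfold <- vapply(dsub$gene_id, function(g) {
      v <- std[std$gene == g, ]
      mean(c(v$relative_expression[v$sample == "SR_P"] /
               v$relative_expression[v$sample == "SR_W"],
             v$relative_expression[v$sample == "MS_P"] /
               v$relative_expression[v$sample == "MS_W"]))
    }, numeric(1))
    rfold <- (dsub$fold_pop1 + dsub$fold_pop2) / 2
    names(rfold) <- dsub$gene_id
    keep <- !names(rfold) %in% outliers
    reg_fold <- if (sum(keep) >= 3)
      regress_loglog(rfold[keep], qfold[keep]) else NULL
    reg_tab <- data.frame(
      comparison = c("rpkm_vs_linear_dct",
                     if (!is.null(reg_fold)) "fold_change"),
      slope = c(reg$slope, if (!is.null(reg_fold)) reg_fold$slope),
      intercept = c(reg$intercept, if (!is.null(reg_fold)) reg_fold$intercept),
      r_squared = c(reg$r_squared, if (!is.null(reg_fold)) reg_fold$r_squared),
      f_statistic = c(reg$f_statistic,
                      if (!is.null(reg_fold)) reg_fold$f_statistic),
      n = c(reg$n, if (!is.null(reg_fold)) reg_fold$n),
      stringsAsFactors = FALSE)
    write_tsv(reg_tab, file.path(config$outdir, "validation.tsv"))
    res$validation <- list(qpcr = std, regression = reg,
                           fold_regression = reg_fold)
    tick("validate", nrow(std), t0)
  } else {
    tick("validate", 0L, t0)
  }
  done()
}
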