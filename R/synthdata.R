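#' Simulation parameters for the synthetic-data module
#'
#' Collects every knob of the synthetic world in one validated list. Defaults
#' emulate the sequencing design the pipeline targets: 40 bp single-end
#' reads, a focal species ~11% diverged from the reference species in coding
#' sequence, at most 1.9% intraspecific variation (two haplotypes per pooled
#' sample), mild 3' coverage bias from poly-A selection, kmer assemblies
#' spanning 19-29 (odd values, capped at read length minus 10), and a small
#' planted set of consistently differentially expressed genes dominated by
#' one CHS-like gene at ~7x purple-over-white.
#'
#' @param n_genes number of reference genes.
#' @param read_length single-end read length in bp.
#' @param reads_per_sample reads generated per sample.
#' @param error_rate per-base sequencing substitution rate.
#' @param bias3p_strength exponential 3'-bias strength; 0 = uniform starts.
#' @param intraspecific_variation maximum per-gene haplotype divergence.
#' @param coding_divergence substitution proportion of focal vs reference
#'   coding sequence.
#' @param utr_divergence_paralog UTR divergence of designated paralogs.
#' @param paralog_fraction fraction of genes given a UTR-divergent paralog.
#' @param kmer_list assembly kmer values (odd, <= read_length - 10).
#' @param mean_contigs_per_gene target mean contigs per gene per kmer.
#' @param chimera_rate fraction of contigs concatenating two genes.
#' @param n_pw,n_wp planted consistently DE gene counts (purple-over-white
#'   and white-over-purple).
#' @param de_fold planted purple/white (or white/purple) fold change.
#' @param chs_fold fold change of the single CHS-like flagship gene.
#' @param sample_noise_sd lognormal sd of per-sample biological noise.
#' @param seed default seed used by generators when none is passed.
#' @return an object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params(n_genes = 20, reads_per_sample = 1000)
#' p$kmer_list
#' @export
sim_params <- function(n_genes = 300,
                       read_length = 40,
                       reads_per_sample = 3e5,
                       error_rate = 0.01,
                       bias3p_strength = 1,
                       intraspecific_variation = 0.019,
                       coding_divergence = 0.11,
                       utr_divergence_paralog = 0.30,
                       paralog_fraction = 0.05,
                       kmer_list = seq(19L, 29L, by = 2L),
                       mean_contigs_per_gene = 1.475,
                       chimera_rate = 0,
                       n_pw = 8L,
                       n_wp = 25L,
                       de_fold = 10 / 3,
                       chs_fold = 7,
                       sample_noise_sd = 0.10,
                       seed = NULL) {
  p <- list(n_genes = as.integer(n_genes), read_length = as.integer(read_length),
            reads_per_sample = as.integer(reads_per_sample),
            error_rate = error_rate, bias3p_strength = bias3p_strength,
            intraspecific_variation = intraspecific_variation,
            coding_divergence = coding_divergence,
            utr_divergence_paralog = utr_divergence_paralog,
            paralog_fraction = paralog_fraction,
            kmer_list = as.integer(kmer_list),
            mean_contigs_per_gene = mean_contigs_per_gene,
            chimera_rate = chimera_rate, n_pw = as.integer(n_pw),
            n_wp = as.integer(n_wp), de_fold = de_fold, chs_fold = chs_fold,
            sample_noise_sd = sample_noise_sd, seed = seed)
  if (p$n_genes < 1L) stop_arg("n_genes must be >= 1")
  if (p$reads_per_sample < 1L) stop_arg("reads_per_sample must be >= 1")
  if (p$error_rate < 0 || p$error_rate >= 1) stop_arg("error_rate must be in [0, 1)")
  for (f in c("intraspecific_variation", "coding_divergence",
              "utr_divergence_paralog"))
    if (p[[f]] < 0 || p[[f]] >= 1) stop_arg(f, " must be in [0, 1)")
  if (any(p$kmer_list %% 2L == 0L))
    stop_arg("kmer values must be odd")
  if (any(p$kmer_list > p$read_length - 10L))
    stop_arg("maximum kmer is read_length - 10")
  if (p$read_length < 14L + 2L)
    stop_arg("read_length must be at least hash length + allowed mismatches")
  structure(p, class = "sim_params")
}

#' Sample labels of the two-morph, two-population design
#'
#' Purple (P) and white (W) pools from two populations: SR (the assembly
#' population) and MS (the replication population).
#' @return character vector of the four sample labels.
#' @export
pipeline_samples <- function() c("SR_P", "SR_W", "MS_P", "MS_W")

#' Generate a reference-species gene set
#'
#' Genes are random ACGT sequences with a CDS flanked by 5' and 3' UTRs.
#' Lengths are log-normal with the requested median, mirroring the length
#' profile of genes retained in short-read transcriptome expression analyses.
#'
#' @param n_genes number of genes (>= 1).
#' @param median_length median gene length in bp.
#' @param sdlog log-scale standard deviation of the length distribution; 0
#'   gives fixed-length genes.
#' @param min_length minimum gene length (>= 150).
#' @param seed RNG seed.
#' @return data.frame with columns `gene_id`, `sequence`, `cds_start`,
#'   `cds_end` (0-based half-open), `strand`.
#' @examples
#' ref <- generate_reference(3, median_length = 300, seed = 1)
#' nchar(ref$sequence)
#' @export
generate_reference <- function(n_genes, median_length = 676, sdlog = 0.45,
                               min_length = 150, seed = NULL) {
  if (n_genes < 1) stop_arg("n_genes must be positive")
  if (min_length < 150) stop_arg("min_length must be >= 150")
  with_seed(seed, {
    len <- round(rlnorm(n_genes, meanlog = log(median_length), sdlog = sdlog))
    len <- pmin(pmax(len, min_length), 3506L)
    u5 <- runif(n_genes, 0.06, 0.16)
    u3 <- runif(n_genes, 0.10, 0.26)
    cds_start <- pmax(round(len * u5), 1L)
    cds_end <- pmin(round(len * (1 - u3)), len - 1L)
    # keep the CDS at least 90 bp
    bad <- cds_end - cds_start < 90L
    cds_start[bad] <- pmax(round(len[bad] * 0.05), 1L)
    cds_end[bad] <- len[bad] - 1L
    data.frame(
      gene_id = sprintf("RS%05d", seq_len(n_genes)),
      sequence = vapply(len, random_dna, character(1)),
      cds_start = as.integer(cds_start),
      cds_end = as.integer(cds_end),
      strand = "+",
      stringsAsFactors = FALSE)
  })
}

#' Derive a diverged focal-species transcriptome with ground truth
#'
#' Each reference gene is mutated at `coding_divergence` (CDS and UTR alike)
#' to produce the focal species' version, then split into two haplotypes
#' differing at up to `intraspecific_variation` of sites (a pooled sample is
#' modeled as one haplotype pair per morph). A fraction of genes receive a
#' paralog whose CDS stays >= ~99% identical while the UTRs diverge at
#' `utr_divergence_paralog`. True expression levels for the four samples are
#' drawn log-normally; `n_pw` genes are planted purple-over-white and `n_wp`
#' white-over-purple at `de_fold`, with one flagship CHS-like gene at
#' `chs_fold`.
#'
#' @param reference data.frame from [generate_reference()].
#' @param params a [sim_params()] object.
#' @param seed RNG seed.
#' @return list with `transcriptome` (data.frame: `gene_id`, `hap1`, `hap2`,
#'   `cds_start`, `cds_end`, `source_gene`, `is_paralog`) and `ground_truth`
#'   (list: `levels` matrix genes x samples, `fold_change` matrix genes x 2
#'   populations, `labels`, `divergence`, `het_rate`, `paralog_map`,
#'   `chs_gene`).
#' @export
mutate_transcriptome <- function(reference, params = sim_params(), seed = NULL) {
  with_seed(seed, {
    n <- nrow(reference)
    div <- params$coding_divergence
    het_rate <- runif(n, 0.25, 1) * params$intraspecific_variation
    hap1 <- character(n)
    realized_div <- numeric(n)
    for (i in seq_len(n)) {
      m <- mutate_seq(reference$sequence[i], div)
      hap1[i] <- m$seq
      realized_div[i] <- m$n_sub / nchar(m$seq)
    }
    hap2 <- vapply(seq_len(n), function(i)
      mutate_seq(hap1[i], het_rate[i])$seq, character(1))
    tx <- data.frame(
      gene_id = reference$gene_id, hap1 = hap1, hap2 = hap2,
      cds_start = reference$cds_start, cds_end = reference$cds_end,
      source_gene = reference$gene_id, is_paralog = FALSE,
      stringsAsFactors = FALSE)

    # paralogs: conserved CDS, divergent UTRs
    n_par <- round(params$paralog_fraction * n)
    paralog_map <- list()
    if (n_par > 0) {
      par_of <- sample.int(n, n_par)
      prow <- lapply(par_of, function(i) {
        s <- hap1[i]
        cs <- reference$cds_start[i]; ce <- reference$cds_end[i]
        cds <- substr(s, cs + 1L, ce)
        utr5 <- substr(s, 1L, cs)
        utr3 <- substr(s, ce + 1L, nchar(s))
        cds2 <- mutate_seq(cds, 0.01)$seq
        utr5b <- mutate_seq(utr5, params$utr_divergence_paralog)$seq
        utr3b <- mutate_seq(utr3, params$utr_divergence_paralog)$seq
        p1 <- paste0(utr5b, cds2, utr3b)
        data.frame(
          gene_id = paste0(reference$gene_id[i], "P"),
          hap1 = p1, hap2 = mutate_seq(p1, het_rate[i])$seq,
          cds_start = cs, cds_end = ce,
          source_gene = reference$gene_id[i], is_paralog = TRUE,
          stringsAsFactors = FALSE)
      })
      paralog_map <- setNames(lapply(prow, function(d) d$gene_id),
                              reference$gene_id[par_of])
      tx <- rbind(tx, do.call(rbind, prow))
    }

    nt <- nrow(tx)
    samples <- pipeline_samples()
    base <- rlnorm(nt, meanlog = log(50), sdlog = 1.2)
    # paralogs expressed lower than their parent
    base[tx$is_paralog] <- 0.3 * base[match(tx$source_gene, tx$gene_id)][tx$is_paralog]
    labels <- rep("null", nt)
    # DE genes are planted on transcripts expressed well enough that even
    # the downregulated morph stays at RPKM >= ~20 (threshold methods
    # cannot recover differential calls from near-filter counts; the real
    # flagship gene, CHS, sits in the top percentiles of expression)
    # ... and on genes whose library share stays bounded: RPKM-ratio fold
    # estimation assumes differential genes are a minor fraction of the
    # library (in the emulated study they are ~0.3% of genes), so at desk
    # scale the planted set must not dominate the read pool either
    len_all <- nchar(tx$hap1)
    base_rpkm <- base * 1e9 / sum(base * len_all)
    exp_count <- params$reads_per_sample * base * len_all / sum(base * len_all)
    floor_count <- 20  # twice the downstream 10-read filter
    pool <- function(adj, need, exclude = integer(0)) {
      lo <- which(!tx$is_paralog & base_rpkm >= 20 * adj &
                    exp_count >= floor_count * adj)
      lo <- setdiff(lo, exclude)
      capped <- lo[exp_count[lo] <= 10 * floor_count * adj]
      # the share cap only matters at scale; small worlds fall back to the
      # detectability floor alone
      if (length(capped) >= need) capped else lo
    }
    eligible_pw <- pool(1, params$n_pw)
    if (params$n_pw > length(eligible_pw))
      stop_arg("too many planted P>W genes for this world")
    pw <- eligible_pw[sample.int(length(eligible_pw), params$n_pw)]
    eligible_wp <- pool(params$de_fold, params$n_wp, exclude = pw)
    if (params$n_wp > length(eligible_wp))
      stop_arg("too many planted W>P genes for this world")
    wp <- eligible_wp[sample.int(length(eligible_wp), params$n_wp)]
    de <- c(pw, wp)
    labels[pw] <- "P>W"; labels[wp] <- "W>P"
    chs_gene <- if (params$n_pw > 0) tx$gene_id[pw[1]] else NA_character_

    fold <- matrix(1, nt, 2, dimnames = list(tx$gene_id, c("SR", "MS")))
    jit <- function(k) exp(rnorm(k, 0, 0.05))
    fold[pw, "SR"] <- params$de_fold * jit(length(pw))
    fold[pw, "MS"] <- params$de_fold * jit(length(pw))
    fold[wp, "SR"] <- (1 / params$de_fold) * jit(length(wp))
    fold[wp, "MS"] <- (1 / params$de_fold) * jit(length(wp))
    if (!is.na(chs_gene)) {
      fold[pw[1], "SR"] <- params$chs_fold * exp(rnorm(1, 0, 0.05))
      fold[pw[1], "MS"] <- params$chs_fold * exp(rnorm(1, 0, 0.05))
    }

    noise <- function(k) exp(rnorm(k, 0, params$sample_noise_sd))
    levels <- cbind(
      SR_P = base * fold[, "SR"] * noise(nt),
      SR_W = base * noise(nt),
      MS_P = base * fold[, "MS"] * noise(nt),
      MS_W = base * noise(nt))
    rownames(levels) <- tx$gene_id

    list(transcriptome = tx,
         ground_truth = list(
           levels = levels, fold_change = fold, labels = labels,
           divergence = setNames(realized_div, reference$gene_id),
           het_rate = setNames(het_rate, reference$gene_id),
           paralog_map = paralog_map, chs_gene = chs_gene))
  })
}

#' Simulate single-end reads for one sample
#'
#' Reads are drawn gene-by-gene with probability proportional to true level
#' times transcript length, from a random haplotype, with fragment start
#' positions weighted exponentially toward the 3' end when
#' `bias3p_strength > 0` (a one-knob stand-in for poly-A selection bias), and
#' per-base substitution errors at `error_rate`.
#'
#' @param transcriptome,ground_truth from [mutate_transcriptome()].
#' @param sample_id one of [pipeline_samples()].
#' @param params a [sim_params()] object.
#' @param seed RNG seed.
#' @return list with `reads` (named character vector, length
#'   `reads_per_sample`) and `truth` (data.frame: `read_id`, `gene_id`,
#'   `hap`, `start`).
#' @export
simulate_reads <- function(transcriptome, ground_truth, sample_id,
                           params = sim_params(), seed = NULL) {
  if (nrow(transcriptome) == 0) stop_arg("empty transcriptome")
  if (!sample_id %in% colnames(ground_truth$levels))
    stop_arg("unknown sample_id: ", sample_id)
  rl <- params$read_length
  len <- nchar(transcriptome$hap1)
  usable <- len >= rl
  if (!any(usable)) stop_arg("no transcript is long enough for read_length")
  with_seed(seed, {
    w <- ground_truth$levels[transcriptome$gene_id, sample_id] * len
    w[!usable] <- 0
    n <- params$reads_per_sample
    gi <- sample.int(nrow(transcriptome), n, replace = TRUE, prob = w)
    hap <- 1L + rbinom(n, 1L, 0.5)
    span <- len[gi] - rl  # max start (0-based)
    u <- runif(n)
    b <- params$bias3p_strength
    start <- if (b > 0) floor((span + 1) * log1p(u * expm1(b)) / b)
             else floor(u * (span + 1))
    start <- pmin(start, span)
    src <- ifelse(hap == 1L, transcriptome$hap1[gi], transcriptome$hap2[gi])
    reads <- substr(src, start + 1L, start + rl)
    # sequencing errors
    ne <- rbinom(n, rl, params$error_rate)
    for (i in which(ne > 0L)) {
      pos <- sample.int(rl, ne[i])
      ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      reads[i] <- paste(ch, collapse = "")
    }
    ids <- sprintf("%s_r%07d", sample_id, seq_len(n))
    list(reads = setNames(reads, ids),
         truth = data.frame(read_id = ids,
                            gene_id = transcriptome$gene_id[gi],
                            hap = hap, start = start,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate multi-kmer contig assemblies
#'
#' Emulates the output of a de Bruijn assembler run per sample and per kmer:
#' each gene yields 1-11 contigs per kmer, with smaller kmers recovering a
#' larger covered fraction of the gene (so smaller kmers tend to produce the
#' longest assemblies). Contigs are substrings of a randomly chosen
#' haplotype; a `chimera_rate` fraction instead concatenate fragments of two
#' genes.
#'
#' @param transcriptome from [mutate_transcriptome()].
#' @param kmer_list integer kmer values.
#' @param params a [sim_params()] object.
#' @param sample_ids labels of samples to generate contigs for.
#' @param seed RNG seed.
#' @return data.frame: `contig_id`, `sample`, `kmer`, `sequence`,
#'   `true_gene`, `is_chimera`, `true_gene2`.
#' @export
simulate_contigs <- function(transcriptome, kmer_list = NULL,
                             params = sim_params(),
                             sample_ids = c("P", "W"), seed = NULL) {
  if (is.null(kmer_list)) kmer_list <- params$kmer_list
  if (length(kmer_list) == 0) stop_arg("kmer_list must be non-empty")
  with_seed(seed, {
    out <- vector("list", 0)
    counter <- 0L
    kmin <- min(kmer_list)
    for (s in sample_ids) for (k in kmer_list) {
      for (i in seq_len(nrow(transcriptome))) {
        glen <- nchar(transcriptome$hap1[i])
        nc <- 1L + min(rpois(1, params$mean_contigs_per_gene - 1), 10L)
        f0 <- max(0.30, 0.95 - 0.035 * (k - kmin))
        f <- stats::rbeta(1, 25 * f0, 25 * (1 - f0))
        total <- max(round(f * glen), min(glen, k + 20L))
        # split the covered length over nc pieces inside nc equal blocks
        piece <- as.vector(stats::rmultinom(1, total, rep(1 / nc, nc)))
        block <- floor(glen / nc)
        for (j in seq_len(nc)) {
          plen <- min(max(piece[j], k + 10L), block)
          if (plen < k + 5L) next
          lo <- (j - 1L) * block
          st <- lo + sample.int(block - plen + 1L, 1L) - 1L
          hap <- if (runif(1) < 0.5) transcriptome$hap1[i] else transcriptome$hap2[i]
          sq <- substr(hap, st + 1L, st + plen)
          counter <- counter + 1L
          chim <- runif(1) < params$chimera_rate && nrow(transcriptome) > 1L
          g2 <- NA_character_
          if (chim) {
            oth <- sample(setdiff(seq_len(nrow(transcriptome)), i), 1L)
            ol <- nchar(transcriptome$hap1[oth])
            fl <- min(ol, max(k + 10L, floor(plen / 2)))
            fs <- sample.int(ol - fl + 1L, 1L) - 1L
            frag <- substr(transcriptome$hap1[oth], fs + 1L, fs + fl)
            sq <- paste0(substr(sq, 1L, max(k + 10L, floor(plen / 2))), frag)
            g2 <- transcriptome$gene_id[oth]
          }
          out[[length(out) + 1L]] <- data.frame(
            contig_id = sprintf("CTG%s_k%02d_%06d", s, k, counter),
            sample = s, kmer = k, sequence = sq,
            true_gene = transcriptome$gene_id[i],
            is_chimera = chim, true_gene2 = g2,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Generate a flat GO annotation table
#'
#' Every gene receives each term independently at its background frequency;
#' genes named in `enriched_term_spec$de_genes` receive the designated term
#' at an elevated frequency instead, planting a known enrichment signal.
#'
#' @param gene_ids character vector of annotated genes.
#' @param n_terms number of GO terms (>= 1).
#' @param enriched_term_spec optional list with elements `term`,
#'   `background`, `de_freq`, `de_genes`.
#' @param background_freq per-term background annotation frequency, recycled
#'   over terms.
#' @param seed RNG seed.
#' @return data.frame with columns `gene_id`, `term_id`.
#' @export
generate_go_annotations <- function(gene_ids, n_terms = 50,
                                    enriched_term_spec = NULL,
                                    background_freq = 0.05, seed = NULL) {
  if (n_terms < 1) stop_arg("n_terms must be >= 1")
  with_seed(seed, {
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    bg <- rep_len(background_freq, n_terms)
    rows <- vector("list", n_terms)
    for (t in seq_len(n_terms)) {
      p <- rep(bg[t], length(gene_ids))
      if (!is.null(enriched_term_spec) && terms[t] == enriched_term_spec$term)
        p[gene_ids %in% enriched_term_spec$de_genes] <- enriched_term_spec$de_freq
      hit <- runif(length(gene_ids)) < p
      if (any(hit))
        rows[[t]] <- data.frame(gene_id = gene_ids[hit], term_id = terms[t],
                                stringsAsFactors = FALSE)
    }
    if (!is.null(enriched_term_spec) &&
        !enriched_term_spec$term %in% terms) {
      p <- rep(enriched_term_spec$background, length(gene_ids))
      p[gene_ids %in% enriched_term_spec$de_genes] <- enriched_term_spec$de_freq
      hit <- runif(length(gene_ids)) < p
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_ids[hit], term_id = enriched_term_spec$term,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out[order(out$gene_id, out$term_id), , drop = FALSE]
  })
}

#' Simulate a qRT-PCR CT table from ground-truth expression
#'
#' CT values decrease log-linearly with true expression at the given
#' amplification efficiency; the endogenous control is constant across
#' samples up to measurement noise.
#'
#' @param ground_truth from [mutate_transcriptome()].
#' @param genes gene ids to assay.
#' @param efficiency amplification efficiency E (fold change per cycle is
#'   1 + E).
#' @param ct_noise sd of CT measurement noise, in cycles.
#' @param seed RNG seed.
#' @return data.frame: `sample`, `gene`, `ct_target`, `ct_control`,
#'   `efficiency`.
#' @export
simulate_qpcr_table <- function(ground_truth, genes, efficiency = 0.963,
                                ct_noise = 0.15, seed = NULL) {
  with_seed(seed, {
    samples <- colnames(ground_truth$levels)
    grid <- expand.grid(gene = genes, sample = samples,
                        stringsAsFactors = FALSE)
    lev <- ground_truth$levels[cbind(grid$gene, grid$sample)]
    data.frame(
      sample = grid$sample, gene = grid$gene,
      ct_target = 30 - log(lev) / log1p(efficiency) +
        rnorm(nrow(grid), 0, ct_noise),
      ct_control = 20 + rnorm(nrow(grid), 0, ct_noise),
      efficiency = efficiency, stringsAsFactors = FALSE)
  })
}
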