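# shared fixture builders (all data generated in code)

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small synthetic world reused across module tests
make_world <- function(n_genes = 12, reads_per_sample = 4000, seed = 42,
                       n_pw = 1L, n_wp = 2L, ...) {
  p <- sim_params(n_genes = n_genes, reads_per_sample = reads_per_sample,
                  n_pw = n_pw, n_wp = n_wp, ...)
  ref <- generate_reference(n_genes, seed = seed)
  mt <- mutate_transcriptome(ref, p, seed = seed + 1L)
  list(params = p, reference = ref, transcriptome = mt$transcriptome,
       ground_truth = mt$ground_truth)
}

# idealized consensus (both haplotypes, full coverage) for mapping tests
world_consensus <- function(w) {
  tx <- w$transcriptome
  setNames(mapply(consensus_from_haplotypes, tx$hap1, tx$hap2), tx$gene_id)
}
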