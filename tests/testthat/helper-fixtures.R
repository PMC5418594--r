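# shared fixture helpers; all data is generated in code

random_dna <- function(n, seed = NULL, gc = 0.44) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# substitute exactly k bases (deterministic under the ambient RNG)
substitute_bases <- function(s, k) {
  pos <- sample.int(nchar(s), k)
  b <- charToRaw(s)
  for (i in pos) {
    alt <- setdiff(charToRaw("ACGT"), b[i])
    b[i] <- alt[sample.int(length(alt), 1)]
  }
  rawToChar(b)
}

# a single-row overlap record as classify_overlap() would emit it
fake_overlap <- function(fosmid_id, wgs_id, wgs_end, f_start, f_end,
                         identity, matched_len, f_len = 40000,
                         strand = "+", overhang = 0) {
  data.frame(wgs_id = wgs_id, wgs_end = wgs_end, fosmid_id = fosmid_id,
             f_start = f_start, f_end = f_end, f_len = f_len,
             strand = strand, identity = identity, matched_len = matched_len,
             overhang = overhang, accepted = TRUE, reason = "ok",
             stringsAsFactors = FALSE)
}

# a small simulated scenario for pipeline-level tests
small_scenario <- function(seed = 1, n_chrom = 2, chrom_len = 250000,
                           n_contigs = 8, n_fosmids = 40,
                           chimera_rate = 0, sub_error_rate = 0,
                           unanchored_rate = 0, unoriented_rate = 0,
                           misorder_rate = 0) {
  truth <- simulate_genome(seed, n_chrom = n_chrom, chrom_len = chrom_len)
  truth <- shred_wgs(truth, n_contigs = n_contigs,
                     chimera_rate = chimera_rate,
                     sub_error_rate = sub_error_rate)
  truth <- simulate_fosmids(truth, n = n_fosmids)
  simulate_anchors(truth, misorder_rate = misorder_rate,
                   unoriented_rate = unoriented_rate,
                   unanchored_rate = unanchored_rate)
}
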