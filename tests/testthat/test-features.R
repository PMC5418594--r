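test_that("telomere arrays are found at chromosome ends, on both strands", {
  set.seed(101)
  body <- random_dna(100000)
  s <- paste0(body, strrep("TTTAGGG", 50))
  arr <- find_telomere_arrays(s, min_copies = 10)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$copies, 50, tolerance = 0.05)
  expect_gte(arr$start, 100000 - 7)
  # mirrored on the reverse complement
  arr_rc <- find_telomere_arrays(revcomp(s), min_copies = 10)
  expect_equal(nrow(arr_rc), 1)
  expect_lte(arr_rc$start, 7)
  expect_equal(arr_rc$end - arr_rc$start, arr$end - arr$start)
})

test_that("random sequence and short arrays stay below the copy threshold", {
  set.seed(102)
  expect_equal(nrow(find_telomere_arrays(random_dna(100000), min_copies = 10)),
               0)
  s <- paste0(random_dna(5000), strrep("AAACCCT", 5), random_dna(5000))
  expect_equal(nrow(find_telomere_arrays(s, min_copies = 10)), 0)
})

test_that("tandem arrays of an arbitrary unit are found despite divergence", {
  set.seed(103)
  unit <- random_dna(155)
  arr_seq <- paste(vapply(1:30, function(i) substitute_bases(unit, 3),
                          character(1)), collapse = "")
  s <- paste0(random_dna(20000), arr_seq, random_dna(20000))
  arr <- find_repeat_arrays(s, unit, min_full_units = 2, min_identity = 0.95)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$copies, 30, tolerance = 0.05)
  # a single copy is not an array
  s1 <- paste0(random_dna(5000), unit, random_dna(5000))
  expect_equal(nrow(find_repeat_arrays(s1, unit, min_full_units = 2)), 0)
  # two distant arrays are not merged
  s2 <- paste0(strrep(unit, 5), random_dna(50000), strrep(unit, 5))
  expect_equal(nrow(find_repeat_arrays(s2, unit, min_full_units = 2)), 2)
  expect_error(find_repeat_arrays(s2, ""), "empty")
})

test_that("circularize trims one terminal repeat copy and normalizes rotation", {
  set.seed(104)
  core <- random_dna(30000)
  ctg <- paste0(core, substr(core, 1, 2000))
  cc <- circularize(ctg, min_overlap = 1000)
  expect_equal(cc$length, 30000)
  expect_equal(cc$trimmed, 2000)
  # rotation-normalized: starting the construct elsewhere gives the same circle
  rot <- paste0(substr(core, 10001, 30000), substr(core, 1, 10000))
  ctg2 <- paste0(rot, substr(rot, 1, 2000))
  cc2 <- circularize(ctg2, min_overlap = 1000)
  expect_equal(cc2$sequence, cc$sequence)
})

test_that("circularize handles organelle-scale constructs and edge cases", {
  set.seed(105)
  core <- random_dna(134546)
  cc <- circularize(paste0(core, substr(core, 1, 2000)), min_overlap = 1000)
  expect_equal(cc$length, 134546)
  expect_null(circularize(random_dna(30000), min_overlap = 1000))
  # a sequence that is half tandem repeat is not a circle
  half <- random_dna(10000)
  expect_error(circularize(paste0(half, half, substr(half, 1, 9000))),
               "tandem")
})

test_that("placement verdicts follow the examination rules", {
  ct <- list(id = "c1", length = 50000)
  mk <- function(q_start, q_end, t_start, identity, class = "assembly",
                 target = "chr1") {
    data.frame(query_id = "c1", target_id = target, strand = "+",
               q_start = q_start, q_end = q_end, q_len = 50000,
               t_start = t_start, t_end = t_start + (q_end - q_start),
               t_len = 10000000,
               matches = round(identity * (q_end - q_start)),
               aln_len = q_end - q_start, identity = identity,
               target_class = class, stringsAsFactors = FALSE)
  }
  # 96% coverage at 98% identity, clean ends: incorporated
  r1 <- classify_placement(ct, mk(1000, 49000, 500000, 0.98))
  expect_equal(r1$verdict, "incorporated")
  # two distant blocks: erroneous
  r2 <- classify_placement(ct, rbind(mk(0, 25000, 500000, 0.99),
                                     mk(25000, 50000, 7000000, 0.99)))
  expect_equal(r2$verdict, "erroneous")
  # single block with a 1.5 kb overhang and low coverage: erroneous
  r3 <- classify_placement(ct, mk(1500, 40000, 500000, 0.99))
  expect_equal(r3$verdict, "erroneous")
  # organelle-covered contig
  r4 <- classify_placement(ct, mk(0, 48000, 1000, 0.96, class = "organelle"))
  expect_equal(r4$verdict, "organelle")
  # nothing aligned
  r5 <- classify_placement(ct, mk(0, 1, 0, 0.99)[0, ])
  expect_equal(r5$verdict, "unclassified")
})

test_that("PV calling applies the block, gap, length and coverage rules", {
  p <- fb_params()
  blocks <- data.frame(ref_chrom = "r1", ref_start = c(0, 10600),
                       ref_end = c(10000, 20000),
                       qry_chrom = "q1", qry_start = c(0, 10000),
                       qry_end = c(10000, 19400), stringsAsFactors = FALSE)
  pv <- call_pv(blocks, side = "ref", params = p)
  expect_equal(nrow(pv), 1)
  expect_equal(pv$length, 600)
  expect_equal(c(pv$start, pv$end), c(10000, 10600))
  # a 300-base gap is recorded as gap but is below the 500 bp PV floor
  blocks2 <- blocks; blocks2$ref_start[2] <- 10300
  expect_equal(nrow(call_pv(blocks2, side = "ref", params = p)), 0)
  # identical genomes, one full-length block: no PV
  blocks3 <- data.frame(ref_chrom = "r1", ref_start = 0, ref_end = 50000,
                        qry_chrom = "q1", qry_start = 0, qry_end = 50000)
  expect_equal(nrow(call_pv(blocks3, side = "ref", params = p)), 0)
  # overlapping blocks are rejected
  blocks4 <- blocks; blocks4$ref_start[2] <- 9000
  expect_error(call_pv(blocks4, side = "ref", params = p), "overlapping")
})

test_that("homology subtraction and the coverage filter remove candidates", {
  set.seed(106)
  p <- fb_params()
  shared <- random_dna(30000)
  insert <- random_dna(2000)
  ga <- paste0(substr(shared, 1, 15000), insert, substr(shared, 15001, 30000))
  blocks <- data.frame(ref_chrom = "ga", ref_start = c(0, 17000),
                       ref_end = c(15000, 32000), qry_chrom = "gb",
                       qry_start = c(0, 15000), qry_end = c(15000, 30000))
  # the insert is genuinely absent from gb: PV survives subtraction
  pv <- call_pv(blocks, side = "ref", self_genome = c(ga = ga),
                other_genome = c(gb = shared), params = p)
  expect_equal(nrow(pv), 1)
  expect_equal(pv$length, 2000)
  # the same interval filled with gb sequence is homology-subtracted away
  ga2 <- paste0(substr(shared, 1, 15000), revcomp(substr(shared, 5001, 7000)),
                substr(shared, 15001, 30000))
  pv2 <- call_pv(blocks, side = "ref", self_genome = c(ga = ga2),
                 other_genome = c(gb = shared), params = p)
  expect_equal(nrow(pv2), 0)
  # short-read coverage above 25% removes a candidate
  cov <- list(ga = rep(1, nchar(ga)))
  pv3 <- call_pv(blocks, side = "ref", coverage = cov, params = p)
  expect_equal(nrow(pv3), 0)
  cov$ga[15001:17000] <- 0
  pv4 <- call_pv(blocks, side = "ref", coverage = cov, params = p)
  expect_equal(nrow(pv4), 1)
})

test_that("PV calling of a genome against itself is empty", {
  set.seed(107)
  g <- random_dna(60000)
  blocks <- data.frame(ref_chrom = "g", ref_start = 0, ref_end = 60000,
                       qry_chrom = "g", qry_start = 0, qry_end = 60000)
  expect_equal(nrow(call_pv(blocks, side = "ref", self_genome = c(g = g),
                            other_genome = c(g = g))), 0)
})

test_that("PV sharing is reciprocal at 75% and symmetric", {
  a <- data.frame(chrom = "c", start = 1000, end = 2000)
  b <- data.frame(chrom = "c", start = 1100, end = 2100)
  expect_equal(nrow(shared_pv(a, b)), 1)       # 900/1000 both ways
  b2 <- data.frame(chrom = "c", start = 1800, end = 2800)
  expect_equal(nrow(shared_pv(a, b2)), 0)      # 200/1000
  expect_equal(nrow(shared_pv(a, a)), 1)       # identical intervals share
  # one-sided containment is not sharing
  big <- data.frame(chrom = "c", start = 0, end = 10000)
  expect_equal(nrow(shared_pv(a, big)), 0)
  expect_equal(nrow(shared_pv(big, a)), 0)
})
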