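test_that("emit_sequence joins across positive and negative junctions", {
  set.seed(51)
  A <- random_dna(10000); B <- random_dna(8000); bridge <- random_dna(3000)
  fos <- contig_set("f1", paste0(substr(A, 4001, 10000), bridge,
                                 substr(B, 1, 6000)), source = "fosmid")
  ct <- contig_set(c("A", "B"), c(A, B))
  e <- make_edge(fake_overlap("f1", "A", "R", 0, 6000, 1, 6000, f_len = 15000),
                 fake_overlap("f1", "B", "L", 9000, 15000, 1, 6000,
                              f_len = 15000))
  em <- emit_sequence(data.frame(contig_id = c("A", "B"),
                                 orient = c("+", "+"),
                                 stringsAsFactors = FALSE), e, ct, fos)
  expect_equal(nchar(em$sequence), 21000)
  expect_equal(em$sequence, paste0(A, bridge, B))
  expect_equal(em$junctions$gap, 3000)

  # negative junction: A and B share 2,000 bases; fosmid provides the overlap
  set.seed(52)
  g <- random_dna(16000)
  A2 <- substr(g, 1, 10000); B2 <- substr(g, 8001, 16000)
  f2 <- contig_set("f2", substr(g, 3001, 14000), source = "fosmid")
  ct2 <- contig_set(c("A", "B"), c(A2, B2))
  e2 <- make_edge(fake_overlap("f2", "A", "R", 0, 7000, 1, 7000, f_len = 11000),
                  fake_overlap("f2", "B", "L", 5000, 11000, 1, 6000,
                               f_len = 11000))
  expect_equal(e2$length, -2000)
  em2 <- emit_sequence(data.frame(contig_id = c("A", "B"),
                                  orient = c("+", "+"),
                                  stringsAsFactors = FALSE), e2, ct2, f2)
  expect_equal(nchar(em2$sequence), 16000)
  expect_equal(em2$sequence, g)
  # the 2,000-base junction region came from the fosmid
  expect_equal(substr(em2$sequence, em2$junctions$j_start + 1,
                      em2$junctions$j_end),
               substr(f2$sequence, 5001, 7000))
})

test_that("emit_sequence leaves a single segment unchanged and checks bounds", {
  ct <- contig_set("A", random_dna(5000, seed = 53))
  em <- emit_sequence(data.frame(contig_id = "A", orient = "+",
                                 stringsAsFactors = FALSE),
                      fosbridge:::empty_edges()[0, ], ct,
                      contig_set("f", "ACGTACGTACGT", source = "fosmid"))
  expect_equal(em$sequence, ct$sequence)

  e_bad <- make_edge(fake_overlap("f", "A", "R", 0, 6000, 1, 6000,
                                  f_len = 50000),
                     fake_overlap("f", "B", "L", 30000, 50000, 1, 10000,
                                  f_len = 50000))
  ct2 <- contig_set(c("A", "B"), c(random_dna(10000), random_dna(10000)))
  expect_error(
    emit_sequence(data.frame(contig_id = c("A", "B"), orient = c("+", "+"),
                             stringsAsFactors = FALSE), e_bad, ct2,
                  contig_set("f", "ACGT", source = "fosmid")),
    "fosmid")
})

test_that("split_chimera applies the 30 kb reuse rule and validates breakpoints", {
  p <- fb_params()
  ct <- contig_set("chim", random_dna(80000, seed = 54))
  call <- data.frame(contig_id = "chim", breakpoint = 45000,
                     stringsAsFactors = FALSE)
  sp <- split_chimera(ct, call, p)
  expect_equal(sp$pieces$length, c(45000, 35000))
  expect_true(all(sp$pieces$reusable))
  expect_setequal(sp$contigs$id, c("chim.p1", "chim.p2"))
  expect_equal(sp$contigs$source, rep("derived-split", 2))
  # piece of 20 kb is retired from reuse
  sp2 <- split_chimera(ct, data.frame(contig_id = "chim", breakpoint = 60000),
                       p)
  expect_equal(sp2$pieces$reusable, c(TRUE, FALSE))
  expect_equal(sp2$contigs$id, "chim.p1")
  expect_error(split_chimera(ct, data.frame(contig_id = "chim",
                                            breakpoint = 0)), "strictly inside")
  expect_error(split_chimera(ct, data.frame(contig_id = "chim",
                                            breakpoint = 80000)),
               "strictly inside")
})

test_that("a terminal overlap with small overhang is a join, not a chimera", {
  set.seed(55)
  g <- random_dna(160000)
  A <- substr(g, 1, 90000); B <- substr(g, 84001, 160000)
  ct <- contig_set(c("A", "B"), c(A, B))
  ws <- find_overlaps(ct, ct, min_len = 5000, min_identity = 0.9)
  calls <- detect_chimeras(ws, fosbridge:::empty_edges()[0, ],
                           ws[0, ], fb_params())
  expect_equal(nrow(calls), 0)
})

test_that("a fosmid-supported mid-contig overlap is called at the fusion point", {
  set.seed(56)
  chrA <- random_dna(200000)
  chrB <- random_dna(120000)
  X <- substr(chrA, 60001, 120000)        # 60 kb piece of chrA
  Y <- substr(chrB, 30001, 95000)         # 65 kb piece of chrB
  chim <- paste0(X, Y)
  # the true right neighbour of X overlaps X's suffix by 8 kb
  R <- substr(chrA, 112001, 190000)
  ct <- contig_set(c("chim", "R"), c(chim, R))
  fos <- contig_set("f1", substr(chrA, 100001, 136000), source = "fosmid")
  fa <- find_overlaps(fos, ct, min_len = 5000, min_identity = 0.9)
  ov <- classify_overlap(fa, 0.97, fb_params())
  ws <- find_overlaps(ct, ct, min_len = 5000, min_identity = 0.9)
  calls <- detect_chimeras(ws, ov, fa, fb_params())
  expect_equal(nrow(calls), 1)
  expect_equal(calls$contig_id, "chim")
  expect_equal(calls$breakpoint, 60000, tolerance = 5e-4)
  # without fosmid support there is no call
  calls2 <- detect_chimeras(ws, ov[0, ], fa[0, ], fb_params())
  expect_equal(nrow(calls2), 0)
})

test_that("merge_pass skips conflicting equal-weight partners", {
  wgs <- contig_set(c("A", "B", "C"),
                    c(random_dna(20000, seed = 57), random_dna(20000),
                      random_dna(20000)))
  anchors <- data.frame(contig_id = c("A", "B", "C"), lg_id = "LG1",
                        order_index = 1:3, cm_position = 1:3,
                        orientation = "+", stringsAsFactors = FALSE)
  # B's right end is courted by A and C with identical weighted scores
  eBA <- make_edge(fake_overlap("f1", "B", "R", 0, 6000, 1, 6000),
                   fake_overlap("f1", "A", "L", 30000, 40000, 1, 6000))
  eBC <- make_edge(fake_overlap("f2", "B", "R", 0, 6000, 1, 6000),
                   fake_overlap("f2", "C", "L", 30000, 40000, 1, 6000))
  g <- build_graph(wgs, anchors, rbind(eBA, eBC))
  g2 <- merge_pass(g, 0.98, "lg_any")
  expect_equal(nrow(g2$junctions), 0)
  expect_equal(fosbridge:::end_state(g2, "B", "R"), "open")
})

test_that("equal-score conflicts resolve to the shortest edge with unanchored nodes", {
  wgs <- contig_set(c("A", "U1", "U2"),
                    c(random_dna(20000, seed = 58), random_dna(20000),
                      random_dna(20000)))
  anchors <- data.frame(contig_id = "A", lg_id = "LG1", order_index = 1L,
                        cm_position = 0, orientation = "+",
                        stringsAsFactors = FALSE)
  # same scores; U1 via a 3 kb edge, U2 via a 7 kb edge
  e1 <- make_edge(fake_overlap("f1", "A", "R", 0, 6000, 1, 6000),
                  fake_overlap("f1", "U1", "L", 9000, 15000, 1, 6000))
  e2 <- make_edge(fake_overlap("f2", "A", "R", 0, 6000, 1, 6000),
                  fake_overlap("f2", "U2", "L", 13000, 19000, 1, 6000))
  expect_equal(c(e1$length, e2$length), c(3000, 7000))
  expect_equal(e1$score, e2$score)
  g <- build_graph(wgs, anchors, rbind(e1, e2))
  g2 <- merge_pass(g, 0.98, "include_unanchored")
  expect_equal(nrow(g2$junctions), 1)
  expect_equal(sort(c(g2$junctions$left_id, g2$junctions$right_id)),
               c("A", "U1"))
})

test_that("a graph with zero edges yields one super-contig per contig", {
  wgs <- contig_set(c("A", "B", "C"),
                    c(random_dna(12000, seed = 59), random_dna(12000),
                      random_dna(12000)))
  fos <- contig_set("f", random_dna(36000), source = "fosmid")
  res <- run_pipeline(wgs, fos, NULL)
  expect_equal(length(res$supercontigs), 3)
  expect_setequal(unlist(lapply(res$supercontigs,
                                function(s) s$segments$contig_id)),
                  c("A", "B", "C"))
})

test_that("build_pseudomolecules concatenates map-ordered super-contigs with N gaps", {
  sc <- function(id, lg, ord, seq) list(id = id, lg = lg, mean_order = ord,
                                        segments = data.frame(), junctions = data.frame(),
                                        sequence = seq)
  s1 <- sc("sc_001", "LG1", 1, random_dna(100000, seed = 60))
  s2 <- sc("sc_002", "LG1", 5, random_dna(200000))
  ps <- build_pseudomolecules(list(s1, s2), gap_n = 10000)
  expect_equal(nchar(ps$sequences[["LG1"]]), 310000)
  expect_equal(substr(ps$sequences[["LG1"]], 100001, 110000),
               strrep("N", 10000))
  # single super-contig: unchanged, no Ns
  ps2 <- build_pseudomolecules(list(s1), gap_n = 10000)
  expect_equal(ps2$sequences[["LG1"]], s1$sequence)
  # conservation: total length = supercontig lengths + gap_n * joins
  s3 <- sc("sc_003", "LG2", 1, random_dna(50000))
  ps3 <- build_pseudomolecules(list(s1, s2, s3), gap_n = 10000)
  expect_equal(sum(nchar(ps3$sequences)),
               100000 + 200000 + 50000 + 10000 * 1)
})

test_that("emitted length obeys signed conservation over junction gaps", {
  truth <- small_scenario(seed = 61)
  res <- run_pipeline(truth$wgs, truth$fosmids, truth$anchors)
  for (sc in res$supercontigs) {
    seg_len <- sum(vapply(sc$segments$contig_id, function(id)
      res$contigs$length[match(id, res$contigs$id)], numeric(1)))
    expected <- seg_len + sum(sc$junctions$gap)
    expect_equal(nchar(sc$sequence), expected)
  }
})
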