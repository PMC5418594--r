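test_that("digest records motif starts on both strands, sorted and unique", {
  s <- random_dna(1000, seed = 91)
  s <- gsub("GCTCTTC|GAAGAGC", "AAAAAAA", s)  # scrub accidental sites
  substr(s, 101, 107) <- "GCTCTTC"
  substr(s, 701, 707) <- "GCTCTTC"
  nm <- digest(s)
  expect_equal(nm$sites, c(100, 700))
  substr(s, 301, 307) <- "GAAGAGC"            # reverse-strand site
  expect_equal(digest(s)$sites, c(100, 300, 700))
  # no motif anywhere
  expect_equal(length(digest(strrep("AC", 500))$sites), 0)
  expect_error(digest(s, motif = "GCTNTTC"), "ACGT")
})

test_that("digest sites mirror under reverse complement", {
  set.seed(92)
  for (i in 1:5) {
    s <- random_dna(20000)
    fwd <- digest(s)$sites
    rev <- digest(revcomp(s))$sites
    expect_equal(sort(nchar(s) - fwd - 7), rev)
  }
})

test_that("a map aligns to itself with every site paired and zero residuals", {
  s <- random_dna(300000, seed = 93)
  nm <- digest(s, id = "m")
  aln <- align_nickmaps(nm, nm)
  expect_equal(nrow(aln$pairs), length(nm$sites))
  expect_equal(aln$pairs$q_pos, aln$pairs$r_pos)
  expect_equal(nrow(call_indels(aln)), 0)
})

test_that("alignment score is symmetric under query/ref exchange", {
  s <- random_dna(250000, seed = 94)
  a <- digest(substr(s, 1, 200000), id = "a")
  b <- digest(substr(s, 30001, 250000), id = "b")
  ab <- align_nickmaps(a, b)
  ba <- align_nickmaps(b, a)
  expect_equal(ab$score, ba$score, tolerance = 1e-9)
})

test_that("an internal deletion appears as one interval difference", {
  s <- random_dna(400000, seed = 95)
  ref <- digest(s, id = "ref")
  qry <- digest(paste0(substr(s, 1, 200000), substr(s, 215001, 400000)),
                id = "qry")
  aln <- align_nickmaps(qry, ref)
  calls <- call_indels(aln)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$size, 15000)
  expect_equal(calls$kind, "insertion")  # the reference has the extra 15 kb
  expect_equal(calls$size_class, "large")
})

test_that("a missing label is skipped without creating an indel", {
  s <- random_dna(300000, seed = 96)
  ref <- digest(s, id = "ref")
  sites <- ref$sites[-floor(length(ref$sites) / 2)]
  qry <- nickmap("qry", ref$length, sites)
  aln <- align_nickmaps(qry, ref)
  expect_equal(nrow(call_indels(aln)), 0)
  expect_equal(nrow(aln$pairs), length(sites))
})

test_that("call_indels applies the 1 kb floor and the 10 kb class boundary", {
  mkaln <- function(diffs) {
    r_pos <- cumsum(c(10000, 20000 + diffs))
    q_pos <- cumsum(c(10000, rep(20000, length(diffs))))
    structure(list(query_id = "q", ref_id = "r", strand = "+", score = 1,
                   pairs = data.frame(qi = seq_along(r_pos),
                                      ri = seq_along(r_pos),
                                      q_pos = q_pos, r_pos = r_pos)),
              class = "fb_mapaln")
  }
  expect_equal(call_indels(mkaln(5000))$size_class, "mid")
  expect_equal(call_indels(mkaln(15000))$size_class, "large")
  expect_equal(nrow(call_indels(mkaln(800))), 0)
  expect_equal(call_indels(mkaln(-5000))$kind, "deletion")
})

test_that("connection coverage and flag fractions follow the definitions", {
  set.seed(97)
  s <- random_dna(500000)
  asm <- paste0(substr(s, 1, 250000), substr(s, 253001, 500000))  # 3 kb deletion
  ref <- digest(asm, id = "pm1")
  # ten junctions; nine inside the aligned span (one of them at the
  # deletion), one beyond it
  jn <- data.frame(ref_id = "pm1",
                   pos = c(seq(40000, 240000, length.out = 8), 250000, 496000))
  mol <- digest(substr(s, 10001, 300000), id = "mol")
  aln <- align_nickmaps(mol, ref)
  cc <- connection_coverage(list(aln), jn)
  expect_equal(cc$covered, 9)
  expect_equal(cc$coverage_pct, 90)
  expect_equal(cc$flagged, 1)          # the junction inside the 3 kb indel
  expect_equal(cc$flagged_pct, 100 * 1 / 9, tolerance = 1e-6)
})

test_that("alternative-path search picks the route matching span and sites", {
  set.seed(98)
  A <- random_dna(110000); B <- random_dna(45000)
  C <- random_dna(110000); D <- random_dna(30000)
  G1 <- paste0(A, B, C); G2 <- paste0(A, D, C)
  mkfos <- function(g, centre) substr(g, centre - 19000, centre + 19000)
  fosc <- contig_set(c("f1", "f2", "f3", "f4"),
                     c(mkfos(G1, 110000), mkfos(G1, 155000),
                       mkfos(G2, 110000), mkfos(G2, 140000)),
                     source = "fosmid")
  ctgs <- contig_set(c("A", "B", "C", "D"), c(A, B, C, D))
  aln <- find_overlaps(fosc, ctgs, min_len = 5000)
  edges <- edges_from_overlaps(classify_overlap(aln, 0.97, fb_params()))
  g <- build_graph(ctgs, NULL, edges)
  res <- find_alternative_path(g, "A", "C", nchar(G1), digest(G1, id = "ref"),
                               ctgs, fosc)
  expect_equal(res$segments$contig_id, c("A", "B", "C"))
  expect_equal(res$span, nchar(G1))
  # the other reference selects the other route
  res2 <- find_alternative_path(g, "A", "C", nchar(G2), digest(G2, id = "ref"),
                                ctgs, fosc)
  expect_equal(res2$segments$contig_id, c("A", "D", "C"))
  # no candidate within tolerance
  expect_null(find_alternative_path(g, "A", "C", nchar(G1) + 50000,
                                    digest(G1, id = "ref"), ctgs, fosc))
  # short flank violates the 100 kb precondition
  expect_error(find_alternative_path(g, "B", "C", 1, digest(G1, id = "ref"),
                                     ctgs, fosc), "flank_min_len")
})

test_that("nick maps round-trip through the CMAP-like TSV", {
  maps <- list(nickmap("m1", 100000, c(5000, 40000, 90000)),
               nickmap("m2", 50000, numeric(0)))
  tsv <- tempfile(fileext = ".tsv")
  write_nickmaps(maps, tsv)
  back <- read_nickmaps(tsv)
  expect_equal(back[["m1"]]$sites, maps[[1]]$sites)
  expect_equal(back[["m2"]]$length, 50000)
  expect_equal(length(back[["m2"]]$sites), 0)
})
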