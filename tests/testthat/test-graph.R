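three_node_graph <- function() {
  wgs <- contig_set(c("A", "B", "C"),
                    c(random_dna(20000, seed = 31), random_dna(20000),
                      random_dna(20000)))
  e1 <- make_edge(fake_overlap("f1", "A", "R", 0, 6000, 1, 6000),
                  fake_overlap("f1", "B", "L", 30000, 40000, 1, 10000))
  e2 <- make_edge(fake_overlap("f2", "B", "R", 0, 6000, 1, 6000),
                  fake_overlap("f2", "C", "L", 30000, 40000, 1, 10000))
  build_graph(wgs, NULL, rbind(e1, e2))
}

test_that("build_graph wires nodes and edges; path degrees are 1,2,1", {
  g <- three_node_graph()
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)
  deg <- table(c(g$edges$a_id, g$edges$b_id))
  expect_equal(as.integer(deg[c("A", "B", "C")]), c(1L, 2L, 1L))
})

test_that("duplicate (fosmid, end-pair) edges are stored once", {
  wgs <- contig_set(c("A", "B"), c(random_dna(20000, seed = 32),
                                   random_dna(20000)))
  e <- make_edge(fake_overlap("f1", "A", "R", 0, 6000, 1, 6000),
                 fake_overlap("f1", "B", "L", 30000, 40000, 1, 10000))
  g <- build_graph(wgs, NULL, rbind(e, e))
  expect_equal(nrow(g$edges), 1)
})

test_that("an edge naming an unknown contig is rejected", {
  wgs <- contig_set("A", random_dna(20000, seed = 33))
  e <- make_edge(fake_overlap("f1", "A", "R", 0, 6000, 1, 6000),
                 fake_overlap("f1", "Z", "L", 30000, 40000, 1, 10000))
  expect_error(build_graph(wgs, NULL, e), "unknown contig: Z")
})

test_that("pair_weight sums scores of valid edges between two exact ends", {
  wgs <- contig_set(c("A", "B"), c(random_dna(20000, seed = 34),
                                   random_dna(20000)))
  e1 <- make_edge(fake_overlap("f1", "A", "R", 0, 6000, 0.99, 6000),
                  fake_overlap("f1", "B", "L", 30000, 40000, 1.0, 5500))
  e2 <- make_edge(fake_overlap("f2", "A", "R", 0, 5000, 0.99, 5000),
                  fake_overlap("f2", "B", "L", 30000, 40000, 1.0, 5000))
  e2$score <- 9900  # as if identity x matched gave 9900
  g <- build_graph(wgs, NULL, rbind(e1, e2))
  expect_equal(pair_weight(g, "A", "R", "B", "L", 0.98), 11440 + 9900)
  # an edge failing the identity threshold contributes nothing
  expect_equal(pair_weight(g, "A", "R", "B", "L", 0.995), 0)
  # no edges between these ends at all
  expect_equal(pair_weight(g, "A", "L", "B", "R", 0.9), 0)
})

test_that("invalidate_end removes incident edges exactly once", {
  g <- three_node_graph()
  e3 <- make_edge(fake_overlap("f3", "A", "R", 0, 5200, 1, 5200),
                  fake_overlap("f3", "B", "L", 30000, 40000, 1, 10000))
  e4 <- make_edge(fake_overlap("f4", "A", "R", 0, 5100, 1, 5100),
                  fake_overlap("f4", "B", "L", 30000, 40000, 1, 10000))
  g$edges <- rbind(g$edges, cbind(e3, active = TRUE), cbind(e4, active = TRUE))
  n_active <- sum(g$edges$active)
  g2 <- invalidate_end(g, "A", "R")
  expect_equal(n_active - sum(g2$edges$active), 3)  # f1, f3, f4
  expect_error(invalidate_end(g2, "A", "R"), "already merged")
  # end with no edges: state change only
  g3 <- invalidate_end(g2, "A", "L")
  expect_equal(sum(g3$edges$active), sum(g2$edges$active))
})

test_that("merging an unanchored node into a LG removes its cross-LG edges", {
  wgs <- contig_set(c("A", "B", "X"),
                    c(random_dna(20000, seed = 35), random_dna(20000),
                      random_dna(20000)))
  anchors <- data.frame(contig_id = c("A", "B"), lg_id = c("LG1", "LG2"),
                        order_index = c(1L, 1L), cm_position = c(0, 0),
                        orientation = c("+", "+"), stringsAsFactors = FALSE)
  eAX <- make_edge(fake_overlap("f1", "A", "R", 0, 6000, 1, 6000),
                   fake_overlap("f1", "X", "L", 30000, 40000, 1, 10000))
  eXB <- make_edge(fake_overlap("f2", "X", "R", 0, 6000, 0.99, 5100),
                   fake_overlap("f2", "B", "L", 30000, 40000, 0.99, 5100))
  g <- build_graph(wgs, anchors, rbind(eAX, eXB))
  g2 <- merge_pass(g, 0.98, "include_unanchored")
  # X joined LG1 through A; its edge to LG2's B must be gone
  expect_equal(g2$nodes$lg[g2$nodes$id == "X"], "LG1")
  sel <- (g2$edges$a_id == "X" & g2$edges$b_id == "B") |
         (g2$edges$b_id == "X" & g2$edges$a_id == "B")
  expect_false(any(g2$edges$active[sel]))
})

test_that("junction set stays acyclic: paths = nodes - junctions", {
  truth <- small_scenario(seed = 41)
  res <- run_pipeline(truth$wgs, truth$fosmids, truth$anchors)
  g <- res$graph
  comp <- fosbridge:::graph_components(g)
  expect_equal(length(unique(comp)), nrow(g$nodes) - nrow(g$junctions))
  # every end participates in at most one junction
  ends <- c(paste(g$junctions$left_id, g$junctions$left_end),
            paste(g$junctions$right_id, g$junctions$right_end))
  expect_false(any(duplicated(ends)))
})

test_that("a path forest of 1,669 nodes and 1,652 junctions has 17 components", {
  ids <- sprintf("c%04d", 1:1669)
  wgs <- data.frame(id = ids, sequence = "ACGT", length = 4L, source = "wgs",
                    parent_id = NA_character_, parent_start = NA_real_,
                    parent_end = NA_real_, stringsAsFactors = FALSE)
  g <- build_graph(wgs, NULL, fosbridge:::empty_edges())
  # chain nodes into 17 paths with 1,652 junctions in total
  sizes <- rep(1669 %/% 17, 17)
  sizes[seq_len(1669 %% 17)] <- sizes[seq_len(1669 %% 17)] + 1
  at <- 0
  jn <- list()
  for (s in sizes) {
    for (k in seq_len(s - 1))
      jn[[length(jn) + 1]] <- data.frame(
        left_id = ids[at + k], left_end = "R", right_id = ids[at + k + 1],
        right_end = "L", fosmid = "f", via = "fosmid_edge", gap = 0,
        score = 1, support_overlap = FALSE, edge_row = NA_integer_,
        stringsAsFactors = FALSE)
    at <- at + s
  }
  g$junctions <- do.call(rbind, jn)
  expect_equal(nrow(g$junctions), 1652)
  comp <- fosbridge:::graph_components(g)
  expect_equal(length(unique(comp)), 17)
})
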