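end_key <- function(id, end) paste(id, end, sep = ":")

#' Build the overlap graph
#'
#' Nodes are WGS contigs (each with an independent LEFT and RIGHT end);
#' edges are fosmid bridges between two node ends. Anchors, where present,
#' attach the linkage-group position and map orientation of a node. Direct
#' WGS-vs-WGS overlap alignments are carried alongside for junction support
#' and chimera detection.
#'
#' @param wgs Contig set of WGS contigs.
#' @param anchors Anchor records ([read_anchors()]) or `NULL`.
#' @param edges Fosmid edge table ([edges_from_overlaps()]).
#' @param wgs_overlaps WGS self-overlap alignment records (optional).
#' @return An `fb_graph` object.
#' @export
build_graph <- function(wgs, anchors = NULL, edges = empty_edges(),
                        wgs_overlaps = NULL) {
  ids <- wgs$id
  if (nrow(edges) > 0) {
    unknown <- setdiff(c(edges$a_id, edges$b_id), ids)
    if (length(unknown) > 0)
      stop("edge references unknown contig: ", unknown[1])
    # one edge per (fosmid, end-pair): de-duplicate on the normalized key
    ka <- end_key(edges$a_id, edges$a_end)
    kb <- end_key(edges$b_id, edges$b_end)
    key <- paste(edges$fosmid, pmin(ka, kb), pmax(ka, kb))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  nodes <- data.frame(id = ids, length = wgs$length,
                      lg = NA_character_, order_index = NA_integer_,
                      cm = NA_real_, map_orient = NA_character_,
                      anchored = FALSE,
                      left_state = "open", right_state = "open",
                      stringsAsFactors = FALSE)
  if (!is.null(anchors) && nrow(anchors) > 0) {
    m <- match(nodes$id, anchors$contig_id)
    hit <- !is.na(m)
    nodes$lg[hit] <- anchors$lg_id[m[hit]]
    nodes$order_index[hit] <- anchors$order_index[m[hit]]
    nodes$cm[hit] <- anchors$cm_position[m[hit]]
    nodes$map_orient[hit] <- anchors$orientation[m[hit]]
    nodes$anchored[hit] <- TRUE
  }
  edges$active <- rep(TRUE, nrow(edges))
  g <- list(nodes = nodes, edges = edges,
            wgs_overlaps = wgs_overlaps,
            junctions = empty_junctions(),
            journal = character(0))
  class(g) <- c("fb_graph", "list")
  g
}

empty_junctions <- function() {
  data.frame(left_id = character(0), left_end = character(0),
             right_id = character(0), right_end = character(0),
             fosmid = character(0), via = character(0),
             gap = numeric(0), score = numeric(0),
             support_overlap = logical(0), edge_row = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.fb_graph <- function(x, ...) {
  cat(sprintf("fb_graph: %d nodes (%d anchored), %d edges (%d active), %d junctions\n",
              nrow(x$nodes), sum(x$nodes$anchored), nrow(x$edges),
              sum(x$edges$active), nrow(x$junctions)))
  invisible(x)
}

end_state <- function(g, id, end) {
  i <- match(id, g$nodes$id)
  if (is.na(i)) stop("unknown node: ", id)
  if (end == "L") g$nodes$left_state[i] else g$nodes$right_state[i]
}

`end_state<-` <- function(g, id, end, value) {
  i <- match(id, g$nodes$id)
  if (end == "L") g$nodes$left_state[i] <- value else g$nodes$right_state[i] <- value
  g
}

# logical index of active edges joining the two exact ends
edges_between <- function(g, id_a, end_a, id_b, end_b) {
  e <- g$edges
  e$active &
    ((e$a_id == id_a & e$a_end == end_a & e$b_id == id_b & e$b_end == end_b) |
     (e$a_id == id_b & e$a_end == end_b & e$b_id == id_a & e$b_end == end_a))
}

#' Weighted score for a pair of node ends
#'
#' The weighted score of a pair of ends is the sum of scores of all active
#' edges joining them whose overlaps satisfy the current identity threshold
#' (length and overhang thresholds were enforced when the overlaps were
#' classified).
#'
#' @param g An `fb_graph`.
#' @param id_a,end_a,id_b,end_b The two ends (`end` is `"L"` or `"R"`).
#' @param identity_thr Identity threshold of the current round.
#' @return The summed score (0 when no valid edge joins the ends).
#' @export
pair_weight <- function(g, id_a, end_a, id_b, end_b, identity_thr) {
  sel <- edges_between(g, id_a, end_a, id_b, end_b)
  sel <- sel & g$edges$min_identity > identity_thr
  if (!any(sel)) return(0)
  sum(g$edges$score[sel])
}

#' Retire a node end after a merge
#'
#' Marks the end merged and deactivates every edge incident to it, so the
#' retired end can no longer attract connections (this is what keeps the
#' junction set a union of simple paths).
#'
#' @param g An `fb_graph`.
#' @param id,end The end to retire.
#' @return The updated graph.
#' @export
invalidate_end <- function(g, id, end) {
  if (end_state(g, id, end) == "merged")
    stop("end already merged: ", end_key(id, end))
  end_state(g, id, end) <- "merged"
  touch <- g$edges$active &
    ((g$edges$a_id == id & g$edges$a_end == end) |
     (g$edges$b_id == id & g$edges$b_end == end))
  g$edges$active[touch] <- FALSE
  g$journal <- c(g$journal,
                 sprintf("invalidate %s (-%d edges)", end_key(id, end), sum(touch)))
  g
}

# drop active edges joining an id to nodes anchored on other LGs
drop_cross_lg_edges <- function(g, id, lg) {
  other <- g$nodes$id[g$nodes$anchored & !is.na(g$nodes$lg) & g$nodes$lg != lg]
  drop <- g$edges$active &
    ((g$edges$a_id == id & g$edges$b_id %in% other) |
     (g$edges$b_id == id & g$edges$a_id %in% other))
  if (any(drop)) {
    g$edges$active[drop] <- FALSE
    g$journal <- c(g$journal,
                   sprintf("drop-cross-lg %s lg=%s (-%d edges)", id, lg, sum(drop)))
  }
  g
}

# contig -> path component id, from the junction set (union-find)
graph_components <- function(g) {
  parent <- seq_len(nrow(g$nodes))
  names(parent) <- g$nodes$id
  root <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(g$junctions) > 0)
    for (k in seq_len(nrow(g$junctions))) {
      a <- root(match(g$junctions$left_id[k], g$nodes$id))
      b <- root(match(g$junctions$right_id[k], g$nodes$id))
      if (a != b) parent[b] <- a
    }
  setNames(vapply(seq_len(nrow(g$nodes)), function(i) root(i), integer(1)),
           g$nodes$id)
}

# ordered contig paths implied by the junction set: list of data.frames
# with columns contig_id, orient and the junction rows joining them
graph_paths <- function(g) {
  nodes <- g$nodes$id
  jn <- g$junctions
  nbr <- list()  # end-key -> list(partner end-key, junction row)
  if (nrow(jn) > 0)
    for (k in seq_len(nrow(jn))) {
      ka <- end_key(jn$left_id[k], jn$left_end[k])
      kb <- end_key(jn$right_id[k], jn$right_end[k])
      nbr[[ka]] <- list(partner = kb, row = k)
      nbr[[kb]] <- list(partner = ka, row = k)
    }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  paths <- list()
  deg <- table(c(jn$left_id, jn$right_id))
  for (start in nodes) {
    if (seen[[start]]) next
    d <- if (start %in% names(deg)) deg[[start]] else 0
    if (d >= 2) next  # interior node; reached from a terminus
    # walk from this terminus
    segs <- data.frame(contig_id = character(0), orient = character(0),
                       stringsAsFactors = FALSE)
    jrows <- integer(0)
    cur <- start
    # entry end: the end NOT used by the first junction
    use <- NULL
    for (e in c("L", "R")) {
      kk <- end_key(cur, e)
      if (!is.null(nbr[[kk]])) use <- e
    }
    if (is.null(use)) {  # singleton
      seen[[cur]] <- TRUE
      paths[[length(paths) + 1]] <- list(
        segments = data.frame(contig_id = cur, orient = "+",
                              stringsAsFactors = FALSE),
        junction_rows = integer(0))
      next
    }
    repeat {
      orient <- if (use == "R") "+" else "-"  # exit via R => forward
      segs <- rbind(segs, data.frame(contig_id = cur, orient = orient,
                                     stringsAsFactors = FALSE))
      seen[[cur]] <- TRUE
      kk <- end_key(cur, use)
      hop <- nbr[[kk]]
      if (is.null(hop)) break
      jrows <- c(jrows, hop$row)
      nxt <- strsplit(hop$partner, ":", fixed = TRUE)[[1]]
      cur <- nxt[1]
      entry <- nxt[2]
      use <- if (entry == "L") "R" else "L"  # exit via the other end
      if (seen[[cur]]) break  # safety: cycles are prevented at merge time
      # if the exit end has no junction, append final contig and stop
      if (is.null(nbr[[end_key(cur, use)]])) {
        orient <- if (entry == "L") "+" else "-"
        segs <- rbind(segs, data.frame(contig_id = cur, orient = orient,
                                       stringsAsFactors = FALSE))
        seen[[cur]] <- TRUE
        break
      }
    }
    paths[[length(paths) + 1]] <- list(segments = segs, junction_rows = jrows)
  }
  paths
}

#' Dump the graph as text
#'
#' GraphViz-style dump of active edges plus the junction list, for
#' debugging.
#' @param g An `fb_graph`.
#' @param path Output path (or `""` for the text).
#' @return The text, invisibly when written to a file.
#' @export
dump_graph <- function(g, path = "") {
  lines <- c("graph overlap {")
  e <- g$edges[g$edges$active, , drop = FALSE]
  if (nrow(e) > 0)
    lines <- c(lines, sprintf('  "%s:%s" -- "%s:%s" [label="%s s=%.0f l=%.0f"];',
                              e$a_id, e$a_end, e$b_id, e$b_end, e$fosmid,
                              e$score, e$length))
  jn <- g$junctions
  if (nrow(jn) > 0)
    lines <- c(lines, sprintf('  "%s:%s" -- "%s:%s" [style=bold];',
                              jn$left_id, jn$left_end, jn$right_id, jn$right_end))
  lines <- c(lines, "}")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (nzchar(path)) { writeLines(lines, path); return(invisible(txt)) }
  txt
}
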