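#' One iterative merge pass over the overlap graph
#'
#' Repeatedly merges the open end-pair with the best weighted score permitted
#' by `scope`, retiring both ends after each merge, until no merge is
#' possible. An end whose two best partners tie at the same weighted score is
#' left open (conflicting overlaps); in scope `include_unanchored` such ties
#' are resolved in favour of the shortest edge. Merging never creates a
#' cycle: a candidate joining two ends of one existing path is skipped.
#'
#' Scopes: `lg_adjacent` merges map-neighbouring anchored pairs (order-index
#' distance 1 on one linkage group); `lg_any` relaxes to distance <= 2;
#' `include_unanchored` additionally admits pairs with at least one
#' unanchored node. When an unanchored node is merged into a linkage group,
#' its edges to nodes anchored on other groups are removed.
#'
#' @param g An `fb_graph`.
#' @param identity_thr Identity threshold of this round.
#' @param scope `"lg_adjacent"`, `"lg_any"` or `"include_unanchored"`.
#' @param params [fb_params()].
#' @return The updated graph; `attr(, "n_merged")` carries the merge count.
#' @export
merge_pass <- function(g, identity_thr,
                       scope = c("lg_adjacent", "lg_any", "include_unanchored"),
                       params = fb_params()) {
  scope <- match.arg(scope)
  n_merged <- 0L
  repeat {
    cand <- merge_candidates(g, identity_thr, scope)
    if (nrow(cand) == 0) break
    pick <- pick_candidate(cand, scope)
    if (is.null(pick)) break
    g <- apply_merge(g, pick, identity_thr, params)
    n_merged <- n_merged + 1L
  }
  attr(g, "n_merged") <- n_merged
  g
}

# candidate end-pairs with weights under the scope rules
merge_candidates <- function(g, identity_thr, scope) {
  e <- g$edges[g$edges$active & g$edges$min_identity > identity_thr, ,
               drop = FALSE]
  empty <- data.frame(a_id = character(0), a_end = character(0),
                      b_id = character(0), b_end = character(0),
                      weight = numeric(0), min_len = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(e) == 0) return(empty)
  ka <- end_key(e$a_id, e$a_end)
  kb <- end_key(e$b_id, e$b_end)
  flip <- ka > kb
  pa_id <- ifelse(flip, e$b_id, e$a_id); pa_end <- ifelse(flip, e$b_end, e$a_end)
  pb_id <- ifelse(flip, e$a_id, e$b_id); pb_end <- ifelse(flip, e$a_end, e$b_end)
  key <- paste(pa_id, pa_end, pb_id, pb_end, sep = "\r")
  agg_w <- tapply(e$score, key, sum)
  agg_l <- tapply(abs(e$length), key, min)
  parts <- strsplit(names(agg_w), "\r", fixed = TRUE)
  cand <- data.frame(a_id = vapply(parts, `[`, "", 1),
                     a_end = vapply(parts, `[`, "", 2),
                     b_id = vapply(parts, `[`, "", 3),
                     b_end = vapply(parts, `[`, "", 4),
                     weight = as.numeric(agg_w),
                     min_len = as.numeric(agg_l),
                     stringsAsFactors = FALSE)
  nd <- g$nodes
  ia <- match(cand$a_id, nd$id); ib <- match(cand$b_id, nd$id)
  open_a <- ifelse(cand$a_end == "L", nd$left_state[ia], nd$right_state[ia]) == "open"
  open_b <- ifelse(cand$b_end == "L", nd$left_state[ib], nd$right_state[ib]) == "open"
  cand <- cand[open_a & open_b, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  ia <- match(cand$a_id, nd$id); ib <- match(cand$b_id, nd$id)
  anch_a <- nd$anchored[ia]; anch_b <- nd$anchored[ib]
  same_lg <- !is.na(nd$lg[ia]) & !is.na(nd$lg[ib]) & nd$lg[ia] == nd$lg[ib]
  dist <- abs(nd$order_index[ia] - nd$order_index[ib])
  ok <- switch(scope,
    lg_adjacent = anch_a & anch_b & same_lg & !is.na(dist) & dist == 1,
    lg_any = anch_a & anch_b & same_lg & !is.na(dist) & dist <= 2,
    include_unanchored = (anch_a & anch_b & same_lg & !is.na(dist) & dist <= 2) |
      !(anch_a & anch_b))
  # never join nodes assigned to different linkage groups
  cross <- !is.na(nd$lg[ia]) & !is.na(nd$lg[ib]) & nd$lg[ia] != nd$lg[ib]
  cand <- cand[ok & !cross, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  # no self-joins, no cycles
  comp <- graph_components(g)
  cand <- cand[cand$a_id != cand$b_id &
               comp[cand$a_id] != comp[cand$b_id], , drop = FALSE]
  cand
}

# conflict rule + deterministic global ordering; NULL when nothing mergeable
pick_candidate <- function(cand, scope) {
  if (nrow(cand) == 0) return(NULL)
  drop <- rep(FALSE, nrow(cand))
  ends <- unique(c(end_key(cand$a_id, cand$a_end), end_key(cand$b_id, cand$b_end)))
  for (ek in ends) {
    inc <- which(end_key(cand$a_id, cand$a_end) == ek |
                 end_key(cand$b_id, cand$b_end) == ek)
    if (length(inc) < 2) next
    best <- max(cand$weight[inc])
    at_best <- inc[cand$weight[inc] == best]
    partners <- ifelse(end_key(cand$a_id[at_best], cand$a_end[at_best]) == ek,
                       cand$b_id[at_best], cand$a_id[at_best])
    if (length(unique(partners)) > 1) {
      if (scope == "include_unanchored") {
        shortest <- at_best[cand$min_len[at_best] == min(cand$min_len[at_best])]
        if (length(unique(ifelse(end_key(cand$a_id[shortest], cand$a_end[shortest]) == ek,
                                 cand$b_id[shortest], cand$a_id[shortest]))) > 1) {
          drop[inc] <- TRUE            # still tied: genuine conflict
        } else {
          drop[setdiff(at_best, shortest)] <- TRUE
        }
      } else {
        drop[inc] <- TRUE              # conflicting overlaps: leave open
      }
    }
  }
  cand <- cand[!drop, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  ord <- order(-cand$weight, cand$min_len, cand$a_id, cand$a_end,
               cand$b_id, cand$b_end)
  cand[ord[1], , drop = FALSE]
}

apply_merge <- function(g, pick, identity_thr, params) {
  sel <- which(edges_between(g, pick$a_id, pick$a_end, pick$b_id, pick$b_end) &
               g$edges$min_identity > identity_thr)
  es <- g$edges[sel, , drop = FALSE]
  best <- sel[order(-es$score, abs(es$length), es$fosmid)][1]
  e <- g$edges[best, , drop = FALSE]
  support <- FALSE
  if (!is.null(g$wgs_overlaps) && nrow(g$wgs_overlaps) > 0) {
    wo <- g$wgs_overlaps
    support <- any((wo$query_id == pick$a_id & wo$target_id == pick$b_id) |
                   (wo$query_id == pick$b_id & wo$target_id == pick$a_id))
  }
  g$junctions <- rbind(g$junctions, data.frame(
    left_id = pick$a_id, left_end = pick$a_end,
    right_id = pick$b_id, right_end = pick$b_end,
    fosmid = e$fosmid, via = "fosmid_edge",
    gap = e$length, score = pick$weight,
    support_overlap = support, edge_row = best,
    stringsAsFactors = FALSE))
  g$journal <- c(g$journal, sprintf(
    "merge %s -- %s via %s w=%.1f len=%.0f",
    end_key(pick$a_id, pick$a_end), end_key(pick$b_id, pick$b_end),
    e$fosmid, pick$weight, e$length))
  g <- invalidate_end(g, pick$a_id, pick$a_end)
  g <- invalidate_end(g, pick$b_id, pick$b_end)
  # propagate linkage-group assignment into unanchored nodes
  nd <- g$nodes
  ia <- match(pick$a_id, nd$id); ib <- match(pick$b_id, nd$id)
  lg_a <- nd$lg[ia]; lg_b <- nd$lg[ib]
  if (is.na(lg_a) && !is.na(lg_b)) {
    g$nodes$lg[ia] <- lg_b
    g <- drop_cross_lg_edges(g, pick$a_id, lg_b)
  } else if (is.na(lg_b) && !is.na(lg_a)) {
    g$nodes$lg[ib] <- lg_a
    g <- drop_cross_lg_edges(g, pick$b_id, lg_a)
  }
  g
}

#' Detect chimeric contigs
#'
#' A contig is called chimeric when another contig's terminal sequence
#' overlaps its middle: overlap length above `chimera_min_overlap`, identity
#' above `chimera_min_identity`, overhang on the called contig above
#' `chimera_min_overhang`, and the overlap supported by at least one fosmid
#' contig that connects the partner's end and reaches the breakpoint. The
#' breakpoint is placed where the partner's sequence terminates inside the
#' called contig.
#'
#' @param wgs_overlaps WGS-vs-WGS alignment records.
#' @param fosmid_overlaps All fosmid-vs-WGS overlap classifications
#'   ([classify_overlap()]), including rejected internal alignments.
#' @param fosmid_aln Raw fosmid-vs-WGS alignment records (for breakpoint
#'   support on the called contig).
#' @param params [fb_params()].
#' @return A `data.frame` of chimera calls: `contig_id`, `breakpoint`,
#'   `partner`, `overlap_len`, `identity`, `overhang`, `fosmids`.
#' @export
detect_chimeras <- function(wgs_overlaps, fosmid_overlaps, fosmid_aln,
                            params = fb_params()) {
  calls <- list()
  wo <- wgs_overlaps
  if (is.null(wo) || nrow(wo) == 0) return(empty_chimera_calls())
  for (i in seq_len(nrow(wo))) {
    r <- wo[i, ]
    if (r$t_end - r$t_start <= params$chimera_min_overlap) next
    if (r$identity <= params$chimera_min_identity) next
    # which query end does the alignment reach?
    q_over_l <- r$q_start
    q_over_r <- r$q_len - r$q_end
    for (q_end in c("L", "R")) {
      over <- if (q_end == "L") q_over_l else q_over_r
      if (over >= params$max_overhang) next
      # the q-terminal block edge lies inside t; the breakpoint is the
      # opposite edge, where both sequences continue but homology stops
      bp <- if ((q_end == "R") == (r$strand == "+")) r$t_start else r$t_end
      # the partner must itself continue past the breakpoint-side edge
      far_over <- if (q_end == "L") q_over_r else q_over_l
      if (far_over <= params$chimera_min_overhang) next
      # internal on the called contig: both flanks beyond the block are long
      t_over <- min(r$t_start, r$t_len - r$t_end)
      if (t_over <= params$chimera_min_overhang) next   # terminal: normal join
      if (bp <= 0 || bp >= r$t_len) next
      # fosmid support: accepted overlap on the partner's end, and an
      # alignment on the called contig reaching the breakpoint
      fq <- fosmid_overlaps[fosmid_overlaps$accepted &
                            fosmid_overlaps$wgs_id == r$query_id &
                            fosmid_overlaps$wgs_end == q_end, , drop = FALSE]
      if (nrow(fq) == 0) next
      ft <- fosmid_aln[fosmid_aln$query_id %in% fq$fosmid_id &
                       fosmid_aln$target_id == r$target_id, , drop = FALSE]
      near <- ft[ft$t_start - 2000 <= bp & bp <= ft$t_end + 2000, , drop = FALSE]
      if (nrow(near) == 0) next
      calls[[length(calls) + 1]] <- data.frame(
        contig_id = r$target_id, breakpoint = bp, partner = r$query_id,
        overlap_len = r$t_end - r$t_start, identity = r$identity,
        overhang = t_over,
        fosmids = paste(sort(unique(near$query_id)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0) return(empty_chimera_calls())
  calls <- do.call(rbind, calls)
  # merge near-duplicate breakpoints on one contig (within 1 kb)
  calls <- calls[order(calls$contig_id, calls$breakpoint, -calls$overlap_len), ]
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))[-1])
    for (j in which(keep[seq_len(i - 1)]))
      if (calls$contig_id[i] == calls$contig_id[j] &&
          abs(calls$breakpoint[i] - calls$breakpoint[j]) <= 1000) {
        keep[i] <- FALSE
        break
      }
  calls[keep, , drop = FALSE]
}

empty_chimera_calls <- function() {
  data.frame(contig_id = character(0), breakpoint = numeric(0),
             partner = character(0), overlap_len = numeric(0),
             identity = numeric(0), overhang = numeric(0),
             fosmids = character(0), stringsAsFactors = FALSE)
}

#' Split a chimeric contig
#'
#' Splits the contig at the breakpoint into two derived-split contigs.
#' Pieces longer than `params$min_reuse_len` re-enter the assembly as new
#' WGS contigs; shorter pieces are retired from reuse.
#'
#' @param contigs Contig set containing the contig to split.
#' @param call One-row chimera call ([detect_chimeras()]).
#' @param params [fb_params()].
#' @return A list with `contigs` (updated set: parent removed, reusable
#'   pieces appended) and `pieces` (all pieces with a `reusable` flag).
#' @export
split_chimera <- function(contigs, call, params = fb_params()) {
  i <- match(call$contig_id, contigs$id)
  if (is.na(i)) stop("unknown contig: ", call$contig_id)
  len <- contigs$length[i]
  bp <- call$breakpoint
  if (bp <= 0 || bp >= len) stop("breakpoint must be strictly inside the contig")
  seqs <- c(substr(contigs$sequence[i], 1, bp),
            substr(contigs$sequence[i], bp + 1, len))
  pieces <- contig_set(paste0(call$contig_id, c(".p1", ".p2")), seqs,
                       source = "derived-split", parent_id = call$contig_id,
                       parent_start = c(0, bp), parent_end = c(bp, len))
  pieces$reusable <- pieces$length > params$min_reuse_len
  out <- contigs[-i, , drop = FALSE]
  keep <- pieces[pieces$reusable, names(contigs), drop = FALSE]
  list(contigs = rbind(out, keep), pieces = pieces)
}

#' Emit the sequence of a super-contig
#'
#' Walks the ordered, oriented segments. At a positive-length junction the
#' two WGS contigs are emitted in full with the fosmid inter-overlap segment
#' between them; at a negative-length junction the overlap region is taken
#' from the fosmid and the flanking WGS contigs are trimmed accordingly.
#' Reverse complement is applied per segment orientation.
#'
#' @param segments `data.frame` with `contig_id`, `orient` in path order.
#' @param junction_edges Edge rows ([make_edge()] columns), one per junction
#'   between consecutive segments.
#' @param contigs,fosmids Contig sets providing the sequences.
#' @return A list: `sequence`, `segments` (with emitted `start`/`end`),
#'   `junctions` (with emitted `j_start`/`j_end` and `gap`).
#' @export
emit_sequence <- function(segments, junction_edges, contigs, fosmids) {
  stopifnot(nrow(junction_edges) == nrow(segments) - 1 || nrow(segments) == 1)
  cseq <- as_seq_vector(contigs)
  fseq <- as_seq_vector(fosmids)
  oriented <- function(id, orient) {
    s <- cseq[[id]]
    if (is.null(s)) stop("unknown contig: ", id)
    if (orient == "-") revcomp(s) else s
  }
  out <- oriented(segments$contig_id[1], segments$orient[1])
  seg_start <- 0
  seg_end <- nchar(out)
  j_start <- numeric(0); j_end <- numeric(0); gaps <- numeric(0)
  if (nrow(segments) > 1) for (j in seq_len(nrow(segments) - 1)) {
    e <- junction_edges[j, ]
    left_id <- segments$contig_id[j]
    right_id <- segments$contig_id[j + 1]
    if (e$a_id == left_id && e$b_id == right_id) {
      L <- list(fs = e$a_fstart, fe = e$a_fend, strand = e$a_strand,
                h = e$a_overhang)
      R <- list(fs = e$b_fstart, fe = e$b_fend, strand = e$b_strand,
                h = e$b_overhang)
    } else if (e$b_id == left_id && e$a_id == right_id) {
      L <- list(fs = e$b_fstart, fe = e$b_fend, strand = e$b_strand,
                h = e$b_overhang)
      R <- list(fs = e$a_fstart, fe = e$a_fend, strand = e$a_strand,
                h = e$a_overhang)
    } else stop("junction edge does not join segments ", left_id, "/", right_id)
    f <- fseq[[e$fosmid]]
    if (is.null(f)) stop("unknown fosmid: ", e$fosmid)
    flen <- nchar(f)
    if (max(L$fe, R$fe) > flen || min(L$fs, R$fs) < 0)
      stop("fosmid interval exceeds fosmid bounds: ", e$fosmid)
    # orient the fosmid along the path
    fo <- if ((L$strand == "+") == (segments$orient[j] == "+")) "+" else "-"
    if (fo == "-") {
      f <- revcomp(f)
      L <- list(fs = flen - L$fe, fe = flen - L$fs, strand = L$strand,
                h = L$h)
      R <- list(fs = flen - R$fe, fe = flen - R$fs, strand = R$strand,
                h = R$h)
    }
    if (L$fs > R$fs) { tmp <- L; L <- R; R <- tmp }
    # effective contig boundaries on the fosmid axis: the left contig truly
    # ends h_L bases beyond its aligned block, the right truly begins h_R
    # bases before its block; trims and the junction piece are measured
    # against these so small alignment overhangs do not duplicate or lose
    # sequence at the splice
    effA <- L$fe + L$h
    effB <- R$fs - R$h
    if (effB >= effA) { ps <- effA; pe <- effB }
    else { ps <- max(0, effB); pe <- min(flen, effA) }
    trimL <- effA - ps
    trimR <- pe - effB
    gap <- effB - effA
    right_seq <- oriented(right_id, segments$orient[j + 1])
    if (trimL >= nchar(out) - seg_start[length(seg_start)] ||
        trimR >= nchar(right_seq) || pe < ps)
      stop("junction overlap exceeds flanking segment length")
    out <- substr(out, 1, nchar(out) - trimL)
    seg_end[length(seg_end)] <- nchar(out)
    js <- nchar(out)
    piece <- substr(f, ps + 1, pe)
    out <- paste0(out, piece, substr(right_seq, trimR + 1, nchar(right_seq)))
    je <- js + (pe - ps)
    seg_start <- c(seg_start, je)
    seg_end <- c(seg_end, je + nchar(right_seq) - trimR)
    j_start <- c(j_start, js); j_end <- c(j_end, je); gaps <- c(gaps, gap)
  }
  segments$start <- seg_start
  segments$end <- seg_end
  jn <- if (nrow(segments) > 1)
    data.frame(fosmid = junction_edges$fosmid, gap = gaps,
               j_start = j_start, j_end = j_end, stringsAsFactors = FALSE)
  else data.frame(fosmid = character(0), gap = numeric(0),
                  j_start = numeric(0), j_end = numeric(0))
  list(sequence = out, segments = segments, junctions = jn)
}

#' Run the full super-contig construction pipeline
#'
#' Implements the staged procedure: (1) overlap detection and graph build,
#' (2) map-adjacent merging at the strictest identity, (3) the same at the
#' relaxed identity, (4) extension with unanchored contigs at successively
#' relaxed identities to a fixpoint, (5) chimera detection and splitting
#' with re-connection, (6) an optional replacement-contig hook, (7) residual
#' joining of unanchored contigs, then sequence emission.
#'
#' @param wgs WGS contig set.
#' @param fosmids Fosmid contig set (entries shorter than
#'   `params$min_fosmid_len` are discarded).
#' @param anchors Anchor records or `NULL`.
#' @param params [fb_params()].
#' @param fosmid_aln Optional precomputed fosmid-vs-WGS alignment records
#'   (PAF); recomputed internally after chimera splits.
#' @param wgs_self Optional precomputed WGS-vs-WGS alignment records.
#' @param replacement_contigs Optional contig set consulted by the gap-flank
#'   replacement hook (see [find_alternative_path()]); stored on the result.
#' @param max_chimera_rounds Maximum detect/split/re-connect rounds.
#' @param verbose Print progress.
#' @return A list: `supercontigs` (each with `id`, `lg`, `mean_order`,
#'   `segments`, `junctions`, `sequence`), `graph`, `chimera_calls`,
#'   `contigs` (final WGS set), `fosmids`, `journal`.
#' @export
run_pipeline <- function(wgs, fosmids, anchors = NULL, params = fb_params(),
                         fosmid_aln = NULL, wgs_self = NULL,
                         replacement_contigs = NULL,
                         max_chimera_rounds = 3, verbose = FALSE) {
  fosmids <- fosmids[fosmids$length >= params$min_fosmid_len, , drop = FALSE]
  thr <- params$identity_thresholds
  thr_lo <- min(thr)
  all_calls <- empty_chimera_calls()
  round <- 0
  repeat {
    round <- round + 1
    if (is.null(fosmid_aln))
      fosmid_aln <- find_overlaps(fosmids, wgs,
                                  min_len = params$min_matched_len,
                                  min_identity = thr_lo - 0.03)
    if (is.null(wgs_self))
      wgs_self <- find_overlaps(wgs, wgs,
                                min_len = params$chimera_min_overlap,
                                min_identity = params$chimera_min_identity - 0.01)
    ov <- classify_overlap(fosmid_aln, thr_lo, params)
    edges <- edges_from_overlaps(ov)
    g <- build_graph(wgs, anchors, edges, wgs_self)
    if (verbose)
      message(sprintf("round %d: %d nodes, %d edges", round, nrow(g$nodes),
                      nrow(g$edges)))
    if (length(thr) >= 1) g <- merge_pass(g, thr[1], "lg_adjacent", params)
    for (t2 in thr[-1]) g <- merge_pass(g, t2, "lg_adjacent", params)
    repeat {
      before <- nrow(g$junctions)
      for (t2 in thr[-1]) g <- merge_pass(g, t2, "include_unanchored", params)
      if (nrow(g$junctions) == before) break
    }
    # residual joining at the most permissive threshold
    g <- merge_pass(g, thr_lo, "include_unanchored", params)
    calls <- detect_chimeras(wgs_self, ov, fosmid_aln, params)
    calls <- calls[!(calls$contig_id %in% all_calls$contig_id), , drop = FALSE]
    if (nrow(calls) == 0 || round >= max_chimera_rounds) break
    if (verbose) message(sprintf("  splitting %d chimera(s)", nrow(calls)))
    for (k in seq_len(nrow(calls))) {
      if (!(calls$contig_id[k] %in% wgs$id)) next
      sp <- split_chimera(wgs, calls[k, ], params)
      wgs <- sp$contigs
      if (!is.null(anchors))
        anchors <- anchors[anchors$contig_id != calls$contig_id[k], , drop = FALSE]
    }
    all_calls <- rbind(all_calls, calls)
    fosmid_aln <- NULL  # recompute against the updated contig set
    wgs_self <- NULL
  }
  scs <- paths_to_supercontigs(g, wgs, fosmids)
  list(supercontigs = scs, graph = g, chimera_calls = all_calls,
       contigs = wgs, fosmids = fosmids,
       replacement_contigs = replacement_contigs, journal = g$journal)
}

paths_to_supercontigs <- function(g, wgs, fosmids) {
  paths <- graph_paths(g)
  nd <- g$nodes
  scs <- list()
  meta <- data.frame(lg = character(0), ord = numeric(0), first = character(0),
                     stringsAsFactors = FALSE)
  for (p in paths) {
    segs <- p$segments
    i <- match(segs$contig_id, nd$id)
    anch <- which(nd$anchored[i])
    # walk direction: anchored order indices must increase
    if (length(anch) >= 2) {
      o <- nd$order_index[i][anch]
      if (stats::cor(seq_along(o), o) < 0) {
        segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
        segs$orient <- ifelse(segs$orient == "+", "-", "+")
        rownames(segs) <- NULL
        p$junction_rows <- rev(p$junction_rows)
        anch <- nrow(segs) + 1 - rev(anch)
      }
    } else if (length(anch) <= 1 && nrow(segs) > 1) {
      if (segs$contig_id[1] > segs$contig_id[nrow(segs)]) {
        segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
        segs$orient <- ifelse(segs$orient == "+", "-", "+")
        rownames(segs) <- NULL
        p$junction_rows <- rev(p$junction_rows)
      }
    }
    i <- match(segs$contig_id, nd$id)
    lgs <- nd$lg[i][!is.na(nd$lg[i])]
    lg <- if (length(lgs) > 0) names(sort(table(lgs), decreasing = TRUE))[1]
          else NA_character_
    ords <- nd$order_index[i][nd$anchored[i]]
    ord <- if (length(ords) > 0) mean(ords) else Inf
    # orientation of single-anchored-contig paths from the map where known
    if (nrow(segs) == 1) {
      mo <- nd$map_orient[i]
      if (!is.na(mo) && mo %in% c("+", "-") && mo != segs$orient[1])
        segs$orient[1] <- mo
    }
    je <- if (length(p$junction_rows) > 0)
      g$edges[g$junctions$edge_row[p$junction_rows], , drop = FALSE]
    else empty_edges()
    em <- emit_sequence(segs, je, wgs, fosmids)
    jn <- cbind(g$junctions[p$junction_rows,
                            c("left_id", "left_end", "right_id", "right_end",
                              "via", "support_overlap"), drop = FALSE],
                em$junctions)
    rownames(jn) <- NULL
    scs[[length(scs) + 1]] <- list(id = NA_character_, lg = lg,
                                   mean_order = ord, segments = em$segments,
                                   junctions = jn, sequence = em$sequence)
    meta <- rbind(meta, data.frame(lg = ifelse(is.na(lg), "~", lg), ord = ord,
                                   first = segs$contig_id[1],
                                   stringsAsFactors = FALSE))
  }
  o <- order(meta$lg, meta$ord, meta$first)
  scs <- scs[o]
  for (k in seq_along(scs)) scs[[k]]$id <- sprintf("sc_%03d", k)
  scs
}

#' Build pseudomolecules from super-contigs
#'
#' Concatenates the super-contigs of each linkage group in map order,
#' separated by `gap_n` N characters. Super-contigs without a linkage group
#' are returned separately as unplaced.
#'
#' @param supercontigs List of super-contigs ([run_pipeline()]).
#' @param gap_n Gap size in N bases.
#' @return A list: `sequences` (named by linkage group), `unplaced` (named
#'   by super-contig id), `layout` (`data.frame` of super-contig placements).
#' @export
build_pseudomolecules <- function(supercontigs, gap_n = 10000) {
  lgs <- vapply(supercontigs, function(s) s$lg %||% NA_character_, character(1))
  ords <- vapply(supercontigs, function(s) s$mean_order, numeric(1))
  ids <- vapply(supercontigs, function(s) s$id, character(1))
  seqs <- list()
  layout <- data.frame(lg = character(0), sc = character(0), start = numeric(0),
                       end = numeric(0), stringsAsFactors = FALSE)
  for (lg in sort(unique(lgs[!is.na(lgs)]))) {
    sel <- which(lgs == lg)
    sel <- sel[order(ords[sel], ids[sel])]
    pieces <- character(0)
    pos <- 0
    for (k in sel) {
      if (length(pieces) > 0) pos <- pos + gap_n
      s <- supercontigs[[k]]$sequence
      layout <- rbind(layout, data.frame(lg = lg, sc = ids[k], start = pos,
                                         end = pos + nchar(s),
                                         stringsAsFactors = FALSE))
      pieces <- c(pieces, s)
      pos <- pos + nchar(s)
    }
    seqs[[lg]] <- paste(pieces, collapse = strrep("N", gap_n))
  }
  unplaced <- setNames(
    lapply(supercontigs[is.na(lgs)], function(s) s$sequence),
    ids[is.na(lgs)])
  list(sequences = unlist(seqs), unplaced = unlist(unplaced) %||% character(0),
       layout = layout)
}
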