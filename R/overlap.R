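#' Detect sequence overlaps between two contig sets
#'
#' Shared-k-mer seeded overlap detection with diagonal clustering, intended
#' for desk-scale data so no external aligner is needed. The scanner models
#' substitution-style divergence: each reported alignment lies on a single
#' diagonal (gap-free), with `matches` counted by direct base comparison
#' over the overlapping span, on both strands. For production-scale inputs
#' supply precomputed PAF via [parse_alignments()] instead.
#'
#' @param query,target Contig sets ([contig_set()]) or named sequence vectors.
#' @param k Seed k-mer size (11--15).
#' @param min_len Minimum overlap span (bases) to report.
#' @param min_identity Minimum identity to report (callers typically filter
#'   harder via [classify_overlap()]).
#' @param seed_step Query seed sampling stride; default scales with `min_len`.
#' @param min_votes Minimum seed hits on a diagonal cluster.
#' @param band Diagonal clustering half-width (bases).
#' @param max_occ Seeds occurring more often than this in the target index are
#'   skipped (repeat masking).
#' @param skip_same_id Drop hits between records sharing one id (self hits).
#' @param dedupe Collapse near-duplicate re-finds of one overlap (disable to
#'   see every diagonal, e.g. for self-alignment of repeat structures).
#' @return Alignment records (see [parse_alignments()] for columns).
#' @export
find_overlaps <- function(query, target, k = 15, min_len = 5000,
                          min_identity = 0.9, seed_step = NULL,
                          min_votes = NULL, band = 50, max_occ = 200,
                          skip_same_id = TRUE, dedupe = TRUE) {
  stopifnot(k >= 11, min_len >= 100)
  q <- as_seq_vector(query)
  t <- as_seq_vector(target)
  if (is.null(seed_step)) seed_step <- max(1L, as.integer(min_len / 40))
  if (is.null(min_votes))
    min_votes <- max(2L, as.integer(floor(min_len / seed_step / 8)))
  aln <- overlap_scan_cpp(names(q), unname(q), names(t), unname(t),
                          as.integer(k), as.integer(min_len),
                          as.numeric(min_identity), as.integer(seed_step),
                          as.integer(min_votes), as.integer(band),
                          as.integer(max_occ), isTRUE(skip_same_id))
  if (dedupe) aln <- dedupe_overlaps(aln)
  if (nrow(aln) == 0) {
    aln$identity <- numeric(0)
    return(aln)
  }
  validate_alignments(aln)
}

# keep the best record among near-duplicate (query,target,strand) alignments:
# records whose query intervals overlap reciprocally by more than half are
# shifted-diagonal re-finds of one true overlap
dedupe_overlaps <- function(aln) {
  if (nrow(aln) < 2) return(aln)
  aln <- aln[order(aln$query_id, aln$target_id, aln$strand,
                   -aln$matches), , drop = FALSE]
  keep <- rep(TRUE, nrow(aln))
  key <- paste(aln$query_id, aln$target_id, aln$strand)
  for (g in split(seq_len(nrow(aln)), key)) {
    if (length(g) < 2) next
    for (i in seq_along(g)[-1]) {
      for (j in seq_len(i - 1)) {
        if (!keep[g[j]]) next
        ov <- min(aln$q_end[g[i]], aln$q_end[g[j]]) -
          max(aln$q_start[g[i]], aln$q_start[g[j]])
        shorter <- min(aln$q_end[g[i]] - aln$q_start[g[i]],
                       aln$q_end[g[j]] - aln$q_start[g[j]])
        if (ov > 0.5 * shorter) { keep[g[i]] <- FALSE; break }
      }
    }
  }
  aln[keep, , drop = FALSE]
}

#' Classify a fosmid-vs-WGS alignment as a qualifying overlap
#'
#' An alignment (query = fosmid contig, target = WGS contig) qualifies as a
#' graph connection when identity exceeds the round's threshold, the matched
#' length on the WGS contig exceeds `params$min_matched_len` and the overhang
#' (unaligned WGS sequence between the aligned block and the nearer contig
#' end) is below `params$max_overhang`. Alignments reaching neither WGS end
#' within the overhang limit are rejected as `internal-alignment` (chimera
#' candidates, not connections).
#'
#' @param aln Alignment records (query = fosmid, target = WGS).
#' @param identity_thr Identity threshold of the current merge round.
#' @param params [fb_params()].
#' @return A `data.frame` with one row per input record: the overlap fields
#'   (`wgs_id`, `wgs_end`, `fosmid_id`, `f_start`, `f_end`, `strand`,
#'   `identity`, `matched_len`, `overhang`), `accepted` and `reason`
#'   (`"ok"`, `"low-identity"`, `"short-overlap"`, `"internal-alignment"`).
#' @export
classify_overlap <- function(aln, identity_thr, params = fb_params()) {
  matched <- aln$t_end - aln$t_start
  over_l <- aln$t_start
  over_r <- aln$t_len - aln$t_end
  wgs_end <- ifelse(over_l <= over_r, "L", "R")
  overhang <- pmin(over_l, over_r)
  reason <- rep("ok", nrow(aln))
  reason[overhang >= params$max_overhang] <- "internal-alignment"
  reason[reason == "ok" & matched <= params$min_matched_len] <- "short-overlap"
  reason[reason == "ok" & aln$identity <= identity_thr] <- "low-identity"
  data.frame(wgs_id = aln$target_id, wgs_end = wgs_end,
             fosmid_id = aln$query_id,
             f_start = aln$q_start, f_end = aln$q_end, f_len = aln$q_len,
             strand = aln$strand, identity = aln$identity,
             matched_len = matched, overhang = overhang,
             accepted = reason == "ok", reason = reason,
             stringsAsFactors = FALSE)
}

#' Build a fosmid edge from two overlaps
#'
#' The edge length is the fosmid sequence length between the two overlaps
#' (negative when the overlapping WGS contigs share sequence, so the
#' intervals on the fosmid intersect). The edge score is the sum over the
#' two overlaps of `identity * matched_len`.
#'
#' @param a,b Single-row overlap records ([classify_overlap()]) on the same
#'   fosmid but different WGS contigs.
#' @return A one-row edge `data.frame`.
#' @export
make_edge <- function(a, b) {
  if (a$fosmid_id != b$fosmid_id) stop("overlaps on different fosmids")
  if (a$wgs_id == b$wgs_id) stop("self-edge: both overlaps on ", a$wgs_id)
  if (a$f_start > b$f_start) { tmp <- a; a <- b; b <- tmp }
  data.frame(fosmid = a$fosmid_id, f_len = a$f_len,
             a_id = a$wgs_id, a_end = a$wgs_end, a_fstart = a$f_start,
             a_fend = a$f_end, a_strand = a$strand, a_identity = a$identity,
             a_matched = a$matched_len, a_overhang = a$overhang,
             b_id = b$wgs_id, b_end = b$wgs_end, b_fstart = b$f_start,
             b_fend = b$f_end, b_strand = b$strand, b_identity = b$identity,
             b_matched = b$matched_len, b_overhang = b$overhang,
             score = a$identity * a$matched_len + b$identity * b$matched_len,
             length = b$f_start - a$f_end,
             min_identity = min(a$identity, b$identity),
             stringsAsFactors = FALSE)
}

#' Turn qualifying overlaps into fosmid edges
#'
#' For each fosmid, every pair of distinct WGS contigs it overlaps yields one
#' edge; when a fosmid overlaps one contig more than once, the highest
#' `identity * matched_len` overlap represents that contig.
#'
#' @param overlaps Accepted overlap records ([classify_overlap()]).
#' @return An edge `data.frame` (zero rows when no pair qualifies).
#' @export
edges_from_overlaps <- function(overlaps) {
  ov <- overlaps[overlaps$accepted, , drop = FALSE]
  out <- list()
  for (g in split(seq_len(nrow(ov)), ov$fosmid_id)) {
    sub <- ov[g, , drop = FALSE]
    ids <- unique(sub$wgs_id)
    if (length(ids) < 2) next
    best <- lapply(ids, function(id) {
      s <- sub[sub$wgs_id == id, , drop = FALSE]
      s[which.max(s$identity * s$matched_len), , drop = FALSE]
    })
    names(best) <- ids
    for (i in seq_len(length(ids) - 1))
      for (j in seq(i + 1, length(ids)))
        out[[length(out) + 1]] <- make_edge(best[[i]], best[[j]])
  }
  if (length(out) == 0) return(empty_edges())
  do.call(rbind, out)
}

empty_edges <- function() {
  e <- make_edge(
    data.frame(fosmid_id = "f", wgs_id = "a", wgs_end = "R", f_start = 0,
               f_end = 1, f_len = 2, strand = "+", identity = 1,
               matched_len = 1, overhang = 0, stringsAsFactors = FALSE),
    data.frame(fosmid_id = "f", wgs_id = "b", wgs_end = "L", f_start = 1,
               f_end = 2, f_len = 2, strand = "+", identity = 1,
               matched_len = 1, overhang = 0, stringsAsFactors = FALSE))
  e[0, , drop = FALSE]
}

#' Write fosmid edges as TSV
#' @param edges Edge table ([edges_from_overlaps()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  out <- edges[c("fosmid", "a_id", "a_end", "b_id", "b_end", "score", "length")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
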