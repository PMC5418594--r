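#' Construct a nicking-site map
#'
#' @param id Map id.
#' @param length Molecule/sequence length in bases.
#' @param sites Strictly increasing 0-based site positions in `[0, length)`.
#' @return An `fb_nickmap` object.
#' @export
nickmap <- function(id, length, sites) {
  sites <- as.numeric(sites)
  if (is.unsorted(sites, strictly = TRUE)) sites <- sort(unique(sites))
  if (length(sites) > 0 && (min(sites) < 0 || max(sites) >= length))
    stop("sites must lie in [0, length)")
  structure(list(id = as.character(id), length = as.numeric(length),
                 sites = sites), class = "fb_nickmap")
}

#' @export
print.fb_nickmap <- function(x, ...) {
  cat(sprintf("nickmap %s: %d sites over %.0f bases\n", x$id,
              length(x$sites), x$length))
  invisible(x)
}

#' In-silico digest of a sequence
#'
#' Records the start positions of the nicking motif on both strands (the
#' reverse strand is matched through the motif's reverse complement on the
#' forward sequence), sorted and de-duplicated. The default motif is the
#' Nt.BspQI recognition site.
#'
#' @param sequence A nucleotide string.
#' @param motif Recognition motif (ACGT only).
#' @param id Id recorded on the resulting map.
#' @return An `fb_nickmap`.
#' @export
digest <- function(sequence, motif = "GCTCTTC", id = "digest") {
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) stop("motif must contain only ACGT")
  sequence <- toupper(sequence)
  hits <- function(pat) {
    m <- gregexpr(pat, sequence, fixed = TRUE)[[1]]
    if (m[1] == -1) numeric(0) else as.numeric(m) - 1
  }
  sites <- sort(unique(c(hits(motif), hits(revcomp(motif)))))
  nickmap(id, nchar(sequence), sites)
}

#' Align two nicking-site maps
#'
#' Dynamic program over site indices: matched site pairs are chained
#' monotonically in both maps, each chunk skipping at most `max_skip` sites
#' per map. A chunk's spans agree when their difference is within
#' `max(3 * sigma * sqrt(skipped + 1), tol)`; larger differences are bridged
#' by a flat-penalty indel move so that genuine insertions or deletions stay
#' inside one chain. Both query orientations are tried.
#'
#' @param query,ref `fb_nickmap` objects.
#' @param sigma Sizing error s.d. in bases.
#' @param max_skip Maximum skipped sites per map between matched pairs.
#' @param tol Floor of the sizing gate in bases.
#' @param try_reverse Also score the reversed query and keep the better.
#' @return An `fb_mapaln`: `query_id`, `ref_id`, `strand`, `score`, `pairs`
#'   (`data.frame` of matched site indices `qi`, `ri` (1-based, on the
#'   oriented query) and positions `q_pos`, `r_pos`).
#' @export
align_nickmaps <- function(query, ref, sigma = 500, max_skip = 2, tol = 1000,
                           try_reverse = TRUE) {
  run <- function(qsites) nickmap_dp_cpp(qsites, ref$sites, sigma,
                                         as.integer(max_skip), tol,
                                         5.0, 3.0, 12.0)
  fwd <- run(query$sites)
  best <- fwd; strand <- "+"; qsites <- query$sites
  if (try_reverse && length(query$sites) > 1) {
    rsites <- sort(query$length - rev(query$sites))
    rev_ <- run(rsites)
    if (rev_$score > fwd$score) { best <- rev_; strand <- "-"; qsites <- rsites }
  }
  pairs <- data.frame(qi = best$qi, ri = best$ri,
                      q_pos = qsites[best$qi], r_pos = ref$sites[best$ri])
  structure(list(query_id = query$id, ref_id = ref$id, strand = strand,
                 score = best$score, pairs = pairs), class = "fb_mapaln")
}

#' Call indels from a map alignment
#'
#' Every interval between consecutive matched site pairs whose span
#' difference (reference minus query) reaches `indel_min` in magnitude
#' becomes a call: positive differences are insertions in the reference
#' (the assembly carries extra sequence relative to the map), negative ones
#' deletions. Calls below `indel_hi` are class `mid`, the rest `large`.
#'
#' @param aln An `fb_mapaln` ([align_nickmaps()]).
#' @param indel_min,indel_hi Size-class boundaries in bases.
#' @return `data.frame`: `ref_id`, `ref_start`, `ref_end`, `size`, `kind`,
#'   `size_class`.
#' @export
call_indels <- function(aln, indel_min = 1000, indel_hi = 10000) {
  p <- aln$pairs
  out <- data.frame(ref_id = character(0), ref_start = numeric(0),
                    ref_end = numeric(0), size = numeric(0),
                    kind = character(0), size_class = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(p) < 2) return(out)
  dq <- diff(p$q_pos)
  dr <- diff(p$r_pos)
  diffd <- dr - dq
  sel <- which(abs(diffd) >= indel_min)
  if (length(sel) == 0) return(out)
  data.frame(ref_id = aln$ref_id, ref_start = p$r_pos[sel],
             ref_end = p$r_pos[sel + 1], size = abs(diffd[sel]),
             kind = ifelse(diffd[sel] > 0, "insertion", "deletion"),
             size_class = ifelse(abs(diffd[sel]) < indel_hi, "mid", "large"),
             stringsAsFactors = FALSE)
}

#' Connection coverage and flag statistics
#'
#' A connecting region (junction) is covered when one map alignment's
#' matched chain has matched sites on both of its flanks; it is flagged when
#' it additionally lies inside a called indel of a covering alignment. The
#' flagged fraction of covered junctions bounds the connection error rate.
#'
#' @param alignments List of `fb_mapaln` objects (maps aligned to
#'   pseudomolecules).
#' @param junctions `data.frame` with `ref_id` and `pos` (junction positions
#'   on the pseudomolecules).
#' @param indel_min,indel_hi Passed to [call_indels()].
#' @return A list: `covered`, `flagged`, `coverage_pct`, `flagged_pct`.
#' @export
connection_coverage <- function(alignments, junctions, indel_min = 1000,
                                indel_hi = 10000) {
  covered <- logical(nrow(junctions))
  flagged <- logical(nrow(junctions))
  for (aln in alignments) {
    p <- aln$pairs
    if (nrow(p) < 2) next
    sel <- which(junctions$ref_id == aln$ref_id &
                 junctions$pos > min(p$r_pos) & junctions$pos < max(p$r_pos))
    if (length(sel) == 0) next
    covered[sel] <- TRUE
    calls <- call_indels(aln, indel_min, indel_hi)
    if (nrow(calls) > 0)
      for (j in sel)
        if (any(calls$ref_start <= junctions$pos[j] &
                junctions$pos[j] < calls$ref_end))
          flagged[j] <- TRUE
  }
  list(covered = sum(covered), flagged = sum(flagged),
       coverage_pct = if (nrow(junctions) > 0)
         100 * sum(covered) / nrow(junctions) else 0,
       flagged_pct = if (sum(covered) > 0)
         100 * sum(flagged) / sum(covered) else 0)
}

#' Search the overlap graph for an alternative path through a flagged region
#'
#' Enumerates simple paths (bounded depth and count) between two long
#' flanking contigs, emits each candidate's sequence, digests it and keeps
#' candidates whose emitted length matches the expected span within
#' `params$match_tolerance` and whose site pattern aligns to the reference
#' map slice with no residual interval difference of `params$indel_min` or
#' more. Among qualifying candidates the one with the highest edge-score sum
#' wins.
#'
#' @param g An `fb_graph` (all edges, including retired ones, are searched).
#' @param left,right Flanking contig ids (each at least
#'   `params$flank_min_len` long).
#' @param target_span Expected emitted length of the replacement path
#'   (bases, flanks included).
#' @param ref_sites `fb_nickmap` slice of the reference map over the region.
#' @param contigs,fosmids Contig sets providing sequences.
#' @param params [fb_params()].
#' @param max_depth Maximum number of contigs on a path.
#' @param max_paths Enumeration cap.
#' @return The winning candidate (list: `segments`, `sequence`, `span`,
#'   `score`) or `NULL` when no path qualifies.
#' @export
find_alternative_path <- function(g, left, right, target_span, ref_sites,
                                  contigs, fosmids, params = fb_params(),
                                  max_depth = 8, max_paths = 10000) {
  for (id in c(left, right)) {
    i <- match(id, g$nodes$id)
    if (is.na(i)) stop("unknown contig: ", id)
    if (g$nodes$length[i] < params$flank_min_len)
      stop("flanking contig ", id, " shorter than flank_min_len")
  }
  e <- g$edges
  n_found <- 0
  cands <- list()
  # DFS over (contig, entry end); edges attach at the exit end
  dfs <- function(path_ids, path_edges, cur, entry) {
    if (n_found >= max_paths || length(path_ids) > max_depth) return()
    if (cur == right) {
      n_found <<- n_found + 1
      cands[[length(cands) + 1]] <<- list(ids = path_ids, edges = path_edges,
                                          entries = attr(path_ids, "entries"))
      return()
    }
    exit <- if (is.na(entry)) NA else if (entry == "L") "R" else "L"
    for (use in (if (is.na(exit)) c("L", "R") else exit)) {
      sel <- which((e$a_id == cur & e$a_end == use) |
                   (e$b_id == cur & e$b_end == use))
      for (k in sel) {
        nxt_id <- if (e$a_id[k] == cur) e$b_id[k] else e$a_id[k]
        nxt_end <- if (e$a_id[k] == cur) e$b_end[k] else e$a_end[k]
        if (nxt_id %in% path_ids) next
        np <- c(path_ids, nxt_id)
        attr(np, "entries") <- c(attr(path_ids, "entries"), nxt_end)
        dfs(np, c(path_edges, k), nxt_id, nxt_end)
      }
    }
  }
  start <- left
  attr(start, "entries") <- character(0)
  dfs(start, integer(0), left, NA)
  best <- NULL
  for (cd in cands) {
    ids <- as.character(cd$ids)
    entries <- cd$entries  # entry end per non-first contig
    orient <- character(length(ids))
    er <- e[cd$edges, , drop = FALSE]
    # first contig orientation: exits via the end the first edge uses
    first_end <- if (er$a_id[1] == ids[1]) er$a_end[1] else er$b_end[1]
    orient[1] <- if (first_end == "R") "+" else "-"
    for (j in seq_along(entries))
      orient[j + 1] <- if (entries[j] == "L") "+" else "-"
    segs <- data.frame(contig_id = ids, orient = orient,
                       stringsAsFactors = FALSE)
    em <- try(emit_sequence(segs, er, contigs, fosmids), silent = TRUE)
    if (inherits(em, "try-error")) next
    span <- nchar(em$sequence)
    if (abs(span - target_span) > params$match_tolerance) next
    dg <- digest(em$sequence, id = "candidate")
    aln <- align_nickmaps(dg, ref_sites, sigma = params$sigma,
                          max_skip = params$max_skip,
                          tol = params$match_tolerance)
    if (nrow(aln$pairs) < 2) next
    resid <- abs(diff(aln$pairs$r_pos) - diff(aln$pairs$q_pos))
    if (any(resid >= params$indel_min)) next
    score <- sum(er$score)
    if (is.null(best) || score > best$score)
      best <- list(segments = segs, sequence = em$sequence, span = span,
                   score = score)
  }
  best
}

#' Write nick maps as a CMAP-like TSV
#' @param maps List of `fb_nickmap` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nickmaps <- function(maps, path) {
  rows <- do.call(rbind, lapply(maps, function(m)
    data.frame(id = m$id, length = m$length,
               site = if (length(m$sites) > 0) m$sites else NA_real_)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read nick maps from a CMAP-like TSV
#' @param path Path written by [write_nickmaps()].
#' @return A list of `fb_nickmap` objects.
#' @export
read_nickmaps <- function(path) {
  tb <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  lapply(split(tb, tb$id), function(s)
    nickmap(s$id[1], s$length[1], s$site[!is.na(s$site)]))
}
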