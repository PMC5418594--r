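rotations <- function(unit) {
  n <- nchar(unit)
  vapply(seq_len(n) - 1L, function(k)
    paste0(substr(unit, k + 1, n), substr(unit, 1, k)), character(1))
}

# exact or mismatch-tolerant hits of a set of patterns; 0-based starts
pattern_hits <- function(sequence, patterns, max_mismatch = 0) {
  if (max_mismatch == 0) {
    starts <- unlist(lapply(patterns, function(p) {
      m <- gregexpr(p, sequence, fixed = TRUE)[[1]]
      if (m[1] == -1) numeric(0) else as.numeric(m) - 1
    }))
  } else {
    subj <- Biostrings::DNAString(sequence)
    starts <- unlist(lapply(patterns, function(p) {
      m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mismatch)
      as.numeric(Biostrings::start(m)) - 1
    }))
  }
  sort(unique(starts))
}

merge_hit_arrays <- function(starts, unit_len, merge_dist = unit_len) {
  if (length(starts) == 0)
    return(data.frame(start = numeric(0), end = numeric(0), n_hits = numeric(0)))
  brk <- c(0, which(diff(starts) > unit_len + merge_dist), length(starts))
  out <- lapply(seq_len(length(brk) - 1), function(i) {
    s <- starts[(brk[i] + 1):brk[i + 1]]
    data.frame(start = s[1], end = s[length(s)] + unit_len, n_hits = length(s))
  })
  do.call(rbind, out)
}

#' Find telomere repeat arrays
#'
#' Searches all cyclic rotations of the telomere unit and of its reverse
#' complement, merges nearby hits into arrays, and reports arrays with at
#' least `min_copies` copies (span / unit length).
#'
#' @param sequence Nucleotide string.
#' @param unit Telomere repeat unit (the plant unit by default; a warning is
#'   given for units of other lengths, which are still searched).
#' @param min_copies Minimum copies per reported array.
#' @param max_divergence Per-unit mismatch fraction tolerated.
#' @return `data.frame`: `start`, `end` (0-based half-open), `unit`,
#'   `copies`, `mean_unit_identity`.
#' @export
find_telomere_arrays <- function(sequence, unit = "AAACCCT", min_copies = 10,
                                 max_divergence = 0) {
  if (nchar(unit) != 7)
    warning("telomere unit is typically 7 bases; searching anyway")
  pats <- unique(c(rotations(unit), rotations(revcomp(unit))))
  find_repeat_arrays(sequence, unit, min_full_units = min_copies,
                     min_identity = 1 - max_divergence, patterns = pats)
}

#' Find tandem repeat arrays of an arbitrary unit
#'
#' Mismatch-tolerant unit matching with hits within one unit length merged
#' into arrays; copies = merged span / unit length.
#'
#' @param sequence Nucleotide string.
#' @param unit Repeat unit.
#' @param min_full_units Minimum copies per reported array.
#' @param min_identity Minimum per-unit identity.
#' @param patterns Optional explicit pattern set (used by the telomere
#'   finder to search unit rotations).
#' @return `data.frame` as in [find_telomere_arrays()].
#' @export
find_repeat_arrays <- function(sequence, unit, min_full_units = 2,
                               min_identity = 0.95, patterns = NULL) {
  if (nchar(unit) == 0) stop("empty repeat unit")
  sequence <- toupper(sequence)
  mm <- floor((1 - min_identity) * nchar(unit))
  if (is.null(patterns)) patterns <- toupper(unit)
  starts <- pattern_hits(sequence, patterns, max_mismatch = mm)
  arr <- merge_hit_arrays(starts, nchar(unit))
  arr$unit <- unit
  arr$copies <- (arr$end - arr$start) / nchar(unit)
  # identity proxy: fraction of the array covered by recognized units
  arr$mean_unit_identity <- pmin(1, arr$n_hits * nchar(unit) /
                                      (arr$end - arr$start))
  arr <- arr[arr$copies >= min_full_units, , drop = FALSE]
  rownames(arr) <- NULL
  arr[c("start", "end", "unit", "copies", "mean_unit_identity")]
}

#' Circularize a contig with a terminal repeat
#'
#' If the contig's prefix and suffix share an overlap of at least
#' `min_overlap` bases at `min_identity` or better, one copy of the repeat
#' is trimmed, the sequence is marked circular and its start is normalized
#' to the lexicographically minimal rotation.
#'
#' @param contig A sequence string, or one-row contig set.
#' @param min_overlap Minimum terminal repeat length.
#' @param min_identity Minimum repeat identity.
#' @return A list (`sequence`, `length`, `trimmed`) or `NULL` when no
#'   terminal overlap is found. Overlaps spanning more than half the contig
#'   raise an error (likely tandem duplication, not a circle).
#' @export
circularize <- function(contig, min_overlap = 1000, min_identity = 0.99) {
  s <- if (is.data.frame(contig)) contig$sequence[1] else contig
  s <- toupper(s)
  n <- nchar(s)
  # full self-alignment (off the main diagonal) so tandem-scale terminal
  # repeats are seen at their full length
  aln <- find_overlaps(setNames(s, "q"), setNames(s, "t"),
                       min_len = max(100, min_overlap),
                       min_identity = min_identity, skip_same_id = FALSE,
                       dedupe = FALSE)
  aln <- aln[aln$strand == "+" & aln$q_start != aln$t_start &
             aln$t_start <= 10 & aln$q_len - aln$q_end <= 10, , drop = FALSE]
  if (nrow(aln) == 0) return(NULL)
  L <- max(aln$t_end - aln$t_start)
  if (L > n / 2) stop("terminal overlap spans >50% of the contig: ",
                      "likely tandem duplication, not circle")
  if (L < min_overlap) return(NULL)
  circ <- substr(s, 1, n - L)
  k <- least_rotation(circ)
  circ <- paste0(substr(circ, k + 1, nchar(circ)), substr(circ, 1, k))
  list(sequence = circ, length = nchar(circ), trimmed = L)
}

# Booth's algorithm: 0-based start of the lexicographically minimal rotation
least_rotation <- function(s) {
  b <- utf8ToInt(paste0(s, s))
  n2 <- length(b)
  f <- rep.int(-1L, n2)
  k <- 0L
  for (j in seq_len(n2 - 1)) {        # j is 0-based index j in 1..n2-1
    sj <- b[j + 1]
    i <- f[j - k]                      # f[(j-k-1) + 1]
    while (i != -1L && sj != b[k + i + 2]) {
      if (sj < b[k + i + 2]) k <- j - i - 1L
      i <- f[i + 1]
    }
    if (sj != b[k + i + 2]) {
      if (sj < b[k + 1]) k <- j
      f[j - k + 1] <- -1L
    } else {
      f[j - k + 1] <- i + 1L
    }
  }
  k
}

#' Classify the placement of a contig against a finished assembly
#'
#' Applies the post-assembly examination rules: a contig is `incorporated`
#' when its best-matched assembly location covers at least `min_coverage`
#' of it at `min_identity` or better; `erroneous` when it aligns to two or
#' more significant non-overlapping locations, or leaves a terminal
#' overhang above 1 kb with low coverage; otherwise `organelle`,
#' `centromeric` or `contaminant-like` by class-specific coverage rules;
#' else `unclassified`. One contig is assigned one best-matched location.
#'
#' @param contig One-row contig set (or a list with `id` and `length`).
#' @param alignments Alignment records of the contig (query) against the
#'   assembly and auxiliary sequence classes, with an extra `target_class`
#'   column in `{"assembly", "organelle", "centromere", "contaminant"}`.
#' @param min_identity,min_coverage Incorporation thresholds.
#' @param organelle_min_identity Identity floor for organelle assignment.
#' @param max_overhang Overhang (bases) beyond which a single-location
#'   alignment with low coverage is called erroneous.
#' @param cluster_gap Blocks within this distance on one target chain into
#'   one candidate location.
#' @return One-row `data.frame`: `contig_id`, `verdict`, `coverage`,
#'   `identity`, `overhang`, `n_locations`.
#' @export
classify_placement <- function(contig, alignments, min_identity = 0.97,
                               min_coverage = 0.95,
                               organelle_min_identity = 0.95,
                               max_overhang = 1000, cluster_gap = 100000) {
  id <- if (is.data.frame(contig)) contig$id[1] else contig$id
  qlen <- if (is.data.frame(contig)) contig$length[1] else contig$length
  report <- function(verdict, coverage = NA, identity = NA, overhang = NA,
                     n_loc = NA)
    data.frame(contig_id = id, verdict = verdict, coverage = coverage,
               identity = identity, overhang = overhang,
               n_locations = n_loc, stringsAsFactors = FALSE)
  cls_cov <- function(cls, min_id = 0) {
    a <- alignments[alignments$target_class == cls &
                    alignments$identity >= min_id, , drop = FALSE]
    if (nrow(a) == 0) return(0)
    iv <- IRanges::reduce(IRanges::IRanges(a$q_start + 1, a$q_end))
    sum(IRanges::width(iv)) / qlen
  }
  asm <- alignments[alignments$target_class == "assembly", , drop = FALSE]
  if (nrow(asm) > 0) {
    # candidate locations: blocks chained per target within cluster_gap
    asm <- asm[order(asm$target_id, asm$t_start), , drop = FALSE]
    loc <- cumsum(c(TRUE, asm$target_id[-1] != asm$target_id[-nrow(asm)] |
                    asm$t_start[-1] - asm$t_end[-nrow(asm)] > cluster_gap))
    locs <- lapply(split(seq_len(nrow(asm)), loc), function(g) {
      a <- asm[g, , drop = FALSE]
      iv <- IRanges::reduce(IRanges::IRanges(a$q_start + 1, a$q_end))
      list(q_cov = sum(IRanges::width(iv)),
           identity = sum(a$matches) / sum(a$aln_len),
           q_min = min(a$q_start), q_max = max(a$q_end))
    })
    sig <- vapply(locs, function(l) l$q_cov >= max(5000, 0.1 * qlen),
                  logical(1))
    n_sig <- sum(sig)
    best <- locs[[which.max(vapply(locs, function(l) l$q_cov, numeric(1)))]]
    coverage <- best$q_cov / qlen
    overhang <- max(best$q_min, qlen - best$q_max)
    if (n_sig >= 2)
      return(report("erroneous", coverage, best$identity, overhang, n_sig))
    if (overhang > max_overhang && coverage < min_coverage)
      return(report("erroneous", coverage, best$identity, overhang, max(n_sig, 1)))
    if (coverage >= min_coverage && best$identity >= min_identity)
      return(report("incorporated", coverage, best$identity, overhang, 1))
  }
  if (cls_cov("organelle", organelle_min_identity) >= min_coverage)
    return(report("organelle", cls_cov("organelle", organelle_min_identity)))
  if (cls_cov("centromere") >= min_coverage)
    return(report("centromeric", cls_cov("centromere")))
  if (cls_cov("contaminant") >= min_coverage)
    return(report("contaminant-like", cls_cov("contaminant")))
  report("unclassified")
}

#' Call presence variations from collinear alignment blocks
#'
#' Gaps of at least `pv_min_gap` bases between consecutive collinear,
#' non-overlapping blocks (each at least `pv_min_block`) are PV candidates.
#' When the other genome's sequence is supplied, candidate segments with
#' homology of 200 bases or more to it are subtracted. Survivors of at least
#' `pv_min_len` are kept; when a short-read coverage track is supplied, only
#' candidates with coverage below `pv_max_coverage` are retained.
#'
#' @param blocks `data.frame` of collinear blocks: `ref_chrom`, `ref_start`,
#'   `ref_end`, `qry_chrom`, `qry_start`, `qry_end` (0-based half-open).
#' @param side `"ref"` or `"qry"`: which genome to call PVs on.
#' @param self_genome Named sequences of the PV-side genome (for homology
#'   subtraction; optional).
#' @param other_genome Named sequences of the other genome (optional).
#' @param coverage Optional per-chromosome numeric coverage track list
#'   (values per base) for the PV-side genome.
#' @param cov_mode `"fraction_covered"` (fraction of candidate bases with
#'   coverage > 0) or `"mean"` (mean per-base coverage fraction).
#' @param params [fb_params()].
#' @return `data.frame` of PVs: `chrom`, `start`, `end`, `length`,
#'   `gap_start`, `gap_end`, `homology_removed`, `coverage`.
#' @export
call_pv <- function(blocks, side = c("ref", "qry"), self_genome = NULL,
                    other_genome = NULL, coverage = NULL,
                    cov_mode = c("fraction_covered", "mean"),
                    params = fb_params()) {
  side <- match.arg(side)
  cov_mode <- match.arg(cov_mode)
  pre <- if (side == "ref") "ref" else "qry"
  bl <- data.frame(chrom = blocks[[paste0(pre, "_chrom")]],
                   start = blocks[[paste0(pre, "_start")]],
                   end = blocks[[paste0(pre, "_end")]],
                   stringsAsFactors = FALSE)
  bl <- bl[bl$end - bl$start >= params$pv_min_block, , drop = FALSE]
  out <- list()
  for (chrom in unique(bl$chrom)) {
    b <- bl[bl$chrom == chrom, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping blocks on ", chrom)
    if (nrow(b) < 2) next
    gs <- b$end[-nrow(b)]
    ge <- b$start[-1]
    keep <- ge - gs >= params$pv_min_gap
    for (i in which(keep)) {
      segs <- data.frame(start = gs[i], end = ge[i])
      removed <- 0
      if (!is.null(self_genome) && !is.null(other_genome)) {
        cand_seq <- substr(self_genome[[chrom]], gs[i] + 1, ge[i])
        hom <- find_overlaps(setNames(cand_seq, "cand"), other_genome,
                             k = 13, min_len = 200, min_identity = 0.8,
                             skip_same_id = FALSE)
        if (nrow(hom) > 0) {
          iv <- IRanges::reduce(IRanges::IRanges(hom$q_start + 1, hom$q_end))
          iv <- iv[IRanges::width(iv) >= 200]
          if (length(iv) > 0) {
            removed <- sum(IRanges::width(iv))
            full <- IRanges::IRanges(1, ge[i] - gs[i])
            left <- IRanges::setdiff(full, iv)
            segs <- if (length(left) == 0)
              data.frame(start = numeric(0), end = numeric(0))
            else data.frame(start = gs[i] + IRanges::start(left) - 1,
                            end = gs[i] + IRanges::end(left))
          }
        }
      }
      segs <- segs[segs$end - segs$start >= params$pv_min_len, , drop = FALSE]
      if (nrow(segs) == 0) next
      segs$coverage <- NA_real_
      if (!is.null(coverage)) {
        tr <- coverage[[chrom]]
        segs$coverage <- vapply(seq_len(nrow(segs)), function(k) {
          v <- tr[(segs$start[k] + 1):segs$end[k]]
          if (cov_mode == "fraction_covered") mean(v > 0) else mean(v)
        }, numeric(1))
        segs <- segs[segs$coverage < params$pv_max_coverage, , drop = FALSE]
        if (nrow(segs) == 0) next
      }
      segs$chrom <- chrom
      segs$gap_start <- gs[i]
      segs$gap_end <- ge[i]
      segs$homology_removed <- removed
      out[[length(out) + 1]] <- segs
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0),
                      gap_start = numeric(0), gap_end = numeric(0),
                      homology_removed = numeric(0), coverage = numeric(0),
                      stringsAsFactors = FALSE))
  pv <- do.call(rbind, out)
  pv$length <- pv$end - pv$start
  rownames(pv) <- NULL
  pv[c("chrom", "start", "end", "length", "gap_start", "gap_end",
       "homology_removed", "coverage")]
}

#' Shared presence variations between two comparisons
#'
#' Two PVs on one reference genome are shared when they overlap each other
#' reciprocally by more than `frac` of each PV's length.
#'
#' @param pvs_a,pvs_b PV tables ([call_pv()]) on the same reference genome.
#' @param frac Reciprocal overlap fraction.
#' @return `data.frame` of shared pairs with the overlap length.
#' @export
shared_pv <- function(pvs_a, pvs_b, frac = 0.75) {
  out <- data.frame(chrom = character(0), a_start = numeric(0),
                    a_end = numeric(0), b_start = numeric(0),
                    b_end = numeric(0), overlap = numeric(0),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pvs_a)))
    for (j in seq_len(nrow(pvs_b))) {
      if (pvs_a$chrom[i] != pvs_b$chrom[j]) next
      ov <- min(pvs_a$end[i], pvs_b$end[j]) -
        max(pvs_a$start[i], pvs_b$start[j])
      la <- pvs_a$end[i] - pvs_a$start[i]
      lb <- pvs_b$end[j] - pvs_b$start[j]
      if (ov > frac * la && ov > frac * lb)
        out <- rbind(out, data.frame(chrom = pvs_a$chrom[i],
                                     a_start = pvs_a$start[i],
                                     a_end = pvs_a$end[i],
                                     b_start = pvs_b$start[j],
                                     b_end = pvs_b$end[j], overlap = ov,
                                     stringsAsFactors = FALSE))
    }
  out
}

#' Write PV intervals as BED
#' @param pvs PV table ([call_pv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pv_bed <- function(pvs, path) {
  out <- data.frame(chrom = pvs$chrom, start = pvs$start, end = pvs$end,
                    name = sprintf("PV_%d", seq_len(nrow(pvs))),
                    length = pvs$length,
                    coverage = ifelse(is.na(pvs$coverage), ".",
                                      format(pvs$coverage, digits = 3)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
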