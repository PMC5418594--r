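random_seq <- function(n, gc = 0.44) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  rawToChar(as.raw(utf8ToInt("ACGT")[sample.int(4, n, replace = TRUE,
                                                prob = p)]))
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  k <- rbinom(1, n, rate)
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  b <- charToRaw(s)
  bases <- charToRaw("ACGT")
  for (i in pos) {
    cur <- b[i]
    alt <- bases[bases != cur]
    b[i] <- alt[sample.int(length(alt), 1)]
  }
  rawToChar(b)
}

#' Simulate a ground-truth genome
#'
#' Generates a deterministic genome (given the seed) with realistic
#' composition: GC content near 44%, telomere repeat arrays at every
#' chromosome end, one diverged centromeric tandem array per chromosome and
#' dispersed LTR-like repeat copies.
#'
#' @param seed Integer seed; every simulated artifact is a pure function of
#'   the seed and parameters.
#' @param n_chrom,chrom_len Number and length of chromosomes.
#' @param gc Target GC fraction.
#' @param repeat_spec A list with optional entries `telomere`
#'   (`unit`, `copies`), `centromere` (`unit_len`, `copies`, `divergence`)
#'   and `ltr` (`n`, `len`, `divergence`); `NULL` entries disable a feature.
#' @return An `fb_simtruth` object holding the genome and all truth tables
#'   filled in by the downstream `simulate_*` steps.
#' @export
simulate_genome <- function(seed = 1, n_chrom = 2, chrom_len = 2500000,
                            gc = 0.44,
                            repeat_spec = list(
                              telomere = list(unit = "TTTAGGG", copies = 100),
                              centromere = list(unit_len = 155, copies = 200,
                                                divergence = 0.02),
                              ltr = list(n = 5, len = 5000,
                                         divergence = 0.05))) {
  set.seed(seed)
  chrom_len <- rep_len(chrom_len, n_chrom)
  cen_unit <- if (!is.null(repeat_spec$centromere))
    random_seq(repeat_spec$centromere$unit_len, gc) else NULL
  ltr_elem <- if (!is.null(repeat_spec$ltr))
    random_seq(repeat_spec$ltr$len, gc) else NULL
  genome <- character(n_chrom)
  names(genome) <- paste0("chr", seq_len(n_chrom))
  for (c_i in seq_len(n_chrom)) {
    s <- random_seq(chrom_len[c_i], gc)
    if (!is.null(repeat_spec$ltr)) {
      margin <- min(100000, chrom_len[c_i] %/% 10)
      room <- chrom_len[c_i] - nchar(ltr_elem) - 2 * margin
      if (room > 0) for (k in seq_len(repeat_spec$ltr$n)) {
        copy <- mutate_seq(ltr_elem, repeat_spec$ltr$divergence)
        at <- sample.int(room, 1) + margin
        substr(s, at, at + nchar(copy) - 1) <- copy
      }
    }
    if (!is.null(repeat_spec$centromere)) {
      arr <- paste(vapply(seq_len(repeat_spec$centromere$copies), function(k)
        mutate_seq(cen_unit, repeat_spec$centromere$divergence), character(1)),
        collapse = "")
      at <- floor(chrom_len[c_i] / 2)
      substr(s, at, at + nchar(arr) - 1) <- arr
    }
    if (!is.null(repeat_spec$telomere)) {
      u <- repeat_spec$telomere$unit
      arr <- strrep(u, repeat_spec$telomere$copies)
      rarr <- strrep(revcomp(u), repeat_spec$telomere$copies)
      substr(s, 1, nchar(rarr)) <- rarr
      substr(s, chrom_len[c_i] - nchar(arr) + 1, chrom_len[c_i]) <- arr
    }
    genome[c_i] <- s
  }
  structure(list(genome = genome, seed = seed, gc = gc,
                 repeat_spec = repeat_spec,
                 layout = NULL, junctions = NULL, chimeras = NULL,
                 fosmid_origins = NULL, anchors_truth = NULL),
            class = "fb_simtruth")
}

#' @export
print.fb_simtruth <- function(x, ...) {
  cat(sprintf("fb_simtruth: %d chromosome(s), %.1f Mb, seed %d\n",
              length(x$genome), sum(nchar(x$genome)) / 1e6, x$seed))
  invisible(x)
}

#' Shred a simulated genome into WGS contigs
#'
#' Contigs tile each chromosome with 5--15 kb overlaps at junctions (so
#' neighbouring contigs share sequence, as real assemblies do at
#' repeat-broken boundaries), are stored in random orientation, and a
#' `chimera_rate` fraction of them are replaced by chimeric concatenations
#' of two segments from different chromosomes. Substitution errors are
#' injected per contig copy at `sub_error_rate`, so the identity of the
#' shared region between two overlapping contigs is about
#' `1 - 2 * sub_error_rate`.
#'
#' @param truth An `fb_simtruth` from [simulate_genome()].
#' @param n_contigs Number of tiling segments before chimerization.
#' @param chimera_rate Fraction of segments fused into chimeras (each
#'   chimera consumes two segments).
#' @param sub_error_rate Per-base substitution probability per contig copy.
#' @return The updated `fb_simtruth` with `$wgs` (contig set), `$layout`
#'   (truth table: `contig_id`, `part`, `chrom`, `start`, `end`, `orient`,
#'   `is_chimera`), `$junctions` (`chrom`, `pos`, `left_id`, `right_id`) and
#'   `$chimeras` (`contig_id`, `breakpoint`).
#' @export
shred_wgs <- function(truth, n_contigs = 60, chimera_rate = 0.05,
                      sub_error_rate = 0) {
  set.seed(truth$seed + 1000003)
  lens <- nchar(truth$genome)
  n_per <- pmax(2, round(n_contigs * lens / sum(lens)))
  layout <- data.frame()
  junctions <- data.frame()
  segs <- list()
  idx <- 0
  for (c_i in seq_along(truth$genome)) {
    len <- lens[c_i]
    chrom <- names(truth$genome)[c_i]
    k <- n_per[c_i]
    cuts <- round(seq(0, len, length.out = k + 1))[-c(1, k + 1)]
    cuts <- cuts + round(runif(length(cuts), -0.02, 0.02) * len / k)
    ovs <- round(runif(length(cuts), 5000, 15000))
    starts <- c(0, cuts - floor(ovs / 2))
    ends <- c(cuts + ceiling(ovs / 2), len)
    for (j in seq_len(k)) {
      idx <- idx + 1
      id <- sprintf("ctg_%03d", idx)
      layout <- rbind(layout, data.frame(
        contig_id = id, part = 1L, chrom = chrom, start = starts[j],
        end = ends[j], orient = "+", is_chimera = FALSE,
        stringsAsFactors = FALSE))
      if (j < k)
        junctions <- rbind(junctions, data.frame(
          chrom = chrom, pos = cuts[j], left_id = id,
          right_id = sprintf("ctg_%03d", idx + 1), stringsAsFactors = FALSE))
    }
  }
  # random stored orientation
  layout$orient <- ifelse(runif(nrow(layout)) < 0.5, "+", "-")
  # chimeras: fuse pairs of segments from different chromosomes
  n_chim <- round(chimera_rate * nrow(layout))
  chimeras <- data.frame(contig_id = character(0), breakpoint = numeric(0),
                         stringsAsFactors = FALSE)
  if (n_chim > 0 && length(unique(layout$chrom)) >= 2) {
    # avoid terminal segments so both pieces stay long and interior
    eligible <- which(!(layout$start == 0 |
                        layout$end == lens[match(layout$chrom,
                                                 names(truth$genome))]))
    pool <- sample(eligible)
    pairs <- list()
    while (length(pairs) < n_chim && length(pool) >= 2) {
      a <- pool[1]
      partner <- pool[-1][layout$chrom[pool[-1]] != layout$chrom[a]]
      if (length(partner) == 0) break
      b <- partner[1]
      pairs[[length(pairs) + 1]] <- c(a, b)
      pool <- setdiff(pool, c(a, b))
    }
    for (p_i in seq_along(pairs)) {
      a <- pairs[[p_i]][1]; b <- pairs[[p_i]][2]
      id <- sprintf("chim_%02d", p_i)
      bp <- layout$end[a] - layout$start[a]
      layout$contig_id[a] <- id
      layout$is_chimera[a] <- TRUE
      layout$contig_id[b] <- id
      layout$part[b] <- 2L
      layout$is_chimera[b] <- TRUE
      chimeras <- rbind(chimeras, data.frame(contig_id = id, breakpoint = bp,
                                             stringsAsFactors = FALSE))
    }
  }
  # realize sequences
  ids <- unique(layout$contig_id)
  seqs <- vapply(ids, function(id) {
    rows <- layout[layout$contig_id == id, , drop = FALSE]
    rows <- rows[order(rows$part), , drop = FALSE]
    pieces <- vapply(seq_len(nrow(rows)), function(r) {
      s <- substr(truth$genome[[rows$chrom[r]]], rows$start[r] + 1, rows$end[r])
      if (rows$orient[r] == "-") revcomp(s) else s
    }, character(1))
    mutate_seq(paste(pieces, collapse = ""), sub_error_rate)
  }, character(1))
  truth$wgs <- contig_set(ids, unname(seqs), source = "wgs")
  truth$layout <- layout
  truth$junctions <- junctions
  truth$chimeras <- chimeras
  truth
}

#' Simulate fosmid contigs
#'
#' Draws fosmid-sized segments from the truth genome. With
#' `junction_bias > 0` one fosmid is first placed across every WGS tiling
#' junction (centred with jitter) so that desk-scale connectivity does not
#' depend on coverage luck; the remainder (or, with `junction_bias = 0`,
#' all) are placed uniformly. Fosmids get a random strand and entries
#' shorter than `min_len` are dropped.
#'
#' @param truth `fb_simtruth` after [shred_wgs()].
#' @param n Total number of fosmids.
#' @param insert_min,insert_max Insert length range (uniform draw).
#' @param junction_bias Fraction in `[0, 1]`; `> 0` guarantees one fosmid
#'   per junction.
#' @param error_rate Per-base substitution rate on fosmid copies.
#' @param min_len Minimum retained fosmid length.
#' @return The updated `fb_simtruth` with `$fosmids` (contig set) and
#'   `$fosmid_origins` (`fosmid_id`, `chrom`, `start`, `end`, `orient`).
#' @export
simulate_fosmids <- function(truth, n = 300, insert_min = 36000,
                             insert_max = 40000, junction_bias = 1,
                             error_rate = 0, min_len = 10000) {
  set.seed(truth$seed + 2000003)
  lens <- nchar(truth$genome)
  origins <- data.frame()
  place <- function(chrom, start, len) {
    clen <- lens[[chrom]]
    start <- max(0, min(start, clen - 1))
    end <- min(clen, start + len)
    c(start = start, end = end)
  }
  k <- 0
  add <- function(chrom, start, len) {
    k <<- k + 1
    iv <- place(chrom, start, len)
    data.frame(fosmid_id = sprintf("fos_%04d", k), chrom = chrom,
               start = iv[["start"]], end = iv[["end"]],
               orient = if (runif(1) < 0.5) "+" else "-",
               stringsAsFactors = FALSE)
  }
  if (junction_bias > 0 && !is.null(truth$junctions) &&
      nrow(truth$junctions) > 0) {
    for (j in seq_len(nrow(truth$junctions))) {
      len <- round(runif(1, insert_min, insert_max))
      jitter <- round(runif(1, -2000, 2000))
      origins <- rbind(origins, add(truth$junctions$chrom[j],
                                    truth$junctions$pos[j] - floor(len / 2) +
                                      jitter, len))
    }
  }
  while (k < n) {
    chrom <- sample(names(truth$genome), 1,
                    prob = lens / sum(lens))
    len <- round(runif(1, insert_min, insert_max))
    origins <- rbind(origins, add(chrom, sample.int(lens[[chrom]], 1) - 1, len))
  }
  seqs <- vapply(seq_len(nrow(origins)), function(i) {
    s <- substr(truth$genome[[origins$chrom[i]]], origins$start[i] + 1,
                origins$end[i])
    if (origins$orient[i] == "-") s <- revcomp(s)
    mutate_seq(s, error_rate)
  }, character(1))
  keep <- nchar(seqs) >= min_len
  truth$fosmids <- contig_set(origins$fosmid_id[keep], seqs[keep],
                              source = "fosmid")
  truth$fosmid_origins <- origins[keep, , drop = FALSE]
  truth
}

#' Simulate a genetic-map anchor table
#'
#' Non-chimeric contigs are anchored in true chromosome order with
#' centimorgan positions accumulating along the map. Local adjacent swaps
#' perturb the order at `misorder_rate`, orientations are blanked to
#' unknown at `unoriented_rate`, and contigs are dropped from the map at
#' `unanchored_rate` (exact seeded counts, `round(rate * n)`). Chimeric
#' contigs are never anchored.
#'
#' @param truth `fb_simtruth` after [shred_wgs()].
#' @param misorder_rate,unoriented_rate,unanchored_rate Perturbation rates.
#' @return The updated `fb_simtruth` with `$anchors` (anchor records) and
#'   `$anchors_truth` (unperturbed).
#' @export
simulate_anchors <- function(truth, misorder_rate = 0, unoriented_rate = 0,
                             unanchored_rate = 0) {
  set.seed(truth$seed + 3000003)
  lay <- truth$layout[!truth$layout$is_chimera, , drop = FALSE]
  anchors <- data.frame()
  for (chrom in unique(lay$chrom)) {
    a <- lay[lay$chrom == chrom, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    cm <- cumsum(runif(nrow(a), 0.5, 2))
    anchors <- rbind(anchors, data.frame(
      contig_id = a$contig_id, lg_id = chrom,
      order_index = seq_len(nrow(a)), cm_position = cm,
      orientation = a$orient, stringsAsFactors = FALSE))
  }
  truth$anchors_truth <- anchors
  n <- nrow(anchors)
  n_swap <- round(misorder_rate * n)
  if (n_swap > 0) {
    for (s in seq_len(n_swap)) {
      lg <- sample(unique(anchors$lg_id), 1)
      rows <- which(anchors$lg_id == lg)
      if (length(rows) < 2) next
      i <- sample(rows[-length(rows)], 1)
      j <- i + 1
      tmp <- anchors$order_index[i]
      anchors$order_index[i] <- anchors$order_index[j]
      anchors$order_index[j] <- tmp
    }
  }
  n_un <- round(unoriented_rate * n)
  if (n_un > 0) anchors$orientation[sample.int(n, n_un)] <- "?"
  n_drop <- round(unanchored_rate * n)
  if (n_drop > 0) anchors <- anchors[-sample.int(n, n_drop), , drop = FALSE]
  # cm must stay non-decreasing with (possibly swapped) order
  anchors <- anchors[order(anchors$lg_id, anchors$order_index), , drop = FALSE]
  for (lg in unique(anchors$lg_id)) {
    rows <- which(anchors$lg_id == lg)
    anchors$cm_position[rows] <- sort(anchors$cm_position[rows])
  }
  rownames(anchors) <- NULL
  truth$anchors <- validate_anchors(anchors)
  truth
}

#' Simulate single-molecule nicking maps
#'
#' Windows of `molecule_len` (stepping half a window) are digested from the
#' truth genome; site positions are jittered by Normal(0, sigma), dropped at
#' `fn_rate` and augmented with spurious sites at `fp_rate` (exact seeded
#' counts).
#'
#' @param truth `fb_simtruth`.
#' @param molecule_len Window length in bases.
#' @param sigma Positional jitter s.d.
#' @param fn_rate,fp_rate Site false-negative and false-positive rates.
#' @param motif Nicking motif.
#' @return A list of `fb_nickmap` objects with a `truth` attribute
#'   (`data.frame`: `id`, `chrom`, `start`).
#' @export
simulate_nickmaps <- function(truth, molecule_len = 250000, sigma = 0,
                              fn_rate = 0, fp_rate = 0, motif = "GCTCTTC") {
  set.seed(truth$seed + 4000003)
  maps <- list()
  origin <- data.frame()
  for (chrom in names(truth$genome)) {
    len <- nchar(truth$genome[[chrom]])
    starts <- unique(c(seq(0, max(0, len - molecule_len),
                           by = floor(molecule_len / 2)),
                       max(0, len - molecule_len)))
    for (s in starts) {
      e <- min(len, s + molecule_len)
      id <- sprintf("mol_%s_%07d", chrom, s)
      dg <- digest(substr(truth$genome[[chrom]], s + 1, e), motif, id = id)
      sites <- dg$sites
      if (sigma > 0) sites <- sites + round(rnorm(length(sites), 0, sigma))
      if (fn_rate > 0 && length(sites) > 0) {
        n_drop <- round(fn_rate * length(sites))
        if (n_drop > 0) sites <- sites[-sample.int(length(sites), n_drop)]
      }
      if (fp_rate > 0) {
        n_add <- round(fp_rate * length(dg$sites))
        if (n_add > 0) sites <- c(sites, sample.int(e - s, n_add) - 1)
      }
      sites <- sort(unique(pmax(0, pmin(e - s - 1, sites))))
      maps[[id]] <- nickmap(id, e - s, sites)
      origin <- rbind(origin, data.frame(id = id, chrom = chrom, start = s,
                                         stringsAsFactors = FALSE))
    }
  }
  attr(maps, "truth") <- origin
  maps
}

# genome placement of any assembled contig id (original or derived piece)
truth_interval <- function(id, truth, contigs) {
  lay <- truth$layout
  rows <- lay[lay$contig_id == id, , drop = FALSE]
  if (nrow(rows) == 1) return(rows)
  if (nrow(rows) > 1) return(NULL)  # chimera parent itself: no single place
  # derived piece: map through the parent part table
  i <- match(id, contigs$id)
  if (is.na(i) || is.na(contigs$parent_id[i])) return(NULL)
  parent <- contigs$parent_id[i]
  ps <- contigs$parent_start[i]; pe <- contigs$parent_end[i]
  parts <- lay[lay$contig_id == parent, , drop = FALSE]
  parts <- parts[order(parts$part), , drop = FALSE]
  if (nrow(parts) == 0) return(NULL)
  off <- 0
  best <- NULL; best_ov <- 0
  for (r in seq_len(nrow(parts))) {
    plen <- parts$end[r] - parts$start[r]
    ov <- min(pe, off + plen) - max(ps, off)
    if (ov > best_ov) {
      best_ov <- ov
      s_in <- max(ps, off) - off          # piece interval within the part
      e_in <- min(pe, off + plen) - off
      if (parts$orient[r] == "+") {
        gs <- parts$start[r] + s_in; ge <- parts$start[r] + e_in
        orient <- "+"
      } else {
        gs <- parts$end[r] - e_in; ge <- parts$end[r] - s_in
        orient <- "-"
      }
      best <- data.frame(contig_id = id, part = parts$part[r],
                         chrom = parts$chrom[r], start = gs, end = ge,
                         orient = orient, is_chimera = FALSE,
                         stringsAsFactors = FALSE)
    }
    off <- off + plen
  }
  best
}

#' Evaluate an assembly against the simulation truth
#'
#' @param result Result of [run_pipeline()].
#' @param truth `fb_simtruth` used to generate the inputs.
#' @param pseudo Optional result of [build_pseudomolecules()] (computed
#'   here when absent) for base-identity scoring.
#' @return A list of metrics: `order_accuracy`, `orientation_accuracy`,
#'   `junction_precision`, `junction_recall`, `base_identity`,
#'   `chimera_recall`, `n_supercontigs`.
#' @export
evaluate <- function(result, truth, pseudo = NULL) {
  # true segment ordering per chromosome (chimera parts at their locations)
  segs <- truth$layout
  segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
  seg_key <- paste(segs$contig_id, segs$part)
  true_pairs <- character(0)
  for (chrom in unique(segs$chrom)) {
    k <- seg_key[segs$chrom == chrom]
    if (length(k) > 1)
      true_pairs <- c(true_pairs, paste(pmin(k[-length(k)], k[-1]),
                                        pmax(k[-length(k)], k[-1]), sep = "|"))
  }
  # predicted pairs + orientations via truth placement
  pred_pairs <- character(0)
  orient_ok <- logical(0)
  for (sc in result$supercontigs) {
    placed <- lapply(sc$segments$contig_id, truth_interval, truth = truth,
                     contigs = result$contigs)
    keys <- vapply(placed, function(p)
      if (is.null(p)) NA_character_ else paste(p$contig_id, p$part),
      character(1))
    # remap derived pieces onto the truth segment they occupy
    for (i in seq_along(placed)) {
      if (is.null(placed[[i]])) next
      hit <- which(segs$chrom == placed[[i]]$chrom &
                   pmin(segs$end, placed[[i]]$end) -
                     pmax(segs$start, placed[[i]]$start) >
                     0.5 * (placed[[i]]$end - placed[[i]]$start))
      if (length(hit) > 0) keys[i] <- seg_key[hit[1]]
    }
    if (length(keys) > 1) {
      ok <- !is.na(keys[-length(keys)]) & !is.na(keys[-1])
      pred_pairs <- c(pred_pairs,
                      paste(pmin(keys[-length(keys)], keys[-1]),
                            pmax(keys[-length(keys)], keys[-1]),
                            sep = "|")[ok])
    }
    for (i in seq_along(placed)) {
      if (is.null(placed[[i]])) next
      truth_orient <- placed[[i]]$orient
      orient_ok <- c(orient_ok, sc$segments$orient[i] == truth_orient)
    }
  }
  order_acc <- if (length(true_pairs) > 0)
    mean(true_pairs %in% pred_pairs) else 1
  precision <- if (length(pred_pairs) > 0)
    mean(pred_pairs %in% true_pairs) else 1
  orient_acc <- if (length(orient_ok) > 0) mean(orient_ok) else 1
  # base identity of pseudomolecules vs truth chromosomes
  if (is.null(pseudo)) pseudo <- build_pseudomolecules(result$supercontigs)
  base_id <- NA_real_
  if (length(pseudo$sequences) > 0) {
    tot <- 0; match_b <- 0
    for (lg in names(pseudo$sequences)) {
      ref <- truth$genome[[lg]]
      if (is.null(ref)) next
      tot <- tot + nchar(ref)
      if (identical(pseudo$sequences[[lg]], ref)) {
        match_b <- match_b + nchar(ref)
      } else if (nchar(pseudo$sequences[[lg]]) == nchar(ref)) {
        match_b <- match_b +
          sum(charToRaw(pseudo$sequences[[lg]]) == charToRaw(ref))
      } else {
        aln <- find_overlaps(setNames(pseudo$sequences[[lg]], "asm"),
                             setNames(ref, "ref"), min_len = 5000,
                             min_identity = 0.8, skip_same_id = FALSE)
        if (nrow(aln) > 0) {
          iv <- IRanges::reduce(IRanges::IRanges(aln$t_start + 1, aln$t_end))
          cov <- sum(IRanges::width(iv))
          match_b <- match_b + min(cov, nchar(ref)) *
            (sum(aln$matches) / sum(aln$aln_len))
        }
      }
    }
    base_id <- if (tot > 0) match_b / tot else NA_real_
  }
  chim_recall <- if (nrow(truth$chimeras) > 0) {
    found <- vapply(seq_len(nrow(truth$chimeras)), function(i)
      any(result$chimera_calls$contig_id == truth$chimeras$contig_id[i] &
          abs(result$chimera_calls$breakpoint -
              truth$chimeras$breakpoint[i]) <= 2000), logical(1))
    mean(found)
  } else NA_real_
  list(order_accuracy = order_acc, orientation_accuracy = orient_acc,
       junction_precision = precision, junction_recall = order_acc,
       base_identity = base_id, chimera_recall = chim_recall,
       n_supercontigs = length(result$supercontigs))
}
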