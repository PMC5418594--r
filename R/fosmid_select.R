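#' Select long reads for a fosmid pool
#'
#' Implements the pool-wise read selection rule used to localize assembly:
#' sequence tags below 97% alignment identity are discarded; a tag counts
#' toward a read's coverage only when aligned in full length, or more than
#' half-aligned when it hangs off a read end. Reads are ranked by
#' coverage x mean tag identity (coverage = fraction of read bases covered
#' by qualifying tags) and admitted in rank order until the cumulative
#' selected bases reach `cap` times the pool insert size; the boundary read
#' is admitted.
#'
#' @param tag_alignments `data.frame` with columns `read_id`, `tag_id`,
#'   `identity`, `aligned_frac` (fraction of the tag aligned), `at_end`
#'   (logical: does the tag hang off a read end), `r_start`, `r_end`
#'   (0-based half-open aligned interval on the read).
#' @param reads `data.frame` with `read_id`, `length`.
#' @param pool_insert_size Mean insert size of the pool in bases.
#' @param cap Coverage multiple defining the capacity (default 20).
#' @param min_tag_identity Tag identity floor.
#' @return A list: `selected` (`data.frame` of admitted reads with
#'   `coverage`, `mean_identity`, `rank_key`, `cum_bases`), `capacity`.
#' @export
select_pool_reads <- function(tag_alignments, reads, pool_insert_size,
                              cap = 20, min_tag_identity = 0.97) {
  if (pool_insert_size <= 0) stop("pool insert size must be positive")
  ta <- tag_alignments
  ta <- ta[ta$identity >= min_tag_identity, , drop = FALSE]
  qualifies <- ta$aligned_frac >= 1 | (ta$at_end & ta$aligned_frac > 0.5)
  ta <- ta[qualifies, , drop = FALSE]
  stats <- data.frame(read_id = reads$read_id, length = reads$length,
                      coverage = 0, mean_identity = 0,
                      stringsAsFactors = FALSE)
  if (nrow(ta) > 0) {
    for (g in split(seq_len(nrow(ta)), ta$read_id)) {
      i <- match(ta$read_id[g[1]], stats$read_id)
      if (is.na(i)) next
      iv <- IRanges::reduce(IRanges::IRanges(ta$r_start[g] + 1, ta$r_end[g]))
      stats$coverage[i] <- min(1, sum(IRanges::width(iv)) / stats$length[i])
      stats$mean_identity[i] <- mean(ta$identity[g])
    }
  }
  stats$rank_key <- stats$coverage * stats$mean_identity
  stats <- stats[order(-stats$rank_key, stats$read_id), , drop = FALSE]
  capacity <- cap * pool_insert_size
  cum <- cumsum(stats$length)
  n_admit <- if (length(cum) == 0) 0 else max(0, sum(cum - stats$length < capacity))
  sel <- stats[seq_len(n_admit), , drop = FALSE]
  sel <- sel[sel$rank_key > 0, , drop = FALSE]
  sel$cum_bases <- cumsum(sel$length)
  rownames(sel) <- NULL
  list(selected = sel, capacity = capacity)
}
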