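#' Pipeline parameters
#'
#' Collects every tunable threshold of the scaffolding and validation
#' pipeline in one validated list. Defaults follow the published
#' fosmid-bridged assembly procedure: overlaps qualify as graph
#' connections at identity above 99% (relaxed to 98% and then 97% in
#' later merge rounds), matched length above 5 kb and overhang below
#' 1 kb; chimeric joins are recognized by the mirror-image signature
#' (long high-identity overlap landing in the middle of a contig with a
#' large overhang); cleaved chimera pieces are reused only above 30 kb;
#' fosmid contigs below 10 kb are discarded; pseudomolecule gaps are
#' 10 kb of N.
#'
#' @param identity_thresholds Strictly decreasing identity fractions for the
#'   successive merge rounds.
#' @param min_matched_len Minimum aligned length (bases) on the WGS contig for
#'   a qualifying overlap.
#' @param max_overhang Maximum unaligned WGS sequence (bases) between the
#'   aligned block and the nearer contig end.
#' @param chimera_min_overlap,chimera_min_identity,chimera_min_overhang
#'   Thresholds for the chimeric-contig signature: overlap length > 5 kb,
#'   identity > 98%, overhang > 1 kb.
#' @param min_reuse_len Minimum length (bases) of a cleaved chimera piece that
#'   re-enters the graph as a new node.
#' @param min_fosmid_len Fosmid contigs shorter than this are discarded.
#' @param gap_n Number of N characters inserted between super-contigs on the
#'   same chromosome.
#' @param pv_min_block,pv_min_gap,pv_min_len,pv_max_coverage,pv_share_frac
#'   Presence-variation calling thresholds: minimum collinear block (200 bp),
#'   minimum unaligned gap (100 bp), minimum reported PV (500 bp), maximum
#'   short-read coverage fraction (25%) and reciprocal sharing fraction (75%).
#' @param indel_min,indel_hi Size classes for map-vs-assembly indel calls:
#'   mid class is `[indel_min, indel_hi)`, large class `>= indel_hi`.
#' @param flank_min_len Minimum flanking-contig length (bases) for
#'   alternative-path correction around an indel.
#' @param sigma Sizing error s.d. (bases) of nick-map intervals.
#' @param max_skip Maximum sites skippable on each map between matched pairs.
#' @param match_tolerance Residual tolerance (bases) when matching a candidate
#'   replacement path to the reference map.
#'
#' @return An object of class `fb_params` (a validated named list).
#' @export
#' @examples
#' p <- fb_params()
#' p$min_matched_len
fb_params <- function(identity_thresholds = c(0.99, 0.98, 0.97),
                      min_matched_len = 5000,
                      max_overhang = 1000,
                      chimera_min_overlap = 5000,
                      chimera_min_identity = 0.98,
                      chimera_min_overhang = 1000,
                      min_reuse_len = 30000,
                      min_fosmid_len = 10000,
                      gap_n = 10000,
                      pv_min_block = 200,
                      pv_min_gap = 100,
                      pv_min_len = 500,
                      pv_max_coverage = 0.25,
                      pv_share_frac = 0.75,
                      indel_min = 1000,
                      indel_hi = 10000,
                      flank_min_len = 100000,
                      sigma = 500,
                      max_skip = 2,
                      match_tolerance = 1000) {
  p <- list(identity_thresholds = as.numeric(identity_thresholds),
            min_matched_len = min_matched_len, max_overhang = max_overhang,
            chimera_min_overlap = chimera_min_overlap,
            chimera_min_identity = chimera_min_identity,
            chimera_min_overhang = chimera_min_overhang,
            min_reuse_len = min_reuse_len, min_fosmid_len = min_fosmid_len,
            gap_n = gap_n, pv_min_block = pv_min_block, pv_min_gap = pv_min_gap,
            pv_min_len = pv_min_len, pv_max_coverage = pv_max_coverage,
            pv_share_frac = pv_share_frac, indel_min = indel_min,
            indel_hi = indel_hi, flank_min_len = flank_min_len,
            sigma = sigma, max_skip = max_skip,
            match_tolerance = match_tolerance)
  if (length(p$identity_thresholds) < 1 ||
      is.unsorted(rev(p$identity_thresholds), strictly = TRUE))
    stop("identity_thresholds must be strictly decreasing")
  if (any(p$identity_thresholds <= 0 | p$identity_thresholds > 1))
    stop("identity_thresholds must be fractions in (0, 1]")
  lens <- c(p$min_matched_len, p$max_overhang, p$chimera_min_overlap,
            p$chimera_min_overhang, p$min_reuse_len, p$min_fosmid_len,
            p$gap_n, p$pv_min_block, p$pv_min_gap, p$pv_min_len,
            p$indel_min, p$indel_hi, p$flank_min_len, p$sigma,
            p$match_tolerance)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all length parameters must be positive")
  if (p$indel_hi <= p$indel_min) stop("indel_hi must exceed indel_min")
  class(p) <- c("fb_params", "list")
  p
}

#' @export
print.fb_params <- function(x, ...) {
  cat("fosbridge parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
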