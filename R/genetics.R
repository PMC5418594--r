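#' Filter SNP markers for map construction
#'
#' Keeps markers at which the two parents are homozygous and different, and
#' at which neither parental genotype is extremely rare in the population:
#' among non-missing calls, each parental homozygote class must reach
#' `min_parent_frac`.
#'
#' @param geno Character matrix of genotypes, markers in rows, individuals in
#'   columns; values `"A"` (parent-1 homozygote), `"B"` (parent-2
#'   homozygote), `"H"` (heterozygote) or `NA`.
#' @param parent1,parent2 Genotype call of each parent per marker (`"A"`,
#'   `"B"`, `"H"` or `NA`).
#' @param min_parent_frac Minimum frequency of each parental class.
#' @return Logical vector of retained markers.
#' @export
filter_markers <- function(geno, parent1, parent2, min_parent_frac = 0.05) {
  if (ncol(geno) == 0) stop("genotype matrix has zero individuals")
  stopifnot(length(parent1) == nrow(geno), length(parent2) == nrow(geno))
  homo_diff <- !is.na(parent1) & !is.na(parent2) &
    parent1 %in% c("A", "B") & parent2 %in% c("A", "B") & parent1 != parent2
  n_ok <- rowSums(!is.na(geno))
  fA <- rowSums(geno == "A", na.rm = TRUE) / pmax(n_ok, 1)
  fB <- rowSums(geno == "B", na.rm = TRUE) / pmax(n_ok, 1)
  homo_diff & n_ok > 0 & fA >= min_parent_frac & fB >= min_parent_frac
}

#' Sliding-window bin genotyping
#'
#' Slides a window of `window` markers (stride `step`) along each
#' individual's genotype vector; each window is called by strict majority of
#' its non-missing genotypes (ties, or windows more than half missing, give
#' `"unknown"` and are merged into the flanking bin with more support).
#' Bins are maximal runs of one call; each breakpoint is placed at the
#' midpoint between the last marker of one bin's final window and the first
#' marker of the next bin's first window.
#'
#' @param geno Character matrix, markers x individuals (one contig's markers
#'   in map order).
#' @param window Window size in markers.
#' @param step Window stride (1 = sliding; `window` = disjoint).
#' @return A list per individual, each a `data.frame` of bins with
#'   `start_marker`, `end_marker` (1-based inclusive marker indices),
#'   `genotype`, and `breakpoint` (marker-scale coordinate of the boundary
#'   preceding the bin; `NA` for the first bin).
#' @export
call_bins <- function(geno, window = 50, step = 1) {
  if (ncol(geno) == 0) stop("genotype matrix has zero individuals")
  n <- nrow(geno)
  lapply(setNames(seq_len(ncol(geno)), colnames(geno)), function(ind) {
    x <- geno[, ind]
    if (n < window) {
      maj <- majority_call(x)
      return(data.frame(start_marker = 1, end_marker = n,
                        genotype = maj, breakpoint = NA_real_,
                        stringsAsFactors = FALSE))
    }
    starts <- seq(1, n - window + 1, by = step)
    calls <- vapply(starts, function(s)
      majority_call(x[s:(s + window - 1)]), character(1))
    # merge unknown windows into the flanking call with more support
    known <- which(calls != "unknown")
    if (length(known) == 0) {
      return(data.frame(start_marker = 1, end_marker = n,
                        genotype = "unknown", breakpoint = NA_real_,
                        stringsAsFactors = FALSE))
    }
    for (i in which(calls == "unknown")) {
      lft <- known[known < i]; rgt <- known[known > i]
      if (length(lft) == 0) calls[i] <- calls[rgt[1]]
      else if (length(rgt) == 0) calls[i] <- calls[lft[length(lft)]]
      else {
        # side with more identically-called neighbouring windows wins
        lrun <- sum(calls[lft] == calls[lft[length(lft)]])
        rrun <- sum(calls[rgt] == calls[rgt[1]])
        calls[i] <- if (lrun >= rrun) calls[lft[length(lft)]] else calls[rgt[1]]
      }
    }
    r <- rle(calls)
    ends_w <- cumsum(r$lengths)        # window indices
    starts_w <- c(1, ends_w[-length(ends_w)] + 1)
    bins <- data.frame(start_marker = numeric(0), end_marker = numeric(0),
                       genotype = character(0), breakpoint = numeric(0),
                       stringsAsFactors = FALSE)
    for (b in seq_along(r$values)) {
      # marker span: first marker of first window .. last marker of last window
      sm <- if (b == 1) 1 else bins$end_marker[b - 1] + 1
      em <- if (b == length(r$values)) n
            else floor((starts[ends_w[b]] + window - 1 +
                        starts[starts_w[b + 1]]) / 2)
      bp <- if (b == 1) NA_real_
            else (starts[ends_w[b - 1]] + window - 1 + starts[starts_w[b]]) / 2
      bins <- rbind(bins, data.frame(start_marker = sm, end_marker = em,
                                     genotype = r$values[b], breakpoint = bp,
                                     stringsAsFactors = FALSE))
    }
    bins
  })
}

majority_call <- function(x) {
  ok <- x[!is.na(x)]
  if (length(ok) <= length(x) / 2) return("unknown")
  tab <- sort(table(ok), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return("unknown")
  names(tab)[1]
}

#' Read a genotype TSV (markers x individuals)
#'
#' Expects columns `contig`, `pos`, then one column per individual; missing
#' calls as `NA` or `-`.
#' @param path Path to the TSV.
#' @return A list: `markers` (`data.frame` of `contig`, `pos`) and `geno`
#'   (character matrix).
#' @export
read_genotypes <- function(path) {
  tb <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", "-"))
  stopifnot(all(c("contig", "pos") %in% names(tb)))
  for (ctg in unique(tb$contig)) {
    p <- tb$pos[tb$contig == ctg]
    if (is.unsorted(p, strictly = TRUE))
      stop("marker positions not strictly increasing on ", ctg)
  }
  geno <- as.matrix(tb[, setdiff(names(tb), c("contig", "pos")), drop = FALSE])
  list(markers = tb[c("contig", "pos")], geno = geno)
}

#' Write bin genotypes as TSV
#' @param bins Result of [call_bins()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bins <- function(bins, path) {
  rows <- do.call(rbind, lapply(names(bins), function(ind)
    cbind(individual = ind, bins[[ind]])))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
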