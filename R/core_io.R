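#' @useDynLib fosbridge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom utils read.table write.table
#' @importFrom methods is
#' @importFrom stats rbinom runif rnorm setNames
NULL

#' Construct a contig set
#'
#' A contig set is a plain `data.frame` with one row per contig and columns
#' `id`, `sequence`, `length`, `source` (one of `"wgs"`, `"fosmid"`,
#' `"derived-split"`) and `parent_id` (NA except for pieces cleaved from a
#' split chimera, which also carry `parent_start`/`parent_end`, the 0-based
#' half-open interval on the parent).
#'
#' @param id Character vector of unique contig ids.
#' @param sequence Character vector of nucleotide sequences (ACGTN).
#' @param source Contig provenance, recycled.
#' @param parent_id,parent_start,parent_end Parent bookkeeping for
#'   derived-split contigs.
#' @return A `data.frame` contig set.
#' @export
contig_set <- function(id, sequence, source = "wgs", parent_id = NA_character_,
                       parent_start = NA_real_, parent_end = NA_real_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(id))
    stop("duplicate contig id: ", id[duplicated(id)][1])
  if (any(!nzchar(sequence)))
    stop("empty sequence for contig: ", id[!nzchar(sequence)][1])
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("non-ACGTN characters in contig: ", id[bad][1])
  src <- rep_len(as.character(source), length(id))
  stopifnot(all(src %in% c("wgs", "fosmid", "derived-split")))
  data.frame(id = id, sequence = sequence, length = nchar(sequence),
             source = src,
             parent_id = rep_len(as.character(parent_id), length(id)),
             parent_start = rep_len(as.numeric(parent_start), length(id)),
             parent_end = rep_len(as.numeric(parent_end), length(id)),
             stringsAsFactors = FALSE)
}

#' Read contigs from a FASTA file
#'
#' Ids are taken from the header up to the first whitespace. Sequences are
#' uppercased and validated over the ACGTN alphabet.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param source Provenance recorded for every contig.
#' @return A contig set ([contig_set()]).
#' @export
parse_fasta <- function(path, source = "wgs") {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  contig_set(ids, as.character(ss), source = source)
}

#' Write contigs to a FASTA file
#'
#' @param contigs A contig set or named character vector of sequences.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 80L) {
  seqs <- as_seq_vector(contigs)
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# named character vector of sequences from contig set / DNAStringSet / vector
as_seq_vector <- function(x) {
  if (is.data.frame(x)) return(setNames(x$sequence, x$id))
  if (methods::is(x, "DNAStringSet")) return(setNames(as.character(x), names(x)))
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    return(x)
  }
  stop("cannot interpret object as sequences")
}

#' Reverse complement
#' @param s Character vector of ACGTN sequences.
#' @return Reverse-complemented character vector.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Parse a PAF alignment file
#'
#' Reads the 12 mandatory PAF columns into alignment records with 0-based
#' half-open coordinates. Identity is computed as `matches / aln_len`
#' (BLAST-like identity over the alignment block).
#'
#' @param path Path to a tab-separated PAF file (no header).
#' @return A `data.frame` of alignment records with columns `query_id`,
#'   `target_id`, `strand`, `q_start`, `q_end`, `q_len`, `t_start`, `t_end`,
#'   `t_len`, `matches`, `aln_len`, `identity`.
#' @export
parse_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    fill = FALSE, comment.char = "")
  if (ncol(raw) < 12) stop("PAF requires >= 12 columns, got ", ncol(raw))
  aln <- data.frame(query_id = as.character(raw[[1]]),
                    q_len = as.numeric(raw[[2]]),
                    q_start = as.numeric(raw[[3]]),
                    q_end = as.numeric(raw[[4]]),
                    strand = as.character(raw[[5]]),
                    target_id = as.character(raw[[6]]),
                    t_len = as.numeric(raw[[7]]),
                    t_start = as.numeric(raw[[8]]),
                    t_end = as.numeric(raw[[9]]),
                    matches = as.numeric(raw[[10]]),
                    aln_len = as.numeric(raw[[11]]),
                    stringsAsFactors = FALSE)
  validate_alignments(aln)
}

validate_alignments <- function(aln) {
  cols <- c("query_id", "target_id", "strand", "q_start", "q_end", "q_len",
            "t_start", "t_end", "t_len", "matches", "aln_len")
  stopifnot(all(cols %in% names(aln)))
  with(aln, {
    if (any(q_end <= q_start | t_end <= t_start))
      stop("malformed alignment record: end <= start")
    if (any(q_start < 0 | q_end > q_len | t_start < 0 | t_end > t_len))
      stop("alignment coordinates outside sequence bounds")
    if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(aln_len < pmax(q_end - q_start, 0)))
      stop("aln_len shorter than query span")
    if (any(matches > aln_len)) stop("matches exceed aln_len (identity > 1)")
  })
  aln$identity <- aln$matches / aln$aln_len
  aln[cols %union_c% "identity"]
}

`%union_c%` <- function(a, b) unique(c(a, b))

#' Write alignment records as PAF
#' @param aln Alignment records as returned by [parse_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  out <- aln[c("query_id", "q_len", "q_start", "q_end", "strand",
               "target_id", "t_len", "t_start", "t_end", "matches", "aln_len")]
  out$mapq <- 60L
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genetic-map anchor table
#'
#' Expects a TSV with header `contig lg order cm orient`; `orient` is `+`,
#' `-` or `?` (unknown). Within each linkage group the order index must be
#' unique and the centimorgan position non-decreasing with order.
#'
#' @param path Path to the anchor TSV.
#' @return A `data.frame` with columns `contig_id`, `lg_id`, `order_index`,
#'   `cm_position`, `orientation`.
#' @export
read_anchors <- function(path) {
  tb <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "lg", "order", "cm", "orient") %in% names(tb)))
  anchors <- data.frame(contig_id = as.character(tb$contig),
                        lg_id = as.character(tb$lg),
                        order_index = as.integer(tb$order),
                        cm_position = as.numeric(tb$cm),
                        orientation = as.character(tb$orient),
                        stringsAsFactors = FALSE)
  validate_anchors(anchors)
}

validate_anchors <- function(anchors) {
  stopifnot(all(anchors$orientation %in% c("+", "-", "?")))
  if (anyDuplicated(anchors$contig_id))
    stop("contig anchored more than once: ",
         anchors$contig_id[duplicated(anchors$contig_id)][1])
  for (lg in unique(anchors$lg_id)) {
    a <- anchors[anchors$lg_id == lg, ]
    if (anyDuplicated(a$order_index))
      stop("duplicate order_index within LG ", lg)
    a <- a[order(a$order_index), ]
    if (is.unsorted(a$cm_position))
      stop("cm_position not non-decreasing with order in LG ", lg)
  }
  anchors
}

#' Write an anchor table
#' @param anchors Anchor records as returned by [read_anchors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchors <- function(anchors, path) {
  out <- data.frame(contig = anchors$contig_id, lg = anchors$lg_id,
                    order = anchors$order_index, cm = anchors$cm_position,
                    orient = anchors$orientation)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write super-contig placements as AGP v2.1
#'
#' Emits one `W` line per contig segment (1-based inclusive object
#' coordinates, component orientation from the segment sign) and one `U`
#' gap line of `gap_n` bases between consecutive super-contigs placed on
#' the same chromosome.
#'
#' @param supercontigs List of super-contigs ([run_pipeline()]).
#' @param path Output path (or `""` to return the text).
#' @param gap_n Gap length between super-contigs on one chromosome.
#' @param object_by `"lg"` builds one AGP object per linkage group
#'   (pseudomolecule layout); `"supercontig"` one object per super-contig.
#' @return The AGP text, invisibly (or visibly when `path == ""`).
#' @export
write_agp <- function(supercontigs, path = "", gap_n = 10000,
                      object_by = c("lg", "supercontig")) {
  object_by <- match.arg(object_by)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- c("##agp-version 2.1")
  groups <- if (object_by == "lg") {
    lgs <- vapply(supercontigs, function(s) s$lg %||% NA_character_, character(1))
    split(supercontigs, ifelse(is.na(lgs), paste0("unplaced_", seq_along(lgs)), lgs))
  } else {
    setNames(lapply(supercontigs, list),
             vapply(supercontigs, function(s) s$id, character(1)))
  }
  for (obj in names(groups)) {
    pos <- 0
    part <- 0
    for (si in seq_along(groups[[obj]])) {
      sc <- groups[[obj]][[si]]
      if (si > 1) {
        part <- part + 1
        lines <- c(lines, paste(obj, fmt(pos + 1), fmt(pos + gap_n), part,
                                "U", fmt(gap_n), "contig", "no", "align_genus",
                                sep = "\t"))
        pos <- pos + gap_n
      }
      seg <- sc$segments
      if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)]))
        stop("overlapping object coordinates in super-contig ", sc$id)
      for (k in seq_len(nrow(seg))) {
        part <- part + 1
        lines <- c(lines, paste(obj, fmt(pos + seg$start[k] + 1),
                                fmt(pos + seg$end[k]), part, "W",
                                seg$contig_id[k], 1,
                                fmt(seg$end[k] - seg$start[k]), seg$orient[k],
                                sep = "\t"))
      }
      pos <- pos + nchar(sc$sequence)
    }
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (nzchar(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
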