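#' Construct a CpG site index
#'
#' A `cpg_index` is an ordered table of CpG site coordinates, optionally
#' partitioned into regions of mutually reachable sites (see
#' [segment_regions()]). Coordinates are 0-based positions of the C of each
#' CG dinucleotide on the forward strand; CpG sites are strand-symmetric, so
#' reads from either strand are counted against this position.
#'
#' @param chrom character vector of chromosome names (recycled to length of
#'   `pos`).
#' @param pos integer vector of 0-based C positions, strictly increasing
#'   within each chromosome.
#' @param region_id optional integer region labels (assigned by
#'   [segment_regions()]); `NA` when not yet segmented.
#' @return An object of class `cpg_index`: a `data.frame` with columns
#'   `chrom`, `pos`, `region_id`.
#' @export
cpg_index <- function(chrom, pos, region_id = NA_integer_) {
  pos <- as.integer(pos)
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  region_id <- rep_len(as.integer(region_id), n)
  idx <- data.frame(chrom = chrom, pos = pos, region_id = region_id,
                    stringsAsFactors = FALSE)
  # keep chromosomes in first-appearance order, positions sorted within
  idx <- idx[order(match(idx$chrom, unique(idx$chrom)), idx$pos), ,
             drop = FALSE]
  rownames(idx) <- NULL
  for (cc in unique(idx$chrom)) {
    p <- idx$pos[idx$chrom == cc]
    if (anyDuplicated(p) || is.unsorted(p, strictly = TRUE))
      stop("CpG positions must be strictly increasing within chromosome ", cc)
  }
  class(idx) <- c("cpg_index", "data.frame")
  idx
}

#' @export
print.cpg_index <- function(x, ...) {
  nreg <- if (all(is.na(x$region_id))) "unsegmented" else
    paste(length(unique(x$region_id)), "regions")
  cat(sprintf("<cpg_index> %d CpG sites on %d chromosome(s), %s\n",
              nrow(x), length(unique(x$chrom)), nreg))
  invisible(x)
}

#' Locate CpG sites in a reference sequence
#'
#' Scans each chromosome for CG dinucleotides on the forward strand and
#' records the position of the C. Matching is case-insensitive; `N` (or any
#' non-ACGT character) never matches, so unresolved reference stretches yield
#' no sites. Sites whose dinucleotide overlaps a blacklist interval are
#' removed.
#'
#' @param sequences a named character vector of chromosome sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param blacklist optional blacklist regions: a `data.frame` with columns
#'   `chrom`, `start`, `end` (0-based half-open) or a path to a BED3 file.
#' @return A [cpg_index()] with `region_id = NA` (call [segment_regions()]
#'   next).
#' @examples
#' find_cpg_sites(c(chr1 = "ACGTCG"))  # sites at 1 and 4
#' @export
find_cpg_sites <- function(sequences, blacklist = NULL) {
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  if (methods::is(sequences, "DNAStringSet")) {
    seqs <- as.character(sequences)
  } else {
    seqs <- vapply(sequences, as.character, character(1))
  }
  if (is.null(names(seqs)))
    stop("sequences must be named by chromosome")
  chroms <- character(0); poss <- integer(0)
  for (cc in names(seqs)) {
    s <- toupper(seqs[[cc]])
    if (!nzchar(s)) next
    hit <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (hit[1] == -1L) next
    p <- as.integer(hit) - 1L  # 0-based position of the C
    chroms <- c(chroms, rep(cc, length(p)))
    poss <- c(poss, p)
  }
  idx <- cpg_index(chroms, poss)
  if (!is.null(blacklist) && nrow(idx) > 0L) {
    bl <- if (is.character(blacklist)) read_bed(blacklist) else blacklist
    keep <- rep(TRUE, nrow(idx))
    for (cc in unique(bl$chrom)) {
      sel <- idx$chrom == cc
      if (!any(sel)) next
      b <- bl[bl$chrom == cc, , drop = FALSE]
      p <- idx$pos[sel]
      hit <- rep(FALSE, length(p))
      for (k in seq_len(nrow(b)))  # dinucleotide [pos, pos+2) vs [start, end)
        hit <- hit | (p < b$end[k] & p + 2L > b$start[k])
      keep[sel] <- !hit
    }
    idx <- idx[keep, , drop = FALSE]
    rownames(idx) <- NULL
    class(idx) <- c("cpg_index", "data.frame")
  }
  idx
}

#' Partition CpG sites into regions of mutually reachable sites
#'
#' Single-linkage chaining: two consecutive sites on the same chromosome
#' share a region iff their distance is at most `link_dist`. A read can only
#' cover several CpG sites when neighbouring sites are closer than the read
#' length, so sites further apart than the longest read are statistically
#' independent and are analysed as separate regions; an isolated site forms
#' a singleton region.
#'
#' @param index a [cpg_index()].
#' @param link_dist linking distance in bp (> 0); use the maximum read length.
#' @return The index with consecutive integer `region_id`s (0-based) assigned
#'   in genomic order.
#' @export
segment_regions <- function(index, link_dist) {
  stopifnot(inherits(index, "cpg_index"), link_dist > 0)
  if (nrow(index) == 0L) return(index)
  gap_break <- c(TRUE, diff(index$pos) > link_dist)
  chrom_break <- c(TRUE, index$chrom[-1L] != index$chrom[-nrow(index)])
  index$region_id <- cumsum(gap_break | chrom_break) - 1L
  attr(index, "link_dist") <- link_dist
  index
}

#' Read / write a CpG position table
#'
#' Plain TSV with columns `chrom`, `pos0` (and `region_id` when segmented).
#'
#' @param path file path.
#' @return `read_cpg_table()` returns a [cpg_index()].
#' @export
read_cpg_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  rid <- if ("region_id" %in% names(dt)) dt$region_id else NA_integer_
  cpg_index(dt$chrom, dt$pos0, rid)
}

#' @rdname read_cpg_table
#' @param index a [cpg_index()] to write.
#' @export
write_cpg_table <- function(index, path) {
  out <- data.frame(chrom = index$chrom, pos0 = index$pos,
                    region_id = index$region_id)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a BED file of mapped reads or blacklist intervals
#'
#' Accepts BED3 to BED6; coordinates stay 0-based half-open. Column names
#' follow the BED convention (`chrom`, `start`, `end`, `name`, `score`,
#' `strand`).
#'
#' @param path path to an uncompressed BED file.
#' @param sample optional sample label attached as a `sample` column.
#' @return A `data.frame` of intervals.
#' @export
read_bed <- function(path, sample = NULL) {
  dt <- if (file.size(path) == 0L) {
    data.frame()
  } else {
    data.table::fread(path, sep = "\t", header = FALSE,
                      data.table = FALSE, fill = TRUE)
  }
  if (nrow(dt) == 0L) {
    dt <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0))
  } else {
    cn <- c("chrom", "start", "end", "name", "score", "strand")
    names(dt)[seq_len(min(ncol(dt), 6L))] <- cn[seq_len(min(ncol(dt), 6L))]
    dt$start <- as.integer(dt$start); dt$end <- as.integer(dt$end)
    if (any(dt$start >= dt$end))
      stop("malformed BED interval (start >= end) in ", path, " at line ",
           which(dt$start >= dt$end)[1])
  }
  if (!is.null(sample)) dt$sample <- rep_len(sample, nrow(dt))
  dt
}

#' Read mapped reads from SAM/BAM as intervals
#'
#' Optional convenience for alignments not yet exported to BED. Mapped
#' records are converted to 0-based half-open intervals spanning the
#' aligned reference range (SAM's 1-based POS converted on read). Requires
#' the Rsamtools package; SAM text is converted to BAM in a temporary
#' directory first.
#'
#' @param path path to a SAM or BAM file.
#' @param sample optional sample label.
#' @return A `data.frame` of intervals as from [read_bed()].
#' @export
read_sam <- function(path, sample = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_sam() needs the Rsamtools package")
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  rec <- Rsamtools::scanBam(
    path, param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "qwidth", "cigar", "strand", "qname"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  width <- .cigar_ref_width(rec$cigar, rec$qwidth)
  dt <- data.frame(chrom = as.character(rec$rname),
                   start = rec$pos - 1L,
                   end = rec$pos - 1L + width,
                   name = rec$qname, score = 0L,
                   strand = as.character(rec$strand),
                   stringsAsFactors = FALSE)
  if (!is.null(sample)) dt$sample <- rep_len(sample, nrow(dt))
  dt
}

# reference-consuming width from CIGAR (M/D/N/=/X), falling back to the
# query width when the CIGAR is absent
.cigar_ref_width <- function(cigar, qwidth) {
  vapply(seq_along(cigar), function(i) {
    cg <- cigar[i]
    if (is.na(cg)) return(as.integer(qwidth[i]))
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}
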