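#' Construct a coverage matrix for one region
#'
#' The coverage matrix is the observation of the read-allocation model for a
#' single region of G CpG sites and n retained reads. Because a read covers a
#' set of *consecutive* CpG sites, each row is stored as its covered index
#' span `[k_i, l_i]` (1-based, into the region's sites); the dense binary
#' expansion has unknown (latent) entries for `k_i <= j <= l_i` and
#' structural zeros elsewhere.
#'
#' @param region_id integer region label.
#' @param chrom chromosome name.
#' @param positions the region's CpG site coordinates (0-based, increasing).
#' @param k,l integer vectors of per-read covered span endpoints, 1-based
#'   indices into `positions`, with `l >= k` (every retained read covers at
#'   least one site).
#' @return An object of class `coverage_matrix`.
#' @export
coverage_matrix <- function(region_id, chrom, positions, k, l) {
  k <- as.integer(k); l <- as.integer(l)
  stopifnot(length(k) == length(l))
  G <- length(positions)
  if (length(k) && (any(k < 1L) || any(l > G) || any(l < k)))
    stop("invalid covered spans: need 1 <= k_i <= l_i <= G")
  structure(list(region_id = as.integer(region_id),
                 chrom = as.character(chrom),
                 positions = as.integer(positions),
                 k = k, l = l, n = length(k), G = G),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("<coverage_matrix> region %d (%s): %d reads x %d CpG sites\n",
              x$region_id, x$chrom, x$n, x$G))
  invisible(x)
}

#' Dense 0/1 expansion of a coverage matrix
#'
#' Entry (i, j) is 1 iff read i covers site j; inside each covered span the
#' model treats the entries as latent, outside they are structural zeros.
#' Used by enumeration oracles and small examples.
#'
#' @param cm a [coverage_matrix()].
#' @return An `n x G` integer matrix.
#' @export
dense_coverage <- function(cm) {
  m <- matrix(0L, cm$n, cm$G)
  for (i in seq_len(cm$n)) m[i, cm$k[i]:cm$l[i]] <- 1L
  m
}

#' Build per-region coverage matrices from mapped reads
#'
#' A read covers CpG site j iff its interval overlaps the 2-bp dinucleotide
#' `[pos_j, pos_j + 2)` by at least `min_overlap` bp. Reads covering no CpG
#' site carry no information about methylation and are discarded (their count
#' is returned in the `discarded` attribute). Each retained read must fall in
#' a single region; a read whose covered sites straddle two regions indicates
#' that `link_dist` used in [segment_regions()] was smaller than the read
#' length, and is a hard error.
#'
#' @param reads `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @param index a segmented [cpg_index()].
#' @param min_overlap 1 (default: any overlap with the dinucleotide) or 2
#'   (require the full CG inside the read).
#' @return A list of [coverage_matrix()] objects (one per region with at
#'   least one read, in region order), with attributes `discarded` (number of
#'   reads covering no site) and `n_input`.
#' @export
build_coverage_matrix <- function(reads, index, min_overlap = 1L) {
  stopifnot(inherits(index, "cpg_index"))
  if (all(is.na(index$region_id)))
    stop("index is unsegmented; call segment_regions() first")
  min_overlap <- as.integer(min_overlap)
  stopifnot(min_overlap >= 1L, min_overlap <= 2L)
  n_input <- nrow(reads)
  rid_all <- integer(0); k_all <- integer(0); l_all <- integer(0)
  discarded <- 0L
  for (cc in unique(reads$chrom)) {
    rd <- reads[reads$chrom == cc, , drop = FALSE]
    sel <- index$chrom == cc
    if (!any(sel)) { discarded <- discarded + nrow(rd); next }
    pos <- index$pos[sel]
    rid <- index$region_id[sel]
    # covered iff pos >= start + min_overlap - 2 and pos <= end - min_overlap
    k <- findInterval(rd$start + min_overlap - 2L - 1L, pos) + 1L
    l <- findInterval(rd$end - min_overlap, pos)
    keep <- l >= k
    discarded <- discarded + sum(!keep)
    k <- k[keep]; l <- l[keep]
    if (!length(k)) next
    if (any(rid[k] != rid[l]))
      stop("read covers CpG sites in two different regions on ", cc,
           "; re-run segment_regions() with link_dist >= the read length")
    # convert to region-local 1-based indices
    first_idx <- match(rid, rid)  # index of first site of each region
    rid_all <- c(rid_all, rid[k])
    k_all <- c(k_all, k - first_idx[k] + 1L)
    l_all <- c(l_all, l - first_idx[k] + 1L)
  }
  out <- list()
  if (length(rid_all)) {
    for (r in sort(unique(rid_all))) {
      sel_r <- index$region_id == r & !is.na(index$region_id)
      rows <- rid_all == r
      out[[length(out) + 1L]] <- coverage_matrix(
        r, index$chrom[sel_r][1], index$pos[sel_r],
        k_all[rows], l_all[rows])
    }
  }
  attr(out, "discarded") <- discarded
  attr(out, "n_input") <- n_input
  out
}

#' Write / read a coverage dump
#'
#' One TSV with two kinds of rows: `region` rows carry the region's
#' chromosome and comma-joined site positions; `read` rows carry the covered
#' span `k`, `l` of each read. Round-trips exactly.
#'
#' @param cms a list of [coverage_matrix()] (from [build_coverage_matrix()]).
#' @param path file path.
#' @export
write_coverage_tsv <- function(cms, path) {
  rows <- list()
  for (cm in cms) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "region", region_id = cm$region_id, chrom = cm$chrom,
      a = paste(cm$positions, collapse = ","), b = "")
    if (cm$n)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "read", region_id = cm$region_id, chrom = cm$chrom,
        a = as.character(cm$k), b = as.character(cm$l))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), region_id = integer(0),
               chrom = character(0), a = character(0), b = character(0))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_coverage_tsv
#' @export
read_coverage_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE,
                          colClasses = list(character = c("a", "b")))
  out <- list()
  for (r in unique(df$region_id[df$type == "region"])) {
    reg <- df[df$type == "region" & df$region_id == r, , drop = FALSE]
    rd <- df[df$type == "read" & df$region_id == r, , drop = FALSE]
    out[[length(out) + 1L]] <- coverage_matrix(
      r, reg$chrom[1],
      as.integer(strsplit(reg$a[1], ",", fixed = TRUE)[[1]]),
      as.integer(rd$a), as.integer(rd$b))
  }
  out
}

#' Count MRE-seq reads per CpG site
#'
#' Methylation-sensitive restriction enzymes cut immediately 5' of the CG in
#' their recognition site (HpaII C^CGG, Hin6I G^CGC, AciI C^CGC), so an
#' MRE-seq read's 5' end sits on (or within a motif-dependent shift of) the
#' unmethylated CpG that produced it. Each read is assigned to the nearest
#' CpG site within `max_shift` bp of its 5' end (read `strand` honoured when
#' present: for minus-strand reads the 5' end is `end` and the candidate C is
#' at `end - 2`); reads anchoring no site are discarded and tallied.
#'
#' @param mre_reads `data.frame` of read intervals (see [read_bed()]).
#' @param index a [cpg_index()].
#' @param enzyme_motifs recognition motifs used to derive the maximum offset
#'   of the CG within a cut site (default HpaII, Hin6I, AciI).
#' @param max_shift override the motif-derived anchor tolerance in bp.
#' @return Integer vector of counts, one per site of `index`, with attribute
#'   `discarded`.
#' @export
mre_site_counts <- function(mre_reads, index,
                            enzyme_motifs = c("CCGG", "GCGC", "CCGC"),
                            max_shift = NULL) {
  if (is.null(max_shift)) {
    off <- vapply(enzyme_motifs,
                  function(m) as.integer(regexpr("CG", m, fixed = TRUE)) - 1L,
                  integer(1))
    if (any(off < 0L)) stop("enzyme motif without CG: ",
                            paste(enzyme_motifs[off < 0L], collapse = ", "))
    max_shift <- max(off)
  }
  counts <- integer(nrow(index))
  discarded <- 0L
  for (cc in unique(mre_reads$chrom)) {
    rd <- mre_reads[mre_reads$chrom == cc, , drop = FALSE]
    sel <- which(index$chrom == cc)
    if (!length(sel)) { discarded <- discarded + nrow(rd); next }
    pos <- index$pos[sel]
    anchor <- rd$start
    if ("strand" %in% names(rd)) {
      minus <- !is.na(rd$strand) & rd$strand == "-"
      anchor[minus] <- rd$end[minus] - 2L
    }
    # nearest site; ties (equidistant) resolve to the lower position
    j <- findInterval(anchor, pos)
    d_lo <- ifelse(j >= 1L, anchor - pos[pmax(j, 1L)], Inf)
    d_hi <- ifelse(j < length(pos), pos[pmin(j + 1L, length(pos))] - anchor,
                   Inf)
    pick <- ifelse(d_lo <= d_hi, j, j + 1L)
    dist <- pmin(d_lo, d_hi)
    ok <- is.finite(dist) & dist <= max_shift
    discarded <- discarded + sum(!ok)
    if (any(ok)) {
      tab <- tabulate(pick[ok], nbins = length(pos))
      counts[sel] <- counts[sel] + tab
    }
  }
  attr(counts, "discarded") <- discarded
  counts
}
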