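## Generative simulator of the MeDIP-seq / MRE-seq read process.
##
## The stated world: CpG sites with binary methylation states sit in regions
## of closely spaced sites; sonication breaks DNA into fragments of a few
## hundred bp at uniform random breakpoints; a fragment is
## immunoprecipitated only if a methylated CpG it covers binds antibody;
## sequenced reads are fragment 5' ends truncated to the read length. Two
## contributor laws mirror the allocation models:
##   "single"       — exactly one covered methylated site caused capture,
##                    drawn with the region's contribution probabilities P
##                    (reads then follow the multinomial law exactly);
##   "at_least_one" — every covered methylated site contributes
##                    independently with its q_j and the fragment is kept
##                    iff at least one contributes (truncated-Bernoulli law
##                    conditional on the covered span).

#' Simulation configuration
#'
#' Defaults describe a CpG-island-like landscape chosen for test power:
#' clusters of 5 sites at 30-100 bp gaps under 50 bp reads, so a read
#' covers one to three neighbouring sites and clusters whose internal gaps
#' exceed the read length split into smaller independent regions at
#' segmentation — the mixture of isolated sites and genuinely ambiguous
#' runs that makes the allocation problem non-trivial. Regions are fully
#' methylated unless `meth_prob` is lowered.
#'
#' @param n_regions number of independent regions.
#' @param sites_per_region CpG sites per region.
#' @param gap_range inter-site gap range in bp (uniform integer draw).
#' @param region_spacing bp between consecutive regions (must exceed
#'   `frag_len` so no fragment straddles regions).
#' @param chrom chromosome name for all simulated coordinates.
#' @param frag_len sonication fragment length in bp (fixed; a few hundred
#'   basepairs). Only the sequenced read interval covers CpG sites, so the
#'   fragment length plays no role in the allocation model itself.
#' @param read_len sequenced read length in bp (default 50, a typical
#'   Illumina MeDIP-seq read). Capture is attributed to a methylated CpG
#'   *within the read*: the read is what the antibody-bound site must sit
#'   on for the read to be part of the immunoprecipitated, sequenced
#'   library. Region coupling (and the default segmentation link distance)
#'   is therefore the read length.
#' @param reads_per_region expected MeDIP reads sequenced per region.
#' @param depth_model `"poisson"` (default): each region's read number is
#'   Poisson(`reads_per_region`), as for a library sampled genome-wide;
#'   `"fixed"`: exactly `reads_per_region` reads.
#' @param meth_prob probability a site is methylated.
#' @param meth_states optional fixed logical vector of length
#'   `sites_per_region` (recycled over regions), overriding the Bernoulli
#'   draw — useful for stating exact methylation layouts.
#' @param model contributor law, `"single"` or `"at_least_one"`.
#' @param p_true optional length-`sites_per_region` contribution
#'   probabilities shared by every region (renormalised over each region's
#'   methylated sites); default: symmetric Dirichlet draw per region.
#' @param q_range range of per-site contribution probabilities q_j for the
#'   at-least-one law.
#' @param mre_avail probability an unmethylated site has a compatible
#'   enzyme cut site.
#' @param mre_depth expected MRE reads per available unmethylated site
#'   (Poisson mean).
#' @param seed RNG seed (mandatory; all draws flow from one generator).
#' @return A `simulate_config` list.
#' @export
simulate_config <- function(n_regions = 20L, sites_per_region = 5L,
                            gap_range = c(30L, 100L),
                            region_spacing = 2000L, chrom = "chrSim",
                            frag_len = 200L, read_len = 50L,
                            reads_per_region = 100L,
                            depth_model = c("poisson", "fixed"),
                            meth_prob = 1, meth_states = NULL,
                            model = c("single", "at_least_one"),
                            p_true = NULL, q_range = c(0.2, 0.6),
                            mre_avail = 0.6, mre_depth = 5, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  model <- match.arg(model)
  depth_model <- match.arg(depth_model)
  stopifnot(n_regions >= 1, sites_per_region >= 1,
            all(gap_range > 0), region_spacing > frag_len,
            frag_len > 2, read_len > 2, reads_per_region >= 0,
            meth_prob >= 0, meth_prob <= 1,
            all(q_range > 0), all(q_range < 1))
  if (!is.null(p_true)) {
    stopifnot(length(p_true) == sites_per_region, all(p_true >= 0),
              abs(sum(p_true) - 1) < 1e-8)
  }
  structure(list(n_regions = as.integer(n_regions),
                 sites_per_region = as.integer(sites_per_region),
                 gap_range = as.integer(gap_range),
                 region_spacing = as.integer(region_spacing),
                 chrom = chrom, frag_len = as.integer(frag_len),
                 read_len = as.integer(read_len),
                 reads_per_region = as.integer(reads_per_region),
                 depth_model = depth_model,
                 meth_prob = meth_prob,
                 meth_states = if (!is.null(meth_states))
                   rep_len(as.logical(meth_states), sites_per_region),
                 model = model, p_true = p_true,
                 q_range = q_range, mre_avail = mre_avail,
                 mre_depth = mre_depth, seed = as.integer(seed)),
            class = "simulate_config")
}

# draw site positions, methylation states and per-region contribution
# parameters; assumes the RNG is already seeded by the caller
.draw_truth <- function(config) {
  G <- config$sites_per_region
  base <- max(1000L, config$frag_len + 10L)
  pos <- integer(0); region_id <- integer(0)
  for (r in seq_len(config$n_regions)) {
    gaps <- sample(config$gap_range[1]:config$gap_range[2], G - 1,
                   replace = TRUE)
    p0 <- c(base, base + cumsum(gaps))
    pos <- c(pos, p0)
    region_id <- c(region_id, rep(r - 1L, G))
    base <- p0[length(p0)] + config$region_spacing
  }
  cluster_id <- region_id  # configured clusters; segmentation may split them
  meth <- if (!is.null(config$meth_states)) {
    rep(config$meth_states, config$n_regions)
  } else {
    stats::rbinom(length(pos), 1L, config$meth_prob) == 1L
  }
  p_list <- vector("list", config$n_regions)
  q_list <- vector("list", config$n_regions)
  for (r in seq_len(config$n_regions)) {
    sel <- region_id == r - 1L
    m <- meth[sel]
    p <- numeric(G); q <- numeric(G)
    if (any(m)) {
      if (!is.null(config$p_true)) {
        p[m] <- config$p_true[m] / sum(config$p_true[m])
      } else {
        w <- stats::rexp(sum(m))  # symmetric Dirichlet(1)
        p[m] <- w / sum(w)
      }
      q[m] <- stats::runif(sum(m), config$q_range[1], config$q_range[2])
    }
    p_list[[r]] <- p; q_list[[r]] <- q
  }
  # segmentation follows the read length: sites further apart than a read
  # can never share one, even when they share a sonication fragment
  index <- segment_regions(cpg_index(config$chrom, pos),
                           link_dist = config$read_len)
  list(index = index, cluster_id = cluster_id, methylated = meth,
       p = p_list, q = q_list)
}

# simulate the MeDIP reads for every region given a drawn truth; RNG
# already seeded by the caller
.draw_reads <- function(config, truth, sample_label) {
  rl <- config$read_len
  starts <- integer(0); contrib <- integer(0)
  for (r in seq_len(config$n_regions)) {
    sel <- which(truth$cluster_id == r - 1L)
    pos <- truth$index$pos[sel]
    m <- truth$methylated[sel]
    if (!any(m)) next  # nothing immunoprecipitates
    n_r <- if (config$depth_model == "poisson")
      stats::rpois(1L, config$reads_per_region) else config$reads_per_region
    if (n_r == 0L) next
    if (config$model == "single") {
      # contributor-first draw of the single-contributor law: contributing
      # site j ~ P over methylated sites, then the read start uniform among
      # the rl + 1 placements overlapping j's dinucleotide by >= 1 bp --
      # equivalent to sonication-uniform placement with capture probability
      # proportional to the total affinity of covered methylated sites
      p <- truth$p[[r]]
      j <- sample(seq_along(pos), n_r, replace = TRUE,
                  prob = p)
      s <- pos[j] - rl + 1L +
        sample.int(rl + 1L, n_r, replace = TRUE) - 1L
      starts <- c(starts, s)
      contrib <- c(contrib, sel[j])
    } else {
      # span-first rejection draw of the at-least-one law: place the read
      # uniformly, let each covered methylated site contribute Bern(q_j),
      # keep the read iff at least one contributed
      q <- truth$q[[r]]
      lo <- pos[1] - rl + 1L; hi <- pos[length(pos)] + 1L
      got <- 0L
      while (got < n_r) {
        s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        cov <- which(pos >= s - 1L & pos <= s + rl - 1L & m)
        if (!length(cov)) next
        x <- stats::rbinom(length(cov), 1L, q[cov])
        if (!any(x == 1L)) next  # read not immunoprecipitated
        got <- got + 1L
        starts <- c(starts, s)
        contrib <- c(contrib, sel[cov[which(x == 1L)[1]]])
      }
    }
  }
  if (!length(starts)) {
    reads <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0),
                        score = integer(0), strand = character(0))
  } else {
    ord <- order(starts)
    starts <- starts[ord]; contrib <- contrib[ord]
    reads <- data.frame(chrom = config$chrom, start = starts,
                        end = starts + rl,
                        name = sprintf("%s_read%06d", sample_label,
                                       seq_along(starts)),
                        score = 0L, strand = "+")
  }
  list(reads = reads, contributor = contrib)
}

#' Simulate one MeDIP-seq sample over a configured CpG landscape
#'
#' Draws the CpG map, methylation states and contribution parameters, then
#' the reads, all from `config$seed`.
#'
#' @param config a [simulate_config()].
#' @return A list: `reads` (BED-like `data.frame`), `index` (segmented
#'   [cpg_index()]), `truth` (list: `methylated`, per-region `p` and `q`,
#'   `contributor` giving each read's true contributing site as a row index
#'   into `index`).
#' @export
simulate_region <- function(config) {
  stopifnot(inherits(config, "simulate_config"))
  set.seed(config$seed)
  truth <- .draw_truth(config)
  drawn <- .draw_reads(config, truth, "simA")
  truth$contributor <- drawn$contributor
  list(reads = drawn$reads, index = truth$index, truth = truth)
}

#' Simulate MRE-seq reads from a drawn truth
#'
#' MRE reads arise only at unmethylated CpG sites: each unmethylated site is
#' enzyme-compatible with probability `mre_avail` (a Bernoulli stand-in for
#' cut-site sequence context), and each compatible site yields a
#' Poisson(`mre_depth`) number of reads whose 5' ends sit exactly on the C.
#'
#' @param config a [simulate_config()].
#' @param truth the truth list from [simulate_region()] /
#'   [simulate_replicate_pair()].
#' @return A BED-like `data.frame` of MRE read intervals.
#' @export
simulate_mre <- function(config, truth) {
  unmeth <- which(!truth$methylated)
  avail <- unmeth[stats::runif(length(unmeth)) < config$mre_avail]
  counts <- stats::rpois(length(avail), config$mre_depth)
  pos <- rep(truth$index$pos[avail], counts)
  if (!length(pos))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0)))
  pos <- sort(pos)
  data.frame(chrom = config$chrom, start = pos,
             end = pos + config$read_len,
             name = sprintf("mre%06d", seq_along(pos)), score = 0L,
             strand = "+")
}

#' Simulate a biological replicate pair sharing one ground truth
#'
#' One truth (CpG map, methylation states, contribution parameters), two
#' independent read draws — the synthetic analogue of comparing two
#' biological replicates of the same sample, where every differential call
#' is a false positive.
#'
#' @param config a [simulate_config()].
#' @param with_mre also draw an MRE-seq read set per replicate.
#' @return A list: `reads_a`, `reads_b`, `index`, `truth` (with
#'   `contributor_a`, `contributor_b`), and `mre_a`, `mre_b` when requested.
#' @export
simulate_replicate_pair <- function(config, with_mre = FALSE) {
  stopifnot(inherits(config, "simulate_config"))
  set.seed(config$seed)
  truth <- .draw_truth(config)
  a <- .draw_reads(config, truth, "repA")
  b <- .draw_reads(config, truth, "repB")
  truth$contributor_a <- a$contributor
  truth$contributor_b <- b$contributor
  out <- list(reads_a = a$reads, reads_b = b$reads, index = truth$index,
              truth = truth)
  if (with_mre) {
    out$mre_a <- simulate_mre(config, truth)
    out$mre_b <- simulate_mre(config, truth)
  }
  out
}
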