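## Per-CpG differential methylation between two samples.
##
## The default statistic is the two-sided exact conditional (Fisher) test on
## the 2x2 table [count_A, total_A - count_A; count_B, total_B - count_B]:
## exact at the small counts typical of single CpG sites, and library size
## enters only through the totals (no scaling factors). The statistic is
## pluggable so an alternative per-site test can be substituted.

# vectorised two-sided Fisher p-value for 2x2 tables, conditioning on the
# column total c_a + c_b; matches stats::fisher.test (two.sided) including
# its relative-error tie rule.
.fisher_p2 <- function(count_a, total_a, count_b, total_b) {
  n <- length(count_a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- total_a[i]; nn <- total_b[i]; kk <- count_a[i] + count_b[i]
    support <- max(0L, kk - nn):min(kk, m)
    d <- stats::dhyper(support, m, nn, kk)
    obs <- d[match(count_a[i], support)]
    p[i] <- min(1, sum(d[d <= obs * (1 + 1e-7)]))
  }
  p
}

#' Exact conditional test for one CpG site (or a vector of sites)
#'
#' Tests whether the proportion of a library's allocated reads falling on a
#' CpG site differs between samples A and B. Arguments are recycled;
#' p-values are two-sided.
#'
#' @param count_a,count_b allocated read counts at the site in each sample.
#' @param total_a,total_b library totals (must be positive and at least the
#'   counts).
#' @param method `"fisher"` (default) or a function
#'   `(count_a, total_a, count_b, total_b) -> p` implementing an alternative
#'   per-site statistic.
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
test_site <- function(count_a, total_a, count_b, total_b,
                      method = "fisher") {
  n <- max(length(count_a), length(count_b), length(total_a),
           length(total_b))
  count_a <- rep_len(as.integer(count_a), n)
  count_b <- rep_len(as.integer(count_b), n)
  total_a <- rep_len(as.integer(total_a), n)
  total_b <- rep_len(as.integer(total_b), n)
  if (any(total_a <= 0L) || any(total_b <= 0L))
    stop("library totals must be positive")
  if (any(count_a < 0L) || any(count_b < 0L) || any(count_a > total_a) ||
      any(count_b > total_b))
    stop("counts must satisfy 0 <= count <= total")
  if (is.function(method))
    return(method(count_a, total_a, count_b, total_b))
  method <- match.arg(method, "fisher")
  .fisher_p2(count_a, total_a, count_b, total_b)
}

#' Benjamini-Hochberg step-up q-values
#'
#' The package's own step-up implementation: `q_(i) = min_{j >= i}
#' (m p_(j) / j)`, capped at 1; monotone non-decreasing in p-value rank.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order; empty input gives empty output.
#' @export
adjust_qvalues <- function(p_values) {
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  ord <- order(p_values, decreasing = TRUE)
  q <- pmin(1, cummin(m / seq(m, 1) * p_values[ord]))
  q[order(ord)]
}

#' Count significant sites at a ladder of cutoffs
#'
#' For each cutoff c, the number of values strictly below c, and the implied
#' rate when the total number of assessed sites is supplied (the
#' false-positive rate in a replicate-vs-replicate comparison).
#'
#' @param values p-values or q-values.
#' @param cutoffs positive cutoffs (reported in decreasing order).
#' @param total_sites optional denominator for the rate.
#' @return A `data.frame` `cutoff`, `n_below` (non-increasing), and `rate`
#'   when `total_sites` is given.
#' @export
cutoff_report <- function(values, cutoffs, total_sites = NULL) {
  stopifnot(all(cutoffs > 0))
  cutoffs <- sort(unique(cutoffs), decreasing = TRUE)
  n_below <- vapply(cutoffs, function(cc) sum(values < cc, na.rm = TRUE),
                    numeric(1))
  out <- data.frame(cutoff = cutoffs, n_below = as.integer(n_below))
  if (!is.null(total_sites)) out$rate <- n_below / total_sites
  out
}

#' Build the per-site pair table for two allocated samples
#'
#' Joins two [allocate_sample()] tables (which share an index), computes
#' per-site p-values on the chosen counts with library totals equal to each
#' sample's summed counts, and appends BH q-values.
#'
#' @param counts_a,counts_b `data.frame`s from [allocate_sample()] over the
#'   same [cpg_index()].
#' @param use `"allocated"` (default) or `"raw"` counts.
#' @param method per-site test, see [test_site()].
#' @return A `data.frame`: `chrom`, `pos0`, `count_a`, `count_b`, `total_a`,
#'   `total_b`, `mre_a`, `mre_b`, `p_value`, `q_value`.
#' @export
diff_table <- function(counts_a, counts_b, use = c("allocated", "raw"),
                       method = "fisher") {
  use <- match.arg(use)
  if (nrow(counts_a) != nrow(counts_b) ||
      any(counts_a$pos0 != counts_b$pos0))
    stop("count tables must come from the same CpG index")
  ca <- counts_a[[use]]; cb <- counts_b[[use]]
  ta <- sum(ca); tb <- sum(cb)
  if (ta == 0L || tb == 0L)
    stop("a sample has zero total counts; nothing to test")
  p <- test_site(ca, ta, cb, tb, method = method)
  data.frame(chrom = counts_a$chrom, pos0 = counts_a$pos0,
             count_a = ca, count_b = cb, total_a = ta, total_b = tb,
             mre_a = counts_a$mre, mre_b = counts_b$mre,
             p_value = p, q_value = adjust_qvalues(p))
}

#' Empirical type-I profile on a simulated replicate pair
#'
#' Simulates two samples from one shared ground truth (biological
#' replicates), runs the full allocation pipeline on both with the
#' deconvolving model and with the raw comparator, and tabulates sites below
#' each p-value cutoff. Any site called differentially methylated between
#' replicates is a false positive, so this is the synthetic analogue of a
#' replicate-vs-replicate false-positive count.
#'
#' @param config a [simulate_config()]; its seed drives all randomness.
#' @param cutoffs p-value cutoffs for the report.
#' @param model allocation model (see [allocate_sample()]).
#' @return A list: `p_allocated`, `p_raw` (per-site p-value vectors),
#'   `report_allocated`, `report_raw` ([cutoff_report()]s with rates over
#'   all simulated sites), `n_sites`.
#' @export
replicate_null_calibration <- function(config,
                                       cutoffs = 10^-(3:8),
                                       model = "multinomial") {
  sim <- simulate_replicate_pair(config)
  counts_a <- allocate_sample(sim$reads_a, sim$index, model = model)
  counts_b <- allocate_sample(sim$reads_b, sim$index, model = model)
  tab_alloc <- diff_table(counts_a, counts_b, use = "allocated")
  tab_raw <- diff_table(counts_a, counts_b, use = "raw")
  n_sites <- nrow(sim$index)
  list(p_allocated = tab_alloc$p_value,
       p_raw = tab_raw$p_value,
       report_allocated = cutoff_report(tab_alloc$p_value, cutoffs,
                                        n_sites),
       report_raw = cutoff_report(tab_raw$p_value, cutoffs, n_sites),
       n_sites = n_sites)
}
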