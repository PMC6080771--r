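## Model core: read-to-CpG allocation for one region.
##
## Latent structure: X_ij = 1 iff site j caused the immunoprecipitation of
## read i. A read's row is only observed up to its covered span [k_i, l_i];
## entries outside the span are structural zeros, entries inside are missing.
## Two contributor laws are supported:
##   multinomial — exactly one site contributes: X_i ~ Multinomial(P),
##                 p_j = lambda_j / sum(lambda);
##   bernoulli   — each site contributes independently, X_ij ~ Bern(q_j),
##                 q_j = lambda_j / (1 + lambda_j), conditioned on >= 1
##                 contributor (truncated product-Bernoulli).

# per-read span sums: sum(p[k_i:l_i]) via cumulative sums, O(n + G)
.span_sums <- function(p, k, l) {
  cs <- c(0, cumsum(p))
  cs[l + 1L] - cs[k]
}

# per-site sum over reads covering the site of per-read weights w_i,
# exploiting span contiguity: difference-array accumulation, O(n + G)
.site_accumulate <- function(w, k, l, G) {
  d <- numeric(G + 1L)
  d_add <- rowsum(w, k)
  ii <- as.integer(rownames(d_add))
  d[ii] <- d[ii] + d_add[, 1L]
  d_sub <- rowsum(w, l + 1L)
  ii <- as.integer(rownames(d_sub))
  d[ii] <- d[ii] - d_sub[, 1L]
  cumsum(d[seq_len(G)])
}

# collapse identical spans to (unique span, multiplicity) — EM iterations
# then cost O(#unique spans); with G sites there are at most G(G+1)/2 spans
.span_weights <- function(k, l, G) {
  id <- (k - 1L) * G + l
  tab <- tabulate(id, nbins = G * G)
  keep <- which(tab > 0L)
  list(k = ((keep - 1L) %/% G) + 1L,
       l = ((keep - 1L) %% G) + 1L,
       w = tab[keep])
}

#' Observed-data log-likelihood of the multinomial allocation model
#'
#' Each read i contributes `log sum_{j = k_i}^{l_i} p_j`: the probability
#' that its single contributing site lies within the covered span. Returns
#' `-Inf` when some read's span has total probability zero.
#'
#' @param cm a [coverage_matrix()].
#' @param p numeric vector of length G on the simplex (contribution
#'   probabilities), e.g. `fit$params`.
#' @return Scalar log-likelihood.
#' @export
loglik_multinomial <- function(cm, p) {
  stopifnot(inherits(cm, "coverage_matrix"))
  if (length(p) != cm$G)
    stop("p has length ", length(p), " but region has ", cm$G, " sites")
  if (cm$n == 0L) return(0)
  s <- .span_sums(p, cm$k, cm$l)
  if (any(s <= 0)) return(-Inf)
  sum(log(s))
}

# observed-data log-likelihood of the truncated-Bernoulli model:
# off-span zeros contribute log(1-q), the span contributes
# log(1 - prod_span(1-q)), and each read is conditioned on >= 1 contributor
# among the region's G sites.
.loglik_bernoulli <- function(cm, q) {
  if (cm$n == 0L) return(0)
  lq <- log1p(-pmin(q, 1 - 1e-12))
  cl <- c(0, cumsum(lq))
  span_lp <- cl[cm$l + 1L] - cl[cm$k]              # log prod_span (1-q)
  t_span <- pmax(-expm1(span_lp), 1e-300)          # 1 - prod_span (1-q)
  total_lp <- cl[cm$G + 1L]
  denom <- pmax(-expm1(total_lp), 1e-300)          # 1 - prod_G (1-q)
  sum(total_lp - span_lp + log(t_span)) - cm$n * log(denom)
}

.em_init <- function(init, G, model) {
  if (is.character(init) && identical(init, "uniform"))
    return(if (model == "multinomial") rep(1 / G, G) else rep(0.5, G))
  init <- as.numeric(init)
  if (length(init) != G) stop("init has wrong length")
  if (model == "multinomial") {
    if (any(init < 0) || abs(sum(init) - 1) > 1e-8)
      stop("multinomial init must lie on the simplex")
  } else if (any(init <= 0) || any(init >= 1)) {
    stop("bernoulli init must lie strictly inside (0, 1)")
  }
  init
}

#' Fit the single-contributor multinomial model by EM
#'
#' E-step: for each read the latent contributor, given that it lies in the
#' covered span, is multinomial over the span with responsibilities
#' `x~_ij = p_j / sum_{s=k_i}^{l_i} p_s`. M-step: `p^_j = sum_i x~_ij / n`.
#' Iterates until the max-norm parameter change drops below `tol`. The
#' starting value does not affect the converged fit (verified as a test
#' property, not assumed); sites covered by no read keep `p^_j = 0` from the
#' first iteration.
#'
#' @param cm a [coverage_matrix()] with `n >= 1`.
#' @param init `"uniform"` (default) or a length-G simplex vector.
#' @param tol convergence tolerance on `max |p^ - p-|` (default 1e-8).
#' @param max_iter iteration cap (default 1e4).
#' @param keep_responsibilities return the final n x G responsibility matrix
#'   (default TRUE; set FALSE to save memory on large regions).
#' @return An `em_fit` object: `model`, `params`, `responsibilities`,
#'   `loglik_trace` (observed-data log-likelihood, starting at the initial
#'   parameters; non-decreasing), `iterations`, `converged`, `n`, `G`.
#' @export
em_multinomial <- function(cm, init = "uniform", tol = 1e-8, max_iter = 1e4,
                           keep_responsibilities = TRUE) {
  stopifnot(inherits(cm, "coverage_matrix"), cm$n >= 1L, tol > 0)
  G <- cm$G; n <- cm$n; k <- cm$k; l <- cm$l
  p <- .em_init(init, G, "multinomial")
  sp <- .span_weights(k, l, G)  # iteration cost O(G^2), not O(n)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- loglik_multinomial(cm, p)
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    s <- pmax(.span_sums(p, sp$k, sp$l), 1e-300)
    p_new <- p * .site_accumulate(sp$w / s, sp$k, sp$l, G) / n
    trace[it + 1L] <- sum(sp$w * log(pmax(.span_sums(p_new, sp$k, sp$l),
                                          1e-300)))
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
  }
  resp <- NULL
  if (keep_responsibilities) {
    s <- pmax(.span_sums(p, k, l), 1e-300)
    resp <- matrix(0, n, G)
    for (i in seq_len(n)) {
      jj <- k[i]:l[i]
      resp[i, jj] <- pmin(p[jj] / s[i], 1)  # guard float round-up
    }
  }
  structure(list(model = "multinomial", params = p, responsibilities = resp,
                 loglik_trace = trace[seq_len(it + 1L)], iterations = it,
                 converged = converged, degenerate = FALSE, n = n, G = G),
            class = "em_fit")
}

#' Fit the at-least-one-contributor truncated-Bernoulli model by EM
#'
#' Under the truncated model each covered site contributes independently
#' with probability `q_j`, conditioned on at least one contributor. E-step
#' for latent entries: `x~_ij = q_j / (1 - prod_{s=k_i}^{l_i} (1 - q_s))`;
#' structural zeros outside the span stay 0. M-step (the closed-form update
#' of the constrained score equations):
#' `q^_j = (sum_i x~_ij) (1 - prod_{s=1}^{G} (1 - q_s)) / n`.
#'
#' A degenerate fixed point with all `q^ -> 0` is reachable on some
#' symmetric inputs; it is detected (parameter collapse) and reported via
#' `converged = FALSE` and `degenerate = TRUE` rather than returned silently.
#'
#' @inheritParams em_multinomial
#' @param init `"uniform"` (all 0.5) or a length-G vector strictly inside
#'   (0, 1).
#' @return An `em_fit` object (see [em_multinomial()]); `loglik_trace` is the
#'   observed-data log-likelihood of the truncated model.
#' @export
em_truncated_bernoulli <- function(cm, init = "uniform", tol = 1e-8,
                                   max_iter = 1e4,
                                   keep_responsibilities = TRUE) {
  stopifnot(inherits(cm, "coverage_matrix"), cm$n >= 1L, tol > 0)
  G <- cm$G; n <- cm$n; k <- cm$k; l <- cm$l
  q <- .em_init(init, G, "bernoulli")
  sp <- .span_weights(k, l, G)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- .loglik_bernoulli(cm, q)
  it <- 0L; converged <- FALSE; degenerate <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    lq <- log1p(-pmin(q, 1 - 1e-12))
    cl <- c(0, cumsum(lq))
    t_span <- pmax(-expm1(cl[sp$l + 1L] - cl[sp$k]), 1e-300)
    colsum <- q * .site_accumulate(sp$w / t_span, sp$k, sp$l, G)
    denom <- pmax(-expm1(cl[G + 1L]), 1e-300)      # 1 - prod_G (1-q)
    q_new <- colsum * denom / n
    trace[it + 1L] <- .loglik_bernoulli(cm, q_new)
    delta <- max(abs(q_new - q))
    # degenerate fixed point: observed likelihood has stagnated but the
    # parameters keep collapsing geometrically toward 0
    if (max(q_new) < 1e-3 &&
        max(q_new) <= max(q) * (1 - 1e-6) &&
        abs(trace[it + 1L] - trace[it]) < 1e-6) {
      q <- q_new
      degenerate <- TRUE
      break
    }
    q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (max(q) < 1e-4) {  # collapsed below any plausible contribution rate
    degenerate <- TRUE
    converged <- FALSE
  }
  resp <- NULL
  if (keep_responsibilities) {
    lq <- log1p(-pmin(q, 1 - 1e-12))
    cl <- c(0, cumsum(lq))
    t_span <- pmax(-expm1(cl[l + 1L] - cl[k]), 1e-300)
    resp <- matrix(0, n, G)
    for (i in seq_len(n)) {
      jj <- k[i]:l[i]
      resp[i, jj] <- pmin(q[jj] / t_span[i], 1)
    }
  }
  structure(list(model = "bernoulli", params = q, responsibilities = resp,
                 loglik_trace = trace[seq_len(it + 1L)], iterations = it,
                 converged = converged, degenerate = degenerate, n = n,
                 G = G),
            class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("<em_fit> %s model: G=%d, n=%d, %d iteration(s), %s%s\n",
              x$model, x$G, x$n, x$iterations,
              if (x$converged) "converged" else "not converged",
              if (isTRUE(x$degenerate)) " (degenerate fixed point)" else ""))
  cat("params:", format(round(x$params, 4), trim = TRUE), "\n")
  invisible(x)
}

#' Allocate integer read counts to CpG sites from a fitted model
#'
#' Multinomial model: the allocated count at site j is `[n p^_j]`;
#' truncated-Bernoulli model: `[n q^_j / (1 - prod_s (1 - q^_s))]`. The
#' bracket is rounding to the nearest integer (half-even); in the
#' multinomial case the rounding residual is redistributed by largest
#' fractional remainder (ties toward the lower index) so that the allocated
#' counts conserve the region's read count exactly.
#'
#' @param result an `em_fit`.
#' @param n number of reads to allocate (default: the fit's read count).
#' @param model `"multinomial"` or `"bernoulli"` (default: the fit's model).
#' @return Integer vector of per-site allocated counts.
#' @export
allocate_counts <- function(result, n = result$n, model = result$model) {
  model <- match.arg(model, c("multinomial", "bernoulli"))
  expected <- if (model == "multinomial") {
    n * result$params
  } else {
    q <- result$params
    denom <- max(1 - prod(1 - q), 1e-300)
    n * q / denom
  }
  counts <- as.integer(round(expected))  # round() is half-even
  if (model == "multinomial") {
    resid <- as.integer(n) - sum(counts)
    if (resid != 0L) {
      frac <- expected - floor(expected)
      ord <- order(if (resid > 0L) -frac else frac, seq_along(frac))
      bump <- if (resid > 0L) 1L else -1L
      i <- 1L
      while (resid != 0L) {
        j <- ord[i]
        if (bump > 0L || counts[j] > 0L) {
          counts[j] <- counts[j] + bump
          resid <- resid - bump
        }
        i <- if (i == length(ord)) 1L else i + 1L
      }
    }
  }
  counts
}

#' Raw per-site covering-read counts
#'
#' The undeconvolved comparator: every read is credited to every CpG site it
#' covers, so `sum_j raw_j = sum_i (l_i - k_i + 1)`.
#'
#' @param cm a [coverage_matrix()].
#' @return Integer vector of per-site counts.
#' @export
raw_counts <- function(cm) {
  stopifnot(inherits(cm, "coverage_matrix"))
  if (cm$n == 0L) return(integer(cm$G))
  as.integer(round(.site_accumulate(rep(1, cm$n), cm$k, cm$l, cm$G)))
}

#' Allocate a whole sample: EM per region plus raw and MRE counts
#'
#' Convenience orchestration of [build_coverage_matrix()],
#' [em_multinomial()] / [em_truncated_bernoulli()], [allocate_counts()] and
#' [raw_counts()] across every region of an index. Sites in regions with no
#' reads are retained with zero counts.
#'
#' @param reads MeDIP-seq read intervals (`data.frame`; see [read_bed()]).
#' @param index a segmented [cpg_index()].
#' @param model `"multinomial"` (default) or `"bernoulli"`.
#' @param mre_reads optional MRE-seq read intervals for [mre_site_counts()].
#' @param tol,max_iter EM controls (see [em_multinomial()]).
#' @param min_overlap see [build_coverage_matrix()].
#' @return A `data.frame` with one row per CpG site: `chrom`, `pos0`,
#'   `region_id`, `n_region` (reads in the site's region), `allocated`,
#'   `raw`, `mre`; attributes `discarded` (MeDIP reads covering no site),
#'   `em_iterations`, `degenerate_regions`.
#' @export
allocate_sample <- function(reads, index, model = c("multinomial",
                                                    "bernoulli"),
                            mre_reads = NULL, tol = 1e-6, max_iter = 1e4,
                            min_overlap = 1L) {
  model <- match.arg(model)
  cms <- build_coverage_matrix(reads, index, min_overlap = min_overlap)
  out <- data.frame(chrom = index$chrom, pos0 = index$pos,
                    region_id = index$region_id,
                    n_region = 0L, allocated = 0L, raw = 0L, mre = 0L)
  iters <- integer(0); degen <- integer(0)
  for (cm in cms) {
    fit <- if (model == "multinomial") {
      em_multinomial(cm, tol = tol, max_iter = max_iter,
                     keep_responsibilities = FALSE)
    } else {
      em_truncated_bernoulli(cm, tol = tol, max_iter = max_iter,
                             keep_responsibilities = FALSE)
    }
    iters <- c(iters, fit$iterations)
    if (isTRUE(fit$degenerate)) degen <- c(degen, cm$region_id)
    sel <- which(out$region_id == cm$region_id)
    out$n_region[sel] <- cm$n
    out$allocated[sel] <- allocate_counts(fit)
    out$raw[sel] <- raw_counts(cm)
  }
  if (!is.null(mre_reads)) {
    mre <- mre_site_counts(mre_reads, index)
    out$mre <- as.integer(mre)
    attr(out, "mre_discarded") <- attr(mre, "discarded")
  }
  attr(out, "discarded") <- attr(cms, "discarded")
  attr(out, "em_iterations") <- iters
  attr(out, "degenerate_regions") <- degen
  out
}
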