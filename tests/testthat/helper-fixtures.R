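# Shared fixtures and independent oracles.

# the worked 5-site / 6-read example: reads cover {1},{1,2},{1,2,3},{3,4},
# {3,4,5},{5}
fig1_cm <- function() {
  coverage_matrix(region_id = 0L, chrom = "chr1",
                  positions = c(100L, 130L, 160L, 190L, 220L),
                  k = c(1L, 1L, 1L, 3L, 3L, 5L),
                  l = c(1L, 2L, 3L, 4L, 5L, 5L))
}

# random small coverage instance with every site identifiable: one singleton
# read per site plus random contiguous spans
random_cm <- function(G, n_extra) {
  k <- seq_len(G); l <- seq_len(G)
  if (n_extra > 0L) {
    a <- sample.int(G, n_extra, replace = TRUE)
    b <- sample.int(G, n_extra, replace = TRUE)
    k <- c(k, pmin(a, b)); l <- c(l, pmax(a, b))
  }
  coverage_matrix(0L, "chrT", positions = seq(100L, by = 40L,
                                              length.out = G), k, l)
}

# dense simplex grid with the given step (fractions of `den`), G <= 4
simplex_grid <- function(G, den = 100L) {
  if (G == 1L) return(matrix(1, 1, 1))
  parts <- switch(as.character(G),
    "2" = {
      a <- 0:den
      cbind(a, den - a)
    },
    "3" = {
      g <- expand.grid(a = 0:den, b = 0:den)
      g <- g[g$a + g$b <= den, ]
      cbind(g$a, g$b, den - g$a - g$b)
    },
    "4" = {
      g <- expand.grid(a = 0:den, b = 0:den, c = 0:den)
      g <- g[g$a + g$b + g$c <= den, ]
      cbind(g$a, g$b, g$c, den - g$a - g$b - g$c)
    },
    stop("G > 4 not supported"))
  unname(parts) / den
}

# observed-data log-likelihood maximiser by dense grid search (independent
# of the EM path)
grid_mle <- function(cm, den = 100L) {
  P <- simplex_grid(cm$G, den)
  A <- dense_coverage(cm)  # n x G span membership
  S <- A %*% t(P)          # n x nGrid span sums
  ll <- colSums(log(S))
  P[which.max(ll), ]
}

# simplex-constrained numerical maximiser via softmax reparameterisation
# (for G > 4 where a 0.01 grid is infeasible); multistart for robustness
optim_mle <- function(cm, n_starts = 5L) {
  A <- dense_coverage(cm)
  negll <- function(theta) {
    p <- exp(theta - max(theta)); p <- p / sum(p)
    -sum(log(pmax(A %*% p, 1e-300)))
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    theta0 <- if (s == 1L) rep(0, cm$G) else stats::rnorm(cm$G)
    fit <- stats::optim(theta0, negll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- exp(best$par - max(best$par))
  p / sum(p)
}

# enumeration oracle for the single-contributor span probability: sum the
# multinomial law over every one-hot assignment consistent with the span
enum_span_prob <- function(p, k, l) {
  tot <- 0
  for (j in seq_along(p)) {
    x <- rep(0L, length(p)); x[j] <- 1L
    consistent <- all(x[setdiff(seq_along(p), k:l)] == 0L)
    if (consistent) tot <- tot + prod(p^x)
  }
  tot
}

# rejection sampler from independent Bernoulli(q) conditioned on the row
# sum being exactly `one` (Theorem-1 world) or at least one (Theorem-2
# world); returns a matrix of accepted rows
sample_conditioned <- function(q, n_target, condition = c("eq1", "ge1")) {
  condition <- match.arg(condition)
  G <- length(q)
  out <- matrix(0L, 0, G)
  while (nrow(out) < n_target) {
    X <- matrix(stats::rbinom(20000L * G, 1L, rep(q, each = 20000L)),
                20000L, G)
    rs <- rowSums(X)
    keep <- if (condition == "eq1") rs == 1L else rs >= 1L
    out <- rbind(out, X[keep, , drop = FALSE])
  }
  out[seq_len(n_target), , drop = FALSE]
}

toy_path <- function(f) system.file("extdata", f, package = "medipcpg")
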