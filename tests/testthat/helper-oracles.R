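# Brute-force oracles and small fixture builders, independent of the
# package's own computation paths.

# build a small ImpairmentMatrix directly from a domains x children logical
# matrix (observed defaults to everywhere-TRUE)
make_im <- function(calls, group, observed = NULL) {
  calls <- as.matrix(calls)
  if (is.null(observed)) observed <- matrix(TRUE, nrow(calls), ncol(calls))
  storage.mode(calls) <- "logical"
  storage.mode(observed) <- "logical"
  calls[!observed] <- FALSE
  if (is.null(rownames(calls)))
    rownames(calls) <- LETTERS[seq_len(nrow(calls))]
  rownames(observed) <- rownames(calls)
  ids <- paste0("c", seq_len(ncol(calls)))
  colnames(calls) <- colnames(observed) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls, observed = observed),
    colData = S4Vectors::DataFrame(group = group, row.names = ids))
  new("ImpairmentMatrix", se)
}

# exhaustive triple-loop pair counts
oracle_pair_counts <- function(calls) {
  d <- nrow(calls)
  out <- matrix(0L, d, d, dimnames = list(rownames(calls), rownames(calls)))
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (i == j) next
    n <- 0L
    for (ch in seq_len(ncol(calls)))
      if (isTRUE(calls[i, ch]) && isTRUE(calls[j, ch])) n <- n + 1L
    out[i, j] <- n
  }
  out
}

# exact two-sided Fisher p for a 2x2 table by full hypergeometric enumeration
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  pobs <- dhyper(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Mann-Whitney U by exhaustive pairwise comparison (ties count 1/2)
oracle_U <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y)
    u <- u + if (xi > yi) 1 else if (xi == yi) 0.5 else 0
  u
}

# direct-formula likelihood-ratio G
oracle_G <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  g <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    if (tab[i, j] > 0) g <- g + 2 * tab[i, j] * log(tab[i, j] / E[i, j])
  g
}

# hand Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# closed-form impairment probability by numerical integration (independent
# of the package's pnorm shortcut): P(lambda*L + sqrt(1-lambda^2)*eps < c)
# with L ~ N(mu, 1)
oracle_impair_prob <- function(lambda, offset, cutoff, mu) {
  f <- function(l)
    pnorm((cutoff - offset - lambda * l) / sqrt(1 - lambda^2)) * dnorm(l, mu)
  integrate(f, mu - 9, mu + 9, rel.tol = 1e-10)$value
}
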