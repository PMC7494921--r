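# Independent oracles and small fixture builders shared across test files.

# matrix stripped to values + dim, for comparisons against plain matrices
bare_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

# seeded random expression layer with unique feature/sample IDs
rand_layer <- function(n, m, seed, layer = "layer", prefix = "f",
                       sample_prefix = "s") {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m,
              dimnames = list(paste0(prefix, seq_len(n)),
                              paste0(sample_prefix, seq_len(m))))
  expression_layer(x, layer)
}

# explicit triple-loop collapse of the implicit tensor x_ijk = a_ij * b_kj
brute_collapse <- function(a, b) {
  n <- nrow(a); m <- ncol(a); k <- nrow(b)
  x <- matrix(0, n, k, dimnames = list(rownames(a), rownames(b)))
  for (i in seq_len(n))
    for (kk in seq_len(k))
      for (j in seq_len(m))
        x[i, kk] <- x[i, kk] + a[i, j] * b[kk, j]
  x
}

# O(m^2) Benjamini-Hochberg straight from the step-up definition
brute_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    min(1, min(vapply(which(p >= p[i]), function(j) p[j] * m / r[j],
                      numeric(1))))
  }, numeric(1))
}

# chi-squared(1 df) survival function via the Gaussian tail, independent
# of pchisq
chi2_sf_oracle <- function(q) 2 * pnorm(-sqrt(q))

# two-sided Fisher P by explicit enumeration over all tables with the
# observed margins, probabilities from the factorial formula
fisher_p_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  logp <- function(aa) {
    bb <- r1 - aa; cc <- c1 - aa; dd <- r2 - cc
    (lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
       lfactorial(n) - lfactorial(aa) - lfactorial(bb) - lfactorial(cc) -
       lfactorial(dd))
  }
  support <- max(0, r1 - c2):min(r1, c1)
  probs <- exp(vapply(support, logp, numeric(1)))
  pobs <- exp(logp(a))
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# text fixture in the GEO series-matrix dialect
geo_fixture_lines <- function() {
  c("!Series_title\t\"tiny synthetic series\"",
    "!Series_platform_id\t\"GPL0000\"",
    "!series_matrix_table_begin",
    "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"",
    "\"probe1\"\t1.5\t2.5",
    "\"probe2\"\t-3\t4e-2",
    "!series_matrix_table_end",
    "!Series_end\t\"x\"")
}

default_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset()
    cache
  }
})

quiet_tdfe <- function(...) suppressMessages(run_tdfe(...))
quiet_pca <- function(...) suppressMessages(run_pca_fe(...))

selected_ids <- function(scores) scores$id[scores$selected]
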