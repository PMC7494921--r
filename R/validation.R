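# Post-selection analyses: cross-layer pair correlations, the supervised
# Welch t-test baseline, and cross-dataset concordance (2x2 confusion
# table + Fisher's exact test).

#' Correlate every selected mRNA with every selected miRNA
#'
#' Pearson correlation and two-sided P-value for each cross-layer pair of
#' features, with Benjamini-Hochberg correction over the full pair grid
#' jointly. Pairs involving a zero-variance feature have an undefined
#' correlation; they are flagged and excluded from the BH adjustment.
#'
#' @param a_sel,b_sel expression matrices restricted to the selected
#'   features of each layer, aligned on identical ordered samples (>= 3).
#' @param alpha FDR threshold for the `significant` flag.
#' @return data frame with one row per (A-feature, B-feature) pair:
#'   `id_a`, `id_b`, `pcc`, `p_raw`, `p_adj`, `significant`, `sign`
#'   (`positive`/`negative`/`zero`/`undefined`). Counts of significant
#'   positive/negative pairs are attached as attributes
#'   `n_significant_positive` / `n_significant_negative` and reported via
#'   `message()`.
#' @export
pairwise_correlations <- function(a_sel, b_sel, alpha = 0.01) {
  if (!identical(colnames(a_sel), colnames(b_sel)))
    stop("layers are not aligned on identical ordered samples")
  m <- ncol(a_sel)
  if (m < 3L) stop("need at least 3 samples for pair correlations")
  va <- rowSums((a_sel - rowMeans(a_sel))^2)
  vb <- rowSums((b_sel - rowMeans(b_sel))^2)
  if (any(va == 0) || any(vb == 0))
    message("pairwise_correlations: ", sum(va == 0), " layer-A and ",
            sum(vb == 0), " layer-B zero-variance features; ",
            "their pairs are flagged undefined and excluded from BH")
  r <- suppressWarnings(cor(t(a_sel), t(b_sel)))
  r[va == 0, ] <- NA_real_
  r[, vb == 0] <- NA_real_
  # two-sided P from the exact t transform of r under the null
  tt <- r * sqrt((m - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(abs(tt), df = m - 2, lower.tail = FALSE)
  tab <- data.frame(id_a = rownames(r)[row(r)],
                    id_b = colnames(r)[col(r)],
                    pcc = as.vector(r),
                    p_raw = as.vector(p),
                    row.names = NULL)
  tab$p_adj <- NA_real_
  defined <- is.finite(tab$pcc)
  tab$p_adj[defined] <- bh_adjust(tab$p_raw[defined])
  tab$significant <- defined & tab$p_adj < alpha
  tab$sign <- ifelse(!defined, "undefined",
                     ifelse(tab$pcc > 0, "positive",
                            ifelse(tab$pcc < 0, "negative", "zero")))
  npos <- sum(tab$significant & tab$sign == "positive")
  nneg <- sum(tab$significant & tab$sign == "negative")
  message(sprintf("pairwise_correlations: %d pairs, %d significant positive, %d significant negative (alpha = %g)",
                  nrow(tab), npos, nneg, alpha))
  attr(tab, "n_significant_positive") <- npos
  attr(tab, "n_significant_negative") <- nneg
  tab
}

#' Supervised Welch t-test baseline
#'
#' Per-feature two-sided Welch (unequal-variance) t-test between case and
#' control samples, vectorized over features, with Benjamini-Hochberg
#' correction. Either threshold on adjusted P (default) or, to compare
#' selection sets of equal size across methods, keep the `top_n` features
#' with the smallest raw P.
#'
#' @param x expression matrix (features x samples).
#' @param annotation class factor named by sample ID (>= 2 per class).
#' @param alpha FDR threshold when `top_n` is `NULL`.
#' @param top_n optional number of top-ranked features (by raw P) to
#'   select instead of thresholding.
#' @return data frame with columns `id`, `layer`, `t`, `df`, `p_raw`,
#'   `p_adj`, `selected`. Features whose Welch statistic is undefined
#'   (both classes constant at equal values) carry NA P-values and are
#'   excluded from BH and never selected.
#' @export
welch_t_baseline <- function(x, annotation, alpha = 0.01, top_n = NULL) {
  cls <- sample_classes(annotation, colnames(x))
  x1 <- x[, cls == "case", drop = FALSE]
  x0 <- x[, cls == "control", drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  dfree <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(abs(tstat), df = dfree, lower.tail = FALSE)
  ok <- is.finite(p)
  p_adj <- rep(NA_real_, length(p))
  p_adj[ok] <- bh_adjust(p[ok])
  tab <- data.frame(id = rownames(x), layer = layer_name(x),
                    t = unname(tstat), df = unname(dfree),
                    p_raw = unname(p), p_adj = unname(p_adj),
                    row.names = NULL)
  if (is.null(top_n)) {
    tab$selected <- ok & tab$p_adj < alpha
  } else {
    top_n <- as.integer(top_n)
    if (is.na(top_n) || top_n < 0L || top_n > sum(ok))
      stop("top_n must be between 0 and the number of testable features")
    tab$selected <- FALSE
    tab$selected[order(tab$p_raw)[seq_len(top_n)]] <- TRUE
  }
  tab
}

#' Build a 2x2 cross-dataset selection confusion table
#'
#' Over a common feature universe, counts features selected in neither
#' dataset (`a`), only in B (`b`), only in A (`c`), and in both (`d`).
#'
#' @param sel_a,sel_b character vectors of selected feature IDs, each a
#'   subset of `universe`.
#' @param universe character vector of all features comparable between the
#'   two datasets.
#' @return object of class `confusion_table` with integer fields `a`, `b`,
#'   `c`, `d` and `universe_size`.
#' @export
cross_dataset_confusion <- function(sel_a, sel_b, universe) {
  universe <- unique(as.character(universe))
  sel_a <- unique(as.character(sel_a))
  sel_b <- unique(as.character(sel_b))
  out_a <- setdiff(sel_a, universe)
  out_b <- setdiff(sel_b, universe)
  if (length(out_a) || length(out_b))
    stop("selections outside the universe: ",
         paste(c(out_a, out_b), collapse = ", "))
  d <- length(intersect(sel_a, sel_b))
  confusion_table(a = length(universe) - length(union(sel_a, sel_b)),
                  b = length(sel_b) - d,
                  c = length(sel_a) - d,
                  d = d)
}

#' Construct a confusion table from its four counts
#'
#' Layout: rows index dataset A (not selected / selected), columns dataset
#' B, so `a` = neither, `b` = B only, `c` = A only, `d` = both.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return object of class `confusion_table`.
#' @export
confusion_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("confusion table counts must be non-negative integers")
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d),
                 universe_size = as.numeric(a + b + c + d)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2L, byrow = TRUE,
              dimnames = list(A = c("not selected", "selected"),
                              B = c("not selected", "selected")))
  print(m)
  invisible(x)
}

#' Fisher's exact test on a confusion table
#'
#' Two-sided P by the probability-mass criterion: conditioning on the
#' margins, the P-value is the sum of hypergeometric probabilities of all
#' tables no more probable than the observed one (a tiny relative slack
#' guards floating-point ties, as in [stats::fisher.test()]). Reports both
#' the sample (cross-product) odds ratio `a*d / (b*c)` — infinite when
#' `b*c = 0` and `a*d > 0` — and the conditional maximum-likelihood
#' estimate from [stats::fisher.test()].
#'
#' @param tab a [confusion_table()] or plain 2x2 matrix
#'   (`rbind(c(a, b), c(c, d))`).
#' @return list with `p_two_sided`, `odds_ratio_sample`,
#'   `odds_ratio_cmle`, `degenerate`. A degenerate margin (a row or column
#'   summing to 0) gives `p_two_sided = 1`, undefined odds ratios, and
#'   `degenerate = TRUE`.
#' @export
fisher_exact <- function(tab) {
  if (inherits(tab, "confusion_table")) {
    a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  } else if (is.matrix(tab) && all(dim(tab) == 2L)) {
    a <- tab[1L, 1L]; b <- tab[1L, 2L]; c <- tab[2L, 1L]; d <- tab[2L, 2L]
  } else stop("tab must be a confusion_table or a 2x2 matrix")
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- a + b + c + d
  if (n == 0 || min(a + b, c + d) == 0 || min(a + c, b + d) == 0)
    return(list(p_two_sided = 1, odds_ratio_sample = NA_real_,
                odds_ratio_cmle = NA_real_, degenerate = TRUE))
  # condition on the margins; the "both selected" cell d is hypergeometric
  r2 <- c + d  # features selected in A
  c2 <- b + d  # features selected in B
  support <- seq.int(max(0, r2 + c2 - n), min(r2, c2))
  probs <- dhyper(support, c2, n - c2, r2)
  pobs <- dhyper(d, c2, n - c2, r2)
  p <- min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
  or_cmle <- unname(fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE))$estimate)
  list(p_two_sided = p,
       odds_ratio_sample = (a * d) / (b * c),
       odds_ratio_cmle = or_cmle,
       degenerate = FALSE)
}
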