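#' Drop degenerate features
#'
#' Removes features carrying any non-finite value and/or features with zero
#' variance across samples, reporting the counts removed.
#'
#' @param x expression matrix (features x samples).
#' @param drop_nonfinite drop features with any NA/NaN/Inf value.
#' @param drop_zero_variance drop features constant across samples.
#' @return the filtered expression matrix.
#' @export
filter_features <- function(x, drop_nonfinite = TRUE, drop_zero_variance = TRUE) {
  keep <- rep(TRUE, nrow(x))
  if (drop_nonfinite) {
    bad <- rowSums(!is.finite(x)) > 0
    if (any(bad)) message("filter_features: dropped ", sum(bad),
                          " features with non-finite values")
    keep <- keep & !bad
  }
  if (drop_zero_variance) {
    ss <- rowSums((x - rowMeans(x))^2)
    zv <- is.finite(ss) & ss == 0
    if (any(zv & keep)) message("filter_features: dropped ", sum(zv & keep),
                                " zero-variance features")
    keep <- keep & !zv
  }
  if (!any(keep)) stop("all features removed by filtering")
  y <- x[keep, , drop = FALSE]
  attr(y, "layer") <- attr(x, "layer", exact = TRUE)
  y
}

#' Standardize every sample column
#'
#' Centers each sample (column) to mean zero over features and rescales it
#' so that its sum of squares equals the number of features N. A column
#' that is constant before centering cannot be rescaled; it becomes all
#' zero and is flagged with a warning.
#'
#' @param x expression matrix with at least 2 features.
#' @return the standardized matrix.
#' @export
standardize_per_sample <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("standardize_per_sample needs at least 2 features")
  xc <- x - rep(colMeans(x), each = n)
  ss <- colSums(xc^2)
  const <- ss == 0
  scl <- sqrt(n / ss)
  scl[const] <- 0
  if (any(const))
    warning("constant sample columns set to zero: ",
            paste(colnames(x)[const], collapse = ", "))
  y <- xc * rep(scl, each = n)
  dimnames(y) <- dimnames(x)
  attr(y, "layer") <- attr(x, "layer", exact = TRUE)
  y
}

#' Preprocess one expression layer
#'
#' Filtering, optional `log2(x + offset)` transform, and per-sample
#' standardization, in that order. The log transform is off by default
#' because RNA-seq abundance estimates and microarray intensities call for
#' different handling; standardization is on by default because the
#' chi-squared feature scoring downstream compares singular-vector entries
#' against a Gaussian-derived null.
#'
#' @inheritParams filter_features
#' @param log2_offset non-negative offset `c` for `log2(x + c)`, or `NULL`
#'   (default) for no log transform.
#' @param standardize apply [standardize_per_sample()].
#' @return the preprocessed expression matrix.
#' @export
preprocess_matrix <- function(x, log2_offset = NULL, standardize = TRUE,
                              drop_nonfinite = TRUE, drop_zero_variance = TRUE) {
  y <- filter_features(x, drop_nonfinite = drop_nonfinite,
                       drop_zero_variance = drop_zero_variance)
  if (!is.null(log2_offset)) {
    if (!is.finite(log2_offset) || log2_offset < 0)
      stop("log2_offset must be a finite non-negative number")
    y2 <- suppressWarnings(log2(y + log2_offset))
    if (any(!is.finite(y2)))
      stop("log2 transform produced non-finite values; ",
           "increase log2_offset or check input range")
    attr(y2, "layer") <- attr(y, "layer", exact = TRUE)
    y <- y2
  }
  if (standardize) y <- standardize_per_sample(y)
  y
}
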