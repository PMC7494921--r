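# PCA route of the same feature-extraction scheme, run per layer. PC
# scores are attributed to features (eigenvectors of the N x N gram matrix
# sum_j x_ij x_i'j) and PC loadings to samples (projections of the data
# onto the scores). The gram eigenproblem is solved through the SVD of x
# rather than by forming the N x N matrix; the contract is fixed by the
# invariants (orthonormal scores, loadings = X' u), not the route.

#' Fit the per-layer PCA factorization
#'
#' @param x standardized expression matrix (see
#'   [standardize_per_sample()]), N features x M samples.
#' @param L number of components, `1 <= L <= min(N, M)`.
#' @return object of class `pca_factorization` with `eigenvalues`
#'   (non-increasing, clamped at 0), `pc_scores` (N x L, orthonormal
#'   columns, deterministic sign convention), `pc_loadings` (M x L,
#'   `t(x) %*% pc_scores`), `sample_ids`, `layer`.
#' @export
pca_fit <- function(x, L = min(10L, min(dim(x)))) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L || L > min(dim(x)))
    stop("L must be an integer in 1..min(N, M)")
  sv <- svd(x, nu = L, nv = 0L)
  scores <- sv$u
  s <- component_sign(scores)
  scores <- scores * rep(s, each = nrow(scores))
  dimnames(scores) <- list(rownames(x), paste0("l", seq_len(L)))
  loadings <- crossprod(x, scores)
  dimnames(loadings) <- list(colnames(x), paste0("l", seq_len(L)))
  structure(list(eigenvalues = pmax(sv$d[seq_len(L)]^2, 0),
                 pc_scores = scores,
                 pc_loadings = loadings,
                 sample_ids = colnames(x),
                 layer = layer_name(x)),
            class = "pca_factorization")
}

#' PCA-based feature extraction for one layer
#'
#' Diagnoses every PC loading with a Welch t-test between classes, chooses
#' the component (auto: smallest class-separation P; manual: stated index),
#' and scores the features of that component's PC-score vector with the
#' chi-squared / Benjamini-Hochberg chain. Layers are processed
#' independently: unlike the tensor route, nothing couples the component
#' index chosen for one layer to the other.
#'
#' @param f a `pca_factorization`.
#' @param annotation class factor named by sample ID (>= 2 per class).
#' @inheritParams score_features
#' @inheritParams choose_component
#' @return list with `scores` (feature score table for the chosen
#'   component), `diagnostics` (data frame `l`, `t_p`), and `component`.
#' @export
pca_select <- function(f, annotation, alpha = 0.01,
                       sd_mode = c("sample", "population"),
                       strategy = c("auto", "manual"), manual_l = NULL) {
  if (!inherits(f, "pca_factorization")) stop("f must be a pca_factorization")
  strategy <- match.arg(strategy)
  sd_mode <- match.arg(sd_mode)
  cls <- sample_classes(annotation, f$sample_ids)
  t_p <- apply(f$pc_loadings, 2L, welch_p, cls = cls)
  diagnostics <- data.frame(l = seq_along(t_p), t_p = unname(t_p))
  l <- if (strategy == "manual") {
    li <- as.integer(manual_l)
    if (is.na(li) || !li %in% diagnostics$l)
      stop("manual_l out of range: ", manual_l)
    li
  } else diagnostics$l[which.min(diagnostics$t_p)]
  scores <- score_features(f$pc_scores[, l], component = l, layer = f$layer,
                           alpha = alpha, sd_mode = sd_mode)
  list(scores = scores, diagnostics = diagnostics, component = l)
}

#' @export
print.pca_factorization <- function(x, ...) {
  cat(sprintf("pca_factorization (%s): %d features, %d samples, %d components\n",
              x$layer, nrow(x$pc_scores), length(x$sample_ids),
              length(x$eigenvalues)))
  invisible(x)
}
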