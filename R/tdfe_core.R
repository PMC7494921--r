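# The three-way tensor x_ijk = a_ij * b_kj is never materialized: its sum
# over samples j is exactly a %*% t(b), so memory stays at N*K.

#' Collapse the implicit paired-layer tensor over samples
#'
#' Computes the feature-by-feature matrix
#' \eqn{x_{ik} = \sum_j a_{ij} b_{kj}} — the sample sum of the implicit
#' rank-structured tensor \eqn{x_{ijk} = a_{ij} b_{kj}} — as a single
#' matrix product. Both layers must already be aligned on identical ordered
#' samples (see [align_layers()]).
#'
#' @param a layer A expression matrix (N features x M samples).
#' @param b layer B expression matrix (K features x M samples).
#' @return N x K numeric matrix with layer-A feature IDs as rownames and
#'   layer-B feature IDs as colnames.
#' @export
collapse_over_samples <- function(a, b) {
  if (ncol(a) != ncol(b) || !identical(colnames(a), colnames(b)))
    stop("layers are not aligned on identical ordered samples; ",
         "run align_layers() first")
  x <- a %*% t(b)
  dimnames(x) <- list(rownames(a), rownames(b))
  x
}

# orient each component so its largest-magnitude layer-A entry is positive
component_sign <- function(u) {
  vapply(seq_len(ncol(u)), function(l) {
    i <- which.max(abs(u[, l]))
    if (u[i, l] < 0) -1 else 1
  }, numeric(1L))
}

#' Factorize the sample-collapsed matrix
#'
#' Dense SVD of the collapsed matrix, truncated to the top `L` components:
#' \eqn{x_{ik} = \sum_l \lambda_l u^{rows}_{li} u^{cols}_{lk}}. Singular
#' vectors carry a deterministic sign convention (largest-magnitude
#' layer-A entry positive), so repeated runs are bit-identical. Sample
#' projections are filled in later by [project_samples()].
#'
#' @param x collapsed matrix from [collapse_over_samples()].
#' @param L number of components, `1 <= L <= min(N, K)`; defaults to
#'   `min(10, min(N, K))` since only low components are ever inspected.
#' @return object of class `td_factorization` with elements `lambdas`
#'   (non-increasing, non-negative), `u_rows` (N x L, orthonormal columns),
#'   `u_cols` (K x L, orthonormal columns), and `proj_rows`/`proj_cols`/
#'   `sample_ids` (`NULL` until projected).
#' @export
td_factorize <- function(x, L = min(10L, min(dim(x)))) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L || L > min(dim(x)))
    stop("L must be an integer in 1..min(N, K)")
  sv <- svd(x, nu = L, nv = L)
  u <- sv$u
  v <- sv$v
  s <- component_sign(u)
  u <- u * rep(s, each = nrow(u))
  v <- v * rep(s, each = nrow(v))
  dimnames(u) <- list(rownames(x), paste0("l", seq_len(L)))
  dimnames(v) <- list(colnames(x), paste0("l", seq_len(L)))
  structure(list(lambdas = sv$d[seq_len(L)],
                 u_rows = u, u_cols = v,
                 proj_rows = NULL, proj_cols = NULL, sample_ids = NULL),
            class = "td_factorization")
}

#' Project samples onto the factor components
#'
#' Completes a factorization with the per-layer sample projections
#' \eqn{u^{A}_{lj} = \sum_i a_{ij} u^{rows}_{li}} and
#' \eqn{u^{B}_{lj} = \sum_k b_{kj} u^{cols}_{lk}} — the sample-mode
#' coordinates of each component seen through each layer.
#'
#' @param a,b the aligned layers the factorization came from.
#' @param f a `td_factorization`.
#' @return `f` with `proj_rows` and `proj_cols` (both M x L) and
#'   `sample_ids` filled in.
#' @export
project_samples <- function(a, b, f) {
  if (!inherits(f, "td_factorization")) stop("f must be a td_factorization")
  if (!identical(rownames(a), rownames(f$u_rows)))
    stop("layer A features do not match the factorization")
  if (!identical(rownames(b), rownames(f$u_cols)))
    stop("layer B features do not match the factorization")
  if (!identical(colnames(a), colnames(b)))
    stop("layers are not aligned on identical ordered samples")
  f$proj_rows <- crossprod(a, f$u_rows)
  f$proj_cols <- crossprod(b, f$u_cols)
  rownames(f$proj_rows) <- rownames(f$proj_cols) <- colnames(a)
  f$sample_ids <- colnames(a)
  f
}

#' @export
print.td_factorization <- function(x, ...) {
  cat(sprintf("td_factorization: %d x %d features, %d components\n",
              nrow(x$u_rows), nrow(x$u_cols), length(x$lambdas)))
  cat("  lambdas:", paste(signif(utils::head(x$lambdas, 5L), 4L),
                          collapse = ", "),
      if (length(x$lambdas) > 5L) "..." else "", "\n")
  cat(if (is.null(x$proj_rows)) "  sample projections: not yet computed\n"
      else sprintf("  sample projections: %d samples\n", nrow(x$proj_rows)))
  invisible(x)
}
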