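welch_p <- function(x, cls) {
  t.test(x[cls == "case"], x[cls == "control"])$p.value
}

#' Per-component class-separation and cross-layer diagnostics
#'
#' For every component l, compares the case vs control sample projections
#' of each layer with a two-sided Welch (unequal-variance) t-test, and
#' correlates the two layers' projections with Pearson's r. P-values and
#' |r| are invariant to the arbitrary sign of singular vectors; the sign of
#' r is reported as computed under the package's orientation convention.
#'
#' @param f a projected `td_factorization` (see [project_samples()]).
#' @param annotation factor with levels `control`/`case` named by sample
#'   ID; every sample in `f` must be annotated, with >= 2 per class.
#' @return data frame with one row per component: `l`, `t_p_rows`,
#'   `t_p_cols`, `pcc`, `pcc_p`.
#' @export
diagnose_components <- function(f, annotation) {
  if (!inherits(f, "td_factorization") || is.null(f$proj_rows))
    stop("f must be a td_factorization with sample projections")
  cls <- sample_classes(annotation, f$sample_ids)
  L <- ncol(f$proj_rows)
  out <- lapply(seq_len(L), function(l) {
    ct <- cor.test(f$proj_rows[, l], f$proj_cols[, l])
    data.frame(l = l,
               t_p_rows = welch_p(f$proj_rows[, l], cls),
               t_p_cols = welch_p(f$proj_cols[, l], cls),
               pcc = unname(ct$estimate),
               pcc_p = ct$p.value)
  })
  do.call(rbind, out)
}

#' Choose the component used for feature selection
#'
#' In `auto` mode, picks the component minimizing the worse of the two
#' layers' class-separation P-values, `max(t_p_rows, t_p_cols)`; ties go to
#' the smaller component index. In `manual` mode the stated component is
#' used after a range check (e.g. fix l = 2 after visual inspection of the
#' diagnostics).
#'
#' @param d diagnostics from [diagnose_components()].
#' @param strategy `"auto"` or `"manual"`.
#' @param manual_l component index when `strategy = "manual"`.
#' @return integer component index.
#' @export
choose_component <- function(d, strategy = c("auto", "manual"), manual_l = NULL) {
  strategy <- match.arg(strategy)
  if (!is.data.frame(d) || !nrow(d)) stop("empty component diagnostics")
  if (strategy == "manual") {
    l <- as.integer(manual_l)
    if (is.na(l) || !l %in% d$l)
      stop("manual_l out of range: ", manual_l)
    return(l)
  }
  d$l[which.min(pmax(d$t_p_rows, d$t_p_cols))]
}

#' Chi-squared feature P-values from a singular-vector component
#'
#' Standardizes the component vector by its own standard deviation and
#' refers each squared standardized entry \eqn{(u_i/\sigma)^2} to the upper
#' tail of a chi-squared distribution with 1 degree of freedom (the square
#' of a standardized Gaussian). Features far out in the component get small
#' P-values.
#'
#' @param u numeric component vector over features (>= 2 distinct values).
#' @param sd_mode denominator for sigma: `"sample"` (n-1, default) or
#'   `"population"` (n).
#' @return vector of raw upper-tail P-values, named like `u`.
#' @export
chi2_pvalues <- function(u, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  if (length(u) < 2L) stop("component vector needs at least 2 entries")
  if (any(!is.finite(u))) stop("component vector has non-finite entries")
  sigma <- if (sd_mode == "sample") sd(u) else sqrt(mean((u - mean(u))^2))
  if (sigma == 0) stop("degenerate component: zero standard deviation")
  pchisq((u / sigma)^2, df = 1L, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Step-up FDR adjustment (sort ascending, scale by m/rank, enforce
#' monotonicity from the largest rank, cap at 1), returned in the original
#' order. Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p vector of raw P-values, all in \[0, 1\].
#' @return vector of adjusted P-values.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("P-values must all lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Apply the selection threshold to a score table
#'
#' @param scores a feature score table with a `p_adj` column.
#' @param alpha FDR threshold in (0, 1\]; features with adjusted P strictly
#'   below `alpha` are selected (default 0.01).
#' @return `scores` with the `selected` flag set.
#' @export
select_features <- function(scores, alpha = 0.01) {
  if (!is.data.frame(scores) || is.null(scores$p_adj))
    stop("scores must be a feature score table with a p_adj column")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  scores$selected <- !is.na(scores$p_adj) & scores$p_adj < alpha
  scores
}

#' Score features on one component
#'
#' Runs the chi-squared / Benjamini-Hochberg selection chain on a single
#' singular-vector (or PC-score) component and returns the full per-feature
#' table. Selection is invariant to a global sign flip of `u`.
#'
#' @param u named component vector over features.
#' @param component integer index of the component scored (recorded in the
#'   table).
#' @param layer layer tag recorded in the table.
#' @inheritParams chi2_pvalues
#' @inheritParams select_features
#' @return data frame with columns `id`, `layer`, `component`, `u`, `chi2`,
#'   `p_raw`, `p_adj`, `selected`.
#' @export
score_features <- function(u, component = NA_integer_, layer = "layer",
                           alpha = 0.01, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  p <- chi2_pvalues(u, sd_mode = sd_mode)
  sigma <- if (sd_mode == "sample") sd(u) else sqrt(mean((u - mean(u))^2))
  tab <- data.frame(id = if (is.null(names(u))) as.character(seq_along(u))
                         else names(u),
                    layer = layer,
                    component = as.integer(component),
                    u = as.numeric(u),
                    chi2 = (as.numeric(u) / sigma)^2,
                    p_raw = as.numeric(p),
                    p_adj = bh_adjust(as.numeric(p)),
                    row.names = NULL)
  select_features(tab, alpha = alpha)
}
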