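# Paired two-layer generator with planted class-driven signal features.
# Model per layer: x_ij = mu_i + delta * s_i * c_j + eps_ij with
# c_j = +1 (case) / -1 (control), feature baseline mu_i ~ N(mu0,
# baseline_sd^2), random per-feature sign s_i, Gaussian noise. With mu0
# well above 0 the leading component of any factorization captures the
# baseline profile and the class contrast lands on a later (typically the
# second) component.

#' Configuration for the synthetic paired-omics generator
#'
#' Defaults are the package's reference study conditions: 2000 + 300
#' features, 30 case + 30 control samples, 50 + 20 planted signal
#' features, effect `delta = 2` on noise `sd = 1`, feature baselines
#' `N(5, 1)`. An unbalanced tumor-heavy cohort can be emulated by setting
#' e.g. `n_case = 253, n_control = 71`.
#'
#' @param n_features_a,n_features_b features per layer (N, K).
#' @param n_case,n_control samples per class.
#' @param n_signal_a,n_signal_b planted signal features per layer.
#' @param effect class effect size delta (> 0, or 0 for a null dataset).
#' @param noise_sd noise standard deviation (> 0).
#' @param baseline_mean,baseline_sd distribution of per-feature baselines.
#' @param distribution `"gaussian"` (default) or `"lognormal"`
#'   (exponentiates the Gaussian field for strictly positive,
#'   right-skewed values).
#' @param seed RNG seed; the dataset is fully reproducible from it.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_features_a = 2000L, n_features_b = 300L,
                             n_case = 30L, n_control = 30L,
                             n_signal_a = 50L, n_signal_b = 20L,
                             effect = 2, noise_sd = 1,
                             baseline_mean = 5, baseline_sd = 1,
                             distribution = c("gaussian", "lognormal"),
                             seed = 20200916L) {
  cfg <- list(n_features_a = as.integer(n_features_a),
              n_features_b = as.integer(n_features_b),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_signal_a = as.integer(n_signal_a),
              n_signal_b = as.integer(n_signal_b),
              effect = as.numeric(effect), noise_sd = as.numeric(noise_sd),
              baseline_mean = as.numeric(baseline_mean),
              baseline_sd = as.numeric(baseline_sd),
              distribution = match.arg(distribution),
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_features_a", "n_features_b", "n_case",
                         "n_control", "n_signal_a", "n_signal_b")])
  if (any(is.na(counts)) || any(counts < 1L))
    stop("all feature/sample/signal counts must be >= 1")
  if (cfg$n_signal_a > cfg$n_features_a || cfg$n_signal_b > cfg$n_features_b)
    stop("planted signal sets cannot exceed the layer size")
  if (!is.finite(cfg$effect) || cfg$effect < 0)
    stop("effect must be a finite non-negative number")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("noise_sd must be positive")
  if (!is.finite(cfg$baseline_sd) || cfg$baseline_sd < 0)
    stop("baseline_sd must be non-negative")
  if (is.na(cfg$seed)) stop("seed must be an integer")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic paired-omics dataset
#'
#' @param cfg a [synthetic_config()] (a plain list of the same fields is
#'   accepted).
#' @return object of class `synthetic_dataset` with `layer_a`, `layer_b`
#'   (expression matrices tagged `"mRNA"` / `"miRNA"`), `annotation`
#'   (class factor named by sample ID), `truth_a`, `truth_b` (planted
#'   feature-ID sets), and `config`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  if (!inherits(cfg, "synthetic_config")) cfg <- do.call(synthetic_config, cfg)
  set.seed(cfg$seed)
  m <- cfg$n_case + cfg$n_control
  sample_ids <- sprintf("S%03d", seq_len(m))
  classes <- factor(rep(c("case", "control"), c(cfg$n_case, cfg$n_control)),
                    levels = c("control", "case"))
  names(classes) <- sample_ids
  cscore <- ifelse(classes == "case", 1, -1)
  make_layer <- function(n_feat, n_signal, tag) {
    ids <- sprintf("%s_%05d", tag, seq_len(n_feat))
    mu <- rnorm(n_feat, cfg$baseline_mean, cfg$baseline_sd)
    signal <- sort(sample.int(n_feat, n_signal))
    s <- sample(c(-1, 1), n_signal, replace = TRUE)
    x <- mu + matrix(rnorm(n_feat * m, 0, cfg$noise_sd), n_feat, m)
    x[signal, ] <- x[signal, ] + cfg$effect * (s %o% cscore)
    if (cfg$distribution == "lognormal") x <- exp(x)
    dimnames(x) <- list(ids, sample_ids)
    list(x = expression_layer(x, tag), truth = ids[signal])
  }
  la <- make_layer(cfg$n_features_a, cfg$n_signal_a, "mRNA")
  lb <- make_layer(cfg$n_features_b, cfg$n_signal_b, "miRNA")
  structure(list(layer_a = la$x, layer_b = lb$x, annotation = classes,
                 truth_a = la$truth, truth_b = lb$truth, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d x %d (mRNA), %d x %d (miRNA), %d case / %d control\n",
              nrow(x$layer_a), ncol(x$layer_a),
              nrow(x$layer_b), ncol(x$layer_b),
              sum(x$annotation == "case"), sum(x$annotation == "control")))
  cat(sprintf("  planted signal: %d + %d features, effect %g, noise sd %g\n",
              length(x$truth_a), length(x$truth_b),
              x$config$effect, x$config$noise_sd))
  invisible(x)
}

#' Precision, recall and F1 of a selection against planted truth
#'
#' Empty selection with empty truth counts as perfect; empty selection
#' against non-empty truth yields precision 0 (flagged with attribute
#' `precision_undefined`).
#'
#' @param selected,truth character vectors of feature IDs.
#' @return list with `precision`, `recall`, `f1`.
#' @export
recovery_metrics <- function(selected, truth) {
  selected <- unique(as.character(selected))
  truth <- unique(as.character(truth))
  hit <- length(intersect(selected, truth))
  if (!length(selected) && !length(truth))
    return(list(precision = 1, recall = 1, f1 = 1))
  precision <- if (length(selected)) hit / length(selected) else 0
  recall <- if (length(truth)) hit / length(truth) else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  out <- list(precision = precision, recall = recall, f1 = f1)
  if (!length(selected) && length(truth))
    attr(out, "precision_undefined") <- TRUE
  out
}
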