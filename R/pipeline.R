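# Orchestration: in-memory pipelines for the three methods plus a
# file-level runner used by the exec/tdfe command-line script.

#' Run tensor feature extraction end to end (in memory)
#'
#' Preprocess both layers, align them, collapse the implicit tensor over
#' samples, factorize, project, diagnose components against the class
#' annotation, choose the working component, and score both layers'
#' features on it.
#'
#' @param a,b expression matrices (features x samples) sharing samples.
#' @param annotation class factor named by sample ID.
#' @param L number of components to extract.
#' @param alpha FDR threshold for selection.
#' @param component `"auto"` or an integer component index.
#' @inheritParams chi2_pvalues
#' @inheritParams preprocess_matrix
#' @return list with `factorization`, `diagnostics`, `component`,
#'   `scores_a`, `scores_b`.
#' @export
run_tdfe <- function(a, b, annotation, L = 10L, alpha = 0.01,
                     component = "auto", sd_mode = c("sample", "population"),
                     log2_offset = NULL, standardize = TRUE) {
  sd_mode <- match.arg(sd_mode)
  pa <- preprocess_matrix(a, log2_offset = log2_offset, standardize = standardize)
  pb <- preprocess_matrix(b, log2_offset = log2_offset, standardize = standardize)
  al <- align_layers(pa, pb)
  x <- collapse_over_samples(al$a, al$b)
  f <- td_factorize(x, L = min(L, min(dim(x))))
  f <- project_samples(al$a, al$b, f)
  d <- diagnose_components(f, annotation)
  l <- if (identical(component, "auto")) choose_component(d, "auto")
       else choose_component(d, "manual", manual_l = component)
  list(factorization = f,
       diagnostics = d,
       component = l,
       scores_a = score_features(f$u_rows[, l], component = l,
                                 layer = layer_name(al$a, "mRNA"),
                                 alpha = alpha, sd_mode = sd_mode),
       scores_b = score_features(f$u_cols[, l], component = l,
                                 layer = layer_name(al$b, "miRNA"),
                                 alpha = alpha, sd_mode = sd_mode))
}

#' Run PCA feature extraction on one layer (in memory)
#'
#' @inheritParams run_tdfe
#' @param x expression matrix for the layer.
#' @param manual_l integer component when `component` is not `"auto"`.
#' @return list with `factorization`, `diagnostics`, `component`, `scores`.
#' @export
run_pca_fe <- function(x, annotation, L = 10L, alpha = 0.01,
                       component = "auto",
                       sd_mode = c("sample", "population"),
                       log2_offset = NULL, standardize = TRUE) {
  sd_mode <- match.arg(sd_mode)
  px <- preprocess_matrix(x, log2_offset = log2_offset, standardize = standardize)
  f <- pca_fit(px, L = min(L, min(dim(px))))
  sel <- if (identical(component, "auto"))
    pca_select(f, annotation, alpha = alpha, sd_mode = sd_mode)
  else
    pca_select(f, annotation, alpha = alpha, sd_mode = sd_mode,
               strategy = "manual", manual_l = component)
  list(factorization = f, diagnostics = sel$diagnostics,
       component = sel$component, scores = sel$scores)
}

#' Write a synthetic dataset to a directory as TSV
#'
#' Emits `mRNA.tsv`, `miRNA.tsv`, `labels.tsv` (sample_id, class with
#' tumor/normal labels), `truth_mRNA.tsv` and `truth_miRNA.tsv`.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  if (!inherits(ds, "synthetic_dataset")) stop("ds must be a synthetic_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_results(ds$layer_a, file.path(dir, "mRNA.tsv"))
  write_results(ds$layer_b, file.path(dir, "miRNA.tsv"))
  ann <- data.frame(sample_id = names(ds$annotation),
                    class = ifelse(ds$annotation == "case", "tumor", "normal"))
  write_results(ann, file.path(dir, "labels.tsv"))
  write_results(data.frame(id = ds$truth_a), file.path(dir, "truth_mRNA.tsv"))
  write_results(data.frame(id = ds$truth_b), file.path(dir, "truth_miRNA.tsv"))
  invisible(dir)
}

log_line <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full file-level pipeline
#'
#' Reads the two layer matrices and the annotation, runs the requested
#' method (`td`, `pca`, or the supervised `ttest` baseline), and writes
#' score tables, component diagnostics and a machine-readable
#' `summary.json` into `out_dir`. Outputs are deterministic: identical
#' configuration yields byte-identical files. Result files are written
#' atomically and only after all stages have succeeded.
#'
#' @param mrna,mirna paths to layer TSV files ([read_matrix_tsv()]; GEO
#'   series-matrix files are detected by their table delimiters).
#' @param labels path to the annotation TSV ([read_annotation_tsv()]).
#' @param out_dir output directory (created if needed).
#' @param method `"td"`, `"pca"` or `"ttest"`.
#' @inheritParams run_tdfe
#' @param case,control annotation labels mapped to case/control.
#' @return invisible list of the in-memory results per layer/method.
#' @export
run_pipeline <- function(mrna, mirna, labels, out_dir,
                         method = c("td", "pca", "ttest"),
                         L = 10L, alpha = 0.01, component = "auto",
                         sd_mode = "sample", log2_offset = NULL,
                         standardize = TRUE,
                         case = "tumor", control = "normal") {
  method <- match.arg(method)
  stage <- "read inputs"
  res <- tryCatch({
    a <- read_any_matrix(mrna, "mRNA")
    b <- read_any_matrix(mirna, "miRNA")
    ann <- read_annotation_tsv(labels, case = case, control = control)
    out <- list(method = method, alpha = alpha)
    if (method == "td") {
      stage <- "tensor feature extraction"
      r <- run_tdfe(a, b, ann, L = L, alpha = alpha, component = component,
                    sd_mode = sd_mode, log2_offset = log2_offset,
                    standardize = standardize)
      out$files <- list(scores_mRNA = r$scores_a, scores_miRNA = r$scores_b,
                        diagnostics = r$diagnostics)
      out$component <- r$component
      out$result <- r
    } else if (method == "pca") {
      stage <- "PCA feature extraction"
      ra <- run_pca_fe(a, ann, L = L, alpha = alpha, component = component,
                       sd_mode = sd_mode, log2_offset = log2_offset,
                       standardize = standardize)
      rb <- run_pca_fe(b, ann, L = L, alpha = alpha, component = component,
                       sd_mode = sd_mode, log2_offset = log2_offset,
                       standardize = standardize)
      out$files <- list(scores_mRNA = ra$scores, scores_miRNA = rb$scores,
                        diagnostics_mRNA = ra$diagnostics,
                        diagnostics_miRNA = rb$diagnostics)
      out$component <- c(mRNA = ra$component, miRNA = rb$component)
      out$result <- list(a = ra, b = rb)
    } else {
      stage <- "t-test baseline"
      pa <- preprocess_matrix(a, log2_offset = log2_offset, standardize = FALSE)
      pb <- preprocess_matrix(b, log2_offset = log2_offset, standardize = FALSE)
      out$files <- list(scores_mRNA = welch_t_baseline(pa, ann, alpha = alpha),
                        scores_miRNA = welch_t_baseline(pb, ann, alpha = alpha))
      out$result <- out$files
    }
    out
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  stage <- "write outputs"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(res$files)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    write_results(res$files[[nm]], path)
    log_line("wrote ", path)
  }
  summary <- list(method = res$method, alpha = alpha,
                  component = res$component,
                  n_selected = lapply(res$files[grep("^scores", names(res$files))],
                                      function(t) sum(t$selected)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line("wrote ", file.path(out_dir, "summary.json"))
  invisible(res)
}

# sniff GEO series-matrix files by their delimiter line
read_any_matrix <- function(path, layer) {
  head_lines <- tryCatch(read_text_lines(path), error = function(e) stop(e))
  if (any(grepl("^!series_matrix_table_begin", head_lines)))
    read_geo_series_matrix(path, layer)
  else read_matrix_tsv(path, layer)
}
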