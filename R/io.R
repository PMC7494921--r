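# Expression layers are plain numeric matrices (features x samples) with a
# "layer" attribute. Parsing is done by hand because the error contracts
# (ragged row with line number, duplicate IDs, non-numeric cell) must be
# precise and the dialects are trivial.

#' Construct an expression layer
#'
#' Validates and tags a features-by-samples numeric matrix. Feature IDs
#' (rownames) and sample IDs (colnames) must be present and unique.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   rownames and colnames set.
#' @param layer short text tag for the omics layer (e.g. `"mRNA"`,
#'   `"miRNA"`); stored as the `"layer"` attribute.
#' @return the matrix, with the `"layer"` attribute attached.
#' @export
expression_layer <- function(values, layer = "layer") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression layer must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression layer needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  attr(values, "layer") <- as.character(layer)[1L]
  values
}

#' Layer tag of an expression matrix
#' @param x expression matrix.
#' @param default tag returned when `x` carries none.
#' @return character scalar.
#' @export
layer_name <- function(x, default = "layer") {
  l <- attr(x, "layer", exact = TRUE)
  if (is.null(l)) default else l
}

# keep the "layer" attribute through column subsetting
subset_samples <- function(x, j) {
  y <- x[, j, drop = FALSE]
  attr(y, "layer") <- attr(x, "layer", exact = TRUE)
  y
}

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")  # reads plain text transparently too
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  lines
}

strip_quotes <- function(x) gsub('^"|"$', "", x)

# tokens treated as missing -> NaN; anything else non-numeric is an error
parse_numeric_cells <- function(x, path) {
  chr <- as.character(x)
  miss <- chr %in% c("", "NA", "NaN", "null", "NULL")
  chr[miss] <- "NaN"
  v <- suppressWarnings(as.numeric(chr))
  bad <- is.na(v) & !miss
  if (any(bad))
    stop(sprintf("non-numeric cell in %s: '%s'", path, chr[which(bad)[1L]]))
  v
}

parse_matrix_lines <- function(lines, path, layer, line_offset = 0L) {
  if (length(lines) < 1L) stop("empty file: ", path)
  header <- strip_quotes(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
  if (length(header) < 2L)
    stop("header of ", path, " must contain a feature-ID column plus sample IDs")
  sample_ids <- header[-1L]
  body <- lines[-1L]
  if (!length(body)) stop("empty matrix (no data rows) in ", path)
  cells <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(cells)
  bad <- which(nf != length(header))
  if (length(bad))
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad[1L] + 1L + line_offset, nf[bad[1L]], length(header)))
  flat <- strip_quotes(unlist(cells, use.names = FALSE))
  chr <- matrix(flat, nrow = length(body), byrow = TRUE)
  feature_ids <- chr[, 1L]
  vals <- matrix(parse_numeric_cells(chr[, -1L, drop = FALSE], path),
                 nrow = length(body),
                 dimnames = list(feature_ids, sample_ids))
  expression_layer(vals, layer)
}

#' Read a features-by-samples expression matrix from TSV
#'
#' The first header field names the feature-ID column; the remaining header
#' fields are sample IDs. Every data row is a feature ID followed by one
#' numeric value per sample (dot decimal, locale-independent). `NA`, `NaN`,
#' `null` and empty cells are read as non-finite and left for
#' [filter_features()]. Gzipped files are read transparently.
#'
#' @param path path to the TSV (optionally gzipped).
#' @param layer layer tag to attach.
#' @return an [expression_layer()] matrix with rows/columns in file order.
#' @export
read_matrix_tsv <- function(path, layer = "layer") {
  parse_matrix_lines(read_text_lines(path), path = path, layer = layer)
}

#' Read the data block of a GEO series-matrix file
#'
#' Ignores all `!`-prefixed metadata lines and parses only the block
#' delimited by `!series_matrix_table_begin` / `!series_matrix_table_end`
#' (probe IDs in the first column, GSM accessions as column headers).
#' Gzipped files are read transparently.
#'
#' @inheritParams read_matrix_tsv
#' @return an [expression_layer()] matrix.
#' @export
read_geo_series_matrix <- function(path, layer = "layer") {
  lines <- read_text_lines(path)
  b <- grep("^!series_matrix_table_begin", lines)
  e <- grep("^!series_matrix_table_end", lines)
  if (length(b) != 1L || length(e) != 1L || e <= b)
    stop("not a GEO series matrix (missing table delimiters): ", path)
  if (e - b < 3L) stop("empty data block in ", path)
  block <- lines[seq.int(b + 1L, e - 1L)]
  parse_matrix_lines(block, path = path, layer = layer, line_offset = b)
}

#' Read a sample annotation table
#'
#' Expects a header line and two tab-separated columns: sample ID and class
#' label. Labels equal to `case` are mapped to the `case` level and labels
#' equal to `control` to the `control` level.
#'
#' @param path path to the TSV.
#' @param case,control the labels in the file denoting case (tumor) and
#'   control (normal) samples.
#' @return factor with levels `c("control", "case")`, named by sample ID.
#' @export
read_annotation_tsv <- function(path, case = "tumor", control = "normal") {
  lines <- read_text_lines(path)
  if (length(lines) < 2L) stop("empty annotation file: ", path)
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(lengths(cells) < 2L))
    stop("annotation rows in ", path, " need sample ID and class label")
  ids <- strip_quotes(vapply(cells, `[[`, "", 1L))
  lab <- strip_quotes(vapply(cells, `[[`, "", 2L))
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  unknown <- setdiff(unique(lab), c(case, control))
  if (length(unknown))
    stop("unknown class labels in ", path, ": ", paste(unknown, collapse = ", "))
  cls <- factor(ifelse(lab == case, "case", "control"),
                levels = c("control", "case"))
  names(cls) <- ids
  cls
}

# validate an annotation against an ordered sample-ID vector and return the
# class factor in that order
sample_classes <- function(annotation, sample_ids, min_per_class = 2L) {
  if (is.null(names(annotation)))
    stop("annotation must be named by sample ID")
  missing <- setdiff(sample_ids, names(annotation))
  if (length(missing))
    stop("samples without annotation: ", paste(missing, collapse = ", "))
  cls <- annotation[sample_ids]
  cls <- factor(as.character(cls), levels = c("control", "case"))
  if (anyNA(cls)) stop("annotation labels must be 'control' or 'case'")
  if (any(table(cls) < min_per_class))
    stop("need at least ", min_per_class, " annotated samples per class")
  names(cls) <- sample_ids
  cls
}

#' Align two expression layers onto their shared samples
#'
#' Restricts both layers to the intersection of their sample IDs, ordered
#' lexicographically (deterministic across runs), and reports how many
#' samples each layer dropped.
#'
#' @param a,b expression matrices.
#' @return list with elements `a` and `b`, columns in identical order.
#' @export
align_layers <- function(a, b) {
  shared <- sort(intersect(colnames(a), colnames(b)))
  if (!length(shared)) stop("no shared samples between layers")
  message(sprintf("align_layers: %d shared samples (dropped %d from %s, %d from %s)",
                  length(shared),
                  ncol(a) - length(shared), layer_name(a, "layer A"),
                  ncol(b) - length(shared), layer_name(b, "layer B")))
  list(a = subset_samples(a, shared), b = subset_samples(b, shared))
}

# full precision round-trippable formatting; R's sprintf renders NA/NaN as is
fmt_num <- function(x) sprintf("%.17g", x)

write_lines_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  ok <- tryCatch({ writeLines(lines, tmp); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  if (!file.rename(tmp, path)) stop("cannot write results to ", path)
  invisible(path)
}

write_matrix_tsv <- function(x, path, id_col = "id") {
  body <- character(0)
  if (nrow(x)) {
    chr <- matrix(fmt_num(x), nrow = nrow(x))
    body <- paste(rownames(x), apply(chr, 1L, paste, collapse = "\t"),
                  sep = "\t")
    if (ncol(x) == 0L) body <- rownames(x)
  }
  write_lines_atomic(c(paste(c(id_col, colnames(x)), collapse = "\t"), body),
                     path)
}

write_table_tsv <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmt_num(col) else as.character(col)
  })
  body <- if (nrow(df)) do.call(paste, c(cols, sep = "\t")) else character(0)
  write_lines_atomic(c(paste(names(df), collapse = "\t"), body), path)
}

write_confusion_tsv <- function(ct, path) {
  lines <- c(paste("", "not selected", "selected", sep = "\t"),
             paste("not selected", ct$a, ct$b, sep = "\t"),
             paste("selected", ct$c, ct$d, sep = "\t"))
  write_lines_atomic(lines, path)
}

#' Write a result object as TSV
#'
#' Score tables and diagnostics (data frames) are written with one header
#' line, stable column order and full-precision `%.17g` numbers, so that
#' P-values survive in scientific notation and numeric matrices round-trip
#' bit-identically through [read_matrix_tsv()]. Confusion tables are written
#' as a labelled 2x2 grid. Writes are atomic (temp file + rename).
#'
#' @param x a data frame, numeric matrix, or [confusion_table()].
#' @param path output file path (directory must exist).
#' @return the path, invisibly.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "confusion_table")) write_confusion_tsv(x, path)
  else if (is.matrix(x)) write_matrix_tsv(x, path)
  else if (is.data.frame(x)) write_table_tsv(x, path)
  else stop("unsupported result type: ", paste(class(x), collapse = "/"))
  invisible(path)
}
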