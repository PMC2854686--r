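#' Expression matrix with mRNA/miRNA row labels
#'
#' A light container for a genes-by-samples matrix of log-scale expression
#' values. Row identifiers are genes or microRNAs (`row_kind` distinguishes
#' them), column identifiers are samples/conditions. mRNAs and miRNAs live in
#' the same matrix even though they are typically measured on different
#' absolute scales: all downstream regulator scoring works on standardized
#' profiles, so the scale never enters the analysis.
#'
#' @param values numeric matrix with unique row and column names.
#' @param row_kind character vector, one of `"mrna"`/`"mirna"` per row
#'   (default all `"mrna"`).
#' @return An `expr_matrix`: the numeric matrix with a `row_kind` attribute.
#' @examples
#' m <- expr_matrix(matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("g1", "mir1"), c("s1", "s2", "s3"))),
#'   row_kind = c("mrna", "mirna"))
#' row_kind(m)
#' @export
expr_matrix <- function(values, row_kind = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row and column names")
  dup_r <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_r))
    stop("duplicate row identifiers: ", paste(dup_r, collapse = ", "))
  dup_c <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_c))
    stop("duplicate column identifiers: ", paste(dup_c, collapse = ", "))
  if (anyNA(values)) stop("expression values contain missing entries")
  row_kind <- row_kind %||% rep("mrna", nrow(values))
  if (length(row_kind) != nrow(values))
    stop("`row_kind` must have one entry per row")
  if (!all(row_kind %in% c("mrna", "mirna")))
    stop("`row_kind` entries must be 'mrna' or 'mirna'")
  structure(values, row_kind = as.character(row_kind),
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  kind <- table(row_kind(x))
  cat(sprintf("<expr_matrix> %d rows (%s) x %d samples\n", nrow(x),
              paste(sprintf("%d %s", kind, names(kind)), collapse = ", "),
              ncol(x)))
  print(head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE], 4))
  invisible(x)
}

#' @rdname expr_matrix
#' @param m an `expr_matrix`.
#' @export
row_kind <- function(m) {
  stats::setNames(attr(m, "row_kind") %||% rep("mrna", nrow(m)), rownames(m))
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  kind <- row_kind(x)
  out <- unclass(x)[i, j, drop = drop]
  if (!is.matrix(out)) return(out)
  expr_matrix(out, row_kind = unname(kind[rownames(out)]))
}

#' Build an expression matrix from a tidy data frame
#'
#' Data-frame-first constructor: one row per gene/miRNA, an `id` column,
#' an optional `kind` column, and one numeric column per sample.
#'
#' @param df a data frame or tibble.
#' @param id_col,kind_col column names holding identifiers and row kinds.
#' @return An [expr_matrix()].
#' @export
as_expr_matrix <- function(df, id_col = "id", kind_col = "kind") {
  df <- as.data.frame(df)
  if (!id_col %in% names(df)) stop("no `", id_col, "` column")
  kind <- if (kind_col %in% names(df)) as.character(df[[kind_col]]) else NULL
  val_cols <- setdiff(names(df), c(id_col, kind_col))
  vals <- as.matrix(df[val_cols])
  if (!is.numeric(vals)) stop("sample columns must be numeric")
  rownames(vals) <- as.character(df[[id_col]])
  expr_matrix(vals, row_kind = kind)
}

#' @describeIn as_expr_matrix Long/tidy view: one row per (gene, sample).
#' @param m an `expr_matrix`.
#' @export
expr_tidy <- function(m) {
  tibble::as_tibble(unclass(m), rownames = "id") |>
    dplyr::mutate(kind = unname(row_kind(m))) |>
    tidyr::pivot_longer(cols = -c("id", "kind"),
                        names_to = "sample", values_to = "value")
}

#' Read an expression matrix from TSV
#'
#' Expected dialect: tab-separated, UTF-8, one header line whose first field
#' is `id`, optionally followed by a `kind` field (`mrna`/`mirna`), then the
#' sample identifiers. Each following line carries the row identifier (and
#' kind) plus one numeric value per sample; scientific notation is accepted.
#'
#' @param path file path.
#' @param strict if `TRUE`, any non-numeric or missing cell is an error; if
#'   `FALSE` (default) such rows are dropped and reported.
#' @return An [expr_matrix()]; attribute `dropped_rows` lists rejected row
#'   identifiers when `strict = FALSE`.
#' @export
read_expression_tsv <- function(path, strict = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("expression TSV needs a header and >= 1 row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1]]
  has_kind <- length(hdr) >= 2 && identical(hdr[2], "kind")
  n_meta <- if (has_kind) 2L else 1L
  samples <- hdr[-seq_len(n_meta)]
  if (!length(samples)) stop("no sample columns in header")
  n_exp <- n_meta + length(samples)

  body <- fields[-1]
  ragged <- which(vapply(body, length, 1L) != n_exp)
  if (length(ragged))
    stop("ragged row at line ", ragged[1] + 1L, ": expected ", n_exp,
         " fields, found ", length(body[[ragged[1]]]))

  ids <- vapply(body, `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate row identifiers: ", paste(dup, collapse = ", "))
  kind <- if (has_kind) vapply(body, `[[`, "", 2L) else rep("mrna", length(ids))

  vals <- matrix(NA_real_, length(ids), length(samples),
                 dimnames = list(ids, samples))
  for (i in seq_along(body))
    vals[i, ] <- suppressWarnings(as.numeric(body[[i]][-seq_len(n_meta)]))
  bad <- rownames(vals)[apply(vals, 1L, anyNA)]
  if (length(bad) && strict)
    stop("non-numeric/missing values in rows: ", paste(bad, collapse = ", "))
  if (length(bad)) {
    message("dropped ", length(bad), " row(s) with non-numeric values: ",
            paste(bad, collapse = ", "))
    keep <- !(rownames(vals) %in% bad)
    vals <- vals[keep, , drop = FALSE]
    kind <- kind[keep]
  }
  if (!nrow(vals)) stop("no usable rows after filtering")
  out <- expr_matrix(vals, row_kind = kind)
  attr(out, "dropped_rows") <- bad
  out
}

#' @rdname read_expression_tsv
#' @param m an `expr_matrix` to write.
#' @export
write_expression_tsv <- function(m, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("id", "kind", colnames(m)), collapse = "\t"), con)
  kind <- unname(row_kind(m))
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], kind[i],
                       formatC(unclass(m)[i, ], format = "g", digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a candidate-regulator list
#'
#' One identifier per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @return Character vector of identifiers.
#' @export
read_regulator_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Read gene sets in GMT format
#'
#' Standard GMT: `name<TAB>description<TAB>member1<TAB>member2...` per line.
#'
#' @param path file path.
#' @param universe optional character vector of the gene universe; defaults
#'   to the union of all set members.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets, universe)
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  universe <- universe %||% unique(unlist(sets))
  bad <- names(sets)[!vapply(sets, function(s) all(s %in% universe), TRUE)]
  if (length(bad))
    stop("sets outside the universe: ", paste(bad, collapse = ", "))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Filter matrix rows by keep-list and variability
#'
#' Generalizes dataset-specific row filtering (e.g. dropping probesets with
#' no usable annotation) to a user-supplied keep-list, plus removal of rows
#' whose across-sample standard deviation falls below `min_sd`.
#'
#' @param m an [expr_matrix()].
#' @param keep_ids optional character vector; rows outside it are dropped.
#' @param min_sd minimum (sample) standard deviation to retain a row.
#' @return The filtered `expr_matrix`; errors if nothing survives.
#' @export
filter_rows <- function(m, keep_ids = NULL, min_sd = 0) {
  stopifnot(min_sd >= 0)
  keep <- rep(TRUE, nrow(m))
  if (!is.null(keep_ids)) keep <- keep & rownames(m) %in% keep_ids
  sds <- apply(unclass(m), 1L, sd)
  keep <- keep & sds >= min_sd
  if (!any(keep)) stop("filter_rows removed every row")
  m[which(keep), , drop = FALSE]
}

#' Standardize one expression profile
#'
#' Centers and scales to mean 0, population (1/n) standard deviation 1.
#' The result is quantized to 9 decimal places so that any positive affine
#' transform of the input (`a * x + b`, `a > 0`) maps to the *identical*
#' standardized vector — the property that makes regulator scores comparable
#' between mRNAs and miRNAs measured on different absolute scales. Constant
#' profiles map to the all-zero vector with attribute `constant = TRUE`
#' rather than erroring, so degenerate regulators simply score as
#' uninformative.
#'
#' @param x numeric vector, length >= 2.
#' @param digits decimal places of the quantization grid (default 9).
#' @return Standardized numeric vector with attribute `constant`.
#' @examples
#' standardize_row(c(1, 2, 3))
#' @export
standardize_row <- function(x, digits = 9) {
  if (length(x) < 2) stop("need at least 2 values to standardize")
  if (anyNA(x)) stop("missing values in profile")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) {
    return(structure(rep(0, length(x)), constant = TRUE, names = names(x)))
  }
  structure(round((x - m) / s, digits), constant = FALSE, names = names(x))
}
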