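#' Samples-by-taxa abundance table
#'
#' The central container of the pipeline: a non-negative numeric matrix with
#' samples in rows and taxa in columns, carrying a `mode` that records whether
#' values are read counts or relative abundances. In `"relative"` mode every
#' row must sum to 1 within `1e-6`; a row summing to 0 is rejected in either
#' mode interpretation of relative data. Values are never renormalized
#' silently — [renormalize()] is the explicit operation.
#'
#' @param values Numeric matrix (samples x taxa) with unique row and column
#'   names, all values `>= 0`.
#' @param mode `"counts"` or `"relative"`.
#' @return An object of class `"abund_table"`: the validated matrix with a
#'   `mode` attribute.
#' @examples
#' m <- matrix(c(5, 3, 2, 0, 1, 9), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' abundance_table(m, "counts")
#' @export
abundance_table <- function(values, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance table needs sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated taxon ids: ", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(values)[neg[1L, 1L]], colnames(values)[neg[1L, 2L]]))
  if (mode == "relative") {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > 1e-6)
    if (length(bad) > 0L)
      stop(sprintf("relative abundance rows must sum to 1 (tolerance 1e-6); offending sample(s): %s (sums: %s)",
                   paste(rownames(values)[bad], collapse = ", "),
                   paste(signif(rs[bad], 6), collapse = ", ")))
  }
  structure(values, mode = mode, class = c("abund_table", "matrix", "array"))
}

#' @export
print.abund_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d samples x %d taxa (%s mode)\n",
              nrow(x), ncol(x), table_mode(x)))
  nshow <- min(5L, nrow(x)); kshow <- min(6L, ncol(x))
  print(unclass(x)[seq_len(nshow), seq_len(kshow), drop = FALSE])
  if (nrow(x) > nshow || ncol(x) > kshow) cat("...\n")
  invisible(x)
}

#' Mode of an abundance table
#' @param table An [abundance_table()].
#' @return `"counts"` or `"relative"`.
#' @export
table_mode <- function(table) attr(table, "mode")

#' Renormalize an abundance table to relative abundances
#'
#' @param table An [abundance_table()]; rows must have positive totals.
#' @return An `abund_table` in relative mode with unit row sums.
#' @export
renormalize <- function(table) {
  stopifnot(inherits(table, "abund_table"))
  rs <- rowSums(table)
  if (any(rs <= 0))
    stop("cannot renormalize sample(s) with zero total: ",
         paste(rownames(table)[rs <= 0], collapse = ", "))
  abundance_table(sweep(unclass(table), 1L, rs, "/"), "relative")
}

#' Read an abundance table from TSV/CSV (or XLSX)
#'
#' Reads a delimited table with a header row of taxon names and a first column
#' of sample identifiers (samples-in-rows, the canonical orientation), or the
#' transpose. Orientation is auto-detected for relative tables from the
#' unit-row-sum signature; for counts the canonical orientation is assumed
#' unless overridden. `.xlsx` files are read through the readxl package when
#' it is installed (`sheet` selects the worksheet).
#'
#' @param path Path to a `.tsv`/`.csv`/`.txt` (tab- or comma-delimited,
#'   inferred from the extension) or `.xlsx` file.
#' @param mode `"counts"` or `"relative"`.
#' @param orientation `"auto"` (default), `"samples_rows"`, or
#'   `"samples_cols"`.
#' @param sheet Worksheet name or index for `.xlsx` input.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, mode = c("counts", "relative"),
                                 orientation = c("auto", "samples_rows", "samples_cols"),
                                 sheet = 1L) {
  mode <- match.arg(mode)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the 'readxl' package")
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                            stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  }
  if (ncol(df) < 2L) stop("table must have an id column plus at least one data column")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in abundance table: ", path)
  rownames(m) <- ids
  if (orientation == "samples_cols") {
    m <- t(m)
  } else if (orientation == "auto" && mode == "relative") {
    row_ok <- all(abs(rowSums(m) - 1) <= 1e-6)
    col_ok <- all(abs(colSums(m) - 1) <= 1e-6)
    if (!row_ok && col_ok) m <- t(m)
  }
  abundance_table(m, mode)
}

#' Write an abundance table as TSV
#'
#' Canonical orientation (samples in rows), full double precision, so a
#' write/read round trip reproduces the table.
#'
#' @param table An [abundance_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abund_table"))
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse an OTU-level table to genus level
#'
#' Sums counts (or relative abundances) of all OTUs assigned to the same
#' genus. OTUs absent from `taxonomy` are pooled into an `"unclassified"`
#' column with a warning. Per-sample totals are conserved exactly in counts
#' mode; relative tables remain valid (row sums unchanged).
#'
#' @param table An [abundance_table()].
#' @param taxonomy Named character vector mapping OTU id to genus name.
#' @return An [abundance_table()] with genus columns, ordered by decreasing
#'   overall abundance (ties by name).
#' @export
collapse_to_genus <- function(table, taxonomy) {
  stopifnot(inherits(table, "abund_table"))
  if (length(taxonomy) == 0L) stop("empty taxonomy")
  if (is.null(names(taxonomy))) stop("taxonomy must be a named vector (OTU -> genus)")
  otus <- colnames(table)
  genus <- unname(taxonomy[otus])
  if (anyNA(genus)) {
    warning("unmapped OTU(s) pooled into 'unclassified': ",
            paste(otus[is.na(genus)], collapse = ", "))
    genus[is.na(genus)] <- "unclassified"
  }
  collapsed <- t(rowsum(t(unclass(table)), group = genus))
  tot <- colSums(collapsed)
  collapsed <- collapsed[, order_by_abundance(tot, colnames(collapsed)), drop = FALSE]
  abundance_table(collapsed, table_mode(table))
}

#' Rename taxa via a relabel map
#'
#' Applies a one-step taxon renaming (each taxon renamed at most once; chains
#' are not followed). A rename that collides with an existing taxon merges the
#' two columns by summation. A cyclic map is rejected.
#'
#' @param table An [abundance_table()].
#' @param map Named character vector, `source -> replacement`. May be empty.
#' @return An [abundance_table()].
#' @examples
#' m <- matrix(c(4, 6), 1, dimnames = list("s1", c("Shuttleworthia", "Prevotella")))
#' tab <- abundance_table(m, "counts")
#' colnames(apply_relabel(tab, c(Shuttleworthia = "BVAB1")))
#' @export
apply_relabel <- function(table, map) {
  stopifnot(inherits(table, "abund_table"))
  if (length(map) == 0L) return(table)
  if (is.null(names(map))) stop("relabel map must be a named vector (source -> replacement)")
  # cycle check: following the map from any source must not return to it
  for (src in names(map)) {
    cur <- src
    for (step in seq_along(map)) {
      if (!cur %in% names(map)) break
      cur <- unname(map[[cur]])
      if (identical(cur, src)) stop("cyclic relabel map involving taxon '", src, "'")
    }
  }
  newnames <- colnames(table)
  hit <- newnames %in% names(map)
  newnames[hit] <- unname(map[newnames[hit]])
  merged <- t(rowsum(t(unclass(table)), group = newnames, reorder = FALSE))
  abundance_table(merged, table_mode(table))
}

#' Top taxa globally and per sample
#'
#' Global ranking is by mean relative abundance across samples (counts are
#' converted to within-sample proportions first); per-sample rankings use
#' within-sample abundance. Ties break by taxon name ascending, so the top-n
#' list is always a prefix of the top-(n+1) list.
#'
#' @param table An [abundance_table()].
#' @param n Number of taxa to report; when `n` exceeds the number of taxa all
#'   taxa are returned.
#' @return List with `global` (character vector) and `per_sample` (named list
#'   of character vectors, one per sample).
#' @export
top_taxa <- function(table, n) {
  stopifnot(inherits(table, "abund_table"))
  stop_if_not_scalar_count(n, "n")
  rel <- if (table_mode(table) == "relative") unclass(table) else {
    rs <- rowSums(table)
    if (any(rs <= 0)) stop("sample(s) with zero total: ",
                           paste(rownames(table)[rs <= 0], collapse = ", "))
    sweep(unclass(table), 1L, rs, "/")
  }
  taxa <- colnames(rel)
  n_use <- min(n, length(taxa))
  global <- taxa[order_by_abundance(colMeans(rel), taxa)][seq_len(n_use)]
  per_sample <- lapply(seq_len(nrow(rel)), function(i)
    taxa[order_by_abundance(rel[i, ], taxa)][seq_len(n_use)])
  names(per_sample) <- rownames(rel)
  list(global = global, per_sample = per_sample)
}
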