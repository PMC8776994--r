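# Core data containers, readers/writers, and the m6A regulator registry.
#
# Containers are deliberately plain (the limma convention): an expression
# matrix is a numeric genes x samples matrix with dimnames, a clinical table
# is a data.frame, a gene-set collection is a named list of character vectors.
# Validators enforce the contracts at the module boundary.

#' Validate an expression matrix
#'
#' An expression matrix is a numeric genes x samples matrix, log2 scale,
#' with unique non-empty rownames (gene symbols) and colnames (sample ids),
#' all values finite, and at least 2 genes and 2 samples.
#'
#' @param x Object to validate.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("expression matrix needs at least 2 genes and 2 samples", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(x)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row and an identifier column (first column). Duplicate
#' gene rows are collapsed by keeping the row with the highest mean
#' expression, the usual microarray convention when several probes map to
#' one symbol.
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.csv` gives `","`, anything else tab).
#' @return A validated genes x samples numeric matrix.
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("expression file needs an id column plus data columns",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  header <- names(df)[-1L]     # before [.data.frame mangles duplicates
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric value %s at row %d, column '%s' of %s",
                     dQuote(as.character(col[bad[1L]])), bad[1L],
                     colnames(vals)[j], path), call. = FALSE)
      vals[[j]] <- num
    } else if (anyNA(col)) {
      stop(sprintf("non-numeric value \"NA\" at row %d, column '%s' of %s",
                   which(is.na(col))[1L], colnames(vals)[j], path),
           call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(ids, header)
  if (orientation == "samples_in_rows") m <- t(m)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers in ", path, call. = FALSE)
  m <- collapse_duplicate_genes(m)
  validate_expression_matrix(m)
  m
}

# Keep, for each duplicated symbol, the row with the highest mean expression.
collapse_duplicate_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  ids <- rownames(m)
  means <- rowMeans(m)
  keep <- vapply(split(seq_len(nrow(m)), ids),
                 function(idx) idx[which.max(means[idx])], integer(1))
  keep <- keep[unique(ids)]   # first-appearance order
  out <- m[keep, , drop = FALSE]
  rownames(out) <- unique(ids)
  out
}

#' Write an expression matrix as TSV
#'
#' Full double precision is kept so that write/read round-trips exactly.
#'
#' @param x Validated expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(gene = rownames(x),
                   format(as.data.frame(x), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Requires columns for sample id (first column or `sample_id`), survival
#' `time` and `event`; any further columns are carried through as
#' annotations (stage, morphology, subtype, ...).
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return A data.frame with columns `sample_id`, `time`, `event`, plus
#'   annotation columns.
#' @export
read_clinical <- function(path, sep = NULL) {
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  nm <- names(df)
  idcol <- if ("sample_id" %in% nm) "sample_id" else nm[1L]
  if (!all(c("time", "event") %in% nm))
    stop("clinical table must contain 'time' and 'event' columns", call. = FALSE)
  out <- data.frame(sample_id = as.character(df[[idcol]]),
                    time = as.numeric(df$time),
                    event = as.numeric(df$event),
                    stringsAsFactors = FALSE)
  extra <- setdiff(nm, c(idcol, "time", "event"))
  for (col in extra) out[[col]] <- df[[col]]
  validate_clinical(out)
  out
}

#' Validate a clinical table
#'
#' @param x data.frame with `sample_id`, `time`, `event`.
#' @return `x` invisibly, or an error.
#' @export
validate_clinical <- function(x) {
  if (!is.data.frame(x) || !all(c("sample_id", "time", "event") %in% names(x)))
    stop("clinical table must have sample_id, time and event columns", call. = FALSE)
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample identifiers in clinical table", call. = FALSE)
  if (anyNA(x$time) || any(x$time < 0))
    stop("survival time must be nonnegative and non-missing", call. = FALSE)
  if (!all(x$event %in% c(0, 1)))
    stop("event indicator must be 0 or 1", call. = FALSE)
  invisible(x)
}

#' Write a clinical table as TSV
#' @param x Clinical data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(x, path) {
  validate_clinical(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Genes are de-duplicated
#' preserving first appearance.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path, call. = FALSE)
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d of %s has fewer than 3 fields", short[1L], path),
         call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names in ", path, call. = FALSE)
  if (any(lengths(sets) == 0L))
    stop("empty gene set after de-duplication in ", path, call. = FALSE)
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2L), names(sets))
  sets
}

#' Write a gene-set collection as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, if (nzchar(desc[[nm]] %||% "")) desc[[nm]] else "na",
            sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' The curated m6A regulator registry
#'
#' The 26 N6-methyladenosine regulators used throughout the pipeline,
#' partitioned into 10 writers (methyltransferase complex), 14 readers
#' (m6A-binding proteins) and 2 erasers (demethylases).
#'
#' @return data.frame with columns `symbol` and `class`
#'   (`writer`/`reader`/`eraser`).
#' @export
load_regulator_registry <- function() {
  writers <- c("KIAA1429", "WTAP", "RBM15", "RBM15B", "ZC3H13", "METTL3",
               "METTL5", "METTL14", "METTL16", "CBLL1")
  readers <- c("YTHDC1", "YTHDC2", "YTHDF1", "YTHDF2", "YTHDF3", "HNRNPC",
               "FMR1", "IGF2BP1", "IGF2BP2", "IGF2BP3", "RBMX", "HNRNPA2B1",
               "LRPPRC", "ELAVL1")
  erasers <- c("FTO", "ALKBH5")
  data.frame(symbol = c(writers, readers, erasers),
             class = rep(c("writer", "reader", "eraser"),
                         c(length(writers), length(readers), length(erasers))),
             stringsAsFactors = FALSE)
}

#' Export the regulator registry as a two-column TSV
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regulator_registry <- function(path) {
  utils::write.table(load_regulator_registry(), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict expression and clinical data to their common samples
#'
#' Both objects are subset to the intersection of their sample ids, in the
#' expression matrix's column order.
#'
#' @param expr Expression matrix.
#' @param clinical Clinical data.frame.
#' @return list with elements `expr` and `clinical`, sample-aligned.
#' @export
align_samples <- function(expr, clinical) {
  validate_expression_matrix(expr)
  validate_clinical(clinical)
  common <- intersect(colnames(expr), clinical$sample_id)
  if (!length(common))
    stop("no samples shared between expression matrix and clinical table",
         call. = FALSE)
  common <- colnames(expr)[colnames(expr) %in% common]
  expr <- expr[, common, drop = FALSE]
  clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  list(expr = expr, clinical = clinical)
}

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
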