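# Readers/writers for the plain-text formats the pipeline touches:
# expression tables (GCT 1.2 / TSV), gene sets (GMT), phenotype labels
# (categorical CLS) and clinical tables (TSV). All parsers validate
# strictly and never drop records silently.

#' Validate a gene-by-sample expression matrix
#'
#' An expression matrix is a dense numeric matrix with unique, non-empty
#' gene identifiers as rownames and unique, non-empty sample identifiers
#' as colnames; every value must be finite and non-negative.
#'
#' @param m numeric matrix.
#' @return the matrix, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression matrix must be a numeric matrix")
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("expression matrix must have at least one gene and one sample")
  g <- rownames(m); s <- colnames(m)
  if (is.null(g) || is.null(s) || any(!nzchar(g)) || any(!nzchar(s)))
    stop("expression matrix needs non-empty gene and sample identifiers")
  if (anyDuplicated(g)) stop("duplicate gene identifiers: ",
                             paste(unique(g[duplicated(g)]), collapse = ", "))
  if (anyDuplicated(s)) stop("duplicate sample identifiers: ",
                             paste(unique(s[duplicated(s)]), collapse = ", "))
  if (any(!is.finite(m))) stop("expression matrix contains non-finite values")
  if (any(m < 0)) stop("expression matrix contains negative values")
  invisible(m)
}

.collapse_duplicate_genes <- function(values, ids) {
  if (!anyDuplicated(ids)) {
    rownames(values) <- ids
    return(values)
  }
  n_dup <- sum(duplicated(ids))
  f <- factor(ids, levels = unique(ids))
  counts <- as.vector(table(f))
  out <- rowsum(values, group = f, reorder = FALSE) / counts
  warning(sprintf("collapsed %d duplicate gene row(s) by arithmetic mean", n_dup))
  rownames(out) <- levels(f)
  out
}

.finish_expression_matrix <- function(values, gene_ids, sample_ids, path) {
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in ", path)
  if (any(!nzchar(gene_ids))) stop("empty gene identifier in ", path)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("non-finite expression value in ", path)
  if (any(values < 0))
    stop("negative expression value in ", path)
  colnames(values) <- sample_ids
  values <- .collapse_duplicate_genes(values, gene_ids)
  validate_expression_matrix(values)
  values
}

#' Read a gene-by-sample expression table
#'
#' Supports GCT version 1.2 (two header lines, then a dimensions-checked
#' body with `Name` and `Description` columns) and plain TSV with gene
#' identifiers in the first column. Duplicate gene rows are collapsed by
#' arithmetic mean with a warning; duplicate sample columns, negative or
#' non-finite values are errors.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gct"` or `"tsv"`.
#' @return a validated expression matrix (genes x samples).
#' @export
read_expression_table <- function(path, format = c("auto", "gct", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L)
      stop("malformed GCT (", path, "): fewer than 3 lines")
    if (trimws(lines[1L]) != "#1.2")
      stop("malformed GCT (", path, "): line 1 must be '#1.2', got '",
           lines[1L], "'")
    dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1]]))
    if (length(dims) != 2L || any(is.na(dims)))
      stop("malformed GCT (", path, "): line 2 must give two integer dimensions")
    body <- read.delim(path, skip = 2L, header = TRUE, check.names = FALSE,
                       stringsAsFactors = FALSE)
    if (ncol(body) < 3L)
      stop("malformed GCT (", path, "): body needs Name, Description and >=1 sample")
    if (nrow(body) != dims[1L])
      stop("malformed GCT (", path, "): declared ", dims[1L],
           " rows but body has ", nrow(body))
    if (ncol(body) - 2L != dims[2L])
      stop("malformed GCT (", path, "): declared ", dims[2L],
           " samples but body has ", ncol(body) - 2L)
    vals <- as.matrix(body[, -(1:2), drop = FALSE])
    .finish_expression_matrix(vals, as.character(body[[1L]]),
                              colnames(body)[-(1:2)], path)
  } else {
    body <- read.delim(path, header = TRUE, check.names = FALSE,
                       stringsAsFactors = FALSE)
    if (ncol(body) < 2L)
      stop("malformed expression TSV (", path, "): need id column plus >=1 sample")
    vals <- as.matrix(body[, -1L, drop = FALSE])
    .finish_expression_matrix(vals, as.character(body[[1L]]),
                              colnames(body)[-1L], path)
  }
}

#' Write a gene-by-sample expression table
#'
#' Values are written with 6 significant digits so a write/read round trip
#' reproduces the matrix to that precision.
#'
#' @param m validated expression matrix.
#' @param path output file path.
#' @param format `"gct"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path, format = c("gct", "tsv")) {
  format <- match.arg(format)
  validate_expression_matrix(m)
  fmt <- function(x) sprintf("%.6g", x)
  body_vals <- apply(m, 2L, fmt)
  if (is.null(dim(body_vals))) body_vals <- matrix(body_vals, nrow = nrow(m))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "gct") {
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    writeLines(paste(c("Name", "Description", colnames(m)), collapse = "\t"), con)
    writeLines(paste(rownames(m), "na",
                     apply(body_vals, 1L, paste, collapse = "\t"),
                     sep = "\t"), con)
  } else {
    writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
    writeLines(paste(rownames(m),
                     apply(body_vals, 1L, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Construct a gene set
#'
#' @param name non-empty set name.
#' @param genes non-empty character vector of unique gene identifiers.
#' @return a `gene_set` object (list with `name` and `genes`).
#' @export
gene_set <- function(name, genes) {
  name <- as.character(name)
  genes <- as.character(genes)
  if (length(name) != 1L || !nzchar(name)) stop("gene set name must be non-empty")
  if (length(genes) == 0L || any(!nzchar(genes)))
    stop("gene set '", name, "' must contain non-empty gene identifiers")
  if (anyDuplicated(genes))
    stop("gene set '", name, "' contains duplicate genes")
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then genes, tab-separated.
#' Duplicate genes within a line are deduplicated with a warning;
#' duplicate set names across lines are an error.
#'
#' @param path GMT file path.
#' @return named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  sets <- list()
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop("malformed GMT (", path, ") line ", i,
           ": need name, description and >=1 gene")
    name <- fields[1L]
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): removed %d duplicate gene(s)",
                      i, name, sum(duplicated(genes))))
      genes <- unique(genes)
    }
    if (name %in% names(sets))
      stop("duplicate gene set name in ", path, ": '", name, "'")
    sets[[name]] <- gene_set(name, genes)
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @param description description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(gs)
    paste(c(gs$name, description, gs$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a categorical CLS phenotype file
#'
#' Dialect: line 1 `N K 1`, line 2 `# name1 ... nameK`, line 3 the N
#' space-separated labels (either class names or 0-based class indices).
#'
#' @param path CLS file path.
#' @return character vector of N labels.
#' @export
read_cls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("malformed CLS (", path, "): need 3 lines")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1]]))
  if (length(hdr) != 3L || any(is.na(hdr)))
    stop("malformed CLS (", path, "): header must be 'N K 1'")
  if (!startsWith(trimws(lines[2L]), "#"))
    stop("malformed CLS (", path, "): line 2 must start with '#'")
  cls_names <- strsplit(trimws(sub("^#", "", lines[2L])), "\\s+")[[1]]
  if (length(cls_names) != hdr[2L])
    stop("malformed CLS (", path, "): header declares ", hdr[2L],
         " classes but line 2 names ", length(cls_names))
  labels <- strsplit(trimws(lines[3L]), "\\s+")[[1]]
  if (length(labels) != hdr[1L])
    stop("malformed CLS (", path, "): header declares ", hdr[1L],
         " labels but body has ", length(labels))
  idx <- suppressWarnings(as.integer(labels))
  if (!any(is.na(idx)) && all(idx >= 0) && all(idx < hdr[2L]))
    labels <- cls_names[idx + 1L]
  if (!all(labels %in% cls_names))
    stop("malformed CLS (", path, "): label not among declared class names")
  labels
}

#' Write a categorical CLS phenotype file
#'
#' @param labels character vector of class labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cls <- function(labels, path) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("no labels to write")
  cls_names <- unique(labels)
  writeLines(c(paste(length(labels), length(cls_names), 1),
               paste("#", paste(cls_names, collapse = " ")),
               paste(labels, collapse = " ")), path)
  invisible(path)
}

.STAGE_LEVELS <- c("early", "late", "metastasis", "unknown")

#' Read a clinical table
#'
#' TSV with mandatory columns `sample_id` and `stage_group` and optional
#' `raw_stage` and `subgroup`. Stage groups are matched case-insensitively
#' against the closed vocabulary early / late / metastasis / unknown;
#' anything else is mapped to `unknown` with a warning.
#'
#' @param path TSV file path.
#' @return data.frame with columns sample_id, stage_group, raw_stage, subgroup.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("sample_id", "stage_group"))
    if (!col %in% names(df))
      stop("clinical table (", path, ") is missing mandatory column '", col, "'")
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    stage_group = tolower(trimws(as.character(df$stage_group))),
    raw_stage = if ("raw_stage" %in% names(df)) as.character(df$raw_stage) else NA_character_,
    subgroup = if ("subgroup" %in% names(df)) as.character(df$subgroup) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$sample_id))
    stop("clinical table (", path, ") has duplicate sample_id values")
  bad <- !out$stage_group %in% .STAGE_LEVELS
  if (any(bad)) {
    warning(sprintf("clinical table: %d unrecognised stage value(s) mapped to 'unknown' (e.g. '%s')",
                    sum(bad), out$stage_group[which(bad)[1]]))
    out$stage_group[bad] <- "unknown"
  }
  out
}

#' Write a clinical table
#'
#' @param clinical data.frame as returned by [read_clinical_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
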