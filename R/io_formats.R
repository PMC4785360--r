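#' Read a gene expression matrix from tab-delimited text
#'
#' Expects a header row of identifiers and an identifier in the first column of
#' every subsequent row. Orientation is normalized to genes-in-rows: when
#' `orientation_hint = "auto"` and `sample_ids` is supplied (e.g. from the
#' sample table), the axis whose labels overlap `sample_ids` more becomes the
#' column axis; otherwise the file is taken as genes-in-rows.
#'
#' @param path file path to a tab-delimited matrix.
#' @param orientation_hint one of `"auto"`, `"genes_in_rows"`,
#'   `"samples_in_rows"`.
#' @param sample_ids optional character vector of known sample identifiers used
#'   by the auto-detection.
#' @return numeric matrix, genes in rows, with unique row and column names.
#' @export
read_expression_matrix <- function(path,
                                   orientation_hint = c("auto", "genes_in_rows",
                                                        "samples_in_rows"),
                                   sample_ids = NULL) {
  orientation_hint <- match.arg(orientation_hint)
  raw <- utils::read.delim(path, header = TRUE, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("expression file must have at least one data column")
  ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]  # before data.frame subsetting repairs names
  body <- raw[, -1L, drop = FALSE]
  if (anyDuplicated(ids))
    stop("duplicate row identifiers in expression file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(col_ids))
    stop("duplicate column identifiers in expression file: ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(ids, col_ids))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   body[[j]][bad[1L]], ids[bad[1L]], col_ids[j]))
    m[, j] <- v
  }
  if (orientation_hint == "samples_in_rows") {
    m <- t(m)
  } else if (orientation_hint == "auto" && !is.null(sample_ids)) {
    in_cols <- mean(colnames(m) %in% sample_ids)
    in_rows <- mean(rownames(m) %in% sample_ids)
    if (in_rows > in_cols) m <- t(m)
  }
  validate_expression_matrix(m)
}

#' Validate an expression matrix (genes in rows)
#'
#' @param m numeric matrix with gene row names and sample column names.
#' @return the matrix, invisibly unchanged, after validation.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers")
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
  m
}

#' Write an expression matrix as tab-delimited text (genes in rows)
#' @param m validated expression matrix.
#' @param path output path.
#' @export
write_expression_matrix <- function(m, path) {
  validate_expression_matrix(m)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.required_sample_columns <- c("sample", "age", "sex", "batch", "cancer",
                              "tissue", "pc1", "pc2", "pc3")

#' Read the per-sample annotation / drug-response table
#'
#' One row per cell line. Required columns: `sample`, `age`, `sex`, `batch`,
#' `cancer`, `tissue`, `pc1`..`pc3`. Any column named `sens_<drug>` carries the
#' activity area for that drug; missing sensitivity values are kept as `NA`
#' (the sample is excluded per-drug at analysis time, never dropped here, so
#' per-drug sample counts may differ).
#'
#' @param path tab-delimited file with a header row.
#' @return data.frame with factor covariates and numeric sensitivity columns.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' Validate a sample table
#' @param df data.frame as described in [read_sample_table()].
#' @return the validated table with typed columns.
#' @export
validate_sample_table <- function(df) {
  missing_cols <- setdiff(.required_sample_columns, names(df))
  if (length(missing_cols))
    stop("sample table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicate sample identifiers")
  df$age <- as.numeric(df$age)
  if (any(is.na(df$age)) || any(df$age < 0))
    stop("age must be non-negative and numeric for every sample")
  for (col in c("sex", "batch", "cancer", "tissue")) {
    if (any(is.na(df[[col]]) | df[[col]] == ""))
      stop("empty value in factor column '", col, "'")
    df[[col]] <- factor(df[[col]])
  }
  for (col in c("pc1", "pc2", "pc3")) df[[col]] <- as.numeric(df[[col]])
  for (col in sensitivity_columns(df)) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.na(df[[col]]) & !is.finite(df[[col]])))
      stop("non-finite sensitivity in column '", col, "'")
  }
  df
}

#' Names of the drugs carried by a sample table
#' @param samples sample table.
#' @return character vector of drug names (the `sens_` columns, prefix removed).
#' @export
drug_names <- function(samples) {
  sub("^sens_", "", sensitivity_columns(samples))
}

sensitivity_columns <- function(samples) {
  grep("^sens_", names(samples), value = TRUE)
}

#' Sensitivity vector for one drug, named by sample
#' @param samples sample table.
#' @param drug drug name (without the `sens_` prefix).
#' @return named numeric vector (may contain `NA`).
#' @export
drug_sensitivity <- function(samples, drug) {
  col <- paste0("sens_", drug)
  if (!col %in% names(samples)) stop("no sensitivity column for drug '", drug, "'")
  stats::setNames(samples[[col]], samples$sample)
}

#' Write a sample table
#' @param samples sample table.
#' @param path output path.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' GMT: one set per line, tab-delimited: name, description, then member genes.
#' Duplicate members within a line are collapsed; duplicate set names are a
#' format error.
#'
#' @param path GMT file.
#' @return named list of character vectors with a `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one gene",
                   i, length(f)))
    nms[i] <- f[1L]
    descs[i] <- f[2L]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(nms))
    stop("duplicate gene-set names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(descs, nms)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors; an optional `descriptions`
#'   attribute supplies the second field (defaults to `"na"`).
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  descs <- attr(sets, "descriptions")
  if (is.null(descs)) descs <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted protein-interaction edge list
#'
#' Three tab-delimited columns: geneA, geneB, confidence score. Scores follow
#' either the unit scale or the STRING combined-score convention (0-1000),
#' auto-detected from the maximum: if any score exceeds 1 all scores are
#' divided by 1000 before thresholding. Self-loops are dropped with a warning;
#' duplicate edges keep the maximum score. Edges below `min_confidence` are
#' removed, along with any node left isolated.
#'
#' @param path edge-list file (a header line is detected and skipped when the
#'   third field is non-numeric).
#' @param min_confidence minimum normalized confidence, default 0.4.
#' @return undirected simple [igraph::graph] with a `weight` edge attribute.
#' @export
read_network_edges <- function(path, min_confidence = 0.4) {
  first <- readLines(path, n = 1L)
  f1 <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  skip <- if (length(f1) >= 3L && is.na(suppressWarnings(as.numeric(f1[3L])))) 1L else 0L
  df <- utils::read.delim(path, header = FALSE, skip = skip,
                          stringsAsFactors = FALSE,
                          col.names = c("a", "b", "score"))
  if (nrow(df) == 0L && skip == 1L) {
    # the "header" was really a malformed data line
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("a", "b", "score"))
    skip <- 0L
  }
  sc <- suppressWarnings(as.numeric(df$score))
  if (any(is.na(sc)))
    stop("unparsable confidence score at edge-list line ",
         which(is.na(sc))[1L] + skip)
  df$score <- sc
  network_from_edges(df$a, df$b, df$score, min_confidence)
}

#' Build a confidence-thresholded PPI graph from edge vectors
#' @param a,b character vectors of endpoint gene identifiers.
#' @param score numeric confidence scores, unit or STRING 0-1000 scale.
#' @param min_confidence minimum normalized confidence to retain an edge.
#' @return undirected simple igraph with `weight` edge attribute.
#' @export
network_from_edges <- function(a, b, score, min_confidence = 0.4) {
  if (max(score) > 1) score <- score / 1000
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop edge(s) dropped")
    a <- a[!self]; b <- b[!self]; score <- score[!self]
  }
  # canonical unordered pair; duplicates keep the maximum score
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  score <- vapply(split(score, key), max, numeric(1))
  ends <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
  keep <- score >= min_confidence
  g <- igraph::graph_from_data_frame(
    data.frame(from = ends[keep, 1L], to = ends[keep, 2L],
               weight = unname(score[keep]), stringsAsFactors = FALSE),
    directed = FALSE)
  g
}

#' Write a network as a 3-column edge list
#' @param g igraph with `weight` edge attribute.
#' @param path output path.
#' @export
write_network_edges <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  if (is.null(el$weight)) el$weight <- 1
  utils::write.table(el[, c("from", "to", "weight")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = c("geneA", "geneB", "score"))
  invisible(path)
}

#' Write a result table with a parameter-recording header comment
#'
#' @param df data.frame of results.
#' @param path output path.
#' @param params named list recorded as `# key=value` comment lines.
#' @export
write_result_table <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(params))
    writeLines(sprintf("# %s=%s", nm, paste(params[[nm]], collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_result_table()]
#' @param path file path.
#' @return data.frame (header comments skipped).
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
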