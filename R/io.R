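#' Read / write the pipeline's plain-text formats
#'
#' Expression and mutation matrices travel as TSV with the gene id in the
#' first column (`gene`) and one column per sample; clinical tables as TSV
#' with columns `sample`, `time`, `event`; CPDAGs as edge lists with columns
#' `source`, `target`, `type`; pathway collections as GMT.
#'
#' @param path file path.
#' @return `read_expression` / `read_mutations`: numeric matrix with
#'   dimnames; `read_clinical`: data frame `sample`/`time`/`event`;
#'   `read_gmt`: named list of character vectors.
#' @name prognet_io
NULL

#' @rdname prognet_io
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus samples")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (any(!is.finite(m))) stop("non-finite expression values in ", path)
  m
}

#' @rdname prognet_io
#' @param expr genes x samples matrix.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname prognet_io
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df)))
    stop("clinical TSV needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in ", path)
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df$event <- as.integer(df$event)
  df
}

#' @rdname prognet_io
#' @param clin clinical data frame (`sample`, `time`, `event`).
#' @export
write_clinical <- function(clin, path) {
  write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname prognet_io
#' @export
read_mutations <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  # MAF-lite (long) form: columns gene, sample[, class] -> collapse to binary
  if (all(c("gene", "sample") %in% names(df)) && ncol(df) <= 3L &&
      !all(vapply(df[-1L], is.numeric, logical(1)))) {
    genes <- sort(unique(df$gene))
    samples <- sort(unique(df$sample))
    m <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(df$gene, genes), match(df$sample, samples))] <- 1L
    return(m)
  }
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  if (!all(m %in% c(0L, 1L))) stop("mutation matrix must be binary")
  m
}

#' @rdname prognet_io
#' @param mut binary genes x samples matrix.
#' @export
write_mutations <- function(mut, path) {
  df <- data.frame(gene = rownames(mut), mut, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname prognet_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("GMT line needs name, description and >= 1 gene")
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  if (anyDuplicated(names(sets))) stop("duplicate pathway names in ", path)
  sets
}

#' @rdname prognet_io
#' @param pathways named list of gene-id character vectors.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
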