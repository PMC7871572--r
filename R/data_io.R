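# Readers/writers for the four tab-separated file kinds: expression matrix,
# regulator list, ranked edge list, gold-standard network. All identifiers are
# opaque case-sensitive strings; no symbol mapping is attempted.

#' Read a gene expression matrix
#'
#' Reads a tab-separated genes x samples table. The first row holds sample
#' identifiers, the first column gene identifiers. Values must be numeric and
#' complete: missing or non-numeric cells are a hard error, never imputed,
#' because silent imputation would change every downstream edge confidence.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (genes in rows, samples in columns) with unique
#'   rownames and colnames, in file order.
#' @export
read_expression <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "")
  if (ncol(tab) < 2L) stop("expression file needs at least one sample column: ", path)
  gene_ids <- tab[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene id(s) in expression file: ",
                        paste(unique(dup), collapse = ", "))
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(sample_ids)) stop("duplicate sample id(s) in expression file")
  vals <- matrix(NA_real_, nrow = nrow(tab), ncol = ncol(tab) - 1L)
  for (j in seq_len(ncol(tab) - 1L)) {
    col <- tab[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                   gene_ids[bad[1L]], sample_ids[j]))
    }
    vals[, j] <- num
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  validate_expression(vals)
}

#' @rdname read_expression
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @export
write_expression <- function(expr, path) {
  expr <- validate_expression(expr)
  # %.17g keeps doubles bitwise through the text round-trip
  body <- apply(expr, 1L, function(row) paste(sprintf("%.17g", row), collapse = "\t"))
  lines <- c(paste(c("", colnames(expr)), collapse = "\t"),
             paste(rownames(expr), body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a genes x samples expression matrix
#'
#' @param expr Numeric matrix; rownames are gene ids, colnames sample ids.
#' @return The matrix, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (any(!nzchar(rownames(expr)))) stop("empty gene id in expression matrix")
  if (any(!nzchar(colnames(expr)))) stop("empty sample id in expression matrix")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids in expression matrix")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  expr
}

#' Read a candidate-regulator list
#'
#' One gene identifier per line. Duplicates are collapsed; an empty file is an
#' error. Whether the regulators occur in an expression matrix is checked at
#' the point of use, not here (gold standards may name regulators absent from
#' the expression data).
#'
#' @param path Path to the list file.
#' @return Character vector of unique regulator ids, in first-seen order.
#' @export
read_regulators <- function(path) {
  if (!file.exists(path)) stop("regulator file not found: ", path)
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  ids <- unique(ids)
  if (!length(ids)) stop("regulator file is empty: ", path)
  ids
}

#' Construct a ranked edge list
#'
#' The container every inference engine and every consensus step works with:
#' a data.frame of directed regulator -> target edges sorted by non-increasing
#' confidence (stable, so construction order breaks confidence ties).
#'
#' @param regulator,target Character vectors of equal length.
#' @param confidence Numeric vector of method-specific confidences.
#' @param method Label of the producing method.
#' @return A `data.frame` of class `ranked_edges` with columns
#'   `regulator`, `target`, `confidence` and attribute `method`.
#' @export
ranked_edge_list <- function(regulator, target, confidence,
                             method = "unnamed") {
  regulator <- as.character(regulator)
  target <- as.character(target)
  confidence <- as.numeric(confidence)
  n <- length(regulator)
  stopifnot(length(target) == n, length(confidence) == n)
  if (anyNA(confidence)) stop("edge confidences must not be NA")
  self <- regulator == target
  if (any(self)) stop("self-edge(s) not allowed: ",
                      paste(utils::head(regulator[self], 3L), collapse = ", "))
  key <- paste(regulator, target, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate edge: ", sub("\r", " -> ", d, fixed = TRUE))
  }
  ord <- order(-confidence)  # stable: ties keep construction order
  out <- data.frame(regulator = regulator[ord], target = target[ord],
                    confidence = confidence[ord], stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("ranked_edges", "data.frame")
  out
}

#' Read a ranked edge list
#'
#' Lines are `regulator<TAB>target[<TAB>confidence]` with no header. When the
#' confidence column is absent the file order IS the ranking: synthetic
#' confidences `n_lines - line_index + 1` are assigned so the order is kept.
#'
#' @param path Path to the edge-list file.
#' @param method Label to attach to the edge list.
#' @return A `ranked_edges` data.frame (see [ranked_edge_list()]).
#' @export
read_edge_list <- function(path, method = basename(path)) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("edge list file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) stop("line ", which(nf < 2L)[1L], ": expected at least 2 tab-separated fields")
  reg <- vapply(parts, `[[`, "", 1L)
  tgt <- vapply(parts, `[[`, "", 2L)
  self <- which(reg == tgt)
  if (length(self)) stop("line ", self[1L], ": self-edge '", reg[self[1L]], "'")
  key <- paste(reg, tgt, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) stop("line ", dup[1L], ": duplicate edge ", reg[dup[1L]], " -> ", tgt[dup[1L]])
  if (all(nf >= 3L)) {
    conf <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(conf)) stop("line ", which(is.na(conf))[1L], ": non-numeric confidence")
  } else {
    conf <- rev(seq_along(lines))  # pure ranking: keep file order
  }
  ranked_edge_list(reg, tgt, conf, method = method)
}

#' Write a ranked edge list
#'
#' @param edges A `ranked_edges` data.frame.
#' @param path Output path; tab-separated `regulator target confidence`, no header.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(inherits(edges, "ranked_edges"))
  utils::write.table(edges[, c("regulator", "target", "confidence")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a gold-standard network
#'
#' @param regulator,target Character vectors of equal length (edge endpoints).
#' @param directed `TRUE` for regulatory networks; `FALSE` for symmetric
#'   (e.g. protein-protein-interaction derived) standards, in which case
#'   `(a,b)` and `(b,a)` denote the same edge and are deduplicated.
#' @return A `data.frame` of class `gold_standard` with attribute `directed`.
#' @export
gold_standard <- function(regulator, target, directed = TRUE) {
  regulator <- as.character(regulator)
  target <- as.character(target)
  stopifnot(length(regulator) == length(target))
  self <- regulator == target
  if (any(self)) stop("self-edge(s) in gold standard: ",
                      paste(utils::head(regulator[self], 3L), collapse = ", "))
  if (directed) {
    key <- paste(regulator, target, sep = "\r")
  } else {
    key <- ifelse(regulator <= target,
                  paste(regulator, target, sep = "\r"),
                  paste(target, regulator, sep = "\r"))
  }
  keep <- !duplicated(key)
  out <- data.frame(regulator = regulator[keep], target = target[keep],
                    stringsAsFactors = FALSE)
  attr(out, "directed") <- directed
  class(out) <- c("gold_standard", "data.frame")
  out
}

#' Read a gold-standard network
#'
#' Two- or three-column tab-separated edge list (any third column is ignored).
#'
#' @param path Path to the file.
#' @param directed Whether edges are directed (see [gold_standard()]).
#' @export
read_gold_standard <- function(path, directed = TRUE) {
  if (!file.exists(path)) stop("gold standard file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("gold standard file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) stop("line ", which(nf < 2L)[1L], ": expected at least 2 fields")
  gold_standard(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L),
                directed = directed)
}

#' @rdname read_gold_standard
#' @param gs A `gold_standard` object.
#' @export
write_gold_standard <- function(gs, path) {
  stopifnot(inherits(gs, "gold_standard"))
  utils::write.table(gs[, c("regulator", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a hub table
#'
#' The tool's primary output: `regulator<TAB>score<TAB>rank`, sorted by
#' descending score (ties broken lexicographically by regulator id).
#'
#' @param scores Named numeric vector of hub scores.
#' @param path Output path.
#' @export
write_hub_table <- function(scores, path) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  ord <- rank_hubs(scores)
  out <- data.frame(regulator = ord, score = unname(scores[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hub_table
#' @export
read_hub_table <- function(path) {
  if (!file.exists(path)) stop("hub table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("regulator", "score", "rank"),
                           colClasses = c("character", "numeric", "integer"))
  scores <- tab$score
  names(scores) <- tab$regulator
  scores
}
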