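#' Typed weighted edge set
#'
#' A data frame of `(source, target, weight)` rows carrying the node-type
#' labels of its endpoints. Identifiers are opaque case-sensitive strings
#' (whitespace-trimmed on read); weights must be finite and, for network
#' construction, nonnegative.
#'
#' @param edges Data frame with columns `source`, `target`, `weight`.
#' @param source_type,target_type One-letter node-type labels (e.g. `"L"`,
#'   `"P"`).
#' @return An `edge_set`: the data frame with type attributes.
#' @export
edge_set <- function(edges, source_type, target_type) {
  stopifnot(is.data.frame(edges))
  need <- c("source", "target", "weight")
  if (!all(need %in% names(edges)))
    stop("'edges' must have columns source, target, weight")
  edges <- edges[need]
  edges$source <- trimws(as.character(edges$source))
  edges$target <- trimws(as.character(edges$target))
  edges$weight <- as.numeric(edges$weight)
  if (nrow(edges) > 0L && any(!is.finite(edges$weight)))
    stop("edge weights must be finite")
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate edge(s): ",
         paste(unique(sub("\r", " -> ", key[duplicated(key)])), collapse = ", "))
  rownames(edges) <- NULL
  structure(edges, source_type = source_type, target_type = target_type,
            class = c("edge_set", "data.frame"))
}

#' Read a 3-column TSV edge list
#'
#' Expects `source_id TAB target_id TAB weight` rows in UTF-8; lines
#' starting with `#` are comments. Malformed rows (not 3 columns, or a
#' non-finite weight) raise an error naming the offending line; duplicate
#' `(source, target)` pairs are an error.
#'
#' @param path File path.
#' @param source_type,target_type Node-type labels for the two columns.
#' @return An [edge_set].
#' @export
read_edge_list <- function(path, source_type, target_type) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(edge_set(data.frame(source = character(), target = character(),
                               weight = numeric()),
                    source_type, target_type))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfields <- lengths(parts)
  if (any(nfields != 3L)) {
    bad <- which(nfields != 3L)[1L]
    stop("line ", lineno[bad], ": expected 3 tab-separated columns, found ",
         nfields[bad])
  }
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  w <- suppressWarnings(as.numeric(m[, 3L]))
  if (any(!is.finite(w))) {
    bad <- which(!is.finite(w))[1L]
    stop("line ", lineno[bad], ": weight '", m[bad, 3L],
         "' is not a finite number")
  }
  edge_set(data.frame(source = m[, 1L], target = m[, 2L], weight = w),
           source_type, target_type)
}

#' Write an edge set as TSV
#'
#' @param edges An [edge_set] (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(as.data.frame(edges)[c("source", "target", "weight")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Combine per-dataset co-expression correlations into one score
#'
#' Merges Pearson correlation scores for one gene pair across expression
#' datasets into a single association weight:
#' `C = 1 - prod(1 - C_d)` over the datasets with a positive score.
#' Non-positive correlations carry no co-expression evidence and are
#' dropped before combination; if no positive score remains the pair gets
#' 0 (no edge). For positive inputs the result is always at least the
#' largest single-dataset score and below 1.
#'
#' @param per_dataset_scores Numeric vector of correlation scores, each in
#'   `(-1, 1]`.
#' @return Combined score in `[0, 1]`.
#' @export
#' @examples
#' combine_coexpression(c(0.5, 0.5))   # 0.75
#' combine_coexpression(c(-0.4, 0.6))  # 0.6
combine_coexpression <- function(per_dataset_scores) {
  s <- as.numeric(per_dataset_scores)
  if (length(s) > 0L && (any(!is.finite(s)) || any(s <= -1) || any(s > 1)))
    stop("correlation scores must lie in (-1, 1]")
  s <- s[s > 0]
  if (length(s) == 0L) return(0)
  1 - prod(1 - s)
}
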