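#' Metapaths
#'
#' A metapath is an ordered sequence of node-type labels constraining walks
#' through the heterogeneous network; `"LLP"` reads lncRNA - lncRNA -
#' protein. Its length in edges is one less than its node count.
#'
#' @param types Character vector of one-letter type labels, length >= 1.
#' @return A `metapath` with fields `types` and `name`.
#' @export
#' @examples
#' metapath(c("L", "L", "P"))
metapath <- function(types) {
  types <- as.character(types)
  if (length(types) < 1L || any(!nzchar(types)))
    stop("a metapath needs at least one non-empty type label")
  structure(list(types = types, name = paste(types, collapse = "")),
            class = "metapath")
}

#' @export
print.metapath <- function(x, ...) {
  cat("<metapath ", x$name, "> (", length(x$types) - 1L, " edge",
      if (length(x$types) != 2L) "s", ")\n", sep = "")
  invisible(x)
}

#' @export
format.metapath <- function(x, ...) x$name

#' Parse a metapath name
#'
#' @param name Compact string of one-letter type codes, e.g. `"LLPP"`.
#' @param alphabet Character vector of known type labels.
#' @return A [metapath].
#' @export
#' @examples
#' parse_metapath("LLP", c("L", "P"))
parse_metapath <- function(name, alphabet = c("L", "P")) {
  types <- strsplit(name, "", fixed = TRUE)[[1L]]
  unknown <- setdiff(types, alphabet)
  if (length(unknown) > 0L)
    stop("unknown type code(s) in '", name, "': ",
         paste(unique(unknown), collapse = ", "))
  metapath(types)
}

#' Enumerate metapaths between two types
#'
#' All type sequences starting at `start` and ending at `end`, with the
#' intermediate positions ranging freely over the alphabet and node counts
#' in `[min_nodes, max_nodes]`. The order is deterministic: by node count,
#' then lexicographic by name. With alphabet `{L, P}` and 3-5 nodes this
#' yields the canonical fourteen lncRNA-to-protein paths (see
#' [canonical_metapaths()] for the published id ordering).
#'
#' @param start,end Endpoint type labels.
#' @param alphabet Character vector of type labels.
#' @param max_nodes,min_nodes Node-count bounds (>= 2).
#' @return List of [metapath]s.
#' @export
#' @examples
#' length(enumerate_metapaths("L", "P", c("L", "P"), 5, 3))  # 14
enumerate_metapaths <- function(start, end, alphabet = c("L", "P"),
                                max_nodes = 5L, min_nodes = 3L) {
  stopifnot(min_nodes >= 2L, max_nodes >= min_nodes)
  alphabet <- sort(unique(as.character(alphabet)))
  out <- list()
  for (k in seq(min_nodes, max_nodes)) {
    n_mid <- k - 2L
    if (n_mid == 0L) {
      names_k <- paste0(start, end)
    } else {
      grid <- do.call(expand.grid,
                      c(rep(list(alphabet), n_mid),
                        list(stringsAsFactors = FALSE)))
      names_k <- apply(grid, 1L, function(mid)
        paste(c(start, mid, end), collapse = ""))
      names_k <- sort(names_k)
    }
    out <- c(out, lapply(names_k, parse_metapath, alphabet = union(alphabet, c(start, end))))
  }
  out
}

#' Canonical lncRNA-to-protein metapaths
#'
#' The fourteen 3-5 node paths from a lncRNA (`L`) to a protein (`P`) over
#' the two-type alphabet, in the published id order recorded in the bundled
#' manifest (`inst/extdata/metapath_manifest.tsv`). This is the default
#' feature-column ordering.
#'
#' @return Named list of [metapath]s; names are the compact path names, in
#'   manifest id order.
#' @export
canonical_metapaths <- function() {
  manifest <- metapath_manifest()
  paths <- lapply(manifest$name, parse_metapath, alphabet = c("L", "P"))
  stats::setNames(paths, manifest$name)
}

#' @rdname canonical_metapaths
#' @return `metapath_manifest()`: data frame with columns `id`, `name`.
#' @export
metapath_manifest <- function() {
  path <- system.file("extdata", "metapath_manifest.tsv",
                      package = "hetesimlpi", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Reverse a metapath
#'
#' @param p A [metapath].
#' @return The [metapath] with its type sequence reversed.
#' @export
reverse_metapath <- function(p) {
  stopifnot(inherits(p, "metapath"))
  metapath(rev(p$types))
}

#' Split a metapath at its midpoint(s)
#'
#' HeteSim evaluates a path by launching walks from both endpoints toward
#' a shared midpoint. A path of even edge count `n` splits once at node
#' `n/2 + 1`; an odd-`n` path cannot be halved exactly and splits twice, at
#' nodes `(n+1)/2` and `(n+3)/2` (the two scores are later averaged). The
#' two parts share the midpoint node, so left edge count plus right edge
#' count equals `n`. Single-node sub-paths (from splitting a 1-edge path)
#' are legal; their reachable matrix is the identity.
#'
#' @param p A [metapath] with edge count >= 1.
#' @return List of splits, each a list with `left`, `right` ([metapath]s)
#'   and `mid` (1-based node index).
#' @export
#' @examples
#' split_metapath(parse_metapath("LLPP"))  # two splits, mid 2 and 3
split_metapath <- function(p) {
  stopifnot(inherits(p, "metapath"))
  n <- length(p$types) - 1L
  if (n < 1L) stop("cannot split a single-node metapath")
  mids <- if (n %% 2L == 0L) n %/% 2L + 1L else c((n + 1L) %/% 2L, (n + 3L) %/% 2L)
  lapply(mids, function(mid)
    list(left = metapath(p$types[seq_len(mid)]),
         right = metapath(p$types[seq(mid, n + 1L)]),
         mid = mid))
}
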