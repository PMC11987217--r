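## Meta-paths from domain to disease and their commuting (path-count)
## matrices, computed as chains of sparse adjacency products.

TYPE_LETTER <- c(domain = "D", protein = "P", disease = "S")
LETTER_TYPE <- setNames(names(TYPE_LETTER), TYPE_LETTER)

## Canonical meta-path list, in printed table order.
## C1..C27 cover lengths 2-5; the ten length-6 paths have no short names
## and are identified by their letter sequence.
REGISTRY_NAMES <- list(
  `2` = c("DPS", "DSS"),
  `3` = c("DPSS", "DPPS", "DSPS", "DPDS"),
  `4` = c("DPPSS", "DPSDS", "DPDSS", "DPSPS", "DSPPS", "DSPSS",
          "DSDPS", "DSPDS", "DSSDS", "DPPDS", "DSSPS"),
  `5` = c("DPPDSS", "DSSPPS", "DPPSDS", "DSSPDS", "DPDSPS",
          "DPPSPS", "DSDPDS", "DPSSDS", "DPSPPS", "DSPDSS"),
  `6` = c("DPPDSPS", "DPPSPDS", "DPPSDSS", "DPDSPPS", "DPSPPSS",
          "DPSSPDS", "DSPDSPS", "DSDPSDS", "DSSPPSS", "DSSPDSS")
)

#' Parse a meta-path name
#'
#' A meta-path is a typed node sequence written over the alphabet D
#' (domain), P (protein), S (disease).  It must start at a domain, end at
#' a disease, have length (number of edges) at least 2, and every
#' consecutive letter pair must be a schema edge type — the only impossible
#' pair is D-D, since domains are never directly linked to domains.
#'
#' @param name Meta-path name, e.g. `"DPSS"`.
#' @return An object of class `metapath`: list with `name`,
#'   `node_sequence` (character vector of node types) and `length`.
#' @examples
#' parse_metapath("DPS")$node_sequence
#' @export
parse_metapath <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("meta-path name must be a non-empty string")
  letters_ <- strsplit(name, "", fixed = TRUE)[[1L]]
  if (!all(letters_ %in% names(LETTER_TYPE)))
    stopf("meta-path name '%s' contains letters outside D/P/S", name)
  if (letters_[1L] != "D" || letters_[length(letters_)] != "S")
    stopf("meta-path '%s' must start at domain and end at disease", name)
  if (length(letters_) < 3L)
    stopf("meta-path '%s' must have length at least 2", name)
  for (k in seq_len(length(letters_) - 1L)) {
    pair <- letters_[c(k, k + 1L)]
    if (all(pair == "D"))
      stopf("meta-path '%s': no edge type D-D at position %d", name, k)
  }
  structure(list(name = name,
                 node_sequence = unname(LETTER_TYPE[letters_]),
                 length = length(letters_) - 1L),
            class = "metapath")
}

#' @export
print.metapath <- function(x, ...) {
  cat(sprintf("Meta-path %s (length %d): %s\n", x$name, x$length,
              paste(x$node_sequence, collapse = " -> ")))
  invisible(x)
}

#' The canonical meta-path registry
#'
#' Returns the fixed list of 37 domain-to-disease meta-paths used for
#' feature extraction: 2 of length 2, 4 of length 3, 11 of length 4, 10 of
#' length 5 (identified C1..C27) and 10 of length 6 (identified by their
#' letter sequence).  The list is a curated canonical set, not an
#' exhaustive enumeration of schema walks: some valid walks (e.g. DSSS)
#' are deliberately absent, so the registry is hard-coded rather than
#' generated.  [parse_metapath()] is available for user-defined extras.
#'
#' @param max_length Maximum meta-path length to include, between 2 and 6.
#'   `max_length = 5` gives the 27-path set behind Feature-I/Feature-II;
#'   `max_length = 3` and `4` give the 6- and 17-path subsets.
#' @return An object of class `metapath_registry`: list with `ids`
#'   (character vector) and `paths` (list of [parse_metapath()] objects).
#' @examples
#' length(canonical_registry(5)$paths)  # 27
#' @export
canonical_registry <- function(max_length = 5) {
  if (!is_number(max_length) || max_length < 2 || max_length > 6)
    stopf("max_length must be between 2 and 6")
  nm <- unlist(REGISTRY_NAMES[as.character(2:max_length)], use.names = FALSE)
  n27 <- sum(lengths(REGISTRY_NAMES[as.character(2:min(max_length, 5))]))
  ids <- c(paste0("C", seq_len(n27)),
           if (max_length == 6) REGISTRY_NAMES[["6"]])
  structure(list(ids = ids, paths = lapply(nm, parse_metapath)),
            class = "metapath_registry")
}

#' @export
length.metapath_registry <- function(x) length(x$paths)

#' @export
print.metapath_registry <- function(x, ...) {
  lens <- vapply(x$paths, `[[`, 0L, "length")
  cat(sprintf("Meta-path registry: %d paths (lengths %s)\n",
              length(x$paths),
              paste(sprintf("%d x %d", table(lens), as.integer(names(table(lens)))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.metapath_registry <- function(x, ...) {
  data.frame(id = x$ids,
             name = vapply(x$paths, `[[`, "", "name"),
             length = vapply(x$paths, `[[`, 0L, "length"),
             stringsAsFactors = FALSE)
}

#' Export a registry as JSON
#'
#' Writes `{id, name, node_sequence, length}` records.
#'
#' @param registry A [canonical_registry()].
#' @param path Output JSON file.
#' @export
write_registry_json <- function(registry, path) {
  recs <- lapply(seq_along(registry$paths), function(k) {
    p <- registry$paths[[k]]
    list(id = registry$ids[[k]], name = p$name,
         node_sequence = p$node_sequence, length = p$length)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Commuting matrix of a meta-path
#'
#' The commuting matrix of a meta-path is the left-to-right product of the
#' adjacency matrices along its edge sequence (with transposes taken as
#' needed for reversed edges).  Entry (i, j) counts the walks — concrete
#' node sequences following the meta-path's types, node revisits allowed —
#' from domain i to disease j.  Counts are exact integers; double-precision
#' accumulation is exact up to 2^53, far beyond any desk-scale network.
#'
#' @param network A `hetnet`.
#' @param path A [parse_metapath()] object or meta-path name.
#' @return A sparse |domain| x |disease| matrix of non-negative integer
#'   counts, with the meta-path attached as attribute `"metapath"`.
#' @export
commuting_matrix <- function(network, path) {
  stopifnot(inherits(network, "hetnet"))
  if (is.character(path)) path <- parse_metapath(path)
  stopifnot(inherits(path, "metapath"))
  seqs <- path$node_sequence
  m <- adjacency(network, seqs[1L], seqs[2L])
  if (length(seqs) > 2L) {
    for (k in 2:(length(seqs) - 1L))
      m <- m %*% adjacency(network, seqs[k], seqs[k + 1L])
  }
  m <- as(as(m, "generalMatrix"), "CsparseMatrix")
  attr(m, "metapath") <- path
  m
}

#' Count walks for one (domain, disease) pair by explicit enumeration
#'
#' Test oracle for [commuting_matrix()]: materializes every concrete walk
#' whose node types follow the meta-path and whose consecutive node pairs
#' are edges, by frontier expansion from the start domain, then counts the
#' walks ending at the given disease.  Nodes may repeat along a walk (the
#' matrix-product convention counts walks, not simple paths).  Intended for
#' tiny networks; refuses when the product of layer sizes along the path
#' exceeds 1e7 possible walks or when more than 1e6 walks materialize.
#'
#' @param network A `hetnet`.
#' @param path A [parse_metapath()] object or name.
#' @param domain_label,disease_label Node labels of the queried pair.
#' @return Integer walk count.
#' @export
brute_force_path_count <- function(network, path, domain_label, disease_label) {
  stopifnot(inherits(network, "hetnet"))
  if (is.character(path)) path <- parse_metapath(path)
  seqs <- path$node_sequence
  sizes <- vapply(seqs, function(t) length(network$nodes[[t]]), 0L)
  if (prod(as.numeric(sizes)) > 1e7)
    stopf("network too large for exhaustive walk enumeration (%.3g potential walks)",
          prod(as.numeric(sizes)))
  d <- match(domain_label, network$nodes$domain)
  s <- match(disease_label, network$nodes$disease)
  if (is.na(d)) stopf("unknown domain label '%s'", domain_label)
  if (is.na(s)) stopf("unknown disease label '%s'", disease_label)

  # walks: matrix, one row per partial walk of concrete node indices
  walks <- matrix(d, nrow = 1L)
  for (k in seq_len(length(seqs) - 1L)) {
    A <- adjacency(network, seqs[k], seqs[k + 1L])
    ends <- walks[, k]
    nbrs <- lapply(ends, function(e) which(A[e, ] != 0))
    reps <- lengths(nbrs)
    if (sum(reps) == 0L) return(0L)
    if (sum(reps) > 1e6)
      stopf("walk enumeration exceeded 1e6 partial walks")
    walks <- cbind(walks[rep(seq_len(nrow(walks)), reps), , drop = FALSE],
                   unlist(nbrs, use.names = FALSE))
  }
  sum(walks[, ncol(walks)] == s)
}

#' Write a commuting matrix as coordinate-format TSV
#'
#' Columns: `domain_id`, `disease_id`, `count`; one row per nonzero.
#'
#' @param cm A [commuting_matrix()] result.
#' @param path Output TSV file.
#' @export
write_commuting_matrix <- function(cm, path) {
  tr <- Matrix::summary(as(cm, "TsparseMatrix"))
  df <- data.frame(domain_id = rownames(cm)[tr$i],
                   disease_id = colnames(cm)[tr$j],
                   count = tr$x)
  df <- df[order(df$domain_id, df$disease_id), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
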