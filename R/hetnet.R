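## Heterogeneous network construction: three node sets (domain, protein,
## disease) and five binary sparse adjacency layers.

NODE_TYPES <- c("domain", "protein", "disease")

## Schema edge layers in their stored orientation (rows x columns).
EDGE_LAYERS <- list(
  DP = c("domain",  "protein"),
  PP = c("protein", "protein"),
  PS = c("protein", "disease"),
  SS = c("disease", "disease"),
  DS = c("domain",  "disease")
)

#' Resolve a (source, target) node-type pair to a stored layer
#'
#' @return list(key, transpose) or NULL when the pair is not a schema edge
#'   type (the only impossible pair is domain-domain).
#' @noRd
resolve_layer <- function(source_type, target_type) {
  for (key in names(EDGE_LAYERS)) {
    lay <- EDGE_LAYERS[[key]]
    if (identical(c(source_type, target_type), lay))
      return(list(key = key, transpose = FALSE))
    if (identical(c(target_type, source_type), lay))
      return(list(key = key, transpose = TRUE))
  }
  NULL
}

check_node_type <- function(type) {
  if (!is.character(type) || length(type) != 1L || !(type %in% NODE_TYPES))
    stopf("unknown node type '%s'; must be one of %s",
          paste(type, collapse = ","), paste(NODE_TYPES, collapse = ", "))
  type
}

#' Create an edge table in memory
#'
#' An edge table holds deduplicated (source, target) label pairs for one of
#' the five schema layers, optionally with a numeric weight used only for
#' thresholding at load time (the network itself is binary).
#'
#' @param source,target Character vectors of node labels (recycled to equal
#'   length is not allowed; they must match).
#' @param source_type,target_type Schema node types, among
#'   `"domain"`, `"protein"`, `"disease"`.
#' @param weight Optional numeric vector of edge weights.
#' @return An object of class `edge_table`: a data.frame with columns
#'   `source`, `target` (and `weight` if given) plus type attributes.
#' @seealso [read_edge_table()] to load from a TSV file.
#' @export
edge_table <- function(source, target, source_type, target_type, weight = NULL) {
  check_node_type(source_type)
  check_node_type(target_type)
  if (is.null(resolve_layer(source_type, target_type)))
    stopf("(%s, %s) is not a schema edge type", source_type, target_type)
  source <- as.character(source); target <- as.character(target)
  if (length(source) != length(target))
    stopf("source and target must have the same length")
  df <- data.frame(source = source, target = target, stringsAsFactors = FALSE)
  if (!is.null(weight)) df$weight <- as.numeric(weight)
  df <- df[!duplicated(df[, c("source", "target")]), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, source_type = source_type, target_type = target_type,
            class = c("edge_table", "data.frame"))
}

#' Load an edge table from a tab-separated file
#'
#' Lines starting with `#` and blank lines are ignored.  Each remaining
#' line must have two or three tab-separated fields:
#' `source_id<TAB>target_id[<TAB>weight]`.  When `min_weight` is given,
#' rows whose weight is below it are dropped (the threshold is inclusive,
#' as in keeping STRING interactions with combined score >= 400); rows
#' without a weight field are kept.  Duplicate (source, target) pairs are
#' collapsed to one record.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param source_type,target_type Schema node types of the columns.
#' @param min_weight Optional inclusive lower bound on the weight column.
#' @return An [edge_table()].
#' @export
read_edge_table <- function(path, source_type, target_type, min_weight = NULL) {
  if (!file.exists(path)) stopf("edge table file not found: %s", path)
  check_node_type(source_type)
  check_node_type(target_type)
  if (is.null(resolve_layer(source_type, target_type)))
    stopf("(%s, %s) is not a schema edge type", source_type, target_type)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep_line <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep_line)
  parts <- strsplit(lines[keep_line], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stopf("parse error at line %d of %s: expected 2 or 3 tab-separated fields, found %d",
          idx[bad[1L]], path, nf[bad[1L]])
  src <- vapply(parts, `[[`, "", 1L)
  tgt <- vapply(parts, `[[`, "", 2L)
  w <- rep(NA_real_, length(parts))
  has_w <- nf == 3L
  if (any(has_w)) {
    wchr <- vapply(parts[has_w], `[[`, "", 3L)
    wnum <- suppressWarnings(as.numeric(wchr))
    if (anyNA(wnum))
      stopf("parse error at line %d of %s: non-numeric weight '%s'",
            idx[has_w][which(is.na(wnum))[1L]], path,
            wchr[which(is.na(wnum))[1L]])
    w[has_w] <- wnum
  }
  if (!is.null(min_weight)) {
    keep <- is.na(w) | w >= min_weight
    src <- src[keep]; tgt <- tgt[keep]; w <- w[keep]
  }
  if (all(is.na(w))) w <- NULL
  edge_table(src, tgt, source_type, target_type, weight = w)
}

#' Build the global heterogeneous network
#'
#' Assembles the five binary sparse adjacency matrices (domain-protein,
#' protein-protein, protein-disease, disease-disease, domain-disease) from
#' edge tables.  Node indices are the union of labels seen, in first
#' appearance order.  Square layers (protein-protein, disease-disease) are
#' symmetrized — an edge listed in either orientation sets both entries —
#' and their diagonals are forced to zero, so self-similarity and
#' self-interaction never contribute degenerate path instances.
#'
#' @param edge_tables List of [edge_table()] objects, exactly one per
#'   schema layer; the domain-disease table may be omitted or empty (an
#'   all-zero reference layer).
#' @return An object of class `hetnet`: a list with `nodes` (character
#'   label vectors `$domain`, `$protein`, `$disease`) and `adj` (sparse
#'   0/1 matrices `$DP`, `$PP`, `$PS`, `$SS`, `$DS`).
#' @export
build_hetnet <- function(edge_tables) {
  if (inherits(edge_tables, "edge_table")) edge_tables <- list(edge_tables)
  keys <- vapply(edge_tables, function(et) {
    resolve_layer(attr(et, "source_type"), attr(et, "target_type"))$key
  }, "")
  if (anyDuplicated(keys))
    stopf("duplicate edge tables for layer %s", keys[duplicated(keys)][1L])
  missing <- setdiff(names(EDGE_LAYERS), keys)
  if (length(setdiff(missing, "DS")))
    stopf("missing edge table(s) for layer(s): %s",
          paste(setdiff(missing, "DS"), collapse = ", "))

  # Node universes in first-appearance order, with cross-type conflict check.
  nodes <- setNames(vector("list", 3L), NODE_TYPES)
  for (t in NODE_TYPES) nodes[[t]] <- character(0)
  seen_type <- new.env(parent = emptyenv())
  note <- function(labels, type) {
    for (lab in unique(labels)) {
      prev <- seen_type[[lab]]
      if (!is.null(prev) && prev != type)
        stopf("schema conflict: label '%s' appears as both %s and %s",
              lab, prev, type)
      assign(lab, type, envir = seen_type)
    }
    nodes[[type]] <<- c(nodes[[type]], setdiff(unique(labels), nodes[[type]]))
  }
  for (et in edge_tables) {
    st <- attr(et, "source_type"); tt <- attr(et, "target_type")
    note(et$source, st)
    note(et$target, tt)
  }

  adj <- list()
  for (key in names(EDGE_LAYERS)) {
    lay <- EDGE_LAYERS[[key]]
    rows <- nodes[[lay[1L]]]; cols <- nodes[[lay[2L]]]
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(rows), length(cols)),
                              dimnames = list(rows, cols))
    k <- match(key, keys)
    if (!is.na(k)) {
      et <- edge_tables[[k]]
      if (nrow(et)) {
        st <- attr(et, "source_type")
        flip <- !identical(st, lay[1L])   # table supplied in reversed orientation
        i <- match(if (flip) et$target else et$source, rows)
        j <- match(if (flip) et$source else et$target, cols)
        m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                  dims = c(length(rows), length(cols)),
                                  dimnames = list(rows, cols))
      }
    }
    if (lay[1L] == lay[2L]) {             # symmetrize, zero the diagonal
      m <- m + Matrix::t(m)
      Matrix::diag(m) <- 0
    }
    m <- as(as(Matrix::drop0(1 * (m != 0)), "generalMatrix"), "CsparseMatrix")
    adj[[key]] <- m
  }

  structure(list(nodes = nodes, adj = adj), class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  cat("Heterogeneous network:",
      length(x$nodes$domain), "domains,",
      length(x$nodes$protein), "proteins,",
      length(x$nodes$disease), "diseases\n")
  for (key in names(x$adj))
    cat(sprintf("  %s: %d x %d, %d edges\n", key,
                nrow(x$adj[[key]]), ncol(x$adj[[key]]),
                Matrix::nnzero(x$adj[[key]])))
  invisible(x)
}

#' Adjacency matrix between two node types
#'
#' Returns the stored layer, or its transpose when the pair is requested in
#' the reversed orientation (the inverse association matrix is the
#' transpose of the stored one).  The result must be treated as read-only.
#'
#' @param network A [build_hetnet()] object.
#' @param source_type,target_type Schema node types.
#' @return A sparse 0/1 matrix of dimension |source| x |target|.
#' @export
adjacency <- function(network, source_type, target_type) {
  stopifnot(inherits(network, "hetnet"))
  check_node_type(source_type)
  check_node_type(target_type)
  lay <- resolve_layer(source_type, target_type)
  if (is.null(lay))
    stopf("schema error: no edge type between %s and %s",
          source_type, target_type)
  m <- network$adj[[lay$key]]
  if (lay$transpose) Matrix::t(m) else m
}

#' Remove domain-disease reference edges
#'
#' Zeroes the listed entries of the domain-disease layer and leaves every
#' other layer untouched.  Removing an absent pair is a no-op, so deletion
#' is idempotent.  The input network is not modified.
#'
#' @param network A `hetnet`.
#' @param pairs Data frame (or 2-column matrix) of (domain label, disease
#'   label) pairs.
#' @return A new `hetnet` with the edges removed.
#' @export
remove_domain_disease_edges <- function(network, pairs) {
  stopifnot(inherits(network, "hetnet"))
  pf <- as_pair_frame(pairs)
  if (!nrow(pf)) return(network)
  di <- match(pf$domain, network$nodes$domain)
  si <- match(pf$disease, network$nodes$disease)
  bad <- which(is.na(di) | is.na(si))
  if (length(bad))
    stopf("unknown label in pair (%s, %s)", pf$domain[bad[1L]], pf$disease[bad[1L]])
  ds <- network$adj$DS
  ds[cbind(di, si)] <- 0
  network$adj$DS <- as(as(Matrix::drop0(ds), "generalMatrix"), "CsparseMatrix")
  network
}

#' Write a network as an edge-list directory
#'
#' Writes the five layers as TSV files plus a JSON manifest with node and
#' edge counts.  Square layers are written with each undirected edge once
#' (upper triangle).
#'
#' @param network A `hetnet`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hetnet <- function(network, dir) {
  stopifnot(inherits(network, "hetnet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(DP = "domain_protein.tsv", PP = "protein_protein.tsv",
             PS = "protein_disease.tsv", SS = "disease_disease.tsv",
             DS = "domain_disease.tsv")
  counts <- list()
  for (key in names(files)) {
    m <- network$adj[[key]]
    if (EDGE_LAYERS[[key]][1L] == EDGE_LAYERS[[key]][2L])
      m <- Matrix::triu(m)
    tr <- Matrix::summary(as(m, "TsparseMatrix"))
    df <- data.frame(source = rownames(network$adj[[key]])[tr$i],
                     target = colnames(network$adj[[key]])[tr$j])
    df <- df[order(df$source, df$target), , drop = FALSE]
    write.table(df, file.path(dir, files[[key]]), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    counts[[key]] <- nrow(df)
  }
  manifest <- list(
    node_counts = lapply(network$nodes, length),
    edge_counts = counts,
    files = as.list(files)
  )
  write_json_file(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a network from an edge-list directory written by [write_hetnet()]
#'
#' @param dir Directory containing the five layer TSVs.
#' @return A `hetnet`.
#' @export
read_hetnet <- function(dir) {
  files <- c(DP = "domain_protein.tsv", PP = "protein_protein.tsv",
             PS = "protein_disease.tsv", SS = "disease_disease.tsv",
             DS = "domain_disease.tsv")
  tabs <- lapply(names(files), function(key) {
    lay <- EDGE_LAYERS[[key]]
    read_edge_table(file.path(dir, files[[key]]), lay[1L], lay[2L])
  })
  build_hetnet(tabs)
}
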