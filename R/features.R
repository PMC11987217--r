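## Per-pair feature tables from commuting matrices, with optional
## random-walk (row) normalization.

#' Random-walk normalization of a commuting matrix
#'
#' Divides every entry by its row sum (the total number of path instances
#' leaving that domain under the meta-path), turning counts into
#' per-domain outgoing proportions in `[0, 1]`.  Rows that sum to zero are
#' left at zero, so the result stays sparse and bounded.
#'
#' @param cm A non-negative matrix (typically from [commuting_matrix()]).
#' @return A sparse matrix of the same shape with nonzero rows summing
#'   to 1.
#' @export
rw_normalize <- function(cm) {
  rs <- Matrix::rowSums(cm)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  out <- Matrix::Diagonal(x = inv) %*% cm
  out <- as(as(out, "generalMatrix"), "CsparseMatrix")
  dimnames(out) <- dimnames(cm)
  attr(out, "metapath") <- attr(cm, "metapath")
  out
}

## Row of a commuting matrix computed as a vector-adjacency chain product.
## Bit-identical to the full product's row; used for per-pair strict
## leakage masking without recomputing whole matrices.
pair_row_counts <- function(network, path, domain_index) {
  seqs <- path$node_sequence
  A1 <- adjacency(network, seqs[1L], seqs[2L])
  v <- A1[domain_index, , drop = FALSE]
  if (length(seqs) > 2L) {
    for (k in 2:(length(seqs) - 1L))
      v <- v %*% adjacency(network, seqs[k], seqs[k + 1L])
  }
  v
}

#' Assemble a per-pair feature table
#'
#' Computes, for each (domain, disease) pair, the path count under every
#' registry meta-path and (optionally) its random-walk normalized value.
#' Columns are in registry order, the counts block first and then the RW
#' block, so the count feature set is always a prefix of the combined one.
#' RW values are read from the row-normalized commuting matrix, i.e. the
#' normalization runs over the full disease universe, not just the queried
#' pairs.
#'
#' When the network carries strict leakage control (see
#' [leakage_controlled_network()] with `mask_mode = "strict"`), any
#' evaluated pair that still has its own domain-disease reference edge has
#' that single edge zeroed during its own feature computation.
#'
#' @param network A `hetnet`.
#' @param pairs Data frame (or 2-column matrix) of (domain, disease)
#'   labels.
#' @param registry A [canonical_registry()] (or compatible) registry.
#' @param mode `"counts"` for path counts only, `"counts+rw"` to append
#'   the RW-normalized block.
#' @param feature_set_name Stored on the result for provenance.
#' @return An object of class `feature_table`: a data.frame with columns
#'   `domain_id`, `disease_id` and one numeric column per feature, named
#'   `<pathname>_count` / `<pathname>_rw`.
#' @export
assemble_features <- function(network, pairs, registry,
                              mode = c("counts", "counts+rw"),
                              feature_set_name = "custom") {
  stopifnot(inherits(network, "hetnet"), inherits(registry, "metapath_registry"))
  mode <- match.arg(mode)
  pf <- as_pair_frame(pairs)
  di <- match(pf$domain, network$nodes$domain)
  si <- match(pf$disease, network$nodes$disease)
  bad <- which(is.na(di) | is.na(si))
  if (length(bad))
    stopf("unknown label in pair (%s, %s)", pf$domain[bad[1L]], pf$disease[bad[1L]])

  n <- nrow(pf)
  npath <- length(registry$paths)
  counts <- matrix(0, n, npath)
  rw <- if (mode == "counts+rw") matrix(0, n, npath) else NULL
  cms <- vector("list", npath)
  for (k in seq_len(npath)) {
    cm <- commuting_matrix(network, registry$paths[[k]])
    cms[[k]] <- cm
    if (n) counts[, k] <- cm[cbind(di, si)]
    if (!is.null(rw) && n) rw[, k] <- rw_normalize(cm)[cbind(di, si)]
  }

  # strict leakage: recompute rows for pairs whose own reference edge is
  # still present, with that one edge zeroed
  if (identical(attr(network, "leakage_mode"), "strict") && n) {
    has_edge <- which(network$adj$DS[cbind(di, si)] != 0)
    for (w in has_edge) {
      net2 <- network
      net2$adj$DS[di[w], si[w]] <- 0
      net2$adj$DS <- Matrix::drop0(net2$adj$DS)
      for (k in seq_len(npath)) {
        v <- pair_row_counts(net2, registry$paths[[k]], di[w])
        counts[w, k] <- v[1L, si[w]]
        if (!is.null(rw)) {
          tot <- sum(v)
          rw[w, k] <- if (tot > 0) v[1L, si[w]] / tot else 0
        }
      }
    }
  }

  names_ <- vapply(registry$paths, `[[`, "", "name")
  out <- data.frame(domain_id = pf$domain, disease_id = pf$disease,
                    stringsAsFactors = FALSE)
  cdf <- as.data.frame(counts)
  names(cdf) <- paste0(names_, "_count")
  out <- cbind(out, cdf)
  if (!is.null(rw)) {
    rdf <- as.data.frame(rw)
    names(rdf) <- paste0(names_, "_rw")
    out <- cbind(out, rdf)
  }
  rownames(out) <- NULL
  structure(out, class = c("feature_table", "data.frame"),
            feature_set_name = feature_set_name,
            registry_ids = registry$ids, mode = mode)
}

#' Named feature presets
#'
#' `TF1`..`TF4` are cumulative path-count sets by maximum meta-path length
#' 3, 4, 5, 6 (6, 17, 27, 37 columns).  `Feature-I` is the 27 raw counts
#' (same columns as TF3); `Feature-II` appends the 27 RW-normalized values
#' for 54 columns.
#'
#' @inheritParams assemble_features
#' @param preset One of `"Feature-I"`, `"Feature-II"`, `"TF1"`, `"TF2"`,
#'   `"TF3"`, `"TF4"`.
#' @return A [assemble_features()] feature table.
#' @export
feature_set <- function(network, pairs,
                        preset = c("Feature-I", "Feature-II",
                                   "TF1", "TF2", "TF3", "TF4")) {
  preset <- match.arg(preset)
  max_len <- switch(preset,
                    "TF1" = 3, "TF2" = 4, "TF3" = 5, "TF4" = 6,
                    "Feature-I" = 5, "Feature-II" = 5)
  mode <- if (preset == "Feature-II") "counts+rw" else "counts"
  assemble_features(network, pairs, canonical_registry(max_len),
                    mode = mode, feature_set_name = preset)
}

#' Numeric feature matrix of a feature table
#' @param ft A `feature_table`.
#' @return Numeric matrix without the id columns.
#' @export
feature_matrix <- function(ft) {
  stopifnot(inherits(ft, "feature_table") || is.data.frame(ft))
  keep <- setdiff(names(ft), c("domain_id", "disease_id", "label",
                               "origin", "split"))
  as.matrix(as.data.frame(ft)[, keep, drop = FALSE])
}

#' Write a feature table as CSV with a JSON provenance sidecar
#'
#' @param ft A `feature_table`.
#' @param path Output CSV path; the sidecar is written at `<path>.json`.
#' @param sidecar Write the sidecar? Default TRUE.
#' @export
write_feature_table <- function(ft, path, sidecar = TRUE) {
  write.csv(as.data.frame(ft), path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(feature_set_name = attr(ft, "feature_set_name"),
                 mode = attr(ft, "mode"),
                 registry_ids = attr(ft, "registry_ids"),
                 n_pairs = nrow(ft),
                 n_feature_columns = ncol(ft) - 2L)
    write_json_file(meta, paste0(path, ".json"))
  }
  invisible(path)
}
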