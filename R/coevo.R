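#' Filter residue-pair couplings at the lipid interface
#'
#' Applies the retention rules for lipid-interface co-evolution analysis: a
#' pair survives iff its coupling probability exceeds `min_prob` (strict),
#' the two residues are at least `min_separation` apart in sequence (pairs
#' closer than that - within about two helix turns - are discarded), at
#' least one member is a known lipid H-bond anchor, and neither member is
#' buried or exposed only to the aqueous vestibule.
#'
#' @param table A `coupling_table` (columns i, j, score, probability).
#' @param annotations data.frame with columns `residue`, `exposure`
#'   (one of "lipid_facing", "buried", "vestibule", "other") and
#'   `hbond_anchor` (logical); must cover every residue in candidate pairs.
#' @param min_prob Probability threshold (default 0.5, strict >).
#' @param min_separation Minimum |i - j| retained (default 8).
#' @return The retained rows of `table` (class preserved).
#' @export
filter_pairs <- function(table, annotations, min_prob = 0.5,
                         min_separation = 8L) {
  need <- c("residue", "exposure", "hbond_anchor")
  stopifnot(all(need %in% names(annotations)))
  resids <- unique(c(table$i, table$j))
  unk <- setdiff(resids, annotations$residue)
  if (length(unk))
    stop("unannotated residue(s) in candidate pairs: ",
         paste(sort(unk), collapse = ", "))
  look <- function(col, r) annotations[[col]][match(r, annotations$residue)]
  keep <- table$probability > min_prob &
    abs(table$i - table$j) >= min_separation &
    (look("hbond_anchor", table$i) | look("hbond_anchor", table$j)) &
    !look("exposure", table$i) %in% c("buried", "vestibule") &
    !look("exposure", table$j) %in% c("buried", "vestibule")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group retained pairs into interface clusters
#'
#' Connected components of the residue-sharing graph over retained pairs: a
#' pair joins a cluster when it shares a residue with a pair already in it;
#' pairs sharing no residue with any other pair form their own cluster.
#' Clusters are ordered (and numbered) by their smallest member residue, so
#' the result is independent of input order.
#'
#' @param pairs Retained pairs (data.frame with columns i, j).
#' @return List of `coevo_cluster` objects, each with `id`, `residues`
#'   (sorted), and `pairs` (data.frame).
#' @export
cluster_pairs <- function(pairs) {
  if (!nrow(pairs)) return(list())
  resids <- sort(unique(c(pairs$i, pairs$j)))
  parent <- seq_along(resids)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  ii <- match(pairs$i, resids); jj <- match(pairs$j, resids)
  for (k in seq_len(nrow(pairs))) union_(ii[k], jj[k])
  roots <- vapply(seq_along(resids), find, integer(1))
  comp_of_pair <- roots[ii]
  comp_ids <- sort(unique(roots))
  out <- lapply(seq_along(comp_ids), function(c) {
    sel <- comp_of_pair == comp_ids[c]
    p <- pairs[sel, , drop = FALSE]
    rownames(p) <- NULL
    structure(list(id = c, residues = sort(unique(c(p$i, p$j))), pairs = p),
              class = "coevo_cluster")
  })
  # order by smallest member residue (already implied by root = min index)
  ord <- order(vapply(out, function(cl) min(cl$residues), numeric(1)))
  out <- out[ord]
  for (k in seq_along(out)) out[[k]]$id <- k
  out
}

#' @export
print.coevo_cluster <- function(x, ...) {
  cat(sprintf("<coevo_cluster %d> %d residues, %d pairs: {%s}\n",
              x$id, length(x$residues), nrow(x$pairs),
              paste(x$residues, collapse = ", ")))
  invisible(x)
}

#' Filter and cluster in one call
#'
#' @inheritParams filter_pairs
#' @return List with `retained` (filtered pairs), `clusters` (list of
#'   `coevo_cluster`), and `fraction_retained` (share of input pairs kept -
#'   reported for comparison with alignment-level summaries, never used as
#'   a filter).
#' @export
coevo_clusters <- function(table, annotations, min_prob = 0.5,
                           min_separation = 8L) {
  retained <- filter_pairs(table, annotations, min_prob, min_separation)
  list(retained = retained, clusters = cluster_pairs(retained),
       fraction_retained = if (nrow(table)) nrow(retained) / nrow(table) else 0)
}

#' Write clusters as CSV and JSON
#' @param clusters List of `coevo_cluster`.
#' @param csv_path,json_path Output paths (either may be NULL to skip).
#' @export
write_clusters <- function(clusters, csv_path = NULL, json_path = NULL) {
  df <- if (length(clusters))
    do.call(rbind, lapply(clusters, function(cl)
      data.frame(cluster = cl$id, residue = cl$residues)))
  else data.frame(cluster = integer(), residue = integer())
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    obj <- lapply(clusters, function(cl)
      list(id = cl$id, residues = cl$residues,
           pairs = cl$pairs[, c("i", "j")]))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
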