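#' Generate a residue-pair coupling table with planted clusters
#'
#' Emulates the output of evolutionary-coupling inference: a table of residue
#' pairs (i, j) with a coupling score and probability. All within-cluster
#' pairs of each planted cluster receive probability > 0.5 and satisfy the
#' downstream retention rules; noise pairs either receive probability <= 0.5
#' or violate the sequence-separation rule, so a correctly implemented filter
#' recovers exactly the planted structure.
#'
#' The companion residue annotations (attached as attribute `"annotations"`
#' and also returned by [coupling_annotations()]) mark every planted residue
#' as lipid-facing with an H-bond anchor; all other residues are "other"
#' without anchor.
#'
#' @param n_residues Length of the protein chain.
#' @param planted_clusters List of integer vectors; clusters must be disjoint
#'   and each within-cluster pair at least `min_separation` apart in
#'   sequence.
#' @param noise_pairs Number of decoy pairs to add.
#' @param seed Integer seed.
#' @param min_separation Sequence-separation rule the planted pairs must
#'   satisfy (default 8).
#' @return data.frame of class `coupling_table` with columns i, j, score,
#'   probability, and attribute "annotations".
#' @export
generate_coupling_table <- function(n_residues, planted_clusters = list(),
                                    noise_pairs = 0, seed = 1L,
                                    min_separation = 8L) {
  all_planted <- unlist(planted_clusters)
  if (length(all_planted)) {
    if (any(all_planted < 1 | all_planted > n_residues))
      stop("planted cluster residues must lie in [1, n_residues]")
    if (anyDuplicated(all_planted))
      stop("planted clusters overlap: residue(s) ",
           paste(unique(all_planted[duplicated(all_planted)]), collapse = ", "))
  }
  with_seed(seed, {
    rows <- list()
    for (cl in planted_clusters) {
      cl <- sort(cl)
      if (length(cl) < 2) stop("planted clusters need >= 2 residues")
      cmb <- utils::combn(cl, 2)
      sep <- abs(cmb[2, ] - cmb[1, ])
      if (any(sep < min_separation))
        stop("planted pair closer than ", min_separation, " in sequence")
      rows[[length(rows) + 1L]] <- data.frame(
        i = cmb[1, ], j = cmb[2, ],
        score = stats::runif(ncol(cmb), 1, 3),
        probability = stats::runif(ncol(cmb), 0.55, 0.99))
    }
    planted_df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(i = integer(), j = integer(),
                 score = numeric(), probability = numeric())
    planted_key <- paste(planted_df$i, planted_df$j)
    made <- 0L; guard <- 0L
    noise <- list()
    while (made < noise_pairs && guard < 50 * noise_pairs + 100) {
      guard <- guard + 1L
      i <- sample.int(n_residues, 1L)
      close_decoy <- stats::runif(1) < 0.5
      j <- if (close_decoy) {
        jj <- i + sample(c(-(min_separation - 1):-1, 1:(min_separation - 1)), 1L)
        if (jj < 1 || jj > n_residues) next
        jj
      } else {
        sample.int(n_residues, 1L)
      }
      if (i == j) next
      lo <- min(i, j); hi <- max(i, j)
      if (paste(lo, hi) %in% planted_key) next
      prob <- if (close_decoy) stats::runif(1, 0.55, 0.95)  # fails separation
              else stats::runif(1, 0.01, 0.5)               # fails probability
      noise[[length(noise) + 1L]] <- data.frame(
        i = lo, j = hi, score = stats::runif(1, 0.1, 1.5), probability = prob)
      made <- made + 1L
    }
    tab <- rbind(planted_df,
                 if (length(noise)) do.call(rbind, noise) else NULL)
    if (is.null(tab)) tab <- planted_df
    rownames(tab) <- NULL
    ann <- data.frame(
      residue = seq_len(n_residues),
      exposure = ifelse(seq_len(n_residues) %in% all_planted,
                        "lipid_facing", "other"),
      hbond_anchor = seq_len(n_residues) %in% all_planted)
    attr(tab, "annotations") <- ann
    class(tab) <- c("coupling_table", "data.frame")
    tab
  })
}

#' Annotations attached to a generated coupling table
#' @param table A `coupling_table` from [generate_coupling_table()].
#' @return The annotations data.frame (residue, exposure, hbond_anchor).
#' @export
coupling_annotations <- function(table) {
  ann <- attr(table, "annotations")
  if (is.null(ann)) stop("table carries no annotations attribute")
  ann
}

#' Write / read coupling tables as EVcouplings-style CSV
#'
#' Columns i, j, score, probability with 1-based residue numbering.
#' @param table A `coupling_table` (or plain data.frame with those columns).
#' @param path CSV path.
#' @export
write_coupling_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("i", "j", "score", "probability")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coupling_csv
#' @export
read_coupling_csv <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("i", "j", "probability") %in% names(tab)))
  if (is.null(tab$score)) tab$score <- NA_real_
  if (any(tab$i == tab$j)) stop("self-pairs (i == j) are not allowed")
  if (any(tab$probability < 0 | tab$probability > 1))
    stop("probabilities must lie in [0, 1]")
  class(tab) <- c("coupling_table", "data.frame")
  tab
}
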