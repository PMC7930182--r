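#' PAM10 substitution matrix
#'
#' The low-divergence Dayhoff-family PAM10 log-odds scoring matrix over the
#' 20 standard amino acids, shipped as a plain-text data file with the
#' package (NCBI matrix-collection values). Used for CDR3 similarity, where
#' sequences are nearly identical and a shallow matrix is appropriate.
#'
#' @return A named 20x20 integer matrix.
#' @export
pam10_matrix <- function() {
  if (is.null(the$pam10)) {
    path <- system.file("extdata", "pam10.txt", package = "cx3score")
    m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                     check.names = FALSE, comment.char = "#"))
    storage.mode(m) <- "integer"
    the$pam10 <- m
  }
  the$pam10
}

#' Global alignment score with PAM10 and a linear gap penalty
#'
#' Needleman-Wunsch global alignment score of two amino-acid sequences under
#' the PAM10 substitution matrix with a linear gap model: every gap position
#' costs `gap` (default 30), with no separate opening/extension terms.
#'
#' @param a,b Non-empty amino-acid strings over the 20 standard residues.
#' @param gap Per-position gap penalty (a positive number; each indel
#'   contributes `-gap`).
#' @param matrix Substitution matrix, default [pam10_matrix()].
#' @return The optimal global alignment score.
#' @examples
#' pam10_align("CASSF", "CASSF")
#' @export
pam10_align <- function(a, b, gap = 30, matrix = pam10_matrix()) {
  ra <- split_residues(a, matrix, "a")
  rb <- split_residues(b, matrix, "b")
  la <- length(ra); lb <- length(rb)
  sub <- matrix[ra, rb, drop = FALSE]
  prev <- -gap * (0:lb)
  for (i in seq_len(la)) {
    cur <- numeric(lb + 1)
    cur[1] <- -gap * i
    for (j in seq_len(lb)) {
      cur[j + 1] <- max(prev[j] + sub[i, j], prev[j + 1] - gap, cur[j] - gap)
    }
    prev <- cur
  }
  prev[lb + 1]
}

split_residues <- function(x, matrix, arg) {
  if (!is.character(x) || length(x) != 1 || !nzchar(x)) {
    cx3_abort(sprintf("`%s` must be a single non-empty amino-acid string", arg))
  }
  res <- strsplit(x, "")[[1]]
  bad <- which(!res %in% rownames(matrix))
  if (length(bad)) {
    cx3_abort(sprintf("unknown residue '%s' at position %d of \"%s\"",
                      res[bad[1]], bad[1], x))
  }
  res
}

#' Alignment-based sequence distance
#'
#' Geometric-mean self-score normalization of the global alignment score:
#' `d(a, b) = 1 - S(a, b) / sqrt(S(a, a) * S(b, b))`. Zero at identity,
#' symmetric; may exceed 1 for strongly dissimilar pairs with negative
#' cross-scores.
#'
#' @inheritParams pam10_align
#' @return A non-negative distance.
#' @export
seq_distance <- function(a, b, gap = 30, matrix = pam10_matrix()) {
  saa <- pam10_align(a, a, gap, matrix)
  sbb <- pam10_align(b, b, gap, matrix)
  if (saa <= 0 || sbb <= 0) cx3_abort("non-positive self-alignment score")
  1 - pam10_align(a, b, gap, matrix) / sqrt(saa * sbb)
}

#' Pairwise distance matrix over CDR3 sequences
#'
#' Symmetric matrix of [seq_distance()] values with zero diagonal, plus an
#' optional per-sequence frequency weight vector carried as attribute
#' `weights` (used to size dendrogram leaves).
#'
#' @param seqs Character vector of unique amino-acid sequences.
#' @param weights Optional frequencies matching `seqs`.
#' @inheritParams pam10_align
#' @return A labelled numeric matrix with attribute `weights`.
#' @export
distance_matrix <- function(seqs, weights = NULL, gap = 30, matrix = pam10_matrix()) {
  if (anyDuplicated(seqs)) cx3_abort("`seqs` must be unique")
  n <- length(seqs)
  if (n < 2) cx3_abort("need at least two sequences")
  self <- vapply(seqs, function(s) pam10_align(s, s, gap, matrix), 0)
  d <- base::matrix(0, n, n, dimnames = list(seqs, seqs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- pam10_align(seqs[i], seqs[j], gap, matrix)
      d[i, j] <- d[j, i] <- 1 - s / sqrt(self[i] * self[j])
    }
  }
  if (!is.null(weights)) {
    if (length(weights) != n) cx3_abort("`weights` must match `seqs`")
    attr(d, "weights") <- setNames(weights, seqs)
  }
  d
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration with the midpoint height convention (two
#' items joined at distance `d` merge at height `d / 2`, so the tree is
#' ultrametric). Input rows are sorted by label before clustering so ties
#' resolve deterministically toward the smallest leaf label.
#'
#' @param d A symmetric distance matrix, e.g. from [distance_matrix()].
#' @return A list of class `cx3_dendrogram` with `hclust` (heights on the
#'   midpoint scale), `merge_heights`, `labels`, and `weights` (frequency
#'   weights when the matrix carries them).
#' @export
upgma_dendrogram <- function(d) {
  if (!is.matrix(d) || nrow(d) < 2 || nrow(d) != ncol(d)) {
    cx3_abort("`d` must be a square matrix with at least two leaves")
  }
  ord <- order(rownames(d))
  dm <- d[ord, ord]
  hc <- hclust(as.dist(dm), method = "average")
  hc$height <- hc$height / 2
  w <- attr(d, "weights")
  structure(list(hclust = hc, merge_heights = hc$height,
                 labels = hc$labels, weights = if (is.null(w)) NULL else w[hc$labels]),
            class = "cx3_dendrogram")
}

#' @export
print.cx3_dendrogram <- function(x, ...) {
  cat(sprintf("<cx3_dendrogram> %d leaves, root height %.4f\n",
              length(x$labels), max(x$merge_heights)))
  invisible(x)
}

#' Write a dendrogram as Newick
#'
#' Converts the UPGMA tree to an `ape` phylo (branch lengths on the midpoint
#' height scale) and writes Newick text.
#'
#' @param dend A [upgma_dendrogram()] result.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    cx3_abort("the `ape` package is required for Newick export", class = "cx3_internal_error")
  }
  phy <- ape::as.phylo(dend$hclust)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' ImmunoMap-style weighted repertoire dendrogram
#'
#' Takes the top-`n` productive CDR3 amino-acid sequences of one or two
#' repertoires, computes PAM10/gap-30 alignment distances, and clusters them
#' by UPGMA. Leaf weights are the (summed) frequencies of each sequence, and
#' an `origin` table records which repertoire(s) each sequence came from.
#'
#' @param reps A named list of one or two productive-filtered repertoires.
#' @param n Top sequences per repertoire, default 100.
#' @param gap Gap penalty, default 30.
#' @return A `cx3_dendrogram` with an extra `origin` tibble.
#' @export
repertoire_dendrogram <- function(reps, n = 100, gap = 30) {
  if (!is.list(reps) || is.data.frame(reps)) reps <- list(reps)
  if (is.null(names(reps)) || any(!nzchar(names(reps)))) {
    names(reps) <- paste0("rep", seq_along(reps))
  }
  tops <- lapply(reps, top_clonotypes, n = n)
  all_seq <- unique(unlist(lapply(tops, `[[`, "amino_acid")))
  freq <- vapply(all_seq, function(s) {
    sum(vapply(tops, function(t) {
      sum(t$frequency[t$amino_acid == s])
    }, 0))
  }, 0)
  origin <- tibble(
    amino_acid = all_seq,
    origin = vapply(all_seq, function(s) {
      paste(names(tops)[vapply(tops, function(t) s %in% t$amino_acid, TRUE)],
            collapse = "+")
    }, character(1))
  )
  dm <- distance_matrix(all_seq, weights = freq, gap = gap)
  dend <- upgma_dendrogram(dm)
  dend$origin <- origin
  dend
}
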