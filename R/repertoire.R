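#' Keep productive rearrangements and renormalize frequencies
#'
#' Diversity and overlap statistics are computed on productive rearrangements
#' only, keyed by nucleotide sequence; this drops all rows whose `status`
#' differs from `productive_value` and recomputes `frequency` as
#' `count / sum(count)` over the retained rows.
#'
#' @param rep A repertoire tibble (see [simulate_repertoire()] /
#'   [read_repertoire()]).
#' @param productive_value Status value marking productive rows, default
#'   `"In"`.
#' @return The filtered, renormalized repertoire tibble.
#' @export
filter_productive <- function(rep, productive_value = "In") {
  check_repertoire(rep)
  out <- rep[rep$status == productive_value, , drop = FALSE]
  if (nrow(out) == 0) cx3_abort("no productive rearrangements after filtering")
  out$frequency <- out$count / sum(out$count)
  out
}

#' TCR clonality (one minus Pielou evenness)
#'
#' `1 - H / log(R)` where `H` is the Shannon entropy of the clonotype
#' frequencies and `R` the number of unique clonotypes (the logarithm base
#' cancels). Values near 0 indicate an even repertoire, values near 1 a
#' highly skewed, near-monoclonal one. Undefined for a single clonotype
#' (returns `NA` with a warning).
#'
#' @param x A repertoire tibble (clonotypes keyed by `nucleotide`) or a
#'   numeric vector of frequencies/counts.
#' @return Clonality in `[0, 1]`, or `NA` when `R = 1`.
#' @examples
#' clonality(c(0.5, 0.25, 0.25))
#' @export
clonality <- function(x) {
  p <- clone_freqs(x)
  r <- length(p)
  if (r < 2) {
    warning("clonality is undefined for a single clonotype")
    return(NA_real_)
  }
  h <- -sum(p * log(p))
  1 - h / log(r)
}

#' Morisita overlap between two repertoires
#'
#' Default is the Morisita-Horn index on frequencies over the union of
#' clonotypes (keyed by nucleotide sequence):
#' `2 * sum(p * q) / (sum(p^2) + sum(q^2))`. The classic count-based
#' Morisita index is available with `variant = "classic"`. Both are 1 for
#' identical frequency vectors and 0 for disjoint clonotype sets.
#'
#' @param rep_a,rep_b Productive-filtered repertoire tibbles.
#' @param variant `"horn"` (default) or `"classic"`.
#' @param key Column keying clonotypes, default `"nucleotide"`.
#' @return Overlap value (in `[0, 1]` for `"horn"`).
#' @export
morisita_overlap <- function(rep_a, rep_b, variant = c("horn", "classic"),
                             key = "nucleotide") {
  variant <- match.arg(variant)
  check_repertoire(rep_a); check_repertoire(rep_b)
  if (nrow(rep_a) == 0 || nrow(rep_b) == 0) cx3_abort("empty repertoire")
  keys <- union(rep_a[[key]], rep_b[[key]])
  xa <- setNames(rep(0, length(keys)), keys)
  xb <- xa
  xa[rep_a[[key]]] <- rep_a$count
  xb[rep_b[[key]]] <- rep_b$count
  if (variant == "horn") {
    p <- xa / sum(xa); q <- xb / sum(xb)
    2 * sum(p * q) / (sum(p^2) + sum(q^2))
  } else {
    bigx <- sum(xa); bigy <- sum(xb)
    lx <- sum(xa * (xa - 1)) / (bigx * (bigx - 1))
    ly <- sum(xb * (xb - 1)) / (bigy * (bigy - 1))
    2 * sum(xa * xb) / ((lx + ly) * bigx * bigy)
  }
}

#' Gini index of the clone-size distribution
#'
#' Mean absolute difference form,
#' `G = sum_ij |f_i - f_j| / (2 R^2 mu)`, evaluated through the equivalent
#' sorted formula `G = 2 * sum(i * f_(i)) / (R * sum(f)) - (R + 1) / R`.
#' 0 for a perfectly even repertoire; approaches `(R - 1) / R` when a single
#' clone dominates.
#'
#' @inheritParams clonality
#' @return Gini index in `[0, 1)`.
#' @examples
#' gini_index(c(0.1, 0.2, 0.3, 0.4)) # 0.25
#' @export
gini_index <- function(x) {
  f <- sort(clone_freqs(x))
  r <- length(f)
  2 * sum(seq_len(r) * f) / (r * sum(f)) - (r + 1) / r
}

#' Lorenz curve of the clone-size distribution
#'
#' Clones sorted ascending by frequency; the curve runs from (0, 0) to
#' (1, 1) and is convex. The Gini index equals one minus twice the
#' trapezoidal area under this curve.
#'
#' @inheritParams clonality
#' @return A tibble with `cum_clones` and `cum_freq` (both starting at 0).
#' @export
lorenz_curve <- function(x) {
  f <- sort(clone_freqs(x))
  r <- length(f)
  tibble(
    cum_clones = seq(0, r) / r,
    cum_freq = c(0, cumsum(f)) / sum(f)
  )
}

#' Top clonotypes by aggregated amino-acid sequence
#'
#' Aggregates productive frequencies by CDR3 amino-acid sequence, sorts by
#' descending frequency with lexicographic tie-breaking, and returns the
#' first `n` (the ImmunoMap-style "top 100 productive sequences" selection).
#' When fewer than `n` unique sequences exist, all are returned and the
#' result carries attribute `short = TRUE`.
#'
#' @param rep A productive-filtered repertoire tibble.
#' @param n Number of sequences to keep, default 100.
#' @return A tibble `amino_acid`, `count`, `frequency` sorted by descending
#'   frequency.
#' @export
top_clonotypes <- function(rep, n = 100) {
  check_repertoire(rep)
  rep <- rep[nzchar(rep$amino_acid), , drop = FALSE]
  if (nrow(rep) == 0) cx3_abort("no amino-acid sequences present")
  agg <- dplyr::summarise(
    dplyr::group_by(rep, .data$amino_acid),
    count = sum(.data$count), frequency = sum(.data$frequency), .groups = "drop"
  )
  agg <- dplyr::arrange(agg, dplyr::desc(.data$frequency), .data$amino_acid)
  short <- nrow(agg) < n
  out <- head(agg, n)
  attr(out, "short") <- short
  out
}

#' Count exactly matched clonotypes between two top lists
#'
#' Exact string intersection of the amino-acid sequences of two top-N lists
#' (the dominant-motif sharing count).
#'
#' @param top_a,top_b Tibbles from [top_clonotypes()], or character vectors.
#' @return A list with `count` and `shared` (the shared sequences).
#' @export
shared_clonotypes <- function(top_a, top_b) {
  sa <- if (is.character(top_a)) top_a else top_a$amino_acid
  sb <- if (is.character(top_b)) top_b else top_b$amino_acid
  if (length(sa) == 0 || length(sb) == 0) cx3_abort("both lists must be non-empty")
  shared <- sort(intersect(sa, sb))
  list(count = length(shared), shared = shared)
}

# frequencies from a repertoire tibble (nucleotide-keyed) or numeric vector
clone_freqs <- function(x) {
  if (is.numeric(x)) {
    if (length(x) < 1 || any(x < 0) || sum(x) <= 0) {
      cx3_abort("frequencies must be non-negative with positive sum")
    }
    return(x / sum(x))
  }
  check_repertoire(x)
  if (nrow(x) == 0) cx3_abort("empty repertoire")
  x$count / sum(x$count)
}

check_repertoire <- function(rep) {
  needed <- c("nucleotide", "amino_acid", "count", "status")
  if (!is.data.frame(rep) || !all(needed %in% names(rep))) {
    cx3_abort(paste0("expected a repertoire tibble with columns ",
                     paste(needed, collapse = ", ")))
  }
  if (any(rep$count <= 0) || any(rep$count != floor(rep$count))) {
    cx3_abort("`count` must be positive integers")
  }
  invisible(TRUE)
}
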