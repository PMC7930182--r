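# Independent oracles used across the suite. These deliberately reimplement
# each quantity by brute force / first principles, never by calling the
# package code they check.

# log-rank O/E/V by direct hypergeometric tabulation over event times
logrank_oracle <- function(time, event, group) {
  group <- as.character(group)
  lv <- sort(unique(group))
  times <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == lv[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == lv[1])
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(observed = o, expected = e, variance = v,
       chi_square = (o - e)^2 / v)
}

# Kaplan-Meier product-limit by hand
km_oracle <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(0)
  for (t in times) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- c(out, s)
  }
  data.frame(time = times, surv = out)
}

# exhaustive global-alignment score by recursion over all alignments
align_enum <- function(a, b, gap, mat) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  rec2 <- function(i, j) {
    if (i > length(ra)) return(-gap * (length(rb) - j + 1))
    if (j > length(rb)) return(-gap * (length(ra) - i + 1))
    max(
      mat[ra[i], rb[j]] + rec2(i + 1, j + 1),
      -gap + rec2(i + 1, j),
      -gap + rec2(i, j + 1)
    )
  }
  rec2(1, 1)
}

# Gini by the O(R^2) pairwise mean-absolute-difference definition
gini_pairwise <- function(f) {
  r <- length(f)
  sum(abs(outer(f, f, "-"))) / (2 * r^2 * mean(f))
}

# Morisita-Horn directly from two named count vectors
morisita_oracle <- function(xa, xb) {
  keys <- union(names(xa), names(xb))
  a <- ifelse(keys %in% names(xa), xa[keys], 0)
  b <- ifelse(keys %in% names(xb), xb[keys], 0)
  p <- a / sum(a); q <- b / sum(b)
  2 * sum(p * q) / (sum(p^2) + sum(q^2))
}

# empirical AUC by looping over all responder x non-responder pairs
auc_pairs <- function(scores, responder) {
  x <- scores[responder]; y <- scores[!responder]
  tot <- 0
  for (xi in x) for (yj in y) tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}

# Youden by exhaustive search over distinct observed cutoffs; J is compared
# through the integer count form tp * n0 + tn * n1 so ties are exact
youden_brute <- function(scores, responder) {
  n1 <- sum(responder); n0 <- sum(!responder)
  cand <- sort(unique(scores))
  best <- -Inf; best_c <- NA
  for (c in cand) {
    jn <- sum(scores[responder] >= c) * n0 + sum(scores[!responder] < c) * n1
    if (jn > best) { best <- jn; best_c <- c }
  }
  list(cutoff = best_c, j = best / (n1 * n0) - 1)
}

make_small_roc_instance <- function(seed) {
  set.seed(seed)
  n1 <- sample(2:6, 1); n0 <- sample(2:6, 1)
  scores <- c(sample(0:10, n1, TRUE) + 0.5 * rbinom(n1, 1, 0.5),
              sample(0:10, n0, TRUE) + 0.5 * rbinom(n0, 1, 0.5))
  list(scores = scores, responder = rep(c(TRUE, FALSE), c(n1, n0)))
}

# responder truth lookup for a cohort's score table
responder_of <- function(cohort, score_tbl) {
  r <- stats::setNames(cohort$metadata$responder, cohort$metadata$patient_id)
  unname(r[score_tbl$patient_id])
}
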