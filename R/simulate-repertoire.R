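#' Simulate a clonally expanded TCR repertoire
#'
#' Clone sizes follow a discretized power law: the rank-`r` clonotype receives
#' weight `r^-power_exponent`, and `total_templates` templates are apportioned
#' to the weights by largest remainder with every clonotype keeping at least
#' one template, so counts are integers and sum exactly to `total_templates`.
#' CDR3 amino-acid sequences have the canonical `CASS...F` shape with uniform
#' interior residues; nucleotide sequences are random synonymous reverse
#' translations, making the nucleotide key unique per clonotype. All
#' clonotypes are productive (`status == "In"`) unless
#' `nonproductive_fraction > 0`, in which case that fraction of extra
#' out-of-frame rows (empty amino-acid sequence, status `"Out"`) is added.
#'
#' @param spec A [repertoire_spec()].
#' @return A tibble with columns `nucleotide`, `amino_acid`, `count`,
#'   `frequency`, `v_gene`, `j_gene`, `status`. Frequencies are
#'   `count / sum(count)` over all rows.
#' @examples
#' rep1 <- simulate_repertoire(repertoire_spec(n_clones = 50, total_templates = 1000))
#' sum(rep1$frequency)
#' @export
simulate_repertoire <- function(spec) {
  spec <- validate_repertoire_spec(spec)
  withr::with_seed(spec$seed, simulate_repertoire_impl(spec))
}

simulate_repertoire_impl <- function(spec) {
  n <- spec$n_clones
  counts <- power_law_counts(n, spec$total_templates, spec$power_exponent)
  aa <- random_cdr3(n, spec$cdr3_length_range)
  nt <- vapply(aa, reverse_translate, character(1))
  # regenerate on the (vanishingly rare) nucleotide collision
  while (anyDuplicated(nt)) {
    dup <- duplicated(nt)
    nt[dup] <- vapply(aa[dup], reverse_translate, character(1))
  }
  out <- tibble(
    nucleotide = unname(nt),
    amino_acid = aa,
    count = counts,
    v_gene = sample(sprintf("TCRBV%02d", 1:30), n, TRUE),
    j_gene = sample(sprintf("TCRBJ%02d", 1:13), n, TRUE),
    status = "In"
  )
  if (spec$nonproductive_fraction > 0) {
    n_np <- max(1L, round(n * spec$nonproductive_fraction))
    np_counts <- power_law_counts(n_np, max(n_np, round(sum(counts) *
      spec$nonproductive_fraction)), spec$power_exponent)
    np <- tibble(
      nucleotide = replicate(n_np, random_dna(3 * spec$cdr3_length_range[1])),
      amino_acid = "",
      count = np_counts,
      v_gene = sample(sprintf("TCRBV%02d", 1:30), n_np, TRUE),
      j_gene = sample(sprintf("TCRBJ%02d", 1:13), n_np, TRUE),
      status = "Out"
    )
    out <- dplyr::bind_rows(out, np)
  }
  out$frequency <- out$count / sum(out$count)
  out[, c("nucleotide", "amino_acid", "count", "frequency",
          "v_gene", "j_gene", "status")]
}

#' Simulate a pair of repertoires with controlled clonotype sharing
#'
#' The two repertoires share exactly `round(shared_fraction * min(n_clones))`
#' clonotype sequences; shared clonotypes occupy the top ranks of both
#' repertoires (the dominant, expanded clones are the shared ones), so the
#' expected Morisita-Horn overlap increases monotonically with
#' `shared_fraction`, reaching 1 for identical specs at `shared_fraction = 1`.
#'
#' @param spec_a,spec_b [repertoire_spec()]s for the two repertoires.
#' @param shared_fraction Proportion of the smaller repertoire's clonotypes
#'   shared between the two.
#' @return A list with elements `a` and `b`, each as in
#'   [simulate_repertoire()].
#' @export
simulate_paired_repertoires <- function(spec_a, spec_b, shared_fraction = 0) {
  spec_a <- validate_repertoire_spec(spec_a)
  spec_b <- validate_repertoire_spec(spec_b)
  chk_prob(shared_fraction, "shared_fraction")
  a <- simulate_repertoire(spec_a)
  b <- simulate_repertoire(spec_b)
  k <- round(shared_fraction * min(spec_a$n_clones, spec_b$n_clones))
  if (k > 0) {
    b$nucleotide[seq_len(k)] <- a$nucleotide[seq_len(k)]
    b$amino_acid[seq_len(k)] <- a$amino_acid[seq_len(k)]
  }
  list(a = a, b = b)
}

# largest-remainder apportionment of `total` templates to rank weights r^-alpha,
# each clone keeping at least one template
power_law_counts <- function(n, total, alpha) {
  w <- seq_len(n)^(-alpha)
  spare <- total - n
  exact <- spare * w / sum(w)
  base <- floor(exact)
  rem <- spare - sum(base)
  if (rem > 0) {
    take <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(1 + base)
}

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# standard codon table, one entry per amino acid
CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  K = c("AAA", "AAG"), M = "ATG", F = c("TTT", "TTC"),
  P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG", Y = c("TAT", "TAC"),
  V = c("GTT", "GTC", "GTA", "GTG")
)

random_cdr3 <- function(n, length_range) {
  lens <- sample(seq(length_range[1], length_range[2]), n, TRUE)
  vapply(lens, function(L) {
    paste0("CASS", paste(sample(AA20, L - 5, TRUE), collapse = ""), "F")
  }, character(1))
}

reverse_translate <- function(aa) {
  res <- strsplit(aa, "")[[1]]
  paste(vapply(res, function(a) {
    cods <- CODONS[[a]]
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
}
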