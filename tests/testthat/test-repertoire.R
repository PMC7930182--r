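make_rep <- function(counts, status = rep("In", length(counts)),
                     aa = sprintf("CASSAA%02dF", seq_along(counts))) {
  tibble::tibble(
    nucleotide = sprintf("NT%03d", seq_along(counts)),
    amino_acid = aa,
    count = as.integer(counts),
    frequency = counts / sum(counts),
    v_gene = "TCRBV01", j_gene = "TCRBJ01",
    status = status
  )
}

test_that("productive filtering renormalizes frequencies over retained counts", {
  r <- make_rep(c(10, 10, 20, 5, 5), status = c("In", "In", "In", "Out", "Out"))
  f <- filter_productive(r)
  expect_equal(nrow(f), 3)
  expect_equal(f$frequency, c(10, 10, 20) / 40)
  # half the template mass non-productive: retained frequencies double
  r2 <- make_rep(c(10, 10), status = c("In", "Out"))
  expect_equal(filter_productive(r2)$frequency, 1)
  expect_error(filter_productive(make_rep(5, status = "Out")), "productive")
  identical_in <- make_rep(c(3, 7))
  expect_equal(filter_productive(identical_in), identical_in)
})

test_that("clonality is 1 - Pielou evenness with its stated limits", {
  expect_equal(clonality(rep(1 / 7, 7)), 0)
  expect_equal(clonality(c(0.5, 0.25, 0.25)),
               1 - (-sum(c(.5, .25, .25) * log(c(.5, .25, .25)))) / log(3),
               tolerance = 1e-12)
  expect_lt(abs(clonality(c(0.5, 0.25, 0.25)) - 0.0536), 1e-4)
  expect_gt(clonality(c(0.999, 0.001)), 0.98)
  expect_warning(v <- clonality(1), "single clonotype")
  expect_true(is.na(v))
  # majorization: moving mass from the smallest to the largest clone
  # strictly increases clonality
  set.seed(8)
  for (i in 1:25) {
    f <- sort(rexp(10)); f <- f / sum(f)
    eps <- f[1] / 2
    g <- f; g[1] <- g[1] - eps; g[10] <- g[10] + eps
    expect_gt(clonality(g), clonality(f))
  }
})

test_that("Morisita-Horn overlap has its closed-form values and bounds", {
  a <- make_rep(c(50, 50))
  b <- a; b$count <- c(30L, 70L); b$frequency <- c(0.3, 0.7)
  expect_equal(morisita_overlap(a, a), 1)
  dis <- make_rep(c(10, 20)); dis$nucleotide <- c("X1", "X2")
  expect_equal(morisita_overlap(a, dis), 0)
  # A = {x: .5, y: .5}, B = {x: 1} -> 2 * .5 / (.5 + 1)
  bx <- make_rep(100); bx$nucleotide <- a$nucleotide[1]
  expect_equal(morisita_overlap(a, bx), 2 * 0.5 / 1.5, tolerance = 1e-12)
  expect_equal(morisita_overlap(a, bx), morisita_overlap(bx, a))
  # random pairs: symmetric, within [0, 1], matches the direct oracle
  set.seed(9)
  for (i in 1:20) {
    ra <- make_rep(sample(1:50, 6)); rb <- make_rep(sample(1:50, 6))
    rb$nucleotide[1:3] <- ra$nucleotide[1:3]
    m <- morisita_overlap(ra, rb)
    expect_equal(m, morisita_oracle(
      setNames(ra$count, ra$nucleotide), setNames(rb$count, rb$nucleotide)
    ), tolerance = 1e-12)
    expect_true(m >= 0 && m <= 1)
    expect_equal(m, morisita_overlap(rb, ra), tolerance = 1e-12)
  }
  # classic count-based variant matches its direct formula (it is slightly
  # above 1 for identical finite samples, unlike the Horn form)
  lam <- 2 * 50 * 49 / (100 * 99)
  expect_equal(morisita_overlap(a, a, variant = "classic"),
               2 * (50^2 + 50^2) / (2 * lam * 100 * 100), tolerance = 1e-12)
  expect_gt(morisita_overlap(a, a, variant = "classic"), 1)
})

test_that("Gini agrees with the pairwise oracle and the Lorenz area", {
  expect_equal(gini_index(rep(0.2, 5)), 0)
  expect_equal(gini_index(c(0.1, 0.2, 0.3, 0.4)), 0.25)
  expect_equal(gini_index(c(0.1, 0.2, 0.3, 0.4)),
               gini_pairwise(c(0.1, 0.2, 0.3, 0.4)))
  set.seed(10)
  for (i in 1:100) {
    f <- rexp(sample(3:40, 1)); f <- f / sum(f)
    g <- gini_index(f)
    expect_equal(g, gini_pairwise(f), tolerance = 1e-12)
    lor <- lorenz_curve(f)
    area <- sum(diff(lor$cum_clones) * (head(lor$cum_freq, -1) + lor$cum_freq[-1]) / 2)
    expect_lt(abs(g - (1 - 2 * area)), 1e-9)
  }
})

test_that("Lorenz curve runs from (0,0) to (1,1), convex, with exact interior points", {
  lor <- lorenz_curve(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(lor$cum_freq[lor$cum_clones == 0.5], 0.3)
  expect_equal(lor$cum_freq[1], 0); expect_equal(lor$cum_freq[5], 1)
  expect_true(all(diff(diff(lor$cum_freq)) >= -1e-12)) # convexity
  uni <- lorenz_curve(rep(1 / 6, 6))
  expect_equal(uni$cum_freq, uni$cum_clones)
})

test_that("top clonotypes aggregate by amino-acid sequence deterministically", {
  r <- make_rep(c(10, 30, 20, 40),
                aa = c("CASSXF", "CASSYF", "CASSXF", "CASSZF"))
  top <- top_clonotypes(r, n = 2)
  expect_equal(top$amino_acid, c("CASSZF", "CASSXF"))
  expect_equal(top$frequency[2], 0.3) # 10 + 20 of 100 aggregated
  all3 <- top_clonotypes(r, n = 100)
  expect_equal(nrow(all3), 3)
  expect_true(attr(all3, "short"))
  # frequency ties break lexicographically
  rt <- make_rep(c(10, 10), aa = c("CASSBF", "CASSAF"))
  expect_equal(top_clonotypes(rt, n = 2)$amino_acid, c("CASSAF", "CASSBF"))
  # top-100 of a big repertoire matches an independent sort
  big <- simulate_repertoire(repertoire_spec(n_clones = 500, total_templates = 50000,
                                             seed = 12))
  top100 <- top_clonotypes(big, n = 100)
  agg <- tapply(big$frequency, big$amino_acid, sum)
  expect_equal(sum(top100$frequency), sum(sort(agg, decreasing = TRUE)[1:100]),
               tolerance = 1e-12)
})

test_that("shared clonotype counting is exact string intersection", {
  expect_equal(shared_clonotypes(c("CASSAF", "CASSBF"), c("CASSCF"))$count, 0)
  expect_equal(shared_clonotypes(c("CASSAF", "CASSBF"),
                                 c("CASSBF", "CASSAF"))$count, 2)
  got <- shared_clonotypes(
    c("CASSPRLGDNYAEQFF", "CASSLVGNQDTQYF"),
    c("CASSLVGNQDTQYF", "CASSPGYAEQFF")
  )
  expect_equal(got$count, 1)
  expect_equal(got$shared, "CASSLVGNQDTQYF")
})
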