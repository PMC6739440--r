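code <- genetic_code()

test_that("codon counts are conserved and reject stops", {
  counts <- codon_counts("ATGATG")
  expect_equal(unname(counts[["ATG"]]), 2)
  expect_equal(sum(counts), 2)
  set.seed(2)
  seq <- paste(sample(code$sense_codons, 100, TRUE), collapse = "")
  expect_equal(sum(codon_counts(seq)), nchar(seq) / 3)
  expect_error(codon_counts("ATGTAA"), "stop")
})

test_that("GC by position matches hand counts and the string-based oracle", {
  gc <- gc_by_position("ATGGCGTTA")
  expect_equal(unname(gc[["gc3"]]), 2 / 3)   # third positions G, G, A
  gc_sat <- gc_by_position(strrep("GCG", 5))
  expect_equal(unname(gc_sat[c("gc1", "gc2", "gc3")]),
               c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(gc_by_position("ATGGCG")[["gc12"]],
               (gc_by_position("ATGGCG")[["gc1"]] +
                  gc_by_position("ATGGCG")[["gc2"]]) / 2)
  set.seed(3)
  for (i in 1:25) {
    seq <- paste(sample(code$sense_codons, 50, TRUE), collapse = "")
    got <- gc_by_position(seq)
    want <- oracle_gc_by_position(seq)
    expect_equal(unname(got[c("gc1", "gc2", "gc3")]), unname(want),
                 tolerance = 1e-12)
    # counts-based and string-based computations agree exactly
    expect_identical(got, gc_by_position(codon_counts(seq)))
  }
})

test_that("RSCU follows the family-normalised definition", {
  counts <- setNames(integer(61), code$sense_codons)
  counts[c("AAA", "AAG")] <- c(3, 1)       # Lys two-fold family
  r <- rscu(counts)
  expect_equal(unname(r[c("AAA", "AAG")]), c(1.5, 0.5))
  counts[c("AAA", "AAG")] <- c(4, 0)
  expect_equal(unname(rscu(counts)[c("AAA", "AAG")]), c(2, 0))
  # empty families are missing, not zero
  expect_true(all(is.na(rscu(counts)[c("GGA", "GGC", "GGG", "GGT")])))
  # uniform usage within every family gives RSCU 1 everywhere
  uniform <- setNames(rep(12L, 61), code$sense_codons)
  r_u <- rscu(uniform)
  expect_equal(unname(r_u), rep(1, 59))
  expect_length(r_u, 59)
  expect_false(any(c("ATG", "TGG") %in% names(r_u)))
})

test_that("RSCU family sums equal family size and match the oracle", {
  set.seed(7)
  for (i in 1:30) {
    counts <- random_counts(150)
    r <- rscu(counts)
    expect_equal(r, oracle_rscu(counts), tolerance = 1e-12)
    for (a in names(code$families)[code$degeneracy > 1]) {
      fam <- code$families[[a]]
      if (sum(counts[fam]) > 0)
        expect_equal(sum(r[fam]), length(fam), tolerance = 1e-9)
    }
  }
})

test_that("RSCU agrees with the seqinr reference implementation", {
  skip_if_not_installed("seqinr")
  set.seed(5)
  for (i in 1:10) {
    seq <- paste(sample(code$sense_codons, 120, TRUE), collapse = "")
    mine <- rscu(codon_counts(seq))
    ref <- seqinr::uco(seqinr::s2c(tolower(seq)), index = "rscu")
    expect_equal(unname(mine), unname(ref[tolower(names(mine))]),
                 tolerance = 1e-10)
  }
})

test_that("ENC hits its analytic boundaries", {
  # one codon per amino acid, each observed 10 times -> maximal bias, 20
  one_per_aa <- setNames(integer(61), code$sense_codons)
  for (fam in code$families) one_per_aa[fam[1]] <- 10L
  expect_equal(enc(one_per_aa), 20)
  # equal use of all 61 sense codons -> no bias, capped at 61
  even <- setNames(rep(100L, 61), code$sense_codons)
  expect_equal(enc(even), 61)
})

test_that("ENC matches the brute-force estimator and respects its range", {
  set.seed(11)
  for (i in 1:40) {
    counts <- random_counts(sample(30:200, 1))
    got <- enc(counts)
    want <- oracle_enc(counts)
    expect_equal(got, want, tolerance = 1e-12)
    if (!is.na(got)) {
      expect_gte(got, 20)
      expect_lte(got, 61)
    }
  }
  # scaling counts converges on the limiting estimator (F -> sum p^2)
  counts <- random_counts(600)  # large enough that every family is seen
  limit_f <- function(fam) {
    x <- counts[fam]
    sum((x / sum(x))^2)
  }
  f_lim <- vapply(names(code$families), function(a)
    limit_f(code$families[[a]]), numeric(1))
  cm <- function(k) mean(f_lim[code$degeneracy == k])
  enc_lim <- min(max(2 + 9 / cm(2) + 1 / cm(3) + 5 / cm(4) + 3 / cm(6),
                     20), 61)
  e10 <- enc(counts * 10L)
  e100 <- enc(counts * 100L)
  expect_lt(abs(e100 - enc_lim), abs(e10 - enc_lim) + 1e-12)
  expect_lt(abs(e100 - enc_lim), 0.15)
})

test_that("the mutation-pressure ENC curve evaluates and is near-symmetric", {
  expect_equal(enc_expected_curve(0.5), 60.5)
  expect_equal(enc_expected_curve(0), 31)
  expect_equal(enc_expected_curve(1), 32)
  # the rational term is exactly symmetric about 0.5
  s <- seq(0, 1, by = 0.05)
  term <- function(x) 29 / (x^2 + (1 - x)^2)
  expect_equal(term(s), term(1 - s))
  expect_error(enc_expected_curve(1.2))
})

test_that("neutrality regression recovers limiting slopes and flags degeneracy", {
  gc3 <- c(0.2, 0.4, 0.6, 0.8)
  flat <- neutrality_regression(gc3, rep(0.45, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  ident <- neutrality_regression(gc3, gc3)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$r, 1, tolerance = 1e-12)
  degen <- neutrality_regression(rep(0.5, 5), runif(5))
  expect_true(is.na(degen$slope))
  expect_match(degen$diagnostic, "variance")
  expect_error(neutrality_regression(c(0.1, 0.2), c(0.1, 0.2)), "3 points")
  # simulated genes with varying GC3 and constrained GC12 give a low slope
  cfg <- simulation_config(seed = 13, n_species = 1, n_cogs = 60,
                           protein_length = list(mean = 120, min = 40),
                           gc3_target = 0.45, gap_rate = 0)
  sim <- simulate_ortholog_set(cfg)
  tab <- composition_table(sim$cds[[1]])
  nr <- neutrality_regression(tab$gc3, tab$gc12)
  expect_lt(abs(nr$slope), 0.25)
})

test_that("codon-GC3 correlations match a direct Pearson oracle and split by codon ending", {
  set.seed(17)
  targets <- seq(0.25, 0.75, length.out = 8)
  sims <- lapply(targets, function(t) {
    cfg <- simulation_config(seed = round(t * 1000), n_species = 1,
                             n_cogs = 5,
                             protein_length = list(mean = 300, min = 40),
                             gc3_target = t, gap_rate = 0)
    cds <- simulate_ortholog_set(cfg)$cds[[1]]
    names(cds) <- paste0("t", t * 100, "_", names(cds))
    cds
  })
  seqs <- unlist(sims)
  tab <- composition_table(seqs)
  m <- rscu_matrix(tab)
  cc <- codon_gc3_correlations(m, tab$gc3)
  # direct oracle per codon
  for (cdn in sample(colnames(m), 10)) {
    ok <- is.finite(m[, cdn])
    want <- if (sum(ok) < 3 || var(m[ok, cdn]) == 0) NA_real_
    else cor(m[ok, cdn], tab$gc3[ok])
    expect_equal(unname(cc[[cdn]]), want, tolerance = 1e-12)
  }
  # GC-ended codons correlate positively with GC3, AT-ended negatively
  ending <- substr(names(cc), 3, 3) %in% c("G", "C")
  expect_gt(mean(cc[ending], na.rm = TRUE), 0.3)
  expect_lt(mean(cc[!ending], na.rm = TRUE), -0.3)
  # constant GC3 -> all missing
  cc0 <- codon_gc3_correlations(m, rep(0.5, nrow(m)))
  expect_true(all(is.na(cc0)))
})
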