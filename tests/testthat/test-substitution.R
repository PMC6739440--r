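code <- genetic_code()

test_that("amino-acid matrices count ordered pairs and transpose on swap", {
  a <- make_superseq("spA", "GCGGCG")   # peptide AA
  b <- make_superseq("spB", "GCGTCG")   # peptide AS
  m <- aa_substitution_matrix(a, b)
  expect_equal(m["A", "A"], 1)
  expect_equal(m["A", "S"], 1)
  expect_equal(sum(m), 2)
  expect_identical(aa_substitution_matrix(b, a), t(m))
  # identical peptides give a purely diagonal matrix
  m2 <- aa_substitution_matrix(a, a)
  expect_equal(sum(m2) - sum(diag(m2)), 0)
  expect_error(substitution_tables(a, make_superseq("spC", "GCG")),
               "length")
})

test_that("codon matrices agree with amino-acid matrices by aggregation", {
  a <- make_superseq("spA", "GCGGCG")
  b <- make_superseq("spB", "GCGTCG")
  tb <- substitution_tables(a, b)
  expect_equal(tb$codon_matrix["GCG", "GCG"], 1)
  expect_equal(tb$codon_matrix["GCG", "TCG"], 1)
  expect_equal(aggregate_codon_matrix(tb$codon_matrix), tb$aa_matrix)

  # on a simulated pair: totals conserved, aggregation exact
  cfg <- simulation_config(seed = 27, n_species = 2, n_cogs = 15,
                           protein_length = list(mean = 80, min = 40),
                           gc3_target = c(0.35, 0.65), aa_sub_rate = 0.07,
                           two_hit_theta = 0.5, gap_rate = 0.05)
  sim <- simulate_ortholog_set(cfg)
  sup <- sim_supersequences(sim)
  tb2 <- substitution_tables(sup[[1]], sup[[2]])
  expect_equal(sum(tb2$aa_matrix), tb2$n_positions)
  expect_equal(sum(tb2$codon_matrix), tb2$n_positions)
  expect_equal(aggregate_codon_matrix(tb2$codon_matrix), tb2$aa_matrix)
  expect_equal(tb2$n_positions, nchar(sup[[1]]$peptide))
})

test_that("usage-deviation chi-square follows the averaged-expectation formula", {
  a <- make_superseq("spA", strrep("GCG", 30))
  b <- make_superseq("spB", paste0(strrep("GCG", 10), strrep("TCG", 20)))
  res <- usage_deviation_test(substitution_tables(a, b))
  ala <- res[res$aa == "A", ]
  expect_equal(ala$count_1, 30)
  expect_equal(ala$count_2, 10)
  expect_equal(ala$expected, 20)
  expect_equal(ala$chi2, 10)       # (10^2/20) + (10^2/20)
  # equal counts give chi2 0 and p 1
  same <- usage_deviation_test(substitution_tables(a, a))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
})

test_that("reciprocal-asymmetry test matches hand and published-count arithmetic", {
  # build a pair with A->S 263 times and S->A 169 times
  codons <- c(rep(c("GCA", "TCA"), 263), rep(c("TCA", "GCA"), 169),
              rep(c("AAA", "AAA"), 50))
  a <- make_superseq("spA", paste(codons[c(TRUE, FALSE)], collapse = ""))
  b <- make_superseq("spB", paste(codons[c(FALSE, TRUE)], collapse = ""))
  res <- reciprocal_asymmetry_test(substitution_tables(a, b))
  as_row <- res[res$aa_1 == "A" & res$aa_2 == "S", ]
  expect_equal(as_row$count_12, 263)
  expect_equal(as_row$count_21, 169)
  expect_equal(as_row$expected, 216)
  expect_equal(as_row$chi2, 2 * 47^2 / 216, tolerance = 1e-12)
  expect_false(as_row$low_count)
  # balanced reciprocals give zero
  bal <- substitution_tables(
    make_superseq("spA", paste(rep(c("GCA", "TCA"), 5), collapse = "")),
    make_superseq("spB", paste(rep(c("TCA", "GCA"), 5), collapse = "")))
  res_bal <- reciprocal_asymmetry_test(bal)
  expect_equal(res_bal$chi2, 0)
  # tiny expected counts are flagged and never in the significant set
  tiny <- substitution_tables(make_superseq("spA", "GCATCAAAA"),
                              make_superseq("spB", "TCAGCAAAA"))
  res_tiny <- reciprocal_asymmetry_test(tiny)
  expect_true(all(res_tiny$low_count[res_tiny$expected < 5]))
  expect_false(any(res_tiny$significant[res_tiny$low_count]))
})

test_that("both chi-square tests match the textbook oracle on random counts", {
  set.seed(41)
  for (i in 1:100) {
    o <- sample(1:500, 2)
    got <- orthocodon:::chi2_two_cell(o[1], o[2])
    expect_equal(got$chi2, oracle_chi2(o[1], o[2]), tolerance = 1e-10)
    expect_equal(got$p,
                 stats::pchisq(oracle_chi2(o[1], o[2]), 1,
                               lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("codon-pair classification distinguishes conserved / synonymous / non-synonymous", {
  a <- make_superseq("spA", "GCGGCGAAA")
  b <- make_superseq("spB", "GCATCAAAA")
  cls <- classify_codon_pairs(a, b)
  gcg <- cls[cls$codon == "GCG", ]
  expect_equal(gcg$synonymous, 1)       # GCG -> GCA, 1 nt
  expect_equal(gcg$non_synonymous, 1)   # GCG -> TCA, 2 nt
  expect_equal(gcg$nt1, 1)
  expect_equal(gcg$nt2, 1)
  aaa <- cls[cls$codon == "AAA", ]
  expect_equal(aaa$conserved, 1)
  # identical super-sequences are all conserved
  cls2 <- classify_codon_pairs(a, a)
  expect_equal(sum(cls2$synonymous) + sum(cls2$non_synonymous), 0)
  expect_equal(sum(cls2$conserved), 3)
})

test_that("two-hit summary reproduces the printed Ala(GCG)->Ser breakdown", {
  m <- matrix(0L, 61, 61,
              dimnames = list(code$sense_codons, code$sense_codons))
  m["GCG", "TCG"] <- 6L
  m["GCG", "TCA"] <- 23L
  m["GCG", "TCT"] <- 15L
  m["GCG", "AGC"] <- 5L
  th <- two_hit_summary(m)
  row <- th[th$from_codon == "GCG" & th$to_aa == "S", ]
  expect_equal(row$n, 49)
  expect_equal(row$single_frac, 6 / 49)    # only TCG is one step away
  expect_gte(row$multi_frac, 38 / 49)
  expect_equal(row$baseline_multi_frac, 0)
  expect_equal(row$excess, 43 / 49)
  # a change whose only observed target is single-step has zero multi fraction
  m2 <- matrix(0L, 61, 61,
               dimnames = list(code$sense_codons, code$sense_codons))
  m2["AAA", "AGA"] <- 10L   # Lys -> Arg via one transition
  th2 <- two_hit_summary(m2)
  expect_equal(th2$multi_frac, 0)
  expect_equal(th2$excess, 0)
})

test_that("two-hit excess is exactly null without re-equilibration and detects it when present", {
  run_excess <- function(theta, seed) {
    cfg <- simulation_config(seed = seed, n_species = 2, n_cogs = 12,
                             protein_length = list(mean = 90, min = 40),
                             gc3_target = c(0.45, 0.45),
                             aa_sub_rate = 0.08, two_hit_theta = theta,
                             gap_rate = 0)
    sim <- simulate_ortholog_set(cfg)
    sup <- sim_supersequences(sim)
    attr(two_hit_summary(substitution_tables(sup[[1]], sup[[2]])),
         "overall_excess")
  }
  ex0 <- vapply(101:105, function(s) run_excess(0, s), numeric(1))
  ex1 <- vapply(101:105, function(s) run_excess(1, s), numeric(1))
  expect_equal(ex0, rep(0, 5))
  expect_true(all(ex1 > ex0))
})
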