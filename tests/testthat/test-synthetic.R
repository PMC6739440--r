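code <- genetic_code()

test_that("identical configurations reproduce identical simulations", {
  cfg <- simulation_config(seed = 99, n_species = 3, n_cogs = 8,
                           protein_length = list(mean = 60, min = 40),
                           gc3_target = c(0.3, 0.5, 0.7), gap_rate = 0.1)
  s1 <- simulate_ortholog_set(cfg)
  s2 <- simulate_ortholog_set(cfg)
  expect_identical(s1$cds, s2$cds)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$truth$provenance, s2$truth$provenance)
  # and the on-disk emission is byte-identical too
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_simulation(s1, d1, hit_tables = simulate_hit_tables(s1))
  write_simulation(s2, d2, hit_tables = simulate_hit_tables(s2))
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("realized GC3 tracks the target and is monotone across targets", {
  cfg <- simulation_config(seed = 55, n_species = 4, n_cogs = 30,
                           protein_length = list(mean = 120, min = 40),
                           gc3_target = c(0.3, 0.45, 0.6, 0.7),
                           gap_rate = 0)
  sim <- simulate_ortholog_set(cfg)
  realized <- vapply(sim$species, function(sp)
    gc_by_position(paste(sim$cds[[sp]], collapse = ""))[["gc3"]],
    numeric(1))
  expect_true(all(abs(realized - cfg$gc3_target) < 0.02))
  expect_true(all(diff(realized) > 0))
})

test_that("an unreachable GC3 target is rejected with the achievable range", {
  cfg <- simulation_config(seed = 1, n_species = 1, n_cogs = 1,
                           protein_length = list(mean = 50, min = 40),
                           gc3_target = 0.02, gap_rate = 0)
  expect_error(simulate_ortholog_set(cfg), "achievable range")
})

test_that("simulated CDS are clean and alignments carry the gap structure", {
  cfg <- simulation_config(seed = 77, n_species = 3, n_cogs = 10,
                           protein_length = list(mean = 60, min = 40),
                           gc3_target = c(0.3, 0.5, 0.7), gap_rate = 0.15)
  sim <- simulate_ortholog_set(cfg)
  for (sp in sim$species) {
    for (id in names(sim$cds[[sp]])) {
      v <- validate_cds(sim$cds[[sp]][[id]], code, id = id)
      expect_true(v$valid)
      expect_true(is.na(v$terminal_stop))  # emitted without stop codons
    }
  }
  # gaps exist at this rate, and every emitted gene appears exactly once
  n_gaps <- sum(vapply(sim$alignments, function(a)
    sum(strsplit(paste(a, collapse = ""), "")[[1]] == "-"), integer(1)))
  expect_gt(n_gaps, 0)
  expect_equal(anyDuplicated(sim$truth$orthology$gene_id), 0)
  # provenance covers every cog x site x species cell
  prov <- sim$truth$provenance
  expect_equal(nrow(prov), sum(vapply(sim$alignments, function(a)
    nchar(a[[1]]), integer(1))) * 3)
})

test_that("substitution provenance honours the two-hit switch", {
  cfg0 <- simulation_config(seed = 61, n_species = 2, n_cogs = 10,
                            protein_length = list(mean = 80, min = 40),
                            gc3_target = c(0.4, 0.6), aa_sub_rate = 0.1,
                            two_hit_theta = 0, gap_rate = 0)
  sim0 <- simulate_ortholog_set(cfg0)
  prov <- sim0$truth$provenance
  ns <- prov[prov$aa != prov$anc_aa, ]
  expect_gt(nrow(ns), 0)
  expect_true(all(ns$event == "single_hit"))
  # with theta 0 every non-synonymous change sits on the minimal path
  expect_true(all(ns$nt_diff_anc == ns$min_diff_anc))
  expect_true(all(ns$nt_diff_anc == 1))

  cfg1 <- simulation_config(seed = 61, n_species = 2, n_cogs = 10,
                            protein_length = list(mean = 80, min = 40),
                            gc3_target = c(0.4, 0.6), aa_sub_rate = 0.1,
                            two_hit_theta = 1, gap_rate = 0)
  sim1 <- simulate_ortholog_set(cfg1)
  ns1 <- sim1$truth$provenance
  ns1 <- ns1[ns1$aa != ns1$anc_aa, ]
  expect_true(all(ns1$event == "two_hit"))
  expect_gt(sum(ns1$nt_diff_anc >= 2), 0)
})

test_that("zero substitution rate yields identical proteins and a diagonal matrix", {
  cfg <- simulation_config(seed = 71, n_species = 2, n_cogs = 8,
                           protein_length = list(mean = 60, min = 40),
                           gc3_target = c(0.5, 0.5), aa_sub_rate = 0,
                           gap_rate = 0)
  sim <- simulate_ortholog_set(cfg)
  for (cg in names(sim$alignments))
    expect_equal(sim$alignments[[cg]][[1]], sim$alignments[[cg]][[2]])
  sup <- sim_supersequences(sim)
  m <- aa_substitution_matrix(sup[[1]], sup[[2]])
  expect_equal(sum(m) - sum(diag(m)), 0)
})

test_that("hit tables keep decoys strictly below the true best hit", {
  cfg <- simulation_config(seed = 81, n_species = 2, n_cogs = 25,
                           protein_length = list(mean = 60, min = 40),
                           gc3_target = 0.5, gap_rate = 0)
  sim <- simulate_ortholog_set(cfg)
  ht <- simulate_hit_tables(sim, decoy_rate = 0.5)
  h <- ht[["sp01__sp02"]]
  truth <- setNames(sim$truth$orthology$gene_id[
    sim$truth$orthology$species == "sp02"],
    sub("^sp02", "sp01", sim$truth$orthology$gene_id[
      sim$truth$orthology$species == "sp02"]))
  for (q in unique(h$qseqid)) {
    sub <- h[h$qseqid == q, ]
    true_e <- sub$evalue[sub$sseqid == truth[[q]]]
    others <- sub$evalue[sub$sseqid != truth[[q]]]
    if (length(others) > 0)
      expect_true(all(others >= 10 * true_e))
  }
  # a hand-planted hit at 1e-4 is filtered by the default cutoff
  planted <- h[1, ]
  planted$evalue <- 1e-4
  planted$qseqid <- "weird_query"
  expect_false("weird_query" %in% names(best_hits(rbind(h, planted))))
})

test_that("simulated expression is finite, non-negative and couples only when asked", {
  cfg <- simulation_config(seed = 91, n_species = 1, n_cogs = 40,
                           protein_length = list(mean = 60, min = 40),
                           gc3_target = 0.5, gap_rate = 0)
  sim <- simulate_ortholog_set(cfg)
  ex0 <- simulate_expression(sim, coupling = 0)
  expect_true(all(is.finite(ex0$expression) & ex0$expression >= 0))
  expect_identical(ex0$cds, sim$cds[[1]])   # no re-tilting at coupling 0
  ex1 <- simulate_expression(sim, coupling = 1, preferred_set = "GCC")
  changed <- ex1$cds != sim$cds[[1]]
  hi <- ex1$expression > quantile(ex1$expression, 0.9)
  expect_true(any(changed))
  expect_true(all(changed[!hi] == FALSE))   # only high genes re-emitted
})
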