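#' Asymmetric substitution tables for one ordered species pair
#'
#' From two equal-length, gap-free super-sequences, counts every aligned
#' position into a 20 x 20 amino-acid matrix and a 61 x 61 codon matrix.
#' Cell `[Z, X]` counts positions where the first species shows `Z` and
#' the second shows `X`; the matrices are asymmetric by construction and
#' rows always belong to the first-named species. Aggregating the codon
#' matrix by encoded amino acid reproduces the amino-acid matrix exactly.
#'
#' @param super_a,super_b `super_sequence` objects (see
#'   [concatenate_superseqs()]), or plain lists with `species`, `peptide`
#'   and `codons`.
#' @param code a [genetic_code()].
#' @return object of class `substitution_tables`: list with
#'   `species_pair` (ordered), `aa_matrix`, `codon_matrix` and
#'   `n_positions`.
#' @export
substitution_tables <- function(super_a, super_b, code = genetic_code()) {
  if (nchar(super_a$peptide) != nchar(super_b$peptide))
    stop("super-sequences differ in length")
  aa_a <- strsplit(super_a$peptide, "", fixed = TRUE)[[1]]
  aa_b <- strsplit(super_b$peptide, "", fixed = TRUE)[[1]]
  cod_a <- split_codons(super_a$codons)
  cod_b <- split_codons(super_b$codons)
  if (any(c(aa_a, aa_b) == "-") || any(c(cod_a, cod_b) == "---"))
    stop("super-sequences must be gap-free")
  lv_aa <- code$amino_acids
  lv_cod <- code$sense_codons
  if (any(!aa_a %in% lv_aa) || any(!aa_b %in% lv_aa))
    stop("stop or unknown amino-acid symbol in super-peptide")
  count_matrix <- function(x, y, lv) {
    m <- unclass(as.matrix(table(factor(x, lv), factor(y, lv))))
    dimnames(m) <- list(lv, lv)
    m
  }
  structure(
    list(species_pair = c(super_a$species, super_b$species),
         aa_matrix = count_matrix(aa_a, aa_b, lv_aa),
         codon_matrix = count_matrix(cod_a, cod_b, lv_cod),
         n_positions = length(aa_a)),
    class = "substitution_tables"
  )
}

#' @export
print.substitution_tables <- function(x, ...) {
  cat(sprintf(
    "substitution_tables %s x %s: %d positions, %d conserved aa\n",
    x$species_pair[1], x$species_pair[2], x$n_positions,
    sum(diag(x$aa_matrix))))
  invisible(x)
}

#' @rdname substitution_tables
#' @return `aa_substitution_matrix()` and `codon_substitution_matrix()`
#'   return the bare count matrix.
#' @export
aa_substitution_matrix <- function(super_a, super_b, code = genetic_code()) {
  substitution_tables(super_a, super_b, code)$aa_matrix
}

#' @rdname substitution_tables
#' @export
codon_substitution_matrix <- function(super_a, super_b,
                                      code = genetic_code()) {
  substitution_tables(super_a, super_b, code)$codon_matrix
}

#' Aggregate a codon substitution matrix by encoded amino acid
#'
#' @param codon_matrix 61 x 61 count matrix with codon dimnames.
#' @param code a [genetic_code()].
#' @return 20 x 20 amino-acid count matrix.
#' @export
aggregate_codon_matrix <- function(codon_matrix, code = genetic_code()) {
  aa_row <- translate_codon(rownames(codon_matrix), code)
  aa_col <- translate_codon(colnames(codon_matrix), code)
  lv <- code$amino_acids
  out <- rowsum(codon_matrix, aa_row)
  out <- t(rowsum(t(out), aa_col))
  out[lv, lv]
}

chi2_two_cell <- function(o1, o2) {
  e <- (o1 + o2) / 2
  chi2 <- (o1 - e)^2 / e + (o2 - e)^2 / e
  list(expected = e, chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Chi-square test of amino-acid usage deviation between a species pair
#'
#' For each amino acid, its total count in species 1 (row sum) and in
#' species 2 (column sum) are compared against their average as the
#' expected value: `chi2 = (c1-e)^2/e + (c2-e)^2/e`, df = 1. Amino acids
#' with zero total in both species are skipped. Raw p-values are reported
#' alongside Benjamini-Hochberg adjusted ones; cells with expected count
#' below 5 are flagged `low_count`.
#'
#' @param tables a [substitution_tables()] object.
#' @return data.frame per tested amino acid: `aa`, `count_1`, `count_2`,
#'   `expected`, `chi2`, `p`, `p_adj`, `low_count`.
#' @export
usage_deviation_test <- function(tables) {
  c1 <- rowSums(tables$aa_matrix)
  c2 <- colSums(tables$aa_matrix)
  keep <- (c1 + c2) > 0
  aa <- names(c1)[keep]
  tst <- chi2_two_cell(c1[keep], c2[keep])
  out <- data.frame(aa = aa, count_1 = unname(c1[keep]),
                    count_2 = unname(c2[keep]),
                    expected = unname(tst$expected),
                    chi2 = unname(tst$chi2), p = unname(tst$p),
                    stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$low_count <- out$expected < 5
  out
}

#' Chi-square test of reciprocal substitution asymmetry
#'
#' For every unordered amino-acid pair \{Z, X\} (Z != X) with at least one
#' observed change, the reciprocal counts `A[Z, X]` and `A[X, Z]` are
#' compared against their average as expected value (df = 1). Pairs with
#' expected count below 5 are flagged `low_count` and excluded from the
#' default significant set. BH adjustment across tested pairs.
#'
#' @param tables a [substitution_tables()] object.
#' @return data.frame per tested pair: `aa_1`, `aa_2`, `count_12`
#'   (`aa_1` in species 1, `aa_2` in species 2), `count_21`, `expected`,
#'   `chi2`, `p`, `p_adj`, `low_count`, `significant`.
#' @param alpha adjusted-p threshold for the `significant` flag.
#' @export
reciprocal_asymmetry_test <- function(tables, alpha = 0.05) {
  m <- tables$aa_matrix
  aa <- rownames(m)
  rows <- list()
  for (i in seq_along(aa)) {
    for (j in seq_along(aa)) {
      if (j <= i) next
      o12 <- m[aa[i], aa[j]]
      o21 <- m[aa[j], aa[i]]
      if (o12 + o21 == 0) next
      rows[[length(rows) + 1L]] <-
        data.frame(aa_1 = aa[i], aa_2 = aa[j],
                   count_12 = o12, count_21 = o21,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(aa_1 = character(0), aa_2 = character(0),
                      count_12 = integer(0), count_21 = integer(0),
                      expected = numeric(0), chi2 = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      low_count = logical(0), significant = logical(0)))
  out <- do.call(rbind, rows)
  tst <- chi2_two_cell(out$count_12, out$count_21)
  out$expected <- tst$expected
  out$chi2 <- tst$chi2
  out$p <- tst$p
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$low_count <- out$expected < 5
  out$significant <- !out$low_count & out$p_adj < alpha
  out
}

#' Classify aligned codon pairs as conserved / synonymous / non-synonymous
#'
#' Per source codon (first species), counts of conserved partners
#' (identical codon), synonymous substitutions (different codon, same
#' amino acid) and non-synonymous changes, plus the histogram of
#' nucleotide differences — the stacked-bar data of the substitution-state
#' summary.
#'
#' @param super_a,super_b `super_sequence` objects.
#' @param code a [genetic_code()].
#' @return data.frame with one row per sense codon: `codon`, `aa`,
#'   `conserved`, `synonymous`, `non_synonymous`, `nt0`..`nt3`.
#' @export
classify_codon_pairs <- function(super_a, super_b, code = genetic_code()) {
  cod_a <- split_codons(super_a$codons)
  cod_b <- split_codons(super_b$codons)
  if (length(cod_a) != length(cod_b))
    stop("super-sequences differ in length")
  aa_a <- translate_codon(cod_a, code)
  aa_b <- translate_codon(cod_b, code)
  d <- nucleotide_diff(cod_a, cod_b)
  status <- ifelse(d == 0L, "conserved",
                   ifelse(aa_a == aa_b, "synonymous", "non_synonymous"))
  lv <- code$sense_codons
  tab <- table(factor(cod_a, lv),
               factor(status, c("conserved", "synonymous",
                                "non_synonymous")))
  nt <- table(factor(cod_a, lv), factor(d, 0:3))
  out <- data.frame(codon = lv, aa = translate_codon(lv, code),
                    conserved = as.integer(tab[, "conserved"]),
                    synonymous = as.integer(tab[, "synonymous"]),
                    non_synonymous = as.integer(tab[, "non_synonymous"]),
                    nt0 = as.integer(nt[, "0"]), nt1 = as.integer(nt[, "1"]),
                    nt2 = as.integer(nt[, "2"]), nt3 = as.integer(nt[, "3"]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Two-hit (double-substitution) analysis of non-synonymous changes
#'
#' For each ordered amino-acid change Z -> X and each source codon c of Z,
#' the observed target codons of X are split into those reachable from c by
#' a single nucleotide substitution versus those needing two or more. The
#' single-step-favouring baseline assumes the target is always a
#' minimal-nucleotide-difference codon of X (ties split equally), so its
#' multi-step fraction is 0 whenever a one-step target exists. The excess
#' (observed minus baseline multi-step fraction) quantifies how often the
#' derived codon has moved beyond the minimal mutational path — the
#' signature of a non-synonymous hit followed by a synonymous
#' GC-restoring hit.
#'
#' @param x a [substitution_tables()] object, or a bare 61 x 61 codon
#'   count matrix with codon dimnames.
#' @param code a [genetic_code()].
#' @return data.frame with one row per (source codon, target amino acid)
#'   cell with observations: `from_aa`, `to_aa`, `from_codon`, `n`,
#'   `single_step`, `multi_step`, `single_frac`, `multi_frac`,
#'   `baseline_multi_frac`, `excess`. Attribute `overall_excess` is the
#'   observation-weighted mean excess over all rows.
#' @export
two_hit_summary <- function(x, code = genetic_code()) {
  m <- if (inherits(x, "substitution_tables")) x$codon_matrix else x
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  aa_row <- translate_codon(rownames(m), code)
  aa_col <- translate_codon(colnames(m), code)
  rows <- list()
  for (i in seq_len(nrow(m))) {
    z <- aa_row[i]
    from <- rownames(m)[i]
    for (xaa in code$amino_acids) {
      if (xaa == z) next
      targets <- colnames(m)[aa_col == xaa]
      obs <- m[i, targets]
      n <- sum(obs)
      if (n == 0) next
      d <- nucleotide_diff(rep(from, length(targets)), targets)
      single <- sum(obs[d == 1L])
      multi <- sum(obs[d >= 2L])
      min_d <- min(d)
      baseline_multi <- if (min_d == 1L) 0 else 1
      rows[[length(rows) + 1L]] <- data.frame(
        from_aa = z, to_aa = xaa, from_codon = from, n = n,
        single_step = single, multi_step = multi,
        single_frac = single / n, multi_frac = multi / n,
        baseline_multi_frac = baseline_multi,
        excess = multi / n - baseline_multi,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(from_aa = character(0), to_aa = character(0),
                      from_codon = character(0), n = numeric(0),
                      single_step = numeric(0), multi_step = numeric(0),
                      single_frac = numeric(0), multi_frac = numeric(0),
                      baseline_multi_frac = numeric(0), excess = numeric(0))
    attr(out, "overall_excess") <- NA_real_
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "overall_excess") <- sum(out$excess * out$n) / sum(out$n)
  out
}
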