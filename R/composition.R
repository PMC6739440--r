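#' Sense-codon counts of a coding sequence
#'
#' @param seq a validated CDS (no stop codons).
#' @param code a [genetic_code()].
#' @return named integer vector over the code's sense codons (sorted).
#' @export
codon_counts <- function(seq, code = genetic_code()) {
  codons <- split_codons(seq)
  aa <- translate_codon(codons, code)
  if (any(aa == "*"))
    stop("stop codon in sequence at codon ", which(aa == "*")[1])
  counts <- table(factor(codons, levels = code$sense_codons))
  stats::setNames(as.integer(counts), code$sense_codons)
}

#' GC fraction by codon position
#'
#' `gc1`/`gc2`/`gc3` are the fractions of G or C at codon positions 1-3
#' over all sense codons; `gc12` is the mean of `gc1` and `gc2`. Computed
#' from codon counts, so a sequence and its count vector agree exactly.
#'
#' @param x a CDS string or a named codon-count vector (names = codons).
#' @param code a [genetic_code()].
#' @return named numeric vector `c(gc1, gc2, gc3, gc12)`; all `NA` when
#'   there are zero codons.
#' @export
gc_by_position <- function(x, code = genetic_code()) {
  counts <- if (is.character(x)) codon_counts(x, code) else x
  n <- sum(counts)
  if (n == 0L)
    return(c(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_,
             gc12 = NA_real_))
  codons <- names(counts)
  gc <- vapply(1:3, function(p) {
    is_gc <- substr(codons, p, p) %in% c("G", "C")
    sum(counts[is_gc]) / n
  }, numeric(1))
  c(gc1 = gc[1], gc2 = gc[2], gc3 = gc[3], gc12 = (gc[1] + gc[2]) / 2)
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon j of an amino acid with k synonymous codons and family counts
#' x, `RSCU_j = x_j / mean(x)`. Methionine and tryptophan (single-codon
#' families) are excluded, giving a 59-entry vector under the standard
#' code. Families with zero total are missing (`NA`), not zero.
#'
#' @param counts named codon-count vector from [codon_counts()].
#' @param code a [genetic_code()].
#' @return named numeric vector over the multi-codon sense codons.
#' @export
rscu <- function(counts, code = genetic_code()) {
  multi <- code$families[code$degeneracy > 1L]
  out <- unlist(lapply(multi, function(fam) {
    x <- counts[fam]
    tot <- sum(x)
    if (tot == 0L) return(stats::setNames(rep(NA_real_, length(fam)), fam))
    stats::setNames(as.numeric(x) / (tot / length(fam)), fam)
  }), use.names = TRUE)
  names(out) <- sub("^[^.]*\\.", "", names(out))
  out[sort(names(out))]
}

#' Wright's effective number of codons (ENC)
#'
#' Per amino acid a with `n_a >= 2` observations, the homozygosity is
#' `F_a = (n_a * sum(p_i^2) - 1) / (n_a - 1)`. Class means `F_k` are taken
#' over amino acids of each degeneracy class with a defined `F`, and
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. If the 3-fold class mean is
#' undefined it is imputed as `(F2 + F4)/2`. The estimate is capped into
#' `[20, 61]`; if any required class mean is zero or undefined after
#' imputation the result is missing (`NA`).
#'
#' @param counts named codon-count vector from [codon_counts()].
#' @param code a [genetic_code()].
#' @return a single numeric ENC value in `[20, 61]`, or `NA`.
#' @export
enc <- function(counts, code = genetic_code()) {
  deg <- code$degeneracy
  f_by_aa <- vapply(names(code$families), function(a) {
    x <- as.numeric(counts[code$families[[a]]])
    n <- sum(x)
    if (n < 2) return(NA_real_)
    p <- x / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  class_mean <- function(k) {
    f <- f_by_aa[deg == k]
    f <- f[!is.na(f)]
    if (length(f) == 0L) NA_real_ else mean(f)
  }
  f2 <- class_mean(2L)
  f3 <- class_mean(3L)
  f4 <- class_mean(4L)
  f6 <- class_mean(6L)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  fs <- c(f2, f3, f4, f6)
  if (anyNA(fs) || any(fs == 0)) return(NA_real_)
  val <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(max(val, 20), 61)
}

#' Expected ENC under pure GC3 mutation pressure
#'
#' The null "bell curve" relating third-position GC content `s` to the
#' effective number of codons in the absence of selection:
#' `ENC(s) = 2 + s + 29 / (s^2 + (1 - s)^2)`.
#'
#' @param s GC3 fraction(s) in `[0, 1]`; vectorised.
#' @return expected ENC value(s).
#' @examples
#' enc_expected_curve(0.5)  # 60.5
#' @export
enc_expected_curve <- function(s) {
  stopifnot(all(s >= 0 & s <= 1))
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of `gc12` on `gc3` over genes (or over species
#' super-genes for the species-level "pseudo" plot). A slope near 1 is the
#' neutral (mutation-driven) limit; a slope near 0 indicates positions 1-2
#' are constrained relative to position 3.
#'
#' @param gc3,gc12 numeric vectors of equal length (>= 3 points).
#' @return list with `slope`, `intercept`, `r` (Pearson correlation) and
#'   `n`; slope is `NA` with a `diagnostic` message when `gc3` variance is
#'   degenerate.
#' @export
neutrality_regression <- function(gc3, gc12) {
  ok <- is.finite(gc3) & is.finite(gc12)
  gc3 <- gc3[ok]; gc12 <- gc12[ok]
  if (length(gc3) < 3L)
    stop("neutrality regression needs at least 3 points")
  if (stats::var(gc3) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                n = length(gc3), diagnostic = "zero GC3 variance"))
  fit <- stats::lm(gc12 ~ gc3)
  r <- if (stats::var(gc12) == 0) 0 else stats::cor(gc3, gc12)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, n = length(gc3))
}

#' Per-codon correlation between codon usage and GC3 across genes
#'
#' For every multi-codon sense codon, the Pearson (default) correlation
#' across genes between per-gene usage (RSCU, or within-family frequency)
#' and per-gene GC3. Genes with missing usage for a codon's family drop
#' pairwise; codons with fewer than 3 informative genes, or zero variance
#' on either side, are missing.
#'
#' @param rscu_matrix genes x codons numeric matrix (e.g. rows of
#'   [rscu()] values, or within-family frequencies).
#' @param gc3 per-gene GC3 vector aligned with the matrix rows.
#' @param method correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return named numeric vector of correlation coefficients per codon.
#' @export
codon_gc3_correlations <- function(rscu_matrix, gc3,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(nrow(rscu_matrix) == length(gc3))
  if (nrow(rscu_matrix) < 3L)
    stop("correlations need at least 3 genes")
  vapply(colnames(rscu_matrix), function(cdn) {
    u <- rscu_matrix[, cdn]
    ok <- is.finite(u) & is.finite(gc3)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::var(u[ok]) == 0 || stats::var(gc3[ok]) == 0)
      return(NA_real_)
    stats::cor(u[ok], gc3[ok], method = method)
  }, numeric(1))
}

#' Full compositional profile of one sequence
#'
#' Bundles codon counts, GC by position, RSCU and ENC for a gene or a
#' species super-gene.
#'
#' @param seq validated CDS string.
#' @param code a [genetic_code()].
#' @param id unit identifier.
#' @param gc3_synonymous if `TRUE`, also report `gc3s`: GC3 restricted to
#'   codons of multi-codon (synonymous) families.
#' @return object of class `composition_profile`.
#' @export
composition_profile <- function(seq, code = genetic_code(),
                                id = NA_character_, gc3_synonymous = FALSE) {
  counts <- codon_counts(seq, code)
  gc <- gc_by_position(counts, code)
  out <- list(id = id, n_codons = sum(counts), codon_counts = counts,
              gc1 = gc[["gc1"]], gc2 = gc[["gc2"]], gc3 = gc[["gc3"]],
              gc12 = gc[["gc12"]],
              rscu = rscu(counts, code), enc = enc(counts, code))
  if (gc3_synonymous) {
    syn <- unlist(code$families[code$degeneracy > 1L], use.names = FALSE)
    sub <- counts[names(counts) %in% syn]
    out$gc3s <- unname(gc_by_position(sub, code)[["gc3"]])
  }
  structure(out, class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf(
    "composition_profile %s: %d codons, GC3 %.3f, GC12 %.3f, ENC %s\n",
    x$id, x$n_codons, x$gc3, x$gc12,
    ifelse(is.na(x$enc), "NA", sprintf("%.2f", x$enc))))
  invisible(x)
}

#' Composition table over many sequences
#'
#' One row per unit with GC metrics, ENC and all RSCU values as columns
#' (`rscu_<codon>`), the layout written by the pipeline's composition
#' stage.
#'
#' @param seqs named character vector of validated CDS.
#' @param code a [genetic_code()].
#' @return data.frame, one row per sequence.
#' @export
composition_table <- function(seqs, code = genetic_code()) {
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  profs <- lapply(seq_along(seqs), function(i)
    composition_profile(seqs[[i]], code, id = names(seqs)[i]))
  rscu_names <- names(profs[[1]]$rscu)
  base <- data.frame(
    id = vapply(profs, `[[`, character(1), "id"),
    n_codons = vapply(profs, `[[`, numeric(1), "n_codons"),
    gc1 = vapply(profs, `[[`, numeric(1), "gc1"),
    gc2 = vapply(profs, `[[`, numeric(1), "gc2"),
    gc3 = vapply(profs, `[[`, numeric(1), "gc3"),
    gc12 = vapply(profs, `[[`, numeric(1), "gc12"),
    enc = vapply(profs, `[[`, numeric(1), "enc"),
    stringsAsFactors = FALSE)
  rscu_mat <- do.call(rbind, lapply(profs, `[[`, "rscu"))
  colnames(rscu_mat) <- paste0("rscu_", rscu_names)
  cbind(base, as.data.frame(rscu_mat))
}

#' Extract the RSCU matrix from a composition table
#'
#' @param tab a [composition_table()] data.frame.
#' @return genes x codons numeric matrix with codon column names.
#' @export
rscu_matrix <- function(tab) {
  cols <- grep("^rscu_", colnames(tab), value = TRUE)
  m <- as.matrix(tab[, cols, drop = FALSE])
  colnames(m) <- sub("^rscu_", "", cols)
  rownames(m) <- tab$id
  m
}
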