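#' Genetic code tables and codon arithmetic
#'
#' A `genetic_code` object holds a codon -> amino-acid map over all 64
#' codons, the synonymous families it induces, and the degeneracy class of
#' every amino acid. The default is the standard nuclear code (61 sense
#' codons, 3 stops). Alternate codes can be supplied as a two-column
#' codon / amino-acid table (see [read_genetic_code()]).
#'
#' @param codon_to_aa named character vector mapping all 64 codons (names,
#'   DNA alphabet) to one-letter amino-acid symbols, with `"*"` for stop.
#'   `NULL` (default) uses the standard nuclear code.
#' @param table_id identifier recorded on the object.
#'
#' @return An object of class `genetic_code` with components
#'   `table_id`, `codon_to_aa`, `sense_codons`, `stop_codons`, `amino_acids`,
#'   `families` (named list: amino acid -> sorted synonymous codons) and
#'   `degeneracy` (named integer: family size per amino acid).
#' @examples
#' code <- genetic_code()
#' code$degeneracy[["L"]]  # leucine is six-fold degenerate
#' @export
genetic_code <- function(codon_to_aa = NULL, table_id = "standard") {
  if (is.null(codon_to_aa)) {
    codon_to_aa <- as.character(Biostrings::GENETIC_CODE)
    names(codon_to_aa) <- names(Biostrings::GENETIC_CODE)
  }
  names(codon_to_aa) <- normalize_codon(names(codon_to_aa))
  all64 <- all_codons()
  if (length(codon_to_aa) != 64L || !setequal(names(codon_to_aa), all64))
    stop("a genetic code must map exactly the 64 codons")
  codon_to_aa <- codon_to_aa[all64]
  aa <- toupper(codon_to_aa)
  sense <- all64[aa != "*"]
  stops <- all64[aa == "*"]
  fam_aa <- sort(unique(aa[aa != "*"]))
  families <- lapply(fam_aa, function(a) sort(all64[aa == a]))
  names(families) <- fam_aa
  structure(
    list(
      table_id = table_id,
      codon_to_aa = stats::setNames(aa, all64),
      sense_codons = sense,
      stop_codons = stops,
      amino_acids = fam_aa,
      families = families,
      degeneracy = vapply(families, length, integer(1))
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf(
    "genetic_code '%s': %d sense codons, %d stops, %d amino acids\n",
    x$table_id, length(x$sense_codons), length(x$stop_codons),
    length(x$amino_acids)
  ))
  invisible(x)
}

#' Read a genetic code from a two-column codon / amino-acid file
#'
#' Plain-text table (whitespace- or tab-separated), one row per codon:
#' codon then one-letter amino acid (`*` for stop). All 64 codons required.
#'
#' @param path file path.
#' @param table_id identifier recorded on the returned object.
#' @return A [genetic_code()] object.
#' @export
read_genetic_code <- function(path, table_id = basename(path)) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("codon", "aa"))
  genetic_code(stats::setNames(tab$aa, tab$codon), table_id = table_id)
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3))
}

# Uppercase and map U -> T (transcriptomic sources use RNA alphabet).
normalize_codon <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Translate codons to amino-acid symbols
#'
#' Case-insensitive; `U` is accepted and treated as `T`. Stops translate to
#' the distinct symbol `"*"`; they are never dropped silently.
#'
#' @param codon character vector of 3-letter codons.
#' @param code a [genetic_code()].
#' @return character vector of one-letter amino-acid symbols (`"*"` = stop).
#' @examples
#' translate_codon(c("ATG", "TAA"))
#' @export
translate_codon <- function(codon, code = genetic_code()) {
  codon <- normalize_codon(codon)
  bad <- nchar(codon) != 3L | !grepl("^[ACGT]{3}$", codon)
  if (any(bad))
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "))
  unname(code$codon_to_aa[codon])
}

#' Translate a coding sequence
#'
#' @param seq a single nucleotide string with length divisible by 3.
#' @param code a [genetic_code()].
#' @return a single amino-acid string (stops rendered as `"*"`).
#' @export
translate_cds <- function(seq, code = genetic_code()) {
  paste(translate_codon(split_codons(seq), code), collapse = "")
}

split_codons <- function(seq) {
  seq <- normalize_codon(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Count differing nucleotide positions between codons
#'
#' Vectorised over pairs; a symmetric metric on codons with values in 0..3.
#'
#' @param codon_a,codon_b character vectors of codons (recycled to common
#'   length).
#' @return integer vector of pairwise position differences.
#' @examples
#' nucleotide_diff("GCG", "TCA")  # 2
#' @export
nucleotide_diff <- function(codon_a, codon_b) {
  codon_a <- normalize_codon(codon_a)
  codon_b <- normalize_codon(codon_b)
  ok <- function(x) grepl("^[ACGT]{3}$", x)
  if (!all(ok(codon_a)) || !all(ok(codon_b)))
    stop("invalid codon(s): ",
         paste(unique(c(codon_a[!ok(codon_a)], codon_b[!ok(codon_b)])),
               collapse = ", "))
  n <- max(length(codon_a), length(codon_b))
  codon_a <- rep_len(codon_a, n)
  codon_b <- rep_len(codon_b, n)
  d <- integer(n)
  for (p in 1:3)
    d <- d + (substr(codon_a, p, p) != substr(codon_b, p, p))
  d
}

# GC fraction of each codon (0, 1/3, 2/3 or 1).
codon_gc_fraction <- function(codons) {
  (nchar(codons) - nchar(gsub("[GC]", "", codons))) / 3
}

#' Group amino acids by the GC content of their synonymous codons
#'
#' Each amino acid is scored by the mean GC fraction of its synonymous
#' codons and the 20 amino acids are split into tertiles by rank
#' (low / medium / high GC). Ties in score are broken by one-letter
#' alphabetical order, so the grouping is deterministic.
#'
#' @param code a [genetic_code()].
#' @return An object of class `aa_gc_groups`: list with `score` (named
#'   numeric, mean codon GC fraction per amino acid) and `group` (named
#'   factor with levels `low`, `medium`, `high`).
#' @examples
#' g <- classify_aa_by_codon_gc()
#' g$group[["K"]]  # lysine: low-GC group
#' @export
classify_aa_by_codon_gc <- function(code = genetic_code()) {
  score <- vapply(code$families, function(cc) mean(codon_gc_fraction(cc)),
                  numeric(1))
  ord <- order(score, names(score))
  n <- length(score)
  n_low <- ceiling(n / 3)
  n_high <- ceiling(n / 3)
  grp <- character(n)
  names(grp) <- names(score)[ord]
  grp[seq_len(n_low)] <- "low"
  grp[seq.int(n - n_high + 1L, n)] <- "high"
  grp[grp == ""] <- "medium"
  grp <- grp[names(score)]
  structure(
    list(score = score,
         group = factor(grp, levels = c("low", "medium", "high"))),
    class = "aa_gc_groups"
  )
}

#' @export
print.aa_gc_groups <- function(x, ...) {
  for (g in levels(x$group))
    cat(g, ": ", paste(names(x$group)[x$group == g], collapse = " "), "\n",
        sep = "")
  invisible(x)
}
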