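# Independent brute-force oracles, written directly from the textbook
# definitions and kept structurally separate from the package internals.

# one-letter amino acids of the standard code, by degeneracy class
.aa_twofold <- c("C", "D", "E", "F", "H", "K", "N", "Q", "Y")
.aa_threefold <- "I"
.aa_fourfold <- c("A", "G", "P", "T", "V")
.aa_sixfold <- c("L", "R", "S")

.codon_table <- function() {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- chartr("U", "T", names(Biostrings::GENETIC_CODE))
  gc
}

oracle_rscu <- function(counts) {
  tab <- .codon_table()
  sense <- names(tab)[tab != "*"]
  out <- c()
  for (a in setdiff(unique(tab[sense]), c("M", "W"))) {
    fam <- sense[tab[sense] == a]
    tot <- sum(counts[fam])
    for (cdn in fam) {
      out[cdn] <- if (tot == 0) NA_real_
      else counts[[cdn]] * length(fam) / tot
    }
  }
  out[sort(names(out))]
}

oracle_enc <- function(counts) {
  tab <- .codon_table()
  sense <- names(tab)[tab != "*"]
  f_of <- function(a) {
    fam <- sense[tab[sense] == a]
    n <- sum(counts[fam])
    if (n < 2) return(NA_real_)
    (n * sum((counts[fam] / n)^2) - 1) / (n - 1)
  }
  avg <- function(aas) {
    f <- vapply(aas, f_of, numeric(1))
    f <- f[!is.na(f)]
    if (length(f) == 0) NA_real_ else mean(f)
  }
  f2 <- avg(.aa_twofold); f3 <- avg(.aa_threefold)
  f4 <- avg(.aa_fourfold); f6 <- avg(.aa_sixfold)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f3, f4, f6)) || any(c(f2, f3, f4, f6) == 0))
    return(NA_real_)
  val <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(max(val, 20), 61)
}

oracle_gc_by_position <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  pos <- (seq_along(chars) - 1) %% 3 + 1
  gc <- chars %in% c("G", "C")
  c(gc1 = mean(gc[pos == 1]), gc2 = mean(gc[pos == 2]),
    gc3 = mean(gc[pos == 3]))
}

# two-cell goodness-of-fit chi-square against equal expectation
oracle_chi2 <- function(o1, o2) {
  unname(stats::chisq.test(c(o1, o2), p = c(0.5, 0.5),
                           correct = FALSE)$statistic)
}

# random codon-count vector over the 61 sense codons (small genes)
random_counts <- function(n_codons = 200) {
  tab <- .codon_table()
  sense <- sort(names(tab)[tab != "*"])
  draw <- sample(sense, n_codons, replace = TRUE,
                 prob = stats::runif(length(sense), 0.2, 1))
  counts <- table(factor(draw, levels = sense))
  stats::setNames(as.integer(counts), sense)
}

make_superseq <- function(species, codons,
                          code = orthocodon::genetic_code()) {
  structure(list(species = species,
                 peptide = orthocodon::translate_cds(codons, code),
                 codons = codons,
                 cog_boundaries = data.frame(cog_id = "COG0001", start = 1,
                                             end = nchar(codons) / 3)),
            class = "super_sequence")
}

# build degapped codon alignments and super-sequences from a simulation
sim_supersequences <- function(sim, code = orthocodon::genetic_code(),
                               min_len = 35L) {
  alns <- lapply(names(sim$alignments), function(cg) {
    aln <- sim$alignments[[cg]]
    cds <- vapply(names(aln), function(sp)
      sim$cds[[sp]][[paste0(sp, "_", cg)]], character(1))
    remove_gapped_columns(
      back_translate_alignment(aln, cds, code, cog_id = cg))
  })
  filt <- filter_short_cogs(alns, min_len)
  concatenate_superseqs(filt$retained, code)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
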