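#' Back-translate a protein alignment into a codon alignment
#'
#' Each aligned amino-acid column is mapped to the codon it came from,
#' consuming each species' CDS left to right with no skips. Gap columns
#' carry the marker `"---"`. The ungapped protein of every species must
#' equal the translation of its CDS exactly.
#'
#' @param protein_alignment named character vector: species -> aligned
#'   amino-acid string (gaps as `-`), all of equal length.
#' @param cds_by_species named character vector: species -> validated CDS.
#' @param code a [genetic_code()].
#' @param cog_id identifier carried on the result.
#' @return An object of class `codon_alignment`: list with `cog_id`,
#'   `species` (row order), `aa` and `codons` (species x column character
#'   matrices) and `src_cols` (1-based source protein-alignment column per
#'   retained column).
#' @export
back_translate_alignment <- function(protein_alignment, cds_by_species,
                                     code = genetic_code(),
                                     cog_id = NA_character_) {
  species <- names(protein_alignment)
  if (is.null(species) || anyNA(species))
    stop("protein_alignment must be a named vector (species -> row)")
  widths <- nchar(protein_alignment)
  if (length(unique(widths)) != 1L)
    stop("alignment rows have unequal lengths")
  ncol <- widths[[1]]
  aa_mat <- matrix("", nrow = length(species), ncol = ncol,
                   dimnames = list(species, NULL))
  codon_mat <- matrix("---", nrow = length(species), ncol = ncol,
                      dimnames = list(species, NULL))
  for (sp in species) {
    row <- toupper(protein_alignment[[sp]])
    chars <- strsplit(row, "", fixed = TRUE)[[1]]
    aa_mat[sp, ] <- chars
    cds <- cds_by_species[[sp]]
    if (is.null(cds) || is.na(cds))
      stop("no CDS supplied for species ", sp)
    codons <- split_codons(cds)
    residues <- which(chars != "-")
    if (length(residues) != length(codons))
      stop(sprintf(
        "%s / %s: aligned protein has %d residues but CDS has %d codons",
        cog_id, sp, length(residues), length(codons)))
    trans <- translate_codon(codons, code)
    mism <- which(trans != chars[residues])
    if (length(mism) > 0L)
      stop(sprintf(
        "%s / %s: translation mismatch at residue %d (protein %s, CDS codon %s -> %s)",
        cog_id, sp, mism[1], chars[residues][mism[1]],
        codons[mism[1]], trans[mism[1]]))
    codon_mat[sp, residues] <- codons
  }
  structure(
    list(cog_id = cog_id, species = species, aa = aa_mat,
         codons = codon_mat, src_cols = seq_len(ncol)),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment %s: %d species x %d columns\n",
              x$cog_id, length(x$species), ncol(x$aa)))
  invisible(x)
}

#' Remove columns gapped in any species
#'
#' A column is removed iff at least one species has a gap there; relative
#' order of survivors is preserved and their original (source) column
#' indices are retained in `src_cols`. Idempotent.
#'
#' @param aln a [back_translate_alignment()] result.
#' @return a gap-free `codon_alignment`.
#' @export
remove_gapped_columns <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  gapped <- apply(aln$aa == "-", 2, any)
  aln$aa <- aln$aa[, !gapped, drop = FALSE]
  aln$codons <- aln$codons[, !gapped, drop = FALSE]
  aln$src_cols <- aln$src_cols[!gapped]
  aln
}

#' Drop degapped orthologue groups shorter than a minimum length
#'
#' `min_len` is a strict lower bound read as "shorter than `min_len` is
#' eliminated": a degapped length of exactly `min_len` survives.
#'
#' @param alns list of degapped `codon_alignment` objects.
#' @param min_len minimum degapped amino-acid length (default 35).
#' @return list with `retained` (the surviving alignments) and `drop_log`
#'   (data.frame of `cog_id` and `length` for dropped groups).
#' @export
filter_short_cogs <- function(alns, min_len = 35L) {
  lens <- vapply(alns, function(a) ncol(a$aa), integer(1))
  keep <- lens >= min_len
  drop_log <- data.frame(
    cog_id = vapply(alns[!keep], function(a) a$cog_id, character(1)),
    length = lens[!keep], stringsAsFactors = FALSE)
  rownames(drop_log) <- NULL
  list(retained = alns[keep], drop_log = drop_log)
}

#' Concatenate degapped alignments into per-species super-sequences
#'
#' Groups are concatenated in ascending `cog_id` order (input order is
#' irrelevant), recording each group's 1-based inclusive amino-acid span.
#'
#' @param alns list of degapped `codon_alignment` objects covering the same
#'   species set.
#' @param code a [genetic_code()].
#' @return named list (one per species) of class `super_sequence`: list with
#'   `species`, `peptide`, `codons` (concatenated strings) and
#'   `cog_boundaries` (data.frame `cog_id`, `start`, `end`).
#' @export
concatenate_superseqs <- function(alns, code = genetic_code()) {
  if (length(alns) == 0L) stop("no alignments to concatenate")
  sp_sets <- lapply(alns, function(a) sort(a$species))
  if (length(unique(vapply(sp_sets, paste, character(1), collapse = ","))) != 1L)
    stop("species sets differ across alignments")
  species <- sp_sets[[1]]
  ids <- vapply(alns, function(a) a$cog_id, character(1))
  alns <- alns[order(ids)]
  ids <- sort(ids)
  lens <- vapply(alns, function(a) ncol(a$aa), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  boundaries <- data.frame(cog_id = ids, start = starts, end = ends,
                           stringsAsFactors = FALSE)
  out <- lapply(species, function(sp) {
    pep <- paste(vapply(alns, function(a) paste(a$aa[sp, ], collapse = ""),
                        character(1)), collapse = "")
    cod <- paste(vapply(alns, function(a) paste(a$codons[sp, ], collapse = ""),
                        character(1)), collapse = "")
    structure(list(species = sp, peptide = pep, codons = cod,
                   cog_boundaries = boundaries),
              class = "super_sequence")
  })
  stats::setNames(out, species)
}

#' @export
print.super_sequence <- function(x, ...) {
  cat(sprintf("super_sequence %s: %d aa over %d orthologue groups\n",
              x$species, nchar(x$peptide), nrow(x$cog_boundaries)))
  invisible(x)
}
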