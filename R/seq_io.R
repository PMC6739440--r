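#' Read a FASTA file
#'
#' Sequence ids are the first whitespace-separated token of each header;
#' record order is preserved and sequences are upper-cased. Gap characters
#' (`-`) are permitted so alignment files read with the same function.
#'
#' @param path FASTA file path.
#' @return named character vector (id -> sequence).
#' @seealso [write_fasta()] — the pair round-trips byte-stably with
#'   60-column wrapping.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector (id -> sequence).
#' @param path output file path.
#' @param width line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Validate a coding sequence
#'
#' Accepts a sequence iff its length is a multiple of 3, its alphabet is
#' clean `A/C/G/T` (after upper-casing and U -> T), and it contains no
#' internal stop codon. A terminal stop codon is trimmed and recorded —
#' the only repair ever applied. Ambiguity codes (`N` etc.) reject the
#' sequence whole.
#'
#' @param seq nucleotide string.
#' @param code a [genetic_code()].
#' @param id optional identifier used in the report.
#' @return list with `valid` (logical), `sequence` (trimmed CDS if valid),
#'   `terminal_stop` (trimmed stop codon or `NA`), and on rejection
#'   `reason` and `position` (1-based codon or nucleotide index).
#' @examples
#' validate_cds("ATGAAATAA")$sequence  # "ATGAAA"
#' @export
validate_cds <- function(seq, code = genetic_code(), id = NA_character_) {
  rejected <- function(reason, position = NA_integer_) {
    list(valid = FALSE, id = id, sequence = NA_character_,
         terminal_stop = NA_character_, reason = reason, position = position)
  }
  raw <- normalize_codon(seq)
  bad <- regexpr("[^ACGT]", raw)
  if (bad > 0L)
    return(rejected(sprintf("invalid character '%s'",
                            substr(raw, bad, bad)), as.integer(bad)))
  if (nchar(raw) %% 3L != 0L)
    return(rejected("length not a multiple of 3"))
  if (nchar(raw) < 3L)
    return(rejected("shorter than one codon"))
  codons <- split_codons(raw)
  aa <- translate_codon(codons, code)
  terminal_stop <- NA_character_
  n <- length(codons)
  if (aa[n] == "*") {
    terminal_stop <- codons[n]
    codons <- codons[-n]
    aa <- aa[-n]
  }
  if (length(codons) == 0L)
    return(rejected("no sense codons after terminal-stop trimming"))
  internal <- which(aa == "*")
  if (length(internal) > 0L)
    return(rejected("internal stop codon", internal[1]))
  list(valid = TRUE, id = id, sequence = paste(codons, collapse = ""),
       terminal_stop = terminal_stop, reason = NA_character_,
       position = NA_integer_)
}

#' Read a 12-column tabular hit table
#'
#' Tab-separated, BLAST `outfmt 6` dialect: `qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`. Rows are kept
#' in file order; e-values parse from scientific notation.
#'
#' @param path TSV file path.
#' @return data.frame with the 12 standard columns, numerics parsed.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 12), cols))
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop(sprintf("hit table %s: expected 12 tab-separated columns, got %d at line %d",
                 path, nf[nf != 12L][1], which(nf != 12L)[1]))
  m <- do.call(rbind, parts)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                    stringsAsFactors = FALSE)
  num <- c(3:12)
  for (i in num) out[[cols[i]]] <- as.numeric(m[, i])
  intcols <- c("length", "mismatch", "gapopen", "qstart", "qend",
               "sstart", "send")
  for (cn in intcols) out[[cn]] <- as.integer(out[[cn]])
  if (anyNA(out$evalue) || anyNA(out$bitscore))
    stop("hit table ", path, ": non-numeric evalue/bitscore at line ",
         which(is.na(out$evalue) | is.na(out$bitscore))[1])
  out
}

#' Read a two-column expression table (gene id, RPKM)
#'
#' Tab-separated; an optional single header row is skipped when its second
#' field is non-numeric. Values must be finite and non-negative. Genes
#' absent from the table are simply missing downstream.
#'
#' @param path TSV file path.
#' @return named numeric vector (gene id -> expression).
#' @export
read_expression_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty expression table: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("expression table ", path, ": expected 2 columns at line ",
         which(lengths(parts) < 2L)[1])
  first_val <- suppressWarnings(as.numeric(parts[[1]][2]))
  if (is.na(first_val)) parts <- parts[-1]  # header row
  ids <- vapply(parts, `[`, character(1), 1L)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(vals))
    stop("expression table ", path, ": non-numeric value for gene ",
         ids[which(is.na(vals))[1]])
  if (any(!is.finite(vals) | vals < 0))
    stop("expression table ", path, ": negative or non-finite value for gene ",
         ids[which(!is.finite(vals) | vals < 0)[1]])
  if (anyDuplicated(ids))
    stop("expression table ", path, ": duplicate gene id ",
         ids[duplicated(ids)][1])
  stats::setNames(vals, ids)
}
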