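#' Best hits per query from one directed hit table
#'
#' Hits with e-value strictly above the cutoff are discarded (a hit exactly
#' at the cutoff is kept). Per query the best subject has the lowest
#' e-value; ties break by highest bitscore, then lexicographically smallest
#' subject id. Self-hits (query == subject) are ignored.
#'
#' @param hits data.frame as returned by [read_hit_table()], all rows from
#'   one ordered species pair (A -> B).
#' @param evalue_cutoff significance cutoff (default `1e-5`).
#' @return named character vector: query id -> best subject id.
#' @export
best_hits <- function(hits, evalue_cutoff = 1e-5) {
  keep <- hits$evalue <= evalue_cutoff & hits$qseqid != hits$sseqid
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(hits$qseqid)
  stats::setNames(hits$sseqid[first], hits$qseqid[first])
}

#' Reciprocal best hits between two species
#'
#' A pair (a, b) is reported iff b is a's best hit in the A -> B table and
#' a is b's best hit in the B -> A table.
#'
#' @param hits_ab,hits_ba hit tables for the two directions of one species
#'   pair.
#' @param evalue_cutoff significance cutoff (default `1e-5`).
#' @return data.frame with columns `gene_a`, `gene_b`, sorted by `gene_a`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_cutoff = 1e-5) {
  ab <- best_hits(hits_ab, evalue_cutoff)
  ba <- best_hits(hits_ba, evalue_cutoff)
  qa <- names(ab)
  keep <- !is.na(ba[ab]) & ba[ab] == qa
  keep[is.na(keep)] <- FALSE
  out <- data.frame(gene_a = qa[keep], gene_b = unname(ab[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

pair_key <- function(a, b) paste0(a, "__", b)

#' Core one-per-species orthologue groups from reciprocal best hits
#'
#' Builds groups containing exactly one gene per species, kept only when
#' every species is represented. Two strategies:
#' \describe{
#'   \item{anchor}{groups are seeded from the genes of an anchor species
#'     (default: first species alphabetically); each other species
#'     contributes its RBH partner with the anchor. Scales linearly in the
#'     number of species.}
#'   \item{clique}{anchor-seeded candidates are additionally required to be
#'     mutually consistent: every within-group species pair must itself be
#'     an RBH. Needs RBH lists for all unordered species pairs.}
#' }
#' Group ids (`COG0001`, ...) are assigned deterministically by sorted
#' anchor gene id.
#'
#' @param rbh_pairs named list of RBH data.frames (from
#'   [reciprocal_best_hits()]); element `"A__B"` holds pairs with `gene_a`
#'   from species `A` and `gene_b` from species `B`. Either orientation of
#'   each unordered pair may be supplied.
#' @param species character vector of species names.
#' @param strategy `"anchor"` (default) or `"clique"`.
#' @param anchor anchor species (default: first alphabetically).
#' @return data.frame with columns `cog_id`, `species`, `gene_id`; attribute
#'   `strategy` records the method used.
#' @export
core_ortholog_groups <- function(rbh_pairs, species,
                                 strategy = c("anchor", "clique"),
                                 anchor = NULL) {
  strategy <- match.arg(strategy)
  species <- sort(unique(species))
  if (is.null(anchor)) anchor <- species[1]
  stopifnot(anchor %in% species)

  # normalized lookup: rbh(map) for ordered pair (A,B) as named vector a->b
  get_rbh <- function(a, b) {
    k1 <- pair_key(a, b); k2 <- pair_key(b, a)
    if (!is.null(rbh_pairs[[k1]])) {
      df <- rbh_pairs[[k1]]
      stats::setNames(df$gene_b, df$gene_a)
    } else if (!is.null(rbh_pairs[[k2]])) {
      df <- rbh_pairs[[k2]]
      stats::setNames(df$gene_a, df$gene_b)
    } else NULL
  }

  others <- setdiff(species, anchor)
  maps <- lapply(others, function(sp) {
    m <- get_rbh(anchor, sp)
    if (is.null(m))
      stop("missing RBH table for species pair ", pair_key(anchor, sp))
    m
  })
  names(maps) <- others

  anchor_genes <- sort(unique(unlist(lapply(maps, names), use.names = FALSE)))
  groups <- list()
  for (g in anchor_genes) {
    partners <- vapply(others, function(sp) {
      p <- maps[[sp]][g]
      if (is.na(p)) NA_character_ else unname(p)
    }, character(1))
    if (anyNA(partners)) next
    members <- c(stats::setNames(g, anchor), stats::setNames(partners, others))
    members <- members[species]
    if (strategy == "clique") {
      ok <- TRUE
      for (i in seq_along(species)) {
        for (j in seq_along(species)) {
          if (j <= i) next
          a <- species[i]; b <- species[j]
          m <- get_rbh(a, b)
          if (is.null(m))
            stop("clique strategy requires RBH table for species pair ",
                 pair_key(a, b))
          p <- m[members[[a]]]
          if (is.na(p) || p != members[[b]]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) next
    }
    groups[[g]] <- members
  }
  if (length(groups) == 0L) {
    out <- data.frame(cog_id = character(0), species = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE)
    attr(out, "strategy") <- strategy
    return(out)
  }
  seed_ids <- sort(names(groups))
  cog_ids <- sprintf("COG%04d", seq_along(seed_ids))
  out <- do.call(rbind, lapply(seq_along(seed_ids), function(i) {
    m <- groups[[seed_ids[i]]]
    data.frame(cog_id = cog_ids[i], species = names(m), gene_id = unname(m),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "strategy") <- strategy
  attr(out, "anchor") <- if (strategy == "anchor") anchor else NA_character_
  out
}
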