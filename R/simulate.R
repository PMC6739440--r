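#' Configuration for the ortholog-family simulator
#'
#' Bundles and validates every knob of [simulate_ortholog_set()]. The
#' defaults describe the data regime the analysis targets: a handful of
#' species whose third-position GC spans a wide range, ortholog families
#' of a few hundred codons, moderate amino-acid divergence, occasional gap
#' columns, and log-normal expression optionally coupled to codon
#' preference.
#'
#' @param seed integer RNG seed; identical configs give byte-identical
#'   output.
#' @param n_species number of species.
#' @param n_cogs number of ortholog families.
#' @param protein_length list with `mean` and `min` (codons); lengths are
#'   drawn normal around `mean` (sd = mean/4) and clamped at `min`.
#' @param gc3_target per-species third-position GC targets in (0, 1),
#'   recycled to `n_species`.
#' @param aa_sub_rate per-site probability that a species substitutes the
#'   ancestral amino acid (by a property-similar one), in `[0, 1)`.
#' @param two_hit_theta probability that a non-synonymous site's codon is
#'   re-equilibrated to the species' GC3 tilt (the two-hit mechanism)
#'   instead of taking the minimal-mutation codon, in `[0, 1]`.
#' @param gap_rate per-column probability of a gap column.
#' @param expression list with `meanlog`, `sdlog` (log-normal RPKM) and
#'   `coupling` (probability that a codon of a high-expression gene is
#'   switched to the preferred codon of its family).
#' @param preferred_set codons planted as preferred in high-expression
#'   genes (default `"GCC"`).
#' @param species optional species names (default `sp01`, `sp02`, ...).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_species = 6L, n_cogs = 100L,
                              protein_length = list(mean = 300, min = 40),
                              gc3_target = c(0.30, 0.40, 0.45,
                                             0.50, 0.60, 0.70),
                              aa_sub_rate = 0.05, two_hit_theta = 0.5,
                              gap_rate = 0.08,
                              expression = list(meanlog = 2, sdlog = 1.5,
                                                coupling = 0.5),
                              preferred_set = "GCC", species = NULL) {
  stopifnot(n_species >= 1L, n_cogs >= 1L,
            protein_length$min >= 1, protein_length$mean >= protein_length$min,
            aa_sub_rate >= 0, aa_sub_rate < 1,
            two_hit_theta >= 0, two_hit_theta <= 1,
            gap_rate >= 0, gap_rate < 1)
  gc3_target <- rep_len(gc3_target, n_species)
  if (any(gc3_target <= 0 | gc3_target >= 1))
    stop("gc3_target must lie strictly inside (0, 1)")
  if (is.null(species))
    species <- sprintf("sp%02d", seq_len(n_species))
  stopifnot(length(species) == n_species, !anyDuplicated(species))
  structure(
    list(seed = as.integer(seed), n_species = as.integer(n_species),
         n_cogs = as.integer(n_cogs), protein_length = protein_length,
         gc3_target = stats::setNames(gc3_target, species),
         aa_sub_rate = aa_sub_rate, two_hit_theta = two_hit_theta,
         gap_rate = gap_rate, expression = expression,
         preferred_set = preferred_set, species = species),
    class = "simulation_config"
  )
}

# Property-similar amino-acid groups used for substitutions: changes stay
# within aliphatic / aromatic / polar / negative / positive residues.
aa_property_groups <- function() {
  list(aliphatic = c("A", "G", "I", "L", "M", "P", "V"),
       aromatic = c("F", "W", "Y"),
       polar = c("C", "N", "Q", "S", "T"),
       negative = c("D", "E"),
       positive = c("H", "K", "R"))
}

# Sense codons one nucleotide substitution away from each sense codon.
codon_neighbors <- function(code) {
  sense <- code$sense_codons
  lapply(stats::setNames(sense, sense), function(cdn) {
    nb <- character(0)
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      x <- cdn
      substr(x, p, p) <- b
      if (x != cdn && x %in% sense) nb <- c(nb, x)
    }
    sort(nb)
  })
}

# Per-family bookkeeping for tilted codon sampling: codons ordered with
# AT-ended first so the inverse-CDF draw is monotone in the tilt.
family_tilt_info <- function(code) {
  lapply(code$families, function(fam) {
    gc3 <- substr(fam, 3, 3) %in% c("G", "C")
    ord <- order(gc3, fam)
    list(codons = fam[ord], is_gc3 = gc3[ord],
         n_gc = sum(gc3), n_at = sum(!gc3))
  })
}

# Solve the logit tilt beta so that the expected GC3 over the given
# amino-acid sequence hits the target; errors when the target is outside
# the achievable range of that sequence.
solve_gc3_tilt <- function(aa_seq, target, tilt_info) {
  n_gc <- vapply(tilt_info[aa_seq], `[[`, numeric(1), "n_gc")
  n_at <- vapply(tilt_info[aa_seq], `[[`, numeric(1), "n_at")
  p_gc <- function(beta) {
    w <- n_gc * exp(beta)
    ifelse(n_at == 0, 1, w / (w + n_at))
  }
  floor_gc3 <- mean(n_at == 0)
  if (target <= floor_gc3 + 1e-9 || target >= 1 - 1e-9)
    stop(sprintf(
      "gc3_target %.3f not achievable for this sequence; achievable range is (%.3f, 1)",
      target, floor_gc3))
  f <- function(beta) mean(p_gc(beta)) - target
  stats::uniroot(f, c(-40, 40), tol = 1e-9)$root
}

# Inverse-CDF draw of one codon per site from the tilted family
# distribution; shared uniforms across species realise the coupling.
tilted_codons <- function(aa_seq, beta, u, tilt_info) {
  out <- character(length(aa_seq))
  for (a in unique(aa_seq)) {
    info <- tilt_info[[a]]
    w <- ifelse(info$is_gc3, exp(beta), 1)
    cp <- cumsum(w / sum(w))
    cp[length(cp)] <- 1  # guard the inverse CDF against rounding
    idx <- which(aa_seq == a)
    out[idx] <- info$codons[findInterval(u[idx], cp) + 1L]
  }
  out
}

#' Simulate ortholog families across species
#'
#' Generates `n_cogs` families of one gene per species. Ancestral proteins
#' are drawn i.i.d. uniform over the 20 amino acids; per species, each
#' site substitutes with probability `aa_sub_rate` to a property-similar
#' amino acid reachable by a single point mutation from the ancestral
#' codon (sites with no such neighbour — tryptophan, notably — never
#' substitute, mirroring its extreme conservation). Codons are assigned
#' per species from their synonymous family with a logit tilt on
#' third-position G/C solved so the expected GC3 of each gene matches the
#' species target. At non-synonymous sites, with probability
#' `two_hit_theta` the codon is re-sampled from the species-tilted
#' distribution (the two-hit re-equilibration: point mutation followed by
#' a synonymous GC-restoring change); otherwise it stays the
#' minimal-nucleotide-difference codon — the single-point-mutation
#' product itself (ties split equally). Gap columns are inserted at
#' `gap_rate`, half private to one species and half shared by a random
#' subset.
#'
#' All per-site draws (family inverse-CDF position, substitution target,
#' tie-break) are shared across species and ancestor, so species with
#' identical GC3 targets carry identical codons wherever no substitution
#' occurred: between-species differences reflect only substitution events
#' and tilt differences, never independent synonymous noise.
#'
#' @param config a [simulation_config()].
#' @param code a [genetic_code()].
#' @return object of class `ortholog_simulation`: list with `config`,
#'   `species`, `cds` (per species, named gene -> CDS), `alignments` (per
#'   COG, named species -> aligned amino-acid string), and `truth`: list
#'   with `orthology` (data.frame `cog_id`, `species`, `gene_id`),
#'   `gc3_target`, and `provenance` (data.frame per cog x site x species:
#'   ancestral and realised amino acid / codon, event type `none` /
#'   `single_hit` / `two_hit`, nucleotide distance to the ancestral codon,
#'   the minimal achievable distance, and gap status).
#' @export
simulate_ortholog_set <- function(config = simulation_config(),
                                  code = genetic_code()) {
  set.seed(config$seed)
  tilt_info <- family_tilt_info(code)
  groups <- aa_property_groups()
  aa_to_group <- stats::setNames(
    rep(names(groups), lengths(groups)), unlist(groups))
  neighbors <- codon_neighbors(code)
  # property-similar single-mutation targets per source codon
  targets_of <- lapply(names(neighbors), function(cdn) {
    a <- translate_codon(cdn, code)
    nb_aa <- unique(translate_codon(neighbors[[cdn]], code))
    sort(intersect(setdiff(nb_aa, a), groups[[aa_to_group[[a]]]]))
  })
  names(targets_of) <- names(neighbors)
  species <- config$species
  S <- length(species)
  targets <- config$gc3_target
  anc_target <- mean(targets)

  lens <- pmax(round(stats::rnorm(config$n_cogs,
                                  mean = config$protein_length$mean,
                                  sd = config$protein_length$mean / 4)),
               config$protein_length$min)
  cog_ids <- sprintf("COG%04d", seq_len(config$n_cogs))

  alignments <- vector("list", config$n_cogs)
  names(alignments) <- cog_ids
  cds_lists <- lapply(species, function(sp) list())
  names(cds_lists) <- species
  prov_list <- vector("list", config$n_cogs)

  for (g in seq_len(config$n_cogs)) {
    L <- lens[g]
    anc_aa <- sample(code$amino_acids, L, replace = TRUE)
    u_fam <- stats::runif(L)
    u_target <- stats::runif(L)
    u_tie <- stats::runif(L)
    u_change <- matrix(stats::runif(L * S), L, S)
    u_theta <- matrix(stats::runif(L * S), L, S)
    u_gapcol <- stats::runif(L)
    u_gaptype <- stats::runif(L)

    beta_anc <- solve_gc3_tilt(anc_aa, anc_target, tilt_info)
    anc_codon <- tilted_codons(anc_aa, beta_anc, u_fam, tilt_info)

    # one beta per distinct species target, solved on the ancestral
    # protein so equal targets share an identical tilt
    beta_by_target <- vapply(unique(targets), function(t)
      solve_gc3_tilt(anc_aa, t, tilt_info), numeric(1))
    names(beta_by_target) <- as.character(unique(targets))

    aa_mat <- matrix(anc_aa, L, S)
    codon_mat <- matrix("", L, S)
    event_mat <- matrix("none", L, S)
    mind_mat <- matrix(0L, L, S)

    for (s in seq_len(S)) {
      beta_s <- beta_by_target[[as.character(targets[s])]]
      changed <- which(u_change[, s] < config$aa_sub_rate)
      aa_s <- anc_aa
      for (i in changed) {
        cand <- targets_of[[anc_codon[i]]]
        if (length(cand) == 0L) next  # no accessible similar residue
        aa_s[i] <- cand[floor(u_target[i] * length(cand)) + 1L]
      }
      codons_s <- tilted_codons(aa_s, beta_s, u_fam, tilt_info)
      for (i in changed) {
        if (aa_s[i] == anc_aa[i]) next
        mind_mat[i, s] <- 1L  # target chosen one point mutation away
        if (u_theta[i, s] < config$two_hit_theta) {
          event_mat[i, s] <- "two_hit"  # keep the tilted re-sample
        } else {
          nb <- neighbors[[anc_codon[i]]]
          mp <- nb[translate_codon(nb, code) == aa_s[i]]
          codons_s[i] <- mp[floor(u_tie[i] * length(mp)) + 1L]
          event_mat[i, s] <- "single_hit"
        }
      }
      aa_mat[, s] <- aa_s
      codon_mat[, s] <- codons_s
    }

    # gap columns: private to one species or shared by a random subset
    gapped <- matrix(FALSE, L, S)
    if (config$gap_rate > 0 && S >= 1L) {
      gap_col <- u_gapcol < config$gap_rate
      for (i in which(gap_col)) {
        if (S == 1L || u_gaptype[i] < 0.5) {
          gapped[i, floor(u_gaptype[i] * 2 * S) %% S + 1L] <- TRUE
        } else {
          k <- 2L + (floor(u_gaptype[i] * 100) %% max(S - 1L, 1L))
          k <- min(k, S)
          gapped[i, sample.int(S, k)] <- TRUE
        }
      }
    }

    aln <- vapply(seq_len(S), function(s) {
      chars <- aa_mat[, s]
      chars[gapped[, s]] <- "-"
      paste(chars, collapse = "")
    }, character(1))
    names(aln) <- species
    alignments[[g]] <- aln

    for (s in seq_len(S)) {
      keep <- !gapped[, s]
      gene_id <- paste0(species[s], "_", cog_ids[g])
      cds_lists[[species[s]]][[gene_id]] <-
        paste(codon_mat[keep, s], collapse = "")
    }

    prov_list[[g]] <- data.frame(
      cog_id = cog_ids[g],
      site = rep(seq_len(L), S),
      species = rep(species, each = L),
      anc_aa = rep(anc_aa, S), anc_codon = rep(anc_codon, S),
      aa = as.vector(aa_mat), codon = as.vector(codon_mat),
      event = as.vector(event_mat),
      nt_diff_anc = nucleotide_diff(rep(anc_codon, S),
                                    as.vector(codon_mat)),
      min_diff_anc = as.vector(mind_mat),
      gapped = as.vector(gapped),
      stringsAsFactors = FALSE)
  }

  orthology <- do.call(rbind, lapply(seq_along(cog_ids), function(g)
    data.frame(cog_id = cog_ids[g], species = species,
               gene_id = paste0(species, "_", cog_ids[g]),
               stringsAsFactors = FALSE)))
  cds <- lapply(cds_lists, function(x) unlist(x))
  structure(
    list(config = config, species = species, cds = cds,
         alignments = alignments,
         truth = list(orthology = orthology,
                      gc3_target = targets,
                      provenance = do.call(rbind, prov_list))),
    class = "ortholog_simulation"
  )
}

#' @export
print.ortholog_simulation <- function(x, ...) {
  cat(sprintf("ortholog_simulation: %d species x %d COGs (seed %d)\n",
              length(x$species), x$config$n_cogs, x$config$seed))
  invisible(x)
}

#' Simulate directed pairwise hit tables from a simulation's truth
#'
#' True orthologs become mutual best hits with e-values `10^-U(20, 80)`
#' (one draw per unordered pair and COG, used in both directions, so
#' reciprocity is exact). Decoy hits are added per query with probability
#' `decoy_rate`, pointing at a random non-orthologous subject with an
#' e-value at least ten-fold weaker than the query's true best hit, so
#' recall of the truth map is unaffected.
#'
#' @param sim an [simulate_ortholog_set()] result.
#' @param decoy_rate per-query probability of an extra spurious hit.
#' @param seed RNG seed for the hit noise.
#' @return named list of 12-column hit data.frames, one per ordered
#'   species pair, names `"A__B"`.
#' @export
simulate_hit_tables <- function(sim, decoy_rate = 0,
                                seed = sim$config$seed + 1L) {
  set.seed(seed)
  species <- sim$species
  orth <- sim$truth$orthology
  cogs <- unique(orth$cog_id)
  genes <- lapply(species, function(sp) {
    v <- orth$gene_id[orth$species == sp]
    names(v) <- orth$cog_id[orth$species == sp]
    v
  })
  names(genes) <- species
  plen <- vapply(cogs, function(cg)
    nchar(sim$alignments[[cg]][[1]]), integer(1))
  names(plen) <- cogs

  # one exponent per unordered pair x COG, then decoys per direction
  expo <- list()
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (j <= i) next
    expo[[pair_key(species[i], species[j])]] <-
      stats::runif(length(cogs), 20, 80)
  }
  out <- list()
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (i == j) next
    a <- species[i]; b <- species[j]
    key_u <- if (i < j) pair_key(a, b) else pair_key(b, a)
    ex <- expo[[key_u]]
    pid <- round(stats::runif(length(cogs), 70, 95), 1)
    len <- plen[cogs]
    df <- data.frame(
      qseqid = unname(genes[[a]][cogs]), sseqid = unname(genes[[b]][cogs]),
      pident = pid, length = unname(len),
      mismatch = as.integer(round(len * (1 - pid / 100))),
      gapopen = 0L, qstart = 1L, qend = unname(len),
      sstart = 1L, send = unname(len),
      evalue = 10^-ex, bitscore = round(ex * 3 + 50, 1),
      stringsAsFactors = FALSE)
    if (decoy_rate > 0 && length(cogs) > 1L) {
      is_decoy <- stats::runif(length(cogs)) < decoy_rate
      if (any(is_decoy)) {
        wrong <- vapply(which(is_decoy), function(k)
          unname(genes[[b]][sample(setdiff(seq_along(cogs), k), 1L)]),
          character(1))
        dex <- pmax(ex[is_decoy] - stats::runif(sum(is_decoy), 1, 10), 0)
        dec <- df[is_decoy, , drop = FALSE]
        dec$sseqid <- wrong
        dec$evalue <- 10^-dex
        dec$bitscore <- round(dex * 3 + 40, 1)
        df <- rbind(df, dec)
      }
    }
    rownames(df) <- NULL
    out[[pair_key(a, b)]] <- df
  }
  out
}

#' Simulate expression and expression-coupled codon preference
#'
#' Draws log-normal expression for one species' genes; genes strictly
#' above the `hi_pct` percentile have each codon whose family contains a
#' preferred codon switched to that codon with probability `coupling`,
#' re-emitting those CDS. This plants the codon-usage / expression
#' association that the preferred-codon caller must recover. Codon-level
#' provenance in `sim$truth` describes the pre-coupling state.
#'
#' @param sim an [simulate_ortholog_set()] result.
#' @param species which species' genes get expression (default: first).
#' @param coupling switch probability for high-expression genes
#'   (default: from the config; 0 = null, no association).
#' @param preferred_set planted preferred codons (default: from config).
#' @param hi_pct percentile above which genes are re-tilted.
#' @param seed RNG seed.
#' @param code a [genetic_code()].
#' @return list with `expression` (named numeric, RPKM-like), `cds` (the
#'   species' CDS vector after re-tilting), `species` and
#'   `preferred_set`.
#' @export
simulate_expression <- function(sim, species = sim$species[1],
                                coupling = sim$config$expression$coupling,
                                preferred_set = sim$config$preferred_set,
                                hi_pct = 90,
                                seed = sim$config$seed + 2L,
                                code = genetic_code()) {
  set.seed(seed)
  cds <- sim$cds[[species]]
  n <- length(cds)
  expr <- stats::rlnorm(n, meanlog = sim$config$expression$meanlog,
                        sdlog = sim$config$expression$sdlog)
  names(expr) <- names(cds)
  if (coupling > 0 && length(preferred_set) > 0) {
    pref_aa <- translate_codon(preferred_set, code)
    if (anyDuplicated(pref_aa))
      stop("preferred_set must contain at most one codon per family")
    fam_of <- stats::setNames(
      translate_codon(code$sense_codons, code), code$sense_codons)
    hi_cut <- stats::quantile(expr, hi_pct / 100, names = FALSE)
    for (gid in names(cds)[expr > hi_cut]) {
      codons <- split_codons(cds[[gid]])
      in_scope <- fam_of[codons] %in% pref_aa
      switch_it <- in_scope & stats::runif(length(codons)) < coupling
      if (any(switch_it)) {
        repl <- stats::setNames(preferred_set, pref_aa)
        codons[switch_it] <- repl[fam_of[codons[switch_it]]]
        cds[[gid]] <- paste(codons, collapse = "")
      }
    }
  }
  list(expression = expr, cds = cds, species = species,
       preferred_set = preferred_set)
}

#' Write a simulation to the on-disk layout the pipeline consumes
#'
#' Emits one CDS FASTA per species (`cds_<species>.fasta`), one aligned
#' protein FASTA per COG under `alignments/`, directed hit tables under
#' `hits/` and a `truth.json` with the orthology map and GC3 targets.
#'
#' @param sim an [simulate_ortholog_set()] result.
#' @param dir output directory (created if needed).
#' @param hit_tables optional [simulate_hit_tables()] result to write.
#' @param expression optional [simulate_expression()] result to write
#'   (as `expression_<species>.tsv`; re-tilted CDS replace that species'
#'   FASTA).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, hit_tables = NULL,
                             expression = NULL) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  cds <- sim$cds
  if (!is.null(expression))
    cds[[expression$species]] <- expression$cds
  for (sp in sim$species)
    write_fasta(cds[[sp]], file.path(dir, paste0("cds_", sp, ".fasta")))
  for (cg in names(sim$alignments))
    write_fasta(sim$alignments[[cg]],
                file.path(dir, "alignments", paste0(cg, ".faa")))
  if (!is.null(hit_tables)) {
    dir.create(file.path(dir, "hits"), showWarnings = FALSE)
    for (key in names(hit_tables)) {
      df <- hit_tables[[key]]
      df$evalue <- sprintf("%.3e", df$evalue)
      utils::write.table(df, file.path(dir, "hits", paste0(key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  if (!is.null(expression)) {
    utils::write.table(
      data.frame(gene = names(expression$expression),
                 rpkm = expression$expression),
      file.path(dir, paste0("expression_", expression$species, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(orthology = sim$truth$orthology,
         gc3_target = as.list(sim$truth$gc3_target),
         seed = sim$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
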