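#' Pipeline configuration
#'
#' Exactly one of `input` (directory layout with per-species CDS FASTA,
#' per-COG protein alignments, directed hit tables and optional expression
#' tables) or `simulate` (a [simulation_config()]) must be given.
#'
#' @param simulate a [simulation_config()], or `NULL` when reading real
#'   inputs.
#' @param input list with paths `cds_dir`, `alignments_dir`, `hits_dir`
#'   and optionally `expression` (named list species -> TSV path), or
#'   `NULL` in simulate mode.
#' @param stages character vector of stages to run, a subset of
#'   `c("orthology", "alignment", "composition", "cluster", "expression",
#'   "substitution")`.
#' @param evalue_cutoff reciprocal-best-hit significance cutoff.
#' @param min_len minimum degapped COG length (amino acids).
#' @param hi_pct,lo_pct expression stratification percentiles.
#' @param alpha adjusted-p threshold for preferred codons and asymmetry
#'   calls.
#' @param ordination `"pca"` or `"coa"`.
#' @param orthology_strategy `"anchor"` or `"clique"`.
#' @param decoy_rate decoy hit rate (simulate mode only).
#' @param seed top-level seed; all pipeline randomness derives from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = simulation_config(), input = NULL,
                            stages = c("orthology", "alignment",
                                       "composition", "cluster",
                                       "expression", "substitution"),
                            evalue_cutoff = 1e-5, min_len = 35L,
                            hi_pct = 90, lo_pct = 10, alpha = 0.05,
                            ordination = c("pca", "coa"),
                            orthology_strategy = c("anchor", "clique"),
                            decoy_rate = 0,
                            seed = if (!is.null(simulate)) simulate$seed else 1L) {
  if (is.null(simulate) == is.null(input))
    stop("exactly one of 'simulate' and 'input' must be supplied")
  stopifnot(evalue_cutoff > 0, min_len >= 1,
            hi_pct > lo_pct, alpha > 0, alpha < 1)
  structure(
    list(simulate = simulate, input = input, stages = stages,
         evalue_cutoff = evalue_cutoff, min_len = as.integer(min_len),
         hi_pct = hi_pct, lo_pct = lo_pct, alpha = alpha,
         ordination = match.arg(ordination),
         orthology_strategy = match.arg(orthology_strategy),
         decoy_rate = decoy_rate, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulate:` block mirrors [simulation_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate))
    sim <- do.call(simulation_config, y$simulate)
  args <- y[setdiff(names(y), "simulate")]
  do.call(pipeline_config, c(list(simulate = sim), args))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the comparative codon-usage pipeline
#'
#' Stages run in dependency order: orthology (reciprocal best hits ->
#' core groups) -> alignment preparation (back-translation, degapping,
#' length filter, super-sequences) -> composition (per-gene and
#' per-species GC / RSCU / ENC, neutrality regressions) -> RSCU consensus
#' clustering -> expression stage (ordination and preferred codons, when
#' expression is available) -> substitution analysis (matrices, chi-square
#' tests, classification, two-hit summary per species pair). All outputs
#' are TSV / Newick / JSON files under `outdir`; a `manifest.json`
#' records the seed, config hash and per-stage row counts. Re-running
#' with an identical config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param code a [genetic_code()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir, code = genetic_code()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("orthocodon")),
    seed = config$seed, stages = list())
  cfg_file <- file.path(outdir, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "input")], cfg_file,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  on_fail <- function(stage, err) {
    writeLines(paste0("FAILED at stage ", stage, ": ",
                      conditionMessage(err)),
               file.path(outdir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(err), call. = FALSE)
  }
  log_stage <- function(stage, counts) {
    manifest$stages[[stage]] <<- counts
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste(names(counts), unlist(counts), sep = "=",
                          collapse = ", ")))
  }

  # ---- inputs -------------------------------------------------------
  simulate_mode <- !is.null(config$simulate)
  if (simulate_mode) {
    sim <- simulate_ortholog_set(config$simulate, code)
    hit_tables <- simulate_hit_tables(sim, decoy_rate = config$decoy_rate)
    expr_res <- simulate_expression(sim)
    cds_all <- sim$cds
    cds_all[[expr_res$species]] <- expr_res$cds
    alignments <- sim$alignments
    expression_tables <- stats::setNames(list(expr_res$expression),
                                         expr_res$species)
    species <- sim$species
  } else {
    inp <- config$input
    cds_files <- list.files(inp$cds_dir, pattern = "\\.fasta$",
                            full.names = TRUE)
    species <- sub("^cds_", "", sub("\\.fasta$", "", basename(cds_files)))
    cds_all <- lapply(cds_files, read_fasta)
    names(cds_all) <- species
    aln_files <- list.files(inp$alignments_dir, pattern = "\\.faa$",
                            full.names = TRUE)
    alignments <- lapply(aln_files, read_fasta)
    names(alignments) <- sub("\\.faa$", "", basename(aln_files))
    hit_files <- list.files(inp$hits_dir, pattern = "\\.tsv$",
                            full.names = TRUE)
    hit_tables <- lapply(hit_files, read_hit_table)
    names(hit_tables) <- sub("\\.tsv$", "", basename(hit_files))
    expression_tables <- NULL
    if (!is.null(inp$expression))
      expression_tables <- lapply(inp$expression, read_expression_table)
  }

  # validated protein sequences per species
  validated <- lapply(species, function(sp) {
    vapply(names(cds_all[[sp]]), function(id) {
      v <- validate_cds(cds_all[[sp]][[id]], code, id = id)
      if (!v$valid)
        stop("invalid CDS ", id, ": ", v$reason)
      v$sequence
    }, character(1))
  })
  names(validated) <- species

  # ---- orthology ----------------------------------------------------
  cogs <- NULL
  if ("orthology" %in% config$stages) {
    res <- tryCatch({
      rbh <- list()
      for (i in seq_along(species)) for (j in seq_along(species)) {
        if (j <= i) next
        a <- species[i]; b <- species[j]
        rbh[[pair_key(a, b)]] <- reciprocal_best_hits(
          hit_tables[[pair_key(a, b)]], hit_tables[[pair_key(b, a)]],
          config$evalue_cutoff)
      }
      core_ortholog_groups(rbh, species,
                           strategy = config$orthology_strategy)
    }, error = function(e) on_fail("orthology", e))
    cogs <- res
    write_tsv(cogs, file.path(outdir, "cogs.tsv"))
    log_stage("orthology",
              list(groups = length(unique(cogs$cog_id)),
                   species = length(species)))
  }

  # ---- alignment preparation ---------------------------------------
  supers <- NULL
  retained <- NULL
  if ("alignment" %in% config$stages) {
    res <- tryCatch({
      keep_cogs <- if (!is.null(cogs)) {
        # map detected groups onto alignment files via member gene ids
        names(alignments)
      } else names(alignments)
      alns <- lapply(keep_cogs, function(cg) {
        aln <- alignments[[cg]]
        # alignment rows are named by species; the member gene id comes
        # from the orthology table when present, else <species>_<cog>
        members <- stats::setNames(paste0(names(aln), "_", cg), names(aln))
        if (!is.null(cogs) && cg %in% cogs$cog_id) {
          sub <- cogs[cogs$cog_id == cg, ]
          members[sub$species] <- sub$gene_id
        }
        cds_by_sp <- vapply(names(aln), function(sp) {
          id <- members[[sp]]
          v <- validated[[sp]]
          if (!id %in% names(v))
            stop("no CDS for ", id, " (COG ", cg, ")")
          v[[id]]
        }, character(1))
        remove_gapped_columns(
          back_translate_alignment(aln, cds_by_sp, code, cog_id = cg))
      })
      filt <- filter_short_cogs(alns, config$min_len)
      write_tsv(filt$drop_log, file.path(outdir, "cog_drop_log.tsv"))
      list(supers = concatenate_superseqs(filt$retained, code),
           retained = filt$retained)
    }, error = function(e) on_fail("alignment", e))
    supers <- res$supers
    retained <- res$retained
    super_fa <- vapply(supers, `[[`, character(1), "codons")
    write_fasta(super_fa, file.path(outdir, "supergenes.fasta"))
    log_stage("alignment",
              list(retained = length(retained),
                   super_length = nchar(supers[[1]]$peptide)))
  }

  # ---- composition --------------------------------------------------
  species_tab <- NULL
  if ("composition" %in% config$stages) {
    res <- tryCatch({
      gene_tabs <- lapply(species, function(sp)
        composition_table(validated[[sp]], code))
      names(gene_tabs) <- species
      all_genes <- do.call(rbind, lapply(species, function(sp)
        cbind(species = sp, gene_tabs[[sp]])))
      write_tsv(all_genes, file.path(outdir, "composition_genes.tsv"))
      sp_tab <- NULL
      if (!is.null(supers)) {
        sp_seqs <- vapply(supers, `[[`, character(1), "codons")
        sp_tab <- composition_table(sp_seqs, code)
        write_tsv(sp_tab, file.path(outdir, "composition_species.tsv"))
      }
      neut <- do.call(rbind, lapply(species, function(sp) {
        tab <- gene_tabs[[sp]]
        nr <- neutrality_regression(tab$gc3, tab$gc12)
        data.frame(species = sp, slope = nr$slope,
                   intercept = nr$intercept, r = nr$r, n = nr$n)
      }))
      if (!is.null(sp_tab) && nrow(sp_tab) >= 3) {
        nr <- neutrality_regression(sp_tab$gc3, sp_tab$gc12)
        neut <- rbind(neut, data.frame(species = "ALL_SPECIES_SUPERGENES",
                                       slope = nr$slope,
                                       intercept = nr$intercept,
                                       r = nr$r, n = nr$n))
      }
      write_tsv(neut, file.path(outdir, "neutrality.tsv"))
      corr <- do.call(rbind, lapply(species, function(sp) {
        tab <- gene_tabs[[sp]]
        if (nrow(tab) < 3) return(NULL)
        cc <- codon_gc3_correlations(rscu_matrix(tab), tab$gc3)
        data.frame(species = sp, codon = names(cc), r = unname(cc))
      }))
      write_tsv(corr, file.path(outdir, "codon_gc3_correlations.tsv"))
      list(gene_tabs = gene_tabs, sp_tab = sp_tab)
    }, error = function(e) on_fail("composition", e))
    gene_tabs <- res$gene_tabs
    species_tab <- res$sp_tab
    log_stage("composition",
              list(genes = sum(vapply(res$gene_tabs, nrow, integer(1)))))
  }

  # ---- RSCU consensus clustering -----------------------------------
  if ("cluster" %in% config$stages && !is.null(species_tab) &&
      nrow(species_tab) >= 3) {
    res <- tryCatch({
      m <- rscu_matrix(species_tab)
      cl <- rscu_cluster_consensus(m)
      write_consensus_newick(cl, file.path(outdir, "rscu_consensus.nwk"))
      cl
    }, error = function(e) on_fail("cluster", e))
    log_stage("cluster", list(species = nrow(species_tab),
                              settings = nrow(res$grid)))
  }

  # ---- expression stage --------------------------------------------
  if ("expression" %in% config$stages && !is.null(expression_tables)) {
    res <- tryCatch({
      out <- list()
      for (sp in names(expression_tables)) {
        tab <- composition_table(validated[[sp]], code)
        counts <- t(vapply(validated[[sp]], codon_counts,
                           integer(length(code$sense_codons)), code))
        ord <- codon_usage_pca(counts, expression_tables[[sp]],
                               config$hi_pct, config$lo_pct,
                               mode = config$ordination)
        write_tsv(ord, file.path(outdir,
                                 paste0("ordination_", sp, ".tsv")))
        pref <- preferred_codons(rscu_matrix(tab),
                                 expression_tables[[sp]],
                                 config$hi_pct, config$lo_pct,
                                 config$alpha)
        write_tsv(pref, file.path(outdir,
                                  paste0("preferred_codons_", sp, ".tsv")))
        out[[sp]] <- sum(pref$preferred)
      }
      out
    }, error = function(e) on_fail("expression", e))
    log_stage("expression",
              list(species = length(res),
                   preferred_calls = sum(unlist(res))))
  }

  # ---- substitution analysis ---------------------------------------
  if ("substitution" %in% config$stages && !is.null(supers)) {
    res <- tryCatch({
      n_pairs <- 0L
      for (i in seq_along(species)) for (j in seq_along(species)) {
        if (j <= i) next
        a <- species[i]; b <- species[j]
        tb <- substitution_tables(supers[[a]], supers[[b]], code)
        key <- pair_key(a, b)
        write_tsv(cbind(aa = rownames(tb$aa_matrix),
                        as.data.frame(tb$aa_matrix)),
                  file.path(outdir, paste0("aa_matrix_", key, ".tsv")))
        write_tsv(cbind(codon = rownames(tb$codon_matrix),
                        as.data.frame(tb$codon_matrix)),
                  file.path(outdir, paste0("codon_matrix_", key, ".tsv")))
        write_tsv(usage_deviation_test(tb),
                  file.path(outdir, paste0("usage_deviation_", key,
                                           ".tsv")))
        write_tsv(reciprocal_asymmetry_test(tb, config$alpha),
                  file.path(outdir, paste0("reciprocal_asymmetry_", key,
                                           ".tsv")))
        write_tsv(classify_codon_pairs(supers[[a]], supers[[b]], code),
                  file.path(outdir, paste0("codon_classes_", key,
                                           ".tsv")))
        th <- two_hit_summary(tb, code)
        write_tsv(th, file.path(outdir, paste0("two_hit_", key, ".tsv")))
        n_pairs <- n_pairs + 1L
      }
      n_pairs
    }, error = function(e) on_fail("substitution", e))
    log_stage("substitution", list(pairs = res))
  }

  manifest$outputs <- sort(list.files(outdir))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Summarise a completed pipeline run
#'
#' Reads the TSV outputs under a run directory and writes a single
#' plain-text report (`report.md`) tabulating species GC by position,
#' ENC and neutrality summaries, the consensus tree, preferred codons,
#' significant asymmetric substitutions and the two-hit excess. Sections
#' whose stage outputs are absent are marked unavailable, never
#' fabricated.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return path of the written report, invisibly.
#' @export
report <- function(run_dir) {
  lines <- c("# Comparative codon usage report", "")
  grab <- function(file) {
    p <- file.path(run_dir, file)
    if (file.exists(p))
      utils::read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  fmt <- function(df, digits = 3) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits)
    c(paste(colnames(df), collapse = "\t"),
      apply(df, 1, paste, collapse = "\t"))
  }
  section <- function(title, body) {
    c(paste("##", title), "", body, "")
  }
  sp <- grab("composition_species.tsv")
  lines <- c(lines, section(
    "Species composition (super-genes)",
    if (is.null(sp)) "unavailable"
    else fmt(sp[, c("id", "n_codons", "gc1", "gc2", "gc3", "gc12",
                    "enc")])))
  neut <- grab("neutrality.tsv")
  lines <- c(lines, section(
    "Neutrality regressions (GC12 ~ GC3)",
    if (is.null(neut)) "unavailable" else fmt(neut)))
  nwk <- file.path(run_dir, "rscu_consensus.nwk")
  lines <- c(lines, section(
    "RSCU consensus clustering",
    if (file.exists(nwk)) readLines(nwk) else "unavailable"))
  prefs <- list.files(run_dir, pattern = "^preferred_codons_",
                      full.names = TRUE)
  pref_body <- "unavailable"
  if (length(prefs) > 0) {
    pref_body <- unlist(lapply(prefs, function(p) {
      df <- utils::read.delim(p, stringsAsFactors = FALSE)
      df <- df[which(df$preferred), , drop = FALSE]
      sp_name <- sub("^preferred_codons_", "",
                     sub("\\.tsv$", "", basename(p)))
      c(paste0("species ", sp_name, ": ",
               if (nrow(df) == 0) "none"
               else paste(df$codon, collapse = " ")))
    }))
  }
  lines <- c(lines, section("Preferred codons (high vs low expression)",
                            pref_body))
  asym <- list.files(run_dir, pattern = "^reciprocal_asymmetry_",
                     full.names = TRUE)
  asym_body <- "unavailable"
  if (length(asym) > 0) {
    asym_body <- unlist(lapply(asym, function(p) {
      df <- utils::read.delim(p, stringsAsFactors = FALSE)
      df <- df[which(df$significant), , drop = FALSE]
      key <- sub("^reciprocal_asymmetry_", "",
                 sub("\\.tsv$", "", basename(p)))
      if (nrow(df) == 0) paste0(key, ": none")
      else c(paste0(key, ":"), fmt(df))
    }))
  }
  lines <- c(lines, section("Significant reciprocal asymmetries",
                            asym_body))
  th <- list.files(run_dir, pattern = "^two_hit_", full.names = TRUE)
  th_body <- "unavailable"
  if (length(th) > 0) {
    th_body <- vapply(th, function(p) {
      df <- utils::read.delim(p, stringsAsFactors = FALSE)
      key <- sub("^two_hit_", "", sub("\\.tsv$", "", basename(p)))
      ex <- if (nrow(df) == 0) NA_real_
      else sum(df$excess * df$n) / sum(df$n)
      sprintf("%s: weighted two-hit excess %.4f over %d cells",
              key, ex, nrow(df))
    }, character(1))
  }
  lines <- c(lines, section("Two-hit excess", th_body))
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
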