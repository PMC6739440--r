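#' Consensus hierarchical clustering of species RSCU profiles
#'
#' Species are clustered on their (dense) RSCU vectors once per setting of
#' a distance x linkage grid; the majority-rule consensus retains the
#' groupings that appear in more than half of the settings, with
#' per-bipartition support frequencies.
#'
#' @param species_rscu species x codons numeric matrix with no missing
#'   entries (species-level RSCU from super-genes is dense).
#' @param grid data.frame with columns `distance` (a [stats::dist()]
#'   method) and `linkage` (a [stats::hclust()] method). Default:
#'   Euclidean distance crossed with complete, average and Ward linkage.
#' @return object of class `consensus_cluster`: list with `grid`, `trees`
#'   (one `phylo` per setting), `consensus` (`phylo`, majority rule, clade
#'   support frequencies as node labels) and `support` (numeric vector per
#'   internal node of the consensus).
#' @export
rscu_cluster_consensus <- function(species_rscu, grid = NULL) {
  if (is.null(grid))
    grid <- data.frame(
      distance = "euclidean",
      linkage = c("complete", "average", "ward.D2"),
      stringsAsFactors = FALSE)
  if (nrow(species_rscu) < 3L)
    stop("consensus clustering needs at least 3 species")
  if (anyNA(species_rscu))
    stop("species RSCU matrix has missing entries; impute upstream ",
         "(species-level vectors from super-genes are dense)")
  species_rscu <- species_rscu[sort(rownames(species_rscu)), , drop = FALSE]
  trees <- lapply(seq_len(nrow(grid)), function(i) {
    d <- stats::dist(species_rscu, method = grid$distance[i])
    ape::as.phylo(stats::hclust(d, method = grid$linkage[i]))
  })
  cons <- ape::consensus(trees, p = 0.5, rooted = TRUE)
  counts <- ape::prop.clades(cons, trees, rooted = TRUE)
  counts[is.na(counts)] <- 0L
  support <- counts / length(trees)
  cons$node.label <- sprintf("%.2f", support)
  structure(list(grid = grid, trees = trees, consensus = cons,
                 support = support),
            class = "consensus_cluster")
}

#' @export
print.consensus_cluster <- function(x, ...) {
  cat(sprintf(
    "consensus_cluster: %d species, %d settings, %d consensus clades\n",
    length(x$consensus$tip.label), length(x$trees), length(x$support)))
  invisible(x)
}

#' Test whether a consensus tree contains a clade with exactly these tips
#'
#' @param cluster a [rscu_cluster_consensus()] result.
#' @param tips character vector of tip labels.
#' @return `TRUE` iff some internal node's descendant tips equal `tips`.
#' @export
has_clade <- function(cluster, tips) {
  tree <- cluster$consensus
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  any(vapply(parts, function(p) setequal(labs[p], tips), logical(1)))
}

#' Write a consensus tree as Newick with support values
#'
#' @param cluster a [rscu_cluster_consensus()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_consensus_newick <- function(cluster, path) {
  ape::write.tree(cluster$consensus, file = path)
  invisible(path)
}

expression_strata <- function(expression, ids, hi_pct = 90, lo_pct = 10) {
  expr <- expression[ids]
  ok <- !is.na(expr)
  if (sum(ok) < 2L) stop("too few genes with expression values")
  qs <- stats::quantile(expr[ok], probs = c(lo_pct, hi_pct) / 100,
                        names = FALSE)
  if (qs[1] == qs[2])
    stop("expression percentiles coincide (all-equal expression?); ",
         "high/low strata are undefined")
  # boundaries exclusive: strictly above / strictly below the percentiles
  group <- rep(NA_character_, length(ids))
  group[ok] <- "mid"
  group[ok & expr > qs[2]] <- "high"
  group[ok & expr < qs[1]] <- "low"
  if (!any(group %in% "high") || !any(group %in% "low"))
    stop("empty expression stratum")
  stats::setNames(group, ids)
}

#' Ordination of genes by codon frequencies, labelled by expression
#'
#' Genes are ordinated on their codon-frequency vectors (counts divided by
#' gene codon total) either by principal components (default) or by
#' correspondence analysis on the count table, and labelled `high`
#' (strictly above the upper expression percentile), `low` (strictly
#' below the lower percentile) or `mid`.
#'
#' @param counts_matrix genes x sense-codons count matrix (rows named by
#'   gene id).
#' @param expression named numeric vector of expression values; genes
#'   missing from it get label `NA`.
#' @param hi_pct,lo_pct stratification percentiles (defaults 90 / 10).
#' @param mode `"pca"` (default) or `"coa"` (correspondence analysis).
#' @return data.frame with `id`, `axis1`, `axis2`, `group`.
#' @export
codon_usage_pca <- function(counts_matrix, expression,
                            hi_pct = 90, lo_pct = 10,
                            mode = c("pca", "coa")) {
  mode <- match.arg(mode)
  if (nrow(counts_matrix) < 10L)
    stop("ordination needs at least 10 genes")
  ids <- rownames(counts_matrix)
  group <- expression_strata(expression, ids, hi_pct, lo_pct)
  if (mode == "pca") {
    freq <- counts_matrix / rowSums(counts_matrix)
    fit <- stats::prcomp(freq, center = TRUE, scale. = FALSE)
    coords <- fit$x[, 1:2, drop = FALSE]
  } else {
    fit <- MASS::corresp(counts_matrix, nf = 2)
    coords <- fit$rscore[, 1:2, drop = FALSE]
  }
  data.frame(id = ids, axis1 = unname(coords[, 1]),
             axis2 = unname(coords[, 2]),
             group = unname(group[ids]), stringsAsFactors = FALSE)
}

#' Expression-stratified preferred-codon calls
#'
#' A codon is preferred when its per-gene RSCU is significantly higher in
#' the high-expression gene set than in the low-expression set — whether
#' or not it is the majority codon of its amino acid. Default test:
#' two-sided Wilcoxon rank-sum on per-gene RSCU, Benjamini-Hochberg
#' adjusted across codons; `test = "chisq"` instead compares each codon's
#' pooled count against the rest of its family between strata.
#'
#' @param rscu_mat genes x codons RSCU matrix (rows named by gene id).
#' @param expression named numeric expression vector.
#' @param hi_pct,lo_pct stratification percentiles (defaults 90 / 10).
#' @param alpha adjusted-p threshold for the preferred flag (default
#'   0.05).
#' @param test `"ranksum"` (default) or `"chisq"`.
#' @param counts_matrix genes x codons count matrix; required for
#'   `test = "chisq"`.
#' @param code a [genetic_code()] (used by the chi-square mode).
#' @return data.frame per codon: `codon`, `mean_high`, `mean_low`,
#'   `statistic`, `p`, `p_adj`, `preferred`; codons untestable in either
#'   stratum carry `NA` and `preferred = FALSE`.
#' @export
preferred_codons <- function(rscu_mat, expression, hi_pct = 90, lo_pct = 10,
                             alpha = 0.05, test = c("ranksum", "chisq"),
                             counts_matrix = NULL, code = genetic_code()) {
  test <- match.arg(test)
  ids <- rownames(rscu_mat)
  group <- expression_strata(expression, ids, hi_pct, lo_pct)
  hi <- ids[group %in% "high"]
  lo <- ids[group %in% "low"]
  res <- lapply(colnames(rscu_mat), function(cdn) {
    xh <- rscu_mat[hi, cdn]; xl <- rscu_mat[lo, cdn]
    xh <- xh[is.finite(xh)]; xl <- xl[is.finite(xl)]
    out <- data.frame(codon = cdn, mean_high = NA_real_,
                      mean_low = NA_real_, statistic = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE)
    if (length(xh) == 0L || length(xl) == 0L) return(out)
    out$mean_high <- mean(xh)
    out$mean_low <- mean(xl)
    if (test == "ranksum") {
      wt <- suppressWarnings(stats::wilcox.test(xh, xl, exact = FALSE))
      out$statistic <- unname(wt$statistic)
      out$p <- wt$p.value
    } else {
      stopifnot(!is.null(counts_matrix))
      fam <- code$families[[translate_codon(cdn, code)]]
      fam_other <- setdiff(fam, cdn)
      tab <- rbind(
        c(sum(counts_matrix[hi, cdn]),
          sum(counts_matrix[hi, fam_other, drop = FALSE])),
        c(sum(counts_matrix[lo, cdn]),
          sum(counts_matrix[lo, fam_other, drop = FALSE])))
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(out)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      out$statistic <- unname(ct$statistic)
      out$p <- ct$p.value
    }
    out
  })
  res <- do.call(rbind, res)
  res$p_adj <- NA_real_
  tested <- !is.na(res$p)
  res$p_adj[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res$preferred <- !is.na(res$p_adj) & res$p_adj < alpha &
    res$mean_high > res$mean_low
  res
}
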