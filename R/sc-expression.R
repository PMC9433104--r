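#' Convert Ct values to log2 expression
#'
#' Standard single-cell qPCR transform: expression
#' `Et = max(0, LOD_Ct - Ct)`, so the detection limit maps to zero and each
#' cycle below it is one log2 unit of expression. Undetected reactions
#' (missing Ct) map to zero.
#'
#' @param ct Genes x cells Ct matrix (`NA` = undetected).
#' @param lod_ct Detection limit in cycles, > 0 (default 40).
#' @return Expression matrix of the same shape, values >= 0.
#' @export
ct_to_expression <- function(ct, lod_ct = 40) {
  if (lod_ct <= 0) stop("lod_ct must be positive")
  expr <- lod_ct - ct
  expr[is.na(expr) | expr < 0] <- 0
  expr
}

#' Quality-control filter for a single-cell expression matrix
#'
#' Two rules: genes detected in the no-cell / no-RT control columns above
#' `control_tol` are flagged (excluded from testing), and cells expressing
#' fewer than `min_genes` genes are removed.
#'
#' @param expr Genes x columns expression matrix (from
#'   [ct_to_expression()]).
#' @param labels Per-column labels; "control" marks control columns.
#' @param control_tol Maximum tolerated control expression (default 0).
#' @param min_genes Minimum detected genes per cell (default 1).
#' @return List: `expr` (controls and failing cells removed), `labels`,
#'   `kept_cells`, `flagged_genes`, `removed_cells`.
#' @export
qc_filter <- function(expr, labels, control_tol = 0, min_genes = 1) {
  stopifnot(ncol(expr) == length(labels))
  is_ctrl <- labels == "control"
  flagged <- rownames(expr)[
    rowSums(expr[, is_ctrl, drop = FALSE] > control_tol) > 0]
  cells <- which(!is_ctrl)
  genes_per_cell <- colSums(expr[, cells, drop = FALSE] > 0)
  keep <- cells[genes_per_cell >= min_genes]
  if (!length(keep)) stop("QC removed every cell")
  removed <- colnames(expr)[setdiff(cells, keep)]
  list(expr = expr[, keep, drop = FALSE], labels = labels[keep],
       kept_cells = colnames(expr)[keep], flagged_genes = flagged,
       removed_cells = removed)
}

#' Migratory-versus-nonmigratory differential expression
#'
#' Per-gene two-sided Mann-Whitney U test between the two label groups with
#' Benjamini-Hochberg adjustment across the tested genes; a gene is called
#' at `q < fdr`. Direction is the sign of the migratory-minus-nonmigratory
#' median difference. Constant genes get p = 1 and a flag.
#'
#' @param expr Genes x cells expression matrix (post-QC, no controls).
#' @param labels Per-cell group labels with exactly two levels; the first
#'   level alphabetically... no: `group1` names the numerator group
#'   (default "migratory").
#' @param group1 Label treated as the "up" direction (default "migratory").
#' @param fdr Significance level on q (default 0.1).
#' @param min_cells Minimum cells per group (default 30).
#' @return Data frame, one row per gene: `gene`, `statistic`, `p`, `q`,
#'   `direction`, `significant`, `flag`.
#' @export
differential_expression <- function(expr, labels, group1 = "migratory",
                                    fdr = 0.1, min_cells = 30) {
  stopifnot(ncol(expr) == length(labels))
  g1 <- labels == group1
  g2 <- !g1
  if (sum(g1) < min_cells || sum(g2) < min_cells)
    stop(sprintf("need at least %d cells per group", min_cells))
  res <- lapply(rownames(expr), function(g) {
    x <- expr[g, g1]; y <- expr[g, g2]
    if (length(unique(c(x, y))) == 1L)
      return(data.frame(gene = g, statistic = NA_real_, p = 1,
                        direction = 0, flag = "constant",
                        stringsAsFactors = FALSE))
    tt <- mann_whitney_u(x, y)
    data.frame(gene = g, statistic = tt$statistic, p = tt$p_two_sided,
               direction = sign(stats::median(x) - stats::median(y)),
               flag = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr
  out[, c("gene", "statistic", "p", "q", "direction", "significant", "flag")]
}

#' Migration correlogram
#'
#' Pearson correlations of each gene with the per-cell migration metric;
#' genes significantly correlated with migration (p < `alpha`) enter a
#' symmetric correlation matrix (migration first) whose entries are masked
#' (`NA`) wherever the pairwise correlation is not significant at `alpha`.
#' Zero-variance genes are masked.
#'
#' @param expr Genes x cells expression matrix.
#' @param metric Per-cell migration metric.
#' @param alpha Significance mask level (default 0.05).
#' @return List: `genes` (selected), `r` (masked correlation matrix with
#'   unit diagonal), `gene_migration` (data frame of per-gene r and p).
#' @export
migration_correlogram <- function(expr, metric, alpha = 0.05) {
  stopifnot(ncol(expr) == length(metric))
  gm <- do.call(rbind, lapply(rownames(expr), function(g) {
    ct <- correlation(expr[g, ], metric)
    data.frame(gene = g, r = ct$r, p = ct$p_two_sided,
               stringsAsFactors = FALSE)
  }))
  sel <- gm$gene[!is.na(gm$p) & gm$p < alpha]
  vars <- c("migration", sel)
  k <- length(vars)
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  dat <- rbind(migration = metric, expr[sel, , drop = FALSE])
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    ct <- correlation(dat[i, ], dat[j, ])
    if (!is.na(ct$p_two_sided) && ct$p_two_sided < alpha)
      r[i, j] <- r[j, i] <- ct$r
  }
  list(genes = sel, r = r, gene_migration = gm)
}
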