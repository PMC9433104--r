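#' Default 95-gene qPCR panel
#'
#' Gene names for the simulated single-cell qPCR panel: receptors known to
#' covary with T cell migration (CD2, CD58, CD244, CXCR3, IL18R1, LAG3),
#' cytotoxicity genes that do not (CAR, FASLG, GZMB, PRF1), and generic
#' filler transcripts.
#'
#' @param n_genes Panel size (default 95).
#' @return Character vector of gene names.
#' @export
qpcr_panel <- function(n_genes = 95) {
  named <- c("CD2", "CD58", "CD244", "CXCR3", "IL18R1", "LAG3",
             "CAR", "FASLG", "GZMB", "PRF1")
  if (n_genes < length(named)) return(named[seq_len(n_genes)])
  c(named, sprintf("GENE%03d", seq_len(n_genes - length(named))))
}

#' Simulate a single-cell qPCR cohort with migration labels
#'
#' Draws Ct values for a panel of genes over migratory and nonmigratory
#' cells. Each cell carries a latent migration score (higher in the
#' migratory group); the `effect_genes` have their expression shifted by
#' `effect_size` log2 units per unit of migration score, so they covary with
#' migration. No-cell and no-RT control columns are included at the Ct
#' detection limit.
#'
#' @param n_migratory,n_nonmigratory Cells per group (defaults 48 and 44).
#' @param n_genes Panel size, default 95.
#' @param effect_genes Genes shifted in migratory cells; default the six
#'   migration receptors of [qpcr_panel()].
#' @param effect_size Shift in log2 expression units (Ct cycles) per unit of
#'   migration score; `1` is a two-fold shift. Must be finite.
#' @param noise_sd Per-measurement Ct noise SD (default 1).
#' @param lod_ct Detection limit in cycles (default 40); draws at or beyond
#'   it are undetected (`NA`).
#' @param n_controls Number of no-cell and of no-RT control columns (each).
#' @param seed Integer seed.
#' @return A `qpcr_cohort` list: `ct` (genes x columns matrix, `NA` =
#'   undetected), `labels` ("migratory", "nonmigratory", "control"),
#'   `migration_metric` (per cell, `NA` for controls), `lod_ct`,
#'   `effect_genes`.
#' @export
simulate_qpcr_cohort <- function(n_migratory = 48, n_nonmigratory = 44,
                                 n_genes = 95,
                                 effect_genes = qpcr_panel(95)[1:6],
                                 effect_size = 1, noise_sd = 1,
                                 lod_ct = 40, n_controls = 2, seed = 1L) {
  if (!is.finite(effect_size)) stop("effect_size must be finite")
  genes <- qpcr_panel(n_genes)
  if (!all(effect_genes %in% genes))
    stop("effect_genes must be a subset of the gene panel")
  with_seed(seed, {
    n_cells <- n_migratory + n_nonmigratory
    labels <- c(rep("migratory", n_migratory),
                rep("nonmigratory", n_nonmigratory),
                rep("control", 2 * n_controls))
    # latent migration score: separated but overlapping groups
    metric <- c(stats::rnorm(n_migratory, 1, 0.25),
                stats::rnorm(n_nonmigratory, 0, 0.25),
                rep(NA_real_, 2 * n_controls))
    base_ct <- stats::runif(n_genes, 22, 32)
    ct <- matrix(stats::rnorm(n_genes * n_cells, 0, noise_sd),
                 n_genes, n_cells) + base_ct
    eff <- genes %in% effect_genes
    ct[eff, ] <- ct[eff, , drop = FALSE] -
      effect_size * matrix(metric[seq_len(n_cells)], sum(eff), n_cells,
                           byrow = TRUE)
    ct <- cbind(ct, matrix(lod_ct, n_genes, 2 * n_controls))
    ct[ct >= lod_ct] <- NA_real_
    dimnames(ct) <- list(genes,
      c(sprintf("cell%03d", seq_len(n_cells)),
        sprintf("nocell%02d", seq_len(n_controls)),
        sprintf("noRT%02d", seq_len(n_controls))))
    structure(list(ct = ct, labels = labels, migration_metric = metric,
                   lod_ct = lod_ct, effect_genes = effect_genes),
              class = "qpcr_cohort")
  })
}
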