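# Synthetic expression matrices with planted DEG clusters, mirroring the
# co-culture RNA-seq design: per cell type, monoculture controls and
# co-culture samples at each timepoint.

#' Generate an expression phantom with planted DEG clusters
#'
#' Baseline expression is log-normal; planted DEGs multiply their
#' co-culture samples by `2^profile` where each cluster has its own
#' temporal log2-FC profile (peaking at a different timepoint, sign by
#' direction). Everything is recorded in `truth`.
#'
#' @param n_genes total genes
#' @param n_up,n_down planted up-/down-regulated DEGs per cell type
#' @param n_clusters_up,n_clusters_down planted temporal clusters per
#'   direction
#' @param timepoints numeric vector of sampling times (h)
#' @param cell_types cell types to simulate
#' @param fc_magnitude peak |log2 FC| of planted DEGs
#' @param noise_sd log2-scale noise added to fold changes
#' @param seed integer seed
#' @return list: `expr` (genes x samples matrix), `samples` (sheet with
#'   sample, cell_type, condition, time), `truth` (planted DEG sets and
#'   cluster memberships per cell type)
#' @export
make_expression_phantom <- function(n_genes = 2000, n_up = 50, n_down = 30,
                                    n_clusters_up = 2, n_clusters_down = 2,
                                    timepoints = c(12, 24),
                                    cell_types = c("EC", "MSC"),
                                    fc_magnitude = 3, noise_sd = 0.1,
                                    seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  nt <- length(timepoints)
  samples <- expand.grid(cell_type = cell_types,
                         condition = c("mono", "co"),
                         time = timepoints, stringsAsFactors = FALSE)
  samples$sample <- with(samples, paste(cell_type, condition, time, sep = "_"))
  expr <- matrix(0, n_genes, nrow(samples),
                 dimnames = list(genes, samples$sample))
  truth <- list()
  base_all <- matrix(2^runif(n_genes * length(cell_types), 4, 10),
                     n_genes, length(cell_types))
  for (ci in seq_along(cell_types)) {
    ct <- cell_types[ci]
    base <- base_all[, ci]
    # disjoint planted DEGs per cell type so no gene changes in both
    offset <- (ci - 1) * (n_up + n_down)
    up_idx <- offset + seq_len(n_up)
    down_idx <- offset + n_up + seq_len(n_down)
    profile <- matrix(0, n_genes, nt)
    assign_cluster <- function(idx, n_cl, sign) {
      cl <- rep(seq_len(n_cl), length.out = length(idx))
      for (j in seq_len(n_cl)) {
        peak_t <- ((j - 1) %% nt) + 1
        shape <- exp(-0.5 * ((seq_len(nt) - peak_t) / 0.6)^2)
        rows <- idx[cl == j]
        profile[rows, ] <<- matrix(sign * fc_magnitude * shape,
                                   length(rows), nt, byrow = TRUE)
      }
      cl
    }
    cl_up <- assign_cluster(up_idx, n_clusters_up, +1)
    cl_down <- assign_cluster(down_idx, n_clusters_down, -1)
    for (ti in seq_len(nt)) {
      mono_col <- samples$sample[samples$cell_type == ct &
                                   samples$condition == "mono" &
                                   samples$time == timepoints[ti]]
      co_col <- samples$sample[samples$cell_type == ct &
                                 samples$condition == "co" &
                                 samples$time == timepoints[ti]]
      noise <- rnorm(n_genes, 0, noise_sd)
      expr[, mono_col] <- base
      expr[, co_col] <- base * 2^(profile[, ti] + noise)
    }
    truth[[ct]] <- list(up = genes[up_idx], down = genes[down_idx],
                        cluster_up = setNames(cl_up, genes[up_idx]),
                        cluster_down = setNames(cl_down, genes[down_idx]))
  }
  list(expr = expr, samples = samples, truth = truth)
}

#' Read a PPI candidate score table
#'
#' Plain-TSV contract standing in for a live interaction-database query:
#' columns `gene_a`, `cell_type_a`, `gene_b`, `cell_type_b`,
#' `database_score`, `experimental_score`, `textmining_score`.
#'
#' @param path TSV file
#' @return data.frame
#' @export
read_ppi_candidates <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
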