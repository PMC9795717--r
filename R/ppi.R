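# Transcriptomic stage: log2 fold changes of co-culture vs monoculture
# expression per cell type and timepoint, DEG calling at |log2FC| > 1,
# temporal clustering (cosine distance + Ward linkage, cut at the
# smallest k whose clusters all satisfy mean within-cluster Pearson
# correlation > 0.6), and cross-cell-type PPI screening at strict
# all-three-scores > 0.9.

#' Log2 fold changes against the monoculture control
#'
#' For each cell type and timepoint, replicate columns are averaged and
#' `log2((co + eps) / (mono + eps))` computed per gene. The pseudocount
#' eps defaults to 1 for integer count matrices and half the smallest
#' positive value otherwise. A z-normalized profile (mean 0, sd 1 across
#' timepoints) is attached per gene; genes with a flat profile get a
#' zero z-profile.
#'
#' @param expr numeric matrix, genes x samples, with rownames
#' @param samples data.frame with columns `sample` (matching colnames of
#'   `expr`), `cell_type`, `condition` (`"mono"` / `"co"`), `time`
#' @param pseudocount override for eps
#' @return object of class `fold_change_set`: per-cell-type `fc` and `z`
#'   matrices (genes x timepoints), `times`, `cell_types`, `eps`
#' @export
fold_changes <- function(expr, samples, pseudocount = NULL) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  need <- c("sample", "cell_type", "condition", "time")
  if (!all(need %in% names(samples)))
    stop("samples sheet must have columns: ", paste(need, collapse = ", "))
  if (!all(samples$sample %in% colnames(expr)))
    stop("sample sheet entries missing from expression matrix")
  eps <- if (!is.null(pseudocount)) pseudocount
         else if (all(expr == round(expr)) && all(expr >= 0)) 1
         else min(expr[expr > 0]) / 2
  cts <- unique(samples$cell_type)
  times <- sort(unique(samples$time))
  fc <- z <- list()
  for (ct in cts) {
    mat <- matrix(NA_real_, nrow(expr), length(times),
                  dimnames = list(rownames(expr), as.character(times)))
    for (ti in seq_along(times)) {
      co <- samples$sample[samples$cell_type == ct &
                             samples$condition == "co" &
                             samples$time == times[ti]]
      mono <- samples$sample[samples$cell_type == ct &
                               samples$condition == "mono" &
                               samples$time == times[ti]]
      if (!length(co) || !length(mono))
        stop("missing ", if (!length(co)) "co" else "mono",
             " samples for cell type ", ct, " at time ", times[ti])
      co_m <- rowMeans(expr[, co, drop = FALSE])
      mono_m <- rowMeans(expr[, mono, drop = FALSE])
      mat[, ti] <- log2((co_m + eps) / (mono_m + eps))
    }
    fc[[ct]] <- mat
    mu <- rowMeans(mat)
    s <- apply(mat, 1, sd)
    zz <- (mat - mu) / ifelse(s == 0, Inf, s)
    z[[ct]] <- zz
  }
  structure(list(fc = fc, z = z, times = times, cell_types = cts, eps = eps),
            class = "fold_change_set")
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when its log2 fold change strictly exceeds `up` (or
#' falls strictly below `down`) at any timepoint; the direction is taken
#' from the timepoint of largest |FC|. A fold change of exactly 1.0 is
#' not a DEG (strict inequality).
#'
#' @param fcs a [fold_changes()] result
#' @param up,down thresholds (log2 units)
#' @return list per cell type with character vectors `up` and `down`
#' @export
call_degs <- function(fcs, up = 1, down = -1) {
  stopifnot(inherits(fcs, "fold_change_set"))
  out <- list()
  for (ct in fcs$cell_types) {
    mat <- fcs$fc[[ct]]
    hit <- apply(mat, 1, function(v) any(v > up) || any(v < down))
    peak <- mat[cbind(seq_len(nrow(mat)), max.col(abs(mat)))]
    dir_up <- peak > 0
    out[[ct]] <- list(up = rownames(mat)[hit & dir_up],
                      down = rownames(mat)[hit & !dir_up])
  }
  structure(out, class = "deg_sets")
}

.cosine_dist <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- Inf          # flat profiles: maximally distant
  mn <- m / nrm
  sim <- tcrossprod(mn)
  sim[!is.finite(sim)] <- 0
  d <- 1 - sim
  d[d < 0] <- 0
  as.dist(d)
}

.mean_pairwise_cor <- function(m) {
  if (nrow(m) < 2) return(1)    # singleton passes vacuously
  cm <- suppressWarnings(cor(t(m)))
  vals <- cm[lower.tri(cm)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(1)
  mean(vals)
}

#' Cluster DEG temporal profiles
#'
#' Agglomerative clustering with Ward linkage on cosine distances among
#' z-normalized fold-change profiles, cut at the smallest number of
#' clusters k such that every cluster's mean pairwise Pearson
#' correlation exceeds `min_within_corr` (singletons pass vacuously).
#' Clusters are labelled `<cellType>-U<j>` / `-D<j>` by the dominant
#' direction of their members, ordered by mean peak time. If the
#' criterion is unreachable before k = n, the all-singleton clustering
#' is returned with a warning.
#'
#' @param fcs [fold_changes()] result
#' @param degs [call_degs()] result
#' @param min_within_corr within-cluster mean pairwise Pearson threshold
#' @return object of class `deg_cluster_set`: `assignments` (data.frame:
#'   gene, cell_type, cluster, direction), `k` per cell type,
#'   `within_correlation` per cluster
#' @export
cluster_degs <- function(fcs, degs, min_within_corr = 0.6) {
  stopifnot(inherits(fcs, "fold_change_set"), inherits(degs, "deg_sets"))
  assignments <- list()
  kk <- list()
  wc <- list()
  for (ct in fcs$cell_types) {
    genes <- c(degs[[ct]]$up, degs[[ct]]$down)
    if (length(genes) < 2) {
      if (length(genes) == 1)
        assignments[[ct]] <- data.frame(gene = genes, cell_type = ct,
                                        cluster = paste0(ct, "-U1"),
                                        direction = "U")
      kk[[ct]] <- length(genes)
      next
    }
    prof <- fcs$z[[ct]][genes, , drop = FALSE]
    hc <- hclust(.cosine_dist(prof), method = "ward.D2")
    cl <- NULL
    for (k in seq_len(length(genes))) {
      cand <- cutree(hc, k = k)
      ok <- all(vapply(split(seq_along(genes), cand), function(ix)
        .mean_pairwise_cor(prof[ix, , drop = FALSE]) > min_within_corr,
        logical(1)))
      if (ok) { cl <- cand; kk[[ct]] <- k; break }
    }
    if (is.null(cl)) {
      warning("within-correlation criterion unreachable for ", ct,
              "; returning singletons")
      cl <- seq_along(genes)
      kk[[ct]] <- length(genes)
    }
    # label clusters by direction and mean peak-time order
    fcmat <- fcs$fc[[ct]][genes, , drop = FALSE]
    info <- lapply(split(seq_along(genes), cl), function(ix) {
      sub <- fcmat[ix, , drop = FALSE]
      peaks <- max.col(abs(sub))
      dir <- if (mean(sub[cbind(seq_len(nrow(sub)), peaks)] > 0) >= 0.5)
        "U" else "D"
      list(ix = ix, dir = dir, peak = mean(fcs$times[peaks]))
    })
    labels_ct <- character(length(genes))
    for (dir in c("U", "D")) {
      grp <- info[vapply(info, function(g) g$dir == dir, logical(1))]
      if (!length(grp)) next
      ord <- order(vapply(grp, function(g) g$peak, numeric(1)))
      for (j in seq_along(ord)) {
        g <- grp[[ord[j]]]
        labels_ct[g$ix] <- paste0(ct, "-", dir, j)
      }
    }
    assignments[[ct]] <- data.frame(gene = genes, cell_type = ct,
                                    cluster = labels_ct,
                                    direction = substr(sub(".*-", "",
                                                           labels_ct), 1, 1))
    for (lab in unique(labels_ct)) {
      ix <- which(labels_ct == lab)
      wc[[lab]] <- .mean_pairwise_cor(prof[ix, , drop = FALSE])
    }
  }
  structure(list(assignments = do.call(rbind, assignments), k = kk,
                 within_correlation = wc),
            class = "deg_cluster_set")
}

#' Screen candidate PPIs for high-confidence cross-cell-type edges
#'
#' An edge is retained when its database, experimental and text-mining
#' scores each strictly exceed `threshold`, its endpoints are DEGs in
#' two different cell types, and neither endpoint gene is a DEG in both
#' cell types (genes changed in both are excluded from the screen).
#'
#' @param candidates data.frame with columns `gene_a`, `cell_type_a`,
#'   `gene_b`, `cell_type_b`, `database_score`, `experimental_score`,
#'   `textmining_score` (all scores in \[0, 1\])
#' @param degs [call_degs()] result
#' @param threshold confidence threshold (strict)
#' @return data.frame of retained edges, class `ppi_network`
#' @export
filter_ppis <- function(candidates, degs, threshold = 0.9) {
  need <- c("gene_a", "cell_type_a", "gene_b", "cell_type_b",
            "database_score", "experimental_score", "textmining_score")
  if (!all(need %in% names(candidates)))
    stop("candidate table must have columns: ", paste(need, collapse = ", "))
  scores <- candidates[, c("database_score", "experimental_score",
                           "textmining_score")]
  bad <- which(rowSums(scores < 0 | scores > 1 | is.na(scores)) > 0)
  if (length(bad))
    stop("malformed score outside [0, 1] in row ", bad[1])
  deg_all <- lapply(degs, function(d) union(d$up, d$down))
  shared <- Reduce(intersect, deg_all)
  in_degs <- function(gene, ct) {
    ct <- as.character(ct)
    !is.null(deg_all[[ct]]) && gene %in% deg_all[[ct]]
  }
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    row <- candidates[i, ]
    all(scores[i, ] > threshold) &&
      row$cell_type_a != row$cell_type_b &&
      in_degs(row$gene_a, row$cell_type_a) &&
      in_degs(row$gene_b, row$cell_type_b) &&
      !(row$gene_a %in% shared) && !(row$gene_b %in% shared)
  }, logical(1))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ppi_network", "data.frame")
  out
}

#' Convert a PPI network table to an igraph object
#'
#' @param network a `ppi_network` (see [filter_ppis()])
#' @return undirected igraph graph with cell-type vertex attributes
#' @export
ppi_graph <- function(network) {
  if (!nrow(network)) return(igraph::make_empty_graph(directed = FALSE))
  verts <- unique(data.frame(
    name = c(paste0(network$cell_type_a, ":", network$gene_a),
             paste0(network$cell_type_b, ":", network$gene_b)),
    cell_type = c(as.character(network$cell_type_a),
                  as.character(network$cell_type_b)),
    gene = c(network$gene_a, network$gene_b)))
  edges <- data.frame(
    from = paste0(network$cell_type_a, ":", network$gene_a),
    to = paste0(network$cell_type_b, ":", network$gene_b),
    database_score = network$database_score,
    experimental_score = network$experimental_score,
    textmining_score = network$textmining_score)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Write a PPI network as GraphML
#'
#' @param network `ppi_network`
#' @param path output file
#' @export
write_ppi_graphml <- function(network, path) {
  igraph::write_graph(ppi_graph(network), path, format = "graphml")
  invisible(path)
}
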