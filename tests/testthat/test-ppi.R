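# Transcriptomic stage: fold changes, DEG calling, temporal clustering
# and PPI screening.

.toy_expr <- function() {
  # 3 genes x (mono, co) for one cell type and one timepoint, counts
  expr <- matrix(c(10, 100, 7,
                   40, 100, 0), ncol = 2,
                 dimnames = list(c("gA", "gB", "gC"),
                                 c("EC_mono_12", "EC_co_12")))
  samples <- data.frame(sample = c("EC_mono_12", "EC_co_12"),
                        cell_type = "EC",
                        condition = c("mono", "co"), time = 12)
  list(expr = expr, samples = samples)
}

test_that("fold changes match hand-computed log2 ratios with pseudocount", {
  toy <- .toy_expr()
  fcs <- fold_changes(toy$expr, toy$samples)
  expect_equal(fcs$eps, 1)   # integer counts
  hand <- log2(c(41, 101, 1) / c(11, 101, 8))
  expect_equal(unname(fcs$fc$EC[, 1]), hand)

  # co = 4 * mono with a large pseudocount-insensitive baseline
  expr <- matrix(c(1000, 4000), 1, dimnames = list("g", c("m", "c")))
  sheet <- data.frame(sample = c("m", "c"), cell_type = "EC",
                      condition = c("mono", "co"), time = 12)
  expect_equal(unname(fold_changes(expr, sheet)$fc$EC[, 1]), 2,
               tolerance = 1e-3)
  # identical conditions give exactly zero
  expr0 <- matrix(c(7, 7), 1, dimnames = list("g", c("m", "c")))
  expect_equal(unname(fold_changes(expr0, sheet)$fc$EC[, 1]), 0)
  # missing control is an error naming the cell type and time
  bad <- sheet; bad$condition <- c("co", "co")
  expect_error(fold_changes(expr, bad), "mono.*EC.*12")
})

test_that("DEG calling is strict at the threshold and exact on planted data", {
  fcs <- structure(list(
    fc = list(EC = matrix(c(1.0, 0.2, -1.2, 0.4,
                            0.9, 1.7, -0.5, -1.0), 4, 2,
                          dimnames = list(paste0("g", 1:4), c("12", "24")))),
    z = list(), times = c(12, 24), cell_types = "EC", eps = 1),
    class = "fold_change_set")
  degs <- call_degs(fcs)
  # g1 peaks at exactly 1.0 -> not a DEG; g2 hits 1.7 -> up;
  # g3 dips to -1.2 -> down; g4 touches -1.0 -> not a DEG
  expect_equal(degs$EC$up, "g2")
  expect_equal(degs$EC$down, "g3")

  exph <- make_expression_phantom(n_up = 50, n_down = 30, seed = 3)
  f <- fold_changes(exph$expr, exph$samples)
  d <- call_degs(f)
  for (ct in c("EC", "MSC")) {
    expect_setequal(d[[ct]]$up, exph$truth[[ct]]$up)
    expect_setequal(d[[ct]]$down, exph$truth[[ct]]$down)
    expect_length(intersect(d[[ct]]$up, d[[ct]]$down), 0)
  }
})

# greedy Ward (ward.D2) agglomeration by the Lance-Williams update,
# tracking merged member sets - an independent oracle for small point sets
.ward_merge_oracle <- function(d) {
  d <- as.matrix(d)^2          # ward.D2 operates on squared dissimilarities
  n <- nrow(d)
  active <- seq_len(n)
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  merges <- list()
  while (length(active) >= 2) {
    best <- c(NA, NA); bestval <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      a <- active[j]; b <- active[i]
      if (d[a, b] < bestval) { bestval <- d[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    merged <- sort(c(members[[a]], members[[b]]))
    merges[[length(merges) + 1]] <- merged
    for (k in setdiff(active, c(a, b))) {
      na <- sizes[a]; nb <- sizes[b]; nk <- sizes[k]
      d_new <- ((na + nk) * d[a, k] + (nb + nk) * d[b, k] -
                  nk * d[a, b]) / (na + nb + nk)
      d[a, k] <- d[k, a] <- d_new
    }
    sizes[a] <- sizes[a] + sizes[b]
    members[[a]] <- merged
    active <- setdiff(active, b)
  }
  merges
}

test_that("Ward linkage on cosine distances matches the Lance-Williams oracle", {
  prof <- rbind(c(1, 0, 0, 0.1), c(0.9, 0.1, 0, 0),
                c(0, 1, 0.2, 0), c(0.05, 0.9, 0.3, 0.02))
  d <- angiocross:::.cosine_dist(prof)
  hc <- hclust(d, method = "ward.D2")
  oracle <- .ward_merge_oracle(d)
  members <- vector("list", 3)
  for (step in 1:3) {
    got <- sort(unlist(lapply(hc$merge[step, ], function(x)
      if (x < 0) -x else members[[x]])))
    members[[step]] <- got
    expect_equal(got, oracle[[step]], info = paste("merge step", step))
  }
})

test_that("cluster_degs recovers planted clusters and honours the 0.6 rule", {
  exph <- make_expression_phantom(timepoints = c(6, 12, 24, 48),
                                  n_clusters_up = 2, n_clusters_down = 2,
                                  seed = 5)
  fcs <- fold_changes(exph$expr, exph$samples)
  degs <- call_degs(fcs)
  cls <- cluster_degs(fcs, degs)
  expect_true(all(unlist(cls$within_correlation) > 0.6))
  for (ct in c("EC", "MSC")) {
    tr <- exph$truth[[ct]]
    truth_lab <- c(paste0("U", tr$cluster_up), paste0("D", tr$cluster_down))
    names(truth_lab) <- c(names(tr$cluster_up), names(tr$cluster_down))
    asn <- cls$assignments[cls$assignments$cell_type == ct, ]
    expect_equal(adjusted_rand_index(truth_lab[asn$gene], asn$cluster), 1)
    # every DEG appears in exactly one cluster
    expect_setequal(asn$gene, c(tr$up, tr$down))
    expect_false(any(duplicated(asn$gene)))
  }

  # all-identical profiles collapse to a single cluster
  expr <- cbind(matrix(2^5, 4, 2), matrix(2^8, 4, 2))
  dimnames(expr) <- list(paste0("g", 1:4), c("m6", "m12", "c6", "c12"))
  sheet <- data.frame(sample = colnames(expr), cell_type = "EC",
                      condition = rep(c("mono", "co"), each = 2),
                      time = rep(c(6, 12), 2))
  f1 <- fold_changes(expr, sheet, pseudocount = 0)
  d1 <- call_degs(f1)
  c1 <- cluster_degs(f1, d1)
  expect_equal(c1$k$EC, 1)
})

test_that("the PPI filter equals a brute-force row filter on a toy table", {
  degs <- structure(list(
    EC = list(up = c("A1", "A2", "SHARED"), down = "A3"),
    MSC = list(up = c("B1", "B2"), down = c("B3", "SHARED"))),
    class = "deg_sets")
  tab <- data.frame(
    gene_a = c("A1", "A1", "A2", "A3", "SHARED", "A1", "ZZ", "A2", "A1", "A2"),
    cell_type_a = c("EC", "EC", "EC", "EC", "EC", "EC", "EC", "EC", "EC", "MSC"),
    gene_b = c("B1", "B2", "B3", "B1", "B1", "SHARED", "B2", "A1", "B1", "B1"),
    cell_type_b = c("MSC", "MSC", "MSC", "MSC", "MSC", "MSC", "MSC", "EC",
                    "MSC", "MSC"),
    database_score = c(0.95, 0.91, 0.99, 0.95, 0.99, 0.95, 0.95, 0.95, 0.90,
                       0.95),
    experimental_score = c(0.99, 0.95, 0.95, 0.92, 0.99, 0.95, 0.95, 0.95,
                           0.95, 0.95),
    textmining_score = c(0.92, 0.95, 0.91, 0.99, 0.99, 0.95, 0.95, 0.95,
                         0.95, 0.95))
  shared <- intersect(c("A1", "A2", "SHARED", "A3"),
                      c("B1", "B2", "B3", "SHARED"))
  brute <- tab[
    tab$database_score > 0.9 & tab$experimental_score > 0.9 &
      tab$textmining_score > 0.9 &
      tab$cell_type_a != tab$cell_type_b &
      mapply(function(g, ct) g %in% unlist(degs[[ct]]), tab$gene_a,
             tab$cell_type_a) &
      mapply(function(g, ct) g %in% unlist(degs[[ct]]), tab$gene_b,
             tab$cell_type_b) &
      !(tab$gene_a %in% shared) & !(tab$gene_b %in% shared), ]
  net <- filter_ppis(tab, degs)
  expect_equal(nrow(net), nrow(brute))
  expect_equal(paste(net$gene_a, net$gene_b),
               paste(brute$gene_a, brute$gene_b))

  # strictness at the threshold and score validation
  row <- tab[1, ]; row$experimental_score <- 0.9
  expect_equal(nrow(filter_ppis(row, degs)), 0)
  bad <- tab[1, ]; bad$database_score <- 1.2
  expect_error(filter_ppis(bad, degs), "row 1")

  # raising the threshold never adds edges
  n_low <- nrow(filter_ppis(tab, degs, threshold = 0.9))
  n_high <- nrow(filter_ppis(tab, degs, threshold = 0.95))
  expect_lte(n_high, n_low)
})

test_that("the documented high-confidence interactions survive the filter", {
  cand <- read_ppi_candidates(
    system.file("extdata", "ppi_candidates_synthetic.tsv",
                package = "angiocross"))
  degs <- structure(list(
    EC = list(up = c("BMP2", "BMP4", "IL1B"), down = "NOTCH4"),
    MSC = list(up = c("BMPR1A", "IL1R1"), down = "PDGFRB")),
    class = "deg_sets")
  net <- filter_ppis(cand, degs)
  expect_setequal(paste(net$gene_a, net$gene_b),
                  c("BMP2 BMPR1A", "BMP4 BMPR1A", "IL1B IL1R1"))
  g <- ppi_graph(net)
  expect_equal(igraph::ecount(g), 3)
})
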