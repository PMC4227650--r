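# Independent brute-force oracles and tiny fixture builders shared by the
# unit tests. Oracles are written with explicit loops, independent of the
# package's vectorized implementations.

# Minimal two-condition compendium from a named value spec:
# values: list(gene_id = c(control_reps, induced_reps))
tiny_compendium <- function(values, n_control, n_induced,
                            scale_tag = "tiny") {
  m <- do.call(rbind, values)
  rownames(m) <- names(values)
  colnames(m) <- c(sprintf("c%d", seq_len(n_control)),
                   sprintf("h%d", seq_len(n_induced)))
  ann <- tibble::tibble(
    sample_id = colnames(m),
    tissue = "seedling",
    condition = rep(c("control", "heat"), c(n_control, n_induced)),
    genotype = "wt",
    timepoint_h = rep(c(0, 2), c(n_control, n_induced)),
    replicate = c(seq_len(n_control), seq_len(n_induced))
  )
  expression_compendium(m, ann, scale_tag = scale_tag)
}

# Brute-force induction statistics: explicit per-gene loops and sums.
oracle_induction <- function(values, ann, control, induced, eps = 1e-6) {
  ctl <- ann$sample_id[ann$condition == control]
  ind <- ann$sample_id[ann$condition == induced]
  out <- NULL
  for (g in rownames(values)) {
    mc <- sum(values[g, ctl]) / length(ctl)
    mi <- sum(values[g, ind]) / length(ind)
    out <- rbind(out, data.frame(
      probe_id = g, mean_control = mc, mean_induced = mi,
      fold = mi / max(mc, eps), difference = mi - mc
    ))
  }
  out
}

# Brute-force per-gene collapse: group-by with an explicit loop, keeping
# the probe with the highest induced mean (probe_id tie-break).
oracle_collapse <- function(records) {
  out <- NULL
  for (g in sort(unique(records$gene_id))) {
    sub <- records[records$gene_id == g, ]
    sub <- sub[order(-sub$mean_induced, sub$probe_id), ]
    out <- rbind(out, sub[1, ])
  }
  out
}

# Independently coded classification rule oracle.
oracle_classify <- function(panel, control, induced, anc) {
  up <- anc$upper_basal; su <- anc$suitability
  if (induced < su$induced_level) return("NOT_INDUCIBLE")
  if (control > up$control_level) return("NOT_INDUCIBLE")
  if (panel <= su$panel_mean) return("SUITABLE")
  if (panel <= up$panel_mean) return("MARGINAL")
  "UNSUITABLE"
}

# Brute-force geNORM M: explicit pairwise loops and a hand-written
# n-1-denominator standard deviation.
oracle_genorm <- function(q) {
  n <- ncol(q); g <- nrow(q)
  sd1 <- function(x) {
    m <- sum(x) / length(x)
    sqrt(sum((x - m)^2) / (length(x) - 1))
  }
  M <- numeric(g)
  for (j in seq_len(g)) {
    acc <- 0
    for (k in seq_len(g)) {
      if (k == j) next
      acc <- acc + sd1(log2(q[j, ] / q[k, ]))
    }
    M[j] <- acc / (g - 1)
  }
  names(M) <- rownames(q)
  M
}

# Brute-force agglomerative clustering (average linkage) on a Euclidean
# distance matrix; returns merge heights in order and the partition after
# each merge.
oracle_agglomerative <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(rownames(x))
  heights <- numeric(0)
  partitions <- list()
  avg_link <- function(a, b) {
    s <- 0
    for (i in a) for (j in b) s <- s + d[i, j]
    s / (length(a) * length(b))
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- avg_link(clusters[[i]], clusters[[j]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

default_synth_anchors <- function() default_anchors(scale_tag = "synthetic")
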