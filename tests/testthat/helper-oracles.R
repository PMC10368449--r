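# Independent oracles and tiny fixture builders used across the suite.

# Brute-force agglomerative clustering: at every step the inter-cluster
# distance is recomputed from scratch over the *original* element
# distances (no Lance-Williams update), with the same lowest-index
# tie-break as the implementation under test.
brute_force_linkage <- function(v, metric = "euclidean",
                                method = "average") {
  d <- as.matrix(stats::dist(v))
  if (metric == "hamming") d <- d^2
  n <- nrow(v)
  clusters <- as.list(seq_len(n))   # formation order: leaves then merges
  alive <- rep(TRUE, n)
  heights <- numeric(0)
  for (k in seq_len(n - 1L)) {
    ids <- which(alive)
    best <- NULL; bd <- Inf
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (b <= a) next
      i <- ids[a]; j <- ids[b]
      cross <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      dd <- switch(method, average = mean(cross),
                   complete = max(cross), single = min(cross))
      if (dd < bd - 1e-12) { bd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    clusters[[length(clusters) + 1L]] <-
      c(clusters[[best[1L]]], clusters[[best[2L]]])
    alive[best] <- FALSE
    alive[length(clusters)] <- TRUE
  }
  heights
}

# Rand / adjusted Rand by explicit enumeration of all unordered pairs.
pairwise_rand <- function(p1, p2) {
  p2 <- p2[names(p1)]
  n <- length(p1)
  same1 <- outer(p1, p1, "==")[upper.tri(diag(n))]
  same2 <- outer(p2, p2, "==")[upper.tri(diag(n))]
  a <- sum(same1 & same2); b <- sum(!same1 & !same2)
  n11 <- a; n00 <- b
  n10 <- sum(same1 & !same2); n01 <- sum(!same1 & same2)
  total <- choose(n, 2)
  rand <- (n11 + n00) / total
  # ARI via pair counts
  exp_idx <- (n11 + n10) * (n11 + n01) / total
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  ari <- if (max_idx == exp_idx) 1 else (n11 - exp_idx) / (max_idx - exp_idx)
  list(rand = rand, ari = ari)
}

# Minimal linear three-residue pathway used for edge-case tests.
tiny_pathway_yaml <- function() {
"name: tiny
regulators: [regX]
lps_genes: [gA, gB, gC, gP]
residues:
  - {name: root, parent: ~, transferases: [], precursors: [], inner_core: true}
  - {name: A, parent: root, transferases: [gA], precursors: [], inner_core: true}
  - {name: B, parent: A, transferases: [gB], precursors: [pB], inner_core: false}
  - {name: C, parent: B, transferases: [gC], precursors: [], inner_core: false}
modifications:
  - {name: A-P, target: A, genes: [gP], phosphate: true, nonstoichiometric: false}
  - {name: B-EtN, target: B, genes: [gE], phosphate: false, nonstoichiometric: true}
"
}

random_strain_table <- function(n_strains, n_rows, seed) {
  set.seed(seed)
  effects <- c("nonsense", "frameshift", "missense", "inframe_indel",
               "is_insertion", "duplication")
  genes <- c("waaC", "waaF", "waaG", "hldE", "galU")
  descs <- paste0("m", sample.int(12L, n_rows, replace = TRUE))
  data.frame(
    strain_id = sample(sprintf("S%02d", seq_len(n_strains)), n_rows,
                       replace = TRUE),
    gene = sample(genes, n_rows, replace = TRUE),
    effect = sample(effects, n_rows, replace = TRUE),
    descriptor = descs,
    position = sample.int(300L, n_rows, replace = TRUE),
    included = TRUE, stringsAsFactors = FALSE)
}

strains_from_df <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  # collapse accidental duplicate (strain, gene, descriptor) rows
  df <- df[!duplicated(df[c("strain_id", "gene", "descriptor")]), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  read_strain_table(path)
}
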