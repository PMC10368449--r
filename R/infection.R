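#' @title Infection matrices, consensus scoring and clustering
#' @name infection
NULL

#' Consensus call for one host-phage spot-assay combination
#'
#' A host is scored sensitive to a phage only when both spotting methods
#' show lysis in at least two of three replicates.  When the two methods
#' disagree, a standard plaque assay decides: sensitive if plaques were
#' observed at both dilutions.  A disagreement without a plaque result is
#' an error (the cell cannot be scored).
#'
#' @param method1,method2 Logical vectors of length 3: lysis per replicate.
#' @param plaque Optional logical: plaques at both dilutions.
#' @param host_id,phage_id Optional ids used in error messages.
#' @return List with \code{sensitive} (logical) and \code{provenance}
#'   (\code{"both_methods"} or \code{"plaque_resolved"}).
#' @export
consensus_call <- function(method1, method2, plaque = NA,
                           host_id = "?", phage_id = "?") {
  if (length(method1) != 3L || length(method2) != 3L)
    stop("exactly three replicates per method are required")
  v1 <- sum(method1) >= 2L
  v2 <- sum(method2) >= 2L
  if (v1 == v2)
    return(list(sensitive = v1, provenance = "both_methods"))
  if (is.na(plaque))
    stop("unresolved cell: methods disagree and no plaque result for (",
         host_id, ", ", phage_id, ")")
  list(sensitive = isTRUE(plaque), provenance = "plaque_resolved")
}

#' Collapse a raw replicated assay table into an infection matrix
#'
#' @param assays Data frame with columns \code{host_id}, \code{phage_id},
#'   \code{m1_r1..m1_r3}, \code{m2_r1..m2_r3}, \code{plaque} (logical or
#'   NA).  Every host x phage combination must appear exactly once.
#' @return An \code{infection_matrix} (see \code{\link{read_matrix}})
#'   with per-cell provenance.
#' @export
consensus_matrix <- function(assays) {
  req <- c("host_id", "phage_id", paste0("m1_r", 1:3), paste0("m2_r", 1:3),
           "plaque")
  missing_cols <- setdiff(req, names(assays))
  if (length(missing_cols) > 0L)
    stop("assay table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  hosts <- unique(assays$host_id)
  phages <- unique(assays$phage_id)
  key <- paste(assays$host_id, assays$phage_id)
  if (anyDuplicated(key) || nrow(assays) != length(hosts) * length(phages))
    stop("assay table must contain each host x phage combination once")
  cells <- matrix(NA_integer_, length(hosts), length(phages),
                  dimnames = list(hosts, phages))
  prov <- matrix(NA_character_, length(hosts), length(phages),
                 dimnames = list(hosts, phages))
  for (i in seq_len(nrow(assays))) {
    r <- assays[i, ]
    cc <- consensus_call(as.logical(unlist(r[paste0("m1_r", 1:3)])),
                         as.logical(unlist(r[paste0("m2_r", 1:3)])),
                         plaque = r$plaque,
                         host_id = r$host_id, phage_id = r$phage_id)
    cells[r$host_id, r$phage_id] <- as.integer(cc$sensitive)
    prov[r$host_id, r$phage_id] <- cc$provenance
  }
  new_infection_matrix(cells, provenance = prov)
}

new_infection_matrix <- function(cells, provenance = NULL) {
  if (any(is.na(cells)) || !all(cells %in% c(0L, 1L)))
    stop("infection matrix cells must all be 0 or 1")
  structure(list(cells = cells,
                 hosts = rownames(cells), phages = colnames(cells),
                 provenance = provenance),
            class = "infection_matrix")
}

#' Read / write a binary infection matrix
#'
#' CSV dialect: first column \code{host_id}, header row of phage ids,
#' cells 0/1, complete (no missing cells).
#'
#' @param path File path.
#' @return An \code{infection_matrix}: list with \code{cells} (integer
#'   matrix, hosts x phages), \code{hosts}, \code{phages}, and optional
#'   per-cell \code{provenance}.
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix parse error: no phage columns")
  hosts <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "integer")
  if (any(is.na(m)) || !all(m %in% c(0L, 1L)))
    stop("matrix parse error: non-binary or missing cell")
  rownames(m) <- hosts
  new_infection_matrix(m)
}

#' @rdname read_matrix
#' @param matrix An \code{infection_matrix}.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "infection_matrix"))
  df <- data.frame(host_id = matrix$hosts, matrix$cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.infection_matrix <- function(x, ...) {
  cat("Infection matrix: ", length(x$hosts), " hosts x ",
      length(x$phages), " phages, ", sum(x$cells), " infections\n",
      sep = "")
  invisible(x)
}

.axis_vectors <- function(matrix, axis = c("hosts", "phages")) {
  axis <- match.arg(axis)
  if (axis == "hosts") matrix$cells else t(matrix$cells)
}

#' Count distinct infectivity profiles
#'
#' Groups the elements of one axis by exact equality of their binary
#' vectors over the other axis.
#'
#' @param matrix An \code{infection_matrix}.
#' @param axis \code{"hosts"} (group rows) or \code{"phages"} (columns).
#' @return List with \code{count} and \code{classes} (named vector of
#'   profile class labels, numbered by first occurrence).
#' @export
distinct_profiles <- function(matrix, axis = c("hosts", "phages")) {
  v <- .axis_vectors(matrix, axis)
  key <- apply(v, 1L, paste, collapse = "")
  cls <- match(key, unique(key))
  list(count = length(unique(key)),
       classes = stats::setNames(paste0("profile", cls), rownames(v)))
}

#' Agglomerative clustering of binary infection profiles
#'
#' Hierarchical clustering of one matrix axis.  The default reproduces
#' the common clustered-heatmap convention: Euclidean distance between
#' binary vectors (\eqn{\sqrt{Hamming}}) with average linkage (UPGMA,
#' cluster distance = mean pairwise distance over original elements).
#' Equal inter-cluster distances are broken deterministically by the
#' lowest (i, j) pair of cluster formation indices.
#'
#' @param matrix An \code{infection_matrix}, or a plain numeric matrix
#'   whose rows are clustered.
#' @param axis \code{"hosts"} or \code{"phages"} (ignored for plain
#'   matrices).
#' @param metric \code{"euclidean"} or \code{"hamming"}.
#' @param method \code{"average"}, \code{"complete"} or \code{"single"}.
#' @return An \code{lps_linkage}: \code{merge} (hclust-style (n-1) x 2),
#'   \code{height}, \code{labels}, \code{metric}, \code{method}.
#' @export
upgma_linkage <- function(matrix, axis = c("hosts", "phages"),
                          metric = c("euclidean", "hamming"),
                          method = c("average", "complete", "single")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  v <- if (inherits(matrix, "infection_matrix"))
    .axis_vectors(matrix, axis) else as.matrix(matrix)
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 elements to cluster")
  labels <- rownames(v)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  d <- as.matrix(stats::dist(v, method = "euclidean"))
  if (metric == "hamming") d <- d^2 / 1  # squared euclidean = Hamming on 0/1

  # active clusters keyed by formation index: leaves 1..n, merges n+1..2n-1
  members <- as.list(seq_len(n))            # original element indices
  sizes <- rep(1L, n)
  active <- seq_len(n)
  # cluster-level distance matrix, updated by Lance-Williams
  D <- d
  rownames(D) <- colnames(D) <- as.character(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    ids <- sort(active)
    sub <- D[as.character(ids), as.character(ids), drop = FALSE]
    best <- c(NA_integer_, NA_integer_); bd <- Inf
    for (a in seq_along(ids)) {
      if (a == length(ids)) break
      for (b in (a + 1L):length(ids)) {
        if (sub[a, b] < bd - 1e-12) {      # strict improvement
          bd <- sub[a, b]; best <- c(ids[a], ids[b])
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    new_id <- n + k
    height[k] <- bd
    merge[k, ] <- c(if (i <= n) -i else i - n,
                    if (j <= n) -j else j - n)
    members[[new_id]] <- c(members[[i]], members[[j]])
    sizes[new_id] <- sizes[i] + sizes[j]
    # distances from the new cluster to every other active cluster
    others <- setdiff(active, c(i, j))
    newd <- vapply(others, function(o) {
      di <- D[as.character(i), as.character(o)]
      dj <- D[as.character(j), as.character(o)]
      switch(method,
             average = (sizes[i] * di + sizes[j] * dj) / (sizes[i] + sizes[j]),
             complete = max(di, dj),
             single = min(di, dj))
    }, 0)
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- as.character(new_id)
    D[as.character(new_id), as.character(others)] <- newd
    D[as.character(others), as.character(new_id)] <- newd
    active <- c(others, new_id)
  }
  structure(list(merge = merge, height = height, labels = labels,
                 metric = metric, method = method),
            class = "lps_linkage")
}

#' Leaf order of a linkage
#'
#' Depth-first traversal placing the earlier-formed subtree (a leaf, or
#' the cluster with the lower merge index) on the left; among two leaves,
#' the lower original index is left.
#'
#' @param linkage An \code{lps_linkage}.
#' @return Character vector of element labels in dendrogram order.
#' @export
leaf_order <- function(linkage) {
  stopifnot(inherits(linkage, "lps_linkage"))
  n <- nrow(linkage$merge) + 1L
  expand <- function(node) {            # node: negative leaf / positive merge
    if (node < 0L) return(-node)
    a <- linkage$merge[node, 1L]; b <- linkage$merge[node, 2L]
    # formation time: leaves at 0, merge k at k
    ta <- if (a < 0L) 0L else a
    tb <- if (b < 0L) 0L else b
    first <- if (ta != tb) {
      if (ta < tb) a else b
    } else {                         # both leaves: lower original index left
      if (-a <= -b) a else b
    }
    second <- if (identical(first, a)) b else a
    c(expand(first), expand(second))
  }
  idx <- expand(nrow(linkage$merge))
  linkage$labels[idx]
}

#' Convert to a base-R hclust object
#' @param x An \code{lps_linkage}.
#' @param ... Unused.
#' @return An object of class \code{hclust} (plottable).
#' @export
as.hclust.lps_linkage <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = match(leaf_order(x), x$labels),
                 labels = x$labels,
                 method = x$method, dist.method = x$metric,
                 call = match.call()),
            class = "hclust")
}

#' Classes forming unbroken leaf spans
#'
#' A class is contiguous when its members occupy consecutive positions in
#' the dendrogram leaf order.  Singleton classes are trivially contiguous
#' and are reported separately from the count over classes with two or
#' more members.
#'
#' @param order Character vector of element ids (e.g.
#'   \code{\link{leaf_order}} output).
#' @param partition Named vector of class labels (names = element ids),
#'   or an \code{lps_partition}.
#' @return List with \code{contiguous} (labels of contiguous classes),
#'   \code{broken}, \code{n_multi_contiguous} and \code{n_multi} (counts
#'   restricted to classes with >= 2 members).
#' @export
contiguous_classes <- function(order, partition) {
  labels <- if (inherits(partition, "lps_partition"))
    partition$labels else partition
  if (!setequal(order, names(labels)))
    stop("leaf order and partition cover different element sets")
  pos <- match(names(labels), order)
  classes <- split(pos, labels)
  is_contig <- vapply(classes, function(p)
    max(p) - min(p) + 1L == length(p), NA)
  multi <- vapply(classes, length, 0L) >= 2L
  list(contiguous = names(classes)[is_contig],
       broken = names(classes)[!is_contig],
       n_multi_contiguous = sum(is_contig & multi),
       n_multi = sum(multi))
}

#' Rand and adjusted Rand concordance between two partitions
#'
#' Standard pair-counting indices over all unordered element pairs.
#'
#' @param p1,p2 Named vectors of class labels over the same element set
#'   (or \code{lps_partition} objects).
#' @return List with \code{rand} and \code{ari}.
#' @export
partition_concordance <- function(p1, p2) {
  l1 <- if (inherits(p1, "lps_partition")) p1$labels else p1
  l2 <- if (inherits(p2, "lps_partition")) p2$labels else p2
  if (!setequal(names(l1), names(l2)))
    stop("partitions cover different element sets")
  l2 <- l2[names(l1)]
  n <- length(l1)
  tab <- table(l1, l2)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  # Rand: agreements = pairs together in both + pairs apart in both
  rand <- (total + 2 * nij - ai - bj) / total
  expected <- ai * bj / total
  max_index <- (ai + bj) / 2
  ari <- if (max_index == expected) 1 else
    (nij - expected) / (max_index - expected)
  list(rand = rand, ari = ari)
}

#' Contiguity sensitivity across metric/linkage conventions
#'
#' Reruns the clustering + contiguity analysis over the full
#' \{euclidean, hamming\} x \{average, complete, single\} grid, since the
#' unbroken-cluster count can depend on the (often unstated) convention a
#' plotting library uses.
#'
#' @param matrix An \code{infection_matrix}.
#' @param partition Named class labels for the clustered axis elements.
#' @param axis Axis to cluster.
#' @return Data frame with columns \code{metric}, \code{method},
#'   \code{n_multi_contiguous}, \code{n_multi}.
#' @export
contiguity_sensitivity <- function(matrix, partition,
                                   axis = c("hosts", "phages")) {
  axis <- match.arg(axis)
  grid <- expand.grid(metric = c("euclidean", "hamming"),
                      method = c("average", "complete", "single"),
                      stringsAsFactors = FALSE)
  labels <- if (inherits(partition, "lps_partition"))
    partition$labels else partition
  keep <- intersect(if (axis == "hosts") matrix$hosts else matrix$phages,
                    names(labels))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    lk <- upgma_linkage(matrix, axis = axis, metric = grid$metric[i],
                        method = grid$method[i])
    ord <- intersect(leaf_order(lk), keep)
    cc <- contiguous_classes(ord, labels[keep])
    data.frame(metric = grid$metric[i], method = grid$method[i],
               n_multi_contiguous = cc$n_multi_contiguous,
               n_multi = cc$n_multi, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
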