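test_that("consensus rule requires both methods, plaque assay breaks ties", {
  # >= 2/3 lysis in both methods
  cc <- consensus_call(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE))
  expect_true(cc$sensitive)
  expect_identical(cc$provenance, "both_methods")
  # disagreement resolved by plaques at both dilutions
  cc2 <- consensus_call(c(TRUE, TRUE, TRUE), c(FALSE, FALSE, TRUE),
                        plaque = TRUE)
  expect_true(cc2$sensitive)
  expect_identical(cc2$provenance, "plaque_resolved")
  cc3 <- consensus_call(c(TRUE, TRUE, TRUE), c(FALSE, FALSE, TRUE),
                        plaque = FALSE)
  expect_false(cc3$sensitive)
  # all-negative
  expect_false(consensus_call(rep(FALSE, 3), rep(FALSE, 3))$sensitive)
  # unresolved disagreement names the offending pair
  expect_error(consensus_call(c(TRUE, TRUE, TRUE), rep(FALSE, 3),
                              host_id = "R2", phage_id = "P9"),
               "unresolved cell.*R2.*P9")
  expect_error(consensus_call(c(TRUE, TRUE), rep(FALSE, 3)),
               "three replicates")
})

test_that("consensus is invariant to replicate order and fills a matrix", {
  set.seed(42)
  for (i in 1:25) {
    m1 <- sample(c(TRUE, FALSE), 3L, replace = TRUE)
    m2 <- sample(c(TRUE, FALSE), 3L, replace = TRUE)
    pl <- sample(c(TRUE, FALSE), 1L)
    a <- consensus_call(m1, m2, pl)
    b <- consensus_call(sample(m1), sample(m2), pl)
    expect_identical(a, b)
  }
  assays <- expand.grid(host_id = c("h1", "h2"), phage_id = c("p1", "p2"),
                        stringsAsFactors = FALSE)
  assays[paste0("m1_r", 1:3)] <- TRUE
  assays[paste0("m2_r", 1:3)] <- TRUE
  assays$plaque <- NA
  # h2/p2: methods disagree, plaque negative
  assays[assays$host_id == "h2" & assays$phage_id == "p2",
         c(paste0("m2_r", 1:3), "plaque")] <- list(FALSE, FALSE, FALSE, FALSE)
  mat <- consensus_matrix(assays)
  expect_identical(sum(mat$cells), 3L)
  expect_identical(mat$provenance["h2", "p2"], "plaque_resolved")
  expect_identical(mat$provenance["h1", "p1"], "both_methods")
})

test_that("matrix I/O round-trips and rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("host_id,p1,p2\nh1,1,0\nh2,0,1", path)
  m <- read_matrix(path)
  expect_identical(sum(diag(m$cells)), 2L)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, path2)
  m2 <- read_matrix(path2)
  expect_identical(m2$cells, m$cells)

  writeLines("host_id,p1,p2\nh1,1,2\nh2,0,1", path)
  expect_error(read_matrix(path), "non-binary")
})

test_that("distinct profiles group identical vectors exactly", {
  cells <- rbind(a = c(1L, 0L), b = c(1L, 0L), c = c(0L, 1L))
  colnames(cells) <- c("p", "q")
  m <- lpsmap:::new_infection_matrix(cells)
  dp <- distinct_profiles(m, "hosts")
  expect_identical(dp$count, 2L)
  expect_identical(unname(dp$classes["a"]), unname(dp$classes["b"]))
  # all identical rows -> 1; mutually distinct -> n
  m1 <- lpsmap:::new_infection_matrix(rbind(a = c(1L, 1L), b = c(1L, 1L)))
  expect_identical(distinct_profiles(m1, "hosts")$count, 1L)
  expect_identical(distinct_profiles(m, "phages")$count, 2L)
})

test_that("UPGMA reproduces the hand-computed three-profile example", {
  v <- rbind(a = c(0, 0), b = c(0, 1), c = c(1, 1))
  lk <- upgma_linkage(v)
  # ties at distance 1 between {a,b} and {b,c}: lowest index pair merges
  expect_identical(lk$merge[1, ], c(-1L, -2L))
  expect_equal(lk$height, c(1, (1 + sqrt(2)) / 2))
  # the height-1 pair stays adjacent in the leaf order
  ord <- leaf_order(lk)
  expect_equal(abs(diff(match(c("a", "b"), ord))), 1)

  expect_error(upgma_linkage(v[1, , drop = FALSE]), "at least 2")
  # two identical rows merge at height zero
  lk0 <- upgma_linkage(rbind(x = c(1, 0), y = c(1, 0)))
  expect_identical(lk0$height, 0)
  expect_identical(leaf_order(lk0), c("x", "y"))
})

test_that("UPGMA merge heights equal the brute-force oracle on random binary matrices", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(3:10, 1L); p <- sample(2:6, 1L)
    v <- matrix(rbinom(n * p, 1L, 0.5), n, p)
    for (method in c("average", "complete", "single")) {
      lk <- upgma_linkage(v, method = method)
      expect_equal(lk$height, brute_force_linkage(v, method = method),
                   tolerance = 1e-10)
    }
  }
})

test_that("UPGMA agrees with stats::hclust and is row-permutation equivariant on tie-free data", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:9, 1L)
    v <- matrix(rnorm(n * 4), n, 4)   # continuous: ties have measure zero
    rownames(v) <- paste0("e", seq_len(n))
    lk <- upgma_linkage(v)
    hc <- stats::hclust(stats::dist(v), method = "average")
    expect_equal(lk$height, hc$height, tolerance = 1e-10)
    # permuting rows permutes labels but preserves merge heights
    perm <- sample(n)
    lk2 <- upgma_linkage(v[perm, , drop = FALSE])
    expect_equal(sort(lk2$height), sort(lk$height), tolerance = 1e-10)
  }
})

test_that("leaf order handles the degenerate cases", {
  lk <- upgma_linkage(rbind(a = c(0, 0), b = c(1, 1)))
  expect_identical(leaf_order(lk), c("a", "b"))
  hc <- as.hclust(lk)
  expect_s3_class(hc, "hclust")
  expect_identical(hc$labels[hc$order], leaf_order(lk))
})

test_that("contiguity detects unbroken leaf spans", {
  p <- c(a = "X", b = "X", c = "Y", d = "Y")
  both <- contiguous_classes(c("a", "b", "c", "d"), p)
  expect_setequal(both$contiguous, c("X", "Y"))
  expect_identical(both$n_multi_contiguous, 2L)
  neither <- contiguous_classes(c("a", "c", "b", "d"), p)
  expect_length(neither$contiguous, 0L)
  expect_identical(neither$n_multi, 2L)
  # singletons are contiguous but excluded from the multi-member count
  p2 <- c(a = "X", b = "X", c = "Z")
  cc <- contiguous_classes(c("a", "b", "c"), p2)
  expect_true("Z" %in% cc$contiguous)
  expect_identical(cc$n_multi, 1L)
  # block partitions are always fully contiguous
  set.seed(3)
  for (i in 1:10) {
    n <- sample(4:12, 1L)
    ids <- paste0("e", seq_len(n))
    k <- sample(2:3, 1L)
    labs <- sort(sample(seq_len(k), n, replace = TRUE))
    cc2 <- contiguous_classes(ids, stats::setNames(as.character(labs), ids))
    expect_length(cc2$broken, 0L)
  }
  expect_error(contiguous_classes(c("a", "b"), p), "different element sets")
})

test_that("Rand and adjusted Rand match enumeration and mclust", {
  p1 <- c(a = "1", b = "1", c = "2", d = "2")
  p2 <- c(a = "1", b = "2", c = "1", d = "2")
  pc <- partition_concordance(p1, p2)
  expect_equal(pc$rand, 1 / 3)
  expect_equal(pc$ari, -0.5)
  expect_equal(partition_concordance(p1, p1)$ari, 1)

  skip_if_not_installed("mclust")
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:25, 1L)
    q1 <- stats::setNames(sample(letters[1:4], n, TRUE), paste0("e", 1:n))
    q2 <- stats::setNames(sample(letters[1:3], n, TRUE), names(q1))
    mine <- partition_concordance(q1, q2)
    expect_equal(mine$ari, mclust::adjustedRandIndex(q1, q2[names(q1)]),
                 tolerance = 1e-12)
    oracle <- pairwise_rand(q1, q2)
    expect_equal(mine$rand, oracle$rand, tolerance = 1e-12)
    expect_equal(mine$ari, oracle$ari, tolerance = 1e-12)
  }
})

test_that("the sensitivity grid covers all six clustering conventions", {
  m <- read_matrix(lps_infection_matrix_file())
  part <- predict_partition(load_pathway(lps_pathway_file()),
                            read_strain_table(lps_strain_table_file()))
  sens <- contiguity_sensitivity(m, part$labels, axis = "hosts")
  expect_identical(nrow(sens), 6L)
  expect_true(all(sens$n_multi == 6L))
})
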