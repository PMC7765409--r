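test_that("tanimoto distance matches hand-computed cases", {
  expect_equal(tanimoto_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(tanimoto_distance(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  # bits {1,2,3} vs {2,3,4}: 1 - 2/4
  a <- c(1, 1, 1, 0); b <- c(0, 1, 1, 1)
  expect_equal(tanimoto_distance(a, b), 0.5)
  expect_equal(tanimoto_distance(numeric(8), numeric(8)), 0)
  expect_error(tanimoto_distance(c(1, 0), c(1, 0, 1)), "length")
  m <- tanimoto_matrix(rbind(a = a, b = b))
  expect_equal(m["a", "b"], 0.5)
  expect_equal(diag(m), c(a = 0, b = 0))
})

test_that("ward_cluster handles base cases and bad input", {
  d <- matrix(c(0, 3, 3, 0), 2, 2)
  lk <- ward_cluster(d)
  expect_equal(lk$height, 3)          # two points merge at their distance
  expect_identical(lk$merge, matrix(c(-1L, -2L), 1))

  # duplicated point: first merge at height 0
  d3 <- as.matrix(dist(c(0, 0, 5)))
  lk3 <- ward_cluster(d3)
  expect_equal(lk3$height[1], 0)

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(ward_cluster(bad), "symmetric")
})

test_that("linkage equals the exhaustive Ward objective oracle (n <= 8)", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n)
    d <- as.matrix(dist(x))
    lk <- ward_cluster(d)
    oracle <- brute_ward(d)
    expect_equal(lk$height, oracle$heights, tolerance = 1e-8)
    expect_identical(linkage_members(lk), oracle$members)
    expect_true(all(diff(lk$height) >= -1e-8))
    # independent cross-check against the standard implementation
    hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
    expect_equal(sort(lk$height), sort(hc$height), tolerance = 1e-8)
  }
})

test_that("permuting compounds permutes labels but not the merge structure", {
  set.seed(33)
  x <- matrix(rnorm(7 * 4), 7)
  rownames(x) <- paste0("C", 1:7)
  d <- as.matrix(dist(x))
  lk1 <- ward_cluster(d)
  perm <- sample(7)
  lk2 <- ward_cluster(d[perm, perm])
  expect_equal(sort(lk1$height), sort(lk2$height), tolerance = 1e-10)
  mem1 <- lapply(linkage_members(lk1), function(i) sort(lk1$labels[i]))
  mem2 <- lapply(linkage_members(lk2), function(i) sort(lk2$labels[i]))
  expect_setequal(sapply(mem1, paste, collapse = "+"),
                  sapply(mem2, paste, collapse = "+"))
})

test_that("cut_clusters produces k stable clusters and recovers families", {
  cs <- generate_compound_set(21, seed = 8, n_families = 3)
  lk <- ward_cluster(tanimoto_matrix(cs$fingerprints))
  expect_identical(unname(cut_clusters(lk, k = 21)), 1:21)
  expect_true(all(cut_clusters(lk, k = 1) == 1L))
  expect_error(cut_clusters(lk, k = 22), "k must be")
  cl <- cut_clusters(lk, k = 3)
  # same partition as the planted families (up to label names)
  expect_equal(length(unique(paste(cl, cs$families))), 3L)
  # newick export parses back to the same leaf set
  tree <- ape::read.tree(text = linkage_newick(lk))
  expect_setequal(tree$tip.label, rownames(cs$fingerprints))
})

test_that("activity matrices aggregate, mask and rank as specified", {
  rec <- data.frame(compound = c("c1", "c1", "c1", "c2"),
                    target = c("T1", "T1", "T2", "T2"),
                    value = c(6.5, 7.5, 6.9, 7.2))
  am <- build_activity_matrix(rec, cutoff = 7.0)
  expect_equal(am$matrix["c1", "T1"], 7.5)   # max across repeats
  expect_equal(am$matrix["c1", "T2"], 6.9)   # present in full matrix
  mv <- masked_view(am)
  expect_true(is.na(mv["c1", "T2"]))         # hidden below cutoff
  expect_equal(mv["c1", "T1"], 7.5)
  expect_true(is.na(am$matrix["c2", "T1"]))  # unmeasured stays missing

  # median within a source stratum, then max across strata
  rec2 <- data.frame(compound = "c", target = "T",
                     value = c(6.0, 6.2, 6.4, 8.0),
                     source = c("intA", "intA", "intA", "chembl"))
  am2 <- build_activity_matrix(rec2)
  expect_equal(am2$matrix["c", "T"], 8.0)
  rec3 <- data.frame(compound = "c", target = "T",
                     value = c(6.0, 6.2, 9), source = "intA")
  expect_equal(build_activity_matrix(rec3)$matrix["c", "T"], 6.2)

  expect_error(build_activity_matrix(
    data.frame(compound = "c", target = "T", value = "seven")),
    "non-numeric")

  cls <- data.frame(target = c("T1", "T2"), class = c("CDK", "EGFR"))
  rk <- rank_target_classes(am, cls)
  expect_identical(rk$class[1], "CDK")       # 1 active pair beats 0
  empty <- build_activity_matrix(rec[0, ], cutoff = 7)
  expect_identical(nrow(rank_target_classes(empty, cls)), 0L)
  low <- build_activity_matrix(data.frame(compound = "c", target = "T1",
                                          value = 5), cutoff = 7)
  expect_true(all(rank_target_classes(low, cls)$n_active_pairs == 0L))
})

test_that("fingerprint CSVs round-trip into clustering", {
  cs <- generate_compound_set(6, seed = 3, n_families = 2, bits = 64)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = rownames(cs$fingerprints),
                       bits = apply(cs$fingerprints, 1, paste,
                                    collapse = "")),
            path, row.names = FALSE)
  fp <- read_fingerprints(path)
  expect_equal(unname(fp), unname(cs$fingerprints),
               ignore_attr = "provenance")
  expect_identical(attr(fp, "provenance"), "precomputed")
  expect_identical(tanimoto_matrix(fp), tanimoto_matrix(cs$fingerprints))
})
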