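test_that("correlation distances match the brute-force oracle", {
  set.seed(81)
  mat <- matrix(rnorm(15, 40, 30), 5, 3,
                dimnames = list(paste0("i", 1:5), c("KA", "KB", "KC")))
  mat[, "KB"] <- mat[, "KA"]          # identical profiles
  mat[, "KC"] <- -2 * mat[, "KA"] + 7 # perfectly anti-correlated
  d <- correlation_distance(toy_dataset(mat), min_overlap = 3)
  expect_equal(d["KA", "KB"], 0, tolerance = 1e-12)
  expect_equal(d["KA", "KC"], 2, tolerance = 1e-12)
  expect_true(all(abs(d - t(d)) == 0))
  expect_true(all(diag(d) == 0))

  set.seed(82)
  m2 <- matrix(rnorm(15, 40, 30), 5, 3,
               dimnames = list(paste0("i", 1:5), c("KA", "KB", "KC")))
  d2 <- correlation_distance(toy_dataset(m2), min_overlap = 3)
  for (a in colnames(m2)) for (b in colnames(m2))
    expect_equal(d2[a, b],
                 if (a == b) 0 else 1 - pearson_oracle(m2[, a], m2[, b]),
                 tolerance = 1e-12)
  expect_true(all(d2 >= 0 & d2 <= 2))
})

test_that("insufficient overlap or zero variance names the failing pairs", {
  mat <- matrix(rnorm(20, 40, 10), 5, 4,
                dimnames = list(paste0("i", 1:5), paste0("K", 1:4)))
  mat[1:3, 2] <- NA
  expect_error(correlation_distance(toy_dataset(mat), min_overlap = 3),
               "K2")
  flat <- mat; flat[, 2] <- 5
  expect_error(correlation_distance(toy_dataset(flat), min_overlap = 3),
               "variance")
})

test_that("including the query leaves the other pairwise distances alone", {
  set.seed(83)
  mat <- matrix(rnorm(40, 40, 30), 10, 4,
                dimnames = list(sprintf("i%02d", 1:10), paste0("K", 1:4)))
  ds <- toy_dataset(mat)
  fp <- toy_fingerprint(setNames(rnorm(10, 40, 30), rownames(mat)))
  d0 <- correlation_distance(ds, min_overlap = 3)
  d1 <- correlation_distance(ds, include_query = fp, min_overlap = 3)
  expect_identical(d1[colnames(d0), colnames(d0)], d0)
  expect_true("toy" %in% colnames(d1))
})

test_that("Ward.D2 linkage matches a step-by-step agglomeration oracle", {
  # duplicated profiles merge first at height zero; n leaves -> n-1 nodes
  set.seed(84)
  mat <- matrix(rnorm(25, 40, 30), 5, 5,
                dimnames = list(paste0("i", 1:5), paste0("K", 1:5)))
  mat[, 2] <- mat[, 1]
  d <- correlation_distance(toy_dataset(mat), min_overlap = 3)
  tree <- ward_linkage(d)
  expect_equal(length(tree$hclust$height), 4)
  first <- sort(clade_keys_for_test(tree$hclust)[[1]])
  expect_identical(first, c("K1", "K2"))
  expect_equal(tree$hclust$height[1], 0, tolerance = 1e-9)
  expect_true(all(diff(tree$hclust$height) >= -1e-12))

  # property: random instances up to 8 leaves agree with the oracle
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(2 * n), n)
    rownames(pts) <- paste0("L", seq_len(n))
    dm <- as.matrix(dist(pts))
    tr <- ward_linkage(dm)
    orc <- ward_oracle(dm)
    expect_equal(tr$hclust$height, orc$heights, tolerance = 1e-9)
    got <- lapply(clade_keys_for_test(tr$hclust), sort)
    expect_identical(got, orc$clades)
  }
})

test_that("malformed distance matrices are rejected", {
  m <- matrix(c(0, 1, 2, 0), 2)
  expect_error(ward_linkage(m), "symmetric")
  m2 <- matrix(c(0, -1, -1, 0), 2)
  expect_error(ward_linkage(m2), "non-negative")
})

test_that("bootstrap support is high for duplicates, low for noise clades", {
  set.seed(85)
  mat <- matrix(rnorm(30 * 8, 40, 30), 30, 8,
                dimnames = list(sprintf("i%02d", 1:30), paste0("K", 1:8)))
  mat[, "K2"] <- mat[, "K1"] + rnorm(30, 0, 0.01)
  ds <- toy_dataset(mat)
  tree <- bootstrap_support(ds, n_boot = 400, seed = 9, min_overlap = 3)
  sup <- tree$support
  dup <- sup[sup$leaves == "K1,K2", ]
  expect_equal(nrow(dup), 1)
  expect_gte(dup$bp, 0.99)
  # the root clade is in every bootstrap tree by construction ...
  expect_equal(sup$bp[which.max(sup$height)], 1)
  # ... but the deepest non-root split of independent random profiles is
  # unstable under resampling
  nonroot <- sup[-which.max(sup$height), ]
  deep_bp <- nonroot$bp[which.max(nonroot$height)]
  expect_lt(deep_bp, 0.9)
  # determinism
  tree2 <- bootstrap_support(ds, n_boot = 400, seed = 9, min_overlap = 3)
  expect_identical(tree$support, tree2$support)
})

test_that("multiscale AU values are defined and consistent with BP extremes", {
  set.seed(86)
  mat <- matrix(rnorm(25 * 6, 40, 30), 25, 6,
                dimnames = list(sprintf("i%02d", 1:25), paste0("K", 1:6)))
  mat[, "K2"] <- mat[, "K1"] + rnorm(25, 0, 0.01)
  tree <- bootstrap_support(toy_dataset(mat), n_boot = 200, seed = 10,
                            multiscale = TRUE, min_overlap = 3)
  sup <- tree$support
  expect_true(all(is.finite(sup$au)))
  expect_true(all(sup$au >= 0 & sup$au <= 1))
  expect_gte(sup$au[sup$leaves == "K1,K2"], 0.95)
})

test_that("Newick export round-trips through an independent parser", {
  set.seed(87)
  mat <- matrix(rnorm(20 * 6, 40, 30), 20, 6,
                dimnames = list(sprintf("i%02d", 1:20),
                                c("KA", "KB", "KC", "KD", "KE", "KF")))
  ds <- toy_dataset(mat)
  tree <- bootstrap_support(ds, n_boot = 150, seed = 11, min_overlap = 3)
  txt <- to_newick(tree)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, colnames(mat))
  # topology preserved: clade sets of the parsed tree equal the hclust's
  parsed_clades <- lapply(ape::prop.part(phy), function(i)
    sort(phy$tip.label[i]))
  ours <- lapply(clade_keys_for_test(tree$hclust), sort)
  for (cl in ours[-length(ours)])  # root clade is implicit in ape
    expect_true(any(vapply(parsed_clades, identical, logical(1), cl)))
  # node labels are AU/BP style percentages
  expect_match(txt, "\\)[0-9]+:")

  # two-leaf tree has the (A:h/2,B:h/2) shape
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  t2 <- ward_linkage(d2)
  expect_match(to_newick(t2), "^\\(A:0.4,B:0.4\\);$")

  # labels with commas are quoted and survive parsing
  d3 <- matrix(c(0, 0.5, 0.5, 0), 2,
               dimnames = list(c("AUR,A", "B"), c("AUR,A", "B")))
  txt3 <- to_newick(ward_linkage(d3))
  expect_match(txt3, "'AUR,A'", fixed = TRUE)
  phy3 <- ape::read.tree(text = txt3)
  expect_equal(length(phy3$tip.label), 2)
  expect_true(any(grepl("AUR,A", phy3$tip.label, fixed = TRUE)))
})
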