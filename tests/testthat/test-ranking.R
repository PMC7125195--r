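make_ds <- function(mat, name = "toy") toy_dataset(mat, name)

test_that("self- and affine-transformed fingerprints correlate at 1", {
  set.seed(3)
  mat <- matrix(rnorm(60, 50, 20), 12, 5,
                dimnames = list(sprintf("i%02d", 1:12), paste0("K", 1:5)))
  ds <- make_ds(mat)
  fp <- toy_fingerprint(setNames(mat[, "K3"], rownames(mat)))
  co <- correlate_fingerprint(fp, ds, min_overlap = 5)
  expect_equal(co$rho[co$profile_label == "K3"], 1, tolerance = 1e-12)

  fp2 <- toy_fingerprint(setNames(0.5 * mat[, "K3"] + 7, rownames(mat)))
  co2 <- correlate_fingerprint(fp2, ds, min_overlap = 5)
  expect_equal(co2$rho[co2$profile_label == "K3"], 1, tolerance = 1e-12)
  # all other coefficients are unchanged by the affine map too
  expect_equal(co2$rho, co$rho, tolerance = 1e-12)
})

test_that("correlations match the textbook Pearson oracle", {
  fp <- toy_fingerprint(c(i1 = 10, i2 = 20, i3 = 30, i4 = 40, i5 = 50))
  mat <- matrix(c(12, 18, 35, 38, 52), 5, 1,
                dimnames = list(paste0("i", 1:5), "KA"))
  co <- correlate_fingerprint(fp, make_ds(mat), min_overlap = 3)
  expect_equal(co$rho, pearson_oracle(c(10, 20, 30, 40, 50),
                                      c(12, 18, 35, 38, 52)),
               tolerance = 1e-12)

  # property: random instances with <= 20 inhibitors, with missingness
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(4:20, 1)
    m <- matrix(rnorm(3 * n, 40, 30), n, 3,
                dimnames = list(sprintf("i%02d", 1:n), c("KA", "KB", "KC")))
    m[sample(length(m), round(0.1 * length(m)))] <- NA
    v <- setNames(rnorm(n, 40, 30), rownames(m))
    co <- correlate_fingerprint(toy_fingerprint(v), make_ds(m),
                                min_overlap = 3)
    for (j in seq_len(nrow(co))) {
      lab <- co$profile_label[j]
      expect_equal(co$rho[j], pearson_oracle(v, m[, lab]), tolerance = 1e-12)
    }
  }
})

test_that("overlap and variance filters drop kinases with logged reasons", {
  mat <- matrix(rnorm(20, 50, 10), 10, 2,
                dimnames = list(sprintf("i%02d", 1:10), c("KA", "KB")))
  mat[4:10, 2] <- NA  # KB overlap = 3
  fp <- toy_fingerprint(setNames(rnorm(10, 50, 10), rownames(mat)))
  co <- correlate_fingerprint(fp, make_ds(mat), min_overlap = 5)
  expect_false("KB" %in% co$profile_label)
  expect_match(attr(co, "dropped")$reason[
                 attr(co, "dropped")$profile_label == "KB"], "overlap")

  flat <- mat; flat[, 2] <- 42  # zero variance
  co2 <- correlate_fingerprint(fp, make_ds(flat), min_overlap = 5)
  expect_match(attr(co2, "dropped")$reason[
                 attr(co2, "dropped")$profile_label == "KB"], "variance")

  # removing a kinase never changes the others' coefficients
  co3 <- correlate_fingerprint(fp, make_ds(mat[, 1, drop = FALSE]),
                               min_overlap = 5)
  expect_equal(co3$rho, co$rho[co$profile_label == "KA"], tolerance = 1e-15)

  # disjoint inhibitor ids name the mapping problem
  bad <- mat; rownames(bad) <- sprintf("x%02d", 1:10)
  expect_error(correlate_fingerprint(fp, make_ds(bad)), "identifiers")
})

test_that("ranking is invariant to positive affine rescaling and id order", {
  set.seed(5)
  mat <- matrix(rnorm(200, 50, 25), 20, 10,
                dimnames = list(sprintf("i%02d", 1:20), paste0("K", 1:10)))
  v <- setNames(rnorm(20, 40, 30), rownames(mat))
  h1 <- rank_hits(correlate_fingerprint(toy_fingerprint(v), make_ds(mat)))
  h2 <- rank_hits(correlate_fingerprint(toy_fingerprint(2.5 * v + 11),
                                        make_ds(mat)))
  expect_identical(h1$profile_label[order(h1$rank_in_dataset)],
                   h2$profile_label[order(h2$rank_in_dataset)])
  # permuting inhibitor order identically leaves every rho unchanged
  perm <- sample(20)
  h3 <- rank_hits(correlate_fingerprint(toy_fingerprint(v[perm]),
                                        make_ds(mat[perm, ])))
  expect_equal(setNames(h3$rho, h3$profile_label)[h1$profile_label],
               setNames(h1$rho, h1$profile_label), tolerance = 1e-12)
})

test_that("hit tables rank per dataset and overall with documented tie-breaks", {
  co1 <- data.frame(dataset = "d1", profile_label = c("A", "B", "C"),
                    gene_symbol = c("A", "B", "C"), family = NA,
                    rho = c(0.9, 0.5, 0.7), n_overlap = c(30L, 30L, 30L),
                    z = NA_real_, stringsAsFactors = FALSE)
  h <- rank_hits(co1)
  expect_identical(h$profile_label[order(h$rank_in_dataset)],
                   c("A", "C", "B"))
  expect_true(all(sort(h$rank_in_dataset) == 1:3))

  # identical rho and z: larger overlap wins
  co2 <- data.frame(dataset = "d1", profile_label = c("A", "B"),
                    gene_symbol = c("A", "B"), family = NA,
                    rho = c(0.8, 0.8), n_overlap = c(40L, 50L),
                    z = c(2, 2), stringsAsFactors = FALSE)
  h2 <- rank_hits(co2)
  expect_identical(h2$profile_label[h2$rank_in_dataset == 1], "B")

  # shared top kinase across three datasets tops the overall ranking
  mk <- function(ds, rhos) data.frame(dataset = ds,
                                      profile_label = c("T", "U", "V"),
                                      gene_symbol = c("T", "U", "V"),
                                      family = NA, rho = rhos,
                                      n_overlap = 20L, z = NA_real_,
                                      stringsAsFactors = FALSE)
  h3 <- rank_hits(list(mk("d1", c(0.9, 0.2, 0.1)),
                       mk("d2", c(0.8, 0.3, 0.2)),
                       mk("d3", c(0.95, 0.4, 0.3))))
  # brute-force pooled ordering: T@d3 (.95) first
  expect_identical(h3$dataset[h3$rank_overall == 1], "d3")
  expect_identical(h3$profile_label[h3$rank_overall == 1], "T")
  expect_true(all(h3$profile_label[h3$rank_overall <= 3] == "T"))
})

test_that("screen confidence follows the z thresholds", {
  base <- data.frame(dataset = "d", profile_label = c("A", "B"),
                     gene_symbol = c("A", "B"), family = NA,
                     rho = c(0.8, 0.3), n_overlap = 20L,
                     z = c(NA, NA), stringsAsFactors = FALSE)
  expect_error(flag_screen_confidence(rank_hits(base)), "null")
  flag_of <- function(zmax) {
    b <- base; b$z <- c(zmax, 1)
    attr(flag_screen_confidence(rank_hits(b)), "confidence")
  }
  expect_identical(flag_of(5.9), "caution")
  expect_identical(flag_of(7.3), "intermediate")
  expect_identical(flag_of(10.0), "robust")  # boundary: "10 or above"
  expect_identical(flag_of(6.0), "intermediate")
})

test_that("KinMap annotation sizes are linear in rho with negative clamp", {
  co <- data.frame(dataset = "d", profile_label = c("A", "B", "C", "D"),
                   gene_symbol = c("A", "B", "C", "D"), family = NA,
                   rho = c(1, 0, -0.4, 0.5), n_overlap = 20L,
                   z = NA_real_, stringsAsFactors = FALSE)
  lines <- export_kinmap_annotation(rank_hits(co), max_size = 100)
  expect_identical(lines[1], "xName\tsize\tfill")
  parsed <- read.delim(text = paste(lines, collapse = "\n"))
  size <- setNames(parsed$size, parsed$xName)
  expect_equal(unname(size["A"]), 100)
  expect_equal(unname(size["B"]), 0)
  expect_equal(unname(size["C"]), 0)
  expect_equal(unname(size["D"]), 50)
  # top hit carries the highlight fill
  expect_identical(parsed$fill[parsed$xName == "A"], "#e31a1c")
  expect_true(all(parsed$fill[parsed$xName != "A"] == "#1f78b4"))
})

test_that("hit tables write with the declared columns", {
  co <- data.frame(dataset = "d", profile_label = c("A", "B"),
                   gene_symbol = c("A", "B"), family = NA,
                   rho = c(0.8, 0.3), n_overlap = 20L, z = c(4, 1),
                   stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(rank_hits(co), p)
  tab <- read.delim(p)
  expect_identical(names(tab),
                   c("screen_id", "dataset", "gene_symbol", "profile_label",
                     "rho", "n_overlap", "z", "rank_in_dataset",
                     "rank_overall"))
  expect_identical(tab$gene_symbol[1], "A")
})
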