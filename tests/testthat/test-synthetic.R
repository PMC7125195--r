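test_that("profile simulation is deterministic and honours its parameters", {
  a <- simulate_profile_dataset(n_kinases = 20, n_inhibitors = 40, seed = 1)
  b <- simulate_profile_dataset(n_kinases = 20, n_inhibitors = 40, seed = 1)
  expect_identical(a$values, b$values)
  c <- simulate_profile_dataset(n_kinases = 20, n_inhibitors = 40, seed = 2)
  expect_false(identical(a$values, c$values))
  expect_equal(sum(a$kinases$is_mutant), 0)  # mutant_fraction 0 default

  mut <- simulate_profile_dataset(n_kinases = 20, n_inhibitors = 40,
                                  mutant_fraction = 0.2, seed = 3)
  expect_equal(sum(mut$kinases$is_mutant), 4)
  # mutant entries duplicate a wild-type gene symbol
  expect_true(all(mut$kinases$gene_symbol[mut$kinases$is_mutant] %in%
                    mut$kinases$gene_symbol[!mut$kinases$is_mutant]))
})

test_that("a noiseless promiscuity-1 generator hits one kinase per inhibitor", {
  ds <- simulate_profile_dataset(n_kinases = 15, n_inhibitors = 30,
                                 noise_sd = 0, promiscuity_mean = 1,
                                 potency_sd = 0, seed = 5)
  # geometric with mean 1 is degenerate at 1 target
  big <- ds$values > 50
  expect_true(all(rowSums(big) == 1))
  expect_true(all(ds$values[!big] == 0))
})

test_that("family blocks induce higher within- than between-family correlation", {
  ds <- simulate_profile_dataset(n_kinases = 40, n_inhibitors = 200,
                                 n_families = 4, within_family_bias = 0.95,
                                 promiscuity_mean = 4, seed = 7)
  rho <- cor(ds$values)
  fam <- ds$kinases$family
  same <- outer(fam, fam, "==") & upper.tri(rho)
  diff_fam <- !outer(fam, fam, "==") & upper.tri(rho)
  expect_gt(mean(rho[same]), mean(rho[diff_fam]))
})

test_that("Kd-kind synthetic panels exercise the Hill conversion path", {
  pct <- simulate_profile_dataset(n_kinases = 10, n_inhibitors = 20,
                                  seed = 9)
  kd <- simulate_profile_dataset(n_kinases = 10, n_inhibitors = 20,
                                 assay_kind = "dissociation_constant_nM",
                                 seed = 9)
  expect_identical(kd$assay_kind, "dissociation_constant_nM")
  expect_true(all(kd$values > 0))
  back <- to_correlation_scale(kd)
  # inversion round-trips through the Hill equation (up to the clamp)
  clamped <- pmin(pmax(pct$values, 1e-3), 100 - 1e-3)
  expect_equal(back$values, clamped, tolerance = 1e-9)
})

test_that("screen simulation follows the residual-activity signal model", {
  ds <- simulate_profile_dataset(n_kinases = 12, n_inhibitors = 24,
                                 noise_sd = 0, seed = 11)
  scr <- simulate_screen_plates(ds, c(K03 = 1), noise_sd = 0, seed = 12)
  w <- scr$wells
  expect_true(all(w$absorbance[w$role == "vehicle_control"] == 1))
  inh <- w[w$role == "inhibitor", ]
  mu <- tapply(inh$absorbance, inh$inhibitor_id, mean)
  expected <- 1 * (100 - ds$values[names(mu), "K03"]) / 100
  expect_equal(as.numeric(mu), as.numeric(expected), tolerance = 1e-12)
  # duplicates adjacent: replicate wells of an inhibitor are consecutive
  first_two <- w$inhibitor_id[1:2]
  expect_identical(first_two[1], first_two[2])

  # determinism
  scr2 <- simulate_screen_plates(ds, c(K03 = 1), noise_sd = 0, seed = 12)
  expect_identical(scr$wells, scr2$wells)

  expect_error(simulate_screen_plates(ds, c(K03 = 0.5, K04 = 0.6),
                                      seed = 1), "sum to 1")
  expect_error(simulate_screen_plates(ds, c(NOPE = 1), seed = 1), "NOPE")
})

test_that("near-noiseless screens recover the contributing kinase at rho = 1", {
  # exactly zero noise leaves the DMSO controls with zero spread, which the
  # normalization rejects by design; a negligible noise keeps the affine
  # argument intact. Profiles are kept inside [0, 100] so the non-negative
  # absorbance clamp never engages and the signal stays exactly affine.
  ds <- simulate_profile_dataset(n_kinases = 15, n_inhibitors = 40,
                                 noise_sd = 0, potency_sd = 0, seed = 21)
  scr <- simulate_screen_plates(ds, c(K06 = 1), noise_sd = 1e-9, seed = 22)
  fp <- assemble_fingerprint(scr)
  co <- correlate_fingerprint(fp, ds)
  expect_equal(co$rho[co$profile_label == "K06"], 1, tolerance = 1e-9)
  expect_equal(which.max(setNames(co$rho, co$profile_label)), c(K06 = 6),
               ignore_attr = FALSE)

  # 50/50 mixture correlates perfectly with the mean of the two profiles
  scr2 <- simulate_screen_plates(ds, c(K02 = 0.5, K09 = 0.5), noise_sd = 1e-9,
                                 seed = 23)
  fp2 <- assemble_fingerprint(scr2)
  v <- setNames(fp2$percent_inhibition, fp2$inhibitor_id)
  mean_prof <- rowMeans(ds$values[names(v), c("K02", "K09")])
  expect_equal(cor(v, mean_prof), 1, tolerance = 1e-9)
})

test_that("large screens span several plates, each with its own controls", {
  ds <- simulate_profile_dataset(n_kinases = 10, n_inhibitors = 400,
                                 seed = 31)
  scr <- simulate_screen_plates(ds, c(K01 = 1), seed = 32)
  w <- scr$wells
  expect_gt(length(unique(w$plate_id)), 1)
  per_plate_dmso <- tapply(w$role == "vehicle_control", w$plate_id, sum)
  expect_true(all(per_plate_dmso == 16))
  counts <- table(w$plate_id)
  expect_true(all(counts <= 384))
  # the pipeline runs across plates
  fp <- assemble_fingerprint(scr)
  expect_equal(nrow(fp), 400)
})

test_that("recovery experiments summarise top-k rates over the grid", {
  ds <- simulate_profile_dataset(n_kinases = 12, n_inhibitors = 30, seed = 41)
  res <- recovery_experiment(ds, list(c(K04 = 1)),
                             noise_levels = c(1e-9, 2), n_replicates = 4,
                             seed = 42, min_overlap = 5)
  expect_equal(nrow(res), 2)
  expect_true(all(res$top1 >= 0 & res$top1 <= 1))
  expect_true(all(res$top5 >= res$top1))
  expect_equal(res$top1[res$noise_sd == 1e-9], 1)
})
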