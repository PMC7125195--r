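# Independent oracles and tiny fixture builders. These deliberately avoid
# the package's own code paths (and stats::cor / stats::hclust) so that
# equivalence tests compare two genuinely different routes.

# Textbook Pearson: covariance over product of standard deviations,
# accumulated by explicit loops, pairwise-complete.
pearson_oracle <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  as.numeric(sxy / sqrt(sxx * syy))
}

# Step-by-step Ward.D2 agglomeration: Lance-Williams recurrence on squared
# dissimilarities, heights reported on the distance scale. Returns merge
# heights (in merge order) and the list of clade leaf sets.
ward_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d2 <- d^2
  active <- seq_len(n)
  members <- lapply(seq_len(n), function(i) labels[i])
  sizes <- rep(1, n)
  heights <- numeric(0)
  clades <- list()
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      v <- d2[active[a], active[b]]
      if (v < bestv) { bestv <- v; best <- c(active[a], active[b]) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestv))
    new_members <- c(members[[i]], members[[j]])
    clades[[length(clades) + 1L]] <- sort(new_members)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * bestv) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    members[[i]] <- new_members
    active <- setdiff(active, j)
  }
  list(heights = heights, clades = clades)
}

# Exhaustive subset enumeration for downsampling recovery on toys:
# recovery of `target` (column index) in the top k, over all n-subsets of
# the inhibitors, using the same tie rule (rho ties count as recovered).
exact_recovery_oracle <- function(x, mat, target, n, k, min_overlap = 3) {
  N <- length(x)
  subsets <- utils::combn(N, n)
  hit <- logical(ncol(subsets))
  for (s in seq_len(ncol(subsets))) {
    idx <- subsets[, s]
    rhos <- rep(NA_real_, ncol(mat))
    for (j in seq_len(ncol(mat))) {
      ok <- is.finite(mat[idx, j]) & is.finite(x[idx])
      if (sum(ok) >= min_overlap)
        rhos[j] <- pearson_oracle(x[idx][ok], mat[idx, j][ok])
    }
    if (is.finite(rhos[target]))
      hit[s] <- (1 + sum(rhos > rhos[target], na.rm = TRUE)) <= k
  }
  mean(hit)
}

# Minimal hand-built plate: one plate, DMSO wells, optional EDTA wells,
# inhibitors as a named list of replicate absorbance vectors.
toy_plate <- function(inhibitors, dmso, edta = numeric(0),
                      plate_id = "P1", screen_id = "toy") {
  rows <- list()
  w <- 0L; wid <- function() sprintf("w%02d", w <<- w + 1L)
  for (id in names(inhibitors))
    for (a in inhibitors[[id]])
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = plate_id, well_id = wid(), role = "inhibitor",
        inhibitor_id = id, absorbance = a, stringsAsFactors = FALSE)
  for (a in dmso)
    rows[[length(rows) + 1L]] <- data.frame(
      plate_id = plate_id, well_id = wid(), role = "vehicle_control",
      inhibitor_id = NA_character_, absorbance = a, stringsAsFactors = FALSE)
  for (a in edta)
    rows[[length(rows) + 1L]] <- data.frame(
      plate_id = plate_id, well_id = wid(), role = "edta_control",
      inhibitor_id = NA_character_, absorbance = a, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

# Small profile dataset straight from a matrix.
toy_dataset <- function(mat, name = "toy", mutants = rep(FALSE, ncol(mat))) {
  kin <- data.frame(profile_label = colnames(mat),
                    gene_symbol = sub("\\(.*\\)$", "", colnames(mat)),
                    is_mutant = mutants, family = NA_character_,
                    stringsAsFactors = FALSE)
  profile_dataset(mat, kin, name = name, assay_kind = "percent_inhibition")
}

# Fingerprint object directly from a named %inhibition vector (standard
# scores reconstructed as a negative affine image so the pair stays
# consistent).
toy_fingerprint <- function(values, screen_id = "toy") {
  structure(data.frame(inhibitor_id = names(values), plate_id = "P1",
                       standard_score = -values / 100,
                       percent_inhibition = unname(values),
                       stringsAsFactors = FALSE),
            screen_id = screen_id, plates = NULL, edta = NULL,
            class = c("kipik_fingerprint", "data.frame"))
}

# Leaf sets of an hclust's internal nodes (wrapper over the package
# internal used for clade identity).
clade_keys_for_test <- function(hc) kipik:::clade_keys(hc)
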