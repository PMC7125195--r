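#' Simulate a kinase-inhibitor profiling dataset
#'
#' Generates a percent-inhibition matrix with the statistical structure of
#' published kinome profiling panels: kinases fall into families whose
#' members respond similarly, each inhibitor strongly hits a small,
#' family-biased set of kinases (its promiscuity), and every measurement
#' carries additive Gaussian background noise. Optionally, mutant entries
#' are created as flagged duplicates of wild-type profiles.
#'
#' Defaults describe a mid-sized panel: 200 kinases in 10 families
#' profiled against 300 inhibitors, true targets inhibited at 85 percent
#' on average, 5 percent-point background noise, and a mean promiscuity of
#' 3 kinases per inhibitor with a 60 percent chance that each extra target
#' stays within the primary target's family.
#'
#' @param n_kinases,n_inhibitors panel dimensions.
#' @param n_families number of kinase-family blocks.
#' @param within_family_bias probability that each additional target of an
#'   inhibitor is drawn from the primary target's family (drives
#'   within-family profile correlation).
#' @param promiscuity_mean mean number of kinases strongly hit per
#'   inhibitor (geometric, shifted so the minimum is 1).
#' @param potency_mean,potency_sd percent inhibition of true targets.
#' @param noise_sd additive background noise, percent points.
#' @param mutant_fraction fraction of kinases duplicated as flagged mutant
#'   constructs.
#' @param missing_fraction fraction of cells set to missing.
#' @param assay_kind `"percent_inhibition"` (default) or
#'   `"dissociation_constant_nM"`, in which case values are converted to
#'   Kd by inverting the Hill relation at `concentration_nM` so the
#'   conversion path is exercised.
#' @param concentration_nM concentration used for the Kd inversion.
#' @param name dataset label.
#' @param seed integer seed; identical arguments and seed give
#'   bit-identical datasets.
#' @return a [profile_dataset()].
#' @export
simulate_profile_dataset <- function(n_kinases = 200, n_inhibitors = 300,
                                     n_families = 10,
                                     within_family_bias = 0.6,
                                     promiscuity_mean = 3,
                                     potency_mean = 85, potency_sd = 8,
                                     noise_sd = 5, mutant_fraction = 0,
                                     missing_fraction = 0,
                                     assay_kind = c("percent_inhibition",
                                                    "dissociation_constant_nM"),
                                     concentration_nM = 500,
                                     name = "synthetic panel", seed) {
  assay_kind <- match.arg(assay_kind)
  stopifnot(n_kinases >= 1, n_inhibitors >= 1, n_families >= 1,
            within_family_bias >= 0, within_family_bias <= 1,
            promiscuity_mean >= 1, noise_sd >= 0,
            mutant_fraction >= 0, mutant_fraction <= 1,
            missing_fraction >= 0, missing_fraction < 1)
  with_seed(seed, {
    klab <- sprintf("K%02d", seq_len(n_kinases))
    family <- sprintf("fam%02d", 1 + (seq_len(n_kinases) - 1) %% n_families)
    ilab <- sprintf("inh%03d", seq_len(n_inhibitors))
    mat <- matrix(stats::rnorm(n_inhibitors * n_kinases, 0, noise_sd),
                  n_inhibitors, n_kinases, dimnames = list(ilab, klab))
    for (i in seq_len(n_inhibitors)) {
      m <- 1L + stats::rgeom(1, 1 / promiscuity_mean)
      m <- min(m, n_kinases)
      primary <- sample.int(n_kinases, 1)
      targets <- primary
      while (length(targets) < m) {
        same_fam <- which(family == family[primary])
        pool <- if (stats::runif(1) < within_family_bias &&
                    length(setdiff(same_fam, targets)))
          setdiff(same_fam, targets) else setdiff(seq_len(n_kinases), targets)
        if (!length(pool)) break
        targets <- c(targets, pool[sample.int(length(pool), 1)])
      }
      mat[i, targets] <- mat[i, targets] +
        stats::rnorm(length(targets), potency_mean, potency_sd)
    }
    kin <- data.frame(profile_label = klab, gene_symbol = klab,
                      is_mutant = FALSE, family = family,
                      stringsAsFactors = FALSE)
    n_mut <- round(mutant_fraction * n_kinases)
    if (n_mut > 0) {
      pick <- sample.int(n_kinases, n_mut)
      mut_mat <- mat[, pick, drop = FALSE] +
        matrix(stats::rnorm(n_inhibitors * n_mut, 0, noise_sd),
               n_inhibitors, n_mut)
      colnames(mut_mat) <- paste0(klab[pick], "(mut)")
      mat <- cbind(mat, mut_mat)
      kin <- rbind(kin, data.frame(profile_label = colnames(mut_mat),
                                   gene_symbol = klab[pick],
                                   is_mutant = TRUE, family = family[pick],
                                   stringsAsFactors = FALSE))
    }
    if (missing_fraction > 0) {
      drop <- sample.int(length(mat), round(missing_fraction * length(mat)))
      mat[drop] <- NA_real_
    }
    conc <- NULL
    if (assay_kind == "dissociation_constant_nM") {
      # invert %inhibition = 100/(1 + Kd/c); clamp into (0, 100) first
      p <- pmin(pmax(mat, 1e-3), 100 - 1e-3)
      mat <- concentration_nM * (100 / p - 1)
    } else {
      conc <- concentration_nM
    }
    profile_dataset(mat, kin, name = name, assay_kind = assay_kind,
                    assay_concentration_nM = conc)
  })
}

#' Simulate ELISA screen plates for a mixture of contributing kinases
#'
#' Emulates the plate-based extract kinase assay: the signal of an
#' inhibitor well is proportional to the residual activity of the
#' contributing kinase mixture under that inhibitor,
#' `baseline * sum_j w_j (100 - I_j) / 100`, plus additive Gaussian read
#' noise. Vehicle (DMSO) wells sit at baseline, EDTA stop-control wells at
#' the fully quenched background. Inhibitor wells are laid out in
#' duplicate (adjacent wells) across as many plates as the capacity
#' requires, each plate carrying its own DMSO and EDTA controls.
#'
#' @param dataset a [profile_dataset()] on the percent-inhibition scale
#'   supplying the true profiles (typically from
#'   [simulate_profile_dataset()]).
#' @param contributing named numeric vector of mixture weights by profile
#'   label; weights must be non-negative and sum to 1.
#' @param baseline mean DMSO absorbance (assay units).
#' @param edta_background mean absorbance of fully quenched wells.
#' @param noise_sd read noise sd as a fraction of baseline (default 0.05).
#' @param wells_per_inhibitor replicate wells per inhibitor (default 2).
#' @param n_dmso,n_edta control wells per plate.
#' @param plate_capacity wells per plate (default 384).
#' @param screen_id screen label.
#' @param seed integer seed.
#' @return a [plate_screen()] whose wells may span several plates.
#' @export
simulate_screen_plates <- function(dataset, contributing, baseline = 1,
                                   edta_background = 0.05, noise_sd = 0.05,
                                   wells_per_inhibitor = 2, n_dmso = 16,
                                   n_edta = 4, plate_capacity = 384,
                                   screen_id = "synthetic screen", seed) {
  stopifnot(inherits(dataset, "profile_dataset"))
  if (is.null(names(contributing)) || any(!nzchar(names(contributing))))
    stop("'contributing' must be a named vector of mixture weights")
  if (any(contributing < 0) || abs(sum(contributing) - 1) > 1e-9)
    stop("mixture weights must be non-negative and sum to 1")
  miss <- setdiff(names(contributing), dataset$kinases$profile_label)
  if (length(miss))
    stop("contributing kinase(s) not in dataset: ",
         paste(miss, collapse = ", "))
  ds <- to_correlation_scale(dataset)
  prof <- ds$values[, names(contributing), drop = FALSE]
  na_frac <- max(colMeans(is.na(prof)))
  if (na_frac > 0.2)
    warning(sprintf("a contributing kinase lacks profile values for %.0f%% of inhibitors",
                    100 * na_frac))
  prof[is.na(prof)] <- 0  # unmeasured = assumed uninhibited
  residual <- as.vector((100 - prof) %*% contributing / 100)
  names(residual) <- rownames(prof)

  n_inh <- length(residual)
  per_plate_ctrl <- n_dmso + n_edta
  cap_inh <- floor((plate_capacity - per_plate_ctrl) / wells_per_inhibitor)
  if (cap_inh < 1) stop("plate_capacity too small for controls + duplicates")
  plate_of <- ceiling(seq_len(n_inh) / cap_inh)
  with_seed(seed, {
    parts <- lapply(unique(plate_of), function(p) {
      pid <- sprintf("P%02d", p)
      inh <- which(plate_of == p)
      # duplicate wells are adjacent: repeat each inhibitor consecutively
      inh_ids <- rep(names(residual)[inh], each = wells_per_inhibitor)
      mu <- c(rep(baseline * residual[inh], each = wells_per_inhibitor),
              rep(baseline, n_dmso), rep(edta_background, n_edta))
      role <- c(rep("inhibitor", length(inh_ids)),
                rep("vehicle_control", n_dmso), rep("edta_control", n_edta))
      abs_ <- pmax(0, mu + stats::rnorm(length(mu), 0, noise_sd * baseline))
      data.frame(plate_id = pid,
                 well_id = sprintf("%s_w%03d", pid, seq_along(mu)),
                 role = role,
                 inhibitor_id = c(inh_ids, rep(NA_character_,
                                               n_dmso + n_edta)),
                 absorbance = abs_, stringsAsFactors = FALSE)
    })
    plate_screen(do.call(rbind, parts), screen_id = screen_id,
                 expected_replicates = wells_per_inhibitor)
  })
}

#' End-to-end recovery experiment over a simulation grid
#'
#' For each combination of screen noise level and contributing-kinase
#' mixture, simulates `n_replicates` complete screens against a common
#' synthetic profiling panel, runs the fingerprint + correlation pipeline,
#' and tabulates how often each true kinase is ranked top-1 and top-5.
#'
#' @param dataset a synthetic [profile_dataset()] (the common panel).
#' @param mixtures list of named weight vectors (each as in
#'   [simulate_screen_plates()]).
#' @param noise_levels vector of read-noise sds (fraction of baseline).
#' @param n_replicates screens per grid cell.
#' @param seed integer seed.
#' @param min_overlap passed to [correlate_fingerprint()].
#' @return data.frame with columns `noise_sd`, `mixture`, `kinase`,
#'   `weight`, `n_replicates`, `top1`, `top5` (recovery fractions).
#' @export
recovery_experiment <- function(dataset, mixtures, noise_levels = c(0.05),
                                n_replicates = 50, seed, min_overlap = 10) {
  stopifnot(inherits(dataset, "profile_dataset"))
  if (is.numeric(mixtures) && !is.list(mixtures)) mixtures <- list(mixtures)
  ds <- exclude_mutant_kinases(to_correlation_scale(dataset))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                      length(noise_levels) * length(mixtures) *
                                        n_replicates))
  si <- 0L
  out <- list()
  for (ns in noise_levels) {
    for (mi in seq_along(mixtures)) {
      mix <- mixtures[[mi]]
      top1 <- top5 <- stats::setNames(numeric(length(mix)), names(mix))
      for (r in seq_len(n_replicates)) {
        si <- si + 1L
        scr <- simulate_screen_plates(dataset, mix, noise_sd = ns,
                                      screen_id = "recovery",
                                      seed = seeds[si])
        fp <- assemble_fingerprint(scr)
        co <- correlate_fingerprint(fp, ds, min_overlap = min_overlap)
        hits <- rank_hits(co)
        for (k in names(mix)) {
          rk <- hits$rank_in_dataset[match(k, hits$profile_label)]
          if (!is.na(rk)) {
            top1[k] <- top1[k] + (rk <= 1)
            top5[k] <- top5[k] + (rk <= 5)
          }
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        noise_sd = ns, mixture = paste(names(mix), collapse = "+"),
        kinase = names(mix), weight = unname(mix),
        n_replicates = n_replicates,
        top1 = unname(top1) / n_replicates,
        top5 = unname(top5) / n_replicates, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "seed") <- seed
  res
}
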