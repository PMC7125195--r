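#' Identify the kinase behind a screen fingerprint
#'
#' The central fit of the package: given a screen's inhibition fingerprint
#' and one or more reference profiling datasets, it (1) puts each dataset
#' on the common inhibition-increasing scale and excludes mutant entries,
#' (2) computes pairwise-complete Pearson correlations between the
#' fingerprint and every kinase profile, (3) builds a permutation null per
#' dataset by relabeling the fingerprint `n_perm` times and converts the
#' observed coefficients into z-scores, (4) ranks hits within each dataset
#' and overall (by raw correlation), and (5) flags screen confidence from
#' the top z-score (below 6: caution; 10 or above: robust).
#'
#' @param fingerprint a `"kipik_fingerprint"` from
#'   [assemble_fingerprint()], or a [plate_screen()] / list of plate
#'   screens (the fingerprint is then assembled first).
#' @param datasets a [profile_dataset()] or list of them.
#' @param min_overlap minimum shared inhibitors per kinase (default 10).
#' @param n_perm permutations for the null (default 100).
#' @param seed integer seed for the permutation null.
#' @param null_scope `"per_dataset"` (default) or `"pooled"`: whether
#'   z-scores are referred to each dataset's own null or to one null
#'   pooled across all datasets of the screen.
#' @param kd_concentration_nM concentration for Kd-to-\%inhibition
#'   conversion (default 500).
#' @param top_n hits shown per dataset by `print`/`summary`.
#' @return an object of class `"kipik"` with elements `hits`
#'   (a `"kipik_hits"` table), `nulls`, `fingerprint`, `datasets`
#'   (the prepared datasets), `confidence`, `z_max`, `seed`, `call`.
#' @examples
#' panel <- simulate_profile_dataset(n_kinases = 30, n_inhibitors = 60,
#'                                   seed = 11)
#' screen <- simulate_screen_plates(panel, contributing = c(K07 = 1),
#'                                  seed = 12)
#' fit <- kipik(screen, panel, seed = 13)
#' fit
#' @export
kipik <- function(fingerprint, datasets, min_overlap = 10, n_perm = 100,
                  seed, null_scope = c("per_dataset", "pooled"),
                  kd_concentration_nM = 500, top_n = 10) {
  null_scope <- match.arg(null_scope)
  cl <- match.call()
  if (inherits(fingerprint, "plate_screen") ||
      (is.list(fingerprint) && !inherits(fingerprint, "kipik_fingerprint") &&
       all(vapply(fingerprint, inherits, logical(1), "plate_screen"))))
    fingerprint <- assemble_fingerprint(fingerprint)
  stopifnot(inherits(fingerprint, "kipik_fingerprint"))
  if (inherits(datasets, "profile_dataset")) datasets <- list(datasets)
  if (!length(datasets)) stop("at least one profiling dataset is required")
  prepped <- lapply(datasets, function(ds)
    exclude_mutant_kinases(to_correlation_scale(ds, kd_concentration_nM)))
  names(prepped) <- vapply(prepped, `[[`, character(1), "name")
  if (anyDuplicated(names(prepped)))
    stop("dataset names must be unique")
  cors <- lapply(prepped, correlate_fingerprint, fp = fingerprint,
                 min_overlap = min_overlap)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                      length(prepped)))
  nulls <- Map(function(ds, s) build_null(fingerprint, ds, n_perm = n_perm,
                                          seed = s, min_overlap = min_overlap),
               prepped, seeds)
  if (null_scope == "pooled") {
    pooled <- pool_nulls(nulls)
    cors <- lapply(cors, z_scores, null = pooled)
    nulls <- c(nulls, list(pooled = pooled))
  } else {
    cors <- Map(z_scores, cors, nulls)
  }
  hits <- flag_screen_confidence(rank_hits(cors, top_n = top_n))
  structure(list(hits = hits,
                 nulls = nulls,
                 fingerprint = fingerprint,
                 datasets = prepped,
                 confidence = attr(hits, "confidence"),
                 z_max = attr(hits, "z_max"),
                 min_overlap = min_overlap,
                 n_perm = n_perm,
                 null_scope = null_scope,
                 seed = seed,
                 call = cl),
            class = "kipik")
}

#' @export
print.kipik <- function(x, ...) {
  cat("KiPIK screen analysis:", attr(x$fingerprint, "screen_id"), "\n")
  cat(sprintf("  %d inhibitors vs %d dataset(s); %d permutations (%s null), seed %s\n",
              nrow(x$fingerprint), length(x$datasets), x$n_perm,
              x$null_scope, format(x$seed)))
  top <- x$hits[x$hits$rank_overall == 1, , drop = FALSE]
  cat(sprintf("  top hit: %s (rho = %.3f, z = %.2f, %s)\n",
              top$gene_symbol, top$rho, top$z, top$dataset))
  cat(sprintf("  confidence: %s (top z = %.2f)\n", x$confidence, x$z_max))
  invisible(x)
}

#' @export
summary.kipik <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$hits)
  invisible(object)
}

#' @export
as.data.frame.kipik <- function(x, ...) {
  as.data.frame(x$hits)
}

#' Extract the per-kinase correlation coefficients of a fit
#'
#' @param object a `"kipik"` fit.
#' @param dataset dataset name; default the first.
#' @param ... unused.
#' @return named numeric vector of Pearson coefficients (names are
#'   profile labels).
#' @export
coef.kipik <- function(object, dataset = NULL, ...) {
  h <- object$hits
  dataset <- dataset %||% h$dataset[1]
  d <- h[h$dataset == dataset, , drop = FALSE]
  stats::setNames(d$rho, d$profile_label)
}

#' Stripchart of screen correlations by dataset
#'
#' One jittered column of per-kinase Pearson coefficients per profiling
#' dataset, with the top hit of each dataset labelled — the standard
#' at-a-glance view of a screen.
#'
#' @param x a `"kipik"` fit.
#' @param ... passed to [graphics::stripchart()].
#' @export
plot.kipik <- function(x, ...) {
  h <- as.data.frame(x$hits)
  sets <- unique(h$dataset)
  graphics::stripchart(split(h$rho, factor(h$dataset, levels = sets)),
                       vertical = TRUE, method = "jitter", pch = 16,
                       cex = 0.6, col = "#00000080",
                       ylab = expression("Pearson " * rho),
                       main = attr(x$fingerprint, "screen_id"), ...)
  for (i in seq_along(sets)) {
    d <- h[h$dataset == sets[i], , drop = FALSE]
    top <- d[which.max(d$rho), , drop = FALSE]
    graphics::points(i, top$rho, col = "#e31a1c", pch = 16)
    graphics::text(i, top$rho, top$gene_symbol, pos = 4, cex = 0.8,
                   col = "#e31a1c")
  }
  invisible(x)
}

#' Simulate screens from a fitted analysis' own top hit
#'
#' Draws `nsim` fresh synthetic screens in which the fit's overall top-hit
#' kinase is the sole contributor, using the first prepared dataset as the
#' profile source — a quick self-consistency check of the identification.
#'
#' @param object a `"kipik"` fit.
#' @param nsim number of simulated screens.
#' @param seed integer seed.
#' @param noise_sd read-noise sd (fraction of baseline).
#' @param ... unused.
#' @return list of `"kipik_fingerprint"` objects.
#' @export
simulate.kipik <- function(object, nsim = 1, seed, noise_sd = 0.05, ...) {
  top <- object$hits[object$hits$rank_overall == 1, , drop = FALSE]
  ds <- object$datasets[[top$dataset]]
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2, nsim))
  lapply(seeds, function(s) {
    scr <- simulate_screen_plates(ds,
                                  stats::setNames(1, top$profile_label),
                                  noise_sd = noise_sd,
                                  screen_id = "simulated", seed = s)
    assemble_fingerprint(scr)
  })
}
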