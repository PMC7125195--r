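#' Permute the inhibitor labels of a fingerprint
#'
#' Randomly reassigns the fingerprint's (standard score, \%inhibition)
#' pairs to inhibitor ids, leaving the multiset of values untouched. This
#' is the elementary move behind the permutation null: a permuted
#' fingerprint carries the same values but no information about which
#' inhibitor produced them.
#'
#' @param fp a `"kipik_fingerprint"` with at least two inhibitors.
#' @param seed integer seed; the same seed always yields the same
#'   permutation.
#' @return a permuted `"kipik_fingerprint"`.
#' @export
permute_fingerprint <- function(fp, seed) {
  stopifnot(inherits(fp, "kipik_fingerprint"))
  if (nrow(fp) < 2) stop("need >= 2 inhibitors to permute")
  perm <- with_seed(seed, sample.int(nrow(fp)))
  out <- fp
  out$standard_score <- fp$standard_score[perm]
  out$percent_inhibition <- fp$percent_inhibition[perm]
  out
}

#' Build the permutation null distribution of correlation coefficients
#'
#' Generates `n_perm` random relabelings of the fingerprint, correlates
#' each against every kinase profile of the dataset with the same
#' pairwise-complete overlap and variance filters as
#' [correlate_fingerprint()], and pools the resulting coefficients into
#' one null sample per (screen, dataset) pair. The null's mean and sd feed
#' [z_scores()].
#'
#' @inheritParams correlate_fingerprint
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @return an object of class `"kipik_null"` with elements `screen_id`,
#'   `dataset_name`, `n_perm`, `sample` (pooled permuted coefficients),
#'   `mean`, `sd`, `seed`.
#' @export
build_null <- function(fp, dataset, n_perm = 100, seed, min_overlap = 10) {
  stopifnot(inherits(fp, "kipik_fingerprint"),
            inherits(dataset, "profile_dataset"))
  if (nrow(fp) < 2) stop("need >= 2 inhibitors to permute")
  v <- fp_vector(fp)
  shared <- intersect(names(v), rownames(dataset$values))
  if (!length(shared))
    stop("no inhibitor ids shared between fingerprint and dataset '",
         dataset$name, "'")
  mat <- dataset$values[shared, , drop = FALSE]
  x <- v[shared]
  # one permutation of the full fingerprint per iteration; the shared
  # subset inherits it, exactly as relabeling the screen would
  perms <- with_seed(seed, replicate(n_perm, sample.int(nrow(fp)),
                                     simplify = FALSE))
  idx <- match(shared, fp$inhibitor_id)
  pooled <- lapply(perms, function(p) {
    xp <- fp$percent_inhibition[p][idx]
    names(xp) <- shared
    r <- correlate_vector(xp, mat, min_overlap)
    r$rho[r$keep]
  })
  samp <- unlist(pooled)
  if (!length(samp))
    stop("no valid permuted coefficients for dataset '", dataset$name, "'")
  if (length(samp) >= 2 &&
      (!is.finite(stats::sd(samp)) || stats::sd(samp) == 0))
    stop("degenerate null distribution for dataset '", dataset$name,
         "': zero spread in permuted coefficients")
  structure(list(screen_id = attr(fp, "screen_id"),
                 dataset_name = dataset$name,
                 n_perm = n_perm,
                 sample = samp,
                 mean = mean(samp),
                 sd = stats::sd(samp),
                 seed = seed),
            class = "kipik_null")
}

#' Pool permutation nulls across datasets
#'
#' Optional alternative to the per-dataset null: concatenates the permuted
#' coefficient samples of several nulls into a single screen-wide null.
#' Outputs are labelled `"pooled"`.
#'
#' @param nulls list of `"kipik_null"` objects from one screen.
#' @return a `"kipik_null"` with `dataset_name = "pooled"`.
#' @export
pool_nulls <- function(nulls) {
  stopifnot(length(nulls) >= 1,
            all(vapply(nulls, inherits, logical(1), "kipik_null")))
  samp <- unlist(lapply(nulls, `[[`, "sample"))
  structure(list(screen_id = nulls[[1]]$screen_id,
                 dataset_name = "pooled",
                 n_perm = sum(vapply(nulls, `[[`, numeric(1), "n_perm")),
                 sample = samp, mean = mean(samp), sd = stats::sd(samp),
                 seed = nulls[[1]]$seed),
            class = "kipik_null")
}

#' @export
print.kipik_null <- function(x, ...) {
  cat(sprintf("Permutation null for screen %s vs %s:\n", x$screen_id,
              x$dataset_name))
  cat(sprintf("  %d permutations, %d pooled coefficients\n", x$n_perm,
              length(x$sample)))
  cat(sprintf("  mean = %.4f, sd = %.4f (seed %s)\n", x$mean, x$sd,
              format(x$seed)))
  invisible(x)
}

#' Convert observed correlations to permutation z-scores
#'
#' `z = (observed rho - null mean) / null sd`: how many null standard
#' deviations an observed coefficient sits above the permutation null.
#'
#' @param correlations output of [correlate_fingerprint()] (or a
#'   `"kipik_hits"` table restricted to one dataset).
#' @param null a `"kipik_null"` built for the same dataset (or a pooled
#'   null).
#' @return `correlations` with the `z` column filled in.
#' @export
z_scores <- function(correlations, null) {
  stopifnot(inherits(null, "kipik_null"))
  if (!is.data.frame(correlations) || !"rho" %in% names(correlations))
    stop("'correlations' must be a correlation data.frame with a 'rho' column")
  if (null$dataset_name != "pooled" &&
      !all(correlations$dataset == null$dataset_name))
    stop("null was built for dataset '", null$dataset_name,
         "' but correlations are for '",
         paste(unique(correlations$dataset), collapse = ", "), "'")
  if (!is.finite(null$sd) || null$sd <= 0) stop("null sd must be positive")
  correlations$z <- (correlations$rho - null$mean) / null$sd
  correlations
}

#' Write a null-distribution summary to a delimited file
#'
#' @param nulls a `"kipik_null"` or list of them.
#' @param path output path.
#' @param full_sample also write `<path>.sample` with the pooled
#'   coefficients, one per line (diagnostics).
#' @param sep field separator; default inferred from extension.
#' @export
write_null_summary <- function(nulls, path, full_sample = FALSE, sep = NULL) {
  if (inherits(nulls, "kipik_null")) nulls <- list(nulls)
  out <- do.call(rbind, lapply(nulls, function(n)
    data.frame(screen_id = n$screen_id, dataset = n$dataset_name,
               n_permutations = n$n_perm, n_pooled = length(n$sample),
               mean = n$mean, sd = n$sd, seed = n$seed,
               stringsAsFactors = FALSE)))
  write_delim_table(out, path, sep)
  if (full_sample)
    writeLines(unlist(lapply(nulls, function(n) fmt_num(n$sample))),
               paste0(path, ".sample"))
  invisible(path)
}
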