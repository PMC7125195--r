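#' Downsampling recovery curves
#'
#' Quantifies how hit identification degrades with inhibitor library size:
#' from the N inhibitors shared by the fingerprint and the dataset, `n`
#' are repeatedly drawn without replacement, kinases are re-ranked by
#' Pearson correlation on the subsample (same overlap and variance filters
#' as the full analysis), and the frequency with which the target kinase
#' lands in the top k is recorded.
#'
#' A kinase tied with the k-th ranked coefficient counts as recovered. A
#' subsample in which the target fails the `min_overlap` or variance
#' filter counts as non-recovery — exactly what a real library of that
#' size would deliver.
#'
#' @inheritParams correlate_fingerprint
#' @param target profile label of the kinase whose recovery is tracked.
#' @param n_values subsample sizes (default `3, ..., N` capped at 25 grid
#'   points, evenly spaced).
#' @param k_values top-k thresholds (default `c(1, 5, 10)`).
#' @param reps subsamples per n (default 10000).
#' @param seed integer seed.
#' @return an object of class `"kipik_downsampling"`: a long data.frame
#'   with columns `dataset`, `target`, `n`, `k`, `reps`,
#'   `recovery_frequency`, plus `seed` attribute.
#' @export
downsample_recovery <- function(fp, dataset, target, n_values = NULL,
                                k_values = c(1, 5, 10), reps = 10000, seed,
                                min_overlap = 10) {
  stopifnot(inherits(fp, "kipik_fingerprint"),
            inherits(dataset, "profile_dataset"))
  tgt <- match(target, dataset$kinases$profile_label)
  if (is.na(tgt))
    stop("target kinase '", target, "' not present in dataset '",
         dataset$name, "'")
  v <- fp_vector(fp)
  shared <- intersect(names(v), rownames(dataset$values))
  N <- length(shared)
  if (N < 3) stop("fewer than 3 shared inhibitors")
  if (is.null(n_values)) {
    n_values <- unique(round(seq(3, N, length.out = min(25, N - 2))))
  }
  n_values <- sort(unique(as.integer(n_values)))
  if (any(n_values < 3) || any(n_values > N))
    stop("n_values must lie in [3, N = ", N, "]")
  k_values <- sort(unique(as.integer(k_values)))
  x <- v[shared]
  mat <- dataset$values[shared, , drop = FALSE]
  rows <- with_seed(seed, {
    out <- vector("list", length(n_values))
    for (i in seq_along(n_values)) {
      n <- n_values[i]
      hits <- matrix(FALSE, reps, length(k_values))
      for (r in seq_len(reps)) {
        sub <- if (n == N) seq_len(N) else sample.int(N, n)
        cv <- correlate_vector(x[sub], mat[sub, , drop = FALSE], min_overlap)
        if (cv$keep[tgt]) {
          # rank with rho ties counting as recovered
          rank_min <- 1L + sum(cv$rho[cv$keep] > cv$rho[tgt])
          hits[r, ] <- rank_min <= k_values
        }
      }
      out[[i]] <- data.frame(dataset = dataset$name, target = target,
                             n = n, k = rep(k_values, each = 1),
                             reps = reps,
                             recovery_frequency = colMeans(hits),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  structure(rows, seed = seed, N = N,
            class = c("kipik_downsampling", "data.frame"))
}

#' Relative top-k grid for a dataset
#'
#' The absolute thresholds k = 1, 5, 10 have a relative counterpart
#' k = size/100, size/20, size/10 (rounded, floored at 1, deduplicated).
#' By default the divisor is the kinase-panel size; set
#' `basis = "inhibitors"` to scale with library size instead.
#'
#' @param dataset a [profile_dataset()].
#' @param basis `"kinases"` (default) or `"inhibitors"`.
#' @return sorted integer vector of k thresholds.
#' @export
relative_k_grid <- function(dataset, basis = c("kinases", "inhibitors")) {
  basis <- match.arg(basis)
  size <- if (basis == "kinases") nrow(dataset$kinases)
          else nrow(dataset$values)
  sort(unique(pmax(1L, as.integer(round(size / c(100, 20, 10))))))
}

#' Write a downsampling curve to a delimited file
#'
#' Long format: columns `dataset`, `target`, `n`, `k`, `reps`,
#' `recovery_frequency`, `seed`.
#'
#' @param curve a `"kipik_downsampling"`.
#' @param path output path.
#' @param sep field separator; default inferred from extension.
#' @export
write_downsampling_curve <- function(curve, path, sep = NULL) {
  stopifnot(inherits(curve, "kipik_downsampling"))
  out <- as.data.frame(curve)
  out$seed <- attr(curve, "seed")
  write_delim_table(out, path, sep)
  invisible(path)
}

#' @export
print.kipik_downsampling <- function(x, ...) {
  cat(sprintf("Downsampling recovery of %s in %s (N = %d shared inhibitors, %d reps)\n",
              x$target[1], x$dataset[1], attr(x, "N"), x$reps[1]))
  w <- stats::reshape(as.data.frame(x)[c("n", "k", "recovery_frequency")],
                      idvar = "n", timevar = "k", direction = "wide")
  names(w) <- sub("recovery_frequency.", "k=", names(w), fixed = TRUE)
  print(w, row.names = FALSE)
  invisible(x)
}
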