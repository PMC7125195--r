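#' Correlate a fingerprint against every kinase profile in a dataset
#'
#' Computes the Pearson correlation between the screen's \%inhibition
#' fingerprint and each kinase's inhibition profile over the
#' pairwise-complete set of shared inhibitors. Kinases whose overlap with
#' the fingerprint is below `min_overlap`, or whose profile (or the
#' fingerprint) has zero variance on the overlap, are dropped with a
#' logged reason rather than assigned a fabricated coefficient.
#'
#' The dataset must already be on the inhibition-increasing scale
#' ([to_correlation_scale()]) and have mutant kinase entries excluded
#' ([exclude_mutant_kinases()]); the high-level [kipik()] fit does both.
#'
#' @param fp a `"kipik_fingerprint"`.
#' @param dataset a [profile_dataset()] on the inhibition scale, mutants
#'   excluded.
#' @param min_overlap minimum number of shared inhibitors (default 10).
#' @return data.frame with columns `dataset`, `profile_label`,
#'   `gene_symbol`, `family`, `rho`, `n_overlap`, `z` (NA until
#'   [z_scores()] is applied); dropped kinases with reasons in attribute
#'   `"dropped"`.
#' @export
correlate_fingerprint <- function(fp, dataset, min_overlap = 10) {
  stopifnot(inherits(fp, "kipik_fingerprint"),
            inherits(dataset, "profile_dataset"))
  if (!nrow(fp)) stop("fingerprint is empty")
  if (!identical(dataset$scale, "inhibition"))
    stop("dataset '", dataset$name, "' is not on the inhibition scale; ",
         "apply to_correlation_scale() first")
  if (any(dataset$kinases$is_mutant))
    stop("dataset '", dataset$name, "' still contains mutant entries; ",
         "apply exclude_mutant_kinases() first")
  v <- fp_vector(fp)
  shared <- intersect(names(v), rownames(dataset$values))
  if (!length(shared))
    stop("no inhibitor ids shared between fingerprint and dataset '",
         dataset$name, "'; check that the screen library and the ",
         "profiling table use the same inhibitor identifiers")
  x <- v[shared]
  mat <- dataset$values[shared, , drop = FALSE]
  res <- correlate_vector(x, mat, min_overlap)
  kin <- dataset$kinases
  keep <- res$keep
  out <- data.frame(dataset = dataset$name,
                    profile_label = kin$profile_label[keep],
                    gene_symbol = kin$gene_symbol[keep],
                    family = kin$family[keep],
                    rho = res$rho[keep],
                    n_overlap = res$n[keep],
                    z = NA_real_,
                    stringsAsFactors = FALSE)
  if (!nrow(out))
    stop("no kinase in '", dataset$name, "' survives the overlap and ",
         "variance filters (min_overlap = ", min_overlap, ")")
  dropped <- data.frame(profile_label = kin$profile_label[!keep],
                        reason = res$reason[!keep], stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  attr(out, "screen_id") <- attr(fp, "screen_id")
  attr(out, "min_overlap") <- min_overlap
  out
}

# Pairwise-complete Pearson of a named vector against matrix columns,
# with overlap and variance filters. Shared by ranking, null model,
# downsampling.
correlate_vector <- function(x, mat, min_overlap) {
  obs <- !is.na(mat) & is.finite(x)
  n <- colSums(obs)
  suppressWarnings(rho <- as.vector(stats::cor(x, mat,
                                               use = "pairwise.complete.obs")))
  keep <- n >= min_overlap & is.finite(rho)
  reason <- rep(NA_character_, length(n))
  reason[n < min_overlap] <- sprintf("overlap %d < min_overlap %d",
                                     n[n < min_overlap], min_overlap)
  reason[n >= min_overlap & !is.finite(rho)] <- "zero variance on overlap"
  list(rho = rho, n = as.integer(n), keep = keep, reason = reason)
}

# Documented tie-break: rho desc, then z desc (NA last), then n_overlap
# desc, then gene_symbol ascending.
hit_order <- function(df) {
  z <- df$z
  z[is.na(z)] <- -Inf
  order(-df$rho, -z, -df$n_overlap, df$gene_symbol)
}

#' Rank kinase hits across one or more profiling datasets
#'
#' Builds the screen's hit table: per-dataset ranks and an overall ranking
#' that pools all (dataset, kinase) rows by raw Pearson coefficient, as
#' the highest-overall-correlation readout does. Ties are broken by higher
#' z (when present), larger overlap, then gene symbol.
#'
#' @param correlations a data.frame from [correlate_fingerprint()] or a
#'   list of them (one per dataset).
#' @param top_n hits to display per dataset in `print`/`summary`
#'   (default 10).
#' @return an object of class `"kipik_hits"`: the combined data.frame with
#'   `rank_in_dataset` and `rank_overall` columns.
#' @export
rank_hits <- function(correlations, top_n = 10) {
  if (is.data.frame(correlations)) correlations <- list(correlations)
  if (!length(correlations)) stop("no correlation results supplied")
  screen_id <- attr(correlations[[1]], "screen_id") %||% "screen"
  min_overlap <- attr(correlations[[1]], "min_overlap") %||% NA_integer_
  parts <- lapply(correlations, function(d) {
    d <- as.data.frame(d)
    d$rank_in_dataset <- NA_integer_
    d$rank_in_dataset[hit_order(d)] <- seq_len(nrow(d))
    d
  })
  tab <- do.call(rbind, parts)
  rownames(tab) <- NULL
  tab$rank_overall <- NA_integer_
  tab$rank_overall[hit_order(tab)] <- seq_len(nrow(tab))
  structure(tab, screen_id = screen_id, top_n = top_n,
            min_overlap = min_overlap, confidence = NA_character_,
            dropped = do.call(rbind, lapply(correlations, attr, "dropped")),
            class = c("kipik_hits", "data.frame"))
}

#' Flag the confidence of a screen from its top z-score
#'
#' Screens whose best z-score is below 6 should be treated with caution;
#' 10 or above appears robust; between the two is intermediate.
#'
#' @param table a `"kipik_hits"` table with z-scores present
#'   (see [z_scores()]).
#' @return the table with attribute `"confidence"` set to `"caution"`,
#'   `"intermediate"` or `"robust"`.
#' @export
flag_screen_confidence <- function(table) {
  stopifnot(inherits(table, "kipik_hits"))
  if (all(is.na(table$z)))
    stop("no z-scores present; build a permutation null with build_null() ",
         "and apply z_scores() first")
  zmax <- max(table$z, na.rm = TRUE)
  attr(table, "confidence") <-
    if (zmax < 6) "caution" else if (zmax < 10) "intermediate" else "robust"
  attr(table, "z_max") <- zmax
  table
}

#' Export a hit table as a KinMap kinome annotation file
#'
#' Produces the tab-separated annotation loaded by the KinMap web tool:
#' one row per kinase with columns `xName` (gene symbol), `size` (circle
#' size, linear in the correlation coefficient from 0 at rho <= 0 to
#' `max_size` at rho = 1) and `fill` (the top hit gets `top_fill`).
#'
#' @param table a `"kipik_hits"` table.
#' @param dataset_name which dataset's correlations to export; default the
#'   first in the table.
#' @param path optional output path; if `NULL` the annotation lines are
#'   returned invisibly as a character vector.
#' @param max_size circle size at rho = 1 (default 100).
#' @param fill,top_fill hex fill colors for ordinary kinases and the
#'   dataset's top hit.
#' @export
export_kinmap_annotation <- function(table, dataset_name = NULL, path = NULL,
                                     max_size = 100, fill = "#1f78b4",
                                     top_fill = "#e31a1c") {
  stopifnot(inherits(table, "kipik_hits"))
  if (!nrow(table)) stop("empty hit table")
  dataset_name <- dataset_name %||% table$dataset[1]
  d <- table[table$dataset == dataset_name, , drop = FALSE]
  if (!nrow(d)) stop("no rows for dataset '", dataset_name, "'")
  size <- round(max_size * pmin(pmax(d$rho, 0), 1))
  lines <- c("xName\tsize\tfill",
             sprintf("%s\t%d\t%s", d$gene_symbol, as.integer(size),
                     ifelse(d$rank_in_dataset == 1, top_fill, fill)))
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(path))
  }
  invisible(lines)
}

#' Write a hit table to a delimited file
#'
#' Columns `screen_id`, `dataset`, `gene_symbol`, `profile_label`, `rho`,
#' `n_overlap`, `z`, `rank_in_dataset`, `rank_overall`.
#'
#' @param table a `"kipik_hits"` table.
#' @param path output path.
#' @param sep field separator; default inferred from extension.
#' @export
write_hit_table <- function(table, path, sep = NULL) {
  stopifnot(inherits(table, "kipik_hits"))
  out <- data.frame(screen_id = attr(table, "screen_id"),
                    as.data.frame(table)[c("dataset", "gene_symbol",
                                           "profile_label", "rho", "n_overlap",
                                           "z", "rank_in_dataset",
                                           "rank_overall")],
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank_overall), , drop = FALSE]
  write_delim_table(out, path, sep)
  invisible(path)
}

#' @export
print.kipik_hits <- function(x, ...) {
  cat("KiPIK hit table for screen:", attr(x, "screen_id"), "\n")
  conf <- attr(x, "confidence")
  if (!is.na(conf))
    cat(sprintf("  confidence: %s (top z = %.2f)\n", conf, attr(x, "z_max")))
  top_n <- attr(x, "top_n") %||% 10
  for (ds in unique(x$dataset)) {
    d <- x[x$dataset == ds, , drop = FALSE]
    d <- d[order(d$rank_in_dataset), , drop = FALSE]
    cat("\n  ", ds, " (", nrow(d), " kinases):\n", sep = "")
    show <- utils::head(d, top_n)
    cat(sprintf("    %2d. %-12s rho=%6.3f  n=%3d%s\n",
                show$rank_in_dataset, show$gene_symbol, show$rho,
                show$n_overlap,
                ifelse(is.na(show$z), "", sprintf("  z=%6.2f", show$z))),
        sep = "")
  }
  invisible(x)
}
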