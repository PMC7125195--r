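#' Reference kinase-inhibitor profiling datasets
#'
#' A profiling dataset is a matrix of measurements of inhibitor effects on a
#' panel of recombinant kinases, published with one of several measurement
#' semantics: single-point percent inhibition, percent remaining activity,
#' dissociation constants (Kd, nM), or thermal-shift values (degrees C).
#' `profile_dataset()` is the low-level constructor; most users will call
#' [read_profile_table()].
#'
#' Values are stored as an inhibitor x kinase matrix (rows named by
#' inhibitor id, columns by the kinase `profile_label` as printed in the
#' source). Missing measurements are `NA` and stay missing: no imputation is
#' performed anywhere; downstream correlations are pairwise-complete.
#'
#' @param values numeric matrix, rows = inhibitors (rownames are inhibitor
#'   ids), columns = kinase entries (colnames are profile labels).
#' @param kinases data.frame with columns `profile_label`, `gene_symbol`,
#'   `is_mutant` (logical) and optionally `family`. Defaults are derived
#'   from the column names with no mutants flagged.
#' @param name dataset label, e.g. `"Nanosyn 1 uM"`.
#' @param assay_kind one of `"percent_inhibition"`,
#'   `"percent_remaining_activity"`, `"dissociation_constant_nM"`,
#'   `"thermal_shift_C"`.
#' @param assay_concentration_nM positive concentration at which the panel
#'   was profiled, or `NULL` (Kd and thermal-shift kinds).
#' @return an object of class `"profile_dataset"`.
#' @export
profile_dataset <- function(values, kinases = NULL, name = "dataset",
                            assay_kind = c("percent_inhibition",
                                           "percent_remaining_activity",
                                           "dissociation_constant_nM",
                                           "thermal_shift_C"),
                            assay_concentration_nM = NULL) {
  assay_kind <- match.arg(assay_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (inhibitors x kinases)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have inhibitor rownames and kinase colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate inhibitor ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate kinase profile labels: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(is.infinite(values)))
    stop("profile values must be finite (use NA for missing)")
  if (all(is.na(values)))
    stop("dataset contains zero parseable values")
  if (assay_kind == "dissociation_constant_nM" &&
      any(values[!is.na(values)] <= 0))
    stop("dissociation constants must be strictly positive")
  if (!is.null(assay_concentration_nM) &&
      (!is.numeric(assay_concentration_nM) || assay_concentration_nM <= 0))
    stop("'assay_concentration_nM' must be a positive number or NULL")

  if (is.null(kinases)) {
    kinases <- data.frame(profile_label = colnames(values),
                          gene_symbol = colnames(values),
                          is_mutant = FALSE,
                          family = NA_character_,
                          stringsAsFactors = FALSE)
  }
  req <- c("profile_label", "gene_symbol", "is_mutant")
  if (!all(req %in% names(kinases)))
    stop("'kinases' must have columns: ", paste(req, collapse = ", "))
  if (!"family" %in% names(kinases)) kinases$family <- NA_character_
  kinases <- kinases[match(colnames(values), kinases$profile_label),
                     c("profile_label", "gene_symbol", "is_mutant", "family")]
  if (anyNA(kinases$profile_label))
    stop("every value column needs a matching row in 'kinases'")
  if (any(!nzchar(kinases$gene_symbol)) || anyNA(kinases$gene_symbol))
    stop("gene_symbol must be non-empty for every kinase entry")
  rownames(kinases) <- NULL

  # drop kinase entries with no measurements at all
  keep <- colSums(!is.na(values)) > 0
  if (!all(keep)) {
    values <- values[, keep, drop = FALSE]
    kinases <- kinases[keep, , drop = FALSE]
    rownames(kinases) <- NULL
  }

  structure(list(name = name,
                 assay_kind = assay_kind,
                 assay_concentration_nM = assay_concentration_nM,
                 values = values,
                 kinases = kinases,
                 scale = if (assay_kind %in% c("percent_inhibition",
                                               "thermal_shift_C"))
                   "inhibition" else "native",
                 provenance = character(0)),
            class = "profile_dataset")
}

#' @export
print.profile_dataset <- function(x, ...) {
  cat("Kinase inhibitor profiling dataset:", x$name, "\n")
  cat("  assay kind:          ", x$assay_kind,
      if (!is.null(x$assay_concentration_nM))
        sprintf(" (at %g nM)", x$assay_concentration_nM) else "", "\n", sep = "")
  cat("  inhibitors:          ", nrow(x$values), "\n", sep = "")
  cat("  kinase entries:      ", ncol(x$values),
      sprintf(" (%d mutant)", sum(x$kinases$is_mutant)), "\n", sep = "")
  cat("  measured values:     ", sum(!is.na(x$values)),
      sprintf(" (%.1f%% missing)", 100 * mean(is.na(x$values))), "\n", sep = "")
  cat("  correlation scale:   ", x$scale, "\n", sep = "")
  for (p in x$provenance) cat("  note: ", p, "\n", sep = "")
  invisible(x)
}

#' Read a profiling table from a delimited file
#'
#' Accepts wide tables (first column inhibitor id, one column per kinase
#' entry) or long tables (columns `kinase`, `inhibitor`, `value`). CSV vs
#' TSV is inferred from the extension and can be overridden. Non-numeric
#' cells become missing values.
#'
#' Mutant/engineered kinase constructs are flagged by matching
#' `mutant_flag_regex` against the profile label; the gene symbol is the
#' label with the matched part removed (trimmed), so e.g. label
#' `"ABL1(T315I)"` with regex `"\\(.*\\)$"` yields gene symbol `"ABL1"`
#' and `is_mutant = TRUE`.
#'
#' @param path file path of the delimited table.
#' @param orientation `"wide"` or `"long"`.
#' @param mutant_flag_regex regex marking mutant constructs in the profile
#'   label, or `NULL` for none.
#' @param sep field separator; default inferred from extension.
#' @inheritParams profile_dataset
#' @return a [profile_dataset()].
#' @export
read_profile_table <- function(path, orientation = c("wide", "long"),
                               assay_kind, name = basename(path),
                               assay_concentration_nM = NULL,
                               mutant_flag_regex = NULL, sep = NULL) {
  orientation <- match.arg(orientation)
  tab <- read_delim_table(path, sep)
  if (orientation == "wide") {
    ids <- as.character(tab[[1]])
    mat <- as.matrix(tab[, -1, drop = FALSE])
    suppressWarnings(storage.mode(mat) <- "double")
    rownames(mat) <- ids
  } else {
    need <- c("kinase", "inhibitor", "value")
    if (!all(need %in% names(tab)))
      stop("long-format table needs columns: ", paste(need, collapse = ", "))
    ids <- unique(as.character(tab$inhibitor))
    kin <- unique(as.character(tab$kinase))
    mat <- matrix(NA_real_, length(ids), length(kin),
                  dimnames = list(ids, kin))
    vals <- suppressWarnings(as.numeric(tab$value))
    mat[cbind(match(as.character(tab$inhibitor), ids),
              match(as.character(tab$kinase), kin))] <- vals
  }
  kinases <- data.frame(profile_label = colnames(mat),
                        gene_symbol = colnames(mat),
                        is_mutant = FALSE, family = NA_character_,
                        stringsAsFactors = FALSE)
  if (!is.null(mutant_flag_regex)) {
    hit <- grepl(mutant_flag_regex, kinases$profile_label)
    kinases$is_mutant <- hit
    kinases$gene_symbol <- trimws(sub(mutant_flag_regex, "",
                                      kinases$profile_label))
  }
  ds <- profile_dataset(mat, kinases, name = name, assay_kind = assay_kind,
                        assay_concentration_nM = assay_concentration_nM)
  ds$provenance <- c(ds$provenance,
                     sprintf("read %d x %d table from %s (%d missing cells)",
                             nrow(mat), ncol(mat), basename(path),
                             sum(is.na(mat))))
  ds
}

#' Write a profiling dataset to a delimited file
#'
#' Wide orientation: first column `inhibitor_id`, remaining columns kinase
#' profile labels. Values round-trip exactly through [read_profile_table()]
#' for decimal inputs of up to six significant digits.
#'
#' @param dataset a [profile_dataset()].
#' @param path output path (`.csv` or `.tsv`).
#' @param sep field separator; default inferred from extension.
#' @export
write_profile_table <- function(dataset, path, sep = NULL) {
  stopifnot(inherits(dataset, "profile_dataset"))
  mat <- dataset$values
  out <- data.frame(inhibitor_id = rownames(mat), stringsAsFactors = FALSE)
  for (j in colnames(mat)) out[[j]] <- fmt_num(mat[, j])
  write_delim_table(out, path, sep)
  invisible(path)
}

#' Convert a dissociation constant to expected percent inhibition
#'
#' Uses the single-site Hill (Langmuir) relation at inhibitor concentration
#' c: \%inhibition = 100 / (1 + Kd / c). The default 500 nM corresponds to
#' profiling at 0.5 uM. The result is strictly decreasing in Kd and bounded
#' in (0, 100).
#'
#' @param kd_nM dissociation constant(s), nM, strictly positive.
#' @param concentration_nM assumed inhibitor concentration, nM (default 500).
#' @return percent inhibition in (0, 100), vectorized over `kd_nM`.
#' @examples
#' kd_to_percent_inhibition(500)   # 50
#' kd_to_percent_inhibition(4500)  # 10
#' @export
kd_to_percent_inhibition <- function(kd_nM, concentration_nM = 500) {
  if (any(!is.finite(kd_nM)) || any(kd_nM <= 0))
    stop("'kd_nM' must be finite and strictly positive")
  if (!is.numeric(concentration_nM) || length(concentration_nM) != 1 ||
      !is.finite(concentration_nM) || concentration_nM <= 0)
    stop("'concentration_nM' must be a single positive number")
  100 / (1 + kd_nM / concentration_nM)
}

#' Put a profiling dataset on the common inhibition-increasing scale
#'
#' Pearson correlation of fingerprints against profiles requires all
#' datasets oriented so that larger values mean more inhibition:
#' * percent inhibition: unchanged;
#' * percent remaining activity: `100 - value`;
#' * dissociation constants: converted via [kd_to_percent_inhibition()] at
#'   `concentration_nM`;
#' * thermal shift: unchanged (Pearson is location/scale invariant and a
#'   larger shift indicates stronger binding).
#'
#' The operation is idempotent: a dataset already on the inhibition scale
#' is returned untouched.
#'
#' @param dataset a [profile_dataset()].
#' @param concentration_nM concentration for the Kd conversion (default
#'   500 nM; the dataset's own `assay_concentration_nM` takes precedence if
#'   set).
#' @param sanity_band remaining-activity values outside this band trigger a
#'   warning but are retained unclipped (default `c(-20, 150)`).
#' @return the dataset with transformed values; the transform is recorded
#'   in `$provenance` and `$scale` is set to `"inhibition"`.
#' @export
to_correlation_scale <- function(dataset, concentration_nM = 500,
                                 sanity_band = c(-20, 150)) {
  stopifnot(inherits(dataset, "profile_dataset"))
  if (identical(dataset$scale, "inhibition")) return(dataset)
  kind <- dataset$assay_kind
  if (kind == "percent_remaining_activity") {
    v <- dataset$values
    bad <- sum(v[!is.na(v)] < sanity_band[1] | v[!is.na(v)] > sanity_band[2])
    if (bad > 0)
      warning(sprintf("%d remaining-activity values outside [%g, %g]; retained",
                      bad, sanity_band[1], sanity_band[2]))
    dataset$values <- 100 - v
    dataset$assay_kind <- "percent_inhibition"
    dataset$provenance <- c(dataset$provenance,
                            "remaining activity converted as 100 - value")
  } else if (kind == "dissociation_constant_nM") {
    conc <- dataset$assay_concentration_nM %||% concentration_nM
    v <- dataset$values
    v[!is.na(v)] <- kd_to_percent_inhibition(v[!is.na(v)], conc)
    dataset$values <- v
    dataset$assay_kind <- "percent_inhibition"
    dataset$provenance <- c(dataset$provenance,
                            sprintf("Kd converted to %%inhibition via Hill equation at %g nM",
                                    conc))
  }
  dataset$scale <- "inhibition"
  dataset
}

#' Remove mutant/engineered kinase constructs from a dataset
#'
#' Screens are matched against wild-type kinases only; engineered constructs
#' (gatekeeper mutants, fusion constructs) are excluded before correlation.
#'
#' @param dataset a [profile_dataset()].
#' @return the dataset with mutant entries removed; the number removed is
#'   recorded in `$provenance`.
#' @export
exclude_mutant_kinases <- function(dataset) {
  stopifnot(inherits(dataset, "profile_dataset"))
  mut <- dataset$kinases$is_mutant
  if (all(mut))
    stop("all kinase entries in '", dataset$name, "' are flagged mutant")
  if (any(mut)) {
    dataset$values <- dataset$values[, !mut, drop = FALSE]
    dataset$kinases <- dataset$kinases[!mut, , drop = FALSE]
    rownames(dataset$kinases) <- NULL
    dataset$provenance <- c(dataset$provenance,
                            sprintf("%d mutant kinase entries excluded",
                                    sum(mut)))
  }
  dataset
}

# Resolve a gene symbol through an alias map (named character vector,
# alias -> canonical), following chains and detecting cycles.
resolve_alias <- function(symbol, alias_map) {
  seen <- character(0)
  cur <- symbol
  while (cur %in% names(alias_map)) {
    if (cur %in% seen)
      stop("alias cycle detected involving: ",
           paste(c(seen, cur), collapse = " -> "))
    seen <- c(seen, cur)
    cur <- unname(alias_map[[cur]])
  }
  cur
}

#' Summarize kinome coverage across profiling datasets
#'
#' Counts the unique canonical gene symbols covered by each dataset and by
#' their union, after mutant exclusion and resolution of gene-symbol
#' aliases through a user-supplied alias table (no bundled annotation
#' database, no network lookups).
#'
#' @param datasets list of [profile_dataset()] objects.
#' @param alias_map named character vector mapping alias -> canonical
#'   symbol; chains are followed, cycles are an error.
#' @return an object of class `"coverage_summary"`: per-dataset entry and
#'   unique-gene counts, the pooled unique-gene count, and an
#'   alias-resolution report.
#' @export
kinome_coverage <- function(datasets, alias_map = NULL) {
  if (!length(datasets)) stop("at least one dataset is required")
  if (inherits(datasets, "profile_dataset")) datasets <- list(datasets)
  alias_map <- alias_map %||% character(0)
  per <- lapply(datasets, function(ds) {
    ds <- exclude_mutant_kinases(ds)
    syms <- ds$kinases$gene_symbol
    canon <- vapply(syms, resolve_alias, character(1), alias_map = alias_map)
    list(name = ds$name, n_entries = length(syms),
         genes = sort(unique(unname(canon))),
         n_resolved = sum(canon != syms))
  })
  pooled <- sort(unique(unlist(lapply(per, `[[`, "genes"))))
  structure(list(
    per_dataset = data.frame(
      dataset = vapply(per, `[[`, character(1), "name"),
      n_entries = vapply(per, `[[`, integer(1), "n_entries"),
      n_genes = vapply(per, function(p) length(p$genes), integer(1)),
      n_alias_resolved = vapply(per, `[[`, integer(1), "n_resolved"),
      stringsAsFactors = FALSE),
    pooled_genes = pooled,
    n_pooled = length(pooled)), class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat("Kinome coverage summary\n")
  print(x$per_dataset, row.names = FALSE)
  cat("pooled unique genes:", x$n_pooled, "\n")
  invisible(x)
}
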