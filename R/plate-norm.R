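#' Screen plate data
#'
#' A plate screen holds the raw well records of one screen: inhibitor wells
#' (typically duplicates), DMSO vehicle-control wells, and optional EDTA
#' stop-control wells, possibly spread over several physical plates. All
#' normalization is strictly per plate.
#'
#' @param wells data.frame with columns `plate_id`, `well_id`, `role`
#'   (one of `inhibitor`, `vehicle_control`, `edta_control`),
#'   `inhibitor_id` (NA for control roles) and `absorbance`.
#' @param screen_id screen label.
#' @param expected_replicates expected wells per inhibitor (default 2);
#'   deviations are reported as warnings, not errors.
#' @return an object of class `"plate_screen"`.
#' @export
plate_screen <- function(wells, screen_id = "screen", expected_replicates = 2) {
  need <- c("plate_id", "well_id", "role", "inhibitor_id", "absorbance")
  if (!all(need %in% names(wells)))
    stop("'wells' must have columns: ", paste(need, collapse = ", "))
  wells <- as.data.frame(wells)[need]
  wells$plate_id <- as.character(wells$plate_id)
  wells$well_id <- as.character(wells$well_id)
  wells$role <- as.character(wells$role)
  wells$inhibitor_id <- as.character(wells$inhibitor_id)
  ok_roles <- c("inhibitor", "vehicle_control", "edta_control")
  if (!all(wells$role %in% ok_roles))
    stop("well roles must be one of: ", paste(ok_roles, collapse = ", "))
  if (any(!is.finite(wells$absorbance)) || any(wells$absorbance < 0))
    stop("absorbance must be finite and non-negative")
  ctrl <- wells$role != "inhibitor"
  if (any(!is.na(wells$inhibitor_id[ctrl]) & nzchar(wells$inhibitor_id[ctrl])))
    stop("control wells must not carry an inhibitor_id")
  wells$inhibitor_id[ctrl] <- NA_character_
  if (any(is.na(wells$inhibitor_id[!ctrl])))
    stop("inhibitor wells must carry an inhibitor_id")
  ndmso <- tapply(wells$role == "vehicle_control", wells$plate_id, sum)
  if (any(ndmso < 2))
    stop("every plate needs >= 2 vehicle_control (DMSO) wells; short: ",
         paste(names(ndmso)[ndmso < 2], collapse = ", "))
  # each inhibitor must sit on exactly one plate
  pl <- tapply(wells$plate_id[!ctrl], wells$inhibitor_id[!ctrl],
               function(p) length(unique(p)))
  if (any(pl > 1))
    stop("inhibitor(s) present on more than one plate: ",
         paste(names(pl)[pl > 1], collapse = ", "))
  structure(list(screen_id = screen_id, wells = wells,
                 expected_replicates = expected_replicates),
            class = "plate_screen")
}

#' @export
print.plate_screen <- function(x, ...) {
  w <- x$wells
  cat("Plate screen:", x$screen_id, "\n")
  cat("  plates:    ", length(unique(w$plate_id)), "\n")
  cat("  inhibitors:", length(unique(w$inhibitor_id[w$role == "inhibitor"])),
      "\n")
  cat("  wells:     ", nrow(w),
      sprintf("(%d DMSO, %d EDTA)\n", sum(w$role == "vehicle_control"),
              sum(w$role == "edta_control")))
  invisible(x)
}

#' Read a plate table from a delimited file
#'
#' Expects columns `plate_id`, `well_id`, `role`, `inhibitor_id`,
#' `absorbance` with roles spelled exactly `inhibitor`, `vehicle_control`,
#' `edta_control`.
#'
#' @inheritParams plate_screen
#' @param path delimited file (`.csv` or `.tsv`).
#' @param sep field separator; default inferred from extension.
#' @return a [plate_screen()].
#' @export
read_plate_table <- function(path, screen_id = basename(path),
                             expected_replicates = 2, sep = NULL) {
  tab <- read_delim_table(path, sep)
  if ("inhibitor_id" %in% names(tab))
    tab$inhibitor_id[tab$inhibitor_id %in% c("", "NA")] <- NA
  plate_screen(tab, screen_id = screen_id,
               expected_replicates = expected_replicates)
}

#' Per-inhibitor standard scores for a plate screen
#'
#' For each plate, the standard score of an inhibitor is
#' `(mean absorbance over its replicate wells - mean DMSO absorbance) / sd
#' of DMSO absorbances` (sample sd, n-1). EDTA stop-control wells are
#' scored per well by the same formula so they can compete for the plate
#' minimum in [percent_inhibition()].
#'
#' @param screen a [plate_screen()].
#' @return data.frame with columns `plate_id`, `id`, `role`, `n_wells`,
#'   `mean_absorbance`, `standard_score`; per-plate DMSO statistics are
#'   attached as attribute `"plates"`.
#' @export
standard_scores <- function(screen) {
  stopifnot(inherits(screen, "plate_screen"))
  w <- screen$wells
  out <- list(); pstats <- list()
  for (p in unique(w$plate_id)) {
    pw <- w[w$plate_id == p, , drop = FALSE]
    dmso <- pw$absorbance[pw$role == "vehicle_control"]
    if (length(dmso) < 2)
      stop("plate ", p, ": need >= 2 DMSO wells to estimate sd")
    m <- mean(dmso); s <- stats::sd(dmso)
    if (!is.finite(s) || s <= 0)
      stop("plate ", p, ": DMSO standard deviation is zero; ",
           "standard scores are undefined")
    inh <- pw[pw$role == "inhibitor", , drop = FALSE]
    if (nrow(inh)) {
      sp <- split(inh$absorbance, inh$inhibitor_id)
      nrep <- lengths(sp)
      if (any(nrep != screen$expected_replicates))
        warning(sprintf("plate %s: %d inhibitor(s) deviate from %d replicates",
                        p, sum(nrep != screen$expected_replicates),
                        screen$expected_replicates))
      mu <- vapply(sp, mean, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        plate_id = p, id = names(sp), role = "inhibitor",
        n_wells = as.integer(nrep), mean_absorbance = unname(mu),
        standard_score = unname((mu - m) / s), stringsAsFactors = FALSE)
    }
    edta <- pw[pw$role == "edta_control", , drop = FALSE]
    if (nrow(edta)) {
      out[[length(out) + 1L]] <- data.frame(
        plate_id = p, id = edta$well_id, role = "edta_control",
        n_wells = 1L, mean_absorbance = edta$absorbance,
        standard_score = (edta$absorbance - m) / s, stringsAsFactors = FALSE)
    }
    pstats[[length(pstats) + 1L]] <- data.frame(
      plate_id = p, dmso_mean = m, dmso_sd = s, dmso_n = length(dmso),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "plates") <- do.call(rbind, pstats)
  attr(res, "screen_id") <- screen$screen_id
  res
}

#' Percent inhibition fingerprint of a plate screen
#'
#' Converts standard scores into the screen's inhibition fingerprint:
#' `%inhibition = 100 * s / min(s)` per plate, where the minimum is taken
#' over all inhibitor scores and all EDTA stop-control scores on that
#' plate. The most inhibitory well therefore defines 100% inhibition; a
#' vehicle-equivalent well scores 0 and an activating compound scores
#' negative. A plate whose minimum score is not negative carries no
#' inhibitory signal and cannot be normalized.
#'
#' @param scores output of [standard_scores()].
#' @param screen the [plate_screen()] the scores came from.
#' @return an object of class `"kipik_fingerprint"`: a data.frame with
#'   columns `inhibitor_id`, `plate_id`, `standard_score`,
#'   `percent_inhibition`, with per-plate control summaries in attribute
#'   `"plates"` and EDTA scores in attribute `"edta"`.
#' @export
percent_inhibition <- function(scores, screen) {
  stopifnot(inherits(screen, "plate_screen"))
  plates <- attr(scores, "plates")
  rows <- list()
  for (i in seq_len(nrow(plates))) {
    p <- plates$plate_id[i]
    sc <- scores[scores$plate_id == p, , drop = FALSE]
    if (!nrow(sc)) next
    jmin <- which.min(sc$standard_score)
    smin <- sc$standard_score[jmin]
    if (!(smin < 0))
      stop("plate ", p, ": no inhibitory signal (minimum standard score ",
           format(smin), " >= 0); a plate with no inhibition or EDTA ",
           "control below the DMSO level cannot be normalized")
    plates$min_standard_score[i] <- smin
    plates$min_source[i] <-
      if (sc$role[jmin] == "edta_control") "edta" else "compound"
    inh <- sc[sc$role == "inhibitor", , drop = FALSE]
    inh$percent_inhibition <- 100 * inh$standard_score / smin
    rows[[length(rows) + 1L]] <- inh
  }
  res <- do.call(rbind, rows)
  fp <- data.frame(inhibitor_id = res$id, plate_id = res$plate_id,
                   standard_score = res$standard_score,
                   percent_inhibition = res$percent_inhibition,
                   stringsAsFactors = FALSE)
  rownames(fp) <- NULL
  fp <- fp[order(fp$plate_id, fp$inhibitor_id), , drop = FALSE]
  rownames(fp) <- NULL
  structure(fp,
            screen_id = screen$screen_id,
            plates = plates,
            edta = scores[scores$role == "edta_control", , drop = FALSE],
            class = c("kipik_fingerprint", "data.frame"))
}

#' Assemble the inhibition fingerprint of a screen
#'
#' Runs [standard_scores()] and [percent_inhibition()] over one or more
#' plate screens sharing a screen id and concatenates the per-plate
#' results. Inhibitor ids must be disjoint across the inputs; each
#' inhibitor is normalized against its own plate's controls.
#'
#' @param plates a [plate_screen()] or list of them (same `screen_id`).
#' @return a `"kipik_fingerprint"` (see [percent_inhibition()]).
#' @examples
#' scr <- simulate_screen_plates(simulate_profile_dataset(n_kinases = 10,
#'   n_inhibitors = 20, seed = 1), contributing = c(K01 = 1), seed = 2)
#' fp <- assemble_fingerprint(scr)
#' head(fp)
#' @export
assemble_fingerprint <- function(plates) {
  if (inherits(plates, "plate_screen")) plates <- list(plates)
  ids <- unique(vapply(plates, `[[`, character(1), "screen_id"))
  if (length(ids) != 1)
    stop("all plate screens must share one screen_id; got: ",
         paste(ids, collapse = ", "))
  parts <- lapply(plates, function(p) percent_inhibition(standard_scores(p), p))
  all_ids <- unlist(lapply(parts, `[[`, "inhibitor_id"))
  if (anyDuplicated(all_ids))
    stop("inhibitor(s) appear in more than one plate screen: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  fp <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(fp) <- NULL
  structure(fp,
            screen_id = ids,
            plates = do.call(rbind, lapply(parts, attr, "plates")),
            edta = do.call(rbind, lapply(parts, attr, "edta")),
            class = c("kipik_fingerprint", "data.frame"))
}

#' @export
print.kipik_fingerprint <- function(x, ...) {
  cat("Inhibition fingerprint for screen:", attr(x, "screen_id"), "\n")
  pl <- attr(x, "plates")
  cat(sprintf("  %d inhibitors on %d plate(s)\n", nrow(x), nrow(pl)))
  for (i in seq_len(nrow(pl)))
    cat(sprintf("  plate %s: DMSO mean %.4g (sd %.3g, n=%d), min score %.3g from %s\n",
                pl$plate_id[i], pl$dmso_mean[i], pl$dmso_sd[i], pl$dmso_n[i],
                pl$min_standard_score[i], pl$min_source[i]))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ... (", nrow(x) - 5, " more rows)\n", sep = "")
  invisible(x)
}

#' Write / read a fingerprint as a delimited file
#'
#' Columns `inhibitor_id`, `plate_id`, `standard_score`,
#' `percent_inhibition`, with a mandatory header row. The reader restores a
#' fingerprint usable for ranking; per-plate control summaries are not
#' stored in the file.
#'
#' @param fp a `"kipik_fingerprint"`.
#' @param path output path.
#' @param sep field separator; default inferred from extension.
#' @export
write_fingerprint <- function(fp, path, sep = NULL) {
  stopifnot(inherits(fp, "kipik_fingerprint"))
  out <- as.data.frame(fp)
  out$standard_score <- fmt_num(out$standard_score)
  out$percent_inhibition <- fmt_num(out$percent_inhibition)
  write_delim_table(out, path, sep)
  invisible(path)
}

#' @rdname write_fingerprint
#' @param screen_id screen label for the restored fingerprint.
#' @export
read_fingerprint <- function(path, screen_id = basename(path), sep = NULL) {
  tab <- read_delim_table(path, sep)
  need <- c("inhibitor_id", "plate_id", "standard_score", "percent_inhibition")
  if (!all(need %in% names(tab)))
    stop("fingerprint file needs columns: ", paste(need, collapse = ", "))
  structure(tab[need], screen_id = screen_id, plates = NULL, edta = NULL,
            class = c("kipik_fingerprint", "data.frame"))
}

# Named %inhibition vector of a fingerprint.
fp_vector <- function(fp) {
  stats::setNames(fp$percent_inhibition, fp$inhibitor_id)
}
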