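#' Correlation distance between kinase inhibition fingerprints
#'
#' Builds the symmetric distance matrix d = 1 - Pearson correlation over
#' pairwise-complete inhibitors, between every pair of kinase profiles in
#' a dataset (optionally including the screen fingerprint as a
#' pseudo-kinase leaf). Distances lie in [0, 2]: 0 for identical profiles,
#' 2 for perfect anti-correlation.
#'
#' @inheritParams correlate_fingerprint
#' @param include_query optional `"kipik_fingerprint"` added as a leaf
#'   named after its screen id.
#' @return a symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(dataset, include_query = NULL,
                                 min_overlap = 10) {
  stopifnot(inherits(dataset, "profile_dataset"))
  mat <- dataset$values
  if (!is.null(include_query)) {
    stopifnot(inherits(include_query, "kipik_fingerprint"))
    v <- fp_vector(include_query)
    q <- rep(NA_real_, nrow(mat))
    names(q) <- rownames(mat)
    shared <- intersect(names(v), rownames(mat))
    q[shared] <- v[shared]
    qname <- attr(include_query, "screen_id") %||% "query"
    mat <- cbind(mat, q)
    colnames(mat)[ncol(mat)] <- qname
  }
  if (ncol(mat) < 2) stop("need >= 2 entities to compute distances")
  obs <- !is.na(mat)
  overlap <- crossprod(obs)
  suppressWarnings(rho <- stats::cor(mat, use = "pairwise.complete.obs"))
  bad <- (overlap < min_overlap) | !is.finite(rho)
  diag(bad) <- FALSE
  if (any(bad)) {
    idx <- which(bad & upper.tri(bad), arr.ind = TRUE)
    pairs <- apply(idx, 1, function(ij)
      paste0(colnames(mat)[ij[1]], " ~ ", colnames(mat)[ij[2]]))
    stop("entity pair(s) with insufficient overlap (< ", min_overlap,
         ") or zero variance: ", paste(utils::head(pairs, 10), collapse = "; "),
         if (length(pairs) > 10) sprintf(" ... and %d more", length(pairs) - 10)
         else "")
  }
  d <- 1 - rho
  diag(d) <- 0
  # enforce exact symmetry against floating-point asymmetries
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

#' Ward.D2 hierarchical clustering of a distance matrix
#'
#' Agglomerates under the Ward.D2 criterion: the Lance-Williams recurrence
#' with Ward coefficients applied to squared dissimilarities, heights
#' reported back on the distance scale (the Murtagh-Legendre definition,
#' as implemented by `hclust(method = "ward.D2")`). Merge heights are
#' guaranteed monotone non-decreasing.
#'
#' @param distances symmetric numeric matrix with zero diagonal and
#'   non-negative off-diagonal entries (e.g. from
#'   [correlation_distance()]), or a `dist` object.
#' @return an object of class `"kipik_tree"` wrapping the `hclust` merge
#'   tree; support values are absent until [bootstrap_support()] is run.
#' @export
ward_linkage <- function(distances) {
  if (inherits(distances, "dist")) distances <- as.matrix(distances)
  if (!is.matrix(distances) || nrow(distances) != ncol(distances))
    stop("'distances' must be a square matrix or dist object")
  if (any(abs(distances - t(distances)) > 1e-8))
    stop("'distances' must be symmetric")
  if (any(distances[row(distances) != col(distances)] < 0))
    stop("'distances' must have non-negative off-diagonal entries")
  hc <- stats::hclust(stats::as.dist(distances), method = "ward.D2")
  structure(list(hclust = hc, labels = hc$labels,
                 support = NULL, n_boot = NULL, seed = NULL),
            class = "kipik_tree")
}

# Leaf sets of every internal node of an hclust tree, in merge order.
# Returned as sorted character keys for clade identity (unordered leaf
# set, heights ignored).
clade_keys <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    m <- hc$merge[i, ]
    left <- if (m[1] < 0) hc$labels[-m[1]] else sets[[m[1]]]
    right <- if (m[2] < 0) hc$labels[-m[2]] else sets[[m[2]]]
    sets[[i]] <- c(left, right)
  }
  lapply(sets, sort)
}

#' Bootstrap support for inhibition-fingerprint clusters
#'
#' Resamples inhibitors (the observations underlying each correlation)
#' with replacement, recomputes the correlation distance and Ward.D2 tree,
#' and reports for every internal node of the full-data tree the fraction
#' of bootstrap trees containing that exact leaf set (Bootstrap
#' Probability, BP). With `multiscale = TRUE`, the Approximately Unbiased
#' (AU) p-value is additionally computed by multiscale bootstrap: the
#' resample size is varied over scale factors 0.5 to 1.4 in steps of 0.1,
#' the per-scale BP values are probit-transformed and a two-parameter
#' curvature model is fitted by weighted least squares, from which
#' AU = 1 - pnorm(d - c).
#'
#' Bootstrap replicates in which some pair fails the overlap/variance
#' filter are skipped and do not count toward the denominator.
#'
#' @inheritParams correlation_distance
#' @param n_boot bootstrap iterations per scale (default 10000).
#' @param seed integer seed.
#' @param multiscale compute AU values (heavier; default `FALSE`).
#' @return a `"kipik_tree"` whose `support` element is a data.frame with
#'   one row per internal node: `node`, `height`, `leaves`, `bp`, `au`.
#' @export
bootstrap_support <- function(dataset, n_boot = 10000, seed,
                              multiscale = FALSE, include_query = NULL,
                              min_overlap = 3) {
  stopifnot(inherits(dataset, "profile_dataset"))
  d0 <- correlation_distance(dataset, include_query, min_overlap)
  if (nrow(d0) < 2) stop("need >= 2 entities")
  tree <- ward_linkage(d0)
  hc <- tree$hclust
  n_inh <- nrow(dataset$values)
  if (n_inh < 3) stop("need >= 3 inhibitors to bootstrap")
  if (n_boot < 100) warning("n_boot < 100 gives very coarse support values")
  keys <- vapply(clade_keys(hc), paste, character(1), collapse = "\r")
  scales <- if (multiscale) seq(0.5, 1.4, by = 0.1) else 1
  # reconstruct the (possibly query-augmented) value matrix once
  mat <- dataset$values
  if (!is.null(include_query)) {
    v <- fp_vector(include_query)
    q <- rep(NA_real_, nrow(mat)); names(q) <- rownames(mat)
    shared <- intersect(names(v), rownames(mat)); q[shared] <- v[shared]
    mat <- cbind(mat, q)
    colnames(mat)[ncol(mat)] <- attr(include_query, "screen_id") %||% "query"
  }
  bp_scale <- matrix(NA_real_, length(keys), length(scales))
  eff <- integer(length(scales))
  with_seed(seed, {
    for (si in seq_along(scales)) {
      nb <- max(3L, as.integer(round(scales[si] * n_inh)))
      counts <- integer(length(keys))
      ok <- 0L
      for (b in seq_len(n_boot)) {
        rows <- sample.int(n_inh, nb, replace = TRUE)
        sub <- mat[rows, , drop = FALSE]
        suppressWarnings(rho <- stats::cor(sub,
                                           use = "pairwise.complete.obs"))
        if (any(!is.finite(rho))) next
        db <- 1 - rho; diag(db) <- 0
        db[lower.tri(db)] <- t(db)[lower.tri(db)]
        hb <- stats::hclust(stats::as.dist(db), method = "ward.D2")
        bkeys <- vapply(clade_keys(hb), paste, character(1), collapse = "\r")
        counts <- counts + (keys %in% bkeys)
        ok <- ok + 1L
      }
      if (ok == 0L)
        stop("every bootstrap replicate failed the variance filter at scale ",
             scales[si])
      bp_scale[, si] <- counts / ok
      eff[si] <- ok
    }
  })
  i1 <- which.min(abs(scales - 1))
  bp <- bp_scale[, i1]
  au <- rep(NA_real_, length(keys))
  if (multiscale) {
    sigma <- sqrt(pmax(3L, round(scales * n_inh)) / n_inh)
    for (j in seq_along(keys))
      au[j] <- au_fit(bp_scale[j, ], sigma, eff)
  }
  support <- data.frame(node = seq_along(keys),
                        height = hc$height,
                        leaves = vapply(clade_keys(hc), paste, character(1),
                                        collapse = ","),
                        bp = bp, au = au, stringsAsFactors = FALSE)
  tree$support <- support
  tree$n_boot <- n_boot
  tree$seed <- seed
  tree$multiscale <- multiscale
  tree
}

# Multiscale-bootstrap AU for one clade: weighted least squares fit of
# qnorm(1 - BP) = d * sigma + c / sigma over usable scales; AU is
# 1 - pnorm(d - c). Returns NA when fewer than 2 informative scales.
au_fit <- function(bp, sigma, n_eff) {
  eps <- 0.5 / n_eff
  usable <- bp > eps & bp < 1 - eps
  if (sum(usable) < 2) {
    # degenerate clade: BP pinned at 0 or 1 across scales
    return(if (mean(bp) > 0.5) 1 else 0)
  }
  b <- pmin(pmax(bp[usable], eps[usable]), 1 - eps[usable])
  s <- sigma[usable]
  psi <- stats::qnorm(1 - b)
  w <- n_eff[usable] * stats::dnorm(psi)^2 / (b * (1 - b))
  X <- cbind(s, 1 / s)
  fit <- tryCatch(stats::lm.wfit(X, psi, w), error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  dd <- fit$coefficients[1]; cc <- fit$coefficients[2]
  if (!all(is.finite(c(dd, cc)))) return(NA_real_)
  unname(1 - stats::pnorm(dd - cc))
}

#' @export
print.kipik_tree <- function(x, ...) {
  n <- length(x$labels)
  cat("Inhibition-fingerprint cluster tree (Ward.D2, 1 - Pearson distance)\n")
  cat("  leaves:", n, " internal nodes:", n - 1, "\n")
  if (!is.null(x$support)) {
    cat(sprintf("  bootstrap: %d iterations (seed %s)%s\n", x$n_boot,
                format(x$seed),
                if (isTRUE(x$multiscale)) ", multiscale AU" else ""))
    top <- x$support[order(-x$support$height), , drop = FALSE]
    top <- utils::head(top, 5)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    node %d (h=%.3f): BP=%.2f%s\n", top$node[i],
                  top$height[i], top$bp[i],
                  if (is.finite(top$au[i])) sprintf(" AU=%.2f", top$au[i])
                  else ""))
  }
  invisible(x)
}

#' @export
plot.kipik_tree <- function(x, ...) {
  graphics::plot(stats::as.dendrogram(x$hclust),
                 main = "Inhibition fingerprint clustering (Ward.D2)",
                 ylab = "1 - Pearson correlation", ...)
  invisible(x)
}

#' Export a cluster tree as Newick text
#'
#' Branch lengths derive from the Ward merge heights (ultrametric, leaf
#' depth = height/2). When bootstrap support is present, internal nodes
#' are labelled `AU/BP` in rounded percent (BP alone when AU was not
#' computed). Leaf names containing Newick metacharacters are
#' single-quoted.
#'
#' @param tree a `"kipik_tree"`.
#' @param path optional output path (`.nwk`); if `NULL` the Newick string
#'   is returned.
#' @return the Newick string, invisibly when written to `path`.
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "kipik_tree"))
  hc <- tree$hclust
  phy <- ape::as.phylo(hc)
  # as.phylo.hclust sanitizes labels; keep the originals (same leaf order)
  orig_tips <- hc$labels %||% as.character(seq_along(phy$tip.label))
  # labels with Newick metacharacters must be single-quoted; write.tree
  # sanitizes such labels, so stand in a placeholder and substitute the
  # quoted original into the serialized string afterwards
  needs_quote <- grepl("[][,;:()' ]", orig_tips)
  placeholders <- sprintf("xQUOTEDTIPx%03d", seq_along(orig_tips))
  phy$tip.label[needs_quote] <- placeholders[needs_quote]
  phy$tip.label[!needs_quote] <- orig_tips[!needs_quote]
  if (!is.null(tree$support)) {
    # map hclust internal nodes to phylo node numbers via clade leaf sets
    keys <- vapply(clade_keys(hc), paste, character(1), collapse = "\r")
    labs <- character(phy$Nnode)
    phy_sets <- phylo_clades_raw(phy, orig_tips)
    for (nd in seq_len(phy$Nnode)) {
      key <- paste(sort(phy_sets[[nd]]), collapse = "\r")
      j <- match(key, keys)
      if (!is.na(j)) {
        bp <- round(100 * tree$support$bp[j])
        au <- tree$support$au[j]
        labs[nd] <- if (is.finite(au))
          sprintf("%d/%d", round(100 * au), bp) else sprintf("%d", bp)
      }
    }
    phy$node.label <- labs
  }
  txt <- ape::write.tree(phy)
  for (i in which(needs_quote))
    txt <- sub(placeholders[i],
               paste0("'", gsub("'", "''", orig_tips[i]), "'"),
               txt, fixed = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

# Leaf-label sets below each internal node of a phylo object, indexed
# 1..Nnode (node number minus Ntip). Uses the original (unquoted) labels.
phylo_clades_raw <- function(phy, labels) {
  nt <- length(phy$tip.label)
  sets <- vector("list", phy$Nnode)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  rec <- function(node) {
    if (node <= nt) return(labels[node])
    out <- unlist(lapply(kids[[as.character(node)]], rec))
    sets[[node - nt]] <<- out
    out
  }
  rec(nt + 1L)
  sets
}

#' Write a clade-support table to a delimited file
#'
#' Columns `node`, `height`, `leaves` (comma-joined leaf set), `bp`, `au`.
#'
#' @param tree a `"kipik_tree"` with bootstrap support.
#' @param path output path.
#' @param sep field separator; default inferred from extension.
#' @export
write_support_table <- function(tree, path, sep = NULL) {
  stopifnot(inherits(tree, "kipik_tree"))
  if (is.null(tree$support)) stop("tree has no bootstrap support")
  write_delim_table(tree$support, path, sep)
  invisible(path)
}
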