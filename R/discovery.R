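# Tentative-signal calling and prioritization: Benjamini-Hochberg FDR
# adjustment per trait x mode family, variance-explained ranking within
# lifestyle category, the cross-trait (>= min_traits) prioritization rule
# restricted to modifiable exposures, and correlation clustering of the
# prioritized set into intervention target groups.

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values of the step-up false-discovery-rate procedure:
#' with order statistics `p_(1) <= ... <= p_(m)`, the adjusted value of
#' `p_(i)` is `min over j >= i of m * p_(j) / j`, capped at 1. Missing
#' entries are excluded from `m` and stay missing.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (m) {
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(m * p[o] / seq.int(m, 1)))[order(o)]
    out[ok] <- adj
  }
  out
}

#' Call FDR-corrected tentative signals
#'
#' Adjusts the screen's p-values within each trait x mode family (all
#' exposures tested against one trait in one analysis mode form one family)
#' and flags associations with adjusted p strictly below `alpha` as
#' tentative signals.
#'
#' @param results An `exposcan_screen` data frame (one or both modes).
#' @param alpha Tentative-signal significance level on the FDR scale.
#' @return The results augmented with `p_fdr`, `family_size` and logical
#'   `tentative`; class `exposcan_signals`.
#' @export
call_signals <- function(results, alpha = 0.05) {
  results <- as.data.frame(results)
  if (!nrow(results)) {
    results$p_fdr <- numeric(0)
    results$family_size <- integer(0)
    results$tentative <- logical(0)
    class(results) <- c("exposcan_signals", "data.frame")
    return(results)
  }
  fam <- interaction(results$trait, results$mode, drop = TRUE)
  results$p_fdr <- NA_real_
  results$family_size <- NA_integer_
  for (f in levels(fam)) {
    i <- which(fam == f)
    results$p_fdr[i] <- bh_adjust(results$p[i])
    results$family_size[i] <- sum(!is.na(results$p[i]))
  }
  results$tentative <- !is.na(results$p_fdr) & results$p_fdr < alpha
  attr(results, "alpha") <- alpha
  class(results) <- c("exposcan_signals", "data.frame")
  results
}

#' Rank tentative signals within trait and category
#'
#' Within each mode x trait x lifestyle category, collapses dummy-indicator
#' rows to their parent variable (keeping the maximum variance explained and
#' the smaller raw p), sorts tentative signals by variance explained
#' (descending; ties broken by smaller raw p, then name) and keeps the top
#' `top_k`.
#'
#' @param signals An `exposcan_signals` table.
#' @param top_k Variables retained per category per trait.
#' @return Data frame of top sets: mode, trait, category, variable,
#'   `var_explained`, `p`, `rank`.
#' @export
rank_and_select <- function(signals, top_k = 5L) {
  sig <- as.data.frame(signals)[which(signals$tentative), , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(mode = character(0), trait = character(0),
                      category = character(0), variable = character(0),
                      var_explained = numeric(0), p = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  key <- paste(sig$mode, sig$trait, sig$parent_variable, sep = "\r")
  collapsed <- do.call(rbind, lapply(split(sig, key), function(d) {
    data.frame(mode = d$mode[1], trait = d$trait[1],
               category = d$category[1], variable = d$parent_variable[1],
               var_explained = max(d$var_explained, na.rm = TRUE),
               p = min(d$p, na.rm = TRUE), stringsAsFactors = FALSE)
  }))
  fam <- paste(collapsed$mode, collapsed$trait, collapsed$category,
               sep = "\r")
  out <- do.call(rbind, lapply(split(collapsed, fam), function(d) {
    d <- d[order(-d$var_explained, d$p, d$variable), , drop = FALSE]
    d <- utils::head(d, top_k)
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(out) <- NULL
  out
}

#' Prioritize exposures consistent across traits
#'
#' A variable is prioritized when it appears in the top-ranked sets of at
#' least `min_traits` distinct traits and is flagged modifiable in the
#' catalog; non-modifiable candidates are retained in the report with their
#' exclusion reason.
#'
#' @param top_sets Output of [rank_and_select()].
#' @param min_traits Minimum number of distinct traits (the "majority"
#'   rule: at least 5 of 9).
#' @param catalog Exposure catalog with the `modifiable` flag.
#' @return List of class `exposcan_priority`: `prioritized` (data frame),
#'   `candidates` (including excluded, with reasons), `top_sets`,
#'   `min_traits`.
#' @export
prioritize <- function(top_sets, min_traits = 5L, catalog) {
  check_cols(catalog, c("exposure", "modifiable"), "catalog column")
  if (!nrow(top_sets)) {
    empty <- data.frame(mode = character(0), variable = character(0),
                        category = character(0), n_traits = integer(0),
                        modifiable = logical(0), reason = character(0),
                        stringsAsFactors = FALSE)
    return(structure(list(prioritized = empty, candidates = empty,
                          top_sets = top_sets, min_traits = min_traits),
                     class = "exposcan_priority"))
  }
  key <- paste(top_sets$mode, top_sets$variable, sep = "\r")
  cand <- do.call(rbind, lapply(split(top_sets, key), function(d) {
    data.frame(mode = d$mode[1], variable = d$variable[1],
               category = d$category[1],
               n_traits = length(unique(d$trait)),
               stringsAsFactors = FALSE)
  }))
  cand <- cand[cand$n_traits >= min_traits, , drop = FALSE]
  cand$modifiable <- catalog$modifiable[match(cand$variable,
                                              catalog$exposure)]
  cand$modifiable[is.na(cand$modifiable)] <- FALSE
  cand$reason <- ifelse(cand$modifiable, "", "non-modifiable")
  cand <- cand[order(cand$mode, -cand$n_traits, cand$variable), ,
               drop = FALSE]
  rownames(cand) <- NULL
  structure(list(prioritized = cand[cand$modifiable, , drop = FALSE],
                 candidates = cand, top_sets = top_sets,
                 min_traits = min_traits),
            class = "exposcan_priority")
}

#' @export
print.exposcan_priority <- function(x, ...) {
  cat(sprintf("Prioritized modifiable exposures (top-ranked in >= %d traits):\n",
              x$min_traits))
  if (!nrow(x$prioritized)) cat("  (none)\n")
  else print(x$prioritized[, c("mode", "variable", "category", "n_traits")],
             row.names = FALSE)
  excl <- x$candidates[!x$candidates$modifiable, , drop = FALSE]
  if (nrow(excl))
    cat(sprintf("Excluded as non-modifiable: %s\n",
                paste(excl$variable, collapse = ", ")))
  invisible(x)
}

#' Pairwise correlation matrix with missing-pair mask
#'
#' Pearson correlations on pairwise-complete observations; pairs with fewer
#' than 3 complete observations or zero variance are masked missing
#' (`NA`). Diagonal 1, symmetric.
#'
#' @param clean Harmonized cohort table.
#' @param variables Column names to correlate (>= 2).
#' @return Correlation matrix with attribute `n_pairs` (complete-pair
#'   counts).
#' @export
correlation_matrix <- function(clean, variables) {
  if (length(variables) < 2)
    stop("correlation_matrix needs at least 2 variables", call. = FALSE)
  check_cols(clean, variables)
  X <- as.matrix(clean[, variables, drop = FALSE])
  n_pairs <- crossprod(!is.na(X))
  R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  R[n_pairs < 3] <- NA
  diag(R) <- 1
  attr(R, "n_pairs") <- n_pairs
  R
}

#' Hierarchical clustering of exposures on correlation distance
#'
#' Agglomerative clustering with distance `1 - r` (signed correlation) and
#' average linkage; masked pairs are imputed with the mean distance of the
#' unmasked off-diagonal pairs. Returns the merge sequence, heights, leaf
#' order and, when `k` or `h` is given, flat cluster assignments.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param k Optional number of flat clusters.
#' @param h Optional cut height.
#' @param method Linkage passed to [stats::hclust()].
#' @return List of class `exposcan_dendro`: `hclust`, `merge`, `heights`,
#'   `order`, `labels`, `clusters` (or `NULL`).
#' @export
hcluster <- function(corr, k = NULL, h = NULL, method = "average") {
  if (nrow(corr) < 2)
    stop("hcluster needs at least 2 variables", call. = FALSE)
  d <- 1 - corr
  off <- d[upper.tri(d)]
  if (all(is.na(off)))
    stop("hcluster needs at least one computable pair", call. = FALSE)
  d[is.na(d)] <- mean(off, na.rm = TRUE)
  hc <- stats::hclust(stats::as.dist(d), method = method)
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k)
  else if (!is.null(h)) stats::cutree(hc, h = h)
  structure(list(hclust = hc, merge = hc$merge, heights = hc$height,
                 order = hc$order, labels = hc$labels, clusters = clusters),
            class = "exposcan_dendro")
}

#' Export a dendrogram as Newick text
#'
#' @param dendro An `exposcan_dendro` from [hcluster()].
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(dendro, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("dendrogram_newick requires the 'ape' package", call. = FALSE)
  phy <- ape::as.phylo(dendro$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
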