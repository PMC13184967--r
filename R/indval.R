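#' Indicator species analysis (IndVal)
#'
#' Classic Dufrene-Legendre indicator values on the 0-1 scale. For taxon i
#' and group g, specificity `A = mean relative abundance in g / sum of mean
#' relative abundances over groups` and fidelity `B = fraction of samples of
#' g where the taxon is present`; `IndVal = A * B`. Each taxon is reported
#' for its best (argmax) group; significance comes from permuting group
#' labels and comparing the permuted maximum IndVal with the observed one,
#' `p = (1 + #{perm >= obs}) / (1 + n_perm)`. Benjamini-Hochberg q-values
#' are reported alongside (no correction is applied to the default filter).
#'
#' @param cm a [community_matrix()].
#' @param groups group labels, one per sample (default: the metadata
#'   treatment column).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param all_groups if `TRUE`, return one row per taxon x group rather than
#'   the best group only.
#' @return Data frame: `taxon`, `group`, `A`, `B`, `indval`, `p_value`,
#'   `q_value`. Taxa absent everywhere get `indval = 0`, `p = 1`.
#' @export
indval <- function(cm, groups = NULL, n_perm = 999, seed = 1,
                   all_groups = FALSE) {
  stopifnot(inherits(cm, "community_matrix"))
  if (is.null(groups)) groups <- cm$metadata$treatment
  groups <- factor(groups)
  if (length(groups) != ncol(cm$counts))
    stop("groups length does not match the samples")
  if (nlevels(groups) < 2) stop("need at least two groups")
  rel <- tss_normalize(cm)
  pres <- cm$counts > 0

  iv_parts <- function(g) {
    gm <- vapply(levels(g), function(l)
      rowMeans(rel[, g == l, drop = FALSE]), numeric(nrow(rel)))
    tot <- rowSums(gm)
    A <- gm / ifelse(tot > 0, tot, 1)
    B <- vapply(levels(g), function(l)
      rowMeans(pres[, g == l, drop = FALSE]), numeric(nrow(rel)))
    A * B
  }
  iv_obs <- iv_parts(groups)
  obs_max <- apply(iv_obs, 1, max)

  set.seed(derive_seed(seed, "indval"))
  exceed <- numeric(nrow(rel))
  for (k in seq_len(n_perm)) {
    pm <- apply(iv_parts(groups[sample.int(length(groups))]), 1, max)
    exceed <- exceed + (pm >= obs_max)
  }
  p <- (1 + exceed) / (1 + n_perm)
  absent <- rowSums(cm$counts) == 0
  p[absent] <- 1

  gm <- vapply(levels(groups), function(l)
    rowMeans(rel[, groups == l, drop = FALSE]), numeric(nrow(rel)))
  tot <- rowSums(gm)
  A <- gm / ifelse(tot > 0, tot, 1)
  B <- vapply(levels(groups), function(l)
    rowMeans(pres[, groups == l, drop = FALSE]), numeric(nrow(rel)))

  if (all_groups) {
    out <- do.call(rbind, lapply(seq_along(levels(groups)), function(j)
      data.frame(taxon = taxa_ids(cm), group = levels(groups)[j],
                 A = A[, j], B = B[, j], indval = iv_obs[, j],
                 p_value = p, row.names = NULL)))
  } else {
    best <- max.col(iv_obs, ties.method = "first")
    out <- data.frame(taxon = taxa_ids(cm), group = levels(groups)[best],
                      A = A[cbind(seq_len(nrow(A)), best)],
                      B = B[cbind(seq_len(nrow(B)), best)],
                      indval = obs_max, p_value = p, row.names = NULL)
  }
  out$indval[absent[match(out$taxon, taxa_ids(cm))]] <- 0
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}

#' Filter indicator results to significant indicators
#'
#' Keeps taxa with `indval` strictly above `indval_min` and permutation p
#' strictly below `alpha` (both conditions required).
#'
#' @param results output of [indval()].
#' @param indval_min IndVal threshold (default 0.5).
#' @param alpha p-value threshold (default 0.05).
#' @return The filtered rows of `results`.
#' @export
significant_indicators <- function(results, indval_min = 0.5, alpha = 0.05) {
  results[results$indval > indval_min & results$p_value < alpha, ,
          drop = FALSE]
}
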