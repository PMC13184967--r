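#' Patristic distance matrix from a phylogeny
#'
#' Tip-to-tip distances summed along branch lengths, restricted and ordered
#' to a requested taxon set.
#'
#' @param tree an `ape::phylo` or a newick string.
#' @param taxa character vector of tip labels to keep (default: all tips).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = `taxa`.
#' @export
#' @examples
#' patristic_matrix("((A:1,B:1):1,C:2);")
patristic_matrix <- function(tree, taxa = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(taxa)) taxa <- tree$tip.label
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa missing from the tree: ", paste(missing, collapse = ", "))
  d <- ape::cophenetic.phylo(tree)[taxa, taxa, drop = FALSE]
  diag(d) <- 0
  d
}

#' Beta mean nearest taxon distance between two communities
#'
#' Abundance-weighted mean phylogenetic distance from each taxon present in
#' one community to its nearest relative present in the other, averaged over
#' both directions. Taxa shared by both communities contribute distance zero
#' (conspecifics included, the standard `comdistnt` convention).
#'
#' @param rel_a,rel_b relative-abundance vectors aligned to the rows of `pd`
#'   (each sums to 1 over its present taxa).
#' @param pd patristic distance matrix from [patristic_matrix()].
#' @return The betaMNTD statistic (non-negative real).
#' @export
beta_mntd <- function(rel_a, rel_b, pd) {
  stopifnot(length(rel_a) == nrow(pd), length(rel_b) == nrow(pd))
  if (sum(rel_a) == 0 || sum(rel_b) == 0) stop("empty community")
  rel <- cbind(a = rel_a, b = rel_b)
  pairs <- matrix(c(0L, 1L), 1, 2)
  cpp_bmntd_pairs(rel, pd, pairs, seq_len(nrow(pd)) - 1L)[1]
}

# Shared driver: betaMNTD observed + taxa-shuffle null for a pair list.
# pairs: 2-column integer matrix of sample indices into cm.
bnti_pairs <- function(rel, pd, pairs, n_null, seed) {
  nt <- nrow(pd)
  idx0 <- cbind(pairs[, 1] - 1L, pairs[, 2] - 1L)
  obs <- cpp_bmntd_pairs(rel, pd, idx0, seq_len(nt) - 1L)
  set.seed(derive_seed(seed, "beta_nti"))
  nulls <- matrix(NA_real_, n_null, nrow(pairs))
  for (k in seq_len(n_null)) {
    perm <- sample.int(nt) - 1L
    nulls[k, ] <- cpp_bmntd_pairs(rel, pd, idx0, perm)
  }
  mu <- colMeans(nulls)
  sdv <- apply(nulls, 2, sd)
  bnti <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  if (anyNA(bnti))
    warning("betaNTI undefined (zero null SD) for ", sum(is.na(bnti)),
            " pair(s); reported as missing", call. = FALSE)
  list(beta_mntd_obs = obs, beta_nti = bnti)
}

#' Beta nearest taxon index (betaNTI) for sample pairs
#'
#' z-score of observed betaMNTD against a taxa-label randomization null: the
#' taxon identities are shuffled across the patristic matrix `n_null` times
#' and betaMNTD recomputed on unchanged abundances. Values below -2 indicate
#' phylogenetically more similar pairs than expected (homogeneous
#' selection); above +2, less similar (variable selection). Computed on
#' TSS relative abundances.
#'
#' @param cm a [community_matrix()].
#' @param pd patristic matrix covering `taxa_ids(cm)` (rows in that order).
#' @param n_null number of null randomizations (>= 99; default 999).
#' @param seed integer seed.
#' @return Symmetric sample-by-sample matrix of betaNTI (diagonal `NA`);
#'   pairs with zero null SD are `NA` with a warning. The observed betaMNTD
#'   matrix is attached as attribute `"beta_mntd"`.
#' @export
beta_nti <- function(cm, pd, n_null = 999, seed = 1) {
  stopifnot(inherits(cm, "community_matrix"))
  if (n_null < 99) stop("n_null must be >= 99")
  stopifnot(identical(rownames(pd), taxa_ids(cm)))
  rel <- tss_normalize(cm)
  ns <- ncol(rel)
  pairs <- t(utils::combn(ns, 2))
  res <- bnti_pairs(rel, pd, pairs, n_null, seed)
  out <- matrix(NA_real_, ns, ns, dimnames = list(sample_ids(cm), sample_ids(cm)))
  bm <- out
  out[pairs] <- res$beta_nti; out[pairs[, 2:1, drop = FALSE]] <- res$beta_nti
  bm[pairs] <- res$beta_mntd_obs; bm[pairs[, 2:1, drop = FALSE]] <- res$beta_mntd_obs
  attr(out, "beta_mntd") <- bm
  out
}

bray_curtis_pair <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# RC_bray for an explicit list of sample-index pairs (integer matrix).
# pool_counts defines occurrence frequencies and regional abundances.
rc_pairs <- function(counts, pairs, n_null, seed, pool_counts = counts) {
  ns <- ncol(pool_counts)
  if (ns < 2) stop("regional pool undefined: need at least two samples")
  occ <- rowSums(pool_counts > 0)
  regab <- rowSums(pool_counts)
  regab <- regab / sum(regab)
  present <- which(occ > 0)
  set.seed(derive_seed(seed, "raup_crick"))
  apply(pairs, 1, function(pr) {
    xa <- counts[, pr[1]]; xb <- counts[, pr[2]]
    obs <- bray_curtis_pair(xa, xb)
    Sa <- sum(xa > 0); Sb <- sum(xb > 0)
    Na <- sum(xa); Nb <- sum(xb)
    nullbc <- numeric(n_null)
    for (k in seq_len(n_null)) {
      ta <- sample(present, Sa, prob = occ[present])
      tb <- sample(present, Sb, prob = occ[present])
      ya <- numeric(nrow(counts)); yb <- numeric(nrow(counts))
      # one read per drawn taxon guarantees the conditioned richness, the
      # remainder is distributed by regional relative abundance
      ya[ta] <- 1 + rmultinom(1, Na - Sa, regab[ta])[, 1]
      yb[tb] <- 1 + rmultinom(1, Nb - Sb, regab[tb])[, 1]
      nullbc[k] <- bray_curtis_pair(ya, yb)
    }
    2 * (sum(nullbc < obs) + 0.5 * sum(nullbc == obs)) / n_null - 1
  })
}

#' Raup-Crick metric on Bray-Curtis (RC_bray)
#'
#' For each sample pair, simulates stochastic community assembly from the
#' regional pool on integer count data: each null community is rebuilt at
#' its observed richness by drawing that many distinct taxa with probability
#' proportional to occurrence frequency across the pool, seeding one read
#' per drawn taxon (so the null realizes the conditioned richness exactly),
#' then distributing the remaining reads multinomially proportional to
#' regional relative abundance over the drawn taxa. RC is the (tie-halved) rank of the
#' observed Bray-Curtis within the null distribution, rescaled to [-1, 1]:
#' above +0.95 indicates dispersal limitation, below -0.95 homogenizing
#' dispersal, in between undominated processes (drift). The regional pool
#' defaults to all samples of `cm` (in the pipeline, the community set being
#' compared) and can be overridden with `pool`.
#'
#' @param cm a [community_matrix()] (integer counts; at least two samples).
#' @param pairs two-column matrix or data frame of sample ids (or indices);
#'   default all pairs.
#' @param n_null number of null assemblies per pair (default 999).
#' @param seed integer seed.
#' @param pool optional [community_matrix()] (same taxa, same order)
#'   defining the regional pool; default `cm` itself.
#' @return Numeric vector of RC values in [-1, 1], one per pair row.
#' @export
raup_crick_bray <- function(cm, pairs = NULL, n_null = 999, seed = 1,
                            pool = cm) {
  stopifnot(inherits(cm, "community_matrix"))
  counts <- cm$counts
  if (is.null(pairs)) pairs <- t(utils::combn(ncol(counts), 2))
  pairs <- as.matrix(pairs)
  if (is.character(pairs))
    pairs <- matrix(match(pairs, sample_ids(cm)), ncol = 2)
  if (anyNA(pairs)) stop("unknown sample id in pairs")
  stopifnot(inherits(pool, "community_matrix"),
            identical(taxa_ids(pool), taxa_ids(cm)))
  rc_pairs(counts, pairs, n_null, seed, pool_counts = pool$counts)
}

PROCESSES <- c("variable_selection", "homogeneous_selection",
               "dispersal_limitation", "homogenizing_dispersal",
               "undominated")

#' Classify the dominant assembly process for a sample pair
#'
#' The two-stage rule: betaNTI below -2 is homogeneous selection, above +2
#' variable selection (strict inequalities; exactly +/-2 falls through to
#' the taxonomic stage). Otherwise RC_bray above +0.95 is dispersal
#' limitation, below -0.95 homogenizing dispersal, and anything between is
#' undominated (ecological drift). Vectorized; `NA` betaNTI yields `NA`.
#'
#' @param beta_nti numeric vector of betaNTI values.
#' @param rc_bray numeric vector of RC_bray values; may be `NA` where
#'   `|beta_nti| > 2` (unused there), but must be present when
#'   `|beta_nti| <= 2`.
#' @return Character vector of process labels.
#' @export
#' @examples
#' classify_process(c(-2.5, 3.1, 0.4, 0), c(NA, NA, 0.97, 0))
classify_process <- function(beta_nti, rc_bray = NA_real_) {
  n <- max(length(beta_nti), length(rc_bray))
  beta_nti <- rep_len(beta_nti, n); rc_bray <- rep_len(rc_bray, n)
  need_rc <- !is.na(beta_nti) & abs(beta_nti) <= 2
  if (any(need_rc & is.na(rc_bray)))
    stop("rc_bray required when |beta_nti| <= 2")
  out <- rep(NA_character_, n)
  out[!is.na(beta_nti) & beta_nti < -2] <- "homogeneous_selection"
  out[!is.na(beta_nti) & beta_nti > 2] <- "variable_selection"
  out[need_rc & rc_bray > 0.95] <- "dispersal_limitation"
  out[need_rc & rc_bray < -0.95] <- "homogenizing_dispersal"
  out[need_rc & abs(rc_bray) <= 0.95] <- "undominated"
  out
}

#' Aggregate pairwise process labels into a partition table
#'
#' Percentage of pairs assigned to each of the five processes within each
#' group (e.g. comparison class, subcommunity, timepoint); per-group
#' percentages sum to 100. Groups with no classified pairs are omitted with
#' a warning.
#'
#' @param pairs data frame containing a `process` column plus any grouping
#'   columns.
#' @param group_by character vector of grouping column names (may be empty
#'   for a single overall group).
#' @return Data frame: grouping columns, `n_pairs`, then one percentage
#'   column per process.
#' @export
partition_processes <- function(pairs, group_by = character()) {
  pairs <- as.data.frame(pairs)
  stopifnot("process" %in% names(pairs))
  keep <- !is.na(pairs$process)
  if (!all(keep)) {
    warning(sum(!keep), " unclassified pair(s) dropped", call. = FALSE)
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs) == 0) {
    warning("no classified pairs; empty partition", call. = FALSE)
    return(data.frame())
  }
  key <- if (length(group_by)) interaction(pairs[group_by], drop = TRUE,
                                           sep = "\r") else factor(rep("all", nrow(pairs)))
  groups <- split(seq_len(nrow(pairs)), key)
  rows <- lapply(groups, function(idx) {
    tab <- table(factor(pairs$process[idx], levels = PROCESSES))
    pct <- as.numeric(tab) / length(idx) * 100
    cbind(pairs[idx[1], group_by, drop = FALSE],
          data.frame(n_pairs = length(idx)),
          as.data.frame(as.list(setNames(pct, PROCESSES))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardized effect size of mean pairwise phylogenetic distance (SES.MPD)
#'
#' Per-sample z-score of abundance-weighted mean pairwise patristic distance
#' against a taxa-label shuffle null; negative values indicate phylogenetic
#' clustering. Weights follow the standard convention of weighting each
#' taxon pair by the product of relative abundances (conspecific pairs, at
#' distance zero, included).
#'
#' @inheritParams beta_nti
#' @return Data frame: `sample`, `mpd_obs`, `ses_mpd` (`NA` with a warning
#'   for single-taxon samples or zero null SD).
#' @export
ses_mpd <- function(cm, pd, n_null = 999, seed = 1) {
  stopifnot(inherits(cm, "community_matrix"))
  stopifnot(identical(rownames(pd), taxa_ids(cm)))
  rel <- tss_normalize(cm)
  nt <- nrow(rel)
  wmpd <- function(D) colSums(rel * (D %*% rel))   # f' D f per sample
  obs <- wmpd(pd)
  set.seed(derive_seed(seed, "ses_mpd"))
  nulls <- matrix(NA_real_, n_null, ncol(rel))
  for (k in seq_len(n_null)) {
    perm <- sample.int(nt)
    nulls[k, ] <- wmpd(pd[perm, perm])
  }
  mu <- colMeans(nulls); sdv <- apply(nulls, 2, sd)
  ses <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  single <- colSums(rel > 0) < 2
  if (any(single)) {
    ses[single] <- NA_real_
    warning(sum(single), " single-taxon sample(s): SES.MPD undefined",
            call. = FALSE)
  }
  data.frame(sample = sample_ids(cm), mpd_obs = obs, ses_mpd = ses,
             row.names = NULL)
}

# Enumerate comparison pairs. within_replicates: same treatment, different
# replicate; between_cs: different treatment. time_matched restricts both
# classes to pairs sharing a timepoint (the paired design default).
comparison_pairs <- function(metadata, comparison_class, time_matched = TRUE) {
  ns <- nrow(metadata)
  pr <- t(utils::combn(ns, 2))
  a <- pr[, 1]; b <- pr[, 2]
  same_trt <- metadata$treatment[a] == metadata$treatment[b]
  same_rep <- metadata$replicate[a] == metadata$replicate[b]
  same_tp <- metadata$timepoint[a] == metadata$timepoint[b]
  keep <- switch(comparison_class,
    within_replicates = same_trt & !same_rep,
    between_cs = !same_trt,
    stop("unknown comparison class: ", comparison_class))
  if (time_matched) keep <- keep & same_tp
  pr[keep, , drop = FALSE]
}

#' Full pairwise process partition for one community set
#'
#' Runs betaNTI on the requested comparison pairs, RC_bray on the pairs not
#' resolved by selection (`|betaNTI| <= 2`), classifies each pair, and
#' aggregates the five-way percentages. Subcommunity runs (`main`, `rare`)
#' first restrict the matrix by mean relative abundance thresholds and are
#' self-contained re-analyses: relative abundances are recomputed within the
#' subcommunity and RC uses the subsetted integer counts.
#'
#' @inheritParams beta_nti
#' @param tree an `ape::phylo` or newick string covering the taxa.
#' @param comparison_class `"within_replicates"` (same treatment, different
#'   replicate) or `"between_cs"` (different treatment).
#' @param subcommunity `"all"`, `"main"` (mean relative abundance > 1%) or
#'   `"rare"` (< 0.1%).
#' @param time_matched restrict pairs to shared timepoints (default `TRUE`);
#'   `FALSE` pools all timepoint combinations.
#' @param per_timepoint additionally aggregate the partition per timepoint.
#' @param main_threshold,rare_threshold subcommunity cutoffs (proportions).
#' @return List with `pairs` (per-pair table: ids, class, timepoint,
#'   betaMNTD, betaNTI, RC, process) and `partition` (the percentage table;
#'   per timepoint when `per_timepoint`).
#' @export
assembly_partition <- function(cm, tree, comparison_class = "within_replicates",
                               subcommunity = "all", n_null = 999, seed = 1,
                               time_matched = TRUE, per_timepoint = FALSE,
                               main_threshold = 0.01, rare_threshold = 0.001) {
  stopifnot(inherits(cm, "community_matrix"))
  subcommunity <- match.arg(subcommunity, c("all", "main", "rare"))
  if (subcommunity != "all") {
    part <- partition_subcommunities(cm, main_threshold, rare_threshold)
    keep <- if (subcommunity == "main") part$main_taxa else part$rare_taxa
    if (length(keep) == 0) stop("empty ", subcommunity, " subcommunity")
    cm <- subset_community(cm, taxa = keep)
  }
  pd <- patristic_matrix(tree, taxa_ids(cm))
  md <- cm$metadata
  pr <- comparison_pairs(md, comparison_class, time_matched)
  if (nrow(pr) == 0) {
    warning("no ", comparison_class, " pairs in this design", call. = FALSE)
    return(list(pairs = data.frame(), partition = data.frame()))
  }
  rel <- tss_normalize(cm)
  bn <- bnti_pairs(rel, pd, pr, n_null, seed)
  rc <- rep(NA_real_, nrow(pr))
  need_rc <- !is.na(bn$beta_nti) & abs(bn$beta_nti) <= 2
  if (any(need_rc))
    rc[need_rc] <- rc_pairs(cm$counts, pr[need_rc, , drop = FALSE], n_null, seed)
  pairs <- data.frame(
    sample_a = sample_ids(cm)[pr[, 1]], sample_b = sample_ids(cm)[pr[, 2]],
    comparison_class = comparison_class, subcommunity = subcommunity,
    timepoint = ifelse(md$timepoint[pr[, 1]] == md$timepoint[pr[, 2]],
                       md$timepoint[pr[, 1]], NA_real_),
    beta_mntd_obs = bn$beta_mntd_obs, beta_nti = bn$beta_nti, rc_bray = rc,
    process = classify_process(bn$beta_nti, rc))
  keys <- c("comparison_class", "subcommunity",
            if (per_timepoint) "timepoint")
  list(pairs = pairs, partition = partition_processes(pairs, keys))
}

#' Time-resolved process partition
#'
#' Convenience wrapper around [assembly_partition()] restricted to
#' time-matched pairs and aggregated per timepoint, tracing how the balance
#' of selection, dispersal and drift shifts along a succession.
#'
#' @inheritParams assembly_partition
#' @return As [assembly_partition()], with one partition row per timepoint.
#' @export
time_resolved_partition <- function(cm, tree,
                                    comparison_class = "within_replicates",
                                    subcommunity = "all", n_null = 999,
                                    seed = 1, ...) {
  assembly_partition(cm, tree, comparison_class, subcommunity, n_null, seed,
                     time_matched = TRUE, per_timepoint = TRUE, ...)
}
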