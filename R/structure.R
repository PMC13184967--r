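#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = 1 - 2 sum(min(x_i, y_i)) / (sum x + sum y)`. A
#' [community_matrix()] is TSS-normalized first (the standard beta-diversity
#' convention); a plain numeric matrix (taxa x samples) is used as given.
#'
#' @param x a [community_matrix()] or numeric taxa-by-samples matrix.
#' @return A `dist` object over samples (values in [0, 1]).
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "community_matrix")) tss_normalize(x) else as.matrix(x)
  if (any(colSums(m) == 0)) stop("zero-sum sample(s)")
  vegan::vegdist(t(m), method = "bray")
}

#' UPGMA clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with size-weighted arithmetic-mean linkage.
#' Merge heights use the ultrametric tree-height convention (half the mean
#' inter-cluster dissimilarity), so clustering an ultrametric distance
#' matrix reproduces the generating tree heights exactly.
#'
#' @param dm a `dist` object (e.g. from [bray_curtis()]).
#' @return An `hclust` object with halved heights; convert with
#'   [upgma_newick()] for clustergram export.
#' @export
upgma <- function(dm) {
  dm <- stats::as.dist(dm)
  if (anyNA(dm)) stop("NA in distance matrix")
  if (attr(dm, "Size") < 2) stop("need at least two samples")
  h <- stats::hclust(dm, method = "average")
  h$height <- h$height / 2
  h$method <- "upgma"
  h
}

#' @rdname upgma
#' @param hc an `hclust` from [upgma()].
#' @return `upgma_newick()`: a newick string of the dendrogram.
#' @export
upgma_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Best-stress configuration over random restarts (delegating to
#' `vegan::metaMDS`/`monoMDS`); deterministic for a fixed seed. For a fully
#' deterministic alternative use [pcoa()].
#'
#' @param dm a `dist` object.
#' @param k embedding dimension (default 2; must be < number of samples).
#' @param seed integer seed.
#' @param n_restarts random restarts (default 20).
#' @return An `ordination` list: `points` (samples x k), `stress` in [0, 1],
#'   `method`, `seed`.
#' @export
nmds <- function(dm, k = 2, seed = 1, n_restarts = 20) {
  dm <- stats::as.dist(dm)
  if (k >= attr(dm, "Size")) stop("k must be smaller than the number of samples")
  set.seed(derive_seed(seed, "nmds"))
  fit <- vegan::metaMDS(dm, k = k, trymax = n_restarts, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  structure(list(points = fit$points, stress = fit$stress, method = "nmds",
                 seed = seed), class = "ordination")
}

#' @rdname nmds
#' @return `pcoa()`: an `ordination` list with `points`, `eigenvalues`,
#'   `method = "pcoa"` (deterministic).
#' @export
pcoa <- function(dm, k = 2) {
  dm <- stats::as.dist(dm)
  if (k >= attr(dm, "Size")) stop("k must be smaller than the number of samples")
  fit <- cmdscale(dm, k = k, eig = TRUE)
  pts <- fit$points
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  structure(list(points = pts, eigenvalues = fit$eig, method = "pcoa",
                 seed = NA), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, k = %d%s\n", x$method,
              nrow(x$points), ncol(x$points),
              if (!is.null(x$stress)) sprintf(", stress = %.4f", x$stress) else ""))
  invisible(x)
}

check_groups <- function(groups, n) {
  groups <- factor(groups)
  if (length(groups) != n) stop("groups length does not match the samples")
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two samples")
  groups
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Samples are embedded by PCoA, per-sample distances to the group spatial
#' median computed (`vegan::betadisper`), and a one-way F statistic on those
#' distances tested by permutation of group labels.
#'
#' @param dm a `dist` object.
#' @param groups group labels, one per sample.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param center `"median"` (spatial median, default) or `"centroid"`.
#' @return List: `F`, `p_value`, `dispersion` (named per-group mean
#'   distance-to-center).
#' @export
permdisp <- function(dm, groups, n_perm = 999, seed = 1, center = "median") {
  dm <- stats::as.dist(dm)
  groups <- check_groups(groups, attr(dm, "Size"))
  bd <- vegan::betadisper(dm, groups, type = match.arg(center, c("median", "centroid")))
  if (stats::var(bd$distances) < 1e-12) {
    # all distances-to-center equal: dispersions are identical by
    # construction and the F statistic is numerically meaningless
    return(list(F = 0, p_value = 1,
                dispersion = as.numeric(tapply(bd$distances, groups, mean))))
  }
  set.seed(derive_seed(seed, "permdisp"))
  pt <- suppressWarnings(vegan::permutest(bd, permutations = n_perm))
  list(F = pt$tab$F[1], p_value = pt$tab$`Pr(>F)`[1],
       dispersion = as.numeric(tapply(bd$distances, groups, mean)))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities; R near 1 means groups are completely
#' separated, near 0 indistinguishable. Delegates to `vegan::anosim`.
#'
#' @inheritParams permdisp
#' @return List: `R`, `p_value`.
#' @export
anosim_test <- function(dm, groups, n_perm = 999, seed = 1) {
  dm <- stats::as.dist(dm)
  groups <- check_groups(groups, attr(dm, "Size"))
  set.seed(derive_seed(seed, "anosim"))
  fit <- vegan::anosim(dm, groups, permutations = n_perm)
  list(R = unname(fit$statistic), p_value = fit$signif)
}

#' Procrustes superimposition and PROTEST
#'
#' Optimal translation/uniform-scaling/rotation of one ordination onto
#' another; m2 is the normalized residual sum of squares (0 = superimposable)
#' and the p-value comes from PROTEST row permutation. Used to test the
#' congruence of e.g. main-taxa vs rare-taxa ordinations.
#'
#' @param ord_a,ord_b `ordination` objects (or coordinate matrices) over the
#'   same samples and dimension.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return List: `m2`, `p_value`.
#' @export
procrustes_protest <- function(ord_a, ord_b, n_perm = 999, seed = 1) {
  pa <- if (inherits(ord_a, "ordination")) ord_a$points else as.matrix(ord_a)
  pb <- if (inherits(ord_b, "ordination")) ord_b$points else as.matrix(ord_b)
  if (!identical(dim(pa), dim(pb)) ||
      !identical(rownames(pa), rownames(pb)))
    stop("ordinations must cover the same samples in the same dimension")
  set.seed(derive_seed(seed, "protest"))
  fit <- vegan::protest(pa, pb, permutations = n_perm)
  list(m2 = fit$ss, p_value = fit$signif)
}

#' Per-sample diversity and richness indices
#'
#' Inverse Simpson diversity (`1 / sum f_i^2` on relative abundances) and
#' Margalef richness (`(S - 1) / ln N`; 0 by convention when `N = 1`).
#'
#' @param cm a [community_matrix()].
#' @return Data frame: `sample`, `inverse_simpson`, `margalef`.
#' @export
diversity_indices <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  rel <- tss_normalize(cm)
  inv <- 1 / colSums(rel^2)
  S <- colSums(cm$counts > 0)
  N <- colSums(cm$counts)
  marg <- ifelse(N > 1, (S - 1) / log(N), 0)
  data.frame(sample = sample_ids(cm), inverse_simpson = unname(inv),
             margalef = unname(marg), row.names = NULL)
}

#' Partition taxa into main, rare and intermediate subcommunities
#'
#' By mean TSS relative abundance over all samples: strictly above
#' `main_threshold` (1% by default) is main, strictly below
#' `rare_threshold` (0.1%) is rare, anything between is intermediate.
#'
#' @param cm a [community_matrix()].
#' @param main_threshold,rare_threshold proportions (defaults 0.01, 0.001).
#' @return List: `main_taxa`, `rare_taxa`, `intermediate_taxa` (disjoint,
#'   exhaustive), and `mean_relative_abundance` (named vector).
#' @export
partition_subcommunities <- function(cm, main_threshold = 0.01,
                                     rare_threshold = 0.001) {
  stopifnot(inherits(cm, "community_matrix"))
  if (main_threshold <= rare_threshold)
    stop("main_threshold must exceed rare_threshold")
  mra <- rowMeans(tss_normalize(cm))
  list(main_taxa = names(mra)[mra > main_threshold],
       rare_taxa = names(mra)[mra < rare_threshold],
       intermediate_taxa = names(mra)[mra >= rare_threshold &
                                        mra <= main_threshold],
       mean_relative_abundance = mra)
}

#' Successional trajectory distance in ordination space
#'
#' Euclidean distance between each treatment's per-timepoint centroid (over
#' replicates) and its reference-timepoint centroid; summarizes how far a
#' community has traveled from its starting configuration.
#'
#' @param ord an `ordination` (or coordinate matrix with sample rownames).
#' @param metadata data frame with `sample`, `treatment`, `timepoint`
#'   covering the ordinated samples.
#' @param reference reference timepoint (default: the earliest per
#'   treatment, which must be present for every treatment).
#' @return Data frame: `treatment`, `timepoint`, `distance`.
#' @export
trajectory_distance <- function(ord, metadata, reference = NULL) {
  pts <- if (inherits(ord, "ordination")) ord$points else as.matrix(ord)
  metadata <- as.data.frame(metadata)
  idx <- match(rownames(pts), metadata$sample)
  if (anyNA(idx)) stop("metadata missing ordinated sample(s)")
  md <- metadata[idx, , drop = FALSE]
  out <- NULL
  for (trt in unique(md$treatment)) {
    sel <- md$treatment == trt
    tps <- sort(unique(md$timepoint[sel]))
    ref <- if (is.null(reference)) tps[1] else reference
    if (!ref %in% tps) stop("reference timepoint absent for treatment ", trt)
    cent <- function(tp) colMeans(pts[sel & md$timepoint == tp, , drop = FALSE])
    ref_c <- cent(ref)
    out <- rbind(out, data.frame(
      treatment = trt, timepoint = tps,
      distance = vapply(tps, function(tp) sqrt(sum((cent(tp) - ref_c)^2)),
                        numeric(1))))
  }
  rownames(out) <- NULL
  out
}

#' Community overlap between paired replicates
#'
#' Overlap is defined as one minus Bray-Curtis dissimilarity on relative
#' abundances, computed for every pair of replicates sharing a treatment and
#' timepoint. Every (treatment, timepoint) cell must contain at least two
#' replicates.
#'
#' @param cm a [community_matrix()].
#' @return Data frame: `treatment`, `timepoint`, `sample_a`, `sample_b`,
#'   `overlap` in [0, 1].
#' @export
community_overlap <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  rel <- tss_normalize(cm)
  md <- cm$metadata
  cells <- split(seq_len(nrow(md)), list(md$treatment, md$timepoint),
                 drop = TRUE)
  if (any(vapply(cells, length, 1L) < 2))
    stop("unpaired input: some (treatment, timepoint) cells have one sample")
  out <- NULL
  for (idx in cells) {
    pr <- t(utils::combn(idx, 2))
    out <- rbind(out, data.frame(
      treatment = md$treatment[pr[, 1]], timepoint = md$timepoint[pr[, 1]],
      sample_a = md$sample[pr[, 1]], sample_b = md$sample[pr[, 2]],
      overlap = apply(pr, 1, function(p)
        1 - bray_curtis_pair(rel[, p[1]], rel[, p[2]]))))
  }
  rownames(out) <- NULL
  out
}
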