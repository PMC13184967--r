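test_that("Bray-Curtis hits hand values and metric structure", {
  m <- matrix(c(6, 2, 2, 2), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["x", "y"], 1 - 8 / 12, tolerance = 1e-12)
  m2 <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(as.matrix(bray_curtis(m2))["x", "y"], 1)   # disjoint
  m3 <- cbind(m, z = m[, "x"])
  d3 <- as.matrix(bray_curtis(m3))
  expect_equal(d3["x", "z"], 0)                            # identical
  expect_true(all(d3 >= 0 & d3 <= 1))
  expect_equal(d3, t(d3))
})

test_that("UPGMA reproduces hand-computed merge heights and is label-invariant", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- upgma(as.dist(d))
  expect_equal(sort(h$height), c(1, 4))
  # ultrametric input: cophenetic distances of the dendrogram reproduce it
  coph <- as.matrix(stats::cophenetic(h)) * 2  # heights are half distances
  expect_equal(coph[c("A", "B", "C"), c("A", "B", "C")], d,
               ignore_attr = TRUE)
  # permuting the input order yields the same topology and heights
  p <- c("C", "A", "B")
  h2 <- upgma(as.dist(d[p, p]))
  expect_equal(sort(h2$height), sort(h$height))
  expect_type(upgma_newick(h), "character")
  expect_error(upgma(as.dist(matrix(NA_real_, 2, 2))), "NA")
})

test_that("ordinations embed structured data faithfully", {
  # colinear points are perfectly embeddable: stress ~ 0
  pts <- cbind(seq(0, 1, length.out = 8), 0)
  d <- dist(pts)
  ord <- suppressWarnings(nmds(d, k = 2, seed = 1, n_restarts = 5))
  expect_lt(ord$stress, 0.01)
  ord2 <- suppressWarnings(nmds(d, k = 2, seed = 1, n_restarts = 5))
  expect_identical(ord$points, ord2$points)   # seeded determinism

  # rank agreement between input and configuration distances
  set.seed(3)
  x <- matrix(rnorm(30), 15, 2)
  rownames(x) <- paste0("s", 1:15)
  dx <- dist(x)
  ordx <- suppressWarnings(nmds(dx, seed = 2))
  expect_gt(cor(as.vector(dx), as.vector(dist(ordx$points)),
                method = "spearman"), 0.95)

  # PCoA on Euclidean distances reproduces them
  pc <- pcoa(dx, k = 2)
  expect_equal(as.vector(dist(pc$points)), as.vector(dx), tolerance = 1e-8)
  expect_error(nmds(dist(x[1:3, ]), k = 3), "smaller")
})

test_that("PERMDISP separates dispersion differences and respects its null", {
  # mirror-image groups with identical distance-to-center multisets: F ~ 0
  pts <- rbind(c(0, 0), c(2, 0), c(10, 0), c(12, 0))
  rownames(pts) <- paste0("s", 1:4)
  pd0 <- permdisp(dist(pts), c("g1", "g1", "g2", "g2"), n_perm = 99, seed = 1)
  expect_equal(pd0$F, 0)
  expect_equal(pd0$dispersion, c(1, 1))

  # tight vs diffuse groups are detected
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    a <- matrix(rnorm(20, sd = 1), 10, 2)
    b <- matrix(rnorm(20, sd = 5), 10, 2)
    pts <- rbind(a, b); rownames(pts) <- paste0("s", 1:20)
    res <- permdisp(dist(pts), rep(c("a", "b"), each = 10),
                    n_perm = 199, seed = s)
    if (res$p_value <= 0.05) hits <- hits + 1
    expect_gte(res$p_value, 1 / 200)   # permutation p-value support
  }
  expect_gte(hits, 9)
  expect_error(permdisp(dist(pts), c("a", rep("b", 19))), "at least two samples")
})

test_that("ANOSIM R hits 1 on separated groups and 0 under the null", {
  # two well-separated clusters: all between > all within
  pts <- rbind(matrix(rnorm(10, sd = 0.1), 5, 2),
               matrix(rnorm(10, 100, sd = 0.1), 5, 2))
  rownames(pts) <- paste0("s", 1:10)
  res <- anosim_test(dist(pts), rep(c("a", "b"), each = 5),
                     n_perm = 199, seed = 1)
  expect_equal(res$R, 1)
  expect_lt(res$p_value, 0.05)

  # random labels on iid points: R near 0 on average
  rs <- vapply(1:10, function(s) {
    set.seed(s)
    pts <- matrix(rnorm(24), 12, 2); rownames(pts) <- paste0("s", 1:12)
    anosim_test(dist(pts), rep(c("a", "b"), 6), n_perm = 99, seed = s)$R
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("Procrustes m2 vanishes for superimposable configurations", {
  set.seed(4)
  a <- matrix(rnorm(20), 10, 2); rownames(a) <- paste0("s", 1:10)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- 3 * a %*% rot + 5
  rownames(b) <- rownames(a)
  res <- procrustes_protest(a, b, n_perm = 99, seed = 1)
  expect_lt(res$m2, 1e-8)
  # self-comparison likewise
  expect_lt(procrustes_protest(a, a, n_perm = 99, seed = 1)$m2, 1e-12)
  # independent configurations: high m2
  c2 <- matrix(rnorm(20), 10, 2); rownames(c2) <- rownames(a)
  expect_gt(procrustes_protest(a, c2, n_perm = 99, seed = 1)$m2, 0.3)
  expect_error(procrustes_protest(a, b[1:5, ]), "same samples")
})

test_that("diversity indices match closed forms", {
  counts <- matrix(0L, 5, 3, dimnames = list(paste0("t", 1:5),
                                             c("even", "single", "mixed")))
  counts[1:4, "even"] <- 25L
  counts["t1", "single"] <- 10L
  counts[, "mixed"] <- c(60L, 20L, 10L, 5L, 5L)
  cm <- make_cm(counts)
  div <- diversity_indices(cm)
  expect_equal(div$inverse_simpson[1], 4)            # uniform: 1/sum((1/4)^2)
  expect_equal(div$inverse_simpson[2], 1)
  expect_equal(div$margalef[2], 0)                   # single taxon
  expect_equal(div$margalef[3], 4 / log(100))        # S=5, N=100
})

test_that("subcommunity partition applies strict thresholds", {
  rel <- c(0.02, 0.0005, 0.005, 0.01, 0.001)  # main, rare, int, int(=1%), int(=0.1%)
  counts <- matrix(round(rel * 1e5), 5, 2,
                   dimnames = list(paste0("t", 1:5), c("s1", "s2")))
  counts <- rbind(counts, filler = 1e5 - colSums(counts))
  cm <- make_cm(counts)
  part <- partition_subcommunities(cm)
  expect_true("t1" %in% part$main_taxa)
  expect_true("t2" %in% part$rare_taxa)
  expect_true(all(c("t3", "t4", "t5") %in% part$intermediate_taxa))
  expect_setequal(c(part$main_taxa, part$rare_taxa, part$intermediate_taxa),
                  taxa_ids(cm))
  expect_error(partition_subcommunities(cm, 0.001, 0.01), "exceed")
})

test_that("trajectory distances measure departure from the reference", {
  md <- data.frame(sample = paste0("s", 1:6), treatment = "a",
                   replicate = rep(c("r1", "r2"), 3),
                   timepoint = rep(0:2, each = 2))
  pts <- cbind(c(0, 0, 1, 1, 3, 3), c(0, 0, 0, 0, 0, 0))
  rownames(pts) <- md$sample
  tr <- trajectory_distance(pts, md)
  expect_equal(tr$distance, c(0, 1, 3))
  # static community: all zero
  pts0 <- matrix(1, 6, 2, dimnames = list(md$sample, NULL))
  expect_true(all(trajectory_distance(pts0, md)$distance == 0))
  expect_error(trajectory_distance(pts, md, reference = 99), "reference")

  # directed drift in ordination space: distance increases with time
  set.seed(8)
  rho <- vapply(1:10, function(s) {
    set.seed(s)
    steps <- matrix(rnorm(40, mean = 0.5), 20, 2)
    walk <- apply(steps, 2, cumsum)
    md2 <- data.frame(sample = paste0("s", 1:20), treatment = "a",
                      replicate = "r1", timepoint = 1:20)
    rownames(walk) <- md2$sample
    d <- trajectory_distance(walk, md2)
    cor(d$timepoint, d$distance, method = "spearman")
  }, numeric(1))
  expect_gt(mean(rho), 0)
})

test_that("community overlap is the Bray-Curtis complement on paired replicates", {
  # overlap is computed on relative abundances; with equal totals the
  # complement of the count-space Bray-Curtis is forced:
  # x=[6,2], y=[2,6] -> BC = 1 - 2*(2+2)/16 = 0.5 -> overlap 0.5
  counts <- matrix(c(6L, 2L, 2L, 6L), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  cm <- make_cm(counts, treatments = c("g", "g"), replicates = c("r1", "r2"),
                timepoints = c(0, 0))
  ov <- community_overlap(cm)
  expect_equal(ov$overlap, 0.5, tolerance = 1e-12)
  # identical replicates: overlap 1; disjoint: 0
  counts2 <- cbind(counts, s3 = counts[, 1])
  cm2 <- make_cm(counts2, treatments = rep("g", 3),
                 replicates = c("r1", "r2", "r3"), timepoints = rep(0, 3))
  ov2 <- community_overlap(cm2)
  expect_equal(ov2$overlap[ov2$sample_b == "s3" & ov2$sample_a == "s1"], 1)
  # unpaired design is an error
  cm3 <- make_cm(counts, treatments = c("g", "g"), replicates = c("r1", "r2"),
                 timepoints = c(0, 12))
  expect_error(community_overlap(cm3), "unpaired")
})
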