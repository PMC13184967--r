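test_that("patristic distances are path sums with tree-metric structure", {
  pd <- patristic_matrix(tree3)
  expect_equal(pd["A", "B"], 2)
  expect_equal(pd["A", "C"], 4)
  expect_equal(pd["B", "C"], 4)
  expect_true(all(diag(pd) == 0))
  expect_equal(pd, t(pd))
  expect_error(patristic_matrix(tree3, c("A", "Z")), "Z")

  # star tree: all off-diagonal distances 2b
  star <- patristic_matrix("(A:3,B:3,C:3,D:3);")
  expect_true(all(star[upper.tri(star)] == 6))

  # triangle inequality on sampled triples of a random tree
  tt <- simulate_tree_and_traits(20, 1, seed = 4)
  pd2 <- patristic_matrix(tt$tree)
  set.seed(1)
  for (i in 1:50) {
    tri <- sample(20, 3)
    expect_lte(pd2[tri[1], tri[2]],
               pd2[tri[1], tri[3]] + pd2[tri[3], tri[2]] + 1e-12)
  }
})

test_that("betaMNTD matches hand values and a brute-force oracle", {
  pd <- patristic_matrix(tree3)
  expect_equal(beta_mntd(c(1, 0, 0), c(0, 1, 0), pd), 2)
  expect_equal(beta_mntd(c(0.5, 0.5, 0), c(0.5, 0.5, 0), pd), 0)
  expect_error(beta_mntd(c(0, 0, 0), c(1, 0, 0), pd), "empty")

  brute <- function(fa, fb, d) {
    ia <- which(fa > 0); ib <- which(fb > 0)
    s <- 0
    for (i in ia) s <- s + fa[i] * min(d[i, ib])
    for (j in ib) s <- s + fb[j] * min(d[ia, j])
    0.5 * s
  }
  set.seed(9)
  for (rep in 1:200) {
    nt <- sample(3:6, 1)
    tt <- simulate_tree_and_traits(nt, 1, seed = rep)
    d <- patristic_matrix(tt$tree)
    fa <- runif(nt) * rbinom(nt, 1, 0.7)
    fb <- runif(nt) * rbinom(nt, 1, 0.7)
    if (sum(fa) == 0) fa[1] <- 1
    if (sum(fb) == 0) fb[nt] <- 1
    fa <- fa / sum(fa); fb <- fb / sum(fb)
    expect_equal(beta_mntd(fa, fb, d), brute(fa, fb, d), tolerance = 1e-12)
  }
})

test_that("betaNTI is symmetric, scale-invariant and calibrated on its null", {
  set.seed(11)
  tt <- simulate_tree_and_traits(60, 1, seed = 5)
  pd <- patristic_matrix(tt$tree)
  counts <- matrix(0L, 60, 8,
                   dimnames = list(tt$tree$tip.label, paste0("s", 1:8)))
  for (s in 1:8) {
    taxa <- sample(60, 20)
    counts[taxa, s] <- rmultinom(1, 500, rep(1 / 20, 20))[, 1]
  }
  cm <- suppressWarnings(make_cm(counts))
  bn <- beta_nti(cm, pd, n_null = 199, seed = 3)
  expect_equal(unname(bn), unname(t(bn)))
  # branch-length scale invariance at a fixed seed (the z-score cancels the
  # scale; the observed betaMNTD itself scales with the branch lengths)
  bn2 <- beta_nti(cm, pd * 7, n_null = 199, seed = 3)
  attr(bn, "beta_mntd") <- NULL; attr(bn2, "beta_mntd") <- NULL
  expect_equal(bn, bn2, tolerance = 1e-9)
  # null-conforming communities stay within +/-2 most of the time
  v <- bn[upper.tri(bn)]
  expect_lt(mean(abs(v) > 2), 0.2)
  expect_error(beta_nti(cm, pd, n_null = 50), "99")
})

test_that("RC_bray hits its boundaries on forced configurations", {
  # identical communities: obs BC = 0, below every null replicate
  counts <- matrix(c(10L, 10L, 10L, 10L, 5L, 5L, 5L, 5L), 4, 2,
                   dimnames = list(paste0("t", 1:4), c("s1", "s2")))
  counts[, 2] <- counts[, 1]
  cm <- make_cm(counts)
  expect_equal(raup_crick_bray(cm, n_null = 199, seed = 1), -1)

  # fully disjoint communities in a rich pool: obs BC = 1, above every null
  set.seed(2)
  nt <- 40
  big <- matrix(rpois(nt * 10, 3), nt, 10,
                dimnames = list(paste0("t", 1:nt), paste0("s", 1:10)))
  big[, 1] <- 0L; big[1:20, 1] <- 5L
  big[, 2] <- 0L; big[21:40, 2] <- 5L
  big[3, colSums(big) == 0] <- 1L
  cmb <- suppressWarnings(make_cm(big))
  rc <- raup_crick_bray(cmb, pairs = cbind(1, 2), n_null = 199, seed = 5)
  expect_equal(rc, 1)
  expect_error(raup_crick_bray(make_cm(counts[, 1, drop = FALSE]),
                               pairs = cbind(1, 1)), "two samples")
})

test_that("process classification reproduces the threshold rule set exactly", {
  # selection requires strict |bNTI| > 2; dispersal strict |RC| > 0.95
  grid <- expand.grid(bnti = c(-3, -2.01, -2, -1, 0, 1, 2, 2.01, 3),
                      rc = c(-1, -0.96, -0.95, 0, 0.95, 0.96, 1))
  got <- classify_process(grid$bnti, grid$rc)
  want <- ifelse(grid$bnti < -2, "homogeneous_selection",
          ifelse(grid$bnti > 2, "variable_selection",
          ifelse(grid$rc > 0.95, "dispersal_limitation",
          ifelse(grid$rc < -0.95, "homogenizing_dispersal", "undominated"))))
  expect_identical(got, want)
  expect_identical(classify_process(-2.5, NA), "homogeneous_selection")
  expect_error(classify_process(0.5, NA), "rc_bray required")
})

test_that("process partitions are percentages summing to 100 per group", {
  pairs <- data.frame(
    process = c(rep("homogeneous_selection", 4)),
    comparison_class = "within_replicates")
  p <- partition_processes(pairs, "comparison_class")
  expect_equal(p$homogeneous_selection, 100)
  expect_equal(p$variable_selection, 0)

  pairs2 <- data.frame(process = c(rep("homogeneous_selection", 2),
                                   rep("dispersal_limitation", 2)))
  p2 <- partition_processes(pairs2)
  expect_equal(p2$homogeneous_selection, 50)
  expect_equal(p2$dispersal_limitation, 50)
  expect_equal(sum(p2[c("variable_selection", "homogeneous_selection",
                        "dispersal_limitation", "homogenizing_dispersal",
                        "undominated")]), 100)
  expect_warning(
    expect_warning(partition_processes(data.frame(process = NA_character_)),
                   "unclassified"),
    "no classified pairs")
})

test_that("SES.MPD detects clade confinement and handles degenerate samples", {
  tt <- simulate_tree_and_traits(80, 1, seed = 6)
  pd <- patristic_matrix(tt$tree)
  tre <- tt$tree
  nodes <- 81:(80 + tre$Nnode)
  sizes <- vapply(nodes, function(n)
    length(ape::extract.clade(tre, n)$tip.label), integer(1))
  clade <- ape::extract.clade(tre, nodes[which.min(abs(sizes - 15))])$tip.label

  hits <- 0; even_z <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    counts <- matrix(0L, 80, 2, dimnames = list(tre$tip.label, c("cl", "ev")))
    counts[clade, 1] <- rmultinom(1, 500, rep(1, length(clade)))[, 1]
    counts[, 2] <- rmultinom(1, 500, rep(1, 80))[, 1]
    cm <- suppressWarnings(make_cm(counts))
    sm <- ses_mpd(cm, pd, n_null = 199, seed = s)
    if (sm$ses_mpd[1] < 0) hits <- hits + 1
    even_z[s] <- sm$ses_mpd[2]
  }
  expect_gte(hits, 9)
  # near-even whole-tree samples are unremarkable under the null on average
  expect_lt(abs(mean(even_z)), 1)

  # identical composition, identical seed -> identical SES
  counts <- matrix(5L, 80, 2, dimnames = list(tre$tip.label, c("a", "b")))
  sm2 <- ses_mpd(make_cm(counts), pd, n_null = 99, seed = 2)
  expect_equal(sm2$ses_mpd[1], sm2$ses_mpd[2])

  # single-taxon sample is flagged missing
  counts3 <- matrix(0L, 80, 2, dimnames = list(tre$tip.label, c("a", "b")))
  counts3[1, 1] <- 5L; counts3[1:10, 2] <- 3L
  cm3 <- suppressWarnings(make_cm(counts3))
  expect_warning(sm3 <- ses_mpd(cm3, pd, n_null = 99, seed = 1),
                 "single-taxon")
  expect_true(is.na(sm3$ses_mpd[1]))
})

test_that("SES.MPD agrees with an independent implementation", {
  skip_if_not_installed("picante")
  tt <- simulate_tree_and_traits(30, 1, seed = 2)
  pd <- patristic_matrix(tt$tree)
  set.seed(5)
  counts <- matrix(rpois(30 * 4, 1), 30, 4,
                   dimnames = list(tt$tree$tip.label, paste0("s", 1:4)))
  counts[1, colSums(counts) == 0] <- 1L
  cm <- suppressWarnings(make_cm(counts))
  ours <- ses_mpd(cm, pd, n_null = 999, seed = 4)
  rel <- t(tss_normalize(cm))
  ref <- picante::ses.mpd(rel, pd, null.model = "taxa.labels",
                          abundance.weighted = TRUE, runs = 999)
  expect_equal(ours$mpd_obs, ref$mpd.obs, tolerance = 1e-12)
  expect_equal(ours$ses_mpd, ref$mpd.obs.z, tolerance = 0.25)
})

test_that("betaMNTD agrees with picante comdistnt on sparse communities", {
  skip_if_not_installed("picante")
  set.seed(7)
  tt <- simulate_tree_and_traits(15, 1, seed = 3)
  pd <- patristic_matrix(tt$tree)
  comm <- matrix(0, 3, 15, dimnames = list(paste0("s", 1:3),
                                           tt$tree$tip.label))
  for (s in 1:3) comm[s, sample(15, 5)] <- runif(5)
  rel <- t(comm / rowSums(comm))
  ref <- as.matrix(picante::comdistnt(comm, pd, abundance.weighted = TRUE))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(beta_mntd(rel[, i], rel[, j], pd), ref[i, j],
                 tolerance = 1e-12)
})

test_that("time-resolved partition tracks a regime switch", {
  # drift for early timepoints, then guild-confined selection: the
  # homogeneous-selection fraction should rise in the late phase
  sc_d <- synthetic_scenario(n_taxa = 100, n_treatments = 1,
                             n_replicates = 3, n_timepoints = 4,
                             regime = "drift", seed = 21)
  sc_h <- synthetic_scenario(n_taxa = 100, n_treatments = 1,
                             n_replicates = 3, n_timepoints = 4,
                             regime = "homogeneous_selection", seed = 21)
  cm_d <- assemble_timeseries(sc_d)
  cm_h <- assemble_timeseries(sc_h)
  tr <- synthetic_truth(sc_h)
  md_late <- cm_h$metadata
  md_late$timepoint <- md_late$timepoint + 4
  md_late$sample <- paste0(md_late$sample, "L")
  md <- rbind(cm_d$metadata, md_late)
  counts <- cbind(cm_d$counts, cm_h$counts)
  colnames(counts) <- md$sample
  cm <- suppressWarnings(community_matrix(counts, md))
  res <- time_resolved_partition(cm, tr$tree, "within_replicates",
                                 n_null = 199, seed = 9)
  part <- res$partition
  expect_true(all(abs(rowSums(part[, c("variable_selection",
                                       "homogeneous_selection",
                                       "dispersal_limitation",
                                       "homogenizing_dispersal",
                                       "undominated")]) - 100) < 1e-9))
  early_hs <- mean(part$homogeneous_selection[part$timepoint < 4])
  late_hs <- mean(part$homogeneous_selection[part$timepoint >= 4])
  expect_gt(late_hs, early_hs)
})

test_that("degenerate designs are reported, not computed", {
  sc <- synthetic_scenario(n_taxa = 30, n_treatments = 1, n_replicates = 2,
                           n_timepoints = 2, regime = "drift", seed = 4)
  tr <- synthetic_truth(sc)
  cm <- assemble_timeseries(tr)
  expect_warning(res <- assembly_partition(cm, tr$tree, "between_cs",
                                           n_null = 99, seed = 1),
                 "no between_cs pairs")
  expect_equal(nrow(res$pairs), 0)
})
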