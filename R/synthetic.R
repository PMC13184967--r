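#' Parameterize a synthetic community scenario
#'
#' Describes a replicated treatment-by-time microcosm design with a known
#' assembly regime, emulating a dense succession experiment (by default six
#' treatments, biological triplicates, 29 timepoints). Communities are drawn
#' from a lognormal regional pool over a simulated phylogeny with Brownian
#' (phylogenetically conserved) substrate-affinity traits; the `regime`
#' controls which ecological process dominates pairwise comparisons and is
#' the planted ground truth recovered by the null models.
#'
#' Regimes: `homogeneous_selection` (every sample confined to one
#' phylogenetically coherent guild clade of about `guild_size` taxa, whose
#' members are partitioned among replicates by a founder lottery - strong
#' selection with within-guild taxonomic turnover),
#' `variable_selection` (well-separated per-treatment Gaussian trait filters),
#' `dispersal_limitation` (replicates draw from disjoint regional subpools,
#' then propagate serially - priority effects), `homogenizing_dispersal`
#' (replicate compositions mixed toward their mean each step), and `drift`
#' (no selection; serial Wright-Fisher resampling of a latent community of
#' `community_size` individuals, observed by multinomial subsampling at
#' `reads_per_sample`).
#'
#' @param n_taxa number of taxa in the regional pool (>= 3).
#' @param n_treatments,n_replicates,n_timepoints design dimensions.
#' @param reads_per_sample sequencing depth per sample.
#' @param community_size latent census size for serial-resampling regimes;
#'   sets the per-step strength of drift relative to sequencing noise.
#' @param regime one of the five assembly regimes above.
#' @param selection_sd Gaussian niche breadth in trait units; `NULL` (the
#'   default) uses 0.25 x the realized trait standard deviation.
#' @param trait_bm_rate Brownian-motion variance per unit branch length.
#' @param environment_values per-treatment optimal trait value; `NULL`
#'   derives them from trait quantiles (shared median under
#'   `homogeneous_selection`, spread quantiles under `variable_selection`).
#' @param pool_overlap fraction of the regional pool shared between
#'   replicates; must be 1 except under `dispersal_limitation`.
#' @param mixing_rate per-step mixing weight under `homogenizing_dispersal`.
#' @param pool_sdlog lognormal shape of the regional rank-abundance curve;
#'   the default 2 yields the long rare tail the main/rare partition needs.
#' @param guild_size target size of the selected guild clade under
#'   `homogeneous_selection`.
#' @param seed master seed; all randomness flows from it via [derive_seed()].
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_taxa = 300, n_treatments = 6,
                               n_replicates = 3, n_timepoints = 29,
                               reads_per_sample = 2000,
                               community_size = 2000,
                               regime = c("homogeneous_selection",
                                          "variable_selection",
                                          "dispersal_limitation",
                                          "homogenizing_dispersal", "drift"),
                               selection_sd = NULL, trait_bm_rate = 1,
                               environment_values = NULL,
                               pool_overlap = NULL, mixing_rate = 0.5,
                               pool_sdlog = 2, guild_size = 30, seed = 1) {
  regime <- match.arg(regime)
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  if (is.null(pool_overlap))
    pool_overlap <- if (regime == "dispersal_limitation") 0 else 1
  if (regime != "dispersal_limitation" && pool_overlap != 1)
    stop("pool_overlap must be 1 for all regimes except dispersal_limitation")
  if (pool_overlap < 0 || pool_overlap > 1) stop("pool_overlap must be in [0,1]")
  if (mixing_rate < 0 || mixing_rate > 1) stop("mixing_rate must be in [0,1]")
  if (!is.null(environment_values) && length(environment_values) != n_treatments)
    stop("environment_values must have one entry per treatment")
  if (!is.null(selection_sd) && selection_sd <= 0)
    stop("selection_sd must be positive")
  structure(list(n_taxa = n_taxa, n_treatments = n_treatments,
                 n_replicates = n_replicates, n_timepoints = n_timepoints,
                 reads_per_sample = reads_per_sample,
                 community_size = community_size, regime = regime,
                 selection_sd = selection_sd, trait_bm_rate = trait_bm_rate,
                 environment_values = environment_values,
                 pool_overlap = pool_overlap, mixing_rate = mixing_rate,
                 pool_sdlog = pool_sdlog, guild_size = guild_size,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Simulate a phylogeny with Brownian traits
#'
#' Pure-birth tree with branch lengths plus a continuous trait evolved by
#' Brownian motion along its branches, so closely related tips carry
#' correlated substrate-affinity traits. The trait is what the selection
#' regimes filter on, which is what makes selection phylogenetically
#' detectable by betaNTI.
#'
#' @param n_taxa number of tips (>= 3).
#' @param trait_bm_rate BM variance per unit branch length (0 gives all tips
#'   the root value).
#' @param seed integer seed.
#' @return List with `tree` (an `ape::phylo`), `newick` (string), and
#'   `traits` (named numeric vector over tips).
#' @export
simulate_tree_and_traits <- function(n_taxa, trait_bm_rate = 1, seed = 1) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  if (trait_bm_rate < 0) stop("trait_bm_rate must be >= 0")
  set.seed(derive_seed(seed, "tree_and_traits"))
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$tip.label <- sprintf("otu%04d", seq_len(n_taxa))
  traits <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(trait_bm_rate),
                            root.value = 0)
  list(tree = tree, newick = ape::write.tree(tree), traits = traits)
}

#' Build the full ground truth for a scenario
#'
#' Draws the phylogeny, traits, lognormal pool abundances, per-treatment
#' environments and (for dispersal limitation) the per-replicate subpools,
#' and records the per-comparison-class process label the regime plants.
#'
#' @param scenario a [synthetic_scenario()].
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  tt <- simulate_tree_and_traits(sc$n_taxa, sc$trait_bm_rate, sc$seed)
  set.seed(derive_seed(sc$seed, "pool"))
  ab <- rlnorm(sc$n_taxa, meanlog = 0, sdlog = sc$pool_sdlog)
  pool <- setNames(ab / sum(ab), tt$tree$tip.label)

  traits <- tt$traits
  sel_sd <- sc$selection_sd
  if (is.null(sel_sd)) sel_sd <- 0.25 * stats::sd(traits)
  if (sel_sd == 0) sel_sd <- 1e-9
  env <- sc$environment_values
  if (is.null(env)) {
    env <- switch(sc$regime,
      homogeneous_selection = rep(stats::median(traits), sc$n_treatments),
      variable_selection = unname(stats::quantile(
        traits, probs = seq(0.05, 0.95, length.out = sc$n_treatments))),
      rep(stats::median(traits), sc$n_treatments))
  }

  guild <- NULL
  if (sc$regime == "homogeneous_selection") {
    # the selected guild: the clade closest in size to guild_size
    nodes <- (sc$n_taxa + 1):(sc$n_taxa + tt$tree$Nnode)
    sizes <- vapply(nodes, function(n)
      length(ape::extract.clade(tt$tree, n)$tip.label), integer(1))
    node <- nodes[which.min(abs(sizes - sc$guild_size))]
    guild <- match(ape::extract.clade(tt$tree, node)$tip.label,
                   tt$tree$tip.label)
  }

  subpools <- NULL
  if (sc$regime == "dispersal_limitation") {
    set.seed(derive_seed(sc$seed, "subpools"))
    n_shared <- round(sc$pool_overlap * sc$n_taxa)
    shared <- sample(sc$n_taxa, n_shared)
    rest <- setdiff(seq_len(sc$n_taxa), shared)
    part <- split(sample(rest), rep_len(seq_len(sc$n_replicates), length(rest)))
    subpools <- lapply(seq_len(sc$n_replicates), function(r)
      sort(c(shared, part[[r]])))
  }

# the comparison class each regime is diagnostic for, and its label
  expected <- switch(sc$regime,
    homogeneous_selection = c(within_replicates = "homogeneous_selection"),
    variable_selection = c(between_cs = "variable_selection"),
    dispersal_limitation = c(within_replicates = "dispersal_limitation"),
    homogenizing_dispersal = c(within_replicates = "homogenizing_dispersal"),
    drift = c(within_replicates = "undominated"))

  structure(list(scenario = sc, tree = tt$tree, newick = tt$newick,
                 traits = traits, pool_abundances = pool,
                 selection_sd = sel_sd, environment_values = env,
                 guild = guild, subpools = subpools,
                 expected_process = expected, planted_couplings = NULL),
            class = "synthetic_truth")
}

selection_weights <- function(pool, traits, e, sel_sd) {
  w <- pool * exp(-(traits - e)^2 / (2 * sel_sd^2))
  if (sum(w) == 0) stop("selection filter removed all taxa; widen selection_sd")
  w / sum(w)
}

#' Assemble a replicated treatment-by-time community table
#'
#' Generates the count table a sequencing run would produce under the
#' scenario's regime. Selection regimes draw every sample multinomially from
#' Gaussian-filtered pool weights; dispersal/drift regimes propagate a latent
#' community of `community_size` individuals by serial multinomial
#' resampling (Wright-Fisher drift) and observe it with `reads_per_sample`
#' multinomial draws. Sample ids are `<treatment>_r<rep>_t<time>`; timepoints
#' are `0, 1, ...` in sampling order.
#'
#' @param truth a [synthetic_truth()] (or a [synthetic_scenario()], which is
#'   expanded with [synthetic_truth()] first).
#' @return A [community_matrix()] whose taxa are the tree tips; every sample
#'   sums to `reads_per_sample`.
#' @export
assemble_timeseries <- function(truth) {
  if (inherits(truth, "synthetic_scenario")) truth <- synthetic_truth(truth)
  stopifnot(inherits(truth, "synthetic_truth"))
  sc <- truth$scenario
  nt <- sc$n_taxa
  pool <- truth$pool_abundances
  traits <- truth$traits
  set.seed(derive_seed(sc$seed, "assembly"))

  treatments <- sprintf("trt%02d", seq_len(sc$n_treatments))
  counts <- NULL
  meta <- NULL
  for (ti in seq_len(sc$n_treatments)) {
    if (sc$regime == "homogeneous_selection") {
      # deterministic confinement to the guild clade; within the guild a
      # founder lottery partitions members among replicates each sampling
      # interval (priority effects), so replicates share the selective
      # environment but turn over taxonomically inside it
      for (tp in seq_len(sc$n_timepoints)) {
        assign_r <- sample(rep_len(seq_len(sc$n_replicates),
                                   length(truth$guild)))
        for (r in seq_len(sc$n_replicates)) {
          w <- numeric(nt)
          w[truth$guild[assign_r == r]] <- 1
          y <- rmultinom(1, sc$reads_per_sample, w / sum(w))[, 1]
          counts <- cbind(counts, y)
          meta <- rbind(meta, data.frame(
            sample = sprintf("%s_r%d_t%02d", treatments[ti], r, tp - 1),
            treatment = treatments[ti], replicate = sprintf("r%d", r),
            timepoint = tp - 1))
        }
      }
      next
    }
    w <- switch(sc$regime,
      variable_selection = selection_weights(pool, traits,
                                             truth$environment_values[ti],
                                             truth$selection_sd),
      pool)
    serial <- sc$regime %in% c("dispersal_limitation",
                               "homogenizing_dispersal", "drift")
    # latent proportions per replicate (serial regimes)
    lat <- vector("list", sc$n_replicates)
    for (r in seq_len(sc$n_replicates)) {
      wr <- w
      if (sc$regime == "dispersal_limitation") {
        wr <- numeric(nt)
        wr[truth$subpools[[r]]] <- pool[truth$subpools[[r]]]
        wr <- wr / sum(wr)
      }
      if (serial)
        lat[[r]] <- rmultinom(1, sc$community_size, wr)[, 1] / sc$community_size
      else
        lat[[r]] <- wr
    }
    for (tp in seq_len(sc$n_timepoints)) {
      if (serial && tp > 1) {
        for (r in seq_len(sc$n_replicates))
          lat[[r]] <- rmultinom(1, sc$community_size, lat[[r]])[, 1] /
            sc$community_size
        if (sc$regime == "homogenizing_dispersal") {
          avg <- Reduce(`+`, lat) / sc$n_replicates
          lat <- lapply(lat, function(p)
            (1 - sc$mixing_rate) * p + sc$mixing_rate * avg)
        }
      }
      for (r in seq_len(sc$n_replicates)) {
        y <- rmultinom(1, sc$reads_per_sample, lat[[r]])[, 1]
        counts <- cbind(counts, y)
        meta <- rbind(meta, data.frame(
          sample = sprintf("%s_r%d_t%02d", treatments[ti], r, tp - 1),
          treatment = treatments[ti], replicate = sprintf("r%d", r),
          timepoint = tp - 1))
      }
    }
  }
  rownames(counts) <- names(pool)
  colnames(counts) <- meta$sample
  suppressWarnings(community_matrix(counts, meta))
}

# Largest-remainder rounding of proportions p to integers summing to total.
quantize_counts <- function(p, total) {
  x <- p * total
  f <- floor(x)
  k <- total - sum(f)
  if (k > 0) {
    ord <- order(x - f, decreasing = TRUE)
    f[ord[seq_len(k)]] <- f[ord[seq_len(k)]] + 1
  }
  as.integer(f)
}

#' Plant lagged pairwise couplings into a community table
#'
#' Overwrites follower-taxon trajectories as a (possibly lagged, possibly
#' sign-flipped) copy of a driver trajectory plus Gaussian noise, then
#' re-normalizes each sample and re-quantizes to integers preserving sample
#' totals (deterministic largest-remainder rounding, so noise-free couplings
#' stay exact up to quantization). Positive couplings copy the driver's
#' relative-abundance series; negative couplings use its range reflection
#' `max + min - x`, whose rank order is exactly reversed. Used as ground
#' truth for local similarity network recovery.
#'
#' @param cm a [community_matrix()].
#' @param couplings data frame with columns `driver`, `follower`, `lag`
#'   (integer >= 0), `sign` (+1/-1).
#' @param noise_sd Gaussian noise, in units of the driver series SD.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param max_lag guard on `lag` (default 3).
#' @return A [community_matrix()] with identical sample totals.
#' @export
plant_couplings <- function(cm, couplings, noise_sd = 0, seed = 1,
                            max_lag = 3) {
  stopifnot(inherits(cm, "community_matrix"))
  if (is.null(couplings) || nrow(as.data.frame(couplings)) == 0) return(cm)
  couplings <- as.data.frame(couplings)
  stopifnot(all(c("driver", "follower", "lag", "sign") %in% names(couplings)))
  bad <- setdiff(c(couplings$driver, couplings$follower), taxa_ids(cm))
  if (length(bad)) stop("unknown coupled taxa: ", paste(bad, collapse = ", "))
  if (any(couplings$lag < 0 | couplings$lag > max_lag))
    stop("lags must be in [0, ", max_lag, "]")
  if (any(couplings$driver == couplings$follower))
    stop("driver and follower must differ")
  set.seed(derive_seed(seed, "plant_couplings"))

  counts <- cm$counts
  md <- cm$metadata
  rel <- tss_normalize(counts)
  traj <- split(seq_len(nrow(md)), list(md$treatment, md$replicate),
                drop = TRUE)
  for (idx in traj) {
    idx <- idx[order(md$timepoint[idx])]
    ntp <- length(idx)
    if (any(couplings$lag >= ntp)) stop("lag must be < number of timepoints")
    for (ci in seq_len(nrow(couplings))) {
      drv <- couplings$driver[ci]; fol <- couplings$follower[ci]
      lag <- couplings$lag[ci]; sgn <- couplings$sign[ci]
      x <- rel[drv, idx]
      y <- x[pmax(1, seq_len(ntp) - lag)]
      if (sgn < 0) y <- max(x) + min(x) - y
      if (noise_sd > 0) y <- y + rnorm(ntp, 0, noise_sd * stats::sd(x))
      y <- pmin(pmax(y, 0), 0.9)
      fi <- match(fol, taxa_ids(cm)); di <- match(drv, taxa_ids(cm))
      for (k in seq_len(ntp)) {
        s <- idx[k]
        p <- rel[, s]
        # hold the driver fixed so the planted relation stays exact;
        # absorb the follower's change into the remaining taxa
        yk <- min(y[k], 1 - p[di])
        others <- setdiff(seq_along(p), c(fi, di))
        rest <- sum(p[others])
        avail <- 1 - yk - p[di]
        if (rest > 0 && avail > 0) {
          p[others] <- p[others] * avail / rest
        } else if (avail <= 0) {
          p[others] <- 0
          yk <- 1 - p[di]
        }
        p[fi] <- yk
        p <- p / sum(p)
        rel[, s] <- p
      }
    }
  }
  tot <- colSums(counts)
  for (s in seq_len(ncol(counts)))
    counts[, s] <- quantize_counts(rel[, s], tot[s])
  suppressWarnings(community_matrix(counts, md))
}

#' Write a synthetic fixture bundle to a directory
#'
#' Writes `counts.tsv`, `metadata.tsv`, `tree.nwk`, and `truth.json`
#' (scenario parameters, expected process labels, planted couplings, seeds).
#' Generator parameters are artifact choices, recorded as such in the JSON.
#'
#' @param truth a [synthetic_truth()].
#' @param cm the matching [community_matrix()] from [assemble_timeseries()].
#' @param dir output directory (created if needed).
#' @param couplings optional planted couplings data frame.
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(truth, cm, dir, couplings = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_community(cm, file.path(dir, "counts.tsv"),
                  file.path(dir, "metadata.tsv"))
  writeLines(truth$newick, file.path(dir, "tree.nwk"))
  info <- list(scenario = unclass(truth$scenario),
               expected_process = as.list(truth$expected_process),
               planted_couplings = couplings,
               note = "synthetic fixture; generator parameters are artifact choices")
  jsonlite::write_json(info, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
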