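#' Rank-based normal-score standardization of a time series
#'
#' Ranks (ties mid-ranked) mapped to normal quantiles, then centered and
#' scaled to unit population variance, making local similarity scores
#' invariant to monotone transforms of the marginal distribution. A constant
#' series standardizes to all zeros with a warning.
#'
#' @param x numeric vector of length >= 4.
#' @return Numeric z-vector with mean 0 and population variance 1.
#' @export
standardize_series <- function(x) {
  n <- length(x)
  if (n < 4) stop("series must have length >= 4")
  if (anyNA(x)) stop("series contains NA")
  if (max(x) == min(x)) {
    warning("constant series standardized to zeros", call. = FALSE)
    return(numeric(n))
  }
  z <- qnorm((rank(x, ties.method = "average") - 0.5) / n)
  z <- z - mean(z)
  z / sqrt(mean(z^2))
}

#' Local similarity between two standardized series
#'
#' Dynamic program over alignment offsets `|d| <= max_delay` finding the
#' maximal-magnitude contiguous partial sum of aligned products, separately
#' for positive and negative runs; the score is that signed sum divided by
#' the series length, so two identical unit-variance z-series score exactly
#' 1. The reported delay `d` means the best alignment pairs `x[t]` with
#' `y[t + d]` (a follower lagging the driver by L is found at `d = L`);
#' `start`/`end` delimit the aligned window in `x` coordinates. Ties prefer
#' smaller |delay|.
#'
#' @param zx,zy standardized series (see [standardize_series()]) of equal
#'   length `n > max_delay`.
#' @param max_delay maximum alignment offset (default 3).
#' @return List: `score` (signed), `delay`, `start`, `end`.
#' @export
local_similarity <- function(zx, zy, max_delay = 3) {
  n <- length(zx)
  if (length(zy) != n) stop("series lengths differ")
  if (n <= max_delay) stop("series length must exceed max_delay")
  cpp_local_similarity(as.numeric(zx), as.numeric(zy), as.integer(max_delay))
}

#' Permutation p-value for a local similarity score
#'
#' Permutes the time order of one series and recomputes |LS|;
#' `p = (1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @inheritParams local_similarity
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
lsa_permutation <- function(zx, zy, max_delay = 3, n_perm = 1000, seed = 1) {
  n <- length(zx)
  if (length(zy) != n) stop("series lengths differ")
  if (n <= max_delay) stop("series length must exceed max_delay")
  set.seed(derive_seed(seed, "lsa_perm"))
  cpp_lsa_pvalue(as.numeric(zx), as.numeric(zy), as.integer(max_delay),
                 as.integer(n_perm))
}

# Per-treatment taxon trajectories: replicate-averaged relative abundances,
# one column per timepoint in time order.
treatment_trajectories <- function(cm, treatment, replicate_mode = "average") {
  md <- cm$metadata
  sel <- md$treatment == treatment
  if (!any(sel)) stop("unknown treatment: ", treatment)
  rel <- tss_normalize(cm)[, sel, drop = FALSE]
  md <- md[sel, , drop = FALSE]
  if (replicate_mode == "average") {
    tps <- sort(unique(md$timepoint))
    out <- vapply(tps, function(tp)
      rowMeans(rel[, md$timepoint == tp, drop = FALSE]), numeric(nrow(rel)))
    colnames(out) <- as.character(tps)
  } else {
    ord <- order(md$replicate, md$timepoint)
    out <- rel[, ord, drop = FALSE]
  }
  out
}

#' Build a local-similarity interaction network for one treatment
#'
#' Replicate trajectories are averaged into one relative-abundance series
#' per taxon and timepoint; taxa present in at least `prevalence_min` of
#' timepoints are normal-score standardized and every pair is scored with
#' [local_similarity()] and tested with [lsa_permutation()]. Benjamini-
#' Hochberg FDR is applied across all tested pairs; pairs with
#' `q <= q_max` become signed edges.
#'
#' @param cm a [community_matrix()].
#' @param treatment treatment whose network to build.
#' @param max_delay maximum time delay (default 3).
#' @param n_perm permutations per pair (default 1000).
#' @param q_max FDR threshold for edges (default 0.05).
#' @param seed integer seed.
#' @param prevalence_min minimum fraction of timepoints a taxon must be
#'   present in to enter the network (default 0.25).
#' @param replicate_mode `"average"` (default) or `"concatenate"`.
#' @return List: `edges` (significant pairs: `taxon_a`, `taxon_b`, `ls`,
#'   `delay`, `p_value`, `q_value`, `sign`), `tests` (all tested pairs),
#'   `summary` (positive/negative edge counts and their ratio, `NA` when
#'   there are no negative edges), and `z` (the standardized series matrix,
#'   for scope classification).
#' @export
build_network <- function(cm, treatment, max_delay = 3, n_perm = 1000,
                          q_max = 0.05, seed = 1, prevalence_min = 0.25,
                          replicate_mode = "average") {
  stopifnot(inherits(cm, "community_matrix"))
  traj <- treatment_trajectories(cm, treatment, replicate_mode)
  ntp <- ncol(traj)
  if (ntp < 8) stop("need at least 8 timepoints per treatment")
  keep <- rowMeans(traj > 0) >= prevalence_min
  traj <- traj[keep, , drop = FALSE]
  if (nrow(traj) < 2) stop("fewer than two taxa pass the prevalence floor")
  z <- t(apply(traj, 1, standardize_series))
  dimnames(z) <- dimnames(traj)

  pr <- t(utils::combn(nrow(z), 2))
  res <- lapply(seq_len(nrow(pr)), function(i) {
    a <- pr[i, 1]; b <- pr[i, 2]
    ls <- local_similarity(z[a, ], z[b, ], max_delay)
    p <- lsa_permutation(z[a, ], z[b, ], max_delay, n_perm,
                         seed = derive_seed(seed, paste0("pair", i)))
    data.frame(taxon_a = rownames(z)[a], taxon_b = rownames(z)[b],
               ls = ls$score, delay = ls$delay, start = ls$start,
               end = ls$end, p_value = p)
  })
  tests <- do.call(rbind, res)
  tests$q_value <- p.adjust(tests$p_value, method = "BH")
  tests$sign <- ifelse(tests$ls >= 0, "positive", "negative")
  edges <- tests[tests$q_value <= q_max, , drop = FALSE]
  rownames(edges) <- NULL
  n_pos <- sum(edges$sign == "positive")
  n_neg <- sum(edges$sign == "negative")
  summary <- data.frame(treatment = treatment, positive = n_pos,
                        negative = n_neg,
                        ratio = if (n_neg > 0) n_pos / n_neg else NA_real_)
  list(edges = edges, tests = tests, summary = summary, z = z,
       params = list(max_delay = max_delay, n_perm = n_perm, q_max = q_max,
                     seed = seed))
}

#' Classify network edges as global or local-only
#'
#' A candidate pair is `global` if it is significant over the full series
#' (its full-series q from [build_network()] is at or below `q_max`). A pair
#' that is not globally significant but reaches `q <= q_max` (BH within its
#' own window batch) in at least one sliding window of `window_length`
#' timepoints is `local_only`; anything else is not an edge.
#'
#' @param net output of [build_network()].
#' @param window_length sliding window length in timepoints (default 10).
#' @param step window step (default 1).
#' @param n_perm permutations per window test (default: as the network).
#' @return The `tests` table with `scope` (`"global"`, `"local_only"` or
#'   `NA`) and `window` (`"start:end"` of the first significant window for
#'   local-only edges).
#' @export
classify_edge_scope <- function(net, window_length = 10, step = 1,
                                n_perm = NULL) {
  z <- net$z
  ntp <- ncol(z)
  if (window_length > ntp) stop("window_length exceeds the series length")
  if (is.null(n_perm)) n_perm <- net$params$n_perm
  q_max <- net$params$q_max
  D <- net$params$max_delay
  tests <- net$tests
  tests$scope <- ifelse(tests$q_value <= q_max, "global", NA_character_)
  tests$window <- NA_character_

  starts <- seq(1, ntp - window_length + 1, by = step)
  todo <- which(is.na(tests$scope))
  for (i in todo) {
    a <- match(tests$taxon_a[i], rownames(z))
    b <- match(tests$taxon_b[i], rownames(z))
    wd <- min(D, window_length - 1)
    pw <- vapply(starts, function(s) {
      w <- s:(s + window_length - 1)
      zx <- suppressWarnings(standardize_series(z[a, w]))
      zy <- suppressWarnings(standardize_series(z[b, w]))
      lsa_permutation(zx, zy, wd, n_perm,
                      seed = derive_seed(net$params$seed,
                                         paste0("win", i, "_", s)))
    }, numeric(1))
    qw <- p.adjust(pw, method = "BH")
    hit <- which(qw <= q_max)
    if (length(hit)) {
      tests$scope[i] <- "local_only"
      s <- starts[hit[1]]
      tests$window[i] <- paste0(s, ":", s + window_length - 1)
    }
  }
  tests
}
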