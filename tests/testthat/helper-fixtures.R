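# Small in-code fixtures shared across test files.

make_cm <- function(counts, treatments = NULL, replicates = NULL,
                    timepoints = NULL) {
  ns <- ncol(counts)
  md <- data.frame(
    sample = colnames(counts),
    treatment = if (is.null(treatments)) rep("a", ns) else treatments,
    replicate = if (is.null(replicates)) paste0("r", seq_len(ns)) else replicates,
    timepoint = if (is.null(timepoints)) rep(0, ns) else timepoints
  )
  community_matrix(counts, md)
}

rand_counts <- function(nt, ns, lambda = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rpois(nt * ns, lambda), nt, ns,
              dimnames = list(paste0("t", seq_len(nt)),
                              paste0("s", seq_len(ns))))
  # ensure no empty sample
  m[1, colSums(m) == 0] <- 1L
  m
}

# 3-tip tree used in hand-computed patristic / betaMNTD examples
tree3 <- "((A:1,B:1):1,C:2);"
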