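#' Build and validate a pipeline configuration
#'
#' Collects input paths, thresholds, permutation counts, the master seed and
#' stage toggles for [run_pipeline()]. Defaults are the conventional
#' thresholds of the analysis framework: main > 1% and rare < 0.1% mean
#' relative abundance, selection at |betaNTI| > 2, dispersal at |RC| > 0.95,
#' indicators at IndVal > 0.5 and p < .05, network FDR q <= 0.05 with
#' maximum delay 3; 999 null randomizations and 1000 LSA permutations.
#'
#' @param counts,metadata,tree input file paths (see [read_community()];
#'   `tree` is newick).
#' @param out_dir output directory for the report bundle.
#' @param main_threshold,rare_threshold subcommunity cutoffs (proportions).
#' @param bnti_threshold,rc_threshold,indval_min,alpha,q_max,max_delay
#'   analysis thresholds.
#' @param n_null,n_lsa_perm permutation counts.
#' @param seed master seed; stages derive child seeds via [derive_seed()].
#' @param stages character subset of
#'   `c("assembly", "structure", "indicator", "network")`.
#' @param time_resolved also compute per-timepoint partitions.
#' @param subcommunities subcommunity runs for the assembly stage.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts, metadata, tree, out_dir,
                            main_threshold = 0.01, rare_threshold = 0.001,
                            bnti_threshold = 2, rc_threshold = 0.95,
                            indval_min = 0.5, alpha = 0.05, q_max = 0.05,
                            max_delay = 3, n_null = 999, n_lsa_perm = 1000,
                            seed = 1,
                            stages = c("assembly", "structure", "indicator",
                                       "network"),
                            time_resolved = FALSE,
                            subcommunities = c("all", "main", "rare")) {
  cfg <- list(counts = counts, metadata = metadata, tree = tree,
              out_dir = out_dir, main_threshold = main_threshold,
              rare_threshold = rare_threshold,
              bnti_threshold = bnti_threshold, rc_threshold = rc_threshold,
              indval_min = indval_min, alpha = alpha, q_max = q_max,
              max_delay = max_delay, n_null = n_null,
              n_lsa_perm = n_lsa_perm, seed = as.integer(seed),
              stages = stages, time_resolved = time_resolved,
              subcommunities = subcommunities)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$main_threshold <= cfg$rare_threshold)
    stop("main_threshold must exceed rare_threshold")
  stopifnot(cfg$bnti_threshold > 0, cfg$rc_threshold > 0,
            cfg$alpha > 0, cfg$alpha < 1, cfg$q_max > 0, cfg$q_max <= 1,
            cfg$n_null >= 99, cfg$n_lsa_perm >= 99, cfg$max_delay >= 0)
  bad <- setdiff(cfg$stages, c("assembly", "structure", "indicator",
                               "network"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(cfg$subcommunities, c("all", "main", "rare"))
  if (length(bad)) stop("unknown subcommunity: ", paste(bad, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()] exactly.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full community-assembly analysis pipeline
#'
#' Load and validate inputs, TSS-normalize, partition subcommunities, run
#' the null-model process partition (both comparison classes, each requested
#' subcommunity, optionally time-resolved), structure statistics
#' (Bray-Curtis, UPGMA clustergram tree, ordination, PERMDISP, ANOSIM,
#' diversity), indicator species, and per-treatment interaction networks,
#' writing a report bundle of TSV/JSON files plus a log. Deterministic for a
#' fixed seed: all stage seeds derive from the master seed.
#'
#' @param config a `pipeline_config` or path to its YAML.
#' @param dry_run validate the configuration and inputs without computing.
#' @return Invisibly, a list with the bundle directory and the summary.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  t_start <- proc.time()[["elapsed"]]
  elapsed <- function() sprintf("%.1fs", proc.time()[["elapsed"]] - t_start)

  cm <- read_community(cfg$counts, cfg$metadata)
  tree <- ape::read.tree(cfg$tree)
  missing <- setdiff(taxa_ids(cm), tree$tip.label)
  if (length(missing))
    stop("stage load: taxa missing from tree: ",
         paste(utils::head(missing, 5), collapse = ", "))
  say("load: %d taxa x %d samples [%s]", nrow(cm$counts), ncol(cm$counts),
      elapsed())
  if (dry_run) {
    say("dry run: configuration and inputs valid")
    writeLines(log_lines, log_path)
    return(invisible(list(out_dir = cfg$out_dir, summary = NULL)))
  }

  # the hash covers the analysis configuration, not output locations
  hcfg <- unclass(cfg); hcfg$out_dir <- NULL
  summary <- list(seed = cfg$seed, config_hash = config_hash(hcfg))
  parts <- partition_subcommunities(cm, cfg$main_threshold, cfg$rare_threshold)
  summary$subcommunity_sizes <- list(
    main = length(parts$main_taxa), rare = length(parts$rare_taxa),
    intermediate = length(parts$intermediate_taxa))

  if ("assembly" %in% cfg$stages) {
    all_pairs <- NULL; all_part <- NULL
    for (sub in cfg$subcommunities) {
      for (cls in c("within_replicates", "between_cs")) {
        res <- tryCatch(
          assembly_partition(cm, tree, cls, sub, n_null = cfg$n_null,
                             seed = derive_seed(cfg$seed,
                                                paste("assembly", cls, sub)),
                             per_timepoint = cfg$time_resolved,
                             main_threshold = cfg$main_threshold,
                             rare_threshold = cfg$rare_threshold),
          error = function(e) stop("stage assembly (", cls, ", ", sub,
                                   "): ", conditionMessage(e)))
        if (nrow(res$pairs)) {
          all_pairs <- rbind(all_pairs, res$pairs)
          all_part <- rbind(all_part, res$partition)
        }
      }
    }
    write_result_tsv(all_pairs, file.path(cfg$out_dir, "pairs.tsv"),
                     cfg$seed, hcfg)
    write_result_tsv(all_part, file.path(cfg$out_dir, "partition.tsv"),
                     cfg$seed, hcfg)
    summary$n_pairs <- nrow(all_pairs)
    say("assembly: %d pairs partitioned [%s]", nrow(all_pairs), elapsed())
  }

  if ("structure" %in% cfg$stages) {
    dm <- bray_curtis(cm)
    ord <- pcoa(dm, k = 2)
    write_result_tsv(data.frame(sample = rownames(ord$points), ord$points),
                     file.path(cfg$out_dir, "ordination.tsv"), cfg$seed,
                     hcfg)
    writeLines(upgma_newick(upgma(dm)),
               file.path(cfg$out_dir, "clustergram.nwk"))
    groups <- cm$metadata$treatment
    stats <- list(
      permdisp = if (length(unique(groups)) > 1)
        permdisp(dm, groups, seed = derive_seed(cfg$seed, "permdisp")),
      anosim = if (length(unique(groups)) > 1)
        anosim_test(dm, groups, seed = derive_seed(cfg$seed, "anosim")))
    summary$structure <- list(
      permdisp_F = stats$permdisp$F, permdisp_p = stats$permdisp$p_value,
      anosim_R = stats$anosim$R, anosim_p = stats$anosim$p_value)
    div <- diversity_indices(cm)
    write_result_tsv(div, file.path(cfg$out_dir, "diversity.tsv"),
                     cfg$seed, hcfg)
    say("structure: ordination, clustergram, diversity written [%s]",
        elapsed())
  }

  if ("indicator" %in% cfg$stages &&
      length(unique(cm$metadata$treatment)) > 1) {
    iv <- indval(cm, n_perm = cfg$n_null,
                 seed = derive_seed(cfg$seed, "indval"))
    write_result_tsv(iv, file.path(cfg$out_dir, "indval.tsv"), cfg$seed,
                     hcfg)
    summary$n_significant_indicators <-
      nrow(significant_indicators(iv, cfg$indval_min, cfg$alpha))
    say("indicator: %d taxa tested [%s]", nrow(iv), elapsed())
  }

  if ("network" %in% cfg$stages) {
    edges <- NULL; nets <- NULL
    for (trt in unique(cm$metadata$treatment)) {
      net <- tryCatch(
        build_network(cm, trt, max_delay = cfg$max_delay,
                      n_perm = cfg$n_lsa_perm, q_max = cfg$q_max,
                      seed = derive_seed(cfg$seed, paste("lsa", trt))),
        error = function(e) stop("stage network (", trt, "): ",
                                 conditionMessage(e)))
      if (nrow(net$edges))
        edges <- rbind(edges, cbind(treatment = trt, net$edges))
      nets <- rbind(nets, net$summary)
    }
    if (is.null(edges))
      edges <- data.frame(treatment = character(), taxon_a = character(),
                          taxon_b = character(), ls = numeric(),
                          delay = integer(), start = integer(),
                          end = integer(), p_value = numeric(),
                          q_value = numeric(), sign = character())
    write_result_tsv(edges, file.path(cfg$out_dir, "edges.tsv"), cfg$seed,
                     hcfg)
    write_result_tsv(nets, file.path(cfg$out_dir, "network_summary.tsv"),
                     cfg$seed, hcfg)
    summary$n_edges <- nrow(edges)
    summary$network <- nets
    say("network: %d edges across %d treatments [%s]", nrow(edges),
        nrow(nets), elapsed())
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  say("done [%s]", elapsed())
  writeLines(log_lines, log_path)
  invisible(list(out_dir = cfg$out_dir, summary = summary))
}
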