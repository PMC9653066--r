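#' Pipeline configuration
#'
#' Validates a configuration for [run_pipeline()]. Exactly one of `input`
#' (paths to a count TSV/BIOM plus metadata, and optional tree / function
#' table) or `synthetic` (arguments for [synthetic_config()]) must be
#' present.
#'
#' @param config a named list, or a path to a YAML/JSON file holding one.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                                simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path",
                             call. = FALSE)
  has_input <- !is.null(config$input)
  has_synth <- !is.null(config$synthetic)
  if (has_input == has_synth)
    stop("config needs exactly one of 'input' or 'synthetic'", call. = FALSE)
  if (has_input) {
    if (is.null(config$input$counts) || is.null(config$input$metadata))
      stop("config$input needs 'counts' and 'metadata' paths", call. = FALSE)
  }
  defaults <- list(rarefaction_depth = NULL, r_threshold = 0.8,
                   p_cut = 0.001, high_q = 0.75, low_q = 0.25, alpha = 0.05,
                   n_permutations = 9999, n_boot = 10000,
                   removal_fraction = 0.5, removal_replicates = 1000,
                   dnci_permutations = 100, generalist_permutations = 1000,
                   path_chains = 4, path_iter = 5000, path_burn_in = 1000,
                   seed = 1, outdir = "netniche_results")
  cfg <- modifyList(defaults, config)
  for (f in c("r_threshold", "p_cut", "high_q", "low_q", "alpha",
              "removal_fraction"))
    check_fraction(cfg[[f]], f, open_lo = TRUE)
  for (f in c("n_permutations", "n_boot", "removal_replicates",
              "dnci_permutations", "generalist_permutations", "path_chains",
              "path_iter", "path_burn_in"))
    check_scalar_count(cfg[[f]], f, min = 1)
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}

run_stage <- function(name, outdir, log, expr) {
  res <- tryCatch(expr, error = function(e) {
    writeLines("FAILED", file.path(outdir, "FAILED"))
    cat(sprintf("stage %s: FAILED (%s)\n", name, conditionMessage(e)),
        file = log, append = TRUE)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  cat(sprintf("stage %s: ok\n", name), file = log, append = TRUE)
  res
}

#' Run the full paired-microbiome analysis pipeline
#'
#' Executes, in order: load or simulate counts; OTU prevalence/abundance
#' filter; optional rarefaction; alpha diversity with gated group tests;
#' PERMANOVA on Bray-Curtis and Jaccard; Venn partition; random-forest
#' screen; function-table comparisons and function diversity (when a
#' function table is available); per-group co-occurrence networks with
#' property suites, bootstrap KS comparisons, 50%-removal stability,
#' robustness sweeps and degree classes; niche breadth/overlap and
#' generalist classification per group; the dispersal-niche continuum
#' test; degree-vs-niche regressions and the Bayesian path model. Every
#' stage writes machine-readable TSV/JSON into `outdir` and logs its seed;
#' re-running with the same config and seed reproduces byte-identical
#' tables. A stage failure aborts with the stage name and leaves a FAILED
#' marker beside the partial outputs.
#'
#' Per-group networks need at least 4 samples per group; the network and
#' downstream stages are the reason pipeline fixtures use more pairs than
#' the three-pair field design.
#'
#' @param config a [pipeline_config()] (or list / YAML path coerced to one).
#' @return invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(cfg$outdir, "run_log.txt")
  cat(sprintf("netniche pipeline\nseed: %d\nR: %s\n", cfg$seed,
              paste(R.version$major, R.version$minor, sep = ".")),
      file = log)
  unlink(file.path(cfg$outdir, "FAILED"))
  out <- list()

  counts <- run_stage("load", cfg$outdir, log, {
    if (!is.null(cfg$synthetic)) {
      args <- modifyList(cfg$synthetic,
                         list(seed = cfg$synthetic$seed %||% cfg$seed))
      sc <- do.call(synthetic_config,
                    args[names(args) %in% names(formals(synthetic_config))])
      sim <- generate_paired_counts(sc)
      write_counts(sim$counts, file.path(cfg$outdir, "counts.tsv"))
      write_json_out(sim$truth[c("true_diff_taxa", "assembly_mode")],
                     file.path(cfg$outdir, "ground_truth.json"))
      out$truth <- sim$truth
      sim$counts
    } else {
      fmt <- if (grepl("\\.biom$", cfg$input$counts)) "biom" else "tsv"
      read_counts(cfg$input$counts, cfg$input$metadata, format = fmt)
    }
  })
  tree <- if (!is.null(cfg$input$tree)) read_newick(cfg$input$tree) else NULL
  ftab <- if (!is.null(cfg$input$functions))
    read_function_table(cfg$input$functions)
  else if (!is.null(cfg$synthetic))
    generate_function_table(counts,
                            n_functions = cfg$synthetic$n_functions %||% 50,
                            map_density = cfg$synthetic$map_density %||% 0.1,
                            seed = stage_seed(cfg$seed, 30))
  else NULL

  filtered <- run_stage("filter", cfg$outdir, log, filter_otus(counts))

  rarefied <- run_stage("rarefy", cfg$outdir, log, {
    depth <- cfg$rarefaction_depth %||% min(colSums(counts$counts))
    rarefy(counts, depth, seed = stage_seed(cfg$seed, 1))
  })

  out$diversity <- run_stage("diversity", cfg$outdir, log, {
    div <- alpha_diversity(rarefied, tree = tree)
    write_tsv(div, file.path(cfg$outdir, "alpha_diversity.tsv"))
    idx <- setdiff(names(div), c("sample_id", "group", "pair"))
    tests <- do.call(rbind, lapply(idx, function(v) {
      r <- tryCatch(auto_group_test(div[[v]], div$group, alpha = cfg$alpha,
                                    variable = v),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(variable = v, method = r$method_used, statistic = r$statistic,
                 p = r$p, normality_p = r$normality_p,
                 homoscedasticity_p = r$homoscedasticity_p)
    }))
    if (!is.null(tests)) {
      tests$p_adjusted <- bh_adjust(tests$p)
      write_tsv(tests, file.path(cfg$outdir, "diversity_tests.tsv"))
    }
    list(indices = div, tests = tests)
  })

  out$permanova <- run_stage("permanova", cfg$outdir, log, {
    res <- lapply(c(bray_curtis = "bray_curtis", jaccard = "jaccard"),
                  function(met) {
      d <- distance_matrix(rarefied, met)
      unclass(permanova(d, sample_groups(rarefied),
                        n_permutations = cfg$n_permutations,
                        seed = stage_seed(cfg$seed, 2), distance_name = met))
    })
    write_json_out(res, file.path(cfg$outdir, "permanova.json"))
    res
  })

  out$venn <- run_stage("venn", cfg$outdir, log, {
    v <- venn_partition(rarefied)
    write_json_out(unclass(v), file.path(cfg$outdir, "venn.json"))
    v
  })

  out$rf <- run_stage("rf_screen", cfg$outdir, log, {
    imp <- rf_screen(filtered, n_trees = cfg$rf_trees %||% 2000,
                     seed = stage_seed(cfg$seed, 3), alpha = cfg$alpha)
    write_tsv(imp, file.path(cfg$outdir, "rf_importance.tsv"))
    imp
  })

  if (!is.null(ftab)) {
    out$functions <- run_stage("functions", cfg$outdir, log, {
      wc <- welch_compare(ftab, sample_groups(counts))
      write_tsv(wc, file.path(cfg$outdir, "function_welch.tsv"))
      fd <- function_diversity(ftab)
      write_tsv(fd, file.path(cfg$outdir, "function_diversity.tsv"))
      list(welch = wc, diversity = fd)
    })
  }

  grp_levels <- sort(unique(sample_groups(filtered)))
  nets <- run_stage("networks", cfg$outdir, log, {
    lapply(setNames(grp_levels, grp_levels), function(g) {
      sub <- subset_counts(filtered, samples = sample_groups(filtered) == g)
      net <- build_network(sub, r_threshold = cfg$r_threshold,
                           p_cut = cfg$p_cut)
      write_network(net, file.path(cfg$outdir,
                                   sprintf("network_%s_edges.tsv", g)),
                    format = "edgelist_tsv")
      net
    })
  })
  out$networks <- nets

  out$properties <- run_stage("properties", cfg$outdir, log, {
    props <- lapply(nets, function(n) unclass(network_properties(n)))
    write_json_out(props, file.path(cfg$outdir, "network_properties.json"))
    props
  })

  out$ks <- run_stage("ks", cfg$outdir, log, {
    boots <- lapply(seq_along(nets), function(i)
      bootstrap_node_attributes(nets[[i]], n_boot = cfg$n_boot,
                                seed = stage_seed(cfg$seed, 10 + i)))
    ks <- lapply(setNames(c("degree", "closeness", "transitivity",
                            "eigenvector"),
                          c("degree", "closeness", "transitivity",
                            "eigenvector")),
                 function(at) unclass(ks_compare(boots[[1]][[at]],
                                                 boots[[2]][[at]],
                                                 attribute = at)))
    write_json_out(ks, file.path(cfg$outdir, "ks_node_attributes.json"))
    ks
  })

  out$stability <- run_stage("stability", cfg$outdir, log, {
    stab <- lapply(seq_along(nets), function(i)
      stability_after_removal(nets[[i]], fraction = cfg$removal_fraction,
                              n_replicates = cfg$removal_replicates,
                              seed = stage_seed(cfg$seed, 20 + i)))
    names(stab) <- names(nets)
    for (g in names(stab))
      write_tsv(stab[[g]], file.path(cfg$outdir,
                                     sprintf("stability_%s.tsv", g)))
    cmp <- list(
      average_degree = unclass(ks_compare(stab[[1]]$average_degree,
                                          stab[[2]]$average_degree,
                                          attribute = "average_degree")),
      natural_connectivity = unclass(ks_compare(
        stab[[1]]$natural_connectivity, stab[[2]]$natural_connectivity,
        attribute = "natural_connectivity")),
      kruskal_average_degree = kruskal.test(
        list(stab[[1]]$average_degree, stab[[2]]$average_degree))$p.value,
      means = lapply(stab, function(s) list(
        average_degree = mean(s$average_degree),
        natural_connectivity = mean(s$natural_connectivity))))
    write_json_out(cmp, file.path(cfg$outdir, "stability_comparison.json"))
    list(replicates = stab, comparison = cmp)
  })

  out$robustness <- run_stage("robustness", cfg$outdir, log, {
    rb <- lapply(seq_along(nets), function(i) {
      lapply(c(nodes = "nodes", edges = "edges"), function(md)
        robustness_sweep(nets[[i]], mode = md,
                         n_replicates = cfg$robustness_replicates %||% 50,
                         seed = stage_seed(cfg$seed, 40 + i)))
    })
    names(rb) <- names(nets)
    for (g in names(rb)) for (md in names(rb[[g]]))
      write_tsv(rb[[g]][[md]]$curve,
                file.path(cfg$outdir, sprintf("robustness_%s_%s.tsv", g, md)))
    rb
  })

  out$degree_classes <- run_stage("degree_classes", cfg$outdir, log, {
    dc <- degree_class_partition(nets[[1]], nets[[2]],
                                 high_q = cfg$high_q, low_q = cfg$low_q)
    write_tsv(dc$shared, file.path(cfg$outdir, "degree_classes_shared.tsv"))
    write_json_out(list(venn = dc$venn, class_abundance = dc$class_abundance),
                   file.path(cfg$outdir, "degree_classes.json"))
    dc
  })

  out$niche <- run_stage("niche", cfg$outdir, log, {
    per_group <- lapply(setNames(grp_levels, grp_levels), function(g) {
      sub <- subset_counts(filtered, samples = sample_groups(filtered) == g)
      b <- levins_breadth(sub)
      o <- pianka_overlap(sub)
      gen <- classify_generalists(sub,
                                  n_perm = cfg$generalist_permutations,
                                  alpha = cfg$alpha,
                                  seed = stage_seed(cfg$seed, 50))
      list(breadth = b, mean_overlap = rowMeans(o, na.rm = TRUE),
           generalists = gen)
    })
    btab <- do.call(rbind, lapply(grp_levels, function(g)
      data.frame(group = g, taxon = names(per_group[[g]]$breadth),
                 breadth = unname(per_group[[g]]$breadth),
                 mean_overlap = unname(per_group[[g]]$mean_overlap),
                 class = per_group[[g]]$generalists$class)))
    write_tsv(btab, file.path(cfg$outdir, "niche_metrics.tsv"))
    per_group
  })

  out$dnci <- run_stage("dnci", cfg$outdir, log, {
    # the unfiltered table keeps the absences the occurrence nulls permute
    dn <- dnci_test(counts, n_perm = cfg$dnci_permutations,
                    seed = stage_seed(cfg$seed, 60))
    write_json_out(list(mean_E = as.list(dn$mean_E),
                        selected_regime = dn$selected_regime),
                   file.path(cfg$outdir, "dnci.json"))
    dn
  })

  out$path <- run_stage("path_model", cfg$outdir, log, {
    ga <- grp_levels[1]; gb <- grp_levels[2]
    deg <- lapply(nets, function(n) igraph::degree(as_igraph(n)))
    recs <- do.call(rbind, lapply(grp_levels, function(g)
      data.frame(group = g, taxon = names(deg[[g]]),
                 degree = unname(deg[[g]]),
                 breadth = unname(out$niche[[g]]$breadth[names(deg[[g]])]),
                 overlap = unname(out$niche[[g]]$mean_overlap[names(deg[[g]])]))))
    recs <- recs[complete.cases(recs), ]
    dd <- delta_degree(out$degree_classes)
    recs$delta_degree <- unname(dd[recs$taxon])

    reg <- list(
      degree_vs_breadth = lapply(setNames(grp_levels, grp_levels), function(g) {
        sub <- recs[recs$group == g, ]
        unclass(fit_regression(sub$breadth, sub$degree))
      }),
      delta_degree_vs_overlap = lapply(setNames(grp_levels, grp_levels),
                                       function(g) {
        sub <- recs[recs$group == g & !is.na(recs$delta_degree), ]
        unclass(fit_regression(sub$overlap, sub$delta_degree))
      }))
    write_json_out(reg, file.path(cfg$outdir, "regressions.json"))

    fit_w <- fit_path_model(recs$group, recs$breadth, recs$degree,
                            n_chains = cfg$path_chains,
                            n_iter = cfg$path_iter,
                            burn_in = cfg$path_burn_in,
                            seed = stage_seed(cfg$seed, 70))
    ov <- recs[!is.na(recs$delta_degree), ]
    fit_o <- fit_path_model(ov$group, ov$overlap, ov$delta_degree,
                            n_chains = cfg$path_chains,
                            n_iter = cfg$path_iter,
                            burn_in = cfg$path_burn_in,
                            seed = stage_seed(cfg$seed, 71))
    write_tsv(rbind(cbind(model = "niche_width_to_degree", fit_w$summary),
                    cbind(model = "niche_overlap_to_delta_degree",
                          fit_o$summary)),
              file.path(cfg$outdir, "path_model.tsv"))
    list(regressions = reg, niche_width = fit_w, niche_overlap = fit_o)
  })

  cat("pipeline complete\n", file = log, append = TRUE)
  invisible(out)
}
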