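# End-to-end orchestration: simulate (or load) a gradient dataset, then run
# clustering, enrichment, gradient statistics, RBP association, and the
# isoform screen, writing every result as a commented TSV plus a JSON
# manifest. All randomness funnels through the single seed in the config.

pipeline_param_defaults <- function() {
  list(
    min_total = 1,          # expression floor (summed TPM) for RNA rows
    cluster_metric = "correlation",
    cluster_linkage = "average",
    cluster_cut = "distance",
    cluster_cut_value = 0.3,
    min_cluster_size = 20,
    enrichment_alpha = 0.05,
    rbp_threshold = 0.85,
    max_ci_width = 0.2,
    strong_cut = 0.5,
    moderate_cut = 0.25,
    weighted_first = 3,
    weighted_last = 24,
    percentile = 20,
    n_perm = 100
  )
}

#' Pipeline configuration
#'
#' @param outdir Output directory for all stage artifacts.
#' @param seed Master seed for every stochastic step.
#' @param stages Character vector of stages to run, in dependency order, from
#'   `c("simulate", "cluster", "enrich", "gradstats", "rbp", "isoforms")`.
#' @param sim A [simulation_config()] used by the `simulate` stage; its seed
#'   is overridden by `seed`.
#' @param input_paths Optional named list of input files (`rna`, `protein`,
#'   `rbp`, `utrs`, `masks`, `clip`, `psi`, `gene_sets`, `annotations`) used
#'   instead of simulation; every referenced file must exist.
#' @param params Named list overriding entries of the default analysis
#'   parameters (see Details). Unknown names are a validation issue.
#' @details Default parameters: expression floor 1 summed TPM;
#'   correlation-distance average-linkage clustering cut at height 0.3;
#'   cluster size floor 20; RBP correlation threshold 0.85; isoform CI width
#'   bound 0.2; delta-PSI cuts 0.5/0.25; weighted-count fraction range 3-24;
#'   percentile 20; 100 permutations for the shuffled-assignment null.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            seed = 1L,
                            stages = c("simulate", "cluster", "enrich",
                                       "gradstats", "rbp", "isoforms"),
                            sim = NULL,
                            input_paths = NULL,
                            params = list()) {
  if (is.null(sim)) sim <- simulation_config(seed = as.integer(seed))
  sim$seed <- as.integer(seed)
  cfg <- structure(
    list(outdir = outdir, seed = as.integer(seed), stages = stages,
         sim = sim, input_paths = input_paths,
         params = utils::modifyList(pipeline_param_defaults(), params)),
    class = "pipeline_config"
  )
  issues <- validate_config(cfg)
  if (length(issues)) {
    stop_cosedim(paste0("Invalid pipeline config:\n",
                        paste("-", issues, collapse = "\n")),
                 "cosedim_validation_error")
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config` (or a bare list with the same fields).
#' @return Character vector of issues; empty when the config is runnable.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  known_stages <- c("simulate", "cluster", "enrich", "gradstats", "rbp",
                    "isoforms")
  bad <- setdiff(config$stages, known_stages)
  if (length(bad)) {
    issues <- c(issues, sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  unknown <- setdiff(names(config$params), names(pipeline_param_defaults()))
  if (length(unknown)) {
    issues <- c(issues, sprintf("unknown parameter(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  p <- utils::modifyList(pipeline_param_defaults(), config$params)
  if (p$moderate_cut >= p$strong_cut) {
    issues <- c(issues, "delta-PSI cuts inverted: moderate_cut must be below strong_cut")
  }
  if (p$rbp_threshold < -1 || p$rbp_threshold > 1) {
    issues <- c(issues, "rbp_threshold must be in [-1, 1]")
  }
  if (p$percentile <= 0 || p$percentile >= 50) {
    issues <- c(issues, "percentile must be in (0, 50)")
  }
  if (!is.null(config$input_paths)) {
    missing <- !vapply(unlist(config$input_paths), file.exists, TRUE)
    if (any(missing)) {
      issues <- c(issues, sprintf("missing input file(s): %s",
                                  paste(unlist(config$input_paths)[missing],
                                        collapse = ", ")))
    }
  }
  issues
}

write_result_tsv <- function(df, path, comment) {
  df <- as_tibble(df)
  num <- vapply(df, is.numeric, TRUE)
  for (cl in names(df)[num]) df[[cl]] <- format_num(df[[cl]])
  lines <- c(paste0("# ", comment),
             paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "\t")))
  writeLines(lines, path)
  path
}

load_pipeline_inputs <- function(paths) {
  list(
    rna = read_profile_tsv(paths$rna, "rna"),
    protein = if (!is.null(paths$protein)) read_profile_tsv(paths$protein, "protein"),
    rbp = if (!is.null(paths$rbp)) read_profile_tsv(paths$rbp, "protein"),
    utrs = if (!is.null(paths$utrs)) read_utr_fasta(paths$utrs),
    masks = if (!is.null(paths$masks)) read_conservation_track(paths$masks),
    clip = if (!is.null(paths$clip)) {
      readr::read_tsv(paths$clip, comment = "#", col_types = "ci", progress = FALSE)
    },
    psi = if (!is.null(paths$psi)) read_psi_table(paths$psi),
    gene_sets = if (!is.null(paths$gene_sets)) read_gmt(paths$gene_sets),
    annotations = if (!is.null(paths$annotations)) {
      readr::read_tsv(paths$annotations, comment = "#", col_types = "cll",
                      progress = FALSE)
    },
    expression = NULL, id_map = NULL, event_scores = NULL, truth = NULL
  )
}

#' Run the co-sedimentation pipeline end to end
#'
#' Stages run in dependency order; each writes its artifacts under `outdir`
#' with a `# key: value` header carrying the seed and the stage parameters,
#' so any stage can be rerun from its declared file inputs alone. Rerunning
#' with the same config overwrites reproducibly (byte-identical outputs).
#'
#' @param config A [pipeline_config()].
#' @return A manifest tibble (`stage`, `status`, `outputs`), invisibly also
#'   written as `manifest.json` together with the parameter echo, seed, and
#'   package version. A stage failure aborts with the partial manifest
#'   attached to the condition.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  issues <- validate_config(config)
  if (length(issues)) {
    stop_cosedim(paste0("Invalid pipeline config:\n",
                        paste("-", issues, collapse = "\n")),
                 "cosedim_validation_error")
  }
  p <- config$params
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- function(stage) {
    sprintf("stage: %s | seed: %d | params: %s", stage, config$seed,
            paste(names(p), unlist(p), sep = "=", collapse = ", "))
  }
  manifest <- tibble(stage = character(), status = character(),
                     outputs = character())
  note <- function(stage, status, outputs = "") {
    manifest <<- bind_rows(manifest,
                           tibble(stage = stage, status = status,
                                  outputs = paste(outputs, collapse = ";")))
  }
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fn) {
    if (!(stage %in% config$stages)) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      note(stage, "failed")
      write_manifest(manifest, config)
      abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
            class = "cosedim_stage_error", manifest = manifest)
    })
  }

  run_stage("simulate", function() {
    if (is.null(config$input_paths)) {
      sim <- simulate_gradient(config$sim)
      paths <- write_simulation(sim, file.path(config$outdir, "sim"))
      state$data <- sim
      note("simulate", "ok", basename(paths))
    } else {
      state$data <- load_pipeline_inputs(config$input_paths)
      note("simulate", "ok", "loaded external inputs")
    }
  })
  if (is.null(state$data)) {
    state$data <- if (is.null(config$input_paths)) {
      simulate_gradient(config$sim)
    } else {
      load_pipeline_inputs(config$input_paths)
    }
  }
  d <- state$data

  run_stage("cluster", function() {
    norm <- suppressMessages(normalize_profiles(d$rna, min_total = p$min_total))
    cl <- cluster_profiles(norm, metric = p$cluster_metric,
                           linkage = p$cluster_linkage,
                           cut = p$cluster_cut, cut_value = p$cluster_cut_value)
    filt <- suppressMessages(filter_clusters_by_size(cl, p$min_cluster_size))
    means <- cluster_mean_profiles(filt, norm)
    state$norm <- norm
    state$clusters <- cl
    state$filtered <- filt
    state$means <- means
    out <- c("cluster_assignment.tsv", "cluster_means.tsv")
    write_result_tsv(filt$assignment,
                     file.path(config$outdir, out[1]), hdr("cluster"))
    write_result_tsv(means, file.path(config$outdir, out[2]), hdr("cluster"))
    jsonlite::write_json(filt$params,
                         file.path(config$outdir, "cluster_params.json"),
                         auto_unbox = TRUE, digits = NA)
    note("cluster", "ok", c(out, "cluster_params.json"))
  })

  run_stage("enrich", function() {
    stopifnot(!is.null(state$filtered), !is.null(d$gene_sets))
    universe <- state$norm$entity_id
    sets <- gene_set_collection(d$gene_sets$sets, universe)
    enr <- purrr::map_dfr(
      split(state$filtered$assignment$entity_id,
            state$filtered$assignment$cluster),
      function(q) suppressWarnings(fisher_enrichment(q, sets, p$enrichment_alpha)),
      .id = "cluster"
    )
    out <- "enrichment.tsv"
    write_result_tsv(enr, file.path(config$outdir, out), hdr("enrich"))
    outputs <- out
    if (!is.null(d$annotations)) {
      scatter <- suppressWarnings(
        cluster_annotation_scatter(state$filtered, d$annotations))
      write_result_tsv(scatter, file.path(config$outdir, "annotation_scatter.tsv"),
                       hdr("enrich"))
      outputs <- c(outputs, "annotation_scatter.tsv")
    }
    state$enrichment <- enr
    note("enrich", "ok", outputs)
  })

  run_stage("gradstats", function() {
    rng <- range(fraction_indices(d$rna))
    wc <- weighted_counts(d$rna, first = max(p$weighted_first, rng[1]),
                          last = min(p$weighted_last, rng[2]))
    write_result_tsv(wc, file.path(config$outdir, "weighted_counts.tsv"),
                     hdr("gradstats"))
    outputs <- "weighted_counts.tsv"
    if (!is.null(d$protein)) {
      pnorm <- suppressMessages(normalize_profiles(d$protein, min_total = 0))
      id_map <- d$id_map %||%
        tibble(rna_id = intersect(d$rna$entity_id, d$protein$entity_id),
               protein_id = intersect(d$rna$entity_id, d$protein$entity_id))
      corrs <- suppressWarnings(
        rna_protein_correlations(state$norm, pnorm, id_map))
      write_result_tsv(corrs, file.path(config$outdir, "rna_protein_corr.tsv"),
                       hdr("gradstats"))
      outputs <- c(outputs, "rna_protein_corr.tsv")
      if (!is.null(d$annotations)) {
        ann <- d$annotations |> select("entity_id", flag = "has_signal")
        rates <- percentile_annotation_rate(
          corrs |> rename(entity_id = "rna_id"), ann, pct = p$percentile)
        write_result_tsv(tibble(top_rate = rates$top_rate,
                                bottom_rate = rates$bottom_rate,
                                n_tail = rates$n_tail),
                         file.path(config$outdir, "percentile_rates.tsv"),
                         hdr("gradstats"))
        outputs <- c(outputs, "percentile_rates.tsv")
      }
      null <- shuffled_assignment_null(state$filtered, pnorm,
                                       n_perm = p$n_perm, seed = config$seed)
      test <- perm_null_test(null)
      write_result_tsv(null$observed,
                       file.path(config$outdir, "cluster_protein_medians.tsv"),
                       hdr("gradstats"))
      write_result_tsv(
        null$null, file.path(config$outdir, "perm_null.tsv"),
        sprintf("%s | n_perm: %d | one_sided_p: %s", hdr("gradstats"),
                null$n_perm, format_num(test$p_value)))
      outputs <- c(outputs, "cluster_protein_medians.tsv", "perm_null.tsv")
      state$perm_null <- null
      state$rna_protein <- corrs
    }
    note("gradstats", "ok", outputs)
  })

  run_stage("rbp", function() {
    stopifnot(!is.null(d$rbp))
    rbp_norm <- suppressMessages(normalize_profiles(d$rbp, min_total = 0))
    target_rbp <- if (!is.null(d$truth)) d$truth$planted_rbp else rbp_norm$entity_id[1L]
    rc <- correlate_rbp_to_rnas(state$norm,
                                rbp_norm[rbp_norm$entity_id == target_rbp, ],
                                threshold = p$rbp_threshold)
    write_result_tsv(rc, file.path(config$outdir, "rbp_rna_corr.tsv"), hdr("rbp"))
    outputs <- "rbp_rna_corr.tsv"
    if (!is.null(state$means)) {
      rbc <- correlate_rbps_to_clusters(rbp_norm, state$means,
                                        threshold = p$rbp_threshold)
      write_result_tsv(rbc, file.path(config$outdir, "rbp_cluster_corr.tsv"),
                       hdr("rbp"))
      outputs <- c(outputs, "rbp_cluster_corr.tsv")
    }
    if (!is.null(d$utrs)) {
      fg_ids <- rc$entity_id[rc$correlated]
      bg_ids <- setdiff(rc$entity_id, fg_ids)
      hx <- hexamer_enrichment(d$utrs |> filter(.data$entity_id %in% fg_ids),
                               d$utrs |> filter(.data$entity_id %in% bg_ids))
      if (!is.null(d$masks)) {
        cons <- hexamer_conservation_rate(d$utrs, d$masks)
        hx <- left_join(hx, cons |> select("hexamer", "conservation_rate"),
                        by = "hexamer")
        class(hx) <- c("hexamer_stats", class(tibble()))
      }
      write_result_tsv(hx, file.path(config$outdir, "hexamers.tsv"), hdr("rbp"))
      outputs <- c(outputs, "hexamers.tsv")
      state$hexamers <- hx
    }
    if (!is.null(d$clip) && !is.null(d$expression)) {
      cb <- suppressWarnings(clip_density_by_bin(d$clip, d$expression, rc))
      write_result_tsv(cb$medians, file.path(config$outdir, "clip_bins.tsv"),
                       hdr("rbp"))
      outputs <- c(outputs, "clip_bins.tsv")
      state$clip_bins <- cb
    }
    state$rbp_corr <- rc
    note("rbp", "ok", outputs)
  })

  run_stage("isoforms", function() {
    stopifnot(!is.null(d$psi))
    conf <- suppressMessages(filter_confident(d$psi, p$max_ci_width))
    ev <- classify_events(max_delta_psi(conf),
                          strong_cut = p$strong_cut,
                          moderate_cut = p$moderate_cut)
    write_result_tsv(ev, file.path(config$outdir, "isoform_events.tsv"),
                     hdr("isoforms"))
    outputs <- "isoform_events.tsv"
    if (!is.null(d$event_scores)) {
      ct <- suppressWarnings(conservation_group_test(ev, d$event_scores))
      write_result_tsv(ct$tests, file.path(config$outdir, "psi_conservation_tests.tsv"),
                       hdr("isoforms"))
      write_result_tsv(ct$ecdf, file.path(config$outdir, "psi_conservation_ecdf.tsv"),
                       hdr("isoforms"))
      outputs <- c(outputs, "psi_conservation_tests.tsv", "psi_conservation_ecdf.tsv")
    }
    state$events <- ev
    note("isoforms", "ok", outputs)
  })

  write_manifest(manifest, config)
  invisible(manifest)
}

write_manifest <- function(manifest, config) {
  jsonlite::write_json(
    list(stages = manifest,
         seed = config$seed,
         params = config$params,
         version = as.character(utils::packageVersion("cosedim"))),
    file.path(config$outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}
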