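# Seeded synthetic-gradient generator. Emits RNA/protein/RBP fraction
# profiles, UTR sequences with conservation masks, CLIP counts, a PSI table,
# gene sets, and annotations -- together with the ground truth that produced
# them -- so every downstream stage can be validated against known answers.

#' Configuration for the synthetic gradient
#'
#' Defaults emulate a 24-fraction sucrose gradient in which fractions 3-24
#' yield usable RNA and fractions 3-19 usable protein, with genes grouped into
#' K co-sedimenting compartments whose mean profiles are enriched 2- to 4-fold
#' over uniform at their peak.
#'
#' @param n_fractions Fractions collected (default 24).
#' @param rna_fractions,protein_fractions Physical fraction numbers with
#'   usable RNA (default 3:24) and protein (default 3:19).
#' @param n_compartments Number of planted co-sedimentation compartments K
#'   (default 6: a light-edge shape, K-2 interior truncated-Gaussian kernels,
#'   and a dense-edge shape).
#' @param genes_per_compartment Genes per compartment (default 150).
#' @param n_background Extra genes with independent random kernels that belong
#'   to no compartment (default 50); these end up as singletons or small
#'   clusters.
#' @param alpha Mixing weight of the compartment kernel against a uniform
#'   baseline in each gene's mean profile (default 0.9; 1 = pure kernel).
#' @param noise_sigma Log-normal multiplicative noise sd on each cell
#'   (default 0.2).
#' @param scale_meanlog,scale_sdlog Per-gene total-abundance (summed TPM)
#'   log-normal parameters (defaults log(20) and 1).
#' @param n_proteins Genes with a measured protein profile (default 400).
#' @param secreted_prob_target,secreted_prob_other Probability a gene is
#'   flagged secreted in the secretory compartment (0.8) versus elsewhere
#'   (0.1). Secreted genes' proteins co-sediment with their RNA; all other
#'   proteins use the fraction-reversed kernel (anti-coupled).
#' @param apex_prob_target,apex_prob_other Probabilities of the
#'   proximity-labeling (APEX-like) annotation, same structure.
#' @param n_rbps RBP peptide profiles, tracking compartments 1..n_rbps
#'   (default 5); the RBP tracking the secretory compartment carries the
#'   planted 3' UTR hexamer.
#' @param planted_hexamer Hexamer planted in target-gene UTRs (default
#'   "TGCATG").
#' @param plant_rate Fraction of target UTRs receiving the motif (default 0.6).
#' @param utr_length_range UTR lengths drawn uniformly in this range
#'   (default 150-500 nt).
#' @param conservation_baseline Per-base conservation probability outside
#'   planted motifs (default 0.5); planted motif bases are fully conserved.
#' @param clip_base_rate CLIP sites per unit mean TPM for unrelated genes
#'   (default 2); counts are Poisson with a rate multiplier ramping smoothly
#'   with a gene's kernel correlation to the RBP, reaching
#'   `clip_target_multiplier` (default 3) on true targets.
#' @param psi_events Named counts of planted isoform events per delta-PSI
#'   class, `c(strong = , moderate = , non = )`.
#' @param psi_noise_sd Per-fraction PSI estimation noise sd (default 0.01).
#' @param ci_width_range Confidence-interval widths for well-estimated
#'   isoforms (default 0.02-0.15).
#' @param wide_ci_rate Fraction of events given one poorly estimated isoform
#'   (CI width in `wide_ci_width_range`), exercising the confidence filter.
#' @param conservation_shift Mean conservation-score shift per event class
#'   (scores are unit-variance normal).
#' @param seed Master seed; every sub-generator derives its own stream from it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_fractions = 24,
                              rna_fractions = 3:24,
                              protein_fractions = 3:19,
                              n_compartments = 6,
                              genes_per_compartment = 150,
                              n_background = 50,
                              alpha = 0.9,
                              noise_sigma = 0.2,
                              scale_meanlog = log(20),
                              scale_sdlog = 1,
                              n_proteins = 400,
                              secreted_prob_target = 0.8,
                              secreted_prob_other = 0.1,
                              apex_prob_target = 0.8,
                              apex_prob_other = 0.1,
                              n_rbps = 5,
                              planted_hexamer = "TGCATG",
                              plant_rate = 0.6,
                              utr_length_range = c(150, 500),
                              conservation_baseline = 0.5,
                              clip_base_rate = 2,
                              clip_target_multiplier = 3,
                              psi_events = c(strong = 15, moderate = 15, non = 20),
                              psi_noise_sd = 0.01,
                              ci_width_range = c(0.02, 0.15),
                              wide_ci_rate = 0.1,
                              wide_ci_width_range = c(0.25, 0.4),
                              conservation_shift = c(strong = 1, moderate = 0.7,
                                                     non_regulated = 0),
                              seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (genes_per_compartment < 1) {
      stop_cosedim("`genes_per_compartment` must be at least 1.",
                   "cosedim_validation_error")
    }
    if (n_compartments < 2) {
      stop_cosedim("Need at least 2 compartments.", "cosedim_validation_error")
    }
    stopifnot(all(rna_fractions >= 1), all(rna_fractions <= n_fractions),
              all(protein_fractions %in% seq_len(n_fractions)))
    assert_scalar_number(alpha, "alpha", min = 0, max = 1)
    assert_scalar_number(noise_sigma, "noise_sigma", min = 0)
    assert_scalar_number(plant_rate, "plant_rate", min = 0, max = 1)
    assert_scalar_number(wide_ci_rate, "wide_ci_rate", min = 0, max = 1)
    if (!grepl("^[ACGT]{6}$", planted_hexamer)) {
      stop_cosedim("`planted_hexamer` must be a 6-mer over ACGT.",
                   "cosedim_validation_error")
    }
    if (n_rbps > n_compartments) {
      stop_cosedim("`n_rbps` cannot exceed `n_compartments`.",
                   "cosedim_validation_error")
    }
  })
  invisible(cfg)
}

# Sedimentation kernels over a fraction grid: a light-edge exponential decay,
# interior truncated Gaussians, and a dense-edge exponential rise. Each kernel
# is nonnegative and sums to 1; shapes and spacing keep peak enrichment over
# uniform between roughly 2- and 4-fold.
compartment_kernels <- function(fractions, K) {
  f <- as.numeric(fractions)
  lo <- min(f); hi <- max(f)
  kernels <- list(light_edge = exp(-(f - lo) / 6))
  if (K > 2) {
    centers <- seq(lo + 5, hi - 5, length.out = K - 2)
    for (i in seq_len(K - 2)) {
      kernels[[paste0("interior_", i)]] <- exp(-(f - centers[i])^2 / (2 * 2.5^2))
    }
  }
  kernels$dense_edge <- exp((f - hi) / 5)
  lapply(kernels, function(k) k / sum(k))
}

compartment_names <- function(K) {
  base <- c("cytosolic_light", "secretory_er", "golgi_vesicle",
            "ribonucleoprotein", "mitochondrial", "dense_granule")
  if (K <= length(base)) base[seq_len(K)] else c(base, paste0("compartment_", seq_len(K - length(base))))
}

# index of the compartment whose genes carry the secreted/APEX annotations
secretory_index <- function(K) min(2L, K)

noisy_profile_matrix <- function(mean_profiles, scales, sigma) {
  n <- nrow(mean_profiles)
  p <- ncol(mean_profiles)
  noise <- if (sigma > 0) {
    matrix(exp(rnorm(n * p, 0, sigma)), n, p)
  } else {
    matrix(1, n, p)
  }
  scales * mean_profiles * noise
}

profile_from_matrix <- function(m, fractions, kind) {
  colnames(m) <- paste0("frac", fractions)
  new_sed_profile(
    dplyr::bind_cols(tibble(entity_id = rownames(m)), as_tibble(m)),
    kind
  )
}

#' Simulate a full synthetic gradient dataset with ground truth
#'
#' @param config A [simulation_config()].
#' @return A `sed_simulation` list: `rna`, `protein`, `rbp` (raw
#'   `sed_profile` tibbles), `utrs` (tibble `entity_id`, `seq`), `masks`
#'   (per-base conservation, named list), `clip` (tibble `entity_id`,
#'   `sites`), `expression` (tibble `entity_id`, `tpm` mean TPM),
#'   `psi` (a `psi_table`), `gene_sets` (a `gene_set_collection` of
#'   compartment memberships plus decoys), `annotations` (tibble `entity_id`,
#'   `in_apex`, `has_signal`), `id_map` (RNA-protein pairing), `truth`, and
#'   `config`. Identical configs (including seed) give identical output.
#' @export
simulate_gradient <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  K <- cfg$n_compartments
  rna_f <- cfg$rna_fractions
  prot_f <- cfg$protein_fractions
  kernels <- compartment_kernels(rna_f, K)
  comp_names <- compartment_names(K)
  names(kernels) <- comp_names
  uniform <- rep(1 / length(rna_f), length(rna_f))

  n_comp_genes <- K * cfg$genes_per_compartment
  n_genes <- n_comp_genes + cfg$n_background
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  compartment <- c(rep(comp_names, each = cfg$genes_per_compartment),
                   rep(NA_character_, cfg$n_background))

  # --- background kernels: independent random truncated Gaussians ---
  bg_kernels <- withr::with_seed(derive_seed(cfg$seed, "background"), {
    lapply(seq_len(cfg$n_background), function(i) {
      ctr <- runif(1, min(rna_f), max(rna_f))
      wd <- runif(1, 1.5, 4)
      k <- exp(-(as.numeric(rna_f) - ctr)^2 / (2 * wd^2))
      k / sum(k)
    })
  })

  gene_mean <- function(g) {
    k <- if (!is.na(compartment[g])) kernels[[compartment[g]]] else bg_kernels[[g - n_comp_genes]]
    (1 - cfg$alpha) * uniform + cfg$alpha * k
  }
  mean_mat <- t(vapply(seq_len(n_genes), gene_mean, numeric(length(rna_f))))
  rownames(mean_mat) <- gene_ids

  rna_mat <- withr::with_seed(derive_seed(cfg$seed, "rna"), {
    scales <- exp(rnorm(n_genes, cfg$scale_meanlog, cfg$scale_sdlog))
    noisy_profile_matrix(mean_mat, scales, cfg$noise_sigma)
  })
  rna <- profile_from_matrix(rna_mat, rna_f, "rna")

  # --- annotations and protein coupling ---
  sec_comp <- comp_names[secretory_index(K)]
  ann <- withr::with_seed(derive_seed(cfg$seed, "annotations"), {
    p_sec <- ifelse(!is.na(compartment) & compartment == sec_comp,
                    cfg$secreted_prob_target, cfg$secreted_prob_other)
    p_apex <- ifelse(!is.na(compartment) & compartment == sec_comp,
                     cfg$apex_prob_target, cfg$apex_prob_other)
    tibble(entity_id = gene_ids,
           has_signal = runif(n_genes) < p_sec,
           in_apex = runif(n_genes) < p_apex)
  })
  coupling <- ifelse(ann$has_signal, "co_sediment", "anti")

  # --- protein matrix over protein fractions ---
  keep_cols <- match(prot_f, rna_f)
  prot_means <- mean_mat[, keep_cols, drop = FALSE]
  prot_means <- prot_means / rowSums(prot_means)
  protein_ids <- withr::with_seed(derive_seed(cfg$seed, "protein_pick"),
                                  sort(sample(gene_ids, min(cfg$n_proteins, n_genes))))
  prot_mat <- withr::with_seed(derive_seed(cfg$seed, "protein"), {
    rows <- lapply(protein_ids, function(g) {
      m <- prot_means[g, ]
      if (coupling[match(g, gene_ids)] == "anti") m <- rev(m)
      m
    })
    pm <- do.call(rbind, rows)
    rownames(pm) <- protein_ids
    scales <- exp(rnorm(length(protein_ids), 0, 0.5))
    noisy_profile_matrix(pm, scales, cfg$noise_sigma)
  })
  protein <- profile_from_matrix(prot_mat, prot_f, "protein")

  # --- RBP peptide matrix (tracks compartments 1..n_rbps) ---
  rbp_ids <- sprintf("rbp%02d", seq_len(cfg$n_rbps))
  rbp_comp <- comp_names[seq_len(cfg$n_rbps)]
  prot_uniform <- rep(1 / length(prot_f), length(prot_f))
  rbp_mat <- withr::with_seed(derive_seed(cfg$seed, "rbp"), {
    rows <- lapply(rbp_comp, function(cn) {
      k <- kernels[[cn]][keep_cols]
      k <- k / sum(k)
      (1 - cfg$alpha) * prot_uniform + cfg$alpha * k
    })
    rm <- do.call(rbind, rows)
    rownames(rm) <- rbp_ids
    noisy_profile_matrix(rm, rep(1, cfg$n_rbps), cfg$noise_sigma)
  })
  rbp <- profile_from_matrix(rbp_mat, prot_f, "protein")
  planted_rbp <- rbp_ids[match(sec_comp, rbp_comp)]
  if (is.na(planted_rbp)) planted_rbp <- rbp_ids[1L]
  target_genes <- gene_ids[!is.na(compartment) &
                             compartment == rbp_comp[match(planted_rbp, rbp_ids)]]

  # --- UTR sequences with planted hexamer + conservation masks ---
  utr_sim <- withr::with_seed(derive_seed(cfg$seed, "utr"), {
    lens <- sample(seq(cfg$utr_length_range[1L], cfg$utr_length_range[2L]),
                   n_genes, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(ALPHABET, L, replace = TRUE), collapse = "")
    }, "")
    names(seqs) <- gene_ids
    masks <- lapply(lens, function(L) runif(L) < cfg$conservation_baseline)
    names(masks) <- gene_ids
    planted <- character(0)
    for (g in target_genes) {
      if (runif(1) < cfg$plant_rate) {
        L <- nchar(seqs[[g]])
        pos <- sample.int(L - 5L, 1L)
        substr(seqs[[g]], pos, pos + 5L) <- cfg$planted_hexamer
        masks[[g]][pos:(pos + 5L)] <- TRUE
        planted <- c(planted, g)
      }
    }
    list(seqs = seqs, masks = masks, planted = planted)
  })
  utrs <- tibble(entity_id = gene_ids, seq = unname(utr_sim$seqs[gene_ids]))

  # --- CLIP site counts for the planted RBP ---
  mean_tpm <- rowMeans(rna_mat)
  rbp_kernel_prot <- {
    k <- kernels[[rbp_comp[match(planted_rbp, rbp_ids)]]][keep_cols]
    k / sum(k)
  }
  r_true <- vapply(seq_len(n_genes), function(g) {
    k <- if (!is.na(compartment[g])) kernels[[compartment[g]]] else bg_kernels[[g - n_comp_genes]]
    kp <- k[keep_cols]
    cor(kp, rbp_kernel_prot)
  }, 0)
  # Smooth ramp to the target multiplier: true targets (r = 1) get the full
  # 3x site rate, uncorrelated or anti-correlated genes the base rate.
  mult <- 1 + (cfg$clip_target_multiplier - 1) * pmax(0, r_true)^2
  clip <- withr::with_seed(derive_seed(cfg$seed, "clip"), {
    tibble(entity_id = gene_ids,
           sites = rpois(n_genes, cfg$clip_base_rate * mean_tpm * mult))
  })

  # --- gene sets: compartment memberships + decoys ---
  sets <- split(gene_ids[!is.na(compartment)], compartment[!is.na(compartment)])
  decoys <- withr::with_seed(derive_seed(cfg$seed, "decoys"), {
    setNames(lapply(1:10, function(i) sample(gene_ids, min(100, n_genes))),
             sprintf("decoy_%02d", 1:10))
  })
  gene_sets <- gene_set_collection(c(sets, decoys), universe = gene_ids)

  # --- PSI table with planted delta-PSI classes ---
  psi_sim <- withr::with_seed(derive_seed(cfg$seed, "psi"),
                              simulate_psi_events(cfg, rna_f))

  # --- conservation scores per event ---
  scores <- withr::with_seed(derive_seed(cfg$seed, "scores"), {
    tibble(event_id = psi_sim$truth$event_id,
           score = rnorm(nrow(psi_sim$truth),
                         cfg$conservation_shift[psi_sim$truth$true_class], 1))
  })

  truth <- list(
    compartments = tibble(entity_id = gene_ids, compartment = compartment),
    coupling = tibble(entity_id = gene_ids, coupling = coupling,
                      secreted = ann$has_signal),
    rbps = tibble(rbp_id = rbp_ids, compartment = rbp_comp),
    planted_rbp = planted_rbp,
    planted_hexamer = cfg$planted_hexamer,
    rbp_targets = target_genes,
    utrs_with_motif = utr_sim$planted,
    psi = psi_sim$truth
  )

  structure(
    list(rna = rna, protein = protein, rbp = rbp,
         utrs = utrs, masks = utr_sim$masks, clip = clip,
         expression = tibble(entity_id = gene_ids, tpm = unname(mean_tpm)),
         psi = psi_sim$table, event_scores = scores,
         gene_sets = gene_sets, annotations = ann,
         id_map = tibble(rna_id = protein_ids, protein_id = protein_ids),
         truth = truth, config = cfg),
    class = "sed_simulation"
  )
}

# Planted AFE/ALE events: two isoforms per event; the tracked isoform's PSI
# ramps linearly across the gradient by the class's target span. Class spans
# leave margins around the 0.25/0.5 boundaries so measurement noise cannot
# flip a label.
simulate_psi_events <- function(cfg, fractions) {
  counts <- cfg$psi_events
  classes <- rep(c("strong", "moderate", "non_regulated"),
                 times = c(counts[["strong"]], counts[["moderate"]], counts[["non"]]))
  n_ev <- length(classes)
  spans <- vapply(classes, function(cl) {
    switch(cl,
           strong = runif(1, 0.55, 0.92),
           moderate = runif(1, 0.30, 0.46),
           non_regulated = runif(1, 0.01, 0.18))
  }, 0)
  types <- rep(c("AFE", "ALE"), length.out = n_ev)
  event_ids <- sprintf("event%03d", seq_len(n_ev))
  fgrid <- (as.numeric(fractions) - min(fractions)) /
    (max(fractions) - min(fractions))
  rows <- purrr::map_dfr(seq_len(n_ev), function(i) {
    p0 <- runif(1, 0.02, 0.98 - spans[i])
    base <- p0 + spans[i] * fgrid
    psi1 <- pmin(1, pmax(0, base + rnorm(length(fgrid), 0, cfg$psi_noise_sd)))
    wide <- runif(1) < cfg$wide_ci_rate
    w1 <- runif(length(fgrid), cfg$ci_width_range[1L], cfg$ci_width_range[2L])
    w2 <- if (wide) {
      runif(length(fgrid), cfg$wide_ci_width_range[1L], cfg$wide_ci_width_range[2L])
    } else {
      runif(length(fgrid), cfg$ci_width_range[1L], cfg$ci_width_range[2L])
    }
    ci_bounds <- function(p, w) {
      lo <- pmin(pmax(p - w / 2, 0), 1 - w)
      list(lo = lo, hi = lo + w)
    }
    b1 <- ci_bounds(psi1, w1)
    b2 <- ci_bounds(1 - psi1, w2)
    bind_rows(
      tibble(event_id = event_ids[i], event_type = types[i],
             isoform_id = paste0(event_ids[i], ".1"), fraction = fractions,
             psi = psi1, ci_low = b1$lo, ci_high = b1$hi),
      tibble(event_id = event_ids[i], event_type = types[i],
             isoform_id = paste0(event_ids[i], ".2"), fraction = fractions,
             psi = 1 - psi1, ci_low = b2$lo, ci_high = b2$hi)
    ) |>
      mutate(wide = wide)
  })
  truth <- rows |>
    distinct(.data$event_id, .data$event_type, .data$wide) |>
    mutate(true_class = classes, true_span = unname(spans),
           ci_confident = !.data$wide) |>
    select("event_id", "event_type", "true_class", "true_span", "ci_confident")
  table <- rows |> select(-"wide")
  # PSI values must respect ci_low <= psi <= ci_high after boundary shifts
  table <- table |>
    mutate(psi = pmin(pmax(.data$psi, .data$ci_low), .data$ci_high))
  list(table = psi_table(table), truth = truth)
}

#' Write all simulated artifacts to a directory
#'
#' Emits the exact dialects the package's loaders consume: profile TSVs, GMT,
#' FASTA, a conservation interval track, PSI TSV, and a truth JSON. Every
#' table carries a header comment with the seed.
#'
#' @param sim A `sed_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sed_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("seed: %d", sim$config$seed)
  paths <- c(
    rna = file.path(dir, "rna_profiles.tsv"),
    protein = file.path(dir, "protein_profiles.tsv"),
    rbp = file.path(dir, "rbp_profiles.tsv"),
    utrs = file.path(dir, "utrs.fa"),
    masks = file.path(dir, "conservation.tsv"),
    clip = file.path(dir, "clip_sites.tsv"),
    psi = file.path(dir, "psi.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_profile_tsv(sim$rna, paths[["rna"]], comment = hdr)
  write_profile_tsv(sim$protein, paths[["protein"]], comment = hdr)
  write_profile_tsv(sim$rbp, paths[["rbp"]], comment = hdr)
  write_utr_fasta(sim$utrs, paths[["utrs"]])
  write_conservation_track(sim$masks, paths[["masks"]])
  readr::write_tsv(sim$clip, paths[["clip"]], progress = FALSE)
  write_psi_table(sim$psi, paths[["psi"]], comment = hdr)
  write_gmt(sim$gene_sets, paths[["gene_sets"]])
  readr::write_tsv(sim$annotations, paths[["annotations"]], progress = FALSE)
  jsonlite::write_json(
    list(
      compartments = sim$truth$compartments,
      coupling = sim$truth$coupling,
      rbps = sim$truth$rbps,
      planted_rbp = sim$truth$planted_rbp,
      planted_hexamer = sim$truth$planted_hexamer,
      rbp_targets = sim$truth$rbp_targets,
      psi = sim$truth$psi,
      seed = sim$config$seed
    ),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Score pipeline results against the simulation's ground truth
#'
#' @param sim A `sed_simulation`.
#' @param clusters Optional `sed_clusters` from the simulated RNA.
#' @param rbp_result Optional [correlate_rbp_to_rnas()] result for the
#'   planted RBP.
#' @param hexamer_stats Optional [hexamer_enrichment()] tibble.
#' @param psi_classes Optional classified events (see [classify_events()]).
#' @return A list with (for the inputs supplied): `ari` (adjusted Rand index
#'   of cluster labels vs planted compartments, over compartment genes present
#'   in the clustering), `compartment_coverage` (fraction of compartment genes
#'   retained in the clustering), `rbp_recall`, `rbp_fpr` (target calls vs
#'   planted targets), `motif_rank` (rank of the planted hexamer by
#'   `log2_ratio`), and `psi_confusion` (true-by-predicted class table).
#' @export
truth_metrics <- function(sim, clusters = NULL, rbp_result = NULL,
                          hexamer_stats = NULL, psi_classes = NULL) {
  stopifnot(inherits(sim, "sed_simulation"))
  out <- list()
  comp <- sim$truth$compartments
  if (!is.null(clusters)) {
    a <- clusters$assignment
    joined <- inner_join(a, comp, by = "entity_id") |>
      filter(!is.na(.data$compartment))
    if (!nrow(joined)) {
      stop_cosedim("No clustered entity matches a planted compartment gene.",
                   "cosedim_validation_error")
    }
    out$ari <- mclust::adjustedRandIndex(joined$compartment, joined$cluster)
    n_comp_genes <- sum(!is.na(comp$compartment) &
                          comp$entity_id %in% sim$rna$entity_id)
    out$compartment_coverage <- nrow(joined) / n_comp_genes
  }
  if (!is.null(rbp_result)) {
    called <- rbp_result$entity_id[rbp_result$correlated]
    targets <- intersect(sim$truth$rbp_targets, rbp_result$entity_id)
    non_targets <- setdiff(rbp_result$entity_id, sim$truth$rbp_targets)
    out$rbp_recall <- length(intersect(called, targets)) / length(targets)
    out$rbp_fpr <- length(setdiff(called, targets)) / length(non_targets)
  }
  if (!is.null(hexamer_stats)) {
    hs <- as_tibble(hexamer_stats) |> arrange(desc(.data$log2_ratio))
    out$motif_rank <- match(sim$truth$planted_hexamer, hs$hexamer)
  }
  if (!is.null(psi_classes)) {
    joined <- inner_join(as_tibble(psi_classes), sim$truth$psi, by = "event_id")
    if (nrow(joined)) {
      out$psi_confusion <- table(
        truth = factor(joined$true_class,
                       levels = c("strong", "moderate", "non_regulated")),
        predicted = factor(as.character(joined$class),
                           levels = c("strong", "moderate", "non_regulated"))
      )
    }
  }
  out
}
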