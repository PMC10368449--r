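#' @title Synthetic genotype / infection-network generator
#' @description Generates strain genotypes, phage capability sets and
#'   noisy infection matrices with known ground truth, emulating the
#'   study design: loss-of-function mutations scattered over the LPS
#'   genes with the observed mutation-type proportions, host receptor
#'   classes that may hide finer subclasses than the pathway model
#'   predicts, per-phage capability sets, and Bernoulli assay noise.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: 31 resistant strains and 16
#' evolved phages, one mutation per strain, mutation-type weights
#' 15:13:1:3 (substitutions : deletions : duplications : IS insertions),
#' noiseless assays.
#'
#' @param n_strains Number of resistant strains.
#' @param pathway An \code{lps_pathway} (default: packaged model).
#' @param mutation_type_weights Nonnegative weights, named
#'   \code{substitution}, \code{deletion}, \code{duplication},
#'   \code{is_insertion}.
#' @param hidden_split_prob Probability that a predicted class with >= 2
#'   strains hides two distinct true receptor subclasses.
#' @param n_phages Number of phages.
#' @param capability_model \code{"one_per_true_class"} (phage i targets
#'   true class i mod K, guaranteeing every true class is discriminable)
#'   or \code{"random"} (random nonempty class subsets).
#' @param noise_eps Per-cell flip probability in the assay matrix.
#' @param seed Integer seed (mandatory).
#' @return A \code{sim_config} list.
#' @export
simulation_config <- function(n_strains = 31L,
                              pathway = load_pathway(lps_pathway_file()),
                              mutation_type_weights = c(substitution = 15,
                                                        deletion = 13,
                                                        duplication = 1,
                                                        is_insertion = 3),
                              hidden_split_prob = 0,
                              n_phages = 16L,
                              capability_model = c("one_per_true_class",
                                                   "random"),
                              noise_eps = 0,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  capability_model <- match.arg(capability_model)
  w <- mutation_type_weights
  stopifnot(all(w >= 0), sum(w) > 0,
            hidden_split_prob >= 0, hidden_split_prob <= 1,
            noise_eps >= 0, noise_eps <= 1)
  req <- c("substitution", "deletion", "duplication", "is_insertion")
  if (!setequal(names(w), req))
    stop("mutation_type_weights must be named: ",
         paste(req, collapse = ", "))
  structure(list(n_strains = as.integer(n_strains), pathway = pathway,
                 mutation_type_weights = w[req],
                 hidden_split_prob = hidden_split_prob,
                 n_phages = as.integer(n_phages),
                 capability_model = capability_model,
                 noise_eps = noise_eps, seed = as.integer(seed)),
            class = "sim_config")
}

# mutation type -> plausible effect category (disruptive mix as observed:
# substitutions mostly nonsense, deletions mostly frameshifts)
.draw_effect <- function(type) {
  switch(type,
         substitution = sample(c("nonsense", "missense"), 1L,
                               prob = c(0.8, 0.2)),
         deletion = sample(c("frameshift", "inframe_indel"), 1L,
                           prob = c(0.92, 0.08)),
         duplication = "duplication",
         is_insertion = "is_insertion")
}

#' Generate strain genotypes with ground truth
#'
#' Each strain receives one LPS gene drawn uniformly over the pathway's
#' mutable genes and a mutation type drawn from the configured weights.
#' The predicted class is the canonical key of the knockout structure.
#' True classes refine predicted classes: each predicted class with at
#' least two strains is split into two nonempty subclasses with
#' probability \code{hidden_split_prob}.
#'
#' @param cfg A \code{sim_config}.
#' @return List with \code{strains} (list of \code{strain_genotype}) and
#'   \code{truth}: data frame \code{strain_id}, \code{gene},
#'   \code{predicted_class}, \code{true_class}.
#' @export
generate_strains <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- cfg$pathway$lps_genes
  if (length(genes) == 0L) stop("config error: empty gene roster")
  w <- cfg$mutation_type_weights
  ids <- sprintf("S%02d", seq_len(cfg$n_strains))

  gene_draw <- sample(genes, cfg$n_strains, replace = TRUE)
  type_draw <- sample(names(w), cfg$n_strains, replace = TRUE,
                      prob = w / sum(w))
  strains <- lapply(seq_len(cfg$n_strains), function(i) {
    eff <- .draw_effect(type_draw[i])
    pos <- sample.int(400L, 1L)
    structure(list(strain_id = ids[i], included = TRUE,
                   mutations = list(structure(
                     list(gene = gene_draw[i], effect = eff,
                          descriptor = paste0(type_draw[i], "@", pos),
                          position = pos),
                     class = "gene_mutation"))),
              class = "strain_genotype")
  })

  predicted <- vapply(gene_draw, function(g)
    canonical_key(predict_structure(cfg$pathway, g)), "")
  true_class <- predicted
  for (cl in unique(predicted)) {
    members <- which(predicted == cl)
    if (length(members) >= 2L &&
        stats::runif(1) < cfg$hidden_split_prob) {
      # split into two nonempty subclasses
      k <- sample(seq_len(length(members) - 1L), 1L)
      sub <- sample(members)
      true_class[sub[seq_len(k)]] <- paste0(cl, "#a")
      true_class[sub[-seq_len(k)]] <- paste0(cl, "#b")
    }
  }
  truth <- data.frame(strain_id = ids, gene = gene_draw,
                      mutation_type = type_draw,
                      predicted_class = predicted,
                      true_class = true_class,
                      stringsAsFactors = FALSE)
  list(strains = strains, truth = truth)
}

#' Generate phage capability sets over true classes
#' @param truth Ground-truth data frame from \code{\link{generate_strains}}.
#' @param cfg A \code{sim_config}.
#' @return Named list phage id -> character vector of true classes.
#' @export
generate_capabilities <- function(truth, cfg) {
  classes <- sort(unique(truth$true_class))
  k <- length(classes)
  pids <- sprintf("P%02d", seq_len(cfg$n_phages))
  caps <- lapply(seq_len(cfg$n_phages), function(i) {
    if (cfg$capability_model == "one_per_true_class") {
      base <- classes[(i - 1L) %% k + 1L]
      extra <- classes[stats::runif(k) < 0.15]
      unique(c(base, extra))
    } else {
      sz <- sample.int(k, 1L)
      sample(classes, sz)
    }
  })
  stats::setNames(caps, pids)
}

#' Generate a noisy infection matrix from ground truth
#'
#' Noiseless rule: host h is infected by phage p iff h's true class is in
#' p's capability set.  Each cell is then flipped independently with
#' probability \code{noise_eps} (symmetric Bernoulli noise).
#'
#' @param truth Ground-truth data frame.
#' @param capabilities Named list phage -> true classes.
#' @param noise_eps Flip probability.
#' @param seed Integer seed for the noise draws.
#' @return An \code{infection_matrix}.
#' @export
generate_matrix <- function(truth, capabilities, noise_eps = 0, seed) {
  if (!missing(seed)) set.seed(seed)
  cells <- vapply(capabilities, function(caps)
    as.integer(truth$true_class %in% caps),
    integer(nrow(truth)))
  if (nrow(truth) == 1L) cells <- matrix(cells, nrow = 1L)
  dimnames(cells) <- list(truth$strain_id, names(capabilities))
  if (noise_eps > 0) {
    flip <- matrix(stats::runif(length(cells)) < noise_eps,
                   nrow(cells), ncol(cells))
    cells[flip] <- 1L - cells[flip]
  }
  new_infection_matrix(cells)
}

#' Simulate a full dataset and write it in the pipeline's file dialects
#'
#' Emits the strain-table TSV and matrix CSV consumed by the readers,
#' plus a ground-truth JSON.
#'
#' @param cfg A \code{sim_config}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- generate_strains(cfg)
  caps <- generate_capabilities(gs$truth, cfg)
  mat <- generate_matrix(gs$truth, caps, cfg$noise_eps)
  paths <- list(strains = file.path(dir, "strains.tsv"),
                matrix = file.path(dir, "matrix.csv"),
                truth = file.path(dir, "truth.json"))
  write_strain_table(gs$strains, paths$strains)
  write_matrix(mat, paths$matrix)
  jsonlite::write_json(list(truth = gs$truth, capabilities = caps),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(strains = gs$strains, truth = gs$truth,
                 capabilities = caps, matrix = mat, paths = paths))
}

#' Recovery experiment: can profiles recover the hidden classes?
#'
#' For each replicate, generates a dataset, groups hosts by identical
#' infection profiles, and measures the concordance of the profile
#' partition with the true and the predicted class partitions, plus the
#' observed profile count against the predicted class count.  This is the
#' study's logic in silico: when predicted classes hide finer true
#' classes resolved by at least one phage, the observed profile count
#' exceeds the predicted class count.
#'
#' @param cfg A \code{sim_config} (its seed spawns per-replicate seeds).
#' @param n_reps Number of replicates (>= 1).
#' @return Data frame with one row per replicate: \code{eps},
#'   \code{hidden_split_prob}, \code{ari_profiles_vs_truth},
#'   \code{ari_profiles_vs_predicted}, \code{profile_count},
#'   \code{predicted_class_count}, \code{true_class_count}.
#' @export
recovery_experiment <- function(cfg, n_reps = 1L) {
  stopifnot(n_reps >= 1L)
  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  res <- lapply(seq_len(n_reps), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- rep_seeds[r]
    gs <- generate_strains(cfg_r)
    caps <- generate_capabilities(gs$truth, cfg_r)
    mat <- generate_matrix(gs$truth, caps, cfg_r$noise_eps)
    prof <- distinct_profiles(mat, "hosts")
    truth_part <- stats::setNames(gs$truth$true_class, gs$truth$strain_id)
    pred_part <- stats::setNames(gs$truth$predicted_class,
                                 gs$truth$strain_id)
    data.frame(
      eps = cfg$noise_eps,
      hidden_split_prob = cfg$hidden_split_prob,
      ari_profiles_vs_truth =
        partition_concordance(prof$classes, truth_part)$ari,
      ari_profiles_vs_predicted =
        partition_concordance(prof$classes, pred_part)$ari,
      profile_count = prof$count,
      predicted_class_count = length(unique(gs$truth$predicted_class)),
      true_class_count = length(unique(gs$truth$true_class)))
  })
  do.call(rbind, res)
}
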