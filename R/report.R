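#' Run the full prediction-vs-observation analysis
#'
#' Orchestrates the pipeline end to end: pathway prediction and
#' rough/deep-rough classification of every strain, mutation summary
#' statistics, (optionally) consensus collapsing of raw assays, distinct
#' infectivity-profile counting, agglomerative clustering with the
#' unbroken-cluster test and its metric/linkage sensitivity grid,
#' partition concordance, and association-rule mining.
#'
#' @param pathway_file,strain_file,phage_file,matrix_file Input paths
#'   (defaults: the packaged reconstructed fixtures).
#' @param assay_file Optional raw replicated assay TSV; when given it is
#'   collapsed by the consensus rule and must agree with
#'   \code{matrix_file} if both are supplied.
#' @param policy Loss-of-function policy.
#' @param metric,method Clustering convention for the headline analysis.
#' @param include_wt Keep the wild-type host row in the clustered panel.
#' @param wt_host Wild-type host row id.
#' @param wt_phage Ancestral phage column id (dropped from the evolved
#'   panel before profile counting/clustering); use \code{NULL} if the
#'   matrix has no such column.
#' @param seed Seed recorded in the provenance block (the analysis itself
#'   is deterministic).
#' @param out Optional path; when given the report is written as JSON.
#' @return An \code{analysis_report} list; see the elements in the
#'   examples and the vignette.
#' @examples
#' rep <- run_full_analysis()
#' rep$predicted_class_count      # distinct predicted structures
#' rep$anticipated_class_count    # + one class per mutated regulator
#' rep$distinct_profiles_phages
#' @export
run_full_analysis <- function(pathway_file = lps_pathway_file(),
                              strain_file = lps_strain_table_file(),
                              phage_file = lps_phage_table_file(),
                              matrix_file = lps_infection_matrix_file(),
                              assay_file = NULL,
                              policy = c("permissive", "conservative"),
                              metric = "euclidean", method = "average",
                              include_wt = TRUE, wt_host = "WT",
                              wt_phage = "WT", seed = 1L, out = NULL) {
  policy <- match.arg(policy)
  model <- load_pathway(pathway_file)
  strains <- read_strain_table(strain_file)
  phages <- read_phage_table(phage_file)
  mat <- if (!is.null(assay_file)) {
    consensus_matrix(utils::read.delim(assay_file, comment.char = "#"))
  } else {
    read_matrix(matrix_file)
  }

  # --- structure prediction ------------------------------------------------
  part <- predict_partition(model, strains, policy = policy)
  pred_ct <- sum(!startsWith(names(part$classes), "unpredicted:"))
  antic_ct <- length(part$classes)
  type_by_strain <- part$types[part$labels]
  rough_ct <- sum(type_by_strain == "rough")
  deep_ct <- sum(type_by_strain == "deep_rough")

  # --- mutation statistics -------------------------------------------------
  mstats <- mutation_stats(strains)
  pstats <- phage_mutation_stats(phages)

  # --- evolved panel: drop ancestral phage column, optionally the WT host --
  evolved <- setdiff(mat$phages, wt_phage)
  resistant <- intersect(mat$hosts, names(part$labels))
  panel_hosts <- if (include_wt) union(resistant, intersect(mat$hosts, wt_host)) else resistant
  panel_hosts <- mat$hosts[mat$hosts %in% panel_hosts]
  panel <- new_infection_matrix(
    mat$cells[panel_hosts, evolved, drop = FALSE])
  resistant_panel <- new_infection_matrix(
    mat$cells[resistant, evolved, drop = FALSE])

  prof_phages <- distinct_profiles(resistant_panel, "phages")
  prof_phages_wt <- distinct_profiles(panel, "phages")
  prof_hosts <- distinct_profiles(resistant_panel, "hosts")

  # --- clustering + contiguity --------------------------------------------
  lk <- upgma_linkage(panel, axis = "hosts", metric = metric,
                      method = method)
  ord <- leaf_order(lk)
  ord_resistant <- intersect(ord, resistant)
  contig <- contiguous_classes(ord_resistant, part$labels[resistant])
  sens <- contiguity_sensitivity(panel, part$labels[resistant],
                                 axis = "hosts")
  conc <- partition_concordance(prof_hosts$classes[resistant],
                                part$labels[resistant])

  # --- association mining --------------------------------------------------
  caps <- capability_sets(resistant_panel_with_wt(mat, resistant, evolved,
                                                  wt_host),
                          part$labels[resistant], wt_host = wt_host)
  rules <- list(wt_loss = perfect_associations(phages, caps, "wt_loss"))

  report <- structure(list(
    predicted_class_count = pred_ct,
    anticipated_class_count = antic_ct,
    rough_count = rough_ct,
    deep_rough_count = deep_ct,
    class_types = part$types,
    partition = part,
    mutation_summary = mstats,
    phage_mutation_summary = pstats,
    distinct_profiles_phages = prof_phages$count,
    distinct_profiles_phages_with_wt_host = prof_phages_wt$count,
    distinct_profiles_hosts = prof_hosts$count,
    linkage = lk,
    leaf_order = ord,
    contiguity = contig,
    contiguity_sensitivity = sens,
    concordance = conc,
    capability_sets = caps,
    association_rules = rules,
    provenance = list(
      pathway_file = unname(tools::md5sum(pathway_file)),
      strain_file = unname(tools::md5sum(strain_file)),
      phage_file = unname(tools::md5sum(phage_file)),
      matrix_file = if (is.null(assay_file))
        unname(tools::md5sum(matrix_file)) else NA_character_,
      policy = policy, metric = metric, method = method,
      include_wt = include_wt, seed = seed,
      version = as.character(utils::packageVersion("lpsmap")))
  ), class = "analysis_report")

  if (!is.null(out)) {
    jsonlite::write_json(report_to_list(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}

# hosts panel for capability mining: resistant hosts plus the WT row
resistant_panel_with_wt <- function(mat, resistant, evolved, wt_host) {
  rows <- c(resistant, intersect(mat$hosts, wt_host))
  rows <- mat$hosts[mat$hosts %in% rows]
  new_infection_matrix(mat$cells[rows, evolved, drop = FALSE])
}

# JSON-serializable subset of the report
report_to_list <- function(report) {
  list(
    predicted_class_count = report$predicted_class_count,
    anticipated_class_count = report$anticipated_class_count,
    rough_count = report$rough_count,
    deep_rough_count = report$deep_rough_count,
    mutation_summary = report$mutation_summary[
      c("total", "unique", "by_effect", "disruptive_fraction")],
    shared_mutations = report$mutation_summary$shared,
    phage_mutation_summary = report$phage_mutation_summary[
      c("total", "unique")],
    distinct_profiles_phages = report$distinct_profiles_phages,
    distinct_profiles_phages_with_wt_host =
      report$distinct_profiles_phages_with_wt_host,
    distinct_profiles_hosts = report$distinct_profiles_hosts,
    leaf_order = report$leaf_order,
    contiguity = report$contiguity[
      c("contiguous", "broken", "n_multi_contiguous", "n_multi")],
    contiguity_sensitivity = report$contiguity_sensitivity,
    concordance = report$concordance,
    wt_loss_rule = list(
      capable = report$association_rules$wt_loss$capable,
      perfect_singles =
        report$association_rules$wt_loss$perfect_singles,
      perfect_pairs = report$association_rules$wt_loss$perfect_pairs,
      nearest_miss = report$association_rules$wt_loss$nearest_miss),
    provenance = report$provenance
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("LPS prediction vs infection-profile analysis\n")
  cat("  predicted structures:      ", x$predicted_class_count, "\n")
  cat("  anticipated classes:       ", x$anticipated_class_count, "\n")
  cat("  rough / deep rough strains:", x$rough_count, "/",
      x$deep_rough_count, "\n")
  cat("  strain mutations:          ", x$mutation_summary$unique,
      "unique of", x$mutation_summary$total, "\n")
  cat("  phage mutations:           ", x$phage_mutation_summary$unique,
      "unique of", x$phage_mutation_summary$total, "\n")
  cat("  distinct phage profiles:   ", x$distinct_profiles_phages, "\n")
  cat("  unbroken multi-member classes:",
      x$contiguity$n_multi_contiguous, "of", x$contiguity$n_multi, "\n")
  invisible(x)
}
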