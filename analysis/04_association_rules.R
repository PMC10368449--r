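#!/usr/bin/env Rscript
# Step 4 — mine phage mutation-capability associations.
#
# Links phage genotypes to host-range capabilities by exact set logic.
# Finding: loss of the ability to infect the wild type is explained by a
# joint two-site rule — the H-protein site 68 change together with the
# F-protein site 154 allele class (Q154K/R) — with no perfect single-site
# explanation; capability rules for individual host classes surface
# their counterexamples (e.g. a phage infecting the first heptoseless
# subgroup without the site-154 change) rather than suppressing them.

suppressPackageStartupMessages(library(lpsmap))
dir.create("results", showWarnings = FALSE)

model <- load_pathway(lps_pathway_file())
strains <- read_strain_table(lps_strain_table_file())
part <- predict_partition(model, strains)
mat <- read_matrix(lps_infection_matrix_file())
phages <- read_phage_table(lps_phage_table_file())

evolved <- setdiff(mat$phages, "WT")
rows <- c(names(part$labels), "WT")
panel <- lpsmap:::new_infection_matrix(
  mat$cells[mat$hosts[mat$hosts %in% rows], evolved])
caps <- capability_sets(panel, part$labels)

rules <- list(wt_loss = perfect_associations(phages, caps, "wt_loss"))
print(rules$wt_loss)
for (cl in sort(unique(part$labels))) {
  rules[[cl]] <- perfect_associations(phages, caps, cl)
}

out <- lapply(rules, function(r) list(
  capability = r$capability, capable = r$capable,
  perfect_singles = r$perfect_singles, perfect_pairs = r$perfect_pairs,
  nearest_miss = r$nearest_miss))
jsonlite::write_json(out, "results/association_rules.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("written: results/association_rules.json\n")
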