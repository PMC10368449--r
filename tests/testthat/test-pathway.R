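model <- load_pathway(lps_pathway_file())
wt <- predict_structure(model)
fig2_genes <- c("waaC", "waaF", "waaG", "waaO", "waaT", "waaW", "waaP",
                "galU", "galE", "gmhA", "gmhB", "gmhD", "hldE")

test_that("packaged model loads with the expected gene roster", {
  expect_s3_class(model, "lps_pathway")
  expect_true(all(fig2_genes %in% model$gene_roster))
  expect_identical(model$regulator_genes, "rfaH")
  expect_setequal(model$lps_genes, fig2_genes)
})

test_that("configuration errors are caught", {
  expect_error(load_pathway(
    "residues:\n  - {name: A, parent: ZZZ, transferases: [g]}\n"),
    "unresolved parent")
  expect_error(load_pathway(paste0(
    "residues:\n",
    "  - {name: A, parent: B, transferases: [g]}\n",
    "  - {name: B, parent: A, transferases: [h]}\n")),
    "cycle")
  expect_error(load_pathway(paste0(
    "residues:\n",
    "  - {name: A, parent: ~, transferases: []}\n",
    "  - {name: A, parent: ~, transferases: []}\n")),
    "duplicate residue")
  expect_error(load_pathway(paste0(
    "residues:\n",
    "  - {name: A, parent: ~, transferases: []}\n",
    "  - {name: B, parent: A, transferases: []}\n")),
    "without transferase")
})

test_that("knockout truncation matches the biology", {
  # no knockout: complete wild-type structure
  expect_setequal(wt$residues, model$residues$name)
  expect_setequal(wt$modifications, names(model$modifications))

  # heptose-transferase loss: complete inner-core truncation past Kdo
  heptless <- predict_structure(model, "waaC")
  expect_setequal(heptless$residues, c("LipidA", "Kdo-I", "Kdo-II"))

  # first outer-core transferase and its precursor gene are equivalent:
  # outer core entirely absent either way
  s_waaG <- predict_structure(model, "waaG")
  s_galU <- predict_structure(model, "galU")
  s_both <- predict_structure(model, c("waaG", "galU"))
  expect_identical(canonical_key(s_waaG), canonical_key(s_galU))
  expect_identical(canonical_key(s_waaG), canonical_key(s_both))
  expect_false(any(c("Glc-I", "Glc-II", "Gal-I", "Gal-II") %in%
                     s_waaG$residues))

  # kinase loss strips phosphates but leaves the backbone complete
  s_waaP <- predict_structure(model, "waaP")
  expect_setequal(s_waaP$residues, model$residues$name)
  expect_false(any(c("Hep-I-P", "Hep-II-P") %in% s_waaP$modifications))

  expect_error(predict_structure(model, "notAGene"), "unknown gene")
  expect_error(predict_structure(model, "rfaH"), "unpredictable")
})

test_that("rough vs deep-rough classification follows the truncation depth", {
  cls <- function(g) classify_lps_type(predict_structure(model, g), wt, model)
  expect_identical(cls("waaO"), "rough")       # partial outer-core loss
  expect_identical(cls("waaT"), "rough")
  expect_identical(cls("waaW"), "rough")
  expect_identical(cls(character(0)), "rough") # WT itself is rough type
  expect_identical(cls("waaP"), "deep_rough")  # phosphate loss
  expect_identical(cls("waaG"), "deep_rough")  # outer core fully absent
  expect_identical(cls("waaC"), "deep_rough")
  expect_identical(cls("waaF"), "deep_rough")
})

test_that("exhaustive single knockouts give exactly 7 distinct mutant structures", {
  keys <- vapply(fig2_genes, function(g)
    canonical_key(predict_structure(model, g)), "")
  expect_length(setdiff(unique(keys), canonical_key(wt)), 7L)
})

test_that("knockout propagation is monotone, connected and order-invariant", {
  singles <- lapply(fig2_genes, identity)
  doubles <- utils::combn(fig2_genes, 2L, simplify = FALSE)
  parent_of <- stats::setNames(model$residues$parent, model$residues$name)
  for (ko in c(singles, doubles)) {
    s <- predict_structure(model, ko)
    # connectivity: every present residue's parent is present
    pars <- parent_of[s$residues]
    expect_true(all(is.na(pars) | pars %in% s$residues))
    # monotonicity against each single-gene subset
    for (g in ko) {
      sup <- predict_structure(model, g)
      expect_true(all(s$residues %in% sup$residues))
      expect_true(all(s$modifications %in% sup$modifications))
    }
    # canonical key ignores input order
    expect_identical(canonical_key(predict_structure(model, rev(ko))),
                     canonical_key(s))
  }
})

test_that("strain partitioning groups by structure and isolates regulator mutants", {
  strains <- read_strain_table(lps_strain_table_file())
  part <- predict_partition(model, strains)
  expect_length(part$labels, 31L)
  expect_identical(unname(part$labels["R9"]),
                   unname(part$labels["R22"]))  # galU/waaG same class
  expect_identical(part$labels[["R25"]], "unpredicted:rfaH")
  expect_identical(unname(part$types["unpredicted:rfaH"]), "unpredicted")
  # every strain labelled exactly once
  expect_setequal(unlist(part$classes), names(part$labels))

  # strains with no pathway-gene mutation are excluded with a warning
  odd <- structure(list(strain_id = "X1", included = TRUE,
                        mutations = list(structure(
                          list(gene = "pssA", effect = "missense",
                               descriptor = "G77D", position = 77L),
                          class = "gene_mutation"))),
                   class = "strain_genotype")
  expect_warning(p2 <- predict_partition(model, list(odd)),
                 "no LoF-callable")
  expect_identical(p2$excluded, "X1")

  # single-strain input: one class
  p1 <- predict_partition(model, strains[vapply(strains, `[[`, "",
                                                "strain_id") == "R18"])
  expect_length(p1$classes, 1L)
})

test_that("tiny model honours precursor requirements and regulators", {
  tm <- load_pathway(tiny_pathway_yaml())
  s <- predict_structure(tm, "pB")   # precursor loss removes B and C
  expect_setequal(s$residues, c("root", "A"))
  expect_error(predict_structure(tm, "regX"), "unpredictable")
  # nonstoichiometric decoration never enters the canonical key
  s2 <- predict_structure(tm, "gE")
  expect_identical(canonical_key(s2), canonical_key(predict_structure(tm)))
})
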