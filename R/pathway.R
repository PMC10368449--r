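#' Load an LPS core-oligosaccharide assembly model
#'
#' Reads a YAML description of the core-OS assembly graph: backbone
#' residues with their attachment point (parent), the transferase gene(s)
#' that attach them and the gene(s) supplying their sugar-nucleotide
#' precursor, plus decoration (modification) nodes gated by their own
#' genes.  Regulator genes (e.g. \code{rfaH}) are declared separately:
#' their loss can affect any number of biosynthesis genes, so structures
#' of regulator mutants are treated as unpredictable rather than guessed.
#'
#' @param path Path to a YAML pathway configuration, or a single string
#'   containing YAML text (detected by the presence of a newline).
#' @return An object of class \code{lps_pathway} with elements
#'   \code{residues} (data frame in topological order), \code{residue_sets}
#'   (named lists of transferase/precursor genes per residue),
#'   \code{modifications}, \code{gene_roster}, \code{regulator_genes},
#'   \code{lps_genes} (the mutable biosynthesis genes) and \code{name}.
#' @examples
#' mod <- load_pathway(lps_pathway_file())
#' mod$gene_roster
#' @export
load_pathway <- function(path) {
  cfg <- if (length(path) == 1L && grepl("\n", path)) {
    yaml::yaml.load(path)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$residues) || length(cfg$residues) == 0L)
    stop("pathway configuration error: no residues declared")

  res_names <- vapply(cfg$residues, function(r) as.character(r$name), "")
  if (anyDuplicated(res_names))
    stop("pathway configuration error: duplicate residue name: ",
         paste(unique(res_names[duplicated(res_names)]), collapse = ", "))

  parents <- vapply(cfg$residues, function(r) {
    p <- r$parent
    if (is.null(p) || length(p) == 0L || is.na(p)) NA_character_ else as.character(p)
  }, "")
  bad <- !is.na(parents) & !(parents %in% res_names)
  if (any(bad))
    stop("pathway configuration error: unresolved parent '",
         parents[bad][1L], "' of residue '", res_names[bad][1L], "'")

  # cycle check + topological order (Kahn; lexicographic name tie-break)
  remaining <- res_names
  par <- stats::setNames(parents, res_names)
  topo <- character(0)
  placed <- character(0)
  while (length(remaining) > 0L) {
    ready <- remaining[is.na(par[remaining]) | par[remaining] %in% placed]
    if (length(ready) == 0L)
      stop("pathway configuration error: cycle in parent links involving: ",
           paste(remaining, collapse = ", "))
    ready <- sort(ready)
    topo <- c(topo, ready)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  ord <- match(topo, res_names)

  getset <- function(r, key) {
    v <- r[[key]]
    if (is.null(v)) character(0) else as.character(unlist(v))
  }
  residue_sets <- lapply(cfg$residues, function(r)
    list(transferases = getset(r, "transferases"),
         precursors   = getset(r, "precursors")))
  names(residue_sets) <- res_names
  residue_sets <- residue_sets[topo]

  residues <- data.frame(
    name = topo,
    parent = unname(par[topo]),
    inner_core = vapply(cfg$residues, function(r) isTRUE(r$inner_core), NA)[ord],
    stringsAsFactors = FALSE
  )
  root <- is.na(residues$parent)
  no_tr <- vapply(residue_sets, function(s) length(s$transferases) == 0L, NA)
  if (any(!root & no_tr))
    stop("pathway configuration error: non-root residue without transferase: ",
         residues$name[!root & no_tr][1L])

  mods <- lapply(cfg$modifications, function(m)
    list(name = as.character(m$name),
         target = as.character(m$target),
         genes = getset(m, "genes"),
         phosphate = isTRUE(m$phosphate),
         nonstoichiometric = isTRUE(m$nonstoichiometric),
         uncertain = isTRUE(m$uncertain)))
  mod_names <- vapply(mods, `[[`, "", "name")
  names(mods) <- mod_names
  if (anyDuplicated(mod_names))
    stop("pathway configuration error: duplicate modification name")
  bad_t <- vapply(mods, function(m) !(m$target %in% res_names), NA)
  if (any(bad_t))
    stop("pathway configuration error: modification targets unknown residue: ",
         mod_names[bad_t][1L])

  gene_roster <- sort(unique(c(
    unlist(lapply(residue_sets, function(s) c(s$transferases, s$precursors))),
    unlist(lapply(mods, `[[`, "genes"))
  )))
  regulators <- as.character(unlist(cfg$regulators))
  lps_genes <- if (is.null(cfg$lps_genes)) gene_roster else
    as.character(unlist(cfg$lps_genes))

  structure(list(
    name = if (is.null(cfg$name)) "lps_pathway" else as.character(cfg$name),
    residues = residues,
    residue_sets = residue_sets,
    modifications = mods,
    gene_roster = gene_roster,
    regulator_genes = regulators,
    lps_genes = lps_genes
  ), class = "lps_pathway")
}

#' Path to the packaged E. coli C pathway configuration
#' @return File path of the YAML configuration shipped with the package.
#' @export
lps_pathway_file <- function() {
  system.file("extdata", "ecoli_c_pathway.yaml", package = "lpsmap",
              mustWork = TRUE)
}

#' @export
print.lps_pathway <- function(x, ...) {
  cat("LPS assembly model '", x$name, "': ", nrow(x$residues),
      " residues, ", length(x$modifications), " modifications, ",
      length(x$gene_roster), " genes (regulators: ",
      paste(x$regulator_genes, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Predict the LPS structure of a loss-of-function mutant
#'
#' Propagates knockouts through the assembly graph under the
#' one-gene-one-phenotype truncation model: a residue is present iff all
#' of its transferase and precursor genes are functional and its parent
#' residue is present; a modification is present iff its gating genes are
#' functional and its target residue is present.  Components assembled
#' downstream of a missing component are therefore absent as well.
#'
#' @param model An \code{lps_pathway}.
#' @param lof_genes Character vector of genes called loss-of-function.
#'   Must be a subset of the model's gene roster; regulator genes are
#'   rejected here (their structures are unpredictable; see
#'   \code{\link{predict_partition}}).
#' @return An \code{lps_structure}: list with \code{residues},
#'   \code{modifications} (present sets, nonstoichiometric ones included),
#'   \code{canonical_key} and \code{model_name}.
#' @examples
#' mod <- load_pathway(lps_pathway_file())
#' predict_structure(mod, "waaC")   # heptoseless deep-rough structure
#' @export
predict_structure <- function(model, lof_genes = character(0)) {
  stopifnot(inherits(model, "lps_pathway"))
  lof_genes <- unique(as.character(lof_genes))
  reg <- intersect(lof_genes, model$regulator_genes)
  if (length(reg) > 0L)
    stop("unpredictable: regulator gene(s) mutated: ",
         paste(reg, collapse = ", "))
  unknown <- setdiff(lof_genes, model$gene_roster)
  if (length(unknown) > 0L)
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))

  present <- character(0)
  for (nm in model$residues$name) {          # topological order
    par <- model$residues$parent[model$residues$name == nm]
    sets <- model$residue_sets[[nm]]
    genes_ok <- !any(c(sets$transferases, sets$precursors) %in% lof_genes)
    parent_ok <- is.na(par) || par %in% present
    if (genes_ok && parent_ok) present <- c(present, nm)
  }
  mods_present <- character(0)
  for (m in model$modifications) {
    if (!any(m$genes %in% lof_genes) && m$target %in% present)
      mods_present <- c(mods_present, m$name)
  }
  new_lps_structure(model, present, mods_present)
}

new_lps_structure <- function(model, residues, modifications) {
  stoich <- vapply(model$modifications, function(m) !m$nonstoichiometric, NA)
  key_mods <- intersect(modifications,
                        names(model$modifications)[stoich])
  key <- paste0("res:", paste(sort(residues), collapse = ","),
                "|mod:", paste(sort(key_mods), collapse = ","))
  structure(list(residues = residues,
                 modifications = modifications,
                 canonical_key = key,
                 model_name = model$name),
            class = "lps_structure")
}

#' @export
print.lps_structure <- function(x, ...) {
  cat("LPS structure [", x$model_name, "]\n  residues: ",
      paste(x$residues, collapse = ", "), "\n  modifications: ",
      paste(x$modifications, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Canonical identity key of a predicted structure
#'
#' Deterministic serialization of the present residue set and the present
#' stoichiometric modifications; nonstoichiometric decorations are
#' excluded, since they never distinguish structural classes here.
#' @param structure An \code{lps_structure}.
#' @return Character scalar usable for equality and partitioning.
#' @export
canonical_key <- function(structure) {
  stopifnot(inherits(structure, "lps_structure"))
  structure$canonical_key
}

#' Classify a predicted structure as rough or deep rough
#'
#' A mutant structure is called \code{deep_rough} when its outer core is
#' completely truncated (no non-inner-core backbone residue remains) or
#' when any stoichiometric phosphate decoration present in the wild type
#' is lost; smaller truncations confined to the outer core (or a
#' structure identical to wild type) are \code{rough}.
#'
#' @param structure,wt \code{lps_structure}s predicted from the same model.
#' @param model The \code{lps_pathway} both derive from.
#' @return Character scalar \code{"rough"} or \code{"deep_rough"}.
#' @export
classify_lps_type <- function(structure, wt, model) {
  stopifnot(inherits(structure, "lps_structure"),
            inherits(wt, "lps_structure"),
            inherits(model, "lps_pathway"))
  if (structure$model_name != wt$model_name ||
      structure$model_name != model$name)
    stop("structures derive from different models")
  outer <- model$residues$name[!model$residues$inner_core]
  outer_gone <- length(outer) > 0L &&
    !any(outer %in% structure$residues)
  stoich_p <- vapply(model$modifications,
                     function(m) m$phosphate && !m$nonstoichiometric, NA)
  p_names <- names(model$modifications)[stoich_p]
  p_lost <- any(p_names %in% wt$modifications &
                  !(p_names %in% structure$modifications))
  if (outer_gone || p_lost) "deep_rough" else "rough"
}

#' Partition strains by predicted LPS structure
#'
#' Calls loss of function on every mutation (see \code{\link{call_lof}}),
#' predicts each strain's structure and groups strains by canonical key.
#' Strains carrying a mutated regulator gene form one class per regulator
#' gene, labelled \code{unpredicted:<gene>}.  Strains with no
#' loss-of-function call in the gene roster are excluded with a warning.
#'
#' @param model An \code{lps_pathway}.
#' @param strains List of \code{strain_genotype} objects
#'   (\code{\link{read_strain_table}}).
#' @param policy Loss-of-function policy, passed to \code{\link{call_lof}}.
#' @return An object of class \code{lps_partition}: list with
#'   \code{labels} (named character vector strain -> class label),
#'   \code{classes} (list class label -> strain ids), \code{structures}
#'   (class label -> \code{lps_structure} or NULL for unpredicted),
#'   \code{types} (class label -> rough/deep_rough/unpredicted) and
#'   \code{excluded}.
#' @examples
#' mod <- load_pathway(lps_pathway_file())
#' strains <- read_strain_table(lps_strain_table_file())
#' p <- predict_partition(mod, strains)
#' length(p$classes)   # distinct predicted structures + regulator classes
#' @export
predict_partition <- function(model, strains,
                              policy = c("permissive", "conservative")) {
  stopifnot(inherits(model, "lps_pathway"))
  policy <- match.arg(policy)
  wt <- predict_structure(model, character(0))

  labels <- stats::setNames(character(0), character(0))
  structures <- list()
  excluded <- character(0)
  for (s in strains) {
    lof <- vapply(s$mutations, function(m)
      call_lof(m, policy = policy)$is_lof, NA)
    genes <- unique(vapply(s$mutations, `[[`, "", "gene")[lof])
    reg <- intersect(genes, model$regulator_genes)
    genes <- intersect(genes, model$gene_roster)
    if (length(reg) > 0L) {
      lab <- paste0("unpredicted:", sort(reg)[1L])
      labels[s$strain_id] <- lab
      structures[[lab]] <- list(NULL)
    } else if (length(genes) == 0L) {
      warning("strain ", s$strain_id,
              " has no LoF-callable mutation in the gene roster; excluded")
      excluded <- c(excluded, s$strain_id)
    } else {
      str <- predict_structure(model, genes)
      lab <- canonical_key(str)
      labels[s$strain_id] <- lab
      structures[[lab]] <- str
    }
  }
  classes <- if (length(labels) > 0L) split(names(labels), labels) else
    stats::setNames(list(), character(0))
  types <- vapply(names(classes), function(lab) {
    if (startsWith(lab, "unpredicted:")) "unpredicted"
    else classify_lps_type(structures[[lab]], wt, model)
  }, "")
  structure(list(labels = labels, classes = classes,
                 structures = structures, types = types,
                 wt_structure = wt, excluded = excluded),
            class = "lps_partition")
}

#' @export
print.lps_partition <- function(x, ...) {
  cat("Predicted LPS partition: ", length(x$classes), " classes over ",
      length(x$labels), " strains\n", sep = "")
  for (lab in names(x$classes))
    cat("  [", x$types[[lab]], "] ",
        paste(sort(x$classes[[lab]]), collapse = ", "), "\n", sep = "")
  invisible(x)
}
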