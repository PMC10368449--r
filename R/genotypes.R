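#' @title Mutation tables for strains and phages
#' @description Readers/writers for the tab-delimited mutation tables and
#'   the loss-of-function policy used throughout the pipeline.
#' @name genotypes
NULL

# whole-line "#" comments only: descriptors may legitimately contain "#"
# (e.g. frameshift notation L249fsTer#263)
.read_tsv_commented <- function(path, colClasses = NA) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  utils::read.delim(text = paste(lines, collapse = "\n"),
                    colClasses = colClasses, stringsAsFactors = FALSE)
}

.effect_vocabulary <- c("nonsense", "frameshift", "missense",
                        "inframe_indel", "is_insertion", "duplication",
                        "regulatory", "intergenic")
.phage_proteins <- c("F", "H", "A", "A*")

#' Read a strain mutation table
#'
#' Tab-delimited, UTF-8, \code{#} comments; columns \code{strain_id},
#' \code{gene}, \code{effect}, \code{descriptor}, \code{position},
#' \code{included}.  One row per mutation; a strain's rows are kept in
#' file order.
#'
#' @param path File path.
#' @param included_only Drop strains flagged \code{included = FALSE}.
#' @return List of \code{strain_genotype} objects: \code{strain_id},
#'   \code{included}, \code{mutations} (list of \code{gene_mutation}:
#'   \code{gene}, \code{effect}, \code{descriptor}, \code{position}).
#' @export
read_strain_table <- function(path, included_only = TRUE) {
  df <- .read_tsv_commented(path)
  required <- c("strain_id", "gene", "effect", "descriptor", "position",
                "included")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("strain table parse error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  bad <- !(df$effect %in% .effect_vocabulary)
  if (any(bad))
    stop("strain table parse error: unknown effect '", df$effect[bad][1L],
         "' in row ", which(bad)[1L], " (strain ", df$strain_id[bad][1L], ")")
  if (any(df$position < 1L))
    stop("strain table parse error: position < 1 in row ",
         which(df$position < 1L)[1L])
  key <- paste(df$strain_id, df$gene, df$descriptor, sep = "\r")
  if (anyDuplicated(key))
    stop("strain table parse error: duplicate (strain, gene, descriptor) ",
         "row ", which(duplicated(key))[1L])
  df$included <- as.logical(df$included)
  if (included_only) df <- df[df$included, , drop = FALSE]

  ids <- unique(df$strain_id)
  lapply(ids, function(id) {
    rows <- df[df$strain_id == id, , drop = FALSE]
    muts <- lapply(seq_len(nrow(rows)), function(i)
      structure(list(gene = rows$gene[i], effect = rows$effect[i],
                     descriptor = rows$descriptor[i],
                     position = as.integer(rows$position[i])),
                class = "gene_mutation"))
    structure(list(strain_id = id, included = rows$included[1L],
                   mutations = muts),
              class = "strain_genotype")
  })
}

#' Write a strain mutation table (round-trips with the reader)
#' @param strains List of \code{strain_genotype}.
#' @param path Output file path.
#' @export
write_strain_table <- function(strains, path) {
  rows <- do.call(rbind, lapply(strains, function(s)
    do.call(rbind, lapply(s$mutations, function(m)
      data.frame(strain_id = s$strain_id, gene = m$gene,
                 effect = m$effect, descriptor = m$descriptor,
                 position = m$position, included = s$included,
                 stringsAsFactors = FALSE)))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Path to the packaged (reconstructed) strain mutation table
#' @return File path of the fixture shipped with the package.
#' @export
lps_strain_table_file <- function() {
  system.file("extdata", "strain_mutations.tsv", package = "lpsmap",
              mustWork = TRUE)
}

#' Path to the packaged (reconstructed) phage mutation table
#' @return File path of the fixture shipped with the package.
#' @export
lps_phage_table_file <- function() {
  system.file("extdata", "phage_mutations.tsv", package = "lpsmap",
              mustWork = TRUE)
}

#' Path to the packaged (reconstructed) infection matrix
#' @return File path of the fixture shipped with the package.
#' @export
lps_infection_matrix_file <- function() {
  system.file("extdata", "infection_matrix.csv", package = "lpsmap",
              mustWork = TRUE)
}

#' Call loss of function for a single mutation
#'
#' Under the default policy every mutation in an LPS gene is assumed to
#' abolish function: confidence is \code{high} for effects that disrupt
#' the reading frame or coding capacity (nonsense, frameshift, IS
#' insertion) and \code{assumed} otherwise.  The conservative policy only
#' calls the high-confidence effects.
#'
#' @param m A \code{gene_mutation}.
#' @param policy \code{"permissive"} or \code{"conservative"}.
#' @return List with \code{is_lof} (logical) and \code{confidence}
#'   (\code{"high"} or \code{"assumed"}).
#' @export
call_lof <- function(m, policy = c("permissive", "conservative")) {
  policy <- match.arg(policy)
  stopifnot(inherits(m, "gene_mutation"))
  high <- m$effect %in% c("nonsense", "frameshift", "is_insertion")
  confidence <- if (high) "high" else "assumed"
  is_lof <- if (policy == "permissive") TRUE else high
  list(is_lof = is_lof, confidence = confidence)
}

#' Summary statistics over strain mutations
#'
#' Counts total and unique mutations (uniqueness keyed on
#' \code{(gene, descriptor)}), lists mutations shared by two or more
#' strains, tallies unique mutations by effect category, and reports the
#' fraction of unique mutations that introduce premature stops or
#' frameshifts.
#'
#' @param strains List of \code{strain_genotype}.
#' @return List with \code{total}, \code{unique}, \code{shared}
#'   (named list key -> strain ids), \code{by_effect} (named integer
#'   vector over the unique mutations) and \code{disruptive_fraction}.
#' @export
mutation_stats <- function(strains) {
  rows <- do.call(rbind, lapply(strains, function(s)
    do.call(rbind, lapply(s$mutations, function(m)
      data.frame(strain_id = s$strain_id, gene = m$gene,
                 effect = m$effect, descriptor = m$descriptor,
                 stringsAsFactors = FALSE)))))
  if (is.null(rows) || nrow(rows) == 0L)
    return(list(total = 0L, unique = 0L, shared = list(),
                by_effect = stats::setNames(integer(0), character(0)),
                disruptive_fraction = NA_real_))
  key <- paste(rows$gene, rows$descriptor, sep = " ")
  total <- nrow(rows)
  # canonical row order so the effect attributed to a unique mutation is
  # independent of strain/file order
  ord <- order(key, rows$effect)
  rows <- rows[ord, , drop = FALSE]
  key <- key[ord]
  uniq <- !duplicated(key)
  n_unique <- sum(uniq)
  by_strain <- split(rows$strain_id, key)
  shared <- lapply(by_strain, function(s) sort(unique(s)))
  shared <- shared[vapply(shared, length, 0L) >= 2L]
  by_effect <- table(rows$effect[uniq])
  by_effect <- stats::setNames(as.integer(by_effect), names(by_effect))
  disruptive <- sum(rows$effect[uniq] %in% c("nonsense", "frameshift"))
  list(total = total, unique = n_unique, shared = shared,
       by_effect = by_effect,
       disruptive_fraction = disruptive / n_unique)
}

#' Read a phage mutation table
#'
#' Tab-delimited, \code{#} comments; columns \code{phage_id},
#' \code{host_of_origin}, \code{transfer}, \code{protein}, \code{change},
#' \code{site}.  Sites are 1-based amino-acid positions counting the
#' initial methionine.  A phage listed in the header comment but with no
#' rows simply does not appear; construct empty genotypes explicitly if
#' needed.
#'
#' @param path File path.
#' @return List of \code{phage_genotype}: \code{phage_id},
#'   \code{host_of_origin}, \code{transfer}, \code{changes} (data frame
#'   \code{protein}, \code{change}, \code{site}).
#' @export
read_phage_table <- function(path) {
  # protein ids like "F" must not be type-inferred into logicals
  df <- .read_tsv_commented(path, colClasses = c(protein = "character"))
  required <- c("phage_id", "host_of_origin", "transfer", "protein",
                "change", "site")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("phage table parse error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  bad <- !(df$protein %in% .phage_proteins)
  if (any(bad))
    stop("phage table parse error: unknown protein '", df$protein[bad][1L],
         "' in row ", which(bad)[1L])
  if (any(df$site < 1L))
    stop("phage table parse error: site < 1 in row ",
         which(df$site < 1L)[1L])
  ids <- unique(df$phage_id)
  lapply(ids, function(id) {
    rows <- df[df$phage_id == id, , drop = FALSE]
    structure(list(phage_id = id,
                   host_of_origin = rows$host_of_origin[1L],
                   transfer = as.integer(rows$transfer[1L]),
                   changes = data.frame(protein = rows$protein,
                                        change = rows$change,
                                        site = as.integer(rows$site),
                                        stringsAsFactors = FALSE)),
              class = "phage_genotype")
  })
}

#' Write a phage mutation table (round-trips with the reader)
#' @param phages List of \code{phage_genotype}.
#' @param path Output file path.
#' @export
write_phage_table <- function(phages, path) {
  rows <- do.call(rbind, lapply(phages, function(p) {
    if (nrow(p$changes) == 0L) return(NULL)
    data.frame(phage_id = p$phage_id, host_of_origin = p$host_of_origin,
               transfer = p$transfer, protein = p$changes$protein,
               change = p$changes$change, site = p$changes$site,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summary statistics over phage protein changes
#'
#' Totals and unique counts with uniqueness keyed on
#' \code{(protein, change)}.
#' @param phages List of \code{phage_genotype}.
#' @return List with \code{total}, \code{unique} and \code{per_phage}
#'   (named integer vector of change counts).
#' @export
phage_mutation_stats <- function(phages) {
  rows <- do.call(rbind, lapply(phages, `[[`, "changes"))
  per <- vapply(phages, function(p) nrow(p$changes), 0L)
  names(per) <- vapply(phages, `[[`, "", "phage_id")
  if (is.null(rows) || nrow(rows) == 0L)
    return(list(total = 0L, unique = 0L, per_phage = per))
  key <- paste(rows$protein, rows$change)
  list(total = nrow(rows), unique = length(unique(key)), per_phage = per)
}
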