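#' @title Phage mutation-capability association mining
#' @name gpm
NULL

#' Capability sets of phages over host classes
#'
#' Summarizes each phage's host range at the level of a host partition:
#' under the default permissive variant a phage has the capability for a
#' class when it infects at least one member; the strict variant requires
#' all members.  The wild-type host (if present in the matrix) is
#' reported as a separate flag, not a class.
#'
#' @param matrix An \code{infection_matrix}.
#' @param host_partition Named class labels over (a subset of) the
#'   matrix's hosts, or an \code{lps_partition}.
#' @param strict Require infection of every class member.
#' @param wt_host Host id treated as the wild type (ignored if absent).
#' @return List of capability sets: \code{phage_id},
#'   \code{infected_classes} (character), \code{infects_wt} (logical or
#'   NA when no WT row exists).
#' @export
capability_sets <- function(matrix, host_partition, strict = FALSE,
                            wt_host = "WT") {
  labels <- if (inherits(host_partition, "lps_partition"))
    host_partition$labels else host_partition
  absent <- setdiff(names(labels), matrix$hosts)
  if (length(absent) > 0L)
    stop("partition element(s) absent from matrix: ",
         paste(absent, collapse = ", "))
  classes <- split(names(labels), labels)
  lapply(matrix$phages, function(ph) {
    col <- matrix$cells[, ph]
    caps <- names(classes)[vapply(classes, function(members) {
      hit <- col[members] == 1L
      if (strict) all(hit) else any(hit)
    }, NA)]
    structure(list(phage_id = ph, infected_classes = caps,
                   infects_wt = if (wt_host %in% matrix$hosts)
                     col[wt_host] == 1L else NA),
              class = "capability_set")
  })
}

#' Collapse protein changes to (protein, site) pairs
#'
#' Allelic variants at the same residue (e.g. Q154K and Q154R) are
#' treated as one site-level allele class.
#'
#' @param changes Data frame with columns \code{protein}, \code{change},
#'   \code{site} (as in \code{phage_genotype$changes}).
#' @return Data frame of unique \code{protein}, \code{site} pairs with an
#'   \code{alleles} column collapsing the observed changes.
#' @export
site_aggregate <- function(changes) {
  if (is.null(changes) || nrow(changes) == 0L)
    return(data.frame(protein = character(0), site = integer(0),
                      alleles = character(0), stringsAsFactors = FALSE))
  key <- paste(changes$protein, changes$site)
  agg <- lapply(split(seq_len(nrow(changes)), key), function(i)
    data.frame(protein = changes$protein[i[1L]],
               site = changes$site[i[1L]],
               alleles = paste(sort(unique(changes$change[i])),
                               collapse = "/"),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- out[order(out$protein, out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.site_label <- function(protein, site) paste0("(", protein, ",", site, ")")

#' Mine perfect mutation-capability associations
#'
#' Exact combinatorial association between (protein, site) alleles and a
#' capability: a perfect single-site rule is a site carried by every
#' capable phage and by no incapable phage; a perfect pair rule is a
#' site pair jointly carried by exactly the capable phages.  With this
#' few isolates, association is set logic, not statistics; a Fisher
#' exact p-value is attached to single-site rules as annotation only.
#' When no perfect single site exists, the nearest misses (fewest
#' counterexamples) are reported with their counterexample phage ids
#' rather than suppressed.
#'
#' @param phages List of \code{phage_genotype}.
#' @param capsets List of capability sets
#'   (\code{\link{capability_sets}}), aligned by phage id.
#' @param capability A class label, or \code{"wt_loss"} for loss of the
#'   ability to infect the wild type.
#' @return An \code{association_rule}: \code{capability},
#'   \code{capable} / \code{incapable} phage ids,
#'   \code{perfect_singles}, \code{perfect_pairs} (data frames with
#'   alleles and support), \code{nearest_miss} (non-empty when no perfect
#'   single-site rule exists).
#' @export
perfect_associations <- function(phages, capsets, capability) {
  ids <- vapply(phages, `[[`, "", "phage_id")
  cap_ids <- vapply(capsets, `[[`, "", "phage_id")
  if (!setequal(ids, cap_ids))
    stop("phage ids differ between genotypes and capability sets")
  capsets <- capsets[match(ids, cap_ids)]

  all_classes <- unique(unlist(lapply(capsets, `[[`, "infected_classes")))
  if (capability == "wt_loss") {
    capable <- vapply(capsets, function(cs) isTRUE(!cs$infects_wt), NA)
  } else {
    if (!(capability %in% all_classes))
      stop("unknown capability label: ", capability)
    capable <- vapply(capsets, function(cs)
      capability %in% cs$infected_classes, NA)
  }

  sites <- lapply(phages, function(p) {
    sa <- site_aggregate(p$changes)
    .site_label(sa$protein, sa$site)
  })
  site_tab <- site_aggregate(do.call(rbind, lapply(phages, `[[`, "changes")))
  universe <- .site_label(site_tab$protein, site_tab$site)
  has <- vapply(universe, function(s)
    vapply(sites, function(ss) s %in% ss, NA), rep(NA, length(ids)))
  if (length(ids) == 1L) has <- matrix(has, nrow = 1L)
  rownames(has) <- ids

  support_row <- function(hit) {
    data.frame(capable_with = sum(capable & hit),
               capable_without = sum(capable & !hit),
               incapable_with = sum(!capable & hit),
               incapable_without = sum(!capable & !hit))
  }
  fisher_p <- function(hit) {
    tab <- matrix(c(sum(capable & hit), sum(capable & !hit),
                    sum(!capable & hit), sum(!capable & !hit)), 2L)
    stats::fisher.test(tab)$p.value
  }

  singles <- do.call(rbind, lapply(seq_along(universe), function(k) {
    hit <- has[, k]
    cbind(data.frame(site = universe[k],
                     alleles = site_tab$alleles[k],
                     perfect = all(hit == capable),
                     mismatches = sum(hit != capable),
                     p_fisher = fisher_p(hit),
                     stringsAsFactors = FALSE),
          support_row(hit))
  }))
  perfect_singles <- singles[singles$perfect, , drop = FALSE]

  pairs <- NULL
  if (length(universe) >= 2L) {
    cmb <- utils::combn(seq_along(universe), 2L)
    pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(c2) {
      k1 <- cmb[1L, c2]; k2 <- cmb[2L, c2]
      hit <- has[, k1] & has[, k2]
      if (!all(hit == capable)) return(NULL)
      cbind(data.frame(sites = paste(universe[k1], universe[k2]),
                       alleles = paste(site_tab$alleles[k1],
                                       site_tab$alleles[k2], sep = " + "),
                       stringsAsFactors = FALSE),
            support_row(hit))
    }))
  }

  nearest_miss <- NULL
  if (nrow(perfect_singles) == 0L) {
    best <- singles[singles$mismatches == min(singles$mismatches), ,
                    drop = FALSE]
    best$counterexamples <- vapply(best$site, function(s) {
      hit <- has[, match(s, universe)]
      paste(ids[hit != capable], collapse = ",")
    }, "")
    nearest_miss <- best
  }

  structure(list(capability = capability,
                 capable = ids[capable], incapable = ids[!capable],
                 perfect_singles = perfect_singles,
                 perfect_pairs = pairs,
                 nearest_miss = nearest_miss),
            class = "association_rule")
}

#' @export
print.association_rule <- function(x, ...) {
  cat("Association rule for capability '", x$capability, "' (",
      length(x$capable), " capable / ", length(x$incapable),
      " incapable phages)\n", sep = "")
  if (nrow(x$perfect_singles) > 0L)
    cat("  perfect single sites:",
        paste(x$perfect_singles$site, collapse = ", "), "\n")
  if (!is.null(x$perfect_pairs) && nrow(x$perfect_pairs) > 0L)
    cat("  perfect site pairs:",
        paste(x$perfect_pairs$sites, collapse = "; "), "\n")
  if (!is.null(x$nearest_miss))
    cat("  no perfect single site; nearest miss:",
        x$nearest_miss$site[1L], "with counterexamples",
        x$nearest_miss$counterexamples[1L], "\n")
  invisible(x)
}
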