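# Dataset curation rules and the conformational-dependency statistic.

#' Count rotatable bonds of a molecule
#'
#' A bond counts as rotatable when it is a single, non-aromatic, non-ring
#' bond between two non-terminal heavy atoms (each end bonded to at least
#' two heavy atoms). Bonds to hydrogen never count. Amide bonds are not
#' excluded.
#'
#' @param mol a [molecule()].
#' @return integer count.
#' @export
count_rotatable_bonds <- function(mol) {
  bonds <- mol$bonds
  if (nrow(bonds) == 0L) return(0L)
  heavy <- mol$elements != "H"
  # heavy-neighbour degree per atom
  hdeg <- integer(length(mol$elements))
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    if (heavy[i] && heavy[j]) {
      hdeg[i] <- hdeg[i] + 1L
      hdeg[j] <- hdeg[j] + 1L
    }
  }
  ring_atoms <- mol$ring_info
  in_ring <- function(i, j) {
    any(vapply(ring_atoms, function(r) i %in% r && j %in% r, logical(1)))
  }
  n <- 0L
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    if (bonds$order[b] == 1L && !bonds$aromatic[b] &&
        heavy[i] && heavy[j] && hdeg[i] >= 2L && hdeg[j] >= 2L &&
        !in_ring(i, j)) {
      n <- n + 1L
    }
  }
  n
}

#' Curation rule set for conformer datasets
#'
#' @param allowed_elements character vector of permitted element symbols
#'   (`NULL` disables the rule).
#' @param max_molecular_weight compounds with MW >= this value (Da) are
#'   removed; the bound is strict ("less than"). `NULL` disables.
#' @param drop_stereocenters,drop_cis_trans drop compounds flagged as
#'   containing stereocenters / cis-trans double bonds.
#' @param min_rotatable_bonds compounds with fewer rotatable bonds are
#'   removed. `NULL` disables.
#' @param top_k_by_rotatable_bonds keep only the `k` compounds with the most
#'   rotatable bonds (ties broken by lexicographic compound id). `NULL`
#'   disables.
#' @return object of class `CurationRules`.
#' @export
curation_rules <- function(allowed_elements = NULL,
                           max_molecular_weight = NULL,
                           drop_stereocenters = FALSE,
                           drop_cis_trans = FALSE,
                           min_rotatable_bonds = NULL,
                           top_k_by_rotatable_bonds = NULL) {
  rules <- list(allowed_elements = allowed_elements,
                max_molecular_weight = max_molecular_weight,
                drop_stereocenters = drop_stereocenters,
                drop_cis_trans = drop_cis_trans,
                min_rotatable_bonds = min_rotatable_bonds,
                top_k_by_rotatable_bonds = top_k_by_rotatable_bonds)
  active <- !is.null(allowed_elements) || !is.null(max_molecular_weight) ||
    isTRUE(drop_stereocenters) || isTRUE(drop_cis_trans) ||
    !is.null(min_rotatable_bonds) || !is.null(top_k_by_rotatable_bonds)
  if (!active) stop("at least one curation rule must be active")
  structure(rules, class = "CurationRules")
}

#' Apply curation rules to a dataset
#'
#' Filters are applied in a fixed order: element alphabet, molecular weight,
#' stereo flags, minimum rotatable bonds, top-k ranking by rotatable bonds.
#' The log records how many compounds each rule removed.
#'
#' @param dataset a [conformer_dataset()].
#' @param rules a [curation_rules()] object.
#' @return list with `dataset` (curated) and `log` (data.frame rule /
#'   removed_count).
#' @export
curate <- function(dataset, rules) {
  stopifnot(inherits(rules, "CurationRules"))
  keep <- names(dataset$ensembles)
  log <- data.frame(rule = character(), removed_count = integer())
  note <- function(rule, before, after) {
    log <<- rbind(log, data.frame(rule = rule,
                                  removed_count = length(before) - length(after)))
  }
  mols <- lapply(dataset$ensembles, `[[`, "molecule")

  if (!is.null(rules$allowed_elements)) {
    ok <- vapply(keep, function(id) {
      all(mols[[id]]$elements %in% rules$allowed_elements)
    }, logical(1))
    new <- keep[ok]; note("allowed_elements", keep, new); keep <- new
  }
  if (!is.null(rules$max_molecular_weight)) {
    ok <- vapply(keep, function(id) {
      molecular_weight(mols[[id]]) < rules$max_molecular_weight
    }, logical(1))
    new <- keep[ok]; note("max_molecular_weight", keep, new); keep <- new
  }
  if (isTRUE(rules$drop_stereocenters)) {
    ok <- !vapply(keep, function(id) mols[[id]]$has_stereocenter, logical(1))
    new <- keep[ok]; note("drop_stereocenters", keep, new); keep <- new
  }
  if (isTRUE(rules$drop_cis_trans)) {
    ok <- !vapply(keep, function(id) mols[[id]]$has_cis_trans, logical(1))
    new <- keep[ok]; note("drop_cis_trans", keep, new); keep <- new
  }
  rot <- NULL
  if (!is.null(rules$min_rotatable_bonds) ||
      !is.null(rules$top_k_by_rotatable_bonds)) {
    rot <- vapply(keep, function(id) count_rotatable_bonds(mols[[id]]),
                  integer(1))
  }
  if (!is.null(rules$min_rotatable_bonds)) {
    new <- keep[rot >= rules$min_rotatable_bonds]
    note("min_rotatable_bonds", keep, new)
    rot <- rot[keep %in% new]; keep <- new
  }
  if (!is.null(rules$top_k_by_rotatable_bonds) &&
      length(keep) > rules$top_k_by_rotatable_bonds) {
    ord <- order(-rot, keep)          # descending count, lexicographic id ties
    new <- sort(keep[ord][seq_len(rules$top_k_by_rotatable_bonds)])
    note("top_k_by_rotatable_bonds", keep, new); keep <- new
  }
  if (length(keep) == 0L) {
    warning("curation removed every compound")
    return(list(dataset = structure(list(ensembles = list(), properties = list()),
                                    class = "ConformerDataset"),
                log = log))
  }
  list(dataset = conformer_dataset(dataset$ensembles[keep],
                                   dataset$properties[keep]),
       log = log)
}

#' Conformational dependency of a property
#'
#' For each compound, the sample standard deviation (denominator n-1; a
#' singleton has SD 0) of its per-conformer property values, scaled by the
#' interquartile range of the per-compound mean values across the dataset
#' (linear-interpolation quantiles). A zero IQR makes the scaled statistic
#' undefined: all values are returned as `NA` with a warning.
#'
#' @param dataset a [conformer_dataset()].
#' @param per_conformer_values named list: compound id -> numeric vector of
#'   the property evaluated on each conformer.
#' @param iqr_population reference population for the IQR: "compound_means"
#'   (default) or "all_values" (pooled conformer-level values).
#' @return named numeric vector of scaled SDs, one per compound.
#' @export
conformational_dependency <- function(dataset, per_conformer_values,
                                      iqr_population = c("compound_means",
                                                         "all_values")) {
  iqr_population <- match.arg(iqr_population)
  ids <- names(dataset$ensembles)
  stopifnot(all(ids %in% names(per_conformer_values)))
  vals <- per_conformer_values[ids]
  stopifnot(all(vapply(vals, length, integer(1)) >= 1L))
  sds <- vapply(vals, function(v) if (length(v) < 2L) 0 else stats::sd(v),
                numeric(1))
  pop <- if (iqr_population == "compound_means") {
    vapply(vals, mean, numeric(1))
  } else {
    unlist(vals, use.names = FALSE)
  }
  iqr <- diff(stats::quantile(pop, c(0.25, 0.75), type = 7, names = FALSE))
  if (iqr <= 0) {
    warning("IQR of the reference population is zero; scaled SDs undefined")
    return(stats::setNames(rep(NA_real_, length(ids)), ids))
  }
  stats::setNames(sds / iqr, ids)
}
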