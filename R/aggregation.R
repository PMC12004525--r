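# Collapsing per-conformer descriptor matrices into per-compound vectors
# (Boltzmann, mean, global minimum, random, RMSD-extreme) or expanding them
# into multi-instance bags (nonaggregation).

#' Boltzmann existence probabilities of conformers
#'
#' p_i proportional to exp(-E_i / (k T)), normalized to sum to 1, with
#' k = 0.0019872041 kcal/(mol K). The minimum energy is subtracted before
#' exponentiation so large-magnitude total energies cannot overflow; the
#' weights are invariant to that shift.
#'
#' @param energies conformer energies, kcal/mol.
#' @param temperature absolute temperature, K (default 298).
#' @return object of class `ConformerWeights`: list with `p` (sums to 1),
#'   `temperature`, `boltzmann_constant`.
#' @export
boltzmann_weights <- function(energies, temperature = 298) {
  if (length(energies) == 0L) stop("empty energy list")
  if (any(!is.finite(energies))) stop("non-finite conformer energies")
  stopifnot(temperature > 0)
  w <- exp(-(energies - min(energies)) / (.kB_KCAL * temperature))
  structure(list(p = w / sum(w), temperature = temperature,
                 boltzmann_constant = .kB_KCAL),
            class = "ConformerWeights")
}

#' Aggregate a per-conformer descriptor matrix into one compound vector
#'
#' Methods: `boltzmann` = sum_i p_i x_i with Boltzmann weights of the
#' supplied energies; `mean` = (1/N) sum_i x_i; `global_min` = the row of
#' the lowest-energy conformer; `random` = one uniformly sampled row
#' (seeded); `rmsd_max` / `rmsd_min` = the row of the conformer with the
#' largest / smallest RMSD to the ground truth. Ties are broken by the
#' lowest row (conformer) index. With a single conformer every method
#' returns that row.
#'
#' @param m `DescriptorMatrix` (rows = conformers in conformer order).
#' @param method one of "boltzmann", "mean", "global_min", "random",
#'   "rmsd_max", "rmsd_min".
#' @param energies conformer energies (kcal/mol); required by "boltzmann"
#'   and "global_min".
#' @param rmsd per-conformer RMSD vector (see [rmsd_to_ground_truth()]);
#'   required by "rmsd_max" / "rmsd_min".
#' @param seed integer; required by "random".
#' @param temperature Kelvin for the Boltzmann weights.
#' @return named numeric vector (class `AggregatedVector`) with attributes
#'   `method` and `compound_id`.
#' @export
aggregate_descriptors <- function(m,
                                  method = c("boltzmann", "mean", "global_min",
                                             "random", "rmsd_max", "rmsd_min"),
                                  energies = NULL, rmsd = NULL, seed = NULL,
                                  temperature = 298) {
  method <- match.arg(method)
  n <- nrow(m)
  need <- function(x, what) {
    if (is.null(x)) stop("method '", method, "' requires ", what)
    if (length(x) != n) stop(what, " length (", length(x),
                             ") != conformer count (", n, ")")
    x
  }
  x <- switch(method,
    boltzmann = {
      en <- need(energies, "conformer energies")
      if (any(is.na(en))) stop("method 'boltzmann' requires energies for every conformer")
      w <- boltzmann_weights(en, temperature)
      as.numeric(w$p %*% m)
    },
    mean = colMeans(m),
    global_min = {
      en <- need(energies, "conformer energies")
      if (any(is.na(en))) stop("method 'global_min' requires energies for every conformer")
      m[which.min(en), ]
    },
    random = {
      if (is.null(seed)) stop("method 'random' requires a seed")
      i <- with_seed(seed, sample.int(n, 1L))
      m[i, ]
    },
    rmsd_max = m[which.max(need(rmsd, "a per-conformer RMSD vector")), ],
    rmsd_min = m[which.min(need(rmsd, "a per-conformer RMSD vector")), ])
  structure(stats::setNames(as.numeric(x), colnames(m)),
            method = method, compound_id = attr(m, "compound_id"),
            class = "AggregatedVector")
}

#' Expand a dataset into multi-instance bags
#'
#' One bag per compound: every conformer's descriptor row becomes an
#' instance carrying the compound's property value. Total instances equal
#' total conformers.
#'
#' @param dataset a [conformer_dataset()].
#' @param matrices named list of `DescriptorMatrix` covering every compound.
#' @return list of bags: `list(compound_id, rows, y)`.
#' @export
expand_bags <- function(dataset, matrices) {
  ids <- names(dataset$ensembles)
  missing <- setdiff(ids, names(matrices))
  if (length(missing) > 0L) {
    stop("no descriptor matrix for compound(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  lapply(ids, function(id) {
    list(compound_id = id, rows = matrices[[id]],
         y = dataset$properties[[id]]$value)
  })
}

#' Pool per-conformer predictions into one compound prediction
#'
#' Arithmetic mean of the conformer-level predictions (the test-time rule of
#' the nonaggregation / instance-wrapper scheme).
#'
#' @param predictions numeric vector, one prediction per conformer.
#' @return numeric scalar.
#' @export
pool_bag_predictions <- function(predictions) {
  if (length(predictions) == 0L) stop("no predictions to pool")
  mean(predictions)
}
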