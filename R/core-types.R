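#' Chemical graph of a compound
#'
#' A light molecular-graph container: element-labelled atoms, bonds with
#' order and aromaticity, and perceived rings. Hydrogens are explicit atoms.
#' This is the 2D input for topological descriptors and curation rules;
#' geometry lives in [conformer()] objects.
#'
#' @param compound_id character scalar identifying the compound.
#' @param elements character vector of element symbols, one per atom.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `order` (1, 2, 3) and `aromatic` (logical). Missing `order`/`aromatic`
#'   default to single, non-aromatic.
#' @param charges integer formal charges per atom (default all 0).
#' @param ring_info list of integer vectors, each the atom set of one ring.
#'   If `NULL`, rings are perceived from the bond graph.
#' @param has_stereocenter,has_cis_trans logical flags consumed by
#'   [curate()]; populated by an external perception adapter (the built-in
#'   chain generator produces neither).
#' @return an object of class `Molecule`.
#' @export
molecule <- function(compound_id, elements, bonds,
                     charges = integer(length(elements)),
                     ring_info = NULL,
                     has_stereocenter = FALSE, has_cis_trans = FALSE) {
  stopifnot(is.character(compound_id), length(compound_id) == 1L,
            is.character(elements), length(elements) >= 1L)
  .element_lookup(elements, "element")  # validates the alphabet
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0L) {
    if (is.null(bonds$order)) bonds$order <- 1L
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    stopifnot(all(bonds$i >= 1L), all(bonds$j >= 1L),
              all(bonds$i <= length(elements)), all(bonds$j <= length(elements)))
    if (any(bonds$i == bonds$j)) stop("self-bond in molecule ", compound_id)
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond in molecule ", compound_id)
  } else {
    bonds <- data.frame(i = integer(), j = integer(),
                        order = integer(), aromatic = logical())
  }
  if (is.null(ring_info)) ring_info <- find_rings(length(elements), bonds)
  structure(list(compound_id = compound_id,
                 elements = elements,
                 charges = as.integer(charges),
                 bonds = bonds,
                 ring_info = ring_info,
                 has_stereocenter = isTRUE(has_stereocenter),
                 has_cis_trans = isTRUE(has_cis_trans)),
            class = "Molecule")
}

#' @export
print.Molecule <- function(x, ...) {
  cat("Molecule", x$compound_id, "-", length(x$elements), "atoms (",
      sum(x$elements != "H"), "heavy ),", nrow(x$bonds), "bonds,",
      length(x$ring_info), "rings\n")
  invisible(x)
}

#' Molecular weight of a molecule (Da)
#' @param mol a [molecule()].
#' @return numeric scalar, Da.
#' @export
molecular_weight <- function(mol) {
  sum(.element_lookup(mol$elements, "mass"))
}

# Indices of non-hydrogen atoms.
heavy_atoms <- function(mol) which(mol$elements != "H")

#' One 3D geometry of a molecule
#'
#' @param molecule_ref compound id this geometry belongs to.
#' @param conformer_index integer >= 0; 0-based within the ensemble.
#' @param coords numeric atom_count x 3 matrix of Cartesian coordinates (A).
#' @param energy conformer energy in kcal/mol, or `NA` when unknown.
#' @return an object of class `Conformer`.
#' @export
conformer <- function(molecule_ref, conformer_index, coords, energy = NA_real_) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 1L)
  if (!all(is.finite(coords))) stop("non-finite coordinates in conformer of ",
                                    molecule_ref)
  structure(list(molecule_ref = molecule_ref,
                 conformer_index = as.integer(conformer_index),
                 coords = unname(coords),
                 energy = as.numeric(energy),
                 atom_count = nrow(coords)),
            class = "Conformer")
}

#' A molecule together with its conformers
#'
#' @param molecule a [molecule()].
#' @param conformers list of [conformer()] objects, all with the molecule's
#'   atom count and unique `conformer_index`.
#' @param ground_truth optional atom_count x 3 coordinate matrix of the
#'   reference ("ground-truth") conformation; it need not equal any member
#'   of `conformers`.
#' @return an object of class `ConformerEnsemble`.
#' @export
conformer_ensemble <- function(molecule, conformers, ground_truth = NULL) {
  stopifnot(inherits(molecule, "Molecule"), length(conformers) >= 1L)
  n_atoms <- length(molecule$elements)
  for (cf in conformers) {
    stopifnot(inherits(cf, "Conformer"))
    if (cf$atom_count != n_atoms) {
      stop("conformer atom count (", cf$atom_count, ") differs from molecule (",
           n_atoms, ") for compound ", molecule$compound_id)
    }
  }
  idx <- vapply(conformers, `[[`, integer(1), "conformer_index")
  if (anyDuplicated(idx)) stop("duplicate conformer_index for compound ",
                               molecule$compound_id)
  if (!is.null(ground_truth)) {
    ground_truth <- unname(as.matrix(ground_truth))
    stopifnot(nrow(ground_truth) == n_atoms, ncol(ground_truth) == 3L)
  }
  structure(list(molecule = molecule,
                 conformers = conformers,
                 ground_truth = ground_truth),
            class = "ConformerEnsemble")
}

#' @export
print.ConformerEnsemble <- function(x, ...) {
  en <- conformer_energies(x)
  cat("ConformerEnsemble", x$molecule$compound_id, "-",
      length(x$conformers), "conformers,",
      if (all(is.na(en))) "no energies," else "energies present,",
      if (is.null(x$ground_truth)) "no ground truth\n" else "ground truth present\n")
  invisible(x)
}

#' Energies of an ensemble's conformers (kcal/mol, NA when absent)
#' @param ensemble a [conformer_ensemble()].
#' @return numeric vector of length N.
#' @export
conformer_energies <- function(ensemble) {
  vapply(ensemble$conformers, `[[`, numeric(1), "energy")
}

#' A measured or simulated compound-level property value
#'
#' @param compound_id compound identifier.
#' @param value finite numeric property value.
#' @param property_name name of the property (e.g. "dipole_moment").
#' @param units unit string, may be empty.
#' @return an object of class `PropertyRecord`.
#' @export
property_record <- function(compound_id, value, property_name, units = "") {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(compound_id = compound_id, value = as.numeric(value),
                 property_name = property_name, units = units),
            class = "PropertyRecord")
}

#' Matched conformer ensembles and property records
#'
#' Ensembles and properties are keyed by compound id; construction enforces
#' the one-to-one match (every ensemble has a property and vice versa).
#'
#' @param ensembles named list of [conformer_ensemble()] objects (names =
#'   compound ids), or an unnamed list (names taken from the molecules).
#' @param properties named list of [property_record()] objects.
#' @return an object of class `ConformerDataset`.
#' @export
conformer_dataset <- function(ensembles, properties) {
  if (is.null(names(ensembles))) {
    names(ensembles) <- vapply(ensembles, function(e) e$molecule$compound_id,
                               character(1))
  }
  if (is.null(names(properties))) {
    names(properties) <- vapply(properties, `[[`, character(1), "compound_id")
  }
  if (!setequal(names(ensembles), names(properties))) {
    stop("ensembles and properties must cover the same compound ids")
  }
  properties <- properties[names(ensembles)]
  structure(list(ensembles = ensembles, properties = properties),
            class = "ConformerDataset")
}

#' @export
print.ConformerDataset <- function(x, ...) {
  n_conf <- sum(vapply(x$ensembles, function(e) length(e$conformers), integer(1)))
  cat("ConformerDataset:", length(x$ensembles), "compounds,",
      n_conf, "conformers\n")
  invisible(x)
}

#' @export
length.ConformerDataset <- function(x) length(x$ensembles)

#' Property values of a dataset, in ensemble order
#' @param dataset a [conformer_dataset()].
#' @return named numeric vector keyed by compound id.
#' @export
dataset_values <- function(dataset) {
  vapply(dataset$properties, `[[`, numeric(1), "value")
}
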