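# Synthetic conformer-ensemble generator: bead-chain molecules with
# tetrahedral geometry, discrete dihedral states plus Gaussian noise, a toy
# 12-6 nonbonded energy, and property values with a tunable conformational
# dependency. Stands in for externally generated/optimized conformer sets so
# the whole pipeline is testable offline.

.BOND_LENGTH_CC <- 1.54   # A, heavy-heavy
.BOND_LENGTH_XH <- 1.09   # A, heavy-hydrogen
.BOND_ANGLE     <- 109.47 # degrees, tetrahedral
.CLASH_DIST     <- 0.9    # A, minimum nonbonded separation
.GT_PERTURB_SD  <- 0.1    # A, ground-truth perturbation

#' Configuration of the synthetic ensemble generator
#'
#' @param n_compounds number of compounds to generate.
#' @param heavy_atoms_range integer (min, max) heavy-chain length.
#' @param element_alphabet elements sampled for chain atoms (hydrogens are
#'   completed implicitly to standard valence).
#' @param conformers_per_compound_range integer (min, max) conformers per
#'   compound. The default cap of 40 mirrors common conformer-generation
#'   protocols.
#' @param dihedral_states backbone dihedral states, degrees (default the
#'   staggered 60/180/300).
#' @param dihedral_noise_sd Gaussian jitter on each dihedral, degrees.
#' @param seed integer; fixes the full output.
#' @return object of class `GeneratorConfig`.
#' @export
generator_config <- function(n_compounds = 50L,
                             heavy_atoms_range = c(4L, 9L),
                             element_alphabet = c("C", "N", "O"),
                             conformers_per_compound_range = c(2L, 40L),
                             dihedral_states = c(60, 180, 300),
                             dihedral_noise_sd = 12,
                             seed = 1L) {
  stopifnot(n_compounds >= 1L,
            length(heavy_atoms_range) == 2L,
            heavy_atoms_range[1] >= 2L,
            heavy_atoms_range[1] <= heavy_atoms_range[2],
            length(conformers_per_compound_range) == 2L,
            conformers_per_compound_range[1] >= 1L,
            conformers_per_compound_range[1] <= conformers_per_compound_range[2],
            length(dihedral_states) >= 1L, dihedral_noise_sd >= 0)
  .element_lookup(element_alphabet, "element")
  structure(list(n_compounds = as.integer(n_compounds),
                 heavy_atoms_range = as.integer(heavy_atoms_range),
                 element_alphabet = element_alphabet,
                 conformers_per_compound_range =
                   as.integer(conformers_per_compound_range),
                 dihedral_states = dihedral_states,
                 dihedral_noise_sd = dihedral_noise_sd,
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

#' Specification of the synthetic property
#'
#' Controls how strongly the generated property depends on conformation:
#' `dependency_weight` (lambda) mixes a geometric, dipole-like term f_geo
#' with a purely compositional term g_graph,
#' value = lambda * f_geo + (1 - lambda) * g_graph + Normal(0, noise_sd).
#' With `mode = "geometric_ground_truth"` f_geo is evaluated on the
#' ground-truth conformer; with `"ensemble_boltzmann_average"` it is the
#' Boltzmann-weighted ensemble average at `temperature`; with
#' `"composition_only"` the value is g_graph alone (a function of the
#' chemical graph, independent of any conformer).
#'
#' @param mode one of "geometric_ground_truth", "ensemble_boltzmann_average",
#'   "composition_only".
#' @param dependency_weight lambda in [0, 1].
#' @param noise_sd SD of additive Gaussian noise on the value.
#' @param temperature Kelvin, used by the Boltzmann-average mode.
#' @return object of class `PropertySpec`.
#' @export
property_spec <- function(mode = c("geometric_ground_truth",
                                   "ensemble_boltzmann_average",
                                   "composition_only"),
                          dependency_weight = 1,
                          noise_sd = 0.1,
                          temperature = 298) {
  mode <- match.arg(mode)
  stopifnot(dependency_weight >= 0, dependency_weight <= 1,
            noise_sd >= 0, temperature > 0)
  structure(list(mode = mode, dependency_weight = dependency_weight,
                 noise_sd = noise_sd, temperature = temperature),
            class = "PropertySpec")
}

#' Generate a linear heavy-atom chain molecule
#'
#' Heavy atoms form a single-bonded chain; elements are sampled i.i.d. from
#' the alphabet (interior positions only from elements with valence >= 2),
#' and hydrogens are appended to complete standard valences. Atom order is
#' heavy chain first, then hydrogens grouped by parent heavy atom.
#'
#' @param n_heavy chain length, >= 2.
#' @param element_alphabet candidate elements.
#' @param seed integer seed; the same seed reproduces the molecule.
#' @param compound_id id for the molecule (default derived from the seed).
#' @return a [molecule()] carrying a `chain_info` attribute used by
#'   [sample_conformers()].
#' @export
generate_chain_molecule <- function(n_heavy, element_alphabet = c("C", "N", "O"),
                                    seed = 1L,
                                    compound_id = sprintf("mol_seed%d", seed)) {
  if (n_heavy < 2L) stop("a chain molecule needs n_heavy >= 2")
  .element_lookup(element_alphabet, "element")
  interior_ok <- element_alphabet[.element_lookup(element_alphabet, "valence") >= 2L]
  if (n_heavy > 2L && length(interior_ok) == 0L) {
    stop("element_alphabet has no element of valence >= 2 for interior positions")
  }
  heavy <- with_seed(seed, {
    e <- character(n_heavy)
    e[c(1L, n_heavy)] <- sample(element_alphabet, 2L, replace = TRUE)
    if (n_heavy > 2L) {
      e[2:(n_heavy - 1L)] <- sample(interior_ok, n_heavy - 2L, replace = TRUE)
    }
    e
  })
  valences <- .element_lookup(heavy, "valence")
  heavy_deg <- c(1L, rep(2L, max(0L, n_heavy - 2L)), 1L)[seq_len(n_heavy)]
  if (n_heavy == 2L) heavy_deg <- c(1L, 1L)
  n_h <- pmax(0L, valences - heavy_deg)
  elements <- c(heavy, rep("H", sum(n_h)))
  bi <- seq_len(n_heavy - 1L)
  bonds <- data.frame(i = bi, j = bi + 1L, order = 1L, aromatic = FALSE)
  h_of <- vector("list", n_heavy)      # hydrogen indices per heavy atom
  next_idx <- n_heavy
  for (a in seq_len(n_heavy)) {
    if (n_h[a] > 0L) {
      idx <- next_idx + seq_len(n_h[a])
      h_of[[a]] <- idx
      bonds <- rbind(bonds, data.frame(i = a, j = idx, order = 1L,
                                       aromatic = FALSE))
      next_idx <- next_idx + n_h[a]
    } else {
      h_of[[a]] <- integer(0)
    }
  }
  mol <- molecule(compound_id, elements, bonds)
  attr(mol, "chain_info") <- list(n_heavy = n_heavy, h_of = h_of)
  mol
}

# Place atom D bonded to C with bond length r, angle theta at C (B-C-D) and
# dihedral phi (A-B-C-D), all angles in radians.
.place_atom <- function(a, b, c_, r, theta, phi) {
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a;  ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  c_ + cbind(bc, m, n) %*% d2
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Deterministic hydrogen placement around heavy-chain coordinates.
.add_hydrogens <- function(heavy_xyz, chain_info, n_atoms) {
  coords <- matrix(NA_real_, n_atoms, 3L)
  n_heavy <- chain_info$n_heavy
  coords[seq_len(n_heavy), ] <- heavy_xyz
  alpha <- pi - .BOND_ANGLE * pi / 180   # cone half-angle off the -bond axis
  half <- (.BOND_ANGLE / 2) * pi / 180
  for (a in seq_len(n_heavy)) {
    hs <- chain_info$h_of[[a]]
    if (length(hs) == 0L) next
    pos <- heavy_xyz[a, ]
    nb <- c(if (a > 1L) a - 1L, if (a < n_heavy) a + 1L)
    dirs <- lapply(nb, function(x) {
      v <- heavy_xyz[x, ] - pos; v / sqrt(sum(v^2))
    })
    if (length(dirs) == 1L) {
      ax <- -dirs[[1L]]
      ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      p <- ref - sum(ref * ax) * ax; p <- p / sqrt(sum(p^2))
      q <- .cross3(ax, p)
      for (k in seq_along(hs)) {
        phi <- 2 * pi * (k - 1L) / 3
        d <- cos(alpha) * ax + sin(alpha) * (cos(phi) * p + sin(phi) * q)
        coords[hs[k], ] <- pos + .BOND_LENGTH_XH * d
      }
    } else {
      u <- -(dirs[[1L]] + dirs[[2L]])
      u <- u / sqrt(sum(u^2))
      v <- .cross3(dirs[[1L]], dirs[[2L]])
      v <- v / sqrt(sum(v^2))
      sgn <- c(1, -1)
      for (k in seq_along(hs)) {
        d <- cos(half) * u + sgn[k] * sin(half) * v
        coords[hs[k], ] <- pos + .BOND_LENGTH_XH * d
      }
    }
  }
  coords
}

# Heavy-chain coordinates for given dihedrals (degrees), NERF construction.
.chain_coords <- function(n_heavy, dihedrals) {
  xyz <- matrix(0, n_heavy, 3L)
  xyz[1L, ] <- c(0, 0, 0)
  if (n_heavy >= 2L) xyz[2L, ] <- c(.BOND_LENGTH_CC, 0, 0)
  theta <- .BOND_ANGLE * pi / 180
  if (n_heavy >= 3L) {
    xyz[3L, ] <- .place_atom(c(0, 1, 0), xyz[1L, ], xyz[2L, ],
                             .BOND_LENGTH_CC, theta, 0)
  }
  if (n_heavy >= 4L) {
    for (k in 4:n_heavy) {
      xyz[k, ] <- .place_atom(xyz[k - 3L, ], xyz[k - 2L, ], xyz[k - 1L, ],
                              .BOND_LENGTH_CC, theta,
                              dihedrals[k - 3L] * pi / 180)
    }
  }
  xyz
}

#' Toy nonbonded conformer energy (kcal/mol)
#'
#' Sum of 12-6 Lennard-Jones terms, eps_ij * ((rm_ij/r)^12 - 2 (rm_ij/r)^6),
#' over all atom pairs at least four bonds apart in the molecular graph,
#' with rm_ij the sum of the elements' van der Waals radii and eps_ij the
#' geometric mean of their well depths (see [element_constants]). The energy
#' is invariant under rigid motion; a pair at exactly rm_ij contributes
#' -eps_ij.
#'
#' @param mol a [molecule()].
#' @param coords atom_count x 3 coordinate matrix (A).
#' @return numeric scalar, kcal/mol.
#' @export
toy_energy <- function(mol, coords) {
  stopifnot(all(is.finite(coords)))
  gd <- graph_distances(length(mol$elements), mol$bonds)
  .toy_energy_pairs(.lj_pairs(mol, gd), as.matrix(coords))
}

# precomputed LJ pair table (indices >= 4 bonds apart, rm and eps per pair)
.lj_pairs <- function(mol, gd) {
  pp <- which(gd >= 4 & upper.tri(gd), arr.ind = TRUE)
  rad <- .element_lookup(mol$elements, "vdw_radius")
  eps <- .element_lookup(mol$elements, "lj_epsilon")
  list(i = pp[, 1L], j = pp[, 2L],
       rm = rad[pp[, 1L]] + rad[pp[, 2L]],
       eps = sqrt(eps[pp[, 1L]] * eps[pp[, 2L]]))
}

.toy_energy_pairs <- function(pairs, coords) {
  if (length(pairs$i) == 0L) return(0)
  r <- sqrt(rowSums((coords[pairs$i, , drop = FALSE] -
                       coords[pairs$j, , drop = FALSE])^2))
  x6 <- (pairs$rm / r)^6
  sum(pairs$eps * (x6 * x6 - 2 * x6))
}

#' Sample a conformer ensemble for a chain molecule
#'
#' Backbone dihedrals are drawn from `config$dihedral_states` plus Gaussian
#' noise; bond lengths are fixed at 1.54 A and bond angles at 109.47 deg;
#' hydrogens are placed deterministically from the backbone. Conformers with
#' any nonbonded atom pair (graph distance >= 2) closer than 0.9 A are
#' rejected and resampled (at most `100 * n_conformers` attempts overall).
#' Each conformer receives a [toy_energy()]; the ensemble's ground truth is
#' a copy of the lowest-energy conformer perturbed by Normal(0, 0.1 A)
#' noise, so ground truth and energetic minimum correlate without
#' coinciding.
#'
#' @param mol a molecule from [generate_chain_molecule()].
#' @param n_conformers number of conformers to sample.
#' @param config a [generator_config()] (its `seed` drives all sampling).
#' @return a [conformer_ensemble()] with energies and ground truth.
#' @export
sample_conformers <- function(mol, n_conformers, config) {
  chain <- attr(mol, "chain_info")
  if (is.null(chain)) {
    stop("sample_conformers requires a molecule from generate_chain_molecule")
  }
  stopifnot(n_conformers >= 1L)
  n_atoms <- length(mol$elements)
  n_dih <- max(0L, chain$n_heavy - 3L)
  gd <- graph_distances(n_atoms, mol$bonds)
  nonbonded <- which(gd >= 2 & upper.tri(gd), arr.ind = TRUE)
  lj <- .lj_pairs(mol, gd)
  with_seed(config$seed, {
    confs <- vector("list", n_conformers)
    attempts <- 0L
    made <- 0L
    while (made < n_conformers) {
      attempts <- attempts + 1L
      if (attempts > 100L * n_conformers) {
        stop("could not sample ", n_conformers, " clash-free conformers for ",
             mol$compound_id, "; try a smaller molecule")
      }
      dih <- if (n_dih > 0L) {
        states <- if (length(config$dihedral_states) == 1L) {
          rep(config$dihedral_states, n_dih)
        } else {
          sample(config$dihedral_states, n_dih, replace = TRUE)
        }
        states + stats::rnorm(n_dih, 0, config$dihedral_noise_sd)
      } else numeric(0)
      xyz <- .add_hydrogens(.chain_coords(chain$n_heavy, dih), chain, n_atoms)
      ok <- TRUE
      if (nrow(nonbonded) > 0L) {
        d2 <- rowSums((xyz[nonbonded[, 1L], , drop = FALSE] -
                         xyz[nonbonded[, 2L], , drop = FALSE])^2)
        ok <- all(d2 >= .CLASH_DIST^2)
      }
      if (!ok) next
      made <- made + 1L
      confs[[made]] <- conformer(mol$compound_id, made - 1L, xyz,
                                 energy = .toy_energy_pairs(lj, xyz))
    }
    energies <- vapply(confs, `[[`, numeric(1), "energy")
    best <- confs[[which.min(energies)]]$coords
    gt <- best + matrix(stats::rnorm(length(best), 0, .GT_PERTURB_SD),
                        nrow(best), 3L)
    conformer_ensemble(mol, confs, ground_truth = gt)
  })
}

#' Magnitude of a point-charge dipole
#'
#' |sum_j q_j r_j| in charge * A. Origin-independent only when the charges
#' sum to zero, which the synthetic property guarantees by mean-centering.
#'
#' @param coords n x 3 coordinates (A).
#' @param charges numeric charges, one per row.
#' @return numeric scalar.
#' @export
dipole_magnitude <- function(coords, charges) {
  stopifnot(nrow(coords) == length(charges))
  sqrt(sum(colSums(coords * charges)^2))
}

# Mean-centred per-element pseudo-charges (Pauling electronegativities).
pseudo_charges <- function(mol) {
  q <- .element_lookup(mol$elements, "pauling_en")
  q - mean(q)
}

# Compositional term: weighted atom-type counts.
graph_term <- function(mol) {
  sum(.element_lookup(mol$elements, "pauling_en") - 2)
}

#' Per-conformer values of the synthetic property (noise-free)
#'
#' The deterministic part of [synthetic_property()] evaluated on each
#' conformer separately: lambda * dipole_i + (1 - lambda) * g_graph (or
#' g_graph alone for composition-only mode). Feeds the
#' conformational-dependency statistic.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param spec a [property_spec()].
#' @return numeric vector, one value per conformer.
#' @export
per_conformer_property <- function(ensemble, spec) {
  g <- graph_term(ensemble$molecule)
  if (spec$mode == "composition_only") {
    return(rep(g, length(ensemble$conformers)))
  }
  q <- pseudo_charges(ensemble$molecule)
  dips <- vapply(ensemble$conformers,
                 function(cf) dipole_magnitude(cf$coords, q), numeric(1))
  spec$dependency_weight * dips + (1 - spec$dependency_weight) * g
}

#' Simulate a compound-level property value for an ensemble
#'
#' value = lambda * f_geo + (1 - lambda) * g_graph + Normal(0, noise_sd),
#' where f_geo is the pseudo-charge dipole magnitude evaluated on the
#' ground-truth conformer (`geometric_ground_truth`) or Boltzmann-averaged
#' over the ensemble at `spec$temperature` (`ensemble_boltzmann_average`),
#' and g_graph is a weighted atom-type count. Deterministic given `seed`.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param spec a [property_spec()].
#' @param seed integer seed for the noise draw.
#' @return a [property_record()].
#' @export
synthetic_property <- function(ensemble, spec, seed = 1L) {
  mol <- ensemble$molecule
  g <- graph_term(mol)
  val <- if (spec$mode == "composition_only") {
    g
  } else {
    q <- pseudo_charges(mol)
    f_geo <- if (spec$mode == "geometric_ground_truth") {
      if (is.null(ensemble$ground_truth)) {
        stop("mode 'geometric_ground_truth' needs an ensemble with ground truth")
      }
      dipole_magnitude(ensemble$ground_truth, q)
    } else {
      en <- conformer_energies(ensemble)
      if (any(is.na(en))) {
        stop("mode 'ensemble_boltzmann_average' needs conformer energies")
      }
      w <- boltzmann_weights(en, spec$temperature)
      dips <- vapply(ensemble$conformers,
                     function(cf) dipole_magnitude(cf$coords, q), numeric(1))
      sum(w$p * dips)
    }
    spec$dependency_weight * f_geo + (1 - spec$dependency_weight) * g
  }
  noise <- if (spec$noise_sd > 0) {
    with_seed(seed, stats::rnorm(1, 0, spec$noise_sd))
  } else 0
  property_record(mol$compound_id, val + noise,
                  property_name = spec$mode, units = "charge*A")
}

#' Generate a complete synthetic benchmark dataset
#'
#' Chains, conformer ensembles and property values for
#' `gen_config$n_compounds` compounds. The returned dataset carries a
#' `manifest` attribute (configs, seed, package version) sufficient for
#' exact regeneration.
#'
#' @param gen_config a [generator_config()].
#' @param prop_spec a [property_spec()].
#' @return a [conformer_dataset()] with a `manifest` attribute.
#' @export
generate_benchmark <- function(gen_config, prop_spec) {
  stopifnot(inherits(gen_config, "GeneratorConfig"),
            inherits(prop_spec, "PropertySpec"))
  seed <- gen_config$seed
  ensembles <- list()
  properties <- list()
  for (c_ in seq_len(gen_config$n_compounds)) {
    id <- sprintf("cmpd_%04d", c_)
    pick <- function(rng) {
      if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
    }
    sizes <- with_seed(derive_seed(seed, paste0("size_", id)), {
      c(pick(gen_config$heavy_atoms_range),
        pick(gen_config$conformers_per_compound_range))
    })
    mol <- generate_chain_molecule(sizes[1L], gen_config$element_alphabet,
                                   seed = derive_seed(seed, paste0("mol_", id)),
                                   compound_id = id)
    cfg_c <- gen_config
    cfg_c$seed <- derive_seed(seed, paste0("conf_", id))
    ens <- sample_conformers(mol, sizes[2L], cfg_c)
    ensembles[[id]] <- ens
    properties[[id]] <- synthetic_property(
      ens, prop_spec, seed = derive_seed(seed, paste0("prop_", id)))
  }
  ds <- conformer_dataset(ensembles, properties)
  attr(ds, "manifest") <- list(
    generator = unclass(gen_config),
    property = unclass(prop_spec),
    seed = seed,
    package = "confagg",
    version = as.character(utils::packageVersion("confagg")))
  ds
}
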