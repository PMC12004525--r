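# Per-conformer 3D descriptors (3D-MoRSE, pharmacophore triplets, MBTR) and
# conformation-independent 2D baselines (Morgan-style circular fingerprint,
# topological pharmacophore triplets).

#' 3D-MoRSE descriptor configuration
#'
#' The descriptor for scattering parameter s and weight scheme w is
#' sum over atom pairs i < j of w_i * w_j * sin(s * r_ij) / (s * r_ij).
#' The default grid of 32 integer s values (1/A) combined with five weight
#' schemes (unit, atomic mass, van der Waals volume, Sanderson
#' electronegativity, polarizability; each scaled relative to carbon) gives
#' the classic 160-component vector.
#'
#' @param s_values ordered numeric scattering parameters, 1/A.
#' @param weight_schemes subset of "unit", "mass", "vdw_volume",
#'   "sanderson_en", "polarizability".
#' @return object of class `MoRSEConfig`.
#' @export
morse_config <- function(s_values = 1:32,
                         weight_schemes = c("unit", "mass", "vdw_volume",
                                            "sanderson_en", "polarizability")) {
  weight_schemes <- match.arg(weight_schemes, several.ok = TRUE)
  stopifnot(length(s_values) >= 1L, all(s_values > 0))
  structure(list(s_values = s_values, weight_schemes = weight_schemes),
            class = "MoRSEConfig")
}

.morse_weights <- function(elements, scheme) {
  switch(scheme,
    unit = rep(1, length(elements)),
    mass = .element_lookup(elements, "mass") /
      element_constants["C", "mass"],
    vdw_volume = .element_lookup(elements, "vdw_volume") /
      element_constants["C", "vdw_volume"],
    sanderson_en = .element_lookup(elements, "sanderson_en") /
      element_constants["C", "sanderson_en"],
    polarizability = .element_lookup(elements, "polarizability") /
      element_constants["C", "polarizability"],
    stop("unknown weight scheme: ", scheme))
}

#' 3D-MoRSE descriptors of one conformer
#'
#' @param mol a [molecule()] supplying the element labels.
#' @param coords atom_count x 3 coordinate matrix (A).
#' @param config a [morse_config()].
#' @return named numeric vector of length
#'   `length(s_values) * length(weight_schemes)`, ordered weight-scheme
#'   major, s ascending. Invariant to rigid motion and atom order.
#' @export
morse <- function(mol, coords, config = morse_config()) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n == length(mol$elements))
  out <- numeric(0)
  if (n >= 2L) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    r <- sqrt(rowSums((coords[pairs[, 1L], , drop = FALSE] -
                         coords[pairs[, 2L], , drop = FALSE])^2))
    if (any(r == 0)) {
      stop("degenerate geometry: coincident atoms in ", mol$compound_id)
    }
  }
  for (scheme in config$weight_schemes) {
    w <- .morse_weights(mol$elements, scheme)
    for (s in config$s_values) {
      val <- if (n < 2L) 0 else {
        ww <- w[pairs[, 1L]] * w[pairs[, 2L]]
        sum(ww * sin(s * r) / (s * r))
      }
      out <- c(out, val)
    }
  }
  names(out) <- as.vector(outer(config$s_values, config$weight_schemes,
                                function(s, sch) paste0("morse_", sch, "_s", s)))
  out
}

#' Pharmacophore triplet configuration
#'
#' @param bin_width distance bin width, A (3D) or bonds (2D); distances are
#'   binned by floor(d / bin_width).
#' @param vertex_rule "ring56_centroids_plus_other_atoms" treats every 5- or
#'   6-membered ring as one centroid vertex;
#'   "aromatic56_centroids_plus_other_atoms" restricts that to aromatic
#'   rings.
#' @param max_binned_distance bins above this value are clamped to it.
#' @param include_hydrogens include hydrogen atoms as vertices (default no).
#' @return object of class `TripletConfig`.
#' @export
triplet_config <- function(bin_width = 1.0,
                           vertex_rule = c("ring56_centroids_plus_other_atoms",
                                           "aromatic56_centroids_plus_other_atoms"),
                           max_binned_distance = 999L,
                           include_hydrogens = FALSE) {
  vertex_rule <- match.arg(vertex_rule)
  stopifnot(bin_width > 0)
  structure(list(bin_width = bin_width, vertex_rule = vertex_rule,
                 max_binned_distance = as.integer(max_binned_distance),
                 include_hydrogens = include_hydrogens),
            class = "TripletConfig")
}

#' Pharmacophore vertices of a molecule
#'
#' Atoms belonging to any 5- or 6-membered ring are replaced by one centroid
#' vertex per such ring (label "R5"/"R6"); every other heavy atom (hydrogens
#' optionally included) is a vertex labelled with its element. In 3D mode
#' (coords given) each vertex carries a position, the centroid being the
#' geometric mean of its ring atoms; in 2D mode each vertex carries its atom
#' set as a topological anchor.
#'
#' @param mol a [molecule()] with `ring_info` populated.
#' @param coords optional atom_count x 3 matrix; supply for 3D vertices.
#' @param config a [triplet_config()].
#' @return list of vertices: `list(label, atoms, position)` (position `NULL`
#'   in 2D mode).
#' @export
pharmacophore_vertices <- function(mol, coords = NULL,
                                   config = triplet_config()) {
  rings56 <- Filter(function(r) length(r) %in% c(5L, 6L), mol$ring_info)
  if (config$vertex_rule == "aromatic56_centroids_plus_other_atoms" &&
      length(rings56) > 0L) {
    arom <- rep(FALSE, length(mol$elements))
    ar_bonds <- mol$bonds[mol$bonds$aromatic, , drop = FALSE]
    arom[c(ar_bonds$i, ar_bonds$j)] <- TRUE
    rings56 <- Filter(function(r) all(arom[r]), rings56)
  }
  ring_atoms <- unique(unlist(rings56))
  verts <- list()
  for (r in rings56) {
    verts[[length(verts) + 1L]] <- list(
      label = paste0("R", length(r)), atoms = r,
      position = if (is.null(coords)) NULL else colMeans(coords[r, , drop = FALSE]))
  }
  for (a in seq_along(mol$elements)) {
    if (a %in% ring_atoms) next
    if (mol$elements[a] == "H" && !config$include_hydrogens) next
    verts[[length(verts) + 1L]] <- list(
      label = mol$elements[a], atoms = a,
      position = if (is.null(coords)) NULL else coords[a, ])
  }
  verts
}

# Canonical key of one triplet: lexicographic minimum over the 6 vertex
# orderings of (label_a, label_b, label_c, d_ab, d_ac, d_bc).
.triplet_key <- function(labels, dists) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  d <- matrix(0L, 3L, 3L)
  d[1, 2] <- d[2, 1] <- dists[1L]   # d_12
  d[1, 3] <- d[3, 1] <- dists[2L]   # d_13
  d[2, 3] <- d[3, 2] <- dists[3L]   # d_23
  best <- NULL
  for (p in perms) {
    key <- sprintf("%s|%s|%s|%04d|%04d|%04d",
                   labels[p[1]], labels[p[2]], labels[p[3]],
                   d[p[1], p[2]], d[p[1], p[3]], d[p[2], p[3]])
    if (is.null(best) || key < best) best <- key
  }
  best
}

.triplet_counts <- function(labels, dist_matrix, config) {
  v <- length(labels)
  counts <- list()
  if (v >= 3L) {
    combos <- utils::combn(v, 3L)
    for (k in seq_len(ncol(combos))) {
      tri <- combos[, k]
      d <- c(dist_matrix[tri[1], tri[2]], dist_matrix[tri[1], tri[3]],
             dist_matrix[tri[2], tri[3]])
      bins <- pmin(as.integer(floor(d / config$bin_width)),
                   config$max_binned_distance)
      key <- .triplet_key(labels[tri], bins)
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  unlist(counts) %||% stats::setNames(integer(0), character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' 3D pharmacophore triplet fingerprint
#'
#' Counts every 3-subset of vertices keyed by its canonical
#' (labels, binned pairwise Euclidean distances) form; the key is minimized
#' over the six vertex orderings so equivalent triplets accumulate on one
#' key. Vertices closer than 1e-6 A are merged first. The total count always
#' equals C(V, 3).
#'
#' @param vertices output of [pharmacophore_vertices()] with positions.
#' @param config a [triplet_config()].
#' @return named integer count vector (sparse: only observed keys).
#' @export
triplet_fingerprint_3d <- function(vertices, config = triplet_config()) {
  if (length(vertices) == 0L) return(stats::setNames(integer(0), character(0)))
  pos <- do.call(rbind, lapply(vertices, `[[`, "position"))
  if (is.null(pos)) stop("vertices carry no positions; use 2D mode instead")
  labels <- vapply(vertices, `[[`, character(1), "label")
  # merge coincident vertices
  keep <- rep(TRUE, nrow(pos))
  if (nrow(pos) >= 2L) {
    for (i in seq_len(nrow(pos) - 1L)) {
      if (!keep[i]) next
      for (j in seq((i + 1L), nrow(pos))) {
        if (keep[j] && sum((pos[i, ] - pos[j, ])^2) < 1e-12) keep[j] <- FALSE
      }
    }
  }
  pos <- pos[keep, , drop = FALSE]
  labels <- labels[keep]
  dm <- as.matrix(stats::dist(pos))
  .triplet_counts(labels, dm, config)
}

#' 2D (topological) pharmacophore triplet fingerprint
#'
#' Same vertex rule and canonicalization as the 3D variant, but pairwise
#' distances are shortest-path bond counts; the distance of a ring-centroid
#' vertex is the minimum over its ring atoms.
#'
#' @param mol a connected [molecule()].
#' @param config a [triplet_config()].
#' @return named integer count vector.
#' @export
triplet_fingerprint_2d <- function(mol, config = triplet_config()) {
  gd <- graph_distances(length(mol$elements), mol$bonds)
  if (any(is.infinite(gd))) stop("disconnected molecular graph in ",
                                 mol$compound_id)
  verts <- pharmacophore_vertices(mol, coords = NULL, config = config)
  if (length(verts) < 3L) return(stats::setNames(integer(0), character(0)))
  v <- length(verts)
  dm <- matrix(0, v, v)
  for (i in seq_len(v - 1L)) {
    for (j in seq((i + 1L), v)) {
      dm[i, j] <- dm[j, i] <- min(gd[verts[[i]]$atoms, verts[[j]]$atoms])
    }
  }
  labels <- vapply(verts, `[[`, character(1), "label")
  .triplet_counts(labels, dm, config)
}

#' Many-body tensor representation configuration
#'
#' Per degree d in {1,2,3}, a Gaussian-broadened distribution of a geometry
#' function over all matching atom tuples is accumulated per element tuple
#' on a fixed grid: degree 1 counts atoms over atomic number, degree 2 uses
#' inverse pairwise distance over unordered element pairs, degree 3 the
#' cosine of the angle at the middle atom over (outer pair unordered,
#' middle) element triples. For n elements the tuple counts are n,
#' n(n+1)/2 and n^2(n+1)/2, so the vector length is their sum times
#' `grid_points` (540 for 4 elements, 950 for 5, with the default 10-point
#' grids).
#'
#' @param element_set ordered character vector of elements.
#' @param degrees subset of 1:3.
#' @param grid_points grid points per distribution (default 10).
#' @param d1_range,d2_range,d3_range grid bounds per degree; defaults:
#'   atomic number [0, max Z + 1], inverse distance [0, 1.1] 1/A,
#'   cosine [-1, 1].
#' @param sigma Gaussian broadening per degree; default one grid-cell width.
#' @return object of class `MBTRConfig`.
#' @export
mbtr_config <- function(element_set, degrees = 1:3, grid_points = 10L,
                        d1_range = NULL, d2_range = c(0, 1.1),
                        d3_range = c(-1, 1), sigma = NULL) {
  stopifnot(all(degrees %in% 1:3), grid_points >= 2L,
            length(element_set) >= 1L, !anyDuplicated(element_set))
  z <- .element_lookup(element_set, "z")
  if (is.null(d1_range)) d1_range <- c(0, max(z) + 1)
  ranges <- list(`1` = d1_range, `2` = d2_range, `3` = d3_range)
  if (is.null(sigma)) {
    sigma <- vapply(ranges, function(r) diff(r) / grid_points, numeric(1))
  } else {
    sigma <- rep_len(sigma, 3L)
    names(sigma) <- c("1", "2", "3")
  }
  structure(list(element_set = element_set, degrees = sort(degrees),
                 grid_points = as.integer(grid_points), ranges = ranges,
                 sigma = sigma),
            class = "MBTRConfig")
}

#' Length of the MBTR vector implied by a configuration
#' @param config an [mbtr_config()].
#' @return integer vector length.
#' @export
mbtr_length <- function(config) {
  n <- length(config$element_set)
  tuples <- c(`1` = n, `2` = n * (n + 1) / 2, `3` = n^2 * (n + 1) / 2)
  as.integer(sum(tuples[as.character(config$degrees)]) * config$grid_points)
}

# Gaussian-broadened accumulation of values onto a fixed grid.
.broaden <- function(values, grid, sigma) {
  out <- numeric(length(grid))
  for (v in values) out <- out + exp(-(grid - v)^2 / (2 * sigma^2))
  out
}

#' Many-body tensor representation of one conformer
#'
#' @param mol a [molecule()]; every element present must be in
#'   `config$element_set`.
#' @param coords atom_count x 3 coordinate matrix (A).
#' @param config an [mbtr_config()].
#' @return named numeric vector of length [mbtr_length()], blocks
#'   concatenated in canonical element-tuple order (element_set order;
#'   unordered pairs with first index <= second). Invariant to rigid motion
#'   and atom reordering.
#' @export
mbtr <- function(mol, coords, config) {
  stopifnot(inherits(config, "MBTRConfig"))
  coords <- as.matrix(coords)
  els <- mol$elements
  if (!all(els %in% config$element_set)) {
    stop("element(s) outside MBTR element_set: ",
         paste(setdiff(els, config$element_set), collapse = ", "))
  }
  es <- config$element_set
  n_el <- length(es)
  gp <- config$grid_points
  grids <- lapply(config$ranges, function(r) seq(r[1], r[2], length.out = gp))
  out <- numeric(0)
  nms <- character(0)
  n_atoms <- length(els)
  dm <- if (n_atoms >= 2L) as.matrix(stats::dist(coords)) else
    matrix(0, n_atoms, n_atoms)

  for (deg in config$degrees) {
    grid <- grids[[as.character(deg)]]
    sg <- config$sigma[[as.character(deg)]]
    if (deg == 1L) {
      z <- .element_lookup(es, "z")
      for (e in seq_len(n_el)) {
        cnt <- sum(els == es[e])
        block <- if (cnt == 0L) numeric(gp) else
          cnt * .broaden(z[e], grid, sg)
        out <- c(out, block)
        nms <- c(nms, paste0("mbtr1_", es[e], "_", seq_len(gp)))
      }
    } else if (deg == 2L) {
      for (e1 in seq_len(n_el)) for (e2 in e1:n_el) {
        ii <- which(els == es[e1]); jj <- which(els == es[e2])
        vals <- numeric(0)
        for (i in ii) for (j in jj) {
          if (e1 == e2 && j <= i) next
          vals <- c(vals, 1 / dm[i, j])
        }
        out <- c(out, .broaden(vals, grid, sg))
        nms <- c(nms, paste0("mbtr2_", es[e1], es[e2], "_", seq_len(gp)))
      }
    } else {
      # degree 3: middle element x unordered outer pair
      for (em in seq_len(n_el)) for (e1 in seq_len(n_el)) for (e2 in e1:n_el) {
        mm <- which(els == es[em])
        ii <- which(els == es[e1]); jj <- which(els == es[e2])
        vals <- numeric(0)
        for (m in mm) for (i in ii) {
          if (i == m) next
          for (j in jj) {
            if (j == m || j == i) next
            if (e1 == e2 && j < i) next
            v1 <- coords[i, ] - coords[m, ]
            v2 <- coords[j, ] - coords[m, ]
            vals <- c(vals, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
          }
        }
        out <- c(out, .broaden(vals, grid, sg))
        nms <- c(nms, paste0("mbtr3_", es[e1], es[em], es[e2], "_", seq_len(gp)))
      }
    }
  }
  stats::setNames(out, nms)
}

#' Morgan-style hashed circular fingerprint
#'
#' A native implementation of the circular-substructure fingerprint family:
#' iterative neighbourhood hashing of per-atom invariants (element, heavy
#' degree, attached hydrogens, charge, aromatic membership) for radii
#' 0..`radius` (diameter 4 at the default radius 2), folded modulo `n_bits`.
#' Purely topological, hence identical for all conformers of a molecule.
#'
#' @param mol a [molecule()].
#' @param radius neighbourhood radius (default 2).
#' @param n_bits folded length (default 2048).
#' @param counts if `TRUE` return substructure counts; otherwise 0/1 bits.
#' @return integer vector of length `n_bits`.
#' @export
circular_fingerprint <- function(mol, radius = 2L, n_bits = 2048L,
                                 counts = FALSE) {
  heavy <- which(mol$elements != "H")
  if (length(heavy) == 0L) return(integer(n_bits))
  n <- length(mol$elements)
  nbrs <- vector("list", n)
  bond_order <- vector("list", n)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    o <- if (mol$bonds$aromatic[b]) 15L else mol$bonds$order[b]
    nbrs[[i]] <- c(nbrs[[i]], j); bond_order[[i]] <- c(bond_order[[i]], o)
    nbrs[[j]] <- c(nbrs[[j]], i); bond_order[[j]] <- c(bond_order[[j]], o)
  }
  arom <- rep(FALSE, n)
  ar_bonds <- mol$bonds[mol$bonds$aromatic, , drop = FALSE]
  arom[c(ar_bonds$i, ar_bonds$j)] <- TRUE
  h_count <- vapply(seq_len(n), function(a) {
    sum(mol$elements[nbrs[[a]]] == "H")
  }, integer(1))
  hdeg <- vapply(seq_len(n), function(a) {
    sum(mol$elements[nbrs[[a]]] != "H")
  }, integer(1))
  inv <- string_hash(paste(mol$elements, hdeg, h_count, mol$charges,
                           as.integer(arom), sep = ":"))
  all_ids <- inv[heavy]
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      new_inv <- inv
      for (a in heavy) {
        hn <- nbrs[[a]][mol$elements[nbrs[[a]]] != "H"]
        ho <- bond_order[[a]][mol$elements[nbrs[[a]]] != "H"]
        env <- paste(ho, inv[hn], sep = "-")
        new_inv[a] <- string_hash(paste(r, inv[a],
                                        paste(sort(env), collapse = "|"),
                                        sep = "#"))
      }
      inv <- new_inv
      all_ids <- c(all_ids, inv[heavy])
    }
  }
  fp <- integer(n_bits)
  idx <- (all_ids %% n_bits) + 1L
  for (i in idx) fp[i] <- fp[i] + 1L
  if (counts) fp else as.integer(fp > 0L)
}

#' Descriptor specification
#'
#' Pairs a registered descriptor name with its configuration. Registered
#' names: "morse", "triplet3d", "triplet2d", "mbtr", "ecfp4".
#'
#' @param name descriptor name.
#' @param config the matching configuration object (defaults are used when
#'   `NULL`; "mbtr" requires an explicit [mbtr_config()]).
#' @param ... extra arguments stored on the spec (e.g. `n_bits`, `counts`
#'   for "ecfp4").
#' @return object of class `DescriptorSpec`.
#' @export
descriptor_spec <- function(name = c("morse", "triplet3d", "triplet2d",
                                     "mbtr", "ecfp4"),
                            config = NULL, ...) {
  name <- match.arg(name)
  if (is.null(config)) {
    config <- switch(name,
      morse = morse_config(),
      triplet3d = triplet_config(),
      triplet2d = triplet_config(),
      mbtr = stop("descriptor 'mbtr' requires an explicit mbtr_config()"),
      ecfp4 = NULL)
  }
  structure(list(name = name, config = config, extra = list(...)),
            class = "DescriptorSpec")
}

# TRUE when the descriptor depends only on the chemical graph.
is_2d_descriptor <- function(spec) spec$name %in% c("triplet2d", "ecfp4")

# Evaluate one descriptor on one geometry.
.descriptor_row <- function(spec, mol, coords) {
  switch(spec$name,
    morse = morse(mol, coords, spec$config),
    triplet3d = {
      v <- pharmacophore_vertices(mol, coords, spec$config)
      x <- triplet_fingerprint_3d(v, spec$config)
      if (length(x) == 0L) stats::setNames(numeric(0), character(0)) else x
    },
    triplet2d = triplet_fingerprint_2d(mol, spec$config),
    mbtr = mbtr(mol, coords, spec$config),
    ecfp4 = {
      fp <- circular_fingerprint(
        mol, radius = 2L,
        n_bits = spec$extra$n_bits %||% 2048L,
        counts = isTRUE(spec$extra$counts))
      stats::setNames(fp, paste0("bit", seq_along(fp)))
    },
    stop("unknown descriptor '", spec$name, "'"))
}

# rbind sparse named vectors over the union of their names, zero-filled.
# Dense descriptors (identical name vectors) keep their natural column
# order; sparse ones get the sorted key union.
.bind_sparse <- function(rows) {
  nm1 <- names(rows[[1L]])
  same <- all(vapply(rows, function(r) identical(names(r), nm1), logical(1)))
  vocab <- if (same) nm1 else sort(unique(unlist(lapply(rows, names))))
  if (is.null(vocab)) vocab <- character(0)
  m <- matrix(0, length(rows), length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) > 0L) m[i, names(r)] <- r
  }
  m
}

#' Compute a per-conformer descriptor matrix for an ensemble
#'
#' One row per conformer, in conformer order. Sparse (triplet) descriptors
#' are unioned over this ensemble's keys; dataset-level alignment is done
#' with [align_to_vocab()] so that model-fitting code can restrict the
#' vocabulary to training compounds.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param spec a [descriptor_spec()].
#' @return numeric matrix with attributes `compound_id` and
#'   `descriptor_name`; class `DescriptorMatrix`.
#' @export
featurize_ensemble <- function(ensemble, spec) {
  stopifnot(inherits(spec, "DescriptorSpec"))
  mol <- ensemble$molecule
  rows <- if (is_2d_descriptor(spec)) {
    one <- .descriptor_row(spec, mol, NULL)
    rep(list(one), length(ensemble$conformers))
  } else {
    lapply(ensemble$conformers, function(cf) {
      .descriptor_row(spec, mol, cf$coords)
    })
  }
  m <- .bind_sparse(rows)
  structure(m, compound_id = mol$compound_id, descriptor_name = spec$name,
            class = c("DescriptorMatrix", class(m)))
}

#' Descriptor of the ground-truth conformation
#'
#' @param ensemble a [conformer_ensemble()] with ground truth.
#' @param spec a [descriptor_spec()].
#' @return 1-row `DescriptorMatrix`.
#' @export
featurize_ground_truth <- function(ensemble, spec) {
  if (is.null(ensemble$ground_truth)) {
    stop("no ground-truth conformation for ", ensemble$molecule$compound_id)
  }
  m <- .bind_sparse(list(.descriptor_row(spec, ensemble$molecule,
                                         ensemble$ground_truth)))
  structure(m, compound_id = ensemble$molecule$compound_id,
            descriptor_name = spec$name,
            class = c("DescriptorMatrix", class(m)))
}

#' Featurize every ensemble of a dataset
#'
#' @param dataset a [conformer_dataset()].
#' @param spec a [descriptor_spec()].
#' @param ground_truth featurize the ground-truth conformation instead of
#'   the ensemble members.
#' @return named list of `DescriptorMatrix`, keyed by compound id.
#' @export
featurize_dataset <- function(dataset, spec, ground_truth = FALSE) {
  f <- if (ground_truth) featurize_ground_truth else featurize_ensemble
  lapply(dataset$ensembles, f, spec = spec)
}

#' Union vocabulary of sparse descriptor matrices
#' @param matrices list of `DescriptorMatrix`.
#' @return sorted character vector of column labels.
#' @export
triplet_vocabulary <- function(matrices) {
  sort(unique(unlist(lapply(matrices, colnames))))
}

#' Align a descriptor matrix to a fixed vocabulary
#'
#' Columns absent from the matrix are zero-filled; columns outside the
#' vocabulary are dropped (a test compound may show triplets never seen in
#' training).
#'
#' @param m a `DescriptorMatrix`.
#' @param vocab character vector of column labels.
#' @return numeric matrix with columns exactly `vocab`.
#' @export
align_to_vocab <- function(m, vocab) {
  out <- matrix(0, nrow(m), length(vocab), dimnames = list(NULL, vocab))
  shared <- intersect(colnames(m), vocab)
  out[, shared] <- m[, shared, drop = FALSE]
  out
}
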