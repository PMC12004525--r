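test_that("3D-MoRSE matches analytic values and has the classic length", {
  pair <- bare_chain(c("C", "C"), id = "pair")
  cfg1 <- morse_config(s_values = 1, weight_schemes = "unit")
  expect_equal(unname(morse(pair, rbind(c(0, 0, 0), c(1, 0, 0)), cfg1)),
               sin(1), tolerance = 1e-12)
  expect_equal(unname(morse(pair, rbind(c(0, 0, 0), c(pi, 0, 0)), cfg1)),
               0, tolerance = 1e-12)

  single <- molecule("atom", "C", data.frame(i = integer(), j = integer(),
                                             order = integer(),
                                             aromatic = logical()))
  v <- morse(single, cbind(0, 0, 0))
  expect_length(v, 160L)
  expect_true(all(v == 0))

  expect_error(morse(pair, rbind(c(0, 0, 0), c(0, 0, 0)), cfg1), "degenerate")
})

test_that("3D-MoRSE equals the naive double loop and is rigid-motion invariant", {
  set.seed(3)
  cfg <- morse_config(s_values = c(1, 2, 5, 17), weight_schemes =
                        c("unit", "mass", "sanderson_en"))
  for (case in 1:4) {
    n <- sample(2:8, 1)
    els <- sample(c("C", "N", "O", "H"), n, replace = TRUE)
    mol <- bare_chain(els, id = "rand")
    co <- matrix(rnorm(3 * n, sd = 2), n, 3)
    expect_equal(unname(morse(mol, co, cfg)),
                 naive_morse(els, co, c(1, 2, 5, 17),
                             c("unit", "mass", "sanderson_en")),
                 tolerance = 1e-10)
    expect_equal(morse(mol, rigid_motion(co, case), cfg), morse(mol, co, cfg),
                 tolerance = 1e-9)
    # atom-order invariance
    perm <- sample(n)
    mol_p <- bare_chain(els[perm], id = "perm")
    expect_equal(unname(morse(mol_p, co[perm, , drop = FALSE], cfg)),
                 unname(morse(mol, co, cfg)), tolerance = 1e-10)
  }
})

test_that("pharmacophore vertices replace 5/6-rings by centroids", {
  chain5 <- bare_chain(rep("C", 5))
  expect_length(pharmacophore_vertices(chain5), 5L)

  vb <- pharmacophore_vertices(make_benzene())
  expect_length(vb, 1L)
  expect_equal(vb[[1]]$label, "R6")

  vt <- pharmacophore_vertices(make_toluene())
  expect_length(vt, 2L)
  expect_setequal(vapply(vt, `[[`, character(1), "label"), c("R6", "C"))

  # 3D mode: centroid position is the ring-atom mean
  vb3 <- pharmacophore_vertices(make_benzene(), coords = benzene_coords())
  expect_equal(vb3[[1]]$position, colMeans(benzene_coords()[1:6, ]),
               tolerance = 1e-12)

  # aromatic rule drops the non-aromatic ring
  v_sat <- pharmacophore_vertices(
    make_cyclohexane(),
    config = triplet_config(vertex_rule = "aromatic56_centroids_plus_other_atoms"))
  expect_length(v_sat, 6L)   # ring kept as individual carbons
})

test_that("3D triplet fingerprints bin, canonicalize and conserve counts", {
  mk <- function(labels, pos) {
    lapply(seq_along(labels), function(i) {
      list(label = labels[i], atoms = i, position = pos[i, ])
    })
  }
  # distances 1.2 / 2.3 / 3.4 -> bins (1, 2, 3)
  p <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(-1.95, 1.21, 0))
  d12 <- sqrt(sum((p[1, ] - p[2, ])^2))
  d13 <- sqrt(sum((p[1, ] - p[3, ])^2))
  d23 <- sqrt(sum((p[2, ] - p[3, ])^2))
  expect_equal(round(c(d12, d13, d23), 1), c(1.2, 2.3, 3.4))
  fp <- triplet_fingerprint_3d(mk(c("C", "C", "C"), p))
  expect_length(fp, 1L)
  expect_equal(unname(fp), 1L)
  expect_match(names(fp), "C\\|C\\|C\\|0001\\|0002\\|0003")

  expect_length(triplet_fingerprint_3d(mk(c("C", "N"), p[1:2, ])), 0L)

  set.seed(9)
  for (v in 3:5) {
    pos <- matrix(rnorm(3 * v, sd = 3), v, 3)
    labels <- sample(c("C", "N", "O", "R6"), v, replace = TRUE)
    fp <- triplet_fingerprint_3d(mk(labels, pos))
    expect_equal(sum(fp), choose(v, 3))
    # canonical keys are invariant to vertex input order
    perm <- sample(v)
    fp_p <- triplet_fingerprint_3d(mk(labels[perm], pos[perm, , drop = FALSE]))
    expect_identical(fp[order(names(fp))], fp_p[order(names(fp_p))])
  }
})

test_that("2D triplets use shortest-path distances and ignore conformation", {
  chain3 <- bare_chain(c("C", "C", "C"))
  fp <- triplet_fingerprint_2d(chain3)
  expect_length(fp, 1L)
  expect_match(names(fp), "C\\|C\\|C\\|0001\\|0001\\|0002")

  two <- bare_chain(c("C", "N"))
  expect_length(triplet_fingerprint_2d(two), 0L)

  disco <- molecule("disco", c("C", "C", "C", "C"),
                    data.frame(i = 1, j = 2, order = 1L, aromatic = FALSE))
  expect_error(triplet_fingerprint_2d(disco), "disconnected")

  ds <- tiny_dataset(n = 1L, seed = 131L, conf_range = c(3L, 3L))
  m <- featurize_ensemble(ds$ensembles[[1]], descriptor_spec("triplet2d"))
  expect_equal(nrow(m), 3L)
  expect_true(all(m[1, ] == m[2, ]) && all(m[2, ] == m[3, ]))
})

test_that("MBTR length follows the tuple-count formula", {
  sets <- list(c("H", "C"), c("H", "C", "N"), c("H", "C", "N", "O"),
               c("H", "C", "N", "O", "S"))
  for (es in sets) {
    n <- length(es)
    expected <- (n + n * (n + 1) / 2 + n^2 * (n + 1) / 2) * 10
    cfg <- mbtr_config(es)
    expect_equal(mbtr_length(cfg), expected)
    mol <- bare_chain(es, id = "probe")
    co <- cbind(seq_len(n) * 1.54, 0, 0)
    expect_length(mbtr(mol, co, cfg), expected)
  }
  expect_equal(mbtr_length(mbtr_config(c("H", "C", "N", "O"))), 540L)
  expect_equal(mbtr_length(mbtr_config(c("H", "C", "N", "O", "S"))), 950L)
})

test_that("MBTR degenerates and invariances behave", {
  cfg <- mbtr_config(c("H", "C"))
  single <- molecule("atom", "C", data.frame(i = integer(), j = integer(),
                                             order = integer(),
                                             aromatic = logical()))
  v <- mbtr(single, cbind(0, 0, 0), cfg)
  d2_block <- v[grepl("^mbtr2", names(v))]
  d3_block <- v[grepl("^mbtr3", names(v))]
  expect_true(all(d2_block == 0) && all(d3_block == 0))
  expect_gt(sum(v[grepl("^mbtr1_C", names(v))]), 0)

  els <- c("C", "C", "H", "H", "O")
  mol <- bare_chain(els, id = "inv")
  set.seed(17)
  co <- matrix(rnorm(15, sd = 2), 5, 3)
  cfg5 <- mbtr_config(c("H", "C", "O"))
  ref <- mbtr(mol, co, cfg5)
  expect_equal(mbtr(mol, rigid_motion(co, 21), cfg5), ref, tolerance = 1e-9)
  perm <- sample(5)
  mol_p <- bare_chain(els[perm], id = "invp")
  expect_equal(mbtr(mol_p, co[perm, , drop = FALSE], cfg5), ref,
               tolerance = 1e-10)

  expect_error(mbtr(bare_chain(c("C", "S")), cbind(c(0, 1.8), 0, 0), cfg),
               "element")
})

test_that("circular fingerprints are topological, consistent bit/count vectors", {
  tol <- make_toluene()
  a <- circular_fingerprint(tol)
  b <- circular_fingerprint(make_toluene())
  expect_identical(a, b)
  expect_true(all(a %in% c(0L, 1L)))
  cnt <- circular_fingerprint(tol, counts = TRUE)
  expect_gte(sum(cnt), sum(a))
  expect_false(identical(circular_fingerprint(make_benzene()), a))
  # folded length honoured
  expect_length(circular_fingerprint(tol, n_bits = 512L), 512L)
})

test_that("ensemble featurization keeps conformer order and aligns vocabularies", {
  ds <- tiny_dataset(n = 3L, seed = 141L, conf_range = c(3L, 3L))
  ens <- ds$ensembles[[1]]
  spec <- descriptor_spec("morse")
  m <- featurize_ensemble(ens, spec)
  expect_equal(nrow(m), 3L)
  expect_equal(unname(m[2, ]),
               unname(morse(ens$molecule, ens$conformers[[2]]$coords)))
  expect_equal(attr(m, "compound_id"), ens$molecule$compound_id)

  gt <- featurize_ground_truth(ens, spec)
  expect_equal(unname(gt[1, ]), unname(morse(ens$molecule, ens$ground_truth)))

  mats <- featurize_dataset(ds, descriptor_spec("triplet3d"))
  vocab <- triplet_vocabulary(mats[1:2])
  aligned <- align_to_vocab(mats[[3]], vocab)
  expect_identical(colnames(aligned), vocab)
  shared <- intersect(colnames(mats[[3]]), vocab)
  expect_equal(aligned[, shared], mats[[3]][, shared])
})
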