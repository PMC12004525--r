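test_that("Kabsch superposition handles identity, translation and the 2-point case", {
  a <- matrix(rnorm(15), 5, 3)
  fit <- superpose(a, a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)

  fit_t <- superpose(a, sweep(a, 2, c(5, 5, 5), `+`))
  expect_equal(fit_t$rmsd, 0, tolerance = 1e-10)

  a2 <- rbind(c(0, 0, 0), c(1, 0, 0))
  b2 <- rbind(c(0, 0, 0), c(0, 2, 0))
  expect_equal(superpose(a2, b2)$rmsd, 0.5, tolerance = 1e-10)

  # degenerate: one set fully coincident
  z <- matrix(0, 3, 3)
  fitz <- superpose(z, matrix(rnorm(9), 3, 3))
  expect_equal(fitz$rotation, diag(3))
  expect_true(is.finite(fitz$rmsd))

  expect_equal(superpose(matrix(c(1, 2, 3), 1, 3),
                         matrix(c(9, 9, 9), 1, 3))$rmsd, 0)
})

test_that("Kabsch RMSD equals the rotation-grid brute-force minimum", {
  set.seed(42)
  for (case in 1:5) {
    n <- sample(3:5, 1)
    a <- matrix(rnorm(3 * n, sd = 2), n, 3)
    b <- matrix(rnorm(3 * n, sd = 2), n, 3)
    expect_equal(superpose(a, b)$rmsd, brute_force_rmsd(a, b),
                 tolerance = 1e-3)
  }
})

test_that("Kabsch agrees with an independent library implementation", {
  set.seed(7)
  for (case in 1:5) {
    a <- matrix(rnorm(18, sd = 2), 6, 3)
    b <- matrix(rnorm(18, sd = 2), 6, 3)
    ours <- superpose(a, b)$rmsd
    ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
    expect_lt(abs(ours - ref), 6e-4)   # bio3d rounds to 3 decimals
  }
})

test_that("RMSD is symmetric and rigid-motion invariant", {
  set.seed(13)
  a <- matrix(rnorm(24), 8, 3)
  b <- matrix(rnorm(24), 8, 3)
  expect_equal(superpose(a, b)$rmsd, superpose(b, a)$rmsd, tolerance = 1e-10)
  expect_equal(superpose(rigid_motion(a, 3), b)$rmsd, superpose(a, b)$rmsd,
               tolerance = 1e-9)
  expect_equal(superpose(a, rigid_motion(b, 4))$rmsd, superpose(a, b)$rmsd,
               tolerance = 1e-9)
})

test_that("ground-truth RMSD honours the heavy-atom switch and invariances", {
  ds <- tiny_dataset(n = 1L, seed = 101L, conf_range = c(3L, 3L))
  ens <- ds$ensembles[[1]]
  rep_all <- rmsd_to_ground_truth(ens, heavy_only = FALSE)
  rep_heavy <- rmsd_to_ground_truth(ens, heavy_only = TRUE)
  expect_length(rep_all$per_conformer_rmsd, 3L)
  expect_equal(rep_all$atom_count_used, length(ens$molecule$elements))
  expect_equal(rep_heavy$atom_count_used, sum(ens$molecule$elements != "H"))
  expect_true(all(rep_all$per_conformer_rmsd >= 0))

  # conformer identical to the ground truth scores zero
  same <- ens
  same$ground_truth <- ens$conformers[[2]]$coords
  expect_equal(rmsd_to_ground_truth(same,
                                    heavy_only = FALSE)$per_conformer_rmsd[2],
               0, tolerance = 1e-10)

  # rotating the ground truth changes nothing
  rot <- ens
  rot$ground_truth <- rigid_motion(ens$ground_truth, 5)
  expect_equal(rmsd_to_ground_truth(rot, heavy_only = FALSE)$per_conformer_rmsd,
               rep_all$per_conformer_rmsd, tolerance = 1e-9)

  no_gt <- ens; no_gt$ground_truth <- NULL
  expect_error(rmsd_to_ground_truth(no_gt), "ground-truth")

  # single-heavy-atom molecule: superposition collapses to zero
  single <- molecule("pt", "C",
                     data.frame(i = integer(), j = integer(),
                                order = integer(), aromatic = logical()))
  e1 <- conformer_ensemble(single, list(conformer("pt", 0, cbind(4, 5, 6))),
                           ground_truth = cbind(0, 0, 0))
  expect_equal(rmsd_to_ground_truth(e1)$per_conformer_rmsd, 0)
})

test_that("pairwise diversity reports max >= mean and degenerates gracefully", {
  ds <- tiny_dataset(n = 5L, seed = 111L, conf_range = c(2L, 6L))
  for (ens in ds$ensembles) {
    d <- pairwise_diversity(ens)
    expect_gte(d$max_pairwise_rmsd, d$mean_pairwise_rmsd)
    expect_gte(d$mean_pairwise_rmsd, 0)
  }
  two <- ds$ensembles[[1]]
  two$conformers <- two$conformers[1:2]
  d2 <- pairwise_diversity(two)
  expect_equal(d2$max_pairwise_rmsd, d2$mean_pairwise_rmsd)

  one <- ds$ensembles[[1]]
  one$conformers <- one$conformers[1]
  d1 <- pairwise_diversity(one)
  expect_null(d1$max_pairwise_rmsd)
  expect_null(d1$mean_pairwise_rmsd)
})

test_that("rotatable-bond counting excludes terminal, ring and H bonds", {
  expect_equal(count_rotatable_bonds(make_ethane()), 0L)
  hexane <- generate_chain_molecule(6, "C", seed = 1)
  expect_equal(count_rotatable_bonds(hexane), 3L)
  expect_equal(count_rotatable_bonds(make_cyclohexane()), 0L)
})

test_that("curation applies rules in order with strict MW and lexicographic ties", {
  # chains of different length: rotatable count = n_heavy - 3
  sizes <- c(a = 10L, b = 8L, c = 8L, d = 6L, e = 4L)
  ens <- list(); props <- list()
  for (id in names(sizes)) {
    mol <- generate_chain_molecule(sizes[[id]], "C", seed = match(id, names(sizes)),
                                   compound_id = id)
    ens[[id]] <- sample_conformers(mol, 2, generator_config(seed = 3))
    props[[id]] <- property_record(id, 1.0, "toy")
  }
  ds <- conformer_dataset(ens, props)

  cur <- curate(ds, curation_rules(top_k_by_rotatable_bonds = 2L))
  expect_setequal(names(cur$dataset$ensembles), c("a", "b"))  # b beats c on id
  expect_equal(cur$log$removed_count[cur$log$rule == "top_k_by_rotatable_bonds"],
               3L)

  # strict "less than" on molecular weight
  mw_a <- molecular_weight(ens$a$molecule)
  cur_mw <- curate(ds, curation_rules(max_molecular_weight = mw_a))
  expect_false("a" %in% names(cur_mw$dataset$ensembles))

  # element filter
  s_mol <- bare_chain(c("C", "S", "C"), id = "sulfur")
  ds2 <- conformer_dataset(
    c(ens["a"], list(sulfur = conformer_ensemble(
      s_mol, list(conformer("sulfur", 0, cbind(0:2 * 1.54, 0, 0)))))),
    c(props["a"], list(sulfur = property_record("sulfur", 2, "toy"))))
  cur_el <- curate(ds2, curation_rules(allowed_elements = c("C", "H", "N", "O")))
  expect_setequal(names(cur_el$dataset$ensembles), "a")

  # min rotatable bonds (the >= 6 rule keeps only chains of 9+ heavy atoms)
  cur_rot <- curate(ds, curation_rules(min_rotatable_bonds = 6L))
  expect_setequal(names(cur_rot$dataset$ensembles), "a")

  # idempotence
  rules <- curation_rules(max_molecular_weight = 200,
                          top_k_by_rotatable_bonds = 3L)
  once <- curate(ds, rules)
  twice <- curate(once$dataset, rules)
  expect_identical(names(once$dataset$ensembles),
                   names(twice$dataset$ensembles))
  expect_true(all(twice$log$removed_count == 0L))
})

test_that("conformational dependency scales per-compound SD by the dataset IQR", {
  ds <- tiny_dataset(n = 4L, seed = 121L)
  ids <- names(ds$ensembles)
  vals <- list(c(0, 2), c(1, 1, 1), c(5, 5), c(10))
  names(vals) <- ids
  out <- conformational_dependency(ds, vals)
  means <- vapply(vals, mean, numeric(1))
  iqr <- unname(diff(quantile(means, c(0.25, 0.75))))
  expect_equal(unname(out[ids[1]]), sqrt(2) / iqr)
  expect_equal(unname(out[ids[2]]), 0)   # constant values
  expect_equal(unname(out[ids[4]]), 0)   # singleton SD is 0

  # degenerate: identical compounds -> zero IQR
  same <- list(c(1, 2), c(1, 2), c(1, 2), c(1, 2))
  names(same) <- ids
  expect_warning(res <- conformational_dependency(ds, same), "IQR")
  expect_true(all(is.na(res)))

  # alternative population flag
  out2 <- conformational_dependency(ds, vals, iqr_population = "all_values")
  pooled_iqr <- unname(diff(quantile(unlist(vals), c(0.25, 0.75))))
  expect_equal(unname(out2[ids[1]]), sqrt(2) / pooled_iqr)
})
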