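# Shared fixtures: hand-built molecules and geometry helpers.

# simple unbranched chain with explicit elements and no hydrogens
bare_chain <- function(elements, id = "chain") {
  n <- length(elements)
  bonds <- if (n >= 2L) {
    data.frame(i = seq_len(n - 1L), j = seq(2L, n), order = 1L,
               aromatic = FALSE)
  } else {
    data.frame(i = integer(), j = integer(), order = integer(),
               aromatic = logical())
  }
  molecule(id, elements, bonds)
}

make_ethane <- function() {
  bonds <- data.frame(i = c(1, 1, 1, 1, 2, 2, 2),
                      j = c(2, 3, 4, 5, 6, 7, 8),
                      order = 1L, aromatic = FALSE)
  molecule("ethane", c("C", "C", rep("H", 6)), bonds)
}

make_benzene <- function(aromatic = TRUE) {
  ring <- data.frame(i = 1:6, j = c(2:6, 1), order = 1L, aromatic = aromatic)
  hs <- data.frame(i = 1:6, j = 7:12, order = 1L, aromatic = FALSE)
  molecule("benzene", c(rep("C", 6), rep("H", 6)), rbind(ring, hs))
}

make_toluene <- function() {
  ring <- data.frame(i = 1:6, j = c(2:6, 1), order = 1L, aromatic = TRUE)
  me <- data.frame(i = 1, j = 7, order = 1L, aromatic = FALSE)
  hs <- data.frame(i = c(2:6, 7, 7, 7), j = 8:15, order = 1L, aromatic = FALSE)
  molecule("toluene", c(rep("C", 7), rep("H", 8)), rbind(ring, me, hs))
}

make_cyclohexane <- function() {
  ring <- data.frame(i = 1:6, j = c(2:6, 1), order = 1L, aromatic = FALSE)
  hs <- data.frame(i = rep(1:6, each = 2), j = 7:18, order = 1L,
                   aromatic = FALSE)
  molecule("cyclohexane", c(rep("C", 6), rep("H", 12)), rbind(ring, hs))
}

# hexagonal planar coordinates for the benzene ring (+ radial hydrogens)
benzene_coords <- function() {
  ang <- (0:5) * pi / 3
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  hs <- cbind(2.48 * cos(ang), 2.48 * sin(ang), 0)
  rbind(ring, hs)
}

# a uniformly random proper rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

rigid_motion <- function(coords, seed) {
  r <- random_rotation(seed)
  set.seed(seed + 1)
  t <- rnorm(3, 0, 5)
  sweep(coords %*% t(r), 2, t, `+`)
}

# small synthetic dataset shared by several tests
tiny_dataset <- function(n = 6L, seed = 11L, mode = "geometric_ground_truth",
                         lambda = 1, noise_sd = 0, conf_range = c(2L, 6L)) {
  generate_benchmark(
    generator_config(n_compounds = n, heavy_atoms_range = c(4L, 6L),
                     conformers_per_compound_range = conf_range, seed = seed),
    property_spec(mode = mode, dependency_weight = lambda,
                  noise_sd = noise_sd))
}
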