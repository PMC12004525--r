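# Independent oracles used by both the module tests and the acceptance
# suite. Each reimplements the checked quantity by a route the package does
# not use: explicit rotation search, naive double loops, full enumeration.

euler_rot <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# minimum RMSD over a dense Euler-angle grid, polished by local search
brute_force_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  obj <- function(p) {
    sqrt(mean(rowSums((ac %*% t(euler_rot(p[1], p[2], p[3])) - bc)^2)))
  }
  best <- Inf; best_p <- c(0, 0, 0)
  for (a1 in seq(0, 2 * pi, length.out = 13)) {
    for (b1 in seq(0, pi, length.out = 7)) {
      for (c1 in seq(0, 2 * pi, length.out = 13)) {
        v <- obj(c(a1, b1, c1))
        if (v < best) { best <- v; best_p <- c(a1, b1, c1) }
      }
    }
  }
  optim(best_p, obj, method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-12))$value
}

# naive double-loop reference for the 3D-MoRSE sum
naive_morse <- function(elements, coords, s_values, schemes) {
  w_of <- function(scheme) {
    tab <- element_constants
    switch(scheme,
           unit = rep(1, length(elements)),
           mass = tab[elements, "mass"] / tab["C", "mass"],
           vdw_volume = tab[elements, "vdw_volume"] / tab["C", "vdw_volume"],
           sanderson_en = tab[elements, "sanderson_en"] /
             tab["C", "sanderson_en"],
           polarizability = tab[elements, "polarizability"] /
             tab["C", "polarizability"])
  }
  out <- numeric(0)
  for (scheme in schemes) {
    w <- w_of(scheme)
    for (s in s_values) {
      acc <- 0
      n <- length(elements)
      if (n >= 2) {
        for (i in 1:(n - 1)) {
          for (j in (i + 1):n) {
            r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
            acc <- acc + w[i] * w[j] * sin(s * r) / (s * r)
          }
        }
      }
      out <- c(out, acc)
    }
  }
  out
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
enumerate_signed_rank_p <- function(d) {
  nz <- d[d != 0]
  n <- length(nz)
  r <- rank(abs(nz))
  w_obs <- sum(r[nz > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  lower <- mean(ws <= w_obs + 1e-9)
  upper <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}
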