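# Internal helpers: seeded RNG scoping, seed derivation, graph utilities.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a global seed and a string tag
#'
#' A single user-facing seed fans out to per-stage / per-compound seeds via a
#' small deterministic polynomial hash, so independent stages draw from
#' unrelated streams while the whole run stays reproducible from one integer.
#'
#' @param seed integer global seed.
#' @param tag character scalar naming the stage/unit (e.g. "compound_12").
#' @return an integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647
  h <- seed %% m
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# All-pairs topological (bond-count) distances by repeated BFS.
# bonds: data.frame with integer columns i, j. Returns n x n matrix, Inf when
# disconnected.
graph_distances <- function(n_atoms, bonds) {
  adj <- vector("list", n_atoms)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(Inf, n_atoms, n_atoms)
  for (s in seq_len(n_atoms)) {
    dist <- rep(Inf, n_atoms)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (dist[w] > dist[v] + 1) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    d[s, ] <- dist
  }
  d
}

# Smallest rings through each bond (union over bonds of the shortest cycle
# containing that bond), capped at max_size. Returns a list of integer
# vectors (sorted atom indices), deduplicated.
find_rings <- function(n_atoms, bonds, max_size = 8L) {
  if (nrow(bonds) == 0L) return(list())
  rings <- list()
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    # shortest path i -> j avoiding the direct edge
    other <- bonds[-b, , drop = FALSE]
    path <- bfs_path(n_atoms, other, i, j)
    if (!is.null(path) && length(path) <= max_size) {
      ring <- sort(unique(path))
      key <- paste(ring, collapse = ",")
      if (is.null(rings[[key]])) rings[[key]] <- ring
    }
  }
  unname(rings)
}

# Shortest path between from and to by BFS; NULL if unreachable.
bfs_path <- function(n_atoms, bonds, from, to) {
  adj <- vector("list", n_atoms)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  prev <- rep(NA_integer_, n_atoms)
  seen <- rep(FALSE, n_atoms)
  seen[from] <- TRUE
  queue <- from
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v == to) {
      path <- v
      while (!is.na(prev[v])) {
        v <- prev[v]
        path <- c(v, path)
      }
      return(path)
    }
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

# Deterministic non-cryptographic string -> integer hash (for fingerprint
# folding and config digests).
string_hash <- function(x) {
  m <- 2147483647
  vapply(x, function(s) {
    h <- 7
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}
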