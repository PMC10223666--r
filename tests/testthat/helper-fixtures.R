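# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; no stored data.

small_vesicle <- function(seed = 1, tail_state = "gel") {
  make_vesicle(vesicle_spec(2.0, 3.5, 60, 190, tail_state = tail_state,
    seed = seed))
}

dense_vesicle <- function(seed = 1, tail_state = "gel") {
  make_vesicle(vesicle_spec(1.2, 2.7, 70, 390, tail_state = tail_state,
    seed = seed))
}

# a hand-built map for n free molecules with `apm` atoms each
toy_map <- function(n, apm = 2) {
  atoms <- tibble::tibble(
    atom = seq_len(n * apm),
    molecule_id = rep(seq_len(n), each = apm),
    species = "amphiphile",
    role = "other",
    role_index = NA_integer_,
    element = "C"
  )
  new_molecule_map(atoms)
}

# O(N^2) brute-force MSD over all (origin, lag) pairs; pos is F x n x 3 (A)
msd_oracle <- function(pos) {
  F <- dim(pos)[1]
  np <- dim(pos)[2]
  out <- numeric(F)
  for (lag in 0:(F - 1)) {
    tot <- 0
    cnt <- 0
    for (t0 in 1:(F - lag)) {
      d <- pos[t0 + lag, , , drop = FALSE] - pos[t0, , , drop = FALSE]
      tot <- tot + sum(d^2)
      cnt <- cnt + np
    }
    out[lag + 1] <- tot / cnt
  }
  out / 100  # A^2 -> nm^2
}

# brute-force transitive closure of the monomer contact graph
cluster_oracle <- function(coords, map, cutoff) {
  at <- map$atoms[map$atoms$species == "amphiphile", ]
  ids <- sort(unique(at$molecule_id))
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      a <- coords[at$atom[at$molecule_id == ids[i]], , drop = FALSE]
      b <- coords[at$atom[at$molecule_id == ids[j]], , drop = FALSE]
      dmin <- sqrt(min(outer(rowSums(a^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)))
      adj[i, j] <- adj[j, i] <- dmin <= cutoff
    }
  }
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% reach > 0)
  }
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cid <- cid + 1
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# independent state-machine oracle for flip-flop counting on one label vector
flip_oracle <- function(lab, min_dwell) {
  events <- list()
  confirmed <- NA_character_
  i <- 1
  n <- length(lab)
  while (i <= n && lab[i] == "unassigned") i <- i + 1
  if (i <= n) confirmed <- lab[i]
  while (i <= n) {
    L <- lab[i]
    if (!is.na(confirmed) && L != "unassigned" && L != confirmed) {
      j <- i
      while (j <= n && lab[j] == L) j <- j + 1
      if (j - i >= min_dwell) {
        events[[length(events) + 1]] <- list(start = i, dir = paste0(confirmed, "_to_", L))
        confirmed <- L
      }
      i <- j
    } else {
      i <- i + 1
    }
  }
  events
}

# Monte-Carlo SASA oracle: uniform random directions on each expanded sphere
sasa_mc_oracle <- function(coords, r_exp, n_samples = 200000, seed = 99) {
  set.seed(seed)
  n <- nrow(coords)
  total <- 0
  for (i in seq_len(n)) {
    z <- stats::runif(n_samples, -1, 1)
    phi <- stats::runif(n_samples, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    P <- cbind(s * cos(phi), s * sin(phi), z) * r_exp[i]
    P <- sweep(P, 2, coords[i, ], "+")
    buried <- rep(FALSE, n_samples)
    for (j in seq_len(n)) {
      if (j == i) next
      buried <- buried | (rowSums(sweep(P, 2, coords[j, ])^2) < r_exp[j]^2)
    }
    total <- total + mean(!buried) * 4 * pi * r_exp[i]^2
  }
  unname(total)
}

random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3)
  qr.Q(qr(m)) * sign(det(qr.Q(qr(m))))
}
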