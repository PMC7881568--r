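# Shared fixtures and independent oracles used across the test files.

ns <- asNamespace("easregio")

# tautomer wrapper around a parsed molecule (no energies)
tautomer_of <- function(smiles) {
  structure(list(graph = ns$mg_from_smiles(smiles),
                 smiles = smiles, rel_energy = 0),
            class = "tautomer")
}

# --- brute-force graph-automorphism orbit oracle ----------------------------
# Enumerates all colour-preserving adjacency-preserving permutations of the
# heavy atoms by backtracking and returns the orbit id of each heavy atom.
# Independent of the igraph/BLISS route used by the implementation.
brute_force_orbits <- function(mg) {
  heavy <- ns$mg_heavy(mg)
  n <- length(heavy)
  nh <- ns$mg_nH(mg)
  arom <- ns$mg_aromatic_atoms(mg)
  col <- paste(mg$elements[heavy], mg$charges[heavy], nh[heavy], arom[heavy])
  ab <- ns$mg_aromatic_bonds(mg, arom)
  # heavy-heavy adjacency with bond colour
  bond_col <- matrix("", n, n)
  b <- mg$bonds
  for (k in seq_len(nrow(b))) {
    i <- match(b$i[k], heavy); j <- match(b$j[k], heavy)
    if (is.na(i) || is.na(j)) next
    cc <- if (ab[k]) "ar" else as.character(b$order[k])
    bond_col[i, j] <- bond_col[j, i] <- cc
  }
  same <- matrix(FALSE, n, n)   # i can map to j?
  for (i in seq_len(n)) for (j in seq_len(n)) same[i, j] <- col[i] == col[j]
  perms <- list()
  extend <- function(map) {
    v <- length(map) + 1L
    if (v > n) { perms[[length(perms) + 1L]] <<- map; return(invisible()) }
    for (w in seq_len(n)) {
      if (w %in% map || !same[v, w]) next
      ok <- TRUE
      for (u in seq_len(v - 1L)) {
        if (bond_col[v, u] != bond_col[w, map[u]]) { ok <- FALSE; break }
      }
      if (ok) extend(c(map, w))
    }
  }
  extend(integer(0))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in perms) {
    for (v in seq_len(n)) {
      a <- find(v); bb <- find(p[v])
      if (a != bb) parent[bb] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  stats::setNames(as.integer(factor(roots)), heavy)
}

same_partition <- function(a, b) {
  # two integer labelings induce the same set partition?
  identical(as.integer(factor(a)), as.integer(factor(b))) ||
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# --- brute-force Butina oracle ----------------------------------------------
# Re-derives the leader clustering directly from a distance matrix: repeat
# { pick the unassigned point with the most unassigned-or-not neighbours
#   within the threshold (original counts; ties -> lowest index); it and its
#   neighbours form a cluster }.
brute_force_butina <- function(d, threshold) {
  n <- nrow(d)
  counts <- vapply(seq_len(n), function(i) {
    sum(d[i, -i] <= threshold)
  }, integer(1))
  assigned <- rep(FALSE, n)
  centers <- integer(0)
  repeat {
    cand <- which(!assigned)
    if (!length(cand)) break
    best <- cand[order(-counts[cand], cand)][1]
    centers <- c(centers, best)
    assigned[best] <- TRUE
    assigned[which(d[best, ] <= threshold)] <- TRUE
  }
  sort(centers)
}

# --- controllable-energy structures -----------------------------------------
# Two bonded hydrogens: surrogate energy = 320 + 100 (d - 0.62)^2, so a
# target energy offset `delta` (kcal/mol) maps to d = 0.62 + sqrt(delta/100).
h2_structure <- function(delta = 0, shift = c(0, 0, 0)) {
  d <- 0.62 + sqrt(delta / 100)
  structure3d(c("H", "H"),
              rbind(shift, shift + c(d, 0, 0)),
              charge = 0L,
              bonds = data.frame(i = 1L, j = 2L, order = 1L))
}

# single-He members let tests dictate exact pairwise RMSDs via positions
he_member <- function(x) {
  list(structure = structure3d("He", matrix(c(x, 0, 0), 1), 0L,
                               bonds = data.frame(i = integer(0),
                                                  j = integer(0),
                                                  order = integer(0))),
       energy = NULL, is_sentinel = FALSE, ff_failed = FALSE)
}

make_ensemble <- function(members, smiles = "[He]") {
  structure(list(species_smiles = smiles, graph = NULL, members = members,
                 stage = "embedded", seed = 90L),
            class = "conformer_ensemble")
}

h2_member <- function(delta) {
  list(structure = h2_structure(delta), energy = NULL,
       is_sentinel = FALSE, ff_failed = FALSE)
}

# methane at standard tetrahedral geometry (C-H 1.09 A)
methane_structure <- function() {
  a <- 1.09 / sqrt(3)
  structure3d(c("C", "H", "H", "H", "H"),
              rbind(c(0, 0, 0), c(a, a, a), c(a, -a, -a),
                    c(-a, a, -a), c(-a, -a, a)))
}

# rigid rotation about z by `theta`
rotate_z <- function(s, theta) {
  R <- matrix(c(cos(theta), sin(theta), 0,
                -sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3)
  s$coords <- s$coords %*% R
  s
}

mock_cfg <- function(...) run_config("MOCK", verbose = FALSE, ...)

# sample() without the scalar-x surprise, clamped to the population size
safe_sample <- function(x, size) {
  size <- min(size, length(x))
  x[sample.int(length(x), size)]
}
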