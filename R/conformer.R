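# Conformer search used for every species (neutral tautomer or protonated
# isomer): k = min(1 + 3 n_rot, 20) starting geometries, a force-field
# pre-screen keeping structures within 3 kcal/mol of the minimum, Butina
# clustering on heavy-atom RMSD (0.5 A) and a final refinement that selects
# the lowest-energy conformer, guarded by the connectivity sentinel.

#' Number of conformers to generate for a species
#'
#' @param n_rot number of rotatable bonds (>= 0).
#' @return `min(1 + 3 * n_rot, 20)`.
#' @export
conformer_count <- function(n_rot) {
  stopifnot(is.numeric(n_rot), all(n_rot >= 0), all(n_rot == floor(n_rot)))
  pmin(1 + 3 * n_rot, 20)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

new_ensemble <- function(species_smiles, graph, members, stage, seed) {
  structure(list(species_smiles = species_smiles, graph = graph,
                 members = members, stage = stage, seed = seed),
            class = "conformer_ensemble")
}

#' Generate starting conformers for a species
#'
#' `k` distance-geometry (ETKDG v2) embeddings at a fixed random seed;
#' deterministic for a given seed, with one randomized-coordinates retry
#' when plain embedding yields nothing. Fewer than `k` members may be
#' returned if individual embeddings fail; at least one is guaranteed.
#' Hydrogens are explicit and the atom order matches the species graph.
#'
#' @param graph internal molecular graph of the species.
#' @param k number of conformers (>= 1).
#' @param seed integer random seed (pipeline default 90).
#' @param species_smiles canonical SMILES recorded on the ensemble.
#' @return a `conformer_ensemble` at stage "embedded".
#' @export
embed_conformers <- function(graph, k, seed = 90L, species_smiles = NULL) {
  stopifnot(inherits(graph, "mol_graph"), k >= 1)
  if (is.null(species_smiles)) species_smiles <- mg_canonical_smiles(graph)
  charge <- mg_net_charge(graph)
  records <- rdkit_embed_sdf(mg_to_molfile(graph), "mol", k, seed)
  members <- lapply(records, function(rec) {
    m <- mg_from_sdf_lines(rec)
    stopifnot(identical(m$elements, graph$elements))
    list(structure = structure3d(graph$elements, m$coords, charge,
                                 bonds = graph$bonds, stage = "embedded"),
         energy = NULL, is_sentinel = FALSE, ff_failed = FALSE)
  })
  new_ensemble(species_smiles, graph, members, "embedded", seed)
}

#' Force-field pre-screen of an ensemble
#'
#' Optimizes every member with the force-field backend and keeps those with
#' energies strictly within `window` kcal/mol of the ensemble minimum. A
#' member whose force-field calculation fails is not discarded: its original
#' embedded structure is retained (flagged `ff_failed`) and passed through to
#' the refinement stage, per the documented fallback.
#'
#' @param e a `conformer_ensemble`.
#' @param spec a `backend_spec` for the pre-screen (FF or MOCK).
#' @param window energy window in kcal/mol (default 3, strict `<`).
#' @return a `conformer_ensemble` at stage "ff_optimized".
#' @export
ff_prescreen <- function(e, spec, window = 3) {
  stopifnot(inherits(e, "conformer_ensemble"), length(e$members) >= 1)
  spec <- backend_with_charge(spec, e$members[[1]]$structure$charge)
  opt <- lapply(e$members, function(m) {
    res <- tryCatch(optimize_structure(m$structure, spec),
                    error = function(err) NULL)
    if (is.null(res) || !isTRUE(res$converged)) {
      m$ff_failed <- TRUE
      m$energy <- NA_real_
      m$structure$stage <- "embedded"
      return(m)
    }
    st <- res$structure; st$stage <- "ff_optimized"
    list(structure = st, energy = res$energy,
         is_sentinel = FALSE, ff_failed = FALSE)
  })
  energies <- vapply(opt, function(m) {
    if (is.null(m$energy)) NA_real_ else m$energy
  }, numeric(1))
  if (all(is.na(energies))) {
    keep <- rep(TRUE, length(opt))            # fallback is total
  } else {
    emin <- min(energies, na.rm = TRUE)
    keep <- is.na(energies) | (energies - emin) < window
    keep[which.min(energies)] <- TRUE
  }
  new_ensemble(e$species_smiles, e$graph, opt[keep], "ff_optimized", e$seed)
}

# Pairwise heavy-atom RMSD after optimal (Kabsch) superposition with the
# identity atom mapping. Hydrogens are excluded.
ensemble_rmsd_matrix <- function(e) {
  heavy <- which(e$members[[1]]$structure$elements != "H")
  xyz <- lapply(e$members, function(m) {
    as.vector(t(m$structure$coords[heavy, , drop = FALSE]))
  })
  n <- length(xyz)
  d <- matrix(0, n, n)
  if (n >= 2) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        r <- if (length(heavy) >= 3) {
          bio3d::rmsd(xyz[[a]], xyz[[b]], fit = TRUE)
        } else {
          # too few atoms for a Kabsch fit; plain per-atom RMSD
          sqrt(mean((xyz[[a]] - xyz[[b]])^2) * 3)
        }
        d[a, b] <- d[b, a] <- r
      }
    }
  }
  d
}

# Leader-style Butina clustering on a precomputed distance matrix.
# Candidate centers are sorted by descending neighbour count within the
# threshold, ties broken by ascending index; members join the first center
# that claims them. Returns the centroid index of each cluster.
butina_centroids <- function(d, threshold) {
  n <- nrow(d)
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= threshold & seq_len(n) != i))
  counts <- lengths(neighbors)
  order_idx <- order(-counts, seq_len(n))
  assigned <- logical(n)
  centroids <- integer(0)
  for (c_i in order_idx) {
    if (assigned[c_i]) next
    centroids <- c(centroids, c_i)
    assigned[c_i] <- TRUE
    assigned[neighbors[[c_i]]] <- TRUE
  }
  sort(centroids)
}

#' Butina clustering of a conformer ensemble
#'
#' Clusters on the pairwise heavy-atom best-fit RMSD matrix with the given
#' threshold and keeps one centroid per cluster.
#'
#' @param e a `conformer_ensemble`.
#' @param rmsd_threshold RMSD threshold in Angstrom (default 0.5, inclusive).
#' @return a `conformer_ensemble` containing the centroids only.
#' @export
cluster_butina <- function(e, rmsd_threshold = 0.5) {
  stopifnot(inherits(e, "conformer_ensemble"), length(e$members) >= 1)
  if (length(e$members) == 1) return(e)
  d <- ensemble_rmsd_matrix(e)
  cent <- butina_centroids(d, rmsd_threshold)
  new_ensemble(e$species_smiles, e$graph, e$members[cent], e$stage, e$seed)
}

#' Refine cluster centroids and select the lowest-energy conformer
#'
#' Every centroid is optimized with the refinement backend; a member whose
#' optimized structure changed connectivity gets the 60,000 kcal/mol
#' sentinel energy. Members whose optimization fails outright are dropped
#' with a warning; if all members are dropped the species fails.
#'
#' @param e a `conformer_ensemble` of centroids.
#' @param spec a `backend_spec` for refinement (TB1/TB2 or MOCK).
#' @return list with `ensemble` (stage "refined"), `best` (list of
#'   `structure` and `energy`, an `energy_value`), and `all_sentinel`.
#' @export
refine <- function(e, spec) {
  stopifnot(inherits(e, "conformer_ensemble"), length(e$members) >= 1)
  spec <- backend_with_charge(spec, e$members[[1]]$structure$charge)
  refined <- list()
  for (m in e$members) {
    res <- tryCatch(optimize_structure(m$structure, spec),
                    error = function(err) NULL)
    if (is.null(res) || !isTRUE(res$converged)) {
      warning("refinement failed for one conformer of ", e$species_smiles,
              "; member dropped", call. = FALSE)
      next
    }
    ev <- apply_connectivity_sentinel(m$structure, res)
    st <- res$structure; st$stage <- "refined"
    refined[[length(refined) + 1]] <-
      list(structure = st, energy = ev$value, is_sentinel = ev$is_sentinel,
           ff_failed = isTRUE(m$ff_failed))
  }
  if (!length(refined)) {
    stop("refinement failed for every conformer of species ",
         e$species_smiles, call. = FALSE)
  }
  energies <- vapply(refined, `[[`, numeric(1), "energy")
  best_idx <- which.min(energies)
  out <- new_ensemble(e$species_smiles, e$graph, refined, "refined", e$seed)
  list(ensemble = out,
       best = list(structure = refined[[best_idx]]$structure,
                   energy = energy_value(refined[[best_idx]]$energy,
                                         refined[[best_idx]]$is_sentinel)),
       all_sentinel = all(vapply(refined, `[[`, logical(1), "is_sentinel")))
}

# Full conformer search for one species: embed, pre-screen, cluster, refine.
conformer_search <- function(graph, ff_spec, refine_spec, seed = 90L,
                             ff_window = 3, rmsd_threshold = 0.5,
                             species_smiles = NULL) {
  k <- conformer_count(mg_n_rot(graph))
  e <- embed_conformers(graph, k, seed, species_smiles)
  e <- ff_prescreen(e, ff_spec, ff_window)
  e <- cluster_butina(e, rmsd_threshold)
  refine(e, refine_spec)
}
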