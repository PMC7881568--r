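# Reaction-center detection, sigma-complex construction (protonation),
# proton affinities, green/red site selection and the qualitative
# low/medium/high reactivity call.

#' Find symmetry-unique aromatic C-H reaction centers
#'
#' One center per symmetry-equivalence class of aromatic carbons bearing at
#' least one hydrogen. Classes come from automorphism orbits of the
#' hydrogen-suppressed coloured graph (stereo-agnostic); the class
#' representative is the lowest atom index.
#'
#' @param t a `tautomer` (or an internal molecular graph).
#' @return list of reaction centers, each with `atom_index` (1-based),
#'   `atom_index0` (0-based), `symmetry_class` and `equivalent_atoms`
#'   (1-based). Empty list (with a warning) when the form has no aromatic
#'   C-H.
#' @export
find_reaction_centers <- function(t) {
  mg <- if (inherits(t, "tautomer")) t$graph else t
  stopifnot(inherits(mg, "mol_graph"))
  arom <- mg_aromatic_atoms(mg)
  nh <- mg_nH(mg)
  cand <- which(mg$elements == "C" & arom & nh >= 1 & mg$charges == 0)
  if (!length(cand)) {
    warning("no EAS sites: molecule has no aromatic C-H", call. = FALSE)
    return(list())
  }
  classes <- mg_symmetry_classes(mg)
  cls <- classes[as.character(cand)]
  out <- list()
  for (cid in sort(unique(cls))) {
    members <- sort(cand[cls == cid])
    out[[length(out) + 1]] <- list(
      atom_index = members[1], atom_index0 = members[1] - 1L,
      symmetry_class = as.integer(cid), equivalent_atoms = members)
  }
  # deterministic order: by representative atom index
  out[order(vapply(out, `[[`, integer(1), "atom_index"))]
}

# unit vector helper
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) c(0, 0, 1) else v / n
}

# Allylic shifts of the positive charge: X(+)-Y=Z  ->  X=Y-Z(+).
# Used to pick a canonical resonance form of the arenium ion.
charge_shift_variants <- function(mg, max_forms = 16) {
  seen <- list(mg)
  keys <- paste(which(mg$charges == 1), collapse = ",")
  queue <- list(mg)
  while (length(queue) && length(seen) < max_forms) {
    g <- queue[[1]]; queue <- queue[-1]
    xs <- which(g$charges == 1)
    for (x in xs) {
      nb <- mg_neighbors(g, x)
      ys <- nb$j[nb$order == 1 & g$elements[nb$j] != "H"]
      for (y in ys) {
        nb2 <- mg_neighbors(g, y)
        zs <- nb2$j[nb2$order == 2 & nb2$j != x]
        for (z in zs) {
          out <- g
          kxy <- which((out$bonds$i == min(x, y)) & (out$bonds$j == max(x, y)))
          kyz <- which((out$bonds$i == min(y, z)) & (out$bonds$j == max(y, z)))
          out$bonds$order[kxy] <- 2L
          out$bonds$order[kyz] <- 1L
          out$charges[x] <- 0L
          out$charges[z] <- 1L
          key <- paste(which(out$charges == 1), collapse = ",")
          if (!(key %in% keys)) {
            keys <- c(keys, key)
            seen[[length(seen) + 1]] <- out
            queue[[length(queue) + 1]] <- out
          }
        }
      }
    }
  }
  seen
}

#' Build the protonated isomer (sigma-complex proxy) at a reaction center
#'
#' Adds a hydrogen to the target aromatic carbon, making it tetrahedral,
#' breaks its double bond and places the resulting +1 charge on the
#' conjugated system. Among the resonance forms reachable by allylic charge
#' shifts, the one with the lexicographically smallest canonical SMILES is
#' kept, so symmetry-equivalent centers yield identical species notation.
#'
#' @param t a `tautomer`.
#' @param center a reaction center from [find_reaction_centers()].
#' @return list with `smiles` (canonical), `graph` (charge +1, new hydrogen
#'   appended as the last atom) and `center`.
#' @export
protonate <- function(t, center) {
  mg <- if (inherits(t, "tautomer")) t$graph else t
  c_at <- center$atom_index
  stopifnot(mg$elements[c_at] == "C")
  nb <- mg_neighbors(mg, c_at)
  dbl <- nb$j[nb$order == 2]
  if (!length(dbl)) stop("center carbon carries no double bond; cannot form ",
                         "the arenium ion", call. = FALSE)
  x <- min(dbl)
  out <- mg
  k <- which((out$bonds$i == min(c_at, x)) & (out$bonds$j == max(c_at, x)))
  out$bonds$order[k] <- 1L
  out$charges[x] <- out$charges[x] + 1L
  # geometry: split the old C-H direction and the ring normal tetrahedrally
  h_old <- nb$j[mg$elements[nb$j] == "H"][1]
  heavy_nb <- nb$j[mg$elements[nb$j] != "H"]
  v1 <- mg$coords[heavy_nb[1], ] - mg$coords[c_at, ]
  v2 <- mg$coords[heavy_nb[min(2, length(heavy_nb))], ] - mg$coords[c_at, ]
  nrm <- unit3(pracma_cross(v1, v2))
  u <- unit3(mg$coords[h_old, ] - mg$coords[c_at, ])
  d_ch <- COVALENT_RADII["C"] + COVALENT_RADII["H"]
  d1 <- unit3(0.577 * u + 0.816 * nrm)
  d2 <- unit3(0.577 * u - 0.816 * nrm)
  h_new <- mg_natoms(out) + 1L
  out$elements <- c(out$elements, "H")
  out$coords <- rbind(out$coords, mg$coords[c_at, ] + d1 * d_ch)
  out$coords[h_old, ] <- mg$coords[c_at, ] + d2 * d_ch
  out$charges <- c(out$charges, 0L)
  out$bonds <- rbind(out$bonds,
                     data.frame(i = c_at, j = h_new, order = 1L))
  out <- new_mol_graph(out$elements, out$coords, out$bonds, out$charges)
  # canonical resonance form by lexicographically smallest canonical SMILES
  variants <- charge_shift_variants(out)
  smis <- vapply(variants, function(g) {
    tryCatch(mg_canonical_smiles(g), error = function(e) NA_character_)
  }, character(1))
  if (all(is.na(smis))) {
    stop("protonated species failed valence sanitization", call. = FALSE)
  }
  best <- which(smis == min(smis, na.rm = TRUE))[1]
  list(smiles = smis[best], graph = variants[[best]], center = center)
}

#' Proton affinity from a neutral/protonated energy pair
#'
#' `PA = E(unprotonated) - E(protonated)`, the solvated proton's own energy
#' being neglected by convention. Positive when protonation is stabilizing.
#'
#' @param e_neutral,e_protonated `energy_value` objects (kcal/mol) or bare
#'   numbers. Sentinel energies are a contract violation here: species whose
#'   every conformer tripped the connectivity sentinel must be excluded
#'   before ranking.
#' @return proton affinity in kcal/mol.
#' @export
proton_affinity <- function(e_neutral, e_protonated) {
  val <- function(e) {
    if (inherits(e, "energy_value")) {
      if (e$is_sentinel) stop("sentinel energy passed to proton_affinity; ",
                              "filter invalid species upstream", call. = FALSE)
      e$value
    } else as.numeric(e)
  }
  val(e_neutral) - val(e_protonated)
}

#' Label reaction centers by proton-affinity deficit
#'
#' Deficits are measured from the highest proton affinity; sites within
#' `green_cut` kcal/mol are green (predicted), within `red_cut` red
#' (borderline), otherwise unlabelled. Both cutoffs are inclusive.
#'
#' @param pas named numeric vector of proton affinities (kcal/mol), one per
#'   center, or a list of `(center, pa)` pairs.
#' @param green_cut,red_cut windows in kcal/mol (defaults 1 and 3).
#' @param centers optional list of reaction centers matching `pas`.
#' @return list of site predictions: `center`, `proton_affinity`, `deficit`,
#'   `label` in {"green", "red", "none"}.
#' @export
select_sites <- function(pas, green_cut = 1, red_cut = 3, centers = NULL) {
  stopifnot(length(pas) >= 1, green_cut < red_cut)
  pa <- as.numeric(pas)
  pa_max <- max(pa)
  deficit <- pa_max - pa
  label <- ifelse(deficit <= green_cut, "green",
                  ifelse(deficit <= red_cut, "red", "none"))
  lapply(seq_along(pa), function(k) {
    list(center = if (!is.null(centers)) centers[[k]]
                  else if (!is.null(names(pas))) names(pas)[k] else k,
         proton_affinity = pa[k], deficit = deficit[k], label = label[k])
  })
}

#' Qualitative reactivity class from the highest proton affinity
#'
#' Most molecules have highest proton affinities in the 70-100 kcal/mol
#' band; values below/above are flagged as unusually low/high reactivity.
#' The band is closed on both ends.
#'
#' @param pa_max highest proton affinity in kcal/mol.
#' @param low_bound,high_bound band bounds (defaults 70 and 100).
#' @return one of "low", "medium", "high".
#' @export
classify_reactivity <- function(pa_max, low_bound = 70, high_bound = 100) {
  stopifnot(is.finite(pa_max))
  if (pa_max < low_bound) "low"
  else if (pa_max > high_bound) "high"
  else "medium"
}

#' Assemble a prediction report
#'
#' @param m a `molecule_record`.
#' @param tautomer_results list of per-tautomer results: `tautomer`, `sites`
#'   (from [select_sites()]), `pa_max`, `reactivity`, `no_sites`,
#'   `not_evaluated` (centers excluded by sanitization/sentinel failures).
#' @param config configuration echo list (backend, seed, cutoffs).
#' @return a `prediction_report`; report-level reactivity comes from the
#'   most stable tautomer that has at least one evaluated site.
#' @export
build_report <- function(m, tautomer_results, config = list()) {
  stopifnot(inherits(m, "molecule_record"), length(tautomer_results) >= 1)
  rel <- vapply(tautomer_results, function(tr) tr$tautomer$rel_energy,
                numeric(1))
  tautomer_results <- tautomer_results[order(rel)]
  overall <- NA_character_
  for (tr in tautomer_results) {
    if (!isTRUE(tr$no_sites) && is.finite(tr$pa_max)) {
      overall <- tr$reactivity
      break
    }
  }
  structure(list(molecule = m, tautomer_results = tautomer_results,
                 reactivity_class = overall, config = config),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report>", x$molecule$id, "(", x$molecule$smiles, ")\n")
  cat("  reactivity:", x$reactivity_class, "\n")
  for (tr in x$tautomer_results) {
    cat(sprintf("  tautomer %s  rel %.1f kcal/mol  [%s]\n",
                tr$tautomer$smiles, tr$tautomer$rel_energy, tr$reactivity))
    for (s in tr$sites) {
      cat(sprintf("    atom %d (0-based %d) PA %.2f kcal/mol  deficit %.2f  %s\n",
                  s$center$atom_index, s$center$atom_index0,
                  s$proton_affinity, s$deficit, s$label))
    }
  }
  invisible(x)
}
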