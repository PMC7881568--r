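# Rule-based tautomer enumeration: 1,3 and 1,5 hydrogen shifts along
# alternating bond paths (D-A=B and D-A=B-C=E), applied over every Kekule
# resonance structure of each form, closed under breadth-first iteration and
# deduplicated by canonical SMILES.
# Restrictions keep the chemistry sane: a heteroatom must take part, the H
# never lands on an aromatic carbon (which would dearomatize the ring), and
# charged atoms are left alone. Heavy-atom indices are preserved across all
# generated forms, which the evaluation module relies on.

TAUTOMER_ELEMENTS <- c("C", "N", "O", "S")
TAUTOMER_HETERO <- c("N", "O", "S")

new_tautomer <- function(smiles, graph, is_input = FALSE,
                         stereo_stripped = FALSE) {
  structure(list(smiles = smiles, graph = graph, rel_energy = NA_real_,
                 best = NULL, is_input = is_input,
                 stereo_stripped = stereo_stripped),
            class = "tautomer")
}

# Tetrahedral stereocenter candidates: sp3 carbon, four substituents, at
# most one hydrogen, heavy neighbours in pairwise distinct symmetry classes.
mg_stereocenters <- function(mg) {
  classes <- tryCatch(mg_symmetry_classes(mg), error = function(e) NULL)
  if (is.null(classes)) return(integer(0))
  nh <- mg_nH(mg)
  out <- integer(0)
  for (a in mg_heavy(mg)) {
    if (mg$elements[a] != "C") next
    nb <- mg_neighbors(mg, a)
    if (nrow(nb) != 4 || any(nb$order != 1)) next
    if (nh[a] > 1) next
    hv <- nb$j[mg$elements[nb$j] != "H"]
    cl <- classes[as.character(hv)]
    if (anyNA(cl)) next
    if (anyDuplicated(cl) == 0) out <- c(out, a)
  }
  out
}

strip_stereo_smiles <- function(smiles) {
  s <- gsub("@", "", smiles, fixed = TRUE)
  s <- gsub("[/\\\\]", "-", s)
  ob_canonical_smiles(s)
}

# All 1,3 and 1,5 hydrogen-shift paths available on one Kekule form.
# A path is an odd alternating chain D-A=B (1,3) or D-A=B-C=E (1,5); the H
# leaves the donor D (which must carry no double bond, so no cumulenes can
# form) and lands on the final atom, which must not be an aromatic carbon.
# Returns a list of atom-index vectors (length 3 or 5).
find_h_shifts <- function(mg, arom) {
  nh <- mg_nH(mg)
  b <- mg$bonds
  has_double <- rep(FALSE, mg_natoms(mg))
  has_double[unique(c(b$i[b$order >= 2], b$j[b$order >= 2]))] <- TRUE
  ok_atom <- function(a) mg$elements[a] %in% TAUTOMER_ELEMENTS &&
    mg$charges[a] == 0
  partners <- function(a, ord) {
    nb <- mg_neighbors(mg, a)
    nb$j[nb$order == ord & mg$elements[nb$j] != "H"]
  }
  acceptor_ok <- function(d_at, e_at) {
    ok_atom(e_at) &&
      (mg$elements[d_at] %in% TAUTOMER_HETERO ||
         mg$elements[e_at] %in% TAUTOMER_HETERO) &&
      !(mg$elements[e_at] == "C" && arom[e_at])
  }
  moves <- list()
  donors <- which(nh >= 1 & !has_double &
                    mg$elements %in% TAUTOMER_ELEMENTS & mg$charges == 0)
  for (d_at in donors) {
    for (a_at in partners(d_at, 1)) {
      if (!ok_atom(a_at)) next
      for (b_at in partners(a_at, 2)) {
        if (b_at == d_at || !ok_atom(b_at)) next
        if (acceptor_ok(d_at, b_at)) {
          moves[[length(moves) + 1]] <- c(d_at, a_at, b_at)
        }
        for (c_at in partners(b_at, 1)) {
          if (c_at %in% c(d_at, a_at) || !ok_atom(c_at)) next
          for (e_at in partners(c_at, 2)) {
            if (e_at %in% c(d_at, a_at, b_at)) next
            if (acceptor_ok(d_at, e_at)) {
              moves[[length(moves) + 1]] <- c(d_at, a_at, b_at, c_at, e_at)
            }
          }
        }
      }
    }
  }
  moves
}

apply_h_shift <- function(mg, move) {
  d_at <- move[1]
  e_at <- move[length(move)]
  out <- mg
  b <- out$bonds
  h_cands <- c(b$j[b$i == d_at & out$elements[b$j] == "H"],
               b$i[b$j == d_at & out$elements[b$i] == "H"])
  h_at <- min(h_cands)
  # rebond the hydrogen donor -> acceptor
  hk <- which((b$i == d_at & b$j == h_at) | (b$i == h_at & b$j == d_at))
  out$bonds$i[hk] <- min(h_at, e_at)
  out$bonds$j[hk] <- max(h_at, e_at)
  # toggle bond orders along the alternating path
  new_orders <- rep(c(2L, 1L), length.out = length(move) - 1)
  for (k in seq_len(length(move) - 1)) {
    i <- min(move[k], move[k + 1]); j <- max(move[k], move[k + 1])
    bk <- which(out$bonds$i == i & out$bonds$j == j)
    out$bonds$order[bk] <- new_orders[k]
  }
  # rough new position for the moved hydrogen (regenerated before any use)
  nb <- mg_neighbors(out, e_at)
  dirs <- out$coords[nb$j[nb$j != h_at], , drop = FALSE]
  v <- -colSums(sweep(dirs, 2, out$coords[e_at, ]))
  if (sqrt(sum(v^2)) < 1e-6) v <- c(0, 0, 1)
  v <- v / sqrt(sum(v^2))
  d0 <- COVALENT_RADII[out$elements[e_at]] + COVALENT_RADII["H"]
  out$coords[h_at, ] <- out$coords[e_at, ] + v * d0
  out
}

#' Enumerate tautomers of a molecule
#'
#' Applies 1,3 and 1,5 hydrogen shifts over all Kekule resonance structures
#' of each form until closure, deduplicating by canonical SMILES. The input form is
#' always the first member. If a shift happens adjacent to a tetrahedral
#' stereocenter, the stereo designation is removed from that form's SMILES.
#'
#' @param m a `molecule_record` from [parse_input()].
#' @param max_tautomers cap on the number of forms (default 32); excess
#'   forms are dropped with a warning, in enumeration order.
#' @return list of `tautomer` objects (relative energies unset).
#' @export
enumerate_tautomers <- function(m, max_tautomers = 32L) {
  stopifnot(inherits(m, "molecule_record"))
  start <- m$graph
  start_smiles <- mg_canonical_smiles(start)
  seen <- start_smiles
  out <- list(new_tautomer(start_smiles, start, is_input = TRUE))
  queue <- list(start)
  truncated <- FALSE
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    arom <- mg_aromatic_atoms(g)
    stereo <- mg_stereocenters(g)
    for (kek in mg_kekule_variants(g)) {
      for (move in find_h_shifts(kek, arom)) {
        cand <- apply_h_shift(kek, move)
        # stereo is dropped when the shift touches (or creates) a
        # stereocenter or happens adjacent to one
        cand_stereo <- unique(c(stereo, mg_stereocenters(cand)))
        near_stereo <- length(cand_stereo) > 0 &&
          any(vapply(cand_stereo, function(s) {
            any(mg_neighbors(cand, s)$j %in% move) || s %in% move
          }, logical(1)))
        smi <- tryCatch(mg_canonical_smiles(cand), error = function(e) NA)
        if (is.na(smi)) next
        if (near_stereo) {
          smi <- tryCatch(strip_stereo_smiles(smi), error = function(e) smi)
        }
        if (smi %in% seen) next
        if (length(out) >= max_tautomers) { truncated <- TRUE; next }
        seen <- c(seen, smi)
        out[[length(out) + 1]] <- new_tautomer(smi, cand,
                                               stereo_stripped = near_stereo)
        queue[[length(queue) + 1]] <- cand
      }
    }
  }
  if (truncated) {
    warning("tautomer enumeration truncated at ", max_tautomers, " forms for ",
            m$id, call. = FALSE)
  }
  out
}

#' Filter tautomers by relative energy
#'
#' Keeps tautomers with relative energies strictly below `cutoff` kcal/mol,
#' sorted ascending. The most stable form (relative energy 0) is always
#' retained.
#'
#' @param ts list of `tautomer` objects with `rel_energy` set.
#' @param cutoff energy cutoff in kcal/mol (default 15, strict `<`).
#' @return filtered, ascending-sorted list of `tautomer` objects.
#' @export
filter_tautomers <- function(ts, cutoff = 15) {
  stopifnot(length(ts) >= 1)
  rel <- vapply(ts, `[[`, numeric(1), "rel_energy")
  if (anyNA(rel)) stop("filter_tautomers: all relative energies must be set")
  if (min(rel) != 0) stop("filter_tautomers: minimum relative energy must be 0")
  keep <- rel < cutoff
  keep[which.min(rel)] <- TRUE
  ts <- ts[keep]
  ts[order(vapply(ts, `[[`, numeric(1), "rel_energy"))]
}
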