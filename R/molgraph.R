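# Internal molecular graph: elements, 3D coordinates, formal charges and a
# Kekule bond table (explicit hydrogens, stable atom order). Heavy atoms keep
# the order of the input SMILES; hydrogens are appended by Open Babel. All
# tautomer / protonation transforms operate on this structure so that atom
# indices stay comparable across species of the same molecule.

new_mol_graph <- function(elements, coords, bonds, charges = NULL) {
  n <- length(elements)
  stopifnot(is.matrix(coords), nrow(coords) == n, ncol(coords) == 3)
  if (is.null(charges)) charges <- integer(n)
  bonds <- as.data.frame(bonds)
  names(bonds) <- c("i", "j", "order")
  swap <- bonds$i > bonds$j
  tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
  bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
  rownames(bonds) <- NULL
  structure(list(elements = elements, coords = coords,
                 bonds = bonds, charges = as.integer(charges)),
            class = "mol_graph")
}

mg_natoms <- function(mg) length(mg$elements)
mg_heavy <- function(mg) which(mg$elements != "H")
mg_net_charge <- function(mg) sum(mg$charges)

# neighbour list: for atom i, data.frame of (j, order)
mg_neighbors <- function(mg, i) {
  b <- mg$bonds
  sel <- b$i == i | b$j == i
  data.frame(j = ifelse(b$i[sel] == i, b$j[sel], b$i[sel]),
             order = b$order[sel])
}

mg_nH <- function(mg) {
  n <- mg_natoms(mg)
  out <- integer(n)
  hb <- mg$bonds[mg$elements[mg$bonds$i] == "H" | mg$elements[mg$bonds$j] == "H", ]
  if (nrow(hb)) {
    heavy_end <- ifelse(mg$elements[hb$i] == "H", hb$j, hb$i)
    tb <- table(heavy_end)
    out[as.integer(names(tb))] <- as.integer(tb)
  }
  out
}

mg_formula <- function(mg) {
  tb <- table(mg$elements)
  els <- names(tb)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(hill, ifelse(tb[hill] > 1, tb[hill], ""), collapse = "")
}

# ---- SDF / molfile I/O -----------------------------------------------------

# Parse the first molecule of SDF text (ChemmineR does the V2000 parsing;
# formal charges come from the "M  CHG" property lines of the raw text).
mg_from_sdf_lines <- function(lines) {
  f <- tempfile(fileext = ".sdf")
  on.exit(unlink(f))
  writeLines(lines, f)
  sdf <- ChemmineR::read.SDFset(f)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  charges <- integer(length(elements))
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- toks[1]
    for (m in seq_len(k)) charges[toks[2 * m]] <- toks[2 * m + 1]
  }
  new_mol_graph(elements, coords, bonds, charges)
}

mg_from_smiles <- function(smiles, seed = 90L) {
  mg_from_sdf_lines(rdkit_embed_sdf(smiles, "smi", 1L, seed)[[1]])
}

# Serialize to MDL molfile (V2000) text. Every atom's valence field is set
# to its explicit bond-order sum (15 = zero bonds): all hydrogens in these
# graphs are explicit atoms, and without the marking readers would add
# implicit hydrogens to under-valent resonance forms of the arenium ions.
mg_to_molfile <- function(mg, title = "easregio") {
  n <- mg_natoms(mg)
  b <- mg$bonds
  vsum <- integer(n)
  for (k in seq_len(nrow(b))) {
    vsum[b$i[k]] <- vsum[b$i[k]] + b$order[k]
    vsum[b$j[k]] <- vsum[b$j[k]] + b$order[k]
  }
  vcode <- ifelse(vsum == 0L, 15L, pmin(vsum, 14L))
  lines <- c(title, " easregio", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)))
  for (k in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0%3d  0  0  0  0  0  0",
      mg$coords[k, 1], mg$coords[k, 2], mg$coords[k, 3], mg$elements[k],
      vcode[k]))
  }
  for (k in seq_len(nrow(b))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", b$i[k], b$j[k], b$order[k]))
  }
  chg <- which(mg$charges != 0)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, mg$charges[grp]),
                                      collapse = "")))
    }
  }
  c(lines, "M  END")
}

mg_canonical_smiles <- function(mg) {
  ob_canonical_from_molfile(mg_to_molfile(mg))
}

# Rebuild 3D coordinates for the current bond table (same atom order).
mg_regen3d <- function(mg, seed = 90L) {
  rec <- rdkit_embed_sdf(mg_to_molfile(mg), "mol", 1L, seed)[[1]]
  out <- mg_from_sdf_lines(rec)
  stopifnot(identical(out$elements, mg$elements))
  out$charges <- mg$charges
  out
}

# ---- ring perception -------------------------------------------------------

# Smallest ring through each cyclic bond (BFS with the bond removed),
# deduplicated by vertex set. Good enough for the ring sizes this package
# works with (max_size guards pathological inputs).
mg_rings <- function(mg, max_size = 8) {
  b <- mg$bonds
  n <- mg_natoms(mg)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(b))) {
    src <- b$i[k]; dst <- b$j[k]
    # BFS from src to dst avoiding the direct edge
    prev <- rep(NA_integer_, n)
    dist <- rep(Inf, n)
    dist[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == dst) break
      if (dist[v] + 1 > max_size - 1) next
      for (w in adj[[v]]) {
        if ((v == src && w == dst)) next
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          prev[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (is.infinite(dist[dst])) next
    path <- dst
    while (path[1] != src) path <- c(prev[path[1]], path)
    key <- paste(sort(path), collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1]] <- path
    }
  }
  rings
}

mg_ring_atoms <- function(mg) sort(unique(unlist(mg_rings(mg))))

mg_bond_in_ring <- function(mg) {
  rings <- mg_rings(mg)
  ring_edges <- character(0)
  for (r in rings) {
    cyc <- c(r, r[1])
    for (k in seq_along(r)) {
      e <- sort(c(cyc[k], cyc[k + 1]))
      ring_edges <- c(ring_edges, paste(e[1], e[2]))
    }
  }
  paste(mg$bonds$i, mg$bonds$j) %in% ring_edges
}

# ---- aromaticity (Hueckel on each perceived ring) --------------------------

# Pi-electron contribution of `atom` to `ring` given the Kekule bond orders:
#   * double bond to a partner inside any ring       -> 1
#   * double bond only to an exocyclic chain atom    -> 0 (e.g. C=O of a
#     lactam carbon: contributes an empty p orbital)
#   * no double bond: N/P with H or 3 sigma bonds    -> 2 (pyrrole-type)
#                     O/S/Se                          -> 2 (furan-type)
#                     anything else                   -> blocks aromaticity
mg_aromatic_atoms <- function(mg) {
  n <- mg_natoms(mg)
  arom <- logical(n)
  rings <- mg_rings(mg)
  if (!length(rings)) return(arom)
  in_any_ring <- seq_len(n) %in% unique(unlist(rings))
  for (ring in rings) {
    if (length(ring) < 5 || length(ring) > 7) next
    pi <- 0
    ok <- TRUE
    for (a in ring) {
      el <- mg$elements[a]
      nb <- mg_neighbors(mg, a)
      dbl <- nb$j[nb$order >= 2]
      if (length(dbl)) {
        if (any(in_any_ring[dbl])) {
          pi <- pi + 1
        } else if (el %in% c("C", "N")) {
          pi <- pi + 0   # exocyclic pi bond, empty/inert p orbital in ring
        } else { ok <- FALSE; break }
      } else {
        if (el %in% c("N", "P")) {
          pi <- pi + 2
        } else if (el %in% c("O", "S", "Se")) {
          pi <- pi + 2
        } else if (el == "C" && mg$charges[a] == 1) {
          pi <- pi + 0   # arenium-type carbocation: empty p orbital
        } else { ok <- FALSE; break }
      }
    }
    if (ok && pi %% 4 == 2) arom[ring] <- TRUE
  }
  arom
}

mg_aromatic_bonds <- function(mg, arom = mg_aromatic_atoms(mg)) {
  in_ring <- mg_bond_in_ring(mg)
  arom[mg$bonds$i] & arom[mg$bonds$j] & in_ring
}

# ---- rotatable bonds -------------------------------------------------------

# Strict rotatable-bond rule (Daylight/RDKit-style): acyclic single bond
# between two non-terminal heavy atoms, excluding atoms involved in triple
# bonds and the amide C-N bond.
mg_rotatable_bonds <- function(mg) {
  b <- mg$bonds
  heavy <- mg$elements != "H"
  heavy_deg <- integer(mg_natoms(mg))
  hb <- b[heavy[b$i] & heavy[b$j], , drop = FALSE]
  if (nrow(hb)) {
    tb <- table(c(hb$i, hb$j))
    heavy_deg[as.integer(names(tb))] <- as.integer(tb)
  }
  in_ring <- mg_bond_in_ring(mg)
  triple_atom <- unique(c(b$i[b$order == 3], b$j[b$order == 3]))
  is_amide_cn <- function(i, j) {
    for (idx in list(c(i, j), c(j, i))) {
      c_at <- idx[1]; n_at <- idx[2]
      if (mg$elements[c_at] == "C" && mg$elements[n_at] == "N") {
        nb <- mg_neighbors(mg, c_at)
        if (any(nb$order == 2 & mg$elements[nb$j] == "O")) return(TRUE)
      }
    }
    FALSE
  }
  rot <- which(b$order == 1 & !in_ring &
                 heavy[b$i] & heavy[b$j] &
                 heavy_deg[b$i] >= 2 & heavy_deg[b$j] >= 2 &
                 !(b$i %in% triple_atom) & !(b$j %in% triple_atom))
  rot[!vapply(rot, function(k) is_amide_cn(b$i[k], b$j[k]), logical(1))]
}

mg_n_rot <- function(mg) length(mg_rotatable_bonds(mg))

# ---- symmetry-equivalence classes ------------------------------------------

# Automorphism orbits of the hydrogen-suppressed, vertex/bond-coloured graph
# (element, formal charge, attached-H count; bond colour = aromatic or Kekule
# order). Bond colours are realised by subdividing every bond with a coloured
# dummy vertex because BLISS colours vertices only. Stereochemistry and
# isotopes are deliberately ignored.
mg_symmetry_classes <- function(mg) {
  heavy <- mg_heavy(mg)
  nh <- mg_nH(mg)
  arom <- mg_aromatic_atoms(mg)
  ab <- mg_aromatic_bonds(mg, arom)
  hmap <- match(seq_len(mg_natoms(mg)), heavy)   # atom index -> heavy index
  atom_key <- paste(mg$elements[heavy], mg$charges[heavy], nh[heavy], arom[heavy])
  atom_col <- as.integer(factor(atom_key))
  b <- mg$bonds
  sel <- which(mg$elements[b$i] != "H" & mg$elements[b$j] != "H")
  n_heavy <- length(heavy)
  if (n_heavy == 1) return(stats::setNames(1L, heavy))
  bond_key <- ifelse(ab[sel], "ar", as.character(b$order[sel]))
  bond_col <- max(atom_col) + as.integer(factor(bond_key))
  edges <- integer(0)
  for (t in seq_along(sel)) {
    k <- sel[t]
    bv <- n_heavy + t
    edges <- c(edges, hmap[b$i[k]], bv, bv, hmap[b$j[k]])
  }
  g <- igraph::make_graph(edges, n = n_heavy + length(sel), directed = FALSE)
  gens <- igraph::automorphism_group(
    g, colors = c(atom_col, bond_col))
  # orbits = connected components of the union of generator mappings
  parent <- seq_len(n_heavy)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in gens) {
    pv <- as.integer(p)[seq_len(n_heavy)]
    for (v in seq_len(n_heavy)) {
      a <- find(v); bb <- find(pv[v])
      if (a != bb) parent[bb] <- a
    }
  }
  roots <- vapply(seq_len(n_heavy), find, integer(1))
  stats::setNames(as.integer(factor(roots)), heavy)
}

# ---- Kekule structure enumeration ------------------------------------------

# All alternative assignments of the ring double bonds (perfect matchings on
# the atoms that currently carry one ring double bond). Used so tautomer
# transforms do not depend on which Kekule form Open Babel happened to write.
mg_kekule_variants <- function(mg, max_variants = 64) {
  b <- mg$bonds
  in_ring <- mg_bond_in_ring(mg)
  ring_dbl <- which(in_ring & b$order == 2)
  matched <- sort(unique(c(b$i[ring_dbl], b$j[ring_dbl])))
  if (!length(matched)) return(list(mg))
  cand <- which(in_ring & b$i %in% matched & b$j %in% matched &
                  b$order %in% c(1, 2))
  matchings <- list()
  recurse <- function(remaining, chosen) {
    if (length(matchings) >= max_variants) return()
    if (!length(remaining)) {
      matchings[[length(matchings) + 1]] <<- chosen
      return()
    }
    a <- remaining[1]
    for (k in cand) {
      if ((b$i[k] == a && b$j[k] %in% remaining) ||
          (b$j[k] == a && b$i[k] %in% remaining)) {
        other <- if (b$i[k] == a) b$j[k] else b$i[k]
        recurse(setdiff(remaining, c(a, other)), c(chosen, k))
      }
    }
  }
  recurse(matched, integer(0))
  lapply(matchings, function(ks) {
    out <- mg
    out$bonds$order[cand] <- 1L
    out$bonds$order[ks] <- 2L
    out
  })
}
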