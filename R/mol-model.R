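# Domain types and structure-level utilities: validated molecule records,
# 3D structures, XYZ I/O, distance-based bond perception and the
# Hartree -> kcal/mol conversion used to compare against all thresholds.

# Covalent radii in Angstrom (Cordero et al. consensus values), used both for
# bond perception and as reference bond lengths d0 of the surrogate backend.
COVALENT_RADII <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Zn = 1.22,
  As = 1.19, Se = 1.20, Br = 1.20, Sn = 1.39, I = 1.39
)

# kcal/mol per Hartree; pinned because the decision windows are sensitive at
# the 1 kcal/mol level.
HARTREE_TO_KCAL <- 627.509474

# Energy set for a species whose optimized structure changed connectivity
# (e.g. an intramolecular proton transfer): large enough that it can never
# win a lowest-energy comparison.
SENTINEL_ENERGY <- 60000.0

#' Convert Hartree to kcal/mol
#'
#' @param e_hartree numeric vector of energies in Hartree.
#' @return energies in kcal/mol (factor 627.509474).
#' @export
hartree_to_kcal <- function(e_hartree) {
  stopifnot(is.numeric(e_hartree), all(is.finite(e_hartree)))
  e_hartree * HARTREE_TO_KCAL
}

#' Energy value with sentinel flag
#'
#' A plain kcal/mol energy, or the 60,000 kcal/mol sentinel assigned when a
#' geometry optimization changed the bonding pattern of a species.
#'
#' @param value energy in kcal/mol.
#' @param is_sentinel logical; if `TRUE`, `value` must equal 60000.
#' @return an `energy_value` object.
#' @export
energy_value <- function(value, is_sentinel = FALSE) {
  stopifnot(is.numeric(value), length(value) == 1)
  if (is_sentinel && value != SENTINEL_ENERGY) {
    stop("sentinel energies must equal ", SENTINEL_ENERGY, " kcal/mol")
  }
  structure(list(value = value, is_sentinel = is_sentinel),
            class = "energy_value")
}

sentinel_energy <- function() energy_value(SENTINEL_ENERGY, TRUE)

#' 3D structure
#'
#' Elements, Cartesian coordinates (Angstrom), total charge and optionally an
#' explicit bond table. `stage` records provenance within the pipeline.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, one row per atom, columns x/y/z.
#' @param charge integer total charge.
#' @param bonds optional data.frame with columns i, j, order (1-based, i < j).
#' @param stage one of "embedded", "ff_optimized", "refined".
#' @return a `structure3d` object.
#' @export
structure3d <- function(elements, coords, charge = 0L, bonds = NULL,
                        stage = c("embedded", "ff_optimized", "refined")) {
  stage <- match.arg(stage)
  coords <- as.matrix(coords)
  stopifnot(length(elements) == nrow(coords), ncol(coords) == 3)
  if (!is.null(bonds)) {
    bonds <- as.data.frame(bonds)
    names(bonds)[1:3] <- c("i", "j", "order")
    stopifnot(all(bonds$i >= 1), all(bonds$j <= length(elements)),
              all(bonds$i < bonds$j),
              !anyDuplicated(paste(bonds$i, bonds$j)))
  }
  structure(list(elements = elements, coords = unname(coords),
                 charge = as.integer(charge), bonds = bonds, stage = stage),
            class = "structure3d")
}

mg_structure <- function(mg, stage = "embedded") {
  structure3d(mg$elements, mg$coords, mg_net_charge(mg),
              bonds = mg$bonds, stage = stage)
}

#' Parse and validate an input molecule
#'
#' Parses a SMILES string, canonicalizes it, rejects molecules with nonzero
#' net formal charge (the proton-affinity model presumes a neutral substrate)
#' and counts rotatable bonds.
#'
#' @param smiles_text SMILES string.
#' @param id short text label for the molecule.
#' @return a `molecule_record` with fields `id`, `smiles` (canonical),
#'   `input_smiles`, `net_charge`, `n_rot` and the internal graph.
#' @export
parse_input <- function(smiles_text, id = "mol") {
  stopifnot(is.character(smiles_text), length(smiles_text) == 1,
            nzchar(smiles_text))
  canonical <- ob_canonical_smiles(smiles_text)
  mg <- mg_from_smiles(smiles_text)
  q <- mg_net_charge(mg)
  if (q != 0L) {
    stop("molecule '", id, "' has net formal charge ", q,
         "; only neutral molecules are supported", call. = FALSE)
  }
  structure(list(id = id, smiles = canonical, input_smiles = smiles_text,
                 net_charge = q, n_rot = mg_n_rot(mg), graph = mg),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule_record>", x$id, "\n  smiles:", x$smiles,
      "\n  net charge:", x$net_charge, " rotatable bonds:", x$n_rot, "\n")
  invisible(x)
}

# ---- XYZ I/O ----------------------------------------------------------------

#' Write a structure as XYZ text
#'
#' Standard dialect: atom count, comment line (energy in kcal/mol when
#' given), then `El x y z` rows.
#'
#' @param s a `structure3d`.
#' @param energy optional energy in kcal/mol for the comment line.
#' @return character vector of lines.
#' @export
write_xyz <- function(s, energy = NULL) {
  stopifnot(inherits(s, "structure3d"))
  comment <- if (is.null(energy)) "" else sprintf("energy_kcal_mol %.8f", energy)
  c(as.character(nrow(s$coords)), comment,
    sprintf("%-3s %16.8f %16.8f %16.8f",
            s$elements, s$coords[, 1], s$coords[, 2], s$coords[, 3]))
}

#' Read XYZ text into a structure
#'
#' @param text character vector of lines (or single string with newlines).
#' @param charge total charge to record on the structure.
#' @return a `structure3d` (coordinates only; no bonds).
#' @export
read_xyz <- function(text, charge = 0L) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  if (length(lines) < 2) stop("malformed XYZ: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ at line 1: atom count expected")
  if (length(lines) < 2 + n) {
    stop("malformed XYZ at line ", length(lines) + 1, ": expected ", n,
         " atom rows, found ", length(lines) - 2)
  }
  rows <- lines[3:(2 + n)]
  toks <- strsplit(trimws(rows), "\\s+")
  for (k in seq_along(toks)) {
    if (length(toks[[k]]) < 4) stop("malformed XYZ at line ", k + 2)
  }
  elements <- vapply(toks, `[`, character(1), 1)
  coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (anyNA(coords)) stop("malformed XYZ: non-numeric coordinate")
  structure3d(elements, coords, charge = charge)
}

# ---- bond perception and connectivity comparison ---------------------------

#' Perceive connectivity from interatomic distances
#'
#' A bond is assigned between atoms i and j when their distance does not
#' exceed 1.3 times the sum of covalent radii. Deterministic; bond orders are
#' not assigned (all reported as 1).
#'
#' @param s a `structure3d`.
#' @param tol radius-sum scale factor (default 1.3).
#' @return data.frame of bonds (i, j, order) with i < j.
#' @export
perceive_connectivity <- function(s, tol = 1.3) {
  stopifnot(inherits(s, "structure3d"))
  radii <- COVALENT_RADII[s$elements]
  if (anyNA(radii)) {
    stop("no covalent radius for element(s): ",
         paste(unique(s$elements[is.na(radii)]), collapse = ", "))
  }
  d <- as.matrix(stats::dist(s$coords))
  n <- nrow(d)
  if (n >= 2) {
    dm <- d[upper.tri(d)]
    if (any(dm < 0.3)) {
      stop("overlapping atoms: interatomic distance below 0.3 Angstrom")
    }
  }
  out <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      if (d[i, j] <= tol * (radii[i] + radii[j])) {
        out <- rbind(out, data.frame(i = i, j = j, order = 1L))
      }
    }
  }
  out
}

bond_key_set <- function(bonds) {
  if (is.null(bonds) || nrow(bonds) == 0) return(character(0))
  sort(paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j)))
}

#' Did a geometry optimization change the bonding pattern?
#'
#' Compares the perceived bond sets (unordered index pairs, bond order
#' ignored) of two structures with identical atom sequences.
#'
#' @param input_s,output_s `structure3d` objects with the same elements.
#' @return `TRUE` iff the perceived connectivity differs.
#' @export
connectivity_changed <- function(input_s, output_s) {
  stopifnot(inherits(input_s, "structure3d"), inherits(output_s, "structure3d"))
  if (!identical(input_s$elements, output_s$elements)) {
    stop("connectivity_changed: structures must share the atom sequence")
  }
  !identical(bond_key_set(perceive_connectivity(input_s)),
             bond_key_set(perceive_connectivity(output_s)))
}
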