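# Bundled small-molecule set used in examples, tests and the evaluation
# demo. Observed sites in the toy CSV are hand-assigned from textbook EAS
# chemistry for the unambiguous (symmetric, strongly directing) cases.

#' Bundled fixture molecules
#'
#' @return data.frame with columns `id` and `smiles`.
#' @export
eas_fixture_molecules <- function() {
  data.frame(
    id = c("benzene", "fluorobenzene", "toluene", "anisole", "aniline",
           "nitrobenzene", "pyridine", "pyrrole", "2-hydroxypyridine",
           "indole", "7-azaindole"),
    smiles = c("c1ccccc1", "Fc1ccccc1", "Cc1ccccc1", "COc1ccccc1",
               "Nc1ccccc1", "O=[N+]([O-])c1ccccc1", "c1ccncc1",
               "c1cc[nH]c1", "Oc1ccccn1", "c1ccc2[nH]ccc2c1",
               "c1ccc2[nH]ccc2n1"),
    stringsAsFactors = FALSE)
}

# Toy observed-site table (0-based indices in the fixture SMILES order).
# benzene: any ring carbon (all equivalent); pyrrole: alpha position;
# anisole: para to the methoxy group; indole: C3 of the pyrrole ring.
eas_fixture_observed <- function() {
  data.frame(
    molecule_id = c("benzene", "pyrrole", "anisole", "indole"),
    smiles = c("c1ccccc1", "c1cc[nH]c1", "COc1ccccc1", "c1ccc2[nH]ccc2c1"),
    observed_sites = c("0", "2", "5", "6"),
    stringsAsFactors = FALSE)
}

#' Write the fixture set to disk
#'
#' Writes `molecules.smi` (SMILES + id per line) and `observed.csv` (toy
#' evaluation table with hand-assigned observed sites).
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
make_fixtures <- function(dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mols <- eas_fixture_molecules()
  smi_path <- file.path(dir, "molecules.smi")
  writeLines(paste(mols$smiles, mols$id), smi_path)
  csv_path <- file.path(dir, "observed.csv")
  utils::write.csv(eas_fixture_observed(), csv_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(smi_path, csv_path))
}
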