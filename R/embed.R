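# Distance-geometry 3D embedding (ETKDG v2) through a bundled helper script
# run with the system Python/RDKit. Deterministic for a fixed random seed,
# which the Open Babel 3D builder cannot guarantee (its rotor search is
# stochastic with no seed control).

python_binary <- function() {
  bin <- Sys.getenv("EASREGIO_PYTHON", "python")
  if (Sys.which(bin) == "") {
    stop("Python executable '", bin, "' (with RDKit) not found on PATH; ",
         "needed for 3D embedding. Set EASREGIO_PYTHON to override.",
         call. = FALSE)
  }
  bin
}

embed_helper_path <- function() {
  p <- system.file("python", "embed_conformers.py", package = "easregio")
  if (p == "") stop("bundled embedding helper not found", call. = FALSE)
  p
}

# Embed `k` conformers of a molecule given as SMILES text or molfile lines.
# Returns a list of SDF record line-vectors (one per conformer), all with
# the same atom ordering (input heavy-atom order, hydrogens appended).
rdkit_embed_sdf <- function(input, type = c("smi", "mol"), k = 1L,
                            seed = 90L) {
  type <- match.arg(type)
  infile <- tempfile(fileext = paste0(".", type))
  outfile <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(infile, outfile)))
  writeLines(input, infile)
  status <- suppressWarnings(
    system2(python_binary(), c(shQuote(embed_helper_path()), shQuote(infile),
                               shQuote(outfile), k, seed),
            stdout = FALSE, stderr = FALSE))
  if (status == 2L) {
    stop("unparseable molecule input for 3D embedding", call. = FALSE)
  }
  if (status != 0L || !file.exists(outfile)) {
    stop("3D embedding failed for species (distance geometry, including ",
         "randomized-coordinates retry)", call. = FALSE)
  }
  lines <- readLines(outfile, warn = FALSE)
  ends <- which(lines == "$$$$")
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_along(ends), function(r) lines[starts[r]:(ends[r] - 1L)])
}
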