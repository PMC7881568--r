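# Thin subprocess layer around the Open Babel CLI (`obabel`).
# Everything that touches SMILES parsing, canonicalization, Kekule bond
# orders and coordinate generation funnels through here, so the external
# contract lives in one file.

ob_binary <- function() {
  bin <- Sys.getenv("EASREGIO_OBABEL", "obabel")
  if (Sys.which(bin) == "") {
    stop("Open Babel executable '", bin, "' not found on PATH. ",
         "Install Open Babel >= 3.0 or set EASREGIO_OBABEL.", call. = FALSE)
  }
  bin
}

#' @keywords internal
ob_run <- function(args) {
  out <- suppressWarnings(system2(ob_binary(), args,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(output = out, status = if (is.null(status)) 0L else status)
}

# obabel reports parse failures on stderr with exit code 0, so success is
# detected by counting converted molecules, not by exit status.
ob_convert_file <- function(infile, informat, outfile, outformat,
                            extra = character()) {
  res <- ob_run(c(paste0("-i", informat), shQuote(infile),
                  paste0("-o", outformat), "-O", shQuote(outfile), extra))
  n <- ob_n_converted(res$output)
  if (res$status != 0L || n < 1L || !file.exists(outfile)) {
    stop("Open Babel conversion failed (", informat, " -> ", outformat, "): ",
         paste(utils::tail(res$output, 3), collapse = " | "), call. = FALSE)
  }
  invisible(n)
}

ob_n_converted <- function(lines) {
  conv <- grep("molecule(s)? converted", lines, value = TRUE)
  if (length(conv) == 0) return(0L)
  as.integer(sub("^([0-9]+) .*$", "\\1", conv[length(conv)]))
}

#' Canonical SMILES via Open Babel
#'
#' Canonicalizes one or more SMILES strings (or molfile texts). Invalid
#' inputs raise an error naming the offending string.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length.
#' @keywords internal
ob_canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  vapply(smiles, function(s) {
    infile <- tempfile(fileext = ".smi")
    on.exit(unlink(infile))
    writeLines(s, infile)
    res <- ob_run(c("-ismi", shQuote(infile), "-ocan"))
    body <- res$output[!grepl("converted|Open Babel|^\\*+$|^==*$|^$", res$output)]
    body <- body[!grepl("Warning|Error|error", body)]
    if (ob_n_converted(res$output) < 1L || length(body) < 1L) {
      stop("unparseable SMILES: '", s, "'", call. = FALSE)
    }
    trimws(sub("\t.*$", "", body[1]))
  }, character(1), USE.NAMES = FALSE)
}

# Canonical SMILES for a molfile text (used for graphs we built ourselves,
# e.g. tautomers and protonated arenium ions).
ob_canonical_from_molfile <- function(moltext) {
  infile <- tempfile(fileext = ".mol")
  on.exit(unlink(infile))
  writeLines(moltext, infile)
  res <- ob_run(c("-imol", shQuote(infile), "-ocan"))
  body <- res$output[!grepl("converted|Open Babel|Warning|^\\*+$|^==*$|^$",
                            res$output)]
  if (ob_n_converted(res$output) < 1L || length(body) < 1L) {
    stop("Open Babel could not canonicalize molfile (valence/sanitization ",
         "failure)", call. = FALSE)
  }
  trimws(sub("\t.*$", "", body[1]))
}

# Molfile text -> 2D layout SDF (hydrogens dropped by obabel; heavy-atom
# order preserved). Used only for depiction.
ob_molfile_gen2d <- function(moltext) {
  infile <- tempfile(fileext = ".mol")
  outfile <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(infile, outfile)))
  writeLines(moltext, infile)
  res <- ob_run(c("-imol", shQuote(infile), "-osdf", "-O", shQuote(outfile),
                  "--gen2d"))
  if (ob_n_converted(res$output) < 1L || !file.exists(outfile)) {
    stop("2D layout failed (Open Babel --gen2d)", call. = FALSE)
  }
  readLines(outfile)
}
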