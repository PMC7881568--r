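# End-to-end orchestration: parse -> enumerate tautomers -> conformer search
# per tautomer -> 15 kcal/mol tautomer filter -> reaction centers ->
# protonated-species conformer search -> proton affinities -> green/red site
# selection -> reactivity class -> JSON report + SVG depiction.

#' Pipeline run configuration
#'
#' @param method refinement backend: "TB1" (GFN1, default), "TB2" (GFN2
#'   fast variant) or "MOCK" (deterministic surrogate; also used for the
#'   pre-screen stage). With "TB1"/"TB2" the pre-screen uses the force field.
#' @param solvent "methanol" (default) or "water".
#' @param seed integer random seed for conformer embedding (default 90).
#' @param green_cut,red_cut site windows in kcal/mol (defaults 1 and 3).
#' @param tautomer_cutoff relative-energy cutoff in kcal/mol (default 15).
#' @param ff_window force-field pre-screen window in kcal/mol (default 3).
#' @param rmsd_threshold Butina threshold in Angstrom (default 0.5).
#' @param band reactivity band bounds in kcal/mol (default c(70, 100)).
#' @param max_tautomers enumeration cap (default 32).
#' @param workers parallel species evaluations (default 1, serial).
#' @param keep_files keep per-species scratch files (default FALSE).
#' @param output_dir where batch reports are written.
#' @param mock_shift additive offset for the MOCK backend (testing).
#' @param verbose emit one log line per pipeline stage per species.
#' @return a `run_config` object.
#' @export
run_config <- function(method = c("TB1", "TB2", "MOCK"),
                       solvent = c("methanol", "water"),
                       seed = 90L, green_cut = 1, red_cut = 3,
                       tautomer_cutoff = 15, ff_window = 3,
                       rmsd_threshold = 0.5, band = c(70, 100),
                       max_tautomers = 32L, workers = 1L,
                       keep_files = FALSE, output_dir = ".",
                       mock_shift = 0, verbose = TRUE) {
  method <- match.arg(method)
  solvent <- match.arg(solvent)
  stopifnot(green_cut > 0, red_cut > 0, green_cut < red_cut,
            tautomer_cutoff > 0, ff_window > 0, rmsd_threshold > 0,
            length(band) == 2, band[1] < band[2])
  structure(list(method = method, solvent = solvent, seed = as.integer(seed),
                 green_cut = green_cut, red_cut = red_cut,
                 tautomer_cutoff = tautomer_cutoff, ff_window = ff_window,
                 rmsd_threshold = rmsd_threshold, band = band,
                 max_tautomers = as.integer(max_tautomers),
                 workers = as.integer(workers), keep_files = keep_files,
                 output_dir = output_dir, mock_shift = mock_shift,
                 verbose = verbose),
            class = "run_config")
}

cfg_backends <- function(cfg) {
  if (cfg$method == "MOCK") {
    ff <- backend_spec("MOCK", cfg$solvent, mock_shift = cfg$mock_shift)
    rf <- ff
  } else {
    ff <- backend_spec("FF", cfg$solvent)
    rf <- backend_spec(cfg$method, cfg$solvent)
  }
  list(ff = ff, refine = rf)
}

stage_log <- function(cfg, species, stage, t0) {
  if (isTRUE(cfg$verbose)) {
    message(sprintf("[%s] %-28s %6.2f s  %s", stage, species,
                    as.numeric(Sys.time()) - t0, format(Sys.time(), "%H:%M:%S")))
  }
}

# Conformer search for one species under a run configuration.
species_search <- function(graph, cfg, backends, species_smiles = NULL) {
  t0 <- as.numeric(Sys.time())
  lbl <- if (is.null(species_smiles)) "species" else species_smiles
  k <- conformer_count(mg_n_rot(graph))
  e <- embed_conformers(graph, k, cfg$seed, species_smiles)
  stage_log(cfg, lbl, "embed", t0)
  e <- ff_prescreen(e, backends$ff, cfg$ff_window)
  stage_log(cfg, lbl, "ff_prescreen", t0)
  e <- cluster_butina(e, cfg$rmsd_threshold)
  stage_log(cfg, lbl, "cluster", t0)
  out <- refine(e, backends$refine)
  stage_log(cfg, lbl, "refine", t0)
  if (isTRUE(cfg$keep_files)) {
    dir <- file.path(cfg$output_dir, "species")
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    traj <- unlist(lapply(out$ensemble$members, function(m) {
      write_xyz(m$structure, energy = m$energy)
    }))
    safe <- gsub("[^A-Za-z0-9]+", "_", lbl)
    writeLines(traj, file.path(dir, paste0(safe, "_refined.xyz")))
  }
  out
}

#' Predict EAS regioselectivity for one molecule
#'
#' Runs the full pipeline on a single SMILES and returns a
#' `prediction_report`.
#'
#' @param smiles input SMILES (neutral molecule).
#' @param id molecule label.
#' @param cfg a `run_config`.
#' @return a `prediction_report`.
#' @export
predict_eas <- function(smiles, id = "mol", cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  backends <- cfg_backends(cfg)
  m <- parse_input(smiles, id)
  taus <- enumerate_tautomers(m, cfg$max_tautomers)

  # conformer search on every tautomer; refined best energy per form
  searched <- list()
  for (t in taus) {
    g <- if (t$is_input) m$graph else tryCatch(mg_regen3d(t$graph),
                                               error = function(e) NULL)
    if (is.null(g)) {
      warning("skipping tautomer ", t$smiles, ": 3D embedding failed",
              call. = FALSE)
      next
    }
    res <- tryCatch(species_search(g, cfg, backends, t$smiles),
                    error = function(e) NULL)
    if (is.null(res) || res$all_sentinel) {
      warning("tautomer ", t$smiles, " excluded: ",
              if (is.null(res)) "conformer search failed"
              else "all conformers tripped the connectivity sentinel",
              call. = FALSE)
      next
    }
    t$best <- res$best
    t$graph <- g
    searched[[length(searched) + 1]] <- t
  }
  if (!length(searched)) stop("no valid tautomer for molecule ", id)

  energies <- vapply(searched, function(t) t$best$energy$value, numeric(1))
  emin <- min(energies)
  for (k in seq_along(searched)) {
    searched[[k]]$rel_energy <- energies[k] - emin
  }
  kept <- filter_tautomers(searched, cfg$tautomer_cutoff)

  tautomer_results <- lapply(kept, function(t) {
    centers <- withCallingHandlers(find_reaction_centers(t),
                                   warning = function(w) invokeRestart("muffleWarning"))
    if (!length(centers)) {
      return(list(tautomer = t, sites = list(), pa_max = NA_real_,
                  reactivity = NA_character_, no_sites = TRUE,
                  not_evaluated = list()))
    }
    pas <- numeric(0)
    eval_centers <- list()
    not_evaluated <- list()
    for (ct in centers) {
      prot <- tryCatch(protonate(t, ct), error = function(e) NULL)
      # the protonated species is rebuilt from its canonical SMILES so its
      # energy depends only on the species identity, never on which member
      # of a symmetry class was protonated (equivalent sites must give
      # identical proton affinities)
      res <- if (is.null(prot)) NULL else {
        tryCatch(species_search(mg_from_smiles(prot$smiles, cfg$seed),
                                cfg, backends, prot$smiles),
                 error = function(e) NULL)
      }
      if (is.null(res) || res$all_sentinel) {
        not_evaluated[[length(not_evaluated) + 1]] <- ct
        next
      }
      pas <- c(pas, proton_affinity(t$best$energy, res$best$energy))
      eval_centers[[length(eval_centers) + 1]] <- ct
    }
    if (!length(eval_centers)) {
      return(list(tautomer = t, sites = list(), pa_max = NA_real_,
                  reactivity = NA_character_, no_sites = TRUE,
                  not_evaluated = not_evaluated))
    }
    sites <- select_sites(pas, cfg$green_cut, cfg$red_cut,
                          centers = eval_centers)
    pa_max <- max(pas)
    list(tautomer = t, sites = sites, pa_max = pa_max,
         reactivity = classify_reactivity(pa_max, cfg$band[1], cfg$band[2]),
         no_sites = FALSE, not_evaluated = not_evaluated)
  })

  build_report(m, tautomer_results, config = config_echo(cfg))
}

config_echo <- function(cfg) {
  list(schema_version = 1L, method = cfg$method, solvent = cfg$solvent,
       dielectric = unname(SOLVENT_DIELECTRIC[cfg$solvent]),
       solvation_model = "GBSA", seed = cfg$seed,
       green_cut = cfg$green_cut, red_cut = cfg$red_cut,
       tautomer_cutoff = cfg$tautomer_cutoff, ff_window = cfg$ff_window,
       rmsd_threshold = cfg$rmsd_threshold, band = cfg$band,
       max_tautomers = cfg$max_tautomers)
}

#' Serialize a prediction report to JSON
#'
#' Deterministic for a deterministic backend and fixed seed (no timestamps).
#' Atom indices appear both 0-based and 1-based.
#'
#' @param r a `prediction_report`.
#' @param path optional output file.
#' @return JSON string (invisibly when `path` is given).
#' @export
report_to_json <- function(r, path = NULL) {
  stopifnot(inherits(r, "prediction_report"))
  rd <- function(x) round(x, 6)
  body <- list(
    schema_version = 1L,
    molecule = list(id = r$molecule$id, smiles = r$molecule$smiles,
                    net_charge = r$molecule$net_charge,
                    n_rot = r$molecule$n_rot),
    reactivity_class = r$reactivity_class,
    config = r$config,
    tautomers = lapply(r$tautomer_results, function(tr) {
      list(smiles = tr$tautomer$smiles,
           rel_energy_kcal_mol = rd(tr$tautomer$rel_energy),
           is_input_form = tr$tautomer$is_input,
           stereo_stripped = tr$tautomer$stereo_stripped,
           reactivity = tr$reactivity,
           no_eas_sites = isTRUE(tr$no_sites),
           pa_max_kcal_mol = if (is.na(tr$pa_max)) NULL else rd(tr$pa_max),
           sites = lapply(tr$sites, function(s) {
             list(atom_index_0based = s$center$atom_index0,
                  atom_index_1based = s$center$atom_index,
                  equivalent_atoms_0based = s$center$equivalent_atoms - 1L,
                  proton_affinity_kcal_mol = rd(s$proton_affinity),
                  deficit_kcal_mol = rd(s$deficit),
                  label = s$label)
           }),
           sites_not_evaluated_0based =
             lapply(tr$not_evaluated, function(ct) ct$atom_index0))
    }))
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Run the pipeline over one or many molecules
#'
#' `input` is a single SMILES string, a `.smi` file (one `SMILES [id]` per
#' line) or a CSV with columns `smiles` and `molecule_id`. Per-molecule
#' failures are isolated and collected in a failures manifest.
#'
#' @param input SMILES string or input file path.
#' @param cfg a `run_config`.
#' @param write_files write JSON report and SVG depiction per molecule into
#'   `cfg$output_dir`.
#' @return list with `reports` (named list of `prediction_report`) and
#'   `failures` (data.frame of id + error message).
#' @export
run_pipeline <- function(input, cfg = run_config(), write_files = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  mols <- pipeline_inputs(input)
  worker <- function(k) {
    tryCatch(list(ok = TRUE,
                  report = predict_eas(mols$smiles[k], mols$id[k], cfg)),
             error = function(e) list(ok = FALSE, id = mols$id[k],
                                      error = conditionMessage(e)))
  }
  results <- if (cfg$workers > 1L) {
    parallel::mclapply(seq_len(nrow(mols)), worker, mc.cores = cfg$workers)
  } else {
    lapply(seq_len(nrow(mols)), worker)
  }
  reports <- list()
  failures <- data.frame(id = character(0), error = character(0))
  for (res in results) {
    if (isTRUE(res$ok)) {
      reports[[res$report$molecule$id]] <- res$report
    } else {
      failures <- rbind(failures, data.frame(id = res$id, error = res$error))
    }
  }
  if (write_files) {
    if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
    for (id in names(reports)) {
      report_to_json(reports[[id]], file.path(cfg$output_dir,
                                              paste0(id, ".json")))
      suppressWarnings(render_depiction(reports[[id]],
                                        file.path(cfg$output_dir,
                                                  paste0(id, ".svg"))))
    }
    if (nrow(failures)) {
      utils::write.csv(failures, file.path(cfg$output_dir, "failures.csv"),
                       row.names = FALSE)
    }
  }
  list(reports = reports, failures = failures)
}

pipeline_inputs <- function(input) {
  if (length(input) == 1 && file.exists(input)) {
    if (grepl("\\.csv$", input, ignore.case = TRUE)) {
      df <- utils::read.csv(input, stringsAsFactors = FALSE)
      if (!"smiles" %in% names(df)) stop("CSV input needs a 'smiles' column")
      ids <- if ("molecule_id" %in% names(df)) df$molecule_id
             else paste0("mol", seq_len(nrow(df)))
      return(data.frame(id = ids, smiles = df$smiles, stringsAsFactors = FALSE))
    }
    lines <- trimws(readLines(input, warn = FALSE))
    lines <- lines[nzchar(lines)]
    toks <- strsplit(lines, "\\s+")
    return(data.frame(
      id = vapply(seq_along(toks), function(k) {
        if (length(toks[[k]]) >= 2) toks[[k]][2] else paste0("mol", k)
      }, character(1)),
      smiles = vapply(toks, `[`, character(1), 1),
      stringsAsFactors = FALSE))
  }
  data.frame(id = "mol", smiles = input, stringsAsFactors = FALSE)
}
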