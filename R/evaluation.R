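# Scoring predictions against experimentally observed reaction sites.
# "Corr": every observed site is green; "Semi": every observed site is green
# or red; "Fail": at least one observed site is not covered. With tautomers
# the criterion is existential: some single tautomer must cover all observed
# sites. Heavy-atom indices are preserved across tautomers by construction,
# so observed sites transfer between forms without remapping.

#' Label a single prediction against observed sites
#'
#' @param observed integer vector of observed reaction-site atom indices
#'   (non-empty; same indexing as `green`/`red`, with symmetry classes
#'   expanded to all member atoms).
#' @param green,red integer vectors of predicted site atoms.
#' @return "Corr", "Semi" or "Fail".
#' @export
label_single <- function(observed, green, red = integer(0)) {
  if (length(observed) == 0) stop("label_single: observed set must be non-empty")
  if (all(observed %in% green)) "Corr"
  else if (all(observed %in% c(green, red))) "Semi"
  else "Fail"
}

#' Label a prediction across tautomers
#'
#' Correct when at least one tautomer predicts every observed site green;
#' semi-correct when at least one tautomer covers every observed site with
#' green or red; failed otherwise. (The semi-correct case extends the
#' published correctness rule, which is stated for green only, by the same
#' existential reading.)
#'
#' @param observed integer vector of observed sites, or a list with one
#'   vector per tautomer when the sites differ between forms.
#' @param per_tautomer list with one element per tautomer, each a list with
#'   components `green` and `red` (integer site vectors).
#' @return "Corr", "Semi" or "Fail".
#' @export
label_with_tautomers <- function(observed, per_tautomer) {
  stopifnot(length(per_tautomer) >= 1)
  obs_for <- function(k) if (is.list(observed)) observed[[k]] else observed
  labels <- vapply(seq_along(per_tautomer), function(k) {
    label_single(obs_for(k), per_tautomer[[k]]$green, per_tautomer[[k]]$red)
  }, character(1))
  if (any(labels == "Corr")) "Corr"
  else if (any(labels == "Semi")) "Semi"
  else "Fail"
}

#' Summarize evaluation labels
#'
#' @param labels character vector of "Corr"/"Semi"/"Fail".
#' @return list with counts `n_corr`, `n_semi`, `n_fail`, `n_total` and
#'   percentage rates (one decimal): `corr_rate`, `semi_rate`, `fail_rate`,
#'   `success_rate` (== corr rate).
#' @export
summarize_labels <- function(labels) {
  stopifnot(length(labels) >= 1, all(labels %in% c("Corr", "Semi", "Fail")))
  n <- length(labels)
  n_corr <- sum(labels == "Corr")
  n_semi <- sum(labels == "Semi")
  n_fail <- sum(labels == "Fail")
  pct <- function(k) round(100 * k / n, 1)
  list(n_corr = n_corr, n_semi = n_semi, n_fail = n_fail, n_total = n,
       corr_rate = pct(n_corr), semi_rate = pct(n_semi),
       fail_rate = pct(n_fail), success_rate = pct(n_corr))
}

#' Read an observed-sites CSV
#'
#' Expected columns: `molecule_id`, `smiles`, `observed_sites` (0-based atom
#' indices in the SMILES atom order, separated by semicolons).
#'
#' @param path CSV file path.
#' @return list of records with `molecule_id`, `smiles`, `observed_sites`
#'   (1-based internal indices).
#' @export
read_observed_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "smiles", "observed_sites")
  if (!all(need %in% names(df))) {
    stop("observed-sites CSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(k) {
    idx0 <- as.integer(strsplit(as.character(df$observed_sites[k]), ";")[[1]])
    if (!length(idx0) || anyNA(idx0)) {
      stop("empty or malformed observed_sites for ", df$molecule_id[k])
    }
    list(molecule_id = df$molecule_id[k], smiles = df$smiles[k],
         observed_sites = idx0 + 1L)
  })
}

# green/red site sets of one tautomer result, expanded to all symmetry-class
# members (1-based indices).
expand_sites <- function(tr) {
  green <- integer(0); red <- integer(0)
  for (s in tr$sites) {
    if (s$label == "green") green <- c(green, s$center$equivalent_atoms)
    else if (s$label == "red") red <- c(red, s$center$equivalent_atoms)
  }
  list(green = sort(unique(green)), red = sort(unique(red)))
}

#' Evaluate prediction reports against observed sites
#'
#' @param reports list of `prediction_report` objects.
#' @param observed list of records as returned by [read_observed_csv()],
#'   matched to reports by `molecule_id`.
#' @return list with `results` (data.frame: molecule_id, label,
#'   label_single_tautomer) and `summary` from [summarize_labels()].
#' @export
evaluate_predictions <- function(reports, observed) {
  ids <- vapply(reports, function(r) r$molecule$id, character(1))
  rows <- lapply(observed, function(rec) {
    r <- reports[[match(rec$molecule_id, ids)]]
    if (is.na(match(rec$molecule_id, ids))) {
      stop("no prediction report for molecule ", rec$molecule_id)
    }
    per_tau <- lapply(r$tautomer_results, expand_sites)
    lab <- label_with_tautomers(rec$observed_sites, per_tau)
    first <- expand_sites(r$tautomer_results[[1]])
    lab1 <- label_single(rec$observed_sites, first$green, first$red)
    data.frame(molecule_id = rec$molecule_id, label = lab,
               label_single_tautomer = lab1, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  list(results = results, summary = summarize_labels(results$label))
}

#' Format an evaluation summary block
#'
#' @param s summary list from [summarize_labels()].
#' @return character vector of lines (Corr/Semi/Fail counts and rates).
#' @export
format_summary <- function(s) {
  c(sprintf("Corr/Semi/Fail  %d/%d/%d", s$n_corr, s$n_semi, s$n_fail),
    sprintf("Rates           %.1f%%/%.1f%%/%.1f%%",
            s$corr_rate, s$semi_rate, s$fail_rate),
    sprintf("Success rate    %.1f%% (n = %d)", s$success_rate, s$n_total))
}
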