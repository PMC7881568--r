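# 2D depiction of a prediction report: one panel per tautomer, heavy-atom
# skeleton from an Open Babel 2D layout, green/red circles on all members of
# predicted site classes, caption with relative energy and reactivity class.

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  gsub("<", "&lt;", x, fixed = TRUE)
}

# One panel: returns list(svg = character vector of elements, width, height)
depict_tautomer_panel <- function(tr, x_off = 0, scale = 30) {
  mg <- tr$tautomer$graph
  lay <- tryCatch(mg_from_sdf_lines(ob_molfile_gen2d(mg_to_molfile(mg))),
                  error = function(e) NULL)
  if (is.null(lay)) return(NULL)
  heavy_orig <- mg_heavy(mg)           # layout keeps heavy atoms, same order
  xy <- lay$coords[, 1:2, drop = FALSE]
  xy[, 2] <- -xy[, 2]
  xy <- sweep(xy, 2, apply(xy, 2, min))
  xy <- xy * scale + 30
  w <- max(xy[, 1]) + 30
  h <- max(xy[, 2]) + 55
  sites <- expand_sites(tr)
  pos <- function(a) match(a, heavy_orig)   # original index -> layout row
  el <- character(0)
  circ <- function(atoms, colour) {
    for (a in atoms) {
      p <- pos(a)
      if (is.na(p)) next
      el <<- c(el, sprintf(
        '<circle cx="%.1f" cy="%.1f" r="9" fill="%s" fill-opacity="0.45"/>',
        x_off + xy[p, 1], xy[p, 2], colour))
    }
  }
  circ(sites$green, "#2ca02c")
  circ(sites$red, "#d62728")
  for (k in seq_len(nrow(lay$bonds))) {
    i <- lay$bonds$i[k]; j <- lay$bonds$j[k]
    seg <- function(dx, dy) sprintf(
      '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black" stroke-width="1.2"/>',
      x_off + xy[i, 1] + dx, xy[i, 2] + dy, x_off + xy[j, 1] + dx, xy[j, 2] + dy)
    el <- c(el, seg(0, 0))
    if (lay$bonds$order[k] >= 2) {
      v <- xy[j, ] - xy[i, ]
      nrm <- c(-v[2], v[1]) / max(sqrt(sum(v^2)), 1e-6) * 2.5
      el <- c(el, seg(nrm[1], nrm[2]))
    }
  }
  for (p in seq_along(lay$elements)) {
    if (lay$elements[p] == "C") next
    el <- c(el, sprintf(
      '<text x="%.1f" y="%.1f" font-size="11" text-anchor="middle" fill="#1f4e9c">%s</text>',
      x_off + xy[p, 1], xy[p, 2] + 4, svg_escape(lay$elements[p])))
  }
  caption <- sprintf("%.1f kcal/mol  [%s]", tr$tautomer$rel_energy,
                     tr$reactivity)
  el <- c(el, sprintf(
    '<text x="%.1f" y="%.1f" font-size="11" text-anchor="middle">%s</text>',
    x_off + w / 2, h - 12, svg_escape(caption)))
  list(svg = el, width = w, height = h)
}

#' Render a prediction report as an SVG document
#'
#' One 2D panel per tautomer; green circles mark all atoms of site classes
#' predicted within 1 kcal/mol of the highest proton affinity, red circles
#' those within 3 kcal/mol. Captions carry the tautomer's relative energy
#' and reactivity class. On depiction failure the panel is skipped with a
#' warning (the report itself is unaffected).
#'
#' @param r a `prediction_report`.
#' @param path optional output file; when given, the SVG is written there.
#' @return character vector of SVG lines (invisibly when `path` is given).
#' @export
render_depiction <- function(r, path = NULL) {
  stopifnot(inherits(r, "prediction_report"))
  panels <- list()
  x_off <- 0
  for (tr in r$tautomer_results) {
    p <- tryCatch(depict_tautomer_panel(tr, x_off),
                  error = function(e) NULL)
    if (is.null(p)) {
      warning("depiction failed for tautomer ", tr$tautomer$smiles,
              "; panel omitted", call. = FALSE)
      next
    }
    panels[[length(panels) + 1]] <- p
    x_off <- x_off + p$width + 10
  }
  if (!length(panels)) {
    warning("depiction failed for every tautomer of ", r$molecule$id,
            call. = FALSE)
    return(invisible(character(0)))
  }
  total_w <- x_off
  total_h <- max(vapply(panels, `[[`, numeric(1), "height"))
  doc <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f">',
    total_w, total_h),
    sprintf('<title>%s</title>', svg_escape(r$molecule$id)),
    unlist(lapply(panels, `[[`, "svg")),
    "</svg>")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
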