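#' Textual top-map
#'
#' Renders the grid as text, one line per y row (y = 1 first), cells
#' separated by `|`.  A cell lists the IDs (or class labels) of all its
#' occupants, comma-separated in a stable (dataset, id) order; empty cells
#' show `.`.
#'
#' @param topmap a [build_topmap()] result.
#' @param mode `"ids"` or `"classes"`.
#' @return character vector of lines.
#' @export
render_topmap_text <- function(topmap, mode = c("ids", "classes")) {
  mode <- match.arg(mode)
  g <- topmap$geometry
  a <- topmap$assignments
  a <- a[order(a$dataset, a$id), , drop = FALSE]
  lab <- if (mode == "ids") a$id else a$class
  cell <- matrix(".", g$nx, g$ny)
  for (i in seq_len(nrow(a))) {
    cur <- cell[a$x[i], a$y[i]]
    cell[a$x[i], a$y[i]] <- if (cur == ".") lab[i]
                            else paste(cur, lab[i], sep = ",")
  }
  width <- max(nchar(cell))
  vapply(seq_len(g$ny), function(y) {
    paste(formatC(cell[, y], width = width, flag = "-"), collapse = "|")
  }, character(1))
}

#' Prediction report text
#'
#' One line per object: ID, excited neuron, experimental value(s),
#' prediction(s) and Euclidean distance to the neuron, plus the
#' applicability-domain verdict when it has been set, and a footer with RMSE
#' and the correlation coefficient.  Numbers print with 2 decimals; the
#' machine-readable values live in the prediction's `table`.
#'
#' @param prediction a `cpann_prediction`.
#' @return character vector of lines.
#' @export
render_prediction_report <- function(prediction) {
  t <- prediction$table
  m <- length(prediction$target_names)
  fmt2 <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", v))
  lines <- vapply(seq_len(nrow(t)), function(i) {
    parts <- c(sprintf("ID=%s", t$id[i]),
               sprintf("neuron=(%d,%d)", t$x[i], t$y[i]))
    for (j in seq_len(m)) {
      parts <- c(parts,
                 sprintf("exp.%d=%s", j, fmt2(t[[paste0("exp.", j)]][i])),
                 sprintf("pred.%d=%s", j, fmt2(t[[paste0("pred.", j)]][i])))
    }
    parts <- c(parts, sprintf("dist=%s", fmt2(t$distance[i])))
    if (!is.na(t$in_domain[i]))
      parts <- c(parts, sprintf("AD=%s",
                                if (t$in_domain[i]) "in" else "out"))
    paste(parts, collapse = "\t")
  }, character(1))
  s <- prediction$summary
  footer <- vapply(seq_len(nrow(s)), function(j) {
    sprintf("target %s: n=%d RMSE=%s R=%s", s$target[j], s$n[j],
            fmt2(s$rmse[j]), fmt2(s$r[j]))
  }, character(1))
  c(sprintf("Predictions for dataset '%s'", prediction$dataset),
    lines, footer)
}

#' Save a numeric grid as a raster image
#'
#' Linear min-max colour scale with a fixed palette and a colour bar;
#' non-finite cells render in a designated "undefined" colour.  The output
#' is a deterministic function of the input grid.
#'
#' @param grid numeric matrix (`nx x ny`), e.g. from [level_plot()],
#'   [euclidean_distance_map()] or [tanimoto_map()].
#' @param path output PNG file.
#' @param palette colour vector (low to high).
#' @param undefined_color colour for non-finite cells.
#' @param title plot title.
#' @export
export_grid_image <- function(grid, path,
                              palette = grDevices::hcl.colors(64, "viridis"),
                              undefined_color = "grey60", title = "") {
  grDevices::png(path, width = 480, height = 420)
  on.exit(grDevices::dev.off())
  finite <- is.finite(grid)
  rng <- if (any(finite)) range(grid[finite]) else c(0, 1)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)  # constant grid
  graphics::layout(matrix(1:2, 1), widths = c(4, 1))
  graphics::par(mar = c(4, 4, 3, 1))
  plotted <- grid
  plotted[!finite] <- NA
  graphics::image(seq_len(nrow(grid)), seq_len(ncol(grid)), plotted,
                  zlim = rng, col = palette, xlab = "x", ylab = "y",
                  main = title)
  if (!all(finite)) {
    bad <- which(!finite, arr.ind = TRUE)
    graphics::rect(bad[, 1] - 0.5, bad[, 2] - 0.5,
                   bad[, 1] + 0.5, bad[, 2] + 0.5,
                   col = undefined_color, border = NA)
  }
  graphics::par(mar = c(4, 1, 3, 3))
  bar <- matrix(seq(rng[1], rng[2], length.out = length(palette)), nrow = 1)
  graphics::image(1, seq(rng[1], rng[2], length.out = length(palette)), bar,
                  col = palette, xlab = "", ylab = "", xaxt = "n")
  invisible(path)
}

smiles_depictable <- function() {
  requireNamespace("ChemmineR", quietly = TRUE)
}

depict_smiles <- function(smiles, ids, path) {
  ok <- tryCatch({
    sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, ids))
    grDevices::png(path, width = 360, height = 360)
    on.exit(grDevices::dev.off())
    ChemmineR::plot(sdf, print = FALSE)
    TRUE
  }, error = function(e) FALSE)
  ok
}

neuron_id_image <- function(ids, classes, path) {
  grDevices::png(path, width = 360, height = 360)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  lab <- if (length(ids)) paste0(ids, " (", classes, ")") else "(empty)"
  graphics::text(0.5, rev(seq_along(lab)) / (length(lab) + 1), lab, cex = 1.2)
  invisible(path)
}

#' Export the top-map as a browsable HTML page
#'
#' Writes `graphview.html` plus one image per occupied neuron under
#' `resultingimages/`.  When a SMILES map is supplied and the ChemmineR
#' stack is available, neuron images show the 2D structures of the
#' occupants; otherwise (or when a SMILES cannot be depicted) the cell image
#' lists the occupant IDs, and a warning names the fallback.  Output is a
#' deterministic function of the inputs: cells render in stable (dataset,
#' id) order.
#'
#' @param topmap a [build_topmap()] result.
#' @param out_dir output directory (created if missing).
#' @param smiles optional `cpann_smiles_map` from [read_smiles_map()].
#' @param depict `"auto"` (depict when possible) or `"never"`.
#' @return path of the written `graphview.html`, invisibly.
#' @export
export_html_map <- function(topmap, out_dir, smiles = NULL,
                            depict = c("auto", "never")) {
  depict <- match.arg(depict)
  g <- topmap$geometry
  a <- topmap$assignments
  a <- a[order(a$dataset, a$id), , drop = FALSE]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out_dir, "resultingimages")
  dir.create(img_dir, showWarnings = FALSE)
  can_depict <- depict == "auto" && !is.null(smiles) && smiles_depictable()

  html <- c("<!DOCTYPE html>", "<html><head><title>CPANN top-map</title>",
            "<style>td{border:1px solid #999;min-width:60px;",
            "text-align:center;vertical-align:top;font-family:monospace}",
            "</style></head><body>",
            sprintf("<h1>CPANN top-map (%dx%d)</h1>", g$nx, g$ny),
            "<table>")
  for (y in seq_len(g$ny)) {
    row <- "<tr>"
    for (x in seq_len(g$nx)) {
      occ <- a[a$x == x & a$y == y, , drop = FALSE]
      if (!nrow(occ)) {
        row <- paste0(row, "<td>&middot;</td>")
        next
      }
      img <- sprintf("neuron_%d_%d.png", x, y)
      drawn <- FALSE
      if (can_depict) {
        smi <- vapply(occ$id, function(i) {
          s <- smiles_for(smiles, i)
          if (is.null(s)) NA_character_ else s
        }, character(1))
        if (!anyNA(smi)) {
          drawn <- depict_smiles(unname(smi), occ$id,
                                 file.path(img_dir, img))
          if (!drawn)
            warning("could not depict SMILES for neuron (", x, ",", y,
                    "); falling back to ID labels", call. = FALSE)
        }
      }
      if (!drawn)
        neuron_id_image(occ$id, occ$class, file.path(img_dir, img))
      row <- paste0(row, sprintf(
        "<td><a href=\"resultingimages/%s\"><img src=\"resultingimages/%s\" width=\"90\"/></a><br/>%s</td>",
        img, img, paste(occ$id, collapse = ", ")))
    }
    html <- c(html, paste0(row, "</tr>"))
  }
  html <- c(html, "</table></body></html>")
  out <- file.path(out_dir, "graphview.html")
  writeLines(html, out)
  invisible(out)
}
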