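#' StDev*Coeff contribution map
#'
#' The classical field-effect summary: for every active descriptor column,
#' the standard deviation of the column over the training molecules
#' multiplied by the column's PLS regression coefficient, both taken in the
#' model's (block-scaled) descriptor space so field kinds are comparable.
#' Positive contributions mark lattice regions where more field value raises
#' predicted activity; negative ones where it lowers it.
#'
#' @param model a `pls_model` fitted on a `descriptor_matrix`.
#' @param dm the `descriptor_matrix` the model was trained on.
#' @return data.frame with one row per active column: `field_kind`,
#'   `grid_index`, lattice coordinates `x,y,z` and `contribution`.
#' @export
stdev_coeff <- function(model, dm) {
  stopifnot(inherits(model, "pls_model"), inherits(dm, "descriptor_matrix"))
  if (is.null(model$dm_meta) || !identical(model$dm_meta$mask, dm$mask)) {
    stop("column-mask mismatch between model and descriptor matrix")
  }
  meta <- dm$col_meta[dm$mask, , drop = FALSE]
  pts <- grid_points(dm$grid)
  gi <- meta$grid_index + 1L
  data.frame(field_kind = meta$field_kind,
             grid_index = meta$grid_index,
             x = pts[gi, 1], y = pts[gi, 2], z = pts[gi, 3],
             contribution = model$col_sd_scaled * model$coef_scaled,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Extract favored/disfavored contour point sets
#'
#' Percentile thresholding of the signed contribution distribution, per field
#' kind: favored points carry a strictly positive contribution at or above
#' the `favored_pct` percentile, disfavored points a strictly negative one at
#' or below the `disfavored_pct` percentile (type-7 quantiles). The two sets
#' are disjoint by construction; an all-zero map yields empty sets.
#'
#' @param contrib contribution map from [stdev_coeff()].
#' @param favored_pct percentile defining the favored level (default 80).
#' @param disfavored_pct percentile defining the disfavored level (default 20).
#' @return object of class `contour_set`: a list per field kind with the
#'   `favored` and `disfavored` point subsets and the levels used.
#' @export
extract_contours <- function(contrib, favored_pct = 80, disfavored_pct = 20) {
  stopifnot(nrow(contrib) > 0, favored_pct > disfavored_pct)
  out <- lapply(split(contrib, contrib$field_kind), function(cc) {
    v <- cc$contribution
    lev_f <- stats::quantile(v, favored_pct / 100, names = FALSE)
    lev_d <- stats::quantile(v, disfavored_pct / 100, names = FALSE)
    list(favored_level = lev_f, disfavored_level = lev_d,
         favored = cc[v >= lev_f & v > 0, , drop = FALSE],
         disfavored = cc[v <= lev_d & v < 0, , drop = FALSE])
  })
  structure(out, class = "contour_set",
            favored_pct = favored_pct, disfavored_pct = disfavored_pct)
}

#' @export
print.contour_set <- function(x, ...) {
  cat("<contour_set>\n")
  for (k in names(x)) {
    cat(sprintf("  %-22s favored %3d pts (level %+.4f), disfavored %3d pts (level %+.4f)\n",
                k, nrow(x[[k]]$favored), x[[k]]$favored_level,
                nrow(x[[k]]$disfavored), x[[k]]$disfavored_level))
  }
  invisible(x)
}

#' Write contour points as PDB pseudo-atoms
#'
#' Favored points become `FAV` residues, disfavored `DIS`, one HETATM per
#' lattice point with the contribution in the B-factor column — loadable in
#' any molecular viewer on top of the ligands.
#'
#' @param contours a `contour_set`.
#' @param path output PDB file.
#' @export
write_contour_pdb <- function(contours, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  serial <- 0L
  for (k in names(contours)) {
    for (cls in c("favored", "disfavored")) {
      pts <- contours[[k]][[cls]]
      resn <- if (cls == "favored") "FAV" else "DIS"
      if (nrow(pts) == 0) next
      for (i in seq_len(nrow(pts))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "HETATM%5d  C   %3s A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
          serial, resn, serial %% 10000L,
          pts$x[i], pts$y[i], pts$z[i],
          max(min(pts$contribution[i], 99.99), -9.99)), con, sep = "\n")
      }
    }
  }
  writeLines("END", con, sep = "\n")
  invisible(path)
}
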