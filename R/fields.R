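#' Probe and truncation settings for field computation
#'
#' Defaults follow the classical field-based 3D-QSAR setup: an sp3-carbon-like
#' probe of van der Waals radius 1.52 Angstrom carrying +1 e, a 30 kcal/mol
#' energy truncation for the Lennard-Jones/Coulomb fields, a
#' distance-dependent dielectric eps(r) = r, and a Gaussian attenuation factor
#' alpha = 0.3 (per Angstrom squared) for the similarity fields. The probe
#' well depth is not defined by the method description and is frozen at a
#' GAFF-like sp3-carbon value.
#'
#' @param probe_charge probe charge, elementary units.
#' @param probe_radius probe van der Waals radius, Angstrom.
#' @param probe_well_depth probe Lennard-Jones well depth, kcal/mol.
#' @param energy_cutoff truncation bound for CoMFA energies, kcal/mol.
#' @param attenuation Gaussian attenuation alpha, 1/Angstrom^2.
#' @param sigma_min_comfa column-filter minimum standard deviation, kcal/mol.
#' @param sigma_min_comsia column-filter minimum standard deviation,
#'   similarity units.
#' @return object of class `field_settings`.
#' @export
field_settings <- function(probe_charge = 1.0,
                           probe_radius = 1.52,
                           probe_well_depth = 0.086,
                           energy_cutoff = 30.0,
                           attenuation = 0.3,
                           sigma_min_comfa = 2.0,
                           sigma_min_comsia = 0.05) {
  stopifnot(energy_cutoff > 0, attenuation > 0, probe_radius > 0,
            probe_well_depth > 0)
  structure(list(probe_charge = probe_charge,
                 probe_radius = probe_radius,
                 probe_well_depth = probe_well_depth,
                 energy_cutoff = energy_cutoff,
                 attenuation = attenuation,
                 dielectric_mode = "distance-dependent",
                 coulomb_k = 332.0636,
                 sigma_min_comfa = sigma_min_comfa,
                 sigma_min_comsia = sigma_min_comsia),
            class = "field_settings")
}

.comfa_kinds <- c("comfa_steric", "comfa_electrostatic")
.comsia_kinds <- c(S = "comsia_S", E = "comsia_E", H = "comsia_H",
                   D = "comsia_D", A = "comsia_A")

#' @rdname field_kinds
#' @export
all_field_kinds <- function() unname(c(.comfa_kinds, .comsia_kinds))

#' Field kind vocabulary
#'
#' `comfa_steric`/`comfa_electrostatic` are probe interaction energies
#' (kcal/mol); `comsia_S/E/H/D/A` are Gaussian similarity indices for the
#' steric, electrostatic, hydrophobic, hydrogen-bond donor and acceptor
#' properties. The single-letter shorthand `S, E, H, D, A` maps onto the
#' CoMSIA kinds.
#'
#' @param x character vector of kinds or single letters.
#' @return canonical field-kind names.
#' @name field_kinds
#' @export
normalize_field_kinds <- function(x) {
  out <- ifelse(x %in% names(.comsia_kinds), .comsia_kinds[x], x)
  bad <- setdiff(out, all_field_kinds())
  if (length(bad)) stop("unknown field kind(s): ", paste(bad, collapse = ", "))
  unname(out)
}

# squared distances atoms x points
.dist2 <- function(xyz, pts) {
  outer(rowSums(xyz^2), rowSums(pts^2), "+") - 2 * xyz %*% t(pts)
}

#' CoMFA probe fields for one molecule
#'
#' At every lattice point q the steric field is the Lennard-Jones energy of
#' the probe, `sum_i eps*_i [ (R*_i/r_iq)^12 - 2 (R*_i/r_iq)^6 ]` with
#' `R*_i = r_vdw,i + probe_radius` and `eps*_i = sqrt(eps_i * eps_probe)`, and
#' the electrostatic field is the Coulomb energy with distance-dependent
#' dielectric, `332.0636 * sum_i q_i * q_probe / r_iq^2`. Both are truncated
#' to `[-cutoff, +cutoff]`. Points whose untruncated steric energy exceeds
#' +cutoff are flagged sterically excluded; [build_descriptor_matrix()] later
#' replaces their electrostatic values by the column mean over non-excluded
#' molecules. A probe exactly on an atom center counts as inside the atom
#' (steric = +cutoff).
#'
#' @param mol parameterized `aligned_molecule`.
#' @param grid a `field_grid` in the same frame (caller contract).
#' @param settings a `field_settings`.
#' @return list with numeric vectors `steric`, `electrostatic` and logical
#'   `excluded`, one entry per lattice point.
#' @export
comfa_fields <- function(mol, grid, settings = field_settings()) {
  if (!isTRUE(mol$params_assigned)) {
    stop("atom parameters not assigned; call assign_atom_params() first")
  }
  at <- mol$atoms
  pts <- grid_points(grid)
  d2 <- .dist2(as.matrix(at[, c("x", "y", "z")]), pts)
  d2[d2 < 1e-12] <- 1e-12  # probe on an atom center: huge repulsion -> cap
  rstar <- at$vdw_radius + settings$probe_radius
  epsstar <- sqrt(at$lj_epsilon * settings$probe_well_depth)
  s6 <- (rstar^2 / t(d2))^3           # points x atoms: (R*/r)^6
  steric_raw <- colSums(t(s6^2 - 2 * s6) * epsstar)
  excluded <- steric_raw > settings$energy_cutoff
  cutoff <- settings$energy_cutoff
  steric <- pmin(pmax(steric_raw, -cutoff), cutoff)
  elec_raw <- settings$coulomb_k * settings$probe_charge *
    colSums(at$charge / d2)           # eps(r) = r  =>  1/(r * r) = 1/r^2
  electrostatic <- pmin(pmax(elec_raw, -cutoff), cutoff)
  list(steric = steric, electrostatic = electrostatic, excluded = excluded)
}

#' CoMSIA similarity fields for one molecule
#'
#' Gaussian-attenuated similarity index at every lattice point:
#' `A_k(q) = -sum_i w_probe,k * w_ik * exp(-alpha * r_iq^2)` with probe weight
#' +1 for every property (+1 e for the electrostatic kind). The per-atom
#' weight `w_ik` is the steric weight (r_vdw^3) for S, the partial charge for
#' E, the hydrophobicity increment for H, and the binary donor/acceptor
#' indicator for D/A. No distance cutoff is applied; the Gaussian decays
#' smoothly.
#'
#' @param mol parameterized `aligned_molecule`.
#' @param grid a `field_grid`.
#' @param settings a `field_settings`.
#' @param kinds subset of `c("S","E","H","D","A")` (or canonical names).
#' @return named list of numeric vectors, one per requested kind, in
#'   canonical-kind order.
#' @export
comsia_fields <- function(mol, grid, settings = field_settings(),
                          kinds = c("S", "E", "H", "D", "A")) {
  if (!isTRUE(mol$params_assigned)) {
    stop("atom parameters not assigned; call assign_atom_params() first")
  }
  kinds <- normalize_field_kinds(kinds)
  kinds <- intersect(unname(.comsia_kinds), kinds)  # canonical order
  .comsia_at_points(mol, grid_points(grid), settings, kinds)
}

# similarity indices at arbitrary probe positions (pts: n x 3 matrix);
# shared by the lattice sampler and the synthetic generator's planted signal
.comsia_at_points <- function(mol, pts, settings, kinds) {
  at <- mol$atoms
  g <- exp(-settings$attenuation *
             .dist2(as.matrix(at[, c("x", "y", "z")]), pts))  # atoms x points
  weights <- list(
    comsia_S = at$steric_weight,
    comsia_E = at$charge * settings$probe_charge,
    comsia_H = at$hydrophobicity,
    comsia_D = as.numeric(at$is_donor),
    comsia_A = as.numeric(at$is_acceptor)
  )
  out <- lapply(kinds, function(k) {
    w <- weights[[k]]
    if (is.null(w) || anyNA(w)) stop("missing atom parameters for field ", k)
    -colSums(g * w)
  })
  names(out) <- kinds
  out
}

#' Assemble the molecules-by-grid-points descriptor matrix
#'
#' Computes the requested field blocks for every molecule over one shared
#' grid, then applies the standard preprocessing in order: (1) electrostatic
#' entries at sterically excluded points are replaced by the column mean over
#' the non-excluded molecules (the column is dropped if every molecule is
#' excluded there); (2) columns whose standard deviation over the molecules is
#' below the kind's minimum-sigma threshold are dropped. The full column
#' metadata and the surviving-column mask are retained so contour maps can be
#' projected back onto the lattice.
#'
#' @param mols list of parameterized `aligned_molecule` sharing the grid frame.
#' @param grid a `field_grid`.
#' @param field_kinds kinds to include (canonical names or S/E/H/D/A letters).
#' @param settings a `field_settings`.
#' @return object of class `descriptor_matrix` with elements `X` (active
#'   columns only), `col_meta` (kind + 0-based grid index for every raw
#'   column), `mask` (logical over raw columns), `y` (pIC50, `NA` allowed),
#'   `ids`, `grid`, `settings`, `field_kinds`.
#' @export
build_descriptor_matrix <- function(mols, grid, field_kinds,
                                    settings = field_settings()) {
  stopifnot(length(mols) >= 1)
  field_kinds <- normalize_field_kinds(field_kinds)
  rb <- .raw_blocks(mols, grid, field_kinds, settings)
  blocks <- rb$blocks
  excl <- rb$excluded

  # (1) impute sterically excluded electrostatic entries with the column mean
  #     of non-excluded molecules; remember the means so rows for new
  #     molecules can be imputed against the training columns
  elec_impute <- NULL
  if ("comfa_electrostatic" %in% field_kinds) {
    E <- blocks[["comfa_electrostatic"]]
    elec_impute <- colMeans(E)
    if (any(excl)) {
      for (j in which(colSums(excl) > 0)) {
        ok <- !excl[, j]
        if (any(ok)) {
          elec_impute[j] <- mean(E[ok, j])
          E[!ok, j] <- elec_impute[j]
        } else {
          E[, j] <- NA_real_  # unusable column; dropped by the sigma filter
          elec_impute[j] <- NA_real_
        }
      }
      blocks[["comfa_electrostatic"]] <- E
    }
  }

  X_full <- do.call(cbind, blocks[field_kinds])
  npt <- n_grid_points(grid)
  col_meta <- data.frame(
    field_kind = rep(field_kinds, each = npt),
    grid_index = rep.int(seq_len(npt) - 1L, length(field_kinds)),
    stringsAsFactors = FALSE
  )

  # (2) minimum-sigma column filter, per field kind
  sds <- apply(X_full, 2, stats::sd)
  sigma_min <- ifelse(col_meta$field_kind %in% .comfa_kinds,
                      settings$sigma_min_comfa, settings$sigma_min_comsia)
  mask <- !is.na(sds) & sds >= sigma_min
  if (!any(mask)) {
    stop("degenerate descriptor matrix: every column fell below the ",
         "minimum-sigma filter")
  }

  y <- vapply(mols, function(m) m$pic50, numeric(1))
  structure(list(X = X_full[, mask, drop = FALSE],
                 col_meta = col_meta,
                 mask = mask,
                 y = y,
                 ids = vapply(mols, function(m) m$id, character(1)),
                 grid = grid,
                 settings = settings,
                 field_kinds = field_kinds,
                 elec_impute = elec_impute),
            class = "descriptor_matrix")
}

# raw (unfiltered, unimputed) field blocks for a molecule list on one grid
.raw_blocks <- function(mols, grid, field_kinds, settings) {
  n <- length(mols)
  npt <- n_grid_points(grid)
  need_comfa <- any(field_kinds %in% .comfa_kinds)
  comsia_req <- intersect(unname(.comsia_kinds), field_kinds)
  blocks <- stats::setNames(
    lapply(field_kinds, function(k) matrix(0.0, n, npt)), field_kinds)
  excl <- matrix(FALSE, n, npt)
  for (i in seq_len(n)) {
    if (need_comfa) {
      cf <- comfa_fields(mols[[i]], grid, settings)
      if ("comfa_steric" %in% field_kinds) {
        blocks[["comfa_steric"]][i, ] <- cf$steric
      }
      if ("comfa_electrostatic" %in% field_kinds) {
        blocks[["comfa_electrostatic"]][i, ] <- cf$electrostatic
      }
      excl[i, ] <- cf$excluded
    }
    if (length(comsia_req)) {
      cs <- comsia_fields(mols[[i]], grid, settings, kinds = comsia_req)
      for (k in comsia_req) blocks[[k]][i, ] <- cs[[k]]
    }
  }
  list(blocks = blocks, excluded = excl)
}

#' Descriptor rows for new molecules under a training template
#'
#' Computes field blocks for new molecules on the template's grid and field
#' kinds, imputes sterically excluded electrostatic entries with the
#' *training* column means, and applies the training column mask — the column
#' filter is never recomputed, so new compounds are described in exactly the
#' training model's descriptor space.
#'
#' @param template a `descriptor_matrix` built from the training set.
#' @param mols list of parameterized `aligned_molecule` in the same frame.
#' @return a `descriptor_matrix` over the template's active columns.
#' @export
apply_matrix_template <- function(template, mols) {
  stopifnot(inherits(template, "descriptor_matrix"))
  rb <- .raw_blocks(mols, template$grid, template$field_kinds,
                    template$settings)
  blocks <- rb$blocks
  if ("comfa_electrostatic" %in% template$field_kinds && any(rb$excluded)) {
    E <- blocks[["comfa_electrostatic"]]
    for (i in seq_len(nrow(E))) {
      bad <- rb$excluded[i, ] & !is.na(template$elec_impute)
      E[i, bad] <- template$elec_impute[bad]
    }
    blocks[["comfa_electrostatic"]] <- E
  }
  X_full <- do.call(cbind, blocks[template$field_kinds])
  out <- template
  out$X <- X_full[, template$mask, drop = FALSE]
  out$y <- vapply(mols, function(m) m$pic50, numeric(1))
  out$ids <- vapply(mols, function(m) m$id, character(1))
  out
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d molecules x %d active columns (of %d; fields: %s)\n",
              nrow(x$X), ncol(x$X), length(x$mask),
              paste(x$field_kinds, collapse = ", ")))
  invisible(x)
}

#' Export one molecule's field block as an OpenDX scalar grid
#'
#' Writes the classic OpenDX "regularpositions / regularconnections" scalar
#' format understood by PyMOL, VMD and Chimera, for contour visualisation.
#' Values are reordered from the package's x-fastest convention to the
#' z-fastest order OpenDX expects.
#'
#' @param values numeric vector, one value per lattice point (x-fastest).
#' @param grid the `field_grid` the values live on.
#' @param path output `.dx` file.
#' @export
write_dx <- function(values, grid, path) {
  stopifnot(length(values) == n_grid_points(grid))
  npt <- grid$npoints
  # x-fastest -> z-fastest
  arr <- array(values, dim = npt)
  vz <- as.vector(aperm(arr, c(3, 2, 1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con, sep = "\n")
  w("object 1 class gridpositions counts %d %d %d", npt[1], npt[2], npt[3])
  w("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3])
  w("delta %.6f 0.000000 0.000000", grid$spacing)
  w("delta 0.000000 %.6f 0.000000", grid$spacing)
  w("delta 0.000000 0.000000 %.6f", grid$spacing)
  w("object 2 class gridconnections counts %d %d %d", npt[1], npt[2], npt[3])
  w("object 3 class array type double rank 0 items %d data follows", length(vz))
  full <- seq_len(length(vz) %/% 3L * 3L)
  if (length(full)) {
    m <- matrix(vz[full], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6e %.6e %.6e", m[, 1], m[, 2], m[, 3]), con, sep = "\n")
  }
  rest <- vz[setdiff(seq_along(vz), full)]
  if (length(rest)) writeLines(paste(sprintf("%.6e", rest), collapse = " "), con)
  w("attribute \"dep\" string \"positions\"")
  w("object \"density\" class field")
  invisible(path)
}
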