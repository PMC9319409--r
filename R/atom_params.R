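#' Element parameter tables
#'
#' Frozen per-element parameters used by the field calculators.
#'
#' * `vdw_radius` (Angstrom): Bondi van der Waals radii.
#' * `lj_epsilon` (kcal/mol): Lennard-Jones well depths, GAFF-like values.
#' * `electronegativity`: Pauling scale, used only by the fallback charge rule.
#' * `hydrophobicity`: dimensionless atom-level lipophilicity increments
#'   (Ghose-Crippen-inspired signs: apolar carbon/halogen positive, polar
#'   heteroatoms negative). Hydrogens inherit a context value at typing time.
#'
#' @format A data.frame with one row per supported element.
#' @keywords internal
element_params <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
    vdw_radius = c(1.20, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98),
    lj_epsilon = c(0.0157, 0.0860, 0.1700, 0.2100, 0.0610,
                   0.2000, 0.2500, 0.2650, 0.3200, 0.4000),
    electronegativity = c(2.20, 2.55, 3.04, 3.44, 3.98, 2.19, 2.58, 3.16, 2.96, 2.66),
    hydrophobicity = c(0.23, 0.70, -0.60, -0.60, 0.20, -0.30, 0.30, 0.35, 0.40, 0.40),
    stringsAsFactors = FALSE
  )
}

# H heavy-atom attachment is decided geometrically: an H within this distance
# (Angstrom) of a heavy atom is treated as covalently bound to it.
.h_attach_dist <- 1.3

#' Assign per-atom field parameters
#'
#' Populates the van der Waals radius, Lennard-Jones well depth, CoMSIA steric
#' weight, hydrophobicity and hydrogen-bond donor/acceptor flags of every atom
#' from the frozen element tables plus rule-based typing:
#'
#' * steric weight = vdw_radius^3 (cubic-radius convention);
#' * donors: hydrogens covalently attached (see geometric rule) to N or O;
#' * acceptors: all N and O atoms;
#' * hydrophobicity: element increment; hydrogens on N/O get the polar value
#'   -0.10 instead of the apolar +0.23.
#'
#' The operation is idempotent: reassigning with the same `param_set` leaves
#' the molecule unchanged.
#'
#' @param mol an `aligned_molecule`.
#' @param param_set name of the parameter table; only `"default"` is shipped.
#' @return the molecule with parameter columns filled in.
#' @export
assign_atom_params <- function(mol, param_set = "default") {
  stopifnot(inherits(mol, "aligned_molecule"))
  if (!identical(param_set, "default")) {
    stop("unknown parameter set: ", param_set)
  }
  at <- mol$atoms
  tab <- element_params()
  idx <- match(at$element, tab$element)
  if (anyNA(idx)) {
    bad <- unique(at$element[is.na(idx)])
    stop("cannot parameterize element(s): ", paste(bad, collapse = ", "))
  }
  at$vdw_radius <- tab$vdw_radius[idx]
  at$lj_epsilon <- tab$lj_epsilon[idx]
  at$steric_weight <- at$vdw_radius^3
  at$hydrophobicity <- tab$hydrophobicity[idx]

  is_h <- at$element == "H"
  is_no <- at$element %in% c("N", "O")
  # geometric H attachment to N/O
  h_on_polar <- rep(FALSE, nrow(at))
  if (any(is_h) && any(is_no)) {
    xyz_h <- as.matrix(at[is_h, c("x", "y", "z")])
    xyz_no <- as.matrix(at[is_no, c("x", "y", "z")])
    d2 <- outer(rowSums(xyz_h^2), rowSums(xyz_no^2), "+") -
      2 * xyz_h %*% t(xyz_no)
    h_on_polar[is_h] <- apply(d2, 1, min) <= .h_attach_dist^2
  }
  at$is_donor <- h_on_polar
  at$is_acceptor <- is_no
  at$hydrophobicity[h_on_polar] <- -0.10

  mol$atoms <- at
  mol$params_assigned <- TRUE
  mol
}

# Fallback partial-charge rule for inputs that carry no charges: residual
# Pauling electronegativity relative to the molecular mean, scaled to a
# plausible magnitude and shifted to zero total charge. Crude by design;
# file-provided charges always take precedence.
.fallback_charges <- function(elements) {
  tab <- element_params()
  chi <- tab$electronegativity[match(elements, tab$element)]
  if (anyNA(chi)) {
    stop("cannot assign fallback charges for element(s): ",
         paste(unique(elements[is.na(chi)]), collapse = ", "))
  }
  q <- (chi - mean(chi)) / 10
  q - mean(q)
}
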