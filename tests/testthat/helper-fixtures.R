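# shared fixture builders; everything is generated in code at test time

mk_mol <- function(elements, xyz, charges = 0, id = "M1", pic50 = NA_real_,
                   params = TRUE) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  m <- aligned_molecule(id, data.frame(
    element = elements, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charges, length(elements)), stringsAsFactors = FALSE),
    pic50 = pic50)
  if (params) m <- assign_atom_params(m) else m
}

# neutral single carbon at the origin
carbon_at_origin <- function(charge = 0) mk_mol("C", c(0, 0, 0), charge)

# methane-like 5-atom molecule (tetrahedral H at 1.09 A)
methane <- function(id = "methane") {
  d <- 1.09 / sqrt(3)
  mk_mol(c("C", "H", "H", "H", "H"),
         c(0, 0, 0, d, d, d, d, -d, -d, -d, d, -d, -d, -d, d),
         charges = c(-0.4, 0.1, 0.1, 0.1, 0.1), id = id)
}

# deterministic rigid rotation (about z then x) plus translation
rigid_transform <- function(xyz, shift = c(1.5, -2.0, 0.7)) {
  a <- 0.7; b <- 0.4
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(b), -sin(b), 0, sin(b), cos(b)), 3, byrow = TRUE)
  sweep(xyz %*% t(Rx %*% Rz), 2, -shift)
}

transform_mol <- function(mol, shift = c(1.5, -2.0, 0.7)) {
  xyz <- rigid_transform(as.matrix(mol$atoms[, c("x", "y", "z")]), shift)
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

# small planted series + split, shared across tests (memoised per session)
.series_cache <- new.env(parent = emptyenv())
get_series <- function(seed = 1) {
  key <- as.character(seed)
  if (is.null(.series_cache[[key]])) {
    .series_cache[[key]] <- generate_series(series_spec(seed = seed))
  }
  .series_cache[[key]]
}

# Table of per-complex binding energies shipped with the package
energies <- function() flt3_binding_energies()
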