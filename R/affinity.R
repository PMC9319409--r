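#' Thermodynamic conversion settings
#'
#' Temperature for the pIC50 to Gibbs-energy conversion. The derived factor
#' `RT ln 10` (kcal/mol per log unit) is 1.3644 at the default 300 K, the MD
#' thermostat target; it is configurable because experimentally tabulated
#' binding energies sometimes imply a slightly different effective
#' temperature.
#'
#' @param temperature kelvin (> 0).
#' @return object of class `thermo_settings` with `temperature` and
#'   `rt_ln10`.
#' @export
thermo_settings <- function(temperature = 300) {
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive")
  }
  R_KCAL <- 1.98720425e-3  # kcal/(mol K)
  structure(list(temperature = temperature,
                 rt_ln10 = R_KCAL * temperature * log(10)),
            class = "thermo_settings")
}

#' Convert pIC50 to binding free energy
#'
#' `dG = -RT ln(10) * pIC50` (kcal/mol), treating the IC50 as a surrogate
#' dissociation constant. [dg_to_pic50()] is the exact inverse.
#'
#' @param pic50 activity, -log10 molar IC50.
#' @param thermo a `thermo_settings`.
#' @return kcal/mol (negative for active compounds).
#' @export
pic50_to_dg <- function(pic50, thermo = thermo_settings()) {
  stopifnot(inherits(thermo, "thermo_settings"), all(is.finite(pic50)))
  -thermo$rt_ln10 * pic50
}

#' @rdname pic50_to_dg
#' @param dg binding free energy, kcal/mol.
#' @export
dg_to_pic50 <- function(dg, thermo = thermo_settings()) {
  stopifnot(inherits(thermo, "thermo_settings"), all(is.finite(dg)))
  -dg / thermo$rt_ln10
}

#' Linear interaction energy from bound/unbound state averages
#'
#' `dG_LIE = 1/2 dE_cou + 1/2 dE_vdW` with each `dE = E_unbound - E_bound`,
#' the half-weighted interaction-energy change between the two
#' quasi-equilibrium states of a pulling trajectory.
#'
#' @param e_bound named vector or list with `e_vdw` and `e_cou` (kcal/mol)
#'   for the bound state.
#' @param e_unbound same terms for the unbound state.
#' @return kcal/mol.
#' @export
lie_energy <- function(e_bound, e_unbound) {
  eb <- as.list(e_bound); eu <- as.list(e_unbound)
  need <- c("e_vdw", "e_cou")
  if (!all(need %in% names(eb)) || !all(need %in% names(eu))) {
    stop("bound and unbound states each need terms: e_vdw, e_cou")
  }
  d_cou <- eu$e_cou - eb$e_cou
  d_vdw <- eu$e_vdw - eb$e_vdw
  stopifnot(is.finite(d_cou), is.finite(d_vdw))
  0.5 * d_cou + 0.5 * d_vdw
}

#' Assemble an MM-PB/GBSA binding free energy
#'
#' `dG = dE_vdW + dE_ELE + dE_GB + dE_SA - T dS`. The equivalent grouping
#' `dE_MM + dG_sol - T dS` (with `dE_MM = dE_vdW + dE_ELE` and
#' `dG_sol = dE_GB + dE_SA`) is computed alongside and cross-checked; the two
#' routes agree by construction.
#'
#' @param components named vector/list with `e_vdw`, `e_ele`, `e_gb`, `e_sa`
#'   (kcal/mol).
#' @param t_ds entropy term `T dS` in kcal/mol (subtracted).
#' @return kcal/mol.
#' @export
mmpbsa_total <- function(components, t_ds = 0) {
  comp <- as.list(components)
  need <- c("e_vdw", "e_ele", "e_gb", "e_sa")
  missing_terms <- setdiff(need, names(comp))
  if (length(missing_terms)) {
    stop("missing required energy term(s): ",
         paste(missing_terms, collapse = ", "))
  }
  vals <- vapply(comp[need], as.numeric, numeric(1))
  stopifnot(all(is.finite(vals)), is.finite(t_ds))
  total <- sum(vals) - t_ds
  e_mm <- vals[["e_vdw"]] + vals[["e_ele"]]
  g_sol <- vals[["e_gb"]] + vals[["e_sa"]]
  stopifnot(abs((e_mm + g_sol - t_ds) - total) < 1e-9)
  total
}

#' Correlate an experimental column with a computed score
#'
#' Pearson correlation between two columns of an energy table after dropping
#' excluded complexes and rows with a missing member of the pair; the
#' standard error is the standard deviation of R over `n_boot` row resamples
#' (resamples with zero variance in either column are redrawn and counted).
#'
#' @param table an `energy_table` (or data.frame with an `id` column).
#' @param x,y column names to pair.
#' @param exclude complex ids to drop before correlating.
#' @param n_boot bootstrap resamples for the standard error (default 1000).
#' @param seed RNG seed.
#' @return object of class `correlation_result`: `x`, `y`, `n`, `excluded`,
#'   `r`, `se`, `n_boot`, `seed`, `redrawn`.
#' @export
correlate <- function(table, x, y, exclude = character(0),
                      n_boot = 1000, seed = 1) {
  for (cn in c(x, y)) {
    if (!cn %in% names(table)) {
      stop("unknown column '", cn, "'; available: ",
           paste(setdiff(names(table), "id"), collapse = ", "))
    }
  }
  keep <- !(table$id %in% exclude)
  xv <- table[[x]][keep]; yv <- table[[y]][keep]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3) stop("fewer than 3 complete pairs after exclusion")
  r <- stats::cor(xv, yv)
  set.seed(seed)
  rs <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(xv[idx]) > 1e-12 && stats::sd(yv[idx]) > 1e-12) break
      redrawn <- redrawn + 1L
    }
    rs[b] <- stats::cor(xv[idx], yv[idx])
  }
  structure(list(x = x, y = y, n = n,
                 excluded = intersect(exclude, table$id),
                 r = r, se = stats::sd(rs),
                 n_boot = n_boot, seed = seed, redrawn = redrawn),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> R(%s, %s) = %.3f +/- %.3f (n = %d, %d bootstrap runs)\n",
              x$x, x$y, x$r, x$se, x$n, x$n_boot))
  invisible(x)
}

#' Batched correlation report
#'
#' Runs [correlate()] for several computed-score columns against one
#' experimental column and assembles a flat report.
#'
#' @param table an `energy_table`.
#' @param x experimental column name.
#' @param ys character vector of computed-score columns.
#' @param exclude ids dropped from every pair.
#' @param n_boot,seed bootstrap controls.
#' @return data.frame with one row per pair (`x`, `y`, `n`, `r`, `se`).
#' @export
score_eval <- function(table, x = "dg_exp", ys, exclude = character(0),
                       n_boot = 1000, seed = 1) {
  if (length(ys) == 0) {
    return(data.frame(x = character(0), y = character(0), n = integer(0),
                      r = numeric(0), se = numeric(0)))
  }
  rows <- lapply(seq_along(ys), function(i) {
    cr <- correlate(table, x, ys[i], exclude = exclude,
                    n_boot = n_boot, seed = seed + i - 1L)
    data.frame(x = x, y = ys[i], n = cr$n, r = cr$r, se = cr$se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bundled wild-type/mutant kinase binding-energy table
#'
#' The per-complex experimental and computed binding energies shipped with
#' the package (`inst/extdata/flt3_binding_energies.csv`): experimental
#' Gibbs energy, MM-PB/GBSA total, rupture force (pN), LIE and FEP estimates
#' for seven wild-type FLT3 complexes plus the D835Y mutant complex of the
#' most active compound.
#'
#' @return an `energy_table` with 8 rows.
#' @export
flt3_binding_energies <- function() {
  path <- system.file("extdata", "flt3_binding_energies.csv",
                      package = "fieldqsar", mustWork = TRUE)
  read_energy_table(path)
}
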