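# ---------------------------------------------------------------------------
# Synthetic congeneric series with a planted field-activity relationship.
#
# The generator emulates the statistical shape of a published congeneric
# kinase-inhibitor series: a rigid fused-bicyclic scaffold (pteridinone-like,
# planar, fixed coordinates so every analogue is born pre-aligned), three
# substitution sites R1-R3, a small hand-built substituent library, ~35
# analogues whose activity is a linear function of Gaussian similarity field
# values at designated probe points plus Gaussian noise, mapped onto a
# three-log-unit pIC50 span. Chemical realism is secondary to controlled
# field structure.
# ---------------------------------------------------------------------------

# fixed planar scaffold: fused six-membered rings with ring nitrogens and a
# carbonyl oxygen; coordinates in Angstrom, z = 0
.scaffold_atoms <- function() {
  data.frame(
    element = c("N", "C", "N", "C", "C", "C", "C", "O", "N", "C", "H"),
    x = c(1.40, 0.70, -0.70, -1.40, -0.70, 0.70, 2.10, 2.80, 2.80, 2.10, 3.80),
    y = c(0.00, 1.21, 1.21, 0.00, -1.21, -1.21, -1.21, -2.30, 0.00, 1.21, 0.00),
    z = 0,
    charge = c(-0.30, 0.15, -0.30, 0.10, 0.05, 0.10, 0.20, -0.35, -0.25,
               0.12, 0.28),
    stringsAsFactors = FALSE
  )
}

# substitution sites: attachment position (a scaffold ring atom) and the
# outward growth direction (unit vector, in-plane)
.sites <- function() {
  list(
    R1 = list(pos = c(2.10, 1.21, 0), dir = c(0.5, 0.8660254, 0)),
    R2 = list(pos = c(-0.70, -1.21, 0), dir = c(-0.5, -0.8660254, 0)),
    R3 = list(pos = c(-1.40, 0.00, 0), dir = c(-1, 0, 0))
  )
}

# substituent templates in a local frame: lx along the growth direction,
# ly/lz perpendicular; charges chosen to keep groups roughly neutral
.substituent_library <- function() {
  sub <- function(el, lx, ly, lz, q) {
    data.frame(element = el, lx = lx, ly = ly, lz = lz, charge = q,
               stringsAsFactors = FALSE)
  }
  list(
    hydrogen = sub("H", 1.0, 0, 0, 0.08),
    methyl = sub(c("C", "H", "H", "H"),
                 c(1.50, 2.10, 2.10, 2.10),
                 c(0, 0.90, -0.45, -0.45),
                 c(0, 0, 0.78, -0.78),
                 c(-0.06, 0.03, 0.03, 0.03)),
    ethyl = sub(c("C", "H", "H", "C", "H", "H", "H"),
                c(1.50, 1.85, 1.85, 2.55, 3.15, 2.90, 2.20),
                c(0, -0.50, 0.50, 0.85, 0.40, 1.45, 1.40),
                c(0, 0.80, -0.80, 0, 0.85, -0.55, 0.75),
                c(-0.05, 0.02, 0.02, -0.08, 0.03, 0.03, 0.03)),
    methoxy = sub(c("O", "C", "H", "H", "H"),
                  c(1.40, 2.60, 3.20, 2.90, 2.60),
                  c(0, 0.55, -0.20, 1.15, 1.10),
                  c(0, 0.60, 1.35, -0.20, 1.40),
                  c(-0.36, 0.09, 0.05, 0.05, 0.05)),
    amino = sub(c("N", "H", "H"),
                c(1.40, 2.00, 2.00),
                c(0, 0.80, -0.80),
                c(0, 0.10, 0.10),
                c(-0.70, 0.35, 0.35)),
    hydroxyl = sub(c("O", "H"),
                   c(1.40, 2.30), c(0, 0.15), c(0, 0),
                   c(-0.40, 0.40)),
    chloro = sub("Cl", 1.75, 0, 0, -0.10),
    trifluoromethyl = sub(c("C", "F", "F", "F"),
                          c(1.50, 2.15, 2.15, 2.15),
                          c(0, 1.05, -0.55, -0.55),
                          c(0, 0, 0.95, -0.95),
                          c(0.45, -0.15, -0.15, -0.15))
  )
}

# orthonormal frame (u, v, w) with u the growth direction
.site_frame <- function(dir) {
  u <- dir / sqrt(sum(dir^2))
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- c(u[2] * ref[3] - u[3] * ref[2],
         u[3] * ref[1] - u[1] * ref[3],
         u[1] * ref[2] - u[2] * ref[1])
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  list(u = u, v = v, w = w)
}

#' Specification of a synthetic congeneric series
#'
#' Defaults mirror the study conditions the generator emulates: 35 analogues
#' on a rigid bicyclic scaffold with three substitution sites, pIC50 spanning
#' 5.26-8.80 (three log units) with Gaussian activity noise of 0.3 log units
#' around a planted linear field-activity signal.
#'
#' @param n_compounds number of analogues (>= 10).
#' @param noise_sd activity noise standard deviation, log units (>= 0).
#' @param span target pIC50 range, `c(low, high)`.
#' @param seed RNG seed for substitution-pattern sampling and noise.
#' @param coefficients named numeric vector of planted weights over the
#'   probe-point field values; names combine site and field kind, e.g.
#'   `"R1.S"`. The defaults plant bulky-favored signal at R1/R3, a
#'   bulky-disfavored and hydrophobicity-favored signal at R2.
#' @param settings `field_settings` used to evaluate the planted fields.
#' @return object of class `series_spec`.
#' @export
series_spec <- function(n_compounds = 35, noise_sd = 0.3,
                        span = c(5.26, 8.80), seed = 7,
                        coefficients = c(R1.S = 1.0, R2.S = -0.4,
                                         R3.S = 1.0, R2.H = 3.0),
                        settings = field_settings()) {
  stopifnot(n_compounds >= 10, noise_sd >= 0, length(span) == 2,
            span[1] < span[2])
  structure(list(n_compounds = as.integer(n_compounds),
                 noise_sd = noise_sd, span = as.numeric(span),
                 seed = as.integer(seed),
                 coefficients = coefficients,
                 settings = settings),
            class = "series_spec")
}

# probe points where the planted signal reads the fields: 2 Angstrom beyond
# each attachment point along the growth direction
.probe_points <- function() {
  sites <- .sites()
  t(vapply(names(sites), function(s) {
    sites[[s]]$pos + 2.0 * sites[[s]]$dir
  }, numeric(3)))
}

#' Generate a synthetic congeneric series with planted activity
#'
#' Each analogue is the fixed scaffold plus one substituent per site, the
#' full substitution patterns sampled without duplication. The true activity
#' is a linear combination of Gaussian similarity (steric and hydrophobic)
#' field values at the designated probe points, affinely mapped onto the
#' target span; Gaussian noise is then added and the noisy vector is rescaled
#' onto the span so the generated series attains the stated range exactly.
#' Everything (patterns, noise) is reproducible from the spec seed.
#'
#' @param spec a `series_spec`.
#' @return list with `molecules` (parameterized, activities attached),
#'   `activities` (an `activity_table`) and `truth` (planted coefficients,
#'   probe points, per-compound field values, noiseless signal and noise
#'   draws) for recovery tests.
#' @export
generate_series <- function(spec = series_spec()) {
  stopifnot(inherits(spec, "series_spec"))
  lib <- .substituent_library()
  sites <- .sites()
  n_pat <- length(lib)^length(sites)
  if (spec$n_compounds > n_pat) {
    stop("substituent library supports only ", n_pat, " unique patterns")
  }
  set.seed(spec$seed)
  pat_idx <- sample.int(n_pat, spec$n_compounds)  # unique patterns
  nlib <- length(lib)
  scaffold <- .scaffold_atoms()

  mols <- vector("list", spec$n_compounds)
  pattern <- matrix("", spec$n_compounds, length(sites),
                    dimnames = list(NULL, names(sites)))
  for (i in seq_len(spec$n_compounds)) {
    code <- pat_idx[i] - 1L
    atoms <- scaffold
    for (s in seq_along(sites)) {
      j <- code %% nlib + 1L
      code <- code %/% nlib
      pattern[i, s] <- names(lib)[j]
      tpl <- lib[[j]]
      fr <- .site_frame(sites[[s]]$dir)
      pos <- sites[[s]]$pos
      gx <- pos[1] + tpl$lx * fr$u[1] + tpl$ly * fr$v[1] + tpl$lz * fr$w[1]
      gy <- pos[2] + tpl$lx * fr$u[2] + tpl$ly * fr$v[2] + tpl$lz * fr$w[2]
      gz <- pos[3] + tpl$lx * fr$u[3] + tpl$ly * fr$v[3] + tpl$lz * fr$w[3]
      atoms <- rbind(atoms,
                     data.frame(element = tpl$element, x = gx, y = gy, z = gz,
                                charge = tpl$charge, stringsAsFactors = FALSE))
    }
    mols[[i]] <- assign_atom_params(
      aligned_molecule(sprintf("C%02d", i), atoms))
  }

  # planted signal: similarity field values at the probe points
  probes <- .probe_points()
  co <- spec$coefficients
  co_site <- sub("\\..*$", "", names(co))
  co_kind <- normalize_field_kinds(sub("^.*\\.", "", names(co)))
  fvals <- matrix(0.0, spec$n_compounds, length(co),
                  dimnames = list(NULL, names(co)))
  kinds_needed <- unique(co_kind)
  for (i in seq_len(spec$n_compounds)) {
    fv <- .comsia_at_points(mols[[i]], probes, spec$settings, kinds_needed)
    for (j in seq_along(co)) {
      fvals[i, j] <- fv[[co_kind[j]]][match(co_site[j], rownames(probes))]
    }
  }
  signal <- drop(fvals %*% co)
  if (stats::sd(signal) < 1e-12) {
    stop("planted signal is constant over the sampled patterns")
  }
  lo <- spec$span[1]; hi <- spec$span[2]
  mapped <- lo + (signal - min(signal)) / (max(signal) - min(signal)) * (hi - lo)
  noise <- stats::rnorm(spec$n_compounds, 0, spec$noise_sd)
  y <- mapped + noise
  # rescale the noisy vector onto the span so the series attains it exactly
  y <- lo + (y - min(y)) / (max(y) - min(y)) * (hi - lo)

  for (i in seq_len(spec$n_compounds)) mols[[i]]$pic50 <- y[i]
  acts <- data.frame(id = vapply(mols, function(m) m$id, character(1)),
                     pic50 = y, stringsAsFactors = FALSE)
  class(acts) <- c("activity_table", "data.frame")

  list(molecules = mols,
       activities = acts,
       truth = list(coefficients = co,
                    probe_points = probes,
                    probe_site = co_site,
                    probe_kind = co_kind,
                    field_values = fvals,
                    signal = signal, mapped = mapped, noise = noise,
                    pattern = as.data.frame(pattern),
                    spec = spec))
}

#' Activity-stratified train/test split
#'
#' Compounds are ranked by pIC50 and cut into low/medium/high tertiles; the
#' requested number of test compounds is allocated across tertiles
#' proportionally to tertile size (remainders go to the largest tertiles) and
#' sampled without replacement under the seed. The training set is the
#' complement, so every activity segment is represented on both sides.
#'
#' @param activities an `activity_table` (columns `id`, `pic50`).
#' @param n_test test-set size (default 9).
#' @param seed RNG seed.
#' @return list with character vectors `train` and `test`.
#' @export
split_train_test <- function(activities, n_test = 9, seed = 1) {
  n <- nrow(activities)
  if (n_test <= 0 || n_test >= n) stop("n_test must be in (0, n_compounds)")
  if (n < n_test + 4) stop("too few compounds for the requested test size")
  ord <- order(activities$pic50)
  sizes <- diff(round(seq(0, n, length.out = 4)))  # near-equal tertiles
  tert <- rep(1:3, times = sizes)
  alloc <- floor(n_test * sizes / n)
  rem <- n_test - sum(alloc)
  if (rem > 0) {
    extra <- order(-sizes)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1L
  }
  # a tertile cannot give more than it holds; push overflow to the others
  over <- alloc > sizes
  if (any(over)) {
    spare <- sum(alloc[over] - sizes[over])
    alloc[over] <- sizes[over]
    room <- which(alloc < sizes)
    for (g in room) {
      take <- min(spare, sizes[g] - alloc[g])
      alloc[g] <- alloc[g] + take
      spare <- spare - take
      if (spare == 0) break
    }
  }
  set.seed(seed)
  test_idx <- integer(0)
  for (g in 1:3) {
    members <- ord[tert == g]
    if (alloc[g] > 0) {
      test_idx <- c(test_idx, sample(members, alloc[g]))
    }
  }
  test_ids <- activities$id[sort(test_idx)]
  list(train = setdiff(activities$id, test_ids), test = test_ids)
}

#' Generate a synthetic per-complex energy table
#'
#' Draws (experimental, computed-score) pairs from a bivariate normal with
#' the requested population correlation, affinely mapped to the given means
#' and standard deviations — a controlled stand-in for per-complex binding
#' energy tables when testing the correlation machinery.
#'
#' @param n number of complexes (>= 4).
#' @param target_r population correlation, strictly inside (-1, 1).
#' @param scales list with numeric `x = c(mean, sd)` and `y = c(mean, sd)`;
#'   defaults to experiment-like Gibbs energies vs an MM-PB/GBSA-like score.
#' @param seed RNG seed.
#' @return an `energy_table` with columns `id`, `dg_exp`, `score`.
#' @export
generate_energy_table <- function(n, target_r,
                                  scales = list(x = c(-10, 1.6),
                                                y = c(-26, 4.0)),
                                  seed = 1) {
  if (n < 4) stop("need at least 4 complexes")
  if (!is.finite(target_r) || abs(target_r) >= 1) {
    stop("target_r must lie strictly inside (-1, 1)")
  }
  set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  zx <- z1
  zy <- target_r * z1 + sqrt(1 - target_r^2) * z2
  out <- data.frame(id = sprintf("CPX%04d", seq_len(n)),
                    dg_exp = scales$x[1] + scales$x[2] * zx,
                    score = scales$y[1] + scales$y[2] * zy,
                    stringsAsFactors = FALSE)
  class(out) <- c("energy_table", "data.frame")
  out
}
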