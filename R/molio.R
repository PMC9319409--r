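#' Construct an aligned molecule
#'
#' A container for one pre-aligned 3D ligand: an atom table (element, Cartesian
#' coordinates in Angstrom, partial charge in elementary-charge units, and the
#' per-atom field parameters filled in by [assign_atom_params()]) plus an
#' optional pIC50. Molecules destined for one model must share a common
#' alignment frame; no re-alignment is ever performed here.
#'
#' @param id compound identifier.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`, `charge`.
#' @param pic50 optional activity, -log10 of the molar IC50.
#' @return an object of class `aligned_molecule`.
#' @export
aligned_molecule <- function(id, atoms, pic50 = NA_real_) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z", "charge") %in% names(atoms)))
  if (nrow(atoms) < 1) stop("molecule '", id, "' has no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("molecule '", id, "' has non-finite coordinates")
  if (!all(is.finite(atoms$charge))) {
    stop("molecule '", id, "' has non-finite partial charges")
  }
  structure(list(id = as.character(id),
                 atoms = atoms,
                 pic50 = as.numeric(pic50),
                 params_assigned = FALSE),
            class = "aligned_molecule")
}

#' @export
print.aligned_molecule <- function(x, ...) {
  cat(sprintf("<aligned_molecule> %s: %d atoms, net charge %+.3f, pIC50 %s\n",
              x$id, nrow(x$atoms), sum(x$atoms$charge),
              ifelse(is.na(x$pic50), "NA", sprintf("%.2f", x$pic50))))
  invisible(x)
}

.element_from_sybyl <- function(elety) {
  e <- sub("\\..*$", "", elety)
  # normalize case: first letter upper, rest lower
  paste0(toupper(substr(e, 1, 1)), tolower(substring(e, 2)))
}

#' Read aligned molecules from SDF or MOL2
#'
#' SDF (V2000) records are parsed with ChemmineR; MOL2 with bio3d. Partial
#' charges are taken from the file when present (the MOL2 charge column, or an
#' SDF `PARTIAL_CHARGES` data field holding one value per atom); otherwise a
#' documented fallback rule assigns residual-electronegativity charges. SDF
#' `PIC50` data fields populate activities; an `activities` table (matched by
#' id) takes precedence. Atom field parameters are assigned on read.
#'
#' Records flagged `2D` whose z coordinates are all zero are rejected:
#' field-based QSAR needs genuine 3D, pre-aligned structures.
#'
#' @param path input file.
#' @param format `"sdf"` or `"mol2"`.
#' @param activities optional data.frame (`id`, `pic50`) to attach.
#' @param param_set parameter table passed to [assign_atom_params()].
#' @return list of `aligned_molecule`.
#' @export
read_molecules <- function(path, format = c("sdf", "mol2"), activities = NULL,
                           param_set = "default") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  mols <- switch(format,
                 sdf = .read_sdf(path),
                 mol2 = .read_mol2(path))
  mols <- lapply(mols, assign_atom_params, param_set = param_set)
  if (!is.null(activities)) {
    stopifnot(all(c("id", "pic50") %in% names(activities)))
    for (i in seq_along(mols)) {
      j <- match(mols[[i]]$id, activities$id)
      if (!is.na(j)) mols[[i]]$pic50 <- activities$pic50[j]
    }
  }
  mols
}

.read_sdf <- function(path) {
  sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                     error = function(e) stop("cannot parse SDF '", path, "': ",
                                              conditionMessage(e)))
  valid <- ChemmineR::validSDF(sdfset)
  if (!all(valid)) {
    stop("malformed SDF record(s) at position(s): ",
         paste(which(!valid), collapse = ", "), " in ", path)
  }
  lapply(seq_along(sdfset), function(i) {
    sdf <- sdfset[[i]]
    hdr <- ChemmineR::header(sdf)
    ab <- ChemmineR::atomblock(sdf)
    db <- ChemmineR::datablock(sdf)
    id <- unname(hdr[["Molecule_Name"]])
    if (is.null(id) || !nzchar(id)) id <- sprintf("MOL%03d", i)
    element <- sub("_.*$", "", rownames(ab))
    xyz <- ab[, c("C1", "C2", "C3"), drop = FALSE]
    if (grepl("2D", hdr[["Source"]], fixed = TRUE) &&
        all(abs(xyz[, 3]) < 1e-6)) {
      stop("record '", id, "' is flagged 2D with all-zero z coordinates; ",
           "3D aligned structures are required")
    }
    if ("PARTIAL_CHARGES" %in% names(db)) {
      charge <- as.numeric(strsplit(trimws(db[["PARTIAL_CHARGES"]]), "\\s+")[[1]])
      if (length(charge) != nrow(ab) || anyNA(charge)) {
        stop("record '", id, "': PARTIAL_CHARGES field does not hold one ",
             "numeric value per atom")
      }
    } else {
      charge <- .fallback_charges(element)
    }
    pic50 <- if ("PIC50" %in% names(db)) as.numeric(db[["PIC50"]]) else NA_real_
    aligned_molecule(id, data.frame(element = element,
                                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                    charge = charge,
                                    stringsAsFactors = FALSE),
                     pic50 = pic50)
  })
}

.read_mol2 <- function(path) {
  lines <- readLines(path)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) stop("no @<TRIPOS>MOLECULE record in ", path)
  # validate ATOM blocks up front so errors can name the offending line
  atom_starts <- grep("^@<TRIPOS>ATOM", lines)
  sections <- grep("^@<TRIPOS>", lines)
  for (a in atom_starts) {
    nxt <- sections[sections > a]
    end <- if (length(nxt)) min(nxt) - 1 else length(lines)
    for (ln in seq(a + 1, end)) {
      txt <- trimws(lines[ln])
      if (!nzchar(txt)) next
      tok <- strsplit(txt, "\\s+")[[1]]
      coords <- suppressWarnings(as.numeric(tok[3:5]))
      if (length(tok) < 6 || anyNA(coords)) {
        stop("malformed @<TRIPOS>ATOM record at line ", ln, " of ", path)
      }
    }
  }
  m <- bio3d::read.mol2(path)
  recs <- if (inherits(m, "mol2")) list(m) else m
  lapply(recs, function(r) {
    at <- r$atom
    element <- .element_from_sybyl(at$elety)
    charge <- at$charge
    if (is.null(charge) || all(is.na(charge)) || all(charge == 0)) {
      charge <- .fallback_charges(element)
    }
    id <- if (!is.null(r$name) && nzchar(r$name[1])) r$name[1] else "MOL001"
    aligned_molecule(id, data.frame(element = element,
                                    x = at$x, y = at$y, z = at$z,
                                    charge = charge,
                                    stringsAsFactors = FALSE))
  })
}

# covalent radii (Angstrom) for the distance bond heuristic of the SDF writer
.cov_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)

.guess_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  r <- .cov_radii[atoms$element]
  r[is.na(r)] <- 0.77
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    cutoff <- 1.25 * (r[i] + r[(i + 1):n])
    j <- which(d <= cutoff & d > 0.1)
    if (length(j)) out <- rbind(out, cbind(i, i + j))
  }
  out
}

#' Write molecules to an SDF (V2000) file
#'
#' Deterministic writer: fixed program line (no timestamps), `%.4f`
#' coordinates, partial charges in a `PARTIAL_CHARGES` data field (`%.6f`, one
#' value per atom, space-separated) and the activity in a `PIC50` field when
#' present. Bonds are reconstructed from a covalent-radius distance heuristic
#' purely so the records are well-formed; nothing downstream uses them.
#' Identical molecule lists produce byte-identical files.
#'
#' @param mols list of `aligned_molecule`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "aligned_molecule")) mols <- list(mols)
  con <- file(path, open = "wb")  # binary: fixed "\n" on every platform
  on.exit(close(con))
  for (mol in mols) {
    at <- mol$atoms
    bonds <- .guess_bonds(at)
    lines <- c(
      mol$id,
      "  fieldqsar          3D",
      "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(at), nrow(bonds)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              at$x, at$y, at$z, at$element)
    )
    if (nrow(bonds) > 0) {
      lines <- c(lines, sprintf("%3d%3d  1  0", bonds[, 1], bonds[, 2]))
    }
    lines <- c(lines, "M  END",
               "> <PARTIAL_CHARGES>",
               paste(sprintf("%.6f", at$charge), collapse = " "),
               "")
    if (!is.na(mol$pic50)) {
      lines <- c(lines, "> <PIC50>", sprintf("%.6f", mol$pic50), "")
    }
    lines <- c(lines, "$$$$")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read an activity table
#'
#' CSV with a header naming at least `id` and `pic50` columns (case
#' insensitive; `compound`/`compound_id` accepted for the id).
#'
#' @param path CSV file.
#' @return data.frame with columns `id`, `pic50`, class `activity_table`.
#' @export
read_activity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  idcol <- intersect(c("id", "compound", "compound_id"), names(df))[1]
  if (is.na(idcol) || !"pic50" %in% names(df)) {
    stop("activity CSV must have an id column and a pic50 column")
  }
  out <- data.frame(id = as.character(df[[idcol]]),
                    pic50 = as.numeric(df[["pic50"]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) {
    stop("duplicate compound id(s): ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  }
  if (!all(is.finite(out$pic50))) stop("non-finite pIC50 values in ", path)
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Read a per-complex energy-component table
#'
#' CSV whose first column is the complex id; the remaining columns are
#' energy terms in kcal/mol (rupture force columns in pN are carried through
#' untouched). Recognized canonical names (case-insensitive) are `dg_exp`,
#' `dg_mmpbsa`, `fmax`, `dg_lie`, `dg_fep`; any other column is preserved as an
#' extra term. Missing cells become `NA`, never zero.
#'
#' @param path CSV file with a header row.
#' @return data.frame of class `energy_table`.
#' @export
read_energy_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 1) stop("energy CSV needs at least an id column")
  names(raw) <- tolower(names(raw))
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate complex id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (cn in names(raw)[-1]) {
    x <- trimws(raw[[cn]])
    x[x == ""] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      stop("non-numeric value '", x[bad[1]], "' in column '", cn,
           "', row ", bad[1])
    }
    if (any(is.infinite(v), na.rm = TRUE)) {
      stop("non-finite value in column '", cn, "'")
    }
    out[[cn]] <- v
  }
  class(out) <- c("energy_table", "data.frame")
  out
}

#' Write a predictions table
#'
#' Standard prediction export: compound id, observed and predicted pIC50,
#' leverage and the applicability-domain flag.
#'
#' @param pred data.frame with columns `id`, `observed`, `predicted`,
#'   `leverage`, `in_domain`.
#' @param path output CSV.
#' @export
write_predictions <- function(pred, path) {
  need <- c("id", "observed", "predicted", "leverage", "in_domain")
  stopifnot(all(need %in% names(pred)))
  utils::write.csv(pred[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
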