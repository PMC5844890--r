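# Atom-record structure model and PQR/PDB I/O.
#
# A Structure is a list with class "Structure":
#   $atoms         data.frame: serial, name, resname, resseq, chain, element,
#                  x, y, z (Angstrom) and, for PQR-derived structures,
#                  charge (e) and radius (Angstrom)
#   $source_format "PQR" or "PDB"
#   $label         free-text label
# Atom order is preserved from file. Coordinates are Angstrom throughout,
# charges in elementary-charge units; no internal unit conversion.

new_structure <- function(atoms, source_format, label = "") {
  stopifnot(is.data.frame(atoms))
  needed <- c("serial", "name", "resname", "resseq", "chain", "element",
              "x", "y", "z")
  miss <- setdiff(needed, names(atoms))
  if (length(miss))
    stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_format = source_format, label = label),
            class = "Structure")
}

#' Test for and count atoms of a Structure
#'
#' @param x object to test / Structure to count.
#' @return `is_structure` a logical; `n_atoms` an integer atom count.
#' @export
is_structure <- function(x) inherits(x, "Structure")

#' @rdname is_structure
#' @export
n_atoms <- function(x) {
  stopifnot(is_structure(x))
  nrow(x$atoms)
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  nres <- nrow(unique(a[, c("chain", "resseq", "resname")]))
  cat(sprintf("Structure '%s' (%s): %d atoms, %d residues, chains: %s\n",
              x$label, x$source_format, nrow(a), nres,
              paste(sort(unique(a$chain)), collapse = " ")))
  if (x$source_format == "PQR" && nrow(a))
    cat(sprintf("  total charge %.4f e\n", sum(a$charge)))
  invisible(x)
}

#' Coordinate matrix of a Structure
#'
#' @param s a Structure.
#' @return numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @export
coords <- function(s) {
  stopifnot(is_structure(s))
  as.matrix(s$atoms[, c("x", "y", "z")])
}

has_charges <- function(s) {
  all(c("charge", "radius") %in% names(s$atoms)) &&
    (nrow(s$atoms) == 0L || !anyNA(s$atoms$charge))
}

# Element inferred from the atom name: strip leading digits, then take the
# leading letters; a short list of common two-letter elements is recognised
# when the full stripped name matches, otherwise the first letter is used
# (so "CA" in a protein residue is carbon, not calcium).
TWO_LETTER_ELEMENTS <- c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "NA", "CU")

infer_element <- function(name) {
  nm <- toupper(gsub("^[0-9' ]+", "", name))
  nm <- gsub("[^A-Z]", "", nm)
  ifelse(nm %in% TWO_LETTER_ELEMENTS, nm, substr(nm, 1L, 1L))
}

#' Read a PQR file
#'
#' Parses the whitespace-delimited PQR dialect (as emitted by pdb2pqr and the
#' H++ server): `ATOM`/`HETATM` records whose last two numeric columns are the
#' per-atom partial charge (e) and radius (Angstrom). The chain-identifier
#' column is optional and detected from the token count.
#'
#' @param path path to a PQR file.
#' @param label optional label stored on the Structure.
#' @return a `Structure` with `charge` and `radius` populated for every atom.
#' @export
read_pqr <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)\\b", lines)
  if (!length(rec)) {
    atoms <- data.frame(serial = integer(), name = character(),
                        resname = character(), resseq = integer(),
                        chain = character(), element = character(),
                        x = double(), y = double(), z = double(),
                        charge = double(), radius = double(),
                        stringsAsFactors = FALSE)
    return(new_structure(atoms, "PQR", label))
  }
  parse_one <- function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    n <- length(tok)
    if (n < 10L)
      stop(sprintf("PQR line %d: expected >= 10 fields, found %d", i, n))
    has_chain <- n >= 11L && grepl("^[A-Za-z]", tok[5])
    chain <- if (has_chain) tok[5] else ""
    off <- if (has_chain) 1L else 0L
    num <- suppressWarnings(as.numeric(tok[c(2, (5 + off):(10 + off))]))
    if (anyNA(num))
      stop(sprintf("PQR line %d: malformed numeric field", i))
    list(serial = as.integer(num[1]), name = tok[3], resname = tok[4],
         resseq = as.integer(num[2]), chain = chain,
         x = num[3], y = num[4], z = num[5], charge = num[6], radius = num[7])
  }
  parsed <- lapply(rec, parse_one)
  atoms <- data.frame(
    serial = vapply(parsed, `[[`, integer(1), "serial"),
    name = vapply(parsed, `[[`, character(1), "name"),
    resname = vapply(parsed, `[[`, character(1), "resname"),
    resseq = vapply(parsed, `[[`, integer(1), "resseq"),
    chain = vapply(parsed, `[[`, character(1), "chain"),
    x = vapply(parsed, `[[`, double(1), "x"),
    y = vapply(parsed, `[[`, double(1), "y"),
    z = vapply(parsed, `[[`, double(1), "z"),
    charge = vapply(parsed, `[[`, double(1), "charge"),
    radius = vapply(parsed, `[[`, double(1), "radius"),
    stringsAsFactors = FALSE)
  if (any(atoms$radius < 0)) stop("negative radius in PQR file")
  atoms$element <- infer_element(atoms$name)
  new_structure(atoms, "PQR", label)
}

#' Write a Structure to a PQR file
#'
#' Emits whitespace-delimited ATOM records (chain column included when chain
#' ids are present). Charges and radii are required.
#'
#' @param s a Structure carrying `charge` and `radius`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(s, path) {
  stopifnot(is_structure(s))
  if (!has_charges(s)) stop("structure has no charges/radii; cannot write PQR")
  a <- s$atoms
  with_chain <- nrow(a) > 0L && any(nzchar(a$chain))
  lines <- if (nrow(a) == 0L) character(0) else if (with_chain) {
    sprintf("ATOM  %6d %-4s %-4s %s %5d %11.3f %11.3f %11.3f %8.4f %7.4f",
            a$serial, a$name, a$resname,
            ifelse(nzchar(a$chain), a$chain, "X"),
            a$resseq, a$x, a$y, a$z, a$charge, a$radius)
  } else {
    sprintf("ATOM  %6d %-4s %-4s %5d %11.3f %11.3f %11.3f %8.4f %7.4f",
            a$serial, a$name, a$resname, a$resseq,
            a$x, a$y, a$z, a$charge, a$radius)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a PDB file
#'
#' Fixed-column PDB parsing (via bio3d). Only MODEL 1 is kept; alternate
#' locations are resolved to the highest-occupancy record, ties broken by the
#' first altloc letter. Atoms carry no charge or radius.
#'
#' @param path path to a PDB file.
#' @param label optional label stored on the Structure.
#' @return a `Structure` with `source_format = "PDB"`.
#' @export
read_pdb <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("PDB parse error: ",
                                           conditionMessage(e)))
  a <- pdb$atom
  if (anyNA(a$x) || anyNA(a$y) || anyNA(a$z))
    stop("unreadable coordinate columns in ", path)
  alt <- ifelse(is.na(a$alt), "", a$alt)
  occ <- ifelse(is.na(a$o), 1, a$o)
  keep <- rep(TRUE, nrow(a))
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  for (k in unique(key[alt != ""])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    best <- idx[order(-occ[idx], alt[idx])][1L]
    keep[setdiff(idx, best)] <- FALSE
  }
  a <- a[keep, , drop = FALSE]
  elem <- ifelse(!is.na(a$elesy) & nzchar(trimws(a$elesy)),
                 toupper(trimws(a$elesy)), infer_element(a$elety))
  atoms <- data.frame(serial = a$eleno, name = a$elety, resname = a$resid,
                      resseq = a$resno,
                      chain = ifelse(is.na(a$chain), "", a$chain),
                      element = elem, x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  new_structure(atoms, "PDB", label)
}

#' Select atoms from a Structure
#'
#' All non-NULL criteria are applied conjunctively; an empty selection returns
#' the structure unchanged. Atom order is preserved and an empty result is
#' valid.
#'
#' @param s a Structure.
#' @param chains character vector of chain ids, or NULL.
#' @param residue_range inclusive `c(lo, hi)` residue-number range, or NULL.
#' @param atom_names character vector of atom names (e.g. `"CA"`), or NULL.
#' @param elements character vector of element symbols, or NULL.
#' @param resnames character vector of residue names, or NULL.
#' @param invert if TRUE, return the complement of the selection (useful to
#'   strip a ligand or waters from a receptor).
#' @return a Structure containing the selected atoms.
#' @export
select_atoms <- function(s, chains = NULL, residue_range = NULL,
                         atom_names = NULL, elements = NULL, resnames = NULL,
                         invert = FALSE) {
  stopifnot(is_structure(s))
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L,
              residue_range[1] <= residue_range[2])
    keep <- keep & a$resseq >= residue_range[1] & a$resseq <= residue_range[2]
  }
  if (!is.null(atom_names)) keep <- keep & a$name %in% atom_names
  if (!is.null(elements)) keep <- keep & a$element %in% toupper(elements)
  if (!is.null(resnames)) keep <- keep & a$resname %in% resnames
  if (invert) keep <- !keep
  new_structure(a[keep, , drop = FALSE], s$source_format, s$label)
}

#' Unweighted centroid of a Structure
#'
#' @param s a Structure with at least one atom.
#' @return length-3 numeric vector, Angstrom.
#' @export
centroid <- function(s) {
  stopifnot(is_structure(s))
  if (nrow(s$atoms) == 0L) stop("centroid of an empty structure is undefined")
  colMeans(coords(s))
}
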