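KNOWN_ELEMENTS <- c("H", "C", "N", "O", "S", "P", "SE", "FE", "ZN", "MG",
                    "CA", "MN", "NA", "K", "CL", "F", "BR", "I", "CU", "NI")

#' Atomic model in a periodic cell
#'
#' The container whose parameters the refinement updates: a unit cell, a
#' symmetry operator set and an ordered atom table. Coordinates are stored
#' fractional (wrapped into [0,1)); orthogonal Angstroms appear only at I/O
#' boundaries and in distance calculations.
#'
#' @param cell A `unit_cell`.
#' @param sym A `symmetry_ops` object.
#' @param atoms data.frame with columns `element`, `u`, `v`, `w` (fractional),
#'   `occ` in \[0,1\], `b_iso` (Angstrom^2, >= 0), `chain`, `resno`, `resname`,
#'   `atom_name`.
#' @return Object of class `atomic_model`.
#' @export
atomic_model <- function(cell, sym, atoms) {
  stopifnot(inherits(cell, "unit_cell"), inherits(sym, "symmetry_ops"))
  need <- c("element", "u", "v", "w", "occ", "b_iso",
            "chain", "resno", "resname", "atom_name")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  if (nrow(atoms)) {
    if (any(atoms$b_iso < 0)) stop("negative b_iso in atom table")
    if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancy outside [0,1]")
    bad <- !toupper(atoms$element) %in% KNOWN_ELEMENTS
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("unknown element '%s' for atom %s %s%d %s",
                   atoms$element[i], atoms$atom_name[i], atoms$chain[i],
                   atoms$resno[i], atoms$resname[i]))
    }
    atoms$element <- toupper(atoms$element)
    atoms[, c("u", "v", "w")] <- wrap_frac(as.matrix(atoms[, c("u", "v", "w")]))
  }
  structure(list(cell = cell, sym = sym, atoms = atoms), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic model: %d atoms, %s,\n  ", nrow(x$atoms), x$sym$name))
  print(x$cell)
  invisible(x)
}

#' Number of atoms in a model
#' @param model An `atomic_model`.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Fractional coordinates of a model as a matrix
#' @param model An `atomic_model`.
#' @return Matrix (n_atoms x 3).
#' @export
model_frac <- function(model) as.matrix(model$atoms[, c("u", "v", "w")])

#' Orthogonal coordinates of a model (Angstroms)
#' @param model An `atomic_model`.
#' @export
model_orth <- function(model) frac_to_orth(model$cell, model_frac(model))

# -- cell/spacegroup records; bio3d parses atoms but not CRYST1/_cell ---------

parse_pdb_cell <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(NULL)
  cl <- cl[1]
  num <- function(i, j) suppressWarnings(as.numeric(substr(cl, i, j)))
  list(cell = c(num(7, 15), num(16, 24), num(25, 33),
                num(34, 40), num(41, 47), num(48, 54)),
       sg = trimws(substr(cl, 56, 66)))
}

cif_item <- function(lines, tag) {
  hit <- grep(paste0("^[[:space:]]*", tag, "[[:space:]]"), lines, value = TRUE)
  if (!length(hit)) return(NA)
  val <- trimws(sub(paste0("^[[:space:]]*", tag), "", hit[1]))
  gsub("^['\"]|['\"]$", "", val)
}

parse_cif_cell <- function(lines) {
  tags <- c("_cell.length_a", "_cell.length_b", "_cell.length_c",
            "_cell.angle_alpha", "_cell.angle_beta", "_cell.angle_gamma")
  vals <- suppressWarnings(as.numeric(vapply(tags, cif_item, "", lines = lines)))
  if (any(is.na(vals))) {
    tags2 <- sub("_cell\\.", "_cell_", tags)
    vals <- suppressWarnings(as.numeric(vapply(tags2, cif_item, "", lines = lines)))
  }
  if (any(is.na(vals))) return(NULL)
  sg <- cif_item(lines, "_symmetry.space_group_name_H-M")
  if (is.na(sg)) sg <- cif_item(lines, "_symmetry_space_group_name_H-M")
  if (is.na(sg)) sg <- cif_item(lines, "_space_group.name_H-M_alt")
  if (is.na(sg)) sg <- "P 1"
  list(cell = vals, sg = sg)
}

#' Read an atomic model from PDB or mmCIF
#'
#' Atom records are parsed by bio3d; the cell and spacegroup records (which
#' bio3d does not return) are read directly. Coordinates are converted to
#' fractional and wrapped into the unit cell. A file without a cell record is
#' an error: the refinement has no meaning without a cell.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif` file.
#' @return An `atomic_model`; atoms in file order.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  cellrec <- if (is_cif) parse_cif_cell(lines) else parse_pdb_cell(lines)
  if (is.null(cellrec) || any(is.na(cellrec$cell)))
    stop("no unit cell record in ", path)
  cell <- do.call(unit_cell, as.list(cellrec$cell))
  sym <- symmetry_ops(if (nzchar(cellrec$sg)) cellrec$sg else "P 1")
  pdb <- if (is_cif) bio3d::read.cif(path, verbose = FALSE)
         else bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (is.null(at) || !nrow(at)) {
    atoms <- data.frame(element = character(), u = numeric(), v = numeric(),
                        w = numeric(), occ = numeric(), b_iso = numeric(),
                        chain = character(), resno = integer(),
                        resname = character(), atom_name = character())
    return(atomic_model(cell, sym, atoms))
  }
  elem <- at$elesy
  fallback <- !nzchar(trimws(ifelse(is.na(elem), "", elem)))
  elem[fallback] <- substr(gsub("[^A-Za-z].*$", "", at$elety[fallback]), 1, 1)
  frac <- orth_to_frac(cell, cbind(at$x, at$y, at$z))
  atoms <- data.frame(element = trimws(elem),
                      u = frac[, 1], v = frac[, 2], w = frac[, 3],
                      occ = ifelse(is.na(at$o), 1, at$o),
                      b_iso = ifelse(is.na(at$b), 0, at$b),
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno,
                      resname = at$resid,
                      atom_name = at$elety,
                      stringsAsFactors = FALSE)
  atomic_model(cell, sym, atoms)
}

#' Write an atomic model as PDB
#'
#' Writes the CRYST1 record followed by the atom records (delegated to
#' bio3d). Round trip preserves coordinates to 1e-3 Angstroms and B factors
#' to 1e-2, the precision of the fixed-width PDB fields.
#'
#' @param model An `atomic_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  cl <- model$cell
  hdr <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                 cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma, model$sym$name)
  ok <- tryCatch({ writeLines(hdr, path); TRUE }, error = function(e) FALSE)
  if (!ok) stop("cannot write model file: ", path)
  at <- model$atoms
  if (nrow(at)) {
    xyz <- frac_to_orth(cl, as.matrix(at[, c("u", "v", "w")]))
    bio3d::write.pdb(file = path, append = TRUE,
                     xyz = as.vector(t(xyz)),
                     type = rep("ATOM", nrow(at)),
                     eleno = seq_len(nrow(at)),
                     elety = at$atom_name,
                     resid = at$resname,
                     chain = at$chain,
                     resno = at$resno,
                     o = at$occ, b = at$b_iso,
                     elesy = at$element, end = TRUE)
  } else {
    cat("END\n", file = path, append = TRUE)
  }
  invisible(path)
}
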