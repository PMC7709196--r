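#' Reflection set
#'
#' Miller indices with observed amplitudes, sigmas and free-R flags, plus the
#' resolution machinery. One record per unique hkl; (0,0,0) is excluded.
#'
#' @param cell A `unit_cell`.
#' @param sym A `symmetry_ops` object.
#' @param refl data.frame with integer columns `h`,`k`,`l`, numeric `fobs`
#'   (>= 0, NA allowed for missing), `sigf` (>= 0) and logical `free`.
#' @return Object of class `reflection_set` with a precomputed `d` column and
#'   `d_min`/`d_max` fields.
#' @export
reflection_set <- function(cell, sym, refl) {
  stopifnot(inherits(cell, "unit_cell"))
  need <- c("h", "k", "l", "fobs", "sigf", "free")
  miss <- setdiff(need, names(refl))
  if (length(miss)) stop("reflection table lacks columns: ", paste(miss, collapse = ", "))
  refl <- as.data.frame(refl)[, need]
  zero <- refl$h == 0 & refl$k == 0 & refl$l == 0
  if (any(zero)) {
    warning("rejecting ", sum(zero), " (0,0,0) reflection record(s)")
    refl <- refl[!zero, , drop = FALSE]
  }
  key <- paste(refl$h, refl$k, refl$l)
  if (anyDuplicated(key)) stop("duplicate hkl records in reflection set")
  refl$free <- as.logical(refl$free)
  refl$d <- d_spacing(cell, as.matrix(refl[, c("h", "k", "l")]))
  rownames(refl) <- NULL
  structure(list(cell = cell, sym = sym, refl = refl,
                 d_min = if (nrow(refl)) min(refl$d) else NA_real_,
                 d_max = if (nrow(refl)) max(refl$d) else NA_real_),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection set: %d reflections, d %.2f - %.2f A, %d free\n",
              nrow(x$refl), x$d_min, x$d_max, sum(x$refl$free, na.rm = TRUE)))
  invisible(x)
}

#' Miller index matrix of a reflection set
#' @param refl A `reflection_set`.
#' @export
hkl_matrix <- function(refl) as.matrix(refl$refl[, c("h", "k", "l")])

#' Read reflection data
#'
#' Reads the package CSV dialect, or an MTZ file via an installed python
#' `gemmi` (converted to the CSV dialect behind the same interface).
#'
#' The CSV dialect: comment lines start with `#`; two are meaningful,
#' `# cell a b c alpha beta gamma` and `# spacegroup NAME`; then a header
#' line `h,k,l,fobs,sigfobs,free` and one unique reflection per row. The
#' `free` column is 0/1 with 1 = free (stated in the header comment written
#' by [write_reflections_csv()]). For MTZ the CCP4 convention applies:
#' `flag == free_value` (default 0) marks the free set.
#'
#' @param path Path to a `.csv` or `.mtz` file.
#' @param cell Optional `unit_cell`, overriding/absent the file's cell record.
#' @param sym Optional `symmetry_ops` (default from file, else P 1).
#' @param free_value Integer flag value marking free reflections in MTZ files.
#' @return A `reflection_set`.
#' @export
read_reflections <- function(path, cell = NULL, sym = NULL, free_value = 0L) {
  if (!file.exists(path)) stop("reflection file not found: ", path)
  if (grepl("\\.mtz$", path, ignore.case = TRUE)) {
    path <- mtz_to_csv(path, free_value)
    on.exit(unlink(path))
  }
  lines <- readLines(path, warn = FALSE)
  comments <- grep("^#", lines, value = TRUE)
  cellline <- grep("^#\\s*cell\\b", comments, value = TRUE, ignore.case = TRUE)
  if (is.null(cell)) {
    if (!length(cellline)) stop("no cell record in ", path,
                                " and no cell= argument given")
    vals <- as.numeric(strsplit(trimws(sub("^#\\s*cell", "", cellline[1],
                                           ignore.case = TRUE)), "\\s+")[[1]])
    if (length(vals) != 6 || any(is.na(vals))) stop("malformed cell comment in ", path)
    cell <- do.call(unit_cell, as.list(vals))
  }
  if (is.null(sym)) {
    sgline <- grep("^#\\s*spacegroup\\b", comments, value = TRUE, ignore.case = TRUE)
    sg <- if (length(sgline)) trimws(sub("^#\\s*spacegroup", "", sgline[1],
                                         ignore.case = TRUE)) else "P 1"
    sym <- symmetry_ops(sg)
  }
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  amp_col <- intersect(c("fobs", "f", "fp"), names(tab))
  if (!length(amp_col))
    stop("no amplitude column in ", path, "; available columns: ",
         paste(names(tab), collapse = ", "))
  sig_col <- intersect(c("sigfobs", "sigf", "sigfp"), names(tab))
  out <- data.frame(h = as.integer(tab$h), k = as.integer(tab$k),
                    l = as.integer(tab$l),
                    fobs = as.numeric(tab[[amp_col[1]]]),
                    sigf = if (length(sig_col)) as.numeric(tab[[sig_col[1]]]) else 0)
  if ("free" %in% names(tab)) {
    out$free <- as.integer(tab$free) == 1L
  } else {
    warning("no free column in ", path, "; all reflections assigned to the work set")
    out$free <- FALSE
  }
  out$free[is.na(out$free)] <- FALSE
  reflection_set(cell, sym, out)
}

mtz_to_csv <- function(path, free_value = 0L) {
  py <- Sys.which("python")
  if (!nzchar(py)) stop("MTZ reading needs a python with gemmi on the PATH")
  out <- tempfile(fileext = ".csv")
  script <- sprintf('
import gemmi, sys
m = gemmi.read_mtz_file(sys.argv[1])
amp = next(c for c in m.columns if c.type == "F")
sig = next((c for c in m.columns if c.type == "Q" and c.label.upper().startswith("SIG")), None)
flg = next((c for c in m.columns if c.type == "I" and "FREE" in c.label.upper()), None)
u = m.cell
with open(sys.argv[2], "w") as f:
    f.write("# cell %%g %%g %%g %%g %%g %%g\\n" %% (u.a, u.b, u.c, u.alpha, u.beta, u.gamma))
    f.write("# spacegroup %%s\\n" %% m.spacegroup.hm)
    f.write("h,k,l,fobs,sigfobs,free\\n")
    import numpy as np
    arr = m.array
    cols = [c.label for c in m.columns]
    for row in arr:
        h, k, l = int(row[0]), int(row[1]), int(row[2])
        fo = row[cols.index(amp.label)]
        if not np.isfinite(fo):
            continue
        sg = row[cols.index(sig.label)] if sig is not None else 0.0
        fr = 1 if (flg is not None and int(row[cols.index(flg.label)]) == %d) else 0
        f.write("%%d,%%d,%%d,%%.6g,%%.6g,%%d\\n" %% (h, k, l, fo, sg, fr))
', as.integer(free_value))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2(py, c(sf, shQuote(path), shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  unlink(sf)
  if (status != 0 || !file.exists(out))
    stop("MTZ conversion via python gemmi failed for ", path)
  out
}

#' Write a reflection set in the package CSV dialect
#'
#' @param refl A `reflection_set`.
#' @param path Output path.
#' @export
write_reflections_csv <- function(refl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cl <- refl$cell
  writeLines(c(sprintf("# cell %g %g %g %g %g %g",
                       cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma),
               sprintf("# spacegroup %s", refl$sym$name),
               "# free column: 1 = free reflection, 0 = work",
               "h,k,l,fobs,sigfobs,free"), con)
  r <- refl$refl
  writeLines(sprintf("%d,%d,%d,%.8g,%.8g,%d", r$h, r$k, r$l,
                     r$fobs, r$sigf, as.integer(r$free)), con)
  invisible(path)
}

#' Truncate a reflection set to a resolution limit
#'
#' Keeps exactly the reflections with d(hkl) >= d.
#'
#' @param refl A `reflection_set`.
#' @param d Resolution limit in Angstroms (> 0).
#' @return A `reflection_set` containing the surviving reflections.
#' @export
truncate_resolution <- function(refl, d) {
  stopifnot(inherits(refl, "reflection_set"), d > 0)
  keep <- refl$refl$d >= d
  if (!any(keep))
    warning(sprintf("no reflections at d >= %.2f A (set extends to %.2f A)",
                    d, refl$d_max))
  reflection_set(refl$cell, refl$sym, refl$refl[keep, names(refl$refl) != "d",
                                                drop = FALSE])
}
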