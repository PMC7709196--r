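#' Crystallographic symmetry operators
#'
#' Minimal symmetry support for the spacegroups the refinement core works in.
#' The shift-field calculation itself operates on the full unit cell with the
#' model expanded to P 1, so only the operator list (rotation + translation in
#' fractional space) is needed: P 1 and the centrosymmetric P -1 are provided,
#' the latter mainly to exercise the centric-reflection likelihood path.
#'
#' @param name Spacegroup symbol, e.g. "P 1" or "P -1" (spacing-insensitive).
#' @return An object of class `symmetry_ops`: list with `name` and `ops`, each
#'   op a list with 3x3 integer `R` and length-3 fractional translation `t`.
#' @export
symmetry_ops <- function(name = "P 1") {
  key <- toupper(gsub("[[:space:]]", "", name))
  ops <- switch(key,
    "P1" = list(list(R = diag(3), t = c(0, 0, 0))),
    "P-1" = list(list(R = diag(3), t = c(0, 0, 0)),
                 list(R = -diag(3), t = c(0, 0, 0))),
    stop("unsupported spacegroup '", name,
         "'; supported: P 1, P -1 (expand other groups to P 1 upstream)"))
  structure(list(name = name, ops = ops), class = "symmetry_ops")
}

#' @export
print.symmetry_ops <- function(x, ...) {
  cat(sprintf("spacegroup %s (%d operator%s)\n", x$name, length(x$ops),
              if (length(x$ops) == 1) "" else "s"))
  invisible(x)
}

#' Number of symmetry operators
#' @param sym A `symmetry_ops` object.
#' @export
n_sym_ops <- function(sym) length(sym$ops)

#' Expand fractional coordinates over the symmetry operators
#'
#' @param sym A `symmetry_ops` object.
#' @param frac Matrix (n x 3) of fractional coordinates.
#' @return Matrix (n * n_ops x 3), wrapped into [0, 1); rows ordered op-major.
#' @export
expand_sym_frac <- function(sym, frac) {
  frac <- rbind2mat(frac)
  out <- lapply(sym$ops, function(op) {
    wrap_frac(frac %*% t(op$R) + matrix(op$t, nrow(frac), 3, byrow = TRUE))
  })
  do.call(rbind, out)
}

#' Polar (floating-origin) axes of a spacegroup
#'
#' Axis k is polar when every symmetry rotation leaves translations along it
#' unchanged, so the structure-factor amplitudes carry no information about
#' the origin along that axis (in P 1 all three axes are polar; in P -1
#' none). Refinement must pin the origin along polar axes or the model
#' drifts freely.
#'
#' @param sym A `symmetry_ops` object.
#' @return Logical 3-vector.
#' @export
polar_axes <- function(sym) {
  vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- 1
    all(vapply(sym$ops, function(op) all(op$R %*% e == e), logical(1)))
  }, logical(1))
}

#' Centric-reflection test
#'
#' A reflection h is centric when some symmetry rotation maps h to -h; its
#' phase is then restricted and the centric likelihood variants apply.
#'
#' @param sym A `symmetry_ops` object.
#' @param hkl Integer matrix (n x 3).
#' @return Logical vector of length n.
#' @export
is_centric <- function(sym, hkl) {
  hkl <- rbind2mat(hkl)
  cen <- rep(FALSE, nrow(hkl))
  for (op in sym$ops) {
    if (all(op$R == diag(3))) next
    hrot <- hkl %*% op$R
    cen <- cen | (rowSums(abs(hrot + hkl)) == 0)
  }
  cen
}
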