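# Four-Gaussian-plus-constant X-ray scattering factors, f(s) = sum a_i
# exp(-b_i s^2/4) + c with s = 1/d. Standard coefficients for the common
# protein elements (International Tables Vol. C tabulation, as distributed
# with the CCP4 atomsf library).
FORM_FACTORS <- list(
  H  = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
            b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P  = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
            b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S  = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
            b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  SE = list(a = c(17.0006, 5.81960, 3.97310, 4.35430),
            b = c(2.40980, 0.272600, 15.2372, 43.8163), c = 2.84090),
  FE = list(a = c(11.7695, 7.35730, 3.52220, 2.30450),
            b = c(4.76110, 0.307200, 15.3535, 76.8805), c = 1.03690),
  MG = list(a = c(5.42040, 2.17350, 1.22690, 2.30730),
            b = c(2.82750, 79.2611, 0.380800, 7.19370), c = 0.858400),
  ZN = list(a = c(14.0743, 7.03180, 5.16520, 2.41000),
            b = c(3.26550, 0.233300, 10.3163, 58.7097), c = 1.30410)
)

#' Atomic scattering factor f(s)
#'
#' Sum-of-Gaussians X-ray form factor evaluated at scattering magnitude
#' s = 1/d: f(s) = sum a_i exp(-b_i s^2 / 4) + c.
#'
#' @param element Element symbol (case-insensitive; must be tabulated).
#' @param s2 Numeric vector of s^2 = 1/d^2 values (inverse square Angstroms).
#' @return Numeric vector of form-factor values (electrons).
#' @export
scatter_factor <- function(element, s2) {
  ff <- FORM_FACTORS[[toupper(element)]]
  if (is.null(ff))
    stop("no form factors tabulated for element '", element, "'")
  out <- rep(ff$c, length(s2))
  for (i in seq_along(ff$a)) out <- out + ff$a[i] * exp(-ff$b[i] * s2 / 4)
  out
}
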