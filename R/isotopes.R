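# Embedded isotope data: monoisotopic masses (amu) and natural abundances
# from the IUPAC/CODATA standard tables (CIAAW 2021 masses, representative
# terrestrial abundances).  The 13C abundance defaults to 1.109%, the ambient
# carbon value used for natural-isotope-abundance (NIA) correction throughout
# this package, and is overridable per call.

.ELECTRON_MASS <- 5.48579909065e-4

.ISOTOPE_DATA <- list(
  H  = list(masses = c(1.00782503223, 2.01410177812),
            abundances = c(0.999885, 0.000115)),
  C  = list(masses = c(12.0, 13.00335483507),
            abundances = c(0.98891, 0.01109)),
  N  = list(masses = c(14.00307400443, 15.00010889888),
            abundances = c(0.99636, 0.00364)),
  O  = list(masses = c(15.99491461957, 16.99913175650, 17.99915961286),
            abundances = c(0.99757, 0.00038, 0.00205)),
  P  = list(masses = c(30.97376199842),
            abundances = c(1.0)),
  S  = list(masses = c(31.9720711744, 32.9714589098, 33.967867004,
                       35.96708071),
            abundances = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Si = list(masses = c(27.97692653465, 28.97649466490, 29.973770136),
            abundances = c(0.92223, 0.04685, 0.03092))
)

#' Isotope mass and abundance table
#'
#' Returns the embedded table of isotope monoisotopic masses (amu) and
#' natural abundance fractions for the elements handled by this package
#' (H, C, N, O, P, S, Si).  Within each element, masses are strictly
#' increasing and abundances sum to one.
#'
#' @param c13 Natural abundance fraction of 13C.  Defaults to 0.01109
#'   (1.109\%), the ambient-carbon value used for NIA correction; the
#'   corresponding 12C abundance is adjusted so the pair sums to one.
#' @return A named list; each entry has components \code{masses} and
#'   \code{abundances}.
#' @export
isotope_table <- function(c13 = 0.01109) {
  stopifnot(is.numeric(c13), length(c13) == 1L, c13 >= 0, c13 < 1)
  tab <- .ISOTOPE_DATA
  tab$C$abundances <- c(1 - c13, c13)
  for (el in names(tab)) {
    e <- tab[[el]]
    if (abs(sum(e$abundances) - 1) > 1e-9)
      stop("isotope abundances of ", el, " do not sum to 1")
    if (is.unsorted(e$masses, strictly = TRUE))
      stop("isotope masses of ", el, " are not strictly increasing")
  }
  tab
}

#' Electron rest mass in amu
#'
#' Used to convert between neutral monoisotopic masses and ion m/z values.
#' @return A single numeric value (amu).
#' @export
electron_mass <- function() .ELECTRON_MASS

#' Mass shift caused by 12C to 13C exchange
#'
#' @param n_13c Number of 12C atoms exchanged for 13C (non-negative integer).
#' @return Mass shift in amu, \code{n_13c * (m(13C) - m(12C))}; one exchange
#'   shifts the mass by +1.0034 amu.
#' @examples
#' round(isotope_mass_shift(1), 4)  # 1.0034
#' round(isotope_mass_shift(3), 4)  # 3.0101
#' @export
isotope_mass_shift <- function(n_13c) {
  stopifnot(is.numeric(n_13c), all(n_13c >= 0))
  d <- .ISOTOPE_DATA$C$masses[2] - .ISOTOPE_DATA$C$masses[1]
  n_13c * d
}
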