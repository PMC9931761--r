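## Default chromophore extinction table for the four acquisition bands.
##
## Hemoglobin molar extinction coefficients at 540/556/560/576 nm are
## taken from the standard compiled whole-blood tabulation (Prahl, OMLC);
## melanin follows the usual descending power law in wavelength
## (Jacques). All values are expressed in units of 1e4 L mol^-1 cm^-1 so
## that effective concentrations of order 0.1 give absorbances of order
## one; the inversion is invariant to this common rescaling, and the
## recovered concentrations are interpreted on an arbitrary linear scale.

.defaultExtinction <- data.frame(
  wavelength_nm = c(540, 556, 560, 576),
  # HbO2 has absorption peaks near 542 and 576 nm; Hb peaks near 556 nm.
  eps_hbo2    = c(5.3236, 3.7020, 3.2613, 5.7634) ,
  eps_hb      = c(4.6592, 5.3412, 5.3788, 3.8220),
  # ~ 1.70e12 * lambda^-3.48, rescaled; decreasing with wavelength.
  eps_melanin = c(1.902, 1.717, 1.675, 1.515)
)

#' Default four-band chromophore basis
#'
#' Extinction coefficients of HbO2, Hb and melanin at the default
#' acquisition wavelengths 540, 556, 560 and 576 nm, on a consistent
#' linear scale (1e4 L mol^-1 cm^-1). The associated design matrix
#' `[eps_hbo2 | eps_hb | eps_melanin | 1]` is well conditioned, so the
#' per-pixel four-band Beer-Lambert system has a unique exact solution.
#'
#' @param wavelengths_nm wavelengths to look up; must be a subset of the
#'   bundled table.
#' @return A [ChromophoreBasis-class].
#' @examples
#' designMatrix(defaultChromophoreBasis())
#' @export
defaultChromophoreBasis <- function(wavelengths_nm = c(540, 556, 560, 576)) {
  idx <- match(wavelengths_nm, .defaultExtinction$wavelength_nm)
  if (any(is.na(idx)))
    stop("no bundled extinction values for wavelengths: ",
         paste(wavelengths_nm[is.na(idx)], collapse = ", "),
         " (supply a ChromophoreBasis explicitly)")
  with(.defaultExtinction[idx, ],
       ChromophoreBasis(wavelength_nm, eps_hbo2, eps_hb, eps_melanin))
}

#' Read / write a chromophore basis as CSV
#'
#' Columns: `wavelength_nm, eps_hbo2, eps_hb, eps_melanin`.
#'
#' @param path CSV path.
#' @param basis a [ChromophoreBasis-class].
#' @return `readBasisCsv` returns a `ChromophoreBasis`; `writeBasisCsv`
#'   invisibly returns `path`.
#' @export
readBasisCsv <- function(path) {
  d <- read.csv(path)
  ChromophoreBasis(d$wavelength_nm, d$eps_hbo2, d$eps_hb, d$eps_melanin)
}

#' @rdname readBasisCsv
#' @export
writeBasisCsv <- function(basis, path) {
  write.csv(data.frame(wavelength_nm = basis@wavelengths_nm,
                       eps_hbo2 = basis@eps_hbo2, eps_hb = basis@eps_hb,
                       eps_melanin = basis@eps_melanin),
            path, row.names = FALSE)
  invisible(path)
}
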