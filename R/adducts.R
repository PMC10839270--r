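## Electrospray adduct arithmetic. Shifts are total mass added to the neutral
## molecule M before division by charge: m/z = (M + shift) / z.

.ADDUCTS <- data.frame(
    adduct = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M+K]+", "[M+H-H2O]+",
               "[M+2H]2+",
               "[M-H]-", "[M+FA-H]-", "[M+Cl]-", "[M-H2O-H]-", "[M-2H]2-"),
    polarity = c(rep("pos", 6L), rep("neg", 5L)),
    shift = c(1.007276, 18.033823, 22.989218, 38.963158, -17.003289,
              2.014552,
              -1.007276, 44.998201, 34.969402, -19.017841, -2.014552),
    charge = c(1, 1, 1, 1, 1, 2, 1, 1, 1, 1, 2),
    stringsAsFactors = FALSE)

#' Known electrospray adducts
#'
#' @return data.frame with columns `adduct`, `polarity`, `shift` (Da added to
#'   the neutral molecule) and `charge`.
#' @export
knownAdducts <- function() .ADDUCTS

.adductRow <- function(adduct) {
    i <- match(adduct, .ADDUCTS$adduct)
    if (any(is.na(i)))
        stop("unknown adduct label(s): ",
             paste(unique(adduct[is.na(i)]), collapse = ", "))
    .ADDUCTS[i, , drop = FALSE]
}

#' Ion m/z of a neutral mass under a given adduct
#'
#' @param exactMass neutral monoisotopic mass in Da.
#' @param adduct adduct label, e.g. `"[M+H]+"`.
#' @return m/z in Da.
#' @export
adductMz <- function(exactMass, adduct) {
    a <- .adductRow(adduct)
    (exactMass + a$shift) / a$charge
}

#' Neutral mass implied by an ion m/z and its adduct
#'
#' @param mz observed m/z in Da.
#' @param adduct adduct label.
#' @return neutral mass in Da.
#' @export
neutralMass <- function(mz, adduct) {
    a <- .adductRow(adduct)
    mz * a$charge - a$shift
}
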