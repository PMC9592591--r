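#' Monoisotopic residue mass table
#'
#' Standard monoisotopic masses (Da) of the glycan residues used in
#' composition strings, plus the small-molecule constants needed for
#' neutral-mass and m/z arithmetic. Residue masses are the dehydrated
#' (in-chain) masses, so a free glycan's neutral mass is the sum of its
#' residue masses plus one water. The values are the community constants
#' used by composition-matching tools such as GlycoMod.
#'
#' @param overrides optional named list overriding individual entries
#'   (names as in the returned vector), e.g. from a JSON config `masses`
#'   section.
#'
#' @return Named numeric vector with elements `hex`, `hexnac`, `dhex`,
#'   `neu5ac`, `neu5gc`, `water`, `proton`, `sodium_cation`.
#' @export
#' @examples
#' residue_masses()[["hex"]]
#' residue_masses(list(hex = 162.1))[["hex"]]
residue_masses <- function(overrides = NULL) {
  m <- c(
    hex           = 162.05282,
    hexnac        = 203.07937,
    dhex          = 146.05791,
    neu5ac        = 291.09542,
    neu5gc        = 307.09033,
    water         = 18.01056,
    proton        = 1.00728,
    sodium_cation = 22.98922
  )
  if (!is.null(overrides) && length(overrides) > 0) {
    if (is.null(names(overrides)) || !all(nzchar(names(overrides)))) {
      stop("mass overrides must be a named list", call. = FALSE)
    }
    bad <- setdiff(names(overrides), names(m))
    if (length(bad) > 0) {
      stop("unknown mass entries: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    m[names(overrides)] <- unlist(overrides)
  }
  if (any(m <= 0)) stop("all masses must be positive", call. = FALSE)
  m
}

#' Derivatization model for glycoblotting MALDI-TOF chemistry
#'
#' Describes the mass consequences of the on-bead chemistry applied before
#' MALDI-TOF acquisition: reducing-end labeling with an aminooxy tag
#' (`tag_delta`, the NET mass change including loss of the condensation
#' water, so it is added once without further water bookkeeping),
#' methyl-esterification of every sialic-acid carboxyl (`methyl_delta` per
#' Neu5Ac or Neu5Gc residue; both carry a carboxyl and are esterified
#' alike), and the charge carrier.
#'
#' `tag_delta` defaults to 0 because the label's elemental composition is
#' a property of the reagent lot, not of the glycan: calibrate it from a
#' known (composition, observed m/z) pair with [calibrate_tag_delta()].
#'
#' @param tag_delta net reducing-end labeling mass change (Da).
#' @param methyl_delta mass added per sialic-acid carboxyl methyl ester
#'   (Da); default +14.01565 (CH2).
#' @param adduct `"protonated"` or `"sodiated"`.
#' @param charge positive integer charge state.
#' @param adduct_delta mass of the charge carrier (Da); defaults to the
#'   proton or sodium-cation mass according to `adduct`.
#' @param masses residue mass table, see [residue_masses()].
#'
#' @return Object of class `derivatization_model`.
#' @export
#' @examples
#' derivatization_model()
#' derivatization_model(tag_delta = 389.2, adduct = "sodiated")
derivatization_model <- function(tag_delta = 0,
                                 methyl_delta = 14.01565,
                                 adduct = c("protonated", "sodiated"),
                                 charge = 1L,
                                 adduct_delta = NULL,
                                 masses = residue_masses()) {
  adduct <- match.arg(adduct)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be >= 1", call. = FALSE)
  if (is.null(adduct_delta)) {
    adduct_delta <- switch(adduct,
      protonated = masses[["proton"]],
      sodiated   = masses[["sodium_cation"]]
    )
  }
  structure(
    list(
      tag_delta = as.numeric(tag_delta),
      methyl_delta = as.numeric(methyl_delta),
      adduct = adduct,
      adduct_delta = as.numeric(adduct_delta),
      charge = charge
    ),
    class = "derivatization_model"
  )
}

#' @export
print.derivatization_model <- function(x, ...) {
  cat(sprintf(
    "Derivatization model: tag %+.5f Da, methyl ester %+.5f Da/sialic acid, %s (%+.5f Da), charge %d\n",
    x$tag_delta, x$methyl_delta, x$adduct, x$adduct_delta, x$charge
  ))
  invisible(x)
}
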