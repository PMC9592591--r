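#' Glycan monosaccharide compositions
#'
#' A composition counts the residues of an N-glycan by class, written in
#' the field's single-letter code: H = hexose (Man/Gal/Glc), N = HexNAc
#' (GlcNAc/GalNAc), D = deoxyhexose (Fuc), A = Neu5Ac, G = Neu5Gc. A
#' composition identifies a glycoform, not a structure: linkage isomers
#' share one composition.
#'
#' Compositions are represented as a data frame with integer columns
#' `h`, `n`, `d`, `a`, `g`, one row per composition, so all mass and
#' classification operations are vectorized. Any counts are representable
#' (solver intermediates included); biosynthetic validity (n >= 2, h >= 3)
#' is a queryable predicate, [is_valid_nglycan()], not a construction
#' constraint.
#'
#' @param h,n,d,a,g non-negative integer residue counts (recycled).
#' @return A `glycan_composition` data frame.
#' @export
#' @examples
#' glycan_composition(h = 5, n = 4, d = 1, a = 2)
#' parse_composition(c("H5N4D1A2", "H3N2"))
glycan_composition <- function(h = 0L, n = 0L, d = 0L, a = 0L, g = 0L) {
  comp <- data.frame(
    h = as.integer(h), n = as.integer(n), d = as.integer(d),
    a = as.integer(a), g = as.integer(g)
  )
  if (anyNA(comp)) stop("residue counts must be integers", call. = FALSE)
  if (any(comp < 0L)) stop("residue counts must be >= 0", call. = FALSE)
  class(comp) <- c("glycan_composition", "data.frame")
  comp
}

LETTER_FIELDS <- c(H = "h", N = "n", D = "d", A = "a", G = "g")

as_composition <- function(x) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.character(x)) return(parse_composition(x))
  if (is.data.frame(x) && all(c("h", "n", "d", "a", "g") %in% names(x))) {
    return(glycan_composition(x$h, x$n, x$d, x$a, x$g))
  }
  stop("cannot interpret input as glycan composition(s)", call. = FALSE)
}

#' Parse single-letter composition strings
#'
#' Accepts the canonical grammar: letters H, N, D, A, G, each at most
#' once, each followed by a positive integer; an omitted letter means a
#' zero count. Letters may appear in any order on input; formatting is
#' canonical (fixed order H, N, D, A, G; zero counts omitted), so
#' `format_composition(parse_composition(x))` is the canonical form and
#' parse/format round-trip exactly.
#'
#' @param text character vector of composition strings.
#' @return A `glycan_composition` data frame with one row per string.
#' @export
#' @examples
#' parse_composition("H5N4D1A2")
#' format_composition(parse_composition("H6N5G2"))
parse_composition <- function(text) {
  if (!is.character(text) || length(text) == 0) {
    stop("composition text must be a non-empty character vector", call. = FALSE)
  }
  counts <- matrix(0L, nrow = length(text), ncol = 5,
                   dimnames = list(NULL, LETTER_FIELDS))
  for (i in seq_along(text)) {
    s <- text[[i]]
    if (is.na(s) || !nzchar(s)) {
      stop(sprintf("composition %d is empty", i), call. = FALSE)
    }
    tokens <- regmatches(s, gregexpr("[A-Za-z][0-9]*|[^A-Za-z]+", s))[[1]]
    seen <- character(0)
    for (tok in tokens) {
      letter <- substr(tok, 1, 1)
      if (!letter %in% names(LETTER_FIELDS)) {
        stop(sprintf("malformed composition '%s': unexpected token '%s'", s, tok),
             call. = FALSE)
      }
      num <- substring(tok, 2)
      if (!grepl("^[0-9]+$", num) || as.integer(num) < 1L) {
        stop(sprintf("malformed composition '%s': letter %s needs a positive integer, got '%s'",
                     s, letter, tok), call. = FALSE)
      }
      if (letter %in% seen) {
        stop(sprintf("malformed composition '%s': letter %s repeated", s, letter),
             call. = FALSE)
      }
      seen <- c(seen, letter)
      counts[i, LETTER_FIELDS[[letter]]] <- as.integer(num)
    }
  }
  glycan_composition(counts[, "h"], counts[, "n"], counts[, "d"],
                     counts[, "a"], counts[, "g"])
}

#' @rdname parse_composition
#' @param comp compositions (`glycan_composition`, plain data frame with
#'   columns h/n/d/a/g, or character, in which case strings are
#'   canonicalized).
#' @export
format_composition <- function(comp) {
  comp <- as_composition(comp)
  out <- character(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    parts <- character(0)
    for (letter in names(LETTER_FIELDS)) {
      cnt <- comp[[LETTER_FIELDS[[letter]]]][i]
      if (cnt > 0L) parts <- c(parts, paste0(letter, cnt))
    }
    out[i] <- if (length(parts)) paste(parts, collapse = "") else ""
  }
  out
}

#' @rdname parse_composition
#' @details A biosynthetically valid N-glycan keeps the chitobiose core
#'   (two GlcNAc) and at least the trimannosyl core truncated no further
#'   than H3 is not required: validity here is `n >= 2 & h >= 3`, which
#'   admits paucimannose H3N2 but not free solver intermediates.
#' @export
is_valid_nglycan <- function(comp) {
  comp <- as_composition(comp)
  comp$n >= 2L & comp$h >= 3L
}

#' Neutral monoisotopic mass of a composition
#'
#' Sum of dehydrated residue masses plus one water; strictly increasing
#' in every residue count. The empty composition returns the water mass.
#'
#' @param comp compositions (see [parse_composition()]).
#' @param masses residue mass table, see [residue_masses()].
#' @return Numeric vector of masses (Da).
#' @export
#' @examples
#' neutral_mass("H3N2")   # 910.3278
#' neutral_mass("H5N2")
neutral_mass <- function(comp, masses = residue_masses()) {
  comp <- as_composition(comp)
  comp$h * masses[["hex"]] + comp$n * masses[["hexnac"]] +
    comp$d * masses[["dhex"]] + comp$a * masses[["neu5ac"]] +
    comp$g * masses[["neu5gc"]] + masses[["water"]]
}

#' Derivatized m/z of a composition
#'
#' Applies the glycoblotting chemistry to the neutral mass: the net
#' reducing-end tag once, one methyl ester per sialic acid (a + g of
#' them), the charge carrier, divided by the charge:
#' `(neutral + tag + (a+g)*methyl + adduct) / z`.
#'
#' @inheritParams neutral_mass
#' @param model a [derivatization_model()].
#' @return Numeric vector of m/z values.
#' @export
#' @examples
#' derivatized_mz("H3N2", derivatization_model())  # neutral + proton
derivatized_mz <- function(comp, model = derivatization_model(),
                           masses = residue_masses()) {
  stopifnot(inherits(model, "derivatization_model"))
  comp <- as_composition(comp)
  nm <- neutral_mass(comp, masses)
  (nm + model$tag_delta + (comp$a + comp$g) * model$methyl_delta +
      model$adduct_delta) / model$charge
}
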