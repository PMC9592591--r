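#' Default composition search bounds
#'
#' Per-letter count ranges for de novo composition solving, covering the
#' mammalian N-glycan space seen in tissue glycomics (up to Man-9/12,
#' tetra-antennary, multiply fucosylated and sialylated forms).
#'
#' @param h,n,d,a,g length-2 integer vectors `c(min, max)`.
#' @return Named list of ranges.
#' @export
composition_bounds <- function(h = c(3L, 12L), n = c(2L, 10L), d = c(0L, 5L),
                               a = c(0L, 5L), g = c(0L, 5L)) {
  b <- list(h = h, n = n, d = d, a = a, g = g)
  for (nm in names(b)) {
    r <- as.integer(b[[nm]])
    if (length(r) != 2 || anyNA(r) || r[1] < 0 || r[2] < r[1]) {
      stop("bounds for ", nm, " must be a finite c(min, max) with 0 <= min <= max",
           call. = FALSE)
    }
    b[[nm]] <- r
  }
  b
}

#' Enumerate the plausible composition grid
#'
#' All compositions inside the bounds that pass the biosynthetic
#' plausibility constraints used for de novo assignment:
#' n >= 2 and h >= 3 (valid N-glycan), d <= n (each fucose needs a
#' GlcNAc attachment point), and a + g <= max(n - 2, 0) + 1 (sialic acids
#' capped by the antenna count, plus one to admit hybrid monosialyl
#' forms such as H5N3G1).
#'
#' @param bounds per-letter ranges from [composition_bounds()].
#' @return A `glycan_composition` data frame.
#' @export
composition_grid <- function(bounds = composition_bounds()) {
  grid <- expand.grid(
    h = seq(bounds$h[1], bounds$h[2]),
    n = seq(bounds$n[1], bounds$n[2]),
    d = seq(bounds$d[1], bounds$d[2]),
    a = seq(bounds$a[1], bounds$a[2]),
    g = seq(bounds$g[1], bounds$g[2]),
    KEEP.OUT.ATTRS = FALSE
  )
  keep <- grid$n >= 2L & grid$h >= 3L & grid$d <= grid$n &
    (grid$a + grid$g) <= pmax(grid$n - 2L, 0L) + 1L
  grid <- grid[keep, , drop = FALSE]
  rownames(grid) <- NULL
  glycan_composition(grid$h, grid$n, grid$d, grid$a, grid$g)
}

mass_error <- function(observed, theoretical) {
  err_da <- observed - theoretical
  data.frame(error_da = err_da, error_ppm = 1e6 * err_da / theoretical)
}

tol_in_da <- function(tol, tol_unit, mz) {
  if (!is.numeric(tol) || length(tol) != 1 || is.na(tol) || tol <= 0) {
    stop("tolerance must be a single positive number", call. = FALSE)
  }
  switch(tol_unit, Da = tol, ppm = tol * 1e-6 * mz)
}

#' Solve monosaccharide compositions for an observed m/z
#'
#' GlycoMod-style enumeration: returns every composition within `bounds`
#' (after plausibility filtering, see [composition_grid()]) whose
#' derivatized m/z under `model` lies within the tolerance of the
#' observed m/z. Candidates are sorted by absolute mass error; ties are
#' broken by fewer total residues, then by canonical composition string,
#' so the ranking is deterministic.
#'
#' @param mz observed m/z (single value).
#' @param model a [derivatization_model()].
#' @param tol tolerance, in `tol_unit`.
#' @param tol_unit `"Da"` or `"ppm"`; default 0.1 Da, the reflector-mode
#'   MALDI scale matching m/z reported to two decimals.
#' @param bounds search bounds, see [composition_bounds()].
#' @param masses residue mass table.
#' @return Data frame with columns `composition`, `h`..`g`, `mz_theoretical`,
#'   `error_da`, `error_ppm`; zero rows when nothing matches.
#' @export
#' @examples
#' m <- derivatization_model()
#' solve_compositions(derivatized_mz("H3N2", m), m)
solve_compositions <- function(mz, model = derivatization_model(),
                               tol = 0.1, tol_unit = c("Da", "ppm"),
                               bounds = composition_bounds(),
                               masses = residue_masses()) {
  tol_unit <- match.arg(tol_unit)
  stopifnot(length(mz) == 1, is.numeric(mz))
  grid <- composition_grid(bounds)
  theo <- derivatized_mz(grid, model, masses)
  tol_da <- tol_in_da(tol, tol_unit, mz)
  hit <- abs(mz - theo) <= tol_da
  cand <- grid[hit, , drop = FALSE]
  theo <- theo[hit]
  err <- mass_error(mz, theo)
  out <- cbind(
    data.frame(composition = format_composition(cand), stringsAsFactors = FALSE),
    as.data.frame(cand),
    data.frame(mz_theoretical = theo), err
  )
  total <- out$h + out$n + out$d + out$a + out$g
  out <- out[order(abs(out$error_da), total, out$composition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a peak list with glycan compositions
#'
#' Each analyte peak is first matched against a library of known
#' compositions within the tolerance (source `"library"`; nearest library
#' mass wins). Peaks with no library match optionally fall back to de
#' novo enumeration with [solve_compositions()] (source `"de_novo"`,
#' taking the top-ranked candidate). The internal-standard peak is never
#' annotated as an analyte.
#'
#' @param peaks data frame with columns `mz`, `area` and optional
#'   `is_internal_standard` (0/1); typically one sample's rows from
#'   [read_peaklists()].
#' @param model a [derivatization_model()].
#' @param library character vector of known composition strings
#'   (duplicates are dropped with a warning), or `NULL` for de novo only.
#' @param tol,tol_unit,bounds,masses as in [solve_compositions()].
#' @param de_novo fall back to enumeration for unmatched peaks?
#' @return `peaks` with added columns `composition` (NA when unassigned),
#'   `source` ("library", "de_novo", "internal_standard", or "none"),
#'   `error_da`, `error_ppm`.
#' @export
annotate_peaklist <- function(peaks, model = derivatization_model(),
                              library = NULL,
                              tol = 0.1, tol_unit = c("Da", "ppm"),
                              bounds = composition_bounds(),
                              masses = residue_masses(),
                              de_novo = TRUE) {
  tol_unit <- match.arg(tol_unit)
  stopifnot(is.data.frame(peaks), all(c("mz", "area") %in% names(peaks)))
  if (any(peaks$mz <= 0)) stop("peak m/z must be positive", call. = FALSE)
  is_std <- if ("is_internal_standard" %in% names(peaks)) {
    peaks$is_internal_standard %in% c(1, TRUE)
  } else rep(FALSE, nrow(peaks))
  if (sum(is_std) > 1) {
    stop("at most one internal-standard peak per sample", call. = FALSE)
  }

  lib_mz <- NULL
  if (!is.null(library) && length(library) > 0) {
    canon <- format_composition(parse_composition(library))
    if (anyDuplicated(canon)) {
      warning("duplicate library compositions dropped: ",
              paste(unique(canon[duplicated(canon)]), collapse = ", "))
      canon <- unique(canon)
    }
    library <- canon
    lib_mz <- derivatized_mz(parse_composition(library), model, masses)
  }

  out <- peaks
  out$composition <- NA_character_
  out$source <- "none"
  out$error_da <- NA_real_
  out$error_ppm <- NA_real_

  for (i in seq_len(nrow(peaks))) {
    if (is_std[i]) {
      out$source[i] <- "internal_standard"
      next
    }
    mz_i <- peaks$mz[i]
    tol_da <- tol_in_da(tol, tol_unit, mz_i)
    if (!is.null(lib_mz)) {
      err <- mz_i - lib_mz
      j <- which.min(abs(err))
      if (length(j) == 1 && abs(err[j]) <= tol_da) {
        out$composition[i] <- library[j]
        out$source[i] <- "library"
        out$error_da[i] <- err[j]
        out$error_ppm[i] <- 1e6 * err[j] / lib_mz[j]
        next
      }
    }
    if (de_novo) {
      cand <- solve_compositions(mz_i, model, tol, tol_unit, bounds, masses)
      if (nrow(cand) > 0) {
        out$composition[i] <- cand$composition[1]
        out$source[i] <- "de_novo"
        out$error_da[i] <- cand$error_da[1]
        out$error_ppm[i] <- cand$error_ppm[1]
      }
    }
  }
  out
}

#' Calibrate the reducing-end tag mass from a known assignment
#'
#' The aminooxy tag's elemental composition is reagent-specific, so its
#' net mass delta is recovered algebraically from one peak whose
#' composition is known: `tag_delta = mz * z - neutral - (a+g)*methyl -
#' adduct`. A second known pair, if given, must reproduce the same delta
#' within `check_tol`, otherwise calibration fails with the residual.
#'
#' @param comp known composition (string or `glycan_composition` row).
#' @param observed_mz its observed m/z.
#' @param model a [derivatization_model()] whose `tag_delta` is ignored.
#' @param check optional list(comp =, observed_mz =) second known pair.
#' @param check_tol agreement tolerance in Da (default 0.05).
#' @param masses residue mass table.
#' @return The calibrated `tag_delta` (Da).
#' @export
calibrate_tag_delta <- function(comp, observed_mz,
                                model = derivatization_model(),
                                check = NULL, check_tol = 0.05,
                                masses = residue_masses()) {
  infer <- function(cmp, mz) {
    cmp <- as_composition(cmp)
    stopifnot(nrow(cmp) == 1)
    mz * model$charge - neutral_mass(cmp, masses) -
      (cmp$a + cmp$g) * model$methyl_delta - model$adduct_delta
  }
  delta <- infer(comp, observed_mz)
  if (!is.null(check)) {
    delta2 <- infer(check$comp, check$observed_mz)
    if (abs(delta - delta2) > check_tol) {
      stop(sprintf(
        "tag-delta calibration inconsistent: pairs disagree by %.4f Da (tolerance %.4f)",
        abs(delta - delta2), check_tol
      ), call. = FALSE)
    }
    delta <- mean(c(delta, delta2))
  }
  delta
}

#' Count sialyl linkage isomers of a complex composition
#'
#' A composition only fixes residue counts; the sialylated positions and
#' their anomeric linkage do not. On a complex topology with its
#' antennary galactoses (inferred Gal sites = h - 3), each of the a + g
#' sialic acids occupies a distinct Gal site and is attached either
#' alpha-2,3 or alpha-2,6, giving `choose(h-3, a+g) * 2^(a+g)` distinct
#' assignments (0 when the sialic acids outnumber the sites). The
#' disialylated biantennary H5N4A2 therefore has 4.
#'
#' @param comp a single complex-type composition.
#' @return Integer isomer count.
#' @export
#' @examples
#' count_sialyl_linkage_isomers("H5N4A2")  # 4
count_sialyl_linkage_isomers <- function(comp) {
  comp <- as_composition(comp)
  stopifnot(nrow(comp) == 1)
  if (classify_type(comp) != "complex") {
    stop("sialyl linkage isomer model is defined for complex-type compositions only",
         call. = FALSE)
  }
  sites <- comp$h - 3L
  ns <- comp$a + comp$g
  if (ns > sites) return(0L)
  as.integer(choose(sites, ns) * 2^ns)
}
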