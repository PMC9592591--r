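#' Classify a composition into the four glycan types
#'
#' Composition-level rule table following the mammalian biosynthetic
#' pathway from high-mannose through hybrid to complex forms:
#' \itemize{
#'   \item n = 2, h <= 3: paucimannose (trimmed core, optionally fucosylated);
#'   \item n = 2, h >= 4: high-mannose (Man-4 truncations upward);
#'   \item n >= 3 and (h - 3) > (n - 2): hybrid — more hexoses than the
#'     antennae could carry as galactose, so a mannose arm remains;
#'   \item otherwise: complex.
#' }
#' The rules partition the valid composition space (exactly one label per
#' composition). Individual compositions can be reassigned through
#' `exceptions`, a named character vector mapping canonical composition
#' strings to types, for the rare forms whose known structure contradicts
#' the composition heuristic.
#'
#' @param comp compositions (string, `glycan_composition`, or data frame
#'   with columns h/n/d/a/g).
#' @param exceptions named character vector: composition string -> type.
#' @return Character vector of types.
#' @export
#' @examples
#' classify_type(c("H3N2", "H9N2", "H5N4A2", "H5N3G1"))
classify_type <- function(comp, exceptions = NULL) {
  comp <- as_composition(comp)
  if (!all(is_valid_nglycan(comp))) {
    bad <- format_composition(comp[!is_valid_nglycan(comp), , drop = FALSE])
    stop("not valid N-glycan composition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  type <- ifelse(
    comp$n == 2L,
    ifelse(comp$h <= 3L, "paucimannose", "high_mannose"),
    ifelse((comp$h - 3L) > (comp$n - 2L), "hybrid", "complex")
  )
  if (!is.null(exceptions) && length(exceptions) > 0) {
    allowed <- c("paucimannose", "high_mannose", "hybrid", "complex")
    if (!all(exceptions %in% allowed)) {
      stop("exception types must be one of: ", paste(allowed, collapse = ", "),
           call. = FALSE)
    }
    key <- format_composition(comp)
    hit <- key %in% names(exceptions)
    type[hit] <- unname(exceptions[key[hit]])
  }
  type
}

#' Most matured terminal sugar of a composition
#'
#' Terminal residues follow the maturation hierarchy
#' Neu5Gc/Neu5Ac > Gal > GlcNAc > Man: a sialic acid caps a galactose,
#' which caps an antennary GlcNAc, which extends the mannose core.
#' At composition level: Neu5Gc if g > 0; else Neu5Ac if a > 0; else Gal
#' when the type is complex or hybrid and h >= 4 (h = 3 leaves only the
#' trimannosyl core, so no galactose can be inferred); else GlcNAc when
#' n >= 3; else Man.
#'
#' @inheritParams classify_type
#' @return Character vector in
#'   `c("Neu5Gc", "Neu5Ac", "Gal", "GlcNAc", "Man")`.
#' @export
#' @examples
#' terminal_sugar(c("H5N2", "H5N4A2", "H3N4D1", "H6N5G2"))
terminal_sugar <- function(comp, exceptions = NULL) {
  comp <- as_composition(comp)
  type <- classify_type(comp, exceptions)
  ifelse(comp$g > 0L, "Neu5Gc",
    ifelse(comp$a > 0L, "Neu5Ac",
      ifelse(type %in% c("complex", "hybrid") & comp$h >= 4L, "Gal",
        ifelse(comp$n >= 3L, "GlcNAc", "Man"))))
}

#' Full glycotype assignment for compositions
#'
#' One row per composition with all five grouping axes used in atlas
#' glycotyping: glycan type, most matured terminal sugar, antenna count
#' (n - 2; a bisecting GlcNAc is indistinguishable from an antenna at
#' composition level), sialic-acid count (a + g) and fucose count (d).
#'
#' @inheritParams classify_type
#' @return Data frame: `composition`, `glycan_type`, `terminal`,
#'   `antennae`, `n_sialic`, `n_fuc`.
#' @export
glycotype_assignments <- function(comp, exceptions = NULL) {
  comp <- as_composition(comp)
  data.frame(
    composition = format_composition(comp),
    glycan_type = classify_type(comp, exceptions),
    terminal = terminal_sugar(comp, exceptions),
    antennae = comp$n - 2L,
    n_sialic = comp$a + comp$g,
    n_fuc = comp$d,
    stringsAsFactors = FALSE
  )
}

#' Glycotype percentage summary of a profile
#'
#' For every sample and each of the five panels (glycan type, terminal
#' sugar, antennae, sialic-acid count, fucose count), the percentage of
#' the sample's total glycan amount carried by each category:
#' `100 * amount in category / total amount`. The internal standard is
#' never part of a `glyco_profile`, so totals are analyte-only. Each
#' panel's percentages sum to 100 for samples with nonzero total;
#' zero-total samples are flagged and excluded from class averages.
#'
#' @param profile a `glyco_profile`.
#' @param exceptions glycan-type exception list, see [classify_type()].
#' @return List with `per_sample` (long data frame: sample_id,
#'   class_label, panel, category, percent), `per_class` (category
#'   percentages averaged over each class's replicates) and
#'   `zero_total_samples`.
#' @export
glycotype_summary <- function(profile, exceptions = NULL) {
  stopifnot(inherits(profile, "glyco_profile"))
  assign <- glycotype_assignments(parse_composition(colnames(profile$abundance)),
                                  exceptions)
  panels <- list(
    glycan_type = assign$glycan_type,
    terminal = assign$terminal,
    antennae = as.character(assign$antennae),
    n_sialic = as.character(assign$n_sialic),
    n_fuc = as.character(assign$n_fuc)
  )
  totals <- rowSums(profile$abundance)
  zero_total <- profile$samples$sample_id[totals == 0]

  rows <- list()
  for (panel in names(panels)) {
    cats <- panels[[panel]]
    for (cat_i in sort(unique(cats))) {
      amt <- rowSums(profile$abundance[, cats == cat_i, drop = FALSE])
      pct <- ifelse(totals > 0, 100 * amt / totals, NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = profile$samples$sample_id,
        class_label = profile$samples$class_label,
        panel = panel, category = cat_i, percent = pct,
        stringsAsFactors = FALSE
      )
    }
  }
  per_sample <- do.call(rbind, rows)
  rownames(per_sample) <- NULL

  ok <- per_sample[!is.na(per_sample$percent), , drop = FALSE]
  per_class <- stats::aggregate(percent ~ class_label + panel + category,
                                data = ok, FUN = mean)
  per_class <- per_class[order(per_class$panel, per_class$class_label,
                               per_class$category), ]
  rownames(per_class) <- NULL

  list(per_sample = per_sample, per_class = per_class,
       zero_total_samples = zero_total)
}
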