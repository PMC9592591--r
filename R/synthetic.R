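#' Specification of a synthetic glycome atlas
#'
#' Defines the generative conditions emulating a tissue glycome atlas:
#' 18 sample classes (organs/tissues/serum/exosomes) times 5 replicates
#' over a 103-glycoform composition library, log-normal abundances
#' spanning roughly four decades with a 0.04 pmol detection limit (the
#' observed atlas range is 0.04-903 pmol per 100 ug protein), sparse
#' class-specific marker glycoforms, and multiplicative replicate noise.
#'
#' @param n_classes number of sample classes (default 18).
#' @param replicates replicates per class (default 5).
#' @param library_size glycoform library size (default 103).
#' @param marker_count class-specific marker glycoforms per class.
#' @param fold_change multiplicative shift applied to a class's markers;
#'   1 means no class signal.
#' @param baseline_meanlog,baseline_sdlog log-abundance location/spread
#'   of the per-glycoform baseline (natural log, pmol). The defaults put
#'   roughly a quarter of cells above the 0.04 pmol detection floor, so
#'   per-sample detected glycoform counts and the 0.04-900 pmol dynamic
#'   range land on the atlas scale.
#' @param class_sdlog per-(class, glycoform) log-scale deviation giving
#'   every class its own profile shape beyond the markers.
#' @param replicate_cv coefficient of variation of multiplicative
#'   replicate noise.
#' @param detection_limit amounts below this (pmol) are non-detections.
#' @param dropout_prob optional extra probabilistic dropout applied to
#'   detected cells (default 0, threshold-only dropout).
#' @param seed integer seed; identical spec + seed gives an identical atlas.
#' @return Object of class `synthetic_atlas_spec`.
#' @export
synthetic_atlas_spec <- function(n_classes = 18L, replicates = 5L,
                                 library_size = 103L,
                                 marker_count = 6L, fold_change = 16,
                                 baseline_meanlog = log(0.01),
                                 baseline_sdlog = 2.5,
                                 class_sdlog = 0.6,
                                 replicate_cv = 0.25,
                                 detection_limit = 0.04,
                                 dropout_prob = 0,
                                 seed = 1L) {
  spec <- list(
    n_classes = as.integer(n_classes), replicates = as.integer(replicates),
    library_size = as.integer(library_size),
    marker_count = as.integer(marker_count), fold_change = fold_change,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    class_sdlog = class_sdlog, replicate_cv = replicate_cv,
    detection_limit = detection_limit, dropout_prob = dropout_prob,
    seed = as.integer(seed)
  )
  if (spec$n_classes < 1 || spec$replicates < 1 || spec$library_size < 1) {
    stop("counts must be positive", call. = FALSE)
  }
  if (spec$replicate_cv < 0) stop("replicate_cv must be >= 0", call. = FALSE)
  if (spec$detection_limit < 0) stop("detection_limit must be >= 0", call. = FALSE)
  if (spec$marker_count > spec$library_size) {
    stop("marker_count cannot exceed library_size", call. = FALSE)
  }
  structure(spec, class = "synthetic_atlas_spec")
}

#' Generate a biosynthetically valid composition library
#'
#' Samples `size` unique compositions from the plausible grid (see
#' [composition_grid()]) with per-type quotas so the library's glycan-type
#' mix resembles a real atlas library rather than the raw grid, which is
#' combinatorially dominated by large sialylated complex forms: roughly
#' 2% paucimannose, 10% high-mannose (the Man-4 to Man-9 series and
#' relatives), 15% hybrid, the rest complex. Every type present in the
#' grid gets at least one member. Deterministic per seed.
#'
#' @param size library size (default 103).
#' @param seed integer seed.
#' @param bounds search bounds, see [composition_bounds()].
#' @return Character vector of canonical composition strings.
#' @export
generate_library <- function(size = 103L, seed = 1L,
                             bounds = composition_bounds()) {
  size <- as.integer(size)
  if (size < 1) stop("size must be >= 1", call. = FALSE)
  grid <- composition_grid(bounds)
  strings <- format_composition(grid)
  if (size > length(strings)) {
    stop(sprintf("size %d exceeds the %d enumerable valid compositions",
                 size, length(strings)), call. = FALSE)
  }
  if (size == 1L) return("H3N2")
  types <- classify_type(grid)
  target <- c(paucimannose = 0.02, high_mannose = 0.10, hybrid = 0.15,
              complex = 0.73)
  with_private_seed(seed, {
    chosen <- character(0)
    for (tp in names(target)) {
      pool <- strings[types == tp]
      quota <- min(length(pool), max(1L, round(target[[tp]] * size)),
                   size - length(chosen))
      if (quota > 0) chosen <- c(chosen, pool[sample.int(length(pool), quota)])
    }
    rest <- setdiff(strings, chosen)
    short <- size - length(chosen)
    if (short > 0) chosen <- c(chosen, rest[sample.int(length(rest), short)])
    sort(chosen)
  })
}

#' Generate a class-structured synthetic atlas
#'
#' Draws per-glycoform baseline log-abundances shared across classes,
#' adds per-class deviations and marker shifts, then per-replicate
#' multiplicative log-normal noise. Amounts below the detection limit
#' become non-detections (amount 0, mask FALSE) — threshold dropout
#' matching deterministic grey-as-absent heatmap semantics — with
#' optional extra probabilistic dropout via `dropout_prob`.
#'
#' @param spec a [synthetic_atlas_spec()].
#' @param library optional composition library (defaults to
#'   `generate_library(spec$library_size, spec$seed)`).
#' @return List with `profile` (a `glyco_profile`) and `truth` (class
#'   mean log-abundances, marker identities, the library and the spec).
#' @export
generate_atlas <- function(spec = synthetic_atlas_spec(), library = NULL) {
  stopifnot(inherits(spec, "synthetic_atlas_spec"))
  if (is.null(library)) library <- generate_library(spec$library_size, spec$seed)
  if (length(library) != spec$library_size) {
    stop("library length must equal spec$library_size", call. = FALSE)
  }
  G <- spec$library_size
  classes <- sprintf("class%02d", seq_len(spec$n_classes))
  sdlog_rep <- sqrt(log(1 + spec$replicate_cv^2))

  with_private_seed(spec$seed, {
    baseline <- stats::rnorm(G, spec$baseline_meanlog, spec$baseline_sdlog)
    class_dev <- matrix(stats::rnorm(spec$n_classes * G, 0, spec$class_sdlog),
                        nrow = spec$n_classes)
    markers <- lapply(seq_len(spec$n_classes), function(i) {
      sort(sample.int(G, spec$marker_count))
    })
    mean_log <- matrix(baseline, nrow = spec$n_classes, ncol = G, byrow = TRUE) +
      class_dev
    for (i in seq_len(spec$n_classes)) {
      mean_log[i, markers[[i]]] <- mean_log[i, markers[[i]]] + log(spec$fold_change)
    }

    n_samples <- spec$n_classes * spec$replicates
    amounts <- matrix(0, nrow = n_samples, ncol = G)
    samples <- data.frame(
      sample_id = character(n_samples), class_label = character(n_samples),
      replicate = integer(n_samples), stringsAsFactors = FALSE
    )
    row <- 0L
    for (i in seq_len(spec$n_classes)) {
      for (r in seq_len(spec$replicates)) {
        row <- row + 1L
        noise <- stats::rnorm(G, 0, sdlog_rep)
        amounts[row, ] <- exp(mean_log[i, ] + noise)
        samples$sample_id[row] <- sprintf("%s_r%d", classes[i], r)
        samples$class_label[row] <- classes[i]
        samples$replicate[row] <- r
      }
    }
    mask <- amounts >= spec$detection_limit
    if (spec$dropout_prob > 0) {
      mask <- mask & (matrix(stats::runif(length(mask)), nrow = nrow(mask)) >=
                        spec$dropout_prob)
    }
    amounts[!mask] <- 0
    dimnames(amounts) <- dimnames(mask) <- list(samples$sample_id, library)

    profile <- structure(list(abundance = amounts, mask = mask, samples = samples),
                         class = "glyco_profile")
    names(markers) <- classes
    list(profile = profile,
         truth = list(class_mean_log = structure(mean_log,
                        dimnames = list(classes, library)),
                      markers = lapply(markers, function(ix) library[ix]),
                      library = library, spec = spec))
  })
}

#' Generate strain-perturbed variants of one class profile
#'
#' Emulates the strain-discrimination design: several mouse strains
#' measured on the same organ, where each non-reference strain perturbs a
#' random subset of glycoforms multiplicatively by `effect_size` relative
#' to the reference mean profile. Replicate noise and dropout follow the
#' base spec.
#'
#' @param base_mean_log named numeric vector: reference class mean
#'   log-abundance per glycoform (e.g. one row of
#'   `generate_atlas()$truth$class_mean_log`).
#' @param effect_size multiplicative perturbation; 1 means strains are
#'   statistically indistinguishable.
#' @param n_affected number of perturbed glycoforms per non-reference
#'   strain.
#' @param n_strains total strains including the reference (default 3).
#' @param replicates replicates per strain (default 5).
#' @param replicate_cv,detection_limit as in [synthetic_atlas_spec()].
#' @param strain_names optional names (default strain1..strainK, strain1
#'   the reference).
#' @param seed integer seed.
#' @return List with `profile` (a `glyco_profile`, class labels are
#'   strains) and `truth` (per-strain affected glycoforms).
#' @export
generate_strain_variants <- function(base_mean_log, effect_size = 4,
                                     n_affected = 10L, n_strains = 3L,
                                     replicates = 5L, replicate_cv = 0.25,
                                     detection_limit = 0.04,
                                     strain_names = NULL, seed = 1L) {
  G <- length(base_mean_log)
  library <- names(base_mean_log)
  if (is.null(library)) stop("base_mean_log must be named by composition",
                             call. = FALSE)
  if (n_affected > G) stop("n_affected cannot exceed the library size",
                           call. = FALSE)
  if (is.null(strain_names)) strain_names <- sprintf("strain%d", seq_len(n_strains))
  sdlog_rep <- sqrt(log(1 + replicate_cv^2))

  with_private_seed(seed, {
    affected <- c(list(integer(0)),
                  lapply(seq_len(n_strains - 1L), function(i) {
                    sort(sample.int(G, n_affected))
                  }))
    n_samples <- n_strains * replicates
    amounts <- matrix(0, nrow = n_samples, ncol = G)
    samples <- data.frame(sample_id = character(n_samples),
                          class_label = character(n_samples),
                          replicate = integer(n_samples),
                          stringsAsFactors = FALSE)
    row <- 0L
    for (s in seq_len(n_strains)) {
      mlog <- base_mean_log
      mlog[affected[[s]]] <- mlog[affected[[s]]] + log(effect_size)
      for (r in seq_len(replicates)) {
        row <- row + 1L
        amounts[row, ] <- exp(mlog + stats::rnorm(G, 0, sdlog_rep))
        samples$sample_id[row] <- sprintf("%s_r%d", strain_names[s], r)
        samples$class_label[row] <- strain_names[s]
        samples$replicate[row] <- r
      }
    }
    mask <- amounts >= detection_limit
    amounts[!mask] <- 0
    dimnames(amounts) <- dimnames(mask) <- list(samples$sample_id, library)
    names(affected) <- strain_names
    list(profile = structure(list(abundance = amounts, mask = mask,
                                  samples = samples), class = "glyco_profile"),
         truth = list(affected = lapply(affected, function(ix) library[ix]),
                      effect_size = effect_size, seed = as.integer(seed)))
  })
}

#' Emit synthetic MALDI peak lists from a profile
#'
#' Inverts quantitation for end-to-end testing: each detected amount
#' becomes a peak whose area is `amount / is_amount * is_area` and whose
#' m/z is the derivatized m/z of its composition; every sample gets an
#' internal-standard peak of area `is_area` at the m/z of the spiked
#' standard's composition (H5N3A2, the non-natural disialylated
#' monoantennary-core standard).
#'
#' @param profile a `glyco_profile`.
#' @param model a [derivatization_model()].
#' @param is_amount spiked standard amount (pmol), default 10.
#' @param is_area internal-standard peak area (arbitrary units).
#' @param is_composition composition string of the internal standard.
#' @return Peak table with columns `sample_id`, `class_label`,
#'   `replicate`, `mz`, `area`, `is_internal_standard`.
#' @export
synthetic_peaklists <- function(profile, model = derivatization_model(),
                                is_amount = 10, is_area = 1e5,
                                is_composition = "H5N3A2") {
  stopifnot(inherits(profile, "glyco_profile"))
  comps <- parse_composition(colnames(profile$abundance))
  mz <- derivatized_mz(comps, model)
  is_mz <- derivatized_mz(is_composition, model)
  rows <- lapply(seq_len(nrow(profile$abundance)), function(i) {
    det <- which(profile$mask[i, ])
    meta <- profile$samples[i, ]
    rbind(
      data.frame(sample_id = meta$sample_id, class_label = meta$class_label,
                 replicate = meta$replicate, mz = mz[det],
                 area = profile$abundance[i, det] / is_amount * is_area,
                 is_internal_standard = 0L, stringsAsFactors = FALSE),
      data.frame(sample_id = meta$sample_id, class_label = meta$class_label,
                 replicate = meta$replicate, mz = is_mz, area = is_area,
                 is_internal_standard = 1L, stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
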