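#' Read peak lists from delimited text
#'
#' Expected columns: `sample_id`, `class_label`, `replicate`, `mz`,
#' `area`, `is_internal_standard` (0/1). TSV or CSV is detected from the
#' extension (`.csv` = comma, otherwise tab). Validation errors name the
#' offending row.
#'
#' @param path path to the peak-list file.
#' @return Validated peak table (data frame), row order preserved.
#' @export
read_peaklists <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "class_label", "replicate", "mz", "area",
            "is_internal_standard")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("peak list missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & nzchar(tab[[col]]))
    if (length(bad) > 0 || anyNA(v)) {
      row <- if (length(bad) > 0) bad[1] else which(is.na(v))[1]
      stop(sprintf("non-numeric %s at row %d: '%s'", col, row, tab[[col]][row]),
           call. = FALSE)
    }
    v
  }
  out <- data.frame(
    sample_id = tab$sample_id,
    class_label = tab$class_label,
    replicate = as.integer(num("replicate")),
    mz = num("mz"),
    area = num("area"),
    is_internal_standard = as.integer(num("is_internal_standard")),
    stringsAsFactors = FALSE
  )
  if (any(out$mz <= 0)) {
    stop("non-positive m/z at row ", which(out$mz <= 0)[1], call. = FALSE)
  }
  if (any(out$area < 0)) {
    stop("negative area at row ", which(out$area < 0)[1], call. = FALSE)
  }
  if (any(out$replicate < 1)) {
    stop("replicate must be >= 1 at row ", which(out$replicate < 1)[1],
         call. = FALSE)
  }
  n_std <- tapply(out$is_internal_standard, out$sample_id, sum)
  if (any(n_std > 1)) {
    stop("duplicate internal-standard rows for sample(s): ",
         paste(names(n_std)[n_std > 1], collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname read_peaklists
#' @param peaks peak table to write.
#' @export
write_peaklists <- function(peaks, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(peaks, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()].
#' Unknown keys in any section are rejected so typos fail before
#' compute; the fully resolved configuration travels with every run's
#' manifest.
#'
#' @param masses named overrides for [residue_masses()].
#' @param derivatization arguments for [derivatization_model()].
#' @param annotation `tolerance`, `tol_unit`, `bounds`, `library`
#'   (character vector of composition strings or path to a one-column
#'   TSV), `de_novo`.
#' @param quantification `is_amount`, `protein_factor`, `min_detections`,
#'   `scope`.
#' @param glycotyping `exceptions` (named composition -> type).
#' @param clustering `on`, `variant`, `k`.
#' @param classification `algorithms`, `n_reps`, `tune`, `grids`.
#' @param seed integer seed for the stochastic stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(masses = list(), derivatization = list(),
                            annotation = list(), quantification = list(),
                            glycotyping = list(), clustering = list(),
                            classification = list(), seed = 1L) {
  defaults <- list(
    masses = list(),
    derivatization = list(tag_delta = 0, methyl_delta = 14.01565,
                          adduct = "protonated", charge = 1L),
    annotation = list(tolerance = 0.1, tol_unit = "Da",
                      bounds = composition_bounds(), library = NULL,
                      de_novo = TRUE),
    quantification = list(is_amount = 10, protein_factor = 1,
                          min_detections = 3, scope = "within-any-group"),
    glycotyping = list(exceptions = NULL),
    clustering = list(on = "raw", variant = "ward.D2", k = 18L),
    classification = list(algorithms = ALGORITHMS, n_reps = 1000L,
                          tune = "once", grids = default_grids())
  )
  user <- list(masses = masses, derivatization = derivatization,
               annotation = annotation, quantification = quantification,
               glycotyping = glycotyping, clustering = clustering,
               classification = classification)
  cfg <- defaults
  for (section in names(user)) {
    u <- user[[section]]
    if (length(u) == 0) next
    if (section != "masses") {
      bad <- setdiff(names(u), names(defaults[[section]]))
      if (length(bad) > 0) {
        stop(sprintf("unknown key(s) in config section '%s': %s",
                     section, paste(bad, collapse = ", ")), call. = FALSE)
      }
    }
    cfg[[section]][names(u)] <- u
  }
  cfg$seed <- as.integer(seed)
  residue_masses(cfg$masses)  # validates override names now
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file with sections named as above.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("masses", "derivatization", "annotation", "quantification",
             "glycotyping", "clustering", "classification", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args <- raw[setdiff(names(raw), "seed")]
  args <- lapply(args, as.list)
  do.call(pipeline_config, c(args, list(seed = raw$seed %||% 1L)))
}

#' Run the full atlas pipeline
#'
#' Executes the computational stages in order — annotate, quantify,
#' filter, matrix, glycotype, cluster, classify — on a peak table and
#' writes every artifact plus a manifest (stages run, resolved config,
#' seed, package version, record counts in/out of each filter) to
#' `out_dir`. A stage failure aborts the run with the failing stage
#' named and removes partial artifacts.
#'
#' @param config a [pipeline_config()].
#' @param peaks peak table (from [read_peaklists()]) or a path to one.
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing and just returns the artifacts.
#' @return Invisibly, a list with `quant`, `retained`, `profile`,
#'   `glycotypes`, `clustering`, `purity`, `evaluation`, `manifest`.
#' @export
run_pipeline <- function(config, peaks, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(peaks)) peaks <- read_peaklists(peaks)
  masses <- residue_masses(config$masses)
  model <- do.call(derivatization_model,
                   c(config$derivatization, list(masses = masses)))
  log_counts <- list()
  stage <- "annotate"
  result <- tryCatch({
    lib <- config$annotation$library
    if (is.character(lib) && length(lib) == 1 && file.exists(lib)) {
      lib <- utils::read.delim(lib, stringsAsFactors = FALSE)[[1]]
    }
    annotated <- do.call(rbind, lapply(split(peaks, peaks$sample_id), function(p) {
      annotate_peaklist(p, model, library = lib,
                        tol = config$annotation$tolerance,
                        tol_unit = config$annotation$tol_unit,
                        bounds = config$annotation$bounds,
                        masses = masses,
                        de_novo = config$annotation$de_novo)
    }))
    rownames(annotated) <- NULL
    log_counts$annotated <- list(peaks = nrow(peaks),
                                 assigned = sum(!is.na(annotated$composition)))

    stage <- "quantify"
    quant <- quantify(annotated, is_amount = config$quantification$is_amount,
                      protein_factor = config$quantification$protein_factor)

    stage <- "filter"
    filt <- detection_filter(quant,
                             min_detections = config$quantification$min_detections,
                             scope = config$quantification$scope)
    log_counts$filter <- list(candidates = nrow(filt$tallies),
                              retained = length(filt$retained))

    stage <- "matrix"
    profile <- build_matrix(quant, filt$retained)

    stage <- "glycotype"
    glycotypes <- glycotype_summary(profile,
                                    exceptions = config$glycotyping$exceptions)

    stage <- "cluster"
    clustering <- ward_cluster(profile, on = config$clustering$on,
                               variant = config$clustering$variant)
    purity <- cut_and_purity(clustering,
                             k = min(config$clustering$k, nrow(profile$abundance)))

    stage <- "classify"
    evaluation <- evaluate_classifiers(
      profile,
      algorithms = config$classification$algorithms,
      n_reps = config$classification$n_reps,
      seed = config$seed,
      tune = config$classification$tune,
      grids = config$classification$grids
    )

    list(quant = quant, retained = filt$retained, profile = profile,
         glycotypes = glycotypes, clustering = clustering, purity = purity,
         evaluation = evaluation)
  }, error = function(e) {
    if (!is.null(out_dir) && dir.exists(out_dir)) {
      unlink(file.path(out_dir, c("quant_table.tsv", "profile_matrix.csv",
                                  "glycotype_summary.csv", "dendrogram.nwk",
                                  "groups.csv", "evaluation.csv",
                                  "manifest.json")))
    }
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  manifest <- list(
    stages = c("annotate", "quantify", "filter", "matrix", "glycotype",
               "cluster", "classify"),
    seed = config$seed,
    config = unclass(config),
    counts = log_counts,
    package_version = as.character(utils::packageVersion("glycoatlas"))
  )
  result$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_quant_table(result$quant, file.path(out_dir, "quant_table.tsv"))
    write_profile_csv(result$profile, file.path(out_dir, "profile_matrix.csv"))
    utils::write.csv(result$glycotypes$per_sample,
                     file.path(out_dir, "glycotype_summary.csv"),
                     row.names = FALSE)
    dendrogram_newick(result$clustering, file.path(out_dir, "dendrogram.nwk"))
    utils::write.csv(result$purity$groups, file.path(out_dir, "groups.csv"),
                     row.names = FALSE)
    utils::write.csv(result$evaluation$per_class,
                     file.path(out_dir, "evaluation.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  }
  invisible(result)
}

#' Recompute atlas benchmark summaries from a quant table
#'
#' Given a real long-format quant table (see [read_quant_table()] for
#' the dialect; e.g. the published 103-glycoform x 90-sample absolute
#' quantification table exported to TSV), recomputes the headline atlas
#' quantities: the retained glycoform count under the >= 3-detection
#' rule, per-class median totals and glycoform counts, Canberra/Ward
#' cluster purity at `k` under both Ward variants, and (optionally)
#' the repeated-holdout F1 evaluation.
#'
#' @param records quant records (data frame) or a path to a quant TSV.
#' @param k cut height for the purity report (default 18 groups).
#' @param n_reps classifier repetitions (0 skips classification).
#' @param seed seed for the evaluation.
#' @return List with `n_retained`, `per_class` summary, `n_pure`
#'   (named by Ward variant), and `evaluation` (or NULL).
#' @export
atlas_benchmarks <- function(records, k = 18L, n_reps = 1000L, seed = 1L) {
  if (is.character(records)) records <- read_quant_table(records)
  filt <- detection_filter(records)
  profile <- build_matrix(records, filt$retained)
  summ <- profile_summary(profile)
  n_pure <- vapply(c("ward.D2", "ward.D"), function(v) {
    cl <- ward_cluster(profile, variant = v)
    cut_and_purity(cl, k = min(k, nrow(profile$abundance)))$n_pure
  }, numeric(1))
  evaluation <- if (n_reps > 0) {
    evaluate_classifiers(profile, n_reps = n_reps, seed = seed)
  }
  list(n_retained = length(filt$retained), per_class = summ$per_class,
       n_pure = n_pure, evaluation = evaluation)
}
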