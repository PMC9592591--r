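#' Internal-standard absolute quantitation
#'
#' Converts isotopic-envelope peak areas to absolute amounts by
#' comparison with the spiked internal standard:
#' `amount_i = (area_i / area_IS) * is_amount * protein_factor`, in pmol
#' per 100 ug total protein. Quantitation is linear and scale-invariant
#' in the raw areas: rescaling all areas (including the standard) leaves
#' amounts unchanged.
#'
#' @param peaks annotated peak table for one or more samples: columns
#'   `sample_id`, `class_label`, `replicate`, `area`, `composition`,
#'   `source` (from [annotate_peaklist()]).
#' @param is_amount spiked internal-standard amount in pmol (default 10,
#'   the glycoblotting spike for tissue and exosome workups).
#' @param protein_factor scale factor normalizing to 100 ug protein when
#'   the workup used a different protein input (default 1).
#' @return Data frame of quant records: `sample_id`, `class_label`,
#'   `replicate`, `composition`, `amount` (pmol / 100 ug protein).
#'   Unassigned peaks are dropped; duplicate assignments within a sample
#'   have their areas summed.
#' @export
quantify <- function(peaks, is_amount = 10, protein_factor = 1) {
  stopifnot(is.data.frame(peaks),
            all(c("sample_id", "area", "composition", "source") %in% names(peaks)))
  if (!is.numeric(is_amount) || length(is_amount) != 1 || is_amount <= 0) {
    stop("is_amount must be a single positive number (pmol)", call. = FALSE)
  }
  if (!"class_label" %in% names(peaks)) peaks$class_label <- NA_character_
  if (!"replicate" %in% names(peaks)) peaks$replicate <- NA_integer_

  records <- lapply(split(peaks, peaks$sample_id), function(p) {
    std <- p[p$source == "internal_standard", , drop = FALSE]
    if (nrow(std) != 1 || std$area <= 0) {
      stop(sprintf("sample '%s': missing or zero-area internal standard, cannot quantify",
                   p$sample_id[1]), call. = FALSE)
    }
    analyte <- p[p$source %in% c("library", "de_novo") & !is.na(p$composition), ,
                 drop = FALSE]
    if (nrow(analyte) == 0) return(NULL)
    amount <- tapply(analyte$area, analyte$composition, sum) / std$area *
      is_amount * protein_factor
    data.frame(
      sample_id = p$sample_id[1],
      class_label = p$class_label[1],
      replicate = p$replicate[1],
      composition = names(amount),
      amount = as.numeric(amount),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Minimum-detection filter over quant records
#'
#' Retains glycoforms detected (amount > 0) often enough to be trusted,
#' mirroring the atlas rule of keeping peaks seen in at least three
#' independent experiments. Two counting scopes:
#' `"within-any-group"` (default) retains a composition if at least one
#' class detects it in >= `min_detections` of that class's replicates;
#' `"global"` counts detections over all samples regardless of class.
#'
#' @param records quant records from [quantify()].
#' @param min_detections minimum detection count (default 3).
#' @param scope `"within-any-group"` or `"global"`.
#' @return List with `retained` (character vector of composition strings,
#'   sorted) and `tallies` (per-composition detection counts; for the
#'   group scope, the maximum over classes).
#' @export
detection_filter <- function(records, min_detections = 3,
                             scope = c("within-any-group", "global")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(records),
            all(c("sample_id", "class_label", "composition", "amount") %in% names(records)))
  if (min_detections < 1) stop("min_detections must be >= 1", call. = FALSE)
  det <- records[records$amount > 0, , drop = FALSE]
  if (nrow(det) == 0) {
    return(list(retained = character(0),
                tallies = data.frame(composition = character(0),
                                     detections = integer(0)),
                scope = scope, min_detections = as.integer(min_detections)))
  }
  if (scope == "global") {
    tally <- tapply(det$sample_id, det$composition, function(x) length(unique(x)))
  } else {
    per_class <- tapply(
      seq_len(nrow(det)),
      list(det$composition, det$class_label),
      function(i) length(unique(det$sample_id[i]))
    )
    per_class[is.na(per_class)] <- 0
    tally <- apply(per_class, 1, max)
  }
  tallies <- data.frame(composition = names(tally), detections = as.integer(tally),
                        stringsAsFactors = FALSE)
  retained <- sort(tallies$composition[tallies$detections >= min_detections])
  list(retained = retained, tallies = tallies[order(tallies$composition), ],
       scope = scope, min_detections = as.integer(min_detections))
}

#' Assemble the samples-by-glycoforms profile matrix
#'
#' Builds the atlas grid: rows are samples (with class label and
#' replicate metadata), columns are retained glycoform compositions,
#' values are absolute amounts. A cell with no record is a non-detection:
#' amount 0 with `mask` FALSE, matching the grey-as-absent heatmap
#' semantics. Zeros enter all downstream totals, distances and
#' classifiers as zeros; the mask is kept so glycoform counts reflect
#' detection, not float positivity.
#'
#' @param records quant records from [quantify()].
#' @param retained compositions to keep (e.g. `detection_filter()$retained`);
#'   default all compositions present.
#' @return Object of class `glyco_profile`: list with `abundance`
#'   (numeric matrix), `mask` (logical matrix), `samples` (data frame
#'   `sample_id`, `class_label`, `replicate`).
#' @export
build_matrix <- function(records, retained = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(retained)) retained <- sort(unique(records$composition))
  rec <- records[records$composition %in% retained, , drop = FALSE]
  key <- paste(rec$sample_id, rec$composition, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (sample, composition) records: ",
         paste(gsub("\r", " / ", utils::head(dup, 5)), collapse = ", "),
         call. = FALSE)
  }
  samples <- unique(records[, c("sample_id", "class_label", "replicate")])
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id maps to more than one (class_label, replicate)", call. = FALSE)
  }
  samples <- samples[order(samples$class_label, samples$replicate, samples$sample_id), ]
  rownames(samples) <- NULL

  abundance <- matrix(0, nrow = nrow(samples), ncol = length(retained),
                      dimnames = list(samples$sample_id, retained))
  mask <- matrix(FALSE, nrow = nrow(samples), ncol = length(retained),
                 dimnames = list(samples$sample_id, retained))
  ij <- cbind(match(rec$sample_id, samples$sample_id),
              match(rec$composition, retained))
  abundance[ij] <- rec$amount
  mask[ij] <- rec$amount > 0

  structure(list(abundance = abundance, mask = mask, samples = samples),
            class = "glyco_profile")
}

#' @export
print.glyco_profile <- function(x, ...) {
  cat(sprintf("N-glycome profile: %d samples x %d glycoforms (%d classes), %.1f%% detected\n",
              nrow(x$abundance), ncol(x$abundance),
              length(unique(x$samples$class_label)),
              100 * mean(x$mask)))
  invisible(x)
}

#' Per-class totals and glycoform counts
#'
#' For each replicate, the total glycan amount (sum over glycoforms) and
#' the number of detected glycoforms (mask count); per class, the median
#' of each across replicates — the atlas summary statistic.
#'
#' @param profile a `glyco_profile` from [build_matrix()].
#' @return List with `per_replicate` (sample_id, class_label, replicate,
#'   total, n_glycoforms) and `per_class` (class_label, median_total,
#'   median_n_glycoforms).
#' @export
profile_summary <- function(profile) {
  stopifnot(inherits(profile, "glyco_profile"))
  per_rep <- data.frame(
    profile$samples,
    total = rowSums(profile$abundance),
    n_glycoforms = rowSums(profile$mask),
    stringsAsFactors = FALSE
  )
  cls <- split(per_rep, per_rep$class_label)
  per_class <- data.frame(
    class_label = names(cls),
    median_total = vapply(cls, function(d) stats::median(d$total), numeric(1)),
    median_n_glycoforms = vapply(cls, function(d) stats::median(d$n_glycoforms), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_class) <- NULL
  list(per_replicate = per_rep, per_class = per_class)
}

#' Read and write quant tables and profile matrices
#'
#' Quant tables are long-format TSV (`sample_id`, `class_label`,
#' `replicate`, `composition`, `amount_pmol_per_100ug`). Profile matrices
#' round-trip to wide CSV with sample metadata in the first three columns
#' and one column per glycoform; non-detected cells are written empty and
#' read back as masked zeros.
#'
#' @param records quant records; `path` a file path; `profile` a
#'   `glyco_profile`.
#' @return Readers return the corresponding object; writers return the
#'   path invisibly.
#' @export
write_quant_table <- function(records, path) {
  out <- records
  names(out)[names(out) == "amount"] <- "amount_pmol_per_100ug"
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_quant_table
#' @export
read_quant_table <- function(path) {
  need <- c("sample_id", "class_label", "replicate", "composition",
            "amount_pmol_per_100ug")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("quant table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(tab$amount_pmol_per_100ug)) {
    stop("amount_pmol_per_100ug must be numeric", call. = FALSE)
  }
  names(tab)[names(tab) == "amount_pmol_per_100ug"] <- "amount"
  tab$sample_id <- as.character(tab$sample_id)
  tab$composition <- format_composition(parse_composition(tab$composition))
  tab
}

#' @rdname write_quant_table
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "glyco_profile"))
  vals <- profile$abundance
  txt <- matrix(as.character(vals), nrow = nrow(vals), dimnames = dimnames(vals))
  txt[!profile$mask] <- ""
  out <- cbind(profile$samples, as.data.frame(txt, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("sample_id", "class_label", "replicate")
  if (!all(meta_cols %in% names(tab))) {
    stop("profile CSV must start with sample_id, class_label, replicate", call. = FALSE)
  }
  comps <- setdiff(names(tab), meta_cols)
  vals <- as.matrix(tab[, comps, drop = FALSE])
  mask <- !is.na(vals)
  storage.mode(vals) <- "double"
  vals[!mask] <- 0
  rownames(vals) <- rownames(mask) <- tab$sample_id
  samples <- tab[, meta_cols]
  samples$sample_id <- as.character(samples$sample_id)
  structure(list(abundance = vals, mask = mask, samples = samples),
            class = "glyco_profile")
}
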