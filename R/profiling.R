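#' Column z-scaling of a profile matrix
#'
#' Per glycoform (column): `(x - mean) / sd` with the sample standard
#' deviation (n - 1 denominator), the scaling used for deviation
#' heatmaps. Zeros arising from non-detections are ordinary values in
#' the mean and SD. Zero-variance columns become all-zero rather than
#' NaN.
#'
#' @param profile a `glyco_profile` or a plain numeric matrix with at
#'   least two rows.
#' @return Same shape as the input: a `glyco_profile` whose `abundance`
#'   holds z-scores (mask untouched), or a matrix.
#' @export
zscore_profile <- function(profile) {
  m <- if (inherits(profile, "glyco_profile")) profile$abundance else profile
  stopifnot(is.matrix(m), is.numeric(m))
  if (nrow(m) < 2) stop("z-scaling needs at least 2 rows", call. = FALSE)
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  z <- sweep(sweep(m, 2, mu), 2, ifelse(sd > 0, sd, 1), "/")
  z[, sd == 0] <- 0
  if (inherits(profile, "glyco_profile")) {
    out <- profile
    out$abundance <- z
    out
  } else z
}

#' Canberra distance
#'
#' `sum_i |x_i - y_i| / (|x_i| + |y_i|)`, with coordinates where both
#' values are zero contributing 0. Each coordinate's term is bounded by
#' 1, so the distance weights relative change near zero heavily — the
#' property that makes it suited to sparse abundance profiles where
#' low-level glycoforms matter. Note this is not `stats::dist`'s
#' Canberra, which drops 0/0 coordinates and rescales the sum by the
#' number of coordinates used.
#'
#' @param x,y numeric vectors of equal length.
#' @return Single distance for `canberra()`; a `dist` object over matrix
#'   rows for `canberra_dist()`.
#' @export
#' @examples
#' canberra(c(1, 3), c(2, 3))  # 1/3
#' canberra(c(0, 1), c(1, 0))  # 2
canberra <- function(x, y) {
  if (length(x) != length(y)) {
    stop("canberra: vectors differ in length", call. = FALSE)
  }
  denom <- abs(x) + abs(y)
  term <- ifelse(denom > 0, abs(x - y) / denom, 0)
  sum(term)
}

#' @rdname canberra
#' @param m numeric matrix; distances are between rows.
#' @export
canberra_dist <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (anyNA(m)) stop("canberra_dist: matrix contains NA", call. = FALSE)
  nr <- nrow(m)
  d <- numeric(nr * (nr - 1) / 2)
  k <- 1L
  for (j in seq_len(nr - 1L)) {
    for (i in seq.int(j + 1L, nr)) {
      d[k] <- canberra(m[j, ], m[i, ])
      k <- k + 1L
    }
  }
  structure(d, Size = nr, Labels = rownames(m), Diag = FALSE, Upper = FALSE,
            method = "canberra", class = "dist")
}

#' Ward hierarchical clustering of glycan profiles
#'
#' Agglomerative clustering of the samples over their pairwise Canberra
#' distances with Ward linkage. Clustering runs on the raw absolute
#' abundances by default (the dissimilarity analysis operates on the
#' quantitative atlas table; z-scores are a display scaling) — set
#' `on = "zscore"` to cluster the scaled matrix. The squared-distance
#' Ward update (`"ward.D2"`) is the default; the classic `"ward.D"`
#' recurrence is selectable since legacy pipelines differ. Merging is
#' deterministic given the input row order; equal-height merge ties fall
#' to the lowest pair index.
#'
#' @param profile a `glyco_profile` (or numeric matrix).
#' @param on `"raw"` or `"zscore"`.
#' @param variant `"ward.D2"` or `"ward.D"`.
#' @param distance distance function over matrix rows returning a `dist`;
#'   default [canberra_dist()].
#' @return Object of class `glyco_clustering`: list with `hclust` (a
#'   [stats::hclust] tree), `dist`, `samples`, `variant`, `on`.
#' @export
ward_cluster <- function(profile, on = c("raw", "zscore"),
                         variant = c("ward.D2", "ward.D"),
                         distance = canberra_dist) {
  on <- match.arg(on)
  variant <- match.arg(variant)
  m <- if (inherits(profile, "glyco_profile")) profile$abundance else profile
  stopifnot(is.matrix(m), nrow(m) >= 2)
  if (on == "zscore") m <- zscore_profile(m)
  d <- distance(m)
  if (anyNA(d)) stop("distance matrix contains NA", call. = FALSE)
  hc <- stats::hclust(d, method = variant)
  samples <- if (inherits(profile, "glyco_profile")) profile$samples else
    data.frame(sample_id = rownames(m) %||% as.character(seq_len(nrow(m))),
               class_label = NA_character_, replicate = NA_integer_,
               stringsAsFactors = FALSE)
  structure(list(hclust = hc, dist = d, samples = samples,
                 variant = variant, on = on),
            class = "glyco_clustering")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cut a clustering into k groups and report purity
#'
#' Cuts the Ward tree into `k` groups and reports, per group, its member
#' samples and class composition. A group is "pure" when all members
#' share one class label — the single-organ groups of the atlas
#' dendrogram. At `k = n` every singleton is pure; purity is not
#' monotone in `k`.
#'
#' @param clustering a `glyco_clustering` from [ward_cluster()].
#' @param k number of groups, `1 <= k <= n` samples.
#' @return List with `groups` (data frame sample_id, class_label, group),
#'   `group_summary` (group, size, n_classes, majority_class, pure) and
#'   `n_pure`.
#' @export
cut_and_purity <- function(clustering, k) {
  stopifnot(inherits(clustering, "glyco_clustering"))
  n <- length(clustering$hclust$order)
  if (k < 1 || k > n) stop("k must be between 1 and the number of samples",
                           call. = FALSE)
  grp <- stats::cutree(clustering$hclust, k = k)
  if (!is.null(names(grp))) grp <- grp[clustering$samples$sample_id]
  groups <- data.frame(
    sample_id = clustering$samples$sample_id,
    class_label = clustering$samples$class_label,
    group = as.integer(grp),
    stringsAsFactors = FALSE
  )
  by_grp <- split(groups, groups$group)
  group_summary <- do.call(rbind, lapply(by_grp, function(g) {
    tab <- sort(table(g$class_label), decreasing = TRUE)
    data.frame(group = g$group[1], size = nrow(g), n_classes = length(tab),
               majority_class = names(tab)[1], pure = length(tab) == 1,
               stringsAsFactors = FALSE)
  }))
  rownames(group_summary) <- NULL
  list(groups = groups, group_summary = group_summary,
       n_pure = sum(group_summary$pure))
}

#' Export a clustering dendrogram as Newick text
#'
#' @param clustering a `glyco_clustering`.
#' @param path optional file to write to.
#' @return Newick string (invisibly when `path` is given).
#' @export
dendrogram_newick <- function(clustering, path = NULL) {
  stopifnot(inherits(clustering, "glyco_clustering"))
  hc <- clustering$hclust
  labs <- hc$labels %||% as.character(seq_along(hc$order))
  node_txt <- character(nrow(hc$merge))
  node_h <- numeric(nrow(hc$merge))
  branch <- function(idx, parent_h) {
    if (idx < 0) sprintf("%s:%.12g", labs[-idx], parent_h)
    else sprintf("%s:%.12g", node_txt[idx], parent_h - node_h[idx])
  }
  for (i in seq_len(nrow(hc$merge))) {
    node_h[i] <- hc$height[i]
    node_txt[i] <- sprintf("(%s,%s)",
                           branch(hc$merge[i, 1], hc$height[i]),
                           branch(hc$merge[i, 2], hc$height[i]))
  }
  nwk <- paste0(node_txt[nrow(hc$merge)], ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
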