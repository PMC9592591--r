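# Independent oracles the implementation is checked against. Each is a
# deliberately naive alternative route: elemental-formula mass sums,
# exhaustive grid filters, explicit enumeration, and a hand-rolled
# Lance-Williams agglomeration.

# --- elemental-formula mass oracle ------------------------------------
# Residue masses recomputed from atomic monoisotopic masses and the
# residues' elemental formulas, never from the package's constants.
ATOMS <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
           Na = 22.98976928)

formula_mass <- function(counts) sum(ATOMS[names(counts)] * counts)

RESIDUE_FORMULAS <- list(
  hex    = c(C = 6, H = 10, O = 5),
  hexnac = c(C = 8, H = 13, N = 1, O = 5),
  dhex   = c(C = 6, H = 10, O = 4),
  neu5ac = c(C = 11, H = 17, N = 1, O = 8),
  neu5gc = c(C = 11, H = 17, N = 1, O = 9)
)

oracle_neutral_mass <- function(h = 0, n = 0, d = 0, a = 0, g = 0) {
  h * formula_mass(RESIDUE_FORMULAS$hex) +
    n * formula_mass(RESIDUE_FORMULAS$hexnac) +
    d * formula_mass(RESIDUE_FORMULAS$dhex) +
    a * formula_mass(RESIDUE_FORMULAS$neu5ac) +
    g * formula_mass(RESIDUE_FORMULAS$neu5gc) +
    formula_mass(c(H = 2, O = 1))
}

# --- exhaustive composition solver oracle -----------------------------
# Filters the raw bounded grid with explicit loops; independent of
# composition_grid()/solve_compositions().
oracle_solve <- function(mz, model, tol_da, bounds) {
  hits <- list()
  for (h in bounds$h[1]:bounds$h[2]) for (n in bounds$n[1]:bounds$n[2])
    for (d in bounds$d[1]:bounds$d[2]) for (a in bounds$a[1]:bounds$a[2])
      for (g in bounds$g[1]:bounds$g[2]) {
        if (n < 2 || h < 3 || d > n || (a + g) > max(n - 2, 0) + 1) next
        rm_ <- residue_masses()
        theo <- (h * rm_[["hex"]] + n * rm_[["hexnac"]] + d * rm_[["dhex"]] +
                   a * rm_[["neu5ac"]] + g * rm_[["neu5gc"]] + rm_[["water"]] +
                   model$tag_delta + (a + g) * model$methyl_delta +
                   model$adduct_delta) / model$charge
        if (abs(mz - theo) <= tol_da) {
          hits[[length(hits) + 1]] <- c(h = h, n = n, d = d, a = a, g = g)
        }
      }
  hits
}

# --- sialyl linkage isomer enumeration oracle -------------------------
# Explicitly enumerates assignments of s sialic acids to distinct Gal
# sites with a binary linkage choice per placed sialic acid.
oracle_isomers <- function(gal_sites, n_sialic) {
  if (n_sialic > gal_sites) return(0L)
  if (n_sialic == 0) return(1L)
  site_sets <- utils::combn(gal_sites, n_sialic, simplify = FALSE)
  as.integer(sum(vapply(site_sets, function(s) 2^length(s), numeric(1))))
}

# --- naive Canberra ---------------------------------------------------
oracle_canberra <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) {
    den <- abs(x[i]) + abs(y[i])
    if (den > 0) s <- s + abs(x[i] - y[i]) / den
  }
  s
}

# --- naive Lance-Williams Ward agglomeration --------------------------
# Returns the cophenetic distance matrix implied by Ward clustering of
# distance matrix `d` (a dist object). For ward.D2 the recurrence runs
# on squared dissimilarities and merge heights are square roots; for
# ward.D it runs on the dissimilarities directly.
oracle_ward_cophenetic <- function(d, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  D <- as.matrix(d)
  n <- nrow(D)
  if (variant == "ward.D2") D <- D^2
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  coph <- matrix(0, n, n)
  for (step in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (D[i, j] < best[1]) best <- c(D[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    h <- if (variant == "ward.D2") sqrt(best[1]) else best[1]
    for (p in members[[i]]) for (q in members[[j]]) {
      coph[p, q] <- coph[q, p] <- h
    }
    for (l in active) {
      if (l == i || l == j) next
      D[i, l] <- D[l, i] <-
        ((sizes[i] + sizes[l]) * D[i, l] + (sizes[j] + sizes[l]) * D[j, l] -
           sizes[l] * D[i, j]) / (sizes[i] + sizes[j] + sizes[l])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  coph
}

# --- tiny fixture builders --------------------------------------------
tiny_annotated_peaks <- function(areas, compositions, sample_id = "s1",
                                 class_label = "organA", replicate = 1L,
                                 is_area = 1000) {
  rbind(
    data.frame(sample_id = sample_id, class_label = class_label,
               replicate = replicate, area = areas,
               composition = compositions, source = "library",
               stringsAsFactors = FALSE),
    data.frame(sample_id = sample_id, class_label = class_label,
               replicate = replicate, area = is_area,
               composition = NA_character_, source = "internal_standard",
               stringsAsFactors = FALSE)
  )
}

quant_records <- function(sample_id, class_label, replicate, composition,
                          amount) {
  data.frame(sample_id = sample_id, class_label = class_label,
             replicate = replicate, composition = composition,
             amount = amount, stringsAsFactors = FALSE)
}

small_atlas <- function(n_classes = 4, replicates = 3, library_size = 20,
                        fold_change = 16, seed = 42L, ...) {
  generate_atlas(synthetic_atlas_spec(
    n_classes = n_classes, replicates = replicates,
    library_size = library_size, fold_change = fold_change, seed = seed, ...))
}
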