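#' Filter phosphosites by localization probability
#'
#' Keeps rows whose maximum localization probability is at least `min_prob`
#' (boundary inclusive, so the default keeps exactly the >= 0.75 class-I
#' sites).
#'
#' @param x Phosphosite tibble.
#' @param min_prob Minimum localization probability (default 0.75).
#' @return Filtered tibble; the number of removed rows is reported.
#' @export
filter_localization <- function(x, min_prob = 0.75) {
  stopifnot(min_prob >= 0, min_prob <= 1)
  keep <- !is.na(x$localization_prob) & x$localization_prob >= min_prob
  if (min_prob == 0) keep <- rep(TRUE, nrow(x))
  removed <- sum(!keep)
  if (removed > 0) {
    inform(paste0("filter_localization: removed ", removed, " of ", nrow(x),
                  " sites below ", min_prob, "."))
  }
  x[keep, , drop = FALSE]
}

#' Remove low log2 intensities cell-wise
#'
#' Sets individual values strictly below `floor_log2` to missing. This is
#' cell-wise, not row-wise: a row whose values all fall below the floor is
#' retained (fully missing) and dropped later by imputation eligibility.
#'
#' @param x Phosphosite tibble (log2 scale).
#' @param floor_log2 Floor (default 5); values `< floor_log2` become missing.
#' @return Tibble with floored cells set to `NA`.
#' @export
floor_filter <- function(x, floor_log2 = 5) {
  m <- values_matrix(x)
  n_floor <- sum(m < floor_log2, na.rm = TRUE)
  m[!is.na(m) & m < floor_log2] <- NA_real_
  if (n_floor > 0) {
    inform(paste0("floor_filter: set ", n_floor, " cells below ", floor_log2,
                  " to missing."))
  }
  set_values(x, m)
}

#' Impute missing values by iterative low-rank SVD completion
#'
#' Applied per condition group. A site is eligible within a condition when it
#' has at least `min_valid` observed replicates there; eligible missing cells
#' are filled by iterative low-rank completion (initialize missing cells at
#' the row mean within the group, then alternate a rank-`rank` truncated SVD
#' reconstruction with a missing-cell refresh until the largest absolute
#' change drops below `tol` or `max_iter` is reached). Observed values are
#' never altered; ineligible cells stay missing.
#'
#' The completion fit pools all rows of the condition with at least
#' `min_valid` observed values.
#'
#' @param x Phosphosite tibble.
#' @param rank Rank of the truncated SVD (default 2).
#' @param min_valid Minimum observed replicates per condition for
#'   eligibility (default 2).
#' @param tol Convergence tolerance on imputed cells (default 1e-6).
#' @param max_iter Iteration cap (default 100).
#' @return Tibble with eligible cells imputed.
#' @export
impute_svd <- function(x, rank = 2, min_valid = 2, tol = 1e-6,
                       max_iter = 100) {
  if (min_valid < 2) abort("min_valid must be >= 2.")
  m <- values_matrix(x)
  design <- table_design(x)
  for (cond in unique(design$condition)) {
    cols <- design$sample[design$condition == cond]
    if (rank >= length(cols)) {
      abort(paste0("SVD rank (", rank, ") must be below the number of ",
                   "replicates in condition '", cond, "' (", length(cols),
                   ")."))
    }
    sub <- m[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    rows <- which(n_obs >= min_valid)
    if (!length(rows)) next
    block <- sub[rows, , drop = FALSE]
    miss <- is.na(block)
    if (!any(miss)) next
    filled <- block
    row_means <- rowMeans(block, na.rm = TRUE)
    filled[miss] <- row_means[row(block)[miss]]
    for (it in seq_len(max_iter)) {
      dec <- svd(filled, nu = rank, nv = rank)
      approx <- dec$u %*% (dec$d[seq_len(rank)] * t(dec$v))
      delta <- max(abs(approx[miss] - filled[miss]))
      filled[miss] <- approx[miss]
      if (delta < tol) break
    }
    block[miss] <- filled[miss]
    sub[rows, ] <- block
    m[, cols] <- sub
  }
  set_values(x, m)
}

#' Impute remaining missing values from a downshifted normal distribution
#'
#' Runs after [impute_svd()] on the merged (all-conditions) table. Each
#' remaining missing cell in column j is drawn from
#' `Normal(mean_j - shift * sd_j, (width * sd_j)^2)`, where `mean_j` and
#' `sd_j` are computed from the observed cells of column j - mimicking low
#' abundance measurements. Defaults (`shift = 1.8`, `width = 0.3`) are the
#' documented defaults of the Perseus-style workflow and are applied per
#' column separately. Deterministic given `seed`.
#'
#' @param x Phosphosite tibble.
#' @param width,shift Downshift parameters in per-column SD units.
#' @param seed Integer seed (optional).
#' @return Tibble with all missing cells imputed.
#' @export
impute_downshift <- function(x, width = 0.3, shift = 1.8, seed = NULL) {
  stopifnot(width > 0, shift > 0)
  m <- values_matrix(x)
  with_seed_if(seed, {
    for (j in seq_len(ncol(m))) {
      obs <- m[, j][!is.na(m[, j])]
      miss <- which(is.na(m[, j]))
      if (!length(miss)) next
      if (length(obs) < 3) {
        abort(paste0("Column '", colnames(m)[j], "' has fewer than 3 ",
                     "observed values; no stable mean/SD for downshift."))
      }
      mu <- mean(obs)
      s <- sd(obs)
      m[miss, j] <- rnorm(length(miss), mu - shift * s, width * s)
    }
  })
  set_values(x, m)
}

#' Normalize phosphosite intensities to source-protein abundance
#'
#' Subtracts, per site and sample, the log2 abundance of the source protein
#' from the site's log2 intensity (a log-ratio). Sites whose accession lacks
#' protein quantification in any table sample are dropped from the
#' normalized output and reported via the `"not_normalizable"` attribute.
#'
#' @param x Phosphosite tibble.
#' @param protein Tibble with `accession` plus the same sample columns.
#' @return Normalized tibble with attribute `not_normalizable` (character
#'   vector of dropped site keys).
#' @export
normalize_to_protein <- function(x, protein) {
  smp <- sample_columns(x)
  missing_smp <- setdiff(smp, names(protein))
  if (length(missing_smp)) {
    abort(paste0("Protein table lacks sample column(s): ",
                 paste(missing_smp, collapse = ", ")))
  }
  prot_ok <- protein$accession[
    rowSums(is.na(protein[, smp, drop = FALSE])) == 0]
  can <- x$accession %in% prot_ok
  dropped <- site_keys(x[!can, , drop = FALSE])
  if (length(dropped)) {
    inform(paste0("normalize_to_protein: ", length(dropped),
                  " site(s) not normalizable (no protein quantification)."))
  }
  kept <- x[can, , drop = FALSE]
  pm <- as.matrix(protein[match(kept$accession, protein$accession), smp,
                          drop = FALSE])
  out <- set_values(kept, values_matrix(kept) - pm)
  attr(out, "not_normalizable") <- dropped
  out
}

#' Run the full preprocessing chain
#'
#' Fixed order: localization filter -> cell-wise intensity floor ->
#' per-condition SVD completion -> merged downshifted-normal imputation ->
#' optional normalization to source proteins. Re-running the filters on their
#' own output is a no-op.
#'
#' @param x Phosphosite tibble.
#' @param min_prob,floor_log2 Filter parameters.
#' @param rank,min_valid,tol,max_iter SVD-completion parameters.
#' @param width,shift Downshift parameters.
#' @param protein Optional protein abundance tibble for
#'   [normalize_to_protein()].
#' @param seed Seed for the downshift draws.
#' @return Fully imputed (and optionally normalized) tibble.
#' @export
preprocess_phospho <- function(x, min_prob = 0.75, floor_log2 = 5,
                               rank = 2, min_valid = 2, tol = 1e-6,
                               max_iter = 100, width = 0.3, shift = 1.8,
                               protein = NULL, seed = NULL) {
  out <- x |>
    filter_localization(min_prob = min_prob) |>
    floor_filter(floor_log2 = floor_log2) |>
    impute_svd(rank = rank, min_valid = min_valid, tol = tol,
               max_iter = max_iter) |>
    impute_downshift(width = width, shift = shift, seed = seed)
  if (!is.null(protein)) out <- normalize_to_protein(out, protein)
  out
}
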