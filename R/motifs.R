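#' Extract phosphosite-centered sequence windows
#'
#' Returns the -flank..+flank window around each site (default 15-mer for
#' flank 7), padded with `"_"` where the window overruns a terminus. The
#' window center must equal the annotated site residue; a mismatch is a hard
#' error (it catches coordinate bugs).
#'
#' @param sites Tibble with `accession`, `position`, `residue`.
#' @param proteome Named character vector of sequences.
#' @param flank Residues on each side (default 7).
#' @return `sites` with a `window` character column (length `2 * flank + 1`).
#' @export
extract_windows <- function(sites, proteome, flank = 7) {
  missing_acc <- setdiff(unique(sites$accession), names(proteome))
  if (length(missing_acc)) {
    abort(paste0("Accession(s) absent from proteome: ",
                 paste(utils::head(missing_acc, 5), collapse = ", ")))
  }
  seqs <- proteome[sites$accession]
  lens <- nchar(seqs)
  oob <- sites$position < 1 | sites$position > lens
  if (any(oob)) {
    abort(paste0("Site position(s) out of sequence bounds: ",
                 paste(utils::head(site_keys(sites[oob, ]), 5),
                       collapse = ", ")))
  }
  center <- substr(seqs, sites$position, sites$position)
  bad <- center != sites$residue
  if (any(bad)) {
    abort(paste0("Center-residue mismatch (annotation vs sequence) at: ",
                 paste(utils::head(paste0(site_keys(sites[bad, ]),
                                          " (sequence has ", center[bad],
                                          ")"), 5), collapse = ", ")))
  }
  lo <- sites$position - flank
  hi <- sites$position + flank
  core <- substr(seqs, pmax(lo, 1), pmin(hi, lens))
  pad_l <- strrep("_", pmax(0, 1 - lo))
  pad_r <- strrep("_", pmax(0, hi - lens))
  dplyr::mutate(sites, window = paste0(pad_l, core, pad_r))
}

#' Position probability matrix of aligned windows
#'
#' Per-position amino-acid frequencies over the 20 standard letters among
#' non-pad characters (pads and non-standard letters are excluded from the
#' denominator, so terminal sites do not distort the statistics). Positions
#' where every window is padded are masked (`NA` column).
#'
#' @param windows Character vector of equal-length windows, or a tibble with
#'   a `window` column.
#' @return A `ppm` matrix (20 x window length), rows named by amino acid,
#'   columns by position relative to the site (`-flank .. +flank`).
#' @export
position_probability_matrix <- function(windows) {
  if (is.data.frame(windows)) windows <- windows$window
  if (!length(windows)) abort("Need at least one window.")
  wlen <- unique(nchar(windows))
  if (length(wlen) != 1) abort("Windows must have equal length.")
  flank <- (wlen - 1) %/% 2
  chars <- matrix(unlist(strsplit(windows, "")), ncol = wlen, byrow = TRUE)
  counts <- vapply(seq_len(wlen), function(j) {
    tabulate(factor(chars[, j], levels = AA20), nbins = 20)
  }, integer(20))
  rownames(counts) <- AA20
  totals <- colSums(counts)
  freq <- sweep(counts, 2, totals, `/`)
  freq[, totals == 0] <- NA_real_
  colnames(freq) <- as.character(seq(-flank, flank))
  structure(freq, class = c("ppm", "matrix", "array"),
            n_windows = length(windows))
}

#' Amino-acid preference (enrichment) matrix
#'
#' Position-wise log2 ratio of amino-acid frequencies between strongly
#' dephosphorylated windows (linear fold change >= the strong threshold,
#' pre-filtered by the caller) and unchanged windows (|log2fc| inside the
#' insensitive band). Cells where either set's count fraction falls below
#' `min_count_frac` (default 1%) are masked rather than smoothed; an
#' additive `pseudocount` (per cell, default 0) is available instead.
#'
#' Swapping the two sets negates every unmasked cell (same mask).
#'
#' @param sensitive_windows,insensitive_windows Character vectors (or
#'   tibbles with a `window` column) of equal-length windows.
#' @param min_count_frac Masking threshold on the count fraction in either
#'   set (default 0.01).
#' @param pseudocount Added to every count before frequencies are formed.
#' @return A `preference_matrix` (20 x window length) of log2 ratios with a
#'   logical `mask` attribute (`TRUE` = masked, no value).
#' @export
preference_matrix <- function(sensitive_windows, insensitive_windows,
                              min_count_frac = 0.01, pseudocount = 0) {
  count_mat <- function(w) {
    if (is.data.frame(w)) w <- w$window
    if (!length(w)) abort("Both window sets must be non-empty.")
    wlen <- unique(nchar(w))
    if (length(wlen) != 1) abort("Windows must have equal length.")
    chars <- matrix(unlist(strsplit(w, "")), ncol = wlen, byrow = TRUE)
    counts <- vapply(seq_len(wlen), function(j) {
      tabulate(factor(chars[, j], levels = AA20), nbins = 20)
    }, integer(20))
    rownames(counts) <- AA20
    counts
  }
  cs <- count_mat(sensitive_windows)
  ci <- count_mat(insensitive_windows)
  if (!identical(dim(cs), dim(ci))) {
    abort("Window lengths differ between the two sets.")
  }
  fs_raw <- sweep(cs, 2, colSums(cs), `/`)
  fi_raw <- sweep(ci, 2, colSums(ci), `/`)
  mask <- fs_raw < min_count_frac | fi_raw < min_count_frac |
    is.na(fs_raw) | is.na(fi_raw)
  fs <- sweep(cs + pseudocount, 2, colSums(cs + pseudocount), `/`)
  fi <- sweep(ci + pseudocount, 2, colSums(ci + pseudocount), `/`)
  value <- log2(fs / fi)
  value[mask] <- NA_real_
  flank <- (ncol(cs) - 1) %/% 2
  colnames(value) <- as.character(seq(-flank, flank))
  colnames(mask) <- colnames(value)
  structure(value, class = c("preference_matrix", "matrix", "array"),
            mask = mask,
            n_sensitive = if (is.data.frame(sensitive_windows))
              nrow(sensitive_windows) else length(sensitive_windows),
            n_insensitive = if (is.data.frame(insensitive_windows))
              nrow(insensitive_windows) else length(insensitive_windows))
}
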