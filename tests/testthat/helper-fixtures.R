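# Small in-code fixtures shared across test files.

# A 3-site x 6-sample table (two conditions, 3 replicates) with known values.
tiny_table <- function(values = NULL) {
  if (is.null(values)) {
    values <- matrix(20 + seq_len(18) / 10, nrow = 3)
  }
  smp <- c("ctrl_1", "ctrl_2", "ctrl_3", "oa_1", "oa_2", "oa_3")
  dplyr::bind_cols(
    tibble::tibble(
      accession = c("P12345", "P12345", "Q99999"),
      position = c(10L, 25L, 7L),
      residue = c("S", "T", "S"),
      localization_prob = c(0.99, 0.8, 0.95),
      multiplicity = 1L
    ),
    tibble::as_tibble(stats::setNames(as.data.frame(values), smp))
  )
}

# Write a tiny table to a wide TSV and return the path.
write_tiny_tsv <- function(tab, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(tab, path, na = "")
  path
}

# Uniform-background model over a reduced alphabet: background is zero
# outside `letters`, uniform within.
reduced_background <- function(letters) {
  bg <- stats::setNames(rep(0, 20), pptarget:::AA20)
  bg[letters] <- 1 / length(letters)
  bg
}

# Exhaustive enumeration oracle for motif p-values over a reduced alphabet:
# scores every possible L-mer and returns P(score >= s) for each query score.
enumerate_pvalues <- function(model, letters, scores) {
  L <- model$length
  grids <- rep(list(letters), L)
  all_mers <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  total <- vapply(seq_len(nrow(all_mers)), function(r) {
    sum(vapply(seq_len(L), function(i) {
      model$weights_int[i, all_mers[r, i][[1]]]
    }, numeric(1)))
  }, numeric(1))
  vapply(scores, function(s) mean(total >= s), numeric(1))
}
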