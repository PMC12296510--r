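#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pt sd rnorm runif plogis quantile median var setNames
NULL

## The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Metadata columns every phosphosite table carries; everything else is a sample.
PHOSPHO_META <- c("accession", "position", "residue",
                  "localization_prob", "multiplicity")

#' Site keys
#'
#' A site key is the exact identity used when intersecting datasets:
#' `"accession|position|residue"`. Equality is exact string equality.
#'
#' @param accession Protein identifier(s).
#' @param position 1-based residue index (integer, >= 1).
#' @param residue One of `"S"`, `"T"`, `"Y"`.
#' @return Character vector of keys.
#' @export
site_key <- function(accession, position, residue) {
  stopifnot(all(position >= 1))
  bad <- !residue %in% c("S", "T", "Y")
  if (any(bad)) {
    abort(paste0("Unknown residue letter(s): ",
                 paste(unique(residue[bad]), collapse = ", ")))
  }
  paste(accession, position, residue, sep = "|")
}

#' @rdname site_key
#' @param x A data frame with `accession`, `position`, `residue` columns.
#' @export
site_keys <- function(x) {
  site_key(x$accession, x$position, x$residue)
}

## Split keys back into their components.
split_site_keys <- function(keys) {
  parts <- stringr::str_split_fixed(keys, stringr::fixed("|"), 3)
  tibble(accession = parts[, 1],
         position = as.integer(parts[, 2]),
         residue = parts[, 3])
}

#' Sample columns and experimental design of a phosphosite table
#'
#' Phosphosite tables are wide tibbles: the metadata columns
#' `accession`, `position`, `residue`, `localization_prob`, `multiplicity`,
#' followed by one numeric log2-intensity column per sample. Sample columns
#' follow the `"condition_replicate"` naming convention (single underscore
#' separating the condition label from the replicate token, e.g. `ctrl_1`).
#'
#' @param x A phosphosite tibble.
#' @return `sample_columns()`: character vector of sample column names.
#'   `table_design()`: a tibble with `sample`, `condition`, `replicate`.
#' @export
sample_columns <- function(x) {
  setdiff(names(x), PHOSPHO_META)
}

#' @rdname sample_columns
#' @export
table_design <- function(x) {
  smp <- if (is.data.frame(x)) sample_columns(x) else x
  ok <- grepl("^.+_[^_]+$", smp)
  if (!all(ok)) {
    abort(paste0("Sample name(s) not in 'condition_replicate' form: ",
                 paste(smp[!ok], collapse = ", ")))
  }
  tibble(
    sample = smp,
    condition = sub("_[^_]+$", "", smp),
    replicate = sub("^.*_", "", smp)
  )
}

## Extract the sample block as a numeric matrix (sites x samples).
values_matrix <- function(x) {
  m <- as.matrix(x[, sample_columns(x), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- site_keys(x)
  m
}

## Put a values matrix back into the tibble (same shape, same order).
set_values <- function(x, m) {
  stopifnot(identical(dim(m), dim(values_matrix(x))))
  x[, sample_columns(x)] <- as_tibble(m, .name_repair = "minimal")
  x
}

#' Validate a phosphosite table
#'
#' Checks column presence, residue letters, localization probabilities,
#' duplicate keys, and that every non-missing intensity is finite.
#'
#' @param x A phosphosite tibble.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_phospho_table <- function(x) {
  missing_cols <- setdiff(PHOSPHO_META, names(x))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(!x$residue %in% c("S", "T", "Y"))) {
    abort(paste0("Unknown residue letter(s): ",
                 paste(setdiff(unique(x$residue), c("S", "T", "Y")),
                       collapse = ", ")))
  }
  if (any(x$position < 1)) abort("Site positions must be >= 1 (1-based).")
  lp <- x$localization_prob
  if (any(!is.na(lp) & (lp < 0 | lp > 1))) {
    abort("localization_prob must lie in [0, 1].")
  }
  full_key <- paste(site_keys(x), x$multiplicity, sep = "|")
  if (anyDuplicated(full_key)) {
    abort(paste0("Duplicate (site, multiplicity) row(s): ",
                 paste(unique(full_key[duplicated(full_key)]), collapse = ", ")))
  }
  m <- values_matrix(x)
  if (any(is.infinite(m))) abort("Non-finite intensity values present.")
  table_design(x)  # errors on malformed sample names
  invisible(x)
}

## Seed-scoped evaluation: run code under a fixed RNG state when seed is given.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
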