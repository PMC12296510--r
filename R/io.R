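#' Read a quantified phosphosite report table
#'
#' Ingests site-level TSV reports of the kind exported by DIA search software,
#' in either wide form (one intensity column per sample) or long form
#' (`sample` + `intensity` columns). Required metadata columns:
#' `accession`, `position`, `residue`, `localization_prob`
#' (`localization_probability` is accepted and renamed); `multiplicity` is
#' optional and defaults to 1. Intensities are assumed to be log2-scale;
#' empty cells and `NA` both read as missing.
#'
#' Sample-to-condition mapping is taken from the `"condition_replicate"`
#' column-name convention unless an explicit `design` tibble
#' (`sample`, `condition`, `replicate`) is supplied, in which case sample
#' columns are renamed to the canonical convention.
#'
#' @param path Path to a TSV file.
#' @param format `"wide"` (default) or `"long"`.
#' @param design Optional design tibble mapping sample names to conditions.
#' @return A validated phosphosite tibble (see [sample_columns()]).
#' @export
read_phospho_table <- function(path, format = c("wide", "long"), design = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE,
                         progress = FALSE)
  if ("localization_probability" %in% names(raw) &&
      !"localization_prob" %in% names(raw)) {
    raw <- dplyr::rename(raw, localization_prob = "localization_probability")
  }
  required <- c("accession", "position", "residue", "localization_prob")
  if (format == "long") required <- c(required, "sample", "intensity")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"multiplicity" %in% names(raw)) raw$multiplicity <- 1L
  raw$position <- as.integer(raw$position)
  raw$multiplicity <- as.integer(raw$multiplicity)

  if (format == "long") {
    bad <- which(!is.na(raw$intensity) &
                   is.na(suppressWarnings(as.numeric(raw$intensity))))
    if (length(bad)) {
      abort(paste0("Non-numeric intensity at row(s): ",
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
    raw$intensity <- as.numeric(raw$intensity)
    x <- tidyr::pivot_wider(raw,
                            id_cols = dplyr::all_of(PHOSPHO_META),
                            names_from = "sample",
                            values_from = "intensity")
  } else {
    smp <- setdiff(names(raw), c(PHOSPHO_META, "localization_probability"))
    for (s in smp) {
      v <- raw[[s]]
      if (!is.numeric(v)) {
        bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
        if (length(bad)) {
          abort(paste0("Non-numeric intensity in column '", s,
                       "' at row(s): ",
                       paste(utils::head(bad, 5), collapse = ", ")))
        }
        raw[[s]] <- as.numeric(v)
      }
    }
    x <- dplyr::relocate(raw, dplyr::all_of(PHOSPHO_META))
  }

  if (!is.null(design)) {
    stopifnot(all(c("sample", "condition", "replicate") %in% names(design)))
    old <- design$sample
    new <- paste(design$condition, design$replicate, sep = "_")
    missing_smp <- setdiff(old, names(x))
    if (length(missing_smp)) {
      abort(paste0("Design names sample(s) absent from table: ",
                   paste(missing_smp, collapse = ", ")))
    }
    names(x)[match(old, names(x))] <- new
  }
  validate_phospho_table(as_tibble(x))
  as_tibble(x)
}

#' Read protein sequences from FASTA
#'
#' Accessions are the first whitespace-delimited token of each header and
#' must be unique. Sequences are uppercased; non-standard letters are kept
#' but reported.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) abort(paste0("Empty FASTA file: ", path))
  acc <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(acc)) {
    abort(paste0("Duplicate accession(s) in FASTA: ",
                 paste(unique(acc[duplicated(acc)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- acc
  odd <- acc[grepl(paste0("[^", paste(AA20, collapse = ""), "]"), seqs)]
  if (length(odd)) {
    inform(paste0("Non-standard letters in ", length(odd), " sequence(s): ",
                  paste(utils::head(odd, 5), collapse = ", ")))
  }
  seqs
}

#' Read per-residue disorder tracks
#'
#' Long-format TSV with columns `accession`, `position`, `score`
#' (scores in \[0, 1\]).
#'
#' @param path Path to a TSV file.
#' @return Tibble with one row per residue.
#' @export
read_disorder_tracks <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("accession", "position", "score"), names(x))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(x$score < 0 | x$score > 1, na.rm = TRUE)) {
    abort("Disorder scores must lie in [0, 1].")
  }
  x$position <- as.integer(x$position)
  as_tibble(x)
}

#' Write a stage result with a run-metadata sidecar
#'
#' Writes `x` as TSV (missing values as empty strings) or JSON (missing as
#' null), preserving column order, and always writes a
#' `<path>.meta.json` sidecar recording the seed, parameters, and a content
#' hash so runs are reproducible.
#'
#' @param x A data frame.
#' @param path Output file path; parent directories are created.
#' @param format `"tsv"` or `"json"`.
#' @param seed,params Optional run metadata recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("tsv", "json"),
                          seed = NULL, params = list()) {
  format <- match.arg(format)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "tsv") {
    readr::write_tsv(x, path, na = "")
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  meta <- list(
    written = format(Sys.time(), tz = "UTC"),
    format = format,
    n_rows = nrow(x),
    columns = names(x),
    seed = seed,
    params = params,
    content_hash = rlang::hash(x)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
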