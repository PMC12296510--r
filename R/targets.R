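#' Construct a named set of target-site keys
#'
#' Site identity for cross-dataset intersection is
#' `(accession, position, residue)`; by default multiply phosphorylated
#' variants are collapsed to one entry per key (the most significant variant
#' when a `q_value` column is present). Set `keep_multiplicity = TRUE` to
#' key on `(accession, position, residue, multiplicity)` instead.
#'
#' @param x Character vector of site keys, or a tibble with key columns
#'   (e.g. a [call_sensitivity()] result, optionally pre-filtered).
#' @param name Set name.
#' @param provenance Contributing contrast name(s) (default: `name`).
#' @param keep_multiplicity Keep multiplicity in the key (default `FALSE`).
#' @return A `target_set` (list with `name`, `sites`, `provenance`).
#' @export
target_set <- function(x, name, provenance = name,
                       keep_multiplicity = FALSE) {
  if (!length(provenance)) abort("provenance must be non-empty.")
  if (is.character(x)) {
    keys <- unique(x)
  } else {
    if (!keep_multiplicity && "q_value" %in% names(x)) {
      x <- dplyr::slice_min(
        dplyr::group_by(x, .data$accession, .data$position, .data$residue),
        .data$q_value, n = 1, with_ties = FALSE)
      x <- dplyr::ungroup(x)
    }
    keys <- site_keys(x)
    if (keep_multiplicity && "multiplicity" %in% names(x)) {
      keys <- paste(keys, x$multiplicity, sep = "|")
    }
    keys <- unique(keys)
  }
  structure(list(name = name, sites = keys, provenance = provenance),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("<target_set> ", x$name, ": ", length(x$sites), " sites (from ",
      paste(x$provenance, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Intersect target-call sets and tabulate Venn regions
#'
#' Computes the full intersection of two or more identically keyed sets plus
#' the counts of every non-empty Venn region (2^n - 1 regions); region
#' counts partition the union.
#'
#' @param sets List of `target_set` objects (or named list of key vectors).
#' @return A `target_overlap` list: `intersection` (a `target_set`),
#'   `venn` (tibble `region`, `count`), `n_union`, `set_sizes`.
#' @export
intersect_calls <- function(sets) {
  if (length(sets) < 2) abort("Need at least two sets.")
  sets <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "target_set")) s
    else target_set(s, name = names(sets)[i] %||% paste0("set", i))
  })
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort("Duplicate set names.")
  universe <- unique(unlist(lapply(sets, `[[`, "sites")))
  member <- vapply(sets, function(s) universe %in% s$sites,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  region <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  venn <- dplyr::count(tibble(region = region), .data$region, name = "count")
  inter_keys <- universe[rowSums(member) == length(sets)]
  structure(list(
    intersection = structure(
      list(name = paste(nm, collapse = " & "), sites = inter_keys,
           provenance = unlist(lapply(sets, `[[`, "provenance"))),
      class = "target_set"),
    venn = venn,
    n_union = length(universe),
    set_sizes = setNames(lengths(lapply(sets, `[[`, "sites")), nm)
  ), class = "target_overlap")
}

#' @export
print.target_overlap <- function(x, ...) {
  cat("<target_overlap> ", length(x$set_sizes), " sets, union ",
      x$n_union, ", intersection ", length(x$intersection$sites), "\n",
      sep = "")
  print(x$venn)
  invisible(x)
}

#' Summarize a target set per source protein
#'
#' @param set A `target_set`.
#' @param proteome Optional named sequence vector; keys whose accession is
#'   absent are counted as unmapped.
#' @return A `target_summary` list: `per_protein` (tibble `accession`,
#'   `n_sites`, `sites`), `distribution` (tibble `n_sites`, `n_proteins`),
#'   `n_unmapped`.
#' @export
summarize_targets <- function(set, proteome = NULL) {
  stopifnot(inherits(set, "target_set"))
  if (!length(set$sites)) {
    return(structure(list(
      per_protein = tibble(accession = character(), n_sites = integer(),
                           sites = list()),
      distribution = tibble(n_sites = integer(), n_proteins = integer()),
      n_unmapped = 0L), class = "target_summary"))
  }
  parsed <- split_site_keys(set$sites)
  n_unmapped <- 0L
  if (!is.null(proteome)) {
    unmapped <- !parsed$accession %in% names(proteome)
    n_unmapped <- sum(unmapped)
    if (n_unmapped > 0) {
      inform(paste0("summarize_targets: ", n_unmapped,
                    " site(s) on accessions absent from the proteome."))
    }
    parsed <- parsed[!unmapped, , drop = FALSE]
  }
  per_protein <- dplyr::summarise(
    dplyr::group_by(parsed, .data$accession),
    n_sites = dplyr::n(),
    sites = list(paste0(.data$residue, .data$position)),
    .groups = "drop")
  distribution <- dplyr::count(per_protein, .data$n_sites,
                               name = "n_proteins")
  structure(list(per_protein = per_protein, distribution = distribution,
                 n_unmapped = n_unmapped), class = "target_summary")
}

#' @export
print.target_summary <- function(x, ...) {
  cat("<target_summary> ", sum(x$per_protein$n_sites), " sites on ",
      nrow(x$per_protein), " proteins (", x$n_unmapped, " unmapped)\n",
      sep = "")
  print(x$distribution)
  invisible(x)
}

#' Overlap a target set with a user-supplied reference list
#'
#' Generic comparison against an external published target list: site-level
#' and protein-level overlaps. No reference lists are packaged.
#'
#' @param set A `target_set`.
#' @param reference Character vector of site keys
#'   (`"accession|position|residue"`).
#' @return Tibble with one row: sizes and overlap counts at site and
#'   protein level.
#' @export
overlap_with_reference <- function(set, reference) {
  stopifnot(inherits(set, "target_set"))
  reference <- unique(reference)
  shared_sites <- intersect(set$sites, reference)
  prot <- function(keys) unique(split_site_keys(keys)$accession)
  tibble(
    n_set_sites = length(set$sites),
    n_reference_sites = length(reference),
    n_shared_sites = length(shared_sites),
    n_set_proteins = length(prot(set$sites)),
    n_reference_proteins = length(prot(reference)),
    n_shared_proteins = length(intersect(prot(set$sites), prot(reference)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
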