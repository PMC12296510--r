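#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a position probability matrix
#'
#' @param x A `ppm`.
#' @param ... Unused.
#' @return Long tibble: `position` (integer offset), `aa`, `frequency`.
#' @method tidy ppm
#' @export
tidy.ppm <- function(x, ...) {
  tibble(
    position = rep(as.integer(colnames(x)), each = nrow(x)),
    aa = rep(rownames(x), times = ncol(x)),
    frequency = as.vector(unclass(x))
  )
}

#' Tidy a preference matrix
#'
#' @param x A `preference_matrix`.
#' @param ... Unused.
#' @return Long tibble: `position`, `aa`, `log2_ratio`, `masked`.
#' @method tidy preference_matrix
#' @export
tidy.preference_matrix <- function(x, ...) {
  tibble(
    position = rep(as.integer(colnames(x)), each = nrow(x)),
    aa = rep(rownames(x), times = ncol(x)),
    log2_ratio = as.vector(unclass(x)),
    masked = as.vector(attr(x, "mask"))
  )
}

#' Tidy a motif model (per-position log2-odds weights)
#'
#' @param x A `motif_model`.
#' @param ... Unused.
#' @return Long tibble: `position`, `aa`, `probability`, `weight`.
#' @method tidy motif_model
#' @export
tidy.motif_model <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$length), times = 20),
    aa = rep(AA20, each = x$length),
    probability = as.vector(x$prob),
    weight = as.vector(x$weights)
  )
}

#' One-row summary of a motif model
#'
#' @param x A `motif_model`.
#' @param ... Unused.
#' @return Tibble with id, length, maximal score, the best attainable exact
#'   p-value, and the default emission threshold.
#' @method glance motif_model
#' @export
glance.motif_model <- function(x, ...) {
  tibble(
    id = x$id,
    length = x$length,
    max_score = x$max_score_int * x$granularity,
    min_p = x$min_p,
    p_threshold = x$p_threshold,
    granularity = x$granularity
  )
}

#' Tidy the Venn regions of a target-set overlap
#'
#' @param x A `target_overlap`.
#' @param ... Unused.
#' @return The `venn` tibble (`region`, `count`).
#' @method tidy target_overlap
#' @export
tidy.target_overlap <- function(x, ...) x$venn

#' One-row summary of a target-set overlap
#'
#' @param x A `target_overlap`.
#' @param ... Unused.
#' @return Tibble with set count, union size, intersection size.
#' @method glance target_overlap
#' @export
glance.target_overlap <- function(x, ...) {
  tibble(
    n_sets = length(x$set_sizes),
    n_union = x$n_union,
    n_intersection = length(x$intersection$sites)
  )
}

#' Tidy simulated ground truth (per-site record)
#'
#' @param x A `sim_truth`.
#' @param ... Unused.
#' @return The per-site truth tibble.
#' @method tidy sim_truth
#' @export
tidy.sim_truth <- function(x, ...) as_tibble(x$sites)

#' One-row summary of simulated ground truth
#'
#' @param x A `sim_truth`.
#' @param ... Unused.
#' @return Tibble with site count and per-mechanism missingness rates.
#' @method glance sim_truth
#' @export
glance.sim_truth <- function(x, ...) {
  mech <- table(x$mechanism$mechanism)
  tot <- sum(mech)
  n_of <- function(k) if (k %in% names(mech)) unname(mech[[k]]) else 0L
  tibble(
    n_sites = nrow(x$sites),
    n_cells = tot,
    frac_mnar = n_of("mnar") / tot,
    frac_mcar = n_of("mcar") / tot
  )
}
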