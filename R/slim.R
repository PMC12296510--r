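#' Default SLiM specifications for PP2A regulatory-subunit families
#'
#' Returns the docking-motif patterns the scanner ships with:
#'
#' * `B56`: the classic LxxIxE-class B56 docking motif
#'   `"[LMFI]xx[IVL]x[ED]"`. Note its information content (~8.4 bits under a
#'   uniform background) caps the best attainable exact p-value at ~3e-3, so
#'   at the default `p_threshold = 1e-4` no hit can be emitted;
#'   [scan_sequence()] warns when this happens. For threshold-level scanning
#'   supply a probability matrix, use `B56ext`, or raise the threshold.
#' * `B56ext`: an acidic-extended LxxIxE-class variant
#'   `"[LMFI]xx[IVL]x[ED]xx[ED][ED]"` with enough information (~15 bits) to
#'   clear p = 1e-4; also the synthetic generator's default embedding.
#' * `B55b`, `B55H`, `B55H2`: **placeholders only.** The B55-family motif
#'   definitions are not machine-readable here; confirm these against the
#'   primary literature before drawing conclusions from B55 scans.
#'
#' @return Named list of pattern strings.
#' @export
default_motifs <- function() {
  list(
    B56    = "[LMFI]xx[IVL]x[ED]",
    B56ext = "[LMFI]xx[IVL]x[ED]xx[ED][ED]",
    B55b   = "[RK]x[VI]xx[RK]",   # placeholder -- confirm before use
    B55H   = "[ILV]xx[ILV][RK]x[RK]",  # placeholder -- confirm before use
    B55H2  = "[RK]xx[ILV][ILV]x[DE]"   # placeholder -- confirm before use
  )
}

## Parse a degenerate pattern ("[LMFI]xx[IVL]x[ED]") into a list of
## per-position letter sets; NULL marks a wildcard.
parse_motif_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  sets <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1
      grp <- character()
      while (j <= length(chars) && chars[j] != "]") {
        grp <- c(grp, toupper(chars[j]))
        j <- j + 1
      }
      if (j > length(chars)) abort("Unclosed '[' in motif pattern.")
      if (!length(grp)) abort("Empty '[]' group in motif pattern.")
      bad <- setdiff(grp, AA20)
      if (length(bad)) {
        abort(paste0("Unknown letter(s) in motif pattern: ",
                     paste(bad, collapse = ", ")))
      }
      sets[[length(sets) + 1]] <- unique(grp)
      i <- j + 1
    } else if (ch %in% c("x", "X", ".")) {
      sets[length(sets) + 1] <- list(NULL)  # wildcard position
      i <- i + 1
    } else {
      ch <- toupper(ch)
      if (!ch %in% AA20) {
        abort(paste0("Unknown letter in motif pattern: ", ch))
      }
      sets[[length(sets) + 1]] <- ch
      i <- i + 1
    }
  }
  if (!length(sets)) abort("Empty motif pattern.")
  sets
}

## Probability matrix (L x 20) from per-position letter sets.
pattern_prob_matrix <- function(sets, background) {
  L <- length(sets)
  prob <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA20))
  for (i in seq_len(L)) {
    s <- sets[[i]]
    if (is.null(s)) {
      prob[i, ] <- background
    } else {
      prob[i, s] <- 1 / length(s)
    }
  }
  prob
}

#' Compile a SLiM specification to a scoring model
#'
#' Accepts either a degenerate pattern over IUPAC-style amino-acid classes
#' (single letters, bracketed sets, `x` wildcards) or an explicit L x 20
#' probability matrix (columns named by one-letter code). Per-position
#' probabilities are mixed with the background using a pseudocount and
#' converted to log2-odds weights; an exact null score distribution is
#' pre-computed by dynamic programming on a discretized score grid so p-values
#' are exact up to the granularity.
#'
#' @param spec Pattern string or L x 20 probability matrix.
#' @param id Motif identifier carried into hits.
#' @param background Named amino-acid frequency vector (default uniform 1/20);
#'   normalized internally. Letters with zero background probability receive
#'   `-Inf` weight and cannot contribute to hits.
#' @param pseudocount Pseudocount fraction mixed into the probabilities
#'   (default 0.1): `p' = (p + pseudocount * background) / (1 + pseudocount)`.
#' @param granularity Score discretization step in bits (default 0.001); the
#'   induced p-value error is bounded by `L * granularity` bits of score. If
#'   the score table would have fewer than 100 bins the granularity is
#'   auto-refined with a warning.
#' @param p_threshold Default emission threshold for [scan_sequence()].
#' @return A `motif_model` object.
#' @export
compile_motif <- function(spec, id = "motif", background = NULL,
                          pseudocount = 0.1, granularity = 0.001,
                          p_threshold = 1e-4) {
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), AA20)
  stopifnot(all(AA20 %in% names(background)))
  background <- background[AA20]
  background <- background / sum(background)

  if (is.character(spec)) {
    sets <- parse_motif_pattern(spec)
    prob <- pattern_prob_matrix(sets, background)
    pattern <- spec
  } else {
    prob <- as.matrix(spec)
    if (ncol(prob) == 20 && !is.null(colnames(prob))) {
      prob <- prob[, AA20, drop = FALSE]
    } else if (nrow(prob) == 20) {
      prob <- t(prob[AA20, , drop = FALSE])
    } else {
      abort("Probability matrix must be L x 20 with amino-acid names.")
    }
    if (any(prob < 0)) abort("Probabilities must be non-negative.")
    prob <- prob / rowSums(prob)
    pattern <- NULL
  }
  L <- nrow(prob)
  if (L < 3) abort("Motif length must be >= 3.")

  padj <- sweep(prob, 2, pseudocount * background, `+`) / (1 + pseudocount)
  weights <- log2(sweep(padj, 2, background, `/`))
  weights[, background == 0] <- -Inf  # letters the background cannot emit

  model <- build_score_table(list(
    id = id, length = L, prob = prob, weights = weights,
    background = background, pattern = pattern,
    pseudocount = pseudocount, granularity = granularity,
    p_threshold = p_threshold
  ))
  structure(model, class = "motif_model")
}

## Discretize weights, convolve per-position score histograms under the
## background, and attach the integer-score survival function.
build_score_table <- function(model) {
  repeat {
    gran <- model$granularity
    wi <- round(model$weights / gran)
    storage.mode(wi) <- "double"  # keep -Inf representable
    bg <- model$background
    keep_letters <- bg > 0
    v <- 1
    off <- 0
    for (i in seq_len(model$length)) {
      w <- wi[i, keep_letters]
      p <- bg[keep_letters]
      fin <- is.finite(w)
      w <- w[fin]; p <- p[fin]
      lo <- off + min(w)
      hi <- off + length(v) - 1 + max(w)
      nv <- numeric(hi - lo + 1)
      for (k in seq_along(w)) {
        s <- off + w[k] - lo
        idx <- (s + 1):(s + length(v))
        nv[idx] <- nv[idx] + p[k] * v
      }
      v <- nv
      off <- lo
    }
    if (length(v) >= 100 || gran <= 1e-6) break
    if (!is.null(model$.prev_bins) && length(v) <= model$.prev_bins) {
      # refining cannot split exactly tied scores (degenerate patterns)
      break
    }
    warn(sprintf(
      "Score table has %d bins at granularity %g; refining to %g.",
      length(v), gran, gran / 10))
    model$.prev_bins <- length(v)
    model$granularity <- gran / 10
  }
  model$.prev_bins <- NULL
  sf <- rev(cumsum(rev(v)))
  model$weights_int <- wi
  model$score_offset <- off
  model$score_sf <- sf
  model$max_score_int <- off + length(v) - 1
  model$min_p <- sf[length(sf)]
  model
}

## Exact p-value for integer scores under the model's background.
motif_pvalue_int <- function(model, score_int) {
  idx <- score_int - model$score_offset + 1
  p <- rep(NA_real_, length(score_int))
  p[idx <= 0] <- 1
  inside <- idx >= 1 & idx <= length(model$score_sf)
  p[inside] <- model$score_sf[idx[inside]]
  p[idx > length(model$score_sf)] <- 0
  p
}

#' Scan a protein sequence for motif occurrences
#'
#' Scores every length-L window as the sum of per-position log2-odds weights
#' and assigns each an exact p-value: the probability, under the background
#' model, that a random L-mer scores at least as high (computed from the
#' pre-tabulated discretized score distribution, so observed scores and the
#' null table share the same discretization). Hits with `p <= p_threshold`
#' are returned sorted by start. Windows containing letters outside the
#' 20-letter alphabet are skipped.
#'
#' @param model A `motif_model` from [compile_motif()].
#' @param sequence Amino-acid sequence string.
#' @param p_threshold Emission threshold (default: the model's).
#' @return Tibble with `start`, `end`, `score` (bits), `p_value`.
#' @export
scan_sequence <- function(model, sequence, p_threshold = model$p_threshold) {
  stopifnot(inherits(model, "motif_model"))
  if (model$min_p > p_threshold) {
    warn(sprintf(
      paste0("Motif '%s': best attainable p-value is %.3g > threshold %.3g; ",
             "no window can be emitted. Supply a higher-information motif ",
             "(e.g. a probability matrix) or raise p_threshold."),
      model$id, model$min_p, p_threshold))
  }
  L <- model$length
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars) - L + 1
  if (n < 1) abort("Sequence shorter than the motif.")
  idx <- match(chars, AA20)
  scores <- rep(0, n)
  for (i in seq_len(L)) {
    scores <- scores + unname(model$weights_int[i, ])[idx[i:(i + n - 1)]]
  }
  ok <- is.finite(scores)
  p <- rep(NA_real_, n)
  p[ok] <- motif_pvalue_int(model, scores[ok])
  hit <- which(ok & p <= p_threshold)
  tibble(
    start = hit,
    end = hit + L - 1L,
    score = scores[hit] * model$granularity,
    p_value = p[hit]
  )
}

#' Scan a whole proteome with one or more motif models
#'
#' @param models A `motif_model` or (named) list of them.
#' @param proteome Named character vector of sequences.
#' @param p_threshold Optional threshold overriding each model's default.
#' @return Tibble with `accession`, `motif`, `start`, `end`, `score`,
#'   `p_value`.
#' @export
scan_proteome <- function(models, proteome, p_threshold = NULL) {
  if (inherits(models, "motif_model")) models <- list(models)
  purrr::map_dfr(models, function(m) {
    thr <- if (is.null(p_threshold)) m$p_threshold else p_threshold
    purrr::imap_dfr(proteome, function(seq, acc) {
      if (nchar(seq) < m$length) return(tibble())
      h <- scan_sequence(m, seq, p_threshold = thr)
      if (nrow(h)) dplyr::mutate(h, accession = acc, motif = m$id,
                                 .before = 1) else tibble()
    })
  })
}

#' Classify motif hits by spacer geometry relative to phosphosites
#'
#' Pairs every hit with every called site on the same protein and assigns a
#' spacer class: `overlapping` when the site lies inside the motif span;
#' `upstream` when the motif ends at least `upstream_min` residues before the
#' site (spacer = site - end); `downstream` when the motif starts at least
#' `downstream_min` residues after the site (spacer = start - site);
#' otherwise `unassigned`. Defaults (10 / 20) are the B56 rule and are applied
#' to every family unless per-motif `rules` are given.
#'
#' @param hits Tibble from [scan_proteome()] (needs `accession`, `motif`,
#'   `start`, `end`).
#' @param sites Tibble of called sites (`accession`, `position`, `residue`).
#' @param upstream_min,downstream_min Default minimum spacers (residues).
#' @param rules Optional tibble (`motif`, `upstream_min`, `downstream_min`)
#'   overriding the defaults per motif.
#' @return One row per (hit, site) pair with `site_position`, `spacer`,
#'   `spacer_class`.
#' @export
classify_hits <- function(hits, sites, upstream_min = 10, downstream_min = 20,
                          rules = NULL) {
  if (upstream_min < 1 || downstream_min < 1) {
    abort("Spacer thresholds must be >= 1.")
  }
  paired <- dplyr::inner_join(
    hits,
    dplyr::select(sites, "accession", site_position = "position",
                  site_residue = "residue"),
    by = "accession", relationship = "many-to-many"
  )
  if (!is.null(rules)) {
    paired <- dplyr::left_join(paired, rules, by = "motif")
    paired$upstream_min <- dplyr::coalesce(paired$upstream_min, upstream_min)
    paired$downstream_min <- dplyr::coalesce(paired$downstream_min,
                                             downstream_min)
  } else {
    paired$upstream_min <- upstream_min
    paired$downstream_min <- downstream_min
  }
  dplyr::mutate(paired,
    spacer_class = dplyr::case_when(
      .data$site_position >= .data$start &
        .data$site_position <= .data$end ~ "overlapping",
      .data$end <= .data$site_position - .data$upstream_min ~ "upstream",
      .data$start >= .data$site_position + .data$downstream_min ~ "downstream",
      TRUE ~ "unassigned"
    ),
    spacer = dplyr::case_when(
      .data$spacer_class == "overlapping" ~ 0L,
      .data$start > .data$site_position ~
        as.integer(.data$start - .data$site_position),
      TRUE ~ as.integer(.data$site_position - .data$end)
    ),
    upstream_min = NULL, downstream_min = NULL
  )
}

#' Flag motif hits in intrinsically disordered regions
#'
#' A hit is disordered when the mean per-residue disorder score over its span
#' is at least `threshold` (boundary inclusive).
#'
#' @param hits Tibble with `accession`, `start`, `end`.
#' @param tracks Disorder tracks: tibble (`accession`, `position`, `score`)
#'   or named list of numeric vectors.
#' @param threshold Mean-disorder cutoff (default 0.5).
#' @return `hits` with a logical `disordered` column.
#' @export
disorder_classify <- function(hits, tracks, threshold = 0.5) {
  if (is.data.frame(tracks)) {
    tracks <- split(tracks$score[order(tracks$accession, tracks$position)],
                    sort(tracks$accession))
    tracks <- lapply(tracks, as.numeric)
  }
  mean_disorder <- purrr::pmap_dbl(
    list(hits$accession, hits$start, hits$end),
    function(acc, s, e) {
      tr <- tracks[[acc]]
      if (is.null(tr)) abort(paste0("No disorder track for ", acc))
      if (length(tr) < e) {
        abort(paste0("Disorder track for ", acc, " shorter than motif end (",
                     length(tr), " < ", e, ")."))
      }
      mean(tr[s:e])
    }
  )
  dplyr::mutate(hits, mean_disorder = mean_disorder,
                disordered = mean_disorder >= threshold)
}

#' Spacer distributions by motif family
#'
#' Summarizes upstream/downstream spacers per motif family: count, mean, sd,
#' quartiles, and the moment-based skewness and excess kurtosis (reported as
#' descriptive statistics; no normality verdict is issued).
#'
#' @param hits Classified hits from [classify_hits()].
#' @param by Grouping column (default `"motif"`).
#' @return Tibble of per-group summaries.
#' @export
spacer_distribution <- function(hits, by = "motif") {
  usable <- dplyr::filter(hits,
                          .data$spacer_class %in% c("upstream", "downstream"))
  if (!nrow(usable)) abort("No upstream/downstream hits to summarize.")
  dplyr::summarise(
    dplyr::group_by(usable, dplyr::across(dplyr::all_of(by))),
    n = dplyr::n(),
    mean = mean(.data$spacer),
    sd = if (dplyr::n() >= 2) stats::sd(.data$spacer) else NA_real_,
    q25 = stats::quantile(.data$spacer, 0.25),
    median = stats::median(.data$spacer),
    q75 = stats::quantile(.data$spacer, 0.75),
    skewness = moment_skewness(.data$spacer),
    excess_kurtosis = moment_kurtosis(.data$spacer),
    .groups = "drop"
  )
}

moment_skewness <- function(x) {
  if (length(x) < 3) return(NA_real_)
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(NA_real_)
  mean((x - m)^3) / s^3
}

moment_kurtosis <- function(x) {
  if (length(x) < 4) return(NA_real_)
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^4) / s2^2 - 3
}

#' Count target sites by docking-motif family carried on their protein
#'
#' Partitions called sites by whether their source protein carries hits from
#' the B55 family only, the B56 family only, or both; sites on proteins with
#' no family hit are reported as `none`. Categories are disjoint and sum to
#' the number of input sites.
#'
#' @param sites Tibble of called sites (`accession`, `position`, `residue`).
#' @param hits Motif hits with `accession` and `motif` columns.
#' @param families Named character vector mapping motif ids to families;
#'   by default ids starting `B55`/`B56` map to those families and anything
#'   else maps to itself.
#' @return Tibble with `category` (`B55_only`, `B56_only`, `both`, `none`)
#'   and `n_sites`, plus per-protein family flags as an attribute.
#' @export
count_slim_site_assignments <- function(sites, hits, families = NULL) {
  fam <- function(id) {
    if (!is.null(families)) {
      out <- unname(families[id])
      out[is.na(out)] <- id[is.na(out)]
      return(out)
    }
    dplyr::case_when(
      startsWith(id, "B55") ~ "B55",
      startsWith(id, "B56") ~ "B56",
      TRUE ~ id
    )
  }
  prot <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(hits, family = fam(.data$motif)),
                    .data$accession),
    has_b55 = any(.data$family == "B55"),
    has_b56 = any(.data$family == "B56"),
    .groups = "drop"
  )
  tagged <- dplyr::left_join(sites, prot, by = "accession")
  tagged$has_b55[is.na(tagged$has_b55)] <- FALSE
  tagged$has_b56[is.na(tagged$has_b56)] <- FALSE
  tagged <- dplyr::mutate(tagged, category = dplyr::case_when(
    .data$has_b55 & .data$has_b56 ~ "both",
    .data$has_b55 ~ "B55_only",
    .data$has_b56 ~ "B56_only",
    TRUE ~ "none"
  ))
  counts <- dplyr::count(tagged, .data$category, name = "n_sites")
  counts <- dplyr::left_join(
    tibble(category = c("B55_only", "B56_only", "both", "none")),
    counts, by = "category")
  counts$n_sites[is.na(counts$n_sites)] <- 0L
  attr(counts, "per_protein") <- prot
  counts
}
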