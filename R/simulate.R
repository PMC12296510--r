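#' Simulate a proteome with embedded docking motifs and disorder tracks
#'
#' Generates random protein sequences residue-wise from a background
#' amino-acid frequency table (uniform by default), writes the requested
#' number of docking-motif instances into them at recorded coordinates, pairs
#' each instance with a phosphorylatable residue (S or T) at a spacer drawn
#' from the configured ranges, and produces per-residue disorder tracks that
#' are elevated over embedded motif spans and low elsewhere. Fully
#' deterministic given `seed`.
#'
#' Each embedded instance is drawn uniformly from the consensus set of
#' `motif_pattern` (wildcard positions from the background). For `upstream`
#' embeddings the motif lies before the site with
#' `spacer = site - motif_end`; for `downstream` embeddings after it with
#' `spacer = motif_start - site`. Default spacer ranges respect the B56
#' classification rule (>= 10 upstream, >= 20 downstream).
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer `(min, max)` protein lengths.
#' @param background Named amino-acid frequency vector (default uniform).
#' @param n_motifs Number of motif instances to embed (default 0).
#' @param motif_pattern Degenerate pattern to embed. Default is the
#'   acidic-extended B56-class docking motif (see [default_motifs()]), whose
#'   information content supports detection at p <= 1e-4.
#' @param motif_id Identifier recorded for embedded instances.
#' @param spacer_classes Classes to draw embeddings from
#'   (`"upstream"`, `"downstream"`).
#' @param upstream_spacer,downstream_spacer Integer spacer ranges.
#' @param disorder_base,disorder_motif Target disorder levels outside/over
#'   motif spans (tracks are smoothed noise clipped to \[0, 1\]).
#' @param max_tries Placement retries per embedding before erroring.
#' @param seed Integer seed (optional).
#' @return A `sim_proteome` list: `sequences` (named character),
#'   `disorder` (tibble `accession`, `position`, `score`), `motifs`
#'   (tibble of embedded instances with paired sites and true spacers),
#'   `background`, `params`.
#' @export
simulate_proteome <- function(n_proteins = 50, length_range = c(200, 600),
                              background = NULL, n_motifs = 0,
                              motif_pattern = default_motifs()$B56ext,
                              motif_id = "B56",
                              spacer_classes = c("upstream", "downstream"),
                              upstream_spacer = c(12, 40),
                              downstream_spacer = c(25, 60),
                              disorder_base = 0.18, disorder_motif = 0.85,
                              max_tries = 100, seed = NULL) {
  stopifnot(n_proteins >= 1, length_range[1] <= length_range[2])
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), AA20)
  background <- background[AA20] / sum(background[AA20])
  sets <- parse_motif_pattern(motif_pattern)
  L <- length(sets)
  if (L > length_range[1]) abort("Motif longer than the shortest protein.")

  with_seed_if(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                   replace = TRUE)
    acc <- sprintf("SP%04d", seq_len(n_proteins))
    seqs <- lapply(lens, function(n) sample(AA20, n, replace = TRUE,
                                            prob = background))
    occupied <- lapply(lens, function(n) logical(n))
    motifs <- vector("list", n_motifs)

    for (e in seq_len(n_motifs)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        p <- sample.int(n_proteins, 1)
        len <- lens[p]
        cls <- sample(spacer_classes, 1)
        spacer <- if (cls == "upstream") {
          sample(seq(upstream_spacer[1], upstream_spacer[2]), 1)
        } else {
          sample(seq(downstream_spacer[1], downstream_spacer[2]), 1)
        }
        if (cls == "upstream") {
          # motif ...spacer... site
          max_start <- len - (L - 1) - spacer
          if (max_start < 1) next
          start <- sample.int(max_start, 1)
          site <- start + L - 1 + spacer
        } else {
          min_start <- spacer + 1
          max_start <- len - L + 1
          if (min_start > max_start) next
          start <- sample(seq(min_start, max_start), 1)
          site <- start - spacer
        }
        span <- start:(start + L - 1)
        if (any(occupied[[p]][c(span, site)])) next
        inst <- vapply(sets, function(s) {
          if (is.null(s)) sample(AA20, 1, prob = background)
          else if (length(s) == 1) s
          else sample(s, 1)
        }, character(1))
        seqs[[p]][span] <- inst
        res <- sample(c("S", "T"), 1)
        seqs[[p]][site] <- res
        occupied[[p]][c(span, site)] <- TRUE
        motifs[[e]] <- tibble(
          accession = acc[p], motif = motif_id,
          start = start, end = start + L - 1L,
          site_position = site, site_residue = res,
          spacer = as.integer(spacer), spacer_class = cls
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        abort("Could not place a motif embedding within the retry bound.")
      }
    }
    motifs <- dplyr::bind_rows(motifs)

    disorder <- purrr::map2_dfr(seq_len(n_proteins), lens, function(p, len) {
      track <- smooth_track(runif(len, disorder_base - 0.12,
                                  disorder_base + 0.12))
      spans <- if (nrow(motifs)) {
        dplyr::filter(motifs, .data$accession == acc[p])
      } else motifs
      if (!is.null(spans) && NROW(spans) > 0) {
        for (r in seq_len(nrow(spans))) {
          lo <- max(1L, spans$start[r] - 2L)
          hi <- min(len, spans$end[r] + 2L)
          track[lo:hi] <- smooth_track(runif(hi - lo + 1,
                                             disorder_motif - 0.08,
                                             disorder_motif + 0.08))
        }
      }
      tibble(accession = acc[p], position = seq_len(len),
             score = pmin(pmax(track, 0), 1))
    })

    structure(list(
      sequences = setNames(vapply(seqs, paste, character(1), collapse = ""),
                           acc),
      disorder = disorder,
      motifs = motifs,
      background = background,
      params = list(n_proteins = n_proteins, length_range = length_range,
                    n_motifs = n_motifs, motif_pattern = motif_pattern,
                    motif_id = motif_id,
                    upstream_spacer = upstream_spacer,
                    downstream_spacer = downstream_spacer,
                    disorder_base = disorder_base,
                    disorder_motif = disorder_motif, seed = seed)
    ), class = "sim_proteome")
  })
}

## Centered running mean (window <= 7) with edge padding.
smooth_track <- function(x) {
  k <- min(7L, length(x))
  if (k %% 2 == 0) k <- k - 1L
  if (k < 3) return(x)
  pad <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  out <- as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))
  out[(pad + 1):(pad + length(x))]
}

#' Simulate a phosphosite intensity table with known ground truth
#'
#' Places phosphosites on S/T residues of a (simulated or real) proteome and
#' draws a site-by-sample log2-intensity table under a 3-replicate-style
#' group design: per-site baselines ~ Normal(`baseline_mean`, `baseline_sd`),
#' per-condition true log2 effects for a designated sensitive fraction
#' (negative shifts = dephosphorylation), replicate noise, and two
#' missingness mechanisms - intensity-dependent dropout (MNAR) with
#' `P(miss) = plogis((mnar_midpoint - true_value) / mnar_slope)` applied to
#' the pre-noise value, plus independent completely-random dropout at
#' `mcar_rate`. Set `mnar_midpoint = -Inf` for no intensity-dependent
#' dropout. Localization probabilities are drawn with a configurable
#' fraction below 0.75 to exercise the filter.
#'
#' When the proteome carries embedded motif records, their paired sites are
#' included as phosphosites and (by default) assigned to the sensitive set
#' first, emulating target sites on docking-motif-bearing proteins.
#'
#' @param proteome A `sim_proteome` or named character vector of sequences.
#' @param n_sites Number of phosphosites (default 2000).
#' @param conditions Named integer vector of replicate counts
#'   (default `c(control = 3, treated = 3)`); all counts must be >= 2.
#' @param effects Named list (one entry per non-reference condition) of
#'   `list(fraction_sensitive, log2_mean, log2_sd)`.
#' @param reference Condition receiving no effects (default first).
#' @param baseline_mean,baseline_sd Site baseline log2-intensity parameters.
#' @param replicate_sd Within-group replicate noise SD (log2).
#' @param mnar_midpoint,mnar_slope Logistic MNAR parameters (log2 units).
#' @param mcar_rate Completely-at-random dropout rate in \[0, 1\].
#' @param frac_low_localization Fraction of sites drawn below the 0.75
#'   localization cutoff.
#' @param exact_fraction If `TRUE` (default) the sensitive count is exactly
#'   `round(fraction * n_sites)`; otherwise binomial.
#' @param motif_sites_sensitive Force embedded-motif-paired sites into the
#'   sensitive set (default `TRUE`).
#' @param seed Integer seed (optional).
#' @return List with `table` (wide phosphosite tibble) and `truth`
#'   (`sites` tibble with per-condition true effects, `mechanism` long tibble
#'   labelling every cell `observed`/`mnar`/`mcar`, `params`).
#' @export
simulate_phospho_data <- function(proteome, n_sites = 2000,
                                  conditions = c(control = 3, treated = 3),
                                  effects = list(treated = list(
                                    fraction_sensitive = 0.10,
                                    log2_mean = -2, log2_sd = 0.5)),
                                  reference = names(conditions)[1],
                                  baseline_mean = 25, baseline_sd = 2.5,
                                  replicate_sd = 0.3,
                                  mnar_midpoint = 20, mnar_slope = 1.5,
                                  mcar_rate = 0.01,
                                  frac_low_localization = 0.05,
                                  exact_fraction = TRUE,
                                  motif_sites_sensitive = TRUE,
                                  seed = NULL) {
  if (any(conditions < 2)) {
    abort("Every condition needs >= 2 replicates (SVD imputation rule).")
  }
  if (mcar_rate < 0 || mcar_rate > 1) abort("mcar_rate must be in [0, 1].")
  for (eff in effects) {
    if (eff$fraction_sensitive < 0 || eff$fraction_sensitive > 1) {
      abort("fraction_sensitive must be in [0, 1].")
    }
  }
  seqs <- if (inherits(proteome, "sim_proteome")) proteome$sequences
          else proteome
  embedded <- if (inherits(proteome, "sim_proteome")) proteome$motifs
              else tibble()

  with_seed_if(seed, {
    # All S/T positions in the proteome.
    pool <- purrr::imap_dfr(seqs, function(s, acc) {
      ch <- strsplit(s, "")[[1]]
      pos <- which(ch %in% c("S", "T"))
      tibble(accession = acc, position = pos, residue = ch[pos])
    })
    pool$key <- site_keys(pool)
    must <- if (NROW(embedded) > 0 && nrow(embedded)) {
      tibble(accession = embedded$accession,
             position = embedded$site_position,
             residue = embedded$site_residue)
    } else tibble()
    must_keys <- if (nrow(must)) unique(site_keys(must)) else character()
    if (n_sites < length(must_keys)) {
      abort("n_sites smaller than the number of embedded motif sites.")
    }
    free <- pool[!pool$key %in% must_keys, ]
    n_extra <- n_sites - length(must_keys)
    if (n_extra > nrow(free)) {
      abort("Not enough S/T residues to place the requested sites.")
    }
    chosen <- dplyr::bind_rows(
      pool[match(must_keys, pool$key), ],
      free[sample.int(nrow(free), n_extra), ]
    )
    chosen <- chosen[order(chosen$accession, chosen$position), ]
    n <- nrow(chosen)

    # Sensitive sets and true effects per treated condition.
    truth_sites <- dplyr::select(chosen, -"key")
    embedded_idx <- which(chosen$key %in% must_keys)
    for (cond in names(effects)) {
      eff <- effects[[cond]]
      k <- if (exact_fraction) round(eff$fraction_sensitive * n)
           else stats::rbinom(1, n, eff$fraction_sensitive)
      idx <- integer()
      if (motif_sites_sensitive && length(embedded_idx)) {
        idx <- embedded_idx[seq_len(min(k, length(embedded_idx)))]
      }
      remaining <- setdiff(seq_len(n), idx)
      if (k > length(idx)) {
        idx <- c(idx, sample(remaining, k - length(idx)))
      }
      delta <- numeric(n)
      delta[idx] <- rnorm(length(idx), eff$log2_mean, eff$log2_sd)
      truth_sites[[paste0("sensitive_", cond)]] <- seq_len(n) %in% idx
      truth_sites[[paste0("effect_", cond)]] <- delta
    }

    # Localization probabilities.
    n_low <- round(frac_low_localization * n)
    loc <- runif(n, 0.75, 1)
    if (n_low > 0) {
      low_idx <- sample.int(n, n_low)
      loc[low_idx] <- runif(n_low, 0.30, 0.7499)
    }

    baseline <- rnorm(n, baseline_mean, baseline_sd)
    truth_sites$baseline <- baseline
    samples <- unlist(lapply(names(conditions), function(cn)
      paste(cn, seq_len(conditions[[cn]]), sep = "_")))
    cond_of <- rep(names(conditions), times = conditions)

    true_cell <- outer(baseline, rep(1, length(samples)))
    for (cond in names(effects)) {
      cols <- which(cond_of == cond)
      true_cell[, cols] <- true_cell[, cols] +
        truth_sites[[paste0("effect_", cond)]]
    }
    values <- true_cell + matrix(rnorm(n * length(samples), 0, replicate_sd),
                                 n, length(samples))

    p_mnar <- plogis((mnar_midpoint - true_cell) / mnar_slope)
    u1 <- matrix(runif(n * length(samples)), n, length(samples))
    u2 <- matrix(runif(n * length(samples)), n, length(samples))
    mech <- matrix("observed", n, length(samples))
    mech[u2 < mcar_rate] <- "mcar"
    mech[u1 < p_mnar] <- "mnar"
    values[mech != "observed"] <- NA_real_

    tab <- dplyr::bind_cols(
      tibble(accession = chosen$accession, position = chosen$position,
             residue = chosen$residue, localization_prob = loc,
             multiplicity = 1L),
      as_tibble(setNames(as.data.frame(values), samples))
    )
    mech_long <- tibble(
      accession = rep(chosen$accession, times = length(samples)),
      position = rep(chosen$position, times = length(samples)),
      residue = rep(chosen$residue, times = length(samples)),
      sample = rep(samples, each = n),
      mechanism = as.vector(mech)
    )
    list(
      table = tab,
      truth = structure(list(
        sites = truth_sites,
        mechanism = mech_long,
        params = list(n_sites = n_sites, conditions = as.list(conditions),
                      effects = effects, reference = reference,
                      baseline_mean = baseline_mean,
                      baseline_sd = baseline_sd,
                      replicate_sd = replicate_sd,
                      mnar_midpoint = mnar_midpoint,
                      mnar_slope = mnar_slope, mcar_rate = mcar_rate,
                      frac_low_localization = frac_low_localization,
                      exact_fraction = exact_fraction, seed = seed)
      ), class = "sim_truth")
    )
  })
}

#' Write a simulated proteome to FASTA / TSV files
#'
#' Emits the same formats the readers consume: a FASTA of sequences, a
#' long-format disorder-track TSV, and (when present) a TSV of embedded
#' motif coordinates.
#'
#' @param proteome A `sim_proteome`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_sim_proteome <- function(proteome, dir) {
  stopifnot(inherits(proteome, "sim_proteome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "proteome.fasta")
  writeLines(paste0(">", names(proteome$sequences), "\n",
                    proteome$sequences), fasta)
  disorder <- file.path(dir, "disorder.tsv")
  readr::write_tsv(proteome$disorder, disorder)
  paths <- c(fasta = fasta, disorder = disorder)
  if (NROW(proteome$motifs) > 0) {
    motifs <- file.path(dir, "embedded_motifs.tsv")
    readr::write_tsv(proteome$motifs, motifs)
    paths <- c(paths, motifs = motifs)
  }
  invisible(paths)
}
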