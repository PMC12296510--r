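#' Unpaired two-sample t test per phosphosite
#'
#' Pooled-variance (Student) two-sample t test of `group_a` against
#' `group_b`, two-sided, with `log2fc = mean(group_a) - mean(group_b)`.
#' Degenerate-variance convention: when the pooled variance is zero the
#' p-value is 1 if the group means are equal, and otherwise is set to the
#' smallest representable double with `degenerate = TRUE` flagged. Sites
#' with fewer than 2 observed values in either group are `not_testable`
#' (all statistics `NA`).
#'
#' @param x Phosphosite tibble.
#' @param group_a,group_b Condition labels from the table design.
#' @param contrast Contrast name carried in the output (default
#'   `"a_vs_b"` built from the labels).
#' @return Tibble: site keys, `contrast`, `n_a`, `n_b`, `log2fc`, `t_stat`,
#'   `df`, `p_value`, `degenerate`.
#' @export
ttest_contrast <- function(x, group_a, group_b,
                           contrast = paste0(group_a, "_vs_", group_b)) {
  design <- table_design(x)
  for (g in c(group_a, group_b)) {
    if (!g %in% design$condition) {
      abort(paste0("Condition '", g, "' not present in the table design."))
    }
  }
  if (group_a == group_b) abort("group_a and group_b must differ.")
  m <- values_matrix(x)
  a <- m[, design$sample[design$condition == group_a], drop = FALSE]
  b <- m[, design$sample[design$condition == group_b], drop = FALSE]
  na <- rowSums(!is.na(a))
  nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE)
  mb <- rowMeans(b, na.rm = TRUE)
  va <- apply(a, 1, var, na.rm = TRUE)
  vb <- apply(b, 1, var, na.rm = TRUE)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t_stat <- (ma - mb) / se
  p <- 2 * pt(-abs(t_stat), df)
  degenerate <- !is.na(sp2) & sp2 == 0
  eq <- degenerate & (ma == mb)
  t_stat[eq] <- 0
  p[eq] <- 1
  ne <- degenerate & (ma != mb)
  t_stat[ne] <- sign(ma - mb)[ne] * Inf
  p[ne] <- .Machine$double.xmin
  testable <- na >= 2 & nb >= 2
  out <- tibble(
    accession = x$accession, position = x$position, residue = x$residue,
    multiplicity = x$multiplicity, contrast = contrast,
    n_a = unname(na), n_b = unname(nb),
    log2fc = unname(ma - mb), t_stat = unname(t_stat), df = unname(df),
    p_value = unname(p), degenerate = unname(degenerate)
  )
  out[!testable, c("log2fc", "t_stat", "p_value")] <- NA_real_
  out$degenerate[!testable] <- NA
  out
}

#' Adjust p-values for multiple testing (Benjamini-Hochberg)
#'
#' Step-up BH q-values; invariant to input order. For the permutation-based
#' alternative, which needs the data rather than p-values, see
#' [phospho_difftest()] with `fdr_method = "permutation"`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param method Only `"bh"` here.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p, method = c("bh")) {
  match.arg(method)
  if (!length(p)) return(numeric())
  stats::p.adjust(p, method = "BH")
}

## Permutation-based plug-in FDR of the (optionally s0-moderated) t
## statistic: for each observed |t|, q = (mean permutation count of
## |t*| >= |t|) / (observed count of |t| >= |t|), capped at 1 and made
## monotone in |t|.
permutation_q <- function(a, b, n_perm = 1000, s0 = 0, seed = NULL) {
  pooled <- cbind(a, b)
  ka <- ncol(a)
  n_tot <- ncol(pooled)
  t_s0 <- function(xa, xb) {
    na <- rowSums(!is.na(xa)); nb <- rowSums(!is.na(xb))
    df <- na + nb - 2
    va <- apply(xa, 1, var, na.rm = TRUE)
    vb <- apply(xb, 1, var, na.rm = TRUE)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    (rowMeans(xa, na.rm = TRUE) - rowMeans(xb, na.rm = TRUE)) / (se + s0)
  }
  t_obs <- abs(t_s0(a, b))
  with_seed_if(seed, {
    perm_counts <- numeric(length(t_obs))
    ord <- order(t_obs)
    sorted_obs <- t_obs[ord]
    for (r in seq_len(n_perm)) {
      lab <- sample.int(n_tot, ka)
      tp <- abs(t_s0(pooled[, lab, drop = FALSE],
                     pooled[, -lab, drop = FALSE]))
      tp <- tp[is.finite(tp)]
      # count permuted |t*| >= each observed threshold
      cnt <- length(tp) - findInterval(sorted_obs - 1e-12, sort(tp))
      perm_counts[ord] <- perm_counts[ord] + cnt
    }
    e_null <- perm_counts / n_perm
    r_obs <- length(t_obs) + 1 - rank(t_obs, ties.method = "max")
    q <- pmin(1, e_null / r_obs)
    # enforce monotone non-increasing q in |t|
    q[ord] <- rev(cummin(rev(q[ord])))
    q
  })
}

#' Differential test with FDR control for one contrast
#'
#' Runs [ttest_contrast()] and appends q-values, either Benjamini-Hochberg
#' (default; deterministic) or a group-label permutation null of the
#' (optionally s0-moderated) t statistic with plug-in FDR estimation.
#'
#' @inheritParams ttest_contrast
#' @param fdr_method `"bh"` or `"permutation"`.
#' @param n_perm Number of label permutations (permutation mode).
#' @param s0 Fudge factor added to the standard error (permutation mode).
#' @param seed Seed for the permutation draw.
#' @return The [ttest_contrast()] tibble plus a `q_value` column.
#' @export
phospho_difftest <- function(x, group_a, group_b,
                             contrast = paste0(group_a, "_vs_", group_b),
                             fdr_method = c("bh", "permutation"),
                             n_perm = 1000, s0 = 0, seed = NULL) {
  fdr_method <- match.arg(fdr_method)
  res <- ttest_contrast(x, group_a, group_b, contrast = contrast)
  testable <- !is.na(res$p_value)
  q <- rep(NA_real_, nrow(res))
  if (fdr_method == "bh") {
    q[testable] <- fdr_adjust(res$p_value[testable])
  } else {
    design <- table_design(x)
    m <- values_matrix(x)
    a <- m[testable, design$sample[design$condition == group_a],
           drop = FALSE]
    b <- m[testable, design$sample[design$condition == group_b],
           drop = FALSE]
    q[testable] <- permutation_q(a, b, n_perm = n_perm, s0 = s0, seed = seed)
  }
  res$q_value <- q
  res
}

#' Call policy for sensitivity / protection classification
#'
#' @param q_threshold FDR cutoff (default 0.05).
#' @param insensitive_band Log2 band (low, high) defining unchanged sites
#'   (default -0.5..+0.5).
#' @param strong_fc_threshold Fold-change cutoff for "strong" sites
#'   (default 3).
#' @param fc_scale Scale of `strong_fc_threshold`: `"linear"` (default;
#'   applied as `|log2fc| >= log2(threshold)`) or `"log2"`.
#' @return A `call_policy` list.
#' @export
call_policy <- function(q_threshold = 0.05, insensitive_band = c(-0.5, 0.5),
                        strong_fc_threshold = 3,
                        fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  if (!(insensitive_band[1] < 0 && insensitive_band[2] > 0)) {
    abort("insensitive_band must straddle 0.")
  }
  if (fc_scale == "linear" && strong_fc_threshold <= 1) {
    abort("strong_fc_threshold must exceed 1 (linear scale).")
  }
  structure(list(q_threshold = q_threshold,
                 insensitive_band = insensitive_band,
                 strong_fc_threshold = strong_fc_threshold,
                 fc_scale = fc_scale),
            class = "call_policy")
}

#' Classify sites as phosphatase-sensitive / inhibitor-protected
#'
#' Operates on stacked [phospho_difftest()] results. In `in_vitro` mode the
#' primary contrast is phosphatase vs control and a site is *sensitive* when
#' `q < q_threshold` and `log2fc < 0` (dephosphorylated upon phosphatase
#' addition); it is additionally a *protected candidate* when the protection
#' contrast (phosphatase vs phosphatase + inhibitor) is also significant
#' with `log2fc < 0` (dephosphorylation blocked by the inhibitor). In
#' `in_vivo` mode a site is sensitive when `q < q_threshold` and
#' `log2fc > 0` in the inhibitor-vs-starved contrast (phosphorylation
#' preserved under inhibition). Sites whose primary log2fc lies inside the
#' insensitive band are *insensitive*; everything else is *unchanged*;
#' untestable sites are *not_testable*. The *strong* flag marks
#' `|fold change| >=` the policy threshold.
#'
#' @param results Stacked difftest tibble (must contain the named contrasts).
#' @param primary Name of the primary contrast.
#' @param protection Name of the protection contrast (`in_vitro` mode;
#'   optional).
#' @param mode `"in_vitro"` or `"in_vivo"`.
#' @param policy A [call_policy()].
#' @return One row per site: key columns, `call` (one of `sensitive`,
#'   `protected_candidate`, `insensitive`, `unchanged`, `not_testable`),
#'   `strong`, primary `log2fc`/`q_value`, and protection stats when given.
#' @export
call_sensitivity <- function(results, primary, protection = NULL,
                             mode = c("in_vitro", "in_vivo"),
                             policy = call_policy()) {
  mode <- match.arg(mode)
  have <- unique(results$contrast)
  need <- c(primary, protection)
  missing_ctr <- setdiff(need, have)
  if (length(missing_ctr)) {
    abort(paste0("Missing required contrast(s): ",
                 paste(missing_ctr, collapse = ", ")))
  }
  key_cols <- c("accession", "position", "residue", "multiplicity")
  prim <- dplyr::filter(results, .data$contrast == primary)
  out <- dplyr::select(prim, dplyr::all_of(key_cols),
                       log2fc = "log2fc", q_value = "q_value")
  sig <- !is.na(out$q_value) & out$q_value < policy$q_threshold
  sensitive <- if (mode == "in_vitro") sig & out$log2fc < 0
               else sig & out$log2fc > 0
  protected <- rep(FALSE, nrow(out))
  if (!is.null(protection)) {
    prot <- dplyr::filter(results, .data$contrast == protection)
    prot <- prot[match(do.call(paste, out[key_cols]),
                       do.call(paste, prot[key_cols])), ]
    out$log2fc_protection <- prot$log2fc
    out$q_value_protection <- prot$q_value
    protected <- sensitive & !is.na(prot$q_value) &
      prot$q_value < policy$q_threshold & prot$log2fc < 0
  }
  band <- policy$insensitive_band
  in_band <- !is.na(out$log2fc) & out$log2fc >= band[1] &
    out$log2fc <= band[2]
  thr_log2 <- if (policy$fc_scale == "linear") {
    log2(policy$strong_fc_threshold)
  } else {
    policy$strong_fc_threshold
  }
  out$strong <- !is.na(out$log2fc) & abs(out$log2fc) >= thr_log2
  out$call <- dplyr::case_when(
    is.na(out$q_value) ~ "not_testable",
    protected ~ "protected_candidate",
    sensitive ~ "sensitive",
    in_band ~ "insensitive",
    TRUE ~ "unchanged"
  )
  out
}
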