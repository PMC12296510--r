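test_that("pattern compilation enumerates the consensus set correctly", {
  # pseudocount 0 leaves exactly tied scores, so the score table is
  # legitimately coarse and compile says so
  expect_warning(
    m <- compile_motif("[LMFI]xx[IVL]x[ED]", id = "B56", pseudocount = 0),
    "bins")
  expect_equal(m$length, 6)
  # all 4 * 3 * 2 consensus combinations share the maximal score
  combos <- expand.grid(c("L", "M", "F", "I"), c("I", "V", "L"),
                        c("E", "D"), stringsAsFactors = FALSE)
  scores <- apply(combos, 1, function(co) {
    m$weights_int[1, co[1]] + m$weights_int[4, co[2]] + m$weights_int[6, co[3]]
  })
  expect_equal(length(unique(scores)), 1)
  expect_equal(max(scores) + sum(m$weights_int[c(2, 3, 5), "A"]),
               m$max_score_int)
  # exact consensus probability under uniform background: (4*3*2)/20^3
  expect_equal(m$min_p, 24 / 8000, tolerance = 1e-12)

  expect_error(compile_motif("A"), ">= 3")
  expect_error(compile_motif("[LZ]xx"), "Unknown")
  expect_error(compile_motif(""), "Empty")
})

test_that("explicit probability matrices round trip through compile", {
  m1 <- compile_motif("[LMFI]xx[IVL]x[ED]", id = "a")
  m2 <- compile_motif(m1$prob, id = "b")
  expect_equal(m2$weights, m1$weights)
  expect_equal(m2$score_sf, m1$score_sf)
})

test_that("DP p-values equal exhaustive enumeration on a reduced alphabet", {
  letters4 <- c("A", "C", "D", "E")
  bg <- reduced_background(letters4)
  m <- compile_motif("[AC]x[DE]A", background = bg, pseudocount = 0.1)
  # enumerate all 4^4 = 256 windows and compare P(score >= s) exactly
  seqs <- apply(expand.grid(rep(list(letters4), 4),
                            stringsAsFactors = FALSE), 1, paste,
                collapse = "")
  scored <- scan_sequence(m, paste(seqs, collapse = ""), p_threshold = 1)
  # restrict to aligned (non-spanning) windows of the concatenation
  aligned <- scored[(scored$start - 1) %% 4 == 0, ]
  expect_equal(nrow(aligned), 256)
  si <- round(aligned$score / m$granularity)
  expect_equal(aligned$p_value, enumerate_pvalues(m, letters4, si))
})

test_that("DP p-values agree with Monte Carlo sampling at 20 letters", {
  m <- compile_motif("[LMFI]xx[IVL]x[ED]", id = "B56")
  set.seed(17)
  n_mc <- 1e6
  draws <- matrix(sample.int(20, n_mc * 6, replace = TRUE), n_mc, 6)
  total <- numeric(n_mc)
  for (i in 1:6) total <- total + m$weights_int[i, ][draws[, i]]
  # evaluate at a score whose exact p is near 1e-3
  target <- quantile(total, 1 - 1e-3, type = 1)
  p_mc <- mean(total >= target)
  p_dp <- pptarget:::motif_pvalue_int(m, as.numeric(target))
  se <- sqrt(p_mc * (1 - p_mc) / n_mc)
  expect_lt(abs(p_dp - p_mc), 3 * se)
})

test_that("p-values are monotone non-increasing in score", {
  m <- compile_motif("[LMFI]xx[IVL]x[ED]xx[ED][ED]")
  s <- seq(m$score_offset, m$max_score_int, length.out = 200)
  p <- pptarget:::motif_pvalue_int(m, round(s))
  expect_true(all(diff(p) <= 1e-15))
})

test_that("scanning finds consensus occurrences with the maximal score", {
  m <- compile_motif("[LMFI]xx[IVL]x[ED]", id = "B56")
  seq <- paste0(strrep("G", 30), "LAAIAE", strrep("G", 30))
  hits <- scan_sequence(m, seq, p_threshold = 0.01)
  expect_equal(hits$start, 31)
  expect_equal(round(hits$score / m$granularity), m$max_score_int)
  expect_equal(hits$p_value, m$min_p)
  # nothing above threshold -> empty
  none <- scan_sequence(m, strrep("G", 50), p_threshold = 0.01)
  expect_equal(nrow(none), 0)
  # low-information motif cannot reach the default 1e-4: loud warning
  expect_warning(scan_sequence(m, seq), "attainable")
})

test_that("spacer classification follows the distance rules exactly", {
  sites <- tibble::tibble(accession = "P1", position = 40L, residue = "S")
  mk_hit <- function(s, e) tibble::tibble(accession = "P1", motif = "B56",
                                          start = s, end = e, score = 1,
                                          p_value = 1e-5)
  up <- classify_hits(mk_hit(20L, 25L), sites)
  expect_equal(up$spacer_class, "upstream")
  expect_equal(up$spacer, 15L)
  ov <- classify_hits(mk_hit(38L, 43L), sites)
  expect_equal(ov$spacer_class, "overlapping")
  expect_equal(ov$spacer, 0L)
  un <- classify_hits(mk_hit(55L, 60L), sites)
  expect_equal(un$spacer_class, "unassigned")  # start - site = 15 < 20
  down <- classify_hits(mk_hit(60L, 65L), sites)
  expect_equal(down$spacer_class, "downstream")
  expect_equal(down$spacer, 20L)
  # boundary: end = site - upstream_min is upstream
  edge <- classify_hits(mk_hit(25L, 30L), sites)
  expect_equal(edge$spacer_class, "upstream")
  expect_error(classify_hits(mk_hit(1L, 6L), sites, upstream_min = 0),
               ">= 1")
  # classes are exclusive and exhaustive
  set.seed(2)
  starts <- sample(1:80, 30, TRUE)
  rand <- classify_hits(mk_hit(starts, starts + 5L), sites)
  expect_true(all(rand$spacer_class %in%
                    c("overlapping", "upstream", "downstream", "unassigned")))
})

test_that("disorder classification averages over the span, >= 0.5 boundary", {
  hits <- tibble::tibble(accession = "P1", start = 1L, end = 6L)
  flat <- function(v) list(P1 = rep(v, 10))
  expect_true(disorder_classify(hits, flat(1))$disordered)
  expect_false(disorder_classify(hits, flat(0.49))$disordered)
  expect_true(disorder_classify(hits, flat(0.5))$disordered)
  mixed <- list(P1 = c(0.4, 0.4, 0.8, 0.8, 0.8, 0.8, 0, 0, 0, 0))
  cl <- disorder_classify(hits, mixed)
  expect_equal(cl$mean_disorder, mean(c(0.4, 0.4, 0.8, 0.8, 0.8, 0.8)))
  expect_true(cl$disordered)
  short <- list(P1 = rep(1, 3))
  expect_error(disorder_classify(hits, short), "shorter")
})

test_that("spacer summaries report moments and degenerate cases", {
  hits <- tibble::tibble(accession = "P1", motif = "B56",
                         start = 1L, end = 6L,
                         spacer = c(10L, 12L, 14L),
                         spacer_class = "upstream")
  sm <- spacer_distribution(hits)
  expect_equal(sm$mean, 12)
  expect_equal(sm$sd, 2)
  single <- spacer_distribution(hits[1, ])
  expect_true(is.na(single$sd))
  # CLT check on simulated spacers
  set.seed(6)
  big <- tibble::tibble(accession = "P1", motif = "B55", start = 1L,
                        end = 6L, spacer = round(rnorm(500, 30, 5)),
                        spacer_class = "downstream")
  sm2 <- spacer_distribution(big)
  expect_lt(abs(sm2$mean - 30), 0.7)
})

test_that("family assignment counts partition sites exactly", {
  sites <- tibble::tibble(accession = c("P1", "P1", "P2", "P3", "P4"),
                          position = 1:5, residue = "S")
  hits <- tibble::tibble(
    accession = c("P1", "P2", "P2", "P3"),
    motif = c("B55H", "B56", "B55b", "B56"))
  counts <- count_slim_site_assignments(sites, hits)
  got <- stats::setNames(counts$n_sites, counts$category)
  expect_equal(got[["B55_only"]], 2)  # two sites on P1
  expect_equal(got[["both"]], 1)      # P2 carries both families
  expect_equal(got[["B56_only"]], 1)  # P3
  expect_equal(got[["none"]], 1)      # P4
  expect_equal(sum(counts$n_sites), nrow(sites))
  # brute-force tabulation oracle on a random fixture
  set.seed(13)
  rs <- tibble::tibble(accession = sample(sprintf("P%02d", 1:30), 200, TRUE),
                       position = 1:200, residue = "S")
  rh <- tibble::tibble(accession = sample(sprintf("P%02d", 1:30), 50, TRUE),
                       motif = sample(c("B55b", "B55H", "B55H2", "B56"),
                                      50, TRUE))
  rc <- count_slim_site_assignments(rs, rh)
  brute <- vapply(seq_len(nrow(rs)), function(i) {
    fams <- unique(ifelse(startsWith(
      rh$motif[rh$accession == rs$accession[i]], "B55"), "B55", "B56"))
    if (all(c("B55", "B56") %in% fams)) "both"
    else if ("B55" %in% fams) "B55_only"
    else if ("B56" %in% fams) "B56_only"
    else "none"
  }, character(1))
  expect_equal(stats::setNames(rc$n_sites, rc$category)[names(table(brute))],
               table(brute), ignore_attr = TRUE)
})
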