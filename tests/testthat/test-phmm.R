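test_that("match-column rule: columns with more than 50% gaps become inserts", {
  msa <- acs_msa(c("a", "b", "c"), c("ACDEF", "ACDEF", "ACDEF"))
  h <- build_profile_hmm(msa, "f")
  expect_equal(h$n_match, 5L)
  # one column 60% gaps (3 of 5) -> insert-generating
  msa2 <- acs_msa(paste0("r", 1:5),
                  c("AC-EF", "AC-EF", "AC-EF", "ACDEF", "ACDEF"))
  h2 <- build_profile_hmm(msa2, "f")
  expect_equal(h2$n_match, 4L)
  # exactly 50% gaps stays a match column
  msa3 <- acs_msa(paste0("r", 1:4), c("A-F", "A-F", "ACF", "ACF"))
  expect_equal(build_profile_hmm(msa3, "f")$n_match, 3L)
  expect_error(build_profile_hmm(acs_msa(c("a", "b"), c("--", "--")), "f"),
               "match columns")
})

test_that("probability rows normalise to 1 after any build", {
  set.seed(14)
  for (k in 1:5) {
    rows <- vapply(1:4, function(i) {
      paste(sample(c("A", "C", "G", "W", "-"), 8, replace = TRUE),
            collapse = "")
    }, "")
    msa <- acs_msa(paste0("r", 1:4), rows)
    h <- tryCatch(build_profile_hmm(msa, "f"), error = function(e) NULL)
    if (is.null(h)) next
    expect_equal(colSums(exp(h$log_emis)), rep(1, h$n_match),
                 tolerance = 1e-9, ignore_attr = TRUE)
    M <- h$n_match
    trs <- cbind(exp(h$tMM) + exp(h$tMI) + exp(h$tMD),
                 exp(h$tIM) + exp(h$tII) + exp(h$tID))
    expect_equal(unname(trs[, 1]), rep(1, M + 1), tolerance = 1e-9)
    expect_equal(unname(trs[, 2]), rep(1, M + 1), tolerance = 1e-9)
    dsum <- exp(h$tDM) + exp(h$tDI) + exp(h$tDD)
    expect_equal(unname(dsum[-1]), rep(1, M), tolerance = 1e-9)
  }
})

test_that("single-sequence model without pseudocounts scores L*ln(20) on itself", {
  s <- "ACDEFGHIKL"
  msa <- acs_msa("one", s)
  h <- suppressWarnings(build_profile_hmm(msa, "f", pseudocount_weight = 0))
  expect_equal(score_sequence(h, s, "viterbi"), nchar(s) * log(20),
               tolerance = 1e-9)
  # point-mass emissions
  expect_equal(max(exp(h$log_emis[, 1])), 1, tolerance = 1e-12)
})

test_that("forward log-odds is at least Viterbi log-odds (sum >= max path)", {
  set.seed(77)
  for (k in 1:8) {
    rows <- vapply(1:3, function(i) {
      paste(sample(c("A", "C", "D", "W", "K", "-"), 7, replace = TRUE,
                   prob = c(rep(0.18, 5), 0.1)), collapse = "")
    }, "")
    msa <- tryCatch(acs_msa(paste0("r", 1:3), rows), error = function(e) NULL)
    h <- tryCatch(build_profile_hmm(msa, "f"), error = function(e) NULL)
    if (is.null(h)) next
    for (q in c("ACDWK", "AAAAAAA", "WW", "KDCA")) {
      expect_gte(score_sequence(h, q, "forward") + 1e-9,
                 score_sequence(h, q, "viterbi"))
    }
  }
})

test_that("forward equals brute-force sum over all state paths on toy models", {
  set.seed(55)
  for (k in 1:6) {
    nrows <- sample(2:3, 1)
    ncols <- sample(2:3, 1)
    rows <- vapply(seq_len(nrows), function(i) {
      paste(sample(c("A", "C", "G", "W"), ncols, replace = TRUE),
            collapse = "")
    }, "")
    h <- build_profile_hmm(acs_msa(paste0("r", seq_len(nrows)), rows), "f")
    for (q in c("A", "AC", "GWA", "CCCA")) {
      got <- score_sequence(h, q, "forward")
      want <- brute_force_hmm_logodds(h, q)
      expect_equal(got, want, tolerance = 1e-9,
                   label = sprintf("model %d query %s", k, q))
    }
  }
})

test_that("held-out sequences score higher under their own subfamily model", {
  g <- small_synth(seqs = 8, seed = 42, n_subfamilies = 2)
  sp <- split_dataset(g$dataset, 0.75, seed = 1)
  lib <- build_hmm_library(sp$train)
  a_test <- sp$test[which(sp$test$label == subfamilies(g$dataset)[1])[1]]
  b_test <- sp$test[which(sp$test$label == subfamilies(g$dataset)[2])[1]]
  ha <- lib[[1]]
  expect_gt(score_sequence(ha, a_test), score_sequence(ha, b_test))
  # and classification agrees end to end
  ra <- classify_hmm(a_test, lib)
  expect_equal(ra$predicted, a_test$label)
})

test_that("HMM classification tie and identity contracts", {
  msa <- acs_msa(c("a", "b"), c("ACDEFGH", "ACDEFGH"))
  h1 <- build_profile_hmm(msa, "famA")
  h2 <- build_profile_hmm(msa, "famB")
  r <- classify_hmm("ACDEFGH", list(famA = h1, famB = h2))
  expect_true(r$tie)
  expect_equal(r$predicted, "famA")  # alphabetical tie-break
  # the sole training sequence of a single-sequence model wins
  msaX <- acs_msa("x", "WWWWYYY")
  hX <- suppressWarnings(build_profile_hmm(msaX, "famX"))
  rX <- classify_hmm("WWWWYYY", list(famA = h1, famX = hX))
  expect_equal(rX$predicted, "famX")
  expect_error(classify_hmm("ACD", list(famA = h1)), "at least two")
})

test_that("HMM JSON round trip preserves scoring behaviour", {
  g <- small_synth(seqs = 5, seed = 9, n_subfamilies = 2)
  msa <- progressive_msa(g$dataset[1:5])
  h <- build_profile_hmm(msa, "fam")
  f <- tempfile(fileext = ".json")
  write_hmm(h, f)
  back <- read_hmm(f)
  q <- g$dataset$residues[7]
  expect_equal(score_sequence(back, q, "viterbi"),
               score_sequence(h, q, "viterbi"), tolerance = 1e-9)
  expect_equal(score_sequence(back, q, "forward"),
               score_sequence(h, q, "forward"), tolerance = 1e-9)
  # including a model with structural -Inf transitions
  h0 <- suppressWarnings(build_profile_hmm(acs_msa("one", "ACDEF"), "f0",
                                           pseudocount_weight = 0))
  write_hmm(h0, f)
  b0 <- read_hmm(f)
  expect_equal(score_sequence(b0, "ACDEF"), score_sequence(h0, "ACDEF"))
})
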