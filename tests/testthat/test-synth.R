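test_that("same seed gives byte-identical FASTA; different seed differs", {
  g1 <- small_synth(seqs = 5, seed = 13)
  g2 <- small_synth(seqs = 5, seed = 13)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(g1$dataset, f1)
  write_fasta(g2$dataset, f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  g3 <- small_synth(seqs = 5, seed = 14)
  expect_false(identical(g1$dataset$residues, g3$dataset$residues))
})

test_that("generated lengths and composition honour the configuration", {
  g <- generate_dataset(synth_config(n_subfamilies = 3,
                                     seqs_per_subfamily = 6, seed = 2))
  expect_equal(length(g$dataset), 18L)
  expect_true(all(nchar(g$dataset$residues) >= 300 &
                    nchar(g$dataset$residues) <= 750))
  expect_equal(sort(unique(g$dataset$label)), c("4CL", "AcCS", "LCS"))
  expect_equal(unname(table(g$dataset$label)), rep(6L, 3), ignore_attr = TRUE)
})

test_that("full SDR conservation stamps the signature into every record", {
  g <- generate_dataset(synth_config(n_subfamilies = 2,
                                     seqs_per_subfamily = 4,
                                     sdr_conservation = 1, indel_rate = 0,
                                     seed = 6))
  for (i in seq_along(g$dataset$id)) {
    sig <- paste(g$signatures[g$dataset$label[i], ], collapse = "")
    expect_equal(g$truth$asp_true[i], sig)
  }
  # and ASP extraction recovers it through alignment
  asps <- extract_asps(g$dataset, g$template)
  m <- asp_matrix(asps)
  truth <- do.call(rbind, strsplit(g$truth$asp_true, ""))
  expect_gt(mean(m == truth), 0.97)
})

test_that("impossible identity targets are rejected", {
  expect_error(synth_config(background_identity = 0.2,
                            cross_subfamily_identity = 0.4),
               "impossible identity targets")
})

test_that("within-subfamily NW similarity exceeds cross-subfamily similarity", {
  g <- small_synth(seqs = 5, seed = 3, n_subfamilies = 2)
  ds <- g$dataset
  a_idx <- which(ds$label == subfamilies(ds)[1])
  b_idx <- which(ds$label == subfamilies(ds)[2])
  within <- vapply(1:4, function(i) {
    needleman_wunsch(ds$residues[a_idx[i]],
                     ds$residues[a_idx[i + 1]])$similarity_pct
  }, 0)
  cross <- vapply(1:4, function(i) {
    needleman_wunsch(ds$residues[a_idx[i]],
                     ds$residues[b_idx[i]])$similarity_pct
  }, 0)
  expect_gt(mean(within), mean(cross))
})

test_that("anomalous records carry one background and another SDR signature", {
  g <- generate_dataset(synth_config(n_subfamilies = 3,
                                     seqs_per_subfamily = 8,
                                     anomaly_fraction = 0.15, seed = 11))
  an <- which(g$truth$anomaly)
  expect_gt(length(an), 0)
  simto <- function(i, f, nref = 4) {
    idx <- which(g$dataset$label == f & !g$truth$anomaly)[seq_len(nref)]
    mean(vapply(idx, function(j) {
      needleman_wunsch(g$dataset$residues[i],
                       g$dataset$residues[j])$similarity_pct
    }, 0))
  }
  for (i in an) {
    expect_false(g$truth$label[i] == g$truth$background[i])
    # whole-sequence similarity points at the background subfamily, not at
    # the SDR-defined truth label
    expect_gt(simto(i, g$truth$background[i]), simto(i, g$truth$label[i]))
  }
})

test_that("fixture PDB writing round-trips through the parser", {
  atoms <- random_toy_structure(nres = 3, seed = 2)
  f <- tempfile(fileext = ".pdb")
  write_fixture_structure(atoms, f)
  st <- parse_pdb(f)
  expect_equal(unique(st$atoms$resno), 1:3)
  expect_equal(nrow(st$het), 2L)
  expect_equal(st$atoms$x, atoms$x[!atoms$het], tolerance = 1e-3)
  expect_error(write_fixture_structure(atoms[atoms$het, , drop = FALSE], f),
               "no protein residues")
})

test_that("template geometry reproduces the designed pocket counts", {
  st <- template_structure()
  s6 <- derive_sdr_positions(st, "PHE", cutoff = 6,
                             manual_additions = c(239L, 278L, 299L))
  expect_equal(sum(s6$provenance == "distance-derived"), 12L)
  expect_equal(length(s6$positions), 15L)
  s10 <- derive_sdr_positions(st, "PHE", cutoff = 10)
  expect_equal(length(s10$positions), 44L)
  expect_true(all(s6$positions %in% s10$positions))
})

test_that("shipped template files stay in sync with run-time derivation", {
  tmpl <- acs_template(15)
  st <- template_structure()
  rederived <- derive_sdr_positions(st, "PHE", cutoff = 6,
                                    manual_additions = c(239L, 278L, 299L))
  expect_equal(tmpl$sdrs$positions, rederived$positions)
  expect_equal(tmpl$sdrs$provenance, rederived$provenance)
  expect_equal(tmpl$sequence$residues, template_sequence()$residues)
  t44 <- acs_template(44)
  expect_equal(t44$sdrs$positions,
               derive_sdr_positions(st, "PHE", cutoff = 10)$positions)
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(small_synth(seqs = 3, seed = 99))
  after <- runif(3)
  expect_identical(before, after)
})
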