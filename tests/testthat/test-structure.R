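test_that("PDB parsing preserves numbering, excludes water, keeps first model", {
  atoms <- data.frame(chain = "A", resno = c(10, 10, 25, 99),
                      resid = c("ALA", "ALA", "GLY", "TRP"),
                      elety = c("N", "CA", "CA", "CA"),
                      elesy = c("N", "C", "C", "C"),
                      x = c(0, 1, 5, 9), y = 0, z = 0, het = FALSE)
  wat <- data.frame(chain = "W", resno = 300, resid = "HOH", elety = "O",
                    elesy = "O", x = 2, y = 2, z = 2, het = TRUE)
  lig <- data.frame(chain = "L", resno = 200, resid = "AMP", elety = "P",
                    elesy = "P", x = 3, y = 3, z = 3, het = TRUE)
  st <- parse_toy(rbind(atoms, wat, lig))
  expect_equal(sort(unique(st$atoms$resno)), c(10, 25, 99))
  expect_equal(unique(st$het$resid), "AMP")  # HOH dropped

  # multi-model: only MODEL 1 kept
  f <- tempfile(fileext = ".pdb")
  write_fixture_structure(atoms, f)
  body <- readLines(f)
  atom_lines <- grep("^ATOM", body, value = TRUE)
  shifted <- sub("^ATOM  ", "ATOM  ", atom_lines)
  writeLines(c("MODEL        1", atom_lines, "ENDMDL",
               "MODEL        2", shifted, "ENDMDL", "END"), f)
  st2 <- parse_pdb(f)
  expect_equal(nrow(st2$atoms), length(atom_lines))
})

test_that("PDB parsing errors on files without coordinates", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), f)
  expect_error(parse_pdb(f))
})

test_that("SDR derivation selects residues by reference-atom distance", {
  # one residue 5 A away, one 7 A away: 6 A cutoff keeps only the near one
  near <- data.frame(chain = "A", resno = 1, resid = "ALA", elety = "CB",
                     elesy = "C", x = 5, y = 0, z = 0, het = FALSE)
  far <- data.frame(chain = "A", resno = 2, resid = "VAL", elety = "CB",
                    elesy = "C", x = 7, y = 0, z = 0, het = FALSE)
  lig <- data.frame(chain = "L", resno = 99, resid = "PHE",
                    elety = c("CA", "CB"), elesy = "C",
                    x = c(1.5, 0), y = 0, z = 0, het = TRUE)
  st <- parse_toy(rbind(near, far, lig))
  s <- derive_sdr_positions(st, "PHE", cutoff = 6)
  expect_equal(s$positions, 1L)
  # manual additions get recorded with provenance
  s2 <- derive_sdr_positions(st, "PHE", cutoff = 6, manual_additions = 2)
  expect_equal(s2$positions, c(1L, 2L))
  expect_equal(s2$provenance, c("distance-derived", "manual"))
  # errors: absent ligand / reference atom
  expect_error(derive_sdr_positions(st, "AMP"), "not found")
  expect_error(derive_sdr_positions(st, "PHE", reference_atom = "OXT"),
               "absent")
})

test_that("SDR derivation is monotone in the cutoff", {
  st <- template_structure()
  s6 <- derive_sdr_positions(st, "PHE", cutoff = 6)
  s8 <- derive_sdr_positions(st, "PHE", cutoff = 8)
  s10 <- derive_sdr_positions(st, "PHE", cutoff = 10)
  expect_true(all(s6$positions %in% s8$positions))
  expect_true(all(s8$positions %in% s10$positions))
})

test_that("pocket extraction agrees with a brute-force distance scan", {
  for (seed in 1:20) {
    atoms <- random_toy_structure(nres = 8, seed = seed)
    st <- parse_toy(atoms)
    lig <- atoms[atoms$het, ]
    for (cutoff in c(0, 4, 8, 1000)) {
      got <- pocket_from_ligand(st, "LIG", cutoff = cutoff)
      want <- brute_force_pocket(atoms[!atoms$het, ],
                                 as.matrix(lig[, c("x", "y", "z")]), cutoff)
      expect_equal(sort(paste(got$residues$chain, got$residues$resno)), want,
                   label = sprintf("seed %d cutoff %g", seed, cutoff))
    }
  }
})

test_that("SDR derivation agrees with the brute-force scan on the template", {
  st <- template_structure()
  lig <- st$het[st$het$resid == "PHE" & trimws(st$het$elety) == "CB", ]
  for (cutoff in c(6, 10)) {
    got <- derive_sdr_positions(st, "PHE", cutoff = cutoff)
    want <- brute_force_pocket(st$atoms, as.matrix(lig[, c("x", "y", "z")]),
                               cutoff)
    expect_equal(paste("A", got$positions), want)
  }
})

test_that("Kabsch superposition: exact cases and rigid invariance", {
  set.seed(5)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(A, A)$rmsd, 0, tolerance = 1e-10)

  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  B <- A %*% t(R) + matrix(rep(c(5, -2, 9), each = 10), 10, 3)
  expect_lt(kabsch_rmsd(A, B)$rmsd, 1e-8)

  # cross-check against bio3d's least-squares fit on noisy pairs
  Bn <- B + matrix(rnorm(30, sd = 0.3), 10, 3)
  got <- kabsch_rmsd(A, Bn)$rmsd
  want <- bio3d::rmsd(as.vector(t(A)), as.vector(t(Bn)), fit = TRUE)
  expect_equal(got, want, tolerance = 1e-3)

  expect_error(kabsch_rmsd(A, A[1:5, ]), "differ")
  expect_error(kabsch_rmsd(A[1:2, ], A[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD matches direct numerical minimisation over rotations", {
  set.seed(9)
  A <- matrix(rnorm(30), 10, 3)
  B <- matrix(rnorm(30), 10, 3)
  got <- kabsch_rmsd(A, B)$rmsd
  # oracle: optimise Euler angles numerically on centred sets
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  obj <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    sqrt(mean(rowSums((Ac - Bc %*% t(Rz %*% Ry %*% Rx))^2)))
  }
  best <- min(vapply(1:40, function(k) {
    set.seed(k)
    optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12))$value
  }, 0))
  expect_equal(got, best, tolerance = 1e-5)
  expect_lte(got, best + 1e-8)  # Kabsch is the optimum
})

test_that("position mapping by superposition: identity, renumbering, deletion", {
  st <- template_structure()
  sdrs <- acs_template(15)$sdrs

  m <- map_positions_by_superposition(st, st, sdrs)
  expect_equal(m$target_resno, sdrs$positions)
  expect_lt(max(m$distance), 1e-8)

  # renumbered target: mapping offsets by +100
  ren <- st
  ren$atoms$resno <- ren$atoms$resno + 100L
  m2 <- map_positions_by_superposition(st, ren, sdrs)
  expect_equal(m2$target_resno, sdrs$positions + 100L)

  # toy pair with well-separated residues: deleting one SDR leaves it
  # unmapped (no other C-alpha within 8 A), the rest map through
  set.seed(21)
  resn <- 1:25
  toy <- do.call(rbind, lapply(resn, function(i) {
    data.frame(chain = "A", resno = i,
               resid = bio3d::aa123(sample(c("A", "L", "K", "F", "D"), 1)),
               elety = c("N", "CA", "CB"), elesy = c("N", "C", "C"),
               x = 10 * i + c(-1, 0, 1), y = c(0.5, 0, -0.5), z = 0,
               het = FALSE)
  }))
  tpl <- parse_toy(toy)
  tgt <- parse_toy(toy[toy$resno != 12, ])
  toysdr <- sdr_set("toy", c(5L, 12L, 18L))
  m3 <- map_positions_by_superposition(tpl, tgt, toysdr)
  expect_true(is.na(m3$target_resno[2]))
  expect_equal(m3$target_resno[-2], c(5L, 18L))
})
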