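# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately naive (enumeration / all-pairs scans / path sums) and share no
# code with the implementation paths they check.

make_asp <- function(symbols, id = "q", sdr_set_id = "toy",
                     positions = seq_along(symbols)) {
  structure(list(query_id = id, symbols = symbols, sdr_set_id = sdr_set_id,
                 positions = positions, alignment_score = 0),
            class = "asp")
}

# ---- alignment enumeration oracle ------------------------------------------

# all global alignments of a and b as pairs of gapped strings
enumerate_alignments <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(ca) && j > length(cb)) return(list(c("", "")))
    out <- list()
    if (i <= length(ca) && j <= length(cb)) {
      for (s in rec(i + 1, j + 1)) {
        out[[length(out) + 1]] <- c(paste0(ca[i], s[1]), paste0(cb[j], s[2]))
      }
    }
    if (i <= length(ca)) {
      for (s in rec(i + 1, j)) {
        out[[length(out) + 1]] <- c(paste0(ca[i], s[1]), paste0("-", s[2]))
      }
    }
    if (j <= length(cb)) {
      for (s in rec(i, j + 1)) {
        out[[length(out) + 1]] <- c(paste0("-", s[1]), paste0(cb[j], s[2]))
      }
    }
    out
  }
  rec(1, 1)
}

# affine-gap score of one explicit alignment: a gap run of length L costs
# open + L * ext; terminal runs cost 0 when free_ends
score_alignment_explicit <- function(al_a, al_b, submat, gap_open, gap_ext,
                                     free_ends = TRUE) {
  ca <- strsplit(al_a, "")[[1]]
  cb <- strsplit(al_b, "")[[1]]
  n <- length(ca)
  score <- 0
  gap_runs <- function(isgap) {
    r <- rle(isgap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    data.frame(start = starts[r$values], end = ends[r$values],
               len = r$lengths[r$values])
  }
  for (k in seq_len(n)) {
    if (ca[k] != "-" && cb[k] != "-") score <- score + submat[ca[k], cb[k]]
  }
  for (g in list(gap_runs(ca == "-"), gap_runs(cb == "-"))) {
    if (nrow(g) == 0) next
    for (r in seq_len(nrow(g))) {
      terminal <- g$start[r] == 1 || g$end[r] == n
      if (!(free_ends && terminal)) {
        score <- score - (gap_open + g$len[r] * gap_ext)
      }
    }
  }
  score
}

# best score over all enumerated alignments
brute_force_nw_score <- function(a, b, submat, gap_open = 10, gap_ext = 0.5,
                                 free_ends = TRUE) {
  max(vapply(enumerate_alignments(a, b), function(s) {
    score_alignment_explicit(s[1], s[2], submat, gap_open, gap_ext, free_ends)
  }, 0))
}

# ---- geometry oracle -------------------------------------------------------

# residues with any heavy atom within cutoff of any reference point:
# plain double loop over atoms and reference rows
brute_force_pocket <- function(atoms, ref_xyz, cutoff) {
  atoms <- atoms[atoms$elesy != "H", , drop = FALSE]
  hits <- character(0)
  for (i in seq_len(nrow(atoms))) {
    for (j in seq_len(nrow(ref_xyz))) {
      d <- sqrt((atoms$x[i] - ref_xyz[j, 1])^2 +
                  (atoms$y[i] - ref_xyz[j, 2])^2 +
                  (atoms$z[i] - ref_xyz[j, 3])^2)
      if (d <= cutoff) hits <- c(hits, paste(atoms$chain[i], atoms$resno[i]))
    }
  }
  sort(unique(hits))
}

# random toy structure: nres residues on random coordinates, one 2-atom ligand
random_toy_structure <- function(nres = 8, seed = 1) {
  set.seed(seed)
  res <- do.call(rbind, lapply(seq_len(nres), function(i) {
    centre <- runif(3, -12, 12)
    data.frame(chain = "A", resno = i, resid = "ALA",
               elety = c("N", "CA", "CB"), elesy = c("N", "C", "C"),
               x = centre[1] + runif(3, -1, 1),
               y = centre[2] + runif(3, -1, 1),
               z = centre[3] + runif(3, -1, 1), het = FALSE)
  }))
  lig <- data.frame(chain = "L", resno = 900, resid = "LIG",
                    elety = c("C1", "CB"), elesy = c("C", "C"),
                    x = runif(2, -3, 3), y = runif(2, -3, 3),
                    z = runif(2, -3, 3), het = TRUE)
  rbind(res, lig)
}

parse_toy <- function(atoms) {
  f <- tempfile(fileext = ".pdb")
  write_fixture_structure(atoms, f)
  on.exit(unlink(f))
  parse_pdb(f)
}

# ---- profile-HMM path-sum oracle -------------------------------------------

# total probability of a sequence under the model relative to background,
# by explicit enumeration of complete state paths (no DP tables)
brute_force_hmm_logodds <- function(hmm, seq) {
  idx <- match(strsplit(seq, "")[[1]], c("A", "C", "D", "E", "F", "G", "H",
                                         "I", "K", "L", "M", "N", "P", "Q",
                                         "R", "S", "T", "V", "W", "Y"))
  L <- length(idx)
  M <- hmm$n_match
  bg <- hmm$background
  total <- 0
  # walk(state, node, i, p): p = probability of the partial path, i = next
  # residue to emit (1-based); end state reached via M-transition from node M
  walk <- function(state, node, i, p) {
    if (p == 0) return(invisible(NULL))
    # transitions out of (state, node)
    step <- function(tvec, to_state) {
      tp <- exp(tvec[node + 1])
      if (to_state == "M") {
        if (node == M) {  # into end state
          if (i == L + 1) total <<- total + p * tp
        } else if (i <= L) {
          walk("M", node + 1, i + 1,
               p * tp * exp(hmm$log_emis[idx[i], node + 1]))
        }
      } else if (to_state == "I") {
        if (i <= L) walk("I", node, i + 1, p * tp * bg)
      } else {  # D
        if (node < M) walk("D", node + 1, i, p * tp)
      }
    }
    if (state == "M") { step(hmm$tMM, "M"); step(hmm$tMI, "I"); step(hmm$tMD, "D") }
    if (state == "I") { step(hmm$tIM, "M"); step(hmm$tII, "I"); step(hmm$tID, "D") }
    if (state == "D") { step(hmm$tDM, "M"); step(hmm$tDI, "I"); step(hmm$tDD, "D") }
  }
  walk("M", 0, 1, 1)
  unname(log(total) - L * log(bg))
}

# small labeled dataset for pipeline tests (fast fixture scale)
small_synth <- function(seqs = 8, seed = 42, n_subfamilies = 2, ...) {
  generate_dataset(synth_config(n_subfamilies = n_subfamilies,
                                seqs_per_subfamily = seqs, seed = seed, ...))
}
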