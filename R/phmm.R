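# In-house Krogh-style profile hidden Markov model: built from a subfamily
# multiple alignment (match / insert / delete architecture), scored by
# Viterbi or forward log-odds against a uniform background null model, with
# best-scoring-subfamily classification.

HMM_BACKGROUND <- 0.05  # uniform background emission per residue

#' Build a profile HMM from a multiple alignment
#'
#' Columns with at most 50% gaps become match states; the remaining columns
#' generate insertions.  Emission and transition probabilities are
#' Laplace-smoothed counts (pseudocount `pseudocount_weight` added to every
#' cell; 0 gives maximum-likelihood point estimates).  Insert-state
#' emissions equal the uniform background, so inserted residues are
#' score-neutral apart from transition costs.
#'
#' @param msa an [acs_msa] (>= 2 rows; a single row is allowed with a
#'   warning).
#' @param subfamily label stored with the model.
#' @param pseudocount_weight Laplace smoothing weight (default 1).
#' @return object of class `profile_hmm` with log-probability matrices
#'   `log_emis` (20 x n_match), transition vectors, `n_match`, `subfamily`,
#'   `background`.
#' @export
build_profile_hmm <- function(msa, subfamily = "model",
                              pseudocount_weight = 1.0) {
  stopifnot(inherits(msa, "acs_msa"))
  m <- msa_matrix(msa)
  if (nrow(m) == 1L) warning("building a profile HMM from a single sequence")
  gapfrac <- colMeans(m == GAP)
  is_match <- gapfrac <= 0.5
  M <- sum(is_match)
  if (M == 0L) stop("no match columns (every column is more than 50% gaps)")
  node_of_col <- cumsum(is_match)  # insert columns attach to preceding node

  pw <- pseudocount_weight
  emis <- matrix(pw, 20, M, dimnames = list(AA20, NULL))
  # transition counts: cn[[from-to]][k + 1] = count of node-k transitions
  cn <- list()
  for (key in c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DI", "DD")) {
    cn[[key]] <- rep(pw, M + 1)
  }
  bump <- function(from_state, from_node, to_state) {
    key <- paste0(from_state, to_state)
    cn[[key]][from_node + 1L] <<- cn[[key]][from_node + 1L] + 1
  }

  for (r in seq_len(nrow(m))) {
    row <- m[r, ]
    prev_state <- "M"  # begin = M_0
    prev_node <- 0L
    for (j in seq_along(row)) {
      ch <- row[j]
      if (is_match[j]) {
        k <- node_of_col[j]
        if (ch == GAP) {
          bump(prev_state, prev_node, "D")
          prev_state <- "D"; prev_node <- k
        } else {
          bump(prev_state, prev_node, "M")
          if (ch %in% AA20) emis[ch, k] <- emis[ch, k] + 1
          prev_state <- "M"; prev_node <- k
        }
      } else if (ch != GAP) {  # insert column, residue present
        bump(prev_state, prev_node, "I")
        prev_state <- "I"  # node unchanged
      }
    }
    bump(prev_state, prev_node, "M")  # into the end state (node M+1)
  }

  # structural impossibilities regardless of pseudocounts
  cn$MD[M + 1] <- cn$ID[M + 1] <- cn$DD[M + 1] <- 0  # no delete after node M
  cn$DM[1] <- cn$DI[1] <- cn$DD[1] <- 0              # D_0 does not exist

  norm_log <- function(x) {
    s <- sum(x)
    if (s == 0) rep(-Inf, length(x)) else log(x / s)
  }
  emis <- matrix(apply(emis, 2, function(col) log(col / sum(col))),
                 nrow = 20, dimnames = list(AA20, NULL))
  tr <- function(a, b, c3) {
    t(vapply(seq_len(length(a)), function(k) norm_log(c(a[k], b[k], c3[k])),
             numeric(3)))
  }
  tM <- tr(cn$MM, cn$MI, cn$MD)  # rows: node 0..M; cols: to M, I, D
  tI <- tr(cn$IM, cn$II, cn$ID)
  tD <- tr(cn$DM, cn$DI, cn$DD)
  tD[1, ] <- -Inf  # from nonexistent D_0

  structure(list(subfamily = subfamily, n_match = M,
                 log_emis = emis,
                 log_ins = matrix(log(HMM_BACKGROUND), 20, M + 1,
                                  dimnames = list(AA20, NULL)),
                 tMM = tM[, 1], tMI = tM[, 2], tMD = tM[, 3],
                 tIM = tI[, 1], tII = tI[, 2], tID = tI[, 3],
                 tDM = tD[, 1], tDI = tD[, 2], tDD = tD[, 3],
                 background = HMM_BACKGROUND,
                 pseudocount_weight = pseudocount_weight,
                 n_training = nrow(m)),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm %s: %d match states, %d training rows\n",
              x$subfamily, x$n_match, x$n_training))
  invisible(x)
}

#' Score a sequence against a profile HMM
#'
#' Log-odds (nats) of the sequence under the model versus a same-length
#' i.i.d. uniform background (0.05 per residue).  `viterbi` scores the best
#' state path; `forward` sums over all paths (hence forward >= viterbi).
#' Ambiguous residues (`X`) emit as background, contributing zero
#' emission log-odds.
#'
#' @param hmm a `profile_hmm`.
#' @param seq a sequence: string or single-record [acs_dataset].
#' @param algorithm `"viterbi"` or `"forward"`.
#' @return numeric log-odds in nats.
#' @export
score_sequence <- function(hmm, seq, algorithm = c("viterbi", "forward")) {
  algorithm <- match.arg(algorithm)
  res <- .as_residues(seq)
  if (!nzchar(res)) stop("empty sequence")
  idx <- match(strsplit(res, "")[[1]], AA20) - 1L
  idx[is.na(idx)] <- -1L  # ambiguity: background emission
  em_odds <- hmm$log_emis - log(hmm$background)
  ei_odds <- hmm$log_ins - log(hmm$background)
  .phmm_score_cpp(em_odds, ei_odds,
                  hmm$tMM, hmm$tMI, hmm$tMD,
                  hmm$tIM, hmm$tII, hmm$tID,
                  hmm$tDM, hmm$tDI, hmm$tDD,
                  idx, algorithm == "viterbi")
}

#' Build a library of subfamily profile HMMs
#'
#' Aligns each subfamily's training sequences with [progressive_msa()] (or
#' uses supplied alignments) and builds one model per subfamily.
#'
#' @param dataset labeled [acs_dataset] (training sequences).
#' @param msas optional named list of [acs_msa] per subfamily, bypassing the
#'   internal aligner.
#' @param pseudocount_weight passed to [build_profile_hmm()].
#' @return named list of `profile_hmm` (alphabetical), class `hmm_library`.
#' @export
build_hmm_library <- function(dataset, msas = NULL,
                              pseudocount_weight = 1.0) {
  fams <- subfamilies(dataset)
  if (length(fams) < 2L && is.null(msas)) {
    warning("fewer than two labeled subfamilies; classification needs >= 2")
  }
  out <- lapply(fams, function(f) {
    sub <- dataset[which(dataset$label == f)]
    msa <- if (!is.null(msas) && f %in% names(msas)) msas[[f]]
    else progressive_msa(sub)
    build_profile_hmm(msa, f, pseudocount_weight)
  })
  names(out) <- fams
  structure(out, class = "hmm_library")
}

#' Classify a sequence by best-scoring subfamily HMM
#'
#' The query is scored against every model in the library and assigned to
#' the best-scoring subfamily; same tie contract as [classify_asp()].
#'
#' @param seq a sequence: string or single-record [acs_dataset].
#' @param library an `hmm_library` (or named list of `profile_hmm`).
#' @param algorithm `"viterbi"` (default) or `"forward"`.
#' @return a `classification_result`.
#' @export
classify_hmm <- function(seq, library, algorithm = "viterbi") {
  if (length(library) < 2L) stop("HMM library needs at least two models")
  scores <- vapply(library, function(h) score_sequence(h, seq, algorithm), 0)
  names(scores) <- vapply(library, function(h) h$subfamily, "")
  .make_classification(.seq_id(seq, "query"), scores)
}

#' Write / read a profile HMM as JSON
#' @param hmm a `profile_hmm`.
#' @param path file path.
#' @return `path` (write) or a `profile_hmm` (read).
#' @export
write_hmm <- function(hmm, path) {
  obj <- unclass(hmm)
  obj$log_emis <- lapply(seq_len(ncol(hmm$log_emis)),
                         function(j) unname(hmm$log_emis[, j]))
  obj$log_ins <- NULL  # reconstructed from background on read
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) {
    x <- unlist(x)
    suppressWarnings(v <- as.numeric(x))
    v[x == "-Inf"] <- -Inf
    v
  }
  # each JSON inner array is one match-state emission column; jsonlite may
  # simplify the list of columns into a (n_match x 20) matrix
  raw <- j$log_emis
  cols <- if (is.list(raw)) raw
  else if (is.null(dim(raw))) list(raw)
  else lapply(seq_len(nrow(raw)), function(i) raw[i, ])
  emis <- matrix(do.call(cbind, lapply(cols, num)), nrow = 20,
                 dimnames = list(AA20, NULL))
  structure(list(subfamily = j$subfamily, n_match = j$n_match,
                 log_emis = emis,
                 log_ins = matrix(log(j$background), 20, j$n_match + 1,
                                  dimnames = list(AA20, NULL)),
                 tMM = num(j$tMM), tMI = num(j$tMI), tMD = num(j$tMD),
                 tIM = num(j$tIM), tII = num(j$tII), tID = num(j$tID),
                 tDM = num(j$tDM), tDI = num(j$tDI), tDD = num(j$tDD),
                 background = j$background,
                 pseudocount_weight = j$pseudocount_weight,
                 n_training = j$n_training),
            class = "profile_hmm")
}
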