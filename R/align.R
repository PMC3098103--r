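# Global pairwise alignment (Needleman-Wunsch with affine gaps) and a
# minimal progressive MSA used for fixture-scale training sets.

.pkg_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix over the 21-symbol alphabet
#'
#' The 20x20 amino-acid block is the standard BLOSUM62 (as distributed with
#' Biostrings); the gap row/column scores 0 against everything, and `X`
#' scores 0 against everything.  Used for pairwise alignment and for
#' sum-of-pairs profile scoring.
#'
#' @return numeric matrix with dimnames over `c(AA20, "-", "X")`.
#' @export
blosum62 <- function() {
  if (is.null(.pkg_env$b62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    full <- e$BLOSUM62
    syms <- c(AA20, GAP, "X")
    m <- matrix(0, 22, 22, dimnames = list(syms, syms))
    m[AA20, AA20] <- full[AA20, AA20]
    .pkg_env$b62 <- m
  }
  .pkg_env$b62
}

.as_residues <- function(x) {
  if (inherits(x, "acs_dataset")) {
    if (length(x) != 1L) stop("expected a single sequence record")
    x$residues
  } else as.character(x)
}

.seq_id <- function(x, default) {
  if (inherits(x, "acs_dataset")) x$id else default
}

#' Needleman-Wunsch global alignment
#'
#' Optimal global alignment under BLOSUM62 with affine gap penalties.  A gap
#' of length L costs `gap_open + L * gap_extend`; terminal gaps are free by
#' default (the convention of EMBOSS needle, whose percentages this
#' reproduces).  Percent identity counts exact matches over the full
#' alignment length (gap columns included in the denominator); percent
#' similarity counts aligned pairs with a positive substitution score.
#'
#' @param a,b sequences: strings or single-record [acs_dataset]s.
#' @param matrix substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @param free_end_gaps if `TRUE` (default) terminal gaps cost nothing.
#' @return object of class `pairwise_alignment`: `aligned_a`, `aligned_b`,
#'   `score`, `identity_pct`, `similarity_pct`, `column_map` (for each
#'   position of `a`, the aligned position of `b` or `NA`).
#' @export
needleman_wunsch <- function(a, b, matrix = blosum62(), gap_open = 10,
                             gap_extend = 0.5, free_end_gaps = TRUE) {
  ra <- .as_residues(a)
  rb <- .as_residues(b)
  if (!nzchar(ra) || !nzchar(rb)) stop("empty sequence")
  ca <- strsplit(ra, "")[[1]]
  cb <- strsplit(rb, "")[[1]]
  if (!all(ca %in% rownames(matrix)) || !all(cb %in% rownames(matrix)))
    stop("sequence contains symbols absent from the substitution matrix")
  S <- matrix[ca, cb, drop = FALSE]
  res <- .nw_align_cpp(S, gap_open, gap_extend, free_end_gaps)
  ai <- res$ai
  bi <- res$bi
  aligned_a <- ifelse(ai == 0L, GAP, ca[pmax(ai, 1L)])
  aligned_b <- ifelse(bi == 0L, GAP, cb[pmax(bi, 1L)])
  len <- length(ai)
  pair <- ai > 0L & bi > 0L
  ident <- sum(pair & aligned_a == aligned_b)
  pos <- sum(matrix[cbind(aligned_a[pair], aligned_b[pair])] > 0)
  column_map <- rep(NA_integer_, length(ca))
  column_map[ai[pair]] <- bi[pair]
  structure(list(
    id_a = .seq_id(a, "a"), id_b = .seq_id(b, "b"),
    aligned_a = paste(aligned_a, collapse = ""),
    aligned_b = paste(aligned_b, collapse = ""),
    score = res$score,
    identity_pct = 100 * ident / len,
    similarity_pct = 100 * pos / len,
    column_map = column_map
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment %s ~ %s: score %.1f, identity %.1f%%, similarity %.1f%%\n",
              x$id_a, x$id_b, x$score, x$identity_pct, x$similarity_pct))
  invisible(x)
}

# ---- progressive MSA -------------------------------------------------------

.profile_freq <- function(mat) {
  # 22-symbol frequency profile (cols of mat are alignment columns)
  syms <- c(AA20, GAP, "X")
  apply(mat, 2, function(col) {
    col[!col %in% syms] <- "X"
    tabulate(match(col, syms), nbins = 22L) / length(col)
  })
}

.merge_profiles <- function(matA, matB, gap_open, gap_extend) {
  fA <- .profile_freq(matA)  # 22 x LA
  fB <- .profile_freq(matB)
  S <- t(fA) %*% blosum62() %*% fB
  res <- .nw_align_cpp(S, gap_open, gap_extend, TRUE)
  ncolnew <- length(res$ai)
  out <- matrix(GAP, nrow(matA) + nrow(matB), ncolnew)
  ia <- res$ai > 0L
  ib <- res$bi > 0L
  out[seq_len(nrow(matA)), ia] <- matA[, res$ai[ia], drop = FALSE]
  out[nrow(matA) + seq_len(nrow(matB)), ib] <- matB[, res$bi[ib], drop = FALSE]
  rownames(out) <- c(rownames(matA), rownames(matB))
  out
}

#' Minimal progressive multiple alignment
#'
#' Intended for fixture-scale training sets (tens of sequences): UPGMA guide
#' tree on Needleman-Wunsch distance (100 - percent identity), then
#' profile-profile merges scored by sum-of-pairs BLOSUM62.  Deterministic
#' given input order.  Production users with large alignments can instead
#' supply an external MSA through [read_alignment()].
#'
#' @param dataset an [acs_dataset] with >= 2 sequences (a single sequence is
#'   returned as a 1-row alignment with a warning).
#' @param gap_open,gap_extend gap penalties passed to the aligner.
#' @return an [acs_msa].
#' @export
progressive_msa <- function(dataset, gap_open = 10, gap_extend = 0.5) {
  n <- length(dataset)
  if (n == 1L) {
    warning("single sequence: returning a 1-row alignment")
    return(acs_msa(dataset$id, dataset$residues))
  }
  # guide distances: self-score-normalised NW similarity (score-only DP)
  sub <- blosum62()
  codes <- lapply(dataset$residues,
                  function(s) match(strsplit(s, "")[[1]], rownames(sub)))
  selfscore <- vapply(codes, function(cd) sum(diag(sub)[cd]), 0)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      s <- .nw_score_codes_cpp(codes[[i]], codes[[j]], sub,
                               gap_open, gap_extend, TRUE)
      D[i, j] <- D[j, i] <- 1 - s / max(min(selfscore[i], selfscore[j]), 1)
    }
  }
  profiles <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(dataset$residues[i], "")[[1]], nrow = 1)
    rownames(m) <- dataset$id[i]
    m
  })
  if (n == 2L) {
    merged <- .merge_profiles(profiles[[1]], profiles[[2]],
                              gap_open, gap_extend)
  } else {
    tree <- stats::hclust(stats::as.dist(D), method = "average")  # UPGMA
    store <- vector("list", n - 1L)
    getp <- function(k) if (k < 0) profiles[[-k]] else store[[k]]
    for (s in seq_len(n - 1L)) {
      store[[s]] <- .merge_profiles(getp(tree$merge[s, 1]),
                                    getp(tree$merge[s, 2]),
                                    gap_open, gap_extend)
    }
    merged <- store[[n - 1L]]
  }
  merged <- merged[dataset$id, , drop = FALSE]  # restore input order
  acs_msa(rownames(merged), apply(merged, 1, paste, collapse = ""))
}
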