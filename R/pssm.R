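# Per-subfamily position-specific scoring matrices over ASP columns, and
# best-score classification (the 15- and 44-position protocols).

PSSM_BACKGROUND <- 0.05  # probability of random occurrence of any symbol
PSSM_FLOOR <- -3.00      # fixed score substituted at zero training frequency

#' Build a subfamily PSSM from active-site profiles
#'
#' The score of symbol `a` at position `p` is `log(Freq(a, p) / 0.05)` where
#' `Freq` is the training frequency over the 21-symbol alphabet (20 amino
#' acids + gap).  Symbols never observed at a position receive the fixed
#' floor score of -3.00.  Scores of symbols with small nonzero frequency are
#' NOT clamped at the floor: the floor is exclusively the zero-frequency
#' substitute.
#'
#' @param asps list of `asp` objects (uniform SDR set) from one subfamily.
#' @param subfamily subfamily label stored with the matrix.
#' @param log_base `"natural"` (default) or `"log10"`.  Classification by
#'   argmax is invariant to the base.
#' @return object of class `acs_pssm`: `subfamily`, `n_positions`, `matrix`
#'   (n_positions x 21), `positions`, `background_p`, `floor_score`,
#'   `log_base`, `n_training`.
#' @export
build_pssm <- function(asps, subfamily, log_base = c("natural", "log10")) {
  log_base <- match.arg(log_base)
  if (length(asps) == 0L) stop("empty ASP list")
  .check_same_sdr(asps)
  m <- asp_matrix(asps)
  m[!m %in% SYMBOLS21] <- "X"  # ambiguity: excluded from the 21-symbol counts
  n <- nrow(m)
  counts <- t(apply(m, 2, function(col) {
    tabulate(match(col, SYMBOLS21), nbins = length(SYMBOLS21))
  }))
  freq <- counts / n
  lg <- if (log_base == "natural") log else log10
  score <- lg(freq / PSSM_BACKGROUND)
  score[freq == 0] <- PSSM_FLOOR
  dimnames(score) <- list(colnames(m), SYMBOLS21)
  structure(list(subfamily = subfamily, n_positions = nrow(score),
                 matrix = score,
                 positions = as.integer(colnames(m)),
                 background_p = PSSM_BACKGROUND, floor_score = PSSM_FLOOR,
                 log_base = log_base, n_training = n),
            class = "acs_pssm")
}

#' @export
print.acs_pssm <- function(x, ...) {
  cat(sprintf("acs_pssm %s: %d positions x %d symbols, %d training ASPs (%s log)\n",
              x$subfamily, x$n_positions, ncol(x$matrix), x$n_training,
              x$log_base))
  invisible(x)
}

#' Score an ASP against a subfamily PSSM
#'
#' Sum over positions of the matrix entry for the ASP symbol.  The ambiguity
#' symbol `X` scores at the floor, with a warning.
#'
#' @param pssm an `acs_pssm`.
#' @param asp an `asp` (same number of positions).
#' @return numeric score.
#' @export
score_asp <- function(pssm, asp) {
  if (length(asp$symbols) != pssm$n_positions) {
    stop("ASP length (", length(asp$symbols), ") does not match PSSM (",
         pssm$n_positions, ")")
  }
  sym <- asp$symbols
  unknown <- !sym %in% SYMBOLS21
  if (any(unknown)) {
    warning("ambiguous symbol(s) scored at floor for query ", asp$query_id)
  }
  s <- ifelse(unknown, pssm$floor_score,
              pssm$matrix[cbind(seq_along(sym),
                                match(sym, SYMBOLS21))])
  sum(s)
}

.make_classification <- function(query_id, scores, tol = 1e-9) {
  scores <- scores[order(-scores, names(scores))]  # ties: alphabetical
  tie <- length(scores) >= 2 && abs(scores[1] - scores[2]) <= tol
  structure(list(query_id = query_id, scores = scores,
                 predicted = names(scores)[1], tie = tie,
                 margin = if (length(scores) >= 2) scores[1] - scores[2]
                 else Inf),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s -> %s%s (margin %.2f): %s\n", x$query_id, x$predicted,
              if (x$tie) " [tie]" else "", x$margin,
              paste(sprintf("%s=%.2f", names(x$scores), x$scores),
                    collapse = " ")))
  invisible(x)
}

#' Classify an ASP by highest-scoring subfamily PSSM
#'
#' Substrate preference is assigned to the subfamily whose PSSM scores the
#' query ASP highest.  Exact ties (within 1e-9) are flagged and broken
#' alphabetically.
#'
#' @param asp an `asp`.
#' @param pssms list of >= 2 `acs_pssm` objects with equal `n_positions`.
#' @return a `classification_result`: `query_id`, `scores` (named, sorted
#'   descending), `predicted`, `tie`, `margin`.
#' @export
classify_asp <- function(asp, pssms) {
  if (length(pssms) < 2L) stop("need at least two subfamily PSSMs")
  np <- unique(vapply(pssms, function(p) p$n_positions, 1L))
  if (length(np) != 1L) stop("PSSMs have mixed position counts")
  scores <- vapply(pssms, function(p) score_asp(p, asp), 0)
  names(scores) <- vapply(pssms, function(p) p$subfamily, "")
  .make_classification(asp$query_id, scores)
}

#' Build one PSSM per subfamily from a labeled ASP collection
#'
#' @param asps list of `asp` objects.
#' @param labels character vector of subfamily labels (same length).
#' @param log_base passed to [build_pssm()].
#' @return named list of `acs_pssm` objects (alphabetical by subfamily).
#' @export
build_pssm_library <- function(asps, labels, log_base = "natural") {
  stopifnot(length(asps) == length(labels))
  fams <- sort(unique(labels[!is.na(labels)]))
  out <- lapply(fams, function(f) {
    build_pssm(asps[which(labels == f)], f, log_base)
  })
  names(out) <- fams
  out
}

#' Write / read a PSSM as JSON
#' @param pssm an `acs_pssm`.
#' @param path file path.
#' @return `path` (write) or an `acs_pssm` (read).
#' @export
write_pssm <- function(pssm, path) {
  obj <- unclass(pssm)
  obj$symbols <- SYMBOLS21
  obj$matrix <- unname(lapply(seq_len(nrow(pssm$matrix)),
                              function(i) unname(pssm$matrix[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- if (is.list(j$matrix)) do.call(rbind, j$matrix) else j$matrix
  dimnames(m) <- list(j$positions, j$symbols)
  structure(list(subfamily = j$subfamily, n_positions = j$n_positions,
                 matrix = m, positions = as.integer(j$positions),
                 background_p = j$background_p, floor_score = j$floor_score,
                 log_base = j$log_base, n_training = j$n_training),
            class = "acs_pssm")
}

#' Classification results as a TSV-ready data frame
#' @param results list of `classification_result`s.
#' @return data frame: `query_id`, `predicted`, `tie`, then one score
#'   column per subfamily.
#' @export
classification_table <- function(results) {
  fams <- sort(unique(unlist(lapply(results, function(r) names(r$scores)))))
  rows <- lapply(results, function(r) {
    df <- data.frame(query_id = r$query_id, predicted = r$predicted,
                     tie = r$tie, margin = r$margin)
    for (f in fams) df[[f]] <- unname(r$scores[f])
    df
  })
  do.call(rbind, rows)
}
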