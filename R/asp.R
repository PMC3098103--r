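# Active-site profiles: the ordered residues of a query at the SDR-aligned
# columns of the structural template, and consensus profiles with
# conservation categories.

#' Extract the active-site profile (ASP) of a query sequence
#'
#' Globally aligns the query to the template sequence and reads off the
#' query symbol aligned to each SDR column.  A gap placed at an SDR column
#' yields `"-"`, which is a first-class 21st symbol downstream.
#'
#' @param query a sequence: string or single-record [acs_dataset].
#' @param template an [acs_template()] list (or a list with `sequence`,
#'   `sdrs`, `offset`).
#' @param gap_open,gap_extend aligner parameters.
#' @return object of class `asp`: `query_id`, `symbols` (character vector,
#'   one per SDR position), `sdr_set_id`, `positions`, `alignment_score`.
#' @export
extract_asp <- function(query, template = acs_template(15), gap_open = 10,
                        gap_extend = 0.5) {
  seq_index <- template$sdrs$positions - template$offset
  tlen <- nchar(template$sequence$residues)
  if (any(seq_index < 1 | seq_index > tlen)) {
    stop("SDR position outside template sequence (corrupt template data)")
  }
  al <- needleman_wunsch(template$sequence$residues, .as_residues(query),
                         gap_open = gap_open, gap_extend = gap_extend)
  qchar <- strsplit(.as_residues(query), "")[[1]]
  qpos <- al$column_map[seq_index]
  symbols <- ifelse(is.na(qpos), GAP, qchar[ifelse(is.na(qpos), 1L, qpos)])
  structure(list(query_id = .seq_id(query, "query"),
                 symbols = symbols,
                 sdr_set_id = template$sdrs$template_id,
                 positions = template$sdrs$positions,
                 alignment_score = al$score),
            class = "asp")
}

#' @export
print.asp <- function(x, ...) {
  cat(sprintf("asp %s [%s]: %s\n", x$query_id, x$sdr_set_id,
              paste(x$symbols, collapse = "")))
  invisible(x)
}

#' Extract ASPs for every record of a dataset
#'
#' @param dataset an [acs_dataset].
#' @inheritParams extract_asp
#' @return list of [extract_asp()] results, named by record id.
#' @export
extract_asps <- function(dataset, template = acs_template(15),
                         gap_open = 10, gap_extend = 0.5) {
  out <- lapply(seq_along(dataset$id), function(i) {
    extract_asp(dataset[i], template, gap_open, gap_extend)
  })
  names(out) <- dataset$id
  out
}

#' ASPs as a character matrix (rows = queries, cols = SDR positions)
#' @param asps list of `asp` objects (same SDR set).
#' @return character matrix with SDR positions as column names.
#' @export
asp_matrix <- function(asps) {
  .check_same_sdr(asps)
  m <- do.call(rbind, lapply(asps, function(a) a$symbols))
  rownames(m) <- vapply(asps, function(a) a$query_id, "")
  colnames(m) <- asps[[1]]$positions
  m
}

.check_same_sdr <- function(asps) {
  if (length(asps) < 1L) stop("need at least one ASP")
  ids <- unique(vapply(asps, function(a) a$sdr_set_id, ""))
  lens <- unique(vapply(asps, function(a) length(a$symbols), 1L))
  if (length(ids) != 1L || length(lens) != 1L) {
    stop("ASPs come from mixed SDR sets")
  }
  invisible(TRUE)
}

#' Consensus active-site profile with conservation categories
#'
#' Per SDR position: the modal non-gap symbol, its percentage among all rows
#' (gaps included in the denominator), and a conservation category: `high`
#' when conservation exceeds 80%, `low` below 50%, `mid` in between
#' (boundaries 50% and 80% are `mid`).
#'
#' @param asps list of `asp` objects over the same SDR set.
#' @return data frame of class `consensus_profile`: `position`,
#'   `consensus_symbol`, `conservation_pct`, `category`.
#' @export
consensus_asp <- function(asps) {
  .check_same_sdr(asps)
  m <- asp_matrix(asps)
  n <- nrow(m)
  out <- lapply(seq_len(ncol(m)), function(p) {
    col <- m[, p]
    tab <- sort(table(col[col != GAP]), decreasing = TRUE)
    if (length(tab) == 0L) {
      return(data.frame(position = as.integer(colnames(m)[p]),
                        consensus_symbol = GAP, conservation_pct = 0,
                        category = "low"))
    }
    pct <- 100 * tab[1] / n
    data.frame(position = as.integer(colnames(m)[p]),
               consensus_symbol = names(tab)[1],
               conservation_pct = as.numeric(pct),
               category = if (pct > 80) "high" else if (pct < 50) "low"
               else "mid")
  })
  out <- do.call(rbind, out)
  class(out) <- c("consensus_profile", "data.frame")
  out
}

#' Write an ASP table as TSV
#'
#' One row per query; columns are the query id followed by one column per
#' SDR position, labeled with the template residue number.
#'
#' @param asps list of `asp` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_asp_tsv <- function(asps, path) {
  m <- asp_matrix(asps)
  df <- data.frame(query_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
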