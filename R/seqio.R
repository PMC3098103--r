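#' @useDynLib acsprofiler, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats hclust as.dist setNames runif rbinom rpois
#' @importFrom utils write.table head modifyList
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP <- "-"
#' The 21-symbol alphabet used by active-site PSSMs: 20 amino acids + gap
#' @format character vector of length 21.
#' @export
SYMBOLS21 <- c(AA20, GAP)

SUBFAMILIES <- c("4CL", "AcCS", "LCS", "Luciferase", "MCS", "NRPS")

.clean_residues <- function(x, id = NULL) {
  x <- toupper(x)
  bad <- gsub(sprintf("[%s]", paste(AA20, collapse = "")), "", x)
  bad <- gsub("X", "", bad, fixed = TRUE)
  if (nzchar(bad)) {
    warning(sprintf("sequence %s: unknown residue characters (%s) mapped to 'X'",
                    if (is.null(id)) "?" else id,
                    paste(unique(strsplit(bad, "")[[1]]), collapse = ",")),
            call. = FALSE)
    ch <- strsplit(x, "")[[1]]
    ch[!ch %in% c(AA20, "X")] <- "X"
    x <- paste(ch, collapse = "")
  }
  x
}

#' Construct a labeled sequence dataset
#'
#' A dataset is an ordered collection of protein sequences, each with an id,
#' an optional free-text description and an optional subfamily label
#' (e.g. `"AcCS"`, `"LCS"`, `"NRPS"`).  Residues are normalised to uppercase
#' and characters outside the 20 standard amino acids are mapped to `"X"`
#' with a warning.
#'
#' @param id character vector of unique sequence identifiers.
#' @param residues character vector of sequences (same length as `id`).
#' @param label optional character vector of subfamily labels (`NA` = none).
#' @param description optional character vector of descriptions.
#' @return An object of class `acs_dataset` with elements `id`, `residues`,
#'   `label`, `description`.
#' @export
acs_dataset <- function(id, residues, label = NA_character_,
                        description = "") {
  id <- as.character(id)
  residues <- as.character(residues)
  stopifnot(length(id) == length(residues))
  if (length(id) == 0L) stop("no sequences")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(residues))) stop("empty sequence for id: ",
                                   paste(id[!nzchar(residues)], collapse = ", "))
  residues <- vapply(seq_along(residues),
                     function(i) .clean_residues(residues[i], id[i]), "")
  label <- rep_len(as.character(label), length(id))
  description <- rep_len(as.character(description), length(id))
  structure(list(id = id, residues = residues, label = label,
                 description = description),
            class = "acs_dataset")
}

#' @export
length.acs_dataset <- function(x) length(x$id)

#' @export
print.acs_dataset <- function(x, ...) {
  labs <- subfamilies(x)
  cat(sprintf("acs_dataset: %d sequences, lengths %d-%d\n", length(x),
              min(nchar(x$residues)), max(nchar(x$residues))))
  if (length(labs)) {
    tab <- table(x$label[!is.na(x$label)])
    cat("  subfamilies:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
`[.acs_dataset` <- function(x, i) {
  structure(list(id = x$id[i], residues = x$residues[i], label = x$label[i],
                 description = x$description[i]),
            class = "acs_dataset")
}

#' Subfamily labels present in a dataset
#' @param x an `acs_dataset`.
#' @return character vector of labels (sorted, `NA` excluded).
#' @export
subfamilies <- function(x) sort(unique(x$label[!is.na(x$label)]))

#' Read a FASTA file into a labeled dataset
#'
#' Subfamily labels are carried in headers as a `label=<name>` token, e.g.
#' `>seq1 label=AcCS some description`.  Records without the token get an
#' `NA` label.
#'
#' @param path path to a FASTA file.
#' @return an [acs_dataset].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("no sequences in ", path)
  headers <- names(aas)
  id <- sub("\\s.*$", "", headers)
  rest <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  label <- ifelse(grepl("label=(\\S+)", rest),
                  sub(".*label=(\\S+).*", "\\1", rest), NA_character_)
  desc <- trimws(gsub("label=\\S+", "", rest))
  acs_dataset(id, as.character(aas), label, desc)
}

#' Write a labeled dataset to FASTA
#'
#' Inverse of [read_fasta()]: labels are emitted as `label=` header tokens so
#' that a write/read round trip reproduces ids, residues and labels exactly.
#'
#' @param x an `acs_dataset`.
#' @param path output file path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  con <- file(path, "wb")  # binary: byte-identical output across platforms
  on.exit(close(con))
  for (i in seq_along(x$id)) {
    hdr <- x$id[i]
    if (!is.na(x$label[i])) hdr <- paste0(hdr, " label=", x$label[i])
    if (nzchar(x$description[i])) hdr <- paste(hdr, x$description[i])
    seqlines <- substring(x$residues[i],
                          seq(1, nchar(x$residues[i]), width),
                          pmin(seq(1, nchar(x$residues[i]), width) + width - 1,
                               nchar(x$residues[i])))
    writeLines(c(paste0(">", hdr), seqlines), con, sep = "\n")
  }
  invisible(path)
}

#' Construct a multiple alignment object
#'
#' @param id character vector of row ids.
#' @param rows character vector of gapped sequences (equal lengths).
#' @return an object of class `acs_msa` with `id`, `rows`, `n_columns`.
#' @export
acs_msa <- function(id, rows) {
  id <- as.character(id)
  rows <- toupper(as.character(rows))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    ragged <- id[lens != stats::median(lens)]
    stop("ragged alignment rows for id(s): ", paste(ragged, collapse = ", "))
  }
  structure(list(id = id, rows = rows, n_columns = lens[1]),
            class = "acs_msa")
}

#' @export
print.acs_msa <- function(x, ...) {
  cat(sprintf("acs_msa: %d rows x %d columns\n", length(x$id), x$n_columns))
  invisible(x)
}

#' Character matrix view of an alignment (rows x columns)
#' @param msa an `acs_msa`.
#' @return character matrix with rownames = ids.
#' @export
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$rows, ""))
  rownames(m) <- msa$id
  m
}

#' Read a multiple alignment
#'
#' Supports aligned FASTA and Clustal dialects.  Clustal conservation lines
#' are ignored; all rows must have equal gapped length.
#'
#' @param path path to the alignment file.
#' @param dialect `"aligned-fasta"` or `"clustal"`.
#' @return an [acs_msa].
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "aligned-fasta") {
    aas <- Biostrings::readAAStringSet(path)
    if (length(aas) == 0L) stop("no sequences in ", path)
    acs_msa(sub("\\s.*$", "", names(aas)), as.character(aas))
  } else {
    aln <- as.character(Biostrings::readAAMultipleAlignment(path,
                                                            format = "clustal"))
    acs_msa(names(aln), unname(aln))
  }
}

#' Write an alignment as aligned FASTA
#' @param msa an `acs_msa`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  write_fasta(structure(list(id = msa$id, residues = msa$rows,
                             label = rep(NA_character_, length(msa$id)),
                             description = rep("", length(msa$id))),
                        class = "acs_dataset"),
              path)
}

#' Drop gaps from an alignment row
#' @param row a gapped sequence string.
#' @return the unaligned sequence.
#' @export
ungap <- function(row) gsub("-", "", row, fixed = TRUE)
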