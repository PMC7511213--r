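# Sequence I/O, genetic-code tables, exon splicing and strand primitives
# shared by every other module. Coordinates are 0-based half-open internally
# and 1-based inclusive in every user-facing structure.

#' Construct a nucleotide sequence record
#'
#' A lightweight record holding one DNA sequence. On construction the
#' sequence is uppercased, RNA `U` is mapped to `T`, and IUPAC ambiguity
#' letters other than A/C/G/T are collapsed to `N` (design modules require
#' an unambiguous alphabet; genome scanning treats `N` as a mismatch).
#' Any character outside the IUPAC nucleotide alphabet is an error.
#'
#' @param seq Character scalar, the nucleotide sequence.
#' @param id Character scalar identifier.
#' @param description Optional free-text description.
#' @return An object of class `nuc_sequence` with fields `id`, `seq`,
#'   `description`.
#' @examples
#' nuc_sequence("atgaaauaa", id = "toy")
#' @export
nuc_sequence <- function(seq, id = "seq1", description = "") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- normalize_seq(seq)
  if (nchar(seq) < 1L) {
    stop("sequence '", id, "' is empty after normalization", call. = FALSE)
  }
  structure(
    list(id = as.character(id), seq = seq, description = as.character(description)),
    class = "nuc_sequence"
  )
}

#' @export
print.nuc_sequence <- function(x, ...) {
  n <- nchar(x$seq)
  head <- if (n > 60) paste0(substr(x$seq, 1, 57), "...") else x$seq
  cat(sprintf("<nuc_sequence> %s (%d nt)\n  %s\n", x$id, n, head))
  invisible(x)
}

# Uppercase, U->T, ambiguity letters -> N; reject anything non-IUPAC.
# `where` customises the error message with file/line context.
normalize_seq <- function(seq, where = NULL) {
  s <- chartr("u", "T", toupper(seq))
  s <- gsub("U", "T", s, fixed = TRUE)
  bad <- regmatches(s, gregexpr("[^ACGTNRYSWKMBDHV]", s))[[1]]
  if (length(bad) > 0) {
    ctx <- if (is.null(where)) "" else paste0(" (", where, ")")
    stop("illegal sequence character '", bad[1], "'", ctx, call. = FALSE)
  }
  # ambiguity codes other than N carry no information the design search can
  # use; collapse them to N so downstream modules see a 5-letter alphabet
  chartr("RYSWKMBDHV", "NNNNNNNNNN", s)
}

#' Read sequences from FASTA or plain text
#'
#' Multi-record input must be FASTA; a file whose first non-blank character
#' is not `>` is treated as a single bare sequence (whitespace stripped) and
#' given a generated id. Sequences are normalized as in [nuc_sequence()].
#'
#' @param path Path to a FASTA or plain-text sequence file.
#' @return A list of `nuc_sequence` records, input order preserved.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[trimws(lines) != ""]
  if (length(nonblank) == 0) stop("empty sequence file: ", path, call. = FALSE)

  # validate sequence characters line by line so errors can name the line
  is_header <- startsWith(trimws(lines), ">")
  for (i in seq_along(lines)) {
    if (is_header[i]) next
    ln <- gsub("[[:space:]]", "", lines[i])
    if (ln == "") next
    bad <- regmatches(toupper(ln), gregexpr("[^ACGTUNRYSWKMBDHV]", toupper(ln)))[[1]]
    if (length(bad) > 0) {
      stop("illegal sequence character '", bad[1], "' at line ", i, " of ", path,
           call. = FALSE)
    }
  }

  if (!startsWith(trimws(nonblank[1]), ">")) {
    seq <- paste(gsub("[[:space:]]", "", lines), collapse = "")
    id <- paste0(tools::file_path_sans_ext(basename(path)), "_1")
    return(list(nuc_sequence(seq, id = id)))
  }

  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path, call. = FALSE)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  recs <- vector("list", length(set))
  for (i in seq_along(set)) {
    recs[[i]] <- nuc_sequence(as.character(set[[i]]), id = ids[i],
                              description = desc[i])
  }
  recs
}

#' Write records to a FASTA file
#'
#' @param records A list of `nuc_sequence` records (or a single record).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "nuc_sequence")) records <- list(records)
  seqs <- vapply(records, function(r) r$seq, character(1))
  ids <- vapply(records, function(r) r$id, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' `N` complements to `N`; the empty string maps to itself.
#'
#' @param seq Character scalar over `{A,C,G,T,N}`.
#' @return The reverse complement, 5'->3'.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Splice exon spans out of a sequence
#'
#' For inputs that contain introns the caller supplies the exon spans
#' (1-based, inclusive, strictly increasing, non-overlapping) and receives
#' the concatenated coding sequence. The record id is suffixed with
#' `_spliced` to mark the operation.
#'
#' @param x A `nuc_sequence`.
#' @param spans A list of `c(start, end)` pairs or a two-column matrix,
#'   1-based inclusive.
#' @return A spliced `nuc_sequence`.
#' @export
splice_exons <- function(x, spans) {
  stopifnot(inherits(x, "nuc_sequence"))
  if (is.matrix(spans)) spans <- lapply(seq_len(nrow(spans)), function(i) spans[i, ])
  n <- nchar(x$seq)
  prev_end <- 0L
  parts <- character(length(spans))
  for (i in seq_along(spans)) {
    sp <- as.integer(spans[[i]])
    if (length(sp) != 2L || any(is.na(sp)) || sp[1] > sp[2]) {
      stop("exon span ", i, " is malformed (need start <= end)", call. = FALSE)
    }
    if (sp[1] < 1L || sp[2] > n) {
      stop("exon span ", i, " [", sp[1], ", ", sp[2], "] lies outside the ",
           n, "-nt sequence", call. = FALSE)
    }
    if (sp[1] <= prev_end) {
      stop("exon span ", i, " overlaps or is not strictly increasing",
           call. = FALSE)
    }
    prev_end <- sp[2]
    parts[i] <- substr(x$seq, sp[1], sp[2])
  }
  nuc_sequence(paste(parts, collapse = ""), id = paste0(x$id, "_spliced"),
               description = x$description)
}

# in-memory cache for the packaged code tables
.cbei_env <- new.env(parent = emptyenv())

genetic_code_registry <- function() {
  if (is.null(.cbei_env$codes)) {
    path <- system.file("extdata", "genetic_codes.json", package = "cbei")
    .cbei_env$codes <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  .cbei_env$codes
}

#' List available genetic-code table ids
#'
#' @return Integer vector of NCBI translation-table ids shipped with the
#'   package (the 25 tables used by ORFfinder).
#' @export
list_genetic_codes <- function() {
  sort(as.integer(names(genetic_code_registry())))
}

#' Load a built-in genetic code
#'
#' Tables follow NCBI translation-table numbering. Table 1 is the standard
#' code with stop set `{TAA, TAG, TGA}`. A codon that NCBI lists as both
#' stop and sense (tables 27, 28, 31) is recorded as stop here, because the
#' inactivation design needs an unambiguous stop set.
#'
#' @param table_id Integer NCBI translation-table id.
#' @return An object of class `genetic_code` with fields `table_id`,
#'   `name`, `codon_to_aa` (named character, `"*"` for stop),
#'   `start_codons`, `stop_codons`.
#' @examples
#' code <- load_genetic_code(1)
#' code$stop_codons
#' @export
load_genetic_code <- function(table_id) {
  reg <- genetic_code_registry()
  key <- as.character(as.integer(table_id))
  if (!key %in% names(reg)) {
    stop("unknown genetic-code table ", table_id, "; available ids: ",
         paste(list_genetic_codes(), collapse = ", "), call. = FALSE)
  }
  raw <- reg[[key]]
  codon_to_aa <- unlist(raw$codon_to_aa)
  structure(
    list(
      table_id = as.integer(raw$id),
      name = raw$name,
      codon_to_aa = codon_to_aa,
      start_codons = unlist(raw$start_codons),
      stop_codons = unlist(raw$stop_codons)
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> table %d: %s\n  starts: %s\n  stops:  %s\n",
              x$table_id, x$name,
              paste(x$start_codons, collapse = " "),
              paste(x$stop_codons, collapse = " ")))
  invisible(x)
}

# translate a vector of codons; codons containing N translate to NA
translate_codons <- function(codons, code) {
  aa <- unname(code$codon_to_aa[codons])
  aa
}

#' GC fraction of a sequence
#'
#' @param seq Character scalar DNA string.
#' @return `(#G + #C) / length`, with `N` counted in the denominator.
#' @export
gc_content <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(NA_real_)
  gc <- n - nchar(gsub("[GC]", "", seq))
  gc / n
}
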