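# Six-frame ORF detection so the user (or the batch pipeline) can pick the
# target coding sequence out of an arbitrary input.

#' Detect open reading frames on all six frames
#'
#' Reports every maximal start->stop ORF of length `>= min_len` on frames
#' +1, +2, +3 (forward) and -1, -2, -3 (reverse complement). An ORF runs
#' from the 5'-most qualifying start codon after the previous in-frame stop
#' through the next in-frame stop codon; the stop codon is included in the
#' reported length. ORFs lacking a terminating stop before the sequence end
#' are not reported (downstream inactivation design needs a bounded CDS).
#' Codons containing `N` never match a start or a stop codon.
#'
#' Coordinates are 1-based positions on the input sequence and
#' orientation-aware: on the minus strand `start` is the first base of the
#' start codon on the input's plus-strand coordinates, so `start > end`.
#'
#' @param x A `nuc_sequence` (or character scalar).
#' @param code A `genetic_code`; default standard table 1.
#' @param min_len Minimum ORF length in nt, stop codon included. Default 75;
#'   the supported configuration range is 24-150.
#' @param strict If `TRUE`, a `min_len` outside `[24, 150]` is an error;
#'   otherwise it is accepted with a warning.
#' @return A data.frame with columns `frame`, `strand`, `start`, `end`,
#'   `length_nt`, `cds_seq`, sorted by (strand, start).
#' @examples
#' detect_orfs(nuc_sequence("ATGAAATAA"), min_len = 9)
#' @export
detect_orfs <- function(x, code = load_genetic_code(1), min_len = 75,
                        strict = FALSE) {
  if (is.character(x)) x <- nuc_sequence(x)
  stopifnot(inherits(x, "nuc_sequence"), inherits(code, "genetic_code"))
  min_len <- as.integer(min_len)
  if (min_len < 24L || min_len > 150L) {
    msg <- paste0("min_len = ", min_len,
                  " is outside the permitted range [24, 150]")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  n <- nchar(x$seq)
  out <- list()
  for (strand in c("+", "-")) {
    work <- if (strand == "+") x$seq else reverse_complement(x$seq)
    for (f in 1:3) {
      ncod <- (n - f + 1L) %/% 3L
      if (ncod < 1L) next
      starts_at <- seq.int(f, by = 3L, length.out = ncod)
      codons <- substring(work, starts_at, starts_at + 2L)
      has_n <- grepl("N", codons, fixed = TRUE)
      is_stop <- codons %in% code$stop_codons & !has_n
      is_start <- codons %in% code$start_codons & !has_n
      stop_idx <- which(is_stop)
      prev_stop <- 0L
      for (s_i in stop_idx) {
        cand <- which(is_start[seq.int(prev_stop + 1L, s_i)]) + prev_stop
        prev_stop <- s_i
        if (length(cand) == 0L) next
        a <- cand[1L]                     # 5'-most qualifying start
        len <- (s_i - a + 1L) * 3L
        if (len < min_len) next
        ws <- starts_at[a]
        we <- starts_at[s_i] + 2L
        if (strand == "+") {
          rec <- list(frame = f, strand = "+", start = ws, end = we)
        } else {
          rec <- list(frame = -f, strand = "-", start = n - ws + 1L,
                      end = n - we + 1L)
        }
        rec$length_nt <- len
        rec$cds_seq <- substr(work, ws, we)
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(frame = integer(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      length_nt = integer(0), cds_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(out, function(r) {
    data.frame(frame = r$frame, strand = r$strand, start = r$start,
               end = r$end, length_nt = r$length_nt, cds_seq = r$cds_seq,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$strand, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Validate that a record is a complete coding sequence
#'
#' Batch (unattended) design assumes each input record already is a CDS.
#' This check inspects frame +1 only: the sequence must begin with a start
#' codon of `code`, end with a stop codon, contain no internal stop, and
#' have a length divisible by 3. Violations produce warnings (not errors)
#' so one malformed record cannot abort a batch run.
#'
#' @param x A `nuc_sequence`.
#' @param code A `genetic_code`.
#' @param warn Emit a warning listing the problems (default `TRUE`).
#' @return Character vector of problem descriptions; empty if valid.
#' @export
validate_cds <- function(x, code = load_genetic_code(1), warn = TRUE) {
  stopifnot(inherits(x, "nuc_sequence"))
  problems <- character(0)
  n <- nchar(x$seq)
  if (n %% 3L != 0L) {
    problems <- c(problems, sprintf("length %d is not divisible by 3", n))
  }
  n3 <- n - n %% 3L
  if (n3 >= 3L) {
    starts_at <- seq.int(1L, n3 - 2L, by = 3L)
    codons <- substring(x$seq, starts_at, starts_at + 2L)
    if (!codons[1] %in% code$start_codons) {
      problems <- c(problems, sprintf("first codon %s is not a start codon", codons[1]))
    }
    last <- codons[length(codons)]
    if (!last %in% code$stop_codons) {
      problems <- c(problems, sprintf("last codon %s is not a stop codon", last))
    }
    internal <- codons[-length(codons)] %in% code$stop_codons
    if (any(internal)) {
      problems <- c(problems, sprintf("internal stop codon at codon %d",
                                      which(internal)[1]))
    }
  } else {
    problems <- c(problems, "sequence shorter than one codon")
  }
  if (warn && length(problems) > 0) {
    warning("record '", x$id, "': ", paste(problems, collapse = "; "),
            call. = FALSE)
  }
  problems
}
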