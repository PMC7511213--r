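# Mismatch-tolerant, PAM-aware off-target search using the anchor
# (pigeonhole) algorithm: a spacer is split into (mismatch + 1) contiguous
# fragments; any genomic window within the mismatch budget must contain at
# least one fragment exactly, so exact fragment matches are the only
# candidate generators needed. Large genomes are processed in segments,
# with short junction segments spanning every internal boundary so sites
# straddling a segment break are not missed.

#' Split a spacer into pigeonhole anchors
#'
#' Produces `m + 1` contiguous, non-overlapping fragments of near-equal
#' length (lengths differ by at most 1, longer fragments first). If a
#' genomic window differs from the spacer in at most `m` positions, at
#' least one fragment must occur in it exactly (pigeonhole principle).
#'
#' @param spacer Protospacer string over `{A,C,G,T}`.
#' @param m Maximum number of mismatches (`>= 0`).
#' @return An object of class `anchor_set`: list with `spacer`,
#'   `max_mismatch`, and `anchors` (data.frame with 0-based `offset` and
#'   `fragment`).
#' @examples
#' build_anchors(strrep("ACGT", 5), m = 3)
#' @export
build_anchors <- function(spacer, m) {
  spacer <- toupper(spacer)
  m <- as.integer(m)
  L <- nchar(spacer)
  if (m < 0L) stop("mismatch budget m must be >= 0", call. = FALSE)
  if (L < m + 1L) {
    stop("spacer of length ", L, " cannot be split into ", m + 1L, " anchors",
         call. = FALSE)
  }
  k <- m + 1L
  base_len <- L %/% k
  extra <- L %% k
  lens <- rep(base_len, k) + c(rep(1L, extra), rep(0L, k - extra))
  offs <- cumsum(c(0L, lens[-k]))
  structure(
    list(spacer = spacer, max_mismatch = m,
         anchors = data.frame(offset = offs,
                              fragment = substring(spacer, offs + 1L, offs + lens),
                              stringsAsFactors = FALSE)),
    class = "anchor_set"
  )
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set> %s, m = %d: %s\n", x$spacer, x$max_mismatch,
              paste(x$anchors$fragment, collapse = " | ")))
  invisible(x)
}

hamming_distance <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Segment a genome for piecewise scanning
#'
#' Each contig is tiled with segments of at most `segment_size` bases; for
#' every internal tile boundary an additional junction segment of
#' `2 * flank` bases centred on the boundary is emitted so sites straddling
#' a break are recovered (they are deduplicated against tile hits by their
#' contig coordinates).
#'
#' @param genome Path to a (multi-)FASTA file, a list of `nuc_sequence`
#'   records, or a named character vector of contig sequences.
#' @param segment_size Maximum segment length in bases (default 50 Mb).
#' @param flank Junction half-width in bases (default 100).
#' @return A list of segments, each a list with `contig`, `seg_start`
#'   (0-based offset of the segment within the contig), `seq`, and
#'   `is_junction`.
#' @export
segment_genome <- function(genome, segment_size = 5e7, flank = 100) {
  segment_size <- as.integer(segment_size)
  flank <- as.integer(flank)
  if (segment_size <= 2L * flank) {
    stop("segment_size must exceed 2 * flank", call. = FALSE)
  }
  contigs <- as_contigs(genome)
  segs <- list()
  for (nm in names(contigs)) {
    s <- contigs[[nm]]
    nc <- nchar(s)
    nseg <- max(1L, as.integer(ceiling(nc / segment_size)))
    for (i in seq_len(nseg)) {
      a <- (i - 1L) * segment_size + 1L
      b <- min(i * segment_size, nc)
      segs[[length(segs) + 1L]] <- list(contig = nm, seg_start = a - 1L,
                                        seq = substr(s, a, b),
                                        is_junction = FALSE)
    }
    if (nseg > 1L) {
      for (i in seq_len(nseg - 1L)) {
        boundary <- i * segment_size          # last base of tile i
        a <- boundary - flank + 1L
        b <- min(boundary + flank, nc)
        segs[[length(segs) + 1L]] <- list(contig = nm, seg_start = a - 1L,
                                          seq = substr(s, a, b),
                                          is_junction = TRUE)
      }
    }
  }
  segs
}

# normalize the accepted genome representations to a named character vector
as_contigs <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    recs <- read_fasta(genome)
    out <- vapply(recs, function(r) r$seq, character(1))
    names(out) <- vapply(recs, function(r) r$id, character(1))
    return(out)
  }
  if (inherits(genome, "nuc_sequence")) genome <- list(genome)
  if (is.list(genome)) {
    out <- vapply(genome, function(r) r$seq, character(1))
    names(out) <- vapply(genome, function(r) r$id, character(1))
    return(out)
  }
  if (is.character(genome)) {
    out <- toupper(genome)
    if (is.null(names(out))) names(out) <- paste0("contig", seq_along(out))
    return(out)
  }
  stop("unsupported genome input", call. = FALSE)
}

# anchor scan of one strand of one segment sequence; returns window starts
# (1-based within the segment string), mismatch counts and sequences
scan_strand <- function(S, anchors, matcher, pam_side) {
  spacer <- anchors$spacer
  L <- nchar(spacer)
  P <- matcher$width
  ns <- nchar(S)
  cand <- integer(0)
  for (i in seq_len(nrow(anchors$anchors))) {
    frag <- anchors$anchors$fragment[i]
    off <- anchors$anchors$offset[i]
    pos <- gregexpr(paste0("(?=", frag, ")"), S, perl = TRUE)[[1]]
    if (pos[1] == -1L) next
    cand <- c(cand, as.integer(pos) - off)
  }
  cand <- sort(unique(cand))
  cand <- cand[cand >= 1L & cand + L - 1L <= ns]
  if (length(cand) == 0L) {
    return(data.frame(w = integer(0), mismatches = integer(0),
                      site_seq = character(0), pam_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  if (pam_side == "3prime") {
    pa <- cand + L
    pb <- cand + L + P - 1L
  } else {
    pa <- cand - P
    pb <- cand - 1L
  }
  ok <- pa >= 1L & pb <= ns
  cand <- cand[ok]; pa <- pa[ok]; pb <- pb[ok]
  if (length(cand) == 0L) {
    return(data.frame(w = integer(0), mismatches = integer(0),
                      site_seq = character(0), pam_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  pam_seq <- substring(S, pa, pb)
  ok <- pam_matches(matcher, pam_seq)
  cand <- cand[ok]; pam_seq <- pam_seq[ok]
  if (length(cand) == 0L) {
    return(data.frame(w = integer(0), mismatches = integer(0),
                      site_seq = character(0), pam_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  site_seq <- substring(S, cand, cand + L - 1L)
  mm <- vapply(site_seq, hamming_distance, integer(1), b = spacer,
               USE.NAMES = FALSE)
  keep <- mm <= anchors$max_mismatch
  data.frame(w = cand[keep], mismatches = mm[keep],
             site_seq = site_seq[keep], pam_seq = pam_seq[keep],
             stringsAsFactors = FALSE)
}

empty_hits_df <- function() {
  data.frame(spacer = character(0), contig = character(0), start = integer(0),
             strand = character(0), mismatches = integer(0),
             site_seq = character(0), pam_seq = character(0),
             is_on_target = logical(0), stringsAsFactors = FALSE)
}

#' Scan one genome segment for off-target hits of one spacer
#'
#' Both strands are scanned: exact anchor occurrences generate candidate
#' protospacer windows, the adjacent PAM is checked on the side the editor
#' requires, and the full-spacer Hamming distance decides acceptance.
#' Windows running off the segment edge are skipped (junction segments
#' recover them). Genomic `N` counts as a mismatch and never satisfies a
#' PAM letter.
#'
#' @param segment One segment from [segment_genome()].
#' @param anchors An `anchor_set` from [build_anchors()].
#' @param model A `cbe_model` (supplies the PAM pattern and side).
#' @return A data.frame of hits with `start` in 1-based contig plus-strand
#'   coordinates (leftmost base of the protospacer span).
#' @export
scan_segment <- function(segment, anchors, model) {
  stopifnot(inherits(anchors, "anchor_set"), inherits(model, "cbe_model"))
  matcher <- iupac_to_matcher(model$pam_pattern)
  S <- toupper(segment$seq)
  ns <- nchar(S)
  L <- nchar(anchors$spacer)
  out <- list()
  fwd <- scan_strand(S, anchors, matcher, model$pam_side)
  if (nrow(fwd) > 0) {
    fwd$contig <- segment$contig
    fwd$start <- segment$seg_start + fwd$w
    fwd$strand <- "+"
    out[[1]] <- fwd
  }
  rev <- scan_strand(reverse_complement(S), anchors, matcher, model$pam_side)
  if (nrow(rev) > 0) {
    rev$contig <- segment$contig
    rev$start <- segment$seg_start + (ns - (rev$w + L - 1L) + 1L)
    rev$strand <- "-"
    out[[2]] <- rev
  }
  if (length(out) == 0L) return(empty_hits_df())
  hits <- do.call(rbind, out)
  hits$spacer <- anchors$spacer
  hits$is_on_target <- hits$mismatches == 0L
  hits <- hits[!duplicated(hits[, c("contig", "start", "strand")]), ,
               drop = FALSE]
  hits[, c("spacer", "contig", "start", "strand", "mismatches", "site_seq",
           "pam_seq", "is_on_target")]
}

#' Off-target search of spacers against a genome
#'
#' Runs the anchor search for every spacer over every genome segment (one
#' shared segmentation pass), deduplicates hits discovered by multiple
#' anchors or by both a tile and a junction segment, and returns the union
#' sorted by (spacer, contig, start).
#'
#' @param spacers Character vector of spacer sequences, a `design_report`,
#'   or a data.frame with a `spacer` column.
#' @param genome Genome input accepted by [segment_genome()].
#' @param model A `cbe_model`.
#' @param m Mismatch budget (inclusive: a hit has `mismatches <= m`).
#'   Values above 3 are allowed with a warning.
#' @param segment_size,flank Segmentation parameters, defaults 50 Mb / 100 nt.
#' @return A data.frame with columns `spacer`, `contig`, `start`, `strand`,
#'   `mismatches`, `site_seq`, `pam_seq`, `is_on_target`.
#' @export
offtarget_search <- function(spacers, genome, model, m = 3,
                             segment_size = 5e7, flank = 100) {
  if (inherits(spacers, "design_report")) spacers <- spacers$sites
  if (is.data.frame(spacers)) spacers <- spacers$spacer
  spacers <- unique(toupper(spacers))
  if (length(spacers) == 0L) stop("empty spacer list", call. = FALSE)
  m <- as.integer(m)
  if (m > 3L) {
    warning("mismatch budget m = ", m,
            " is above the typical range 0-3; the search may be slow",
            call. = FALSE)
  }
  segs <- segment_genome(genome, segment_size = segment_size, flank = flank)
  res <- list()
  for (sp in spacers) {
    anchors <- build_anchors(sp, m)
    for (seg in segs) {
      h <- scan_segment(seg, anchors, model)
      if (nrow(h) > 0) res[[length(res) + 1L]] <- h
    }
  }
  if (length(res) == 0L) return(empty_hits_df())
  hits <- do.call(rbind, res)
  hits <- hits[!duplicated(hits[, c("spacer", "contig", "start", "strand")]), ,
               drop = FALSE]
  hits <- hits[order(hits$spacer, hits$contig, hits$start, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
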