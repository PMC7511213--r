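# The core search: spacers whose in-window C->T edits (C->T on the spacer
# strand; equivalently G->A on the CDS sense strand for minus-strand
# spacers) convert a codon of the selected CDS into a premature stop codon.
#
# The search is general: it simulates the strand-aware edits and consults
# the active genetic code, rather than pattern-matching a fixed codon list.
# Under the standard code the qualifying codons come out as exactly
# {CAA, CAG, CGA, TGG}; that is an emergent, tested property.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# nonempty subsets of seq_len(k), ordered by (size, lexicographic), so the
# first qualifying subset is the minimal one with 5'-most tie-break
nonempty_subsets <- function(k) {
  sets <- list()
  for (size in seq_len(k)) {
    cmb <- utils::combn(k, size)
    for (j in seq_len(ncol(cmb))) sets[[length(sets) + 1L]] <- cmb[, j]
  }
  sets
}

#' Enumerate strand-aware C->T edits that convert a codon into a stop
#'
#' Considers every nonempty subset of eligible positions within the codon:
#' on the sense (+) strand the eligible bases are `C` (edited to `T`); on
#' the antisense (-) strand they are sense-strand `G` (edited to `A`,
#' because the antisense `C` pairing it is deaminated). Edits on the two
#' strands are never mixed, and a codon that is already a stop yields the
#' empty set (no new stop is created).
#'
#' @param codon A 3-letter codon over `{A,C,G,T}`.
#' @param code A `genetic_code`.
#' @return A list of records with fields `strand` (`"+"`/`"-"`), `offsets`
#'   (1-based positions within the codon, ascending), `stop` (the stop
#'   codon produced). Empty list if no conversion exists.
#' @examples
#' stop_creating_edits("CAA", load_genetic_code(1))
#' @export
stop_creating_edits <- function(codon, code = load_genetic_code(1)) {
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L)
  if (grepl("[^ACGT]", codon)) return(list())
  if (codon %in% code$stop_codons) return(list())
  bases <- strsplit(codon, "")[[1]]
  out <- list()
  for (strand in c("+", "-")) {
    target <- if (strand == "+") "C" else "G"
    repl <- if (strand == "+") "T" else "A"
    elig <- which(bases == target)
    if (length(elig) == 0L) next
    for (idx in nonempty_subsets(length(elig))) {
      edited <- bases
      edited[elig[idx]] <- repl
      new_codon <- paste(edited, collapse = "")
      if (new_codon %in% code$stop_codons) {
        out[[length(out) + 1L]] <- list(strand = strand,
                                        offsets = elig[idx],
                                        stop = new_codon)
      }
    }
  }
  out
}

#' Scan all 64 codons for stop-convertible ones
#'
#' @param code A `genetic_code`.
#' @return Character vector of codons with at least one stop-creating edit
#'   under [stop_creating_edits()], sorted.
#' @export
convertible_codons <- function(code = load_genetic_code(1)) {
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(codons[vapply(codons, function(cd) length(stop_creating_edits(cd, code)) > 0,
                     logical(1))])
}

# empty sites table with the full column set
empty_sites_df <- function() {
  data.frame(cds_id = character(0), cbe = character(0), strand = character(0),
             proto_start = integer(0), spacer = character(0), pam = character(0),
             window = character(0), codon_index = integer(0),
             codon_before = character(0), codon_after = character(0),
             edit_positions = character(0), context = character(0),
             context_rank = integer(0), cds_fraction = numeric(0),
             annotation = character(0), stringsAsFactors = FALSE)
}

#' Find all CBE-inactivation sites on a coding sequence
#'
#' Enumerates every placement, on both strands, where the protospacer and
#' its adjacent PAM lie fully within the CDS and the PAM matches the
#' editor's pattern, then asks whether some nonempty subset of in-window
#' C->T edits (strand-aware) converts a codon into a premature stop.
#' One site row is emitted per (placement, edited codon) pair;
#' `edit_positions` records the minimal qualifying subset (fewest edited
#' bases, ties broken by the 5'-most window position on the spacer strand).
#' A codon qualifies only if the stop-creating base itself is inside the
#' editing window; an edit recreating the natural terminator is not
#' premature and is not reported; placements containing `N` are skipped.
#'
#' @param cds A `nuc_sequence` (or character scalar) holding the CDS,
#'   sense strand, 5'->3'.
#' @param model A `cbe_model`.
#' @param code A `genetic_code`.
#' @param region_fraction Search-region percentage used for the in-region
#'   count (default 50: the first base of the edited codon must lie in the
#'   top 50% of the CDS body).
#' @return An object of class `design_report`: a list with `cds_id`, `cbe`,
#'   `n_sites_whole_cds`, `n_sites_in_region`, `region_fraction`, `sites`
#'   (data.frame, all sites on the whole CDS, sorted by `proto_start`),
#'   `strand_counts`, `position_bins` (site counts per decile of the CDS)
#'   and `short_input` (flag: CDS shorter than spacer + PAM).
#' @seealso [region_filter()], [stop_creating_edits()]
#' @export
find_cbei_sites <- function(cds, model, code = load_genetic_code(1),
                            region_fraction = 50) {
  if (is.character(cds)) cds <- nuc_sequence(cds)
  stopifnot(inherits(cds, "nuc_sequence"), inherits(model, "cbe_model"),
            inherits(code, "genetic_code"))
  if (region_fraction <= 0 || region_fraction > 100) {
    stop("region_fraction must be in (0, 100]", call. = FALSE)
  }
  n <- nchar(cds$seq)
  L <- model$spacer_len
  P <- nchar(model$pam_pattern)
  matcher <- iupac_to_matcher(model$pam_pattern)
  if (n < L + P) {
    rep <- new_design_report(cds$id, model, empty_sites_df(), n,
                             region_fraction, short_input = TRUE)
    return(rep)
  }
  if (n %% 3L != 0L) {
    warning("CDS '", cds$id, "' length ", n,
            " is not divisible by 3; trailing bases ignored for codon math",
            call. = FALSE)
  }
  n3 <- n - n %% 3L
  ncod <- n3 %/% 3L
  chv <- strsplit(cds$seq, "")[[1]]
  codon_starts <- seq.int(1L, n3 - 2L, by = 3L)
  codons <- substring(cds$seq, codon_starts, codon_starts + 2L)
  winpos <- window_positions(model)
  rc <- reverse_complement(cds$seq)

  rows <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") cds$seq else rc
    # overlapping PAM occurrences on the search strand
    hits <- gregexpr(paste0("(?=", matcher$regex, ")"), ss, perl = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (q in as.integer(hits)) {
      if (model$pam_side == "3prime") {
        s <- q - L
        if (s < 1L || q + P - 1L > n) next
      } else {
        s <- q + P
        if (s + L - 1L > n) next
      }
      spacer <- substr(ss, s, s + L - 1L)
      if (grepl("N", spacer, fixed = TRUE)) next
      pam_seq <- substr(ss, q, q + P - 1L)
      # map window positions to CDS sense coordinates
      wcoord <- s + winpos - 1L
      cdspos <- if (strand == "+") wcoord else n - wcoord + 1L
      target <- if (strand == "+") "C" else "G"
      ok <- cdspos <= n3 & chv[cdspos] == target
      if (!any(ok)) next
      elig_win <- winpos[ok]
      elig_cds <- cdspos[ok]
      kvec <- (elig_cds - 1L) %/% 3L + 1L
      for (k in unique(kvec)) {
        if (k >= ncod) next                       # natural terminator
        cb <- codons[k]
        if (grepl("N", cb, fixed = TRUE) || cb %in% code$stop_codons) next
        pos_k <- elig_win[kvec == k]              # ascending window coords
        cds_k <- elig_cds[kvec == k]
        off_k <- (cds_k - 1L) %% 3L + 1L
        found <- NULL
        for (idx in nonempty_subsets(length(pos_k))) {
          edited <- strsplit(cb, "")[[1]]
          edited[off_k[idx]] <- if (strand == "+") "T" else "A"
          new_codon <- paste(edited, collapse = "")
          if (new_codon %in% code$stop_codons) {
            found <- list(positions = pos_k[idx], stop = new_codon)
            break
          }
        }
        if (is.null(found)) next
        ctx <- site_context(chv, n, strand,
                            cds_pos = cds_k[match(found$positions[1], pos_k)],
                            context_order = model$context_order)
        proto_start <- if (strand == "+") s else n - (s + L - 1L) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          cds_id = cds$id, cbe = model$name, strand = strand,
          proto_start = proto_start, spacer = spacer, pam = pam_seq,
          window = paste0(model$window_start, "-", model$window_end),
          codon_index = k, codon_before = cb, codon_after = found$stop,
          edit_positions = paste(found$positions, collapse = ","),
          context = ctx$context, context_rank = ctx$rank,
          cds_fraction = (3 * (k - 1) + 1) / n,
          annotation = render_annotation(spacer, pam_seq, model,
                                         found$positions, cb, found$stop, k),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  sites <- if (length(rows) == 0L) empty_sites_df() else do.call(rbind, rows)
  sites <- sites[order(sites$proto_start, sites$strand, sites$codon_index), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  new_design_report(cds$id, model, sites, n, region_fraction)
}

# 5'-dinucleotide context of the stop-creating C on the edited strand
site_context <- function(chv, n, strand, cds_pos, context_order) {
  if (strand == "+") {
    if (cds_pos <= 1L) return(list(context = NA_character_, rank = NA_integer_))
    base5 <- chv[cds_pos - 1L]
  } else {
    if (cds_pos >= n) return(list(context = NA_character_, rank = NA_integer_))
    base5 <- unname(COMPLEMENT[chv[cds_pos + 1L]])
  }
  if (is.na(base5) || !base5 %in% c("A", "C", "G", "T")) {
    return(list(context = NA_character_, rank = NA_integer_))
  }
  ctx <- paste0(base5, "C")
  list(context = ctx, rank = match(ctx, context_order))
}

# plain-text rendering of the web tool's colored markup: {spacer} braces,
# [window] brackets, (C>T) parentheses for the stop-creating edits, PAM
# after a pipe, then the codon change
render_annotation <- function(spacer, pam, model, edit_positions, codon_before,
                              codon_after, codon_index) {
  ch <- strsplit(spacer, "")[[1]]
  repl <- if (any(ch[edit_positions] == "C")) ">T" else ">A"
  for (p in edit_positions) ch[p] <- paste0("(", ch[p], repl, ")")
  ch[model$window_start] <- paste0("[", ch[model$window_start])
  ch[model$window_end] <- paste0(ch[model$window_end], "]")
  body <- paste0("{", paste(ch, collapse = ""), "}")
  unit <- if (model$pam_side == "3prime") paste0(body, "|", pam) else paste0(pam, "|", body)
  paste0(unit, " ", codon_before, ">", codon_after, "@", codon_index)
}

new_design_report <- function(cds_id, model, sites, cds_len, region_fraction,
                              short_input = FALSE) {
  in_region <- sites$cds_fraction <= region_fraction / 100
  bins <- table(cut(sites$cds_fraction, breaks = seq(0, 1, 0.1),
                    include.lowest = TRUE))
  structure(
    list(cds_id = cds_id, cbe = model$name, cds_len = cds_len,
         n_sites_whole_cds = nrow(sites),
         n_sites_in_region = sum(in_region),
         region_fraction = region_fraction,
         sites = sites,
         strand_counts = c(plus = sum(sites$strand == "+"),
                           minus = sum(sites$strand == "-")),
         position_bins = as.integer(bins),
         short_input = short_input),
    class = "design_report"
  )
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> %s x %s: %d site(s) in whole CDS, %d in top %g%%\n",
              x$cds_id, x$cbe, x$n_sites_whole_cds, x$n_sites_in_region,
              x$region_fraction))
  if (x$short_input) cat("  (input shorter than spacer + PAM; nothing searched)\n")
  invisible(x)
}

#' Restrict a design report to a search region
#'
#' Keeps the sites whose edited (stop-creating) codon begins within the top
#' `region_fraction` percent of the CDS body and updates the in-region
#' count. The whole-CDS count is preserved.
#'
#' @param report A `design_report`.
#' @param region_fraction Percentage in `(0, 100]`.
#' @return A `design_report` whose `sites` are the filtered view.
#' @export
region_filter <- function(report, region_fraction) {
  stopifnot(inherits(report, "design_report"))
  if (region_fraction <= 0 || region_fraction > 100) {
    stop("region_fraction must be in (0, 100]", call. = FALSE)
  }
  keep <- report$sites$cds_fraction <= region_fraction / 100
  out <- report
  out$sites <- report$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$region_fraction <- region_fraction
  out$n_sites_in_region <- sum(keep)
  out$strand_counts <- c(plus = sum(out$sites$strand == "+"),
                         minus = sum(out$sites$strand == "-"))
  out
}

#' Recompute the sequence-context annotation of a site
#'
#' The context is the base 5' of the stop-creating C on the edited strand
#' plus the C itself (`TC`, `CC`, `AC` or `GC`), ranked by the editor's
#' preference order (default `TC > CC > AC > GC`). A stop-creating C at the
#' CDS terminus has no 5' base within the sequence; its context is `NA`.
#'
#' @param site A one-row data.frame (a row of `design_report$sites`).
#' @param cds The `nuc_sequence` the site was found on.
#' @param model The `cbe_model` used.
#' @return The site row with `context` and `context_rank` refreshed.
#' @export
annotate_context <- function(site, cds, model) {
  if (is.character(cds)) cds <- nuc_sequence(cds)
  chv <- strsplit(cds$seq, "")[[1]]
  n <- nchar(cds$seq)
  first_edit <- as.integer(strsplit(site$edit_positions, ",")[[1]][1])
  L <- model$spacer_len
  # spacer-strand window position -> CDS sense coordinate
  if (site$strand == "+") {
    cds_pos <- site$proto_start + first_edit - 1L
  } else {
    s_rc <- n - (site$proto_start + L - 1L) + 1L   # spacer start on rc coords
    cds_pos <- n - (s_rc + first_edit - 1L) + 1L
  }
  ctx <- site_context(chv, n, site$strand, cds_pos, model$context_order)
  site$context <- ctx$context
  site$context_rank <- ctx$rank
  site
}
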