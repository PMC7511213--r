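# Synthetic CDSs and genomes with planted, known ground truth, so every
# module is testable without downloading real data. Generation is fully
# reproducible from the spec's seed, and every planted feature's expected
# detection outcome is returned in a ledger alongside the sequences.

utils::globalVariables(c("fraction", "ability", "cbe"))

#' Specification for a synthetic CDS set
#'
#' @param seed Integer RNG seed (mandatory; no hidden global randomness).
#' @param n_cds Number of CDSs to generate.
#' @param length_range Two-element nt range; lengths are drawn uniformly and
#'   rounded to multiples of 3 (minimum 30 nt).
#' @param gc Target GC fraction of the background (positions are drawn
#'   i.i.d. with `P(G) = P(C) = gc/2`).
#' @param plants List of plant descriptors from [plant_cbei_site()].
#' @param at_head_fraction If non-`NULL`, the codons whose first base lies
#'   within this 5' fraction of each CDS are drawn from A/T-only non-stop
#'   codons. Such a head contains no editable C or G, so by construction no
#'   premature stop can be created there (plants placed inside the head
#'   overwrite it).
#' @return An object of class `cds_fixture_spec`.
#' @export
cds_fixture_spec <- function(seed, n_cds = 10, length_range = c(300, 900),
                             gc = 0.5, plants = list(),
                             at_head_fraction = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (min(length_range) < 30) stop("length_range must be >= 30 nt", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_cds = as.integer(n_cds),
         length_range = as.integer(length_range), gc = gc,
         plants = plants, at_head_fraction = at_head_fraction),
    class = "cds_fixture_spec"
  )
}

#' Describe a CBE site to plant into a synthetic CDS
#'
#' The plant writes a protospacer + PAM cassette into the CDS so that the
#' `C` of a stop-convertible codon (default `CAA`) sits at a chosen editing
#' window position of a spacer with a valid concrete PAM; the expected
#' design outcome (a site converting the codon to a stop) is recorded in
#' the ledger.
#'
#' @param cds Index of the CDS (1-based) to plant into.
#' @param model A `cbe_model` or preset name; default `"BE3"`.
#' @param codon The sense-strand codon to plant: `"CAA"`, `"CAG"` or
#'   `"CGA"` (offset-1 C codons).
#' @param window_pos Window position for the stop-creating C; default the
#'   middle of the editor's window. Must leave the whole codon inside the
#'   spacer (`window_pos + 2 <= spacer_len`).
#' @param at_fraction Approximate CDS fraction where the edited codon is
#'   placed (default 0.25).
#' @return A plant descriptor list.
#' @export
plant_cbei_site <- function(cds = 1, model = "BE3", codon = "CAA",
                            window_pos = NULL, at_fraction = 0.25) {
  codon <- toupper(codon)
  if (!codon %in% c("CAA", "CAG", "CGA")) {
    stop("plantable codons are CAA, CAG, CGA (sense-strand offset-1 C)",
         call. = FALSE)
  }
  list(cds = as.integer(cds), model = model, codon = codon,
       window_pos = window_pos, at_fraction = at_fraction)
}

AT_CODONS <- c("AAA", "AAT", "ATA", "ATT", "TAA", "TAG", "TAT", "TGA",
               "TTA", "TTT")  # filtered against the active code's stops below

random_codons <- function(k, gc, code) {
  if (k <= 0L) return(character(0))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- character(k)
  i <- 1L
  while (i <= k) {
    cd <- paste(sample(names(p), 3L, replace = TRUE, prob = p), collapse = "")
    if (cd %in% code$stop_codons) next
    out[i] <- cd
    i <- i + 1L
  }
  out
}

# first concrete expansion of an IUPAC pattern (A-first), or a random one
concrete_pam <- function(pattern, random = FALSE) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  vapply(letters, function(l) {
    opts <- strsplit(IUPAC_CLASSES[[l]], "")[[1]]
    if (random) sample(opts, 1L) else opts[1L]
  }, character(1)) |> paste(collapse = "")
}

# a concrete string of the PAM's width that fails the pattern (for
# invalid-PAM plants); NULL if the pattern accepts everything
invalid_pam <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  for (i in seq_along(letters)) {
    opts <- strsplit(IUPAC_CLASSES[[letters[i]]], "")[[1]]
    out <- setdiff(c("A", "C", "G", "T"), opts)
    if (length(out) > 0) {
      res <- vapply(letters, function(l) strsplit(IUPAC_CLASSES[[l]], "")[[1]][1],
                    character(1))
      res[i] <- out[1]
      return(paste(res, collapse = ""))
    }
  }
  NULL
}

#' Generate a synthetic CDS set with planted CBE sites
#'
#' Every CDS starts with `ATG`, ends with a stop codon of the active code,
#' and contains no internal in-frame stop. Plants overwrite codon-aligned
#' cassettes (random non-stop filler, the planted codon, and a concrete
#' valid PAM); filler bases are re-rolled if fixing the PAM would create an
#' in-frame stop.
#'
#' @param spec A `cds_fixture_spec`.
#' @param code A `genetic_code`.
#' @return A list with `records` (list of `nuc_sequence`) and `ledger`
#'   (data.frame: one row per plant with the expected design outcome).
#' @export
make_cds <- function(spec, code = load_genetic_code(1)) {
  stopifnot(inherits(spec, "cds_fixture_spec"))
  set.seed(spec$seed)
  at_pool <- setdiff(AT_CODONS, code$stop_codons)
  if (!"ATG" %in% code$start_codons) {
    stop("fixture generator requires a code with ATG as a start codon",
         call. = FALSE)
  }
  records <- vector("list", spec$n_cds)
  ledger <- list()
  for (i in seq_len(spec$n_cds)) {
    len <- sample(seq(spec$length_range[1], spec$length_range[2]), 1L)
    len <- (len %/% 3L) * 3L
    ncod <- len %/% 3L
    codons <- c("ATG", random_codons(ncod - 2L, spec$gc, code),
                sample(code$stop_codons, 1L))
    if (!is.null(spec$at_head_fraction)) {
      # codon k starts at base 3(k-1)+1; force A/T codons over the head
      k_max <- min(ncod - 1L, floor((spec$at_head_fraction * len - 1) / 3) + 1L)
      if (k_max >= 2L) {
        codons[2:k_max] <- sample(at_pool, k_max - 1L, replace = TRUE)
      }
    }
    for (pl in spec$plants) {
      if (pl$cds != i) next
      planted <- apply_cds_plant(codons, len, pl, code)
      codons <- planted$codons
      ledger[[length(ledger) + 1L]] <- data.frame(
        cds_id = sprintf("syncds_%03d", i), kind = "cbei_site",
        model = planted$model_name, codon_index = planted$codon_index,
        codon_before = pl$codon, expected_stop = planted$expected_stop,
        window_pos = planted$window_pos,
        proto_start = planted$proto_start,
        cds_fraction = (3 * (planted$codon_index - 1) + 1) / len,
        stringsAsFactors = FALSE)
    }
    records[[i]] <- nuc_sequence(paste(codons, collapse = ""),
                                 id = sprintf("syncds_%03d", i),
                                 description = "synthetic CDS")
  }
  ledger <- if (length(ledger) == 0L) {
    data.frame(cds_id = character(0), kind = character(0), model = character(0),
               codon_index = integer(0), codon_before = character(0),
               expected_stop = character(0), window_pos = integer(0),
               proto_start = integer(0), cds_fraction = numeric(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, ledger)
  list(records = records, ledger = ledger)
}

# overwrite a codon-aligned cassette so `pl$codon`'s C sits at window
# position `wp` of a spacer with a valid concrete PAM
apply_cds_plant <- function(codons, len, pl, code) {
  model <- if (inherits(pl$model, "cbe_model")) pl$model else load_preset(pl$model)
  L <- model$spacer_len
  P <- nchar(model$pam_pattern)
  ncod <- length(codons)
  wp <- pl$window_pos
  if (is.null(wp)) {
    wp <- min(floor((model$window_start + model$window_end) / 2), L - 2L)
  }
  if (wp < model$window_start || wp > model$window_end) {
    stop("infeasible plant: window position ", wp, " outside editing window ",
         model$window_start, "-", model$window_end, call. = FALSE)
  }
  if (wp + 2L > L) {
    stop("infeasible plant: codon at window position ", wp,
         " would extend beyond the ", L, "-nt spacer", call. = FALSE)
  }
  # choose the edited codon index near the requested fraction, then derive
  # the spacer start so the codon's C lands on window position wp with the
  # codon grid respected (spacer start s: C at s + wp - 1 = 3(k-1)+1)
  k <- max(3L, min(ncod - 2L, round(pl$at_fraction * ncod)))
  placed <- FALSE
  for (k_try in unique(pmax(3L, pmin(ncod - 2L, k + 0:20)))) {
    c0 <- 3L * (k_try - 1L) + 1L
    s <- c0 - wp + 1L
    unit_a <- if (model$pam_side == "3prime") s else s - P
    unit_b <- if (model$pam_side == "3prime") s + L + P - 1L else s + L - 1L
    if (unit_a >= 4L && unit_b <= len - 3L) {
      k <- k_try
      placed <- TRUE
      break
    }
  }
  if (!placed) stop("infeasible plant: cassette does not fit in the CDS",
                    call. = FALSE)
  c0 <- 3L * (k - 1L) + 1L
  s <- c0 - wp + 1L
  unit_a <- if (model$pam_side == "3prime") s else s - P
  unit_b <- if (model$pam_side == "3prime") s + L + P - 1L else s + L - 1L
  ka <- (unit_a - 1L) %/% 3L + 1L
  kb <- (unit_b - 1L) %/% 3L + 1L

  for (attempt in 1:25) {
    filler <- random_codons(kb - ka + 1L, 0.5, code)
    seqv <- strsplit(paste(codons, collapse = ""), "")[[1]]
    seqv[(3L * (ka - 1L) + 1L):(3L * kb)] <- strsplit(paste(filler, collapse = ""), "")[[1]]
    seqv[c0:(c0 + 2L)] <- strsplit(pl$codon, "")[[1]]
    pam <- concrete_pam(model$pam_pattern, random = attempt > 1)
    pam_at <- if (model$pam_side == "3prime") s + L else s - P
    seqv[pam_at:(pam_at + P - 1L)] <- strsplit(pam, "")[[1]]
    new_codons <- codons
    for (kk in ka:kb) {
      new_codons[kk] <- paste(seqv[(3L * (kk - 1L) + 1L):(3L * kk)], collapse = "")
    }
    if (!any(new_codons[ka:kb] %in% code$stop_codons)) {
      edits <- stop_creating_edits(pl$codon, code)
      plus_edits <- Filter(function(e) e$strand == "+" && 1L %in% e$offsets, edits)
      if (length(plus_edits) == 0L) {
        stop("infeasible plant: ", pl$codon,
             " has no sense-strand stop-creating edit under this code",
             call. = FALSE)
      }
      return(list(codons = new_codons, codon_index = k, window_pos = wp,
                  proto_start = s, model_name = model$name,
                  expected_stop = plus_edits[[1]]$stop))
    }
  }
  stop("infeasible plant: could not fill cassette without creating a stop",
       call. = FALSE)
}

#' Specification for a synthetic genome with planted off-target loci
#'
#' @param seed Integer RNG seed.
#' @param contig_lengths Integer vector of contig lengths (bases).
#' @param gc Background GC fraction.
#' @param plants List of descriptors from [plant_offtarget()].
#' @param scrub_mismatch Background windows within this Hamming distance of
#'   any planted spacer next to a valid PAM are mutated away before
#'   planting, so the planted loci are the only hits and expected counts
#'   are exact (default 3).
#' @param scrub_spacers Additional spacer sequences (not planted) whose
#'   accidental near-matches are scrubbed from the background as well.
#' @return An object of class `genome_fixture_spec`.
#' @export
genome_fixture_spec <- function(seed, contig_lengths = 1e4, gc = 0.5,
                                plants = list(), scrub_mismatch = 3,
                                scrub_spacers = character(0)) {
  structure(
    list(seed = as.integer(seed), contig_lengths = as.integer(contig_lengths),
         gc = gc, plants = plants, scrub_mismatch = as.integer(scrub_mismatch),
         scrub_spacers = toupper(scrub_spacers)),
    class = "genome_fixture_spec"
  )
}

#' Describe an off-target locus to plant into a synthetic genome
#'
#' @param spacer The spacer sequence whose (mutated) copy is planted.
#' @param contig Contig index (1-based).
#' @param pos 1-based plus-strand position of the protospacer's leftmost
#'   base, or `NULL` for a random non-colliding position.
#' @param strand `"+"` or `"-"`.
#' @param dist Hamming distance of the planted copy from the spacer.
#' @param mut_positions Optional explicit positions (1-based on the spacer)
#'   to mutate; default: evenly spread positions.
#' @param pam_valid Plant a valid (`TRUE`) or pattern-violating (`FALSE`)
#'   PAM next to the copy.
#' @return A plant descriptor list.
#' @export
plant_offtarget <- function(spacer, contig = 1, pos = NULL, strand = "+",
                            dist = 0, mut_positions = NULL, pam_valid = TRUE) {
  spacer <- toupper(spacer)
  if (dist > nchar(spacer)) {
    stop("planted distance exceeds the spacer length", call. = FALSE)
  }
  list(spacer = spacer, contig = as.integer(contig), pos = pos,
       strand = strand, dist = as.integer(dist),
       mut_positions = mut_positions, pam_valid = isTRUE(pam_valid))
}

# mismatch profile of spacer against every window of gseq (one strand)
mismatch_profile <- function(gseq, spacer) {
  g <- utf8ToInt(gseq)
  sp <- utf8ToInt(spacer)
  L <- length(sp)
  nwin <- length(g) - L + 1L
  if (nwin < 1L) return(integer(0))
  mm <- integer(nwin)
  for (j in seq_len(L)) mm <- mm + (g[j:(j + nwin - 1L)] != sp[j])
  mm
}

other_base <- function(b) {
  setdiff(c("A", "C", "G", "T"), b)[1]
}

# mutate background windows that are accidental near-matches of any plant
# spacer (distance <= scrub_mismatch with a valid PAM on either strand)
scrub_background <- function(contig_seq, spacers, model, max_mm) {
  matcher <- iupac_to_matcher(model$pam_pattern)
  P <- matcher$width
  for (iter in 1:50) {
    dirty <- FALSE
    for (sp in spacers) {
      L <- nchar(sp)
      for (strand in c("+", "-")) {
        S <- if (strand == "+") contig_seq else reverse_complement(contig_seq)
        mm <- mismatch_profile(S, sp)
        hits <- which(mm <= max_mm)
        for (w in hits) {
          pa <- if (model$pam_side == "3prime") w + L else w - P
          if (pa < 1L || pa + P - 1L > nchar(S)) next
          if (!pam_matches(matcher, substr(S, pa, pa + P - 1L))) next
          # break the match: flip the first agreeing window base
          ch <- strsplit(substr(S, w, w + L - 1L), "")[[1]]
          spch <- strsplit(sp, "")[[1]]
          j <- which(ch == spch)[1]
          if (is.na(j)) j <- 1L
          pos_S <- w + j - 1L
          if (strand == "+") {
            substr(contig_seq, pos_S, pos_S) <- other_base(substr(S, pos_S, pos_S))
          } else {
            pos_plus <- nchar(contig_seq) - pos_S + 1L
            cur <- substr(contig_seq, pos_plus, pos_plus)
            substr(contig_seq, pos_plus, pos_plus) <- other_base(cur)
          }
          dirty <- TRUE
        }
      }
    }
    if (!dirty) return(contig_seq)
  }
  stop("could not scrub background of accidental near-matches", call. = FALSE)
}

#' Generate a synthetic genome with planted off-target loci
#'
#' The background is i.i.d. random sequence at the target GC; before
#' planting it is scrubbed of accidental windows within `scrub_mismatch`
#' of any planted spacer adjacent to a valid PAM, so the ledger's expected
#' hits are exact. Plants are placed at the requested positions (or at
#' random non-overlapping positions) with the requested number of
#' substitutions and a valid or invalid PAM, on either strand.
#'
#' @param spec A `genome_fixture_spec`.
#' @param model A `cbe_model` supplying the PAM pattern and side.
#' @return A list with `records` (list of `nuc_sequence` contigs) and
#'   `ledger` (data.frame: one row per plant with `contig`, `start`
#'   (1-based plus-strand position of the protospacer), `strand`, `dist`,
#'   `pam_valid`, `site_seq`, `pam_seq`).
#' @export
make_genome <- function(spec, model) {
  stopifnot(inherits(spec, "genome_fixture_spec"), inherits(model, "cbe_model"))
  set.seed(spec$seed)
  p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2,
         T = (1 - spec$gc) / 2)
  contigs <- lapply(spec$contig_lengths, function(nc) {
    paste(sample(names(p), nc, replace = TRUE, prob = p), collapse = "")
  })
  names(contigs) <- sprintf("synctg_%02d", seq_along(contigs))
  spacers <- unique(c(vapply(spec$plants, function(x) x$spacer, character(1)),
                      spec$scrub_spacers))
  if (length(spacers) > 0) {
    for (ci in seq_along(contigs)) {
      contigs[[ci]] <- scrub_background(contigs[[ci]], spacers, model,
                                        spec$scrub_mismatch)
    }
  }
  P <- nchar(model$pam_pattern)
  ledger <- list()
  occupied <- lapply(seq_along(contigs), function(i) integer(0))
  for (pl in spec$plants) {
    L <- nchar(pl$spacer)
    unit_len <- L + P
    nc <- nchar(contigs[[pl$contig]])
    site <- mutate_spacer(pl)
    pam <- if (pl$pam_valid) concrete_pam(model$pam_pattern) else {
      iv <- invalid_pam(model$pam_pattern)
      if (is.null(iv)) stop("PAM pattern accepts every string; cannot plant an invalid PAM",
                            call. = FALSE)
      iv
    }
    unit <- if (model$pam_side == "3prime") paste0(site, pam) else paste0(pam, site)
    if (pl$strand == "-") unit <- reverse_complement(unit)
    pos <- pl$pos   # 1-based position of the protospacer's leftmost base
    for (try in 1:100) {
      if (is.null(pl$pos)) pos <- sample(seq(P + 2L, nc - unit_len - P - 1L), 1L)
      # leftmost base of the whole unit on the plus strand
      ua <- if ((model$pam_side == "3prime") == (pl$strand == "+")) pos else pos - P
      if (ua < 1L || ua + unit_len - 1L > nc) {
        if (is.null(pl$pos)) next
        stop("plant position out of contig bounds", call. = FALSE)
      }
      span <- ua:(ua + unit_len - 1L)
      if (length(intersect(span, occupied[[pl$contig]])) > 0) {
        if (is.null(pl$pos)) next
        stop("collision between plants", call. = FALSE)
      }
      occupied[[pl$contig]] <- c(occupied[[pl$contig]], span)
      substr(contigs[[pl$contig]], ua, ua + unit_len - 1L) <- unit
      break
    }
    ledger[[length(ledger) + 1L]] <- data.frame(
      spacer = pl$spacer, contig = names(contigs)[pl$contig], start = pos,
      strand = pl$strand, dist = pl$dist, pam_valid = pl$pam_valid,
      site_seq = site, pam_seq = pam, stringsAsFactors = FALSE)
  }
  records <- lapply(seq_along(contigs), function(i) {
    nuc_sequence(contigs[[i]], id = names(contigs)[i],
                 description = "synthetic genome contig")
  })
  ledger <- if (length(ledger) == 0L) {
    data.frame(spacer = character(0), contig = character(0), start = integer(0),
               strand = character(0), dist = integer(0), pam_valid = logical(0),
               site_seq = character(0), pam_seq = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, ledger)
  list(records = records, ledger = ledger)
}

# a copy of the spacer with `dist` substitutions at the requested or
# evenly spread positions
mutate_spacer <- function(pl) {
  ch <- strsplit(pl$spacer, "")[[1]]
  if (pl$dist == 0L) return(pl$spacer)
  pos <- pl$mut_positions
  if (is.null(pos)) {
    pos <- unique(round(seq(2, length(ch) - 1, length.out = pl$dist)))
    while (length(pos) < pl$dist) {
      extra <- setdiff(seq_along(ch), pos)[1]
      pos <- c(pos, extra)
    }
  }
  if (length(pos) != pl$dist) {
    stop("mut_positions must have length dist", call. = FALSE)
  }
  for (j in pos) ch[j] <- other_base(ch[j])
  paste(ch, collapse = "")
}
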