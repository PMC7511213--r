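# Independent brute-force oracles used to verify the package's search
# algorithms. These deliberately share no code with the implementation:
# plain enumeration, naive per-position checks, and full re-translation.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# naive per-position IUPAC check of a concrete string against a pattern
oracle_iupac_match <- function(pattern, s) {
  if (nchar(pattern) != nchar(s)) return(FALSE)
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  all(vapply(seq_along(pc), function(i) sc[i] %in% ORACLE_IUPAC[[pc[i]]],
             logical(1)))
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# ---- ORF oracle: enumerate every start codon on all 6 frames and walk to
# the next in-frame stop; keep the 5'-most start per (frame, stop) --------

oracle_orfs <- function(seqstr, code, min_len) {
  n <- nchar(seqstr)
  rows <- list()
  for (strand in c("+", "-")) {
    work <- if (strand == "+") seqstr else oracle_revcomp(seqstr)
    for (f in 1:3) {
      ncod <- (n - f + 1) %/% 3
      if (ncod < 1) next
      at <- seq(f, by = 3, length.out = ncod)
      codons <- substring(work, at, at + 2)
      start_is <- which(codons %in% code$start_codons & !grepl("N", codons))
      stop_is <- which(codons %in% code$stop_codons & !grepl("N", codons))
      if (length(stop_is) == 0 || length(start_is) == 0) next
      found <- list()   # stop index -> earliest start index
      for (a in start_is) {
        # smallest in-frame stop at or after the start codon
        pos <- findInterval(a - 0.5, stop_is) + 1
        if (pos > length(stop_is)) next
        s_i <- stop_is[pos]
        key <- as.character(s_i)
        if (is.null(found[[key]]) || a < found[[key]]) found[[key]] <- a
      }
      for (key in names(found)) {
        a <- found[[key]]
        s_i <- as.integer(key)
        len <- (s_i - a + 1) * 3
        if (len < min_len) next
        ws <- at[a]; we <- at[s_i] + 2
        rows[[length(rows) + 1]] <- data.frame(
          frame = if (strand == "+") f else -f,
          strand = strand,
          start = if (strand == "+") ws else n - ws + 1,
          end = if (strand == "+") we else n - we + 1,
          length_nt = len,
          cds_seq = substr(work, ws, we),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(frame = integer(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      length_nt = integer(0), cds_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$strand, df$start), ]
  rownames(df) <- NULL
  df
}

# ---- design oracle: every placement x strand x in-window edit subset,
# re-translate the edited CDS, detect the new premature stop --------------

oracle_design_sites <- function(seqstr, model, code) {
  n <- nchar(seqstr)
  L <- model$spacer_len
  P <- nchar(model$pam_pattern)
  n3 <- n - n %% 3
  ncod <- n3 %/% 3
  win <- model$window_start:model$window_end
  chv <- strsplit(seqstr, "")[[1]]
  orig_aa <- vapply(seq_len(ncod), function(k) {
    code$codon_to_aa[[paste(chv[(3 * k - 2):(3 * k)], collapse = "")]]
  }, character(1))
  rows <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") seqstr else oracle_revcomp(seqstr)
    for (s in seq_len(n)) {
      if (s + L - 1 > n) next
      if (model$pam_side == "3prime") { pa <- s + L; pb <- s + L + P - 1 }
      else { pa <- s - P; pb <- s - 1 }
      if (pa < 1 || pb > n) next
      if (!oracle_iupac_match(model$pam_pattern, substr(ss, pa, pb))) next
      spacer <- substr(ss, s, s + L - 1)
      if (grepl("N", spacer, fixed = TRUE)) next
      # sense coordinates of the window positions
      sense_pos <- if (strand == "+") s + win - 1 else n - (s + win - 1) + 1
      editable <- if (strand == "+") chv[sense_pos] == "C" else chv[sense_pos] == "G"
      for (k in seq_len(ncod - 1)) {
        in_codon <- which(editable & (sense_pos - 1) %/% 3 + 1 == k)
        if (length(in_codon) == 0) next
        if (orig_aa[k] == "*") next
        hit <- NULL
        # subsets ordered by size then ascending window position
        for (size in seq_along(in_codon)) {
          cmb <- combn(seq_along(in_codon), size)
          for (j in seq_len(ncol(cmb))) {
            sel <- in_codon[cmb[, j]]
            edited <- chv
            edited[sense_pos[sel]] <- if (strand == "+") "T" else "A"
            new_codon <- paste(edited[(3 * k - 2):(3 * k)], collapse = "")
            if (code$codon_to_aa[[new_codon]] == "*") {
              hit <- list(positions = win[sel], stop = new_codon)
              break
            }
          }
          if (!is.null(hit)) break
        }
        if (is.null(hit)) next
        rows[[length(rows) + 1]] <- data.frame(
          strand = strand,
          proto_start = if (strand == "+") s else n - (s + L - 1) + 1,
          codon_index = k,
          codon_before = paste(chv[(3 * k - 2):(3 * k)], collapse = ""),
          codon_after = hit$stop,
          edit_positions = paste(hit$positions, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(strand = character(0), proto_start = integer(0),
                      codon_index = integer(0), codon_before = character(0),
                      codon_after = character(0), edit_positions = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df[order(df$strand, df$proto_start, df$codon_index), ]
}

# sort + key columns for comparing implementation vs design oracle
design_key <- function(df) {
  key <- df[, c("strand", "proto_start", "codon_index", "codon_before",
                "codon_after", "edit_positions")]
  key <- key[order(key$strand, key$proto_start, key$codon_index), ]
  rownames(key) <- NULL
  key
}

# ---- off-target oracle: naive sliding-window Hamming scan with PAM check

oracle_offtarget <- function(contigs, spacer, model, m) {
  L <- nchar(spacer)
  P <- nchar(model$pam_pattern)
  sp_int <- utf8ToInt(spacer)
  rows <- list()
  for (nm in names(contigs)) {
    cs <- contigs[[nm]]
    nc <- nchar(cs)
    for (strand in c("+", "-")) {
      S <- if (strand == "+") cs else oracle_revcomp(cs)
      g <- utf8ToInt(S)
      nwin <- nc - L + 1
      if (nwin < 1) next
      mm <- integer(nwin)
      for (j in seq_len(L)) mm <- mm + (g[j:(j + nwin - 1)] != sp_int[j])
      for (w in which(mm <= m)) {
        if (model$pam_side == "3prime") { pa <- w + L; pb <- w + L + P - 1 }
        else { pa <- w - P; pb <- w - 1 }
        if (pa < 1 || pb > nc) next
        if (!oracle_iupac_match(model$pam_pattern, substr(S, pa, pb))) next
        rows[[length(rows) + 1]] <- data.frame(
          spacer = spacer, contig = nm,
          start = if (strand == "+") w else nc - (w + L - 1) + 1,
          strand = strand, mismatches = mm[w],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(spacer = character(0), contig = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$spacer, df$contig, df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

hit_key <- function(df) {
  key <- df[, c("spacer", "contig", "start", "strand", "mismatches")]
  key <- key[order(key$spacer, key$contig, key$start, key$strand), ]
  rownames(key) <- NULL
  key
}
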