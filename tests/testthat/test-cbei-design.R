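code1 <- load_genetic_code(1)
be3 <- load_preset("BE3")

# 60-nt toy CDS built codon by codon: a single CAA whose C sits at window
# position 5 of the unique NGG-adjacent 20-nt protospacer starting at base 9
toy60 <- paste0("ATG", "AAT", "ATT",        # A/T-only head
                "TAT", "CAA", "ATT", "TTT", "AAT", "TTA",
                "AAG", "GAT",               # provides the only GG (PAM AGG at 29-31)
                "AAT", "ATT", "TTA", "TAT", "AAA", "TTT", "ATA", "AAT",
                "TAA")

test_that("stop_creating_edits enumerates strand-aware conversions", {
  caa <- stop_creating_edits("CAA", code1)
  expect_length(caa, 1)
  expect_equal(caa[[1]]$strand, "+")
  expect_equal(caa[[1]]$offsets, 1L)
  expect_equal(caa[[1]]$stop, "TAA")

  expect_length(stop_creating_edits("AAA", code1), 0)

  # TGG is edited through the antisense strand: sense G->A
  tgg <- stop_creating_edits("TGG", code1)
  expect_true(all(vapply(tgg, function(e) e$strand == "-", logical(1))))
  expect_setequal(vapply(tgg, function(e) e$stop, character(1)),
                  c("TAG", "TGA", "TAA"))

  # a codon that is already a stop creates nothing new
  expect_length(stop_creating_edits("TGA", code1), 0)
})

test_that("exactly four codon types are stop-convertible under the standard code", {
  expect_equal(convertible_codons(code1), c("CAA", "CAG", "CGA", "TGG"))
  # under the ciliate nuclear code (TAA/TAG recoded to Gln) the set differs,
  # and the search path derives it rather than assuming the standard four
  code6 <- load_genetic_code(6)
  conv6 <- convertible_codons(code6)
  expect_false(setequal(conv6, c("CAA", "CAG", "CGA", "TGG")))
  expect_true(all(c("CGA", "TGG") %in% conv6))   # TGA is still a stop there
})

test_that("the toy CDS yields exactly one site with the planted properties", {
  rep <- find_cbei_sites(toy60, be3, code1)
  expect_equal(rep$n_sites_whole_cds, 1)
  s <- rep$sites
  expect_equal(s$strand, "+")
  expect_equal(s$proto_start, 9L)
  expect_equal(s$codon_before, "CAA")
  expect_equal(s$codon_after, "TAA")
  expect_equal(s$edit_positions, "5")
  expect_equal(s$codon_index, 5L)
  expect_equal(s$pam, "AGG")
  expect_equal(s$context, "TC")      # base 5' of the edited C is T
  expect_equal(s$context_rank, 1L)
  expect_equal(s$cds_fraction, 13 / 60)
  # and the brute-force enumerator agrees
  expect_equal(design_key(s), design_key(oracle_design_sites(toy60, be3, code1)))
})

test_that("no PAM match means no sites; short input sets the warning flag", {
  atonly <- paste0("ATG", strrep("AAT", 17), "TAA")
  rep <- find_cbei_sites(atonly, load_preset("VRER-BE3"), code1)
  expect_equal(rep$n_sites_whole_cds, 0)

  short <- find_cbei_sites("ATGCAATAA", be3, code1)
  expect_true(short$short_input)
  expect_equal(short$n_sites_whole_cds, 0)
})

test_that("an edit recreating the natural terminator is not reported", {
  m <- cbe_model("tiny5p", "TTT", "5prime", spacer_len = 9,
                 window_start = 1, window_end = 9)
  cds <- paste0("ATG", "AAA", "TTT", "AAA", "ATT", "ATA", "TTT",
                "CAA", "ATA", "CAA")   # codon 10 (CAA) is the final codon
  rep <- suppressWarnings(find_cbei_sites(cds, m, code1))
  expect_equal(rep$sites$codon_index, 8L)   # only the internal CAA qualifies
  expect_equal(rep$n_sites_whole_cds, 1)
})

test_that("placements containing N are skipped silently", {
  with_n <- paste0("ATG", "AAT", "ATT",
                   "TAT", "CNA", "ATT", "TTT", "AAT", "TTA",
                   "AAG", "GAT",
                   "AAT", "ATT", "TTA", "TAT", "AAA", "TTT", "ATA", "AAT",
                   "TAA")
  expect_silent(rep <- find_cbei_sites(with_n, be3, code1))
  expect_equal(rep$n_sites_whole_cds, 0)
})

test_that("find_cbei_sites equals the brute-force enumerator on random CDSs", {
  set.seed(404)
  models <- list(be3, load_preset("Target-AID"), load_preset("Cas12a-BE"))
  for (i in 1:8) {
    n <- sample(seq(150, 600, 3), 1)
    cds <- random_dna(n, gc = runif(1, 0.35, 0.65))
    model <- models[[1 + (i %% length(models))]]
    got <- find_cbei_sites(cds, model, code1)$sites
    want <- oracle_design_sites(cds, model, code1)
    expect_equal(design_key(got), design_key(want),
                 info = sprintf("rep %d model %s", i, model$name))
  }
})

test_that("replaying each recorded edit reproduces the stop codon", {
  set.seed(505)
  cds <- random_dna(900)
  sites <- find_cbei_sites(cds, be3, code1)$sites
  expect_gt(nrow(sites), 0)
  chv <- strsplit(cds, "")[[1]]
  L <- be3$spacer_len
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    pos <- as.integer(strsplit(s$edit_positions, ",")[[1]])
    cds_pos <- if (s$strand == "+") s$proto_start + pos - 1 else
      s$proto_start + L - pos
    edited <- chv
    expect_true(all(edited[cds_pos] == if (s$strand == "+") "C" else "G"))
    edited[cds_pos] <- if (s$strand == "+") "T" else "A"
    k <- s$codon_index
    new_codon <- paste(edited[(3 * k - 2):(3 * k)], collapse = "")
    expect_equal(new_codon, s$codon_after)
    expect_true(new_codon %in% code1$stop_codons)
    expect_false(s$codon_before %in% code1$stop_codons)
    expect_lt(k, nchar(cds) / 3)
  }
})

test_that("reported codon_before values stay within the convertible set", {
  set.seed(606)
  seen <- character(0)
  for (i in 1:20) {
    cds <- random_dna(600)
    seen <- c(seen, find_cbei_sites(cds, be3, code1)$sites$codon_before)
  }
  expect_gt(length(seen), 0)
  expect_true(all(seen %in% c("CAA", "CAG", "CGA", "TGG")))
})

test_that("region_filter applies the threshold and is monotone", {
  rep <- find_cbei_sites(toy60, be3, code1)
  expect_equal(region_filter(rep, 100)$sites, rep$sites)
  # site fraction is 13/60 ~ 0.2167: inside at 25%, outside at 20%
  expect_equal(region_filter(rep, 25)$n_sites_in_region, 1)
  expect_equal(region_filter(rep, 20)$n_sites_in_region, 0)
  expect_error(region_filter(rep, 0), "0, 100")
  expect_error(region_filter(rep, 150), "0, 100")

  set.seed(707)
  rep2 <- find_cbei_sites(random_dna(1200), be3, code1)
  counts <- vapply(c(10, 25, 50, 75, 100), function(f) {
    region_filter(rep2, f)$n_sites_in_region
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[5], rep2$n_sites_whole_cds)
})

test_that("context annotation reflects the 5' base on the edited strand", {
  rep <- find_cbei_sites(toy60, be3, code1)
  refreshed <- annotate_context(rep$sites[1, ], nuc_sequence(toy60), be3)
  expect_equal(refreshed$context, rep$sites$context[1])
  expect_equal(refreshed$context_rank, rep$sites$context_rank[1])

  # a stop-creating C at the CDS 5' terminus has no context
  m1 <- cbe_model("w1", "AGG", "3prime", 6, 1, 6)
  cds <- paste0("CAA", "ATT", "AGG", "TAA")  # spacer 1-6 "CAAATT", PAM "AGG"
  rep2 <- find_cbei_sites(cds, m1, code1)
  expect_equal(rep2$n_sites_whole_cds, 1)
  expect_true(is.na(rep2$sites$context))
  expect_true(is.na(rep2$sites$context_rank))
})

test_that("minus-strand sites agree with the oracle on a TGG-rich CDS", {
  # TGG codons give antisense-editable sites; CCN upstream provides the
  # minus-strand NGG PAM
  set.seed(808)
  cds <- paste0("ATG", paste(sample(c("TGG", "CCA", "ATT", "AAT", "CCT"),
                                    40, replace = TRUE), collapse = ""), "TAA")
  got <- find_cbei_sites(cds, be3, code1)$sites
  want <- oracle_design_sites(cds, be3, code1)
  expect_gt(nrow(got), 0)
  expect_true(any(got$strand == "-"))
  expect_equal(design_key(got), design_key(want))
})
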