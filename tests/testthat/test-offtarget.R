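be3 <- load_preset("BE3")
code1 <- load_genetic_code(1)

test_that("anchors split the spacer into m+1 near-equal exact fragments", {
  sp20 <- strrep("ACGTT", 4)
  a3 <- build_anchors(sp20, 3)
  expect_equal(nrow(a3$anchors), 4)
  expect_equal(nchar(a3$anchors$fragment), rep(5L, 4))
  expect_equal(paste(a3$anchors$fragment, collapse = ""), sp20)

  a0 <- build_anchors(sp20, 0)
  expect_equal(a0$anchors$fragment, sp20)

  a2 <- build_anchors(sp20, 2)
  expect_equal(sort(nchar(a2$anchors$fragment), decreasing = TRUE), c(7L, 7L, 6L))
  # fragments are contiguous: offsets are the cumulative lengths
  expect_equal(a2$anchors$offset, cumsum(c(0L, nchar(a2$anchors$fragment)[-3])))

  expect_error(build_anchors("ACG", 3), "anchors")
})

test_that("segmentation tiles contigs and adds junction flanks", {
  set.seed(12)
  g <- list(nuc_sequence(random_dna(2500), id = "big"),
            nuc_sequence(random_dna(400), id = "small"))
  segs <- segment_genome(g, segment_size = 1000, flank = 50)
  big <- Filter(function(s) s$contig == "big", segs)
  tiles <- Filter(function(s) !s$is_junction, big)
  juncs <- Filter(function(s) s$is_junction, big)
  expect_length(tiles, 3)   # 1000 + 1000 + 500
  expect_length(juncs, 2)   # one per internal boundary
  expect_equal(vapply(juncs, function(s) nchar(s$seq), integer(1)), c(100L, 100L))
  # tiles reassemble the contig without gaps
  expect_equal(paste(vapply(tiles, function(s) s$seq, character(1)), collapse = ""),
               g[[1]]$seq)
  expect_equal(vapply(juncs, function(s) s$seg_start, integer(1)), c(950L, 1950L))

  small <- Filter(function(s) s$contig == "small", segs)
  expect_length(small, 1)
  expect_false(small[[1]]$is_junction)

  expect_error(segment_genome(g, segment_size = 90, flank = 50), "exceed")
})

test_that("planted sites are found at and only at sufficient mismatch budgets", {
  set.seed(21)
  sp <- random_dna(20)
  fx <- make_genome(genome_fixture_spec(
    seed = 33, contig_lengths = 10000, gc = 0.5,
    plants = list(
      plant_offtarget(sp, pos = 2000, dist = 0),
      plant_offtarget(sp, pos = 5000, dist = 2, mut_positions = c(3, 17)),
      plant_offtarget(sp, pos = 8000, dist = 0, pam_valid = FALSE)
    )), be3)
  hits2 <- offtarget_search(sp, fx$records, be3, m = 2)
  expect_equal(sort(hits2$start), c(2000L, 5000L))
  expect_equal(hits2$mismatches[order(hits2$start)], c(0L, 2L))
  expect_true(hits2$is_on_target[hits2$start == 2000])

  hits1 <- offtarget_search(sp, fx$records, be3, m = 1)
  expect_equal(hits1$start, 2000L)   # the d=2 plant needs m >= 2
  # the invalid-PAM plant is never reported
  expect_false(8000 %in% offtarget_search(sp, fx$records, be3, m = 3)$start)
})

test_that("minus-strand plants are reported with plus-strand coordinates", {
  set.seed(22)
  sp <- random_dna(20)
  fx <- make_genome(genome_fixture_spec(
    seed = 44, contig_lengths = 6000,
    plants = list(plant_offtarget(sp, pos = 3000, strand = "-", dist = 1,
                                  mut_positions = 10))), be3)
  hits <- offtarget_search(sp, fx$records, be3, m = 1)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 3000L)
  expect_equal(hits$mismatches, 1L)
  # the reported site sequence is the protospacer on its own strand
  expect_equal(sum(strsplit(hits$site_seq, "")[[1]] != strsplit(sp, "")[[1]]), 1)
})

test_that("a site straddling a forced segment boundary is reported exactly once", {
  set.seed(23)
  sp <- random_dna(20)
  # protospacer spans the 1-kb tile boundary (bases 990-1009, PAM 1010-1012)
  fx <- make_genome(genome_fixture_spec(
    seed = 55, contig_lengths = 3000,
    plants = list(plant_offtarget(sp, pos = 990, dist = 1, mut_positions = 5))),
    be3)
  hits <- offtarget_search(sp, fx$records, be3, m = 1,
                           segment_size = 1000, flank = 100)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 990L)
  # and the full search equals the naive oracle on the same genome
  contigs <- stats::setNames(vapply(fx$records, function(r) r$seq, character(1)),
                             vapply(fx$records, function(r) r$id, character(1)))
  expect_equal(hit_key(hits), hit_key(oracle_offtarget(contigs, sp, be3, 1)))
})

test_that("anchor search equals the naive Hamming scan across m and strands", {
  set.seed(24)
  for (rep in 1:4) {
    sp <- random_dna(20)
    fx <- make_genome(genome_fixture_spec(
      seed = 100 + rep, contig_lengths = c(8000, 4000), gc = runif(1, 0.35, 0.6),
      plants = list(
        plant_offtarget(sp, contig = 1, pos = 1500, dist = 0),
        plant_offtarget(sp, contig = 1, pos = 4000, dist = 3, strand = "-"),
        plant_offtarget(sp, contig = 2, pos = 2000, dist = 2))), be3)
    contigs <- stats::setNames(vapply(fx$records, function(r) r$seq, character(1)),
                               vapply(fx$records, function(r) r$id, character(1)))
    for (m in 0:3) {
      got <- offtarget_search(sp, fx$records, be3, m = m,
                              segment_size = 2000, flank = 100)
      expect_equal(hit_key(got), hit_key(oracle_offtarget(contigs, sp, be3, m)),
                   info = sprintf("rep %d m %d", rep, m))
    }
  }
})

test_that("hit sets are nested in the mismatch budget and free of duplicates", {
  set.seed(25)
  sp <- random_dna(20)
  fx <- make_genome(genome_fixture_spec(
    seed = 66, contig_lengths = 9000,
    plants = list(plant_offtarget(sp, pos = 2000, dist = 0),
                  plant_offtarget(sp, pos = 4500, dist = 1),
                  plant_offtarget(sp, pos = 7000, dist = 3))), be3)
  keysets <- lapply(0:3, function(m) {
    h <- offtarget_search(sp, fx$records, be3, m = m, segment_size = 2000)
    k <- paste(h$spacer, h$contig, h$start, h$strand)
    expect_equal(anyDuplicated(k), 0L)
    k
  })
  for (i in 1:3) expect_true(all(keysets[[i]] %in% keysets[[i + 1]]))
})

test_that("all m+1 anchors are necessary for completeness", {
  # adversarial site: for each anchor, mutate one base inside every OTHER
  # anchor; only the untouched anchor still matches exactly, so dropping it
  # would lose the hit
  set.seed(26)
  sp <- random_dna(20)
  m <- 2
  full <- build_anchors(sp, m)
  for (keep in seq_len(m + 1)) {
    ch <- strsplit(sp, "")[[1]]
    for (j in seq_len(m + 1)) {
      if (j == keep) next
      off <- full$anchors$offset[j]
      ch[off + 1] <- setdiff(c("A", "C", "G", "T"), ch[off + 1])[1]
    }
    site <- paste(ch, collapse = "")
    fx <- make_genome(genome_fixture_spec(
      seed = 200 + keep, contig_lengths = 4000,
      plants = list(plant_offtarget(sp, pos = 1500, dist = m,
                                    mut_positions = full$anchors$offset[setdiff(1:(m + 1), keep)] + 1))),
      be3)
    hits <- offtarget_search(sp, fx$records, be3, m = m)
    expect_equal(hits$start, 1500L, info = paste("keep anchor", keep))
    # a crippled search using every anchor except `keep` misses the site
    crippled <- full
    crippled$anchors <- crippled$anchors[-keep, , drop = FALSE]
    seg <- segment_genome(fx$records)[[1]]
    miss <- scan_segment(seg, crippled, be3)
    expect_false(1500 %in% miss$start, info = paste("without anchor", keep))
  }
})

test_that("searching a spacer against its own source CDS returns the on-target site", {
  set.seed(27)
  fx <- make_cds(cds_fixture_spec(seed = 77, n_cds = 1,
                                  length_range = c(300, 300),
                                  plants = list(plant_cbei_site(cds = 1))))
  site <- find_cbei_sites(fx$records[[1]], be3, code1)$sites[1, ]
  hits <- offtarget_search(site$spacer, fx$records, be3, m = 0)
  expect_true(any(hits$is_on_target))
  expect_true(site$proto_start %in% hits$start)
})

test_that("empty spacer lists error and m > 3 warns", {
  expect_error(offtarget_search(character(0), "ACGT", be3), "empty")
  set.seed(28)
  g <- list(nuc_sequence(random_dna(500), id = "g"))
  expect_warning(offtarget_search(random_dna(20), g, be3, m = 4), "0-3")
})
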