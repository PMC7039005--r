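test_that("the bundled catalogue matches the printed linker toolbox", {
  lk <- catalogue_linkers()
  expect_length(lk, 15L)
  classes <- table(vapply(lk, `[[`, character(1), "flexibility_class"))
  expect_equal(classes[["short"]], 4L)
  expect_equal(classes[["flexible"]], 4L)
  expect_equal(classes[["rigid"]], 4L)
  expect_equal(classes[["semi-flexible"]], 3L)
  expect_equal(lk$GGS15$aa_seq, "GGSGGSGGSGGSGSG")
  expect_equal(lk$GGS15$length_aa, 15L)
  expect_equal(lk$GGS15$flexibility_class, "flexible")
  expect_equal(lk$EAAAK16$aa_seq, "GGAEAAAKEAAAKAGG")
  expect_equal(lk$EAAAK16$length_aa, 16L)
  expect_equal(lk$EAAAK16$flexibility_class, "rigid")
  # printed lengths include the bridging Gly residues: length == nchar(aa)
  for (p in lk) expect_equal(p$length_aa, nchar(p$aa_seq), info = p$id)
  # domains ship as named length-only stubs
  dm <- load_catalogue("domains")
  expect_equal(dm$FRB$length_aa, 91L)
  expect_equal(dm$TVMV$length_aa, 222L)
  expect_null(dm$FRB$dna_seq)
})

test_that("validation flags forbidden sites, stops and frame problems", {
  # GCAATG encodes Ala-Met in frame: a clean way to plant a BsrDI site
  p <- part("bad1", "domain", "AM", dna_seq = "GCAATG")
  r <- validate_part(p)
  expect_false(r$passed)
  expect_true(any(r$violations$rule == "forbidden_site" &
                    grepl("BsrDI", r$violations$detail)))
  # internal stop codon (object built directly: the constructor refuses it)
  p2 <- structure(list(id = "bad2", role = "domain", aa_seq = NULL,
                       dna_seq = "GGTTAAGGT", flexibility_class = "n/a",
                       length_aa = 3L, description = ""), class = "iflc_part")
  r2 <- validate_part(p2)
  expect_true(any(r2$violations$rule == "stop_codon"))
  # frame violation
  p3 <- structure(list(id = "bad3", role = "domain", aa_seq = NULL,
                       dna_seq = "GGTT", flexibility_class = "n/a",
                       length_aa = 1L, description = ""), class = "iflc_part")
  expect_true(any(validate_part(p3)$violations$rule == "frame"))
  # empty DNA is a precondition error, not a report
  expect_error(validate_part(structure(list(id = "e", dna_seq = NULL),
                                       class = "iflc_part")), "no DNA")
  # every synthesized catalogue linker passes
  for (p in catalogue_linkers()) expect_true(validate_part(p)$passed, info = p$id)
})

test_that("validate_part finds exactly the sites scan_sites finds", {
  set.seed(41)
  ez <- enzymes()
  for (rep in 1:10) {
    s <- random_dna(3 * 120)
    p <- structure(list(id = "r", role = "domain", aa_seq = NULL, dna_seq = s,
                        flexibility_class = "n/a", length_aa = 120L,
                        description = ""), class = "iflc_part")
    hits <- validate_part(p)$violations
    hits <- hits[hits$rule == "forbidden_site", , drop = FALSE]
    want <- sum(vapply(ez, function(e)
      nrow(scan_sites(duplex(s), e)), integer(1)))
    expect_equal(nrow(hits), want)
  }
})

test_that("reverse translation is deterministic, faithful and clean", {
  expect_equal(reverse_translate_linker("G"), "GGT")
  lk <- catalogue_linkers()
  for (p in lk) {
    dna <- p$dna_seq
    expect_equal(nchar(dna), 3L * p$length_aa, info = p$id)
    expect_equal(translate_orf(dna), p$aa_seq, info = p$id)       # round trip
    expect_equal(nrow(forbidden_sites(dna)), 0L, info = p$id)
    # repeat rule: no direct repeat longer than 8 nt (naive oracle)
    expect_false(naive_has_repeat(dna, 9L), info = p$id)
  }
  # determinism
  expect_identical(reverse_translate_linker("GPPPPPPPG"),
                   reverse_translate_linker("GPPPPPPPG"))
  expect_equal(nchar(reverse_translate_linker("GTPTPTPTPTG")), 33L)
  # impossible encodings fail loudly: a one-codon-per-residue policy whose
  # only choice spells an EcoRI site
  pol <- codon_policy()
  pol$codons$E <- "GAA"
  pol$codons$F <- "TTC"
  expect_error(reverse_translate_linker("EF", pol), "reverse translation failed")
  expect_error(reverse_translate_linker("GZG"), "non-standard")
})

test_that("translation reports stops and rejects broken frames", {
  expect_equal(translate_orf("GGTGGT"), "GG")
  expect_equal(translate_orf("TAA"), "*")
  expect_error(translate_orf("GGTG"), "frame")
})
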