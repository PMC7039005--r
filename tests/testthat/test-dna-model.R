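test_that("site scanning reports 0-based positions on both strands", {
  ez <- enzymes()
  # palindromic site reported once, on the top strand
  hits <- scan_sites(duplex("GAATTC"), ez$EcoRI)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 0L)
  expect_equal(hits$strand, "top")
  # reverse complement of GCAGTG: one BtsI site on the bottom strand only
  hits <- scan_sites(duplex("TTTCACTGCTTT"), ez$BtsI)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "bottom")
  expect_equal(hits$position, 3L)
  # circular scanning crosses the origin
  s <- paste0("ATTC", strrep("A", 30), "GA")  # GAATTC spans the origin
  expect_equal(nrow(scan_sites(duplex(s, "circular"), ez$EcoRI)), 1L)
  expect_equal(nrow(scan_sites(duplex(s, "linear"), ez$EcoRI)), 0L)
  # invalid IUPAC motif is a configuration error
  expect_error(restriction_enzyme("bad", "GCAXTG", 2, 0), "IUPAC")
})

test_that("site counts agree with a naive both-strand oracle on random DNA", {
  set.seed(101)
  ez <- enzymes()
  for (rep in 1:3) {
    s <- random_dna(10000)
    for (topo in c("linear", "circular")) {
      dx <- duplex(s, topo)
      for (nm in names(ez)) {
        expect_equal(nrow(scan_sites(dx, ez[[nm]])),
                     naive_scan_count(s, ez[[nm]]$recognition,
                                      circular = topo == "circular"),
                     info = paste(nm, topo, rep))
      }
    }
  }
})

test_that("type IIS digestion yields 2-nt 3' overhangs and conserves length", {
  ez <- enzymes()
  m <- duplex("AAAAAGCAGTGCCTTTTTT", id = "one-btsi")
  fr <- digest(m, ez$BtsI)
  expect_length(fr, 2L)
  expect_equal(fr[[1]]$right_end$polarity, "3prime")
  expect_equal(nchar(fr[[1]]$right_end$overhang), 2L)
  expect_equal(fr[[2]]$left_end$polarity, "3prime")
  expect_equal(nchar(fr[[2]]$left_end$overhang), 2L)
  expect_true(fr[[1]]$right_end$phosphorylated)
  expect_equal(sum(vapply(fr, dx_length, integer(1))), dx_length(m))
  # BsrDI likewise; EcoRI/SpeI give 4-nt 5' overhangs (enzyme-level check)
  expect_equal(ez$BsrDI$overhang_length, 2L)
  expect_equal(ez$BsrDI$polarity, "3prime")
  expect_equal(ez$EcoRI$overhang_length, 4L)
  expect_equal(ez$EcoRI$polarity, "5prime")
  expect_equal(ez$SpeI$overhang_length, 4L)
  expect_equal(ez$SpeI$polarity, "5prime")
})

test_that("digestion handles circular molecules, no-site identity and edge cuts", {
  ez <- enzymes()
  set.seed(5)
  circ <- duplex(paste0("GAATTC", gsub("GAATTC", "ACACAC", random_dna(50))),
                 "circular", id = "c1")
  fr <- digest(circ, ez$EcoRI)
  expect_length(fr, 1L)
  expect_equal(fr[[1]]$topology, "linear")
  expect_equal(dx_length(fr[[1]]), dx_length(circ))
  # k sites on a circle -> k fragments
  set.seed(7)
  spacer <- function(n) gsub("GAATTC", "ACACAC", random_dna(n))
  circ3 <- duplex(paste0("GAATTC", spacer(40), "GAATTC", spacer(60),
                         "GAATTC", spacer(30)), "circular")
  expect_length(digest(circ3, ez$EcoRI), 3L)
  # no sites: identity
  none <- duplex("ACGTACGTACGT")
  expect_identical(digest(none, ez$EcoRI)[[1]], none)
  # cut falling outside a linear molecule is a degenerate-input error
  expect_error(digest(duplex("AAAGCAGTGC"), ez$BtsI), "outside")
})

test_that("nucleotide conservation holds for random multi-enzyme digests", {
  set.seed(11)
  ez <- enzymes()
  for (rep in 1:20) {
    s <- paste0(random_dna(80), "GAATTC", random_dna(80), "GCAGTG",
                random_dna(40), random_dna(60), "ACTAGT", random_dna(80))
    for (topo in c("linear", "circular")) {
      dx <- duplex(s, topo)
      fr <- tryCatch(digest(dx, ez), error = function(e) NULL)
      if (is.null(fr)) next  # site too close to a linear end
      expect_equal(sum(vapply(fr, dx_length, integer(1))), dx_length(dx))
    }
  }
})

test_that("dephosphorylation clears flags, is idempotent and blocks ligation", {
  ez <- enzymes()
  fr <- digest(duplex(paste0("AAA", "GAATTC", "TTTTT")), ez$EcoRI)
  dp <- dephosphorylate(fr[[1]])
  expect_false(dp$left_end$phosphorylated)
  expect_false(dp$right_end$phosphorylated)
  expect_identical(dephosphorylate(dp), dp)
  expect_identical(dp$top_strand, fr[[1]]$top_strand)
  expect_warning(dephosphorylate(duplex("ACGT", "circular")), "circular")
  # both junction partners dephosphorylated: ligation refused
  dp2 <- dephosphorylate(fr[[2]])
  expect_false(ends_compatible(dp$right_end, dp2$left_end))
  expect_error(ligate(list(dp, dp2)), "incompatible")
  # one phosphorylated partner suffices
  expect_true(ends_compatible(dp$right_end, fr[[2]]$left_end))
  expect_s3_class(ligate(list(dp, fr[[2]])), "iflc_duplex")
})

test_that("end compatibility follows the reverse-complement and polarity rules", {
  e5 <- function(ov, ph = TRUE) fragment_end(ov, "5prime", ph)
  e3 <- function(ov, ph = TRUE) fragment_end(ov, "3prime", ph)
  expect_true(ends_compatible(e5("AATT"), e5("AATT")))   # EcoRI religation
  expect_true(ends_compatible(e3("CA"), e3("TG")))
  expect_false(ends_compatible(e3("CA"), e3("CA")))
  expect_false(ends_compatible(e5("CA"), e3("TG")))      # polarity mismatch
  expect_false(ends_compatible(e5("AATT", FALSE), e5("AATT", FALSE)))
  # blunt ligation only when enabled
  b <- fragment_end("", "blunt", TRUE)
  expect_false(ends_compatible(b, b))
  expect_true(ends_compatible(b, b, blunt_ligation = TRUE))
})

test_that("digest then ligate restores the parent exactly", {
  ez <- enzymes()
  lin <- duplex(paste0("AAACCC", "GAATTC", "GGGTTT"), id = "p")
  fr <- digest(lin, ez$EcoRI)
  rel <- ligate(fr)
  expect_true(duplex_identical(rel, lin))
  expect_true(grepl("GAATTC", rel$top_strand, fixed = TRUE))
  # circular round trip with mixed cutters, up to rotation
  set.seed(23)
  for (rep in 1:30) {
    s <- paste0(random_dna(60), "GCAGTG", random_dna(60), "GAATTC",
                random_dna(60), "ACTAGT", random_dna(60))
    circ <- duplex(s, "circular")
    fr <- digest(circ, ez)
    back <- ligate(fr, circularize = TRUE)
    expect_true(duplex_identical(back, circ))
  }
  # explicit-order contract: incompatible junction names the junction
  expect_error(ligate(list(fr[[1]], fr[[1]])), "junction")
})

test_that("flipping a duplex is an involution that preserves end typing", {
  ez <- enzymes()
  fr <- digest(duplex(paste0("AA", "GCAGTG", "CCTTTTTT", "GAATTC", "AAAA")),
               list(ez$BtsI, ez$EcoRI))
  for (f in fr) {
    g <- reverse_duplex(reverse_duplex(f))
    expect_identical(g$top_strand, f$top_strand)
    expect_identical(g$left_end, f$left_end)
    expect_identical(g$right_end, f$right_end)
    # a flip swaps ends but keeps polarity and overhang sequence
    h <- reverse_duplex(f)
    expect_identical(h$left_end$overhang, f$right_end$overhang)
    expect_identical(h$left_end$polarity, f$right_end$polarity)
  }
})
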