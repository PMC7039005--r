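test_that("fixture entry plasmids satisfy the entry contract", {
  lk <- catalogue_linkers()
  ep <- fixture_entry(lk$GPG)
  ez <- enzymes()
  expect_equal(ep$molecule$topology, "circular")
  for (nm in names(ez))
    expect_equal(nrow(scan_sites(ep$molecule, ez[[nm]])), 1L, info = nm)
  expect_equal(translate_orf(ep$insert_orf), "GPG")
  # invalid parts are refused
  bad <- part("bad", "domain", "AM", dna_seq = "GCAATG")
  expect_error(make_entry_plasmid(bad, seed = 1), "refusing")
  # the single-G linker has no plasmid of its own
  expect_error(make_entry_plasmid(lk$G, seed = 1), "junction")
  # a molecule with two type IIS sites violates the contract
  m2 <- duplex(paste0(ep$molecule$top_strand, "GCAGTG"), "circular")
  expect_error(entry_plasmid(m2, list(lk$GPG)), "BtsI")
})

test_that("cycle planning picks resolvable fragments deterministically", {
  lk <- catalogue_linkers()
  ai <- fixture_domain("AI", 60)
  ep_ai <- fixture_entry(ai, "pFD")
  ep_gpg <- fixture_entry(lk$GPG)
  plan <- choose_enzyme_pair(ep_gpg, ep_ai)
  expect_s3_class(plan, "iflc_cycle_plan")
  expect_equal(plan$donor_typeIIS, "BtsI")
  expect_equal(plan$acceptor_typeIIS, "BsrDI")
  expect_gte(plan$resolvability, 1.2)
  # the planned lengths are exactly the lengths of the gel-selected products
  # of an exhaustive re-digestion (brute-force oracle)
  ez <- enzymes()
  fd <- digest(ep_gpg$molecule, list(ez$BtsI, ez[[plan$flank_choice]]))
  fa <- digest(ep_ai$molecule, list(ez$BsrDI, ez[[plan$flank_choice]]))
  expect_true(plan$selected_fragment_lengths["donor"] %in%
                vapply(fd, dx_length, integer(1)))
  expect_true(plan$selected_fragment_lengths["acceptor"] %in%
                vapply(fa, dx_length, integer(1)))
  expect_identical(plan, choose_enzyme_pair(ep_gpg, ep_ai))  # deterministic
  # same plasmid on both sides: no productive fusion
  expect_error(choose_enzyme_pair(ep_ai, ep_ai), "planning error")
})

test_that("gel selection behaves like a band cut with co-migration errors", {
  mk <- function(n) duplex(strrep("A", n))
  expect_equal(dx_length(gel_select(list(mk(3000), mk(150)), 3000)), 3000L)
  expect_error(gel_select(list(mk(1000), mk(1050)), 1000, tolerance = 0.2),
               "co-migrating")
  expect_error(gel_select(list(mk(100), mk(400)), 3000), "no fragment")
  # randomized sets agree with a naive filter
  set.seed(51)
  for (rep in 1:20) {
    lens <- sample(100:5000, 6)
    target <- sample(lens, 1)
    naive <- which(abs(lens - target) <= 0.1 * target)
    frags <- lapply(lens, mk)
    if (length(naive) == 1L) {
      expect_equal(dx_length(gel_select(frags, target)), lens[naive])
    } else {
      expect_error(gel_select(frags, target))
    }
  }
})

test_that("an assembly cycle fuses in frame through the bridging Gly", {
  lk <- catalogue_linkers()
  ai <- fixture_domain("AI", 60)
  fkbp <- fixture_domain("FKBP12", 106)
  ep_ai <- fixture_entry(ai, "pFD")
  ep_gpg <- fixture_entry(lk$GPG)
  ep_fkbp <- fixture_entry(fkbp, "pFD")
  prod <- ifc_cycle(ep_ai, ep_gpg)
  expect_equal(insert_protein(prod), paste0(ai$aa_seq, "GPG"))
  prod2 <- ifc_cycle(prod, ep_fkbp)
  expect_equal(insert_protein(prod2), paste0(ai$aa_seq, "GPG", fkbp$aa_seq))
  expect_equal(nchar(insert_protein(prod2)), 60L + 3L + 106L)
  # a domain-domain cycle inserts exactly the single bridging Gly
  dd <- ifc_cycle(ep_ai, ep_fkbp)
  expect_equal(insert_protein(dd), paste0(ai$aa_seq, "G", fkbp$aa_seq))
  # determinism: byte-identical product
  expect_identical(ifc_cycle(ep_ai, ep_gpg)$molecule$top_strand,
                   prod$molecule$top_strand)
})

test_that("cycle products remain valid entry plasmids over many rounds", {
  lk <- catalogue_linkers()
  dom <- fixture_domain("D40", 40)
  ep_dom <- fixture_entry(dom, "pFD")
  ep_l <- fixture_entry(lk$GGS4)
  ez <- enzymes()
  acc <- ep_dom
  expected_aa <- dom$aa_seq
  for (i in 1:10) {
    if (i %% 2L == 1L) {
      acc <- ifc_cycle(acc, ep_l)
      expected_aa <- paste0(expected_aa, lk$GGS4$aa_seq)
    } else {
      acc <- ifc_cycle(acc, ep_dom)
      expected_aa <- paste0(expected_aa, dom$aa_seq)
    }
    # the defining iterability property: every product is itself an entry
    for (nm in names(ez))
      expect_equal(nrow(scan_sites(acc$molecule, ez[[nm]])), 1L)
    expect_equal(insert_protein(acc), expected_aa)
    expect_false(grepl("*", translate_orf(acc$insert_orf), fixed = TRUE))
  }
})

test_that("fusion verification reports the first mismatching residue", {
  lk <- catalogue_linkers()
  ai <- fixture_domain("AI", 60)
  prod <- ifc_cycle(fixture_entry(ai, "pFD"), fixture_entry(lk$GPG))
  expect_true(verify_fusion(prod, prod$parts)$passed)
  # mutate the junction Gly codon in the product ORF
  mut <- prod
  orf_at <- regexpr(prod$insert_orf, prod$molecule$top_strand, fixed = TRUE)
  jpos <- orf_at + 3L * 61L  # codon of the junction Gly (= linker residue 1)
  s <- mut$molecule$top_strand
  substr(s, jpos, jpos + 2L) <- "GCT"
  mut$molecule$top_strand <- s
  mut$insert_orf <- substr(s, orf_at, orf_at + nchar(prod$insert_orf) - 1L)
  r <- verify_fusion(mut, prod$parts)
  expect_false(r$passed)
  expect_equal(r$violations$position, 62L)  # flank G + 60 domain residues + 1
})

test_that("transfer to the destination vector preserves the insert ORF", {
  lk <- catalogue_linkers()
  ai <- fixture_domain("AI", 60)
  prod <- ifc_cycle(fixture_entry(ai, "pFD"), fixture_entry(lk$GPG))
  dest <- memo("dest", make_destination_vector(seed = 1))
  xc <- transfer_to_destination(prod, dest)
  expect_equal(xc$topology, "circular")
  expect_identical(attr(xc, "insert_orf"), prod$insert_orf)
  # GenBank round trip of the product is byte-stable
  f1 <- withr_local_tempfile(".gb"); f2 <- withr_local_tempfile(".gb")
  write_genbank(xc, f1)
  write_genbank(read_genbank(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 1),
                   readBin(f2, "raw", file.size(f2) + 1))
  # an entry whose ORF no longer matches its declared chain is refused
  broken <- prod
  broken$parts <- list(ai)  # claims a chain it does not encode
  expect_error(transfer_to_destination(broken, dest), "refused")
})
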