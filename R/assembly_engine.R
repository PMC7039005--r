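## Assembly engine: the elementary iFLinkC cycle (digest donor and acceptor
## entry plasmids, gel-select, ligate in frame through a bridging Gly,
## regenerate the entry plasmid) and transfer to the destination vector.
##
## Cassette convention (documented in the methods vignette): every entry
## cassette reads
##     GCAGTG | GT | core | GGT | CATTGC
## on the top strand. The terminal G of the BtsI site is the first base of a
## junction Gly codon (default GGT) whose last two bases "GT" form the 2-nt
## 3' overhang; CATTGC is the BsrDI site on the bottom strand, cutting so
## that the 2-nt overhang falls inside the downstream junction GGT. `core` of
## a linker is its coding DNA minus the first and last (bridging Gly) codons;
## `core` of a domain is its full coding DNA. A domain-domain cycle therefore
## inserts exactly one bridging Gly -- the single-"G" linker -- while a
## stored linker shares its printed terminal Gly residues with the junctions.

JUNCTION_CODON <- "GGT"

core_dna <- function(p, junction_codon = JUNCTION_CODON) {
  stopifnot(inherits(p, "iflc_part"))
  if (is.null(p$dna_seq)) stop("part ", p$id, " has no DNA attached", call. = FALSE)
  if (p$role == "linker") {
    if (p$length_aa == 1L) return("")  # single-G linker: pure junction
    # normalize bridging Gly codons to the junction codon
    n <- nchar(p$dna_seq)
    substr(p$dna_seq, 4L, n - 3L)
  } else {
    p$dna_seq
  }
}

core_aa <- function(p) {
  if (p$role == "linker") {
    if (p$length_aa == 1L) return("")
    substr(p$aa_seq, 2L, p$length_aa - 1L)
  } else p$aa_seq
}

is_g1 <- function(p) p$role == "linker" && p$length_aa == 1L

# parts of a chain that materialize a core block (single-G linkers collapse
# into the junction between their neighbours)
chain_blocks <- function(parts) Filter(Negate(is_g1), parts)

# DNA of the cassette core region: cores joined by the junction Gly codon
chain_core_dna <- function(parts, junction_codon = JUNCTION_CODON) {
  blocks <- chain_blocks(parts)
  if (!length(blocks)) stop("chain has no sequence-bearing parts", call. = FALSE)
  paste(vapply(blocks, core_dna, character(1), junction_codon = junction_codon),
        collapse = junction_codon)
}

# translation of the full cassette ORF: flank Gly + cores joined by Gly + Gly
expected_orf_aa <- function(parts) {
  blocks <- chain_blocks(parts)
  paste0("G", paste(vapply(blocks, core_aa, character(1)), collapse = "G"), "G")
}

#' Protein encoded by an ordered domain/linker chain
#'
#' The protein-level ground truth of a design: the concatenation of the parts'
#' printed amino-acid sequences, with one bridging Gly inserted at every
#' domain-domain junction (the single-"G" linker) and the shared Gly merged at
#' a (rare) linker-linker junction. Linker sequences already include their
#' bridging Gly residues, so for the usual alternating domain-linker designs
#' this is a plain concatenation and the protein length is the sum of the
#' domain lengths and the printed linker lengths.
#'
#' @param parts ordered list of `iflc_part`.
#' @return amino-acid string.
#' @export
chain_protein <- function(parts) {
  out <- parts[[1L]]$aa_seq
  for (i in seq_along(parts)[-1L]) {
    a <- parts[[i - 1L]]; b <- parts[[i]]
    if (a$role == "domain" && b$role == "domain") {
      out <- paste0(out, "G", b$aa_seq)
    } else if (a$role == "linker" && b$role == "linker") {
      out <- paste0(out, substr(b$aa_seq, 2L, nchar(b$aa_seq)))
    } else {
      out <- paste0(out, b$aa_seq)
    }
  }
  out
}

## ---- entry plasmids ---------------------------------------------------------

#' Construct and validate an entry plasmid
#'
#' Normalizes the molecule (BtsI site on the top strand, cassette starting at
#' position 1) and enforces the entry contract: circular; exactly one BtsI,
#' one BsrDI, one EcoRI and one SpeI site; the insert ORF in frame, stop-free,
#' and translating to the chain's expected sequence.
#'
#' @param molecule circular `iflc_duplex`.
#' @param parts ordered list of `iflc_part` making up the insert.
#' @param backbone_id `"pL2"` or `"pFD"`.
#' @param junction_codon Gly codon used at fusion boundaries.
#' @return an object of class `iflc_entry`.
#' @export
entry_plasmid <- function(molecule, parts, backbone_id = "pL2",
                          junction_codon = JUNCTION_CODON) {
  stopifnot(inherits(molecule, "iflc_duplex"))
  if (inherits(parts, "iflc_part")) parts <- list(parts)
  if (molecule$topology != "circular")
    stop("entry plasmid must be circular", call. = FALSE)
  enz <- iflc_enzymes()
  # orientation: exactly one BtsI site, on the top strand after normalization
  bts <- scan_sites(molecule, enz$BtsI)
  if (nrow(bts) != 1L)
    stop(sprintf("entry invariant violated: %d BtsI sites (expected 1)", nrow(bts)),
         call. = FALSE)
  if (bts$strand == "bottom") {
    molecule <- reverse_duplex(molecule)
    bts <- scan_sites(molecule, enz$BtsI)
  }
  # rotate so the cassette starts at position 1
  n <- dx_length(molecule)
  p0 <- bts$position  # 0-based
  if (p0 != 0L) {
    dbls <- paste0(molecule$top_strand, molecule$top_strand)
    molecule <- duplex(substr(dbls, p0 + 1L, p0 + n), "circular",
                       id = molecule$id, allow_n = TRUE)
  }
  for (nm in c("BsrDI", "EcoRI", "SpeI")) {
    k <- nrow(scan_sites(molecule, enz[[nm]]))
    if (k != 1L)
      stop(sprintf("entry invariant violated: %d %s sites (expected 1)", k, nm),
           call. = FALSE)
  }
  top <- molecule$top_strand
  r <- regexpr("CATTGC", top, fixed = TRUE)  # BsrDI on bottom strand
  if (r < 7L) stop("entry invariant violated: cassette structure not found",
                   call. = FALSE)
  orf <- substr(top, 6L, r - 1L)  # from the flank G (last base of GCAGTG)
  if (nchar(orf) %% 3L != 0L)
    stop("entry invariant violated: insert ORF out of frame", call. = FALSE)
  aa <- translate_orf(orf)
  if (grepl("*", aa, fixed = TRUE))
    stop("entry invariant violated: stop codon in insert ORF", call. = FALSE)
  expect <- expected_orf_aa(parts)
  if (aa != expect)
    stop(sprintf("entry ORF does not encode the declared chain (got %s, expected %s)",
                 aa, expect), call. = FALSE)
  structure(list(molecule = molecule, parts = parts, backbone_id = backbone_id,
                 junction_codon = junction_codon, insert_orf = orf),
            class = "iflc_entry")
}

#' @export
print.iflc_entry <- function(x, ...) {
  ids <- vapply(x$parts, `[[`, character(1), "id")
  cat(sprintf("<iflc_entry> %s [%s], %d bp, insert: %s (%d aa)\n",
              x$backbone_id, x$molecule$id, dx_length(x$molecule),
              paste(ids, collapse = "-"), nchar(chain_protein(x$parts))))
  invisible(x)
}

#' Protein sequence of an entry plasmid's insert
#'
#' @param entry an `iflc_entry`.
#' @return amino-acid string per [chain_protein()].
#' @export
insert_protein <- function(entry) chain_protein(entry$parts)

## ---- cycle planning ---------------------------------------------------------

# fragment carrying a given motif (on either strand)
frag_has_motif <- function(frag, motif) {
  grepl(motif, frag$top_strand, fixed = TRUE) ||
    grepl(revcomp(motif), frag$top_strand, fixed = TRUE)
}

#' Plan an iFLinkC cycle
#'
#' The acceptor (upstream partner) is always opened at its downstream
#' boundary with BsrDI, the donor at its upstream boundary with BtsI; the
#' shared flank enzyme (SpeI or EcoRI) is chosen so that, in both digests,
#' the gel-selected fragment differs in size from its sibling by at least the
#' resolvable-size ratio. Deterministic given the inputs.
#'
#' @param donor,acceptor `iflc_entry` plasmids.
#' @param min_ratio resolvable gel-size ratio (default 1.2, i.e. 20%).
#' @return an object of class `iflc_cycle_plan`.
#' @export
choose_enzyme_pair <- function(donor, acceptor, min_ratio = 1.2) {
  stopifnot(inherits(donor, "iflc_entry"), inherits(acceptor, "iflc_entry"))
  if (duplex_identical(donor$molecule, acceptor$molecule))
    stop("planning error: donor and acceptor are the same plasmid (no productive fusion)",
         call. = FALSE)
  enz <- iflc_enzymes()
  evaluate <- function(flank) {
    fa <- digest(acceptor$molecule, list(enz$BsrDI, enz[[flank]]))
    fd <- digest(donor$molecule, list(enz$BtsI, enz[[flank]]))
    if (length(fa) != 2L || length(fd) != 2L) return(NULL)
    keep_a <- which(vapply(fa, frag_has_motif, logical(1), "GCAGTG"))
    keep_d <- which(vapply(fd, frag_has_motif, logical(1), "CATTGC"))
    if (length(keep_a) != 1L || length(keep_d) != 1L) return(NULL)
    la <- vapply(fa, dx_length, integer(1))
    ld <- vapply(fd, dx_length, integer(1))
    ra <- max(la) / min(la)
    rd <- max(ld) / min(ld)
    list(flank = flank, acceptor_len = la[keep_a], donor_len = ld[keep_d],
         ratio = min(ra, rd))
  }
  cands <- Filter(Negate(is.null), lapply(c("SpeI", "EcoRI"), evaluate))
  cands <- Filter(function(x) x$ratio >= min_ratio, cands)
  if (!length(cands))
    stop("planning error: no enzyme combination yields gel-resolvable fragments; consider the alternative insert orientation",
         call. = FALSE)
  best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "ratio"))]]
  structure(list(donor_id = donor$molecule$id, acceptor_id = acceptor$molecule$id,
                 donor_typeIIS = "BtsI", acceptor_typeIIS = "BsrDI",
                 flank_choice = best$flank,
                 selected_fragment_lengths = c(acceptor = unname(best$acceptor_len),
                                               donor = unname(best$donor_len)),
                 resolvability = best$ratio,
                 dephosphorylated_side = "acceptor"),
            class = "iflc_cycle_plan")
}

#' @export
print.iflc_cycle_plan <- function(x, ...) {
  cat(sprintf("<iflc_cycle_plan> donor %s (BtsI) + acceptor %s (BsrDI) with %s; keep %d / %d bp; dephos: %s\n",
              x$donor_id, x$acceptor_id, x$flank_choice,
              x$selected_fragment_lengths["donor"],
              x$selected_fragment_lengths["acceptor"],
              x$dephosphorylated_side))
  invisible(x)
}

#' Select a gel band by size
#'
#' Returns the unique fragment within `tolerance` of `target_length`;
#' zero or two-and-more matches mimic an unresolvable gel band and raise a
#' selection error.
#'
#' @param fragments list of `iflc_duplex`.
#' @param target_length integer bp.
#' @param tolerance fractional size window (default 0.1).
#' @return the selected `iflc_duplex`.
#' @export
gel_select <- function(fragments, target_length, tolerance = 0.1) {
  stopifnot(length(fragments) >= 1L)
  lens <- vapply(fragments, dx_length, integer(1))
  hit <- which(abs(lens - target_length) <= tolerance * target_length)
  if (length(hit) == 0L)
    stop(sprintf("gel selection error: no fragment within %.0f%% of %d bp (have: %s)",
                 100 * tolerance, target_length, paste(lens, collapse = ", ")),
         call. = FALSE)
  if (length(hit) > 1L)
    stop(sprintf("gel selection error: %d co-migrating fragments near %d bp (%s)",
                 length(hit), target_length, paste(lens[hit], collapse = ", ")),
         call. = FALSE)
  fragments[[hit]]
}

# orient a fragment so its junction (2-nt 3' overhang) end is on the given side
orient_junction <- function(frag, side = c("right", "left")) {
  side <- match.arg(side)
  is_junction <- function(e) e$polarity == "3prime" && nchar(e$overhang) == 2L
  e <- if (side == "right") frag$right_end else frag$left_end
  if (is_junction(e)) return(frag)
  frag2 <- reverse_duplex(frag)
  e2 <- if (side == "right") frag2$right_end else frag2$left_end
  if (!is_junction(e2)) stop("fragment has no 2-nt junction end", call. = FALSE)
  frag2
}

#' Execute one iFLinkC assembly cycle
#'
#' Digests the acceptor with BsrDI + flank enzyme and the donor with BtsI +
#' flank enzyme, gel-selects the planned fragments, dephosphorylates the
#' planned side, and ligates/circularizes. The product is a fully valid entry
#' plasmid encoding acceptor-chain + junction Gly context + donor-chain, so
#' cycles can be iterated indefinitely.
#'
#' @param acceptor upstream `iflc_entry` (keeps its backbone left of the
#'   insert).
#' @param donor downstream `iflc_entry`.
#' @param plan optional [choose_enzyme_pair()] plan; computed if missing.
#' @param tolerance gel-selection size tolerance.
#' @return the product `iflc_entry`.
#' @export
ifc_cycle <- function(acceptor, donor, plan = NULL, tolerance = 0.1) {
  stopifnot(inherits(acceptor, "iflc_entry"), inherits(donor, "iflc_entry"))
  if (is.null(plan)) plan <- choose_enzyme_pair(donor, acceptor)
  enz <- iflc_enzymes()
  flank <- enz[[plan$flank_choice]]

  fa <- digest(acceptor$molecule, list(enz[[plan$acceptor_typeIIS]], flank))
  keep_a <- gel_select(fa, plan$selected_fragment_lengths["acceptor"], tolerance)
  fd <- digest(donor$molecule, list(enz[[plan$donor_typeIIS]], flank))
  keep_d <- gel_select(fd, plan$selected_fragment_lengths["donor"], tolerance)

  keep_a <- orient_junction(keep_a, "right")
  keep_d <- orient_junction(keep_d, "left")
  if (plan$dephosphorylated_side == "acceptor") {
    keep_a <- dephosphorylate(keep_a)
  } else {
    keep_d <- dephosphorylate(keep_d)
  }
  prod_id <- sprintf("%s+%s", acceptor$molecule$id, donor$molecule$id)
  product <- ligate(list(keep_a, keep_d), circularize = TRUE, id = prod_id)
  entry_plasmid(product, c(acceptor$parts, donor$parts),
                backbone_id = acceptor$backbone_id,
                junction_codon = acceptor$junction_codon)
}

#' An ordered assembly design
#'
#' @param parts ordered list of `iflc_part` (domains and linkers).
#' @param name design label; default joins the part ids.
#' @return an object of class `iflc_design`.
#' @export
assembly_design <- function(parts, name = NULL) {
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, logical(1), "iflc_part")))
  if (is.null(name))
    name <- paste(vapply(parts, `[[`, character(1), "id"), collapse = "-")
  structure(list(name = name, parts = parts,
                 protein = chain_protein(parts)), class = "iflc_design")
}

#' @export
print.iflc_design <- function(x, ...) {
  cat(sprintf("<iflc_design> %s: %d parts, %d aa\n", x$name, length(x$parts),
              nchar(x$protein)))
  invisible(x)
}

#' Verify an assembled product against its design
#'
#' The in silico stand-in for Sanger verification: checks that the product's
#' translated insert ORF equals the design's expected protein context exactly
#' and reports the first mismatching residue otherwise. Report-only.
#'
#' @param product an `iflc_entry`.
#' @param expected an `iflc_design` (or list of parts).
#' @return an `iflc_validation` report.
#' @export
verify_fusion <- function(product, expected) {
  stopifnot(inherits(product, "iflc_entry"))
  parts <- if (inherits(expected, "iflc_design")) expected$parts else expected
  got <- translate_orf(product$insert_orf)
  want <- expected_orf_aa(parts)
  v <- data.frame(rule = character(0), position = integer(0),
                  detail = character(0), stringsAsFactors = FALSE)
  if (got != want) {
    ga <- strsplit(got, "")[[1]]; wa <- strsplit(want, "")[[1]]
    m <- min(length(ga), length(wa))
    pos <- which(ga[seq_len(m)] != wa[seq_len(m)])
    pos <- if (length(pos)) pos[1] else m + 1L
    v <- data.frame(rule = "orf_mismatch", position = pos,
                    detail = sprintf("residue %d: got %s, expected %s", pos,
                                     substr(got, pos, pos), substr(want, pos, pos)),
                    stringsAsFactors = FALSE)
  }
  structure(list(part_id = product$molecule$id, violations = v,
                 passed = nrow(v) == 0L), class = "iflc_validation")
}

#' Assemble a design by iterated cycles
#'
#' Left-fold of [ifc_cycle()] over the design's parts: single-Gly ("G")
#' linkers are realized by the junction itself and consume no cycle.
#'
#' @param design an `iflc_design`.
#' @param plasmids named list of `iflc_entry` plasmids keyed by part id
#'   (every non-"G" part must be present).
#' @return the assembled `iflc_entry`.
#' @export
assemble_design <- function(design, plasmids) {
  stopifnot(inherits(design, "iflc_design"))
  blocks <- chain_blocks(design$parts)
  ids <- vapply(blocks, `[[`, character(1), "id")
  missing <- setdiff(ids, names(plasmids))
  if (length(missing))
    stop("missing entry plasmids for parts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  acc <- plasmids[[ids[1L]]]
  for (id in ids[-1L]) acc <- ifc_cycle(acc, plasmids[[id]])
  # re-attach the full chain (incl. implicit G linkers) for bookkeeping
  entry_plasmid(acc$molecule, design$parts, backbone_id = acc$backbone_id,
                junction_codon = acc$junction_codon)
}

#' Transfer a finished fusion to the destination vector
#'
#' Excises the insert from the entry plasmid with BtsI + BsrDI and ligates it
#' between the destination backbone's junction flanks, yielding a circular
#' expression construct whose insert ORF translation is unchanged. The
#' non-palindromic 2-nt overhangs enforce the orientation.
#'
#' @param entry a verified `iflc_entry`.
#' @param destination circular `iflc_duplex` destination vector carrying the
#'   standard cassette with a stuffer (see [make_destination_vector()]).
#' @return circular `iflc_duplex` expression construct with attribute
#'   `"insert_orf"`.
#' @export
transfer_to_destination <- function(entry, destination) {
  stopifnot(inherits(entry, "iflc_entry"), inherits(destination, "iflc_duplex"))
  # refuse unverified products
  vr <- verify_fusion(entry, entry$parts)
  if (!vr$passed) stop("entry plasmid fails verification; transfer refused",
                       call. = FALSE)
  enz <- iflc_enzymes()
  cut2 <- list(enz$BtsI, enz$BsrDI)
  ef <- digest(entry$molecule, cut2)
  ins <- which(!vapply(ef, function(f)
    frag_has_motif(f, "GCAGTG") || frag_has_motif(f, "GCAATG"), logical(1)))
  if (length(ins) != 1L) stop("could not isolate the insert fragment", call. = FALSE)
  insert <- ef[[ins]]
  df <- digest(destination, cut2)
  bb <- which(vapply(df, function(f) frag_has_motif(f, "GCAGTG"), logical(1)))
  if (length(bb) != 1L) stop("destination backbone incompatible", call. = FALSE)
  backbone <- dephosphorylate(orient_junction(df[[bb]], "right"))
  insert <- orient_junction(insert, "left")
  product <- ligate(list(backbone, insert), circularize = TRUE,
                    id = sprintf("pFLinkC-XE:%s", entry$molecule$id))
  top <- canonical_rotation(product)
  product <- duplex(top, "circular", id = product$id)
  r1 <- regexpr("GCAGTG", product$top_strand, fixed = TRUE)
  # rotate so the cassette is contiguous for ORF extraction
  n <- dx_length(product)
  dbls <- paste0(product$top_strand, product$top_strand)
  rot <- substr(dbls, r1, r1 + n - 1L)
  r2 <- regexpr("CATTGC", rot, fixed = TRUE)
  attr(product, "insert_orf") <- substr(rot, 6L, r2 - 1L)
  product
}
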