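#' @importFrom stats coef lm median predict rnorm sd setNames vcov
#' @importFrom utils head read.csv tail write.csv
NULL

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a plain DNA string
#'
#' Internal string helper used throughout the duplex model; operates on the
#' ACGT alphabet (IUPAC ambiguity codes are handled where motifs are parsed).
#'
#' @param x character scalar, DNA 5'->3'.
#' @return character scalar, reverse complement 5'->3'.
#' @keywords internal
revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

complement_chr <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

check_dna_alphabet <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, x))
    stop(sprintf("%s contains characters outside the %s alphabet",
                 what, if (allow_n) "ACGTN" else "ACGT"), call. = FALSE)
  invisible(x)
}

#' Construct a typed fragment end
#'
#' A `fragment_end` describes one extremity of a linear duplex: the protruding
#' single-stranded overhang (read 5'->3' on whichever strand protrudes), its
#' polarity, and whether the terminal 5' phosphate is present.
#'
#' @param overhang character, overhang sequence 5'->3' (`""` for blunt ends).
#' @param polarity one of `"5prime"`, `"3prime"`, `"blunt"`.
#' @param phosphorylated logical, 5'-phosphate present.
#' @return an object of class `iflc_end`.
#' @export
fragment_end <- function(overhang = "", polarity = c("blunt", "5prime", "3prime"),
                         phosphorylated = TRUE) {
  polarity <- match.arg(polarity)
  overhang <- toupper(overhang)
  check_dna_alphabet(overhang, what = "overhang")
  if (polarity == "blunt" && nzchar(overhang))
    stop("blunt ends must have an empty overhang", call. = FALSE)
  if (polarity != "blunt" && !nzchar(overhang))
    stop("sticky ends must have a non-empty overhang", call. = FALSE)
  structure(list(overhang = overhang, polarity = polarity,
                 phosphorylated = isTRUE(phosphorylated)),
            class = "iflc_end")
}

blunt_end <- function(phosphorylated = TRUE) fragment_end("", "blunt", phosphorylated)

#' Construct a double-stranded DNA molecule
#'
#' Molecules are stored by their physical top strand (5'->3'). For linear
#' molecules each end is a [fragment_end()]; overhang nucleotides carried by
#' the *bottom* strand (a 3' overhang on the left end, a 5' overhang on the
#' right end) are represented only in the end object, so that the top-strand
#' length is exactly conserved by digestion and ligation.
#'
#' @param top_strand character, top strand 5'->3' (ACGT; N allowed with
#'   `allow_n = TRUE` for scratch sequences).
#' @param topology `"linear"` or `"circular"`.
#' @param left_end,right_end [fragment_end()] objects (linear only).
#' @param id optional label.
#' @param allow_n permit N in the sequence (rejected for parts).
#' @return an object of class `iflc_duplex`.
#' @export
duplex <- function(top_strand, topology = c("linear", "circular"),
                   left_end = blunt_end(), right_end = blunt_end(),
                   id = "", allow_n = FALSE) {
  topology <- match.arg(topology)
  top_strand <- toupper(top_strand)
  check_dna_alphabet(top_strand, allow_n = allow_n, what = "top strand")
  if (!nzchar(top_strand)) stop("empty molecule", call. = FALSE)
  if (topology == "circular") {
    left_end <- NULL
    right_end <- NULL
  } else {
    stopifnot(inherits(left_end, "iflc_end"), inherits(right_end, "iflc_end"))
    # a top-protruding overhang must actually be present in the top strand
    need <- nchar(top_strand)
    ov <- nchar(left_end$overhang) * (left_end$polarity == "5prime") +
      nchar(right_end$overhang) * (right_end$polarity == "3prime")
    if (ov > need) stop("overhangs longer than the molecule", call. = FALSE)
  }
  structure(list(top_strand = top_strand, topology = topology,
                 left_end = left_end, right_end = right_end, id = id),
            class = "iflc_duplex")
}

#' @export
print.iflc_duplex <- function(x, ...) {
  cat(sprintf("<iflc_duplex> %s %s, %d nt%s\n",
              if (nzchar(x$id)) x$id else "(unnamed)", x$topology,
              dx_length(x),
              if (x$topology == "linear")
                sprintf(" [%s|%s]", end_label(x$left_end), end_label(x$right_end))
              else ""))
  s <- x$top_strand
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
  invisible(x)
}

end_label <- function(e) {
  if (is.null(e)) return("")
  if (e$polarity == "blunt") return(if (e$phosphorylated) "blunt" else "blunt(deP)")
  sprintf("%s'%s%s", substr(e$polarity, 1, 1), e$overhang,
          if (e$phosphorylated) "" else "(deP)")
}

#' Length of a duplex in base pairs
#'
#' Top-strand length; overhang nucleotides are counted exactly once across a
#' junction (the strand that physically carries them).
#'
#' @param x an `iflc_duplex`.
#' @return integer length.
#' @export
dx_length <- function(x) nchar(x$top_strand)

#' Reverse-complement (flip) a duplex
#'
#' Swaps the two strands: the new top strand is the old bottom strand read
#' 5'->3', and the left/right ends exchange places (polarity and overhang
#' sequence are invariant under flipping).
#'
#' @param x a linear or circular `iflc_duplex`.
#' @return the flipped molecule.
#' @export
reverse_duplex <- function(x) {
  if (x$topology == "circular")
    return(duplex(revcomp(x$top_strand), "circular", id = x$id, allow_n = TRUE))
  duplex(bottom_strand(x), "linear",
         left_end = x$right_end, right_end = x$left_end, id = x$id, allow_n = TRUE)
}

# physical bottom strand 5'->3' (right to left over the molecule)
bottom_strand <- function(x) {
  stopifnot(x$topology == "linear")
  top <- x$top_strand
  n <- nchar(top)
  lo <- if (x$left_end$polarity == "5prime") nchar(x$left_end$overhang) else 0L
  hi <- if (x$right_end$polarity == "3prime") nchar(x$right_end$overhang) else 0L
  dup <- substr(top, lo + 1L, n - hi)   # double-stranded core
  paste0(if (x$right_end$polarity == "5prime") x$right_end$overhang else "",
         revcomp(dup),
         if (x$left_end$polarity == "3prime") x$left_end$overhang else "")
}

#' Canonical rotation of a circular molecule
#'
#' The lexicographically minimal rotation of the top strand; defines equality
#' of circular molecules (a plasmid religated from its own fragments is the
#' same molecule whatever the ligation order started from).
#'
#' @param x circular `iflc_duplex` or plain string.
#' @return character, canonical top strand.
#' @export
canonical_rotation <- function(x) {
  s <- if (inherits(x, "iflc_duplex")) x$top_strand else x
  n <- nchar(s)
  if (n == 0L) return(s)
  dbl <- paste0(s, s)
  rots <- vapply(seq_len(n), function(i) substr(dbl, i, i + n - 1L), character(1))
  min(rots)
}

#' Test circular/linear molecule identity
#'
#' Circular molecules compare equal up to rotation (and flip if
#' `ignore_strand`); linear molecules compare by top strand and ends.
#'
#' @param a,b `iflc_duplex` objects.
#' @param ignore_strand also accept the flipped molecule as identical.
#' @return logical.
#' @export
duplex_identical <- function(a, b, ignore_strand = TRUE) {
  if (a$topology != b$topology) return(FALSE)
  if (a$topology == "circular") {
    if (canonical_rotation(a) == canonical_rotation(b)) return(TRUE)
    if (ignore_strand &&
        canonical_rotation(revcomp(a$top_strand)) == canonical_rotation(b))
      return(TRUE)
    return(FALSE)
  }
  same <- function(u, v) {
    identical(u$top_strand, v$top_strand) &&
      identical(u$left_end[c("overhang", "polarity")],
                v$left_end[c("overhang", "polarity")]) &&
      identical(u$right_end[c("overhang", "polarity")],
                v$right_end[c("overhang", "polarity")])
  }
  same(a, b) || (ignore_strand && same(reverse_duplex(a), b))
}

## ---- restriction enzymes ----------------------------------------------------

IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
               S = "[GC]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
               D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_regex <- function(motif) {
  ch <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(ch, names(IUPAC_MAP))
  if (length(bad))
    stop(sprintf("invalid IUPAC symbol(s) in motif: %s", paste(bad, collapse = ",")),
         call. = FALSE)
  paste0(IUPAC_MAP[ch], collapse = "")
}

iupac_revcomp <- function(motif) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(toupper(motif), "")[[1]]), collapse = ""))
}

#' Define a restriction enzyme
#'
#' Cut offsets follow the REBASE convention, signed relative to the 3'
#' boundary of the recognition site on the top strand: BtsI = GCAGTG(2/0)
#' gives `cut_top = 2, cut_bottom = 0` (a 2-nt 3' overhang); EcoRI G^AATTC
#' gives `cut_top = -5, cut_bottom = -1` (a 4-nt 5' overhang).
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition motif (top strand).
#' @param cut_top,cut_bottom signed cut offsets.
#' @return an object of class `iflc_enzyme` with derived `overhang_length`
#'   and `polarity`.
#' @export
restriction_enzyme <- function(name, recognition, cut_top, cut_bottom) {
  iupac_regex(recognition)  # validates
  len <- abs(cut_top - cut_bottom)
  polarity <- if (cut_top == cut_bottom) "blunt"
  else if (cut_top > cut_bottom) "3prime" else "5prime"
  structure(list(name = name, recognition = toupper(recognition),
                 cut_top = as.integer(cut_top), cut_bottom = as.integer(cut_bottom),
                 overhang_length = as.integer(len), polarity = polarity,
                 palindromic = toupper(recognition) == iupac_revcomp(recognition)),
            class = "iflc_enzyme")
}

#' @export
print.iflc_enzyme <- function(x, ...) {
  cat(sprintf("<iflc_enzyme> %s %s(%d/%d): %d-nt %s overhang\n", x$name,
              x$recognition, x$cut_top, x$cut_bottom, x$overhang_length,
              x$polarity))
  invisible(x)
}

#' Load enzyme definitions from a YAML config file
#'
#' @param path YAML file with entries `name: {recognition, cut_top, cut_bottom}`;
#'   defaults to the bundled definitions of BtsI, BsrDI, EcoRI and SpeI.
#' @return named list of [restriction_enzyme()] objects.
#' @export
load_enzymes <- function(path = system.file("extdata", "enzymes.yaml",
                                            package = "iflinkc")) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    e <- cfg[[nm]]
    restriction_enzyme(nm, e$recognition, e$cut_top, e$cut_bottom)
  })
  names(out) <- names(cfg)
  out
}

.iflc_env <- new.env(parent = emptyenv())

#' Default iFLinkC enzyme set
#'
#' BtsI GCAGTG(2/0), BsrDI GCAATG(2/0) (2-nt 3' overhangs), EcoRI G^AATTC and
#' SpeI A^CTAGT (4-nt 5' overhangs), read once from the bundled config.
#'
#' @return named list of `iflc_enzyme` objects.
#' @export
iflc_enzymes <- function() {
  if (is.null(.iflc_env$enzymes)) .iflc_env$enzymes <- load_enzymes()
  .iflc_env$enzymes
}

## ---- site scanning ----------------------------------------------------------

match_all <- function(subject, pattern_regex) {
  m <- gregexpr(sprintf("(?=%s)", pattern_regex), subject, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L   # 0-based
}

#' Scan a duplex for restriction sites
#'
#' Finds every occurrence of the recognition motif on both strands. Positions
#' are 0-based, half-open on the top strand; a bottom-strand match is reported
#' at the start of the reverse-complement motif on the top strand. Palindromic
#' sites are reported once (top strand). Circular molecules are scanned across
#' the origin by doubling the sequence.
#'
#' @param seq an `iflc_duplex`.
#' @param enzyme an `iflc_enzyme`.
#' @return data.frame with columns `position` (0-based) and `strand`
#'   (`"top"`/`"bottom"`).
#' @export
scan_sites <- function(seq, enzyme) {
  stopifnot(inherits(seq, "iflc_duplex"), inherits(enzyme, "iflc_enzyme"))
  s <- seq$top_strand
  n <- nchar(s)
  subject <- if (seq$topology == "circular") paste0(s, s) else s
  fwd <- match_all(subject, iupac_regex(enzyme$recognition))
  if (enzyme$palindromic) {
    rev <- integer(0)
  } else {
    rev <- match_all(subject, iupac_regex(iupac_revcomp(enzyme$recognition)))
  }
  if (seq$topology == "circular") {
    fwd <- unique(fwd[fwd < n])
    rev <- unique(rev[rev < n])
  }
  out <- data.frame(position = c(fwd, rev),
                    strand = rep(c("top", "bottom"), c(length(fwd), length(rev))),
                    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

# cut coordinates (points between bases, 0..L on top-strand coordinates) for
# one site; returns c(top_cut, bottom_cut), possibly outside [0, L] for
# linear molecules (caller validates)
site_cuts <- function(site_pos, strand, enzyme, motif_len) {
  if (strand == "top") {
    e <- site_pos + motif_len
    c(top = e + enzyme$cut_top, bottom = e + enzyme$cut_bottom)
  } else {
    s <- site_pos
    c(top = s - enzyme$cut_bottom, bottom = s - enzyme$cut_top)
  }
}

#' Digest a molecule with one or more restriction enzymes
#'
#' Complete digestion: every site of every enzyme is cut. Fragments carry
#' typed, phosphorylated [fragment_end()]s whose overhang sequence and
#' polarity derive from the enzyme's staggered cut. Top-strand length is
#' conserved: the fragment lengths sum to the parent length with each
#' overhang counted once. A circular molecule with k sites yields k linear
#' fragments; a molecule with no sites is returned unchanged.
#'
#' @param seq an `iflc_duplex`.
#' @param enzymes a single `iflc_enzyme` or list of them.
#' @return list of `iflc_duplex` fragments in top-strand order.
#' @export
digest <- function(seq, enzymes) {
  stopifnot(inherits(seq, "iflc_duplex"))
  if (inherits(enzymes, "iflc_enzyme")) enzymes <- list(enzymes)
  top <- seq$top_strand
  n <- nchar(top)

  cuts <- list()
  for (enz in enzymes) {
    sites <- scan_sites(seq, enz)
    if (!nrow(sites)) next
    ml <- nchar(enz$recognition)
    for (i in seq_len(nrow(sites))) {
      cc <- site_cuts(sites$position[i], sites$strand[i], enz, ml)
      if (seq$topology == "circular") {
        cc <- ((cc %% n) + n) %% n
        # keep the pair coherent across the origin: express bottom relative to top
        d <- cc["bottom"] - cc["top"]
        if (d > n / 2) cc["bottom"] <- cc["bottom"] - n
        if (d < -n / 2) cc["bottom"] <- cc["bottom"] + n
      } else if (cc["top"] < 0 || cc["top"] > n || cc["bottom"] < 0 || cc["bottom"] > n) {
        stop(sprintf(
          "degenerate input: %s site at position %d cuts outside the molecule",
          enz$name, sites$position[i]), call. = FALSE)
      }
      cuts[[length(cuts) + 1L]] <- list(top = unname(cc["top"]),
                                        bottom = unname(cc["bottom"]))
    }
  }
  if (!length(cuts)) return(list(seq))

  tops <- vapply(cuts, `[[`, numeric(1), "top")
  cuts <- cuts[order(tops)]
  tops <- sort(tops)
  if (anyDuplicated(tops))
    stop("degenerate input: coincident cut positions (sites too close)",
         call. = FALSE)
  # staggered cuts must not interleave: each cut's span (between its top and
  # bottom scissions) has to clear its neighbours'
  spans <- vapply(cuts, function(cc) range(cc$top, cc$bottom), numeric(2))
  k <- length(cuts)
  ok_pair <- function(i, j, wrap = 0) spans[2, i] <= spans[1, j] + wrap
  if (k > 1L) {
    for (i in seq_len(k - 1L))
      if (!ok_pair(i, i + 1L))
        stop("degenerate input: overlapping staggered cuts (sites too close)",
             call. = FALSE)
  }
  if (seq$topology == "circular" && !ok_pair(k, 1L, wrap = n))
    stop("degenerate input: overlapping staggered cuts (sites too close)",
         call. = FALSE)
  if (seq$topology == "circular" && k == 1L &&
      abs(cuts[[1L]]$top - cuts[[1L]]$bottom) > n)
    stop("degenerate input: cut span exceeds the molecule", call. = FALSE)

  # substring on top-strand coordinates with circular wrap-around; `from` may
  # be negative and `to` may exceed n (overhang windows near the origin)
  dbl <- paste0(top, top)
  cyc_abs <- function(from, to) {
    len <- to - from
    start <- ((from %% n) + n) %% n
    substr(dbl, start + 1L, start + len)
  }
  frag_left_end <- function(cut) {  # end created on the fragment RIGHT of a cut
    t <- cut$top; b <- cut$bottom
    if (t > b) fragment_end(revcomp(cyc_abs(b, t)), "3prime", TRUE)
    else if (t < b) fragment_end(cyc_abs(t, b), "5prime", TRUE)
    else blunt_end(TRUE)
  }
  frag_right_end <- function(cut) {  # end on the fragment LEFT of a cut
    t <- cut$top; b <- cut$bottom
    if (t > b) fragment_end(cyc_abs(b, t), "3prime", TRUE)
    else if (t < b) fragment_end(revcomp(cyc_abs(t, b)), "5prime", TRUE)
    else blunt_end(TRUE)
  }
  frags <- list()
  k <- length(cuts)
  if (seq$topology == "linear") {
    bounds_t <- c(0, tops, n)
    for (i in seq_len(k + 1L)) {
      le <- if (i == 1L) seq$left_end else frag_left_end(cuts[[i - 1L]])
      re <- if (i == k + 1L) seq$right_end else frag_right_end(cuts[[i]])
      frags[[i]] <- duplex(substr(top, bounds_t[i] + 1L, bounds_t[i + 1L]),
                           "linear", left_end = le, right_end = re,
                           id = sprintf("%s.f%d", seq$id, i), allow_n = TRUE)
    }
  } else {
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      from <- tops[i]
      to <- if (i == k) tops[j] + n else tops[j]
      frags[[i]] <- duplex(cyc_abs(from, to), "linear",
                           left_end = frag_left_end(cuts[[i]]),
                           right_end = frag_right_end(cuts[[j]]),
                           id = sprintf("%s.f%d", seq$id, i), allow_n = TRUE)
    }
  }
  frags
}

#' Remove 5'-terminal phosphates from a linear fragment
#'
#' Marks both ends `phosphorylated = FALSE`; the sequence is untouched.
#' Idempotent. Circular molecules have no free ends: returned unchanged with
#' a warning.
#'
#' @param seq an `iflc_duplex`.
#' @return the dephosphorylated molecule.
#' @export
dephosphorylate <- function(seq) {
  stopifnot(inherits(seq, "iflc_duplex"))
  if (seq$topology == "circular") {
    warning("dephosphorylate: circular molecule has no free ends; no-op")
    return(seq)
  }
  seq$left_end$phosphorylated <- FALSE
  seq$right_end$phosphorylated <- FALSE
  seq
}

#' Can two fragment ends be ligated?
#'
#' True iff the polarities match, the overhang of `a` is the reverse
#' complement of the overhang of `b`, and at least one of the two ends still
#' carries a 5' phosphate (T4 ligase seals at most a nick otherwise).
#' Blunt-blunt joining requires `blunt_ligation = TRUE` (off by default;
#' the iFLinkC workflow never uses it).
#'
#' @param a,b [fragment_end()] objects: `a` the upstream fragment's right end,
#'   `b` the downstream fragment's left end.
#' @param blunt_ligation allow blunt joins.
#' @return logical.
#' @export
ends_compatible <- function(a, b, blunt_ligation = FALSE) {
  stopifnot(inherits(a, "iflc_end"), inherits(b, "iflc_end"))
  if (!(a$phosphorylated || b$phosphorylated)) return(FALSE)
  if (a$polarity == "blunt" && b$polarity == "blunt") return(isTRUE(blunt_ligation))
  if (a$polarity != b$polarity) return(FALSE)
  identical(a$overhang, revcomp(b$overhang))
}

#' Ligate an ordered chain of fragments
#'
#' Joins the fragments in the given (explicit) order, checking every junction
#' with [ends_compatible()]; with `circularize = TRUE` the terminal ends must
#' also be compatible and the product is circular. The junction duplex is
#' reconstituted from the two overhangs, counted once, so religating a
#' molecule's own digestion fragments in original order reconstructs the
#' parent exactly (up to rotation when circular).
#'
#' @param parts list of linear `iflc_duplex` fragments, in order.
#' @param circularize close the chain into a circle.
#' @param blunt_ligation allow blunt junctions.
#' @param id label for the product.
#' @return an `iflc_duplex` (circular if `circularize`).
#' @export
ligate <- function(parts, circularize = FALSE, blunt_ligation = FALSE, id = "") {
  if (inherits(parts, "iflc_duplex")) parts <- list(parts)
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, logical(1), "iflc_duplex")))
  if (any(vapply(parts, function(p) p$topology, character(1)) == "circular"))
    stop("ligate: all parts must be linear", call. = FALSE)
  k <- length(parts)
  for (i in seq_len(k - 1L)) {
    if (!ends_compatible(parts[[i]]$right_end, parts[[i + 1L]]$left_end,
                         blunt_ligation))
      stop(sprintf("ligation error: incompatible junction between parts %d (%s) and %d (%s)",
                   i, end_label(parts[[i]]$right_end),
                   i + 1L, end_label(parts[[i + 1L]]$left_end)), call. = FALSE)
  }
  top <- paste0(vapply(parts, `[[`, character(1), "top_strand"), collapse = "")
  if (circularize) {
    if (!ends_compatible(parts[[k]]$right_end, parts[[1L]]$left_end, blunt_ligation))
      stop(sprintf("ligation error: incompatible circularization junction (%s vs %s)",
                   end_label(parts[[k]]$right_end), end_label(parts[[1L]]$left_end)),
           call. = FALSE)
    duplex(top, "circular", id = id, allow_n = TRUE)
  } else {
    duplex(top, "linear", left_end = parts[[1L]]$left_end,
           right_end = parts[[k]]$right_end, id = id, allow_n = TRUE)
  }
}
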