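## Parts registry: linker/domain parts, codon-policy reverse translation,
## forbidden-site validation.

# E. coli K-12 synonymous codons, ordered by decreasing usage. GGT leads the
# Gly block so the preferred Gly codon coincides with the junction codon used
# by the assembly engine.
ECOLI_CODONS <- list(
  A = c("GCG", "GCC", "GCA", "GCT"),
  R = c("CGT", "CGC", "CGG", "CGA", "AGA", "AGG"),
  N = c("AAC", "AAT"),
  D = c("GAT", "GAC"),
  C = c("TGC", "TGT"),
  Q = c("CAG", "CAA"),
  E = c("GAA", "GAG"),
  G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  L = c("CTG", "TTA", "TTG", "CTT", "CTC", "CTA"),
  K = c("AAA", "AAG"),
  M = "ATG",
  F = c("TTT", "TTC"),
  P = c("CCG", "CCA", "CCT", "CCC"),
  S = c("AGC", "TCT", "TCC", "AGT", "TCG", "TCA"),
  T = c("ACC", "ACG", "ACT", "ACA"),
  W = "TGG",
  Y = c("TAT", "TAC"),
  V = c("GTG", "GTT", "GTC", "GTA")
)

#' Default codon policy
#'
#' @param organism only `"ecoli"` is bundled; the policy is a plain named
#'   list (amino acid -> codons in preference order) so users can supply
#'   their own.
#' @param max_repeat longest direct repeat (nt) tolerated in synthesized
#'   linker DNA; repeats longer than this trigger codon rotation.
#' @return list with elements `codons` and `max_repeat`.
#' @export
codon_policy <- function(organism = "ecoli", max_repeat = 8L) {
  stopifnot(organism == "ecoli")
  list(codons = ECOLI_CODONS, max_repeat = as.integer(max_repeat))
}

#' Translate an in-frame open reading frame
#'
#' Standard-table translation via `Biostrings::GENETIC_CODE`. Stop codons are
#' reported as `*`, never truncated.
#'
#' @param dna DNA string, length divisible by 3.
#' @return amino-acid string.
#' @export
translate_orf <- function(dna) {
  dna <- toupper(dna)
  check_dna_alphabet(dna, what = "ORF")
  if (nchar(dna) %% 3L != 0L)
    stop("frame error: ORF length not divisible by 3", call. = FALSE)
  if (!nzchar(dna)) return("")
  codons <- substring(dna, seq(1, nchar(dna), 3L), seq(3, nchar(dna), 3L))
  paste0(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Forbidden restriction sites of the iFLinkC chemistry
#'
#' Scans a plain DNA string for BsrDI, BtsI, EcoRI and SpeI sites on both
#' strands (positions 0-based on the given strand's top coordinates).
#'
#' @param dna DNA string.
#' @param enzymes enzyme list, default [iflc_enzymes()].
#' @return data.frame with columns `enzyme`, `position`, `strand`.
#' @export
forbidden_sites <- function(dna, enzymes = iflc_enzymes()) {
  dx <- duplex(toupper(dna), "linear", allow_n = TRUE)
  out <- lapply(names(enzymes), function(nm) {
    hits <- scan_sites(dx, enzymes[[nm]])
    if (!nrow(hits)) return(NULL)
    cbind(enzyme = nm, hits)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(enzyme = character(0), position = integer(0),
                      strand = character(0))
  out
}

# any direct repeat strictly longer than `max_repeat` nt?
has_long_repeat <- function(dna, max_repeat = 8L) {
  k <- max_repeat + 1L
  n <- nchar(dna)
  if (n < 2L * 1L || n < k + 1L) return(FALSE)
  kmers <- substring(dna, 1:(n - k + 1L), k:n)
  anyDuplicated(kmers) > 0L
}

#' Reverse translate a peptide under a codon policy
#'
#' Deterministic left-to-right synthesis: each residue takes the most
#' preferred codon that does not create a forbidden restriction site (either
#' strand) or a direct repeat longer than the policy's `max_repeat` in the
#' sequence built so far; on conflict the synonymous codons are rotated in
#' preference order. This emulates ordering synthesizable, clone-compatible
#' linker DNA despite high GC content and repeats.
#'
#' @param aa_seq amino-acid string (standard 20 residues).
#' @param policy a [codon_policy()].
#' @param context optional DNA prepended for boundary checking only (e.g. an
#'   upstream vector flank); not returned.
#' @return DNA string, `3 * nchar(aa_seq)` nt, translating back to `aa_seq`.
#' @export
reverse_translate_linker <- function(aa_seq, policy = codon_policy(), context = "") {
  aa <- strsplit(toupper(aa_seq), "")[[1]]
  bad <- setdiff(aa, names(policy$codons))
  if (length(bad))
    stop(sprintf("non-standard amino acid(s): %s", paste(unique(bad), collapse = ",")),
         call. = FALSE)
  ok <- function(s) {
    !nrow(forbidden_sites(s)) && !has_long_repeat(s, policy$max_repeat)
  }
  # deterministic depth-first search, left to right in codon-preference
  # order, backtracking when no synonymous codon extends the prefix; the
  # first solution found is therefore the rotation-minimal one
  n <- length(aa)
  choice <- integer(n)      # preference index used at each residue
  prefix <- character(n + 1L)
  prefix[1L] <- context
  i <- 1L
  nodes <- 0L
  deepest <- 0L
  while (i >= 1L && i <= n) {
    cods <- policy$codons[[aa[i]]]
    placed <- FALSE
    for (j in seq(choice[i] + 1L, length.out = length(cods) - choice[i])) {
      nodes <- nodes + 1L
      if (nodes > 20000L)
        stop("reverse translation search exhausted its budget", call. = FALSE)
      if (ok(paste0(prefix[i], cods[j]))) {
        choice[i] <- j
        prefix[i + 1L] <- paste0(prefix[i], cods[j])
        placed <- TRUE
        break
      }
    }
    if (placed) {
      deepest <- max(deepest, i)
      i <- i + 1L
    } else {
      choice[i] <- 0L
      i <- i - 1L  # backtrack and advance the previous residue's codon
    }
  }
  if (i == 0L)
    stop(sprintf(
      "reverse translation failed: no forbidden-site-free, repeat-compatible encoding exists under the policy (blocked near residue %d, window ...%s)",
      max(deepest, 1L),
      substr(prefix[max(deepest, 1L)],
             max(1L, nchar(prefix[max(deepest, 1L)]) - 11L),
             nchar(prefix[max(deepest, 1L)]))), call. = FALSE)
  substr(prefix[n + 1L], nchar(context) + 1L, nchar(prefix[n + 1L]))
}

#' Construct a part (linker or functional domain)
#'
#' @param id part label, e.g. `"GPG"`, `"P9"`, `"FKBP12"`.
#' @param role `"linker"` or `"domain"`.
#' @param aa_seq amino-acid sequence.
#' @param dna_seq coding DNA; if `NULL` for a linker it is synthesized with
#'   [reverse_translate_linker()]; domains may ship as sequence-less stubs.
#' @param flexibility_class `"short"`, `"flexible"`, `"rigid"`,
#'   `"semi-flexible"` or `"n/a"` (domains).
#' @param description free text.
#' @return an object of class `iflc_part` with `length_aa = nchar(aa_seq)`.
#' @export
part <- function(id, role = c("linker", "domain"), aa_seq, dna_seq = NULL,
                 flexibility_class = "n/a", description = "") {
  role <- match.arg(role)
  aa_seq <- toupper(aa_seq)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", aa_seq))
    stop("aa_seq contains non-standard residues", call. = FALSE)
  if (is.null(dna_seq) && role == "linker")
    dna_seq <- synthesize_part_dna(aa_seq)
  if (!is.null(dna_seq)) {
    dna_seq <- toupper(dna_seq)
    check_dna_alphabet(dna_seq, what = "dna_seq")
    if (nchar(dna_seq) %% 3L != 0L)
      stop("dna_seq length not divisible by 3", call. = FALSE)
    if (translate_orf(dna_seq) != aa_seq)
      stop(sprintf("dna_seq of part %s does not translate to aa_seq", id),
           call. = FALSE)
  }
  structure(list(id = id, role = role, aa_seq = aa_seq, dna_seq = dna_seq,
                 flexibility_class = flexibility_class,
                 length_aa = nchar(aa_seq), description = description),
            class = "iflc_part")
}

#' @export
print.iflc_part <- function(x, ...) {
  cat(sprintf("<iflc_part> %s (%s, %s): %d aa%s\n", x$id, x$role,
              x$flexibility_class, x$length_aa,
              if (is.null(x$dna_seq)) " [no DNA attached]" else ""))
  cat(" ", x$aa_seq, "\n")
  invisible(x)
}

#' Load the bundled part catalogue
#'
#' Returns the 15 linker elements of the toolbox (exact peptide sequences,
#' lengths and flexibility classes; linker lengths include the two bridging
#' Gly residues) plus the functional domains as named, length-only stubs —
#' domain coding sequences are user-supplied or fixture-generated, never
#' downloaded.
#'
#' @param what `"all"`, `"linkers"` or `"domains"`.
#' @return named list of `iflc_part` objects.
#' @export
load_catalogue <- function(what = c("all", "linkers", "domains")) {
  what <- match.arg(what)
  read_tab <- function(f) {
    p <- system.file("extdata", f, package = "iflinkc")
    if (!nzchar(p) || !file.size(p)) stop("catalogue file missing or corrupt: ", f)
    read.delim(p, stringsAsFactors = FALSE)
  }
  out <- list()
  if (what %in% c("all", "linkers")) {
    lk <- read_tab("linker_catalogue.tsv")
    if (nrow(lk) != 15L) stop("catalogue file corrupt: expected 15 linkers")
    for (i in seq_len(nrow(lk)))
      out[[lk$id[i]]] <- part(lk$id[i], "linker", lk$aa_seq[i],
                              flexibility_class = lk$class[i],
                              description = lk$description[i])
  }
  if (what %in% c("all", "domains")) {
    dm <- read_tab("domain_catalogue.tsv")
    for (i in seq_len(nrow(dm)))
      out[[dm$id[i]]] <- structure(
        list(id = dm$id[i], role = "domain", aa_seq = NULL, dna_seq = NULL,
             flexibility_class = "n/a", length_aa = dm$length_aa[i],
             description = dm$description[i]),
        class = "iflc_part")
  }
  out
}

#' Validate a part for iFLinkC compatibility
#'
#' Pure report, no mutation: flags every BsrDI/BtsI/EcoRI/SpeI site on either
#' strand of the coding DNA, frame violations, translation mismatches and
#' internal stop codons.
#'
#' @param p an `iflc_part` with DNA attached.
#' @return an object of class `iflc_validation` with fields `part_id`,
#'   `violations` (data.frame rule/position/detail) and `passed`.
#' @export
validate_part <- function(p) {
  stopifnot(inherits(p, "iflc_part"))
  if (is.null(p$dna_seq) || !nzchar(p$dna_seq))
    stop("validate_part: part has no DNA sequence", call. = FALSE)
  v <- data.frame(rule = character(0), position = integer(0),
                  detail = character(0), stringsAsFactors = FALSE)
  add <- function(rule, position, detail)
    rbind(v, data.frame(rule = rule, position = position, detail = detail,
                        stringsAsFactors = FALSE))
  hits <- forbidden_sites(p$dna_seq)
  for (i in seq_len(nrow(hits)))
    v <- add("forbidden_site", hits$position[i],
             sprintf("%s site on %s strand", hits$enzyme[i], hits$strand[i]))
  if (nchar(p$dna_seq) %% 3L != 0L) {
    v <- add("frame", nchar(p$dna_seq), "length not divisible by 3")
  } else {
    tr <- translate_orf(p$dna_seq)
    stops <- gregexpr("*", tr, fixed = TRUE)[[1]]
    if (stops[1] != -1L)
      for (s in stops) v <- add("stop_codon", (s - 1L) * 3L,
                                sprintf("internal stop at residue %d", s))
    if (!is.null(p$aa_seq) && tr != p$aa_seq)
      v <- add("translation_mismatch", 0L, "dna_seq does not encode aa_seq")
  }
  structure(list(part_id = p$id, violations = v, passed = nrow(v) == 0L),
            class = "iflc_validation")
}

#' @export
print.iflc_validation <- function(x, ...) {
  cat(sprintf("<iflc_validation> %s: %s\n", x$part_id,
              if (x$passed) "PASS" else sprintf("FAIL (%d violations)",
                                                nrow(x$violations))))
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}
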