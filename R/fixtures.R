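## Fixture generators: everything the workflow needs that is not printed in
## a catalogue — entry/destination backbones, domain stand-in sequences, and
## simulated plate-reader data. All deterministic under a fixed seed; each
## generator draws from its own derived stream so adding one never shifts
## another's output.

# run expr under a temporary RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a sub-stream seed from a base seed and a stream name (kept < 2^31)
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (abs(as.integer(seed)) %% 1000003L) * 1013L + (h %% 1000L)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

FORBIDDEN_MOTIFS <- c("GCAGTG", "CACTGC", "GCAATG", "CATTGC", "GAATTC", "ACTAGT")

# junction-context compatibility: a part's DNA must stay site-free when
# flanked by the junction Gly codon on either side (none of the forbidden
# motifs contains GGT, so this check also covers any future fusion junction)
junction_clean <- function(dna) {
  s <- paste0(JUNCTION_CODON, dna, JUNCTION_CODON)
  !any(vapply(FORBIDDEN_MOTIFS, grepl, logical(1), x = s, fixed = TRUE))
}

# reverse translation plus junction-context guard: rotates the terminal
# codons if the bare synthesis leaves a boundary-spanning site
synthesize_part_dna <- function(aa_seq, policy = codon_policy()) {
  base <- reverse_translate_linker(aa_seq, policy, context = JUNCTION_CODON)
  if (junction_clean(base)) return(base)
  n <- nchar(base)
  last <- substr(aa_seq, nchar(aa_seq), nchar(aa_seq))
  for (cod in policy$codons[[last]]) {
    cand <- paste0(substr(base, 1L, n - 3L), cod)
    if (junction_clean(cand) && !has_long_repeat(paste0(JUNCTION_CODON, cand),
                                                 policy$max_repeat))
      return(cand)
  }
  stop("could not synthesize junction-compatible DNA for ", aa_seq, call. = FALSE)
}

#' Generate a random stand-in part
#'
#' Draws a random amino-acid sequence of the requested length and synthesizes
#' stop-free, forbidden-site-free, junction-compatible coding DNA for it.
#' Reproducible per seed; used to stand in for functional domains whose real
#' sequences are not bundled (the generated parts are synthetic stand-ins,
#' not the natural sequences).
#'
#' @param length_aa protein length (>= 1).
#' @param role `"domain"` or `"linker"`.
#' @param seed integer seed.
#' @param id part label.
#' @param max_attempts regeneration bound.
#' @return an `iflc_part` passing [validate_part()].
#' @export
random_part_sequence <- function(length_aa, role = "domain", seed = 1L,
                                 id = sprintf("rnd%d_%d", length_aa, seed),
                                 max_attempts = 50L) {
  stopifnot(length_aa >= 1L)
  with_seed(stream_seed(seed, paste0("part:", id)), {
    for (att in seq_len(max_attempts)) {
      aa <- paste(sample(AA20, length_aa, replace = TRUE), collapse = "")
      dna <- try(synthesize_part_dna(aa), silent = TRUE)
      if (inherits(dna, "try-error")) next
      return(part(id, role, aa, dna_seq = dna))
    }
    stop("random_part_sequence: no valid sequence after ", max_attempts,
         " attempts", call. = FALSE)
  })
}

# random DNA free of the forbidden motifs: draw, then mutate any motif hit
scrub_segment <- function(len, max_rounds = 200L) {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  for (round in seq_len(max_rounds)) {
    hit <- NULL
    for (m in FORBIDDEN_MOTIFS) {
      p <- regexpr(m, s, fixed = TRUE)
      if (p > 0) { hit <- as.integer(p); break }
    }
    if (is.null(hit)) return(s)
    pos <- hit + 2L  # middle of the motif
    old <- substr(s, pos, pos)
    substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  stop("scrub_segment failed to converge", call. = FALSE)
}

#' Build a fixture entry plasmid for a part
#'
#' Synthesizes a minimal circular entry backbone (resistance-marker
#' placeholder sequence, ~2.5 kb) around the standard cassette
#' `GCAGTG-GT-core-GGT-CATTGC`, with single EcoRI and SpeI sites placed
#' asymmetrically so both flank-enzyme digests give gel-resolvable
#' fragments. The product satisfies every entry-plasmid invariant.
#'
#' @param p an `iflc_part` with DNA (single-Gly linkers have no plasmid:
#'   they are realized by the junction itself).
#' @param backbone_id `"pL2"` or `"pFD"`.
#' @param seed integer seed.
#' @param segment_lengths backbone segment lengths (cassette->EcoRI,
#'   EcoRI->SpeI, SpeI->cassette).
#' @return an `iflc_entry`.
#' @export
make_entry_plasmid <- function(p, backbone_id = "pL2", seed = 1L,
                               segment_lengths = c(400L, 700L, 1400L)) {
  stopifnot(inherits(p, "iflc_part"))
  if (is_g1(p))
    stop("the single-'G' linker is a junction, not an insert; it has no entry plasmid",
         call. = FALSE)
  if (is.null(p$dna_seq)) stop("part ", p$id, " has no DNA attached", call. = FALSE)
  vp <- validate_part(p)
  if (!vp$passed)
    stop("part ", p$id, " fails validation; refusing to build a plasmid",
         call. = FALSE)
  if (!junction_clean(p$dna_seq))
    stop("part ", p$id, " DNA is not junction-compatible", call. = FALSE)
  cassette <- paste0("GCAGTG", "GT", chain_core_dna(list(p)), "GGT", "CATTGC")
  with_seed(stream_seed(seed, paste0("plasmid:", backbone_id, ":", p$id)), {
    for (att in 1:25) {
      top <- paste0(cassette,
                    scrub_segment(segment_lengths[1]), "GAATTC",
                    scrub_segment(segment_lengths[2]), "ACTAGT",
                    scrub_segment(segment_lengths[3]))
      mol <- duplex(top, "circular", id = sprintf("%s-%s", backbone_id, p$id))
      ep <- try(entry_plasmid(mol, list(p), backbone_id = backbone_id),
                silent = TRUE)
      if (!inherits(ep, "try-error")) return(ep)
    }
    stop("make_entry_plasmid: could not build a valid backbone", call. = FALSE)
  })
}

#' Build the fixture destination vector
#'
#' A circular expression vector carrying an ATG + tag leader in frame with
#' the standard junction cassette around a stuffer, and a stop codon after
#' the downstream flank, emulating the role of the pFLinkC-XE destination
#' vector (synthetic stand-in; the real vector sequence is not published).
#'
#' @param seed integer seed.
#' @param stuffer_aa length of the throwaway stuffer ORF (default 80 aa).
#' @param segment_lengths backbone segment lengths as in
#'   [make_entry_plasmid()].
#' @return circular `iflc_duplex`.
#' @export
make_destination_vector <- function(seed = 1L, stuffer_aa = 80L,
                                    segment_lengths = c(400L, 700L, 1400L)) {
  with_seed(stream_seed(seed, "destination"), {
    stuffer <- random_part_sequence(stuffer_aa, "domain", seed = seed,
                                    id = "stuffer")
    # leader: Met + Strep-tag-like leader, in frame with GCAGTG (Ala-Val)
    leader_aa <- "WSHPQFEK"
    leader <- reverse_translate_linker(leader_aa)
    tail_aa <- "SAWSHPQFEK"
    tail <- reverse_translate_linker(tail_aa)
    for (att in 1:25) {
      top <- paste0("ATG", leader,
                    "GCAGTG", "GT", chain_core_dna(list(stuffer)), "GGT", "CATTGC",
                    tail, "TAA",
                    scrub_segment(segment_lengths[1]), "GAATTC",
                    scrub_segment(segment_lengths[2]), "ACTAGT",
                    scrub_segment(segment_lengths[3]))
      mol <- duplex(top, "circular", id = "pFLinkC-XE")
      counts <- vapply(iflc_enzymes(), function(e) nrow(scan_sites(mol, e)),
                       integer(1))
      if (all(counts == 1L)) return(mol)
    }
    stop("make_destination_vector: could not build a valid backbone",
         call. = FALSE)
  })
}

#' Simulate a plate-reader kinetic trace
#'
#' `rfu = background + rate * t`, optionally capped at a plateau (substrate
#' exhaustion), with multiplicative Gaussian noise
#' `rfu_obs = rfu * (1 + sd * z)`. Seed-reproducible.
#'
#' @param rate true initial rate, RFU/s.
#' @param duration assay length in seconds.
#' @param n_points number of reads.
#' @param noise multiplicative Gaussian SD (default 0.02).
#' @param seed integer seed.
#' @param plateau_at optional RFU ceiling.
#' @param background baseline RFU at t = 0.
#' @param well,variant,ligand,concentration trace annotations.
#' @return an `iflc_trace`.
#' @export
simulate_trace <- function(rate, duration = 600, n_points = 61L, noise = 0.02,
                           seed = 1L, plateau_at = NULL, background = 50,
                           well = "", variant = "", ligand = NA_character_,
                           concentration = NA_real_) {
  times <- seq(0, duration, length.out = n_points)
  mu <- background + rate * times
  if (!is.null(plateau_at)) mu <- pmin(mu, plateau_at)
  rfu <- with_seed(stream_seed(seed, paste0("trace:", well, ":", variant)),
                   mu * (1 + noise * rnorm(n_points)))
  kinetic_trace(times, rfu, well = well, variant = variant, ligand = ligand,
                concentration = concentration)
}

#' Simulate an initial-rate dose series
#'
#' Rates from the named binding/inhibition model over a dose grid (default:
#' 12 log-spaced concentrations from 50 nM to 1 mM, the titration range used
#' for switch characterization), with multiplicative Gaussian noise.
#'
#' @param model `"kd-hyperbolic"`, `"kd-tight"`, `"ki-hyperbolic"` or
#'   `"ki-tight"`.
#' @param true_K molar constant of the generating model.
#' @param enzyme_conc molar switch/protease concentration E.
#' @param doses molar dose grid; default 12 points, 50e-9 to 1e-3.
#' @param noise multiplicative Gaussian SD (0 = exact curve).
#' @param seed integer seed.
#' @param v0 basal rate (RFU/s); for ki models the uninhibited rate.
#' @param vmax saturating rate for kd models.
#' @return list with `doses`, `rates`, `model`, `true_K`, `enzyme_conc`.
#' @export
simulate_dose_series <- function(model = c("kd-hyperbolic", "kd-tight",
                                           "ki-hyperbolic", "ki-tight"),
                                 true_K, enzyme_conc,
                                 doses = exp(seq(log(50e-9), log(1e-3),
                                                 length.out = 12)),
                                 noise = 0, seed = 1L, v0 = 0.5, vmax = 60) {
  model <- match.arg(model)
  tight <- grepl("tight", model)
  f <- binding_fraction(doses, true_K, enzyme_conc, tight)
  mu <- if (grepl("^kd", model)) v0 + (vmax - v0) * f else v0 * (1 - f)
  rates <- if (noise > 0)
    with_seed(stream_seed(seed, paste0("doses:", model)),
              mu * (1 + noise * rnorm(length(mu))))
  else mu
  list(doses = doses, rates = rates, model = model, true_K = true_K,
       enzyme_conc = enzyme_conc)
}

#' Write a fixture bundle to disk
#'
#' Backbones as GenBank, parts as FASTA (nt), traces and dose series as CSV —
#' the offline input set for the command-line workflow.
#'
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(seed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  doms <- load_catalogue("domains")
  parts <- lapply(doms[c("FRB", "FKBP12")], function(d)
    random_part_sequence(d$length_aa, "domain", seed = seed, id = d$id))
  linkers <- load_catalogue("linkers")
  gpg <- linkers$GPG
  eps <- lapply(parts, make_entry_plasmid, backbone_id = "pFD", seed = seed)
  for (ep in eps)
    write_genbank(ep$molecule, file.path(dir, paste0(ep$molecule$id, ".gb")))
  write_genbank(make_destination_vector(seed), file.path(dir, "pFLinkC-XE.gb"))
  mols <- lapply(c(parts, list(gpg)), function(p)
    duplex(p$dna_seq, "linear", id = p$id))
  write_duplex_fasta(mols, file.path(dir, "parts_nt.fasta"))
  tr <- simulate_trace(5, seed = seed, well = "A1", variant = "demo")
  write.csv(data.frame(well = tr$well, time_s = tr$times, rfu = tr$rfu),
            file.path(dir, "traces.csv"), row.names = FALSE)
  ds <- simulate_dose_series("kd-tight", 20e-9, 20e-9, seed = seed)
  write.csv(data.frame(dose_M = ds$doses, rate = ds$rates),
            file.path(dir, "dose_series.csv"), row.names = FALSE)
  invisible(dir)
}
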