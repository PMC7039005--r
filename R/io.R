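## Molecule I/O: FASTA (Biostrings) and a minimal GenBank flat-file
## reader/writer (LOCUS topology, FEATURES, ORIGIN). Unmodified records
## round-trip byte-exactly through write -> read -> write.

#' Read DNA molecules from FASTA
#'
#' FASTA carries no topology; molecules are assumed linear with blunt,
#' phosphorylated ends.
#'
#' @param path FASTA file.
#' @return list of `iflc_duplex` objects.
#' @export
read_duplex_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(ss), function(i)
    duplex(as.character(ss[[i]]), "linear", id = names(ss)[i], allow_n = TRUE))
  names(out) <- names(ss)
  out
}

#' Write DNA molecules to FASTA
#'
#' @param molecules list of `iflc_duplex` (or a single one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_duplex_fasta <- function(molecules, path) {
  if (inherits(molecules, "iflc_duplex")) molecules <- list(molecules)
  seqs <- vapply(molecules, `[[`, character(1), "top_strand")
  ids <- vapply(molecules, `[[`, character(1), "id")
  ids[!nzchar(ids)] <- paste0("seq", seq_along(ids))[!nzchar(ids)]
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a molecule as a GenBank record
#'
#' Minimal flat-file writer: LOCUS line (length, molecule type, topology),
#' optional FEATURES (a data.frame with columns `key`, `start`, `end`,
#' 1-based inclusive, and `note`), and the ORIGIN sequence block.
#'
#' @param x an `iflc_duplex`.
#' @param path output file.
#' @param features optional feature table.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(x, path, features = NULL) {
  stopifnot(inherits(x, "iflc_duplex"))
  con <- file(path, "wb")  # binary mode: byte-stable newlines
  on.exit(close(con))
  name <- if (nzchar(x$id)) gsub("[^A-Za-z0-9_.-]", "_", x$id) else "molecule"
  name <- substr(name, 1, 16)  # LOCUS field width; DEFINITION matches it
  wl <- function(s) writeLines(s, con, sep = "\n")
  wl(sprintf("LOCUS       %-16s %6d bp    DNA     %-8s SYN 01-JAN-1980",
             name, dx_length(x), x$topology))
  wl(sprintf("DEFINITION  %s.", name))
  wl("FEATURES             Location/Qualifiers")
  wl(sprintf("     source          1..%d", dx_length(x)))
  if (!is.null(features) && nrow(features)) {
    for (i in seq_len(nrow(features))) {
      wl(sprintf("     %-15s %d..%d", substr(features$key[i], 1, 15),
                 features$start[i], features$end[i]))
      if (!is.null(features$note) && nzchar(features$note[i]))
        wl(sprintf("                     /note=\"%s\"", features$note[i]))
    }
  }
  wl("ORIGIN")
  s <- tolower(x$top_strand)
  n <- nchar(s)
  for (start in seq(1, n, 60)) {
    chunk <- substr(s, start, min(start + 59, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    wl(sprintf("%9d %s", start, paste(blocks, collapse = " ")))
  }
  wl("//")
  invisible(path)
}

#' Read a GenBank record
#'
#' Parses the LOCUS line for topology, the feature table (simple
#' `key start..end` spans with `/note`), and the ORIGIN sequence.
#'
#' @param path GenBank flat file.
#' @return an `iflc_duplex` with attribute `"features"`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank record: no LOCUS line", call. = FALSE)
  topo <- if (grepl("circular", locus[1], ignore.case = TRUE)) "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  feats <- data.frame(key = character(0), start = integer(0), end = integer(0),
                      note = character(0), stringsAsFactors = FALSE)
  if (length(fstart) && length(ostart)) {
    block <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    km <- regmatches(block, regexec("^     (\\S+)\\s+(\\d+)\\.\\.(\\d+)", block))
    cur <- 0L
    for (i in seq_along(block)) {
      if (length(km[[i]])) {
        feats <- rbind(feats, data.frame(key = km[[i]][2],
                                         start = as.integer(km[[i]][3]),
                                         end = as.integer(km[[i]][4]),
                                         note = "", stringsAsFactors = FALSE))
        cur <- nrow(feats)
      } else if (cur > 0L && grepl("/note=", block[i])) {
        feats$note[cur] <- sub('.*?/note="([^"]*)".*', "\\1", block[i])
      }
    }
    feats <- feats[feats$key != "source", , drop = FALSE]
    rownames(feats) <- NULL
  }
  if (!length(ostart)) stop("no ORIGIN block", call. = FALSE)
  endl <- grep("^//", lines)
  endl <- endl[endl > ostart[1]][1]
  seqlines <- lines[(ostart[1] + 1L):(endl - 1L)]
  s <- toupper(gsub("[^acgtnACGTN]", "", paste(seqlines, collapse = "")))
  out <- duplex(s, topo, id = if (is.na(id)) "" else id, allow_n = TRUE)
  attr(out, "features") <- feats
  out
}
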