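# Shared fixtures and independent oracles. Expensive objects are memoised in
# a session-local cache so each is built once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, value) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(value)
  .cache[[key]]
}

enzymes <- function() iflc_enzymes()

catalogue_linkers <- function() memo("linkers", load_catalogue("linkers"))

fixture_domain <- function(id, len, seed = 1L)
  memo(paste0("dom:", id, len, seed),
       random_part_sequence(len, "domain", seed = seed, id = id))

fixture_entry <- function(p, backbone = "pL2", seed = 1L)
  memo(paste0("ep:", p$id, backbone, seed),
       make_entry_plasmid(p, backbone, seed = seed))

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

withr_local_tempfile <- function(ext, env = parent.frame()) {
  f <- tempfile(fileext = ext)
  withr::defer(unlink(f), envir = env)
  f
}

# independent naive O(n*m) both-strand site scanner (brute-force oracle)
naive_scan_count <- function(s, motif, circular = FALSE) {
  count_one <- function(s, motif) {
    n <- nchar(s); m <- nchar(motif)
    if (n < m) return(0L)
    hits <- 0L
    for (i in 1:(n - m + 1L)) if (substr(s, i, i + m - 1L) == motif) hits <- hits + 1L
    hits
  }
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  subject <- if (circular) paste0(s, substr(s, 1, nchar(motif) - 1L)) else s
  k <- count_one(subject, motif)
  if (motif != rc(motif)) k <- k + count_one(subject, rc(motif))
  k
}

# brute-force direct-repeat detector: any substring of length `len` occurring
# at two distinct positions
naive_has_repeat <- function(s, len) {
  n <- nchar(s)
  if (n < len + 1L) return(FALSE)
  subs <- substring(s, 1:(n - len + 1L), len:n)
  any(duplicated(subs))
}

# Monte-Carlo occupancy oracle: mean and SE of the unique-variant count when
# drawing N uniform clones from diversity D
mc_unique <- function(N, D, reps, chunk = 5000L) {
  counts <- numeric(0)
  left <- reps
  while (left > 0L) {
    k <- min(chunk, left)
    m <- stats::rmultinom(k, N, rep(1 / D, D))
    counts <- c(counts, colSums(m > 0L))
    left <- left - k
  }
  c(mean = mean(counts), se = sd(counts) / sqrt(reps))
}
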