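# Independent oracles used by the tests. These deliberately re-derive results
# from first principles (direct enumeration, textbook DP, closed forms) and
# share no code with the package implementation they check.

# --- brute-force six-frame ORF enumeration on a circular genome -------------
# For every position and strand, read codons (wrapping) until a stop; keep
# ATG-led spans of >= min_aa codons; for each stop keep only the longest call
# (the 5'-most ATG of its segment).
oracle_scan_orfs <- function(genome, min_aa = 50L) {
  L <- genome$length
  seq_fwd <- genome$sequence
  seq_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq_fwd)))
  base_at <- function(s, p) substr(s, (p %% L) + 1L, (p %% L) + 1L)
  codon_at <- function(s, p) paste0(base_at(s, p), base_at(s, p + 1L),
                                    base_at(s, p + 2L))
  stops <- c("TAA", "TAG", "TGA")
  calls <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_fwd else seq_rev
    for (p in 0:(L - 1L)) {
      if (codon_at(s, p) != "ATG") next
      q <- p
      ncod <- 0L
      found <- FALSE
      while (ncod * 3L < L) {
        if (codon_at(s, q) %in% stops) { found <- TRUE; break }
        q <- q + 3L
        ncod <- ncod + 1L
      }
      if (!found || ncod < min_aa) next
      calls[[length(calls) + 1L]] <- data.frame(
        p_scan = p, stop_scan = q %% L, ncod = ncod, strand = strand
      )
    }
  }
  if (length(calls) == 0L) {
    return(data.frame(start = integer(), end = integer(), strand = character()))
  }
  df <- do.call(rbind, calls)
  # keep the longest ORF per (strand, stop codon)
  df <- df[order(-df$ncod), ]
  df <- df[!duplicated(df[, c("strand", "stop_scan")]), ]
  # convert scan coordinates to forward-genome 0-based half-open spans
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    span <- 3L * (r$ncod + 1L)
    if (r$strand == "+") {
      start <- r$p_scan %% L
    } else {
      start <- (L - (r$p_scan + span)) %% L
    }
    data.frame(start = start, end = start + span, strand = r$strand,
               length_codons = r$ncod)
  })
  out <- do.call(rbind, out)
  out[order(out$start, out$strand), ]
}

# --- independent translation oracle (seqinr's own code table) ---------------
oracle_translate <- function(cds) {
  aa <- seqinr::translate(strsplit(tolower(cds), "")[[1]])
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# --- Gotoh affine-gap DP, gap of length k costs go + k*ge -------------------
oracle_local_align_score <- function(a, b, go = 11, ge = 1) {
  sm <- get_blosum62()
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)     # best ending in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consuming a)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consuming b)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
    Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    s <- sm[a[i - 1], b[j - 1]]
    M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i - 1, j - 1] + s,
                   Y[i - 1, j - 1] + s)
    best <- max(best, M[i, j])
  }
  best
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# --- random additive distance matrix from a random tree ---------------------
oracle_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::runif(k, 0.5, 3))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

random_dna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
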