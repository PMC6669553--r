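# Direct-repeat and homologous-region (hr) discovery. hrs in baculovirus
# genomes are clusters of short imperfect palindromic core motifs; drs are
# tandem arrays (here, e.g. four 68-nt copies inside vp80). Detection is
# k-mer-seeded: candidate periods come from exact k-mer recurrences, arrays
# are extended unit-by-unit against a consensus, and overlapping reports are
# resolved keeping the higher-scoring (then smallest) period.

hamming_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- min(length(va), length(vb))
  if (n == 0L) return(0)
  100 * sum(va[seq_len(n)] == vb[seq_len(n)]) / n
}

consensus_of <- function(units) {
  mat <- do.call(rbind, strsplit(units, ""))
  paste(apply(mat, 2, function(col) names(which.max(table(col)))), collapse = "")
}

# Extend a tandem array of period d seeded at 0-based position pos in `text`.
# Returns c(start, end) (0-based half-open) or NULL.
extend_array <- function(text, pos, d, min_identity) {
  n <- nchar(text)
  unit_at <- function(s) substr(text, s + 1L, s + d)
  # slide the seed left to the array start using exact per-base agreement
  s <- pos
  while (s > 0L && substr(text, s, s) == substr(text, s + d, s + d)) s <- s - 1L
  anchor <- unit_at(s)
  # extend right by whole units against the running consensus
  units <- anchor
  e <- s + d
  while (e + d <= n) {
    nxt <- unit_at(e)
    cons <- consensus_of(units)
    if (hamming_identity(nxt, cons) < min_identity) break
    units <- c(units, nxt)
    e <- e + d
  }
  # fractional trailing copy: count exact-matching prefix bases
  if (e < n) {
    cons <- consensus_of(units)
    extra <- 0L
    while (e + extra < n && extra < d &&
           substr(text, e + extra + 1L, e + extra + 1L) ==
           substr(cons, extra + 1L, extra + 1L)) {
      extra <- extra + 1L
    }
    e <- e + extra
  }
  if (length(units) < 2L) return(NULL)
  c(s, e)
}

#' Find tandem repeats on a (circular) genome
#'
#' k-mer-seeded detection: exact k-mer recurrences at spacing `d`
#' (`min_unit <= d <= max_unit`) propose candidate periods; each candidate is
#' extended while per-unit identity to the running consensus stays at or above
#' `min_identity`; overlapping reports are merged keeping the higher-scoring
#' report, with the smallest period winning among harmonics. Wrap-aware on
#' circular genomes (the scan runs on the doubled sequence and arrays are
#' deduplicated modulo the genome length).
#'
#' @param genome A [circular_genome()].
#' @param min_unit,max_unit Period range in nt.
#' @param min_copies Minimum (possibly fractional) copy number to report.
#' @param min_identity Minimum per-unit percent identity to the consensus.
#' @return A tibble: `start`, `end` (0-based half-open, unwrapped),
#'   `unit_length`, `copies`, `consensus_unit`, `internal_identity` (mean
#'   percent identity of full copies to the consensus), ordered by start.
#' @export
find_tandem_repeats <- function(genome, min_unit = 10L, max_unit = 100L,
                                min_copies = 3, min_identity = 85) {
  stopifnot(min_unit >= 1L, min_unit <= max_unit, max_unit <= 2000L)
  L <- genome$length
  circ <- is_circular(genome)
  text <- if (circ) {
    paste0(genome$sequence,
           substr(genome$sequence, 1L, min(L, max_unit * 12L)))
  } else genome$sequence
  n <- nchar(text)
  k <- max(4L, min(7L, min_unit))
  if (n < 2L * min_unit + k) return(empty_repeat_tbl())

  starts <- seq_len(n - k + 1L)
  kmers <- substring(text, starts, starts + k - 1L)
  idx <- split(starts - 1L, kmers)            # 0-based positions per k-mer
  idx <- idx[lengths(idx) >= 2L]

  seeds <- list()
  for (pos in idx) {
    d <- diff(pos)
    ok <- which(d >= min_unit & d <= max_unit)
    for (j in ok) seeds[[length(seeds) + 1L]] <- c(pos[j], d[j])
  }
  if (length(seeds) == 0L) return(empty_repeat_tbl())
  seeds <- unique(do.call(rbind, seeds))
  # one seed per (period, approximate region) is enough; keep the earliest
  seeds <- seeds[order(seeds[, 2], seeds[, 1]), , drop = FALSE]

  found <- list()
  covered <- list()   # per period: integer vector of covered positions flag
  for (r in seq_len(nrow(seeds))) {
    pos <- seeds[r, 1]; d <- seeds[r, 2]
    key <- as.character(d)
    cov <- covered[[key]]
    if (!is.null(cov) && pos + 1L <= length(cov) && cov[pos + 1L]) next
    arr <- extend_array(text, pos, d, min_identity)
    if (is.null(arr)) next
    s <- arr[1]; e <- arr[2]
    copies <- (e - s) / d
    if (copies < min_copies) next
    if (is.null(cov)) cov <- logical(n)
    cov[(s + 1L):min(e, n)] <- TRUE
    covered[[key]] <- cov
    full <- (e - s) %/% d
    units <- substring(text, s + seq(0L, (full - 1L) * d, d) + 1L,
                       s + seq_len(full) * d)
    cons <- consensus_of(units)
    ident <- round(mean(purrr::map_dbl(units, hamming_identity, b = cons)), 1)
    if (ident < min_identity) next
    found[[length(found) + 1L]] <- tibble::tibble(
      start = s, end = e, unit_length = d, copies = round(copies, 2),
      consensus_unit = cons, internal_identity = ident
    )
  }
  if (length(found) == 0L) return(empty_repeat_tbl())
  rep_tbl <- dplyr::bind_rows(found)
  if (circ) {
    rep_tbl <- rep_tbl[rep_tbl$start < L & (rep_tbl$end - rep_tbl$start) <= L, ,
                       drop = FALSE]
    rep_tbl <- dplyr::distinct(
      dplyr::mutate(rep_tbl, .s = .data$start %% L),
      .data$.s, .data$unit_length, .keep_all = TRUE
    ) |> dplyr::select(-".s")
  }
  if (nrow(rep_tbl) == 0L) return(empty_repeat_tbl())

  # resolve overlaps: longer (bucketed) span wins, then the smallest period --
  # an array reportable at period p is also reportable at its harmonics 2p,
  # 3p, ... with near-identical span, and p is the canonical report
  span <- rep_tbl$end - rep_tbl$start
  rep_tbl$score <- span * rep_tbl$internal_identity / 100
  rep_tbl <- rep_tbl[order(-round(span / 10), rep_tbl$unit_length,
                           -rep_tbl$score, rep_tbl$start), ]
  keep <- integer(0)
  for (i in seq_len(nrow(rep_tbl))) {
    ok <- TRUE
    for (j in keep) {
      ov <- max(0L, min(rep_tbl$end[i], rep_tbl$end[j]) -
                    max(rep_tbl$start[i], rep_tbl$start[j]))
      if (ov > 0.5 * (rep_tbl$end[i] - rep_tbl$start[i])) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  rep_tbl[keep, , drop = FALSE] |>
    dplyr::select(-"score") |>
    dplyr::arrange(.data$start) |>
    dplyr::mutate(start = as.integer(.data$start), end = as.integer(.data$end),
                  unit_length = as.integer(.data$unit_length))
}

empty_repeat_tbl <- function() {
  tibble::tibble(start = integer(), end = integer(), unit_length = integer(),
                 copies = numeric(), consensus_unit = character(),
                 internal_identity = numeric())
}

#' Count motif occurrences on a circular genome
#'
#' Possibly overlapping occurrences with up to `max_mismatch` mismatches on
#' the selected strand(s); on circular genomes occurrences spanning the
#' origin are included. Counts on the two strands are summed (a palindromic
#' motif therefore counts once per selected strand at a matching site).
#'
#' @param genome A [circular_genome()].
#' @param motif DNA string (A/C/G/T).
#' @param strands `"both"` (default), `"forward"` or `"reverse"`.
#' @param max_mismatch Mismatch allowance (default 0: exact).
#' @param overlapping Count overlapping occurrences (default `TRUE`).
#' @return Integer count.
#' @examples
#' count_motif(circular_genome("g", "AAAAGG", "linear"), "AAA",
#'             strands = "forward")  # 2
#' @export
count_motif <- function(genome, motif, strands = c("both", "forward", "reverse"),
                        max_mismatch = 0L, overlapping = TRUE) {
  strands <- match.arg(strands)
  motif <- toupper(motif)
  if (grepl("[^ACGTN]", motif)) stop("motif contains non-IUPAC characters", call. = FALSE)
  m <- nchar(motif)
  L <- genome$length
  stopifnot(m >= 1L, m <= L)
  text <- if (is_circular(genome) && m > 1L) {
    paste0(genome$sequence, substr(genome$sequence, 1L, m - 1L))
  } else genome$sequence
  count_one <- function(pat) {
    hits <- Biostrings::matchPattern(pat, Biostrings::DNAString(text),
                                     max.mismatch = max_mismatch)
    st <- BiocGenerics::start(hits)
    st <- st[st <= L]
    if (!overlapping && length(st) > 1L) {
      keep <- st[1]; last <- st[1]
      for (s in st[-1]) if (s >= last + m) { keep <- c(keep, s); last <- s }
      st <- keep
    }
    length(st)
  }
  fwd <- if (strands %in% c("both", "forward")) count_one(motif) else 0L
  rev <- if (strands %in% c("both", "reverse")) count_one(revcomp(motif)) else 0L
  fwd + rev
}

# motif hit start positions (0-based, forward text coords) on both strands
motif_hits <- function(genome, motif, max_mismatch = 1L) {
  m <- nchar(motif)
  L <- genome$length
  text <- if (is_circular(genome) && m > 1L) {
    paste0(genome$sequence, substr(genome$sequence, 1L, m - 1L))
  } else genome$sequence
  subj <- Biostrings::DNAString(text)
  pos <- integer(0)
  for (pat in unique(c(motif, revcomp(motif)))) {
    st <- BiocGenerics::start(
      Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
    )
    pos <- c(pos, st[st <= L] - 1L)
  }
  sort(unique(pos))
}

#' Cluster core-motif hits into homologous regions (hrs)
#'
#' All hits of the core motifs (default up to 1 mismatch, both strands) are
#' projected to genome positions and single-linkage clustered with gap
#' `<= window`; clusters with at least `min_hits` hits become hr regions
#' spanning first-to-last hit. Regions are named sequentially from the
#' genome origin (`hr1a`, `hr1b`, `hr2a`, ...): consecutive regions closer
#' than `group_gap` share a number and differ in letter.
#'
#' @param genome A [circular_genome()].
#' @param core_motifs Character vector of core motifs.
#' @param window Single-linkage gap in nt (default 2000).
#' @param min_hits Minimum hits per region (default 2).
#' @param max_mismatch Per-hit mismatch allowance (default 1).
#' @param group_gap Regions closer than this share an hr number (default
#'   15000 nt).
#' @return A tibble: `name`, `start`, `end`, `n_hits`, `motif_hits`
#'   (list-column of hit positions).
#' @export
cluster_hrs <- function(genome, core_motifs, window = 2000L, min_hits = 2L,
                        max_mismatch = 1L, group_gap = 15000L) {
  stopifnot(length(core_motifs) >= 1L, window > 0L)
  mlen <- nchar(core_motifs)
  hits <- sort(unique(unlist(purrr::map(
    core_motifs, function(m) motif_hits(genome, m, max_mismatch)
  ))))
  if (length(hits) == 0L) {
    return(tibble::tibble(name = character(), start = integer(),
                          end = integer(), n_hits = integer(),
                          motif_hits = list()))
  }
  gaps <- diff(hits)
  cl <- cumsum(c(1L, as.integer(gaps > window)))
  regions <- tibble::tibble(pos = hits, cl = cl) |>
    dplyr::group_by(.data$cl) |>
    dplyr::summarise(start = min(.data$pos),
                     end = max(.data$pos) + max(mlen),
                     n_hits = dplyr::n(),
                     motif_hits = list(.data$pos), .groups = "drop") |>
    dplyr::filter(.data$n_hits >= min_hits) |>
    dplyr::arrange(.data$start)
  if (nrow(regions) == 0L) return(dplyr::mutate(regions, name = character()))
  # positional naming grouped by inter-region distance
  grp <- cumsum(c(1L, as.integer(diff(regions$start) > group_gap)))
  letters_in <- stats::ave(seq_len(nrow(regions)), grp, FUN = seq_along)
  n_in_grp <- stats::ave(seq_len(nrow(regions)), grp, FUN = length)
  regions$name <- ifelse(
    n_in_grp == 1L, paste0("hr", grp),
    paste0("hr", grp, letters[letters_in])
  )
  dplyr::select(regions, "name", "start", "end", "n_hits", "motif_hits") |>
    dplyr::mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

#' Global pairwise nucleotide identity
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -2,
#' gap extend -1 by default); identity is 100 x matches / alignment columns,
#' to one decimal.
#'
#' @param seq_a,seq_b DNA strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (penalties
#'   positive).
#' @return Percent identity.
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                              gap_open = 2, gap_extend = 1) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(seq_a)), Biostrings::DNAString(toupper(seq_b)),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  round(100 * sum(a == b & a != "-") / length(a), 1)
}
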