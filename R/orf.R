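# Six-frame ORF discovery on circular genomes under the liberal annotation
# criterion: ATG start, >= 50 codons, retained unless >= 50% of the ORF's own
# length lies inside an already-retained (longer) neighbour.

GENETIC_CODE_TBL <- Biostrings::GENETIC_CODE
STOP_CODONS <- names(GENETIC_CODE_TBL)[GENETIC_CODE_TBL == "*"]

#' Translate a CDS with the standard genetic code
#'
#' @param cds_sequence Nucleotide string, length divisible by 3, no `N`.
#'   A trailing stop codon is dropped; an internal stop is an error.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGTAA")  # "M"
#' @export
translate_cds <- function(cds_sequence) {
  cds_sequence <- toupper(cds_sequence)
  n <- nchar(cds_sequence)
  if (n %% 3 != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  if (grepl("N", cds_sequence, fixed = TRUE)) {
    stop("CDS contains N; cannot translate", call. = FALSE)
  }
  codons <- substring(cds_sequence, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(GENETIC_CODE_TBL[codons])
  if (any(is.na(aa))) stop("invalid codon in CDS", call. = FALSE)
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) stop("internal stop codon in CDS", call. = FALSE)
  paste(aa, collapse = "")
}

# Scan one linear character string for maximal ATG..stop ORFs (5'-most ATG per
# stop-to-stop segment). Returns 0-based half-open spans on that string.
scan_orfs_linear <- function(seq, min_aa) {
  n <- nchar(seq)
  codon_at <- function(i) substr(seq, i + 1L, i + 3L)  # 0-based i
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(frame, n - 3L, by = 3L)
    if (length(starts) == 0L || starts[1] > n - 3L) next
    codons <- substring(seq, starts + 1L, starts + 3L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    seg_open <- NA_integer_   # index (in codons) of 5'-most ATG since last stop
    for (k in seq_along(codons)) {
      if (is_stop[k]) {
        if (!is.na(seg_open)) {
          ncod <- k - seg_open            # codons excluding the stop
          if (ncod >= min_aa) {
            out[[length(out) + 1L]] <- c(starts[seg_open], starts[k] + 3L, frame)
          }
        }
        seg_open <- NA_integer_
      } else if (is.na(seg_open) && is_atg[k]) {
        seg_open <- k
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(), frame = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(start = m[, 1], end = m[, 2], frame = m[, 3])
}

#' Six-frame ORF discovery
#'
#' Every maximal ATG-to-stop span with at least `min_aa` codons (stop
#' excluded) on either strand; within a stop-to-stop frame segment only the
#' 5'-most ATG defines the ORF. Circular genomes are scanned on the doubled
#' sequence so origin-spanning ORFs are found once, and an ORF reported from
#' the first copy without a genuine upstream stop is superseded by the longer
#' call sharing its stop codon. ORFs containing `N` in any codon are dropped.
#'
#' @param genome A [circular_genome()].
#' @param min_aa Minimum protein length in codons (default 50).
#' @return A tibble with one row per ORF: `genome_id`, `start`, `end`
#'   (0-based half-open, `end > L` when the ORF wraps the origin), `strand`,
#'   `frame`, `length_nt`, `length_codons` (stop excluded), `protein`,
#'   `label`, `kind = "CDS"`, ordered by genomic start.
#' @export
scan_orfs <- function(genome, min_aa = 50L) {
  stopifnot(min_aa >= 1L)
  L <- genome$length
  if (L < 3L * (min_aa + 1L)) return(empty_orf_tbl())
  circ <- is_circular(genome)
  fwd <- if (circ) paste0(genome$sequence, genome$sequence) else genome$sequence
  n2 <- nchar(fwd)
  rev <- revcomp(fwd)

  plus <- scan_orfs_linear(fwd, min_aa)
  plus$strand <- "+"
  minus <- scan_orfs_linear(rev, min_aa)
  # map reverse-scan coords back onto forward coordinates
  if (nrow(minus)) {
    tmp_start <- n2 - minus$end
    minus$end <- n2 - minus$start
    minus$start <- tmp_start
  }
  minus$strand <- "-"
  orfs <- dplyr::bind_rows(plus, minus)
  if (nrow(orfs) == 0L) return(empty_orf_tbl())
  orfs$span <- orfs$end - orfs$start
  orfs <- orfs[orfs$span <= L, , drop = FALSE]

  if (circ) {
    # 5'-most-ATG rule across the origin: group by the stop codon's genome
    # position and keep the longest call, then deduplicate the two copies.
    stop_pos <- ifelse(orfs$strand == "+", (orfs$end - 3L) %% L, orfs$start %% L)
    orfs <- orfs |>
      dplyr::mutate(.stop = stop_pos) |>
      dplyr::group_by(.data$strand, .data$.stop) |>
      dplyr::slice_max(.data$span, n = 1L, with_ties = TRUE) |>
      dplyr::ungroup() |>
      dplyr::mutate(start = .data$start %% L, end = .data$start + .data$span) |>
      dplyr::distinct(.data$start, .data$strand, .data$span, .keep_all = TRUE) |>
      dplyr::select(-".stop")
  }
  if (nrow(orfs) == 0L) return(empty_orf_tbl())

  # translate; drop ORFs with N in a codon
  keep <- logical(nrow(orfs))
  protein <- character(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    nt <- circular_subsequence(genome, orfs$start[i], orfs$end[i])
    if (orfs$strand[i] == "-") nt <- revcomp(nt)
    if (grepl("N", nt, fixed = TRUE)) next
    protein[i] <- translate_cds(nt)
    keep[i] <- TRUE
  }
  orfs <- orfs[keep, , drop = FALSE]
  protein <- protein[keep]
  if (nrow(orfs) == 0L) return(empty_orf_tbl())

  tibble::tibble(
    genome_id = genome$id,
    start = as.integer(orfs$start), end = as.integer(orfs$end),
    strand = orfs$strand, frame = as.integer(orfs$start %% 3L),
    length_nt = as.integer(orfs$span),
    length_codons = as.integer(orfs$span %/% 3L - 1L),
    protein = protein,
    label = "", kind = "CDS"
  ) |>
    dplyr::arrange(.data$start, .data$strand)
}

empty_orf_tbl <- function() {
  tibble::tibble(
    genome_id = character(), start = integer(), end = integer(),
    strand = character(), frame = integer(), length_nt = integer(),
    length_codons = integer(), protein = character(),
    label = character(), kind = character()
  )
}

# overlap in nt between two possibly wrapped spans on a circular genome
wrapped_overlap <- function(s1, e1, s2, e2, L) {
  pieces <- function(s, e) {
    if (e <= L) list(c(s, e)) else list(c(s, L), c(0L, e - L))
  }
  a <- pieces(s1, e1); b <- pieces(s2, e2)
  tot <- 0L
  for (p in a) for (q in b) {
    tot <- tot + max(0L, min(p[2], q[2]) - max(p[1], q[1]))
  }
  tot
}

#' Filter ORF candidates by the liberal overlap criterion
#'
#' Greedy retention in decreasing length order (ties: smaller start, then `+`
#' strand first). A candidate is discarded iff, against some already-retained
#' ORF, its wrapped nucleotide overlap divided by its own wrapped length is
#' `>= max_fraction`. Overlap is computed on genome coordinates irrespective
#' of strand.
#'
#' @param candidates ORF tibble from [scan_orfs()] (one genome).
#' @param max_fraction Overlap fraction at or above which a candidate is
#'   dropped (default 0.5).
#' @param genome_length Genome length; inferred from the largest coordinate
#'   if omitted (only safe when some ORF wraps).
#' @return The retained subset, genomic order.
#' @export
filter_overlaps <- function(candidates, max_fraction = 0.5,
                            genome_length = NULL) {
  if (nrow(candidates) == 0L) return(candidates)
  L <- genome_length %||% max(candidates$end)
  ord <- order(-candidates$length_nt, candidates$start,
               candidates$strand != "+")
  cand <- candidates[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    own <- cand$length_nt[i]
    ok <- TRUE
    for (j in kept) {
      ov <- wrapped_overlap(cand$start[i], cand$end[i],
                            cand$start[j], cand$end[j], L)
      if (ov / own >= max_fraction) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  cand[sort(kept), , drop = FALSE] |>
    dplyr::arrange(.data$start, .data$strand)
}

#' Label ORFs against reference proteomes
#'
#' Each ORF is aligned (local, BLOSUM62-style, see [align_proteins()]) against
#' every reference protein; the best-scoring reference names the ORF when its
#' score reaches `min_score`, otherwise the ORF is labelled `"unique"`.
#' `core_gene` is `TRUE` when the best reference belongs to `core_names`
#' (the 38 genes conserved across all baculovirus genomes, supplied by the
#' caller).
#'
#' @param orfs ORF tibble ([scan_orfs()] / [filter_overlaps()] output).
#' @param reference_proteins Named character vector of reference amino-acid
#'   sequences (names are the homolog labels).
#' @param min_score Minimum local alignment score to accept a homolog call.
#' @param core_names Character vector of core-gene labels.
#' @return The input tibble with `label`, `best_score` and `core_gene`
#'   columns filled.
#' @export
label_homologs <- function(orfs, reference_proteins, min_score = 60,
                           core_names = character()) {
  if (length(reference_proteins) == 0L) {
    warning("empty reference set: every ORF labelled 'unique'")
    return(dplyr::mutate(orfs, label = "unique", best_score = NA_real_,
                         core_gene = FALSE))
  }
  stopifnot(!is.null(names(reference_proteins)),
            all(nzchar(names(reference_proteins))))
  labels <- character(nrow(orfs))
  scores <- numeric(nrow(orfs))
  refset <- Biostrings::AAStringSet(reference_proteins)
  for (i in seq_len(nrow(orfs))) {
    sc <- Biostrings::pairwiseAlignment(
      refset, Biostrings::AAString(orfs$protein[i]), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE
    )
    best <- which.max(sc)
    scores[i] <- sc[best]
    labels[i] <- if (sc[best] >= min_score) names(reference_proteins)[best] else "unique"
  }
  dplyr::mutate(orfs, label = labels, best_score = scores,
                core_gene = labels %in% core_names)
}
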