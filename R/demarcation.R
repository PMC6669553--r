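# Kimura 2-parameter distances on marker genes (lef-8, lef-9, polh) and the
# alphabaculovirus species-demarcation rule: pairwise marker K2P distance
# > 0.05 substitutions/site indicates distinct species, < 0.015 the same
# species. d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q) with P, Q the transition and
# transversion proportions over pairwise-deleted sites.

PURINES <- c("A", "G")

#' Transition/transversion proportions of an aligned pair
#'
#' Sites where either sequence has a gap (`-`) or `N` are excluded
#' (pairwise deletion).
#'
#' @param seq_a,seq_b Equal-length gapped DNA strings.
#' @return A list: `n_sites`, `P` (transition proportion), `Q` (transversion
#'   proportion).
#' @export
count_substitutions <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  stopifnot(length(a) == length(b))
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable sites after pairwise deletion", call. = FALSE)
  diff <- a != b
  ts <- diff & ((a %in% PURINES) == (b %in% PURINES))
  list(n_sites = n, P = sum(ts) / n, Q = sum(diff & !ts) / n)
}

#' Kimura 2-parameter distance
#'
#' `d = -0.5 log(1 - 2P - Q) - 0.25 log(1 - 2Q)`. When a log argument is
#' non-positive the distance is saturated: `defined = FALSE` and `d = Inf`.
#'
#' @param seq_a,seq_b Equal-length gapped DNA strings, or pass `P`/`Q`
#'   directly (then sequences may be omitted).
#' @param P,Q Transition/transversion proportions (override counting).
#' @return A list: `d`, `defined`, `P`, `Q`, `n_sites`.
#' @examples
#' k2p_distance(P = 0.1, Q = 0.05)$d  # ~0.1702
#' @export
k2p_distance <- function(seq_a = NULL, seq_b = NULL, P = NULL, Q = NULL) {
  n_sites <- NA_integer_
  if (is.null(P) || is.null(Q)) {
    cnt <- count_substitutions(seq_a, seq_b)
    P <- cnt$P; Q <- cnt$Q; n_sites <- cnt$n_sites
  }
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    return(list(d = Inf, defined = FALSE, P = P, Q = Q, n_sites = n_sites))
  }
  list(d = -0.5 * log(a1) - 0.25 * log(a2), defined = TRUE,
       P = P, Q = Q, n_sites = n_sites)
}

#' K2P distance matrix of a multiple alignment
#'
#' Per-pair pairwise deletion; undefined (saturated) pairs carry `Inf` and
#' are flagged.
#'
#' @param alignment Named character vector of equal-length gapped sequences,
#'   or a `Biostrings::DNAStringSet`/`DNAMultipleAlignment`.
#' @return An object of class `k2p_dist`: list with `d` (symmetric matrix,
#'   zero diagonal), `defined` (logical matrix), `n_sites`.
#' @export
k2p_distance_matrix <- function(alignment) {
  if (inherits(alignment, "DNAMultipleAlignment")) {
    alignment <- as.character(Biostrings::DNAStringSet(alignment))
  } else if (inherits(alignment, "XStringSet")) {
    alignment <- as.character(alignment)
  }
  stopifnot(length(alignment) >= 2L, !is.null(names(alignment)))
  taxa <- names(alignment)
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  defined <- matrix(TRUE, n, n, dimnames = list(taxa, taxa))
  nsites <- matrix(NA_integer_, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    est <- k2p_distance(alignment[[i]], alignment[[j]])
    d[i, j] <- d[j, i] <- est$d
    defined[i, j] <- defined[j, i] <- est$defined
    nsites[i, j] <- nsites[j, i] <- est$n_sites
  }
  structure(list(d = d, defined = defined, n_sites = nsites),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat("<k2p_dist>", nrow(x$d), "taxa\n")
  print(round(x$d, 4))
  if (any(!x$defined[upper.tri(x$defined)])) {
    cat("note: saturated (undefined) pairs present\n")
  }
  invisible(x)
}

#' Species demarcation from a marker-gene K2P distance
#'
#' Distinct species when `d > t_high` (0.05 substitutions/site), same species
#' when `d < t_low` (0.015), indeterminate between the bounds and exactly at
#' them. A saturated (undefined) distance is called `different_species` with
#' `saturated = TRUE`: saturation itself evidences deep divergence.
#'
#' @param d Distance(s), substitutions/site.
#' @param t_low,t_high Demarcation bounds.
#' @param marker Optional marker name(s) carried into the output.
#' @return A tibble: `marker`, `d`, `decision`, `saturated`.
#' @export
classify_species <- function(d, t_low = 0.015, t_high = 0.050, marker = NA_character_) {
  saturated <- !is.finite(d)
  decision <- dplyr::case_when(
    saturated ~ "different_species",
    d > t_high ~ "different_species",
    d < t_low ~ "same_species",
    TRUE ~ "indeterminate"
  )
  tibble::tibble(marker = marker, d = d, decision = decision,
                 saturated = saturated)
}

#' Concatenate per-gene alignments column-wise
#'
#' @param per_gene_alignments Named list of named character vectors (gene ->
#'   taxon -> gapped sequence). Taxon sets must agree unless `pad = TRUE`,
#'   in which case missing taxa get all-gap blocks.
#' @param pad Pad missing taxa with gaps.
#' @return A list: `alignment` (named character vector over the taxon union)
#'   and `partitions` (tibble `gene`, `start`, `end`, 1-based inclusive
#'   columns).
#' @export
concatenate_alignments <- function(per_gene_alignments, pad = FALSE) {
  stopifnot(length(per_gene_alignments) >= 1L)
  taxa <- unique(unlist(purrr::map(per_gene_alignments, names)))
  if (anyDuplicated(taxa)) stop("duplicated taxon names", call. = FALSE)
  for (g in names(per_gene_alignments)) {
    gene <- per_gene_alignments[[g]]
    if (anyDuplicated(names(gene))) {
      stop("duplicated taxon names in gene ", g, call. = FALSE)
    }
    if (!pad && !setequal(names(gene), taxa)) {
      stop("gene ", g, " is missing taxa (set pad = TRUE to gap-fill)",
           call. = FALSE)
    }
  }
  out <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- list()
  col <- 0L
  for (g in names(per_gene_alignments)) {
    gene <- per_gene_alignments[[g]]
    w <- unique(nchar(gene))
    if (length(w) != 1L) stop("gene ", g, ": unequal sequence lengths", call. = FALSE)
    block <- stats::setNames(rep(strrep("-", w), length(taxa)), taxa)
    block[names(gene)] <- unname(gene)
    out <- paste0(out, block)
    names(out) <- taxa
    parts[[g]] <- tibble::tibble(gene = g, start = col + 1L, end = col + w)
    col <- col + w
  }
  list(alignment = out, partitions = dplyr::bind_rows(parts))
}

#' Neighbor joining from a distance matrix
#'
#' Canonical NJ agglomeration (Saitou-Nei with the standard Q criterion).
#' Ties in Q are broken by lexicographic taxon-pair order; a negative branch
#' length is clamped to 0 with the deficit moved to its sister branch. With
#' two taxa the distance is split evenly across a single edge.
#'
#' @param d A symmetric numeric matrix with dimnames, a `dist`, or a
#'   `k2p_dist`.
#' @return An `ape::phylo` (unrooted).
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "k2p_dist")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix is not symmetric", call. = FALSE)
  n <- nrow(d)
  stopifnot(n >= 2L)
  labels <- rownames(d)
  if (n == 2L) {
    nwk <- sprintf("(%s:%.12g,%s:%.12g);", labels[1], d[1, 2] / 2,
                   labels[2], d[1, 2] / 2)
    return(ape::read.tree(text = nwk))
  }
  # active nodes represented by newick fragments
  frag <- labels
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Qm <- (m - 2) * D - outer(r, r, "+")
    diag(Qm) <- Inf
    # lexicographic tie-break on the (sorted) active-node names
    best <- NULL; bestq <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      q <- Qm[i, j]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      else if (abs(q - bestq) <= 1e-12 && !is.null(best)) {
        cur <- sort(rownames(D)[best]); new <- sort(rownames(D)[c(i, j)])
        if (paste(new, collapse = "\r") < paste(cur, collapse = "\r")) best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    # clamp negatives, moving the deficit to the sister branch
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], vi, frag[j], vj)
    new_name <- paste0("(", rownames(D)[i], ",", rownames(D)[j], ")")
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], new_name)
    D <- D2
    frag <- c(frag[keep], new_frag)
  }
  # terminal 3-node star: three-point formulas
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (k in 1:3) assign(paste0("v", k), max(0, get(paste0("v", k))))
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", frag[1], v1, frag[2], v2, frag[3], v3)
  ape::read.tree(text = nwk)
}

#' Marker-gene species demarcation against a reference panel
#'
#' Convenience wrapper: per-gene K2P distance of a query taxon against every
#' other taxon in each marker alignment, with the demarcation decision.
#'
#' @param marker_alignments Named list (gene -> named character vector of
#'   aligned sequences including the query).
#' @param query Taxon name of the query genome.
#' @param t_low,t_high Demarcation bounds.
#' @return A tibble: `marker`, `taxon`, `d`, `decision`, `saturated`.
#' @export
demarcate_species <- function(marker_alignments, query, t_low = 0.015,
                              t_high = 0.050) {
  purrr::imap_dfr(marker_alignments, function(aln, gene) {
    stopifnot(query %in% names(aln))
    others <- setdiff(names(aln), query)
    purrr::map_dfr(others, function(tx) {
      est <- k2p_distance(aln[[query]], aln[[tx]])
      dplyr::mutate(
        classify_species(est$d, t_low, t_high, marker = gene),
        taxon = tx, .after = "marker"
      )
    })
  })
}
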