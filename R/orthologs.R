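# Protein-level reciprocal-best-hit (RBH) orthology across re-annotated
# genomes, pan-genome Venn partitioning, and anchored locus-context
# extraction (the iap-3 / tmk locus between the ac30-like and fgf anchors).

#' Local protein alignment (BLOSUM62-style)
#'
#' Smith-Waterman local alignment with the BLOSUM62 matrix, gap open 11,
#' gap extend 1 (the classic protein-search defaults).
#'
#' @param a,b Amino-acid strings.
#' @param gap_open,gap_extend Penalties (positive).
#' @return A list: `score`, `identity` (percent over alignment columns),
#'   `coverage` (aligned length / shorter protein, percent).
#' @export
align_proteins <- function(a, b, gap_open = 11, gap_extend = 1) {
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cols <- length(pa)
  aligned_res <- sum(pa != "-")
  list(
    score = Biostrings::score(aln),
    identity = if (cols) round(100 * sum(pa == pb & pa != "-") / cols, 1) else 0,
    coverage = round(100 * aligned_res / min(nchar(a), nchar(b)), 1)
  )
}

# Fast batched scoring: one vectorized scoreOnly call per query; coverage is
# computed by full alignment only for pairs already passing min_score.
score_all_pairs <- function(proteome_a, proteome_b, min_score = -Inf,
                            gap_open = 11, gap_extend = 1) {
  bset <- Biostrings::AAStringSet(proteome_b)
  score <- t(vapply(proteome_a, function(a) {
    Biostrings::pairwiseAlignment(
      bset, Biostrings::AAString(a), type = "local",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
    )
  }, numeric(length(proteome_b))))
  dimnames(score) <- list(names(proteome_a), names(proteome_b))
  cov <- matrix(100, nrow(score), ncol(score), dimnames = dimnames(score))
  need <- which(score >= min_score, arr.ind = TRUE)
  for (r in seq_len(nrow(need))) {
    i <- need[r, 1]; j <- need[r, 2]
    cov[i, j] <- align_proteins(proteome_a[[i]], proteome_b[[j]],
                                gap_open, gap_extend)$coverage
  }
  list(score = score, coverage = cov)
}

#' Reciprocal best hits between two proteomes
#'
#' `(x, y)` is reported iff `y` is the unique best-scoring hit of `x` in B
#' and `x` the unique best of `y` in A, with both passing `min_score` and
#' `min_coverage` (percent of the shorter protein aligned). Ties for best
#' yield no pair.
#'
#' @param proteome_a,proteome_b Named character vectors of amino-acid
#'   sequences.
#' @param min_score Minimum local alignment score.
#' @param min_coverage Minimum coverage percent.
#' @return A tibble: `gene_a`, `gene_b`, `score`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, min_score = 60,
                                 min_coverage = 50) {
  stopifnot(length(proteome_a) > 0L, length(proteome_b) > 0L)
  sc <- score_all_pairs(proteome_a, proteome_b, min_score = min_score)
  pass <- sc$score >= min_score & sc$coverage >= min_coverage
  s <- sc$score
  s[!pass] <- -Inf
  unique_best <- function(v) {
    m <- max(v)
    if (!is.finite(m) || sum(v == m) != 1L) NA_integer_ else which.max(v)
  }
  best_b <- apply(s, 1, unique_best)   # for each a: its best b
  best_a <- apply(s, 2, unique_best)   # for each b: its best a
  rows <- list()
  for (i in seq_along(best_b)) {
    j <- best_b[i]
    if (!is.na(j) && !is.na(best_a[j]) && best_a[j] == i) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_a = names(proteome_a)[i], gene_b = names(proteome_b)[j],
        score = s[i, j]
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          score = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Build ortholog groups from pairwise RBH tables
#'
#' Single-linkage union of RBH pairs across genomes. Edges are added in
#' decreasing score order; an edge that would put two genes of one genome in
#' the same group is dropped (so each group holds at most one member per
#' genome). Genes in no surviving pair become singleton groups.
#'
#' @param rbh_pairs A tibble with `genome_a`, `gene_a`, `genome_b`, `gene_b`,
#'   `score` — the union of all pairwise [reciprocal_best_hits()] runs, with
#'   genome ids attached.
#' @param proteomes Named list (genome id -> named character vector) giving
#'   the full gene complement, so unpaired genes appear as singletons.
#' @return A tibble: `group_id`, `genome_id`, `gene_label`.
#' @export
build_ortholog_groups <- function(rbh_pairs, proteomes) {
  key <- function(g, x) paste0(g, "\r", x)
  all_nodes <- unlist(purrr::imap(proteomes, function(p, g) key(g, names(p))))
  parent <- stats::setNames(seq_along(all_nodes), all_nodes)
  node_genome <- stats::setNames(
    rep(names(proteomes), lengths(proteomes)), all_nodes
  )
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  members_of <- function(root) all_nodes[vapply(seq_along(parent), find, 0L) == root]

  if (nrow(rbh_pairs)) {
    ord <- order(-rbh_pairs$score)
    for (e in ord) {
      na <- key(rbh_pairs$genome_a[e], rbh_pairs$gene_a[e])
      nb <- key(rbh_pairs$genome_b[e], rbh_pairs$gene_b[e])
      ra <- find(which(names(parent) == na))
      rb <- find(which(names(parent) == nb))
      if (ra == rb) next
      ga <- node_genome[members_of(ra)]
      gb <- node_genome[members_of(rb)]
      if (length(intersect(ga, gb)) > 0L) next   # would duplicate a genome
      parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(parent), find, 0L)
  grp <- match(roots, unique(roots))
  tibble::tibble(
    group_id = sprintf("og%04d", grp),
    genome_id = unname(node_genome[all_nodes]),
    gene_label = sub("^.*\r", "", all_nodes)
  ) |> dplyr::arrange(.data$group_id, .data$genome_id)
}

#' Pan-genome Venn partition of ortholog groups
#'
#' Each group is assigned to the exact subset of genomes represented in it;
#' counts per subset are returned over every non-empty subset of
#' `genome_ids` (zero counts included).
#'
#' @param groups Output of [build_ortholog_groups()].
#' @param genome_ids Character vector of genome ids (order fixes subset
#'   naming).
#' @return A tibble: `subset` (genome ids joined by `&`), `n_genomes`,
#'   `count`.
#' @export
venn_partition <- function(groups, genome_ids) {
  present <- groups |>
    dplyr::distinct(.data$group_id, .data$genome_id) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(subset = paste(sort(unique(.data$genome_id)),
                                    collapse = "&"), .groups = "drop")
  all_subsets <- unlist(purrr::map(
    seq_along(genome_ids),
    function(k) utils::combn(sort(genome_ids), k,
                             FUN = paste, collapse = "&")
  ))
  counts <- table(factor(present$subset, levels = all_subsets))
  tibble::tibble(
    subset = all_subsets,
    n_genomes = stringr::str_count(all_subsets, stringr::fixed("&")) + 1L,
    count = as.integer(counts)
  )
}

#' Ordered gene content between two anchor genes
#'
#' Genes strictly between the two anchors in genome order, following the
#' shorter arc on a circular genome, oriented so `anchor_1` comes first.
#' Invariant under genome rotation.
#'
#' @param annotations Feature/ORF tibble with `start`, `end`, `strand`,
#'   `label`.
#' @param anchor_label_1,anchor_label_2 Labels present exactly once each.
#' @param genome_length Genome length (for the circular arc choice).
#' @return The annotation rows between the anchors, in anchor_1-to-anchor_2
#'   order, with a `position_in_locus` column.
#' @export
locus_context <- function(annotations, anchor_label_1, anchor_label_2,
                          genome_length) {
  idx1 <- which(annotations$label == anchor_label_1)
  idx2 <- which(annotations$label == anchor_label_2)
  if (length(idx1) != 1L || length(idx2) != 1L) {
    stop("anchors must each be present exactly once (", anchor_label_1, ": ",
         length(idx1), ", ", anchor_label_2, ": ", length(idx2), ")",
         call. = FALSE)
  }
  L <- genome_length
  mid <- function(i) ((annotations$start[i] + annotations$end[i]) / 2) %% L
  m1 <- mid(idx1); m2 <- mid(idx2)
  fwd_arc <- (m2 - m1) %% L        # arc following increasing coordinates
  use_fwd <- fwd_arc <= L - fwd_arc
  mids <- vapply(seq_len(nrow(annotations)), mid, 0)
  if (use_fwd) {
    rel <- (mids - m1) %% L
    inside <- rel > 0 & rel < fwd_arc
    ord <- order(rel[inside])
  } else {
    rel <- (m1 - mids) %% L        # walk the other way from anchor 1
    inside <- rel > 0 & rel < (L - fwd_arc)
    ord <- order(rel[inside])
  }
  inside[c(idx1, idx2)] <- FALSE
  out <- annotations[which(inside)[ord], , drop = FALSE]
  dplyr::mutate(out, position_in_locus = dplyr::row_number())
}
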