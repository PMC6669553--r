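# Seeded generators producing inputs with the statistical structure every
# pipeline stage assumes: a circular genome with planted ORFs (ATG start,
# in-frame stop guard so the planted start is the 5'-most ATG of its
# segment), hr loci built from divergence-mutated core motifs, tandem direct
# repeats, SNVs with known synonymous/non-synonymous truth, and marker pairs
# diverged under the K2P process.

NON_STOP_CODONS <- names(GENETIC_CODE_TBL)[GENETIC_CODE_TBL != "*"]

#' Describe a synthetic genome
#'
#' The default design emulates the architecture of the study genome: a
#' circular 122,075-bp sequence at G+C 0.509 carrying 153 ORFs (one spanning
#' the origin), five hr loci built from the four hr core motifs, and two
#' direct repeats - dr1 with a 10-nt unit and dr2 with four 68-nt copies one
#' substitution apart.
#'
#' @param length Genome length (nt).
#' @param gc Target G+C fraction.
#' @param n_orfs Number of planted ORFs (lengths drawn 50-400 codons).
#' @param orf_lengths Optional explicit codon lengths (overrides `n_orfs`).
#' @param origin_spanning Plant the first ORF across the origin.
#' @param hr_designs Tibble `core_motif`, `copies`, `divergence`, `window`.
#' @param dr_designs Tibble `unit_length`, `copies`, `divergence`
#'   (substitution count over the whole array).
#' @return A `genome_design` list.
#' @export
genome_design <- function(length = 122075L, gc = 0.509, n_orfs = 153L,
                          orf_lengths = NULL, origin_spanning = TRUE,
                          hr_designs = default_hr_designs(),
                          dr_designs = default_dr_designs()) {
  structure(
    list(length = as.integer(length), gc = gc, n_orfs = as.integer(n_orfs),
         orf_lengths = orf_lengths, origin_spanning = origin_spanning,
         hr_designs = hr_designs, dr_designs = dr_designs),
    class = "genome_design"
  )
}

#' @rdname genome_design
#' @export
default_hr_designs <- function() {
  tibble::tibble(
    core_motif = c("TTTTTAGCGATG", "TTTTTAGCGATG", "TTACGAGAACATT",
                   "GTACTCGAAAA", "AAAATAGAACA"),
    copies = c(8L, 8L, 8L, 7L, 7L),
    divergence = 0.05,
    window = c(900L, 900L, 1300L, 800L, 500L)
  )
}

#' @rdname genome_design
#' @export
default_dr_designs <- function() {
  tibble::tibble(unit_length = c(10L, 68L), copies = c(6L, 4L),
                 divergence = c(0L, 1L))
}

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# random non-stop codon, approximately honouring the G+C target
random_codons <- function(n, gc) {
  out <- character(n)
  filled <- 0L
  while (filled < n) {
    draw <- matrix(random_bases(3L * (n - filled) * 2L, gc), nrow = 3L)
    cods <- apply(draw, 2, paste, collapse = "")
    cods <- cods[!cods %in% STOP_CODONS]
    take <- min(length(cods), n - filled)
    if (take > 0L) {
      out[(filled + 1L):(filled + take)] <- cods[seq_len(take)]
      filled <- filled + take
    }
  }
  out
}

mutate_string <- function(s, n_sub) {
  if (n_sub == 0L) return(s)
  v <- strsplit(s, "")[[1]]
  at <- sample(length(v), min(n_sub, length(v)))
  for (i in at) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

write_block <- function(chars, p, block, L) {
  v <- strsplit(block, "")[[1]]
  idx <- ((p + seq_along(v) - 1L) %% L) + 1L
  chars[idx] <- v
  chars
}

#' Simulate a circular genome with planted features
#'
#' Background bases are drawn i.i.d. at the target G+C. Each planted ORF is
#' written as an in-frame stop guard, ATG, random non-stop codons and a stop,
#' so the planted start is exactly the 5'-most ATG of its stop-to-stop
#' segment and [scan_orfs()] recovers the planted coordinates. hr loci place
#' `copies` divergence-mutated core motifs inside `window`; drs are tandem
#' unit arrays with `divergence` total substitutions. Identical seeds give
#' byte-identical output.
#'
#' @param design A [genome_design()].
#' @param seed Integer seed.
#' @param id Genome identifier.
#' @return A list: `genome` (a [circular_genome()]) and `truth` (list of
#'   tibbles `orfs`, `repeats`; background chance ORFs are not enumerated).
#' @export
simulate_genome <- function(design = genome_design(), seed = 1L,
                            id = "synthetic_genome") {
  set.seed(seed)
  L <- design$length
  chars <- random_bases(L, design$gc)

  lens <- design$orf_lengths %||%
    (if (design$n_orfs > 0L) sample(50:400, design$n_orfs, replace = TRUE)
     else integer(0))

  # build every feature block up front, then lay blocks out around the circle
  # with multinomially distributed background gaps (dense designs pack
  # deterministically instead of failing rejection sampling)
  blocks <- list()
  for (k in seq_along(lens)) {
    ncod <- lens[k]
    strand <- sample(c("+", "-"), 1L)
    codons <- random_codons(ncod - 1L, design$gc)
    block <- paste0("TAA", "ATG", paste(codons, collapse = ""), "TAA")
    if (strand == "-") block <- revcomp(block)
    blocks[[length(blocks) + 1L]] <- list(
      type = "orf", seq = block, strand = strand, length_codons = ncod,
      protein = paste0("M", paste(unname(GENETIC_CODE_TBL[codons]),
                                  collapse = "")),
      label = sprintf("orf_%03d", k)
    )
  }
  hr <- design$hr_designs
  for (k in seq_len(NROW(hr))) {
    motif <- hr$core_motif[k]
    m <- nchar(motif)
    win <- hr$window[k]
    wchars <- random_bases(win, design$gc)
    slots <- floor(seq(0L, win - m, length.out = hr$copies[k]))
    for (s in slots) {
      inst <- mutate_string(motif, stats::rbinom(1L, m, hr$divergence[k]))
      wchars[(s + 1L):(s + m)] <- strsplit(inst, "")[[1]]
    }
    blocks[[length(blocks) + 1L]] <- list(
      type = "hr", seq = paste(wchars, collapse = ""), unit_length = m,
      copies = as.numeric(hr$copies[k]), core_motif = motif
    )
  }
  dr <- design$dr_designs
  for (k in seq_len(NROW(dr))) {
    u <- dr$unit_length[k]
    unit <- paste(random_bases(u, design$gc), collapse = "")
    arr <- mutate_string(strrep(unit, dr$copies[k]), dr$divergence[k])
    blocks[[length(blocks) + 1L]] <- list(
      type = "dr", seq = arr, unit_length = u,
      copies = as.numeric(dr$copies[k]), core_motif = unit
    )
  }

  total <- sum(purrr::map_int(blocks, function(b) nchar(b$seq)))
  if (total > L) {
    stop("design does not fit: planted features need ", total,
         " nt but the genome is ", L, " nt", call. = FALSE)
  }
  if (length(blocks)) {
    # shuffle ORF blocks, then spread repeat blocks evenly between them so
    # distinct planted repeat regions stay far apart on the circle (two hr
    # loci dropped into one clustering window would merge into one region)
    types <- purrr::map_chr(blocks, "type")
    orf_blocks <- sample(which(types == "orf"))
    rep_blocks <- which(types != "orf")
    if (length(rep_blocks) && length(orf_blocks)) {
      at <- floor(seq(1L, length(orf_blocks),
                      length.out = length(rep_blocks) + 1L))[seq_along(rep_blocks)]
      ord <- integer(0)
      for (i in seq_along(orf_blocks)) {
        ord <- c(ord, orf_blocks[i], rep_blocks[which(at == i)])
      }
      blocks <- blocks[ord]
    } else {
      blocks <- blocks[sample.int(length(blocks))]
    }
    slack <- L - total
    gaps <- if (slack > 0L) {
      as.integer(stats::rmultinom(1L, slack, rep(1, length(blocks))))
    } else rep(0L, length(blocks))
    # offset so the first ORF block straddles the origin when requested
    first_orf <- which(purrr::map_chr(blocks, "type") == "orf")[1]
    offset <- 0L
    starts <- cumsum(c(0L, purrr::map_int(blocks, function(b) nchar(b$seq)) +
                         gaps))[seq_along(blocks)] + gaps
    if (design$origin_spanning && !is.na(first_orf)) {
      offset <- (L - starts[first_orf] -
                   nchar(blocks[[first_orf]]$seq) %/% 2L) %% L
    }
    for (k in seq_along(blocks)) blocks[[k]]$start <- (starts[k] + offset) %% L
    for (b in blocks) chars <- write_block(chars, b$start, b$seq, L)
  }

  orf_rows <- list(); rep_rows <- list()
  for (b in blocks) {
    if (b$type == "orf") {
      blen <- nchar(b$seq)
      start <- if (b$strand == "+") (b$start + 3L) %% L else b$start
      span <- blen - 3L                   # ORF = ATG..stop, guard excluded
      orf_rows[[length(orf_rows) + 1L]] <- tibble::tibble(
        genome_id = id, start = start, end = start + span, strand = b$strand,
        length_nt = span, length_codons = b$length_codons,
        protein = b$protein, label = b$label, kind = "CDS"
      )
    } else {
      rep_rows[[length(rep_rows) + 1L]] <- tibble::tibble(
        kind = b$type, start = b$start, end = b$start + nchar(b$seq),
        unit_length = b$unit_length, copies = b$copies,
        core_motif = b$core_motif
      )
    }
  }

  genome <- circular_genome(id, paste(chars, collapse = ""), "circular")
  truth <- list(
    orfs = if (length(orf_rows)) dplyr::bind_rows(orf_rows) else empty_orf_tbl(),
    repeats = if (length(rep_rows)) dplyr::bind_rows(rep_rows) else
      tibble::tibble(kind = character(), start = integer(), end = integer(),
                     unit_length = integer(), copies = numeric(),
                     core_motif = character())
  )
  list(genome = genome, truth = truth)
}

#' Diverge a sequence under the K2P substitution process
#'
#' Per-site substitution with the exact K80 transition probabilities at
#' branch length `true_d` and transition:transversion rate ratio `kappa`;
#' no indels.
#'
#' @param sequence DNA string (the ancestral copy).
#' @param true_d Expected substitutions/site along the branch.
#' @param kappa Transition:transversion rate ratio.
#' @param seed Integer seed.
#' @return A list: `seq_a` (input), `seq_b` (diverged), `true_d`, `kappa`.
#' @export
simulate_divergence <- function(sequence, true_d, kappa = 2, seed = 1L) {
  stopifnot(true_d >= 0, kappa > 0)
  set.seed(seed)
  v <- strsplit(toupper(sequence), "")[[1]]
  beta <- true_d / (kappa + 2)
  alpha <- kappa * beta
  p_ts <- 0.25 + 0.25 * exp(-4 * beta) - 0.5 * exp(-2 * (alpha + beta))
  p_tv <- 0.5 - 0.5 * exp(-4 * beta)      # both transversion targets together
  u <- stats::runif(length(v))
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))
  out <- v
  do_ts <- u < p_ts
  do_tv <- !do_ts & u < p_ts + p_tv
  out[do_ts] <- ts_partner[v[do_ts]]
  if (any(do_tv)) {
    pick <- stats::runif(sum(do_tv)) < 0.5
    out[do_tv] <- vapply(seq_len(sum(do_tv)), function(i) {
      tv_partners[[v[do_tv][i]]][if (pick[i]) 1L else 2L]
    }, character(1))
  }
  list(seq_a = sequence, seq_b = paste(out, collapse = ""),
       true_d = true_d, kappa = kappa)
}

# genome position (0-based) of coding-frame offset `off` in an ORF row
orf_offset_to_genome <- function(orf, off, L) {
  if (orf$strand == "+") ((orf$start + off) %% L) else ((orf$end - 1L - off) %% L)
}

#' Simulate SNVs with known effect truth
#'
#' Positions are sampled to hit the requested coding/intergenic and
#' synonymous/non-synonymous composition exactly (synonymity enforced by
#' codon-aware alternate-base choice; start and stop codons are avoided).
#' Frequencies are drawn from a normal clipped to (0.01, 0.99). The defaults
#' mirror the study's SNV table: 203 variants, 180 coding of which 92
#' synonymous, frequencies 0.38 +/- 0.046.
#'
#' @param genome A [circular_genome()].
#' @param truth_orfs Planted ORF tibble (non-overlapping).
#' @param n Total SNVs.
#' @param frac_coding Fraction inside ORFs.
#' @param frac_syn Fraction of coding SNVs that are synonymous.
#' @param freq_mean,freq_sd Frequency distribution parameters (fractions).
#' @param seed Integer seed.
#' @return A list: `variants` (tibble as [read_variants()] returns) and
#'   `truth` (tibble with the planted `effect` and `gene_label`).
#' @export
simulate_variants <- function(genome, truth_orfs, n = 203L,
                              frac_coding = 180 / 203, frac_syn = 92 / 180,
                              freq_mean = 0.38, freq_sd = 0.046, seed = 1L) {
  stopifnot(n >= 0L, frac_coding >= 0, frac_coding <= 1,
            frac_syn >= 0, frac_syn <= 1)
  set.seed(seed)
  L <- genome$length
  n_coding <- round(n * frac_coding)
  n_syn <- round(n_coding * frac_syn)
  n_nonsyn <- n_coding - n_syn
  n_inter <- n - n_coding

  in_orf <- logical(L)
  for (i in seq_len(nrow(truth_orfs))) {
    span <- truth_orfs$end[i] - truth_orfs$start[i]
    in_orf[((truth_orfs$start[i] + seq_len(span) - 1L) %% L) + 1L] <- TRUE
  }

  used <- logical(L)
  rows <- list()
  draw_coding <- function(want_syn, max_try = 500L) {
    for (try in seq_len(max_try)) {
      oi <- sample.int(nrow(truth_orfs), 1L)
      orf <- truth_orfs[oi, ]
      ci <- sample(2:(orf$length_codons - 1L), 1L)     # avoid start codon
      nt <- circular_subsequence(genome, orf$start, orf$end)
      if (orf$strand == "-") nt <- revcomp(nt)
      codon <- substr(nt, (ci - 1L) * 3L + 1L, ci * 3L)
      cps <- sample(1:3)
      for (cp in cps) {
        ref_c <- substr(codon, cp, cp)
        for (alt_c in sample(setdiff(c("A", "C", "G", "T"), ref_c))) {
          alt_codon <- codon
          substr(alt_codon, cp, cp) <- alt_c
          syn <- GENETIC_CODE_TBL[alt_codon] == GENETIC_CODE_TBL[codon]
          if (syn != want_syn || GENETIC_CODE_TBL[alt_codon] == "*") next
          off <- (ci - 1L) * 3L + (cp - 1L)
          p <- orf_offset_to_genome(orf, off, L)
          if (used[p + 1L]) next
          gref <- if (orf$strand == "+") ref_c else unname(COMPLEMENT[ref_c])
          galt <- if (orf$strand == "+") alt_c else unname(COMPLEMENT[alt_c])
          used[p + 1L] <<- TRUE
          return(tibble::tibble(
            position = p, ref = gref, alt = galt,
            effect = if (want_syn) "synonymous" else "non_synonymous",
            gene_label = orf$label
          ))
        }
      }
    }
    stop("could not place a ", if (want_syn) "synonymous" else "non-synonymous",
         " variant after ", max_try, " tries", call. = FALSE)
  }

  for (i in seq_len(n_syn)) rows[[length(rows) + 1L]] <- draw_coding(TRUE)
  for (i in seq_len(n_nonsyn)) rows[[length(rows) + 1L]] <- draw_coding(FALSE)
  free <- which(!in_orf & !used) - 1L
  if (n_inter > length(free)) stop("not enough intergenic space", call. = FALSE)
  for (p in sample(free, n_inter)) {
    ref <- circular_subsequence(genome, p, p + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      position = p, ref = ref, alt = alt, effect = "intergenic",
      gene_label = "intergenic"
    )
  }
  if (length(rows) == 0L) {
    empty <- tibble::tibble(position = integer(), ref = character(),
                            alt = character(), frequency = numeric(),
                            depth = integer())
    return(list(variants = empty,
                truth = tibble::tibble(position = integer(),
                                       effect = character(),
                                       gene_label = character())))
  }
  truth <- dplyr::bind_rows(rows)
  freq <- pmin(pmax(stats::rnorm(nrow(truth), freq_mean, freq_sd), 0.01), 0.99)
  variants <- tibble::tibble(
    position = truth$position, ref = truth$ref, alt = truth$alt,
    frequency = freq, depth = NA_integer_
  )
  ord <- order(variants$position)
  list(variants = variants[ord, ], truth = truth[ord, ])
}

#' Simulate a pan-genome gene-content design
#'
#' Builds `n_genomes` synthetic proteomes from a shared core set plus
#' per-genome private genes, each ortholog copy diverged by point
#' substitution, so RBH orthology and the Venn partition can be checked
#' against the design exactly.
#'
#' @param n_genomes Number of genomes.
#' @param n_core Ortholog groups present in every genome.
#' @param n_private Private genes per genome.
#' @param protein_length Length of each synthetic protein.
#' @param divergence Per-residue substitution probability between ortholog
#'   copies.
#' @param seed Integer seed.
#' @return A list: `proteomes` (named list of named character vectors) and
#'   `design` (tibble `gene`, `genomes`).
#' @export
simulate_proteome_set <- function(n_genomes = 5L, n_core = 20L,
                                  n_private = 5L, protein_length = 120L,
                                  divergence = 0.1, seed = 1L) {
  set.seed(seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rand_prot <- function(n) paste(sample(aas, n, replace = TRUE), collapse = "")
  mutate_prot <- function(s, pdiv) {
    v <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(v)) < pdiv
    v[hit] <- sample(aas, sum(hit), replace = TRUE)
    paste(v, collapse = "")
  }
  gids <- paste0("genome", seq_len(n_genomes))
  proteomes <- stats::setNames(vector("list", n_genomes), gids)
  for (g in gids) proteomes[[g]] <- character(0)
  design <- list()
  for (k in seq_len(n_core)) {
    anc <- rand_prot(protein_length)
    for (g in gids) {
      proteomes[[g]][[sprintf("core%03d", k)]] <- mutate_prot(anc, divergence)
    }
    design[[length(design) + 1L]] <- tibble::tibble(
      gene = sprintf("core%03d", k), genomes = paste(gids, collapse = "&")
    )
  }
  for (g in gids) {
    for (k in seq_len(n_private)) {
      nm <- sprintf("%s_private%02d", g, k)
      proteomes[[g]][[nm]] <- rand_prot(protein_length)
      design[[length(design) + 1L]] <- tibble::tibble(gene = nm, genomes = g)
    }
  }
  list(proteomes = purrr::map(proteomes, unlist),
       design = dplyr::bind_rows(design))
}
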