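test_that("translation follows the standard code and rejects bad input", {
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_equal(translate_cds("ATGGCTGCCTAA"), "MAA")
  expect_error(translate_cds("ATGTAAGCGTAA"), "internal stop")
  expect_error(translate_cds("ATGC"), "divisible")
  expect_error(translate_cds("ATGNNN"), "N")
  for (seed in 1:5) {
    cds <- paste0("ATG", paste(sample(NON_STOP_CODONS, 299, replace = TRUE),
                               collapse = ""), "TGA")
    expect_equal(translate_cds(cds), oracle_translate(cds))
  }
})

test_that("a genome with no ATG yields no ORFs", {
  g <- circular_genome("noatg", strrep("C", 600))
  expect_equal(nrow(scan_orfs(g, min_aa = 5)), 0L)
  expect_equal(nrow(scan_orfs(circular_genome("tiny", "ATGTAA"))), 0L)
})

test_that("scan_orfs equals the brute-force six-frame oracle on small genomes", {
  for (seed in 1:6) {
    g <- circular_genome(paste0("g", seed), random_dna(3000, seed))
    got <- scan_orfs(g, min_aa = 25)
    want <- oracle_scan_orfs(g, min_aa = 25)
    got_key <- sort(paste(got$start, got$end, got$strand))
    want_key <- sort(paste(want$start, want$end, want$strand))
    expect_equal(got_key, want_key, info = paste("seed", seed))
  }
})

test_that("an origin-spanning minus-strand ORF is found once with planted coordinates", {
  set.seed(42)
  ncod <- 122L
  codons <- sample(NON_STOP_CODONS, ncod - 1L, replace = TRUE)
  block <- paste0("TAA", "ATG", paste(codons, collapse = ""), "TAA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(block)))
  L <- 5000L
  bg <- random_dna(L, 43)
  p <- L - nchar(block) %/% 2L            # block straddles the origin
  chars <- strsplit(bg, "")[[1]]
  idx <- ((p + seq_len(nchar(block)) - 1L) %% L) + 1L
  chars[idx] <- strsplit(rc, "")[[1]]
  g <- circular_genome("wrap", paste(chars, collapse = ""))
  got <- scan_orfs(g, min_aa = 50)
  span <- 3L * (ncod + 1L)
  hit <- got[got$strand == "-" & got$start == p %% L & got$end == p %% L + span, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$protein,
               paste0("M", paste(unname(GENETIC_CODE_TBL[codons]), collapse = "")))
  # found once only
  expect_equal(sum(got$start == p %% L & got$strand == "-"), 1L)
})

test_that("scan_orfs is rotation-invariant and strand-symmetric", {
  sim <- simulate_genome(genome_design(length = 8000, n_orfs = 6,
                                       hr_designs = default_hr_designs()[0, ],
                                       dr_designs = default_dr_designs()[0, ]),
                         seed = 8)
  g <- sim$genome
  L <- genome_length(g)
  base <- scan_orfs(g, min_aa = 50)
  rot <- 2511L
  g_rot <- circular_genome("rot", circular_subsequence(g, rot, rot + L))
  rotated <- scan_orfs(g_rot, min_aa = 50)
  expect_equal(
    sort(paste((base$start - rot) %% L, base$length_nt, base$strand)),
    sort(paste(rotated$start, rotated$length_nt, rotated$strand))
  )
  g_rc <- circular_genome("rc", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(g$sequence))))
  flipped <- scan_orfs(g_rc, min_aa = 50)
  expect_setequal(base$protein, flipped$protein)
  expect_equal(sum(base$strand == "+"), sum(flipped$strand == "-"))
})

test_that("all planted ORFs are recovered exactly", {
  sim <- simulate_genome(genome_design(length = 30000, n_orfs = 40),
                         seed = 12)
  got <- scan_orfs(sim$genome, min_aa = 50)
  truth <- sim$truth$orfs
  key <- function(d) paste(d$start, d$end, d$strand)
  expect_true(all(key(truth) %in% key(got)))
  expect_equal(truth$protein,
               got$protein[match(key(truth), key(got))])
})

test_that("overlap filtering applies the <50%-of-own-length rule", {
  mk <- function(start, len, strand = "+") tibble::tibble(
    genome_id = "g", start = start, end = start + len, strand = strand,
    frame = start %% 3L, length_nt = len, length_codons = len %/% 3L - 1L,
    protein = "M", label = "", kind = "CDS"
  )
  # disjoint: both retained
  two <- dplyr::bind_rows(mk(0L, 300L), mk(400L, 150L))
  expect_equal(nrow(filter_overlaps(two, genome_length = 1000L)), 2L)
  # A 300 nt, B 150 nt, overlap 100: B drops (100/150 >= 0.5), A stays
  ab <- dplyr::bind_rows(mk(0L, 300L), mk(200L, 150L, "-"))
  kept <- filter_overlaps(ab, genome_length = 1000L)
  expect_equal(kept$length_nt, 300L)
  # equal 300-nt ORFs overlapping by 149: both retained (149/300 < 0.5)
  near <- dplyr::bind_rows(mk(0L, 300L), mk(151L, 300L, "-"))
  expect_equal(nrow(filter_overlaps(near, genome_length = 1000L)), 2L)
  # exactly 150/300 = 50% overlap: the later one drops (boundary is >=)
  at <- dplyr::bind_rows(mk(0L, 300L), mk(150L, 300L))
  expect_equal(nrow(filter_overlaps(at, genome_length = 1000L)), 1L)
})

test_that("overlap filtering is idempotent and its output pairwise satisfies the bound", {
  sim <- simulate_genome(genome_design(length = 12000, n_orfs = 10),
                         seed = 21)
  cand <- scan_orfs(sim$genome, min_aa = 50)
  L <- genome_length(sim$genome)
  kept <- filter_overlaps(cand, genome_length = L)
  again <- filter_overlaps(kept, genome_length = L)
  expect_equal(kept, again)
  if (nrow(kept) > 1L) {
    for (i in 1:(nrow(kept) - 1L)) for (j in (i + 1L):nrow(kept)) {
      ov <- wrapped_overlap(kept$start[i], kept$end[i],
                            kept$start[j], kept$end[j], L)
      expect_lt(ov / min(kept$length_nt[i], kept$length_nt[j]), 0.5)
    }
  }
})

test_that("homology labelling names identical matches and calls random ORFs unique", {
  set.seed(77)
  refs <- c(polh = random_protein(240), lef8 = random_protein(300),
            gp64 = random_protein(200))
  orfs <- tibble::tibble(
    genome_id = "g", start = c(0L, 1000L), end = c(723L, 1600L),
    strand = "+", frame = 0L, length_nt = c(723L, 600L),
    length_codons = c(240L, 199L),
    protein = c(refs[["polh"]], random_protein(199)),
    label = "", kind = "CDS"
  )
  lab <- label_homologs(orfs, refs, min_score = 60,
                        core_names = c("polh", "lef8"))
  expect_equal(lab$label, c("polh", "unique"))
  expect_equal(lab$core_gene, c(TRUE, FALSE))
  expect_warning(label_homologs(orfs, character(0)), "unique")
})
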