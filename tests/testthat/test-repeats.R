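test_that("motif counting matches enumeration, wraps, and is strand-consistent", {
  lin <- circular_genome("l", "AAAA", "linear")
  expect_equal(count_motif(lin, "AAA", strands = "forward"), 2L)
  expect_equal(count_motif(lin, "GGG", strands = "forward"), 0L)
  expect_equal(count_motif(lin, "AAA", strands = "forward",
                           overlapping = FALSE), 1L)
  # wrap: motif spans the origin on a circular genome
  g <- circular_genome("c", "TGAAAC")          # ...ACTGA wraps into CT? no: ACTG
  expect_equal(count_motif(g, "ACTG", strands = "forward"), 1L)
  # palindromic motif counts once per selected strand
  pal <- circular_genome("p", "GAATTCGG", "linear")
  expect_equal(count_motif(pal, "GAATTC", strands = "forward"), 1L)
  expect_equal(count_motif(pal, "GAATTC", strands = "both"), 2L)
  expect_error(count_motif(pal, "GAAXTC"), "non-IUPAC")
})

test_that("forward counts equal reverse counts on the reverse complement", {
  for (seed in 1:5) {
    g <- circular_genome("g", random_dna(400, seed))
    rc <- circular_genome("rc", as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(g$sequence))))
    motif <- substr(random_dna(8, seed + 100), 1, 8)
    rcm <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))
    expect_equal(count_motif(g, motif, strands = "forward"),
                 count_motif(rc, rcm, strands = "forward"))
    # both-strand counts are rotation-invariant
    rot <- circular_genome("rot", circular_subsequence(g, 137, 137 + 400))
    expect_equal(count_motif(g, motif), count_motif(rot, motif))
  }
})

test_that("no tandem repeats are reported on plain random sequence", {
  g <- circular_genome("r", random_dna(10000, 5))
  hits <- find_tandem_repeats(g, min_unit = 30, max_unit = 100,
                              min_copies = 3, min_identity = 90)
  expect_equal(nrow(hits), 0L)
})

test_that("a planted 68-nt x4 array with one substitution is found at high identity", {
  set.seed(6)
  unit <- random_dna(68)
  arr <- strsplit(strrep(unit, 4), "")[[1]]
  at <- sample(length(arr), 1)
  arr[at] <- setdiff(c("A", "C", "G", "T"), arr[at])[1]
  bg <- strsplit(random_dna(8000, 7), "")[[1]]
  bg[3000 + seq_along(arr) - 1] <- arr
  g <- circular_genome("dr2", paste(bg, collapse = ""))
  hits <- find_tandem_repeats(g, min_unit = 30, max_unit = 100,
                              min_copies = 3, min_identity = 90)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit_length, 68L)
  expect_equal(hits$copies, 4, tolerance = 0.1)
  expect_gte(hits$internal_identity, 98)
})

test_that("the smallest period wins over harmonics", {
  set.seed(9)
  unit <- random_dna(10)
  bg <- strsplit(random_dna(3000, 10), "")[[1]]
  bg[1000 + seq_len(120) - 1] <- strsplit(strrep(unit, 12), "")[[1]]
  g <- circular_genome("dr1", paste(bg, collapse = ""))
  hits <- find_tandem_repeats(g, min_unit = 5, max_unit = 60,
                              min_copies = 3, min_identity = 95)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit_length, 10L)
  expect_gte(hits$copies, 11.5)
})

test_that("planted arrays are recovered with the right unit length across seeds", {
  ok <- 0L
  n_sim <- 20L
  for (seed in seq_len(n_sim)) {
    set.seed(seed + 400)
    u_len <- sample(10:100, 1)
    n_cop <- sample(3:10, 1)
    unit <- random_dna(u_len)
    arr <- strsplit(strrep(unit, n_cop), "")[[1]]
    # 3% expected divergence, hard-capped at the 5% regime bound
    n_mut <- min(rbinom(1, length(arr), 0.03),
                 floor(0.05 * length(arr)))
    if (n_mut > 0) {
      at <- sample(length(arr), n_mut)
      for (i in at) arr[i] <- sample(setdiff(c("A", "C", "G", "T"), arr[i]), 1)
    }
    bg <- strsplit(random_dna(6000, seed + 800), "")[[1]]
    bg[2000 + seq_along(arr) - 1] <- arr
    g <- circular_genome("p", paste(bg, collapse = ""))
    hits <- find_tandem_repeats(g, min_unit = 5, max_unit = 120,
                                min_copies = 2.5, min_identity = 85)
    hit <- hits[hits$start > 1800 & hits$start < 2200, ]
    if (nrow(hit) >= 1L && any(hit$unit_length == u_len)) ok <- ok + 1L
  }
  expect_gte(ok / n_sim, 0.95)
})

test_that("hr clustering recovers planted clusters and honours the gap window", {
  motif <- "TTTTTAGCGATG"
  bg <- strsplit(random_dna(40000, 11), "")[[1]]
  put <- function(bg, pos) {
    bg[pos + seq_len(nchar(motif)) - 1] <- strsplit(motif, "")[[1]]
    bg
  }
  c1 <- c(5000, 5400, 5900, 6300, 6800, 7100, 7500, 7900)   # 8 hits
  c2 <- c(28000, 28500, 29100, 29600, 30000)                # 5 hits
  for (p in c(c1, c2)) bg <- put(bg, p)
  g <- circular_genome("hr", paste(bg, collapse = ""))
  regs <- cluster_hrs(g, motif, window = 2000, min_hits = 3, max_mismatch = 0)
  expect_equal(nrow(regs), 2L)
  expect_equal(regs$n_hits, c(8L, 5L))
  expect_equal(regs$start, c(4999L, 27999L))
  expect_equal(regs$end, c(7899L, 29999L) + nchar(motif))
  # a single cluster whose largest internal gap equals the window stays one
  bg2 <- strsplit(random_dna(10000, 12), "")[[1]]
  pos2 <- c(1000, 3000, 5000)                               # gaps exactly 2000
  for (p in pos2) bg2 <- put(bg2, p)
  g2 <- circular_genome("hr2", paste(bg2, collapse = ""))
  regs2 <- cluster_hrs(g2, motif, window = 2000, min_hits = 2,
                       max_mismatch = 0)
  expect_equal(nrow(regs2), 1L)
  regs3 <- cluster_hrs(g2, motif, window = 1999, min_hits = 1,
                       max_mismatch = 0)
  expect_equal(nrow(regs3), 3L)
  # no hits: empty
  empty <- cluster_hrs(circular_genome("e", strrep("C", 5000)), motif)
  expect_equal(nrow(empty), 0L)
})

test_that("pairwise identity matches hand alignments and is symmetric", {
  s <- random_dna(50, 13)
  expect_equal(pairwise_identity(s, s), 100.0)
  a10 <- "ACGTACGTAC"
  b10 <- "ACGTTCGTAC"                                    # one substitution
  expect_equal(pairwise_identity(a10, b10), 90.0)
  # sequence vs itself minus a 10-nt internal block: the single-gap alignment
  # gives 100 matches over 110 columns
  s110 <- random_dna(110, 14)
  del <- paste0(substr(s110, 1, 45), substr(s110, 56, 110))
  expect_equal(pairwise_identity(s110, del), 90.9)
  for (seed in 1:4) {
    x <- random_dna(60, seed + 50); y <- random_dna(60, seed + 60)
    expect_equal(pairwise_identity(x, y), pairwise_identity(y, x))
    expect_lt(pairwise_identity(x, y), 100)
  }
})
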