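test_that("six-frame translation covers both strands and handles N and stops", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(fr[["+1"]], "MK")
  expect_equal(six_frame_translate("TTTCAT")[["-1"]], "MK")
  expect_equal(six_frame_translate("ATGTAAATG")[["+1"]], "M*M")
  expect_equal(six_frame_translate("ATGNAA")[["+1"]], "MX")
  # trailing partial codons dropped
  expect_equal(six_frame_translate("ATGAAAC")[["+1"]], "MK")
  expect_error(six_frame_translate("ATGQ"), "non-nucleotide")
})

test_that("local alignment matches hand scores and the exhaustive DP oracle", {
  sc <- scoring_scheme()
  # BLOSUM62 diagonal: M 5, K 5, T 5
  expect_equal(local_align("MKT", "MKT", sc)$score, 15)
  expect_true(local_align("AAA", "WWW", sc)$no_hit)

  set.seed(99)
  for (i in 1:80) {
    a <- paste(sample(c("A", "R", "N", "D"), sample(1:6, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "R", "N", "D"), sample(1:6, 1),
                      replace = TRUE), collapse = "")
    got <- local_align(a, b, sc)
    want <- sw_oracle(a, b, sc$matrix)
    expect_equal(if (got$no_hit) 0 else got$score, want,
                 info = paste(a, b))
  }
  expect_error(local_align("MJZ", "MKT"), "alphabet")
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(7)
  for (i in 1:20) {
    a <- random_protein(sample(5:40, 1))
    b <- random_protein(sample(5:40, 1))
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  }
})

test_that("E-values follow the Karlin-Altschul formula", {
  sc <- scoring_scheme()
  # closed-form inversion: E = 1 at score ln(K m n) / lambda
  s1 <- log(sc$K * 100 * 1000) / sc$lambda
  expect_equal(evalue(s1, 100, 1000), 1)
  # linear in the search space
  expect_equal(evalue(30, 100, 2e5), 2 * evalue(30, 100, 1e5))
  # arithmetic oracle, evaluated independently of the implementation
  expect_equal(evalue(50, 100, 1e5, sc),
               0.134 * 100 * 1e5 * exp(-0.3176 * 50))
  # monotone decreasing in score
  e <- evalue(seq(0, 100, by = 5), 100, 1e5)
  expect_true(all(diff(e) < 0))
})

test_that("ORF extraction recovers planted genes exactly, on both strands", {
  fam <- make_family(172, 2, 0.03, seed = 31)
  gen <- make_genomes(list(g = list(species = "s", genes = list(
    list(family = "sc", protein = fam$members[[1]], strand = "+"),
    list(family = "sc", protein = fam$members[[2]], strand = "-")))),
    intergenic_len = 120, seed = 32)
  res <- survey(gen$genomes, c(anc = fam$ancestor))
  tr <- truth_cds(gen$truth)
  expect_equal(nrow(res), 2)
  for (i in 1:2) {
    j <- which(res$strand == tr$strand[i])
    expect_equal(res$start[j], tr$cds_start[i])
    expect_equal(res$end[j], tr$cds_end[i])
    expect_equal(res$protein[j], tr$protein[i])
    expect_equal(res$length_aa[j], 172)
  }
})

test_that("ORF extraction on a hand-built toy genome places coordinates correctly", {
  # forward gene: stop TAA + ATG AAA TGG + stop TGA at offset 6
  g <- paste0("ACACAC", "TAA", "ATGAAATGG", "TGA", "ACACAA")
  orf <- extract_orf(g, frame = +1, hit_interval = c(3L, 6L))
  expect_equal(orf$protein, "MKW")
  expect_equal(c(orf$start, orf$end), c(9, 18))
  expect_equal(orf$strand, "+")
  # same gene on the reverse strand
  grc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  orf2 <- extract_orf(grc, frame = -1, hit_interval = c(3L, 6L))
  expect_equal(orf2$protein, "MKW")
  expect_equal(orf2$strand, "-")
  expect_equal(orf2$end - orf2$start, 9)
  expect_equal(c(orf2$start, orf2$end), nchar(g) - c(18, 9))
})

test_that("a stop codon inside the aligned interval resolves to the larger segment", {
  # frame: xxx STOP [AAA AAA STOP CCC] STOP -> larger sub-segment is AAA AAA
  g <- paste0("TAA", "AAAAAA", "TGA", "CCCCCC", "TAG")
  expect_warning(
    orf <- extract_orf(g, frame = +1, hit_interval = c(1L, 6L)),
    "stop codon inside")
  expect_equal(orf$protein, "KK")
})

test_that("ORFs arising in random background are short (geometric stop spacing)", {
  # stop density 3/64 per codon; mean stop-to-stop length ~ 64/3 codons
  set.seed(55)
  lens <- replicate(300, {
    g <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
    fr <- six_frame_translate(g)[["+1"]]
    runs <- nchar(strsplit(fr, "*", fixed = TRUE)[[1]])
    mean(runs)
  })
  expect_lt(abs(mean(lens) - 64 / 3), 2)
})

test_that("survey recovers planted genes, deduplicates and rejects degenerate input", {
  fams <- lapply(1:3, function(k)
    make_family(c(172, 320, 350)[k], 3, 0.05, seed = 40 + k))
  genes <- list()
  for (k in 1:3) for (i in 1:3)
    genes[[length(genes) + 1]] <- list(
      family = c("sc", "lc_typeI", "lc_typeII")[k],
      protein = fams[[k]]$members[[i]],
      strand = c("+", "-")[(i %% 2) + 1])
  gen <- make_genomes(list(gX = list(species = "x", genes = genes[1:5]),
                           gY = list(species = "y", genes = genes[6:9])),
                      intergenic_len = 150, seed = 44)
  queries <- c(q_sc = fams[[1]]$ancestor, q1 = fams[[2]]$ancestor,
               q2 = fams[[3]]$ancestor)
  res <- survey(gen$genomes, queries)
  tr <- truth_cds(gen$truth)
  expect_equal(nrow(res), 9)
  expect_setequal(paste(res$genome_id, res$start, res$end),
                  paste(tr$genome_id, tr$cds_start, tr$cds_end))
  # each locus reported once even when hit by multiple queries
  expect_false(any(duplicated(
    paste(res$genome_id, res$strand, res$start, res$end))))
  # impossible threshold
  expect_equal(nrow(survey(gen$genomes, queries, cutoff = 0)), 0)
  expect_error(survey(Biostrings::DNAStringSet(), queries))
})

test_that("survey recall is 100% for planted genes up to 20% divergence", {
  recalls <- vapply(1:20, function(s) {
    fam <- make_family(172, 3, sub_rate = 0.2, seed = 500 + s)
    gen <- make_genomes(list(g = list(species = "s", genes = list(
      list(family = "sc", protein = fam$members[[1]], strand = "+"),
      list(family = "sc", protein = fam$members[[2]], strand = "-"),
      list(family = "sc", protein = fam$members[[3]], strand = "+")))),
      intergenic_len = 150, seed = 600 + s)
    res <- survey(gen$genomes, c(anc = fam$ancestor))
    tr <- truth_cds(gen$truth)
    mean(paste(tr$cds_start, tr$cds_end) %in% paste(res$start, res$end))
  }, numeric(1))
  expect_true(all(recalls == 1))
})

test_that("surveying a genome and its reverse complement yields the same proteins", {
  fam <- make_family(170, 2, 0.1, seed = 71)
  gen <- make_genomes(list(g = list(species = "s", genes = list(
    list(family = "sc", protein = fam$members[[1]], strand = "+"),
    list(family = "sc", protein = fam$members[[2]], strand = "-")))),
    intergenic_len = 150, seed = 72)
  fwd <- survey(gen$genomes, c(q = fam$ancestor))
  rc <- Biostrings::reverseComplement(gen$genomes)
  names(rc) <- names(gen$genomes)
  rev <- survey(rc, c(q = fam$ancestor))
  expect_setequal(fwd$protein, rev$protein)
  expect_setequal(fwd$strand, c("+", "-"))
  expect_setequal(rev$strand, c("-", "+"))
})
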