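test_that("family generation obeys the zero-rate identity and determinism", {
  fam <- make_family(100, n = 5, sub_rate = 0, seed = 3)
  expect_true(all(fam$members == fam$ancestor))

  a <- make_family(120, n = 4, sub_rate = 0.1, seed = 9)
  b <- make_family(120, n = 4, sub_rate = 0.1, seed = 9)
  expect_identical(a, b)
  c <- make_family(120, n = 4, sub_rate = 0.1, seed = 10)
  expect_false(identical(a$members, c$members))

  expect_error(make_family(0, 3, 0.1, seed = 1))
  expect_error(make_family(100, 0, 0.1, seed = 1))
  expect_error(make_family(100, 3, 1.5, seed = 1))
})

test_that("mean pairwise identity of a diverged family matches the Monte-Carlo expectation", {
  # Independent oracle: simulate many substituted pairs and count matching
  # sites directly (excluding the fixed initiator), then compare the
  # generator's observed identity with the simulated expectation.
  sub_rate <- 0.05
  L <- 170
  set.seed(404)
  sim <- replicate(1e4, {
    anc <- sample(20, L - 1, replace = TRUE)
    mutate <- function(s) {
      hit <- runif(L - 1) < sub_rate
      s[hit] <- vapply(s[hit], function(x) sample(setdiff(1:20, x), 1), 1L)
      s
    }
    mean(mutate(anc) == mutate(anc))
  })
  expected <- mean(sim)

  # members of one family share an ancestor, so pairwise identities are
  # correlated; average over several independent families
  observed <- mean(vapply(1:5, function(s) {
    fam <- make_family(L, n = 20, sub_rate = sub_rate, seed = s)
    mem <- do.call(rbind, strsplit(fam$members, ""))[, -1, drop = FALSE]
    pairs <- utils::combn(nrow(mem), 2)
    mean(apply(pairs, 2, function(p) mean(mem[p[1], ] == mem[p[2], ])))
  }, numeric(1)))
  expect_lt(abs(observed - expected), 0.01)
})

test_that("planted genomes are truth-consistent on both strands", {
  fam <- make_family(172, n = 2, sub_rate = 0.05, seed = 5)
  specs <- list(
    gA = list(species = "spA", genes = list(
      list(family = "sc", protein = fam$members[[1]], strand = "+"),
      list(family = "sc", protein = fam$members[[2]], strand = "-"),
      list(family = "lc_typeI", length = 320, strand = "+",
           localization = "SPI"))),
    gB = list(species = "spB", genes = list()))
  gen <- make_genomes(specs, intergenic_len = 100, seed = 6)
  expect_true(check_truth(gen$genomes, gen$truth))
  expect_equal(nrow(gen$truth), 3)
  expect_setequal(gen$truth$strand[1:2], c("+", "-"))
  # locus invariant: 3*aa + 3 nucleotides fit exactly
  expect_true(all(gen$truth$end - gen$truth$start ==
                    3 * gen$truth$length_aa + 3))
  # determinism
  gen2 <- make_genomes(specs, intergenic_len = 100, seed = 6)
  expect_identical(as.character(gen$genomes), as.character(gen2$genomes))
})

test_that("a hand-built reverse-strand gene round-trips through its locus", {
  # 9-residue toy gene placed explicitly; check coordinates by hand
  gen <- make_genomes(list(g = list(species = "s", genes = list(
    list(family = "sc", protein = "MKTAYIAKQ", strand = "-", at = 12)))),
    intergenic_len = 10, seed = 8)
  tr <- truth_cds(gen$truth)
  nt <- substr(as.character(gen$genomes[[1]]), tr$cds_start + 1, tr$cds_end)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  expect_identical(
    as.character(Biostrings::translate(Biostrings::DNAString(rc))),
    "MKTAYIAKQ")
  # explicit placement: segment spans [12, 12 + 27 + 6)
  expect_equal(gen$truth$start, 12)
  expect_equal(gen$truth$end, 12 + 27 + 3)
})

test_that("overlapping explicit loci are rejected", {
  expect_error(
    make_genomes(list(g = list(species = "s", genes = list(
      list(family = "sc", protein = "MKTAYIAKQ", strand = "+", at = 10),
      list(family = "sc", protein = "MNPLLGLLK", strand = "+", at = 20)))),
      intergenic_len = 10, seed = 1),
    "overlap")
})

test_that("truth tables round-trip through TSV with 1-based coordinates", {
  gen <- make_genomes(list(g = list(species = "s", genes = list(
    list(family = "sc", length = 160, strand = "+")))), seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(gen$truth, path)
  on_disk <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(on_disk$start, gen$truth$start + 1)  # 1-based inclusive
  back <- read_truth_table(path)
  expect_equal(back$start, gen$truth$start)
  expect_equal(back$protein, gen$truth$protein)
})

test_that("kinetic datasets honour the noiseless midpoint and noise calibration", {
  m <- kinetic_model(Vmax = 10, Km = 2)
  d <- make_kinetic_dataset(m, S_grid = 2)
  expect_equal(d$v, 5)  # S = Km -> Vmax / 2

  d1 <- make_kinetic_dataset(m, c(0.5, 1, 2), noise_cv = 0.05, seed = 11)
  d2 <- make_kinetic_dataset(m, c(0.5, 1, 2), noise_cv = 0.05, seed = 11)
  expect_identical(d1, d2)

  # Monte-Carlo oracle: mean of noisy v at fixed S approaches noiseless v
  n <- 1e4
  vs <- vapply(seq_len(n), function(i)
    make_kinetic_dataset(m, 1, noise_cv = 0.1, seed = 2e6 + i)$v, 0)
  v0 <- velocity(1, m)
  se <- stats::sd(vs) / sqrt(n)
  expect_lt(abs(mean(vs) - v0), 3 * se)
  expect_error(make_kinetic_dataset(m, c(-1, 2)))
})

test_that("coordinate sets reproduce the planted rigid transform and jitter level", {
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  cc <- make_coords(60, R, c(4, -2, 9), jitter_sd = 0, seed = 21)
  expect_equal(kabsch_superpose(cc$reference, cc$transformed)$rmsd, 0,
               tolerance = 1e-10)

  # per-coordinate sd sigma -> 3-D rms displacement sigma * sqrt(3)
  cc2 <- make_coords(200, R, c(1, 1, 1), jitter_sd = 0.5, seed = 22)
  rmsd <- kabsch_superpose(cc2$reference, cc2$transformed)$rmsd
  expect_lt(abs(rmsd - 0.5 * sqrt(3)) / (0.5 * sqrt(3)), 0.1)

  expect_error(make_coords(10, diag(3) * 2, seed = 1), "rotation")
  expect_error(make_coords(3, seed = 1,
                           reference = cbind(1:3, 1:3, 1:3)), "collinear")
})

test_that("pH profiles plant a recoverable optimum", {
  prof <- make_ph_profile(optimum_pH = 9, noise_cv = 0)
  expect_equal(ph_optimum(prof)$ph_optimum, 9)
  expect_equal(nrow(prof), 14)  # pH 4.5..11 in 0.5 steps

  # planted optimum recovered under mild noise in >= 95/100 seeded runs
  hits <- sum(vapply(1:100, function(s) {
    p <- make_ph_profile(optimum_pH = 9, noise_cv = 0.02, seed = s)
    ph_optimum(p)$ph_optimum == 9
  }, logical(1)))
  expect_gte(hits, 95)

  # flat profile: tie broken to the lowest pH, flagged
  flat <- data.frame(pH = c(5, 6, 7), activity = c(1, 1, 1))
  res <- ph_optimum(flat)
  expect_equal(res$ph_optimum, 5)
  expect_true(res$tie)
  expect_error(make_ph_profile(grid = numeric()))
})

test_that("negative-control genomes yield no survey hits on almost all seeds", {
  query <- make_family(172, 1, 0, seed = 77)$ancestor
  zero <- vapply(1:50, function(s) {
    gen <- make_genomes(list(g = list(species = "s", genes = list())),
                        intergenic_len = 3000, seed = 1000 + s)
    nrow(survey(gen$genomes, c(q = query))) == 0L
  }, logical(1))
  expect_gte(sum(zero), 49)
})
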