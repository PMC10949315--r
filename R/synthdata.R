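#' Generate a mutationally diverged protein family
#'
#' Simulates a family of homologous proteins by applying independent
#' per-site substitutions to a common ancestor, emulating the sequence
#' divergence that makes related asparaginases cluster together in a
#' similarity graph. Substitutions replace a residue uniformly with any of
#' the other 19 amino acids. The first residue is fixed to methionine so
#' that family members remain translatable as complete ORFs.
#'
#' @param ancestor_length Ancestor length in residues (ignored when
#'   `ancestor` is supplied).
#' @param n Number of descendant sequences to generate.
#' @param sub_rate Per-site substitution probability in `[0, 1]`.
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @param ancestor Optional ancestor sequence (single string); generated
#'   uniformly at random when `NULL`.
#' @return A list with elements `ancestor` (string) and `members`
#'   (character vector of length `n`, named `fam1`, `fam2`, ...).
#' @examples
#' fam <- make_family(172, n = 5, sub_rate = 0.05, seed = 1)
#' nchar(fam$members)
#' @export
make_family <- function(ancestor_length, n, sub_rate, seed, ancestor = NULL) {
  assert_scalar_number(n, "n", min = 1)
  assert_scalar_number(sub_rate, "sub_rate", min = 0)
  if (sub_rate > 1) stop("'sub_rate' must be at most 1", call. = FALSE)
  withr::with_seed(seed, {
    if (is.null(ancestor)) {
      assert_scalar_number(ancestor_length, "ancestor_length", min = 1,
                           strict = FALSE)
      if (ancestor_length < 1) stop("'ancestor_length' must be positive")
      anc <- c("M", sample(AA20, ancestor_length - 1L, replace = TRUE))
    } else {
      assert_protein(ancestor, "ancestor")
      anc <- strsplit(ancestor, "")[[1]]
    }
    members <- vapply(seq_len(n), function(i) {
      s <- anc
      hit <- which(runif(length(s)) < sub_rate)
      hit <- hit[hit > 1L]  # keep the initiator Met
      if (length(hit)) {
        s[hit] <- vapply(s[hit], function(a)
          sample(setdiff(AA20, a), 1L), character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    list(ancestor = paste(anc, collapse = ""),
         members = setNames(members, paste0("fam", seq_len(n))))
  })
}

# Reverse-translate a protein, drawing uniformly among synonymous codons.
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    cand <- names(gc)[gc == a]
    if (!length(cand)) stop("no codon for residue ", a)
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }, character(1))
  paste(codons, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate synthetic genomes with planted asparaginase ORFs
#'
#' Builds nucleotide genomes in which protein-coding genes of known
#' sequence, strand and length class are embedded stop-to-stop in a random
#' intergenic background, together with a truth table recording every
#' planted locus. This replaces a genome snapshot downloaded from a
#' sequence archive: downstream search results can be scored against the
#' planted truth. Intergenic background is i.i.d. uniform over A/C/G/T,
#' which maximises stop-codon density and keeps spurious ORFs short;
#' codons are drawn uniformly among synonymous choices.
#'
#' Each element of `genome_specs` describes one genome: a list with a
#' `species` string and a `genes` list. Each gene is a list with fields
#' `family` (e.g. `"sc"`, `"lc_typeI"`, `"lc_typeII"`), `strand`
#' (`"+"`/`"-"`), `localization` (`"cytoplasmic"`, `"SPI"`, `"SPII"`),
#' and either `protein` (explicit sequence) or `length` (residues, drawn
#' gene is then generated as a fresh random protein). Short-chain lengths
#' default to 160--180 and long-chain to 300--400 when `length` is `NA`.
#' An optional `at` gives an explicit 0-based forward-strand start for the
#' embedded segment; overlapping requests are rejected.
#'
#' @param genome_specs Named list of genome descriptions (names become
#'   genome ids); see Details.
#' @param intergenic_len Intergenic spacer length in nucleotides (>= 3).
#' @param seed Integer seed.
#' @return A list with `genomes` (a named [Biostrings::DNAStringSet]) and
#'   `truth` (data frame: `genome_id`, `species`, `start`, `end`, `strand`,
#'   `family`, `localization`, `length_aa`, `protein`). `start`/`end` are
#'   0-based half-open forward-strand coordinates of the CDS plus its stop
#'   codon; use [truth_cds()] for the stop-free CDS interval.
#' @seealso [write_truth_table()], [survey()]
#' @export
make_genomes <- function(genome_specs, intergenic_len = 200, seed) {
  if (!length(genome_specs)) stop("'genome_specs' must be non-empty")
  if (is.null(names(genome_specs)) || anyNA(names(genome_specs)) ||
      any(names(genome_specs) == ""))
    stop("'genome_specs' must be a named list (names are genome ids)")
  assert_scalar_number(intergenic_len, "intergenic_len", min = 3)
  withr::with_seed(seed, {
    truth <- list()
    seqs <- character(length(genome_specs))
    for (gi in seq_along(genome_specs)) {
      gid <- names(genome_specs)[gi]
      spec <- genome_specs[[gi]]
      species <- spec$species %||% gid
      genes <- spec$genes %||% list()
      placed <- list()   # list of c(start, end) of embedded segments
      cursor <- intergenic_len
      segs <- list()
      for (g in genes) {
        prot <- g$protein
        if (is.null(prot)) {
          len <- g$length
          if (is.null(len) || is.na(len)) {
            len <- if (identical(g$family, "sc")) sample(160:180, 1L)
                   else sample(300:400, 1L)
          }
          prot <- paste(c("M", sample(AA20, len - 1L, replace = TRUE)),
                        collapse = "")
        }
        assert_protein(prot, "protein")
        strand <- g$strand %||% "+"
        if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
        cds <- reverse_translate(prot)
        seg <- paste0(sample(STOP_CODONS, 1L), cds, sample(STOP_CODONS, 1L))
        at <- g$at %||% cursor
        seg_iv <- c(at, at + nchar(seg))
        for (p in placed)
          if (seg_iv[1] < p[2] && p[1] < seg_iv[2])
            stop("requested loci overlap in genome '", gid, "'",
                 call. = FALSE)
        placed[[length(placed) + 1L]] <- seg_iv
        # locus = CDS + its stop codon, on forward-strand coordinates
        locus <- if (strand == "+") c(seg_iv[1] + 3L, seg_iv[2])
                 else c(seg_iv[1], seg_iv[2] - 3L)
        segs[[length(segs) + 1L]] <- list(
          seq = if (strand == "+") seg else revcomp_chr(seg),
          start = seg_iv[1], end = seg_iv[2])
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = gid, species = species,
          start = locus[1], end = locus[2], strand = strand,
          family = g$family %||% "sc",
          localization = g$localization %||% "cytoplasmic",
          length_aa = nchar(prot), protein = prot,
          stringsAsFactors = FALSE)
        cursor <- max(cursor, seg_iv[2]) + intergenic_len
      }
      total <- if (length(placed)) max(vapply(placed, `[`, 0, 2)) +
                 intergenic_len else intergenic_len
      gseq <- strsplit(random_dna(total), "")[[1]]
      for (s in segs)
        gseq[(s$start + 1L):s$end] <- strsplit(s$seq, "")[[1]]
      seqs[gi] <- paste(gseq, collapse = "")
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(genome_id = character(), species = character(),
                 start = integer(), end = integer(), strand = character(),
                 family = character(), localization = character(),
                 length_aa = integer(), protein = character())
    genomes <- Biostrings::DNAStringSet(setNames(seqs, names(genome_specs)))
    list(genomes = genomes, truth = truth)
  })
}

#' CDS interval of a truth-table row
#'
#' Strips the stop codon from a planted locus, returning the 0-based
#' half-open forward-strand interval of the coding sequence proper (the
#' interval reported by [extract_orf()]).
#'
#' @param truth A truth table from [make_genomes()] (or one row of it).
#' @return The truth table with `cds_start`/`cds_end` columns added.
#' @export
truth_cds <- function(truth) {
  truth$cds_start <- ifelse(truth$strand == "+", truth$start, truth$start + 3L)
  truth$cds_end <- ifelse(truth$strand == "+", truth$end - 3L, truth$end)
  truth
}

#' Verify truth-table consistency
#'
#' Checks that strand-aware translation of every planted locus reproduces
#' the stored protein exactly.
#'
#' @param genomes Named [Biostrings::DNAStringSet].
#' @param truth Truth table from [make_genomes()].
#' @return `TRUE` invisibly, or an error naming the offending row.
#' @export
check_truth <- function(genomes, truth) {
  truth <- truth_cds(truth)
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    nt <- substr(as.character(genomes[[row$genome_id]]),
                 row$cds_start + 1L, row$cds_end)
    if (row$strand == "-") nt <- revcomp_chr(nt)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    if (!identical(prot, row$protein))
      stop("truth table row ", i, " does not translate to its protein")
  }
  invisible(TRUE)
}

#' Write / read a truth table as TSV
#'
#' Coordinates are written 1-based inclusive (`start`, `end` columns) and
#' converted back to the internal 0-based half-open convention on read.
#'
#' @param truth Truth table from [make_genomes()].
#' @param path Output/input TSV path.
#' @return `write_truth_table()`: the path, invisibly;
#'   `read_truth_table()`: the truth table.
#' @export
write_truth_table <- function(truth, path) {
  out <- truth
  out$start <- out$start + 1L  # 1-based inclusive on disk
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  x$start <- x$start - 1L
  x
}

#' Generate a synthetic kinetic assay dataset
#'
#' Evaluates a kinetic model (see [velocity()]) on a substrate grid and
#' multiplies each velocity by mean-one lognormal noise of a given
#' coefficient of variation, emulating replicate scatter in initial-rate
#' measurements. `noise_cv = 0` returns exact model values.
#'
#' @param model A [kinetic_model()].
#' @param S_grid Substrate concentrations, mM (all > 0).
#' @param E0 Enzyme concentration (same units used to convert Vmax to
#'   kcat); stored as an attribute for downstream fits. Optional.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed (required when `noise_cv > 0`).
#' @return Data frame with columns `S_mM` and `v` plus attribute `E0`.
#' @export
make_kinetic_dataset <- function(model, S_grid, E0 = NULL, noise_cv = 0,
                                 seed = NULL) {
  if (any(S_grid <= 0)) stop("substrate concentrations must be positive")
  assert_scalar_number(noise_cv, "noise_cv", min = 0)
  v <- velocity(S_grid, model)
  if (noise_cv > 0) {
    if (is.null(seed)) stop("'seed' is required when noise_cv > 0")
    v <- withr::with_seed(seed, {
      sdlog <- sqrt(log(1 + noise_cv^2))
      v * exp(rnorm(length(v), mean = -sdlog^2 / 2, sd = sdlog))
    })
  }
  out <- data.frame(S_mM = S_grid, v = v)
  attr(out, "E0") <- E0
  out
}

#' Generate paired coordinate sets related by a rigid transform
#'
#' Produces a reference point cloud and a copy that has been rotated,
#' translated and optionally perturbed with isotropic Gaussian jitter --
#' fixtures for testing least-squares superposition.
#'
#' @param n_points Number of points (>= 3).
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation Length-3 translation vector, Angstrom.
#' @param jitter_sd Gaussian jitter standard deviation per coordinate,
#'   Angstrom.
#' @param seed Integer seed.
#' @param reference Optional explicit reference matrix (`n_points` x 3);
#'   collinear point sets are rejected.
#' @return List with `reference` and `transformed` (both n x 3 matrices).
#' @export
make_coords <- function(n_points, rotation = diag(3),
                        translation = c(0, 0, 0), jitter_sd = 0, seed,
                        reference = NULL) {
  assert_scalar_number(n_points, "n_points", min = 3)
  check_rotation(rotation)
  assert_scalar_number(jitter_sd, "jitter_sd", min = 0)
  withr::with_seed(seed, {
    ref <- if (is.null(reference))
      matrix(rnorm(n_points * 3, sd = 10), ncol = 3) else as.matrix(reference)
    if (nrow(ref) < 3) stop("at least 3 points are required")
    ctr <- scale(ref, scale = FALSE)
    if (qr(ctr)$rank < 2)
      stop("reference points are collinear; superposition would be degenerate")
    trans <- ref %*% t(rotation) +
      matrix(translation, nrow(ref), 3, byrow = TRUE)
    if (jitter_sd > 0)
      trans <- trans + matrix(rnorm(length(trans), sd = jitter_sd), ncol = 3)
    list(reference = ref, transformed = trans)
  })
}

check_rotation <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)))
    stop("'rotation' must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("'rotation' must be a proper rotation (orthonormal, det +1)")
  invisible(R)
}

#' Generate a synthetic pH-activity profile
#'
#' Bell-shaped (Gaussian in pH) relative activity peaking at a planted
#' optimum, evaluated on an assay grid, with optional mean-one lognormal
#' noise. The default grid is the 14-point series from pH 4.5 to 11.0 in
#' steps of 0.5 commonly used for buffer screens.
#'
#' @param optimum_pH Planted optimum.
#' @param width Bell width (Gaussian sigma), pH units.
#' @param grid pH grid (all within 0--14, non-empty).
#' @param noise_cv Coefficient of variation of multiplicative noise.
#' @param seed Integer seed (required when `noise_cv > 0`).
#' @return Data frame with columns `pH` and `activity` (percent of peak).
#' @export
make_ph_profile <- function(optimum_pH = 9, width = 1.5,
                            grid = seq(4.5, 11, by = 0.5), noise_cv = 0,
                            seed = NULL) {
  if (!length(grid)) stop("'grid' must be non-empty")
  if (any(grid < 0 | grid > 14)) stop("pH grid must lie within 0-14")
  act <- 100 * exp(-0.5 * ((grid - optimum_pH) / width)^2)
  if (noise_cv > 0) {
    if (is.null(seed)) stop("'seed' is required when noise_cv > 0")
    act <- withr::with_seed(seed, {
      sdlog <- sqrt(log(1 + noise_cv^2))
      act * exp(rnorm(length(act), mean = -sdlog^2 / 2, sd = sdlog))
    })
  }
  data.frame(pH = grid, activity = act)
}

#' Generate a species table with planted co-occurrence structure
#'
#' Builds a protein record table for a roster of species partitioned into
#' long-chain repertoire groups (0, 1, or >1 long-chain genes per
#' species), with the fraction of species in each group that carry a
#' short-chain gene planted exactly (counts are rounded once, then the
#' first species of each group receive the short-chain gene), so
#' co-occurrence statistics can be checked against construction.
#' Long-chain localizations are drawn so that a single cytoplasmic enzyme
#' is the modal non-empty repertoire.
#'
#' @param n_per_group Species counts for the lc-count groups `0`, `1`,
#'   `>1` (length-3 integer vector).
#' @param sc_fraction Planted fraction of species with a short-chain gene
#'   in each group (length 3, same order).
#' @param seed Integer seed.
#' @return List with `records` (data frame: `id`, `species`,
#'   `length_class`, `localization`, `length_aa`) and `roster` (character
#'   vector of all species, including those with no records).
#' @export
make_cooccurrence_records <- function(n_per_group = c(100, 100, 100),
                                      sc_fraction = c(0.05, 0.03, 0.38),
                                      seed = 1) {
  stopifnot(length(n_per_group) == 3, length(sc_fraction) == 3,
            all(sc_fraction >= 0 & sc_fraction <= 1))
  withr::with_seed(seed, {
    groups <- rep(c("0", "1", ">1"), n_per_group)
    species <- sprintf("sp_%s_%03d", rep(c("g0", "g1", "gm"), n_per_group),
                       unlist(lapply(n_per_group, seq_len)))
    recs <- list()
    sc_flag <- logical(length(species))
    off <- 0L
    for (g in 1:3) {
      n <- n_per_group[g]
      if (n > 0) {
        k <- round(sc_fraction[g] * n)
        sc_flag[off + seq_len(n)] <- seq_len(n) <= k
      }
      off <- off + n
    }
    for (i in seq_along(species)) {
      n_lc <- switch(groups[i], "0" = 0L, "1" = 1L,
                     ">1" = sample(2:4, 1L))
      if (n_lc > 0) {
        loc <- c("cytoplasmic",
                 if (n_lc > 1) sample(c("cytoplasmic", "SPI", "SPII"),
                                      n_lc - 1L, replace = TRUE,
                                      prob = c(0.5, 0.35, 0.15)))
        recs[[length(recs) + 1L]] <- data.frame(
          id = sprintf("%s_lc%d", species[i], seq_len(n_lc)),
          species = species[i], length_class = "long", localization = loc,
          length_aa = sample(300:400, n_lc, replace = TRUE),
          stringsAsFactors = FALSE)
      }
      if (sc_flag[i]) {
        recs[[length(recs) + 1L]] <- data.frame(
          id = paste0(species[i], "_sc1"), species = species[i],
          length_class = "short", localization = "cytoplasmic",
          length_aa = sample(160:180, 1L), stringsAsFactors = FALSE)
      }
    }
    list(records = do.call(rbind, recs), roster = species)
  })
}
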