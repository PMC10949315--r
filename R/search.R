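#' Scoring scheme for translated homology searches
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used to convert alignment scores to
#' E-values. Defaults are BLOSUM62 with gap open 11 / extend 1 and the
#' standard ungapped constants lambda = 0.3176 nats per score unit,
#' K = 0.134. Codons containing N translate to `X`, which scores 0
#' against every residue.
#'
#' @param matrix 20x20+ integer substitution matrix (default BLOSUM62 with
#'   the `X` row/column zeroed).
#' @param gap_open,gap_extend Positive gap penalties.
#' @param lambda,K Karlin-Altschul parameters (both > 0).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                           lambda = 0.3176, K = 0.134) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
    matrix["X", ] <- 0L
    matrix[, "X"] <- 0L
  }
  sub <- matrix[rownames(matrix) %in% c(AA20, "X"),
                colnames(matrix) %in% c(AA20, "X")]
  if (!isSymmetric(unname(sub)))
    stop("substitution matrix must be symmetric")
  assert_scalar_number(lambda, "lambda", min = 0, strict = TRUE)
  assert_scalar_number(K, "K", min = 0, strict = TRUE)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates the three forward frames (+1, +2, +3) and the three frames
#' of the reverse complement (-1, -2, -3). Trailing partial codons are
#' dropped; codons containing N translate to `X`; internal stops are kept
#' as `*`.
#'
#' @param genome A nucleotide sequence (string or [Biostrings::DNAString])
#'   over A/C/G/T/N.
#' @return Named character vector of six translations
#'   (`"+1"`, `"+2"`, `"+3"`, `"-1"`, `"-2"`, `"-3"`).
#' @examples
#' six_frame_translate("ATGAAA")[["+1"]]  # "MK"
#' @export
six_frame_translate <- function(genome) {
  g <- toupper(as.character(genome))
  if (grepl("[^ACGTN]", g))
    stop("genome contains non-nucleotide symbols", call. = FALSE)
  fwd <- Biostrings::DNAString(g)
  rev <- Biostrings::reverseComplement(fwd)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out <- vapply(seq_along(frames), function(i) {
    src <- if (i <= 3) fwd else rev
    off <- (i - 1L) %% 3L
    len <- (length(src) - off) %/% 3L * 3L
    if (len <= 0) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(src, start = off + 1L, width = len),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }, character(1))
  setNames(out, frames)
}

#' Smith-Waterman local alignment of two protein sequences
#'
#' Optimal local alignment under affine gap penalties (an exact
#' stand-in for heuristic seeded search at desk scale). A maximal score
#' of 0 is reported as "no hit".
#'
#' @param query,subject Protein sequences (query over the 20 residues +
#'   `X`; the subject may additionally contain `*` from translated frames,
#'   which never scores positively).
#' @param scheme A [scoring_scheme()].
#' @return List of class `local_hit` with `score`, `no_hit`,
#'   `query_interval` and `subject_interval` (0-based half-open).
#' @export
local_align <- function(query, subject, scheme = scoring_scheme()) {
  if (!nzchar(query) || !nzchar(subject))
    stop("sequences must be non-empty", call. = FALSE)
  assert_protein(query, "query", allow = "X")
  assert_protein(subject, "subject", allow = c("X", "*"))
  aln <- Biostrings::pairwiseAlignment(
    query, subject, type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  score <- Biostrings::score(aln)
  if (score <= 0)
    return(structure(list(score = 0, no_hit = TRUE,
                          query_interval = c(0L, 0L),
                          subject_interval = c(0L, 0L)),
                     class = "local_hit"))
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  structure(list(
    score = score, no_hit = FALSE,
    query_interval = c(Biostrings::start(p) - 1L, Biostrings::end(p)),
    subject_interval = c(Biostrings::start(s) - 1L, Biostrings::end(s))),
    class = "local_hit")
}

#' Karlin-Altschul E-value of an alignment score
#'
#' Expected number of chance local alignments with score at least `score`
#' in a search space of `m * n` residues: `E = K * m * n * exp(-lambda *
#' score)`.
#'
#' @param score Alignment score (vectorised).
#' @param m Query length, residues (vectorised).
#' @param n Search-space length, residues.
#' @param scheme A [scoring_scheme()] supplying `lambda` and `K`.
#' @return The expectation E (>= 0).
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme()) {
  if (any(m <= 0) || any(n <= 0))
    stop("'m' and 'n' must be positive", call. = FALSE)
  scheme$K * m * n * exp(-scheme$lambda * score)
}

# Convert an interval on a translated frame (protein coords, 0-based
# half-open) to forward-strand nucleotide coordinates.
frame_to_forward <- function(frame, p_start, p_end, genome_len) {
  off <- abs(frame) - 1L
  nt_start <- off + 3L * p_start
  nt_end <- off + 3L * p_end
  if (frame > 0) c(nt_start, nt_end)
  else c(genome_len - nt_end, genome_len - nt_start)
}

#' Extract the full-length ORF containing a hit
#'
#' Expands an aligned region on a translated frame to the surrounding
#' in-frame, stop-to-stop open reading frame, optionally trimmed to the
#' first start codon (ATG/GTG/TTG). If an in-frame stop falls inside the
#' aligned interval, the stop-free segment with the larger overlap is
#' taken and a warning is issued.
#'
#' @param genome Nucleotide sequence (string or DNAString).
#' @param frame Frame of the hit, one of +1, +2, +3, -1, -2, -3.
#' @param hit_interval Aligned interval on the translated frame, 0-based
#'   half-open (protein coordinates).
#' @param start_trim Trim the ORF to its first start codon when one
#'   exists (`TRUE`, default) or keep the full stop-to-stop segment.
#' @param genome_id Optional id carried through to the output.
#' @return List of class `open_reading_frame`: `genome_id`, `strand`,
#'   `start`, `end` (forward-strand 0-based half-open, stop codon
#'   excluded), `nucleotide`, `protein`.
#' @export
extract_orf <- function(genome, frame, hit_interval, start_trim = TRUE,
                        genome_id = NA_character_) {
  g <- toupper(as.character(genome))
  L <- nchar(g)
  strand <- if (frame > 0) "+" else "-"
  oriented <- if (frame > 0) g else revcomp_chr(g)
  off <- abs(frame) - 1L
  n_codons <- (nchar(oriented) - off) %/% 3L
  if (hit_interval[1] < 0 || hit_interval[2] > n_codons ||
      hit_interval[1] >= hit_interval[2])
    stop("hit interval outside the translated frame", call. = FALSE)
  codons <- substring(oriented, off + 3L * (seq_len(n_codons) - 1L) + 1L,
                      off + 3L * seq_len(n_codons))
  is_stop <- codons %in% STOP_CODONS
  h0 <- hit_interval[1] + 1L   # 1-based codon indices of the hit
  h1 <- hit_interval[2]
  inside <- which(is_stop[h0:h1])
  if (length(inside)) {
    warning("in-frame stop codon inside the aligned interval; ",
            "keeping the segment with larger overlap")
    bounds <- c(h0 - 1L, h0 - 1L + inside, h1 + 1L)
    seg_ov <- vapply(seq_len(length(bounds) - 1L), function(k) {
      lo <- bounds[k] + 1L; hi <- bounds[k + 1L] - 1L
      if (hi < lo) 0L else hi - lo + 1L
    }, integer(1))
    k <- which.max(seg_ov)
    h0 <- bounds[k] + 1L; h1 <- bounds[k + 1L] - 1L
  }
  lo <- h0
  while (lo > 1L && !is_stop[lo - 1L]) lo <- lo - 1L
  hi <- h1
  while (hi < n_codons && !is_stop[hi + 1L]) hi <- hi + 1L
  if (start_trim) {
    starts <- which(codons[lo:hi] %in% START_CODONS)
    if (length(starts)) lo <- lo + starts[1] - 1L
  }
  nt <- paste(codons[lo:hi], collapse = "")
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                             no.init.codon = TRUE))
  iv <- frame_to_forward(frame, lo - 1L, hi, L)
  structure(list(genome_id = genome_id, strand = strand,
                 start = iv[1], end = iv[2],
                 nucleotide = nt, protein = prot),
            class = "open_reading_frame")
}

#' Translated homology survey of genomes
#'
#' For every genome x query pair, aligns the protein query against all six
#' translated frames, converts scores to E-values with the search space
#' set to the total translated length of all six frames across the genome
#' set, keeps hits with `E <= cutoff`, and expands each hit to its
#' full-length ORF. ORFs found via multiple queries are reported once,
#' annotated with the best (lowest-E) query.
#'
#' @param genomes Named [Biostrings::DNAStringSet] (or named character
#'   vector) of nucleotide genomes.
#' @param queries Named [Biostrings::AAStringSet] (or named character
#'   vector) of protein queries.
#' @param cutoff E-value cutoff (default 0.01).
#' @param scheme A [scoring_scheme()].
#' @param species Optional named character vector mapping genome id to
#'   species; defaults to the genome id.
#' @param start_trim Passed to [extract_orf()].
#' @return Data frame of class `protein_record_table` with columns
#'   `genome_id`, `species`, `start`, `end`, `strand`, `length_aa`,
#'   `best_query`, `evalue`, `protein` (coordinates 0-based half-open,
#'   forward strand).
#' @export
survey <- function(genomes, queries, cutoff = 0.01,
                   scheme = scoring_scheme(), species = NULL,
                   start_trim = TRUE) {
  genomes <- setNames(as.character(genomes), names(genomes))
  queries <- setNames(as.character(queries), names(queries))
  if (!length(genomes) || !length(queries))
    stop("at least one genome and one query are required", call. = FALSE)
  if (is.null(names(genomes)))
    names(genomes) <- paste0("genome", seq_along(genomes))
  if (is.null(names(queries)))
    names(queries) <- paste0("query", seq_along(queries))
  frames_by_genome <- lapply(genomes, six_frame_translate)
  n_space <- sum(vapply(frames_by_genome,
                        function(fr) sum(nchar(fr)), numeric(1)))
  rows <- list()
  for (gid in names(genomes)) {
    frames <- frames_by_genome[[gid]]
    for (qid in names(queries)) {
      q <- queries[[qid]]
      for (fr_name in names(frames)) {
        subj <- frames[[fr_name]]
        if (!nzchar(subj)) next
        # iterate best-hit + mask so several genes in one reading frame
        # are all reported, not just the top-scoring one
        for (round in 1:100) {
          hit <- local_align(q, subj, scheme)
          if (hit$no_hit) break
          e <- evalue(hit$score, nchar(q), n_space, scheme)
          if (e > cutoff) break
          orf <- extract_orf(genomes[[gid]], as.integer(fr_name),
                             hit$subject_interval, start_trim = start_trim,
                             genome_id = gid)
          rows[[length(rows) + 1L]] <- data.frame(
            genome_id = gid,
            species = if (is.null(species)) gid else
              unname(species[gid]),
            start = orf$start, end = orf$end, strand = orf$strand,
            length_aa = nchar(orf$protein), best_query = qid, evalue = e,
            protein = orf$protein, stringsAsFactors = FALSE)
          iv <- hit$subject_interval
          substr(subj, iv[1] + 1L, iv[2]) <-
            strrep("*", iv[2] - iv[1])
        }
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(genome_id = character(), species = character(),
                      start = integer(), end = integer(),
                      strand = character(), length_aa = integer(),
                      best_query = character(), evalue = numeric(),
                      protein = character(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    # deduplicate by locus, keeping the best-E query
    out <- out[order(out$genome_id, out$strand, out$start, out$end,
                     out$evalue), ]
    key <- paste(out$genome_id, out$strand, out$start, out$end)
    out <- out[!duplicated(key), ]
    rownames(out) <- NULL
  }
  class(out) <- c("protein_record_table", class(out))
  out
}
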