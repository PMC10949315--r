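#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions and
#' substitutions transforming one string into another. Symmetric and
#' satisfies the triangle inequality.
#'
#' @param a,b Strings (vectorised; recycled as in [utils::adist()]).
#' @return Integer distance(s).
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
  d <- utils::adist(a, b)
  if (length(a) == 1L && length(b) == 1L) as.integer(d) else d
}

# Global (Needleman-Wunsch) alignment of two proteins; returns the two
# aligned strings and the number of identical aligned positions.
global_align <- function(a, b, scheme = scoring_scheme()) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       nmatch = Biostrings::nmatch(aln))
}

#' Greedy identity clustering of protein sequences
#'
#' Representative selection in the style of standard redundancy-reduction
#' tools: sequences are sorted by decreasing length; each sequence joins
#' the first existing representative to which its global-alignment
#' identity (matches divided by the shorter sequence length) reaches the
#' threshold, otherwise it founds a new cluster.
#'
#' @param sequences Named character vector of protein sequences.
#' @param identity_threshold Identity threshold in (0, 1]; default 0.9.
#' @param scheme A [scoring_scheme()] used for the global alignments.
#' @return List with `representatives` (character vector of ids) and
#'   `membership` (named character vector: sequence id -> representative
#'   id).
#' @export
greedy_cluster <- function(sequences, identity_threshold = 0.9,
                           scheme = scoring_scheme()) {
  if (!length(sequences)) stop("no sequences supplied", call. = FALSE)
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("'identity_threshold' must be in (0, 1]", call. = FALSE)
  ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
  ord <- order(-nchar(sequences))
  reps <- character()
  membership <- setNames(character(length(sequences)), ids)
  for (i in ord) {
    assigned <- FALSE
    for (r in reps) {
      ga <- global_align(sequences[[i]], sequences[[which(ids == r)]],
                         scheme)
      ident <- ga$nmatch / min(nchar(sequences[[i]]),
                               nchar(sequences[[which(ids == r)]]))
      if (ident >= identity_threshold) {
        membership[ids[i]] <- r
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, ids[i])
      membership[ids[i]] <- ids[i]
    }
  }
  list(representatives = reps, membership = membership)
}

# Merge a pairwise alignment (center-with-gaps, other-with-gaps) into a
# growing multiple alignment whose first row is the center: "once a gap,
# always a gap".
merge_into_msa <- function(rows, center_gapped, other_gapped) {
  master <- strsplit(rows[[1L]], "")[[1]]
  ca <- strsplit(center_gapped, "")[[1]]
  ob <- strsplit(other_gapped, "")[[1]]
  i <- 1L; j <- 1L
  new_master_cols <- integer()  # for each output col: source (1 = master,
  out_m <- integer(); out_c <- integer()  # 2 = pair, 0 = gap in that side)
  res_master <- character(); res_other <- character()
  nm <- length(master); nc <- length(ca)
  while (i <= nm || j <= nc) {
    mi <- if (i <= nm) master[i] else NULL
    cj <- if (j <= nc) ca[j] else NULL
    if (!is.null(mi) && mi == "-" && (is.null(cj) || cj != "-")) {
      # master has an old gap column the pairwise center lacks
      res_master <- c(res_master, "-"); res_other <- c(res_other, "-")
      out_m <- c(out_m, i); out_c <- c(out_c, 0L)
      i <- i + 1L
    } else if (!is.null(cj) && cj == "-" && (is.null(mi) || mi != "-")) {
      # new gap column introduced by this pairwise alignment
      res_master <- c(res_master, "-"); res_other <- c(res_other, ob[j])
      out_m <- c(out_m, 0L); out_c <- c(out_c, j)
      j <- j + 1L
    } else {
      # residue/residue (or gap/gap) column
      res_master <- c(res_master, if (is.null(mi)) "-" else mi)
      res_other <- c(res_other, if (is.null(cj)) "-" else ob[j])
      out_m <- c(out_m, if (is.null(mi)) 0L else i)
      out_c <- c(out_c, if (is.null(cj)) 0L else j)
      if (!is.null(mi)) i <- i + 1L
      if (!is.null(cj)) j <- j + 1L
    }
  }
  # re-expand previously aligned rows onto the merged column set
  expanded <- lapply(rows, function(r) {
    rc <- strsplit(r, "")[[1]]
    paste(ifelse(out_m == 0L, "-", rc[pmax(out_m, 1L)]), collapse = "")
  })
  c(expanded, list(paste(res_other, collapse = "")))
}

#' Center-star multiple sequence alignment
#'
#' Aligns a set of sequences around the center sequence (the one with the
#' smallest total edit distance to all others) by merging pairwise global
#' alignments under the "once a gap, always a gap" rule. A simple,
#' deterministic aligner adequate for conservation profiling of closely
#' related families; externally produced alignments can be supplied to
#' [shannon_profile()] instead via [as_alignment()].
#'
#' @param sequences Named character vector (>= 2 sequences).
#' @param scheme A [scoring_scheme()] for the pairwise alignments.
#' @return Object of class `alignment`: list with `ids` and `aligned`
#'   (equal-length gapped strings, gap symbol `-`).
#' @export
center_star_align <- function(sequences, scheme = scoring_scheme()) {
  n <- length(sequences)
  if (n < 2) stop("at least two sequences are required", call. = FALSE)
  ids <- names(sequences) %||% paste0("seq", seq_len(n))
  D <- utils::adist(sequences)
  center <- which.min(rowSums(D))
  others <- setdiff(seq_len(n), center)
  rows <- list(sequences[[center]])
  row_ids <- ids[center]
  for (k in others) {
    ga <- global_align(sequences[[center]], sequences[[k]], scheme)
    # ga$a is the center with gaps relative to this pair; merge
    rows <- merge_into_msa(rows, ga$a, ga$b)
    row_ids <- c(row_ids, ids[k])
  }
  # restore the input order
  ord <- match(ids, row_ids)
  as_alignment(setNames(unlist(rows)[ord], ids))
}

#' Construct an alignment object from gapped strings
#'
#' @param aligned Named character vector of equal-length gapped sequences
#'   (gap symbol `-`).
#' @return Object of class `alignment`.
#' @export
as_alignment <- function(aligned) {
  if (length(unique(nchar(aligned))) != 1L)
    stop("aligned rows must all have the same length", call. = FALSE)
  structure(list(ids = names(aligned) %||%
                   paste0("seq", seq_along(aligned)),
                 aligned = unname(aligned),
                 ncol = nchar(aligned[[1]])),
            class = "alignment")
}

#' Read / write an aligned FASTA file
#'
#' @param path File path.
#' @return `read_alignment()`: an `alignment` object;
#'   `write_alignment()`: the path, invisibly.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  as_alignment(setNames(as.character(x), names(x)))
}

#' @rdname read_alignment
#' @param alignment An `alignment` object.
#' @export
write_alignment <- function(alignment, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(alignment$aligned, alignment$ids)),
    path)
  invisible(path)
}

#' Per-column Shannon conservation profile
#'
#' For each alignment column, computes the amino-acid frequency
#' distribution (gaps and `X` excluded), its Shannon entropy H in bits,
#' and the Shannon conservation score `log2(20) - H`: about 4.3 bits for
#' a perfectly conserved column, 0 for a column in which all 20 amino
#' acids are uniformly represented. All-gap columns are flagged and get
#' an undefined (NA) score.
#'
#' @param alignment An `alignment` object (see [as_alignment()]).
#' @return Data frame of class `conservation_profile` with columns
#'   `column`, `n_residues`, `gap_fraction`, `entropy_bits`,
#'   `shannon_score`, `modal_residue`, `all_gap`.
#' @export
shannon_profile <- function(alignment) {
  stopifnot(inherits(alignment, "alignment"))
  m <- do.call(rbind, strsplit(alignment$aligned, ""))
  n_col <- ncol(m)
  out <- data.frame(column = seq_len(n_col), n_residues = 0L,
                    gap_fraction = 0, entropy_bits = NA_real_,
                    shannon_score = NA_real_,
                    modal_residue = NA_character_, all_gap = FALSE)
  for (j in seq_len(n_col)) {
    col <- m[, j]
    out$gap_fraction[j] <- mean(col == "-")
    res <- col[col %in% AA20]
    out$n_residues[j] <- length(res)
    if (!length(res)) {
      out$all_gap[j] <- TRUE
      next
    }
    p <- table(res) / length(res)
    H <- -sum(p * log2(p))
    out$entropy_bits[j] <- H
    out$shannon_score[j] <- log2(20) - H
    out$modal_residue[j] <- names(which.max(table(res)))[1]
  }
  class(out) <- c("conservation_profile", class(out))
  out
}

total_edit_distance <- function(candidates, sequences) {
  rowSums(utils::adist(candidates, sequences))
}

#' Levenshtein median string of a sequence set
#'
#' The median string minimises the summed edit distance to all input
#' sequences and serves as a family consensus. `mode = "exact"`
#' exhaustively scores every string over the observed alphabet with
#' length between the shortest and longest input (a global minimiser
#' exists in that range) and is limited to small instances;
#' `mode = "heuristic"` starts from the set medoid and hill-climbs over
#' single-character substitutions, insertions and deletions until no
#' single edit lowers the total distance. The heuristic never returns a
#' string worse than the best input.
#'
#' @param sequences Character vector (>= 1).
#' @param mode `"heuristic"` (default) or `"exact"`.
#' @param max_candidates Exact-mode safety limit on the number of
#'   enumerated candidate strings (default 2e5).
#' @return List of class `consensus_result`: `median`, `total_distance`,
#'   `method`.
#' @export
median_string <- function(sequences, mode = c("heuristic", "exact"),
                          max_candidates = 2e5) {
  mode <- match.arg(mode)
  if (!length(sequences)) stop("no sequences supplied", call. = FALSE)
  alphabet <- sort(unique(unlist(strsplit(sequences, ""))))
  lens <- nchar(sequences)
  if (mode == "exact") {
    n_cand <- sum(length(alphabet)^(min(lens):max(lens)))
    if (n_cand > max_candidates)
      stop("exact mode would enumerate ", format(n_cand, big.mark = ","),
           " candidates; use mode = 'heuristic'", call. = FALSE)
    best <- NULL; best_d <- Inf
    for (L in min(lens):max(lens)) {
      cand <- apply(do.call(expand.grid,
                            rep(list(alphabet), L))[, L:1, drop = FALSE],
                    1, paste, collapse = "")
      d <- total_edit_distance(cand, sequences)
      # lexicographically smallest among minima, for determinism
      hit <- cand[d == min(d)]
      if (min(d) < best_d ||
          (min(d) == best_d && min(hit) < best)) {
        best_d <- min(d); best <- min(hit)
      }
    }
    return(structure(list(median = best, total_distance = best_d,
                          method = "exact"), class = "consensus_result"))
  }
  totals <- total_edit_distance(sequences, sequences)
  cur <- sequences[[which.min(totals)]]
  cur_d <- min(totals)
  repeat {
    chars <- strsplit(cur, "")[[1]]
    L <- length(chars)
    cand <- character()
    for (pos in seq_len(L)) {
      for (a in setdiff(alphabet, chars[pos]))  # substitution
        cand <- c(cand, paste(replace(chars, pos, a), collapse = ""))
      cand <- c(cand, paste(chars[-pos], collapse = ""))  # deletion
    }
    for (pos in 0:L)                            # insertion
      for (a in alphabet)
        cand <- c(cand, paste(append(chars, a, after = pos),
                              collapse = ""))
    cand <- unique(cand[nzchar(cand)])
    d <- total_edit_distance(cand, sequences)
    if (min(d) >= cur_d) break
    cur_d <- min(d)
    cur <- min(cand[d == cur_d])
  }
  structure(list(median = cur, total_distance = cur_d,
                 method = "medoid+refinement"),
            class = "consensus_result")
}

#' Key-residue conservation report
#'
#' Maps residue numbers of a reference sequence (1-based, ungapped) to
#' alignment columns via the cumulative non-gap count, and reports each
#' column's Shannon score, modal residue and the rows deviating from the
#' mode -- the form used to ask whether catalytic residues (such as the
#' N-terminal active-site threonine) are conserved across a family.
#'
#' @param alignment An `alignment` object.
#' @param profile Matching [shannon_profile()] result (computed when
#'   `NULL`).
#' @param reference_id Row id of the reference sequence.
#' @param positions Integer residue numbers on the ungapped reference.
#' @return Data frame with `position`, `column`, `ref_residue`,
#'   `shannon_score`, `modal_residue`, `n_exceptions`, `exceptions`
#'   (comma-separated `id:residue`, gaps shown as `-`).
#' @export
key_residue_report <- function(alignment, profile = NULL, reference_id,
                               positions) {
  stopifnot(inherits(alignment, "alignment"))
  if (is.null(profile)) profile <- shannon_profile(alignment)
  ri <- match(reference_id, alignment$ids)
  if (is.na(ri)) stop("reference id '", reference_id,
                      "' not in alignment", call. = FALSE)
  ref <- strsplit(alignment$aligned[[ri]], "")[[1]]
  notgap <- cumsum(ref != "-")
  ref_len <- max(notgap)
  if (any(positions < 1 | positions > ref_len))
    stop("positions must lie within the reference length (", ref_len, ")",
         call. = FALSE)
  cols <- vapply(positions, function(p) which(notgap == p & ref != "-")[1],
                 integer(1))
  m <- do.call(rbind, strsplit(alignment$aligned, ""))
  rows <- lapply(seq_along(positions), function(k) {
    j <- cols[k]
    modal <- profile$modal_residue[j]
    dev <- which(m[, j] != modal)
    data.frame(position = positions[k], column = j,
               ref_residue = ref[j],
               shannon_score = profile$shannon_score[j],
               modal_residue = modal, n_exceptions = length(dev),
               exceptions = paste(sprintf("%s:%s", alignment$ids[dev],
                                          m[dev, j]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
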