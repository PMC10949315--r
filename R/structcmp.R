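#' Extract a C-alpha trace from a structure file
#'
#' Reads a PDB or mmCIF file and returns the ordered C-alpha coordinates
#' of one chain. Only the first model is used; for residues with
#' alternate locations the highest-occupancy altloc is kept (ties to the
#' first encountered).
#'
#' @param file Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param chain Chain identifier.
#' @return Object of class `chain_trace`: data frame with `resno`,
#'   `resid` (3-letter residue type), `x`, `y`, `z` (Angstrom) and
#'   attributes `structure_id`, `chain`.
#' @export
read_calpha <- function(file, chain) {
  if (!file.exists(file))
    stop("cannot read structure file: ", file, call. = FALSE)
  is_cif <- grepl("\\.(cif|mmcif)$", file, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(file, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(file, verbose = FALSE, multi = FALSE,
                         rm.alt = FALSE),
    error = function(e) stop("failed to parse ", file, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$elety == "CA" & at$chain == chain & at$type == "ATOM", ,
           drop = FALSE]
  if (!nrow(at))
    stop("chain '", chain, "' with C-alpha atoms not found in ", file,
         call. = FALSE)
  # keep the highest-occupancy alternate location per residue
  occ <- if (is.null(at$o)) rep(1, nrow(at)) else
    ifelse(is.na(at$o), 1, at$o)
  at <- at[order(at$resno, -occ), , drop = FALSE]
  at <- at[!duplicated(at$resno), , drop = FALSE]
  at <- at[order(at$resno), , drop = FALSE]
  if (any(!is.finite(c(at$x, at$y, at$z))))
    stop("non-finite coordinates in ", file, call. = FALSE)
  out <- data.frame(resno = at$resno, resid = at$resid,
                    x = at$x, y = at$y, z = at$z,
                    stringsAsFactors = FALSE)
  attr(out, "structure_id") <- sub("\\.[^.]*$", "", basename(file))
  attr(out, "chain") <- chain
  class(out) <- c("chain_trace", class(out))
  out
}

#' Pair residues common to two C-alpha traces
#'
#' Matches residues by equal residue number (the natural pairing for two
#' chains of the same protein with a shared numbering scheme) and
#' returns the paired coordinate arrays in residue order.
#'
#' @param a,b `chain_trace` objects from [read_calpha()].
#' @return List with `resno`, `xyz_a` and `xyz_b` (n x 3 matrices).
#' @export
pair_common_residues <- function(a, b) {
  common <- sort(intersect(a$resno, b$resno))
  if (length(common) < 3)
    stop("fewer than 3 common residues; superposition is underdetermined",
         call. = FALSE)
  ia <- match(common, a$resno); ib <- match(common, b$resno)
  list(resno = common,
       xyz_a = as.matrix(a[ia, c("x", "y", "z")]),
       xyz_b = as.matrix(b[ib, c("x", "y", "z")]))
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation that minimise the
#' root-mean-square deviation between two paired coordinate sets
#' (mapping set B onto set A) via singular value decomposition of the
#' cross-covariance matrix, with the reflection case corrected so that
#' the returned rotation has determinant +1.
#'
#' @param xyz_a Fixed (reference) coordinates, n x 3 matrix, or the list
#'   returned by [pair_common_residues()].
#' @param xyz_b Moving coordinates, n x 3 (omit when `xyz_a` is a paired
#'   list).
#' @return Object of class `superposition_result`: `rotation` (3x3,
#'   det +1), `translation` (length 3), `rmsd` (Angstrom), `n_pairs`,
#'   `resno` (when pairing information was supplied). The transform maps
#'   b to `b %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(xyz_a, xyz_b = NULL) {
  resno <- NULL
  if (is.list(xyz_a) && !is.null(xyz_a$xyz_a)) {
    resno <- xyz_a$resno
    xyz_b <- xyz_a$xyz_b
    xyz_a <- xyz_a$xyz_a
  }
  A <- as.matrix(xyz_a); B <- as.matrix(xyz_b)
  stopifnot(ncol(A) == 3, ncol(B) == 3, nrow(A) == nrow(B))
  n <- nrow(A)
  if (n < 3) stop("at least 3 paired points are required", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (qr(A0)$rank < 2 || qr(B0)$rank < 2)
    stop("degenerate (collinear) coordinates", call. = FALSE)
  H <- crossprod(B0, A0)              # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rot_b <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((rot_b - A0)^2)))
  structure(list(rotation = R, translation = as.numeric(ca - R %*% cb),
                 rmsd = rmsd, n_pairs = n, resno = resno),
            class = "superposition_result")
}

#' Superpose two chains of a structure (or two structures)
#'
#' Convenience wrapper: extracts the C-alpha traces, pairs common
#' residue numbers and runs the Kabsch superposition. Optionally applies
#' iterative outlier trimming for cross-protein comparisons where the
#' common-numbering pairing is approximate: pairs deviating by more than
#' `trim_factor` times the current rmsd are dropped and the superposition
#' repeated, up to `max_cycles` cycles.
#'
#' @param file1,chain1 Reference structure file and chain.
#' @param file2,chain2 Moving structure file and chain (default: same
#'   file as the reference).
#' @param trim Logical; apply outlier trimming (default `FALSE`).
#' @param trim_factor Multiple of the current rmsd beyond which a pair is
#'   dropped (default 2).
#' @param max_cycles Maximum trimming cycles (default 5).
#' @return A `superposition_result` (see [kabsch_superpose()]).
#' @export
superpose_chains <- function(file1, chain1, file2 = file1, chain2,
                             trim = FALSE, trim_factor = 2,
                             max_cycles = 5) {
  pr <- pair_common_residues(read_calpha(file1, chain1),
                             read_calpha(file2, chain2))
  res <- kabsch_superpose(pr)
  if (trim) {
    for (cycle in seq_len(max_cycles)) {
      B1 <- sweep(pr$xyz_b %*% t(res$rotation), 2, -res$translation)
      dev <- sqrt(rowSums((B1 - pr$xyz_a)^2))
      keep <- dev <= trim_factor * res$rmsd
      if (all(keep) || sum(keep) < 3) break
      pr <- list(resno = pr$resno[keep],
                 xyz_a = pr$xyz_a[keep, , drop = FALSE],
                 xyz_b = pr$xyz_b[keep, , drop = FALSE])
      res <- kabsch_superpose(pr)
    }
  }
  res
}

#' Percent sequence identity of an aligned pair
#'
#' `100 * identical non-gap columns / columns containing no gap in either
#' row`. Columns with a gap in either sequence (including fully gapped
#' columns) contribute to neither numerator nor denominator.
#'
#' @param a,b Equal-length aligned strings (gap symbol `-`).
#' @return Percent identity.
#' @export
sequence_identity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("aligned sequences must have equal length", call. = FALSE)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  nogap <- ca != "-" & cb != "-"
  if (!any(nogap)) stop("no gap-free columns", call. = FALSE)
  100 * sum(ca[nogap] == cb[nogap]) / sum(nogap)
}
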