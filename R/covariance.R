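# Interprotein covariance: c(i,j) = < dRi . dRj > over frames, where dR is
# the displacement from the trajectory-averaged position, and its
# normalization C(i,j) = c(i,j) / sqrt(c(i,i) c(j,j)).

# Indices of the representative atoms of each protein; errors unless the
# current representation carries exactly one atom per residue per protein.
protein_indices <- function(traj) {
  at <- traj$atoms
  i1 <- which(at$protein_tag == "protein1")
  i2 <- which(at$protein_tag == "protein2")
  if (!length(i1) || !length(i2))
    stop("trajectory must contain atoms tagged protein1 and protein2")
  for (idx in list(i1, i2)) {
    key <- paste(at$chain_id[idx], at$residue_id[idx])
    if (anyDuplicated(key))
      stop("covariance requires one representative atom per residue; ",
           "apply select_representation() first")
  }
  list(p1 = i1, p2 = i2)
}

#' Inter-residue distance matrix on a reference structure
#'
#' Distances (Angstrom) between every protein-1 and protein-2
#' representative atom of an averaged (or single-frame) structure.
#'
#' @param avg a `cc_avg_structure` whose atom set has one atom per residue.
#' @return n x m numeric matrix with residue labels as dimnames.
#' @export
residue_distance_matrix <- function(avg) {
  at <- avg$atoms
  i1 <- which(at$protein_tag == "protein1")
  i2 <- which(at$protein_tag == "protein2")
  a <- avg$mean_coords[i1, , drop = FALSE]
  b <- avg$mean_coords[i2, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d <- sqrt(pmax(d2, 0))
  dimnames(d) <- list(atom_residue_label(at[i1, , drop = FALSE]),
                      atom_residue_label(at[i2, , drop = FALSE]))
  d
}

#' Static-structure distance prefilter mask
#'
#' Marks the residue pairs whose reference-structure distance is within
#' `cutoff_A`; covariance is then computed only for those pairs, which
#' reduces memory and compute for large interfaces. The reference may be
#' the trajectory-averaged structure (default) or a single representative
#' frame passed as `avg`.
#'
#' @param avg a `cc_avg_structure` (averaged or built from one frame).
#' @param cutoff_A distance cutoff in Angstrom (> 0).
#' @param reference `"average_structure"` or `"single_frame"`, recorded for
#'   provenance.
#' @return object of class `cc_prefilter_mask` with logical `keep` matrix.
#' @export
build_prefilter_mask <- function(avg, cutoff_A,
                                 reference = c("average_structure", "single_frame")) {
  reference <- match.arg(reference)
  if (!is.numeric(cutoff_A) || cutoff_A <= 0) stop("cutoff_A must be > 0")
  d <- residue_distance_matrix(avg)
  structure(list(keep = d <= cutoff_A, cutoff_A = cutoff_A,
                 reference = reference),
            class = "cc_prefilter_mask")
}

#' Averaged-structure view of a single frame
#'
#' Wraps one trajectory frame as a `cc_avg_structure` so it can serve as
#' the prefilter or contact-filter reference.
#'
#' @param traj a `cc_trajectory`.
#' @param frame frame index.
#' @return a `cc_avg_structure` with `source_n_frames = 1`.
#' @export
single_frame_structure <- function(traj, frame = 1L) {
  structure(list(mean_coords = frame_coords(traj, frame),
                 source_n_frames = 1L, atoms = traj$atoms),
            class = "cc_avg_structure")
}

#' Interprotein covariance matrix
#'
#' For every protein-1 residue i and protein-2 residue j, the
#' trajectory-averaged dot product of their 3D displacement vectors from
#' the mean structure, in Angstrom^2. By default frames are first
#' rigid-body superposed on the whole complex so that global diffusion
#' does not masquerade as correlated motion. With a prefilter mask, only
#' pairs marked `keep` are computed; all other elements are exactly 0.
#'
#' @param traj a `cc_trajectory` (one representative atom per residue,
#'   e.g. after `select_representation(mode = "calpha")`), `n_frames >= 2`.
#' @param mask optional `cc_prefilter_mask`.
#' @param superpose superpose frames before computing displacements.
#' @param unbiased divide by `n_frames - 1` instead of `n_frames`. The
#'   default is the ensemble-average (biased) estimator matching the
#'   `< . >` notation.
#' @return object of class `cc_covariance` with fields `values`,
#'   `row_labels`, `col_labels`, `normalized = FALSE`, `auto_cov1`,
#'   `auto_cov2` (per-residue self-covariances) and `avg` (the averaged
#'   structure the displacements were measured from).
#' @export
compute_covariance <- function(traj, mask = NULL, superpose = TRUE,
                               unbiased = FALSE) {
  if (traj$n_frames < 2L)
    stop("covariance requires at least 2 frames")
  idx <- protein_indices(traj)
  if (superpose) traj <- superpose_trajectory(traj)

  mu <- colMeans(traj$xyz)
  X <- sweep(traj$xyz, 2L, mu)            # centered, frames x 3N
  denom <- if (unbiased) traj$n_frames - 1L else traj$n_frames

  n <- length(idx$p1); m <- length(idx$p2)
  A <- X[, xyz_cols(idx$p1), drop = FALSE]
  B <- X[, xyz_cols(idx$p2), drop = FALSE]

  sum_axes <- function(M, nr, nc) {
    # collapse a 3n x 3m per-coordinate matrix to n x m by summing the
    # x, y, z diagonal terms of each residue block
    M[seq(1, 3 * nr, 3), seq(1, 3 * nc, 3), drop = FALSE] +
      M[seq(2, 3 * nr, 3), seq(2, 3 * nc, 3), drop = FALSE] +
      M[seq(3, 3 * nr, 3), seq(3, 3 * nc, 3), drop = FALSE]
  }

  if (is.null(mask)) {
    vals <- sum_axes(crossprod(A, B), n, m) / denom
  } else {
    if (!identical(dim(mask$keep), c(n, m)))
      stop("prefilter mask dimensions do not match the residue sets")
    vals <- matrix(0, n, m)
    for (i in seq_len(n)) {
      cols <- which(mask$keep[i, ])
      if (!length(cols)) next
      Ai <- A[, (3 * i - 2):(3 * i), drop = FALSE]
      Bi <- B[, xyz_cols(cols), drop = FALSE]
      cp <- crossprod(Ai, Bi)              # 3 x 3k
      vals[i, cols] <- (cp[1, seq(1, ncol(cp), 3)] +
                        cp[2, seq(2, ncol(cp), 3)] +
                        cp[3, seq(3, ncol(cp), 3)]) / denom
    }
  }

  auto <- function(cols) colSums(X[, cols, drop = FALSE]^2) / denom
  a1 <- rowSums(matrix(auto(xyz_cols(idx$p1)), n, 3, byrow = TRUE))
  a2 <- rowSums(matrix(auto(xyz_cols(idx$p2)), m, 3, byrow = TRUE))

  at <- traj$atoms
  rl <- atom_residue_label(at[idx$p1, , drop = FALSE])
  cl <- atom_residue_label(at[idx$p2, , drop = FALSE])
  dimnames(vals) <- list(rl, cl)

  avg <- structure(list(mean_coords = matrix(mu, ncol = 3L, byrow = TRUE),
                        source_n_frames = traj$n_frames, atoms = at),
                   class = "cc_avg_structure")

  structure(list(values = vals, row_labels = rl, col_labels = cl,
                 normalized = FALSE, auto_cov1 = stats::setNames(a1, rl),
                 auto_cov2 = stats::setNames(a2, cl), avg = avg,
                 estimator = if (unbiased) "unbiased" else "ensemble"),
            class = "cc_covariance")
}

#' Normalize a covariance matrix to cross-correlations
#'
#' Divides each element by the geometric mean of the two per-residue
#' self-covariances, yielding values bounded in [-1, 1]: 1 for completely
#' correlated, -1 for completely anticorrelated motion. Elements are
#' clamped to the bounds only to absorb floating-point rounding. A residue
#' with zero self-covariance (frozen) yields 0 for all its elements, with
#' a warning, since it carries no correlation signal.
#'
#' @param raw a raw `cc_covariance` from [compute_covariance()].
#' @param auto_cov1,auto_cov2 per-residue self-covariances; default those
#'   stored in `raw`.
#' @return a normalized `cc_covariance`.
#' @export
normalize_covariance <- function(raw, auto_cov1 = raw$auto_cov1,
                                 auto_cov2 = raw$auto_cov2) {
  if (isTRUE(raw$normalized)) stop("covariance matrix is already normalized")
  if (any(auto_cov1 < 0) || any(auto_cov2 < 0))
    stop("negative self-covariance: numerical integrity violated")
  denom <- outer(sqrt(auto_cov1), sqrt(auto_cov2))
  vals <- raw$values / denom
  zero <- denom == 0
  if (any(zero)) {
    warning(sprintf("%d element(s) involve a frozen residue (zero self-covariance); set to 0",
                    sum(zero)))
    vals[zero] <- 0
  }
  over <- abs(vals) > 1 + 1e-6
  if (any(over))
    warning(sprintf("%d normalized element(s) exceed [-1, 1] beyond rounding tolerance",
                    sum(over)))
  vals <- pmin(pmax(vals, -1), 1)
  out <- raw
  out$values <- vals
  out$normalized <- TRUE
  out
}

#' Count significant normalized covariance elements
#'
#' Number of elements strictly below `neg_thresh` or strictly above
#' `pos_thresh` (defaults -0.08 and 0.1). Used to measure how much a
#' static-structure prefilter shrinks the matrix.
#'
#' @param cov a normalized `cc_covariance` (or `cc_close_contact`).
#' @param neg_thresh,pos_thresh strict thresholds.
#' @return integer count.
#' @export
count_significant_elements <- function(cov, neg_thresh = -0.08,
                                       pos_thresh = 0.1) {
  if (!isTRUE(cov$normalized))
    stop("count_significant_elements requires a normalized covariance matrix")
  sum(cov$values < neg_thresh | cov$values > pos_thresh)
}

#' @export
print.cc_covariance <- function(x, ...) {
  cat(sprintf("<cc_covariance> %d x %d (%s)\n", nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw, Angstrom^2"))
  invisible(x)
}

#' Write a labeled matrix as CSV
#'
#' Rows and columns carry "chain:resid:resname" residue labels.
#'
#' @param values labeled numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(values, path) {
  df <- data.frame(residue = rownames(values), values, check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}
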