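# Step II: sign-dependent spatial filtering of the normalized covariance
# matrix. Positive elements survive within pos_cutoff_A (default 11 A),
# negative elements within neg_cutoff_A (default 13 A); everything else is
# zeroed, yielding the close-contact covariance matrix.

#' Apply the sign-dependent close-contact filter
#'
#' Retains element (i, j) iff `C > 0` and the averaged inter-residue
#' distance is `<= pos_cutoff_A`, or `C < 0` and the distance is
#' `<= neg_cutoff_A`; all other elements are set to zero. The negative
#' cutoff is wider to catch the slightly longer-range push-pull motion of
#' confined like-charged pairs. Distances are measured between the
#' representative (e.g. C-alpha) atoms on the averaged structure; the
#' boundary is inclusive. Retained values are copied unchanged.
#'
#' @param cov a normalized `cc_covariance` (or an existing
#'   `cc_close_contact`, in which case filtering is idempotent).
#' @param avg reference `cc_avg_structure`; defaults to the one the
#'   covariance was computed from.
#' @param pos_cutoff_A,neg_cutoff_A cutoffs in Angstrom (defaults 11, 13).
#' @return object of class `cc_close_contact`: the filtered `values`
#'   matrix, a `pairs` data.frame (res_i, res_j, C, mean_distance_A, sign)
#'   enumerating the nonzero elements, the cutoffs, distances and labels.
#' @export
apply_close_contact_filter <- function(cov, avg = cov$avg,
                                       pos_cutoff_A = 11, neg_cutoff_A = 13) {
  if (!isTRUE(cov$normalized))
    stop("close-contact filtering expects a normalized covariance matrix")
  if (pos_cutoff_A <= 0 || neg_cutoff_A <= 0)
    stop("distance cutoffs must be > 0")
  if (neg_cutoff_A < pos_cutoff_A)
    warning("negative cutoff smaller than positive cutoff (unusual configuration)")

  d <- residue_distance_matrix(avg)
  if (!identical(dim(d), dim(cov$values)))
    stop("averaged structure does not cover the covariance residue sets")
  v <- cov$values
  keep <- (v > 0 & d <= pos_cutoff_A) | (v < 0 & d <= neg_cutoff_A)
  out <- v
  out[!keep] <- 0

  nz <- which(keep & v != 0, arr.ind = TRUE)
  pairs <- data.frame(
    res_i = cov$row_labels[nz[, 1]],
    res_j = cov$col_labels[nz[, 2]],
    C = v[nz],
    mean_distance_A = d[nz],
    sign = ifelse(v[nz] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)

  structure(list(values = out, pairs = pairs,
                 pos_cutoff_A = pos_cutoff_A, neg_cutoff_A = neg_cutoff_A,
                 row_labels = cov$row_labels, col_labels = cov$col_labels,
                 distances = d, normalized = TRUE, avg = avg),
            class = c("cc_close_contact", "cc_covariance"))
}

#' Enumerate close-contact pairs by correlation strength
#'
#' Nonzero elements of a close-contact matrix with `|C| > min_abs_C`,
#' sorted by decreasing `|C|`; ties broken lexicographically by
#' (res_i, res_j) so the ordering is deterministic.
#'
#' @param ccm a `cc_close_contact`.
#' @param min_abs_C minimum absolute correlation (default 0, strict).
#' @return the `pairs` data.frame, ordered.
#' @export
enumerate_contact_pairs <- function(ccm, min_abs_C = 0) {
  p <- ccm$pairs
  p <- p[abs(p$C) > min_abs_C, , drop = FALSE]
  if (nrow(p)) {
    p <- p[order(-abs(p$C), p$res_i, p$res_j), , drop = FALSE]
    rownames(p) <- NULL
  }
  p
}

#' @export
print.cc_close_contact <- function(x, ...) {
  cat(sprintf("<cc_close_contact> %d x %d, %d retained pairs (cutoffs %g/%g Angstrom)\n",
              nrow(x$values), ncol(x$values), nrow(x$pairs),
              x$pos_cutoff_A, x$neg_cutoff_A))
  invisible(x)
}

#' Write a close-contact pair list as TSV
#'
#' @param pairs pair data.frame from [enumerate_contact_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
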