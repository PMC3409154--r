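#' Signed fold change between genotypes
#'
#' Computes the mutant/wild-type ratio of mean intensities and reports it
#' on the signed-fold convention: values \eqn{\ge 1} mean higher expression
#' in mutants (genetic repression by the factor), values \eqn{\le -1} mean
#' lower expression in mutants (genetic activation), and no value lies
#' strictly between -1 and 1. The p-value is a two-sample, two-tailed,
#' equal-variance Student's t on log2 intensities (variance stabilization);
#' the fold SD comes from first-order (delta-method) propagation of the
#' ratio of means.
#'
#' @param wt_values,mut_values Positive linear-scale intensities of the
#'   replicate arrays for each genotype (length \eqn{\ge 2} each).
#' @return A \code{fold_record} list: \code{signed_fold}, \code{fold_sd},
#'   \code{p_value}, \code{wt_mean}, \code{mut_mean}.
#' @examples
#' signed_fold(c(100, 110, 90), c(48, 52, 50))  # about -2
#' @export
signed_fold <- function(wt_values, mut_values) {
  if (any(wt_values <= 0) || any(mut_values <= 0))
    stop("intensities must be positive")
  wm <- mean(wt_values); mm <- mean(mut_values)
  r <- mm / wm
  signed <- if (r >= 1) r else -1 / r
  # delta method on the ratio of means: relative variances add
  var_r <- r^2 * (stats::var(wt_values) / (length(wt_values) * wm^2) +
                  stats::var(mut_values) / (length(mut_values) * mm^2))
  fold_sd <- if (r >= 1) sqrt(var_r) else sqrt(var_r) / r^2
  p <- if (length(wt_values) >= 2L && length(mut_values) >= 2L &&
           (stats::var(log2(wt_values)) > 0 ||
            stats::var(log2(mut_values)) > 0))
    stats::t.test(log2(mut_values), log2(wt_values),
                  var.equal = TRUE)$p.value
  else if (isTRUE(all.equal(wm, mm))) 1 else 0
  structure(list(signed_fold = signed, fold_sd = fold_sd, p_value = p,
                 wt_mean = wm, mut_mean = mm), class = "fold_record")
}

#' @export
print.fold_record <- function(x, ...) {
  cat(sprintf("signed fold %+.3g +/- %.2g (p = %.3g)\n",
              x$signed_fold, x$fold_sd, x$p_value))
  invisible(x)
}

# vectorized signed fold over the rows of paired intensity matrices
.signed_fold_rows <- function(wt_mat, mut_mat) {
  r <- rowMeans(mut_mat) / rowMeans(wt_mat)
  ifelse(r >= 1, r, -1 / r)
}

#' Fold-change table for every probe of an expression matrix
#'
#' Applies \code{\link{signed_fold}} row by row for a wild-type vs mutant
#' contrast.
#'
#' @param mat Numeric matrix (probes x arrays), positive intensities.
#' @param genotypes Character vector, one of \code{"WT"}/\code{"MUT"} (or
#'   \code{"HET"}, ignored) per column.
#' @return Data frame: \code{probe_id}, \code{signed_fold}, \code{fold_sd},
#'   \code{p_value}.
#' @export
fold_table <- function(mat, genotypes) {
  stopifnot(ncol(mat) == length(genotypes))
  wt <- mat[, genotypes == "WT", drop = FALSE]
  mut <- mat[, genotypes == "MUT", drop = FALSE]
  if (ncol(wt) < 2L || ncol(mut) < 2L)
    stop("need at least 2 replicate arrays per contrasted genotype")
  recs <- lapply(seq_len(nrow(mat)),
                 function(i) signed_fold(wt[i, ], mut[i, ]))
  data.frame(probe_id = rownames(mat),
             signed_fold = vapply(recs, `[[`, numeric(1), "signed_fold"),
             fold_sd = vapply(recs, `[[`, numeric(1), "fold_sd"),
             p_value = vapply(recs, `[[`, numeric(1), "p_value"),
             stringsAsFactors = FALSE)
}

#' Collapse probe sets to one row per gene
#'
#' When several probe sets monitor one gene, the probe set with the highest
#' mean intensity over all arrays is retained (on 3'-biased expression
#' arrays this is generally the 3'-most probe set). Exact ties are broken
#' lexicographically by probe id. Probes absent from the map are passed
#' through unchanged under their probe id.
#'
#' @param mat Numeric matrix (probes x arrays) with probe ids as rownames.
#' @param probe_gene_map Data frame with columns \code{probe_id},
#'   \code{gene}.
#' @return Matrix with one row per gene (plus unmapped probes), rownames
#'   set accordingly.
#' @export
collapse_probe_sets <- function(mat, probe_gene_map) {
  stopifnot(all(c("probe_id", "gene") %in% names(probe_gene_map)))
  mapped <- rownames(mat) %in% probe_gene_map$probe_id
  keep_rows <- character(0)
  genes <- character(0)
  for (g in unique(probe_gene_map$gene)) {
    probes <- probe_gene_map$probe_id[probe_gene_map$gene == g]
    probes <- sort(intersect(probes, rownames(mat)))
    if (length(probes) == 0L) next
    m <- rowMeans(mat[probes, , drop = FALSE])
    best <- probes[which.max(m)]   # which.max takes the first = lexicographic
    keep_rows <- c(keep_rows, best)
    genes <- c(genes, g)
  }
  out <- mat[c(keep_rows, rownames(mat)[!mapped]), , drop = FALSE]
  rownames(out) <- c(genes, rownames(mat)[!mapped])
  out
}

# balanced mixed relabelings for an n-vs-n contrast: subsets of the 2n
# arrays taken as pseudo-WT that mix true genotypes, with mirror pairs
# deduplicated (for 3 vs 3 there are 9)
.null_relabelings <- function(wt_idx, mut_idx) {
  all_idx <- c(wt_idx, mut_idx)
  n <- length(wt_idx)
  stopifnot(length(mut_idx) == n)
  combos <- utils::combn(all_idx, n, simplify = FALSE)
  mixed <- Filter(function(s) {
    nw <- sum(s %in% wt_idx)
    nw > 0L && nw < n
  }, combos)
  # each relabeling and its mirror give the same |fold| counts
  Filter(function(s) all_idx[1] %in% s, mixed)
}

#' Fold-scanning false-discovery-rate curve
#'
#' For each fold cutoff, counts the probes beyond the cutoff in the true
#' wild-type vs mutant contrast and compares that with the mean count over
#' balanced null relabelings of the arrays (label permutations that mix
#' genotypes, excluding the true labeling and its mirror; mirror-equivalent
#' relabelings are counted once). Mixing the genotype labels destroys the
#' true contrast while preserving per-array noise, so the ratio estimates
#' the false discovery rate as a function of fold cutoff.
#'
#' @param mat Numeric matrix (probes x arrays), positive intensities.
#' @param genotypes Character vector of \code{"WT"}/\code{"MUT"} labels per
#'   column; the two groups must be the same size (\eqn{\ge 2}).
#' @param cutoffs Fold thresholds \eqn{\ge 1}.
#' @return Data frame: \code{cutoff}, \code{n_observed}, \code{n_null},
#'   \code{fdr} (\code{NA} where no probe exceeds the cutoff).
#' @export
fold_scan_fdr <- function(mat, genotypes, cutoffs = c(1.2, 1.4, 2.0)) {
  stopifnot(ncol(mat) == length(genotypes))
  if (any(cutoffs < 1)) stop("fold cutoffs must be >= 1")
  wt_idx <- which(genotypes == "WT")
  mut_idx <- which(genotypes == "MUT")
  if (length(wt_idx) != length(mut_idx) || length(wt_idx) < 2L)
    stop("fold scanning needs equal group sizes of at least 2")
  count_beyond <- function(g1, g2) {
    f <- .signed_fold_rows(mat[, g1, drop = FALSE], mat[, g2, drop = FALSE])
    vapply(cutoffs, function(cc) sum(abs(f) > cc), numeric(1))
  }
  obs <- count_beyond(wt_idx, mut_idx)
  labelings <- .null_relabelings(wt_idx, mut_idx)
  all_idx <- c(wt_idx, mut_idx)
  null_counts <- vapply(labelings, function(s) {
    count_beyond(s, setdiff(all_idx, s))
  }, numeric(length(cutoffs)))
  n_null <- if (is.matrix(null_counts)) rowMeans(null_counts)
            else mean(null_counts)
  data.frame(cutoff = cutoffs, n_observed = obs, n_null = n_null,
             fdr = ifelse(obs > 0, n_null / obs, NA_real_))
}

#' Percent of probes regulated, as printed in summary text
#'
#' \code{100 * n_regulated / n_total}, rounded half-up to an integer
#' percent.
#'
#' @param n_regulated,n_total Counts, with
#'   \code{0 <= n_regulated <= n_total} and \code{n_total > 0}.
#' @return Integer percent.
#' @export
fraction_regulated <- function(n_regulated, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_regulated < 0 || n_regulated > n_total)
    stop("need 0 <= n_regulated <= n_total")
  as.integer(floor(100 * n_regulated / n_total + 0.5))
}

#' Reference-normalized relative abundance from qPCR triplicates
#'
#' Efficiency-corrected relative expression of a target transcript in
#' mutants versus wild type, normalized against a reference gene (e.g.
#' Gapdh): \deqn{fold = \frac{S_{MUT}(target)/S_{MUT}(ref)}
#' {S_{WT}(target)/S_{WT}(ref)}} with signals from
#' \code{\link{ct_to_signal}}. Equivalent to the efficiency-corrected
#' delta-delta-Ct method, and invariant both to the \eqn{10^{10}} signal
#' prefactor and to any shift applied equally to all Cts.
#'
#' @param target_wt,target_mut,ref_wt,ref_mut Ct triplicates (numeric, NA
#'   = undetermined well) for the target and reference gene in each
#'   genotype.
#' @param efficiency Amplification efficiency in (1, 2]; default 2.
#' @return List with \code{fold} (mutant vs wild type) and \code{nd}
#'   (\code{TRUE}, with fold \code{NA}, when any component triplicate is
#'   not detected).
#' @export
qpcr_relative_abundance <- function(target_wt, target_mut, ref_wt, ref_mut,
                                    efficiency = 2) {
  ss <- lapply(list(target_wt, target_mut, ref_wt, ref_mut),
               summarize_triplicate, efficiency = efficiency)
  if (!all(vapply(ss, `[[`, logical(1), "detected")))
    return(list(fold = NA_real_, nd = TRUE))
  m <- vapply(ss, `[[`, numeric(1), "mean_signal")
  list(fold = (m[2] / m[4]) / (m[1] / m[3]), nd = FALSE)
}

#' Read a tab-separated expression matrix
#'
#' Header row gives the array labels; first column the probe ids. Lines
#' starting with \code{#} are ignored.
#'
#' @param file Path to the TSV.
#' @return Numeric matrix with probe ids as rownames.
#' @export
read_expression_matrix <- function(file) {
  d <- utils::read.delim(file, check.names = FALSE, comment.char = "#")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix must not contain missing values")
  m
}
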