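#' Normalization coefficient between paired chromatin extracts
#'
#' The ratio of the mean wild-type input signal to the mean mutant input
#' signal, used to put the two precipitates of an extract pair on the same
#' chromatin-amount scale. Values outside [0.5, 2] trigger a warning (a
#' plausibility envelope around the observed experimental range of
#' well-matched extract pairs), not an error.
#'
#' @param wt_input,mut_input Input-fraction measurements for each genotype:
#'   either \code{signal_summary} objects or numeric vectors of per-well
#'   signals.
#' @return The coefficient \eqn{k > 0}.
#' @export
normalization_coefficient <- function(wt_input, mut_input) {
  wm <- .mean_signal(wt_input)
  mm <- .mean_signal(mut_input)
  if (!is.finite(wm) || !is.finite(mm) || wm <= 0 || mm <= 0)
    stop("input signal means must be positive and detected")
  k <- wm / mm
  if (k < 0.5 || k > 2)
    warning(sprintf(
      "normalization coefficient %.3g outside the plausible [0.5, 2] range",
      k))
  k
}

.mean_signal <- function(x) {
  if (inherits(x, "signal_summary")) {
    if (!x$detected) return(NA_real_)
    x$mean_signal
  } else mean(as.numeric(x))
}

.signals_of <- function(x) {
  if (inherits(x, "signal_summary")) x$signals else as.numeric(x)
}

.sd_signal <- function(x) {
  if (inherits(x, "signal_summary")) x$sd_signal else stats::sd(as.numeric(x))
}

.is_detected <- function(x) {
  if (inherits(x, "signal_summary")) x$detected
  else sum(!is.na(x)) >= 2L
}

#' Fold deviation of a normalization coefficient from unity
#'
#' \code{max(k, 1/k)}: how far, in fold, an extract pair is from perfectly
#' matched chromatin amounts regardless of direction.
#'
#' @param k Normalization coefficient(s).
#' @return Numeric vector of fold deviations, all \eqn{\ge 1}.
#' @export
fold_deviation <- function(k) pmax(k, 1 / k)

#' Factor-specific precipitate signal by mutant background subtraction
#'
#' The mutant genotype lacks the immunoprecipitated factor, so its
#' precipitate signal measures collective background (nonspecific capture
#' plus measurement noise) with the identical antibody preparation. The
#' specific signal is the input-normalized wild-type precipitate minus the
#' mutant precipitate; its SD combines the two triplicate SDs in quadrature
#' (first-order propagation, with \eqn{k} treated as a fixed plug-in
#' constant). Negative values are reported as-is, never clamped.
#'
#' @param wt_ppt,mut_ppt Precipitate triplicates (\code{signal_summary} or
#'   numeric signal vectors).
#' @param k Normalization coefficient from
#'   \code{\link{normalization_coefficient}}.
#' @return List with \code{value}, \code{sd} and \code{nd} (TRUE when
#'   either precipitate failed to amplify in at least two wells; value and
#'   sd are then \code{NA}).
#' @export
specific_signal <- function(wt_ppt, mut_ppt, k) {
  if (!.is_detected(wt_ppt) || !.is_detected(mut_ppt))
    return(list(value = NA_real_, sd = NA_real_, nd = TRUE))
  value <- .mean_signal(wt_ppt) / k - .mean_signal(mut_ppt)
  sd <- sqrt((.sd_signal(wt_ppt) / k)^2 + .sd_signal(mut_ppt)^2)
  list(value = value, sd = sd, nd = FALSE)
}

#' Percent of genomes occupied by the factor at a site
#'
#' Divides the factor-specific signal by the average input signal, where
#' wild-type input wells are first normalized by \eqn{k} and then pooled
#' with the mutant input wells. Because inputs measure total genome copies
#' and the specific signal measures factor-bound copies, the ratio is the
#' fraction of genomes in the biopsy occupied at that site (reported as a
#' percentage). The division also cancels amplicon-specific PCR
#' efficiencies.
#'
#' By default the reported SD propagates only the specific-signal SD
#' (\code{100 * specific$sd / input_avg}); with
#' \code{propagate_input_error = TRUE} the relative variance of the pooled
#' input mean (pooled SD / sqrt(n)) is added in quadrature.
#'
#' @param specific Output of \code{\link{specific_signal}}.
#' @param wt_input,mut_input Input triplicates (\code{signal_summary} or
#'   numeric signal vectors).
#' @param k Normalization coefficient.
#' @param propagate_input_error Add the pooled-input variance term
#'   (default \code{FALSE}).
#' @return List with \code{percent}, \code{sd}, \code{input_avg} and
#'   \code{nd}.
#' @export
percent_occupancy <- function(specific, wt_input, mut_input, k,
                              propagate_input_error = FALSE) {
  if (isTRUE(specific$nd))
    return(list(percent = NA_real_, sd = NA_real_, input_avg = NA_real_,
                nd = TRUE))
  pooled <- c(.signals_of(wt_input) / k, .signals_of(mut_input))
  pooled <- pooled[!is.na(pooled)]
  input_avg <- mean(pooled)
  if (!is.finite(input_avg) || input_avg <= 0)
    stop("pooled input mean must be positive")
  percent <- 100 * specific$value / input_avg
  if (propagate_input_error) {
    rel2 <- (specific$sd / specific$value)^2 +
      (stats::sd(pooled) / sqrt(length(pooled)) / input_avg)^2
    sd <- abs(percent) * sqrt(rel2)
  } else {
    sd <- 100 * specific$sd / input_avg
  }
  list(percent = percent, sd = sd, input_avg = input_avg, nd = FALSE)
}

#' Significance code for a two-tailed p-value
#'
#' Maps p-values to the fixed confidence code table:
#' \code{****} (>99.99\%, p < 0.0001), \code{***} (>99\%), \code{**}
#' (>95\%), \code{*} (>90\%), \code{±} (>70\%), \code{ne} (no
#' evidence).
#'
#' @param p Numeric vector of two-tailed p-values.
#' @return Character vector of codes.
#' @export
significance_code <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return("nd")
    if (pp < 1e-4) "****"
    else if (pp < 0.01) "***"
    else if (pp < 0.05) "**"
    else if (pp < 0.1) "*"
    else if (pp < 0.3) "±"
    else "ne"
  }, character(1))
}

#' Two-sample significance of occupancy between genotypes
#'
#' Classical two-sample equal-variance Student's t-test (two-tailed)
#' between input-normalized wild-type precipitate signals and mutant
#' precipitate signals; 3 vs 3 wells give 4 degrees of freedom. Degenerate
#' triplicates with zero pooled variance yield p = 1 (equal means) or the
#' p = 0 limit (unequal means).
#'
#' @param wt_norm_signals Wild-type precipitate signals already divided by
#'   \eqn{k}, so that the test and the point estimate describe the same
#'   quantities.
#' @param mut_signals Mutant precipitate signals.
#' @return List with \code{t}, \code{df}, \code{p_value} and \code{code}.
#' @export
occupancy_significance <- function(wt_norm_signals, mut_signals) {
  x <- wt_norm_signals[!is.na(wt_norm_signals)]
  y <- mut_signals[!is.na(mut_signals)]
  if (length(x) < 2L || length(y) < 2L)
    return(list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                code = "nd"))
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2L
  s2p <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  if (s2p == 0) {
    p <- if (mean(x) == mean(y)) 1 else 0
    return(list(t = if (p == 1) 0 else Inf, df = df, p_value = p,
                code = significance_code(p)))
  }
  tval <- (mean(x) - mean(y)) / sqrt(s2p * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(t = tval, df = df, p_value = p, code = significance_code(p))
}

#' Differential co-factor occupancy between genotypes
#'
#' Same statistical machinery as \code{\link{occupancy_significance}}, but
#' the interpretation differs: co-factors such as histone deacetylases are
#' present in both genotypes, so no background subtraction applies and the
#' code expresses the chance that co-factor occupancy differs between
#' wild type and mutant at the site.
#'
#' @param wt_ppt,mut_ppt Precipitate triplicates (\code{signal_summary} or
#'   numeric signal vectors).
#' @param k Normalization coefficient of the extract pair.
#' @return List with \code{t}, \code{df}, \code{p_value} and \code{code};
#'   code \code{"nd"} when either triplicate failed to amplify.
#' @export
hdac_differential <- function(wt_ppt, mut_ppt, k) {
  if (!.is_detected(wt_ppt) || !.is_detected(mut_ppt))
    return(list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                code = "nd"))
  occupancy_significance(.signals_of(wt_ppt) / k, .signals_of(mut_ppt))
}

#' Per-amplicon occupancy analysis of a ChIP-qPCR plate
#'
#' Runs the full mutant-null occupancy quantification on a plate table (see
#' \code{\link{read_plate_csv}} for the dialect): per extract pair
#' (\code{sample} column) the normalization coefficient is computed from
#' all input wells; per amplicon the wild-type precipitate is normalized,
#' the mutant background subtracted, percent genome occupancy and
#' propagated errors computed, and the wild-type/mutant difference tested.
#' When an amplicon was measured in several extract pairs all are reported
#' and the one with the lowest p-value is flagged as primary.
#'
#' @param plate Plate data frame.
#' @param antibody Which precipitate antibody to analyse (default
#'   \code{"Pitx2"}); input wells are identified by
#'   \code{fraction == "input"} regardless of antibody.
#' @param propagate_input_error Passed to \code{\link{percent_occupancy}}.
#' @return Data frame with one row per (extract pair, amplicon):
#'   \code{amplicon_id}, \code{antibody}, \code{pair_id}, \code{k},
#'   \code{wtppt_norm}, \code{mutppt}, \code{specific_signal},
#'   \code{specific_sd}, \code{input_avg}, \code{percent_occupancy},
#'   \code{percent_sd}, \code{t}, \code{df}, \code{p_value}, \code{code},
#'   \code{primary}.
#' @export
analyze_occupancy <- function(plate, antibody = "Pitx2",
                              propagate_input_error = FALSE) {
  stopifnot(all(.plate_header %in% names(plate)))
  plate$genotype <- toupper(plate$genotype)
  if (!all(plate$genotype %in% c("WT", "MUT")))
    stop("genotype column must contain only WT and MUT")
  rows <- list()
  for (pair in unique(plate$sample)) {
    pp <- plate[plate$sample == pair, , drop = FALSE]
    inp <- pp[pp$fraction == "input", , drop = FALSE]
    if (nrow(inp) == 0L) {
      warning("extract pair '", pair, "' has no input wells; skipped")
      next
    }
    sig <- function(d) ct_to_signal(d$ct, d$efficiency)
    wt_in_all <- sig(inp[inp$genotype == "WT", ])
    mut_in_all <- sig(inp[inp$genotype == "MUT", ])
    k <- normalization_coefficient(wt_in_all[!is.na(wt_in_all)],
                                   mut_in_all[!is.na(mut_in_all)])
    ppt <- pp[pp$fraction == "precipitate" & pp$antibody == antibody, ,
              drop = FALSE]
    for (amp in unique(ppt$amplicon)) {
      wt_d <- ppt[ppt$genotype == "WT" & ppt$amplicon == amp, ]
      mut_d <- ppt[ppt$genotype == "MUT" & ppt$amplicon == amp, ]
      wt_s <- summarize_triplicate(wt_d$ct, wt_d$efficiency[1])
      mut_s <- summarize_triplicate(mut_d$ct, mut_d$efficiency[1])
      # per-amplicon inputs when present, else the pair-level pool
      inp_amp <- inp[inp$amplicon == amp, , drop = FALSE]
      if (nrow(inp_amp) == 0L) inp_amp <- inp
      wt_in <- sig(inp_amp[inp_amp$genotype == "WT", ])
      mut_in <- sig(inp_amp[inp_amp$genotype == "MUT", ])
      spec <- specific_signal(wt_s, mut_s, k)
      if (spec$nd) {
        rows[[length(rows) + 1L]] <- data.frame(
          amplicon_id = amp, antibody = antibody, pair_id = pair, k = k,
          wtppt_norm = NA_real_, mutppt = NA_real_,
          specific_signal = NA_real_, specific_sd = NA_real_,
          input_avg = NA_real_, percent_occupancy = NA_real_,
          percent_sd = NA_real_, t = NA_real_, df = NA_real_,
          p_value = NA_real_, code = "nd", stringsAsFactors = FALSE)
        next
      }
      pct <- percent_occupancy(spec, wt_in, mut_in, k,
                               propagate_input_error = propagate_input_error)
      tst <- occupancy_significance(wt_s$signals / k, mut_s$signals)
      rows[[length(rows) + 1L]] <- data.frame(
        amplicon_id = amp, antibody = antibody, pair_id = pair, k = k,
        wtppt_norm = wt_s$mean_signal / k, mutppt = mut_s$mean_signal,
        specific_signal = spec$value, specific_sd = spec$sd,
        input_avg = pct$input_avg, percent_occupancy = pct$percent,
        percent_sd = pct$sd, t = tst$t, df = tst$df, p_value = tst$p_value,
        code = tst$code, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  # flag, per amplicon, the extract pair with the most significant occupancy
  out$primary <- FALSE
  for (amp in unique(out$amplicon_id)) {
    idx <- which(out$amplicon_id == amp)
    pv <- out$p_value[idx]
    if (all(is.na(pv))) next
    out$primary[idx[which.min(pv)]] <- TRUE
  }
  rownames(out) <- NULL
  out
}
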