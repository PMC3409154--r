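#' Configuration for ChIP-qPCR plate simulation
#'
#' Embodies the additive signal model behind mutant-null background
#' subtraction: the wild-type precipitate captures specific (occupied)
#' plus background genome copies, while the mutant precipitate - the
#' genotype lacking the factor - captures background only.
#'
#' @param true_occupancy Fraction of genomes occupied at a site, in [0, 1];
#'   default 0.02 (2 percent).
#' @param background Fraction of genomes nonspecifically precipitated;
#'   default 0.005.
#' @param genomes Genome copies per reaction; default 3e4 (puts input Cts
#'   near 18 and precipitate Cts in the mid-20s at E = 2).
#' @param ct_noise_sd SD of Gaussian noise on the Ct scale, in cycles;
#'   default 0.15.
#' @param efficiency Amplification efficiency in (1, 2]; default 2.
#' @param capture Capture efficiency of occupied fragments; default 1.
#' @param input_fraction Fraction of the extract sampled as input;
#'   default 1.
#' @param k_range Interval from which the realized chromatin imbalance
#'   between the genotypes (the normalization coefficient) is drawn;
#'   default \code{c(0.6, 1.55)}, the envelope of well-matched extract
#'   pairs.
#' @param fragment_range,fragment_center Sheared chromatin fragment length
#'   envelope in bp (metadata only; defaults 200-500 centered at 300 - the
#'   fragment length does not enter the signal arithmetic).
#' @param seed Integer seed; the generator is a pure function of it.
#' @return A \code{chip_sim_config} list.
#' @export
chip_sim_config <- function(true_occupancy = 0.02, background = 0.005,
                            genomes = 3e4, ct_noise_sd = 0.15,
                            efficiency = 2, capture = 1, input_fraction = 1,
                            k_range = c(0.6, 1.55),
                            fragment_range = c(200, 500),
                            fragment_center = 300, seed = 1L) {
  stopifnot(true_occupancy >= 0, true_occupancy <= 1, background > 0,
            genomes > 0, ct_noise_sd >= 0, capture > 0, input_fraction > 0,
            length(k_range) == 2L, k_range[1] > 0,
            k_range[2] >= k_range[1])
  .check_efficiency(efficiency)
  structure(list(true_occupancy = true_occupancy, background = background,
                 genomes = genomes, ct_noise_sd = ct_noise_sd,
                 efficiency = efficiency, capture = capture,
                 input_fraction = input_fraction, k_range = k_range,
                 fragment_range = fragment_range,
                 fragment_center = fragment_center,
                 seed = as.integer(seed)), class = "chip_sim_config")
}

#' Simulate a matched WT/MUT ChIP-qPCR extract pair
#'
#' For each amplicon the expected precipitate copy numbers are
#' \code{genomes * (background + f * capture)} in wild type and
#' \code{genomes * background} in the mutant (occupancy forced to zero in
#' the genotype lacking the factor); inputs sample \code{genomes *
#' input_fraction} copies. A chromatin-amount imbalance is drawn uniformly
#' from \code{k_range} and applied to the mutant extract, so the realized
#' normalization coefficient falls in that interval. Copy numbers are
#' converted to ideal Cts by inverting the signal equation and Gaussian
#' noise of \code{ct_noise_sd} cycles is added per well; technical
#' triplicates are emitted in the plate CSV dialect.
#'
#' With zero Ct noise the full occupancy pipeline inverts the generator
#' exactly: recovered percent occupancy equals
#' \code{100 * f * capture / input_fraction} to floating-point round-off.
#'
#' @param cfg A \code{\link{chip_sim_config}}.
#' @param amplicons Amplicon set: a character vector of ids (all using
#'   \code{cfg$true_occupancy}) or a data frame with columns
#'   \code{amplicon_id} and \code{true_occupancy}. Default one amplicon
#'   \code{"amp1"}.
#' @param pair_id Extract-pair identifier placed in the \code{sample}
#'   column; default \code{"pair1"}.
#' @param antibody Antibody recorded on precipitate wells; default
#'   \code{"Pitx2"}.
#' @return Plate data frame (see \code{\link{read_plate_csv}}) with
#'   attributes \code{truth} (per-amplicon planted occupancy),
#'   \code{k_true}, and \code{fragment_length} metadata.
#' @export
simulate_chip_pair <- function(cfg, amplicons = "amp1", pair_id = "pair1",
                               antibody = "Pitx2") {
  stopifnot(inherits(cfg, "chip_sim_config"))
  if (is.character(amplicons))
    amplicons <- data.frame(amplicon_id = amplicons,
                            true_occupancy = cfg$true_occupancy,
                            stringsAsFactors = FALSE)
  stopifnot(all(c("amplicon_id", "true_occupancy") %in% names(amplicons)))
  set.seed(cfg$seed)
  k_true <- stats::runif(1, cfg$k_range[1], cfg$k_range[2])
  wt_amount <- cfg$genomes
  mut_amount <- cfg$genomes / k_true
  rows <- list()
  well <- 0L
  emit <- function(copies, genotype, fraction, ab, amp) {
    ct_ideal <- signal_to_ct(copies, cfg$efficiency)
    for (r in 1:3) {
      well <<- well + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        well = sprintf("W%03d", well), sample = pair_id,
        genotype = genotype, fraction = fraction, antibody = ab,
        amplicon = amp,
        ct = ct_ideal + stats::rnorm(1, 0, cfg$ct_noise_sd),
        efficiency = cfg$efficiency, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(amplicons))) {
    amp <- amplicons$amplicon_id[i]
    f <- amplicons$true_occupancy[i]
    emit(wt_amount * cfg$input_fraction, "WT", "input", "none", amp)
    emit(mut_amount * cfg$input_fraction, "MUT", "input", "none", amp)
    emit(wt_amount * (cfg$background + f * cfg$capture), "WT",
         "precipitate", antibody, amp)
    emit(mut_amount * cfg$background, "MUT", "precipitate", antibody, amp)
  }
  plate <- do.call(rbind, rows)
  attr(plate, "truth") <- amplicons
  attr(plate, "k_true") <- k_true
  attr(plate, "fragment_length") <- list(range = cfg$fragment_range,
                                         center = cfg$fragment_center)
  plate
}

#' Configuration for expression-matrix simulation
#'
#' Emulates the pooled-replicate microarray design: three replicate arrays
#' per genotype, each from a pool of embryos, with log-normal baseline
#' intensities, multiplicative array noise at a given coefficient of
#' variation, a planted regulated subset, and an optional outlier replicate
#' set with inflated noise.
#'
#' @param n_genes Number of genes; default 200.
#' @param n_replicates Replicate arrays per genotype; default 3.
#' @param regulated_fraction Fraction of genes given a planted fold;
#'   default 0.05.
#' @param fold_meanlog,fold_sdlog Log-normal parameters for planted fold
#'   magnitudes; defaults \code{log(2)} and 0.4.
#' @param fold_min Floor on planted fold magnitudes; default 1.2.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline intensity
#'   parameters; defaults \code{log(500)} and 1.
#' @param cv Per-array multiplicative noise coefficient of variation;
#'   default 0.10.
#' @param outlier_set Inflate the noise of one replicate set (its WT and
#'   MUT arrays); default \code{FALSE}.
#' @param outlier_factor Noise inflation factor for the outlier set;
#'   default 3.
#' @param planted_folds Optional named numeric vector (names = gene ids
#'   such as \code{"gene_001"}) of signed folds to plant exactly,
#'   overriding the random draw for those genes.
#' @param seed Integer seed.
#' @return An \code{expr_sim_config} list.
#' @export
expr_sim_config <- function(n_genes = 200L, n_replicates = 3L,
                            regulated_fraction = 0.05,
                            fold_meanlog = log(2), fold_sdlog = 0.4,
                            fold_min = 1.2, baseline_meanlog = log(500),
                            baseline_sdlog = 1, cv = 0.10,
                            outlier_set = FALSE, outlier_factor = 3,
                            planted_folds = NULL, seed = 1L) {
  stopifnot(n_genes >= 1, n_replicates >= 2, regulated_fraction >= 0,
            regulated_fraction <= 1, fold_min >= 1, cv >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 regulated_fraction = regulated_fraction,
                 fold_meanlog = fold_meanlog, fold_sdlog = fold_sdlog,
                 fold_min = fold_min, baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, cv = cv,
                 outlier_set = outlier_set, outlier_factor = outlier_factor,
                 planted_folds = planted_folds, seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Simulate an expression matrix with known planted folds
#'
#' Each gene gets a log-normal baseline mean; regulated genes multiply the
#' mutant mean by their planted signed fold (divide by its magnitude when
#' negative). Per-array noise is multiplicative log-normal with the
#' configured CV, mean-one, so the planted fold is the expected
#' ratio of means. The truth table records every gene's planted fold
#' (1 for unregulated genes).
#'
#' @param cfg An \code{\link{expr_sim_config}}.
#' @return List with \code{matrix} (genes x arrays), \code{genotypes},
#'   \code{replicate_set} (per-column labels) and \code{truth} (data frame
#'   \code{gene_id}, \code{planted_fold}).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes; nr <- cfg$n_replicates
  gene_id <- sprintf("gene_%03d", seq_len(ng))
  base <- stats::rlnorm(ng, cfg$baseline_meanlog, cfg$baseline_sdlog)
  fold <- rep(1, ng)
  n_reg <- round(cfg$regulated_fraction * ng)
  if (n_reg > 0) {
    idx <- sample.int(ng, n_reg)
    mag <- pmax(cfg$fold_min,
                stats::rlnorm(n_reg, cfg$fold_meanlog, cfg$fold_sdlog))
    sgn <- sample(c(-1, 1), n_reg, replace = TRUE)
    fold[idx] <- ifelse(sgn > 0, mag, -mag)
  }
  if (!is.null(cfg$planted_folds)) {
    j <- match(names(cfg$planted_folds), gene_id)
    if (anyNA(j)) stop("planted_folds names must be gene ids")
    fold[j] <- cfg$planted_folds
  }
  mut_mean <- ifelse(fold >= 1, base * fold, base / abs(fold))
  sdlog <- sqrt(log(1 + cfg$cv^2))
  sdlog_out <- sqrt(log(1 + (cfg$cv * cfg$outlier_factor)^2))
  cols <- c(paste0("WT_set", seq_len(nr)), paste0("MUT_set", seq_len(nr)))
  genotypes <- rep(c("WT", "MUT"), each = nr)
  replicate_set <- rep(paste0("set", seq_len(nr)), times = 2)
  mat <- matrix(0, ng, 2 * nr, dimnames = list(gene_id, cols))
  for (j in seq_len(2 * nr)) {
    s <- if (cfg$outlier_set && replicate_set[j] == paste0("set", nr))
      sdlog_out else sdlog
    mu <- if (genotypes[j] == "WT") base else mut_mean
    mat[, j] <- mu * stats::rlnorm(ng, -s^2 / 2, s)
  }
  list(matrix = mat, genotypes = genotypes, replicate_set = replicate_set,
       truth = data.frame(gene_id = gene_id, planted_fold = fold,
                          stringsAsFactors = FALSE))
}

.default_species <- c("mouse", "rat", "human", "chimp", "dog", "cow",
                      "horse", "elephant", "opossum", "chicken", "frog",
                      "zebrafish")

#' Configuration for synthetic multi-species alignment generation
#'
#' The default configuration is the bundled demo locus: a 6 kb reference
#' over 12 named vertebrates with three motif sites planted at
#' species-conservation counts 4, 6 and 7 (reference included), so that
#' the default conservation threshold of 6 retains exactly two candidate
#' sites. Species names are arbitrary placeholder strings.
#'
#' @param n_species Number of species (reference first); at most 20.
#' @param seq_length Reference sequence length in bp.
#' @param planted_sites List of planted sites, each a list with \code{pos}
#'   (0-based start of the hexamer on the reference) and either
#'   \code{n_species} (conservation count, reference included) or
#'   \code{species} (explicit conserving subset including the reference).
#' @param gap_rate Per-base deletion rate in non-reference rows;
#'   default 0.02.
#' @param substitution_rate Per-base substitution rate in non-reference
#'   rows; default 0.10.
#' @param n_insertions Number of insertion columns (reference gap, other
#'   species a base); default 5.
#' @param motif IUPAC consensus being planted; default \code{"TAATCY"}
#'   (planted realization \code{TAATCC}).
#' @param species Species name panel; default 12 placeholder vertebrates.
#' @param seed Integer seed.
#' @return An \code{aln_sim_config} list.
#' @export
aln_sim_config <- function(n_species = 12L, seq_length = 6000L,
                           planted_sites = list(
                             list(pos = 1000L, n_species = 4L),
                             list(pos = 2500L, n_species = 6L),
                             list(pos = 4200L, n_species = 7L)),
                           gap_rate = 0.02, substitution_rate = 0.10,
                           n_insertions = 5L, motif = "TAATCY",
                           species = .default_species, seed = 1L) {
  stopifnot(n_species >= 1, n_species <= 20, seq_length >= 10)
  species <- species[seq_len(n_species)]
  w <- nchar(motif)
  pos <- vapply(planted_sites, function(s) as.integer(s$pos), integer(1))
  if (length(pos) > 1L) {
    o <- order(pos)
    if (any(diff(pos[o]) < w)) stop("planted sites must not overlap")
  }
  if (any(pos < 0L | pos + w > seq_length))
    stop("planted sites must lie within the sequence")
  structure(list(n_species = as.integer(n_species),
                 seq_length = as.integer(seq_length),
                 planted_sites = planted_sites, gap_rate = gap_rate,
                 substitution_rate = substitution_rate,
                 n_insertions = as.integer(n_insertions),
                 motif = toupper(motif), species = species,
                 seed = as.integer(seed)), class = "aln_sim_config")
}

# remove every occurrence of the motif (both strands) from a character
# vector sequence, leaving the protected windows untouched
.scrub_motifs <- function(chars, motif, protected) {
  pat_f <- paste0("(?=", .iupac_regex(motif), ")")
  pat_r <- paste0("(?=", .iupac_regex(.revcomp_chr(motif)), ")")
  w <- nchar(motif)
  for (iter in 1:50) {
    s <- paste(chars, collapse = "")
    hits <- c(unlist(gregexpr(pat_f, s, perl = TRUE)),
              unlist(gregexpr(pat_r, s, perl = TRUE)))
    hits <- hits[hits > 0]
    # leave the planted hexamers themselves alone; anything with a free
    # base (including partial overlaps with a planted window) is scrubbed
    hits <- hits[!vapply(hits, function(h)
      all(seq(h, h + w - 1L) %in% protected), logical(1))]
    if (length(hits) == 0L) return(chars)
    for (h in hits) {
      free <- setdiff(seq(h, h + w - 1L), protected)
      if (length(free) == 0L) next
      i <- free[ceiling(length(free) / 2)]
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
  }
  stop("could not scrub accidental motifs from background sequence")
}

.iupac_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  paste(vapply(chars, function(ch) {
    set <- Biostrings::IUPAC_CODE_MAP[[ch]]
    if (nchar(set) == 1L) set else paste0("[", set, "]")
  }, character(1)), collapse = "")
}

.revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Simulate a multi-species alignment with planted conserved motifs
#'
#' Generates a motif-free random reference sequence, plants a concrete
#' motif realization (\code{TAATCC} for the default consensus) at the
#' configured positions, then derives the other species rows by copying
#' the reference and applying random substitutions and deletions outside
#' the planted hexamers. Species in a site's conserving subset keep the
#' hexamer intact; all others have its first base changed so the site
#' cannot match on either strand. A few insertion columns (gap in the
#' reference) exercise coordinate-to-column mapping. The scanner and
#' annotator therefore recover exactly the planted positions and
#' conservation counts.
#'
#' @param cfg An \code{\link{aln_sim_config}}.
#' @return List with \code{block} (an \code{\link{alignment_block}}) and
#'   \code{truth} (BED-like data frame: \code{chrom}, \code{start},
#'   \code{end}, \code{name}, \code{score} = intended conservation count,
#'   \code{strand}).
#' @export
simulate_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "aln_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$seq_length
  w <- nchar(cfg$motif)
  species <- cfg$species
  ref_name <- species[1]
  # planted hexamer: concrete realization of the consensus
  realization <- strsplit(gsub("Y", "C", gsub("R", "G", cfg$motif)), "")[[1]]
  protected <- unlist(lapply(cfg$planted_sites, function(s)
    seq(s$pos + 1L, s$pos + w)))
  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  for (s in cfg$planted_sites)
    ref[(s$pos + 1L):(s$pos + w)] <- realization
  ref <- .scrub_motifs(ref, cfg$motif, protected)
  # conserving subsets (always include the reference)
  subsets <- lapply(cfg$planted_sites, function(s) {
    if (!is.null(s$species)) {
      sub <- unique(c(ref_name, s$species))
    } else {
      k <- as.integer(s$n_species)
      stopifnot(k >= 1, k <= length(species))
      sub <- c(ref_name, sample(species[-1], k - 1L))
    }
    sub
  })
  rows <- matrix("", nrow = length(species), ncol = L,
                 dimnames = list(species, NULL))
  rows[1, ] <- ref
  free <- setdiff(seq_len(L), protected)
  for (i in seq_along(species)[-1]) {
    r <- ref
    sub_at <- free[stats::runif(length(free)) < cfg$substitution_rate]
    for (p in sub_at)
      r[p] <- sample(setdiff(c("A", "C", "G", "T"), r[p]), 1)
    gap_at <- free[stats::runif(length(free)) < cfg$gap_rate]
    r[gap_at] <- "-"
    for (j in seq_along(cfg$planted_sites)) {
      s <- cfg$planted_sites[[j]]
      if (!(species[i] %in% subsets[[j]]))
        r[s$pos + 1L] <- "G"       # breaks TAATCY and RGATTA alike
    }
    rows[i, ] <- r
  }
  # insertion columns: reference gap, other species a random base
  if (cfg$n_insertions > 0L) {
    at <- sort(sample(setdiff(seq_len(L - 1L), protected),
                      cfg$n_insertions))
    out <- matrix("", nrow = length(species),
                  ncol = L + cfg$n_insertions,
                  dimnames = list(species, NULL))
    shift <- 0L
    prev <- 0L
    for (a in at) {
      cols <- (prev + 1L):a
      out[, cols + shift] <- rows[, cols, drop = FALSE]
      ins <- c("-", sample(c("A", "C", "G", "T"), length(species) - 1L,
                           replace = TRUE))
      out[, a + shift + 1L] <- ins
      shift <- shift + 1L
      prev <- a
    }
    if (prev < L) out[, (prev + shift + 1L):(L + shift)] <-
        rows[, (prev + 1L):L, drop = FALSE]
    rows <- out
  }
  block <- alignment_block(apply(rows, 1L, paste, collapse = ""),
                           ref_species = ref_name)
  np <- length(cfg$planted_sites)
  truth <- data.frame(
    chrom = rep("chr1", np),
    start = vapply(cfg$planted_sites, function(s) as.integer(s$pos),
                   integer(1)),
    end = vapply(cfg$planted_sites, function(s) as.integer(s$pos) + w,
                 integer(1)),
    name = sprintf("planted_%d", seq_len(np)),
    score = vapply(subsets, length, integer(1)),
    strand = rep("+", np), stringsAsFactors = FALSE)
  list(block = block, truth = truth)
}
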