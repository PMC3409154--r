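#' @importFrom Biostrings DNAString matchPattern reverseComplement IUPAC_CODE_MAP
NULL

.check_iupac <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0L)
    stop("invalid IUPAC character(s) in motif: ", paste(bad, collapse = ", "))
  chars
}

# TRUE if the concrete characters `chars` (reference orientation) satisfy the
# IUPAC pattern `pattern_chars` position by position; gaps and N never match.
.iupac_ok <- function(chars, pattern_chars) {
  if (length(chars) != length(pattern_chars)) return(FALSE)
  for (i in seq_along(chars)) {
    allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[pattern_chars[i]]], "")[[1]]
    if (!(chars[i] %in% c("A", "C", "G", "T")) || !(chars[i] %in% allowed))
      return(FALSE)
  }
  TRUE
}

.empty_sites <- function(block, motif) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    strand = character(), hexamer = character(),
                    n_species = integer(), stringsAsFactors = FALSE)
  out$conserved_species <- list()
  structure(out, class = c("motif_sites", "data.frame"),
            motif = toupper(motif), ref_species = block$ref_species,
            ref_start = block$ref_start,
            seq_length = nchar(ref_sequence(block)))
}

#' Scan the reference sequence of an alignment for core-motif occurrences
#'
#' Finds every occurrence of an IUPAC consensus (default the bicoid-class
#' homeodomain core \code{TAATCY}) on the gap-free reference sequence. Both
#' strands are scanned by default: homeodomain cores are orientation
#' independent, so the reverse complement (\code{RGATTA} for \code{TAATCY})
#' is reported as a minus-strand site with the reference-strand hexamer
#' recorded. Overlapping occurrences are all reported; sites are sorted by
#' start, then strand (\code{+} before \code{-}). Ambiguity codes in the
#' reference (\code{N}) never match.
#'
#' Returned sites carry a \code{conserved_species} list column initialised
#' to the reference species alone; use \code{\link{annotate_conservation}}
#' to fill in the other species.
#'
#' @param block An \code{\link{alignment_block}}, or a plain character
#'   sequence (treated as a single-species block named \code{"ref"}).
#' @param motif IUPAC consensus string; default \code{"TAATCY"}.
#' @param both_strands Scan the reverse complement as well (default
#'   \code{TRUE}); \code{FALSE} restores forward-only scanning.
#' @return A \code{motif_sites} data frame with columns \code{chrom},
#'   \code{start}, \code{end} (0-based half-open reference coordinates),
#'   \code{strand}, \code{hexamer}, \code{n_species} and the list column
#'   \code{conserved_species}.
#' @examples
#' scan_reference_motifs(alignment_block(c(mouse = "GGTAATCCAA")))
#' @export
scan_reference_motifs <- function(block, motif = "TAATCY",
                                  both_strands = TRUE) {
  if (is.character(block) && length(block) == 1L)
    block <- alignment_block(c(ref = block))
  stopifnot(inherits(block, "alignment_block"))
  .check_iupac(motif)
  refseq <- ref_sequence(block)
  if (nchar(refseq) == 0L) return(.empty_sites(block, motif))
  subject <- Biostrings::DNAString(refseq)
  pat_fwd <- Biostrings::DNAString(toupper(motif))
  hit_df <- function(pat, strand) {
    m <- Biostrings::matchPattern(pat, subject, fixed = "subject")
    if (length(m) == 0L) return(NULL)
    data.frame(start = BiocGenerics::start(m) - 1L,
               end = BiocGenerics::end(m),
               strand = strand,
               hexamer = as.character(m), stringsAsFactors = FALSE)
  }
  hits <- hit_df(pat_fwd, "+")
  if (both_strands) {
    rc <- Biostrings::reverseComplement(pat_fwd)
    hits <- rbind(hits, hit_df(rc, "-"))
  }
  if (is.null(hits) || nrow(hits) == 0L) return(.empty_sites(block, motif))
  hits <- hits[order(hits$start, match(hits$strand, c("+", "-"))), ,
               drop = FALSE]
  rownames(hits) <- NULL
  out <- data.frame(chrom = block$ref_chrom,
                    start = block$ref_start + hits$start,
                    end = block$ref_start + hits$end,
                    strand = hits$strand, hexamer = hits$hexamer,
                    n_species = 1L, stringsAsFactors = FALSE)
  out$conserved_species <- rep(list(block$ref_species), nrow(out))
  structure(out, class = c("motif_sites", "data.frame"),
            motif = toupper(motif), ref_species = block$ref_species,
            ref_start = block$ref_start, seq_length = nchar(refseq))
}

#' Annotate motif sites with species conservation
#'
#' For each site, the six reference bases are mapped to their alignment
#' columns; a species is recorded as conserving the site if and only if its
#' characters at those columns, read on the site's strand, match the motif
#' pattern with no gaps and no \code{N} (columnar orthology: nearby sequence
#' is not re-searched). The reference species always conserves its own sites
#' by construction.
#'
#' @param block The \code{\link{alignment_block}} the sites came from.
#' @param sites A \code{motif_sites} data frame from
#'   \code{\link{scan_reference_motifs}}.
#' @param motif IUPAC consensus; defaults to the motif recorded on
#'   \code{sites}.
#' @return \code{sites} with \code{conserved_species} and \code{n_species}
#'   filled in.
#' @export
annotate_conservation <- function(block, sites,
                                  motif = attr(sites, "motif")) {
  stopifnot(inherits(block, "alignment_block"))
  if (is.null(motif)) motif <- "TAATCY"
  pat_fwd <- .check_iupac(motif)
  pat_rev <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(motif)))), "")[[1]]
  if (nrow(sites) == 0L) return(sites)
  refseq_len <- nchar(ref_sequence(block))
  row_mat <- do.call(rbind, strsplit(unname(block$rows), ""))
  rownames(row_mat) <- names(block$rows)
  ref_cols <- which(row_mat[block$ref_species, ] != "-")
  width <- nchar(motif)
  species <- names(block$rows)
  for (i in seq_len(nrow(sites))) {
    rel <- sites$start[i] - block$ref_start
    if (rel < 0L || rel + width > refseq_len)
      stop("site at ", sites$start[i], " outside block reference span")
    cols <- ref_cols[(rel + 1L):(rel + width)]
    pat <- if (sites$strand[i] == "+") pat_fwd else pat_rev
    keep <- vapply(species, function(sp) .iupac_ok(row_mat[sp, cols], pat),
                   logical(1))
    conserved <- union(block$ref_species, species[keep])
    sites$conserved_species[[i]] <- conserved
    sites$n_species[i] <- length(conserved)
  }
  sites
}

#' Select candidate sites by conservation depth
#'
#' Retains sites conserved in at least \code{min_species} species (the
#' reference included), preserving coordinate order. Deeply conserved core
#' motifs are the candidate cis-regulatory modules taken forward to amplicon
#' design.
#'
#' @param sites Annotated \code{motif_sites}.
#' @param min_species Minimum conservation count; default 6.
#' @return The retained subset of \code{sites}.
#' @export
select_candidate_sites <- function(sites, min_species = 6L) {
  if (!is.numeric(min_species) || min_species < 1)
    stop("min_species must be >= 1")
  keep <- sites$n_species >= min_species
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("motif", "ref_species", "ref_start", "seq_length")] <-
    attributes(sites)[c("motif", "ref_species", "ref_start", "seq_length")]
  out
}

#' Design PCR amplicon windows around motif sites
#'
#' Each window is centered on the motif midpoint (the left flank is rounded
#' down when the split is odd) and clipped to the sequence bounds; if
#' clipping would shorten the window below 70 bp it is instead shifted
#' inward to preserve \code{target_len}. Every returned window has length in
#' [70, 150] and fully contains its motif.
#'
#' @param sites \code{motif_sites} (one or more rows).
#' @param seq_length Reference sequence length in bp; defaults to the length
#'   recorded on \code{sites}.
#' @param target_len Target amplicon length in bp, within [70, 150];
#'   default 110.
#' @return Data frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{site_id}, \code{length}.
#' @export
design_amplicon_window <- function(sites, seq_length = attr(sites, "seq_length"),
                                   target_len = 110L) {
  if (target_len < 70L || target_len > 150L)
    stop("target_len must be within [70, 150]")
  if (is.null(seq_length)) stop("seq_length is required")
  if (seq_length < 70L)
    stop("sequence of length ", seq_length,
         " cannot host a 70 bp amplicon window")
  offset <- attr(sites, "ref_start")
  if (is.null(offset)) offset <- 0L
  n <- nrow(sites)
  out <- data.frame(chrom = character(n), start = integer(n),
                    end = integer(n), site_id = character(n),
                    length = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- sites$start[i] - offset
    e <- sites$end[i] - offset
    if (s < 0L || e > seq_length)
      stop("site at ", sites$start[i], " outside [0, seq_length)")
    mid <- (s + e) %/% 2L
    ws <- mid - target_len %/% 2L
    we <- ws + target_len
    cs <- max(0L, ws)
    ce <- min(seq_length, we)
    if (ce - cs < 70L) {           # shift inward, preserving target_len
      cs <- max(0L, min(ws, seq_length - target_len))
      ce <- cs + target_len
    }
    if (cs > s || ce < e)          # never emit a window missing its motif
      stop("window for site at ", sites$start[i], " cannot contain the motif")
    out$chrom[i] <- sites$chrom[i]
    out$start[i] <- offset + cs
    out$end[i] <- offset + ce
    out$site_id[i] <- sprintf("site_%d_%s", sites$start[i], sites$strand[i])
    out$length[i] <- ce - cs
  }
  out
}

#' Select motif-free control regions
#'
#' Greedy left-to-right selection of up to \code{n} non-overlapping regions
#' of \code{region_len} bp such that no motif site (any strand, any
#' conservation level) lies within \code{exclusion} bp of the region on
#' either side. Fewer than \code{n} regions are returned when the sequence
#' is exhausted.
#'
#' @param seq_length Reference sequence length in bp.
#' @param all_sites The complete, unfiltered \code{motif_sites} table.
#' @param region_len Control region length in bp; default 110.
#' @param exclusion Exclusion margin in bp; default 1000.
#' @param n Maximum number of regions.
#' @return Data frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{length}.
#' @export
select_control_regions <- function(seq_length, all_sites, region_len = 110L,
                                   exclusion = 1000L, n = 3L) {
  offset <- attr(all_sites, "ref_start")
  if (is.null(offset)) offset <- 0L
  chrom <- if (nrow(all_sites) > 0L) all_sites$chrom[1] else "chr1"
  ss <- all_sites$start - offset
  se <- all_sites$end - offset
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    length = integer(), stringsAsFactors = FALSE)
  pos <- 0L
  while (nrow(out) < n && pos + region_len <= seq_length) {
    lo <- pos - exclusion
    hi <- pos + region_len + exclusion
    clash <- which(se > lo & ss < hi)
    if (length(clash) == 0L) {
      out <- rbind(out, data.frame(chrom = chrom, start = offset + pos,
                                   end = offset + pos + region_len,
                                   length = region_len,
                                   stringsAsFactors = FALSE))
      pos <- pos + region_len
    } else {
      # jump past the leftmost conflicting site's exclusion zone
      pos <- max(pos + 1L, min(se[clash]) + exclusion)
    }
  }
  rownames(out) <- NULL
  out
}

#' Export motif sites as BED6
#'
#' Writes a standard 0-based half-open BED6 file: the score column carries
#' the species-conservation count and the strand column the motif strand.
#'
#' @param sites Annotated \code{motif_sites}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
export_sites_bed <- function(sites, file) {
  if (nrow(sites) == 0L) {
    writeLines(character(0), file)
    return(invisible(file))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = sites$strand,
    name = sprintf("site_%d_%s", sites$start, sites$strand),
    score = sites$n_species)
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
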